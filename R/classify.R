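# Multi-class linear discriminant classification of per-epoch features:
# one Fisher discriminant per unordered pair of the six EEG states
# (1S1, 1S2, 2S1, 2S2, 3, 4), combined by voting; state decisions are
# merged to four grades and post-processed by a majority vote over the
# recording, with a two-thirds majority marking a certain decision.

STATE_LEVELS <- c("1S1", "1S2", "2S1", "2S2", "3", "4")

#' Fit one pairwise Fisher discriminant
#'
#' Closed-form maximiser of the Fisher criterion
#' `J(w) = |m1 - m2|^2 / (s1^2 + s2^2)`: `w` is proportional to
#' `Sw^-1 (mu_i - mu_j)` with `Sw` the pooled within-class scatter,
#' ridge-regularised (`lambda = 1e-6 * trace(Sw)/d`) when near-singular.
#' `w` is scaled to unit norm; projected class centres and scatters
#' (root-mean-square deviations, 1/n convention) are stored for the
#' scatter-scaled distance decision rule.
#'
#' @param x_i,x_j Numeric matrices of feature samples (rows = epochs) for
#'   the two classes; at least 2 rows each.
#' @param classes Length-2 character vector of class labels `(i, j)`.
#' @return A `pair_lda` list with `w`, `centres`, `scatters`, `classes`,
#'   `J`.
#' @export
fit_pair <- function(x_i, x_j, classes = c("i", "j")) {
  x_i <- as.matrix(x_i); x_j <- as.matrix(x_j)
  stopifnot(nrow(x_i) >= 2L, nrow(x_j) >= 2L, ncol(x_i) == ncol(x_j))
  d <- ncol(x_i)
  mu_i <- colMeans(x_i); mu_j <- colMeans(x_j)
  ci <- sweep(x_i, 2L, mu_i); cj <- sweep(x_j, 2L, mu_j)
  Sw <- crossprod(ci) + crossprod(cj)
  lam <- 1e-6 * sum(diag(Sw)) / d
  w <- tryCatch(solve(Sw, mu_i - mu_j),
                error = function(e) solve(Sw + diag(lam + 1e-12, d), mu_i - mu_j))
  nrm <- sqrt(sum(w^2))
  if (nrm > 0) w <- w / nrm
  y_i <- drop(x_i %*% w); y_j <- drop(x_j %*% w)
  proj_scatter <- function(y) sqrt(mean((y - mean(y))^2))
  s_i <- proj_scatter(y_i); s_j <- proj_scatter(y_j)
  J <- (mean(y_i) - mean(y_j))^2 / max(s_i^2 + s_j^2, 1e-300)
  structure(list(w = w, centres = c(mean(y_i), mean(y_j)),
                 scatters = c(s_i, s_j), classes = classes, J = J),
            class = "pair_lda")
}

#' Classify a sample with one pairwise discriminant
#'
#' The sample is projected onto `w` and assigned to the class whose
#' projected centre is nearer in scatter-scaled (Mahalanobis-style)
#' distance `|y - m| / s`. Exact ties go to the class listed first (the
#' lower-numbered state).
#'
#' @param model A `pair_lda`.
#' @param x Numeric feature vector (normalised with the training
#'   normalisation model).
#' @return List with `class` and `margin` (absolute scaled-distance
#'   difference).
#' @export
classify_pair <- function(model, x) {
  y <- sum(model$w * x)
  s <- pmax(model$scatters, 1e-12)
  d <- abs(y - model$centres) / s
  k <- if (d[2L] < d[1L]) 2L else 1L
  list(class = model$classes[k], margin = abs(d[1L] - d[2L]),
       distances = stats::setNames(d, model$classes))
}

#' Fit all pairwise discriminants over the observed classes
#'
#' @param features Matrix or data frame of normalised feature samples.
#' @param labels Character vector of class labels per row.
#' @return A `pairwise_lda`: list of `pair_lda` models (one per unordered
#'   class pair) plus the class list.
#' @export
fit_pairwise <- function(features, labels) {
  x <- as.matrix(features)
  classes <- STATE_LEVELS[STATE_LEVELS %in% unique(labels)]
  if (length(classes) < 2L) stop("need at least two classes to fit a classifier")
  pairs <- utils::combn(classes, 2L, simplify = FALSE)
  models <- purrr::map(pairs, function(p) {
    fit_pair(x[labels == p[1L], , drop = FALSE],
             x[labels == p[2L], , drop = FALSE], classes = p)
  })
  structure(list(models = models, classes = classes,
                 features = colnames(x)), class = "pairwise_lda")
}

#' Classify one epoch by combining all pairwise votes
#'
#' Every pairwise discriminant votes; the class with most votes wins.
#' Vote ties are broken by the smallest total scaled distance accumulated
#' over the pairwise decisions, then by the lower-numbered state.
#'
#' @param models A `pairwise_lda`.
#' @param x Normalised feature vector for one epoch.
#' @return The winning 6-state label.
#' @export
classify_epoch <- function(models, x) {
  cls <- models$classes
  votes <- stats::setNames(numeric(length(cls)), cls)
  dist_sum <- stats::setNames(numeric(length(cls)), cls)
  for (m in models$models) {
    r <- classify_pair(m, x)
    votes[r$class] <- votes[r$class] + 1
    dist_sum[m$classes] <- dist_sum[m$classes] + r$distances[m$classes]
  }
  top <- which(votes == max(votes))
  if (length(top) > 1L) {
    top <- top[order(dist_sum[top], match(cls[top], STATE_LEVELS))][1L]
  }
  cls[top]
}

#' Merge the six EEG states into four grades
#'
#' `1S1`/`1S2` become grade 1, `2S1`/`2S2` grade 2; grades 3 and 4 map to
#' themselves.
#'
#' @param state Character vector of 6-state labels.
#' @return Integer vector of grades 1-4.
#' @export
merge_states <- function(state) {
  map <- c("1S1" = 1L, "1S2" = 1L, "2S1" = 2L, "2S2" = 2L, "3" = 3L, "4" = 4L)
  if (!all(state %in% names(map))) {
    stop("unknown state label: ", paste(setdiff(state, names(map)), collapse = ", "))
  }
  unname(map[state])
}

#' Majority vote over per-epoch grades
#'
#' Selects the modal grade across the recording's epochs. The decision is
#' certain when the modal fraction reaches two thirds. Modal ties are
#' broken towards the more severe (higher) grade.
#'
#' @param epoch_grades Integer vector of per-epoch 4-level grades (>= 1
#'   epoch).
#' @return A `grade_decision`: list with `final_grade`, `vote_fraction`,
#'   `certain`, `tallies` and `epoch_grades`.
#' @export
majority_vote <- function(epoch_grades) {
  if (!length(epoch_grades)) stop("majority vote requires at least one epoch")
  tal <- table(factor(epoch_grades, levels = 1:4))
  top <- which(tal == max(tal))
  final <- max(as.integer(names(tal)[top]))   # severity tie-break
  frac <- max(tal) / length(epoch_grades)
  structure(list(final_grade = final, vote_fraction = as.numeric(frac),
                 certain = frac >= 2 / 3, tallies = tal,
                 epoch_grades = epoch_grades),
            class = "grade_decision")
}

#' @export
print.grade_decision <- function(x, ...) {
  cat(sprintf("<grade_decision> grade %d (%.0f%% of %d epochs, %s)\n",
              x$final_grade, 100 * x$vote_fraction, length(x$epoch_grades),
              if (x$certain) "certain" else "uncertain"))
  invisible(x)
}

#' Train the automated grading system on labelled recordings
#'
#' Runs the full pipeline on each training record (high-pass, downsample,
#' segment, AM/IF features), keeps artefact-free epochs, subsamples each
#' record to at most `train_minutes` minutes' worth of epochs (randomly,
#' under `seed`), fits the Box-Cox normalisation on the pooled training
#' epochs, and fits the pairwise Fisher classifier on the 6-state truth
#' labels.
#'
#' @param records Named list of `eeg_record`s with grade truth.
#' @param params A [preprocess_params()].
#' @param feature_subset Optional character vector of feature names to use
#'   (default: all sixteen).
#' @param train_minutes Per-record cap on training data, minutes.
#' @param seed Seed for the per-record epoch subsample.
#' @return An `ags_model` with the normalisation model, pairwise
#'   classifier, parameters and feature names.
#' @export
train_ags <- function(records, params = preprocess_params(),
                      feature_subset = NULL, train_minutes = 7, seed = 1) {
  feature_subset <- feature_subset %||% FEATURE_NAMES
  tabs <- purrr::imap(records, function(rec, id) {
    ft <- ags_epoch_features(rec, params)
    ft$label <- epoch_truth_labels_from_tab(ft, rec$truth$grade4)
    ft[!ft$artefact, , drop = FALSE]
  })
  max_epochs <- max(1L, floor(train_minutes * 60 /
                                (params$epoch_length * (1 - params$overlap_fraction))))
  tabs <- with_seed(seed, purrr::map(tabs, function(tt) {
    if (nrow(tt) > max_epochs) tt[sort(sample.int(nrow(tt), max_epochs)), ] else tt
  }))
  train <- dplyr::bind_rows(tabs)
  if (!nrow(train)) stop("no artefact-free training epochs available")
  bc <- boxcox_fit(train[feature_subset])
  norm <- boxcox_apply(bc, train[feature_subset])
  lda <- fit_pairwise(norm, train$label)
  structure(list(boxcox = bc, lda = lda, params = params,
                 features = feature_subset, seed = seed),
            class = "ags_model")
}

#' @export
print.ags_model <- function(x, ...) {
  cat(sprintf("<ags_model> %d-state pairwise Fisher LDA (%d pair models), %d features\n",
              length(x$lda$classes), length(x$lda$models), length(x$features)))
  cat(sprintf("  epoch %g s, HPF %g Hz\n", x$params$epoch_length,
              x$params$hpf_cutoff))
  invisible(x)
}

# Feature table of one record under given pre-processing parameters.
ags_epoch_features <- function(record, params) {
  es <- preprocess_record(record, params)
  if (!length(es$epochs)) stop("no epochs: record shorter than one epoch length")
  extract_features(es, f_lo = params$hpf_cutoff)
}

epoch_truth_labels_from_tab <- function(tab, grade) {
  if (grade %in% 3:4) return(rep(as.character(grade), nrow(tab)))
  st <- tab$state
  st[is.na(st) | !(st %in% STATE_LEVELS)] <- paste0(grade, "S1")
  st
}

#' Grade a recording with a trained model
#'
#' Pre-processes the record, extracts and normalises features, classifies
#' every epoch into a 6-state label, merges to 4 grades and applies the
#' majority vote. Artefact epochs are included (validation mode) unless
#' `exclude_artefact = TRUE`.
#'
#' @param record An `eeg_record`.
#' @param model An `ags_model` from [train_ags()].
#' @param exclude_artefact Drop artefact-flagged epochs before voting.
#' @return A `grade_decision`; per-epoch states in `$epoch_states`,
#'   per-epoch table in `$epochs_tbl`.
#' @export
grade_recording <- function(record, model, exclude_artefact = FALSE) {
  ft <- ags_epoch_features(record, model$params)
  if (exclude_artefact) ft <- ft[!ft$artefact, , drop = FALSE]
  if (!nrow(ft)) stop("no epochs available for grading")
  norm <- boxcox_apply(model$boxcox, ft[model$features])
  states <- vapply(seq_len(nrow(norm)), function(i) {
    classify_epoch(model$lda, as.numeric(norm[i, ]))
  }, character(1L))
  grades <- merge_states(states)
  dec <- majority_vote(grades)
  dec$epoch_states <- states
  dec$epochs_tbl <- tibble::tibble(epoch_start = ft$epoch_start,
                                   artefact = ft$artefact,
                                   state = states, grade = grades)
  dec
}
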