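# Agreement scoring and cross-validation: Cohen's kappa, confusion
# matrices, leave-one-subject-out (LOSO) cross-validation, and the nested
# greedy searches over pre-processing parameters and features.

#' Build a confusion matrix of reference vs system grades
#'
#' @param reference,predicted Vectors of grades (coerced to factors over
#'   `levels`).
#' @param levels Grade levels (default 1:4).
#' @return A `conf_mat`: integer matrix, rows = reference, columns =
#'   system output.
#' @export
confusion_matrix <- function(reference, predicted, levels = 1:4) {
  m <- table(reference = factor(reference, levels = levels),
             predicted = factor(predicted, levels = levels))
  structure(unclass(m), class = "conf_mat")
}

#' Cohen's kappa from a confusion matrix
#'
#' `kappa = (p_a - p_e) / (1 - p_e)` with `p_a` the observed agreement
#' (diagonal mass) and `p_e` the chance agreement (sum over classes of the
#' product of row and column marginals).
#'
#' @param cm Square matrix/table of counts (any orientation: kappa is
#'   symmetric in transposition).
#' @return List with `kappa`, `p_a`, `p_e`, `n`. `kappa` is `NA` with a
#'   warning for the degenerate single-cell case `p_e = 1`.
#' @export
cohens_kappa <- function(cm) {
  cm <- as.matrix(unclass(cm))
  stopifnot(nrow(cm) == ncol(cm))
  n <- sum(cm)
  if (n <= 0) stop("empty confusion matrix")
  p <- cm / n
  p_a <- sum(diag(p))
  p_e <- sum(rowSums(p) * colSums(p))
  kappa <- if (abs(1 - p_e) < 1e-15) {
    warning("degenerate confusion matrix: p_e = 1, kappa undefined")
    NA_real_
  } else (p_a - p_e) / (1 - p_e)
  list(kappa = kappa, p_a = p_a, p_e = p_e, n = n)
}

#' @export
print.conf_mat <- function(x, ...) {
  cat("<conf_mat> reference (rows) vs system (columns)\n")
  print(unclass(x))
  k <- cohens_kappa(x)
  cat(sprintf("accuracy %.1f%%, kappa %.3f\n", 100 * k$p_a, k$kappa))
  invisible(x)
}

# ---- feature cache ---------------------------------------------------------

# Per-record feature tables are cached by (record id, epoch length, cutoff)
# so the nested searches do not repeat the costly extraction.
corpus_features <- function(records, params, cache = NULL) {
  purrr::imap(records, function(rec, id) {
    key <- sprintf("%s|%g|%g", id, params$epoch_length, params$hpf_cutoff)
    if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
    ft <- ags_epoch_features(rec, params)
    ft$label <- epoch_truth_labels_from_tab(ft, rec$truth$grade4)
    ft$grade <- rec$truth$grade4
    if (!is.null(cache)) cache[[key]] <- ft
    ft
  })
}

# Fit normalisation + pairwise classifier on pooled feature tables
# (artefact-free epochs, per-record subsample).
ags_fit_tabs <- function(tabs, feature_subset, step_s, train_minutes = 7,
                         seed = 1) {
  tabs <- purrr::map(tabs, function(tt) tt[!tt$artefact, , drop = FALSE])
  max_epochs <- max(1L, floor(train_minutes * 60 / step_s))
  tabs <- with_seed(seed, purrr::map(tabs, function(tt) {
    if (nrow(tt) > max_epochs) tt[sort(sample.int(nrow(tt), max_epochs)), ] else tt
  }))
  train <- dplyr::bind_rows(tabs)
  bc <- boxcox_fit(train[feature_subset])
  lda <- fit_pairwise(boxcox_apply(bc, train[feature_subset]), train$label)
  list(boxcox = bc, lda = lda, features = feature_subset)
}

ags_grade_tab <- function(tab, fit, exclude_artefact = FALSE) {
  if (exclude_artefact) tab <- tab[!tab$artefact, , drop = FALSE]
  norm <- boxcox_apply(fit$boxcox, tab[fit$features])
  states <- vapply(seq_len(nrow(norm)), function(i) {
    classify_epoch(fit$lda, as.numeric(norm[i, ]))
  }, character(1L))
  grades <- merge_states(states)
  dec <- majority_vote(grades)
  dec$epoch_states <- states
  dec
}

# Pooled majority-vote and epoch-level kappas of an inner LOSO over `tabs`.
inner_loso_kappa <- function(tabs, feature_subset, step_s, train_minutes,
                             seed) {
  subjects <- names(tabs)
  mv_truth <- integer(0); mv_pred <- integer(0)
  ep_truth <- integer(0); ep_pred <- integer(0)
  for (s in subjects) {
    train_tabs <- tabs[setdiff(subjects, s)]
    grades_avail <- unique(vapply(train_tabs, function(t) t$grade[1L], integer(1L)))
    if (length(grades_avail) < 2L) next
    fit <- ags_fit_tabs(train_tabs, feature_subset, step_s, train_minutes, seed)
    dec <- ags_grade_tab(tabs[[s]], fit)
    mv_truth <- c(mv_truth, tabs[[s]]$grade[1L])
    mv_pred <- c(mv_pred, dec$final_grade)
    ep_truth <- c(ep_truth, merge_states(tabs[[s]]$label))
    ep_pred <- c(ep_pred, dec$epoch_grades)
  }
  list(mv = cohens_kappa(confusion_matrix(mv_truth, mv_pred))$kappa,
       epoch = cohens_kappa(confusion_matrix(ep_truth, ep_pred))$kappa)
}

#' Greedy search of pre-processing parameters by nested LOSO
#'
#' Evaluates every (epoch length, high-pass cutoff) combination on an
#' inner leave-one-subject-out loop over the training subjects only, and
#' selects the combination maximising the majority-vote Cohen's kappa.
#' Deadlocks are broken by the kappa of the short-term (per-epoch)
#' decisions, then by the smaller epoch length and lower cutoff.
#'
#' @param records Named list of training `eeg_record`s (the held-out test
#'   subject must not be among them).
#' @param epoch_grid Candidate epoch lengths, seconds, within \[8, 64\].
#' @param cutoff_grid Candidate high-pass cutoffs, Hz, within \[0.5, 3\].
#' @param feature_subset Features used by the wrapper classifier.
#' @param train_minutes Per-record training subsample, minutes.
#' @param seed Subsample seed.
#' @param cache Optional environment for feature-table caching.
#' @return List with `epoch_length`, `hpf_cutoff` and the search `trace`
#'   tibble.
#' @export
grid_search_preproc <- function(records, epoch_grid = c(8, 16, 32, 64),
                                cutoff_grid = c(0.5, 1, 1.5, 2, 2.5, 3),
                                feature_subset = NULL, train_minutes = 7,
                                seed = 1, cache = NULL) {
  feature_subset <- feature_subset %||% FEATURE_NAMES
  grid <- expand.grid(epoch_length = epoch_grid, hpf_cutoff = cutoff_grid)
  res <- purrr::pmap(grid, function(epoch_length, hpf_cutoff) {
    params <- preprocess_params(epoch_length, hpf_cutoff)
    tabs <- corpus_features(records, params, cache)
    k <- inner_loso_kappa(tabs, feature_subset, epoch_length / 2,
                          train_minutes, seed)
    tibble::tibble(epoch_length = epoch_length, hpf_cutoff = hpf_cutoff,
                   kappa_mv = k$mv, kappa_epoch = k$epoch)
  })
  trace <- dplyr::bind_rows(res)
  ord <- order(-trace$kappa_mv, -trace$kappa_epoch, trace$epoch_length,
               trace$hpf_cutoff)
  best <- trace[ord[1L], ]
  list(epoch_length = best$epoch_length, hpf_cutoff = best$hpf_cutoff,
       trace = trace)
}

#' Greedy backward feature elimination by nested LOSO
#'
#' Starting from the full feature set, repeatedly removes the feature
#' whose removal gives the largest nested-LOSO majority-vote kappa, and
#' stops as soon as no removal strictly improves on the current kappa.
#'
#' @param records Named list of training `eeg_record`s.
#' @param params A [preprocess_params()].
#' @param feature_names Starting feature set (>= 2 features).
#' @param train_minutes,seed Training subsample controls.
#' @param cache Optional feature cache environment.
#' @return List with `features` (selected subset) and `trace` (kappa after
#'   each removal).
#' @export
backward_elimination <- function(records, params = preprocess_params(),
                                 feature_names = FEATURE_NAMES,
                                 train_minutes = 7, seed = 1, cache = NULL) {
  stopifnot(length(feature_names) >= 2L)
  step_s <- params$epoch_length * (1 - params$overlap_fraction)
  tabs <- corpus_features(records, params, cache)
  current <- feature_names
  k_cur <- inner_loso_kappa(tabs, current, step_s, train_minutes, seed)$mv
  trace <- tibble::tibble(removed = NA_character_, n_features = length(current),
                          kappa = k_cur)
  repeat {
    if (length(current) <= 2L) break
    cand <- purrr::map_dbl(current, function(f) {
      inner_loso_kappa(tabs, setdiff(current, f), step_s, train_minutes,
                       seed)$mv
    })
    i <- which.max(cand)
    if (cand[i] > k_cur) {
      k_cur <- cand[i]
      trace <- dplyr::bind_rows(trace, tibble::tibble(
        removed = current[i], n_features = length(current) - 1L,
        kappa = k_cur))
      current <- current[-i]
    } else break
  }
  list(features = current, trace = trace)
}

#' Leave-one-subject-out cross-validation of the grading system
#'
#' Each subject in turn is held out; the grading system is trained on the
#' remaining subjects (optionally with nested-LOSO parameter search and
#' backward feature elimination inside the training fold, so the held-out
#' subject never influences model selection) and applied to the held-out
#' full recording. Decisions are pooled into one confusion matrix with one
#' row per recording; the score is the majority-vote Cohen's kappa.
#'
#' @param records Named list of `eeg_record`s with grade truth (>= 2
#'   subjects, >= 2 grades).
#' @param params Fixed [preprocess_params()] (used when no search grids
#'   are supplied, and as the source of fixed fields).
#' @param epoch_grid,cutoff_grid Optional grids enabling the nested
#'   pre-processing search.
#' @param select_features Run nested backward elimination per fold.
#' @param feature_subset Features used when `select_features = FALSE`.
#' @param train_minutes,seed Training subsample controls.
#' @return A `cv_result`: per-fold tibble `folds`, pooled `confusion`,
#'   `kappa`, `p_a` and the seed.
#' @export
loso <- function(records, params = preprocess_params(), epoch_grid = NULL,
                 cutoff_grid = NULL, select_features = FALSE,
                 feature_subset = NULL, train_minutes = 7, seed = 1) {
  stopifnot(length(records) >= 2L)
  subjects <- names(records)
  truth_all <- vapply(records, function(r) r$truth$grade4, integer(1L))
  if (length(unique(truth_all)) < 2L) stop("need at least two grades in the corpus")
  cache <- new.env(parent = emptyenv())
  folds <- purrr::map(subjects, function(s) {
    train_rec <- records[setdiff(subjects, s)]
    if (length(unique(vapply(train_rec, function(r) r$truth$grade4,
                             integer(1L)))) < 2L) {
      warning("fold ", s, " skipped: training set has fewer than two grades")
      return(NULL)
    }
    ep <- params$epoch_length; cut <- params$hpf_cutoff
    if (!is.null(epoch_grid) || !is.null(cutoff_grid)) {
      sel <- grid_search_preproc(train_rec,
                                 epoch_grid %||% params$epoch_length,
                                 cutoff_grid %||% params$hpf_cutoff,
                                 feature_subset, train_minutes, seed, cache)
      ep <- sel$epoch_length; cut <- sel$hpf_cutoff
    }
    fold_params <- preprocess_params(ep, cut, params$transition_width,
                                     params$target_fs)
    feats <- feature_subset %||% FEATURE_NAMES
    if (select_features) {
      feats <- backward_elimination(train_rec, fold_params, feats,
                                    train_minutes, seed, cache)$features
    }
    tabs <- corpus_features(train_rec, fold_params, cache)
    fit <- ags_fit_tabs(tabs, feats, ep / 2, train_minutes, seed)
    test_tab <- corpus_features(records[s], fold_params, cache)[[1L]]
    dec <- ags_grade_tab(test_tab, fit)
    tibble::tibble(subject = s, truth = records[[s]]$truth$grade4,
                   predicted = dec$final_grade,
                   vote_fraction = dec$vote_fraction, certain = dec$certain,
                   epoch_length = ep, hpf_cutoff = cut,
                   n_features = length(feats),
                   features = list(feats),
                   epoch_grades = list(dec$epoch_grades),
                   epoch_truth = list(merge_states(test_tab$label)),
                   epoch_artefact = list(test_tab$artefact))
  })
  folds <- dplyr::bind_rows(folds)
  cm <- confusion_matrix(folds$truth, folds$predicted)
  k <- cohens_kappa(cm)
  structure(list(folds = folds, confusion = cm, kappa = k$kappa,
                 p_a = k$p_a, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d subjects, accuracy %.1f%%, kappa %.3f\n",
              nrow(x$folds), 100 * x$p_a, x$kappa))
  invisible(x)
}

#' Grading performance as a function of recording duration
#'
#' Re-applies the majority vote to the first fraction of each recording's
#' per-epoch decisions.
#'
#' @param cv A `cv_result` from [loso()] (its per-fold epoch decisions are
#'   reused).
#' @param fractions Grid of recording fractions in (0, 1].
#' @return Tibble with `fraction`, `kappa`, `p_a`.
#' @export
duration_curve <- function(cv, fractions = seq(0.1, 1, by = 0.1)) {
  purrr::map_dfr(fractions, function(f) {
    pred <- purrr::map_int(cv$folds$epoch_grades, function(g) {
      k <- max(1L, floor(f * length(g)))
      majority_vote(g[seq_len(k)])$final_grade
    })
    kk <- cohens_kappa(confusion_matrix(cv$folds$truth, pred))
    tibble::tibble(fraction = f, kappa = kk$kappa, p_a = kk$p_a)
  })
}

#' Per-epoch error rates split by artefact contamination
#'
#' Per-recording epoch error rates (system 4-grade vs truth) separately
#' for artefact-free and artefact-flagged epochs; medians and
#' interquartile ranges across recordings.
#'
#' @param cv A `cv_result` from [loso()].
#' @return List with the per-recording tibble `per_recording` and
#'   `summary` (median and IQR of each rate, percent).
#' @export
artefact_error_split <- function(cv) {
  per <- purrr::pmap_dfr(
    list(cv$folds$subject, cv$folds$epoch_grades, cv$folds$epoch_truth,
         cv$folds$epoch_artefact),
    function(s, pred, truth, art) {
      err <- pred != truth
      tibble::tibble(
        subject = s,
        error_clean = if (any(!art)) 100 * mean(err[!art]) else NA_real_,
        error_artefact = if (any(art)) 100 * mean(err[art]) else NA_real_)
    })
  qs <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
    c(median = stats::median(v),
      q1 = unname(stats::quantile(v, 0.25)),
      q3 = unname(stats::quantile(v, 0.75)))
  }
  list(per_recording = per,
       summary = rbind(clean = qs(per$error_clean),
                       artefact = qs(per$error_artefact)))
}
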