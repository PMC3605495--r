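# broom-style tidy()/glance() methods for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a grading decision into its per-epoch table
#'
#' @param x A `grade_decision` from [grade_recording()].
#' @param ... Unused.
#' @return Tibble with one row per epoch (`epoch_start`, `state`, `grade`,
#'   `artefact`) when available, otherwise the epoch grades alone.
#' @method tidy grade_decision
#' @export
tidy.grade_decision <- function(x, ...) {
  if (!is.null(x$epochs_tbl)) return(x$epochs_tbl)
  tibble::tibble(epoch = seq_along(x$epoch_grades), grade = x$epoch_grades)
}

#' @rdname tidy.grade_decision
#' @method glance grade_decision
#' @export
glance.grade_decision <- function(x, ...) {
  tibble::tibble(final_grade = x$final_grade,
                 vote_fraction = x$vote_fraction,
                 certain = x$certain,
                 n_epochs = length(x$epoch_grades))
}

#' Tidy a confusion matrix into long form
#'
#' @param x A `conf_mat`.
#' @param ... Unused.
#' @return Tibble with `reference`, `predicted`, `n`.
#' @method tidy conf_mat
#' @export
tidy.conf_mat <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    reference = rep(rownames(m), times = ncol(m)),
    predicted = rep(colnames(m), each = nrow(m)),
    n = as.vector(m))
}

#' @rdname tidy.conf_mat
#' @method glance conf_mat
#' @export
glance.conf_mat <- function(x, ...) {
  k <- cohens_kappa(x)
  tibble::tibble(kappa = k$kappa, p_a = k$p_a, p_e = k$p_e, n = k$n)
}

#' Tidy a cross-validation result
#'
#' @param x A `cv_result` from [loso()].
#' @param ... Unused.
#' @return The per-fold tibble (subject, truth, prediction, certainty,
#'   selected parameters).
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) {
  dplyr::select(x$folds, -dplyr::any_of(c("epoch_grades", "epoch_truth",
                                          "epoch_artefact", "features")))
}

#' @rdname tidy.cv_result
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(kappa = x$kappa, p_a = x$p_a, n_subjects = nrow(x$folds))
}

#' Tidy a trained grading model into its discriminant weights
#'
#' @param x An `ags_model`.
#' @param ... Unused.
#' @return Tibble with one row per (class pair, feature) weight.
#' @method tidy ags_model
#' @export
tidy.ags_model <- function(x, ...) {
  purrr::map_dfr(x$lda$models, function(m) {
    tibble::tibble(class_a = m$classes[1L], class_b = m$classes[2L],
                   feature = x$features, weight = as.numeric(m$w),
                   J = m$J)
  })
}

#' @rdname tidy.ags_model
#' @method glance ags_model
#' @export
glance.ags_model <- function(x, ...) {
  tibble::tibble(n_classes = length(x$lda$classes),
                 n_pairs = length(x$lda$models),
                 n_features = length(x$features),
                 epoch_length = x$params$epoch_length,
                 hpf_cutoff = x$params$hpf_cutoff)
}
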