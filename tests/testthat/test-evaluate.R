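# Cohen's kappa, LOSO cross-validation and the nested greedy searches.

test_that("kappa matches a brute-force oracle and its invariances", {
  # independent oracle: explicit double loops over cells
  kappa_brute <- function(cm) {
    n <- sum(cm); M <- nrow(cm)
    p_a <- 0
    for (i in 1:M) p_a <- p_a + cm[i, i] / n
    p_e <- 0
    for (k in 1:M) {
      row_k <- 0; col_k <- 0
      for (j in 1:M) { row_k <- row_k + cm[k, j]; col_k <- col_k + cm[j, k] }
      p_e <- p_e + (row_k / n) * (col_k / n)
    }
    (p_a - p_e) / (1 - p_e)
  }
  set.seed(6)
  for (i in 1:100) {
    cm <- matrix(rpois(16, 5), 4)
    if (sum(cm) == 0 || abs(1 - sum(rowSums(cm / sum(cm)) *
                                    colSums(cm / sum(cm)))) < 1e-12) next
    expect_equal(cohens_kappa(cm)$kappa, kappa_brute(cm), tolerance = 1e-12)
    perm <- sample(4)
    expect_equal(cohens_kappa(cm[perm, perm])$kappa, cohens_kappa(cm)$kappa,
                 tolerance = 1e-12)
  }
  expect_equal(cohens_kappa(diag(c(5, 3, 2, 9)))$kappa, 1)
  expect_equal(cohens_kappa(matrix(1, 2, 2))$kappa, 0)
  expect_warning(k0 <- cohens_kappa(matrix(c(7, 0, 0, 0), 2)), "degenerate")
  expect_true(is.na(k0$kappa))
})

test_that("the printed-table worked example reproduces kappa 0.762", {
  cm <- matrix(c(20, 2, 0, 0,
                 3, 10, 1, 0,
                 0, 3, 9, 0,
                 0, 0, 0, 6), nrow = 4, byrow = TRUE)
  k <- cohens_kappa(cm)
  expect_equal(round(k$kappa, 3), 0.762)
  expect_equal(k$p_a, 45 / 54)
})

test_that("LOSO on a separable corpus is perfect and tests each subject once", {
  corp <- tiny_corpus(2, 120, seed = 11)
  cv <- loso(corp, preprocess_params(32, 2.5), seed = 4)
  expect_identical(sort(cv$folds$subject), sort(names(corp)))
  expect_identical(anyDuplicated(cv$folds$subject), 0L)
  expect_equal(cv$kappa, 1)
  expect_equal(cv$p_a, 1)
  expect_identical(sum(unclass(cv$confusion)), length(corp))
  expect_equal(glance(cv)$kappa, 1)
  expect_identical(nrow(tidy(cv)), length(corp))
})

test_that("LOSO kappa collapses towards zero under label shuffling", {
  corp <- tiny_corpus(2, 120, seed = 11)
  ks <- vapply(1:3, function(s) {
    shuffled <- corp
    perm <- neograde:::with_seed(s, sample(length(corp)))
    for (i in seq_along(shuffled)) {
      shuffled[[i]]$truth$grade4 <- corp[[perm[i]]]$truth$grade4
    }
    loso(shuffled, preprocess_params(32, 2.5), seed = 4)$kappa
  }, numeric(1))
  expect_lt(abs(mean(ks)), 0.3)
})

test_that("degenerate corpora are rejected or skipped with a warning", {
  corp <- tiny_corpus(2, 120, seed = 11)
  one_grade <- corp[1:2]                       # both grade 1
  expect_error(loso(one_grade, preprocess_params(32, 2.5)), "two grades")
})

test_that("the pre-processing search returns grid points under its tie rules", {
  corp <- tiny_corpus(2, 120, seed = 11)
  single <- grid_search_preproc(corp, epoch_grid = 32, cutoff_grid = 2.5,
                                seed = 4)
  expect_identical(single$epoch_length, 32)
  expect_identical(single$hpf_cutoff, 2.5)
  sel <- grid_search_preproc(corp, epoch_grid = c(16, 32),
                             cutoff_grid = c(1, 2.5), seed = 4)
  tr <- sel$trace
  expect_identical(nrow(tr), 4L)
  ord <- order(-tr$kappa_mv, -tr$kappa_epoch, tr$epoch_length, tr$hpf_cutoff)
  expect_identical(c(sel$epoch_length, sel$hpf_cutoff),
                   c(tr$epoch_length[ord[1]], tr$hpf_cutoff[ord[1]]))
})

test_that("backward elimination only removes features that raise kappa", {
  corp <- tiny_corpus(2, 120, seed = 11)
  be <- backward_elimination(corp, preprocess_params(32, 2.5),
                             feature_names = c("am_mean", "am_std", "if_mean",
                                               "ibi", "sync_lag"),
                             seed = 4)
  expect_true(all(be$features %in% c("am_mean", "am_std", "if_mean", "ibi",
                                     "sync_lag")))
  expect_gte(length(be$features), 2L)
  expect_true(all(diff(be$trace$kappa) > 0))   # every removal improved
  expect_identical(nrow(be$trace) - 1L,
                   length(setdiff(c("am_mean", "am_std", "if_mean", "ibi",
                                    "sync_lag"), be$features)))
})

test_that("the duration curve reduces to the full-record kappa at f = 1", {
  corp <- tiny_corpus(2, 120, seed = 11)
  cv <- loso(corp, preprocess_params(32, 2.5), seed = 4)
  dc <- duration_curve(cv, fractions = c(0.25, 0.5, 1))
  expect_equal(dc$kappa[dc$fraction == 1], cv$kappa)
  # constant per-epoch decisions give a flat curve
  cv2 <- cv
  cv2$folds$epoch_grades <- lapply(cv$folds$truth, function(g) rep(g, 10))
  dc2 <- duration_curve(cv2, fractions = c(0.3, 0.6, 1))
  expect_true(all(dc2$kappa == dc2$kappa[1]))
})

test_that("artefact error split computes per-recording rates", {
  fake <- list(folds = tibble::tibble(
    subject = c("a", "b"),
    truth = c(1L, 3L),
    epoch_grades = list(c(1L, 1L, 2L, 1L), c(3L, 4L, 3L, 3L)),
    epoch_truth = list(rep(1L, 4), rep(3L, 4)),
    epoch_artefact = list(c(FALSE, FALSE, TRUE, TRUE),
                          c(FALSE, TRUE, FALSE, FALSE))))
  sp <- artefact_error_split(fake)
  expect_equal(sp$per_recording$error_clean, c(0, 0))
  expect_equal(sp$per_recording$error_artefact, c(50, 100))
  perfect <- fake
  perfect$folds$epoch_grades <- perfect$folds$epoch_truth
  sp0 <- artefact_error_split(perfect)
  expect_equal(sp0$summary["clean", "median"], 0)
  expect_equal(sp0$summary["artefact", "median"], 0)
  wrong <- fake
  wrong$folds$epoch_grades <- list(rep(4L, 4), rep(1L, 4))
  spw <- artefact_error_split(wrong)
  expect_equal(unname(spw$summary[, "median"]), c(100, 100))
})
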