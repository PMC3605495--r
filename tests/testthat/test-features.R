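# Per-epoch feature battery and Box-Cox normalisation.

test_that("moments match hand computation and conventions", {
  x <- c(0, 0, 0, 1)
  # oracle by direct central-moment arithmetic
  mu <- 1 / 4
  d <- x - mu
  m2 <- mean(d^2); m3 <- mean(d^3); m4 <- mean(d^4)
  m <- moments(x)
  expect_equal(unname(m["mean"]), 0.25)
  expect_equal(unname(m["std"]), sqrt(sum(d^2) / 3))
  expect_equal(unname(m["skew"]), m3 / m2^1.5)
  expect_equal(unname(m["kurt"]), m4 / m2^2)
  # Gaussian kurtosis tends to 3 (non-excess convention)
  set.seed(2)
  g <- moments(rnorm(1e5))
  expect_lt(abs(unname(g["kurt"]) - 3), 0.2)
  cst <- moments(rep(4, 10))
  expect_identical(unname(cst["std"]), 0)
  expect_true(is.na(cst["skew"]) && is.na(cst["kurt"]))
})

test_that("relative delta power splits band energy correctly", {
  fs <- 64
  t <- (0:(64 * fs - 1)) / fs
  expect_gt(rel_delta_power(sin(2 * pi * 2 * t), fs), 0.95)
  expect_lt(rel_delta_power(sin(2 * pi * 10 * t), fs), 0.05)
  mix <- sin(2 * pi * 2 * t) + sin(2 * pi * 10 * t)
  expect_lt(abs(rel_delta_power(mix, fs) - 0.5), 0.05)
  z <- rel_delta_power(numeric(64 * 8), fs)
  expect_identical(as.numeric(z), 0)
  expect_true(attr(z, "flagged"))
})

test_that("AM/IF covariance follows closed forms", {
  am <- rep(c(1, 3), each = 32)
  expect_equal(am_if_covariance(list(am = am, iff = rep(5, 64))), 0)
  expect_equal(am_if_covariance(list(am = am, iff = am)), stats::var(am))
  sq <- rep(c(1, -1), each = 32)
  expect_equal(am_if_covariance(list(am = sq, iff = -sq)), -stats::var(sq))
})

test_that("the IBI detector recovers generator truth on raw envelopes", {
  fs <- 64
  e <- make_envelope(600, fs, bs_spec(30), seed = 3)
  est <- estimate_ibi(e$envelope, fs, threshold = 15)
  expect_gt(est, 25); expect_lt(est, 35)
  # continuous epoch: no suppression, flagged zero
  cont <- estimate_ibi(rep(40, fs * 64), fs, threshold = 15)
  expect_identical(as.numeric(cont), 0)
  expect_true(attr(cont, "flagged"))
  # inactive epoch: one suppression run covering the whole epoch
  expect_equal(estimate_ibi(rep(2, fs * 64), fs, threshold = 15), 64)
})

test_that("the symmetry index reflects inter-hemispheric power imbalance", {
  fs <- 64
  set.seed(7)
  x <- matrix(rnorm(4 * fs * 32), nrow = 4)
  expect_lt(symmetry_index(x, x, fs), 0.02)
  expect_gt(symmetry_index(x, 0 * x, fs), 0.95)
  half <- symmetry_index(x, 0.5 * x, fs)        # 4:1 power -> 3/5
  expect_lt(abs(half - 0.6), 0.05)
  z <- symmetry_index(0 * x, 0 * x, fs)
  expect_identical(as.numeric(z), 0)
  expect_true(attr(z, "flagged"))
})

test_that("synchrony finds the cross-correlation peak and its lag", {
  fs <- 32
  e <- make_envelope(128, fs, bs_spec(20), seed = 5)$envelope
  s <- synchrony(e, e, fs)
  expect_equal(unname(s["sync_max"]), 1, tolerance = 1e-9)
  expect_equal(unname(s["sync_lag"]), 0)
  sh <- c(rep(e[1], 2 * fs), e[1:(length(e) - 2 * fs)])
  s2 <- synchrony(e, sh, fs)
  expect_gt(unname(s2["sync_max"]), 0.85)
  expect_lt(abs(abs(unname(s2["sync_lag"])) - 2), 0.3)
  set.seed(8)
  s3 <- synchrony(rnorm(4096), rnorm(4096), fs)
  expect_lt(unname(s3["sync_max"]), 0.3)
  expect_true(attr(synchrony(rep(1, 100), rnorm(100), fs), "flagged"))
})

test_that("channel combination is a permutation-invariant median", {
  m <- matrix(1:8, nrow = 8, ncol = 3)
  colnames(m) <- c("a", "b", "c")
  expect_equal(unname(channel_combine(m)["a"]), 4.5)
  perm <- m[sample(8), , drop = FALSE]
  expect_identical(channel_combine(m), channel_combine(perm))
  same <- matrix(2, nrow = 8, ncol = 2, dimnames = list(NULL, c("x", "y")))
  expect_identical(unname(channel_combine(same)), c(2, 2))
})

test_that("Box-Cox normalisation standardises training data and inverts", {
  set.seed(12)
  train <- tibble::tibble(a = rlnorm(5000), b = rnorm(5000, 10, 2))
  bm <- boxcox_fit(train)
  expect_lt(abs(bm$pars$a$lambda), 0.15)      # log-normal -> lambda near 0
  z <- boxcox_apply(bm, train)
  expect_equal(colMeans(as.matrix(z)), c(a = 0, b = 0), tolerance = 1e-9)
  expect_equal(apply(as.matrix(z), 2, stats::sd), c(a = 1, b = 1),
               tolerance = 1e-9)
  back <- boxcox_invert(bm, z)
  expect_lt(max(abs(back$a - train$a)) / stats::sd(train$a), 1e-6)
  expect_lt(max(abs(back$b - train$b)) / stats::sd(train$b), 1e-6)
  # lambda = 1 is an order-preserving affine map
  y <- neograde:::boxcox_transform(train$b, 1)
  expect_identical(order(y), order(train$b))
})

test_that("feature extraction is channel-order invariant and amplitude-consistent", {
  rec <- simulate_record(2, duration = 96, fs = 64, seed = 21,
                         state_cycle = FALSE)
  es <- segment(rec, preprocess_params(32))
  ft <- extract_features(es, f_lo = 2.5)
  # permuting channels within each hemisphere leaves the features unchanged
  rec_p <- rec
  rec_p$samples <- rec$samples[c(4:1, 8:5), ]
  ft_p <- extract_features(segment(rec_p, preprocess_params(32)), f_lo = 2.5)
  expect_equal(as.data.frame(ft), as.data.frame(ft_p), tolerance = 1e-9)
  # doubling the signal doubles am_mean but leaves if_mean unchanged
  rec_2 <- rec
  rec_2$samples <- 2 * rec$samples
  ft_2 <- extract_features(segment(rec_2, preprocess_params(32)), f_lo = 2.5)
  expect_equal(ft_2$am_mean, 2 * ft$am_mean, tolerance = 1e-6)
  expect_equal(ft_2$if_mean, ft$if_mean, tolerance = 1e-6)
})

test_that("discontinuity features increase from grade 1 to grade 3", {
  corp <- tiny_corpus(3, 120, seed = 31)
  params <- preprocess_params(64, 2.5)
  med <- sapply(1:3, function(g) {
    recs <- corp[vapply(corp, function(r) r$truth$grade4, integer(1)) == g]
    ft <- dplyr::bind_rows(lapply(recs, function(r) {
      extract_features(preprocess_record(r, params), f_lo = 2.5)
    }))
    c(cv = median(ft$am_std / ft$am_mean), ibi = median(ft$ibi))
  })
  expect_true(all(diff(med["cv", ]) > 0))
  expect_true(all(diff(med["ibi", ]) > 0))
})
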