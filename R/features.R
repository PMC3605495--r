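# Per-epoch feature battery on the AM/IF sub-signals and the raw EEG,
# combined across channels by the median, plus Box-Cox normalisation.
#
# The sixteen features per epoch: mean/sd/skewness/kurtosis of AM and of
# IF, AM-IF covariance, relative delta power, EEG skewness, EEG kurtosis,
# interburst interval, inter-hemispheric symmetry, and synchrony (maximum
# envelope cross-correlation and its lag).

FEATURE_NAMES <- c("am_mean", "am_std", "am_skew", "am_kurt",
                   "if_mean", "if_std", "if_skew", "if_kurt",
                   "am_if_cov", "rel_delta_power", "eeg_skew", "eeg_kurt",
                   "ibi", "symmetry", "sync_max", "sync_lag")

#' First four time-domain moments of a series
#'
#' Mean, standard deviation (sample, n-1), skewness and kurtosis from the
#' standard central-moment ratios. Kurtosis is reported in the non-excess
#' (Pearson) convention: a Gaussian series tends to 3. A zero-variance
#' series yields `NA` skewness and kurtosis.
#'
#' @param x Numeric vector, length >= 4.
#' @return Named numeric vector `(mean, std, skew, kurt)`.
#' @export
moments <- function(x) {
  stopifnot(length(x) >= 4L)
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 <= 0) {
    return(c(mean = m, std = 0, skew = NA_real_, kurt = NA_real_))
  }
  c(mean = m,
    std = stats::sd(x),
    skew = mean(d^3) / m2^1.5,
    kurt = mean(d^4) / m2^2)
}

#' Relative delta-band power of an epoch
#'
#' Welch-periodogram band power in 0.5-4 Hz divided by total power in
#' 0.5-32 Hz.
#'
#' @param x Epoch samples (one channel).
#' @param fs Sampling rate, Hz.
#' @return Fraction in `[0, 1]`; 0 with attribute `flagged` when the epoch
#'   carries no power.
#' @export
rel_delta_power <- function(x, fs) {
  p <- welch_psd(x, fs, nperseg = min(length(x), 4L * fs))
  total <- p$freq >= 0.5 & p$freq <= 32
  delta <- p$freq >= 0.5 & p$freq <= 4
  tp <- sum(p$psd[total])
  if (tp <= 0) return(structure(0, flagged = TRUE))
  min(sum(p$psd[delta]) / tp, 1)
}

#' Covariance between the AM and IF sub-signals
#'
#' @param pair An `am_if_pair` (or a list with `am` and `iff`).
#' @return Sample covariance with respect to time.
#' @export
am_if_covariance <- function(pair) {
  stopifnot(length(pair$am) == length(pair$iff))
  stats::cov(pair$am, pair$iff)
}

#' Interburst interval from the AM envelopes
#'
#' Envelope-threshold detector: suppression is any run of the AM below
#' `threshold` microvolts lasting at least `min_duration` seconds; the
#' per-channel IBI is the median suppression duration and channels are
#' combined by the median. A continuous epoch (no suppression anywhere)
#' returns 0 with attribute `flagged`; a fully suppressed epoch returns the
#' epoch length.
#'
#' @param am_channels Numeric matrix (channels x time) or vector of AM
#'   values, microvolts.
#' @param fs Sampling rate of the AM series, Hz.
#' @param threshold Suppression threshold, microvolts.
#' @param min_duration Minimum suppression duration, seconds.
#' @return IBI estimate in seconds.
#' @export
estimate_ibi <- function(am_channels, fs, threshold = 15, min_duration = 1) {
  if (is.null(dim(am_channels))) am_channels <- matrix(am_channels, nrow = 1L)
  per_ch <- apply(am_channels, 1L, function(am) {
    runs <- logical_runs(am < threshold)
    if (!nrow(runs)) return(NA_real_)
    dur <- (runs[, "end"] - runs[, "start"] + 1L) / fs
    dur <- dur[dur >= min_duration]
    if (!length(dur)) return(NA_real_)
    stats::median(dur)
  })
  if (all(is.na(per_ch))) return(structure(0, flagged = TRUE))
  stats::median(per_ch, na.rm = TRUE)
}

#' Inter-hemispheric spectral symmetry index
#'
#' Core construction of a brain symmetry index: hemisphere-average Welch
#' spectral densities `L(f)` and `R(f)` give
#' `mean over f of |L - R| / (L + R)` over 0.5-32 Hz. 0 for identical
#' hemispheres, approaching 1 when power is one-sided.
#'
#' @param left,right Channel-by-time matrices for each hemisphere.
#' @param fs Sampling rate, Hz.
#' @return Index in `[0, 1]`; 0 with attribute `flagged` if both sides are
#'   powerless.
#' @export
symmetry_index <- function(left, right, fs) {
  if (is.null(dim(left))) left <- matrix(left, nrow = 1L)
  if (is.null(dim(right))) right <- matrix(right, nrow = 1L)
  stopifnot(nrow(left) >= 1L, nrow(right) >= 1L)
  avg_psd <- function(m) {
    ps <- apply(m, 1L, function(x) welch_psd(x, fs, min(ncol(m), 4L * fs))$psd)
    rowMeans(ps)
  }
  f <- welch_psd(left[1L, ], fs, min(ncol(left), 4L * fs))$freq
  L <- avg_psd(left)
  R <- avg_psd(right)
  band <- f >= 0.5 & f <= 32
  L <- L[band]; R <- R[band]
  tot <- L + R
  if (all(tot <= 0)) return(structure(0, flagged = TRUE))
  keep <- tot > 0
  mean(abs(L[keep] - R[keep]) / tot[keep])
}

#' Envelope synchrony between hemispheres
#'
#' Maximum of the normalised cross-correlation between the two AM series
#' over lags up to `max_lag` seconds, and the lag (seconds) at which it is
#' attained.
#'
#' @param am_left,am_right AM series of equal length.
#' @param fs Sampling rate of the AM series, Hz.
#' @param max_lag Lag search bound, seconds.
#' @return Named vector `(sync_max, sync_lag)`; flagged `(NA, NA)` when an
#'   input is constant.
#' @export
synchrony <- function(am_left, am_right, fs, max_lag = 10) {
  stopifnot(length(am_left) == length(am_right))
  n <- length(am_left)
  xl <- am_left - mean(am_left)
  xr <- am_right - mean(am_right)
  sx <- sqrt(mean(xl^2)); sy <- sqrt(mean(xr^2))
  if (sx == 0 || sy == 0) {
    return(structure(c(sync_max = NA_real_, sync_lag = NA_real_),
                     flagged = TRUE))
  }
  L <- min(round(max_lag * fs), n - 1L)
  lags <- -L:L
  cc <- vapply(lags, function(k) {
    if (k >= 0) sum(xl[(1L + k):n] * xr[1L:(n - k)]) else
      sum(xl[1L:(n + k)] * xr[(1L - k):n])
  }, numeric(1L)) / (n * sx * sy)
  i <- which.max(cc)
  c(sync_max = cc[i], sync_lag = lags[i] / fs)
}

#' Median-combine per-channel feature vectors
#'
#' Element-wise median across channels; features computed once per epoch
#' from channel groups (symmetry, synchrony) pass through unchanged.
#'
#' @param per_channel Data frame or matrix, channels in rows, features in
#'   columns.
#' @return Named numeric vector of medians.
#' @export
channel_combine <- function(per_channel) {
  m <- as.matrix(per_channel)
  if (anyNA(m)) warning("missing channel values; median over available channels")
  apply(m, 2L, stats::median, na.rm = TRUE)
}

#' Extract the per-epoch feature table from an epoch set
#'
#' For every epoch and channel the non-negative smoothed time-frequency
#' distribution is computed, the AM/IF sub-signals extracted with moments
#' over `[hpf_cutoff, 32]` Hz, and the feature battery evaluated; channel
#' features are combined by the median. Inter-hemispheric symmetry uses the
#' raw signals and synchrony the hemisphere-mean AM envelopes.
#'
#' @param epoch_set An `epoch_set` from [segment()] or
#'   [preprocess_record()].
#' @param f_lo Lower moment-integration bound, Hz (the high-pass cutoff).
#' @param left_channels,right_channels Row indices of each hemisphere.
#' @param hop Time decimation of the TFD (samples); features are summary
#'   statistics and insensitive to it.
#' @param tfd_method `"spectrogram"` (fast, default) or `"spwvd"`.
#' @param ibi_threshold Suppression threshold for [estimate_ibi()],
#'   microvolts. The default `NULL` adapts it per epoch to
#'   `max(3, 0.5 * Q90(AM))` (3 microvolts is roughly the post-filter
#'   equivalent of the raw 15 microvolt suppression threshold), since
#'   high-pass filtering scales the AM well below raw-EEG amplitudes.
#' @return A tibble, one row per epoch: `epoch_start`, `artefact`, `state`,
#'   and the sixteen feature columns.
#' @export
extract_features <- function(epoch_set, f_lo = 2.5,
                             left_channels = 5:8, right_channels = 1:4,
                             hop = 2L, tfd_method = "spectrogram",
                             ibi_threshold = NULL) {
  fs <- epoch_set$fs
  kern <- kernel_spec(1, 1)
  rows <- purrr::map(seq_along(epoch_set$epochs), function(i) {
    ep <- epoch_set$epochs[[i]]
    nch <- nrow(ep)
    lch <- intersect(left_channels, seq_len(nch))
    rch <- intersect(right_channels, seq_len(nch))
    am_mat <- NULL
    per_ch <- matrix(NA_real_, nrow = nch, ncol = 13L)
    colnames(per_ch) <- FEATURE_NAMES[1:13]
    for (ch in seq_len(nch)) {
      x <- ep[ch, ]
      rho <- tfd_epoch(x, fs, kern, n_freq = 128L, hop = hop,
                       method = tfd_method)
      pair <- extract_am_if(rho, f_range = c(f_lo, 32))
      if (is.null(am_mat)) {
        am_mat <- matrix(0, nrow = nch, ncol = length(pair$am))
      }
      am_mat[ch, ] <- pair$am
      am_m <- moments(pair$am)
      if_m <- moments(pair$iff)
      per_ch[ch, ] <- c(am_m, if_m,
                        am_if_covariance(pair),
                        rel_delta_power(x, fs),
                        moments(x)[c("skew", "kurt")],
                        NA_real_)
    }
    am_fs <- fs / hop
    thr <- ibi_threshold %||%
      max(3, 0.5 * stats::quantile(am_mat, 0.9, names = FALSE))
    per_ch[, "ibi"] <- estimate_ibi(am_mat, am_fs, threshold = thr)
    comb <- channel_combine(per_ch)
    sym <- if (length(lch) && length(rch)) {
      symmetry_index(ep[lch, , drop = FALSE], ep[rch, , drop = FALSE], fs)
    } else NA_real_
    syn <- if (length(lch) && length(rch)) {
      synchrony(colMeans(am_mat[lch, , drop = FALSE]),
                colMeans(am_mat[rch, , drop = FALSE]), am_fs)
    } else c(sync_max = NA_real_, sync_lag = NA_real_)
    tibble::tibble(
      epoch_start = epoch_set$start_times[i],
      artefact = epoch_set$artefact_flags[i],
      state = epoch_set$state_labels[i],
      !!!as.list(comb),
      symmetry = as.numeric(sym),
      sync_max = unname(syn["sync_max"]),
      sync_lag = unname(syn["sync_lag"]))
  })
  dplyr::bind_rows(rows)
}

# ---- Box-Cox normalisation -------------------------------------------------

boxcox_loglik <- function(x, lambda) {
  n <- length(x)
  y <- if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
  -n / 2 * log(stats::var(y) * (n - 1) / n) + (lambda - 1) * sum(log(x))
}

#' Fit a per-feature Box-Cox normalisation model on training data
#'
#' For each feature an offset makes all training values strictly positive,
#' the power-transform parameter lambda is chosen by profile maximum
#' likelihood on the shifted values, and the transformed values are centred
#' and scaled to zero mean, unit variance. Apply-time epochs reuse the
#' stored offset, lambda, centre and scale.
#'
#' @param train Data frame / tibble of training feature values (columns =
#'   features).
#' @param lambda_range Search interval for lambda.
#' @return A `boxcox_model`.
#' @export
boxcox_fit <- function(train, lambda_range = c(-3, 3)) {
  feats <- names(train)
  pars <- purrr::map(feats, function(f) {
    x <- train[[f]]
    x <- x[is.finite(x)]
    if (!length(x)) {
      return(list(offset = 0, lambda = 1, centre = 0, scale = 1))
    }
    offset <- if (min(x) <= 0) -min(x) + 0.05 * max(stats::sd(x), 1e-6) else 0
    xs <- x + offset
    lambda <- if (stats::sd(xs) == 0) 1 else {
      stats::optimize(function(l) boxcox_loglik(xs, l),
                      lambda_range, maximum = TRUE)$maximum
    }
    y <- boxcox_transform(xs, lambda)
    sc <- stats::sd(y)
    list(offset = offset, lambda = lambda, centre = mean(y),
         scale = if (is.finite(sc) && sc > 0) sc else 1)
  })
  names(pars) <- feats
  structure(list(features = feats, pars = pars), class = "boxcox_model")
}

boxcox_transform <- function(x, lambda) {
  if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
}

boxcox_inverse_transform <- function(y, lambda) {
  if (abs(lambda) < 1e-8) exp(y) else (lambda * y + 1)^(1 / lambda)
}

#' Apply a fitted Box-Cox model to a feature table
#'
#' @param model A `boxcox_model` from [boxcox_fit()].
#' @param features Data frame with (at least) the model's feature columns.
#' @return The data frame with those columns transformed and standardised.
#' @export
boxcox_apply <- function(model, features) {
  for (f in model$features) {
    p <- model$pars[[f]]
    x <- pmax(features[[f]] + p$offset, 1e-12)
    y <- boxcox_transform(x, p$lambda)
    features[[f]] <- (y - p$centre) / p$scale
  }
  features
}

#' Invert a Box-Cox normalisation
#'
#' @param model A `boxcox_model`.
#' @param features Data frame of normalised values.
#' @return Data frame on the original feature scale.
#' @export
boxcox_invert <- function(model, features) {
  for (f in model$features) {
    p <- model$pars[[f]]
    y <- features[[f]] * p$scale + p$centre
    features[[f]] <- boxcox_inverse_transform(y, p$lambda) - p$offset
  }
  features
}
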