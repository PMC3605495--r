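# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so simulation helpers are
#' deterministic without clobbering the session stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Welch-averaged one-sided power spectral density
#'
#' Hamming-windowed overlapping segments, periodograms averaged. Units are
#' power per Hz so that sum(psd) * df approximates the signal variance.
#' @noRd
welch_psd <- function(x, fs, nperseg = min(length(x), 256L), overlap = 0.5) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  w <- signal::hamming(nperseg)
  step <- max(1L, floor(nperseg * (1 - overlap)))
  starts <- seq.int(1L, n - nperseg + 1L, by = step)
  U <- sum(w^2)
  acc <- numeric(nperseg)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)] * w
    acc <- acc + abs(stats::fft(seg))^2
  }
  psd <- acc / (length(starts) * fs * U)
  nh <- floor(nperseg / 2) + 1L
  out <- psd[seq_len(nh)]
  if (nh > 2L) out[2:(nh - 1L)] <- 2 * out[2:(nh - 1L)]
  list(freq = (seq_len(nh) - 1L) * fs / nperseg, psd = out)
}

# Apply a symmetric (linear-phase) FIR filter with group-delay compensation,
# returning an output aligned with and of the same length as the input.
fir_apply <- function(h, x) {
  n <- length(x)
  d <- (length(h) - 1L) / 2
  y <- signal::fftfilt(h, c(x, rep(0, length(h))))
  y[(d + 1L):(d + n)]
}

# Least-squares slope of log10(psd) against log10(freq) over a band.
loglog_slope <- function(freq, psd, f1, f2) {
  keep <- freq >= f1 & freq <= f2 & psd > 0
  stats::coef(stats::lm(log10(psd[keep]) ~ log10(freq[keep])))[[2L]]
}

# Contiguous runs of a logical vector as a two-column matrix of
# (start index, end index), 1-based inclusive.
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
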