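# Filtering, downsampling and segmentation into overlapping analysis epochs.

#' Pre-processing parameters
#'
#' @param epoch_length Analysis epoch length, seconds, in \[8, 64\].
#' @param hpf_cutoff High-pass cutoff, Hz, in \[0.5, 3\].
#' @param transition_width High-pass transition width, Hz.
#' @param target_fs Working sampling rate after decimation, Hz.
#' @param overlap_fraction Epoch overlap (fixed at 0.5).
#' @return A `preprocess_params` list.
#' @export
preprocess_params <- function(epoch_length = 64, hpf_cutoff = 2.5,
                              transition_width = 0.5, target_fs = 64,
                              overlap_fraction = 0.5) {
  if (epoch_length < 8 || epoch_length > 64) {
    stop("epoch_length out of range [8, 64] s")
  }
  if (hpf_cutoff < 0.5 || hpf_cutoff > 3) {
    stop("hpf_cutoff out of range [0.5, 3] Hz")
  }
  structure(list(epoch_length = epoch_length, hpf_cutoff = hpf_cutoff,
                 transition_width = transition_width, target_fs = target_fs,
                 overlap_fraction = overlap_fraction),
            class = "preprocess_params")
}

#' Design a linear-phase FIR high-pass filter
#'
#' Windowed-sinc (Hamming) design; the order follows the Hamming
#' transition-width rule `order = 3.3 * fs / transition_width`, rounded up
#' to even so the high-pass is realisable with a symmetric impulse
#' response. At 256 Hz with a 0.5 Hz transition this yields order 1690,
#' comparable to the order-1858 filter used in the original grading system.
#'
#' @param cutoff Cutoff frequency, Hz (0 < cutoff < fs/2).
#' @param transition_width Transition band width, Hz.
#' @param fs Sampling rate, Hz.
#' @return Numeric coefficient vector with attribute `order`.
#' @export
design_highpass <- function(cutoff, transition_width = 0.5, fs = 256) {
  if (!(cutoff > 0 && cutoff < fs / 2)) stop("cutoff must lie in (0, fs/2)")
  order <- ceiling(3.3 * fs / transition_width)
  if (order %% 2 == 1) order <- order + 1
  if (order + 1 > fs * 3600) stop("transition width infeasible at this sampling rate")
  h <- signal::fir1(order, 2 * cutoff / fs, type = "high")
  h <- as.numeric(h)
  attr(h, "order") <- order
  h
}

#' Downsample a record with anti-alias filtering
#'
#' A linear-phase FIR low-pass (cutoff at 87.5% of the new Nyquist rate) is
#' applied before decimation by the integer factor `fs / target_fs`.
#'
#' @param record An `eeg_record`.
#' @param target_fs New sampling rate; must divide `record$fs`.
#' @return The decimated `eeg_record` (annotations and truth carried over).
#' @export
downsample <- function(record, target_fs = 64) {
  fs <- record$fs
  if (fs == target_fs) return(record)
  factor <- fs / target_fs
  if (factor != round(factor)) stop("sampling rate must be an integer multiple of target_fs")
  cutoff <- 0.875 * target_fs / 2
  order <- 256L
  h <- as.numeric(signal::fir1(order, 2 * cutoff / fs))
  keep <- seq(1L, ncol(record$samples), by = factor)
  out <- t(apply(record$samples, 1L, function(x) fir_apply(h, x)[keep]))
  record$samples <- out
  record$fs <- target_fs
  record
}

# High-pass filter every channel, compensating the group delay.
highpass_record <- function(record, cutoff, transition_width = 0.5) {
  h <- design_highpass(cutoff, transition_width, record$fs)
  record$samples <- t(apply(record$samples, 1L, function(x) fir_apply(h, x)))
  record
}

#' Segment a record into overlapping epochs
#'
#' Fixed-length epochs with 50% overlap; a trailing part-epoch is
#' discarded. Each epoch is flagged as artefact if it overlaps any
#' artefact annotation by at least one sample, and is assigned an S1/S2
#' state label by majority overlap with the record's state spans (truth
#' spans if present, otherwise S1/S2 annotations).
#'
#' @param record An `eeg_record`.
#' @param params A [preprocess_params()].
#' @return An `epoch_set`: list with `epochs` (list of channels x samples
#'   matrices), `start_times`, `artefact_flags`, `state_labels`, `fs`,
#'   `epoch_length`.
#' @export
segment <- function(record, params = preprocess_params()) {
  fs <- record$fs
  L <- round(params$epoch_length * fs)
  step <- round(L * (1 - params$overlap_fraction))
  n <- ncol(record$samples)
  if (n < L) {
    warning("record shorter than one epoch; returning an empty epoch set")
    return(structure(list(epochs = list(), start_times = numeric(0),
                          artefact_flags = logical(0),
                          state_labels = character(0), fs = fs,
                          epoch_length = params$epoch_length),
                     class = "epoch_set"))
  }
  n_epochs <- floor((n - L) / step) + 1L
  starts <- (seq_len(n_epochs) - 1L) * step
  start_s <- starts / fs
  end_s <- start_s + params$epoch_length

  art <- record$annotations[record$annotations$label == "artefact", , drop = FALSE]
  art_flag <- vapply(seq_len(n_epochs), function(i) {
    any(art$start < end_s[i] & art$end > start_s[i])
  }, logical(1L))

  spans <- NULL
  if (!is.null(record$truth) && !is.null(record$truth$states)) {
    spans <- record$truth$states
    names(spans)[names(spans) == "state6"] <- "label"
  } else if (nrow(record$annotations)) {
    spans <- record$annotations[record$annotations$label %in% c("S1", "S2"), ,
                                drop = FALSE]
  }
  state <- rep(NA_character_, n_epochs)
  if (!is.null(spans) && nrow(spans)) {
    for (i in seq_len(n_epochs)) {
      ov <- pmin(spans$end, end_s[i]) - pmax(spans$start, start_s[i])
      if (any(ov > 0)) state[i] <- spans$label[which.max(ov)]
    }
  }

  epochs <- lapply(starts, function(s0) {
    record$samples[, (s0 + 1L):(s0 + L), drop = FALSE]
  })
  structure(list(epochs = epochs, start_times = start_s,
                 artefact_flags = art_flag, state_labels = state,
                 fs = fs, epoch_length = params$epoch_length),
            class = "epoch_set")
}

#' Full pre-processing chain: high-pass, downsample, segment
#'
#' @param record An `eeg_record` at 256 or 64 Hz.
#' @param params A [preprocess_params()].
#' @return An `epoch_set` at `params$target_fs`.
#' @export
preprocess_record <- function(record, params = preprocess_params()) {
  record <- highpass_record(record, params$hpf_cutoff, params$transition_width)
  record <- downsample(record, params$target_fs)
  segment(record, params)
}
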