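# Synthetic neonatal background EEG with known grade, EEG-state, envelope
# and spectral ground truth. The generative model is multiplicative:
# EEG(t) = a_m(t) * X(t), where X(t) is band-limited coloured noise with a
# 1/f^alpha amplitude response and a_m(t) is a slowly varying non-negative
# amplitude-modulation envelope encoding the grade-specific pattern
# (continuous, trace alternant, burst suppression, inactive).

DEFAULT_MONTAGE <- c(
  "F4-C4", "C4-O2", "T4-C4", "C4-Cz",
  "F3-C3", "C3-O1", "Cz-C3", "C3-T3"
)
RIGHT_CHANNELS <- DEFAULT_MONTAGE[1:4]
LEFT_CHANNELS <- DEFAULT_MONTAGE[5:8]

#' Spectral model for the coloured-noise carrier
#'
#' Describes the stochastic carrier `X(t)`: band-limited noise whose
#' amplitude response follows a `1/f^alpha` power law between `f1` and `f2`,
#' so the power spectral density decays as `f^(-2*alpha)`.
#'
#' @param alpha Spectral exponent (dimensionless). Must exceed 1 unless
#'   `white = TRUE`, the validity domain of the closed-form instantaneous
#'   frequency (see [powerlaw_if()]).
#' @param f1,f2 Lower and upper band edges in Hz, `0 < f1 < f2`.
#' @param white If `TRUE` the shaping filter is bypassed and flat-spectrum
#'   (white) band noise is produced; `alpha` is ignored.
#' @return A `noise_model` list.
#' @export
noise_model <- function(alpha = 1.5, f1 = 0.5, f2 = 32, white = FALSE) {
  if (!white && alpha <= 1) {
    stop("invalid noise model: alpha must be > 1 (use white = TRUE for a flat spectrum)")
  }
  if (!(f1 > 0 && f2 > f1)) stop("invalid noise model: need 0 < f1 < f2")
  structure(list(alpha = alpha, f1 = f1, f2 = f2, white = white),
            class = "noise_model")
}

#' Generate band-limited coloured noise with a power-law spectrum
#'
#' White Gaussian noise is shaped in the frequency domain: its spectrum is
#' multiplied by `f^(-alpha)` inside the model band and zeroed outside, then
#' inverse transformed. This gives exact slope control and simple
#' determinism. The result is standardised to zero mean, unit variance.
#'
#' @param n_samples Number of samples (> 0).
#' @param fs Sampling rate in Hz.
#' @param model A [noise_model()].
#' @param seed Optional integer seed; identical seeds give identical output.
#' @return Numeric vector of length `n_samples`, zero mean, unit variance.
#' @export
make_colored_noise <- function(n_samples, fs, model = noise_model(), seed = NULL) {
  stopifnot(inherits(model, "noise_model"), n_samples > 0)
  f2 <- min(model$f2, fs / 2)
  with_seed(seed, {
    y <- stats::rnorm(n_samples)
    Y <- stats::fft(y)
    k <- seq_len(n_samples) - 1L
    f <- k * fs / n_samples
    f <- pmin(f, fs - f)              # two-sided frequency magnitude
    gain <- if (model$white) rep(1, n_samples) else {
      g <- numeric(n_samples)
      inband <- f >= model$f1 & f <= f2
      g[inband] <- f[inband]^(-model$alpha)
      g
    }
    if (!model$white) {
      gain[f < model$f1 | f > f2] <- 0
    }
    x <- Re(stats::fft(Y * gain, inverse = TRUE)) / n_samples
    x <- x - mean(x)
    s <- stats::sd(x)
    if (s > 0) x <- x / s
    x
  })
}

#' Amplitude-envelope specification for one EEG pattern
#'
#' The envelope encodes a background pattern by alternating a low amplitude
#' (`baseline_amplitude`, the suppression / low phase) and a high amplitude
#' (`burst_amplitude`), with burst onsets drawn from a jittered renewal
#' process: inter-burst intervals are truncated-normal with mean `mean_ibi`,
#' sd `ibi_jitter`, clipped to `ibi_range`. Burst edges are smoothed with a
#' 0.5 s raised-cosine ramp so the envelope varies slowly relative to the
#' carrier.
#'
#' @param pattern One of `"continuous"`, `"trace_alternant"`,
#'   `"burst_suppression"`, `"inactive"`.
#' @param baseline_amplitude,burst_amplitude Amplitudes in microvolts (>= 0).
#' @param mean_ibi,ibi_jitter Mean and jitter of the inter-burst interval, s.
#' @param burst_duration Burst length, s.
#' @param ibi_range Two-element clip range for realised intervals, s.
#' @param ramp Raised-cosine edge length, s.
#' @return An `envelope_spec` list.
#' @export
envelope_spec <- function(pattern = c("continuous", "trace_alternant",
                                      "burst_suppression", "inactive"),
                          baseline_amplitude = 40, burst_amplitude = 40,
                          mean_ibi = 5, ibi_jitter = 1, burst_duration = 4,
                          ibi_range = c(1, 60), ramp = 0.5) {
  pattern <- match.arg(pattern)
  if (baseline_amplitude < 0 || burst_amplitude < 0) {
    stop("invalid envelope spec: amplitudes must be non-negative")
  }
  if (any(c(mean_ibi, ibi_jitter, burst_duration, ramp) < 0)) {
    stop("invalid envelope spec: durations must be non-negative")
  }
  structure(list(pattern = pattern,
                 baseline_amplitude = baseline_amplitude,
                 burst_amplitude = burst_amplitude,
                 mean_ibi = mean_ibi, ibi_jitter = ibi_jitter,
                 burst_duration = burst_duration,
                 ibi_range = ibi_range, ramp = ramp),
            class = "envelope_spec")
}

# Truncated-normal renewal draw, clipped to range.
draw_interval <- function(mean, sd, range) {
  v <- stats::rnorm(1L, mean, sd)
  min(max(v, range[1L]), range[2L])
}

#' Generate a non-negative amplitude envelope and its burst timing truth
#'
#' @param duration Record length in seconds (> 0).
#' @param fs Sampling rate, Hz.
#' @param spec An [envelope_spec()].
#' @param seed Optional seed.
#' @return List with `envelope` (numeric, microvolts, all >= 0), `bursts`
#'   (tibble of start/end seconds) and `ibis` (realised suppression
#'   durations, s).
#' @export
make_envelope <- function(duration, fs, spec = envelope_spec(), seed = NULL) {
  stopifnot(inherits(spec, "envelope_spec"), duration > 0)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs

  if (spec$pattern == "continuous") {
    return(list(envelope = rep(spec$baseline_amplitude, n),
                bursts = tibble::tibble(start = 0, end = duration),
                ibis = numeric(0)))
  }
  if (spec$pattern == "inactive") {
    return(list(envelope = rep(spec$baseline_amplitude, n),
                bursts = tibble::tibble(start = numeric(0), end = numeric(0)),
                ibis = numeric(0)))
  }

  # Renewal process of bursts separated by jittered inter-burst intervals.
  # trace_alternant uses the same machinery with short, regular intervals
  # and a non-zero low phase.
  with_seed(seed, {
    starts <- numeric(0)
    ends <- numeric(0)
    ibis <- numeric(0)
    cur <- draw_interval(spec$mean_ibi, spec$ibi_jitter, spec$ibi_range)
    ibis <- c(ibis, cur)
    while (cur < duration) {
      b_end <- min(cur + spec$burst_duration, duration)
      starts <- c(starts, cur)
      ends <- c(ends, b_end)
      gap <- draw_interval(spec$mean_ibi, spec$ibi_jitter, spec$ibi_range)
      if (b_end < duration) ibis <- c(ibis, min(gap, duration - b_end))
      cur <- b_end + gap
    }
    mask <- numeric(n)
    for (i in seq_along(starts)) {
      mask <- pmax(mask, ramped_pulse(t, starts[i], ends[i], spec$ramp))
    }
    env <- spec$baseline_amplitude +
      (spec$burst_amplitude - spec$baseline_amplitude) * mask
    list(envelope = pmax(env, 0),
         bursts = tibble::tibble(start = starts, end = ends),
         ibis = ibis)
  })
}

# Unit pulse on [start, end] with raised-cosine edges of length `ramp`.
ramped_pulse <- function(t, start, end, ramp) {
  if (ramp <= 0) return(as.numeric(t >= start & t < end))
  up <- (t - (start - ramp)) / ramp
  down <- ((end + ramp) - t) / ramp
  v <- pmin(pmax(pmin(up, down), 0), 1)
  0.5 - 0.5 * cos(pi * v)
}

grade_recipe <- function(grade) {
  switch(grade,
    `1` = list(
      alpha = 1.5,
      s1 = envelope_spec("trace_alternant", baseline_amplitude = 25,
                         burst_amplitude = 50, mean_ibi = 5, ibi_jitter = 1,
                         burst_duration = 5, ibi_range = c(2, 9)),
      s2 = envelope_spec("continuous", baseline_amplitude = 40),
      hemi_scale = c(1, 0.97)),
    `2` = list(
      alpha = 1.5,
      s1 = envelope_spec("burst_suppression", baseline_amplitude = 10,
                         burst_amplitude = 35, mean_ibi = 6, ibi_jitter = 1.5,
                         burst_duration = 4, ibi_range = c(2, 9.5)),
      s2 = envelope_spec("burst_suppression", baseline_amplitude = 13,
                         burst_amplitude = 35, mean_ibi = 4, ibi_jitter = 1,
                         burst_duration = 5, ibi_range = c(2, 9.5)),
      hemi_scale = c(1, 0.8)),
    `3` = list(
      alpha = 2.0,
      s1 = envelope_spec("burst_suppression", baseline_amplitude = 3,
                         burst_amplitude = 25, mean_ibi = 30, ibi_jitter = 8,
                         burst_duration = 6, ibi_range = c(10.5, 59)),
      s2 = NULL,
      hemi_scale = c(1, 0.9)),
    `4` = list(
      alpha = NA_real_, white = TRUE,
      s1 = envelope_spec("inactive", baseline_amplitude = 2),
      s2 = NULL,
      hemi_scale = c(1, 1))
  )
}

new_eeg_record <- function(samples, fs, channel_labels, annotations = NULL,
                           truth = NULL) {
  annotations <- annotations %||%
    tibble::tibble(start = numeric(0), end = numeric(0), label = character(0))
  structure(list(samples = samples, fs = fs,
                 channel_labels = channel_labels,
                 annotations = annotations, truth = truth),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d channels x %.1f s @ %g Hz\n",
              nrow(x$samples), ncol(x$samples) / x$fs, x$fs))
  if (!is.null(x$truth)) cat(sprintf("  truth grade: %d\n", x$truth$grade4))
  if (nrow(x$annotations)) {
    cat(sprintf("  annotations: %d spans\n", nrow(x$annotations)))
  }
  invisible(x)
}

record_duration <- function(record) ncol(record$samples) / record$fs

#' Simulate a multi-channel neonatal EEG recording of known grade
#'
#' Builds an 8-channel bipolar record from the multiplicative model: one
#' master burst train per hemisphere (shared within a hemisphere so
#' synchrony is meaningful, optionally lagged per channel), independent
#' coloured-noise carriers per channel, and hemisphere amplitude scalars to
#' exercise the symmetry feature. Grades 1-2 alternate EEG states S1/S2 on
#' a fixed-period square schedule; grade 3 is burst suppression with
#' inter-burst intervals in 10-60 s; grade 4 is inactive with signal
#' amplitude kept below 10 microvolts.
#'
#' @param grade Integer 1-4.
#' @param duration Record length, seconds.
#' @param fs Sampling rate, Hz (64 or 256).
#' @param n_channels Number of channels (8 for montage operations).
#' @param seed Integer seed; the record is fully determined by it.
#' @param state_cycle Alternate S1/S2 states within grades 1-2.
#' @param state_cycle_period Full S1+S2 cycle length, seconds (the schedule
#'   is half S1, half S2).
#' @param asynchrony Maximum per-channel burst lag in seconds (default 0).
#' @param amplitude_scale Overall multiplier on the grade's default
#'   amplitudes (models inter-subject variability).
#' @return An `eeg_record` carrying grade/state ground truth.
#' @export
simulate_record <- function(grade, duration = 3600, fs = 64, n_channels = 8,
                            seed = 1, state_cycle = TRUE,
                            state_cycle_period = 3600, asynchrony = 0,
                            amplitude_scale = 1) {
  stopifnot(grade %in% 1:4, duration > 0, fs %in% c(64, 256))
  recipe <- grade_recipe(grade)
  n <- round(duration * fs)
  has_states <- grade %in% 1:2 && state_cycle
  if (has_states && duration <= state_cycle_period / 2) {
    warning("record no longer than one EEG-state half-cycle; emitting a single state")
    has_states <- FALSE
  }

  # State schedule: square alternation starting in S1.
  if (has_states) {
    half <- state_cycle_period / 2
    edges <- seq(0, duration, by = half)
    if (edges[length(edges)] < duration) edges <- c(edges, duration)
    states <- tibble::tibble(
      start = edges[-length(edges)],
      end = edges[-1L],
      state6 = paste0(grade, rep(c("S1", "S2"), length.out = length(edges) - 1L))
    )
  } else {
    lab <- if (grade %in% 1:2) paste0(grade, "S1") else as.character(grade)
    states <- tibble::tibble(start = 0, end = duration, state6 = lab)
  }

  with_seed(seed, {
    # Per-hemisphere master envelopes, built state span by state span so the
    # burst statistics switch with the EEG state.
    hemi_env <- list()
    for (h in 1:2) {
      env <- numeric(n)
      for (i in seq_len(nrow(states))) {
        sp <- states[i, ]
        spec <- if (endsWith(sp$state6, "S2") && !is.null(recipe$s2)) recipe$s2 else recipe$s1
        span_n <- round((sp$end - sp$start) * fs)
        i0 <- round(sp$start * fs)
        piece <- make_envelope(sp$end - sp$start, fs, spec,
                               seed = sample.int(2^31 - 1L, 1L))
        env[i0 + seq_len(span_n)] <- piece$envelope[seq_len(span_n)]
      }
      hemi_env[[h]] <- env
    }

    labels <- if (n_channels == 8) DEFAULT_MONTAGE else paste0("Ch", seq_len(n_channels))
    hemi_of <- if (n_channels == 8) rep(1:2, each = 4) else
      rep(1:2, length.out = n_channels)
    nm <- if (isTRUE(recipe$white)) noise_model(white = TRUE) else
      noise_model(alpha = recipe$alpha, f1 = 0.5, f2 = fs / 2)

    samples <- matrix(0, nrow = n_channels, ncol = n)
    for (ch in seq_len(n_channels)) {
      env <- hemi_env[[hemi_of[ch]]]
      if (asynchrony > 0) {
        lag <- round(stats::runif(1L, 0, asynchrony) * fs)
        if (lag > 0) env <- c(rep(env[1L], lag), env[seq_len(n - lag)])
      }
      x <- make_colored_noise(n, fs, nm, seed = sample.int(2^31 - 1L, 1L))
      samples[ch, ] <- env * x *
        recipe$hemi_scale[hemi_of[ch]] * amplitude_scale
    }

    if (grade == 4) {
      # Inactive rule: background activity strictly below 10 microvolts.
      peak <- max(abs(samples))
      if (peak >= 10) samples <- samples * (9 / peak)
    }

    truth <- list(grade4 = as.integer(grade), states = states)
    new_eeg_record(samples, fs, labels, truth = truth)
  })
}

#' Inject an artefact segment into a record
#'
#' `high_amplitude` superimposes a 2 Hz oscillation exceeding 250 microvolts
#' (the major movement artefact definition: > 250 uV for more than 3 s);
#' `baseline_drift` adds a 0.3 Hz, 200 microvolt sinusoid. The span is added
#' to the record's annotations with label `"artefact"`; overlapping
#' annotations are all kept.
#'
#' @param record An `eeg_record`.
#' @param kind `"high_amplitude"` or `"baseline_drift"`.
#' @param start,duration Span in seconds; must lie within the record.
#' @param channels Channel indices affected (default all).
#' @return The modified `eeg_record`.
#' @export
inject_artefact <- function(record, kind = c("high_amplitude", "baseline_drift"),
                            start, duration, channels = NULL) {
  kind <- match.arg(kind)
  if (duration <= 0) return(record)
  dur_rec <- record_duration(record)
  if (start < 0 || start + duration > dur_rec) {
    stop("artefact span must lie within the record")
  }
  fs <- record$fs
  idx <- (round(start * fs) + 1L):round((start + duration) * fs)
  t <- (idx - 1L) / fs
  wave <- switch(kind,
    high_amplitude = 350 * sin(2 * pi * 2 * t),
    baseline_drift = 200 * sin(2 * pi * 0.3 * t))
  channels <- channels %||% seq_len(nrow(record$samples))
  for (ch in channels) {
    record$samples[ch, idx] <- record$samples[ch, idx] + wave
  }
  record$annotations <- dplyr::bind_rows(
    record$annotations,
    tibble::tibble(start = start, end = start + duration, label = "artefact"))
  record
}

#' Simulate a labelled corpus of recordings
#'
#' One record per subject, grades balanced. Per-subject amplitude scale is
#' drawn log-normally (sd 0.1) to model inter-subject variability. For
#' records shorter than the default hour the S1/S2 cycle period is set to
#' the record duration, preserving the half-and-half state proportion.
#'
#' @param n_per_grade Records per grade.
#' @param duration Record length, seconds.
#' @param fs Sampling rate.
#' @param seed Corpus seed.
#' @param artefact_fraction Fraction of records receiving one injected
#'   high-amplitude artefact (default 0).
#' @return A list of `eeg_record`s with subject ids in `names()`.
#' @export
simulate_corpus <- function(n_per_grade = 10, duration = 600, fs = 64,
                            seed = 1, artefact_fraction = 0) {
  grades <- rep(1:4, each = n_per_grade)
  records <- with_seed(seed, {
    seeds <- sample.int(2^31 - 1L, length(grades))
    scales <- exp(stats::rnorm(length(grades), 0, 0.1))
    art <- stats::runif(length(grades)) < artefact_fraction
    purrr::pmap(list(grades, seeds, scales, art), function(g, s, sc, a) {
      rec <- simulate_record(g, duration = duration, fs = fs, seed = s,
                             state_cycle = TRUE,
                             state_cycle_period = min(3600, duration),
                             amplitude_scale = sc)
      if (a) {
        t0 <- stats::runif(1L, 0, duration - 30)
        rec <- inject_artefact(rec, "high_amplitude", start = t0, duration = 20)
      }
      rec
    })
  })
  names(records) <- sprintf("subj%02d_g%d", seq_along(grades), grades)
  records
}
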