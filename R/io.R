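# EDF (European Data Format) input/output, plain-text sidecar annotation
# and truth files, and configuration loading. EDF stores 16-bit samples
# with per-signal physical scaling; records are written with a 1 s record
# duration and the physical dimension set to microvolts.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write an EEG record to an EDF file
#'
#' 16-bit encoding with symmetric physical limits covering the signal
#' range; a trailing part-second of samples is dropped (EDF stores whole
#' data records of 1 s here).
#'
#' @param record An `eeg_record` with finite samples.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path) {
  samples <- record$samples
  if (anyNA(samples) || !all(is.finite(samples))) {
    stop("cannot write EDF: samples contain NA or non-finite values")
  }
  fs <- record$fs
  ns <- nrow(samples)
  n_rec <- floor(ncol(samples) / fs)
  if (n_rec < 1L) stop("record shorter than one EDF data record (1 s)")

  peak <- max(abs(samples), 1e-6)
  phys_max <- signif(peak * 1.0001, 7)
  phys_min <- -phys_max
  dig_max <- 32767L; dig_min <- -32767L   # symmetric so zero maps exactly
  scale <- (dig_max - dig_min) / (phys_max - phys_min)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + ns * 256L
  writeChar(paste0(
    edf_pad("0", 8L),
    edf_pad("X X X X", 80L),
    edf_pad("Startdate X X X X", 80L),
    edf_pad("01.01.00", 8L), edf_pad("00.00.00", 8L),
    edf_pad(hdr_bytes, 8L), edf_pad("", 44L),
    edf_pad(n_rec, 8L), edf_pad(1, 8L), edf_pad(ns, 4L)),
    con, eos = NULL)
  field <- function(values, width) {
    writeChar(paste(vapply(values, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  field(record$channel_labels, 16L)
  field(rep("", ns), 80L)
  field(rep("uV", ns), 8L)
  field(rep(format(phys_min, digits = 7), ns), 8L)
  field(rep(format(phys_max, digits = 7), ns), 8L)
  field(rep(dig_min, ns), 8L)
  field(rep(dig_max, ns), 8L)
  field(rep("", ns), 80L)
  field(rep(fs, ns), 8L)
  field(rep("", ns), 32L)

  dig <- round((samples - phys_min) * scale) + dig_min
  dig <- pmin(pmax(dig, dig_min), dig_max)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into an EEG record
#'
#' All signals must share one sampling rate (the montage assumption of
#' the grading pipeline). Samples are returned in physical units
#' (microvolts for files written by [write_edf()]).
#'
#' @param path EDF file path.
#' @return An `eeg_record` (without annotations or truth; see
#'   [read_annotations()]).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8L)                 # version
  rd(80L); rd(80L); rd(8L); rd(8L)
  hdr_bytes <- as.integer(rd(8L))
  rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  if (is.na(ns) || ns < 1L) stop("corrupt EDF header: bad signal count")
  fields <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- fields(16L)
  fields(80L); fields(8L)
  phys_min <- as.numeric(fields(8L))
  phys_max <- as.numeric(fields(8L))
  dig_min <- as.numeric(fields(8L))
  dig_max <- as.numeric(fields(8L))
  fields(80L)
  spr <- as.integer(fields(8L))
  fields(32L)
  if (length(unique(spr)) != 1L) stop("EDF signals have differing sampling rates")
  fs <- spr[1L] / rec_dur

  expect <- n_rec * sum(spr) * 2L
  raw_data <- readBin(con, "integer", n = n_rec * sum(spr), size = 2L,
                      signed = TRUE, endian = "little")
  if (length(raw_data) < n_rec * sum(spr)) {
    stop(sprintf("truncated EDF: expected %d data bytes after the %d-byte header, got %d",
                 expect, hdr_bytes, length(raw_data) * 2L))
  }
  samples <- matrix(0, nrow = ns, ncol = n_rec * spr[1L])
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      seg <- raw_data[(pos + 1L):(pos + spr[ch])]
      pos <- pos + spr[ch]
      cols <- ((r - 1L) * spr[ch] + 1L):(r * spr[ch])
      samples[ch, cols] <- seg * scale[ch] + phys_min[ch] - dig_min[ch] * scale[ch]
    }
  }
  new_eeg_record(samples, fs, labels)
}

#' Write / read a sidecar annotation file
#'
#' Plain-text, one span per line: `start_s<TAB>end_s<TAB>label`, with
#' labels from `{artefact, S1, S2, grade:N}`. The same dialect stores the
#' simulation ground truth.
#'
#' @param annotations Tibble with `start`, `end`, `label`.
#' @param path File path.
#' @return `path` invisibly (write); a tibble (read).
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("start", "end", "label"),
                           colClasses = c("numeric", "numeric", "character"))
  bad <- tab$start >= tab$end
  if (any(bad)) stop("invalid annotation span(s): start must precede end")
  if (sum(grepl("^grade:", tab$label)) > 1L) {
    stop("at most one grade label per annotation file")
  }
  tibble::as_tibble(tab)
}

# Attach annotations/truth from a sidecar table to a record.
apply_annotations <- function(record, annotations) {
  g <- grep("^grade:", annotations$label)
  spans <- annotations[setdiff(seq_len(nrow(annotations)), g), , drop = FALSE]
  record$annotations <- dplyr::bind_rows(
    record$annotations,
    spans[spans$label == "artefact", , drop = FALSE],
    spans[spans$label %in% c("S1", "S2"), , drop = FALSE])
  if (length(g)) {
    grade <- as.integer(sub("^grade:", "", annotations$label[g]))
    st <- spans[spans$label %in% c("S1", "S2"), , drop = FALSE]
    states <- if (nrow(st)) {
      tibble::tibble(start = st$start, end = st$end,
                     state6 = if (grade %in% 1:2)
                       paste0(grade, st$label) else as.character(grade))
    } else {
      tibble::tibble(start = 0, end = record_duration(record),
                     state6 = if (grade %in% 1:2) paste0(grade, "S1")
                              else as.character(grade))
    }
    record$truth <- list(grade4 = grade, states = states)
  }
  record
}

CONFIG_DEFAULTS <- list(
  epoch_length = 64, hpf_cutoff = 2.5, transition_width = 0.5,
  target_fs = 64, overlap_fraction = 0.5, train_minutes = 7, seed = 1)

#' Load a pipeline configuration file
#'
#' YAML key-value file with keys matching [preprocess_params()] fields
#' plus `train_minutes` and `seed`. Missing keys take the defaults (the
#' optimal operating point: 64 s epochs, 2.5 Hz cutoff); unknown keys and
#' out-of-range values are rejected.
#'
#' @param path Config file path, or `NULL` for pure defaults.
#' @return Named list of validated parameters.
#' @export
load_config <- function(path = NULL) {
  cfg <- CONFIG_DEFAULTS
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (length(user)) {
      unknown <- setdiff(names(user), names(CONFIG_DEFAULTS))
      if (length(unknown)) {
        stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
      }
      cfg[names(user)] <- user
    }
  }
  if (cfg$epoch_length < 8 || cfg$epoch_length > 64) {
    stop("epoch_length out of range [8, 64] s")
  }
  if (cfg$hpf_cutoff < 0.5 || cfg$hpf_cutoff > 3) {
    stop("hpf_cutoff out of range [0.5, 3] Hz")
  }
  cfg
}

config_params <- function(cfg) {
  preprocess_params(cfg$epoch_length, cfg$hpf_cutoff, cfg$transition_width,
                    cfg$target_fs, cfg$overlap_fraction)
}
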