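#' Single-channel EEG recording
#'
#' Lightweight container for one monopolar EEG channel. Amplitudes are in
#' microvolts at the native sampling rate; no resampling is ever applied
#' because every downstream feature is defined on windows measured in
#' seconds.
#'
#' @param samples Numeric vector of amplitudes (uV).
#' @param fs Sampling rate in Hz; at least 128.
#' @param subject_id Subject identifier.
#' @param channel Channel label, typically `"C4-A1"`.
#' @return An object of class `eeg_recording`: a list with elements
#'   `samples`, `fs`, `subject_id`, `channel`.
#' @export
eeg_recording <- function(samples, fs, subject_id = "S001", channel = "C4-A1") {
  if (!is.numeric(fs) || length(fs) != 1L || fs < 128)
    abort("`fs` must be a single number >= 128 Hz.")
  if (!is.numeric(samples) || length(samples) == 0L)
    abort("`samples` must be a non-empty numeric vector.")
  if (!all(is.finite(samples)))
    abort("`samples` must be finite.")
  structure(
    list(samples = as.numeric(samples), fs = fs,
         subject_id = as.character(subject_id), channel = as.character(channel)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s, channel %s: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$channel, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' Recording duration in whole seconds
#' @param recording An [eeg_recording()].
#' @return Integer number of complete seconds.
#' @export
recording_seconds <- function(recording) {
  as.integer(floor(length(recording$samples) / recording$fs))
}

norm_channel <- function(x) toupper(gsub("[ _-]", "", x))

#' Read one EEG channel from an EDF file
#'
#' Compact reader for European Data Format recordings (16-bit samples).
#' Channel matching tolerates the usual label dialects (`"C4-A1"`, `"C4A1"`,
#' `"C4_A1"`, case and whitespace differences). Samples are returned on the
#' physical scale declared in the header, i.e. in microvolts for EEG.
#'
#' @param path Path to an EDF file.
#' @param channel Channel label to extract (default `"C4-A1"`).
#' @param subject_id Subject id to attach; defaults to the file's local
#'   recording identification field, or the file name.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, channel = "C4-A1", subject_id = NULL) {
  if (!file.exists(path)) abort(sprintf("EDF file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rd_str <- function(n) {
    raw <- readBin(con, "raw", n)
    trimws(rawToChar(raw))
  }
  version <- rd_str(8)
  patient <- rd_str(80)
  recinfo <- rd_str(80)
  rd_str(8); rd_str(8)                       # start date, time
  n_header <- suppressWarnings(as.integer(rd_str(8)))
  rd_str(44)
  n_rec <- suppressWarnings(as.integer(rd_str(8)))
  rec_dur <- suppressWarnings(as.numeric(rd_str(8)))
  ns <- suppressWarnings(as.integer(rd_str(4)))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || is.na(rec_dur))
    abort(sprintf("Not a readable EDF file (malformed header): %s", path))
  field <- function(w) vapply(seq_len(ns), function(i) rd_str(w), character(1))
  labels <- field(16)
  field(80)                                  # transducer
  field(8)                                   # physical dimension
  pmin <- as.numeric(field(8)); pmax <- as.numeric(field(8))
  dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8))
  field(80)                                  # prefiltering
  spr <- as.integer(field(8))                # samples per record
  field(32)
  idx <- match(norm_channel(channel), norm_channel(labels))
  if (is.na(idx))
    abort(sprintf("Channel '%s' not found. Available channels: %s",
                  channel, paste(labels, collapse = ", ")))
  total_per_rec <- sum(spr)
  dat <- readBin(con, "integer", n = n_rec * total_per_rec, size = 2,
                 signed = TRUE, endian = "little")
  if (length(dat) < n_rec * total_per_rec)
    abort(sprintf("EDF file truncated: %s", path))
  offs <- c(0L, cumsum(spr))[idx]
  take <- as.vector(outer(seq_len(spr[idx]) + offs,
                          (seq_len(n_rec) - 1L) * total_per_rec, `+`))
  dig <- dat[take]
  gain <- (pmax[idx] - pmin[idx]) / (dmax[idx] - dmin[idx])
  phys <- (dig - dmin[idx]) * gain + pmin[idx]
  fs <- spr[idx] / rec_dur
  if (is.null(subject_id)) {
    subject_id <- if (nzchar(recinfo)) recinfo else basename(path)
  }
  eeg_recording(phys, fs, subject_id = subject_id, channel = labels[idx])
}

#' Write a recording to an EDF file
#'
#' Minimal single-channel EDF writer (16-bit, one-second data records) used
#' mainly to materialise synthetic cohorts on disk.
#'
#' @param recording An [eeg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  fs <- recording$fs
  if (fs != round(fs)) abort("EDF writer requires an integer sampling rate.")
  n_sec <- recording_seconds(recording)
  x <- recording$samples[seq_len(n_sec * fs)]
  pmax <- max(abs(x), 1e-6)
  pmin <- -pmax
  dmin <- -32768; dmax <- 32767
  dig <- round((x - pmin) / (pmax - pmin) * (dmax - dmin) + dmin)
  dig <- as.integer(pmin(pmax(dig, dmin), dmax))
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(s, w) {
    s <- substr(s, 1, w)
    writeChar(formatC(s, width = -w), con, eos = NULL)
  }
  pad("0", 8)
  pad(recording$subject_id, 80)
  pad(recording$subject_id, 80)
  pad("01.01.00", 8); pad("00.00.00", 8)
  pad(as.character(256L + 256L), 8)
  pad("", 44)
  pad(as.character(n_sec), 8)
  pad("1", 8)
  pad("1", 4)
  pad(recording$channel, 16)
  pad("", 80)
  pad("uV", 8)
  pad(formatC(pmin, format = "g", digits = 6), 8)
  pad(formatC(pmax, format = "g", digits = 6), 8)
  pad(as.character(dmin), 8)
  pad(as.character(dmax), 8)
  pad("", 80)
  pad(as.character(as.integer(fs)), 8)
  pad("", 32)
  writeBin(dig, con, size = 2, endian = "little")
  invisible(path)
}

cap_subtypes <- function() c("A1", "A2", "A3")

#' Read CAP A-phase annotations
#'
#' Reads the canonical annotation format: a tab-separated table with header
#' `onset_s  duration_s  subtype`, subtype one of `A1`, `A2`, `A3`. Events
#' are returned sorted chronologically. Durations outside the 2--60 s range
#' an A-phase may take raise a warning but the events are kept.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `onset`, `duration`, `subtype` (factor).
#' @export
read_cap_annotations <- function(path) {
  if (!file.exists(path)) abort(sprintf("Annotation file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  if (length(lines_keep) == 0L) return(empty_events())
  header <- strsplit(lines[lines_keep[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(trimws(header), c("onset_s", "duration_s", "subtype")))
    abort(sprintf("Line %d: expected header 'onset_s\\tduration_s\\tsubtype'.",
                  lines_keep[1]))
  body <- lines_keep[-1]
  if (length(body) == 0L) return(empty_events())
  rows <- lapply(body, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 3L)
      abort(sprintf("Line %d: expected 3 tab-separated fields, got %d.", i, length(f)))
    onset <- suppressWarnings(as.numeric(f[1]))
    dur <- suppressWarnings(as.numeric(f[2]))
    sub <- trimws(f[3])
    if (is.na(onset) || onset < 0)
      abort(sprintf("Line %d: invalid onset '%s'.", i, f[1]))
    if (is.na(dur) || dur <= 0)
      abort(sprintf("Line %d: invalid duration '%s'.", i, f[2]))
    if (!sub %in% cap_subtypes())
      abort(sprintf("Line %d: unknown subtype '%s' (expected A1, A2 or A3).", i, sub))
    tibble(onset = onset, duration = dur, subtype = sub)
  })
  ev <- dplyr::bind_rows(rows)
  bad <- ev$duration < 2 | ev$duration > 60
  if (any(bad))
    warn(sprintf("%d event(s) with duration outside [2, 60] s kept as-is.", sum(bad)))
  ev <- dplyr::arrange(ev, .data$onset)
  ev$subtype <- factor(ev$subtype, levels = cap_subtypes())
  ev
}

empty_events <- function() {
  tibble(onset = numeric(), duration = numeric(),
         subtype = factor(character(), levels = cap_subtypes()))
}

#' Best-effort importer for Physionet-style CAP scoring files
#'
#' The CAP scoring files distributed with polysomnography databases are
#' free-text tables (clock times, event tokens such as `MCAP-A1`, duration
#' columns). This importer scans each line for a clock time `hh:mm:ss`, a
#' token containing `A1`/`A2`/`A3` and a trailing duration in seconds, and
#' converts clock times to onsets relative to `start_time` (the recording
#' start, `"hh:mm:ss"`; defaults to the first event's time). Times crossing
#' midnight are unwrapped. Lines that do not parse are skipped silently --
#' this path is best-effort by design; the canonical strict format is
#' [read_cap_annotations()].
#'
#' @param path Path to the free-text scoring file.
#' @param start_time Recording start clock time `"hh:mm:ss"`, or `NULL`.
#' @return A tibble with columns `onset`, `duration`, `subtype`, sorted by
#'   onset.
#' @export
read_cap_annotations_physionet <- function(path, start_time = NULL) {
  if (!file.exists(path)) abort(sprintf("Annotation file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  to_sec <- function(hms) {
    p <- as.numeric(strsplit(hms, ":", fixed = TRUE)[[1]])
    p[1] * 3600 + p[2] * 60 + p[3]
  }
  rows <- list()
  for (ln in lines) {
    tm <- regmatches(ln, regexpr("\\b\\d{1,2}:\\d{2}:\\d{2}\\b", ln))
    sub <- regmatches(ln, regexpr("A[123]\\b", ln))
    dur <- regmatches(ln, regexpr("\\b\\d+(\\.\\d+)?\\s*$", ln))
    if (length(tm) != 1 || length(sub) != 1 || length(dur) != 1) next
    rows[[length(rows) + 1L]] <-
      tibble(clock = to_sec(tm), duration = as.numeric(trimws(dur)),
             subtype = sub)
  }
  if (length(rows) == 0L) return(empty_events())
  ev <- dplyr::bind_rows(rows)
  t0 <- if (is.null(start_time)) ev$clock[1] else to_sec(start_time)
  onset <- ev$clock - t0
  onset[onset < 0] <- onset[onset < 0] + 86400   # crossed midnight
  out <- tibble(onset = onset, duration = ev$duration,
                subtype = factor(ev$subtype, levels = cap_subtypes()))
  dplyr::arrange(out, .data$onset)
}

#' Write CAP A-phase annotations
#'
#' Inverse of [read_cap_annotations()]; writes the canonical 3-column TSV.
#'
#' @param events Tibble with columns `onset`, `duration`, `subtype`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cap_annotations <- function(events, path) {
  lines <- c("onset_s\tduration_s\tsubtype",
             sprintf("%s\t%s\t%s",
                     format(events$onset, trim = TRUE, scientific = FALSE),
                     format(events$duration, trim = TRUE, scientific = FALSE),
                     as.character(events$subtype)))
  writeLines(lines, path)
  invisible(path)
}

#' Per-second class labels from A-phase events
#'
#' Discretises annotation intervals to the 1 Hz label grid used everywhere
#' in the package. Time is 0-based with half-open epochs `[t, t+1)`. Each
#' second takes the subtype with the largest overlap; where A-events overlap,
#' the later-onset event wins; an exact tie between an A subtype and
#' background goes to the A subtype, so boundary effects never erode the
#' minority class.
#'
#' @param events Tibble of events as from [read_cap_annotations()].
#' @param duration Recording duration in seconds.
#' @param subject_id Subject id attached to the output.
#' @return A tibble with columns `subject`, `second` (0-based), `label`
#'   (factor with levels `B`, `A1`, `A2`, `A3`).
#' @export
build_second_labels <- function(events, duration, subject_id = "S001") {
  n <- as.integer(floor(duration))
  lab <- rep("B", n)
  if (nrow(events) > 0L) {
    ev <- dplyr::arrange(events, .data$onset)
    if (any(ev$onset + ev$duration > duration)) {
      warn("Event(s) extending past the recording end were truncated.")
      ev$duration <- pmin(ev$duration, duration - ev$onset)
      ev <- ev[ev$duration > 0, ]
    }
    first <- if (nrow(ev) > 0L) max(0L, as.integer(floor(min(ev$onset)))) else n
    for (t in seq_len(max(0L, n - first)) + first - 1L) {
      lo <- t; hi <- t + 1
      cover <- pmin(ev$onset + ev$duration, hi) - pmax(ev$onset, lo)
      hit <- which(cover > 0)
      if (length(hit) == 0L) next
      # paint overlapping events later-onset-on-top within this second
      bounds <- sort(unique(c(lo, hi,
                              pmax(lo, pmin(hi, ev$onset[hit])),
                              pmax(lo, pmin(hi, ev$onset[hit] + ev$duration[hit])))))
      seg_cov <- setNames(numeric(3), cap_subtypes())
      for (s in seq_len(length(bounds) - 1L)) {
        mid <- (bounds[s] + bounds[s + 1]) / 2
        on_seg <- hit[ev$onset[hit] <= mid & ev$onset[hit] + ev$duration[hit] > mid]
        if (length(on_seg) == 0L) next
        top <- on_seg[which.max(ev$onset[on_seg])]
        st <- as.character(ev$subtype[top])
        seg_cov[st] <- seg_cov[st] + (bounds[s + 1] - bounds[s])
      }
      a_total <- sum(seg_cov)
      if (a_total == 0) next
      b_cov <- 1 - a_total
      best <- names(seg_cov)[which.max(seg_cov)]
      # A wins exact ties with B; between subtypes the larger painted cover wins
      if (max(seg_cov) >= b_cov) lab[t + 1L] <- best
    }
  }
  tibble(subject = as.character(subject_id), second = seq_len(n) - 1L,
         label = cap_factor(lab))
}
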