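#' Specification of a synthetic CAP cohort
#'
#' Parameters of the synthetic generator. The defaults describe the study
#' conditions used throughout the package's own evaluation: 8 subjects,
#' 20 minutes per subject at 128 Hz, 25 uV background, A1 events doubling
#' the delta-band amplitude (comfortably above the defining one-third
#' increase), A3 events doubling the fast-band amplitude, 1.5 events per
#' minute and a subtype mix dominated by A1 as in clinical scoring.
#'
#' @param n_subjects Number of subjects.
#' @param duration Seconds per subject (>= 300).
#' @param fs Sampling rate (Hz).
#' @param background_sigma Background standard deviation (uV).
#' @param a1_gain Multiplicative delta-band amplitude factor during A1
#'   spans; must be at least 4/3 (an A1 raises amplitude by at least a
#'   third over background).
#' @param a3_gain Fast-band (8--35 Hz) amplitude factor during A3 spans.
#' @param event_rate Planted A-phases per minute.
#' @param subtype_mix Probabilities of subtypes A1, A2, A3; must sum to 1.
#' @param sigma_jitter Relative per-subject jitter of `background_sigma`
#'   (uniform within `1 +/- sigma_jitter`), emulating inter-subject
#'   amplitude variability.
#' @param seed Master seed; per-subject seeds are derived from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 8L, duration = 1200, fs = 128,
                           background_sigma = 25, a1_gain = 2, a3_gain = 2,
                           event_rate = 1.5,
                           subtype_mix = c(A1 = 0.4, A2 = 0.3, A3 = 0.3),
                           sigma_jitter = 0.2, seed = 1L) {
  if (abs(sum(subtype_mix) - 1) > 1e-8) abort("`subtype_mix` must sum to 1.")
  if (length(subtype_mix) != 3L) abort("`subtype_mix` must have 3 entries (A1, A2, A3).")
  if (a1_gain < 4 / 3) abort("`a1_gain` must be at least 4/3.")
  if (duration < 300) abort("`duration` must be at least 300 s.")
  if (n_subjects < 1) abort("`n_subjects` must be positive.")
  structure(
    list(n_subjects = as.integer(n_subjects), duration = duration, fs = fs,
         background_sigma = background_sigma, a1_gain = a1_gain,
         a3_gain = a3_gain, event_rate = event_rate,
         subtype_mix = setNames(as.numeric(subtype_mix), c("A1", "A2", "A3")),
         sigma_jitter = sigma_jitter, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate 1/f background EEG
#'
#' Zero-mean noise with a 1/f power spectrum band-limited to 0.3--35 Hz,
#' the minimal background model under which all band-amplitude features
#' take non-degenerate values. The output is rescaled so its standard
#' deviation equals `sigma` exactly.
#'
#' @param duration Seconds (>= 120, so the 60 s background window of the
#'   amplitude features is meaningful).
#' @param fs Sampling rate (Hz).
#' @param sigma Target standard deviation (uV).
#' @param seed Integer seed; same seed gives identical samples.
#' @param subject_id Subject id for the returned recording.
#' @return An [eeg_recording()].
#' @export
generate_background <- function(duration, fs = 128, sigma = 25, seed = 1L,
                                subject_id = "S001") {
  if (!is.numeric(duration) || duration < 120)
    abort("`duration` must be at least 120 s.")
  if (!is.numeric(fs) || fs <= 0) abort("`fs` must be positive.")
  withr::local_seed(seed)
  n <- as.integer(round(duration * fs))
  w <- rnorm(n)
  f <- (seq_len(n) - 1L) / n * fs
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  gain <- ifelse(f >= 0.3 & f <= 35, 1 / sqrt(pmax(f, 0.3)), 0)
  x <- Re(fft(fft(w) * gain, inverse = TRUE)) / n
  x <- x - mean(x)
  x <- x * (sigma / sd(x))
  eeg_recording(x, fs, subject_id = subject_id)
}

draw_event_durations <- function(n) {
  pmin(60, pmax(2, round(stats::rgamma(n, shape = 2.2, scale = 4.5))))
}

#' Plant CAP A-phases into a background recording
#'
#' Plants non-overlapping A-phase events (>= 2 s apart, integer-second
#' aligned, durations in 2--60 s) into a background recording. A1 events
#' multiply the delta-band component by `a1_gain`; A3 events add fast
#' (8--35 Hz) activity scaled to `a3_gain` times the background fast-band
#' amplitude while attenuating the delta component; A2 events apply the A1
#' modification over a uniform 50--80% leading fraction of the event and
#' the A3 modification over the remainder, matching the subtype definition.
#'
#' @param background An [eeg_recording()], typically from
#'   [generate_background()].
#' @param spec A [synthetic_spec()] (its gains, rate and mix are used).
#' @param seed Integer seed for event placement and subtype draws.
#' @return A list with `recording` (modified [eeg_recording()]), `labels`
#'   (per-second tibble from [build_second_labels()]) and `events` (tibble
#'   of onset/duration/subtype).
#' @export
plant_a_phases <- function(background, spec, seed = 1L) {
  withr::local_seed(seed)
  fs <- background$fs
  n_sec <- recording_seconds(background)
  x <- background$samples
  n_events <- as.integer(round(spec$event_rate * n_sec / 60))
  if (n_events == 0L) {
    return(list(recording = background,
                labels = build_second_labels(empty_events(), n_sec,
                                             background$subject_id),
                events = empty_events()))
  }
  durs <- draw_event_durations(n_events)
  slack <- n_sec - sum(durs) - 2L * (n_events + 1L)
  if (slack < 0)
    abort("`event_rate` too high: events cannot be placed non-overlapping with 2 s gaps.")
  extra <- as.vector(stats::rmultinom(1, slack, rep(1, n_events + 1L)))
  onsets <- integer(n_events)
  t <- 0L
  for (i in seq_len(n_events)) {
    t <- t + 2L + extra[i]
    onsets[i] <- t
    t <- t + durs[i]
  }
  subtypes <- sample(c("A1", "A2", "A3"), n_events, replace = TRUE,
                     prob = spec$subtype_mix)

  delta_x <- bandpass(x, fs, 0.3, 4)
  fast_ref <- mean(abs(bandpass(x, fs, 8, 35)))
  w2 <- rnorm(length(x), sd = sd(x))
  fast_x <- bandpass(w2, fs, 8, 35)
  fast_x <- fast_x * (fast_ref / mean(abs(fast_x)))

  apply_a1 <- function(idx) x[idx] <<- x[idx] + (spec$a1_gain - 1) * delta_x[idx]
  apply_a3 <- function(idx) {
    x[idx] <<- x[idx] - 0.6 * delta_x[idx] +
      (spec$a3_gain - 1) * fast_x[idx]
  }
  for (i in seq_len(n_events)) {
    i0 <- onsets[i] * fs
    idx <- (i0 + 1L):(i0 + durs[i] * fs)
    if (subtypes[i] == "A1") {
      apply_a1(idx)
    } else if (subtypes[i] == "A3") {
      apply_a3(idx)
    } else {
      frac <- runif(1, 0.5, 0.8)
      n_a1 <- max(1L, round(frac * durs[i])) * fs
      apply_a1(idx[seq_len(n_a1)])
      if (n_a1 < length(idx)) apply_a3(idx[(n_a1 + 1L):length(idx)])
    }
  }
  events <- tibble(onset = as.numeric(onsets), duration = as.numeric(durs),
                   subtype = factor(subtypes, levels = cap_subtypes()))
  rec <- eeg_recording(x, fs, subject_id = background$subject_id,
                       channel = background$channel)
  list(recording = rec,
       labels = build_second_labels(events, n_sec, background$subject_id),
       events = events)
}

#' Generate a multi-subject synthetic cohort
#'
#' Independent recordings per subject with per-subject seeds derived from
#' the master seed (background seed `seed + i`, planting seed
#' `seed + 10000 + i`) and per-subject background amplitude jitter.
#' Subject ids are `"S001"`, `"S002"`, ...
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `synthetic_cohort`: list with `recordings`,
#'   `labels` (list of per-second tibbles), `events` (list of tibbles) and
#'   `spec`.
#' @export
generate_cohort <- function(spec) {
  out <- lapply(seq_len(spec$n_subjects), function(i) {
    sid <- sprintf("S%03d", i)
    withr::with_seed(spec$seed + 20000L + i, {
      sig <- spec$background_sigma *
        runif(1, 1 - spec$sigma_jitter, 1 + spec$sigma_jitter)
    })
    bg <- generate_background(spec$duration, spec$fs, sig,
                              seed = spec$seed + i, subject_id = sid)
    plant_a_phases(bg, spec, seed = spec$seed + 10000L + i)
  })
  structure(
    list(recordings = lapply(out, `[[`, "recording"),
         labels = lapply(out, `[[`, "labels"),
         events = lapply(out, `[[`, "events"),
         spec = spec),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects x %g s @ %g Hz\n",
              length(x$recordings), x$spec$duration, x$spec$fs))
  invisible(x)
}

#' Combined label table of a cohort
#'
#' @param cohort A `synthetic_cohort`.
#' @return Tibble with columns `subject`, `second`, `label` over all
#'   subjects.
#' @export
cohort_labels <- function(cohort) dplyr::bind_rows(cohort$labels)
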