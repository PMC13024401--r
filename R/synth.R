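#' Rhythm generation specification
#'
#' Parameters controlling how one rhythm class is synthesized: the heart-rate
#' range, P-wave presence/amplitude, QRS width and shape, and beat-to-beat
#' R-R variability. Defaults follow standard clinical conventions for the
#' five classes: NSR 60-100 bpm, ST 100-150 bpm, SB 40-59 bpm, SVT 150-220
#' bpm (P waves absent/obscured, narrow QRS), VT 120-250 bpm (wide distorted
#' QRS, no P).
#'
#' @param label one of `RHYTHM_CLASSES`.
#' @param hr_range_bpm closed heart-rate interval in beats/min, lower > 0.
#' @param p_wave_present logical; whether a P deflection precedes each QRS.
#' @param p_amplitude_scale non-negative scale on the P amplitude (0 removes
#'   the P wave even when `p_wave_present`).
#' @param qrs_width_ms target half-height width of the R complex in
#'   milliseconds; must exceed 120 ms for `wide_distorted` shapes.
#' @param qrs_shape `"narrow"` (sinus/supraventricular morphology) or
#'   `"wide_distorted"` (ventricular morphology).
#' @param rr_jitter_frac fractional standard deviation of instantaneous
#'   heart rate around the recording mean.
#' @return object of class `rhythm_spec`.
#' @export
rhythm_spec <- function(label,
                        hr_range_bpm = NULL,
                        p_wave_present = NULL,
                        p_amplitude_scale = NULL,
                        qrs_width_ms = NULL,
                        qrs_shape = NULL,
                        rr_jitter_frac = NULL) {
  assert_rhythm_label(label)
  def <- .default_rhythm_specs[[label]]
  spec <- list(
    label = label,
    hr_range_bpm = hr_range_bpm %||% def$hr_range_bpm,
    p_wave_present = p_wave_present %||% def$p_wave_present,
    p_amplitude_scale = p_amplitude_scale %||% def$p_amplitude_scale,
    qrs_width_ms = qrs_width_ms %||% def$qrs_width_ms,
    qrs_shape = qrs_shape %||% def$qrs_shape,
    rr_jitter_frac = rr_jitter_frac %||% def$rr_jitter_frac
  )
  if (spec$hr_range_bpm[1] <= 0 || spec$hr_range_bpm[2] < spec$hr_range_bpm[1])
    stop("hr_range_bpm must satisfy 0 < lower <= upper", call. = FALSE)
  if (spec$qrs_width_ms <= 0)
    stop("qrs_width_ms must be positive", call. = FALSE)
  if (!spec$qrs_shape %in% c("narrow", "wide_distorted"))
    stop("qrs_shape must be 'narrow' or 'wide_distorted'", call. = FALSE)
  if (spec$qrs_shape == "wide_distorted" && spec$qrs_width_ms <= 120)
    stop("wide_distorted QRS requires qrs_width_ms > 120", call. = FALSE)
  if (spec$p_amplitude_scale < 0 || spec$rr_jitter_frac < 0)
    stop("p_amplitude_scale and rr_jitter_frac must be >= 0", call. = FALSE)
  class(spec) <- "rhythm_spec"
  spec
}

.default_rhythm_specs <- list(
  NSR = list(hr_range_bpm = c(60, 100), p_wave_present = TRUE,
             p_amplitude_scale = 1, qrs_width_ms = 80, qrs_shape = "narrow",
             rr_jitter_frac = 0.05),
  ST  = list(hr_range_bpm = c(100, 150), p_wave_present = TRUE,
             p_amplitude_scale = 1, qrs_width_ms = 80, qrs_shape = "narrow",
             rr_jitter_frac = 0.03),
  SB  = list(hr_range_bpm = c(40, 59), p_wave_present = TRUE,
             p_amplitude_scale = 1, qrs_width_ms = 80, qrs_shape = "narrow",
             rr_jitter_frac = 0.06),
  SVT = list(hr_range_bpm = c(150, 220), p_wave_present = FALSE,
             p_amplitude_scale = 0, qrs_width_ms = 80, qrs_shape = "narrow",
             rr_jitter_frac = 0.02),
  VT  = list(hr_range_bpm = c(120, 250), p_wave_present = FALSE,
             p_amplitude_scale = 0, qrs_width_ms = 160,
             qrs_shape = "wide_distorted", rr_jitter_frac = 0.04)
)

#' Noise configuration for synthetic recordings
#'
#' Amplitudes are relative to the unit R-wave amplitude. Defaults emulate a
#' moderately noisy single-lead strip: sinusoidal baseline wander, white
#' high-frequency noise, and occasional smooth motion-artifact transients.
#'
#' @param baseline_wander_amp baseline-wander amplitude (relative units).
#' @param baseline_wander_freq_hz baseline-wander frequency in Hz.
#' @param hf_noise_sd standard deviation of additive white noise.
#' @param artifact_prob probability in \[0,1\] that a recording contains a
#'   motion-artifact transient.
#' @return object of class `noise_config`.
#' @export
noise_config <- function(baseline_wander_amp = 0.15,
                         baseline_wander_freq_hz = 0.3,
                         hf_noise_sd = 0.05,
                         artifact_prob = 0.1) {
  if (baseline_wander_amp < 0 || hf_noise_sd < 0)
    stop("noise amplitudes must be >= 0", call. = FALSE)
  if (baseline_wander_freq_hz <= 0)
    stop("baseline_wander_freq_hz must be positive", call. = FALSE)
  if (artifact_prob < 0 || artifact_prob > 1)
    stop("artifact_prob must lie in [0,1]", call. = FALSE)
  structure(list(baseline_wander_amp = baseline_wander_amp,
                 baseline_wander_freq_hz = baseline_wander_freq_hz,
                 hf_noise_sd = hf_noise_sd,
                 artifact_prob = artifact_prob),
            class = "noise_config")
}

#' Noise-free configuration
#'
#' Convenience constructor for the "clean" mode used by morphology and rate
#' oracles.
#' @return a `noise_config` with all noise sources off.
#' @export
noise_off <- function() noise_config(0, 0.3, 0, 0)

#' Synthetic dataset configuration
#'
#' @param per_class_count recordings to generate per rhythm class.
#' @param duration_s recording duration in seconds (default 10).
#' @param fs_hz sampling rate in Hz (default 250).
#' @param seed integer master seed; the full dataset is a pure function of
#'   this configuration.
#' @param noise a [noise_config()]; use [noise_off()] for clean signals.
#' @param specs named list of per-class [rhythm_spec()]s; defaults used for
#'   classes not listed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(per_class_count,
                         duration_s = 10,
                         fs_hz = 250,
                         seed = 1L,
                         noise = noise_config(),
                         specs = NULL) {
  if (per_class_count < 1 || per_class_count != round(per_class_count))
    stop("per_class_count must be a positive integer", call. = FALSE)
  if (duration_s <= 0 || fs_hz <= 0)
    stop("duration_s and fs_hz must be positive", call. = FALSE)
  n <- duration_s * fs_hz
  if (abs(n - round(n)) > 1e-9)
    stop("duration_s * fs_hz must be an integer sample count", call. = FALSE)
  all_specs <- lapply(RHYTHM_CLASSES, rhythm_spec)
  names(all_specs) <- RHYTHM_CLASSES
  for (nm in names(specs)) all_specs[[nm]] <- specs[[nm]]
  structure(list(per_class_count = as.integer(per_class_count),
                 duration_s = duration_s, fs_hz = fs_hz,
                 seed = as.integer(seed), noise = noise, specs = all_specs),
            class = "synth_config")
}

# Gaussian deflection components (center ms relative to R, sd ms, amplitude)
# for one beat. Late components are compressed at short cycle lengths, as
# diastole shortens at high rates.
beat_components <- function(spec, rr_ms) {
  comps <- list()
  if (spec$qrs_shape == "narrow") {
    sd_r <- spec$qrs_width_ms / (2 * sqrt(2 * log(2)))  # FWHM -> sd
    if (spec$p_wave_present && spec$p_amplitude_scale > 0) {
      comps$P <- c(-min(160, 0.35 * rr_ms), 22, 0.15 * spec$p_amplitude_scale)
    }
    comps$Q <- c(-0.9 * spec$qrs_width_ms, 10, -0.08)
    comps$R <- c(0, sd_r, 1.0)
    comps$S <- c(0.9 * spec$qrs_width_ms, 10, -0.10)
    comps$T <- c(min(280, 0.45 * rr_ms), min(55, 0.12 * rr_ms), 0.30)
  } else {
    # monomorphic ventricular morphology: wide R, no discrete Q/S/P,
    # discordant (inverted) T
    sd_r <- spec$qrs_width_ms / (2 * sqrt(2 * log(2)))
    comps$R <- c(0, sd_r, 1.0)
    # discordant T placed late enough not to cut into the R half-height
    comps$T <- c(min(280, 0.62 * rr_ms), min(50, 0.10 * rr_ms), -0.3)
  }
  comps
}

# Add one beat's deflections (centered at onset_s) to signal vector `x`
# sampled at fs; evaluation restricted to +/- 5 sd support.
add_beat <- function(x, fs, onset_s, comps) {
  n <- length(x)
  for (cp in comps) {
    c_s <- onset_s + cp[1] / 1000
    sd_s <- cp[2] / 1000
    i0 <- max(1L, floor((c_s - 5 * sd_s) * fs) + 1L)
    i1 <- min(n, ceiling((c_s + 5 * sd_s) * fs) + 1L)
    if (i0 > i1) next
    t <- (seq.int(i0, i1) - 1) / fs
    x[i0:i1] <- x[i0:i1] + cp[3] * exp(-0.5 * ((t - c_s) / sd_s)^2)
  }
  x
}

#' Template waveform for one cardiac cycle
#'
#' Builds a single P-QRS-T cycle for a rhythm specification as a sum of
#' Gaussian deflections, at the nominal cycle length implied by the midpoint
#' of the class heart-rate range. The R peak sits at the center of the
#' returned vector (attribute `"r_index"`); the R complex's half-height
#' width equals `spec$qrs_width_ms` by construction.
#'
#' @param spec a [rhythm_spec()].
#' @param fs_hz sampling rate in Hz, at least 100.
#' @return numeric vector of one cycle, with attributes `r_index` and
#'   `fs_hz`.
#' @export
make_beat_template <- function(spec, fs_hz) {
  if (!inherits(spec, "rhythm_spec")) stop("spec must be a rhythm_spec",
                                           call. = FALSE)
  if (!is.numeric(fs_hz) || length(fs_hz) != 1 || fs_hz < 100)
    stop("fs_hz must be a single number >= 100", call. = FALSE)
  hr <- mean(spec$hr_range_bpm)
  rr_ms <- 60000 / hr
  n <- round(rr_ms / 1000 * fs_hz)
  x <- numeric(n)
  r_index <- floor(n / 2) + 1L
  onset_s <- (r_index - 1) / fs_hz
  x <- add_beat(x, fs_hz, onset_s, beat_components(spec, rr_ms))
  attr(x, "r_index") <- r_index
  attr(x, "fs_hz") <- fs_hz
  x
}

#' Half-height width of the dominant R complex
#'
#' Locates the global maximum of a (clean) waveform and measures the width,
#' in milliseconds, between the two points where the signal crosses half of
#' the peak height above baseline, using linear interpolation between
#' samples. The baseline is the 10th percentile of the waveform — a robust
#' flat-segment estimate that stays valid when a wide ventricular complex
#' occupies most of the cycle.
#'
#' @param x numeric waveform.
#' @param fs_hz sampling rate in Hz.
#' @return width in milliseconds.
#' @export
qrs_half_width <- function(x, fs_hz) {
  x <- as.numeric(x)
  base <- unname(stats::quantile(x, 0.1))
  ipk <- which.max(x)
  half <- base + (x[ipk] - base) / 2
  # walk left
  i <- ipk
  while (i > 1 && x[i - 1] > half) i <- i - 1
  left <- if (i == 1) 1 else {
    i - 1 + (half - x[i - 1]) / (x[i] - x[i - 1])
  }
  j <- ipk
  n <- length(x)
  while (j < n && x[j + 1] > half) j <- j + 1
  right <- if (j == n) n else {
    j + (half - x[j]) / (x[j + 1] - x[j])
  }
  (right - left) / fs_hz * 1000
}

#' Generate one labeled synthetic recording
#'
#' Draws a mean heart rate inside the class range (with a 5% interior
#' margin), lays beats on an R-R grid with multiplicative rate jitter
#' renormalized so that the mean instantaneous rate over in-record intervals
#' equals the drawn rate, renders Gaussian P-QRS-T deflections, and adds
#' configured noise. The result is a pure function of
#' `(label, cfg, record_seed)`.
#'
#' @param label rhythm class, one of `RHYTHM_CLASSES`.
#' @param cfg a [synth_config()].
#' @param record_seed integer seed distinguishing recordings.
#' @return an [ecg_record()] with ground-truth `label`.
#' @export
generate_recording <- function(label, cfg, record_seed = 1L) {
  assert_rhythm_label(label)
  if (!inherits(cfg, "synth_config")) stop("cfg must be a synth_config",
                                           call. = FALSE)
  spec <- cfg$specs[[label]]
  fs <- cfg$fs_hz
  dur <- cfg$duration_s
  n <- round(dur * fs)
  seed <- combine_seeds(cfg$seed, record_seed,
                        match(label, RHYTHM_CLASSES) * 7919L)
  with_seed(seed, {
    lo <- spec$hr_range_bpm[1]; hi <- spec$hr_range_bpm[2]
    margin <- 0.05 * (hi - lo)
    hr <- stats::runif(1, lo + margin, hi - margin)
    n_beats <- ceiling(dur * hr / 60) + 6L
    jit <- pmax(pmin(stats::rnorm(n_beats, 0, spec$rr_jitter_frac), 2.5 *
                       spec$rr_jitter_frac), -2.5 * spec$rr_jitter_frac)
    rates <- hr * (1 + jit)
    onset1 <- stats::runif(1, 0, 60 / hr)
    onsets <- onset1 + c(0, cumsum(60 / rates))
    # renormalize rates of in-record intervals so their mean equals hr
    inside <- which(onsets >= 0 & onsets < dur)
    if (length(inside) >= 3) {
      idx <- inside[-length(inside)]  # intervals between in-record onsets
      rates[idx] <- rates[idx] * hr / mean(rates[idx])
      onsets <- onset1 + c(0, cumsum(60 / rates))
    }
    # one extra beat before the record start so early samples look natural
    onsets <- c(onset1 - 60 / hr, onsets)
    x <- numeric(n)
    for (b in seq_along(onsets)) {
      if (onsets[b] < -0.6 || onsets[b] > dur + 0.6) next
      rr_ms <- if (b < length(onsets)) (onsets[b + 1] - onsets[b]) * 1000
               else 60000 / hr
      x <- add_beat(x, fs, onsets[b], beat_components(spec, rr_ms))
    }
    nz <- cfg$noise
    if (nz$baseline_wander_amp > 0) {
      tt <- (seq_len(n) - 1) / fs
      x <- x + nz$baseline_wander_amp *
        sin(2 * pi * nz$baseline_wander_freq_hz * tt + stats::runif(1, 0, 2 * pi))
    }
    if (nz$hf_noise_sd > 0) x <- x + stats::rnorm(n, 0, nz$hf_noise_sd)
    if (nz$artifact_prob > 0 && stats::runif(1) < nz$artifact_prob) {
      c_s <- stats::runif(1, 0.5, dur - 0.5)
      amp <- sample(c(-1, 1), 1) * stats::runif(1, 0.3, 0.8)
      tt <- (seq_len(n) - 1) / fs
      x <- x + amp * exp(-0.5 * ((tt - c_s) / 0.08)^2)
    }
    ecg_record(x, fs_hz = fs, lead = "I", label = label,
               source_id = sprintf("synth_%s_%06d", label, record_seed),
               subject_id = sprintf("synth_%s_%06d", label, record_seed))
  })
}

#' Generate a balanced, patient-wise partitioned synthetic dataset
#'
#' Generates `per_class_count` recordings for each of the five rhythm
#' classes (or explicit per-partition counts) and assigns each synthetic
#' subject's recordings to exactly one of train/validation/test.
#'
#' @param cfg a [synth_config()].
#' @param split either proportions summing to 1 (named `train`,
#'   `validation`, `test`) or absolute per-class counts per partition. When
#'   counts are given they define the per-class total and
#'   `cfg$per_class_count` is ignored.
#' @param records_per_subject recordings contributed by each synthetic
#'   subject (default 1; larger values emulate continuous-monitoring sources
#'   where one subject yields several strips).
#' @return object of class `ecg_dataset`: list with `records` (list of
#'   [ecg_record()]s), `manifest` (data.frame with record_id, subject_id,
#'   label, partition, fs), and `config`.
#' @export
generate_dataset <- function(cfg,
                             split = c(train = 0.6, validation = 0.2,
                                       test = 0.2),
                             records_per_subject = 1L) {
  if (!inherits(cfg, "synth_config")) stop("cfg must be a synth_config",
                                           call. = FALSE)
  if (length(split) != 3) stop("split must have three entries", call. = FALSE)
  if (is.null(names(split)) || !all(names(split) %in%
                                    c("train", "validation", "test")))
    names(split) <- c("train", "validation", "test")
  split <- split[c("train", "validation", "test")]
  if (any(split < 0)) stop("split entries must be >= 0", call. = FALSE)
  if (abs(sum(split) - 1) < 1e-9 && all(split <= 1)) {
    total <- cfg$per_class_count
    if (all(split > 0) && total < 3)
      stop("per_class_count too small to fill three partitions",
           call. = FALSE)
    counts <- floor(split * total)
    counts["train"] <- counts["train"] + (total - sum(counts))
    if (any(split > 0 & counts == 0))
      stop("per_class_count too small to fill every non-empty partition",
           call. = FALSE)
  } else {
    if (any(split != round(split)))
      stop("split must be proportions summing to 1 or integer counts",
           call. = FALSE)
    counts <- as.integer(split)
    names(counts) <- names(split)
    total <- sum(counts)
    if (total < 1) stop("split counts sum to zero", call. = FALSE)
  }
  records <- list()
  rows <- list()
  rec_i <- 0L
  for (label in RHYTHM_CLASSES) {
    part_of <- rep(names(counts), times = counts)
    for (i in seq_len(total)) {
      rec_i <- rec_i + 1L
      rec <- generate_recording(label, cfg, record_seed = rec_i)
      subj <- sprintf("%s_subj%05d", label,
                      as.integer(ceiling(i / records_per_subject)))
      rec$subject_id <- subj
      # subjects never straddle partitions: a whole subject block takes the
      # partition of its first record
      first_of_subj <- ((i - 1L) %/% records_per_subject) *
        records_per_subject + 1L
      rec$partition <- part_of[first_of_subj]
      records[[rec_i]] <- rec
      rows[[rec_i]] <- data.frame(record_id = rec$source_id,
                                  subject_id = subj, label = label,
                                  partition = rec$partition,
                                  fs = cfg$fs_hz,
                                  stringsAsFactors = FALSE)
    }
  }
  structure(list(records = records,
                 manifest = do.call(rbind, rows),
                 config = cfg),
            class = "ecg_dataset")
}

#' Subset a dataset by partition
#'
#' @param ds an `ecg_dataset` from [generate_dataset()].
#' @param partition one of `"train"`, `"validation"`, `"test"`.
#' @return list of [ecg_record()]s in that partition.
#' @export
dataset_partition <- function(ds, partition) {
  stopifnot(inherits(ds, "ecg_dataset"))
  partition <- match.arg(partition, c("train", "validation", "test"))
  ds$records[vapply(ds$records, function(r) identical(r$partition, partition),
                    logical(1))]
}

#' Write a dataset to disk
#'
#' Writes each recording in CSV (`sample_index,value`) or WFDB format plus a
#' tab-separated manifest `manifest.tsv` with columns
#' `record_id, subject_id, label, partition, fs`.
#'
#' @param ds an `ecg_dataset`.
#' @param dir output directory (created if missing).
#' @param format `"csv"` or `"wfdb"`.
#' @return invisibly, the manifest path.
#' @export
write_ecg_dataset <- function(ds, dir, format = c("csv", "wfdb")) {
  stopifnot(inherits(ds, "ecg_dataset"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in ds$records) {
    path <- file.path(dir, paste0(rec$source_id,
                                  if (format == "csv") ".csv" else ".hea"))
    write_ecg(rec, path, dialect = format)
  }
  man_path <- file.path(dir, "manifest.tsv")
  utils::write.table(ds$manifest, man_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(man_path)
}
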