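#' Single-lead ECG record
#'
#' Container for one ECG strip: the sample vector, sampling rate, lead tag,
#' optional ground-truth rhythm label, and source/subject identifiers.
#' Sample `i` (0-based) occurs at time `i / fs_hz` seconds.
#'
#' @param samples non-empty numeric vector of amplitudes (arbitrary units or
#'   z-units).
#' @param fs_hz positive sampling rate in Hz.
#' @param lead lead tag: `"I"`, `"II"`, or `"other"`.
#' @param label optional rhythm label (one of `RHYTHM_CLASSES`).
#' @param source_id identifier of the originating record.
#' @param subject_id identifier of the subject (for patient-wise splitting).
#' @return object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs_hz, lead = "other", label = NULL,
                       source_id = "", subject_id = "") {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("samples must be non-empty", call. = FALSE)
  if (anyNA(samples)) stop("samples must not contain NA", call. = FALSE)
  if (!is.numeric(fs_hz) || length(fs_hz) != 1 || fs_hz <= 0)
    stop("fs_hz must be a single positive number", call. = FALSE)
  if (!lead %in% c("I", "II", "other"))
    stop("lead must be 'I', 'II', or 'other'", call. = FALSE)
  if (!is.null(label)) assert_rhythm_label(label)
  structure(list(samples = samples, fs_hz = fs_hz, lead = lead,
                 label = label, source_id = source_id,
                 subject_id = subject_id),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s: %d samples @ %g Hz (%.2f s), lead %s%s\n",
              if (nzchar(x$source_id)) x$source_id else "(unnamed)",
              length(x$samples), x$fs_hz, length(x$samples) / x$fs_hz,
              x$lead,
              if (!is.null(x$label)) paste0(", label ", x$label) else ""))
  invisible(x)
}

#' Read an ECG record from disk
#'
#' Supports two dialects: CSV with header `sample_index,value` (one sample
#' per row), and WFDB header/signal pairs (formats 16 and 212). For
#' multi-channel WFDB records, the first lead in `lead_preference` that is
#' present is extracted.
#'
#' @param path path to a `.csv` file or a WFDB `.hea` header.
#' @param dialect `"auto"` (by extension), `"csv"`, or `"wfdb"`.
#' @param lead_preference character vector of lead names tried in order for
#'   multi-channel WFDB input.
#' @param label optional rhythm label to attach.
#' @return an [ecg_record()] at the file's original sampling rate.
#' @export
read_ecg <- function(path, dialect = c("auto", "csv", "wfdb"),
                     lead_preference = c("I", "II"), label = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.hea$", path, ignore.case = TRUE)) "wfdb"
               else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rec <- switch(dialect,
                csv = read_ecg_csv(path),
                wfdb = read_wfdb(path, lead_preference = lead_preference))
  if (!is.null(label)) {
    assert_rhythm_label(label)
    rec$label <- label
  }
  rec
}

read_ecg_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("CSV format error in ", path,
                              ": no data rows", call. = FALSE)
  header <- tolower(gsub("\\s", "", lines[1]))
  if (header != "sample_index,value")
    stop("CSV format error in ", path,
         ": expected header 'sample_index,value', got '", lines[1], "'",
         call. = FALSE)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, ",", fixed = TRUE)
  vals <- vapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) != 2)
      stop("CSV format error in ", path, " at data row ", i,
           ": expected 2 fields", call. = FALSE)
    v <- suppressWarnings(as.numeric(p[2]))
    if (is.na(v))
      stop("CSV format error in ", path, " at data row ", i,
           ": non-numeric value '", p[2], "'", call. = FALSE)
    v
  }, numeric(1))
  fs <- attr_from_csv_comment(lines[1])  # default 250 if absent
  ecg_record(vals, fs_hz = fs, lead = "other",
             source_id = sub("\\.csv$", "", basename(path),
                             ignore.case = TRUE))
}

# CSV carries no rate metadata; the written form is always paired with a
# manifest carrying fs. Standalone CSVs default to 250 Hz.
attr_from_csv_comment <- function(header_line) 250

#' Write an ECG record to disk
#'
#' @param rec an [ecg_record()].
#' @param path output path: `.csv`, or a WFDB `.hea` path (the `.dat` signal
#'   file is written alongside).
#' @param dialect `"auto"`, `"csv"`, or `"wfdb"`.
#' @return invisibly, `path`.
#' @export
write_ecg <- function(rec, path, dialect = c("auto", "csv", "wfdb")) {
  stopifnot(inherits(rec, "ecg_record"))
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.hea$", path, ignore.case = TRUE)) "wfdb"
               else "csv"
  }
  if (dialect == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("sample_index,value", con)
    writeLines(paste(seq_along(rec$samples) - 1L,
                     format(rec$samples, digits = 17, scientific = FALSE,
                            trim = TRUE), sep = ","), con)
  } else {
    write_wfdb(rec, path)
  }
  invisible(path)
}

# ---- Minimal WFDB (PhysioNet waveform database) support -------------------
# Formats 16 (little-endian int16) and 212 (packed 12-bit) are read; format
# 16 is written. Physical value = (adc - baseline) / gain.

parse_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2)
    stop("WFDB format error in ", hea_path, ": header too short",
         call. = FALSE)
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4)
    stop("WFDB format error in ", hea_path,
         ": record line needs 'name nsig fs nsamp'", call. = FALSE)
  nsig <- as.integer(top[2])
  fs <- as.numeric(sub("/.*$", "", top[3]))  # strip counter frequency
  nsamp <- as.integer(top[4])
  sig <- lapply(seq_len(nsig), function(i) {
    f <- strsplit(trimws(lines[1 + i]), "\\s+")[[1]]
    if (length(f) < 2)
      stop("WFDB format error in ", hea_path, ": signal line ", i,
           call. = FALSE)
    gain_field <- if (length(f) >= 3 && !is.na(f[3])) f[3] else "200"
    gain <- as.numeric(sub("^([-0-9.eE+]+).*$", "\\1", gain_field))
    baseline <- if (grepl("\\(", gain_field))
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_field)) else 0
    if (is.na(gain) || gain == 0) gain <- 200
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else ""
    list(file = f[1], format = sub("x.*|:.*|\\+.*", "", f[2]),
         gain = gain, baseline = baseline, description = desc)
  })
  list(name = top[1], nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

read_wfdb_signal <- function(dat_path, format, nsig, nsamp) {
  if (format == "16") {
    raw <- readBin(dat_path, what = "integer", n = nsig * nsamp, size = 2L,
                   signed = TRUE, endian = "little")
  } else if (format == "212") {
    bytes <- readBin(dat_path, what = "integer", n = ceiling(nsig * nsamp * 1.5),
                     size = 1L, signed = FALSE)
    npairs <- length(bytes) %/% 3
    b1 <- bytes[seq(1, by = 3, length.out = npairs)]
    b2 <- bytes[seq(2, by = 3, length.out = npairs)]
    b3 <- bytes[seq(3, by = 3, length.out = npairs)]
    s1 <- b1 + bitwShiftL(bitwAnd(b2, 15L), 8L)
    s2 <- b3 + bitwShiftL(bitwShiftR(b2, 4L), 8L)
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
    raw <- as.vector(rbind(s1, s2))[seq_len(nsig * nsamp)]
  } else {
    stop("unsupported WFDB signal format '", format, "'", call. = FALSE)
  }
  matrix(raw, nrow = nsig)  # channel-interleaved -> rows = channels
}

read_wfdb <- function(hea_path, lead_preference = c("I", "II")) {
  hdr <- parse_wfdb_header(hea_path)
  descs <- vapply(hdr$signals, `[[`, character(1), "description")
  chan <- NA_integer_
  for (want in lead_preference) {
    hit <- which(toupper(trimws(descs)) == toupper(want) |
                   toupper(trimws(descs)) == toupper(paste("lead", want)))
    if (length(hit) > 0) { chan <- hit[1]; break }
  }
  if (is.na(chan)) {
    if (hdr$nsig == 1 && all(!nzchar(descs))) {
      chan <- 1L  # unlabeled single-channel record
    } else {
      stop("missing channel: none of [", paste(lead_preference,
                                               collapse = ", "),
           "] present in ", hea_path, " (channels: ",
           paste(descs, collapse = ", "), ")", call. = FALSE)
    }
  }
  sig <- hdr$signals[[chan]]
  dat_path <- file.path(dirname(hea_path), sig$file)
  if (!file.exists(dat_path))
    stop("WFDB signal file not found: ", dat_path, call. = FALSE)
  adc <- read_wfdb_signal(dat_path, sig$format, hdr$nsig, hdr$nsamp)[chan, ]
  lead <- if (toupper(trimws(descs[chan])) %in% c("I", "LEAD I")) "I"
          else if (toupper(trimws(descs[chan])) %in% c("II", "LEAD II")) "II"
          else "other"
  ecg_record((adc - sig$baseline) / sig$gain, fs_hz = hdr$fs, lead = lead,
             source_id = hdr$name)
}

write_wfdb <- function(rec, hea_path, gain = 200) {
  name <- sub("\\.hea$", "", basename(hea_path), ignore.case = TRUE)
  dat_name <- paste0(name, ".dat")
  n <- length(rec$samples)
  adc <- as.integer(round(rec$samples * gain))
  if (any(abs(adc) > 32767))
    stop("signal amplitude exceeds 16-bit WFDB range at gain ", gain,
         call. = FALSE)
  desc <- if (rec$lead %in% c("I", "II")) rec$lead else "ECG"
  checksum <- sum(adc) %% 65536
  if (checksum > 32767) checksum <- checksum - 65536
  hea <- c(sprintf("%s 1 %s %d", name, format(rec$fs_hz), n),
           sprintf("%s 16 %d(0)/mV 16 0 %d %d 0 %s",
                   dat_name, as.integer(gain), adc[1], checksum, desc))
  writeLines(hea, hea_path)
  writeBin(adc, file.path(dirname(hea_path), dat_name), size = 2L,
           endian = "little")
  invisible(hea_path)
}

# ---- Standardization -------------------------------------------------------

#' Resample a record to 250 Hz
#'
#' Fourier-domain resampling: the spectrum is truncated or zero-padded so the
#' output has `round(duration * 250)` samples. Amplitude and phase of any
#' band-limited component below the output Nyquist frequency are preserved.
#' A record already at 250 Hz is returned unchanged.
#'
#' @param rec an [ecg_record()].
#' @return an [ecg_record()] with `fs_hz == 250`.
#' @export
resample_to_250 <- function(rec) {
  stopifnot(inherits(rec, "ecg_record"))
  if (rec$fs_hz == 250) return(rec)
  n <- length(rec$samples)
  m <- round(n / rec$fs_hz * 250)
  if (m < 2) stop("record too short to resample", call. = FALSE)
  out <- rec
  out$samples <- fft_resample(rec$samples, m)
  out$fs_hz <- 250
  out
}

# Resample x (length n) to length m by spectrum truncation/zero-padding.
fft_resample <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(m)
  nk <- min(n, m)
  half <- (nk - 1) %/% 2  # positive-frequency bins excluding DC and Nyquist
  Y[1] <- X[1]
  if (half > 0) {
    Y[2:(half + 1)] <- X[2:(half + 1)]
    Y[(m - half + 1):m] <- X[(n - half + 1):n]
  }
  if (nk %% 2 == 0) {
    # shared Nyquist bin of the shorter grid
    nyq <- X[nk %/% 2 + 1]
    if (m > n) {
      Y[n %/% 2 + 1] <- nyq / 2
      Y[m - n %/% 2 + 1] <- Conj(nyq) / 2
    } else {
      Y[m %/% 2 + 1] <- nyq
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Z-score normalize a record
#'
#' Centers and scales the full strip: \eqn{(x - \bar x) / \sigma} with the
#' population (divide-by-N) standard deviation computed over the whole
#' recording, never per window, so relative morphology (e.g. R versus T
#' height) is preserved within the strip.
#'
#' @param rec an [ecg_record()] with at least 2 samples.
#' @return an [ecg_record()] with mean 0 and population SD 1.
#' @export
zscore_normalize <- function(rec) {
  stopifnot(inherits(rec, "ecg_record"))
  x <- rec$samples
  if (length(x) < 2) stop("need at least 2 samples", call. = FALSE)
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0)
    stop("degenerate signal: constant amplitude carries no rhythm",
         call. = FALSE)
  out <- rec
  out$samples <- (x - mu) / sigma
  out
}

#' Standardize a record to the model's input form
#'
#' Resamples to 250 Hz and z-score normalizes. Records shorter than
#' `duration_s` after resampling are rejected; longer records are rejected
#' unless `crop = TRUE`, in which case the first `duration_s` seconds are
#' kept (continuous-monitoring style input).
#'
#' @param rec an [ecg_record()].
#' @param duration_s target duration (default 10 s, i.e. 2500 samples).
#' @param crop take the first `duration_s` seconds of longer records.
#' @return standardized [ecg_record()] of exactly `round(duration_s * 250)`
#'   samples at 250 Hz.
#' @export
standardize_record <- function(rec, duration_s = 10, crop = FALSE) {
  rec <- resample_to_250(rec)
  target <- round(duration_s * 250)
  n <- length(rec$samples)
  if (n < target)
    stop("record too short: ", n, " samples after resampling, need ",
         target, call. = FALSE)
  if (n > target) {
    if (!crop)
      stop("record longer than ", duration_s,
           " s; pass crop = TRUE to take the first ", duration_s, " s",
           call. = FALSE)
    rec$samples <- rec$samples[seq_len(target)]
  }
  zscore_normalize(rec)
}
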