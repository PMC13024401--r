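test_that("rhythm specifications enforce their invariants", {
  expect_error(rhythm_spec("AFIB"), "invalid rhythm label")
  expect_error(rhythm_spec("NSR", hr_range_bpm = c(100, 60)), "hr_range")
  expect_error(rhythm_spec("NSR", qrs_width_ms = -5), "qrs_width_ms")
  expect_error(rhythm_spec("VT", qrs_width_ms = 100), "wide_distorted")
  sp <- rhythm_spec("SVT")
  expect_false(sp$p_wave_present)
  expect_identical(sp$p_amplitude_scale, 0)
})

test_that("beat templates carry the class morphology", {
  fs <- 250
  # wide ventricular complex: measured half-height width tracks the
  # construction parameter and exceeds the 120 ms wide-QRS bound
  vt <- make_beat_template(rhythm_spec("VT", qrs_width_ms = 160), fs)
  w_vt <- qrs_half_width(vt, fs)
  expect_gt(w_vt, 120)
  expect_lt(abs(w_vt - 160) / 160, 0.2)

  # sinus template has a P extremum 120-200 ms before the R peak
  nsr <- make_beat_template(rhythm_spec("NSR"), fs)
  r_idx <- attr(nsr, "r_index")
  pre <- nsr[1:(r_idx - round(0.1 * fs))]
  p_idx <- which.max(pre)
  lead_ms <- (r_idx - p_idx) / fs * 1000
  expect_gte(lead_ms, 120)
  expect_lte(lead_ms, 200)
  expect_lt(abs(qrs_half_width(nsr, fs) - 80) / 80, 0.2)

  # zero P amplitude leaves no deflection above numerical floor before R
  svt <- make_beat_template(rhythm_spec("SVT", p_amplitude_scale = 0), fs)
  r_svt <- attr(svt, "r_index")
  pre_svt <- svt[1:(r_svt - round(0.075 * fs))]
  expect_lt(max(abs(pre_svt)), 0.02)

  expect_error(make_beat_template(rhythm_spec("NSR"), fs_hz = -1), "fs_hz")
})

test_that("generated recordings respect length, rate range, and determinism", {
  cfg <- make_clean_config()
  rec <- generate_recording("NSR", cfg, record_seed = 7)
  expect_s3_class(rec, "ecg_record")
  expect_length(rec$samples, 2500)
  expect_identical(rec$label, "NSR")

  # rate oracle: peak counts and mean HR inside the class band
  pk <- oracle_detect_peaks(rec$samples, 250)
  expect_gte(length(pk), 10)
  expect_lte(length(pk), 17)

  sb <- generate_recording("SB", cfg, record_seed = 3)
  pk_sb <- oracle_detect_peaks(sb$samples, 250)
  expect_gte(length(pk_sb), 6)
  expect_lte(length(pk_sb), 10)

  expect_identical(generate_recording("ST", cfg, 11)$samples,
                   generate_recording("ST", cfg, 11)$samples)
  expect_false(identical(generate_recording("ST", cfg, 11)$samples,
                         generate_recording("ST", cfg, 12)$samples))
})

test_that("sinus classes separate perfectly on oracle-estimated rate", {
  cfg <- make_clean_config(per_class = 8, seed = 77)
  textbook <- function(hr) if (hr < 60) "SB" else if (hr <= 100) "NSR" else "ST"
  for (lab in c("NSR", "ST", "SB")) {
    for (i in seq_len(8)) {
      r <- generate_recording(lab, cfg, record_seed = i)
      hr <- oracle_mean_hr(oracle_detect_peaks(r$samples, 250), 250)
      expect_identical(textbook(hr), lab)
    }
  }
})

test_that("ventricular morphology is wider than supraventricular in every draw", {
  cfg <- make_clean_config(per_class = 10, seed = 5)
  w_svt <- vapply(1:10, function(i)
    qrs_half_width(generate_recording("SVT", cfg, i)$samples, 250), numeric(1))
  w_vt <- vapply(1:10, function(i)
    qrs_half_width(generate_recording("VT", cfg, i)$samples, 250), numeric(1))
  expect_true(min(w_vt) > max(w_svt))
})

test_that("datasets are balanced, complete, and patient-wise disjoint", {
  cfg <- synth_config(per_class_count = 10, seed = 9, noise = noise_off())
  ds <- generate_dataset(cfg, split = c(train = 0.6, validation = 0.2,
                                        test = 0.2))
  man <- ds$manifest
  expect_identical(nrow(man), 50L)
  counts <- table(man$label)
  expect_true(all(counts == 10))
  # every class appears in every partition at the configured ratio
  tab <- table(man$label, man$partition)
  expect_true(all(tab[, "train"] == 6))
  expect_true(all(tab[, "validation"] == 2))
  expect_true(all(tab[, "test"] == 2))
  # patient-wise: no subject id in more than one partition
  by_subj <- tapply(man$partition, man$subject_id,
                    function(p) length(unique(p)))
  expect_true(all(by_subj == 1))
  # labels conserved on the records themselves
  expect_identical(vapply(ds$records, `[[`, character(1), "label"),
                   man$label)
})

test_that("count-style splits reproduce the 1500/500 train/validation design", {
  cfg <- synth_config(per_class_count = 400, seed = 2, noise = noise_off())
  ds <- generate_dataset(cfg, split = c(train = 300, validation = 100,
                                        test = 0))
  tab <- table(ds$manifest$partition)
  expect_identical(unname(tab["train"]), 1500L)
  expect_identical(unname(tab["validation"]), 500L)
  expect_false("test" %in% ds$manifest$partition)
})

test_that("datasets are a pure function of their configuration", {
  cfg <- synth_config(per_class_count = 5, seed = 31, noise = noise_config())
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(lapply(d1$records, `[[`, "samples"),
                   lapply(d2$records, `[[`, "samples"))
  expect_identical(d1$manifest, d2$manifest)
})

test_that("undersized configurations are rejected", {
  expect_error(generate_dataset(synth_config(per_class_count = 2, seed = 1)),
               "too small")
})

test_that("multi-recording subjects still never straddle partitions", {
  cfg <- synth_config(per_class_count = 12, seed = 4, noise = noise_off())
  ds <- generate_dataset(cfg, records_per_subject = 3)
  man <- ds$manifest
  expect_lt(length(unique(man$subject_id)), nrow(man))
  by_subj <- tapply(man$partition, man$subject_id,
                    function(p) length(unique(p)))
  expect_true(all(by_subj == 1))
})
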