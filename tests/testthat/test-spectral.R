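test_that("epoch segmentation counts match the overlap arithmetic", {
  fs <- 256
  rec60 <- eeg_recording(matrix(rnorm(fs * 60), 1), fs)
  expect_length(segment_epochs(rec60, 2, 0.75), 117) # floor((60-2)/0.5)+1
  expect_length(segment_epochs(rec60, 2, 0), 30)
  rec2 <- eeg_recording(matrix(rnorm(fs * 2), 1), fs)
  expect_length(segment_epochs(rec2, 2, 0.75), 1)
  expect_error(segment_epochs(eeg_recording(matrix(rnorm(fs), 1), fs), 2), "shorter")
  expect_error(segment_epochs(rec60, 2, 1), "overlap")
  # offsets advance by the step
  ep <- segment_epochs(rec60, 2, 0.75)
  expect_equal(attr(ep[[2]], "offset_s") - attr(ep[[1]], "offset_s"), 0.5)
})

test_that("artifact rejection fires the right rule", {
  fs <- 256
  t <- seq_len(2 * fs) / fs
  good <- 10 * sin(2 * pi * 10 * t)
  spike <- good; spike[100] <- 150
  flat <- rep(0, length(t))
  steppy <- good; steppy[200] <- steppy[199] + 60
  epochs <- list(
    matrix(good, 1), matrix(spike, 1), matrix(flat, 1), matrix(steppy, 1)
  )
  attr(epochs, "sampling_rate") <- fs
  out <- suppressWarnings(reject_artifact_epochs(epochs))
  expect_equal(out$mask$kept, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$mask$reason[2:4], c("minmax", "low_activity", "step"))
  expect_length(out$kept, 1)
})

test_that("preprocessing removes DC, attenuates 60 Hz, and re-references mastoids", {
  fs <- 512
  t <- seq_len(10 * fs) / fs
  # DC-offset-only input: high-pass wipes it out
  dc <- matrix(5, 3, length(t))
  rec <- eeg_recording(dc, fs, c("TP9", "TP10", "Cz"))
  pp <- preprocess_eeg(rec, keep_eyes_closed = FALSE)
  expect_lt(max(abs(pp$samples)), 1e-6)
  expect_equal(pp$sampling_rate, 256)

  # pure 60-Hz tone: notch + low-pass attenuate it by far more than 20 dB
  tone <- sin(2 * pi * 60 * t)
  rec2 <- eeg_recording(rbind(0 * tone, 0 * tone, tone), fs,
                        c("TP9", "TP10", "Cz"))
  pp2 <- preprocess_eeg(rec2, keep_eyes_closed = FALSE)
  ratio_db <- 10 * log10(mean(pp2$samples[3, ]^2) / mean(tone^2))
  expect_lt(ratio_db, -20)

  # identical mastoid signal is subtracted from every channel
  common <- sin(2 * pi * 8 * t)
  sig <- sin(2 * pi * 12 * t)
  rec3 <- eeg_recording(rbind(common, common, common + sig), fs,
                        c("TP9", "TP10", "Cz"))
  pp3 <- preprocess_eeg(rec3, notch = NULL, keep_eyes_closed = FALSE)
  # mastoid rows become ~0; Cz keeps only its own signal
  expect_lt(mean(pp3$samples[1, ]^2), 1e-10)
  expect_gt(mean(pp3$samples[3, ]^2), 0.3)

  expect_error(preprocess_eeg(eeg_recording(dc, fs, c("A", "B", "C"))), "mastoid")
})

test_that("eyes-closed retention keeps only annotated periods", {
  fs <- 256
  x <- matrix(rnorm(3 * fs * 20), 3)
  seg <- data.frame(onset_s = c(0, 10), duration_s = c(5, 5),
                    label = c("eyes_open", "eyes_closed"))
  rec <- eeg_recording(x, fs, c("TP9", "TP10", "Cz"), seg)
  pp <- preprocess_eeg(rec)
  expect_equal(recording_duration(pp), 5, tolerance = 0.01)
  seg_open <- data.frame(onset_s = 0, duration_s = 20, label = "eyes_open")
  rec2 <- eeg_recording(x, fs, c("TP9", "TP10", "Cz"), seg_open)
  expect_error(preprocess_eeg(rec2), "eyes-closed")
})

test_that("windowed periodogram satisfies Parseval's identity", {
  set.seed(4)
  for (n in c(512, 511)) {
    x <- rnorm(n)
    pg <- periodogram_hamming(x, 256)
    energy <- sum((x * signal::hamming(n))^2)
    expect_lt(abs(sum(pg$power) - energy) / energy, 1e-6)
  }
})

test_that("band power concentrates at the tone frequency", {
  rec <- make_tone_recording(10, 1, 30)
  ep <- segment_epochs(rec)
  bp <- band_power(ep)
  expect_equal(colnames(bp)[which.max(bp[1, ])], "alpha1") # 10 Hz in 8.5-10
  off_target <- bp[1, c("theta", "beta2", "beta3")]
  expect_true(all(off_target < 0.01 * max(bp)))

  two <- make_tone_recording(c(5, 20), c(1, 1), 30)
  bp2 <- band_power(segment_epochs(two))
  expect_gt(bp2[1, "delta"], 10 * bp2[1, "theta"])
  expect_gt(bp2[1, "beta2"], 10 * bp2[1, "alpha2"])

  expect_error(
    band_power(ep, bands = tibble::tibble(band = "x", low = 100, high = 200)),
    "Nyquist"
  )
})

test_that("white-noise band power is flat per bin (mean) and width-scaled (sum)", {
  set.seed(12)
  rec <- eeg_recording(matrix(rnorm(256 * 240), 1), 256)
  ep <- segment_epochs(rec, 2, 0)
  bp_mean <- band_power(ep)
  bp_sum <- band_power(ep, aggregate = "sum")
  bands <- eeg_bands()
  n_bins <- vapply(seq_len(nrow(bands)), function(b) {
    freq <- seq(0, 128, by = 0.5)
    sum(freq >= bands$low[b] & freq <= bands$high[b])
  }, numeric(1))
  # per-bin means equal across bands; sums proportional to bin counts
  expect_lt(max(bp_mean) / min(bp_mean), 1.2)
  ratio <- bp_sum[1, ] / n_bins
  expect_lt(max(ratio) / min(ratio), 1.2)
})

test_that("normalize_log_map is an exact scale-free normalization", {
  set.seed(5)
  m <- matrix(rexp(40) + 0.1, 4, 10)
  out <- normalize_log_map(m)
  expect_equal(rowSums(exp(out)), rep(1, 4), tolerance = 1e-12)
  expect_equal(normalize_log_map(2 * m), out, tolerance = 1e-12)
  u <- normalize_log_map(matrix(7, 2, 5))
  expect_equal(as.numeric(u), rep(-log(5), 10))
  expect_error(normalize_log_map(matrix(c(1, -1), 1)), "positive")
})

test_that("epoch overlap changes variance, not expected band power", {
  set.seed(8)
  rec <- eeg_recording(matrix(rnorm(256 * 120), 1), 256)
  bp0 <- band_power(segment_epochs(rec, 2, 0))
  bp75 <- band_power(segment_epochs(rec, 2, 0.75))
  expect_equal(as.numeric(bp75 / bp0), rep(1, 7), tolerance = 0.25)
})

test_that("reliability split yields 4 segments with consistent power and errors when short", {
  set.seed(10)
  # stationary alpha-dominated signal shared within subject
  rec <- make_tone_recording(10, 20, 120, noise_sd = 3)
  segs <- split_segments_for_reliability(rec)
  expect_length(segs, 4)
  alphas <- vapply(segs, function(s) s[1, "alpha1"], numeric(1))
  expect_lt(max(alphas) / min(alphas), 1.3)

  short <- make_tone_recording(10, 20, 100)
  expect_error(split_segments_for_reliability(short), "too short")
})

test_that("band definitions can be read from YAML and are validated", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("bands:", "  slow: [1.0, 8.0]", "  fast: [8.5, 30.0]"), path)
  b <- read_bands_yaml(path)
  expect_equal(b$band, c("slow", "fast"))
  expect_equal(b$high, c(8, 30))
  writeLines(c("bands:", "  bad: [5.0, 2.0]"), path)
  expect_error(read_bands_yaml(path), "low < high")
  unlink(path)
})
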