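# Trigger-bit decoding, event algebra, and artifact detectors.

stim_rec <- function(codes, sfreq = 1100, t0 = 0) {
  recording(channel_info("STI101", "STIM"), matrix(codes, 1), sfreq,
            first_sample_time = t0)
}

test_that("trigger bits decode per bit and match a brute-force oracle", {
  # 0,17,0: 17 = 10001 -> bits 1 and 5 at the onset sample
  codes <- c(rep(0, 10), rep(17, 5), rep(0, 10))
  ev <- decode_trigger_bits(stim_rec(codes))
  expect_setequal(ev$label, c("bit1", "bit5"))
  expect_equal(unique(ev$onset), 10 / 1100)

  # constant channel -> empty
  expect_equal(nrow(decode_trigger_bits(stim_rec(rep(7, 50)))), 0)

  # fuzz: random code stream vs per-sample bit-diff oracle
  set.seed(42)
  for (rep_i in 1:5) {
    codes <- sample(0:31, 400, replace = TRUE)
    ev <- decode_trigger_bits(stim_rec(codes))
    brute <- list()
    for (b in 1:5) {
      bit <- codes %/% 2^(b - 1) %% 2
      hits <- which(diff(bit) == 1) + 1
      brute[[b]] <- data.frame(label = rep(paste0("bit", b), length(hits)),
                               onset = (hits - 1) / 1100)
    }
    brute <- do.call(rbind, brute)
    brute <- brute[order(brute$onset, brute$label), ]
    got <- ev[order(ev$onset, ev$label), ]
    expect_equal(got$label, brute$label)
    expect_equal(got$onset, brute$onset, tolerance = 1e-12)
  }

  # encode-decode identity: events re-encoded as a bit stream decode back
  expect_error(decode_trigger_bits(stim_rec(rep(0, 10)), "NOPE"),
               "missing stim channel")
})

test_that("bit combination applies the face/unfamiliar/scrambled rules", {
  mk <- function(code) {
    codes <- c(rep(0, 8), rep(code, 6), rep(0, 8))
    combine_bit_events(decode_trigger_bits(stim_rec(codes)),
                       face_stimulus_rules(), 1100)
  }
  expect_equal(mk(13)$label, "Unfamiliar")    # 01101
  expect_equal(mk(13)$code, 13)
  expect_equal(mk(5)$label, "Familiar")       # 00101
  expect_equal(mk(17)$label, "Scrambled")     # 10001
  expect_equal(mk(17)$code, 17)
  expect_equal(nrow(mk(2)), 0)                # matches no rule -> dropped
  # full printed code table
  for (code in c(5, 6, 7)) expect_equal(mk(code)$label, "Familiar")
  for (code in c(13, 14, 15)) expect_equal(mk(code)$label, "Unfamiliar")
  for (code in c(17, 18, 19)) expect_equal(mk(code)$label, "Scrambled")
  # conflicting rules matching one onset -> error
  bad_rules <- list(A = c("1" = 1), B = c("3" = 1))
  codes <- c(rep(0, 5), rep(5, 5), rep(0, 5))
  expect_error(combine_bit_events(decode_trigger_bits(stim_rec(codes)),
                                  bad_rules, 1100), "conflicting")
})

test_that("event transforms: offset is exact and invertible, counts conserved", {
  ev <- event_list(c("Familiar", "Scrambled", "Familiar"), c(1, 2, 3))
  # +34.5 ms to all stimulus events
  sh <- transform_events(ev, "add_offset", offset = 0.0345)
  expect_equal(sh$onset, c(1.0345, 2.0345, 3.0345))
  back <- transform_events(sh, "add_offset", offset = -0.0345)
  expect_identical(back$onset, ev$onset)        # exactly invertible

  # delete then count = 0
  del <- transform_events(ev, "delete", labels = "Familiar")
  expect_equal(sum(del$label == "Familiar"), 0)
  expect_equal(nrow(del), 1)

  # grouping merges onsets sorted; renaming onto an existing label errors
  gr <- transform_events(ev, "group_by_name",
                         labels = c("Familiar", "Scrambled"), to = "Stim")
  expect_equal(gr$label, rep("Stim", 3))
  expect_equal(gr$onset, sort(ev$onset))
  expect_error(transform_events(ev, "rename", from = "Familiar",
                                to = "Scrambled"), "group_by_name")
  # rename conserves counts
  rn <- transform_events(ev, "rename", from = "Familiar", to = "Famous")
  expect_equal(sum(rn$label == "Famous"), 2)
})

test_that("threshold detector finds injected blink bumps within 50 ms", {
  sfreq <- 500
  t <- (0:(60 * sfreq - 1)) / sfreq
  x <- rnorm(length(t), 0, 5e-6)
  truth <- c(6, 15.3, 29.8, 44.1, 55)
  for (bt in truth)
    x <- x + 150e-6 * exp(-(t - bt)^2 / (2 * 0.08^2))
  rec <- recording(channel_info(c("EEG062", "OTHER"), c("EOG", "EEG")),
                   rbind(x, 0), sfreq)
  ev <- detect_threshold_events(rec, "EEG062", band = c(0.3, 20),
                                threshold = 100e-6)
  expect_equal(nrow(ev), length(truth))
  mid <- ev$onset + ev$duration / 2
  expect_true(all(abs(mid - truth) < 0.05))
  expect_true(all(grepl("_bad$", ev$label)))

  # flat signal -> empty; threshold 0 -> one event spanning everything
  rec0 <- recording(channel_info("EEG062", "EOG"),
                    matrix(0, 1, 1000), sfreq)
  expect_equal(nrow(detect_threshold_events(rec0, "EEG062",
                                            threshold = 1e-6)), 0)
  ev0 <- detect_threshold_events(rec, "EEG062", threshold = 0)
  expect_equal(nrow(ev0), 1)
  expect_gt(ev0$duration, 59)
  # bad channel input -> error
  recb <- mark_bad_channels(rec, "EEG062")
  expect_error(detect_threshold_events(recb, "EEG062", threshold = 1),
               "bad")
})

test_that("heartbeat detection counts 72 bpm beats and survives polarity flips", {
  spec <- simulation_spec(n_runs = 1, n_trials = 2, isi = c(26, 27), pad = 3,
                          n_meg = 8, n_eeg = 2, cortex_subdiv = 1,
                          heart_rate = 1.2, blink_rate = 0)
  sim <- simulate_subject(spec, seed = 5)
  rec <- sim$runs[[1]]
  truth <- sim$truth$artifacts[[1]]$beat_times
  ev <- detect_heartbeats(rec)
  expect_lte(abs(nrow(ev) - length(truth)), 1)
  # rate ~72 bpm over the run
  rate_bpm <- 60 * nrow(ev) / diff(range(ev$onset))
  expect_lt(abs(rate_bpm - 72), 2)
  # physiological inter-beat intervals
  expect_true(all(diff(ev$onset) > 0.3 & diff(ev$onset) < 2))
  # inverted polarity: same onsets within 10 ms
  rec2 <- rec
  i <- which(rec$channels$kind == "ECG")
  rec2$data[i, ] <- -rec2$data[i, ]
  ev2 <- detect_heartbeats(rec2)
  expect_equal(nrow(ev2), nrow(ev))
  expect_lt(max(abs(ev2$onset - ev$onset)), 0.010)
  # zero signal -> empty
  rec$data[i, ] <- 0
  rec$data[rec$channels$kind == "MEG_MAG", ] <- 0
  expect_equal(nrow(detect_heartbeats(rec)), 0)
})

test_that("cHPI onset detection marks the pre-activation span", {
  spec <- simulation_spec(n_runs = 1, n_trials = 4, first_sample_time = 226,
                          chpi_start = 248, pad = 2, isi = c(6, 7),
                          n_meg = 12, n_eeg = 4, cortex_subdiv = 1)
  sim <- simulate_subject(spec, seed = 3)
  seg <- detect_chpi_onset(sim$runs[[1]])
  expect_equal(seg$start, 226)
  expect_equal(seg$end - seg$start, 22)
  expect_match(seg$label, "bad")

  # HPI on from the first sample -> no bad segment
  spec2 <- simulation_spec(n_runs = 1, n_trials = 2, first_sample_time = 100,
                           chpi_start = 100, pad = 2, isi = c(4, 5),
                           n_meg = 8, n_eeg = 2, cortex_subdiv = 1)
  sim2 <- simulate_subject(spec2, seed = 4)
  expect_equal(nrow(detect_chpi_onset(sim2$runs[[1]])), 0)

  # HPI never on -> whole file flagged with a warning
  spec3 <- simulation_spec(n_runs = 1, n_trials = 2, pad = 2, isi = c(4, 5),
                           n_meg = 8, n_eeg = 2, cortex_subdiv = 1)
  sim3 <- simulate_subject(spec3, seed = 4)
  expect_warning(seg3 <- detect_chpi_onset(sim3$runs[[1]]), "whole")
  expect_equal(unname(seg3$start), rec_span(sim3$runs[[1]])[1])
  expect_equal(unname(seg3$end), rec_span(sim3$runs[[1]])[2])
})

test_that("band-limited artifact detection flags bursts and controls false positives", {
  set.seed(31)
  sfreq <- 500
  n <- 90 * sfreq
  nch <- 4
  x <- matrix(rnorm(nch * n, 0, 1e-12), nch)
  # 3 s broadband burst at t = 40 s
  sel <- (40 * sfreq):(43 * sfreq)
  x[, sel] <- x[, sel] + matrix(rnorm(nch * length(sel), 0, 2e-11), nch)
  ch <- channel_info(paste0("M", 1:nch), "MEG_MAG",
                     position = matrix(rnorm(nch * 3), ncol = 3),
                     orientation = matrix(rep(c(0, 0, 1), nch), ncol = 3,
                                          byrow = TRUE))
  rec <- recording(ch, x, sfreq)
  ev <- detect_band_artifacts(rec, bands = list(c(1, 7), c(40, 240)),
                              z_threshold = 5)
  for (lab in c("movement_bad", "muscle_bad")) {
    hits <- ev[ev$label == lab, ]
    expect_gte(nrow(hits), 1)
    expect_true(any(hits$onset < 43 & hits$onset + hits$duration > 40))
  }
  # stationary noise: false-positive rate under the null < 1% of windows
  set.seed(32)
  fp <- 0; n_win <- 0
  for (r in 1:3) {
    xn <- matrix(rnorm(nch * n, 0, 1e-12), nch)
    recn <- recording(ch, xn, sfreq)
    evn <- detect_band_artifacts(recn, z_threshold = 5)
    fp <- fp + sum(evn$duration)
    n_win <- n_win + 2 * 90
  }
  expect_lt(fp / (3 * 2 * 90), 0.01)
  # window longer than recording -> error
  short <- recording(ch, x[, 1:100, drop = FALSE], sfreq)
  expect_error(detect_band_artifacts(short, window_s = 10), "window")
})

test_that("stimulus category counts equal the codes present in the stream", {
  set.seed(8)
  codes <- numeric(4000)
  schedule <- sample(c(5, 6, 7, 13, 14, 15, 17, 18, 19, 0, 2, 32), 30,
                     replace = TRUE)
  pos <- sort(sample(seq(10, 3900, by = 20), 30))
  for (k in seq_along(pos)) codes[pos[k] + 0:5] <- schedule[k]
  rec <- stim_rec(codes)
  ev <- combine_bit_events(decode_trigger_bits(rec), face_stimulus_rules(),
                           1100)
  expect_equal(nrow(ev),
               sum(schedule %in% c(5, 6, 7, 13, 14, 15, 17, 18, 19)))
})
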