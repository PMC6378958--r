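# Shared fixtures built in code: tiny recordings, meshes, and a light
# group-study runner used by both the module tests and the acceptance suite.

sine_recording <- function(freqs, amps = 1, sfreq = 1100, duration = 10,
                           n_channels = 1, noise_sd = 0) {
  t <- (seq_len(round(duration * sfreq)) - 1) / sfreq
  x <- Reduce(`+`, Map(function(f, a) a * sin(2 * pi * f * t),
                       freqs, rep_len(amps, length(freqs))))
  data <- matrix(rep(x, n_channels), nrow = n_channels, byrow = TRUE)
  if (noise_sd > 0) data <- data + matrix(rnorm(length(data), 0, noise_sd),
                                          n_channels)
  recording(channel_info(paste0("CH", seq_len(n_channels)), "EEG"),
            data, sfreq)
}

# flat regular grid mesh in the z=0 plane, h meter spacing
flat_grid_mesh <- function(nx = 41, ny = 41, h = 0.001) {
  vx <- cbind(as.matrix(expand.grid(x = (seq_len(nx) - (nx + 1) / 2) * h,
                                    y = (seq_len(ny) - (ny + 1) / 2) * h)), 0)
  idx <- function(i, j) (j - 1) * nx + i
  fc <- matrix(0L, 0, 3)
  for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1))
    fc <- rbind(fc, c(idx(i, j), idx(i + 1, j), idx(i, j + 1)),
                c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1)))
  list(mesh = surface_mesh(unname(vx), fc), idx = idx, nx = nx, ny = ny,
       h = h)
}

# cached small head geometry + constrained MEG gain (built once per session)
.test_cache <- new.env(parent = emptyenv())

small_gain_setup <- function() {
  if (!is.null(.test_cache$gain)) return(.test_cache$gain)
  spec <- simulation_spec(n_meg = 30, n_eeg = 0, cortex_subdiv = 1)
  geom <- simulate_head_geometry(spec)
  ch <- geom$channels[geom$channels$kind == "MEG_MAG", , drop = FALSE]
  class(ch) <- c("channel_info", "data.frame")
  gain <- assemble_gain(geom$cortex, ch, meg_model = geom$sphere,
                        constrained = TRUE)
  cov <- structure(list(C = diag(nrow(gain$G)) * (5e-14)^2,
                        channel_names = ch$name, channel_kinds = ch$kind,
                        source = "synthetic", n_samples = 10000,
                        regularized = 0.1),
                   class = "noise_covariance")
  .test_cache$gain <- list(geom = geom, ch = ch, gain = gain, cov = cov)
  .test_cache$gain
}

# light 16-subject sensor-level study: returns the paired subject evoked
# arrays (subjects x channels x times, decimated) and the sensor adjacency
light_group_study <- function(seed, effect = TRUE, n_subjects = 16,
                              n_trials = 20) {
  spec <- simulation_spec(n_runs = 1, n_trials = n_trials, sfreq = 275,
                          n_meg = 20, n_eeg = 0, cortex_subdiv = 1,
                          pad = 1.5, isi = c(1.2, 1.4),
                          blink_rate = 0, heart_rate = 0)
  if (!effect) spec$amp_ventral["Familiar"] <- spec$amp_ventral["Scrambled"]
  grp <- simulate_group(n_subjects, seed = seed, subject_spec = spec)
  evs <- lapply(seq_len(n_subjects), function(i) {
    sim <- realize_subject(grp, i)
    rec <- sim$runs[[1]]
    stim <- transform_events(
      combine_bit_events(decode_trigger_bits(rec), face_stimulus_rules(),
                         rec$sfreq),
      "add_offset", offset = 0.0345)
    lapply(c("Familiar", "Scrambled"), function(cond)
      average_condition(make_epochs(rec, stim, label = cond,
                                    window = c(-0.2, 0.5))))
  })
  ev1 <- evs[[1]][[1]]
  meg_i <- which(ev1$channels$kind == "MEG_MAG")
  dec <- seq(1, length(ev1$times), by = 4)
  A <- aperm(vapply(evs, function(e) e[[1]]$data[meg_i, dec],
                    matrix(0, length(meg_i), length(dec))), c(3, 1, 2))
  B <- aperm(vapply(evs, function(e) e[[2]]$data[meg_i, dec],
                    matrix(0, length(meg_i), length(dec))), c(3, 1, 2))
  pos <- as.matrix(ev1$channels[meg_i, c("x", "y", "z")])
  adj <- suppressWarnings(build_adjacency(pos, dist_threshold = 0.07))
  list(A = A, B = B, adjacency = adj, times = ev1$times[dec])
}

group_cluster_detects <- function(seed, effect = TRUE, n_rand = 300) {
  st <- light_group_study(seed, effect = effect)
  cl <- cluster_permutation(st$A, st$B, st$adjacency, n_rand = n_rand,
                            seed = seed + 1)
  any(cl$clusters$p <= 0.05)
}
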