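# Synthetic multi-subject MEG/EEG generator with full ground truth: bit-coded
# triggers, condition-dependent evoked dipoles, blink/cardiac/cHPI artifacts,
# 1/f + line + white noise, multiple runs, between-subject variability.

#' Default single-subject simulation parameters
#'
#' Desk-scale defaults: 3 runs of 40 trials per condition, two stimulus
#' categories (Familiar faces, code 5; Scrambled images, code 17), 60
#' magnetometers + 20 EEG electrodes at 1100 Hz, a 642-vertex cortical
#' source space, evoked SNR 3. An occipital source peaks ~100 ms in every
#' condition; a ventral face-sensitive source peaks ~155 ms with amplitude
#' Faces > Scrambled.
#'
#' @param ... overrides of any default element.
#' @return a named list of parameters.
#' @export
simulation_spec <- function(...) {
  spec <- list(
    n_runs = 3,
    n_trials = 40,                       # per condition per run
    conditions = c(Familiar = 5, Scrambled = 17),
    sfreq = 1100,
    n_meg = 60, n_eeg = 20,
    cortex_subdiv = 3,                   # 642 vertices
    scalp_radius = 0.09, cortex_radius = 0.062, sensor_radius = 0.12,
    isi = c(1.4, 1.7),                   # inter-stimulus interval range, s
    pad = 3,                             # run edge padding, s
    trigger_delay = 0.0345,              # hardware presentation delay, s
    pulse_s = 0.05,                      # trigger pulse width
    amp_occipital = 30e-9,               # A*m
    amp_ventral = c(Familiar = 40e-9, Scrambled = 16e-9),
    latency_occipital = 0.100, latency_ventral = 0.155,
    width_occipital = 0.020, width_ventral = 0.025,
    snr = 3,                             # evoked peak / noise sd at best MEG
    noise_corner = 2,                    # 1/f corner, Hz
    line_freq = 50,
    line_rel = 0.5,                      # line amplitude / noise sd
    white_rel = 0.3,                     # white floor / 1/f sd
    blink_rate = 0.08,                   # Hz (Poisson)
    heart_rate = 1.2,                    # Hz
    blink_amp_eog = 150e-6,              # V on the EOG channel
    cardiac_amp_meg = 0,                 # set > 0 to contaminate MEG
    blink_amp_meg = 0,
    chpi_start = NULL,                   # absolute time, s (NULL = off)
    chpi_freqs = c(293, 307, 314, 321, 328),
    chpi_rel = 20,
    first_sample_time = 0,
    bad_channels = character(),
    eeg_shells = NULL                    # filled from geometry
  )
  modifyList(spec, list(...))
}

# Fibonacci lattice directions on the upper cap
cap_directions <- function(n, zmin = 0) {
  g <- (1 + sqrt(5)) / 2
  k <- seq_len(n) - 0.5
  z <- zmin + (1 - zmin) * (k / n)
  phi <- 2 * pi * k / g
  cbind(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
}

#' Synthetic head geometry and sensor layout
#'
#' Spherical scalp, a radially perturbed icosphere cortex (so that surface
#' normals are not purely radial and MEG sees the sources), magnetometers on
#' a helmet cap and EEG electrodes on the scalp, plus EOG/ECG/STIM channels.
#'
#' @param spec a [simulation_spec()].
#' @return list: `channels`, `scalp`, `cortex`, `sphere` (MEG), `shells`
#'   (EEG).
#' @export
simulate_head_geometry <- function(spec = simulation_spec()) {
  scalp <- icosphere(2, spec$scalp_radius)
  ctx <- icosphere(spec$cortex_subdiv, 1)
  dir <- ctx$vertices
  phi <- atan2(dir[, 2], dir[, 1])
  # asymmetric radial corrugation: normals are nowhere exactly radial, so no
  # cortical source is completely invisible to MEG
  bump <- 1 + 0.12 * sin(3 * phi + 0.7 * dir[, 3]) * (1 - dir[, 3]^2) +
    0.06 * dir[, 3]^2 + 0.05 * sin(2 * phi + 1.3) * dir[, 3]
  ctx <- surface_mesh(dir * (spec$cortex_radius * bump), ctx$faces)
  meg_dir <- cap_directions(spec$n_meg, zmin = 0.05)
  meg_pos <- meg_dir * spec$sensor_radius
  eeg_dir <- cap_directions(spec$n_eeg, zmin = 0.0)
  eeg_pos <- eeg_dir * spec$scalp_radius
  aux_pos <- matrix(NA_real_, 3, 3)
  ch <- channel_info(
    name = c(sprintf("MEG%03d", seq_len(spec$n_meg)),
             sprintf("EEG%03d", seq_len(spec$n_eeg)),
             "EEG062", "EEG063", "STI101"),
    kind = c(rep("MEG_MAG", spec$n_meg), rep("EEG", spec$n_eeg),
             "EOG", "ECG", "STIM"),
    position = rbind(meg_pos, eeg_pos, aux_pos),
    orientation = rbind(meg_dir, matrix(NA_real_, spec$n_eeg + 3, 3)))
  ch$is_bad[ch$name %in% spec$bad_channels] <- TRUE
  shells <- shell_model(radii = spec$scalp_radius * c(0.89, 0.94, 1.0),
                        conductivities = c(0.33, 0.0042, 0.33))
  list(channels = ch, scalp = scalp, cortex = ctx,
       sphere = structure(list(center = c(0, 0, 0),
                               radius = spec$scalp_radius),
                          class = "sphere_model"),
       shells = shells)
}

# sensor-space field pattern (length = all channels; aux rows 0) of a unit
# dipole at cortex vertex j along its normal
unit_dipole_pattern <- function(geom, j, transfer = NULL) {
  ch <- geom$channels
  pos <- geom$cortex$vertices[j, ]
  mom <- geom$cortex$normals[j, ]
  out <- numeric(nrow(ch))
  for (i in seq_len(nrow(ch))) {
    if (ch$kind[i] == "MEG_MAG") {
      out[i] <- meg_forward_sphere(pos, mom,
                                   as.numeric(ch[i, c("x", "y", "z")]),
                                   as.numeric(ch[i, c("ox", "oy", "oz")]),
                                   geom$sphere)
    } else if (ch$kind[i] == "EEG") {
      out[i] <- eeg_forward_spheres(pos, mom,
                                    as.numeric(ch[i, c("x", "y", "z")]),
                                    geom$shells, transfer = transfer)
    }
  }
  out
}

pick_source_vertices <- function(geom) {
  v <- geom$cortex$vertices
  nrm <- geom$cortex$normals
  # tangential fraction of the normal: proxy for MEG coupling in a sphere
  er <- v / sqrt(rowSums(v^2))
  tang <- sqrt(pmax(0, 1 - rowSums(nrm * er)^2))
  occ <- which.min(v[, 1] - 0.3 * v[, 3])           # posterior
  # ventral: posterior-inferior candidates with usable coupling
  score <- v[, 1] + 2.5 * v[, 3]
  cand <- setdiff(order(score)[seq_len(max(4, nrow(v) %/% 10))], occ)
  ven <- cand[which.max(tang[cand])]
  c(occipital = unname(occ), ventral = unname(ven))
}

gauss_pulse <- function(t, t0, width) exp(-(t - t0)^2 / (2 * width^2))

# 1/f + white noise trace via spectral shaping
colored_noise <- function(n, sfreq, corner) {
  f <- c(seq(0, floor(n / 2)), -seq(ceiling(n / 2) - 1, 1)) * sfreq / n
  shape <- 1 / sqrt(pmax(abs(f), corner))
  shape[1] <- 0
  x <- Re(fft(fft(rnorm(n)) * shape, inverse = TRUE) / n)
  x / sd(x)
}

#' Simulate one subject
#'
#' Generates `n_runs` continuous recordings (evoked dipole responses +
#' artifacts + 1/f, line and white noise + bit-coded trigger channel) and
#' the complete ground truth needed to validate every downstream estimate.
#'
#' @param spec a [simulation_spec()]; @param seed integer RNG seed.
#' @return list of class `sim_subject`: `runs` (list of recordings),
#'   `truth` (schedules, artifact times, source parameters, geometry, seed).
#' @export
simulate_subject <- function(spec = simulation_spec(), seed = 1) {
  set.seed(seed)
  geom <- simulate_head_geometry(spec)
  src_idx <- pick_source_vertices(geom)
  transfer <- if (any(geom$channels$kind == "EEG"))
    shell_transfer_table(geom$shells) else NULL
  pat_occ <- unit_dipole_pattern(geom, src_idx["occipital"], transfer)
  pat_ven <- unit_dipole_pattern(geom, src_idx["ventral"], transfer)
  runs <- vector("list", spec$n_runs)
  schedules <- vector("list", spec$n_runs)
  artifacts <- vector("list", spec$n_runs)
  conds <- names(spec$conditions)
  n_stim <- spec$n_trials * length(conds)
  for (r in seq_len(spec$n_runs)) {
    isi <- runif(n_stim, spec$isi[1], spec$isi[2])
    trig_t <- spec$first_sample_time + spec$pad + cumsum(isi)
    cond_seq <- sample(rep(conds, spec$n_trials))
    duration <- (trig_t[n_stim] - spec$first_sample_time) + spec$pad + 1.5
    n <- round(duration * spec$sfreq)
    t <- spec$first_sample_time + (seq_len(n) - 1) / spec$sfreq
    stim_t <- trig_t + spec$trigger_delay      # true presentation times
    # trigger channel: code pulses at trigger time
    trig <- numeric(n)
    for (k in seq_len(n_stim)) {
      s0 <- round((trig_t[k] - spec$first_sample_time) * spec$sfreq) + 1
      trig[s0:min(n, s0 + round(spec$pulse_s * spec$sfreq))] <-
        spec$conditions[cond_seq[k]]
    }
    # source time courses
    tc_occ <- numeric(n); tc_ven <- numeric(n)
    for (k in seq_len(n_stim)) {
      tc_occ <- tc_occ + spec$amp_occipital *
        gauss_pulse(t, stim_t[k] + spec$latency_occipital,
                    spec$width_occipital)
      tc_ven <- tc_ven + spec$amp_ventral[cond_seq[k]] *
        gauss_pulse(t, stim_t[k] + spec$latency_ventral, spec$width_ventral)
    }
    x <- outer(pat_occ, tc_occ) + outer(pat_ven, tc_ven)
    # noise scaled per kind for the target evoked SNR
    meg_i <- which(geom$channels$kind == "MEG_MAG")
    eeg_i <- which(geom$channels$kind == "EEG")
    peak_meg <- max(abs(x[meg_i, ]))
    peak_eeg <- if (length(eeg_i)) max(abs(x[eeg_i, ])) else 0
    for (i in c(meg_i, eeg_i)) {
      lvl <- (if (i %in% meg_i) peak_meg else peak_eeg) / spec$snr
      if (lvl == 0) next
      ns <- colored_noise(n, spec$sfreq, spec$noise_corner) +
        spec$white_rel * rnorm(n)
      ns <- ns / sd(ns) +
        spec$line_rel * sin(2 * pi * spec$line_freq * t + runif(1, 0, 2 * pi))
      x[i, ] <- x[i, ] + lvl * ns
    }
    # noisy bad channels
    for (nm in spec$bad_channels) {
      i <- match(nm, geom$channels$name)
      if (!is.na(i)) x[i, ] <- x[i, ] + 20 * peak_eeg * rnorm(n)
    }
    x[which(geom$channels$kind == "STIM")[1], ] <- trig
    rec <- recording(geom$channels, x, spec$sfreq,
                     first_sample_time = spec$first_sample_time)
    inj <- inject_artifacts(rec, blink_rate = spec$blink_rate,
                            heart_rate = spec$heart_rate,
                            blink_amp_eog = spec$blink_amp_eog,
                            blink_amp_meg = spec$blink_amp_meg,
                            cardiac_amp_meg = spec$cardiac_amp_meg,
                            chpi_start = spec$chpi_start,
                            chpi_freqs = spec$chpi_freqs,
                            chpi_rel = spec$chpi_rel * peak_meg)
    runs[[r]] <- inj$rec
    schedules[[r]] <- data.frame(run = r, trigger = trig_t, onset = stim_t,
                                 condition = cond_seq,
                                 code = unname(spec$conditions[cond_seq]),
                                 stringsAsFactors = FALSE)
    artifacts[[r]] <- inj$truth
  }
  structure(list(runs = runs,
                 truth = list(schedule = do.call(rbind, schedules),
                              artifacts = artifacts,
                              source_vertices = src_idx,
                              patterns = list(occipital = pat_occ,
                                              ventral = pat_ven),
                              geometry = geom, spec = spec, seed = seed)),
            class = "sim_subject")
}

#' Inject artifacts into a recording
#'
#' Blinks: smooth 400 ms raised-cosine bumps at Poisson times on a frontal
#' topography, mirrored on the EOG channel. Heartbeats: a sharp biphasic
#' template at quasi-periodic times on a fixed cardiac topography, mirrored
#' on the ECG channel. Optionally, cHPI sinusoids (> 290 Hz) starting at a
#' configurable absolute time.
#'
#' @param rec a recording with EOG/ECG channels.
#' @param blink_rate Poisson rate, Hz; @param heart_rate beats per second.
#' @param blink_amp_eog,blink_amp_meg,cardiac_amp_meg amplitudes (V, T).
#' @param chpi_start absolute start time (s) or NULL; @param chpi_freqs Hz;
#'   @param chpi_rel amplitude (T).
#' @return list: `rec` (contaminated), `truth` (blink/beat times, chpi
#'   start).
#' @export
inject_artifacts <- function(rec, blink_rate = 0.08, heart_rate = 1.2,
                             blink_amp_eog = 150e-6, blink_amp_meg = 0,
                             cardiac_amp_meg = 0, chpi_start = NULL,
                             chpi_freqs = c(293, 307, 314, 321, 328),
                             chpi_rel = 0) {
  stopifnot(blink_rate >= 0, heart_rate >= 0)
  t <- rec_times(rec)
  n <- length(t)
  span <- rec_span(rec)
  x <- rec$data
  ch <- rec$channels
  blink_t <- numeric(0)
  if (blink_rate > 0) {
    nb <- stats::rpois(1, diff(span) * blink_rate)
    blink_t <- sort(runif(nb, span[1] + 0.5, span[2] - 0.5))
    if (length(blink_t) > 1)
      blink_t <- blink_t[c(TRUE, diff(blink_t) > 0.8)]
  }
  blink_win <- 0.4
  if (0.8 > diff(span)) stop("artifact template longer than recording")
  eog_i <- which(ch$kind == "EOG")
  meg_i <- which(ch$kind == "MEG_MAG")
  eeg_i <- which(ch$kind == "EEG")
  front <- c(0.08, 0, 0.02)
  t0 <- rec$first_sample_time
  win_idx <- function(bt, half) {
    s <- round((bt - half - t0) * rec$sfreq) + 1
    e <- round((bt + half - t0) * rec$sfreq) + 1
    seq(max(1, s), min(n, e))
  }
  for (bt in blink_t) {
    sel <- win_idx(bt, blink_win / 2)
    bump <- 0.5 * (1 + cos(2 * pi * (t[sel] - bt) / blink_win))
    if (length(eog_i))
      x[eog_i, sel] <- x[eog_i, sel] + blink_amp_eog * bump
    if (blink_amp_meg > 0 && length(meg_i)) {
      pos <- as.matrix(ch[meg_i, c("x", "y", "z")])
      w <- exp(-sqrt(rowSums((pos - rep(front, each = length(meg_i)))^2)) /
                 0.05)
      x[meg_i, sel] <- x[meg_i, sel] + blink_amp_meg * outer(w, bump)
    }
    if (length(eeg_i)) {
      pos <- as.matrix(ch[eeg_i, c("x", "y", "z")])
      w <- exp(-sqrt(rowSums((pos - rep(front, each = length(eeg_i)))^2)) /
                 0.04)
      x[eeg_i, sel] <- x[eeg_i, sel] + 0.3 * blink_amp_eog * outer(w, bump)
    }
  }
  beat_t <- numeric(0)
  if (heart_rate > 0) {
    period <- 1 / heart_rate
    beat_t <- seq(span[1] + 0.5, span[2] - 0.5, by = period) +
      rnorm(length(seq(span[1] + 0.5, span[2] - 0.5, by = period)), 0, 0.005)
    beat_t <- beat_t[beat_t > span[1] + 0.2 & beat_t < span[2] - 0.2]
  }
  ecg_i <- which(ch$kind == "ECG")
  qrs <- function(dt) {
    # biphasic R-wave, ~80 ms support
    (dt > -0.04 & dt < 0.04) *
      (exp(-(dt / 0.008)^2) - 0.35 * exp(-((dt - 0.025) / 0.012)^2))
  }
  card_topo <- NULL
  if (cardiac_amp_meg > 0 && length(meg_i)) {
    card_topo <- sin(seq_along(meg_i)) + 0.5 * cos(2 * seq_along(meg_i))
    card_topo <- card_topo / sqrt(sum(card_topo^2))
  }
  for (bt in beat_t) {
    sel <- win_idx(bt, 0.05)
    pulse <- qrs(t[sel] - bt)
    if (length(ecg_i))
      x[ecg_i, sel] <- x[ecg_i, sel] + 1e-3 * pulse
    if (!is.null(card_topo))
      x[meg_i, sel] <- x[meg_i, sel] + cardiac_amp_meg * outer(card_topo, pulse)
  }
  chpi_t0 <- NULL
  if (!is.null(chpi_start) && chpi_rel > 0 && length(meg_i)) {
    sel <- t >= chpi_start
    if (any(sel)) {
      hp <- Reduce(`+`, lapply(chpi_freqs, function(f)
        sin(2 * pi * f * t[sel])))
      x[meg_i, sel] <- x[meg_i, sel] +
        chpi_rel * outer(rep(1, length(meg_i)), hp)
      chpi_t0 <- chpi_start
    }
  }
  rec$data <- x
  list(rec = rec,
       truth = list(blink_times = blink_t, beat_times = beat_t,
                    chpi_start = chpi_t0, cardiac_topography = card_topo))
}

#' Simulate an empty-room noise recording
#'
#' MEG-only noise (1/f + line + white) with no subject; used for noise
#' covariance estimation.
#'
#' @param spec a [simulation_spec()]; @param duration seconds; @param seed
#'   RNG seed; @param noise_level sensor noise sd (T).
#' @return a recording with the subject's MEG channels.
#' @export
simulate_empty_room <- function(spec = simulation_spec(), duration = 60,
                                seed = 1, noise_level = 5e-14) {
  set.seed(seed)
  geom <- simulate_head_geometry(spec)
  meg <- geom$channels[geom$channels$kind == "MEG_MAG", , drop = FALSE]
  class(meg) <- c("channel_info", "data.frame")
  n <- round(duration * spec$sfreq)
  t <- (seq_len(n) - 1) / spec$sfreq
  x <- t(vapply(seq_len(nrow(meg)), function(i) {
    ns <- colored_noise(n, spec$sfreq, spec$noise_corner) +
      spec$white_rel * rnorm(n)
    noise_level * (ns / sd(ns) +
                     spec$line_rel * sin(2 * pi * spec$line_freq * t +
                                           runif(1, 0, 2 * pi)))
  }, numeric(n)))
  recording(meg, x, spec$sfreq)
}

#' Simulate a multi-subject group dataset
#'
#' Draws per-subject amplitude and latency jitter around the group-level
#' effect, with a shared template cortex and per-subject (identity)
#' vertex mappings. Subjects are realized lazily with [realize_subject()] to
#' bound memory.
#'
#' @param n_subjects number of subjects; @param between_subject_sd relative
#'   sd of the per-subject amplitude scaling; @param latency_sd s.
#' @param seed RNG seed; @param subject_spec base [simulation_spec()].
#' @return list of class `sim_group`: `subjects` (per-subject spec + seed),
#'   `template` mesh, `mappings`, `seed`.
#' @export
simulate_group <- function(n_subjects = 16, between_subject_sd = 0.15,
                           latency_sd = 0.008, seed = 1,
                           subject_spec = simulation_spec()) {
  stopifnot(n_subjects >= 2)
  set.seed(seed)
  geom0 <- simulate_head_geometry(subject_spec)
  subjects <- lapply(seq_len(n_subjects), function(i) {
    scale <- max(0.2, 1 + rnorm(1, 0, between_subject_sd))
    jit <- rnorm(1, 0, latency_sd)
    sp <- subject_spec
    sp$amp_occipital <- sp$amp_occipital * scale
    sp$amp_ventral <- sp$amp_ventral * scale
    sp$latency_occipital <- sp$latency_occipital + jit
    sp$latency_ventral <- sp$latency_ventral + jit
    list(id = sprintf("sub-%02d", i), spec = sp,
         seed = seed * 1000L + i, scale = scale, latency_jitter = jit)
  })
  nv <- nrow(geom0$cortex$vertices)
  mappings <- lapply(seq_len(n_subjects), function(i) diag(nv))
  structure(list(subjects = subjects, template = geom0$cortex,
                 mappings = mappings, seed = seed,
                 subject_spec = subject_spec),
            class = "sim_group")
}

#' Realize one subject of a simulated group
#' @param group a `sim_group`; @param i subject index.
#' @return a `sim_subject` (see [simulate_subject()]).
#' @export
realize_subject <- function(group, i)
  simulate_subject(group$subjects[[i]]$spec, group$subjects[[i]]$seed)

#' Write a simulated subject as a standard dataset layout
#'
#' Raw container + channels.tsv + events.tsv per run, plus a truth JSON.
#' @param sim a `sim_subject`; @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_sim_subject <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in seq_along(sim$runs)) {
    stem <- file.path(dir, sprintf("run-%02d", r))
    write_raw(sim$runs[[r]], stem)
    write_channels_tsv(sim$runs[[r]]$channels,
                       paste0(stem, "_channels.tsv"))
  }
  truth <- sim$truth
  truth$geometry <- NULL   # meshes are re-derivable from spec + seed
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA,
                       auto_unbox = TRUE, null = "null", na = "null",
                       force = TRUE)
  invisible(dir)
}
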