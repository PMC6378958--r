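# Noise covariance, WMNE kernels, dSPM/sLORETA standardizations, z-scoring.

test_that("noise covariance estimation matches direct formulas", {
  set.seed(41)
  nch <- 8
  ch <- channel_info(paste0("M", 1:nch), "MEG_MAG",
                     position = matrix(rnorm(nch * 3), ncol = 3),
                     orientation = matrix(rep(c(0, 0, 1), nch), ncol = 3,
                                          byrow = TRUE))
  # white noise sigma^2 = 4: diagonal ~ 4, off-diagonal ~ 0 within 3 MC s.e.
  n <- 40000
  rec <- recording(ch, matrix(rnorm(nch * n, 0, 2), nch), 1000)
  cov <- estimate_noise_cov(rec, "empty_room")
  se_d <- 4 * sqrt(2 / n); se_o <- 4 / sqrt(n)
  expect_true(all(abs(diag(cov$C) - 4) < 3 * se_d))
  off <- cov$C[upper.tri(cov$C)]
  expect_true(all(abs(off) < 4 * se_o))
  expect_equal(cov$n_samples, n)
  # bad segments excluded
  rec2 <- rec
  rec2$data[, 1:1000] <- 1e3
  rec2 <- add_bad_segment(rec2, 0, 1.0, "jump")
  cov2 <- estimate_noise_cov(rec2, "empty_room")
  expect_lt(max(abs(diag(cov2$C) - 4)), 3 * se_d + 0.1)

  # two perfectly correlated channels -> rank deficiency visible
  rec3 <- rec
  rec3$data[2, ] <- rec3$data[1, ]
  cov3 <- estimate_noise_cov(rec3, "empty_room")
  expect_lt(min(eigen(cov3$C, symmetric = TRUE, only.values = TRUE)$values),
            1e-10)

  # baseline mode equals the brute-force covariance of the concatenated block
  spec <- simulation_spec(n_runs = 1, n_trials = 5, sfreq = 275, n_meg = 10,
                          n_eeg = 0, cortex_subdiv = 1, pad = 1.5,
                          isi = c(1.3, 1.5), blink_rate = 0, heart_rate = 0)
  sim <- simulate_subject(spec, 11)
  rec4 <- sim$runs[[1]]
  stim <- transform_events(combine_bit_events(decode_trigger_bits(rec4),
                                              face_stimulus_rules(),
                                              rec4$sfreq),
                           "add_offset", offset = 0.0345)
  ep <- make_epochs(rec4, stim)
  covb <- estimate_noise_cov(ep, "baseline")
  sel <- ep$times >= -0.5 & ep$times <= -0.0009
  picks <- which(!ep$channels$is_bad &
                   ep$channels$kind %in% c("MEG_MAG", "MEG_GRAD", "EEG"))
  blk <- do.call(cbind, lapply(which(ep$good), function(k)
    ep$data[k, picks, sel]))
  blk <- blk - rowMeans(blk)
  Cref <- tcrossprod(blk) / (ncol(blk) - 1)
  expect_equal(covb$C, Cref, tolerance = 1e-12)
})

test_that("diagonal loading regularizes per channel kind", {
  nch <- 6
  kinds <- c(rep("MEG_MAG", 3), rep("EEG", 3))
  C <- diag(c(1, 2, 3, 100, 200, 300))
  cov <- structure(list(C = C, channel_names = paste0("c", 1:6),
                        channel_kinds = kinds, source = "synthetic",
                        n_samples = 100, regularized = 0),
                   class = "noise_covariance")
  # fraction 0 -> identity operation
  expect_identical(regularize_cov(cov, 0)$C, C)
  r <- regularize_cov(cov, 0.1)
  expect_equal(diag(r$C)[1:3] - diag(C)[1:3], rep(0.1 * 2, 3))
  expect_equal(diag(r$C)[4:6] - diag(C)[4:6], rep(0.1 * 200, 3))
  # singular covariance becomes invertible
  covs <- cov; covs$C <- matrix(1, 6, 6)
  rs <- regularize_cov(covs, 0.1)
  expect_gt(rcond(rs$C), 1e-12)
  expect_error(regularize_cov(cov, -0.5), "negative")
})

test_that("WMNE kernel matches the dense formula and its exact-inverse limit", {
  setup <- small_gain_setup()
  G <- setup$gain$G; cov <- setup$cov
  kern <- compute_wmne_kernel(setup$gain, cov, depth_gamma = 0.5, snr = 3)
  # dense-formula oracle computed independently
  g2 <- colSums(G^2)
  w <- g2^(-0.5); w <- pmin(w, min(w) * 10)
  GR <- G %*% diag(w)
  lam2 <- sum(diag(GR %*% t(G))) / (9 * sum(diag(cov$C)))
  Kref <- diag(w) %*% t(G) %*% solve(GR %*% t(G) + lam2 * cov$C)
  expect_equal(kern$K, Kref, tolerance = 1e-9)
  expect_equal(kern$lambda2, lam2, tolerance = 1e-12)

  # gamma = 0, lambda -> 0, square well-conditioned G: K -> G^-1
  set.seed(42)
  Gs <- diag(6) + matrix(rnorm(36, 0, 0.05), 6)
  covs <- structure(list(C = diag(6), channel_names = paste0("c", 1:6),
                         channel_kinds = rep("MEG_MAG", 6),
                         source = "synthetic", n_samples = 100,
                         regularized = 0), class = "noise_covariance")
  k0 <- compute_wmne_kernel(Gs, covs, depth_gamma = 0, lambda2 = 1e-12)
  expect_lt(max(abs(k0$K %*% Gs - diag(6))), 1e-6)

  # depth weighting: stronger columns get smaller priors
  ord <- order(g2, decreasing = TRUE)
  expect_true(all(diff(kern$R[ord]) >= -1e-18))
  # kernel linearity
  y1 <- rnorm(nrow(G)); y2 <- rnorm(nrow(G))
  expect_equal(kern$K %*% (2 * y1 + y2),
               2 * kern$K %*% y1 + kern$K %*% y2, tolerance = 1e-9)
  # mismatched channels -> error
  expect_error(compute_wmne_kernel(G[1:10, ], cov), "match")
})

test_that("single-source recovery: WMNE within 2 mesh edges; dSPM no worse", {
  setup <- small_gain_setup()
  G <- setup$gain$G; cov <- setup$cov
  mesh <- setup$geom$cortex
  e <- mesh_edges(mesh)
  edge_len <- mean(sqrt(rowSums((mesh$vertices[e[, 1], ] -
                                   mesh$vertices[e[, 2], ])^2)))
  kern <- compute_wmne_kernel(setup$gain, cov)
  kd <- standardize_kernel(kern, cov, "dspm")
  set.seed(43)
  L <- chol(cov$C)
  err_w <- err_d <- numeric(20)
  for (s in 1:20) {
    j <- sample(ncol(G), 1)
    amp <- 20e-9
    y <- G[, j] * amp
    noise <- as.vector(t(L) %*% rnorm(nrow(G))) * max(abs(y)) /
      (3 * sqrt(mean(diag(cov$C))))
    yn <- y + noise
    dist_to <- function(k) sqrt(sum((mesh$vertices[k, ] -
                                       mesh$vertices[j, ])^2))
    err_w[s] <- dist_to(which.max(abs(kern$K %*% yn)))
    err_d[s] <- dist_to(which.max(abs(kd$K %*% yn)))
  }
  expect_lte(median(err_w), 2 * edge_len)
  expect_lte(median(err_d), median(err_w))
})

test_that("dSPM yields unit noise variance; sLORETA has zero localization error", {
  setup <- small_gain_setup()
  cov <- setup$cov
  kern <- compute_wmne_kernel(setup$gain, cov)
  kd <- standardize_kernel(kern, cov, "dspm")
  set.seed(44)
  L <- chol(cov$C)
  noise <- t(L) %*% matrix(rnorm(nrow(cov$C) * 20000), nrow(cov$C))
  sv <- apply(kd$K %*% noise, 1, sd)
  expect_true(all(abs(sv - 1) < 0.05))          # unit variance +-5%
  # scaling data by 10 scales the output by 10 (linearity preserved)
  y <- rnorm(nrow(cov$C))
  expect_equal(kd$K %*% (10 * y), 10 * kd$K %*% y, tolerance = 1e-12)

  # sLORETA: noiseless single sources peak at the true vertex, everywhere
  ks <- standardize_kernel(kern, cov, "sloreta")
  miss <- 0
  for (j in seq_len(ncol(setup$gain$G))) {
    est <- abs(ks$K %*% setup$gain$G[, j])
    if (which.max(est) != j) miss <- miss + 1
  }
  expect_equal(miss, 0)
})

test_that("baseline z-scoring is exact and matches the two-pass oracle", {
  set.seed(45)
  times <- seq(-0.2, 0.9, by = 1 / 275)
  x <- matrix(rnorm(5 * length(times)), 5)
  x[, times > 0] <- x[, times > 0] + 4        # post-stimulus shift
  est <- structure(list(data = x, times = times, method = "wmne"),
                   class = "source_estimate")
  z <- zscore_baseline(est, c(-0.2, -0.005))
  base <- times >= -0.2 & times <= -0.005
  expect_lt(max(abs(rowMeans(z$data[, base]))), 1e-12)
  expect_equal(apply(z$data[, base], 1, sd), rep(1, 5), tolerance = 1e-12)
  # constant shift Delta -> z = Delta / sd_base
  mu <- rowMeans(x[, base]); sdv <- apply(x[, base], 1, sd)
  expect_equal(z$data, (x - mu) / sdv, tolerance = 1e-12)
  # degenerate baseline -> errors
  x0 <- x; x0[2, base] <- 7
  est0 <- structure(list(data = x0, times = times, method = "wmne"),
                    class = "source_estimate")
  expect_error(zscore_baseline(est0), "zero baseline variance")
  expect_error(zscore_baseline(est, c(5, 6)), "baseline")
})
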