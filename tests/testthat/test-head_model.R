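# Registration (fiducials, ICP, electrode projection), sphere fitting, and
# the spherical MEG/EEG forward models.

rand_rotation <- function(angle) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

test_that("fiducial alignment recovers rigid motions and matches Kabsch", {
  set.seed(21)
  fid_d <- rbind(NAS = c(0.09, 0, 0), LPA = c(0, 0.07, 0),
                 RPA = c(0, -0.07, 0))
  R <- rand_rotation(0.4); tr <- c(0.01, -0.02, 0.005)
  fid_a <- t(R %*% t(fid_d)) + rep(tr, each = 3)
  tf <- align_fiducials(list(digitizer = fid_d, anatomy = fid_a))
  expect_lt(tf$residual, 1e-12)
  expect_lt(max(abs(tf$R - R)), 1e-9)
  expect_lt(max(abs(tf$t - tr)), 1e-9)
  # identity frames -> identity transform
  tid <- align_fiducials(list(digitizer = fid_d, anatomy = fid_d))
  expect_lt(max(abs(tid$matrix - diag(4))), 1e-12)
  # noisy points: equals a brute-force SVD solution on the centered cloud
  pts <- matrix(rnorm(30), 10, 3)
  tgt <- t(R %*% t(pts)) + rep(tr, each = 10) + matrix(rnorm(30, 0, 0.002), 10)
  got <- megevoke:::kabsch(pts, tgt)
  cf <- colMeans(pts); ct <- colMeans(tgt)
  H <- t(pts - rep(cf, each = 10)) %*% (tgt - rep(ct, each = 10))
  sv <- svd(H)
  Rb <- sv$v %*% diag(c(1, 1, sign(det(sv$v %*% t(sv$u))))) %*% t(sv$u)
  expect_lt(max(abs(got$R - Rb)), 1e-9)
  # collinear points -> error
  col <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(align_fiducials(list(digitizer = col, anatomy = col)),
               "collinear")
})

test_that("points below the nasion are removed per-point", {
  set.seed(22)
  nasion <- c(0.09, 0, 0.01)
  pts <- matrix(rnorm(300, 0, 0.05), 100, 3)
  kept <- remove_points_below_nasion(pts, nasion)
  expect_equal(nrow(kept), sum(pts[, 3] >= nasion[3]))
  expect_true(all(kept[, 3] >= nasion[3]))
  above <- pts[pts[, 3] >= nasion[3], , drop = FALSE]
  expect_identical(remove_points_below_nasion(above, nasion), above)
  below <- pts[pts[, 3] < nasion[3], , drop = FALSE]
  expect_warning(out <- remove_points_below_nasion(below, nasion), "below")
  expect_equal(nrow(out), 0)
})

test_that("ICP recovers a rigid perturbation with non-increasing cost", {
  set.seed(23)
  scalp <- icosphere(3, 1)
  # ellipsoidal scalp: registration is identifiable (a sphere would leave
  # rotations about its center unconstrained)
  scalp <- surface_mesh(scalp$vertices %*% diag(c(0.10, 0.085, 0.07)),
                        scalp$faces)
  # head points sampled on the scalp (upper half)
  idx <- sample(which(scalp$vertices[, 3] > 0), 80)
  pts_anat <- scalp$vertices[idx, ]
  R <- rand_rotation(0.2)                    # ~11 degrees
  tr <- c(0.012, -0.008, 0.015)
  # digitizer points = anatomy points moved by the inverse motion
  pts_dig <- t(t(R) %*% (t(pts_anat) - tr))
  init <- megevoke:::kabsch(pts_dig[1:10, ], pts_anat[1:10, ] +
                              matrix(rnorm(30, 0, 0.004), 10))
  tf <- icp_refine(pts_dig, scalp, init, max_iter = 200, tol = 0)
  expect_true(all(diff(tf$cost_trace) <= 1e-15))       # monotone
  expect_lt(max(abs(apply_transform(tf, pts_dig) - pts_anat)), 1e-3)
  ang <- acos((sum(diag(t(tf$R) %*% R)) - 1) / 2) * 180 / pi
  expect_lt(ang, 0.5)
  # init = truth -> no change beyond tolerance
  truth <- init; truth$R <- R; truth$t <- tr
  tf2 <- icp_refine(pts_dig, scalp, truth, max_iter = 10, tol = 1e-10)
  expect_lt(max(abs(tf2$R - R)), 1e-2)
  expect_error(icp_refine(pts_dig[1:5, ], scalp, init), "at least 10")
})

test_that("electrode projection lands on the surface", {
  scalp <- icosphere(3, 0.09)
  set.seed(24)
  dirs <- matrix(rnorm(45), 15, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  elec <- dirs * 0.095                        # 5 mm off a 90 mm sphere mesh
  pr <- project_electrodes_to_scalp(elec, scalp)
  r <- sqrt(rowSums(pr$points^2))
  # mesh-resolution bound: chord sagitta of a subdiv-3 icosphere < 1 mm
  expect_true(all(abs(r - 0.09) < 1e-3))
  expect_true(all(pr$displacement > 0.004 & pr$displacement < 0.007))
  # an electrode already on the surface stays put
  v17 <- scalp$vertices[17, , drop = FALSE]
  pr2 <- project_electrodes_to_scalp(v17, scalp)
  expect_lt(pr2$displacement, 1e-12)
  # post-projection distance to the surface ~ 0 for all electrodes
  d2 <- closest_point_on_mesh(pr$points, scalp)$distance
  expect_lt(max(d2), 1e-9)
})

test_that("sphere fits are exact on spheres and match nonlinear LS on caps", {
  set.seed(25)
  ctr <- c(0.01, -0.02, 0.03); rad <- 0.087
  dirs <- matrix(rnorm(120), 40, 3); dirs <- dirs / sqrt(rowSums(dirs^2))
  pts <- dirs * rad + rep(ctr, each = 40)
  fit <- fit_sphere(pts)
  expect_lt(max(abs(fit$center - ctr)), 1e-9)
  expect_lt(abs(fit$radius - rad), 1e-9)
  # hemisphere samples with noise vs brute-force nonlinear least squares
  hemi <- dirs[dirs[, 3] > 0, , drop = FALSE] * rad +
    rep(ctr, each = sum(dirs[, 3] > 0))
  hemi <- hemi + matrix(rnorm(length(hemi), 0, 2e-4), nrow(hemi))
  fit2 <- fit_sphere(hemi)
  obj <- function(p) sum((sqrt(rowSums((hemi - rep(p[1:3],
                                                   each = nrow(hemi)))^2)) -
                            p[4])^2)
  nls_fit <- optim(c(ctr, rad), obj, method = "BFGS",
                   control = list(reltol = 1e-14))
  expect_lt(max(abs(fit2$center - nls_fit$par[1:3])), 5e-4)
  expect_lt(abs(fit2$radius - nls_fit$par[4]), 5e-4)
  # coplanar points -> error
  flat <- cbind(matrix(rnorm(40), 20, 2), 0)
  expect_error(fit_sphere(flat), "coplanar")

  # local spheres vary smoothly across neighboring sensors on an ellipsoid
  ell <- icosphere(3, 1)
  ell$vertices <- ell$vertices %*% diag(c(0.095, 0.085, 0.08))
  ell <- surface_mesh(ell$vertices, ell$faces)
  sens <- cap_dirs <- rbind(c(0, 0, 0.12), c(0.015, 0, 0.119),
                            c(0.03, 0, 0.116))
  fits <- lapply(seq_len(3), function(i) fit_local_sphere(sens[i, ], ell))
  ctrs <- do.call(rbind, lapply(fits, `[[`, "center"))
  step <- sqrt(rowSums(diff(ctrs)^2))
  expect_true(all(step < 0.01))               # continuity across 15 mm moves
})

test_that("Sarvas field obeys the spherical-conductor theorem and a term-wise oracle", {
  sph <- structure(list(center = c(0, 0, 0), radius = 0.09),
                   class = "sphere_model")
  set.seed(26)
  for (k in 1:10) {
    r0 <- rnorm(3); r0 <- r0 / sqrt(sum(r0^2)) * runif(1, 0.02, 0.07)
    sens <- rnorm(3); sens <- sens / sqrt(sum(sens^2)) * 0.12
    ori <- rnorm(3); ori <- ori / sqrt(sum(ori^2))
    # radial dipole -> exactly null external field
    expect_lt(abs(meg_forward_sphere(r0, r0 * 1e-7, sens, ori, sph)), 1e-25)
    # independent term-by-term evaluation of the closed form
    q <- rnorm(3) * 1e-8
    a_vec <- sens - r0
    a <- sqrt(sum(a_vec^2)); rn <- sqrt(sum(sens^2))
    Fv <- a * (rn * a + rn^2 - sum(r0 * sens))
    adotr <- sum(a_vec * sens)
    gF <- (a^2 / rn + adotr / a + 2 * a + 2 * rn) * sens -
      (a + 2 * rn + adotr / a) * r0
    qx <- c(q[2] * r0[3] - q[3] * r0[2], q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
    Bref <- 1e-7 * (Fv * qx - sum(qx * sens) * gF) / Fv^2
    got <- meg_forward_sphere(r0, q, sens, ori, sph)
    expect_equal(got, sum(Bref * ori), tolerance = 1e-12)
    # linear in the moment
    expect_equal(meg_forward_sphere(r0, 5 * q, sens, ori, sph), 5 * got,
                 tolerance = 1e-12)
  }
  # gradiometer = two-point difference over the baseline
  r0 <- c(0.02, 0.01, 0.05); q <- c(0, 1e-8, 0)
  sens <- c(0, 0, 0.12); ori <- c(0, 0, 1); ax <- c(1, 0, 0)
  g <- meg_forward_sphere(r0, q, sens, ori, sph, grad_axis = ax,
                          grad_baseline = 0.0168)
  b1 <- meg_forward_sphere(r0, q, sens + 0.0084 * ax, ori, sph)
  b2 <- meg_forward_sphere(r0, q, sens - 0.0084 * ax, ori, sph)
  expect_equal(g, (b1 - b2) / 0.0168, tolerance = 1e-15)
})

test_that("shell potentials reduce to the homogeneous sphere and honor symmetry", {
  R <- 0.09
  sig <- 0.33
  sh_eq <- shell_model(radii = c(0.08, 0.085, R),
                       conductivities = rep(sig, 3))
  # independent oracle: direct homogeneous-sphere Legendre series
  homog <- function(dip, mom, elec, nmax = 300) {
    b <- sqrt(sum(dip^2)); er <- dip / b
    re <- elec / sqrt(sum(elec^2))
    cosg <- min(1, max(-1, sum(er * re)))
    tv <- re - cosg * er; tv <- tv / sqrt(sum(tv^2))
    mr <- sum(mom * er); mt <- sum(mom * tv)
    p <- numeric(nmax + 1); p[1] <- 1; p[2] <- cosg
    for (n in 2:nmax) p[n + 1] <- ((2 * n - 1) * cosg * p[n] -
                                     (n - 1) * p[n - 1]) / n
    sint <- sqrt(max(0, 1 - cosg^2))
    tot <- 0
    for (n in 1:nmax) {
      dp <- n * (p[n] - cosg * p[n + 1]) / max(1 - cosg^2, 1e-12)
      tot <- tot + (2 * n + 1) / n * (b / R)^(n - 1) *
        (n * mr * p[n + 1] + mt * sint * dp)
    }
    tot / (4 * pi * sig * R^2)
  }
  set.seed(27)
  for (k in 1:6) {
    dip <- rnorm(3); dip <- dip / sqrt(sum(dip^2)) * runif(1, 0.01, 0.065)
    mom <- rnorm(3) * 1e-8
    elec <- rnorm(3); elec <- elec / sqrt(sum(elec^2)) * R
    v <- eeg_forward_spheres(dip, mom, elec, sh_eq)
    expect_equal(v, homog(dip, mom, elec), tolerance = 1e-3)
  }
  # central radial dipole: potential proportional to cos(angle to moment)
  sh3 <- shell_model()
  mom <- c(0, 0, 1e-8)
  angs <- seq(0, pi, length.out = 7)
  vv <- vapply(angs, function(a)
    eeg_forward_spheres(c(0, 0, 0), mom,
                        0.09 * c(sin(a), 0, cos(a)), sh3), 0)
  expect_equal(vv, vv[1] * cos(angs), tolerance = 1e-9)
  # equatorial ring is the zero crossing (antisymmetry)
  expect_lt(abs(vv[4]), 1e-20)
  expect_equal(vv[7], -vv[1], tolerance = 1e-9)
  # dipole outside the innermost shell -> error
  expect_error(eeg_forward_spheres(c(0.085, 0, 0), mom, c(0, 0, 0.09), sh3),
               "innermost")
})

test_that("gain assembly has the right shape, constraint identity, and row symmetry", {
  setup <- small_gain_setup()
  geom <- setup$geom; ch <- setup$ch
  # free vs constrained shapes and the contraction identity
  sub <- surface_mesh(geom$cortex$vertices[1:10, ],
                      matrix(c(1, 2, 3), 1))   # 10 vertices, minimal faces
  sub$normals <- geom$cortex$normals[1:10, ]
  free <- assemble_gain(sub, ch, meg_model = geom$sphere, constrained = FALSE)
  cons <- assemble_gain(sub, ch, meg_model = geom$sphere, constrained = TRUE)
  expect_equal(dim(free$G), c(nrow(ch), 30))
  expect_equal(dim(cons$G), c(nrow(ch), 10))
  for (j in 1:10)
    expect_equal(cons$G[, j],
                 as.vector(free$G[, (3 * j - 2):(3 * j)] %*% sub$normals[j, ]),
                 tolerance = 1e-12)
  # swapping two identical sensors permutes gain rows exactly
  ch2 <- ch; ch2[c(1, 2), ] <- ch[c(2, 1), ]
  class(ch2) <- class(ch)
  g2 <- assemble_gain(sub, ch2, meg_model = geom$sphere, constrained = TRUE)
  expect_identical(g2$G[1, ], cons$G[2, ])
  expect_identical(g2$G[2, ], cons$G[1, ])
  # sensor data simulated as gain %*% source reproduces the forward values
  j <- 4
  y <- cons$G[, j] * 2e-8
  for (i in c(1, 7, 19))
    expect_equal(y[i],
                 2e-8 * meg_forward_sphere(sub$vertices[j, ], sub$normals[j, ],
                                           as.numeric(ch[i, c("x", "y", "z")]),
                                           as.numeric(ch[i, c("ox", "oy", "oz")]),
                                           geom$sphere),
                 tolerance = 1e-15)
  # vertex outside the conductor -> error naming the offender
  bad <- sub; bad$vertices[3, ] <- c(0, 0, 0.2)
  expect_error(assemble_gain(bad, ch, meg_model = geom$sphere,
                             eeg_model = geom$shells, constrained = TRUE),
               "outside")

  # radial-orientation columns are null relative to tangential ones when a
  # single shared sphere is used
  er <- sub$vertices / sqrt(rowSums(sub$vertices^2))
  rad_norm <- tan_norm <- numeric(10)
  for (j in 1:10) {
    cols <- free$G[, (3 * j - 2):(3 * j)]
    rad <- cols %*% er[j, ]
    t1 <- er[j, c(2, 1, 3)] * c(-1, 1, 0)
    t1 <- t1 - sum(t1 * er[j, ]) * er[j, ]; t1 <- t1 / sqrt(sum(t1^2))
    rad_norm[j] <- sqrt(sum(rad^2))
    tan_norm[j] <- sqrt(sum((cols %*% t1)^2))
  }
  expect_lt(max(rad_norm) / max(tan_norm), 1e-6)
})
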