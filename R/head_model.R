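# Sensor-anatomy registration (fiducials, ICP, electrode projection) and
# spherical forward models for MEG (Sarvas) and EEG (concentric shells) on a
# constrained cortical source space.

#' Rigid transform from fiducials
#'
#' Closed-form least-squares rigid alignment (Kabsch) of the NAS/LPA/RPA
#' triplets, mapping the digitizer frame into the anatomy frame.
#'
#' @param fid list with `digitizer` and `anatomy`, each a 3 x 3 matrix with
#'   rows NAS, LPA, RPA (meters).
#' @return list of class `rigid_transform`: `R` (3x3 rotation), `t`
#'   (translation), `matrix` (4x4), `residual` (RMS, m).
#' @export
align_fiducials <- function(fid) {
  kabsch(fid$digitizer, fid$anatomy)
}

kabsch <- function(from, to, weights = NULL) {
  from <- as.matrix(from); to <- as.matrix(to)
  if (is.null(weights)) weights <- rep(1, nrow(from))
  w <- weights / sum(weights)
  if (collinear(from) || collinear(to))
    stop("points are collinear; rigid transform undetermined")
  cf <- colSums(from * w); ct <- colSums(to * w)
  A <- t((from - rep(cf, each = nrow(from))) * w) %*%
    (to - rep(ct, each = nrow(to)))
  sv <- svd(A)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- ct - as.vector(R %*% cf)
  fit <- t(R %*% t(from)) + rep(tr, each = nrow(from))
  M <- rbind(cbind(R, tr), c(0, 0, 0, 1))
  structure(list(R = R, t = tr, matrix = M,
                 residual = sqrt(mean(rowSums((fit - to)^2)))),
            class = "rigid_transform")
}

collinear <- function(p) {
  if (nrow(p) < 3) return(TRUE)
  v1 <- p[2, ] - p[1, ]; v2 <- p[3, ] - p[1, ]
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  sqrt(sum(cr^2)) < 1e-12 * max(1, sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
}

#' Apply a rigid transform to points
#' @param transform a `rigid_transform`; @param points n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, points) {
  t(transform$R %*% t(as.matrix(points))) +
    rep(transform$t, each = nrow(as.matrix(points)))
}

#' Discard digitized points below the nasion
#'
#' Keeps points whose superior (Z) coordinate is at or above the nasion's;
#' used when the anatomical surface is de-faced below that level.
#'
#' @param points n x 3 matrix (head frame, Z superior); @param nasion
#'   3-vector.
#' @return the filtered matrix (warning when empty).
#' @export
remove_points_below_nasion <- function(points, nasion) {
  keep <- points[, 3] >= nasion[3]
  if (!any(keep)) warning("all points below nasion; empty result")
  points[keep, , drop = FALSE]
}

# closest point on one triangle (clamped barycentric, Ericson)
closest_on_triangle <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(a)
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(b)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return(a + ab * d1 / (d1 - d3))
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(c)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return(a + ac * d2 / (d2 - d6))
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
    return(b + (c - b) * (d4 - d3) / ((d4 - d3) + (d5 - d6)))
  denom <- 1 / (va + vb + vc)
  a + ab * (vb * denom) + ac * (vc * denom)
}

#' Closest points on a mesh surface
#' @param points n x 3 matrix; @param mesh a `surface_mesh`.
#' @return list `points` (n x 3 projected points), `distance` (n).
#' @export
closest_point_on_mesh <- function(points, mesh) {
  v <- mesh$vertices; f <- mesh$faces
  fc <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
           v[f[, 3], , drop = FALSE]) / 3
  out <- matrix(0, nrow(points), 3)
  dist <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    d2c <- rowSums((fc - rep(p, each = nrow(fc)))^2)
    cand <- order(d2c)[seq_len(min(40, nrow(fc)))]
    best <- NULL; bd <- Inf
    for (k in cand) {
      q <- closest_on_triangle(p, v[f[k, 1], ], v[f[k, 2], ], v[f[k, 3], ])
      d <- sum((q - p)^2)
      if (d < bd) { bd <- d; best <- q }
    }
    out[i, ] <- best; dist[i] <- sqrt(bd)
  }
  list(points = out, distance = dist)
}

#' Refine a registration with iterative closest points
#'
#' Alternates closest-point-on-mesh association with a closed-form rigid
#' update; the mean squared distance is non-increasing by construction.
#'
#' @param points n x 3 digitized head points (digitizer frame).
#' @param scalp_mesh anatomy-frame `surface_mesh`.
#' @param init_transform starting `rigid_transform` (from
#'   [align_fiducials()]).
#' @param max_iter,tol stopping rules (tol on the RMS distance decrease, m).
#' @return a `rigid_transform` with an extra `cost_trace` field (RMS per
#'   iteration).
#' @export
icp_refine <- function(points, scalp_mesh, init_transform,
                       max_iter = 50, tol = 1e-7) {
  if (nrow(points) < 10) stop("need at least 10 points for ICP")
  cur <- init_transform
  trace <- numeric()
  for (it in seq_len(max_iter)) {
    moved <- apply_transform(cur, points)
    cp <- closest_point_on_mesh(moved, scalp_mesh)
    rms <- sqrt(mean(cp$distance^2))
    if (length(trace) && rms > trace[length(trace)] + 1e-15) {
      warning("degenerate association; stopping")
      break
    }
    trace <- c(trace, rms)
    upd <- kabsch(points, cp$points)
    if (length(trace) > 1 &&
        trace[length(trace) - 1] - rms < tol) { cur <- upd; break }
    cur <- upd
  }
  cur$cost_trace <- trace
  cur
}

#' Project electrodes onto the scalp surface
#'
#' Moves each electrode to its nearest point on the mesh (vertex, edge or
#' face interior) and reports the displacement.
#'
#' @param electrodes n x 3 matrix (registered frame).
#' @param scalp_mesh a `surface_mesh`.
#' @return list `points` (projected n x 3), `displacement` (m).
#' @export
project_electrodes_to_scalp <- function(electrodes, scalp_mesh) {
  cp <- closest_point_on_mesh(as.matrix(electrodes), scalp_mesh)
  list(points = cp$points, displacement = cp$distance)
}

#' Least-squares sphere fit
#'
#' Algebraic (linear) least squares on `|p - c|^2 = r^2`; optional weights.
#'
#' @param points n x 3 matrix (n >= 4, non-coplanar).
#' @param weights optional nonnegative weights.
#' @return a `sphere_model`: `center`, `radius`.
#' @export
fit_sphere <- function(points, weights = NULL) {
  p <- as.matrix(points)
  if (nrow(p) < 4) stop("need at least 4 points")
  if (is.null(weights)) weights <- rep(1, nrow(p))
  X <- cbind(2 * p, 1)
  y <- rowSums(p^2)
  W <- weights / mean(weights)
  XtX <- t(X * W) %*% X
  if (rcond_est(XtX) < 1e-12) stop("points are (nearly) coplanar")
  beta <- solve(XtX, t(X * W) %*% y)
  center <- beta[1:3]
  r2 <- beta[4] + sum(center^2)
  structure(list(center = as.vector(center), radius = sqrt(max(r2, 0))),
            class = "sphere_model")
}

rcond_est <- function(M) {
  s <- svd(M, nu = 0, nv = 0)$d
  min(s) / max(s)
}

#' Sphere locally fitted to the scalp around one sensor
#'
#' Weights scalp vertices by a Gaussian of angular (arc) distance to the
#' sensor's closest scalp point; kernel width 0.1 rad by default.
#'
#' @param sensor_pos 3-vector; @param scalp_mesh a `surface_mesh`.
#' @param kernel_rad Gaussian width, radians of scalp arc.
#' @return a `sphere_model`.
#' @export
fit_local_sphere <- function(sensor_pos, scalp_mesh, kernel_rad = 0.1) {
  v <- scalp_mesh$vertices
  global <- fit_sphere(v)
  cp <- closest_point_on_mesh(matrix(sensor_pos, 1), scalp_mesh)$points[1, ]
  u0 <- (cp - global$center); u0 <- u0 / sqrt(sum(u0^2))
  uv <- v - rep(global$center, each = nrow(v))
  uv <- uv / sqrt(rowSums(uv^2))
  ang <- acos(pmin(1, pmax(-1, uv %*% u0)))
  w <- exp(-0.5 * (ang / kernel_rad)^2)
  fit_sphere(v, weights = w + 1e-9)
}

MU0 <- 4e-7 * pi

#' Magnetic field of a current dipole in a spherical conductor (Sarvas)
#'
#' Closed-form field at a point outside the sphere, projected on the sensor
#' orientation. Radial dipoles produce an exactly null external field. Planar
#' gradiometers are modeled as the difference of two magnetometer readings
#' divided by the baseline.
#'
#' @param dipole_pos,dipole_moment 3-vectors (m; A*m), dipole inside the
#'   sphere.
#' @param sensor_pos,sensor_ori 3-vectors (sensor outside; unit orientation).
#' @param sphere a `sphere_model` (only the center matters for MEG).
#' @param grad_axis,grad_baseline optional unit tangent axis and baseline (m)
#'   for a planar gradiometer reading (T/m).
#' @return field value (T, or T/m for gradiometers).
#' @export
meg_forward_sphere <- function(dipole_pos, dipole_moment, sensor_pos,
                               sensor_ori, sphere,
                               grad_axis = NULL, grad_baseline = NULL) {
  if (!is.null(grad_axis)) {
    d <- grad_baseline / 2
    b1 <- meg_forward_sphere(dipole_pos, dipole_moment,
                             sensor_pos + d * grad_axis, sensor_ori, sphere)
    b2 <- meg_forward_sphere(dipole_pos, dipole_moment,
                             sensor_pos - d * grad_axis, sensor_ori, sphere)
    return((b1 - b2) / grad_baseline)
  }
  sum(sarvas_field(dipole_pos, dipole_moment, sensor_pos, sphere$center) *
        sensor_ori)
}

sarvas_field <- function(r0, q, r, center) {
  r0 <- r0 - center; r <- r - center
  a_vec <- r - r0
  a <- sqrt(sum(a_vec^2)); rn <- sqrt(sum(r^2))
  if (a < 1e-12) stop("sensor coincides with dipole")
  F_ <- a * (rn * a + rn^2 - sum(r0 * r))
  if (abs(F_) < 1e-30) return(c(0, 0, 0))
  gradF <- (a^2 / rn + sum(a_vec * r) / a + 2 * a + 2 * rn) * r -
    (a + 2 * rn + sum(a_vec * r) / a) * r0
  qxr0 <- cross3(q, r0)
  (MU0 / (4 * pi * F_^2)) * (F_ * qxr0 - sum(qxr0 * r) * gradF)
}

# deterministic tangential axis for a planar gradiometer's coil pair
tangent_axis <- function(ori) {
  ref <- if (abs(ori[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- cross3(ori, ref)
  t1 / sqrt(sum(t1^2))
}

cross3 <- function(u, v)
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])

#' Concentric-shells model for the EEG forward problem
#'
#' @param radii strictly increasing shell outer radii (m), innermost
#'   (brain) first.
#' @param conductivities matching conductivities (S/m), positive.
#' @param center 3-vector.
#' @return a `shell_model`.
#' @export
shell_model <- function(radii = c(0.08, 0.085, 0.09) * 1.0,
                        conductivities = c(0.33, 0.0042, 0.33),
                        center = c(0, 0, 0)) {
  stopifnot(length(radii) == length(conductivities),
            all(diff(radii) > 0), all(conductivities > 0))
  structure(list(radii = radii, sigma = conductivities, center = center),
            class = "shell_model")
}

# Legendre P_n(x) and P_n^1(x) = sin(theta) dP_n/dx for n = 1..nmax
legendre_pair <- function(x, nmax) {
  p <- numeric(nmax + 1); p[1] <- 1; p[2] <- x
  for (n in 2:nmax) p[n + 1] <- ((2 * n - 1) * x * p[n] - (n - 1) * p[n - 1]) / n
  sint <- sqrt(max(0, 1 - x^2))
  dp <- numeric(nmax + 1)
  for (n in 1:nmax)
    dp[n + 1] <- n * (p[n] - x * p[n + 1]) / max(1 - x^2, 1e-300)
  list(P = p[-1], P1 = sint * dp[-1])
}

# Per-degree radial transfer of the concentric-shell Laplace problem: the
# dimensionless surface potential factor T_n such that
#   V(electrode) = 1/(4 pi sigma_1 R^2) * sum_n T_n (b/R)^(n-1)
#                  [n m_r P_n + m_t P_n^1].
# Solved exactly per degree from the boundary conditions, with per-region
# scaled unknowns (B_j rho_j^n, C_j rho_j^-(n+1), rho = r/R) so the system
# stays well conditioned at high n. Homogeneous case: T_n = (2n+1)/n.
shell_transfer <- function(n, radii, sigma) {
  L <- length(radii)
  rho <- radii / radii[L]
  if (L == 1) return(1 + (n + 1) / n)
  nun <- 1 + 2 * (L - 1)
  M <- matrix(0, nun, nun); rhs <- numeric(nun)
  colA1 <- 1
  colB <- function(j) 2 * (j - 1)      # j >= 2
  colC <- function(j) 2 * (j - 1) + 1
  row <- 0
  # source coefficient alpha = 1 (term rho^-(n+1) in region 1, scaled units)
  for (j in seq_len(L - 1)) {
    up <- (rho[j] / rho[j + 1])^n            # outer-region r^n at interface
    dn <- (rho[j + 1] / rho[j])^(n + 1)      # outer-region r^-(n+1) there
    row <- row + 1                           # potential continuity
    if (j == 1) {
      M[row, colA1] <- 1
      rhs[row] <- -rho[1]^(-(n + 1))
    } else {
      M[row, colB(j)] <- 1; M[row, colC(j)] <- 1
    }
    M[row, colB(j + 1)] <- -up; M[row, colC(j + 1)] <- -dn
    row <- row + 1                           # radial current continuity
    if (j == 1) {
      M[row, colA1] <- sigma[1] * n
      rhs[row] <- sigma[1] * (n + 1) * rho[1]^(-(n + 1))
    } else {
      M[row, colB(j)] <- sigma[j] * n
      M[row, colC(j)] <- -sigma[j] * (n + 1)
    }
    M[row, colB(j + 1)] <- -sigma[j + 1] * n * up
    M[row, colC(j + 1)] <- sigma[j + 1] * (n + 1) * dn
  }
  row <- row + 1                             # insulating outer surface
  M[row, colB(L)] <- n
  M[row, colC(L)] <- -(n + 1)
  sol <- solve(M, rhs)
  sol[colB(L)] + sol[colC(L)]
}

#' Electric potential of a dipole in concentric conductive shells
#'
#' Truncated Legendre-series solution of the multilayer sphere problem; the
#' per-degree radial factors come from an exact boundary-value solve, so the
#' equal-conductivity case reduces to the homogeneous-sphere solution. The
#' series stops when the relative term falls below `tol`.
#'
#' @param dipole_pos,dipole_moment 3-vectors (dipole strictly inside the
#'   innermost shell).
#' @param electrode_pos 3-vector on (or near) the outer radius; it is
#'   radially projected onto it.
#' @param shells a `shell_model`.
#' @param tol relative truncation tolerance; @param max_terms series cap.
#' @param transfer optional precomputed [shell_transfer_table()] (a speed-up
#'   when evaluating many dipole/electrode pairs for one model).
#' @return potential in volts (infinity reference; apply an average
#'   reference downstream).
#' @export
eeg_forward_spheres <- function(dipole_pos, dipole_moment, electrode_pos,
                                shells, tol = 1e-6, max_terms = 200,
                                transfer = NULL) {
  ctr <- shells$center
  r0 <- dipole_pos - ctr
  re <- electrode_pos - ctr
  R <- shells$radii[length(shells$radii)]
  b <- sqrt(sum(r0^2))
  if (b >= shells$radii[1]) stop("dipole outside the innermost shell")
  re <- re / sqrt(sum(re^2)) * R
  if (is.null(transfer)) transfer <- shell_transfer_table(shells, max_terms)
  if (b < 1e-12) {
    # central dipole: pure n = 1 term
    return(sum(dipole_moment * re / R) * transfer[1] /
             (4 * pi * shells$sigma[1] * R^2))
  }
  er <- r0 / b
  cosg <- sum(er * re) / R
  cosg <- min(1, max(-1, cosg))
  tvec <- re / R - cosg * er
  tn <- sqrt(sum(tvec^2))
  tvec <- if (tn > 1e-12) tvec / tn else c(0, 0, 0)
  m_r <- sum(dipole_moment * er)
  m_t <- sum(dipole_moment * tvec)
  nmax <- min(max_terms, length(transfer))
  leg <- legendre_pair(cosg, nmax)
  rel <- b / R
  total <- 0; scale_ref <- 0
  for (n in seq_len(nmax)) {
    term <- transfer[n] * rel^(n - 1) *
      (n * m_r * leg$P[n] + m_t * leg$P1[n])
    total <- total + term
    scale_ref <- max(scale_ref, abs(term))
    if (n > 5 && abs(term) < tol * max(scale_ref, 1e-300)) {
      return(total / (4 * pi * shells$sigma[1] * R^2))
    }
  }
  stop("Legendre series did not converge in ", max_terms, " terms")
}

#' Precompute per-degree shell transfer factors
#' @param shells a `shell_model`; @param nmax highest Legendre degree.
#' @return numeric vector of length `nmax`.
#' @export
shell_transfer_table <- function(shells, nmax = 200)
  vapply(seq_len(nmax), shell_transfer, 0,
         radii = shells$radii, sigma = shells$sigma)

#' Assemble the forward gain matrix
#'
#' Free-orientation gain (3 columns per source vertex) or its contraction
#' with the vertex normals (constrained). MEG rows use the Sarvas sphere
#' field, with an optional per-sensor locally fitted sphere; EEG rows use the
#' concentric-shell potential. Active projectors (including the EEG average
#' reference) are applied to the rows.
#'
#' @param source_space a `surface_mesh` with vertex normals (the cortical
#'   source space).
#' @param channels a [channel_info()] table (good MEG/EEG channels are used).
#' @param meg_model a `sphere_model`, or list of one per MEG channel (local
#'   spheres).
#' @param eeg_model a `shell_model` (required when EEG channels present).
#' @param constrained contract with vertex normals?
#' @param projectors optional projector list applied to the rows.
#' @return object of class `gain_matrix`: `G` (sensors x 3V or sensors x V),
#'   `channel_names`, `n_vertices`, `constrained`.
#' @export
assemble_gain <- function(source_space, channels, meg_model = NULL,
                          eeg_model = NULL, constrained = TRUE,
                          projectors = list()) {
  use <- !channels$is_bad & channels$kind %in% c("MEG_MAG", "MEG_GRAD", "EEG")
  ch <- channels[use, , drop = FALSE]
  v <- source_space$vertices
  nv <- nrow(v)
  check_inside(v, ch, meg_model, eeg_model)
  G <- matrix(0, nrow(ch), 3 * nv)
  eye <- diag(3)
  transfer <- if (any(ch$kind == "EEG") && !is.null(eeg_model))
    shell_transfer_table(eeg_model) else NULL
  for (i in seq_len(nrow(ch))) {
    pos <- as.numeric(ch[i, c("x", "y", "z")])
    ori <- as.numeric(ch[i, c("ox", "oy", "oz")])
    if (ch$kind[i] %in% c("MEG_MAG", "MEG_GRAD")) {
      sph <- if (is.list(meg_model) && !inherits(meg_model, "sphere_model"))
        meg_model[[i]] else meg_model
      ga <- if (ch$kind[i] == "MEG_GRAD") tangent_axis(ori) else NULL
      gb <- if (ch$kind[i] == "MEG_GRAD") 0.0168 else NULL
      for (j in seq_len(nv)) for (k in 1:3)
        G[i, 3 * (j - 1) + k] <-
          meg_forward_sphere(v[j, ], eye[k, ], pos, ori, sph,
                             grad_axis = ga, grad_baseline = gb)
    } else {
      for (j in seq_len(nv)) for (k in 1:3)
        G[i, 3 * (j - 1) + k] <-
          eeg_forward_spheres(v[j, ], eye[k, ], pos, eeg_model,
                              transfer = transfer)
    }
  }
  if (length(projectors))
    G <- apply_projectors(G, projectors, channel_names = ch$name)
  if (constrained) {
    Gc <- matrix(0, nrow(ch), nv)
    for (j in seq_len(nv))
      Gc[, j] <- G[, (3 * j - 2):(3 * j), drop = FALSE] %*%
        source_space$normals[j, ]
    G <- Gc
  }
  structure(list(G = G, channel_names = ch$name, channel_kinds = ch$kind,
                 n_vertices = nv, constrained = constrained),
            class = "gain_matrix")
}

check_inside <- function(v, ch, meg_model, eeg_model) {
  offend <- integer()
  if (!is.null(eeg_model) && any(ch$kind == "EEG")) {
    r <- sqrt(rowSums(sweep(v, 2, eeg_model$center)^2))
    offend <- union(offend, which(r >= eeg_model$radii[1]))
  }
  if (!is.null(meg_model) && inherits(meg_model, "sphere_model") &&
      is.finite(meg_model$radius) && meg_model$radius > 0) {
    r <- sqrt(rowSums(sweep(v, 2, meg_model$center)^2))
    offend <- union(offend, which(r >= meg_model$radius))
  }
  if (length(offend))
    stop("source vertices outside the conductor: ",
         paste(head(offend, 10), collapse = ", "))
}
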