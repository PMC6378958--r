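# Noise covariance estimation and regularized, depth-weighted minimum-norm
# source estimation with dSPM / sLORETA / baseline z-score standardizations.

#' Estimate the sensor noise covariance
#'
#' Sample covariance after mean removal. In "empty_room" mode the good
#' samples of a (noise) recording are used; in "baseline" mode the
#' pre-stimulus baselines of all good trials are concatenated.
#'
#' @param x a recording (empty_room) or an `epoch_set` (baseline).
#' @param mode "empty_room" or "baseline".
#' @param baseline c(t0, t1) seconds, baseline window for epoch mode.
#' @param picks channel indices (default: all good data channels).
#' @return object of class `noise_covariance`: `C`, `channel_names`,
#'   `source`, `n_samples`, `regularized`.
#' @export
estimate_noise_cov <- function(x, mode = c("empty_room", "baseline"),
                               baseline = c(-0.5, -0.0009), picks = NULL) {
  mode <- match.arg(mode)
  if (mode == "empty_room") {
    stopifnot(inherits(x, "meg_recording"))
    if (is.null(picks)) picks <- pick_channels(x, c("MEG_MAG", "MEG_GRAD", "EEG"))
    good <- good_sample_mask(x)
    block <- rec_data(x, picks)[, good, drop = FALSE]
    names <- x$channels$name[picks]
    kinds <- x$channels$kind[picks]
  } else {
    stopifnot(inherits(x, "epoch_set"))
    if (is.null(picks))
      picks <- which(!x$channels$is_bad &
                       x$channels$kind %in% c("MEG_MAG", "MEG_GRAD", "EEG"))
    sel <- x$times >= baseline[1] - 1e-12 & x$times <= baseline[2] + 1e-12
    gi <- which(x$good)
    if (!length(gi)) stop("no good trials for baseline covariance")
    block <- do.call(cbind, lapply(gi, function(k)
      x$data[k, picks, sel, drop = TRUE]))
    names <- x$channels$name[picks]
    kinds <- x$channels$kind[picks]
  }
  n <- ncol(block)
  if (n < length(picks))
    warning("fewer samples than channels; regularization is mandatory")
  block <- block - rowMeans(block)
  C <- tcrossprod(block) / (n - 1)
  structure(list(C = C, channel_names = names, channel_kinds = kinds,
                 source = mode, n_samples = n, regularized = 0),
            class = "noise_covariance")
}

#' Diagonal-loading regularization of a noise covariance
#'
#' Adds `fraction * mean(diag)` to the diagonal, separately per channel kind
#' (magnetometers, gradiometers and EEG have different scales).
#'
#' @param cov a `noise_covariance`; @param fraction loading fraction (>= 0).
#' @return the regularized `noise_covariance`.
#' @export
regularize_cov <- function(cov, fraction = 0.1) {
  if (fraction < 0) stop("negative regularization fraction")
  if (fraction == 0) return(cov)
  d <- diag(cov$C)
  load <- numeric(length(d))
  for (k in unique(cov$channel_kinds)) {
    sel <- cov$channel_kinds == k
    load[sel] <- fraction * mean(d[sel])
  }
  cov$C <- cov$C + diag(load, nrow(cov$C))
  cov$regularized <- fraction
  cov
}

#' Depth-weighted minimum-norm inverse kernel
#'
#' Source prior `R_jj = ||g_j||^(-2*gamma)` (constrained orientation; the
#' triplet norm for free orientation), clipped so the weight ratio does not
#' exceed `10^(2*gamma)`; regularization `lambda2 =
#' trace(G R G') / (snr^2 * trace(C))`; kernel
#' `K = R G' (G R G' + lambda2 C)^-1`. The source estimate is then the pure
#' linear operator `K %*% data`.
#'
#' @param gain a `gain_matrix` (constrained) or plain matrix.
#' @param cov a (regularized) `noise_covariance` over the same channels.
#' @param depth_gamma depth-weighting exponent (0 disables).
#' @param snr amplitude signal-to-noise assumption.
#' @param lambda2 override for the regularization parameter (optional).
#' @return object of class `inverse_kernel`: `K` (sources x channels),
#'   `method`, `gamma`, `lambda2`, `snr`, `R` (prior diagonal), `gain`.
#' @export
compute_wmne_kernel <- function(gain, cov, depth_gamma = 0.5, snr = 3,
                                lambda2 = NULL) {
  G <- if (inherits(gain, "gain_matrix")) gain$G else gain
  C <- cov$C
  if (nrow(G) != nrow(C)) stop("gain rows do not match covariance channels")
  g2 <- colSums(G^2)
  if (depth_gamma > 0) {
    w <- g2^(-depth_gamma)
    w <- pmin(w, min(w) * 10^(2 * depth_gamma))   # clip depth-weight ratio
  } else w <- rep(1, ncol(G))
  Rdiag <- w
  GR <- G * rep(Rdiag, each = nrow(G))
  GRGt <- GR %*% t(G)
  if (is.null(lambda2))
    lambda2 <- sum(diag(GRGt)) / (snr^2 * sum(diag(C)))
  K <- t(GR) %*% solve(GRGt + lambda2 * C)
  structure(list(K = K, method = "wmne", gamma = depth_gamma,
                 lambda2 = lambda2, snr = snr, R = Rdiag, G = G,
                 channel_names = cov$channel_names),
            class = "inverse_kernel")
}

#' Noise- or resolution-standardized inverse kernel (dSPM / sLORETA)
#'
#' dSPM divides each kernel row by the noise standard deviation it passes
#' (`sqrt((K C K')_jj)`); sLORETA divides by the resolution-based factor
#' `sqrt((K G R)_jj)`. Both produce dimensionless statistics.
#'
#' @param kernel a `wmne` `inverse_kernel`.
#' @param cov the noise covariance used to build it.
#' @param method "dspm" or "sloreta".
#' @return the standardized `inverse_kernel`.
#' @export
standardize_kernel <- function(kernel, cov, method = c("dspm", "sloreta")) {
  method <- match.arg(method)
  K <- kernel$K
  denom2 <- if (method == "dspm") {
    # diag(K C K') via the Cholesky factor: nonnegative by construction
    L <- chol(cov$C)
    rowSums((K %*% t(L))^2)
  } else {
    # diag(K G R) = diag(RG' M^-1 GR) = ||RG' L^-T||^2 rowwise, M = L'L
    GR <- kernel$G * rep(kernel$R, each = nrow(kernel$G))
    M <- GR %*% t(kernel$G) + kernel$lambda2 * cov$C
    L <- chol(M)
    X <- t(backsolve(L, GR, transpose = TRUE))
    rowSums(X^2)
  }
  if (any(denom2 <= 0))
    stop("zero standardization diagonal at source(s) ",
         paste(head(which(denom2 <= 0), 5), collapse = ", "))
  kernel$K <- K / sqrt(denom2)
  kernel$method <- method
  kernel
}

#' Apply an inverse kernel to sensor data
#'
#' @param kernel an `inverse_kernel`; @param data channels x samples matrix
#'   or an `evoked`.
#' @param times latency grid when `data` is a matrix.
#' @return object of class `source_estimate`: `data` (sources x samples),
#'   `times`, `method`.
#' @export
apply_inverse <- function(kernel, data, times = NULL) {
  if (inherits(data, "evoked")) {
    idx <- match(kernel$channel_names, data$channels$name)
    if (anyNA(idx)) stop("evoked lacks kernel channels")
    times <- data$times
    data <- data$data[idx, , drop = FALSE]
  }
  structure(list(data = kernel$K %*% data, times = times,
                 method = kernel$method),
            class = "source_estimate")
}

#' @export
print.source_estimate <- function(x, ...) {
  cat(sprintf("<source_estimate> %s: %d sources x %d samples\n",
              x$method, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Baseline z-score standardization of source traces
#'
#' Per source trace: `(x(t) - mean_baseline) / sd_baseline`.
#'
#' @param est a `source_estimate` (or any object with `data` sources x
#'   samples and `times`).
#' @param baseline c(t0, t1) seconds.
#' @return the standardized object (method suffixed "+z").
#' @export
zscore_baseline <- function(est, baseline = c(-0.2, -0.005)) {
  sel <- est$times >= baseline[1] - 1e-12 & est$times <= baseline[2] + 1e-12
  if (!any(sel)) stop("baseline outside the latency grid")
  mu <- rowMeans(est$data[, sel, drop = FALSE])
  sdv <- apply(est$data[, sel, drop = FALSE], 1, sd)
  zero <- sdv <= 0
  if (any(zero))
    stop("zero baseline variance at source(s) ",
         paste(head(which(zero), 5), collapse = ", "))
  est$data <- (est$data - mu) / sdv
  est$method <- paste0(est$method %||% "", "+z")
  est
}
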