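# Morlet-wavelet time-frequency decomposition: power maps, trial averaging,
# edge-effect masking, ERS/ERD baseline scaling.

#' Logarithmically spaced frequency grid
#'
#' @param fmin,fmax endpoints, Hz (inclusive); @param n number of bins.
#' @param sfreq optional sampling rate for a Nyquist check.
#' @return numeric vector `exp(seq(log(fmin), log(fmax), length.out = n))`.
#' @export
make_freq_grid <- function(fmin = 6, fmax = 60, n = 20, sfreq = NULL) {
  stopifnot(fmin > 0, fmax > fmin, n >= 2)
  if (!is.null(sfreq) && fmax >= sfreq / 2)
    stop("fmax at or above Nyquist")
  exp(seq(log(fmin), log(fmax), length.out = n))
}

# Morlet parameters: mother wavelet of central frequency fc (Hz) and temporal
# FWHM fwhm_tc (s); at analysis frequency f the envelope scales by fc/f.
morlet_sigma_t <- function(f, fc = 1, fwhm_tc = 3)
  fwhm_tc * fc / f / (2 * sqrt(2 * log(2)))

#' Morlet time-frequency power of an epoch
#'
#' Convolution with complex Morlet wavelets whose temporal FWHM is
#' `fwhm_tc * fc / f`; output is squared modulus (power), scaled so a unit
#' sinusoid at a grid frequency yields power ~1. The validity mask excludes
#' samples within the wavelet half-support (the 1/e amplitude point of the
#' Gaussian envelope, `sigma_t * sqrt(2)`) of either epoch edge; with the
#' default mother wavelet a [-500, 1200] ms epoch analyzed down to 6 Hz is
#' valid over [-200, +900] ms.
#'
#' @param data channels x samples matrix (one trial or an average).
#' @param times latency grid, seconds; @param sfreq sampling rate.
#' @param grid analysis frequencies from [make_freq_grid()].
#' @param fc,fwhm_tc mother-wavelet central frequency (Hz) and temporal
#'   FWHM (s).
#' @return object of class `tf_map`: `power` (channels x freqs x samples),
#'   `freqs`, `times`, `mask` (freqs x samples validity), `normalization`,
#'   `n_trials`.
#' @export
morlet_tf <- function(data, times, sfreq, grid = make_freq_grid(),
                      fc = 1, fwhm_tc = 3) {
  if (is.null(dim(data))) data <- matrix(data, 1)
  nch <- nrow(data); ns <- ncol(data)
  nf <- length(grid)
  power <- array(0, c(nch, nf, ns))
  mask <- matrix(TRUE, nf, ns)
  span <- range(times)
  for (fi in seq_len(nf)) {
    f <- grid[fi]
    sig <- morlet_sigma_t(f, fc, fwhm_tc)
    half <- ceiling(4 * sig * sfreq)
    tt <- seq(-half, half) / sfreq
    w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sig^2))
    w <- w / (sum(Mod(w)) / 2)   # unit-amplitude sinusoid -> |coef| ~ 1
    half_support <- sig * sqrt(2)
    mask[fi, ] <- times >= span[1] + half_support - 1e-12 &
      times <= span[2] - half_support + 1e-12
    if (2 * half + 1 > ns) {
      mask[fi, ] <- FALSE
      warning(sprintf("epoch shorter than the wavelet at %.2f Hz; row masked", f))
    }
    nconv <- ns + length(w) - 1
    nfft <- stats::nextn(nconv, 2)
    Wf <- fft(c(w, complex(real = rep(0, nfft - length(w)))))
    for (ci in seq_len(nch)) {
      Xf <- fft(c(data[ci, ], rep(0, nfft - ns)))
      conv <- fft(Xf * Wf, inverse = TRUE) / nfft
      power[ci, fi, ] <- Mod(conv[(half + 1):(half + ns)])^2
    }
  }
  structure(list(power = power, freqs = grid, times = times, mask = mask,
                 normalization = "none", n_trials = 1L),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map> %d channels x %d freqs [%.1f, %.1f] Hz x %d samples (%s, n=%d)\n",
              dim(x$power)[1], dim(x$power)[2], min(x$freqs), max(x$freqs),
              dim(x$power)[3], x$normalization, x$n_trials))
  invisible(x)
}

#' Average time-frequency maps across trials
#'
#' Arithmetic mean of the power arrays; validity masks are intersected.
#' Averaging power keeps non-phase-locked (induced) activity that cancels in
#' the evoked (amplitude) average.
#'
#' @param tfmaps list of `tf_map` on identical grids.
#' @return a `tf_map` with `n_trials` = total.
#' @export
average_tf <- function(tfmaps) {
  f1 <- tfmaps[[1]]
  for (m in tfmaps[-1])
    if (length(m$freqs) != length(f1$freqs) ||
        max(abs(m$freqs - f1$freqs)) > 1e-9 ||
        length(m$times) != length(f1$times))
      stop("grid mismatch across tf maps")
  acc <- Reduce(`+`, lapply(tfmaps, function(m) m$power))
  msk <- Reduce(`&`, lapply(tfmaps, function(m) m$mask))
  f1$power <- acc / length(tfmaps)
  f1$mask <- msk
  f1$n_trials <- sum(vapply(tfmaps, function(m) m$n_trials, 1L))
  f1
}

#' ERS/ERD baseline normalization
#'
#' Per channel and frequency bin, power is centered and scaled by its
#' baseline mean: `100 * (P - mu_base) / mu_base` (percent change), the
#' event-related synchronization/desynchronization convention, which
#' compensates the 1/f amplitude decrease across bins.
#'
#' @param tf a `tf_map`; @param baseline c(t0, t1) seconds (must lie in the
#'   valid mask).
#' @return the normalized `tf_map` (normalization = "ersd", percent units).
#' @export
ersd_normalize <- function(tf, baseline = c(-0.2, -0.005)) {
  sel <- tf$times >= baseline[1] - 1e-12 & tf$times <= baseline[2] + 1e-12
  if (!any(sel)) stop("baseline outside the latency grid")
  for (fi in seq_along(tf$freqs)) {
    if (!all(tf$mask[fi, sel]))
      warning(sprintf("baseline overlaps masked samples at %.2f Hz", tf$freqs[fi]))
    for (ci in seq_len(dim(tf$power)[1])) {
      mu <- mean(tf$power[ci, fi, sel])
      if (mu == 0) stop("zero baseline mean power")
      tf$power[ci, fi, ] <- 100 * (tf$power[ci, fi, ] - mu) / mu
    }
  }
  tf$normalization <- "ersd"
  tf
}

#' Crop a TF map to its valid (edge-free) window
#' @param tf a `tf_map`; @param window optional c(lo, hi) s; defaults to the
#'   intersection of all per-frequency valid windows.
#' @return the cropped `tf_map`.
#' @export
crop_tf_valid <- function(tf, window = NULL) {
  sel <- if (is.null(window)) apply(tf$mask, 2, all)
  else tf$times >= window[1] - 1e-12 & tf$times <= window[2] + 1e-12
  if (!any(sel)) stop("no valid samples to keep")
  tf$power <- tf$power[, , sel, drop = FALSE]
  tf$mask <- tf$mask[, sel, drop = FALSE]
  tf$times <- tf$times[sel]
  tf
}

#' Export one channel of a TF map as TSV (frequency x time table)
#' @param tf a `tf_map`; @param channel row index; @param path output path.
#' @export
write_tf_tsv <- function(tf, channel, path) {
  df <- data.frame(frequency = rep(tf$freqs, each = length(tf$times)),
                   time = rep(tf$times, length(tf$freqs)),
                   power = as.vector(t(tf$power[channel, , ])),
                   valid = as.vector(t(tf$mask)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
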