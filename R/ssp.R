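# Signal-space projection: build projectors from artifact-locked data
# statistics (PCA), apply them lazily, report topographies.

#' Build an artifact SSP projector
#'
#' Concatenates band-passed data in windows around artifact events (good
#' channels of one kind only) and takes the PCA of the channels x samples
#' block. Components are sorted by decreasing singular value; by default only
#' the first component is active, mirroring common practice for cardiac
#' artifacts. Channel kinds are never mixed within one projector.
#'
#' @param rec a recording.
#' @param events artifact events (e.g. from [detect_heartbeats()]).
#' @param window_s c(lo, hi) seconds around each event onset (cardiac default
#'   +-40 ms; blinks typically c(-0.2, 0.2)).
#' @param band_hz band-pass applied before the PCA (cardiac default 13-40 Hz;
#'   blinks typically c(1.5, 15)).
#' @param channel_kind one of "MEG_MAG", "MEG_GRAD", "EEG".
#' @param n_keep number of component vectors stored.
#' @return an object of class `meg_projector` with fields `vectors`
#'   (orthonormal, channels x k), `sv`, `var_frac`, `active`.
#' @export
build_artifact_ssp <- function(rec, events, window_s = c(-0.04, 0.04),
                               band_hz = c(13, 40),
                               channel_kind = c("MEG_MAG", "MEG_GRAD", "EEG"),
                               n_keep = 8) {
  channel_kind <- match.arg(channel_kind)
  if (nrow(events) == 0) stop("zero artifact events")
  picks <- pick_channels(rec, channel_kind)
  if (nrow(events) < 10)
    warning("fewer than 10 artifact events; projector may be unstable")
  else if (nrow(events) < length(picks) / 10)
    warning("fewer events than channels/10; projector may be unstable")
  x <- t(apply(rec$data[picks, , drop = FALSE], 1, bandpass_trace,
               sfreq = rec$sfreq, band = band_hz))
  t0 <- rec$first_sample_time
  w0 <- round(window_s[1] * rec$sfreq); w1 <- round(window_s[2] * rec$sfreq)
  cols <- unlist(lapply(events$onset, function(on) {
    s <- round((on - t0) * rec$sfreq) + 1
    idx <- (s + w0):(s + w1)
    idx[idx >= 1 & idx <= ncol(x)]
  }))
  blk <- x[, cols, drop = FALSE]
  blk <- blk - rowMeans(blk)
  sv <- svd(blk, nu = min(n_keep, nrow(blk)), nv = 0)
  k <- ncol(sv$u)
  vf <- sv$d^2 / sum(sv$d^2)
  structure(list(name = paste0("SSP: ", channel_kind),
                 kind = channel_kind, type = "ssp",
                 channel_names = rec$channels$name[picks],
                 vectors = structure(sv$u,
                                     dimnames = list(rec$channels$name[picks],
                                                     NULL)),
                 sv = sv$d[seq_len(k)], var_frac = vf[seq_len(k)],
                 active = c(TRUE, rep(FALSE, k - 1))),
            class = "meg_projector")
}

#' @export
print.meg_projector <- function(x, ...) {
  cat(sprintf("<meg_projector> %s (%s), %d channels, %d components (%s active)\n",
              x$name, x$type, length(x$channel_names), ncol(x$vectors),
              paste(which(x$active), collapse = ",")))
  if (!all(is.na(x$var_frac)))
    cat("  variance fractions:",
        paste(sprintf("%.1f%%", 100 * head(x$var_frac, 5)), collapse = " "),
        "\n")
  invisible(x)
}

#' Apply projectors to a data matrix
#'
#' Applies `P = I - U U'` (active component vectors U) on the channel subset
#' of each projector, in order. Idempotent and contracting; rows in the
#' spanned subspace are annihilated.
#'
#' @param data channels x samples matrix (rownames used for matching when
#'   `channel_names` is missing).
#' @param projectors list of `meg_projector`.
#' @param channel_names names of the rows of `data`.
#' @return the projected matrix.
#' @export
apply_projectors <- function(data, projectors, channel_names = rownames(data)) {
  if (!length(projectors)) return(data)
  if (is.null(channel_names))
    stop("channel names required to apply projectors")
  for (p in projectors) {
    act <- p$active
    if (!any(act)) next
    rows <- match(p$channel_names, channel_names)
    if (anyNA(rows))
      stop("projector '", p$name, "' references channels absent from data")
    U <- p$vectors[, act, drop = FALSE]
    data[rows, ] <- data[rows, , drop = FALSE] -
      U %*% (t(U) %*% data[rows, , drop = FALSE])
  }
  data
}

#' Component topography of a projector
#'
#' @param projector a `meg_projector`; @param component index.
#' @return named numeric vector (unit norm), keyed by channel name.
#' @export
projector_topography <- function(projector, component = 1) {
  if (component < 1 || component > ncol(projector$vectors))
    stop("component index out of range")
  setNames(projector$vectors[, component], projector$channel_names)
}

#' Toggle active components of a projector
#' @param projector a `meg_projector`; @param active indices made active.
#' @return the modified projector.
#' @export
select_components <- function(projector, active = 1) {
  projector$active <- seq_len(ncol(projector$vectors)) %in% active
  projector
}
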