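# Epoch extraction with bad-trial bookkeeping, weighted / unweighted
# averaging, condition contrasts, time cropping.

#' Extract epochs around events
#'
#' One trial per event of the selected label. The latency grid is anchored on
#' the exact event sample (latency 0); the default DC baseline
#' `[-500, -0.9] ms` resolves to every sample strictly before the event.
#' Trials overlapping any bad segment or bad event are flagged bad (reason
#' "artifact"); trials running off the recording edge are flagged "edge".
#' Active projectors of the recording are materialized into the trial data.
#'
#' @param rec a recording.
#' @param events an [event_list()]; @param label condition label to epoch
#'   (default: all non-bad events).
#' @param window c(lo, hi) seconds around each event.
#' @param dc_baseline baseline for DC-offset removal, or NULL to skip.
#' @param run_id provenance tag recorded on the epoch set.
#' @return an object of class `epoch_set`: `data` (trials x channels x
#'   samples), `times`, `channels`, `good`, `reason`, `condition`, `run_id`.
#' @export
make_epochs <- function(rec, events, label = NULL,
                        window = c(-0.5, 1.2),
                        dc_baseline = c(-0.5, -0.0009), run_id = "run") {
  ev <- if (is.null(label)) events[!events$is_bad, , drop = FALSE]
  else events[events$label == label, , drop = FALSE]
  if (nrow(ev) == 0) stop("no events to epoch")
  stopifnot(window[1] < 0, window[2] > 0)
  n_pre <- round(-window[1] * rec$sfreq)
  n_post <- round(window[2] * rec$sfreq)
  times <- (seq(-n_pre, n_post)) / rec$sfreq
  x <- rec_data(rec)
  nch <- nrow(x); ns <- ncol(x)
  t0 <- rec$first_sample_time
  spans <- rec$bad_segments[, c("start", "end"), drop = FALSE]
  bad_ev <- events[events$is_bad, , drop = FALSE]
  if (nrow(bad_ev))
    spans <- rbind(spans, data.frame(start = bad_ev$onset,
                                     end = bad_ev$onset + bad_ev$duration))
  data <- array(0, c(nrow(ev), nch, length(times)))
  good <- rep(TRUE, nrow(ev)); reason <- rep("", nrow(ev))
  for (k in seq_len(nrow(ev))) {
    s0 <- round((ev$onset[k] - t0) * rec$sfreq) + 1
    idx <- (s0 - n_pre):(s0 + n_post)
    if (idx[1] < 1 || idx[length(idx)] > ns) {
      good[k] <- FALSE; reason[k] <- "edge"
      next
    }
    trial <- x[, idx, drop = FALSE]
    if (!is.null(dc_baseline))
      trial <- remove_dc_offset(trial, times, dc_baseline)
    data[k, , ] <- trial
    tw <- ev$onset[k] + window
    if (nrow(spans) &&
        any(spans$start <= tw[2] & spans$end >= tw[1])) {
      good[k] <- FALSE; reason[k] <- "artifact"
    }
  }
  structure(list(condition = if (is.null(label)) "all" else label,
                 data = data, times = times, channels = rec$channels,
                 good = good, reason = reason, run_id = run_id,
                 sfreq = rec$sfreq),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> '%s': %d trials (%d good) x %d channels x %d samples [%g, %g] s\n",
              x$condition, dim(x$data)[1], sum(x$good), dim(x$data)[2],
              dim(x$data)[3], min(x$times), max(x$times)))
  invisible(x)
}

new_evoked <- function(condition, data, times, channels, n_good, weighting,
                       provenance = list(), sfreq = NULL) {
  stopifnot(n_good >= 1)
  structure(list(condition = condition, data = data, times = times,
                 channels = channels, n_good = n_good, weighting = weighting,
                 provenance = provenance, sfreq = sfreq),
            class = "evoked")
}

#' @export
print.evoked <- function(x, ...) {
  cat(sprintf("<evoked> '%s' (%s, n_good=%d): %d channels x %d samples [%g, %g] s\n",
              x$condition, x$weighting, x$n_good, nrow(x$data),
              ncol(x$data), min(x$times), max(x$times)))
  invisible(x)
}

#' Average good trials of one condition
#'
#' @param epochs an `epoch_set` with at least one good trial.
#' @return an `evoked` (arithmetic mean over good trials, `n_good` recorded).
#' @export
average_condition <- function(epochs) {
  gi <- which(epochs$good)
  if (!length(gi)) stop("zero good trials in condition ", epochs$condition)
  avg <- apply(epochs$data[gi, , , drop = FALSE], c(2, 3), mean)
  new_evoked(epochs$condition, avg, epochs$times, epochs$channels,
             n_good = length(gi), weighting = "unweighted",
             provenance = list(list(run_id = epochs$run_id,
                                    n_good = length(gi))),
             sfreq = epochs$sfreq)
}

check_compatible <- function(evokeds) {
  t1 <- evokeds[[1]]$times
  for (e in evokeds[-1])
    if (length(e$times) != length(t1) || max(abs(e$times - t1)) > 1e-9)
      stop("mismatched latency grids")
  invisible(TRUE)
}

#' Weighted average of evoked responses
#'
#' `sum(n_k * avg_k) / sum(n_k)`: algebraically identical to the arithmetic
#' mean of the pooled good trials. Used for subject-level (across-run)
#' averages and for the Faces = Familiar+Unfamiliar combination.
#'
#' @param evokeds list of `evoked`; @param weights defaults to their `n_good`.
#' @param condition label of the result.
#' @return an `evoked` with `n_good = sum(n_k)`.
#' @export
weighted_average <- function(evokeds, weights = NULL, condition = NULL) {
  check_compatible(evokeds)
  if (is.null(weights)) weights <- vapply(evokeds, function(e) e$n_good, 0)
  acc <- Reduce(`+`, Map(function(e, w) w * e$data, evokeds, weights))
  new_evoked(condition %||% evokeds[[1]]$condition,
             acc / sum(weights), evokeds[[1]]$times, evokeds[[1]]$channels,
             n_good = sum(vapply(evokeds, function(e) e$n_good, 0)),
             weighting = "weighted",
             provenance = lapply(seq_along(evokeds), function(i)
               list(provenance = evokeds[[i]]$provenance,
                    weight = weights[i])),
             sfreq = evokeds[[1]]$sfreq)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Grand average across subjects
#'
#' Unweighted arithmetic mean of one evoked per subject, regardless of their
#' trial counts.
#'
#' @param evokeds list of `evoked`; @param subject_ids unique ids.
#' @return an `evoked` with `n_good` = number of subjects.
#' @export
grand_average <- function(evokeds, subject_ids = NULL) {
  if (is.null(subject_ids)) subject_ids <- seq_along(evokeds)
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids")
  check_compatible(evokeds)
  acc <- Reduce(`+`, lapply(evokeds, function(e) e$data))
  new_evoked(evokeds[[1]]$condition, acc / length(evokeds),
             evokeds[[1]]$times, evokeds[[1]]$channels,
             n_good = length(evokeds), weighting = "unweighted",
             provenance = list(subjects = subject_ids),
             sfreq = evokeds[[1]]$sfreq)
}

#' Condition contrast
#'
#' Amplitude contrast `A - B` keeps current polarity; magnitude contrast
#' `|A| - |B|` is agnostic to it (activation-style comparisons). E.g.
#' (A,B) = (-10,-5) gives A-B = -5; (A,B) = (-10,10) gives |A-B| = 20 while
#' |A|-|B| = 0.
#'
#' @param evA,evB compatible `evoked` objects.
#' @param mode "amplitude" or "magnitude".
#' @return an `evoked` holding the contrast.
#' @export
contrast <- function(evA, evB, mode = c("amplitude", "magnitude")) {
  mode <- match.arg(mode)
  check_compatible(list(evA, evB))
  if (!all(dim(evA$data) == dim(evB$data))) stop("shape mismatch")
  d <- if (mode == "amplitude") evA$data - evB$data
  else abs(evA$data) - abs(evB$data)
  new_evoked(paste0(evA$condition, " - ", evB$condition, " (", mode, ")"),
             d, evA$times, evA$channels,
             n_good = min(evA$n_good, evB$n_good), weighting = "contrast",
             sfreq = evA$sfreq)
}

#' Crop an evoked / epoch set / source estimate in time
#'
#' @param obj object with `times` and a data array whose last dimension is
#'   time.
#' @param window c(lo, hi) seconds.
#' @return the cropped object.
#' @export
crop_time <- function(obj, window = c(-0.2, 0.9)) {
  sel <- obj$times >= window[1] - 1e-12 & obj$times <= window[2] + 1e-12
  if (!any(sel)) stop("empty intersection with crop window")
  nd <- length(dim(obj$data) %||% c(1, length(obj$data)))
  obj$data <- if (is.null(dim(obj$data))) obj$data[sel]
  else if (nd == 2) obj$data[, sel, drop = FALSE]
  else obj$data[, , sel, drop = FALSE]
  obj$times <- obj$times[sel]
  obj
}

#' Plot an evoked response (butterfly plot)
#' @param x an `evoked`; @param kind channel kind to plot; @param ... passed
#'   to [graphics::matplot()].
#' @export
plot.evoked <- function(x, kind = NULL, ...) {
  sel <- if (is.null(kind)) !x$channels$is_bad
  else x$channels$kind %in% kind & !x$channels$is_bad
  graphics::matplot(x$times, t(x$data[sel, , drop = FALSE]), type = "l",
                    lty = 1, xlab = "time (s)", ylab = "amplitude",
                    main = x$condition, ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}
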