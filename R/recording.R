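#' @importFrom stats median sd mad quantile rnorm runif rbinom qt pt setNames
#'   fft convolve approx p.adjust var complete.cases optim
#' @importFrom utils head tail read.delim write.table modifyList
NULL

CHANNEL_KINDS <- c("MEG_MAG", "MEG_GRAD", "EEG", "EOG", "ECG", "STIM", "NOSIG")

#' Channel metadata table
#'
#' Builds the per-channel metadata table used by [recording()]. Positions are
#' in meters in the head frame (X toward the nasion, Y toward the left
#' pre-auricular point, Z superior); MEG orientations are unit vectors.
#'
#' @param name character vector of unique channel names.
#' @param kind channel kind, one of `r paste(CHANNEL_KINDS, collapse=", ")`.
#' @param unit physical unit string ("T", "T/m", "V", or "" for dimensionless).
#' @param position n x 3 matrix of sensor positions (m), or `NULL`.
#' @param orientation n x 3 matrix of unit sensing orientations (MEG), or `NULL`.
#' @param is_bad logical vector; bad channels never contribute to any
#'   multichannel estimate.
#' @return a `data.frame` of class `channel_info`.
#' @export
channel_info <- function(name, kind, unit = NULL,
                         position = NULL, orientation = NULL,
                         is_bad = FALSE) {
  name <- as.character(name)
  n <- length(name)
  if (anyDuplicated(name))
    stop("duplicate channel names: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  kind <- rep_len(as.character(kind), n)
  bad_kind <- !(kind %in% CHANNEL_KINDS)
  if (any(bad_kind)) {
    warning("unknown channel kind(s) mapped to NOSIG: ",
            paste(unique(kind[bad_kind]), collapse = ", "))
    kind[bad_kind] <- "NOSIG"
  }
  if (is.null(unit)) {
    unit <- c(MEG_MAG = "T", MEG_GRAD = "T/m", EEG = "V", EOG = "V",
              ECG = "V", STIM = "", NOSIG = "")[kind]
  }
  pos <- if (is.null(position)) matrix(NA_real_, n, 3) else {
    stopifnot(nrow(position) == n, ncol(position) == 3)
    as.matrix(position)
  }
  ori <- if (is.null(orientation)) matrix(NA_real_, n, 3) else {
    stopifnot(nrow(orientation) == n, ncol(orientation) == 3)
    orientation <- as.matrix(orientation)
    nrm <- sqrt(rowSums(orientation^2))
    ok <- is.na(nrm) | abs(nrm - 1) < 1e-9
    if (!all(ok)) stop("MEG orientations must have unit norm (+-1e-9)")
    orientation
  }
  df <- data.frame(name = name, kind = kind,
                   unit = rep_len(as.character(unit), n),
                   x = pos[, 1], y = pos[, 2], z = pos[, 3],
                   ox = ori[, 1], oy = ori[, 2], oz = ori[, 3],
                   is_bad = rep_len(as.logical(is_bad), n),
                   stringsAsFactors = FALSE)
  class(df) <- c("channel_info", "data.frame")
  df
}

#' Event list
#'
#' Point events have zero duration. An event is bad iff its label contains the
#' tag "bad"; bad events (and bad segments) exclude overlapping trials from
#' all further analysis.
#'
#' @param label,onset,duration character / numeric vectors (seconds; onsets
#'   absolute on the recording clock).
#' @return a `data.frame` of class `event_list`, sorted by onset.
#' @export
event_list <- function(label = character(), onset = numeric(),
                       duration = 0) {
  n <- length(onset)
  if (n > 0 && any(!is.finite(onset))) stop("non-numeric or non-finite onset")
  df <- data.frame(label = rep_len(as.character(label), n),
                   onset = as.numeric(onset),
                   duration = rep_len(as.numeric(duration), n),
                   stringsAsFactors = FALSE)
  if (any(df$duration < 0)) stop("negative event duration")
  df$is_bad <- grepl("bad", df$label, fixed = TRUE)
  df <- df[order(df$onset), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_list", "data.frame")
  df
}

empty_events <- function() event_list()

#' Continuous multichannel recording
#'
#' The central container: a channels x samples matrix in SI units with channel
#' metadata, absolute-time events, bad segments and an ordered list of lazy
#' linear projectors. Sample `i` is at time `first_sample_time + (i-1)/sfreq`.
#' Projectors are *not* applied destructively: any downstream multichannel
#' estimate applies the active ones on the fly (see [rec_data()]), so deleting
#' a projector recovers the original data exactly.
#'
#' @param channels a [channel_info()] table.
#' @param data channels x samples numeric matrix.
#' @param sfreq sampling frequency, Hz.
#' @param first_sample_time absolute time of the first sample, seconds.
#' @param events an [event_list()].
#' @param bad_segments data.frame with columns start, end, label (seconds).
#' @param projectors list of projectors (see [build_artifact_ssp()],
#'   [rereference_average()]).
#' @return an object of class `meg_recording`.
#' @export
recording <- function(channels, data, sfreq, first_sample_time = 0,
                      events = empty_events(), bad_segments = NULL,
                      projectors = list()) {
  data <- as.matrix(data)
  stopifnot(nrow(data) == nrow(channels), sfreq > 0)
  if (is.null(bad_segments))
    bad_segments <- data.frame(start = numeric(), end = numeric(),
                               label = character(), stringsAsFactors = FALSE)
  rec <- structure(list(channels = channels, data = data,
                        sfreq = as.numeric(sfreq),
                        first_sample_time = as.numeric(first_sample_time),
                        events = events, bad_segments = bad_segments,
                        projectors = projectors),
                   class = "meg_recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  span <- rec_span(rec)
  bs <- rec$bad_segments
  if (nrow(bs) && (any(bs$end < bs$start) ||
                   any(bs$start < span[1] - 1e-9) ||
                   any(bs$end > span[2] + 1e-9)))
    stop("bad segments must lie within the recording time span")
  invisible(rec)
}

#' Time span / sample times of a recording
#' @param rec a recording.
#' @return `rec_span`: c(first, last) sample times (s); `rec_times`: the full
#'   time vector.
#' @export
rec_span <- function(rec)
  c(rec$first_sample_time,
    rec$first_sample_time + (ncol(rec$data) - 1) / rec$sfreq)

#' @rdname rec_span
#' @export
rec_times <- function(rec)
  rec$first_sample_time + (seq_len(ncol(rec$data)) - 1) / rec$sfreq

#' @export
print.meg_recording <- function(x, ...) {
  sp <- rec_span(x)
  cat(sprintf("<meg_recording> %d channels x %d samples @ %g Hz, t = [%.3f, %.3f] s\n",
              nrow(x$data), ncol(x$data), x$sfreq, sp[1], sp[2]))
  cat(sprintf("  kinds: %s\n",
              paste(sprintf("%s:%d", names(table(x$channels$kind)),
                            table(x$channels$kind)), collapse = " ")))
  cat(sprintf("  %d events, %d bad segments, %d projectors (%d active)\n",
              nrow(x$events), nrow(x$bad_segments), length(x$projectors),
              sum(vapply(x$projectors, function(p) any(p$active), TRUE))))
  invisible(x)
}

#' Indices of channels by kind / goodness
#'
#' @param rec a recording.
#' @param kind optional kind filter (vector of kinds).
#' @param good_only drop channels flagged bad.
#' @return integer indices into the channel table.
#' @export
pick_channels <- function(rec, kind = NULL, good_only = TRUE) {
  keep <- rep(TRUE, nrow(rec$channels))
  if (!is.null(kind)) keep <- keep & rec$channels$kind %in% kind
  if (good_only) keep <- keep & !rec$channels$is_bad
  which(keep)
}

channel_index <- function(rec, name) {
  i <- match(name, rec$channels$name)
  if (anyNA(i)) stop("channel not found: ", paste(name[is.na(i)], collapse = ", "))
  i
}

#' Mark channels bad
#' @param rec a recording; @param names channel names to flag.
#' @return the modified recording.
#' @export
mark_bad_channels <- function(rec, names) {
  rec$channels$is_bad[channel_index(rec, names)] <- TRUE
  rec
}

#' Add a bad segment
#' @param rec a recording; @param start,end seconds; @param label segment label
#'   (a "bad" tag is appended if missing).
#' @return the modified recording.
#' @export
add_bad_segment <- function(rec, start, end, label = "bad") {
  if (!grepl("bad", label)) label <- paste0(label, "_bad")
  rec$bad_segments <- rbind(rec$bad_segments,
                            data.frame(start = start, end = end, label = label,
                                       stringsAsFactors = FALSE))
  validate_recording(rec)
}

#' Good-sample mask of a recording
#'
#' TRUE where a sample lies outside every bad segment and bad event span.
#' @param rec a recording.
#' @return logical vector, one per sample.
#' @export
good_sample_mask <- function(rec) {
  t <- rec_times(rec)
  ok <- rep(TRUE, length(t))
  spans <- rec$bad_segments[, c("start", "end"), drop = FALSE]
  ev <- rec$events
  if (nrow(ev)) {
    bad_ev <- ev[ev$is_bad, , drop = FALSE]
    if (nrow(bad_ev))
      spans <- rbind(spans, data.frame(start = bad_ev$onset,
                                       end = bad_ev$onset + bad_ev$duration))
  }
  for (k in seq_len(nrow(spans)))
    ok[t >= spans$start[k] - 1e-12 & t <= spans$end[k] + 1e-12] <- FALSE
  ok
}

#' Materialized data with active projectors applied
#'
#' @param rec a recording.
#' @param picks optional channel indices (rows of the result).
#' @return channels x samples matrix after applying all active projectors.
#' @export
rec_data <- function(rec, picks = NULL) {
  x <- apply_projectors(rec$data, rec$projectors,
                        channel_names = rec$channels$name)
  if (!is.null(picks)) x <- x[picks, , drop = FALSE]
  x
}
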