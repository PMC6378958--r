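# Event construction from the bit-coded trigger channel, and artifact
# detectors (threshold excursions, ECG R-peaks, cHPI activation, band-limited
# movement/muscle segments).

#' Decode per-bit transition events from a trigger channel
#'
#' For each bit b (1 = least significant), a point event `bit<b>` is created
#' at every sample where that bit switches 0 -> 1. Decoding each bit
#' independently is robust to overlapping codes on shared trigger lines.
#'
#' @param rec a recording; @param stim_channel name of the STIM channel.
#' @param n_bits number of bits to scan.
#' @return an [event_list()] of point events.
#' @export
decode_trigger_bits <- function(rec, stim_channel = "STI101", n_bits = 16) {
  i <- match(stim_channel, rec$channels$name)
  if (is.na(i)) stop("missing stim channel: ", stim_channel)
  x <- round(rec$data[i, ])
  if (any(x < 0)) stop("stim channel must hold nonnegative integers")
  t <- rec_times(rec)
  labs <- character(); ons <- numeric()
  for (b in seq_len(n_bits)) {
    bit <- x %/% 2^(b - 1) %% 2
    hit <- which(diff(bit) == 1) + 1L
    if (length(hit)) {
      labs <- c(labs, rep(paste0("bit", b), length(hit)))
      ons <- c(ons, t[hit])
    }
  }
  event_list(labs, ons)
}

#' Combine coincident bit events into labeled stimulus events
#'
#' Bit events occurring within one sample of each other form one trigger code;
#' each rule maps a label to a required bit pattern (1 = bit must be set,
#' 0 = bit must be clear, absent = don't care). Codes matching no rule are
#' dropped; a code matching several rules is an error.
#'
#' @param events bit events from [decode_trigger_bits()].
#' @param rules named list; each element is a named numeric vector of 0/1 over
#'   bit indices, e.g. `list(Familiar = c("3" = 1, "4" = 0, "5" = 0))`.
#' @param sfreq sampling rate used to define coincidence (one sample).
#' @return an [event_list()] with an extra `code` column (decimal trigger code).
#' @export
combine_bit_events <- function(events, rules, sfreq) {
  bits <- as.integer(sub("^bit", "", events$label))
  if (anyNA(bits)) stop("combine_bit_events expects bit<k> events only")
  ord <- order(events$onset)
  bits <- bits[ord]; ons <- events$onset[ord]
  grp <- cumsum(c(TRUE, diff(ons) > 1 / sfreq + 1e-12))
  out_lab <- character(); out_on <- numeric(); out_code <- integer()
  for (g in unique(grp)) {
    sel <- grp == g
    present <- sort(unique(bits[sel]))
    code <- sum(2^(present - 1))
    matches <- vapply(rules, function(r) {
      bi <- as.integer(names(r))
      all((bi[r == 1] %in% present)) && !any(bi[r == 0] %in% present)
    }, TRUE)
    if (sum(matches) > 1)
      stop("conflicting rules match code ", code, " at onset ", min(ons[sel]),
           ": ", paste(names(rules)[matches], collapse = ", "))
    if (sum(matches) == 1) {
      out_lab <- c(out_lab, names(rules)[matches])
      out_on <- c(out_on, min(ons[sel]))
      out_code <- c(out_code, code)
    }
  }
  ev <- event_list(out_lab, out_on)
  ev$code <- out_code[order(out_on)]
  ev
}

#' Stimulus category rules for the face-perception trigger scheme
#'
#' Bit 3 codes face, bit 4 unfamiliarity, bit 5 scrambling: Familiar faces are
#' codes 5-7, Unfamiliar faces 13-15, Scrambled images 17-19.
#' @return a rules list for [combine_bit_events()].
#' @export
face_stimulus_rules <- function() {
  list(Familiar  = c("3" = 1, "4" = 0, "5" = 0),
       Unfamiliar = c("3" = 1, "4" = 1, "5" = 0),
       Scrambled = c("5" = 1))
}

#' Transform an event list
#'
#' @param events an [event_list()].
#' @param op one of "rename", "group_by_name", "delete", "add_offset".
#' @param ... operation arguments: `from`,`to` (rename); `labels`,`to`
#'   (group_by_name); `labels` (delete); `offset` seconds and optional
#'   `labels` (add_offset; negative offsets allowed).
#' @return the transformed [event_list()]; extra columns are preserved.
#' @export
transform_events <- function(events,
                             op = c("rename", "group_by_name", "delete",
                                    "add_offset"), ...) {
  op <- match.arg(op)
  args <- list(...)
  ev <- events
  if (op == "rename") {
    if (args$to %in% setdiff(ev$label, args$from))
      stop("label '", args$to,
           "' already exists; use group_by_name to merge labels")
    ev$label[ev$label == args$from] <- args$to
  } else if (op == "group_by_name") {
    ev$label[ev$label %in% args$labels] <- args$to
  } else if (op == "delete") {
    ev <- ev[!(ev$label %in% args$labels), , drop = FALSE]
  } else if (op == "add_offset") {
    sel <- if (is.null(args$labels)) rep(TRUE, nrow(ev))
    else ev$label %in% args$labels
    ev$onset[sel] <- ev$onset[sel] + args$offset
  }
  ev$is_bad <- grepl("bad", ev$label, fixed = TRUE)
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("event_list", "data.frame")
  ev
}

# zero-phase 4th-order Butterworth band-pass of one trace
bandpass_trace <- function(x, sfreq, band, order = 4) {
  ny <- sfreq / 2
  lo <- max(band[1], 0) / ny
  hi <- min(band[2], 0.99 * ny) / ny
  bf <- if (lo <= 1e-9) signal::butter(order, hi, type = "low")
  else signal::butter(order / 2, c(lo, hi), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Detect supra-threshold excursions on one channel
#'
#' Band-passes the channel (zero phase), then marks one event per contiguous
#' excursion of the absolute signal above `threshold`; excursions separated by
#' less than `min_gap` are merged.
#'
#' @param rec a recording; @param channel channel name (must not be bad).
#' @param band c(lo, hi) Hz within (0, sfreq/2).
#' @param threshold in channel units (e.g. 100e-6 for 100 uV).
#' @param min_gap merge gap, seconds.
#' @param label event label; @param mark_bad append "_bad" so overlapping
#'   trials are excluded.
#' @return an [event_list()] of spanning events.
#' @export
detect_threshold_events <- function(rec, channel, band = c(0.3, 20),
                                    threshold, min_gap = 0.5,
                                    label = "blink", mark_bad = TRUE) {
  i <- channel_index(rec, channel)
  if (rec$channels$is_bad[i]) stop("channel ", channel, " is marked bad")
  stopifnot(band[1] >= 0, band[2] <= rec$sfreq / 2)
  x <- abs(bandpass_trace(rec$data[i, ], rec$sfreq, band))
  above <- x > threshold
  if (!any(above)) return(empty_events())
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  seg <- cbind(starts[r$values], ends[r$values])
  # merge close excursions
  gap <- round(min_gap * rec$sfreq)
  merged <- seg[1, , drop = FALSE]
  for (k in seq_len(nrow(seg))[-1]) {
    if (seg[k, 1] - merged[nrow(merged), 2] <= gap)
      merged[nrow(merged), 2] <- seg[k, 2]
    else merged <- rbind(merged, seg[k, ])
  }
  t <- rec_times(rec)
  lab <- if (mark_bad) paste0(label, "_bad") else label
  event_list(rep(lab, nrow(merged)), t[merged[, 1]],
             (merged[, 2] - merged[, 1]) / rec$sfreq)
}

#' Detect heartbeats (R-peaks) on the ECG channel
#'
#' Local-maximum search on a band-passed, amplitude-normalized trace with an
#' adaptive threshold and a physiological refractory period. Detection is
#' polarity-invariant (operates on the absolute trace).
#'
#' @param rec a recording; @param ecg_channel ECG channel name (default: the
#'   first ECG-typed channel).
#' @param band QRS emphasis band, Hz; @param refractory minimum inter-beat
#'   interval, seconds.
#' @return an [event_list()] of point events labeled "cardiac".
#' @export
detect_heartbeats <- function(rec, ecg_channel = NULL, band = c(5, 30),
                              refractory = 0.3) {
  if (is.null(ecg_channel)) {
    k <- pick_channels(rec, "ECG", good_only = FALSE)
    if (!length(k)) stop("no ECG-typed channel present")
    ecg_channel <- rec$channels$name[k[1]]
  }
  i <- channel_index(rec, ecg_channel)
  x <- abs(bandpass_trace(rec$data[i, ], rec$sfreq, band))
  if (max(x) <= 0) return(empty_events())
  x <- x / max(x)
  thr <- max(0.4 * quantile(x, 0.999), 4 * median(x))
  if (!any(x > thr)) return(empty_events())
  refr <- round(refractory * rec$sfreq)
  cand <- which(x > thr)
  peaks <- integer()
  k <- 1
  while (k <= length(cand)) {
    run <- cand[cand >= cand[k] & cand < cand[k] + refr]
    peaks <- c(peaks, run[which.max(x[run])])
    k <- match(run[length(run)], cand) + 1
    while (k <= length(cand) && cand[k] - peaks[length(peaks)] < refr)
      k <- k + 1
  }
  t <- rec_times(rec)
  event_list(rep("cardiac", length(peaks)), t[peaks])
}

#' Detect the cHPI activation transition
#'
#' Head-position-indicator coils emit strong narrowband sinusoids well above
#' the physiological band. Per sliding window, the detector measures the
#' spectral peakedness of the high band (largest periodogram bin over the
#' mean bin above `hp_edge`): coil sinusoids concentrate power into single
#' bins (peakedness in the thousands) while broadband sensor noise stays
#' near ~log(#bins). The span from the start of the file to the first
#' HPI-active window is returned as one bad segment.
#'
#' @param rec a recording; @param channel channel to scan (default: first
#'   good MEG channel).
#' @param window_s analysis window, seconds; @param hp_edge high-band lower
#'   edge, Hz; @param peak_ratio peakedness criterion for an active window.
#' @return data.frame with start/end/label (zero rows if HPI is on from the
#'   first sample; the whole file flagged with a warning if HPI never starts).
#' @export
detect_chpi_onset <- function(rec, channel = NULL, window_s = 1,
                              hp_edge = 100, peak_ratio = 50) {
  if (is.null(channel)) {
    k <- pick_channels(rec, c("MEG_MAG", "MEG_GRAD"))
    if (!length(k)) k <- pick_channels(rec)
    channel <- rec$channels$name[k[1]]
  }
  x <- rec$data[channel_index(rec, channel), ]
  w <- round(window_s * rec$sfreq)
  nw <- floor(length(x) / w)
  if (nw < 2) stop("recording shorter than two analysis windows")
  freqs <- (seq_len(w) - 1) / w * rec$sfreq
  hi_bins <- which(freqs >= hp_edge & freqs <= rec$sfreq / 2)
  active <- vapply(seq_len(nw), function(k) {
    seg <- x[((k - 1) * w + 1):(k * w)]
    p <- Mod(fft(seg - mean(seg))[hi_bins])^2
    max(p) / mean(p) > peak_ratio
  }, TRUE)
  none <- data.frame(start = numeric(), end = numeric(), label = character(),
                     stringsAsFactors = FALSE)
  if (active[1]) return(none)               # active from the first sample
  t0 <- rec$first_sample_time
  if (!any(active)) {
    warning("no cHPI activation found; flagging the whole recording")
    return(data.frame(start = t0, end = rec_span(rec)[2],
                      label = "chpi_absent_bad", stringsAsFactors = FALSE))
  }
  onset_w <- which(active)[1]
  data.frame(start = t0, end = t0 + (onset_w - 1) * w / rec$sfreq,
             label = "chpi_bad", stringsAsFactors = FALSE)
}

#' Detect band-limited artifact segments (movement / muscle)
#'
#' For each band, computes the band-limited RMS over all good channels in
#' sliding windows, robust z-scores it across windows (median/MAD), and marks
#' windows with z above `z_threshold`. The 1-7 Hz band targets body and eye
#' movements, the 40-240 Hz band muscle contraction; the upper edge is clipped
#' below Nyquist.
#'
#' @param rec a recording.
#' @param bands list of c(lo, hi) Hz.
#' @param z_threshold robust z-score criterion.
#' @param window_s sliding window, seconds; 50% overlap.
#' @return an [event_list()] of "movement_bad"/"muscle_bad" spans (adjacent
#'   flagged windows merged).
#' @export
detect_band_artifacts <- function(rec, bands = list(c(1, 7), c(40, 240)),
                                  z_threshold = 5, window_s = 1) {
  w <- round(window_s * rec$sfreq)
  if (w > ncol(rec$data)) stop("window longer than recording")
  hop <- max(1, w %/% 2)
  starts <- seq(1, ncol(rec$data) - w + 1, by = hop)
  picks <- pick_channels(rec, c("MEG_MAG", "MEG_GRAD", "EEG"))
  if (!length(picks)) picks <- pick_channels(rec)
  t <- rec_times(rec)
  out <- empty_events()
  labs <- c("movement", "muscle")
  for (bi in seq_along(bands)) {
    band <- bands[[bi]]
    band[2] <- min(band[2], 0.95 * rec$sfreq / 2)
    xb <- t(apply(rec$data[picks, , drop = FALSE], 1, bandpass_trace,
                  sfreq = rec$sfreq, band = band))
    rms <- vapply(starts, function(s)
      sqrt(mean(xb[, s:(s + w - 1)]^2)), 0)
    z <- (rms - median(rms)) / max(mad(rms), 1e-30)
    flag <- z > z_threshold
    if (any(flag)) {
      r <- rle(flag)
      ends <- cumsum(r$lengths); beg <- ends - r$lengths + 1
      lab <- paste0(if (bi <= 2) labs[bi] else paste0("band", bi), "_bad")
      for (k in which(r$values)) {
        s0 <- starts[beg[k]]; s1 <- starts[ends[k]] + w - 1
        out <- rbind(out, event_list(lab, t[s0], (s1 - s0) / rec$sfreq))
      }
    }
  }
  out <- out[order(out$onset), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("event_list", "data.frame")
  out
}
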