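# Readers/writers for the BIDS-style sidecars (channels.tsv, events.tsv) and
# the package's raw container (flat float64 matrix + JSON sidecar).

BIDS_TYPE_MAP <- c(MEGMAG = "MEG_MAG", MEGGRADPLANAR = "MEG_GRAD",
                   MEGGRADAXIAL = "MEG_GRAD", MEG_MAG = "MEG_MAG",
                   MEG_GRAD = "MEG_GRAD", EEG = "EEG", EOG = "EOG",
                   ECG = "ECG", TRIG = "STIM", STIM = "STIM",
                   NOSIG = "NOSIG", MISC = "NOSIG")

#' Read a channels.tsv sidecar
#'
#' Tab-separated with a header holding at least `name`, `type`, `units`
#' columns ("n/a" for missing). Optional columns: `status` ("good"/"bad"),
#' positions `x,y,z` and orientations `ox,oy,oz` (meters, head frame).
#' Unknown types map to NOSIG with a warning.
#'
#' @param path file path.
#' @return a [channel_info()] table.
#' @export
read_channels_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = "n/a", check.names = FALSE)
  req <- c("name", "type", "units")
  if (!all(req %in% names(df)))
    stop("channels.tsv missing required column(s): ",
         paste(setdiff(req, names(df)), collapse = ", "))
  if (nrow(df) == 0)
    return(channel_info(character(), character()))
  if (anyDuplicated(df$name))
    stop("duplicate channel names in ", path)
  kind <- unname(BIDS_TYPE_MAP[toupper(df$type)])
  unknown <- is.na(kind)
  if (any(unknown)) {
    warning("unknown channel type(s) mapped to NOSIG: ",
            paste(unique(df$type[unknown]), collapse = ", "))
    kind[unknown] <- "NOSIG"
  }
  pos <- if (all(c("x", "y", "z") %in% names(df)))
    as.matrix(df[, c("x", "y", "z")]) else NULL
  ori <- if (all(c("ox", "oy", "oz") %in% names(df)))
    as.matrix(df[, c("ox", "oy", "oz")]) else NULL
  is_bad <- if ("status" %in% names(df)) !is.na(df$status) & df$status == "bad"
  else FALSE
  units <- ifelse(is.na(df$units), "", df$units)
  channel_info(df$name, kind, units, pos, ori, is_bad)
}

#' Write a channels.tsv sidecar
#' @param channels a [channel_info()] table; @param path output path.
#' @return `path`, invisibly.
#' @export
write_channels_tsv <- function(channels, path) {
  inv <- names(BIDS_TYPE_MAP)[match(channels$kind, BIDS_TYPE_MAP)]
  df <- data.frame(name = channels$name, type = inv,
                   units = ifelse(channels$unit == "", "n/a", channels$unit),
                   status = ifelse(channels$is_bad, "bad", "good"),
                   x = channels$x, y = channels$y, z = channels$z,
                   ox = channels$ox, oy = channels$oy, oz = channels$oz,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "n/a")
  invisible(path)
}

#' Read an events.tsv sidecar
#'
#' Columns `onset`, `duration`, `trial_type` (BIDS convention; onsets in
#' seconds). Zero-duration rows become point events. Rows whose label contains
#' "bad" are returned in `$bad_segments` as well so they can be attached to a
#' recording.
#'
#' @param path file path.
#' @return list with elements `events` ([event_list()]) and `bad_segments`
#'   (data.frame start/end/label).
#' @export
read_events_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = "n/a")
  if (!all(c("onset", "duration", "trial_type") %in% names(df)))
    stop("events.tsv missing required column(s)")
  if (nrow(df) && (!is.numeric(df$onset) || anyNA(df$onset)))
    stop("non-numeric onset in ", path)
  if (nrow(df) == 0)
    return(list(events = empty_events(),
                bad_segments = data.frame(start = numeric(), end = numeric(),
                                          label = character())))
  df$duration[is.na(df$duration)] <- 0
  ev <- event_list(df$trial_type, df$onset, df$duration)
  bad <- ev[ev$is_bad & ev$duration > 0, , drop = FALSE]
  list(events = ev,
       bad_segments = data.frame(start = bad$onset,
                                 end = bad$onset + bad$duration,
                                 label = bad$label, stringsAsFactors = FALSE))
}

#' Write an events.tsv sidecar
#' @param events an [event_list()]; @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  df <- data.frame(onset = sprintf("%.9f", events$onset),
                   duration = sprintf("%.9f", events$duration),
                   trial_type = events$label, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a recording in the raw container format
#'
#' The container is a flat little-endian float64 binary matrix (`<stem>.bin`,
#' channel-major) plus a JSON sidecar (`<stem>.json`) carrying the sampling
#' rate, first-sample time, matrix shape and the channel table, plus
#' `<stem>_events.tsv` when events are present. Data round-trip bit-exactly.
#'
#' @param rec a recording; @param stem path stem (no extension).
#' @return `stem`, invisibly.
#' @export
write_raw <- function(rec, stem) {
  con <- file(paste0(stem, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 8, endian = "little")
  side <- list(format = "megevoke-raw-v1",
               sfreq = rec$sfreq,
               first_sample_time = rec$first_sample_time,
               n_channels = nrow(rec$data),
               n_samples = ncol(rec$data),
               channels = as.data.frame(unclass(rec$channels),
                                        stringsAsFactors = FALSE),
               bad_segments = rec$bad_segments,
               projectors = serialize_projectors(rec$projectors))
  jsonlite::write_json(side, paste0(stem, ".json"), digits = NA,
                       auto_unbox = TRUE, null = "null", na = "null")
  if (nrow(rec$events))
    write_events_tsv(rec$events, paste0(stem, "_events.tsv"))
  invisible(stem)
}

#' Read a recording from the raw container format
#' @param stem path stem used by [write_raw()].
#' @return a recording; metadata and data values identical to what was written.
#' @export
read_raw <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  need <- c("sfreq", "first_sample_time", "n_channels", "n_samples", "channels")
  if (!all(need %in% names(side)))
    stop("corrupted sidecar: missing field(s) ",
         paste(setdiff(need, names(side)), collapse = ", "))
  nbytes <- file.size(paste0(stem, ".bin"))
  n <- side$n_channels * side$n_samples
  if (!isTRUE(nbytes == 8 * n))
    stop("shape mismatch between sidecar and binary matrix")
  con <- file(paste0(stem, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  ch <- side$channels
  chans <- channel_info(ch$name, ch$kind, ch$unit,
                        position = cbind(ch$x, ch$y, ch$z),
                        orientation = if (all(is.na(ch$ox))) NULL else
                          cbind(ch$ox, ch$oy, ch$oz),
                        is_bad = ch$is_bad)
  ev_path <- paste0(stem, "_events.tsv")
  ev <- if (file.exists(ev_path)) read_events_tsv(ev_path)$events
  else empty_events()
  bs <- side$bad_segments
  if (is.null(bs) || length(bs) == 0 || NROW(bs) == 0)
    bs <- NULL
  else bs <- as.data.frame(bs, stringsAsFactors = FALSE)
  recording(chans, matrix(x, side$n_channels, side$n_samples),
            sfreq = side$sfreq, first_sample_time = side$first_sample_time,
            events = ev, bad_segments = bs,
            projectors = deserialize_projectors(side$projectors))
}

serialize_projectors <- function(projs) {
  lapply(projs, function(p) {
    p$vectors <- apply(p$vectors, 2, identity, simplify = FALSE)
    p
  })
}

deserialize_projectors <- function(raw) {
  if (is.null(raw) || length(raw) == 0) return(list())
  lapply(raw, function(p) {
    p$vectors <- do.call(cbind, lapply(p$vectors, unlist))
    rownames(p$vectors) <- p$channel_names
    class(p) <- "meg_projector"
    p
  })
}
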