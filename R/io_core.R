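#' Sleep-stage vocabulary shared by all modules
#'
#' AASM stage codes plus `U` for unscored epochs. Unscored epochs are excluded
#' from every downstream analysis.
#' @keywords internal
SLEEP_STAGES <- c("W", "N1", "N2", "N3", "R", "U")

#' Construct a multichannel field-potential recording
#'
#' The basic container for one night of intracranial data: a channels-by-time
#' sample matrix in microvolts plus per-channel metadata (cortex/subcortex,
#' hemisphere) and night identifiers.
#'
#' @param samples numeric matrix, channels x time, microvolts.
#' @param fs sampling rate in Hz.
#' @param channels data.frame with columns `label`, `region`
#'   (`"cortex"`/`"subcortex"`) and `hemisphere` (`"L"`/`"R"`), one row per
#'   matrix row.
#' @param night_id,participant_id identifiers carried through feature tables.
#' @param stim_state `"ON"` or `"OFF"` deep-brain stimulation.
#' @return an object of class `fp_recording`.
#' @export
new_recording <- function(samples, fs, channels, night_id = "night1",
                          participant_id = "P1", stim_state = "ON") {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1L)
  stopifnot(is.numeric(samples), fs > 0)
  channels <- as.data.frame(channels, stringsAsFactors = FALSE)
  req <- c("label", "region", "hemisphere")
  if (!all(req %in% names(channels)))
    stop("channel metadata must have label, region and hemisphere columns")
  if (nrow(channels) != nrow(samples))
    stop("one metadata row per channel required")
  if (anyDuplicated(channels$label))
    stop("channel labels must be unique within a recording")
  if (!all(channels$region %in% c("cortex", "subcortex")))
    stop("region must be 'cortex' or 'subcortex'")
  if (!all(channels$hemisphere %in% c("L", "R")))
    stop("hemisphere must be 'L' or 'R'")
  if (anyNA(samples))
    stop("samples must not contain NA; represent gaps with an explicit mask")
  if (!stim_state %in% c("ON", "OFF")) stop("stim_state must be ON or OFF")
  structure(list(samples = samples, fs = fs, channels = channels,
                 night_id = night_id, participant_id = participant_id,
                 stim_state = stim_state),
            class = "fp_recording")
}

#' @export
print.fp_recording <- function(x, ...) {
  cat(sprintf("<fp_recording> %d channels x %d samples @ %g Hz (%.1f min)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs / 60))
  cat(sprintf("  night %s / participant %s / stim %s\n",
              x$night_id, x$participant_id, x$stim_state))
  print(x$channels)
  invisible(x)
}

#' Construct a hypnogram
#'
#' 30 s sleep-stage labels (AASM codes W/N1/N2/N3/R plus U for unscored),
#' optionally with a 5 s fine re-scored track near awakenings (six fine labels
#' per 30 s epoch).
#'
#' @param stages character vector of stage codes at 30 s resolution.
#' @param fine_stages optional character vector at 5 s resolution,
#'   length `6 * length(stages)`.
#' @param epoch_len_s epoch length, fixed at 30 s by scoring convention.
#' @return an object of class `hypnogram`.
#' @export
new_hypnogram <- function(stages, fine_stages = NULL, epoch_len_s = 30) {
  stages <- as.character(stages)
  if (!all(stages %in% SLEEP_STAGES))
    stop("unknown stage code; allowed: ", paste(SLEEP_STAGES, collapse = ","))
  if (!is.null(fine_stages)) {
    fine_stages <- as.character(fine_stages)
    if (length(fine_stages) != 6L * length(stages))
      stop("fine_stages must have 6 labels per 30 s epoch")
    if (!all(fine_stages %in% SLEEP_STAGES)) stop("unknown fine stage code")
  }
  structure(list(epoch_len_s = epoch_len_s, stages = stages,
                 fine_stages = fine_stages),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$stages, levels = SLEEP_STAGES))
  cat(sprintf("<hypnogram> %d x %g s epochs (%.1f h)%s\n", length(x$stages),
              x$epoch_len_s, length(x$stages) * x$epoch_len_s / 3600,
              if (is.null(x$fine_stages)) "" else " + 5 s fine track"))
  print(tab)
  invisible(x)
}

#' Construct a tri-axial accelerometry trace
#'
#' @param xyz numeric matrix, 3 x time, in g.
#' @param fs sampling rate in Hz.
#' @param source `"implant"` (pulse-generator accelerometer) or `"headband"`.
#' @return an object of class `accel_trace`.
#' @export
new_accel <- function(xyz, fs, source = c("implant", "headband")) {
  source <- match.arg(source)
  if (!is.matrix(xyz) || nrow(xyz) != 3L) stop("xyz must be a 3 x time matrix")
  stopifnot(fs > 0)
  structure(list(xyz = xyz, fs = fs, source = source), class = "accel_trace")
}

## ---------------------------------------------------------------------------
## Epoch-grid bookkeeping

#' Non-overlapping epoch grid
#'
#' Splits `[0, total_dur_s)` into contiguous epochs of `epoch_len_s`, dropping
#' a trailing partial epoch. Each epoch is labelled by its midpoint, so the
#' epoch covering 0-5 s carries the time label 2.5 s.
#'
#' @param total_dur_s total duration in seconds.
#' @param epoch_len_s epoch length in seconds.
#' @return data.frame with columns `start_s`, `stop_s`, `t_label_s`.
#' @export
epoch_grid <- function(total_dur_s, epoch_len_s) {
  stopifnot(epoch_len_s > 0, total_dur_s >= epoch_len_s)
  n <- floor(total_dur_s / epoch_len_s)
  start <- (seq_len(n) - 1) * epoch_len_s
  data.frame(start_s = start, stop_s = start + epoch_len_s,
             t_label_s = start + epoch_len_s / 2)
}

#' Expand a hypnogram to 5 s resolution
#'
#' Returns the fine re-scored track when present (the precise awakening
#' ground truth); otherwise each 30 s label is replicated six times.
#'
#' @param h a [new_hypnogram()] object.
#' @return character vector of 5 s stage labels.
#' @export
expand_stages <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  if (!is.null(h$fine_stages)) return(h$fine_stages)
  rep(h$stages, each = 6L)
}

## ---------------------------------------------------------------------------
## EDF I/O (16-bit continuous EDF). Region/hemisphere ride in the transducer
## field as "<region> <hemisphere>".

.pad <- function(x, n) {
  x <- substr(as.character(x), 1L, n)
  formatC(x, width = n, flag = "-")
}

#' Write a recording to EDF
#'
#' Continuous 16-bit EDF with 1 s data records. Channel region and hemisphere
#' are stored in the transducer field so that [read_recording()] can rebuild
#' the metadata. Sample values are quantized to the 16-bit grid spanned by
#' each channel's physical range; the trailing partial second is dropped.
#'
#' @param rec an [new_recording()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording_edf <- function(rec, path) {
  stopifnot(inherits(rec, "fp_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires integer fs")
  fs <- as.integer(round(fs))
  ns <- nrow(rec$samples)
  n_rec <- floor(ncol(rec$samples) / fs)
  if (n_rec < 1L) stop("recording shorter than one EDF data record (1 s)")
  x <- rec$samples[, seq_len(n_rec * fs), drop = FALSE]

  pmin <- apply(x, 1, min); pmax <- apply(x, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .pad("0", 8), .pad(rec$participant_id, 80),
    .pad(paste("Startdate X", rec$night_id, "stim", rec$stim_state), 80),
    .pad("01.01.00", 8), .pad("00.00.00", 8),
    .pad(256L * (1L + ns), 8), .pad("", 44),
    .pad(n_rec, 8), .pad("1", 8), .pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(v, w) writeChar(paste(vapply(v, .pad, "", n = w),
                                        collapse = ""), con, eos = NULL)
  fld(rec$channels$label, 16)
  fld(paste(rec$channels$region, rec$channels$hemisphere), 80)
  fld(rep("uV", ns), 8)
  fld(formatC(pmin, digits = 6, format = "g"), 8)
  fld(formatC(pmax, digits = 6, format = "g"), 8)
  fld(rep(dmin, ns), 8)
  fld(rep(dmax, ns), 8)
  fld(rep("", ns), 80)
  fld(rep(fs, ns), 8)
  fld(rep("", ns), 32)

  scale <- (dmax - dmin) / (pmax - pmin)
  dig <- matrix(0L, nrow = ns, ncol = ncol(x))
  for (i in seq_len(ns)) {
    d <- round((x[i, ] - pmin[i]) * scale[i]) + dmin
    dig[i, ] <- as.integer(pmin(pmax(d, dmin), dmax))
  }
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

.read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  num <- function(s) suppressWarnings(as.numeric(trimws(s)))
  rd(8)                       # version
  pid <- trimws(rd(80)); ridf <- trimws(rd(80))
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- num(rd(8)); dur <- num(rd(8)); ns <- num(rd(4))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || is.na(dur))
    stop("malformed EDF header")
  ns <- as.integer(ns)
  fldv <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- fldv(16); transducer <- fldv(80); fldv(8)
  pmin <- num(fldv(8)); pmax <- num(fldv(8))
  dmin <- num(fldv(8)); dmax <- num(fldv(8))
  fldv(80); spr <- num(fldv(8)); fldv(32)
  if (anyNA(c(pmin, pmax, dmin, dmax, spr))) stop("malformed EDF header")
  spr <- as.integer(spr)
  if (length(unique(spr)) != 1L)
    stop("mixed per-channel sampling rates are not supported")
  total <- as.integer(n_rec) * spr[1]
  dig <- matrix(0L, nrow = ns, ncol = total)
  for (r in seq_len(as.integer(n_rec))) {
    blk <- readBin(con, "integer", n = ns * spr[1], size = 2L, signed = TRUE,
                   endian = "little")
    if (length(blk) < ns * spr[1]) stop("truncated EDF data section")
    idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    dig[, idx] <- matrix(blk, nrow = ns, byrow = TRUE)
  }
  phys <- dig
  for (i in seq_len(ns)) {
    phys[i, ] <- pmin[i] + (dig[i, ] - dmin[i]) *
      (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
  }
  list(samples = phys, fs = spr[1] / dur, labels = labels,
       transducer = transducer, patient = pid, recording_field = ridf)
}

.parse_region_hemisphere <- function(s, labels) {
  parts <- strsplit(trimws(s), "[[:space:]:|]+")
  region <- vapply(parts, function(p) if (length(p) >= 1) p[1] else "", "")
  hem <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", "")
  bad <- !(region %in% c("cortex", "subcortex")) | !(hem %in% c("L", "R"))
  if (any(bad))
    stop("metadata error: channel(s) ", paste(labels[bad], collapse = ", "),
         " lack a resolvable region/hemisphere tag")
  data.frame(label = labels, region = region, hemisphere = hem,
             stringsAsFactors = FALSE)
}

#' Read a recording from EDF or CSV
#'
#' For EDF, channel metadata come from the transducer field
#' (`"<region> <hemisphere>"`); for CSV, the file must have a header
#' `time_s,<ch>,...` where each channel column is named
#' `label:region:hemisphere`. A channel without a resolvable region or
#' hemisphere raises a metadata error.
#'
#' @param path file path.
#' @param format `"EDF"` or `"CSV"`; guessed from the extension by default.
#' @param night_id,participant_id,stim_state identifiers; for EDF,
#'   participant and night default to the header fields.
#' @return an [new_recording()] object.
#' @export
read_recording <- function(path, format = c("auto", "EDF", "CSV"),
                           night_id = NULL, participant_id = NULL,
                           stim_state = "ON") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "EDF" else "CSV"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "EDF") {
    e <- .read_edf(path)
    meta <- .parse_region_hemisphere(e$transducer, e$labels)
    if (is.null(participant_id)) participant_id <-
        if (nzchar(e$patient)) e$patient else "P1"
    if (is.null(night_id)) {
      m <- regmatches(e$recording_field,
                      regexpr("Startdate X ([^ ]+)", e$recording_field))
      night_id <- if (length(m)) sub("Startdate X ", "", m) else "night1"
    }
    st <- if (grepl("stim OFF", e$recording_field)) "OFF" else stim_state
    new_recording(e$samples, e$fs, meta, night_id = night_id,
                  participant_id = participant_id, stim_state = st)
  } else {
    d <- utils::read.csv(path, check.names = FALSE)
    if (!identical(names(d)[1], "time_s"))
      stop("format error: CSV signal files must start with a time_s column")
    if (nrow(d) < 2) stop("format error: need at least two samples")
    fs <- 1 / stats::median(diff(d$time_s))
    cn <- names(d)[-1]
    parts <- strsplit(cn, ":", fixed = TRUE)
    labels <- vapply(parts, `[`, "", 1)
    meta <- .parse_region_hemisphere(
      vapply(parts, function(p) paste(p[-1], collapse = " "), ""), labels)
    new_recording(t(as.matrix(d[, -1, drop = FALSE])), fs, meta,
                  night_id = night_id %||% "night1",
                  participant_id = participant_id %||% "P1",
                  stim_state = stim_state)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a recording as CSV
#'
#' Debug-friendly fallback format: header `time_s,label:region:hemisphere,...`.
#'
#' @inheritParams write_recording_edf
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "fp_recording"))
  d <- data.frame(time_s = (seq_len(ncol(rec$samples)) - 1) / rec$fs,
                  t(rec$samples))
  names(d)[-1] <- paste(rec$channels$label, rec$channels$region,
                        rec$channels$hemisphere, sep = ":")
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a hypnogram CSV
#'
#' Expects columns `epoch_index,stage` with contiguous zero- or one-based
#' indices. Unknown stage strings (e.g. movement-time codes) map to `U`
#' (unscored) with a warning. An optional fine-label CSV
#' (`segment_index,stage`, 5 s resolution) supplies re-scored awakenings.
#'
#' @param path hypnogram CSV path.
#' @param fine_path optional 5 s fine-label CSV path.
#' @return a [new_hypnogram()] object.
#' @export
read_hypnogram <- function(path, fine_path = NULL) {
  parse_track <- function(p, idx_col) {
    d <- utils::read.csv(p, stringsAsFactors = FALSE)
    if (!all(c(idx_col, "stage") %in% names(d)))
      stop("format error: expected columns ", idx_col, ",stage in ", p)
    idx <- d[[idx_col]]
    if (anyDuplicated(idx) || !all(diff(sort(idx)) == 1))
      stop("format error: ", idx_col, " must be contiguous and unique")
    st <- as.character(d$stage[order(idx)])
    unknown <- !(st %in% SLEEP_STAGES)
    if (any(unknown)) {
      warning(sum(unknown), " unknown stage label(s) (e.g. '",
              st[unknown][1], "') mapped to U")
      st[unknown] <- "U"
    }
    st
  }
  stages <- parse_track(path, "epoch_index")
  fine <- if (!is.null(fine_path)) parse_track(fine_path, "segment_index")
  new_hypnogram(stages, fine_stages = fine)
}

#' Write a hypnogram (and optional fine labels) as CSV
#'
#' @param h a [new_hypnogram()] object.
#' @param path output CSV (`epoch_index,stage`).
#' @param fine_path optional output CSV for the 5 s track.
#' @export
write_hypnogram <- function(h, path, fine_path = NULL) {
  stopifnot(inherits(h, "hypnogram"))
  utils::write.csv(data.frame(epoch_index = seq_along(h$stages) - 1L,
                              stage = h$stages),
                   path, row.names = FALSE, quote = FALSE)
  if (!is.null(fine_path) && !is.null(h$fine_stages))
    utils::write.csv(data.frame(segment_index = seq_along(h$fine_stages) - 1L,
                                stage = h$fine_stages),
                     fine_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
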