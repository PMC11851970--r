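# Minimal EDF (European Data Format) container support: 256-byte fixed
# header, one 256-byte signal-header block per channel, then 16-bit
# little-endian samples in 1 s data records. Enough of the format to
# round-trip scalp-EEG recordings and to read files laid out like the public
# scalp EEG archives; EDF+ embedded annotations are out of scope (seizure
# times come from the plain-text summary files instead).

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width)
}

#' Write a recording to an EDF file
#'
#' Samples are quantised to 16-bit integers against each channel's physical
#' range, the container's native resolution. Record duration is 1 s, so the
#' recording is truncated to a whole number of seconds.
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("write_edf needs an integer sampling rate")
  fs <- as.integer(round(fs))
  nrec <- floor(ncol(rec$signal) / fs)
  if (nrec < 1) stop("recording shorter than one 1 s data record")
  ns <- nrow(rec$signal)
  x <- rec$signal[, seq_len(nrec * fs), drop = FALSE]
  pmin <- apply(x, 1, min); pmax <- apply(x, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(rec$subject_id, 80),
    pad_field("Startdate 01-JAN-2000", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8),
    pad_field("", 44),
    pad_field(nrec, 8),
    pad_field(1, 8),
    pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  sighdr <- paste0(
    paste(vapply(rec$channel_labels, pad_field, "", width = 16), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field("uV", 8), ns), collapse = ""),
    paste(vapply(signif(pmin, 7), pad_field, "", width = 8), collapse = ""),
    paste(vapply(signif(pmax, 7), pad_field, "", width = 8), collapse = ""),
    paste(rep(pad_field(dmin, 8), ns), collapse = ""),
    paste(rep(pad_field(dmax, 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field(fs, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = ""))
  writeChar(sighdr, con, eos = NULL)
  pmin_r <- as.numeric(pad_field(signif(pmin, 7), 8))
  pmax_r <- as.numeric(pad_field(signif(pmax, 7), 8))
  scale <- (dmax - dmin) / (pmax_r - pmin_r)
  dig <- round((x - pmin_r) * scale) + dmin
  dig[dig < dmin] <- dmin; dig[dig > dmax] <- dmax
  storage.mode(dig) <- "integer"
  for (r in seq_len(nrec)) {
    block <- dig[, ((r - 1L) * fs + 1L):(r * fs), drop = FALSE]
    writeBin(as.integer(t(block)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

# parse an EDF file into raw header info + physical-unit signal matrix
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8); patient <- rd(80); recinfo <- rd(80)
  rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  nrec <- as.integer(rd(8)); recdur <- as.numeric(rd(8)); ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("not an EDF file: bad signal count in ", path)
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fld(16); fld(80); fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)
  seek(con, hdr_bytes)
  total <- sum(spr)
  sig <- matrix(0, ns, nrec * spr[1])
  # common case: identical samples-per-record across channels
  raw <- readBin(con, "integer", n = nrec * total, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < nrec * total) stop("EDF data truncated in ", path)
  offs <- c(0L, cumsum(spr))
  for (r in seq_len(nrec)) {
    base <- (r - 1L) * total
    for (i in seq_len(ns)) {
      idx <- base + (offs[i] + 1L):offs[i + 1L]
      sig[i, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <- raw[idx]
    }
  }
  gain <- (pmax - pmin) / (dmax - dmin)
  sig <- sig * gain + (pmin - dmin * gain)
  list(signal = sig, labels = labels, fs = spr / recdur,
       patient = patient, recinfo = recinfo, n_records = nrec)
}

#' Read an EEG recording from an EDF file
#'
#' Reads the signal at the sampling rate declared in the file header and
#' returns the channels named in `channel_selection`, in exactly that order
#' (downstream correlation-map row/column `i` therefore always corresponds to
#' `channel_selection[i]`). Duplicate labels in the file are resolved to the
#' first occurrence, with a message.
#'
#' @param path EDF file path.
#' @param channel_selection character vector of channel labels to keep, in
#'   the desired order; `NULL` keeps the file's full channel list.
#' @param expected_fs sampling rate the pipeline expects (default 256 Hz); a
#'   differing header rate triggers a warning and is recorded in the
#'   returned object's `provenance` attribute.
#' @param subject_id subject identifier; defaults to the EDF patient field.
#' @param annotations optional annotation data frame (see
#'   [read_annotations()]).
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, channel_selection = NULL, expected_fs = 256,
                           subject_id = NULL, annotations = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  edf <- read_edf(path)
  labels <- edf$labels
  if (is.null(channel_selection)) channel_selection <- unique(labels)
  idx <- match(channel_selection, labels)   # first occurrence wins
  if (anyNA(idx)) {
    missing <- channel_selection[is.na(idx)]
    stop("channel label(s) not present in ", basename(path), ": ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(labels[labels %in% channel_selection]))
    message("duplicate channel labels in ", basename(path),
            "; first occurrence used")
  fs <- edf$fs[idx[1]]
  prov <- list(path = path, header_fs = fs)
  if (!is.null(expected_fs) && abs(fs - expected_fs) > 1e-9) {
    warning("sampling rate in ", basename(path), " is ", fs,
            " Hz, expected ", expected_fs, " Hz")
    prov$fs_mismatch <- TRUE
  }
  rec <- eeg_recording(edf$signal[idx, , drop = FALSE], fs,
                       channel_labels = channel_selection,
                       annotations = annotations,
                       subject_id = subject_id %||% edf$patient)
  attr(rec, "provenance") <- prov
  rec
}

#' Read seizure annotations from a plain-text summary file
#'
#' Parses the summary dialect used alongside scalp-EEG EDF archives: blocks of
#' `File Name: <name>`, `Number of Seizures in File: <n>`, followed by
#' `Seizure Start Time: <s> seconds` / `Seizure End Time: <s> seconds` pairs
#' (with or without a seizure index between "Seizure" and "Start"/"End").
#'
#' @param summary_path path to the summary text file.
#' @param recording_name EDF file name whose seizures to return.
#' @return data frame with columns `start_s`, `end_s`, sorted ascending by
#'   start; zero rows when the file declares no seizures.
#' @export
read_annotations <- function(summary_path, recording_name) {
  if (!file.exists(summary_path)) stop("file not found: ", summary_path)
  lines <- readLines(summary_path, warn = FALSE)
  starts <- grep("^\\s*File Name\\s*:", lines)
  if (!length(starts)) stop("no 'File Name:' entries in ", summary_path)
  names_in_file <- trimws(sub("^\\s*File Name\\s*:", "", lines[starts]))
  hit <- which(names_in_file == recording_name)
  if (!length(hit)) stop("recording '", recording_name, "' not listed in ",
                         summary_path)
  block <- lines[starts[hit[1]]:(if (hit[1] < length(starts))
    starts[hit[1] + 1] - 1 else length(lines))]
  n_line <- grep("Number of Seizures in File\\s*:", block, value = TRUE)
  if (!length(n_line)) stop("no seizure count for '", recording_name, "'")
  n_seiz <- as.integer(sub(".*:\\s*", "", n_line[1]))
  get_times <- function(kind) {
    ln <- grep(paste0("^\\s*Seizure\\s*[0-9]*\\s*", kind, "\\s*Time\\s*:"),
               block, value = TRUE)
    as.numeric(sub("seconds?\\s*$", "", sub(".*:\\s*", "", ln)))
  }
  st <- get_times("Start"); en <- get_times("End")
  if (n_seiz > 0 && (length(st) != n_seiz || length(en) != n_seiz ||
                     anyNA(st) || anyNA(en)))
    stop("summary declares ", n_seiz, " seizure(s) for '", recording_name,
         "' but start/end times are missing or malformed")
  if (n_seiz == 0) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  o <- order(st)
  data.frame(start_s = st[o], end_s = en[o])
}

#' Write a seizure summary file for synthetic recordings
#'
#' Emits the same plain-text dialect that [read_annotations()] parses, so
#' synthetic EDF exports exercise the real parser.
#'
#' @param entries named list: `entries[[edf_name]]` is a data frame with
#'   `start_s`, `end_s` columns (possibly empty).
#' @param path output path.
#' @param fs sampling rate noted in the file header line.
#' @return `path`, invisibly.
#' @export
write_chbmit_summary <- function(entries, path, fs = 256) {
  out <- c(sprintf("Data Sampling Rate: %g Hz", fs), "")
  for (nm in names(entries)) {
    ann <- entries[[nm]]
    out <- c(out, sprintf("File Name: %s", nm),
             sprintf("Number of Seizures in File: %d", NROW(ann)))
    if (NROW(ann)) {
      for (i in seq_len(nrow(ann))) {
        out <- c(out,
                 sprintf("Seizure %d Start Time: %g seconds", i, ann$start_s[i]),
                 sprintf("Seizure %d End Time: %g seconds", i, ann$end_s[i]))
      }
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}
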