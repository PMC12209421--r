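# File input/output: EDF / BDF readers, the epoched container, event tables
# and plain-text configuration.
#
# The EDF reader follows the published European Data Format layout: a 256-byte
# ASCII header, 256 ASCII bytes per signal, then data records of 16-bit
# little-endian integers scaled channel-wise to physical units.  BDF (the
# BioSemi variant) is identical except for the leading 0xFF "BIOSEMI" magic
# and 24-bit samples.

.read_ascii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

.parse_edf_header <- function(con, bdf) {
  if (bdf) {
    magic <- readBin(con, "raw", 8)
    if (magic[1] != as.raw(255) ||
        rawToChar(magic[2:8]) != "BIOSEMI")
      stop("not a BDF file (bad magic)", call. = FALSE)
  } else {
    ver <- .read_ascii(con, 8)
    if (ver != "0") stop("not an EDF file (bad version field)", call. = FALSE)
  }
  invisible(.read_ascii(con, 80))   # patient id
  invisible(.read_ascii(con, 80))   # recording id
  invisible(.read_ascii(con, 8))    # start date
  invisible(.read_ascii(con, 8))    # start time
  invisible(.read_ascii(con, 8))    # header size
  invisible(.read_ascii(con, 44))   # reserved
  n_rec <- as.integer(.read_ascii(con, 8))
  rec_dur <- as.numeric(.read_ascii(con, 8))
  ns <- as.integer(.read_ascii(con, 4))
  if (is.na(ns) || ns < 1) stop("corrupt header: bad signal count",
                                call. = FALSE)
  fld <- function(w) vapply(seq_len(ns), function(i) .read_ascii(con, w), "")
  labels <- fld(16)
  invisible(fld(80))                # transducer
  invisible(fld(8))                 # physical dimension
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  invisible(fld(80))                # prefilter
  spr <- as.integer(fld(8))         # samples per record
  invisible(fld(32))                # reserved
  list(n_rec = n_rec, rec_dur = rec_dur, ns = ns, labels = labels,
       pmin = pmin, pmax = pmax, dmin = dmin, dmax = dmax, spr = spr)
}

.read_int24 <- function(con, n) {
  raw <- readBin(con, "raw", 3 * n)
  if (length(raw) < 3 * n) stop("truncated BDF data record", call. = FALSE)
  b <- matrix(as.integer(raw), nrow = 3)
  v <- b[1, ] + 256L * b[2, ] + 65536L * b[3, ]
  ifelse(v >= 8388608, v - 16777216, v)
}

.read_edf_like <- function(path, bdf) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- tryCatch(.parse_edf_header(con, bdf),
                error = function(e) stop("cannot parse ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  if (any(h$spr <= 0) || length(unique(h$spr)) != 1)
    stop("only uniform sampling rates across signals are supported",
         call. = FALSE)
  spr <- h$spr[1]
  fs <- spr / h$rec_dur
  dat <- matrix(0, h$ns, h$n_rec * spr)
  for (r in seq_len(h$n_rec)) {
    for (s in seq_len(h$ns)) {
      v <- if (bdf) .read_int24(con, spr)
           else readBin(con, "integer", spr, size = 2, endian = "little")
      if (length(v) < spr) stop("truncated data record ", r, call. = FALSE)
      dat[s, ((r - 1) * spr + 1):(r * spr)] <- v
    }
  }
  scale <- (h$pmax - h$pmin) / (h$dmax - h$dmin)
  for (s in seq_len(h$ns))
    dat[s, ] <- (dat[s, ] - h$dmin[s]) * scale[s] + h$pmin[s]
  list(samples = dat, fs = fs, labels = h$labels)
}

#' Read a raw EEG recording
#'
#' Reads BDF (BioSemi 24-bit), EDF, or the package's own serialized container.
#' Event onsets for EDF/BDF come from an accompanying tab-separated file with
#' columns `onset_s` and `label` (default: same path with extension
#' `.events.tsv`); montage positions are attached from the bundled idealized
#' layouts when the file carries none.
#'
#' @param path file path.
#' @param format one of `"bdf"`, `"edf"`, `"container"`; default guesses from
#'   the extension.
#' @param events_path optional explicit path to the events TSV.
#' @return An [eeg_recording()] (or the stored [trial_set()] for containers
#'   that hold epoched data).
#' @export
read_raw <- function(path, format = c("auto", "bdf", "edf", "container"),
                     events_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bdf = "bdf", edf = "edf", "container")
  }
  if (format == "container") {
    obj <- readRDS(path)
    if (!identical(obj$container, "fingerbci-v1"))
      stop("not a fingerbci container: ", path, call. = FALSE)
    return(obj$payload)
  }
  if (file.size(path) < 256) stop("unreadable/truncated file: ", path,
                                  call. = FALSE)
  raw <- .read_edf_like(path, bdf = (format == "bdf"))
  if (nrow(raw$samples) < 2) stop("need at least 2 channels", call. = FALSE)
  events <- NULL
  if (is.null(events_path))
    events_path <- paste0(tools::file_path_sans_ext(path), ".events.tsv")
  if (file.exists(events_path)) events <- read_events(events_path)
  eeg_recording(raw$samples, raw$fs, raw$labels,
                positions = montage_positions(raw$labels), events = events)
}

#' Read an events table
#'
#' Tab-separated file with columns `onset_s` (seconds) and `label`.
#'
#' @param path file path.
#' @return tibble with `onset_s`, `label`.
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("onset_s", "label") %in% names(df)))
    stop("events file needs columns onset_s and label", call. = FALSE)
  tibble::tibble(onset_s = as.numeric(df$onset_s),
                 label = as.character(df$label))
}

#' Write the single-file session container
#'
#' Stores a continuous recording or an epoched trial set in a versioned
#' single-file container holding the datasets data, labels/events, fs, t0,
#' channels and positions as float64.  [read_raw()] with
#' `format = "container"` restores the object bit-exactly.
#'
#' @param x an [eeg_recording()] or [trial_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_container <- function(x, path) {
  stopifnot(inherits(x, "eeg_recording") || inherits(x, "trial_set"))
  saveRDS(list(container = "fingerbci-v1", payload = x), path)
  invisible(path)
}

#' Read a plain-text configuration file
#'
#' YAML file whose top-level keys select the component (`synth`, `protocol`,
#' `train`, `preprocess`); each section is passed as arguments to the matching
#' constructor ([synth_config()], [online_protocol()], [train_config()]).
#'
#' @param path YAML file path.
#' @return named list of sections.
#' @export
read_config <- function(path) yaml::read_yaml(path)
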