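#' Construct a multichannel recording
#'
#' @param samples Numeric matrix, channels x time, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_ids Character vector of unique site identifiers, one per row.
#' @param block_id Label of the task block.
#' @return A list of class `hg_recording`.
#' @export
recording <- function(samples, fs, channel_ids, block_id = "block1") {
  samples <- as.matrix(samples)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a single positive number")
  channel_ids <- as.character(channel_ids)
  if (anyDuplicated(channel_ids))
    stop("duplicate channel labels: ",
         paste(unique(channel_ids[duplicated(channel_ids)]), collapse = ", "))
  if (length(channel_ids) != nrow(samples))
    stop("number of channel_ids (", length(channel_ids),
         ") does not match number of sample rows (", nrow(samples), ")")
  structure(list(samples = samples, fs = fs, channel_ids = channel_ids,
                 block_id = block_id), class = "hg_recording")
}

#' @export
print.hg_recording <- function(x, ...) {
  cat(sprintf("<hg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s), block %s\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs, x$block_id))
  invisible(x)
}

#' Read a continuous recording
#'
#' Two dialects are supported. `"raw_binary"` is a float32 little-endian
#' matrix stored channel after channel, with a JSON sidecar (same path with
#' extension `.json`) declaring `fs`, `channels` and `units`. `"edf"` is the
#' European Data Format (16-bit); values are converted to microvolts using
#' each signal's physical dimension field (`uV`, `mV` or `V`).
#'
#' @param path File path (`.bin`/`.dat` with `.json` sidecar, or `.edf`).
#' @param dialect `"auto"` (by extension), `"raw_binary"` or `"edf"`.
#' @param block_id Block label to attach.
#' @return An `hg_recording` with values in microvolts.
#' @export
read_recording <- function(path, dialect = c("auto", "raw_binary", "edf"),
                           block_id = "block1") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "raw_binary"
  if (dialect == "edf") return(read_edf(path, block_id = block_id))

  sidecar <- paste0(sub("\\.[^.]+$", "", path), ".json")
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar)
  hdr <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(hdr$fs)) stop("format error: sidecar declares no fs")
  if (is.null(hdr$channels) || length(hdr$channels) == 0)
    stop("format error: sidecar declares no channel labels")
  chans <- as.character(hdr$channels)
  if (anyDuplicated(chans))
    stop("format error: duplicate channel labels in sidecar")
  n_bytes <- file.info(path)$size
  n_vals <- n_bytes / 4
  if (n_vals %% length(chans) != 0)
    stop("format error: file size not divisible by channel count")
  vals <- readBin(path, what = "numeric", n = n_vals, size = 4,
                  endian = "little")
  scale <- switch(tolower(hdr$units %||% "uV"),
                  "uv" = 1, "mv" = 1e3, "v" = 1e6,
                  stop("unsupported units: ", hdr$units))
  samples <- matrix(vals * scale, nrow = length(chans), byrow = TRUE)
  recording(samples, hdr$fs, chans, block_id = block_id)
}

#' Write a recording in the raw binary + JSON dialect
#'
#' @param rec An `hg_recording`.
#' @param path Output `.bin` path; a `.json` sidecar is written alongside.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "hg_recording"))
  sidecar <- paste0(sub("\\.[^.]+$", "", path), ".json")
  writeBin(as.numeric(t(rec$samples)), path, size = 4, endian = "little")
  jsonlite::write_json(list(fs = rec$fs, channels = rec$channel_ids,
                            units = "uV", block_id = rec$block_id),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

edf_pad <- function(x, width) substr(formatC(as.character(x), width = width,
                                             flag = "-"), 1, width)

# format a number to fit an 8-character ascii EDF field
edf_num8 <- function(x) {
  vapply(x, function(v) {
    for (d in 7:1) {
      s <- formatC(v, format = "g", digits = d)
      if (nchar(s) <= 8) return(s)
    }
    "0"
  }, "")
}

#' Write a recording as EDF
#'
#' Minimal continuous EDF writer: 16-bit samples, physical dimension `uV`,
#' per-channel physical range taken from the data. If the signal length is a
#' whole number of seconds, 1-second data records are used; otherwise the
#' whole signal is stored as a single record. Amplitudes are quantised to the
#' 16-bit range, the documented lossiness of this dialect.
#'
#' @param rec An `hg_recording`.
#' @param path Output `.edf` path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "hg_recording"))
  ns <- nrow(rec$samples)
  n <- ncol(rec$samples)
  if (n %% rec$fs == 0 && n > rec$fs) {
    rec_dur <- 1
    spr <- as.integer(rec$fs)
    n_rec <- n / rec$fs
  } else {
    rec_dur <- n / rec$fs
    spr <- n
    n_rec <- 1
  }
  pmin_ <- apply(rec$samples, 1, min)
  pmax_ <- apply(rec$samples, 1, max)
  flat <- pmax_ <= pmin_
  pmax_[flat] <- pmin_[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(edf_pad("0", 8),
                edf_pad("X", 80), edf_pad("X", 80),
                edf_pad("01.01.26", 8), edf_pad("00.00.00", 8),
                edf_pad(256 * (ns + 1), 8), edf_pad("", 44),
                edf_pad(n_rec, 8),
                edf_pad(edf_num8(rec_dur), 8),
                edf_pad(ns, 4))
  sig <- paste0(paste(edf_pad(substr(rec$channel_ids, 1, 16), 16), collapse = ""),
                paste(rep(edf_pad("", 80), ns), collapse = ""),
                paste(rep(edf_pad("uV", 8), ns), collapse = ""),
                paste(edf_pad(edf_num8(pmin_), 8), collapse = ""),
                paste(edf_pad(edf_num8(pmax_), 8), collapse = ""),
                paste(rep(edf_pad(-32768, 8), ns), collapse = ""),
                paste(rep(edf_pad(32767, 8), ns), collapse = ""),
                paste(rep(edf_pad("", 80), ns), collapse = ""),
                paste(rep(edf_pad(spr, 8), ns), collapse = ""),
                paste(rep(edf_pad("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL)
  # header physical min/max as re-parsed by a reader (limited ascii precision)
  pmin_r <- as.numeric(edf_num8(pmin_))
  pmax_r <- as.numeric(edf_num8(pmax_))
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- round((rec$samples[ch, idx] - pmin_r[ch]) /
                     (pmax_r[ch] - pmin_r[ch]) * 65535 - 32768)
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path, block_id = "block1") {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) trimws(readChar(con, nchars, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("format error: bad EDF signal count")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  if (anyDuplicated(labels)) stop("format error: duplicate channel labels")
  for (i in seq_len(ns)) rd(80)                       # transducer
  dims <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)                       # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (is.na(rec_dur) || rec_dur <= 0) stop("format error: fs absent in EDF")
  scale <- vapply(dims, function(d) switch(tolower(d), "uv" = 1, "mv" = 1e3,
                                           "v" = 1e6, 1), 0)
  out <- matrix(0, nrow = ns, ncol = spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      phys <- pmin_[ch] + (dig - dmin_[ch]) / (dmax_[ch] - dmin_[ch]) *
        (pmax_[ch] - pmin_[ch])
      out[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <- phys * scale[ch]
    }
  }
  recording(out, spr[1] / rec_dur, labels, block_id = block_id)
}
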