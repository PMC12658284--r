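#' Multichannel EEG recording
#'
#' @param signal Numeric matrix, samples x channels (microvolts), column
#'   names matching the montage labels.
#' @param fs Sampling rate (Hz).
#' @param m A `montage` describing the channels.
#' @return Object of class `eeg_recording` with fields `signal`, `fs`,
#'   `montage`, `duration_s`.
#' @export
eeg_recording <- function(signal, fs, m = montage()) {
  signal <- as.matrix(signal)
  if (ncol(signal) != length(m$labels))
    stop("signal must have one column per montage channel", call. = FALSE)
  if (is.null(colnames(signal))) colnames(signal) <- m$labels
  if (!identical(colnames(signal), m$labels)) {
    if (!setequal(colnames(signal), m$labels))
      stop("signal column names do not match the montage", call. = FALSE)
    signal <- signal[, m$labels, drop = FALSE]
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar", call. = FALSE)
  structure(list(signal = signal, fs = fs, montage = m,
                 duration_s = nrow(signal) / fs),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples, %g Hz, %.1f s\n",
              ncol(x$signal), nrow(x$signal), x$fs, x$duration_s))
  invisible(x)
}

pad16 <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording as EDF
#'
#' Minimal EDF writer: 16-bit samples, physical dimension microvolts,
#' 1-s data records. The recording must span a whole number of seconds and
#' have an integer sampling rate (EDF stores one record per second).
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate", call. = FALSE)
  n <- nrow(rec$signal)
  if (n %% fs != 0)
    stop("EDF writer requires a whole number of 1-s records (n = ", n,
         " samples at fs = ", fs, ")", call. = FALSE)
  n_rec <- n %/% fs
  nc <- ncol(rec$signal)

  pmin_ <- pmax_ <- numeric(nc)
  dig <- matrix(0L, n, nc)
  for (k in seq_len(nc)) {
    # physical range rounded to 4 significant digits so the 8-char ASCII
    # header field holds it exactly; encode with the same affine map the
    # reader inverts, keeping round-trip error at the 16-bit half-step
    r <- signif(max(abs(rec$signal[, k]), 1e-6) * 1.001, 4)
    pmin_[k] <- -r; pmax_[k] <- r
    step <- 2 * r / 65535
    dig[, k] <- as.integer(round((rec$signal[, k] + r) / step) - 32768L)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad16("0", 8), pad16("X", 80), pad16("ictalsync", 80),
    pad16("01.01.00", 8), pad16("00.00.00", 8),
    pad16(256 * (1 + nc), 8), pad16("", 44),
    pad16(n_rec, 8), pad16("1", 8), pad16(nc, 4))
  fld <- function(vals, w) paste(vapply(vals, pad16, "", width = w), collapse = "")
  sig_hdr <- paste0(
    fld(paste0("EEG ", rec$montage$labels, "-Ref"), 16),
    fld(rep("AgAgCl cup electrode", nc), 80),
    fld(rep("uV", nc), 8),
    fld(formatC(pmin_, digits = 6, format = "g"), 8),
    fld(formatC(pmax_, digits = 6, format = "g"), 8),
    fld(rep("-32768", nc), 8), fld(rep("32767", nc), 8),
    fld(rep("HP:0.5Hz LP:70Hz N:50Hz", nc), 80),
    fld(rep(fs, nc), 8), fld(rep("", nc), 32))
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL, useBytes = TRUE)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(as.vector(dig[rows, ])), con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf_header <- function(con) {
  chr <- function(nbytes) {
    raw <- readBin(con, "raw", nbytes)
    if (length(raw) < nbytes) stop("EDF header truncated", call. = FALSE)
    trimws(rawToChar(raw))
  }
  version <- chr(8)
  if (version != "0") stop("not an EDF file (bad version field)", call. = FALSE)
  chr(80); chr(80); chr(8); chr(8)
  header_bytes <- as.integer(chr(8)); chr(44)
  n_rec <- as.integer(chr(8))
  rec_dur <- as.numeric(chr(8))
  nc <- as.integer(chr(4))
  if (any(is.na(c(header_bytes, n_rec, rec_dur, nc))) || nc < 1L)
    stop("unreadable EDF header", call. = FALSE)
  per <- function(w) vapply(seq_len(nc), function(i) chr(w), "")
  labels <- per(16); per(80)
  dim_ <- per(8)
  pmin_ <- as.numeric(per(8)); pmax_ <- as.numeric(per(8))
  dmin_ <- as.numeric(per(8)); dmax_ <- as.numeric(per(8))
  per(80)
  spr <- as.integer(per(8)); per(32)
  list(n_rec = n_rec, rec_dur = rec_dur, nc = nc, labels = labels, dim = dim_,
       pmin = pmin_, pmax = pmax_, dmin = dmin_, dmax = dmax_, spr = spr)
}

#' Read an EDF recording
#'
#' Reads an EDF/EDF+ file, locates the eight montage channels by normalized
#' label (tolerant of "EEG Fp1-Ref"-style decoration, case-insensitive) and
#' returns them in canonical montage order with the sampling rate taken
#' from the header.
#'
#' @param path EDF file path.
#' @param m Target `montage`.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, m = montage()) {
  if (!file.exists(path)) stop("EDF file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  canon <- normalize_channel_label(h$labels, m$labels)
  sel <- match(m$labels, canon)
  if (anyNA(sel)) {
    missing <- m$labels[is.na(sel)]
    stop("channel ", paste(missing, collapse = ", "), " not found in ", path,
         call. = FALSE)
  }
  if (length(unique(h$spr[sel])) != 1L)
    stop("montage channels disagree on samples per record", call. = FALSE)
  spr <- h$spr[sel][1L]
  fs <- spr / h$rec_dur
  per_rec <- sum(h$spr)
  sig <- matrix(0, h$n_rec * spr, length(sel))
  offs <- c(0L, cumsum(h$spr))
  for (r in seq_len(h$n_rec)) {
    rec <- readBin(con, "integer", per_rec, size = 2L, signed = TRUE,
                   endian = "little")
    if (length(rec) < per_rec) stop("EDF data truncated at record ", r, call. = FALSE)
    for (k in seq_along(sel)) {
      ch <- sel[k]
      sig[((r - 1L) * spr + 1L):(r * spr), k] <-
        rec[(offs[ch] + 1L):(offs[ch] + h$spr[ch])]
    }
  }
  # digital -> physical
  for (k in seq_along(sel)) {
    ch <- sel[k]
    scale <- (h$pmax[ch] - h$pmin[ch]) / (h$dmax[ch] - h$dmin[ch])
    sig[, k] <- (sig[, k] - h$dmin[ch]) * scale + h$pmin[ch]
  }
  colnames(sig) <- m$labels
  eeg_recording(sig, fs, m)
}
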