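# WFDB (PhysioNet) record / annotation I/O.
#
# No WFDB reader exists on CRAN/Bioconductor, so the subset of the format
# needed for single-lead beat detection is implemented here: headers (.hea),
# signal files (.dat) in formats 16 and 212, and MIT-format annotation files.
# Amplitudes are converted to physical units (mV) at load via the header's
# gain/baseline; all indices are 0-based as in WFDB itself.

# Annotation type codes from the WFDB library's ecgcodes.h.
WFDB_CODES <- c(
  "N" = 1L, "L" = 2L, "R" = 3L, "a" = 4L, "V" = 5L, "F" = 6L, "J" = 7L,
  "A" = 8L, "S" = 9L, "E" = 10L, "j" = 11L, "/" = 12L, "Q" = 13L, "~" = 14L,
  "|" = 16L, "s" = 18L, "T" = 19L, "*" = 20L, "D" = 21L, "\"" = 22L,
  "=" = 23L, "p" = 24L, "B" = 25L, "^" = 26L, "t" = 27L, "+" = 28L,
  "u" = 29L, "?" = 30L, "!" = 31L, "[" = 32L, "]" = 33L, "e" = 34L,
  "n" = 35L, "@" = 36L, "x" = 37L, "f" = 38L, "(" = 39L, ")" = 40L,
  "r" = 41L
)

#' Standard beat annotation symbols
#'
#' The AAMI beat classes used by default when reading reference annotations:
#' every symbol that marks a QRS complex, excluding rhythm, noise and other
#' non-beat annotations.
#' @return character vector of annotation symbols.
#' @export
wfdb_beat_symbols <- function() {
  c("N", "L", "R", "B", "A", "a", "J", "S", "V", "r",
    "F", "e", "j", "n", "E", "f", "Q", "?")
}

parse_hea <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty WFDB header: ", hea_path, call. = FALSE)
  top <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  rec_name <- sub("/.*$", "", top[[1]])
  nsig <- as.integer(top[[2]])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*$", "", top[[3]])) else 250
  nsamp <- if (length(top) >= 4) as.numeric(top[[4]]) else NA_real_
  if (length(lines) < 1 + nsig)
    stop("WFDB header lists ", nsig, " signals but has too few lines",
         call. = FALSE)
  sig <- lapply(seq_len(nsig), function(i) {
    tok <- strsplit(trimws(lines[[1 + i]]), "\\s+")[[1]]
    fmt <- as.integer(sub("[x:+].*$", "", tok[[2]]))
    gain_tok <- if (length(tok) >= 3) tok[[3]] else "200"
    units <- if (grepl("/", gain_tok)) sub("^.*/", "", gain_tok) else "mV"
    gain_tok <- sub("/.*$", "", gain_tok)
    baseline <- if (grepl("\\(", gain_tok))
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_tok)) else NA_real_
    gain <- as.numeric(sub("\\(.*$", "", gain_tok))
    if (is.na(gain) || gain == 0) gain <- 200
    adc_zero <- if (length(tok) >= 5) as.numeric(tok[[5]]) else 0
    if (is.na(baseline)) baseline <- adc_zero
    desc <- if (length(tok) >= 9) paste(tok[9:length(tok)], collapse = " ")
            else NA_character_
    list(file = tok[[1]], fmt = fmt, gain = gain, baseline = baseline,
         units = units, desc = desc)
  })
  list(record = rec_name, nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

read_dat_16 <- function(path, nsig) {
  sz <- file.info(path)$size
  con <- file(path, "rb"); on.exit(close(con))
  v <- readBin(con, "integer", n = sz %/% 2L, size = 2L,
               signed = TRUE, endian = "little")
  nf <- length(v) %/% nsig
  matrix(v[seq_len(nf * nsig)], ncol = nsig, byrow = TRUE)
}

read_dat_212 <- function(path, nsig) {
  sz <- file.info(path)$size
  con <- file(path, "rb"); on.exit(close(con))
  raw <- readBin(con, "raw", n = sz)
  ntrip <- length(raw) %/% 3L
  b <- matrix(as.integer(raw[seq_len(ntrip * 3L)]), ncol = 3L, byrow = TRUE)
  s1 <- b[, 1L] + bitwAnd(b[, 2L], 15L) * 256L
  s2 <- b[, 3L] + bitwAnd(bitwShiftR(b[, 2L], 4L), 15L) * 256L
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  flat <- as.vector(rbind(s1, s2))
  nf <- length(flat) %/% nsig
  matrix(flat[seq_len(nf * nsig)], ncol = nsig, byrow = TRUE)
}

#' Read a WFDB record
#'
#' Reads one channel of a PhysioNet WFDB record (header + signal file,
#' formats 16 and 212) and converts it to physical units (mV) using the
#' header gain and baseline.
#'
#' @param record_path path to the record without extension (e.g.
#'   `"data/100"` for `100.hea` / `100.dat`).
#' @param channel 0-based signal channel to extract (default 0, usually the
#'   modified limb lead II in MIT-BIH records).
#' @return An [ecg_signal] with `fs` taken from the header.
#' @export
read_wfdb <- function(record_path, channel = 0L) {
  hea_path <- paste0(record_path, ".hea")
  if (!file.exists(hea_path))
    stop("WFDB header not found: ", hea_path, call. = FALSE)
  hdr <- parse_hea(hea_path)
  channel <- as.integer(channel)
  if (channel < 0L || channel >= hdr$nsig)
    stop("channel ", channel, " out of range for a ", hdr$nsig,
         "-channel record", call. = FALSE)
  sig <- hdr$signals[[channel + 1L]]
  dat_path <- file.path(dirname(record_path), sig$file)
  if (!file.exists(dat_path))
    stop("WFDB signal file not found: ", dat_path, call. = FALSE)
  files <- vapply(hdr$signals, `[[`, "", "file")
  if (!all(files == files[[1L]]))
    stop("multi-file WFDB records are not supported", call. = FALSE)
  adc <- switch(as.character(sig$fmt),
    "16"  = read_dat_16(dat_path, hdr$nsig),
    "212" = read_dat_212(dat_path, hdr$nsig),
    stop("unsupported WFDB format ", sig$fmt, call. = FALSE))
  x <- (adc[, channel + 1L] - sig$baseline) / sig$gain
  if (!is.na(hdr$nsamp) && hdr$nsamp > 0 && hdr$nsamp <= length(x))
    x <- x[seq_len(hdr$nsamp)]
  ecg_signal(x, fs = hdr$fs, lead_name = sig$desc)
}

#' Write a WFDB record (format 16)
#'
#' Writes one or more signals as a WFDB record; used mainly to build test
#' fixtures and to export synthetic records in a form WFDB tools understand.
#'
#' @param signals an [ecg_signal] or list of them (shared `fs`).
#' @param record_path output path without extension.
#' @param gain ADC units per mV (default 200).
#' @param adc_zero ADC value corresponding to 0 mV (default 0).
#' @return `record_path`, invisibly.
#' @export
write_wfdb <- function(signals, record_path, gain = 200, adc_zero = 0L) {
  if (inherits(signals, "ecg_signal")) signals <- list(signals)
  fs <- signals[[1L]]$fs
  if (!all(vapply(signals, function(s) identical(s$fs, fs), logical(1))))
    stop("all signals must share one sampling rate", call. = FALSE)
  n <- unique(vapply(signals, function(s) length(s$samples), numeric(1)))
  if (length(n) != 1L) stop("all signals must have equal length", call. = FALSE)
  rec <- basename(record_path)
  adc <- vapply(signals, function(s) {
    v <- round(s$samples * gain) + adc_zero
    pmin(pmax(v, -32768), 32767)
  }, numeric(n))
  adc <- matrix(as.integer(adc), ncol = length(signals))
  con <- file(paste0(record_path, ".dat"), "wb")
  writeBin(as.integer(t(adc)), con, size = 2L, endian = "little")
  close(con)
  hea <- c(
    sprintf("%s %d %g %d", rec, length(signals), fs, n),
    vapply(seq_along(signals), function(i) {
      lead <- signals[[i]]$lead_name
      sprintf("%s.dat 16 %g(%d)/mV 16 %d %d 0 0 %s",
              rec, gain, as.integer(adc_zero), as.integer(adc_zero),
              adc[1L, i], if (is.null(lead)) paste0("ch", i - 1L) else lead)
    }, character(1))
  )
  writeLines(hea, paste0(record_path, ".hea"))
  invisible(record_path)
}

#' Read WFDB beat annotations
#'
#' Reads an MIT-format annotation file and keeps only annotations whose
#' symbol is in `beat_symbols` (by default the standard beat classes, so
#' rhythm changes, noise markers and other non-beat annotations are
#' dropped). Indices are 0-based and returned strictly increasing.
#'
#' @param annotation_path path to the annotation file (e.g. `"100.atr"`).
#' @param beat_symbols character vector of annotation symbols to keep.
#' @return A [beat_annotations] object.
#' @export
read_annotations <- function(annotation_path,
                             beat_symbols = wfdb_beat_symbols()) {
  if (!file.exists(annotation_path))
    stop("annotation file not found: ", annotation_path, call. = FALSE)
  sz <- file.info(annotation_path)$size
  con <- file(annotation_path, "rb"); on.exit(close(con))
  w <- readBin(con, "integer", n = sz %/% 2L, size = 2L,
               signed = FALSE, endian = "little")
  code_of <- bitwShiftR(w, 10L)
  dt_of <- bitwAnd(w, 1023L)
  t <- 0; i <- 1L
  times <- integer(0); codes <- integer(0)
  while (i <= length(w)) {
    code <- code_of[[i]]; dt <- dt_of[[i]]
    if (code == 0L && dt == 0L) break               # EOF
    if (code == 59L) {                              # SKIP: 4-byte interval
      if (i + 2L > length(w)) break
      t <- t + dt_of[[i]] + w[[i + 1L]] * 65536 + w[[i + 2L]]
      i <- i + 3L
    } else if (code %in% c(60L, 61L, 62L)) {        # NUM / SUB / CHN
      i <- i + 1L
    } else if (code == 63L) {                       # AUX string
      i <- i + 1L + ((dt + 1L) %/% 2L)
    } else {
      t <- t + dt
      times <- c(times, t); codes <- c(codes, code)
      i <- i + 1L
    }
  }
  sym <- names(WFDB_CODES)[match(codes, WFDB_CODES)]
  sym[is.na(sym)] <- "?"
  keep <- sym %in% beat_symbols
  beat_annotations(times[keep], labels = sym[keep])
}

#' Write WFDB beat annotations (MIT format)
#'
#' Counterpart of [read_annotations()]; used for fixtures and to export
#' detections in a form `bxb`-style tools accept.
#'
#' @param annotations a [beat_annotations] object (or 0-based index vector).
#' @param annotation_path output file path.
#' @param default_symbol symbol for beats without labels (default `"N"`).
#' @return `annotation_path`, invisibly.
#' @export
write_annotations <- function(annotations, annotation_path,
                              default_symbol = "N") {
  idx <- beat_indices(annotations)
  labels <- if (inherits(annotations, "beat_annotations") &&
                !is.null(annotations$labels)) annotations$labels
            else rep(default_symbol, length(idx))
  codes <- WFDB_CODES[labels]
  codes[is.na(codes)] <- WFDB_CODES[["Q"]]
  words <- integer(0)
  t_prev <- 0
  for (k in seq_along(idx)) {
    dt <- idx[[k]] - t_prev
    if (dt > 1023) {                                # emit SKIP + 4-byte gap
      words <- c(words, bitwShiftL(59L, 10L),
                 dt %/% 65536L, dt %% 65536L)
      dt <- 0L
    }
    words <- c(words, bitwShiftL(codes[[k]], 10L) + dt)
    t_prev <- idx[[k]]
  }
  words <- c(words, 0L)                             # EOF
  con <- file(annotation_path, "wb"); on.exit(close(con))
  writeBin(as.integer(words), con, size = 2L, endian = "little")
  invisible(annotation_path)
}

#' Read an ECG signal from CSV/TSV
#'
#' Reads a delimited text file with one sample per row. A header row is
#' auto-detected; the amplitude column defaults to the last column (so
#' `time, amplitude` files work unconfigured).
#'
#' @param path file path.
#' @param fs sampling rate in Hz (CSV carries none).
#' @param column amplitude column as name or 1-based position; default: last.
#' @param sep field separator; `""` auto-detects comma vs tab.
#' @return An [ecg_signal].
#' @export
read_ecg_csv <- function(path, fs, column = NULL, sep = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be > 0", call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (sep == "") sep <- if (grepl("\t", first)) "\t" else ","
  fields1 <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(fields1))))
  df <- utils::read.table(path, header = has_header, sep = sep,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  col <- if (is.null(column)) ncol(df)
         else if (is.character(column)) {
           j <- match(column, names(df))
           if (is.na(j)) stop("no column named '", column, "'", call. = FALSE)
           j
         } else as.integer(column)
  if (col < 1L || col > ncol(df))
    stop("column ", col, " out of range", call. = FALSE)
  raw <- df[[col]]
  vals <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.finite(vals))
  if (length(bad))
    stop(sprintf("non-numeric amplitude '%s' at data row %d of %s",
                 raw[[bad[[1]]]], bad[[1]], path), call. = FALSE)
  ecg_signal(vals, fs = fs)
}

#' Write an ECG signal to CSV
#'
#' Writes `index` (0-based), `time_s` and `amplitude_mV` columns; the file
#' round-trips through [read_ecg_csv()].
#'
#' @param signal an [ecg_signal].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(signal, path) {
  n <- length(signal$samples)
  df <- data.frame(index = seq_len(n) - 1L,
                   time_s = (seq_len(n) - 1L) / signal$fs,
                   amplitude_mV = signal$samples)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
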