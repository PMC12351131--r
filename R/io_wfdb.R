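# Minimal WFDB-compatible reader/writer: text header (.hea), format-16
# signal file (.dat, 16-bit two's-complement little-endian) and MIT binary
# annotation files (.atr). Covers the single-segment records the package
# needs; no installed package provides WFDB access, so the subset is
# implemented here and kept deliberately small.

ANN_NORMAL <- 1L   # annotation code: normal beat
ANN_SKIP <- 59L    # annotation code: long interval escape

wfdb_base <- function(path) {
  sub("\\.(hea|dat|atr)$", "", path)
}

write_wfdb <- function(rec, path, adc_bits = 12L, adc_range = 10) {
  base <- wfdb_base(path)
  record <- basename(base)
  gain <- 2^adc_bits / adc_range            # ADU per amplitude unit
  half <- 2^(adc_bits - 1)
  adu <- as.integer(pmin(half - 1, pmax(-half, round(rec$samples * gain))))
  n <- length(adu)
  checksum <- sum(as.double(adu)) %% 65536
  if (checksum >= 32768) checksum <- checksum - 65536
  hea <- c(
    sprintf("%s 1 %s %d", record, format(rec$fs), n),
    sprintf("%s.dat 16 %s(0)/mV %d 0 %d %d 0 ECG", record,
            format(gain), adc_bits, adu[1L], as.integer(checksum)),
    sprintf("# subject_id: %s", rec$subject_id),
    if (rec$label != "unknown") sprintf("# label: %s", rec$label)
  )
  writeLines(hea, paste0(base, ".hea"))
  con <- file(paste0(base, ".dat"), "wb")
  on.exit(close(con))
  writeBin(adu, con, size = 2L, endian = "little")
  if (!is.null(rec$r_peaks)) {
    write_wfdb_annotations(rec$r_peaks - 1L, paste0(base, ".atr"))
  }
  invisible(NULL)
}

read_wfdb <- function(path, channel = 1L) {
  base <- wfdb_base(path)
  hea_path <- paste0(base, ".hea")
  if (!file.exists(hea_path)) {
    stop("WFDB header not found: ", hea_path, call. = FALSE)
  }
  lines <- readLines(hea_path, warn = FALSE)
  comments <- lines[startsWith(lines, "#")]
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  n_sig <- as.integer(hdr[2L])
  fs <- as.numeric(sub("/.*$", "", hdr[3L]))   # strip counter-frequency part
  if (is.na(fs)) fs <- 250                      # WFDB default rate
  n_samp <- if (length(hdr) >= 4L) as.integer(hdr[4L]) else NA_integer_
  if (channel > n_sig) {
    stop("record has only ", n_sig, " signal(s)", call. = FALSE)
  }
  sig <- strsplit(trimws(lines[1L + channel]), "\\s+")[[1L]]
  dat_file <- file.path(dirname(hea_path), sig[1L])
  fmt <- sub("x.*|:.*|\\+.*", "", sig[2L])
  if (fmt != "16") {
    stop("only WFDB signal format 16 is supported (got ", sig[2L], ")",
         call. = FALSE)
  }
  gain_field <- if (length(sig) >= 3L) sig[3L] else "200"
  gain <- as.numeric(sub("[(/].*$", "", gain_field))
  if (is.na(gain) || gain == 0) gain <- 200
  baseline <- 0
  if (grepl("\\(", gain_field)) {
    baseline <- as.numeric(sub("^.*\\(([^)]*)\\).*$", "\\1", gain_field))
  }
  raw_n <- file.info(dat_file)$size %/% 2L
  con <- file(dat_file, "rb")
  on.exit(close(con))
  adu <- readBin(con, integer(), n = raw_n, size = 2L, signed = TRUE,
                 endian = "little")
  if (n_sig > 1L) {
    adu <- adu[seq(channel, length(adu), by = n_sig)]
  }
  if (!is.na(n_samp) && n_samp > 0L && length(adu) >= n_samp) {
    adu <- adu[seq_len(n_samp)]
  }
  samples <- (adu - baseline) / gain
  meta <- parse_meta_comments(comments)
  atr_path <- paste0(base, ".atr")
  r_peaks <- NULL
  if (file.exists(atr_path)) {
    r_peaks <- read_wfdb_annotations(atr_path) + 1L
  }
  ecg_record(samples, fs = fs,
             subject_id = meta$subject_id %||% basename(base),
             label = meta$label %||% "unknown", r_peaks = r_peaks)
}

# MIT annotation format: stream of 16-bit little-endian words, annotation
# code in the top 6 bits, inter-annotation interval (samples) in the low 10;
# intervals above 1023 are escaped with a SKIP word followed by a 32-bit
# interval in PDP-11 byte order (high word first, each little-endian);
# a zero word terminates the stream. Sample numbers here are 0-based.
write_wfdb_annotations <- function(samples0, path, code = ANN_NORMAL) {
  words <- integer(0)
  prev <- 0
  for (s in samples0) {
    dt <- s - prev
    prev <- s
    if (dt > 1023) {
      words <- c(words,
                 bitwShiftL(ANN_SKIP, 10),
                 dt %/% 65536, dt %% 65536,
                 bitwShiftL(code, 10))
    } else {
      words <- c(words, bitwOr(bitwShiftL(code, 10), dt))
    }
  }
  words <- c(words, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(words), con, size = 2L, endian = "little")
  invisible(NULL)
}

read_wfdb_annotations <- function(path) {
  raw_n <- file.info(path)$size %/% 2L
  con <- file(path, "rb")
  on.exit(close(con))
  # read unsigned: reconstruct from raw bytes
  bytes <- readBin(con, "raw", n = raw_n * 2L)
  lo <- as.integer(bytes[seq(1L, length(bytes), by = 2L)])
  hi <- as.integer(bytes[seq(2L, length(bytes), by = 2L)])
  words <- lo + 256L * hi
  samples <- integer(0)
  t <- 0
  i <- 1L
  pending_skip <- 0
  while (i <= length(words)) {
    w <- words[i]
    code <- w %/% 1024L
    dt <- w %% 1024L
    if (w == 0L) break
    if (code == ANN_SKIP) {
      pending_skip <- words[i + 1L] * 65536 + words[i + 2L]
      if (pending_skip >= 2^31) pending_skip <- pending_skip - 2^32
      i <- i + 3L
      next
    }
    t <- t + dt + pending_skip
    pending_skip <- 0
    if (code < 50L) {  # beat / non-escape annotation codes
      samples <- c(samples, t)
    }
    i <- i + 1L
  }
  as.integer(samples)
}

parse_meta_comments <- function(comments) {
  out <- list()
  for (cm in comments) {
    m <- regmatches(cm, regexec("^#\\s*(subject_id|label)\\s*:\\s*(.+?)\\s*$",
                                cm))[[1L]]
    if (length(m) == 3L) out[[m[2L]]] <- m[3L]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
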