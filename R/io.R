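#' Read an ECG recording
#'
#' Reads a single-lead ECG recording from disk as an [ecg_record()].
#' Two on-disk layouts are supported:
#'
#' * **wfdb** -- a PhysioNet-style record: text header `<base>.hea`,
#'   format-16 signal `<base>.dat` and, when present, a binary MIT
#'   annotation file `<base>.atr` whose beat annotations populate `r_peaks`.
#'   `path` may be the record base name or the `.hea` file.
#' * **csv** -- comma-separated, two columns (time-in-seconds or sample
#'   index, amplitude), '.' decimal, an optional single header line, and
#'   optional leading `# key: value` comment lines (`fs`, `subject_id`,
#'   `label`). R-peaks are read from a plain-text sidecar `<base>.rpeaks`
#'   (one sample number per line) when present.
#'
#' Sample numbers in annotation files and sidecars are 0-based (the
#' PhysioNet convention) unless `index_base = 1`; they are converted to the
#' package's 1-based indexing on read.
#'
#' @param path Path to the record (base name, `.hea` or `.csv` file).
#' @param format `"wfdb"`, `"csv"`, or `"auto"` (from the file extension).
#' @param fs Sampling rate in Hz for CSV input; overrides the `# fs:` comment
#'   and the rate inferred from the time column.
#' @param index_base 0 or 1: indexing convention used by annotation files.
#' @param channel Signal channel to select from a multi-signal WFDB record.
#' @return An [ecg_record()].
#' @seealso [write_record()]
#' @export
read_record <- function(path, format = c("auto", "wfdb", "csv"), fs = NULL,
                        index_base = 0L, channel = 1L) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path)) "csv" else "wfdb"
  }
  if (format == "wfdb") {
    rec <- read_wfdb(path, channel = channel)
  } else {
    rec <- read_csv_record(path, fs = fs)
  }
  if (index_base == 1L && !is.null(rec$r_peaks)) {
    # sidecar was 1-based already: undo the 0->1 shift applied on read
    rec$r_peaks <- rec$r_peaks - 1L
  }
  rec
}

#' Write an ECG recording
#'
#' Writes an [ecg_record()] in one of the layouts understood by
#' [read_record()]. WFDB output quantizes amplitudes to `adc_bits` over a
#' symmetric `adc_range` (defaults mirror a 12-bit converter spanning 10
#' units, i.e. a quantization step of `10/2^12`); CSV output is lossless to
#' printed precision. An annotation sidecar (`.atr` for WFDB, `.rpeaks` for
#' CSV, 0-based sample numbers) is written iff the record carries R-peaks.
#'
#' @param rec An [ecg_record()].
#' @param path Output path (base name for WFDB; `.csv` appended for CSV if
#'   missing).
#' @param format `"wfdb"` or `"csv"`.
#' @param adc_bits,adc_range WFDB quantization: bits of resolution and the
#'   symmetric amplitude range they span.
#' @return Invisibly, the base path written.
#' @export
write_record <- function(rec, path, format = c("wfdb", "csv"),
                         adc_bits = 12L, adc_range = 10) {
  stopifnot(inherits(rec, "ecg_record"))
  format <- match.arg(format)
  if (format == "wfdb") {
    write_wfdb(rec, path, adc_bits = adc_bits, adc_range = adc_range)
    invisible(wfdb_base(path))
  } else {
    write_csv_record(rec, path)
  }
}

read_csv_record <- function(path, fs = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  meta_lines <- lines[startsWith(lines, "#")]
  meta <- parse_meta_comments(meta_lines)
  fs_comment <- NULL
  for (cm in meta_lines) {
    m <- regmatches(cm, regexec("^#\\s*fs\\s*:\\s*([0-9.eE+-]+)", cm))[[1L]]
    if (length(m) == 2L) fs_comment <- as.numeric(m[2L])
  }
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(body)) stop("no data rows in ", path, call. = FALSE)
  first <- strsplit(body[1L], ",")[[1L]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  if (has_header) body <- body[-1L]
  parts <- strsplit(body, ",")
  tcol <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  amp <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  bad <- which(!is.finite(amp))
  if (length(bad)) {
    stop("non-finite amplitude at data row ", bad[1L], " of ", path,
         call. = FALSE)
  }
  if (anyNA(tcol) || any(diff(tcol) <= 0)) {
    stop("time/index column must be strictly increasing in ", path,
         call. = FALSE)
  }
  fs_use <- fs %||% fs_comment
  if (is.null(fs_use)) {
    dt <- mean(diff(tcol))
    if (dt <= 0) stop("cannot infer sampling rate from ", path, call. = FALSE)
    fs_use <- 1 / dt
  }
  base <- sub("\\.csv$", "", path)
  rpeaks_path <- paste0(base, ".rpeaks")
  r_peaks <- NULL
  if (file.exists(rpeaks_path)) {
    rl <- readLines(rpeaks_path, warn = FALSE)
    rl <- rl[!startsWith(rl, "#") & nzchar(trimws(rl))]
    r_peaks <- as.integer(rl) + 1L
  }
  ecg_record(amp, fs = fs_use,
             subject_id = meta$subject_id %||% basename(base),
             label = meta$label %||% "unknown", r_peaks = r_peaks)
}

write_csv_record <- function(rec, path) {
  if (!grepl("\\.csv$", path)) path <- paste0(path, ".csv")
  base <- sub("\\.csv$", "", path)
  hdr <- c(sprintf("# fs: %s", format(rec$fs)),
           sprintf("# subject_id: %s", rec$subject_id),
           if (rec$label != "unknown") sprintf("# label: %s", rec$label),
           "time,amplitude")
  t <- (seq_along(rec$samples) - 1) / rec$fs
  rows <- paste(format(t, digits = 15, scientific = FALSE, trim = TRUE),
                format(rec$samples, digits = 15, trim = TRUE), sep = ",")
  writeLines(c(hdr, rows), path)
  if (!is.null(rec$r_peaks)) {
    writeLines(as.character(rec$r_peaks - 1L), paste0(base, ".rpeaks"))
  }
  invisible(base)
}
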