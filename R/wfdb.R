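#' Minimal WFDB record reader / writer
#'
#' Reads and writes the subset of the WFDB format this package needs: a
#' `.hea` header plus a single interleaved format-16 `.dat` signal file
#' (16-bit little-endian two's complement, amplitude = (adc - baseline) /
#' gain). Signal names are mapped case-insensitively to the canonical
#' 12-lead names; an unmapped name is an error, never a guess. No R WFDB
#' reader exists on CRAN/Bioconductor, hence this purpose-built one.
#'
#' @param record Record path without extension (reads `record.hea` +
#'   `record.dat`).
#' @param require_all12 Require all 12 canonical leads (default `TRUE`).
#' @return An `[ecg_sequence()]`.
#' @export
read_wfdb <- function(record, require_all12 = TRUE) {
  hea <- paste0(record, ".hea")
  if (!file.exists(hea)) stop("file not found: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 4) stop("format error: bad WFDB header line in ", hea)
  rec_name <- hdr[1]
  n_sig <- as.integer(hdr[2])
  fs <- as.numeric(hdr[3])
  n_samp <- as.integer(hdr[4])
  if (length(lines) < 1 + n_sig) stop("format error: missing signal lines in ", hea)
  sig <- lapply(lines[1 + seq_len(n_sig)], function(l) strsplit(trimws(l), "\\s+")[[1]])
  dat_file <- unique(vapply(sig, `[`, "", 1))
  if (length(dat_file) != 1) stop("format error: multi-file WFDB records are not supported")
  fmt <- vapply(sig, `[`, "", 2)
  if (!all(fmt == "16")) stop("format error: only WFDB format 16 is supported, got ", paste(unique(fmt), collapse = ","))
  # gain field may look like "200(0)/mV"; baseline defaults to 0
  gain <- numeric(n_sig); baseline <- numeric(n_sig); nm <- character(n_sig)
  for (i in seq_len(n_sig)) {
    g <- if (length(sig[[i]]) >= 3) sig[[i]][3] else "200"
    m <- regmatches(g, regexec("^([0-9.eE+-]+)(\\(([0-9+-]+)\\))?(/(.*))?$", g))[[1]]
    gain[i] <- as.numeric(m[2])
    baseline[i] <- if (m[4] != "") as.numeric(m[4]) else 0
    if (!is.finite(gain[i]) || gain[i] == 0) gain[i] <- 200
    nm[i] <- sig[[i]][length(sig[[i]])]
  }
  canon <- ecg_leads()
  idx <- match(tolower(nm), tolower(canon))
  if (anyNA(idx)) {
    stop("unmapped WFDB signal name(s): ", paste(nm[is.na(idx)], collapse = ", "))
  }
  dat <- file.path(dirname(hea), dat_file)
  if (!file.exists(dat)) stop("file not found: ", dat)
  raw <- readBin(dat, "integer", n = n_sig * n_samp, size = 2,
                 signed = TRUE, endian = "little")
  if (length(raw) < n_sig * n_samp) stop("format error: truncated .dat file ", dat)
  m <- matrix(raw, nrow = n_sig)  # interleaved sample-major
  leads <- setNames(lapply(seq_len(n_sig), function(i) {
    (m[i, ] - baseline[i]) / gain[i]
  }), canon[idx])
  ecg_sequence(leads, fs = fs, subject_id = rec_name,
               require_all12 = require_all12)
}

#' @rdname read_wfdb
#' @param x An `ecg_sequence` to write.
#' @param gain ADC units per mV (default 1000; amplitudes are quantised
#'   to 1/gain mV on write).
#' @export
write_wfdb <- function(x, record, gain = 1000) {
  stopifnot(inherits(x, "ecg_sequence"))
  n_sig <- length(x$leads)
  n_samp <- length(x$leads[[1]])
  rec_name <- basename(record)
  dat_name <- paste0(rec_name, ".dat")
  adc <- vapply(x$leads, function(v) {
    a <- round(v * gain)
    if (any(abs(a) > 32767)) stop("amplitude overflows 16-bit range at gain ", gain)
    as.integer(a)
  }, integer(n_samp))
  hdr <- c(
    sprintf("%s %d %g %d", rec_name, n_sig, x$fs, n_samp),
    sprintf("%s 16 %g(0)/mV 16 0 0 0 0 %s", dat_name, gain, names(x$leads))
  )
  writeLines(hdr, paste0(record, ".hea"))
  con <- file(file.path(dirname(record), dat_name), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(adc)), con, size = 2, endian = "little")
  invisible(record)
}
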