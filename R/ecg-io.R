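#' Construct and validate a 12-lead ECG sequence
#'
#' An `ecg_sequence` holds one multi-lead ECG record: a named list of
#' equal-length numeric sample vectors in millivolts, the sampling
#' frequency in Hz, and optional subject metadata. Lead names must come
#' from the canonical 12-lead set (`[ecg_leads()]`); for full-pipeline use
#' all 12 must be present. Leads are stored in canonical order.
#'
#' @param leads Named list of numeric vectors (mV), one per lead.
#' @param fs Sampling frequency in Hz (> 0). Default 500, the convention
#'   of the target acquisition device (500 Hz for 11 s, 5500 samples).
#' @param subject_id Opaque subject identifier string.
#' @param sex One of `"male"`, `"female"`, `"unknown"`.
#' @param require_all12 Require all 12 canonical leads (default `TRUE`).
#' @return An object of class `ecg_sequence`.
#' @export
#' @examples
#' x <- ecg_sequence(setNames(replicate(12, sin(seq_len(100) / 5),
#'   simplify = FALSE), ecg_leads()), fs = 500)
#' x
ecg_sequence <- function(leads, fs = 500, subject_id = "anon",
                         sex = c("unknown", "male", "female"),
                         require_all12 = TRUE) {
  sex <- match.arg(sex)
  if (!is.list(leads) || is.null(names(leads)) || any(names(leads) == "")) {
    stop("`leads` must be a named list of numeric vectors")
  }
  canon <- ecg_leads()
  unknown <- setdiff(names(leads), canon)
  if (length(unknown) > 0) {
    stop("unknown lead name(s): ", paste(unknown, collapse = ", "))
  }
  if (require_all12) {
    missing <- setdiff(canon, names(leads))
    if (length(missing) > 0) {
      stop("missing lead(s): ", paste(missing, collapse = ", "))
    }
  }
  leads <- leads[intersect(canon, names(leads))]
  lens <- vapply(leads, length, integer(1))
  if (length(unique(lens)) != 1) {
    stop("all leads must share one length; got lengths ",
         paste(unique(lens), collapse = ", "))
  }
  for (nm in names(leads)) {
    v <- leads[[nm]]
    if (!is.numeric(v)) stop("lead ", nm, " is not numeric")
    if (!all(is.finite(v))) stop("lead ", nm, " contains non-finite samples")
    leads[[nm]] <- as.numeric(v)
  }
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)")
  }
  structure(
    list(leads = leads, fs = as.numeric(fs),
         subject_id = as.character(subject_id), sex = sex),
    class = "ecg_sequence"
  )
}

#' @export
print.ecg_sequence <- function(x, ...) {
  n <- length(x$leads[[1]])
  cat(sprintf("12-lead ECG sequence '%s': %d leads x %d samples @ %g Hz (%.2f s), sex = %s\n",
              x$subject_id, length(x$leads), n, x$fs, n / x$fs, x$sex))
  invisible(x)
}

#' @export
length.ecg_sequence <- function(x) length(x$leads[[1]])

#' Read / write an ECG sequence as wide CSV
#'
#' The CSV dialect is wide: one header row of canonical lead names, one
#' row per sample, values in millivolts. A header of the form
#' `"I (uV)"` (any lead, unit `uV`/`µV`) is converted to mV on read.
#' `read_ecg()` dispatches on `format`: `"csv"` or `"wfdb"`
#' (see `[read_wfdb()]`).
#'
#' @param path File path (for WFDB, the record path without extension).
#' @param format Input format, `"csv"` (default) or `"wfdb"`.
#' @param fs Sampling frequency for CSV input (Hz); WFDB carries its own.
#' @param x An `ecg_sequence` (for writing).
#' @param ... Passed through to the format reader.
#' @return `read_ecg()` returns a validated `ecg_sequence`; `write_ecg()`
#'   invisibly returns `path`.
#' @export
read_ecg <- function(path, format = c("csv", "wfdb"), fs = 500, ...) {
  format <- match.arg(format)
  if (format == "wfdb") return(read_wfdb(path, ...))
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    read.csv(path, check.names = FALSE, colClasses = "numeric"),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e))
  )
  nms <- names(df)
  # optional unit suffix, e.g. "V1 (uV)"
  unit <- rep(1, length(nms))
  m <- regmatches(nms, regexec("^(\\S+)\\s*\\((uV|µV|mV)\\)$", nms))
  for (i in seq_along(m)) {
    if (length(m[[i]]) == 3) {
      nms[i] <- m[[i]][2]
      if (m[[i]][3] != "mV") unit[i] <- 1e-3
    }
  }
  leads <- setNames(lapply(seq_along(nms), function(i) df[[i]] * unit[i]), nms)
  ecg_sequence(leads, fs = fs, ...)
}

#' @rdname read_ecg
#' @export
write_ecg <- function(x, path, format = c("csv", "wfdb"), ...) {
  stopifnot(inherits(x, "ecg_sequence"))
  format <- match.arg(format)
  if (format == "wfdb") return(write_wfdb(x, path, ...))
  # %.17g keeps the write/read round trip bit-exact for doubles
  txt <- vapply(x$leads, function(v) sprintf("%.17g", v),
                character(length(x$leads[[1]])))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(x$leads), collapse = ","), con)
  writeLines(apply(txt, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Label LVH from left-ventricular mass index
#'
#' The echocardiographic gold standard: LVH is present when LVMI exceeds
#' 115 g/m2 for a man or 95 g/m2 for a woman (strict inequality).
#'
#' @param lvmi Left-ventricular mass index, g/m2 (>= 0). Vectorised.
#' @param sex `"male"` or `"female"` (recycled); `"unknown"` is an error
#'   because the threshold is sex-specific.
#' @return Logical vector: `TRUE` = LVH.
#' @export
#' @examples
#' lvh_label(c(116, 115), "male")   # TRUE FALSE
#' lvh_label(96, "female")          # TRUE
lvh_label <- function(lvmi, sex) {
  if (!is.numeric(lvmi) || any(!is.finite(lvmi)) || any(lvmi < 0)) {
    stop("`lvmi` must be finite and >= 0 (g/m2)")
  }
  sex <- rep_len(as.character(sex), length(lvmi))
  if (!all(sex %in% c("male", "female"))) {
    stop("`sex` must be 'male' or 'female'; LVMI thresholds are undefined otherwise")
  }
  thr <- ifelse(sex == "male", 115, 95)
  lvmi > thr
}

#' Read / write case labels as JSON
#'
#' Labels are stored as a JSON array of objects with fields `subject_id`,
#' `lvh`, and optionally `lvmi` (g/m2) and `sex`. On read, any record with
#' both `lvmi` and a known sex is checked for consistency with
#' `[lvh_label()]`.
#'
#' @param labels Data frame with columns `subject_id`, `lvh`, optionally
#'   `lvmi`, `sex`.
#' @param path JSON file path.
#' @return `read_labels()` returns the labels data frame.
#' @export
write_labels <- function(labels, path) {
  stopifnot(is.data.frame(labels), all(c("subject_id", "lvh") %in% names(labels)))
  jsonlite::write_json(labels, path, auto_unbox = FALSE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  labels <- jsonlite::fromJSON(path)
  stopifnot(all(c("subject_id", "lvh") %in% names(labels)))
  labels$lvh <- as.logical(labels$lvh)
  if (all(c("lvmi", "sex") %in% names(labels))) {
    known <- labels$sex %in% c("male", "female") & is.finite(labels$lvmi)
    if (any(known)) {
      implied <- lvh_label(labels$lvmi[known], labels$sex[known])
      bad <- which(implied != labels$lvh[known])
      if (length(bad) > 0) {
        stop("label inconsistent with LVMI threshold rule for subject(s): ",
             paste(labels$subject_id[known][bad], collapse = ", "))
      }
    }
  }
  labels
}
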