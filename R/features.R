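#' Case-level 24-feature vector from per-lead annotations
#'
#' For each lead independently: the first and last detected cycles are
#' dropped (they may be incomplete or noisy at the record edges), then
#' the R feature is the median of the remaining R amplitudes and the S
#' feature is the median of the remaining S-valley magnitudes. The S
#' magnitude of a beat is `max(0, -s_amp)`: the depth of the valley
#' below baseline, floored at 0 when no downward S deflection exists.
#' An even count of interior beats takes the mean of the two middle
#' values (the usual median).
#'
#' @param annotations Named list of per-lead beat data frames (an
#'   `[detect_ecg()]` result, or the `truth` element of a
#'   `[synth_record()]`), each with columns `r_amp` and `s_amp`.
#' @return Named numeric vector of length 24 in canonical feature order
#'   (`[lvh_features()]`), amplitudes in mV.
#' @export
median_amplitudes <- function(annotations) {
  canon <- ecg_leads()
  missing <- setdiff(canon, names(annotations))
  if (length(missing) > 0) {
    stop("annotations missing lead(s): ", paste(missing, collapse = ", "))
  }
  out <- setNames(numeric(24), lvh_features())
  for (nm in canon) {
    a <- annotations[[nm]]
    if (nrow(a) < 3) {
      stop("lead ", nm, " has ", nrow(a),
           " beats; at least 3 are needed (1 interior beat)")
    }
    interior <- a[2:(nrow(a) - 1), , drop = FALSE]
    out[paste0("R", nm)] <- median(interior$r_amp)
    out[paste0("S", nm)] <- median(pmax(0, -interior$s_amp))
  }
  out
}

#' R-anchored beat segmentation into per-beat feature vectors
#'
#' Splits a multi-beat record into one 24-feature row per interior beat
#' of the reference lead (the first and last cycles are excluded, so the
#' row count is always `n_R(reference) - 2`). For each reference beat,
#' every lead contributes the R/S amplitudes of its own beat whose R
#' index is nearest the reference R index, matched one-to-one within a
#' tolerance (default 0.15 s); a lead with no beat inside the tolerance
#' falls back to that lead's case-median amplitudes.
#'
#' @param annotations Named list of 12 per-lead beat data frames.
#' @param reference_lead Lead whose beats anchor the rows (default
#'   `"II"`, the conventional rhythm lead).
#' @param fs Sampling frequency (Hz), needed to convert the tolerance.
#' @param tolerance_s Cross-lead matching tolerance in seconds.
#' @param subject_id,label Carried into the output rows (the beat label
#'   is the case label).
#' @return Data frame of class `beat_table`: `subject_id`, `beat`, the
#'   24 canonical features, and `label` (if given).
#' @export
segment_beats <- function(annotations, reference_lead = "II", fs = 500,
                          tolerance_s = 0.15, subject_id = "anon",
                          label = NA) {
  canon <- ecg_leads()
  stopifnot(reference_lead %in% canon,
            all(canon %in% names(annotations)))
  ref <- annotations[[reference_lead]]
  if (nrow(ref) < 3) {
    stop("reference lead ", reference_lead, " has ", nrow(ref),
         " beats; at least 3 are needed")
  }
  medians <- median_amplitudes(annotations)
  tol <- win_samples(tolerance_s, fs)
  ref_idx <- ref$r_index[2:(nrow(ref) - 1)]   # interior beats only
  n_rows <- length(ref_idx)
  m <- matrix(NA_real_, nrow = n_rows, ncol = 24,
              dimnames = list(NULL, lvh_features()))
  for (nm in canon) {
    a <- annotations[[nm]]
    match_idx <- match_beats(ref_idx, a$r_index, tol)
    for (i in seq_len(n_rows)) {
      j <- match_idx[i]
      if (is.na(j)) {  # dropout: fall back to the case medians
        m[i, paste0("R", nm)] <- medians[paste0("R", nm)]
        m[i, paste0("S", nm)] <- medians[paste0("S", nm)]
      } else {
        m[i, paste0("R", nm)] <- a$r_amp[j]
        m[i, paste0("S", nm)] <- max(0, -a$s_amp[j])
      }
    }
  }
  out <- data.frame(subject_id = subject_id, beat = seq_len(n_rows),
                    as.data.frame(m), label = label)
  structure(out, class = c("beat_table", "data.frame"))
}

# One-to-one nearest-neighbour matching of reference R indices to a
# lead's R indices within +/- tol samples. Pairs are assigned globally
# by increasing distance (greedy), so one lead beat never serves two
# reference beats.
match_beats <- function(ref_idx, lead_idx, tol) {
  n <- length(ref_idx)
  out <- rep(NA_integer_, n)
  if (length(lead_idx) == 0 || n == 0) return(out)
  d <- abs(outer(ref_idx, lead_idx, "-"))
  d[d > tol] <- NA
  pairs <- which(!is.na(d), arr.ind = TRUE)
  if (nrow(pairs) == 0) return(out)
  ord <- order(d[pairs])
  used_ref <- logical(n); used_lead <- logical(length(lead_idx))
  for (k in ord) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (!used_ref[i] && !used_lead[j]) {
      out[i] <- j
      used_ref[i] <- TRUE; used_lead[j] <- TRUE
    }
  }
  out
}

#' Segment every subject of a cohort into one beat table
#'
#' @param annotations_list Named list (by subject) of per-subject
#'   annotation lists.
#' @param labels Data frame with `subject_id` and `lvh`.
#' @param ... Passed to `[segment_beats()]`.
#' @return A single stacked `beat_table`.
#' @export
segment_cohort <- function(annotations_list, labels, ...) {
  rows <- lapply(names(annotations_list), function(id) {
    lab <- labels$lvh[match(id, labels$subject_id)]
    segment_beats(annotations_list[[id]], subject_id = id, label = lab, ...)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("beat_table", "data.frame"))
}

#' Z-score normalisation fitted on training data
#'
#' `zscore_fit()` learns per-column means and population (n-denominator)
#' standard deviations from the training matrix; `zscore_apply()`
#' transforms any matrix with those statistics. Columns with sd below
#' 1e-12 have it clamped to 1, so constant features map to zeros rather
#' than NaN. Statistics are fitted on training data only, never on test
#' data, to avoid information leakage.
#'
#' @param x Numeric matrix or data frame (rows = cases).
#' @param fit A fit returned by `zscore_fit()`.
#' @param train,test Matrices for the one-shot `zscore_fit_apply()`.
#' @return `zscore_fit()`: list of class `zscore_fit` with `mean` and
#'   `sd`; `zscore_apply()`: the transformed matrix;
#'   `zscore_fit_apply()`: list `train`, `test`, `fit`.
#' @export
#' @examples
#' f <- zscore_fit(cbind(a = c(1, 2, 3)))
#' zscore_apply(cbind(a = c(1, 2, 3)), f)   # -1.22..., 0, 1.22...
zscore_fit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("z-score fitting needs at least 2 rows")
  mu <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2, mu)^2))  # population sd
  sdev[sdev < 1e-12] <- 1
  structure(list(mean = mu, sd = sdev), class = "zscore_fit")
}

#' @rdname zscore_fit
#' @export
zscore_apply <- function(x, fit) {
  stopifnot(inherits(fit, "zscore_fit"))
  x <- as.matrix(x)
  stopifnot(ncol(x) == length(fit$mean))
  sweep(sweep(x, 2, fit$mean), 2, fit$sd, "/")
}

#' @rdname zscore_fit
#' @export
zscore_fit_apply <- function(train, test = NULL) {
  fit <- zscore_fit(train)
  list(train = zscore_apply(train, fit),
       test = if (!is.null(test)) zscore_apply(test, fit),
       fit = fit)
}

#' Write / read a feature table as CSV
#'
#' Wide CSV with `subject_id`, optional `beat` and `label`, and the 24
#' canonical feature columns.
#'
#' @param x Feature data frame.
#' @param path CSV path.
#' @return `read_features()` returns the data frame.
#' @export
write_features <- function(x, path) {
  missing <- setdiff(lvh_features(), names(x))
  if (length(missing) > 0) {
    stop("feature table missing column(s): ", paste(missing, collapse = ", "))
  }
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  missing <- setdiff(lvh_features(), names(df))
  if (length(missing) > 0) {
    stop("feature CSV missing column(s): ", paste(missing, collapse = ", "))
  }
  df
}
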