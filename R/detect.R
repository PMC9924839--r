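#' Detector parameters for R-peak / S-valley extraction
#'
#' Tuning constants of the automatic R/S detector. Defaults follow the
#' published algorithm at 500 Hz: a minimum peak amplitude `mpa` of
#' 0.025 mV, a refractory interval `miR` of 0.6 s (300 samples at 500 Hz,
#' the upper bound of the normal 60-100 bpm RR interval), a 0.12 s
#' forward window for the S valley, a 0.25 s backward window for the
#' T-misdetection check, and a 0.12 s backward window for the corrected
#' R search.
#'
#' @param mpa Minimum R amplitude in mV (>= 0).
#' @param miR_s Refractory interval in seconds; converted to samples as
#'   `round(miR_s * fs)` by the detector.
#' @param s_forward_s S-valley search window after R, seconds.
#' @param t_backward_s T-misdetection check window before R, seconds.
#' @param r_backward_s Corrected-R search window before the updated S,
#'   seconds.
#' @param step7_direction Direction of the corrected-R search relative to
#'   the updated S valley: `"backward"` (default; an R precedes its S in
#'   a QRS complex) or `"forward"` (the literal algorithm-box reading,
#'   kept for fidelity experiments).
#' @return A list of class `detector_params`.
#' @export
#' @examples
#' detector_params()
detector_params <- function(mpa = 0.025, miR_s = 0.6, s_forward_s = 0.12,
                            t_backward_s = 0.25, r_backward_s = 0.12,
                            step7_direction = c("backward", "forward")) {
  step7_direction <- match.arg(step7_direction)
  stopifnot(mpa >= 0, miR_s > 0, s_forward_s > 0, t_backward_s > 0,
            r_backward_s > 0)
  structure(list(mpa = mpa, miR_s = miR_s, s_forward_s = s_forward_s,
                 t_backward_s = t_backward_s, r_backward_s = r_backward_s,
                 step7_direction = step7_direction),
            class = "detector_params")
}

#' @export
print.detector_params <- function(x, ...) {
  cat(sprintf(paste0("R/S detector parameters: mpa = %g mV, refractory = %g s,",
                     " S window = %g s, T check = %g s, R search = %g s (%s)\n"),
              x$mpa, x$miR_s, x$s_forward_s, x$t_backward_s, x$r_backward_s,
              x$step7_direction), ...)
  invisible(x)
}

# window length in samples, half-up rounding (0.12 s @ 500 Hz -> 60)
win_samples <- function(duration_s, fs) as.integer(floor(duration_s * fs + 0.5))

#' Preliminary R-peak detection (refractory-constrained greedy scan)
#'
#' Scans the signal left to right and accepts every first sample that
#' (a) exceeds the amplitude floor `mpa`, (b) is a local maximum
#' (`x[j-1] < x[j]` and `x[j+1] < x[j]`; a flat apex is accepted at the
#' last sample of its plateau), and (c) lies at least one refractory
#' interval `miR` after the previously accepted peak. The scan is greedy:
#' after each accepted peak the next qualifying sample wins, not the
#' largest one.
#'
#' @param signal Numeric sample vector (mV).
#' @param fs Sampling frequency, Hz.
#' @param params A `[detector_params()]` object.
#' @return Integer vector of R-peak sample indices (1-based), possibly
#'   empty.
#' @export
detect_preliminary_r <- function(signal, fs, params = detector_params()) {
  n <- length(signal)
  if (n < 3) return(integer(0))
  miR <- max(1L, win_samples(params$miR_s, fs))
  # candidate local maxima above mpa; runs of equal values collapse to
  # their last sample so flat-topped R waves are kept
  r <- rle(signal)
  ends <- cumsum(r$lengths)
  k <- length(r$values)
  if (k < 3) return(integer(0))
  mid <- 2:(k - 1)
  is_peak <- r$values[mid] > r$values[mid - 1] &
    r$values[mid] > r$values[mid + 1] &
    r$values[mid] > params$mpa
  cand <- ends[mid][is_peak]
  if (length(cand) == 0) return(integer(0))
  out <- integer(0)
  nxt <- 1L  # next admissible index
  for (j in cand) {
    if (j >= nxt) {
      out <- c(out, j)
      nxt <- j + miR
    }
  }
  out
}

#' Locate the S valley after an R peak
#'
#' Returns the minimum of the signal over the half-open window
#' `(r_index, r_index + round(0.12 s * fs)]`, truncated at the signal
#' end; the S valley usually appears within 0.12 s of its R peak. Ties
#' resolve to the earliest index.
#'
#' @inheritParams detect_preliminary_r
#' @param r_index R-peak sample index (1-based).
#' @return List with `s_index` (sample) and `s_amp` (signed mV, the raw
#'   sample value).
#' @export
locate_s_valley <- function(signal, r_index, fs, params = detector_params()) {
  n <- length(signal)
  stopifnot(r_index >= 1, r_index <= n)
  hi <- min(n, r_index + win_samples(params$s_forward_s, fs))
  if (hi <= r_index) stop("empty S search window: R peak at the last sample")
  w <- (r_index + 1L):hi
  s <- w[which.min(signal[w])]
  list(s_index = s, s_amp = signal[s])
}

#' Correct a T-wave misdetection for one beat
#'
#' When the T-wave apex exceeds the R apex, the preliminary scan can
#' accept a T peak as R. The check: take the minimum `m` of the signal
#' over the 0.25 s window before the putative R; if `m` is lower than
#' the current S valley, the putative "R" was likely a T wave, so the S
#' valley moves to that minimum, the R peak is re-located as the maximum
#' of the 0.12 s window adjacent to the updated S (backward by default),
#' and a fresh forward S search from the new R restores the R-before-S
#' ordering. Otherwise the beat is returned unchanged. A backward window
#' that is entirely off-signal leaves the beat unchanged.
#'
#' @inheritParams locate_s_valley
#' @param s_index Current S-valley sample index.
#' @return List with `r_index`, `s_index`, `s_amp`, and `corrected`
#'   (logical).
#' @export
correct_t_misdetection <- function(signal, r_index, s_index, fs,
                                   params = detector_params()) {
  n <- length(signal)
  stopifnot(r_index >= 1, s_index > r_index, s_index <= n)
  wT <- win_samples(params$t_backward_s, fs)
  lo <- max(1L, r_index - wT)
  unchanged <- list(r_index = r_index, s_index = s_index,
                    s_amp = signal[s_index], corrected = FALSE)
  if (lo > r_index - 1L) return(unchanged)  # backward window off-signal
  back <- lo:(r_index - 1L)
  m_idx <- back[which.min(signal[back])]
  if (signal[m_idx] >= signal[s_index]) return(unchanged)
  # misdetection: the true S is in the backward window
  wR <- win_samples(params$r_backward_s, fs)
  if (params$step7_direction == "backward") {
    rlo <- max(1L, m_idx - wR)
    if (rlo > m_idx - 1L) return(unchanged)
    rw <- rlo:(m_idx - 1L)
  } else {
    rhi <- min(n, m_idx + wR)
    if (rhi < m_idx + 1L) return(unchanged)
    rw <- (m_idx + 1L):rhi
  }
  r_new <- rw[which.max(signal[rw])]
  if (r_new >= n) return(unchanged)  # no room for a forward S re-pair
  s_new <- locate_s_valley(signal, r_new, fs, params)
  list(r_index = r_new, s_index = s_new$s_index, s_amp = s_new$s_amp,
       corrected = TRUE)
}

#' Detect all R peaks and S valleys in one lead
#'
#' Composes the full per-lead algorithm: preliminary refractory-greedy
#' R detection, per-R S-valley location, and T-misdetection correction
#' for every beat, then sorts, de-duplicates, and re-validates the beat
#' records (strictly increasing R indices; each S within the forward
#' window of its R).
#'
#' @inheritParams detect_preliminary_r
#' @param lead Lead name attached to the annotations.
#' @return A data frame of class `peak_annotations` with columns `beat`,
#'   `r_index`, `r_amp`, `s_index`, `s_amp` (signed, mV) and `corrected`;
#'   attributes `lead`, `fs`, and `few_beats` (TRUE when fewer than 3
#'   beats were found, too few for median features or segmentation).
#' @export
detect_lead <- function(signal, fs, params = detector_params(), lead = NA_character_) {
  r0 <- detect_preliminary_r(signal, fs, params)
  n <- length(signal)
  r0 <- r0[r0 < n]  # an R at the last sample has no S window
  beats <- vector("list", length(r0))
  for (i in seq_along(r0)) {
    s0 <- locate_s_valley(signal, r0[i], fs, params)
    beats[[i]] <- correct_t_misdetection(signal, r0[i], s0$s_index, fs, params)
  }
  if (length(beats) > 0) {
    df <- do.call(rbind, lapply(beats, as.data.frame))
    df <- df[order(df$r_index), , drop = FALSE]
    df <- df[!duplicated(df$r_index), , drop = FALSE]
    df$r_amp <- signal[df$r_index]
    df <- df[, c("r_index", "r_amp", "s_index", "s_amp", "corrected")]
  } else {
    df <- data.frame(r_index = integer(0), r_amp = numeric(0),
                     s_index = integer(0), s_amp = numeric(0),
                     corrected = logical(0))
  }
  df <- cbind(beat = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  structure(df, class = c("peak_annotations", "data.frame"),
            lead = lead, fs = fs, few_beats = nrow(df) < 3)
}

#' Detect R peaks and S valleys in all 12 leads
#'
#' Runs `[detect_lead()]` independently on every lead of an ECG sequence.
#'
#' @param x An `[ecg_sequence()]`.
#' @param params A `[detector_params()]` object.
#' @return A named list of `peak_annotations` (one per lead), of class
#'   `ecg_annotations`, with attributes `fs` and `subject_id`.
#' @export
detect_ecg <- function(x, params = detector_params()) {
  stopifnot(inherits(x, "ecg_sequence"))
  ann <- lapply(names(x$leads), function(nm) {
    detect_lead(x$leads[[nm]], x$fs, params, lead = nm)
  })
  names(ann) <- names(x$leads)
  structure(ann, class = "ecg_annotations", fs = x$fs,
            subject_id = x$subject_id)
}

#' @export
print.ecg_annotations <- function(x, ...) {
  counts <- vapply(x, nrow, integer(1))
  cat(sprintf("R/S annotations for subject '%s' (%g Hz): beats per lead\n",
              attr(x, "subject_id"), attr(x, "fs")))
  print(counts)
  invisible(x)
}

#' Export annotations as a long CSV
#'
#' One row per (lead, beat): `lead, beat, r_index, r_amp_mV, s_index,
#' s_amp_mV, corrected`. Sample indices are 1-based.
#'
#' @param ann An `ecg_annotations` object (or named list of
#'   `peak_annotations`).
#' @param path Optional CSV path; when `NULL`, the data frame is returned
#'   without writing.
#' @return The long-format data frame, invisibly when `path` is given.
#' @export
annotations_to_csv <- function(ann, path = NULL) {
  rows <- lapply(names(ann), function(nm) {
    a <- as.data.frame(ann[[nm]])
    if (nrow(a) == 0) return(NULL)
    cbind(lead = nm, a)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(lead = character(0), beat = integer(0),
                     r_index = integer(0), r_amp = numeric(0),
                     s_index = integer(0), s_amp = numeric(0),
                     corrected = logical(0))
  }
  names(df)[names(df) == "r_amp"] <- "r_amp_mV"
  names(df)[names(df) == "s_amp"] <- "s_amp_mV"
  if (!is.null(path)) {
    write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
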