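#' Parametric beat template (P-QRS-T Gaussian morphology)
#'
#' One heartbeat is modelled as a sum of five Gaussian bumps, one per
#' wave, each with a signed amplitude (mV), a centre offset from the R
#' apex (s), and a width (s, the Gaussian sd). Gaussian morphology is
#' deliberately simple: it gives analytic ground truth for the apex and
#' valley of every rendered beat, which is what the detector tests need;
#' fidelity to real ECG morphology is a non-goal.
#'
#' The default P amplitude is 0.01 mV, well below the detector's
#' 0.025 mV amplitude floor: the published R-detection scan has no
#' P-rejection step, so a physiological P wave (0.1-0.25 mV) would be
#' accepted as an R peak by a greedy left-to-right scan, and even a
#' near-floor P becomes detectable once additive noise rides on it. See
#' the package vignette.
#'
#' @param r,s,t,p,q Wave amplitudes in mV (R > 0, S <= 0 required).
#' @param offsets Named numeric: centre offset of each wave from the R
#'   apex in seconds (P, Q negative; S, T positive).
#' @param widths Named numeric: Gaussian sd of each wave in seconds.
#' @return A data frame of class `beat_template` with columns `wave`,
#'   `amp`, `offset`, `width`.
#' @export
#' @examples
#' beat_template()                  # default morphology
#' beat_template(t = 1.3)           # T taller than R
beat_template <- function(r = 1.0, s = -0.30, t = 0.35, p = 0.01, q = -0.06,
                          offsets = c(P = -0.17, Q = -0.045, R = 0,
                                      S = 0.05, T = 0.28),
                          widths = c(P = 0.020, Q = 0.012, R = 0.018,
                                     S = 0.015, T = 0.050)) {
  waves <- c("P", "Q", "R", "S", "T")
  stopifnot(setequal(names(offsets), waves), setequal(names(widths), waves))
  amp <- c(P = p, Q = q, R = r, S = s, T = t)
  tpl <- data.frame(wave = waves, amp = unname(amp[waves]),
                    offset = unname(offsets[waves]),
                    width = unname(widths[waves]))
  validate_template(tpl)
  structure(tpl, class = c("beat_template", "data.frame"))
}

validate_template <- function(tpl) {
  stopifnot(is.data.frame(tpl),
            all(c("wave", "amp", "offset", "width") %in% names(tpl)))
  g <- function(w, col) tpl[[col]][tpl$wave == w]
  if (g("R", "amp") <= 0) stop("template R amplitude must be > 0")
  if (g("S", "amp") > 0) stop("template S amplitude must be <= 0")
  ok <- g("P", "offset") < g("Q", "offset") && g("Q", "offset") < 0 &&
    g("R", "offset") == 0 && g("S", "offset") > 0 &&
    g("T", "offset") > g("S", "offset")
  if (!ok) stop("template wave ordering must be P < Q < R(0) < S < T")
  if (any(tpl$width <= 0)) stop("template widths must be > 0")
  invisible(tpl)
}

#' Default per-lead beat templates
#'
#' Twelve templates with roughly physiological relative R/S amplitudes:
#' tall R in II, V4-V6; deep S in V1-V3; aVR with its conventional small
#' r, deep S, and inverted (negative) T wave, which exercises the
#' signed-amplitude handling downstream.
#'
#' @param t_over_r T amplitude as a fraction of R (default 0.35; values
#'   above 1 give the T-taller-than-R morphology that confounds naive
#'   peak detectors); aVR's T is negative regardless.
#' @param p_amp P amplitude in mV (0 suppresses the P wave).
#' @param t_offset,t_width T-wave centre offset and width in seconds;
#'   shrink these for high heart rates so consecutive beats stay
#'   disjoint.
#' @return Named list of 12 `[beat_template()]` objects.
#' @export
default_lead_templates <- function(t_over_r = 0.35, p_amp = 0.01,
                                   t_offset = 0.28, t_width = 0.050) {
  ra <- c(I = 0.80, II = 1.10, III = 0.40, aVR = 0.10, aVL = 0.45,
          aVF = 0.70, V1 = 0.25, V2 = 0.45, V3 = 0.80, V4 = 1.40,
          V5 = 1.50, V6 = 1.30)
  sa <- c(I = -0.15, II = -0.20, III = -0.25, aVR = -0.60, aVL = -0.20,
          aVF = -0.20, V1 = -0.90, V2 = -1.10, V3 = -0.80, V4 = -0.50,
          V5 = -0.35, V6 = -0.25)
  out <- lapply(ecg_leads(), function(nm) {
    tamp <- if (nm == "aVR") -max(0.15, t_over_r * ra[[nm]]) else
      t_over_r * ra[[nm]]
    beat_template(r = ra[[nm]], s = sa[[nm]], t = tamp, p = p_amp,
                  offsets = c(P = -0.17, Q = -0.045, R = 0, S = 0.05,
                              T = t_offset),
                  widths = c(P = 0.020, Q = 0.012, R = 0.018, S = 0.015,
                             T = t_width))
  })
  names(out) <- ecg_leads()
  out
}

# Render Gaussian bumps; each wave only evaluated within +/- 4 sd.
render_lead <- function(tpl, apex_times, n, fs) {
  x <- numeric(n)
  for (w in seq_len(nrow(tpl))) {
    amp <- tpl$amp[w]
    if (amp == 0) next
    off <- tpl$offset[w]; wid <- tpl$width[w]
    for (tk in apex_times) {
      mu <- tk + off
      i1 <- max(1L, as.integer(floor((mu - 4 * wid) * fs)) + 1L)
      i2 <- min(n, as.integer(ceiling((mu + 4 * wid) * fs)) + 1L)
      if (i1 > i2) next
      tt <- (i1:i2 - 1L) / fs
      x[i1:i2] <- x[i1:i2] + amp * exp(-((tt - mu)^2) / (2 * wid^2))
    }
  }
  x
}

# span of the non-zero waves of a template, +/- 2 sd
template_span <- function(tpl) {
  nz <- tpl[tpl$amp != 0, , drop = FALSE]
  max(nz$offset + 2 * nz$width) - min(nz$offset - 2 * nz$width)
}

#' Simulate a 12-lead ECG record with exact ground truth
#'
#' Renders each lead as a sum of per-beat Gaussian wave bumps at
#' RR-spaced apex times (optionally jittered), plus optional white noise
#' and sinusoidal baseline wander. Ground truth carries, per lead, the
#' exact R-apex and S-valley indices and amplitudes of the *noiseless*
#' rendered signal, so detector accuracy can be scored exactly.
#'
#' @param templates Named list of 12 `[beat_template()]`s (default
#'   `[default_lead_templates()]`).
#' @param heart_rate Beats per minute (must lie in 40-180).
#' @param duration_s Record length in seconds (default 11, the target
#'   device's sampling period).
#' @param fs Sampling frequency, Hz (default 500).
#' @param noise_sd White-noise sd, mV (default 0).
#' @param wander_amp,wander_freq Baseline-wander amplitude (mV) and
#'   frequency (Hz); defaults 0 and 0.3.
#' @param rr_jitter_sd Relative sd of the per-interval RR jitter
#'   (default 0).
#' @param first_apex_s Time of the first R apex, seconds (default 0.35).
#' @param seed Integer seed; the record is a pure function of
#'   (arguments, seed).
#' @param subject_id,sex Metadata attached to the returned
#'   `[ecg_sequence()]`.
#' @return List of class `synth_record`: `ecg` (an `[ecg_sequence()]`),
#'   `truth` (named list of per-lead data frames with `beat`, `r_index`,
#'   `r_amp`, `s_index`, `s_amp`), and `apex_times` (s).
#' @export
#' @examples
#' rec <- synth_record(heart_rate = 72, seed = 1)
#' nrow(rec$truth$II)   # ~13 beats in 11 s at 72 bpm
synth_record <- function(templates = default_lead_templates(),
                         heart_rate = 72, duration_s = 11, fs = 500,
                         noise_sd = 0, wander_amp = 0, wander_freq = 0.3,
                         rr_jitter_sd = 0, first_apex_s = 0.35,
                         seed = NULL, subject_id = "synth",
                         sex = "unknown") {
  stopifnot(heart_rate >= 40, heart_rate <= 180, duration_s > 0, fs > 0)
  canon <- ecg_leads()
  stopifnot(setequal(names(templates), canon))
  templates <- templates[canon]
  for (tpl in templates) validate_template(tpl)
  rr <- 60 / heart_rate
  span <- max(vapply(templates, template_span, numeric(1)))
  if (span > rr) {
    stop(sprintf(paste0("template waves (span %.3f s) overlap adjacent beats",
                        " at RR = %.3f s: ambiguous morphology"), span, rr))
  }
  n <- as.integer(round(duration_s * fs))
  with_local_seed(seed, {
    # RR-spaced apices with optional multiplicative jitter
    apex <- first_apex_s
    while (TRUE) {
      gap <- rr * max(0.5, 1 + if (rr_jitter_sd > 0) rnorm(1, 0, rr_jitter_sd) else 0)
      nxt <- apex[length(apex)] + gap
      if (nxt > duration_s - 1 / fs) break
      apex <- c(apex, nxt)
    }
    params <- detector_params()
    sW <- win_samples(params$s_forward_s, fs)
    halo <- max(1L, win_samples(0.03, fs))
    leads <- list(); truth <- list()
    for (nm in canon) {
      clean <- render_lead(templates[[nm]], apex, n, fs)
      # exact truth from the noiseless rendering: apex = argmax near the
      # nominal beat time, valley = forward argmin (same rule the
      # detector uses)
      rows <- list()
      for (tk in apex) {
        i0 <- as.integer(round(tk * fs)) + 1L
        w <- max(1L, i0 - halo):min(n, i0 + halo)
        ri <- w[which.max(clean[w])]
        if (ri >= n) next  # apex too close to the record end
        sv <- locate_s_valley(clean, ri, fs, params)
        rows[[length(rows) + 1L]] <- data.frame(
          r_index = ri, r_amp = clean[ri],
          s_index = sv$s_index, s_amp = sv$s_amp)
      }
      tr <- do.call(rbind, rows)
      tr <- cbind(beat = seq_len(nrow(tr)), tr)
      x <- clean
      if (wander_amp > 0) {
        phase <- runif(1, 0, 2 * pi)
        x <- x + wander_amp * sin(2 * pi * wander_freq * (0:(n - 1)) / fs + phase)
      }
      if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
      leads[[nm]] <- x
      truth[[nm]] <- tr
    }
    structure(list(
      ecg = ecg_sequence(leads, fs = fs, subject_id = subject_id, sex = sex),
      truth = truth, apex_times = apex
    ), class = "synth_record")
  })
}

#' @export
print.synth_record <- function(x, ...) {
  cat(sprintf("synthetic ECG record '%s': %d beats, %d samples/lead @ %g Hz\n",
              x$ecg$subject_id, nrow(x$truth[[1]]),
              length(x$ecg$leads[[1]]), x$ecg$fs))
  invisible(x)
}

#' Cohort specification for the synthetic study population
#'
#' Bundles the knobs of `[synth_cohort()]`. Defaults emulate the study
#' conditions this package targets: 500 Hz, 11 s records, heart rates in
#' the normal 60-95 bpm band (the detector is not guaranteed outside
#' 60-100 bpm), a male-dominated cohort (90% male), low additive noise
#' (0.004 mV sd, comfortably below the 0.025 mV detection floor), and an
#' LVH effect expressed as amplified S in V1-V3 and R in aVL/V5/V6 — the
#' leads the published voltage criteria read.
#'
#' @param n_lvh,n_control Class sizes.
#' @param hr_range Heart-rate range, bpm.
#' @param noise_sd White-noise sd, mV; the default 0.004 keeps baseline
#'   noise several sd below the 0.025 mV detection floor, matching
#'   diagnostic-quality hardware-filtered recordings.
#' @param wander_amp Baseline-wander amplitude, mV.
#' @param duration_s,fs Record length (s) and sampling frequency (Hz).
#' @param lvh_gain_mean,lvh_gain_sd Mean/sd of the per-subject LVH
#'   amplitude multiplier on the LVH-sensitive leads (truncated at 1.1).
#' @param lead_gain_sd Log-sd of the per-subject per-lead gain scatter.
#' @param male_fraction Probability a subject is male.
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_lvh = 30, n_control = 30, hr_range = c(60, 95),
                        noise_sd = 0.004, wander_amp = 0, duration_s = 11,
                        fs = 500, lvh_gain_mean = 1.9, lvh_gain_sd = 0.25,
                        lead_gain_sd = 0.12, male_fraction = 0.9,
                        seed = 1L) {
  stopifnot(n_lvh >= 0, n_control >= 0, hr_range[1] >= 40, hr_range[2] <= 180,
            hr_range[1] <= hr_range[2], noise_sd >= 0, fs > 0)
  structure(list(n_lvh = n_lvh, n_control = n_control, hr_range = hr_range,
                 noise_sd = noise_sd, wander_amp = wander_amp,
                 duration_s = duration_s, fs = fs,
                 lvh_gain_mean = lvh_gain_mean, lvh_gain_sd = lvh_gain_sd,
                 lead_gain_sd = lead_gain_sd, male_fraction = male_fraction,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a labelled two-class ECG cohort
#'
#' Draws `n_lvh` LVH and `n_control` control subjects. Every subject gets
#' per-lead amplitude gains scattered around the default templates;
#' LVH subjects additionally have the S amplitudes of V1-V3 and the R
#' amplitudes of aVL, V5, V6 multiplied by a subject-specific gain
#' (see `[cohort_spec()]`), mirroring the increased QRS voltages that the
#' published criteria key on. Each subject also receives a sex and an
#' LVMI drawn consistently with the class, so the threshold labelling
#' rule (`[lvh_label()]`) reproduces the class assignment exactly.
#'
#' @param spec A `[cohort_spec()]`.
#' @return List of class `synth_cohort`: `records` (list of
#'   `synth_record`), `truth_features` (data frame: `subject_id`, `sex`,
#'   `lvmi`, `lvh`, and the 24 features computed from the ground-truth
#'   annotations via `[median_amplitudes()]`), and `labels`.
#' @export
synth_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_lvh + spec$n_control
  lvh <- rep(c(TRUE, FALSE), c(spec$n_lvh, spec$n_control))
  lvh_leads_s <- c("V1", "V2", "V3")
  lvh_leads_r <- c("aVL", "V5", "V6")
  with_local_seed(spec$seed, {
    sexes <- ifelse(runif(n) < spec$male_fraction, "male", "female")
    hrs <- runif(n, spec$hr_range[1], spec$hr_range[2])
    sub_seeds <- sample.int(2^31 - 2, n)
    records <- vector("list", n)
    feats <- vector("list", n)
    lvmi <- numeric(n)
    for (i in seq_len(n)) {
      tpl <- default_lead_templates()
      gains <- exp(rnorm(12, 0, spec$lead_gain_sd))
      names(gains) <- ecg_leads()
      if (lvh[i]) {
        g <- max(1.1, rnorm(1, spec$lvh_gain_mean, spec$lvh_gain_sd))
      }
      for (nm in ecg_leads()) {
        tpl[[nm]]$amp <- tpl[[nm]]$amp * gains[[nm]]
        if (lvh[i]) {
          if (nm %in% lvh_leads_s) {
            tpl[[nm]]$amp[tpl[[nm]]$wave == "S"] <-
              tpl[[nm]]$amp[tpl[[nm]]$wave == "S"] * g
          }
          if (nm %in% lvh_leads_r) {
            tpl[[nm]]$amp[tpl[[nm]]$wave %in% c("R", "T")] <-
              tpl[[nm]]$amp[tpl[[nm]]$wave %in% c("R", "T")] * g
          }
        }
      }
      lvmi[i] <- if (lvh[i]) {
        if (sexes[i] == "male") runif(1, 120, 170) else runif(1, 100, 150)
      } else {
        if (sexes[i] == "male") runif(1, 70, 110) else runif(1, 55, 90)
      }
      id <- sprintf("S%03d", i)
      records[[i]] <- synth_record(
        templates = tpl, heart_rate = hrs[i], duration_s = spec$duration_s,
        fs = spec$fs, noise_sd = spec$noise_sd, wander_amp = spec$wander_amp,
        rr_jitter_sd = 0.02, seed = sub_seeds[i], subject_id = id,
        sex = sexes[i])
      fv <- median_amplitudes(records[[i]]$truth)
      feats[[i]] <- data.frame(subject_id = id, sex = sexes[i],
                               lvmi = lvmi[i], lvh = lvh[i],
                               as.data.frame(as.list(fv)))
    }
    truth_features <- do.call(rbind, feats)
    stopifnot(all(lvh_label(truth_features$lvmi, truth_features$sex) ==
                    truth_features$lvh))
    labels <- truth_features[, c("subject_id", "lvh", "lvmi", "sex")]
    structure(list(records = records, truth_features = truth_features,
                   labels = labels, spec = spec),
              class = "synth_cohort")
  })
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("synthetic ECG cohort: %d LVH + %d control subjects @ %g Hz x %g s\n",
              x$spec$n_lvh, x$spec$n_control, x$spec$fs, x$spec$duration_s))
  invisible(x)
}

#' Simulate a two-class 24-feature table with a controlled effect size
#'
#' An abstract (unitless, already z-scaled) feature table for classifier
#' experiments: every feature is standard normal in both classes, and the
#' named `shifted` features have their class means separated by
#' `effect_size` standard deviations. Used for parameter-recovery and
#' null (label-permutation) experiments.
#'
#' @param n_per_class Rows per class.
#' @param shifted Character subset of `[lvh_features()]` carrying the
#'   shift (default: six criteria-relevant features).
#' @param effect_size Mean separation in sd units (>= 0).
#' @param seed Integer seed.
#' @return List with `x` (data frame, 24 canonical columns) and `y`
#'   (logical labels, `TRUE` = positive/LVH class).
#' @export
#' @examples
#' tab <- synth_feature_table(50, effect_size = 2, seed = 1)
#' table(tab$y)
synth_feature_table <- function(n_per_class,
                                shifted = c("SV1", "SV3", "RaVL",
                                            "RV4", "RV5", "RV6"),
                                effect_size = 1, seed = NULL) {
  stopifnot(effect_size >= 0, all(shifted %in% lvh_features()),
            n_per_class >= 1)
  feats <- lvh_features()
  n <- 2L * n_per_class
  with_local_seed(seed, {
    x <- matrix(rnorm(n * length(feats)), nrow = n,
                dimnames = list(NULL, feats))
    y <- rep(c(TRUE, FALSE), each = n_per_class)
    x[y, shifted] <- x[y, shifted] + effect_size
    list(x = as.data.frame(x), y = y)
  })
}
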