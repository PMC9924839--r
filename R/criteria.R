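#' Threshold table for the seven ECG voltage criteria
#'
#' All thresholds live in one editable table (mV) so cohort-specific
#' recalibration never touches code. Strictness follows the published
#' definitions: Cornell, Framingham and Lewis are strict (`>`); Sokolow,
#' Peguero, Gubner and sum-of-12-leads are non-strict (`>=`).
#'
#' @return Named list of thresholds in mV.
#' @export
lvh_criteria_thresholds <- function() {
  list(
    cornell_male = 2.8, cornell_female = 2.0,
    sokolow = 3.5,
    peguero_male = 2.8, peguero_female = 2.3,
    framingham_ravl = 1.1, framingham_rv456 = 2.5, framingham_sv123 = 2.5,
    framingham_sv12_rv56 = 3.5, framingham_ri_siii = 2.5,
    gubner = 2.2,
    sum12 = 17.9,
    lewis = 1.7
  )
}

criterion_result <- function(name, score, threshold, positive, detail = NULL) {
  structure(list(name = name, score = score, threshold = threshold,
                 positive = positive, detail = detail),
            class = "criterion_result")
}

#' @export
print.criterion_result <- function(x, ...) {
  cat(sprintf("%s: score = %s mV, threshold = %s mV -> %s\n", x$name,
              format(x$score), format(x$threshold),
              if (isTRUE(x$positive)) "LVH positive" else "negative"))
  if (!is.null(x$detail) && length(x$detail)) {
    cat("  clauses fired: ", paste(x$detail, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

fv_get <- function(f, nms) {
  f <- unlist(f)
  missing <- setdiff(nms, names(f))
  if (length(missing) > 0) {
    stop("feature vector missing: ", paste(missing, collapse = ", "))
  }
  f[nms]
}

check_sex <- function(sex) {
  if (length(sex) != 1 || !sex %in% c("male", "female")) {
    stop("`sex` must be 'male' or 'female' for this sex-specific criterion")
  }
  sex
}

#' Cornell voltage criterion
#'
#' `SV3 + RaVL > 2.8 mV` (man) or `> 2.0 mV` (woman); strict inequality.
#'
#' @param f Named feature vector or one-row data frame with the 24
#'   canonical amplitudes (mV; S features are magnitudes >= 0).
#' @param sex `"male"` or `"female"`.
#' @param thresholds Threshold table, see `[lvh_criteria_thresholds()]`.
#' @return A `criterion_result`: name, score (mV), threshold, and the
#'   boolean LVH call.
#' @export
#' @examples
#' f <- setNames(numeric(24), lvh_features())
#' f["SV3"] <- 1.5; f["RaVL"] <- 1.4
#' criterion_cornell(f, "male")   # 2.9 mV, positive
criterion_cornell <- function(f, sex, thresholds = lvh_criteria_thresholds()) {
  sex <- check_sex(sex)
  v <- fv_get(f, c("SV3", "RaVL"))
  thr <- if (sex == "male") thresholds$cornell_male else thresholds$cornell_female
  score <- unname(v["SV3"] + v["RaVL"])
  criterion_result("cornell", score, thr, score > thr)
}

#' Sokolow-Lyon voltage criterion
#'
#' `SV1 + max(RV5, RV6) >= 3.5 mV`; non-strict.
#'
#' @inheritParams criterion_cornell
#' @return A `criterion_result`.
#' @export
criterion_sokolow <- function(f, thresholds = lvh_criteria_thresholds()) {
  v <- fv_get(f, c("SV1", "RV5", "RV6"))
  score <- unname(v["SV1"] + max(v["RV5"], v["RV6"]))
  criterion_result("sokolow", score, thresholds$sokolow,
                   score >= thresholds$sokolow)
}

#' Peguero-Lo Presti criterion
#'
#' `SD + SV4 >= 2.8 mV` (man) / `>= 2.3 mV` (woman), where `SD` is the
#' deepest S wave in any of the 12 leads (which may itself be SV4, in
#' which case SV4 counts twice); non-strict.
#'
#' @inheritParams criterion_cornell
#' @return A `criterion_result`; `detail` names the lead carrying `SD`.
#' @export
criterion_peguero <- function(f, sex, thresholds = lvh_criteria_thresholds()) {
  sex <- check_sex(sex)
  s_all <- fv_get(f, paste0("S", ecg_leads()))
  sd_lead <- names(s_all)[which.max(s_all)]
  score <- unname(max(s_all) + s_all["SV4"])
  thr <- if (sex == "male") thresholds$peguero_male else thresholds$peguero_female
  criterion_result("peguero", score, thr, score >= thr, detail = sd_lead)
}

#' Framingham criterion
#'
#' Positive when any of five strict clauses holds: `RaVL > 1.1`;
#' `RV4 or RV5 or RV6 > 2.5`; `SV1 or SV2 or SV3 > 2.5`;
#' `max(SV1, SV2) + max(RV5, RV6) > 3.5`; `RI + SIII > 2.5` (all mV).
#'
#' @inheritParams criterion_cornell
#' @return A `criterion_result`; `score` is the fourth clause's combined
#'   voltage and `detail` names every clause that fired.
#' @export
criterion_framingham <- function(f, thresholds = lvh_criteria_thresholds()) {
  v <- fv_get(f, c("RaVL", "RV4", "RV5", "RV6", "SV1", "SV2", "SV3",
                   "RI", "SIII"))
  fired <- c(
    ravl = unname(v["RaVL"]) > thresholds$framingham_ravl,
    rv456 = max(v[c("RV4", "RV5", "RV6")]) > thresholds$framingham_rv456,
    sv123 = max(v[c("SV1", "SV2", "SV3")]) > thresholds$framingham_sv123,
    sv12_rv56 = max(v[c("SV1", "SV2")]) + max(v[c("RV5", "RV6")]) >
      thresholds$framingham_sv12_rv56,
    ri_siii = unname(v["RI"] + v["SIII"]) > thresholds$framingham_ri_siii
  )
  score <- unname(max(v[c("SV1", "SV2")]) + max(v[c("RV5", "RV6")]))
  criterion_result("framingham", score, thresholds$framingham_sv12_rv56,
                   any(fired), detail = names(fired)[fired])
}

#' Gubner-Ungerleider criterion
#'
#' `RI + SIII >= 2.2 mV`; non-strict.
#'
#' @inheritParams criterion_cornell
#' @return A `criterion_result`.
#' @export
criterion_gubner <- function(f, thresholds = lvh_criteria_thresholds()) {
  v <- fv_get(f, c("RI", "SIII"))
  score <- unname(v["RI"] + v["SIII"])
  criterion_result("gubner", score, thresholds$gubner,
                   score >= thresholds$gubner)
}

#' Sum-of-12-leads criterion
#'
#' Sum over all 12 leads of `max(R, S)` amplitude `>= 17.9 mV`;
#' non-strict.
#'
#' @inheritParams criterion_cornell
#' @return A `criterion_result`.
#' @export
criterion_sum12 <- function(f, thresholds = lvh_criteria_thresholds()) {
  r <- fv_get(f, paste0("R", ecg_leads()))
  s <- fv_get(f, paste0("S", ecg_leads()))
  score <- sum(pmax(r, s))
  criterion_result("sum12", score, thresholds$sum12,
                   score >= thresholds$sum12)
}

#' Lewis index
#'
#' `(RI + SIII) - (RIII + SI) > 1.7 mV`; strict. The score may be
#' negative.
#'
#' @inheritParams criterion_cornell
#' @return A `criterion_result`.
#' @export
criterion_lewis <- function(f, thresholds = lvh_criteria_thresholds()) {
  v <- fv_get(f, c("RI", "SIII", "RIII", "SI"))
  score <- unname((v["RI"] + v["SIII"]) - (v["RIII"] + v["SI"]))
  criterion_result("lewis", score, thresholds$lewis,
                   score > thresholds$lewis)
}

#' Evaluate all seven criteria on one feature vector
#'
#' @inheritParams criterion_cornell
#' @param sex Needed by the Cornell and Peguero criteria; may be
#'   `"unknown"` if only the sex-free criteria are wanted (the
#'   sex-specific ones are then `NA`).
#' @return Data frame with one row per criterion: `criterion`, `score`,
#'   `threshold`, `positive`.
#' @export
evaluate_criteria <- function(f, sex = "unknown",
                              thresholds = lvh_criteria_thresholds()) {
  sexed <- sex %in% c("male", "female")
  res <- list(
    if (sexed) criterion_cornell(f, sex, thresholds) else
      criterion_result("cornell", NA_real_, NA_real_, NA),
    criterion_sokolow(f, thresholds),
    if (sexed) criterion_peguero(f, sex, thresholds) else
      criterion_result("peguero", NA_real_, NA_real_, NA),
    criterion_framingham(f, thresholds),
    criterion_gubner(f, thresholds),
    criterion_sum12(f, thresholds),
    criterion_lewis(f, thresholds)
  )
  data.frame(
    criterion = vapply(res, `[[`, "", "name"),
    score = vapply(res, `[[`, 0, "score"),
    threshold = vapply(res, `[[`, 0, "threshold"),
    positive = vapply(res, function(r) as.logical(r$positive), NA)
  )
}

#' Score every criterion against echo-derived labels on a cohort
#'
#' Applies the seven criteria to each case and scores each criterion's
#' boolean call against the LVH label (LVH = positive class), yielding a
#' confusion-based `[model_report()]` per criterion. Cases whose sex is
#' unknown are excluded from the sex-specific criteria only.
#'
#' @param features Data frame with the 24 canonical feature columns and
#'   optionally `sex`.
#' @param labels Logical vector of LVH labels, one per row.
#' @param sex Character vector (recycled) if not a `features` column.
#' @param thresholds Threshold table.
#' @return Data frame: one row per criterion with confusion counts and
#'   accuracy / precision / sensitivity / specificity.
#' @export
evaluate_criteria_cohort <- function(features, labels, sex = NULL,
                                     thresholds = lvh_criteria_thresholds()) {
  stopifnot(nrow(features) == length(labels), is.logical(labels))
  if (is.null(sex)) {
    sex <- if ("sex" %in% names(features)) features$sex else "unknown"
  }
  sex <- rep_len(sex, nrow(features))
  calls <- lapply(seq_len(nrow(features)), function(i) {
    ev <- evaluate_criteria(features[i, lvh_features(), drop = FALSE],
                            sex = sex[i], thresholds = thresholds)
    setNames(ev$positive, ev$criterion)
  })
  calls <- do.call(rbind, calls)
  out <- lapply(colnames(calls), function(cr) {
    ok <- !is.na(calls[, cr])
    rep <- model_report_from(predicted = calls[ok, cr], actual = labels[ok])
    data.frame(criterion = cr, n = sum(ok), tp = rep$tp, fp = rep$fp,
               tn = rep$tn, fn = rep$fn, accuracy = rep$accuracy,
               precision = rep$precision, sensitivity = rep$sensitivity,
               specificity = rep$specificity)
  })
  do.call(rbind, out)
}
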