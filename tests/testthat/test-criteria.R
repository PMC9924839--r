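test_that("Cornell criterion: sex-specific strict thresholds", {
  r <- criterion_cornell(fv(SV3 = 1.5, RaVL = 1.4), "male")
  expect_equal(r$score, 2.9)
  expect_true(r$positive)
  expect_false(criterion_cornell(fv(SV3 = 1.5, RaVL = 1.3), "male")$positive)  # 2.8, strict
  expect_true(criterion_cornell(fv(SV3 = 1.0, RaVL = 1.05), "female")$positive) # 2.05 > 2.0
  expect_false(criterion_cornell(fv(SV3 = 1.0, RaVL = 1.0), "female")$positive)
  expect_error(criterion_cornell(fv(), "unknown"), "sex")
})

test_that("Sokolow-Lyon criterion: non-strict 3.5 mV on SV1 + max(RV5, RV6)", {
  expect_true(criterion_sokolow(fv(SV1 = 1, RV5 = 2.5, RV6 = 2))$positive)   # exactly 3.5
  expect_false(criterion_sokolow(fv())$positive)
  r <- criterion_sokolow(fv(SV1 = 1, RV5 = 2, RV6 = 2.6))
  expect_equal(r$score, 3.6)   # RV6 carries the max
  expect_true(r$positive)
  expect_false(criterion_sokolow(fv(SV1 = 1, RV5 = 2.49, RV6 = 0))$positive)
})

test_that("Peguero criterion: deepest S in any lead plus SV4, non-strict", {
  r <- criterion_peguero(fv(SV4 = 1.5), "male")   # SV4 is itself the deepest
  expect_equal(r$score, 3.0)
  expect_true(r$positive)
  expect_equal(r$detail, "SV4")
  r <- criterion_peguero(fv(SV2 = 1.2, SV4 = 1.0), "female")
  expect_equal(r$score, 2.2)
  expect_false(r$positive)                        # 2.2 < 2.3
  expect_true(criterion_peguero(fv(SV2 = 1.3, SV4 = 1.0), "female")$positive)
  expect_false(criterion_peguero(fv(), "male")$positive)
  # the deepest-S scan covers aVR
  r <- criterion_peguero(fv(SaVR = 2.0, SV4 = 0.8), "male")
  expect_equal(r$score, 2.8)
  expect_true(r$positive)
})

test_that("Framingham criterion: any of five strict clauses fires", {
  r <- criterion_framingham(fv(RaVL = 1.2))
  expect_true(r$positive)
  expect_identical(r$detail, "ravl")
  r <- criterion_framingham(fv(RI = 1.3, SIII = 1.3))
  expect_true(r$positive)                 # 2.6 > 2.5
  expect_identical(r$detail, "ri_siii")
  expect_false(criterion_framingham(fv())$positive)
  expect_false(criterion_framingham(fv(RaVL = 1.1))$positive)   # strict
  expect_false(criterion_framingham(fv(RV5 = 2.5))$positive)    # strict
  expect_true(criterion_framingham(fv(SV2 = 1.51, RV6 = 2.0))$positive)
  expect_false(criterion_framingham(fv(SV2 = 1.5, RV6 = 2.0))$positive)
})

test_that("Gubner and Lewis criteria respect their printed strictness", {
  expect_true(criterion_gubner(fv(RI = 1.1, SIII = 1.1))$positive)  # 2.2, non-strict
  expect_false(criterion_gubner(fv())$positive)
  expect_false(criterion_gubner(fv(RI = 1.0, SIII = 1.1))$positive) # 2.1
  r <- criterion_lewis(fv(RI = 1.0, SIII = 1.5, RIII = 0.2, SI = 0.1))
  expect_equal(r$score, 2.2)
  expect_true(r$positive)
  expect_false(criterion_lewis(fv())$positive)
  expect_false(criterion_lewis(fv(RI = 1, SIII = 1, RIII = 1, SI = 1))$positive)
  expect_false(criterion_lewis(fv(RI = 1.7))$positive)    # exactly 1.7: strict
  expect_lt(criterion_lewis(fv(RIII = 2))$score, 0)       # negative scores allowed
})

test_that("sum-of-12-leads uses max(R, S) per lead, non-strict at 17.9 mV", {
  f <- setNames(rep(c(1.5, 1.0), each = 12), lvh_features())
  r <- criterion_sum12(f)
  expect_equal(r$score, 18)
  expect_true(r$positive)
  expect_false(criterion_sum12(fv())$positive)
  # S deeper than R contributes through the max
  f2 <- fv(SV1 = 17.9)
  expect_true(criterion_sum12(f2)$positive)
})

test_that("criteria are monotone in their constituent amplitudes", {
  set.seed(1)
  for (i in 1:25) {
    base <- setNames(runif(24, 0, 2), lvh_features())
    bumped <- base + runif(24, 0, 0.5)
    for (fun in list(function(f) criterion_cornell(f, "male"),
                     criterion_sokolow,
                     function(f) criterion_peguero(f, "female"),
                     criterion_framingham, criterion_gubner,
                     criterion_sum12)) {
      expect_false(fun(base)$positive && !fun(bumped)$positive)
    }
  }
})

test_that("cohort-level criteria evaluation builds correct confusion reports", {
  # nobody positive, nobody LVH: specificity 1 everywhere
  n <- 8
  feats <- as.data.frame(matrix(0.1, n, 24,
                                dimnames = list(NULL, lvh_features())))
  rep0 <- evaluate_criteria_cohort(feats, rep(FALSE, n), sex = "male")
  expect_true(all(rep0$specificity == 1))
  expect_true(all(is.na(rep0$sensitivity)))   # no positives: undefined, not 0
  # constructed separable cohort: Sokolow score > 3.5 iff LVH
  set.seed(9)
  n <- 40; lvh <- rep(c(TRUE, FALSE), each = 20)
  feats <- as.data.frame(matrix(runif(n * 24, 0, 0.2), n, 24,
                                dimnames = list(NULL, lvh_features())))
  feats$SV1 <- ifelse(lvh, 2.2, 0.5)
  feats$RV5 <- ifelse(lvh, 2.0, 0.8)
  rep1 <- evaluate_criteria_cohort(feats, lvh, sex = "male")
  expect_equal(rep1$accuracy[rep1$criterion == "sokolow"], 1.0)
  # random labels: accuracy near 0.5 within binomial noise
  set.seed(10)
  n <- 400
  feats <- as.data.frame(matrix(runif(n * 24, 0, 1), n, 24,
                                dimnames = list(NULL, lvh_features())))
  feats$SV1 <- ifelse(runif(n) < 0.5, 3.6, 0)   # coin-flip sokolow calls
  labs <- runif(n) < 0.5
  rep2 <- evaluate_criteria_cohort(feats, labs, sex = "male")
  acc <- rep2$accuracy[rep2$criterion == "sokolow"]
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / n) + 0.05)
})
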