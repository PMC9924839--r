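params <- detector_params()

test_that("refractory window and amplitude floor follow the device arithmetic", {
  expect_equal(ecglvh:::win_samples(0.6, 500), 300L)    # miR at 500 Hz
  expect_equal(ecglvh:::win_samples(0.12, 500), 60L)
  expect_equal(ecglvh:::win_samples(0.25, 500), 125L)
  # all-zero signal: nothing exceeds mpa
  expect_identical(detect_preliminary_r(numeric(1000), 500, params),
                   integer(0))
  # two spikes 200 samples apart, refractory 300: only the first survives
  x <- numeric(1000); x[c(300, 500)] <- 1
  expect_identical(detect_preliminary_r(x, 500, params), 300L)
  x <- numeric(1000); x[c(300, 650)] <- 1   # 350 apart: both survive
  expect_identical(detect_preliminary_r(x, 500, params), c(300L, 650L))
})

test_that("preliminary detection recovers Gaussian R apices and handles plateaus", {
  fs <- 500
  apices <- seq(200, by = 400, length.out = 10)
  t <- seq_len(4400)
  x <- rowSums(vapply(apices, function(a) exp(-((t - a)^2) / (2 * 9^2)),
                      numeric(length(t))))
  expect_identical(detect_preliminary_r(x, fs, params), as.integer(apices))
  # flat apex: accepted at the last sample of the plateau
  x <- c(0, 1, 2, 3, 3, 3, 2, 1, 0)
  expect_identical(detect_preliminary_r(x, fs, params), 6L)
  # degenerate inputs
  expect_identical(detect_preliminary_r(c(0, 1), fs, params), integer(0))
})

test_that("detect_preliminary_r matches the exhaustive greedy oracle on random signals", {
  set.seed(42)
  miR_samples <- ecglvh:::win_samples(params$miR_s, 500)
  for (i in 1:250) {
    n <- sample(50:2000, 1)
    x <- rnorm(n, sd = runif(1, 0.01, 1))
    got <- detect_preliminary_r(x, 500, params)
    want <- oracle_preliminary_r(x, params$mpa, miR_samples)
    expect_identical(got, want)
    if (length(got) > 1) expect_true(all(diff(got) >= miR_samples))
    expect_true(all(x[got] > params$mpa))
  }
})

test_that("locate_s_valley returns the forward-window argmin with earliest-tie rule", {
  x <- numeric(200)
  x[100] <- 1; x[130] <- -0.4
  s <- locate_s_valley(x, 100, 500, params)
  expect_equal(s$s_index, 130)
  expect_equal(s$s_amp, -0.4)
  # monotone decreasing segment: the window's last sample wins
  x <- seq(1, -1, length.out = 300)
  expect_equal(locate_s_valley(x, 10, 500, params)$s_index, 70)
  # tie resolves to the earliest index
  x <- numeric(200); x[100] <- 1; x[c(120, 140)] <- -0.3
  expect_equal(locate_s_valley(x, 100, 500, params)$s_index, 120)
  # empty window at the last sample
  expect_error(locate_s_valley(numeric(10), 10, 500, params), "empty")
  # synthetic QRS: S offset 25 samples after R recovered exactly
  rec <- synth_record(heart_rate = 72, seed = 5)
  tr <- rec$truth$II
  got <- locate_s_valley(rec$ecg$leads$II, tr$r_index[2], 500, params)
  expect_equal(got$s_index, tr$s_index[2])
  # S placed 0.05 s (25 samples) after R, +/- 1 sample of wave overlap
  expect_lte(abs(tr$s_index[2] - tr$r_index[2] - 25), 2)
})

test_that("T-misdetection correction fires only when warranted and is idempotent", {
  fs <- 500
  # normal morphology: backward min (Q wave) is above the S valley
  rec <- synth_record(heart_rate = 72, seed = 11)
  x <- rec$ecg$leads$V5
  tr <- rec$truth$V5
  r <- tr$r_index[3]; s <- tr$s_index[3]
  out <- correct_t_misdetection(x, r, s, fs, params)
  expect_false(out$corrected)
  expect_equal(out$r_index, r)
  # truncated backward window near the record start: no error
  x2 <- numeric(200); x2[40] <- 1; x2[60] <- -0.2
  out2 <- correct_t_misdetection(x2, 40, 60, fs, params)
  expect_false(out2$corrected)
  # T accepted as R (tachycardia, T > R): corrected back to the true R
  rec <- synth_record(templates = tachy_templates(1.3), heart_rate = 110,
                      seed = 2)
  x <- rec$ecg$leads$II
  prelim <- detect_preliminary_r(x, fs, params)
  truth_idx <- rec$truth$II$r_index
  mis <- setdiff(prelim, truth_idx)
  expect_gt(length(mis), 0)            # some T peaks were accepted
  for (t_idx in mis) {
    s0 <- locate_s_valley(x, t_idx, fs, params)
    out <- correct_t_misdetection(x, t_idx, s0$s_index, fs, params)
    expect_true(out$corrected)
    expect_true(out$r_index %in% truth_idx)
    # idempotence: a second pass leaves the corrected beat unchanged
    again <- correct_t_misdetection(x, out$r_index, out$s_index, fs, params)
    expect_equal(again[c("r_index", "s_index")],
                 out[c("r_index", "s_index")])
  }
})

test_that("detect_lead satisfies the annotation invariants end to end", {
  sW <- ecglvh:::win_samples(params$s_forward_s, 500)
  for (seed in 1:5) {
    rec <- synth_record(heart_rate = 60 + 7 * seed, seed = seed,
                        rr_jitter_sd = 0.02)
    for (nm in c("II", "V2", "aVR")) {
      a <- detect_lead(rec$ecg$leads[[nm]], 500, params, lead = nm)
      expect_true(all(diff(a$r_index) > 0))
      expect_true(all(a$s_index > a$r_index))
      expect_true(all(a$s_index - a$r_index <= sW))
      expect_equal(a$r_amp, rec$ecg$leads[[nm]][a$r_index])
      expect_equal(a$s_amp, rec$ecg$leads[[nm]][a$s_index])
    }
  }
})

test_that("detect_ecg recovers ground truth exactly on clean records and within 2 samples under noise", {
  rec <- synth_record(heart_rate = 72, seed = 1)
  ann <- detect_ecg(rec$ecg)
  for (nm in ecg_leads()) {
    expect_identical(ann[[nm]]$r_index, rec$truth[[nm]]$r_index)
    expect_identical(ann[[nm]]$s_index, rec$truth[[nm]]$s_index)
  }
  # low-amplitude white noise (sd well below the 0.025 mV floor)
  recn <- synth_record(heart_rate = 72, noise_sd = 0.004, seed = 21)
  annn <- detect_ecg(recn$ecg)
  for (nm in c("II", "V4", "V5")) {
    expect_equal(nrow(annn[[nm]]), nrow(recn$truth[[nm]]))
    expect_true(all(abs(annn[[nm]]$r_index - recn$truth[[nm]]$r_index) <= 2))
  }
  # degenerate input
  a <- detect_lead(c(0, 0.1), 500, params)
  expect_equal(nrow(a), 0)
  expect_true(attr(a, "few_beats"))
})

test_that("annotations export to long CSV with 1-based indices", {
  rec <- synth_record(heart_rate = 70, seed = 9)
  ann <- detect_ecg(rec$ecg)
  path <- tempfile(fileext = ".csv")
  annotations_to_csv(ann, path)
  df <- read.csv(path)
  expect_setequal(unique(df$lead), ecg_leads())
  expect_true(all(df$r_index >= 1))
  expect_named(df, c("lead", "beat", "r_index", "r_amp_mV", "s_index",
                     "s_amp_mV", "corrected"))
})
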