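# Independent direct convolution of a boxcar with the double-gamma HRF,
# used as the oracle for the simulator's event responses.
oracle_response <- function(t_eval, onsets, amplitude, duration = 1,
                            dt = 0.005) {
  grid <- seq(0, max(t_eval) + 1, by = dt)
  h <- hrf_double_gamma(grid)
  resp <- numeric(length(grid))
  for (on in onsets) {
    box <- as.numeric(grid >= on & grid < on + duration)
    conv <- stats::convolve(box, rev(h), type = "open")[seq_along(grid)] * dt
    resp <- resp + conv
  }
  # normalize by the single-event peak, matching the unit-peak contract
  box1 <- as.numeric(grid >= 0 & grid < duration)
  single <- stats::convolve(box1, rev(h), type = "open")[seq_along(grid)] * dt
  amplitude * stats::approx(grid, resp / max(single), xout = t_eval)$y
}

test_that("the HRF has unit peak and vanishes for negative time", {
  t <- seq(-2, 30, by = 0.01)
  h <- hrf_double_gamma(t)
  expect_equal(max(h), 1, tolerance = 1e-6)
  expect_true(all(h[t < 0] == 0))
  expect_lt(abs(t[which.max(h)] - 5.2), 1) # peak near 5 s
  expect_lt(min(h), 0)                     # post-peak undershoot exists
})

test_that("a noiseless single event reaches its amplitude at the response peak", {
  des <- event_design("hit")
  sp <- lattice_spec(dim = c(4, 4, 2), radii = c(2, 2, 1), noise_sd = 0)
  sim <- simulate_bold(des, sp, amplitudes = c(hit = 1), seed = 1)
  vox <- which(sp$truth)[1]
  series <- 100 * (array(sim$data, c(prod(sp$dim), des$n_volumes))[vox, ] /
                   sp$baseline - 1)
  expect_equal(max(series), 1, tolerance = 0.03) # TR sampling of unit peak
  expect_equal(series, oracle_response((seq_along(series) - 1) * 2, 12, 1),
               tolerance = 0.01)
})

test_that("two events superpose linearly (direct convolution oracle)", {
  des <- event_design(c("hit", "hit")) # onsets 12 and 24 s
  sp <- lattice_spec(dim = c(4, 4, 2), radii = c(2, 2, 1), noise_sd = 0)
  sim <- simulate_bold(des, sp, amplitudes = c(hit = 0.6), seed = 1)
  vox <- which(sp$truth)[1]
  series <- 100 * (array(sim$data, c(prod(sp$dim), des$n_volumes))[vox, ] /
                   sp$baseline - 1)
  expect_equal(series,
               oracle_response((seq_along(series) - 1) * 2, c(12, 24), 0.6),
               tolerance = 0.01)
})

test_that("zero amplitudes leave region and non-region voxels indistinguishable", {
  des <- event_design(rep("hit", 6))
  sp <- lattice_spec(dim = c(8, 8, 4), radii = c(2, 2, 1.5), noise_sd = 0.5)
  sim <- simulate_bold(des, sp, amplitudes = c(hit = 0), seed = 9)
  g <- glm_contrast(sim, c(hit = 1))
  tt <- two_sample_t(g$t[as.vector(sp$truth)], g$t[!as.vector(sp$truth)])
  expect_gt(tt$p, 0.01)
})

test_that("GLM p-values are uniform under the null and explode without noise", {
  # null calibration on 1000 pure-noise voxels (white noise so the OLS
  # t reference distribution is exact)
  des <- event_design(rep(c("hit", "cr"), 10))
  sp <- lattice_spec(dim = c(10, 10, 10), radii = c(0.1, 0.1, 0.1),
                     noise_sd = 0.5, ar1 = 0)
  sim <- simulate_bold(des, sp, amplitudes = c(hit = 0, cr = 0), seed = 4)
  g <- glm_contrast(sim, c(hit = 1, cr = -1))
  expect_gt(stats::ks.test(g$p, "punif")$p.value, 0.01)

  # noiseless responsive voxel: perfect fit, minimal p
  sp2 <- lattice_spec(dim = c(3, 3, 2), radii = c(1, 1, 1), noise_sd = 0)
  sim2 <- simulate_bold(des, sp2, amplitudes = c(hit = 0.8, cr = 0.2),
                        seed = 5)
  g2 <- glm_contrast(sim2, c(hit = 1, cr = -1))
  centre <- which(as.vector(sp2$truth))[1]
  expect_gt(abs(g2$t[centre]), 1e6)
  expect_lt(g2$p[centre], 1e-12)

  # equal amplitudes under a [1, -1] contrast: t centred on zero
  sp3 <- lattice_spec(dim = c(8, 8, 3), radii = c(3, 3, 1.5), noise_sd = 0.5)
  sim3 <- simulate_bold(des, sp3, amplitudes = c(hit = 0.5, cr = 0.5),
                        seed = 6)
  g3 <- glm_contrast(sim3, c(hit = 1, cr = -1))
  expect_lt(abs(mean(g3$t)), 0.2)
})

test_that("rank-deficient designs are reported with the collinear column", {
  des <- event_design(c("a", "a"))
  des$events$condition <- c("a", "b")
  des$events$onset_s <- c(12, 12) # identical regressors
  sp <- lattice_spec(dim = c(2, 2, 2), radii = c(1, 1, 1), noise_sd = 0.1)
  sim <- suppressWarnings(
    simulate_bold(des, sp, amplitudes = c(a = 0.5, b = 0.5), seed = 1))
  expect_error(glm_contrast(sim, c(a = 1, b = -1)), "collinear")
})

test_that("BH thresholding matches a brute-force step-up oracle", {
  brute_bh <- function(p, q) {
    m <- length(p)
    o <- order(p)
    passed <- which(p[o] <= q * seq_len(m) / m)
    rej <- logical(m)
    if (length(passed)) rej[o[seq_len(max(passed))]] <- TRUE
    rej
  }
  # the worked four-voxel example: all rejected by step-up
  p4 <- c(0.01, 0.02, 0.03, 0.04)
  expect_true(all(brute_bh(p4, 0.05)))
  roi4 <- define_roi(p4, q = 0.05, dim = c(4, 1, 1))
  expect_identical(roi4$voxels, 1:4)
  expect_identical(roi4$threshold_used, "fdr_q05")

  for (s in 1:100) {
    p <- counter_uniform(s, 1:2000)^2 # skew towards small values
    impl <- stats::p.adjust(p, "BH") <= 0.05
    expect_identical(impl, brute_bh(p, 0.05), label = paste("seed", s))
  }
})

test_that("unlocalizable lattices fall back and then flag failure", {
  p <- rep(1, 8)
  roi <- define_roi(p, dim = c(2, 2, 2))
  expect_false(roi$localized)
  expect_identical(roi$n_voxels, 0L)
  # fallback engages when FDR fails but p < 0.003 voxels exist: with 100
  # voxels the step-up thresholds (0.0005, 0.001, ...) miss p = 0.002
  p2 <- c(0.002, 0.0025, rep(0.9, 98))
  roi2 <- define_roi(p2, dim = c(10, 10, 1))
  expect_identical(roi2$threshold_used, "p003_uncorrected")
  expect_identical(sort(roi2$voxels), 1:2)
})

test_that("contiguity filtering keeps the largest 6-connected component", {
  dim3 <- c(5, 1, 1)
  # voxels 1,2 form one component; voxel 4 a second; keep the pair
  p <- c(1e-6, 1e-6, 1, 1e-6, 1)
  roi <- define_roi(p, dim = dim3)
  expect_identical(sort(roi$voxels), 1:2)
  # tie in size: the component with higher mean |t| wins
  p2 <- c(1e-6, 1, 1e-6, 1, 1)
  roi2 <- define_roi(p2, dim = dim3, t = c(2, 0, 9, 0, 0))
  expect_identical(roi2$voxels, 3L)
})

test_that("a strongly responsive region is recovered almost entirely", {
  des <- block_design()
  hits <- 0
  for (s in 1:10) {
    sp <- lattice_spec(dim = c(12, 12, 6), radii = c(3, 2.5, 2),
                       noise_sd = 0.5)
    sim <- simulate_bold(des, sp, amplitudes = c(biological = 1.2,
                                                 scrambled = 0.2), seed = s)
    roi <- define_roi(glm_contrast(sim, c(biological = 1, scrambled = -1)))
    truth <- which(as.vector(sp$truth))
    hits <- hits + (mean(truth %in% roi$voxels) >= 0.9)
  }
  expect_gte(hits, 9)
})

test_that("event-related averaging returns exact epochs in degenerate cases", {
  # spacing beyond the HRF support (and on the TR grid) makes the
  # noiseless epochs identical
  des <- event_design(rep("hit", 4), isi_s = 39)
  sp <- lattice_spec(dim = c(4, 4, 2), radii = c(2, 2, 1), noise_sd = 0)
  sim <- simulate_bold(des, sp, amplitudes = c(hit = 0.6), seed = 1)
  series <- roi_mean_series(sim, which(sp$truth))
  tc <- event_related_average(series, des, "hit")
  i0 <- floor(des$events$onset_s[2] / 2) + 1
  single <- series[i0:(i0 + 6)]
  expect_equal(tc$pct_signal, single, tolerance = 1e-4)
  expect_error(event_related_average(series, des, "miss"), "no events")
})

test_that("peak percent change reads the raw averaged time course", {
  flat <- data.frame(time_s = seq(0, 12, 2), pct_signal = rep(0.2, 7))
  expect_equal(peak_percent_change(flat), 0)
  rise <- data.frame(time_s = seq(0, 12, 2),
                     pct_signal = c(0.1, 0.3, 0.5, 0.4, 0.2, 0.1, 0.1))
  expect_equal(peak_percent_change(rise), 0.4)
  short <- data.frame(time_s = c(0, 2, 4), pct_signal = c(0, 1, 0))
  expect_error(peak_percent_change(short), "window too short")

  # generator round trip: injected amplitude recovered from the average
  des <- event_design(rep("hit", 4), isi_s = 15)
  sp <- lattice_spec(dim = c(4, 4, 2), radii = c(2, 2, 1), noise_sd = 0)
  sim <- simulate_bold(des, sp, amplitudes = c(hit = 0.6), seed = 1)
  ra <- roi_event_analysis(sim, which(sp$truth), window_s = 14)
  expect_equal(unname(ra$peaks["hit"]), 0.6, tolerance = 0.05)
})

test_that("simulated runs round-trip through NIfTI", {
  des <- event_design(rep("hit", 2))
  sp <- lattice_spec(dim = c(4, 4, 2), radii = c(2, 2, 1), noise_sd = 0.3)
  sim <- simulate_bold(des, sp, amplitudes = c(hit = 0.5), seed = 2)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_bold_nifti(sim, f)
  back <- read_bold_nifti(f)
  expect_equal(dim(back), dim(sim$data))
  expect_equal(back, sim$data, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("response-contingent amplitude maps reproduce the group peak patterns", {
  # control-like: hit and false-alarm responses drive the region harder
  # than correct rejections; patient-like: all conditions equal
  run_session <- function(amps, obs, seed) {
    beh <- run_exp3_behavioral(obs, seed = seed, n_runs = 3)
    des <- event_design(beh$log$condition)
    sp <- lattice_spec(dim = c(10, 10, 5), radii = c(2.5, 2, 1.5),
                       noise_sd = 0.5)
    sim <- simulate_bold(des, sp, amplitudes = amps, seed = seed)
    roi_event_analysis(sim, which(sp$truth),
                       conditions = c("hit", "correct_rejection",
                                      "false_alarm"))$peaks
  }
  ok_control <- ok_patient <- 0
  n_seeds <- 12
  for (s in seq_len(n_seeds)) {
    pc <- run_session(c(hit = 0.6, false_alarm = 0.6, correct_rejection = 0.3,
                        intermediate = 0.45),
                      observer_preset("categorization", "control",
                                      derive_seed(61L, s)),
                      derive_seed(62L, s))
    pp <- run_session(c(hit = 0.4, false_alarm = 0.4, correct_rejection = 0.4,
                        intermediate = 0.4),
                      observer_preset("categorization", "patient",
                                      derive_seed(63L, s)),
                      derive_seed(64L, s))
    ok_control <- ok_control +
      (min(pc["hit"], pc["false_alarm"]) - pc["correct_rejection"] > 0.1 &&
       abs(pc["hit"] - pc["false_alarm"]) < 0.15)
    ok_patient <- ok_patient + (max(pp) - min(pp) < 0.15)
  }
  expect_gte(ok_control, n_seeds - 1)
  expect_gte(ok_patient, n_seeds - 1)
})
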