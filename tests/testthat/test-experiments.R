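test_that("trial logs satisfy the design row counts exactly", {
  r2 <- run_exp2(observer_preset("discrimination", "control", 1), seed = 2)
  expect_identical(nrow(r2$log), 160L)
  expect_true(all(table(r2$log$condition) == 40))
  # activities cycle evenly within each pair
  expect_true(all(table(r2$log$activity, r2$log$condition) == 4))

  r3 <- run_exp3_behavioral(observer_preset("categorization", "control", 1),
                            seed = 2)
  expect_identical(nrow(r3$log), 216L)
  expect_true(all(table(r3$log$stimulus_class) == 72))
  expect_true(all(table(r3$log$stimulus_class, r3$log$run) == 8))
})

test_that("experiment runners are deterministic given (observer seed, design seed)", {
  o <- observer_preset("detection", "patient", seed = 4)
  a <- run_exp1(o, seed = 6)
  b <- run_exp1(o, seed = 6)
  expect_identical(a$log, b$log)
  expect_identical(a$threshold, b$threshold)
  # the design seed governs interval assignment; the observer seed governs
  # response draws
  c <- run_exp1(o, seed = 7)
  expect_false(identical(a$log$signal_interval, c$log$signal_interval))
  d <- run_exp1(observer_preset("detection", "patient", seed = 5), seed = 6)
  expect_false(identical(a$log$correct, d$log$correct))

  o2 <- observer_preset("discrimination", "control", seed = 4)
  expect_identical(run_exp2(o2, seed = 6)$log, run_exp2(o2, seed = 6)$log)
})

test_that("an ideal detection observer never reverses and hits the trial cap", {
  ideal <- detection_observer(alpha = 1e9, beta = 2, seed = 1)
  run <- run_exp1(ideal, staircase_config(max_trials = 60), seed = 3)
  expect_identical(length(run$reversal_levels), 0L)
  expect_identical(nrow(run$log), 60L)
  expect_true(is.na(run$threshold))
})

test_that("a guessing observer's staircase drifts to the floor", {
  # huge sigma makes every choice a coin flip; the 2-up/1-down random walk
  # then drifts down because P(down) = 1/2 > P(up) = 1/4 per trial pair
  guess <- detection_observer(alpha = 1e-6, beta = 2, lapse = 0.0, seed = 2)
  ths <- vapply(1:40, function(i) {
    run <- run_exp1(detection_observer(1e-6, 2, seed = derive_seed(5L, i)),
                    seed = derive_seed(6L, i))
    run$threshold
  }, numeric(1))
  expect_lt(mean(ths), 10)
})

test_that("noise-free and guessing discrimination observers bracket accuracy", {
  sharp <- discrimination_observer(gain = 1, sigma = 1e-9, exponent = 1,
                                   seed = 3)
  r <- run_exp2(sharp, seed = 5)
  expect_true(all(r$accuracy$by_condition$pct_correct == 100))

  # chance-level observer: pooled accuracy inside the binomial 99% interval
  flat <- discrimination_observer(gain = 1e-9, sigma = 1, exponent = 1,
                                  seed = 3)
  acc <- mean(run_exp2(flat, seed = 5)$log$correct)
  expect_lt(abs(acc - 0.5), 2.58 * sqrt(0.25 / 160))
})

test_that("control-preset discrimination accuracy declines across the four pairs", {
  p <- vapply(seq_len(nrow(biomotion:::EXP2_PAIRS)), function(j)
    p_correct_discrimination(observer_preset("discrimination", "control", 1),
                             biomotion:::EXP2_PAIRS[j, 1],
                             biomotion:::EXP2_PAIRS[j, 2]),
    numeric(1))
  expect_true(all(diff(p) < 0))
  # and the simulated accuracy over a cohort follows in expectation
  acc <- colMeans(do.call(rbind, lapply(1:200, function(i) {
    o <- observer_preset("discrimination", "control", derive_seed(8L, i))
    run_exp2(o, seed = derive_seed(9L, i))$accuracy$by_condition$pct_correct
  })))
  expect_true(all(diff(acc) < 0))
})

test_that("categorization sessions recover the generating d-prime", {
  # balanced criterion keeps both rates away from saturation, where the
  # log-linear correction would shrink the estimate
  dp <- 2.54
  runs <- lapply(1:60, function(i)
    run_exp3_behavioral(categorization_observer(dp, dp / 2,
                                                seed = derive_seed(13L, i)),
                        seed = derive_seed(14L, i)))
  dps <- vapply(runs, function(r) r$sdt$dprime, numeric(1))
  expect_lt(abs(mean(dps) - dp), 0.15)
})

test_that("zero intermediate evidence makes intermediate trials behave like scrambled", {
  o <- categorization_observer(dprime = 3, criterion = 0.8,
                               intermediate_mean_frac = 0, seed = 21)
  runs <- lapply(1:40, function(i)
    run_exp3_behavioral(categorization_observer(3, 0.8, 0,
                                                seed = derive_seed(23L, i)),
                        seed = derive_seed(24L, i)))
  fa <- mean(vapply(runs, function(r) r$sdt$false_alarms / 72, numeric(1)))
  ir <- mean(vapply(runs, function(r) r$intermediate_biological_rate,
                    numeric(1)))
  se <- sqrt(pnorm(-0.8) * (1 - pnorm(-0.8)) / (40 * 72))
  expect_lt(abs(fa - ir), 5 * se * sqrt(2))
})

test_that("cohort summaries reproduce the group-level orderings", {
  thc <- run_cohort("detection", "control", n = 15, seed = 41)
  thp <- run_cohort("detection", "patient", n = 15, seed = 42)
  expect_gt(thc$mean[["threshold"]], thp$mean[["threshold"]])
  cmp <- compare_cohorts(thc, thp)
  expect_gt(cmp$t, 0)

  dc <- run_cohort("categorization", "control", n = 10, seed = 43)
  dp <- run_cohort("categorization", "patient", n = 10, seed = 44)
  expect_gt(dc$mean[["dprime"]], dp$mean[["dprime"]])
  expect_gt(dp$mean[["fa_rate"]], dc$mean[["fa_rate"]])
  expect_gt(dp$mean[["intermediate_biological_rate"]],
            dc$mean[["intermediate_biological_rate"]])
})

test_that("trial logs serialize to CSV", {
  r <- run_exp2(observer_preset("discrimination", "patient", 2), seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trial_log(r, f)
  back <- utils::read.csv(f)
  expect_identical(nrow(back), nrow(r$log))
  expect_identical(back$correct, r$log$correct)
})
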