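test_that("scrambling preserves every dot's displacement sequence", {
  s <- fixture_walker()
  scr <- scramble_spatial(s, window_deg = 11, seed = 3)
  expect_lt(max(abs(displacements(scr$scrambled) - displacements(s))), 1e-9)
  # first frame inside the window
  expect_true(all(abs(scr$scrambled$positions[1, , ]) <= 5.5))
  # offsets recorded as scrambled minus original first frame
  expect_equal(scr$offsets,
               scr$scrambled$positions[1, , ] - s$positions[1, , ],
               tolerance = 1e-12)
})

test_that("scrambling is deterministic given the seed and static stays static", {
  s <- fixture_walker()
  expect_identical(scramble_spatial(s, 11, seed = 9)$scrambled$positions,
                   scramble_spatial(s, 11, seed = 9)$scrambled$positions)
  p <- action_params("frozen", arm_amp = c(0, 0), elbow_amp = c(0, 0),
                     leg_amp = c(0, 0), knee_amp = c(0, 0),
                     torso_sway_amp = 0, bounce_amp = 0)
  st <- generate_action(p, n_frames = 6)
  sc <- scramble_spatial(st, 11, seed = 2)$scrambled
  for (t in 2:6) expect_equal(sc$positions[t, , ], sc$positions[1, , ])
})

test_that("morph endpoints are exact and interpolation is linear", {
  s <- fixture_walker()
  scr <- scramble_spatial(s, window_deg = 7, seed = 5)
  expect_equal(perturb(s, scr, 0)$positions, s$positions, tolerance = 1e-12)
  expect_equal(perturb(s, scr, 1)$positions, scr$scrambled$positions,
               tolerance = 1e-12)
  mid <- perturb(s, scr, 0.5)$positions
  expect_equal(mid, (s$positions + scr$scrambled$positions) / 2,
               tolerance = 1e-12)
})

test_that("a 15% morph divides the original-to-scrambled segment 15:85", {
  # single static dot at the origin scrambled to (10, 0)
  s <- fixture_path_sequence(matrix(0, nrow = 3, ncol = 2))
  scr <- scramble_spatial(s, window_deg = 0, seed = 1)
  scr$offsets <- matrix(c(10, 0), 1)
  scr$scrambled$positions[, 1, 1] <- 10
  p <- perturb(s, scr, 0.15)
  expect_equal(p$positions[1, 1, ], c(1.5, 0))
})

test_that("morphs preserve per-dot velocities at every level", {
  s <- fixture_walker()
  scr <- scramble_spatial(s, window_deg = 7, seed = 5)
  base <- displacements(s)
  for (lam in c(0.15, 0.30, 0.45, 0.60, 0.375))
    expect_lt(max(abs(displacements(perturb(s, scr, lam)) - base)), 1e-9)
})

test_that("motion energy is invariant across morph levels of one action", {
  s <- fixture_walker()
  scr <- scramble_spatial(s, window_deg = 7, seed = 5)
  ref <- motion_energy(s)
  for (lam in c(0.15, 0.45, 1)) {
    me <- motion_energy(perturb(s, scr, lam))
    expect_equal(me$angular_deviation_total, ref$angular_deviation_total,
                 tolerance = 1e-9)
    expect_equal(me$path_excursion_total, ref$path_excursion_total,
                 tolerance = 1e-9)
  }
})

test_that("perturb validates its inputs", {
  s <- fixture_walker()
  scr <- scramble_spatial(s, 7, seed = 1)
  expect_error(perturb(s, scr, -0.1), "lam")
  expect_error(perturb(s, scr, 1.1), "lam")
  other <- scramble_spatial(fixture_walker(10L), 7, seed = 1)
  expect_error(perturb(s, other, 0.5), "inconsistent")
})

test_that("motion energy matches closed forms on constructed paths", {
  # straight line: 10 unit displacements, no direction change
  line <- fixture_path_sequence(cbind(0:10, 0))
  me <- motion_energy(line)
  expect_equal(me$path_excursion_total, 10)
  expect_equal(me$angular_deviation_total, 0)

  # closed square path returning to the initial direction: four 90-deg
  # turns, the exterior-angle sum of a convex closed path
  sq <- fixture_path_sequence(rbind(c(0, 0), c(1, 0), c(2, 0), c(2, 1),
                                    c(2, 2), c(1, 2), c(0, 2), c(0, 1),
                                    c(0, 0), c(1, 0)))
  expect_equal(motion_energy(sq)$angular_deviation_total, 360)

  # static sequence: both components zero
  st <- fixture_path_sequence(matrix(0, 5, 2))
  me0 <- motion_energy(st)
  expect_equal(me0$angular_deviation_total, 0)
  expect_equal(me0$path_excursion_total, 0)

  expect_error(motion_energy(fixture_path_sequence(matrix(0, 2, 2))),
               "3 frames")
})

test_that("noise masking keeps figure geometry and copies trajectories", {
  s <- fixture_walker()
  spec <- noise_mask_spec(n_noise = 60, seed = 11)
  masked <- add_noise_mask(s, spec)
  expect_identical(dim(masked$positions)[2], 72L)

  # jittered figure keeps its pairwise inter-dot distances
  fig <- masked$positions[, attr(masked, "figure_dots"), , drop = FALSE]
  d0 <- dist(s$positions[1, , ])
  d1 <- dist(fig[1, , ])
  # the permutation reorders dots, so compare sorted distance sets
  expect_equal(sort(as.vector(d1)), sort(as.vector(d0)), tolerance = 1e-9)

  # every noise dot replays some figure dot's displacements modulo the
  # window wrap
  w <- spec$window_deg
  base_disp <- displacements(s)
  noise_idx <- which(!attr(masked, "figure_dots"))
  src <- attr(masked, "noise_source")[noise_idx]
  for (k in seq_along(noise_idx)) {
    nd <- masked$positions[-1, noise_idx[k], ] -
      masked$positions[-dim(masked$positions)[1], noise_idx[k], ]
    resid <- (nd - base_disp[, src[k], ]) %% w
    resid <- pmin(resid, w - resid)
    expect_lt(max(abs(resid)), 1e-9)
  }
})

test_that("zero noise dots and zero jitter leave the figure untouched", {
  s <- fixture_walker()
  spec <- noise_mask_spec(n_noise = 0, jitter_deg = 0, seed = 4)
  masked <- add_noise_mask(s, spec)
  expect_identical(dim(masked$positions)[2], 12L)
  perm_inv <- order(order(counter_uniform(4L, 2 + seq_len(12))))
  reordered <- masked$positions[, perm_inv, , drop = FALSE]
  expect_equal(reordered, s$positions, tolerance = 1e-12)
})

test_that("noise mask spec validates its fields", {
  expect_error(noise_mask_spec(-1), "n_noise")
  expect_error(noise_mask_spec(5, window_deg = 5, figure_window_deg = 7),
               "window_deg")
})
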