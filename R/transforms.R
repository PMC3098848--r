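# add a per-dot constant (D x 2) to every frame of a T x D x 2 array
.shift_dots <- function(pos, off, scale = 1) {
  Tn <- dim(pos)[1]; D <- dim(pos)[2]
  pos[, , 1] <- pos[, , 1] + matrix(scale * off[, 1], Tn, D, byrow = TRUE)
  pos[, , 2] <- pos[, , 2] + matrix(scale * off[, 2], Tn, D, byrow = TRUE)
  pos
}

# Stimulus manipulations: first-frame spatial scrambling, graded perturbation
# morphs, trajectory-matched noise masking, figure-position jitter, and the
# motion-energy index. The common contract is velocity invariance: every
# manipulation except masking leaves each dot's frame-to-frame displacement
# vectors untouched, so local motion cannot betray the manipulation.

#' Spatially scramble a point-light sequence
#'
#' Redraws each dot's first-frame position uniformly inside a square window
#' centred on fixation and then replays the dot's original displacement
#' sequence from the new start, destroying the global body structure while
#' preserving every local trajectory.
#'
#' @param seq a [pl_sequence()].
#' @param window_deg side of the square window for the randomized first
#'   frame; the 11-deg noise field for masked detection stimuli, the figure
#'   box (7 deg) for morph endpoints.
#' @param seed integer seed; scrambling is deterministic given it.
#' @return an object of class `pl_scramble`: list with `scrambled`
#'   (a [pl_sequence()]), `offsets` (D x 2 matrix of first-frame
#'   displacements, scrambled minus original), `seed`, `window_deg`.
#' @export
scramble_spatial <- function(seq, window_deg = 11, seed = 1L) {
  stopifnot(inherits(seq, "pl_sequence"))
  if (!is.numeric(window_deg) || window_deg < 0)
    stop("`window_deg` must be >= 0")
  D <- n_dots(seq)
  u <- counter_uniform(seed, seq_len(2L * D))
  new1 <- cbind(window_deg * (u[seq_len(D)] - 0.5),
                window_deg * (u[D + seq_len(D)] - 0.5))
  offsets <- new1 - matrix(seq$positions[1, , ], ncol = 2)
  pos <- .shift_dots(seq$positions, offsets)
  scrambled <- pl_sequence(pos, seq$frame_duration_s, seq$dot_labels,
                           paste0(seq$action_name, "_scrambled"),
                           is_cyclic = seq$is_cyclic)
  structure(list(scrambled = scrambled, offsets = offsets,
                 seed = seed, window_deg = window_deg),
            class = "pl_scramble")
}

#' Graded perturbation morph between a sequence and its scramble
#'
#' Places every dot at the point dividing the segment from its normal to its
#' scrambled position in the ratio `lam : (1 - lam)`, at every frame. Because
#' the scramble preserves displacements, this reduces to a per-dot constant
#' translation of `lam * offsets`, so per-dot velocities are unchanged at
#' every morph level.
#'
#' @param seq the original [pl_sequence()].
#' @param scr the [scramble_spatial()] result derived from `seq`.
#' @param lam morph weight in `[0, 1]`; 0 returns the original, 1 the
#'   scrambled endpoint, 0.15 the "15 percent perturbed" stimulus.
#' @return a [pl_sequence()].
#' @export
perturb <- function(seq, scr, lam) {
  stopifnot(inherits(seq, "pl_sequence"), inherits(scr, "pl_scramble"))
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0 || lam > 1)
    stop("`lam` must be a single value in [0, 1]")
  if (!identical(dim(scr$scrambled$positions), dim(seq$positions)))
    stop("`scr` is inconsistent with `seq`: dimensions differ")
  expected <- .shift_dots(seq$positions, scr$offsets)
  if (max(abs(expected - scr$scrambled$positions)) > 1e-6)
    stop("`scr` is inconsistent with `seq`: it was not derived from this sequence")
  pos <- .shift_dots(seq$positions, scr$offsets, scale = lam)
  pl_sequence(pos, seq$frame_duration_s, seq$dot_labels,
              sprintf("%s_perturbed_%d", seq$action_name, round(100 * lam)),
              is_cyclic = seq$is_cyclic)
}

#' Noise-mask specification
#'
#' @param n_noise number of noise dots (>= 0).
#' @param window_deg side of the square display window holding all dots.
#' @param figure_window_deg side of the central box the figure occupies.
#' @param jitter_deg maximum trial-to-trial displacement of the figure from
#'   the window centre (uniform draw in a disc of this radius).
#' @param dot_size_arcmin nominal rendered dot size (metadata only).
#' @param seed integer seed.
#' @return an object of class `noise_mask_spec`.
#' @export
noise_mask_spec <- function(n_noise, window_deg = 11, figure_window_deg = 7,
                            jitter_deg = 1.4, dot_size_arcmin = 5, seed = 1L) {
  if (!is.numeric(n_noise) || n_noise < 0 || n_noise != round(n_noise))
    stop("`n_noise` must be a non-negative integer")
  if (window_deg < figure_window_deg)
    stop("`window_deg` must be >= `figure_window_deg`")
  structure(list(n_noise = as.integer(n_noise), window_deg = window_deg,
                 figure_window_deg = figure_window_deg, jitter_deg = jitter_deg,
                 dot_size_arcmin = dot_size_arcmin, seed = as.integer(seed)),
            class = "noise_mask_spec")
}

#' Embed a figure in trajectory-matched noise
#'
#' Translates the figure by a random jitter about the window centre, then
#' adds `n_noise` dots, each of which replays the full displacement
#' trajectory of a randomly chosen figure dot (with replacement) from a
#' random start inside the window; noise positions wrap torus-style at the
#' window edge so density stays constant. Dot order is randomized so the
#' figure cannot be identified by index. The permutation and each noise
#' dot's source are kept as attributes (`figure_dots`, `noise_source`) for
#' analysis provenance; they are no part of the rendered stimulus.
#'
#' @param figure a [pl_sequence()] (the biological or scrambled figure).
#' @param spec a [noise_mask_spec()].
#' @return a [pl_sequence()] with `12 + n_noise` dots.
#' @export
add_noise_mask <- function(figure, spec) {
  stopifnot(inherits(figure, "pl_sequence"), inherits(spec, "noise_mask_spec"))
  Tn <- n_frames(figure); D <- n_dots(figure)
  w <- spec$window_deg
  seed <- spec$seed

  # jitter: uniform in a disc of radius jitter_deg about the window centre
  u <- counter_uniform(seed, 1:2)
  r <- spec$jitter_deg * sqrt(u[1]); a <- 2 * pi * u[2]
  fig <- figure$positions
  fig[, , 1] <- fig[, , 1] + r * cos(a)
  fig[, , 2] <- fig[, , 2] + r * sin(a)

  nn <- spec$n_noise
  if (nn > 0L) {
    src <- 1L + floor(D * counter_uniform(seed, 2L + seq_len(nn)))
    u0 <- counter_uniform(seed, 2L + nn + seq_len(2L * nn))
    start <- cbind(w * (u0[seq_len(nn)] - 0.5), w * (u0[nn + seq_len(nn)] - 0.5))
    noise <- array(NA_real_, c(Tn, nn, 2))
    wrap <- function(x) ((x + w / 2) %% w) - w / 2
    for (j in seq_len(nn)) {
      traj <- figure$positions[, src[j], ] # displacements only are used
      noise[, j, 1] <- wrap(start[j, 1] + traj[, 1] - traj[1, 1])
      noise[, j, 2] <- wrap(start[j, 2] + traj[, 2] - traj[1, 2])
    }
    all_pos <- array(NA_real_, c(Tn, D + nn, 2))
    all_pos[, seq_len(D), ] <- fig
    all_pos[, D + seq_len(nn), ] <- noise
  } else {
    all_pos <- fig
  }

  total <- D + nn
  perm <- order(counter_uniform(seed, 2L + 3L * nn + seq_len(total)))
  all_pos <- all_pos[, perm, , drop = FALSE]
  out <- pl_sequence(all_pos, figure$frame_duration_s,
                     sprintf("dot%03d", seq_len(total)),
                     paste0(figure$action_name, "_masked"))
  attr(out, "figure_dots") <- perm <= D
  attr(out, "noise_source") <- ifelse(perm > D,
                                      if (nn > 0L) src[pmax(perm - D, 1L)] else NA_integer_,
                                      NA_integer_)
  out
}

#' Motion-energy index of a sequence
#'
#' Two related summaries of how much the dots move: `excursion` is the total
#' path length traced by all dots (deg), and `angular` is the total
#' unsigned change in each dot's direction of motion, summed over dots and
#' frame transitions (deg), with direction changes undefined around zero
#' displacements contributing 0. Both are invariant across morph levels of
#' one action because morphs preserve per-dot velocities.
#'
#' @param seq a [pl_sequence()]; the angular method needs at least 3 frames.
#' @param method which component to report as `value`; both are computed.
#' @return an object of class `motion_energy`: list with
#'   `angular_deviation_total`, `path_excursion_total`, `method`, `value`.
#' @export
motion_energy <- function(seq, method = c("angular", "excursion")) {
  stopifnot(inherits(seq, "pl_sequence"))
  method <- match.arg(method)
  Tn <- n_frames(seq)
  if (method == "angular" && Tn < 3L)
    stop("angular motion energy needs at least 3 frames")
  pos <- seq$positions
  dx <- pos[-1L, , 1, drop = FALSE] - pos[-Tn, , 1, drop = FALSE]
  dy <- pos[-1L, , 2, drop = FALSE] - pos[-Tn, , 2, drop = FALSE]
  dx <- array(dx, dim(dx)[1:2]); dy <- array(dy, dim(dy)[1:2])
  step <- sqrt(dx^2 + dy^2)
  excursion <- sum(step)

  angular <- 0
  if (Tn >= 3L) {
    theta <- atan2(dy, dx)
    for (i in seq_len(ncol(theta))) {
      ok <- step[, i] > 0
      dth <- diff(theta[, i])
      both <- ok[-length(ok)] & ok[-1]
      dth <- dth[both]
      dth <- ((dth + pi) %% (2 * pi)) - pi # wrap to (-pi, pi]
      angular <- angular + sum(abs(dth))
    }
    angular <- angular * 180 / pi
  }
  structure(list(angular_deviation_total = angular,
                 path_excursion_total = excursion,
                 method = method,
                 value = if (method == "angular") angular else excursion),
            class = "motion_energy")
}

#' @export
print.motion_energy <- function(x, ...) {
  cat(sprintf("<motion_energy: angular %.1f deg, excursion %.2f deg (method: %s)>\n",
              x$angular_deviation_total, x$path_excursion_total, x$method))
  invisible(x)
}
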