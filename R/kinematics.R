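# Parametric point-light action sequences.
#
# Twelve dots mark the head, torso and major joints of an articulated figure
# whose limbs swing as sinusoidal pendulums about torso-anchored pivots.
# Generated sequences are scaled so the mean per-dot speed is 4 deg/s and the
# full space-time bounding box fits inside a 7 x 7 deg window centred on
# fixation, the geometry used for the masked-detection display.

PL_DOT_LABELS <- c("head", "torso",
                   "elbow_l", "elbow_r", "wrist_l", "wrist_r",
                   "hip_l", "hip_r", "knee_l", "knee_r",
                   "ankle_l", "ankle_r")

#' Point-light sequence container
#'
#' @param positions numeric array `T x D x 2` of (x, y) dot positions in
#'   degrees of visual angle; x rightward, y upward, origin at fixation.
#' @param frame_duration_s duration of one frame in seconds.
#' @param dot_labels character vector of length `D`.
#' @param action_name label carried through transforms.
#' @param is_cyclic whether the action repeats with the cycle period.
#' @return an object of class `pl_sequence`.
#' @export
pl_sequence <- function(positions, frame_duration_s, dot_labels = NULL,
                        action_name = "custom", is_cyclic = FALSE) {
  if (!is.array(positions) || length(dim(positions)) != 3L || dim(positions)[3] != 2L)
    stop("`positions` must be a T x D x 2 array")
  if (dim(positions)[1] < 2L) stop("a sequence needs at least 2 frames")
  if (!all(is.finite(positions))) stop("all coordinates must be finite")
  if (!is.numeric(frame_duration_s) || length(frame_duration_s) != 1L ||
      frame_duration_s <= 0)
    stop("`frame_duration_s` must be a positive scalar")
  D <- dim(positions)[2]
  if (is.null(dot_labels)) {
    dot_labels <- if (D == 12L) PL_DOT_LABELS else sprintf("dot%02d", seq_len(D))
  }
  if (length(dot_labels) != D)
    stop("`dot_labels` must have one entry per dot")
  structure(list(positions = positions,
                 frame_duration_s = frame_duration_s,
                 dot_labels = as.character(dot_labels),
                 action_name = as.character(action_name),
                 is_cyclic = isTRUE(is_cyclic)),
            class = "pl_sequence")
}

#' @export
print.pl_sequence <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("<pl_sequence '%s': %d frames x %d dots, %.0f ms/frame, %.2f s%s>\n",
              x$action_name, d[1], d[2], 1000 * x$frame_duration_s,
              d[1] * x$frame_duration_s, if (x$is_cyclic) ", cyclic" else ""))
  invisible(x)
}

#' @export
plot.pl_sequence <- function(x, frame = 1L, ...) {
  p <- x$positions[frame, , , drop = FALSE]
  graphics::plot(p[1, , 1], p[1, , 2], asp = 1, pch = 16,
                 xlab = "x (deg)", ylab = "y (deg)",
                 main = sprintf("%s, frame %d", x$action_name, frame), ...)
  invisible(x)
}

n_frames <- function(seq) dim(seq$positions)[1]
n_dots <- function(seq) dim(seq$positions)[2]

#' Parameters of a synthetic articulated action
#'
#' Describes one action as sinusoidal joint-angle excursions of the four
#' limbs (two segments each, angles measured from straight down, radians)
#' plus torso sway, vertical bounce and a constant whole-body translation.
#' Left/right values are length-2 vectors `(left, right)`.
#'
#' @param action_name preset or free-form name.
#' @param cycle_period_s period of the underlying movement cycle (s).
#' @param translation_deg_s whole-body drift velocity `(vx, vy)` in deg/s.
#' @param arm_mean,arm_amp,arm_phase,arm_freq upper-arm angle: mean, sinusoid
#'   amplitude, phase (radians) and frequency in cycles per period.
#' @param elbow_mean,elbow_amp,elbow_phase forearm flexion relative to the
#'   upper arm.
#' @param leg_mean,leg_amp,leg_phase,leg_freq thigh angle parameters.
#' @param knee_mean,knee_amp,knee_phase shank flexion relative to the thigh.
#' @param torso_sway_amp,torso_sway_phase lateral sway of the trunk axis
#'   (deg of offset per unit body height).
#' @param bounce_amp,bounce_freq,bounce_phase vertical pelvis oscillation.
#' @param phase_jitter_sd standard deviation of per-joint phase jitter
#'   (radians) applied deterministically from the generation seed; 0 gives a
#'   perfectly stereotyped action.
#' @return an object of class `action_params`.
#' @export
action_params <- function(action_name = "custom",
                          cycle_period_s = 1,
                          translation_deg_s = c(0, 0),
                          arm_mean = c(0, 0), arm_amp = c(0.6, 0.6),
                          arm_phase = c(0, pi), arm_freq = 1,
                          elbow_mean = c(0.3, 0.3), elbow_amp = c(0.4, 0.4),
                          elbow_phase = c(0, pi),
                          leg_mean = c(0, 0), leg_amp = c(0.55, 0.55),
                          leg_phase = c(pi, 0), leg_freq = 1,
                          knee_mean = c(-0.25, -0.25), knee_amp = c(0.45, 0.45),
                          knee_phase = c(pi, 0),
                          torso_sway_amp = 0.05, torso_sway_phase = 0,
                          bounce_amp = 0.06, bounce_freq = 2, bounce_phase = 0,
                          phase_jitter_sd = 0) {
  p <- list(action_name = action_name, cycle_period_s = cycle_period_s,
            translation_deg_s = translation_deg_s,
            arm_mean = arm_mean, arm_amp = arm_amp, arm_phase = arm_phase,
            arm_freq = arm_freq,
            elbow_mean = elbow_mean, elbow_amp = elbow_amp,
            elbow_phase = elbow_phase,
            leg_mean = leg_mean, leg_amp = leg_amp, leg_phase = leg_phase,
            leg_freq = leg_freq,
            knee_mean = knee_mean, knee_amp = knee_amp, knee_phase = knee_phase,
            torso_sway_amp = torso_sway_amp, torso_sway_phase = torso_sway_phase,
            bounce_amp = bounce_amp, bounce_freq = bounce_freq,
            bounce_phase = bounce_phase,
            phase_jitter_sd = phase_jitter_sd)
  amps <- c(p$arm_amp, p$elbow_amp, p$leg_amp, p$knee_amp, p$bounce_amp)
  if (any(amps < 0)) stop("amplitudes must be >= 0")
  if (!is.numeric(cycle_period_s) || cycle_period_s <= 0)
    stop("`cycle_period_s` must be > 0")
  if (length(translation_deg_s) != 2L || !all(is.finite(translation_deg_s)))
    stop("`translation_deg_s` must be a finite length-2 vector")
  structure(p, class = "action_params")
}

# skeleton geometry in internal (pre-scaling) units
.SKEL <- list(hip_half = 0.35, shoulder_half = 0.55, shoulder_h = 1.6,
              torso_h = 1.0, head_h = 2.05, upper_arm = 0.75, forearm = 0.75,
              thigh = 0.9, shank = 0.9)

# evaluate the 12-dot pose at times t (vector); returns length(t) x 12 x 2
.pose_at <- function(p, t, jit = rep(0, 8)) {
  S <- .SKEL
  w <- 2 * pi / p$cycle_period_s
  ang <- function(mean2, amp2, ph2, freq, j1, j2)
    cbind(mean2[1] + amp2[1] * sin(w * freq * t + ph2[1] + j1),
          mean2[2] + amp2[2] * sin(w * freq * t + ph2[2] + j2))
  th_ua <- ang(p$arm_mean, p$arm_amp, p$arm_phase, p$arm_freq, jit[1], jit[2])
  th_fo <- ang(p$elbow_mean, p$elbow_amp, p$elbow_phase, p$arm_freq, jit[3], jit[4])
  th_th <- ang(p$leg_mean, p$leg_amp, p$leg_phase, p$leg_freq, jit[5], jit[6])
  th_sh <- ang(p$knee_mean, p$knee_amp, p$knee_phase, p$leg_freq, jit[7], jit[8])

  nt <- length(t)
  pelvis_x <- p$translation_deg_s[1] * t
  pelvis_y <- p$translation_deg_s[2] * t +
    p$bounce_amp * sin(w * p$bounce_freq * t + p$bounce_phase)
  sway <- p$torso_sway_amp * sin(w * t + p$torso_sway_phase)

  pos <- array(NA_real_, c(nt, 12, 2))
  put <- function(i, x, y) { pos[, i, 1] <<- x; pos[, i, 2] <<- y }
  put(1, pelvis_x + sway * S$head_h, pelvis_y + S$head_h)           # head
  put(2, pelvis_x + sway * S$torso_h, pelvis_y + S$torso_h)         # torso
  for (side in 1:2) {                                               # arms
    sgn <- if (side == 1) -1 else 1
    shx <- pelvis_x + sgn * S$shoulder_half + sway * S$shoulder_h
    shy <- pelvis_y + S$shoulder_h
    ex <- shx + S$upper_arm * sin(th_ua[, side])
    ey <- shy - S$upper_arm * cos(th_ua[, side])
    wx <- ex + S$forearm * sin(th_ua[, side] + th_fo[, side])
    wy <- ey - S$forearm * cos(th_ua[, side] + th_fo[, side])
    put(2 + side, ex, ey)        # elbows at 3, 4
    put(4 + side, wx, wy)        # wrists at 5, 6
  }
  for (side in 1:2) {                                               # legs
    sgn <- if (side == 1) -1 else 1
    hx <- pelvis_x + sgn * S$hip_half
    hy <- pelvis_y
    kx <- hx + S$thigh * sin(th_th[, side])
    ky <- hy - S$thigh * cos(th_th[, side])
    ax <- kx + S$shank * sin(th_th[, side] + th_sh[, side])
    ay <- ky - S$shank * cos(th_th[, side] + th_sh[, side])
    put(6 + side, hx, hy)        # hips at 7, 8
    put(8 + side, kx, ky)        # knees at 9, 10
    put(10 + side, ax, ay)       # ankles at 11, 12
  }
  pos
}

#' Generate a point-light action sequence
#'
#' Evaluates the articulated figure described by `params` at `n_frames`
#' instants, then rescales uniformly so the mean per-dot speed is exactly
#' 4 deg/s (skipped for a fully static figure) and recentres the space-time
#' bounding box on fixation. An error is raised if the speed-normalised
#' figure does not fit the 7 x 7 deg stimulus box, which marks the
#' parameters as invalid for experiment use.
#'
#' @param params an [action_params()] object.
#' @param n_frames number of frames (>= 2); 20 frames at 50 ms give the 1-s
#'   sequences used throughout the experiments.
#' @param frame_duration_s frame duration in seconds.
#' @param seed integer seed; only consumed by the optional per-joint phase
#'   jitter, so generation is bit-reproducible given (params, seed).
#' @param speed_deg_s target mean per-dot speed (deg/s).
#' @param box_deg side of the square window the figure must fit (deg).
#' @return a [pl_sequence()].
#' @export
generate_action <- function(params, n_frames = 20L, frame_duration_s = 0.05,
                            seed = 1L, speed_deg_s = 4, box_deg = 7) {
  if (!inherits(params, "action_params")) stop("`params` must be action_params")
  if (n_frames < 2L) stop("`n_frames` must be >= 2")
  jit <- if (params$phase_jitter_sd > 0)
    params$phase_jitter_sd * counter_norm(seed, 1:8) else rep(0, 8)
  t <- (seq_len(n_frames) - 1L) * frame_duration_s
  pos <- .pose_at(params, t, jit)

  # uniform rescale to the target mean per-dot speed
  disp <- pos[-1L, , , drop = FALSE] - pos[-n_frames, , , drop = FALSE]
  path <- apply(sqrt(disp[, , 1]^2 + disp[, , 2]^2), 2, sum)
  vbar <- mean(path) / ((n_frames - 1L) * frame_duration_s)
  if (vbar > 0) pos <- pos * (speed_deg_s / vbar)

  # recentre the space-time bounding box on fixation
  rx <- range(pos[, , 1]); ry <- range(pos[, , 2])
  pos[, , 1] <- pos[, , 1] - mean(rx)
  pos[, , 2] <- pos[, , 2] - mean(ry)
  if (diff(rx) > box_deg || diff(ry) > box_deg)
    stop(sprintf(
      "invalid action parameters: speed-normalised figure spans %.2f x %.2f deg, exceeding the %g deg box",
      diff(rx), diff(ry), box_deg))

  pl_sequence(pos, frame_duration_s, PL_DOT_LABELS, params$action_name,
              is_cyclic = all(params$translation_deg_s == 0))
}

#' Named action presets
#'
#' A library of parametric stand-ins for motion-capture actions: walking
#' variants, jumps, kicks, throws and a crouch, each a distinct setting of
#' the limb sinusoids. `exp2_activities()` names the ten presets used for
#' the graded-perturbation discrimination design.
#'
#' @return `action_presets()`: a named list of [action_params()];
#'   `exp2_activities()`: a character vector of ten preset names.
#' @export
action_presets <- function() {
  ap <- action_params
  list(
    walk = ap("walk", translation_deg_s = c(1.6, 0)),
    walk_back = ap("walk_back", translation_deg_s = c(-1.4, 0),
                   arm_amp = c(0.45, 0.45), leg_amp = c(0.5, 0.5)),
    run = ap("run", cycle_period_s = 0.7, translation_deg_s = c(2.2, 0),
             arm_amp = c(0.9, 0.9), leg_amp = c(0.8, 0.8),
             knee_amp = c(0.8, 0.8), bounce_amp = 0.12),
    climb = ap("climb", cycle_period_s = 0.8, translation_deg_s = c(0.6, 1.1),
               arm_mean = c(1.5, 1.5), arm_amp = c(0.7, 0.7),
               elbow_amp = c(0.6, 0.6),
               leg_amp = c(0.8, 0.8), knee_mean = c(-0.5, -0.5),
               knee_amp = c(0.7, 0.7), bounce_amp = 0.1),
    jump = ap("jump", translation_deg_s = c(0, 0),
              arm_phase = c(0, 0), arm_amp = c(1.0, 1.0),
              leg_phase = c(0, 0), leg_amp = c(0.35, 0.35),
              knee_phase = c(0, 0), knee_amp = c(0.7, 0.7),
              bounce_amp = 0.35, bounce_freq = 1),
    rope_jump = ap("rope_jump", cycle_period_s = 0.5,
                   arm_mean = c(0.9, 0.9), arm_amp = c(0.35, 0.35),
                   arm_phase = c(0, 0), elbow_amp = c(0.7, 0.7),
                   elbow_phase = c(0, 0), leg_phase = c(0, 0),
                   leg_amp = c(0.2, 0.2), knee_phase = c(0, 0),
                   knee_amp = c(0.45, 0.45), bounce_amp = 0.22,
                   bounce_freq = 1),
    crouch_jump = ap("crouch_jump", arm_phase = c(0, 0),
                     arm_amp = c(0.8, 0.8), leg_phase = c(0, 0),
                     leg_mean = c(-0.35, 0.35), leg_amp = c(0.4, 0.4),
                     knee_mean = c(-0.9, -0.9), knee_amp = c(0.75, 0.75),
                     knee_phase = c(0, 0), bounce_amp = 0.3, bounce_freq = 1),
    kick_front = ap("kick_front", leg_amp = c(0.15, 1.2),
                    leg_phase = c(pi, 0), knee_amp = c(0.2, 0.9),
                    knee_phase = c(pi, 0.6), arm_amp = c(0.5, 0.5),
                    bounce_amp = 0.08),
    kick_side = ap("kick_side", leg_amp = c(0.2, 1.0),
                   leg_mean = c(0, 0.45), knee_amp = c(0.25, 0.7),
                   arm_amp = c(0.6, 0.4), torso_sway_amp = 0.12),
    kick_soccer = ap("kick_soccer", cycle_period_s = 0.8,
                     leg_amp = c(0.25, 1.3), knee_amp = c(0.3, 1.0),
                     knee_phase = c(pi, 0.9), arm_amp = c(0.7, 0.55),
                     bounce_amp = 0.1),
    toss = ap("toss", cycle_period_s = 0.7, arm_amp = c(0.4, 1.2),
              arm_mean = c(0, 0.3), elbow_amp = c(0.3, 0.9),
              leg_amp = c(0.35, 0.35), knee_amp = c(0.35, 0.35),
              bounce_amp = 0.12),
    bowl = ap("bowl", arm_amp = c(0.3, 1.3), arm_mean = c(0, -0.2),
              elbow_amp = c(0.15, 0.3), leg_amp = c(0.35, 0.35),
              knee_mean = c(-0.45, -0.45), bounce_amp = 0.12),
    throw_over = ap("throw_over", cycle_period_s = 0.7,
                    arm_mean = c(0.1, 1.4), arm_amp = c(0.5, 1.2),
                    elbow_amp = c(0.3, 1.0), elbow_phase = c(0, pi / 2),
                    leg_amp = c(0.4, 0.4), knee_amp = c(0.5, 0.5),
                    torso_sway_amp = 0.1, bounce_amp = 0.1),
    throw_under = ap("throw_under", cycle_period_s = 0.7,
                     arm_mean = c(0.1, -0.3), arm_amp = c(0.5, 1.3),
                     elbow_amp = c(0.25, 0.4), leg_amp = c(0.5, 0.5),
                     knee_mean = c(-0.35, -0.35), knee_amp = c(0.5, 0.5),
                     bounce_amp = 0.1),
    crouch = ap("crouch", cycle_period_s = 0.8,
                arm_amp = c(0.7, 0.7), arm_phase = c(0, 0),
                arm_mean = c(0.4, 0.4), leg_mean = c(-0.4, 0.4),
                leg_amp = c(0.45, 0.45), leg_phase = c(0, 0),
                knee_mean = c(-0.9, -0.9), knee_amp = c(0.7, 0.7),
                knee_phase = c(0, 0), bounce_amp = 0.3, bounce_freq = 1)
  )
}

#' @rdname action_presets
#' @export
exp2_activities <- function() {
  c("jump", "kick_side", "crouch_jump", "kick_soccer", "kick_front",
    "walk_back", "bowl", "rope_jump", "toss", "throw_over")
}

#' Mean per-dot speed of a sequence (deg/s)
#' @param seq a [pl_sequence()].
#' @export
mean_dot_speed <- function(seq) {
  pos <- seq$positions
  Tn <- dim(pos)[1]
  disp <- pos[-1L, , , drop = FALSE] - pos[-Tn, , , drop = FALSE]
  path <- apply(sqrt(disp[, , 1]^2 + disp[, , 2]^2), 2, sum)
  mean(path) / ((Tn - 1L) * seq$frame_duration_s)
}
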