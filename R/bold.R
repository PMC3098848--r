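# Synthetic event-related / block-design BOLD on a voxel lattice, and the
# ROI analysis chain: GLM contrasts, FDR (or uncorrected-fallback)
# thresholding with 6-connectivity contiguity filtering, event-related
# averaging in percent-signal units, and the peak percent-signal-change
# summary taken from the raw averaged time course (no curve fitting).

#' Double-gamma hemodynamic response function
#'
#' Canonical difference-of-gammas impulse response (peak near 5-6 s,
#' undershoot near 15 s), normalized to unit peak on a fine grid.
#'
#' @param t times in seconds (>= 0; negative times return 0).
#' @param peak_shape,undershoot_shape gamma shape parameters (rate 1).
#' @param undershoot_ratio relative undershoot amplitude.
#' @return HRF values, unit peak.
#' @export
hrf_double_gamma <- function(t, peak_shape = 6, undershoot_shape = 16,
                             undershoot_ratio = 1 / 6) {
  raw <- function(x) stats::dgamma(x, shape = peak_shape, rate = 1) -
    undershoot_ratio * stats::dgamma(x, shape = undershoot_shape, rate = 1)
  fine <- seq(0, 40, by = 0.01)
  peak <- max(raw(fine))
  ifelse(t < 0, 0, raw(t) / peak)
}

#' fMRI designs: event-related and block
#'
#' `event_design()` lays out one event per behavioural trial at a constant
#' stimulus-plus-ISI spacing (1 s + 11 s by default), labelling each event
#' with its response-contingent condition. `block_design()` lays out
#' alternating condition blocks (7 x 14 s per condition for the
#' biological-vs-scrambled localizer; 14 blocks per condition for the
#' motion-vs-static localizer).
#'
#' @param conditions character vector: one condition label per event (for
#'   events, typically the `condition` column of a categorization trial
#'   log), or the pair of alternating labels for blocks.
#' @param TR_s repetition time (s).
#' @param stimulus_duration_s event duration (s).
#' @param isi_s inter-stimulus interval (s).
#' @param initial_rest_s rest before the first onset (s).
#' @param final_rest_s rest appended after the last event window (s).
#' @return an object of class `fmri_design`: data frame `events` (onset_s,
#'   duration_s, condition) plus `TR_s`, `run_length_s`, `n_volumes`.
#' @export
event_design <- function(conditions, TR_s = 2, stimulus_duration_s = 1,
                         isi_s = 11, initial_rest_s = 12, final_rest_s = 14) {
  stopifnot(length(conditions) >= 1, TR_s > 0, stimulus_duration_s > 0,
            isi_s >= 0)
  n <- length(conditions)
  onsets <- initial_rest_s + (seq_len(n) - 1L) * (stimulus_duration_s + isi_s)
  run_length <- onsets[n] + stimulus_duration_s + final_rest_s
  .fmri_design(data.frame(onset_s = onsets,
                          duration_s = stimulus_duration_s,
                          condition = as.character(conditions)),
               TR_s, run_length)
}

#' @rdname event_design
#' @param block_length_s block duration (s).
#' @param n_blocks_per_condition number of blocks of each condition.
#' @export
block_design <- function(conditions = c("biological", "scrambled"),
                         block_length_s = 14, n_blocks_per_condition = 7,
                         TR_s = 2, initial_rest_s = 8, final_rest_s = 14) {
  stopifnot(length(conditions) == 2L, block_length_s > 0,
            n_blocks_per_condition >= 1)
  labels <- rep(conditions, times = n_blocks_per_condition)
  onsets <- initial_rest_s + (seq_along(labels) - 1L) * block_length_s
  run_length <- onsets[length(onsets)] + block_length_s + final_rest_s
  .fmri_design(data.frame(onset_s = onsets, duration_s = block_length_s,
                          condition = labels),
               TR_s, run_length)
}

.fmri_design <- function(events, TR_s, run_length_s) {
  structure(list(events = events, TR_s = TR_s,
                 run_length_s = run_length_s,
                 n_volumes = ceiling(run_length_s / TR_s)),
            class = "fmri_design")
}

#' @export
print.fmri_design <- function(x, ...) {
  cat(sprintf("<fmri_design: %d events (%s), TR %g s, %d volumes (%.0f s)>\n",
              nrow(x$events),
              paste(names(table(x$events$condition)), collapse = ", "),
              x$TR_s, x$n_volumes, x$run_length_s))
  invisible(x)
}

# response of one event (unit amplitude) sampled at times `t` after onset:
# boxcar of `duration` convolved with the HRF, normalized to unit peak so
# simulated amplitudes are peak percent-signal changes
.event_response <- function(t, duration, hrf_params = list(), dt = 0.05) {
  grid <- seq(0, 40 + duration, by = dt)
  h <- do.call(hrf_double_gamma, c(list(t = grid), hrf_params))
  box <- as.numeric(grid < duration)
  conv <- stats::convolve(box, rev(h), type = "open")[seq_along(grid)] * dt
  conv <- conv / max(conv)
  out <- numeric(length(t))
  ok <- t >= 0 & t <= max(grid)
  out[ok] <- stats::approx(grid, conv, xout = t[ok])$y
  out
}

# condition regressors sampled at volume times; unit peak per isolated event
.design_matrix <- function(design, hrf_params = list()) {
  tv <- (seq_len(design$n_volumes) - 1L) * design$TR_s
  conds <- unique(design$events$condition)
  X <- sapply(conds, function(cn) {
    ev <- design$events[design$events$condition == cn, ]
    rowSums(sapply(seq_len(nrow(ev)), function(i)
      .event_response(tv - ev$onset_s[i], ev$duration_s[i], hrf_params)))
  })
  colnames(X) <- conds
  X
}

#' Specification of a synthetic voxel lattice
#'
#' A 3D grid of voxels with one embedded ellipsoidal "responsive region"
#' whose voxels carry the condition signal; every voxel gets AR(1)-plus-
#' white noise in percent-signal units around a constant baseline. The
#' default region holds about 60 voxels, inside the 15-174 voxel range the
#' localizer analysis is expected to produce.
#'
#' @param dim lattice dimensions (voxels).
#' @param center,radii ellipsoid centre and semi-axes (voxel units).
#' @param baseline mean signal level (arbitrary scanner units).
#' @param noise_sd stationary noise SD in percent of baseline.
#' @param ar1 lag-1 autocorrelation of the noise.
#' @return an object of class `lattice_spec`; `truth` is the logical 3D
#'   membership mask of the responsive region.
#' @export
lattice_spec <- function(dim = c(20, 20, 10), center = NULL,
                         radii = c(3, 2.5, 2), baseline = 100,
                         noise_sd = 0.5, ar1 = 0.3) {
  stopifnot(length(dim) == 3L, all(dim >= 1), baseline > 0, noise_sd >= 0,
            abs(ar1) < 1)
  if (is.null(center)) center <- (dim + 1) / 2
  idx <- as.matrix(expand.grid(x = seq_len(dim[1]), y = seq_len(dim[2]),
                               z = seq_len(dim[3])))
  inside <- ((idx[, 1] - center[1]) / radii[1])^2 +
    ((idx[, 2] - center[2]) / radii[2])^2 +
    ((idx[, 3] - center[3]) / radii[3])^2 <= 1
  truth <- array(inside, dim)
  structure(list(dim = dim, truth = truth, baseline = baseline,
                 noise_sd = noise_sd, ar1 = ar1),
            class = "lattice_spec")
}

#' Simulate BOLD time series on a voxel lattice
#'
#' Every truth-region voxel's series is baseline times one plus the summed
#' per-event responses (condition amplitude x unit-peak double-gamma
#' response) plus noise, in percent; other voxels get noise only. The noise
#' is stationary AR(1) with white innovations, identical in distribution
#' across voxels and independent between voxels.
#'
#' @param design an [event_design()] or [block_design()].
#' @param spec a [lattice_spec()].
#' @param amplitudes named vector: peak percent-signal amplitude per
#'   condition; conditions missing from it get amplitude 0.
#' @param seed integer seed (drives the R RNG for the noise field).
#' @param hrf_params optional list passed to [hrf_double_gamma()].
#' @return an object of class `bold_sim`: list with `data` (4D array
#'   x,y,z,t in scanner units), `spec`, `design`, `amplitudes`.
#' @export
simulate_bold <- function(design, spec = lattice_spec(), amplitudes,
                          seed = 1L, hrf_params = list()) {
  stopifnot(inherits(design, "fmri_design"), inherits(spec, "lattice_spec"),
            !is.null(names(amplitudes)), all(is.finite(amplitudes)))
  if (nrow(design$events) > 1L &&
      min(diff(sort(design$events$onset_s))) < design$TR_s)
    warning("events closer than one TR; responses superpose")
  nvol <- design$n_volumes
  tv <- (seq_len(nvol) - 1L) * design$TR_s

  signal_pct <- numeric(nvol)
  for (i in seq_len(nrow(design$events))) {
    ev <- design$events[i, ]
    a <- if (ev$condition %in% names(amplitudes)) amplitudes[[ev$condition]] else 0
    if (a != 0)
      signal_pct <- signal_pct +
        a * .event_response(tv - ev$onset_s, ev$duration_s, hrf_params)
  }

  nvox <- prod(spec$dim)
  set.seed(seed)
  innov_sd <- spec$noise_sd * sqrt(1 - spec$ar1^2)
  noise <- matrix(stats::rnorm(nvol * nvox, sd = innov_sd), nvol, nvox)
  if (spec$ar1 != 0) {
    noise[1, ] <- noise[1, ] / sqrt(1 - spec$ar1^2) # stationary start
    for (t in 2:nvol) noise[t, ] <- spec$ar1 * noise[t - 1, ] + noise[t, ]
  }
  pct <- noise + outer(signal_pct, as.numeric(spec$truth))
  # pct is volumes x voxels; the 4D array wants voxel-major order per volume
  data <- array(t(spec$baseline * (1 + pct / 100)), c(spec$dim, nvol))
  structure(list(data = data, spec = spec, design = design,
                 amplitudes = amplitudes, seed = seed,
                 hrf_params = hrf_params),
            class = "bold_sim")
}

#' @export
print.bold_sim <- function(x, ...) {
  cat(sprintf("<bold_sim: %s lattice, %d volumes, %d truth voxels>\n",
              paste(x$spec$dim, collapse = "x"), x$design$n_volumes,
              sum(x$spec$truth)))
  invisible(x)
}

#' Read/write a simulated run as NIfTI
#'
#' @param sim a [simulate_bold()] result.
#' @param path `.nii` or `.nii.gz` file path.
#' @export
write_bold_nifti <- function(sim, path) {
  stopifnot(inherits(sim, "bold_sim"))
  img <- RNifti::asNifti(sim$data)
  RNifti::pixdim(img) <- c(1, 1, 1, sim$design$TR_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @return `read_bold_nifti()`: the 4D data array.
#' @export
read_bold_nifti <- function(path) {
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim(arr))
}

#' Voxelwise GLM contrast
#'
#' Ordinary least squares of every voxel's series on an intercept plus one
#' unit-peak convolved regressor per condition; the contrast is a named
#' weight vector over conditions. Two-sided p-values use the t distribution
#' with residual degrees of freedom.
#'
#' @param sim a `bold_sim` (or 4D array via `data`).
#' @param contrast named numeric vector of condition weights, e.g.
#'   `c(biological = 1, scrambled = -1)`.
#' @param design used when `sim` is a bare array.
#' @param hrf_params passed to the regressor builder.
#' @return an object of class `glm_result`: list with vectors `beta`
#'   (contrast effect, percent), `t`, `p` over voxels (column-major), plus
#'   `df` and `dim`.
#' @export
glm_contrast <- function(sim, contrast, design = NULL, hrf_params = list()) {
  if (inherits(sim, "bold_sim")) {
    design <- sim$design
    if (!length(hrf_params)) hrf_params <- sim$hrf_params
    data <- sim$data
  } else data <- sim
  stopifnot(inherits(design, "fmri_design"), !is.null(names(contrast)))
  d <- dim(data)
  nvol <- d[4]; nvox <- prod(d[1:3])
  Y <- t(array(data, c(nvox, nvol))) # volumes x voxels

  Xc <- .design_matrix(design, hrf_params)
  X <- cbind(`(intercept)` = 1, Xc)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  unknown <- setdiff(names(contrast), colnames(Xc))
  if (length(unknown))
    stop("contrast names not in design: ", paste(unknown, collapse = ", "))
  cvec <- c(0, contrast[match(colnames(Xc), names(contrast))])
  cvec[is.na(cvec)] <- 0

  XtXi <- solve(crossprod(X))
  beta <- XtXi %*% crossprod(X, Y)
  res <- Y - X %*% beta
  df <- nvol - ncol(X)
  sigma2 <- colSums(res^2) / df
  eff <- as.numeric(crossprod(cvec, beta))
  se <- sqrt(as.numeric(crossprod(cvec, XtXi %*% cvec)) * sigma2)
  tval <- eff / se
  pval <- 2 * stats::pt(-abs(tval), df)
  structure(list(beta = eff, t = tval, p = pval, df = df, dim = d[1:3],
                 contrast = contrast),
            class = "glm_result")
}

# 6-connected component labels over a logical 3D mask; returns integer array
.label_components <- function(mask, dim) {
  lab <- integer(prod(dim))
  cur <- 0L
  nx <- dim[1]; ny <- dim[2]; nz <- dim[3]
  idx_of <- function(x, y, z) x + nx * (y - 1L) + nx * ny * (z - 1L)
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[length(queue)]; queue <- queue[-length(queue)]
      z <- (v - 1L) %/% (nx * ny) + 1L
      rem <- (v - 1L) %% (nx * ny)
      y <- rem %/% nx + 1L
      x <- rem %% nx + 1L
      for (nb in list(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
                      c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))) {
        xx <- x + nb[1]; yy <- y + nb[2]; zz <- z + nb[3]
        if (xx < 1L || xx > nx || yy < 1L || yy > ny || zz < 1L || zz > nz)
          next
        w <- idx_of(xx, yy, zz)
        if (mask[w] && lab[w] == 0L) {
          lab[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

#' Define an ROI from voxelwise p-values
#'
#' Benjamini-Hochberg step-up over all voxels at rate `q`; if no voxel
#' survives, re-threshold at the uncorrected fallback p-value; then keep
#' the largest 6-connected component of the surviving set (ties broken by
#' higher mean absolute t). An empty set after the fallback is flagged as
#' not localizable.
#'
#' @param glm a [glm_contrast()] result (or a numeric p vector with `dim`
#'   and `t` supplied).
#' @param q FDR level.
#' @param fallback_p uncorrected fallback threshold.
#' @param dim,t lattice dimensions and t-values when `glm` is a bare
#'   vector.
#' @return an object of class `roi_result`: list with `voxels` (linear
#'   indices), `n_voxels`, `threshold_used` (`"fdr_q05"`,
#'   `"p003_uncorrected"` or `NA`), `localized`, `dim`.
#' @export
define_roi <- function(glm, q = 0.05, fallback_p = 0.003, dim = NULL,
                       t = NULL) {
  if (inherits(glm, "glm_result")) {
    p <- glm$p; t <- glm$t; dim <- glm$dim
  } else p <- glm
  stopifnot(all(p >= 0 & p <= 1), !is.null(dim), length(p) == prod(dim))
  if (is.null(t)) t <- rep(0, length(p))

  surviving <- stats::p.adjust(p, method = "BH") <= q
  threshold_used <- "fdr_q05"
  if (!any(surviving)) {
    surviving <- p < fallback_p
    threshold_used <- "p003_uncorrected"
  }
  if (!any(surviving))
    return(structure(list(voxels = integer(0), n_voxels = 0L,
                          threshold_used = NA_character_, localized = FALSE,
                          dim = dim),
                     class = "roi_result"))
  lab <- .label_components(surviving, dim)
  sizes <- table(lab[lab > 0L])
  biggest <- as.integer(names(sizes)[sizes == max(sizes)])
  if (length(biggest) > 1L) { # tie: keep the component with higher mean |t|
    mt <- vapply(biggest, function(b) mean(abs(t[lab == b])), numeric(1))
    biggest <- biggest[which.max(mt)]
  }
  voxels <- which(lab == biggest)
  structure(list(voxels = voxels, n_voxels = length(voxels),
                 threshold_used = threshold_used, localized = TRUE,
                 dim = dim),
            class = "roi_result")
}

#' @export
print.roi_result <- function(x, ...) {
  if (!x$localized) cat("<roi_result: not localizable>\n")
  else cat(sprintf("<roi_result: %d voxels at %s>\n", x$n_voxels,
                   x$threshold_used))
  invisible(x)
}

#' Mean ROI time series in percent-signal units
#'
#' Each voxel's series is converted to percent change about its own run
#' mean, then averaged over the ROI.
#'
#' @param sim a `bold_sim` or 4D array.
#' @param roi a [define_roi()] result (or vector of linear voxel indices).
#' @return numeric vector, one value per volume.
#' @export
roi_mean_series <- function(sim, roi) {
  data <- if (inherits(sim, "bold_sim")) sim$data else sim
  voxels <- if (inherits(roi, "roi_result")) roi$voxels else roi
  if (!length(voxels)) stop("empty ROI")
  d <- dim(data)
  Y <- array(data, c(prod(d[1:3]), d[4]))[voxels, , drop = FALSE]
  pct <- 100 * (Y / rowMeans(Y) - 1)
  colMeans(pct)
}

#' Event-related average of a condition
#'
#' Cuts the percent-signal series into epochs aligned to the onsets of one
#' condition (onset sample to `window_s` after) and averages them. Events
#' whose window runs past the series end are dropped; a condition with no
#' usable events is an error, mirroring the exclusion of empty
#' response-contingent categories.
#'
#' @param series_pct percent-signal series (from [roi_mean_series()]).
#' @param design the matching `fmri_design`.
#' @param condition condition label to average.
#' @param window_s epoch length after onset (s).
#' @return an object of class `era_timecourse`: data frame with `time_s`
#'   (0 = onset sample) and `pct_signal`, plus attribute `n_events`.
#' @export
event_related_average <- function(series_pct, design, condition,
                                  window_s = 12) {
  stopifnot(inherits(design, "fmri_design"))
  TR <- design$TR_s
  onsets <- design$events$onset_s[design$events$condition == condition]
  if (!length(onsets)) stop("no events of condition '", condition, "'")
  k <- floor(window_s / TR)
  i0 <- floor(onsets / TR) + 1L # sample at or just before onset
  ok <- i0 + k <= length(series_pct)
  if (!any(ok)) stop("no events of condition '", condition,
                     "' with a complete window")
  seg <- vapply(i0[ok], function(i) series_pct[i:(i + k)], numeric(k + 1L))
  tc <- data.frame(time_s = (0:k) * TR, pct_signal = rowMeans(seg))
  attr(tc, "n_events") <- sum(ok)
  class(tc) <- c("era_timecourse", "data.frame")
  tc
}

#' Peak percent-signal change of an event-related average
#'
#' Difference between the maximum over post-onset samples inside the search
#' window and the value at the onset sample, read from the raw averaged
#' values (no hemodynamic model fitting).
#'
#' @param timecourse an [event_related_average()] result.
#' @param peak_window_s post-onset search window (s); the default 10 s ends
#'   before the warning cue for the next trial.
#' @return peak minus onset value (percent signal).
#' @export
peak_percent_change <- function(timecourse, peak_window_s = 10) {
  stopifnot(is.data.frame(timecourse),
            all(c("time_s", "pct_signal") %in% names(timecourse)))
  post <- timecourse$time_s > 0 & timecourse$time_s <= peak_window_s
  if (sum(post) < 3L)
    stop("window too short: need at least 3 post-onset samples")
  if (!any(timecourse$time_s == 0))
    stop("timecourse must include the onset sample")
  max(timecourse$pct_signal[post]) -
    timecourse$pct_signal[timecourse$time_s == 0]
}

#' Full ROI event-related analysis
#'
#' Convenience chain: ROI mean series, event-related average and peak
#' percent change for each requested condition.
#'
#' @param sim a `bold_sim`.
#' @param roi a `roi_result` or voxel index vector.
#' @param conditions conditions to analyse (default: all with >= 1 event).
#' @param window_s,peak_window_s passed through.
#' @return an object of class `roi_analysis`: list with `timecourses`
#'   (named list of `era_timecourse`), `peaks` (named numeric),
#'   `n_events` (named integer), `roi`.
#' @export
roi_event_analysis <- function(sim, roi, conditions = NULL, window_s = 12,
                               peak_window_s = 10) {
  stopifnot(inherits(sim, "bold_sim"))
  if (is.null(conditions))
    conditions <- unique(sim$design$events$condition)
  series <- roi_mean_series(sim, roi)
  tcs <- lapply(conditions, function(cn)
    event_related_average(series, sim$design, cn, window_s))
  names(tcs) <- conditions
  peaks <- vapply(tcs, peak_percent_change, numeric(1),
                  peak_window_s = peak_window_s)
  structure(list(timecourses = tcs, peaks = peaks,
                 n_events = vapply(tcs, attr, integer(1), "n_events"),
                 roi = roi),
            class = "roi_analysis")
}

#' @export
print.roi_analysis <- function(x, ...) {
  cat("<roi_analysis: peak percent change by condition>\n")
  print(round(x$peaks, 3))
  invisible(x)
}
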