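# Parametric simulated observers standing in for human participants.
#
# Three response models, one per task: a Weibull-type psychometric function
# of noise-dot count for masked detection; a noisy coherence comparison for
# paired perturbation discrimination; and an equal-variance Gaussian
# signal-detection model for yes/no categorization. All decisions are drawn
# through the counter-based RNG, so an observer's response on trial k
# depends only on (observer seed, k).

#' Detection observer (masked 2IFC task)
#'
#' Probability correct at noise level n is
#' `guess + (1 - guess - lapse) * exp(-(n / alpha)^beta)`:
#' a decreasing Weibull-type function from 1 at n = 0 towards the guess
#' rate.
#'
#' @param alpha noise-level scale (dots); larger = more noise tolerated.
#' @param beta slope.
#' @param lapse lapse rate in `[0, 0.1)`.
#' @param guess guess rate, fixed at 0.5 for the 2IFC design.
#' @param seed integer seed for the observer's private response stream.
#' @return an object of class `detection_observer`.
#' @export
detection_observer <- function(alpha, beta = 2, lapse = 0, guess = 0.5,
                               seed = 1L) {
  stopifnot(alpha > 0, beta > 0, lapse >= 0, lapse < 0.1)
  structure(list(alpha = alpha, beta = beta, lapse = lapse, guess = guess,
                 seed = as.integer(seed)),
            class = c("detection_observer", "observer"))
}

#' @rdname detection_observer
#' @param obs a `detection_observer`.
#' @param n_noise noise-dot count(s), >= 0.
#' @export
p_correct_detection <- function(obs, n_noise) {
  stopifnot(inherits(obs, "detection_observer"), all(n_noise >= 0))
  obs$guess + (1 - obs$guess - obs$lapse) * exp(-(n_noise / obs$alpha)^obs$beta)
}

#' @rdname detection_observer
#' @param p target probability correct; the default is the two-up/one-down
#'   convergence point sqrt(1/2).
#' @export
detection_level_at_p <- function(obs, p = sqrt(0.5)) {
  stopifnot(inherits(obs, "detection_observer"))
  r <- (p - obs$guess) / (1 - obs$guess - obs$lapse)
  if (r <= 0 || r >= 1) stop("`p` outside the observer's attainable range")
  obs$alpha * (-log(r))^(1 / obs$beta)
}

#' @rdname detection_observer
#' @param trial trial counter(s); draws depend only on (seed, trial).
#' @return `respond_detection()`: logical vector, `TRUE` when correct.
#' @export
respond_detection <- function(obs, n_noise, trial) {
  p <- p_correct_detection(obs, n_noise)
  counter_uniform(obs$seed, 8 * trial + 1) < p
}

#' Discrimination observer (paired perturbation task)
#'
#' Each sequence yields an internal coherence sample
#' `gain * (1 - lam)^exponent + Normal(0, sigma)` and the observer picks
#' the side with the larger sample. With `exponent = 1` this is a linear
#' coherence code; `exponent > 1` makes coherence fall off convexly with
#' perturbation so that equal 15-point perturbation differences become
#' harder to tell apart at higher base perturbation, which is the shape of
#' the group accuracy profiles. The probability of choosing the
#' less-perturbed member of a pair is
#' `pnorm((c(lam_lo) - c(lam_hi)) / (sigma * sqrt(2)))`.
#'
#' @param gain sensitivity scale in `(0, 1]`.
#' @param sigma internal coherence noise SD (> 0).
#' @param exponent coherence fall-off exponent (>= 0); 1 = linear.
#' @param seed integer seed.
#' @return an object of class `discrimination_observer`.
#' @export
discrimination_observer <- function(gain, sigma, exponent = 1, seed = 1L) {
  stopifnot(gain > 0, gain <= 1, sigma > 0, exponent >= 0)
  structure(list(gain = gain, sigma = sigma, exponent = exponent,
                 seed = as.integer(seed)),
            class = c("discrimination_observer", "observer"))
}

coherence <- function(obs, lam) obs$gain * (1 - lam)^obs$exponent

#' @rdname discrimination_observer
#' @param obs a `discrimination_observer`.
#' @param lam_lo,lam_hi the smaller and larger perturbation of the pair.
#' @export
p_correct_discrimination <- function(obs, lam_lo, lam_hi) {
  stopifnot(inherits(obs, "discrimination_observer"),
            all(lam_lo >= 0 & lam_lo <= 1), all(lam_hi >= 0 & lam_hi <= 1))
  stats::pnorm((coherence(obs, lam_lo) - coherence(obs, lam_hi)) /
               (obs$sigma * sqrt(2)))
}

#' @rdname discrimination_observer
#' @param lam_left,lam_right perturbation levels of the two sides.
#' @param trial trial counter(s).
#' @return `respond_discrimination()`: character vector `"left"`/`"right"`,
#'   the side judged more normal (higher sampled coherence).
#' @export
respond_discrimination <- function(obs, lam_left, lam_right, trial) {
  stopifnot(inherits(obs, "discrimination_observer"))
  zl <- counter_norm(obs$seed, 8 * trial + 2)
  zr <- counter_norm(obs$seed, 8 * trial + 3)
  cl <- coherence(obs, lam_left) + obs$sigma * zl
  cr <- coherence(obs, lam_right) + obs$sigma * zr
  ifelse(cl >= cr, "left", "right")
}

#' Categorization observer (yes/no biological-vs-scrambled task)
#'
#' Equal-variance Gaussian signal detection: evidence is Normal(0, 1) for
#' scrambled, Normal(dprime, 1) for biological, and
#' Normal(intermediate_mean_frac * dprime, 1) for partially scrambled
#' sequences; the observer responds "biological" iff evidence exceeds the
#' criterion. Expected hit rate is `pnorm(dprime - criterion)` and expected
#' false-alarm rate `pnorm(-criterion)`.
#'
#' @param dprime sensitivity (>= 0).
#' @param criterion decision criterion on the evidence axis.
#' @param intermediate_mean_frac evidence mean for intermediate stimuli as
#'   a fraction of `dprime`, in `[0, 1]`; 0 makes intermediate trials
#'   behave exactly like scrambled ones.
#' @param seed integer seed.
#' @return an object of class `categorization_observer`.
#' @export
categorization_observer <- function(dprime, criterion,
                                    intermediate_mean_frac = 0, seed = 1L) {
  stopifnot(dprime >= 0, is.finite(criterion),
            intermediate_mean_frac >= 0, intermediate_mean_frac <= 1)
  structure(list(dprime = dprime, criterion = criterion,
                 intermediate_mean_frac = intermediate_mean_frac,
                 seed = as.integer(seed)),
            class = c("categorization_observer", "observer"))
}

#' @rdname categorization_observer
#' @param obs a `categorization_observer`.
#' @param stimulus_class character vector over
#'   `"biological"`, `"scrambled"`, `"intermediate"`.
#' @param trial trial counter(s).
#' @return `respond_categorization()`: character vector
#'   `"biological"`/`"scrambled"`.
#' @export
respond_categorization <- function(obs, stimulus_class, trial) {
  stopifnot(inherits(obs, "categorization_observer"))
  stimulus_class <- match.arg(stimulus_class,
                              c("biological", "scrambled", "intermediate"),
                              several.ok = TRUE)
  mu <- c(biological = obs$dprime, scrambled = 0,
          intermediate = obs$intermediate_mean_frac * obs$dprime)[stimulus_class]
  ev <- mu + counter_norm(obs$seed, 8 * trial + 4)
  ifelse(ev > obs$criterion, "biological", "scrambled")
}

#' @export
print.observer <- function(x, ...) {
  pars <- x[setdiff(names(x), "seed")]
  cat(sprintf("<%s: %s; seed %d>\n", class(x)[1],
              paste(names(pars), signif(unlist(pars), 4), sep = "=",
                    collapse = ", "), x$seed))
  invisible(x)
}

#' Calibrated observer presets for the two groups
#'
#' Parameter settings whose simulated group summaries land near the
#' group-level behaviour the study conditions specify: control detection
#' thresholds around 56 noise dots versus around 41 for patients; control
#' discrimination accuracy declining from roughly 89 to 52 percent across
#' the four perturbation pairs with patients uniformly lower and at chance
#' by the 30-vs-45 pair; categorization d-prime 3.82 (controls) versus 2.54
#' (patients) with false-alarm rates near 20 and 38 percent. Calibration is
#' documentation of the emulated conditions, not a fitted result.
#'
#' @param experiment `"detection"`, `"discrimination"` or
#'   `"categorization"`.
#' @param group `"control"` or `"patient"`.
#' @param seed integer seed for the returned observer.
#' @return an observer object of the matching class.
#' @export
observer_preset <- function(experiment = c("detection", "discrimination",
                                           "categorization"),
                            group = c("control", "patient"), seed = 1L) {
  experiment <- match.arg(experiment)
  group <- match.arg(group)
  switch(experiment,
    detection = {
      # alpha chosen so the 70.7%-correct point sits at the group threshold
      alpha <- if (group == "control") 59.60 else 43.49
      detection_observer(alpha = alpha, beta = 2, lapse = 0, seed = seed)
    },
    discrimination = {
      gain <- if (group == "control") 1 else 0.56
      discrimination_observer(gain = gain, sigma = 0.275, exponent = 4,
                              seed = seed)
    },
    categorization = {
      if (group == "control")
        categorization_observer(dprime = 3.82, criterion = 0.8524, seed = seed)
      else
        categorization_observer(dprime = 2.54, criterion = 0.3134, seed = seed)
    })
}

#' Sample a cohort of observers
#'
#' Returns `n` preset observers with distinct derived seeds and, optionally,
#' log-normal between-subject variation of the principal sensitivity
#' parameter (alpha, gain or dprime) with coefficient of variation
#' `param_cv`.
#'
#' @inheritParams observer_preset
#' @param n cohort size.
#' @param param_cv between-subject coefficient of variation; 0 gives
#'   identical parameters.
#' @return list of observers.
#' @export
observer_cohort <- function(experiment, group, n, seed = 1L, param_cv = 0.15) {
  stopifnot(n >= 1, param_cv >= 0)
  lapply(seq_len(n), function(i) {
    obs <- observer_preset(experiment, group, seed = derive_seed(seed, i))
    if (param_cv > 0) {
      sdlog <- sqrt(log(1 + param_cv^2))
      fac <- exp(sdlog * counter_norm(seed, 1000000 + i) - sdlog^2 / 2)
      key <- switch(experiment, detection = "alpha",
                    discrimination = "gain", categorization = "dprime")
      obs[[key]] <- if (key == "gain") min(1, obs[[key]] * fac)
        else obs[[key]] * fac
    }
    obs
  })
}
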