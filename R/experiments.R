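# End-to-end experiment runners on simulated observers. Each runner returns
# a per-trial log carrying full stimulus provenance (action, perturbation or
# noise level, seeds), so any trial's stimulus can be re-rendered, plus the
# derived endpoint (threshold, accuracy table, SDT summary).

EXP2_PAIRS <- rbind(c(0, 0.15), c(0.15, 0.30), c(0.30, 0.45), c(0.45, 0.60))
EXP2_PAIR_LABELS <- c("0% vs 15%", "15% vs 30%", "30% vs 45%", "45% vs 60%")
INTERMEDIATE_LAM <- 0.375 # labelled "37%": midway between 30% and 45%

# deterministic permutation of 1..n from the counter stream
.counter_shuffle <- function(n, seed, offset = 0) order(counter_uniform(seed, offset + seq_len(n)))

#' Run a masked-detection staircase session
#'
#' Two-interval forced choice: each trial presents a biological sequence in
#' noise in one randomly chosen interval and its scrambled counterpart in
#' the same noise level in the other; the noise-dot count follows the
#' two-up/one-down staircase until it terminates. Correctness comes from
#' the observer's psychometric function at the current noise level.
#'
#' @param observer a [detection_observer()].
#' @param cfg a [staircase_config()].
#' @param seed design seed governing interval assignment and action order.
#' @param actions character vector of preset names cycled over trials.
#' @return an object of class `exp1_run`: list with `log` (data frame:
#'   trial, level, action, signal_interval, response_interval, correct,
#'   reversal, n_reversals), `reversal_levels`, `threshold`, `observer`,
#'   `cfg`, `seed`.
#' @export
run_exp1 <- function(observer, cfg = staircase_config(), seed = 1L,
                     actions = names(action_presets())) {
  stopifnot(inherits(observer, "detection_observer"))
  state <- staircase_new(cfg)
  rows <- vector("list", cfg$max_trials)
  while (!state$finished) {
    trial <- state$trial_index + 1L
    level <- state$level
    action <- actions[(trial - 1L) %% length(actions) + 1L]
    signal_interval <- 1L + (counter_uniform(seed, 8 * trial + 5) > 0.5)
    correct <- respond_detection(observer, level, trial)
    response_interval <- if (correct) signal_interval else 3L - signal_interval
    n_rev_before <- length(state$reversal_levels)
    state <- staircase_update(state, correct)
    rows[[trial]] <- data.frame(
      trial = trial, level = level, action = action,
      signal_interval = signal_interval,
      response_interval = response_interval, correct = correct,
      reversal = length(state$reversal_levels) > n_rev_before,
      n_reversals = length(state$reversal_levels))
  }
  log <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  threshold <- if (length(state$reversal_levels) >= cfg$threshold_last_k)
    staircase_threshold(state) else NA_real_
  structure(list(log = log, reversal_levels = state$reversal_levels,
                 threshold = threshold, observer = observer, cfg = cfg,
                 seed = seed),
            class = "exp1_run")
}

#' @export
print.exp1_run <- function(x, ...) {
  cat(sprintf("<exp1_run: %d trials, %d reversals, threshold %.2f noise dots>\n",
              nrow(x$log), length(x$reversal_levels), x$threshold))
  invisible(x)
}

#' Run a paired perturbation-discrimination session
#'
#' Constant-stimuli design: `n_per_pair` trials for each of the four
#' perturbation pairs differing by 15 points, activities cycled evenly
#' within each pair, trial order and left/right assignment randomized.
#' Accuracy is scored as choosing the less-perturbed member.
#'
#' @param observer a [discrimination_observer()].
#' @param seed design seed.
#' @param activities activity preset names (the ten-exemplar set by
#'   default).
#' @param n_per_pair trials per perturbation pair.
#' @return an object of class `exp2_run`: list with `log` (trial,
#'   condition, activity, lam_left, lam_right, side_of_lower, choice,
#'   correct), `accuracy` (an [accuracy_table()]), `observer`, `seed`.
#' @export
run_exp2 <- function(observer, seed = 1L, activities = exp2_activities(),
                     n_per_pair = 40L) {
  stopifnot(inherits(observer, "discrimination_observer"),
            length(activities) >= 1L, n_per_pair >= 1L)
  cond <- rep(seq_len(nrow(EXP2_PAIRS)), each = n_per_pair)
  activity <- rep_len(activities, length(cond))
  ord <- .counter_shuffle(length(cond), seed, offset = 10000)
  cond <- cond[ord]; activity <- activity[ord]
  trial <- seq_along(cond)

  lam_lo <- EXP2_PAIRS[cond, 1]; lam_hi <- EXP2_PAIRS[cond, 2]
  lower_left <- counter_uniform(seed, 8 * trial + 6) > 0.5
  lam_left <- ifelse(lower_left, lam_lo, lam_hi)
  lam_right <- ifelse(lower_left, lam_hi, lam_lo)
  choice <- respond_discrimination(observer, lam_left, lam_right, trial)
  correct <- (choice == "left") == lower_left

  log <- data.frame(trial = trial, condition = EXP2_PAIR_LABELS[cond],
                    activity = activity, lam_left = lam_left,
                    lam_right = lam_right,
                    side_of_lower = ifelse(lower_left, "left", "right"),
                    choice = choice, correct = correct)
  structure(list(log = log, accuracy = accuracy_table(log),
                 observer = observer, seed = seed),
            class = "exp2_run")
}

#' @export
print.exp2_run <- function(x, ...) {
  cat(sprintf("<exp2_run: %d trials>\n", nrow(x$log)))
  print(x$accuracy$by_condition, row.names = FALSE)
  invisible(x)
}

#' Run a yes/no categorization session
#'
#' Nine runs of 24 trials (eight biological, eight fully scrambled, eight
#' intermediate 37%-scrambled, shuffled per run). d-prime is computed from
#' biological versus fully scrambled trials only; intermediate trials have
#' no correct answer and are summarized by the proportion judged
#' biological. Each trial's response-contingent condition (hit, miss,
#' correct_rejection, false_alarm, intermediate) is recorded for use as an
#' event-related fMRI predictor.
#'
#' @param observer a [categorization_observer()].
#' @param seed design seed.
#' @param n_runs number of runs.
#' @param trials_per_class_per_run trials per stimulus class per run.
#' @return an object of class `exp3_run`: list with `log` (run, trial,
#'   stimulus_class, lam, response, condition), `sdt` (an `sdt_result`),
#'   `intermediate_biological_rate`, `observer`, `seed`.
#' @export
run_exp3_behavioral <- function(observer, seed = 1L, n_runs = 9L,
                                trials_per_class_per_run = 8L) {
  stopifnot(inherits(observer, "categorization_observer"))
  classes <- c("biological", "scrambled", "intermediate")
  per_run <- rep(classes, each = trials_per_class_per_run)
  logs <- lapply(seq_len(n_runs), function(r) {
    ord <- .counter_shuffle(length(per_run), derive_seed(seed, r))
    data.frame(run = r, stimulus_class = per_run[ord])
  })
  log <- do.call(rbind, logs)
  log$trial <- seq_len(nrow(log))
  log$lam <- c(biological = 0, scrambled = 1,
               intermediate = INTERMEDIATE_LAM)[log$stimulus_class]
  log$response <- respond_categorization(observer, log$stimulus_class, log$trial)

  log$condition <- ifelse(
    log$stimulus_class == "intermediate", "intermediate",
    ifelse(log$stimulus_class == "biological",
           ifelse(log$response == "biological", "hit", "miss"),
           ifelse(log$response == "biological", "false_alarm",
                  "correct_rejection")))

  hits <- sum(log$condition == "hit")
  misses <- sum(log$condition == "miss")
  fas <- sum(log$condition == "false_alarm")
  crs <- sum(log$condition == "correct_rejection")
  sdt <- dprime(hits, misses, fas, crs, correction = "loglinear")
  irate <- mean(log$response[log$stimulus_class == "intermediate"] == "biological")
  structure(list(log = log, sdt = sdt,
                 intermediate_biological_rate = irate,
                 observer = observer, seed = seed),
            class = "exp3_run")
}

#' @export
print.exp3_run <- function(x, ...) {
  cat(sprintf("<exp3_run: %d trials; d' = %.2f, c = %.2f; P(\"biological\" | 37%%) = %.3f>\n",
              nrow(x$log), x$sdt$dprime, x$sdt$criterion_c,
              x$intermediate_biological_rate))
  invisible(x)
}

#' Simulate a cohort through one experiment
#'
#' Runs `n` preset observers of one group through the chosen experiment and
#' summarizes the per-observer endpoint (detection threshold,
#' per-condition accuracy vector, or d-prime with rates).
#'
#' @inheritParams observer_cohort
#' @param experiment `"detection"`, `"discrimination"` or
#'   `"categorization"`.
#' @param ... passed to the underlying runner.
#' @return an object of class `cohort_summary`: list with `experiment`,
#'   `group`, `endpoints` (data frame, one row per observer), `mean`, `se`
#'   over the principal endpoint column(s).
#' @export
run_cohort <- function(experiment = c("detection", "discrimination",
                                      "categorization"),
                       group = c("control", "patient"), n = 12L, seed = 1L,
                       param_cv = 0.15, ...) {
  experiment <- match.arg(experiment)
  group <- match.arg(group)
  cohort <- observer_cohort(experiment, group, n, seed, param_cv)
  endpoints <- switch(experiment,
    detection = do.call(rbind, lapply(seq_len(n), function(i) {
      run <- run_exp1(cohort[[i]], seed = derive_seed(seed, 100000 + i), ...)
      data.frame(observer = i, threshold = run$threshold,
                 n_trials = nrow(run$log))
    })),
    discrimination = do.call(rbind, lapply(seq_len(n), function(i) {
      run <- run_exp2(cohort[[i]], seed = derive_seed(seed, 100000 + i), ...)
      acc <- run$accuracy$by_condition
      out <- data.frame(observer = i)
      for (j in seq_len(nrow(acc)))
        out[[paste0("pct_", gsub("[^0-9v]", "", acc$condition[j]))]] <-
          acc$pct_correct[j]
      out
    })),
    categorization = do.call(rbind, lapply(seq_len(n), function(i) {
      run <- run_exp3_behavioral(cohort[[i]],
                                 seed = derive_seed(seed, 100000 + i), ...)
      data.frame(observer = i, dprime = run$sdt$dprime,
                 hit_rate = run$sdt$hit_rate, fa_rate = run$sdt$fa_rate,
                 intermediate_biological_rate = run$intermediate_biological_rate)
    })))
  num <- endpoints[setdiff(names(endpoints), "observer")]
  structure(list(experiment = experiment, group = group,
                 endpoints = endpoints,
                 mean = colMeans(num),
                 se = vapply(num, stats::sd, numeric(1)) / sqrt(n),
                 n = n, seed = seed),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary: %s, %s group, n = %d>\n", x$experiment,
              x$group, x$n))
  print(round(rbind(mean = x$mean, se = x$se), 3))
  invisible(x)
}

#' Compare two cohort summaries on one endpoint
#'
#' Pooled-variance t test and summary-based Cohen's d between matching
#' endpoint columns of two [run_cohort()] results.
#'
#' @param a,b `cohort_summary` objects from the same experiment.
#' @param endpoint endpoint column name; defaults to the first.
#' @return list with group means/SEs, `t`, `df`, `p`, `cohens_d`.
#' @export
compare_cohorts <- function(a, b, endpoint = NULL) {
  stopifnot(inherits(a, "cohort_summary"), inherits(b, "cohort_summary"),
            a$experiment == b$experiment)
  if (is.null(endpoint)) endpoint <- names(a$mean)[1]
  xs <- a$endpoints[[endpoint]]; ys <- b$endpoints[[endpoint]]
  tt <- two_sample_t(xs, ys)
  list(endpoint = endpoint,
       mean_a = mean(xs), se_a = stats::sd(xs) / sqrt(length(xs)),
       mean_b = mean(ys), se_b = stats::sd(ys) / sqrt(length(ys)),
       t = tt$t, df = tt$df, p = tt$p,
       cohens_d = cohens_d_from_summary(
         mean(xs), stats::sd(xs) / sqrt(length(xs)), length(xs),
         mean(ys), stats::sd(ys) / sqrt(length(ys)), length(ys)))
}

#' Write a trial log as CSV
#'
#' @param run an `exp1_run`, `exp2_run` or `exp3_run`.
#' @param path output file.
#' @export
write_trial_log <- function(run, path) {
  stopifnot(!is.null(run$log))
  utils::write.csv(run$log, path, row.names = FALSE)
  invisible(path)
}
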