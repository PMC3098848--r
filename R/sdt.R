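# Signal-detection and behavioural statistics: d-prime with extreme-rate
# correction, the exact binomial above-chance criterion, summary-based
# effect size, and thin wrappers over the textbook association tests.

#' d-prime from yes/no counts
#'
#' Computes sensitivity `d' = z(H) - z(F)` and criterion
#' `c = -(z(H) + z(F)) / 2` under the equal-variance Gaussian model. With
#' the log-linear correction (default) rates are `(x + 0.5) / (n + 1)`,
#' which keeps z finite when a rate would be 0 or 1; with
#' `correction = "none"` such rates are an error.
#'
#' @param hits,misses count of "biological" / "scrambled" responses on
#'   signal (biological) trials.
#' @param false_alarms,correct_rejections same on noise (scrambled) trials.
#' @param correction `"loglinear"` or `"none"`.
#' @return an object of class `sdt_result` with counts, rates, `dprime`,
#'   `criterion_c` and the correction used.
#' @export
dprime <- function(hits, misses, false_alarms, correct_rejections,
                   correction = c("loglinear", "none")) {
  correction <- match.arg(correction)
  counts <- c(hits, misses, false_alarms, correct_rejections)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  n_signal <- hits + misses
  n_noise <- false_alarms + correct_rejections
  if (n_signal == 0 || n_noise == 0)
    stop("both signal and noise trial totals must be positive")
  if (correction == "loglinear") {
    hr <- (hits + 0.5) / (n_signal + 1)
    fr <- (false_alarms + 0.5) / (n_noise + 1)
  } else {
    hr <- hits / n_signal
    fr <- false_alarms / n_noise
    if (hr %in% c(0, 1) || fr %in% c(0, 1))
      stop("a rate of 0 or 1 gives infinite d'; use correction = \"loglinear\"")
  }
  res <- dprime_from_rates(hr, fr)
  structure(list(n_signal = n_signal, n_noise_trials = n_noise,
                 hits = hits, false_alarms = false_alarms,
                 hit_rate = hr, fa_rate = fr,
                 dprime = res["dprime"][[1]],
                 criterion_c = res["criterion_c"][[1]],
                 correction = correction),
            class = "sdt_result")
}

#' @rdname dprime
#' @param hit_rate,fa_rate rates in (0, 1), already corrected if needed.
#' @return `dprime_from_rates()`: named vector `c(dprime, criterion_c)`.
#' @export
dprime_from_rates <- function(hit_rate, fa_rate) {
  stopifnot(hit_rate > 0, hit_rate < 1, fa_rate > 0, fa_rate < 1)
  zh <- stats::qnorm(hit_rate); zf <- stats::qnorm(fa_rate)
  c(dprime = zh - zf, criterion_c = -(zh + zf) / 2)
}

#' @export
print.sdt_result <- function(x, ...) {
  cat(sprintf(
    "<sdt_result: H %d/%d (%.3f), FA %d/%d (%.3f), d' = %.3f, c = %.3f [%s]>\n",
    x$hits, x$n_signal, x$hit_rate, x$false_alarms, x$n_noise_trials,
    x$fa_rate, x$dprime, x$criterion_c, x$correction))
  invisible(x)
}

#' Exact binomial above-chance criterion
#'
#' Smallest number of correct responses k such that the exact one-sided
#' tail probability `P(X >= k | n, p0)` falls below `alpha`. For 40 trials
#' at chance 0.5 and alpha 0.05 this is 26, the per-condition criterion
#' used to count above-chance observers.
#'
#' @param n_trials number of trials (>= 1).
#' @param p0 chance success probability.
#' @param alpha one-sided significance level.
#' @return integer criterion k (may be `n_trials + 1` when even a perfect
#'   score is not significant at `alpha`).
#' @export
binomial_above_chance_k <- function(n_trials, p0 = 0.5, alpha = 0.05) {
  stopifnot(n_trials >= 1, n_trials == round(n_trials),
            p0 > 0, p0 < 1, alpha > 0, alpha < 1)
  tail_p <- stats::pbinom(0:n_trials - 1L, n_trials, p0, lower.tail = FALSE)
  k <- which(tail_p < alpha)
  if (length(k) == 0L) as.integer(n_trials) + 1L else as.integer(k[1] - 1L)
}

#' Cohen's d from group summaries
#'
#' Pooled-SD standardized mean difference, with each group's SD recovered
#' from its standard error as `se * sqrt(n)`. Reported as a magnitude.
#'
#' @param mean1,se1,n1 first group's mean, standard error and size.
#' @param mean2,se2,n2 second group's.
#' @return non-negative effect size.
#' @export
cohens_d_from_summary <- function(mean1, se1, n1, mean2, se2, n2) {
  stopifnot(se1 > 0, se2 > 0)
  if (n1 <= 1 || n2 <= 1) stop("group sizes must exceed 1")
  sd1 <- se1 * sqrt(n1); sd2 <- se2 * sqrt(n2)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  abs(mean1 - mean2) / sp
}

#' Association and location tests used for group comparisons
#'
#' Thin wrappers with fixed conventions: Pearson correlation,
#' Pearson chi-square on a 2x2 table without continuity correction, and the
#' pooled-variance two-sample t test (from samples or from summaries).
#'
#' @param xs,ys numeric vectors.
#' @return `pearson_r()`: list with `r` and `p`.
#' @export
pearson_r <- function(xs, ys) {
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop("degenerate variance: correlation undefined")
  ct <- stats::cor.test(xs, ys)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' @rdname pearson_r
#' @param table a 2x2 contingency matrix of counts.
#' @return `contingency_chi2()`: list with `chi2`, `df`, `p`.
#' @export
contingency_chi2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0))
  ct <- stats::chisq.test(table, correct = FALSE)
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter), p = ct$p.value)
}

#' @rdname pearson_r
#' @return `two_sample_t()`: list with `t`, `df`, `p`.
#' @export
two_sample_t <- function(xs, ys) {
  if (stats::sd(c(xs, ys)) == 0) stop("degenerate variance")
  tt <- stats::t.test(xs, ys, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' @rdname pearson_r
#' @inheritParams cohens_d_from_summary
#' @return `two_sample_t_summary()`: list with `t`, `df`, `p`.
#' @export
two_sample_t_summary <- function(mean1, se1, n1, mean2, se2, n2) {
  stopifnot(se1 >= 0, se2 >= 0, n1 > 1, n2 > 1)
  sd1 <- se1 * sqrt(n1); sd2 <- se2 * sqrt(n2)
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 == 0) stop("degenerate variance")
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Accuracy table from a paired-discrimination trial log
#'
#' Per-condition percent correct (the four perturbation pairs, 40 trials
#' each in the full design) and per-activity percent correct pooled across
#' all pairs except the most extreme one, where the task is impossible for
#' everyone.
#'
#' @param log a trial-log data frame with columns `condition`, `activity`,
#'   `correct`.
#' @param exclude_condition condition label excluded from the per-activity
#'   pooling.
#' @return an object of class `accuracy_table`: list with `by_condition`
#'   and `by_activity` data frames (percent scale).
#' @export
accuracy_table <- function(log, exclude_condition = "45% vs 60%") {
  stopifnot(all(c("condition", "activity", "correct") %in% names(log)))
  byc <- stats::aggregate(correct ~ condition, data = log,
                   FUN = function(x) 100 * mean(x))
  names(byc) <- c("condition", "pct_correct")
  byc$n_trials <- stats::aggregate(correct ~ condition, data = log, FUN = length)$correct
  keep <- log[log$condition != exclude_condition, ]
  bya <- stats::aggregate(correct ~ activity, data = keep,
                   FUN = function(x) 100 * mean(x))
  names(bya) <- c("activity", "pct_correct")
  bya$n_trials <- stats::aggregate(correct ~ activity, data = keep, FUN = length)$correct
  structure(list(by_condition = byc, by_activity = bya,
                 excluded = exclude_condition),
            class = "accuracy_table")
}

#' @export
print.accuracy_table <- function(x, ...) {
  cat("Accuracy by condition (% correct):\n")
  print(x$by_condition, row.names = FALSE)
  cat(sprintf("Accuracy by activity (pooled, excluding %s):\n", x$excluded))
  print(x$by_activity, row.names = FALSE)
  invisible(x)
}
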