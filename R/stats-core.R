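#' Welch two-sample t-test
#'
#' Unequal-variance t-test with Welch--Satterthwaite degrees of freedom,
#' two-sided. Degenerate inputs (both groups with zero variance) do not
#' error: identical means give `t = 0, p = 1`, differing means give `p = 0`,
#' and the result is flagged.
#'
#' @param a,b Numeric vectors, each with at least 2 finite values.
#' @return A list with `t`, `df`, `p`, `mean_a`, `mean_b`, `sd_a`, `sd_b`,
#'   `n_a`, `n_b` and a logical `degenerate` flag.
#' @examples
#' welch_t_test(c(1, 2, 3, 4), c(2, 3, 4, 5))$p
#' @export
welch_t_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L || !all(is.finite(a)) || !all(is.finite(b)))
    stop("welch_t_test: each sample needs >= 2 finite values")
  va <- stats::var(a); vb <- stats::var(b)
  out <- list(mean_a = mean(a), mean_b = mean(b),
              sd_a = stats::sd(a), sd_b = stats::sd(b),
              n_a = length(a), n_b = length(b), degenerate = FALSE)
  if (va == 0 && vb == 0) {
    out$degenerate <- TRUE
    out$df <- NA_real_
    if (mean(a) == mean(b)) { out$t <- 0; out$p <- 1 } else {
      out$t <- sign(mean(a) - mean(b)) * Inf; out$p <- 0
    }
    return(out)
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  out$t <- unname(tt$statistic)
  out$df <- unname(tt$parameter)
  out$p <- tt$p.value
  out
}

#' Brown--Forsythe test for equality of group variances
#'
#' One-way ANOVA F statistic computed on the absolute deviations from each
#' group's median, `z_ij = |x_ij - median_j|`. For even group sizes the
#' median is the mean of the central pair. All-zero deviations (every group
#' constant) return `W = 0, p = 1` with a flag instead of an error.
#'
#' @param groups A list of >= 2 numeric vectors, each with >= 2 values.
#' @return A list with `W`, `df1`, `df2`, `p` and a `degenerate` flag.
#' @export
brown_forsythe <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("brown_forsythe: need a list of >= 2 groups")
  if (any(vapply(groups, length, 1L) < 2L))
    stop("brown_forsythe: each group needs >= 2 values")
  z <- lapply(groups, function(x) abs(x - stats::median(x)))
  zv <- unlist(z, use.names = FALSE)
  g <- factor(rep.int(seq_along(z), lengths(z)))
  k <- length(groups); N <- length(zv)
  if (all(zv == 0) || stats::var(zv) == 0)
    return(list(W = 0, df1 = k - 1, df2 = N - k, p = 1, degenerate = TRUE))
  ow <- stats::oneway.test(zv ~ g, var.equal = TRUE)
  list(W = unname(ow$statistic), df1 = unname(ow$parameter[1L]),
       df2 = unname(ow$parameter[2L]), p = ow$p.value, degenerate = FALSE)
}

#' Benjamini--Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, returned in input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("bh_adjust: p-values must be finite and in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Gini index of a count vector
#'
#' Population Gini coefficient of inequality,
#' \eqn{G = \sum_i (2i - n - 1) x_{(i)} / (n^2 \bar x)} over the ascending
#' order statistics; identical to the pairwise mean-absolute-difference form
#' \eqn{\sum_{ij} |x_i - x_j| / (2 n^2 \bar x)}. Used as the screen's
#' per-sample selection metric: uniform guide representation gives 0, a few
#' dominating guides push it toward 1.
#'
#' @param counts Non-negative numeric vector with positive sum.
#' @return Gini index in `[0, 1)`.
#' @examples
#' gini_index(c(5, 5, 5, 5))  # 0
#' gini_index(c(1, 0, 0, 0))  # 0.75
#' @export
gini_index <- function(counts) {
  x <- as.numeric(counts)
  if (length(x) < 1L || any(!is.finite(x)) || any(x < 0))
    stop("gini_index: counts must be finite and non-negative")
  s <- sum(x)
  if (s <= 0) stop("gini_index: all-zero vector, Gini undefined")
  x <- sort(x)
  n <- length(x)
  sum((2 * seq_len(n) - n - 1) * x) / (n * s)
}

#' Kaplan--Meier survival estimate
#'
#' Product-limit estimator with right censoring. The median is the earliest
#' time at which the survival curve reaches `S(t) <= 0.5` (first-crossing
#' convention, matching common survival plotters); `NA` if the curve never
#' reaches 0.5.
#'
#' @param times Non-negative event/censoring times (months).
#' @param events 0/1 event indicators (1 = event).
#' @return A list with `time`, `surv` (step function values at the event
#'   times), `n_risk`, `n_event`, and `median`.
#' @export
km_estimate <- function(times, events) {
  times <- as.numeric(times); events <- as.integer(events)
  if (length(times) == 0L) stop("km_estimate: empty input")
  if (any(times < 0) || any(!is.finite(times))) stop("km_estimate: times must be finite and >= 0")
  if (!all(events %in% c(0L, 1L))) stop("km_estimate: events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  surv <- fit$surv; tm <- fit$time
  med <- if (any(surv <= 0.5)) tm[which(surv <= 0.5)[1L]] else NA_real_
  list(time = tm, surv = surv, n_risk = fit$n.risk, n_event = fit$n.event,
       median = med)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square (1 df) comparing two survival curves, with
#' hypergeometric variance and simultaneous risk-set accounting for ties.
#' If neither group has any events the test is degenerate: `chi2 = 0,
#' p = 1`, flagged.
#'
#' @param times_a,events_a Group A times and 0/1 event indicators.
#' @param times_b,events_b Group B, same form.
#' @return A list with `chi2`, `p`, and a `degenerate` flag.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0L || length(times_b) == 0L)
    stop("logrank_test: both groups must be non-empty")
  ev <- c(as.integer(events_a), as.integer(events_b))
  if (sum(ev) == 0L)
    return(list(chi2 = 0, p = 1, degenerate = TRUE))
  tm <- c(as.numeric(times_a), as.numeric(times_b))
  grp <- factor(rep(c("a", "b"), c(length(times_a), length(times_b))))
  sd_ <- survival::survdiff(survival::Surv(tm, ev) ~ grp)
  chi2 <- unname(sd_$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Compare two groups of a continuous measurement
#'
#' Bundles the Welch two-sample t-test (difference in means) and the
#' Brown--Forsythe test (difference in variances) the way the screen's
#' biophysical assays report group contrasts.
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @return A `group_comparison` list: group means/sds/sizes, Welch `t`,
#'   `df`, `p`, and Brown--Forsythe `W`, `df1`, `df2`, `p`.
#' @export
compare_groups <- function(a, b) {
  w <- welch_t_test(a, b)
  bf <- brown_forsythe(list(a, b))
  structure(list(
    mean_a = w$mean_a, mean_b = w$mean_b, sd_a = w$sd_a, sd_b = w$sd_b,
    n_a = w$n_a, n_b = w$n_b,
    welch_t = w$t, welch_df = w$df, welch_p = w$p,
    bf_stat = bf$W, bf_df1 = bf$df1, bf_df2 = bf$df2, bf_p = bf$p,
    degenerate = w$degenerate || bf$degenerate
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison (n = %d vs %d)\n", x$n_a, x$n_b))
  cat(sprintf("  means: %.4g vs %.4g   sds: %.4g vs %.4g\n",
              x$mean_a, x$mean_b, x$sd_a, x$sd_b))
  cat(sprintf("  Welch t = %.4g (df %.2f), p = %.3g\n", x$welch_t, x$welch_df, x$welch_p))
  cat(sprintf("  Brown-Forsythe W = %.4g (df %d, %d), p = %.3g\n",
              x$bf_stat, x$bf_df1, x$bf_df2, x$bf_p))
  invisible(x)
}
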