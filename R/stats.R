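#' Cohort descriptive summary
#'
#' Mean and sample standard deviation (n - 1 denominator) of per-crown fit
#' metrics in micrometres.
#'
#' @param values numeric vector of per-crown metrics (um), length >= 2.
#' @param label cohort label.
#' @param n,mean,sd alternatively, construct a summary directly from
#'   printed statistics via `group_summary(label, n, mean, sd)`.
#' @return a `group_summary`.
#' @export
summarize_group <- function(values, label = "group") {
  if (length(values) < 2L)
    stop("need at least 2 values to summarize, got ", length(values))
  group_summary(label, length(values), mean(values), stats::sd(values))
}

#' @rdname summarize_group
#' @export
group_summary <- function(label, n, mean, sd) {
  if (n < 2L) stop("n must be >= 2")
  if (sd < 0) stop("sd must be >= 0")
  structure(list(label = label, n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %s: n = %d, mean = %.3f um, sd = %.3f um\n",
              x$label, x$n, x$mean, x$sd))
  invisible(x)
}

#' Independent two-sample t test from summary statistics
#'
#' Pooled-variance (Student's) t test computed from group means, standard
#' deviations and sizes, so it can be applied directly to published summary
#' tables. The statistic is computed on `group2 mean - group1 mean` (the
#' first-listed cohort is the reference, so a negative t means the second
#' cohort's mean is smaller), with
#' \deqn{s_p^2 = \frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2},\quad
#'       t = \frac{m_2 - m_1}{s_p\sqrt{1/n_1 + 1/n_2}},\quad
#'       df = n_1+n_2-2,}
#' and the two-sided p-value from the regularized incomplete beta
#' \eqn{p = I_{df/(df+t^2)}(df/2, 1/2)}. A Welch (unpooled) variant is
#' available behind `welch = TRUE` but is not the default, since the pooled
#' form with df = n1 + n2 - 2 is the one conventionally reported. Normality
#' of the per-crown metrics is assumed, not tested.
#'
#' @param g1,g2 `group_summary` objects (g1 is listed first).
#' @param alpha significance level (default 0.05).
#' @param welch use the Welch unpooled test instead of the pooled test.
#' @return a `group_comparison`: `group1`, `group2`, `t`, `df`,
#'   `p_two_sided` (full precision; round only for display), `alpha`,
#'   `significant`, `method`.
#' @export
student_t_from_summaries <- function(g1, g2, alpha = 0.05, welch = FALSE) {
  stopifnot(inherits(g1, "group_summary"), inherits(g2, "group_summary"))
  n1 <- g1$n; n2 <- g2$n
  if (welch) {
    se2 <- g1$sd^2 / n1 + g2$sd^2 / n2
    if (se2 == 0) {
      if (g1$mean == g2$mean) { t <- 0; df <- n1 + n2 - 2 }
      else stop("degenerate variance: sd = 0 in both groups with unequal means")
    } else {
      t <- (g2$mean - g1$mean) / sqrt(se2)
      df <- se2^2 / ((g1$sd^2 / n1)^2 / (n1 - 1) +
                     (g2$sd^2 / n2)^2 / (n2 - 1))
    }
  } else {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * g1$sd^2 + (n2 - 1) * g2$sd^2) / df
    if (sp2 == 0) {
      if (g1$mean == g2$mean) t <- 0
      else stop("degenerate variance: pooled sd = 0 with unequal means")
    } else {
      t <- (g2$mean - g1$mean) / sqrt(sp2 * (1 / n1 + 1 / n2))
    }
  }
  # two-sided p via the regularized incomplete beta I_{df/(df+t^2)}(df/2, 1/2)
  p <- stats::pbeta(df / (df + t^2), df / 2, 0.5)
  structure(list(group1 = g1, group2 = g2, t = t, df = df,
                 p_two_sided = p, alpha = alpha,
                 significant = p < alpha,
                 method = if (welch) "welch" else "pooled"),
            class = "group_comparison")
}

#' Independent two-sample t test from raw per-crown metrics
#'
#' Equivalent to [student_t_from_summaries()] applied to
#' [summarize_group()] of each vector.
#'
#' @param values1,values2 numeric vectors (um), each of length >= 2.
#' @param labels length-2 character vector of cohort labels.
#' @inheritParams student_t_from_summaries
#' @return a `group_comparison`.
#' @export
student_t_from_raw <- function(values1, values2,
                               labels = c("group1", "group2"),
                               alpha = 0.05, welch = FALSE) {
  student_t_from_summaries(summarize_group(values1, labels[1]),
                           summarize_group(values2, labels[2]),
                           alpha = alpha, welch = welch)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> independent-sample t test",
      if (x$method == "welch") "(Welch)" else "(pooled)", "\n")
  print(x$group1)
  print(x$group2)
  cat(sprintf("  t(%s) = %.3f, p = %.3f (%ssignificant at alpha = %g)\n",
              format(x$df, digits = 4), x$t, x$p_two_sided,
              if (x$significant) "" else "not ", x$alpha))
  cat(sprintf("  sign convention: t is computed on %s mean minus %s mean\n",
              x$group2$label, x$group1$label))
  cat("  note: normality of the per-crown metrics is assumed, not tested\n")
  invisible(x)
}
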