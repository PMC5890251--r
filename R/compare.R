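#' Compare tortuosity between two groups
#'
#' Summarizes the pre- and post-branch tortuosity ratios and tests their
#' difference with a two-sample two-tailed Student's t-test (pooled variance
#' by default; Welch optional). The percent decrease is computed from the
#' group means, `100 * (mean_pre - mean_post) / mean_pre`, the convention
#' under which printed group means of 11 and 6 give a ~45.5% decrease
#' (commonly rounded to "about 50%"). Zero-variance inputs are handled
#' explicitly: identical constant groups give `t = 0, p = 1`; distinct
#' constant groups give `t = +/-Inf, p = 0`.
#'
#' @param pre,post numeric vectors of per-image ratios (>= 2 each).
#' @param var_equal pooled-variance Student's t (default) or Welch if `FALSE`.
#' @return object of class `group_comparison`: list with `mean_pre`,
#'   `mean_post`, `sem_pre`, `sem_post`, `range_pre`, `range_post`,
#'   `percent_decrease`, `t_stat`, `df`, `p_value`, `method`, `n_pre`,
#'   `n_post`.
#' @export
compare_groups <- function(pre, post, var_equal = TRUE) {
  pre <- as.numeric(pre)
  post <- as.numeric(post)
  if (length(pre) < 2 || length(post) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  if (any(!is.finite(pre)) || any(!is.finite(post))) {
    stop("non-finite ratios in input", call. = FALSE)
  }
  m1 <- mean(pre)
  m2 <- mean(post)
  n1 <- length(pre)
  n2 <- length(post)
  if (stats::var(pre) == 0 && stats::var(post) == 0) {
    if (m1 == m2) {
      t_stat <- 0
      p <- 1
    } else {
      t_stat <- sign(m1 - m2) * Inf
      p <- 0
    }
    df <- n1 + n2 - 2
  } else {
    tt <- stats::t.test(pre, post, var.equal = var_equal)
    t_stat <- unname(tt$statistic)
    df <- unname(tt$parameter)
    p <- tt$p.value
  }
  structure(list(
    mean_pre = m1, mean_post = m2,
    sem_pre = stats::sd(pre) / sqrt(n1),
    sem_post = stats::sd(post) / sqrt(n2),
    range_pre = range(pre), range_post = range(post),
    percent_decrease = 100 * (m1 - m2) / m1,
    t_stat = t_stat, df = df, p_value = p,
    method = if (var_equal) "two-sample t (pooled variance, two-tailed)"
    else "Welch two-sample t (two-tailed)",
    n_pre = n1, n_post = n2
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("lambda/d pre : mean %.3g (sem %.2g, range %.3g-%.3g, n=%d)\n",
              x$mean_pre, x$sem_pre, x$range_pre[1], x$range_pre[2], x$n_pre))
  cat(sprintf("lambda/d post: mean %.3g (sem %.2g, range %.3g-%.3g, n=%d)\n",
              x$mean_post, x$sem_post, x$range_post[1], x$range_post[2],
              x$n_post))
  cat(sprintf("percent decrease: %.1f%%\n", x$percent_decrease))
  cat(sprintf("%s: t = %.4g, df = %.4g, p = %.3g\n",
              x$method, x$t_stat, x$df, x$p_value))
  invisible(x)
}
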