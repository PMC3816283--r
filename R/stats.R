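# Group comparisons: Student t-test and one-way ANOVA with Monte-Carlo
# Dunnett many-to-one contrasts.

#' Two-sample Student t-test
#'
#' Two-sided t-test between two groups; pooled (equal-variance) by default,
#' Welch optionally.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param paired logical, paired test.
#' @param var_equal logical, pooled-variance (classic Student) test; set
#'   FALSE for Welch.
#' @param alpha significance level recorded on the result.
#' @return object of class `group_comparison` with `statistic`, `df`,
#'   `p_value`, `method`, `alpha`, `significant`.
#' @export
two_sample_t <- function(a, b, paired = FALSE, var_equal = TRUE,
                         alpha = 0.05) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  tt <- stats::t.test(a, b, paired = paired, var.equal = var_equal,
                      alternative = "two.sided")
  structure(
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, method = "t_test", alpha = alpha,
         significant = tt$p.value < alpha,
         estimate = unname(diff(rev(tt$estimate)))),
    class = "group_comparison"
  )
}

# 1-alpha quantile of the null max-|t| Dunnett statistic by Monte Carlo.
# k treatment groups of sizes n_t against a control of size n_c, pooled
# variance on df degrees of freedom. Group means enter only through
# independent N(0, 1/n) draws; the shared control mean and shared pooled SD
# induce the between-contrast correlation.
dunnett_mc_max_t <- function(n_c, n_t, df, n_mc) {
  z_c <- stats::rnorm(n_mc, 0, sqrt(1 / n_c))
  s <- sqrt(stats::rchisq(n_mc, df) / df)
  max_t <- rep(0, n_mc)
  for (j in seq_along(n_t)) {
    z_j <- stats::rnorm(n_mc, 0, sqrt(1 / n_t[j]))
    t_j <- abs(z_j - z_c) / (s * sqrt(1 / n_t[j] + 1 / n_c))
    max_t <- pmax(max_t, t_j)
  }
  max_t
}

#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' Fits a one-way fixed-effects ANOVA over the control and treatment
#' groups, then compares every treatment to the control with pooled-variance
#' t statistics. Family-wise error is controlled at `alpha` by referring
#' the statistics to the null distribution of the maximum absolute Dunnett
#' statistic, obtained by seeded Monte-Carlo simulation (default 1e5
#' draws), which is exact to Monte-Carlo error for any number of groups and
#' unequal group sizes. Adjusted p-values are the Monte-Carlo tail
#' probabilities of max-|t|.
#'
#' @param control numeric control sample (n >= 2).
#' @param treatments named list of treatment samples (each n >= 2).
#' @param alpha family-wise significance level.
#' @param n_mc Monte-Carlo draws for the null max-|t| distribution.
#' @param seed integer seed for the Monte-Carlo draws.
#' @return object of class `group_comparison` with the ANOVA `statistic`
#'   (F), `df`, `p_value`, the Monte-Carlo `critical_value`, and a
#'   `comparisons` data.frame (`treatment`, `estimate`, `t`, `p_adjusted`,
#'   `significant`).
#' @export
anova_dunnett <- function(control, treatments, alpha = 0.05, n_mc = 1e5,
                          seed = 1) {
  if (!is.list(treatments) || length(treatments) == 0L) {
    stop("`treatments` must be a non-empty list of samples", call. = FALSE)
  }
  if (is.null(names(treatments)) || any(!nzchar(names(treatments)))) {
    names(treatments) <- paste0("treatment", seq_along(treatments))
  }
  sizes <- vapply(treatments, length, integer(1))
  if (length(control) < 2L || any(sizes < 2L)) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  y <- c(control, unlist(treatments, use.names = FALSE))
  g <- factor(rep(c("control", names(treatments)),
                  c(length(control), sizes)),
              levels = c("control", names(treatments)))
  fit <- stats::aov(y ~ g)
  an <- summary(fit)[[1]]
  df_err <- an["Residuals", "Df"]
  s2 <- an["Residuals", "Mean Sq"]
  est <- vapply(treatments, mean, numeric(1)) - mean(control)
  se <- sqrt(s2 * (1 / sizes + 1 / length(control)))
  t_obs <- est / se
  max_t_null <- with_seed(seed, {
    dunnett_mc_max_t(length(control), sizes, df_err, n_mc)
  })
  crit <- unname(stats::quantile(max_t_null, 1 - alpha, type = 8))
  p_adj <- vapply(t_obs, function(t) mean(max_t_null >= abs(t)), numeric(1))
  structure(
    list(statistic = an["g", "F value"], df = c(an["g", "Df"], df_err),
         p_value = an["g", "Pr(>F)"], method = "anova_dunnett",
         alpha = alpha, critical_value = crit, n_mc = n_mc,
         significant = an["g", "Pr(>F)"] < alpha,
         comparisons = data.frame(
           treatment = names(treatments), estimate = unname(est),
           t = unname(t_obs), p_adjusted = unname(p_adj),
           significant = unname(abs(t_obs) > crit)
         )),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  if (x$method == "t_test") {
    cat(sprintf("Student t-test: t = %.4g (df %.4g), p = %.4g\n",
                x$statistic, x$df, x$p_value))
  } else {
    cat(sprintf("One-way ANOVA: F = %.4g (df %d, %d), p = %.4g\n",
                x$statistic, x$df[1], x$df[2], x$p_value))
    cat(sprintf("Dunnett many-to-one (alpha %.3g, MC critical |t| %.4g):\n",
                x$alpha, x$critical_value))
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}
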