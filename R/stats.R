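# Inferential layer: paired t tests with Cohen's d_z, Bonferroni correction
# and JZS default Bayes factors; two-factor repeated-measures ANOVA with
# generalized eta squared; exact noncentral-t power and sample-size
# calculations for paired designs.

#' Paired t test with effect size and Bayes factor
#'
#' Classical paired t test on per-participant differences, with Bonferroni
#' correction over `k_corrections` planned tests, the within-subject effect
#' size d_z = t / sqrt(n), and the JZS default Bayes factor.
#'
#' @param x first condition values, or differences if `y` is NULL.
#' @param y optional second condition values (paired with `x`).
#' @param k_corrections number of tests in the Bonferroni family.
#' @param bayes a [bayes_config()].
#' @return object of class `idc_ttest`: t, df, n, p_raw, p_corrected, d_z,
#'   bf10, bf01, mean_diff, sd_diff.
#' @export
paired_t <- function(x, y = NULL, k_corrections = 1,
                     bayes = bayes_config()) {
  d <- if (is.null(y)) x else x - y
  d <- d[is.finite(d)]
  n <- length(d)
  stop_if(n < 2, "paired_t needs at least 2 finite differences")
  sdd <- sd(d)
  stop_if(sdd == 0 && mean(d) != 0,
          "degenerate input: zero-variance nonzero differences")
  t_stat <- if (sdd == 0) 0 else mean(d) / (sdd / sqrt(n))
  df <- n - 1
  p_raw <- 2 * pt(abs(t_stat), df, lower.tail = FALSE)
  bf10 <- jzs_bf_ttest(t_stat, n, bayes)
  structure(list(t = t_stat, df = df, n = n, p_raw = p_raw,
                 p_corrected = min(1, k_corrections * p_raw),
                 d_z = t_stat / sqrt(n), bf10 = bf10, bf01 = 1 / bf10,
                 mean_diff = mean(d), sd_diff = sdd),
            class = "idc_ttest")
}

#' @export
print.idc_ttest <- function(x, ...) {
  cat(sprintf("Paired t test: t(%d) = %.2f, p = %.4g (corrected %.4g)\n",
              x$df, x$t, x$p_raw, x$p_corrected))
  cat(sprintf("  d_z = %.2f, BF10 = %.2f, BF01 = %.2f\n",
              x$d_z, x$bf10, x$bf01))
  invisible(x)
}

#' JZS default Bayes factor for a paired/one-sample t statistic
#'
#' Computes the Jeffreys-Zellner-Siow Bayes factor BF10 for a one-sample
#' (or paired-difference) design from the t statistic: a Cauchy prior with
#' scale `prior_scale` on the standardized effect size, equivalent to a
#' scale mixture of normals with an inverse-chi-squared mixing density on
#' the relative prior variance g.  The marginal likelihood under the
#' alternative is obtained by adaptive quadrature of
#' \deqn{\int_0^\infty (1 + N g r^2)^{-1/2}
#'   \left(1 + \frac{t^2}{(1 + N g r^2)\,\nu}\right)^{-(\nu+1)/2}
#'   (2\pi)^{-1/2} g^{-3/2} e^{-1/(2g)} \, dg}
#' with \eqn{\nu = N - 1}, and divided by the null likelihood
#' \eqn{(1 + t^2/\nu)^{-(\nu+1)/2}}.  The result is invariant to the sign
#' of t.
#'
#' @param t observed t statistic.
#' @param n number of pairs (or observations).
#' @param bayes a [bayes_config()] (prior scale, integration tolerance).
#' @return BF10 (> 0); BF01 is its reciprocal.
#' @export
jzs_bf_ttest <- function(t, n, bayes = bayes_config()) {
  stop_if(!is.finite(t), "t must be finite")
  stop_if(n < 2, "n must be >= 2")
  r <- bayes$prior_scale
  nu <- n - 1
  # work on the log scale relative to the null likelihood for stability at
  # large |t|
  log_null <- -(nu + 1) / 2 * log1p(t^2 / nu)
  integrand <- function(g) {
    a <- 1 + n * g * r^2
    exp(-0.5 * log(a) - (nu + 1) / 2 * log1p(t^2 / (a * nu)) - log_null -
          0.5 * log(2 * pi) - 1.5 * log(g) - 1 / (2 * g))
  }
  val <- tryCatch(
    integrate(integrand, 0, Inf, rel.tol = bayes$rel_tol,
              subdivisions = 500L)$value,
    error = function(e) stop("Bayes factor integration failed: ",
                             conditionMessage(e), call. = FALSE))
  stop_if(!is.finite(val) || val <= 0,
          "Bayes factor integration did not converge")
  val
}

#' Two-factor repeated-measures ANOVA
#'
#' Fully within-subject two-way ANOVA by direct sums-of-squares
#' decomposition: each main effect and the interaction is tested against
#' its own subject-by-effect error stratum (uncorrected degrees of
#' freedom).  Participants with incomplete cells are removed listwise;
#' multiple observations per cell are averaged first.  Effect size is
#' generalized eta squared (SS_effect over SS_effect plus all
#' subject-related error sums of squares).
#'
#' @param data data frame in long format.
#' @param dv,id,a,b column names of the dependent variable, participant id
#'   and the two within factors.
#' @return object of class `idc_anova`: data frame with one row per effect
#'   (a, b, a:b): F, df_num, df_den, p, eta_sq_gen; attribute `n` is the
#'   number of participants retained.
#' @export
rm_anova_2way <- function(data, dv = "value", id = "participant",
                          a = "condition", b = "bin") {
  d <- data.frame(y = data[[dv]], id = factor(data[[id]]),
                  A = factor(data[[a]]), B = factor(data[[b]]))
  d <- d[complete.cases(d), , drop = FALSE]
  d <- aggregate(y ~ id + A + B, data = d, FUN = mean)
  # listwise removal of participants with missing cells
  full <- nlevels(d$A) * nlevels(d$B)
  cnt <- table(d$id)
  keep <- names(cnt)[cnt == full]
  removed <- setdiff(levels(d$id), keep)
  if (length(removed))
    message("rm_anova_2way: removed ", length(removed),
            " participant(s) with incomplete cells")
  d <- droplevels(d[d$id %in% keep, , drop = FALSE])
  n <- nlevels(d$id); p <- nlevels(d$A); q <- nlevels(d$B)
  stop_if(n < 2, "need at least 2 complete participants")

  gm <- mean(d$y)
  m_id <- tapply(d$y, d$id, mean)
  m_a <- tapply(d$y, d$A, mean)
  m_b <- tapply(d$y, d$B, mean)
  m_ab <- tapply(d$y, list(d$A, d$B), mean)
  m_ia <- tapply(d$y, list(d$id, d$A), mean)
  m_ib <- tapply(d$y, list(d$id, d$B), mean)

  ss_id <- p * q * sum((m_id - gm)^2)
  ss_a <- n * q * sum((m_a - gm)^2)
  ss_b <- n * p * sum((m_b - gm)^2)
  ss_ab <- n * sum((m_ab - outer(m_a - gm, m_b - gm, "+") - gm)^2)
  ss_ia <- q * sum((m_ia - outer(m_id - gm, m_a - gm, "+") - gm)^2)
  ss_ib <- p * sum((m_ib - outer(m_id - gm, m_b - gm, "+") - gm)^2)
  ss_tot <- sum((d$y - gm)^2)
  ss_iab <- ss_tot - ss_id - ss_a - ss_b - ss_ab - ss_ia - ss_ib

  eff <- data.frame(
    effect = c(a, b, paste0(a, ":", b)),
    ss = c(ss_a, ss_b, ss_ab),
    ss_err = c(ss_ia, ss_ib, ss_iab),
    df_num = c(p - 1, q - 1, (p - 1) * (q - 1)),
    df_den = c((p - 1) * (n - 1), (q - 1) * (n - 1),
               (p - 1) * (q - 1) * (n - 1)),
    stringsAsFactors = FALSE)
  eff$F <- (eff$ss / eff$df_num) / (eff$ss_err / eff$df_den)
  eff$p <- pf(eff$F, eff$df_num, eff$df_den, lower.tail = FALSE)
  ss_sub_err <- ss_id + ss_ia + ss_ib + ss_iab
  eff$eta_sq_gen <- eff$ss / (eff$ss + ss_sub_err)
  res <- eff[, c("effect", "F", "df_num", "df_den", "p", "eta_sq_gen")]
  attr(res, "n") <- n
  class(res) <- c("idc_anova", "data.frame")
  res
}

#' @export
print.idc_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (n = %d)\n", attr(x, "n")))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-20s F(%d, %d) = %.2f, p = %.4g, eta^2_G = %.3f\n",
                x$effect[i], x$df_num[i], x$df_den[i], x$F[i], x$p[i],
                x$eta_sq_gen[i]))
  invisible(x)
}

#' Exact power of a two-sided paired t test
#'
#' Power under the noncentral t distribution with df = n - 1 and
#' noncentrality d_z * sqrt(n), against the two-sided critical value at
#' `alpha`.
#'
#' @param n number of pairs.
#' @param d_z standardized within-subject effect size.
#' @param alpha two-sided significance level.
#' @return power in (0, 1).
#' @export
power_paired_t <- function(n, d_z, alpha = 0.05) {
  stop_if(alpha <= 0 || alpha >= 1, "alpha must be in (0, 1)")
  stop_if(n < 2, "n must be >= 2")
  df <- n - 1
  tc <- qt(1 - alpha / 2, df)
  ncp <- d_z * sqrt(n)
  pt(tc, df, ncp = ncp, lower.tail = FALSE) + pt(-tc, df, ncp = ncp)
}

#' Smallest sample size reaching a target power
#'
#' Scans n upward and returns the first n whose exact paired-t power (see
#' [power_paired_t()]) reaches `target_power`.
#'
#' @param target_power desired power, in (alpha, 1).
#' @param d_z standardized effect size.
#' @param alpha two-sided significance level.
#' @param n_max search bound.
#' @return integer n with power(n) >= target_power > power(n - 1).
#' @export
sample_size_paired_t <- function(target_power = 0.80, d_z = 0.5,
                                 alpha = 0.05, n_max = 1e5) {
  stop_if(target_power <= alpha || target_power >= 1,
          "target_power must be in (alpha, 1)")
  for (n in 2:n_max)
    if (power_paired_t(n, d_z, alpha) >= target_power) return(as.integer(n))
  stop("target power unreachable within n_max", call. = FALSE)
}
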