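#' Standard error of a log odds ratio from its printed confidence interval
#'
#' Recovers the log-scale standard error from a reported odds ratio and
#' two-sided 95\% confidence interval: se = (ln U - ln L) / (2 x 1.959964).
#' This lets published per-study rows enter an inverse-variance pooling.
#'
#' @param or_hat point estimate (must lie within the interval).
#' @param ci_low,ci_high interval bounds, `0 < ci_low < ci_high`.
#' @return standard error on the log-OR scale.
#' @examples
#' se_from_ci(1.00, 0.86, 1.17)
#' @export
se_from_ci <- function(or_hat, ci_low, ci_high) {
  .assert(all(ci_low > 0), "interval bounds must be positive")
  .assert(all(ci_low < ci_high), "ci_low must be strictly below ci_high")
  .assert(all(ci_low <= or_hat & or_hat <= ci_high),
          "the point estimate must lie inside its interval")
  (log(ci_high) - log(ci_low)) / (2 * qnorm(0.975))
}

#' Fixed-effects inverse-variance meta-analysis with Cochran's Q
#'
#' Pools per-study log odds ratios by the generic inverse-variance method
#' under a fixed-effects model: with weights w_i = 1 / se_i^2, the pooled
#' estimate is sum(w b) / sum(w) with standard error 1 / sqrt(sum(w)).
#' Heterogeneity is assessed by Cochran's Q = sum(w (b - pooled)^2),
#' referred to a chi-square distribution with (k - 1) degrees of freedom.
#' Studies with missing estimates are dropped; a single remaining study is
#' passed through with Q reported as not applicable (NA).
#'
#' @param estimates data.frame with columns `beta` and `se` (log-OR scale)
#'   and optionally `study`; rows with NA in either column are dropped.
#' @param alternative one-sided direction for the pooled p-value
#'   (`"less"`, `"greater"`, or `"two.sided"`).
#' @return A `meta_result` list: `k`, `pooled_beta`, `pooled_se`,
#'   `pooled_or`, `ci_low`, `ci_high`, `p_two_sided`, `p_one_sided`,
#'   `q_stat`, `df`, `p_het`.
#' @examples
#' pool_fixed_effects(data.frame(beta = c(0, 0.2), se = c(0.1, 0.2)))
#' @export
pool_fixed_effects <- function(estimates,
                               alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  .assert(is.data.frame(estimates) && all(c("beta", "se") %in% names(estimates)),
          "estimates must have beta and se columns")
  est <- estimates[!is.na(estimates$beta) & !is.na(estimates$se), , drop = FALSE]
  .assert(nrow(est) >= 1, "no usable study estimates")
  .assert(all(est$se > 0), "standard errors must be positive")
  k <- nrow(est)
  w <- 1 / est$se^2
  pooled_beta <- sum(w * est$beta) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  if (k >= 2) {
    q <- sum(w * (est$beta - pooled_beta)^2)
    df <- k - 1
    p_het <- pchisq(q, df, lower.tail = FALSE)
  } else {
    q <- NA_real_; df <- 0L; p_het <- NA_real_
  }
  z <- pooled_beta / pooled_se
  p_two <- 2 * pnorm(-abs(z))
  p_one <- switch(alternative, two.sided = NA_real_,
                  less = pnorm(z), greater = pnorm(-z))
  crit <- qnorm(0.975)
  structure(list(k = k, pooled_beta = pooled_beta, pooled_se = pooled_se,
                 pooled_or = exp(pooled_beta),
                 ci_low = exp(pooled_beta - crit * pooled_se),
                 ci_high = exp(pooled_beta + crit * pooled_se),
                 p_two_sided = p_two, p_one_sided = p_one,
                 q_stat = q, df = df, p_het = p_het),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("fixed-effects meta-analysis of %d studies\n", x$k))
  cat(sprintf("  pooled OR %.3f (95%% CI %.3f-%.3f), two-sided p = %.3g\n",
              x$pooled_or, x$ci_low, x$ci_high, x$p_two_sided))
  if (!is.na(x$q_stat)) {
    cat(sprintf("  Cochran's Q = %.3f on %d df, p_het = %.3g\n",
                x$q_stat, x$df, x$p_het))
  } else {
    cat("  heterogeneity: not applicable (single study)\n")
  }
  invisible(x)
}

#' Meta-analyze published per-study odds-ratio rows
#'
#' Convenience wrapper: takes rows shaped like a published replication
#' table (`study`, `or`, `ci_low`, `ci_high`), reconstructs log-scale
#' standard errors with [se_from_ci()], and pools with
#' [pool_fixed_effects()].
#'
#' @param rows data.frame with `or`, `ci_low`, `ci_high` and optionally
#'   `study`; rows with any NA are dropped (unavailable studies).
#' @param alternative passed to [pool_fixed_effects()].
#' @return A `meta_result`.
#' @export
pool_or_table <- function(rows, alternative = "two.sided") {
  keep <- !is.na(rows$or) & !is.na(rows$ci_low) & !is.na(rows$ci_high)
  rows <- rows[keep, , drop = FALSE]
  .assert(nrow(rows) >= 1, "no usable study rows")
  est <- data.frame(beta = log(rows$or),
                    se = se_from_ci(rows$or, rows$ci_low, rows$ci_high))
  if (!is.null(rows$study)) est$study <- rows$study
  pool_fixed_effects(est, alternative = alternative)
}
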