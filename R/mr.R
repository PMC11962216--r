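# Genetic arm, stage 2: two-sample MR estimators on harmonized instruments
# plus the heterogeneity / pleiotropy sensitivity suite.

mr_estimate <- function(method, beta, se, nsnp, df = NA_real_) {
  z <- beta / se
  pval <- if (is.finite(df)) p_two_sided_t(z, df) else p_two_sided(z)
  if (!is.finite(z)) pval <- NA_real_
  structure(list(
    method = method, nsnp = as.integer(nsnp),
    beta = beta, se = se, pval = pval,
    or_ = exp(beta),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se)
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (nsnp=%d): beta %.4f (se %.4f), OR %.3f (95%% CI %.3f-%.3f), p=%.3g\n",
              x$method, x$nsnp, x$beta, x$se, x$or_, x$ci_low, x$ci_high, x$pval))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, nsnp = x$nsnp, beta = x$beta, se = x$se,
             pval = x$pval, or = x$or_, ci_low = x$ci_low, ci_high = x$ci_high,
             stringsAsFactors = FALSE)
}

# Per-SNP Wald ratios and their first-order delta-method SEs.
ratio_stats <- function(pairs) {
  list(ratio = pairs$beta_out / pairs$beta_exp,
       se = pairs$se_out / abs(pairs$beta_exp))
}

#' Wald ratio estimate from a single instrument
#'
#' The causal effect proxied by one SNP: `beta_out / beta_exp`. The default
#' standard error is the first-order delta approximation
#' `se_out / |beta_exp|`; `second_order = TRUE` adds the term propagating
#' uncertainty in the SNP-exposure effect.
#'
#' @param pair one-row harmonized-pairs data.frame.
#' @param second_order use the second-order delta-method standard error.
#' @return `mr_estimate` with `method = "wald_ratio"`.
#' @export
wald_ratio <- function(pair, second_order = FALSE) {
  if (nrow(pair) != 1L) stop("wald_ratio expects exactly one pair")
  if (pair$beta_exp == 0) stop("beta_exp is zero: Wald ratio undefined")
  beta <- pair$beta_out / pair$beta_exp
  se <- pair$se_out / abs(pair$beta_exp)
  if (second_order) {
    se <- sqrt(pair$se_out^2 / pair$beta_exp^2 +
                 pair$beta_out^2 * pair$se_exp^2 / pair$beta_exp^4)
  }
  mr_estimate("wald_ratio", beta, se, 1L)
}

#' Inverse-variance-weighted MR estimate
#'
#' The primary estimator: a weighted regression of outcome effects on
#' exposure effects through the origin, weights `1/se_out^2`. Equivalent to
#' the weighted mean of per-SNP Wald ratios with weights
#' `beta_exp^2 / se_out^2`. The default is fixed-effect; with
#' `random_effects = TRUE` the standard error is inflated by
#' `max(1, sqrt(Q / (nsnp - 1)))` (multiplicative random effects).
#'
#' @param pairs harmonized-pairs data.frame with at least two rows.
#' @param random_effects inflate the SE under heterogeneity.
#' @return `mr_estimate` with `method = "ivw"`.
#' @export
ivw <- function(pairs, random_effects = FALSE) {
  if (nrow(pairs) < 2L) {
    stop("ivw needs at least 2 instruments; use wald_ratio for a single SNP")
  }
  w <- pairs$beta_exp^2 / pairs$se_out^2
  ratio <- pairs$beta_out / pairs$beta_exp
  beta <- sum(w * ratio) / sum(w)
  se <- 1 / sqrt(sum(w))
  if (random_effects) {
    q <- sum(w * (ratio - beta)^2)
    se <- se * max(1, sqrt(q / (nrow(pairs) - 1)))
  }
  mr_estimate("ivw", beta, se, nrow(pairs))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome on exposure effects with a free
#' intercept (weights `1/se_out^2`), after orienting every instrument so
#' the exposure effect is positive. A nonzero intercept indicates
#' directional pleiotropy; the slope is a pleiotropy-adjusted causal
#' estimate. Inference uses t(nsnp - 2); the coefficient standard errors
#' follow the usual MR-Egger convention of flooring the residual scale at
#' 1 (multiplicative random effects, never deflating).
#'
#' @param pairs harmonized-pairs data.frame with at least three rows.
#' @return list with `slope` (`mr_estimate`), `intercept`, `intercept_se`,
#'   `intercept_pval`.
#' @export
mr_egger <- function(pairs) {
  n <- nrow(pairs)
  if (n < 3L) stop("mr_egger needs at least 3 instruments")
  flip <- sign(pairs$beta_exp)
  bx <- pairs$beta_exp * flip
  by <- pairs$beta_out * flip
  w <- 1 / pairs$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  scale <- max(1, sm$sigma)
  slope <- sm$coefficients["bx", "Estimate"]
  slope_se <- sm$coefficients["bx", "Std. Error"] / sm$sigma * scale
  int <- sm$coefficients["(Intercept)", "Estimate"]
  int_se <- sm$coefficients["(Intercept)", "Std. Error"] / sm$sigma * scale
  list(
    slope = mr_estimate("egger", slope, slope_se, n, df = n - 2),
    intercept = int,
    intercept_se = int_se,
    intercept_pval = p_two_sided_t(int / int_se, n - 2)
  )
}

# Interpolated weighted median of values x with weights w: the point where
# the centred cumulative weight (cumsum(w) - w/2) / sum(w) crosses one half.
weighted_median_point <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[1] >= 0.5) return(x[1])
  if (s[length(s)] <= 0.5) return(x[length(x)])
  k <- max(which(s < 0.5))
  x[k] + (x[k + 1] - x[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

#' Weighted-median MR estimate
#'
#' The weighted median of per-SNP Wald ratios with inverse-variance weights
#' `1/se(ratio)^2`, consistent when instruments carrying at least half of
#' the weight are valid. The standard error comes from a seeded parametric
#' bootstrap that redraws both exposure and outcome effects from their
#' sampling distributions.
#'
#' @param pairs harmonized-pairs data.frame with at least three rows.
#' @param n_boot bootstrap replicates for the standard error (0 skips the
#'   bootstrap and returns `se = NA`).
#' @param seed RNG seed for the bootstrap.
#' @return `mr_estimate` with `method = "weighted_median"`.
#' @export
weighted_median <- function(pairs, n_boot = 1000, seed = 1) {
  n <- nrow(pairs)
  if (n < 3L) stop("weighted_median needs at least 3 instruments")
  rs <- ratio_stats(pairs)
  beta <- weighted_median_point(rs$ratio, 1 / rs$se^2)
  se <- NA_real_
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      bx <- matrix(stats::rnorm(n_boot * n, pairs$beta_exp, pairs$se_exp),
                   nrow = n_boot, byrow = TRUE)
      by <- matrix(stats::rnorm(n_boot * n, pairs$beta_out, pairs$se_out),
                   nrow = n_boot, byrow = TRUE)
      vapply(seq_len(n_boot), function(b) {
        r <- by[b, ] / bx[b, ]
        rse <- pairs$se_out / abs(bx[b, ])
        weighted_median_point(r, 1 / rse^2)
      }, numeric(1))
    })
    se <- stats::sd(boots)
  }
  mr_estimate("weighted_median", beta, se, n)
}

# Argmax of the weighted kernel density of the ratios; bandwidth is
# `bandwidth` times the modified Silverman rule 0.9 min(sd, mad) n^(-1/5).
weighted_mode_point <- function(ratio, w, bandwidth) {
  spread <- c(stats::sd(ratio), stats::mad(ratio))
  spread <- spread[spread > 0]
  if (!length(spread)) return(ratio[1])
  h <- bandwidth * 0.9 * min(spread) * length(ratio)^(-1 / 5)
  d <- stats::density(ratio, weights = w / sum(w), bw = h,
                      from = min(ratio), to = max(ratio), n = 512)
  d$x[which.max(d$y)]
}

#' Weighted-mode MR estimate
#'
#' The mode of the smoothed, inverse-variance-weighted empirical density of
#' per-SNP Wald ratios: consistent when the largest group of instruments
#' sharing the same ratio is valid, even if they carry less than half the
#' weight. The standard error comes from a seeded parametric bootstrap.
#'
#' @param pairs harmonized-pairs data.frame with at least three rows.
#' @param bandwidth multiplier on the modified Silverman bandwidth rule.
#' @param n_boot bootstrap replicates for the standard error.
#' @param seed RNG seed for the bootstrap.
#' @return `mr_estimate` with `method = "weighted_mode"`.
#' @export
weighted_mode <- function(pairs, bandwidth = 1.0, n_boot = 1000, seed = 1) {
  n <- nrow(pairs)
  if (n < 3L) stop("weighted_mode needs at least 3 instruments")
  rs <- ratio_stats(pairs)
  w <- 1 / rs$se^2
  beta <- weighted_mode_point(rs$ratio, w, bandwidth)
  se <- NA_real_
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      bx <- matrix(stats::rnorm(n_boot * n, pairs$beta_exp, pairs$se_exp),
                   nrow = n_boot, byrow = TRUE)
      by <- matrix(stats::rnorm(n_boot * n, pairs$beta_out, pairs$se_out),
                   nrow = n_boot, byrow = TRUE)
      vapply(seq_len(n_boot), function(b) {
        r <- by[b, ] / bx[b, ]
        rse <- pairs$se_out / abs(bx[b, ])
        weighted_mode_point(r, 1 / rse^2, bandwidth)
      }, numeric(1))
    })
    se <- stats::sd(boots)
  }
  mr_estimate("weighted_mode", beta, se, n)
}

#' Heterogeneity, pleiotropy and leave-one-out sensitivity suite
#'
#' Computes Cochran's Q against the IVW estimate (weights
#' `beta_exp^2 / se_out^2`, chi-squared on nsnp - 1 df), the MR-Egger
#' intercept with its test (NA below 3 instruments), and the leave-one-out
#' series of IVW estimates (Wald ratio when only one SNP remains).
#'
#' @param pairs harmonized-pairs data.frame with at least two rows.
#' @param primary optional `mr_estimate` to centre Q on; defaults to the
#'   fixed-effect IVW estimate of `pairs`.
#' @return list of class `sensitivity_report`: `q`, `q_df`, `q_pval`,
#'   `egger_intercept`, `egger_intercept_se`, `egger_intercept_pval`, and
#'   `loo` (data.frame: excluded `snp_id`, `beta`, `se`, `pval`).
#' @export
sensitivity <- function(pairs, primary = NULL) {
  n <- nrow(pairs)
  if (n < 2L) stop("sensitivity requires at least 2 instruments")
  if (is.null(primary)) primary <- ivw(pairs)
  w <- pairs$beta_exp^2 / pairs$se_out^2
  ratio <- pairs$beta_out / pairs$beta_exp
  q <- sum(w * (ratio - primary$beta)^2)
  q_df <- n - 1L
  q_pval <- stats::pchisq(q, df = q_df, lower.tail = FALSE)
  if (n >= 3L) {
    eg <- mr_egger(pairs)
    egger_intercept <- eg$intercept
    egger_intercept_se <- eg$intercept_se
    egger_intercept_pval <- eg$intercept_pval
  } else {
    egger_intercept <- egger_intercept_se <- egger_intercept_pval <- NA_real_
  }
  loo <- do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- pairs[-i, , drop = FALSE]
    est <- if (nrow(rest) == 1L) wald_ratio(rest) else ivw(rest)
    data.frame(snp_id = pairs$snp_id[i], beta = est$beta, se = est$se,
               pval = est$pval, stringsAsFactors = FALSE)
  }))
  structure(list(q = q, q_df = q_df, q_pval = q_pval,
                 egger_intercept = egger_intercept,
                 egger_intercept_se = egger_intercept_se,
                 egger_intercept_pval = egger_intercept_pval,
                 loo = loo),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Cochran Q = %.3f on %d df (p = %.3g)\n", x$q, x$q_df, x$q_pval))
  if (!is.na(x$egger_intercept)) {
    cat(sprintf("Egger intercept = %.4f (se %.4f, p = %.3g)\n",
                x$egger_intercept, x$egger_intercept_se,
                x$egger_intercept_pval))
  }
  cat(sprintf("leave-one-out: %d refits\n", nrow(x$loo)))
  invisible(x)
}
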