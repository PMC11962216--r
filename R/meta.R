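# Genetic arm, stage 5: inverse-variance meta-analysis of per-source MR
# estimates for the same gene-outcome pair.

#' Assemble meta-analysis input
#'
#' @param label character vector of study/source labels.
#' @param beta numeric vector of per-study effect estimates (log scale).
#' @param se numeric vector of per-study standard errors; alternatively
#'   supply `p` and the SE is back-derived as `|beta| / qnorm(1 - p/2)`.
#' @param p optional numeric vector of two-sided p-values used only where
#'   `se` is missing. Bound-style values ("<0.01") are not accepted: the
#'   caller must resolve them to numbers first.
#' @return data.frame of class `meta_input` with columns `label`, `beta`,
#'   `se`.
#' @export
meta_input <- function(label, beta, se = NULL, p = NULL) {
  n <- length(beta)
  stopifnot(length(label) == n)
  if (is.null(se)) se <- rep(NA_real_, n)
  stopifnot(length(se) == n)
  need <- is.na(se)
  if (any(need)) {
    if (is.null(p)) stop("se missing and no p-values supplied")
    if (!is.numeric(p)) {
      stop("p must be numeric; resolve bound-style values (e.g. '<0.01') ",
           "to numbers before calling")
    }
    if (any(is.na(p[need])) || any(p[need] <= 0 | p[need] >= 1)) {
      stop("p-values used to derive se must lie strictly in (0, 1)")
    }
    if (any(beta[need] == 0)) {
      stop("cannot derive se from p when beta is zero")
    }
    se[need] <- abs(beta[need]) / stats::qnorm(1 - p[need] / 2)
  }
  if (any(se <= 0)) stop("standard errors must be positive")
  structure(data.frame(label = as.character(label), beta = beta, se = se,
                       stringsAsFactors = FALSE),
            class = c("meta_input", "data.frame"))
}

meta_result <- function(model, beta, se, k, q, q_df, tau2 = 0) {
  q_pval <- if (q_df > 0) stats::pchisq(q, df = q_df, lower.tail = FALSE) else NA_real_
  i2 <- if (q > 0 && q_df > 0) max(0, 100 * (q - q_df) / q) else 0
  structure(list(
    model = model, k = as.integer(k),
    beta = beta, se = se, pval = p_two_sided(beta / se),
    or_ = exp(beta),
    ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
    q = q, q_df = as.integer(q_df), q_pval = q_pval, i2 = i2, tau2 = tau2
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("%s-effect meta (k=%d): OR %.3f (95%% CI %.3f-%.3f), p=%.3g\n",
              x$model, x$k, x$or_, x$ci_low, x$ci_high, x$pval))
  cat(sprintf("Q = %.3f on %d df (p = %.3g), I2 = %.1f%%, tau2 = %.4f\n",
              x$q, x$q_df, x$q_pval, x$i2, x$tau2))
  invisible(x)
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools per-source estimates with weights `1/se^2`; Cochran's Q and I2
#' quantify between-source heterogeneity. A single study is returned
#' unchanged with a warning rather than rejected, so pipelines degrade
#' gracefully when only one outcome source yields an estimate.
#'
#' @param input `meta_input` data.frame (or any data.frame with `label`,
#'   `beta`, `se`).
#' @return `meta_result` with `model = "fixed"`.
#' @export
meta_fixed <- function(input) {
  b <- input$beta
  se <- input$se
  k <- length(b)
  if (k < 2L) {
    warning("fewer than 2 studies: returning the single estimate unpooled")
    return(meta_result("fixed", b, se, k, q = 0, q_df = 0))
  }
  w <- 1 / se^2
  beta <- sum(w * b) / sum(w)
  q <- sum(w * (b - beta)^2)
  meta_result("fixed", beta, 1 / sqrt(sum(w)), k, q, k - 1L)
}

#' Random-effects (DerSimonian-Laird) meta-analysis
#'
#' Estimates the between-study variance as
#' `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effect weights `w = 1/se^2`, then pools with weights
#' `1/(se^2 + tau2)`. Reduces to [meta_fixed()] when `Q <= df`.
#'
#' @inheritParams meta_fixed
#' @return `meta_result` with `model = "random"`.
#' @export
meta_random <- function(input) {
  b <- input$beta
  se <- input$se
  k <- length(b)
  if (k < 2L) {
    warning("fewer than 2 studies: returning the single estimate unpooled")
    return(meta_result("random", b, se, k, q = 0, q_df = 0))
  }
  w <- 1 / se^2
  beta_fe <- sum(w * b) / sum(w)
  q <- sum(w * (b - beta_fe)^2)
  df <- k - 1
  tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  w_re <- 1 / (se^2 + tau2)
  beta <- sum(w_re * b) / sum(w_re)
  meta_result("random", beta, 1 / sqrt(sum(w_re)), k, q, df, tau2 = tau2)
}
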