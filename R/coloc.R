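# Genetic arm, stage 4: Bayesian colocalization of eQTL and GWAS signals
# over a cis region via Wakefield approximate Bayes factors.

#' Log approximate Bayes factor for one SNP association
#'
#' Wakefield's approximation: with shrinkage `r = prior_sd^2 /
#' (prior_sd^2 + se^2)` and `z = beta/se`, the log Bayes factor for
#' association against the null is `0.5 log(1 - r) + 0.5 z^2 r`.
#'
#' @param beta effect estimate.
#' @param se standard error (> 0).
#' @param prior_sd prior standard deviation of the true effect (> 0).
#' @return log approximate Bayes factor (vectorized).
#' @export
#' @examples
#' log_abf(0.3, 0.05, 0.15)
log_abf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stop("se must be positive")
  if (any(prior_sd < 0)) stop("prior_sd must be nonnegative")
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  z <- beta / se
  0.5 * log1p(-r) + 0.5 * z^2 * r
}

# Per-SNP log ABFs for one trait's records; backs beta/se out of the
# p-value, allele frequency and sample size when they are missing.
abf_for_trait <- function(assoc, prior_sd, trait_label) {
  beta <- assoc$beta
  se <- assoc$se
  fallback <- is.na(beta) | is.na(se)
  if (any(fallback)) {
    i <- fallback
    ok <- !is.na(assoc$pval[i]) & !is.na(assoc$eaf[i]) & !is.na(assoc$n[i])
    if (!all(ok)) {
      stop(trait_label, ": records missing beta/se need pval, eaf and n ",
           "for the p-value fallback")
    }
    maf <- pmin(assoc$eaf[i], 1 - assoc$eaf[i])
    se[i] <- 1 / sqrt(2 * maf * (1 - maf) * assoc$n[i])
    z <- stats::qnorm(pmax(assoc$pval[i], 1e-300) / 2, lower.tail = FALSE)
    beta[i] <- z * se[i]
  }
  log_abf(beta, se, prior_sd)
}

#' Approximate-Bayes-factor colocalization over a region
#'
#' Assuming at most one causal variant per trait, computes posterior
#' probabilities of the five hypotheses: H0 no association with either
#' trait; H1/H2 association with trait 1/2 only; H3 both traits but
#' distinct causal variants; H4 both traits through one shared variant.
#' All hypothesis sums are accumulated in log space. Records are
#' intersected on `snp_id`; the per-SNP evidence is the Wakefield log ABF
#' of each trait.
#'
#' @param trait1,trait2 summary-statistics data.frames (see
#'   [assoc_records()]); trait 1 is conventionally the quantitative eQTL
#'   trait, trait 2 the case-control GWAS.
#' @param p1,p2 prior probability a SNP is causal for trait 1 / trait 2
#'   only.
#' @param p12 prior probability a SNP is causal for both traits.
#' @param prior_sd1,prior_sd2 prior effect SDs (0.15 for a quantitative
#'   trait, 0.2 on the log-odds scale for a case-control trait).
#' @param gene_id,outcome_id labels carried into the result.
#' @return list of class `coloc_result`: `gene_id`, `outcome_id`,
#'   `n_snps`, `pp` (named vector `pp_h0` .. `pp_h4`), `priors`, `verdict`.
#' @export
coloc_abf <- function(trait1, trait2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd1 = 0.15, prior_sd2 = 0.2,
                      gene_id = NA_character_, outcome_id = NA_character_) {
  trait1 <- assoc_records(trait1)
  trait2 <- assoc_records(trait2)
  if (anyDuplicated(trait1$snp_id) || anyDuplicated(trait2$snp_id)) {
    stop("duplicate snp_id within a trait")
  }
  shared <- intersect(trait1$snp_id, trait2$snp_id)
  if (!length(shared)) stop("traits share no SNPs after intersection")
  t1 <- trait1[match(shared, trait1$snp_id), , drop = FALSE]
  t2 <- trait2[match(shared, trait2$snp_id), , drop = FALSE]
  l1 <- abf_for_trait(t1, prior_sd1, "trait1")
  l2 <- abf_for_trait(t2, prior_sd2, "trait2")

  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  # H3 sums ABF1_i * ABF2_j over i != j = (sum_i)(sum_j) - sum over i == j.
  s3 <- logdiffexp(s1 + s2, s12)

  logpost <- c(
    0,
    log(p1) + s1,
    log(p2) + s2,
    if (is.finite(s3)) log(p1) + log(p2) + s3 else -Inf,
    log(p12) + s12
  )
  denom <- logsumexp(logpost)
  pp <- exp(logpost - denom)
  names(pp) <- paste0("pp_h", 0:4)
  res <- structure(list(
    gene_id = gene_id, outcome_id = outcome_id,
    n_snps = length(shared), pp = pp,
    priors = c(p1 = p1, p2 = p2, p12 = p12),
    verdict = NA_character_
  ), class = "coloc_result")
  res$verdict <- classify_coloc(res)
  res
}

#' Classify a colocalization result by its H4 posterior
#'
#' Shared-causal-variant evidence is called `possible` when PP.H4 exceeds
#' 50% and `highly_likely` once it reaches 80%; otherwise `none`.
#'
#' @param result `coloc_result` object (or a list with a `pp` vector).
#' @return one of `"none"`, `"possible"`, `"highly_likely"`.
#' @export
classify_coloc <- function(result) {
  h4 <- unname(result$pp["pp_h4"])
  if (h4 >= 0.8) "highly_likely" else if (h4 > 0.5) "possible" else "none"
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc %s -> %s over %d SNPs: ", x$gene_id, x$outcome_id,
              x$n_snps))
  cat(paste(sprintf("%s=%.3f", names(x$pp), x$pp), collapse = " "), "\n")
  cat("verdict:", x$verdict, "\n")
  invisible(x)
}
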