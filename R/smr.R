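# Genetic arm, stage 3: summary-data-based MR at the top cis-eQTL SNP and
# the HEIDI test separating a shared causal variant from linkage.

# Tail probability P(Q > q) for Q = sum(lambda_i * chi2_1) via the
# Liu-Tang-Zhang moment-matched noncentral chi-squared approximation.
pquadform_liu <- function(q, lambda) {
  lambda <- lambda[lambda > 1e-12]
  if (!length(lambda)) return(NA_real_)
  c1 <- sum(lambda)
  c2 <- sum(lambda^2)
  c3 <- sum(lambda^3)
  c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  mu_q <- c1
  sigma_q <- sqrt(2 * c2)
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    ncp <- s1 * a^3 - a^2
    df <- a^2 - 2 * ncp
  } else {
    ncp <- 0
    df <- 1 / s2
  }
  mu_x <- df + ncp
  sigma_x <- sqrt(2 * (df + 2 * ncp))
  t_star <- (q - mu_q) / sigma_q * sigma_x + mu_x
  stats::pchisq(t_star, df = df, ncp = ncp, lower.tail = FALSE)
}

#' Summary-data-based MR at the top cis-eQTL SNP
#'
#' Uses the single strongest eQTL (smallest exposure p-value) as
#' instrument: `b_smr = beta_out / beta_exp` there. The test statistic is
#' the harmonic combination of the two z-scores,
#' `T = z_x^2 z_y^2 / (z_x^2 + z_y^2)`, referred to chi-squared on 1 df;
#' the SE is backed out as `|b_smr| / sqrt(T)`.
#'
#' @param pairs harmonized-pairs data.frame covering the cis region (need
#'   not be clumped).
#' @param gene_id,outcome_id labels carried into the result.
#' @return list of class `smr_result`: `gene_id`, `outcome_id`, `top_snp`,
#'   `b_smr`, `se_smr`, `p_smr`, `p_heidi` (NA until [heidi_test()] is
#'   run), `n_heidi_snps`.
#' @export
smr_test <- function(pairs, gene_id = NA_character_,
                     outcome_id = NA_character_) {
  if (!nrow(pairs)) stop("smr_test needs at least one harmonized pair")
  top <- which.min(pairs$pval_exp)
  bx <- pairs$beta_exp[top]
  if (bx == 0) stop("top eQTL SNP has beta_exp = 0: SMR undefined")
  by <- pairs$beta_out[top]
  zx <- bx / pairs$se_exp[top]
  zy <- by / pairs$se_out[top]
  t_smr <- (zx^2 * zy^2) / (zx^2 + zy^2)
  b_smr <- by / bx
  se_smr <- abs(b_smr) / sqrt(t_smr)
  structure(list(
    gene_id = gene_id, outcome_id = outcome_id,
    top_snp = pairs$snp_id[top],
    b_smr = b_smr, se_smr = se_smr,
    p_smr = stats::pchisq(t_smr, df = 1, lower.tail = FALSE),
    p_heidi = NA_real_, n_heidi_snps = 0L
  ), class = "smr_result")
}

#' @export
print.smr_result <- function(x, ...) {
  cat(sprintf("SMR %s -> %s: top %s, b = %.4f (se %.4f), p = %.3g",
              x$gene_id, x$outcome_id, x$top_snp, x$b_smr, x$se_smr, x$p_smr))
  if (!is.na(x$p_heidi)) {
    cat(sprintf(", HEIDI p = %.3g (%d SNPs)", x$p_heidi, x$n_heidi_snps))
  }
  cat("\n")
  invisible(x)
}

#' HEIDI test: heterogeneity in dependent instruments
#'
#' Under a single causal variant shared by expression and outcome, the
#' ratio `beta_out / beta_exp` is the same at every SNP in LD with it; under
#' linkage (distinct causal variants) the ratios diverge. HEIDI tests the
#' differences `d_i = b_smr(snp_i) - b_smr(top)` across cis SNPs that are
#' themselves eQTLs (`pval_exp < p_eqtl_max`) and in intermediate LD with
#' the top SNP (`r^2` within `r2_range`), capped at `max_snps` by ascending
#' exposure p-value. The covariance of `d` follows from the LD matrix by
#' the delta method; the statistic `sum((d_i / sd(d_i))^2)` is referred to
#' a weighted chi-squared mixture with weights from the eigenvalues of the
#' correlation matrix of `d`.
#'
#' @param region_pairs harmonized-pairs data.frame for the cis region.
#' @param ld square correlation matrix with SNP-id dimnames.
#' @param top_snp id of the SMR top SNP (must appear in both inputs).
#' @param p_eqtl_max eligibility threshold on the exposure p-value.
#' @param r2_range inclusive LD bounds (with the top SNP) for eligibility.
#' @param max_snps maximum number of non-top SNPs used.
#' @param min_snps below this many eligible SNPs the test is not run and
#'   `p_heidi` is NA.
#' @return list with `p_heidi` and `n_heidi_snps` (number of non-top SNPs
#'   used).
#' @export
heidi_test <- function(region_pairs, ld, top_snp, p_eqtl_max = 1.57e-3,
                       r2_range = c(0.05, 0.9), max_snps = 20,
                       min_snps = 3) {
  if (!(top_snp %in% region_pairs$snp_id)) {
    stop("top_snp '", top_snp, "' not present in region_pairs")
  }
  if (!(top_snp %in% rownames(ld))) {
    stop("top_snp '", top_snp, "' not present in LD matrix")
  }
  miss <- setdiff(region_pairs$snp_id, rownames(ld))
  if (length(miss)) stop("SNP absent from LD matrix: ", miss[1])
  top_i <- match(top_snp, region_pairs$snp_id)
  r_top <- ld[top_snp, region_pairs$snp_id]
  r2_top <- r_top^2
  eligible <- which(
    seq_len(nrow(region_pairs)) != top_i &
      region_pairs$pval_exp < p_eqtl_max &
      r2_top >= r2_range[1] & r2_top <= r2_range[2]
  )
  if (length(eligible) > max_snps) {
    eligible <- eligible[order(region_pairs$pval_exp[eligible])][seq_len(max_snps)]
  }
  m <- length(eligible)
  if (m < min_snps) {
    warning("only ", m, " eligible SNPs for HEIDI (need >= ", min_snps,
            "); returning NA")
    return(list(p_heidi = NA_real_, n_heidi_snps = m))
  }
  use <- c(top_i, eligible)
  sub <- region_pairs[use, , drop = FALSE]
  r_sub <- ld[sub$snp_id, sub$snp_id]
  k <- nrow(sub)

  bx <- sub$beta_exp
  by <- sub$beta_out
  sx <- sub$se_exp
  sy <- sub$se_out
  sigma_x <- r_sub * tcrossprod(sx)
  sigma_y <- r_sub * tcrossprod(sy)

  # d_i = by_i/bx_i - by_1/bx_1 for i = 2..k (index 1 is the top SNP);
  # J_x, J_y are the Jacobians of d w.r.t. the bx and by vectors.
  jx <- matrix(0, k - 1, k)
  jy <- matrix(0, k - 1, k)
  for (i in 2:k) {
    jx[i - 1, i] <- -by[i] / bx[i]^2
    jy[i - 1, i] <- 1 / bx[i]
    jx[i - 1, 1] <- by[1] / bx[1]^2
    jy[i - 1, 1] <- -1 / bx[1]
  }
  v <- jx %*% sigma_x %*% t(jx) + jy %*% sigma_y %*% t(jy)
  d <- by / bx - by[1] / bx[1]
  d <- d[-1]
  sd_d <- sqrt(diag(v))
  z_d <- d / sd_d
  t_heidi <- sum(z_d^2)
  corr_d <- v / tcrossprod(sd_d)
  lambda <- eigen(corr_d, symmetric = TRUE, only.values = TRUE)$values
  lambda[lambda < 0] <- 0
  list(p_heidi = pquadform_liu(t_heidi, lambda), n_heidi_snps = m)
}

#' Run SMR and HEIDI together over a cis region
#'
#' Convenience wrapper: [smr_test()] on the region, then [heidi_test()]
#' around the top SNP, with results merged into one `smr_result`.
#'
#' @inheritParams heidi_test
#' @inheritParams smr_test
#' @param ... further arguments passed to [heidi_test()].
#' @return `smr_result` with `p_heidi` and `n_heidi_snps` filled in.
#' @export
smr_heidi <- function(region_pairs, ld, gene_id = NA_character_,
                      outcome_id = NA_character_, ...) {
  res <- smr_test(region_pairs, gene_id = gene_id, outcome_id = outcome_id)
  h <- heidi_test(region_pairs, ld, res$top_snp, ...)
  res$p_heidi <- h$p_heidi
  res$n_heidi_snps <- as.integer(h$n_heidi_snps)
  res
}
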