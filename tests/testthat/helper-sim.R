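# Shared fixtures and independent oracles used across test files.

# Harmonized-pairs frame from raw vectors (defaults give strong instruments).
make_pairs <- function(beta_exp, beta_out, se_exp = 0.01,
                       se_out = 0.01, eaf = 0.3, n_exp = 30000,
                       n_out = 50000) {
  k <- length(beta_exp)
  data.frame(
    snp_id = sprintf("rs%04d", seq_len(k)),
    beta_exp = beta_exp, se_exp = rep_len(se_exp, k),
    pval_exp = 2 * pnorm(-abs(beta_exp / rep_len(se_exp, k))),
    n_exp = rep_len(n_exp, k), eaf = rep_len(eaf, k),
    beta_out = beta_out, se_out = rep_len(se_out, k),
    pval_out = 2 * pnorm(-abs(beta_out / rep_len(se_out, k))),
    n_out = rep_len(n_out, k), flipped = FALSE,
    stringsAsFactors = FALSE
  )
}

# Summary-statistics frame from raw vectors, all on chromosome 1.
make_assoc <- function(snp_id, pos_bp, beta, se, pval = NULL, eaf = 0.3,
                       n = 30000, effect_allele = "A", other_allele = "G",
                       chrom = "1") {
  k <- length(snp_id)
  if (is.null(pval)) pval <- 2 * pnorm(-abs(beta / se))
  data.frame(
    snp_id = snp_id, chrom = rep_len(chrom, k), pos_bp = pos_bp,
    effect_allele = rep_len(effect_allele, k),
    other_allele = rep_len(other_allele, k),
    eaf = rep_len(eaf, k), beta = beta, se = rep_len(se, k),
    pval = pval, n = rep_len(n, k), stringsAsFactors = FALSE
  )
}

# One synthetic case report row with overridable fields.
make_report <- function(case_id, version = 1L, drug = "haloperidol",
                        role = "suspect", pt = "Seizure", sex = "F",
                        age_years = 40, weight_kg = 70, reporter = "MD",
                        country = "US", year = 2019L) {
  data.frame(case_id = case_id, version = version, drug = drug, role = role,
             pt = pt, sex = sex, age_years = age_years,
             weight_kg = weight_kg, reporter = reporter, country = country,
             year = year, stringsAsFactors = FALSE)
}

# Simulate a study and return harmonized pairs plus the sim object.
sim_harmonized <- function(seed, theta = 0, n_snps = 20, ld_rho = 0, ...) {
  cfg <- sim_config(n_snps = n_snps, ld_rho = ld_rho, seed = seed, ...)
  tr_args <- list(...)[intersect(names(list(...)),
                                 c("pleiotropy_effect"))]
  tr <- do.call(sim_truth, c(list(cfg = cfg, theta = theta), tr_args))
  st <- simulate_summary_stats(cfg, tr)
  list(pairs = harmonize(st$exposure, st$outcome), sim = st)
}

# Independent oracle: interpolated weighted median computed directly from
# its defining cumulative-weight construction on an explicit grid search.
oracle_weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  cw <- cumsum(w) - 0.5 * w
  stats::approx(cw, x, xout = 0.5, rule = 2)$y
}

# Independent oracle for greedy LD clumping: enumerate every admissible
# subset (all pairwise r2 strictly below the threshold within the window)
# and return the one that is greedily optimal in priority order, i.e. the
# lexicographically first maximal admissible subset under the ranking
# (pval, pos, snp_id).
oracle_clump <- function(records, ld, cfg) {
  n <- nrow(records)
  rank_order <- order(records$pval, records$pos_bp, records$snp_id)
  ranked <- records[rank_order, , drop = FALSE]
  r2 <- ld[ranked$snp_id, ranked$snp_id]^2
  window_bp <- cfg$clump_window_kb * 1000
  admissible <- function(idx) {
    if (length(idx) < 2) return(TRUE)
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (a >= b) next
        i <- idx[a]; j <- idx[b]
        near <- abs(ranked$pos_bp[i] - ranked$pos_bp[j]) <= window_bp
        if (near && r2[i, j] >= cfg$clump_r2) return(FALSE)
      }
    }
    TRUE
  }
  best <- NULL
  for (code in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(code, 2^(seq_len(n) - 1L)) > 0)
    if (!admissible(idx)) next
    maximal <- all(vapply(setdiff(seq_len(n), idx), function(j) {
      !admissible(sort(c(idx, j)))
    }, logical(1)))
    if (!maximal) next
    if (is.null(best)) {
      best <- idx
    } else {
      # lexicographic comparison on the ranked indices
      l <- max(length(best), length(idx))
      a <- c(best, rep(Inf, l - length(best)))
      b <- c(idx, rep(Inf, l - length(idx)))
      d <- which(a != b)
      if (length(d) && b[d[1]] < a[d[1]]) best <- idx
    }
  }
  sort(ranked$snp_id[best])
}
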