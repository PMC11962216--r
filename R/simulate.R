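# Synthetic-data generator: LD-structured eQTL/GWAS summary statistics with
# known causal structure, and adverse-event report tables with a known
# drug-event reporting risk ratio. Everything the pipeline consumes can be
# generated here, so every stage is testable against ground truth.

#' Simulation configuration
#'
#' Default study conditions are desk-scale but realistic for the setting
#' the generator emulates: a cis region of 20 SNPs, an expression panel of
#' 30,000 (blood-eQTL scale) and an outcome GWAS of 50,000, a spontaneous
#' -report stream of 10,000 cases with a 2% baseline target-event
#' reporting rate and 10% target-drug share.
#'
#' @param n_snps number of SNPs in the cis region.
#' @param ld_rho AR(1) LD decay parameter in `[0, 1)`: `r[i,j] =
#'   ld_rho^|i-j|`.
#' @param maf_range range minor allele frequencies are drawn from.
#' @param n_exp,n_out exposure (eQTL) and outcome (GWAS) sample sizes.
#' @param n_causal_eqtl number of SNPs with a true (joint) eQTL effect.
#' @param pleiotropy_mode `"none"`, `"directional"` (all invalid SNPs share
#'   the same direct-effect sign) or `"balanced"` (alternating signs).
#' @param pleiotropy_prop proportion of SNPs given a direct outcome effect
#'   when `pleiotropy_mode != "none"`.
#' @param gene_start_bp,snp_spacing_bp region layout; the simulated gene
#'   body sits at the centre of the SNP grid.
#' @param n_reports number of adverse-event case reports.
#' @param target_drug_prevalence probability a report concerns the target
#'   drug.
#' @param baseline_event_rate probability a non-target-drug report lists
#'   the target event.
#' @param concomitant_fraction fraction of target-drug reports where the
#'   drug is concomitant rather than primary suspect.
#' @param duplicate_fraction fraction of cases resubmitted as a version-2
#'   report (to exercise deduplication).
#' @param year_range calendar years reports are drawn from.
#' @param seed global seed; per-component substreams are derived from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 20, ld_rho = 0, maf_range = c(0.1, 0.5),
                       n_exp = 30000, n_out = 50000,
                       n_causal_eqtl = n_snps,
                       pleiotropy_mode = c("none", "directional", "balanced"),
                       pleiotropy_prop = 1,
                       gene_start_bp = 10e6, snp_spacing_bp = 2000,
                       n_reports = 10000, target_drug_prevalence = 0.1,
                       baseline_event_rate = 0.02,
                       concomitant_fraction = 0.1,
                       duplicate_fraction = 0.05,
                       year_range = c(2004, 2023), seed = 1) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(n_snps >= 1, ld_rho >= 0, ld_rho < 1,
            n_causal_eqtl <= n_snps, n_causal_eqtl >= 0,
            baseline_event_rate > 0, baseline_event_rate < 1,
            target_drug_prevalence > 0, target_drug_prevalence < 1,
            pleiotropy_prop >= 0, pleiotropy_prop <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Ground-truth parameters for a simulation
#'
#' Holds everything the pipeline is supposed to recover: the causal effect
#' `theta` of expression on outcome (log-odds per expression SD), the
#' joint (causal) eQTL effects per SNP, any direct SNP-to-outcome
#' pleiotropic effects, and the drug-event reporting risk ratio.
#' Unspecified eQTL effects are drawn uniformly from
#' `eqtl_beta_range` at `n_causal_eqtl` SNPs chosen by the truth
#' substream of `cfg$seed`; pleiotropy is laid out per
#' `cfg$pleiotropy_mode`.
#'
#' @param cfg [sim_config()] object.
#' @param theta true causal effect of expression on the outcome.
#' @param eqtl_beta_range range of per-SNP causal eQTL effect sizes.
#' @param pleiotropy_effect absolute direct effect given to invalid SNPs.
#' @param rr_report true drug-event reporting risk ratio.
#' @param eqtl_effects optional explicit length-`n_snps` vector of joint
#'   eQTL effects (overrides the random draw).
#' @param pleiotropy optional explicit length-`n_snps` vector of direct
#'   outcome effects.
#' @return list of class `sim_truth`.
#' @export
sim_truth <- function(cfg, theta = 0, eqtl_beta_range = c(0.25, 0.45),
                      pleiotropy_effect = 0.02, rr_report = 1,
                      eqtl_effects = NULL, pleiotropy = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_snps
  if (is.null(eqtl_effects)) {
    eqtl_effects <- with_seed(derive_seed(cfg$seed, "truth"), {
      eff <- numeric(n)
      causal <- if (cfg$n_causal_eqtl > 0) {
        sort(sample.int(n, cfg$n_causal_eqtl))
      } else integer()
      eff[causal] <- stats::runif(length(causal), eqtl_beta_range[1],
                                  eqtl_beta_range[2])
      eff
    })
  }
  stopifnot(length(eqtl_effects) == n)
  if (is.null(pleiotropy)) {
    pleiotropy <- numeric(n)
    if (cfg$pleiotropy_mode != "none" && cfg$pleiotropy_prop > 0) {
      n_invalid <- max(1L, round(cfg$pleiotropy_prop * n))
      idx <- with_seed(derive_seed(cfg$seed, "pleiotropy"),
                       sort(sample.int(n, n_invalid)))
      signs <- if (cfg$pleiotropy_mode == "directional") {
        rep(1, n_invalid)
      } else {
        rep_len(c(1, -1), n_invalid)
      }
      pleiotropy[idx] <- signs * pleiotropy_effect
    }
  }
  stopifnot(length(pleiotropy) == n)
  names(eqtl_effects) <- names(pleiotropy) <- sprintf("rs%04d", seq_len(n))
  structure(list(theta = theta, eqtl_effects = eqtl_effects,
                 pleiotropy = pleiotropy, rr_report = rr_report,
                 seed = cfg$seed),
            class = "sim_truth")
}

#' AR(1) LD correlation matrix
#'
#' `r[i, j] = ld_rho^|i - j|`: a standard stand-in for the decaying
#' correlation along a chromosome, positive definite for `ld_rho < 1`.
#'
#' @param n_snps number of SNPs.
#' @param ld_rho decay parameter in `[0, 1)`.
#' @param snp_ids optional SNP ids used as dimnames.
#' @return correlation matrix with SNP-id dimnames.
#' @export
simulate_ld <- function(n_snps, ld_rho, snp_ids = sprintf("rs%04d", seq_len(n_snps))) {
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)")
  idx <- seq_len(n_snps)
  r <- ld_rho^abs(outer(idx, idx, "-"))
  dimnames(r) <- list(snp_ids, snp_ids)
  r
}

# Draw one trait's marginal summary statistics: z ~ MVN(marginal beta / se,
# LD), returned as beta-hat, se, p. `chol_ld` is the upper Cholesky factor.
draw_sumstats <- function(joint_beta, ld, chol_ld, se) {
  mu <- drop(ld %*% joint_beta) / se
  z <- mu + drop(crossprod(chol_ld, stats::rnorm(length(se))))
  list(beta = z * se, se = se, pval = p_two_sided(z))
}

non_palindromic_pairs <- matrix(c(
  "A", "C", "A", "G", "C", "A", "C", "T",
  "G", "A", "G", "T", "T", "C", "T", "G"
), ncol = 2, byrow = TRUE)

#' Simulate exposure and outcome summary statistics over a cis region
#'
#' Works directly at the z-score level of the two-sample summary-data
#' setting: per-SNP marginal effects are the LD matrix times the true
#' joint effects; estimated z-scores are drawn jointly with covariance
#' equal to the LD matrix (independently for the exposure and outcome
#' samples); standard errors follow `1/sqrt(2 maf (1-maf) n)`. The true
#' joint outcome effects are `theta * eqtl_effects + pleiotropy`.
#'
#' @param cfg [sim_config()] object.
#' @param truth [sim_truth()] object.
#' @return list of class `sim_study`: `exposure` and `outcome`
#'   summary-statistics data.frames, `ld` matrix, `gene` ([gene_info()]),
#'   `truth`.
#' @export
simulate_summary_stats <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  n <- cfg$n_snps
  ids <- sprintf("rs%04d", seq_len(n))
  ld <- simulate_ld(n, cfg$ld_rho, ids)
  chol_ld <- chol(ld)
  out <- with_seed(derive_seed(cfg$seed, "sumstats"), {
    maf <- stats::runif(n, cfg$maf_range[1], cfg$maf_range[2])
    pair_idx <- sample.int(nrow(non_palindromic_pairs), n, replace = TRUE)
    ea <- non_palindromic_pairs[pair_idx, 1]
    oa <- non_palindromic_pairs[pair_idx, 2]
    se_exp <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_exp)
    se_out <- 1 / sqrt(2 * maf * (1 - maf) * cfg$n_out)
    exp_draw <- draw_sumstats(unname(truth$eqtl_effects), ld, chol_ld, se_exp)
    joint_out <- truth$theta * unname(truth$eqtl_effects) +
      unname(truth$pleiotropy)
    out_draw <- draw_sumstats(joint_out, ld, chol_ld, se_out)
    list(maf = maf, ea = ea, oa = oa, exp_draw = exp_draw,
         out_draw = out_draw)
  })
  pos <- as.integer(cfg$gene_start_bp - (n %/% 2) * cfg$snp_spacing_bp +
                      (seq_len(n) - 1L) * cfg$snp_spacing_bp)
  make_df <- function(d, n_sample) {
    df <- data.frame(
      snp_id = ids, chrom = "1", pos_bp = pos,
      effect_allele = out$ea, other_allele = out$oa,
      eaf = out$maf, beta = unname(d$beta), se = unname(d$se),
      pval = unname(d$pval), n = n_sample, stringsAsFactors = FALSE
    )
    rownames(df) <- NULL
    df
  }
  gene <- gene_info("GENE1", "1", as.integer(cfg$gene_start_bp),
                    as.integer(cfg$gene_start_bp + 5e4))
  structure(list(
    exposure = make_df(out$exp_draw, cfg$n_exp),
    outcome = make_df(out$out_draw, cfg$n_out),
    ld = ld, gene = gene, truth = truth
  ), class = "sim_study")
}

#' Simulate spontaneous adverse-event case reports
#'
#' Draws `n_reports` cases: target-drug exposure with configured
#' prevalence, target-event occurrence at the baseline reporting rate for
#' other drugs and `baseline * rr_report` for the target drug, plus
#' demographics from realistic categorical mixes (large missing fractions,
#' as in spontaneous-report data). A `duplicate_fraction` of cases is
#' emitted twice (versions 1 and 2) to exercise deduplication; the number
#' of injected duplicates is recorded in the `n_duplicates` attribute.
#'
#' @param cfg [sim_config()] object.
#' @param truth [sim_truth()] object (uses `rr_report`).
#' @return case-report data.frame (see [case_reports()]) with attributes
#'   `n_duplicates` and `target_drug`/`target_pt` labels.
#' @export
simulate_reports <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  n <- cfg$n_reports
  target_drug <- "haloperidol"
  target_pt <- "Seizure"
  df <- with_seed(derive_seed(cfg$seed, "reports"), {
    exposed <- stats::runif(n) < cfg$target_drug_prevalence
    p_event <- ifelse(exposed, pmin(cfg$baseline_event_rate * truth$rr_report,
                                    0.99),
                      cfg$baseline_event_rate)
    event <- stats::runif(n) < p_event
    other_drugs <- paste0("drug_", LETTERS[1:8])
    other_pts <- paste0("pt_", sprintf("%02d", 1:12))
    role <- ifelse(stats::runif(n) < cfg$concomitant_fraction,
                   "concomitant", "suspect")
    sex <- sample(c("F", "M", NA), n, replace = TRUE,
                  prob = c(0.45, 0.42, 0.13))
    age <- ifelse(stats::runif(n) < 0.48, NA_real_,
                  pmax(1, stats::rnorm(n, 45, 20)))
    weight <- ifelse(stats::runif(n) < 0.79, NA_real_,
                     pmax(10, stats::rnorm(n, 75, 20)))
    reporter <- sample(c("CN", "HP", "LW", "MD", "OT", "PH", "RN", NA), n,
                       replace = TRUE,
                       prob = c(0.34, 0.06, 0.02, 0.28, 0.14, 0.09, 0.005,
                                0.065))
    country <- sample(c("US", "JP", "FR", "DE", "UK", NA), n, replace = TRUE,
                      prob = c(0.37, 0.03, 0.01, 0.01, 0.02, 0.56))
    data.frame(
      case_id = sprintf("C%07d", seq_len(n)),
      version = 1L,
      drug = ifelse(exposed, target_drug,
                    sample(other_drugs, n, replace = TRUE)),
      role = role,
      pt = ifelse(event, target_pt, sample(other_pts, n, replace = TRUE)),
      sex = sex, age_years = age, weight_kg = weight,
      reporter = reporter, country = country,
      year = sample(seq(cfg$year_range[1], cfg$year_range[2]), n,
                    replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
  n_dup <- floor(cfg$duplicate_fraction * n)
  if (n_dup > 0) {
    dup_idx <- with_seed(derive_seed(cfg$seed, "duplicates"),
                         sample.int(n, n_dup))
    dup <- df[dup_idx, , drop = FALSE]
    dup$version <- 2L
    df <- rbind(df, dup)
    rownames(df) <- NULL
  }
  df <- case_reports(df)
  attr(df, "n_duplicates") <- n_dup
  attr(df, "target_drug") <- target_drug
  attr(df, "target_pt") <- target_pt
  df
}
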