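# Orchestration: per gene-outcome instrument selection -> MR (+sensitivity)
# -> SMR/HEIDI -> colocalization, meta-analysis across outcome sources, and
# the clumping-threshold consistency sweep.

#' Run the full analysis for one gene against one outcome
#'
#' Stages: instrument selection ([select_instruments()]); the primary MR
#' estimate (Wald ratio for a single instrument, fixed-effect IVW
#' otherwise) with MR-Egger / weighted-median / weighted-mode assists and
#' the sensitivity suite where the instrument count permits; then, when
#' the primary p-value passes the follow-up gate (default p < 0.05), SMR
#' with HEIDI and colocalization over the un-clumped cis region.
#'
#' @param exposure,outcome summary-statistics data.frames.
#' @param ld square LD correlation matrix with SNP-id dimnames.
#' @param gene [gene_info()] object.
#' @param cfg [threshold_config()] object.
#' @param gate_p primary-MR p-value below which follow-up analyses run.
#' @param followup `"significant"` (gate on `gate_p`), `"all"` (always run
#'   SMR/coloc) or `"none"`.
#' @param n_boot bootstrap replicates for the median/mode assists.
#' @param seed RNG seed for the bootstrap estimators.
#' @param outcome_id label carried into results.
#' @return list of class `gene_outcome_result` with `status`
#'   (`"ok"`, `"no_instruments"`), `instruments`, `estimates` (named list
#'   of `mr_estimate`), `primary_method`, `sensitivity`, `smr`, `coloc`,
#'   `followup_status` (`"done"`, `"not_significant"`, `"skipped"`).
#' @export
run_gene_outcome <- function(exposure, outcome, ld, gene,
                             cfg = threshold_config(), gate_p = 0.05,
                             followup = c("significant", "all", "none"),
                             n_boot = 1000, seed = 1,
                             outcome_id = "outcome") {
  followup <- match.arg(followup)
  inst <- select_instruments(exposure, outcome, ld, gene, cfg)
  base <- list(gene_id = gene$gene_id, outcome_id = outcome_id,
               instruments = inst, estimates = list(),
               primary_method = NA_character_, sensitivity = NULL,
               smr = NULL, coloc = NULL, followup_status = "skipped")
  n <- nrow(inst$pairs)
  if (n == 0L) {
    base$status <- "no_instruments"
    return(structure(base, class = "gene_outcome_result"))
  }
  base$status <- "ok"
  ests <- list()
  if (n == 1L) {
    ests$wald_ratio <- wald_ratio(inst$pairs)
    base$primary_method <- "wald_ratio"
  } else {
    ests$ivw <- ivw(inst$pairs)
    base$primary_method <- "ivw"
    base$sensitivity <- sensitivity(inst$pairs, ests$ivw)
    if (n >= 3L) {
      ests$egger <- mr_egger(inst$pairs)$slope
      ests$weighted_median <- weighted_median(inst$pairs, n_boot = n_boot,
                                              seed = derive_seed(seed, "wm"))
      ests$weighted_mode <- weighted_mode(inst$pairs, n_boot = n_boot,
                                          seed = derive_seed(seed, "wmode"))
    }
  }
  base$estimates <- ests
  primary <- ests[[base$primary_method]]

  run_follow <- switch(followup,
                       all = TRUE,
                       none = FALSE,
                       significant = primary$pval < gate_p)
  if (!run_follow) {
    base$followup_status <- if (followup == "none") "skipped" else "not_significant"
    return(structure(base, class = "gene_outcome_result"))
  }
  # SMR/HEIDI and coloc use the whole cis region (no p-threshold, no
  # clumping): build region pairs from cis-window + MAF filtering only.
  region_cfg <- cfg
  region_cfg$p_instrument <- 1
  region <- select_cis_snps(exposure, gene, region_cfg)
  region_pairs <- harmonize(region, outcome)
  base$smr <- tryCatch(
    smr_heidi(region_pairs, ld, gene_id = gene$gene_id,
              outcome_id = outcome_id),
    warning = function(w) {
      suppressWarnings(smr_heidi(region_pairs, ld, gene_id = gene$gene_id,
                                 outcome_id = outcome_id))
    }
  )
  keep <- region$snp_id %in% region_pairs$snp_id
  base$coloc <- coloc_abf(region[keep, , drop = FALSE],
                          outcome[outcome$snp_id %in% region_pairs$snp_id, ,
                                  drop = FALSE],
                          gene_id = gene$gene_id, outcome_id = outcome_id)
  base$followup_status <- "done"
  structure(base, class = "gene_outcome_result")
}

#' @export
print.gene_outcome_result <- function(x, ...) {
  cat(sprintf("%s -> %s [%s]\n", x$gene_id, x$outcome_id, x$status))
  for (e in x$estimates) print(e)
  if (!is.null(x$smr)) print(x$smr)
  if (!is.null(x$coloc)) print(x$coloc)
  invisible(x)
}

#' Meta-analyse one gene's primary estimates across outcome sources
#'
#' @param results list of `gene_outcome_result` objects for the same gene
#'   (e.g. the same outcome from two GWAS sources).
#' @param model `"fixed"` or `"random"`.
#' @return `meta_result`, or `NULL` when fewer than two results carry a
#'   primary estimate.
#' @export
meta_across_sources <- function(results, model = c("fixed", "random")) {
  model <- match.arg(model)
  ok <- Filter(function(r) r$status == "ok", results)
  if (length(ok) < 2L) return(NULL)
  inp <- meta_input(
    label = vapply(ok, function(r) r$outcome_id, character(1)),
    beta = vapply(ok, function(r) r$estimates[[r$primary_method]]$beta,
                  numeric(1)),
    se = vapply(ok, function(r) r$estimates[[r$primary_method]]$se,
                numeric(1))
  )
  if (model == "fixed") meta_fixed(inp) else meta_random(inp)
}

#' Flatten gene-outcome results into a wide results table
#'
#' One row per result with the per-method estimates, sensitivity
#' statistics, SMR/HEIDI p-values and colocalization posteriors: the shape
#' of a per-gene summary table in a drug-target MR study.
#'
#' @param results list of `gene_outcome_result` objects.
#' @return data.frame, one row per (gene, outcome) with an explicit
#'   `status` column.
#' @export
results_table <- function(results) {
  if (inherits(results, "gene_outcome_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    row <- data.frame(
      gene_id = r$gene_id, outcome_id = r$outcome_id, status = r$status,
      primary_method = r$primary_method,
      nsnp = if (r$status == "ok") r$estimates[[r$primary_method]]$nsnp else 0L,
      beta = NA_real_, se = NA_real_, pval = NA_real_,
      or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      q_pval = NA_real_, egger_intercept_pval = NA_real_,
      b_smr = NA_real_, p_smr = NA_real_, p_heidi = NA_real_,
      pp_h4 = NA_real_, coloc_verdict = NA_character_,
      followup_status = r$followup_status,
      stringsAsFactors = FALSE
    )
    if (r$status == "ok") {
      p <- r$estimates[[r$primary_method]]
      row$beta <- p$beta; row$se <- p$se; row$pval <- p$pval
      row$or <- p$or_; row$ci_low <- p$ci_low; row$ci_high <- p$ci_high
    }
    if (!is.null(r$sensitivity)) {
      row$q_pval <- r$sensitivity$q_pval
      row$egger_intercept_pval <- r$sensitivity$egger_intercept_pval
    }
    if (!is.null(r$smr)) {
      row$b_smr <- r$smr$b_smr; row$p_smr <- r$smr$p_smr
      row$p_heidi <- r$smr$p_heidi
    }
    if (!is.null(r$coloc)) {
      row$pp_h4 <- unname(r$coloc$pp["pp_h4"])
      row$coloc_verdict <- r$coloc$verdict
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write pipeline outputs to a directory
#'
#' Emits `results.tsv` (the [results_table()]), `dropped_snps.tsv` (the
#' per-SNP filter ledger) and, when available, `sensitivity.tsv`
#' (leave-one-out rows per gene-outcome).
#'
#' @param results list of `gene_outcome_result` objects.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(results, out_dir) {
  if (inherits(results, "gene_outcome_result")) results <- list(results)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(results_table(results),
                     file.path(out_dir, "results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dropped <- do.call(rbind, lapply(results, function(r) {
    d <- r$instruments$dropped
    if (!nrow(d)) return(NULL)
    cbind(gene_id = r$gene_id, outcome_id = r$outcome_id, d,
          stringsAsFactors = FALSE)
  }))
  if (is.null(dropped)) {
    dropped <- data.frame(gene_id = character(), outcome_id = character(),
                          snp_id = character(), reason = character(),
                          stage = character())
  }
  utils::write.table(dropped, file.path(out_dir, "dropped_snps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  loo <- do.call(rbind, lapply(results, function(r) {
    if (is.null(r$sensitivity)) return(NULL)
    cbind(gene_id = r$gene_id, outcome_id = r$outcome_id,
          q = r$sensitivity$q, q_pval = r$sensitivity$q_pval,
          egger_intercept = r$sensitivity$egger_intercept,
          egger_intercept_pval = r$sensitivity$egger_intercept_pval,
          r$sensitivity$loo, stringsAsFactors = FALSE)
  }))
  if (!is.null(loo)) {
    utils::write.table(loo, file.path(out_dir, "sensitivity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}

#' Consistency of the primary estimate across clumping thresholds
#'
#' Repeats instrument selection and the primary MR fit at each LD r-squared
#' threshold in `r2_grid` and reports the estimates side by side, with the
#' sign-agreement fraction and maximum absolute difference in beta as
#' attributes. Looser thresholds keep more correlated instruments;
#' agreement across the grid indicates the finding is not an artifact of
#' the clumping choice.
#'
#' @param exposure,outcome summary-statistics data.frames.
#' @param ld square LD correlation matrix.
#' @param gene [gene_info()] object.
#' @param cfg [threshold_config()] object (its `clump_r2` is overridden).
#' @param r2_grid thresholds to sweep.
#' @return data.frame with one row per threshold (`clump_r2`, `status`,
#'   `method`, `nsnp`, `beta`, `se`, `pval`), attributes `sign_agreement`
#'   and `max_delta_beta`.
#' @export
consistency_sweep <- function(exposure, outcome, ld, gene,
                              cfg = threshold_config(),
                              r2_grid = c(0.3, 0.2, 0.05, 0.01)) {
  rows <- lapply(r2_grid, function(r2) {
    cfg_i <- cfg
    cfg_i$clump_r2 <- r2
    inst <- select_instruments(exposure, outcome, ld, gene, cfg_i)
    n <- nrow(inst$pairs)
    if (n == 0L) {
      return(data.frame(clump_r2 = r2, status = "no_instruments",
                        method = NA_character_, nsnp = 0L, beta = NA_real_,
                        se = NA_real_, pval = NA_real_,
                        stringsAsFactors = FALSE))
    }
    est <- if (n == 1L) wald_ratio(inst$pairs) else ivw(inst$pairs)
    data.frame(clump_r2 = r2, status = "ok", method = est$method,
               nsnp = est$nsnp, beta = est$beta, se = est$se,
               pval = est$pval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  betas <- out$beta[!is.na(out$beta)]
  attr(out, "sign_agreement") <- if (length(betas)) {
    max(mean(sign(betas) == 1), mean(sign(betas) == -1))
  } else NA_real_
  attr(out, "max_delta_beta") <- if (length(betas) > 1) {
    max(betas) - min(betas)
  } else 0
  out
}
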