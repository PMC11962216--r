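# Genetic arm, stage 1: cis-eQTL instrument selection and harmonization of
# exposure (expression) and outcome (disease) summary statistics.

assoc_columns <- c("snp_id", "chrom", "pos_bp", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n")

#' Validate a table of per-SNP summary associations
#'
#' One row per SNP: identifier, position, effect/other allele, effect-allele
#' frequency, per-allele effect estimate with standard error, p-value and
#' sample size. This is the common exchange format for both eQTL (exposure)
#' and GWAS (outcome) summary statistics.
#'
#' @param df data.frame with columns `snp_id`, `chrom`, `pos_bp`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @return validated data.frame.
#' @export
assoc_records <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(assoc_columns, names(df))
  if (length(missing_cols)) {
    stop("summary-statistics table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[assoc_columns]
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$pos_bp <- as.integer(df$pos_bp)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  num <- c("eaf", "beta", "se", "pval")
  for (col in num) df[[col]] <- as.numeric(df[[col]])
  df$n <- as.numeric(df$n)
  bad_allele <- !(df$effect_allele %in% c("A", "C", "G", "T")) |
    !(df$other_allele %in% c("A", "C", "G", "T"))
  if (any(bad_allele)) stop("alleles must be single bases A/C/G/T")
  if (any(df$effect_allele == df$other_allele)) {
    stop("effect and other allele must differ")
  }
  if (any(!is.na(df$se) & df$se <= 0)) stop("standard errors must be positive")
  if (any(!is.na(df$pval) & (df$pval <= 0 | df$pval > 1))) {
    stop("p-values must lie in (0, 1]")
  }
  rownames(df) <- NULL
  df
}

#' Gene coordinates for cis-window selection
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome label.
#' @param start_bp,end_bp 1-based inclusive gene body coordinates.
#' @return list of class `gene_info`.
#' @export
gene_info <- function(gene_id, chrom, start_bp, end_bp) {
  if (start_bp > end_bp) stop("start_bp must be <= end_bp")
  structure(list(gene_id = gene_id, chrom = as.character(chrom),
                 start_bp = as.integer(start_bp), end_bp = as.integer(end_bp)),
            class = "gene_info")
}

#' Instrument-selection thresholds
#'
#' Defaults reflect common drug-target MR practice: a 1 Mb cis window on
#' either side of the gene body, minor allele frequency above 1%, eQTL
#' p-value below 1e-5, greedy LD clumping at r-squared 0.3 within 10 Mb,
#' and instrument F-statistic above 10.
#'
#' @param cis_window_bp cis window in base pairs on either side of the gene.
#' @param maf_min minimum minor allele frequency (exclusive).
#' @param p_instrument maximum exposure p-value (exclusive).
#' @param clump_r2 LD r-squared threshold (exclusive) for clumping.
#' @param clump_window_kb clumping window in kilobases.
#' @param f_min minimum instrument F-statistic (exclusive).
#' @return list of class `threshold_config`.
#' @export
threshold_config <- function(cis_window_bp = 1e6, maf_min = 0.01,
                             p_instrument = 1e-5, clump_r2 = 0.3,
                             clump_window_kb = 10000, f_min = 10) {
  stopifnot(cis_window_bp > 0, maf_min > 0, p_instrument > 0,
            clump_r2 > 0, clump_r2 < 1, clump_window_kb > 0, f_min > 0)
  structure(list(cis_window_bp = cis_window_bp, maf_min = maf_min,
                 p_instrument = p_instrument, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb, f_min = f_min),
            class = "threshold_config")
}

dropped_frame <- function(snp_id = character(), reason = character()) {
  data.frame(snp_id = as.character(snp_id), reason = as.character(reason),
             stringsAsFactors = FALSE)
}

#' Select cis-window SNPs passing MAF and p-value thresholds
#'
#' Keeps records within `cis_window_bp` of the gene body (inclusive at both
#' boundaries), with minor allele frequency strictly above `maf_min` and
#' exposure p-value strictly below `p_instrument`. Records with missing EAF
#' pass the MAF filter (frequency unknown, not evidently rare). Dropped
#' SNPs are recorded with a reason in the `"dropped"` attribute.
#'
#' @param assoc summary-statistics data.frame (see [assoc_records()]).
#' @param gene [gene_info()] object.
#' @param cfg [threshold_config()] object.
#' @return kept records, with attribute `dropped` (`snp_id`, `reason`).
#' @export
select_cis_snps <- function(assoc, gene, cfg = threshold_config()) {
  assoc <- assoc_records(assoc)
  stopifnot(inherits(gene, "gene_info"))
  on_chrom <- assoc$chrom == gene$chrom
  lo <- gene$start_bp - cfg$cis_window_bp
  hi <- gene$end_bp + cfg$cis_window_bp
  in_cis <- on_chrom & assoc$pos_bp >= lo & assoc$pos_bp <= hi
  maf <- pmin(assoc$eaf, 1 - assoc$eaf)
  maf_ok <- is.na(maf) | maf > cfg$maf_min
  p_ok <- !is.na(assoc$pval) & assoc$pval < cfg$p_instrument
  reason <- ifelse(!in_cis, "cis_window",
                   ifelse(!maf_ok, "maf",
                          ifelse(!p_ok, "pval", NA_character_)))
  kept <- assoc[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "dropped") <- dropped_frame(assoc$snp_id[!is.na(reason)],
                                         reason[!is.na(reason)])
  kept
}

ld_r2_lookup <- function(ld, ids) {
  miss <- setdiff(ids, rownames(ld))
  if (length(miss)) stop("SNP absent from LD matrix: ", miss[1])
  ld[ids, ids, drop = FALSE]^2
}

#' Greedy LD clumping
#'
#' Sorts candidates by ascending p-value (ties: smaller position, then
#' lexicographic SNP id) and accepts each SNP only if its squared
#' correlation with every already-accepted SNP within `clump_window_kb` is
#' strictly below `clump_r2`. The result is therefore independent of input
#' order.
#'
#' @param records candidate summary-statistics data.frame.
#' @param ld square correlation matrix with SNP ids as dimnames.
#' @param cfg [threshold_config()] object.
#' @return accepted records in acceptance (p-value) order, with attribute
#'   `dropped`.
#' @export
ld_clump <- function(records, ld, cfg = threshold_config()) {
  records <- assoc_records(records)
  if (!nrow(records)) {
    attr(records, "dropped") <- dropped_frame()
    return(records)
  }
  miss <- setdiff(records$snp_id, rownames(ld))
  if (length(miss)) stop("SNP absent from LD matrix: ", miss[1])
  o <- order(records$pval, records$pos_bp, records$snp_id)
  records <- records[o, , drop = FALSE]
  r2 <- ld_r2_lookup(ld, records$snp_id)
  window_bp <- cfg$clump_window_kb * 1000
  accepted <- integer()
  dropped <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    ok <- TRUE
    for (j in accepted) {
      near <- abs(records$pos_bp[i] - records$pos_bp[j]) <= window_bp
      if (near && r2[i, j] >= cfg$clump_r2) {
        ok <- FALSE
        break
      }
    }
    if (ok) accepted <- c(accepted, i) else dropped[i] <- TRUE
  }
  out <- records[accepted, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped_frame(records$snp_id[dropped],
                                        rep("ld_clump", sum(dropped)))
  out
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome effects to the exposure effect allele
#'
#' Matches records by SNP id. Pairs whose outcome alleles are swapped
#' relative to the exposure have the outcome effect negated (`flipped`).
#' Palindromic SNPs (A/T, C/G) are always dropped because their strand
#' cannot be resolved from summary data; allele-set mismatches and records
#' with missing effect or standard error are dropped as well, each with a
#' recorded reason.
#'
#' @param exposure,outcome summary-statistics data.frames keyed by `snp_id`.
#' @return data.frame of harmonized pairs (`snp_id`, `beta_exp`, `se_exp`,
#'   `pval_exp`, `n_exp`, `eaf`, `beta_out`, `se_out`, `pval_out`, `n_out`,
#'   `flipped`), with attribute `dropped`.
#' @export
harmonize <- function(exposure, outcome) {
  exposure <- assoc_records(exposure)
  outcome <- assoc_records(outcome)
  if (anyDuplicated(exposure$snp_id)) {
    stop("duplicate snp_id in exposure: ",
         exposure$snp_id[duplicated(exposure$snp_id)][1])
  }
  if (anyDuplicated(outcome$snp_id)) {
    stop("duplicate snp_id in outcome: ",
         outcome$snp_id[duplicated(outcome$snp_id)][1])
  }
  idx <- match(exposure$snp_id, outcome$snp_id)
  n <- nrow(exposure)
  reason <- rep(NA_character_, n)
  beta_out <- se_out <- pval_out <- n_out <- rep(NA_real_, n)
  flipped <- rep(FALSE, n)
  for (i in seq_len(n)) {
    j <- idx[i]
    if (is.na(j)) {
      reason[i] <- "missing"
      next
    }
    ea_x <- exposure$effect_allele[i]; oa_x <- exposure$other_allele[i]
    ea_y <- outcome$effect_allele[j]; oa_y <- outcome$other_allele[j]
    if (is_palindromic(ea_x, oa_x)) {
      reason[i] <- "palindrome"
      next
    }
    same <- ea_x == ea_y && oa_x == oa_y
    swap <- ea_x == oa_y && oa_x == ea_y
    if (!same && !swap) {
      reason[i] <- "allele_mismatch"
      next
    }
    if (is.na(exposure$beta[i]) || is.na(exposure$se[i]) ||
        is.na(outcome$beta[j]) || is.na(outcome$se[j])) {
      reason[i] <- "missing"
      next
    }
    beta_out[i] <- if (swap) -outcome$beta[j] else outcome$beta[j]
    se_out[i] <- outcome$se[j]
    pval_out[i] <- outcome$pval[j]
    n_out[i] <- outcome$n[j]
    flipped[i] <- swap
  }
  keep <- is.na(reason)
  pairs <- data.frame(
    snp_id = exposure$snp_id[keep],
    beta_exp = exposure$beta[keep], se_exp = exposure$se[keep],
    pval_exp = exposure$pval[keep], n_exp = exposure$n[keep],
    eaf = exposure$eaf[keep],
    beta_out = beta_out[keep], se_out = se_out[keep],
    pval_out = pval_out[keep], n_out = n_out[keep],
    flipped = flipped[keep],
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(pairs, "dropped") <- dropped_frame(exposure$snp_id[!keep], reason[!keep])
  pairs
}

# Variance in a trait explained by one SNP from summary data:
# 2p(1-p)b^2 / (2p(1-p)b^2 + 2p(1-p) se^2 n), which reduces to
# b^2 / (b^2 + se^2 n). Falls back to F/(F + n - 2) when EAF is missing
# and NA when the sample size is missing too.
r2_explained <- function(beta, se, n, eaf) {
  if (!is.na(eaf)) {
    v <- 2 * eaf * (1 - eaf)
    return((v * beta^2) / (v * beta^2 + se^2 * n * v))
  }
  if (!is.na(n)) {
    f <- beta^2 / se^2
    return(f / (f + n - 2))
  }
  NA_real_
}

#' Steiger directionality filter
#'
#' Keeps instruments that explain strictly more variance in the exposure
#' than in the outcome, guarding against reverse causation. When the
#' variance explained cannot be computed on either side (sample size
#' missing) the pair is kept with a warning rather than silently dropped.
#'
#' @param pairs harmonized-pairs data.frame from [harmonize()].
#' @return retained pairs with attribute `dropped` (reason `steiger`).
#' @export
steiger_filter <- function(pairs) {
  n <- nrow(pairs)
  keep <- logical(n)
  warned <- FALSE
  for (i in seq_len(n)) {
    r2x <- r2_explained(pairs$beta_exp[i], pairs$se_exp[i],
                        pairs$n_exp[i], pairs$eaf[i])
    r2y <- r2_explained(pairs$beta_out[i], pairs$se_out[i],
                        pairs$n_out[i], pairs$eaf[i])
    if (is.na(r2x) || is.na(r2y)) {
      keep[i] <- TRUE
      warned <- TRUE
    } else {
      keep[i] <- r2x > r2y
    }
  }
  if (warned) {
    warning("sample size missing for some pairs; Steiger direction not ",
            "evaluable, pairs retained")
  }
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped_frame(pairs$snp_id[!keep],
                                        rep("steiger", sum(!keep)))
  out
}

#' Weak-instrument filter on the F-statistic
#'
#' Retains pairs with `F = beta_exp^2 / se_exp^2` strictly above `f_min`;
#' instruments at or below the threshold are considered weak and excluded.
#'
#' @param pairs harmonized-pairs data.frame.
#' @param cfg [threshold_config()] object (uses `f_min`).
#' @return retained pairs with attribute `dropped` (reason `weak_f`).
#' @export
f_filter <- function(pairs, cfg = threshold_config()) {
  f <- pairs$beta_exp^2 / pairs$se_exp^2
  keep <- f > cfg$f_min
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped_frame(pairs$snp_id[!keep],
                                        rep("weak_f", sum(!keep)))
  out
}

#' Full instrument-selection pipeline for one gene
#'
#' Applies, in order: cis-window/MAF/p-value selection, greedy LD clumping,
#' allele harmonization against the outcome, the Steiger directionality
#' filter and the F-statistic filter. Every exposure SNP appears exactly
#' once: either in the surviving pairs or in the dropped ledger with the
#' stage and reason it was removed.
#'
#' @param exposure,outcome summary-statistics data.frames.
#' @param ld square correlation matrix with SNP-id dimnames.
#' @param gene [gene_info()] object.
#' @param cfg [threshold_config()] object.
#' @return list of class `instrument_set`: `gene_id`, `pairs`, `dropped`
#'   (`snp_id`, `stage`, `reason`).
#' @export
select_instruments <- function(exposure, outcome, ld, gene,
                               cfg = threshold_config()) {
  exposure <- assoc_records(exposure)
  dropped <- list()
  note <- function(d, stage) {
    if (nrow(d)) cbind(d, stage = stage, stringsAsFactors = FALSE) else NULL
  }
  cis <- select_cis_snps(exposure, gene, cfg)
  dropped$cis <- note(attr(cis, "dropped"), "select_cis")
  clumped <- ld_clump(cis, ld, cfg)
  dropped$clump <- note(attr(clumped, "dropped"), "ld_clump")
  pairs <- harmonize(clumped, outcome)
  dropped$harm <- note(attr(pairs, "dropped"), "harmonize")
  pairs <- steiger_filter(pairs)
  dropped$steiger <- note(attr(pairs, "dropped"), "steiger")
  pairs <- f_filter(pairs, cfg)
  dropped$f <- note(attr(pairs, "dropped"), "f_filter")
  ledger <- do.call(rbind, dropped[!vapply(dropped, is.null, logical(1))])
  if (is.null(ledger)) {
    ledger <- cbind(dropped_frame(), stage = character())
  }
  rownames(ledger) <- NULL
  attr(pairs, "dropped") <- NULL
  structure(list(gene_id = gene$gene_id, pairs = pairs, dropped = ledger),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("instrument_set for %s: %d instruments, %d dropped\n",
              x$gene_id, nrow(x$pairs), nrow(x$dropped)))
  if (nrow(x$dropped)) print(table(x$dropped$reason))
  invisible(x)
}
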