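# Instrument selection: cis/MAF/p filters, LD clumping, harmonization,
# Steiger direction and F-statistic filters, and pipeline accounting.

test_that("cis window is inclusive and MAF/p thresholds are strict", {
  gene <- gene_info("G", "1", 5e6, 5.05e6)
  cfg <- threshold_config()
  a <- make_assoc(
    snp_id = c("s_edge_lo", "s_out_lo", "s_edge_hi", "s_rare", "s_pboundary",
               "s_ok"),
    pos_bp = c(5e6 - 1e6, 5e6 - 1e6 - 1, 5.05e6 + 1e6, 5e6, 5e6, 5e6),
    beta = 0.3, se = 0.03,
    pval = c(1e-8, 1e-8, 1e-8, 1e-8, 1e-5, 1e-8)
  )
  a$eaf[4] <- 0.995  # MAF 0.005 < 0.01
  kept <- select_cis_snps(a, gene, cfg)
  dropped <- attr(kept, "dropped")
  expect_setequal(kept$snp_id, c("s_edge_lo", "s_edge_hi", "s_ok"))
  expect_equal(dropped$reason[dropped$snp_id == "s_out_lo"], "cis_window")
  expect_equal(dropped$reason[dropped$snp_id == "s_rare"], "maf")
  # p exactly at the threshold is excluded (strict <)
  expect_equal(dropped$reason[dropped$snp_id == "s_pboundary"], "pval")
})

test_that("greedy clumping drops correlated SNPs and keeps boundary r2", {
  a <- make_assoc(c("snp1", "snp2", "snp3"), pos_bp = c(100, 2100, 4100),
                  beta = c(0.5, 0.4, 0.3), se = 0.05,
                  pval = c(1e-8, 1e-6, 1e-4))
  ld <- diag(3)
  dimnames(ld) <- list(a$snp_id, a$snp_id)
  ld["snp1", "snp2"] <- ld["snp2", "snp1"] <- 0.7  # r2 = 0.49 >= 0.3
  kept <- ld_clump(a, ld, threshold_config())
  expect_setequal(kept$snp_id, c("snp1", "snp3"))
  expect_equal(attr(kept, "dropped")$snp_id, "snp2")

  # independent SNPs all survive
  kept2 <- ld_clump(a, diag(3) |> `dimnames<-`(list(a$snp_id, a$snp_id)),
                    threshold_config())
  expect_equal(nrow(kept2), 3)

  # r2 just under the threshold keeps both
  ld3 <- ld
  ld3["snp1", "snp2"] <- ld3["snp2", "snp1"] <- sqrt(0.29)
  expect_equal(nrow(ld_clump(a, ld3, threshold_config())), 3)
  # r2 exactly at the threshold is pruned (strict <): r = 0.5 against a
  # threshold of r2 = 0.25 is representable exactly
  ld4 <- ld
  ld4["snp1", "snp2"] <- ld4["snp2", "snp1"] <- 0.5
  expect_setequal(ld_clump(a, ld4, threshold_config(clump_r2 = 0.25))$snp_id,
                  c("snp1", "snp3"))
  expect_error(ld_clump(a, diag(2) |> `dimnames<-`(list(a$snp_id[1:2],
                                                        a$snp_id[1:2])),
                        threshold_config()), "snp3")
})

test_that("clumping ignores LD beyond the window and is order-independent", {
  a <- make_assoc(c("far1", "far2"), pos_bp = c(1, 2e7),
                  beta = c(0.5, 0.4), se = 0.05, pval = c(1e-8, 1e-6))
  ld <- matrix(c(1, 0.95, 0.95, 1), 2,
               dimnames = list(a$snp_id, a$snp_id))
  # 20 Mb apart: outside the 10 Mb window, both kept despite r2 = 0.9
  expect_equal(nrow(ld_clump(a, ld, threshold_config())), 2)

  set.seed(21)
  cfg <- sim_config(n_snps = 12, ld_rho = 0.85, seed = 77)
  st <- simulate_summary_stats(cfg, sim_truth(cfg, theta = 0.2))
  perm <- st$exposure[sample.int(12), ]
  k1 <- ld_clump(st$exposure, st$ld, threshold_config())
  k2 <- ld_clump(perm, st$ld, threshold_config())
  expect_equal(k1$snp_id, k2$snp_id)
})

test_that("greedy clumping equals exhaustive search on small regions", {
  cfg_t <- threshold_config()
  for (seed in 1:12) {
    set.seed(seed)
    n <- sample(4:9, 1)
    rho <- runif(1, 0.3, 0.95)
    ld <- simulate_ld(n, rho, sprintf("s%02d", 1:n))
    a <- make_assoc(sprintf("s%02d", 1:n),
                    pos_bp = seq(1000, by = 2000, length.out = n),
                    beta = runif(n, 0.1, 0.5), se = 0.05,
                    pval = runif(n, 1e-10, 1e-4))
    greedy <- sort(ld_clump(a, ld, cfg_t)$snp_id)
    expect_equal(greedy, oracle_clump(a, ld, cfg_t),
                 info = paste("seed", seed))
  }
})

test_that("harmonization aligns, flips, and drops with reasons", {
  ex <- make_assoc(c("s1", "s2", "s3", "s4"), pos_bp = 1:4 * 1000,
                   beta = 0.1, se = 0.02)
  ex$effect_allele <- c("A", "A", "A", "A")
  ex$other_allele <- c("G", "T", "G", "G")
  out <- make_assoc(c("s1", "s2", "s3", "s5"), pos_bp = 1:4 * 1000,
                    beta = 0.05, se = 0.01)
  out$effect_allele <- c("G", "A", "A", "A")
  out$other_allele <- c("A", "T", "C", "G")
  h <- harmonize(ex, out)
  d <- attr(h, "dropped")
  # s1: swapped alleles -> beta negated
  expect_equal(h$snp_id, "s1")
  expect_equal(h$beta_out, -0.05)
  expect_true(h$flipped)
  expect_equal(d$reason[d$snp_id == "s2"], "palindrome")   # A/T
  expect_equal(d$reason[d$snp_id == "s3"], "allele_mismatch")
  expect_equal(d$reason[d$snp_id == "s4"], "missing")
  expect_error(harmonize(rbind(ex, ex[1, ]), out), "duplicate")
})

test_that("harmonizing an already-aligned set is the identity", {
  cfg <- sim_config(n_snps = 10, seed = 5)
  st <- simulate_summary_stats(cfg, sim_truth(cfg, theta = 0.1))
  out <- st$outcome
  # swap the allele labels (and negate beta) on half the outcome records
  swap <- seq(1, 10, by = 2)
  tmp <- out$effect_allele[swap]
  out$effect_allele[swap] <- out$other_allele[swap]
  out$other_allele[swap] <- tmp
  out$beta[swap] <- -out$beta[swap]
  out$eaf[swap] <- 1 - out$eaf[swap]
  h1 <- harmonize(st$exposure, out)
  expect_equal(sort(h1$snp_id[h1$flipped]), sort(out$snp_id[swap]))
  # rebuild outcome records aligned to the exposure allele from h1, then
  # re-harmonize: betas unchanged and nothing flips
  aligned <- st$exposure
  aligned$beta <- h1$beta_out[match(aligned$snp_id, h1$snp_id)]
  aligned$se <- h1$se_out[match(aligned$snp_id, h1$snp_id)]
  aligned$pval <- h1$pval_out[match(aligned$snp_id, h1$snp_id)]
  aligned$n <- h1$n_out[match(aligned$snp_id, h1$snp_id)]
  h2 <- harmonize(st$exposure, aligned)
  expect_equal(h2$beta_out, h1$beta_out)
  expect_false(any(h2$flipped))
  # flipping restores the outcome effects on the original orientation
  expect_equal(h1$beta_out[match(st$outcome$snp_id, h1$snp_id)],
               st$outcome$beta)
})

test_that("Steiger filter keeps exposure-dominant pairs, drops ties", {
  p <- make_pairs(beta_exp = c(0.5, 0.1), beta_out = c(0.01, 0.3),
                  se_exp = 0.02, se_out = 0.02, n_exp = 30000,
                  n_out = 30000)
  kept <- steiger_filter(p)
  expect_equal(kept$snp_id, p$snp_id[1])
  expect_equal(attr(kept, "dropped")$reason, "steiger")

  # a perfectly symmetric pair fails the strict inequality
  tie <- make_pairs(0.3, 0.3, se_exp = 0.02, se_out = 0.02,
                    n_exp = 30000, n_out = 30000)
  expect_equal(nrow(steiger_filter(tie)), 0)

  # missing sample size: retained with a warning, not dropped
  nas <- make_pairs(0.3, 0.01)
  nas$n_exp <- NA
  nas$eaf <- NA
  expect_warning(k2 <- steiger_filter(nas), "Steiger")
  expect_equal(nrow(k2), 1)
})

test_that("Steiger filter keeps nearly all instruments under a true causal effect", {
  kept_frac <- vapply(1:100, function(s) {
    h <- sim_harmonized(seed = s, theta = 0.2)$pairs
    nrow(suppressWarnings(steiger_filter(h))) / nrow(h)
  }, numeric(1))
  expect_gte(mean(kept_frac), 0.95)
})

test_that("F filter applies beta^2/se^2 strictly above the threshold", {
  p <- make_pairs(beta_exp = c(0.1, 0.03, 0.02), beta_out = 0.01,
                  se_exp = c(0.02, 0.01, 0.02 / sqrt(10)))
  # F = 25, 9, 10: only F > 10 survives
  kept <- f_filter(p, threshold_config())
  expect_equal(kept$snp_id, p$snp_id[1])
  expect_setequal(attr(kept, "dropped")$snp_id, p$snp_id[2:3])

  set.seed(4)
  mixed <- make_pairs(beta_exp = rnorm(30, 0, 0.1), beta_out = 0,
                      se_exp = 0.02)
  kept2 <- f_filter(mixed, threshold_config())
  brute <- mixed$snp_id[mixed$beta_exp^2 / mixed$se_exp^2 > 10]
  expect_setequal(kept2$snp_id, brute)
})

test_that("pipeline accounts for every exposure SNP exactly once", {
  cfg <- sim_config(n_snps = 30, ld_rho = 0.6, seed = 13)
  st <- simulate_summary_stats(cfg, sim_truth(cfg, theta = 0.15))
  inst <- suppressWarnings(
    select_instruments(st$exposure, st$outcome, st$ld, st$gene)
  )
  all_ids <- sort(c(inst$pairs$snp_id, inst$dropped$snp_id))
  expect_equal(all_ids, sort(st$exposure$snp_id))
  expect_equal(anyDuplicated(all_ids), 0)
  expect_true(all(inst$dropped$reason %in%
                    c("cis_window", "maf", "pval", "ld_clump",
                      "allele_mismatch", "palindrome", "missing", "steiger",
                      "weak_f")))
})
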