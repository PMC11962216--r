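# MR estimators: Wald ratio, IVW, MR-Egger, weighted median/mode, and the
# sensitivity suite.

test_that("Wald ratio follows the delta-method formula", {
  p <- make_pairs(0.25, 0.05, se_out = 0.02)
  e <- wald_ratio(p)
  expect_equal(e$beta, 0.2)
  expect_equal(e$se, 0.08)
  expect_equal(e$nsnp, 1L)
  expect_equal(wald_ratio(make_pairs(0.25, 0))$beta, 0)
  expect_error(wald_ratio(make_pairs(0, 0.05)), "zero")
})

test_that("first- and second-order Wald SEs agree for strong instruments", {
  # F = (0.5/0.01)^2 = 2500 >> 100
  p <- make_pairs(0.5, 0.1, se_exp = 0.01, se_out = 0.02)
  se1 <- wald_ratio(p)$se
  se2 <- wald_ratio(p, second_order = TRUE)$se
  expect_lt(abs(se2 - se1) / se1, 0.05)
})

test_that("IVW matches the hand-evaluated weighted sum", {
  p <- make_pairs(beta_exp = c(0.1, 0.2), beta_out = c(0.05, 0.1),
                  se_out = c(0.01, 0.02))
  e <- ivw(p)
  expect_equal(e$beta, 0.5)
  expect_equal(e$se, 1 / sqrt(200))
  expect_error(ivw(p[1, ]), "wald_ratio")
})

test_that("IVW is exact when all ratios agree and sign-flip invariant", {
  p <- make_pairs(beta_exp = c(0.1, 0.2, 0.3), beta_out = c(0.03, 0.06, 0.09),
                  se_out = c(0.01, 0.02, 0.015))
  expect_equal(ivw(p)$beta, 0.3)

  set.seed(2)
  q <- make_pairs(beta_exp = runif(8, 0.1, 0.4),
                  beta_out = rnorm(8, 0.05, 0.02),
                  se_out = runif(8, 0.01, 0.03))
  flipped <- q
  idx <- c(2, 5, 7)
  flipped$beta_exp[idx] <- -flipped$beta_exp[idx]
  flipped$beta_out[idx] <- -flipped$beta_out[idx]
  expect_equal(ivw(flipped)$beta, ivw(q)$beta)
  expect_equal(ivw(flipped)$se, ivw(q)$se)
})

test_that("multiplicative random-effects IVW never deflates the SE", {
  set.seed(9)
  p <- make_pairs(beta_exp = runif(10, 0.1, 0.4),
                  beta_out = rnorm(10, 0.06, 0.05), se_out = 0.01)
  expect_gte(ivw(p, random_effects = TRUE)$se, ivw(p)$se)
})

test_that("MR-Egger recovers an exact affine relationship", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  p <- make_pairs(beta_exp = bx, beta_out = 0.01 + 0.5 * bx,
                  se_out = c(0.01, 0.02, 0.01, 0.03))
  e <- mr_egger(p)
  expect_equal(e$slope$beta, 0.5, tolerance = 1e-10)
  expect_equal(e$intercept, 0.01, tolerance = 1e-10)
  expect_error(mr_egger(p[1:2, ]), "3")
})

test_that("Egger slope approaches IVW without pleiotropy", {
  # exogenous exposure effects, no pleiotropy: both estimators target 0.2
  est <- vapply(1:200, function(s) {
    set.seed(s + 300)
    bx <- runif(15, 0.1, 0.5)
    p <- make_pairs(beta_exp = bx, beta_out = 0.2 * bx + rnorm(15, 0, 0.02),
                    se_exp = 1e-6, se_out = 0.02)
    c(ivw(p)$beta, mr_egger(p)$slope$beta)
  }, numeric(2))
  mc_se <- apply(est, 1, sd) / sqrt(ncol(est))
  expect_lt(abs(mean(est[1, ]) - 0.2), 2 * mc_se[1])
  expect_lt(abs(mean(est[2, ]) - 0.2), 2 * mc_se[2])
  # and the two agree closely on average
  expect_lt(abs(mean(est[2, ] - est[1, ])), 0.01)
})

test_that("weighted median interpolates at the half-weight point", {
  p <- make_pairs(beta_exp = c(1, 1, 1), beta_out = c(0.4, 0.5, 0.6),
                  se_out = 0.01)
  expect_equal(weighted_median(p, n_boot = 0)$beta, 0.5)
  e <- weighted_median(p, n_boot = 200, seed = 4)
  expect_true(is.finite(e$se) && e$se > 0)
  # identical seed, identical bootstrap SE
  expect_equal(weighted_median(p, n_boot = 200, seed = 4)$se, e$se)
})

test_that("weighted median equals the brute-force oracle and tracks weight", {
  set.seed(31)
  for (i in 1:10) {
    k <- sample(3:9, 1)
    p <- make_pairs(beta_exp = runif(k, 0.1, 0.5),
                    beta_out = rnorm(k, 0.1, 0.05),
                    se_out = runif(k, 0.005, 0.03))
    r <- p$beta_out / p$beta_exp
    w <- (p$beta_exp / p$se_out)^2
    expect_equal(weighted_median(p, n_boot = 0)$beta,
                 oracle_weighted_median(r, w), tolerance = 1e-12)
  }
  # duplicating one SNP doubles its weight and pulls the median toward it
  p <- make_pairs(beta_exp = c(1, 1, 1), beta_out = c(0.2, 0.5, 0.8),
                  se_out = 0.01)
  dup <- rbind(p, p[3, ])
  dup$snp_id <- sprintf("rs%04d", 1:4)
  m1 <- weighted_median(p, n_boot = 0)$beta
  m2 <- weighted_median(dup, n_boot = 0)$beta
  r <- dup$beta_out / dup$beta_exp
  w <- (dup$beta_exp / dup$se_out)^2
  expect_equal(m2, oracle_weighted_median(r, w), tolerance = 1e-12)
  expect_gt(m2, m1)
})

test_that("weighted mode finds the majority cluster and stays in range", {
  p <- make_pairs(beta_exp = rep(1, 9),
                  beta_out = c(rep(0.2, 6), rep(0.8, 3)),
                  se_out = 0.02)
  e <- weighted_mode(p, n_boot = 0)
  expect_equal(e$beta, 0.2, tolerance = 0.02)

  # all ratios identical: returns that ratio with vanishing bootstrap noise
  same <- make_pairs(beta_exp = c(0.2, 0.3, 0.4),
                     beta_out = c(0.1, 0.15, 0.2), se_exp = 1e-6,
                     se_out = 1e-6)
  es <- weighted_mode(same, n_boot = 100, seed = 2)
  expect_equal(es$beta, 0.5, tolerance = 1e-6)
  expect_lt(es$se, 1e-3)

  set.seed(17)
  for (i in 1:10) {
    k <- sample(3:10, 1)
    q <- make_pairs(beta_exp = runif(k, 0.1, 0.5),
                    beta_out = rnorm(k, 0.1, 0.1),
                    se_out = runif(k, 0.005, 0.03))
    r <- q$beta_out / q$beta_exp
    m <- weighted_mode(q, n_boot = 0)$beta
    expect_gte(m, min(r))
    expect_lte(m, max(r))
  }
})

test_that("sensitivity suite: Q, Egger intercept and leave-one-out", {
  # exact proportionality: zero heterogeneity
  p0 <- make_pairs(beta_exp = c(0.1, 0.2, 0.4),
                   beta_out = c(0.02, 0.04, 0.08), se_out = 0.01)
  s0 <- sensitivity(p0)
  expect_equal(s0$q, 0, tolerance = 1e-20)
  expect_equal(s0$q_pval, 1)
  expect_equal(s0$q_df, 2L)
  expect_equal(nrow(s0$loo), 3)

  set.seed(7)
  p <- make_pairs(beta_exp = runif(6, 0.1, 0.5),
                  beta_out = rnorm(6, 0.08, 0.04), se_out = 0.02)
  s <- sensitivity(p)
  # Q recomputed from its definition
  w <- p$beta_exp^2 / p$se_out^2
  ratio <- p$beta_out / p$beta_exp
  b <- ivw(p)$beta
  expect_equal(s$q, sum(w * (ratio - b)^2))
  expect_equal(s$egger_intercept, mr_egger(p)$intercept)
  # each leave-one-out row equals the direct refit
  for (i in seq_len(6)) {
    expect_equal(s$loo$beta[i], ivw(p[-i, ])$beta)
  }
  # removing the largest-weight SNP moves IVW at least as much as removing
  # the smallest-weight SNP
  shift <- abs(s$loo$beta - b)
  expect_gte(shift[which.max(w)], shift[which.min(w)])
})

test_that("Cochran Q is chi-squared calibrated under homogeneity", {
  qs <- vapply(1:300, function(s) {
    h <- sim_harmonized(seed = s + 900, theta = 0.2)$pairs
    sensitivity(h)$q
  }, numeric(1))
  # mean of a chi2(19) is 19; allow Monte-Carlo slack
  expect_equal(mean(qs), 19, tolerance = 0.08)
})

test_that("odds-ratio transform preserves ordering", {
  set.seed(5)
  for (i in 1:20) {
    p <- make_pairs(beta_exp = runif(4, 0.1, 0.5),
                    beta_out = rnorm(4, 0, 0.1), se_out = 0.02)
    e <- ivw(p)
    expect_lt(e$ci_low, e$or_)
    expect_gt(e$ci_high, e$or_)
    expect_equal(e$or_, exp(e$beta))
  }
})
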