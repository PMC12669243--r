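test_that("filter_for_association drops zero-ROH samples then rare columns", {
  r <- matrix(0L, 10, 5,
              dimnames = list(sprintf("s%02d", 1:10), paste0("v", 1:5)))
  r[1:6, 1] <- 1L          # common column
  r[2:5, 2] <- 1L          # common column
  r[3, 3] <- 1L            # 1 carrier / 9 remaining ~ 11% -> kept at 1%
  # sample 10 has no ROH anywhere -> dropped first
  out <- filter_for_association(r, freq_min = 0.01)
  rep <- attr(out, "report")
  expect_equal(rep$samples_removed, 4)       # s07..s10 all-zero
  expect_equal(rownames(out), sprintf("s%02d", 1:6))
  expect_equal(rep$snps_removed, 2)          # v4, v5 empty
  # a 0.5% column among 200 samples is removed
  r2 <- matrix(0L, 200, 2)
  r2[, 1] <- 1L
  r2[1, 2] <- 1L
  out2 <- filter_for_association(r2, freq_min = 0.01)
  expect_equal(ncol(out2), 1)
  expect_error(filter_for_association(r2[, 2, drop = FALSE] * 0L),
               "no SNP")
})

test_that("with an identity GRM the null LMM collapses to OLS", {
  set.seed(61)
  n <- 150
  x <- cbind(pc1 = rnorm(n), sex = rbinom(n, 1, 0.5), age = runif(n, 20, 70))
  y <- 2 + x %*% c(0.5, 1, 0.02) + rnorm(n)
  fit <- fit_null_lmm(y, x, diag(n))
  ols <- lm(y ~ x)
  expect_equal(fit$var_g + fit$var_e, summary(ols)$sigma^2, tolerance = 0.02)
  expect_equal(fit$fixed$estimate, unname(coef(ols)), tolerance = 1e-3)
  # a status column orthogonal to the trait: GLS p matches OLS p closely
  s <- rbinom(n, 1, 0.3)
  res <- test_regional(matrix(s, ncol = 1), fit)
  ols2 <- summary(lm(y ~ x + s))$coefficients["s", ]
  expect_equal(res$beta, unname(ols2["Estimate"]), tolerance = 1e-5)
  expect_equal(res$p, unname(ols2["Pr(>|t|)"]), tolerance = 1e-5)
})

test_that("REML recovers planted variance components on family data", {
  k <- family_kinship(n_families = 60, family_size = 5)   # n = 300
  x <- cbind(age = runif(300, 20, 70))
  vg_hat <- ve_hat <- numeric(8)
  for (s in 1:8) {
    y <- draw_lmm_trait(x, k, beta = c(1, 0.02), var_g = 2, var_e = 1,
                        seed = 100 + s)
    fit <- fit_null_lmm(y, x, k)
    vg_hat[s] <- fit$var_g; ve_hat[s] <- fit$var_e
  }
  expect_equal(mean(vg_hat), 2, tolerance = 0.25)
  expect_equal(mean(ve_hat), 1, tolerance = 0.25)
})

test_that("pure-noise traits drive the genetic variance to zero", {
  k <- family_kinship(30, 5)
  x <- cbind(age = runif(150, 20, 70))
  vg <- vapply(1:7, function(s) {
    set.seed(200 + s)
    fit_null_lmm(rnorm(150), x, k)$var_g
  }, numeric(1))
  expect_lt(median(vg), 0.05)
})

test_that("two-stage p-values track exact per-SNP REML refits", {
  # the refit re-estimates the variance components with the SNP included;
  # the two-stage test holds the null variance ratio fixed, so agreement
  # is near-exact for the bulk of SNPs while chance-significant null SNPs
  # can deviate somewhat more
  rel_all <- c()
  for (inst in 1:3) {
    set.seed(600 + inst)
    k <- family_kinship(40, 5)                      # n = 200
    n <- 200
    x <- cbind(sex = rbinom(n, 1, 0.5), age = runif(n, 20, 70))
    y <- draw_lmm_trait(x, k, beta = c(5, 0.5, 0.01), var_g = 1, var_e = 1,
                        seed = 700 + inst)
    status <- matrix(rbinom(n * 25, 1, 0.15), n, 25)
    colnames(status) <- paste0("v", 1:25)
    fit <- fit_null_lmm(y, x, k)
    two_stage <- test_regional(status, fit)
    p_exact <- vapply(seq_len(25), function(j) {
      refit <- fit_null_lmm(y, cbind(x, s = status[, j]), k)
      refit$fixed$p[refit$fixed$term == "s"]
    }, numeric(1))
    rel_all <- c(rel_all, abs(two_stage$p - p_exact) /
                   pmax(p_exact, two_stage$p))
  }
  expect_lt(stats::median(rel_all), 0.03)
  expect_gte(mean(rel_all <= 0.10), 0.95)
  expect_lt(max(rel_all), 0.30)
})

test_that("the regional test is invariant to affine trait rescaling", {
  set.seed(65)
  k <- family_kinship(20, 5)
  n <- 100
  x <- cbind(age = runif(n, 20, 70))
  y <- draw_lmm_trait(x, k, beta = c(1, 0.02), var_g = 1, var_e = 1,
                      seed = 66)
  status <- matrix(rbinom(n * 5, 1, 0.3), n, 5)
  a <- test_regional(status, fit_null_lmm(y, x, k))
  b <- test_regional(status, fit_null_lmm(3 * y + 7, x, k))
  expect_equal(b$p, a$p, tolerance = 1e-6)
  expect_equal(b$beta, 3 * a$beta, tolerance = 1e-6)
})

test_that("constant status columns are flagged, not tested", {
  set.seed(67)
  n <- 60
  x <- cbind(age = runif(n, 20, 70))
  fit <- fit_null_lmm(rnorm(n), x, diag(n))
  status <- cbind(all0 = rep(0L, n), mixed = rbinom(n, 1, 0.5),
                  all1 = rep(1L, n))
  res <- test_regional(status, fit)
  expect_true(is.na(res$p[1]) && is.na(res$p[3]))
  expect_false(is.na(res$p[2]))
  expect_equal(res$note[1], "constant status")
})

test_that("bonferroni_threshold is alpha over the test count", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
  expect_equal(bonferroni_threshold(0.05, 410000), 0.05 / 410000)
  expect_error(bonferroni_threshold(0.05, 0))
})

test_that("clumping follows the greedy hand trace", {
  set.seed(68)
  n <- 400
  base <- rbinom(n, 2, 0.5)
  noisy <- function(k) { x <- base; i <- sample(n, k); x[i] <- 2 - x[i]; x }
  calls <- cbind(base, noisy(20), rbinom(n, 2, 0.5))
  g <- chrom_fixture(calls, pos = c(1e5, 1.5e5, 2e5))
  expect_gt(cor(calls[, 1], calls[, 2])^2, 0.5)
  expect_lt(cor(calls[, 1], calls[, 3])^2, 0.5)
  res <- data.frame(id = c("v1", "v2", "v3"), chrom = "1",
                    pos = c(1e5, 1.5e5, 2e5),
                    p = c(1e-10, 1e-8, 1e-9))
  cl <- clump_assoc(res, g)
  expect_equal(cl$clump[cl$id == "v1"], "v1")   # index
  expect_equal(cl$clump[cl$id == "v2"], "v1")   # assigned to v1
  expect_equal(cl$clump[cl$id == "v3"], "v3")   # independent index
  # a single sub-p1 SNP forms a clump of size one
  cl2 <- clump_assoc(res[1, ], g)
  expect_equal(cl2$clump, "v1")
  # p above p1 and no nearby index: unclumped
  cl3 <- clump_assoc(transform(res, p = c(1e-3, 0.5, 0.9)), g)
  expect_true(all(is.na(cl3$clump)))
})

test_that("clump assignments ignore input row order", {
  set.seed(69)
  g <- hwe_genotypes(n = 300, m = 12, seed = 70)
  res <- data.frame(id = g$variants$id, chrom = g$variants$chrom,
                    pos = g$variants$pos,
                    p = 10^-runif(12, 2, 9))
  a <- clump_assoc(res, g)
  b <- clump_assoc(res[sample(12), ], g)
  expect_identical(a, b)
})

test_that("encode_genotype maps dosages per model", {
  expect_equal(encode_genotype(c(0L, 1L, 2L, NA), "additive"),
               c(0, 1, 2, NA))
  expect_equal(encode_genotype(c(0L, 1L, 2L, NA), "recessive"),
               c(0, 0, 1, NA))
  expect_error(encode_genotype(1L, "dominant"))
})

test_that("test_genotype recovers a planted effect within 2 SE", {
  set.seed(71)
  n <- 500
  covar <- cbind(age = runif(n, 20, 70))
  dose <- rbinom(n, 2, 0.3)
  y <- 1 + 0.02 * covar[, 1] + 0.4 * dose + rnorm(n)
  res <- test_genotype(dose, y, covar, model = "additive")
  expect_lt(abs(res$beta - 0.4), 2 * res$se)
  expect_lt(res$p, 1e-4)
  # constant regressor flagged; tiny n errors
  expect_equal(test_genotype(rep(1, n), y, covar)$note, "constant regressor")
  expect_error(test_genotype(dose[1:5], y[1:5], covar[1:5, , drop = FALSE]),
               "complete cases")
})

test_that("a recessive architecture favors the recessive encoding", {
  set.seed(72)
  wins <- 0
  for (s in 1:15) {
    n <- 500
    dose <- rbinom(n, 2, 0.4)
    covar <- cbind(age = runif(n, 20, 70))
    y <- 0.5 * (dose == 2) + rnorm(n)
    p_rec <- test_genotype(encode_genotype(dose, "recessive"), y, covar,
                           "recessive")$p
    p_add <- test_genotype(encode_genotype(dose, "additive"), y, covar,
                           "additive")$p
    wins <- wins + (p_rec < p_add)
  }
  expect_gte(wins, 12)
})
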