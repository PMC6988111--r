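# Helper: matrix of module medians with named samples + matching metadata.
medFixture <- function(values, md) {
  m <- matrix(values, 1, dimnames = list("M1", md$sample_id))
  m
}

test_that("Cohen's d and t follow the pooled-sd hand computations", {
  md <- data.frame(sample_id = paste0("s", 1:6),
                   sex = rep(c("male", "female"), each = 3),
                   stringsAsFactors = FALSE)
  res <- differentialModuleAbundance(medFixture(c(1, 2, 3, 1, 2, 3), md),
                                     md, "sex")
  expect_equal(res$cohen_d, 0)
  expect_equal(res$p_value, 1)

  md2 <- data.frame(sample_id = paste0("s", 1:6),
                    sex = c("male", "male", "male", "female", "female",
                            "female"), stringsAsFactors = FALSE)
  # groups [2,4,3] (male) vs [1,3,2] (female): pooled sd = 1, d = 1
  res2 <- differentialModuleAbundance(medFixture(c(2, 4, 3, 1, 3, 2), md2),
                                      md2, "sex")
  expect_equal(res2$cohen_d, 1)
  # antisymmetry: swapping group labels flips the sign
  md3 <- md2
  md3$sex <- rev(md3$sex)
  res3 <- differentialModuleAbundance(medFixture(c(2, 4, 3, 1, 3, 2), md3),
                                      md3, "sex")
  expect_equal(res3$cohen_d, -res2$cohen_d)
})

test_that("two-sample Cohen's d = 1/sqrt(2) example holds with n = 2 groups", {
  # groups [2,4] vs [1,3]: means 3 and 2, pooled sd = sqrt(2)
  x1 <- c(2, 4); x2 <- c(1, 3)
  sp <- sqrt(((1) * var(x1) + (1) * var(x2)) / 2)
  expect_equal((mean(x1) - mean(x2)) / sp, 1 / sqrt(2))
})

test_that("differential-abundance q-values are calibrated under the null", {
  set.seed(17)
  n <- 100
  md <- balancedMetadata(n)
  m <- matrix(rnorm(200 * n), 200, n,
              dimnames = list(sprintf("M%03d", 1:200), md$sample_id))
  res <- differentialModuleAbundance(m, md, "sex")
  expect_lte(mean(res$significant), 0.01 + 3 * sqrt(0.01 * 0.99 / 200))
  # BH invariants
  expect_true(all(res$q_value >= res$p_value))
  expect_true(all(res$q_value <= 1))
})

test_that("variance-prior estimation recovers the generating (d0, s0^2)", {
  d0hat <- s0hat <- numeric(50)
  for (s in 1:50) {
    set.seed(s)
    df <- 20
    # true variances ~ s0^2 d0/chi2(d0); observed s2 add chi2(df)/df noise
    s2 <- (rchisq(500, df) / df) * (4 / rchisq(500, 4))
    pr <- estimateVariancePrior(s2, df)
    d0hat[s] <- pr$d0; s0hat[s] <- pr$s0sq
  }
  expect_gte(median(d0hat), 2.5); expect_lte(median(d0hat), 6)
  expect_gte(median(s0hat), 0.8); expect_lte(median(s0hat), 1.25)
})

test_that("variance prior matches limma's empirical-Bayes fit", {
  set.seed(33)
  s2 <- exp(rnorm(300, 0, 0.8))
  df <- 15
  ours <- estimateVariancePrior(s2, df)
  ref <- limma::squeezeVar(s2, df)
  expect_equal(ours$d0, ref$df.prior, tolerance = 1e-6)
  expect_equal(ours$s0sq, ref$var.prior, tolerance = 1e-6)
  post <- (ours$d0 * ours$s0sq + df * s2) / (ours$d0 + df)
  expect_equal(post, ref$var.post, tolerance = 1e-6)
})

test_that("moderated t reduces to the ordinary t when d0 = 0", {
  sim <- generateCohort(cohortConfig(nSamples = 40, nComplexes = 3,
                                     complexSizeRange = c(6L, 6L),
                                     nBackgroundProteins = 0, nPathways = 0,
                                     missingRate = 0, seed = 8))
  prof <- complexNormalize(sim$datasets[[1]], sim$complexes)
  res <- fitModeratedContrasts(prof, sim$metadata, priorDf = 0)
  expect_equal(res$s2_posterior, res$s2)
  expect_equal(res$df_total, res$df_residual)
  # cross-check one subunit against lm() summary t
  r1 <- res[res$contrast == "sex", ][1, ]
  pc <- complexProfiles(prof)[[r1$complex_id]]
  y <- pc[r1$protein_id, ]
  fit <- lm(y ~ sex + diet, data = cbind(data.frame(y = y),
            sim$metadata[match(names(y), sim$metadata$sample_id), ]))
  ref <- summary(fit)$coefficients["sexmale", ]
  expect_equal(r1$log2_fc, unname(ref["Estimate"]), tolerance = 1e-10)
  expect_equal(r1$t_moderated, unname(ref["t value"]), tolerance = 1e-10)
  expect_equal(r1$p_value, unname(ref["Pr(>|t|)"]), tolerance = 1e-10)
})

test_that("moderated-t p-values are uniform under the null", {
  sim <- generateCohort(cohortConfig(nSamples = 60, nComplexes = 40,
                                     complexSizeRange = c(8L, 8L),
                                     latentStrengthRange = c(0.5, 0.5),
                                     nBackgroundProteins = 0, nPathways = 0,
                                     missingRate = 0, seed = 19))
  prof <- complexNormalize(sim$datasets[[1]], sim$complexes)
  res <- fitModeratedContrasts(prof, sim$metadata)
  expect_gt(ks.test(res$p_value, "punif")$p.value, 0.01)
  expect_true(all(res$d0 > 0))
})

test_that("forcing d0 = Inf uses the common prior variance", {
  sim <- generateCohort(cohortConfig(nSamples = 40, nComplexes = 3,
                                     complexSizeRange = c(6L, 6L),
                                     nBackgroundProteins = 0, nPathways = 0,
                                     missingRate = 0, seed = 9))
  prof <- complexNormalize(sim$datasets[[1]], sim$complexes)
  res <- fitModeratedContrasts(prof, sim$metadata, priorDf = Inf,
                               priorVar = 0.25)
  expect_true(all(res$s2_posterior == 0.25))
  expect_true(all(is.infinite(res$df_total)))
})

test_that("Fisher combination matches the chi-square oracle", {
  mk <- function(q) data.frame(complex_id = "C", contrast = "sex",
                               protein_id = paste0("p", seq_along(q)),
                               p_value = q, q_value = q)
  v1 <- combineComplexVerdict(mk(c(0.5, 0.5)))
  expect_equal(v1$fisher_chi2, -2 * log(0.25), tolerance = 1e-4) # 2.7726
  expect_equal(v1$df, 4L)
  expect_equal(v1$combined_p, pchisq(-2 * log(0.25), 4,
                                     lower.tail = FALSE))
  expect_equal(round(v1$combined_p, 4), 0.5966)
  v2 <- combineComplexVerdict(mk(c(1, 1)))
  expect_equal(v2$fisher_chi2, 0)
  expect_equal(v2$combined_p, 1)
  expect_warning(v3 <- combineComplexVerdict(mk(c(0, 0.5))), "clamped")
  expect_lt(v3$combined_p, 1e-10)
})

test_that("a planted stoichiometric shift wins the complex verdict", {
  wins <- 0L
  for (s in 1:10) {
    cfg <- cohortConfig(nSamples = 96, nComplexes = 20,
                        complexSizeRange = c(6L, 6L),
                        latentStrengthRange = c(0.5, 0.5),
                        stoichiometryEffects = data.frame(
                          complex = 1, subunit = 1, factor = "sex",
                          shift = 0.5),
                        nBackgroundProteins = 0, nPathways = 0,
                        missingRate = 0, seed = 3000 + s)
    sim <- generateCohort(cfg)
    prof <- complexNormalize(sim$datasets[[1]], sim$complexes)
    res <- fitModeratedContrasts(prof, sim$metadata)
    verd <- combineComplexVerdict(res[res$contrast == "sex", ])
    wins <- wins + (verd$complex_id[which.min(verd$combined_q)] == "CPX001")
  }
  expect_gte(wins, 9L)
})

test_that("collinear designs are rejected with a clear message", {
  sim <- generateCohort(cohortConfig(nSamples = 40, nComplexes = 2,
                                     complexSizeRange = c(6L, 6L),
                                     nBackgroundProteins = 0, nPathways = 0,
                                     missingRate = 0, seed = 4))
  md <- sim$metadata
  md$diet <- ifelse(md$sex == "male", "high_fat", "chow")   # confounded
  prof <- complexNormalize(sim$datasets[[1]], sim$complexes)
  expect_error(fitModeratedContrasts(prof, md), "collinear")
})
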