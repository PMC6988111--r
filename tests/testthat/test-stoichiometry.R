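test_that("trimmed-mean normalization matches the worked example", {
  m <- matrix(c(10, 11, 12, 13, 20, 21, 22, 23), 4, 2,
              dimnames = list(paste0("P", 1:4), c("s1", "s2")))
  cat <- ModuleCatalog(list(C = paste0("P", 1:4)), "complex")
  prof <- complexNormalize(makeSet(m), cat, trim = 0.25, minMembers = 4)
  # reference = mean(11, 12) = 11.5 after dropping one value per side
  expect_equal(unname(normalizedAbundances(prof)[, "s1"]),
               c(-1.5, -0.5, 0.5, 1.5))
})

test_that("complex normalization is shift-invariant and preserves missingness", {
  set.seed(5)
  m <- matrix(rnorm(6 * 30, 20), 6, 30,
              dimnames = list(paste0("P", 1:6), sprintf("s%02d", 1:30)))
  m[2, 5] <- NA
  cat <- ModuleCatalog(list(C = paste0("P", 1:6)), "complex")
  prof <- complexNormalize(makeSet(m), cat)
  m2 <- m
  m2[, 7] <- m2[, 7] + 2          # complex-level shift in one sample
  prof2 <- complexNormalize(makeSet(m2), cat)
  expect_equal(normalizedAbundances(prof2), normalizedAbundances(prof),
               tolerance = 1e-12)
  expect_true(is.na(normalizedAbundances(prof)[2, 5]))
  # samples with < 3 quantified subunits get no reference
  m3 <- m
  m3[1:4, 9] <- NA
  prof3 <- complexNormalize(makeSet(m3), cat, minQuantifiedSubunits = 3)
  expect_true(all(is.na(normalizedAbundances(prof3)[, 9])))
})

test_that("multi-complex proteins average their complex-normalized values", {
  # shared protein X: normalized -1 in c1 and +1 in c2 -> combined 0
  s <- paste0("s", 1:3)
  m <- rbind(X = c(10, 10, 10),
             A1 = c(11, 11, 11), A2 = c(11, 11, 11), A3 = c(11, 11, 11),
             A4 = c(11, 11, 11),
             B1 = c(9, 9, 9), B2 = c(9, 9, 9), B3 = c(9, 9, 9),
             B4 = c(9, 9, 9))
  colnames(m) <- s
  cat <- ModuleCatalog(list(c1 = c("X", paste0("A", 1:4)),
                            c2 = c("X", paste0("B", 1:4))), "complex")
  prof <- complexNormalize(makeSet(m), cat, trim = 0.25)
  expect_equal(complexProfiles(prof)$c1["X", ], setNames(rep(-1, 3), s))
  expect_equal(complexProfiles(prof)$c2["X", ], setNames(rep(1, 3), s))
  expect_equal(normalizedAbundances(prof)["X", ], setNames(rep(0, 3), s))
})

test_that("variance z-scores standardize within complex", {
  prof <- new("StoichiometryProfile", datasetId = "t",
              normalized = matrix(0, 0, 0), perComplex = list(),
              zTable = data.frame(complex_id = character(),
                                  protein_id = character(),
                                  variance = numeric(), z = numeric()))
  # construct per-complex matrices with known variances 1, 2, 3
  set.seed(2)
  n <- 400
  mk <- function(v) sqrt(v) * scale(rnorm(n))[, 1]
  pc <- rbind(a = mk(1), b = mk(2), c = mk(3))
  colnames(pc) <- sprintf("s%03d", 1:n)
  prof@perComplex <- list(C = pc)
  zt <- zTable(subunitVarianceZ(prof))
  expect_equal(zt$z, c(-1, 0, 1), tolerance = 1e-8)
  # exactly equal variances -> all z 0
  base <- rnorm(n)
  pc2 <- rbind(a = base, b = -base, c = base)
  colnames(pc2) <- colnames(pc)
  prof@perComplex <- list(C = pc2)
  expect_equal(zTable(subunitVarianceZ(prof))$z, c(0, 0, 0),
               tolerance = 1e-8)
  # z-scores have mean ~0 per complex by construction
  expect_equal(mean(zt$z), 0, tolerance = 1e-12)
})

test_that("an inflated-variance subunit attains the top z-score", {
  hits <- 0L
  for (s in 1:50) {
    cfg <- cohortConfig(nSamples = 200, nComplexes = 1,
                        complexSizeRange = c(10L, 10L),
                        nVariableSubunitsPerComplex = 1L,
                        variableVarianceMultiplier = 4,
                        nBackgroundProteins = 0L, nPathways = 0L,
                        missingRate = 0, seed = 1000 + s)
    sim <- generateCohort(cfg)
    prof <- subunitVarianceZ(complexNormalize(sim$datasets[[1]],
                                              sim$complexes))
    zt <- zTable(prof)
    planted <- sim$groundTruth$subunits$protein_id[
      sim$groundTruth$subunits$variable]
    hits <- hits + (zt$protein_id[which.max(zt$z)] == planted)
  }
  expect_gte(hits, 48L)   # >= 95% of seeds
})

test_that("component calls follow the one-sided normal tails", {
  prof <- new("StoichiometryProfile", datasetId = "t",
              normalized = matrix(0, 0, 0), perComplex = list(),
              zTable = data.frame(complex_id = "C",
                                  protein_id = c("a", "b", "c", "d"),
                                  variance = 1:4,
                                  z = c(1.645, 0, -2, 1.4)))
  calls <- callComponentsWithinDataset(prof, alpha = 0.05)
  expect_equal(calls$label, c("variable", "neutral", "stable", "neutral"))
  expect_equal(calls$display_label, c("variable", "neutral", "stable",
                                      "neutral"))
  expect_equal(calls$p_upper[1], 0.05, tolerance = 1e-3)  # boundary z
})

test_that("complex normalization strips the shared-factor component", {
  cfg <- cohortConfig(nSamples = 150, nComplexes = 1,
                      complexSizeRange = c(8L, 8L),
                      latentStrengthRange = c(0.7, 0.7),
                      nBackgroundProteins = 0, nPathways = 0,
                      missingRate = 0, seed = 77)
  sim <- generateCohort(cfg)
  raw <- abundances(sim$datasets[[1]])
  prof <- complexNormalize(sim$datasets[[1]], sim$complexes)
  pcShare <- function(m) {
    s <- svd(scale(t(m), scale = FALSE))$d^2
    s[1] / sum(s)
  }
  expect_lt(pcShare(normalizedAbundances(prof)), pcShare(raw))
})

test_that("cross-dataset test recovers planted variable subunits", {
  cfg <- cohortConfig(nSamples = 120, nComplexes = 8,
                      complexSizeRange = c(8L, 8L),
                      nVariableSubunitsPerComplex = 1L,
                      variableVarianceMultiplier = 4,
                      nBackgroundProteins = 0, nPathways = 0,
                      missingRate = 0, nDatasets = 4, seed = 55)
  sim <- generateCohort(cfg)
  profiles <- lapply(sim$datasets, function(d)
    subunitVarianceZ(complexNormalize(d, sim$complexes)))
  calls <- crossDatasetComponentTest(profiles)
  gt <- sim$groundTruth$subunits
  planted <- gt$protein_id[gt$variable]
  hit <- calls$q_value[calls$protein_id %in% planted] < 0.05
  expect_gte(mean(hit), 0.75)
  # a subunit observed in a single dataset is untested
  one <- crossDatasetComponentTest(profiles[1])
  expect_true(all(is.na(one$p_value)))
})

test_that("z-score consistency separates replicates from permutations", {
  cfg <- cohortConfig(nSamples = 120, nComplexes = 10,
                      complexSizeRange = c(8L, 8L),
                      nVariableSubunitsPerComplex = 1L,
                      variableVarianceMultiplier = 6,
                      nBackgroundProteins = 0, nPathways = 0,
                      missingRate = 0, nDatasets = 3, seed = 66)
  sim <- generateCohort(cfg)
  profiles <- lapply(sim$datasets, function(d)
    subunitVarianceZ(complexNormalize(d, sim$complexes)))
  cons <- zscoreConsistency(profiles, nPerm = 100, seed = 2)
  expect_gt(cons$meanR, 0)
  expect_lt(cons$p, 0.01)
  # a z-vector against itself correlates perfectly
  self <- zscoreConsistency(profiles[c(1, 1)], nPerm = 10, seed = 1)
  expect_equal(self$meanR, 1)
})
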