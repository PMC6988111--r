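test_that("complex median co-abundance applies definition and member floor", {
  set.seed(3)
  base <- rnorm(50, 20)
  m <- rbind(t(replicate(3, base)),              # identical profiles
             matrix(rnorm(6 * 50, 20), 6))
  rownames(m) <- c(paste0("T", 1:3), paste0("N", 1:6))
  colnames(m) <- paste0("s", 1:50)
  x <- makeSet(m)
  cat <- ModuleCatalog(list(tight = paste0("T", 1:3),
                            noisy = paste0("N", 1:6)), "complex")
  tab <- complexMedianCoabundance(x, cat, minMembers = 5)
  expect_equal(tab$module_id, "noisy")           # 3-member complex skipped
  tab2 <- complexMedianCoabundance(x, cat, minMembers = 3)
  expect_equal(tab2$median_r[tab2$module_id == "tight"], 1)
  rs <- pairwiseCorrelations(x, t(combn(paste0("N", 1:6), 2)), 6)$r
  expect_equal(tab$median_r, median(rs))
})

test_that("independent-noise complexes have near-zero median co-abundance", {
  inside <- 0L
  for (s in 1:40) {
    x <- randomSet(5, 100, seed = s)
    cat <- ModuleCatalog(list(C = rownames(x)), "complex")
    mr <- complexMedianCoabundance(x, cat)$median_r
    inside <- inside + (abs(mr) <= 0.2)
  }
  expect_gte(inside, 38L)   # >= 95% of seeds
})

test_that("landscape aggregation classifies quartiles and handles few datasets", {
  mk <- function(ranks, id) data.frame(
    dataset_id = id, module_id = sprintf("C%02d", seq_along(ranks)),
    n_members_quantified = 6L, median_r = 1 - ranks / 10,
    rank = ranks, rank_fraction = ranks / length(ranks))
  land <- aggregateLandscape(list(mk(1:10, "a"), mk(1:10, "b")))
  expect_equal(land$median_rank_fraction[land$module_id == "C01"], 0.1)
  expect_equal(land$class[land$module_id == "C01"], "stable")
  expect_equal(land$class[land$module_id == "C10"], "variable")
  # order invariance
  land2 <- aggregateLandscape(list(mk(1:10, "b"), mk(1:10, "a")))
  expect_equal(land, land2)
  # complex ranked 1st and 10th of 10: median fraction 0.55, intermediate
  flip <- mk(c(10, 2:9, 1), "b")
  land3 <- aggregateLandscape(list(mk(1:10, "a"), flip))
  expect_equal(land3$median_rank_fraction[land3$module_id == "C01"], 0.55)
  expect_equal(land3$class[land3$module_id == "C01"], "intermediate")
  # complex present in one dataset only: class NA
  land4 <- aggregateLandscape(list(mk(1:10, "a"), mk(1:9, "b")))
  expect_true(is.na(land4$class[land4$module_id == "C10"]))
})

test_that("landscape rank tracks planted co-abundance strength", {
  cfg <- cohortConfig(nSamples = 100, nComplexes = 40,
                      latentStrengthRange = c(0, 0.9),
                      nBackgroundProteins = 50, nPathways = 0,
                      nDatasets = 2, seed = 31)
  sim <- generateCohort(cfg)
  land <- aggregateLandscape(lapply(sim$datasets, function(d)
    complexMedianCoabundance(d, sim$complexes)))
  strength <- sim$groundTruth$complexes$latent_strength[
    match(land$module_id, sim$groundTruth$complexes$module_id)]
  expect_gte(cor(strength, -land$median_rank_fraction,
                 method = "spearman"), 0.9)
})

test_that("decoy complexes are size-matched and disjoint from real ones", {
  x <- randomSet(60, 20, seed = 2)
  cat <- ModuleCatalog(list(C1 = rownames(x)[1:5], C2 = rownames(x)[6:13]),
                       "complex")
  dec <- decoyComplexes(x, cat, seed = 4)
  expect_equal(unname(sort(lengths(moduleMembers(dec)))), c(5L, 8L))
  expect_length(intersect(unlist(moduleMembers(dec)),
                          unlist(moduleMembers(cat))), 0L)
  expect_identical(moduleMembers(decoyComplexes(x, cat, seed = 4)),
                   moduleMembers(dec))
  # small pool: reuse across decoys with a warning
  xs <- randomSet(16, 20, seed = 3)
  cat2 <- ModuleCatalog(list(C1 = rownames(xs)[1:5],
                             C2 = rownames(xs)[6:10]), "complex")
  expect_warning(dec2 <- decoyComplexes(xs, cat2, seed = 1), "reusing")
  expect_equal(unname(sort(lengths(moduleMembers(dec2)))), c(5L, 5L))
})

test_that("decoy complexes behave like background on null data", {
  # on a null cohort, decoy median co-abundances match real-noise complexes
  x <- randomSet(200, 100, seed = 11)
  cat <- ModuleCatalog(list(C1 = rownames(x)[1:6], C2 = rownames(x)[7:12],
                            C3 = rownames(x)[13:18]), "complex")
  dec <- decoyComplexes(x, cat, seed = 5)
  realR <- complexMedianCoabundance(x, cat)$median_r
  decR <- complexMedianCoabundance(x, dec)$median_r
  expect_gt(wilcox.test(realR, decR)$p.value, 0.05)
})

test_that("within-protein permutation preserves marginals and kills correlation", {
  x <- randomSet(500, 100, seed = 8)
  m <- abundances(x)
  m[sample(length(m), 300)] <- NA
  x <- makeSet(m, "withNA")
  perm <- permuteWithinProtein(x, seed = 3)
  pm <- abundances(perm)
  for (i in sample(nrow(m), 20))
    expect_equal(unname(sort(pm[i, ])), unname(sort(m[i, ])))
  expect_equal(sum(is.na(pm)), sum(is.na(m)))
  expect_identical(abundances(permuteWithinProtein(x, seed = 3)), pm)
  set.seed(1)
  pairs <- cbind(sample(rownames(m), 300, TRUE),
                 sample(rownames(m), 300, TRUE))
  pairs <- pairs[pairs[, 1] != pairs[, 2], ]
  pr <- pairwiseCorrelations(perm, pairs)
  expect_lt(mean(abs(pr$r)), 0.1)
})

test_that("replicate datasets give a consistent landscape; permuted ones do not", {
  cfg <- cohortConfig(nSamples = 80, nComplexes = 20,
                      latentStrengthRange = c(0, 0.9),
                      nBackgroundProteins = 40, nPathways = 0,
                      nDatasets = 2, seed = 41)
  sim <- generateCohort(cfg)
  cons <- landscapeConsistency(sim$datasets, sim$complexes, nPerm = 30,
                               seed = 6)
  expect_gte(cons$meanRho, 0.6)
  expect_lt(cons$p, 0.01)
  # a dataset against its own copy ranks identically
  self <- landscapeConsistency(list(sim$datasets[[1]], sim$datasets[[1]]),
                               sim$complexes, nPerm = 5, seed = 1)
  expect_equal(self$meanRho, 1)
  # two permuted datasets sit inside the null band
  permPair <- list(permuteWithinProtein(sim$datasets[[1]], 1),
                   permuteWithinProtein(sim$datasets[[2]], 2))
  consNull <- landscapeConsistency(permPair, sim$complexes, nPerm = 40,
                                   seed = 9)
  band <- quantile(consNull$nullRho, c(0.025, 0.975))
  expect_gte(consNull$meanRho, band[[1]])
  expect_lte(consNull$meanRho, band[[2]])
})

test_that("bias diagnostic bins complexes and sees no bias in unbiased data", {
  x <- randomSet(64, 60, seed = 13)
  members <- split(rownames(x), rep(1:8, each = 8))
  names(members) <- sprintf("C%02d", 1:8)
  cat <- ModuleCatalog(members, "complex")
  diag <- biasDiagnostic(x, cat, nBins = 4)
  expect_equal(as.vector(table(diag$perComplex$abundance_bin)),
               rep(2L, 4))                      # 8 complexes -> 4 bins of 2
  expect_equal(nrow(diag$abundanceTests), 6L)    # all bin pairs tested
  # abundance-independent planted correlation: no strongly significant pair
  sig <- c(diag$abundanceTests$p, diag$varianceTests$p)
  expect_true(all(sig > 0.01, na.rm = TRUE) || mean(sig < 0.01,
                                                    na.rm = TRUE) < 0.2)
})
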