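#' @include AllClasses.R
NULL

#' Configuration for a synthetic proteome cohort
#'
#' Defines the generative model of \code{\link{generateCohort}}: log2-scale
#' protein abundances in which each complex's subunits share a latent
#' complex-abundance factor of configurable strength, designated "variable"
#' subunits are decoupled from their complex and given inflated residual
#' variance, sex and diet act additively on complex abundance (through the
#' latent factor) and on individual-subunit stoichiometry (log2 shifts), and
#' background proteins and weakly co-varying pathways fill out the matrix.
#' Replicate datasets share all planted parameters but draw independent
#' noise.
#'
#' @param nSamples number of samples; sex and diet are balanced and crossed.
#' @param nComplexes number of planted complexes.
#' @param complexSizeRange integer (min, max) subunit counts per complex.
#' @param latentStrengthRange (low, high) fraction of a subunit's variance
#'   contributed by the complex's shared latent factor; per-complex strengths
#'   are evenly spaced across the range (low = first complex).
#' @param nVariableSubunitsPerComplex variable subunits planted per complex.
#' @param variableVarianceMultiplier residual-variance multiplier (> 1) for
#'   variable subunits.
#' @param variableLambdaShrink factor (default 0) shrinking a variable
#'   subunit's loading on the shared factor; 0 fully decouples it.
#' @param sexEffectFractions,dietEffectFractions per-complex fraction of the
#'   latent factor's variance attributable to sex / diet (scalar recycled or
#'   length-\code{nComplexes}); fractions must sum below 1 per complex.
#' @param stoichiometryEffects \code{NULL} or data.frame with columns
#'   \code{complex} (index), \code{subunit} (index within complex),
#'   \code{factor} ("sex"/"diet") and \code{shift} (log2 units added to
#'   male / high_fat samples), planting subunit-level stoichiometry changes.
#' @param nBackgroundProteins module-free pure-noise proteins.
#' @param nPathways,pathwaySizeRange,pathwayStrength pathway modules built
#'   like complexes but with their own (typically weaker) shared-factor
#'   strength and no covariate effects.
#' @param missingRate completely-at-random dropout probability per cell.
#' @param noiseSd residual (subunit-specific) standard deviation in log2
#'   units.
#' @param nDatasets number of replicate datasets.
#' @param seed integer master seed; fully determines the cohort.
#' @return a validated \code{CohortConfig} list.
#' @export
cohortConfig <- function(nSamples = 100L, nComplexes = 50L,
                         complexSizeRange = c(5L, 12L),
                         latentStrengthRange = c(0.6, 0.6),
                         nVariableSubunitsPerComplex = 0L,
                         variableVarianceMultiplier = 4,
                         variableLambdaShrink = 0,
                         sexEffectFractions = 0,
                         dietEffectFractions = 0,
                         stoichiometryEffects = NULL,
                         nBackgroundProteins = 500L,
                         nPathways = 10L, pathwaySizeRange = c(5L, 15L),
                         pathwayStrength = 0.2,
                         missingRate = 0.05, noiseSd = 0.3,
                         nDatasets = 1L, seed = 1L) {
  cfg <- list(nSamples = as.integer(nSamples),
              nComplexes = as.integer(nComplexes),
              complexSizeRange = as.integer(complexSizeRange),
              latentStrengthRange = as.numeric(latentStrengthRange),
              nVariableSubunitsPerComplex =
                as.integer(nVariableSubunitsPerComplex),
              variableVarianceMultiplier = variableVarianceMultiplier,
              variableLambdaShrink = variableLambdaShrink,
              sexEffectFractions = rep_len(sexEffectFractions, nComplexes),
              dietEffectFractions = rep_len(dietEffectFractions, nComplexes),
              stoichiometryEffects = stoichiometryEffects,
              nBackgroundProteins = as.integer(nBackgroundProteins),
              nPathways = as.integer(nPathways),
              pathwaySizeRange = as.integer(pathwaySizeRange),
              pathwayStrength = pathwayStrength,
              missingRate = missingRate, noiseSd = noiseSd,
              nDatasets = as.integer(nDatasets), seed = as.integer(seed))
  stopifnot(cfg$nSamples >= 4L, cfg$nComplexes >= 1L,
            cfg$complexSizeRange[1L] >= 2L,
            cfg$complexSizeRange[1L] <= cfg$complexSizeRange[2L],
            all(cfg$latentStrengthRange >= 0),
            all(cfg$latentStrengthRange < 1),
            cfg$variableVarianceMultiplier >= 1,
            cfg$variableLambdaShrink >= 0, cfg$variableLambdaShrink <= 1,
            cfg$missingRate >= 0, cfg$missingRate < 1, cfg$noiseSd > 0,
            cfg$nDatasets >= 1L)
  if (any(cfg$sexEffectFractions < 0) || any(cfg$dietEffectFractions < 0) ||
      any(cfg$sexEffectFractions + cfg$dietEffectFractions >= 1))
    stop("infeasible variance budget: per-complex sex + diet fractions ",
         "must be >= 0 and sum below 1")
  se <- cfg$stoichiometryEffects
  if (!is.null(se)) {
    if (!all(c("complex", "subunit", "factor", "shift") %in% names(se)))
      stop("stoichiometryEffects needs columns complex, subunit, factor, shift")
    if (!all(se$factor %in% c("sex", "diet")))
      stop("stoichiometryEffects factor must be \"sex\" or \"diet\"")
  }
  class(cfg) <- "CohortConfig"
  cfg
}

# Fixed architecture shared by all replicate datasets: sample labels, module
# definitions and per-protein generative parameters. Seeded by cfg$seed so
# generateCohort() and plantedR2() agree on the planted structure.
.cohortArchitecture <- function(cfg) {
  restore <- .localSeed(cfg$seed)
  on.exit(restore(), add = TRUE)
  n <- cfg$nSamples
  half <- n %/% 2L
  sex <- rep(c("female", "male"), c(half, n - half))
  diet <- unlist(lapply(c(half, n - half), function(k)
    rep(c("chow", "high_fat"), c(k %/% 2L, k - k %/% 2L))))
  samples <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                        sex = sex, diet = diet, stringsAsFactors = FALSE)
  sexc <- ifelse(sex == "male", 0.5, -0.5)      # centered +/-0.5 codes
  dietc <- ifelse(diet == "high_fat", 0.5, -0.5)

  mkModules <- function(nMod, sizeRange, prefix, strengths) {
    sizeChoices <- seq(sizeRange[1L], sizeRange[2L])
    sizes <- if (nMod) sizeChoices[sample.int(length(sizeChoices), nMod,
                                              replace = TRUE)] else integer()
    lapply(seq_len(nMod), function(i) {
      k <- sizes[i]
      list(module_id = sprintf("%s%03d", prefix, i),
           proteins = sprintf("%s%03d_P%02d", prefix, i, seq_len(k)),
           strength = strengths[i], size = k)
    })
  }
  L <- if (cfg$nComplexes > 1L)
    seq(cfg$latentStrengthRange[1L], cfg$latentStrengthRange[2L],
        length.out = cfg$nComplexes) else mean(cfg$latentStrengthRange)
  complexes <- mkModules(cfg$nComplexes, cfg$complexSizeRange, "CPX", L)
  pathways <- mkModules(cfg$nPathways, cfg$pathwaySizeRange, "PWY",
                        rep(cfg$pathwayStrength, cfg$nPathways))

  sigma <- cfg$noiseSd
  subunitParams <- function(mod, idx, sexFrac = 0, dietFrac = 0) {
    k <- mod$size
    Lc <- mod$strength
    lambda <- if (Lc > 0) sigma * sqrt(Lc / (1 - Lc)) else 0
    varIdx <- integer()
    if (idx <= cfg$nComplexes && cfg$nVariableSubunitsPerComplex > 0L)
      varIdx <- sample(k, min(cfg$nVariableSubunitsPerComplex, k))
    lam <- rep(lambda, k); sd <- rep(sigma, k)
    lam[varIdx] <- lam[varIdx] * cfg$variableLambdaShrink
    sd[varIdx] <- sd[varIdx] * sqrt(cfg$variableVarianceMultiplier)
    data.frame(module_id = mod$module_id, protein_id = mod$proteins,
               mu = stats::rnorm(k, 25, 2), lambda = lam, sd = sd,
               variable = seq_len(k) %in% varIdx,
               sex_shift = 0, diet_shift = 0,
               sex_fraction = sexFrac, diet_fraction = dietFrac,
               stringsAsFactors = FALSE)
  }
  cpxPar <- do.call(rbind, lapply(seq_along(complexes), function(i)
    subunitParams(complexes[[i]], i, cfg$sexEffectFractions[i],
                  cfg$dietEffectFractions[i])))
  pwyPar <- if (length(pathways))
    do.call(rbind, lapply(seq_along(pathways), function(i)
      subunitParams(pathways[[i]], cfg$nComplexes + i))) else NULL
  se <- cfg$stoichiometryEffects
  if (!is.null(se)) {
    for (r in seq_len(nrow(se))) {
      mod <- complexes[[se$complex[r]]]
      row <- which(cpxPar$module_id == mod$module_id)[se$subunit[r]]
      col <- paste0(se$factor[r], "_shift")
      cpxPar[row, col] <- cpxPar[row, col] + se$shift[r]
    }
  }
  bgSd <- sqrt(mean(cpxPar$lambda^2) + sigma^2)   # match subunit marginals
  bgPar <- if (cfg$nBackgroundProteins)
    data.frame(protein_id = sprintf("BG%05d",
                                    seq_len(cfg$nBackgroundProteins)),
               mu = stats::rnorm(cfg$nBackgroundProteins, 25, 2),
               sd = bgSd, stringsAsFactors = FALSE) else NULL
  list(samples = samples, sexc = sexc, dietc = dietc,
       complexes = complexes, pathways = pathways,
       cpxPar = cpxPar, pwyPar = pwyPar, bgPar = bgPar)
}

# Draw one dataset's log2 matrix from the architecture (RNG state is the
# caller's responsibility).
.drawDataset <- function(arch, cfg, nSamples = cfg$nSamples,
                         sexc = arch$sexc, dietc = arch$dietc) {
  drawModuleBlock <- function(mod, par, sexFrac = 0, dietFrac = 0) {
    a <- 2 * sqrt(sexFrac); b <- 2 * sqrt(dietFrac)   # Var(codes) = 1/4
    eta <- stats::rnorm(nSamples, 0, sqrt(1 - sexFrac - dietFrac))
    f <- a * sexc + b * dietc + eta                    # Var(f) = 1
    rows <- lapply(seq_along(mod$proteins), function(j) {
      p <- par[par$protein_id == mod$proteins[j], ]
      p$mu + p$lambda * f +
        p$sex_shift * (sexc + 0.5) + p$diet_shift * (dietc + 0.5) +
        stats::rnorm(nSamples, 0, p$sd)
    })
    m <- do.call(rbind, rows)
    rownames(m) <- mod$proteins
    m
  }
  blocks <- c(
    lapply(seq_along(arch$complexes), function(i)
      drawModuleBlock(arch$complexes[[i]],
                      arch$cpxPar[arch$cpxPar$module_id ==
                                  arch$complexes[[i]]$module_id, ],
                      cfg$sexEffectFractions[i], cfg$dietEffectFractions[i])),
    lapply(arch$pathways, function(mod)
      drawModuleBlock(mod, arch$pwyPar[arch$pwyPar$module_id ==
                                       mod$module_id, ]))
  )
  if (!is.null(arch$bgPar)) {
    bg <- arch$bgPar$mu +
      matrix(stats::rnorm(nrow(arch$bgPar) * nSamples, 0, arch$bgPar$sd[1L]),
             nrow(arch$bgPar), nSamples)
    rownames(bg) <- arch$bgPar$protein_id
    blocks <- c(blocks, list(bg))
  }
  m <- do.call(rbind, blocks)
  colnames(m) <- arch$samples$sample_id[seq_len(nSamples)]
  if (cfg$missingRate > 0)
    m[stats::runif(length(m)) < cfg$missingRate] <- NA_real_
  m
}

#' Generate a synthetic multi-dataset proteome cohort
#'
#' Draws the cohort defined by a \code{\link{cohortConfig}}: one log2-scale
#' \linkS4class{AbundanceSet} per replicate dataset (shared planted
#' architecture, independent latent-factor and residual noise and dropout),
#' sample metadata, complex and pathway catalogs, an interaction table
#' (within-complex pairs at combined score 0.9 plus an equal number of decoy
#' background pairs at 0.1), and the planted ground truth.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return list with elements \code{datasets} (list of
#'   \linkS4class{AbundanceSet}), \code{metadata} (data.frame),
#'   \code{complexes} and \code{pathways} (\linkS4class{ModuleCatalog}),
#'   \code{interactions} (\linkS4class{InteractionTable}) and
#'   \code{groundTruth} (list of data.frames: \code{complexes},
#'   \code{subunits}, \code{pathways}).
#' @examples
#' sim <- generateCohort(cohortConfig(nSamples = 40, nComplexes = 5,
#'                                    nBackgroundProteins = 50, seed = 7))
#' sim$datasets[[1]]
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  arch <- .cohortArchitecture(config)
  restore <- .localSeed(config$seed + 1L)
  on.exit(restore(), add = TRUE)
  datasets <- lapply(seq_len(config$nDatasets), function(d) {
    AbundanceSet(.drawDataset(arch, config),
                 datasetId = sprintf("synthetic_d%02d", d), scale = "log2",
                 colData = arch$samples[, c("sex", "diet")])
  })
  complexes <- ModuleCatalog(
    stats::setNames(lapply(arch$complexes, `[[`, "proteins"),
                    vapply(arch$complexes, `[[`, "", "module_id")),
    category = "complex")
  pathways <- if (length(arch$pathways))
    ModuleCatalog(
      stats::setNames(lapply(arch$pathways, `[[`, "proteins"),
                      vapply(arch$pathways, `[[`, "", "module_id")),
      category = "pathway") else NULL
  pos <- do.call(rbind, lapply(arch$complexes, function(mod) {
    if (mod$size < 2L) return(NULL)
    cmb <- utils::combn(mod$proteins, 2L)
    data.frame(protein1 = cmb[1L, ], protein2 = cmb[2L, ],
               stringsAsFactors = FALSE)
  }))
  decoyPool <- if (!is.null(arch$bgPar)) arch$bgPar$protein_id else character()
  nDecoy <- if (length(decoyPool) >= 2L) nrow(pos) else 0L
  dec <- if (nDecoy) {
    d1 <- sample(decoyPool, nDecoy, replace = TRUE)
    d2 <- sample(decoyPool, nDecoy, replace = TRUE)
    keep <- d1 != d2
    data.frame(protein1 = d1[keep], protein2 = d2[keep],
               stringsAsFactors = FALSE)
  } else NULL
  interactions <- InteractionTable(
    c(pos$protein1, dec$protein1), c(pos$protein2, dec$protein2),
    c(rep(0.9, nrow(pos)), rep(0.1, if (is.null(dec)) 0L else nrow(dec))))
  groundTruth <- list(
    complexes = unique(arch$cpxPar[, c("module_id", "sex_fraction",
                                       "diet_fraction")]) |>
      merge(data.frame(module_id = vapply(arch$complexes, `[[`, "",
                                          "module_id"),
                       latent_strength = vapply(arch$complexes, `[[`, 0,
                                                "strength"))),
    subunits = arch$cpxPar[, c("module_id", "protein_id", "variable",
                               "sex_shift", "diet_shift")],
    pathways = if (length(arch$pathways))
      data.frame(module_id = vapply(arch$pathways, `[[`, "", "module_id"),
                 strength = vapply(arch$pathways, `[[`, 0, "strength"))
      else data.frame(module_id = character(), strength = numeric()))
  list(datasets = datasets, metadata = arch$samples, complexes = complexes,
       pathways = pathways, interactions = interactions,
       groundTruth = groundTruth)
}

#' Theoretical variance fraction planted on a module's abundance response
#'
#' Numeric oracle for effect-size recovery: simulates a large virtual cohort
#' (default n = 100000) from the same generative components as
#' \code{\link{generateCohort}}, computes the module's median-abundance
#' response per virtual sample, and returns the fraction of its variance
#' explained by the requested predictor set (population OLS R-squared).
#'
#' @param config the \code{\link{cohortConfig}} describing the cohort.
#' @param moduleId a complex id present in the config's architecture.
#' @param predictorSet \code{"sex"}, \code{"diet"} or \code{"sex_plus_diet"}.
#' @param nVirtual virtual cohort size.
#' @param seed seed for the virtual draw.
#' @return a single numeric variance fraction.
#' @export
plantedR2 <- function(config, moduleId,
                      predictorSet = c("sex", "diet", "sex_plus_diet"),
                      nVirtual = 100000L, seed = 1L) {
  predictorSet <- match.arg(predictorSet)
  arch <- .cohortArchitecture(config)
  idx <- which(vapply(arch$complexes, `[[`, "", "module_id") == moduleId)
  if (!length(idx)) stop("unknown module: ", moduleId)
  restore <- .localSeed(seed)
  on.exit(restore(), add = TRUE)
  sexc <- rep_len(c(-0.5, 0.5), nVirtual)
  dietc <- rep_len(c(-0.5, -0.5, 0.5, 0.5), nVirtual)
  mod <- arch$complexes[[idx]]
  par <- arch$cpxPar[arch$cpxPar$module_id == moduleId, ]
  sexFrac <- config$sexEffectFractions[idx]
  dietFrac <- config$dietEffectFractions[idx]
  f <- 2 * sqrt(sexFrac) * sexc + 2 * sqrt(dietFrac) * dietc +
    stats::rnorm(nVirtual, 0, sqrt(1 - sexFrac - dietFrac))
  block <- vapply(seq_len(nrow(par)), function(j)
    par$mu[j] + par$lambda[j] * f +
      par$sex_shift[j] * (sexc + 0.5) + par$diet_shift[j] * (dietc + 0.5) +
      stats::rnorm(nVirtual, 0, par$sd[j]),
    numeric(nVirtual))
  y <- apply(block, 1L, stats::median)
  X <- switch(predictorSet, sex = cbind(sexc), diet = cbind(dietc),
              sex_plus_diet = cbind(sexc, dietc))
  fit <- stats::lm.fit(cbind(1, X), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}
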