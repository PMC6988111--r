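#' @include AllClasses.R landscape.R stoichiometry.R covariates.R
NULL

#' Closed-form ridge regression with unpenalized intercept
#'
#' Solves (X'X + A) b = X'y where A puts the penalty \code{alpha} on every
#' slope and 0 on the intercept. Predictors are used as given (binary 0/1
#' dummies in this pipeline; no standardization).
#'
#' @param X numeric predictor matrix (no intercept column).
#' @param y numeric response.
#' @param alpha L2 penalty on the slopes (default 1).
#' @return list with \code{intercept}, \code{coef} (slopes) and
#'   \code{fitted}.
#' @examples
#' ridgeSolve(matrix(c(1, -1)), c(1, -1), alpha = 1)$coef   # 2/3
#' @export
ridgeSolve <- function(X, y, alpha = 1) {
  X <- as.matrix(X)
  stopifnot(alpha > 0, nrow(X) == length(y))
  X1 <- cbind(1, X)
  A <- diag(c(0, rep(alpha, ncol(X))), ncol(X1))
  b <- solve(crossprod(X1) + A, crossprod(X1, y))
  list(intercept = b[1L], coef = b[-1L, , drop = TRUE],
       fitted = as.vector(X1 %*% b))
}

.predictorMatrix <- function(metadata, samples,
                             predictorSet = c("sex", "diet",
                                              "sex_plus_diet")) {
  predictorSet <- match.arg(predictorSet)
  cols <- switch(predictorSet, sex = "sex", diet = "diet",
                 sex_plus_diet = c("sex", "diet"))
  X <- vapply(cols, function(f)
    as.numeric(.checkFactor(metadata, samples, f)) - 1, numeric(length(samples)))
  X <- matrix(X, ncol = length(cols),
              dimnames = list(samples, cols))
  X
}

# Stratified fold assignment: shuffle within each predictor-level stratum
# and deal folds round-robin so every training set sees both levels.
.foldAssignment <- function(X, kFolds, maxTries = 100L) {
  strata <- apply(X, 1L, paste, collapse = "/")
  n <- nrow(X)
  for (try in seq_len(maxTries)) {
    fold <- integer(n)
    offset <- 0L
    for (s in unique(strata)) {
      idx <- sample(which(strata == s))
      fold[idx] <- ((seq_along(idx) + offset - 1L) %% kFolds) + 1L
      offset <- offset + length(idx)
    }
    ok <- all(vapply(seq_len(kFolds), function(k) {
      tr <- X[fold != k, , drop = FALSE]
      nrow(tr) > 0L && all(apply(tr, 2L, function(v) length(unique(v)) > 1L))
    }, NA))
    if (ok) return(fold)
  }
  stop("could not build folds with both predictor levels in every ",
       "training set after ", maxTries, " tries")
}

#' Cross-validated global R-squared of a ridge model
#'
#' Effect size of a predictor set on one or more sample-indexed responses:
#' for each of \code{nRepeats} seeded stratified fold assignments, a ridge
#' model (\code{\link{ridgeSolve}}, penalty \code{alpha} on the binary
#' sex/diet dummies) is trained on k-1 folds and used to predict the
#' held-out fold; the global R-squared = 1 - SS_res/SS_tot is computed on
#' the pooled out-of-fold predictions. The reported value is the median
#' over repeats, and additionally the median over response vectors when
#' \code{responses} is a matrix (e.g. the complex-normalized subunit
#' vectors of a stoichiometry readout). Negative values are reported as-is.
#'
#' @param responses named numeric vector (one response; names = sample ids)
#'   or matrix with sample columns (one response per row).
#' @param metadata data.frame with \code{sample_id}, \code{sex},
#'   \code{diet}.
#' @param predictorSet \code{"sex"}, \code{"diet"} or
#'   \code{"sex_plus_diet"}.
#' @param alpha ridge penalty (default 1).
#' @param kFolds number of folds (default 10).
#' @param nRepeats repeated fold assignments (default 5).
#' @param seed integer seed.
#' @return the median global R-squared (single numeric).
#' @export
ridgeCvR2 <- function(responses, metadata,
                      predictorSet = c("sex", "diet", "sex_plus_diet"),
                      alpha = 1, kFolds = 10L, nRepeats = 5L, seed = 1L) {
  predictorSet <- match.arg(predictorSet)
  if (is.null(dim(responses)))
    responses <- matrix(responses, 1L,
                        dimnames = list("y", names(responses)))
  Xall <- .predictorMatrix(metadata, colnames(responses), predictorSet)
  restore <- .localSeed(seed)
  on.exit(restore(), add = TRUE)
  perResponse <- apply(responses, 1L, function(y) {
    ok <- !is.na(y) & stats::complete.cases(Xall)
    y <- y[ok]
    X <- Xall[ok, , drop = FALSE]
    if (length(y) < 2L * kFolds || stats::var(y) == 0) return(NA_real_)
    r2 <- vapply(seq_len(nRepeats), function(rep) {
      fold <- .foldAssignment(X, kFolds)
      pred <- numeric(length(y))
      for (k in seq_len(kFolds)) {
        tr <- fold != k
        fit <- ridgeSolve(X[tr, , drop = FALSE], y[tr], alpha)
        pred[fold == k] <- fit$intercept +
          X[fold == k, , drop = FALSE] %*% matrix(fit$coef)
      }
      1 - sum((y - pred)^2) / sum((y - mean(y))^2)
    }, 0)
    stats::median(r2)
  })
  stats::median(perResponse, na.rm = TRUE)
}

#' Permutation-based empirical FDR for ridge effect sizes
#'
#' Re-runs the full cross-validated ridge analysis on predictor labels
#' permuted across samples \code{nPerm} times per module, yielding the
#' plus-one empirical p-value (1 + #null R2 >= observed)/(1 + nPerm),
#' Benjamini-Hochberg adjusted across modules.
#'
#' @param responsesList named list of responses (vector or matrix), one per
#'   module.
#' @param metadata,predictorSet,alpha,kFolds,nRepeats see
#'   \code{\link{ridgeCvR2}}.
#' @param nPerm permutations per module (>= 100 recommended for a usable
#'   FDR floor).
#' @param seed integer seed.
#' @return data.frame: \code{module_id}, \code{r2}, \code{empirical_p},
#'   \code{fdr_q}.
#' @export
permutationFdr <- function(responsesList, metadata, predictorSet,
                           alpha = 1, kFolds = 10L, nRepeats = 5L,
                           nPerm = 200L, seed = 1L) {
  stopifnot(nPerm >= 1L)
  ids <- names(responsesList)
  rows <- lapply(seq_along(responsesList), function(i) {
    obs <- ridgeCvR2(responsesList[[i]], metadata, predictorSet, alpha,
                     kFolds, nRepeats, seed = seed + 31L * i)
    nullR2 <- vapply(seq_len(nPerm), function(p) {
      restore <- .localSeed(seed + 31L * i + 1000003L * p)
      perm <- sample(nrow(metadata))
      restore()
      md <- metadata
      md$sample_id <- metadata$sample_id[perm]
      ridgeCvR2(responsesList[[i]], md, predictorSet, alpha, kFolds,
                nRepeats, seed = seed + 31L * i + 1000003L * p)
    }, 0)
    data.frame(module_id = ids[i], r2 = obs,
               empirical_p = (1 + sum(nullR2 >= obs)) / (1 + nPerm),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_q <- stats::p.adjust(out$empirical_p, "BH")
  out
}

#' Pre-filter pathways by co-abundance against a reshuffled null
#'
#' Keeps pathways whose median pairwise co-abundance exceeds what
#' within-protein permutation of the dataset produces: per pathway, the
#' plus-one empirical p-value of the observed median r against \code{nPerm}
#' permuted recomputations, BH-adjusted, retained at q < \code{qThreshold}.
#'
#' @param x a log2-scale \linkS4class{AbundanceSet}.
#' @param pathways pathway \linkS4class{ModuleCatalog}.
#' @param nPerm permutation rounds (> 0).
#' @param seed integer seed.
#' @param qThreshold retention cutoff (default 0.1).
#' @param minMembers,minOverlap forwarded to
#'   \code{\link{complexMedianCoabundance}}.
#' @return list: \code{catalog} (retained \linkS4class{ModuleCatalog}, or
#'   NULL when none pass), \code{table} (per-pathway median r, empirical_p,
#'   q, retained).
#' @export
selectCoabundantPathways <- function(x, pathways, nPerm = 100L, seed = 1L,
                                     qThreshold = 0.1, minMembers = 5L,
                                     minOverlap = 6L) {
  if (nPerm < 1L) stop("nPerm must be >= 1")
  obs <- complexMedianCoabundance(x, pathways, minMembers, minOverlap)
  nullR <- matrix(NA_real_, nrow(obs), nPerm,
                  dimnames = list(obs$module_id, NULL))
  for (p in seq_len(nPerm)) {
    perm <- permuteWithinProtein(x, seed = seed + 7907L * p)
    tab <- complexMedianCoabundance(perm, pathways, minMembers, minOverlap)
    nullR[tab$module_id, p] <- tab$median_r
  }
  empP <- vapply(seq_len(nrow(obs)), function(i) {
    nn <- nullR[obs$module_id[i], ]
    nn <- nn[!is.na(nn)]
    (1 + sum(nn >= obs$median_r[i])) / (1 + length(nn))
  }, 0)
  tab <- data.frame(module_id = obs$module_id, median_r = obs$median_r,
                    empirical_p = empP,
                    q_value = stats::p.adjust(empP, "BH"),
                    stringsAsFactors = FALSE)
  tab$retained <- tab$q_value < qThreshold
  kept <- tab$module_id[tab$retained]
  catalog <- if (length(kept))
    ModuleCatalog(moduleMembers(pathways)[kept], category = "pathway")
    else NULL
  list(catalog = catalog, table = tab)
}

#' Effect-size grid: modules x predictor sets x readouts
#'
#' Builds the full table of cross-validated ridge effect sizes: for each
#' complex (and optionally each co-abundance-selected pathway), the
#' variance of its median abundance and of its complex-normalized subunit
#' stoichiometry explained by sex, diet, and sex + diet; optionally also
#' per-protein abundance records. Permutation FDR is attached when
#' \code{nPerm > 0}.
#'
#' @param x a log2-scale \linkS4class{AbundanceSet} whose \code{colData}
#'   or \code{metadata} carries sex/diet.
#' @param complexes complex \linkS4class{ModuleCatalog}.
#' @param metadata data.frame with \code{sample_id}, \code{sex},
#'   \code{diet}.
#' @param pathways optional pathway \linkS4class{ModuleCatalog}, filtered
#'   through \code{\link{selectCoabundantPathways}} first.
#' @param includeProteins also produce per-protein abundance records
#'   (readout \code{"protein"}).
#' @param alpha,kFolds,nRepeats ridge/CV parameters (defaults 1, 10, 5).
#' @param nPerm permutations for the empirical FDR (0 = skip).
#' @param nPermPathway permutations for the pathway pre-filter.
#' @param trim,minMembers normalization parameters.
#' @param seed integer seed.
#' @return list: \code{records} (module_id, readout, predictor_set, r2 and,
#'   with \code{nPerm > 0}, empirical_p, fdr_q), \code{summary} (median r2
#'   and median variance-explained percent per readout x predictor set,
#'   over modules).
#' @export
effectSizeTable <- function(x, complexes, metadata, pathways = NULL,
                            includeProteins = FALSE, alpha = 1,
                            kFolds = 10L, nRepeats = 5L, nPerm = 0L,
                            nPermPathway = 100L, trim = 0.25,
                            minMembers = 5L, seed = 1L) {
  predictorSets <- c("sex", "diet", "sex_plus_diet")
  responses <- list(abundance = list(), stoichiometry = list(),
                    protein = list())
  med <- complexMedianAbundance(x, complexes, minSubunits = minMembers)
  for (id in rownames(med)) responses$abundance[[id]] <- med[id, ]
  prof <- complexNormalize(x, complexes, trim = trim,
                           minMembers = minMembers)
  for (id in names(complexProfiles(prof)))
    responses$stoichiometry[[id]] <- complexProfiles(prof)[[id]]
  if (!is.null(pathways)) {
    sel <- selectCoabundantPathways(x, pathways, nPerm = nPermPathway,
                                    seed = seed, minMembers = minMembers)
    if (!is.null(sel$catalog)) {
      pmed <- complexMedianAbundance(x, sel$catalog,
                                     minSubunits = minMembers)
      for (id in rownames(pmed)) responses$abundance[[id]] <- pmed[id, ]
      pprof <- complexNormalize(x, sel$catalog, trim = trim,
                                minMembers = minMembers)
      for (id in names(complexProfiles(pprof)))
        responses$stoichiometry[[id]] <- complexProfiles(pprof)[[id]]
    }
  }
  if (includeProteins) {
    m <- abundances(x)
    for (p in rownames(m)) responses$protein[[p]] <- m[p, ]
  }
  records <- list()
  for (readout in names(responses)) {
    if (!length(responses[[readout]])) next
    for (ps in predictorSets) {
      if (nPerm > 0L) {
        tab <- permutationFdr(responses[[readout]], metadata, ps,
                              alpha, kFolds, nRepeats, nPerm,
                              seed = seed + match(ps, predictorSets))
        tab$readout <- readout; tab$predictor_set <- ps
      } else {
        tab <- do.call(rbind, lapply(names(responses[[readout]]),
                                     function(id) {
          data.frame(module_id = id, readout = readout,
                     predictor_set = ps,
                     r2 = ridgeCvR2(responses[[readout]][[id]], metadata,
                                    ps, alpha, kFolds, nRepeats,
                                    seed = seed +
                                      match(ps, predictorSets)),
                     stringsAsFactors = FALSE)
        }))
      }
      records[[length(records) + 1L]] <- tab
    }
  }
  records <- do.call(rbind, lapply(records, function(d)
    d[, intersect(c("module_id", "readout", "predictor_set", "r2",
                    "empirical_p", "fdr_q"), names(d)), drop = FALSE]))
  rownames(records) <- NULL
  summary <- do.call(rbind, lapply(
    split(records, paste(records$readout, records$predictor_set)),
    function(d) data.frame(
      readout = d$readout[1L], predictor_set = d$predictor_set[1L],
      n_modules = nrow(d), median_r2 = stats::median(d$r2, na.rm = TRUE),
      median_pct_explained =
        100 * stats::median(pmax(d$r2, 0), na.rm = TRUE),
      stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  list(records = records, summary = summary)
}
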