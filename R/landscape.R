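#' @include AllClasses.R recovery.R
NULL

#' Median within-complex co-abundance, ranked within a dataset
#'
#' For each complex with at least \code{minMembers} quantified members,
#' computes the median of all pairwise Pearson correlations among its
#' quantified members (jointly non-missing samples, \code{minOverlap} rule),
#' then ranks complexes within the dataset by descending median co-abundance.
#' \code{rank_fraction} = rank / number of qualifying complexes normalizes
#' ranks across datasets with different catalogs; ties get average ranks.
#'
#' @param x a log2-scale \linkS4class{AbundanceSet}.
#' @param catalog a complex \linkS4class{ModuleCatalog}.
#' @param minMembers minimum quantified members per complex (default 5).
#' @param minOverlap minimum jointly quantified samples per pair.
#' @return data.frame: \code{dataset_id}, \code{module_id},
#'   \code{n_members_quantified}, \code{median_r}, \code{rank},
#'   \code{rank_fraction}.
#' @export
complexMedianCoabundance <- function(x, catalog, minMembers = 5L,
                                     minOverlap = 6L) {
  m <- abundances(x)
  rows <- lapply(names(moduleMembers(catalog)), function(id) {
    mem <- intersect(moduleMembers(catalog)[[id]], rownames(m))
    if (length(mem) < minMembers) return(NULL)
    cmb <- utils::combn(mem, 2L)
    rs <- pairwiseCorrelations(x, t(cmb), minOverlap)$r
    if (!length(rs)) return(NULL)
    data.frame(dataset_id = datasetId(x), module_id = id,
               n_members_quantified = length(mem),
               median_r = stats::median(rs), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no complex qualifies (minMembers = ", minMembers, ")")
  out$rank <- rank(-out$median_r, ties.method = "average")
  out$rank_fraction <- out$rank / nrow(out)
  out[order(out$rank), , drop = FALSE]
}

#' Aggregate per-dataset complex co-abundance ranks into the landscape
#'
#' Takes each complex's median \code{rank_fraction} across the datasets in
#' which it qualifies and classifies the top quartile (highest co-abundance,
#' lowest rank fraction) as \code{stable}, the bottom quartile as
#' \code{variable}, the rest \code{intermediate}. Quartile thresholds are
#' computed on the aggregated landscape. Complexes qualifying in fewer than
#' 2 datasets are reported with class \code{NA}. The result is invariant to
#' the order of the input datasets.
#'
#' @param perDataset list of \code{\link{complexMedianCoabundance}} tables.
#' @return data.frame: \code{module_id}, \code{n_datasets},
#'   \code{median_rank_fraction}, \code{median_r}, \code{class}.
#' @export
aggregateLandscape <- function(perDataset) {
  if (length(perDataset) < 2L) stop("need >= 2 datasets to aggregate")
  all <- do.call(rbind, perDataset)
  agg <- do.call(rbind, lapply(split(all, all$module_id), function(d) {
    data.frame(module_id = d$module_id[1L], n_datasets = nrow(d),
               median_rank_fraction = stats::median(d$rank_fraction),
               median_r = stats::median(d$median_r),
               stringsAsFactors = FALSE)
  }))
  agg$class <- NA_character_
  ok <- agg$n_datasets >= 2L
  if (any(ok)) {
    q <- stats::quantile(agg$median_rank_fraction[ok], c(0.25, 0.75))
    cls <- rep("intermediate", sum(ok))
    cls[agg$median_rank_fraction[ok] <= q[[1L]]] <- "stable"
    cls[agg$median_rank_fraction[ok] >= q[[2L]]] <- "variable"
    agg$class[ok] <- cls
  }
  rownames(agg) <- NULL
  agg[order(agg$median_rank_fraction), , drop = FALSE]
}

#' Size-matched decoy complexes from module-free proteins
#'
#' Builds one artificial complex per real complex, with the same size
#' distribution, drawing members only from quantified proteins that belong
#' to no real complex. When the module-free pool is too small to fill all
#' decoys without reuse, members are reused across decoys (never within one)
#' with a warning.
#'
#' @param x an \linkS4class{AbundanceSet} (defines the quantified universe).
#' @param catalog the real complex \linkS4class{ModuleCatalog}.
#' @param seed integer seed.
#' @return a decoy \linkS4class{ModuleCatalog} (category \code{complex},
#'   module ids prefixed \code{DECOY_}).
#' @export
decoyComplexes <- function(x, catalog, seed = 1L) {
  pool <- setdiff(rownames(x), unlist(moduleMembers(catalog)))
  sizes <- lengths(moduleMembers(catalog))
  if (max(sizes) > length(pool))
    stop("module-free pool smaller than the largest complex")
  restore <- .localSeed(seed)
  on.exit(restore(), add = TRUE)
  withReplacement <- sum(sizes) > length(pool)
  if (withReplacement)
    warning("module-free pool smaller than total decoy membership; ",
            "reusing proteins across decoys")
  remaining <- sample(pool)
  members <- lapply(seq_along(sizes), function(i) {
    if (withReplacement) return(sample(pool, sizes[i]))
    picked <- remaining[seq_len(sizes[i])]
    remaining <<- remaining[-seq_len(sizes[i])]
    picked
  })
  names(members) <- paste0("DECOY_", names(moduleMembers(catalog)))
  ModuleCatalog(members, category = "complex")
}

#' Permute each protein's values across samples
#'
#' Independently shuffles every row (missing entries shuffled along with
#' values), destroying all inter-protein correlation while preserving each
#' protein's marginal distribution and missingness count. This is the
#' permutation null used by the landscape and z-score consistency tests.
#'
#' @param x an \linkS4class{AbundanceSet}.
#' @param seed integer seed.
#' @return the permuted \linkS4class{AbundanceSet}.
#' @export
permuteWithinProtein <- function(x, seed = 1L) {
  m <- abundances(x)
  restore <- .localSeed(seed)
  on.exit(restore(), add = TRUE)
  for (i in seq_len(nrow(m))) m[i, ] <- m[i, sample.int(ncol(m))]
  AbundanceSet(m, datasetId = datasetId(x), scale = abundanceScale(x),
               colData = colData(x))
}

#' Cross-dataset consistency of the complex co-abundance landscape
#'
#' Computes the pairwise Spearman correlation of complex co-abundance ranks
#' between datasets, and compares the observed correlations (two-sided t
#' test) to a null distribution obtained by within-protein permutation of
#' every dataset followed by re-ranking, repeated \code{nPerm} times.
#'
#' @param datasets list (>= 2) of log2-scale \linkS4class{AbundanceSet}s.
#' @param catalog complex \linkS4class{ModuleCatalog}.
#' @param nPerm number of permutation rounds (default 1000).
#' @param seed integer seed.
#' @param minMembers,minOverlap forwarded to
#'   \code{\link{complexMedianCoabundance}}.
#' @return list: \code{rho} (observed pairwise Spearman values),
#'   \code{meanRho}, \code{nullRho} (all null values), \code{p} (two-sided
#'   t comparing observed to null).
#' @export
landscapeConsistency <- function(datasets, catalog, nPerm = 1000L, seed = 1L,
                                 minMembers = 5L, minOverlap = 6L) {
  if (length(datasets) < 2L) stop("need >= 2 datasets")
  rankVectors <- function(ds) lapply(ds, function(d) {
    tab <- complexMedianCoabundance(d, catalog, minMembers, minOverlap)
    stats::setNames(tab$rank_fraction, tab$module_id)
  })
  pairRho <- function(rv) {
    idx <- utils::combn(length(rv), 2L)
    vapply(seq_len(ncol(idx)), function(k) {
      a <- rv[[idx[1L, k]]]; b <- rv[[idx[2L, k]]]
      shared <- intersect(names(a), names(b))
      if (length(shared) < 3L) return(NA_real_)
      stats::cor(a[shared], b[shared], method = "spearman")
    }, 0)
  }
  obs <- pairRho(rankVectors(datasets))
  nullRho <- unlist(lapply(seq_len(nPerm), function(p) {
    perm <- lapply(seq_along(datasets), function(i)
      permuteWithinProtein(datasets[[i]], seed = seed + 7919L * p + i))
    pairRho(rankVectors(perm))
  }))
  obs <- obs[!is.na(obs)]; nullRho <- nullRho[!is.na(nullRho)]
  p <- if (length(obs) >= 2L)
    stats::t.test(obs, nullRho)$p.value
  else stats::t.test(nullRho, mu = obs)$p.value
  list(rho = obs, meanRho = mean(obs), nullRho = nullRho, p = p)
}

#' Abundance/variance bias diagnostic for complex co-abundance
#'
#' Checks whether median within-complex co-abundance depends on complex
#' abundance or variance: complexes are rank-sorted by median abundance
#' (and, separately, by median per-subunit variance), split into
#' \code{nBins} equal bins, and the per-bin distributions of median
#' co-abundance are compared by pairwise two-sided t tests.
#'
#' @param x a log2-scale \linkS4class{AbundanceSet}.
#' @param catalog complex \linkS4class{ModuleCatalog}.
#' @param nBins number of rank bins (default 4, i.e. 25\% bins).
#' @param minMembers,minOverlap forwarded to
#'   \code{\link{complexMedianCoabundance}}.
#' @return list: \code{perComplex} (complex, median_r, abundance/variance
#'   bins), \code{abundanceTests} and \code{varianceTests} (pairwise bin t
#'   tests: \code{bin_a}, \code{bin_b}, \code{p}).
#' @export
biasDiagnostic <- function(x, catalog, nBins = 4L, minMembers = 5L,
                           minOverlap = 6L) {
  tab <- complexMedianCoabundance(x, catalog, minMembers, minOverlap)
  if (nrow(tab) < 2L * nBins)
    stop("need >= ", 2L * nBins, " qualifying complexes")
  m <- abundances(x)
  stat <- vapply(tab$module_id, function(id) {
    mem <- intersect(moduleMembers(catalog)[[id]], rownames(m))
    vals <- m[mem, , drop = FALSE]
    c(stats::median(vals, na.rm = TRUE),
      stats::median(apply(vals, 1L, stats::var, na.rm = TRUE), na.rm = TRUE))
  }, numeric(2L))
  binOf <- function(v) {
    rk <- rank(v, ties.method = "first")
    as.integer(ceiling(rk * nBins / length(v)))
  }
  tab$abundance_bin <- binOf(stat[1L, ])
  tab$variance_bin <- binOf(stat[2L, ])
  binTests <- function(bins) {
    idx <- utils::combn(sort(unique(bins)), 2L)
    do.call(rbind, lapply(seq_len(ncol(idx)), function(k) {
      a <- tab$median_r[bins == idx[1L, k]]
      b <- tab$median_r[bins == idx[2L, k]]
      p <- if (length(a) >= 2L && length(b) >= 2L &&
               (stats::var(a) > 0 || stats::var(b) > 0))
        stats::t.test(a, b)$p.value else NA_real_
      data.frame(bin_a = idx[1L, k], bin_b = idx[2L, k], p = p)
    }))
  }
  list(perComplex = tab, abundanceTests = binTests(tab$abundance_bin),
       varianceTests = binTests(tab$variance_bin))
}
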