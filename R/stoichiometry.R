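#' @include AllClasses.R
NULL

# Symmetric trimmed (interquartile) mean: sort the k values, drop
# floor(trim*k) from each end, average the remainder.
.trimmedMean <- function(v, trim) {
  k <- length(v)
  d <- floor(trim * k)
  s <- sort(v)
  mean(s[seq.int(d + 1L, k - d)])
}

#' Module-wise (trimmed-mean) complex normalization
#'
#' Separates complex stoichiometry from complex abundance: in every sample,
#' each subunit's log2 abundance is normalized by (subtracted from) the
#' symmetric trimmed mean of the complex's quantified subunits in that
#' sample. Subtraction in log space corresponds to a ratio to the complex
#' reference in linear space, so the normalized values carry each subunit's
#' deviation from its complex's overall abundance. Samples in which fewer
#' than \code{minQuantifiedSubunits} subunits are quantified get a missing
#' reference (all subunits missing there). Proteins belonging to several
#' complexes receive, in the combined matrix, the average of their
#' complex-specific normalized values.
#'
#' @param x a log2-scale \linkS4class{AbundanceSet}.
#' @param catalog complex \linkS4class{ModuleCatalog}.
#' @param trim fraction trimmed from each end of the subunit values
#'   (default 0.25: interquartile mean).
#' @param minQuantifiedSubunits minimum quantified subunits per sample for a
#'   defined reference (default 3).
#' @param minMembers minimum quantified members for a complex to be
#'   normalized at all (default 5).
#' @return a \linkS4class{StoichiometryProfile} (z-scores not yet computed;
#'   see \code{\link{subunitVarianceZ}}).
#' @export
complexNormalize <- function(x, catalog, trim = 0.25,
                             minQuantifiedSubunits = 3L, minMembers = 5L) {
  if (abundanceScale(x) != "log2")
    stop("complexNormalize requires log2-scale data")
  stopifnot(trim >= 0, trim < 0.5)
  m <- abundances(x)
  perComplex <- list()
  for (id in names(moduleMembers(catalog))) {
    mem <- intersect(moduleMembers(catalog)[[id]], rownames(m))
    if (length(mem) < minMembers) next
    sub <- m[mem, , drop = FALSE]
    ref <- apply(sub, 2L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < minQuantifiedSubunits) NA_real_
      else .trimmedMean(v, trim)
    })
    perComplex[[id]] <- sweep(sub, 2L, ref, `-`)
  }
  if (!length(perComplex))
    stop("no complex with >= ", minMembers, " quantified members")
  proteins <- sort(unique(unlist(lapply(perComplex, rownames))))
  norm <- matrix(NA_real_, length(proteins), ncol(m),
                 dimnames = list(proteins, colnames(m)))
  cnt <- matrix(0L, length(proteins), ncol(m))
  for (pc in perComplex) {
    i <- match(rownames(pc), proteins)
    ok <- !is.na(pc)
    add <- pc; add[!ok] <- 0
    prev <- norm[i, , drop = FALSE]; prev[is.na(prev)] <- 0
    norm[i, ] <- prev + add
    cnt[i, ] <- cnt[i, ] + ok
  }
  norm <- norm / ifelse(cnt > 0L, cnt, NA_integer_)
  new("StoichiometryProfile", datasetId = datasetId(x), normalized = norm,
      perComplex = perComplex,
      zTable = data.frame(complex_id = character(), protein_id = character(),
                          variance = numeric(), z = numeric()))
}

#' Per-subunit variance z-scores after complex normalization
#'
#' Computes, per complex, the variance of each subunit's complex-normalized
#' values across samples and standardizes the variances to z-scores within
#' the complex (mean 0, sd 1 over its subunits; all z = 0 when the subunit
#' variances are identical). Subunits with complex-normalized values in
#' fewer than \code{minSampleFraction} of samples are excluded; complexes
#' with fewer than 3 eligible subunits are skipped.
#'
#' @param profile a \linkS4class{StoichiometryProfile}.
#' @param minSampleFraction required fraction of samples with a defined
#'   normalized value (default 0.5).
#' @return the profile with its \code{zTable} filled (columns
#'   \code{complex_id}, \code{protein_id}, \code{variance}, \code{z}).
#' @export
subunitVarianceZ <- function(profile, minSampleFraction = 0.5) {
  rows <- lapply(names(complexProfiles(profile)), function(id) {
    pc <- complexProfiles(profile)[[id]]
    eligible <- rowMeans(!is.na(pc)) >= minSampleFraction
    if (sum(eligible) < 3L) return(NULL)
    v <- apply(pc[eligible, , drop = FALSE], 1L, stats::var, na.rm = TRUE)
    s <- stats::sd(v)
    z <- if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    data.frame(complex_id = id, protein_id = names(v), variance = unname(v),
               z = unname(z), stringsAsFactors = FALSE)
  })
  zt <- do.call(rbind, rows)
  if (is.null(zt)) zt <- data.frame(complex_id = character(),
                                    protein_id = character(),
                                    variance = numeric(), z = numeric())
  initialize(profile, zTable = zt)
}

#' Stable/variable component calls within one dataset
#'
#' Labels each (complex, subunit) from its variance z-score using one-sided
#' standard-normal tail probabilities: \code{variable} when the upper-tail p
#' is at or below \code{alpha}, \code{stable} when the lower-tail p is,
#' otherwise \code{neutral}. A display label at |z| > \code{displayThreshold}
#' (default 1.5) is also emitted for figure-style output.
#'
#' @param profile a \linkS4class{StoichiometryProfile} with z-scores.
#' @param alpha one-sided tail level per direction (default 0.05).
#' @param displayThreshold |z| cutoff for the display label (default 1.5).
#' @return data.frame: \code{complex_id}, \code{protein_id}, \code{z},
#'   \code{p_upper}, \code{p_lower}, \code{label}, \code{display_label}.
#' @export
callComponentsWithinDataset <- function(profile, alpha = 0.05,
                                        displayThreshold = 1.5) {
  zt <- zTable(profile)
  if (!nrow(zt)) stop("profile has no z-scores; run subunitVarianceZ() first")
  pUp <- stats::pnorm(zt$z, lower.tail = FALSE)
  pLo <- stats::pnorm(zt$z)
  label <- rep("neutral", nrow(zt))
  label[pUp <= alpha] <- "variable"
  label[pLo <= alpha] <- "stable"
  disp <- rep("neutral", nrow(zt))
  disp[zt$z > displayThreshold] <- "variable"
  disp[zt$z < -displayThreshold] <- "stable"
  data.frame(zt[, c("complex_id", "protein_id", "z")], p_upper = pUp,
             p_lower = pLo, label = label, display_label = disp,
             stringsAsFactors = FALSE)
}

#' Cross-dataset variable-component test
#'
#' For every (complex, subunit) observed in at least 2 datasets, compares
#' the subunit's variance z-scores across datasets to the pooled z-scores of
#' all other subunits of the same complex across all datasets with a
#' one-sided Welch t test (alternative: greater, the variable direction),
#' then adjusts across all tested pairs by Benjamini-Hochberg.
#'
#' @param profiles list of \linkS4class{StoichiometryProfile}s with
#'   z-scores.
#' @param alpha q-value threshold for the \code{variable} label
#'   (default 0.05).
#' @return data.frame: \code{complex_id}, \code{protein_id},
#'   \code{n_datasets}, \code{mean_z}, \code{p_value}, \code{q_value},
#'   \code{label} (untested subunits carry NA p/q).
#' @export
crossDatasetComponentTest <- function(profiles, alpha = 0.05) {
  zt <- do.call(rbind, lapply(profiles, function(p) {
    z <- zTable(p); z$dataset_id <- datasetId(p); z
  }))
  if (is.null(zt) || !nrow(zt)) stop("no z-scores in the supplied profiles")
  out <- do.call(rbind, lapply(split(zt, zt$complex_id), function(cz) {
    do.call(rbind, lapply(split(cz, cz$protein_id), function(pz) {
      others <- cz$z[cz$protein_id != pz$protein_id[1L]]
      p <- if (nrow(pz) >= 2L && length(others) >= 2L)
        stats::t.test(pz$z, others, alternative = "greater")$p.value
      else NA_real_
      data.frame(complex_id = pz$complex_id[1L],
                 protein_id = pz$protein_id[1L], n_datasets = nrow(pz),
                 mean_z = mean(pz$z), p_value = p, stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out$q_value <- NA_real_
  tested <- !is.na(out$p_value)
  out$q_value[tested] <- stats::p.adjust(out$p_value[tested], "BH")
  out$label <- ifelse(!tested, NA_character_,
                      ifelse(out$q_value < alpha, "variable", "neutral"))
  out
}

#' Cross-dataset consistency of variance z-score matrices
#'
#' Matches (complex, subunit) z-scores between dataset pairs and computes
#' their Pearson correlation; the observed correlations are compared
#' (two-sided t test) to a null distribution built by permuting each
#' dataset's z-vector \code{nPerm} times. Dataset pairs sharing fewer than
#' \code{minShared} entries are skipped.
#'
#' @param profiles list of \linkS4class{StoichiometryProfile}s with
#'   z-scores.
#' @param nPerm permutation rounds (default 1000).
#' @param seed integer seed.
#' @param minShared minimum shared (complex, subunit) entries per pair
#'   (default 10).
#' @return list: \code{r} (observed pairwise correlations), \code{meanR},
#'   \code{nullR}, \code{p}.
#' @export
zscoreConsistency <- function(profiles, nPerm = 1000L, seed = 1L,
                              minShared = 10L) {
  if (length(profiles) < 2L) stop("need >= 2 profiles")
  vecs <- lapply(profiles, function(p) {
    zt <- zTable(p)
    stats::setNames(zt$z, paste(zt$complex_id, zt$protein_id, sep = "\r"))
  })
  idx <- utils::combn(length(vecs), 2L)
  shared <- lapply(seq_len(ncol(idx)), function(k)
    intersect(names(vecs[[idx[1L, k]]]), names(vecs[[idx[2L, k]]])))
  usable <- lengths(shared) >= minShared
  if (!any(usable)) stop("no dataset pair shares >= ", minShared, " entries")
  pairR <- function(vs) vapply(which(usable), function(k) {
    stats::cor(vs[[idx[1L, k]]][shared[[k]]], vs[[idx[2L, k]]][shared[[k]]])
  }, 0)
  obs <- pairR(vecs)
  restore <- .localSeed(seed)
  on.exit(restore(), add = TRUE)
  nullR <- unlist(lapply(seq_len(nPerm), function(p) {
    pairR(lapply(vecs, function(v) stats::setNames(sample(v), names(v))))
  }))
  p <- if (length(obs) >= 2L) stats::t.test(obs, nullR)$p.value
       else stats::t.test(nullR, mu = obs)$p.value
  list(r = obs, meanR = mean(obs), nullR = nullR, p = p)
}
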