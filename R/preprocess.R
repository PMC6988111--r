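#' @include AllClasses.R
NULL

#' Per-sample Shapiro-Wilk normality assessment
#'
#' Tests each sample's non-missing abundance values for deviation from
#' normality. Samples with more than \code{maxN} values are subsampled
#' (seeded) to stay within the test's supported range; samples with fewer
#' than 3 values are flagged untested.
#'
#' @param x an \linkS4class{AbundanceSet}.
#' @param maxN subsample size cap for the test (Shapiro-Wilk supports at most
#'   5000 values).
#' @param seed integer seed for the subsampling.
#' @return data.frame with columns \code{sample_id}, \code{n},
#'   \code{shapiro_w}, \code{p_value}, \code{tested}.
#' @export
assessNormality <- function(x, maxN = 5000L, seed = 1L) {
  m <- abundances(x)
  rng <- .localSeed(seed)
  out <- lapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    v <- v[!is.na(v)]
    if (length(v) < 3L)
      return(data.frame(sample_id = colnames(m)[j], n = length(v),
                        shapiro_w = NA_real_, p_value = NA_real_,
                        tested = FALSE))
    if (length(v) > maxN) v <- sample(v, maxN)
    sw <- stats::shapiro.test(v)
    data.frame(sample_id = colnames(m)[j], n = length(v),
               shapiro_w = unname(sw$statistic), p_value = sw$p.value,
               tested = TRUE)
  })
  on.exit(rng(), add = TRUE)
  do.call(rbind, out)
}

#' Log2 transform and quantile-normalize an abundance matrix
#'
#' Linear-scale input is log2-transformed first (log2 throughout the
#' pipeline, compatible with log2 fold-change reporting); log2 input skips
#' the transform. Quantile normalization then replaces each sample's k-th
#' smallest non-missing value by the mean k-th smallest value across samples,
#' with reference quantiles interpolated on a common grid where samples have
#' different numbers of missing values, and ties receiving the mean of their
#' would-be values. Missing entries stay missing; output scale is log2.
#'
#' @param x an \linkS4class{AbundanceSet}.
#' @param quantileNormalize set \code{FALSE} to apply only the log transform.
#' @return an \linkS4class{AbundanceSet} on the log2 scale.
#' @export
logQuantileNormalize <- function(x, quantileNormalize = TRUE) {
  m <- abundances(x)
  if (abundanceScale(x) == "linear") {
    if (any(m <= 0, na.rm = TRUE))
      stop("non-positive value under scale=linear; cannot log-transform")
    m <- log2(m)
  }
  if (quantileNormalize && ncol(m) > 1L)
    m <- limma::normalizeQuantiles(m, ties = TRUE)
  AbundanceSet(m, datasetId = datasetId(x), scale = "log2",
               colData = colData(x))
}

#' Conditionally normalize a dataset based on sample normality
#'
#' Reproduces the conditional application of normalization: a dataset is
#' log + quantile-normalized only when more than \code{maxFracNonNormal} of
#' its samples reject Shapiro-Wilk normality at \code{alpha} (a proxy for
#' published processing having left batch effects behind). \code{force}
#' overrides the decision in either direction. Linear-scale input is always
#' log2-transformed regardless of the decision.
#'
#' @param x an \linkS4class{AbundanceSet}.
#' @param alpha per-sample Shapiro-Wilk rejection level.
#' @param maxFracNonNormal fraction of rejecting samples above which
#'   normalization is applied.
#' @param force \code{"auto"} (default), \code{"always"} or \code{"never"}.
#' @param seed seed for the normality subsampling.
#' @return list with elements \code{dataset} (log2
#'   \linkS4class{AbundanceSet}), \code{normalized} (logical) and
#'   \code{report} (the normality table).
#' @export
preprocessDataset <- function(x, alpha = 0.01, maxFracNonNormal = 0.10,
                              force = c("auto", "always", "never"),
                              seed = 1L) {
  force <- match.arg(force)
  report <- assessNormality(x, seed = seed)
  frac <- mean(report$p_value < alpha, na.rm = TRUE)
  doQN <- switch(force, always = TRUE, never = FALSE,
                 auto = is.finite(frac) && frac > maxFracNonNormal)
  list(dataset = logQuantileNormalize(x, quantileNormalize = doQN),
       normalized = doQN, report = report)
}

#' Remove incompletely quantified proteins
#'
#' Drops proteins quantified (non-missing) in fewer than \code{minFraction}
#' of samples. The comparison is \code{>= minFraction} (a protein seen in
#' exactly half the samples survives the default 0.5 cutoff).
#'
#' @param x an \linkS4class{AbundanceSet}.
#' @param minFraction required fraction of samples, in (0, 1].
#' @return the filtered \linkS4class{AbundanceSet}.
#' @export
filterByCompleteness <- function(x, minFraction = 0.5) {
  if (!is.numeric(minFraction) || minFraction <= 0 || minFraction > 1)
    stop("minFraction must lie in (0, 1]")
  m <- abundances(x)
  keep <- rowMeans(!is.na(m)) >= minFraction
  if (!any(keep)) stop("no protein passes the completeness filter")
  x[keep, ]
}

# Run `expr`-style seeded code without disturbing the caller's RNG stream:
# set the seed and return a restorer closure for on.exit().
.localSeed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}
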