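#' @include AllClasses.R io.R
NULL

#' Median complex abundance per sample
#'
#' For each complex, the per-sample median log2 abundance over its eligible
#' subunits. Subunits quantified in fewer than \code{minQuantifiedFraction}
#' of samples are excluded everywhere before taking medians; complexes with
#' fewer than \code{minSubunits} eligible subunits are skipped. A sample in
#' which all eligible subunits are missing gets a missing module value.
#'
#' @param x a log2-scale \linkS4class{AbundanceSet}.
#' @param catalog complex (or pathway) \linkS4class{ModuleCatalog}.
#' @param minQuantifiedFraction per-subunit completeness requirement
#'   (default 0.5).
#' @param minSubunits minimum eligible subunits per complex (default 5).
#' @return modules x samples numeric matrix.
#' @export
complexMedianAbundance <- function(x, catalog, minQuantifiedFraction = 0.5,
                                   minSubunits = 5L) {
  m <- abundances(x)
  rows <- lapply(names(moduleMembers(catalog)), function(id) {
    mem <- intersect(moduleMembers(catalog)[[id]], rownames(m))
    sub <- m[mem, , drop = FALSE]
    sub <- sub[rowMeans(!is.na(sub)) >= minQuantifiedFraction, ,
               drop = FALSE]
    if (nrow(sub) < minSubunits) return(NULL)
    med <- apply(sub, 2L, function(v)
      if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE))
    matrix(med, 1L, dimnames = list(id, colnames(m)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no module with >= ", minSubunits,
                         " eligible subunits")
  out
}

#' Sex/diet differential abundance of module medians
#'
#' Two-sided two-sample t test (pooled variance) of each module's median
#' abundance between the two levels of a factor, with Cohen's d (pooled,
#' n-1-weighted standard deviation) as the effect size. The sign convention
#' is male - female for sex and high_fat - chow for diet. P-values are
#' Benjamini-Hochberg adjusted across modules; modules are flagged
#' significant at q < \code{qThreshold}.
#'
#' @param moduleMedians modules x samples matrix
#'   (\code{\link{complexMedianAbundance}}).
#' @param metadata data.frame with \code{sample_id} and the factor column.
#' @param factorName \code{"sex"} or \code{"diet"} (or another two-level
#'   metadata column).
#' @param qThreshold significance cutoff on the BH q-value (default 0.01).
#' @return data.frame: \code{module_id}, \code{factor}, \code{n1},
#'   \code{n2}, \code{cohen_d}, \code{t_stat}, \code{p_value},
#'   \code{q_value}, \code{significant} (zero pooled variance yields NA
#'   statistics).
#' @export
differentialModuleAbundance <- function(moduleMedians, metadata, factorName,
                                        qThreshold = 0.01) {
  f <- .checkFactor(metadata, colnames(moduleMedians), factorName)
  lv <- levels(f)              # (female, male) / (chow, high_fat)
  out <- do.call(rbind, lapply(rownames(moduleMedians), function(id) {
    v <- moduleMedians[id, ]
    x1 <- v[f == lv[2L] & !is.na(v) & !is.na(f)]   # male / high_fat
    x2 <- v[f == lv[1L] & !is.na(v) & !is.na(f)]
    if (length(x1) < 3L || length(x2) < 3L)
      return(data.frame(module_id = id, factor = factorName,
                        n1 = length(x1), n2 = length(x2),
                        cohen_d = NA_real_, t_stat = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    sp <- sqrt(((length(x1) - 1) * stats::var(x1) +
                (length(x2) - 1) * stats::var(x2)) /
               (length(x1) + length(x2) - 2))
    if (sp == 0)
      return(data.frame(module_id = id, factor = factorName,
                        n1 = length(x1), n2 = length(x2),
                        cohen_d = if (mean(x1) == mean(x2)) 0 else NA_real_,
                        t_stat = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    tt <- stats::t.test(x1, x2, var.equal = TRUE)
    data.frame(module_id = id, factor = factorName,
               n1 = length(x1), n2 = length(x2),
               cohen_d = (mean(x1) - mean(x2)) / sp,
               t_stat = unname(tt$statistic), p_value = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$q_value <- NA_real_
  ok <- !is.na(out$p_value)
  out$q_value[ok] <- stats::p.adjust(out$p_value[ok], "BH")
  out$significant <- !is.na(out$q_value) & out$q_value < qThreshold
  out
}

# limma-style Newton inversion of the trigamma function.
.trigammaInverse <- function(y) {
  vapply(y, function(yi) {
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (-dif / x < 1e-8) break
    }
    x
  }, 0)
}

#' Estimate the empirical-Bayes variance prior (d0, s0^2)
#'
#' Method-of-moments fit of the scaled inverse-chi-square prior underlying
#' variance moderation: residual variances s2 with df residual degrees of
#' freedom are modelled as s0^2 F(df, d0); matching the mean and variance of
#' log s2 to the theoretical log-F moments gives d0 (via the inverse
#' trigamma) and s0^2. When the spread of log s2 does not exceed its
#' chi-square sampling floor, d0 is infinite and s0^2 = the common variance.
#'
#' @param s2 positive residual variances.
#' @param df residual degrees of freedom (scalar or per-variance vector).
#' @return list with \code{d0} (prior df, possibly \code{Inf}) and
#'   \code{s0sq} (prior variance).
#' @export
estimateVariancePrior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  s2 <- s2[ok]
  df <- rep_len(df, length(ok))[ok]
  if (length(s2) < 2L) stop("need >= 2 variances to estimate the prior")
  z <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(z)
  evar <- stats::var(z) - mean(trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * .trigammaInverse(evar)
    s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0sq <- exp(emean)
  }
  list(d0 = d0, s0sq = s0sq)
}

#' Moderated-t contrasts on complex-normalized abundances
#'
#' Fits, per (complex, subunit), an additive two-factor linear model
#' (intercept + sex + diet, binary codes male = 1 / high_fat = 1, casewise
#' deletion of missing values) to the complex-normalized log2 abundances,
#' so each factor's contrast controls for the other. Residual variances are
#' moderated by the empirical-Bayes prior of
#' \code{\link{estimateVariancePrior}}: the posterior variance
#' (d0 s0^2 + d s2)/(d0 + d) replaces s2 in the t statistic and the degrees
#' of freedom become d0 + d, giving a conservative variance estimate for
#' subunits with few observations. P-values (two-sided) are BH-adjusted
#' jointly across all (complex, subunit, contrast) tests; \code{log2_fc} is
#' the contrast coefficient (male - female, high_fat - chow).
#'
#' @param profile a \linkS4class{StoichiometryProfile}.
#' @param metadata data.frame with \code{sample_id}, \code{sex},
#'   \code{diet}.
#' @param contrasts which factor contrasts to report (default both).
#' @param minSampleFraction per-subunit completeness requirement on the
#'   normalized values (default 0.5).
#' @param priorDf,priorVar optional override of the estimated (d0, s0^2);
#'   \code{priorDf = 0} disables moderation (ordinary t),
#'   \code{priorDf = Inf} uses the common variance \code{priorVar}.
#' @param qThreshold stoichiometric-hit cutoff on q (default 0.01).
#' @return data.frame: \code{complex_id}, \code{protein_id},
#'   \code{contrast}, \code{n}, \code{log2_fc}, \code{s2},
#'   \code{s2_posterior}, \code{d0}, \code{s0_sq}, \code{df_residual},
#'   \code{df_total}, \code{t_moderated}, \code{p_value}, \code{q_value},
#'   \code{significant}.
#' @export
fitModeratedContrasts <- function(profile, metadata,
                                  contrasts = c("sex", "diet"),
                                  minSampleFraction = 0.5,
                                  priorDf = NULL, priorVar = NULL,
                                  qThreshold = 0.01) {
  contrasts <- match.arg(contrasts, c("sex", "diet"), several.ok = TRUE)
  samples <- colnames(normalizedAbundances(profile))
  sexF <- .checkFactor(metadata, samples, "sex")
  dietF <- .checkFactor(metadata, samples, "diet")
  X <- cbind(intercept = 1, sex = as.numeric(sexF) - 1,
             diet = as.numeric(dietF) - 1)
  if (qr(X[stats::complete.cases(X), , drop = FALSE])$rank < ncol(X))
    stop("design is collinear: factors sex and diet are confounded")
  fits <- list()
  for (id in names(complexProfiles(profile))) {
    pc <- complexProfiles(profile)[[id]]
    eligible <- rowMeans(!is.na(pc)) >= minSampleFraction
    for (prot in rownames(pc)[eligible]) {
      y <- pc[prot, ]
      ok <- !is.na(y) & stats::complete.cases(X)
      n <- sum(ok)
      dfRes <- n - ncol(X)
      if (dfRes < 2L) next
      Xo <- X[ok, , drop = FALSE]
      if (qr(Xo)$rank < ncol(Xo)) next
      fit <- stats::lm.fit(Xo, y[ok])
      XtXinv <- chol2inv(chol(crossprod(Xo)))
      fits[[length(fits) + 1L]] <- list(
        complex_id = id, protein_id = prot, n = n, dfRes = dfRes,
        coef = fit$coefficients,
        s2 = sum(fit$residuals^2) / dfRes,
        seFactor = stats::setNames(sqrt(diag(XtXinv)), colnames(Xo)))
    }
  }
  if (!length(fits)) stop("no subunit passes the completeness requirement")
  s2 <- vapply(fits, `[[`, 0, "s2")
  dfRes <- vapply(fits, `[[`, 0, "dfRes")
  if (is.null(priorDf)) {
    prior <- estimateVariancePrior(s2, dfRes)
  } else {
    prior <- list(d0 = priorDf,
                  s0sq = if (!is.null(priorVar)) priorVar
                         else estimateVariancePrior(s2, dfRes)$s0sq)
  }
  d0 <- prior$d0; s0sq <- prior$s0sq
  s2post <- if (is.infinite(d0)) rep(s0sq, length(s2))
            else (d0 * s0sq + dfRes * s2) / (d0 + dfRes)
  out <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    do.call(rbind, lapply(contrasts, function(ct) {
      tmod <- f$coef[[ct]] / (sqrt(s2post[i]) * f$seFactor[[ct]])
      dfTot <- d0 + f$dfRes
      data.frame(complex_id = f$complex_id, protein_id = f$protein_id,
                 contrast = ct, n = f$n, log2_fc = f$coef[[ct]],
                 s2 = f$s2, s2_posterior = s2post[i], d0 = d0,
                 s0_sq = s0sq, df_residual = f$dfRes, df_total = dfTot,
                 t_moderated = tmod,
                 p_value = 2 * stats::pt(-abs(tmod), dfTot),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out$q_value <- stats::p.adjust(out$p_value, "BH")
  out$significant <- out$q_value < qThreshold
  out
}

#' Combine component-level evidence per complex by Fisher's method
#'
#' Combines each complex's component q-values (BH-adjusted moderated-t
#' values, as the procedure prescribes; set \code{useRawP = TRUE} for the
#' conventional raw-p combination) into chi2 = -2 sum(log q) with 2k
#' degrees of freedom, and BH-adjusts the combined p-values across
#' complexes. Combination is per contrast when a \code{contrast} column is
#' present. Zero q-values are clamped to the smallest positive double with
#' a warning.
#'
#' @param results output of \code{\link{fitModeratedContrasts}}.
#' @param useRawP combine raw p-values instead of q-values.
#' @return data.frame: \code{complex_id} (, \code{contrast}),
#'   \code{n_components}, \code{fisher_chi2}, \code{df}, \code{combined_p},
#'   \code{combined_q}.
#' @export
combineComplexVerdict <- function(results, useRawP = FALSE) {
  val <- if (useRawP) results$p_value else results$q_value
  if (any(val == 0, na.rm = TRUE)) {
    warning("zero p/q value(s) clamped to the smallest positive double")
    val[val == 0] <- .Machine$double.xmin
  }
  results$.val <- val
  byCols <- intersect(c("complex_id", "contrast"), names(results))
  key <- do.call(paste, c(results[byCols], sep = "\r"))
  out <- do.call(rbind, lapply(split(results, key), function(d) {
    d <- d[!is.na(d$.val), , drop = FALSE]
    if (nrow(d) < 2L) return(NULL)
    chi2 <- -2 * sum(log(d$.val))
    df <- 2L * nrow(d)
    cbind(d[1L, byCols, drop = FALSE],
          data.frame(n_components = nrow(d), fisher_chi2 = chi2, df = df,
                     combined_p = stats::pchisq(chi2, df,
                                                lower.tail = FALSE)))
  }))
  if (is.null(out)) stop("no complex with >= 2 tested components")
  rownames(out) <- NULL
  if ("contrast" %in% byCols && length(unique(out$contrast)) > 1L) {
    out$combined_q <- NA_real_
    for (ct in unique(out$contrast)) {
      i <- out$contrast == ct
      out$combined_q[i] <- stats::p.adjust(out$combined_p[i], "BH")
    }
  } else out$combined_q <- stats::p.adjust(out$combined_p, "BH")
  out
}
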