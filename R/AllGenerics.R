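#' @include AllClasses.R
NULL

#' Accessors for pipeline containers
#'
#' \code{datasetId} returns the dataset identifier; \code{abundanceScale} the
#' scale flag of an \linkS4class{AbundanceSet}; \code{abundances} the
#' proteins x samples matrix; \code{moduleCategory}, \code{moduleMembers} and
#' \code{wellDefined} the parts of a \linkS4class{ModuleCatalog};
#' \code{interactions} the pair table of an \linkS4class{InteractionTable};
#' \code{normalizedAbundances}, \code{complexProfiles} and \code{zTable} the
#' parts of a \linkS4class{StoichiometryProfile}.
#'
#' @param x a pipeline container object.
#' @return the corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("datasetId", function(x) standardGeneric("datasetId"))
#' @rdname accessors
#' @export
setMethod("datasetId", "AbundanceSet", function(x) x@datasetId)
#' @rdname accessors
#' @export
setMethod("datasetId", "StoichiometryProfile", function(x) x@datasetId)

#' @rdname accessors
#' @export
setGeneric("abundanceScale", function(x) standardGeneric("abundanceScale"))
#' @rdname accessors
#' @export
setMethod("abundanceScale", "AbundanceSet", function(x) x@abundanceScale)

#' @rdname accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
#' @rdname accessors
#' @export
setMethod("abundances", "AbundanceSet",
          function(x) assay(x, "abundance"))

#' @rdname accessors
#' @export
setGeneric("moduleCategory", function(x) standardGeneric("moduleCategory"))
#' @rdname accessors
#' @export
setMethod("moduleCategory", "ModuleCatalog", function(x) x@category)

#' @rdname accessors
#' @export
setGeneric("moduleMembers", function(x) standardGeneric("moduleMembers"))
#' @rdname accessors
#' @export
setMethod("moduleMembers", "ModuleCatalog", function(x) x@members)

#' @rdname accessors
#' @export
setGeneric("wellDefined", function(x) standardGeneric("wellDefined"))
#' @rdname accessors
#' @export
setMethod("wellDefined", "ModuleCatalog", function(x) x@wellDefined)

#' @rdname accessors
#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))
#' @rdname accessors
#' @export
setMethod("interactions", "InteractionTable", function(x) x@interactions)

#' @rdname accessors
#' @export
setGeneric("normalizedAbundances",
           function(x) standardGeneric("normalizedAbundances"))
#' @rdname accessors
#' @export
setMethod("normalizedAbundances", "StoichiometryProfile",
          function(x) x@normalized)

#' @rdname accessors
#' @export
setGeneric("complexProfiles", function(x) standardGeneric("complexProfiles"))
#' @rdname accessors
#' @export
setMethod("complexProfiles", "StoichiometryProfile", function(x) x@perComplex)

#' @rdname accessors
#' @export
setGeneric("zTable", function(x) standardGeneric("zTable"))
#' @rdname accessors
#' @export
setMethod("zTable", "StoichiometryProfile", function(x) x@zTable)

setMethod("show", "AbundanceSet", function(object) {
  cat("AbundanceSet \"", object@datasetId, "\": ",
      nrow(object), " proteins x ", ncol(object), " samples (",
      object@abundanceScale, " scale, ",
      sprintf("%.1f", 100 * mean(is.na(assay(object, "abundance")))),
      "% missing)\n", sep = "")
  if (ncol(colData(object)))
    cat("sample covariates:", paste(colnames(colData(object)),
                                    collapse = ", "), "\n")
})

setMethod("show", "ModuleCatalog", function(object) {
  n <- lengths(object@members)
  cat("ModuleCatalog: ", length(n), " ", object@category, " module(s), ",
      "sizes ", if (length(n)) paste0(min(n), "-", max(n)) else "-",
      ", ", length(unique(unlist(object@members))),
      " distinct proteins\n", sep = "")
})

setMethod("show", "InteractionTable", function(object) {
  d <- object@interactions
  cat("InteractionTable: ", nrow(d), " unordered pair(s), ",
      sum(d$combined_score > 0.7), " high-confidence (score > 0.7)\n",
      sep = "")
})

setMethod("show", "StoichiometryProfile", function(object) {
  cat("StoichiometryProfile \"", object@datasetId, "\": ",
      nrow(object@normalized), " proteins x ", ncol(object@normalized),
      " samples, ", length(object@perComplex), " complex(es)",
      if (nrow(object@zTable)) paste0(", ", nrow(object@zTable),
                                      " subunit z-scores") else "",
      "\n", sep = "")
})
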