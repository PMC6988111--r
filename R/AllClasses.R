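#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' AbundanceSet: one cohort's protein abundance matrix
#'
#' Container for a single dataset's proteins x samples abundance matrix,
#' extending \linkS4class{SummarizedExperiment}. Rows are proteins, columns
#' samples; the single assay \code{"abundance"} may contain \code{NA} for
#' unquantified (protein, sample) cells. The \code{scale} slot records whether
#' values are raw linear intensities or log2-transformed; most of the pipeline
#' requires \code{"log2"} input (see \code{\link{logQuantileNormalize}}).
#'
#' @slot datasetId single string identifying the cohort/dataset.
#' @slot abundanceScale either \code{"linear"} or \code{"log2"}. On the linear
#'   scale all non-missing values must be strictly positive.
#'
#' @seealso \code{\link{readAbundanceMatrix}}, \code{\link{generateCohort}}
#' @export
setClass("AbundanceSet",
  contains = "SummarizedExperiment",
  representation(datasetId = "character", abundanceScale = "character")
)

setValidity("AbundanceSet", function(object) {
  msg <- character()
  if (length(object@datasetId) != 1L || is.na(object@datasetId) ||
      !nzchar(object@datasetId))
    msg <- c(msg, "'datasetId' must be a single non-empty string")
  if (length(object@abundanceScale) != 1L ||
      !object@abundanceScale %in% c("linear", "log2"))
    msg <- c(msg, "'abundanceScale' must be \"linear\" or \"log2\"")
  if (!"abundance" %in% names(assays(object)))
    msg <- c(msg, "assay \"abundance\" is required")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "protein identifiers (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers (colnames) must be present and unique")
  if (length(msg) == 0L && identical(object@abundanceScale, "linear")) {
    v <- assay(object, "abundance")
    if (any(v <= 0, na.rm = TRUE))
      msg <- c(msg, "scale=linear requires all non-missing values > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AbundanceSet
#'
#' @param values numeric matrix, proteins in rows (rownames = protein ids),
#'   samples in columns (colnames = sample ids); \code{NA} marks missing.
#' @param datasetId single string naming the dataset.
#' @param scale \code{"linear"} or \code{"log2"}.
#' @param colData optional per-sample \code{DataFrame}/data.frame (e.g. sex,
#'   diet) aligned with \code{colnames(values)}.
#' @return an \linkS4class{AbundanceSet}.
#' @examples
#' m <- matrix(rnorm(6, 20), 3, 2,
#'             dimnames = list(c("P1","P2","P3"), c("s1","s2")))
#' AbundanceSet(m, "demo", scale = "log2")
#' @export
AbundanceSet <- function(values, datasetId, scale = c("log2", "linear"),
                         colData = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colData)) {
    colData <- DataFrame(row.names = colnames(values))
  } else {
    colData <- as(colData, "DataFrame")
    rownames(colData) <- colnames(values)
  }
  se <- SummarizedExperiment(assays = list(abundance = values),
                             colData = colData)
  new("AbundanceSet", se, datasetId = datasetId, abundanceScale = scale)
}

#' ModuleCatalog: named protein sets of one category
#'
#' Holds modules (complexes, pathways, compartments, chromosome groups, or
#' flagged housekeeping/essential sets) as named member sets. Membership lists
#' are deduplicated character vectors; empty modules are not allowed.
#'
#' @slot category one of \code{"complex"}, \code{"pathway"},
#'   \code{"compartment"}, \code{"chromosome"}, \code{"housekeeping"},
#'   \code{"essential"}.
#' @slot members named list of character vectors (module id -> member ids).
#' @slot wellDefined named logical vector (complexes only; may be empty), one
#'   entry per module, marking manually curated, well-defined complexes.
#' @seealso \code{\link{readModuleCatalog}}
#' @export
setClass("ModuleCatalog",
  representation(category = "character", members = "list",
                 wellDefined = "logical")
)

.moduleCategories <- c("complex", "pathway", "compartment", "chromosome",
                       "housekeeping", "essential")

setValidity("ModuleCatalog", function(object) {
  msg <- character()
  if (length(object@category) != 1L ||
      !object@category %in% .moduleCategories)
    msg <- c(msg, paste0("'category' must be one of: ",
                         paste(.moduleCategories, collapse = ", ")))
  m <- object@members
  if (is.null(names(m)) || anyDuplicated(names(m)))
    msg <- c(msg, "module ids must be present and unique within the category")
  if (any(lengths(m) == 0L))
    msg <- c(msg, "modules must have non-empty member sets")
  if (any(vapply(m, anyDuplicated, 0L) > 0L))
    msg <- c(msg, "member sets must be deduplicated")
  if (length(object@wellDefined) &&
      !setequal(names(object@wellDefined), names(m)))
    msg <- c(msg, "'wellDefined' must be named after the module ids")
  if (length(msg)) msg else TRUE
})

#' Construct a ModuleCatalog
#'
#' @param members named list of character vectors (module id -> member protein
#'   ids); members are deduplicated, empty modules dropped with a warning.
#' @param category module category (see \linkS4class{ModuleCatalog}).
#' @param wellDefined optional named logical flag per module (complexes).
#' @return a \linkS4class{ModuleCatalog}.
#' @export
ModuleCatalog <- function(members, category = "complex", wellDefined = logical()) {
  members <- lapply(members, function(x) unique(as.character(x)))
  empty <- lengths(members) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty), " empty module(s): ",
            paste(utils::head(names(members)[empty], 5L), collapse = ", "))
    members <- members[!empty]
    wellDefined <- wellDefined[names(wellDefined) %in% names(members)]
  }
  new("ModuleCatalog", category = category, members = members,
      wellDefined = wellDefined)
}

#' InteractionTable: scored protein-protein interaction pairs
#'
#' Undirected interaction pairs in STRING flat-file style with a combined
#' confidence score in [0, 1]. Pairs are stored canonically with
#' \code{protein1 < protein2}; self-pairs are disallowed.
#'
#' @slot interactions data.frame with columns \code{protein1},
#'   \code{protein2}, \code{combined_score}.
#' @seealso \code{\link{readInteractions}}
#' @export
setClass("InteractionTable", representation(interactions = "data.frame"))

setValidity("InteractionTable", function(object) {
  d <- object@interactions
  msg <- character()
  if (!all(c("protein1", "protein2", "combined_score") %in% names(d)))
    return("columns protein1, protein2, combined_score are required")
  if (any(d$protein1 == d$protein2))
    msg <- c(msg, "self-pairs are not allowed")
  if (any(d$protein1 > d$protein2))
    msg <- c(msg, "pairs must be stored with protein1 < protein2")
  if (anyDuplicated(paste(d$protein1, d$protein2, sep = "\r")))
    msg <- c(msg, "duplicate pairs are not allowed")
  if (any(d$combined_score < 0 | d$combined_score > 1, na.rm = TRUE))
    msg <- c(msg, "scores must lie in [0, 1] after normalization")
  if (length(msg)) msg else TRUE
})

#' Construct an InteractionTable
#'
#' Pairs are canonicalized (unordered), deduplicated keeping the maximum
#' score, and self-pairs dropped with a warning. Scores on the STRING 0-1000
#' convention (any score > 1) are divided by 1000.
#'
#' @param protein1,protein2 character vectors of interaction partners.
#' @param score numeric combined scores, either in [0, 1] or on the 0-1000
#'   scale.
#' @return an \linkS4class{InteractionTable}.
#' @export
InteractionTable <- function(protein1, protein2, score) {
  protein1 <- as.character(protein1); protein2 <- as.character(protein2)
  score <- as.numeric(score)
  self <- protein1 == protein2
  if (any(self)) {
    warning("dropping ", sum(self), " self-interaction row(s)")
    protein1 <- protein1[!self]; protein2 <- protein2[!self]
    score <- score[!self]
  }
  if (any(score > 1, na.rm = TRUE)) score <- score / 1000
  a <- pmin(protein1, protein2); b <- pmax(protein1, protein2)
  key <- paste(a, b, sep = "\r")
  score <- vapply(split(score, key), max, 0)
  ab <- strsplit(names(score), "\r", fixed = TRUE)
  d <- data.frame(protein1 = vapply(ab, `[`, "", 1L),
                  protein2 = vapply(ab, `[`, "", 2L),
                  combined_score = unname(score),
                  stringsAsFactors = FALSE, row.names = NULL)
  new("InteractionTable", interactions = d)
}

#' StoichiometryProfile: complex-normalized abundances and variance z-scores
#'
#' Result of module-wise (trimmed-mean) normalization of an
#' \linkS4class{AbundanceSet}. \code{normalized} holds, per protein and
#' sample, the log2 abundance minus the trimmed mean of its complex in that
#' sample, averaged across complexes for proteins in several complexes.
#' \code{perComplex} keeps the complex-specific normalized submatrices used
#' for per-(complex, subunit) variance z-scores; \code{zTable} holds those
#' z-scores once \code{\link{subunitVarianceZ}} has been applied.
#'
#' @slot datasetId dataset identifier inherited from the input.
#' @slot normalized proteins x samples matrix of complex-normalized log2
#'   abundances (NA wherever input missing or the complex reference was
#'   undefined).
#' @slot perComplex named list (complex id -> subunits x samples normalized
#'   matrix).
#' @slot zTable data.frame with columns \code{complex_id}, \code{protein_id},
#'   \code{variance}, \code{z} (empty until z-scores are computed).
#' @export
setClass("StoichiometryProfile",
  representation(datasetId = "character", normalized = "matrix",
                 perComplex = "list", zTable = "data.frame")
)

setValidity("StoichiometryProfile", function(object) {
  msg <- character()
  if (length(object@datasetId) != 1L)
    msg <- c(msg, "'datasetId' must be a single string")
  if (nrow(object@zTable) &&
      !all(c("complex_id", "protein_id", "variance", "z") %in%
           names(object@zTable)))
    msg <- c(msg, "zTable needs columns complex_id, protein_id, variance, z")
  if (length(msg)) msg else TRUE
})
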