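#' @include AllClasses.R
NULL

# Missing cells are encoded as "" or "NA" on read and "" on write, matching
# the supplementary-table dialects the pipeline consumes.
.naStrings <- c("", "NA")

#' Read a protein abundance matrix from TSV
#'
#' Expects a tab-separated file with a header row of sample identifiers and a
#' first column of protein identifiers; empty cells or \code{NA} mark missing
#' values. Identifier matching downstream is exact-string: inputs must be
#' pre-mapped to a single identifier space.
#'
#' @param path path to the TSV file.
#' @param datasetId dataset identifier to attach.
#' @param scale \code{"linear"} or \code{"log2"}; on the linear scale a zero
#'   or negative value is a validation error.
#' @return an \linkS4class{AbundanceSet}.
#' @seealso \code{\link{writeAbundanceMatrix}}
#' @export
readAbundanceMatrix <- function(path, datasetId, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  d <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                         colClasses = "character", na.strings = .naStrings)
  if (ncol(d) < 2L)
    stop("abundance file needs a protein-id column plus >= 1 sample column")
  ids <- d[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate protein identifier(s): ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5L), collapse = ", "))
  cells <- as.matrix(d[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(vals) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("malformed numeric cell at row \"%s\", column \"%s\": \"%s\"",
                 ids[bad[1L, 1L]], colnames(cells)[bad[1L, 2L]],
                 cells[bad[1L, , drop = FALSE]]))
  dimnames(vals) <- list(ids, colnames(cells))
  AbundanceSet(vals, datasetId = datasetId, scale = scale)
}

#' Write an AbundanceSet as TSV
#'
#' Inverse of \code{\link{readAbundanceMatrix}}: missing values become empty
#' cells, so a write/read round trip preserves the missingness pattern.
#'
#' @param x an \linkS4class{AbundanceSet}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeAbundanceMatrix <- function(x, path) {
  m <- abundances(x)
  d <- data.frame(protein_id = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a module catalog (GMT or long TSV)
#'
#' Two dialects are auto-detected: GMT (\code{module_id<TAB>description<TAB>
#' member...}) and long TSV with header columns \code{module_id},
#' \code{protein_id} and optionally \code{well_defined}. Member sets are
#' deduplicated; modules left empty after parsing are dropped with a warning.
#'
#' @param path path to the file.
#' @param category module category (see \linkS4class{ModuleCatalog}).
#' @param format \code{"auto"} (default), \code{"gmt"} or \code{"tsv"}.
#' @return a \linkS4class{ModuleCatalog}.
#' @export
readModuleCatalog <- function(path, category = "complex",
                              format = c("auto", "gmt", "tsv")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty module file: ", path)
  if (format == "auto") {
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    format <- if (all(c("module_id", "protein_id") %in% header)) "tsv"
              else if (length(header) >= 3L) "gmt"
              else stop("unrecognized module file dialect: ", path)
  }
  if (format == "gmt") {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 2L))
      stop("malformed GMT line (need id + description): ", path)
    members <- lapply(parts, function(p) p[-(1:2)][nzchar(p[-(1:2)])])
    names(members) <- vapply(parts, `[`, "", 1L)
    wd <- logical()
  } else {
    d <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
    if (!all(c("module_id", "protein_id") %in% names(d)))
      stop("long-TSV module file needs columns module_id, protein_id")
    keep <- !is.na(d$protein_id) & nzchar(d$protein_id)
    members <- split(d$protein_id[keep], d$module_id[keep])
    lost <- setdiff(unique(d$module_id), names(members))
    if (length(lost))
      warning("dropping ", length(lost), " empty module(s): ",
              paste(utils::head(lost, 5L), collapse = ", "))
    wd <- logical()
    if ("well_defined" %in% names(d)) {
      wd <- vapply(split(d$well_defined, d$module_id),
                   function(x) any(tolower(x) %in% c("true", "1", "yes")),
                   NA)
      wd <- wd[names(members)]
    }
  }
  ModuleCatalog(members, category = category, wellDefined = wd)
}

#' Write a ModuleCatalog as GMT
#'
#' @param x a \linkS4class{ModuleCatalog}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeModuleCatalog <- function(x, path) {
  members <- moduleMembers(x)
  lines <- vapply(names(members), function(id) {
    paste(c(id, moduleCategory(x), members[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a STRING-style interaction table
#'
#' Expects TSV columns \code{protein1}, \code{protein2},
#' \code{combined_score}. Scores on the STRING 0-1000 integer convention
#' (detected by any score > 1) are divided by 1000, so both published score
#' conventions land on [0, 1]; the normalization is idempotent. Unordered
#' duplicate pairs keep the maximum score; self-interaction rows are dropped
#' with a warning.
#'
#' @param path path to the TSV file.
#' @return an \linkS4class{InteractionTable}.
#' @export
readInteractions <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         na.strings = .naStrings)
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(d)))
    stop("interaction file needs columns: ", paste(need, collapse = ", "))
  InteractionTable(d$protein1, d$protein2, d$combined_score)
}

#' Read a sample metadata table
#'
#' TSV with a \code{sample_id} column plus categorical covariate columns
#' (typically \code{sex} in \{male, female, unknown\} and \code{diet} in
#' \{chow, high_fat, unknown\}). Unrecognized levels in \code{sex}/\code{diet}
#' are an error; additional factor columns are carried through as-is.
#'
#' @param path path to the TSV file.
#' @return a data.frame with rownames = sample ids.
#' @export
readSampleMetadata <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character", na.strings = .naStrings)
  if (!"sample_id" %in% names(d)) stop("metadata needs a sample_id column")
  if (anyDuplicated(d$sample_id)) stop("duplicate sample_id in metadata")
  if ("sex" %in% names(d)) {
    bad <- setdiff(unique(d$sex), c("male", "female", "unknown", NA))
    if (length(bad)) stop("unknown sex level(s): ", paste(bad, collapse = ", "))
  }
  if ("diet" %in% names(d)) {
    bad <- setdiff(unique(d$diet), c("chow", "high_fat", "unknown", NA))
    if (length(bad)) stop("unknown diet level(s): ", paste(bad, collapse = ", "))
  }
  rownames(d) <- d$sample_id
  d
}

#' Write a sample metadata table
#'
#' @param metadata data.frame with a \code{sample_id} column.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSampleMetadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# Require >= 2 samples per analyzed level of a two-level factor; returns the
# validated factor aligned with `samples`, with its declared level order.
.checkFactor <- function(metadata, samples, factorName) {
  if (!factorName %in% names(metadata))
    stop("metadata has no column \"", factorName, "\"")
  levs <- switch(factorName,
                 sex = c("female", "male"),
                 diet = c("chow", "high_fat"),
                 NULL)
  v <- metadata[match(samples, metadata$sample_id), factorName]
  v[v %in% "unknown"] <- NA
  f <- if (is.null(levs)) factor(v) else factor(v, levels = levs)
  tab <- table(f)
  if (length(tab) < 2L || any(tab < 2L))
    stop("factor \"", factorName,
         "\" needs >= 2 samples in each of >= 2 levels")
  f
}
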