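# Shared in-code fixtures: tiny abundance sets and catalogs built on the fly.

makeSet <- function(values, datasetId = "test", scale = "log2",
                    colData = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  AbundanceSet(values, datasetId = datasetId, scale = scale,
               colData = colData)
}

# Gaussian matrix with named dims; proteins x samples.
randomSet <- function(nProteins, nSamples, seed = 1, sd = 1, mean = 20,
                      datasetId = "rand") {
  set.seed(seed)
  makeSet(matrix(rnorm(nProteins * nSamples, mean, sd), nProteins,
                 nSamples), datasetId = datasetId)
}

# Balanced crossed sex/diet metadata for n samples named S0001...
balancedMetadata <- function(n) {
  half <- n %/% 2
  data.frame(sample_id = sprintf("S%04d", seq_len(n)),
             sex = rep(c("female", "male"), c(half, n - half)),
             diet = unlist(lapply(c(half, n - half), function(k)
               rep(c("chow", "high_fat"), c(k %/% 2, k - k %/% 2)))),
             stringsAsFactors = FALSE)
}

tmpWrite <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
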