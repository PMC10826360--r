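#' @include AllClasses.R
NULL

#' Read and write OTU count tables
#'
#' The TSV layout is samples in rows: first column the sample id, header row
#' the OTU ids, integer cells. Group labels and depths travel in a sidecar
#' TSV with columns `sample_id`, `group`, `depth` (written next to the table
#' as `<file>.samples.tsv` and read back automatically when present).
#' MatrixMarket triplet input is supported via `readCountsMtx()` with
#' separate one-id-per-line row (sample) and column (OTU) files.
#'
#' @param path TSV file path.
#' @param table a [CountTable-class].
#' @param sidecar path of the sample-metadata sidecar; defaults to
#'   `<path>.samples.tsv`.
#' @return `readCountTable` a [CountTable-class]; `writeCountTable` the main
#'   path, invisibly.
#' @export
readCountTable <- function(path, sidecar = paste0(path, ".samples.tsv")) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  counts <- as.matrix(df)
  groups <- rep(NA_character_, nrow(counts))
  if (file.exists(sidecar)) {
    meta <- utils::read.table(sidecar, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    groups <- meta$group[match(rownames(counts), meta$sample_id)]
  }
  countTable(counts, groups = groups)
}

#' @rdname readCountTable
#' @export
writeCountTable <- function(table, path,
                            sidecar = paste0(path, ".samples.tsv")) {
  stopifnot(is(table, "CountTable"))
  cc <- otuCounts(table)
  df <- data.frame(sample_id = rownames(cc), cc, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = rownames(cc), group = table@groups,
                     depth = rowSums(cc))
  utils::write.table(meta, sidecar, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname readCountTable
#' @param mtxPath MatrixMarket triplet file (rows = samples, columns = OTUs).
#' @param sampleIdsPath,otuIdsPath one-id-per-line files naming the rows and
#'   columns of the triplet matrix.
#' @export
readCountsMtx <- function(mtxPath, sampleIdsPath, otuIdsPath) {
  header <- readLines(mtxPath, n = 1)
  if (!grepl("^%%MatrixMarket", header))
    stop("not a MatrixMarket file: ", mtxPath)
  lines <- readLines(mtxPath)
  lines <- lines[!startsWith(lines, "%")]
  dims <- scan(text = lines[1], quiet = TRUE)
  trip <- utils::read.table(text = lines[-1])
  sampleIds <- readLines(sampleIdsPath)
  otuIds <- readLines(otuIdsPath)
  if (dims[1] != length(sampleIds) || dims[2] != length(otuIds))
    stop("id files do not match the matrix dimensions")
  counts <- matrix(0, dims[1], dims[2],
                   dimnames = list(sampleIds, otuIds))
  counts[cbind(trip[[1]], trip[[2]])] <- trip[[3]]
  countTable(counts, groups = rep(NA_character_, dims[1]))
}

#' Read and write depth vectors
#'
#' Plain text, one integer library size per line.
#'
#' @param path file path.
#' @param depths integer vector of library sizes.
#' @return `readDepths` an integer vector; `writeDepths` the path,
#'   invisibly.
#' @export
readDepths <- function(path) {
  as.integer(readLines(path))
}

#' @rdname readDepths
#' @export
writeDepths <- function(depths, path) {
  writeLines(as.character(as.integer(depths)), path)
  invisible(path)
}

#' Write a normalized table with a JSON provenance sidecar
#'
#' The values go to a TSV (first column `sample_id`); the provenance
#' (method, threshold quantile, \eqn{N_{L,m}} when known, iteration count,
#' seed, removed samples, groups) goes to `<path>.json`.
#'
#' @param norm a [NormalizedTable-class].
#' @param path TSV path.
#' @return the path, invisibly.
#' @export
writeNormalizedTable <- function(norm, path) {
  stopifnot(is(norm, "NormalizedTable"))
  v <- normValues(norm)
  df <- data.frame(sample_id = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(method = norm@method,
               threshold_quantile = norm@thresholdQuantile,
               n_iterations = norm@nIterations,
               N_L_m = norm@provenance$NLm,
               seed = norm@provenance$seed,
               removed_samples = norm@removedSamples,
               groups = as.list(stats::setNames(norm@groups, rownames(v))))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname writeNormalizedTable
#' @export
readNormalizedTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  methods::new("NormalizedTable", values = as.matrix(df),
               method = meta$method,
               thresholdQuantile = meta$threshold_quantile,
               nIterations = meta$n_iterations,
               removedSamples = as.character(meta$removed_samples %||%
                                               character()),
               groups = as.character(unlist(meta$groups)),
               provenance = list(NLm = meta$N_L_m, seed = meta$seed))
}

#' Read and write distance matrices
#'
#' Square tab-delimited matrix with a header row and a leading id column
#' (readable as PHYLIP square format with an id column).
#'
#' @param dm a [DistanceMatrix-class].
#' @param path TSV path.
#' @param method,normalization provenance recorded when reading back.
#' @return `writeDistanceMatrix` the path, invisibly; `readDistanceMatrix` a
#'   [DistanceMatrix-class].
#' @export
writeDistanceMatrix <- function(dm, path) {
  stopifnot(is(dm, "DistanceMatrix"))
  v <- distValues(dm)
  df <- data.frame(sample_id = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDistanceMatrix
#' @export
readDistanceMatrix <- function(path, method = "bray",
                               normalization = "raw") {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  v <- as.matrix(df)
  v <- (v + t(v)) / 2  # absorb round-tripping noise
  methods::new("DistanceMatrix", values = v, method = method,
               normalization = normalization, removedSamples = character())
}

#' Read and write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] kept for a
#' uniform I/O surface.
#'
#' @param path Newick file path.
#' @param tree an `ape::phylo`.
#' @return `readOtuTree` an `ape::phylo`; `writeOtuTree` the path,
#'   invisibly.
#' @export
readOtuTree <- function(path) ape::read.tree(path)

#' @rdname readOtuTree
#' @export
writeOtuTree <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}
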