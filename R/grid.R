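#' @include AllClasses.R
NULL

#' Define a simulation condition grid
#'
#' Enumerates the factorial design driving the benchmark: effect sizes,
#' depth-distribution models, target median depths, depth-to-group
#' assignment schemes, and the rare-OTU filter toggle, replicated
#' `nReplicates` times under seeds derived from `masterSeed`.
#'
#' @param effectSizes mixing effect sizes (default the conventional menu of
#'   8).
#' @param depthModels `"empirical_resample"` and/or `"log_scaled"`.
#' @param targetMedians target median depths, subset of 1000, 2000, 5000,
#'   10000, 50000 reads.
#' @param assignments `"randomized"` and/or `"confounded"`.
#' @param filters logical vector: apply the two-step rare-OTU filter.
#' @param nReplicates replicates per condition (default 100).
#' @param masterSeed master seed from which every per-cell seed is derived.
#' @return an object of class `"conditionGrid"`: a list with the condition
#'   data frame (`conditions`), `nReplicates`, and `masterSeed`.
#' @seealso [gridPreset()], [runGrid()]
#' @export
#' @examples
#' g <- conditionGrid(effectSizes = c(1, 1.15), targetMedians = 1000,
#'                    nReplicates = 5)
#' nrow(g$conditions)
conditionGrid <- function(effectSizes = .EFFECT_SIZES,
                          depthModels = .DEPTH_KINDS,
                          targetMedians = .TARGET_MEDIANS,
                          assignments = "randomized",
                          filters = TRUE,
                          nReplicates = 100, masterSeed = 1) {
  stopifnot(all(effectSizes >= 1), all(depthModels %in% .DEPTH_KINDS),
            all(targetMedians %in% .TARGET_MEDIANS),
            all(assignments %in% .ASSIGNMENTS), is.logical(filters),
            nReplicates >= 1)
  conditions <- expand.grid(depth_model = depthModels,
                            target_median = targetMedians,
                            assignment = assignments,
                            effect_size = effectSizes,
                            filtered = filters,
                            KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE)
  structure(list(conditions = conditions,
                 nReplicates = as.integer(nReplicates),
                 masterSeed = as.integer(masterSeed)),
            class = "conditionGrid")
}

#' @export
print.conditionGrid <- function(x, ...) {
  cat(sprintf(
    "conditionGrid: %d conditions x %d replicates (master seed %d)\n",
    nrow(x$conditions), x$nReplicates, x$masterSeed))
  invisible(x)
}

#' Preset condition grids
#'
#' `"wnwn"` reproduces the original benchmark's Simulation A arithmetic:
#' 8 effect sizes x 4 target medians x 5 replicates = 160 simulated data
#' sets (empirical depth model, randomized assignment, filtered).
#' `"full"` is the expanded design: 8 effect sizes x 2 depth models x
#' 5 target medians x 2 assignment schemes x 100 replicates (a multi-hour
#' run). `"desk"` is the package's reduced default for interactive use and
#' testing: 3 effect sizes (1.00, 1.15, 1.50), both depth models, target
#' medians 1000 and 10000, both assignments, 25 replicates.
#'
#' @param preset `"wnwn"`, `"full"`, or `"desk"`.
#' @param masterSeed master seed (default 1).
#' @return a `"conditionGrid"` (see [conditionGrid()]).
#' @export
#' @examples
#' nrow(gridPreset("wnwn")$conditions) * gridPreset("wnwn")$nReplicates
gridPreset <- function(preset = c("desk", "wnwn", "full"), masterSeed = 1) {
  preset <- match.arg(preset)
  switch(preset,
    wnwn = conditionGrid(effectSizes = .EFFECT_SIZES,
                         depthModels = "empirical_resample",
                         targetMedians = c(1000, 2000, 5000, 10000),
                         assignments = "randomized", filters = TRUE,
                         nReplicates = 5, masterSeed = masterSeed),
    full = conditionGrid(nReplicates = 100, masterSeed = masterSeed,
                         assignments = .ASSIGNMENTS),
    desk = conditionGrid(effectSizes = c(1.00, 1.15, 1.50),
                         targetMedians = c(1000, 10000),
                         assignments = .ASSIGNMENTS, filters = TRUE,
                         nReplicates = 25, masterSeed = masterSeed))
}

#' Count simulated data sets in the original benchmark's design
#'
#' The original Simulation A grid: 8 effect sizes x 4 median sequencing
#' depths x 5 replicates = 160 simulations.
#'
#' @return 160.
#' @export
enumerateWnwnGrid <- function() {
  g <- gridPreset("wnwn")
  nrow(g$conditions) * g$nReplicates
}

#' Count per-data-set processing combinations
#'
#' For each simulated data set the expanded benchmark applies 2 filtering
#' choices x 20 normalizations (raw, relative abundance, variance
#' stabilization, upper-quartile log-fold-change, trimmed-mean-of-M-values,
#' relative-log-expression, and single subsampling and rarefaction at each
#' of 7 library-size quantile thresholds) x 7 distance calculations = 280
#' combinations. TMM, RLE and the BCV distance are counted in the grid but
#' not computed here (their results were never presented in the source
#' analyses).
#'
#' @return 280.
#' @export
enumerateProcessingCombinations <- function() {
  nFilters <- 2L
  nNormalizations <- 4L + 2L + 2L * length(.THRESHOLD_QUANTILES)
  nDistances <- length(.DIST_METHODS) + 1L  # + BCV, counted but not computed
  nFilters * nNormalizations * nDistances
}

# One long-format record row set for a single evaluated cell.
.recordRows <- function(cond, replicate, seed, normalization,
                        thresholdQuantile, distance, measures) {
  data.frame(depth_model = cond$depth_model,
             target_median = cond$target_median,
             assignment = cond$assignment,
             effect_size = cond$effect_size,
             filtered = cond$filtered,
             replicate = replicate,
             seed = seed,
             normalization = normalization,
             threshold_quantile = thresholdQuantile,
             distance = distance,
             measure = names(measures),
             value = unname(unlist(measures)),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Evaluate every requested normalization x distance x analysis on one
# simulated table. Subsampled tables and rarefaction iterations are shared
# across distances so each cell reuses the same draws.
.evaluateReplicate <- function(table, tree, cond, replicate, seed,
                               normalizations, quantiles, distances,
                               clusterMethods, nIterationsRarefy, nPerm,
                               nTop, alphaMetrics) {
  groups <- sampleGroups(table)
  rows <- list()
  pairing <- admissiblePairs()

  analyzeDm <- function(vals, removed, normalization, quantile, distance,
                        admissible) {
    measures <- list()
    if (!admissible) {
      for (m in clusterMethods) measures[[paste0("accuracy_", m)]] <- NA_real_
      measures$p_permanova <- NA_real_
    } else {
      retainedGroups <- groups[rownames(vals)]
      for (m in clusterMethods) {
        labels <- clusterSamples(vals, m, k = 2,
                                 seed = deriveSeed(seed, "cluster", m,
                                                   normalization, quantile,
                                                   distance))
        measures[[paste0("accuracy_", m)]] <-
          clusteringAccuracy(labels, retainedGroups, nRemoved = length(removed))
      }
      measures$p_permanova <- pValue(
        permanova(vals, retainedGroups, nPerm = nPerm,
                  seed = deriveSeed(seed, "permanova", normalization,
                                    quantile, distance)))
    }
    .recordRows(cond, replicate, seed, normalization, quantile, distance,
                measures)
  }

  alphaRows <- function(values, removed, normalization, quantile,
                        doRichness = TRUE, doShannon = TRUE) {
    retainedGroups <- groups[rownames(values)]
    measures <- list()
    if (doRichness) {
      r <- rowSums(values > 0)
      measures$p_wilcoxon_richness <- pValue(wilcoxonTwoSample(
        r[retainedGroups == "A"], r[retainedGroups == "B"], "richness"))
    }
    if (doShannon) {
      s <- vegan::diversity(pmax(values, 0), index = "shannon")
      measures$p_wilcoxon_shannon <- pValue(wilcoxonTwoSample(
        s[retainedGroups == "A"], s[retainedGroups == "B"], "shannon"))
    }
    .recordRows(cond, replicate, seed, normalization, quantile, NA_character_,
                measures)
  }

  for (norm in setdiff(normalizations, c("subsample", "rarefy"))) {
    nt <- switch(norm, raw = normalizeRaw(table),
                 relabund = normalizeRelabund(table),
                 vst = normalizeVst(table),
                 uq_logfc = normalizeUq(table))
    if (norm == "vst") {
      nf <- detectNegativeFraction(nt)
      rows[[length(rows) + 1L]] <-
        .recordRows(cond, replicate, seed, norm, 0, NA_character_,
                    list(negative_fraction = nf$fractionNegative))
    }
    for (dist in distances) {
      admissible <- dist %in% pairing[[norm]]
      vals <- if (admissible)
        .distCore(normValues(nt), dist, tree, norm, nTop, FALSE)
      else matrix(0, 0, 0)
      rows[[length(rows) + 1L]] <-
        analyzeDm(vals, character(), norm, 0, dist, admissible)
    }
    # alpha diversity: vst excluded (negative values); uq gets Shannon only
    # (its output has identical richness in every sample)
    if (alphaMetrics && norm %in% c("raw", "relabund", "uq_logfc"))
      rows[[length(rows) + 1L]] <-
        alphaRows(normValues(nt), character(), norm, 0,
                  doRichness = norm != "uq_logfc")
  }

  for (q in quantiles) {
    if ("subsample" %in% normalizations) {
      params <- pickThreshold(table, q, nIterations = 1,
                              seed = deriveSeed(seed, "subsample", q))
      nt <- subsampleOnce(table, params)
      for (dist in distances) {
        admissible <- dist %in% pairing[["subsample"]]
        vals <- if (admissible)
          .distCore(normValues(nt), dist, tree, "subsample", nTop, FALSE)
        else matrix(0, 0, 0)
        rows[[length(rows) + 1L]] <-
          analyzeDm(vals, params@removedSamples, "subsample", q, dist,
                    admissible)
      }
      if (alphaMetrics)
        rows[[length(rows) + 1L]] <-
          alphaRows(normValues(nt), params@removedSamples, "subsample", q)
    }
    if ("rarefy" %in% normalizations) {
      params <- pickThreshold(table, q, nIterations = nIterationsRarefy,
                              seed = deriveSeed(seed, "rarefy", q))
      rd <- .rarefyAll(table, params, tree, distances, pairing, nTop,
                       alphaMetrics)
      for (dist in distances) {
        admissible <- dist %in% pairing[["rarefy"]]
        rows[[length(rows) + 1L]] <-
          analyzeDm(if (admissible) rd$dms[[dist]] else matrix(0, 0, 0),
                    params@removedSamples, "rarefy", q, dist, admissible)
      }
      if (alphaMetrics) {
        retained <- setdiff(rownames(otuCounts(table)),
                            params@removedSamples)
        gr <- groups[retained]
        measures <- list(
          p_wilcoxon_richness = pValue(wilcoxonTwoSample(
            rd$richness[gr == "A"], rd$richness[gr == "B"], "richness")),
          p_wilcoxon_shannon = pValue(wilcoxonTwoSample(
            rd$shannon[gr == "A"], rd$shannon[gr == "B"], "shannon")))
        rows[[length(rows) + 1L]] <-
          .recordRows(cond, replicate, seed, "rarefy", q, NA_character_,
                      measures)
      }
    }
  }
  do.call(rbind, rows)
}

# Shared rarefaction loop: one set of subsampling draws feeds every
# requested distance matrix plus the alpha metrics, averaged elementwise.
.rarefyAll <- function(table, params, tree, distances, pairing, nTop,
                       alphaMetrics) {
  r <- .retainedCounts(table, params)
  nIter <- as.integer(params@nIterations)
  seeds <- spawnSeeds(if (is.na(params@seed)) NULL else params@seed, nIter)
  wanted <- intersect(distances, pairing[["rarefy"]])
  dms <- stats::setNames(vector("list", length(wanted)), wanted)
  richAcc <- shanAcc <- NULL
  for (i in seq_len(nIter)) {
    sub <- withSeed(seeds[i], suppressWarnings(vegan::rrarefy(r$counts, params@NLm)))
    for (dist in wanted) {
      v <- .distCore(sub, dist, tree, "rarefy", nTop, FALSE)
      dms[[dist]] <- if (is.null(dms[[dist]])) v else dms[[dist]] + v
    }
    if (alphaMetrics) {
      rich <- rowSums(sub > 0)
      shan <- vegan::diversity(sub, index = "shannon")
      richAcc <- if (is.null(richAcc)) rich else richAcc + rich
      shanAcc <- if (is.null(shanAcc)) shan else shanAcc + shan
    }
  }
  list(dms = lapply(dms, function(v) v / nIter),
       richness = if (alphaMetrics) richAcc / nIter,
       shannon = if (alphaMetrics) shanAcc / nIter)
}

#' Run the benchmark over a condition grid
#'
#' For every condition and replicate, simulates one 80-sample count table
#' (shared across all normalization, distance and analysis cells), applies
#' the requested normalizations and distances, clusters the samples, runs
#' PERMANOVA, and (optionally) the alpha-diversity Wilcoxon tests, emitting
#' one long-format record per measured quantity. Every cell's seed is
#' derived from the master seed and the cell's key, so reruns are
#' reproducible and adding conditions never perturbs existing cells.
#'
#' With `outDir` set, each (condition, replicate) chunk is written as a TSV
#' with an MD5 payload checksum; an interrupted run resumes by reloading
#' verified chunks and recomputing the rest.
#'
#' @param grid a `"conditionGrid"` (see [conditionGrid()], [gridPreset()]).
#' @param parents a [ParentPair-class] shared by the whole grid.
#' @param normalizations subset of `"raw"`, `"relabund"`, `"vst"`,
#'   `"uq_logfc"`, `"subsample"`, `"rarefy"`.
#' @param quantiles library-size threshold percentiles for subsampling and
#'   rarefaction (default 0).
#' @param distances distance methods to evaluate; inadmissible
#'   normalization-distance pairs are recorded as `NA` cells, never dropped.
#' @param clusterMethods subset of `"pam"`, `"kmeans"`, `"hclust"`.
#' @param nIterationsRarefy rarefaction iterations (default 25; 100 is the
#'   conventional full-scale choice).
#' @param nPerm PERMANOVA permutations (default 999).
#' @param nTop top-MSD window (default 500, clamped to the OTU count).
#' @param alphaMetrics also test richness and Shannon diversity between
#'   groups (default `TRUE`).
#' @param outDir optional directory for resumable chunk files and the final
#'   `records.tsv`.
#' @param verbose print per-condition progress to stderr.
#' @return a long-format data frame of run records with columns
#'   `depth_model`, `target_median`, `assignment`, `effect_size`,
#'   `filtered`, `replicate`, `seed`, `normalization`,
#'   `threshold_quantile`, `distance`, `measure`, `value`.
#' @export
#' @examples
#' pp <- makeSyntheticParents(nOtus = 60, seed = 1)
#' g <- conditionGrid(effectSizes = 1.5, targetMedians = 1000,
#'                    depthModels = "log_scaled", nReplicates = 2)
#' rec <- runGrid(g, pp, normalizations = c("raw", "subsample"),
#'                distances = "bray", nPerm = 99, alphaMetrics = FALSE)
#' head(rec)
runGrid <- function(grid, parents,
                    normalizations = c("raw", "relabund", "vst", "uq_logfc",
                                       "subsample", "rarefy"),
                    quantiles = 0,
                    distances = c("bray", "euclidean", "unifrac_w",
                                  "top_msd"),
                    clusterMethods = c("pam", "kmeans", "hclust"),
                    nIterationsRarefy = 25, nPerm = 999, nTop = 500,
                    alphaMetrics = TRUE, outDir = NULL, verbose = FALSE) {
  stopifnot(inherits(grid, "conditionGrid"), is(parents, "ParentPair"),
            all(normalizations %in% .NORM_METHODS),
            all(quantiles %in% .THRESHOLD_QUANTILES),
            all(distances %in% .DIST_METHODS))
  conditions <- grid$conditions
  master <- grid$masterSeed
  tree <- parentTree(parents)
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  # the 26 emulated base depths are fixed data shared by the whole grid
  empiricalBase <- makeEmpiricalDepths(seed = deriveSeed(master,
                                                         "empirical_base"))
  chunks <- list()
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, , drop = FALSE]
    if (verbose)
      message(sprintf("condition %d/%d: %s median=%d %s effect=%.2f%s",
                      ci, nrow(conditions), cond$depth_model,
                      cond$target_median, cond$assignment, cond$effect_size,
                      if (cond$filtered) " filtered" else ""))
    model <- depthModel(cond$depth_model, targetMedian = cond$target_median,
                        assignment = cond$assignment,
                        baseDepths = if (cond$depth_model ==
                                         "empirical_resample") empiricalBase)
    for (rep in seq_len(grid$nReplicates)) {
      seed <- deriveSeed(master, cond$depth_model, cond$target_median,
                         cond$assignment, cond$effect_size, cond$filtered,
                         rep)
      chunkFile <- if (!is.null(outDir))
        file.path(outDir, sprintf("rec_%d.tsv", seed))
      if (!is.null(chunkFile) && file.exists(chunkFile)) {
        chunk <- .readChunk(chunkFile)
        if (!is.null(chunk)) { chunks[[length(chunks) + 1L]] <- chunk; next }
      }
      assignment <- assignDepths(model, seed = deriveSeed(seed, "depths"))
      table <- simulateCounts(parents, cond$effect_size, assignment,
                              seed = deriveSeed(seed, "counts"))
      if (cond$filtered) table <- filterRareOtus(table)
      chunk <- .evaluateReplicate(table, tree, cond, rep, seed,
                                  normalizations, quantiles, distances,
                                  clusterMethods, nIterationsRarefy, nPerm,
                                  min(nTop, ncol(otuCounts(table))),
                                  alphaMetrics)
      if (!is.null(chunkFile)) .writeChunk(chunk, chunkFile)
      chunks[[length(chunks) + 1L]] <- chunk
    }
  }
  records <- do.call(rbind, chunks)
  rownames(records) <- NULL
  if (!is.null(outDir))
    utils::write.table(records, file.path(outDir, "records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  records
}

.writeChunk <- function(chunk, path) {
  tmp <- paste0(path, ".tmp")
  con <- textConnection("payload", "w", local = TRUE)
  utils::write.table(chunk, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  payload <- paste0(paste(payload, collapse = "\n"), "\n")
  writeLines(c(sprintf("# md5:%s", .md5string(payload)),
               sub("\n$", "", payload)), tmp)
  file.rename(tmp, path)
}

.readChunk <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || !startsWith(lines[1], "# md5:")) return(NULL)
  payload <- paste0(paste(lines[-1], collapse = "\n"), "\n")
  if (!identical(sub("^# md5:", "", lines[1]), .md5string(payload)))
    return(NULL)  # partial or corrupt write: recompute this cell
  utils::read.table(text = payload, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

.md5string <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeChar(x, tmp, eos = NULL)
  unname(tools::md5sum(tmp))
}

#' Summarize accuracy records per condition
#'
#' Medians, empirical 95% intervals (2.5 and 97.5 percentiles) and
#' interquartile ranges of the accuracy measures across replicates, per
#' condition x normalization x distance x clustering method.
#'
#' @param records long-format run records from [runGrid()].
#' @param measures which measures to summarize (default the accuracy
#'   measures present).
#' @return a data frame with one row per condition cell and columns
#'   `median`, `ci_lo`, `ci_hi`, `iqr`, `n`.
#' @export
summarizeRecords <- function(records,
                             measures = grep("^accuracy_", records$measure,
                                             value = TRUE)) {
  sub <- records[records$measure %in% measures & !is.na(records$value), ,
                 drop = FALSE]
  if (nrow(sub) == 0) stop("no records to summarize")
  keyCols <- intersect(c("depth_model", "target_median", "assignment",
                         "effect_size", "filtered", "normalization",
                         "threshold_quantile", "distance", "measure"),
                       names(sub))
  key <- interaction(sub[keyCols], drop = TRUE, sep = "\1")
  out <- do.call(rbind, lapply(split(seq_len(nrow(sub)), key), function(ix) {
    row <- sub[ix[1], keyCols, drop = FALSE]
    v <- sub$value[ix]
    row$n <- length(v)
    row$median <- stats::median(v)
    qs <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
    row$ci_lo <- qs[1]
    row$ci_hi <- qs[2]
    row$iqr <- stats::IQR(v)
    row
  }))
  rownames(out) <- NULL
  out
}
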