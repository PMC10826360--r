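#' @include AllClasses.R
NULL

#' Construct a CountTable
#'
#' @param counts nonnegative integer matrix, samples in rows, OTUs in
#'   columns. Unnamed dimensions get `S..`/`OTU..` names.
#' @param groups group label per sample.
#' @param effectSize mixing effect size for simulated tables (`NA` for real
#'   data).
#' @return a [CountTable-class].
#' @export
countTable <- function(counts, groups, effectSize = NA_real_) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("S%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("OTU%04d", seq_len(ncol(counts)))
  methods::new("CountTable", counts = counts, groups = as.character(groups),
               effectSize = as.numeric(effectSize))
}

#' Mix two parent distributions at a given effect size
#'
#' Each treatment group's community is a renormalized mixture that up-weights
#' its own parent by the effect size: group A receives
#' `effectSize * pA + pB` and group B receives `pA + effectSize * pB`. An
#' effect size of 1.00 makes the two mixtures identical (the null model), and
#' the separation between the mixtures is monotone in the effect size.
#'
#' @param parents a [ParentPair-class].
#' @param effectSize multiplier `>= 1`; the conventional menu is 1.00, 1.15,
#'   1.25, 1.50, 1.75, 2.00, 2.50, 3.50.
#' @return a list with probability vectors `mixA` and `mixB` (each sums
#'   to 1).
#' @export
#' @examples
#' pp <- makeSyntheticParents(nOtus = 50, seed = 1)
#' m <- mixParents(pp, 1.00)
#' all.equal(m$mixA, m$mixB)
mixParents <- function(parents, effectSize) {
  stopifnot(is(parents, "ParentPair"))
  if (effectSize < 1) stop("effectSize must be >= 1")
  a <- effectSize * parents@pA + parents@pB
  b <- parents@pA + effectSize * parents@pB
  list(mixA = stats::setNames(a / sum(a), parents@otuIds),
       mixB = stats::setNames(b / sum(b), parents@otuIds))
}

#' Draw multinomial community samples at assigned depths
#'
#' Each of the 80 samples is an independent multinomial draw of its assigned
#' library size from its treatment group's mixture, so row sums equal the
#' assigned depths exactly.
#'
#' @param mixA,mixB probability vectors over the same OTU index (sums to 1).
#' @param assignment a [DepthAssignment-class].
#' @param seed integer seed; fixed seed gives a bit-identical table.
#' @param effectSize effect size recorded on the table (bookkeeping only).
#' @return a [CountTable-class] of 80 samples.
#' @export
drawSamples <- function(mixA, mixB, assignment, seed = NULL,
                        effectSize = NA_real_) {
  stopifnot(is(assignment, "DepthAssignment"))
  if (abs(sum(mixA) - 1) > 1e-8 || abs(sum(mixB) - 1) > 1e-8)
    stop("mixture vectors must each sum to 1")
  if (length(mixA) != length(mixB))
    stop("mixture vectors must share one OTU index")
  depths <- assignment@depths
  groups <- assignment@groups
  withSeed(seed, {
    counts <- matrix(0, nrow = 80L, ncol = length(mixA),
                     dimnames = list(names(depths),
                                     names(mixA) %||%
                                       sprintf("OTU%04d", seq_along(mixA))))
    for (i in seq_len(80L)) {
      p <- if (groups[i] == "A") mixA else mixB
      counts[i, ] <- stats::rmultinom(1, size = depths[i], prob = p)
    }
    countTable(counts, groups = groups, effectSize = effectSize)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate one 80-sample count table from parents
#'
#' Convenience wrapper: mixes the parents at the requested effect size and
#' draws the multinomial samples at the assigned depths.
#'
#' @inheritParams mixParents
#' @inheritParams drawSamples
#' @return a [CountTable-class].
#' @export
#' @examples
#' pp <- makeSyntheticParents(nOtus = 50, seed = 1)
#' a <- assignDepths(depthModel("log_scaled", targetMedian = 1000), seed = 2)
#' tab <- simulateCounts(pp, 1.15, a, seed = 3)
simulateCounts <- function(parents, effectSize, assignment, seed = NULL) {
  mix <- mixParents(parents, effectSize)
  drawSamples(mix$mixA, mix$mixB, assignment, seed = seed,
              effectSize = effectSize)
}

#' Two-step rare-OTU filter
#'
#' Step 1 removes an OTU only if its total abundance across all samples is
#' below 3 *and* it appears in fewer than 3 samples. Step 2 removes an OTU
#' only if it has more than one read in at most 5% of the samples *and* its
#' total abundance is at most half the per-group sample count (20 reads for
#' 40-sample groups). Each step reads the removal rule as a conjunction: an
#' OTU survives a step by passing either of its two clauses. Surviving
#' columns keep their order and counts; samples are never removed. The filter
#' is idempotent.
#'
#' @param table a [CountTable-class] (the canonical input has 80 samples).
#' @return the filtered [CountTable-class].
#' @export
filterRareOtus <- function(table) {
  stopifnot(is(table, "CountTable"))
  cc <- otuCounts(table)
  n <- nrow(cc)
  total <- colSums(cc)
  prevalence <- colSums(cc > 0)
  drop1 <- total < 3 & prevalence < 3
  cc <- cc[, !drop1, drop = FALSE]
  nGt1 <- colSums(cc > 1)
  total <- colSums(cc)
  drop2 <- nGt1 <= 0.05 * n & total <= n / 4
  cc <- cc[, !drop2, drop = FALSE]
  if (ncol(cc) == 0)
    stop("no OTUs survive the two-step rare-OTU filter")
  countTable(cc, groups = table@groups, effectSize = table@effectSize)
}
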