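setOldClass("phylo")

.DEPTH_KINDS <- c("empirical_resample", "log_scaled")
.ASSIGNMENTS <- c("randomized", "confounded")
.TARGET_MEDIANS <- c(1000, 2000, 5000, 10000, 50000)
.EFFECT_SIZES <- c(1.00, 1.15, 1.25, 1.50, 1.75, 2.00, 2.50, 3.50)
.NORM_METHODS <- c("raw", "relabund", "vst", "uq_logfc", "subsample", "rarefy")
.THRESHOLD_QUANTILES <- c(0, 5, 10, 15, 20, 25, 40)
.DIST_METHODS <- c("bray", "euclidean", "poisson", "unifrac_u", "unifrac_w",
                   "top_msd")

#' Pair of parent community distributions with a shared phylogeny
#'
#' Holds the two relative-abundance vectors that seed every simulated
#' treatment group, plus a rooted phylogeny over the same OTU set used for
#' UniFrac distances. Both vectors are defined on an identical OTU index and
#' sum to one.
#'
#' @slot otuIds character vector of OTU identifiers.
#' @slot pA,pB numeric relative-abundance vectors over `otuIds`, each summing
#'   to 1.
#' @slot tree a rooted `ape::phylo` tree with branch lengths whose tips are
#'   exactly `otuIds`.
#' @seealso [makeSyntheticParents()], [buildParentsFromCounts()]
#' @export
setClass("ParentPair",
  representation(otuIds = "character", pA = "numeric", pB = "numeric",
                 tree = "phylo"))

setValidity("ParentPair", function(object) {
  msg <- character()
  n <- length(object@otuIds)
  if (length(object@pA) != n || length(object@pB) != n)
    msg <- c(msg, "pA, pB and otuIds must have identical length")
  if (any(object@pA < 0) || any(object@pB < 0))
    msg <- c(msg, "parent abundances must be nonnegative")
  if (abs(sum(object@pA) - 1) > 1e-12 || abs(sum(object@pB) - 1) > 1e-12)
    msg <- c(msg, "parent abundances must each sum to 1 within 1e-12")
  if (!setequal(object@tree$tip.label, object@otuIds) ||
      length(object@tree$tip.label) != n)
    msg <- c(msg, "tree tips must map one-to-one onto otuIds")
  if (length(msg)) msg else TRUE
})

#' Sequencing-depth model
#'
#' Describes how the 80 per-sample library sizes of one simulated data set are
#' generated: resampling with replacement from 26 empirical depths, or using
#' each of 80 log-spaced depths exactly once; how they are rescaled to a
#' target median; and whether depth is randomized across or fully confounded
#' with the treatment groups.
#'
#' @slot kind `"empirical_resample"` (26 base depths, drawn with replacement)
#'   or `"log_scaled"` (80 base depths, each used once).
#' @slot baseDepths integer vector of base library sizes (reads).
#' @slot targetMedian the median library size the 80 depths are scaled to;
#'   one of 1000, 2000, 5000, 10000, 50000 reads.
#' @slot assignment `"randomized"` or `"confounded"`.
#' @seealso [depthModel()], [assignDepths()]
#' @export
setClass("DepthModel",
  representation(kind = "character", baseDepths = "numeric",
                 targetMedian = "numeric", assignment = "character"))

setValidity("DepthModel", function(object) {
  msg <- character()
  if (!object@kind %in% .DEPTH_KINDS)
    msg <- c(msg, sprintf("kind must be one of %s",
                          paste(.DEPTH_KINDS, collapse = ", ")))
  if (any(object@baseDepths < 1))
    msg <- c(msg, "all base depths must be >= 1 read")
  n.expected <- if (identical(object@kind, "empirical_resample")) 26L else 80L
  if (length(object@baseDepths) != n.expected)
    msg <- c(msg, sprintf("%s models carry %d base depths, got %d",
                          object@kind, n.expected, length(object@baseDepths)))
  if (!object@targetMedian %in% .TARGET_MEDIANS)
    msg <- c(msg, sprintf("targetMedian must be one of %s",
                          paste(.TARGET_MEDIANS, collapse = ", ")))
  if (!object@assignment %in% .ASSIGNMENTS)
    msg <- c(msg, sprintf("assignment must be one of %s",
                          paste(.ASSIGNMENTS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Per-sample library sizes and treatment labels
#'
#' The realized depths for one simulated data set: 80 library sizes scaled so
#' their median hits the model's target, and 80 group labels (40 `"A"`,
#' 40 `"B"`), either shuffled independently of depth or fully confounded with
#' it.
#'
#' @slot depths integer vector of 80 library sizes (reads), named by sample.
#' @slot groups character vector of 80 labels in `{"A","B"}`, 40 of each.
#' @slot targetMedian the median the depths were scaled to (reads).
#' @seealso [assignDepths()]
#' @export
setClass("DepthAssignment",
  representation(depths = "numeric", groups = "character",
                 targetMedian = "numeric"))

setValidity("DepthAssignment", function(object) {
  msg <- character()
  if (length(object@depths) != 80L || length(object@groups) != 80L)
    msg <- c(msg, "a depth assignment covers exactly 80 samples")
  if (any(object@depths < 1))
    msg <- c(msg, "depths must be >= 1 read")
  tab <- table(factor(object@groups, levels = c("A", "B")))
  if (!all(tab == 40L))
    msg <- c(msg, "groups must contain exactly 40 'A' and 40 'B' labels")
  if (length(msg)) msg else TRUE
})

#' OTU count table
#'
#' An integer samples-by-OTU count matrix together with treatment-group
#' labels and, for simulated tables, the effect size that generated it.
#' Library sizes are the row sums. Unlike the simulated 80-sample tables, a
#' loaded real table may have any number of samples.
#'
#' @slot counts nonnegative integer matrix, samples in rows, OTUs in columns,
#'   with row and column names.
#' @slot groups character group label per sample (row).
#' @slot effectSize the mixing effect size used to simulate the table, or
#'   `NA` for real data.
#' @seealso [drawSamples()], [filterRareOtus()], [readCountTable()]
#' @export
setClass("CountTable",
  representation(counts = "matrix", groups = "character",
                 effectSize = "numeric"))

setValidity("CountTable", function(object) {
  msg <- character()
  cc <- object@counts
  if (is.null(rownames(cc)) || is.null(colnames(cc)))
    msg <- c(msg, "counts must have sample rownames and OTU colnames")
  if (any(cc < 0) || any(cc != round(cc)))
    msg <- c(msg, "counts must be nonnegative integers")
  if (length(object@groups) != nrow(cc))
    msg <- c(msg, "one group label is required per sample")
  if (length(msg)) msg else TRUE
})

#' Normalized abundance table
#'
#' A real-valued samples-by-OTU matrix produced by one of the normalization
#' strategies, carrying its provenance: the method, the minimum-library-size
#' quantile threshold, the samples removed for falling below the threshold,
#' and (for rarefaction) the number of subsampling iterations. Only the
#' variance-stabilized method may contain negative values.
#'
#' @slot values numeric matrix, retained samples in rows, OTUs in columns.
#' @slot method one of `"raw"`, `"relabund"`, `"vst"`, `"uq_logfc"`,
#'   `"subsample"`, `"rarefy"`.
#' @slot thresholdQuantile minimum-library-size percentile in
#'   `{0,5,10,15,20,25,40}`.
#' @slot nIterations subsampling iterations (rarefaction only; otherwise 1).
#' @slot removedSamples ids of samples whose depth fell below the threshold.
#' @slot groups group label per retained sample.
#' @slot provenance free-form list (seed, size factors, dispersion fit, ...).
#' @export
setClass("NormalizedTable",
  representation(values = "matrix", method = "character",
                 thresholdQuantile = "numeric", nIterations = "numeric",
                 removedSamples = "character", groups = "character",
                 provenance = "list"))

setValidity("NormalizedTable", function(object) {
  msg <- character()
  if (!object@method %in% .NORM_METHODS)
    msg <- c(msg, sprintf("method must be one of %s",
                          paste(.NORM_METHODS, collapse = ", ")))
  if (!object@thresholdQuantile %in% .THRESHOLD_QUANTILES)
    msg <- c(msg, "thresholdQuantile must be one of 0, 5, 10, 15, 20, 25, 40")
  if (length(object@groups) != nrow(object@values))
    msg <- c(msg, "one group label is required per retained sample")
  if (any(object@removedSamples %in% rownames(object@values)))
    msg <- c(msg, "removed samples may not also be retained")
  if (object@method != "vst" && any(object@values < 0))
    msg <- c(msg, "negative values are only allowed for the vst method")
  if (length(msg)) msg else TRUE
})

#' Rarefaction parameters
#'
#' The minimum library size \eqn{N_{L,m}}, the number of subsampling
#' iterations, the seed driving the draws, and the samples discarded for
#' having fewer than \eqn{N_{L,m}} reads.
#'
#' @slot NLm minimum library size (reads); samples below it are discarded.
#' @slot nIterations number of independent subsamplings (1 = single
#'   subsampling; 100 is the conventional rarefaction default).
#' @slot seed integer seed for the subsampling draws.
#' @slot thresholdQuantile the library-size percentile `NLm` was picked at.
#' @slot removedSamples ids of samples with depth below `NLm`.
#' @seealso [pickThreshold()], [subsampleOnce()], [rarefyMetric()]
#' @export
setClass("RarefactionParams",
  representation(NLm = "numeric", nIterations = "numeric", seed = "numeric",
                 thresholdQuantile = "numeric", removedSamples = "character"))

setValidity("RarefactionParams", function(object) {
  msg <- character()
  if (object@NLm < 1) msg <- c(msg, "NLm must be >= 1 read")
  if (object@nIterations < 1) msg <- c(msg, "nIterations must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Pairwise sample dissimilarity matrix
#'
#' A symmetric, zero-diagonal matrix of pairwise dissimilarities over the
#' retained samples, tagged with the distance method and the normalization it
#' was computed from.
#'
#' @slot values symmetric numeric matrix with zero diagonal, row/column names
#'   the retained sample ids.
#' @slot method one of `"bray"`, `"euclidean"`, `"poisson"`, `"unifrac_u"`,
#'   `"unifrac_w"`, `"top_msd"`.
#' @slot normalization the normalization method the input table came from.
#' @slot removedSamples ids of samples excluded before the calculation.
#' @export
setClass("DistanceMatrix",
  representation(values = "matrix", method = "character",
                 normalization = "character", removedSamples = "character"))

setValidity("DistanceMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  if (nrow(v) > 0) {
    if (max(abs(v - t(v))) > 1e-10) msg <- c(msg, "values must be symmetric")
    if (max(abs(diag(v))) > 1e-10) msg <- c(msg, "diagonal must be zero")
  }
  if (!object@method %in% .DIST_METHODS)
    msg <- c(msg, sprintf("method must be one of %s",
                          paste(.DIST_METHODS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Result of a hypothesis test
#'
#' Statistic and p-value from a PERMANOVA on a distance matrix or a two-sample
#' Wilcoxon test on an alpha-diversity metric.
#'
#' @slot statistic the pseudo-F (PERMANOVA) or rank-sum W (Wilcoxon); may be
#'   `NA` for degenerate inputs.
#' @slot pValue p-value in (0, 1].
#' @slot test `"permanova"` or `"wilcoxon"`.
#' @slot metric what was tested: a distance method, `"richness"`, or
#'   `"shannon"`.
#' @export
setClass("HypothesisResult",
  representation(statistic = "numeric", pValue = "numeric",
                 test = "character", metric = "character"))

setValidity("HypothesisResult", function(object) {
  msg <- character()
  if (!is.na(object@pValue) &&
      (object@pValue <= 0 || object@pValue > 1))
    msg <- c(msg, "pValue must lie in (0, 1]")
  if (!object@test %in% c("permanova", "wilcoxon"))
    msg <- c(msg, "test must be 'permanova' or 'wilcoxon'")
  if (length(msg)) msg else TRUE
})
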