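#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("otuIds", "ParentPair", function(object) object@otuIds)

#' @rdname accessors
#' @export
setMethod("otuIds", "CountTable", function(object) colnames(object@counts))

#' @rdname accessors
#' @export
setMethod("otuIds", "NormalizedTable", function(object) colnames(object@values))

#' Parent relative-abundance vectors and tree
#'
#' @param object a [ParentPair-class].
#' @return `parentA`/`parentB` a named relative-abundance vector; `parentTree`
#'   the `ape::phylo` tree over the OTUs.
#' @export
parentA <- function(object) {
  stopifnot(is(object, "ParentPair"))
  stats::setNames(object@pA, object@otuIds)
}

#' @rdname parentA
#' @export
parentB <- function(object) {
  stopifnot(is(object, "ParentPair"))
  stats::setNames(object@pB, object@otuIds)
}

#' @rdname parentA
#' @export
parentTree <- function(object) {
  stopifnot(is(object, "ParentPair"))
  object@tree
}

#' @rdname accessors
#' @export
setMethod("sampleDepths", "DepthAssignment", function(object) {
  stats::setNames(object@depths, names(object@depths))
})

#' @rdname accessors
#' @export
setMethod("sampleDepths", "CountTable", function(object) rowSums(object@counts))

#' @rdname accessors
#' @export
setMethod("sampleGroups", "DepthAssignment", function(object) {
  stats::setNames(object@groups, names(object@depths))
})

#' @rdname accessors
#' @export
setMethod("sampleGroups", "CountTable", function(object) {
  stats::setNames(object@groups, rownames(object@counts))
})

#' @rdname accessors
#' @export
setMethod("sampleGroups", "NormalizedTable", function(object) {
  stats::setNames(object@groups, rownames(object@values))
})

#' @rdname accessors
#' @export
setMethod("otuCounts", "CountTable", function(object) object@counts)

#' @rdname accessors
#' @export
setMethod("normValues", "NormalizedTable", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("distValues", "DistanceMatrix", function(object) object@values)

#' Effect size that generated a simulated table
#' @param object a [CountTable-class].
#' @return the mixing effect size, or `NA` for real data.
#' @export
effectSize <- function(object) {
  stopifnot(is(object, "CountTable"))
  object@effectSize
}

#' Normalization provenance accessors
#' @param object a [NormalizedTable-class] or [DistanceMatrix-class].
#' @return `normMethod`/`distMethod` a string; `removedSamples` a character
#'   vector of discarded sample ids.
#' @export
normMethod <- function(object) {
  stopifnot(is(object, "NormalizedTable"))
  object@method
}

#' @rdname normMethod
#' @export
distMethod <- function(object) {
  stopifnot(is(object, "DistanceMatrix"))
  object@method
}

#' @rdname normMethod
#' @export
removedSamples <- function(object) {
  if (is(object, "NormalizedTable") || is(object, "DistanceMatrix") ||
      is(object, "RarefactionParams"))
    return(object@removedSamples)
  stop("no removed-sample bookkeeping on this object")
}

#' Minimum library size of a rarefaction parameter set
#' @param object a [RarefactionParams-class].
#' @return the minimum library size in reads.
#' @export
minLibrarySize <- function(object) {
  stopifnot(is(object, "RarefactionParams"))
  object@NLm
}

#' p-value and statistic of a test result
#' @param object a [HypothesisResult-class].
#' @return `pValue` the p-value; `testStatistic` the pseudo-F or W statistic.
#' @export
pValue <- function(object) {
  stopifnot(is(object, "HypothesisResult"))
  object@pValue
}

#' @rdname pValue
#' @export
testStatistic <- function(object) {
  stopifnot(is(object, "HypothesisResult"))
  object@statistic
}

#' @export
#' @describeIn DistanceMatrix-class coerce to a base `dist` object.
#' @param m a [DistanceMatrix-class].
as.dist.DistanceMatrix <- function(m, ...) stats::as.dist(m@values)

setMethod("show", "ParentPair", function(object) {
  cat(sprintf("ParentPair: %d OTUs (%d shared between parents)\n",
              length(object@otuIds),
              sum(object@pA > 0 & object@pB > 0)))
  cat(sprintf("  parent A support: %d OTUs; parent B support: %d OTUs\n",
              sum(object@pA > 0), sum(object@pB > 0)))
  cat(sprintf("  tree: %d tips, %d internal nodes\n",
              length(object@tree$tip.label), object@tree$Nnode))
})

setMethod("show", "DepthModel", function(object) {
  cat(sprintf("DepthModel: %s (%d base depths), target median %s reads, %s\n",
              object@kind, length(object@baseDepths),
              format(object@targetMedian, big.mark = ","),
              object@assignment))
})

setMethod("show", "DepthAssignment", function(object) {
  cat(sprintf(
    "DepthAssignment: 80 samples, depths %s-%s (median %s), %s\n",
    format(min(object@depths), big.mark = ","),
    format(max(object@depths), big.mark = ","),
    format(stats::median(object@depths), big.mark = ","),
    paste(names(table(object@groups)), table(object@groups),
          sep = "=", collapse = ", ")))
})

setMethod("show", "CountTable", function(object) {
  cat(sprintf("CountTable: %d samples x %d OTUs", nrow(object@counts),
              ncol(object@counts)))
  if (!is.na(object@effectSize))
    cat(sprintf(", effect size %.2f", object@effectSize))
  cat(sprintf("\n  depths %s-%s (median %s)\n",
              format(min(rowSums(object@counts)), big.mark = ","),
              format(max(rowSums(object@counts)), big.mark = ","),
              format(stats::median(rowSums(object@counts)), big.mark = ",")))
})

setMethod("show", "NormalizedTable", function(object) {
  cat(sprintf(
    "NormalizedTable (%s): %d retained samples x %d OTUs, threshold q%d",
    object@method, nrow(object@values), ncol(object@values),
    as.integer(object@thresholdQuantile)))
  if (object@method == "rarefy")
    cat(sprintf(", %d iterations", as.integer(object@nIterations)))
  cat(sprintf("; %d samples removed\n", length(object@removedSamples)))
})

setMethod("show", "RarefactionParams", function(object) {
  cat(sprintf(
    "RarefactionParams: N_L,m = %s reads, %d iteration(s), %d sample(s) removed\n",
    format(object@NLm, big.mark = ","), as.integer(object@nIterations),
    length(object@removedSamples)))
})

setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix (%s on %s): %d x %d samples\n",
              object@method, object@normalization, nrow(object@values),
              ncol(object@values)))
})

setMethod("show", "HypothesisResult", function(object) {
  cat(sprintf("%s on %s: statistic = %.4g, p = %.4g\n", object@test,
              object@metric, object@statistic, object@pValue))
})
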