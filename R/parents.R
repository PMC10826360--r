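#' @include AllClasses.R
NULL

#' Construct a ParentPair
#'
#' Low-level constructor; most users will call [makeSyntheticParents()] or
#' [buildParentsFromCounts()].
#'
#' @param otuIds character OTU identifiers.
#' @param pA,pB nonnegative abundance vectors over `otuIds`; renormalized to
#'   sum to 1.
#' @param tree rooted `ape::phylo` tree whose tips are exactly `otuIds`.
#' @return a [ParentPair-class].
#' @export
newParentPair <- function(otuIds, pA, pB, tree) {
  methods::new("ParentPair", otuIds = as.character(otuIds),
               pA = pA / sum(pA), pB = pB / sum(pB), tree = tree)
}

# Random bifurcating topology with exponential(1) branch lengths over the
# given tips; a synthetic stand-in used when no real phylogeny is supplied.
randomOtuTree <- function(otuIds, seed = NULL) {
  withSeed(seed, {
    tree <- ape::rtree(length(otuIds), rooted = TRUE, br = stats::rexp)
    tree$tip.label <- otuIds[as.integer(sub("^t", "", tree$tip.label))]
    tree
  })
}

#' Generate a synthetic pair of parent community distributions
#'
#' Emulates the structure of two pooled real communities: two lognormal
#' species-abundance distributions over a common OTU index, sharing a
#' configurable fraction of their support, together with a random bifurcating
#' phylogeny (exponential(1) branch lengths) over the OTUs. The non-shared
#' OTUs are split evenly between the two parents' private supports.
#'
#' @param nOtus number of OTUs (default 2000, the size of the pooled parent
#'   distributions this generator emulates).
#' @param overlapFraction fraction of OTUs present in both parents, in
#'   `[0, 1]`. The default 0.45 mirrors the reported sharing between the two
#'   real parent communities (roughly 900 of 2,000 OTUs).
#' @param sadShape lognormal sigma of the species-abundance distribution
#'   (default 2.0).
#' @param seed integer seed; fixed seed gives a bit-identical pair.
#' @return a [ParentPair-class].
#' @export
#' @examples
#' pp <- makeSyntheticParents(nOtus = 100, overlapFraction = 0.6, seed = 1)
#' sum(parentA(pp) > 0 & parentB(pp) > 0)  # 60 shared OTUs
makeSyntheticParents <- function(nOtus = 2000, overlapFraction = 0.45,
                                 sadShape = 2.0, seed = NULL) {
  if (nOtus < 10) stop("nOtus must be >= 10")
  if (overlapFraction < 0 || overlapFraction > 1)
    stop("overlapFraction must lie in [0, 1]")
  if (sadShape <= 0) stop("sadShape must be positive")
  otuIds <- sprintf("OTU%04d", seq_len(nOtus))
  nShared <- as.integer(ceiling(overlapFraction * nOtus))
  nRest <- nOtus - nShared
  nAOnly <- nRest %/% 2L
  suppA <- seq_len(nShared + nAOnly)
  suppB <- c(seq_len(nShared),
             if (nRest > nAOnly) (nShared + nAOnly + 1L):nOtus else integer())
  withSeed(seed, {
    pA <- numeric(nOtus)
    pB <- numeric(nOtus)
    pA[suppA] <- stats::rlnorm(length(suppA), meanlog = 0, sdlog = sadShape)
    pB[suppB] <- stats::rlnorm(length(suppB), meanlog = 0, sdlog = sadShape)
    tree <- ape::rtree(nOtus, rooted = TRUE, br = stats::rexp)
    tree$tip.label <- otuIds[as.integer(sub("^t", "", tree$tip.label))]
    newParentPair(otuIds, pA, pB, tree)
  })
}

#' Build parent distributions from a real count table
#'
#' Follows the pooling recipe used to derive the two parent communities from
#' real data: keep OTUs observed in more than one of the pooled samples, sort
#' by prevalence (descending) then by total abundance (descending), take the
#' first `nTop`, then pool counts within each sample group and convert to
#' proportions.
#'
#' @param table a [CountTable-class] of real samples.
#' @param groupASamples,groupBSamples sample ids forming the two pools.
#' @param nTop number of top-ranked OTUs to keep (default 2000).
#' @param tree optional `ape::phylo` covering at least the selected OTUs; it
#'   is pruned to them. When `NULL`, a random synthetic tree is simulated.
#' @param seed seed for the synthetic tree when `tree` is `NULL`.
#' @return a [ParentPair-class].
#' @export
buildParentsFromCounts <- function(table, groupASamples, groupBSamples,
                                   nTop = 2000, tree = NULL, seed = NULL) {
  stopifnot(is(table, "CountTable"))
  cc <- otuCounts(table)
  pooled <- c(groupASamples, groupBSamples)
  missing <- setdiff(pooled, rownames(cc))
  if (length(missing))
    stop("sample id(s) not in table: ", paste(missing, collapse = ", "))
  sub <- cc[pooled, , drop = FALSE]
  prevalence <- colSums(sub > 0)
  total <- colSums(sub)
  qualifying <- which(prevalence > 1)
  if (length(qualifying) < nTop)
    stop(sprintf(paste0("only %d OTUs appear in more than one pooled sample; ",
                        "%d requested (shortfall of %d)"),
                 length(qualifying), nTop, nTop - length(qualifying)))
  ord <- qualifying[.orderDesc2(prevalence[qualifying], total[qualifying])]
  keep <- sort(ord[seq_len(nTop)])  # preserve original column order
  ids <- colnames(cc)[keep]
  pA <- colSums(cc[groupASamples, keep, drop = FALSE])
  pB <- colSums(cc[groupBSamples, keep, drop = FALSE])
  if (sum(pA) == 0 || sum(pB) == 0)
    stop("a pooled group has zero total abundance over the selected OTUs")
  if (is.null(tree)) {
    tree <- randomOtuTree(ids, seed = seed)
  } else {
    absent <- setdiff(ids, tree$tip.label)
    if (length(absent))
      stop("tree is missing OTU(s): ", paste(utils::head(absent, 5),
                                             collapse = ", "))
    tree <- ape::keep.tip(tree, ids)
  }
  newParentPair(ids, pA, pB, tree)
}
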