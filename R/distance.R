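#' @include AllClasses.R
NULL

# Admissible (normalization, distance) pairings. The variance-stabilized
# table pairs only with Euclidean distances by default; the "pathology" flag
# additionally allows the negative-value-sensitive pairings (Bray-Curtis,
# weighted UniFrac) for studying exactly that failure mode.
.PAIRING <- list(
  raw       = c("bray", "euclidean", "poisson", "unifrac_w"),
  relabund  = c("bray", "unifrac_u", "unifrac_w"),
  subsample = c("bray", "euclidean", "poisson", "unifrac_u", "unifrac_w",
                "top_msd"),
  rarefy    = c("bray", "euclidean", "poisson", "unifrac_u", "unifrac_w",
                "top_msd"),
  vst       = "euclidean",
  uq_logfc  = "top_msd")
.PAIRING_PATHOLOGY <- list(vst = c("bray", "euclidean", "unifrac_w"))

#' Admissible normalization-distance pairings
#'
#' @param pathology include the negative-value-sensitive pairings of the
#'   variance-stabilized table.
#' @return a named list mapping each normalization method to the distance
#'   methods it may feed.
#' @export
admissiblePairs <- function(pathology = FALSE) {
  p <- .PAIRING
  if (pathology)
    for (m in names(.PAIRING_PATHOLOGY))
      p[[m]] <- union(p[[m]], .PAIRING_PATHOLOGY[[m]])
  p
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' \eqn{\sum_g |x_g - y_g| / \sum_g (x_g + y_g)}, in `[0, 1]` for nonnegative
#' input.
#'
#' @param x,y abundance vectors over the same OTU index.
#' @param allowNegative permit negative entries (the formula is then no
#'   longer bounded or meaningful; used only to reproduce the pathology of
#'   pairing variance-stabilized values with Bray-Curtis).
#' @return the dissimilarity.
#' @export
#' @examples
#' brayCurtis(c(2, 2), c(1, 3))  # 0.25
brayCurtis <- function(x, y, allowNegative = FALSE) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (!allowNegative && (any(x < 0) || any(y < 0)))
    stop("Bray-Curtis requires nonnegative input")
  tot <- sum(x + y)
  if (tot == 0) stop("both vectors are all-zero")
  sum(abs(x - y)) / tot
}

#' Euclidean distance between two vectors
#'
#' \eqn{\sqrt{\sum_g (x_g - y_g)^2}}; sign-safe, so negative entries (e.g.
#' variance-stabilized values) are fine.
#'
#' @param x,y numeric vectors of equal length.
#' @return the distance.
#' @export
euclideanDistance <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  sqrt(sum((x - y)^2))
}

# Power-transform selection: the smallest-misfit alpha on a grid, chosen so
# the Poisson goodness-of-fit statistic of x^alpha is closest to its degrees
# of freedom (n - 1)(G - 1).
.findPowerTransform <- function(x, alphas = seq(0.01, 1, by = 0.01)) {
  df <- (nrow(x) - 1) * (ncol(x) - 1)
  gof <- vapply(alphas, function(a) {
    xa <- x^a
    e <- outer(rowSums(xa), colSums(xa)) / sum(xa)
    ok <- e > 0
    abs(sum((xa[ok] - e[ok])^2 / e[ok]) - df)
  }, numeric(1))
  alphas[which.min(gof)]
}

#' Poisson dissimilarity matrix
#'
#' Model-based dissimilarity for count data: counts are optionally
#' power-transformed (exponent chosen so the Poisson goodness-of-fit
#' statistic matches its degrees of freedom), and each pair of samples is
#' scored by the sum over OTUs of the Poisson log-likelihood-ratio deviations
#' between separate per-sample rates and a shared rate with
#' total-count size factors:
#' \deqn{d(i,j) = \sum_g x_{ig} \log\frac{x_{ig}}{s_i (x_{ig}+x_{jg})} +
#'   x_{jg} \log\frac{x_{jg}}{s_j (x_{ig}+x_{jg})},}
#' with \eqn{s_i = N_i / (N_i + N_j)} and \eqn{0 \log 0 = 0}.
#'
#' @param x a [CountTable-class], a `"subsample"` [NormalizedTable-class], or
#'   an integer samples-by-OTU matrix.
#' @param transform apply the power transform (default `TRUE`).
#' @return a [DistanceMatrix-class] with method `"poisson"`.
#' @export
poissonDistance <- function(x, transform = TRUE) {
  norm <- "raw"
  if (is(x, "NormalizedTable")) { norm <- x@method; x <- x@values }
  if (is(x, "CountTable")) x <- otuCounts(x)
  if (any(x != round(x)) || any(x < 0))
    stop("Poisson distances require nonnegative integer counts")
  alpha <- if (transform) .findPowerTransform(x) else 1
  xa <- x^alpha
  n <- nrow(xa)
  d <- matrix(0, n, n, dimnames = list(rownames(xa), rownames(xa)))
  tot <- rowSums(xa)
  xlogx <- function(v, e) ifelse(v > 0, v * log(v / e), 0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      si <- tot[i] / (tot[i] + tot[j])
      pooled <- xa[i, ] + xa[j, ]
      dij <- sum(xlogx(xa[i, ], si * pooled)) +
        sum(xlogx(xa[j, ], (1 - si) * pooled))
      d[i, j] <- d[j, i] <- dij
    }
  }
  methods::new("DistanceMatrix", values = d, method = "poisson",
               normalization = norm, removedSamples = character())
}

# Per-branch masses: postorder accumulation of per-sample OTU masses up the
# tree. Returns the samples-by-branches mass matrix and branch lengths.
.branchMasses <- function(abund, tree) {
  absent <- setdiff(colnames(abund), tree$tip.label)
  if (length(absent))
    stop("OTU(s) missing from the tree: ",
         paste(utils::head(absent, 5), collapse = ", "))
  if (length(setdiff(tree$tip.label, colnames(abund))))
    tree <- ape::keep.tip(tree, colnames(abund))
  ntip <- length(tree$tip.label)
  tre <- stats::reorder(tree, "postorder")
  M <- matrix(0, nrow(abund), ntip + tree$Nnode)
  M[, seq_len(ntip)] <- abund[, tre$tip.label, drop = FALSE]
  for (k in seq_len(nrow(tre$edge)))
    M[, tre$edge[k, 1]] <- M[, tre$edge[k, 1]] + M[, tre$edge[k, 2]]
  list(mass = M[, tre$edge[, 2], drop = FALSE], len = tre$edge.length)
}

#' UniFrac phylogenetic dissimilarity matrix
#'
#' Unweighted UniFrac is the fraction of branch length leading to OTUs
#' present in exactly one of the two samples, over the branch length leading
#' to OTUs present in either; it depends only on presence/absence. Weighted
#' UniFrac is \eqn{\sum_b \ell_b |A_b - B_b|} over branches, where
#' \eqn{A_b} is the fraction of a sample's reads descending from branch `b`;
#' with `normalized = TRUE` (the common default) it is divided by its maximum
#' attainable value \eqn{\sum_b \ell_b (A_b + B_b)}.
#'
#' @param x a [CountTable-class], [NormalizedTable-class], or nonnegative
#'   samples-by-OTU matrix; columns must all be tips of `tree`.
#' @param tree rooted `ape::phylo` tree with branch lengths.
#' @param weighted abundance-weighted variant (default `FALSE`).
#' @param normalized divide the weighted variant by its maximum (default
#'   `TRUE`); ignored when `weighted = FALSE`.
#' @return a [DistanceMatrix-class] with method `"unifrac_u"` or
#'   `"unifrac_w"`.
#' @export
uniFrac <- function(x, tree, weighted = FALSE, normalized = TRUE) {
  norm <- "raw"
  if (is(x, "NormalizedTable")) { norm <- x@method; x <- x@values }
  if (is(x, "CountTable")) x <- otuCounts(x)
  if (any(x < 0)) stop("UniFrac requires nonnegative abundances")
  ids <- rownames(x)
  n <- nrow(x)
  if (weighted) {
    rs <- rowSums(x)
    if (any(rs == 0)) stop("weighted UniFrac cannot handle an empty sample")
    bm <- .branchMasses(x / rs, tree)
    G <- sweep(bm$mass, 2, bm$len, "*")
    num <- as.matrix(stats::dist(G, method = "manhattan"))
    d <- if (normalized) {
      denom <- outer(rowSums(G), rowSums(G), "+")
      out <- num / denom
      out[denom == 0] <- 0
      out
    } else num
    method <- "unifrac_w"
  } else {
    bm <- .branchMasses(x, tree)
    P <- (bm$mass > 0) * 1
    Q <- sweep(P, 2, bm$len, "*")
    shared <- tcrossprod(P, Q)
    shared <- (shared + t(shared)) / 2
    totals <- rowSums(Q)
    either <- outer(totals, totals, "+") - shared
    d <- pmax(1 - shared / either, 0)  # clamp rounding noise at zero
    d[either == 0] <- 0
    method <- "unifrac_u"
  }
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  methods::new("DistanceMatrix", values = d, method = method,
               normalization = norm, removedSamples = character())
}

#' Top mean-squared-difference dissimilarity matrix
#'
#' For each pair of samples, squares the per-OTU differences of log-scale
#' values, averages the `nTop` largest squared differences, and takes the
#' square root.
#'
#' @param x a log-scale [NormalizedTable-class] (e.g. upper-quartile log-CPM)
#'   or numeric matrix; a `"subsample"` table or raw counts are converted
#'   with `log2(x + 1)`.
#' @param nTop number of largest squared differences to average (default
#'   500); clamped to the OTU count with a warning.
#' @return a [DistanceMatrix-class] with method `"top_msd"`.
#' @export
topMsd <- function(x, nTop = 500) {
  norm <- "uq_logfc"
  if (is(x, "NormalizedTable")) {
    norm <- x@method
    v <- x@values
    if (x@method %in% c("raw", "subsample")) v <- log2(v + 1)
  } else if (is(x, "CountTable")) {
    norm <- "raw"
    v <- log2(otuCounts(x) + 1)
  } else v <- x
  G <- ncol(v)
  if (nTop > G) {
    warning(sprintf("nTop = %d exceeds the %d OTUs; clamping", nTop, G))
    nTop <- G
  }
  n <- nrow(v)
  d <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d2 <- (v[i, ] - v[j, ])^2
      d[i, j] <- d[j, i] <- sqrt(mean(sort(d2, decreasing = TRUE)[seq_len(nTop)]))
    }
  }
  methods::new("DistanceMatrix", values = d, method = "top_msd",
               normalization = norm, removedSamples = character())
}

# Bray-Curtis matrix tolerant of negative input (pathology mode only).
.brayMatrix <- function(v) {
  if (all(v >= 0)) return(as.matrix(vegan::vegdist(v, method = "bray")))
  n <- nrow(v)
  d <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- sum(abs(v[i, ] - v[j, ])) / sum(v[i, ] + v[j, ])
  d
}

#' Pairwise distance matrix from a normalized table
#'
#' Computes the requested dissimilarity over the retained samples, honoring
#' the admissible normalization-distance pairings: an inadmissible pair
#' returns `NA` (a recorded outcome, not an error). For rarefaction, pass the
#' raw [CountTable-class] together with [RarefactionParams-class] whose
#' `nIterations > 1`: the matrix is then the elementwise mean of the
#' per-iteration matrices on independent subsamplings.
#'
#' @param x a [NormalizedTable-class], or a [CountTable-class] (with `params`
#'   for the subsample/rarefy route).
#' @param method one of `"bray"`, `"euclidean"`, `"poisson"`, `"unifrac_u"`,
#'   `"unifrac_w"`, `"top_msd"`.
#' @param tree phylogeny over the OTUs (UniFrac methods only).
#' @param params [RarefactionParams-class] for the rarefaction route.
#' @param nTop top-MSD window (default 500).
#' @param pathology allow the negative-value-sensitive pairings of the
#'   variance-stabilized table.
#' @return a [DistanceMatrix-class], or `NA` for an inadmissible pairing.
#' @export
distanceMatrix <- function(x, method, tree = NULL, params = NULL, nTop = 500,
                           pathology = FALSE) {
  if (!method %in% .DIST_METHODS)
    stop("unknown distance method: ", method)
  pairing <- admissiblePairs(pathology)

  if (is(x, "CountTable") && !is.null(params)) {
    if (!method %in% pairing[["rarefy"]]) return(NA)
    metric <- function(sub) .distCore(sub, method, tree, "rarefy", nTop,
                                      pathology)
    avg <- rarefyMetric(x, params, metric = metric)
    return(methods::new("DistanceMatrix", values = avg, method = method,
                        normalization = if (params@nIterations > 1) "rarefy"
                                        else "subsample",
                        removedSamples = params@removedSamples))
  }
  if (is(x, "CountTable")) x <- normalizeRaw(x)
  stopifnot(is(x, "NormalizedTable"))
  if (!method %in% pairing[[x@method]]) return(NA)
  vals <- .distCore(x@values, method, tree, x@method, nTop, pathology)
  methods::new("DistanceMatrix", values = vals, method = method,
               normalization = x@method, removedSamples = x@removedSamples)
}

.distCore <- function(v, method, tree, norm, nTop, pathology) {
  switch(method,
    bray = .brayMatrix(v),
    euclidean = as.matrix(stats::dist(v)),
    poisson = poissonDistance(v)@values,
    unifrac_u = {
      if (is.null(tree)) stop("UniFrac requires a tree")
      uniFrac(v, tree, weighted = FALSE)@values
    },
    unifrac_w = {
      if (is.null(tree)) stop("UniFrac requires a tree")
      uniFrac(v, tree, weighted = TRUE)@values
    },
    top_msd = {
      if (norm %in% c("raw", "subsample", "rarefy")) v <- log2(v + 1)
      topMsd(v, nTop = nTop)@values
    })
}
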