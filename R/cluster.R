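#' @include AllClasses.R
NULL

#' Cluster samples from a distance matrix
#'
#' Assigns the retained samples to `k` clusters by one of three methods: PAM
#' (classical k-medoids, BUILD + swap, on the dissimilarities), k-means
#' (Lloyd's algorithm on the rows of the distance matrix treated as feature
#' vectors, best of `nstart` restarts by within-cluster sum of squares), or
#' complete-linkage hierarchical clustering cut at `k`. PAM and hierarchical
#' clustering are deterministic; k-means is deterministic given the seed.
#'
#' Treating distance-matrix rows as k-means features mirrors common practice
#' on this benchmark but is geometrically unorthodox; set
#' `kmeansEmbed = TRUE` to run k-means on a classical multidimensional
#' scaling (principal-coordinate) embedding instead.
#'
#' @param dm a [DistanceMatrix-class] (or symmetric matrix).
#' @param method `"pam"`, `"kmeans"`, or `"hclust"`.
#' @param k number of clusters (default 2).
#' @param seed seed for the k-means restarts.
#' @param nstart k-means restarts (default 10).
#' @param kmeansEmbed run k-means on a PCoA embedding rather than on raw
#'   distance-matrix rows.
#' @return integer cluster labels in `1..k`, named by sample.
#' @export
#' @examples
#' m <- matrix(c(0, 1, 9, 9, 1, 0, 9, 9, 9, 9, 0, 1, 9, 9, 1, 0), 4, 4,
#'             dimnames = list(letters[1:4], letters[1:4]))
#' clusterSamples(m, "hclust")
clusterSamples <- function(dm, method = c("pam", "kmeans", "hclust"), k = 2,
                           seed = NULL, nstart = 10, kmeansEmbed = FALSE) {
  method <- match.arg(method)
  v <- if (is(dm, "DistanceMatrix")) dm@values else as.matrix(dm)
  n <- nrow(v)
  if (k > n) stop("k exceeds the number of samples")
  ids <- rownames(v) %||% sprintf("S%02d", seq_len(n))
  labels <- switch(method,
    pam = cluster::pam(stats::as.dist(v), k = k, diss = TRUE,
                       cluster.only = TRUE),
    kmeans = withSeed(seed, {
      feats <- if (kmeansEmbed) {
        stats::cmdscale(stats::as.dist(v), k = min(n - 1, max(k, 2)))
      } else v
      stats::kmeans(feats, centers = k, nstart = nstart)$cluster
    }),
    hclust = stats::cutree(stats::hclust(stats::as.dist(v),
                                         method = "complete"), k = k))
  stats::setNames(as.integer(labels), ids)
}

#' Best-matched clustering accuracy
#'
#' Fraction of all samples (retained plus removed) assigned to the correct
#' cluster, maximized over the two possible cluster-to-group label matchings.
#' Samples removed before clustering (for falling below the library-size
#' threshold) always count as mis-clustered, so the denominator is the full
#' sample count and accuracies can fall below 50%: removing 12 of 80 samples
#' caps the accuracy at 68/80 = 0.85.
#'
#' @param labels integer cluster labels (1/2) for the retained samples.
#' @param trueGroups true group labels (`"A"`/`"B"`) for the same samples, in
#'   the same order (or named, in which case names are matched).
#' @param nRemoved number of samples removed before clustering (default 0).
#' @return the accuracy in `[0, 1]`.
#' @export
#' @examples
#' clusteringAccuracy(c(1, 1, 2, 2), c("A", "A", "B", "B"))  # 1
clusteringAccuracy <- function(labels, trueGroups, nRemoved = 0) {
  if (!is.null(names(labels)) && !is.null(names(trueGroups)))
    trueGroups <- trueGroups[names(labels)]
  if (length(labels) != length(trueGroups))
    stop("labels and trueGroups must cover the same samples")
  total <- length(labels) + nRemoved
  match1 <- sum((labels == 1) == (trueGroups == "A"))
  max(match1, length(labels) - match1) / total
}

#' How often each clustering method achieves the top accuracy
#'
#' For each clustering method, the fraction of evaluated cells (condition x
#' replicate x normalization x distance) in which its accuracy is at least as
#' high as every other method's on the same cell. Ties count for every tied
#' method, so the fractions need not sum to 1.
#'
#' @param records a run-record data frame (see [runGrid()]) containing
#'   `measure` values `"accuracy_pam"`, `"accuracy_kmeans"`,
#'   `"accuracy_hclust"` in long format, or a wide data frame with those
#'   columns.
#' @return a named numeric vector of win rates per clustering method.
#' @export
methodWinRates <- function(records) {
  acc <- c("accuracy_pam", "accuracy_kmeans", "accuracy_hclust")
  if (all(c("measure", "value") %in% names(records))) {
    sub <- records[records$measure %in% acc, , drop = FALSE]
    keyCols <- setdiff(names(sub), c("measure", "value"))
    key <- do.call(paste, c(sub[keyCols], sep = "\1"))
    wide <- do.call(rbind, lapply(split(seq_len(nrow(sub)), key), function(ix) {
      stats::setNames(sub$value[ix], sub$measure[ix])[acc]
    }))
  } else {
    present <- intersect(acc, names(records))
    wide <- as.matrix(records[, present, drop = FALSE])
  }
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  if (nrow(wide) == 0) stop("no complete accuracy records")
  best <- apply(wide, 1, max)
  rates <- colMeans(wide >= best)
  stats::setNames(rates, sub("^accuracy_", "", colnames(wide)))
}
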