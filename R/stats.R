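#' @include AllClasses.R
NULL

#' Observed OTU richness
#'
#' Number of OTUs with a strictly positive count, per sample.
#'
#' @param x an integer count vector, a samples-by-OTU matrix, a
#'   [CountTable-class], or an integer-valued [NormalizedTable-class] (e.g.
#'   a single subsampling).
#' @return a count (vector input) or a named vector of counts (matrix input).
#' @export
#' @examples
#' richness(c(0, 0, 5))  # 1
richness <- function(x) {
  if (is(x, "CountTable")) x <- otuCounts(x)
  if (is(x, "NormalizedTable")) x <- x@values
  if (any(x != round(x)))
    stop("richness is defined on integer-valued input")
  if (is.matrix(x)) rowSums(x > 0) else sum(x > 0)
}

#' Shannon diversity (natural log)
#'
#' \eqn{-\sum_i p_i \ln p_i} over the OTUs with positive abundance, where
#' `p` is the row renormalized to proportions.
#'
#' @param x a nonnegative abundance vector with positive sum, or a
#'   samples-by-OTU matrix / [CountTable-class] / [NormalizedTable-class]
#'   for per-sample values.
#' @return diversity in nats (vector input) or a named vector (matrix input).
#' @export
#' @examples
#' shannonDiversity(c(0.5, 0.5))  # log(2)
shannonDiversity <- function(x) {
  if (is(x, "CountTable")) x <- otuCounts(x)
  if (is(x, "NormalizedTable")) x <- x@values
  if (is.matrix(x)) return(vegan::diversity(x, index = "shannon"))
  if (sum(x) <= 0) stop("abundances must have positive sum")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' Expected richness of a subsample (closed form)
#'
#' The exact expectation of observed richness after subsampling `n` reads
#' without replacement from a sample with counts `counts` (total `N`):
#' \eqn{E[S] = \sum_g 1 - \binom{N - c_g}{n} / \binom{N}{n}}. Used as the
#' analytical reference for rarefied richness.
#'
#' @param counts integer count vector for one sample.
#' @param n subsample size (reads).
#' @return the expected richness.
#' @export
expectedRarefiedRichness <- function(counts, n) {
  N <- sum(counts)
  if (n > N) stop("subsample size exceeds the library size")
  c0 <- counts[counts > 0]
  # log-scale hypergeometric zero-class probability, stable for large N
  sum(1 - exp(lchoose(N - c0, n) - lchoose(N, n)))
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Midranks for ties; the exact null distribution when both groups have at
#' most 10 observations and the pooled data are tie-free, and the normal
#' approximation with continuity correction otherwise. Constant pooled data
#' give p = 1.
#'
#' @param a,b numeric value vectors for the two groups (each of length >= 2).
#' @param metric label recorded on the result (e.g. `"richness"`).
#' @return a [HypothesisResult-class] with the rank-sum statistic W.
#' @export
#' @examples
#' pValue(wilcoxonTwoSample(c(1, 2), c(3, 4)))  # 1/3
wilcoxonTwoSample <- function(a, b, metric = "alpha") {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least two values")
  if (length(unique(c(a, b))) == 1L)
    return(methods::new("HypothesisResult", statistic = NA_real_, pValue = 1,
                        test = "wilcoxon", metric = metric))
  ties <- anyDuplicated(c(a, b)) > 0
  useExact <- length(a) <= 10 && length(b) <= 10 && !ties
  res <- suppressWarnings(stats::wilcox.test(a, b, exact = useExact,
                                             correct = TRUE))
  methods::new("HypothesisResult",
               statistic = unname(res$statistic),
               pValue = min(res$p.value, 1), test = "wilcoxon",
               metric = metric)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance for a one-factor design:
#' with squared distances \eqn{d^2_{ij}},
#' \eqn{SS_{total} = \sum_{i<j} d^2_{ij}/n},
#' \eqn{SS_{within} = \sum_a \sum_{i<j \in a} d^2_{ij}/n_a}, and the
#' pseudo-F is \eqn{(SS_{between}/(a-1)) / (SS_{within}/(n-a))}. The p-value
#' is \eqn{(1 + \#\{F^* \ge F\}) / (n_{perm} + 1)} over seeded label
#' permutations.
#'
#' @param dm a [DistanceMatrix-class] or symmetric matrix.
#' @param groups group label per sample (>= 2 groups, each with >= 2
#'   samples), in row order or named.
#' @param nPerm number of label permutations (default 999).
#' @param seed permutation seed.
#' @return a [HypothesisResult-class] with the pseudo-F statistic. A
#'   degenerate all-zero matrix yields p = 1 with an `NA` statistic.
#' @export
permanova <- function(dm, groups, nPerm = 999, seed = NULL) {
  v <- if (is(dm, "DistanceMatrix")) dm@values else as.matrix(dm)
  n <- nrow(v)
  if (!is.null(names(groups)) && !is.null(rownames(v)))
    groups <- groups[rownames(v)]
  if (length(groups) != n)
    stop("one group label is required per sample")
  groups <- as.factor(groups)
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes < 2))
    stop("PERMANOVA needs >= 2 groups with >= 2 samples each")
  a <- length(sizes)
  d2 <- v^2
  ssTotal <- sum(d2[upper.tri(d2)]) / n
  metric <- if (is(dm, "DistanceMatrix")) dm@method else "distance"
  if (ssTotal == 0)
    return(methods::new("HypothesisResult", statistic = NA_real_, pValue = 1,
                        test = "permanova", metric = metric))

  ssWithinFor <- function(g) {
    sw <- 0
    for (lev in levels(groups)) {
      idx <- which(g == lev)
      sw <- sw + sum(d2[idx, idx]) / (2 * length(idx))
    }
    sw
  }
  fStat <- function(ssw) ((ssTotal - ssw) / (a - 1)) / (ssw / (n - a))
  fObs <- fStat(ssWithinFor(groups))
  exceed <- withSeed(seed, {
    sum(vapply(seq_len(nPerm), function(k) {
      fStat(ssWithinFor(sample(groups))) >= fObs
    }, logical(1)))
  })
  methods::new("HypothesisResult", statistic = fObs,
               pValue = (1 + exceed) / (nPerm + 1), test = "permanova",
               metric = metric)
}

#' Type-I error and power from run records
#'
#' Groups long-format run records carrying p-value measures by condition and
#' computes the fraction of replicates with `p <= alpha`: the type-I error
#' rate where the effect size is 1.00, and the power elsewhere.
#'
#' @param records run-record data frame (see [runGrid()]) with columns
#'   `effect_size`, `replicate`, `measure`, `value`, plus condition keys.
#' @param alpha significance level (default 0.05).
#' @param measures which p-value measures to aggregate (default all
#'   `measure` values starting with `"p_"`).
#' @return a data frame keyed by condition and measure with columns `n`
#'   (replicates), `fraction_significant`, and `rate_type` (`"type_I"` or
#'   `"power"`).
#' @export
aggregateErrorPower <- function(records, alpha = 0.05, measures = NULL) {
  stopifnot(all(c("effect_size", "measure", "value") %in% names(records)))
  if (is.null(measures))
    measures <- unique(grep("^p_", records$measure, value = TRUE))
  sub <- records[records$measure %in% measures, , drop = FALSE]
  if (nrow(sub) == 0) stop("no p-value records to aggregate")
  keyCols <- intersect(c("depth_model", "target_median", "assignment",
                         "effect_size", "filtered", "normalization",
                         "threshold_quantile", "distance", "measure"),
                       names(sub))
  key <- interaction(sub[keyCols], drop = TRUE, sep = "\1")
  out <- do.call(rbind, lapply(split(seq_len(nrow(sub)), key), function(ix) {
    row <- sub[ix[1], keyCols, drop = FALSE]
    vals <- sub$value[ix]
    row$n <- sum(!is.na(vals))
    row$fraction_significant <- mean(vals <= alpha, na.rm = TRUE)
    row
  }))
  rownames(out) <- NULL
  out$rate_type <- ifelse(out$effect_size == 1, "type_I", "power")
  out
}
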