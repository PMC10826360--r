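#' @include AllClasses.R
NULL

.newNormalized <- function(values, method, thresholdQuantile = 0,
                           nIterations = 1, removedSamples = character(),
                           groups, provenance = list()) {
  methods::new("NormalizedTable", values = values, method = method,
               thresholdQuantile = as.numeric(thresholdQuantile),
               nIterations = as.numeric(nIterations),
               removedSamples = removedSamples, groups = groups,
               provenance = provenance)
}

#' Pick the minimum library size at a depth percentile
#'
#' Sets \eqn{N_{L,m}} to the library size at the requested percentile of the
#' observed depths and marks samples with fewer reads for removal. For `n`
#' samples at percentile `q`, \eqn{N_{L,m}} is the
#' `floor(q/100 * n) + 1`-th smallest depth, so with distinct depths exactly
#' `floor(q/100 * n)` samples fall below it (e.g. 12 of 80 at the 15th
#' percentile); at the 0th percentile every sample is kept. Retained samples
#' always satisfy `depth >= NLm`.
#'
#' @param x a [CountTable-class] or a vector of library sizes (named by
#'   sample).
#' @param quantile percentile in `{0, 5, 10, 15, 20, 25, 40}`.
#' @param nIterations subsampling iterations to record (default 1).
#' @param seed seed to record for downstream subsampling draws.
#' @return a [RarefactionParams-class].
#' @export
#' @examples
#' p <- pickThreshold(seq(100, 8000, by = 100), 15)
#' minLibrarySize(p); length(removedSamples(p))
pickThreshold <- function(x, quantile, nIterations = 1, seed = NULL) {
  if (!quantile %in% .THRESHOLD_QUANTILES)
    stop("quantile must be one of 0, 5, 10, 15, 20, 25, 40")
  depths <- if (is(x, "CountTable")) sampleDepths(x) else x
  if (is.null(names(depths)))
    names(depths) <- sprintf("S%02d", seq_along(depths))
  k <- floor(quantile / 100 * length(depths))
  NLm <- sort(depths)[k + 1]
  removed <- names(depths)[depths < NLm]
  methods::new("RarefactionParams", NLm = as.numeric(NLm),
               nIterations = as.numeric(nIterations),
               seed = as.numeric(seed %||% NA_real_),
               thresholdQuantile = as.numeric(quantile),
               removedSamples = removed)
}

.retainedCounts <- function(table, params) {
  cc <- otuCounts(table)
  keep <- !rownames(cc) %in% params@removedSamples
  cc <- cc[keep, , drop = FALSE]
  if (any(rowSums(cc) < params@NLm))
    stop("a retained sample has fewer reads than N_L,m")
  list(counts = cc, groups = table@groups[keep])
}

#' Raw-count "normalization"
#'
#' Passes the counts through unchanged (the no-normalization arm of the
#' benchmark), recorded with method `"raw"` and threshold quantile 0.
#'
#' @param table a [CountTable-class].
#' @return a [NormalizedTable-class].
#' @export
normalizeRaw <- function(table) {
  stopifnot(is(table, "CountTable"))
  .newNormalized(otuCounts(table), "raw", groups = table@groups)
}

#' Relative-abundance normalization
#'
#' Divides each sample's counts by its library size, so every row sums to 1.
#' All samples are kept (threshold quantile 0).
#'
#' @param table a [CountTable-class] with no zero-depth sample.
#' @return a [NormalizedTable-class] with method `"relabund"`.
#' @export
normalizeRelabund <- function(table) {
  stopifnot(is(table, "CountTable"))
  cc <- otuCounts(table)
  depths <- rowSums(cc)
  if (any(depths == 0)) stop("cannot normalize a zero-depth sample")
  .newNormalized(cc / depths, "relabund", groups = table@groups)
}

#' Single subsampling to a common depth
#'
#' Draws, for each retained sample, a multivariate-hypergeometric subsample
#' of exactly \eqn{N_{L,m}} reads without replacement from its counts
#' (rarefying with a single randomization).
#'
#' @param table a [CountTable-class].
#' @param params a [RarefactionParams-class] from [pickThreshold()].
#' @param seed overrides the seed recorded in `params`.
#' @return a [NormalizedTable-class] of integer counts with every row summing
#'   to `NLm`, method `"subsample"`.
#' @export
subsampleOnce <- function(table, params, seed = NULL) {
  stopifnot(is(table, "CountTable"), is(params, "RarefactionParams"))
  seed <- seed %||% (if (is.na(params@seed)) NULL else params@seed)
  r <- .retainedCounts(table, params)
  sub <- withSeed(seed, suppressWarnings(vegan::rrarefy(r$counts, params@NLm)))
  .newNormalized(sub, "subsample", thresholdQuantile = params@thresholdQuantile,
                 removedSamples = params@removedSamples, groups = r$groups,
                 provenance = list(NLm = params@NLm, seed = seed))
}

.builtinMetric <- function(metric) {
  switch(metric,
    richness = function(m) apply(m, 1, function(r) sum(r > 0)),
    shannon = function(m) vegan::diversity(m, index = "shannon"),
    bray = function(m) as.matrix(vegan::vegdist(m, method = "bray")),
    euclidean = function(m) as.matrix(stats::dist(m)),
    stop("unknown built-in metric: ", metric))
}

#' Rarefaction: average a metric over repeated subsamplings
#'
#' Computes the metric on each of `nIterations` independent subsamplings to
#' \eqn{N_{L,m}} reads and returns the elementwise mean. The averaging always
#' happens on the metric (a per-sample alpha-diversity vector or a distance
#' matrix), never on the subsampled counts themselves.
#'
#' @param table a [CountTable-class].
#' @param params a [RarefactionParams-class]; `params@nIterations` sets the
#'   number of subsamplings (100 is the conventional default).
#' @param metric a function taking the subsampled samples-by-OTU count matrix
#'   and returning a numeric vector or matrix, or one of the built-in names
#'   `"richness"`, `"shannon"`, `"bray"`, `"euclidean"`.
#' @param returnIterations if `TRUE`, also return the per-iteration values.
#' @return the elementwise mean of the metric across iterations; with
#'   `returnIterations = TRUE` a list with elements `mean` and `iterations`.
#' @export
#' @examples
#' pp <- makeSyntheticParents(nOtus = 40, seed = 1)
#' a <- assignDepths(depthModel("log_scaled", targetMedian = 1000), seed = 2)
#' tab <- simulateCounts(pp, 1.5, a, seed = 3)
#' p <- pickThreshold(tab, 0, nIterations = 10, seed = 4)
#' r <- rarefyMetric(tab, p, "richness")
rarefyMetric <- function(table, params, metric = "bray",
                         returnIterations = FALSE) {
  stopifnot(is(table, "CountTable"), is(params, "RarefactionParams"))
  if (is.character(metric)) metric <- .builtinMetric(metric)
  r <- .retainedCounts(table, params)
  if (any(rowSums(r$counts) < params@NLm))
    stop("a retained sample has fewer reads than N_L,m")
  nIter <- as.integer(params@nIterations)
  # one iteration reduces exactly to subsampleOnce: reuse its seed directly
  seeds <- if (nIter == 1L) list(if (is.na(params@seed)) NULL
                                 else params@seed)
           else as.list(spawnSeeds(if (is.na(params@seed)) NULL
                                   else params@seed, nIter))
  iterations <- vector("list", nIter)
  acc <- NULL
  for (i in seq_len(nIter)) {
    sub <- withSeed(seeds[[i]], suppressWarnings(vegan::rrarefy(r$counts, params@NLm)))
    val <- metric(sub)
    if (returnIterations) iterations[[i]] <- val
    acc <- if (is.null(acc)) val else acc + val
  }
  avg <- acc / nIter
  if (returnIterations) list(mean = avg, iterations = iterations) else avg
}

#' Variance-stabilizing transformation of counts
#'
#' A negative-binomial variance-stabilizing transform: size factors are
#' computed by median-of-ratios against the geometric-mean reference on
#' pseudocounted counts; a common mean-dispersion curve
#' \eqn{\alpha(\mu) = a_0/\mu + a_1} is fit by method of moments on the
#' size-factor-normalized counts; and the closed-form transform for that
#' curve,
#' \deqn{f(q) = \log_2\!\big[(1 + a_0 + 2 a_1 q +
#'   2\sqrt{a_1 q (1 + a_0 + a_1 q)}) / (4 a_1)\big],}
#' is applied per cell. The transform is monotone increasing within a sample,
#' approaches `log2` of the normalized count for large counts, and may be
#' negative for small ones.
#'
#' @param table a [CountTable-class] with at least two samples.
#' @param pseudocount added to every cell before the size-factor and
#'   transform steps (default 1).
#' @return a [NormalizedTable-class] with method `"vst"`; provenance carries
#'   `sizeFactors`, `a0`, `a1`.
#' @export
normalizeVst <- function(table, pseudocount = 1) {
  stopifnot(is(table, "CountTable"))
  cc <- otuCounts(table)
  if (nrow(cc) < 2) stop("vst needs at least two samples")
  K <- cc + pseudocount
  logGeo <- colMeans(log(K))
  sf <- apply(K, 1, function(row) exp(stats::median(log(row) - logGeo)))
  q <- K / sf
  mu <- colMeans(q)
  v <- apply(q, 2, stats::var)
  # method-of-moments dispersion per OTU, alpha_g = (v - mu) / mu^2, then a
  # least-squares fit of the curve alpha(mu) = a0/mu + a1 across OTUs
  alphaHat <- (v - mu) / mu^2
  fit <- stats::lm.fit(cbind(1 / mu, 1), alphaHat)
  a0 <- max(unname(fit$coefficients[1]), 0)
  a1 <- unname(fit$coefficients[2])
  if (is.na(a1) || a1 <= 0) {
    warning("asymptotic dispersion estimate <= 0; falling back to 1e-8")
    a1 <- 1e-8
  }
  vstValues <- log2((1 + a0 + 2 * a1 * q +
                       2 * sqrt(a1 * q * (1 + a0 + a1 * q))) / (4 * a1))
  .newNormalized(vstValues, "vst", groups = table@groups,
                 provenance = list(sizeFactors = sf, a0 = a0, a1 = a1,
                                   pseudocount = pseudocount))
}

#' Fraction of negative cells in a variance-stabilized table
#'
#' @param norm a [NormalizedTable-class] with method `"vst"`.
#' @return a list with `fractionNegative` (proportion of strictly negative
#'   cells) and `anyNegative` (logical).
#' @export
detectNegativeFraction <- function(norm) {
  stopifnot(is(norm, "NormalizedTable"))
  if (norm@method != "vst")
    stop("negative-value diagnostics apply to the vst method only")
  frac <- mean(norm@values < 0)
  list(fractionNegative = frac, anyNegative = frac > 0)
}

#' Upper-quartile log-fold-change normalization
#'
#' Per-sample scaling factors are the 75th percentile of each sample's
#' nonzero counts divided by its library size, rescaled so the factors have
#' geometric mean 1. The output is log2 counts-per-million computed against
#' the effective library size (depth times factor), with the pseudocount
#' applied on the CPM scale: `log2(cpm + pseudocount)`. Doubling every count
#' in a sample leaves its output row unchanged, and every zero count maps to
#' the same finite value (`log2(pseudocount)`) in every sample, which is why
#' this output is excluded from richness comparisons.
#'
#' @param table a [CountTable-class] with at least two samples and no
#'   all-zero sample.
#' @param pseudocount added on the counts-per-million scale (default 1).
#' @return a [NormalizedTable-class] with method `"uq_logfc"`; provenance
#'   carries the scaling `factors` and `effectiveLibSizes`.
#' @export
normalizeUq <- function(table, pseudocount = 1) {
  stopifnot(is(table, "CountTable"))
  cc <- otuCounts(table)
  if (nrow(cc) < 2) stop("upper-quartile normalization needs >= 2 samples")
  depths <- rowSums(cc)
  if (any(depths == 0)) stop("a sample has all-zero counts")
  f <- vapply(seq_len(nrow(cc)), function(i) {
    nz <- cc[i, cc[i, ] > 0]
    stats::quantile(nz, 0.75, names = FALSE) / depths[i]
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  effLib <- depths * f
  logcpm <- log2(sweep(cc, 1, effLib, "/") * 1e6 + pseudocount)
  .newNormalized(logcpm, "uq_logfc", groups = table@groups,
                 provenance = list(factors = stats::setNames(f, rownames(cc)),
                                   effectiveLibSizes = effLib,
                                   pseudocount = pseudocount))
}

#' Apply a named normalization strategy
#'
#' Dispatcher over the six strategies. `"raw"`, `"relabund"`, `"vst"` and
#' `"uq_logfc"` keep all samples (threshold quantile 0); `"subsample"` and
#' `"rarefy"` honor the quantile threshold. `"rarefy"` has no single
#' normalized table — use [rarefyMetric()] or [distanceMatrix()] for
#' rarefaction-averaged quantities — so this dispatcher refuses it.
#'
#' @param table a [CountTable-class].
#' @param method one of `"raw"`, `"relabund"`, `"vst"`, `"uq_logfc"`,
#'   `"subsample"`.
#' @param quantile threshold percentile for `"subsample"`.
#' @param seed subsampling seed.
#' @return a [NormalizedTable-class].
#' @export
normalizeCounts <- function(table, method, quantile = 0, seed = NULL) {
  switch(method,
    raw = normalizeRaw(table),
    relabund = normalizeRelabund(table),
    vst = normalizeVst(table),
    uq_logfc = normalizeUq(table),
    subsample = subsampleOnce(table, pickThreshold(table, quantile,
                                                   seed = seed)),
    rarefy = stop("rarefaction averages a metric, not a table; ",
                  "use rarefyMetric() or distanceMatrix()"),
    stop("unknown normalization method: ", method))
}
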