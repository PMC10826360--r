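#' @include AllClasses.R
NULL

# Summary statistics of the 26 empirical library sizes the default depth
# model emulates: mean 1,085,256.8 reads, range 58,688-2,357,181. Only the
# moments are published, so the default sd is set to span the printed range
# at roughly +/- 2 sd.
.EMPIRICAL_N <- 26L
.EMPIRICAL_MEAN <- 1085256.8
.EMPIRICAL_SD <- 574623
.EMPIRICAL_MIN <- 58688L
.EMPIRICAL_MAX <- 2357181L

#' Emulate an empirical library-size distribution
#'
#' Draws `n` library sizes from a normal distribution clipped to
#' `[minDepth, maxDepth]` and rounded to integers, emulating the roughly
#' normal 26-sample empirical depth distribution that seeds the
#' `empirical_resample` depth model.
#'
#' @param n number of depths (default 26).
#' @param mean,sd normal parameters in reads.
#' @param minDepth,maxDepth clipping bounds in reads.
#' @param seed integer seed; fixed seed gives an identical vector.
#' @return an integer vector of `n` library sizes.
#' @export
#' @examples
#' d <- makeEmpiricalDepths(seed = 1)
#' range(d)
makeEmpiricalDepths <- function(n = .EMPIRICAL_N, mean = .EMPIRICAL_MEAN,
                                sd = .EMPIRICAL_SD,
                                minDepth = .EMPIRICAL_MIN,
                                maxDepth = .EMPIRICAL_MAX, seed = NULL) {
  if (n < 2) stop("n must be >= 2")
  if (sd <= 0) stop("sd must be positive")
  if (minDepth >= maxDepth) stop("minDepth must be below maxDepth")
  withSeed(seed, {
    d <- stats::rnorm(n, mean = mean, sd = sd)
    as.integer(round(pmin(pmax(d, minDepth), maxDepth)))
  })
}

#' Log-spaced library sizes
#'
#' `n` depths evenly spaced on the log scale from `minDepth` to `maxDepth`
#' inclusive, rounded to integers. With the defaults (80 depths between
#' 58,688 and 2,357,181 reads) the vector has median 372,040 and mean
#' 629,825 reads.
#'
#' @param n number of depths (default 80).
#' @param minDepth,maxDepth endpoints in reads.
#' @return an integer vector of `n` strictly increasing library sizes.
#' @export
#' @examples
#' median(makeLogScaledDepths())
makeLogScaledDepths <- function(n = 80, minDepth = .EMPIRICAL_MIN,
                                maxDepth = .EMPIRICAL_MAX) {
  if (n < 2) stop("n must be >= 2")
  if (minDepth < 1) stop("minDepth must be >= 1")
  if (minDepth >= maxDepth) stop("minDepth must be below maxDepth")
  as.integer(round(exp(seq(log(minDepth), log(maxDepth), length.out = n))))
}

#' Construct a sequencing-depth model
#'
#' @param kind `"empirical_resample"` (80 depths drawn with replacement from
#'   26 base depths) or `"log_scaled"` (80 log-spaced depths, each used once).
#' @param targetMedian median library size after rescaling; one of 1000,
#'   2000, 5000, 10000, 50000 reads.
#' @param assignment `"randomized"` (group labels shuffled independently of
#'   depth) or `"confounded"` (below-median depths in group A, above-median
#'   in group B).
#' @param baseDepths base library sizes; defaults to
#'   [makeEmpiricalDepths()] (seeded by `seed`) or [makeLogScaledDepths()]
#'   according to `kind`.
#' @param seed seed for the default empirical base depths.
#' @return a [DepthModel-class].
#' @export
#' @examples
#' depthModel("log_scaled", targetMedian = 10000)
depthModel <- function(kind = c("empirical_resample", "log_scaled"),
                       targetMedian = 10000,
                       assignment = c("randomized", "confounded"),
                       baseDepths = NULL, seed = NULL) {
  kind <- match.arg(kind)
  assignment <- match.arg(assignment)
  if (is.null(baseDepths))
    baseDepths <- if (kind == "empirical_resample")
      makeEmpiricalDepths(seed = seed) else makeLogScaledDepths()
  methods::new("DepthModel", kind = kind, baseDepths = as.numeric(baseDepths),
               targetMedian = as.numeric(targetMedian),
               assignment = assignment)
}

# Rescale depths so their median hits the target; nearest-integer rounding
# with a floor of one read. Rank order is preserved.
scaleDepthsToMedian <- function(depths, targetMedian) {
  pmax(1, round(depths * targetMedian / stats::median(depths)))
}

#' Realize per-sample depths and treatment labels from a depth model
#'
#' Draws the 80 library sizes (with replacement from the 26 empirical base
#' depths, or a permutation of the 80 log-spaced depths), rescales them so
#' their median equals the model's target, and attaches group labels: either
#' shuffled independently of depth, or fully confounded (the 40 smallest
#' depths in group A, the 40 largest in group B).
#'
#' @param model a [DepthModel-class].
#' @param seed integer seed.
#' @return a [DepthAssignment-class] with samples named `S01..S80`.
#' @export
#' @examples
#' a <- assignDepths(depthModel("log_scaled", targetMedian = 1000), seed = 7)
#' median(sampleDepths(a))
assignDepths <- function(model, seed = NULL) {
  stopifnot(is(model, "DepthModel"))
  withSeed(seed, {
    raw <- if (model@kind == "empirical_resample")
      sample(model@baseDepths, 80L, replace = TRUE)
    else
      sample(model@baseDepths)  # each of the 80 depths exactly once
    depths <- scaleDepthsToMedian(raw, model@targetMedian)
    groups <- if (model@assignment == "randomized") {
      sample(rep(c("A", "B"), each = 40L))
    } else {
      g <- character(80L)
      g[rank(depths, ties.method = "first") <= 40L] <- "A"
      g[g == ""] <- "B"
      g
    }
    names(depths) <- sprintf("S%02d", seq_len(80L))
    methods::new("DepthAssignment", depths = depths, groups = groups,
                 targetMedian = model@targetMedian)
  })
}
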