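test_that("threshold picking removes the samples below the percentile", {
  d <- seq(100, 8000, by = 100)  # 80 distinct depths
  p0 <- pickThreshold(d, 0)
  expect_equal(minLibrarySize(p0), 100)
  expect_length(removedSamples(p0), 0)
  p15 <- pickThreshold(d, 15)
  expect_length(removedSamples(p15), 12)
  expect_equal(minLibrarySize(p15), 1300)
  # all depths equal: nothing is ever removed
  pEq <- pickThreshold(rep(500, 80), 40)
  expect_length(removedSamples(pEq), 0)
  expect_error(pickThreshold(d, 17), "quantile")
  # retained samples always satisfy depth >= NLm
  set.seed(1)
  dd <- sample(makeLogScaledDepths(), 80)
  for (q in c(0, 5, 25, 40)) {
    p <- pickThreshold(dd, q)
    keep <- dd[!sprintf("S%02d", 1:80) %in% removedSamples(p)]
    expect_true(all(keep >= minLibrarySize(p)))
    expect_length(removedSamples(p), floor(q / 100 * 80))
  }
})

test_that("relative abundance rows sum to one and ignore depth", {
  tab <- countTable(rbind(s1 = c(2, 2, 4), s2 = c(1, 1, 2)),
                    groups = c("A", "B"))
  rel <- normalizeRelabund(tab)
  expect_equal(unname(normValues(rel)[1, ]), c(0.25, 0.25, 0.5))
  expect_equal(unname(rowSums(normValues(rel))), c(1, 1))
  # scaling a sample's counts leaves its proportions unchanged
  tab7 <- countTable(rbind(s1 = c(2, 2, 4) * 7, s2 = c(1, 1, 2)),
                     groups = c("A", "B"))
  expect_equal(normValues(normalizeRelabund(tab7))[1, ],
               normValues(rel)[1, ])
  zero <- countTable(rbind(s1 = c(0, 0), s2 = c(1, 1)), groups = c("A", "B"))
  expect_error(normalizeRelabund(zero), "zero-depth")
})

test_that("single subsampling draws exact totals without replacement", {
  tab <- countTable(rbind(s1 = c(5L, 0L), s2 = c(7L, 3L)),
                    groups = c("A", "B"))
  p <- methods::new("RarefactionParams", NLm = 3, nIterations = 1, seed = 42,
                    thresholdQuantile = 0, removedSamples = character())
  sub <- subsampleOnce(tab, p)
  expect_equal(unname(normValues(sub)[1, ]), c(3, 0))  # single-support row
  expect_equal(unname(rowSums(normValues(sub))), c(3, 3))
  expect_error(subsampleOnce(tab, methods::new("RarefactionParams", NLm = 6,
                                               nIterations = 1, seed = 1,
                                               thresholdQuantile = 0,
                                               removedSamples = character())),
               "fewer reads")
  row1 <- normValues(subsampleOnce(countTable(rbind(s1 = c(3L, 2L)), "A"),
                                   methods::new("RarefactionParams", NLm = 5,
                                                nIterations = 1, seed = 1,
                                                thresholdQuantile = 0,
                                                removedSamples = character())))
  expect_equal(unname(row1[1, ]), c(3, 2))
})

test_that("subsampled counts follow the hypergeometric mean", {
  counts <- c(40L, 25L, 10L, 5L)
  tab <- countTable(matrix(counts, 1, dimnames = list("s1", NULL)), "A")
  n <- 20
  nDraw <- 4000
  sums <- numeric(4)
  for (s in seq_len(nDraw)) {
    p <- methods::new("RarefactionParams", NLm = n, nIterations = 1, seed = s,
                      thresholdQuantile = 0, removedSamples = character())
    sums <- sums + normValues(subsampleOnce(tab, p))[1, ]
  }
  m <- sums / nDraw
  expected <- n * counts / sum(counts)
  N <- sum(counts)
  varHyper <- n * (counts / N) * (1 - counts / N) * (N - n) / (N - 1)
  expect_true(all(abs(m - expected) <= 3 * sqrt(varHyper / nDraw)))
})

test_that("rarefaction averages the metric, not the counts", {
  tab <- tinyTable()
  p1 <- pickThreshold(tab, 0, nIterations = 1, seed = 77)
  # one iteration reduces exactly to a single subsampling
  viaRarefy <- rarefyMetric(tab, p1, "richness")
  viaOnce <- rowSums(normValues(subsampleOnce(tab, p1)) > 0)
  expect_equal(viaRarefy, viaOnce)
  # mean rarefied richness matches the closed form within 3 SE
  p <- pickThreshold(tab, 0, nIterations = 200, seed = 78)
  out <- rarefyMetric(tab, p, "richness", returnIterations = TRUE)
  closed <- apply(otuCounts(tab), 1, expectedRarefiedRichness,
                  n = minLibrarySize(p))
  perIter <- do.call(rbind, out$iterations)
  se <- apply(perIter, 2, sd) / sqrt(nrow(perIter))
  expect_true(all(abs(out$mean - closed) <= 3 * se + 1e-9))
})

test_that("rarefied estimates are less variable than single subsamples", {
  tab <- tinyTable(seed = 31)
  nRuns <- 40
  rarefied <- single <- numeric(nRuns)
  for (r in seq_len(nRuns)) {
    pR <- pickThreshold(tab, 0, nIterations = 20, seed = 5000 + r)
    rarefied[r] <- mean(rarefyMetric(tab, pR, "richness"))
    p1 <- pickThreshold(tab, 0, nIterations = 1, seed = 9000 + r)
    single[r] <- mean(rowSums(normValues(subsampleOnce(tab, p1)) > 0))
  }
  expect_lt(var(rarefied), var(single))
})

test_that("variance stabilization is monotone and asymptotically log2", {
  tab <- filterRareOtus(tinyTable())
  v <- normalizeVst(tab)
  expect_s4_class(v, "NormalizedTable")
  # monotone within each sample
  cc <- otuCounts(tab)
  vv <- normValues(v)
  for (i in c(1, 40, 80)) {
    o <- order(cc[i, ])
    expect_true(all(diff(vv[i, o]) >= -1e-9))
  }
  # identical samples get unit size factors
  two <- countTable(rbind(s1 = c(10, 20, 30), s2 = c(10, 20, 30)),
                    groups = c("A", "B"))
  expect_equal(unname(normalizeVst(two)@provenance$sizeFactors), c(1, 1))
  # high-count regime: transformed differences approach log2 differences
  a1 <- v@provenance$a1
  f <- function(x) log2((1 + v@provenance$a0 + 2 * a1 * x +
                           2 * sqrt(a1 * x * (1 + v@provenance$a0 + a1 * x))) /
                          (4 * a1))
  expect_equal((f(2e6) - f(1e6)) / (log2(2e6) - log2(1e6)), 1,
               tolerance = 1e-3)
})

test_that("vst flattens the variance of simulated NB counts", {
  set.seed(42)
  nS <- 40; nG <- 120
  mu <- exp(runif(nG, log(20), log(2000)))
  counts <- t(vapply(mu, function(m) rnbinom(nS, mu = m, size = 1 / 0.3),
                     numeric(nS)))
  tab <- countTable(t(counts), groups = rep(c("A", "B"), each = nS / 2))
  vv <- normValues(normalizeVst(tab))
  vars <- apply(vv, 2, var)
  bins <- cut(log(mu), 4)
  binVar <- tapply(vars, bins, median)
  expect_lt(max(binVar) / min(binVar), 3)
})

test_that("negative-value diagnostics report the strict fraction", {
  tab <- filterRareOtus(tinyTable())
  v <- normalizeVst(tab)
  nf <- detectNegativeFraction(v)
  expect_gte(nf$fractionNegative, 0)
  expect_lte(nf$fractionNegative, 1)
  expect_identical(nf$anyNegative, nf$fractionNegative > 0)
  fake <- methods::new("NormalizedTable",
                       values = matrix(c(-1, 1, 2, 3), 2,
                                       dimnames = list(c("a", "b"), NULL)),
                       method = "vst", thresholdQuantile = 0,
                       nIterations = 1, removedSamples = character(),
                       groups = c("A", "B"), provenance = list())
  expect_equal(detectNegativeFraction(fake)$fractionNegative, 0.25)
  expect_error(detectNegativeFraction(normalizeRelabund(tab)), "vst")
})

test_that("upper-quartile factors are normalized and scale-invariant", {
  tab <- filterRareOtus(tinyTable())
  u <- normalizeUq(tab)
  f <- u@provenance$factors
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)
  # identical samples -> unit factors
  two <- countTable(rbind(s1 = c(10, 0, 30), s2 = c(10, 0, 30)),
                    groups = c("A", "B"))
  expect_equal(unname(normalizeUq(two)@provenance$factors), c(1, 1))
  # doubling one sample's counts leaves its log-CPM row unchanged
  cc <- otuCounts(tab)
  cc2 <- cc
  cc2[1, ] <- cc2[1, ] * 2L
  u2 <- normalizeUq(countTable(cc2, groups = tab@groups))
  expect_equal(normValues(u2)[1, ], normValues(u)[1, ], tolerance = 1e-12)
  # every zero count maps to exactly log2(pseudocount), whatever the sample
  zeros <- normValues(u)[cc == 0]
  expect_true(all(abs(zeros - log2(1)) < 1e-12))
  zero <- countTable(rbind(s1 = c(0, 0), s2 = c(1, 1)), groups = c("A", "B"))
  expect_error(normalizeUq(zero), "all-zero")
})

test_that("upper-quartile factors equal edgeR's on dense counts", {
  skip_if_not_installed("edgeR")
  # on a zero-free table the nonzero-count convention coincides with
  # edgeR's all-count quantile, so the factors must agree exactly
  set.seed(10)
  cc <- matrix(rpois(20 * 50, 40) + 1L, nrow = 20,
               dimnames = list(sprintf("s%02d", 1:20),
                               sprintf("g%02d", 1:50)))
  tab <- countTable(cc, groups = rep(c("A", "B"), each = 10))
  fEdger <- edgeR::calcNormFactors(t(cc), method = "upperquartile")
  fOurs <- normalizeUq(tab)@provenance$factors
  expect_equal(unname(fOurs), unname(fEdger), tolerance = 1e-10)
})
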