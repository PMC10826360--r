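test_that("richness and Shannon follow their definitions", {
  expect_equal(richness(c(0, 0, 5)), 1)
  expect_equal(richness(c(0, 0, 0)), 0)
  expect_error(richness(c(0.5, 1)), "integer")
  m <- rbind(s1 = c(1L, 0L, 2L), s2 = c(0L, 0L, 9L))
  expect_equal(unname(richness(m)), c(2, 1))
  expect_equal(shannonDiversity(c(0.5, 0.5)), log(2))
  expect_equal(shannonDiversity(c(0, 7)), 0)
  expect_equal(shannonDiversity(rep(1, 4)), log(4))
  expect_error(shannonDiversity(c(0, 0)), "positive sum")
})

test_that("closed-form rarefied richness matches simulation", {
  counts <- c(50L, 20L, 5L, 2L, 0L)
  n <- 10
  nDraw <- 3000
  tab <- countTable(matrix(counts, 1, dimnames = list("s", NULL)), "A")
  obs <- vapply(seq_len(nDraw), function(s) {
    p <- methods::new("RarefactionParams", NLm = n, nIterations = 1,
                      seed = s, thresholdQuantile = 0,
                      removedSamples = character())
    sum(normValues(subsampleOnce(tab, p)) > 0)
  }, numeric(1))
  expected <- expectedRarefiedRichness(counts, n)
  expect_lt(abs(mean(obs) - expected), 3 * sd(obs) / sqrt(nDraw))
  # exhaustive draw recovers the full support
  expect_equal(expectedRarefiedRichness(counts, sum(counts)), 4)
})

test_that("Wilcoxon rank-sum handles exact, tied and degenerate cases", {
  # {1,2} vs {3,4}: most extreme of the C(4,2) = 6 rank splits
  r <- wilcoxonTwoSample(c(1, 2), c(3, 4))
  expect_equal(pValue(r), 1 / 3)
  # identical multisets: statistic at its center, p near 1
  expect_gt(pValue(wilcoxonTwoSample(c(1, 2, 3), c(1, 2, 3))), 0.9)
  # constant pooled data
  expect_equal(pValue(wilcoxonTwoSample(c(5, 5), c(5, 5))), 1)
  # invariance under monotone transforms of the pooled data
  a <- c(3, 9, 14, 2); b <- c(21, 8, 17, 30)
  expect_equal(pValue(wilcoxonTwoSample(a, b)),
               pValue(wilcoxonTwoSample(log(a), log(b))))
  expect_equal(pValue(wilcoxonTwoSample(a, b)),
               pValue(wilcoxonTwoSample(a^3, b^3)))
  expect_error(wilcoxonTwoSample(1, c(2, 3)), "two values")
  # agrees with the reference implementation in the approximate regime
  set.seed(2)
  x <- rnorm(30); y <- rnorm(30) + 0.5
  expect_equal(pValue(wilcoxonTwoSample(x, y)),
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
})

test_that("PERMANOVA matches brute force and adonis2 on the pseudo-F", {
  set.seed(31)
  pts <- matrix(rnorm(12), 6, 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(letters[1:6], letters[1:6])
  groups <- rep(c("A", "B"), each = 3)
  r <- permanova(d, groups, nPerm = 9999, seed = 1)
  expect_equal(testStatistic(r), bruteF(d, groups), tolerance = 1e-9)
  ref <- vegan::adonis2(as.dist(d) ~ g,
                        data = data.frame(g = groups), permutations = 99)
  expect_equal(testStatistic(r), ref$F[1], tolerance = 1e-9)
  # exact p by exhaustive enumeration of all C(6,3) = 20 balanced labelings
  combs <- combn(6, 3)
  fAll <- apply(combs, 2, function(idx) {
    g <- rep("B", 6); g[idx] <- "A"
    bruteF(d, g)
  })
  pExact <- mean(fAll >= testStatistic(r) - 1e-12)
  expect_lt(abs(pValue(r) - pExact),
            3 * sqrt(pExact * (1 - pExact) / 9999) + 2e-4)
})

test_that("PERMANOVA separates perfectly split groups at the floor p", {
  d <- blockDistance(nPerBlock = 10, within = 0, between = 1, jitterSeed = 0)
  d[d < 0.5] <- 0; d[d >= 0.5] <- 1; diag(d) <- 0
  groups <- rep(c("A", "B"), each = 10)
  r <- permanova(d, groups, nPerm = 199, seed = 2)
  expect_equal(pValue(r), 1 / 200)
  # degenerate all-zero matrix
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  rz <- permanova(z, c("A", "A", "B", "B"), nPerm = 99, seed = 1)
  expect_equal(pValue(rz), 1)
  expect_true(is.na(testStatistic(rz)))
  expect_error(permanova(z, c("A", "A", "A", "B")), ">= 2")
})

test_that("pseudo-F is invariant to rescaling the distance matrix", {
  set.seed(7)
  pts <- matrix(rnorm(20), 10, 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(sprintf("s%d", 1:10), sprintf("s%d", 1:10))
  g <- rep(c("A", "B"), each = 5)
  f1 <- testStatistic(permanova(d, g, nPerm = 9, seed = 1))
  f2 <- testStatistic(permanova(7.3 * d, g, nPerm = 9, seed = 1))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("PERMANOVA p-values are uniform under the null", {
  set.seed(12)
  pts <- matrix(rnorm(20), 10, 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(sprintf("s%d", 1:10), sprintf("s%d", 1:10))
  pvals <- vapply(1:400, function(s) {
    g <- rarebench:::withSeed(s, sample(rep(c("A", "B"), each = 5)))
    pValue(permanova(d, g, nPerm = 199, seed = 10000 + s))
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.001)
  # super-uniform at worst at alpha = 0.05
  expect_lte(mean(pvals <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("error/power aggregation keys on condition and effect size", {
  rec <- data.frame(depth_model = "log_scaled", target_median = 1000,
                    assignment = "randomized",
                    effect_size = rep(c(1, 1.15), each = 4),
                    filtered = TRUE, replicate = rep(1:4, 2), seed = 1,
                    normalization = "rarefy", threshold_quantile = 0,
                    distance = "bray", measure = "p_permanova",
                    value = c(0.01, 0.01, 0.01, 0.01, 0.5, 0.5, 0.5, 0.5))
  agg <- aggregateErrorPower(rec)
  expect_equal(nrow(agg), 2)
  t1 <- agg[agg$effect_size == 1, ]
  expect_equal(t1$fraction_significant, 1.0)
  expect_equal(t1$rate_type, "type_I")
  pw <- agg[agg$effect_size == 1.15, ]
  expect_equal(pw$fraction_significant, 0.0)
  expect_equal(pw$rate_type, "power")
})
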