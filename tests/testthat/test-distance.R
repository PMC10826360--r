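test_that("Bray-Curtis and Euclidean primitives match hand values", {
  expect_equal(brayCurtis(c(2, 2), c(1, 3)), 0.25)
  expect_equal(brayCurtis(c(1, 1), c(1, 1)), 0)
  expect_equal(brayCurtis(c(1, 0), c(0, 2)), 1)  # disjoint supports
  expect_error(brayCurtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(brayCurtis(c(-1, 2), c(1, 1)), "nonnegative")
  expect_equal(euclideanDistance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclideanDistance(c(1, 2), c(1, 2)), 0)
  # sign-safe on variance-stabilized style input
  expect_equal(euclideanDistance(c(-3, 0), c(0, 4)), 5)
  # the matrix path agrees with vegan
  m <- rbind(s1 = c(2, 2, 1), s2 = c(1, 3, 0), s3 = c(0, 0, 4))
  expect_equal(rarebench:::.brayMatrix(m),
               as.matrix(vegan::vegdist(m, "bray")), ignore_attr = TRUE)
})

test_that("Poisson dissimilarity matches an independent deviance oracle", {
  x <- rbind(s1 = c(10L, 3L), s2 = c(2L, 9L))
  d <- poissonDistance(countTable(x, groups = c("A", "B")),
                       transform = FALSE)
  # oracle: sum over both samples of Poisson log-likelihood at the MLE rate
  # minus at the shared (size-factored) rate, via dpois
  ll <- function(obs, rate) sum(dpois(obs, rate, log = TRUE)[obs > 0],
                                (-rate + 0)[obs == 0])
  s1 <- sum(x[1, ]) / sum(x)
  pooled <- x[1, ] + x[2, ]
  oracle <- (ll(x[1, ], pmax(x[1, ], 1e-300)) - ll(x[1, ], s1 * pooled)) +
    (ll(x[2, ], pmax(x[2, ], 1e-300)) - ll(x[2, ], (1 - s1) * pooled))
  expect_equal(distValues(d)[1, 2], oracle, tolerance = 1e-9)
  expect_equal(distValues(d)[1, 2], distValues(d)[2, 1])
  same <- poissonDistance(rbind(a = c(5L, 5L), b = c(5L, 5L)),
                          transform = FALSE)
  expect_equal(max(abs(distValues(same))), 0)
  expect_error(poissonDistance(rbind(a = c(0.5, 1), b = c(1, 1))),
               "integer")
})

test_that("UniFrac matches hand values on a two-leaf tree", {
  tree <- ape::read.tree(text = "(x:1,y:1);")
  m <- rbind(s1 = c(x = 4, y = 0), s2 = c(x = 0, y = 9))
  u <- uniFrac(m, tree, weighted = FALSE)
  w <- uniFrac(m, tree, weighted = TRUE, normalized = TRUE)
  expect_equal(distValues(u)[1, 2], 1)
  expect_equal(distValues(w)[1, 2], 1)
  ident <- rbind(s1 = c(x = 2, y = 2), s2 = c(x = 2, y = 2))
  expect_equal(max(abs(distValues(uniFrac(ident, tree, weighted = TRUE)))), 0)
  expect_equal(max(abs(distValues(uniFrac(ident, tree)))), 0)
  expect_error(uniFrac(rbind(s1 = c(x = 1, z = 1)), tree), "missing")
})

test_that("unweighted UniFrac only sees presence/absence", {
  pp <- tinyParents(nOtus = 12, seed = 3)
  tree <- parentTree(pp)
  set.seed(8)
  m <- matrix(rpois(5 * 12, 2), 5, 12,
              dimnames = list(sprintf("s%d", 1:5), otuIds(pp)))
  m2 <- m
  m2[2, ] <- m2[2, ] * 13  # rescale one row
  expect_equal(distValues(uniFrac(m, tree)), distValues(uniFrac(m2, tree)))
})

test_that("UniFrac equals brute-force branch enumeration on random trees", {
  for (s in 1:4) {
    pp <- makeSyntheticParents(nOtus = 10, overlapFraction = 1, seed = s)
    tree <- ape::keep.tip(parentTree(pp), otuIds(pp)[1:8])
    set.seed(100 + s)
    m <- matrix(rpois(6 * 8, 3), 6, 8,
                dimnames = list(sprintf("s%d", 1:6), tree$tip.label))
    m[m == 0 & row(m) == 1] <- 1  # avoid an empty sample
    for (weighted in c(FALSE, TRUE)) {
      mine <- distValues(uniFrac(m, tree, weighted = weighted))
      brute <- bruteUniFrac(m, tree, weighted = weighted)
      expect_lt(max(abs(mine - brute)), 1e-9)
    }
  }
})

test_that("unweighted UniFrac agrees with picante", {
  skip_if_not_installed("picante")
  pp <- makeSyntheticParents(nOtus = 15, overlapFraction = 1, seed = 2)
  tree <- parentTree(pp)
  set.seed(5)
  m <- matrix(rpois(6 * 15, 2) + 1L, 6, 15,
              dimnames = list(sprintf("s%d", 1:6), otuIds(pp)))
  mine <- distValues(uniFrac(m, tree, weighted = FALSE))
  ref <- as.matrix(picante::unifrac(as.data.frame(m), tree))
  expect_equal(mine[rownames(ref), colnames(ref)], ref, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("top-MSD picks the largest squared log differences", {
  v <- rbind(s1 = c(1, 2, 3), s2 = c(2, 4, 6))  # log-scale differences 1,2,3
  d <- topMsd(v, nTop = 2)
  expect_equal(distValues(d)[1, 2], sqrt((9 + 4) / 2))
  # nTop = all OTUs collapses to the root-mean-square difference
  dAll <- topMsd(v, nTop = 3)
  expect_equal(distValues(dAll)[1, 2], sqrt(mean(c(1, 4, 9))))
  expect_equal(distValues(topMsd(rbind(a = 1:3, b = 1:3), nTop = 3))[1, 2], 0)
  expect_warning(topMsd(v, nTop = 10), "clamping")
})

test_that("the pairing table gates distanceMatrix and records NA", {
  tab <- filterRareOtus(tinyTable())
  tree <- parentTree(tinyParents())
  v <- normalizeVst(tab)
  expect_identical(distanceMatrix(v, "bray"), NA)
  expect_s4_class(distanceMatrix(v, "euclidean"), "DistanceMatrix")
  expect_identical(distanceMatrix(normalizeUq(tab), "bray"), NA)
  expect_s4_class(distanceMatrix(normalizeUq(tab), "top_msd"),
                  "DistanceMatrix")
  # the admissible count per normalization matches the pairing table
  p <- admissiblePairs()
  expect_equal(lengths(p)[c("raw", "relabund", "subsample", "rarefy", "vst",
                            "uq_logfc")],
               c(raw = 4L, relabund = 3L, subsample = 6L, rarefy = 6L,
                 vst = 1L, uq_logfc = 1L))
  expect_true("bray" %in% admissiblePairs(pathology = TRUE)$vst)
})

test_that("distance matrices are symmetric, zero-diagonal and bounded", {
  tab <- filterRareOtus(tinyTable())
  pp <- tinyParents()
  rel <- normalizeRelabund(tab)
  for (meth in c("bray", "unifrac_u", "unifrac_w")) {
    dm <- distanceMatrix(rel, meth, tree = parentTree(pp))
    v <- distValues(dm)
    expect_lt(max(abs(v - t(v))), 1e-10)
    expect_equal(max(abs(diag(v))), 0)
    expect_true(all(v >= 0 & v <= 1 + 1e-12))
  }
})

test_that("rarefaction-averaged matrices stay in the iteration envelope", {
  tab <- filterRareOtus(tinyTable())
  params <- pickThreshold(tab, 0, nIterations = 8, seed = 55)
  avg <- distValues(distanceMatrix(tab, "bray", params = params))
  iters <- rarefyMetric(tab, params, "bray", returnIterations = TRUE)
  lo <- Reduce(pmin, iters$iterations)
  hi <- Reduce(pmax, iters$iterations)
  expect_true(all(avg >= lo - 1e-12 & avg <= hi + 1e-12))
  expect_equal(avg, iters$mean)
})
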