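test_that("mixing is null at effect size 1 and follows the formula", {
  pp <- tinyParents()
  m <- mixParents(pp, 1.00)
  expect_equal(m$mixA, m$mixB)
  expect_equal(sum(m$mixA), 1, tolerance = 1e-12)
  # two disjoint single-OTU parents at effect 3.5
  tree <- ape::read.tree(text = "(OTU1:1,OTU2:1);")
  pp2 <- newParentPair(c("OTU1", "OTU2"), c(1, 0), c(0, 1), tree)
  m2 <- mixParents(pp2, 3.5)
  expect_equal(unname(m2$mixA), c(3.5, 1) / 4.5)
  expect_equal(unname(m2$mixB), c(1, 3.5) / 4.5)
  expect_error(mixParents(pp, 0.9), "effectSize")
})

test_that("multinomial draws hit assigned depths exactly and are seeded", {
  a <- tinyAssignment()
  tab <- tinyTable(assignment = a)
  expect_identical(unname(sampleDepths(tab)), unname(sampleDepths(a)))
  expect_identical(otuCounts(tinyTable(assignment = a)), otuCounts(tab))
  expect_false(identical(otuCounts(tinyTable(seed = 99, assignment = a)),
                         otuCounts(tab)))
  expect_identical(sampleGroups(tab), sampleGroups(a))
})

test_that("per-OTU count means match the binomial moments", {
  # depth * mix within 3 Monte-Carlo SE, averaged over replicate draws
  tree <- ape::read.tree(text = "((OTU1:1,OTU2:1):1,OTU3:2);")
  pp <- newParentPair(paste0("OTU", 1:3), c(6, 3, 1), c(1, 3, 6), tree)
  m <- mixParents(pp, 2)
  a <- tinyAssignment(seed = 5)
  depth <- sampleDepths(a)
  nRep <- 200
  sums <- matrix(0, 80, 3)
  for (r in seq_len(nRep))
    sums <- sums + otuCounts(drawSamples(m$mixA, m$mixB, a, seed = r))
  means <- sums / nRep
  p <- t(vapply(sampleGroups(a),
                function(g) if (g == "A") m$mixA else m$mixB, numeric(3)))
  expected <- p * depth
  se <- sqrt(depth * p * (1 - p) / nRep)
  expect_true(all(abs(means - expected) <= 3 * se + 1e-9))
})

test_that("the two-step rare-OTU filter applies its conjunctions", {
  base <- matrix(5L, nrow = 80, ncol = 1, dimnames = list(NULL, "keep"))
  mk <- function(col, name) {
    countTable(cbind(base, matrix(col, ncol = 1,
                                  dimnames = list(NULL, name))),
               groups = rep(c("A", "B"), each = 40))
  }
  # total 2 in 1 sample: fails both step-1 clauses -> removed
  v <- integer(80); v[1] <- 2L
  expect_false("low" %in% otuIds(filterRareOtus(mk(v, "low"))))
  # count 2 in each of 5 samples: survives step 1 (prevalence 5) and step 2
  # (more than one read in 5 > 4 samples) -> retained
  v <- integer(80); v[1:5] <- 2L
  expect_true("five2s" %in% otuIds(filterRareOtus(mk(v, "five2s"))))
  # a single count of 25: fails the >1-read-in->4-samples clause but its
  # total 25 > 20 rescues it in step 2 -> retained
  v <- integer(80); v[1] <- 25L
  expect_true("single25" %in% otuIds(filterRareOtus(mk(v, "single25"))))
  # one read in each of 4 samples: survives step 1 (prevalence 4 >= 3),
  # removed in step 2 (0 samples with >1 read, total 4 <= 20)
  v <- integer(80); v[1:4] <- 1L
  expect_false("spread1s" %in% otuIds(filterRareOtus(mk(v, "spread1s"))))
})

test_that("filtering is idempotent, drops only columns, keeps counts", {
  tab <- tinyTable()
  f1 <- filterRareOtus(tab)
  f2 <- filterRareOtus(f1)
  expect_identical(otuCounts(f1), otuCounts(f2))
  expect_identical(rownames(otuCounts(f1)), rownames(otuCounts(tab)))
  expect_identical(otuCounts(f1),
                   otuCounts(tab)[, otuIds(f1), drop = FALSE])
  allLow <- countTable(matrix(c(1L, rep(0L, 79)), ncol = 1,
                              dimnames = list(NULL, "only")),
                       groups = rep(c("A", "B"), each = 40))
  expect_error(filterRareOtus(allLow), "no OTUs survive")
})

test_that("null simulations show no systematic group difference", {
  # effect 1.00: two-sample t on per-OTU group means across replicate
  # tables rejects at roughly the nominal rate
  pp <- tinyParents(nOtus = 30, seed = 3)
  a <- tinyAssignment(seed = 4)
  nRep <- 60
  mA <- mB <- matrix(NA_real_, nRep, 30)
  for (r in seq_len(nRep)) {
    tab <- simulateCounts(pp, 1.00, a, seed = 1000 + r)
    rel <- normValues(normalizeRelabund(tab))
    g <- sampleGroups(tab)
    mA[r, ] <- colMeans(rel[g == "A", ])
    mB[r, ] <- colMeans(rel[g == "B", ])
  }
  # per-OTU two-sample t across replicates; nominal rejection rate
  pvals <- vapply(seq_len(30), function(g) t.test(mA[, g], mB[, g])$p.value,
                  numeric(1))
  expect_lt(mean(pvals < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 30))
})
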