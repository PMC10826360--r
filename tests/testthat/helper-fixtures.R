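# Shared fixtures, built in code at test time.

# Small parent pair + depth assignment + simulated table for pipeline tests.
tinyParents <- function(nOtus = 60, overlap = 0.6, seed = 11) {
  makeSyntheticParents(nOtus = nOtus, overlapFraction = overlap, seed = seed)
}

tinyAssignment <- function(targetMedian = 1000, assignment = "randomized",
                           seed = 12) {
  assignDepths(depthModel("log_scaled", targetMedian = targetMedian,
                          assignment = assignment), seed = seed)
}

tinyTable <- function(effectSize = 1.5, seed = 13, parents = tinyParents(),
                      assignment = tinyAssignment()) {
  simulateCounts(parents, effectSize, assignment, seed = seed)
}

# Two tight, well-separated blocks of samples as a distance matrix.
blockDistance <- function(nPerBlock = 5, within = 0.1, between = 5,
                          jitterSeed = 21) {
  n <- 2 * nPerBlock
  d <- matrix(between, n, n)
  d[seq_len(nPerBlock), seq_len(nPerBlock)] <- within
  d[(nPerBlock + 1):n, (nPerBlock + 1):n] <- within
  set.seed(jitterSeed)
  noise <- matrix(stats::runif(n * n, 0, 0.01), n, n)
  d <- d + noise + t(noise)
  diag(d) <- 0
  dimnames(d) <- list(sprintf("S%02d", 1:n), sprintf("S%02d", 1:n))
  (d + t(d)) / 2
}

# Independent brute-force UniFrac: enumerate every branch, find its
# descendant tips by walking the edge table, and apply the definitions
# directly. Used as the oracle for the postorder implementation.
bruteUniFrac <- function(x, tree, weighted = FALSE, normalized = TRUE) {
  tips <- tree$tip.label
  descendantTips <- function(node) {
    if (node <= length(tips)) return(tips[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, descendantTips))
  }
  branches <- lapply(seq_len(nrow(tree$edge)), function(k)
    list(len = tree$edge.length[k],
         tips = descendantTips(tree$edge[k, 2])))
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (weighted) {
        pi <- x[i, ] / sum(x[i, ])
        pj <- x[j, ] / sum(x[j, ])
        num <- den <- 0
        for (b in branches) {
          ai <- sum(pi[b$tips]); aj <- sum(pj[b$tips])
          num <- num + b$len * abs(ai - aj)
          den <- den + b$len * (ai + aj)
        }
        d[i, j] <- d[j, i] <- if (normalized) num / den else num
      } else {
        uniq <- shared <- 0
        for (b in branches) {
          ini <- any(x[i, b$tips] > 0); inj <- any(x[j, b$tips] > 0)
          if (xor(ini, inj)) uniq <- uniq + b$len
          if (ini || inj) shared <- shared + b$len
        }
        d[i, j] <- d[j, i] <- uniq / shared
      }
    }
  }
  d
}

# Exact PERMANOVA pseudo-F, coded independently from the package (explicit
# double loop over pairs).
bruteF <- function(d, groups) {
  n <- nrow(d)
  a <- length(unique(groups))
  sst <- ssw <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sst <- sst + d[i, j]^2 / n
      if (groups[i] == groups[j])
        ssw <- ssw + d[i, j]^2 / sum(groups == groups[i])
    }
  }
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}
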