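# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain-R dynamic programming, exhaustive
# enumeration, and quadratic brute force.

# Full (unbanded) semiglobal edit-distance DP in plain R: unit costs,
# anchored at the start of both sequences, trailing gaps free (minimum over
# last row and last column); N matches nothing.
oracle_similarity <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  D <- matrix(0L, m + 1, n + 1)
  D[, 1] <- 0:m; D[1, ] <- 0:n
  for (i in 1:m) for (j in 1:n) {
    mis <- if (av[i] == bv[j] && av[i] != "N") 0L else 1L
    D[i + 1, j + 1] <- min(D[i, j] + mis, D[i, j + 1] + 1L, D[i + 1, j] + 1L)
  }
  d <- min(min(D[m + 1, ]), min(D[, n + 1]))
  max(0, 1 - d / min(m, n))
}

# exhaustive enumeration of all C(N, n) uniform samples; returns the
# probability that every listed cluster contributes <= 1 sampled sequence
# (miss-all) and, for a single cluster, the detection probability
enumerate_samples <- function(N, n, cluster_of) {
  # cluster_of: integer vector length N; 0 = background
  combs <- utils::combn(N, n)
  ncl <- max(cluster_of)
  miss_all <- 0L; detect_first <- 0L
  for (s in seq_len(ncol(combs))) {
    got <- tabulate(cluster_of[combs[, s]], nbins = max(ncl, 1))
    if (all(got <= 1L)) miss_all <- miss_all + 1L
    if (ncl >= 1L && got[1] >= 2L) detect_first <- detect_first + 1L
  }
  list(p_miss_all = miss_all / ncol(combs),
       p_detect_first = detect_first / ncol(combs))
}

cluster_labels <- function(N, rho) {
  # first clusters, then background
  lab <- integer(N)
  pos <- 1L
  for (k in seq_along(rho)) {
    lab[pos:(pos + rho[k] - 1L)] <- k
    pos <- pos + rho[k]
  }
  lab
}

# quadratic brute-force fragmentation curve
oracle_fragmentation <- function(sizes) {
  sizes <- sizes[sizes >= 2]
  xs <- sort(unique(sizes), decreasing = TRUE)
  data.frame(x = xs,
             F = vapply(xs, function(x) {
               tot <- 0L
               for (s in sizes) if (s >= x) tot <- tot + s
               tot
             }, integer(1)))
}

random_dna <- function(L) paste(sample(c("A", "C", "G", "T"), L,
                                       replace = TRUE), collapse = "")

# small well-separated planted community for kernel tests
tiny_community <- function(seed = 1, nClusters = 4, size = 5, L = 60,
                           threshold = 0.9) {
  simulateCommunity(nClusters = nClusters, sizeDistribution = "uniform",
                    sizeParams = list(min = size, max = size),
                    singletonFraction = 0, seqLength = L,
                    threshold = threshold, seed = seed)
}
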