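test_that("similarity handles identity, free trailing gaps and substitutions", {
  expect_equal(seqSimilarity("ACGT", "ACGT"), 1)
  expect_equal(seqSimilarity("ACGT", "ACGTTT"), 1)      # trailing gaps free
  expect_equal(seqSimilarity("ACGTTT", "ACGT"), 1)      # either sequence
  expect_equal(seqSimilarity("ACGT", "AGGT"), 0.75)     # one substitution / 4
  expect_equal(seqSimilarity("TACGT", "ACGT"), 0.75)    # leading gap costs
  expect_error(seqSimilarity("", "ACGT"), "non-empty")
})

test_that("N bases match nothing", {
  expect_equal(seqSimilarity("ACNT", "ACGT"), 0.75)
  expect_equal(seqSimilarity("ACNT", "ACNT"), 0.75)  # N does not match N
})

test_that("similarity agrees with a plain-R full-DP oracle on random pairs", {
  set.seed(42)
  n_pairs <- 1000
  a <- character(n_pairs); b <- character(n_pairs)
  for (i in seq_len(n_pairs)) {
    La <- sample(8:40, 1); a[i] <- random_dna(La)
    if (i %% 3 == 0) {
      # related pair: mutate a few positions / extend the end
      v <- strsplit(a[i], "")[[1]]
      k <- sample(0:3, 1)
      if (k > 0) {
        pos <- sample(length(v), k)
        v[pos] <- sample(c("A", "C", "G", "T", "N"), k, replace = TRUE)
      }
      b[i] <- paste(c(v, sample(c("A", "C", "G", "T"),
                                sample(0:5, 1), replace = TRUE)),
                    collapse = "")
    } else {
      b[i] <- random_dna(sample(8:40, 1))
    }
  }
  got <- seqSimilarity(a, b)
  want <- mapply(oracle_similarity, a, b, USE.NAMES = FALSE)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("similarity is symmetric for equal-length inputs and 1 on self", {
  set.seed(7)
  for (i in 1:50) {
    a <- random_dna(30); b <- random_dna(30)
    expect_identical(seqSimilarity(a, b), seqSimilarity(b, a))
    expect_equal(seqSimilarity(a, a), 1)
  }
})

test_that("greedy clustering merges identical sequences and splits distant ones", {
  amp <- AmpliconSet(c(a = "ACGTACGTACGT", b = "ACGTACGTACGT"))
  cs <- greedyCluster(amp, 0.9)
  expect_equal(nClusters(cs), 1L)
  expect_equal(unname(clusterSizes(cs, "distinct")), 2L)

  far <- AmpliconSet(c(a = "ACGTACGTACGT", b = "TTTTGGGGCCCC"))
  cs2 <- greedyCluster(far, 0.9)
  expect_equal(nClusters(cs2), 2L)
})

test_that("greedy clustering recovers well-separated planted clusters and partitions the sample", {
  # members carry at most 1% edits, clustered at a 3% radius: any two
  # members of one planted cluster are within 2% of each other, so the
  # greedy pass cannot split a planted cluster
  comm <- simulateCommunity(nClusters = 4, sizeDistribution = "uniform",
                            sizeParams = list(min = 5, max = 5),
                            singletonFraction = 0, seqLength = 100,
                            threshold = 0.99, seed = 9)
  cs <- greedyCluster(comm$amplicons, 0.97)
  expect_equal(nClusters(cs), 4L)
  mem <- clusterMembers(cs)
  # partition: every input record appears exactly once
  expect_setequal(mem$member_id, names(comm$amplicons))
  expect_false(anyDuplicated(mem$member_id) > 0)
  # clusters match ground truth
  truth <- comm$truth
  agree <- merge(mem, truth, by = "member_id")
  grouping <- table(agree$cluster_id.x, agree$cluster_id.y)
  expect_true(all(rowSums(grouping > 0) == 1))  # no cluster mixes truths
  # every member satisfies the radius to its representative (hard invariant)
  sims <- seqSimilarity(
    as.character(sequences(comm$amplicons)[mem$member_id]),
    as.character(sequences(comm$amplicons)[mem$representative_id]))
  expect_true(all(sims >= 0.97))
})

test_that("sequences are processed longest-first and join the first matching cluster", {
  # L1 seeds first (longest); S matches both L1 and L2 but must join L1,
  # the first-created cluster, not the closer L2
  base <- strrep("ACGT", 8)                       # 32 bp
  L1 <- paste0(base, "TTTTT")                     # 37 bp, seeds first
  v <- strsplit(base, "")[[1]]; v[1] <- "G"
  L2 <- paste0(paste(v, collapse = ""), "AAAA")   # 36 bp, second seed
  S <- paste(v, collapse = "")                    # 32bp: identical prefix of L2
  amp <- AmpliconSet(c(l1 = L1, l2 = L2, s = S))
  cs <- greedyCluster(amp, 0.9)
  mem <- clusterMembers(cs)
  expect_equal(mem$cluster_id[mem$member_id == "s"], "l1")
})

test_that("baiting assigns pool sequences to the best representative with stated tie-breaks", {
  rep1 <- strrep("ACGT", 10)
  other <- random_dna(40)
  reps <- AmpliconSet(c(r1 = rep1))
  pool <- AmpliconSet(c(copy = rep1, junk = other))
  res <- baitPool(reps, pool, 0.9)
  expect_equal(res$assignments$member_id, "copy")
  expect_equal(res$leftover, "junk")
  # conservation
  expect_equal(nrow(res$assignments) + length(res$leftover), length(pool))

  # equidistant sequence goes to the higher-multiplicity representative
  set.seed(2)
  center <- random_dna(40)
  v <- strsplit(center, "")[[1]]
  va <- v; va[5] <- setdiff(c("A","C","G","T"), v[5])[1]
  vb <- v; vb[30] <- setdiff(c("A","C","G","T"), v[30])[1]
  repA <- paste(va, collapse = ""); repB <- paste(vb, collapse = "")
  reps2 <- AmpliconSet(c(zA = repA, aB = repB), multiplicity = c(5L, 2L))
  res2 <- baitPool(reps2, AmpliconSet(c(x = center)), 0.9)
  expect_equal(res2$assignments$rep_id, "zA")  # mult 5 beats mult 2 despite id order
  expect_error(baitPool(AmpliconSet(Biostrings::DNAStringSet()),
                        AmpliconSet(c(x = center)), 0.9), "empty")
})

test_that("baiting with true centroids recovers planted memberships", {
  comm <- simulateCommunity(nClusters = 10, sizeDistribution = "uniform",
                            sizeParams = list(min = 8, max = 20),
                            singletonFraction = 0.2, seqLength = 120,
                            threshold = 0.95, seed = 21)
  cen_ids <- unname(comm$centroids)
  pool <- comm$amplicons[setdiff(names(comm$amplicons), cen_ids)]
  res <- baitPool(comm$amplicons[cen_ids], pool, 0.95)
  truth <- comm$truth
  want <- truth[truth$member_id %in% names(pool), ]
  # every planted member recruited to its own centroid; singletons leftover
  expect_equal(sort(res$assignments$member_id), sort(want$member_id))
  agreement <- merge(res$assignments, want, by = "member_id")
  cen_cluster <- stats::setNames(names(comm$centroids), unname(comm$centroids))
  expect_true(all(cen_cluster[agreement$rep_id] == agreement$cluster_id))
})

test_that("threshold-gated banded recruitment agrees with the full-DP oracle", {
  set.seed(33)
  theta <- 0.9
  reps <- replicate(5, random_dna(50))
  pool <- character(60)
  for (i in 1:60) {
    if (i %% 2 == 0) {
      v <- strsplit(sample(reps, 1), "")[[1]]
      k <- sample(0:6, 1)
      if (k > 0) { pos <- sample(length(v), k); v[pos] <- sample(c("A","C","G","T"), k, replace = TRUE) }
      pool[i] <- paste(v, collapse = "")
    } else pool[i] <- random_dna(50)
  }
  got <- iterotu:::.sim_to_reps(pool, reps, theta)
  for (i in seq_along(pool)) for (k in seq_along(reps)) {
    s <- oracle_similarity(pool[i], reps[k])
    if (s >= theta) expect_equal(got[i, k], s, tolerance = 1e-12)
    else expect_true(is.na(got[i, k]))
  }
})
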