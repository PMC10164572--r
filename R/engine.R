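#' Engine configuration for iterative clustering
#'
#' Bundles the tunable parameters of the iterative
#' sample-cluster-recruit loop.
#'
#' @param threshold Similarity radius in (0, 1) (default 0.97).
#' @param alpha0 Initial sampling rate: fraction of the unclustered pool
#'   drawn each iteration (default 0.001).
#' @param adapt Adapt the sampling rate upward when iteration productivity
#'   drops (default TRUE).
#' @param adaptGamma Adaptation gain: alpha grows by `adaptGamma` times the
#'   relative drop in sequences clustered versus the previous iteration
#'   (default 1).
#' @param alphaMax Cap on the adapted sampling rate (default 0.05).
#' @param modeShift Reassign each cluster's representative to its
#'   highest-multiplicity member and re-bait (default TRUE).
#' @param modeShiftRounds Number of shift-and-re-bait rounds per iteration
#'   (default 1).
#' @param maxIterations Iteration cap (default 50).
#' @param minClusterSize Minimum distinct size for a subsample cluster to be
#'   kept and for a final cluster to be reported (default 2; size-1 remnants
#'   dissolve back into the pool).
#' @param convergenceWindow,convergenceSize Terminate when no cluster of
#'   total size `>= convergenceSize` has been found in the last
#'   `convergenceWindow` iterations (defaults 5 and 10).
#' @param weightedSampling Sample records with probability proportional to
#'   multiplicity instead of uniformly (default FALSE: the pool is
#'   deduplicated and sampling is uniform over distinct records).
#' @return A classed list of settings.
#' @export
engineConfig <- function(threshold = 0.97, alpha0 = 0.001, adapt = TRUE,
                         adaptGamma = 1, alphaMax = 0.05, modeShift = TRUE,
                         modeShiftRounds = 1L, maxIterations = 50L,
                         minClusterSize = 2L, convergenceWindow = 5L,
                         convergenceSize = 10L, weightedSampling = FALSE) {
  stopifnot(threshold > 0, threshold < 1, alpha0 > 0, alpha0 <= alphaMax,
            alphaMax <= 1, adaptGamma > 0, adaptGamma <= 1,
            modeShiftRounds >= 1, maxIterations >= 1, minClusterSize >= 1,
            convergenceWindow >= 1, convergenceSize >= 1)
  structure(list(threshold = threshold, alpha0 = alpha0, adapt = adapt,
                 adaptGamma = adaptGamma, alphaMax = alphaMax,
                 modeShift = modeShift,
                 modeShiftRounds = as.integer(modeShiftRounds),
                 maxIterations = as.integer(maxIterations),
                 minClusterSize = as.integer(minClusterSize),
                 convergenceWindow = as.integer(convergenceWindow),
                 convergenceSize = as.integer(convergenceSize),
                 weightedSampling = weightedSampling),
            class = "engineConfig")
}

#' Draw one iteration's subsample from the unclustered pool
#'
#' `n = max(2, round(alpha * N))` distinct records are drawn without
#' replacement, uniformly (or multiplicity-weighted), under a seed derived
#' deterministically from the run seed and the iteration index.
#'
#' @param pool An [AmpliconSet-class] of unclustered records.
#' @param alpha Sampling rate.
#' @param seed Run seed.
#' @param iteration Iteration index (>= 1).
#' @param weighted Multiplicity-weighted sampling (default FALSE).
#' @return Character vector of sampled record ids, or `NULL` if the pool
#'   has fewer than 2 records (termination signal).
#' @export
samplePool <- function(pool, alpha, seed, iteration, weighted = FALSE) {
  N <- length(pool)
  if (N < 2L) return(NULL)
  n <- min(N, max(2L, as.integer(round(alpha * N))))
  ids <- names(pool)
  .with_seed(.iter_seed(seed, iteration), {
    if (weighted)
      sample(ids, n, prob = pool@multiplicity)
    else
      sample(ids, n)
  })
}

#' Adaptive sampling-rate update
#'
#' When the number of sequences clustered drops from one iteration to the
#' next, the sampling rate grows by `gamma` times the relative drop,
#' capped at `alphaMax`; otherwise it is unchanged. The rate is therefore
#' non-decreasing over a run.
#'
#' @param alpha Current rate.
#' @param prevClustered,curClustered Sequences clustered in the previous and
#'   current iteration.
#' @param gamma Adaptation gain in (0, 1].
#' @param alphaMax Rate cap.
#' @return The updated rate.
#' @examples
#' updateAlpha(0.001, 1000, 500, gamma = 1, alphaMax = 0.05)  # 0.0015
#' @export
updateAlpha <- function(alpha, prevClustered, curClustered, gamma = 1,
                        alphaMax = 0.05) {
  stopifnot(alpha > 0, gamma > 0, gamma <= 1, alphaMax <= 1)
  if (curClustered < prevClustered)
    alpha <- min(alphaMax,
                 alpha * (1 + gamma * (prevClustered - curClustered) /
                            max(prevClustered, 1)))
  alpha
}

#' Convergence test on the iteration history
#'
#' The run has converged when, over the last `window` iterations, no newly
#' found cluster had total size `>= sizeCutoff`: later iterations are then
#' only recovering small clusters and singleton-dominated samples.
#'
#' @param sizesByIteration List of integer vectors: total sizes of the
#'   clusters found in each iteration so far.
#' @param window Number of trailing iterations to examine.
#' @param sizeCutoff Size that still counts as progress.
#' @return `TRUE` if converged. Fewer than `window` iterations: `FALSE`.
#' @export
hasConverged <- function(sizesByIteration, window = 5L, sizeCutoff = 10L) {
  if (length(sizesByIteration) < window) return(FALSE)
  tail_sizes <- sizesByIteration[(length(sizesByIteration) - window + 1L):
                                   length(sizesByIteration)]
  !any(vapply(tail_sizes, function(s) any(s >= sizeCutoff), logical(1)))
}

# choose a cluster's mode: highest multiplicity, ties -> longer sequence,
# then lexicographically smaller bases
.pick_mode <- function(member_ids, amplicons) {
  m <- unname(multiplicities(amplicons)[member_ids])
  w <- Biostrings::width(sequences(amplicons)[member_ids])
  b <- as.character(sequences(amplicons)[member_ids])
  member_ids[order(-m, -w, b, method = "radix")[1L]]
}

#' Mode-shift a single cluster against a pool
#'
#' Reassigns the cluster's representative to its highest-multiplicity
#' member (ties: longer sequence, then lexicographically smaller bases) and
#' recomputes the membership by baiting the union of the old members and
#' the pool against the new representative. Old members that fall outside
#' the radius of the new representative are released. Repeated
#' `rounds` times.
#'
#' @param memberIds Character vector of the cluster's current member ids
#'   (representative included).
#' @param poolIds Ids of unclustered records that may be newly recruited.
#' @param amplicons The [AmpliconSet-class] holding all records.
#' @param threshold Similarity radius.
#' @param rounds Number of shift-and-re-bait rounds (default 1).
#' @return A list with `representative` (id), `members` (data.frame
#'   `member_id`, `similarity`; includes the representative at similarity
#'   1), and `released` (old member ids now outside the radius).
#' @export
modeShiftCluster <- function(memberIds, poolIds, amplicons, threshold,
                             rounds = 1L) {
  stopifnot(length(memberIds) >= 1L)
  released_all <- character(0)
  rep_id <- NA_character_
  members <- data.frame(member_id = memberIds,
                        similarity = NA_real_, stringsAsFactors = FALSE)
  for (r in seq_len(rounds)) {
    rep_id <- .pick_mode(members$member_id, amplicons)
    cand <- setdiff(union(members$member_id, poolIds), rep_id)
    bait <- baitPool(amplicons[rep_id], amplicons[cand], threshold)
    new_members <- rbind(
      data.frame(member_id = rep_id, similarity = 1, stringsAsFactors = FALSE),
      data.frame(member_id = bait$assignments$member_id,
                 similarity = bait$assignments$similarity,
                 stringsAsFactors = FALSE))
    released <- setdiff(members$member_id, new_members$member_id)
    released_all <- union(setdiff(released_all, new_members$member_id),
                          released)
    poolIds <- union(setdiff(poolIds, new_members$member_id), released)
    members <- new_members
  }
  list(representative = rep_id, members = members, released = released_all)
}

# joint mode shift for all of an iteration's clusters: pick every cluster's
# mode, merge clusters that chose the same mode, then re-bait all current
# members plus the leftover pool against the new representatives in one
# competitive pass (released sequences may rejoin a different cluster here)
.mode_shift_all <- function(clusters, leftover, amplicons, threshold,
                            rounds) {
  for (r in seq_len(rounds)) {
    reps <- vapply(clusters, function(m) .pick_mode(m$member_id, amplicons),
                   character(1))
    if (anyDuplicated(reps)) {
      merged <- lapply(unique(reps), function(rid) {
        do.call(rbind, clusters[reps == rid])
      })
      clusters <- merged
      reps <- unique(reps)
    }
    all_members <- unlist(lapply(clusters, `[[`, "member_id"),
                          use.names = FALSE)
    cand <- setdiff(union(all_members, leftover), reps)
    bait <- baitPool(amplicons[reps], amplicons[cand], threshold)
    asg <- bait$assignments
    clusters <- lapply(reps, function(rid) {
      hit <- asg$rep_id == rid
      rbind(data.frame(member_id = rid, similarity = 1,
                       stringsAsFactors = FALSE),
            data.frame(member_id = asg$member_id[hit],
                       similarity = asg$similarity[hit],
                       stringsAsFactors = FALSE))
    })
    names(clusters) <- reps
    leftover <- bait$leftover
  }
  list(clusters = clusters, leftover = leftover)
}

#' Run the iterative sample-cluster-recruit engine
#'
#' Per iteration: (1) draw a subsample of the unclustered pool at the
#' current rate; (2) cluster the subsample greedily at the similarity
#' radius; (3) keep subsample clusters with at least `minClusterSize`
#' distinct members and return subsample singletons to the pool; (4) use
#' the kept representatives as baits to recruit from the whole pool; (5)
#' optionally mode-shift every cluster's representative to its
#' highest-multiplicity member and re-bait competitively (released
#' sequences may rejoin another cluster or fall back into the pool); (6)
#' remove the finally clustered records from the pool, record statistics,
#' adapt the sampling rate, and test convergence. Clusters whose distinct
#' size drops below `minClusterSize` after mode shifting are dissolved back
#' into the pool.
#'
#' @param x An [AmpliconSet-class] of deduplicated sequences.
#' @param config An [engineConfig()] list.
#' @param seed Integer run seed; identical input and seed give identical
#'   output.
#' @return An [IterativeRun-class].
#' @export
iterativeCluster <- function(x, config = engineConfig(), seed = 1L) {
  stopifnot(is(x, "AmpliconSet"), inherits(config, "engineConfig"))
  seed <- as.integer(seed)
  theta <- config$threshold
  pool_ids <- names(x)
  alpha <- config$alpha0
  history <- list(); sizes_by_iter <- list(); final_clusters <- list()
  prev_clustered <- NA_real_
  otu_counter <- 0L

  for (iter in seq_len(config$maxIterations)) {
    t0 <- proc.time()[["elapsed"]]
    N <- length(pool_ids)
    if (N < 2L) break
    pool <- x[pool_ids]
    sample_ids <- samplePool(pool, alpha, seed, iter,
                             weighted = config$weightedSampling)
    if (is.null(sample_ids)) break
    n_sampled <- length(sample_ids)

    sub_cs <- greedyCluster(x[sample_ids], theta)
    mem <- clusterMembers(sub_cs)
    dsz <- table(mem$cluster_id)
    kept_ids <- names(dsz)[dsz >= config$minClusterSize]

    clusters <- list(); leftover <- pool_ids
    if (length(kept_ids)) {
      kept <- mem[mem$cluster_id %in% kept_ids, , drop = FALSE]
      clusters <- lapply(split(kept, kept$cluster_id), function(d)
        data.frame(member_id = d$member_id, similarity = d$similarity,
                   stringsAsFactors = FALSE))
      # split() names the list by cluster_id, which greedyCluster sets to
      # the representative id
      pool_rest <- setdiff(pool_ids, kept$member_id)
      bait <- baitPool(x[names(clusters)], x[pool_rest], theta)
      asg <- bait$assignments
      clusters <- lapply(names(clusters), function(rid) {
        hit <- asg$rep_id == rid
        rbind(clusters[[rid]],
              data.frame(member_id = asg$member_id[hit],
                         similarity = asg$similarity[hit],
                         stringsAsFactors = FALSE))
      })
      leftover <- bait$leftover

      if (config$modeShift) {
        ms <- .mode_shift_all(clusters, leftover, x, theta,
                              config$modeShiftRounds)
        clusters <- ms$clusters
        leftover <- ms$leftover
      }
      # dissolve sub-minimum remnants back into the pool
      sz <- vapply(clusters, nrow, integer(1))
      drop <- sz < config$minClusterSize
      if (any(drop)) {
        leftover <- union(leftover,
                          unlist(lapply(clusters[drop], `[[`, "member_id"),
                                 use.names = FALSE))
        clusters <- clusters[!drop]
      }
    }

    clustered_ids <- unlist(lapply(clusters, `[[`, "member_id"),
                            use.names = FALSE)
    total_sizes <- vapply(clusters, function(d)
      sum(unname(multiplicities(x)[d$member_id])), numeric(1))
    reads_clustered <- sum(total_sizes)

    if (length(clusters)) {
      rows <- lapply(seq_along(clusters), function(j) {
        d <- clusters[[j]]
        rep_id <- d$member_id[which(d$similarity == 1)[1L]]
        data.frame(cluster_id = sprintf("OTU%05d", otu_counter + j),
                   representative_id = rep_id,
                   member_id = d$member_id,
                   member_multiplicity =
                     unname(multiplicities(x)[d$member_id]),
                   similarity = d$similarity,
                   stringsAsFactors = FALSE)
      })
      otu_counter <- otu_counter + length(clusters)
      final_clusters[[length(final_clusters) + 1L]] <- do.call(rbind, rows)
    }

    pool_ids <- setdiff(pool_ids, clustered_ids)
    sizes_by_iter[[iter]] <- as.integer(total_sizes)
    history[[iter]] <- data.frame(
      iteration = iter, alpha_used = alpha, n_sampled = n_sampled,
      clusters_found = length(clusters),
      distinct_clustered = length(clustered_ids),
      reads_clustered = reads_clustered,
      largest_cluster = if (length(total_sizes)) max(total_sizes) else 0L,
      entropy_bits = sizeEntropy(as.integer(total_sizes)),
      pool_after = length(pool_ids),
      elapsed_s = proc.time()[["elapsed"]] - t0)

    if (config$adapt && !is.na(prev_clustered))
      alpha <- updateAlpha(alpha, prev_clustered, reads_clustered,
                           config$adaptGamma, config$alphaMax)
    prev_clustered <- reads_clustered

    # the convergence test is meaningful only once discovery has started:
    # an all-empty prefix at a small alpha is a cold start, not a plateau
    if (otu_counter > 0L &&
        hasConverged(sizes_by_iter, config$convergenceWindow,
                     config$convergenceSize)) break
  }

  members <- if (length(final_clusters)) do.call(rbind, final_clusters) else
    data.frame(cluster_id = character(0), representative_id = character(0),
               member_id = character(0), member_multiplicity = integer(0),
               similarity = numeric(0), stringsAsFactors = FALSE)
  hist_df <- if (length(history)) do.call(rbind, history) else
    data.frame(iteration = integer(0), alpha_used = numeric(0),
               n_sampled = integer(0), clusters_found = integer(0),
               distinct_clustered = integer(0), reads_clustered = numeric(0),
               largest_cluster = numeric(0), entropy_bits = numeric(0),
               pool_after = integer(0), elapsed_s = numeric(0))
  new("IterativeRun",
      clusters = new("ClusterSet", members = members, threshold = theta),
      pool = x[pool_ids], history = hist_df,
      sizesByIteration = sizes_by_iter,
      config = unclass(config), seed = seed)
}
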