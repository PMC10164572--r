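#' Generate a synthetic deduplicated amplicon community with ground truth
#'
#' Emulates the statistical structure of a deduplicated amplicon data set:
#' well-separated cluster centroids, non-singleton clusters whose total
#' (multiplicity-weighted) sizes follow a chosen distribution, a fixed
#' fraction of each cluster's mass emitted as exact centroid copies (so the
#' centroid record carries the highest multiplicity in its cluster), the
#' remaining mass as members derived from the centroid by a bounded number
#' of random edits, and a stated fraction of the total pool made of
#' singleton sequences unrelated to any centroid.
#'
#' Each member is verified to lie within the similarity radius of its
#' centroid, and every centroid pair is verified to be separated by more
#' than the radius plus a margin, so the planted partition is exactly
#' recoverable by baiting with the true centroids.
#'
#' @param nClusters Number of non-singleton clusters.
#' @param sizeDistribution One of `"geometric"`, `"uniform"`, `"normal"`;
#'   cluster total sizes are drawn from it and truncated to `>= 2`.
#' @param sizeParams Distribution parameters: `geometric` uses `list(p=)`
#'   (sizes `2 + rgeom(p)`); `uniform` uses `list(min=, max=)`; `normal`
#'   uses `list(mean=, sd=)`.
#' @param singletonFraction Fraction of the total pool that is singleton
#'   sequences (default 0.2).
#' @param seqLength Centroid length in bases (default 250).
#' @param threshold Similarity radius members must satisfy to their
#'   centroid (default 0.97).
#' @param centroidMultBoost Fraction of each cluster's mass emitted as exact
#'   centroid copies, i.e. the centroid record's multiplicity (default 0.4).
#' @param separationMargin Centroid pairs (and singleton-centroid pairs)
#'   must have similarity below `threshold - separationMargin`
#'   (default 0.05).
#' @param indelProb Probability that a single member edit is an indel rather
#'   than a substitution (default 0.1).
#' @param seed Integer seed; generation is fully deterministic given the
#'   seed.
#' @param maxAttempts Rejection-sampling cap per generated sequence.
#' @return A list with `amplicons` (an [AmpliconSet-class]),
#'   `truth` (data.frame `member_id`, `cluster_id`; singletons excluded),
#'   `centroids` (named character: cluster id -> centroid record id), and
#'   `sizes` (named integer: planted total size per cluster).
#' @export
simulateCommunity <- function(nClusters = 50L,
                              sizeDistribution = c("geometric", "uniform",
                                                   "normal"),
                              sizeParams = list(),
                              singletonFraction = 0.2,
                              seqLength = 250L,
                              threshold = 0.97,
                              centroidMultBoost = 0.4,
                              separationMargin = 0.05,
                              indelProb = 0.1,
                              seed = 1L,
                              maxAttempts = 200L) {
  sizeDistribution <- match.arg(sizeDistribution)
  stopifnot(nClusters >= 1, singletonFraction >= 0, singletonFraction < 1,
            threshold > 0.5, threshold < 1, centroidMultBoost > 0,
            centroidMultBoost <= 1, separationMargin >= 0,
            threshold - separationMargin > 0.5)
  bases <- c("A", "C", "G", "T")
  emax <- max(1L, as.integer(floor((1 - threshold + 1e-9) * seqLength)))
  .with_seed(seed, {
    sizes <- switch(sizeDistribution,
      geometric = {
        p <- if (is.null(sizeParams$p)) 0.02 else sizeParams$p
        2L + stats::rgeom(nClusters, p)
      },
      uniform = {
        a <- if (is.null(sizeParams$min)) 2L else as.integer(sizeParams$min)
        b <- if (is.null(sizeParams$max)) 200L else as.integer(sizeParams$max)
        sample(max(2L, a):b, nClusters, replace = TRUE)
      },
      normal = {
        mu <- if (is.null(sizeParams$mean)) 100 else sizeParams$mean
        sdv <- if (is.null(sizeParams$sd)) 30 else sizeParams$sd
        pmax(2L, as.integer(round(stats::rnorm(nClusters, mu, sdv))))
      })
    cluster_ids <- sprintf("C%03d", seq_len(nClusters))
    names(sizes) <- cluster_ids

    rand_seq <- function(L) paste(sample(bases, L, replace = TRUE),
                                  collapse = "")
    # centroids: rejection-sample until separated from all previous ones
    centroid_seq <- character(nClusters)
    for (k in seq_len(nClusters)) {
      ok <- FALSE
      for (att in seq_len(maxAttempts)) {
        cand <- rand_seq(seqLength)
        if (k == 1L ||
            all(.separated(cand, centroid_seq[seq_len(k - 1L)],
                           threshold - separationMargin))) {
          centroid_seq[k] <- cand; ok <- TRUE; break
        }
      }
      if (!ok)
        stop("could not place separated centroids; increase seqLength or ",
             "reduce nClusters")
    }

    seq_list <- list(); mult_list <- list(); id_list <- list()
    truth_member <- list(); truth_cluster <- list()
    for (k in seq_len(nClusters)) {
      s <- sizes[k]
      n_copies <- max(1L, as.integer(round(centroidMultBoost * s)))
      n_members <- s - n_copies
      cen_id <- paste0(cluster_ids[k], "_centroid")
      ids <- cen_id; seqs <- centroid_seq[k]; mult <- n_copies
      if (n_members > 0L) {
        mem_seqs <- character(n_members)
        for (j in seq_len(n_members)) {
          okm <- FALSE
          for (att in seq_len(maxAttempts)) {
            cand <- .mutate_seq(centroid_seq[k], sample(emax, 1L), indelProb,
                                bases)
            if (cand != centroid_seq[k] && !(cand %in% mem_seqs) &&
                seqSimilarity(cand, centroid_seq[k]) >= threshold) {
              mem_seqs[j] <- cand; okm <- TRUE; break
            }
          }
          if (!okm) stop("could not generate an in-radius member; ",
                         "check threshold/seqLength")
        }
        ids <- c(ids, sprintf("%s_m%03d", cluster_ids[k],
                              seq_len(n_members)))
        seqs <- c(seqs, mem_seqs)
        mult <- c(mult, rep(1L, n_members))
      }
      seq_list[[k]] <- seqs; mult_list[[k]] <- mult; id_list[[k]] <- ids
      truth_member[[k]] <- ids
      truth_cluster[[k]] <- rep(cluster_ids[k], length(ids))
    }

    M <- sum(sizes)
    n_single <- as.integer(round(singletonFraction / (1 - singletonFraction)
                                 * M))
    single_seqs <- character(n_single)
    for (j in seq_len(n_single)) {
      oks <- FALSE
      for (att in seq_len(maxAttempts)) {
        cand <- rand_seq(seqLength)
        if (all(.separated(cand, centroid_seq,
                           threshold - separationMargin))) {
          single_seqs[j] <- cand; oks <- TRUE; break
        }
      }
      if (!oks) stop("could not place separated singletons")
    }

    all_seqs <- c(unlist(seq_list), single_seqs)
    all_ids <- c(unlist(id_list),
                 if (n_single) sprintf("S%05d", seq_len(n_single)) else
                   character(0))
    all_mult <- c(unlist(mult_list), rep(1L, n_single))
    amp <- AmpliconSet(stats::setNames(all_seqs, all_ids), all_mult)
    list(amplicons = amp,
         truth = data.frame(member_id = unlist(truth_member),
                            cluster_id = unlist(truth_cluster),
                            stringsAsFactors = FALSE),
         centroids = stats::setNames(paste0(cluster_ids, "_centroid"),
                                     cluster_ids),
         sizes = sizes)
  })
}

# TRUE per reference sequence iff cand is separated from it (similarity
# strictly below sep); cheap banded check
.separated <- function(cand, refs, sep) {
  sims <- .sim_to_reps(cand, refs, sep)
  is.na(sims[1L, ])
}

# apply nEdits random edits (substitution, or indel with prob indelProb)
.mutate_seq <- function(s, nEdits, indelProb, bases) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  for (e in seq_len(nEdits)) {
    if (stats::runif(1) < indelProb && length(v) > 2L) {
      if (stats::runif(1) < 0.5) {
        pos <- sample(length(v), 1L)          # deletion
        v <- v[-pos]
      } else {
        pos <- sample(length(v) + 1L, 1L)     # insertion
        v <- append(v, sample(bases, 1L), after = pos - 1L)
      }
    } else {
      pos <- sample(length(v), 1L)            # substitution
      cur <- v[pos]
      v[pos] <- sample(setdiff(bases, cur), 1L)
    }
  }
  paste(v, collapse = "")
}

#' Lengthen a non-centroid member so greedy clustering seeds on it
#'
#' Test fixture for the mode-shifting path: appends trailing bases to one
#' non-centroid member of a planted cluster so that the longest-first greedy
#' pass seeds the cluster on a peripheral member instead of the centroid.
#' Trailing bases are free under the semiglobal similarity, so the member
#' stays within the radius of its centroid.
#'
#' @param community A community as returned by [simulateCommunity()].
#' @param clusterId Cluster to perturb.
#' @param nExtra Number of trailing bases to append beyond the longest
#'   sequence in the data set (default 3).
#' @param seed Integer seed for the appended bases.
#' @return The community list with `amplicons` modified, plus
#'   `perturbed_id` and `original_bases` (enough to revert).
#' @export
perturbRepresentative <- function(community, clusterId, nExtra = 3L,
                                  seed = 1L) {
  amp <- community$amplicons
  truth <- community$truth
  cen <- community$centroids[[clusterId]]
  members <- setdiff(truth$member_id[truth$cluster_id == clusterId], cen)
  if (!length(members))
    stop("cluster has no non-centroid member to perturb: ", clusterId)
  target <- sort(members)[1]
  seqs <- as.character(sequences(amp))
  .with_seed(seed, {
    maxlen <- max(nchar(seqs))
    extra <- maxlen + nExtra - nchar(seqs[target])
    tail_bases <- paste(sample(c("A", "C", "G", "T"), extra, replace = TRUE),
                        collapse = "")
  })
  original <- seqs[target]
  seqs[target] <- paste0(original, tail_bases)
  out <- community
  out$amplicons <- AmpliconSet(seqs, unname(multiplicities(amp)))
  out$perturbed_id <- target
  out$original_bases <- unname(original)
  out
}

#' Score a clustering against a simulated community's ground truth
#'
#' Maps every found cluster to a planted cluster through its representative
#' (the representative's ground-truth assignment) and reports recovery and
#' agreement statistics.
#'
#' @param clusters A [ClusterSet-class] (e.g. `runClusters()` of a run).
#' @param community A community from [simulateCommunity()].
#' @param minSize Only planted clusters with total size `>= minSize` count
#'   toward the recovery and recall figures (default 2: all of them).
#' @return A list: `recovered` (planted cluster ids found), `nTarget`
#'   (planted clusters at or above `minSize`), `recovery` (fraction of
#'   target clusters recovered), `precision` (fraction of member
#'   assignments whose planted cluster matches their representative's),
#'   `recall` (fraction of target-cluster members assigned to the matching
#'   found cluster), `singletonsClustered` (planted singletons placed in
#'   any cluster), and `repExact` (fraction of found clusters whose
#'   representative bases equal the planted centroid exactly).
#' @export
scoreAgainstTruth <- function(clusters, community, minSize = 2L) {
  stopifnot(is(clusters, "ClusterSet"))
  mem <- clusterMembers(clusters)
  truth <- community$truth
  truth_of <- stats::setNames(truth$cluster_id, truth$member_id)
  seqs <- as.character(sequences(community$amplicons))
  target <- names(community$sizes)[community$sizes >= minSize]

  rep_truth <- unname(truth_of[mem$representative_id])
  mem_truth <- unname(truth_of[mem$member_id])
  recovered <- unique(rep_truth[!is.na(rep_truth)])
  precision <- if (nrow(mem)) mean(!is.na(mem_truth) &
                                   !is.na(rep_truth) &
                                   mem_truth == rep_truth) else NA_real_
  # recall over members of recovered-eligible target clusters
  tgt_members <- truth$member_id[truth$cluster_id %in% target]
  placed <- mem$member_id[!is.na(mem_truth) & !is.na(rep_truth) &
                          mem_truth == rep_truth]
  recall <- if (length(tgt_members))
    mean(tgt_members %in% placed) else NA_real_
  singletons <- sum(!(mem$member_id %in% truth$member_id))

  reps <- representatives(clusters)
  rep_cluster <- truth_of[unname(reps)]
  cen_seq <- seqs[unname(community$centroids[rep_cluster])]
  rep_exact <- if (length(reps))
    mean(!is.na(rep_cluster) & seqs[unname(reps)] == cen_seq) else NA_real_

  list(recovered = recovered, nTarget = length(target),
       recovery = if (length(target))
         mean(target %in% recovered) else NA_real_,
       precision = precision, recall = recall,
       singletonsClustered = singletons, repExact = rep_exact)
}
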