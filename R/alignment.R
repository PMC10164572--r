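#' Semiglobal sequence similarity
#'
#' Similarity between two DNA sequences, defined as
#' `1 - d / length(shorter)`, where `d` is the minimum unit-cost edit
#' distance over alignments anchored at the start of both sequences with
#' trailing gaps free on either sequence (the minimum over the last row and
#' last column of the edit-distance dynamic program), clamped at 0. `N`
#' bases match nothing. This is the radius definition used throughout the
#' package: a sequence belongs to a cluster iff its similarity to the
#' cluster representative is at least the threshold.
#'
#' @param a,b Character vectors of DNA sequences (recycled elementwise; must
#'   have equal length after recycling), or single strings.
#' @return Numeric vector of similarities in `[0, 1]`.
#' @examples
#' seqSimilarity("ACGT", "ACGT")    # 1
#' seqSimilarity("ACGT", "ACGTTT")  # 1: trailing gaps are free
#' seqSimilarity("ACGT", "AGGT")    # 0.75
#' @export
seqSimilarity <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (length(a) != length(b)) {
    n <- max(length(a), length(b))
    a <- rep_len(a, n); b <- rep_len(b, n)
  }
  if (any(!nzchar(a)) || any(!nzchar(b))) stop("sequences must be non-empty")
  .sg_similarity(a, b)
}

# processing order of the greedy pass: decreasing length, then decreasing
# multiplicity, then id
.greedy_order <- function(x) {
  w <- Biostrings::width(x@sequences)
  order(-w, -x@multiplicity, names(x@sequences), method = "radix")
}

#' Greedy fixed-radius clustering
#'
#' Clusters sequences in decreasing order of length (ties: decreasing
#' multiplicity, then id): each sequence joins the first existing cluster
#' whose representative it matches at `>= threshold`, otherwise it seeds a
#' new cluster with itself as representative. All clusters, singletons
#' included, are returned. This is the incremental greedy paradigm of
#' CD-HIT-style OTU clustering.
#'
#' @param x An [AmpliconSet-class] (the subsample to cluster).
#' @param threshold Similarity radius in (0, 1).
#' @return A [ClusterSet-class]; cluster ids are the representative ids.
#' @export
greedyCluster <- function(x, threshold) {
  stopifnot(is(x, "AmpliconSet"), length(x) >= 1L,
            threshold > 0, threshold < 1)
  o <- .greedy_order(x)
  xs <- x[o]
  res <- .greedy_first_match(as.character(xs@sequences), threshold)
  ids <- names(xs@sequences)
  rep_ids <- ids[res$rep_index]
  df <- data.frame(cluster_id = rep_ids[res$cluster],
                   representative_id = rep_ids[res$cluster],
                   member_id = ids,
                   member_multiplicity = xs@multiplicity,
                   similarity = res$similarity,
                   stringsAsFactors = FALSE)
  new("ClusterSet", members = df, threshold = threshold)
}

#' Recruit pool sequences to fixed representatives (baiting)
#'
#' Every pool sequence within the similarity radius of at least one
#' representative is assigned to exactly one: the representative with the
#' highest similarity, ties broken by larger representative multiplicity,
#' then lexicographic representative id. Unrecruited sequences are returned
#' as the leftover pool. Conservation holds: assigned + leftover = pool.
#'
#' @param representatives An [AmpliconSet-class] of bait sequences.
#' @param pool An [AmpliconSet-class] to scan.
#' @param threshold Similarity radius in (0, 1).
#' @return A list with `assignments` (data.frame: `member_id`, `rep_id`,
#'   `similarity`) and `leftover` (character vector of unassigned pool ids).
#' @export
baitPool <- function(representatives, pool, threshold) {
  stopifnot(is(representatives, "AmpliconSet"), is(pool, "AmpliconSet"),
            threshold > 0, threshold < 1)
  if (length(representatives) == 0L)
    stop("empty representative set")
  empty <- data.frame(member_id = character(0), rep_id = character(0),
                      similarity = numeric(0), stringsAsFactors = FALSE)
  if (length(pool) == 0L)
    return(list(assignments = empty, leftover = character(0)))
  sims <- .sim_to_reps(as.character(pool@sequences),
                       as.character(representatives@sequences), threshold)
  rep_ids <- names(representatives@sequences)
  rep_mult <- representatives@multiplicity
  # per pool sequence: best similarity, ties -> larger rep multiplicity,
  # then lexicographic rep id
  rep_rank <- order(-rep_mult, rep_ids, method = "radix")
  rep_pref <- integer(length(rep_ids)); rep_pref[rep_rank] <- seq_along(rep_ids)
  pick <- apply(sims, 1L, function(s) {
    ok <- which(!is.na(s))
    if (!length(ok)) return(NA_integer_)
    best <- ok[s[ok] == max(s[ok])]
    best[which.min(rep_pref[best])]
  })
  hit <- !is.na(pick)
  assignments <- data.frame(
    member_id = names(pool@sequences)[hit],
    rep_id = rep_ids[pick[hit]],
    similarity = sims[cbind(which(hit), pick[hit])],
    stringsAsFactors = FALSE)
  list(assignments = assignments,
       leftover = names(pool@sequences)[!hit])
}
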