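#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet width
NULL

#' AmpliconSet: deduplicated amplicon sequences with multiplicities
#'
#' Container for a set of deduplicated amplicon sequences. Each record is a
#' DNA sequence over \{A,C,G,T,N\} with a unique id and a multiplicity: the
#' number of identical copies of that sequence observed in the raw
#' (pre-deduplication) data. The multiplicity-weighted total
#' (\code{totalReads}) is therefore the raw data set size the records stand
#' for.
#'
#' @slot sequences A [Biostrings::DNAStringSet] whose names are the record
#'   ids (unique, non-empty).
#' @slot multiplicity Integer vector, one value per sequence, all >= 1.
#'
#' @seealso [readAmplicons()], [dedupAmplicons()], [AmpliconSet()]
#' @export
setClass("AmpliconSet",
  representation(sequences = "DNAStringSet", multiplicity = "integer"))

setValidity("AmpliconSet", function(object) {
  s <- object@sequences
  m <- object@multiplicity
  msg <- character()
  if (length(s) != length(m))
    msg <- c(msg, "multiplicity length must match number of sequences")
  if (length(s)) {
    ids <- names(s)
    if (is.null(ids) || any(!nzchar(ids)))
      msg <- c(msg, "all sequences must have non-empty ids")
    else if (anyDuplicated(ids))
      msg <- c(msg, sprintf("duplicate sequence id(s): %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if (any(Biostrings::width(s) == 0L))
      msg <- c(msg, "sequences must be non-empty")
    if (any(is.na(m)) || any(m < 1L))
      msg <- c(msg, "multiplicities must be positive integers")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AmpliconSet
#'
#' @param sequences A [Biostrings::DNAStringSet] or named character vector of
#'   DNA sequences; names are record ids.
#' @param multiplicity Integer vector of per-record copy numbers (default all
#'   1).
#' @return An [AmpliconSet-class] object.
#' @examples
#' AmpliconSet(c(a = "ACGT", b = "ACGG"), multiplicity = c(3L, 1L))
#' @export
AmpliconSet <- function(sequences, multiplicity = NULL) {
  if (is.character(sequences))
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  if (is.null(multiplicity)) multiplicity <- rep(1L, length(sequences))
  multiplicity <- as.integer(multiplicity)
  new("AmpliconSet", sequences = sequences, multiplicity = multiplicity)
}

#' ClusterSet: OTU clusters over an AmpliconSet
#'
#' Result container for radius-based clustering. Each cluster has a
#' representative record and a set of members (the representative included),
#' each member annotated with its similarity to the representative. Cluster
#' sizes come in two flavours: \code{distinct} (number of deduplicated
#' records) and \code{total} (sum of member multiplicities, i.e. raw reads).
#'
#' @slot members A data.frame with columns \code{cluster_id},
#'   \code{representative_id}, \code{member_id}, \code{member_multiplicity},
#'   \code{similarity}.
#' @slot threshold The similarity radius the clusters satisfy.
#' @export
setClass("ClusterSet",
  representation(members = "data.frame", threshold = "numeric"))

setValidity("ClusterSet", function(object) {
  df <- object@members
  need <- c("cluster_id", "representative_id", "member_id",
            "member_multiplicity", "similarity")
  msg <- character()
  if (!all(need %in% names(df)))
    msg <- c(msg, paste("members must have columns:", paste(need, collapse = ", ")))
  else if (nrow(df)) {
    if (anyDuplicated(df$member_id))
      msg <- c(msg, "cluster membership overlaps: a member id appears twice")
    byc <- split(df, df$cluster_id)
    repin <- vapply(byc, function(d) d$representative_id[1] %in% d$member_id,
                    logical(1))
    if (!all(repin))
      msg <- c(msg, "every representative must be one of its cluster's members")
  }
  if (length(object@threshold) != 1L || object@threshold <= 0 ||
      object@threshold >= 1)
    msg <- c(msg, "threshold must be a single value in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' IterativeRun: state and history of an iterative clustering run
#'
#' @slot clusters The final [ClusterSet-class].
#' @slot pool The leftover unclustered [AmpliconSet-class].
#' @slot history Per-iteration statistics (one row per iteration): alpha
#'   used, sample size, clusters found, distinct and multiplicity-weighted
#'   sequences clustered, largest cluster (total size), entropy (bits) of the
#'   cluster sizes discovered, elapsed seconds.
#' @slot sizesByIteration List of integer vectors: total sizes of the
#'   clusters discovered in each iteration (for convergence and confidence
#'   diagnostics).
#' @slot config The engine configuration list used.
#' @slot seed The run seed.
#' @export
setClass("IterativeRun",
  representation(clusters = "ClusterSet", pool = "AmpliconSet",
                 history = "data.frame", sizesByIteration = "list",
                 config = "list", seed = "integer"))
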