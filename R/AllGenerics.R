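#' Accessors for AmpliconSet and ClusterSet
#'
#' @param x An [AmpliconSet-class] or [ClusterSet-class] object.
#' @name accessors
NULL

#' @describeIn accessors The underlying [Biostrings::DNAStringSet].
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @describeIn accessors Integer multiplicities (copies in the raw data).
#' @export
setGeneric("multiplicities", function(x) standardGeneric("multiplicities"))

#' @describeIn accessors Multiplicity-weighted total (raw read count).
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' @describeIn accessors Number of clusters.
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @describeIn accessors Cluster sizes, either multiplicity-weighted
#'   (`mode = "total"`, the default) or deduplicated record counts
#'   (`mode = "distinct"`).
#' @param mode Size flavour, `"total"` or `"distinct"`.
#' @export
setGeneric("clusterSizes", function(x, mode = c("total", "distinct"))
  standardGeneric("clusterSizes"))

#' @describeIn accessors Representative ids, one per cluster.
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

setMethod("sequences", "AmpliconSet", function(x) x@sequences)
setMethod("multiplicities", "AmpliconSet", function(x) {
  m <- x@multiplicity
  names(m) <- names(x@sequences)
  m
})
setMethod("totalReads", "AmpliconSet", function(x) sum(x@multiplicity))

#' @export
setMethod("length", "AmpliconSet", function(x) length(x@sequences))

#' @export
setMethod("names", "AmpliconSet", function(x) names(x@sequences))

#' Subset an AmpliconSet by index, id or logical mask
#' @param x An AmpliconSet.
#' @param i Index vector (integer, character id, or logical).
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "AmpliconSet", function(x, i, j, ..., drop = FALSE) {
  new("AmpliconSet", sequences = x@sequences[i],
      multiplicity = unname(multiplicities(x)[i]))
})

setMethod("show", "AmpliconSet", function(object) {
  cat(sprintf("AmpliconSet with %d deduplicated record(s), %d raw read(s)\n",
              length(object), totalReads(object)))
  if (length(object)) {
    w <- Biostrings::width(object@sequences)
    cat(sprintf("  lengths: %d..%d; multiplicities: %d..%d\n",
                min(w), max(w), min(object@multiplicity),
                max(object@multiplicity)))
  }
})

setMethod("nClusters", "ClusterSet", function(x)
  length(unique(x@members$cluster_id)))

setMethod("representatives", "ClusterSet", function(x) {
  df <- unique(x@members[, c("cluster_id", "representative_id")])
  stats::setNames(df$representative_id, df$cluster_id)
})

setMethod("clusterSizes", "ClusterSet", function(x,
    mode = c("total", "distinct")) {
  mode <- match.arg(mode)
  df <- x@members
  if (!nrow(df)) return(stats::setNames(integer(0), character(0)))
  if (mode == "total")
    v <- tapply(df$member_multiplicity, df$cluster_id, sum)
  else
    v <- tapply(df$member_id, df$cluster_id, length)
  stats::setNames(as.integer(v), names(v))
})

#' @describeIn accessors Membership table of a ClusterSet.
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))
setMethod("clusterMembers", "ClusterSet", function(x) x@members)

setMethod("show", "ClusterSet", function(object) {
  sz <- clusterSizes(object)
  cat(sprintf("ClusterSet: %d cluster(s) at similarity >= %.3f\n",
              nClusters(object), object@threshold))
  if (length(sz))
    cat(sprintf("  total sizes: min %d, median %d, max %d; %d member record(s)\n",
                min(sz), as.integer(stats::median(sz)), max(sz),
                nrow(object@members)))
})

setMethod("show", "IterativeRun", function(object) {
  h <- object@history
  cat(sprintf("IterativeRun: %d iteration(s), %d cluster(s), %d record(s) left unclustered\n",
              nrow(h), nClusters(object@clusters), length(object@pool)))
  if (nrow(h))
    cat(sprintf("  clustered %d of %d raw reads (%.1f%%)\n",
                sum(h$reads_clustered),
                sum(h$reads_clustered) + totalReads(object@pool),
                100 * sum(h$reads_clustered) /
                  (sum(h$reads_clustered) + totalReads(object@pool))))
})

#' @describeIn accessors Final clusters of an IterativeRun.
#' @export
setGeneric("runClusters", function(x) standardGeneric("runClusters"))
setMethod("runClusters", "IterativeRun", function(x) x@clusters)

#' @describeIn accessors Leftover unclustered pool of an IterativeRun.
#' @export
setGeneric("runPool", function(x) standardGeneric("runPool"))
setMethod("runPool", "IterativeRun", function(x) x@pool)

#' @describeIn accessors Per-iteration statistics of an IterativeRun.
#' @export
setGeneric("runHistory", function(x) standardGeneric("runHistory"))
setMethod("runHistory", "IterativeRun", function(x) x@history)
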