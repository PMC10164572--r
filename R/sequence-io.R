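#' Read amplicon sequences from FASTA
#'
#' Reads a (optionally gzip-compressed) FASTA file into an
#' [AmpliconSet-class]. Multiplicities are parsed from a USEARCH-style
#' `;size=K` suffix on the header when present, otherwise set to 1.
#' Sequences are uppercased.
#'
#' @param path Path to a FASTA or FASTA.gz file.
#' @return An [AmpliconSet-class].
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a;size=3", "ACGT", ">b", "ACGG"), f)
#' readAmplicons(f)
#' @export
readAmplicons <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  head_lines <- readLines(con, n = 50L)
  close(con)
  nonblank <- head_lines[nzchar(trimws(head_lines))]
  if (!length(nonblank))
    stop("empty FASTA: no records in ", path)
  if (!startsWith(nonblank[1], ">")) {
    line_no <- which(nzchar(trimws(head_lines)))[1]
    stop(sprintf("malformed FASTA at line %d of %s: expected '>' header",
                 line_no, path))
  }
  seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (!length(seqs)) stop("empty FASTA: no records in ", path)
  hdr <- sub("\\s.*$", "", names(seqs))  # first token of the header
  size <- rep(1L, length(hdr))
  has <- grepl(";size=\\d+;?$", hdr)
  size[has] <- as.integer(sub("^.*;size=(\\d+);?$", "\\1", hdr[has]))
  ids <- sub(";size=\\d+;?$", "", hdr)
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(seqs) <- ids
  AmpliconSet(seqs, size)
}

#' Write an AmpliconSet to FASTA
#'
#' Headers carry the multiplicity as a `;size=K` suffix so that
#' [readAmplicons()] round-trips the object.
#'
#' @param x An [AmpliconSet-class].
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return Invisibly, `path`.
#' @export
writeAmplicons <- function(x, path) {
  stopifnot(is(x, "AmpliconSet"))
  s <- x@sequences
  names(s) <- paste0(names(s), ";size=", x@multiplicity)
  Biostrings::writeXStringSet(s, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Merge exact-duplicate sequences, summing multiplicities
#'
#' Records with identical bases (after uppercasing) are merged into a single
#' record whose multiplicity is the sum of the merged multiplicities and
#' whose id is the lexicographically smallest of the merged ids. The
#' multiplicity-weighted total is conserved and the operation is idempotent.
#' Reverse complements are not collapsed (amplicon reads are
#' orientation-consistent).
#'
#' @param x An [AmpliconSet-class].
#' @return A deduplicated [AmpliconSet-class].
#' @export
dedupAmplicons <- function(x) {
  stopifnot(is(x, "AmpliconSet"))
  if (!length(x)) return(x)
  bases <- as.character(x@sequences)
  ids <- names(x@sequences)
  grp <- split(seq_along(bases), bases)
  keep_id <- vapply(grp, function(i) min(ids[i]), character(1))
  mult <- vapply(grp, function(i) sum(x@multiplicity[i]), numeric(1))
  # preserve first-appearance order of each distinct sequence
  first <- vapply(grp, function(i) min(i), integer(1))
  o <- order(first)
  out <- Biostrings::DNAStringSet(names(grp)[o])
  names(out) <- keep_id[o]
  AmpliconSet(out, as.integer(mult[o]))
}

#' Write clusters to a TSV and a representatives FASTA
#'
#' The TSV has one row per member with columns `cluster_id`,
#' `representative_id`, `member_id`, `member_multiplicity`,
#' `similarity_to_representative`. The companion FASTA holds each cluster's
#' representative sequence with a `;size=` suffix carrying the cluster's
#' total (multiplicity-weighted) size.
#'
#' @param clusters A [ClusterSet-class].
#' @param amplicons The [AmpliconSet-class] the clusters refer to (source of
#'   the representative sequences).
#' @param path Output TSV path.
#' @param repFasta Output FASTA path for representatives (default: `path`
#'   with a `.reps.fasta` suffix); `NULL` skips it.
#' @return Invisibly, `path`.
#' @export
writeClusterTable <- function(clusters, amplicons, path,
                              repFasta = paste0(path, ".reps.fasta")) {
  stopifnot(is(clusters, "ClusterSet"))
  df <- clusters@members
  out <- data.frame(cluster_id = df$cluster_id,
                    representative_id = df$representative_id,
                    member_id = df$member_id,
                    member_multiplicity = df$member_multiplicity,
                    similarity_to_representative = df$similarity,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(repFasta)) {
    reps <- representatives(clusters)
    tot <- clusterSizes(clusters, "total")
    if (length(reps)) {
      s <- sequences(amplicons)[unname(reps)]
      names(s) <- paste0(unname(reps), ";size=", unname(tot[names(reps)]))
      Biostrings::writeXStringSet(s, repFasta)
    } else {
      file.create(repFasta)
    }
  }
  invisible(path)
}

#' Read a cluster TSV written by writeClusterTable
#'
#' @param path TSV path.
#' @param threshold Similarity radius to stamp on the returned object
#'   (defaults to the smallest member similarity, or 0.5 for an empty table).
#' @return A [ClusterSet-class].
#' @export
readClusterTable <- function(path, threshold = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "character",
                                         "integer", "numeric"),
                          stringsAsFactors = FALSE)
  names(df) <- c("cluster_id", "representative_id", "member_id",
                 "member_multiplicity", "similarity")
  if (is.null(threshold))
    threshold <- if (nrow(df)) min(df$similarity, 0.999999) else 0.5
  threshold <- max(min(threshold, 1 - 1e-9), 1e-9)
  new("ClusterSet", members = df, threshold = threshold)
}
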