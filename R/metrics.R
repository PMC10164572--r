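#' Fragmentation curve of a clustering
#'
#' Orders clusters by decreasing size and reports, for every distinct
#' non-singleton size `x`, the total number of sequences contained in
#' clusters of size `x` or greater. Singleton clusters are ignored. When two
#' clusterings of the same data are compared, the one whose curve lies on
#' top is the less fragmented.
#'
#' @param sizes Positive integer cluster sizes (typically
#'   `clusterSizes(x, "total")`).
#' @return A data.frame with columns `x` (decreasing distinct sizes >= 2)
#'   and `F` (sequences in clusters of size >= x); zero rows if all input
#'   clusters are singletons.
#' @examples
#' fragmentationCurve(c(5, 3, 3, 1))  # x = 5: 5; x = 3: 11
#' @export
fragmentationCurve <- function(sizes) {
  stopifnot(all(sizes >= 1))
  sizes <- as.integer(sizes[sizes >= 2L])
  if (!length(sizes))
    return(data.frame(x = integer(0), F = integer(0)))
  xs <- sort(unique(sizes), decreasing = TRUE)
  Fv <- vapply(xs, function(x) sum(sizes[sizes >= x]), integer(1))
  data.frame(x = xs, F = Fv)
}

#' Shannon entropy (bits) of a set of cluster sizes
#'
#' Entropy of the empirical distribution of cluster sizes discovered in one
#' iteration; 0 for empty input or a single distinct size.
#'
#' @param sizes Integer cluster sizes.
#' @return Non-negative entropy in bits.
#' @examples
#' sizeEntropy(c(4, 4, 4))      # 0
#' sizeEntropy(c(2, 8))         # 1
#' sizeEntropy(c(2, 2, 8, 16))  # 1.5
#' @export
sizeEntropy <- function(sizes) {
  if (!length(sizes)) return(0)
  p <- table(sizes) / length(sizes)
  p <- as.numeric(p[p > 0])
  -sum(p * log2(p))
}

#' Compare two fragmentation curves for dominance
#'
#' Evaluates both curves as step functions over the union of their size
#' break points and reports whether one dominates the other everywhere or
#' the curves cross. `F(x)` of a curve at an arbitrary `x` is the total
#' sequence count in clusters of size `>= x`, i.e. the curve value at the
#' smallest break point `>= x` (0 beyond the largest).
#'
#' @param a,b Fragmentation curves as returned by [fragmentationCurve()].
#' @return A list with `relation` (one of `"equal"`, `"a_dominates"`,
#'   `"b_dominates"`, `"cross"`), and `crossings` (the x values where the
#'   sign of `a - b` changes; empty unless `relation == "cross"`).
#' @export
compareFragmentation <- function(a, b) {
  grid <- sort(unique(c(a$x, b$x)), decreasing = TRUE)
  evalF <- function(curve, x) {
    ok <- curve$x >= x
    if (!any(ok)) return(0L)
    curve$F[max(which(ok))]  # smallest break point >= x (x sorted desc)
  }
  fa <- vapply(grid, function(x) evalF(a, x), integer(1))
  fb <- vapply(grid, function(x) evalF(b, x), integer(1))
  d <- fa - fb
  if (all(d == 0)) return(list(relation = "equal", crossings = integer(0)))
  if (all(d >= 0)) return(list(relation = "a_dominates", crossings = integer(0)))
  if (all(d <= 0)) return(list(relation = "b_dominates", crossings = integer(0)))
  s <- sign(d)
  cross_at <- grid[which(s[-1] != 0 & s[-length(s)] != 0 &
                         s[-1] != s[-length(s)]) + 1L]
  list(relation = "cross", crossings = cross_at)
}
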