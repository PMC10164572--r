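#' Detection and miss probabilities under uniform subsampling
#'
#' A cluster of size `rho` in a pool of `N` deduplicated sequences is
#' *detected* by a uniform sample of `n` sequences (drawn without
#' replacement) iff the sample contains at least two of its members — the
#' minimum needed for the cluster to appear as a non-singleton in the
#' subsample clustering. These functions give the exact hypergeometric
#' probabilities and their closed-form exponential bounds. All binomial
#' coefficients are evaluated in log space (log-gamma), so pool sizes up to
#' 1e7 and beyond are safe.
#'
#' @param N Pool size (positive integer).
#' @param n Sample size, `1 <= n <= N`.
#' @param rho Cluster size(s): a single positive integer for [pDetect()] and
#'   [pMissOne()]; a vector of `m` positive integers with `sum(rho) <= N`
#'   for [pMissMany()].
#' @name detection-probability
NULL

.check_Nn <- function(N, n) {
  stopifnot(length(N) == 1L, length(n) == 1L, N >= 1, n >= 1, n <= N,
            N == round(N), n == round(n))
}

# log(sum(exp(x))) without overflow
.logsumexp <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' @describeIn detection-probability Exact probability that the cluster is
#'   detected (at least two members sampled):
#'   `sum_{i=2}^{min(n, rho)} C(N-rho, n-i) C(rho, i) / C(N, n)`.
#' @return A probability in `[0, 1]`.
#' @examples
#' pDetect(N = 10, n = 10, rho = 2)  # whole pool sampled: 1
#' pDetect(N = 10, n = 1, rho = 5)   # cannot sample two: 0
#' @export
pDetect <- function(N, n, rho) {
  .check_Nn(N, n)
  stopifnot(length(rho) == 1L, rho >= 1, rho <= N, rho == round(rho))
  imax <- min(n, rho)
  if (imax < 2) return(0)
  i <- 2:imax
  lt <- lchoose(N - rho, n - i) + lchoose(rho, i) - lchoose(N, n)
  p <- exp(.logsumexp(lt))
  min(max(p, 0), 1)
}

#' @describeIn detection-probability Probability of missing one cluster
#'   (fewer than two members sampled). Exact form
#'   `[C(N-rho, n-1) rho + C(N-rho, n)] / C(N, n)`; the exponential bound is
#'   `exp(-rho n / N) (1 + (rho n / N) exp(rho / N))`. Exact + [pDetect()]
#'   equals 1.
#' @param bound If `TRUE` return the closed-form exponential upper bound
#'   instead of the exact value.
#' @export
pMissOne <- function(N, n, rho, bound = FALSE) {
  .check_Nn(N, n)
  stopifnot(length(rho) == 1L, rho >= 1, rho <= N, rho == round(rho))
  if (bound) {
    a <- rho * n / N
    return(exp(-a) * (1 + a * exp(rho / N)))
  }
  lcNn <- lchoose(N, n)
  t1 <- lchoose(N - rho, n - 1) + log(rho) - lcNn
  t2 <- lchoose(N - rho, n) - lcNn
  p <- exp(.logsumexp(c(t1, t2)))
  min(max(p, 0), 1)
}

# elementary symmetric polynomials e_0..e_m of rho via the standard
# recurrence B[i, j] = B[i-1, j-1] * rho_i + B[i-1, j], B[0, 0] = 1
.elem_sym <- function(rho) {
  m <- length(rho)
  B <- c(1, rep(0, m))
  for (i in seq_len(m)) {
    # update in place right-to-left
    for (j in rev(seq_len(i))) B[j + 1] <- B[j] * rho[i] + B[j + 1]
  }
  B
}

#' @describeIn detection-probability Probability that all of `m` clusters of
#'   sizes `rho[1] <= ... <= rho[m]` are simultaneously missed. Exact form
#'   `sum_{i=0}^{m} e_i(rho) C(N - sum(rho), n - i) / C(N, n)` where `e_i`
#'   is the i-th elementary symmetric polynomial of the cluster sizes; the
#'   bound is `exp(-m rho[1] n / N) (1 + (rho[1] n / N) exp(m rho[1] / N))^m`.
#'   Reduces to [pMissOne()] for `m = 1`.
#' @export
pMissMany <- function(N, n, rho, bound = FALSE) {
  .check_Nn(N, n)
  stopifnot(length(rho) >= 1L, all(rho >= 1), all(rho == round(rho)),
            sum(rho) <= N)
  rho <- sort(rho)
  m <- length(rho)
  if (bound) {
    a <- rho[1] * n / N
    return(exp(-m * a) * (1 + a * exp(m * rho[1] / N))^m)
  }
  S <- sum(rho)
  e <- .elem_sym(rho)          # e[i + 1] = e_i
  lcNn <- lchoose(N, n)
  lt <- vapply(0:m, function(i) {
    lc <- lchoose(N - S, n - i)
    if (!is.finite(lc)) return(-Inf)
    log(e[i + 1]) + lc - lcNn
  }, numeric(1))
  p <- exp(.logsumexp(lt))
  min(max(p, 0), 1)
}

#' Coin-flip simulation of the iterative detection process
#'
#' Sequence-free simulator of the iterative sampling process: a community of
#' non-singleton cluster sizes plus a fixed singleton count is sampled at
#' rate `alpha` each round; each remaining cluster is independently detected
#' with its exact detection probability ([pDetect()]) via a biased coin
#' flip, detected clusters are removed, and the pool shrinks by their
#' sizes. Per-round diagnostics (entropy of the detected size distribution,
#' largest detected cluster, remaining pool) reproduce the qualitative
#' behaviour of the full algorithm: large clusters fall early, and the
#' entropy of the discovered sizes decays with the remaining pool.
#'
#' @param sizes Integer vector of non-singleton cluster sizes (all >= 2).
#' @param singletonFraction Fraction of the total pool made of singleton
#'   sequences (default 0.2): `round(f/(1-f) * sum(sizes))` singletons are
#'   added.
#' @param alpha Sampling rate per round (fraction of the remaining pool).
#' @param seed Integer seed.
#' @param maxRounds Safety cap on rounds (default 1000).
#' @return A data.frame with one row per round: `round`, `n_sampled`,
#'   `clusters_detected`, `sequences_detected`, `largest_detected`,
#'   `entropy_bits`, `remaining` (pool size after removal), and
#'   `remaining_clusters`.
#' @export
simulateDetection <- function(sizes, singletonFraction = 0.2, alpha = 0.001,
                              seed = 1L, maxRounds = 1000L) {
  stopifnot(all(sizes >= 2), singletonFraction >= 0, singletonFraction < 1,
            alpha > 0, alpha <= 1)
  sizes <- as.integer(sizes)
  n_single <- as.integer(round(singletonFraction / (1 - singletonFraction) *
                               sum(sizes)))
  N <- sum(sizes) + n_single
  rows <- vector("list", 0L)
  .with_seed(seed, {
    remaining <- sizes
    round_i <- 0L
    while (length(remaining) && round_i < maxRounds) {
      round_i <- round_i + 1L
      n <- max(2L, as.integer(round(alpha * N)))
      n <- min(n, N)
      if (N < 2L) break
      p <- vapply(remaining, function(r) pDetect(N, n, r), numeric(1))
      hit <- stats::runif(length(remaining)) < p
      det <- remaining[hit]
      rows[[round_i]] <- data.frame(
        round = round_i, n_sampled = n,
        clusters_detected = length(det),
        sequences_detected = sum(det),
        largest_detected = if (length(det)) max(det) else 0L,
        entropy_bits = sizeEntropy(det),
        remaining = N - sum(det),
        remaining_clusters = sum(!hit))
      remaining <- remaining[!hit]
      N <- N - sum(det)
    }
  })
  if (!length(rows))
    return(data.frame(round = integer(0), n_sampled = integer(0),
                      clusters_detected = integer(0),
                      sequences_detected = integer(0),
                      largest_detected = integer(0),
                      entropy_bits = numeric(0), remaining = integer(0),
                      remaining_clusters = integer(0)))
  do.call(rbind, rows)
}
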