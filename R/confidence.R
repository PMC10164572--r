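#' Confidence configuration for the detection bound
#'
#' @param r Number of simulated realizations (default 1000).
#' @param epsilon Tolerated miss fraction in (0, 1) (default 0.05).
#' @param sizeGrid Candidate cluster sizes to test (default `2:500`).
#' @return A classed list of settings.
#' @export
confidenceConfig <- function(r = 1000L, epsilon = 0.05, sizeGrid = 2:500) {
  stopifnot(r >= 1, epsilon > 0, epsilon < 1, length(sizeGrid) >= 1,
            all(sizeGrid >= 2))
  structure(list(r = as.integer(r), epsilon = epsilon,
                 sizeGrid = sort(as.integer(sizeGrid))),
            class = "confidenceConfig")
}

#' Simulation-based bound on the size of clusters that may remain undetected
#'
#' For each candidate cluster size `k`, the number of size-`k` clusters that
#' could exist this round is hypothesized as the count actually discovered
#' in the iteration plus a conservative worst-case remainder of
#' `floor(poolSize / k)` clusters hiding in the unclustered pool. The
#' round's sampling is then re-simulated `r` times: each hypothesized
#' cluster is detected with its coin-flip probability ([pDetect()]) at the
#' round's pool and sample size. Size `k` is marked *detected* when the
#' observed discovered count is at least the simulated count in at least
#' `(1 - epsilon) * r` realizations — i.e. the data are consistent with no
#' size-`k` cluster having been missed. The reported upper bound is the
#' smallest `k` such that every size `>= k` in the grid is marked detected:
#' clusters at least that large are unlikely to remain in the pool.
#'
#' @param discoveredSizes Integer vector: total sizes of the clusters
#'   discovered in the iteration under scrutiny.
#' @param poolSize Number of unclustered sequences remaining after the
#'   iteration.
#' @param nSampled Sample size used by the iteration.
#' @param cfg A [confidenceConfig()].
#' @param seed Integer seed (simulation is deterministic given it).
#' @return A list with `detected` (logical vector over `cfg$sizeGrid`),
#'   `upperBound` (smallest size from which everything is detected; `NA` if
#'   even the largest grid size is not), and `sizeGrid`.
#' @export
detectionBound <- function(discoveredSizes, poolSize, nSampled,
                           cfg = confidenceConfig(), seed = 1L) {
  stopifnot(inherits(cfg, "confidenceConfig"), poolSize >= 0, nSampled >= 1)
  grid <- cfg$sizeGrid
  N <- poolSize + sum(discoveredSizes)
  n <- min(nSampled, max(N, 1))
  detected <- logical(length(grid))
  .with_seed(seed, {
    for (gi in seq_along(grid)) {
      k <- grid[gi]
      obs <- sum(discoveredSizes == k)
      hyp <- obs + poolSize %/% k
      # hyp >= 1 implies N >= k (a size-k cluster was seen or fits the pool)
      if (hyp == 0L || N < 2L) { detected[gi] <- TRUE; next }
      p <- pDetect(N, n, k)
      sims <- stats::rbinom(cfg$r, hyp, p)
      detected[gi] <- mean(obs >= sims) >= 1 - cfg$epsilon
    }
  })
  ub <- NA_integer_
  ok_from <- rev(cumprod(rev(detected))) == 1
  if (any(ok_from)) ub <- grid[which(ok_from)[1L]]
  list(detected = detected, upperBound = ub, sizeGrid = grid)
}

#' Per-iteration detection bounds for a finished run
#'
#' Applies [detectionBound()] to every iteration of an [IterativeRun-class],
#' giving the trajectory of the upper bound on undetected cluster sizes
#' (the shaded-band diagnostic for a run).
#'
#' @param run An [IterativeRun-class].
#' @param cfg A [confidenceConfig()].
#' @param seed Integer seed.
#' @return A data.frame with `iteration`, `upper_bound`.
#' @export
runDetectionBounds <- function(run, cfg = confidenceConfig(), seed = 1L) {
  h <- runHistory(run)
  ub <- vapply(seq_len(nrow(h)), function(i) {
    db <- detectionBound(run@sizesByIteration[[i]], h$pool_after[i],
                         h$n_sampled[i], cfg,
                         seed = .iter_seed(seed, i))
    if (is.na(db$upperBound)) NA_integer_ else db$upperBound
  }, integer(1))
  data.frame(iteration = h$iteration, upper_bound = ub)
}
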