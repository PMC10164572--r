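# iterotu

Iterative subsample-and-recruit OTU clustering for amplicon sequences.

## What it is for

Marker-gene surveys (16S rRNA and similar) are clustered into operational
taxonomic units — groups of sequences within a fixed similarity radius of a
representative. One-shot greedy clusterers spend most of their time on
singletons and tiny clusters that downstream analyses discard. `iterotu`
clusters iteratively instead: each round draws a small uniform subsample of
the still-unclustered pool, greedily clusters only the subsample, and uses
the representatives of its non-singleton clusters as **baits** to recruit
everything in the pool within the radius. Abundant clusters are
overwhelmingly likely to put two members into even a tiny subsample, so the
largest clusters fall out first and the run can be stopped as soon as the
clusters of interest are in hand. Two refinements keep small subsamples
productive:

* **adaptive sampling** — when a round clusters fewer sequences than the
  previous one, the sampling rate α grows by the relative drop (capped);
* **mode shifting** — each cluster's representative is reassigned to its
  highest-multiplicity member (the most exact copies in the raw data, a
  better estimate of the biological template than the longest read) and the
  pool is re-baited once.

The target audience is microbiome researchers and method developers who
want radius-guaranteed OTUs from large deduplicated amplicon sets, plus the
probability machinery to reason about what a subsampling round can and
cannot detect.

## The model in brief

Similarity is semiglobal edit similarity: alignments anchored at the start
of both sequences, trailing gaps free, `sim = 1 − d / |shorter|`. A cluster
of size ρ in a pool of N is *detected* by a uniform sample of n sequences
iff the sample contains ≥ 2 of its members; with X ~ Hypergeometric(N, ρ, n),

```
p_detect = Σ_{i=2..min(n,ρ)} C(N−ρ, n−i) C(ρ, i) / C(N, n)  =  1 − P(X ≤ 1)
```

`pDetect()`, `pMissOne()` and `pMissMany()` evaluate these exactly in log
space, together with their closed-form exponential bounds; a coin-flip
simulator (`simulateDetection()`) and a bootstrap bound on undetected
cluster sizes (`detectionBound()`) build on them. Cluster quality is
summarised by the fragmentation curve F(x) = total sequences in clusters of
size ≥ x (singletons excluded; higher curve = less fragmented) and by the
entropy of the sizes discovered per iteration. A synthetic community
generator with ground truth (`simulateCommunity()`) makes the whole
pipeline testable offline. See the vignette
(`vignettes/iterative-otu-clustering.Rmd`) for assumptions, parameter
meanings and design decisions.

## Worked example

```r
library(iterotu)

comm <- simulateCommunity(nClusters = 12, sizeDistribution = "geometric",
                          sizeParams = list(p = 0.02), seqLength = 250,
                          threshold = 0.97, seed = 11)
comm$amplicons
#> AmpliconSet with 709 deduplicated record(s), 1028 raw read(s)
#>   lengths: 248..252; multiplicities: 1..89

run <- iterativeCluster(comm$amplicons,
                        engineConfig(threshold = 0.97, alpha0 = 0.01,
                                     maxIterations = 20), seed = 1)
run
#> IterativeRun: 16 iteration(s), 10 cluster(s), 233 record(s) left unclustered
#>   clustered 781 of 1028 raw reads (76.0%)

head(runHistory(run)[, c("iteration", "alpha_used", "n_sampled",
                         "clusters_found", "reads_clustered")], 4)
#>   iteration alpha_used n_sampled clusters_found reads_clustered
#> 1         1       0.01         7              0               0
#> 2         2       0.01         7              1             124
#> 3         3       0.01         6              0               0
#> 4         4       0.02        13              2             366
```

Iteration 1 finds nothing (a 7-record sample of 709 records rarely pairs),
iteration 2 lands two members of the biggest cluster and baiting recruits
all 124 of its reads; after the empty iteration 3 the adaptive rule doubles
α. The 233 leftover records are the planted singletons plus members of
clusters too small to pair reliably — exactly the part of the data the
iteration is designed to postpone. Against the generator's ground truth:

```r
sc <- scoreAgainstTruth(runClusters(run), comm, minSize = 20L)
cat(sprintf("recovery %.0f%%  precision %.1f%%  singletons clustered %d\n",
            100 * sc$recovery, 100 * sc$precision, sc$singletonsClustered))
#> recovery 90%  precision 100.0%  singletons clustered 0
```

and the detection model says why stopping early is safe at scale — a
cluster of 5000 reads among ~10^6, sampled at α = 0.1%:

```r
pDetect(N = 981080, n = 981, rho = 5000)
#> [1] 0.9599689
```

A command-line wrapper is installed at
`system.file("exec", "iterotu", package = "iterotu")` with subcommands
`cluster`, `prob`, `simulate-community`, `simulate-sampling`,
`fragmentation` and `confidence`; `cluster` writes a member-level TSV, a
representatives FASTA (`;size=` annotated), a per-iteration stats log and a
JSON manifest sufficient to reproduce the run byte-identically.

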