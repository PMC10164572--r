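---
title: "Iterative subsample-and-recruit OTU clustering: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative subsample-and-recruit OTU clustering: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iterotu)
```

## The problem

Amplicon surveys (16S rRNA gene and similar marker genes) produce millions
of reads that are conventionally grouped into operational taxonomic units
(OTUs): clusters of sequences within a fixed similarity radius of a
representative. Classical greedy clusterers (CD-HIT, UCLUST, DNACLUST)
process the whole data set at once, and a large share of their work is
spent on singletons and very small clusters that downstream analyses
ignore. `iterotu` implements an iterative alternative: repeatedly draw a
small uniform subsample of the still-unclustered pool, cluster only the
subsample, and use the representatives of its non-singleton clusters as
*baits* to recruit, from the whole pool, everything within the radius.
Because the probability that a subsample contains two or more members of a
cluster grows with the cluster's abundance, the iteration discovers the
largest clusters first, and the process can be stopped as soon as the
clusters of interest have been found.

## The similarity measure

All radius decisions use a semiglobal unit-cost edit distance: alignments
are anchored at the start of both sequences, gaps at the *end* of either
sequence are free (the DP minimum is taken over the last row and last
column), and

$$\mathrm{similarity}(a, b) = 1 - \frac{d(a,b)}{\min(|a|, |b|)},$$

clamped at zero. `N` bases match nothing (a conservative treatment of
ambiguity codes; the upstream tools this measure descends from do not
specify one). Free trailing gaps make length heterogeneity at amplicon 3'
ends — incomplete trimming, slight over-merging — cost nothing, while
leading gaps are disallowed because amplicons start at a common primer.
This exact anchored/free-trailing dialect is this package's definition,
stated here because upstream descriptions leave the end-gap convention
partly implicit.

Internally the DP is banded at width one beyond the largest admissible
distance for the current threshold, with early exit once a row exceeds
that limit. Any alignment of cost $d$ strays at most $d$ cells from the
diagonal, so banded values are exact whenever they matter; the test suite
checks this against an unbanded plain-R implementation on a thousand
random pairs.

## One iteration

Given the unclustered pool of $N$ deduplicated records and sampling rate
$\alpha$:

1. draw $n = \max(2, \mathrm{round}(\alpha N))$ records uniformly without
   replacement;
2. cluster the subsample greedily in decreasing length order (ties:
   decreasing multiplicity, then id) — each sequence joins the first
   existing cluster whose representative it matches at or above the
   threshold, otherwise it seeds a new one;
3. subsample clusters with fewer than two distinct members are returned to
   the pool (a sequence that fails to pair within a subsample is *not*
   known to be a singleton);
4. the remaining representatives bait the whole pool: every pool record
   within the radius of at least one representative joins the one with the
   highest similarity (ties: higher representative multiplicity, then id);
5. with mode shifting enabled, each cluster's representative is reassigned
   to its highest-multiplicity member and one joint competitive re-bait is
   run over all members plus the leftover pool; records now outside every
   radius fall back into the pool, and clusters reduced below two distinct
   members dissolve;
6. the finally clustered records leave the pool, statistics are recorded,
   the sampling rate adapts, and convergence is tested.

### Detection probability

A cluster of size $\rho$ is detectable in a round exactly when the sample
holds at least two of its members. With $X \sim$
Hypergeometric$(N, \rho, n)$,

$$p_{\mathrm{detect}} = \sum_{i=2}^{\min(n,\rho)}
\frac{\binom{N-\rho}{n-i}\binom{\rho}{i}}{\binom{N}{n}} = 1 - P(X \le 1).$$

`pDetect()`, `pMissOne()` and `pMissMany()` evaluate the exact forms in
log space (log-gamma), so pool sizes of $10^7$ and beyond are safe. The
miss probability for $m$ clusters of sizes $\rho_1 \le \dots \le \rho_m$
uses the elementary symmetric polynomials $e_i(\rho_1..\rho_m)$,

$$\bar p^{(m)} = \sum_{i=0}^{m} e_i(\rho)\,
\frac{\binom{N-\sum_j \rho_j}{n-i}}{\binom{N}{n}},$$

computed with the standard recurrence
$B_{i,j} = B_{i-1,j-1}\rho_i + B_{i-1,j}$, base $B_{0,0}=1$. A printed
source of this recurrence gives the base case as $0$ for $i=0$, which
annihilates the whole sum; the $e_0 = 1$ base is the standard one and is
validated here against exhaustive enumeration over all $\binom{N}{n}$
samples for small instances.

### The closed-form bounds and their regime

The companion exponential bounds,

$$\bar p \le e^{-\rho n/N}\Bigl(1 + \tfrac{\rho n}{N} e^{\rho/N}\Bigr),
\qquad
\bar p^{(m)} \le e^{-m\rho_1 n/N}\Bigl(1 + \tfrac{\rho_1 n}{N}
e^{m\rho_1/N}\Bigr)^m,$$

are implemented exactly as printed (`bound = TRUE`). They are useful
summaries when $\rho n / N$ is appreciable, but they are **not** valid
upper bounds in the small-$\rho n/N$ corner: for example, at
$N = 500$, $n = 50$, $\rho = 2$ the exact miss probability is
$1 - \frac{50\cdot 49}{500\cdot 499} = 0.99018$ while the formula gives
$0.98313$. The slack factor needed in the linear term behaves like
$e^{n/N}$ rather than $e^{\rho/N}$, so tiny clusters at moderate sampling
rates fall outside the bound's validity. The exact forms are the authority
throughout this package; one test asserts the printed inequality over a
wide grid and is expected to flag this corner.

### Adaptive sampling

True singletons can never pair, so as large clusters are removed the
singleton density of the pool rises and a fixed $\alpha$ becomes
unproductive. Whenever the number of sequences clustered drops relative to
the previous iteration, the rate grows by the relative drop:

$$\alpha \leftarrow \min\Bigl(\alpha_{\max},\;
\alpha\bigl(1 + \gamma\,\tfrac{\mathrm{prev} - \mathrm{cur}}
{\max(\mathrm{prev},1)}\bigr)\Bigr)
\quad\text{when } \mathrm{cur} < \mathrm{prev}.$$

The gain $\gamma$ defaults to 1 and the cap $\alpha_{\max}$ to 0.05; the
published description of this step is verbal rather than arithmetic, so
this codification (and its defaults) is this package's own, stated
openly. The rate is non-decreasing over a run.

### Mode shifting

Greedy clusterers use the longest sequence as representative, but
sequence length is shaped by experimental artifacts. The member with the
highest *multiplicity* — the most exact copies in the raw data — is a
better estimate of the biological template from which the cluster's
members diverged by sequencing error. After baiting, each cluster shifts
its representative to that member (ties: longer sequence, then
lexicographically smaller bases, for determinism) and the baiting is
repeated once with the new representatives (`modeShiftRounds` allows
more). Released sequences compete in the same re-bait pass before
returning to the pool; whether such sequences may rejoin a different
cluster within the same iteration is not pinned down by the published
description, and letting them compete immediately both conserves work and
keeps every final member inside its final representative's radius, which
the test suite asserts as a hard invariant.

### Convergence

The run stops at `maxIterations`, when fewer than two records remain, or
when no cluster of total size at least `convergenceSize` (default 10) has
been found in the last `convergenceWindow` (default 5) iterations. The
window test is only armed once at least one cluster has been found:
during a cold start at a very small $\alpha$, several initial iterations
can come up empty while the adaptive rule has had no productivity *drop*
to react to, and an unarmed window would mistake that for a plateau (this
is observable at $\alpha_0 = 0.001$ on ten-thousand-record pools).

## The detection-confidence bound

After an iteration, `detectionBound()` asks: how large could a cluster be
that is still hiding in the pool? For each candidate size $k$ it
hypothesizes the observed count of size-$k$ discoveries plus a worst-case
$\lfloor \mathrm{pool}/k \rfloor$ undiscovered clusters, simulates the
round $r$ times (default 1000) with the exact coin-flip probability, and
marks $k$ *detected* when the observed count matches or beats the
simulation in at least $(1-\varepsilon)r$ realizations (default
$\varepsilon = 0.05$). The reported bound is the smallest $k$ from which
every larger grid size is detected. How the published procedure estimates
the residual size distribution is not specified; the worst-case remainder
used here is conservative by construction, which the coverage test (50
repeated rounds on a known community) confirms.

## Diagnostics

`fragmentationCurve()` reports, for every non-singleton size $x$, the
total number of sequences in clusters of size $\ge x$; when two
clusterings of the same data are compared (`compareFragmentation()`), the
higher curve is the less fragmented. `sizeEntropy()` gives the Shannon
entropy (base 2; the base is this package's choice) of the cluster sizes
discovered in one iteration. In the coin-flip simulator
(`simulateDetection()`) the entropy of discovered sizes falls with the
remaining pool — early rounds remove a diverse set of large clusters,
late rounds a uniform trickle of small ones. The correlation checks in
the test suite evaluate rounds that discovered at least one cluster,
since the entropy of an empty discovery set carries no information and
long zero-detection stretches only add rank ties. Both diagnostics default
to multiplicity-weighted (total) cluster sizes, with distinct-record
counts available via `clusterSizes(x, "distinct")`; the probability
detection model counts sequences, and multiplicities are sequences, but the
sampler operates on deduplicated records, so both views are exposed.

## The synthetic community generator

`simulateCommunity()` emulates the structure of a deduplicated amplicon
data set, at the conditions used throughout the package's tests:

* non-singleton cluster sizes from a geometric, uniform or truncated
  normal distribution (minimum 2);
* 20% of the total pool as singleton sequences by default;
* centroid length 250 bp by default;
* a `centroidMultBoost` fraction (default 0.4) of each cluster's mass
  emitted as exact centroid copies, so the centroid record carries the
  highest multiplicity in its cluster;
* members derived from the centroid by 1 to
  $\lfloor(1-\theta)L\rfloor$ random edits, 10% of which are indels —
  amplicon platforms are substitution-dominated, and the indels exercise
  the end-gap alignment path; every member is verified to sit within the
  radius of its centroid;
* centroids (and singletons against centroids) rejection-sampled until
  pairwise similarity is below threshold minus a separation margin
  (default 0.05).

Singleton-versus-singleton separation is not checked: two independent
random 250-mers within a 0.95 radius is beyond negligible. What the
generator deliberately does *not* emulate: chimeras, quality-correlated
error profiles, clusters that abut or overlap at the radius, and
realistic phylogenetic correlation between centroids. Tests passing on
these communities therefore demonstrate the machinery (radius guarantees,
conservation, recovery of well-separated structure), not robustness to
the hard ambiguous cases of real data, where clusters blur into one
another and fixed-radius methods genuinely fragment.

`perturbRepresentative()` lengthens one non-centroid member with trailing
bases (free under the similarity) so that the longest-first greedy pass
seeds on a peripheral member — the situation mode shifting exists to
repair.

## Numerical and design choices

* All binomial coefficients in log space; probabilities clamped to
  $[0,1]$; enumeration agreement is asserted to $10^{-12}$.
* Unit edit costs (match 0, mismatch/indel 1) — the definition of edit
  distance the similarity quotes.
* Greedy assignment uses *first* match (the incremental paradigm);
  baiting uses *best* match because multiple baits compete
  simultaneously. All tie-breaks (multiplicity, length, id, bases) are
  total orders, making runs byte-reproducible for a given seed.
* Sampling is uniform over distinct records by default, matching the
  deduplicated pool the iteration operates on; multiplicity-weighted
  sampling is available (`weightedSampling`).
* Per-iteration sampling derives its stream from the run seed and the
  iteration index, so a run is reproducible from its manifest alone.

## Problem sizes used by the checks

The bundled verification uses communities of 50 clusters with total sizes
20–500 (about 12,000 distinct records) for recovery, 50 small-cluster
communities across thresholds 0.95–0.99 for the radius/conservation
sweep, 15–25 cluster communities for the mode-shift and
adaptive-versus-naive comparisons, and 60-cluster coin-flip communities
with mean cluster size 2000 for the entropy trend — sizes chosen as the
smallest at which the studied effects are comfortably visible.

## Known limitations

* A fixed similarity radius inflates richness estimates on real data;
  mode shifting concentrates clusters on dense regions of sequence space
  but does not remove the limitation.
* The closed-form miss bounds are unsafe for tiny clusters (see above);
  use the exact forms.
* Baiting is single-threaded here; per-cluster parallel baiting is a
  known avenue but out of scope.
* Only plain (optionally gzipped) FASTA with `;size=` multiplicities is
  read; quality handling, merging and primer trimming belong upstream.
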