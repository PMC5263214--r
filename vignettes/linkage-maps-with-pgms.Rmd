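---
title: "Linkage maps from probabilistic graphical models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linkage maps from probabilistic graphical models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgmmap)
```

## The problem

Genetic linkage maps order molecular markers along chromosomes and space
them in centiMorgans. Classical construction proceeds in three steps --
group markers into chromosomes, order them within a group, and estimate
adjacent distances -- and is notoriously sensitive to genotyping errors:
an erroneous marker inflates its apparent recombination with *both*
neighbours, stretching the map and destabilizing the order. The usual
remedy is post hoc: build the map assuming no error, then discard markers
with high nearest-neighbour stress (N.N.Stress). That filter is applied to
an order that the errors themselves have already distorted.

`pgmmap` takes a different route. For doubled-haploid (DH) and RIL-type
populations with two parental alleles coded $-1/+1$, the markers along a
chromosome form a Markov chain, so the *conditional-independence graph* of
the markers is a path: each marker is independent of the rest given its
two neighbours. Estimating that graph directly -- with the skeleton phase
of the PC-stable algorithm -- performs grouping, ordering and error
screening in a single step: error-laden markers lose their edges to the
chain and are "pulled aside", while translocation-induced pseudo-linkage
shows up as a cross rather than being forced into a false linear order.

## The triplet model

All closed forms live in an exactly solvable unit: an ordered triplet
$M_1$--$M_2$--$M_3$ with true recombination frequencies
$\theta_{12}, \theta_{23} \in (0, 0.5)$, no crossover interference
($\theta_{13} = \theta_{12} + \theta_{23} - 2\theta_{12}\theta_{23}$), and
locus-specific genotyping error rates $\varepsilon_k \in [0, 0.5)$ (the
probability of observing the opposite allele). With $-1/+1$ scores each
marker has mean 0 and variance 1, so correlations are plain product
moments, and each error channel simply attenuates them:

$$r_{ij} = (1 - 2\theta_{ij})(1 - 2\varepsilon_i)(1 - 2\varepsilon_j).$$

The observed recombination frequency is inflated instead:
$\rho_{ij} = \theta_{ij}(1 - e) + (1-\theta_{ij})\,e$ with
$e = \varepsilon_i + \varepsilon_j - 2\varepsilon_i\varepsilon_j$, which
factorizes as $1 - 2\rho_{ij} = (1-2\theta_{ij})(1-2\varepsilon_i)(1-2\varepsilon_j)$.
`triplet_distribution()` builds the full eight-cell phenotype distribution
by composing the transmission chain with the three flip channels rather
than transcribing per-cell formulas; the tests verify every cell and both
moments against it to $10^{-12}$.

Two consequences drive the whole package:

* **N.N.Stress law.** With Haldane distances
  $d = -\tfrac12\log(1 - 2\rho)$ of the *observed* recombination
  frequencies, the stress of the middle marker,
  $d_{12} + d_{23} - d_{13}$, collapses to $-\log(1 - 2\varepsilon_2)$:
  it depends only on the middle marker's error rate, and vanishes when
  that marker is clean no matter how noisy the flanks are
  (`theoretical_nn_stress()`).
* **Partial correlations.** The first-order partial correlation of the
  flanking pair given the middle marker,
  $\rho_{M_1 M_3 | M_2} = (r_{13} - r_{12} r_{23}) / \sqrt{(1-r_{12}^2)(1-r_{23}^2)}$,
  is exactly 0 when $M_2$ is clean and grows with $\varepsilon_2$, while
  the partial correlation between $M_2$ and either flank shrinks. This is
  what lets a conditional-independence learner drop an erroneous marker's
  edges and connect its neighbours directly.

A note on the error-configuration orderings: with
$u = 1-2\theta_{12}$, $v = 1-2\theta_{23}$, $x = 1-2\varepsilon$ for a
flank error and $w = 1-2\varepsilon_2$, the two single-flank-error bypass
partials share a numerator and differ only in denominator, with
$\mathrm{den}^2_{(\varepsilon\ \mathrm{on}\ M_1)} -
\mathrm{den}^2_{(\varepsilon\ \mathrm{on}\ M_3)} = w^2(1-x^2)(u^2-v^2)$.
Hence for $\theta_{12} > \theta_{23}$ the configuration with the error on
$M_1$ (the flank across the longer interval) yields the *larger* bypass
partial. The tests assert this derived direction on parameter grids,
together with the outer inequalities
$0 < \rho(\text{all flanks err}) < \rho(\text{one flank err}) <
\rho(\text{only } M_2 \text{ err}) < 1$.

## Skeleton estimation

`pc_skeleton()` implements the first (skeleton) phase of PC-stable.
Starting from the complete graph on the marker correlation matrix, level
$\ell = 0, 1, 2, \ldots$ freezes every node's adjacency set, then tests
each remaining edge $(i, j)$ against all conditioning sets of size $\ell$
drawn from the frozen neighbourhoods of $i$ and $j$; edges are removed
only after the level completes. Batch removal is what makes the edge set
invariant to the order in which markers appear in the input -- the suite
asserts identity across 20 random column permutations of a 300 × 200
dataset. Higher-order partial correlations are computed by recursive
application of the first-order formula; independence is judged by the
Fisher-z test, $\sqrt{n - |S| - 3}\,|\mathrm{atanh}\, r|$ against a
standard normal.

Choices that were genuinely open:

* **Test and conditioning bound.** Fisher-z with `max_cond = 3` by
  default. Marker chains rarely require higher-order separators (a path
  needs only order 1), and the bound keeps the level enumeration tractable
  at $p = 200$. Both are configuration, not dogma.
* **Binary data under a Gaussian test.** The scores are binary, and the
  Fisher-z variance $1/(n-|S|-3)$ is a bivariate-normal result. For a pair
  with recombination fraction $\rho$ the actual variance of
  $\mathrm{atanh}\,\hat r$ is $1/(4n\rho(1-\rho))$ -- close to nominal for
  loosely linked pairs, but about $17/n$ at $\rho \approx 0.015$ (1.5 cM).
  At very dense spacing the test is therefore strongly overdispersed:
  p-values are anti-conservative, true chain edges occasionally drop, and
  weakly attenuated edges survive. This is a property of the standard
  practice the package mirrors, and it is the main reason dense-map error
  screening by skeleton alone is unreliable at $n$ of a few hundred (see
  *Limitations*).
* **Degenerate conditioning** (duplicated markers make intermediate
  partials hit $\pm 1$): treated as dependence -- the edge is kept and the
  event counted -- because false removals are the costlier mistake, and
  duplicates should be collapsed by `dedup_markers()` beforehand anyway.

## Diagonal ordering

`diagonalize()` permutes the skeleton's adjacency matrix to maximize the
number of 1-entries on the first super-diagonal -- equivalently, it seeks
a vertex ordering in which as many consecutive pairs as possible are
edges. The optimum equals $p$ minus the minimum number of vertex-disjoint
paths covering the graph, a Hamiltonian-path-like (NP-hard) objective, so:

* components with at most 10 nodes are solved *exactly* by dynamic
  programming over vertex subsets (state: best score for arranging a
  subset ending at a given node);
* larger components use greedy path extension -- start at an unvisited
  node of minimal unvisited degree, extend both ends preferring
  chain-continuation neighbours -- followed by 2-opt segment reversals
  until no single reversal gains. On chain-structured skeletons the greedy
  start is already optimal or within one reversal of it; the suite checks
  equality against an independent exhaustive-permutation oracle
  (`brute_force_diagonalize()`) on 200 random graphs.

Ties are always broken by marker name, so the ordering is deterministic.
Disconnected components are ordered independently and concatenated by
decreasing size; the score counts within-component pairs only.

The **main string** is the longest consecutive run of the permutation in
which every adjacent pair is an edge; all other markers are **pulled
aside**. On a hub-and-arms skeleton (translocation), the main string can
traverse only two arms, and the remaining arms are reported as secondary
strings -- preserving the cross in the graph export instead of forcing a
line through it.

## Simulated populations

`sim_dh()` draws each individual as an independent doubled gamete: the
first marker of a chromosome is $\pm 1$ with probability $\tfrac12$, and
each subsequent marker flips with the inverse-Haldane probability of the
interval. No interference, independent chromosomes. The error and
missingness channels (`apply_genotyping_errors()`, `apply_missing()`) are
independent per-cell operations that never modify their input.

`sim_error_benchmark()` is the package's standard study condition: 200
markers evenly spaced over a single 300 cM chromosome (199 intervals of
300/199 cM, markers at both ends), 300 DH individuals, and errors at six
designated markers -- 34, 51, 63, 128, 155, 184 at rates 1, 3, 5, 1, 3,
5%. The truth and the error channel use separate substreams of the one
root seed, so the clean and observed matrices are individually
reproducible.

`sim_translocation()` models pseudo-linkage around a reciprocal
translocation breakpoint as a star of Markov chains: a latent hub variable
(the co-segregating breakpoint region) seeds four arms that extend outward
with Haldane transitions. This reproduces the characteristic cross --
complete recombination suppression at the breakpoint, linear arms --
without modelling gamete-viability selection, which the cross topology
does not require. What the generator deliberately does *not* emulate:
segregation distortion, heterozygous calls in DH data, locus-dependent
missingness patterns, and interference. Tests passing on these
simulations therefore certify the estimators and the graph machinery, not
robustness to every artefact of real genotyping platforms.

## Numerical and interface conventions

* Internal map unit is the Morgan; every user-facing column is cM.
* RF estimates $\geq 0.5$ are clamped to $0.5 - 10^{-6}$ before the
  Haldane transform, with a warning; the transform diverges at 0.5 and the
  estimator has no business there on linked markers.
* Pairwise-complete (not listwise) observations for both the RF and the
  correlation matrix; entries with fewer than `min_pairs` (default 10)
  complete pairs are flagged `NA` rather than silently reported.
* Correlations are uncentered product moments, matching the segregation
  model's zero mean; on complete data $r = 1 - 2\hat\rho$ holds exactly
  and is asserted to $10^{-12}$.
* Linkage grouping uses a strict inequality ($\hat\rho <$ threshold);
  k-medoids representative selection is PAM (BUILD + SWAP) on the RF
  matrix, deterministic given its input.
* Maps are built over the main string only; pulled-aside markers are
  reported with their classification, never placed. Spacing uses two-point
  adjacent estimates.

## Problem sizes in the test suite

The suite keeps every stochastic check at a size where the relevant
asymptotics have set in but runtimes stay in seconds: closed-form layers
are tested on parameter grids (exact); recombination-rate and stress
convergence on $n = 10^5$ two- and three-marker simulations; skeleton and
ordering behaviour on 12--50 marker chains at $n = 300$; the full
benchmark (300 × 200) for order independence, error-marker screening and
replicate-mean stress (20--30 replicates).

## Limitations

* At very dense spacing (about 1--2 cM between markers) and moderate
  population size, the Gaussian Fisher-z approximation for binary scores
  is overdispersed (see above). Consequences, all visible in the
  benchmark: occasional spurious breaks in the recovered chain,
  and unreliable detection of low-error markers by the skeleton route at
  the default $\alpha = 0.05$ -- a 1% error changes the flank partial
  correlation from ~0.70 to ~0.53, which a sample of 300 comfortably
  distinguishes from zero. The stress profile (`nn_stress_profile()`),
  whose signal is additive rather than threshold-based, remains the more
  reliable detector in this regime; the skeleton route shines with wider
  spacing or when errors are large.
* Detection of a marker's error by conditional independence requires the
  marker to be an *intermediate* conditioning variable; terminal markers
  of a chain are only screened by the stress profile.
* No interference (Haldane only), no F2/outbred populations, no
  multi-point EM spacing, no HMM imputation of missing data. RIL data are
  handled by heterozygote masking, not by a dedicated meiosis model.
* Exhaustive ordering is refused above 10 nodes; beyond the exact-DP
  cutoff the heuristic guarantees only a local optimum of the 2-opt
  neighbourhood (near-paths are in practice solved exactly).
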