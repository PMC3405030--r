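---
title: "Identifying phenotype-responsive network modules"
author: "ResponsiveModules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying phenotype-responsive network modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Expression profiling measures thousands of genes per sample, but genes act
through interacting partners. Given (i) a gene-level expression matrix over
samples that fall into known phenotype groups (for instance cell-cycle
phases under different perturbations) and (ii) an undirected
protein--protein interaction (PPI) network, we want the *network modules* —
not individual genes — whose activity discriminates the phenotypes. A
module whose activity profile separates the groups is a candidate
subnetwork biomarker; a module selected when classifying two consecutive
phases under a stimulus versus control is a candidate driver (or arrester)
of that phase transition.

## The model

**Standardization.** Each gene $i$ is z-transformed over all $m$ samples,
$z_{ij} = (g_{ij} - \mu_i)/\sigma_i$, with $\sigma_i$ the sample standard
deviation ($m-1$ denominator; this makes a three-point row $(1,2,3)$ map
exactly to $(-1,0,1)$ and matches common microarray practice). Rows with
zero variance carry no evidence and are removed before standardization;
they are never assigned $z = 0$, which would fabricate neutral evidence.

**Modules.** The PPI network, restricted to edges whose both endpoints are
measured, is decomposed into disjoint modules by Markov clustering (MCL):
the column-stochastic flow matrix (adjacency plus unit self-loops,
column-normalized) is alternately *expanded* (matrix power $e$) and
*inflated* (element-wise power $r$ with column renormalization, plus
pruning of entries below a threshold) until it stops changing. Attractor
rows (positive diagonal) seed the clusters; each node joins the attractor
receiving its largest flow, ties to the lowest attractor index, so the
clustering is hard, disjoint and fully deterministic. Defaults are the
canonical MCL settings: expansion 2, inflation 2.0, prune $10^{-5}$,
tolerance $10^{-6}$, at most 100 iterations. Modules smaller than 3 nodes
are dropped by default; published responsive modules in this setting have
3--9 members, and below 3 nodes "module" structure is indistinguishable
from a stray edge.

**Module activity.** The responsive value of module $k$ in sample $j$ is
the combined z-score
$$v_{kj} = \frac{1}{\sqrt{m_k}} \sum_{i \in k} z_{ij},$$
with $m_k$ the module size. Under independent standard-normal member
scores $v_{kj}$ is standard normal, so activities are comparable across
module sizes (the test suite verifies this calibration by simulation).

**Selection as multi-classification.** Let $\pi_0$ be the target partition
of the samples into their $C$ phenotype groups. For any partition $\pi$
and module $k$, $w_k(\pi)$ is the within-cluster sum of squares of the
module's responsive values. Because the embedding of samples in a selected
subspace is coordinate-wise, the within-cluster SSE of any binary module
selection $x$ decomposes as $W(x, \pi) = \sum_k x_k\, w_k(\pi)$ — the
quadratic form in $x$ collapses to a linear one since $x_k^2 = x_k$. With
the contribution matrix $a_{kr} = w_k(\pi_r) - w_k(\pi_0)$ over alternative
partitions $\pi_1, \dots, \pi_R$, the selection classifies the samples
when every margin $L_r(x) = \sum_k x_k a_{kr}$ is non-negative, i.e. the
target attains the minimum within-cluster SSE in the selected subspace.
The program asks for a feasible $x$ of minimum cardinality; it is a binary
integer program and NP-hard in general.

**Solvers.** `solveExact()` searches all non-empty subsets in order of
increasing size (lexicographic within a size) and is the oracle for small
instances (guarded at $K \le 20$). `greedySelect()` is the two-step
heuristic: rank modules by $s_k = -\sum_r a_{kr}$ ascending (largest
aggregate separation first, stable ties), then walk the ranked prefixes
$M_n$ computing the average power of classification
$$P(M_n) = \frac{1}{|M_n|} \sum_r \max(0,\, -L_r(M_n)),$$
and stop at the smallest prefix attaining the minimum of $P$. $P = 0$
certifies feasibility. The concrete forms of $s_k$ and $P$ are design
choices of this package: they are consistent with every stated property of
the original two-step procedure (per-module column provenance, ascending
ranking, a minimum-of-$P$ stopping rule, preference for few modules), and
both are isolated behind `rankModules()`/`greedySelect()` so they can be
swapped; the exact solver bounds the damage of a wrong guess, and the test
suite asserts that a feasible greedy selection is never smaller than the
exact optimum.

**Alternative partitions.** Exhaustively enumerating all partitions of
$m$ samples into $C$ groups is possible only while the Stirling number
$S(m, C)$ is moderate; at a realistic scale (say $m = 20$, $C = 10$,
$S \approx 5.9\times 10^{12}$) it is hopeless. `selectModules()` therefore
enumerates exhaustively when $S(m, C) \le 10^6$ (restricted-growth-string
generation, duplicate-free by construction) and otherwise uses the
*reassignment neighborhood* of the target: all canonical partitions
obtained by moving at most $d$ samples to other clusters, with $d = 2$ by
default. The neighborhood is where misclassification pressure is
concentrated — an alternative differing in one or two samples is exactly a
near-miss classification — and it is validated against a move-distance
oracle in the tests. Both the mode and $d$ are exposed.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | one-way ANOVA retention threshold (raw p) |
| `expansion`, `inflation` | 2, 2.0 | MCL flow sharpening; larger inflation, finer modules |
| `pruneThreshold` | 1e-5 | MCL sparsification per iteration |
| `minSize` | 3 | smallest module kept after clustering |
| `mode`, `cap` | auto, 1e6 | exhaustive enumeration iff $S(m,C) \le$ cap |
| `d` | 2 | neighborhood radius (samples reassigned) |
| `solver` | greedy | `exact` available for $K \le 20$ |

The ANOVA pre-filter uses the raw p-value by design (no multiple-testing
correction): it is a noise-reduction step for real expression data, not an
inference, and correcting it would only shrink the analysis universe that
downstream enrichment conditions on. The phenotype groups as labeled
(condition $\times$ phase $\times$ replicate cells collapsed to their
condition:phase label) are the ANOVA groups.

## What the synthetic generator emulates

`studyDesign()`/`makeStudy()` generate a planted-partition network (each
within-module pair an edge with probability `pIn` = 0.9, each
between-module pair with `pOut` = 0.02) and an expression matrix with one
sample per (condition, phase, replicate): Gaussian noise
$N(0, \sigma^2)$ plus an additive shift $\delta$ for the genes of a
*responsive* module in its designated phenotype cells. The default design
is two conditions $\times$ three ordered phases $\times$ two biological
replicates, ten planted modules with sizes drawn uniformly from 4--9
(published modules in this setting have 3--9 members; planted blocks below
4 nodes cannot be guaranteed denser than background at these edge
probabilities), and effect $\delta = 2$ at noise $\sigma = 1$.

Three of the ten modules respond by default. The default *responsive plan*
assigns each responsive module a distinct non-zero binary codeword over
the phenotype cells: module $b$ is shifted in the cells whose code has bit
$b$ set. Distinct codes make every pair of cells separable by at least one
module — with only two responsive modules the six cells of the default
design would be pairwise indistinguishable in at least one pair and no
selection could classify them — and excluding the zero codeword gives
every cell at least one active module, so no phenotype is defined purely
negatively. Identifiability of the multi-classification is thus built into
the design rather than left to chance.

Known distance-1 code pairs (cells separated by a single module) are the
fragile part of the design: with two replicates and $\delta/\sigma = 2$
the realized margins for alternatives that reshuffle such cells are small,
and a minority of simulated studies are genuinely infeasible. This is a
property of the stated study conditions, not of the solver; the margins
have been verified exactly against brute-force subspace SSE.

The generator does **not** emulate probe-level artifacts, heavy-tailed
intensity distributions, gene--gene correlation beyond the planted module
shifts, or time-course autocorrelation. Passing tests on these studies
demonstrate that the machinery recovers planted structure under the
model's own assumptions (Gaussian noise, additive shifts, modular
topology); they say nothing about robustness to the violations real
microarray data exhibit. For the same reason the synthetic benchmarks skip
the ANOVA pre-filter: at $\delta = 2$ with two replicates the per-gene
one-way F test has power near 0.5, so filtering would shred the planted
modules; on real data with thousands of genes the filter plays its
intended role of discarding the uninformative bulk.

All generator randomness derives from a single mandatory seed through R's
Mersenne-Twister stream (network and expression use disjoint sub-seeds;
`seedOffset` draws fresh replicates of the same truth), and the global RNG
state is saved and restored around every draw.

## Numerical choices and degenerate inputs

* Sample standard deviation ($m-1$) throughout; zero-variance genes are
  removed (with a message) before the filter and are an error if they reach
  the z-transform.
* Feasibility is $L_r \ge 0$: a tie in within-cluster SSE counts as
  classified, and margins are always reported so ties are visible.
* All ranking and tie-breaks are stable (lowest index first); MCL attractor
  ties resolve to the lowest attractor index; there is no randomness
  anywhere outside the synthetic generator, so identical inputs give
  byte-identical outputs.
* Column stochasticity is tracked across all MCL iterations; the largest
  observed deviation of any column sum from 1 is recorded in the module
  set's provenance (observed $< 10^{-9}$ on all fixtures).
* `enumeratePartitions()` refuses above the partition cap instead of
  exhausting memory, pointing at neighborhood mode.
* Degenerate enrichment terms (no member in the background) report
  $p = 1$ with a flag rather than being dropped silently.
* The enrichment background is the analysis universe — all genes surviving
  preprocessing — since overlaps can only be observed there.

## Problem sizes in the shipped tests

The test and acceptance suites run entirely on generated data: 25-seed
planted-recovery studies of ~65 network nodes and 12 samples, random
condition systems up to $K = 12$ modules and $R = 30$ conditions compared
against the exhaustive solver, full partition enumeration up to $m = 9$,
and null calibrations with 200--50,000 genes. These sizes were chosen so
that the exact solver and brute-force oracles remain exact references
while exercising every code path; the method itself has no intrinsic limit
other than the partition cap and the exact solver guard.

## Known limitations

* The greedy selection has no approximation guarantee; it is validated
  empirically against the exact solver on small instances only.
* Neighborhood mode checks near-miss partitions only; a selection feasible
  against the $d = 2$ neighborhood may not be feasible against all
  partitions (the exhaustive check is available whenever $S(m,C)$ permits).
* MCL granularity depends on inflation, for which no principled default
  exists beyond the canonical 2.0; module-level results should be read
  with that sensitivity in mind.
* Gene and protein identifiers are assumed to share one namespace; no
  identifier translation is provided.
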