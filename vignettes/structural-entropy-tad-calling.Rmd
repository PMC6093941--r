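---
title: "Structural-entropy TAD calling: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural-entropy TAD calling: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dedocr)
```

## The model

A binned Hi-C contact matrix $M = \{m_{ij}\}$ of one chromosome is read as
the adjacency matrix of a weighted undirected graph $G = (V, E)$: bins are
vertices, raw counts are edge weights. Calling TADs becomes a graph
partitioning problem. The objective is the *structural entropy* of $G$
under a *coding tree* $T$ — a rooted tree whose root carries all of $V$,
whose internal nodes' children partition their parent's vertex set (its
*marker*), and whose leaves carry single bins. Every non-root node $\alpha$
contributes

$$H^T(G;\alpha) \;=\; -\frac{g_\alpha}{2w}\,
  \log_2 \frac{V_\alpha}{V_{\alpha^-}},$$

with $g_\alpha$ the total weight of edges crossing the marker's boundary,
$V_\alpha$ the sum of weighted degrees inside it, $V_{\alpha^-}$ the parent
volume, and $w$ the total edge weight. $H^T(G)$ is the sum over all
non-root nodes; it measures the number of bits needed to locate a
stationary random walk within the tree's codewords. The height-1 tree
degenerates to the Shannon entropy of the degree distribution,
$H^1(G) = -\sum_i \frac{d_i}{2w}\log_2\frac{d_i}{2w}$, which is also the
entropy of the height-2 tree with a single module — an identity the test
suite verifies on random weighted graphs.

Minimizing $H^T$ over height-2 trees rewards partitions whose modules have
small boundary cuts ($g$) relative to their volumes: exactly the
block-diagonal enrichment that defines TADs. Because only aggregate cuts
and volumes enter, the objective is insensitive to per-entry noise, which
is why no normalization step exists anywhere in the package — raw counts in,
domains out — and why calls degrade gracefully when reads are thinned.

## The greedy caller

`dedoc2()` implements the height-2 minimization: start from all-singleton
modules under the root; among all candidate module pairs, apply the merge
with the largest positive entropy gain; repeat until no merge gains. The
gain of merging modules $a, b$ joined by weight $w_{ab}$ is computed
incrementally from $(g_a, V_a)$, $(g_b, V_b)$ and $w_{ab}$ alone, so a
merge costs $O(\log n)$ amortized with a lazily invalidated priority queue
(per-module version stamps). The compiled core keeps per-module neighbor
weight maps, folded smaller-into-larger on each merge.

Numerical and algorithmic choices, each of which the test suite pins down:

* **Strict positivity.** A merge fires only for gain $> 0$; a zero gain
  (e.g. the two singletons of a single-edge graph) leaves the partition
  alone.
* **Candidate pruning.** Only module pairs connected by at least one edge
  are candidates: merging a disconnected pair changes the module terms by
  $\frac{g_a}{2w}\log_2\frac{V_{ab}}{V_a} + \frac{g_b}{2w}\log_2\frac{V_{ab}}{V_b}$
  and the leaf terms by the same expression with $g$ replaced by $-V$;
  since $g \le V$, the sum is never positive. The pruning is therefore
  exact, not heuristic.
* **Tie-breaking.** Among equal gains the pair whose smaller first-bin
  index is lowest wins, then the partner's first bin: output is a pure
  function of the input.
* **Conventions at the boundary of the formula's domain.** $0\log 0 := 0$;
  a node with zero cut, zero volume, or volume equal to its parent's
  contributes nothing. Zero-contact bins (unmappable regions) thus stay in
  the bin axis as vertices, influence nothing, and are reported separately
  (`zero_bins`) rather than called as domains.
* **Diagonal.** Self-contacts are excluded from the graph by default: they
  cross no cut, so they could only inflate volumes asymmetrically. With
  `keep_diagonal = TRUE` a self-contact of weight $m$ enters as a standard
  self-loop ($2m$ to its vertex degree, $m$ to $w$), preserving
  $\sum_i d_i = 2w$ exactly.
* **Height-2 only.** The combining operator (inserting a new internal node
  above two sisters) is implemented and tested as a library primitive
  (`combine_nodes()`), but the production caller never invokes it: any
  combine of depth-1 modules would push leaves to depth 3. Full
  higher-dimensional minimization is out of scope.

### Contiguity

TADs are contiguous by definition, but entropy minimization is blind to
genomic order. Two modes are offered:

* `free` (default): merge any connected pair; afterwards, modules whose
  bins are not consecutive are removed and their bins reported in
  `dropped_bins` — a QC signal, not silent loss. On synthetic planted
  matrices the dropped fraction is routinely zero because adjacent bins
  interact far more than distant ones.
* `adjacent`: only genomically neighboring modules may merge, so every
  module is an interval by construction. This is also the fast path: with
  banded sparse matrices its measured runtime grows close to linearly in
  the bin count (the acceptance suite fits a log–log slope across
  500–4000 bins and requires $< 1.6$).

### deDoc(E) and deDoc(M)

`call_domains_E()` converts the height-2 modules into domains.
`call_domains_M()` reruns `dedoc2()` on each domain's induced subgraph,
producing sub-domains nested inside the E-level ones (domains of $\le 2$
bins pass through). Because the refinement optimizes each subgraph in
isolation, its flat height-2 entropy on the full graph may exceed the
E partition's; the object therefore reports both that flat entropy and the
entropy of the 3-level tree that keeps the E-domains as the middle layer
(`entropy_depth3`) and leaves the choice to the analyst.

## Binsize selection

Entropies at different binsizes are not comparable (more bins, more bits),
so the scanner normalizes: 1D-nSE $= H^1/\log_2 n_k$ and 2D-nSE
$= H^2/H^1$, both in $(0,1]$. A binsize is *stable* when its nSE is a
strict local minimum — strictly below both neighbors — and the selector
returns the stable binsize with the smallest value, or none (some inputs,
e.g. very short or contact-poor chromosomes, have no interior minimum).
Strictness is deliberate: plateaus are not minima, and scan endpoints can
never be selected, which also guards against the trivially low values that
the smallest binsizes produce on sparse data.

Resolution selection is a sparse-data problem. When coverage is deep, the
finest binsize is simply best and the nSE curve has no interior optimum
worth finding; the regime the selector is built for is the contact-starved
one (single cells, shallow libraries), and the package's own selection test
runs there: planted 100-kb domains on a 2-Mb chromosome with roughly 500
total contacts, scanned from 10 to 200 kb with the 2D metric. The default
metric is `1d` purely because it is much faster; both are sound.

## Weighted similarity

`weighted_similarity(P, Q)` scores each reference domain $X_j$ by its best
match in the query, $S(j) = \max_i |X_j \cap Y_i| / \sqrt{|X_j||Y_i|}$, and
averages with length weights. All sizes are measured in base pairs on
half-open intervals, so partitions called at different binsizes compare
directly. The measure is asymmetric ($ws(P,P)=1$, but halving every block
of $P$ gives $ws = 1/\sqrt2 \approx 0.707$ against it); both directions are
printed by the CLI. Gaps not covered by the query simply contribute zero
overlap — no special casing. The production sweep restricts each reference
domain to the overlapping run of query domains; the suite checks it against
a literal double loop on random sub-covers.

## The synthetic generator

`simulate_hic()` emits, for each bin pair $i \le j$, an independent Poisson
count with rate $B \cdot (1+|i-j|)^{-\gamma} \cdot \varepsilon^{[\text{same
domain}]}$ (compounded with a second factor inside sub-domains), then
symmetrizes. This is the minimal model exhibiting the two features the
caller exploits — power-law distance decay and block-diagonal enrichment.
Defaults ($B = 20$ per pair at the working binsize, $\gamma = 1$,
$\varepsilon = 6$, three 10-bin domains at 40-kb bins) represent a
well-covered bulk experiment; the sparsity tests raise $B$ to 1000 so that
1% binomial thinning still leaves $\sim$140 contacts per bin, and the
binsize tests lower $B$ to 0.2 per 10-kb pair for the sparse regime
discussed above. `downsample_matrix()` thins each contact unit
independently (binomial per entry), which is distributionally equivalent to
sampling reads when reads are independent.

What the generator does *not* emulate: fragment-level and mappability
biases, translocations or other structural variation, trans contacts,
distance-dependent noise correlations, and the soft, overlapping boundary
structure of real chromatin. Passing tests therefore demonstrate that the
implementation performs the computation it claims under the stated
statistical model — not that the model captures every property of real
Hi-C, for which the original validation against experimental data stands.

A known behavior worth stating plainly: the height-2 objective itself
prefers modules of roughly 5–7 bins at bulk-like coverage, so long planted
domains may be split into consecutive pieces whose internal boundaries are
extra, while the true boundaries remain exactly recovered. The recovery
metric used throughout (`boundary_recovery()`, fraction of true internal
boundaries matched within a tolerance) measures what the caller actually
promises. At deep coverage the splits disappear.

## Problem sizes and reproducibility

The test suite runs entirely on generated data: exhaustive-partition
oracles up to 8 vertices (all set partitions), delta-consistency checks on
200 random graph/tree/pair triples, 20-seed recovery and thinning
experiments on 30-bin matrices, 5-seed binsize scans on 200-bin matrices,
and the 500–4000-bin scaling fit — sizes chosen so the whole suite completes
in well under a minute while each property is still measured, not assumed.
Every stochastic path takes an explicit seed; fixed seed in, identical
output out, and the acceptance script threads its single `--seed` through
every draw.

## Limitations

* Greedy minimization carries no optimality guarantee; the suite only
  verifies it never beats the exhaustive optimum on small graphs and
  attains it on planted two-block structure.
* Only intra-chromosomal (cis) matrices are handled; one chromosome per
  call.
* deDoc(3) — full height-3 minimization — is not implemented; deDoc(M) is
  the cheaper surrogate for sub-domain structure.
* The binsize scanner recomputes the binning per candidate; for the 2D
  metric this includes one greedy run per binsize.
```{r session}
sessionInfo()
```
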