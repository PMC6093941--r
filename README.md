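# dedocr — normalization-free TAD calling by structural entropy minimization

`dedocr` detects topologically associating domains (TADs) in Hi-C contact
maps. It treats the raw contact matrix of a chromosome as the adjacency
matrix of a weighted undirected graph — bins are vertices, contact counts are
edge weights — and partitions that graph by greedily minimizing its
*structural entropy*, the uncertainty of locating a stationary random walk
within the codewords of a hierarchical partition (a *coding tree*). No
matrix balancing or normalization is applied at any point, and the caller
has no tunable parameters; this makes the method unusually robust to
extremely sparse inputs such as pooled single-cell Hi-C.

## The model in brief

For a coding tree *T* of the Hi-C graph *G* with total edge weight *w*,
every non-root node α contributes

    H_T(G; α) = −(g_α / 2w) · log2(V_α / V_{α⁻})

where *g*_α is the total weight of edges leaving α's vertex set, *V*_α the
sum of weighted degrees inside it, and α⁻ the parent node. The structural
entropy given *T* is the sum of these terms; the height-1 tree degenerates
to the Shannon entropy of the degree distribution (1D SE),

    H¹(G) = −Σᵢ (dᵢ / 2w) · log2(dᵢ / 2w).

The caller, deDoc(E), starts from singleton modules and repeatedly applies
the sister-node merge with the largest positive entropy gain until no merge
helps; the resulting height-2 tree's modules are the domains. deDoc(M)
reapplies the same minimization inside each domain, yielding a nested,
finer partition. Two companion tools round out the package:

* a **binsize selector**: scan binsizes, compute normalized entropies
  (1D-nSE = H¹/log2 n; 2D-nSE = H²/H¹) and pick the *stable* binsize — a
  strict interior local minimum of nSE — with the smallest value;
* the **weighted similarity** (WS) between two domain partitions: per
  reference domain the best overlap score |X∩Y|/√(|X||Y|), averaged with
  length weights (asymmetric by design, computed on the bp axis).

A seeded synthetic generator (Poisson counts, power-law distance decay,
planted block-diagonal domain enrichment, binomial read thinning) makes the
whole pipeline testable without external data.

## Worked example

```r
library(dedocr)

sim  <- simulate_hic(n_bins = 30, boundaries = c(0, 10, 20),
                     background = 1000, decay = 1, enrichment = 6,
                     binsize = 40000, seed = 1)
tads <- call_domains_E(sim$matrix)
tads$domains
#>   start_bin end_bin start_bp  end_bp
#> 1         0       9        0  400000
#> 2        10      19   400000  800000
#> 3        20      29   800000 1200000

for (f in c(0.1, 0.01)) {
  thin <- downsample_matrix(sim$matrix, f, seed = 2)
  ds   <- call_domains_E(thin)
  cat(sprintf("%4.0f%% of reads: %5.0f contacts, %d domains, WS to full %.3f\n",
              100 * f, total_weight(thin), nrow(ds$domains),
              weighted_similarity(tads, ds)))
}
#>   10% of reads: 42956 contacts, 3 domains, WS to full 1.000
#>    1% of reads:  4283 contacts, 3 domains, WS to full 1.000
```

The three planted 400-kb domains are recovered exactly from the full matrix
(~427,000 contacts) and still exactly after thinning the reads to 1%: the
entropy objective depends on aggregate cut weights and volumes, not on
individual matrix entries, which is what makes the caller insensitive to
sequencing depth.

A command-line front end is installed with the package
(`system.file("exec", "dedoc", package = "dedocr")`) with subcommands
`call`, `binsize`, `compare` and `simulate`; each prints its options with
`--help`.

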