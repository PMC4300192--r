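# gcoex

Gene co-expression network construction from a gene × sample expression
matrix, for researchers who want a fast, fully scripted route from an
abundance table to an edge list, a binary co-expression network and gene
modules — with every intermediate statistic written to plain-text files.

## The method

For *m* genes measured on *n* samples with abundances *x<sub>ij</sub>*, the
pipeline runs four stages:

1. **Entropy filter.** Each gene's profile is normalized to
   *p<sub>ij</sub>* = |*x<sub>ij</sub>*| / Σ<sub>k</sub> |*x<sub>ik</sub>*|
   and scored by its Shannon entropy
   *H<sub>i</sub>* = −Σ<sub>j</sub> *p<sub>ij</sub>* log *p<sub>ij</sub>*.
   A uniformly expressed gene attains the maximum *H* = log *n* and shows no
   differential expression, so the ⌈*f·m*⌉ genes with the **largest**
   entropy are removed (default *f* = 0.5).
2. **All-pairs Pearson correlation.** The *t* = *k*(*k*−1)/2 coefficients
   ρ for the *k* surviving genes are computed by blocked matrix products
   over standardized rows and stored in a packed strictly-lower-triangular
   vector (row-major; pair (*i*,*j*), *i* > *j*, lives at slot
   (*i*−1)(*i*−2)/2 + *j* in 1-based indices).
3. **Edge significance.** Each coefficient is standardized against the whole
   coefficient population, *z* = (ρ − ρ̄)/*S* (sample sd over all *t*
   coefficients), converted to a two-sided normal p-value and adjusted by
   Benjamini–Hochberg FDR to a q-value.
4. **Network and modules.** Pairs with *q* ≤ τ become edges of a binary
   adjacency matrix (zero diagonal); connectivity is the node degree;
   zero-connectivity genes are pruned; the topological-overlap similarity
   *s<sub>ij</sub>* = (*h<sub>ij</sub>* + *a<sub>ij</sub>*) /
   (*c<sub>i</sub>* + *c<sub>j</sub>* − *h<sub>ij</sub>* − *a<sub>ij</sub>*)
   (with *h<sub>ij</sub>* the shared-neighbor count) is clustered by
   average linkage on 1 − *s* and cut at a fixed height; groups of at least
   `min_module_size` genes become modules.

See `vignettes/coexpression-methods.Rmd` for assumptions, parameter
guidance and known limitations — in particular when the population
z-statistic is conservative and a larger τ is appropriate.

## Worked example

```r
library(gcoex)

# simulate 320 genes x 200 samples: 4 planted modules of 50 genes
# (within-module rho ~ 0.6), 100 background genes, 20 flat genes
sim <- simulate_expression(synthetic_spec(seed = 9))

res <- run_pipeline(sim$expression, "out",
                    filter_fraction = 20 / 320,  # matches the flat genes
                    tau = 0.25)                  # dense planted signal
#> input: 320 genes x 200 samples
#> entropy filter: removed 20 of 320 genes (fraction 0.0625)
#> correlation: 44850 pairwise coefficients
#> network: 4809 edges at tau = 0.25; 100 unconnected genes; 4 modules

res
#> <coex_pipeline>
#>   input: 320 genes x 200 samples
#>   entropy filter: run (20 genes removed)
#>   correlation: 300 genes, 44850 pairs
#>   edges called (q <= 0.25): 4809
#>   modules: 4 (100 genes unconnected, 0 unassigned)
```

All 20 flat genes were cut by the entropy filter; the 100 uncorrelated
background genes end up with no significant edges and are pruned as
`unconnected`; the four planted modules are recovered exactly (adjusted
Rand index 1.0 against the simulation truth via `tidy(res)` +
`adjusted_rand_index()`). `out/` now holds `entropy.tsv`, `edges.tsv`
(per-pair ρ, z, p, q and adjacency), `modules.tsv`, `network.graphml` and a
JSON run manifest with parameters, input checksum and per-stage gene
counts.

The same pipeline is available from a shell:

```sh
inst/cli/gcoex simulate --out simdir --seed 9
inst/cli/gcoex run --input simdir/expression.tsv --out outdir \
    --filter-fraction 0.0625 --tau 0.25
```

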