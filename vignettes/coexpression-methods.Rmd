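---
title: "Methods: entropy-filtered co-expression networks with population-normalized edge significance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entropy-filtered co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcoex)
```

# The model

`gcoex` builds a gene co-expression network from an $m \times n$ abundance
matrix $x_{ij}$ ($m$ genes, $n$ samples) in four stages. Each stage is an
exported function; `run_pipeline()` chains them and writes every
intermediate to a plain-text file.

## 1. Entropy filter

A gene's across-sample profile is normalized to
$p_{ij} = |x_{ij}| / \sum_k |x_{ik}|$ and scored by its Shannon entropy
$H_i = -\sum_j p_{ij} \log p_{ij}$ (natural log). $H_i$ is maximal, at
$\log n$, exactly when the profile is uniform — i.e. when the gene shows no
differential expression across samples — and minimal, 0, for a point mass.
The filter therefore removes the $\lceil f \cdot m \rceil$ genes with the
**largest** entropy. The direction matters and is easy to get backwards:
low entropy means variable (interesting) expression here, because entropy
is taken over samples, not over genes.

Choices worth stating explicitly:

* **Log base.** Natural log internally. The base rescales all entropies by
  the same constant and cannot change the ranking, hence never changes
  which genes are cut; `gene_entropy(x, base = 2)` reports bits for
  display.
* **Rounding.** $\lceil f m \rceil$ genes are removed, so $f = 0.5$ on an
  odd $m$ removes the strict majority.
* **Ties at the cut.** The gene with the smaller original row index is
  retained; output is deterministic.
* **All-zero rows.** Their profile is undefined; they are assigned $H = 0$
  and therefore *retained* by the cut rather than silently dropped — a
  second, undocumented filter would be worse. They are neutralized at the
  correlation stage instead (below).
* **$f = 0$** skips the stage entirely: no entropy is computed and no
  `entropy.tsv` is written.

## 2. All-pairs Pearson correlation in packed storage

All $t = k(k-1)/2$ pairwise coefficients for the $k$ surviving genes are
stored in a flat vector holding the strictly lower triangle in row-major
order: pair $(i, j)$ with $i > j$ (1-based) lives at slot
$(i-1)(i-2)/2 + j$. `pair_to_index()` / `index_to_pair()` expose the
mapping and are exact inverses (tested exhaustively); every downstream file
and function uses this one convention. The lower-triangle, row-major
orientation is a package convention and is what `edges.tsv` rows follow.

Numerically, the engine standardizes each row (subtract the mean, scale to
unit sum of squares) and forms blocked matrix products of standardized
rows — the serial analogue of a massively parallel per-pair kernel, and
$O(nk^2)$ either way, but dramatically faster in R than a per-pair double
loop. The classical one-pass sums-of-products form of Pearson's $\rho$ is
algebraically identical but numerically unstable for rows with large means;
the test suite uses it (and a naive two-pass per-pair loop) as independent
oracles, at tolerances $10^{-8}$ and $10^{-10}$ respectively.

A zero-variance row (constant gene, including all-zero rows passed through
by the entropy filter) has no defined correlation. The engine sets every
coefficient involving it to 0 — such edges can never be called — and warns
with the gene names. NaN propagation or a hard stop would either corrupt
the coefficient population silently or make the pipeline brittle to a
legitimate input.

## 3. Population z-normalization, p-values, FDR

The coefficients are standardized against their own population:
$z_i = (\rho_i - \bar\rho)/S$ with $\bar\rho$ the mean and $S$ the sample
standard deviation over **all $t$ coefficients** (denominator $t - 1$).
Treating $z$ as approximately standard normal, two-sided p-values
$p = 2(1 - \Phi(|z|))$ are adjusted by the Benjamini–Hochberg step-up to
q-values.

Design decisions:

* The standard deviation is taken over the $t$ coefficients with a $t-1$
  denominator. The statistic normalizes the population of all $t$
  pairwise coefficients, so that is the population its spread must be
  measured on.
* Two-sided p-values by default: co-expression is not signed a priori.
  `tail = "right"` restricts to positive co-expression.
* Benjamini–Hochberg is the canonical parameter-free FDR procedure; it is
  implemented via `stats::p.adjust(method = "BH")` behind `fdr_qvalues()`
  and cross-checked in the tests against an independently coded
  sort-and-running-minimum oracle, exactly, up to $t = 10^5$.
* The per-pair Fisher transform $z = \operatorname{atanh}(\rho)\sqrt{n-3}$
  is available as `method = "fisher"` for comparison. It is a deliberate
  departure from the population method: it tests each pair against its own
  sampling null with $n$ fixed, not against the coefficient population.

### When the population statistic is conservative

The empirical normalization assumes truly co-expressed pairs are a small
minority, so that $\bar\rho$ and $S$ estimate a null location and scale. If
a large fraction of pairs is truly correlated, the signal itself inflates
$S$ and compresses every $z$: with a fraction $\varphi$ of pairs at
correlation $\rho_0$ and the rest near zero, the attainable signal $z$ is
bounded by roughly $\sqrt{(1-\varphi)/\varphi}$ no matter how strong
$\rho_0$ is. With $\varphi \approx 0.11$ (the default synthetic scenario:
4 modules of 50 genes among 300) that bound is $\approx 2.85$, and the
minimum attainable q-value is $\approx 0.13$ — at $\tau = 0.05$ *no* edge
can be called, for any seed. The q-values of truly co-expressed pairs
plateau at about 0.13–0.35 while background pairs sit near 1, so any
$\tau$ in roughly $[0.2, 0.9]$ yields the same, correct graph. The
planted-recovery experiments (tests and `scripts/acceptance.R`) therefore
run that dense scenario at $\tau = 0.25$; the pipeline default stays at the
conventional $\tau = 0.05$, which is the right operating point for the
sparse-signal data the statistic assumes. This conservatism is a property
of the method worth knowing before choosing $\tau$ on real data: inspect
the q-value distribution (`tidy(edge_stats)`) rather than assuming 0.05 is
meaningful when co-expression is pervasive.

## 4. Adjacency, connectivity, pruning, topological overlap, modules

Edges are the pairs with $q_{ij} \le \tau$; the adjacency matrix is binary
and symmetric with a **zero diagonal** — applying the threshold literally
to the diagonal would make every gene its own neighbor ($q_{ii} = 0$) and
corrupt the connectivity $c_i = \sum_j a_{ij}$. Genes with $c_i = 0$ are
pruned before the similarity step (their removal is recorded: they appear
in `modules.tsv` as `unconnected`, never silently dropped), both to cut the
$O(k^3)$ cost of the similarity product and because the similarity
denominator would vanish for them.

The topological-overlap similarity on the pruned network is
$$ s_{ij} = \frac{h_{ij} + a_{ij}}{c_i + c_j - h_{ij} - a_{ij}}, \qquad
   h_{ij} = \sum_u a_{iu} a_{uj}, $$
computed as one dense matrix product ($h = A^2$) rather than a triple
loop; the tests verify exact agreement with the brute force on random
graphs. On a pruned network the denominator is provably $\ge 1$ (from
$h_{ij} \le \min(c_i, c_j)$ and the zero diagonal) and is asserted at run
time; $s_{ij} \in [0, 1]$ with $s_{ij} = 1$ exactly for genes with
identical neighborhoods, and $s_{ii} = 1$ by convention.

Modules are found by average-linkage agglomerative clustering of
$d = 1 - s$ with a static cut. No clustering algorithm is canonical for
this similarity; average linkage with a fixed height is the established
simple choice, keeps the result deterministic, and makes modules visible
as hot blocks along the diagonal when the similarity matrix is reordered
by dendrogram leaf order (`order_for_heatmap()`,
`plot_similarity_heatmap()`). Groups of at least `min_size` genes become
modules labeled `"1"`, `"2"`, … by decreasing size (ties by smallest member
index); smaller groups are `"unassigned"`. Dynamic tree cutting, module
merging and eigengene summaries are deliberately out of scope.

Defaults: `cut_height = 0.5` (genes stay together while their average
topological overlap exceeds 0.5 — halfway between identical and disjoint
neighborhoods) and `min_size = 5` (smaller groups are rarely
interpretable as modules). Both are conventions, not derived quantities,
and are surfaced as parameters everywhere.

# The synthetic-data generator

`synthetic_spec()` / `simulate_expression()` draw a latent-factor model:
each planted module has one standard-normal factor per sample, and a
member gene is
$$ x_{ij} = \text{baseline} + \lambda f_j + \sigma \varepsilon_{ij}, $$
giving within-module correlation $\lambda^2 / (\lambda^2 + \sigma^2)$.
Background genes are baseline plus noise; flat genes are the baseline
constant plus negligible jitter (sd $10^{-6}$), which makes them the
most-uniform profiles in the matrix — the designated targets of the
entropy filter. The default scenario is 4 modules × 50 genes with
$\lambda = \sqrt{1.5}\,\sigma$ (within-module $\rho = 0.6$), 100
background genes, 20 flat genes, $\sigma = 0.6$, baseline 10, over 200
samples.

What the generator does *not* emulate: counts and mean–variance coupling
(RNA-seq overdispersion), library-size and batch effects, heavy-tailed or
skewed abundance distributions, overlapping modules, negative
co-expression, and hub-dominated degree distributions. Passing the
recovery tests therefore shows the pipeline's stages compose correctly and
recover clean block structure; it does not certify performance on real
transcriptomes, where the filter fraction and $\tau$ need data-driven
choices.

A note on the absolute value in the entropy profile: the baseline keeps
simulated abundances positive, so $|x|$ is the identity on the documented
path; negative values are legal inputs and exercise the $|x|$ branch.

# Reading and writing

Input is a delimited text matrix (TSV by default, CSV by extension or
explicit delimiter), genes in rows, header of sample IDs, gene IDs in the
first column; `transpose` handles the opposite layout. Duplicated gene
IDs, ragged rows and non-numeric or missing cells are hard errors that
name the offender — missingness is rejected, not imputed, because every
downstream formula assumes complete rows. `write_expression()` renders
full precision (17 significant digits) so a write/read round trip is exact;
the human-readable `edges.tsv` uses 6 significant digits. The pruned
network is exported as GraphML with `gene_id` and `module` node
attributes via igraph.

# Determinism and degenerate inputs

Everything downstream of the input matrix is deterministic — there is no
RNG anywhere in the pipeline — so identical input and configuration
reproduce `edges.tsv` and `modules.tsv` byte for byte; the generator is
deterministic given its seed and restores the caller's RNG state.
Degenerate situations fail loudly at the stage that owns them: a single
sample (entropy undefined), fewer than 3 samples or 2 genes
(correlation), an all-identical coefficient population ($S = 0$), an
unpruned network fed to the similarity step, a $\tau$ that isolates every
gene. `run_pipeline()` removes partial outputs on any stage failure.

# Problem sizes in the test suite

The suite verifies oracle agreement at $k = 100$, $n = 50$ (correlation),
$t = 10^5$ (FDR), $k = 500$ exhaustive (index mapping), 100 replicates of
a $k = 100$ global null, and planted-module recovery on the default
320-gene scenario over 10 seeds plus a 96-gene sparse-signal scenario.
These sizes keep the whole suite under a minute while leaving the blocked
engine's block boundaries, the step-up's tie handling and the similarity
product's integer exactness genuinely exercised; the engine itself is
designed (packed storage, blocked products) for $k$ in the tens of
thousands, where the packed $\rho$ vector for $k = 16{,}000$ occupies
about 1 GB in double precision.

# Known limitations

* The empirical z-statistic's null is the coefficient population itself;
  under pervasive co-expression it is conservative (see above) and under
  strong global confounding (batch effects) it can be anticonservative.
  It never uses $n$ beyond computing $\rho$, so more samples sharpen
  $\rho$ but not the nominal null.
* Hard thresholding discards edge-strength information; no soft-threshold
  or scale-free-topology fitting is provided, by design.
* The static tree cut cannot separate nested or overlapping modules.
* Correlation is Pearson-only; rank-based or mutual-information measures
  are out of scope.
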