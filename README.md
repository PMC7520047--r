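# generelevance

Which genes drive a cell's position in a t-SNE, UMAP or diffusion map?
Linear embeddings answer this with PCA loadings; non-linear embeddings —
the standard for single-cell RNA-seq — have no loadings at all.
`generelevance` computes a loadings analogue for *any* embedding: per-cell
**gene relevance scores**, their aggregation into **local** and **global
gene relevance**, and a smoothed **gene relevance map** that labels each
region of the embedding with its locally most relevant gene. It is aimed
at anyone who has a cells × genes expression matrix, a low-dimensional
embedding of it, and the question "what is changing *here*?".

## Method in brief

For gene $g$, cell $c$ and embedding coordinates $s_{pc}$, the differential

$$(d_{gc})_p = \operatorname*{median}_{n \in NN_k(c),\, n \neq c} \frac{x_{gc} - x_{gn}}{s_{pn} - s_{pc}}, \qquad d_{gc} \text{ undefined if } x_{gc} = 0,$$

estimates how fast expression changes per unit embedding displacement,
using the cell's $k$ nearest neighbors in expression space (spearman
rank-correlation distance by default). The per-cell score is
$\|d_{gc}\|_2$; ranking genes by score within each cell and counting, for
a cell set $\Psi$, how often a gene beats a rank cutoff $r_{gmax}$ gives
the local relevance

$$LR_{r_{gmax}}(g,\Psi) = \frac{1}{|\Psi|}\sum_{c\in\Psi}\big[r_g^{(c)} < r_{gmax}\big],$$

with global relevance $GR = LR$ over all cells. Binned $LR$ over a grid on
the embedding yields tile plots of where each gene matters; a
neighbor-majority smoothing of the per-cell argmax gene yields the
relevance map. Rank-biased overlap (`rbo()`) compares the resulting gene
rankings with lists from other methods.

## Worked example

The package ships a synthetic benchmark generator: 300 cells on a Y-shaped
two-branch trajectory, 200 genes of which five are planted — four varying
across the whole embedding, one restricted to the second branch — under
20% dropout and noise a third of the effect size.

```r
library(generelevance)

sim <- simulate_relevance_data(synthetic_spec(seed = 1))
res <- gene_relevance(sim$expression, sim$embedding, n_bins = c(8, 8))
res
#> gene_relevance: 300 cells x 200 genes, 2-D embedding (k = 17, spearman)
#>   rank cutoff 10, 20.0% of differentials undefined
#>   top globally relevant genes:
#>    1. gene0004     GR = 0.263
#>    2. gene0003     GR = 0.210
#>    3. gene0001     GR = 0.167
#>    4. gene0002     GR = 0.130
#>    5. gene0005     GR = 0.103
#>    ...
```

The five top-ranked genes are exactly the five planted ones
(`sim$truth`): `gene0001`–`gene0004` planted across the whole embedding
and `gene0005` planted only on branch 2 — correctly the weakest of the
five globally, since its relevance is confined to a quarter of the cells.
A GR of 0.263 means gene0004 ranks among the nine most relevant genes in
26.3% of cells; 20% of differentials are undefined, matching the simulated
dropout rate. The relevance map labels contiguous regions of the embedding
with these genes:

```r
res$map
#> relevance_map: 300 cells, m = 1, pool of 10 genes
#>   labels: gene0004 (139), gene0003 (68), gene0001 (45), gene0002 (32),
#>           gene0005 (5), ...
```

and `binned_local_relevance()` / `write_relevance_tables()` export the
per-bin tables behind local-relevance tile plots. Comparing the global
top-10 against the planted list with rank-biased overlap:

```r
rbo(head(res$global$ranking$gene, 10), sim$truth$gene, p = 0.9)
#> [1] 0.783
```

## Command line

A thin CLI over the same functions lives at `inst/cli/generelevance.R`
(installed under `system.file("cli", package = "generelevance")`):

```sh
Rscript generelevance.R simulate --n-cells 300 --n-genes 200 --seed 1 --out sim/
Rscript generelevance.R run --expr sim/expression.tsv --embedding sim/embedding.tsv --out out/
Rscript generelevance.R map --run-dir out/ --smooth 3 --out map3/   # re-smooth cheaply
Rscript generelevance.R compare --list-a ours.txt --list-b theirs.txt --p 0.9
```

Every run writes a `provenance.json` with parameters, seeds and input
checksums.

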