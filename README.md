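# lascout

Liquid-association scouting for mediators of gene coexpression.

## The problem

Correlation analysis of expression compendia finds gene pairs that move
together, but many functionally linked genes are *conditionally*
coexpressed: their correlation switches on or off depending on the
state of a third gene. Liquid association (LA) quantifies exactly this
three-way structure. For profiles standardized to a common Gaussian
scale,

    LA(X, Y | Z) = (1/n) * sum_i  X_i * Y_i * Z_i ,

the mean elementwise triple product, which equals the covariance
between the mediator Z's level and the conditional correlation of the
pair (X, Y). Scanning every gene as a candidate Z for a lead pair — or
every pair (Y, Z) for a single lead gene — ranks genome-wide "scouting"
genes whose expression level modulates the pair's coexpression. The
motivating use case is batched bacterial microarray compendia (e.g.
merged *Shewanella oneidensis* MR-1 stress-response series), where such
scans link electron-transfer gene pairs to chemotaxis and transporter
genes, but the machinery is generic.

The package implements the full workflow:

* **Ingestion** — plain TSV and GEO series-matrix tables
  (`read_expression_table()`), multi-series merging with batch labels
  (`merge_series()`), gene alias resolution (`resolve_gene()`).
* **Gaussianization** — per-gene, per-series normal-score transform
  (`transform_dataset()`), the pipeline's batch handling.
* **Scouting** — `la_score()`, genome-wide `scout_z()` and
  `search_pairs()` (dense matrix-product formulations),
  `lead_set_report()` for lead gene sets in the standard
  X/Y/Z/score/corr-high/corr-low/p/place schema.
* **Significance** — seeded within-batch permutation tests, a
  large-sample normal approximation, and the random-pair null-pool
  experiment estimating chance detection rates.
* **LAP views** — high/low mediator splits with subgroup correlations
  (`lap_split()`) and the red-triangle/blue-dot scatter
  (`render_lap_plot()`).
* **Synthetic data** — batched generators with planted, analytically
  tractable mediation (`generate_dataset()`, `expected_la()`), used by
  the whole test suite; no downloads required anywhere.

A thin command-line wrapper over these functions ships at
`inst/cli/lascout` (subcommands `simulate`, `transform`, `scout`,
`search`, `multilead`, `nullpool`, `lapplot`).

## Worked example

A small bundled synthetic dataset (30 genes, two batches of 10 and 14
samples, 5% missing values) carries one planted triplet: the
correlation of `g0001` and `g0002` rises steeply with the level of
`g0003`.

```r
library(lascout)

expr <- system.file("extdata", "synthetic_demo_expression.tsv", package = "lascout")
bmap <- system.file("extdata", "synthetic_demo_batches.tsv", package = "lascout")
st <- read_expression_table(expr, "tsv")
bm <- read_batch_map(bmap)
ds <- expression_dataset(st$values, unname(bm[st$sample_ids]), name = "demo")

tds <- transform_dataset(ds)          # per-batch normal scores
scout_z(tds, "g0001", "g0002", top_k = 3)
#> <scout_table> lead pair (g0001, g0002), 28 candidates
#> TOP (positive LA-scouting genes):
#>      z  la_score place
#>  g0003 0.3543441     1
#>  g0020 0.3004786     2
#>  g0005 0.2702105     3
#> ...
```

The planted mediator `g0003` leads the positive end. The LAP view shows
why: the pair is strongly coexpressed when `g0003` is high and
anti-correlated when it is low,

```r
sp <- lap_split_genes(tds, "g0001", "g0002", "g0003")
sp
#> <lap_split> (g0001, g0002 | g0003) LA = 0.3543; r(high, n=12) = 0.8518; r(low, n=12) = -0.6902
render_lap_plot(sp, "lap.png")        # red triangles = high-Z samples

permutation_pvalue(tds$values["g0001", ], tds$values["g0002", ],
                   tds$values["g0003", ], B = 10000, seed = 1,
                   batch_labels = tds$batch_labels)
#> <pvalue_result> permutation one_sided_signed: p = 0.006699 (observed LA 0.3543, n = 21, B = 10000)
```

So a mediator this strong is seen roughly 7 times in a thousand
mediator-destroying shuffles. How often would *any* background gene
lead a random pair purely by chance? `null_pool_experiment()` draws
random lead pairs from a user-supplied pool of irrelevant genes, scouts
each pair genome-wide, and counts place-1 detections of the targets —
the chance-detection rate behind a scouting claim.

The methods vignette
(`vignettes/liquid-association-methods.Rmd`) documents the transform
conventions, denominator and tie-break policies, the p-value methods,
the split-fraction convention for subgroup correlations, and the
synthetic model's assumptions and limits.

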