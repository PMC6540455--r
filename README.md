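# corsig

Driver-gene correlation signatures for transcriptome matrices.

## The problem

In several tumour entities a single driver gene — c-MYC in choroid plexus
tumours is the motivating case — is overexpressed in only a subset of
tumours, and the genes whose expression tracks the driver across a cohort
form an interpretable *correlation signature*: a transcriptional footprint
of driver activity that can be clustered, compared across platforms, and
carried across species through ortholog maps. `corsig` implements this
workflow end to end for two kinds of input:

* **probe-level exon-array matrices**, where a gene is interrogated by
  several probesets that must first be checked for coherence and later
  summarised to gene level, and
* **gene-level matrices** (RNA-seq CPM or any summarised expression),
  where genes are correlated with the driver's row directly.

## The statistic at the core

For each feature *x* against a driver reference profile *y* over *n*
samples, the package computes the sample Pearson coefficient *r* and its
two-sided significance from the classical *t* transformation

    t = r * sqrt((n - 2) / (1 - r^2)),   p = 2 * P(T_{n-2} > |t|),

and retains features with `|r| >= r_min` (inclusive) and `p < p_max`
(strict). No multiple-testing correction is applied — the thresholds are
raw, and every screen reports the implied expected false-positive count.
With few samples the significance threshold binds: at *n* = 6 and
`p < 0.05` no gene below `|r| ~ 0.811` can pass, whatever `r_min` says
(`effective_r_cutoff()` computes this inversion).

The probe-level fit (`exon_signature()`) runs five stages:

1. **Coherence selection** — the largest subset of the driver's probes
   with all pairwise *r* > 0.5 (signed: the probes must agree, not merely
   co-vary in magnitude).
2. **Probe screen** — keep every probe correlated with at least one
   retained driver probe at `|r| >= 0.5`, `p < 0.01`.
3. **Robust standardisation** — per probe, subtract the median and divide
   by the interquartile range (linear-interpolation quantiles).
4. **Gene aggregation** — per gene, the mean of its standardised screened
   probes.
5. **Gene filter** — correlate every aggregated gene against the
   aggregated driver row and apply the thresholds again.

Around the fit: Ward/Euclidean hierarchical clustering with a named
high/medium/low partition of samples by driver expression
(`ward_linkage()`, `cut_partition()`), a cumulative-proportion transform
that maps each sample onto [0, 1) by cumulative expression share —
invariant to per-sample scaling, hence usable across platforms —
(`cumulative_proportion_transform()`), ortholog pairing and a
transcriptome-wide Spearman correlogram for cross-species comparison
(`pair_orthologs()`, `correlogram()`), and a latent-factor synthetic-data
generator with full ground truth (`simulate_exon_dataset()` and
relatives).

## Worked example

```r
library(corsig)

d   <- simulate_exon_dataset(synthetic_config(seed = 11))
fit <- exon_signature(d$matrix, d$annotation, "MYC")
fit
#> Driver-correlation signature (probe-level)
#>   driver gene: MYC
#>   driver probes: 6 annotated, 5 retained as coherent
#>   screened probes: 501; aggregated genes: 132
#>   thresholds: |r| >= 0.5, p < 0.01
#>   signature genes: 124 (driver excluded)
```

The generator planted 120 module genes on a latent driver factor at
population *r* = 0.8 among 2000 background genes (40 samples, 4 probes
per gene); the driver got six probes, one deliberately decorrelated. The
fit rejects that probe (5 of 6 retained), recovers the module, and admits
a handful of background genes at the rate the raw `p < 0.01` screen
implies. `summary(fit)` lists the strongest signature genes with their
records:

```r
summary(fit)
#>   positively correlated: 122; negatively: 2
#>   strongest signature genes:
#>  gene_symbol     r        p  n passes is_target
#>      MOD0092 0.920 4.58e-17 40   TRUE     FALSE
#>      MOD0095 0.910 4.00e-16 40   TRUE     FALSE
#>      ...
```

`coef(fit)` returns the named vector of signature-gene correlations,
`plot(fit)` draws the Ward-clustered heatmap, `write_gene_table(fit,
path)` serializes the records exactly, and `write_run_report(fit, path)`
emits a JSON report with every intermediate count.

Real matrices enter through `read_expression_matrix()` (plain TSV or the
GEO series-matrix table dialect), `read_probe_annotation()` and
`read_ortholog_map()`. Public choroid plexus tumour exon-array data are
the natural probe-level input; note that the literature cites the human
CPT cohort under two different GEO accessions (GSE60892 and GSE60886) —
the loader is accession-agnostic and takes whatever matrix it is given.

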