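---
title: "Driver-gene correlation signatures: model, conventions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Driver-gene correlation signatures: model, conventions and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corsig)
```

## The model

`corsig` estimates which genes co-vary with a named driver gene across a
cohort of tumour transcriptomes. The underlying statistical picture is a
single latent driver axis: tumours differ in driver activity, genes
downstream of (or co-regulated with) the driver load on that axis, and
everything else is noise. The estimator is deliberately simple — a
thresholded correlation screen — because that is what the screened
quantity supports: with cohort sizes of a few dozen samples, anything
richer than a marginal correlation against the driver profile is poorly
identified.

For a feature vector $x$ and the driver reference $y$ over $n$ samples,
the screen computes the sample Pearson coefficient $r$ and refers

$$t = r\,\sqrt{\frac{n-2}{1-r^2}}$$

to a central $t$ distribution with $n-2$ degrees of freedom for a
two-sided $p$. A feature is retained when $|r| \ge r_\min$ (inclusive)
**and** $p < p_\max$ (strict). Two asymmetries are intentional:

* Driver-probe **coherence** uses the *signed* coefficient
  ($r > r_{\mathrm{pair}}$): a gene's own probes must agree in
  direction. The **screens** use $|r|$: anti-correlated genes belong in
  the signature.
* The $p$ threshold is redundant in large cohorts (at $n = 40$,
  $p < 0.01$ is implied by $|r| \ge 0.403 < 0.5$) but binds in small
  ones: at $n = 6$, $p < 0.05$ requires $|r| > 0.811$.
  `effective_r_cutoff(n, p_max)` inverts the $t$ map so users can see
  which constraint is active.

No multiplicity correction is applied anywhere. The thresholds are
conventional raw cutoffs; every screen logs the implied expected
false-positive count (feature count $\times p_\max$) so the consequence
is visible. Users wanting FDR control should treat the output records
(`fit$records` carry $r$, $p$, $n$ per gene) as input to `p.adjust()`
themselves — the signature definition here is the raw-threshold one.

## The probe-level procedure

Exon arrays interrogate one gene with several probesets, so the fit
composes five stages, each exported and individually testable:

1. `select_coherent_probes()` — the largest subset of the driver's
   probes with all pairwise $r > 0.5$, found by exhaustive subset
   enumeration (probe counts per gene are single digits; the search is
   exact and deterministic, ties broken by larger mean pairwise $r$,
   then input order). A probeset that fails to track its siblings —
   cross-hybridisation, a non-expressed exon — is thereby excluded from
   the reference.
2. `screen_probes()` — every probe correlated with at least one
   retained driver probe at the thresholds.
3. `robust_standardize()` — per-probe median/IQR standardisation, so
   that probes with different dynamic ranges contribute comparably to
   the gene mean.
4. `aggregate_probes()` — per-gene arithmetic mean of the standardised
   *screened* probes (only probes that passed the screen enter the gene
   value).
5. `filter_genes_by_correlation()` — the same thresholds applied to
   aggregated genes against the aggregated driver row.

The driver itself trivially passes the final filter; it is excluded from
the signature count by default (`exclude_target = TRUE`) and always
reported separately, since conventions differ on whether the driver
belongs to its own signature. The reference for the final filter is the
aggregated driver row by default; `reference = "per_probe"` instead
tests each gene against every retained standardised driver probe and
keeps genes passing for at least one — both readings of "correlate the
genes against the driver" are defensible, and the aggregated form is the
smoother, hence default, one.

## Numerical conventions

* **Quantiles.** IQR standardisation uses linear interpolation between
  order statistics (R's default, type 7). The convention changes which
  boundary probes survive in edge cases, so it is fixed rather than
  configurable, and the idempotence property (a standardised row is a
  fixed point) holds exactly under it.
* **Degenerate features.** Zero-variance probes/genes are excluded per
  stage with logged counts — never errors — so accession-scale runs
  survive constant rows. A zero-variance *reference* is an error. At
  $|r| = 1$ the $t$ map is infinite; the smallest positive double is
  returned so strict `p < p_max` comparisons behave.
* **Missing values.** Rejected at load. Every downstream $n$ is then
  the full sample count; pairwise-complete correlation is deliberately
  not offered.
* **Ward clustering.** `ward_linkage()` dispatches to
  `stats::hclust(method = "ward.D2")` on Euclidean distances, whose
  merge heights equal $\sqrt{2\,\Delta\mathrm{ESS}}$; the test suite
  verifies the full merge sequence against a naive
  recompute-all-variances implementation. `cut_partition()` names the
  $k = 3$ sample clusters high/medium/low by mean driver reference.
* **Cumulative-proportion transform.** Per sample, values sorted
  descending; the gene at position $i$ receives
  $1 - \mathrm{cumsum}_i/\mathrm{total}$. Ties all take their block-end
  value, making the result order-free; a constant sample maps to zeros.
  The transform depends only on within-sample ranks and relative
  magnitudes and is invariant to positive per-sample scaling (to
  floating-point rounding), which is what makes heterogeneous platforms
  comparable. It requires linear non-negative input; log-scale matrices
  must be explicitly de-logged (`from_log2 = TRUE`) — auto-detection is
  refused because a silent wrong guess would corrupt every downstream
  rank.

## The synthetic generators

The generators exist so every stage can be validated against known
truth, at desk scale, with no downloads. They emulate exactly the
structure the estimator assumes:

* one standard-normal latent factor per sample (the driver axis);
* module genes $g = \beta\,L + \sigma\,\varepsilon$, giving a known
  population correlation $\beta/\sqrt{\beta^2+\sigma^2}$
  (`expected_population_correlation()`); the defaults $\beta = 1$,
  $\sigma = 0.75$ plant the module at $r = 0.8$;
* independent background genes (SD 1);
* probe replication as gene value plus probe noise (SD 0.3, so sibling
  probes cohere at $r \approx 0.94$);
* a driver with six probes, one replaced by independent noise, so
  coherence selection has a realistic rejection to make (five of six
  retained);
* a count-scale analog drawing negative-binomial counts with natural-log
  mean $\mathrm{baseline} + \beta L$ (baseline mean 100, dispersion
  0.1), converted to CPM;
* monotone platform distortions (`apply_platform_distortion()`):
  per-sample power response, scale factor and optional multiplicative
  jitter — rank-preserving when jitter is off;
* grouped cohorts (`simulate_group_cohort()`) with the latent factor at
  evenly spaced group levels, adjacent means $3\sigma$ apart and
  within-group jitter $\sigma/2$ — separated but not degenerate groups,
  the regime where a high/medium/low partition is meaningful. (With
  substantially larger within-group latent spread the three groups
  genuinely overlap in one dimension and no clustering method can
  recover them reliably; that regime tests the biology, not the
  algorithm.)

All generation is bit-reproducible from one integer seed, with
per-stage sub-streams, and never touches the caller's RNG state.

What the generators do **not** emulate — and therefore what passing
tests do not show about real data: Affymetrix probe intensity
distributions and probe-affinity biases, batch structure, library-size
biology, correlated background modules (the background is independent
noise, so the false-positive calibration is against a clean null), and
multi-factor regulation (one latent axis only).

Two count-scale caveats surfaced during validation and are properties of
the data type, not of the implementation:

* **CPM is compositional.** If the planted module is a large fraction
  of the library, its inflation depresses every other gene's CPM and
  the driver's CPM profile decouples from the latent factor. Realistic
  configurations keep the module small relative to the library; users
  analysing real RNA-seq where composition shifts are plausible should
  prefer TMM-style normalised input (not provided here).
* **Normal-theory $p$ on CPM is mildly anti-conservative.** On skewed
  CPM marginals at $n = 40$ the null pass rate of the
  $|r| \ge 0.5$ screen is about 1.4× the $t$-map prediction (0.0015 vs
  0.0010, measured over $10^5$ null genes). On Gaussian data the
  analytic rate is matched exactly. The validation suite holds the
  count-scale null to its simulated truth and the Gaussian null to the
  closed form.

## Validation design and problem sizes

The test suite runs entirely on generated data: the correlation kernel
against exhaustive permutation enumeration (50 fixtures at $n \le 7$;
the unconditional $t$ $p$ and the conditional permutation $p$ agree to
a mean gap of ~0.03, individual fixtures up to ~0.2 — the two are
different conditioning targets at tiny $n$, which is why both are
reported); standardisation exactness; 20 end-to-end probe-level fits at
the default study conditions (40 samples, 120 module genes at
population $r = 0.8$, 2000 background genes, 4 probes per gene) with
every reported record re-derived by an independent
standardise–aggregate–correlate recomputation; Ward merges against the
naive oracle on 100 random instances; and the calibration checks above.
The whole suite runs in well under a minute; `scripts/acceptance.R`
recomputes the headline numbers from scratch for any seed.

## Known limitations

* The signature is marginal: correlated genes are not causally ordered,
  and a strong co-regulated module unrelated to the driver would enter
  if it happens to track the driver in the cohort at hand.
* Raw thresholds mean the background admission rate scales with the
  transcriptome size; the logged expected false-positive count should be
  read alongside any signature.
* The cumulative-proportion transform discards absolute expression
  scale by construction; it enables cross-platform *comparison*, not
  cross-platform *quantification*.
* Ortholog pairing is one-to-one by default; many-to-many homology is
  dropped (with counts), which under-uses gene families.
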