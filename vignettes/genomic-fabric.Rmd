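---
title: "The genomic fabric model: statistics, simulator and design choices"
author: "gfabric"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The genomic fabric model: statistics, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfabric)
```

# The model

`gfabric` treats a replicated expression experiment as a collection of
(region, phenotype) *datasets*, each holding, for every gene *i*, the
normalized signals $a_{ik\xi}$ of its redundant probes $k = 1..R_i$ on
biological replicas $\xi = 1..n$ (four in the motivating design, one animal
per replica). Three per-gene characteristics are treated as independent
axes of the transcriptome:

**Average expression (AVE).** The mean over spots of the spot replicate
means, $\mathrm{AVE}_i = R_i^{-1}\sum_k \mu_{ik}$. Because each
hybridization is scaled to its own median, AVE is expressed in multiples of
the median gene expression — a unit that transfers across arrays.

**Relative expression variability (REV).** A pooled coefficient of
variation across replicas,
$\sqrt{R_i^{-1}\sum_k (s_{ik}/\mu_{ik})^2}$, multiplied by the midpoint of
the chi-square confidence-interval multipliers for a standard deviation
estimated with $r_i = nR_i - 1$ degrees of freedom,
$\tfrac12\left(\sqrt{r_i/\chi^2_{r_i;1-\alpha/2}} +
\sqrt{r_i/\chi^2_{r_i;\alpha/2}}\right)$, and reported in percent. The
correction (> 1, shrinking to 1 as $r_i$ grows) compensates the downward
bias of small-sample dispersion estimates, so genes probed by fewer spots
are not flattered. A worked value used throughout the tests: one spot with
replicas (8, 10, 10, 12) has CV 0.1633, $r = 3$, correction 2.1475, hence
REV = 35.07%. Low REV is read as strong homeostatic control.

**Expression correlation (COR).** The Pearson correlation of two genes'
per-replica profiles $v_{i\xi} = R_i^{-1}\sum_k a_{ik\xi}$, across
replicas. Significance uses the exact t-transform
$t = r\sqrt{(n-2)/(1-r^2)}$; at $n = 4$ the two-tailed 5% threshold is
$|r| = 0.950$, a deliberately blunt instrument that the null-calibration
tests verify is exactly calibrated. Significant positive pairs are called
*synergistic*, negative *antagonistic*, otherwise *independent*. A note on
the definition: centering per-spot replicate *means* by themselves would be
degenerate, so correlations are always computed on the per-replica
profiles, which is also what the paired cross-region analysis requires.

**Gene Commanding Height (GCH).** The hierarchy score combines expression
control and transcriptome-wide coordination:
$$\mathrm{GCH}_i \;=\; \frac{\mathrm{REV}_{\mathrm{med}}}{\mathrm{REV}_i}\,
\exp\!\Big(\frac{n}{N}\sum_{j\neq i}\mathrm{COR}^2_{ij} \;-\; 1\Big),$$
with $N$ the common-universe gene count and
$\mathrm{REV}_{\mathrm{med}}$ the dataset median REV (a mean can be chosen
instead). Under the null, $E[r^2] = 1/(n-1) = 1/3$, so a typical gene sits
near $e^{1/3} \approx 1.4$, while a tightly controlled gene coordinated
with everything approaches
$(\mathrm{REV}_{\mathrm{med}}/\mathrm{REV}_i)\,e^{\,n-1}$ — two orders of
magnitude, matching the dynamic range such hierarchies display in practice.
An alternative parenthesization of the exponent,
$n(\langle \mathrm{COR}^2\rangle - 1)$, is available as
`gch_variant = "scaled"`; it compresses the baseline to $\approx e^{-8/3}$
and is kept only as an audit switch, stamped into the run manifest. The
rank-1 gene is the Gene Master Regulator (GMR); ties break by gene id for
reproducibility.

**Composite regulation call.** For a comparison "test vs reference" within
a region, the signed expression ratio is
$x_i = \mathrm{AVE}_{i,\mathrm{test}}/\mathrm{AVE}_{i,\mathrm{ref}}$ when
the test value is at least the reference and
$-\mathrm{AVE}_{i,\mathrm{ref}}/\mathrm{AVE}_{i,\mathrm{test}}$ otherwise,
so $|x| \ge 1$ always and the sign is the direction in the *first-named*
phenotype. A gene is significantly regulated iff **both**
$|x_i| > \mathrm{CUT}_i = 1 + \sqrt{2(\mathrm{REV}^2_{\mathrm{test}} +
\mathrm{REV}^2_{\mathrm{ref}})}/100$ (strict) and the two-tailed Welch
p-value on replica profiles is below $\alpha$ (strict). The cutoff makes
noisy genes clear a proportionally higher bar, which can only remove calls
relative to the p-criterion alone — the package's null simulations measure
composite call rates far below the nominal 5% at CV 20%.

**Weighted regulation (WIR / WPR).**
$\mathrm{WIR}_i = \mathrm{AVE}_{i,\mathrm{ref}}\cdot\mathrm{sign}(x_i)
\cdot(|x_i|-1)\cdot(1-p_i)$ is computed for *all* genes, significant or
not: it rewards large net fold changes of well-expressed genes called with
confidence, and is zero exactly when $|x| = 1$ or $p = 1$. The orientation
convention (reference = second-named phenotype) is fixed by an internal
consistency requirement: for any gene, the implied confidence
$\mathrm{WIR}/(\mathrm{AVE}_{\mathrm{ref}}(|x|-1))$ must lie in $(0,1)$,
which the acceptance suite checks both on published table rows and by
construction on random inputs. Pathway scores aggregate magnitudes:
$\mathrm{WPR}_\Gamma$ is the mean $|\mathrm{WIR}|$ over the pathway's
quantified genes (Card(Γ) counts only genes present in the tensor); a
root-mean-square variant is provided (`wpr_variant = "rms"`) because the
aggregation could defensibly be read either way — both preserve pathway
orderings in simulation.

**Cross-region synchrony.** Replica indices identify animals, so the same
gene's profiles in two regions can be correlated across the four paired
animals; significant positive correlation is *in-phase*, negative
*anti-phase*. Percentages are reported over all quantified genes of the
queried set (no expression floor is applied).

# Ingest and normalization

Spots are dropped if flagged corrupted or if foreground fluorescence is
below twice the background; the boundary (exactly 2×) is retained, reading
the detection rule literally. Background-subtracted signals that are not
strictly positive are dropped (the CV and ratio machinery requires positive
values). Each array — one (region, phenotype, replica) hybridization — is
then divided by the median of its own valid signals, before any gene
selection, so normalization commutes with later subsetting. Within a
dataset, a (gene, spot) series is kept only if it has a value in every
replica; a gene survives if at least one series does, and the analysis
universe is the intersection of surviving genes over all datasets, so one
gene count $N$ applies to the whole experiment. How partially missing genes
should be treated before quoting a single $N$ is genuinely open; the
common-universe rule is this package's choice and is reported alongside the
per-dataset drop lists.

Degenerate cases follow documented conventions: a Welch test between two
zero-variance groups returns p = 1 for equal means and p = 0 otherwise;
zero-variance profiles yield an undefined COR that is flagged and excluded
from coordination sums; a gene with REV = 0 (possible only in synthetic
data) is substituted by the smallest positive REV for GCH with a warning;
correlations are clipped to $[-1, 1]$ against rounding before squaring.

# The synthetic-data generator

`simulate_experiment()` emulates the statistical structure the estimators
assume, not array physics. Per gene: a lognormal baseline abundance
(meanlog 4, sdlog 1.5 by default — about three decades of signal, as on a
high-density two-color array); multiplicative lognormal replicate noise
with a gene-specific CV drawn from `cv_range` (default 5–50%, spanning
tightly controlled to loosely controlled genes); a smaller multiplicative
spot-within-replicate term (sd 0.05). Foreground is background plus gain ×
expression with background about 1% of the median signal, so detection
failures come only from the two injected corruption mechanisms: a
`frac_corrupted_spots` fraction gets the quality flag, and a
`frac_low_signal_spots` fraction is forced under the foreground ≥ 2 ×
background rule (defaults 1% and 2%).

Co-regulation is induced by additive latent factors on the log scale. A
block with loading $\lambda$ replaces a member's standard normal deviate
$\varepsilon$ by
$(\lambda L + (1-\lambda)\varepsilon)/\sqrt{\lambda^2 + (1-\lambda)^2}$ —
an amplitude mixture that preserves the configured CV exactly and gives two
members the population correlation
$\lambda^2/(\lambda^2 + (1-\lambda)^2)$ (0.997 at loading 0.95, 1 at
loading 1). Cross-region sets use one latent value per (phenotype, animal),
shared by both regions — the paired-animal structure the synchrony analysis
keys on. Ground truth (true CVs, baselines, fold matrix, block memberships,
latent values, per-spot validity labels) is returned and serialized with
the fixture.

The generator does **not** emulate dye chemistry or dye swaps, spatial
array artifacts, probe-sequence effects, heavy-tailed outliers or
batch/scanner drift. Passing recovery tests on these simulations therefore
demonstrates correctness of the estimators under the stated noise model,
not robustness to everything real arrays do.

# Calibration and recovery studies: sizes and their rationale

The test suite and `scripts/acceptance.R` run seeded simulation studies
sized to give stable Monte Carlo estimates in seconds: null calibration
uses 1,000-gene two-phenotype datasets at CV 20% over up to 100 seeds
(composite call rate, and coordination edge rate over thousands of disjoint
null pairs); power uses 100-gene datasets with one 8-fold gene (detection
rate, and WPR ordering against a matched null pathway sharing 19 of 20
genes, which removes between-pathway abundance noise from the comparison);
synchrony uses 2,000-gene two-region datasets with fifty shared-factor
genes split over ten independent per-animal factors, so the estimate does
not hinge on a handful of latent draws.

Two desk-scale effects are worth recording because they shaped the study
designs. First, the per-array median is itself an estimate: its
array-to-array jitter is roughly $1.25\,\sigma/\sqrt{N}$ on the log scale
(σ the typical replicate noise of genes near the median). At $N$ = 16,863
this is negligible (~0.3%), but on a simulated 200-gene "array" it reaches
~3% — the same order as the tight control the hierarchy analysis must
detect — and simultaneously caps a low-CV gene's measurable stability,
decorrelates it from its co-regulation block, and (if a block is made large
enough to compensate through the coordination term) leaks the block signal
into every gene via the median. The hierarchy-recovery study therefore
evaluates `gene_commanding_height()` on expression tensors built directly
from simulated per-replica profiles (`expression_tensor()`), downstream of
ingest: a 200-gene dataset whose first 50 genes share a loading-1 latent
factor, with the first member under much tighter control (CV 2% vs 30%).
There the constructed hub tops the hierarchy in ≈98–99% of runs. Second,
pooled REV has only about $n-1 = 3$ effective degrees of freedom regardless
of spot redundancy (redundant spots share the same animals), so across
hundreds of null genes a few per run realize very small REV by chance; the
hub construction's coordination block is what makes the true hierarchy
unambiguous despite this.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | two-tailed level for COR/edge/phase significance, the Welch clause, and the REV chi-square interval |
| `gch_variant` | `"offset"` | GCH exponent parenthesization (`"scaled"` as audit alternative) |
| `rev_center` | `"median"` | dataset REV norm in GCH (`"mean"` alternative) |
| `wpr_variant` | `"mean_abs"` | pathway aggregation of WIR (`"rms"` alternative) |
| `block_size` | 512 | rows per block for streamed correlation passes |

p-values are deliberately not multiplicity-adjusted: the composite
criterion is defined on raw p < 0.05, with the REV-dependent fold-change
cutoff as the second guard. Users wanting FDR control can apply
`p.adjust()` to the regulation table's `p` column themselves; the package
does not silently change the calling rule.

# Known limitations

- With four replicas, per-pair correlation significance requires
  |COR| > 0.95; individual edges are coarse, and only aggregate patterns
  (edge rates, $\sum \mathrm{COR}^2$, phase percentages) are stable.
- The O(N²) correlation pass streams in blocks, but a full 16,863-gene GCH
  computation is a large job by design; `gch = FALSE` skips it when only
  AVE/REV/regulation are needed.
- The amplification ratio reported by `gfp_counts()` is the computed
  quantity (workable values ÷ AVE count); it is not comparable across
  designs with different correlation bookkeeping conventions.
- Reading vendor feature-extraction or series-matrix formats is out of
  scope; the ingest surface is the documented spot TSV plus
  `expression_tensor()` for already-normalized values.
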