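---
title: "Calling accessibility domains: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling accessibility domains: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hadcall)
```

## The model

`hadcall` treats a differential ATAC-seq peak table — intervals with a
knockout-vs-wildtype log2 fold change and a p-value — as a sparse,
irregularly spaced signal along each chromosome. The premise is that loss
of a replication-coupled chromatin-assembly factor depresses accessibility
coherently over megabase-scale blocks of heterochromatin, so individual
peak-level changes, noisy on their own, become detectable after local
averaging. The caller therefore:

1. anchors one data point per peak at the interval midpoint (all peaks,
   not only significant ones: a filtered track would bias the local mean
   toward extreme values and break the spacing structure the gap rule
   relies on);
2. smooths with a centered 25-point sliding mean, truncating windows at
   chromosome ends so every input point yields an output point;
3. marks smoothed points at or below the cutoff −0.58 and merges marked
   points whose support footprints lie within 1 Mb of each other,
   regardless of intervening unmarked points.

The assumptions worth stating: peak midpoints are an adequate spatial
anchor (summits are not required in differential tables); windows in
*data points* rather than base pairs are intended, which makes the
effective bandwidth adapt to peak density — wide in peak-poor
heterochromatin, narrow in peak-dense euchromatin; and a domain is a
*gap-limited run of depressed windows*, not a changepoint segmentation.

## Parameters

| parameter | default | units | why |
|---|---|---|---|
| `da_lfc_threshold` | 1.0 (inclusive) | log2 units | a two-fold change; `±1` reads as boundary included |
| `da_p_threshold` | 0.01 (strict `<`) | — | raw p as printed; an FDR column can be substituted with `use_fdr` |
| `window_points` | 25, odd enforced | data points | odd keeps the window centered on its anchor |
| `domain_cutoff` | −0.58 | log2 units | log2(1/1.5) rounded to two decimals, i.e. a 1.5-fold loss; marking uses `<=` so values tying the rounded cutoff still count as a 1.5-fold change |
| `max_gap` | 1,000,000 | bp | "no more than 1 Mb": strict `<=`, measured end-of-footprint to start-of-next-footprint |
| `density_bin` | 1,000,000 | bp | peaks/Mb is the natural unit for domain-scale density |
| `de_fold_threshold`, `de_p_threshold` | 1.5, 0.05 | fold, — | expression integration thresholds |
| `promoter_upstream/downstream` | 3000/3000 | bp | the ±3 kb convention of standard peak annotators |
| `downstream_bp` | 3000 | bp | same convention for the "downstream" category |
| `excluded_chromosomes` | chrY | — | sex-chromosome domains are dropped after calling |

## Numerical and convention choices

* **Coordinates** are 0-based half-open (BED-native) everywhere inside the
  package; GTF input is converted at the reader boundary. Chromosome name
  matching is exact text — no "chr" aliasing, so input mismatches surface
  as errors rather than silently empty joins.
* **Window alignment.** Whether the original smoothing was centered or
  trailing is not knowable from the outputs alone; both are implemented
  (`align` in `sliding_window_average()`) and centered is the default
  because symmetric windows avoid a systematic half-window shift of domain
  boundaries. Edge windows are truncated rather than dropped so domain
  counts are comparable across chromosome ends.
* **Footprints, not anchors.** A domain's interval is the union span of
  its members' *support intervals* (first to last contributing peak), so a
  single isolated marked window still yields a domain of positive width —
  consistent with sub-kilobase domains being observable.
* **Ties and degenerate inputs.** Marking uses `<=` at the cutoff;
  identical anchors are kept and ordered by start then end; an empty
  selection reports `fraction_down` as NaN (not 0); empty domain sets give
  NaN fractions; a density-association call errors when no bin midpoint is
  inside (or when every one is), and a *rotated* set with no inside bin
  scores −Inf in the null (it cannot exceed the observed statistic) — at
  default sizes this cannot happen since every domain exceeds the 1 Mb bin
  spacing.
* **Membership is midpoint/TSS containment**, a partition: each site or
  gene is counted exactly once, which is what percentage tables over
  categories require. Gene-body overlap membership for the expression
  integration is available behind `membership = "body"`.
* **Overlap** between domain sets counts a query domain from 1 bp of
  overlap with the merged subject by default (`min_bp` exposes a stricter
  bar); element-wise overlap fraction is asymmetric by construction, and
  the base-pair Jaccard complements it symmetrically.
* **The percentage of down-regulated genes in domains** is returned
  unrounded; display-level rounding is left to reports (printed summaries
  round a 5.50 to "~5%"-style figures, and the package does not bake that
  into the value).
* **Permutation nulls** use per-chromosome circular rotation, which
  preserves the size and spacing multiset of the rotated set exactly —
  the conservative standard for interval association — with the add-one
  estimator `(1 + #{null >= obs})/(1 + n_perm)`, so p is never 0.

## What the synthetic generator emulates

`sim_params()` defaults define a toy genome chosen to carry the
statistical structure the analysis assumes, at a size where the full
pipeline plus two 199-rotation permutation tests run in seconds:

* 3 chromosomes × 100 Mb; 7 LAD-like domains per chromosome, 5–9 Mb
  (real LADs run 0.1–10 Mb; the upper end is used so each planted domain
  carries enough peaks for stable window statistics), separated by at
  least 3 Mb so that distinct domains are never bridged by the 1 Mb merge
  rule; 20 of the 21 LADs contain one planted low-accessibility domain
  occupying 50–100% of the LAD span — nested, not coincident, so the
  domain-in-LAD overlap statistic is nontrivial.
* Differential peaks by a renewal process: mean spacing 7.5 kb outside
  and 25 kb inside planted domains (sparser peaks in gene-poor, AT-rich
  domains; ~30,000 peaks genome-wide; ≥80 peaks in the smallest planted
  domain, comfortably above one 25-point window). log2FC ~ N(0, 0.3)
  outside, N(−1.5, 0.5) inside planted domains; the p-value is the
  two-sided background tail of the drawn log2FC, so the joint (log2FC, p)
  structure resembles a volcano plot and selection on both columns
  behaves as it does on real tables.
* A target fraction (0.88) of selected sites losing accessibility is met
  by planting isolated gained-accessibility peaks among the background at
  an analytically calibrated count (normal tail probabilities under the
  default selection); the mechanism vanishes in the null configuration
  where the domain log2FC model equals the background.
* ChIP peaks: homogeneous Poisson at 30 peaks/Mb in both conditions, plus
  10 peaks/Mb inside planted domains in the knockout only.
* Genes: Poisson placement at 10/Mb outside and 2/Mb inside the LAD-like
  compartment — the gene-poor territory is the *LAD*, not just its planted
  core, mirroring the biology of lamina-associated heterochromatin. 992
  differentially expressed genes (709 down, 283 up), drawn with
  class-total odds 19:1 outside:inside planted domains, so 5% of DE genes
  are expected inside; signs are assigned independently of location.
* Isochores: 0.3–3 Mb tiles partitioning each chromosome, labeled
  L1/L2/H1/H2/H3 at genome-like proportions, with planted-domain tiles
  biased to the GC-poor classes L1/L2.

Every output is a pure function of `(params, seed)`: one global seed
spawns fixed per-stream sub-seeds (truth +1, peaks +2, ChIP WT/KO +3/+4,
genes +5, isochores +6), so streams are reproducible independently.

**What it does not emulate** — and hence what passing tests do not show
about real data: read-level noise (FASTQ, fragment sizes, Tn5 insertion
bias), peak-calling artifacts and blacklist regions, replicate structure
and shrinkage in the upstream differential model, sequence composition
(isochores are labels, not GC content), facultative vs constitutive LAD
dynamics, and any chromosome-scale heterogeneity (all toy chromosomes are
exchangeable). Boundary precision claims transfer only to data whose peak
spacing near domain edges resembles the simulated regime: the called
footprint systematically overreaches a true domain edge by roughly half a
window of flanking peaks (~12–15 background spacings, ~100 kb here),
which is why recovery is evaluated as base-pair overlap rather than exact
boundaries.

## Problem sizes used in the checks

The test suite exercises the caller against a brute-force transitive
merge oracle on 1,000 random tracks of up to 50 points, the smoother
against brute-force means, and the overlap statistic against a per-base
oracle on small spans; genome-scale checks (planted-domain recovery,
density association with 199 rotations, and 50 null replicates for the
uniformity of the permutation p-value) use the default toy genome above.
These sizes were chosen as the smallest at which the domain-scale
statistics are stable.

## Known limitations

* Windows in data points mean the bp bandwidth depends on local peak
  density; two datasets with different peak calling depth are not
  directly comparable at the same `window_points`.
* The gap-merge rule has no notion of domain *strength*; a long shallow
  run just below the cutoff and a short deep one are merged identically.
* Rotation nulls condition on the chromosome's own track; they do not
  model inter-chromosomal exchange.
* The pipeline consumes differential statistics as given; it does not
  recompute them from counts, nor does it model their estimation error.

```{r example, eval = FALSE}
# the full synthetic run shown in the README
report <- run_pipeline(list(seed = 1L, simulation = TRUE))
```
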