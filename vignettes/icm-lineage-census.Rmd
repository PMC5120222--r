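---
title: "Methods: a single-cell lineage census of the blastocyst ICM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a single-cell lineage census of the blastocyst ICM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icmcensus)
```

## The biological setting

In the mouse blastocyst, the inner cell mass (ICM) resolves into two
lineages: the NANOG-positive epiblast (EPI) and the GATA6-positive
primitive endoderm (PrE). Early ICM cells co-express both markers
(double-positive, DP) and behave as bipotent progenitors; as development
proceeds (conveniently indexed by the embryo's total cell count), these
progenitors commit asynchronously and irreversibly to one of the two fates,
until the ICM stabilises at roughly a 3:2 PrE:EPI ratio while very few DP
cells remain. Late in development, part of the epiblast downregulates NANOG
and scores double-negative (DN); these cells are treated as late-stage EPI
throughout. FGF/MAPK signalling selects the fate of committing progenitors:
saturating FGF4 drives them to PrE, while MEK or FGF-receptor inhibition
drives them to EPI; committed cells no longer respond.

`icmcensus` implements this picture end to end: a forward model that
simulates per-nucleus immunofluorescence cell tables; the depth-decay
correction and the two cell classifiers used to analyse such tables; staging
and composition statistics; and the treatment simulator with its
progenitor-pool outcome predictor. Because every synthetic cell carries its
generating lineage, each analysis stage can be validated as a
parameter-recovery exercise through the full measurement model.

## The synthetic-data generator

`generator_config()` fixes the study conditions; `generate_cohort()` draws
embryos per developmental stage bin (totals uniform within the half-open
bins 32–64, 64–90, 90–120, 120–150, >150 cells, the last capped at 200 for
sampling).

**Lineage allocation.** Each ICM cell is DP with the stage-dependent
probability `dp_fraction_expected()`: a linear interpolation from 1 at 32
cells down to `dp_floor` (default 0.05) at `allocation_completion_size`
(default 100 cells), constant thereafter. This is the simplest monotone law
consistent with the stage-wise ranges the census reports (roughly 50–75%,
25–50%, under 25%, and ~5% DP across successive stages). Committed cells
are PrE with probability `allocation_ratio` (0.6, the 3:2 ratio) and EPI
otherwise; in embryos beyond 150 cells each EPI cell independently converts
to DN with probability `dn_late_fraction` (default 0.25, chosen so that DN
is a visible minority of the late epiblast). Allocation is drawn once per
cell and never revised: commitment is irreversible by construction.

**Compartments.** The trophectoderm fraction is constant across stages
(`te_icm_ratio`, default 0.66). The census literature does not quote this
ratio numerically; 0.66 reflects the usual situation where roughly two
thirds of blastocyst cells are TE, and the package asserts constancy, not
the value itself.

**Fluorescence model.** Per cell and channel, log intensity =
lineage/channel emission mean + biological deviate (sd 0.25 log-units) +
embryo decay slope x depth + measurement noise (sd 0.15 log-units). Default
emission means put marker-positive populations at 150 a.u., negative ones
at 15 a.u., and DP at 120 a.u. on both channels, so the four populations
sit in the quadrants that the fixed 50 a.u. thresholds delimit on the
linear scale. The per-embryo decay slope is drawn once
(mean -0.0125 log a.u. per micron, between-embryo sd 0.003, small
per-channel jitter), multiplying intensities by about 0.5 across the
60-micron nuclear span — typical attenuation for a confocal stack of a
whole-mount embryo. Linear intensities are clipped to the 8-bit range
[0, 255]; clipped cells are flagged so analyses can exclude saturation
artifacts.

**What the generator does not emulate.** Segmentation errors,
under/over-segmentation corrections, spatial structure (positions are
uniform; no ICM/TE geometry), channel cross-talk, litter effects beyond an
id, and temporal drift across imaging sessions. Passing recovery tests on
these synthetic cohorts therefore validates the analysis chain under the
stated measurement model, not robustness to every artifact of real
microscopy data.

## Depth-decay correction

Fluorescence decays multiplicatively with imaging depth. `fit_decay()`
regresses log raw intensity on z (ordinary least squares) per embryo and
channel, over all cells of the embryo — TE included, since decay is an
optical, not biological, effect and every cell adds precision; an
ICM-only fit can be had by subsetting beforehand. Raw values are floored at
1 a.u. before the log so 8-bit zeros stay finite.

Because each embryo contributes only a moderate number of cells — and
because the lineage mixture makes the residuals bimodal — the raw slopes
are noisy. `eb_shrink()` therefore pools them per channel under the
standard normal–normal empirical-Bayes model: the between-embryo variance
is estimated by the method of moments,
tau^2 = max(0, var(b) - mean(se^2)), and each slope is pulled towards the
cohort mean with precision weight w = tau^2 / (tau^2 + se^2). Shrinkage is
linear, so every shrunk slope lies weakly between its raw value and the
cohort mean, and the spread of shrunk slopes never exceeds that of the raw
ones. Pooling is per processed batch (one input cohort), mirroring
experiment-wise correction. `correct_z()` subtracts shrunk-slope x z from
the log intensity, referencing all cells to the first optical section
(z = 0); any constant offset is immaterial downstream because both
classifiers are fit on corrected data.

One practical note: in roughly a tenth of default embryos the *raw* OLS
slope fluctuates towards zero (its standard error is ~0.006 against a true
slope of -0.0125), and there the corrected depth trend can exceed the raw
estimate in magnitude even though the shrunk slope is closer to the truth.
The tests therefore check that the strong majority of embryos flatten, that
the median depth trend shrinks severalfold, and that shrinkage reduces the
mean absolute error against the generating slopes.

## Classification

Two classifiers, applied to ICM cells only:

* `classify_threshold()` implements the fixed quadrant rule on corrected
  linear-scale intensities: a marker is positive at or above 50 a.u.
  (EPI: NANOG+/GATA6-; PrE: GATA6+/NANOG-; DP: both; DN: neither).
  Exact-threshold values count as positive; comparisons are made in the log
  domain, which is equivalent and numerically exact under the log/exp
  round trip.
* `fit_centers()` + `assign_by_centers()` implement the data-driven
  scheme: k-means (k = 3, k-means++-style restarts via `stats::kmeans`
  with `nstart` random starts under a fixed seed) on the pooled
  (log GATA6, log NANOG) distribution of the early (32–64) and late
  (120–150) reference stages, which together contain a dominant DP cluster
  and two fully segregated committed clusters. Fitted centers are labelled
  by coordinate extremes (highest NANOG = EPI, highest GATA6 = PrE,
  remainder = DP) — stage-robust, unlike labelling by cluster size — and a
  DN center is synthesized at (GATA6 of EPI, NANOG of PrE). Cells go to the
  nearest center by unweighted Euclidean distance (both axes share log-a.u.
  units, so no standardisation), with ties broken by the fixed priority
  EPI > PrE > DP > DN. For cultured or treated batches acquired with their
  own imaging parameters, `refit_for_batch()` re-anchors the centers on the
  batch's control embryos and applies them to every condition.

With the default geometry the nearest lineage centers are ~2.1 log-units
apart against a total per-channel dispersion of ~0.29 (biological 0.25 plus
noise 0.15 in quadrature) — about 7 total-sd, or 14x the measurement noise.
The nearest-center error rate for a pair of centers at distance d is
approximately 2 Phi(-d / 2 sigma), i.e. below 0.1% here; 98% accuracy
requires d of at least ~4.7 total-sd, which the defaults exceed
comfortably. The same margin makes the threshold and k-means labels agree
on well over 95% of terminal-stage cells.

## Staging and composition

`stage_bin()` uses half-open [lower, upper) bins, so a 64-cell embryo is
"64–90" and 150 cells falls in ">150" — a convention the overlapping
printed bin labels force. `composition()` reports per-embryo counts and ICM
fractions (summing to one; empty ICMs are flagged, not dropped silently),
plus the PrE share of the committed ICM (PrE / (PrE + EPI + DN)). That
committed share is the scale on which the terminal "60% PrE / 40% EPI"
figure is quoted — the committed shares add to 100% while the residual ~5%
DP pool is reported separately as a fraction of the whole ICM — and it is
how the package reports terminal composition. `bin_composition()` averages
unweighted across embryos (each embryo counts once, as in per-embryo
composition plots). `smooth_composition()` runs local regression
(`stats::loess`, tricube weights, degree 1, span 0.75 — degree and span
are choices; the census cites local regression without parameters) of each
fraction against total cell count, clipped to [0, 1]. A span this wide
flattens the curve near the completion kink by up to ~0.1; the tests
compare against the same smoother applied to the exact allocation law to
separate sampling error from that intrinsic bias.

`scaling_experiment()` builds half-, single- and double-sized cohorts with
a paired design (the three groups share per-index seeds, emulating
halves/doubles derived from the same litters), runs the full pipeline with
control-anchored centers, and summarises sizes and composition. Scale
enters only the cell counts: allocation follows the control embryo's
developmental stage, so composition is scale-invariant by construction —
the property the halved/doubled-embryo experiment demonstrates.

## Treatment simulation and the progenitor-pool predictor

`apply_treatment()` grows each embryo exponentially (10 h doubling time,
the preimplantation cell-cycle scale) towards a per-embryo terminal size
drawn uniformly from 120–170 cells, with divisions assigned uniformly at
random (daughters inherit compartment and current label). Only DP
progenitors change fate:

* **Control** — progenitors commit on the developmental schedule, splitting
  0.6 : 0.4 between PrE and EPI. During extended culture the allocation law
  is applied with floor zero: commitment completes once the embryo passes
  the completion size, the residual 5% DP floor being a feature of freshly
  collected embryos (developmental delay), not of cultured ones.
* **FGF4** — saturating ligand converts every progenitor to PrE, and each
  EPI cell downregulates NANOG (DN) with probability `fgf4_dn_prob`
  (default 0.3; a qualitative knob, not an asserted value).
* **MEKi / FGFRi** — modelled identically (the two inhibitors give
  comparable results): committing progenitors become EPI on the normal
  schedule, and NANOG is maintained or restored, so DN reverts to EPI.
  Because commitment still follows the developmental clock, an embryo
  treated with MEKi from the 8-cell stage for 30 h (reaching ~64 cells)
  retains roughly half its ICM as GATA6-expressing progenitors — which a
  subsequent release into control medium then converts into a regenerated
  PrE compartment — whereas FGF4 for the same period exhausts the pool, and
  release leaves an all-PrE ICM.

Labels, not cells, are treated: committed EPI and PrE never interconvert
under any condition sequence (EPI may still appear as DN under FGF4, being
NANOG downregulation of the same lineage). After treatment the fluorescence
of the embryo is re-emitted for the new expression state. Late-stage
NANOG downregulation is not applied during treatment culture — a
simplification that keeps Control bookkeeping exact and matches the
control-anchored classification of cultured batches.

`predict_outcome()` is the deterministic counterpart on initial ICM
fractions: FGF4 moves DP to PrE (and a `fgf4_dn_prob` share of EPI to DN),
MEKi/FGFRi move DP and DN to EPI, Control splits DP 0.6 : 0.4. It conserves
fraction mass exactly and ignores differential proliferation. Under the
growth model above, it equals the Monte-Carlo mean of `apply_treatment()`,
which is the formal statement of the observation that the single-positive
proportion at treatment onset predicts the outcome; the total-variation
distance between a treated and a control prediction grows linearly with the
progenitor fraction at onset, which is why late-stage treatments are
indistinguishable from controls.

## Numerical and design notes

* **Determinism.** Every stochastic entry point takes a seed; cohorts
  derive per-embryo sub-seeds (kept below 2^31) from the cohort seed, and
  library code saves and restores the caller's RNG state. The pipeline is
  byte-reproducible given a seed.
* **Degenerate inputs.** Fewer than 3 usable cells on a channel is a
  degenerate decay fit: an error for a single embryo, a logged warning and
  exclusion at cohort level. A single embryo per channel skips shrinkage
  (slope kept, warning). tau^2 truncates at zero, in which case every slope
  collapses to the cohort mean. k-means requires at least k distinct
  reference points and refuses ambiguous labelling (one cluster maximal on
  both markers). Empty ICMs are flagged; totals under 32 cells are rejected
  as pre-blastocyst.
* **Problem sizes.** The validation suite uses cohorts of 30 embryos per
  stage bin (~150 embryos, ~16,000 cells) for composition recovery, 500
  replicate embryos for slope-bias checks, and 200-embryo cohorts for
  predictor agreement — sizes at which Monte-Carlo error is a small
  fraction of each tolerance.
* **Limitations.** The generator's allocation law is linear by choice, not
  derived from dynamics; treatment growth is exponential with a hard cap;
  no spatial sorting, no segmentation artifacts, no GATA4/OCT4 channels
  (three-channel identities were assigned manually in the source data and
  are out of scope); no hypothesis tests between groups. The optional
  residual-signalling reading of FGF4 washout is not modelled (config flag
  deliberately absent rather than default-off: release into control medium
  always stops conversion).
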