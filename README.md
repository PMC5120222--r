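# icmcensus

Single-cell lineage census of the mouse blastocyst inner cell mass (ICM).

In the blastocyst, ICM cells resolve into NANOG+ epiblast (EPI) and GATA6+
primitive endoderm (PrE) through the incremental, irreversible commitment
of GATA6+/NANOG+ double-positive (DP) progenitors; late epiblast cells may
downregulate NANOG and score double-negative (DN). Quantifying this process
from confocal immunofluorescence requires per-nucleus intensity tables,
correction of depth-dependent signal decay, and a reproducible assignment
of cell identities. `icmcensus` implements that full analysis chain for
people who work with such censuses — developmental biologists
quantifying ICM composition, and method developers who need a controlled
forward model to validate classification pipelines.

The package provides:

* **A synthetic-cohort generator** (`generate_cohort()`): stage-binned
  embryos (32 to >150 total cells) with a constant TE:ICM ratio; ICM cells
  are DP with probability linear in total cell count (from 1 at 32 cells to
  a residual 0.05 at 100), committed cells are PrE with probability
  ρ = 0.6; log-normal two-channel emission, multiplicative Z-decay
  (linear in log intensity), measurement noise and 8-bit clipping.
* **Depth-decay correction** (`fit_decay_cohort()`, `eb_shrink()`,
  `correct_z()`): per-embryo, per-channel OLS of log intensity on z,
  with empirical-Bayes shrinkage of slopes towards the cohort mean
  (w = τ² / (τ² + se²), τ² by method of moments), then
  corrected log F = log F − b\*·z.
* **Dual classifiers** (`classify_threshold()` with 50 a.u. quadrants;
  `fit_centers()`/`assign_by_centers()` with k-means centers anchored on
  the 32–64 + 120–150-cell reference stages and a synthesized DN center;
  `refit_for_batch()` for control-anchored batches).
* **Staging and composition** (`stage_bin()`, `composition()`,
  `bin_composition()`, `smooth_composition()`, `scaling_experiment()`).
* **Treatment simulation and prediction** (`apply_treatment()`,
  `release_experiment()`, `predict_outcome()`): FGF4 converts progenitors
  to PrE, MEKi/FGFRi to EPI, Control splits ρ : 1−ρ; committed cells never
  change fate, so the single-positive fractions at treatment onset predict
  the outcome.

## Worked example

```r
library(icmcensus)

cfg     <- generator_config(seed = 42, n_per_bin = 10)
cohort  <- generate_cohort(cfg)                       # 50 embryos, 1 row/cell
shr     <- eb_shrink(fit_decay_cohort(cohort))        # decay slopes + shrinkage
cohort  <- correct_z(cohort, shr)
centers <- fit_centers(cohort, seed = 42)             # reference-anchored k-means
cohort  <- assign_by_centers(cohort, centers)
bin_composition(composition(cohort))
```

```
    stage n_embryos total n_icm frac_epi frac_pre frac_dp frac_dn pre_share_committed
1   32-64        10    53    18     0.18     0.17   0.648    0.00                0.47
2   64-90        10    79    27     0.29     0.42   0.289    0.00                0.60
3  90-120        10   101    34     0.37     0.50   0.129    0.00                0.57
4 120-150        10   129    44     0.39     0.55   0.062    0.00                0.58
5    >150        10   174    59     0.28     0.56   0.057    0.11                0.59
```

Reading the table: the DP (progenitor) fraction falls from ~65% of the ICM
in early blastocysts to ~6% beyond 120 cells, while the committed PrE share
(`pre_share_committed`, PrE / (PrE + EPI + DN)) settles at the 3:2 ratio
(~0.6); DN cells appear only in the >150-cell bin as NANOG is
downregulated. The fitted cluster centers (`print(centers)`) sit within a
few hundredths of a log-unit of the generating emission means, which is
what makes the census a parameter-recovery exercise.

The outcome predictor is plain bookkeeping on the progenitor pool:

```r
predict_outcome(c(EPI = 0.25, PrE = 0.35, DP = 0.40, DN = 0), "FGF4")
#> Predicted ICM composition after FGF4 treatment:
#>  EPI  PrE   DP   DN
#> 0.25 0.75 0.00 0.00
```

A thin command-line front end lives at `inst/cli/icm-census`
(`generate`, `correct`, `classify`, `summarize`, `treat`, `predict`,
`run`), and `run_pipeline()` executes the whole chain and writes CSV/YAML
artifacts plus a manifest sufficient to regenerate them byte-identically.

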