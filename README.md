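# nucmorph

Quantitative 3D nuclear morphometry, FISH gene positioning and
dose-response analysis for single-cell imaging — with a synthetic-data
module that makes every stage testable by parameter recovery.

## The problem

HDAC inhibitors such as vorinostat reorganise interphase chromatin, and the
reorganisation is measurable at the cytological scale. In single-cell
absorption volumes (optical CT of hematoxylin-stained cells) the relevant
read-outs are four diagnostically established descriptors per cell:

* **nuclear volume** (µm³),
* **nuclear-cytoplasmic (NC) ratio**, V_nuc / (V_cell − V_nuc),
* **nuclear shape concavity**, the convex-hull volume deficit
  100·(V_hull − V_nuc)/V_hull (%),
* **dense intra-nuclear clump count**, a chromatin-texture proxy.

In confocal immuno-FISH stacks the read-outs are the **relative radial
distance** (RRD) of a gene locus — 0 at the nuclear periphery, 1 at the
geometric nuclear centre, computed by casting a ray from the nucleus
centroid through the spot — and the **Pearson colocalization** of the FISH
channel with a euchromatin (H3K9ac) stain. Drug potency is summarised by
IC50s from the four-parameter logistic

```
Y = Bottom + (Top − Bottom) / (1 + 10^((LogIC50 − X)·HillSlope)),  X = log10(dose)
```

and expression changes by the efficiency-corrected Pfaffl ratio
`E_t^ΔCt_t / E_ref^ΔCt_ref`. Group differences are reported as mean ± SEM
with Mann-Whitney / Kolmogorov-Smirnov comparisons (Bonferroni-adjusted
within the four-feature family) and Anderson-Darling normality checks.

`nucmorph` implements this entire chain as a tested R package, and — since
the motivating experiments deposited no raw images — ships generators for
single-cell phantoms, multi-channel FISH stacks, viability plates and qPCR
Ct tables with planted, voxel-level ground truth.

For the models, defaults and their rationale, see the methods vignette
(`vignettes/nucmorph-methods.Rmd`).

## Worked example

```r
library(nucmorph)

# a synthetic cell: 5 dense clumps, one surface invagination
spec <- cell_phantom_spec(n_clumps = 5, n_invaginations = 1,
                         invagination_radius_um = 2.5, seed = 42)
ph  <- make_cell_phantom(spec)
seg <- segment_cell_nucleus(ph$volume)
morphometry_record(ph$volume, seg$cell, seg$nucleus, cell_id = "demo")
#> # A tibble: 1 × 5
#>   cell_id nuclear_volume nc_ratio concavity_pct clump_count
#>   <chr>            <dbl>    <dbl>         <dbl>       <int>
#> 1 demo              495.    0.525          3.58           5

ph$truth   # generator ground truth, computed from the emitted masks
#> # A tibble: 1 × 5
#>   nuclear_volume cell_volume nc_ratio concavity_pct clump_count
#>            <dbl>       <dbl>    <dbl>         <dbl>       <int>
#> 1           495.       1439.    0.524          3.67           5
```

The measured record matches the planted truth: volume exact to the voxel,
NC ratio to 0.2%, concavity to 0.1 percentage points, clump count exactly.
Dose-response fitting works the same way — simulate a plate at a known
IC50, fit, and read the recovery:

```r
tab <- make_viability_table(logic50 = log10(0.94), noise_sd = 3, seed = 1)
fit <- fit_4pl(tab$dose_um, tab$response)
fit
#> <dr_fit> IC50 = 0.9064 uM  (Top 101, Bottom 0.603, LogIC50 -0.04269, Hill -0.998)
glance(fit)
#> # A tibble: 1 × 4
#>    ic50 sigma converged  nobs
#>   <dbl> <dbl> <lgl>     <int>
#> 1 0.906  2.61 TRUE         60
```

A simulated plate planted at 0.94 µM is recovered at 0.91 µM from 60 noisy
wells (Top/Bottom/Hill returned with standard errors via `tidy(fit)`;
`autoplot(fit)` draws the curve). `run_study()` chains everything —
phantom cohorts for several conditions, segmentation, morphometry,
comparisons, dose-response and FISH arms — into one reproducible report
directory (`inst/scripts/run_study.R` is a shell wrapper over it).

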