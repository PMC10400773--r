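# dtialps

Glymphatic-function analysis along the Alzheimer's disease continuum with
the **DTI-ALPS** (diffusion along perivascular spaces) index, as a fully
tested R pipeline. It is written for neuroimaging methodologists who want
every stage of an ALPS study — tensor fitting, index computation, scanner
harmonization, group statistics, classification — exercisable against
synthetic data with known ground truth.

At the lateral-ventricle level, projection fibers run head-foot (*z*),
association fibers run anterior-posterior (*y*), and perivascular spaces
run left-right (*x*). With `Dxx`, `Dyy`, `Dzz` the diagonal diffusivities
of the fitted tensor averaged over 5 mm spherical ROIs in the
projection- and association-fiber regions,

```
ALPS = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)
```

ALPS equals 1 in isotropic tissue; diffusion along the perivascular axis
raises it above 1, and its decline is a proxy for failing glymphatic
clearance. The package implements, per module:

* **synthetic data** — DWI phantoms with exactly known periventricular
  tensor geometry (`phantom_spec()`, `generate_phantom_dwi()`, Rician
  noise) and three-group NC/MCI/AD cohorts with programmed effect
  structure (`cohort_gen_spec()`, `generate_cohort()`);
* **tensor** — log-linear OLS tensor fit (`fit_tensor_loglinear()`),
  closed-form eigen maps FA/MD/Dxx/Dyy/Dzz (`derive_maps()`),
  mask-normalized Gaussian smoothing (`smooth_maps()`);
* **alps** — sphere ROIs in world mm (`sphere_mask()`), ROI-center
  averaging, diffusivity extraction and the index itself
  (`extract_alps_inputs()`, `alps_index()`, `compute_alps()`,
  `alps_from_dwi()`);
* **harmonize** — parametric empirical-Bayes ComBat
  (`combat_harmonize()`, matches `sva::ComBat` to 1e-6), ICC(2,1)/(3,1)
  and paired t for test-retest stability;
* **stats** — covariate residualization, one-way ANOVA with Tukey
  post-hoc, partial correlations, BH-FDR, and the feature-by-scale
  correlation program (`run_correlation_program()`);
* **classify** — repeated stratified 4:1 splits with 5-fold
  cost-selection CV, linear SVM, rank-based ROC/AUC with percentile CIs
  (`svm_repeated_eval()`, `run_classification()`);
* **io / pipeline** — NIfTI-1 + FSL bval/bvec readers and writers, cohort
  CSV validation, YAML configuration and a deterministic end-to-end
  driver (`run_pipeline()`).

## Worked example

A phantom with `d_perp = 0.4e-3`, `d_axial = 1.4e-3` mm²/s and glymphatic
activity `g = 0.5` has analytic ALPS `0.9/0.4 = 2.25`:

```r
library(dtialps)
gtab <- default_gradient_table(n_dir = 32, b = 1000)
ph   <- generate_phantom_dwi(phantom_spec(g = 0.5, noise_sigma = 0), gtab)
alps_from_dwi(ph$dwi, gtab, ph$rois)[, c("L_ALPS", "R_ALPS", "Bi_ALPS")]
#>   L_ALPS R_ALPS Bi_ALPS
#> 1   2.25   2.25    2.25
```

The full synthetic study is the `analysis/` directory, five numbered
drivers run from the repository root:

```sh
Rscript analysis/01_phantom_validation.R   # pipeline vs closed form
Rscript analysis/02_simulate_cohort.R      # 300-subject NC/MCI/AD cohort
Rscript analysis/03_harmonize_stability.R  # ComBat + ICC/paired-t
Rscript analysis/04_group_stats.R          # ANOVA, partial correlations
Rscript analysis/05_classify.R             # SVM/ROC experiments
```

Each writes its tables to `results/` and prints what it found; from one
run of the chain:

```
noise-free phantoms: max |pipeline - analytic| ALPS = 4.93e-14
Bi-ALPS batch-mean spread: 0.1483 before, 0.0163 after ComBat
retest subset: ICC(2,1) = 0.7641, paired-t p = 0.8777 (n = 15)
Tukey post-hoc (Bi_ALPS):
  comparison        diff        p_adj stars
      MCI-NC -0.08843157 3.970013e-07    **
       AD-NC -0.17599211 8.981704e-13    **
      AD-MCI -0.08756054 1.388054e-05    **
L_ALPS highlights (r, q):
   scale      r        q stars
  MoCA_B  0.552 1.47e-24    **
    IADL -0.506 2.61e-20    **
NC vs AD: FA alone 0.6581; best FA+ALPS 0.9152
```

i.e. the programmed NC > MCI > AD gradient is detected after covariate
adjustment, ALPS correlates positively with cognition scores and
negatively with impairment scores after FDR correction, and adding ALPS
to FA substantially improves NC-vs-AD discrimination — the qualitative
pattern the pipeline exists to test. (Group means for ALPS are a
documented design choice of the cohort generator, so magnitudes are
generator properties, not clinical estimates; see the methods vignette.)

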