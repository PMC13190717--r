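# tremornet

Within-subject FDG-PET analysis of thalamic deep brain stimulation (DBS) in
essential tremor, for researchers studying how stimulation-induced changes
in brain glucose metabolism relate to a template "tremor treatment network"
and to clinical tremor relief.

Patients are scanned in two conditions — Stim-On (clinically optimized
settings) and Stim-Off (stimulation withheld) — with tremor severity rated
on the Fahn-Tolosa-Marin scale (FTM-TRS, items 1–9) in each. The package
implements the full analysis chain on such paired data:

- **Volumes** (`read_volume`, `intensity_normalize`, `gaussian_smooth`,
  `resample`, `mirror`): axis-aligned NIfTI maps with explicit masks,
  parenchyma-mean intensity normalization, separable Gaussian smoothing,
  block down-sampling, and rigid hemisphere mirroring about x = 0.
- **Voxel-wise statistics** (`one_sample_perm_t`, `voxelwise_regression`):
  mass-univariate t / slope maps on the per-patient subtraction images
  Δᵢ = Onᵢ − Offᵢ, with sign-flip (or covariate-permutation) max-statistic
  family-wise error correction; all 2ⁿ sign patterns are enumerated exactly
  when feasible (2¹⁴ = 16,384 at n = 14).
- **Spatial surrogate inference** (`build_weights`, `moran_eigenbasis`,
  `msr_surrogates`, `similarity_test`): Moran spectral randomization. Two
  maps are compared by a voxel-wise Spearman rank correlation ρ, and its
  null distribution is built from surrogate maps that preserve the permuted
  map's spatial autocorrelation — surrogates are re-synthesized from the
  eigenvectors of the doubly centred inverse-squared-distance weight matrix
  with sign-randomized loadings, so the Moran spectrum is retained. This is
  the correct null for smooth brain maps, where naive voxel shuffling is
  badly anticonservative.
- **Network alignment and outcome** (`cohort_alignment`,
  `outcome_regression`, `screen_confounds`, `vta_overlap_roi`):
  per-patient alignment of Δᵢ with the template network (Spearman or
  voxel-product sum over the nonzero template), z-scored and regressed
  against relative improvement 100·(TRS_off − TRS_on)/TRS_off with
  stimulation amplitude as covariate; plus the local analysis in the
  ≥3-VTA-overlap stimulation-site ROI.
- **Connectivity GLM** (`split_signed`, `connectivity_glm`,
  `cluster_correct`): per-voxel OLS of Δᵢ on sign-split normative
  connectivity (positive and negative parts as separate predictors) and
  demeaned amplitude, with Freedman–Lane permutation cluster-level FWE
  correction.
- **Covariance pattern** (`ortcva_fit`, `pattern_vs_tmap`): a simplified
  ordinal-trends analysis — PCA of within-subject-centred condition maps
  restricted to five components, combined by the closed-form weights
  maximizing the paired t of projected On−Off differences, with
  subject-level bootstrap voxel stability.
- **Synthetic cohorts** (`cohort_config`, `simulate_cohort`,
  `write_cohort`): a generator with known ground truth —
  offᵢ = baseline + sᵢ·T + ε, onᵢ = offᵢ + aᵢ·c_L·L + gᵢ·c_T·T + ε, and
  improvement% = β₀ + β₁·gᵢ + η — used by the test suite for calibration
  and parameter-recovery checks.
- **Pipeline** (`run_pipeline`): the stages end-to-end with one run seed
  and a JSON summary.

## Worked example

```r
library(tremornet)

sim <- simulate_cohort(cohort_config(), seed = 1)   # 14 synthetic patients
clin <- clinical_table(sim$cohort)
paired_ttest(clin$trs_off, clin$trs_on)

st <- one_sample_perm_t(diff_maps(sim$cohort), n_perm = 2000, seed = 101)
st
similarity_test(resample(st$stat, 8), resample(sim$truth$template_network, 8),
                n_surr = 1000, seed = 404, support = "nonzero_b")
```

prints

```
<tn_paired_ttest> Off 14.34, On 3.74 (mean +/- SEM change -10.61 +/- 0.64); t(13) = 16.542, p = 4.1e-10 (two_sided)
<tn_stat_map> tail=two_sided, df=13, 2,000 permutations; 7968 voxels (0 zero-variance dropped); max |t| = 11.544; min p_fwe = 0.0005
<tn_similarity> Spearman rho = 0.5147; p < 0.001 (1,000 surrogates, side a, greater, 732 voxels)
```

The paired test shows the simulated stimulation effect on tremor scores
(mean −10.6 points On−Off). The permutation t-map localizes consistent
metabolic change (max |t| ≈ 11.5 at the stimulation site); its rank
correlation with the planted template network over the template's nonzero
voxels is ρ ≈ 0.51, larger than every one of 1,000 autocorrelation-matched
surrogate maps (p < 0.001).

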