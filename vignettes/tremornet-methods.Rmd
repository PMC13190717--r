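---
title: "Methods: metabolic network analysis of DBS tremor control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolic network analysis of DBS tremor control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tremornet)
```

# The analysis problem

Thalamic deep brain stimulation suppresses essential tremor, but the
mechanism is debated: is relief driven by the local field around the
electrode, or by engagement of a distributed tremor network? The design
analysed here contrasts two within-subject conditions — FDG-PET and tremor
ratings with stimulation On and Off — and asks three quantitative
questions:

1. Where does stimulation change glucose metabolism consistently across
   patients (mass-univariate inference on the subtraction images
   $\Delta_i = \mathrm{On}_i - \mathrm{Off}_i$)?
2. Does the group-level change map look like the template tremor-treatment
   network more than chance would allow, given that smooth brain maps
   always correlate somewhat (spatially constrained surrogate inference)?
3. Does a patient's individual alignment with the template predict their
   relative tremor improvement, beyond what stimulation amplitude explains
   (amplitude-controlled outcome regression)?

Two further components probe robustness: a voxel-wise linear model of
$\Delta_i$ on sign-split normative connectivity plus demeaned amplitude
(with cluster-level correction), and a multivariate covariance-pattern
analysis cross-validating the univariate map.

# Data model and preprocessing

All maps live on axis-aligned grids: world coordinate of voxel $(i,j,k)$ is
$\mathrm{origin} + (i,j,k) \odot \mathrm{voxelsize}$. Rotated or sheared
NIfTI headers are rejected rather than silently resampled — the analysis
assumes co-registered maps in one template space, and keeping the
coordinate arithmetic affine-free makes every geometric operation exactly
testable.

* **Intensity normalization** divides by the mean over a reference
  (parenchyma) mask, making the reference mean exactly 1. The reference
  mask is accepted separately from the analysis mask, since the two need
  not coincide.
* **Smoothing** is separable Gaussian convolution,
  $\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$ per axis in voxel units,
  computed on the full grid with out-of-mask voxels as zero, then
  re-masked. There is no mask-weighted renormalization; consequently a
  constant map is invariant only away from the zero-padded boundary, and
  the kernel (discretely normalized to sum 1) preserves the global sum of
  interior sources to numerical precision.
* **Down-sampling** is block averaging with an integer voxel-size ratio;
  an output voxel is kept when at least half its source block is in-mask.
* **Mirroring** about the midsagittal plane ($x = 0$) is a rigid
  reflection. A voxel is "left" iff its world $x < 0$; voxels at exactly
  $x = 0$ belong to neither hemisphere. `left_to_right_bilateral` fills
  out-of-mask voxels from their in-mask mirror images (turning a
  left-lateralized template bilateral); `average_to_left` averages
  mirror-pairs onto the left hemisphere. The original analysis used a
  nonlinear warp for this step; the rigid reflection preserves the logic
  of the comparison while remaining exactly invertible
  (bilateral-then-average recovers a left-only map identically).

# Voxel-wise permutation inference

The one-sample t-map of the subtraction images uses a sign-flip null:
under the null of no stimulation effect, $\Delta_i$ and $-\Delta_i$ are
exchangeable, so whole subject maps are multiplied by random signs and the
per-voxel $t = \bar\Delta / (s/\sqrt n)$ recomputed. Family-wise error is
controlled by the max-statistic rule: the FWE p of a voxel is the fraction
of permutations whose extreme statistic over the mask reaches that voxel's
observed value. The identity permutation is always counted, so
$p \ge 1/P$. With $2^n \le$ the permutation budget the full set of $2^n$
sign patterns is enumerated and the result is seed-independent — at the
study size $n = 14$ this is $16{,}384$ patterns, which is cheap. Voxels
with (numerically) zero variance across subjects have no defined t; they
are removed from the inference mask and counted in the result rather than
silently imputed. Voxel-wise covariate regression (tremor severity on the
Stim-Off maps; improvement on the change maps) uses the same max-statistic
machinery with the covariate permuted across subjects.

No cluster enhancement or TFCE is applied at this stage; cluster-level
inference lives in the connectivity model below.

# Moran spectral randomization

The central inferential device is the similarity test between two maps.
The statistic is a voxel-wise Spearman rank correlation (average ranks for
ties), so it is invariant to any strictly monotone transform of either
map. The null must preserve spatial autocorrelation: smooth random fields
correlate substantially by chance, and an i.i.d. voxel shuffle grossly
overstates significance (the test suite demonstrates rejection rates above
15% at nominal 5%).

Surrogates are built from the spatial weight matrix
$w_{ij} = 1/d_{ij}^2$ (inverse squared distance between voxel centres, in
mm, zero diagonal, no distance threshold). Let $H$ be the centering
projector and $V$ the eigenvectors of $HWH$ — the Moran eigenvector maps,
orthonormal and orthogonal to the constant; Moran's
$I$ of eigenvector $k$ is $(n/S_0)\lambda_k$. A source map $x$ with
loadings $r = V^\top(x - \bar x)$ is randomized by flipping loading signs
("singleton" procedure): $x^\ast = \bar x + V(\varepsilon \odot r)$,
$\varepsilon \in \{\pm1\}^{n-1}$. Because $I$ is quadratic in the
loadings, every surrogate has *exactly* the source's Moran's I, and after
the final re-standardization the source mean and SD are matched to
$10^{-10}$. The p-value is the fraction of surrogate correlations at least
as large as observed (ties toward the null); a zero count is reported as
the bound $1/n_\mathrm{surr}$ with an explicit flag, never as $p = 0$.
Both permutation directions are computed and reported: the observed $\rho$
is identical, the p-values generally differ because the surrogate ensemble
depends on which map is randomized.

Practical choices, all recorded in the result object: one-sided "greater"
tail by default (the hypothesis is similarity); unstandardized symmetric
weights; support either the mask intersection (whole-brain comparisons) or
the nonzero voxels of the template side. The dense eigenbasis is quadratic
in memory, so the test enforces a voxel cap (default 10,000) and the
pipeline block-resamples maps to 8 mm for this stage only — the same
resample-first strategy the underlying design uses at 4 mm from scanner
resolution; calibration was verified at ~2,000 support voxels.

# Alignment and clinical models

Per-patient alignment is the Spearman correlation (or, as a robustness
variant, the unnormalized voxel-product sum) between $\Delta_i$ and the
template over the template's exactly-nonzero voxels; no magnitude
threshold is applied. Scores are z-scored across the cohort with the
sample (n−1) SD. The outcome model is OLS of relative improvement
$100(\mathrm{TRS_{off}} - \mathrm{TRS_{on}})/\mathrm{TRS_{off}}$ on the
alignment score, reported with and without stimulation amplitude (per
patient: the mean of both hemispheres' amplitudes) as covariate.
Stimulation parameters (amplitude, pulse width, frequency) are screened by
univariate correlation, variance-inflation factors, and partial t in the
joint model, at $\alpha = 0.05$ with no multiplicity correction across
this small set of clinical models. The local counterpart extracts the mean
$\Delta$FDG (optionally Stim-On uptake, via a flag) in the cohort-level
stimulation-site ROI — voxels covered by at least three patients' VTAs —
z-scores it, and fits the same models. The cohort "average relative
reduction" is reported both as the mean of per-patient percentages and as
the group-mean ratio; the two readings differ slightly and both are
labeled.

# Connectivity GLM and cluster correction

Each patient's signed normative connectivity map is split exactly into
positive and negative parts (opposite-sign voxels zeroed; the parts sum
back to the original). At each voxel, OLS across patients models
$\Delta_i(v) \sim 1 + \mathrm{pos}_i(v) + \mathrm{neg}_i(v) +
(a_i - \bar a)$. A connectivity predictor that is constant across patients
at a voxel is dropped there and recorded in a support mask. One
observation per patient leaves no repeated-measures structure, so this is
a fixed-effects per-voxel OLS rather than a mixed model — an explicit,
labeled deviation.

Cluster-level correction replaces random-field theory with permutation:
suprathreshold voxels ($|t|$ above the two-sided quantile for the
cluster-forming p, default 0.001, at the voxel's residual df) are grouped
by 26-connectivity, and the null of the maximum cluster statistic is built
by Freedman–Lane permutation (fit the reduced model without the tested
predictor, permute its residuals across subjects, add back the reduced
fit, refit). Both extent and mass statistics are available. Extent is the
reported convention, but its integer ties — counted toward the null — make
the permutation p conservative on sparse suprathreshold sets; the
continuous mass statistic is exactly calibrated, and the calibration test
uses it.

# Simplified ordinal-trends covariance analysis

The multivariate cross-check stacks the $2n$ condition maps, removes each
subject's mean map (within-subject centering, so condition contrasts drive
the decomposition), and takes the first five principal components — the
a priori restriction of the original simplified model. In component space
the On−Off difference coordinates $d_i$ are combined with weights
$w \propto S_d^{-1}\bar d$ (sample covariance and mean of $d$), the
closed-form maximizer of the paired t statistic of projected differences
over unit-norm directions in that subspace. The voxel pattern
$V_5 w$ is normalized to unit norm and sign-fixed so the mean On−Off
expression difference is positive; subject expressions are plain
projections of the original maps. Ordinal violations count subjects whose
On expression does not exceed their Off expression. Voxel stability comes
from bootstrap resampling of subjects (pairs, preserving the
within-subject design; 100 iterations by default), each refit sign-aligned
to the point estimate, giving $z = \mathrm{weight}/\mathrm{SD_{boot}}$. A
singular difference covariance (possible under bootstrap duplication)
falls back to a ridge of $10^{-8}\,\mathrm{tr}(S_d)$ and is flagged. The
reference implementation's Monte-Carlo significance of the ordinal trend
itself is not reproduced; the pattern is validated spatially, against the
univariate t-map, through the MSR similarity test in both directions.

# The synthetic cohort generator

Because individual patient data are not redistributable, the package ships
a generator whose defaults emulate the study conditions and whose ground
truth enables recovery testing. Per patient $i$ on a 24×28×24 grid at 4 mm
(≈ 8,000 in-mask voxels in a superellipsoid "parenchyma"):

$$\mathrm{off}_i = 1 + s_i T + \varepsilon,\qquad
\mathrm{on}_i = \mathrm{off}_i + a_i c_L L + g_i c_T T + \varepsilon$$

with $T$ the hub template (bilateral positive sensorimotor and cerebellar
hubs, negative frontal and occipital hubs, smoothed at 8 mm), $L$ a
smoothed bilateral kernel at the thalamic stimulation locus, and
$\varepsilon$ Gaussian random fields smoothed to 8 mm FWHM and scaled to
3% of the normalized uptake — a realistic regional noise level for
intensity-normalized FDG. Clinical coupling:
$\mathrm{TRS_{off}} = 15 + 3 s_i + \eta$ and
$\mathrm{improvement\%} = 60 + 10\,g_i + \eta'$ with
$g_i \sim N(1.5, 1)$ and $\eta' \sim N(0, 8)$, then
$\mathrm{TRS_{on}} = \mathrm{TRS_{off}}(1 - \mathrm{improvement}/100)$
clipped at zero. The positive mean gain matters: it gives the consistent
group-level network engagement that the one-sample t-map analysis
presupposes, while producing a mean relative reduction near 75% with a
range of roughly 33–100% and amplitude-adjusted outcome R² values in the
0.4–0.6 band — the regime the published cohort reports. Amplitudes are
uniform on 1.5–4.5 mA (a config value, not a claim about any cohort);
VTAs are spheres of radius $2 + 0.8a_i$ mm with 1.5 mm centre jitter;
connectivity maps are $T$ plus patient-level smooth noise. Tremor scores
stay continuous by default (rounding is a flag) since all downstream
statistics are continuous.

Per-patient randomness uses the substream seed `seed + patient_index`
(recorded in the ground truth). A consequence worth knowing: cohorts at
adjacent seeds share patient substreams, so replicate-cohort studies
should stride their seeds (the test suite uses multiples of 1,000).

What the generator does **not** emulate: PET count statistics, scanner
point-spread, attenuation, nonlinear anatomy, or the covariance structure
of a real connectome beyond "template + smooth noise". Passing tests
therefore certify the statistical machinery — calibration of the surrogate
and permutation nulls, unbiased recovery of planted effects, exact
structural identities — not performance on real scanner data.

# Numerical choices and edge cases

* Zero-variance voxels: excluded from inference, counted, never imputed.
* Degenerate normalization (reference mean ≈ 0 in relative terms),
  constant maps in correlation or Moran statistics, empty ROIs,
  rank-deficient designs, and identical-condition covariance fits raise
  typed errors rather than producing NaN maps.
* Surrogate p floor $1/n_\mathrm{surr}$ with an upper-bound flag; FWE p
  floor $1/P$ via the identity permutation.
* The paired t, z-scoring, sign-split reconstruction,
  normalize-twice, and mirror-composition identities hold at $10^{-10}$
  or better; condition-swap antisymmetry of the covariance pattern is
  exact in exact arithmetic and holds to ~$10^{-7}$ numerically (the
  reordered stack changes the SVD round-off path).
* Problem sizes used by the shipped checks: similarity calibration on
  2,000-voxel supports with 500 surrogates and 200 replicates; sign-flip
  FWE calibration with full $2^{14}$ enumeration over 500 replicates;
  cluster calibration at ~550 voxels, 100 permutations, 200 replicates;
  recovery over 50 replicate cohorts at n = 14. These sizes were chosen as
  the smallest at which the binomial error bands are meaningfully tight.

# Known limitations

Rigid (not nonlinear) mirroring; fixed-effects OLS instead of a mixed
model in the connectivity GLM; permutation instead of random-field-theory
cluster p-values; a simplified covariance-pattern model whose component
combination rule is this package's own definition; axis-aligned grids
only. Each deviation is tagged in the corresponding result objects and in
the pipeline summary JSON.
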