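---
title: "Models and methods behind mreatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mreatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mreatlas` is a desk-scale re-creation of a brain magnetic resonance
elastography (MRE) atlas study: it generates digital viscoelastic brain
phantoms, simulates the 50 Hz steady-state shear-wave fields an MRE scanner
would measure, gates the data on octahedral-shear-strain SNR, reconstructs
the complex shear modulus with a subzone-based nonlinear inversion,
converts it to shear stiffness and damping ratio, averages subjects into a
template-space atlas, and analyses regional means with a general linear
mixed model. Because no raw in vivo MRE cohort is publicly available,
every quantitative claim the package makes is a *parameter-recovery*
claim: ground truth is prescribed in the phantom, pushed through the full
measurement-and-analysis chain, and compared with what comes out.

## The viscoelastic model and its reporting parameters

Tissue is modelled as a linear isotropic viscoelastic solid with complex
shear modulus $G^* = G' + iG''$ (storage and loss moduli, kPa). Results
are reported in the two derived parameters used throughout the brain MRE
literature:

* shear stiffness $\mu = 2|G^*|^2 / (G' + |G^*|)$ (kPa), equal to
  $\rho c^2$ for shear-wave speed $c$ — waves travel faster in stiffer
  tissue; and
* damping ratio $\xi = G'' / (2G')$ (dimensionless), the relative
  attenuation level — larger values mean more fluid-like tissue.

The package also provides the closed-form inverse (with
$a = \sqrt{1 + 4\xi^2}$: $G' = \mu(1+a)/(2a^2)$, $G'' = 2\xi G'$), which
is what lets phantoms be *prescribed* in the same $(\mu, \xi)$ units the
population tables report. The pair round-trips to $10^{-10}$ relative
over $\mu \in [0.5, 6]$ kPa, $\xi \in [0, 0.45]$, and this is tested.

## Synthetic cohorts: the stated world

`region_spec()` / `phantom_spec()` describe parametric phantom geometry
(ellipsoids, shells, shell sectors inside an ellipsoidal brain mask), and
each region carries a population model: mean and between-subject SD for
$\mu$ and $\xi$, an additive stiffness offset applied to male subjects, an
additive damping-ratio offset applied to female subjects, and an optional
additive study-level shift. Per subject and region, values are drawn from
normals truncated at 3 SD and at the physical bounds ($\mu > 0$,
$0 \le \xi < 0.5$), then converted to $(G', G'')$. Variation is applied on
the $(\mu, \xi)$ scale because that is the scale on which population
dispersion is reported. The registry `mre_reference_values()` holds the
regional population parameters the standard phantoms emulate (global
compartments, six subcortical structures, twelve white-matter tracts,
twelve cortical parcels, with sex-specific columns).

Deliberate idealizations: no cortical folding, no anatomical segmentation
(structures are ellipsoids and shell sectors of realistic *size*, at least
4 voxels across the minor axis and at least 8 mm for thin structures), a
single excitation frequency, no scanner physics (the simulated field *is*
the ideal sampled displacement), and noise that is i.i.d. complex
Gaussian per component. A green recovery test therefore establishes that
the inversion-and-statistics chain recovers prescribed contrasts under
idealized measurement conditions at matched resolution — not that it
reproduces scanner artifacts, partial-volume anatomy, or inter-site
protocol differences. Tissue density is not an observable of the
emulated protocol; the standard soft-tissue value
$\rho = 1000\,\mathrm{kg\,m^{-3}}$ is the default and configurable. The
reported population SDs are treated as between-subject variation; the
generator keeps measurement noise (`snr_target`) as a separate component
rather than guessing a split between the two.

## Wave simulation

The forward model is the heterogeneous time-harmonic equation per
displacement component,
$\rho\,(2\pi f)^2 u + \nabla\!\cdot(G^* \nabla u) = 0$,
the standard curl-dominated approximation in MRE (the pressure term of the
nearly incompressible Navier equations is omitted). It is discretized
with second-order finite differences on the voxel grid (face coefficients
by arithmetic averaging; a harmonic-averaging variant exists specifically
to *break the inverse crime* when testing inversions against simulated
data). Excitation is a Dirichlet displacement applied on the inferior
mask surface — the analog of a vibrating pad under the head. The
effective condition at the skull is genuinely unknown; a first-order
impedance-matched ("absorbing") condition is the default and a rigid
option is provided, per face. Equation rows are scaled by
$1/(\rho\omega^2)$ so the reported relative residual (contract:
$\le 10^{-8}$, typically $10^{-12}$) is meaningful in double precision.
Full-domain systems are solved by BiCGSTAB with incomplete-LU
preconditioning, falling back to a direct sparse LU whenever the
iterative residual misses $10^{-9}$. Units: moduli are converted to Pa
and spacing to metres internally; displacements are in micrometres.

At 50 Hz and 2.6 kPa the shear wavelength is 32.25 mm, about 16 voxels at
2 mm — comfortably resolved, and verified against the plane-wave
dispersion relation and the viscoelastic decay rate.

## Quality control

The octahedral shear strain
$\gamma_{oct} = \tfrac{2}{3}\sqrt{(\epsilon_{11}-\epsilon_{22})^2 + \dots + 6(\epsilon_{12}^2+\epsilon_{23}^2+\epsilon_{13}^2)}$
is computed from the complex strain tensor by mask-aware finite
differences, with moduli taken per voxel. OSS-SNR is the mask-mean
signal strain divided by the expected mask-mean strain of pure noise at
the recorded noise SD; the noise term is propagated through the *same*
strain operator by Monte Carlo (25 replicates, fixed internal seed), so
signal and noise see identical discretization. The gate threshold is 3.
The estimator uses the mask mean (not median); the report records this
choice. Because the noise strain is linear in the noise SD,
`calibrate_noise_sd()` can set noise to hit any target OSS-SNR exactly in
expectation — recovery cohorts use OSS-SNR $\approx 5$.

## Inversion

Two routes, deliberately kept separate so one can check the other:

* `direct_inversion()` — algebraic Helmholtz inversion,
  $G^* = -\rho\omega^2 \sum_c u_c \overline{\nabla^2 u_c} / \sum_c |\nabla^2 u_c|^2$,
  followed by Gaussian smoothing. Fast, amplitude-invariant, exact for
  noiseless plane waves, badly noise-sensitive. Used as an oracle and
  baseline, never as the pipeline's estimator.
* `subzone_nli()` — the iterative subzone-based nonlinear inversion. The
  mask is tiled with overlapping cubic subzones (edge 19.6 mm, the
  standardized brain value); each subzone solves the local forward model
  with measured-displacement Dirichlet boundaries and updates nodal
  $(G', G'')$ by adjoint-gradient descent under a log parameterization
  (positivity by construction); overlapping estimates are blended with
  separable hat weights; the global update is low-pass filtered; the loop
  repeats until the global data misfit stops decreasing.

Numerical choices that mattered, all benchmarked on recovery phantoms and
chosen once:

* **Two-stage subzone optimization.** A 2-parameter multiplicative
  (homogeneous-scale) fit runs before nodal refinement. Pure nodal
  gradient descent moves so slowly that results anchor to the initial
  guess; the scalar stage removes that anchor in 2-3 evaluations.
* **Blockwise Barzilai-Borwein steps.** The loss-modulus block has a much
  smaller curvature scale than the storage block; separate step lengths
  let $G''$ converge at its own rate.
* **25% subzone overlap** (not the minimal 10%): below 25% the
  pallidum-analog (a 15-17 mm structure with +34% contrast) recovered 8-12%
  low; at 25% it recovers within 4-6%.
* **State filtering.** The 1-voxel Gaussian filter is applied to the
  accumulated property volume each pass. Filtering only the update
  preserves a little more stiffness contrast but biases the damping
  ratio, because $\mu$ and $\xi$ stay consistent only when $G'$ and
  $G''$ diffuse identically.
* **Initial guess** $\mu_0 = 3$ kPa, $\xi_0 = 0.2$ (mid-range of healthy
  brain values); convergence tolerance $10^{-3}$ on the relative
  objective decrease with early stop after two consecutive rejected
  (uphill) passes; the accepted objective trace is non-increasing by
  construction.

The local forward model shares its discretization with the simulator — an
inverse crime, acknowledged; the harmonic-averaging simulation variant
exists to break it in robustness checks. Soft prior regularization
(enforcing homogeneity over anatomically predefined regions) is
deliberately *not* implemented, matching the analysis this package
emulates, which evaluated many regions never validated for that prior.
Known limitation: structures much smaller than half the subzone edge
recover attenuated contrast (tested: a 6 mm sphere is biased more than a
20 mm one), and damping-ratio contrasts converge more slowly than
stiffness contrasts, leaving a few-percent attenuation at desk-scale
iteration budgets.

## Atlas construction

Registration machinery is not this package's contribution, so spatial
normalization is affine-only with an import hook for externally computed
transforms (4x4 world-space text matrices; NIfTI sform, RAS+
convention). `estimate_affine()` maximizes 32-bin normalized mutual
information with a centre-of-mass initialization, a rigid stage, then a
full 12-parameter stage (Nelder-Mead); hitting the search-box boundary is
an error, not a silent clamp. `resample_to_template()` composes the whole
transform chain into one matrix and interpolates exactly once
(trilinearly), re-binarizing the resampled mask at 0.5. The template grid
is fixed at 91 x 109 x 91 voxels, 2 mm isotropic. `build_atlas()`
averages voxelwise over the subjects whose mask covers each voxel, and
emits the voxelwise SD and the coverage count; both subject-coverage and
template-intersection modes are provided because the original averaging
convention is not documented.

## Regional statistics

For each measure, regional means follow
$y_s = X_s\beta + \varepsilon_s$, $\varepsilon_s \sim N(0, \Sigma)$ with
$\Sigma$ unstructured over regions and subjects independent; fixed
effects are region, sex, sex-by-region, and study. The likelihood uses
each subject's observed subvector (EM), so removed or missing entries do
not discard the subject. Marginal means use equal weights over sex and
study levels ("modified population marginal means").

Inference is by Wald contrasts with a Hotelling-Lawley scaling:
$F = W(\nu - q + 1)/(\nu q)$ on $(q, \nu - q + 1)$ df, where $W$ is the
Wald statistic under the REML-style corrected covariance
($\Sigma \cdot n/\nu$, $\nu = n - \mathrm{rank}$ of the between-subject
design). This choice — instead of a Satterthwaite approximation — is
exact in the balanced complete case: it reproduces $F = t^2$ for two
regions and Hotelling's $T^2$ for the sex-by-region contrast, and its
simulated type-I error at $n = 60$ is 0.051 over 1000 null replicates.
"Box-plot outlier" removal is operationalized as the 1.5 IQR whisker rule
on per-region residuals (about 0.7% of rows under normality, matching the
handful of removals per region the emulated analysis reports), applied
once followed by a single refit. Bonferroni correction uses
$R(R-1)/2$ pairwise region tests and $R$ sex-within-region tests.
Normality is checked per region with the Shapiro-Wilk test.

## Recovery studies and what the acceptance run does

`scripts/acceptance.R` regenerates every recovery target from scratch:
20-subject cohorts on 32^3 grids at 2 mm with between-subject SDs taken
from the population registry and noise at OSS-SNR 5, inverted subject by
subject and summarized as cohort means of eroded-mask region means. The
sex-contrast cohort (30 male + 30 female) prescribes the male/female WM
damping ratios as ground truth with zero between-subject SD on a 24^3
grid without added noise: that target isolates the sex effect, and the
percentage contrast would otherwise be dominated by noise-induced
damping-ratio bias rather than by what it claims to measure. The
inversion is capped at 6-10 global iterations for the run-time budget;
its tolerance typically stops it at 4-6 anyway.

## Known limitations

* Scalar Helmholtz physics: no mode conversion, no pressure wave, no
  anisotropy (white-matter tracts are mechanically isotropic here).
* Inverse crime between simulator and inversion unless the harmonic
  scheme is requested.
* Affine-only registration; dense warps must be imported.
* Damping-ratio contrast attenuation of a few percent at desk-scale
  iteration budgets (see above); very small structures (under ~10 mm)
  recover attenuated stiffness contrast.
* The NIfTI reader/writer covers the single-file NIfTI-1 subset the
  pipeline emits (sform, scalar dtypes), not the full specification.
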