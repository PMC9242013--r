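---
title: "Methods: quasiharmonic barriers, physical-organic descriptors, and delta-learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quasiharmonic barriers, physical-organic descriptors, and delta-learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(deltabarrier)
```

This vignette documents the models behind the package, the defaults
and why they were chosen, what the synthetic generators do and do not
emulate, and the numerical decisions a maintainer would want written
down. It states no empirical result that the test suite does not
itself compute.

## 1. Thermochemistry

Every species enters as a `qm_record`: a geometry (Å), an electronic
energy (Hartree), optionally a solvent-corrected single-point energy,
harmonic wavenumbers (cm⁻¹, negative = imaginary), and optional
Mulliken charges. Units are fixed at ingestion; every conversion runs
through the single constants table `qc_constants`
(1 Hartree = 627.5094740631 kcal/mol, CODATA 2018 elsewhere).

`rrho_thermo()` evaluates ideal-gas rigid-rotor harmonic-oscillator
partition functions at 1 atm and assembles

G_qh = E + ZPE + U_trans + U_rot + U_vib + RT − T·S_qh + RT ln(c·RT/p°),

with E the solvent single point when present, else the gas-phase
energy. The last term converts to a molar standard state
(`standard_state_correction()`; ≈ +1.89 kcal/mol for 1 mol/L at
298.15 K). `activation_barrier()` is the bimolecular difference
G(TS) − G(MA) − G(nucleophile), all three species at the same T and
standard state.

**Quasiharmonic entropy.** Harmonic-oscillator entropies diverge for
the soft modes that dominate TSs of associative reactions. The default
treatment is the damped free-rotor interpolation: each mode
contributes w·S_HO + (1−w)·S_FR with w = 1/(1+(ν₀/ν)⁴) and ν₀ =
100 cm⁻¹ (the common default of the standard post-processing tools);
the free-rotor moment is capped with an averaged molecular moment of
10⁻⁴⁴ kg m². Truhlar-style frequency raising is available
(`qh_scheme = "truhlar"`). The cutoff → 0 limit recovers pure RRHO to
< 10⁻⁶ kcal/mol (tested). Note that far above the cutoff the *relative*
agreement of the per-mode quasiharmonic and harmonic entropies is
limited by the free-rotor leakage (1−w)·S_FR against a per-mode S_HO
that is itself ~10⁻³ cal/(mol K); agreement there is asserted in
absolute terms.

**Defaults chosen where the method leaves them open.** Symmetry
numbers are σ = 1 for every species (the enumerated substrates have no
useful symmetry and the bias cancels substantially in differences);
frequency scaling is 1.0 by default and configurable per level; the
TS's single imaginary mode is excluded from all vibrational sums and a
second imaginary mode is a hard error, surfaced by
`check_role_frequencies()` before any thermochemistry.

## 2. Descriptors

All descriptors are deterministic — no RNG-seeded point sets — so
feature tables are bit-reproducible.

* **PEOE charges** (`peoe_charges()`): Gasteiger–Marsili partial
  equalization with the original electronegativity polynomials, 8
  damped iterations (damping ½ᵏ), H⁺ electronegativity 20.02.
  Hybridization is assigned from heavy-atom connectivity degree.
  Conservation of net charge is exact by construction; values agree
  with an independent reference implementation to 10⁻³ e on carbonyl
  and alcohol test molecules (frozen in the test suite).
* **EState** (`estate_indices()`): Kier–Hall intrinsic states
  ((2/n)²δᵛ + 1)/δ perturbed by Σ(Iᵢ−Iⱼ)/d², d = bonds + 1; hydrogens
  enter only through hydrogen counts. An isolated heavy atom falls
  back to its free-atom intrinsic state with a logged message.
* **Sterimol** (`sterimol()`): L is the maximal vdW extent along the
  attachment axis measured from the attachment atom; B5 the maximal
  perpendicular extent; B1 the minimum over rotations of the projected
  support function, evaluated on a 0.02° scan (the acceptance oracle
  uses an independent 0.1° scan). No +0.40 Å CPK correction is added
  to L.
* **Buried volume** (`percent_buried_volume()`): grid integration
  (0.05 Å pitch) of scaled (×1.17) Bondi spheres inside a 3.5 Å probe
  sphere — community-standard buried-volume conventions.
* **SASA** (`sasa()`): Shrake–Rupley with a deterministic golden-spiral
  point set, 960 points/atom, probe 1.4 Å.
* **Rotation invariance.** Grid and point-set integrals are evaluated
  after rotating coordinates into a canonical molecule-fixed frame
  (eigenvectors of the coordinate covariance, signs fixed by
  atom-index-weighted projections). This makes PBV and SASA exactly
  invariant under rigid motions of the input, which a lab-fixed grid
  cannot achieve; the residual is floating-point noise.
* **vdW radii** are the Bondi set (C = 1.70 Å, so the C⋯C contact sum
  is 3.40 Å and the 90% contact threshold 3.06 Å); covalent radii for
  bond perception are the Cordero values with a 1.2 tolerance factor.
* **Dispersion descriptors** are *not* computed: the published formula
  for the P_int-style descriptor is not available in the main text of
  the source, and inventing one would be worse than omitting it.
  `descriptor_set()` accepts externally supplied per-atom dispersion
  values so archive-derived tables can still carry them.

## 3. Feature tables and preprocessing

`assemble()` builds one row per reaction. Subsets mirror the study
design: `MA` (reactant-only descriptors), `TS`, and `All` = MA ∪ TS ∪
the SQM reaction barrier. The raw SQM barrier is additionally kept as
the delta-learning baseline, unstandardized, so the delta target is
well-defined regardless of feature scaling. Reactions missing any
descriptor are excluded with a logged reason — never imputed, since in
this domain a missing value means a failed calculation.

`standardize()` centers/scales with statistics computed **only** on
the training rows and stores them for reuse; `prune()` drops
zero-variance features, then greedily one member of each pair with
|r| > 0.95, keeping the lexicographically earlier name (deterministic
tie-break). The 0.95 default is deliberately conservative: the 0.7
figure often quoted as a collinearity threshold describes
feature–target correlation commentary, not a pruning rule, so the
threshold is exposed as a parameter instead.

Leakage is made structural rather than conventional: `ft_lock()` locks
a table to its train rows and every train-side routine reads rows
through a guard that raises on locked access; `evaluate_model()`
unlocks explicitly. A property test permutes held-out rows and asserts
unchanged preprocessing parameters.

## 4. Learning harness

Seven regressor families are implemented natively (the environment
provides no counterpart of the usual ML toolkits, and the estimators
are small enough that owning them is cheaper than approximating their
interfaces): exact penalized ridge, k-NN, CART-based random forest and
gradient boosting, kernel SVR (squared ε-insensitive primal solved
with L-BFGS — smooth, so quasi-Newton applies), kernel ridge (closed
form), and Gaussian-process regression with a Matern kernel.

Grids are documented defaults standing in for settings the source does
not publish: ridge α ∈ 10⁻³…10³; k ∈ 1…15; trees {100, 300, 500} ×
depth {3, 5, ∞}; SVR C ∈ 10⁻²…10³, ε ∈ {0.01, 0.1, 0.5}, RBF γ ∈
{scale, 10⁻³…1}; KRR α ∈ 10⁻⁴…10 with RBF or degree-2/3 polynomial
kernels; GPR Matern ν ∈ {1.5, 2.5}. Tuning is grid search by k-fold
(default 5) CV MAE inside the train split. GPR is the exception: per ν
the length scale, signal and noise variances are optimized by marginal
likelihood on the full train set (Nelder-Mead on log-parameters, the
standard GP practice), ν is chosen by marginal likelihood, and the
reported train CV MAE refits the posterior per fold at the chosen
kernel — running the optimizer inside every fold would multiply cost
for no measurable gain at these sizes.

Delta mode fits y − baseline and adds the baseline back at prediction,
so all reported errors are in kcal/mol on the barrier scale. Forward
selection (`select_features()`) is plain greedy SFS with tol = 0.01
kcal/mol and patience 3 — the cheapest member of the sequential
family; floating variants buy little on tables of ~10² features.
Standard errors are SD(|error|)/√n, comparable across sample sizes.
`double_cv()` repeats the whole pipeline over extra splits;
`learning_curve()` and `permutation_importance()` follow the usual
definitions (importance = mean MAE degradation over column shuffles,
per evaluation set). Reports serialize to canonical JSON
(`report_json()`) and identical seeds give byte-identical reports.

## 5. The synthetic world

Real inputs are outputs of electronic-structure programs; the
generators fabricate statistically faithful stand-ins.

`generate_reactions()` enumerates an α,β-unsaturated carbonyl core
with four variable R positions (H, Me, F, Cl, OH, NH₂ templates) and a
nitronate nucleophile, placing the TS with a forming C–C distance of
2.10 Å at the reference level and 2.06 Å at the cheap level (the
reference distance is 0.04 Å longer, matching the direction and
magnitude seen when semi-empirical TSs are compared with DFT). The
"SQM" level adds isotropic coordinate noise (default SD 0.1 Å, chosen
to land full-structure RMSDs in the 0.05–0.3 Å band) and an electronic
barrier bias that is a sparse additive function of substituent size
and electron-withdrawing scores plus N(0, 0.5 kcal/mol) noise. TS mode
sets are built from the reactant modes plus five new low-frequency
intermolecular modes and one planted imaginary mode, so ZPE is nearly
additive and free-energy barriers span the usual DFT range (the
electronic draw is offset for the ~+13 kcal/mol bimolecular entropy
penalty). Everything is written in the same XYZ/log/manifest formats
the parsers read, and a ground-truth sidecar records the planted
quantities.

`generate_feature_table()` draws AR(1)-correlated Gaussian features;
the baseline barrier is uniform on 7.83–42.38 kcal/mol — the printed
span of semi-empirical barriers for this reaction class — and
independent of the features, so the baseline carries information the
features do not; the target is baseline + Σβ·x_active + ε with σ = 0.5
kcal/mol by default, giving an irreducible MAE floor of σ√(2/π) ≈ 0.40
kcal/mol, the regime where the chemical-accuracy question is actually
decided.

**What a green test does and does not establish.** The synthetic world
exercises parsing, thermochemistry, descriptor numerics, leakage
control, and the statistical machinery, and it reproduces the
*structure* of the delta-learning advantage (an informative baseline
plus a sparse smooth correction). It does not certify the headline
accuracies of the real study: those depend on the deposited QM archive
and settings published only in supporting information. Real data enter
through the same manifest interface (Gaussian-style logs are supported
via the parser registry), and the dataset-level comparisons are an
optional archive-driven exercise, not part of the desk-scale suite.

## 6. Numerical choices and degenerate inputs

* Kabsch RMSD uses SVD with reflection correction; nearly collinear
  subsets are solved but flagged. Subsets need ≥ 3 atoms.
* Manifest atom indices are 0-based on disk (explicit interchange
  convention) and converted to R's 1-based indexing at load.
* Log parsers keep the *last* geometry/energy block, matching how
  optimizers append intermediate steps; a frequency count differing
  from 3N−6/3N−5 warns rather than errors (projection conventions
  vary).
* R-group membership for stripped RMSDs is defined by graph traversal
  from each attachment atom with the core as a wall; nucleophile
  membership in a TS is its connected component (the forming bond is
  beyond the covalent threshold). Hydrogens are included in RMSDs by
  default and excludable.
* Zero-variance features reaching `standardize()` are an error by
  design: silent division by ~0 would corrupt every downstream model.
* The barrier is linear in any common shift of the three electronic
  energies with slope −1 (a bimolecular barrier is not invariant under
  such shifts); the test suite pins the exact linear response.

## 7. Known limitations

* No anharmonic corrections, hindered-rotor treatments, tunnelling, or
  rate constants; σ = 1 throughout.
* PEOE parameters cover H, C, N, O, S and halogens — the elements of
  this reaction class; anything else errors by name.
* The native random forest and boosting trees are adequate for the
  table sizes here but not tuned for very wide data.
* The Gaussian-log parser handles the common block layouts, not every
  dialect of every program version; the registry exists precisely so a
  stricter parser can be plugged in without touching downstream code.
* Product-role species are parsed and validated but unused by the
  pipeline.
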