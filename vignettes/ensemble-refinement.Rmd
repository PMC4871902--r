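---
title: "Ensemble refinement of protein complexes from CXMS restraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble refinement of protein complexes from CXMS restraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlensemble)
```

## The model

Chemical cross-linking coupled with mass spectrometry identifies pairs of
residues close enough in space to be bridged by a reagent of known maximum
span. `xlensemble` converts each confident inter-subunit identification
into an upper bound on a Cα–Cα distance and refines the rigid-body
arrangement of two subunits against those bounds. Three reagents are
supported: the amine-reactive BS³ (24 Å between lysines, 19 Å when one end
is the protein N-terminus) and BS²G (20/15 Å), and the carboxylate-reactive
PDH (22 Å between Glu/Asp). When a link was observed with BS²G — alone or
together with BS³ — the tighter BS²G bound applies.

The restraint potential is a square well: zero when the (effective)
distance is within the bound, `k (d − bound)²` beyond it. Both subunits are
internally rigid; the only degrees of freedom are the rotation and
translation of each conformer of the mobile subunit. Internal flexibility
of the subunits is explicitly out of scope.

### Ambiguous ensemble-averaged restraints

A transient or fleeting complex populates several binding modes, so a
cross-link may be formed in a mode other than the stereospecific one. With
the mobile subunit represented by N conformers, every restraint is applied
to the ensemble through the inverse-sixth-power average

$$d_\mathrm{eff} = \Big(\tfrac1m \sum_{i=1}^{m} d_i^{-6}\Big)^{-1/6},
\qquad d_\mathrm{eff} \le \min_i d_i \cdot m^{1/6},$$

where the sum runs over the N conformers and, for a homodimer where the two
chains are isotopically indistinguishable, additionally over the
chain-swapped assignment (m = N or 2N). The steep distance dependence
biases the average towards the closest conformer, so a single conformer
within the bound (with margin `bound (1 − m^{-1/6})`) silences the
restraint — the defining property of an ambiguous distance restraint. The
*mean* (not the sum) is used inside the average; the resulting mild
N-dependence of the satisfaction margin is documented by the inequality
above and covered by tests. A useful consequence of the averaging, asserted
as a property test: adding a conformer at least as close as the current
closest one can never raise a restraint's energy. (Adding a conformer
merely below the *farthest* one can raise `d_eff`; the inverse-sixth mean
is not monotone under that weaker condition.)

### Other energy terms

* **Repulsion.** A soft-sphere penalty `k_rep (r_clash − d)²` over
  fixed–mobile Cα pairs closer than `r_clash` = 4 Å (`k_rep` =
  10 kcal/(mol·Å²)). Conformer–conformer contacts within the ensemble are
  *not* penalized: conformers are alternative states of one subunit and may
  overlap freely. Cα-level spheres are the natural resolution for a
  rigid-body, Cα-driven refinement; both parameters are configurable.
* **C₂ symmetry (homodimers).** The penalty is `k_sym` times the RMSD
  between subunit B and the image of subunit A under the best-fit two-fold
  operation. The best axis has a closed form: writing centered coordinates
  `p, q` and centroid offset `dc`, the residual for a 180° rotation about
  axis `u` is `Σ|p+q|² − uᵀ(4M − n·dc dcᵀ)u` with `M = Σ(pqᵀ+qpᵀ)/2`,
  minimized by the leading eigenvector. A genuine two-fold can absorb any
  displacement perpendicular to its axis (by shifting the axis) but none
  along it, hence the axial-offset term; the closed form is cross-checked
  against a grid search over axes in the tests. The term is exactly zero
  for a perfect C₂ dimer and is an error to request for a heterodimer.
* Covalent terms are vacuous for rigid bodies and are not computed.

### Search protocol

Refinement is Metropolis Monte-Carlo simulated annealing over rigid-body
poses — the protocol's contract is the energy model, the schedule and the
selection rule, not a specific integrator. Defaults:

| parameter | default | meaning |
|---|---|---|
| temperature | 3000 K → 298 K, geometric, 50 stages | Metropolis bath |
| force constant k | 1 → 30 kcal/(mol·Å²), geometric ramp | restraint stiffness |
| translation σ | 5 → 0.2 Å | per-move Gaussian step |
| rotation σ | 30° → 1° | per-move axis-angle step |
| steps/stage | 200 per conformer | stage length |
| quench | 300 downhill-only steps | final polish |
| runs | 512 | independent restarts |

Each run starts from a uniform (Haar) random orientation with the mobile
center of mass on a shell at `R_fixed + R_mobile + 5 Å` — clash-free by
construction. Per-run seeds are `seed + run index`, so batches are
bit-reproducible and independent of run order. Models with every
`d_eff ≤ bound + 0.1 Å` (numerical slack; configurable to 0) and repulsion
≤ 1 kcal/mol are accepted. Unit tests and the ground-truth checks use
shorter schedules (20–30 stages × 50–80 steps) and 64–256 runs; those sizes
are stated with each check and were chosen as the smallest batches that
make the stochastic assertions stable.

### Ensemble-size selection and over-fitting

`scan_ensemble_size()` repeats the batch for N = 1, 2, … and reports the
average violation — mean over restraints within a model, then over accepted
models (the ten lowest-violation models when nothing was accepted; the
aggregation order is fixed here for reproducibility since a single plotted
curve does not determine it). The chosen N is the smallest that satisfies
every restraint. Beyond the minimal N, `detect_overfitting()` flags
conformers whose removal leaves every restraint satisfied — the signature
of an over-fitted ensemble, where surplus conformers scatter without
touching the CXMS energy — and reports each conformer slot's positional
spread. Homodimer scans keep the C₂ term at every N.

## Identification handling

Cross-link tables arrive as TSV with columns `chain_a, res_a, kind_a,
chain_b, res_b, kind_b, n_bs2g, n_bs3, n_pdh, total, best_evalue` (the
machine-readable dialect is this package's definition; extra columns pass
through). Spectrum-level filtering (FDR < 0.05, E < 10⁻³) is the search
engine's job and is assumed done upstream; `filter_identifications()`
applies the peptide-level rules — spectral count ≥ 2 and best E-value
< 10⁻⁸. Records on a homodimer (same protein on both sides) get
`swap_allowed`, since ¹⁴N/¹⁵N labelling cannot distinguish the chains.
Compatibility against a reference structure uses the *inclusive* bound
(`distance ≤ bound`): bounds are stated as maxima.

The ¹⁴N/¹⁵N mixing analytics solve the channel model in closed form: with
light fraction p, intermolecular links distribute LL:LH:HL:HH as
`p² : p(1−p) : (1−p)p : (1−p)²` and intramolecular links as `p : 1−p`
over the pure channels, giving a mixed/pure intensity ratio
`r = f(1−p)/(fp + 1 − f)` for intermolecular fraction f, inverted as
`f = r/((1−p)(1+r))`. The ratio is taken as one mixed channel over its
matching pure channel (LH/LL); the alternative convention
`(LH+HL)/(LL+HH)` gives the same value at p = ½. At the 0.14 assignment
threshold f ≈ 0.246, i.e. about 25% intermolecular contribution.

## Solvent-accessible surface distance

`enumerate_theoretical()` lists all chemistry-eligible inter-subunit pairs
within a cutoff, either by Euclidean distance or by SASD — the shortest
path outside the protein volume, the physically meaningful linker span. The
SASD is a breadth-first shortest path on a grid (default 1 Å, configurable)
whose cells count as solvent when farther than probe (1.4 Å) + heavy-atom
radius (1.7 Å) from every atom; endpoints attach through the single nearest
accessible cell. Because a 6-connected grid path is an L1 path, SASD ≥
Euclidean holds by construction (asserted as a property test); the same L1
geometry overestimates free-space distances by up to √3, so SASD values are
conservative upper estimates at the default connectivity.

## What the synthetic generator emulates — and what it does not

`make_subunit()` builds ideal Cα traces (3.8 Å virtual bonds): a
deterministic α-helix or a compact self-avoiding walk ("globule").
`plant_poses_and_links()` places k clash-free poses of the mobile subunit
in contact with the fixed one and samples lysine–lysine links satisfied
with ≥ 2 Å margin in their own pose; links prefer distinct anchor residues
on both subunits (affinely independent restraints) and near-bound
distances, which are the informative ones. With `exclusive = TRUE` every
link violates its bound by ≥ 10 Å in every other pose, *and* each pose pair
carries a geometric certificate of joint unsatisfiability — one link from
each pose whose fixed anchors are farther apart than `2·bound` plus the
rigid mobile-anchor separation, so no single conformer can cover both
poses (exclusivity between planted poses alone does not rule out an
intermediate third pose; the certificate does). Homodimer systems are exact
two-fold images with `swap_allowed` records. The margins (2 Å
satisfiability, 10 Å exclusivity) keep stochastic search from blurring the
ground truth.

The generator emulates the geometry of the problem, not the biology or the
mass spectrometry: no side chains, no sequence realism, no false
identifications, no missing data, and cross-links are planted under exact
Cα bounds rather than real linker conformational preferences. Passing the
ground-truth tests therefore demonstrates that the search and selection
machinery recovers known answers under the stated noise-free conditions; it
does not by itself validate performance on experimental data with
mis-assigned or sparse links.

Problem sizes used by the ground-truth checks: pose recovery uses a
120-residue fixed and 50-residue mobile globule with 10 links and 256 runs
(the bound-to-radius ratio then resembles real complexes; with far smaller
toys the feasible pose set is genuinely wide and recovery is not a fair
target). Ensemble-size recovery (K = 1, 2, 3) uses a 100-residue helical
fixed subunit — an elongated scaffold provides the anchor separations the
exclusivity certificate needs — with a 10-residue mobile helix, BS²G
bounds, 4 links per pose and 64 runs per N.

## Analysis outputs

* **Probability maps** deposit a Gaussian kernel (σ = 2 Å, truncated at 4σ
  so ≥ 99.8% of the mass is kept) at every mobile Cα across accepted
  models, equal weights per model (a `weights` hook exists; reweighting
  schemes are deliberately not chosen for the user), normalized to max 1
  and exported as CCP4/MRC mode-2 volumes. Maps are thresholded as
  fractions of the maximum.
* **Spherical projections** express each conformer's center of mass in the
  fixed subunit's principal-axis frame (axes by decreasing Cα variance,
  signs fixed by the third moment — falling back to the largest component
  when the moment is degenerate — right-handed, z = first axis), giving the
  (θ, φ, r) plots in which distinct binding modes separate; the frame
  convention is fixed so plots are reproducible across runs.
* **Clustering** is DBSCAN on center-of-mass coordinates (ε = 8 Å,
  minimum 3 points; both configurable). DBSCAN needs no preset cluster
  count and leaves stragglers as noise (cluster 0), which suits
  encounter-mode discovery. Each cluster is then assigned the restraints
  its members satisfy at the single-conformer level, reproducing the
  per-mode cross-link bookkeeping.

## Numerical choices and degenerate inputs

* Rotations are stored as unit quaternions (re-normalized on construction),
  so long move chains cannot drift off the rotation group; matrices are
  derived on demand.
* Square-well boundaries are inclusive; the well is continuous at the bound
  with a C¹ kink only there.
* Superposition is Kabsch via SVD with the determinant sign fixed, so
  reflections are never returned; fewer than 3 common residues is an error.
* Backbone-heavy-atom RMSD (N, CA, C, O) is used when those atoms are
  present; otherwise the computation downgrades to Cα-only with a message.
  RMSD between complexes is computed over the common residue set.
* Alternate locations keep altloc A; waters/heteroatoms are ignored;
  insertion codes are rejected rather than silently renumbered.
* A restraint distance of exactly zero would make the inverse-sixth average
  singular; distances must be positive and non-finite energies abort a run
  with a diagnostic.

## Known limitations

* Subunit flexibility is not modelled; all conformers are rigid copies.
* The SASD grid path uses 6-connectivity (an upper estimate); finer grids
  or wider connectivity trade accuracy for time.
* The C₂ term is one admissible realization of a symmetry restraint; other
  software may weight the operator differently.
* Batch refinement is single-threaded; wall-clock scales linearly in runs,
  stages, steps and conformers.
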