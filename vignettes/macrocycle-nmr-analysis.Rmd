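---
title: "Methods: curating macrocycle ensembles and back-calculating NMR observables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curating macrocycle ensembles and back-calculating NMR observables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macrochameleon)
```

## The problem

Macrocycles beyond the rule-of-five can behave as *molecular
chameleons*: in an apolar medium (chloroform, dielectric constant 4.8)
they bury their polar groups in intramolecular hydrogen bonds (IMHBs)
and NH···&pi; contacts, while in a polar medium (DMSO, 46.7) they expose
them to solvent. Whether a conformational-sampling protocol captures
this switch is judged against solution NMR: amide chemical shifts,
vicinal couplings, and NOE-derived interproton distances.

`macrochameleon` implements the desk-scale half of that workflow. The
expensive engines — force-field conformational searches, explicit-solvent
MD propagation, DFT geometry optimization and GIAO shielding
calculations — stay outside; their *outputs* (multi-model structure
files, trajectories, per-conformer energies, isotropic shielding tables,
NOESY integral tables) are this package's inputs. Everything downstream
of those files is implemented and tested here:

1. ensemble curation (superposition, duplicate elimination with
   degeneracy bookkeeping, energy-window filtering, Boltzmann weighting,
   trajectory subsampling);
2. trajectory descriptors of chameleonicity (IMHB and NH···&pi; series,
   dihedrals, RMSD series, two-state classification);
3. NMR back-calculation (shifts from shieldings, ensemble averaging,
   Karplus couplings, r⁻⁶ effective distances);
4. quantitative NOESY build-up analysis (normalization, initial-rate
   fitting, reference-pair distance calibration);
5. evaluation of predicted against experimental shifts.

## Curation model and parameters

**Superposition.** All RMSDs are least-squares (Kabsch) superpositions:
the covariance of the centered coordinate sets is decomposed by SVD and
the reflection branch is excluded, so the rotation is always proper.
Selections must contain at least three non-collinear atoms; collinear
selections are rejected rather than silently fit.

**Duplicate elimination and degeneracy.** Sampling engines that revisit
the same basin emit near-identical conformers. `deduplicate()` walks the
ensemble in input order, absorbing any conformer within
`rmsd_threshold` (default **0.75 Å**, superposed, heavy atoms only) of
an already-retained representative and incrementing that
representative's *degeneracy index*. The greedy in-order rule is a
deliberate choice: it is deterministic, matches how iterative samplers
deduplicate on the fly, and conserves total degeneracy mass (the sum of
degeneracies always equals the number of input conformations — a tested
invariant). Hydrogens are excluded from the comparison because their
placement is the noisiest part of generated geometries; an `heavy_only
= FALSE` switch restores all-atom comparison.

**Representative selection.** `select_top_degeneracy()` keeps the `n =
10` most-recurrent conformers — degeneracy is a proxy for basin breadth
— breaking ties by lower energy, then input order, so builds are
reproducible. `energy_window_filter()` retains conformers within
`window` (default **10 kcal/mol**) of the minimum-energy conformer
(MEC), which is always retained; the filter is monotone in the window.
`minimum_energy_conformer()` resolves ties to the first conformer in
input order and says so.

**Boltzmann weighting.** Optional population weighting uses
w ∝ exp(−ΔE/RT) with R = 1.98720425×10⁻³ kcal/(mol·K) and a default
T = 300 K (the usual production-run thermostat). The default for shift
averaging is nevertheless the *unweighted* mean (below).

**Trajectory subsampling.** `subsample_every()` keeps frames `stride,
2·stride, …` (tail-aligned), so a 5000-frame trajectory at stride 500
yields exactly 10 conformers — an unbiased selection that favors no
segment of the run.

## Interaction descriptors

* **IMHB**: a frame counts as hydrogen-bonded when the H···acceptor
  distance is inside **1.5–2.5 Å** *and* the donor–H···acceptor angle
  is ≥ **120°**. The window is defined on the H···A distance (the only
  distance for which that range is physical); the angle cutoff is this
  package's addition, to exclude strained near-contacts that no
  spectroscopist would call a bond.
* **NH···&pi;**: distance from the amide nitrogen to the *unweighted
  centroid* of the aromatic ring atoms, flagged inside **2.9–3.6 Å**
  (the shielding-effective range).
* **Dihedrals**: signed, right-handed IUPAC convention in (−180°, 180°],
  validated against an independent vector-algebra oracle and
  `bio3d::torsion.xyz`. The ϕ/ψ atom quadruples of the ring's dipeptide
  fragment are user-declared — atom naming is compound-specific and not
  guessed.
* **RMSD series**: per-frame superposed RMSD against a reference
  geometry (typically the first frame), over a declared selection such
  as the ring heavy atoms.

Trajectories are assumed pre-imaged (solute whole); no minimum-image
arithmetic is applied. All descriptors are invariant under global rigid
motion of every frame — a tested property, not an assumption.

## Two-state classification

Two classifiers are provided under one contract and report per-frame
labels plus populations:

* **RMSD split** (`classify_states()`): deterministic two-means on the
  1-D series, initialized at the min/max, threshold at the midpoint of
  the fitted centers; state 1 is the cluster nearer the reference. A
  two-state call is accepted only if the split explains ≥ 0.8 of the
  series variance. That gate is the package's answer to a real failure
  mode: an optimal two-means split of *any* unimodal sample still
  explains ~0.64 (Gaussian) to 0.75 (uniform) of the variance, and a
  lone outlier can look like a tiny second cluster, so a
  separation-based test misfires on noise. Genuinely switching series
  with well-separated modes approach 1. Below the gate the series is
  declared single-state, populations (1, 0), with a warning.
* **Face signs** (`classify_states_faces()`): fits the mean plane of
  the macrocycle ring per frame (smallest principal direction of the
  centered ring coordinates — the paper-agnostic least-squares choice)
  and takes the sign of the out-of-plane component of two amide N–H
  vectors. Opposite faces ⇒ state 1; same face ⇒ state 2, matching the
  in-plane amide-flip picture of the switch.

On noiseless planted fixtures the two classifiers agree frame-wise
(tested at ≥ 95%).

## NMR observables

Chemical shifts derive from isotropic shieldings as δ = σ_ref − σ.
σ_ref (TMS for ¹H) depends on the level of theory and is a **required
input** with every shielding table — the package refuses to default it.
Ensemble shifts are the per-proton mean over the conformers inside the
energy window; the plain mean is the default because that is what the
reporting convention states, with Boltzmann weighting available as
`mode = "boltzmann"` (and converging to the mean as T → ∞, a tested
limit).

³J couplings use the Karplus form J(θ) = A·cos²θ + B·cosθ + C. The one
shipped coefficient set (A = 6.51, B = −1.76, C = 1.60 Hz, Vuister &
Bax 1993, for backbone HN–Hα) is *configuration, not truth*: any set
can be supplied, but a literature provenance string is mandatory, so a
J value can never silently outrun its parametrization.

NOE-effective distances over fluctuating ensembles use
r_eff = ⟨r⁻⁶⟩^(−1/6), which is dominated by close-approach excursions
and never exceeds the arithmetic mean (a tested convexity property).

## NOESY build-up analysis

Cross-peak intensities are normalized per mixing time as
η(i,j,τ) = I_cross(i,j,τ) / √(I_diag(i,τ)·I_diag(j,τ)). The
single-diagonal alternative I_cross/I_diag(i) is one switch away; since
distances are calibrated against a reference pair measured under the
same convention, convention-dependent constants cancel and the choice
does not propagate into distances.

`fit_buildup()` implements the initial-rate selection rule: among
consecutive windows in sorted mixing-time order, always anchored at the
shortest mixing time, the longest window of ≥ 4 points whose
least-squares line reaches R² ≥ 0.95 defines the build-up rate σ_ij
(its slope). Lines include an intercept by default to absorb baseline
offsets (`zero_intercept = TRUE` disables this). A pair with no
qualifying window is returned as *rejected*, not an error — weak and
spin-diffused peaks are expected casualties, and the CLI exits with a
distinct code when any pair is rejected.

Distances follow r_ij = r_ref·(σ_ref/σ_ij)^(1/6) against a
locked-in-distance reference pair, default geminal protons at
**1.78 Å**. The calibration is scale-invariant in the rates (tested),
which is exactly why the normalization convention is harmless.

## Synthetic fixtures and what they do (and do not) show

Because no real ensembles or spectra ship with the package, every input
class has a seeded generator with a recorded ground truth:

* `build_macrocycle_scaffold()` — an idealized 18-membered ring (1.5 Å
  edges on a circle), amide-like nitrogens at positions 1/7/13 with
  axial N–H hydrogens (1 and 13 up, 7 down), and a coplanar phenyl
  side-chain at position 10. Ring perception on its bond graph returns
  18.
* `simulate_two_state_trajectory()` — an amide-flip analog: state 2
  reflects a chosen substituent through the ring plane. Run lengths are
  drawn multinomially inside an exact per-state frame budget, so planted
  label fractions equal the requested populations (default 70/30) at
  frame resolution; Gaussian jitter (default 0.02 Å) sits on top.
* `plant_contact_events()` — rewrites one atom's position per frame so
  a contact is inside its window in exactly the requested fraction of
  frames (planted hydrogen bonds are made linear so the angle criterion
  cannot interfere with the distance schedule).
* `simulate_buildup_curves()` — inverts the calibration law
  (σ = σ_ref·(r_ref/r)⁶) on a 50–350 ms seven-point mixing-time grid,
  with η flattening beyond a saturation time τ_sat and optional
  multiplicative noise; a geminal reference pair at exactly r_ref is
  always included. The default rate scale (σ_ref = 2×10⁻⁴ /ms) puts
  normalized intensities in the few-percent range typical of small-
  molecule NOESY integrals.
* `simulate_shielding_tables()` — inverts δ = σ_ref − σ.

Each generator hashes its own name into the seed, restores the caller's
RNG state, and is byte-reproducible — tested.

These fixtures are chemically idealized, not force-field minimized.
Passing tests therefore demonstrate that the *computational rules* are
implemented correctly (windows applied as stated, rates and populations
recovered from data that obey the model), **not** that the protocol
resolves real spectra: real trajectories have correlated noise, spin
diffusion bends real build-ups before R² flags them, and real amide
flips move heavy atoms, not just a hydrogen. The two-state fixture's
flip moves only an N–H hydrogen, so RMSD-based state analysis of it
must include hydrogens in the selection; on real trajectories the
default heavy-atom selection is the right one.

## Numerical choices and degenerate inputs

* Superposition rejects collinear selections (second singular value
  < 10⁻⁸ of the first); reflections are never returned.
* Ties everywhere resolve by (criterion, energy, input order); MEC ties
  are logged.
* Missing energies are a typed error in every energy-dependent
  operation — never assumed zero. The one exception is
  `select_top_degeneracy()`, which treats absent energies as equal-rank
  (selection by degeneracy happens before any energy is computed in an
  MCMM-style workflow).
* Dihedrals on collinear triples raise an error naming the frame.
* Build-up windows with zero intensity variance carry no rate and are
  skipped; an unfittable *reference* pair aborts calibration loudly.
* Constant observed shifts make both R² conventions undefined (error),
  while RMSE is always defined.
* TSV dialect is fixed (UTF-8, tab, one header row, `.` decimals) so
  table round-trips are bit-exact, and NOESY tables normalize column
  storage types on construction for the same reason.

## Evaluation metrics

Two "R²" conventions are computed side by side because reporting
practice in this area conflates them: the *identity-line coefficient of
determination* 1 − Σ(obs−pred)²/Σ(obs−mean(obs))², which measures
accuracy against the y = x line and goes negative when predictions do
worse than the observed mean (precisely the regime failed sampling
protocols land in), and the squared Pearson correlation, which is
affine-invariant and only measures association. Published tables that
label negative values "Pearson's R²" are internally inconsistent; this
package reports both, headline first, rather than guessing which was
meant. RMSE is reported in ppm alongside the pair count, pooled over
compounds and protons within each solvent.

## Problem sizes used in the test suite

The shipped tests run the full stack at reduced but non-trivial sizes:
two-state trajectories of 400–5000 frames, 12–40-conformer ensembles
for deduplication oracles, 50-seed Monte Carlo for noisy distance
recovery (median relative error ≤ 5% at 2% multiplicative noise), and
brute-force rotation-grid superposition oracles on 4-point systems.
These sizes were chosen as the smallest at which the statistical checks
are meaningful; all of them are properties of the method, not of any
particular dataset.

## Known limitations

* No relaxation-matrix treatment: the build-up analysis is strictly
  initial-rate (ISPA); spin diffusion is handled only by the R²
  window rule, not corrected.
* Ring perception targets monocycles with pendant rings (the scaffold
  chemistry in scope); heavily fused polycycles may report a ring that
  is not in a minimal SSSR basis.
* The RMSD-split classifier is 1-D and two-state by construction; more
  than two basins require the face-sign route or an external
  clustering.
* Solvent–solute hydrogen-bond inventories over explicit solvent boxes
  are out of scope, except insofar as a declared acceptor atom happens
  to belong to a retained solvent molecule.
* Shieldings, couplings and energies are consumed, never computed; the
  package's predictions are only as good as the upstream theory that
  produced those tables.
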