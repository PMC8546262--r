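---
title: "Estimating stroke-lesion conductivity from transcranial stimulation and EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating stroke-lesion conductivity from transcranial stimulation and EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lesionbem)
```

## The problem

Transcranial electric stimulation (tES) injects a weak current through scalp
electrodes; how much of it reaches a targeted brain region depends on the
conductivities of the tissues in between. In chronic stroke patients the
lesion is a large, electrically atypical inclusion — reported conductivities
span 0.1–1.77 S/m, from brain-like scar tissue to pure cerebrospinal fluid —
and guessing its value wrongly distorts any model-based dose calculation.
`lesionbem` implements a simulation framework for the question: *can the
lesion's conductivity be estimated in vivo by driving a small current
through the head and comparing recorded scalp potentials to a
patient-specific volume-conduction model?* And if so, how does the
achievable accuracy depend on lesion size, depth, conductivity contrast,
electrode count, and electrode-coregistration error?

All geometry in this package is synthetic and spherical; no patient data are
used or required. That choice is what makes the package's tests and studies
exactly reproducible, and it is also the main caveat when transferring
numbers to real heads (see *Limitations*).

## The volume conductor and its solver

A head model is an ordered set of nested closed triangle surfaces — scalp,
skull, CSF, brain, and optionally a spherical lesion — each carrying the
conductivity of the tissue it encloses:

| compartment | default radius (mm) | conductivity (S/m) |
|---|---|---|
| scalp | 92 | 0.414 |
| skull | 86 | 0.016 |
| CSF   | 80 | 1.71 |
| brain | 78 | 0.37 |
| lesion | configurable | 0.74 / 1.23 / 1.71 |

The exterior is insulating. A stimulation electrode pair is modelled as a
balanced pair of current monopoles (±0.1 mA) inset 3 mm beneath the scalp
along the local normal. Under the quasi-static approximation the potential
on the compartment boundaries satisfies a second-kind boundary integral
equation with the double-layer (solid-angle) kernel, weighted by the
conductivity jump across each surface.

The solver is a linear-collocation boundary element method with vertex
unknowns. Element integrals are evaluated in closed form: the solid angle of
each triangle via the van Oosterom–Strackee formula and the first moments of
the kernel via analytic edge (logarithm) integrals, so no numerical
quadrature enters the operator. Two details matter for accuracy on
polyhedral meshes:

* **Vertex jump coefficient.** At a mesh vertex the potential jump involves
  the interior solid angle of the polyhedron there, not the smooth-surface
  value 2π. The package computes it from the row sums of the vertex's own
  surface block, which is exactly the quantity the analytic integrals
  already provide. A by-product is that the assembled operator annihilates
  constant potentials to machine precision — a built-in consistency check
  (the constant vector is the physical gauge freedom of an insulated
  conductor).
* **Deflation.** That same constant null space makes the raw system
  singular. An area-weighted rank-one deflation term renders it uniquely
  solvable; solutions are reported in the gauge where the area-weighted mean
  potential is zero and are then re-referenced to the nasion electrode, as a
  recording would be.

Mesh resolution follows the study design: each compartment is an icosphere
with the smallest subdivision giving at least the requested number of
elements (a request of 3,200 yields 5,120 — icospheres only admit
20·4^k triangles), and the scalp and skull meshes are refined near the
stimulation electrodes (red–green subdivision within a 25 mm capture radius,
new vertices re-projected onto the analytic sphere) because the potential
varies steeply within a few millimetres of the monopoles.

## Validation oracle

There is a closed-form solution for a point-current source inside concentric
conducting spherical shells: a Legendre series whose radial coefficients
propagate through the layers by continuity of potential and normal current,
with an insulating outer boundary. `layered_sphere_potential()` implements
it with per-layer normalized radial basis functions (numerically stable to
arbitrary degree) and an explicit tail-convergence check. The spherically
symmetric n = 0 mode of a *single* monopole has no steady state in an
insulated conductor; it cancels exactly between the two poles of a balanced
pair, so the series starts at n = 1 and pair fields are superpositions of
two calls.

The forward-solver acceptance gate compares BEM scalp potentials for an
antipodal pair at 3 mm depth against this oracle at the 126 recording
electrodes. At the study resolution (requested 3,200 elements/surface, one
local refinement pass) the solver achieves a relative difference measure
(RDM) of about 0.008 and a magnitude ratio within 2% — comfortably inside
the RDM ≤ 0.05, |ln MAG| ≤ 0.1 gate — and a second refinement pass strictly
reduces the scalp-wide RDM (measured on a seeded uniform sample of the
scalp, which, unlike the top-heavy electrode montage, samples the refined
equatorial caps fairly). Because the error is already this small without any
isolated-skull treatment, no isolated-problem approach is implemented; the
sources sit in the scalp, outside the resistive skull, which is the benign
case for this formulation.

## Montage search, perturbation, estimation

**Optimal pair.** For each lesion, all 190 unordered pairs of the 20
outer-edge 10/5 electrodes are scored by the RMSD between the scalp
potentials of the lesioned and lesion-free models at the remaining 126
electrodes, and the argmax is selected (lexicographic tie-break). By
linearity, the search needs only 20 single-monopole solves per model against
one factorization; pair fields are column differences. The potential
differences are **average-referenced** before scoring. This matters: scored
against the nasion reference, the search systematically favours pairs that
stimulate next to the reference electrode, because the lesion's effect on
the nasion potential itself is then broadcast to every channel as a
common-mode term — an artifact of the reference location, not a usable
sensitivity, and precisely the component that coregistration error corrupts.
The average-referenced score is reference-independent. The default
`refine = "winner"` policy scores the search on unrefined meshes and
re-solves only the winning pair on refined meshes; refining all 190
candidate pairs (`refine = "full"`) is available but costs two orders of
magnitude more and, on sphere heads, does not change the winner in our
checks (the refined scores of the top candidates preserve the coarse
ranking).

**Coregistration error.** Electrode mis-placement is modelled as a rigid
rotation of the whole measurement montage about a head axis through the
head center: "coronal" about x (left–right), "sagittal" about y
(anterior–posterior), in a frame with x = right, y = anterior, z = superior
and Cz at the vertex. Angles span 0–5°; on the default head a 5° rotation
displaces electrodes by about 8 mm on average. Rotated electrodes are *not*
re-projected onto the scalp — the recording step projects them onto the
nearest scalp triangle for interpolation (tolerating up to 10 mm off-surface)
— and the stimulation monopoles stay at their true positions: only the
*measurement* montage is mis-coregistered. Electrode subsets of 8 (the fixed
near-Cz set: Cz, FCz, CPz, C1, C2, FFC1h, Fz, AFF1), 16, 32, 64 (nested
farthest-point samples seeded at Cz) or all 128 electrodes can be recorded,
always with a nasion reference.

**Estimator.** The "recorded" potentials ψ are the forward solution of the
true model sampled at the rotated subset; the model potentials φ(σ) are
sampled at the nominal positions. The estimate minimises ‖ψ − φ(σ)‖² by
damped Gauss–Newton on the scalar σ: central finite differences with a 1%
relative step, step halving until the residual decreases, stopping when the
relative change between successive iterates falls below 0.1%, ten random
starts drawn uniformly in [0.033, 2] S/m from a caller-supplied seed, guard
bounds [0.01, 4] S/m (hitting them marks the start non-converged), and the
minimal-residual converged start reported. For a single scalar parameter
the damped Gauss–Newton step is the natural update rule, and the package
verifies it independently against a brute-force grid search of the same
residual (agreement within 0.5%) plus a unimodality check of the residual
profile.

**Woodbury re-solves.** The system matrix depends on the lesion conductivity
only through its lesion-surface columns, affinely. One factorization of the
deflated base matrix plus a low-rank correction therefore yields φ(σ) at any
σ for the cost of a small dense solve; `lesion_forward_cache()` bundles this
and serves every ψ and φ(σ) for a given lesion/pair geometry. This is what
makes the multi-start estimator and the full study sweeps tractable: one
assembly per lesion instead of one per residual evaluation.

## The synthetic study and what it can(not) show

`run_study()` reproduces the sweep structure on sphere heads: a battery of
spherical lesions with radii 2.9, 14.2, 23.0 and 27.3 mm (about 0.1, 12, 51
and 85 ml, spanning the clinically reported volume range) at a fixed
left-temporal center 49 mm from the head center (depth ≈ 43 mm to the
nearest scalp node), three lesion conductivities, both rotation axes with
angles 0/0.1/0.5/1/5°, and all five subset sizes. Zero rotation is evaluated
once and shared across axes. Non-converged estimations are flagged, excluded
from the mean ± sd summaries of `summarize_study()` (sample sd; defined as 0
for single-observation groups) and counted separately.

Because ψ is generated by the same discretized model the estimator uses
(deliberately: the study isolates the effect of electrode error, not model
error), recovery at 0° rotation is exact to numerical precision for every
lesion, conductivity and subset. Under rotation the study reproduces, on a
single synthetic geometry, several qualitative findings: errors grow
monotonically with the rotation angle; above 1° the estimate is essentially
never within 5% of the truth (at 5° it usually fails to converge at all);
lesions below ~1 ml are unestimable under realistic perturbations (no start
converges); and the lesion's scalp-potential footprint (optimal-pair RMSD)
grows monotonically with lesion volume and with the lesion-brain
conductivity contrast.

The headline robustness claim — relative error below 5% at 0.1° rotation for
lesions larger than 50 ml — does **not** reproduce under these matched
synthetic conditions, and the corresponding acceptance check is implemented
faithfully and fails. The reason is instructive. For the ~51 ml left-temporal
lesion the sensitivity scores of the top candidate pairs are a near-tie
(within ~3%): several pairs combining the electrode over the lesion (TTP7h)
with a contralateral frontal or temporal electrode are equally informative
about σ. The argmax selection lands on the frontal combination (Fp2–TTP7h),
and frontal montages are rotation-fragile: the measurement electrodes
adjacent to the frontal stimulation site — and the nasion reference itself —
sit in the steep-gradient region and are carried *across* the isopotential
lines by a coronal rotation, so a 0.1° rotation (0.16 mm mean displacement)
perturbs the recording by more than the entire lesion signal and biases the
estimate by 17–36%. The near-tied temporal pair (T8–TTP7h), lying close to
the coronal rotation axis, keeps the error below 2% in identical conditions.
The montage-selection criterion (maximum lesion-effect RMSD) is blind to
this fragility. The underlying mechanism — rotation robustness depends on
whether the most-affected electrodes move tangent to or across the
isopotential lines — applies to real patient geometries as well; which
regime the argmax pair falls into is geometry-specific, and on this
symmetric synthetic head it falls into the fragile one.

A related between-subject tendency — relative errors under 0.5° rotation
smaller at high lesion conductivity (1.71 S/m) than at low (0.74 S/m) — is
regime-dependent in our conditions. In the large-error regime of the
fragile frontal montage the ordering holds (mean over both axes and the
64/128-electrode subsets: ~0.90 vs ~1.72), essentially because relative
errors are normalized by a larger σ. In the moderate-error regime of a
temporal montage the ordering *reverses* by roughly 20–30% per cell: the
scalp-potential sensitivity dφ/dσ of an inclusion saturates as its
conductivity rises (for a sphere the response scales like
(σ_l − σ_b)/(σ_l + 2σ_b), with derivative decaying as (σ_l + 2σ_b)^−2), so
the same electrode-position perturbation maps to a larger conductivity
deviation at higher σ.

## Numerical choices and degenerate inputs

* Problem sizes: the forward-solver validation runs at the full study
  resolution (5,120 elements/surface plus refinement, ~11k unknowns); all
  estimation studies and tests run on 1,280-element meshes (~3.5k unknowns),
  where the estimator's behaviour — not forward accuracy — is under test.
* The montage search declares itself degenerate (error, not a silent result)
  when no pair's RMSD exceeds 10⁻¹² of the scalp-potential RMS scale, which
  happens exactly when the lesion has zero conductivity contrast.
* A lesion surface with σ_lesion = σ_brain changes recorded potentials by
  < 10⁻¹⁴ relative RMS (the operator contribution carries a zero jump
  weight), and the estimator then recovers σ_brain from lesion-free data.
* Interface continuity of the oracle holds to 10⁻⁸ relative when probed at
  ±10 pm; probing at larger offsets measures the genuine one-sided gradient
  jump (a factor ≈ 107 across skull–CSF), not solver error.
* Ties in the pair search are broken lexicographically by (anode, cathode);
  they do not occur on generic geometry.
* Estimator edge cases: a flat objective (zero Jacobian) and exhausted step
  damping both terminate with zero inter-iterate change, i.e. the stopping
  rule; guard-bound hits mark the start non-converged and are never reported
  as estimates.

## Limitations

Spherical shells with a spherical lesion lack cortical folding, skull
inhomogeneity, anisotropy and realistic lesion shape; the electrode table is
the standard 10/5 template, not a digitized cap. The inverse-crime design
(same mesh for ψ and φ) is intentional — it isolates coregistration error —
but means the reported accuracies are upper bounds for real data, where
segmentation and conductivity mis-specification add further error.
Background EEG noise is not modelled: at 0.1 mA stimulation, averaging over
a prolonged stimulation window is assumed to suppress it, and modelling it
is out of scope here. Gray/white matter separation and skull-conductivity estimation
are out of scope.
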