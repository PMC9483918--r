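---
title: "Membrane binding of charged small molecules: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane binding of charged small molecules: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`membindr` analyzes MD trajectories of lipid bilayers with charged
small-molecule solutes. This vignette documents the models the package
implements, the conventions chosen where the field leaves room, and what
the synthetic-data generators do and do not emulate.

```{r setup}
library(membindr)
```

## Data model

A **topology** is a tibble of atoms (name, element, residue, molecule,
partial charge in elementary charges, mass in amu) with named selections
attached as an attribute. Atom ids are **1-based and dense** — the natural
R convention; file formats with 0- or 1-based serials are normalized at the
I/O boundary. A **trajectory** bundles a topology with ordered frames, each
an n×3 coordinate matrix in nm, an **orthorhombic** box (nm) and a time in
ps. Triclinic boxes are rejected with a clear error: planar bilayer
simulations are semi-isotropically coupled and orthorhombic throughout, and
nothing downstream needs the general case. Units are nm / ps / kJ mol⁻¹
everywhere.

The membrane normal is the z axis by convention. Centering on a reference
group (typically all lipid atoms) first unwraps the group across periodic
boundaries — a circular-mean anchor followed by minimum-image unwrapping —
because a bilayer split by wrapping otherwise yields a meaningless center
of mass. Centering is idempotent to machine precision. The center of mass
is mass-weighted; a geometric-center mode would shift profiles slightly and
is deliberately not offered to keep one convention.

Supported inputs are GRO, PDB (via bio3d) and the package's own JSON
fixture format (atom table, per-frame position blocks, box, optional
ground-truth record). Compressed binary trajectory formats (XTC/TRR/DCD)
have no reader in the package's dependency set and are out of scope; the
loader dispatches on extension, so adding one later is additive.

## Order parameters

For each labelled set of C–H bonds (e.g. the head-group α and β segments),

$$S_\mathrm{CH} = \left\langle \frac{3\cos^2\theta - 1}{2} \right\rangle,$$

with θ the angle between the C–H bond vector and the membrane normal and
the average over all frames, molecules and equivalent hydrogens under the
label. Note the **squared** cosine: this is the second Legendre polynomial,
the standard NMR order-parameter definition, bounded to [−0.5, 1]. (The
unsquared form sometimes seen in print cannot reproduce physical values and
is not what any analysis code computes.) θ is measured against the fixed z
axis, not an instantaneous local normal — appropriate for planar bilayers
and consistent with the standard analysis codes.

Equivalent hydrogens are pooled into one S per label because the observable
of interest is the per-segment response; `per_hydrogen = TRUE` splits them,
since R/S prochiral hydrogens can genuinely differ.

**Uncertainty** is estimated by block averaging over 5 equal time blocks
(stderr = sd(block means)/√5). Five blocks is the package-wide convention;
whether error bars should run over molecules or time blocks is a judgment
call, and block-over-time was chosen because consecutive frames are the
dominant source of correlation. ΔS against a solute-free reference
propagates uncertainties in quadrature.

## Binding criterion and its selection

A solute molecule is **bound** when at least a fraction *f* of its heavy
atoms lies within *d* of any lipid atom (minimum-image, inclusive `<=`).
Heavy atoms only on the solute side: hydrogens ride on heavy atoms and
would double-count; the lipid side uses all atoms. The (d, f) pair is not
asserted a priori: `criterion_scan()` computes the time-averaged bound
count over a grid (default 0.1–1.0 nm × 0.1–1.0, ten points each — a
configurable default, not a claim about any particular study), and
`select_criterion()` picks the node where the magnitude of the
finite-difference gradient is minimal — the point where the answer depends
least on the arbitrary choice. Both axes are normalized by their grid span
so nm and fractions are commensurate; central differences in the interior,
one-sided at the edges; ties broken deterministically (smallest cutoff,
then largest fraction); a constant-gradient surface returns the tie-break
node with a `degenerate` flag and a warning.

The scan surface is non-decreasing in *d* and non-increasing in *f* by
construction, and both invariants are asserted on every scan.

`equilibration_split()` finds the smallest index t\* such that the two
halves of the remaining series agree within twice their pooled block
standard error, declaring non-convergence if none exists before 50% of the
series. With the 5-block default this accepts smooth relaxations somewhat
early, because a ramp inflates the block standard error; raising `n_blocks`
(e.g. 20) sharpens the split toward the true plateau onset. The default
keeps the package-wide block convention; the parameter is exposed.

Two normalizations turn bound counts into isotherm axes:
`bound_per_lipid()` (time-averaged bound count / n_lipids) and
`bulk_concentration()` = ⟨n_free⟩ / n_waters × 55,500 mM, the pure-water
molarity convention. The count-ratio definition is robust in small boxes
where a density-profile bulk plateau is poorly sampled.

## Density profiles and PMF

`density_profile()` centers every frame on the lipid center of mass,
histograms z positions with bin edges anchored at integer multiples of the
bin width (default 1/30 nm = 1/3 Å), and normalizes by frames × bin volume
with the box cross-section averaged over frames (it fluctuates under
semi-isotropic pressure coupling). Anchoring at z = 0 makes leaflet
symmetrization (`symmetrize_profile()`) exact. Count conservation —
Σ ρ Δv × frames = atoms × frames — holds to machine precision and is
tested.

`pmf_from_density()` applies Boltzmann inversion,
PMF(z) = −k_B T ln(ρ(z)/ρ_ref). Two numerical conventions:

* ρ_ref is the **geometric mean** of positive densities in the reference
  region, which makes the PMF average exactly zero over the reference
  bins (an arithmetic mean would not). The default reference region is
  the outermost 20% of sampled z on each side — bulk water. Absolute PMF
  values therefore carry an arbitrary additive constant; differences
  (barrier heights, well depths) do not.
* Zero-density bins give an **NA** PMF, never ±Inf or a clipped large
  value: a profile simply ends where sampling ends.

## Contacts

Two atoms are in contact when their minimum-image distance is **strictly**
smaller than 0.325 nm (the boundary case is pinned by a test). Contacts are
counted per atom pair — one solute atom touching three lipid atoms is three
contacts — which is the counting that makes multi-atom solutes land an
order of magnitude above monoatomic ions. The denominator is bound
molecule-frames, the only reading under which "contacts per bound molecule"
is a well-defined time average; when nothing is ever bound the result is an
explicit "no bound molecules" record with NA statistics, not zeros.
Phosphate oxygens are identified by a configurable atom-name list
(defaults: the four phosphate oxygens of PC lipids). The implementation
uses a periodic cell-grid neighbor search; tests require exact integer
agreement with an all-pairs brute-force oracle.

## Permeation

Marker z series (e.g. the amine nitrogen of an anesthetic, the phosphorus
of TPP) are classified into three regions: bulk above (z > +h), membrane
(|z| ≤ h), bulk below (z < −h). An event requires the sequence
bulk → membrane → opposite bulk; returning to the entry-side bulk resets
the state, and events still in progress at the end of the trajectory are
not counted. Successive-frame displacements are minimized over periodic
images first, so a marker leaving through the top and re-entering through
the bottom is **not** an event (half-box steps are ambiguous and warn with
the frame index). The half-width h defaults to the z where the symmetrized
lipid density falls to 50% of its plateau, and is overridable — a stated
convention, since external tools define their regions in their own ways.
Event counts respect reflection (z → −z) and time-reversal symmetry with
directions swapped; both are tested.

## ECC charge scaling

The electronic continuum correction, in its simplest form, scales partial
charges by a constant factor — default 0.75, approximately 1/√ε_el for
water. `scale_charges()` is **scope-based**: only the requested atom set is
touched, because a typical setup scales the solute while the lipids use a
separately parameterized ECC-compatible model; an empty scope is an error
so a no-op must be requested explicitly. A per-molecule net-charge report
(before/after) is always attached. Scaling is linear and composable to
1e-12, and atoms outside the scope are bit-identical — both tested.
Lennard-Jones adjustments or other refinements beyond charge scaling are
out of scope.

## Response curves

`build_response_curve()` assembles ΔS of one segment against
bound-per-lipid or bulk concentration across systems, against a solute-free
reference. `fit_response_slope()` fits a weighted least-squares line
**through the origin** — with no bound solute there is no response, and the
observed linearity of ΔS in bound charge makes the origin-constrained slope
the meaningful summary; a free-intercept option exists for diagnostics.
Weights are 1/stderr² when available, else unit. The slope standard error
is calibrated by a 1000-replicate Monte-Carlo test (within 10% of the
empirical scatter and of the closed form σ/√Σx²). `compare_curves()`
reports the simulation/experiment slope ratio and the RMS ΔS deviation at
the experimental x positions by linear interpolation (no extrapolation);
experimental curves load from CSV (`x_kind,label,x,delta_s[,stderr]`).

## Synthetic generators: what they emulate, and what they do not

All generators are seeded, restore the caller's RNG state, and attach
ground truth so acceptance tests never re-derive truth from the data under
test.

* `gen_orientation_trajectory()` — C–H pairs with bond vectors from a fixed
  angle, a cone (fixed θ, uniform azimuth), or the uniform sphere; analytic
  S is (3cos²θ−1)/2, (3cos²θ−1)/2 and 0 respectively. var(P₂) = 1/5 for
  the isotropic case gives the sampling bound used in tests.
* `gen_membrane_system()` — a static point-cloud slab of pseudo-lipids
  (with O13/O14 phosphate-oxygen stand-ins), rigid multi-atom solutes, and
  bulk waters. Binding is a discrete-time two-state Markov chain with
  per-step switch probabilities 1 − exp(−k·dt): exact stationary
  distribution k_on/(k_on+k_off), no integrator error. Bound solutes are
  placed in contact with a randomly chosen lipid atom; free solutes at
  least `bulk_margin` (0.5 nm) outside the slab, so a criterion with
  cutoff ≤ ~0.35 nm reproduces the generator's bound flags exactly.
* `gen_density_system()` — i.i.d. draws from any prescribed density via
  inverse-CDF sampling on a fine grid.
* `gen_permeation_trajectory()` — markers linearly interpolated between
  scripted (time, z) waypoints, wrapped into the box.

Not emulated: excluded volume, electrostatics, solute diffusion
(positions are redrawn per frame within the current state), lipid internal
structure, or frame-to-frame correlation of orientations. Passing tests
therefore validate the **observables and estimators**, not force-field
physics; on real trajectories the statistical uncertainties will be larger
than the generators' i.i.d. sampling suggests because of temporal
correlation — which is exactly why block averaging is used for error bars.

## Problem sizes and runtime

The test suite runs ~10⁵-sample orientation ensembles, membrane fixtures of
20–120 lipids × 25–400 frames, 50 randomized oracle-comparison fixtures,
300-atom contact fixtures and 1000-replicate slope calibrations — sizes
chosen so the whole suite completes in about a minute on one core while
leaving every statistical bound at least ~5σ wide of its threshold. The
acceptance script (`scripts/acceptance.R`) rebuilds all headline quantities
from scratch in a few seconds.

## Known limitations

* Orthorhombic periodicity only; no triclinic cells.
* No XTC/TRR/DCD readers; convert to GRO frames or the JSON fixture format.
* No kinetic rate estimation (k_on/k_off fitting) — occupancy statistics
  only.
* No umbrella-sampling/WHAM free energies — only Boltzmann inversion of
  unbiased densities.
* No hydrogen reconstruction for united-atom trajectories; explicit
  hydrogens are required for order parameters.
* Bulk concentration assumes the water count tracks the bulk volume; in
  strongly dehydrated systems the 55,500 mM convention loses meaning.
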