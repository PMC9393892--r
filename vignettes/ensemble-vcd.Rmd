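---
title: "Ensemble-averaged VCD spectra: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble-averaged VCD spectra: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcdspec)
```

## The problem

A flexible chiral molecule in solution populates many conformers, and its
measured vibrational circular dichroism (VCD) spectrum is the
population-weighted average of the per-conformer spectra. Because VCD bands
are signed and individually conformation-sensitive, the averaged spectrum
can change qualitatively when the conformer populations shift. Turning a
set of per-conformer quantum-chemistry results into a defensible
calculated-versus-experimental comparison therefore involves a chain of
small, well-defined numerical steps, each with conventions that matter.
This vignette documents those conventions as implemented here.

## Conformer deduplication

Sampling tools and subsequent geometry optimizations frequently deliver
several copies of the same minimum. Two conformers are treated as
duplicates when **all three** of these hold:

* |ΔE| ≤ 0.05 kcal/mol (selected energy field; electronic by default),
* Kabsch-superposition RMSD ≤ 0.125 Å (plain Cartesian, unweighted),
* max over the three rotational constants of |ΔB| / mean(B) ≤ 1%.

The thresholds are user-configurable; the defaults are the documented
defaults of the CREST sampling tool, whose criteria the post-optimization
cleanup conventionally reuses. Notes on the individual criteria:

* **RMSD.** Atom order is treated as fixed (optimization pipelines
  preserve it), so no permutation search is done; symmetry-equivalent
  rotamers (e.g. methyl rotations) are out of scope. Mass weighting is off
  by default because the criterion is phrased in terms of Cartesian
  coordinates; a flag enables it. The rotation is the SVD-based Kabsch
  solution with the determinant correction, so reflections are never used.
* **Rotational constants.** Computed from the mass-weighted inertia tensor
  with most-abundant-isotope masses (solvent deuteration affects the
  experiment, not the gas-phase model). The relative difference
  |ΔB|/mean(B) is scale-free and symmetric. A principal moment below
  1e-10 amu Å² is treated as exactly zero (linear molecule) and its
  constant is excluded from the test.
* **Sweep order.** Duplicate relations need not be transitive at finite
  thresholds. The pruner sweeps in ascending energy and keeps a conformer
  unless it duplicates an already-kept one — a deterministic rule that
  always retains the lowest-energy representative of each group, rather
  than a clustering whose outcome could depend on traversal order.

Whether "total energy" in the duplicate test means electronic or free
energy is a genuine ambiguity in practice; electronic energy is the
default and the field is selectable.

## Energy window and Boltzmann weights

Geometry optimization and spectral calculation are expensive, so only
conformers within a window of the most stable one — 2.5 kcal/mol by
default, inclusive ("at most") — are carried forward. The kept count is
monotone in the window width, and the minimum-energy conformer is always
kept.

Populations follow the Boltzmann distribution
`w_i = exp(−ΔE_i/RT) / Σ_j exp(−ΔE_j/RT)` with ΔE in kcal/mol,
R = 1.987204×10⁻³ kcal/(mol·K), and T = 298.15 K by default (the standard
state assumed by thermochemistry outputs; the temperature is not otherwise
determined by the inputs and is configurable). Energies are shifted to the
minimum before exponentiation so large gaps cannot underflow. Gibbs free
energies are the default field; enthalpies or electronic energies can be
selected to probe the sensitivity of the averaged spectrum to the
weighting scheme — a comparison worth making whenever dispersion
corrections or solvation models reorder the low-energy conformers.

One exact identity is worth stating because it is easy to get wrong:
computing weights on a window-filtered ensemble is *identical* to
computing weights on the full ensemble, zeroing the outside-window
entries, and renormalizing — restricting a Boltzmann distribution to a
subset and renormalizing is the Boltzmann distribution on that subset.
What does change is the weight each kept conformer had in the *full*
ensemble; the tests pin down both facts.

The >5% significance cutoff (strict comparison) is bookkeeping by default:
it reports how many conformers matter, but the averaged spectra include
all retained unique conformers. An option restricts averaging to the
significant set (renormalized); the default is off because averaging over
everything is the safer reading and the sub-5% tail rarely changes the
spectrum visibly.

## Spectrum synthesis

Each vibrational mode contributes a band
`I(ν) = strength · C · ν · L(ν − ν₀; Γ)` with the unit-area Lorentzian
`L(x; Γ) = (Γ/2π)/(x² + (Γ/2)²)`. Conventions:

* **FWHM** Γ = 10 cm⁻¹ by default; 16 cm⁻¹ is selectable for experiments
  with broader bands. A broadened single band attains half its maximum at
  ν₀ ± Γ/2 up to the slight skew of the ν prefactor (≈0.3% across a band
  at 1650 cm⁻¹ — far below the grid step).
* **Conversion constants** C map dipole strength (10⁻⁴⁰ esu²cm²) and
  rotational strength (10⁻⁴⁴ esu²cm²) to molar absorptivity as
  ε(ν) = ν ΣD_iL_i/2.296×10⁻³⁹ and Δε(ν) = 4ν ΣR_iL_i/2.296×10⁻³⁹.
  Because the overlap statistic below is normalized, these constants
  cancel in every S value; they only set absolute plot axes. Whether the ν
  prefactor sits inside or outside the mode sum differs between plotting
  programs; the ν·L convention is used here and is covered by the
  regression tests, so a change would be visible immediately.
* **Grid**: ascending, uniform, 1 cm⁻¹ step, padded 100 cm⁻¹ beyond the
  extreme sticks by default. A warning (not an error) is raised when a
  requested grid truncates band tails within 5Γ of a stick.
* **Ensemble averaging** is the pointwise weighted sum of the broadened
  per-conformer spectra — linear in the weights, so identical sticks under
  any weights collapse to the single-conformer spectrum (a convexity check
  in the tests).

Gaussian/Voigt line shapes and anharmonic corrections are out of scope.

## Comparing spectra

The overlap estimate
`S_ab = ∫I_aI_b dν / √(∫I_a² dν · ∫I_b² dν)`
is evaluated by the trapezoid rule after linearly resampling both spectra
onto the finer of the two grids, restricted to the comparison region
(1800–1500 cm⁻¹ for amide I+II, 1800–1100 cm⁻¹ when the amide III region
is measured too). S is symmetric, invariant to positive rescaling of
either spectrum, and bounded in [−1, 1] by Cauchy–Schwarz: 1 means
identical shapes, −1 a perfect mirror image (the opposite enantiomer).
Linear interpolation is adequate because the spectra are smooth at
1 cm⁻¹ relative to 10–16 cm⁻¹ bandwidths; halving the grid step moves S
by less than 1e-4 in the tests. Experimental spectra are compared as read
— no baseline correction, since none is assumed by the protocol.

Harmonic frequencies carry a systematic method error, corrected by a
multiplicative **scaling factor** f. When an experimental spectrum is
available, f is chosen by grid search (default 0.94–1.01, step 0.001,
spanning the factors typical of hybrid functionals) to maximize the
combined objective S_IR + S_VCD. Equal weighting of the two modalities is
the least-assumptive combination; a weight option exists. Ties are broken
toward the f closest to 1. The search rebuilds the broadened ensemble
spectra from scaled sticks at every f — scaling the sticks, not the grid —
which the tests verify equals broadening at scaled centers. Intensity
matching (scaling the strongest calculated band to the corresponding
experimental band) is applied for display and reported as a factor; it
cannot affect S.

Sign patterns ("−/+/+/−", read from high to low wavenumber) are extracted
as the local extrema exceeding 5% of the region's maximum absolute
intensity. Overlapping modes of opposite sign can merge into a single
band in the broadened spectrum; the stick spectra are always available
(and exported by the pipeline) for exactly that situation.

## The synthetic generator

Fixtures are geometric toys, not chemically valid peptides: every in-scope
computation depends only on coordinates, energies, frequencies and
strengths. The generator emulates the statistical structure the pipeline
assumes:

* a puckered 12-atom carbon ring as the base geometry (ring-like, chiral
  enough to have three distinct rotational constants);
* 5 distinct conformers with per-atom perturbations of 0.8 Å, energies
  evenly spread over 3 kcal/mol — kcal-scale gaps with several conformers
  inside a 2.5 kcal/mol window, as observed for small cyclic peptides;
* planted duplicates differing by 0.02 Å noise plus a random rigid motion
  and an energy jitter of at most half the energy threshold. Each planted
  duplicate is verified against the three criteria (with a 0.8 safety
  margin on the RMSD and rotational-constant thresholds) and its noise
  shrunk geometrically if needed, so the planted partition is exact by
  construction rather than probabilistically;
* four signed bands at 1673(−)/1668(+)/1650(+)/1643(−) cm⁻¹ — an
  alternating amide-I pattern of a cyclic tetrapeptide — with small
  per-conformer frequency jitter (sd 1.5 cm⁻¹);
* a pseudo-experiment built by scaling the frequency axis by 0.975 (a
  typical hybrid-functional factor) and adding seeded intensity noise.

Every generator is a pure function of its seed, with module-local streams
so adding a generator never perturbs existing fixtures. What passing tests
on these fixtures do **not** show: that real CREST/DFT ensembles are
complete, that harmonic intensities are accurate, or that solvent models
reproduce band positions — the generator has no chemistry in it. They do
show that every post-processing step computes what it claims on inputs
with the right statistical shape.

## Problem sizes and numerical choices

The test-suite and verification runs use small problems chosen for quick,
deterministic feedback: ensembles of 3–7 conformers of 8–14 atoms,
4-mode stick spectra, 1 cm⁻¹ grids over ≈500 points, 71-point scaling
scans, and 20-seed repetitions for the noisy recovery study. All
tolerances asserted in tests were computed from the independent oracles
(closed forms, quadrature, brute-force searches) before being frozen.

Degenerate inputs are handled explicitly: empty ensembles, coincident
atoms, all-zero spectra, zero-norm overlap regions and non-positive
scaling factors are errors; imaginary frequencies are rejected at parse
time because the protocol requires true minima.

## Known limitations

* Cartesian genetic crossing only (`R_new = R_ref + (R_i − R_j)`); the
  internal-coordinate variant used inside samplers is not reproduced, and
  the crossed geometry is returned unoptimized, without energies.
* No atom-permutation handling in RMSD; ensembles must share atom order.
* The reported scaling factor resolves only to the scan step (0.001 by
  default); no local refinement beyond the grid is attempted because the
  objective is piecewise-smooth but cheap to scan.
* The qm_log dialect targets one widely used frequency-job text layout;
  other engines need their own dialect behind the same flag.
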