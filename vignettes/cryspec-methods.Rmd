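---
title: "Methods: spectra, stability and disorder analysis of molecular-crystal polymorphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectra, stability and disorder analysis of molecular-crystal polymorphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryspec)
```

cryspec post-processes the outputs of lattice-dynamics and molecular-dynamics
calculations on molecular crystals — force constants, Born effective charges,
dipole trajectories, torsion scans — into the quantities experimentalists
compare against: powder terahertz/infrared absorption spectra, pressure-
dependent polymorph stability, and statistics of torsional disorder and
hydrogen-bond motifs. The motivating class of systems is small hydrogen-bonded
molecular crystals (amino-acid polymorphs and the like) in which a single
soft torsion — here a thiol C–C–S–H dihedral, tau — switches the crystal
between two hydrogen-bond motifs, S–H···S and S–H···O, producing static and
dynamic disorder that is visible mainly below ~150 cm^-1.

The package deliberately contains no electronic-structure code. Everything a
DFT engine would supply is either read from plain-text files or generated by
the synthetic-data module, which builds toy harmonic crystals and stochastic
processes whose exact answers are known, so that every analysis stage can be
validated end to end at desk scale.

## Static route: phonons to powder absorption

Given a Gamma-point force-constant matrix K (eV/Å², 3N×3N) and site masses,
`gamma_phonons()` enforces the translational acoustic sum rule (self blocks
replaced by minus the sum of the interatomic blocks — interatomic force
constants are never altered), diagonalizes the mass-weighted dynamical matrix
and reports wavenumbers with mass-weighted orthonormal eigenvectors. Negative
eigenvalues are flagged imaginary and kept; modes with |omega| below an
acoustic tolerance (0.5 cm^-1 by default) are flagged acoustic. Both flags
exclude a mode from free energies and oscillator-strength sums, and the
counts are carried in the returned object rather than silently dropped.

For infrared intensities, each mode k gets a Born-charge-weighted dipole
derivative Z_k = sum_a Z*_a · e_{k,a} / sqrt(m_a) and an oscillator-strength
tensor proportional to Z_k ⊗ Z_k / V. The dielectric function is the Lorentz
oscillator sum

    eps(omega) = eps_inf + sum_k S_k / (omega_k^2 - omega^2 - i gamma omega)

with all frequencies in cm^-1 and a CODATA-derived prefactor making the
contribution dimensionless; the default broadening is gamma = 5 cm^-1. Powder
orientation averaging takes the tensor trace/3 *before* effective-medium
mixing; averaging after mixing would require an orientation integral of the
anisotropic mixing rule and is deliberately not done — users comparing with
strongly anisotropic crystals should know the scalar average enters first.
The powder is modelled as dilute spheres (default volume fraction f = 0.10)
in a host matrix of permittivity 2.0 (a PTFE-like value; the literature names
the polymer but not a number, so 2.0 is this package's configurable choice)
via the Maxwell–Garnett mixture

    eps_eff = eps_m [eps_i(1+2f) + 2 eps_m(1-f)] / [eps_i(1-f) + eps_m(2+f)].

The absorption coefficient is alpha = 4 pi omega~ Im sqrt(eps_eff) with the
principal square-root branch (Im sqrt >= 0 enforced), reported per effective
path length in cm^-1. Conversion to molar units is a constant post-factor
left to the user, so spectra are comparable in shape and relative intensity
rather than absolute scale.

## Dynamic route: cell-dipole correlation to absorption

`dipole_acf()` removes the mean dipole (fluctuation convention) and computes
C(t) = <dM(0)·dM(t)> by zero-padded FFT with the biased 1/N lag
normalization, so C(0) is the summed per-component population variance and
the spectral estimate stays non-negative for valid windows; the FFT path is
tested to agree with the direct O(N^2) lag sum to 1e-10. A window filter
(`window_spec()`: Hann, Gaussian or exponential, all equal to 1 at zero lag)
imposes the finite line width; the imposed width is recorded in the result's
provenance because the resulting peak widths reflect the window, not the
physical phonon lifetimes. The classical linear-response transform

    chi(omega) = [C(0) + i omega  ∫ C(t) e^{i omega t} dt] / (3 V eps0 kB T)

gives eps(omega) = eps_inf + chi(omega) (eps_inf defaults to 1 for the
dynamic route, where the electronic response is not part of the sampled
dipole), and absorption follows exactly as in the static route. An optional
harmonic quantum-correction factor beta hbar omega / (1 - e^{-beta hbar
omega}) can be applied to Im eps; it is off by default and recorded in the
provenance when used. The per-frame cell volume enters as the trajectory
mean, which covers both NVT (constant) and NPT (fluctuating) runs.

A note on sampling rates: published protocols sometimes quote dipole sampling
intervals (e.g. 0.5 ps) whose Nyquist limit (~33 cm^-1) cannot resolve
mid-infrared features. cryspec therefore never guesses dt — the user states
it — and the synthetic fixtures default to dt = 0.5 fs.

## Quasi-harmonic stability

`vibrational_free_energy()` evaluates the harmonic expression
F_vib = sum_k [hbar w_k/2 + kB T ln(1 - e^{-hbar w_k/kB T})] per cell in eV,
excluding acoustic and imaginary-flagged modes with a recorded count.
`relative_stability_curves()` combines static lattice energy, an optional
P·V term and F_vib into a per-molecule Gibbs energy relative to a named
reference polymorph (kJ/mol) on a pressure grid, and reports stability
crossovers as sign-change brackets with linearly interpolated P*. Published
free-energy-versus-pressure figures are ambiguous about whether the P·V term
is explicit or absorbed into per-pressure re-optimized energies, so both
modes exist (`include_pv`); per-molecule normalization uses the stated
molecule counts. Volumes are taken as supplied per pressure — no
equation-of-state fitting is attempted.

`analyze_torsion_profile()` treats a torsion scan as a periodic grid,
locates all local minima, and reports for each ordered pair of adjacent
minima the maximum energy along the connecting grid arc, above the departing
minimum. These are path barriers of a constrained scan, not transition-state
heights, matching how constrained-optimization scans are usually reported.

## Trajectory analysis and the flip automaton

`torsion_timeseries()` re-measures dihedrals frame by frame (each frame's
own cell supplies the minimum images) and keeps wrapped and
continuous-unwrapped views; unwrapping takes the minimal angular step per
frame and counts steps above 90 degrees as under-sampled.
`torsion_distribution()` normalizes histograms so the integrated area is
exactly 100, the convention used in the experimental-comparison literature.

Flip detection needs an operational definition, because trajectories visit a
metastable region near ±180 degrees and make short abortive excursions. The
committed-basin automaton used here: a torsion keeps its current basin label
until it has resided in a *different* basin continuously for at least the
dwell time (default 0.5 ps, matching the metastable-residence scale reported
for these systems), at which point one flip is recorded at the entry time.
Time outside all basins interrupts a pending commitment but never commits,
so ±180 is a distinct metastable label, not a basin. An out-and-back
excursion counts as two flips only when both residences meet the dwell. The
default basins are tau in (30, 150] for the S–H···S-like well and
(-150, -30] for the S–H···O-like well, bracketing the ~+87/−78 degree well
centers; both basins and dwell are configurable. Because any such automaton
is a convention, flip *counts* from other definitions (including published
ones) are not expected to be reproduced exactly.

`classify_sh_motif()` labels a thiol hydrogen by the element class of its
nearest S/O acceptor over all periodic images within a cutoff. The cutoff is
not stated in the motivating literature; 3.0 Å separates the ~2 Å
hydrogen-bond contacts from next-shell contacts in these lattices and is the
package default. A tie at exactly equal distance resolves to S (documented,
arbitrary).

## Disorder models

`generate_disorder_model()` assigns one of two motif angles to each listed
torsion: round(fraction·N) torsions (half-up rounding — the motivating use
only ever needs exact halves, so the rounding rule only matters for other
fractions) are chosen uniformly at random with an explicit seed and set to
the first angle, the rest to the second. The modified crystal is verified by
re-measuring every torsion. Setting a torsion rotates only the atoms distal
to the B–C bond, identified from the covalent bond graph (1.2× covalent
radius sum; user-supplied molecular partitions override bond inference);
rotations that would split a ring raise a topology error.

## The synthetic-data module

Toy crystals are triangles of three charged beads (charges summing to zero,
isotropic Born tensors) chained along the a axis with harmonic springs,
including boundary-crossing springs, so the force-constant matrix is
symmetric, positive-semidefinite, obeys the acoustic sum rule by
construction, and has exactly three zero modes; seeded orientation jitter
breaks accidental degeneracies. Langevin (BAOAB) dynamics on this force
field supplies dipole trajectories whose spectra must match the static route
on the same matrix — the package's central cross-method check. Langevin was
chosen over the thermostats typical of ab initio MD for its provable
stationary distribution; this is a deliberate simplification, as chemical
realism is a non-goal of the toys.

The default two-well torsion potential is a fixed order-2 Fourier series
solved so the wells sit at +87 and −78 degrees, the negative well 1.0 kJ/mol
above the positive one, and the path barrier through 0 degrees 6.0 kJ/mol —
the well geometry and the 1–6 kJ/mol energy scale typical of thiol rotors in
these crystals. Overdamped Euler–Maruyama dynamics on it converges to the
Boltzmann distribution (KL divergence < 0.05 at 10^6 steps in the tests).
The Ornstein–Uhlenbeck dipole generator uses the exact discretization, so
its correlation time and amplitude are recoverable benchmarks.

What the toys emulate: charge-neutral polar molecular units, acoustic/optical
mode structure, IR activity, two-basin torsional kinetics with planted
energetics. What they do not emulate: anharmonic phonon coupling, NPT cell
fluctuations, hydrogen-bond network cooperativity, or any element-specific
chemistry. Passing tests therefore validate the analysis chain, not the
quality of any particular DFT model of a real crystal.

## Numerical choices and problem sizes

- One CODATA-2018 constant table (`phys_const`) feeds every conversion;
  reporting units are cm^-1, eV, kJ/mol, GPa, Å^3.
- Coordinates are stored fractionally and wrapped to [0, 1); all distances
  go through the cell matrix with minimum-image convention (cells used here
  far exceed the interaction cutoffs).
- Structure I/O covers the loop-based small-molecule CIF subset, VASP
  POSCAR, and extended XYZ with `Lattice=` (plus optional `Time=` and
  `Dipole=`) records, written by this package and round-trip tested.
- Dihedral sign convention: IUPAC right-hand rule, cis = 0, range
  (−180, 180], cross-checked against an independent projection construction.
- Complex square roots always take the principal branch with Im >= 0.
- Seeds are explicit function arguments everywhere; generators save and
  restore the global RNG state.
- The validation suite runs MD of 10^5–2×10^5 steps on 6–18-bead crystals
  and 20-seed batches of 5×10^5-step torsion Langevin runs — sizes chosen so
  the stochastic tolerances (5–10%) are comfortably resolved on a single
  CPU in minutes.

## Known limitations

- Only the Maxwell–Garnett spherical-inclusion mixture is implemented; no
  Bruggeman scheme, non-spherical shapes, ATR or scattering corrections.
- Absorption is per effective path length; absolute molar intensities need
  an external conversion.
- No q ≠ Gamma phonons, no thermal expansion, no equation-of-state fits.
- The motif cutoff, flip automaton and disorder rounding are declared
  conventions; quantities that depend on them should be compared across
  conventions before being compared across studies.
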