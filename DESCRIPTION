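Package: cryspec
Title: Terahertz and Infrared Spectra, Stability, and Disorder Analysis of
    Molecular-Crystal Polymorphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-processing toolkit for lattice-dynamics and molecular-dynamics
    studies of molecular-crystal polymorphs. Computes powder infrared and
    terahertz absorption spectra from Gamma-point phonons and Born effective
    charges through a Lorentz-oscillator dielectric function and the
    Maxwell-Garnett effective-medium approximation; computes the same spectra
    from molecular-dynamics cell-dipole trajectories via the dipole
    autocorrelation function; ranks polymorph stability with quasi-harmonic
    vibrational free energies on a pressure grid; analyses torsion-scan energy
    profiles, dihedral-angle trajectories and hydrogen-bond-motif flips; builds
    supercells and dispersed-disorder models from CIF, POSCAR and extended-XYZ
    structures. A synthetic-data module generates toy harmonic crystals,
    Langevin trajectories and stochastic dipole processes with known spectra so
    that every stage can be exercised and validated at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
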