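# excitonxs

Frenkel-exciton simulation of metal L-edge X-ray absorption (XAS),
resonant inelastic X-ray scattering (RIXS), and partial fluorescence yield
(PFY) spectra of molecular dimers.

## The problem

Soft X-ray L-edge spectroscopy probes the 2p → 3d excitations of
transition-metal complexes. For aggregates — the motivating case is an
iron porphyrin (hemin-like) complex that dimerizes in water — a
supermolecular multiconfigurational treatment of all relevant spin-orbit
coupled (SOC) states is computationally hopeless: a monomer needs ~800 SOC
states, the corresponding dimer ~137,000. `excitonxs` is for spectroscopists
and theorists who already have *monomer* electronic-structure data (state
energies and complex transition-dipole matrices, e.g. from RASSCF/RASSI)
and want aggregate L-edge spectra without the supermolecule.

## The model

Aggregate states are direct products |A₁B₂⟩ of monomer SOC eigenstates.
The dimer Hamiltonian (eV) has the zeroth-order energies E_A¹ + E_B² on
the diagonal and point transition-dipole Coulomb couplings off it:

    J = (d_{A₁D₁} · d_{B₂C₂}) / |X|³ − 3 (X·d_{A₁D₁})(X·d_{B₂C₂}) / |X|⁵

with dipoles in atomic units and X the center-to-center vector.
One-particle (OPA) or two-particle (TPA, exact for a dimer) exciton bases
are supported, with configurable coupling-neglect rules (weak g↔v classes,
static dipoles) and a ±5σ core-state energy window that cuts the
RIXS-relevant TPA rank from 140,964 to the ten-thousand scale. After
Hermitian diagonalization, spectra follow the standard first- and
second-order expressions — XAS sticks weighted by w(E_i)(E_f−E_i)|d|²/3
under a Voigt profile, the Kramers–Heisenberg coherent sum with
energy-dependent lifetime widths Γ(E_n) for RIXS, and emission-integrated
RIXS for PFY — with Boltzmann or lowest-Kramers-doublet initial states and
numerical orientational averaging for freely tumbling molecules.

A seeded synthetic-monomer generator emulates the hemin-like manifold
layout (ground Kramers doublets, valence states up to 7.3 eV, core states
at 710.6–732.9 eV, complex Hermitian dipoles), so the whole pipeline runs
and is tested without any external data. Brute-force reference
implementations (naive full-product Hamiltonian, explicit-loop RIXS
amplitude) ship in the package and back the test suite.

## Worked example

```r
library(excitonxs)

# seeded hemin-like toy monomer: 6 ground + 12 valence + 24 core states
m <- make_toy_monomer(toy_monomer_spec(preset = "hemin-like-small", seed = 1))
m
#> <monomer_states> 42 states (6 ground, 12 valence, 24 core)
#>   energy range: 0.0000 .. 732.7195 eV

# two-particle basis with a +/-1.25 eV core window at 712 eV,
# dimer at 7 a.u. separation, monomer 2 rotated by 90 degrees
b   <- build_basis(m, m, "TPA", window = c(712, 1.25))
nrow(b)
#> [1] 361
eig <- diagonalize(assemble_hamiltonian(b, m, m, make_dimer_geometry(7, 90)))

cfg <- spectroscopy_config(
  excitation_grid = seq(703, 716, by = 0.05),
  emission_grid   = seq(698, 716, by = 0.10),
  initial_state_mode = "lowest-kramers")   # 4 lowest Kramers products

sp <- xas(eig, cfg)
# strongest absorption of this fixture: intensity 4.60 (arb. units) at
# 708.10 eV on the rendered axis (the default -2.8 eV shift is applied)
sp$energy[which.max(sp$intensity)]
#> [1] 708.1

map <- rixs(eig, cfg, excitation_energies = c(711.8, 714.6))
pfy(map, 698, 716)
#> # A tibble: 2 x 2
#>   energy intensity
#>    <dbl>     <dbl>
#> 1   709  0.000253
#> 2   712. 0.0000162
autoplot(map)   # emission x excitation raster
```

The XAS intensities are in arbitrary units (oscillator-weighted Voigt
lines); the PFY rows are the emission-integrated RIXS intensity at the two
requested excitation energies (709.0 and 711.8 eV after the global shift).

A thin command-line front end with `xas` / `rixs` / `pfy` subcommands over
exchange-format monomer files and a YAML config lives at
`inst/cli/excitonxs.R`.

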