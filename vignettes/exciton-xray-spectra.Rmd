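---
title: "Frenkel-exciton modelling of metal L-edge XAS and RIXS for molecular dimers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frenkel-exciton modelling of metal L-edge XAS and RIXS for molecular dimers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excitonxs)
```

## The problem

Metal L-edge spectroscopies (XAS, RIXS, PFY) probe 2p core excitations of
transition-metal complexes. For aggregates of such complexes — for example
an iron porphyrin that dimerizes in aqueous solution — a supermolecular
multiconfigurational calculation of all relevant states is out of reach:
the number of spin-orbit coupled (SOC) states grows from hundreds for a
monomer to hundreds of thousands for a dimer. `excitonxs` implements the
alternative: a Frenkel-exciton construction in which the aggregate states
are direct (Hartree) products of *monomer* SOC eigenstates, coupled only by
the intermonomer Coulomb interaction in the point transition-dipole
approximation. Monomer energies and complex transition-dipole matrices are
the *inputs* (from any quantum-chemistry program, via a neutral exchange
format); the package owns everything downstream.

## The model

With monomer states $|A_M\rangle$ of energies $E_A^M$ (eV, relative to each
monomer's ground state), the dimer Hamiltonian over product configurations
$|A_1 B_2\rangle$ has

* diagonal elements $E_A^1 + E_B^2$ (zeroth order), and
* off-diagonal elements
  $J(A_1 B_2, C_2 D_1) =
  \frac{\mathbf d_{A_1 D_1}\!\cdot\!\mathbf d_{B_2 C_2}}{|\mathbf X|^3}
  - 3\,\frac{(\mathbf X\!\cdot\!\mathbf d_{A_1 D_1})
             (\mathbf X\!\cdot\!\mathbf d_{B_2 C_2})}{|\mathbf X|^5}$,

where $\mathbf d_{AD} = \langle A|\mathbf d|D\rangle$ are (complex)
transition dipoles in atomic units and $\mathbf X$ the center-to-center
vector. Dipoles and distances stay in atomic units; each coupling is
converted once to eV (1 hartree = 27.211386245988 eV) before entering the
Hamiltonian, which is kept entirely in eV.

**Complex contraction.** SOC makes the transition dipoles complex, and the
point-dipole formula is written for real transition densities, so a
convention is needed. The package uses the bilinear (unconjugated) product
$\mathbf d_A\!\cdot\!\mathbf d_B=\sum_k d_{A,k}d_{B,k}$. Hermiticity of the
aggregate Hamiltonian is then *inherited* from the Hermiticity of the
monomer dipole matrices ($\mathbf d_{AD}=\mathbf d_{DA}^*$), not imposed
per element; assembly preserves it to the last bit, and tests assert that.

**Exciton bases.** The one-particle approximation (OPA) keeps all
ground-manifold products plus configurations with exactly one excited
monomer; it is adequate for one-photon absorption. The two-particle
approximation (TPA) adds doubly excited products $|a_1 b_2\rangle$ and is
exact for a dimer; it is required for the two-photon RIXS pathways
$g \to c \to a$. Because the ground manifold may hold several Kramers
components, the TPA union collapses to the full product space; bases are
deduplicated and sorted by (zeroth-order energy, index 1, index 2), which
makes their ordering reproducible. Two counting conventions coexist in
`count_basis()`: the unambiguous full-product set size, used by the
enumeration oracle, and the "ledger" formula
$2\,n_{val}n_{core} + 2\,n_{val}$ that quotes the rank of the
RIXS-relevant block (with the ground state counted inside $n_{val}$, and
the doubly ground configuration entering both single-excitation terms).
With 102 valence-manifold and 690 core states per monomer the ledger gives
140,964.

**Coupling-neglect rules.** Three switchable rules keep the physics
honest and the cost down: (a) couplings between two $g\!\leftrightarrow\!v$
transitions and between $g\!\leftrightarrow\!v$ and
$v\!\leftrightarrow\!c$ transitions are zeroed (these transitions are weak
for metal-centered L-edge physics); (b) static (same-state) dipoles couple
to nothing, which keeps the diagonal at zeroth order and makes the trace
of the Hamiltonian exactly the sum of configuration energies — a tested
invariant; (c) core states are pre-selected inside an energy window of
$\pm 5\sigma$ around the excitation-pulse center (closed interval;
$\sigma = 0.25$ eV gives the $\pm 1.25$ eV window). Couplings between
$g\!\leftrightarrow\!c$ and $v\!\leftrightarrow\!c$ transitions are *not*
on the neglect list; the package retains them by default and exposes
`neglect_gc_vc` for the stricter variant, since the written rules leave
this class open. Intra-manifold transitions (e.g. between two distinct
valence states) are likewise retained — only the explicitly listed classes
are dropped.

## Spectra

After dense Hermitian diagonalization (eigenvalues ascending; aggregate
transition dipoles $U^\dagger \mu U$ componentwise, where the
configuration-level dipole changes at most one monomer),

* **XAS** is a stick spectrum with weights
  $w(E_i)\,(E_f-E_i)\,\overline{|\mathbf e_1\!\cdot\!\mathbf d_{fi}|^2}$,
  convolved with a Voigt profile. The printed oscillator-strength-like
  prefactor $(E_f-E_i)$ is retained as such. The isotropic orientational
  average $\overline{|\mathbf e_1\!\cdot\!\mathbf d|^2}=|\mathbf d|^2/3$
  is exact for first-order absorption and is used directly.
* **RIXS** follows the Kramers–Heisenberg form: for initial $i$, final $f$
  and excitation energy $E_{exc}$ the coherent amplitude
  $\sum_n (\mathbf e_2\!\cdot\!\mathbf d_{fn})
          (\mathbf e_1\!\cdot\!\mathbf d_{ni})
   /(E_i + E_{exc} - E_n - i\Gamma_n)$
  is squared and averaged over orientations; the emission-energy delta is
  replaced by a Gaussian of the pulse width, centered at
  $E_{exc}+E_i-E_f$.
* **PFY** integrates the RIXS map over emission energy in a window
  (default 695–735 eV, the $3d \to 2p$ radiative channel) by the
  trapezoidal rule on the emission grid.

**Broadening composition.** The line width has two physical sources — the
finite lifetimes of the (intermediate) states and the Gaussian line shape
of the excitation pulse — without a prescribed composition rule. The
package composes them as follows: XAS uses a Voigt profile (Lorentzian
$\Gamma(E_f)$ from the lifetime model, Gaussian $\sigma$ from the pulse);
RIXS keeps the Lorentzian $\Gamma_n$ inside the amplitude denominator,
where the Kramers–Heisenberg form prescribes it, and applies the Gaussian
$\sigma$ on the emission axis. The pulse "width" of 0.25 eV is interpreted
as the Gaussian standard deviation, which is the reading consistent with
$\pm 5\sigma = \pm 1.25$ eV. The Voigt function is evaluated through the
Faddeeva function $w(z)$ with Weideman's 64-term rational approximation
(machine precision on the upper half plane; validated in the tests against
direct numerical convolution).

**Lifetime model.** $\Gamma(E)$ is piecewise constant. The iron L-edge
default is 0.09 eV below 709.2 eV, 0.26 eV between 709.2 and 711.6 eV,
0.43 eV between 711.6 and 719.2 eV, and 0.61 eV above. An energy exactly
at a band edge takes the upper band's value, matching the
below/between/above wording of the band definitions.

**Initial states.** Two modes: `boltzmann-ground` populates all
eigenstates within `ground_span` (default 0.01 eV, wide enough for the
SOC-split Kramers doublets of a sextet ground state) of the minimum with
Boltzmann weights at the configured temperature
($k_B = 8.617333262\times 10^{-5}$ eV/K; at $T=0$ the weight is split
equally over the degenerate minimum); `lowest-kramers` takes the
`n_initial` lowest eigenstates with equal weights — the very-low-
temperature choice for a dimer, where only the four products of the two
monomers' lowest Kramers doublets are populated.

**Orientational averaging.** Free tumbling in solution with the outgoing
polarization detected orthogonal to the incoming one does not reduce to a
published closed form here, so the average over molecular orientations is
numerical: a product Euler-angle quadrature (equally spaced $\alpha,
\gamma$; Gauss–Legendre in $\cos\beta$). The integrand is quartic in the
rotation-matrix entries, so the rule is *exact* from order 5 on; `rixs()`
uses a single fixed-order pass (default 6), while the exported
`orientational_average()` doubles the order until two successive results
agree to $10^{-6}$ and errors out if a cap is reached. For unanalyzed
("isotropic") emission the outgoing polarization is summed over a complete
lab triad, which removes the $\mathbf e_2$ dependence exactly and yields
the analytic $1/3 \cdot 1/3$ factorization for a single channel — kept as
a cross-check of the numerical path. Rigid rotation of the whole aggregate
leaves averaged spectra unchanged to $10^{-8}$ (tested).

**Energy scales.** Everything is computed on the unshifted monomer scale;
the configured `global_shift` (default $-2.8$ eV, the alignment used for
iron L-edge plots) is applied only when rendering axes. Excitation
energies passed to `rixs()` are on the physical scale; the returned map's
axes carry the shift.

## A subtlety: permanent-dipole pathways

The Kramers–Heisenberg sum over *all* intermediates includes off-resonant
self-terms ($n=i$, $n=f$) built from permanent (static) dipoles. These are
tiny but physically distinct: in a dimer the configuration's permanent
dipole is the *sum* of both monomers' static dipoles, so the uncoupled
dimer is not exactly the sum of its monomers unless intermediates are
restricted to the resonant (core) manifold — which is precisely what the
intermediate-state window does in production use. The additivity tests
therefore window the intermediates, and the elastic line is excluded from
additivity comparisons: coherent elastic scattering from two emitters
interferes even at zero coupling, which is genuine physics (a structure
factor), not an implementation artifact.

## The synthetic generator

`make_toy_monomer()` emulates the *structure* the method assumes, not any
particular molecule's values: a small ground manifold of exactly
degenerate Kramers pairs separated by a configurable splitting (real
ground-sextet splittings are not tabulated, so the default 0.001 eV keeps
all components inside the 0.01 eV ground span); valence energies uniform
in $[0.1, 7.3]$ eV; core energies uniform in $[710.6, 732.9]$ eV; complex
Hermitian dipoles with uniformly distributed phases (real-only fixtures
would mask conjugation bugs) and block scales
$g\!-\!c > v\!-\!c > g\!-\!v$, mirroring the dominance of the
$2p \to 3d$ transitions. Diagonal (static) dipoles are forced real, as
Hermiticity requires. What it does *not* emulate: multiplet structure
within the manifolds, realistic dipole magnitudes (not tabulated — the
scales are free parameters), spin selection rules between specific states,
and any axial-ligand chemistry. Passing tests therefore demonstrate the
correctness of the *machinery* — basis construction, coupling rules,
diagonalization, spectral formulas — not agreement with measured hemin
spectra, which would require actual RASSCF monomer data supplied through
the exchange format.

Presets: `minimal-3-state` (deterministic g/v/c three-level monomer for
closed-form tests), `hemin-like-small` (6 + 12 + 24 states), and
`hemin-like-full-counts` (6 + 96 + 690, reproducing the 102/690 manifold
bookkeeping).

## Numerical choices

* Dipole Hermiticity tolerance $10^{-10}$ a.u. (file round-trip noise),
  configurable.
* The exchange format is versioned JSON with doubles at 17 significant
  digits: round trips are bit-exact, and the format stays diffable text.
* Window intervals are closed on both ends; boundary states are
  indistinguishable at floating precision, so exclusivity would be
  arbitrary.
* Dense diagonalization is capped (default rank 2500); beyond it the
  package errors and points to core-state windowing rather than silently
  truncating.
* Degenerate eigenvalues (Kramers degeneracy is pervasive) get no
  canonical gauge; all observables are gauge-invariant sums over
  degenerate subspaces, and tests only compare such quantities.
* The brute-force oracles (`full_product_hamiltonian()`,
  `direct_rixs_amplitude()`) share no computational code with the
  production paths and refuse, rather than approximate, oversized inputs.

## Problem sizes

The shipped tests and the acceptance script run on seeded toy dimers of up
to $6 \times 6$ monomer states (36 product configurations), emission grids
of a few dozen points, and orientation quadratures of order 5–6 — sizes
chosen so every check completes in seconds while still exercising complex
dipoles, degenerate manifolds, windowing and averaging. The bookkeeping
operations (`count_soc_states()`, `count_basis()`) reproduce the full-size
monomer and supermolecule counts (792; 137,426; 140,964) exactly, since
they are closed-form.

## Limitations

* Dimers only; the basis builder is n-monomer-ready but no larger
  aggregate path is implemented or tested.
* Point-dipole Coulomb couplings only: no transition-density integrals,
  no exchange contributions, no monopole terms for charged systems, no
  $\pi$-stacking orbital overlap effects.
* No fitting of lifetime bands to experiment, and no attempt to reproduce
  measured spectra; monomer electronic structure is an input, never
  computed here.
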