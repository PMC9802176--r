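---
title: "Spin Hamiltonians and powder EPR spectra for the S2-state Mn4CaO5 cluster"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spin Hamiltonians and powder EPR spectra for the S2-state Mn4CaO5 cluster}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oecspin)
```

## The model

The S2 state of the oxygen-evolving Mn4CaO5 cluster in photosystem II is an
exchange-coupled tetramer of Mn ions. In the closed-cubane valence isomer
the three cubane ions Mn1–Mn3 are Mn(IV) (local spins $s_1 = s_2 = s_3 =
3/2$) and the dangling Mn4 is Mn(III) ($s_4 = 2$); the open-cubane isomer
swaps the Mn(III) onto Mn1. The product Hilbert space of the closed-cubane
pattern has dimension $4^3 \times 5 = 320$, small enough that every
calculation in this package uses exact dense diagonalization.

The spin Hamiltonian is

$$
\hat H \;=\; -\sum_{i<j} 2 J_{ij}\, \hat{\mathbf S}_i\!\cdot\!\hat{\mathbf S}_j
\;+\; \hat H_{\mathrm{ZFS}}
\;+\; g\,\mu_B\, \mathbf B_0\!\cdot\!\hat{\mathbf S}_{\mathrm{total}} ,
$$

with all six pairwise exchange couplings $J_{ij}$ in cm$^{-1}$.
**Sign convention:** under $-2J\,\mathbf S\!\cdot\!\mathbf S$ a *positive*
$J$ is ferromagnetic. Published couplings quoted under $+J$ or $-J$
conventions must be rescaled before use. The electronic $g$ is isotropic
and site-independent ($g = 2$), and hyperfine structure is not modelled
explicitly — it is absorbed into the Gaussian linewidth below.

Two zero-field-splitting (ZFS) schemes are supported:

* **total** — one tensor on the total spin,
  $D[\hat S_{z,\mathrm{tot}}^2 - \tfrac13\hat S_{\mathrm{tot}}^2] +
  E(\hat S_{x,\mathrm{tot}}^2 - \hat S_{y,\mathrm{tot}}^2)$;
* **site** — the tensor on a single ion (by default the dangling Mn(III)),
  with onsite parameters $d_4$, $e_4$ of the same form.

The package default is the total scheme with $D = -0.445$ cm$^{-1}$ and
$E/D = 0.25$, the parameters appropriate for the high-spin S2 signal. The
onsite parameters of the site scheme were never published for the
reference simulations it mimics; when the site scheme is requested without
parameters the package assumes $d_4 = -0.445$ cm$^{-1}$, and this default
is an assumption, not a published value. Tensors are canonicalized to the
standard rhombicity window $0 \le E/D \le 1/3$ by proper axis
permutations folded into the stored orientation, so the physical tensor is
never altered.

Units are fixed throughout: energies in cm$^{-1}$, fields in Gauss,
$\mu_B = 4.668645\times10^{-5}$ cm$^{-1}$ G$^{-1}$, frequencies converted
by $\mathrm{GHz}/29.9792458$, and 219474.63 cm$^{-1}$ per hartree.

## From broken-symmetry energies to couplings

Quantum-chemical broken-symmetry calculations yield one total energy per
up/down pattern $\sigma$ of the four site spins. Under the classical
(Ising) approximation each configuration energy is linear in the
couplings,

$$
E(\sigma) = c_0 + \sum_{i<j} (-2\,\sigma_i \sigma_j s_i s_j)\, J_{ij},
$$

which for the closed-cubane spins yields the familiar $\pm 9/2$
coefficients on Mn(IV)–Mn(IV) pairs and $\pm 6$ on pairs involving the
Mn(III). `fit_exchange_couplings()` solves this linear system over the
eight canonical sign classes by singular value decomposition
(pseudo-inverse with a $10^{-10}$ relative singular-value cutoff — safe
for an $8\times 7$ system). A constant offset $c_0$ is always co-fitted:
real quantum-chemical energies carry a huge spin-independent part that the
classical expressions omit, and the offset column absorbs it without
biasing the couplings. The J block of the eight-configuration design
matrix has rank 6, so all six pairwise couplings are identified; an
underdetermined subset of configurations raises an error naming the
unresolvable coupling combinations. Energies may be supplied in hartree
or cm$^{-1}$; conversion happens exactly once at parse time.

The same classical expression is the quantum operator's expectation value
in the corresponding maximal-projection product state, which the test
suite uses as a cross-module oracle tying the fit stage to the exact
Hamiltonian.

## The synthetic energy generator

The broken-symmetry energy tables behind published coupling sets live in
supplements without machine-readable accessions, so
`generate_bs_energies()` emulates them: it evaluates the classical
expressions for a ground-truth coupling set, adds a constant offset of
hartree-scale magnitude ($-0.5$ hartree by default, so the offset column
of the fit is genuinely exercised), and adds i.i.d. Gaussian noise per
configuration. No error model for DFT energies is published; the default
noise of 0.5 cm$^{-1}$ is chosen to be small relative to the 1–45
cm$^{-1}$ magnitude of the couplings themselves. The generator is
deterministic under a seed. What it does *not* emulate: geometry
relaxation (adiabatic versus vertical energies), spin-projection
corrections beyond the Ising mapping, or any systematic (non-Gaussian)
structure in DFT errors — so a passing round-trip test demonstrates the
algebraic correctness of the fit, not the accuracy of any quantum
chemistry.

```{r}
sys <- spin_system(oxidation = "IV,IV,IV,III")
truth <- fixture("closed_W1OH_D170axis")$couplings
energies <- generate_bs_energies(truth, sys, noise_sd = 0, seed = 1)
fit <- fit_exchange_couplings(energies, sys)
tidy(fit)
glance(fit)
```

## Spin ladders and total-spin labels

The exchange Hamiltonian commutes with $\hat S^2_{\mathrm{total}}$, so its
spectrum organizes into $(2S+1)$-degenerate multiplets. `spin_ladder()`
diagonalizes the 320-dimensional operator, groups states into levels
(grouping tolerance $10^{-6}$ cm$^{-1}$), and labels each level by the
half-integer $S$ nearest to the measured $\langle \hat S^2\rangle$; a
labelling residual above $10^{-3}$ aborts, since it signals a
non-exchange term contaminating the input. The ground-state spin decides
the EPR phenomenology: the high-spin $g\simeq 4$ signal requires an
isolated $S = 5/2$ ground multiplet.

```{r}
glance(spin_ladder(sys, truth))
```

A caveat discovered while validating against the published tables: for
the all-H$_2$O closed-cubane coupling set the published table lists a
ground spin of 11/2, but exact diagonalization of those couplings (here
and in an independent implementation) gives 13/2, with 11/2 as the first
excited multiplet 19 cm$^{-1}$ up — consistent, incidentally, with the
14 sublevels (a $2S+1$ of $S=13/2$) used in the published level diagram
for that model. The corresponding assertion in the acceptance tests is
left failing rather than silenced.

## Powder EPR simulation

`powder_spectrum()` implements a field-swept golden-rule absorption
calculation:

1. the zero-field Hamiltonian (exchange + ZFS) is diagonalized once and
   truncated to the lowest `n_sublevels` eigenstates (default 6, the
   isolated $S=5/2$ multiplet; a cut through a Kramers doublet is
   extended to the multiplet boundary with a warning);
2. for every orientation of $\mathbf B_0$ on a $\sin\theta$-weighted
   $31\times 62$ hemisphere product grid and every field on a 50–6000 G,
   512-point sweep, the Zeeman term is added in the reduced basis and the
   Hamiltonian rediagonalized;
3. each state pair contributes
   $\rho(|E_k-E_n| - h\nu)\,\overline{|\langle k|\hat{\mathbf
   S}_{\mathrm{total}}\!\cdot\!\mathbf b_1|n\rangle|^2}$, where $\rho$ is
   a normalized Gaussian of width $\Delta = 0.033$ cm$^{-1}$ (the field
   equivalent of roughly 350 G at $g=2$, standing in for unresolved Mn
   hyperfine structure) and the microwave-polarization average over
   $\mathbf b_1 \perp \mathbf B_0$ is done analytically as the mean of
   two orthogonal polarizations — exactly equivalent to the polarization
   integral for a bilinear matrix element, and much cheaper.

The lineshape is evaluated in the energy domain at each field point;
resonance-field root finding is deliberately avoided. Transitions are
weighted equally by default because the golden-rule expressions carry no
population factor; an optional `temperature` applies Boltzmann population
differences. The inner loop (about $10^6$ small Hermitian eigensolves
per spectrum at defaults) is compiled C++ (RcppArmadillo); the R-level
`transition_intensity()` computes the identical per-pair quantity and
serves as its independent cross-check in the tests. The orientation grid
covers a hemisphere only — the spin Hamiltonian is invariant under field
inversion. A printed rotation-matrix form sometimes attached to this
integral is not orthogonal as printed (an apparent typo); any proper
rotation carrying the lab axis over the sphere is equivalent for a powder
average, which is what the direction grid implements.

## Reading off the effective g

`effective_g()` reports $g = h\nu/(\mu_B B^\*)$ with $B^\*$ the
absorption maximum (parabolically refined) or the derivative
zero-crossing. One subtlety matters for comparison with reported g
values: a powder envelope is asymmetric, so convolution with the
hyperfine-width Gaussian shifts its *maximum* away from the underlying
resonance feature — for the closed-cubane high-spin sets the broadened
maximum sits at $g = 4.16$ at $\Delta = 0.033$ cm$^{-1}$, while the line
position is width-independent at $g = 4.00$. The conventional "g value
of a signal" is the line position, and `resonance_g()` estimates it by
running the same powder integral at a small numerical width (default
0.002 cm$^{-1}$, about one field-grid step at $g\sim4$; the estimate
moves by <0.01 under halving or doubling of either the resolution or the
orientation grid). The acceptance checks of published g values use
`resonance_g()`.

```{r, eval = FALSE}
fx <- fixture("closed_W1OH_D170axis")
sp <- powder_spectrum(fx$system, fx$couplings, fx$zfs, spectrum_settings())
effective_g(sp) # 4.16: broadened absorption maximum
resonance_g(fx$system, fx$couplings, fx$zfs) # 4.00: line position
autoplot(sp)
```

## The effective two-spin model

`two_spin_model()` collapses the cubane into one super-spin $S_A = 9/2$
coupled to the dangler $S_B = 2$ by a single $J_{\mathrm{eff}}$, with the
anisotropy on the dangler. Its exchange ladder obeys the Landé interval
rule exactly, which the tests assert. `two_spin_g_scan()` sweeps
$J_{\mathrm{eff}}$, simulates each powder spectrum, and interpolates the
$|J_{\mathrm{eff}}|$ at which the effective g first reaches a target —
the strong-exchange limit of the scan reproduces the spectrum of a bare
$S=5/2$ carrying the multiplet-projected tensor, a consistency check in
the test suite. Because the onsite tensor used in the published two-spin
simulations was never printed, the package makes no claim to reproduce
the published two-spin threshold numerically; the scan is validated by
its limits instead.

## Numerical choices and problem sizes

* Dense eigensolvers everywhere: the largest matrix is $320\times 320$.
* Level grouping at $10^{-6}$ cm$^{-1}$; Kramers degeneracy tolerance the
  same; SVD cutoff $10^{-10}$ relative.
* Default spectra use $31\times62$ orientations $\times$ 512 fields
  (a few seconds per spectrum); unit tests use reduced grids
  ($9\times18\times256$) where only structure is asserted, and the
  convergence tests double the default grid.
* Euler angles are active Z-Y-Z rotations; the default orientation puts
  the ZFS principal frame on the lab frame, so "$B_0 \parallel D$-z"
  level diagrams use `field_axis = "z"`.
* Ties in adiabatic level tracking (equal eigenvector overlaps) fall
  back to energy ordering; tracking is used only for diagrams, never for
  spectra.

## Limitations

No anisotropic or site-dependent g tensors, no explicit hyperfine
Hamiltonian, no inter-site dipolar ZFS, no frequency-swept or pulsed
observables, and no fitting of simulated spectra to experimental traces.
The synthetic generator stands in for quantum-chemical energy tables; it
cannot validate the chemistry that produced published couplings, only the
algebra downstream of them.
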