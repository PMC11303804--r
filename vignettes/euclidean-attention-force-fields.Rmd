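---
title: "Euclidean-attention force fields: model, dynamics and exploration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Euclidean-attention force fields: model, dynamics and exploration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic data does and does not emulate, the numerical choices, and the
known limitations.

## 1. The representation: invariant features + Euclidean variables

A machine-learned force field maps atomic numbers and Cartesian
coordinates to a potential energy `E` and forces `F = -dE/dr`. For the
energy to be physical, `E` must be invariant under rotations,
translations and atom permutations, and the forces must rotate with the
molecule. Fully equivariant message-passing networks achieve this by
passing spherical-tensor messages coupled with Clebsch–Gordan (CG) tensor
products, which costs `O((l_max+1)^6)` per message.

This package implements the cheaper route: each atom carries

* **invariant features** `f_i` (dimension `F`), and
* **Euclidean variables** (EV) `x_i`, a real spherical tensor with one
  block of length `2l+1` per degree `l`. The EV are seeded from the
  neighborhood geometry,
  `x_ilm = <N>^-1 sum_j phi(r_ij) Y_lm(r_hat_ij)` (or from zeros, in
  which case the first attention update populates them), and rotate
  block-wise by Wigner-D matrices.

The only place rotational information enters a scalar computation is the
**per-degree invariant contraction**: the projection of `x (x) x` onto
total degree zero. In the real orthonormal basis the CG matrix of the
`L = 0` block is diagonal, `(-1)^l delta_{m1 m2} / sqrt(2l+1)`, so the
projection collapses to a per-degree trace `sum_m x_lm^2` — `O(l_max^2)`
in total. The package fixes the contraction constant to
`1/sqrt(2l+1)` (positive); tests compare against the full CG projection
through the fixed degree-wise sign. The full CG machinery (`cg_table`,
`wigner_3j`) exists only as the test oracle, never on the hot path.

**Spherical-harmonic conventions.** Real, orthonormal harmonics; ordering
degree-major with `m = -l..l`; negative orders carry `sin(|m| phi)`. The
network path evaluates them as Cartesian polynomials (hard-coded with
analytic gradients, degrees up to 3 — the degrees actually used by the
architecture); a recursion-based implementation covers arbitrary degree
for tests. `wigner_d` builds the real rotation matrices from ZYZ Euler
angles and the complex Wigner small-d matrix via the complex-to-real
basis change, and satisfies `Y(Ru) = D(R) Y(u)` to machine precision.

## 2. The transformer block

Each of `T` blocks performs Euclidean self-attention followed by an
interaction update:

1. Per directed edge `(i, j)`: the geometric shift `x_ij = x_j - x_i` is
   contracted to one invariant per degree; distances are expanded in `K`
   radial basis functions; a two-branch filter MLP maps both to an
   `F`-dimensional filter `w_ij`.
2. Attention coefficients are signed dot products
   `alpha = d^-1/2 q_i^T (w_ij * k_j)` with `q = Q f`, `k = K f`,
   computed on `h` slices of width `F/h` for the feature channel and on
   one slice of width `F/n_degrees` per degree for the EV channel (the
   same `q`, `k`, `w` vectors, sliced differently). There is no softmax:
   coefficients are signed reals, which lets messages both attract and
   repel.
3. Features aggregate `phi(r_ij) alpha_ij V f_j` (the value matrix `V` is
   included; setting `V = I` recovers the plain aggregation of the
   features themselves); EV aggregate
   `phi(r_ij) alpha_ijl Y_lm(r_hat_ij)`. Both updates are additive skip
   connections, and the cosine cutoff `phi` guarantees that every
   pairwise term vanishes smoothly at `r_cut`, so the potential energy
   surface is continuous as atoms cross the cutoff sphere.
4. The interaction block maps `concat(f_att, contraction(x_att))` through
   a single silu layer to a feature refinement `a` and one gain `b_l` per
   degree, applied as `f <- f_att + a`, `x_lm <- (1 + b_l) x_att,lm`.
   With zero weights the block is exactly the identity.

Per-atom energies come from a two-layer readout MLP
(`F -> F/2 -> 1`, silu), scaled and shifted per element, and are summed.
Invariance of the energy and block-wise equivariance of the EV are tested
property-style (random systems, random weights, 100 trials).

**Parameters that matter.**

| parameter | meaning | default |
|---|---|---|
| `feature_dim` (F) | invariant feature width | 132 |
| `heads` (h) | invariant attention heads | 4 |
| `n_blocks` (T) | transformer blocks | 3 |
| `degrees` | EV degrees (max 3) | 0:3 |
| `r_cut` | interaction cutoff, A | 5 |
| `n_rbf` (K) | radial basis functions | 32 |
| `rbf_length_scale` | length scale of the radial basis, A | 1 |
| `ev_init` | EV seeding (`neighborhood`/`zeros`) | neighborhood |

`F` must be divisible by `h` and by the number of degrees. The mean
neighbor count `<N>` is a dataset statistic fitted at training time and
frozen into the model.

**Radial basis length scale.** The basis
`g_k(r) = exp(-gamma (exp(-r/l) - mu_k)^2)` with centers equally spaced
in `[exp(-r_cut/l), 1]` has its resolution concentrated where
`exp(-r/l)` varies, i.e. at `r` of order `l`. The conventional `l = 1` A
suits covalently bonded molecules (bonds 1–2 A). For rare-gas clusters
with `sigma = 3.4` A nearly all relevant distances collapse into a
fraction of one basis width at `l = 1`, and training force errors plateau
roughly sixfold higher; the Lennard-Jones experiments therefore use
`l = 3` A (the `sigma` scale) and `r_cut = 8` A so the cutoff sphere
covers the whole cluster. The rule of thumb: set `l` to the typical
nearest-neighbor distance.

## 3. Forces and training without an autodiff framework

Forces are the exact gradient of the energy, computed by a hand-written
reverse pass mirroring the forward pass; they match central finite
differences (`h = 1e-4` A) to better than `1e-5` relative and sum to zero
by translation invariance.

Training minimizes `(1-beta)(E-E~)^2 + beta/(3n) sum (F-F~)^2` with
`beta = 0.99`, Adam at `eta0 = 1e-3`, and exponential decay by 0.7 at a
configurable interval (the production protocol decays every 100k steps;
desk-scale runs use shorter intervals scaled to their length). The batch
size follows the dataset-size rule (1 if the training split has at most
1000 structures, else 10). The force term of the loss gradient needs
`d2E/(dr dtheta)`; the package computes it as a **complex-step
directional derivative**: running the (complex-safe) forward+reverse code
at positions `r + i h (F - F~)` and taking `Im(grad_theta E)/h` with
`h = 1e-10` gives the exact Hessian-vector product without subtractive
cancellation. This is verified against finite differences of the loss.

Validation is split off with the training seed before training; the
best-validation parameters (evaluated every `eval_every` steps) are
returned. Runs are bit-reproducible given the seed on a single thread,
with one caveat: the very first invocation in a fresh R session can
differ in the last float bit from all later ones while R's JIT compiles
the run-time closures, and chaotic loss landscapes amplify that bit; the
reproducibility test therefore compares the second and third runs.

## 4. Molecular dynamics

Units are Angstrom / fs / eV / amu; `k_B = 8.617333262e-5` eV/K and the
acceleration conversion `0.009648533212` (A/fs^2 per eV/A/amu) are fixed
to 10 significant digits. Engines: velocity Verlet (NVE), Langevin in the
BAOAB splitting (`gamma` in 1/fs; `gamma = 0` reduces exactly to
Verlet), and a single Nose-Hoover thermostat in relaxation-time form,
`dxi/dt = (T/T0 - 1)/tau^2`, integrated time-reversibly with the
velocity scalings `exp(-xi dt/2)` on both sides of a Verlet core
(default `tau = 100 dt`). Energy-conservation checks (NVE total energy, the Nose-Hoover extended
energy) bound the *secular* drift — the linear-fit slope times the run
length — because the endpoint difference also samples the bounded
`O(dt^2)` oscillation of the integrator's shadow Hamiltonian.
Maxwell-Boltzmann initialization removes the center-of-mass momentum and
either draws at twice the target temperature (the standard start for NVE
from a relaxed structure) or rescales to the target exactly. The
temperature convention is `N_dof = 3N - 3` for isolated systems, `3N`
for periodic ones.

**Equipartition at a minimum.** Starting NVE exactly at a harmonic
minimum with instantaneous temperature `T0`, each vibrational mode keeps
half of its initial kinetic energy on time average, so `mean(T) ~ T0/2`.
For a finite molecule the three free rotations keep *all* of their
initial kinetic energy, so the exact expectation is
`mean(T)/T0 = N/(2(N-1))` — the package's equipartition check uses a
100-atom elastic-network molecule (expected ratio 0.5051), where the
rigid-body correction is inside the 2% band; a small molecule cannot
exhibit the textbook 0.5.

## 5. Stability diagnostics

An MD run is called stable while (A) the instantaneous temperature stays
below `spike_factor` (default 100) times the target — the signature of a
non-physical "explosion" — and (B) every designated bond stays within
50% of its reference length. Bonds are detected as pairs closer than 1.25
times the sum of covalent radii (both factors configurable; the 50% bound
is the substantive criterion, the others are operational choices). The
stability coefficient `c_s = n_s/n_tot` is the fraction of planned steps
completed before the earliest failure, 1 for a clean run. Because the
check scans stored frames, a denser stride can only detect a failure at
the same or an earlier physical time.

## 6. Observables

* `rdf`: shell-normalized pair-distance histogram with ideal-gas
  normalization for periodic systems; for isolated molecules there is no
  bulk density, so the normalized pair-distance density is returned.
* `vacf_spectrum`: `C(t) = <v(0).v(t)>` averaged over atoms and time
  origins (FFT-based, unbiased origin weighting), Hann window, zero
  padding to the next power of two, one-sided intensity on a wavenumber
  axis in 1/cm. Mass weighting is off by default and toggleable.
* `normal_modes`: Hessian from central differences of the *analytic*
  forces (step `1e-3` A), mass weighting, projection of the rigid-body
  space (rank-aware, so linear molecules lose 5 modes, nonlinear 6),
  frequencies from the eigenvalues and `ZPE = hbar/2 sum omega`.
  Negative-curvature directions beyond tolerance are reported as
  imaginary frequencies and flag a non-minimum.
* `zpe_temperature`: distributes a ZPE over `3n - 6` vibrational degrees
  of freedom, `T = E/( (3n-6) k_B )`; with 56 atoms and 12.979 eV this
  gives ~930 K, which pins the degree-of-freedom convention.
* `radius_of_gyration`, `end_to_end_distance`, `dihedral` (IUPAC signed
  torsion) complete the set used for conformational analyses.

The spectral consistency check synthesizes exact normal-mode dynamics
from the computed modes and verifies that the VACF spectrum peaks at the
same frequencies within one FFT bin — an internal consistency test
between two independent code paths.

## 7. Minima hopping and disconnectivity

The explorer alternates escape MD (Maxwell-Boltzmann velocities rescaled
exactly to the current `T`, NVE for `escape_fs`) with L-BFGS relaxation
to `max |F_atom| < 1e-4` eV/A. A candidate is identified with a stored
minimum when the RMSD — centers of mass removed, minimized over proper
rotations by the Kabsch construction with the determinant constraint —
is at most 0.1 A. Atom order is fixed: permutants of identical atoms
count as distinct entries (a known limitation for symmetric clusters;
distinct *energy levels* are unaffected). Adaptation follows the
standard convention: `T` is multiplied by 1.05 when an escape returns a
known minimum and divided by 1.05 for a new one; the acceptance window
`E_diff` widens on rejection and narrows on acceptance. The
transition-state estimate between two minima is the maximum potential
energy observed along the connecting escape path — an upper bound; when
a pair is crossed repeatedly the smallest observed maximum is kept. The
disconnectivity graph merges minima by union-find over an ascending
energy grid; disconnected basins are reported, not an error.

Defaults `T0 = 1000 K`, `E_diff = 2 eV` suit covalently bonded molecules.
For argon-parameter Lennard-Jones clusters those values would vaporize
the system (`k_B * 1000 K ~ 8 epsilon`); the cluster experiments use
`T0 = 40 K`, `E_diff = 0.02 eV`, 5 ps escapes at `dt = 5` fs, which the
heavier mass and softer landscape justify.

## 8. What the synthetic data does and does not show

The generators produce thermally sampled, analytically labeled
configurations: Langevin sampling of an argon-parameter LJ cluster
(defaults: `epsilon = 0.0104` eV, `sigma = 3.405` A, 30 K — the
anharmonic-vibration regime of the solid-like cluster), harmonic and
elastic-network molecules with exact spectra, and a double-well diatomic
with a closed-form barrier. They emulate the *shape* of quantum-chemistry
datasets (configurations + energies + forces, thermal sampling, smooth
labels) but not their electronic-structure content: no bond
breaking/formation, no charge transfer, label noise exactly zero, and
force scales (~0.01 eV/A at 30 K) far below covalent ones. Passing the
desk-scale learning test therefore demonstrates that the architecture,
gradients and training loop work end to end — not that the model reaches
benchmark accuracy on real molecules.

## 9. Numerical choices and problem sizes

Double precision throughout. Desk-scale problem sizes used by the test
suite and the acceptance script: 1000 LJ7 frames / 10k training steps for
the learning check; 10^4 NVE steps for conservation; 100 symmetry trials;
10^4 restarts for the minima-hopping oracle; 4096-frame spectra. The
checkpoint format is JSON with 17 significant digits, which round-trips
IEEE doubles bit-exactly. Degenerate inputs are checked explicitly:
non-unit directions, improper rotations, out-of-table elements, empty
neighborhoods (isolated atoms are handled exactly — both network states
pass through unchanged), single-atom temperature (an error by
convention), disconnected bond topologies, and corrupted checkpoints.

## 10. Known limitations

* Network degrees are limited to `l <= 3` (the degrees the architecture
  uses); the math layer supports arbitrary degree.
* No long-range electrostatics/dispersion beyond the cutoff and no
  Ewald summation; periodic support is minimum-image with the half-cell
  cutoff restriction.
* No permutation-invariant structure identity in the explorer.
* Single Nose-Hoover thermostat (not a chain): on purely harmonic
  systems it is weakly ergodic, and thermostat checks use anharmonic or
  Cartesian-anharmonic fixtures.
* Training is practical at desk scale (tens of thousands of steps on
  small models); it is a faithful, not a fast, implementation.
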