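---
title: "Single-trajectory semiclassical vibrational spectra: models, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-trajectory semiclassical vibrational spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scivr)
```

## The problem

Hydrogen-bonded complexes such as the guanine–cytosine (GC) base pair are
assigned from their high-frequency NH/OH stretch spectra, where anharmonicity
and hydrogen-bond red shifts of tens to hundreds of cm⁻¹ decide between
tautomers. Harmonic frequencies scaled by empirical factors (0.893 for NH,
0.867 for OH stretches) are the traditional workaround; single-trajectory
semiclassical dynamics offers a quantum-aware alternative at a cost comparable
to one classical trajectory. This package implements that machinery —
quasiclassical trajectory (QCT) spectra, time-averaged semiclassical initial
value representation (TA SCIVR) spectra with multiple-coherent (MC) reference
states, and divide-and-conquer (DC SCIVR) subspace projection — on analytic
model potentials whose exact quantum levels are available from an independent
sinc-DVR oracle, plus the downstream peak-assignment workflow (peak picking,
FWHM, scaled-harmonic comparison, mean absolute errors, spectral-signature
classification).

Everything internal is in Hartree atomic units with ħ = 1, in mass-scaled
normal coordinates (every degree of freedom has unit mass). Wavenumbers,
angstroms and femtoseconds appear only at I/O boundaries.

## Model systems and what they emulate

The built-in surfaces stand in for on-the-fly ab initio surfaces:

* `make_harmonic(omega, coupling)` — separable or bilinearly coupled harmonic
  modes; the exactly solvable baseline on which the semiclassical machinery
  must be exact.
* `make_morse(D, alpha, mass)` — the canonical anharmonic stretch. With
  D = 0.25 hartree, α = 1 bohr⁻¹ and a proton-scale mass of 1836 mₑ the
  harmonic frequency is 3622 cm⁻¹ and the fundamental 3502 cm⁻¹ — the NH/OH
  stretch scale with a realistic ~120 cm⁻¹ anharmonic shift. Bound levels are
  known in closed form.
* `make_hbond_mimic(omega_stretch, omega_bath, coupling)` — the minimal
  hydrogen-bond model: a fast stretch r (default 3450 cm⁻¹) cubically coupled
  (c·r²R) to a slow donor–acceptor "bath" coordinate R (default 330 cm⁻¹, a
  typical intermolecular H-bond mode). The r²R form shifts the effective
  stretch curvature ω_r² + 2cR without moving the minimum, so increasing c
  red-shifts the stretch at fixed initial conditions — the model-level
  restatement of "a stronger hydrogen bond perturbs the NH stretch more". The
  defaults and the sweep 0…9×10⁻⁷ used in the tests span shifts from 0 to
  ~190 cm⁻¹, the range separating weakly and strongly H-bonded NH stretches.

What these models do **not** emulate: mode count (a 29-atom dimer has 81
vibrations), Fermi resonances between stretch fundamentals and bend overtones,
rotational structure, and dipole weighting (all spectra here are power
spectra, not IR absorption). Passing tests on these models validate the
machinery — integrator, phases, projections, assignment logic — not the
quality of any real molecular surface.

## The quantum oracle

`grid_oracle()` diagonalizes the sinc (Colbert–Miller) DVR Hamiltonian on a
uniform grid, refined by doubling until the highest requested level moves by
less than 10⁻⁸ hartree. It shares no code with the trajectory machinery, so
agreement between the two is meaningful. The automatic grid range finds the
classical turning points at an energy covering the requested states and
extends 60% into the forbidden region per side. On the Morse model above the
oracle agrees with the closed-form levels to better than 0.1 cm⁻¹ for the
lowest five states.

## Trajectories, monodromy and phases

`propagate()` integrates Hamilton's equations with velocity Verlet (default
dt = 10 au, 2500 steps = 25 000 au ≈ 605 fs). The monodromy matrix is
advanced with the *same* kick–drift–kick splitting using the local Hessian,
so each factor is exactly symplectic and the accumulated MᵀJM − J defect
stays at roundoff (< 10⁻¹² in practice, bounded at 10⁻⁶ in the tests). The
classical action S_t = ∫(T − V)dt accumulates by the trapezoidal rule on the
step grid.

**Energy conservation.** A symplectic integrator exactly conserves a shadow
Hamiltonian; the measured energy therefore *oscillates* with amplitude
~(ωdt)²/8 (≈10⁻³ relative at ωdt = 0.1) but does not drift. Two metrics are
monitored: the instantaneous fluctuation max|E(t) − E₀|/|E₀| (bounded by
`fluct_tol`, default 10⁻²; halving dt reduces it 4×, the second-order
signature) and the secular drift. The drift estimator regresses E(t) on a
line plus the leading shadow-correction regressors (pᵀV″p and |∇V|² along
the path) plus sinusoids at the dominant periodogram frequencies of the
residual; the coefficient of t, times T/|E₀|, is the secular drift. This
removes the bounded oscillation without masking genuine drift and lands at
10⁻⁹–10⁻¹⁷ for all model surfaces at dt = 10, against the 10⁻⁶ bound.

**The prefactor phase.** The Herman–Kluk prefactor
C_t = √det½(M_qq + Γ⁻¹M_ppΓ − iM_qpΓ + iΓ⁻¹M_pq) enters the working spectrum
formula only through its phase φ_t (the "separable approximation"). The
square-root branch is tracked by unwrapping the argument of the determinant
between consecutive steps, never by a principal-value square root. The sign
convention is pinned by an analytic test: for the 1D harmonic oscillator with
Γ = ω, C_t = e^{−iωt/2}, i.e. φ_t = −ωt/2. Determinants passing through zero
abort with advice to reduce dt.

**Velocity Verlet renormalizes frequencies** by the factor 1 + (ωdt)²/24
(≈ +0.9 cm⁻¹ at 2200 cm⁻¹ for dt = 10). Spectra that must localize peaks to
one 1 cm⁻¹ grid point are therefore run at dt = 2–5 au; the mechanics checks
stay at the dt = 10 default, where the renormalization is irrelevant to the
symplectic and drift metrics.

## Spectra

`qct_spectrum()` implements
I_j(E) = (2πħT)⁻¹ |∫₀ᵀ p_j(t) e^{iEt/ħ} dt|²
per normal mode. The finite observation time imposes a sinc² line shape with
main-lobe FWHM 5.566/T — 48.9 cm⁻¹ at T = 25 000 au, which is why all
linewidths on bound models sit near 50 cm⁻¹. No window is applied by default
(the finite-time shape is the physics); a Hann window is available for
side-lobe suppression. The normalization prefactor is a convention — only
peak positions are compared to references. The quadrature kernel (trapezoid
on the stored grid, evaluated at arbitrary energies in chunks) is
cross-checked in the tests against a zero-padded FFT on the aligned grid to
10⁻⁸ relative.

`ta_scivr_spectrum()` implements
I(E) = (2πħ)^{-N_v}(2πħT)⁻¹ |∫₀ᵀ dt ⟨Ψ|g_t⟩ e^{i(S_t + Et + φ_t)/ħ}|²
with coherent-state widths Γ_j = ω_j (the standard SCIVR choice, maximizing
overlap with harmonic eigenstates). It is exact on quadratic surfaces: peaks
at Σ(n_j + ½)ħω_j to within one grid point.

`mc_reference()` builds the multiple-coherent two-term reference
|g(p_eq, q_eq)⟩ ± |g(p̃, q_eq)⟩ with the target mode's momentum sign flipped.
Parity −1 annihilates even-quantum lines, +1 the odd ones. Besides amplifying
weak transitions this removes sinc-tail interference from neighboring strong
lines, which otherwise pulls a weak peak by a few cm⁻¹ — the parity-projected
references are what the harmonic-exactness checks use.

**Tailored trajectories.** A stationary-phase analysis of the time-averaged
integral shows that a single trajectory at energy E places the k-th peak at
E₀(E) + k·ω_cl(E), with ω_cl the classical frequency at that energy. Each
quantum state is therefore probed by a trajectory *tailored* to it: harmonic
initial conditions with n quanta in the target mode. On the Morse model the
n = 0 trajectory reproduces the oracle ZPE within 2 cm⁻¹ and the n = 1
trajectory the E₁ level within 3 cm⁻¹; asking the n = 0 trajectory for E₁
instead returns E₀ + ω_cl(E₀), ~59 cm⁻¹ high — a property of the
single-trajectory method, which the tailoring is designed to fix, not an
implementation artifact.

## Divide and conquer

`dc_spectrum()` evaluates the same formula with every ingredient restricted
to a subspace of normal modes while the trajectory remains full-dimensional:
subspace components of (q_t, p_t), subspace sub-blocks of the monodromy for
φ_t, and a projected action whose potential term is either

* `difference` (default): Ṽ(t) = V(q_t) − V(q_t with subspace coordinates
  reset to equilibrium), or
* `clamped`: Ṽ(t) = V(subspace coordinates from the trajectory, all others
  at equilibrium).

The projected potential is the genuinely under-determined ingredient of the
method; both variants ship and coincide exactly on separable surfaces, where
the subspace spectrum equals the corresponding lower-dimensional TA SCIVR
spectrum to 10⁻⁸ relative (machine precision in practice). The sub-block
monodromy is extracted without re-symplectification; its symplectic defect is
logged per step and the maximum reported in the spectrum metadata, making the
approximation observable. Note that subspace spectra measure energies
*without* the excluded modes' zero-point energy; comparisons with full-space
spectra are made on transitions (E₁ − E₀), which agree within one grid point
on the H-bond mimic.

`partition_modes()` groups modes greedily by descending |LᵀH L| off-diagonal
magnitude, ties broken by lowest index, respecting a maximum subspace size;
modes with all couplings below threshold stay singletons. Because the
equilibrium Hessian is diagonal in its own normal-mode basis, an optional
`displacement` probes Hessians displaced along each mode — that is how the
cubic stretch–bath coupling of the H-bond mimic, invisible at equilibrium,
is detected.

## Assignment workflow

`pick_peaks()` takes local maxima above a relative height threshold and
interpolates the half-height crossings linearly for the FWHM. `mae()` pairs
computed against reference lines, drops rows without a reference (e.g. lines
suppressed by alkylation in the locked-tautomer experiment), and reports the
raw mean absolute deviation alongside its half-up integer rounding, because
published tables print integers. On the packaged GC line list the
scaled-harmonic Watson–Crick rows give exactly 48.0; the keto–enol rows give
15.2 (DC SCIVR) and 25.2 (scaled harmonic), rounding to 15 and 25. The
published Watson–Crick DC-SCIVR summary value of 43 is *not* reproduced by
its own rows, which give 43.67; the raw float is always reported rather than
forcing agreement.

`assign_tautomer()` evaluates windowed presence/absence rules with optional
FWHM bounds against a peak list. The shipped rule file encodes the two
signatures that discriminate the GC tautomers: a *sharp* guanine NH₂ stretch
near 3436 cm⁻¹ (keto–enol form, weak H-bond) versus a *broad* H-bonded NH
stretch near 3283 cm⁻¹ (Watson–Crick form). "Broad" defaults to FWHM >
60 cm⁻¹, between the ~50 cm⁻¹ finite-time floor of bound species and the
~125 cm⁻¹ width of metastable ones. Contradictory rules are rejected at load.

## A worked model run

```{r demo, eval = FALSE}
demo <- system.file("extdata", "demo_hbond.yaml", package = "scivr")
out <- run_pipeline(demo, outdir = tempdir())
out$assignment$label
#> [1] "K7E-1-like"
```

The demo config propagates the H-bond mimic at weak coupling (3×10⁻⁷) for
25 000 au, computes QCT and DC-SCIVR spectra, and classifies the sharp
stretch peak at 3434 cm⁻¹ (FWHM ≈ 49 cm⁻¹) as keto–enol-like. Reruns are
byte-identical: the pipeline has no stochastic stage, and every artifact
carries the config hash.

## Numerical choices and degenerate inputs

* Finite-difference Hessians (surfaces without an analytic one): central
  differences of the gradient, step 10⁻³ mass-scaled bohr.
* Hessian eigenvalues in (−10⁻⁸, 10⁻⁸) hartree² are zero modes; more
  near-zero modes than the projected rigid-body count is an error. Negative
  eigenvalues beyond tolerance are reported as imaginary modes, never
  dropped.
* The Eckart rotational projection is applied to Cartesian molecular systems
  by default and is meaningless for abstract model systems (none of which
  carry rotations); center-of-mass translation is always projected for
  Cartesian systems.
* Tied couplings in `partition_modes()` break by lowest mode index.
* Flat or empty spectra yield empty peak lists; a peak whose half-height
  crossing leaves the grid reports `NA` FWHM and matches only rules without
  FWHM bounds.
* Problem sizes throughout (2 500–12 500 steps, 1–2 modes, ≤ 128 DVR points
  per dimension) are chosen so that every model-level claim is testable in
  seconds while the finite-T physics (linewidths, sidelobe interference) is
  the same as at production scale.

## Limitations

Single-trajectory TA SCIVR probes one energy shell per run (hence the
tailoring); many-trajectory phase-space-averaged SCIVR is out of scope. No
dipole surfaces, so intensities are power-spectral weights, not IR cross
sections. The external-engine adapter defines the contract for on-the-fly
ab initio surfaces (energy/gradient per geometry, cached by geometry hash)
but no engine ships with the package. The classifier reports
spectral-signature matches only; it decides nothing about mutagenesis or
biology.
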