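---
title: "Ionic plasmons in membrane-bounded electrolyte spheres: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ionic plasmons in membrane-bounded electrolyte spheres: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionplasm)
```

## The physical model and its assumptions

`ionplasm` treats a binary electrolyte confined to a sphere of radius $a$ by
an electrically neutral, insulating membrane. Both ion species are mobile;
charge conservation couples their fluctuations, and the package adopts the
effective-jellium picture: each species oscillates against a fictitious
rigid background of the opposite sign, the two backgrounds cancelling
exactly. This reduces the two-component dynamics to a pair of identical
one-component problems, formally the same as the jellium model of a metallic
nanosphere, and is a controlled idealization for *small* density
fluctuations with equal (or similar) ion masses and charges.

The density-fluctuation dynamics is linearized in the random-phase
approximation (RPA): products of fluctuations are dropped, and the mean ion
kinetic energy is taken from Maxwell–Boltzmann statistics — the electrolyte
is classical and non-degenerate, so a Thomas–Fermi (degenerate Fermi gas)
closure would be inappropriate. Point-like ions carry $3kT/2$; linear and
three-dimensional ionic molecules add rotational degrees of freedom,
$5kT/2$ and $6kT/2$, exposed as the factor `dof_factor` $f \in \{3,5,6\}$
(default 3).

The resulting mode structure:

* **Surface modes** ($l \ge 1$, charge confined to $r = a$):
  $\omega_{0l} = \omega_p\sqrt{l/((2l+1)\varepsilon_1)}$, temperature
  independent, renormalized by the outer permittivity $\varepsilon_1$. There
  is no $l = 0$ surface mode (total charge conservation).
* **Volume modes** ($l \ge 1$, $i \ge 1$, radial profile
  $j_l(x_{li} r/a)$ vanishing at the membrane):
  $\omega_{li} = \omega_p\sqrt{1 + (f/3)\,kT x_{li}^2/(\omega_p^2 a^2 m)}$,
  always $\ge \omega_p$, thermally stiffened. Because the electric field of
  surface charges vanishes inside the sphere, the volume problem is
  insulated from the surroundings; the $\varepsilon_1$ renormalization is
  therefore applied to surface modes only. Volume modes *induce* surface
  oscillations through the coupling implemented in
  `induced_surface_amplitude()`; the reverse coupling is absent.

A spatially uniform driving field (the long-wavelength/dipole approximation,
excellent here since resonant wavelengths exceed the sphere size by orders
of magnitude) couples only to the $l = 1$ surface channel, whose Cartesian
dipole moment scales as the system volume $a^3$.

## Parameters

| Parameter | Symbol | Units | Preset values | Notes |
|---|---|---|---|---|
| radius | $a$ | m | 1e-6 (nominal) | sweeps supply their own grids |
| molarity | $\eta$ | mol/L | 1e-2 / 1e-3 | $n = \eta N_0$, $N_0 = 6.02214\times10^{26}$ m$^{-3}$/M |
| charge number | $Z$ | — | 3 | effective charge $q = Ze$, screened as $q/\sqrt\varepsilon$ |
| effective mass | $m$ | kg | $10^4 m_e$ | hydrated-ion scale |
| temperature | $T$ | K | 300 | room temperature |
| inner permittivity | $\varepsilon$ | — | 1 | folded into the effective charge in the presets |
| outer permittivity | $\varepsilon_1$ | — | 2 | membrane/surroundings |
| boundary constant | $C$ | — | 2 | order unity, membrane specific |
| bulk mean free path | $\lambda_b$ | m | 1e-7 / 3e-7 | ion–ion/solvent scattering |
| dof factor | $f$ | — | 3 | 3 point ions, 5 linear, 6 3D molecules |

The presets pin $\omega_p$ explicitly ($9.3\times10^{13}$ and
$2.93\times10^{12}$ rad/s) via `plasma_frequency_override` rather than
deriving it from $n$, $Z$, $m$. These canonical values are not reproduced by
the standard formula from the same parameter rows; rather than silently
altering either, every downstream operation accepts $\omega_p$ as an input
and the presets carry the canonical values, while `plasma_frequency()`
computes the SI formula whenever no override is set. The two sample sets are
also not mutually consistent under $\sqrt n$ scaling; comparisons across
presets should therefore treat each as an independent parameter set.

## Damping model

Two channels, with opposite size dependence:

* **Scattering** (Ohmic-type): $1/\tau_0 = v/(2\lambda_b) + Cv/(2a)$ with
  $v = \sqrt{3kT/m}$. The $1/a$ membrane term dominates for small spheres.
* **Radiation (Lorentz friction)**: the radiation-reaction field
  $\mathbf E_L = (2/(3c^3))\,\partial_t^3 \mathbf D$. To first order it adds
  $(\omega_1/(3\sqrt{\varepsilon_1}))(\omega_p a/(c\sqrt3))^3$ to the rate
  — the $a^3$ law.

The total perturbative rate is minimal at
$a^* = (9Cv\varepsilon_1 c^3/(2\omega_p^4))^{1/4}$. Two printed variants of
this closed form circulate ($\omega_p^3$ vs $\omega_p^4$ in the
denominator); the package implements the $\omega_p^4$ form because it is
the one that is dimensionally a length$^4$ under the fourth root, it is the
exact stationary point of the implemented rate (verified against a numerical
minimizer on every call), and it reproduces the canonical
$a^* = 2.7\times10^{-7}$ m to within $\sim$9%.

The perturbative description fails when the dimensionless attenuation
$u + g/2$ (with $u = 1/(\tau_0\omega_1)$,
$g = (2/(3\sqrt{\varepsilon_1}))(a\omega_p/(c\sqrt3))^3$) reaches 1: the
red-shifted frequency $\omega_1' = \omega_1\sqrt{1 - 1/(\omega_1\tau)^2}$
is driven to zero. (One printed source states this self-referentially;
the formula above is the intended reading.) `perturbative_limit_radius()`
finds that onset radius $a_{limit}$ by bracketed root finding and reports
$\tilde a = a_{limit}/2$ as the practical validity limit. An alternative
bookkeeping of the dimensionless rate ($2u + g$ instead of $u + g/2$)
differs only in a factor-2 convention and is numerically indistinguishable
at the preset parameters, where $u \sim 10^{-4}$.

In the coupling $g$, the velocity scale inside the cube is the speed of
light $c$: this is required dimensionally, matches the perturbative rate's
$(\omega_p a/(c\sqrt3))^3$, and is the only choice that lands the
characteristic radii on the canonical micrometre scale. (A thermal-velocity
symbol appears in one printed form of the dimensionless equation; it is
treated as a typo for $c$.)

### Exact treatment

Substituting $e^{i\Omega t'}$ (dimensionless time $t' = \omega_1 t$) into
the free dipole equation with the full third-derivative friction term gives
the cubic

$$ i g \Omega^3 - \Omega^2 + 2iu\Omega + 1 = 0 .$$

Its three roots are: a purely imaginary $\Omega_1$ with negative imaginary
part — the exponentially growing self-acceleration *runaway*, a known
artifact of radiation reaction, discarded by prescription — and a decaying
pair $\Omega_2 = \omega + i/\tau$, $\Omega_3 = -\omega + i/\tau$ that
carries the physical frequency and rate. `radius_max_damping()` locates the
radius $a^{**}$ of maximal Im $\Omega_2$; beyond it the exact rate
*saturates* while the perturbative $a^3$ law diverges, and the exact
solution remains oscillatory past $a_{limit}$.

## Numerical choices

* **Spherical Bessel nodes.** $j_l$ is evaluated via the half-integer-order
  Bessel function; nodes are bracketed by the interlacing property
  $x_{l-1,i} < x_{l,i} < x_{l-1,i+1}$ (starting from the exact
  $x_{0i} = i\pi$) and refined by bisection to machine precision. This is
  uniformly robust in $(l, i)$, unlike asymptotic expansions at small
  order. Enumeration caps: $l \le 60$, $i \le 100$, with explicit errors.
* **Cubic roots.** The printed closed-form radicals are evaluated with the
  principal complex cube root, with two safeguards: the radical's
  discriminant argument is expanded analytically (it cancels to
  $O(g^2)$ and would otherwise lose all digits for $g \lesssim 10^{-6}$),
  and each root is polished by a few complex Newton steps on the
  polynomial, since the oscillatory pair arises from cancellation of three
  $O(1/g)$ terms. Every call cross-checks the result against an independent
  polynomial solver (`polyroot`) with pairing by minimal distance. Root
  residuals are assessed as backward error (normalized by the polynomial's
  term magnitude), the meaningful measure for the $O(1/g)$ runaway root.
* **Classification thresholds.** Roots with $|\mathrm{Re}\,\Omega| <
  10^{-9}$ count as purely imaginary; if the remaining pair is also
  imaginary the solution is flagged over-damped and the frequency reported
  as 0.
* **Quadrature.** The radial coupling integral uses adaptive quadrature
  (`integrate`, rel.tol 1e-12); tests cross-check against a dense
  trapezoid rule and sphere quadrature (Gauss–Legendre × uniform azimuth)
  for harmonic orthonormality.
* **Time-domain integration.** The second-order dipole ODE is integrated
  with `deSolve::lsoda` (rtol 1e-10, atol scaled to the problem's natural
  dipole amplitude so zero-state starts remain well conditioned). The
  third-order radiation-reaction equation is *never* integrated directly —
  it is stiff and carries the runaway; instead the exact free decay is
  synthesized from the $\Omega_2/\Omega_3$ pair fitted to the initial
  conditions. The Lorentz field along a trajectory is obtained by
  cubic-spline differentiation of the stored second derivative and requires
  at least 4 samples per oscillation period.
* **Driven dynamics.** The right-hand prefactor of the dipole equation is
  taken as $\varepsilon_1 a^3\omega_1^2 = a^3\omega_p^2/3$, the reading
  consistent with the equation's own left-hand derivation; drives default
  to $E_0\cos(\omega t + \phi)$ with initial conditions
  $\mathbf D = \dot{\mathbf D} = 0$ (not prescribed by the model; stated
  here as the package default).
* **Degenerate inputs.** $g = 0$ falls back to the damped-oscillator
  quadratic; $T = 0$ collapses volume modes to $\omega_p$ exactly; the
  volume→surface coupling raises an explicit error within $10^{-9}$
  (relative) of its resonant denominator, a region outside the physical
  domain since $\omega_{li} \ge \omega_p$.

## What the presets emulate — and what they do not

The bundled parameter sets describe a micrometre-scale compartment of a
moderately dilute electrolyte with heavy, multiply charged effective ions —
the regime where the damping cross-over and strong radiative losses fall in
the experimentally interesting micrometre range. Passing tests demonstrate
internal consistency of the model at those conditions. They do **not**
demonstrate: Debye screening, ion pairing or activity corrections (the
jellium is ideal and uniform); retardation/full-Mie electromagnetic
corrections (frequencies are quasistatic); solvent absorption (water's
GHz rotational and ~50 THz vibrational windows overlap parts of the ionic
plasmon range and would mask resonances there in a real measurement); or
non-spherical geometries.

## Problem sizes

The test suite exercises the cubic solver on a $100\times100$
$(u, g)$ log grid, damping sweeps on 300-point log radius grids in
$[10^{-8}, 10^{-4}]$ m, trajectories of 3000–8000 samples spanning several
decay times, and sphere quadrature at 40 Gauss nodes × 80 azimuths — sizes
chosen so the full suite completes in seconds while leaving every assertion
comfortably resolved.

## Known limitations

* The effective-jellium reduction worsens as the two ion species' masses
  and charges diverge; the model is at its best for near-symmetric
  electrolytes.
* Surface and volume modes are strictly separated (no spill-out); this is
  accurate for membrane-bounded ions but would not capture sub-10-nm
  metallic clusters.
* `evolve_dipole(damping_model = "lorentz_exact")` supports free decay
  only: a driven exact-radiation trajectory would require the full
  third-order Green function, which the characteristic-root decomposition
  does not provide.
* The amplitudes of the homogeneous mode fields are arbitrary by
  construction; mixed-mode superpositions are reported per unit amplitude
  without an absolute normalization.
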