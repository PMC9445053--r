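---
title: "Orientation-factor analysis for tethered FRET dyes"
author: "fretkappa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orientation-factor analysis for tethered FRET dyes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretkappa)
```

## The model

Förster theory writes the energy-transfer rate between a donor and an
acceptor fluorophore as

$$k_T = \frac{9\ln 10\,\kappa^2\varphi_D}{128\pi^5 N_A n^4 \tau_D R_{DA}^6}\,J,$$

with the orientation factor $\kappa^2$, donor quantum yield $\varphi_D$
and lifetime $\tau_D$, spectral overlap $J$, medium refractive index $n$
and donor–acceptor distance $R_{DA}$. Dropping $k_T\tau_D$ defines the
Förster radius $R_0$ (the 50%-efficiency distance), and the measured rate
inverts to $R_{DA} = R_0 (k_T\tau_D)^{-1/6}$. Because
$R_{DA}\propto(\kappa^2)^{1/6}$, an error in the assumed $\kappa^2$
propagates gently but systematically into the distance.

$\kappa^2$ belongs to the *point-dipole* (DD) picture of the electronic
coupling,

$$V^{DD} = \frac{|\mu_D||\mu_A|\,\kappa}{4\pi\varepsilon_0 n^2 R_{DA}^3},
\qquad
\kappa = \hat\mu_D\cdot\hat\mu_A -
3(\hat\mu_D\cdot\hat e)(\hat\mu_A\cdot\hat e),$$

which is the leading multipole term and degrades when $R_{DA}$ is
comparable to the chromophore size — precisely the regime of a dye
conjugated next to a pigment ring. The transition-charge (TrESP)
coupling replaces the two point dipoles by per-atom transition charges
$q_i$ fitted to each molecule's transition density,

$$V^{TrESP} = \frac{1}{4\pi\varepsilon_0 n^2}
\sum_{i\in D}\sum_{j\in A}\frac{q_i q_j}{r_{ij}},$$

retaining all higher multipole orders at classical cost. The two pictures
are bridged by the *effective orientation factor*

$$\kappa^2_{\mathrm{eff}} = \left(\frac{R_{DA}^3}{|\mu_D||\mu_A|}
\sum_{i\in D}\sum_{j\in A}\frac{q_i q_j}{r_{ij}}\right)^{\!2},$$

the $\kappa^2$ a single DD interaction would need to reproduce the TrESP
coupling exactly. The $4\pi\varepsilon_0 n^2$ prefactor cancels in the
ratio, so $\kappa^2_{\mathrm{eff}}$ is screening-free, non-negative, and
invariant under rigid motions of the whole assembly. In the point-dipole
limit (internal charge separation small against $R_{DA}$) it converges to
the angle-formula $\kappa^2$; the test suite asserts agreement to $10^{-3}$
at $\delta/R \le 10^{-3}$.

Quantum-chemical inputs are deliberately out of scope: transition charges
are *inputs* (a delimited table with columns `index, element, q`), as are
coordinates (PDB via bio3d, or XYZ). The package's contribution is
everything downstream of them.

## Parameters, units and conventions

* Coordinates and distances: Å. Charges: units of the elementary charge
  e; transition dipoles: e·Å. Couplings: cm⁻¹ via the pinned constant
  $e^2/(4\pi\varepsilon_0) = 14.399645$ eV·Å $\times\ 8065.543937$
  cm⁻¹/eV $= 116140.97$ cm⁻¹·Å (`fret_constants()` is the single source
  of truth, documented to 7 significant digits).
* **Spectral overlap**: `J_M1cm3` is the overlap integral in M⁻¹cm³.
  Inside the Förster expressions it becomes $J' = 1000\,J$ cm⁶ mol⁻¹ and
  meets the Avogadro constant. Literature values quoted simply in "cm⁶"
  are numerically identical under this convention; with it, the
  experimental parameter set of the LH2–A647 conjugate
  ($\varphi_D = 0.2$, $\tau_D = 0.8$ ns, $J = 2.6\times10^{-13}$ M⁻¹cm³,
  $n = 1.45$, $k_T = 2.7\times10^{11}$ s⁻¹) reproduces the reference
  distances 17.8 Å ($\kappa^2 = 2/3$) and 20.5 Å ($\kappa^2 = 1.55$).
  This convention is locked by the acceptance tests.
* **Screening**: the DD and TrESP couplings accept an explicit
  `n_screen` with default 1 (unscreened), because published coupling
  values do not always state which index they include;
  $\kappa^2_{\mathrm{eff}}$ needs no choice since screening cancels.
* **Isotropic averages**: `isotropic_kappa_mc()` reports both
  $E[\kappa^2]$ (analytically $2/3$, the dynamic convention) and
  $(E[|\kappa|])^2$ (the static convention). The static literature value
  0.476 matches the $(E[|\kappa|])^2$ convention — an independent
  numerical quadrature of the three-angle integral gives 0.47623 — and
  that is the convention this package implements and reports.
* Comparisons against values printed to 0.1 Å use half-up rounding
  (`round_half_up`), matching how printed tables are produced.

## The Euler-angle scan

`orientation_scan()` enumerates donor orientations as z–y–z Euler triples
$R = R_z(\gamma)R_y(\beta)R_z(\alpha)$ on a full
$[0^\circ, 360^\circ)^3$ grid. The full range on all three angles is
intentionally redundant ($\beta$ over half the range would already cover
orientation space): counts like $18^3 = 5832$ at a 20° step follow the
full-range convention, and the redundancy is harmless for ranking.
Rotation is about the donor's all-atom centre of mass; the acceptor, the
environment and $R_{DA}$ are constants of the scan. A rotated structure
is discarded when any of its atoms (hydrogens included) lies *strictly*
closer than the cutoff (default 1 Å) to any environment atom; a pair at
exactly the cutoff survives. The brute-force minimum over all atom pairs
is the defining clash semantics. Survivors are ranked by
$\kappa^2_{\mathrm{eff}}$, ties broken lexicographically by
$(\alpha, \beta, \gamma)$, and the unrotated reference $(0,0,0)$ is
always evaluated and reported first. The accompanying angle table
reports $\theta_{DA}, \theta_D, \theta_A$ for interpretation only — the
tabulated orientation factor is the transition-charge value, which the
angle formula reproduces only in the point-dipole limit.

## Trajectory statistics

`frame_metrics()` evaluates one snapshot: the geometric distance between
configured reference points (a donor atom selection, e.g. a π-conjugated
plane, against an acceptor reference atom, e.g. a central Mg), the
effective orientation factor *at that frame's instantaneous distance*,
the TrESP coupling, and the Förster-inverted distance obtained by
substituting the frame's $\kappa^2_{\mathrm{eff}}$ into the fixed
experimental parameter set (the measured $k_T$ is not varied per frame).
Transition charges are held fixed across frames — they are computed once
for a reference geometry — which is a documented approximation, not a
physical claim.

`aggregate_frames()` reports both routes from an ensemble to one
distance: inverting once at the mean $\kappa^2$, and averaging the
per-frame inversions. They agree exactly for a constant ensemble;
otherwise the per-frame average is smaller because
$R\propto(\kappa^2)^{1/6}$ is concave (Jensen), and the tests assert that
direction on synthetic ensembles.

## What the synthetic generators emulate

The generators replace the two expensive upstream stages (MD sampling and
quantum-chemical charge fitting) with seeded constructions whose ground
truth is known:

* `make_point_dipole()` — two charges $\pm q$ at separation $\delta$: the
  ideal-dipole realization used to probe every point-dipole limit.
* `make_chromophore()` — a planar carbon ring whose charges are the
  minimum-norm solution of $\sum q_i = 0$ and $\sum q_i r_i =
  \mu_{\mathrm{target}}$, both satisfied exactly. Planarity makes an
  out-of-plane target provably infeasible, which is tested as an error.
* `make_restricted_trajectory()` — the linker-restriction cartoon: the
  donor dipole axis wobbles uniformly *in solid angle* (uniform in
  $\cos\theta$, uniform azimuth — stated so recovery targets are
  well-defined) inside a cone about its initial direction, with uniform
  distance jitter along a fixed separation axis. Defaults follow the
  study conditions the package addresses: 0.1 ns frame spacing and
  centre distances near 25 Å. The generator computes its own mean
  $\kappa^2$ target by large-sample Monte Carlo using straight-line
  vector code that deliberately duplicates the $\kappa$ formula instead
  of calling the pipeline, so a pipeline bug cannot validate itself.
* `make_protein_shell()` — a spherical cap of environment atoms covering
  a chosen solid-angle fraction: the "crowded protein" surrogate for
  clash filtering. For a donor with a single protruding tip at the shell
  radius, `shell_occlusion_prediction()` counts, by pure angle
  arithmetic independent of the scan code, which fraction of the Euler
  grid must clash. Two subtleties matter and are built in: the z–y–z
  grid is uniform in $\beta$, not in $\cos\beta$, so grid tip directions
  are *not* uniform on the sphere (a cap about a tilted axis gives the
  prediction finer granularity than one about +z); and in the
  dense-shell limit a tip just outside the cap still clashes within a
  rim of angular width $2\arcsin(\mathrm{cutoff}/2r)$. The acceptance
  suite uses a calibration held fixed after a pilot enumeration: cap
  coverage 0.79 about the axis $(1,0,1)/\sqrt2$, shell radius 10 Å, 4000
  shell atoms, cutoff 1 Å, step 20°, predicting 78.4% removal; ten
  seeded shells reproduce it within five percentage points.

What passing these tests does *not* show: real proteins are not thin
spherical caps, real dye wobble is not a uniform cone, and real
transition charges have multipole structure a minimum-norm ring only
caricatures. The generators validate the *machinery* — limits,
invariances, parameter recovery — not any biological conclusion.

## Numerical choices

* Arc-cosine arguments are clamped to $[-1, 1]$; $|\hat e| = 1$ is
  enforced to $10^{-9}$.
* The TrESP double sum errors on donor–acceptor atom pairs closer than
  $10^{-6}$ Å rather than returning a huge number; the vectorized sum is
  required by the tests to match an explicit double loop to $10^{-10}$
  cm⁻¹.
* Charges that do not sum to zero (beyond $10^{-4}$ e) are an error —
  the dipole would be origin-dependent — unless renormalization is
  requested, which subtracts the mean charge and provably leaves the
  dipole about the centroid unchanged.
* Distance scans flag geometries with overlapping atoms instead of
  computing them, and define the DD↔TrESP convergence distance as the
  smallest scanned R from which the deviation stays within the threshold
  for all larger scanned R.
* All randomness flows through explicit integer seeds; generators scope
  the RNG locally and restore global state, so results are bit-identical
  per seed and independent of ambient R state.
* Problem sizes in the shipped tests are deliberately desk-scale — e.g.
  $10^6$ Monte Carlo pairs, 200-frame ensembles, 4000-atom shells, one
  full 5832-point grid scan per seed — chosen so the whole suite runs in
  well under a minute per property while leaving every statistical
  assertion at three standard errors or better.

## Known limitations

* The exchange (Dexter) contribution to the coupling is not modelled;
  at the separations of interest it is negligible, and the TrESP sum is
  the Coulomb part only.
* Multi-acceptor excitonic effects (generalized Förster) are out of
  scope; `multi_acceptor_couplings()` ranks pairwise couplings but does
  not mix states.
* Published sensitivity tables rounded to 0.1 Å can be irreproducible at
  the half-ulp level from their own printed inputs: with the printed
  ensemble mean $\kappa^2 = 1.55$, two of the ten reference rows differ
  by 0.054–0.058 Å, consistent with an unrounded mean near 1.552. The
  acceptance test keeps the strict ±0.05 Å band and documents the
  failing row rather than widening the tolerance.
* Polarizable-medium refinements of the screening (effective dielectric
  beyond a single $1/n^2$) are not implemented; `n_screen` is a single
  scalar.
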