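---
title: "Modelling encapsulated chemistry in variable-volume vesicles"
author: "osmocell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling encapsulated chemistry in variable-volume vesicles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osmocell)
```

## The model

`osmocell` models a mass-action reaction network enclosed in a unilamellar
lipid vesicle. The membrane is semi-permeable: each solute species $i$
crosses it by passive diffusion with a constant $D_i$, expressed as a
dimensionless multiplier of the permeability of ribose through an oleic
acid bilayer ($D_\mathrm{ribose} = 2.65\times10^{8}$ dm$^2$ s$^{-1}$
mol$^{-1}$, bilayer thickness $\lambda = 4\times10^{-8}$ dm). Water crosses
much faster than any solute, so the model assumes *instantaneous* osmotic
equilibration: the total internal concentration of solutes plus trapped
buffer always equals the total external concentration $C_\varepsilon$.
That isotonic condition removes the volume as a state variable — the scaled
volume (Avogadro's number times the liter volume) is the algebraic function

$$\Omega = \frac{B_T}{C_\varepsilon - \sum_j s_j},$$

where $B_T > 0$ counts impermeable, non-reacting buffer molecules trapped
in the vesicle. The membrane surface is slaved to the volume by assuming
the vesicle stays spherical, $S_\mu = (36\pi (\Omega/N_A)^2)^{1/3}$, so
lipid exchange kinetics need not be modelled. With a changing solvent
volume the concentration ODEs acquire a dilution term; writing
$g_i = r_i(\vec{s}) + \frac{S_\mu D_i}{B_T}(C_\varepsilon - \sum_j s_j)
(s_{i\varepsilon} - s_i)$ for the reaction-plus-diffusion balance, the
full dynamics are

$$\frac{ds_i}{dt} = g_i - \frac{s_i}{C_\varepsilon}\sum_j g_j ,$$

where the subtracted term is exactly the dilution correction
$-(s_i/\Omega)\,d\Omega/dt$ after the isotonic volume relation is
substituted. The package also provides the three classical bulk limits for
comparison — reservoir conditions (pinned resource/waste concentrations),
the CSTR with residence time $\theta$, and the high-buffer vesicle, which
reduces *exactly* to a CSTR with $\theta = B_T/(S_\mu D b_\varepsilon)$
when all species share one diffusion constant. These identities are unit
tested, not merely asserted.

All state can equivalently be carried in molecule numbers,
$n_i = s_i\,\Omega$, where the balance is simply
$\dot n_i = \Omega r_i + S_\mu D_i (s_{i\varepsilon} - s_i)$ with
$\Omega = (B_T + \sum_j n_j)/C_\varepsilon$ and no dilution term at all.
The two formulations are integrated by independent code paths and checked
against each other; syringe injections are implemented in number space,
where an injection is an exact `+rate` on one derivative.

## Units

Concentrations are molar, time in seconds, lengths in dm (volumes in
liters, areas in dm$^2$). Rate constants are bare numbers in the M-based
convention, units M$^{1-\text{order}}$ s$^{-1}$. $\Omega$ is
dimensionless. Morphology-space axes report volume and surface as the nm
diameter of the equivalent sphere.

A note on the spherical-surface constant: the package uses exact sphere
geometry $S = (36\pi V^2)^{1/3}$ with $V = \Omega/N_A$ taken in dm$^3$.
This is the unique choice under which the reduced surface
$\Phi = S_\mu/(36\pi(\Omega/N_A)^2)^{1/3}$ equals 1 exactly for a
spherical vesicle, which the model requires at all times.
$N_A = 6.02214\times10^{23}$.

## Fixed points: the graphical method

The spherical-surface map makes the steady-state equations non-polynomial.
The package therefore follows a two-stage ("graphical") strategy:

1. **Fixed surface.** With $S_\mu$ pinned at $S_\mu^\varnothing$ and the
   dilution term dropped (volume is stationary at any steady state), the
   steady-state conditions are multivariate *polynomials* in the
   concentrations. `steady_state_system()` builds them and
   `solve_all_fixed_points()` finds **all** isolated roots by total-degree
   polynomial homotopy continuation: every combination of roots of unity
   of the start system $z_i^{d_i}-1$ is tracked into the target system by
   an adaptive Euler-predictor/Newton-corrector with a random complex
   $\gamma$ (the standard genericity trick), then Newton-polished.
   Variables are pre-scaled by $C_\varepsilon$ so tracked roots are O(1).
2. **Sweep and intersect.** `sweep_surface()` repeats this over a grid of
   surface areas (default 200 log-spaced values spanning 50–2000 nm
   equivalent-sphere diameters), links fixed points across neighbouring
   grid values into branches (nearest neighbour in
   $(\log_{10}\Omega^*, \vec{s}^*/C_\varepsilon)$, distance cap 0.2 per
   step), and `spherical_crossings()` finds where branches cross the
   $\Phi = 1$ line — which are precisely the steady states of the full
   variable-volume model. Crossings are refined by bisection on
   $S_\mu^\varnothing$ until $|\Phi - 1| < 10^{-6}$; bisection was chosen
   over secant refinement because each function evaluation involves a
   fresh all-roots solve and robustness matters more than order of
   convergence.

### Numerical choices

* Real-root tolerance $|\mathrm{Im}| < 10^{-8}(1+|\mathrm{Re}|)$ per
  coordinate; duplicate roots merged within $10^{-8}$ relative distance.
* Validity filters follow the screening protocol: non-negative
  concentrations, positive volume ($\sum s^* < C_\varepsilon$), and
  $\Omega^*$ below a 2000-nm-diameter sphere (the upper end of the GUV
  range). A relative-residual cut of $10^{-10}$ additionally rejects
  ill-polished near-roots of higher multiplicity.
* The hyperplane $\sum_j s_j = C_\varepsilon$ is a singular manifold of
  the model: the volume diverges there, the diffusion terms vanish, and
  for many networks it carries exact (sometimes non-isolated) solutions
  of the polynomial system. Homotopy paths ending on or near it stall on
  multiple roots; the tracker classifies such endpoints by a tiered
  Newton-polish, and the volume cap removes them from every physical
  result. This is why the volume cap is a structural part of the method
  and not merely a plausibility filter.
* Stability tolerance: eigenvalue real parts within
  $10^{-9}\times$ spectral radius are "marginal".

### Quasi-stability and the dilution projection

Stability evaluated at fixed surface is only a *predictor* of stability
in the full model ("quasi-stability"): the surface is actually variable.
One refinement proved essential. At a fixed point the dilution term
linearises to the exact rank-one projection
$J \mapsto (I - \vec{s}\,\mathbb{1}^{T}/C_\varepsilon)\,J$. Large-volume
steady states live close to the singular manifold (their internal buffer
concentration $b^* = B_T/\Omega^* \to 0$), where the *unprojected*
Jacobian carries a large spurious positive eigenvalue along the osmotic
mode — the mode that volume relaxation physically cancels. Without the
projection every large-vesicle state would be labelled unstable, although
full-model integration shows them to be attracting. `quasi_stability()`
therefore applies the projection by default (`dilution = FALSE` recovers
the unprojected labels), and `confirm_crossing_stability()` double-checks
any spherical crossing by perturbing all molecule numbers by a few percent
and integrating the full model back to it.

## Bulk reference models

Two classical bistable schemes are built in with their bulk bistable
regimes: the Schlögl model ($X + 2Y \rightleftharpoons 3Y$,
$Y \rightleftharpoons Z$) and the Wilhelm model (four irreversible, at
most bimolecular steps). Their reservoir fixed points have closed forms
(a cubic and a quadratic) that serve as independent oracles for the
homotopy solver. One constant deserves a remark: with the bulk regime
used here, only $k_{1r} = 2.85\times10^{3}$ M$^{-2}$s$^{-1}$ is
consistent with the known fixed points
$\{5.03\times10^{-5}, 4.01\times10^{-3}, 7.86\times10^{-3}\}$ M — both
Vieta relations of the cubic (root sum $= k_1 x/k_{1r}$, root product
$= k_{2r} z/k_{1r}$) confirm it to three significant figures — so that is
the package default, exposed as an ordinary parameter.

## Monte-Carlo parameter-space search

`census()` reproduces the screening protocol for encapsulated reactions:
parameter sets are drawn uniformly, the fixed-surface system is solved at
a 400-nm-diameter surface, and valid fixed points are counted. The
generic wide-area ranges are: forward rates in $(0,10)$ (any order),
reverse rates in $(0, k/10)$, $D_i^\times \in (1/5, 50)$,
$s_{i\varepsilon} \in (0, 0.2)$ M, $b_\varepsilon = 0.2$ M $\pm 40\%$,
$B_T = 63064 \pm 40\%$. The encapsulated Schlögl/Wilhelm censuses use the
case-study overrides shipped as presets `schlogl_cs1` / `wilhelm_cs1`:
$s_{i\varepsilon} \in (0, 0.002)$ M for intermediates,
$b_\varepsilon = 0.002$ M $\pm 40\%$, $B_T \in (2, 2000)$, reservoir
species pinned ($x_\varepsilon, z_\varepsilon$ for Schlögl;
$x_\varepsilon$ for Wilhelm, with the waste W sampled as an ordinary
diffusing species — the bulk regime places no constraint on it), rate
constants pinned to the bulk regimes. Whether the original census used
the misprinted or the Vieta-consistent trimolecular reverse constant is
unknowable; the presets use the consistent value.

`find_bistable_regimes()` mechanises the two-phase search for emergent
bistability:

* **Phase 1** — wide-area sampling at the 400-nm surface, keeping sets
  whose system has exactly three valid fixed points; hot-spot sampling
  ($\pm 20\%$ uniform around a hit) amplifies candidates when needed.
* **Phase 2** — the bifurcation curve of a candidate is computed once and
  then *steered* with the exact invariance of
  $K_i = S_\mu D_i/B_T$: scaling $D_i \to D_i\,a\,c$ and
  $B_T \to B_T\,b\,c$ maps every fixed point's morphology as
  $\{\Omega, S_\mu\} \to \{\Omega\,bc,\ S_\mu\,b/a\}$ with concentrations
  unchanged. In log-log morphology space this is a free translation, so
  the crossing pattern with the spherical line depends only on the offset
  $\Delta = \tfrac12\log_{10}a + \tfrac13\log_{10}c$. The package scans
  $\Delta$ finely for a stable/unstable/stable triple whose log-size span
  fits the viability window (default 50–2000 nm, the GUV validity bound),
  centres the triple in the window with the remaining degree of freedom,
  and then verifies the chosen scaling by re-solving the transformed
  sweep and classifying its spherical crossings. This replaces the manual
  trial-and-error step of the original procedure with a deterministic,
  reproducible scan.

`rescale_concentrations()` implements the companion rescaling rule: all
external concentrations and $B_T$ divided by $n$, second-order rates
multiplied by $n$, third-order by $n^2$ (reverse rates by their own
order), which moves every fixed point's concentrations by $1/n$ at
identical morphology and identical time scale (Jacobian spectra are
preserved — tested).

Searched schemes and the seeded budgets used by the package's own test
suite (wall time a few minutes per scheme):

| scheme | budget | seed |
|---|---|---|
| $2X \to Z \to 2Y$ | 6000 | 11 |
| $X \to 2Z \to Y$ | 1000 | 11 |
| $X \to Y$, $P \to Q$ (chemically independent) | 4000 | 101 |

All three yield a verified stable/unstable/stable crossing triple whose
two stable spherical states are re-confirmed by full-model integration.
The packaged configuration `pair_unimolecular_bistable.yaml` is the
regime discovered for the unimolecular pair; bistability of that pair is
a pure osmotic-coupling effect — the two reactions share no species, both
conserve molecule number, and the coupling is carried entirely by the
shared solvent volume through the species' differing permeabilities.

## What the sampled conditions do and do not show

The censuses and searches operate on synthetic parameter sets drawn from
the published ranges, so passing tests demonstrate that the *model* and
*protocol* reproduce the reported statistics and phenomena under those
conditions. They do not calibrate any parameter to experimental vesicle
data: real membranes have tension-dependent permeabilities, finite water
permeation, non-spherical fluctuations and stochastic copy-number
effects, all outside this deterministic, well-stirred model. Known
limitations carried over from the model itself: no limit-cycle search,
no explicit lipid-exchange kinetics, at most four state variables for
the all-roots solve in practice (the Bézout count, and with it path
count, grows multiplicatively), and quasi-stability remains a heuristic
away from the spherical line.

## Problem sizes in the test suite

The packaged suite keeps problem sizes modest by design: five replicate
censuses of 1000 sets per model, pooled to the 5000-set size of the
original screening (binomial standard error about 1.2–1.4 percentage
points per replicate, ~0.5 pooled), solver-oracle equivalence on 100 seeded one- and two-species
systems against a 150-start damped-Newton enumeration (a start density
at which the enumeration was verified to recover every root of every
test system), and the three
search budgets above. `scripts/acceptance.R` re-runs the two censuses at
2000 sets each.
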