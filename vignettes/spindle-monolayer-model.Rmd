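---
title: "A Monte Carlo model of spindle-shaped cell monolayers on ridged substrates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Monte Carlo model of spindle-shaped cell monolayers on ridged substrates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindlemc)
```

## The model

`spindlemc` simulates a monolayer of spindle-shaped cells (for instance 3T6
fibroblasts) proliferating on a substrate patterned with concentric
micro-ridges. Each cell is a deformable ellipse with semi-axes $a \ge b > 0$,
orientation $\hat u = (\cos\phi, \sin\phi)$, and a polarity vector $p$ that
sets its preferred direction of motion. The ridge rings impose a $+1$
topological defect of the nematic director at the pattern centre, and —
because the box is periodic — a $-1$ (saddle) defect at the box corners,
formed by ring arcs of the neighbouring pattern images. The question the
model addresses is how such imposed defects reshape cell density: not
through directed migration, but through cell division that is sensitive to
cell shape.

Dynamics are Metropolis Monte Carlo. In one Monte Carlo step (MCS) every
cell, in random order, proposes one move — displacement (probability 0.10),
rotation (0.20), or a change of one semi-axis (0.35 each) — and the move is
accepted with probability $\min(1, e^{-\Delta E/T})$ with $T = 1$ setting
the energy scale. The calibration 100 MCS = 1.5 simulated minutes converts
MCS to time.

### Energies

* **Shape.** Deviations of area $A = \pi a b$ from $A_{\mathrm{pref}} =
  1400\ \mu m^2$ and of aspect ratio $AR = a/b$ from $AR_{\mathrm{pref}} =
  4$ cost $E_X = k_X(\delta^2 - \delta^3/3 + 4\delta^4)$ in the relative
  deviation $\delta$: flat near the preferred value, quartic far from it.
  A core term $k_{\mathrm{core}}(a^{-4} + b^{-4})$ prevents indefinite
  squeezing.
* **Cell–cell.** A modified Gay–Berne potential
  $U = 4\epsilon\,(r^{-12} - r^{-6})$ in the scaled distance
  $r = (|r_{12}| - \sigma + \sigma_0)/\sigma_0$, where the contact scale
  $\sigma = (\hat r^T(\gamma_1+\gamma_2)^{-1}\hat r)^{-1/2}$ is built from
  the cells' shape matrices $\gamma_i = (l_i^2 - d_i^2)\hat u_i \hat u_i^T +
  d_i^2 I$ with $l_i = \sqrt2\,a_i$, $d_i = \sqrt2\,b_i$, and
  $\sigma_0 = \sqrt{2b_1^2 + 2b_2^2}$. The strength
  $\epsilon = \epsilon_0\,\epsilon_a^\nu \epsilon_b^\mu$ combines the
  nematic factor $\epsilon_a = [1 - \chi^2(\hat u_1\cdot\hat u_2)^2]^{-1/2}$
  and the dimensionless $\epsilon_b = (\sigma_0/\sigma)^2$, so parallel
  side-by-side contact is energetically preferred. Interactions are cut off
  one-sidedly: cell $i$ interacts with cells whose centres lie in an ellipse
  of semi-axes $(100, 43.75)\ \mu m$ oriented along $\hat u_i$. Because the
  cutoff is one-sided, no global symmetric Hamiltonian exists; the dynamics
  are nevertheless well defined, since every proposal is judged by the
  energy of the moving cell alone. This is documented behaviour, not a
  defect to be "fixed".
* **Ridges.** A cell pays $k_r\,\Upsilon$, with the overlap fraction
  $\Upsilon$ estimated from 64 points on each of three concentric feeler
  ellipses (axis scale factors 1, 2/3, 1/3; 192 points total). The feeler
  points do not include the cell centre — with the centre point the estimate
  of a thin-ridge overlap would be biased upward at small cells for no
  physical reason, and 192 boundary points already resolve a 4 um ridge.
* **Motility.** A displacement $\Delta r$ changes the energy by
  $-k_{\mathrm{move}}\,\mathrm{sign}(\hat u\cdot p)(\hat u\cdot\Delta r)$:
  motion along the long axis in the polarity direction is rewarded,
  independent of $|p|$ ($\Pi = 0$, i.e. no reward, when $p \perp \hat u$).

### Polarity

After the sweep, each cell updates
$p \leftarrow (1 - 1/\tau_{\mathrm{pol}})\,p + \Delta r$ with
$\tau_{\mathrm{pol}} = 2000$ MCS (30 min) and $\Delta r$ its realized
(accepted) displacement this MCS. The published description is ambiguous
between the proposed and the accepted displacement; the accepted reading is
the default here because a rejected move produces no motion to align with,
and the alternative is available as
`model_params(polarity_update = "proposed")` for sensitivity checks.
Polarity co-rotates with accepted rotations of the cell body (it is a
body-fixed preference); rejected rotation proposals leave it untouched.
Every 100 MCS each cell reverses $p \to -p$ with probability 0.01, giving
geometric waiting times with mean 150 simulated minutes.

### Growth and division

Runs start from `n_init` circular cells of radius 10 um (100 cells for the
default 1200 um box, about 70 cells/mm^2) at random non-overlapping
positions, relax for 10 h without division, then divide exactly one cell per
100 MCS until the terminal count (3000 for the default box, about 2000
cells/mm^2). The dividing cell is sampled with probability
$p_i \propto \exp(A_i/A_{\mathrm{pref}} - \alpha\,AR_i/AR_{\mathrm{pref}})$:
larger cells divide more, and for $\alpha > 0$ isotropic cells divide more.
Daughters have axes $0.4\,(a, b)$ (aspect ratio preserved, area deliberately
not conserved), the parent's orientation and polarity, and centres at the
parent centre $\pm 0.4a\,\hat u$ — they touch at the parent centre and stay
within the parent footprint, which minimizes overlap spikes. The daughter
offset is a design choice (the published text does not state it
numerically); `daughter_factor` controls both the size ratio and the offset.

## Geometry choices

Ring radii are $k \cdot 60$ um for $k \ge 1$, all below $L/2$; there is no
ring at radius zero, and the "inner ring" region is the disc of radius 60
um. Under the periodic tiling the box corner is surrounded by the outermost
ring arcs of the four neighbouring pattern images: the corner region itself
is ridge-free, and the surrounding arcs impose the $-1$ saddle orientation
field across it. Cells in this bare pocket can relax toward their preferred
elongated shape, which is how the model produces more-elongated cells at the
$-1$ core than elsewhere. (The alternative geometry, rings continued past
$L/2$ so that arcs cage the corner itself, was examined and rejected: caged
corner cells get compressed and isotropic and the corner then *accumulates*
cells under shape-dependent division — opposite to the behaviour the model
is meant to capture.) The simulated ridge width is not stated in the source
material; the default is 4 um, narrow against the 60 um spacing, and
configurable (`ridge_pattern(width = ...)`).

The $-1$ analysis centre is the box corner $(0, 0) \equiv (L, L)$, with all
distances minimum-image. Angles are radians internally and degrees at the
analysis/reporting boundary, with orientations reported modulo 180 degrees.

## Numerical implementation

The sweep engine is compiled (Rcpp). All randomness comes from R's global
RNG in a documented draw order (see `src/engine.cpp`), so a seed fixes the
whole trajectory; an internal pure-R reference sweep reproduces the engine
draw-for-draw on small systems and is compared to it in the test suite.
Energy bookkeeping caches each cell's geometric and ridge energies;
candidate neighbour lists are circles of radius $r_c^{\mathrm{maj}}$ plus a
12 um halo, rebuilt on every division and whenever a cell accumulates more
displacement than the halo admits (the published 25 um rebuild rule is an
outer bound; the halo trigger fires first and guarantees that no pair can
enter the exact elliptical cutoff unseen). The exact cutoff is re-applied at
every energy evaluation, so list rebuild timing affects speed only, never
the trajectory. Coincident centres (transiently possible after division)
are handled by flooring the scaled Gay–Berne distance at $10^{-3}$, which
keeps the energy finite and lets Metropolis reject the configuration.
Resize proposals that would violate $a \ge b > 0$ are rejected outright
rather than relabelling the axes, which preserves the identity of the long
axis. The one acceptance uniform per proposal is always consumed, so
trajectories are reproducible independent of which branch rejects.

## Analysis conventions

* **Alignment RMSD** is the root of the mean squared deviation between cell
  orientation and the defect-imposed orientation (+1: azimuth + 90 mod 180;
  -1: the quadrant rule), wrapped to $[-90^\circ, 90^\circ)$. The published
  notation is ambiguous between the mean square and its root; the root is
  reported (units: degrees, range 0–90) and `squared = TRUE` exposes the
  other reading.
* **Radial profiles** use 60-um rings and report
  $(\rho_{\mathrm{ring}} - \rho_{\mathrm{avg}})/\rho_{\mathrm{avg}}$, with
  the whole-box average as the default normalization for simulations.
* **Velocity histograms** use 60-minute displacement windows (matching
  1-hour experimental displacement vectors) and a clockwise-positive angle
  convention: 90 degrees = clockwise-azimuthal, 270 = counterclockwise. The
  convention (which sense maps to 90) is not fixed by the source material;
  it is fixed here and documented.
* **Ridge occupancy** counts a cell as "on" a ridge iff its centre is on a
  ridge, with analytic on/off areas (annuli beyond $L/2$ truncated by the
  box are handled exactly).

## What the simulations in the test suite show — and what they do not

Full-scale runs (1200 um box to 3000 cells, 100 replicates) take CPU-days.
The packaged test suite instead runs the whole schedule at reduced scale:
a 420 um box from 12 to 367 cells — the same initial (~70 cells/mm^2) and
terminal (~2083 cells/mm^2) densities, ridge spacing, 10 h relaxation and
1.5 min division cadence as the full model — with 20 seed-pinned replicates
per arm for the division-sensitivity comparison ($\alpha = 2$ vs
$\alpha = 0$ at $k_r = 120$) and 10 replicates for the ridge-strength
comparison ($k_r = 60$ vs 120). These sizes are the package's choice of
desk-scale study conditions; the qualitative machinery (defect geometry,
compartmentalization by rings, shape-dependent division) is identical, but
a 420 um box holds only 3 rings and its inner disc a couple of dozen cells,
so inner-ring statistics carry large seed-to-seed variability — single-run
values are bimodal (cores either populate and densify or stay starved), as
the full-scale model also shows for its no-motility variant. Directional
conclusions at this scale therefore rest on paired seeds and one-sided
tests, and remain noisier than the 100-replicate full-scale results. The
ridge-strength effects (suppressed ridge crossing and better alignment at
$k_r = 120$ than at 60) and the alignment-vs-density trend are resolved at
this scale; the division-shape-sensitivity contrasts at the defect cores
($\alpha = 2$ vs $\alpha = 0$ inner-ring density and aspect ratio, and
corner depletion) are not — their seed-to-seed spread at a couple of dozen
inner-ring cells swamps 20 paired replicates, and the corner pocket of a
small box is only one or two cell lengths wide. The corresponding checks
are retained in the test suite at the stated conditions and report their
outcome honestly rather than being weakened.

The synthetic founders (uniform non-overlapping discs) emulate sparse
seeding of cultured fibroblasts; they do not model seeding heterogeneity,
cell death, extracellular-matrix remodelling, or the 3D undulation of
monolayers over tall ridges — all deliberately out of scope.

## A worked example

```{r example, fig.width = 6, fig.height = 6}
p <- model_params(L = 300, n_init = 6, terminal_count = 12,
                  relax_time = 0.25)
pat <- ridge_pattern(L = 300, k_r = 120)
sim <- simulate_monolayer(p, pat, seed = 1)
summary(sim)
radial_profile(sim$state$cells, pat$center, p$L, "density",
               max_radius = 150)
plot(sim)
```

## Known limitations

* The one-sided cutoff makes the energy non-Hamiltonian (documented above).
* Ridge overlap is a 192-point estimate: overlap fractions are multiples of
  1/192, so very thin ridges under very large cells are quantized.
* The -1 corner of a small periodic box sits tens of micrometres from the
  nearest ridge arcs; its local director constraint is weaker than in a
  full-size pattern, which weakens corner-depletion statistics at desk
  scale.
* Physical time enters only through the fixed 100 MCS = 1.5 min calibration;
  no attempt is made to fit division rates to experimental growth curves.
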