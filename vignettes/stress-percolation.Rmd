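---
title: "Stress-chain percolation in active cell monolayers: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress-chain percolation in active cell monolayers: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science implemented by `stresschains`: a
three-dimensional multi-phase-field model of a confluent cell monolayer, the
coarse-graining of cell tractions into stress fields, the solid/liquid
structural diagnostics, and the threshold-percolation finite-size-scaling
(FSS) analysis of the isotropic stress.  It records every modelling
assumption, numerical choice and design decision a maintainer would need to
judge or change.

## The model

Each of the `N` cells is a smooth indicator field $\phi_i(\vec x, t) \in
[0,1]$ on a 3D lattice (spacing $a_0 = 1$), periodic in $x$ and $y$, with a
static substrate field $\phi_w$ occupying the bottom of the box.  The fields
follow relaxational (model A) dynamics with an advective term,

$$\partial_t \phi_i + \vec v_i \cdot \nabla \phi_i =
  -\Gamma \frac{\delta F}{\delta \phi_i},$$

driven by the free energy

$$F = \sum_i c_\text{bulk}\!\int\! \left\{4\phi_i^2(1-\phi_i)^2 +
      \lambda^2 |\nabla\phi_i|^2\right\}
    + \sum_i \mu\left(1 - \tfrac{1}{V_0}\!\int\!\phi_i^2\right)^{\!2}
    + \sum_{i \ne j} c_\text{rep}\!\int\!\phi_i^2\phi_j^2
    + \sum_{i \ne j} c_\text{adh}\!\int\!\nabla\phi_i\!\cdot\!\nabla\phi_j
    + \text{(substrate analogues)}.$$

The double well keeps the interior at $\phi = 1$ and the exterior at
$\phi = 0$, joined by a diffuse interface of width $\lambda$; $\mu$ softly
constrains the cell volume to $V_0 = \frac{4}{3}\pi R_0^3$; the
$\phi_i^2\phi_j^2$ terms penalize overlap (repulsion) and the gradient
cross-terms reward shared interface (adhesion), separately for cell–cell
and cell–substrate contacts.  Because more than one reading of the energy
prefactors is in circulation, the three combinations are exposed as
independently configurable coefficients with defaults
$c_\text{bulk} = E\lambda/2$, $c_\text{rep} = \kappa/\lambda$,
$c_\text{adh} = \omega\lambda^2$; the universality analysis is insensitive
to this convention and either reading is a one-line configuration change.

Forces follow from an overdamped balance: the passive traction of cell $i$
is $\vec T_i = -\int (\delta F/\delta\phi_i)\,\nabla\phi_i$, the active
polar force is $\vec F^\text{act}_i = \alpha \hat F^\text{pol}_i$ with
$\hat F^\text{pol}_i = (\cos\theta_i, \sin\theta_i, 0)$, and the cell
velocity is $\vec v_i = (\vec T_i + \vec F^\text{act}_i)/\xi$ with substrate
friction $\xi$.  Polarity follows contact inhibition of locomotion: the
angle relaxes toward the direction of the in-plane traction,
$\partial_t\theta_i = -(|\vec T_i|/\tau_\text{pol})\,\Delta\Theta_i +
D_r\,\eta$, where $\Delta\Theta_i$ is the signed smallest angle from the
traction direction to the polarity.  Two conventions are fixed here and
recorded: (i) the drift uses the *in-plane* traction magnitude, since the
alignment angle is only defined in-plane; when the in-plane traction
vanishes the drift is zero and only noise acts; (ii) the noise enters
literally as $D_r\eta$ (Euler–Maruyama, increment
$D_r\sqrt{\Delta t}\,\mathcal N(0,1)$), so the angular diffusion constant is
$D_r^2/2$; the common $\sqrt{2D_r}$ scaling is a rescale of $D_r$.

Two dimensionless drives control the solid-to-liquid transition and are the
sweep axes of every experiment: the adhesion ratio
$\tilde\omega = \omega_{cc}/\omega_{cw} \in [0.1, 0.5]$ and the
dimensionless traction
$\tilde\alpha = \alpha\tau_\text{pol}/(\xi R_0) \in [0, 0.8]$.  Confluence
is maintained with no proliferation and no extrusion; a run-time monitor
flags any cell whose $\int\phi_i^2$ drops below half of $V_0$.

## Default parameters and how they were calibrated

The model's source publications do not ship a usable parameter table, so the
defaults here are the package's own, calibrated **only** to produce a
stable, confluent, desk-scale monolayer in which the low-drive corner of
the $(\tilde\omega, \tilde\alpha)$ plane is actually solid (caged cells)
and the high-drive corner is liquid.  In lattice units: $E = 1$,
$\lambda = 2$, $\mu = 8000$, $\Gamma = 0.2$, $\kappa_{cc} = 0.5$,
$\kappa_{cw} = 1$, $\omega_{cw} = 0.25$, $\xi = 400$,
$\tau_\text{pol} = 20$, $D_r = 0.5$, $R_0 = 8$, $\Delta t = 0.025$.
Three constraints discovered during calibration are worth recording:

* **Anti-phase adhesion instability.**  The gradient cross-term makes the
  collective mode in which overlapping neighbours' fields anti-align
  effectively anti-diffusive once
  $c_\text{adh} \cdot k \gtrsim c_\text{bulk}\lambda^2$, with $k$ the local
  number of overlapping neighbours.  $\omega_{cw} = 0.25$ keeps
  $c_\text{adh} \le 0.5$ over the whole $\tilde\omega$ sweep, safely inside
  the stable region at $\Delta t = 0.025$.
* **Monolayer integrity.**  Cell–substrate adhesion must dominate
  cell–cell adhesion, otherwise in-plane pressure pushes cells off the
  substrate and the monolayer stacks into a bilayer.  (The drive range
  $\tilde\omega \le 0.5$ respects this ordering by construction.)
* **Caging.**  The solid regime requires pressed confluence: the fixture
  box gives each cell an in-plane area of about $0.93^2 \cdot 4R_0^2$
  per near-triangular packing site (coverage $\approx 1.1$), so passive
  repulsion barriers exceed the low-drive active force.

The initial tanh spheres are inflated by $0.44\lambda$ so that
$\int\phi_i^2$ starts near $V_0$ (the $\phi^2$ support of a tanh profile
sits inside its nominal radius).  Every run begins with a passive
relaxation phase (`n_relax` steps with $\alpha = D_r = 0$).

## Numerics

Time integration is explicit Euler with first-order upwind advection; each
cell advects rigidly with its own $\vec v_i$.  The advection CFL number is
monitored every step and the run aborts with a diagnostic if
$|\vec v|_\text{max}\Delta t / a_0 > 0.45$.  Fields are clamped to $[0,1]$
after each step and clamp events are counted (explicit schemes overshoot;
silent NaNs are worse).  The discrete gradient energy uses forward
differences, whose exact variation is the standard 7-point Laplacian with
zero-flux clamps in $z$ — so the functional derivative assembled by the
stepper is the *exact* gradient of the discrete free energy, and the
finite-difference test agrees to $10^{-4}$ by construction rather than by
tolerance tuning.  The stability bound that actually binds is the
symmetric-mode interface diffusion
$\Delta t < a_0^2 / (6\,\Gamma\,(2c_\text{bulk}\lambda^2 + 2 c_\text{adh}
k))$; $\Delta t = 0.025$ sits at roughly half of it at the strongest
adhesion swept.

Phase fields are stored on the full grid (a dense nodes × cells matrix in
compiled code).  Desk-scale runs (16 cells, $60 \times 52 \times 24$) fit
easily; the full 400-cell, $320^2$ configuration would need the moving
cell-local subdomain optimization, which is deliberately out of scope —
the package validates and accepts that configuration but running it is
cluster-scale work.

## From tractions to stress fields

The per-node traction density sums, over cells, the passive density
$-(\delta F/\delta\phi_i)\nabla\phi_i$ and the active density
$\alpha\hat F^\text{pol}_i \phi_i^2 / \int\phi_i^2$ (distributing the
active force proportionally to $\phi_i^2$ so the per-cell integral recovers
$\alpha\hat F^\text{pol}_i$ exactly).  Stress lives on the complementary
(dual) lattice: analysis node $i$ at $(x-\tfrac12, y-\tfrac12)$ collects
the four facially adjacent original-lattice columns and forms the
symmetrized moment
$\sigma_i = a_0^{-3}\sum_{j \in N_i} \vec r_{ij} \otimes \vec T_j$ with
$\vec r_{ij} = \vec x_i - \vec x_j$, where the in-plane offsets are
$\pm a_0/2$ and the vertical offset is taken from the slab mid-height,
$z_\text{mid} - z_j$.  Two properties are preserved exactly: linearity in
the tractions, and annihilation of any globally uniform traction (the
offsets sum to zero over the stencil).  The mid-height vertical moment is a
deliberate design decision: contracting per-layer dual-cell stresses by a
plain $z$-sum telescopes the $zz$ component to boundary terms (verified
numerically — the resulting field is ~25× smaller than the in-plane
components and carries no interior information), which would make the
out-of-plane analysis vacuous.  The column moment instead measures the
vertical force dipole of the column — the natural embedding of
$\sigma_{zz}$ in a 2D field.  The resulting analysis lattice has
$(L_x+1)\times(L_y+1)$ nodes whose first/last rows and columns are periodic
duplicates.

Scalar reductions: isotropic stress $\bar\sigma^\text{iso} =
\tfrac13\mathrm{tr}\,\bar\sigma$ (positive = expansion, negative =
compression; optionally normalized by the maximum compressive magnitude,
with a max-absolute-value variant), out-of-plane $\bar\sigma_{zz}$, and
maximum in-plane shear $\sigma_\tau = \tfrac12(\sigma_\text{max} -
\sigma_\text{min}) = \sqrt{((\sigma_{xx}-\sigma_{yy})/2)^2 +
\sigma_{xy}^2}$ of the in-plane block.  Fluctuations are quantified by the
extensive susceptibility $\chi = n(\langle x^2\rangle - \langle
x\rangle^2)$ with $n$ the number of lattice sites (the standard extensive
reading of an ambiguous convention; configurable in principle by computing
the variance directly).  Sweep statistics are computed on the raw
time-averaged fields and the *statistics* are normalized by their value at
the reference control point; normalizing the fields by their own maxima
first would let the normalization constant swamp the trend being measured.

## Solid/liquid diagnostics

The pair correlation $g(r) = (N\rho)^{-1}\langle\sum_{i\ne j}
\delta(r - |\vec r_i - \vec r_j|)\rangle$ is computed in-plane from
*time-averaged* cell centroids (trajectories are unwrapped across the
periodic boundaries, averaged, then wrapped back), with bin width $R_0/20$
and $r_\text{max}$ = half the shorter box edge, normalized so a Poisson
configuration gives $g \equiv 1$.  A caged (solid) monolayer keeps its
neighbour shell: the dominant peak sits near the cell diameter,
$r/R_0 \approx 2$.  When cells rearrange, their time-averaged positions
smear and approach each other, producing dominant weight at separations
well below the diameter.  The classifier smooths $g$ with a 3-bin moving
average, finds local maxima above 1.05 outside the self-overlap region
($r/R_0 < 0.2$), and labels the state solid if the dominant peak lies in
$[1.6, 2.4]$, liquid if it lies below 1.2, indeterminate otherwise (all
thresholds are arguments).  A 2D static structure factor
$S(\vec q) = |\sum_j e^{i\vec q\cdot\vec r_j}|^2/N$ on box-commensurate
wavevectors provides the confirming reciprocal-space view.

## Threshold percolation and finite-size scaling

The time-averaged isotropic stress field is reduced to an occupancy
problem: at occupation probability $p$, the occupied sites are those whose
value is strictly greater than the $(1-p)\cdot100$-th percentile of the
field's own distribution (both compressive and tensile values enter the
ranking).  On an i.i.d. continuous field this occupies exactly the top
$k(p)$ sites — site percolation in the *fixed-count* (microcanonical)
ensemble, which is what underpins the validation stage.  Because the rank
rule suppresses the binomial fluctuations of the occupied count, its
finite-size curve widths differ from the canonical (independent
Bernoulli occupation) ensemble in which reference threshold and exponent
values are usually quoted; `percolation_curves(ensemble = "binomial")`
converts to the canonical ensemble by convolving the fixed-count
observables with the binomial distribution of the count (the classic
incremental-occupation construction), at no extra labelling cost since
every aggregate is maintained incrementally.  Both ensembles flow through
the identical collapse machinery and, at the validation sizes, recover the
same universality-class parameters within errors.  Connectivity defaults
to nearest neighbours (`face4`),
matching the reference threshold $p_c = 0.5927$ of the universality class
the analysis is validated against; eight-point connectivity (`moore8`) is
available, and the tension between the two conventions in the source
material is surfaced in the documentation rather than hidden.

Clusters are labelled with a union–find; observables follow the standard
conventions: spanning means touching both opposite edges along either axis
(open boundaries within subsystems); $P$ is the fraction of *all* sites in
spanning clusters; $S$ is the second-moment mean cluster size
$\sum s^2 n_s / \sum s n_s$ over non-spanning clusters (the convention
presupposed by $S \sim |p-p_c|^{-\gamma}$; the arithmetic mean is a
switch); the correlation length is the size-weighted gyration measure
$\xi^2 = \sum 2R_s^2 s^2 n_s / \sum s^2 n_s$, equal to the r.m.s.
same-cluster site separation.  The implementation occupies sites in
decreasing field order and merges cluster aggregates incrementally, so a
whole occupation grid costs one sorted pass; every observable is also
cross-checked in the tests against dense brute-force oracles.

Curves $P(p,\ell)$, $S(p,\ell)$, $\Pi(p,\ell)$, $\xi(p,\ell)$ are
accumulated over non-overlapping $(\ell+1)^2$ subsystems and independent
realizations.  The threshold is first estimated from pairwise crossings of
probit fits to $\Pi(p,\ell)$, then refined by the FSS collapse: Nelder–Mead
multi-start minimization of a master-curve scatter objective — each size's
scaled points $(x, y) = ((p-p_c)\ell^{1/\nu},\ \ell^{\beta/\nu}P)$ (or
$\log(\ell^{-\gamma/\nu}S)$; $S$ spans decades, hence log space) are
compared with the linear interpolation through the pooled points of the
*other* sizes, and the normalized mean squared residual is minimized over
$(p_c, \text{ratio}, 1/\nu)$ within the scaling window
$|x| \le x_\text{max}$.

Three safeguards make this otherwise fragile three-parameter fit
well-behaved, and each is worth recording.  (i) The default window is
per-observable: $x_\text{max} = 3$ for $P$ and $1.5$ for $S$.  For the
monotone $P$ curves, vertical stretching ($\ell^{\beta/\nu}$) and
horizontal squeezing ($\ell^{1/\nu}$) are nearly interchangeable if the
window only covers the rising flank — the fit then wanders along a flat
valley; including the knee where the curves bend over breaks the
degeneracy.  The peaked $S$ curves have no such degeneracy, and a narrower
window limits correction-to-scaling contamination of the log-space fit.
(ii) $1/\nu$ is restricted to $[0.4, 1.6]$ — $\nu$ between 0.625 and 2.5, a
generous band around all plausible 2D percolation-like values — because
the unconstrained log-space $S$ collapse admits degenerate flat-scaling
minima far outside the physical region; $p_c$ is likewise kept within
$\pm 0.05$ of the crossing seed.  (iii) The window must contain real
signal for every size (its maximum of the raw observable at least a
quarter of that size's global maximum); otherwise a window placed in the
zero-signal tails, where near-constant values scatter trivially little,
can masquerade as a perfect collapse.  Exponent ratios are converted with
the fitted $\nu$; uncertainties come from bootstrap resampling of
realizations (not of subsystems within a realization), with the replicate
optimizations started from the point estimate.

## Synthetic generators: what they emulate, and what they do not

* `iid_uniform_field` — the null ensemble: percentile thresholding of it
  *is* site percolation, so the whole chain must recover the
  random-percolation threshold and exponents from it.  It emulates the
  short-range-correlated limit of a stress field, not any monolayer
  physics.
* `gaussian_correlated_field` — spectral synthesis with power spectrum
  $|q|^{-s}$ (real symmetric filter, DC mode zeroed): the long-range
  correlated contrast case.
* `dipole_chain_field` — signed anisotropic ridges mimicking the
  filamentary geometry of compressive/tensile stress chains; a shape
  fixture, with no force balance behind it.
* `scaling_curve_set` — curves satisfying the FSS forms exactly, with
  fixed smooth master functions ($F(x) = 1/(1+e^{-2x})$,
  $G(x) = e^{-x^2/2}$) and multiplicative log-normal noise.  Its
  occupation grids are size-adapted ($p = p_c + x\,\ell^{-1/\nu}$ on a
  common $x$ grid) so that at the true parameters the scaled points of all
  sizes coincide and a perfect collapse is exactly representable — making
  zero-noise collapse quality a machine-precision check and noisy recovery
  a calibrated self-test of the estimator.
* `monolayer_fixture` — ready-to-run desk-scale configurations on the two
  sides of the transition: `solid_like` at drives $(0.1, 0.2)$ and
  `liquid_like` at $(0.5, 0.8)$, identical numerics otherwise.

Passing tests on these generators show that the *analysis machinery* is
correct and that the *model* produces the qualitative phenomenology (caged
vs. mobile states, rising stress fluctuations along both drives).  They do
not show that real tissues are described by this model, nor do desk-scale
runs reproduce published full-scale exponent estimates — that requires the
400-cell, $321^2$-lattice, multi-realization protocol shipped as
`inst/extdata/full_scale.yaml`, which validates and runs through the same
pipeline but needs cluster-scale compute.

## Problem sizes used by the shipped checks

The validation study uses 400 independent i.i.d. fields per size
$\{64^2, 128^2, 256^2\}$, an occupation grid of step 0.005 on
$[0.30, 0.90]$, and 30–50 bootstrap replicates; the monolayer checks use 16
cells ($R_0 = 8$) on a $60\times52\times24$ box, 600 relaxation steps, and
1200–2400 recorded steps.  These sizes were chosen as the smallest at which
the stochastic checks are comfortably signal-dominated (for the exponent
$\nu$ in particular, the collapse estimator's stream-to-stream spread at
200 fields per size is comparable to the quoted reference precision, so the
ensemble is doubled).

## Known limitations

* Explicit Euler limits $\Delta t$; stiff parameter corners (strong
  adhesion, large $\mu$) need smaller steps than the default.
* First-order upwind advection is diffusive; steady translation speeds are
  accurate to a few percent, not machine precision.
* The dense full-grid state makes memory scale as (nodes × cells); the
  cell-local subdomain layout needed for 400-cell runs is future work.
* The dual-lattice stencil and the vertical-moment contraction are
  reasoned reconstructions of an under-specified published construction;
  both are pluggable, and all universality-class conclusions were checked
  to be insensitive to the in-plane stencil choice.
* $g(r)$-based classification at $N = 16$ is coarse; the thresholds of
  `classify_state` are explicit arguments so larger studies can tighten
  them.
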