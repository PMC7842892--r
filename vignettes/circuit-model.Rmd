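---
title: "An equivalent-circuit network model of a plasma-exposed culture well"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An equivalent-circuit network model of a plasma-exposed culture well}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmawell)
```

## The problem

In microdischarge-plasma (MDP) gene transfection, a thin high-voltage
electrode generates a micro-scale atmospheric plasma above the centre of a
96-well plate well. Adherent cells at the well bottom, covered by a thin
conductive TE/PBS buffer, receive both electrical factors (field and
current delivered through the plasma) and chemical factors (reactive
species). Separating the two electrical factors — is it the electric field
or the electrical current that matters? — requires knowing not just the
shape of the radial field distribution in the liquid but the absolute
voltage across and current through each cell's membrane.

A uniform-medium description of the liquid cannot provide that: field and
current density are proportional through the conductivity, so their
profiles are identical and per-cell quantities are inaccessible. This
package instead represents the whole well — buffer, a monolayer of cells
with explicit membrane layers, and the polystyrene plate above the
grounded copper plane — as one axisymmetric lumped-element network, solves
it in the sinusoidal steady state, and converts branch phasors into the
exposure quantities a cell experiences.

## The network

The well bottom (radius 3.2 mm) is divided into `n_segments = 16`
concentric rings of width $\Delta r = 0.2$ mm, ring $n$ centred at

$$r_n = \left(n - \tfrac12\right)\Delta r, \qquad n = 1, \dots, 16.$$

Each ring carries a vertical stack of six elements, from the grounded
plate up to the buffer surface:

```
G --C0n-- D_n --Czon-- L_n --Rzon-- M_n --Rzin-- U_n --Czin-- T_n --R0n-- B_n
```

* `C0n` — plate capacitance, $\varepsilon_w 2\pi r_n \Delta r / H_w$;
* `Czon`, `Czin` — lower/upper membrane capacitances,
  $\varepsilon_m 2\pi r_n \Delta r / H_m$;
* `Rzon`, `Rzin` — lower/upper cytoplasm half-resistances,
  $\frac{(H_c - 2H_m)/2}{\sigma_c\, 2\pi r_n (\Delta r / H_c)(H_c - 2H_m)}$;
* `R0n` — buffer column resistance, $\frac{H_b}{\sigma_b\, 2\pi r_n \Delta r}$.

Radial links couple adjacent rings: the buffer resistor
`R1n` $= \frac{\Delta r}{\sigma_b 2\pi r_n H_b}$ joins buffer nodes
$B_n \to B_{n+1}$, and the cell layer is joined mid-cytoplasm by the
four-element series branch

```
M_n --Rron(n)-- --Cron(n)-- --Crin(n+1)-- --Rrin(n+1)-- M_{n+1}
```

with radial membrane capacitances
$C_r = \varepsilon_m 2\pi r_n H_c / ((\Delta r/H_c) H_m)$ and radial
cytoplasm half-resistances
$R_r = \frac{(\Delta r/H_c)(H_c-2H_m)/2}{\sigma_c 2\pi r_n (H_c-2H_m)}$.
The reduced radial extents $(\Delta r / H_c) H_m$ and
$(\Delta r/H_c)(H_c - 2H_m)$ preserve the membrane:cytoplasm height ratio
within the ring, so the ring of real cells and its lumped stand-in have
the same per-unit-length impedances.

Three topology choices were genuinely open and are fixed as follows
(`export_netlist()` makes the realized topology auditable line by line):

* **Cell-radial junctions sit at the mid-cytoplasm nodes `M_n`**, and the
  inner/outer element pairs play distinct roles: current leaves ring $n$
  through its *outer* half-resistance and *outer* radial membrane, and
  enters ring $n+1$ through that ring's *inner* radial membrane and
  half-resistance. This is the only wiring in which the paired `i`/`o`
  elements and the per-ring half-lengths of the cytoplasm formulas all
  have a distinct physical meaning.
* **The outermost ring has no outward link** — the well wall is
  insulating polystyrene.
* **The plate layer is vertical-only** (one grounded capacitor per ring):
  the ground plane is an equipotential, so radial plate elements would
  connect equipotential points.

The plasma column approximates a zero-resistance conductor, so the drive
is an ideal sinusoidal source (no internal impedance) between ground and
the innermost buffer node `B1`. Element count:
$6n + 5(n-1) = 11n - 5 = 171$ at $n = 16$.

## Parameters

| quantity | default | meaning |
|---|---|---|
| $\sigma_b$ | 0.376 S/m | TE/PBS buffer conductivity (as prepared for exposure) |
| $\varepsilon_m$ | $30\,\varepsilon_0$ | membrane permittivity |
| $\sigma_c$ | 1 S/m | cytoplasm conductivity |
| $\varepsilon_w$ | $2.4\,\varepsilon_0$ | polystyrene plate permittivity |
| $H_w$ | 1.5 mm | plate thickness |
| $H_c$ | 50 µm | cell-layer height (fibroblast diameter) |
| $H_m$ | 0.5 µm | membrane-layer height ($H_c/100$) |
| $H_b$ | 50 mm | buffer-layer height (see below) |
| $n$, $\Delta r$ | 16, 0.2 mm | radial discretization |
| $V_{pp}$, $f$ | 15 kV, 20 kHz | sinusoidal drive |

$\varepsilon_0 = 8.854\times10^{-12}$ F/m, carried to 4 significant
figures to match the precision of the derived admittance constants.
Everything is SI internally; JSON configuration files may use explicit
`_mm`/`_um` suffixed keys (`read_parameters()`), because the main
practical risk in this model is a silent mm/µm slip.

### The buffer-height contradiction

The nominal parameter set states $H_b = 50$ mm *and* states that the
height is the dispensed volume divided by the well-bottom area — but 6 µL
over a 3.2 mm-radius disc gives $\approx 0.19$ mm
(`buffer_height_from_volume()`), a 260-fold difference. The package
refuses to adjudicate silently: the default is the stated 50 mm, the
volume-derived film is one argument away, every run logs the resolved
value, and the test suite runs both. The choice matters:

* with $H_b = 50$ mm the buffer is a near-equipotential reservoir; the
  exposure profile is almost perfectly flat (peak per-cell current
  ≈ 37 nA) and has no centre feature at all;
* with $H_b \approx 0.19$ mm the film's spreading resistance concentrates
  current at the centre: peak per-cell current ≈ 103 nA at $r_1$,
  two orders of magnitude above the ~1 nA ion-channel transport scale,
  decaying toward ~37 nA at the rim — the centre-peaked shape the model's
  figure-level claims describe.

Both readings conserve charge and agree with the brute-force oracle to
round-off; only the thin-film reading reproduces the
"two digits above membrane-transport current" magnitude.

## The phasor solve

The drive is a single 20 kHz sinusoid, six orders of magnitude below any
electromagnetic resonance of a millimetre-scale well, so the
electro-quasistatic steady state is solved by complex nodal analysis at
$\omega = 2\pi f$. Conventions:

* **Phasors carry RMS magnitude**: the source phasor is
  $V_{pp}/(2\sqrt2) \approx 5303$ V, so every reported "effective value"
  is simply `Mod(phasor)` with no trailing factors.
* **The ideal source is eliminated by substitution** (the source node is
  a known, not an unknown) — exact, and better conditioned than a
  penalty conductance.
* **Series chains are collapsed before the solve**: every internal
  degree-2 node (the four interior nodes of each vertical stack, the
  three interior nodes of each cell-radial branch) is merged into a
  single branch impedance; after solving the ~31-unknown reduced system,
  per-element voltages and interior node potentials are recovered by
  impedance division. `solve_network_dense()` assembles the full
  142-unknown system with no reduction, as an independent route; the two
  agree to $<10^{-15}$ relative.
* **The solve runs in a source-referenced frame** ($u = V - V_{\rm rms}$)
  with two steps of iterative refinement. In this network all node
  potentials sit within a fraction of a percent of the source potential,
  so differencing absolute potentials would forfeit five digits of every
  branch voltage; in the shifted frame the large constant is carried by
  the exactly-known ground value and branch voltages come out at full
  precision. The maximum Kirchhoff current-law residual over nodes,
  relative to the source current, is ~$10^{-12}$, and complex power
  balances (Tellegen) to ~$10^{-13}$.

A closed-form check pins the solver to hand arithmetic: a single-segment
chain with the membrane layers shorted and $\sigma_c = \sigma_b$ is an
elementary series divider $R_0 + R_{zi} + R_{zo} + 1/(j\omega C_0)$, and
the solver matches it to $10^{-9}$ relative.

## From branch phasors to exposure

Each element knows the length and cross-sectional area of the material
slab it lumps, so $E = |V|/\ell$ and $J = |I|/A$ per element. Per ring
and layer, `layer_profiles()` reports a vertical component (the
upper/lower element pair averaged), a radial component (the inner and
outer incident branches averaged; boundary rings use their single
incident branch — no phantom elements), and their mean. The mean is the
spatial average of the flux through a spherical cell of diameter $H_c$:
its projected areas in $r$ and in $z$ are equal ($\pi H_c^2/4$ each, of
the $\pi H_c^2$ sphere surface), so the surface-averaged current density
reduces to $(J_r + J_z)/2$.

The "cell" curves are taken from the membrane elements: the vertical
stack is a series path (membrane and cytoplasm carry the same vertical
branch current), and it is the membrane that the exposure conversion
targets. Both membrane and cytoplasm layers are exported for comparison.

`membrane_exposure()` converts to what a cell experiences:
$V_m(r_n) = E_{\rm mean}({\rm membrane}) \cdot H_m$ and
$I_{\rm cell}(r_n) = J_{\rm mean} \cdot \pi H_c^2$, annotated with three
physiological reference scales: the ~0.1 V action-potential ceiling of
normal cell activity, the 0.5–1 V range above which membranes suffer
irreversible damage, and the ~1 nA scale of ion-channel membrane
transport. Off-centre, $V_m$ stays near 0.07 V — below even the
action-potential band, far below damage — while the per-cell current is
tens to a hundred nanoamperes, far above the transport scale. That
asymmetry (current far above its physiological scale, voltage below its
own) is the model's core output.

```{r exposure, eval = FALSE}
params <- well_parameters(H_b = buffer_height_from_volume())
exposure <- membrane_exposure(
  layer_profiles(solve_network(build_network(params))))
autoplot(exposure, quantity = "I_cell")
```

## The uniform-medium reference solver

For contrast with the prior, cell-free description, the package includes
an axisymmetric finite-difference (finite-volume) solver of
$\nabla\cdot\left((\sigma + j\omega\varepsilon)\nabla\varphi\right) = 0$
over buffer and plate, with harmonic-mean face conductivities, Dirichlet
ground under the plate, and insulating axis, wall and free surface. It is
deliberately finite-difference, not finite-element: the comparison is
qualitative, and a desk-scale conservative scheme suffices.

Two choices deserve justification:

* **Drive mode.** The plasma contact disc ($r < 0.4$ mm) is driven by a
  *uniform current density* over the disc by default, because that is the
  physical picture of the discharge current supply this model emulates. A
  Dirichlet equipotential disc is also available (`drive = "potential"`,
  plasma as a 1 S/m conducting row), but it produces the classic
  edge-of-electrode current concentration (a factor ~7 between disc edge
  and axis) rather than a near-flat profile under the disc. The injected
  total defaults to $V_{\rm rms}\,\omega\varepsilon_w \pi r_{\max}^2 /
  H_w$ — the plate-dominated admittance of the whole well — which keeps
  magnitudes commensurate with the circuit model and exactly linear in
  $V_{pp}$.
* **Geometry.** Reference runs in the tests use the volume-derived
  ~0.19 mm film. Under a 50 mm water column the mid-depth current
  density is radially uniform *everywhere* (the contrast this solver
  exists to show — near-flat under the disc, decaying beyond it, versus
  the circuit model's strict decay from the first ring — cannot appear at
  any sampling depth), and 50 mm of liquid in a 96-well is not a
  physically realizable exposure anyway.

The profile is sampled at mid-buffer depth by default (`depth_frac`
configurable; no canonical depth exists for this comparison). Discrete
conservation holds cell-by-cell to ~$10^{-10}$ relative and the
disc-to-ground current balance to ~$10^{-10}$. Grid convergence of the
sampled profile between 64×64 and 128×128 is just under 5%; the limiting
feature is the influx discontinuity at the disc edge, which degrades the
scheme locally to first order.

## Overlay scaling and the synthetic efficiency fixture

Comparing a computed profile with a normalized transfection-efficiency
profile $\eta(r)$ requires choosing a vertical scale; "adjust the axis so
the curves overlap" is formalized as the least-squares ratio

$$s = \frac{\sum_w y\,\eta}{\sum_w y^2}$$

over a stated radial window $w$, with the RMS misfit reported
(`overlay_scale()`). Default windows: $r < 1.6$ mm for the cell profile,
0.2–0.5 mm for the circuit-model buffer profile, 0.4–1.6 mm for the
uniform-medium buffer profile.

Measured efficiency profiles enter as two-column CSV
(`read_efficiency()`). For tests and demonstrations,
`synth_efficiency()` generates the characteristic shape: a flat plateau
out to 1.6 mm, a sharp logistic collapse to near zero beyond, plus
truncated Gaussian noise, deterministic under a seed. The generator
emulates only that shape; it does not emulate well-to-well variability,
spatially correlated noise, imaging segmentation artifacts, or any
dependence of the drop radius on operating conditions — so tests passing
against it demonstrate the correctness of the overlay procedure, not
biological fidelity of the model.

## Problem sizes, tolerances, defaults

* Circuit solves: $n = 16$ rings (171 elements, 142 nodes) in
  milliseconds; oracle comparisons at $n \in \{2, 4, 16\}$, agreement
  required at $10^{-10}$ (achieved ~$10^{-15}$).
* Conservation: KCL and power-balance thresholds $10^{-9}$ relative
  (achieved ~$10^{-12}$).
* Reference solver: property checks at 48²–128²; 128×128 solves in a few
  seconds. "Near-flat under the disc" is asserted as max/min ≤ 2.5
  (the residual variation is the film's intrinsic radial funneling), and
  "approximately uniform" vertical membrane current as max/min ≤ 2 over
  the off-centre rings — both thresholds are this package's own
  quantifications of qualitative statements.
* Netlist round-trip: values to 12 significant digits (the writer emits
  15).

## Limitations

* Single-frequency sinusoidal steady state; a frequency sweep is a loop,
  but there is no transient integration and no multi-tone support.
* All elements are linear: no membrane electroporation/breakdown, no
  plasma sheath dynamics, no dielectric dispersion or temperature
  dependence.
* The cell monolayer is strictly one layer; localized cell stacking is
  not represented.
* Chemical factors (reactive species generation and transport) are
  entirely out of scope; the package computes electrical exposure
  profiles and reference bands, and makes no claim about the transfection
  mechanism itself.
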