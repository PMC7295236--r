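---
title: "Modeling microwave tumor ablation with mwablate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling microwave tumor ablation with mwablate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwablate)
```

# The model

`mwablate` simulates microwave ablation (MWA) of solid tumors: a coaxial
slot antenna inserted through the tumor center deposits electromagnetic
power in the surrounding tissue, the tissue heats, and heat kills cells.
Four coupled submodels run on one shared 2-D axisymmetric (r, z)
finite-volume mesh.

**Electromagnetic stage.** Because the geometry — a coaxial antenna on the
axis of a spheroidal tumor — is rotationally symmetric, the full vector
frequency-domain wave equation reduces exactly to a scalar Helmholtz
problem for the azimuthal magnetic field $H_\phi$:

$$\partial_z\!\left(\tilde\epsilon^{-1}\partial_z u\right) +
  \partial_r\!\left(\tilde\epsilon^{-1} r^{-1}\partial_r (r u)\right) +
  \omega^2\mu\, u = 0,
  \qquad \tilde\epsilon = \epsilon_0\epsilon_r - j\sigma/\omega .$$

Conductors are perfect electric conductors; the coax feed is driven with
the TEM mode through a matched port whose net Poynting flux is normalized
to the requested input power; outer boundaries carry first-order absorbing
conditions (adequate because lossy tissue absorbs nearly all power before
the boundary — a perfectly matched layer could replace them later). The
coax is short-circuited at the antenna tip, so radiation leaves through
the slot(s). Resistive heating is $Q_{ext} = \sigma|E|^2/2$.

**Thermal stage.** The Pennes bioheat equation with temperature-dependent
conductivity and perfusion,

$$\rho C\,\partial_t T = \nabla\cdot(k(T)\nabla T)
  + \rho_b C_b \omega_b(T)\,(T_b - T) + Q_m + Q_{ext} + Q_E,$$

is advanced with backward Euler; $k$ and $\omega_b$ are lagged and updated
by Picard iteration to a relative tolerance of $10^{-3}$. The outer tissue
boundary exchanges heat with the surroundings through a Robin condition
$k\,\partial T/\partial n = h\,(T - T_0)$; the symmetry axis and the
antenna surface are adiabatic.

**Dielectric and thermal property laws.** Relative permittivity and
electrical conductivity fall with temperature as tissue water is driven
off, following sigmoid laws
$s_1\,(1 - 1/(1 + e^{s_2 - s_3 T}))$ and
$r_1\,(1 - 1/(1 + e^{r_2 - r_3 T}))$, with tumor amplitudes ($s_1 = 54.8$,
$r_1 = 2$ S/m) above healthy liver ($44.3$, $1.8$ S/m) and shared decay
coefficients — the packaged constants are dumped by
`materials_to_list(default_materials())` or the `mwablate defaults` CLI
subcommand. Thermal conductivity is affine,
$k = k_0 + \Delta k\,(T - T_0)$ with $\Delta k = 1.161\times10^{-3}$
W/m K per K, and perfusion is affine in temperature,
$\omega_b = 2.1\times10^{-5}\,T + 3.5\times10^{-3}$ s$^{-1}$ (evaluated on
the Celsius scale by default; the scale is configurable because the
source law does not state it).

**Cell-death stage.** Each node carries the three-state kinetics
$A \rightleftharpoons V \rightarrow D$,

$$\frac{dA}{dt} = -k_f A + k_b (1 - A - D), \qquad
  \frac{dD}{dt} = k_f (1 - A - D), \qquad
  k_f = \bar k_f\, e^{T/T_k}\,(1 - A),$$

integrated per node with classical RK4 on substeps sized so the fastest
local rate is resolved to better than $10^{-6}$ against a brute-force
reference. The dead state is absorbing and $A + V + D = 1$ holds by
construction. The lesion ("ablation zone") is the region where $V + D$
exceeds a threshold (default 0.5; no published value exists, so it is
configurable), characterized by its axial (long) and radial-diameter
(short) axes. Treatment efficacy is the volume-averaged dead fraction $D$
over the tumor.

**Shrinkage diagnostics.** A temperature-time integral (TTI) accumulates
the temperature excess over the baseline with piecewise coefficients
(0 below 12 °C, 0.1573 to 44.1 °C, 0.3011 to 102.1 °C, 0.54163 above);
the thermal-expansion coefficient is
$\alpha_t = -0.03\,\mathrm{TTI}^{0.4684}/(T_K - 285)$ and the thermal
strain $E_{th} = \alpha_t (T - T_{ref})$. Shrinkage is reported as the
volume-weighted mean of $(1 + E_{th})^3 - 1$; it is a post-processing
diagnostic only — the mesh is not deformed and nothing feeds back into
the EM or thermal solves, because the full elastic problem is outside the
package's scope and the headline metrics are defined on the undeformed
domain. The printed form of the $\alpha_t$ law is typographically
ambiguous in its source; the division reading with absolute temperature is
the default and the parsing is a config switch whose output is labeled.
The first TTI branch is printed inconsistently in its source
("0, (12°C ≤ T)"); the only reading consistent with the second branch —
zero *below* 12 °C — is implemented.

# Numerical choices

* **Mesh.** Tensor-product cells with faces snapped to every antenna
  radius, the tip and the slot edges; radial spacing grows geometrically
  from 0.14 mm at the catheter to ≤ 1.8 mm at the outer wall, axial
  spacing is 0.65 mm in a window around the tumor and slots and 2.6 mm
  outside. The default multiplier (`res = 1`) yields roughly 45 × 60–90
  cells depending on tumor size — the package's desk-scale operating
  point; `res = 2` halves every target spacing.
* **Time step.** The configuration default is 0.1 s. The packaged
  scenario sweeps run at 0.5 s and the acceptance reproduction at 1 s,
  both with a 5 s metric cadence: halving the step from 1 s to 0.25 s
  moves a representative stopping-rule outcome by under one percentage
  point, so these steps are comfortably in the converged regime for the
  reported metrics.
* **Segregated coupling.** The EM field is re-solved only when the
  conductivity field has drifted more than 2% (relative, with the
  per-node reference floored at 5% of the field scale so desiccated
  near-zero nodes do not force perpetual re-solves) since the last solve;
  after each solve the deposition is rescaled so port power stays exact.
* **Evaporation.** The energy of vaporizing tissue water
  ($w\,\rho\,L_{vap}$ per unit volume, $w = 0.778$ for liver) is absorbed
  across a 99–105 °C band by an operator-split enthalpy correction: the
  plateau temperature rises linearly across the band as the local water
  budget fills, the correction is closed-form per cell and conserves
  energy exactly, and once the budget is exhausted temperatures rise
  freely. A band formulation inside the implicit iteration was rejected
  because the apparent capacity is ~80× the sensible capacity and makes
  fixed-point iteration cycle.
* **Dielectric-law validity clamp.** The sigmoid property laws were
  fitted below ~150 °C and decay toward zero far beyond it; evaluated
  literally, a fully desiccated cell becomes a lossless capacitive gap
  whose field diverges ($Q \propto 1/\sigma$), which sent hot-spot
  temperatures to physically meaningless values. The laws are therefore
  evaluated at $\min(T, 160\,°C)$, holding desiccated tissue at its
  plateau properties ($\epsilon_r \approx 1.8$,
  $\sigma \approx 0.09$ S/m for healthy liver).
* **Hyper-stiff kinetics.** Nodes whose forward rate would turn the state
  over more than five times within one step (reached only above roughly
  300 °C) are set directly to the absorbing limit $D = 1$; elsewhere RK4
  substeps keep the integrator within $10^{-6}$ of the reference.
* **Initial alive fraction.** $k_f \propto (1 - A)$ makes $A = 1$ a fixed
  point, so the default state seeds 1% vulnerable cells
  (`A_init = 0.99`); the kinetics parameters
  ($\bar k_f = 3.33\times10^{-3}$ 1/s, $k_b = 7.77\times10^{-3}$ 1/s,
  $T_k = 40.5$ °C) are the fitted values of the source three-state model,
  exposed in `cell_death_params()` because different cell lines calibrate
  differently.

# Scenarios and the stopping rule

`run_until_side_effect()` terminates a treatment at the first recording
instant where the monitored healthy-tissue damage reaches the allowable
level $D_s$ (default 10%): the mean dead fraction over a healthy shell of
eight tumor volumes (a similar spheroid scaled by $9^{1/3}$) for
shape/frequency/antenna studies, or the dead fraction at a fixed point
2.5 mm radially outside the tumor border for size studies, where a
constant-volume shell would not be comparable across sizes.

Tumor shapes are equal-volume spheroids: prolate semi-axes
$(r_{eq}\lambda^{-1/3}, r_{eq}\lambda^{2/3})$ with the major axis along
the antenna, oblate $(r_{eq}\lambda^{1/3}, r_{eq}\lambda^{-2/3})$ with the
short axis along the antenna. The single slot sits at the tumor center;
the double-slot layout puts the bottom slot half a semi-major axis below
the center with slot-to-slot distance $L$ expressed in units of the
semi-major axis $b$.

Packaged presets (`scenario_suite()`): `power_size` (0.5/1/1.5 cm spheres
at 25 and 50 W), `shape_lambda` (oblate/prolate at aspect ratios 2 and 5,
20 W), `frequency_shape` (the five shapes at 2.45 vs 6 GHz; the study's
input power is not published, so the preset reuses the 20 W of the shape
study and its outcomes are labeled assumption-dependent), `antenna_slots`
(prolate $\lambda = 5$ at 70 W: single slot, double slot $L = b$ and
$L = 1.4b$), and two validation presets (`sun_validation`: homogeneous
liver at 80 W/915 MHz and 50 W/2.45 GHz for 600 s; `yang_validation`:
excised liver from 5 °C at 75 W/2.45 GHz for 150 s with perfusion off and
the boundary temperature tied to the initial value).

Antenna dimensions are not published for the reference design; the
surrogate radii (inner conductor 0.135 mm, dielectric 0.47 mm, outer
conductor 0.595 mm, catheter 0.895 mm, slot height 1 mm) are standard
thin-coax values and fully configurable. The domain is a 4 cm × 8 cm
cylinder with the antenna tip 1 cm above the bottom and the tumor
centered at mid-height.

# What the synthetic fixtures emulate

The package tests itself without any external data:

* `make_manufactured()` builds exact solutions of the bioheat equation
  (with matching volumetric forcing and boundary data) that are linear in
  time, so a backward-Euler step is temporally exact and the measured
  convergence isolates the spatial discretization (observed order ≈ 1.94
  on the 40→80 cell pair).
* `make_sar()` provides analytic deposition surrogates — a separable
  Gaussian and a skewed "teardrop" mimicking how ablation zones elongate
  along the antenna — normalized to a prescribed total power, so the
  thermal/kinetics/metrics chain can be exercised with the EM stage
  bypassed.
* `temperature_program()` supplies constant/ramp/step/recorded traces
  driving the kinetics and shrinkage stages in isolation.

These fixtures reproduce the *structure* of real runs, not their physics:
passing tests demonstrate correct numerics (conservation, convergence,
oracle agreement), not clinical fidelity. Real tissue heterogeneity,
vascular sinks, antenna reflection mismatch and measurement noise are all
outside what the fixtures emulate.

# Known limitations

* The published scenario outcomes were produced with a 3-D commercial FEM
  whose antenna geometry, some treatment durations and the cell-death
  parameter triple are not printed. With the surrogate antenna and the
  source-model kinetics, this implementation reproduces the input-power
  study and the prolate/single-slot outcomes closely, but it predicts
  larger ablation zones than published for the homogeneous-liver
  validation scenario and higher dead fractions for oblate tumors, and
  its double-slot layout distributes power between the slots differently
  (top-slot dominated), reversing the published single-vs-double ranking.
  All three discrepancies are sensitive to the unpublished antenna
  dimensions and kinetics constants; the configuration surface exposes
  every such parameter.
* First-order absorbing boundaries slightly under-absorb at 915 MHz where
  tissue attenuation is weaker.
* Density and specific heat are temperature-independent; water transport
  and vapor convection are not modeled beyond the enthalpy sink.
* The shrinkage stage reports contraction diagnostics only; no
  stress/displacement solve, no mesh deformation.

# A small worked example

```{r example, eval = FALSE}
cfg <- scenario_config(shape = "prolate", r_eq_mm = 5, lambda = 2,
                       power_W = 20, frequency_GHz = 2.45,
                       duration_s = 1200, dt_s = 0.5, cadence_s = 5)
res <- run_until_side_effect(cfg)
print(res)
write_outputs(res, "prolate-run")
```

The run stops when the shell-mean dead fraction reaches 10% and reports
the tumor-mean dead fraction, the lesion axes and the volumetric
contraction; `write_outputs()` emits the metric time series as CSV, the
final fields as legacy VTK and a JSON manifest with the configuration
hash.
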