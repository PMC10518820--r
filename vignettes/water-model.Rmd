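---
title: "An analytical four-state model of liquid water in two dimensions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An analytical four-state model of liquid water in two dimensions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbwater)
```

## The model

`mbwater` implements a nearly analytical statistical-mechanical theory of
liquid water built on the two-dimensional Mercedes-Benz (MB) picture: each
water molecule is a Lennard-Jones disk with three hydrogen-bonding arms at
120 degrees. Bookkeeping is done on the hexagonal lattice underlying ice-like
order; the theory considers one molecule and its clockwise neighbour around a
hexagon, whose relationship is in one of four states:

* **HB** -- a hydrogen bond. Pointing an arm at angle $\theta$ (within the
  window $|\theta| \le \theta_{\max}$) at the neighbour costs
  $E_{HB}(\theta) = -(\epsilon_{HB} + \epsilon_{LJ}) + k_s\theta^2$:
  a harmonic angular well of depth $\epsilon_{HB}$ on top of the dispersion
  contact.
* **LJ** -- a van der Waals contact only, $E_{LJ} = -\epsilon_{LJ}$,
  orientation independent and tighter in area.
* **0** -- no interaction, $E_0 = 0$.
* **c** -- the cooperative hexagonal cage: when all six members of a hexagon
  hydrogen bond at once, each gains an extra stabilization $\epsilon_c$ and
  occupies the larger, open cage area $v_c$.

Working at constant temperature and pressure (reduced units:
$T^* = k_BT/|\epsilon_{HB}|$, $p^* = p\,r_{HB}^2/|\epsilon_{HB}|$, $k_B = 1$),
each state gets an isothermal--isobaric weight
$\Delta_i \propto e^{\beta\,\text{(well depth)}}\,e^{-\beta p^* v_i}$, the HB
and cage weights additionally carrying the normalized orientational factor
$I(\beta) = \frac{1}{2\theta_{\max}}\int_{-\theta_{\max}}^{\theta_{\max}}
e^{-\beta k_s \theta^2}\,d\theta$. The six bonds of a hexagon are independent
except that the all-bonded ring is promoted to the cage channel:

$$\Psi = (\Delta_{HB} + \Delta_{LJ} + \Delta_0)^6 - \Delta_{HB}^6
      + (\delta\,\Delta_c)^6 , \qquad \delta = e^{\beta\epsilon_c},$$

and the system partition function is $Q = \Psi^{N/6}$ (each molecule has
three interaction sites, and each bond is shared by two molecules, so $N$
molecules own $N/6$ hexagons' worth of independent bond sums). Populations
are logarithmic derivatives,
$f_i = \tfrac{1}{6}\,\partial\ln\Psi/\partial\ln\Delta_i$, which sum to one
structurally because $\Psi$ is homogeneous of degree six in the weights.

On top of the bond term every molecule carries a translational free-volume
factor $\big(v_{\mathrm{free}}/(\beta p^*)\big)$ with fraction
$v_{\mathrm{free}} = 0.1$: a cell-model term representing the centre-of-mass
room a molecule has inside its cage of neighbours. It is state independent,
so it cancels exactly in the populations, but it gives the equation of state
a finite, gas-like compressibility floor,
$v = \sum_i f_i v_i + v_{\mathrm{free}} T^*/p^*$. Without it the lattice
volume is pinned to the discrete state volumes and the compressibility
collapses exponentially whenever a single state dominates, which makes the
speed of sound diverge in the cold liquid and inverts the low-temperature
behaviour of the thermal conductivity. The fraction 0.1 is a typical liquid
free-volume fraction; it is exposed as `v_free_frac` (set it to 0 for the
bare lattice model).

### Why the cooperativity factor is $\ge 1$

The cage channel must be *stabilizing*: cold water's anomalies come from
ice-like cages proliferating on cooling, and the cage mean bond energy is
$\langle E_c\rangle = \langle E_{HB}\rangle - \epsilon_c$. Thermodynamic
consistency then fixes the weight: the enthalpy computed from populations,
$h = \sum_i f_i(\langle E_i\rangle + p^* v_i)$, must equal
$-\tfrac{1}{6}\,\partial\ln\Psi/\partial\beta$, which requires
$\delta = e^{+\beta\epsilon_c}$. The package stores $\epsilon_c \ge 0$ as the
magnitude of the (negative) cooperativity energy. With the opposite sign
convention the analytic and numeric temperature derivatives of $\ln\Psi$
disagree by about one percent at liquid state points -- the package's
consistency tests would catch it.

## From equilibrium to transport

Molecules random-walk between cage-of-neighbour sites. Each state has a step
size $\lambda_i$ (the HB distance $r_{HB}$ for HB and cage molecules, the
contact distance $\sigma_{LJ}$ for LJ, and the mean intermolecular distance
$\sqrt{v_0}$ for free molecules) and a hop rate equal to the Boltzmann factor
of its mean bond enthalpy,

$$\nu_i = C\,e^{\beta(\langle E_i\rangle - p^* v_i)} .$$

Escaping a state means breaking its bond *and* doing $pV$ work to open a
void, so compression slows every state. This is the form that produces the
observed two-pressure-regime diffusion anomaly; with an energy-only factor
(`freq_form = "energy"`) the per-state rates are pressure independent and a
cold isotherm $D(p^*)$ can only rise toward its dense-liquid limit. The
random-walk numerical prefactor is absorbed into the unit-fixing constant
$C$ (`c_freq`).

The transport chain is then

* $D = \sum_i f_i \lambda_i^2 \nu_i$ (population-weighted mixture, exact),
* $\eta = T^*/(c_{SE}\,D\,d)$ -- the Stokes--Einstein inversion with average
  diameter $d = (f_{HB}+f_{LJ}+f_0)\,r_{HB} + 2 f_c\,r_{HB}$ (a caged
  molecule moves with its hexagon, of diameter $2r_{HB}$),
* $c_s = \sqrt{c_p/(c_v\,\rho\,\kappa_T)}$ -- adiabatic sound speed with
  unit molecular mass,
* $\kappa = 2\,\rho^{1/2} c_s$ -- the two-dimensional Bridgman relation
  (molecular spacing scales as $\rho^{-1/2}$ in 2D, and the prefactor is the
  spatial dimensionality; both are exposed as parameters),
* $a = \kappa/(\rho\,c_p)$ -- thermal diffusivity.

By construction $\eta\,D\,d\,c_{SE} = T^*$ identically; the *physical*
Stokes--Einstein breakdown of the model appears instead as state points with
equal $\eta/T^*$ but different $D$ (the acceptance script reports the spread
it finds, about 40% across the default grid).

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `eps_hb` | 1 | energy | optimal hydrogen-bond depth (sets the scale) |
| `r_hb` | 1 | length | hydrogen-bond separation (sets the scale) |
| `eps_lj` | 0.1 | energy | LJ contact depth |
| `sigma_lj` | 0.7 | length | LJ contact distance |
| `k_s` | 10 | energy/rad^2 | angular spring constant of the HB well |
| `eps_c` | 0.03 | energy | cage cooperativity bonus per molecule |
| `v_hb`, `v_0` | 1.0 | area | area per molecule, HB and open states |
| `v_lj` | `sigma_lj`^2 = 0.49 | area | area per molecule, LJ contact |
| `v_c` | 1.2 | area | area per molecule in the open, ice-like cage |
| `theta_max` | $\pi/3$ | rad | half-width of the bonding window |
| `v_free_frac` | 0.1 | -- | translational free-volume fraction |
| `c_freq` | 1 | frequency | unit-fixing hop-rate prefactor |
| `c_se` | $3\pi$ | -- | Stokes--Einstein constant (stick value) |

The six interaction constants are the standard parameterisation of the 2D
model. The per-state areas are not published alongside them; the defaults
encode the physics that matters -- the LJ contact is tight
($v_{LJ} = \sigma_{LJ}^2$) and the cage is open ($v_c > v_{HB}$, ratio 1.2
comparable to the ice/water density ratio exaggerated for 2D) -- and all are
configurable. `theta_max` defaults to the full $\pi/3$ bonding window; the
per-arm reading ($\pi/6$) is also defensible, so it is exposed rather than
hard-coded.

## Numerical choices

* **Log-space weights.** All weight arithmetic uses log-sum-exp; the hexagon
  bracket is evaluated as $1 - a^6 + q^6$ with $a = \Delta_{HB}/S < 1$
  strictly, so there is no catastrophic cancellation and the code survives
  $\beta$ of 50 and beyond.
* **Quadrature.** The orientational integrals use adaptive quadrature
  (`stats::integrate`, relative tolerance $10^{-12}$), validated against a
  $10^5$-node composite trapezoid oracle to $10^{-8}$. Results are cached per
  isotherm, since they are pressure independent.
* **Derivatives.** $v$, $h$, $s$ are analytic (population-weighted closed
  forms; the identities $v = \partial g/\partial p$ and
  $h = -\tfrac{1}{6}\partial\ln\Psi/\partial\beta + v_{\mathrm{free}}T^*$
  are verified numerically to $10^{-6}$ in the tests). Second-derivative
  quantities ($\kappa_T$, $\alpha_p$, $c_p$) differentiate those analytic
  functions with five-point central stencils (relative step $10^{-4}$,
  shrunk near the $p^* = 0$ boundary) plus one Richardson level; the
  free-volume tail is differentiated in closed form so small pressures lose
  no accuracy.
* **Oracles.** The enumeration oracle discretizes the bond angle on an odd
  number of trapezoid nodes (so $\theta = 0$, the well bottom, is always a
  node) and sums Boltzmann weights over hexagon configurations; the
  factorized per-bond route is exact for this partition function and fast,
  and a full $(n_\theta + 2)^6$ configuration sweep (refused above
  $n_\theta = 9$) cross-checks the factorization.
* **Problem sizes.** The test suite evaluates populations on the full
  50 x 20 default grid, enumerates against the oracle at 12 fixed-seed state
  points for $n_\theta \in \{5, 9, 15, 21\}$, and scans trends on isotherm /
  isobar grids of 21--27 points; the whole suite runs in well under a minute.

## What the trend checks do and do not show

The model panel claims are qualitative: $D$ rises and $\eta$ falls with
temperature at fixed pressure; a cold isotherm ($T^* = 0.16$) passes through
an interior maximum of $D(p^*)$ -- compression first breaks cages, freeing
molecules, and only then crowds the liquid -- while a hot isotherm
($T^* = 0.30$) only slows down; the thermal conductivity has an interior
maximum in temperature on a high-pressure isobar ($p^* = 0.5$) and is
monotonic at low pressure ($p^* = 0.05$). The tests assert exactly these
sign patterns on the model's own grids. They do not assert quantitative
agreement with real water: the model is two-dimensional, so units and
geometry differ and only trends are comparable. The anomaly loci (the cold
$D(p^*)$ peak near $p^* \approx 0.33$, the conductivity peak near
$T^* \approx 0.2$) are properties of this parameterisation, found by grid
scan, not fitted to experiment.

## Known limitations

* Two-dimensional: quantitative comparison with real water is out of scope.
* No phase-boundary location, spinodals, or interfacial properties; at
  $p^* \to 0$ the free-volume term diverges (the liquid evaporates), so the
  equation of state requires $p^* > 0$.
* The Stokes--Einstein constant in 2D is conventional; `c_se` rescales
  $\eta$ uniformly and nothing else.
* At pressures well above $p^* \approx 0.7$ the cold end of
  $\kappa(T^*)$ turns back up (the hydrogen-bonded liquid stiffens once
  cages are crushed); the high-pressure interior maximum lives on the
  $p^* \approx 0.3$--$0.6$ isobars.
* Hop rates are local-equilibrium Boltzmann factors; there is no
  time-correlation-function transport theory behind them, and no attempt to
  locate a dynamic crossover.

## A worked state point

```{r example}
st <- thermo_state(0.2, 0.19)
eq <- equilibrium_properties(st)
eq
dyn <- dynamic_properties(st, eq = eq)
dyn
```

Note the negative thermal expansivity (`alpha_p`): at this cold state point
the model is inside its density-anomaly region -- heating converts open
cages into denser states and the liquid contracts.

```{r trends}
tab <- run_sweep(t_grid = seq(0.16, 0.34, length.out = 7),
                 p_values = c(0.05, 0.5))
trend_report(tab)
```
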