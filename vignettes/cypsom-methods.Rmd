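---
title: "Methods: two-site occupancy modelling and trajectory regioselectivity analysis"
author: "cypsom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-site occupancy modelling and trajectory regioselectivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypsom)
```

## The scientific problem

Human CYP3A4 hydroxylates midazolam (MDZ) at two positions: C1 (the major
product, 1-OH MDZ) and C4 (the minor product, 4-OH MDZ). Which position is
attacked depends on the occupancy state of the enzyme: with only one MDZ
bound in the productive position of the active site, the product is
essentially pure 1-OH; when a second molecule — MDZ itself or a
heterotropic effector such as progesterone — occupies the peripheral
allosteric site at the protein–membrane interface, about 35% of the
product appears as 4-OH. The ratio of the two formation rates, the
site-of-metabolism (SOM) ratio, is therefore a sensitive reporter of
allosteric binding, and its concentration dependence distinguishes
allosteric effectors from competitive inhibitors.

This package implements that reasoning as a quantitative pipeline: an
equilibrium occupancy model that predicts rates and the SOM ratio, fitting
machinery to recover binding constants from rate data, a classifier for
effector mode, a geometric analysis of MD trajectories that rationalises
the regioselectivity shift, and seeded synthetic-data generators that make
every stage testable without access to experimental or simulation data.

## The two-site occupancy model

### States and weights

Two sites are modelled: the productive position `P` in the substrate
pocket and the allosteric site `A`. Each can be empty, hold substrate
`S`, or hold effector `X`, giving a 3 × 3 state grid. Binding is treated
as rapid equilibrium with stepwise constants, and the allosteric site is
only populated when the productive site is already occupied — the
stepwise scheme under which the homotropic partition function reduces to
the classical two-step form

$$Z = 1 + \frac{s}{K_1} + \frac{s^2}{K_1 K_2},$$

with $K_1$ = `kd_prod_s` and $K_2$ = `kd_allo_s`. State weights are
products of site terms $[\mathrm{ligand}]/K_d$; a disabled binding mode
(spelled `disabled` for the effector–allosteric constant, `nobind` for
the effector–productive constant, `Inf` in code) contributes weight zero,
so the corresponding grid cells are exactly zero rather than merely
small. No equation for the scheme is fixed by the experiments themselves;
the stepwise form was chosen because the resolved constants are stepwise
constants, and because it keeps the homotropic limit identifiable from a
single progress curve. Simultaneous three-ligand binding (a third steroid
site exists at the membrane interface) is deliberately out of scope.

### Turnover and regioselectivity

Only states with substrate in the productive position turn over:
`(S, empty)`, `(S, S)` and `(S, X)`. Each has a turnover number
(`kcat_s`, `kcat_ss`, `kcat_sx`, min⁻¹ per enzyme; all default to 1 so
that attention stays on regioselectivity, with unequal values available
for rate-inhibition scenarios) and a 4-OH product fraction (`f4oh_s = 0`,
`f4oh_ss = 0.35` by default; `f4oh_sx` is a per-effector free parameter).
States with the effector in the productive position are catalytically
silent, which is what makes them *competitive*: they drain occupancy
without contributing product.

Rates are occupancy-weighted sums. The SOM ratio `v_1oh / v_4oh` is
reported as a typed `NA` sentinel whenever no 4-OH is formed — never
`Inf` — so result tables serialise cleanly.

Default binding constants are 5.1 µM (productive) and 14.7 µM
(allosteric), the stepwise values resolved for MDZ in nanodisc-bound
CYP3A4. Two structural consequences of the model are worth stating
because the tests rely on them: the 4-OH product share rises
monotonically with substrate and saturates at `f4oh_ss` (35% by default),
and the heterotropic perturbation of the SOM ratio shrinks as substrate
outcompetes the effector at the allosteric site, vanishing in the
saturating limit.

## Fitting

`fit_rate_data()` minimises the weighted joint residual
$\sum_i [(v_{1,i} - \hat v_{1,i})^2 + (v_{4,i} - \hat v_{4,i})^2]/sd_i^2$
with Levenberg–Marquardt (via minpack.lm). Numerical choices:

* dissociation constants and turnovers are log-parameterised, product
  fractions logit-parameterised, so every iterate respects positivity and
  `[0, 1]` bounds without constrained optimisation;
* 10 multi-starts: the first from the user's initial values, the rest
  from seeded Gaussian perturbations (sd 0.5 on the unconstrained scale);
  the lowest residual wins, ties broken by the smaller parameter norm;
* identifiability is checked *post hoc* from the numeric Jacobian at the
  optimum: a free parameter whose residual derivatives vanish (for
  example the effector constant when no row contains effector) is
  flagged and its standard error reported as `NA` rather than silently
  returned;
* standard errors come from the Gauss–Newton covariance on the
  unconstrained scale, delta-transformed back to natural units;
* non-convergence of every start raises a typed convergence error; a
  best-effort optimum that did not formally converge is returned with
  its flag lowered, never silently.

Spin-shift titrations are fitted by the same machinery through
`fit_titration()`, as a non-cooperative Langmuir isotherm
$B_{max} \, l / (K_s + l)$. A flat response raises an identifiability
error; designs sampling only far below $K_s$ converge but report the
large $K_s$ uncertainty honestly, since such data constrain only the
initial slope.

## Effector-mode classification

`classify_effector_mode()` compares observed rates under effector against
the baseline model fitted to effector-free rows, at matched substrate
concentrations, and aggregates by medians for robustness to noise. The
relative SOM shift and relative total-rate shift are each compared to a
threshold (default 0.2, i.e. a 20% change; chosen well above the spread
produced by 5% measurement noise yet far below the several-fold shifts
typical of genuine effectors). SOM down → `allosteric-4OH-favoring`; SOM
up → `allosteric-4OH-suppressing`; rate down with SOM flat →
`competitive-inhibition`; both → `mixed`; neither → `no-effect`. A
baseline producing no 4-OH at all that acquires a finite SOM under
effector counts as a maximal SOM decrease.

## Trajectory analysis

### Virtual ferryl oxygen

The reactive Compound I oxygen is not present in classical MD, so it is
represented by a virtual point. Construction: least-squares plane through
the four pyrrole nitrogens; unit normal oriented away from the proximal
cysteine thiolate sulfur; the point is placed `fe_o_distance` along that
normal from the iron. The default 1.65 Å is a typical ferryl Fe=O bond
length; the exact value used by the original analysis is not recorded, so
it is exposed as a parameter. The construction is rigid-motion
equivariant (tested to 10⁻⁹ Å), and degenerate geometries — collinear
nitrogens, an axial sulfur in the heme plane, nitrogens more than 0.5 Å
out of plane — raise typed geometry errors instead of producing a
silently misoriented oxygen.

### Frame classification

A frame is *productive* when C1 is within 4.5 Å (inclusive) of the
virtual oxygen, matching the hydrogen-abstraction geometry of P450
catalysis; a productive frame is *selective* when C4 is strictly more
than 5.5 Å away, and *non-selective* otherwise. Boundary conventions
mirror the wording "within" and "more than". The 5.5 Å criterion is
measured to the virtual oxygen, not to the iron — the source wording
("further away from heme") is ambiguous on this point, and the choice is
recorded here deliberately; users can reproduce the other reading by
passing `fe_o_distance = 0`. Frame indices are 0-based over the
trajectory as read, and stride is applied after reading.

### Contacts

A residue is in contact with the ligand in a frame when any heavy-atom
pair distance is at most 4.0 Å (hydrogens excluded). No cutoff is fixed
by the original analysis; 4.0 Å is a standard close-contact heavy-atom
criterion, and it is exposed as `contact_cutoff`. Contact frequencies
over productive frames are compared between conditions as relative
changes, with ±50% flagged as major losses/gains; residues with zero
baseline frequency are reported as a `new-contact` category rather than
divided by zero.

Trajectories are read from PDB topologies with multi-model PDB or binary
DCD coordinates (via bio3d), all in Ångström. XTC input is not supported
in this implementation.

## Synthetic data: what it emulates and what it does not

The generators stand in for data that are not publicly deposited; they
emulate the *statistical structure* the analysis consumes, not the
physics.

* **Kinetics** (`generate_rate_dataset()`): exact model rates plus
  `none`/`additive`/`proportional` Gaussian noise, truncated at zero.
  Default design: 12 log-spaced substrate points over 0.5–100 µM,
  bracketing both binding constants.
* **Titrations** (`generate_titration()`): Langmuir responses with
  additive noise clipped to `[0, 1]`.
* **Toy trajectories** (`generate_toy_trajectory()`): an idealised rigid
  heme, the two substrate carbons, and one pseudo-atom per watched
  residue. Per frame, productive/selective labels are drawn first and
  the C1/C4 distances are then sampled from truncated normals on the
  correct side of the thresholds — means 3.8/5.2 Å for C1 in/out and
  4.8/6.3 Å for C4 near/far, sd 0.3 Å, truncated 0.05 Å clear of the
  boundaries. This guarantees an exact label round trip through the
  classifier while spanning a plausible distance range. Contact
  pseudo-atoms are placed inside the cutoff (relative to C1) or outside
  it (relative to the C1/C4 midpoint, with geometric clearance) per
  sampled Bernoulli indicators.

Passing tests on these fixtures demonstrates that the *analysis* is
correct against known ground truth; it does not demonstrate anything
about real CYP3A4 ensembles, which have flexible hemes, correlated
frames, full residues, and distance distributions that no one has
published in numerical form.

Scenario presets encode the published experimental designs (15 µM
progesterone; steroid panels at 20/50 µM; medroxyprogesterone at 2/8 µM
because it binds much tighter; a weak Schisandrin-like effector probed at
0.3–1.3 × its Ks). Effector-specific constants are *not* published for
this system, so the presets fix plausible values once: allosteric Kd of
5 µM for progesterone (binding must be strong at 15 µM for the observed
effect, and MDZ outcompetes it above ~15 µM), 20 µM for generic steroids,
2 µM for medroxyprogesterone, 8–10 µM for the non-steroids. The
opposite-direction preset (`anf_gefitinib_opposite`) sets `f4oh_sx = 0`:
the idealised suppressing effector locks the substrate into its C1-only
orientation, which makes the SOM increase unambiguous across the whole
substrate range rather than reversing sign below ~2.5 µM as intermediate
`f4oh_sx` values do. The trajectory pair preset encodes the simulation
signature: equal productive fractions (~52%), selective fraction dropping
from 0.8 to 0.6 under effector, major contact losses at residues 106,
108, 215, 218, 220, minor losses at 217 and 309, a major gain at 214 and
a minor gain at 304. Designated major-change probabilities are kept at
least ~3 standard errors from the 50% flag boundary at the default 1000
frames, so sampling noise cannot flip a designated flag.

## Problem sizes

The test-suite and acceptance computations use desk-scale sizes chosen to
make every statistical check sharp but quick: 12-point concentration
designs, 20 noisy replicates for the recovery study, 50 seeds for the
titration bias study, 1000-frame trajectories for the condition
comparison, and 10,000 random frames / 10,000-frame generators for the
exact-agreement and binomial-convergence checks. The original
simulation-scale numbers (eight trajectories totalling 3.8 µs, ~14,000
productive frames per condition) require the unreleased trajectories and
are not reproduced.

## Known limitations

* The occupancy model is equilibrium-only; kinetic binding schemes,
  NADPH coupling and product inhibition are out of scope.
* The stepwise scheme excludes allosteric-only occupancy states; an
  effector that binds the allosteric site of the *empty* enzyme is
  indistinguishable from one that waits for substrate, because only
  product rates are observed.
* Effector identifiability requires concentration variation: with a
  single effector level, `kd_allo_x` and `f4oh_sx` are partially
  confounded, and the fit reports correspondingly large uncertainties.
* The toy trajectory generator samples frames independently; it cannot
  emulate autocorrelation, and contact indicators are independent across
  residues, unlike real loop motions.
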