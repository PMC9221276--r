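# cypsom

Modelling and analysis of heterotropic drug–drug interactions at human
cytochrome P450 CYP3A4, using midazolam (MDZ) as the probe substrate.

CYP3A4 metabolises a large share of marketed drugs, and molecules that bind
its peripheral allosteric site — the pocket between the F–F′ and G–G′ loops
and the membrane lipid head groups — can change how a co-administered
substrate is metabolised without ever entering the active site. Midazolam
makes this visible: it is hydroxylated at C1 (1-OH MDZ, major product) and
C4 (4-OH MDZ, minor product), and the **site-of-metabolism (SOM) ratio**
`v_1OH / v_4OH` shifts when an effector occupies the allosteric site. This
package is aimed at enzymologists and modellers who want to simulate,
fit, and classify such interactions, and at simulation scientists who want
to connect them to molecular-dynamics trajectories.

## The model

The enzyme is described by two ligand sites: the productive position `P`
inside the substrate-binding pocket and the peripheral allosteric site
`A`. Binding is rapid-equilibrium and stepwise (the allosteric site is
populated only once the productive site is occupied), giving the state
weights

```
w(P, A) = w_P · w_A,   w_P ∈ {1, s/K1, x/K_Px},   w_A ∈ {1, s/K2, x/K_Ax}
```

with `s` the substrate and `x` the effector concentration (µM), `K1`,
`K2` the stepwise dissociation constants of the substrate at the
productive and allosteric sites (defaults 5.1 and 14.7 µM, the values
resolved for MDZ in nanodiscs), and `K_Ax`, `K_Px` the effector constants
(either may be disabled). Fractions follow from the partition function
`Z = Σ w`; in the homotropic limit `Z = 1 + s/K1 + s²/(K1·K2)`.

Each productive state carries a turnover `kcat` and a regioselectivity
`f4OH`, the fraction of product hydroxylated at C4. The singly-bound
state makes 1-OH exclusively (`f4OH = 0`); a second MDZ or an effector at
the allosteric site unlocks ~35% 4-OH formation. Predicted rates are
occupancy-weighted sums, and the SOM ratio follows.

On the simulation side, trajectory frames are classified *productive*
when the substrate C1 lies within 4.5 Å of a virtual Compound I ferryl
oxygen (placed 1.65 Å above the heme iron along the distal pyrrole-plane
normal), and *selective* when C4 additionally sits more than 5.5 Å away.
Per-residue ligand contact frequencies over productive frames are
compared between conditions, flagging residues whose contact frequency
changes by at least 50%.

## Worked example

Progesterone-like effector (allosteric `Kd` 5 µM, `f4OH_SX = 0.35`) at
15 µM against the homotropic baseline:

```r
library(cypsom)
p <- occupancy_params(kd_prod_s = 5.1, kd_allo_s = 14.7,
                      kd_allo_x = 5, f4oh_sx = 0.35)
som_curve(p, s_grid = c(1, 5, 25, 100), x_levels = c(0, 15))
#>   s_um x_um     v_1oh       v_4oh som_ratio
#> 1    1    0 0.1692952 0.003860152 43.857143
#> 2    5    0 0.5173805 0.050440998 10.257143
#> 3   25    0 0.7248447 0.204923792  3.537143
#> 4  100    0 0.6903439 0.303162330  2.277143
#> 5    1   15 0.3265935 0.117125473  2.788407
#> 6    5   15 0.5916060 0.218100363  2.712540
#> 7   25   15 0.6868183 0.278632884  2.464958
#> 8  100   15 0.6791928 0.316108398  2.148607
```

At 1 µM substrate the effector drives the SOM ratio from ~44 down to
~2.8 (4-OH strongly favoured); by 100 µM the substrate has outcompeted
the effector at the allosteric site and the curves nearly merge — the
concentration-dependent signature of a true allosteric effector.

Fitting recovers the generating constants from synthetic data:

```r
d <- generate_rate_dataset(occupancy_params(), rate_design(seed = 42))
fit_rate_data(d, occupancy_params(kd_prod_s = 2, kd_allo_s = 40),
              free = c("kd_prod_s", "kd_allo_s"))
#> Occupancy model fit (12 rows, 10 starts)
#>   converged: TRUE   RSS: 0
#>           estimate se identifiable
#> kd_prod_s      5.1  0         TRUE
#> kd_allo_s     14.7  0         TRUE
```

End-to-end workflows (`run_kinetics_workflow()`,
`run_trajectory_workflow()`, `make_synthetic()`) orchestrate fitting,
SOM curves, effector-mode verdicts and trajectory comparisons from a
flat YAML config; `inst/cli/cypsom.R` exposes them as shell subcommands.

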