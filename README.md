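# cgligand

Coarse-grained simulation of ligand–receptor binding kinetics, and of the
selectivity of bivalent chimeric ligands.

## The problem

Cell-surface receptors are the most common drug target, and rational design
of synthetic ligands needs models that sit between two extremes: reaction-
kinetics ODEs, which erase the spatial structure of the membrane encounter,
and atomistic simulation, which cannot reach many-particle statistics.
`cgligand` implements a tunable middle ground: ligands are spheres
performing Langevin dynamics in 3-D above a flat membrane; receptors are
spheres confined to the membrane plane; a complementary pair binds through
an anisotropic (patchy) Lennard-Jones potential

V(r, θ) = V_rep(r) + g(θ) · V_att(r),   g(θ) = cos(πθ / 2θ_c)^(2n) inside
the binding cone, 0 outside,

so two parameters control the chemistry: the well depth ε (binding
strength, mainly the dissociation rate k_off) and the geometric factor n
(angular specificity, mainly the association rate k_on). Because both rate
constants of L + R ⇌ C can be *measured* from ensembles of simulations —
k_off from the exponential decay of pre-formed complexes, k_on from the
short-time linear growth of complexes or from the equilibrium balance —
the model can be calibrated to a target ligand-receptor pair and then used
for questions where geometry matters: diffusion-limited kinetics, receptor
crowding, and bivalent (chimeric) ligands whose activity and targeting
subunits are joined by a worm-like-chain linker.

Everything is in reduced units: lengths in the receptor diameter σ_R,
energies in ε₀ (= k_BT at the default temperature), times in
τ = σ_R √(m/ε₀).

## A worked example

Measure the dissociation rate at ε = 5 k_BT, n = 2 from an ensemble of
100 pre-formed complexes, four replicates:

```r
library(cgligand)

spec <- experiment_spec("dissociation", n_receptors = 100,
                        surface_density = 0.01, box_height = 20,
                        epsilon = 5, n_geom = 2,
                        n_replicates = 4, seed = 120,
                        n_steps = 2e4, sample_interval = 100)
out <- simulate_dissociation(spec)
out$koff
#> <cg_rate> exp_decay: 0.07283 +/- 0.015 (R^2 = 0.9404, n = 94, window [0, 18.6])
generics::tidy(out$koff)
#> # A tibble: 1 x 3
#>   term  estimate std.error
#>   <chr>    <dbl>     <dbl>
#> 1 rate    0.0728    0.0150
autoplot(out$series)   # ensemble-averaged decay curve
```

The bound ensemble is thermalized for 5 τ before measurement (complexes
are built at the exact potential minimum), then the surviving-complex
count decays exponentially: the fitted rate says a thermalized complex at
this interaction strength survives 1/k_off ≈ 14 τ on average. The
standard error is the leave-one-replicate-out jackknife over the four
replicates; R² rises towards 0.99 as the replicate count grows (the
acceptance suite uses 32).

The chimera selectivity screen sweeps the abundance of targeting-element
receptors (TER) and reports the relative gain in equilibrium activity
complexes over the TER-free baseline:

```r
base <- experiment_spec("chimera", n_aer = 24, ligand_conc = 0.012,
                        surface_density = 0.04, box_height = 10,
                        eps_te = 10, linker = linker_spec(32, 0.5, 1),
                        n_replicates = 12, seed = 1,
                        n_steps = 2e5, sample_interval = 2500)
sweep <- ter_sweep(base, ter_counts = c(0, 24, 48, 96), ae_affinity = "low")
autoplot(sweep)        # increment (%) vs TER abundance
```

A command-line wrapper (`inst/scripts/cgligand`) exposes the same
experiments as subcommands (`dissociation`, `association`, `chimera`,
`sweep`, `fixtures`, `analyze`) driven by a YAML config with an explicit
reduced-units declaration; every run writes its series, estimates and a
JSON manifest with checksums.

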