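---
title: "A tunable coarse-grained model of ligand-receptor binding kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A tunable coarse-grained model of ligand-receptor binding kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cgligand)
```

## The model

`cgligand` simulates ligand-receptor binding at a deliberately coarse level:
ligands are spheres of diameter $\sigma_L$ diffusing in three dimensions
above a flat membrane (the $z = 0$ plane), receptors are spheres of diameter
$\sigma_R$ confined to that plane. Two ingredients define the chemistry:

1. **Excluded volume.** Particles of the same type repel through a WCA
   potential (Lennard-Jones truncated at its minimum $2^{1/6}\sigma$ and
   shifted up by $\epsilon$), and non-complementary cross pairs through the
   same form at the mixed diameter $\sigma_{ij} = (\sigma_i + \sigma_j)/2$.

2. **Directional binding.** A complementary ligand-receptor pair interacts
   through an anisotropic (patchy) Lennard-Jones potential
   $$V(r, \theta) = V_{rep}(r) + g(\theta)\, V_{att}(r),$$
   where $r$ is the pair distance, $\theta$ the angle between the
   receptor-to-ligand separation and the receptor's binding axis (the
   membrane normal), $V_{rep} = 4\epsilon[(\sigma/r)^{12} -
   (\sigma/r_c)^{12}]$ and $V_{att} = -4\epsilon[(\sigma/r)^{6} -
   (\sigma/r_c)^{6}]$. The split is shifted so that $V(r_c, \theta) = 0$
   for every angle. The angular weight
   $$g(\theta) = \cos\!\left(\frac{\pi\theta}{2\theta_c}\right)^{2n},
   \qquad \theta < \theta_c,$$
   and $g = 0$ outside the binding cone, makes the interaction purely
   repulsive outside the patch. $g$ and its derivative are continuous at the
   cone edge for $n \ge 1$; $g(0) = 1$; increasing the geometric factor $n$
   narrows the attractive patch. The pair $(\epsilon, n)$ is the model's
   tunable chemistry: $\epsilon$ sets the well depth (and, through a
   Boltzmann-like factor, the dissociation rate), $n$ the angular
   specificity (mainly the association rate). The exact algebraic form of
   the angular weight is a design choice of this package: any smooth,
   monotone bump with these boundary properties produces the same
   qualitative physics, and the cosine-power form is the simplest that is
   $C^1$ at the cone edge.

All quantities are reduced: energies in $\epsilon_0$, lengths in $\sigma_R$,
times in $\tau = \sigma_R\sqrt{m_L/\epsilon_0}$, with $k_BT = 1\,\epsilon_0$.

### Dynamics

Particles follow Langevin dynamics integrated with velocity-Verlet using the
BAOAB splitting, which gives accurate configurational averages at large
friction. Friction per species is $\gamma = k_BT/(m D)$, so the input is the
physically meaningful diffusion coefficient. Defaults: $D_L = 0.1\,
\sigma^2/\tau$, $D_R = 0.01\,\sigma^2/\tau$ (receptor diffusion is two
orders slower in the membrane; monovalent protocols freeze receptors
entirely, $D_R = 0$). The default timestep is $dt = 0.002\,\tau$; the
thermostat holds the kinetic temperature within 2% at this step. The box is
periodic in $x, y$. In $z$ the membrane plane and the box ceiling are
reflective walls: a periodic $z$ boundary would let ligands tunnel from the
bulk to the membrane's far side, which has no physical counterpart here, so
reflection is the consistent reading. Membrane receptors are constrained to
$z = 0$ exactly and receive in-plane noise only.

Forces are evaluated with a linked-cell neighbour search (half stencil,
minimum image in $x, y$); an all-pairs reference path is kept and the two
agree to machine precision, which the test suite asserts.

### Chimeric ligands

A chimeric ligand is a bivalent construct: an activity element (AE) that
binds its receptor AER, and a targeting element (TE) binding TER, joined by
a flexible polypeptide linker. The linker is not resolved; it acts as an
effective worm-like-chain tension between the subunits,
$$F(r) = \frac{k_BT}{l_p}\left[\frac{1}{4(1 - r/L_0)^2} - \frac14 +
\frac{r}{L_0}\right],$$
with contour length $L_0 = N b$ ($N$ monomers of size $b$) and persistence
length $l_p$. The divergence at $r \to L_0$ is an artifact of the continuum
law at finite timestep, so the tension is capped at its value at
$0.99\,L_0$; capped configurations are logged as over-stretch events and
never occurred in the accepted runs reported by the test suite.

Two conventions exist for the linker's "length". The free Kratky-Porod
chain has $\langle r^2\rangle = 2 l_p L_0 [1 - (l_p/L_0)(1 -
e^{-L_0/l_p})]$. A dimer tethered by the force law above, however, samples
the Boltzmann distribution $P(r) \propto r^2 e^{-U(r)/k_BT}$ of that very
potential, whose mean is 20-30% below $\sqrt{\langle r^2\rangle}$ for
flexible linkers. Since the simulation realizes the force law, not the
discrete chain, `wlc_mean_extension()` defaults to the self-consistent
Boltzmann mean (computed by quadrature) and offers the Kratky-Porod
interpolation as an option. The simulated mean extension of a free dimer
matches the quadrature within sampling error; the acceptance suite checks
3%.

Non-complementary pairs (AE-TER, TE-AER, AE-TE between different chimeras)
are purely steric. Bonded AE-TE partners interact only through the linker
tension: the excluded-volume term is omitted within a chimera so that the
linker statistics follow the WLC law exactly.

## Measurement protocols

**Binding criterion.** The model has no discrete bond variable, so a
complex is defined energetically: a pair is bound when $V < -\epsilon/2$.
Each ligand matches at most one receptor (lowest energy wins, ties broken
by index). The $-\epsilon/2$ threshold is hysteresis-free and validated by
the Markov-recovery property test: dissociation survival curves generated
by the simulator are statistically indistinguishable from a two-state
Markov process with the fitted rate.

**Dissociation.** All receptors start bound (one ligand at each on-axis
potential minimum), no free ligands, a tall box ($l_z = 20$) and low
surface density ($\rho_s = 0.01\,\sigma^{-2}$) suppress rebinding. Because
the build places every ligand at the exact minimum, the protocol first
thermalizes the bound ensemble (default $5\,\tau$, discarded, time
re-zeroed): an instantaneous energy criterion applied to an unthermalized
ensemble mixes the intra-well relaxation into the decay and masquerades as
a fast initial "dissociation" phase. After thermalization the
ensemble-averaged complex count decays exponentially,
$C(t) = C_0 e^{-k_{off} t}$, and $k_{off}$ is fitted by nonlinear least
squares with $C_0$ fixed to the first thermalized count; points below a
shot-noise floor of 5 complexes are excluded, and the reported standard
error is the leave-one-replicate-out jackknife (the fit covariance alone
understates ensemble-to-ensemble spread). With the energetic binding
criterion the measured $k_{off}(\epsilon)$ follows an Arrhenius-like law
with effective barrier close to $\epsilon/2$ — the threshold sits at half
depth, and angular escape paths contribute — so usable decay statistics at
a few hundred $\tau$ require $\epsilon \lesssim 8\,k_BT$ in this package's
defaults. For anisotropic patches the escape rate of a freshly thermalized
ensemble still relaxes over the angular mixing time of the well (a few
$\tau$ at the default geometry) before settling on the quasi-stationary
single-exponential; the fit window is long enough that this transient
contributes negligibly to the rate estimate.

**Association.** All receptors start unbound; ligands are seeded uniformly
beyond the interaction cutoff. At short times, before dissociation and
depletion matter, $C(t) \approx k_{on} [L]_0 R_{tot}\, t$: the estimator
fits through the origin over the window where counts stay below 20%
receptor occupancy. Within any finite window the true curve already bends
toward its plateau, so a pure straight line underestimates the initial
slope by up to tens of percent; the estimator therefore includes a
quadratic curvature term and reports the linear coefficient, which is
unbiased to second order. At steady state the mass-action balance gives
the independent estimate
$k_{on} = k_{off} C_{eq} / ([L](R_{tot} - C_{eq}))$, accepted only after a
plateau test on the final quartile. The two estimators agree within joint
error on the same ensembles (asserted by the acceptance suite).

**Diffusion dependence.** Both rates are measured across a grid of ligand
diffusion coefficients; in the diffusion-limited regime they grow linearly
with $D$, the signature that transport, not intrinsic chemistry, sets the
measured rates. `transport_decomposition()` inverts
$1/k_{meas} = 1/k_{int} + 1/k_T$ when an estimate of the transport rate
$k_T \propto D$ is available.

## The chimera selectivity study

The selectivity screen (`ter_sweep()`) measures the equilibrium AE-AER
occupancy as a function of the TER abundance at fixed membrane area, and
reports the relative increment over the zero-TER baseline. The mechanism is
reduction of dimensionality: a chimera anchored by its TE searches for AER
in a thin shell near the membrane, raising the effective association rate
and — through fast rebinding of a tethered AE — lowering the effective
dissociation rate. Both effects matter more when the intrinsic AE affinity
is weak, which is why selectivity is maximal for low-affinity activity
elements.

The study conditions are scaled down from a workstation-scale study to a
size a test suite can afford, preserving the regimes rather than any
particular absolute numbers (the regime logic, not specific parameter
values, is what transfers):

* Interaction strengths $\epsilon_{AE} = 12\,k_BT$ (high) and $6\,k_BT$
  (low), $\epsilon_{TE} = 10\,k_BT$, geometric factors $n = 2$. With the
  measured $k_{off}(\epsilon) \approx 2.4\,e^{-\epsilon/2}/\tau$ these give
  $k_{off}\,t_{run} \ll 1$ in the high-affinity regime (binding effectively
  irreversible on the run timescale, occupancy kinetically limited, with
  $k_{on}[c]\,t_{run} \approx 1$ so the baseline retains headroom) and
  $k_{off} \sim k_{on}[c]$ in the low-affinity regime (occupancy
  equilibrium-limited) — the two regimes the selectivity contrast requires.
* 24 activity receptors at surface density $0.04\,\sigma^{-2}$ (area fixed
  as TERs are added), box height $10\,\sigma$, chimera concentration
  $0.012\,\sigma^{-3}$, receptor diffusion $D_R = 0.01$, linker $L_0 = 16$
  ($32$ monomers of size $0.5$), $l_p = 1$. The receptor spacing
  ($\approx 5\,\sigma$ at the base density) and the linker's Boltzmann mean
  extension ($\approx 4.5\,\sigma$) are deliberately commensurate: an
  anchored chimera can reach a neighbouring activity receptor without
  waiting for slow receptor diffusion, which is the dimensionality-reduction
  channel the selectivity mechanism relies on. With sparser receptors or a
  much shorter linker the anchored channel is throttled by the
  $D_R$-limited encounter time and the selectivity increments collapse
  toward zero — a genuine prediction of the model, not a numerical
  artifact.
* TER abundance swept over $0$ to $4\times$ the AER count; equilibrium
  occupancy is the mean over the final quartile of each run after a plateau
  check; increments are averaged over independent replicates (12 in the
  acceptance protocol, 6 in the test suite). At these scaled sizes the
  replicate-level spread of the maximum increment is of order 10 (high
  affinity) to 25 (low affinity) percentage points, and that spread, not
  estimator bias, dominates the uncertainty of the headline numbers.

The linker study (`linker_sweep()`) measures the effective AE-AER
association rate versus linker contour length and receptor spacing $d$
(summarized as the uniform-disk mean $d = \tfrac23\sqrt{A/(N_{TER}\pi)}$).
The sweep uses a wide fit window (up to 50% occupancy) and the
window-average slope, because the anchored channel develops on the
receptor-diffusion timescale and a fit confined to the earliest times
would see only the bulk channel. The optimum linker for clustered
receptors is longer than the minimal length that lets both subunits bind
simultaneously: very short linkers pay a stiffness penalty — the capped
WLC tension is already steep at small fractional extensions of a short
chain — while very long linkers dilute the dimensionality-reduction
effect. A caveat this package's own experiments expose: at test-scale
sizes the *initial formation rate* is dominated by chimeras binding
directly from solution, a channel indifferent to receptor spacing, so the
spacing dependence of the effective rate is weak relative to replicate
noise; the anchored channel's clearest signature is in equilibrium
occupancy (through tethered rebinding), which is what the selectivity
screen measures.

## Numerical choices and degenerate inputs

* $r_{cut} = 2.5\,\sigma_{LR}$ for the binding potential, the conventional
  Lennard-Jones cutoff; WCA interactions cut at their minimum by
  construction. Cutoffs must not exceed half the smallest periodic box
  edge (enforced).
* The isotropic convention $n = 0$, $\theta_c = \pi/2$ means $g \equiv 1$
  everywhere; an anisotropic patch requires $n \ge 1$ so the angular weight
  stays $C^1$ at the cone edge.
* Initial configurations use rejection sampling with a minimum receptor
  separation of $\sigma_R$ and a bulk clearance of the interaction cutoff;
  placement failure after $10^4$ tries per particle is a hard error, as are
  overlaps below $10^{-6}\sigma$ and non-finite coordinates during a run.
* Bound detection at sampling times only; the series sampling interval
  therefore bounds the time resolution of the rate fits.
* Replicates are seeded `seed + k - 1` and ensemble-averaged before
  fitting; replicate-level spread provides the uncertainty of equilibrium
  occupancies.

## What the synthetic generators emulate — and what they do not

The synthetic fixtures (`make_decay_series()`, `make_saturating_series()`,
two-state Markov ensembles, scripted trajectories) reproduce the
*statistical structure* the estimators must invert: exponential survival,
shot noise, short-time linearity, saturation. They contain no spatial
physics, so estimator tests passing on them demonstrates correct inference,
not correct dynamics — the MD-level acceptance checks (decay shape,
box-height invariance, estimator consistency, diffusion linearity,
equipartition, Einstein relations) close that gap. None of this validates
the model against any particular experimental ligand-receptor pair:
mapping $(\epsilon, n)$ to a real system requires calibrating both rates
against measured values, which is the intended use of the
$(\epsilon, n) \to (k_{on}, k_{off})$ characterization.

## Known limitations

* Receptors carry a fixed binding axis (the membrane normal) and no
  rotational dynamics; binding-pocket asymmetry and ligand orientation are
  outside the model's resolution.
* The angular functions and the linker-length convention are surrogates
  with the documented properties; numerical equality with any other
  implementation of the same ideas is not expected.
* The dissociation rate's dependence on $\epsilon$ is set in part by the
  $-\epsilon/2$ binding threshold; comparisons across binding criteria
  require re-calibration.
* Problem sizes in the test and acceptance suites (tens of receptors,
  hundreds of particles, runs of a few hundred $\tau$) are chosen for a
  single-CPU test environment; the estimators' statistical errors at those
  sizes are reported alongside every rate.
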