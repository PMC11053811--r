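---
title: "Models and methods: depolymerization-driven demicellization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: depolymerization-driven demicellization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`demicellr` simulates the self-assembly, triggered depolymerization and
cargo release of amphiphilic copolymer micelles with a coarse-grained
bead-spring model, and analyses the resulting trajectories. This vignette
is the package's account of the model, its parameters, and the numerical
and design choices behind the implementation.

## The model

All molecules are chains of Lennard-Jones beads with unit mass and diameter
(reduced units: lengths in sigma, energies in epsilon, time in
tau = sqrt(m sigma^2 / epsilon)). A copolymer carries 30 hydrophilic A
beads and 30 hydrophobic beads; the hydrophobic content is arranged as one
block (`A30B30`), or as two or three branches joined at the last A bead
(`A30(B15)2`, `A30(B10)3` miktoarm stars). The terminal bead of each
hydrophobic block or branch is an *end-cap* (EC), chemically labile but
interacting exactly as a B bead. Cargo molecules are hydrophobic trimers
(`C3`); trigger molecules are single hydrophobic T beads. Solvent is
implicit.

Nonbonded interactions use a truncated and shifted Lennard-Jones potential,

$$U_{LJ}(r) = 4\varepsilon_{ij}\left[ \left(\tfrac{\sigma}{r}\right)^{12}
 - \left(\tfrac{\sigma}{r}\right)^{6}
 - \left(\tfrac{\sigma}{r_c}\right)^{12}
 + \left(\tfrac{\sigma}{r_c}\right)^{6}\right], \quad r \le r_c,$$

zero beyond the cutoff. Pairs involving a hydrophilic A bead (or the inert
X species) are purely repulsive: $r_c = 2^{1/6}\sigma$, the
Weeks-Chandler-Andersen form. Hydrophobic pairs (B-B, B-C, C-C and the
trigger pairs T-T, B-T, T-C) are attractive with $r_c = 2.5\sigma$.
Attraction strengths are specified through an effective pair temperature
$T^*_{ij}$: the thermostat runs at $k_BT = 1.8\,\varepsilon$, so
$\varepsilon_{ij} = 1.8/T^*_{ij}$ and a *lower* $T^*$ is a *deeper* well.
B-B is fixed at $T^* = 1.8$ ($\varepsilon_{BB} = 1$); the cargo couplings
B-C and C-C default to $T^* = 1.4$, the strong-encapsulation condition.
The mapping direction matters: with the inverse convention
(`eps_mapping = "direct"`, also exposed) lowering $T^*$ would weaken the
attraction and the encapsulation trends reverse; we adopt the reading
under which "lower $T^*$" means "more attractive", consistent with
$T^* = k_BT/\varepsilon$ at fixed thermostat temperature.

Bonds are FENE springs, $U = -\tfrac12 k R_0^2 \ln(1 - (r/R_0)^2)$ with
$k = 25\,\varepsilon/\sigma^2$ and $R_0 = 1.5\sigma$, composed with the LJ
pair term on bonded pairs (the Kremer-Grest convention; a flag disables
it). A bond at or beyond $R_0$ is unphysical and aborts the run.

## Dynamics and protocol

The integrator is BAOAB-split Langevin dynamics: velocity-Verlet drift and
kick halves around an exact Ornstein-Uhlenbeck velocity refresh. With
friction `gamma = 0` it reduces to plain velocity Verlet, which is how the
energy-conservation checks run. Defaults: `dt = 0.006` tau,
`tstar = 1.8`, `gamma = 1` per tau. The friction is not a physical
observable of the model, so kinetic time axes are meaningful only up to a
time-scale factor; all cross-architecture comparisons are made under
identical settings and reported as dimensionless fractions or orderings.

Initial states place molecules as random walks (bond length 0.97 sigma) at
a total bead density `phi = 0.12`, with a minimum non-bonded insertion
distance of 0.8 sigma enforced under the minimum image convention. The
standard protocol then runs three stages: a *push-off* with every cutoff
truncated to $2^{1/6}\sigma$ (purely repulsive) that erases the bias of
the random start, an equilibration, and a production stage that emits
snapshots. During push-off the per-step displacement is capped at 0.05
sigma (the `nve/limit` idea): random-walk starts contain minimum-image
overlaps whose raw forces would otherwise overflow the FENE bonds in the
first few steps. Pair forces use a cell list plus Verlet neighbor list
(skin 0.4 sigma) rebuilt on a displacement trigger; forces match an
all-pairs reference to 1e-10 in the test suite.

## Reactions: triggered head-to-tail depolymerization

Depolymerization proceeds in reaction sweeps interleaved with integration
every `attempt_every` steps. Two channels:

1. **End-cap scission.** An intact end-cap bond is eligible when at least
   one active trigger bead lies within `r_cutoff = 1` sigma of the end-cap
   (minimum image). It breaks with probability `rp_t` — one Bernoulli draw
   per bond per sweep regardless of how many triggers are in range. On
   success the end-cap detaches and, by default, the nearest participating
   trigger is consumed (retyped to inert X), so each trigger acts once and
   stoichiometric dosing is meaningful.
2. **Propagation.** Once a branch has lost its end-cap, its exposed
   terminal hydrophobic bond breaks with probability `rp_b` per sweep, one
   bond per branch per sweep, strictly head-to-tail, no stimulus needed.
   The final scission of a branch is the junction bond to the A block.

Detached beads keep their hydrophobic identity by default
(`detached_bead_fate = "keep_type"`); an `"inert"` option retypes them.
The ledger counts end-cap beads removed and hydrophobic beads detached;
because every scission detaches exactly one hydrophobic bead, the
bond-based and bead-based depolymerization fractions coincide, both
reaching 1 at complete depolymerization.

## Analysis stack

**Micelles.** Two chains share a micelle when any two nonbonded
hydrophobic beads, one from each chain, are within 1.5 sigma (the
Stillinger criterion); micelles are connected components of this
chain-contact graph, with neighbor searches done on bead contacts under
periodic boundaries — equivalent to density clustering with a 1.5 sigma
neighborhood and two-point minimum, projected to chains. Chains whose
hydrophobic beads have all detached cannot participate and count as free;
detached single beads are never chains. Micelles split by the periodic
boundary are consolidated by walking the intra-micelle contact+bond graph
and translating each bead by its minimum-image displacement from an
already-placed neighbor; the result is anchor-independent up to a rigid
translation, and a warning is raised if a cluster spans more than half the
box (unwrap ambiguous).

**Observables.** The mass distribution P(N) is the fraction of micellized
chains in micelles of aggregation number N (free chains excluded); the
preferential aggregation number N_p is its mode, ties resolved toward the
smaller N. Size and shape come from the gyration tensor of unwrapped
coordinates (copolymer beads only, by default, to keep the molecular
weight comparable between micelles of equal N): Rg^2 is its trace and the
relative shape anisotropy kappa^2 ranges from 0 (sphere-like) to 1 (rod).
A cargo molecule is encapsulated when any of its beads is within 1.5 sigma
of a micellized chain's hydrophobic bead; loading capacity is the w/w
percentage of cargo beads in the loaded carrier. Multi-snapshot averages
use ten-block averaging.

**Kinetics.** The tracer autocorrelation
$C(t) = (\langle N(t_0{+}t)N(t_0)\rangle - \langle N\rangle^2) /
(\langle N^2\rangle - \langle N\rangle^2)$ over all chains and origins
defines the relaxation time at the 1/e crossing (linearly interpolated).
Cargo mobility is quantified by the origin-averaged MSD of unwrapped
coordinates with the exponent alpha fitted on log-log axes over the last
temporal decade (the asymptotic window; the model does not fix a window,
so this is a package choice). Release is the fraction of initially
encapsulated cargo currently free — re-encapsulation lowers it, matching
the observed noise in release curves. The Korsmeyer-Peppas law
$M_t/M_\infty = k t^n$ is fitted by nonlinear least squares (a log-log
linear fit provides the starting values) to the points with release at
most 0.60; exponents 0.45 < n < 1 are labeled non-Fickian.

## Scaled study conditions

The reference experiment (1000 chains, 2000-4000 cargo, hundreds of
millions of steps) is far beyond a single-CPU R session, so the package's
tests and the acceptance script run the same pipeline at desk scale:

* equilibrium micelle statistics: 24 chains, 2 cargo per chain,
  2k push-off / 30k equilibration / 10k production steps; encapsulation
  contrasts average three independent replicates per condition;
* depolymerization kinetics: 16 chains, reaction stages of 50k-100k steps
  with sweeps every 25 steps, `rp_t = 0.5`, `rp_b = 0.2`, triggers dosed
  stoichiometrically (one per end-cap) or at a constant 4 per chain.

Desk runs have roughly 2.4e3 reaction sweeps against the reference's
~3e6, so the per-sweep probabilities are scaled up to observe comparable
depolymerization progress. The kinetic regime in which the end-cap step is
rate-limiting (reference probabilities RP_T = 1e-4 < RP_B = 1e-3) is
nevertheless preserved: the geometric eligibility requirement — a trigger
within 1 sigma of a buried end-cap — suppresses the *effective* end-cap
rate by roughly three orders of magnitude relative to propagation, which
needs no trigger.

What the scaled runs do and do not show: micellization, the encapsulation
response to the B-C/C-C attraction, trigger-count-driven depolymerization
orderings and release curves all emerge at 16-24 chains. But aggregation
numbers at this size are far from the thermodynamic limit — consistent
micelle statistics require on the order of a thousand chains, and in a
24-chain box the cargo-free system simply coalesces into one cluster, so
the preferential aggregation number saturates at the chain supply and the
loaded-vs-unloaded N_p comparison cannot be expressed. Mass distributions
are modes of a handful of micelles, and single-seed orderings of closely
spaced curves can flip. Passing scaled tests demonstrates that the
machinery reproduces the mechanisms, not that a 24-chain box
quantitatively reproduces 1000-chain observables.

## Numerical choices and limitations

* Tie-breaks: nearest in-range trigger is consumed; N_p ties go to the
  smaller N; the first frame of production anchors time series.
* Degenerate inputs are first-class: constant tracer series (undefined
  autocorrelation), static beads (undefined MSD exponent), never-relaxing
  C(t), and empty micelle sets all return flagged results or errors rather
  than silent numbers.
* The engine targets mixtures of the five species at liquid-like densities
  in cubic periodic boxes; there is no pressure coupling, electrostatics,
  or parallel decomposition.
* Absolute times depend on the Langevin friction, which the model leaves
  free; only dimensionless fractions and orderings are comparable across
  settings.

## Reproducibility

Every stochastic stage takes an explicit integer seed; experiment-level
seeds are split into named substreams (placement, thermostat stages,
trigger insertion, reactions) so that toggling one stage does not perturb
the others. Identical seed and package version give bit-identical
trajectories, ledgers and output files, which the test suite asserts.
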