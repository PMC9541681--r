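---
title: "Suppression gene drives in bounded 1D space: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Suppression gene drives in bounded 1D space: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drivewave)
```

## The problem

Sex-distorter suppression gene drives aim to eradicate a pest population by
forcing the sex ratio toward males. In a well-mixed population an ideal drive
of this kind always wins: its allele frequency recursion has no interior fixed
point, so it rises to fixation and the female fraction falls to zero. Real
populations, however, live in space and in finite numbers. Local suppression
creates density gradients; dispersal across those gradients creates founder
events; founder events put small wild-type (WT) colonies behind the advancing
drive wave, where the drive may never catch them again. `drivewave` simulates
exactly this situation — an individual-based stochastic model on a bounded
one-dimensional landscape — together with the deterministic theory that says
what *should* happen without space and chance, so that the gap between the two
can be measured.

Two drive systems are modelled, both with the drive on the male-determining
path:

* **X-shredder (driving Y)** — XY sex determination; carrier males (`XYd`)
  destroy X-bearing gametes with efficiency $c$, so they sire (mostly) carrier
  sons.
* **W-shredder (Z-linked)** — ZW sex determination; carrier females (`ZdW`)
  destroy W-bearing gametes, so they produce (mostly) sons, half of which
  carry the drive.

Resistance evolution and drive fitness costs are out of scope: the package
models the *ideal* drive, which is the interesting case precisely because it
still fails in space.

## Local dynamics

Each individual spreads one unit of "influence" over space as a standard
normal kernel (bandwidth fixed at 1 spatial unit; this sets the scale of local
dynamics). The density an individual experiences is the kernel sum over the
population, Eq. (1)-style:

$$N_i = \sum_j \tfrac{1}{\sqrt{2\pi}} e^{-d_{ij}^2/2}.$$

Two conventions coexist in the package, deliberately:

* **Competition density** (used in reproduction) *excludes* the focal
  individual's own kernel term — an individual competes with neighbours, not
  with itself. This choice makes the realized equilibrium density equal
  $N^*$, hence the equilibrium population $N^* \times$ landscape length
  (12,500 at defaults), which is the model's design point. Including the self
  term would shift the realized equilibrium down by $1/\sqrt{2\pi}$ per unit
  (about 8% at $N^* = 5$).
* **Density field** (used for wave heights and mate choice weights)
  *includes* every individual listed: it is the field evaluated at a point, so
  an isolated individual has height $1/\sqrt{2\pi}$, not zero.

Kernel terms beyond 6 units (< 1e-8 each) are dropped; the pairwise sums are
the computational bottleneck and are written in C++ with a sorted two-pointer
scan.

Mated females produce a Poisson number of offspring with Beverton–Holt mean
$R/(1 + aN_i)$, where $a = (R-2)/(2N^*)$ so that a female at equilibrium
density expects exactly 2 offspring — replacement, given the ½ sex ratio.
Females choose a single mate within 3 units, with probability proportional to
the kernel density the male provides at her location; a female with no male in
range dies unmated. This is the model's Allee effect and the proximate cause
of drive loss at low density. Offspring are born at the mother's position,
receive one gamete from each parent under the shredder rules, disperse by a
Normal(0, $\sigma^2$) displacement, and replace the adults (non-overlapping
generations). Dispersers leaving $[0, L]$ die (absorbing boundaries).

Shredding is modelled at the gamete stage with renormalization: a fraction
$c$ of the targeted gametes is destroyed and the survivors are rescaled so
carriers' total output — and hence their fecundity — is unchanged, matching
the model's assumption of cost-free drives. The resulting carrier gamete
distribution is $P(\text{drive gamete}) = 1/(2-c)$.

## Deterministic theory

Iterating the expectation of the gamete rules over mating classes in a
well-mixed population gives the one-generation recursions

$$q_{t+1}^{X} = \frac{2q}{2 - c + cq}, \qquad
  q_{t+1}^{W} = \frac{8q - 3cq - cq^2}{8 - 4c},$$

with female fraction $\phi = (2 - c - cq)/(4 - 2c)$ and density recursion
$N_{t+1} = N_t\, \phi\, R/(1 + aN_t)$. The package's
`panmictic_next_frequency()` re-derives both recursions mechanistically from
`gamete_distribution()` — an exact expectation over mating classes, not a
simulation — and the test suite checks agreement to $10^{-12}$ on a dense
$(q, c)$ grid.

One subtlety surfaced in that derivation. For the ZW system the recursion's
state variable is the *individual-weighted* drive frequency (the mean over
individuals of the within-individual Zd fraction; females have one Z slot,
males two), not the chromosome-count frequency. The two differ because the
sex ratio is skewed: at $q = 0.5$, $c = 1$ the individual-weighted recursion
gives 0.5625 while chromosome counting gives 0.5714. `drive_allele_frequency()`
exposes both weightings; simulation records carry both columns; all
comparisons against the recursions use the individual weighting. For the XY
system the weightings coincide (one Y slot per male).

Identifying $dq/dt$ with $\Delta q$ gives the logistic form
$dq/dt = m\,q(1-q)$ with intrinsic drive fitness

$$m_W = \frac{c}{8 - 4c}, \qquad m_X = \frac{c}{2 - c + cq},$$

and the Fisher–KPP speed bounds $v = 2\sqrt{Dm}$ for the drive (advection —
the asymmetric gene flow caused by suppression — is ignored, so this is an
upper bound) and $v = 2\sqrt{Dr}$ for WTs, with $r = R/2 - 1$ the low-density
growth rate under an unskewed sex ratio. Setting $r = m$ and solving for $R$
(`critical_fecundity()`, a root solve, not a constant) gives the fecundities
above which the WT wave outruns the ideal drive: 2.5 for the W-shredder and
4.0 for the X-shredder. For theory-vs-simulation overlays the diffusion
coefficient is mapped as $D = \sigma^2/2$, the standard correspondence for a
Gaussian dispersal kernel applied once per generation.

## Events, waves and outcomes

A standard scenario initializes $5 \times (1250-250) = 5000$ WTs uniformly on
$[250, 1250]$ of a 2500-unit landscape and releases 1% of that count as
heterozygous carriers at $x = 250$ (actively shredding genotypes: `XYd` males
or `ZdW` females, so the two systems are comparable from the first
generation). Runs stop at eradication, at 1000 generations, or 10 generations
after the drive allele is lost.

Per generation the simulator records population size, female fraction, mean
and SD of local density, both drive-frequency weightings, offspring means
(overall and split by WT-only vs drive-carrying parent pairs), and the class
extremes that the event detectors need:

* **Penetration** — a WT at least $\sigma$ units left of the drive's trailing
  edge (the lowest-positioned carrier). Only the first event is scored; after
  the landscape fragments the single-wave assumption fails.
* **Chasing** — reinvasion after penetration. Operationally: at some later
  generation a carrier sits at or left of the rightmost WT that was behind
  the *previous* generation's trailing edge. The raw per-generation extremes
  are kept in the record so alternative reifications can be re-scored without
  re-simulation.
* **Outcome** — SUCCESS iff the WT count reaches zero by the horizon;
  otherwise FAILURE with mode DRIFT_LOSS (drive lost, never penetrated),
  WT_ESCAPE (drive lost after penetration) or COEXISTENCE (both classes
  extant at the horizon).

Wave properties are measured inside the window that starts at generation 1
and ends at the first penetration or at boundary contact (leading individual
within $\sigma$ of the edge): velocities as the mean per-generation advance of
the leading individual, heights as the maximum class-specific density, and
widths per the leading/trailing definitions, averaged across the window
generations (the generation-1 snapshot is stored separately).

Two measurement choices deserve comment, because naive versions fail:

* *The WT leading-edge peak.* The WT wave is flat-topped, and individual
  kernel densities fluctuate strongly (offspring are born at their mother's
  position, so sibling clumps create spikes ~50% above the plateau). A plain
  density argmax therefore lands anywhere on the plateau, and a
  high-quantile threshold locks onto clumps. The package instead anchors the
  front at the rightmost individual whose class density still attains the
  *median* class density — a plateau-dominated, clump-insensitive level. On a
  noise-free synthetic sigmoid front this returns the shoulder to within a
  couple of spatial units (this validation is itself a unit test).
* *The drive peak.* The drive wave is pulse-shaped, so its peak is the plain
  argmax; exact ties (isolated carriers, all at the self-term density)
  resolve to the rightmost tied individual, the leading-edge side.

## Experiments

`grid_spec()`/`run_scenario_grid()` reproduce the published design — 10
equidistant fecundities on $[2, 10]$ × 10 equidistant dispersal scales on
$[2, 20]$, both endpoints included, per system — with deterministic
per-replicate seeds (`seed_base + (scenario-1) * replicates + replicate - 1`)
so any cell can be recomputed in isolation. `fit_width_scaling()` is the
log–log OLS $\ln(\text{width}) = a + s \ln\sigma$; rows whose widths are
undefined (drive lost before the window opened, penetration at generation ≤ 1)
are dropped and counted. `fit_event_model()` fits univariate logistic models
of penetration/escape against one wave characteristic at a time and reports
the rank-statistic AUC (ties ½), which the tests verify against exhaustive
pair counting.

## Problem sizes used by the shipped checks

The full published design (20,000 runs × up to 1000 generations) is a
cluster-scale computation. The package's own checks use these scales, chosen
as standard reduced designs:

* **Width scaling**: 10 σ values × 30 replicates per system, fecundity
  cycling over the 10-point grid, runs capped at 50 generations. At this
  scale the X-shredder experiment gives a WT exponent near 0.95 and drive
  trailing exponents above 1 with the X-shredder's the largest — the
  published ordering. Exponent estimates wander by roughly ±0.1 between
  seed sets at this replication.
* **Equilibrium recovery**: one WT-only run over the full 2500-unit domain,
  160–200 generations, averaging from generation 50. The long-run mean sits
  2–4% above $N^* \times 2500$; the small upward bias is a Jensen effect
  (the Beverton–Holt mean is convex in density, and local density
  fluctuates), and its sign confirms the competition-density convention.
* **Outcome structure**: a 48-run stratified sub-grid capped at 350
  generations. The cap relabels slow, still-chasing runs as COEXISTENCE
  earlier than the full horizon would, inflating the failure fraction and
  obscuring the X-vs-W failure ordering, so only the pooled structure is
  asserted: failure common, chasing in most failures, drive loss nearly
  always a post-penetration WT escape, failure probability decreasing in σ.
  The full outcome frequencies need the full grid (`grid_spec()` defaults),
  which is a long offline job.
* **Near-panmixia**: a 400-unit landscape at σ = 20 with carriers scattered
  through the WT block approximates a well-mixed population while keeping
  boundary losses tolerable. Deterministic trajectories run inside the
  stochastic envelope for most of the rise and reach high drive frequency
  weakly faster than the stochastic median — the expected direction, since
  the theory ignores advection and drift.

## What the synthetic scenarios do and do not show

Everything the simulator produces is synthetic: the generator *is* the study
system. Passing checks show that the implementation reproduces the model's
internal logic (recursions, equilibria, wave scalings, event taxonomy) — they
say nothing about any real species. The model's realism limits are the usual
ones: one spatial dimension (founder events are easier to detect but
geometrically special), a rigid mating radius that does not scale with σ,
cost-free drives without resistance evolution, and absorbing boundaries that
make cornering possible at all. Numerical choices that matter: kernel
truncation at 6 units (error < 1e-8 per pair), nearest-integer rounding of
initialization counts (exactly 5000 + 50 at defaults), a single RNG stream
per run seeded from the scenario seed, and undefined statistics (empty
classes, zero denominators) signalled as `NA`, never as 0.
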