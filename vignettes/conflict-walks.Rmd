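---
title: "Adaptive walks under two-party conflict: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive walks under two-party conflict: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgmconflict)
```

## The model

`fgmconflict` simulates the evolution of a single quantitative trait $z$ by
successive fixation of new mutations, in the tradition of Fisher's geometric
model, and extends it to *joint phenotypes*: traits whose value is the shared
outcome of two antagonistic parties, such as the probability that a pathogen
infects a host, that a predator catches a prey, or the amount of provisioning
a chick extracts from a host parent. Each party $i \in \{1, 2\}$ has Gaussian
fitness

$$w_i = e^{-\omega_i (o_i - z)^2},$$

maximal ($w_i = 1$) at its own optimum $o_i$ and falling off at a rate set by
the shape parameter $\omega_i$ (phenotype$^{-2}$ units; larger $\omega$ =
narrower curve = stronger selection). When the two optima differ, any $z$
between them leaves both parties short of their maximum, and a change that
helps one party generally hurts the other — the geometry of evolutionary
conflict.

**Conflict intensity.** The two fitness curves intersect at a point we define
as the origin $z = 0$, where both parties have the same fitness $w_0$ and
hence the same *lag load* $1 - w_0$. That shared lag load is the package's
single knob for conflict intensity: given $\omega_i$ and $w_0$ the optima
are placed at

$$o_i = \pm\sqrt{-\ln w_0 / \omega_i},$$

party 1 taking the positive root by convention. Raising the lag load spreads
the optima apart.

**Dynamics.** Populations are monomorphic between fixations
(strong-selection/weak-mutation): each elementary step draws one mutation with
additive effect $m$ on $z$, computes the proposing party's selection
coefficient $s = w_m / w - 1$, and fixes it with Kimura's probability —
$\Pi = 1 - e^{-2s}$ for $s > 0$ (and 0 otherwise) when the population is
effectively infinite, or
$\Pi = (1 - e^{-2s})/(1 - e^{-4Ns})$ for a finite population of size $N$,
where drift can also fix deleterious mutations. A fixation shifts $z$ for
*both* parties; nothing else changes state.

Mutation effects are unbiased (symmetric about zero). Three distributions are
supported, all parameterized by the mean absolute effect
$\bar m = \sigma\sqrt{2/\pi}$ so they are compared at matched average size:
normal $N(0, \sigma^2)$; uniform on $(-2\bar m, 2\bar m)$ (since
$E|U(-b,b)| = b/2$); and exponential magnitudes with mean $\bar m$ carrying a
fair-coin sign. The uniform and exponential parameterizations are this
package's convention for matching mean sizes, chosen because the
distributions are only meaningfully comparable at equal $\bar m$.

## The three regimes

* **standard** — one party, fixed optimum $o_1$, one proposal per iteration.
  The no-conflict control, always parameterized like party 1.
* **conflict** — both parties act on the shared $z$. Each iteration a fair
  coin picks the first mover; party 1 performs its block of $r$ contiguous
  proposal–resolution rounds and party 2 its single round, in coin order.
* **abiotic_matched** — a moving-optimum control for party 1. A paired
  conflict run with identical parameters is executed first; at the start of
  iteration $t$ of the control run, the optimum is displaced by the magnitude
  of party 2's net change to $z$ in iteration $t$ of the paired run (zero
  when party 2 fixed nothing), in a fair-coin direction; party 1 then runs
  its own proposal rounds. Biotic and abiotic environmental change thus have
  identical magnitudes per iteration, differing only in direction: the
  opponent's changes are systematically malevolent, the abiotic ones random.

## Parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `lag_load` | shared lag load $1 - w_0$ at the curve intersection | 0.2 | moderate conflict; optima $\pm 0.668$ at $\omega = 1/2$ |
| `omega` | baseline curve shape $\omega_2$ (phenotype$^{-2}$) | 1/2 | baseline used throughout; results are robust 4-fold up or down since rescaling $\omega$ is equivalent to rescaling mutation sizes |
| `mean_size` | party 2's mean absolute mutation effect $\bar m_2$ | 0.1 | small relative to the inter-optimum distance, the classic small-mutation regime |
| `f` | relative selection strength, $\omega_1 = f\,\omega_2$ | 1 | symmetric baseline |
| `kappa` | relative mutation size, $\bar m_1 = \kappa\,\bar m_2$ | 1 | symmetric baseline |
| `r` | mutational input: party-1 proposals per iteration | 1 | symmetric baseline |
| `pop_size1/2` | population sizes $N_i$ | `Inf` | drift-free baseline |
| `burn_in` | discarded initial-adaptation iterations | $\lceil 250/\min(\omega_1,\omega_2)\rceil$ | the wider (slower-adapting) curve sets the adaptation timescale |
| `n_iterations` | equilibrium window | 5000 | long relative to fluctuation timescales |
| `n_replicates` | replicate walks | 200 | see *Problem sizes* |
| `z_init` | starting trait value | 0 (origin) | configurable; starting at $o_1$ is also meaningful |

**The `f` gauge.** $f$ is defined by the ratio $\omega_1 = f\,\omega_2$,
which leaves open which party's shape the scalar `omega` fixes. This package
holds party 2 at `omega` and strengthens party 1 ($\omega_1 = f\,\omega_2$),
parallel to how `kappa` and `r` also multiply party 1's capabilities. Under
this gauge the power gain from stronger selection shows the expected
saturation already over $f \in \{1, 2, 4\}$; under the alternative gauge
(hold $\omega_1$, weaken party 2) the first increments are equal within
Monte-Carlo error and saturation only appears at larger $f$. Since the
asymmetry parameters are meant to describe *party 1's advantage*, the
party-1-multiplier gauge is the coherent choice.

## Summary statistics

Per replicate and party, over the post-burn-in window: mean distance
$|z - o_i|$ and mean fitness $w_i$, sampled once per iteration at iteration
end so regimes with different round counts are sampled comparably; fixation
fraction (that party's fixed / proposed mutations within the window — the
only denominator that stays comparable across `r`); and the mean absolute
effect among fixed mutations, reported as missing (not zero) when nothing
fixed. The mean lag load is $1 -$ mean fitness over the same samples, so the
identity is exact.

*Fitness power* of party 1 is $P_{w1} = 1 - L_1/(L_1 + L_2)$ with $L_i$ the
mean lag loads: 0.5 means a stalemate, 1 means party 1 holds $z$ at its own
optimum. Power is computed per replicate from that replicate's mean lag
loads, then averaged across replicates (ratio of means within a replicate,
mean of ratios across) — the two orders differ slightly and this one keeps
each replicate's power a well-defined quantity with a standard error.

## Numerical choices

* **Neutral mutations, infinite $N$:** $\Pi$ is defined piecewise for
  $s > 0$ and $s < 0$; exactly $s = 0$ is assigned $\Pi = 0$ (a neutral
  mutation in an infinite population fixes with probability 0). Exact ties
  only arise from degenerate inputs such as a zero-effect mutation.
* **Finite-$N$ formula near $s = 0$:** the ratio is 0/0; for
  $|4Ns| < 10^{-8}$ the limiting value $1/(2N)$ is returned.
* **Deleterious overflow guard:** for $s < 0$ with $4N|s| > 700$,
  $e^{4N|s|}$ overflows; the asymptotic form
  $e^{2|s| - 4N|s|}(1 - e^{-2|s|})$ is used. Below roughly $e^{-745}$ the
  true probability underflows double precision and 0 is returned.
* **Fitness underflow:** $w$ may underflow to 0 at astronomically large
  $|z - o|$; the selection coefficient then raises a clear error rather than
  returning NaN. No tested parameter regime approaches this.
* **Reproducibility:** a single random-number stream per replicate, consumed
  in a fixed documented order (per proposal: effect draw(s), then one
  fixation uniform — always consumed, even when $\Pi = 0$; one first-mover
  coin per conflict iteration; one direction coin per nonzero abiotic
  displacement). The C++ engine and the pure-R reference engine consume the
  stream identically and produce bit-identical logs, which the test suite
  asserts; replicate seeds derive deterministically from
  `(base seed, cell, replicate)` so any grid cell reruns in isolation.
* **Abiotic pairing:** two-pass — the conflict run completes, its per-
  iteration displacement magnitudes are extracted, and the control walk runs
  on a fresh stretch of the stream. The pairing is defined by magnitudes per
  iteration, not by shared randomness, so sharing draws with the conflict
  run would create spurious coupling without making the comparison tighter.
  When the paired opponent fixed nothing the two walks are identical by
  construction, which the tests check exactly.

## What the simulations emulate — and what they do not

The generator produces the study conditions themselves (there is no external
data): monomorphic haploid parties, one unidimensional trait, additive
mutations, sequential sweeps. Passing tests therefore demonstrate properties
of the model, not of any real host–parasite system: there is no standing
variation, clonal interference, linkage, pleiotropy with other traits,
population dynamics or extinction, and abiotic change never reverts toward a
central value (real environments often do, which would make conflict look
even worse by comparison). The Gaussian fitness function is phenomenological;
fitness falls off on both sides of each optimum, which suits tug-of-war
joint phenotypes but not, say, open-ended escalation.

## Problem sizes

Equilibrium analyses use 200 replicates × (500 burn-in + 5,000 window)
iterations at the baseline $\omega = 1/2$ — the package's reduced-scale
default, which resolves all the qualitative contrasts at 4-standard-error
precision while keeping any experiment preset in the minutes range on one
core. Replicate counts are a single argument away when tighter Monte-Carlo
error is wanted.

## Known limitations

* The uniform/exponential matched-mean-size convention is this package's
  choice of parameterization; other conventions rescale those distributions.
* At very high precision, small real differences between regimes become
  statistically resolvable: conflict parties fix mutations a few percent
  larger than magnitude-matched abiotic parties at the baseline, even though
  the two are practically equal relative to their common elevation above the
  standard model.
* `r` is an integer proposal multiplier; fractional mutational-input ratios
  are not supported (swap party labels to express ratios below 1).

## A minimal session

```{r example, eval = FALSE}
cfg <- scenario_config("conflict", lag_load = 0.2, mean_size = 0.1,
                       n_replicates = 50, seed = 42)
res <- run_scenario(cfg)
res$power_aggregate

# paired abiotic control, with its conflict twin riding along
cfg_a <- scenario_config("abiotic_matched", n_replicates = 50, seed = 42)
res_a <- run_scenario(cfg_a)

# a power sweep over selection-strength asymmetry
grid <- experiment_grid(regime = "conflict", f = c(1, 2, 4, 8),
                        n_replicates = 50)
run_experiment(grid, "power-sweep")
```
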