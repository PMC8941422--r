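---
title: "Coupled dynamics of behavioural diffusion and group-level institutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled dynamics of behavioural diffusion and group-level institutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(instdyn)
```

## The model

instdyn simulates a population divided into many groups of $n$ individuals.
Each group holds $i$ adopters of a group-beneficial behaviour (cooperation,
a pro-social norm, a public-health practice) and carries a discrete
institutional strength $\ell \in [\ell_{\min}, \ell_{\max}]$ that scales how
effectively the behaviour spreads inside the group.

The mean-field state is the fraction $G_{i,\ell}(t)$ of groups in each
$(i, \ell)$ class. Behaviour spreads within groups by an SIS-style contagion
whose adoption flow from $(i-1,\ell)$ to $(i,\ell)$ is

$$\ell\beta\,[(i-1) + R]\,(n-i+1)\,G_{i-1,\ell},$$

and adopters relax back at rate $\gamma i$. The bracket couples groups
through a global diffusion field

$$R = \rho \sum_{i',\ell'} i' G_{i',\ell'},$$

i.e. $\rho$ times the mean number of adopters per group: adopters anywhere
exert influence on non-adopters everywhere, but only in proportion to the
receiving group's institutional strength $\ell$. Two consequences matter
throughout:

* at $\ell = 0$ the behaviour cannot spread at all, locally or from
  outside — the only way a no-institution group holds adopters is by having
  switched down from an institutionalized level while carrying them;
* at $\rho = 0$ within-group contagion still operates wherever
  $\ell \beta > 0$.

Institutions change by group-level selection. Each level has a perceived
fitness, the occupancy-weighted mean of $e^{b i - c \ell}$ over the groups
at that level:

$$Z_\ell = \frac{\sum_i e^{b i - c \ell} G_{i,\ell}}{\sum_i G_{i,\ell}},$$

so groups gain log-fitness $b$ per adopter and pay $c$ per institutional
level, and only the aggregate success of a strategy is observable, not the
behaviour of individual groups. Groups switch to an adjacent level at
per-group rate

$$\rho\left[\max\!\left(\tfrac{Z_{\ell'}}{Z_\ell} - 1,\, 0\right)
  + \mu\right],$$

keeping their adopter count $i$ unchanged. The innovation rate $\mu$ is
fitness-independent and lets empty levels be discovered. The same $\rho$
sets the timescale of both between-group behavioural diffusion and
institutional imitation.

### The clamp on selection rates

Written as a literal flow balance, the fitness-biased term has prefactor
$(Z_{\ell'}/Z_\ell - 1 + \mu)$, which is negative whenever the target level
is sufficiently less fit. A master equation needs non-negative transition
rates — a negative rate can push $G$ below zero — so the fitness-driven part
is clamped at zero and the *reverse* flow's positive rate carries the net
effect. This matches the verbal description of the process (groups move
towards a level *proportionally to* its relative fitness) and keeps every
individual flow interpretable as a rate.

### Empty levels and boundaries

$Z_\ell$ is a 0/0 when a level is unoccupied. A level counts as occupied
when its total mass exceeds $10^{-12}$ (a single named constant used by
both the R and C++ paths). Flows *into* an unoccupied level carry only the
$\rho\mu$ innovation term; the sentinel value $e^{-c\ell}$ reported for an
empty level is never used in a fitness ratio. At $\ell_{\min}$ and
$\ell_{\max}$ the neighbour flows that would leave the range simply do not
exist — including their $\mu$ parts — so mass is conserved exactly. $R$ and
$Z$ are recomputed from the current state at every derivative evaluation;
nothing is lagged.

## Parameters

| symbol | meaning | default |
|---|---|---|
| $n$ | group size | 20 |
| $\beta$ | within-group transmission per (adopter, non-adopter) pair | 0.1 |
| $\gamma$ | abandonment rate per adopter (sets the time unit) | 1.0 |
| $\rho$ | global diffusion rate; also scales institutional change | 0.05 |
| $b$ | log-fitness benefit per adopter | 0.18 |
| $c$ | log-fitness cost per institutional level | 1.0 |
| $\mu$ | innovation rate | $10^{-4}$ |
| $\ell$ range | institutional strengths | $[0, 5]$ |

$n$, $\gamma$, $b$, $\mu$ and the level range are the model's standard
study conditions and are left fixed throughout. $\beta$, $\rho$ and $c$
have no single canonical value — the interesting phenomena live on
different slices of that space — so the package ships a documented
reference point chosen as follows: $\beta = 0.1$ makes level-1 groups
modestly supercritical ($\ell\beta n = 2$ against $\gamma = 1$), so the
weakest institution suffices to sustain the behaviour but not
overwhelmingly; $\rho = 0.05$ keeps between-group coupling and
institutional change slow relative to within-group dynamics; $c = 1$ sits
in the active phase at that $\beta$. All experiment drivers accept explicit
values, and each shipped experiment below states its own point.

## Numerics

The coupled system is a $(n+1) \times L$-dimensional ODE (126 dimensions at
the defaults) integrated with a fixed-step classical 4th-order Runge–Kutta
scheme, $dt = 0.01$ by default. At the reference point the fastest rates
are $O(\ell_{\max} \beta n^2/4) \approx 50$, so $dt \cdot \text{rate} \ll 1$;
the step-halving test confirms the discretization error in the mean adopter
count at $t = 100$ is below $10^{-8}$. Rates grow with the global field, so
strongly coupled runs ($\rho \gtrsim 2$ at the defaults) need a smaller
step; the integrator aborts with the failure time and a suggestion to
shrink $dt$ whenever a state entry falls below $-10^{-9}$. Entries in
$(-10^{-9}, 0)$ — integration noise — are clipped to zero, and the state is
renormalized only when total mass drifts beyond $10^{-12}$; both events are
counted and reported on the trajectory object.

Steady state follows a two-part criterion: $t \ge t_{\min}$ (default
10 000) *and* the mean number of adopters per group
$\langle i \rangle = \sum i\, G_{i,\ell}$ changes by less than $10^{-10}$
over a window $\Delta t = 1$. "Average difference in groups" is read as
this change in $\langle i \rangle$; a stricter full-state criterion would
only delay detection without changing any recorded summary. A hard cap at
$10\, t_{\min}$ stops non-convergent runs (slow drifts near thresholds);
such runs are reported with `converged = FALSE`, never silently treated as
stationary.

## The stochastic oracle

The mean-field equations use a closure: every group feels the same $R$ and
the same $Z$ profile. To verify them, `simulate_ensemble()` runs an exact
event-driven (Gillespie) simulation of $M$ explicit groups under the same
per-group rates, recomputing the empirical field $\hat R$ and fitness
profile $\hat Z$ from the instantaneous ensemble after every event.
Because groups are exchangeable, the ensemble is stored as state counts
$C_{i,\ell}$ (the empirical distribution times $M$), with the aggregate
sums that the rates need maintained incrementally — this makes the per-event
cost independent of $M$ up to the state-space size. Permuting the input
group order therefore cannot change a trajectory, which is tested.

Agreement with the master equations is asymptotic in $M$: at $M = 2000$ and
the reference point, the ensemble mean of $\langle i \rangle(t)$ and of
every level occupancy stays within 3 Monte-Carlo standard errors of the
mean-field trajectory across 11 recorded times (20 replicates). The
discrepancy shrinks as $M$ grows, which is tested at $M \in \{10^2, 10^3,
10^4\}$. The oracle is a verification instrument for the implementation,
not a separate scientific claim: it shares the model's rates by
construction and checks the closure plus the integration, nothing more.

## Experiments and the phenomena they detect

All sweeps restart each grid point from the standard initial condition —
groups uniform over levels, adopter counts binomial with a 1% adoption
probability — so path dependence cannot leak between points; hysteresis is
probed only and explicitly by `detect_bistability()`.

**Cost collapse.** At the reference point, sweeping
$c \in \{1.0, \dots, 2.0\}$ gives steady adoption that declines gently and
then collapses discontinuously: global frequency drops from 0.462 to 0
between $c = 1.8$ and $c = 1.9$ (jump 0.46). `locate_discontinuity()`
brackets the largest adjacent jump and classifies it (threshold 0.2 in
global frequency), with optional bisection refinement capped at 12 steps.

**Institutional free-riding.** With $c = 1.4$ and rising $\rho \in
\{0.5, 1, 2, 3\}$ (integrated at $dt = 0.002$ for stability), the occupancy
of the no-institution level rises strictly, and the adopter frequency
*inside* $\ell = 0$ groups climbs from 0.11 to 0.30 even though those
groups cannot generate a single adoption event: the behaviour is imported
by groups that switch down while carrying adopters, whose presence then
raises the fitness of the costless strategy. This is the source-sink
mechanism by which strong global diffusion selects against institutions.
Pushed further ($\rho = 4$ at this $c$), the no-institution level grows
towards dominance, but equilibration becomes very slow; the shipped grid
stops where the steady-state protocol still converges.

**Bistability.** Near the collapse bracket the extinct and active states
coexist: at $c = 1.82$, a 1%-adoption start dies out while a 50%-adoption
start settles at global frequency 0.461. The probe's default high start is
90% adoption, but the shipped experiment uses 50%: at very high initial
adoption the costless $\ell = 0$ level is transiently the fittest level in
the population — it enjoys $b$ per adopter while paying no cost — so
institutions collapse from *both* starts and the active basin is missed. A
moderate high start near the active attractor is the honest probe of basin
structure.

**Institutional localization.** At $\beta = 0.06$, $c = 0.9$ the
steady-state occupancy is bimodal: about 25% of groups at $\ell = 0$, 75%
at $\ell = 2$, and the intervening level essentially empty, because
$\ell = 1$ is subcritical enough that its fitness falls below both
neighbours, trapping no-institution groups. The drift between the two
modes is extremely slow (the run is recorded at $t = 20\,000$ without
formal convergence), but the bimodal structure is established early and
stable.

## Extinction without global diffusion

With $\rho = 0$ there is no selection (every institutional-change rate
carries $\rho$) and no field, and the all-$i{=}0$ state is absorbing and
globally attracting. But the *time* to reach it depends sharply on
$\beta$: when even the strongest level is subcritical
($\ell_{\max}\beta n < \gamma$, i.e. $\beta < 0.01$ at the defaults),
$\langle i \rangle$ decays monotonically and is below $10^{-6}$ by
$t = 50$; when some level is supercritical, that level's groups sit in a
metastable endemic state whose decay time grows exponentially with $n$, and
$\langle i \rangle$ stays $O(1)$ on any practical horizon (about 1.8 at the
defaults). The package's tests assert fast extinction in the subcritical
regime and document the metastable case; claims of universal extinction by
a fixed finite time would be wrong for this model.

## Problem sizes

The shipped tests and the reproduction script use: the full protocol
horizon $t = 10\,000$ at $dt = 0.01$ for single steady states; 7-point cost
grids and 4-point $\rho$ grids for the sweeps; $M = 2000$ with 20
replicates for the oracle comparison; and $t = 20\,000$ for the
localization probe. These sizes were chosen so each phenomenon is
established well inside its asymptotic regime while a full run of every
experiment completes in a few minutes on a single core.

## Limitations

The model is fully mixed between groups: no network structure, no
spatially local diffusion. Individuals carry no payoffs and do no
utility-maximizing or payoff-biased imitation — only the group-level
strategy is selected on. Costs are per level and independent of how many
members adopt, which is deliberately harsh on strong institutions.
The mean-field closure ignores correlations between a group's state and
the field it experiences; the stochastic oracle quantifies, but does not
remove, that approximation. Finally, the synthetic initial condition
(uniform levels, binomial adopters) is a modelling convention: real
populations start from structured, correlated configurations that the
generator does not attempt to emulate, so passing tests demonstrate
internal correctness and the model's qualitative mechanisms, not calibrated
predictions for any empirical system.
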