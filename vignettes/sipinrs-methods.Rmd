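---
title: "Modelling emotional contagion with competing disseminator camps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling emotional contagion with competing disseminator camps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipinrs)
```

## The compartmental model and its assumptions

`sipinrs` models an online population exposed to a charged event. Every user
is in one of four states: emotionally susceptible (`S`), positive
disseminator (`Ip`), negative disseminator (`In`), or immune (`R`). Seven
flows connect them:

* mass-action infection `α1·S·Ip` and `α2·S·In` — a susceptible user adopts
  the sentiment of the disseminators they meet, in proportion to how
  prevalent each camp is;
* conversion between camps, `θ1·In` (purification, negative turns positive)
  and `θ2·Ip` (incitement, the reverse) — these are per-individual
  probabilities, so they enter linearly in the source compartment rather
  than as contact terms;
* immunization `β1·Ip`, `β2·In`, plus a *direct* path `γ·S` for users who see
  the content and immediately lose interest without ever disseminating;
* degradation `ε·R` — immunity decays and users re-enter the susceptible
  pool, which is what lets the contagion smoulder indefinitely instead of
  burning out.

The population is closed (`S + Ip + In + R = 1`), homogeneous, and
continuously mixed; all eight rates are constants in `[0, 1]` per unit time.
The classical SIRS comparator (`sirs_params()`, `integrate_sirs()`)
deliberately lacks the `γ` path, so every immune individual there must first
have been infected.

## Threshold and stability analysis

Because the equilibrium structure does not depend on how the infected mass
is split between camps, the analysis runs on the reduced system
(`I = Ip + In`, unified `α` and `β`):

$$X = -\alpha S I - \gamma S + \epsilon(1 - S - I), \qquad
  Y = \alpha S I - \beta I.$$

Setting $Y = 0$ gives the disseminator-free state $P_0 =
(\epsilon/(\gamma+\epsilon),\, 0)$ — note that even with nobody infected, the
$\gamma$/$\epsilon$ tug-of-war keeps only part of the population
susceptible — and the endemic state $P^* = (\beta/\alpha,\,
(\epsilon\alpha - \epsilon\beta - \gamma\beta)/(\alpha(\epsilon+\beta)))$.
The threshold is the infection pressure at $P_0$,

$$R_0 = \frac{\alpha S_0}{\beta} =
  \frac{\alpha\epsilon}{\beta(\gamma+\epsilon)},$$

and $P^*$ has a positive infected fraction exactly when $R_0 > 1$. The
package classifies stability from the eigenvalues of the analytic Jacobian
(with the Routh–Hurwitz coefficients `b`, `c` exposed for cross-checks); a
±1e−12 band on the eigenvalue real parts reports the knife-edge $R_0 = 1$
case as `"marginal"` instead of letting floating-point noise pick a side.
At $P_0$ the Jacobian is triangular, so its eigenvalues are
$-(\gamma+\epsilon)$ and $\beta(R_0 - 1)$: the stability label provably
tracks the sign of $R_0 - 1$, and the test suite confirms that long-run
integration lands on whichever point the threshold selects (to 1e−3 after
$t = 2000$) across random parameter draws.

## Numerical integration

Trajectories use classic fixed-step fourth-order Runge–Kutta (default
`dt = 0.1`, horizon `t_end = 200`; both configurable). The systems are
non-stiff at rates in `[0, 1]`, and a fixed grid keeps CSV exports and
comparisons trivially alignable; step-halving changes reference terminal
states by less than 1e−5. Tiny negative excursions (above −1e−6) are clipped
to zero after each step; non-finite states abort with the offending time.
Scenario summaries report the composition at the first grid point where the
largest derivative component falls below 1e−7 per unit time — "the detected
equilibrium" — rather than at an arbitrary horizon. Conservation
(`|S+Ip+In+R−1| < 1e−6` along every run) is asserted in the tests, and an
adaptive-solver oracle (`deSolve::lsoda` at 1e−10 tolerance) pins the RK4
results to 1e−7.

## The network model

The mean-field model assumes everyone meets everyone. The agent-based
extension replaces that with a contact graph. Node $i$ (degree $k_i$) reads
its neighborhood through the *degree-weighted* tallies $d_S, d_{Ip}, d_{In},
d_R$ — the summed degrees of neighbors in each state — and through the
imbalance $A = |d_{Ip} - d_{In}|$. The rationale: a well-connected neighbor
carries more influence, and opposing camps of equal weight neutralize each
other. The per-round probabilities are

* $F_{SR} = \gamma\,(d_S+d_R)/(d_S+d_R+A)$ — direct immunization, damped
  when the neighborhood is emotionally charged;
* $F_{SIp} = \alpha_1\,2A\,d_{Ip}/(k_i(d_{Ip}+d_{In}))$ *only when*
  $d_{Ip} > d_{In}$, and symmetrically $F_{SIn}$ with $\alpha_2$ — only the
  locally dominant camp infects, and high-degree nodes resist
  (the $k_i$ in the denominator);
* $F_{InIp} = \theta_1 A/k_i$ when $d_{Ip} > d_{In}$, $F_{IpIn} = \theta_2
  A/k_i$ when $d_{In} > d_{Ip}$ — conversion tracks local dominance;
* $F_{IpR} = \beta_1\,2(d_S+d_R)/(d_S+d_R+A)$ and likewise $F_{InR}$ with
  $\beta_2$ — neutral surroundings promote disengagement.

Design choices the formulas themselves leave open, fixed as follows:

* **Clamping and renormalization.** The factor 2 and the unbounded ratio
  $A/k_i$ make raw values exceed 1 on highly imbalanced neighborhoods; each
  probability is clamped to `[0, 1]` (clamp counts are tracked), and a
  node's exit set is rescaled only when its clamped sum still exceeds 1,
  preserving the ratios of a valid categorical draw.
* **Synchronous updates.** All probabilities come from the pre-round
  snapshot; each node consumes exactly one uniform draw per round,
  partitioned among its exits in a fixed order. This makes the vectorized
  engine bit-for-bit reproducible and testable against a naive per-node
  reference implementation under the same seed.
* **Degenerate neighborhoods.** An isolated node makes no contact-driven
  transitions; its direct immunization falls back to plain $\gamma$ and its
  degradation to plain $\epsilon$. When $d_S + d_R + A = 0$ on a connected
  node, the damping ratio is taken at its balanced-neighborhood limit 1.
* **Ties.** $d_{Ip} = d_{In}$ gives $A = 0$ and therefore zero infection and
  conversion probability — balanced camps cancel out, taken literally.
* **Degradation** is neighborhood-independent ($\epsilon$ per node per
  round), mirroring the mean-field `ε·R` term.

Defaults: 50 rounds, 25 replicates, base seed 20220801; replicate `r` is
seeded with `seed + r` covering both its initial state assignment and its
update draws, so a `simulation_config` fully determines the output.

## Networks and their generators

`generate_ws(n, k, p)` (ring lattice with rewiring) and `generate_ba(n, m)`
(preferential attachment from `m` unconnected seed nodes, hence exactly
`m(n − m)` edges) are thin, seedable wrappers over igraph's generators; the
reference experiments use WS(10000, 8, 0.4) and BA(10000, 4). The rewiring
probability default `p = 0.4` is chosen so the lattice clustering
$3(k-2)/(4(k-1)) \approx 0.643$ drops to $0.643(1-p)^3 \approx 0.14$,
a realistic small-world regime for a social graph of mean degree 8.
`read_edge_list()` ingests empirical networks (one pair per line, comments
and blanks skipped, duplicates and self-loops dropped with a reported
count); follower relations are symmetrized to an undirected graph because
the transition probabilities presume mutual visibility between neighbors.
`network_summary()` reports the usual substrate statistics (edge counts,
average degree, Pearson degree assortativity, mean local clustering with
degree-<2 nodes contributing 0, maximum degree).

## What the simulations show — and a structural caveat

On both generated topologies the reference parameterization produces the
expected outbreak: susceptibles collapse within a few rounds, the
disseminator counts spike at rounds 3–5, and immunity builds while
degradation keeps feeding fresh susceptibles back in.

The camp dynamics, however, are *bistable*. Conversion and infection only
act for the locally dominant camp, so once one camp dominates most
neighborhoods the other loses its inflows and decays; which camp wins a
given replicate depends on early stochastic fluctuations (the `α` advantage
of the positive camp competes with its faster immunization `β1 > β2`).
Replicate-level outcomes are therefore bimodal, and the across-replicate
median trajectory can rise again after the outbreak peak toward a high
plateau of the winning camp. Two practical consequences:

* `detect_peak()` (the earliest global argmax of the median count) is the
  right tool for the outbreak peak only when the late plateau stays below
  it; on long horizons the argmax can land at the end of the run.
* The property suite therefore measures *outbreak acceleration* by the
  round at which the median `In` count first reaches half the comparison
  run's peak — a statistic that isolates the outbreak phase — while peak
  *heights* are compared with `detect_peak()` directly.

The directional effects hold as expected under these measures: raising the
negative infection rate raises and advances the negative peak; raising
purification lifts the terminal positive share; raising degradation lowers
terminal immunity; seeding more initial negatives, or placing them on the
highest-degree hubs, makes the negative outbreak higher and no slower.

## What the synthetic substrates do and do not emulate

Generated WS/BA graphs reproduce the degree mixing, clustering regime, and
hub structure that drive the model's contact process, and the edge-list
reader accepts real microblog follower graphs. They do not emulate
community structure, degree caps, directed influence asymmetry, temporal
rewiring, or content-dependent behavior of real platforms — so passing
tests demonstrate internal correctness and the stated qualitative
mechanisms, not calibrated forecasts for any particular platform. Fitting
against observed sentiment series is supported only descriptively, via
`compare_trajectories()` (per-compartment RMSE and maximum deviation on a
shared grid).

## Problem sizes used by the test suite

Analytic and ODE checks run at full fidelity (`dt = 0.1`, horizons up to
`t = 2000`). Agent-based acceptance runs use the reference substrates
(10,000 nodes, 25 replicates, 50 rounds); directional property checks use
2,000-node graphs with 25 replicates and 15–50 rounds, sizes at which the
across-replicate medians are stable for the effects being asserted.

## Known limitations

* The transition-probability formulas are taken at face value, including
  the factor 2 and the resulting need for clamping; no attempt is made to
  renormalize them into sub-unit rates.
* No asynchronous/sequential update variant, no continuous-time
  (Gillespie) formulation, no parameter estimation from data.
* The bistability described above means long-horizon medians mix two
  qualitatively different outcomes; analyses that care about the camp race
  should inspect per-replicate trajectories (`$counts`) rather than the
  median alone.
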