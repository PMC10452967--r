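---
title: "Methods: contextuality analysis of collective nest-site choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contextuality analysis of collective nest-site choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antcontext)
```

## The scientific question

Intransitive (cyclic) preferences are well documented in individual animals
and in collective-intelligence systems such as ant colonies. Because a
cyclic preference pattern breaks *sign transitivity* of the pairwise
correlations, it is a natural place to look for *true (Type II)
contextuality*: correlations among a cycle of measurements stronger than any
context-independent joint probability model allows. The
Contextuality-by-Default (CbD) framework makes this testable for a *cyclic
system of rank n*: n "contents" (things measured) and n contexts arranged in
a cycle, each content measured in two contexts.

This package reimplements a complete simulation study of that question for
nest-site choice by *Temnothorax albipennis*-like colonies. A colony driven
from its destroyed home nest chooses between a nearby inferior nest (the
*context*, qualities c1–c4 = 3.1, 3.6, 4.1, 4.6) and a distant superior nest
(the *content*, qualities q1–q4 = 5, 5.5, 6, 6.5). Eight experiments pair
each superior nest with two contexts so that the linked pairs
(1,2), (3,4), (5,6), (7,8) — sharing their good nest — chain into a single
4-cycle (`build_design()`).

## Contextuality statistics for cyclic systems

Each linked pair contributes a correlation between the +1/−1 coded outcomes
("migrated to the good nest" = +1) of its two experiments, computed from the
two marginals and a joint:

$$E_k = 1 - 2p_a - 2p_b + 4p_{ab}.$$

The CHSH-type statistic uses the maximal odd-signed sum
$s_\mathrm{odd}(E) = \max \sum \pm E_k$ over sign patterns with an odd
number of minuses (closed form: $\sum_k |E_k|$ if an odd number of $E_k$ are
negative, else that sum minus $2\min_k|E_k|$; the package tests this against
brute-force enumeration up to rank 6). The two reported statistics are

$$\Delta C_\mathrm{CHSH} = s_\mathrm{odd}(E) - (n-2), \qquad
  \Delta C_\mathrm{CbD} = s_\mathrm{odd}(E) - (n-2) - \Delta,$$

where $\Delta = \sum_k |m_A(k) - m_B(k)|$ (with $m = 2p - 1$) measures
*inconsistent connectedness* (Type I contextuality): how much the same
content's marginal shifts between its two contexts. Positive
$\Delta C_\mathrm{CbD}$ indicates true contextuality. Both conventions are
always reported side by side because only their pair disambiguates boundary
cases. Violation flags use strict positivity with a `1e-9` tolerance, so a
system exactly on the boundary counts as a non-violation.

A deliberate feature of this design is that both the product correlations
*and* $\Delta$ are computed on the same four linked same-content pairs. In
the orthodox CbD layout the within-bunch joints couple different contents
and the connection differences are taken across bunches; the present design
is the pragmatic adaptation used in the study being reimplemented, and it is
the unique convention that reproduces all four of that study's headline
numbers (−1.68, −2.87, 2, 0) from its printed tables.

### The independent oracle

`noncontextual_lp_oracle()` decides CbD noncontextuality without the
closed form: a system is noncontextual iff a single distribution over the
$2^{2n}$ deterministic outcome atoms reproduces every pair's marginals and
joint while *simultaneously* attaining every connection's maximal agreement
probability $1 - |p - p'|$. Existence is decided by non-negative least
squares (Lawson–Hanson, `pracma::lsqnonneg`): the constraint system is
feasible iff the residual is numerically zero, and the reported margin is
minus the residual distance. NNLS was chosen over a textbook simplex
because the deterministic and PR-box reference systems make the LP basis
degenerate, which crashes naive pivoting; the least-squares active-set
method is unconditionally robust here. The test suite checks the oracle
against the `s_odd <= 2` criterion on 1,000 random consistently connected
zero-marginal rank-4 systems.

One instructive fixture: the deterministic intransitive "ice-cream"
preference cycle attains the algebraic maximum 4 of the CHSH expression,
yet the oracle correctly reports it *noncontextual* — being deterministic it
is trivially couplable, and its entire violation is carried by inconsistent
connectedness ($\Delta = 2$, $\Delta C_\mathrm{CbD} = 0$). Maximal CHSH
violation without inconsistent connectedness (the PR box) is contextual.

## The agent-based emigration simulator

`run_experiment()` implements a Markov-process colony of individually
simulated ants with five states (evaluating home/inferior/superior site,
committed to inferior/superior site). Each ant draws a lifetime acceptance
threshold from Normal(5, 1); every evaluation perceives the true quality
plus fresh Normal(0, 1) assessment noise and commits — irreversibly — iff
the perceived quality reaches the threshold. The home nest has quality
−1000 and is never accepted. Time advances in one-decision epochs: the ant
checks the three sites in random order, each discovered independently with
the per-epoch probability in `default_discovery_prob()`; the first success
is travelled to (`default_travel_time()`, seconds; diagonal entries are
one-second stay/re-assessment epochs) and evaluated; if nothing is
discovered the ant waits one second. Rejected sites remain the ant's
location; re-discovery of the current site re-evaluates it with fresh noise.

**Discovery-matrix orientation.** The published parameter table lists
"probabilities of finding nests" with an ambiguous row/column orientation.
The package stores the matrix as `[from, to]`, i.e. the *transpose* of the
published block, reading published rows as the nest being found and columns
as the searcher's location. This is the only orientation consistent with
the published switch rates: from home the poor and good sites are then
found at 0.06 and 0.03 per epoch, so one third of ants discover the good
site first, which is required for acceptance probabilities around 0.5 to
coexist with switch rates below 0.2. Under this orientation the simulator
reproduces the published acceptance column to within about 0.04 uniformly;
under the row-wise reading it is about 0.17 low everywhere. The residual
~0.04 bias reflects scheduling details of the original implementation that
its description does not fix (its printed standard errors are likewise
inconsistent with a simple proportion at n = 10,000); the orderings, the
experiment-8 preference reversal, and the joint-probability structure all
reproduce.

**Determinism.** Each experiment runs from one seeded stream with
epoch-synchronous vectorised updates over the active ants; identical
configurations give bit-identical results. (A per-ant-stream scheduler
would be statistically equivalent here but an order of magnitude slower in
R.) `max_time` (default ten times the longest observed duration) bounds
pathological stragglers; such ants are flagged uncommitted, never silently
dropped.

## Joint probabilities and errors

Because thresholds are fixed, ants with thresholds high enough to reject
the poor nest in every encounter choose the good site in both experiments
of a linked pair by necessity. `joint_accept_good()` therefore uses the
high-threshold decomposition

$$p_{ab} = h + (p_a - h)(p_b - h),$$

where `h` is the minimum, across the two experiments, fraction of ants that
evaluated the poor site at least once and did not commit to it (the
operationalisation of "invariably rejects"); the remaining mass is treated
as independent. The construction is heuristic, so values outside the
Fréchet bounds are clipped with a warning (downstream statistics require a
valid joint). Marginal uncertainties use the standard error of a
proportion; joint uncertainties use a bootstrap (study convention: 100,000
resamples). Since the joint depends on the per-ant data only through four
cells (committed-to-good × rejected-poor), each resample collapses to a
multinomial draw, which the tests validate against naive per-ant index
resampling. Study-level errors on both $\Delta C$ statistics resample all
eight experiments.

## The infinite-population model

An infinitely large colony selects a site with certainty whenever a bare
majority of individuals prefers it, so the colony-level outcome is binary:
`outcome_sign(H)` is +1 iff the individual acceptance probability H ≥ 0.5
(the tie resolves to the superior site — the only rule consistent with the
zero-noise headline pair (2, 0) given H = 0.50 in experiment 1). Joints of
deterministic outcomes are products, giving the zero-noise cyclic system of
`zero_noise_cyclic_outcomes()`.

The published description constrains the dynamic model only behaviourally
(binary winner fixed by H; recruitment rate $\alpha_s$, leak rate $\alpha$
and scout fraction z shape the duration, never the winner), so
`run_colony_ode()` implements a minimal four-compartment recruitment system
with those properties:

$$h' = -\alpha_s h + \alpha u,\quad
  u' = \alpha_s h - (\alpha_s + \alpha) u + \alpha_s c_w c_l,\quad
  c_w' = \alpha_s H_w u,\quad
  c_l' = \alpha_s (1 - H_w) u - \alpha_s c_w c_l$$

(home, scouting, committed-to-winner, committed-to-loser; $H_w$ is the
preference for the winning site; minority-committed ants are poached by
majority recruiters at mass-action rate $\alpha_s c_w c_l$). The winner's
committed fraction tends to 1, and the duration is the integration time
(deSolve, root-stopping) until it reaches 0.9. Durations are strictly
decreasing in $\alpha_s$ and increasing in $\alpha$ at the study's
parameter values; no quantitative durations are claimed.

## Problem sizes and numerical choices

The package's own study runs use n = 10,000 ants per experiment and
100,000 bootstrap resamples, matching the study conditions; the test suite
exercises the same code paths at n = 100–2,000 (with 5 seeds for the
monotonicity property) and the full n = 10,000 sweep once, keeping the
default suite around a minute. Probability and Fréchet validation use a
1e-9 tolerance; the NNLS oracle accepts a coupling below a 1e-7 residual.
Exact-zero correlations are treated as sign-indeterminate (not sign
transitive), since the definition requires one shared sign.

## What the simulations do and do not show

The simulator emulates threshold heterogeneity, noisy assessment,
distance-mediated discovery and irreversible commitment; it deliberately
omits tandem running, carrying, quorum plebiscites and spatial geometry
beyond the travel-time/discovery abstraction. Passing tests therefore show
that the *pipeline* is faithful and that this class of threshold-rule
colony model comes close to, but does not produce, true contextuality —
they do not show that real colonies cannot. The known limitations are the
~0.04 acceptance-probability offset against the original implementation
(scheduling under-determination) and the schematic character of the
infinite-population dynamic, whose contract is behavioural rather than a
specific published equation set.
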