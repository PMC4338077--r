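---
title: "Quorum signaling in collective action games: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quorum signaling in collective action games: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quorumsig)
```

## The game

A well-mixed population of $Z$ individuals repeatedly assembles into groups
of size $N$ to face a threshold public goods problem whose value depends on
an exogenous state of Nature: state $\alpha$ (probability $\lambda$) makes
collective action profitable, state $\beta$ (probability $1-\lambda$) makes
it worthless. Individuals carry a four-bit genotype
$(\sigma_\alpha\,\sigma_\beta \mid A_0\,A_1)$: the signal emitted under each
state and the action taken under each *majority* group signal. Signals carry
no intrinsic meaning; any meaning must co-evolve with behavior. Signal 1
costs its emitter $c_S$; signal 0 is free. A cooperator pays $c$; with $k$
cooperators in the group, the good is produced iff $k \ge M$ (we use
$\theta(0)=1$, so exactly $M$ contributors suffice). Against defectors each
beneficiary receives $Fkc/N$; against loners a cooperator receives
$Fc\,\theta(k-M)-c$ and the loner nothing. Majority ties (possible only for
even $N$) are worth the even mixture of both readings in the analytic
payoff; the simulator flips an actual coin.

Two genotypes are *signaling systems*: $(10|01)$, which marks the
cooperative state with the costly signal, and its mirror $(01|10)$, which
uses the free signal (a collective "secret handshake"). `signal_flip()`
implements the relabeling that swaps the two systems; when $c_S=0$ the whole
game is invariant under it, which the test suite exploits.

## Fitness, fixation, and the embedded chain

Fitness is the exact expectation of the focal payoff over hypergeometric
group assembly. For $k$ copies of $U$ among $Z-k$ of $V$,
$$\Omega_U(k) = \binom{Z-1}{N-1}^{-1}\sum_{j=0}^{N-1}
\binom{k-1}{j}\binom{Z-k}{N-1-j}\,\pi_U(j),$$
with $\pi_U(j)$ the focal payoff with $j$ same-type co-players, and
analogously for $\Omega_V$ (weights $\binom{k}{j}\binom{Z-k-1}{N-1-j}$).
Out-of-range binomials are zero, so edge compositions need no special
casing; both weight vectors are probability distributions, which is tested.

Strategy updating is pairwise comparison with Fermi probability
$[1+e^{-\gamma\Delta\Omega}]^{-1}$. The fixation probability of a single
mutant,
$$\rho_{V,U} = \Big[\sum_{i=0}^{Z-1}\prod_{j=1}^{i}
e^{-\gamma(\Omega_U(j)-\Omega_V(j))}\Big]^{-1},$$
depends only on the ratio $\phi_j = T^-(j)/T^+(j)$, so the prefactor
convention in $T^\pm$ cannot affect any chain-level result. In the
small-mutation limit the population is monomorphic between invasion
attempts and evolution is a Markov chain over the $n_S$ monomorphic states
with off-diagonal entries $\eta\,\rho_{V,U}$, $\eta = (n_S-1)^{-1}$. The
stationary distribution of this chain is each strategy's long-run
prevalence. A strategy is evolutionarily robust (ERS) when every mutant
fixes with probability strictly below $1/Z$.

```{r chain}
space <- strategy_space()
p <- game_params(Z = 100, N = 9, M = 5, c = 0.3, c_S = 0.06, F = 10,
                 lambda = 0.8, gamma = 0.5)
chain <- embedded_chain(space, p)
round(sort(stationary_distribution(chain), decreasing = TRUE)[1:4], 4)
```

## Parameters that matter

* $Z$ (population size, default 100 in the worked examples): enters both the
  hypergeometric sampling and the neutral rate $1/Z$.
* $N$, $M$ (group size and quorum): coordination is hardest for large $M/N$,
  which is precisely where signaling strategies prevail.
* $c$, $c_S$ (costs, payoff units): the costly-signal system dominates only
  while $c_S < c/2$; above that, signaling collapses.
* $F$ (enhancement factor, dimensionless): with $F$ up to $\approx N$ the
  game remains a genuine coordination dilemma.
* $\lambda$: the probability collective action is needed; both limits
  $\lambda\in\{0,1\}$ have exact symmetry-forced solutions that the tests
  verify (four strategies at 25% each).
* $\gamma$ (selection intensity): $\gamma=0$ is neutral drift (all
  $\rho = 1/Z$ exactly); the implementation stays accurate at least to
  $\gamma \sim 10^3$ via log-domain evaluation.

## Numerical choices

* $\rho$ is evaluated as a log-sum-exp of cumulative sums of
  $-\gamma\,\Delta\Omega$ (max-subtraction), so strong selection cannot
  overflow. An exactly neutral profile returns $1/Z$ *exactly*: robustness
  classifications use strict comparisons against $1/Z$, and behaviorally
  identical genotype pairs (e.g. $(00|00)$ vs $(00|01)$, which differ only
  in an action that is never expressed between them) must sit exactly on
  the boundary rather than a rounding error below it.
* The stationary vector solves $\pi(T-I)=0,\ \sum\pi=1$ by least squares
  (LAPACK QR) rather than eigendecomposition, for determinism. Uniqueness is
  decided structurally — the chain must have a single closed communicating
  class of its positive-transition graph — because near-symmetric clusters
  (the four $(0*|1*)$ states at $\lambda=1$) push the second singular value
  of $T^\top - I$ below any fixed rank tolerance while the stationary vector
  remains unique. The solution is validated by its residual
  $\|\pi T - \pi\|_\infty < 10^{-8}$.
* ERS boundary: strict inequality, so $\rho = 1/Z$ never certifies
  robustness. Consequently a node of the invasion graph with no outgoing
  edges need not be an ERS when it has an exactly-neutral partner; the two
  classifiers are computed independently.
* The alternative stability measures: `ers_plus_fitness` additionally
  requires $\Omega_B(1) < \Omega_A(1)$ for every mutant $B$ (fitness
  comparison at a single mutant), a subset of ERS by construction;
  `counter_invasion` demands $\rho_{B,A} > \rho_{A,B}$ for every favored
  invader. They are variants, not the headline classifier.

## The stochastic simulator

`run_simulation()` is an explicit agent-based realization: per step, a focal
individual imitates a random other with the Fermi probability and then
mutates with probability $\mu$ to a uniformly drawn strategy (self
included). One time step is one pairwise update attempt. Mutation is
attached to the replacement event; for the validated regime
$\mu < 1/Z^2$ the coupling convention is immaterial. Fitness uses the exact
bimorphic expectation whenever at most two strategies are present and
otherwise averages over sampled groups (focal plus $N-1$ distinct others,
matching the hypergeometric assumption). The simulator shares no code with
the analytic chain — payoffs are recomputed per group in compiled code, ties
are resolved by real coin flips — and is therefore used as an independent
oracle. `estimate_fixation()` simulates the embedded jump chain of the
mutation-free process (identical absorption law, far fewer draws).

The reference comparison runs at $Z=36$, $N=5$, $M=3$, $c=0.5$, $c_S=0.2$,
$F=10$, $\lambda=0.8$, $\gamma=0.5$, $\mu=10^{-5}$ with $5\times10^9$ update
steps: at $\mu=10^{-5}$ a strategy transition occurs only every
$\sim 10^6$ steps, and the rank correlation across all 16 states needs a few
thousand transitions to stabilize, which that run length provides (Spearman
$\approx 0.94$ against the chain).

## What the tests do and do not show

All quantitative checks run on the model's own synthetic dynamics: exact
limit cases ($\lambda\in\{0,1\}$, $\gamma=0$), brute-force enumeration
oracles at small $Z$, the tridiagonal absorption solve, the geometric-series
closed form, game symmetries, and chain-vs-simulation agreement. Passing
them shows the implementation is internally consistent and reproduces the
model's published behavior; it says nothing about how well the model
captures any real signaling organism — states of Nature are binary, groups
are assembled uniformly at random, signals are noiseless and the strategy
repertoire is the minimal quorum-sensing set. Within the model, results for
$\mu > 1/Z^2$, structured populations or continuous signals are out of
scope; the simulator is the only route to moderate-$\mu$ behavior and loses
its exact-fitness fast path once more than two strategies coexist.
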