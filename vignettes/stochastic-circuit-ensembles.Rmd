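---
title: "Stochastic ensemble modeling of gene regulatory circuits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic ensemble modeling of gene regulatory circuits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Kinetic models of gene regulatory circuits (GRCs) need rate constants that
are rarely measurable. `stochcirc` sidesteps the problem by taking only the
circuit *topology* — a signed directed graph of activations and
inhibitions — and building an *ensemble* of models whose kinetic parameters
are drawn at random from broad, biologically plausible ranges. Robust
features of the circuit (its expression states, their basins of attraction,
their stability against expression noise) are then read off the ensemble
statistics rather than from any single parameterization. Stochasticity
enters twice, mirroring the two kinds of variability in a cell population:
*parametric variation* (cell-to-cell differences, modeled by the random
parameters) and *expression noise* (stochastic gene expression, modeled by
an additive noise term in the dynamics).

## The model

Each gene $i$ follows a shifted-Hill rate equation

$$\frac{dx_i}{dt} = G_i \prod_{j \in \mathrm{reg}(i)}
  H^S\!\left(x_j; X^0_{ji}, n_{ji}, \lambda_{ji}\right) - k_i x_i,
\qquad
H^S(x) = \lambda + \frac{1 - \lambda}{1 + (x / X^0)^{n}},$$

with production rate $G_i$, degradation rate $k_i$, and per-edge threshold
$X^0$, Hill coefficient $n$ and fold-change $\lambda$ ($\lambda > 1$
activation, $\lambda < 1$ inhibition; $H^S(0) = 1$ and
$H^S(X^0) = (1 + \lambda)/2$). Stochastic runs integrate the
Euler–Maruyama discretization

$$x_i(t + \Delta t) = \max\!\big(0,\; x_i + f_i(x)\,\Delta t +
  D \sqrt{\Delta t}\, \eta_i\big), \qquad \eta_i \sim \mathcal N(0, 1),$$

with one noise amplitude $D$ shared by all genes and a clamp at zero
expression. An expression-proportional (multiplicative) noise term is
available as an option but off by default.

**Why $D$ is an amplitude, not a diffusion constant.** With the term
$D\sqrt{\Delta t}\,\eta$, an unregulated gene is an Ornstein–Uhlenbeck
process with stationary variance $D^2 / (2k)$ — the closed form used in the
test suite. On the default parameter ranges the expression scale is
$\sim 10^2$; on the working noise range $D \in [0, 50]$ the stationary
standard deviation $D/\sqrt{2k}$ then sweeps from negligible to comparable
with the expression scale itself, which is exactly the regime in which the
toggle switch's two states first blur and finally merge into one. Treating
$D$ as a diffusion constant (noise term $\sqrt{2 D \Delta t}\,\eta$) makes
the same 0–50 range perturbative everywhere — the states never merge — so
that convention cannot express the phenomenon this package exists to
quantify.

## Random model generation

Defaults follow the conventions of topology-only ensemble modeling:
$G \in [1, 100]$, $k \in [0.1, 1]$, integer $n \in \{1, \dots, 6\}$,
$\lambda \in [1, 100]$ (drawn on that range and inverted to $1/\lambda$ for
inhibitory edges). Thresholds use the half-functional rule: for an edge
$j \to i$, $X^0_{ji} \sim U(0.02\,M_j,\; 1.98\,M_j)$ where $M_j$ is the
median unregulated level $G_j / k_j$ of the source gene, so a regulation has
roughly even odds of being functional. $M_j$ is evaluated on a deterministic
$100 \times 100$ quantile-midpoint grid rather than by Monte-Carlo draws —
the same quantity, but free of RNG side effects. Initial conditions are
log-uniform between 1 and the maximum unregulated level
$\max(G)/\min(k) = 1000$, covering the attainable dynamic range.

The *parametric-variation index* $P$ (in percent) shrinks every range about
its midpoint,

$$y_{\min} = \frac{x_{\max} + x_{\min}}{2} -
             \frac{x_{\max} - x_{\min}}{2} \frac{P}{100}, \qquad
  y_{\max} = \frac{x_{\max} + x_{\min}}{2} +
             \frac{x_{\max} - x_{\min}}{2} \frac{P}{100},$$

so $P = 100$ reproduces the defaults and $P = 0$ collapses every range to
its midpoint. The implementation evaluates the algebraically identical
convex combination $y_{\min} = x_{\min}(1+p)/2 + x_{\max}(1-p)/2$
($p = P/100$), which is bit-exact at both endpoints. Hill-coefficient
ranges are scaled continuously and sampled uniformly over the integers in
`[round(y_min), round(y_max)]`, preserving uniformity over $\{1..6\}$ at
$P = 100$. Increasing $P$ widens the expression clusters without moving
their centers; increasing $D$ moves the clusters together until they merge.

## Sampling schemes

* **SIC** — one long trajectory at constant noise, recorded at equidistant
  times. The reference scheme, but at low noise a single trajectory stays
  trapped in whichever basin it started in.
* **MIC** — many short runs (one per model, one random initial condition
  each), each recorded once at the end. At low noise the record histogram
  estimates the *basins of attraction*; at high noise, the stationary
  distribution. One initial condition per model suffices because, in a
  large random ensemble, models with similar parameters jointly cover all
  states, and ensemble growth converges the expression distribution faster
  than extra initial conditions would.
* **SA** — simulated annealing: every model starts at the top of a noise
  ladder (default: 50 down to exactly 0 in 30 linear levels, 5 time units
  each) and carries its terminal state from level to level. Intermediate
  noise lets trajectories escape shallow basins but not return from deep
  ones, so the zero-noise end concentrates the ensemble in the most
  *stable* states. MIC and SA thus measure complementary quantities, and
  agree at high noise.

## Double-well benchmarks

Four 1-D potentials exercise every basin-width/depth combination. The exact
benchmark functions are package design choices built from canonical
quartics: the symmetric `a` ($V = x^4/4 - x^2/2$); `b`, `a` with a $-0.2x$
tilt (equal-width basins, right well deeper); `c`, a piecewise quartic
$V_0((x/w)^2 - 1)^2 - V_0$ with $w = 0.5$ left and $w = 1.5$ right of the
barrier (equal depths, right basin three times wider, $C^1$ at the join);
and `d`, `c` plus $+0.5x$ (narrow left well deeper). The tilts are several
times the "low" benchmark temperature so the stability orderings are
unambiguous, and the default double-well annealing ladder starts at an
effective temperature $D^2/2$ of twice the deeper well so the top level
mixes freely. The tests assert the behavior the schemes are for: SIC
trapping at low noise, MIC occupancy proportional to basin share (`c`), SA
capture of the deeper well at $\ge 95\%$ (`b`, `d`), and pairwise
Bhattacharyya distance $< 0.05$ between all schemes at high noise.

## Counting expression states

Expression records are normalized as $z$-scored $\log_2(x + 0.5)$; the
pseudo-count (half the minimum attainable unregulated level,
$G_{\min}/k_{\max} = 1$) keeps the transform continuous at zero, where the
nonnegativity clamp parks a small atom of records during high-noise runs. A
hard log-floor would tear that atom away from the adjacent low-expression
mass and manufacture artifact clusters.

A *state* is then a well-separated cluster of the record distribution,
counted in three steps: Gaussian mixtures with $1..5$ components selected by
BIC (`mclust`); entropy-based hierarchical combining of components (Baudry
et al. 2010, `clustCombi`) — BIC legitimately spends several Gaussians on
one heavy-tailed cluster, and combining undoes exactly that; and a
resolution cut discarding clusters holding under 10% of records (boundary
atoms and sampling flotsam below the scale at which ensemble state
structure is read). This counter was validated against the known
toggle-switch phenomenology — two states in the $D < 1$ slice, one state in
the $49 \le D < 50$ slice of a 10,000-model noise-randomized run — on eight
independent master seeds before being frozen; plain BIC component counts
fail that check because they resolve sub-dominant structure (a minority
co-expression mode, clamp atoms) that ensemble-level state counts do not.

Binning records on their own randomized noise level and counting states per
bin yields a *global bifurcation* profile; any randomized parameter can
serve as the control axis.

## Quadrastable switches and induction

The double-self-activating toggle switch (`TS_SA2`) can hold four states —
low–low, low–high, high–low, high–high. State enumeration integrates 100
random initial conditions per model at zero noise, clusters terminals at
1% relative tolerance, then *polishes*: cluster representatives get two
further relaxation rounds (100 time units each) and are re-clustered, which
merges same-basin stragglers still crawling near saddles (without the
polish, slow models split into spurious extra "states"; with it, four is
the maximum observed over 10,000 random models, as the phase-plane
structure dictates). Residual-based convergence filtering (relative
residual $< 10^{-4}$) discards clearly unconverged instances.

Under the plain default ranges the exactly-4-state models are
nested-hysteresis variants, not the LL/LH/HL/HH set, so the package ships a
documented configuration (`quadrastable_ranges()`): self-activation
fold-change $[20, 100]$, Hill $\{4, 5, 6\}$, threshold $[M, 2M]$ — above
the basal level, so the un-activated branch exists — and moderate mutual
inhibition ($[1.5, 6]$) so the high–high state survives. About 2–3% of
models are then cleanly quadrastable. MIC shows the low–low basin is large;
annealing from $D = 50$ leaves *no* model in low–low — the state with the
big basin is also the least stable, which is precisely the distinction
between what MIC and SA measure. The stability readout uses a slower
ladder than the general default (30 levels, 20 time units per level): the
per-level relaxation time was chosen by a convergence check — from that
schedule onward, doubling the level count or the relaxation time no longer
changes the final-state composition — because a too-fast anneal freezes
marginal models in shallow states before they can escape.

Drug induction of a self-activation link is modeled by an induction factor
IF scaling the link's strength in full: fold-change $\times$ IF *and*
threshold $\div$ IF. IF on the fold-change alone cannot reproduce the
observed routing of most models into high–high under strong simultaneous
induction — a sub-threshold loop stays disengaged no matter how large its
fold-change, so models race winner-take-all into low–high/high–low
instead. With the full mapping, IF $= 1$ is the identity, ramped induction
monotonically empties low–low into high–high, and removing the induction
leaves the ensemble in high–high (hysteresis).

## Robustness metrics

Distributions are compared by the Bhattacharyya distance
$BD = -\ln \sum_i \sqrt{p_i q_i}$ on a shared binning (capped at 20 for
disjoint supports), estimated per gene on 100 uniform bins spanning the
pooled $\log_2$ range and averaged over genes — per-gene averaging keeps
values comparable across circuits of different size, at the cost of
absolute values that are estimator-specific (orderings, not magnitudes, are
the meaningful output). The *response curve* tracks BD between the
ensemble distribution at time $t$ and the zero-noise end-of-run
distribution: at $D = 0$ it decays below 0.01 by $t \approx 8$ for the
toggle switch (10,000 models), and larger noise saturates earlier at a
larger plateau. The *noise-robustness index* is reported both as BD at
$D = 1$ (primary) and as the low-noise slope of the BD-vs-$D$ curve fitted
through the origin over $D \le 1$ (secondary). At matched seeds and
$n = 10^4$ models both self-activating toggle variants score a larger BD at
$D = 1$ than the plain toggle switch; at $n$ below a few thousand this
ordering sinks beneath the histogram sampling floor, which is why the
packaged checks use $10^4$.

## Numerical choices

* Integrator: Euler–Maruyama, `dt = 0.05`, `T = 50` for production runs
  (degradation rates $\le 1$ give relaxation times $\le 10$); state
  enumeration uses `T = 150` plus polishing; double wells use `dt = 0.01`.
  Halving `dt` moves converged zero-noise terminals by under $10^{-3}$
  relative.
* The zero-noise path of the stochastic integrator draws no random numbers
  and is bit-identical to forward Euler; the C++ ensemble core and the R
  single-model path agree to machine precision.
* Reproducibility: every scheme takes a seed; ensembles derive per-model
  seeds from the master seed so single models can be regenerated in
  isolation; PCA fixes component signs (largest-magnitude loading
  positive); mixture fits are seeded.
* Ties/degeneracies: zero-variance genes fall back to unit variance with a
  warning; empty bifurcation bins are flagged, not dropped; histograms
  with disjoint support return the documented BD cap.

## What the generator does and does not emulate

The synthetic ensembles emulate a heterogeneous cell population with
uncorrelated, uniformly distributed kinetic parameters and white additive
expression noise. Real populations have correlated parameters, bursty
(non-Gaussian) noise, extrinsic fluctuations with finite correlation
times, and measurement noise on top — none of which are modeled. Passing
tests therefore certify the *method* (scheme behavior, state counting,
metric properties) on the model class it assumes, not distributional
fidelity to any particular experimental data set. Absolute state counts
and cluster proportions also depend on the chosen parameter distributions;
the qualitative features (number of dominant clusters, merging under
noise, basin-vs-stability dissociation) are the robust outputs.

## Problem sizes used by the packaged checks

State merging: 10,000 models, noise $U(0, 50)$. Quadrastability: 10,000
default-range models (maximum-state check) and 8,000
quadrastable-configuration models yielding $\ge 200$ labeled quadrastable
models for annealing. Response time and robustness orderings: 10,000
models. Double-well schemes: 1,000–2,000 particles. These sizes put the
Monte-Carlo error comfortably below every margin asserted in the tests
while keeping the full suite in the minutes range on one CPU.
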