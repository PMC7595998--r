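---
title: "Methods: slow-fast reduction of multi-strain SIS dynamics with co-colonization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: slow-fast reduction of multi-strain SIS dynamics with co-colonization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocodyn)
```

## The model and its assumptions

`cocodyn` implements an N-strain SIS model in which hosts can carry up to two
colonization episodes at a time. The compartments are the susceptible
fraction $S$, singly colonized fractions $I_i$, and co-colonized fractions
$I_{ij}$ ordered by acquisition (first $i$, then $j$; same-strain double
carriage $I_{ii}$ is a real compartment). The assumptions that make the
reduction work are baked in and deliberate:

* all strains share the transmission rate $\beta$ and clearance rate
  $\gamma$; clearance is equal for single and double carriage (e.g.
  strain-transcending immunity or within-host growth limitation);
* recruitment of susceptibles equals mortality ($r = d$), so the compartments
  sum to 1 for all time;
* co-colonized hosts transmit each carried strain at half the single-carrier
  rate, giving the force of infection $F_i = \beta J_i$ with
  $J_i = I_i + \tfrac12\sum_j (I_{ij} + I_{ji})$;
* strain identity matters **only** through the interaction matrix $K$:
  $K_{ij}$ multiplies the rate at which hosts carrying $i$ acquire
  co-colonizer $j$ ($K_{ij} > 1$ facilitation, $< 1$ inhibition). Entries
  must be non-negative; a negative susceptibility factor is rejected as
  unphysical.

With $m = \gamma + r$ and $R_0 = \beta/m$, the aggregated pair $(S, T)$
closes on itself and is independent of $K$; for $R_0 > 1$ it settles at
$(1/R_0,\, 1 - 1/R_0)$.

## Similarity decomposition

`decompose_interactions()` writes $K_{ij} = k + \varepsilon\,\alpha_{ij}$
with $k$ the entrywise mean, $\varepsilon$ the root-mean-square deviation
from $k$, and $A = (K - k)/\varepsilon$. This makes $A$ mean-zero with
Frobenius norm exactly $N$, and $\varepsilon$ the natural smallness
parameter. The framing is non-unique: a user-supplied reference $k$ is
accepted (then $\varepsilon$ is recomputed about it and $A$ need not have
mean zero), which matters when a structural identity pins the diagonal — for
instance a symmetric $K$ with $K_{ii} = k$ yields the clean identity
$\lambda_i^j = \alpha_{ij}$ only when decomposed about that structural
reference. When $K$ is constant ($\varepsilon = 0$), $A$ is set to the zero
matrix, the decomposition is flagged neutral, and every downstream quantity
degenerates gracefully (zero fitness matrix, frozen frequencies);
$\varepsilon$ is never divided by.

## The neutral model and its fast linearization

At $\varepsilon = 0$ the totals reach
$I^* = mT^*/(m + \beta k T^*)$ and $D^* = T^* - I^*$ in closed form, with
total single colonization relaxing as
$I(t) = I^* + e^{-t(m + \beta k T^*)}(I(0) - I^*)$. Each strain's pair
$(I_i, J_i)$ then obeys a linear system with matrix

$$A_0 = \begin{pmatrix} -(m + \beta k T^*) & m \\ -\beta k T^*/2 & \beta k I^*/2 \end{pmatrix}.$$

**Sign of the (2,1) entry.** Some renderings of this linearization show the
(2,1) entry with a positive sign. Linearizing the aggregated $\dot J_i$
equation at $I = I^*$ gives $-\beta k T^*/2$, and only this sign makes
$\det A_0 = 0$ — which must hold, because the neutral model conserves strain
frequencies, so the linearization has a zero eigenvalue with the slow
direction $(I^*, T^*)$ as kernel. The implementation uses the negative sign
and exposes the fast decay rate $\xi = -\mathrm{tr}(A_0)$ explicitly, since
everything downstream (post-transient windows, decay-rate checks) is phrased
in terms of it.

The eigencoordinates of $A_0$ define `fast_coordinates()`: $H_i$ measures
the gap between strain $i$'s share of single colonization and its share of
total carriage and decays at rate $\xi$; $z_i$ is the strain frequency,
conserved on the fast timescale. After the transient the three candidate
frequency definitions $J_i/T$, $I_i/I$, $D_i/D$ coincide; the package uses
$J_i/T$ throughout as the best-conditioned one ($T$ is the largest and most
stable denominator). For the co-colonization share we take the symmetric
reading $D_i = \tfrac12\sum_{j \ne i}(I_{ij} + I_{ji}) + I_{ii}$, which sums
to $D$ over strains.

## The replicator equation and invasion fitness

For $\varepsilon > 0$, on the slow time $\tau = \varepsilon t$ frequencies
obey $\dot z_i = \Theta z_i((\Lambda z)_i - z^\top\Lambda z)$ with
$\lambda_i^j = \alpha_{ji} - \alpha_{jj} + \mu(\alpha_{ji} - \alpha_{ij})$,
$\mu = I^*/D^* = 1/(k(R_0 - 1))$ and
$\Theta = \beta T^* I^* D^*/(2T^{*2} - I^* D^*)$. The constructor zeroes the
diagonal exactly ($\lambda_i^i = 0$ by definition: a strain cannot invade
itself). Three algebraically equivalent formulations exist — the direct
$(A, \mu, q(z))$ form, the payoff form $M = \mu(A^\top - A) + A^\top$, and
the invasion-fitness form — and the test suite holds them to $10^{-12}$ of
each other on random inputs; the package integrates the $\Lambda$ form.

Two constants deserve comment. $\Theta$ is an explicit "clock": the
conventional replicator analysis sets $\Theta = 1$ because time is scaled
arbitrarily, and `simulate_replicator()` and the ensemble tools default to
that convention, while calendar-time work (reconstruction, full-system
comparison) uses the $\Theta$ from `neutral_equilibrium()` together with the
explicit `slow_time()`/`real_time()` converters — the $\tau = \varepsilon t$
mapping is never applied implicitly. $\mu$ amplifies interaction
asymmetries: the scarcer co-colonization is (large $\mu$), the more the
antisymmetric part of $A$ dominates invasion.

The mean fitness $Q(\tau) = z^\top\Lambda z$ summarizes the community's
feedback on itself: antisymmetric $\Lambda$ (a zero-sum game) pins $Q$ at
exactly zero for **every** $z$ — an algebraic identity, so the ensemble
check on it is tolerance-free in spirit and uses $10^{-9}$ only to absorb
round-off; symmetric $\Lambda$ makes $Q$ non-decreasing along trajectories
(the Fisher property). The related quantity $q(z) = z^\top A z$ gives the
effective mean interaction trait $\bar k = k + \varepsilon q(z)$; the two
differ by $\sum_j \alpha_{jj} z_j$, so community mean fitness and mean
co-colonization trait need not move together.

## Pairwise outcomes and canonical structures

For a strain pair with both $|\lambda| >$ `tol`, the sign pattern decides
the outcome: $(+,+)$ coexistence, $(-,-)$ bistability (priority effect),
mixed signs competitive exclusion by the invader with $\lambda > 0$. Edges
with a fitness at or below tolerance are reported as `"marginal"` rather
than forced into a class, because the four-outcome classification assumes a
nonzero product. `classify_structure()` tests, in order, antisymmetric,
symmetric, invader-driven (entries depend only on the invader, i.e. equal
columns off the diagonal), resident-driven (equal rows), then
almost-antisymmetric, using relative Frobenius deviations. Defaults:
$10^{-9}$ for the exact classes (pure floating-point slack) and $0.1$ for
almost-antisymmetric — no principled value exists for "a small
perturbation", so it is a user-settable convention. The zero matrix, being
both symmetric and antisymmetric, is reported as `"neutral/degenerate"`.

The structured generators in `structured_interaction_matrix()` reproduce the
canonical correspondences, verified entrywise in the tests: symmetric $K$
with neutral diagonal gives symmetric $\Lambda$; the "shared-deviation"
symmetric structure $K_{ij} = K_{ii} + K_{jj} - k$ gives invader-driven
$\Lambda$; off-diagonal-constant $K$ gives resident-driven; row-constant
(colonizer-driven), column-constant (cocolonizer-driven) and antisymmetric
$K$ all give antisymmetric $\Lambda$, with coefficients
$\mu(\alpha_j - \alpha_i)$, $(\mu + 1)(\alpha_i - \alpha_j)$ and
$(1 + 2\mu)\alpha_{ji}$ respectively. The last coefficient follows from
direct substitution of $\alpha_{ij} = -\alpha_{ji}$, $\alpha_{jj} = 0$ into
the invasion-fitness formula.

## Reconstruction and the quasi-neutrality test

Given a frequency path, the epidemiological variables are recovered as
$S = S^*$, $T = T^*$, $I_i = I^* z_i(\varepsilon t)$,
$I_{ij} = D^* z_i z_j$ — exactly on the simplex for any simplex $z$. The
pair-prevalence product law
$I_{ij} = k R_0[1 + k(R_0 - 1)]\, I_i I_j$ is equivalent to the
reconstruction because the prefactor equals $D^*/I^{*2}$ identically (held
to $10^{-10}$ over random parameters in the tests).

`quasi_neutrality_test()` turns the two invariants into diagnostics on a
full-system trajectory: (a) $\max_i |I_i/I - J_i/T|$ and (b)
$\max_{ij} |I_{ij} - \text{predicted}|$ normalized by the mean pair
prevalence $D/N^2$, reported from `window_start` onward (default $5/\xi$,
five fast e-folding times; user-overridable — the neutral-case unit test
uses a later window because the doubles relax toward the product law at the
slower rate $m$). The normalization in (b) is worth understanding before
interpreting the numbers: to first order the quasi-stationary doubles are
$I_{ij} \approx R_0 K_{ij} I_i J_j$, so the normalized deviation is
$\varepsilon\, \alpha_{ij} z_i z_j N^2 / k + O(\varepsilon^2)$. It is
$O(\varepsilon)$, but the constant grows toward $N^2\max|\alpha|/k$ as
frequencies concentrate on few strains (large $z_i z_j$ relative to
$1/N^2$). The acceptance test bounds the measured deviation by exactly that
first-order envelope rather than by an arbitrary multiple of $\varepsilon$.

`approximation_error()` quantifies the reduction directly: for each
$\varepsilon$ in a ladder it integrates the full system from a slow-manifold
start and the reduced pipeline from the same frequencies, and reports the
sup-norm over a shared slow-time horizon of the frequency difference
($z^{\text{full}} = J_i/T$) and of the compartment difference. The expected
behaviour — error decreasing monotonically in $\varepsilon$, bounded without
blow-up at $\varepsilon = 0.3$, at solver tolerance at $\varepsilon = 0$ —
is what the acceptance suite asserts; no convergence *rate* is estimated, by
design.

## Synthetic inputs: what the generators emulate

There is no external dataset here; the model's "data" are interaction
matrices. `random_interaction_matrix()` draws $N^2$ i.i.d. normal entries
with mean $k$ and standard deviation $\varepsilon$ (defaults $k = 1$,
$\varepsilon = 0.1$, the regime used for the worked examples). Normal is a
modelling choice — only the first two moments are specified by the target
regime — and negative draws are clipped at zero with a warning; clipping
shifts the realized moments, so analyses always recover $\hat k$ and
$\hat\varepsilon$ by decomposition instead of trusting the nominal values.
Random $\Lambda$ ensembles use uniform entries on $[-1, 1]$ with the
diagonal forced to zero, and simplex starts are flat Dirichlet (uniform on
the simplex) — the least-informative choice. What these generators do *not*
emulate: empirically structured interaction matrices (phylogenetic or
serotype block structure), strain-specific transmission or clearance,
demographic noise. Tests passing under them show the mathematics of the
reduction is implemented correctly, not that any particular pathogen system
satisfies the equal-traits assumptions.

## Numerical choices

* **State ordering** for the full system is
  $[S, I_1\ldots I_N, I_{11}, I_{12}, \ldots, I_{NN}]$ (doubles row-major),
  stable across versions; trajectories export in long form with labels
  `S`, `I_i`, `I_i_j`.
* **Solvers**: `deSolve::lsoda` with rtol $10^{-8}$ / atol $10^{-10}$ for
  the full system (mildly stiff near the fast transient) and rtol
  $10^{-10}$ / atol $10^{-12}$ for the replicator; both user-overridable.
* **Non-negativity**: the right-hand side is never clamped; tiny solver
  undershoots are zeroed only in returned trajectories and counted in the
  `clamped` attribute.
* **Simplex drift**: the replicator RHS sums to zero algebraically, so the
  solver conserves $\sum z_i$ near machine precision; output states are
  renormalized only when $|\sum z - 1| > 10^{-12}$, the count is recorded,
  and the raw pre-renormalization sums are kept in the `raw_sums` attribute
  so conservation can be audited rather than taken on faith.
* **Degenerate inputs**: $\varepsilon = 0$ short-circuits to the neutral
  conventions everywhere; $R_0 \le 1$ raises an explicit "no endemic
  equilibrium" error; marginal invasion edges are labelled, not classified.
* **Problem sizes**: the test suite and validation runs use $N \le 10$,
  replicator horizons $\tau \le 500$, full-system horizons $t \le 900$, and
  30-replicate ensembles — comfortably desk-scale, matching the regimes the
  model analysis targets ($N$ of order 10, $\varepsilon \in [0.05, 0.3]$).

## Known limitations

The reduction, and therefore the package, assumes equal $\beta$ and $\gamma$
across strains, at most two colonization episodes per host, no host
population structure, and deterministic dynamics. The replicator
approximation degrades as $\varepsilon$ grows (validated only up to
$\varepsilon \approx 0.3$ here) and near $R_0 = 1$, where the endemic
equilibrium itself degenerates. For $N > 2$ no symbolic equilibrium analysis
is attempted — attractors are whatever the integrator finds — and no formal
convergence order in $\varepsilon$ is estimated.
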