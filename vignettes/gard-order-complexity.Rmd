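---
title: "Order and complexity in GARD micellar reproduction: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Order and complexity in GARD micellar reproduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gardsim)
```

# The model

`gardsim` simulates compositional inheritance in amphiphile micelles. An
assembly is an integer composition vector $n$ over $N_G$ amphiphile types;
its dynamics follow the mutually catalytic GARD rate law

$$\frac{dn_i}{dt} = \left(k_i \pi_i N - k_{-i} n_i\right)
  \left(1 + \frac{1}{N}\sum_j \beta_{ij} n_j\right),$$

with buffered external fractions $\pi_i$, rate constants $k_i, k_{-i}$, and
the catalytic enhancement matrix $\beta$. The environment is buffered: the
monomer pool is never depleted, which keeps the system away from
equilibrium together with the externally driven fission step.

**Parenthesization of the rate law.** Written out flat, the rate law is
ambiguous about whether the catalytic factor multiplies the whole net term
or only the backward term. The default, `rate_form = "factor_on_net"`,
applies it to both directions: a catalyst lowers the barrier for entry and
exit alike and therefore accelerates kinetics without shifting the
equilibrium composition, which is how the factor appears throughout the
GARD literature. The literal backward-only reading is available as
`rate_form = "factor_on_backward"` for comparison; all downstream machinery
works with either.

**Stochastic realization.** The rate law is a mean-field statement; the
populations of interest are tens of assemblies of tens of molecules, so the
reactor realizes it as an event-per-step kinetic Monte Carlo: a type-$i$
gain fires with propensity $k_i \pi_i N F_i$ and a type-$i$ loss with
propensity $k_{-i} n_i F_i$, where $F_i$ is the catalytic factor implied by
the rate form. One growth–split event is the time unit of every figure and
analysis; continuous waiting times are deliberately not tracked, because
the observables are functions of the composition sequence only. A
deterministic fixed-step Euler mode (`kinetics_mode =
"deterministic_euler"`) integrates the same rate law with real-valued
counts; it is validated against the stochastic mean on two-type systems and
is mainly useful for checking mean behavior. A single-molecule assembly
never loses its last molecule — dissolution is outside the model — so loss
propensities vanish at $N = 1$.

**Fission.** A grown assembly of even size splits into two halves by
multivariate hypergeometric sampling (sampling molecules without
replacement), the unbiased model of random fission: per-type progeny counts
always sum exactly to the parent counts, and expected progeny composition
equals the parent's. This is the sole inheritance channel; its sampling
noise is the model's mutation process.

**The constant-population reactor.** `run_reactor()` keeps exactly
`n_assemblies` assemblies: each generation one assembly is chosen uniformly
at random, grown to `split_size`, and split; both progeny are kept and one
uniformly chosen non-progeny assembly is evicted (with a population of one,
one progeny replaces the parent). This is the simplest Moran-type
bookkeeping consistent with a constant population; selection is neutral, so
all population-level dynamics derive from the per-lineage kinetics. Whether
the original simulations kept both progeny is not fixed by the sources this
model follows; keeping both with uniform eviction was chosen for its
symmetry. A single R random stream is seeded once per run from
`ReactorConfig$seed`, making every trajectory a deterministic function of
its configuration.

# Composomes and compotypes

A **composome** is a self-reproducing compositional assembly. The package
operationalizes this as a parent–progeny test: a progeny is composomal when
the cosine similarity between its composition and its parent's pre-split
composition reaches a threshold `eta`. The default `eta = 0.90` is a
convention, not a measured constant — the concept is qualitative in the
sources — and it is exposed everywhere. Raising `eta` shrinks the composome
pool toward only the most faithful reproducers; the preset analyses use
0.95, where uncatalyzed (drifting) assemblies mostly fail the test and
attractor-bound assemblies mostly pass it.

Composomal compositions are clustered into `k` **compotypes** by k-means on
composition *fractions* (so assembly size cannot confound compotype
identity), with seeded deterministic restarts and labels ordered by
abundance. Non-composomal assemblies are never assigned to a compotype;
they form the drift pool, so $\sum_k P_k(t) + \mathrm{drift}(t) = 1$
exactly. The default `k = 3` matches the three-composome analyses the
package reproduces; no automatic model selection is attempted. The
trajectory CSV stores only compositions and lineage links; the parent's
pre-split composition is reconstructed during analysis as progeny plus
sibling (mass conservation makes this lossless), so `eta` can be chosen at
analysis time.

# The two observables

**Sequential entropy and order.** The order measure is the reciprocal of
the entropy assigned to an ensemble of virtual random walks that traverse
all units of the system — aqueous monomers and micelles alternating. With
$H(q) = \sum_i q_i \ln(1/q_i)$ (and the $0\ln 0 = 0$ convention),

$$S_r = k_B\,\frac{M N_{rw}}{M+N} H(\pi)
      + k_B \sum_k P_k\,\frac{N_{rw}}{M+N}\,N_k\,H(p_{\cdot,k}).$$

The geometric walk itself (nearest-neighbor moves, loop avoidance) is not
simulated: only its statistical outcome enters the formula, and
`sample_walk_string()` realizes exactly that outcome — segments of $M$
draws from $\pi$ followed by one micelle drawn from the populations — to
serve as an independent Monte-Carlo oracle. The sampler draws
$\mathrm{round}(N_{rw}/(M+N))$ segments per walk and does not count the
log-probability of the compotype choice itself (the closed form has no
$\sum_k P_k \ln P_k$ term); its expected mean negative log-probability then
equals $S_r/k_B$ exactly whenever $N_{rw}/(M+N)$ is an integer, which the
oracle-equivalence tests arrange.

When the compotype fractions do not exhaust the population, the remainder
is treated as micelles at the environment composition $\pi$ with mean size
$N$ — in both the closed form and the sampler, keeping the two consistent.
These drift micelles carry walk entropy but no complexity: a micelle at the
environment composition is reproduced by the same random generator as the
solution and needs no extra code.

Molar units follow the prescription of dividing $N_{rw}$ by Avogadro's
number: `molar = TRUE` reports $S_r$ per mole of walk units,
$R\,[\,M H(\pi) + \sum_k P_k N_k H(p_k)\,]/(M+N)$ in J/(K·mol), which is
exactly $N_A/N_{rw}$ times the per-walk value. In the pure-monomer uniform
limit ($M \to \infty$, 20 types) this gives $R \ln 20 \approx
24.9\ \mathrm{J/(K\,mol)}$, the ideal-mixing benchmark the tests pin down.

**Complexity.** The code size needed to reproduce the walk statistics once
attractors deviate from $\pi$. A compotype materially using $N_{Ck}$ types
over $N_k$ molecules has $\binom{N_{Ck}+N_k-1}{N_k}$ possible compositions
(computed through log-gamma, so large repertoires cannot overflow), and
contributes $c_k = P_k\,\frac{N_{rw}}{M+N}\log_2\binom{N_{Ck}+N_k-1}{N_k}$
bits. The effective repertoire $N_{Ck}$ counts profile entries above a
participation threshold `epsilon`; types present only at environment-level
traces need no code. The default `epsilon = 0.01` treats sub-percent types
as background; the rapid-takeover preset uses 0.10 because with its
ten-to-twelve-type repertoires the uniform share itself is 0.08–0.10, and a
type is only "materially participating" when enriched beyond that level.

**Indexing conventions.** `metrics_timeseries()` supports both readings of
the population index $k$: per-compotype (on a clustered series, with the
centroid profiles and mean sizes) and per-micelle (on a trajectory, every
assembly its own population with $P_k = 1/n$). The sources also mention a
reading with $N_k = 1$ for all $k$; since $N_k$ is defined as a micelle's
molecule count, this is interpreted as a unit-weight variant and is
available as `unit_sizes = TRUE` rather than as the default. Relative-value
columns are scaled to each series' maximum, the normalization used in
relative time-course plots.

**The binary coding.** `binary_information()` emits the simplest
compositional code: one bit per type, 1 for enriched-or-unchanged relative
to the solution, 0 for depleted. Its length is always $N_G$ bits — 20 bits
for the canonical twenty-type composome, the information content of a
ten-base RNA strand at two bits per base (`rna_equivalent_length()`).

# Scenario presets and what they emulate

The catalytic matrices behind published takeover runs are not public, so
the presets construct engineered block matrices whose qualitative dynamics
are fixed by design rather than found by searching random matrices — the
reproducibility of the patterns under a fixed seed matters more here than
realism of any particular matrix. Random matrices are still available
(`beta_spec("lognormal_random")`, defaulting to the conventional heavy-tailed
$\ln\beta \sim \mathcal{N}(-4, 4^2)$).

All presets run 100 assemblies splitting at 60 molecules. The population
size is the takeover clock: each lineage reproduces every ~100 generations,
commitment to an attractor takes a few reproductions, and attractor-to-
attractor conversion takes from a few to tens, so the patterns unfold over
hundreds to thousands of growth–split events.

* **`slow_takeover`** — a broad, common, weakly catalytic block (types 1–4)
  wins the initial commitment race from multinomial seeds; a rarer,
  strongly self-catalytic block (types 5–7) invades lineage by lineage
  through stochastic tipping. Dominance is exchanged gradually and the
  total composome fraction keeps rising as compositions sharpen.
* **`rapid_takeover`** — a narrow two-type attractor at high external
  concentration polarizes first; once its rare six-type competitor with
  very strong self-catalysis ignites inside a lineage, conversion is
  quick, so the population exchange completes within a few hundred
  generations. The narrow state reproduces more faithfully than its broad
  successor, so the total composome fraction passes an interior maximum;
  the broadening costs order while the larger effective repertoire raises
  complexity — the transient order dip with rising complexity.
* **`env_shift`** — two equally strong three-type attractors whose
  commitment is decided by the external fractions; at generation 2000 the
  concentrations of the two blocks are swapped, the influx stops supporting
  the resident attractor, and every lineage converts: the dominance ranking
  reverses. Only $\pi$ changes; rate constants are untouched.

What the engineered runs do *not* emulate: real amphiphile chemistry,
lognormal catalytic heterogeneity, covalent modification, or vesicle
morphology. Passing the preset checks shows that the reactor, detection and
metric machinery express the intended population phenomena — not that any
particular lipid system behaves this way.

Closed-form `fixture_compotype_series()` curves (logistic rises and falls
with fixed permutation-symmetric profiles) bypass the simulation entirely
for deterministic metric tests; the `fig4_like` fixture uses three profiles
with identical entropy, which makes order and complexity provably monotone
in the total composome fraction.

# Numerical choices and degenerate inputs

* Entropy sums use the $0 \ln 0 = 0$ convention; `order_value(0)` returns
  `Inf` with a warning (a perfectly ordered, degenerate system).
* Multiset coefficients are evaluated in log space (`lchoose`); exact
  integers are returned below $2^{53}$. Non-integer mean sizes $N_k$ pass
  through the gamma function.
* `grow_to_split()` caps at $10^6$ events before raising a progress error,
  preventing silent hangs when loss propensities dominate.
* k-means restarts (`nstart = 10`) run under a locally seeded RNG that is
  restored afterwards; cluster labels are canonically ordered by
  time-summed abundance so reruns are label-stable.
* Walk parameters for analyses default to $M = 5$–$10$ aqueous monomers
  between micelles, $N$ equal to the trajectory's mean assembly size, and
  $N_{rw} = N_A$ with molar units, so entropies land on the J/(K·mol)
  scale.

# Problem sizes

The shipped analyses and tests run reactors of 5–100 assemblies, split
sizes 10–60, repertoires of up to 20 types, and up to 4,500 growth–split
events; Monte-Carlo oracles use 8,000–10,000 sampled walks per
configuration and 50 randomized configurations. These sizes were chosen so
that each preset reproduces its qualitative phenomenon with comfortable
margins while a full analysis completes in seconds on one core; the
dynamics of interest (commitment, tipping, conversion) scale with
population size and would only stretch proportionally at larger settings.

# Known limitations

* Selection in the reactor is neutral (uniform parent choice); fitness
  differences between attractors express themselves only through
  conversion flows, not through differential reproduction rates.
* A single global clustering covers the whole trajectory; compotypes do not
  appear or disappear dynamically.
* The geometric random walk is represented by its segment statistics only.
* The complexity estimator is the combinatorial code-size bound, not true
  (uncomputable) Kolmogorov complexity, and no free-energy bookkeeping is
  attempted.
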