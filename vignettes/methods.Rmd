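---
title: "Learning and interpreting driver-event networks with gatedbn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning and interpreting driver-event networks with gatedbn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatedbn)
```

## The problem and the model

A cancer cohort reduced to driver events is a binary matrix: one row
per patient, one column per event (a mutation, deletion, translocation
or karyotype pattern), a 1 where the event was called in that patient.
`gatedbn` models such a matrix with a discrete Bayesian network: an
acyclic directed graph over the events plus one conditional probability
table (CPT) per node, so that the joint probability factorises as the
product over *families* — each node conditioned on its parents. The
family, not the edge, is the unit of interpretation throughout: a
family is a small multi-way interaction that can be heatmapped, tested,
and summarised as a logic gate.

No causal reading is intended. Directions are needed internally to
define families, but score-equivalent structures (e.g. the two
orientations of a single edge) receive identical scores, so all visual
exports render edges undirected, and children–parents relations should
be read as correlations.

## Scoring

Structures are ranked by a decomposable log posterior: the data
likelihood under the structure plus the log of an edge-penalty prior
P(M) ∝ e^(−nϵ), n being the edge count. Each family therefore
contributes one penalised local score,

> local(child, parents) − ϵ · |parents|,

in natural-log units, and the network score is their sum.

Two local scores are provided:

* **BDeu** (default): the Bayesian Dirichlet equivalent uniform
  marginal likelihood with equivalent sample size `ess`. For a binary
  child with q = 2^|parents| parent configurations, the Dirichlet
  weights are ess/q per configuration and ess/(2q) per cell, and the
  score is the usual ratio of log-Gamma sums. BDeu is
  likelihood-equivalent (Markov-equivalent structures tie), which is
  what justifies suppressing directions. The default `ess = 1` is the
  conventional default of exact structure-learning software; the score
  is finite for any data, and an empty data set scores 0.
* **BIC**: maximised multinomial log likelihood minus
  (log N)/2 · 2^|parents|. Offered as a prior-free alternative; on
  large samples both scores select the same structures (asserted in the
  tests at n = 20,000).

The penalty reading is deliberately literal: with ϵ read in natural-log
units, a network with n edges loses exactly n·ϵ nats, so ϵ is an
integer "cost per edge" a non-statistician can set. Because the penalty
is linear, a score table built at one ϵ can be re-penalised at another
without recomputing any likelihood (`with_epsilon()`), which makes
sweeps over ϵ = 1…20 cheap.

## The two knobs

* **μ** removes events carried by fewer than μ patients before any
  learning. The boundary is strict: count ≥ μ is kept. Rare events
  cannot support stable family structure and mostly add noise edges;
  μ is a data-preparation decision, not a tuned hyperparameter. The
  filter is monotone (raising μ only removes events) and idempotent,
  and every run writes a filter report listing what was removed with
  its count.
* **ϵ** controls sparsity. A useful property of the exact optimiser is
  that the optimal edge count is non-increasing in ϵ (checked as an
  acceptance property over ϵ = 1…20 on simulated cohorts), so ϵ can be
  raised until the network is communicable. `edge_nesting_report()`
  quantifies how well sparser networks nest inside denser ones across a
  sweep.

## Exact structure search

Finding the highest-scoring DAG is NP-hard in general, but for the
cohort sizes this package targets (tens of variables after the μ
filter) it can be solved exactly. The search is the classic dynamic
program over variable subsets: first, for every variable and every
candidate set S, the best admissible parent set within S is tabulated
by a max-transform over the subset lattice; second, the best network
over each subset is assembled by choosing its best "sink" (last
variable in a topological order). Both passes are O(V·2^V) vectorised
steps, so time and memory grow exponentially; the implementation
refuses problems above `hard_limit` (default 20) variables. The
returned network carries the same optimality guarantee as ILP-based
solvers on the problems it accepts; above the limit, either tighten μ
or export the score table in the plain-text parent-set format
(`write_jaakkola()`) for an external solver.

Determinism matters for reproducible figures, so ties are broken by
fixed rules: among equal-score parent sets, the smaller set, then the
lexicographically smallest by canonical (column) order; among
equal-score sinks, the lexicographically smallest variable. Repeated
runs return bit-identical structures, and the reported total score is
re-summed in canonical family order so it does not depend on the DP's
accumulation order.

`brute_force_optimal_dag()` enumerates every labelled DAG (feasible to
V = 5, where 29,281 exist) and is used in the tests as an independent
oracle: on random score tables the DP and the enumeration must agree to
the bit.

## The packaged example network

`example_bn()` is a five-node network used for simulation studies:
A, B, D are Bernoulli(0.5) roots; C has parents A, B; E has parents C,
D. The CPTs are noisy gates with fidelity 0.8: for every parent
configuration the child takes the gate output (C = A AND NOT B,
E = C OR D) with probability 0.8, in particular
p(C=1 | A=0, B=0) = 0.2. The 0.8/0.2 parameterization applies the same
symmetric noise to every row, which keeps the example honest: the
gates are recoverable but never deterministic. Forward sampling is
ancestral in topological order (Kahn's algorithm, ties broken by
canonical order) using R's default Mersenne–Twister generator, so one
integer seed reproduces a cohort bit-exactly.

What the simulator emulates is the *structure* of cohort data — binary
events with family-structured dependence and realistic noise. What it
does not emulate: per-sample mutation-rate heterogeneity, panel
differences, missing calls, and subclonal effects present in real
cohorts. Passing the recovery tests therefore shows the machinery is
correct, not that any particular biological matrix will yield a stable
network.

## Pairwise statistics and styling

Every unordered pair of retained events is tested with Fisher's exact
test (`stats::fisher.test`): two-sided p, conditional-MLE odds ratio
(the sample cross-product ratio is available as an option). The
Benjamini–Hochberg correction is applied across exactly that family of
choose(V, 2) tests — not just the learned edges — so edge annotations
agree with standalone "Fisher networks" built from the same table.
Degenerate tables (an event never or always present) carry no
information and are reported as p = 1, OR = 1, flagged.

Styling conventions: green for co-occurrence (OR > 1), yellow for
mutual exclusivity (OR < 1); solid line iff adjusted p < α (default
0.05); width = 0.5 · max(OR, 1/OR), capped at 8. The reciprocal
folding is an interpretive choice: odds ratios below 1 would otherwise
render invisibly thin, and folding gives a mutual exclusivity of 1/4
the same visual weight as a co-occurrence of 4. The legend quotes the
calibration (OR = 4 ↔ width 2). Node emphasis (bold outline) defaults
to events above the 95th percentile of event counts.

## Gate fitting

For each family the package enumerates every boolean formula that uses
each parent exactly once — internal nodes drawn from the enabled gate
set (default AND, OR, XOR; NOT on leaves can be enabled) — evaluates it
on the cohort, and keeps the formula whose output minimises the Fisher
p against the child column. Candidates are deduplicated by truth table
over the parents, so commutatively or associatively equal trees are
scored once; nested runs of one gate are flattened to n-ary form
(((A AND B) AND C) reports as AND(A,B,C)).

Tie handling is deterministic and layered. Identical output vectors
give bit-identical tables and p-values; distinct tables are considered
tied when their p-values agree within a relative 1e-12. Among tied
candidates the preference is: positively associated orientation first
(a two-sided test cannot distinguish a formula from its complement, and
a gate should match the child, not its negation — this matters in
practice, e.g. OR(B, NOT A) is the complement of AND(A, NOT B)); then
the smaller tree; then XOR over OR over AND at the root; then the
canonical string. The XOR-over-OR step is the rule that fires when
parents never co-occur, where the two gates produce identical vectors.

Gate p-values are reported unadjusted, with an optional BH-adjusted
column across the fitted families (`fit_all_gates(adjust = "BH")`);
they are summaries of already-selected families, not discovery tests,
which is why adjustment is optional rather than default. Because the
default gate set omits NOT, a family generated with a negated input
(like C in the example network) is summarised by its best
NOT-free approximation; enabling `allow_not` recovers the negated form.

## Numerical and degenerate-input choices

* Matrix ingestion accepts 0/1 and TRUE/FALSE tokens; missing cells
  error by default (`na_policy = "reject"`) and are only recoded to 0
  on explicit request. Non-binary cells, duplicate sample ids and
  duplicate event names error with the offending coordinates.
* Constant columns are allowed (the scores remain finite) but warned
  about; a μ that removes every event raises an explicit "empty model"
  error before any learning.
* `fit_cpts()` with pseudocount 0 sets rows for unobserved parent
  configurations to uniform and warns, rather than erroring — sparse
  cohorts routinely miss rare configurations.
* CPT rows must sum to 1 within 1e-12; probabilities are clamped to
  [0, 1] after validation.
* All file formats are plain text (TSV, JSON, DOT, GraphML); images
  are PNG/PDF/SVG chosen by extension.

## Problem sizes used in the tests

The suite verifies structure recovery on 1000-sample cohorts from the
five-node network (50 seeds), sampler calibration at n = 100,000,
DP-vs-brute-force equality on 100 random score tables at V ∈ {3,4,5},
ϵ-monotonicity on 700-sample cohorts at V = 11, BH/Fisher hand-checked
values, null-simulation FDR control (200 replicates, V = 10, n = 500),
and exhaustive gate recovery for 2–3 parents. These sizes were chosen
so the whole suite runs in well under a minute while keeping every
stochastic assertion comfortably inside its tolerance.

## Limitations

* The exact search is exponential in V; 28–46-variable cohorts that
  ILP solvers handle are out of reach of the DP — use the score-table
  export for those.
* Only binary variables are supported; discrete BNs with more levels
  (and hence non-binary drivers like multi-state karyotypes) are not.
* There is no inference engine beyond direct conditional frequencies;
  the networks are descriptive models of a cohort, not predictive
  classifiers.
* Gate fitting summarises, it does not estimate noisy-gate parameters;
  a noisy-OR fit is out of scope.
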