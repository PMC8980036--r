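# gatedbn

Optimal Bayesian networks of binary driver events, with Fisher-test
edge annotation, family heatmaps, and logic-gate fitting.

## What it is for

Large cancer cohort studies routinely reduce each patient to a binary
vector of driver events — is *TP53* mutated, is *5q* deleted, is the
karyotype complex — and then hunt for patterns of **co-occurrence** and
**mutual exclusivity** among those events. Pairwise Fisher testing is
the standard tool, but it cannot see n-way structure: three genes that
substitute for one another in a pathway may show no significant
pairwise signal at all. `gatedbn` instead learns a full **Bayesian
network** over the events and then makes it readable for biologists and
clinicians: each network *family* (a child node plus its parents) is a
small multi-way interaction that can be inspected as a heatmap,
annotated with pairwise statistics, and optionally summarised as a
boolean logic gate.

The workflow has exactly two tuning knobs:

* **μ** (`mu`) — minimum event count. Events present in fewer than μ
  samples are dropped before learning (an event with count exactly μ is
  kept).
* **ϵ** (`epsilon`) — integer edge penalty. The structure prior is
  P(M) ∝ e^(−nϵ) for a network with n edges, i.e. every edge costs ϵ
  nats of log posterior; larger ϵ gives sparser networks (typical range
  1–20).

## The model

A Bayesian network over binary variables X₁…X_V factorises the joint as
p(X₁,…,X_V) = ∏ᵥ p(Xᵥ | Pa(Xᵥ)). Structures are scored by the log
posterior

  log P(M | D) = ∑ᵥ score(Xᵥ, Pa(Xᵥ); D) − ϵ·|edges| + const,

where the local score is the BDeu marginal likelihood (default, with
equivalent sample size 1) or BIC. Because the score decomposes over
families, the globally optimal DAG can be found exactly by dynamic
programming over variable subsets (best-parents tables plus a best-sink
recursion). The search is exhaustive in score space: the returned
network provably maximises the penalised score among all DAGs with at
most `max_parents` parents per node (default 3). A brute-force
enumerator over all labelled DAGs (V ≤ 5) is included as an independent
check. The exact search is practical to about 20 variables; beyond
that, tighten μ or export the score table (`write_jaakkola()`) for an
external ILP solver.

Learned networks are rendered undirected — edge directions are an
artefact of score equivalence, not causal claims. Edges are coloured by
the Fisher exact test between their endpoints (green = odds ratio > 1,
co-occurrence; yellow = odds ratio < 1, mutual exclusivity), drawn
solid when the Benjamini–Hochberg adjusted p is below 0.05 and dotted
otherwise, with width proportional to max(OR, 1/OR). Each family can
additionally be fitted with a boolean gate (AND/OR/XOR over the
parents, optional NOT on inputs): every candidate formula is evaluated
on the cohort and the one minimising the Fisher p against the child
column is reported, preferring XOR over OR on identical statistics.

## Worked example

The package ships a five-node example network (`example_bn()`):
roots A, B, D are Bernoulli(0.5); C is a noisy `A AND NOT B` and E a
noisy `C OR D`, each with fidelity 0.8 — so p(C=1 | A=0, B=0) = 0.2.
Sampling a cohort from it and running the pipeline recovers the
generating structure:

```r
library(gatedbn)
bn  <- example_bn()
write_event_matrix(forward_sample(bn, 1000, seed = 11), "cohort.tsv")
cfg <- run_config("cohort.tsv", "out", mu = 10, epsilon = 1)
man <- run_pipeline(cfg)
man$result
#> optimal DAG (dp_exact): 5 variables, 4 edges, score -3119.401448
dag_edges(man$result$dag)
#>      from to
#> [1,] "A"  "C"
#> [2,] "B"  "C"
#> [3,] "C"  "E"
#> [4,] "D"  "E"
for (f in man$gate_fits) print(f)
#> C = XOR(A,B)  (p = 8.32e-24)
#> E = OR(C,D)  (p = 5.13e-76)
```

The learned skeleton is exactly the generating one. `E = OR(C,D)` is
the generating gate; for C the default gate set (no NOT) cannot express
`A AND NOT B`, and XOR(A,B) is its closest available summary — rerun
`fit_all_gates(..., allow_not = TRUE)` and the fit becomes
`C = AND(A,NOT B)` (p = 9.05e-72). The most significant pairwise
associations line up with the structure:

```r
head(man$pair_stats[order(man$pair_stats$q_value), ], 4)
#>    event_a event_b n11 odds_ratio      q_value          direction
#> 10       D       E 395  6.2986399 2.236336e-40      co_occurrence
#> 5        B       C  90  0.2096145 1.569927e-28 mutual_exclusivity
#> 2        A       C 261  4.0286192 1.436836e-23      co_occurrence
#> 9        C       E 274  3.1953780 4.578236e-16      co_occurrence
```

B–C is yellow (mutual exclusivity, OR ≈ 0.21): C was generated with
`NOT B` in its gate. The output directory contains the filter report,
the pair table, the network as JSON/DOT/GraphML, the gated network, one
heatmap per family (presence red, absence blue, samples sorted into
contiguous blocks), and a log echoing every effective parameter.

The same pipeline runs from the shell:

```sh
Rscript inst/scripts/gatedbn learn --input cohort.tsv \
    --mu 10 --epsilon 1 --out out
Rscript inst/scripts/gatedbn simulate --network bn.json \
    --n 1000 --seed 7 --out cohort.tsv
```

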