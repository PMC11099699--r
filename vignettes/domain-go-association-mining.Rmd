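---
title: "Mining domain-GO associations from co-annotation: models and methods"
author: "domap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining domain-GO associations from co-annotation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domap)
```

## The problem

Protein domains are the structural and evolutionary units of proteins, and a
large fraction of newly sequenced proteins can be annotated with domains long
before any experimental characterization of their function exists. `domap`
asks a simple question of an annotation corpus: *which Gene Ontology (GO)
terms does a domain imply?* It mines statistically reliable domain-term
associations from co-annotation patterns — proteins that carry both the
domain and the term — and then propagates those associations back to proteins
as scored function predictions, evaluated with the CAFA protein-centric
protocol.

The pipeline has four statistical stages, each exposed as ordinary R
functions and chained by `run_pipeline()`:

1. **Co-occurrence scoring.** Every domain–term pair co-annotated on at
   least one protein becomes a candidate mapping with support `n` (number of
   co-annotated proteins) and the Dice-type similarity
   `S = 2 n / (N_D + N_GO)`, where `N_D` and `N_GO` are the protein counts of
   the domain and the term in their respective annotation datasets. `S` lies
   in (0, 1] and reaches 1 exactly when the two protein sets coincide.
2. **Null calibration.** A randomized mapping table is built by permuting the
   GO column of the co-annotation records and recomputing supports. For a
   grid of candidate thresholds (S lower bounds 0.1–0.6 crossed with n lower
   bounds 1–5) the filtered S distributions of the real and randomized
   tables are compared with a two-sample Kolmogorov–Smirnov test; the minimal
   pair that rejects the null at `alpha = 0.01` marks where signal separates
   from chance. The final filter applies `n >= 2` and strictly `S > 0.2`, one
   step above the minimal separating pair, as a safety margin.
3. **EM refinement.** Each co-annotation triplet (domain *i*, protein *p*,
   term *j*) carries a latent responsibility `C_p` in [0, 1]: does pair
   (*i*, *j*) explain its own co-occurrence on *p*, or is a competing pair on
   the same protein responsible? With `M = sum C_p`, `K = sum (1 - C_p)`, and
   `Z` the count of proteins carrying exactly one of the two annotations, the
   association probability is `theta = M / (M + K + Z)`. The E-step shares
   each protein's explanatory mass among its pairs,
   `U(C_p) = theta_ij / (1 - prod_{(x,y) in A(p)} (1 - theta_xy))`, and the
   M-step re-estimates `theta`; the likelihood
   `L = prod theta^(M + alpha) (1 - theta)^(K + Z + beta)` is monitored until
   it stops improving. Initialization sets all `C_p = 1`, which makes the
   initial `theta` the Jaccard index of the pair's two protein sets.
4. **Evidence scoring.** For each pair the EM is rerun with that pair's
   `theta` pinned to zero, so only competitors may explain its proteins. The
   evidence score is the log likelihood-ratio
   `E = sum_p log[(1 - prod (1 - theta)) / (1 - prod (1 - theta_bar))]`
   over the pair's co-annotated proteins: large when the pair itself, rather
   than its competitors, carries the explanatory weight.

Accepted mappings become protein predictions: a protein carrying domain *i*
inherits term *j* with score `S_ij` (S mode) or the min–max-scaled `E_ij`
(E mode); the naive frequency baseline and a hybrid max-merge are provided
for calibration. Evaluation reports Fmax, Smin, and coverage in full and
partial modes.

## Reading of the E-step quotient and the likelihood exponents

Two spots in the model require an interpretive decision, recorded here as the
package's reading:

* The responsibility update is implemented as a **quotient**,
  `U = theta / (1 - prod(1 - theta))`. Because the pair is itself a member of
  `A(p)`, the denominator is at least `theta`, so `U <= 1` always holds and
  `U` is a proper responsibility weight. A product reading would not be
  bounded this way. This follows the noisy-OR style EM used for
  domain–domain interaction inference, which this model descends from.
* The likelihood exponents are `(M + alpha)` and `(K + Z + beta)` with
  `alpha = beta = 0` by default; the pseudocounts are exposed in
  `em_config()` but the model is well-behaved without them because all
  probabilities are floored at `epsilon` before logs.

## Tunable parameters

| parameter | where | default | meaning |
|---|---|---|---|
| `excluded_evidence` | `read_go_annotations()` | `"IEA"` | evidence codes dropped on load; IEA (uncurated electronic) annotations are excluded by default |
| `s_grid`, `n_grid` | `select_thresholds()` | 0.1–0.6, 1–5 | 30-cell candidate threshold grid |
| `alpha` (KS) | `select_thresholds()` | 0.01 | significance level for the null rejection |
| `s_min`, `n_min` | `filter_mappings()` | 0.2, 2 | final reliability filter; strict on S, inclusive on n |
| `alpha`, `beta` | `em_config()` | 0, 0 | likelihood pseudocounts |
| `max_iterations` | `em_config()` | 150 | EM iteration cap |
| `rel_tolerance` | `em_config()` | 1e-4 | relative log-likelihood improvement defining convergence |
| `epsilon` | `em_config()` | 1e-12 | probability floor for logs and shared-mass denominators |
| `e_score_iterations` | `em_config()` | 10 | EM iterations per pinned (leave-one-out) rerun |
| `em_s_min` | `pipeline_config()` | 0.1 | S cutoff restricting the EM triplet pool |
| `floor` | `minmax_scale()` | 0.01 | lower end of the E-mode prediction score range |
| `tau_grid` | `fmax()`, `smin()` | 0.01–1.00 | 100-step evaluation threshold grid |

Numerical behavior at the guards: pairs whose leave-one-out denominator
underflows `epsilon` are reported in the `capped` column of the evidence
table rather than silently clamped; EM iteration order is fixed (sorted pair
keys) so likelihood traces are bit-reproducible; the constant-vector case of
min–max scaling maps to 1.

## Information content and Smin

The ontology side needs a per-term information content for the semantic
distance. The package uses marginal-frequency IC computed **per namespace**:
`ic(t) = -log2(n_t / n_root)` with counts taken from the propagated training
annotations, so the root of each namespace has IC 0 and IC grows
monotonically toward the leaves. Terms never observed in the corpus receive
the maximum observed IC of their namespace — a smoothing choice that keeps
Smin finite while preserving the ranking of informative terms. Conditional
(parent-given-child) IC, as used by some CAFA tools, is a deliberate
non-goal; the definition in force is recorded in the IC table's attributes.

## Precision/recall conventions

Precision at threshold `tau` averages `TP/(TP+FP)` over the `m(tau)` proteins
with at least one prediction scoring `>= tau`; recall averages `TP/(TP+FN)`
over all benchmark proteins (full mode) or over the proteins the method
predicts at all (partial mode). Thresholds where `m(tau) = 0` are skipped
rather than scored 0, matching common CAFA tooling. Namespace roots are
excluded from predictions and truth before scoring — they are certain for
every protein and would inflate every metric.

## The synthetic test bed

Real results in this problem domain depend on specific database snapshots
(domain assignments, GO releases, curated reference mappings) that are both
large and moving targets. The package therefore ships a generator,
`generate_synthetic()`, that builds a complete miniature study: an ontology
with three namespaces, a protein set with domain annotations, GO annotations
containing **planted** domain–term associations plus noise, a curated-style
reference set (the planted pairs), and a held-out no-knowledge benchmark
(20% of annotated proteins whose annotations are withheld from training and
become evaluation truth).

Default study conditions: 500 proteins, 50 domains, 100 terms, 30 planted
associations, noise rate 0.2, dropout rate 0.1. Design choices worth
spelling out, because they determine what a passing test does and does not
show:

* **One domain per protein (default).** This guarantees that no two planted
  associations share proteins, so each planted pair's co-occurrence signal is
  attributable to that pair alone. Widening `domains_per_protein` creates
  multi-domain proteins whose bystander domains inherit planted terms —
  realistic, and available for studying the EM's ability to resolve such
  competition, but it blurs the ground truth the recovery assertions rely
  on.
* **Planted terms sit directly under their namespace root.** A planted term
  at the bottom of a private chain would hand its perfect co-occurrence
  signal verbatim to every chain ancestor, creating "spurious" survivors
  that are really just the planted signal under another name; a shared
  mid-level parent of ~10 planted siblings would instead hover right at the
  reliability threshold (`S ~ 2n/(n_d + 10n)` is approximately 0.18–0.22).
  Shallow planting keeps the planted/spurious dichotomy sharp.
* **Noise concentrates on one common background term per namespace.** Real
  corpora use a few broad terms very often; at desk scale this skew is also
  what keeps chance co-occurrence harmless, because a background term
  annotated to ~33 proteins needs four or more coincidental hits on a single
  10-protein domain before its S crosses 0.2 — roughly a 0.1% event. A
  uniform noise vocabulary, by contrast, is maximally adversarial at this
  scale: every noise term is rare, so two coincident hits already clear the
  threshold.
* **Balanced domain assignment.** Domains are drawn favoring the least-used
  ones, keeping marginal protein counts near-equal; the generator is a
  controlled test bed, and controlled marginals keep the chance-overlap
  geometry predictable. Skewed, realistic marginals are an explicit
  non-goal.
* **Chains.** Each namespace carries an unannotated chain to depth
  `dag_depth` below its first planted term, so the ontology has real depth
  and ancestor propagation is exercised structurally even though the deep
  terms carry no annotation mass.

What the generator does **not** emulate: realistic GO topology (tens of
thousands of terms, multiple inheritance rich enough to matter), skewed
domain-usage distributions, inter-protein correlation (families, paralogs),
annotation biases that correlate noise with specific domains, and any
sequence-level signal. Consequently, passing recovery tests demonstrate that
the statistical machinery does what it claims under its own model of the
data — planted signal plus independent noise — not that the same thresholds
are optimal on a real corpus.

## Problem sizes

The test suite and the acceptance script run the full study conditions (500
proteins) for the end-to-end assertions and smaller corpora (10–150
proteins) for the per-operation oracle comparisons; the EM oracle checks use
deliberately tiny fixtures (two proteins, three pairs) where an
independently coded loop implementation is feasible. These sizes were chosen
so the whole suite completes in well under a minute while every code path —
including the leave-one-out reruns, which dominate the cost at scale — is
exercised.

## Known limitations

* The E score is computed by rerunning a truncated EM (10 iterations by
  default) per pair, which is faithful to the method but quadratic-feeling
  in practice; the `pairs` argument of `compute_e_scores()` exists precisely
  so users restrict it to an S-filtered subset.
* A single randomized table is used for threshold selection (no replicate
  shuffles, no multiple-testing correction across the 30 grid cells); the
  selection is a calibration heuristic, not an inference procedure.
* The OBO parser covers the subset of the format the pipeline needs
  (`is_a`, `relationship: part_of`, `alt_id`, `is_obsolete`, `namespace`);
  cross-ontology links, taxon constraints, and GO-Plus axioms are out of
  scope.
* Coverage is reported as a fraction in [0, 1]; multiply by 100 for a
  percentage rendering.
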