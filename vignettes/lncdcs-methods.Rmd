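---
title: "Scoring lncRNA-disease associations through shared miRNA neighborhoods"
author: "lncdcs maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring lncRNA-disease associations through shared miRNA neighborhoods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncdcs)
```

## The model

`lncdcs` predicts lncRNA–disease associations from two bipartite
association tables — disease–miRNA and miRNA–lncRNA — under two
assumptions: similar diseases show similar interaction patterns with
miRNAs, and similar lncRNAs do too. No known lncRNA–disease pair enters
the scoring at any point; the gold standard is consumed only by the
evaluation harness. This makes the method applicable to diseases with no
annotated lncRNA at all, and it makes "leave-one-out" evaluation cheap:
leaving a pair out changes nothing upstream, so scores are computed once
and each held-out pair is simply ranked against the unconfirmed pairs.

The scoring chain is:

1. intersect the two tables on their shared miRNAs, M = M₁ ∩ M₂,
   and stack them into a tripartite graph (block order: diseases,
   miRNAs, lncRNAs; adjacency matrix AM, N = D + M + L nodes);
2. capped shortest paths SPM(i,j) ∈ {0, 1, …, r}, where 0 means
   "no path of length ≤ r" (never "distance zero");
3. closeness weights DCCM(i,j) = 1 − SPM(i,j)/(r+1) within the radius,
   0 outside, r/(r+1) on the diagonal;
4. association degrees AD(i,j) = (rowsumᵢ + colsumⱼ)/N of the DCCM;
5. the D × L block C₁₃ of AD is the raw prediction;
6. optionally FAD = FSD · C₁₃ · FSL, weighting by miRNA-based
   functional similarity of diseases (FSD) and lncRNAs (FSL).

Similarity uses information-content weighting: miRNA m contributes
C(m) = −log(deg(m)/|E|) — rare miRNAs certify similarity more strongly
than promiscuous ones — and a pair (i, j) scores
exp(S/Q) with S the summed contribution of the shared neighborhood and
Q = |N(i)| + |N(j)| − |N(i) ∩ N(j)|.

## Parameters that matter

* **`r` (radius, default 6).** The only tuning parameter of the scorer.
  Walks in a bipartite disease/lncRNA-vs-miRNA graph alternate sides, so
  disease–lncRNA distances are even and disease–miRNA distances odd;
  r = 6 admits paths up to three miRNA hops. Smaller r makes the score
  more local (r = 2 counts only directly shared miRNAs); larger r
  saturates once r exceeds the network diameter.
* **Log bases (10 for FSD, 2 for FSL).** Kept asymmetric exactly as the
  method defines them; both are configurable in
  `mirna_contribution()`. The base is a monotone rescaling of the
  contribution values, but not of the final similarities (sums of
  contributions do not commute with the rescaling), so the choice is
  preserved rather than unified.
* **`convention` (default `quotient_inside_exp`).** The similarity
  formula's typography does not disambiguate exp(S/Q) from exp(S)/Q.
  The default reads the fraction as a single argument of exp, which
  keeps disjoint-neighborhood pairs at exactly exp(0) = 1; the
  alternative (`exp_over_denominator`) yields values below 1 for weakly
  linked pairs and is selectable everywhere a similarity is computed.
* **Ranking policy (default `global`).** Each gold pair is ranked in
  the single pooled candidate set. `per_disease` first maps every score
  to its within-disease candidate percentile (ties counted half), then
  applies the same pooled machinery; this keeps the ROC/AUC
  self-consistency property for both policies and makes them coincide
  exactly when only one disease is present.
* **`fraction` (default 0.005).** Prediction lists report the top
  ceiling(fraction · D · L) pairs, ties broken lexicographically by
  (disease, lncRNA) for reproducibility.

## Numerical choices

Distances come from breadth-first search (igraph), but the contract is
the matrix-power definition — SPM(i,j) = min{k ≤ r : (AMᵏ)(i,j) ≠ 0} —
and the test suite enforces entrywise equality against a matrix-power
oracle. The closeness weight is computed as (r+1−k)/(r+1), algebraically
equal to 1 − k/(r+1) but exact at the upper end: the distance-1 weight
equals the diagonal value r/(r+1) to the last bit, so the documented
codomain and range bounds hold without tolerance. The SPM diagonal is
forced to 0 (the power definition would give 2 for any non-isolated
node); nothing downstream consumes it, since the DCCM diagonal is set
separately. The AUC is the tie-corrected Mann–Whitney rank statistic,
cross-checked against trapezoidal integration of the threshold ROC to
1e-9. All pipeline comparisons in the tests use absolute tolerance
1e-10.

Degenerate inputs are defined rather than crashed on: a pair of
entities with empty joint neighborhood (Q = 0) scores exp(0) = 1 with a
warning; entities isolated by the miRNA intersection stay in the node
registry by default (so matrix dimensions reflect the raw tables) and
can be removed with `drop_isolated = TRUE`; an empty gold standard
filters with a warning and is refused by the evaluator with an explicit
error.

## What the synthetic generator emulates — and what it does not

`generate_tables()` draws the two tables as independent Bernoulli edge
sets (defaults: 20 diseases × 15 miRNAs × 25 lncRNAs at 8% density,
mirroring the shape, at reduced scale, of the curated datasets the
method was designed for: a disease–miRNA table of a few thousand pairs
and a denser miRNA–lncRNA table) and then plants `n_gold` = 10
disease–lncRNA pairs by wiring `signal_overlap` = 3 shared miRNAs to
both members. Planting creates exactly the structure the raw score
rewards: short disease–miRNA–lncRNA paths and larger DCCM row sums for
the planted entities.

Two properties of real data are deliberately not emulated: heavy-tailed
degree distributions (real miRNA hubs are far more skewed than the
Bernoulli model), and correlated association patterns *within* the
disease and lncRNA layers. The second omission matters for
interpretation: on real curated data the similarity weighting
FSD · C₁₃ · FSL improves the LOOCV AUC, because diseases that share
lncRNA associations genuinely do share miRNA neighborhoods. The
generator plants no such layer-internal structure — and worse, planting
raises the degrees of the chosen miRNAs, which *lowers* their
information content and so depresses the planted entities' similarity
scores. Consequently, on this synthetic world the raw C₁₃ arm recovers
the planted signal strongly (LOOCV AUC ≈ 0.87 at seed 1, planted pairs
outscore background in 50/50 seeds), while the similarity-weighted arm
hovers near or below chance at individual seeds (≈ 0.44 at seed 1;
≈ 0.64 averaged over seeds). A green planted-signal test therefore
establishes that the network scoring recovers co-neighborhood signal —
it does **not** establish that similarity weighting helps, and a red
weighted-arm number on synthetic data is not evidence that it hurts on
real data. The acceptance test asserts the recovery bound on the raw
arm and prints both numbers.

## Design choices where the design was open

* **Shortest-path definition.** A naive piecewise matrix-power
  definition ("0 if AMʳ(i,j) = 0, else the first nonzero power") is
  self-contradictory on bipartite graphs: walk lengths have fixed
  parity, so AMʳ can vanish for pairs reachable at shorter distances.
  The min-k reading is the only one consistent with calling the object
  a shortest-path matrix, and is what the package implements.
* **Similarity on full tables.** FSD and FSL are computed on the
  complete disease–miRNA and miRNA–lncRNA tables *before* the miRNA
  intersection, since the similarity definitions are stated on the
  original bipartite graphs; the matrices are then aligned (explicitly,
  by name) to the network's block order. `final_scores()` refuses
  misaligned name orders rather than reordering silently.
* **Diagonal of the similarity matrices.** Computed by the literal
  formula, exp(mean contribution of the neighborhood), not forced to a
  constant maximum: the weighting step multiplies by these matrices and
  the method defines no rescaling.
* **Association degrees over all N nodes.** The degree formula's
  denominator D + M + L fixes the node universe; the miRNA block
  participates in the row and column sums even though only the
  disease × lncRNA block is ever read out.
* **Scores are rankings.** FAD values can exceed 1 and are never
  normalized to probabilities; every consumer (ROC, top lists) is
  rank-based, and positive rescaling of FSD or FSL provably leaves
  rankings unchanged (a tested invariant).

## Known limitations

The radius r is a genuine free parameter with no principled selection
rule here. Disease names are matched as normalized strings — there is no
ontology mapping, so synonymous disease labels fragment the network.
The miRNA name normalization implements casefolding, locus-copy merging
(`-1/-2/-3`) and arm preservation (`-5p/-3p`) only; nonstandard
identifiers pass through untouched. The AD score is a function of DCCM
row sums only, so it is centrality-driven: two pairs (i, j) and (i, j′)
with equally embedded j, j′ tie regardless of *where* j and j′ sit
relative to i beyond the radius cap. And as discussed above, the
synthetic benchmark cannot certify the value of the similarity
weighting; that claim needs real curated tables.
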