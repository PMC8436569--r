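---
title: "Mining amino-acid association rules from protein sequences"
author: "aarules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining amino-acid association rules from protein sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aarules)
```

## The problem and the model

Misfolding diseases such as sickle cell anemia trace back to the amino-acid
composition of a single protein chain. One way to summarise which residues
dominate a chain, and which residues travel together, is to treat the chain
as a transaction database: partition it into consecutive windows of ten
residues, regard each window as a market basket whose items are the
distinct amino-acid letters it contains, and mine frequent itemsets and
association rules over those baskets.

`aarules` implements that workflow end to end:

1. **Windowing** (`partition_windows()`): a chain of length $L$ becomes
   $\lceil L/10 \rceil$ consecutive non-overlapping windows; the trailing
   partial window is kept as a transaction. The 147-residue hemoglobin
   subunit beta chain (bundled as a fixture) yields 15 windows, the last of
   length 7.
2. **Frequent itemset mining** (`apriori()`): levelwise Apriori with
   prefix-join candidate generation, thresholded by an absolute minimum
   support *count*.
3. **Rule generation** (`enumerate_rules()`, `rule_confidence()`,
   `filter_strong()`): every frequent $k$-itemset ($k \ge 2$) contributes
   all $2^k - 2$ antecedent/consequent partitions; a rule
   $A \rightarrow B$ is *strong* when its confidence
   $\mathrm{conf}(A \rightarrow B) = \mathrm{supp}(A \cup B)/\mathrm{supp}(A)$
   reaches the threshold (default 90%, inclusive).
4. **Usefulness pruning** (`rule_metrics()`): strong rules are scored by
   lift, bi-lift, bi-improve and bi-confidence and kept as *useful* only
   when all four positive-correlation criteria hold strictly.

## Two counting modes

The package supports two support-counting conventions, selected by the
`mode` argument everywhere:

* **`set`** — classical market-basket semantics: the support of any itemset
  is the number of windows whose distinct-letter set contains it.
* **`paper`** (default) — identical for itemsets of size $\ge 2$, but the
  support of a **1-itemset** is the letter's total occurrence count across
  all windows, with multiplicity. This convention is what published
  confidence tables for this mining style actually use: on the hemoglobin
  beta windows, conf($D \rightarrow A$) is reported as 43%, which is
  $3/7$ — three windows contain both D and A, and D occurs 7 times in the
  chain — not the $3/5$ that window counting would give.

The two modes therefore disagree only where a singleton's occurrence count
exceeds its window count. For measure computation in paper mode the
convention propagates into $P(A)$ and $P(B)$ (occurrence basis for
singletons, so these pseudo-probabilities may exceed 1), while every
complement-event quantity stays on the window basis:
$P(\bar A) = 1 - P_\mathrm{win}(A)$ and
$P(\bar A B) = P(B) - P(AB)$ rather than a direct count of windows holding
$B$ without $A$ (the two coincide in set mode). The bi-confidence
denominator $P(A)(1 - P(A))$ likewise always uses the window-containment
probability. These choices are the only combination consistent with every
cross-checkable published measure row; `set` mode is offered as the
principled textbook alternative.

## The interestingness measures

For a rule $A \rightarrow B$ with window probabilities as above:

$$\mathrm{lift} = \frac{P(AB)}{P(A)P(B)}, \qquad
  \mathrm{improve} = P(B \mid A) - P(B)$$

$$\text{bi-lift} = \frac{\mathrm{lift}(A \rightarrow B)}
                        {\mathrm{lift}(\bar A \rightarrow B)}, \qquad
  \text{bi-improve} = \frac{P(AB) - P(A)P(B)}{P(\bar A)}, \qquad
  \text{bi-confidence} = \frac{P(AB) - P(A)P(B)}{P(A)\,(1 - P(A))}$$

All five share the sign of $P(AB) - P(A)P(B)$ (with lift and bi-lift
centred at 1), so they agree on the *direction* of association and differ
in how they normalise its strength. A strong rule is **useful** iff

lift $> 1$ **and** bi-lift $> 1$ **and** bi-improve $> 0$ **and**
bi-confidence $> 0$,

all strictly: a rule at exact independence (1, 1, 0, 0) is redundant.
Improve is computed and reported but deliberately excluded from the
verdict — its sign always matches bi-improve's, so it adds no information.
Degenerate cases are reported as markers rather than errors: when the
antecedent fills every window the complement event is null and bi-lift,
bi-improve and bi-confidence are undefined (`NA`, which fails its clause);
when $B$ never occurs without $A$, bi-lift is `Inf`, which passes the
$> 1$ clause (the measure's range is $[0, \infty]$).

## Worked example

```{r worked}
hbb <- read_fasta(hbb_fasta_path())[[1]]
report <- mine_protein(hbb, window_len = 10, minsup = 3,
                       min_conf = 0.90, mode = "paper")
report
```

The run reproduces the published benchmark for this chain: 15 windows,
135 frequent itemsets (16/50/50/17/2 across sizes 1–5), 698 candidate
rules, 95 strong at the 90% threshold, and 59 useful after pruning. The
flagship useful rule:

```{r gt-an}
db <- partition_windows(hbb)
p <- rule_probabilities("GT", "AN", db, "paper")
c(lift = lift(p), bi_lift = bi_lift(p),
  bi_improve = round_half_up(bi_improve(p), 3),
  bi_confidence = round_half_up(bi_confidence(p), 3))
```

## Tunable parameters

| parameter    | default | meaning                                                        |
|--------------|---------|----------------------------------------------------------------|
| `window_len` | 10      | window (transaction) length in residues                        |
| `minsup`     | 3       | minimum support **count** (absolute, not a fraction)           |
| `min_conf`   | 0.90    | inclusive confidence threshold for strong rules                |
| `mode`       | `paper` | singleton support basis: occurrences (`paper`) or windows (`set`) |

`mining_presets()` records the support counts used for the five study
proteins: 3 for the 147-residue hemoglobin beta chain, 5 for the long
BRCA1 (1863 aa) and CFTR (1480 aa) chains, and 4 for the mid-length
vasopressin V2 receptor (371 aa) and rhodopsin (348 aa). The threshold is
an absolute count because the windows of one protein form a single small
database; scaling it with sequence length keeps the rule lists comparable
in size across proteins.

## Numerical choices

* Confidence is an exact ratio of integer counts; filtering compares the
  ratio, never a rounded percentage. Display rounding is half away from
  zero in a single step (so $5/13 = 38.46\%$ prints as 38%).
* Measures are computed in double precision from small-denominator
  rationals; displayed to 3 decimals. The set-mode bi-confidence bound
  $[-1, 1]$ holds exactly in rational arithmetic and to within one float
  ulp in the implementation.
* The miner is fully deterministic: canonical alphabetical itemset order,
  size-then-lexicographic listing, subset-enumeration rule order. Written
  artifacts are byte-identical across reruns.
* The downward-closure candidate prune is applied only in set mode; in
  paper mode level 1 lives on a different counting basis, so size-2
  candidates are generated from all frequent singleton pairs and counted
  directly. Since every candidate's support is counted anyway, the prune
  never changes the output — only the candidate count.

## The synthetic-sequence generator

`random_protein()` draws residues i.i.d. from the 20-letter alphabet,
uniformly by default or from user weights, deterministically for a fixed
seed. It is used by the test suite to property-test the miner against
brute-force subset enumeration, the measures against explicit 2×2
contingency tables, and the report's count-conservation identities.
Uniform i.i.d. sequences emulate the transaction structure of real
chains — window size, alphabet, sparsity — but not their biology: real
proteins have skewed residue usage, local repeats and domain structure.
Passing property tests therefore certifies the *combinatorics and
arithmetic* of the pipeline, not any biological claim; the benchmark
checks against the published hemoglobin beta numbers are what tie the
implementation to real data. Property tests run on sequences of 40–100
residues (4–10 windows) with minimum support 2 — small enough for
exhaustive enumeration oracles, large enough to exercise itemsets up to
size 6 and beyond.

## Known limitations

* Windows do not overlap and are not randomised; patterns straddling a
  window border lose support. Overlapping or repeated random partitioning
  would average the border bias away at extra cost, and window lengths
  other than 10 change the rule lists; both are deliberately out of scope.
* Paper mode's occurrence-based singleton probabilities are not true
  probabilities (they can exceed 1); they exist to reproduce the published
  convention and are clearly separated from the window-based quantities.
* Rules are generated from all frequent itemsets, not only maximal or
  closed ones, so the rule list contains logically related entries; no
  redundancy-aware condensation is attempted beyond the usefulness
  verdict.
* No network retrieval: users supply FASTA files. Only the hemoglobin
  beta chain is bundled, because it is the one sequence printed in full
  in the public benchmark tables.
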