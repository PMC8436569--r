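# aarules

Frequent amino-acid pattern and association-rule mining from protein
sequences.

Proteins implicated in misfolding diseases (sickle cell anemia, cystic
fibrosis, some cancers) are long chains over the 20-letter amino-acid
alphabet. `aarules` asks which residues dominate such a chain and which
residues travel together, by casting the chain as a transaction database:
the sequence is partitioned into consecutive 10-residue windows, each
window is a market basket of amino-acid letters, and the levelwise
Apriori algorithm mines frequent itemsets over those baskets. Every
frequent itemset is split into all antecedent/consequent partitions
`A -> B`; rules are kept as **strong** when

```
conf(A -> B) = supp(A ∪ B) / supp(A) >= 0.90
```

and a strong rule is finally kept as **useful** only when all four
positive-correlation criteria hold strictly:

```
lift          = P(AB) / (P(A) P(B))                    > 1
bi-lift       = lift(A -> B) / lift(Ā -> B)            > 1
bi-improve    = (P(AB) − P(A) P(B)) / P(Ā)             > 0
bi-confidence = (P(AB) − P(A) P(B)) / (P(A) (1 − P(A))) > 0
```

Two support-counting modes are provided: classical window containment
(`set`) and the published convention (`paper`, default) in which a single
letter's support is its occurrence count with multiplicity — the basis
that reproduces published confidence tables for this mining style. See
the vignette (`vignettes/amino-acid-association-mining.Rmd`) for the full
model, conventions and numerical choices.

## Worked example

The 147-residue human hemoglobin subunit beta chain (UniProt P68871, the
sickle-cell protein) ships with the package:

```r
library(aarules)
hbb <- read_fasta(hbb_fasta_path())[[1]]
report <- mine_protein(hbb, window_len = 10, minsup = 3,
                       min_conf = 0.90, mode = "paper")
report
#> <mining_report> P68871 (147 aa)
#>   window_len 10, minsup 3, min_conf 0.90, mode 'paper'
#>   15 windows -> 135 frequent itemsets -> 698 rules
#>   95 strong (603 rejected) -> 59 useful, 36 redundant
```

The chain splits into 15 windows (the last of length 7); mining at
minimum support count 3 yields 135 frequent itemsets (sizes 1–5), which
generate 698 candidate rules; 95 reach 90% confidence and 59 survive the
interestingness pruning. The top useful rule, `GT -> AN` (windows
containing glycine and threonine also contain alanine and asparagine):

```r
db <- partition_windows(hbb)
p <- rule_probabilities("GT", "AN", db, "paper")
c(lift(p), bi_lift(p), bi_improve(p), bi_confidence(p))
#> [1]  3.7500000 12.0000000  0.1833333  0.9166667
```

lift 3.75 and bi-lift 12 (strong positive correlation), bi-improve 0.183
and bi-confidence 0.917 (both positive): the rule passes all four
criteria.

A whole FASTA file (any number of records) runs through
`run_pipeline()`, which writes `itemsets.tsv`, `rules.tsv`, `metrics.tsv`
and a versioned `report.json` per record:

```r
run_pipeline(hbb_fasta_path(), minsup = 3, out_dir = "out")
```

or from a shell via the thin CLI (exit codes: 0 ok, 2 validation, 3 I/O):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","aarules-mine.R",package="aarules"))')" \
  mine --fasta my.fasta --minsup 3 --min-conf 0.9 --mode paper --out out/
```

`mining_presets()` lists the support counts used for the five benchmark
proteins (3–5 by sequence length).

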