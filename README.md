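# ppirules

High-precision rule-based extraction of protein–protein interactions
(PPIs) from annotated biomedical text, with per-relation evaluation and a
generic two-tier classifier pipeline.

## The problem

Literature-mined PPI networks are built from sentence-level classifiers:
for every pair of protein mentions co-occurring in a sentence (an
*instance*), decide whether an interaction is asserted. Benchmarks
conventionally score this per instance. But a corpus describes the same
*relation* — the distinct protein pair, e.g. IL-6/gp130 — many times in
different linguistic forms, and for downstream use (knowledge-base
construction, network building) it is enough to catch *one* of them, while
a single false positive can wrongly flag a pair that is annotated negative
throughout. For large corpora this favors ultra-high-precision extractors
and a **per-relation** view of precision and recall.

`ppirules` implements:

- an eight-rule PPI classifier over dependency parses in the
  collapsed-Stanford dialect (`nsubj`, `dobj`, `prep_of`, `prep_between`,
  `conj_and`, `neg`, ...), with explicit negation handling and a 67-keyword
  interaction lexicon in five categories (Activation, Deactivation,
  Creating bond, Breaking bond, Signaling);
- corpus preprocessing: protein masking (`PROTEIN0`, `PROTEIN1`, ...),
  removal of protein-free parentheticals, conservative clause splitting,
  candidate-pair enumeration;
- per-instance and per-relation precision / recall / F:

  ```
  Precision = TP / (TP + FP)     Recall = TP / (TP + FN)
  F = 2 * Recall * Precision / (Recall + Precision)
  ```

  where at relation level TP/FP/FN count distinct protein pairs and one
  predicted-positive instance makes the relation predicted positive, with
  MIpR ("minimum #instances per relation") stratification;
- a two-tier pipeline: instances rejected by a first classifier are
  re-screened by a second, positives of either tier are final — so a
  high-precision rule tier can be combined with any recall-oriented tool,
  plus dependency-chain bigram features and a deterministic reference
  classifier for the machine-learning tier contract;
- executable worked-example fixtures and a synthetic corpus generator with
  controlled per-relation multiplicities, so everything is testable
  offline.

### The eight rules

| # | Pattern | Type |
|---|---------|------|
| 1 | `P_i` –nsubj→ REL-verb –dobj/prep_*→ `P_j` | dependency |
| 2 | REL-noun –prep_of→ `P_i`, –prep_X→ `P_j` ("binding of A to B") | dependency |
| 3 | REL-noun –prep_between/of→ `P_i` –conj_and→ `P_j` | dependency |
| 4 | conjunction `P_i and P_j` as nsubj of intransitive REL-verb | dependency |
| 5 | `P_i{-,/}P_j` + {interaction, complex, heterodimer, product, assembly} | lexical |
| 6 | `P_i` VERB {receptor, ligand, substrate, binding protein} {for, of} `P_j` | mixed |
| 7 | `P_i` {receptor, ligand, substrate, binding protein} `( P_j )` | lexical |
| 8 | `P_i` {binding domain, binding site} {in, within, on, of} ... `P_j` | lexical |

Rules are applied in order; the first match wins (order affects only the
reported rule id, never the decision). Rules 1–6 are vetoed by a `neg`
dependency at the trigger, its subject, or the governing verb; rules 1–4
additionally require a seven-token surface window and at most three
dependency-bearing words between the proteins.

## Worked example

```r
library(ppirules)

s <- annotated_sentence(
  "ex1", "IL-6 directly interacts with gp130 and LIFR",
  data.frame(mention_id = c("m1", "m2", "m3"),
             start = c(1, 30, 40), end = c(4, 34, 43)))
s
#> <ppi_sentence> ex1: "PROTEIN0 directly interacts with PROTEIN1 and PROTEIN2"
#>   3 mentions, 0 gold pairs

tree <- read_conllu(system.file("extdata", "worked_trees.conllu",
                                package = "ppirules"))[["wx.rule1_conjunction"]]
tree$sentence_id <- "ex1"
extract_corpus(structure(list(s), class = "ppi_corpus"), list(ex1 = tree))
#>   sentence_id e1 e2    label rule_id  trigger negated
#> 1         ex1 m1 m2 positive       1 interact   FALSE
#> 2         ex1 m1 m3 positive       1 interact   FALSE
#> 3         ex1 m2 m3 negative      NA     <NA>   FALSE
```

IL-6/gp130 and IL-6/LIFR are extracted by rule 1 — IL-6 is the nominal
subject of the relation word "interacts", gp130 its prepositional
modifier, and LIFR is reached through the propagated `conj_and` edge. The
gp130/LIFR pair matches no rule and stays negative.

Evaluation example, recomputing benchmark metrics from raw confusion
counts shipped with the package:

```r
head(recompute_benchmark_metrics(), 2)
#>   mipr    level  tp fp  fn precision    recall   f_score
#> 1    1 relation 132  7 486 0.9496403 0.2135922 0.3487450
#> 2    1 instance 153 10 847 0.9386503 0.1530000 0.2631126
```

A command-line wrapper is provided in `inst/cli/ppirules.R`
(`ppirules extract|evaluate|pipeline|synth`).

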