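---
title: "Rule-based PPI extraction, per-relation evaluation, and two-tier pipelining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based PPI extraction, per-relation evaluation, and two-tier pipelining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppirules)
```

## The extraction model

`ppirules` treats PPI extraction as binary classification of candidate
pairs: every unordered pair of protein mentions within one sentence (or
clause) is an *instance*, labeled positive when the sentence asserts an
interaction. The classifier is a fixed cascade of eight patterns over a
dependency parse plus the token sequence. The cascade is deliberately
precision-first: it only fires on constructions that almost always denote
an interaction, and it refuses long-range configurations where parsers
and annotators are unreliable.

The design rests on three assumptions:

1. **Masking.** Protein mentions are replaced by single placeholder
   tokens `PROTEIN0`, `PROTEIN1`, ... before parsing, so multi-word names
   cannot mislead the parser, and the rules can refer to protein tokens
   directly. Masking is a bijection (unmask ∘ mask = identity), verified
   by tests.
2. **Label dialect.** All rules are written against collapsed-Stanford
   labels (`prep_of`, `prep_between`, `conj_and`, `neg`, `nsubj`,
   `dobj`). Universal Dependencies input is converted once by
   `collapse_ud()` — `nmod:X`/`obl:X` (or `nmod` + `case`) to `prep_X`,
   `conj` + `cc`("and") to `conj_and`, `advmod`("not") and `det`("no") to
   `neg` — rather than matched in two dialects. The conversion is
   idempotent, so pre-collapsed parses pass through unchanged.
3. **Conjunction propagation.** For each `conj_and` edge the second
   conjunct receives propagated copies of the first conjunct's incoming
   `nsubj`/`dobj`/`prep_*` edges, flagged `propagated`. This is what lets
   "P0 interacts with P1 and P2" yield both P0–P1 and P0–P2: the second
   pair is reached through the propagated `prep_with`. Propagated edges
   participate in rule matching exactly like primary edges, but are
   excluded from tree walks that need the unique root path
   (`tree_path()`), and are not serialized to CoNLL-U.

### Negation

A match of rules 1–6 is vetoed when a `neg` dependency sits on the
trigger, on its subject, or on the governing verb — the nearest verbal
ancestor on the head chain ("no interaction of A with B was found" negates
at the noun, "activation of A by B was not identified" at the verb). The
determiner "no" is mapped to `neg` during collapsing so both forms go
through one code path, `has_negation()`/`negated_with_verb()`. Rules 7 and
8 are naming patterns ("erythropoietin receptor (EPOR)", "CD30L binding
domain on ... CD30") that assert a binding property rather than an event;
they carry no negation handling by construction. When a rule's pattern is
present but vetoed, the result records `negated = TRUE` for auditability.

### Locality constraints

Two tunable constraints implement the precision-first stance for the
dependency rules 1–4:

- `window_tokens` (default **7**): the surface token count from the first
  to the second protein, both inclusive, may not exceed seven.
- `max_dep_words` (default **3**): at most three *dependency-bearing*
  words may sit strictly between the proteins. A token is
  dependency-bearing when it participates in at least one edge whose
  label is outside the function-word set {`case`, `cc`, `punct`, `det`,
  `mark`} and its coarse POS is not ADP/CCONJ/PUNCT/DET — so collapsed
  prepositions ("with") and coordinations ("and") do not count. This
  operationalizes the informal notion "content words in between"; the
  reference conjunction fixture ("PROTEIN0 directly interacts with
  PROTEIN1 and PROTEIN2") has exactly three such words ("directly",
  "interacts", "PROTEIN1") between the outer pair, which calibrates the
  default.

Rule 8 enforces `window_tokens` only (its cue bigram is anchored to the
first protein but allows noun-phrase material before the second); rules 5
and 7 are inherently local token sequences. Both constraints are
config-overridable (`rule_config()`), and shrinking either can only remove
positives (a tested monotonicity property).

### Other parameters

- Rule 2's second slot accepts `prep_X` with X in {to, by, with, on, for}
  (a whitelist generalizing the attested "to"/"by"/"with" examples);
  `rule2_wildcard = TRUE` accepts any preposition except "of". The
  whitelist is the default because precision is the design goal.
- Rule 4 rejects the match when the keyword verb also governs a `dobj` or
  `prep_*` (it then relates the conjoined subjects to something else),
  with one exception: "form" is accepted iff its direct object is
  "complex" (`rule4_form_requires_complex`).
- Rule 6's verb slot accepts any verb linking the subject protein to the
  cue noun (copular or not); `rule6_copula_only = TRUE` restricts it to
  the copular analysis.
- Pairs of co-referent mentions (identical normalized entity key) are
  never positive: a self-interaction assertion cannot be distinguished
  from a parsing artifact at this precision level.
- Instances without an aligned parse are classified by the lexical rules
  (5, 7, 8) only; if none fires they default to negative, consistent with
  the cascade's default return.

## The keyword lexicon

The 67 interaction lemmas (12 Activation, 12 Deactivation, 19 Creating
bond, 10 Breaking bond, 14 Signaling) ship as a TSV data file and are
matched morphologically: each lemma is expanded once, deterministically,
into inflected forms (-s/-es, -ed, -ing) and nominalizations
(-ion/-ation/-ization and the -ing noun), with a hand-curated exception
table for irregulars ("form" → "formation", "reduce" → "reduction",
"recognize" → "recognition"). "bound" is a lemma in its own right, so the
surface "bound" maps to it rather than to the past tense of "bind"; a
parser-supplied lemma takes precedence when available. The category is
recorded in every match for reporting but never used by the rules. The
expansion table is regenerated at load time, so a user-supplied lexicon
file gets the same treatment.

## Evaluation: instances, relations, MIpR

`eval_result()` implements precision = TP/(TP+FP), recall = TP/(TP+FN),
F = 2PR/(P+R), with the conventions precision = 0 when TP+FP = 0,
recall = 0 when TP+FN = 0, F = 0 when P+R = 0 (so all three are zero
whenever TP = 0). F equals 2TP/(2TP+FP+FN) algebraically; the tests check
this numerically.

Per-relation evaluation groups instances by the corpus-wide *relation
key*: the canonically ordered pair of normalized entity keys (case-folded,
whitespace/hyphen-stripped surface form by default; corpora may supply
explicit keys). One gold-positive instance makes the relation gold
positive; one predicted-positive instance makes it predicted positive.
More sophisticated vote-based aggregation is deliberately out of scope.
Relation identity is corpus-wide by default (the same pair discussed in
several documents is one relation); `corpus_instances(per_document =
TRUE)` scopes it per document instead.

MIpR stratification (`filter_mipr()`) keeps a relation and all its
instances iff it has at least *k* instances; a gold-positive relation must
additionally have at least *k* gold-positive instances (it typically also
has negatively annotated instances, which would otherwise let a
single-mention relation slip into high strata). Gold-negative relations
are filtered on total count only, and *k* = 1 is the identity.

Reports round to three decimals with round-half-even. Note one
consequence: an F-score printed in a report that was *recomputed from the
rounded* P and R can differ from the rounding of the exact F by one unit
in the third decimal; the shipped benchmark-count tests compare at that
resolution.

## The two-tier pipeline

`pipeline(tier1, tier2, instances)` labels every instance with tier 1 and
re-screens only its rejections with tier 2; the predicted-positive set is
the union of tier-1 positives and tier-2 positives among tier-1
negatives. Two consequences are tested as invariants: a tier-1 positive
is never flipped, and an always-negative tier 2 reduces the pipeline to
tier 1. A tier is anything satisfying the small classifier contract
(`ppi_classifier`): the rule engine (`rules_classifier()`), a file of
precomputed labels from an external system (`fixed_labels_classifier()`,
so third-party tools are spliced in rather than reimplemented), or a
fitted model.

For model tiers the package provides dependency-chain features: the
*forward chain* is the root-to-first-protein path of the tree, the
*backward chain* the root-to-second-protein path; features are the
bigrams of (label, lemma) elements along each chain, rendered
"label/lemma" (configurable to labels or lemmas only — the mixed rendering
is the default because it is the most informative and the choice is
isolated in `chain_bigrams()`). `select_top_features()` keeps the top-100
forward bigrams by (forward count − backward count), and symmetrically
for backward, with ties broken by higher raw same-direction count and
then lexicographically — a deterministic, instance-order-invariant
selection. Optional extra features: the two dependency lengths (edge
counts of the chains) and the surface offset distance (second minus first
protein token index; adjacent proteins have distance 1). The shipped
`reference_classifier()` thresholds the count of active bigram features,
fitting the smallest threshold that maximizes training F — a deliberately
simple, fully deterministic stand-in exercising the contract; SVM-class
learners are out of scope.

## Preprocessing decisions

- **Parenthetical stripping** deletes every top-level balanced `(...)`
  region containing no protein placeholder; regions with a protein are
  kept verbatim including nested parentheses (the decision is made at the
  top level). Unmatched parentheses are treated as literal tokens —
  fail-safe over clever repair.
- **Clause splitting** is not specified by any single standard procedure;
  the package uses a conservative heuristic: split at sentence-medial
  semicolons, and at "and"/"but"/"or" immediately preceded by a comma
  when both sides contain a protein and at least two tokens (and, when a
  parse is available, a subject dependency on each side). The fallback is
  no split, and splitting can be disabled wholesale. Gold pairs whose
  mentions land in different clauses are dropped from clause-level
  classification and reported via the `straddlers` attribute rather than
  silently scored either way.
- **Coordinates.** Internally all character spans and token indices are
  1-based inclusive, the native R convention; the PPI-XML reader converts
  the format's 0-based inclusive `charOffset` ranges and the standoff-TSV
  reader its 0-based half-open offsets at the boundary. CoNLL-U token ids
  are 1-based already.
- **Overlapping entity spans** keep the longest span; contained spans are
  dropped with a warning.
- **Exhaustive annotation.** For corpora annotated exhaustively
  (AIMed-style), unannotated candidate pairs are materialized as gold
  negative (`exhaustive = TRUE`, the reader default); for other dialects
  they stay unlabeled.

## The synthetic generator

`generate_corpus(synth_config(...))` emulates the *statistical structure*
that the per-relation methodology depends on, using template sentences
with hand-templated dependency trees: per-relation instance
multiplicities (exact when given as vectors, otherwise sampled to match
the benchmark corpus profile — about 21% of relations positive, positive
relations averaging 1.6 positive and 1.5 negative instances, negative
relations about 1.7 instances), a rule mix for realizing positives,
negated variants of the rule 1–6 templates (`negation_rate`), and
keyword-free distractor co-occurrences (`distractor_rate`). Template
vocabulary is restricted to the rules' own example phrasing plus neutral
filler, so no accidental keyword hits occur; the gold label always equals
the template intent. Generation is byte-identical for equal seeds.

What the generator does **not** emulate: lexical diversity, parser error
distributions, annotation noise, cross-sentence phenomena. Passing tests
on synthetic corpora therefore demonstrate that the implementation is
faithful to its specification — the rules fire exactly on their
constructions, negation dominates, metrics and strata are computed
correctly — not that the measured precision/recall transfer to real
corpora. Real-corpus figures require the external benchmark corpus and
are represented here only by the shipped confusion counts, from which the
published precision/recall/F are recomputed arithmetically.

## Problem sizes and numerics

The test suite and acceptance script run on synthetic corpora of 20–60
relations (roughly 40–130 instances), sizes at which every property is
checked exhaustively against brute-force oracles in seconds. All
randomness flows through explicit seeds; the shipped classifiers are
fully deterministic, and any stochastic plug-in tier must accept a seed
through the classifier contract. Degenerate inputs are pinned by tests:
empty corpora, sentences with fewer than two mentions, instances without
parses, empty chains (a protein at the tree root), zero-TP metric
conventions, and the k = 1 identity of MIpR filtering.

## Known limitations

- The clause-splitting heuristic is a stand-in; real multi-clause
  biomedical prose is messier than the patterns it recognizes.
- Rule 6's non-copular analysis accepts any verb with the cue noun as
  complement; genuinely modal or hypothetical contexts ("may be a
  receptor for") are not distinguished.
- Negation handling recognizes `neg` dependencies only; downward-entailing
  environments without an explicit negator ("fails to bind") are out of
  scope, as are interaction directionality and interaction-type
  prediction (categories are reported, not predicted).
- The CoNLL-U reader ignores multiword-token ranges and the enhanced
  dependency column; collapsing is recomputed locally so that its
  behavior is identical for all parser frontends.
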