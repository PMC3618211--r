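# Shared helpers: tiny sentences/corpora built in code at test time.

# A two-mention sentence from explicit surfaces (offsets computed here so
# individual tests stay readable).
two_protein_sentence <- function(id, text, s1, s2, label = "positive",
                                 extra_pairs = NULL) {
  find_span <- function(surf, from = 1L) {
    p <- regexpr(surf, substr(text, from, nchar(text)), fixed = TRUE)
    c(from + as.integer(p) - 1L, from + as.integer(p) + nchar(surf) - 2L)
  }
  sp1 <- find_span(s1)
  sp2 <- find_span(s2, from = sp1[2] + 1L)
  mentions <- data.frame(mention_id = c("m1", "m2"),
                         start = c(sp1[1], sp2[1]), end = c(sp1[2], sp2[2]),
                         stringsAsFactors = FALSE)
  gp <- data.frame(e1 = "m1", e2 = "m2", label = label,
                   stringsAsFactors = FALSE)
  annotated_sentence(id, text, mentions, gp)
}

# Independent brute-force confusion-matrix oracle over joined labels.
oracle_counts <- function(gold_labels, pred_labels) {
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_along(gold_labels)) {
    if (pred_labels[i] == "positive" && gold_labels[i] == "positive") tp <- tp + 1L
    if (pred_labels[i] == "positive" && gold_labels[i] == "negative") fp <- fp + 1L
    if (pred_labels[i] == "negative" && gold_labels[i] == "positive") fn <- fn + 1L
  }
  list(tp = tp, fp = fp, fn = fn)
}

# small deterministic synthetic corpus shared by several test files
synth_small <- function(seed = 11L, ...) {
  generate_corpus(synth_config(n_relations = 25L, seed = seed, ...))
}
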