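test_that("PPI-XML reading resolves offsets, pairs and the candidate flag", {
  xml <- paste0(
    '<corpus><document id="d1">',
    '<sentence id="s1" text="IL-6 binds gp130">',
    '<entity id="e1" charOffset="0-3" text="IL-6"/>',
    '<entity id="e2" charOffset="11-15" text="gp130"/>',
    '<pair id="p1" e1="e1" e2="e2" interaction="True"/>',
    "</sentence>",
    '<sentence id="s2" text="gp130 was expressed">',
    '<entity id="e3" charOffset="0-4" text="gp130"/>',
    "</sentence>",
    "</document></corpus>")
  co <- read_ppi_corpus(xml)
  expect_length(co, 2L)
  s1 <- co[[1]]
  expect_equal(s1$text, "PROTEIN0 binds PROTEIN1")
  expect_equal(s1$mentions$surface, c("IL-6", "gp130"))
  expect_equal(nrow(s1$gold_pairs), 1L)
  expect_equal(s1$gold_pairs$label, "positive")
  expect_true(s1$candidate)
  # sentences with fewer than two proteins are retained but non-candidate
  expect_false(co[[2]]$candidate)
  expect_equal(nrow(enumerate_candidates(co[[2]])), 0L)
})

test_that("exhaustive-annotation mode materializes unannotated pairs as negative", {
  xml <- paste0(
    '<corpus><document id="d1">',
    '<sentence id="s1" text="A binds B near C">',
    '<entity id="e1" charOffset="0-0" text="A"/>',
    '<entity id="e2" charOffset="8-8" text="B"/>',
    '<entity id="e3" charOffset="15-15" text="C"/>',
    '<pair id="p1" e1="e1" e2="e2" interaction="True"/>',
    "</sentence></document></corpus>")
  co <- read_ppi_corpus(xml, exhaustive = TRUE)
  expect_equal(nrow(co[[1]]$gold_pairs), 3L)
  expect_equal(sum(co[[1]]$gold_pairs$label == "negative"), 2L)
  co2 <- read_ppi_corpus(xml, exhaustive = FALSE)
  expect_equal(nrow(co2[[1]]$gold_pairs), 1L)
})

test_that("malformed XML and dangling pair references are rejected", {
  expect_error(read_ppi_corpus("<corpus><sentence></corpus>"),
               "malformed PPI-XML")
  bad <- paste0(
    '<corpus><document id="d1">',
    '<sentence id="s1" text="A binds B">',
    '<entity id="e1" charOffset="0-0" text="A"/>',
    '<pair id="p1" e1="e1" e2="eX" interaction="True"/>',
    "</sentence></document></corpus>")
  expect_error(read_ppi_corpus(bad), "corpus-integrity")
})

test_that("a generated 10-sentence corpus round-trips through XML and JSONL", {
  gen <- generate_corpus(synth_config(n_relations = 10L,
                                      rel_instances = rep(1L, 10L),
                                      rel_positives = rep(1L, 10L),
                                      seed = 42L))
  expect_length(gen$corpus, 10L)
  for (writer in c("xml", "jsonl")) {
    tf <- tempfile(fileext = paste0(".", writer))
    if (writer == "xml") {
      write_ppi_corpus(gen$corpus, tf)
      back <- read_ppi_corpus(tf)
    } else {
      write_sentences_jsonl(gen$corpus, tf)
      back <- read_sentences_jsonl(tf)
    }
    expect_length(back, length(gen$corpus))
    for (i in seq_along(back)) {
      a <- gen$corpus[[i]]; b <- back[[i]]
      expect_equal(b$sentence_id, a$sentence_id)
      expect_equal(b$text, a$text)
      cols <- c("mention_id", "start", "end", "surface", "mask_label",
                "entity_key")
      expect_equal(b$mentions[cols], a$mentions[cols])
      expect_equal(b$gold_pairs, a$gold_pairs)
    }
  }
})

test_that("masking assigns placeholders in appearance order and is invertible", {
  m <- mask_proteins("IL-6 binds gp130",
                     data.frame(mention_id = c("m1", "m2"),
                                start = c(1, 12), end = c(4, 16)))
  expect_equal(m$text, "PROTEIN0 binds PROTEIN1")
  expect_equal(m$mentions$mask_label, c("PROTEIN0", "PROTEIN1"))
  expect_equal(unmask_proteins(m$text, m$mentions), "IL-6 binds gp130")

  # the rule-7 naming pattern keeps both names distinct
  m2 <- mask_proteins("erythropoietin receptor (EPOR)",
                      data.frame(mention_id = c("m1", "m2"),
                                 start = c(1, 26), end = c(14, 29)))
  expect_equal(m2$text, "PROTEIN0 receptor (PROTEIN1)")

  # identical surfaces at different positions get distinct labels
  m3 <- mask_proteins("RAS activates RAS",
                      data.frame(mention_id = c("m1", "m2"),
                                 start = c(1, 15), end = c(3, 17)))
  expect_equal(m3$mentions$mask_label, c("PROTEIN0", "PROTEIN1"))
  expect_equal(m3$mentions$entity_key, c("ras", "ras"))
  expect_equal(unmask_proteins(m3$text, m3$mentions), "RAS activates RAS")

  # nested span resolution: longest kept, contained dropped with a warning
  expect_warning(
    m4 <- mask_proteins("interleukin 6 receptor binds X",
                        data.frame(mention_id = c("m1", "m2", "m3"),
                                   start = c(1, 1, 30), end = c(22, 13, 30))),
    "contained")
  expect_equal(nrow(m4$mentions), 2L)
  expect_equal(m4$mentions$surface[1], "interleukin 6 receptor")
})

test_that("parenthetical stripping deletes exactly the protein-free regions", {
  # the four flat/nested x protein/no-protein cases, oracle by hand
  expect_equal(strip_parentheticals("PROTEIN0 (p53) binds PROTEIN1"),
               "PROTEIN0 binds PROTEIN1")
  expect_equal(strip_parentheticals("PROTEIN0 receptor (PROTEIN1)"),
               "PROTEIN0 receptor (PROTEIN1)")
  expect_equal(
    strip_parentheticals("PROTEIN0 (see (PROTEIN1) above) binds X"),
    "PROTEIN0 (see (PROTEIN1) above) binds X")
  expect_equal(
    strip_parentheticals("PROTEIN0 (see (figure 1) above) binds PROTEIN1"),
    "PROTEIN0 binds PROTEIN1")
  # unbalanced parentheses are literal
  expect_equal(strip_parentheticals("PROTEIN0 ( binds PROTEIN1"),
               "PROTEIN0 ( binds PROTEIN1")
  # sentence-level variant recomputes offsets and never loses a mention
  s <- annotated_sentence(
    "t", "p53 (the tumor suppressor) binds mdm2",
    data.frame(mention_id = c("m1", "m2"), start = c(1, 34), end = c(3, 37)))
  s2 <- strip_parentheticals(s)
  expect_equal(s2$text, "PROTEIN0 binds PROTEIN1")
  expect_equal(s2$tokens[s2$mentions$token_index], c("PROTEIN0", "PROTEIN1"))
})

test_that("clause splitting reassigns mentions and reports straddling pairs", {
  s <- annotated_sentence(
    "t3", "AKT binds PDK1 , and RAF inhibits MEK",
    data.frame(mention_id = paste0("m", 1:4),
               start = c(1, 11, 22, 35), end = c(3, 14, 24, 37)),
    data.frame(e1 = c("m1", "m2"), e2 = c("m2", "m3"),
               label = c("positive", "negative")))
  cl <- split_clauses(s)
  expect_length(cl, 2L)
  expect_equal(cl[[1]]$text, "PROTEIN0 binds PROTEIN1")
  expect_equal(cl[[2]]$text, "PROTEIN0 inhibits PROTEIN1")
  # token conservation: no clause token outside the original sentence
  all_tokens <- c(cl[[1]]$tokens, cl[[2]]$tokens)
  expect_equal(sum(grepl("^PROTEIN", all_tokens)), 4L)
  expect_equal(cl[[1]]$gold_pairs$label, "positive")
  strad <- attr(cl, "straddlers")
  expect_equal(nrow(strad), 1L)
  expect_equal(sort(c(strad$e1, strad$e2)), c("m2", "m3"))
  # single-clause sentence: identity
  s1 <- two_protein_sentence("t4", "AKT binds PDK1", "AKT", "PDK1")
  expect_length(split_clauses(s1), 1L)
  expect_identical(split_clauses(s1)[[1]], s1)
  expect_length(split_clauses(s, enabled = FALSE), 1L)
})

test_that("candidate enumeration returns all n(n-1)/2 pairs with span counts", {
  words <- c("A1", "binds", "B2", "near", "C3", "and", "D4", "plus", "E5")
  s <- fixture_sentence("t5", words, c(1, 3, 5, 7, 9))
  cand <- enumerate_candidates(s)
  expect_equal(nrow(cand), choose(5, 2))
  # brute-force oracle over token positions
  pos <- c(1, 3, 5, 7, 9)
  k <- 0L
  for (i in 1:4) for (j in (i + 1):5) {
    k <- k + 1L
    row <- cand[cand$t1 == pos[i] & cand$t2 == pos[j], ]
    expect_equal(nrow(row), 1L)
    expect_equal(row$span_tokens, pos[j] - pos[i] + 1L)
  }
  expect_equal(k, nrow(cand))
  # 3 mentions -> 3 pairs
  s3 <- fixture_sentence("t6", c("A1", "binds", "B2", "and", "C3"), c(1, 3, 5))
  expect_equal(nrow(enumerate_candidates(s3)), 3L)
  # co-referent mentions are emitted but flagged
  s4 <- annotated_sentence(
    "t7", "RAS activates RAS",
    data.frame(mention_id = c("m1", "m2"), start = c(1, 15), end = c(3, 17)))
  expect_true(enumerate_candidates(s4)$self_relation)
})
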