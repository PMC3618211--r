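figure1_tree <- function() {
  s <- fixture_sentence("f1", c("IL6", "directly", "interacts", "with",
                                "GPA", "and", "GPB"), c(1, 5, 7))
  fixture_tree(s, list(c(0, 3, "root"), c(3, 1, "nsubj"), c(3, 2, "advmod"),
                       c(3, 5, "prep_with"), c(5, 4, "case"), c(5, 6, "cc"),
                       c(5, 7, "conj_and")),
               upos = c("3" = "VERB", "2" = "ADV"))
}

test_that("CoNLL-U blocks parse into trees with labeled edges and a root", {
  lines <- c(
    "# sent_id = x1",
    "1\tPROTEIN0\tprotein0\tPROPN\t_\t_\t2\tnsubj\t_\t_",
    "2\tbinds\tbind\tVERB\t_\t_\t0\troot\t_\t_",
    "3\tPROTEIN1\tprotein1\tPROPN\t_\t_\t2\tdobj\t_\t_",
    "4\t.\t.\tPUNCT\t_\t_\t2\tpunct\t_\t_",
    "")
  trees <- read_conllu(paste(lines, collapse = "\n"))
  expect_named(trees, "x1")
  tr <- trees$x1
  expect_equal(tr$root, 2L)
  expect_equal(sort(tr$edges$label), sort(c("nsubj", "root", "dobj", "punct")))
  expect_equal(tr$tokens$lemma[2], "bind")
})

test_that("UD labels are preserved verbatim until collapsing", {
  lines <- c(
    "# sent_id = x2",
    "1\tPROTEIN0\tprotein0\tPROPN\t_\t_\t2\tnsubj\t_\t_",
    "2\tinteracts\tinteract\tVERB\t_\t_\t0\troot\t_\t_",
    "3\twith\twith\tADP\t_\t_\t4\tcase\t_\t_",
    "4\tPROTEIN1\tprotein1\tPROPN\t_\t_\t2\tnmod\t_\t_",
    "")
  tr <- read_conllu(paste(lines, collapse = "\n"))$x2
  expect_true("nmod" %in% tr$edges$label)
  col <- collapse_ud(tr)
  expect_true("prep_with" %in% col$edges$label)
  expect_false("nmod" %in% col$edges$label)
})

test_that("fixture trees round-trip through CoNLL-U", {
  wx <- worked_examples()
  with_trees <- Filter(function(c) !is.null(c$tree), wx)
  trees <- lapply(with_trees, `[[`, "tree")
  names(trees) <- vapply(trees, `[[`, "", "sentence_id")
  tf <- tempfile(fileext = ".conllu")
  write_conllu(trees, tf)
  back <- read_conllu(tf)
  expect_length(back, length(trees))
  for (id in names(trees)) {
    a <- trees[[id]]$edges[order(trees[[id]]$edges$dependent), ]
    b <- back[[id]]$edges[order(back[[id]]$edges$dependent), ]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(b, a, label = id)
    expect_equal(back[[id]]$tokens$text, trees[[id]]$tokens$text)
  }
})

test_that("token-count mismatch against the masked sentence is an alignment error", {
  s <- two_protein_sentence("s9", "AKT binds PDK1", "AKT", "PDK1")
  corpus <- structure(list(s), class = "ppi_corpus")
  lines <- c("# sent_id = s9",
             "1\tPROTEIN0\t_\tPROPN\t_\t_\t2\tnsubj\t_\t_",
             "2\tbinds\t_\tVERB\t_\t_\t0\troot\t_\t_",
             "")
  expect_error(read_conllu(paste(lines, collapse = "\n"), corpus),
               "alignment error")
})

test_that("collapsing handles conj propagation, neg mapping, and is idempotent", {
  # UD-style conj + cc with the preposition attached by case
  lines <- c(
    "# sent_id = x3",
    "1\tPROTEIN0\t_\tPROPN\t_\t_\t2\tnsubj\t_\t_",
    "2\tinteracts\tinteract\tVERB\t_\t_\t0\troot\t_\t_",
    "3\twith\t_\tADP\t_\t_\t4\tcase\t_\t_",
    "4\tPROTEIN1\t_\tPROPN\t_\t_\t2\tnmod\t_\t_",
    "5\tand\t_\tCCONJ\t_\t_\t6\tcc\t_\t_",
    "6\tPROTEIN2\t_\tPROPN\t_\t_\t4\tconj\t_\t_",
    "")
  col <- collapse_ud(read_conllu(paste(lines, collapse = "\n"))$x3)
  expect_true(any(col$edges$label == "conj_and"))
  # the second conjunct is reachable from the verb via the propagated edge
  prop <- col$edges[col$edges$propagated, ]
  expect_true(any(prop$head == 2L & prop$dependent == 6L &
                    prop$label == "prep_with"))
  expect_equal(dependents(col, 2L, "prep_*"), c(4L, 6L))
  # det "no" and advmod "not" become neg
  s <- fixture_sentence("x4", c("no", "ITRA", "binds", "ITRB"), c(2, 4))
  tr <- fixture_tree(s, list(c(0, 3, "root"), c(3, 2, "nsubj"),
                             c(2, 1, "det"), c(3, 4, "dobj")),
                     upos = c("3" = "VERB"))
  col2 <- collapse_ud(tr)
  expect_true(has_negation(col2, 2L))
  # idempotence on every fixture tree
  for (case in worked_examples()) {
    if (is.null(case$tree)) next
    once <- collapse_ud(case$tree)
    twice <- collapse_ud(once)
    expect_equal(twice$edges, once$edges, label = case$name)
  }
})

test_that("dependents answers the queries the rules are written in", {
  tr <- collapse_ud(figure1_tree())
  expect_equal(dependents(tr, 3L, "nsubj"), 1L)
  expect_equal(dependents(tr, 3L, "prep_*"), c(5L, 7L))
  expect_equal(dependents(tr, 3L, ""), integer(0))
  # prep_* of a relation noun reaches both proteins ("binding of A to B")
  s <- fixture_sentence("b1", c("binding", "of", "BRA", "to", "BRB"),
                        c(3, 5))
  tb <- fixture_tree(s, list(c(0, 1, "root"), c(1, 3, "prep_of"),
                             c(3, 2, "case"), c(1, 5, "prep_to"),
                             c(5, 4, "case")))
  expect_equal(dependents(tb, 1L, "prep_*"), c(3L, 5L))
  expect_equal(dependents(tb, 1L, "prep_of"), 3L)
})

test_that("negation detection covers verb, noun-determiner and ancestor-verb scopes", {
  wx <- worked_examples()
  tr <- collapse_ud(wx$rule1_neg_verb$tree)
  expect_true(has_negation(tr, 4L))       # "bind" carries neg
  expect_false(has_negation(tr, 1L))
  tr2 <- collapse_ud(wx$rule2_neg_noun$tree)
  expect_true(has_negation(tr2, 2L))      # det "no" on "interaction"
  tr3 <- collapse_ud(figure1_tree())
  expect_false(has_negation(tr3, 3L))
})

test_that("dependency-bearing word counts match hand-labeled fixtures", {
  tr <- collapse_ud(figure1_tree())
  s <- fixture_sentence("f1", c("IL6", "directly", "interacts", "with",
                                "GPA", "and", "GPB"), c(1, 5, 7))
  # P0..P2: "directly", "interacts", "GPA" count; "with"/"and" do not
  expect_equal(intervening_dep_words(s, tr, 1L, 7L), 3L)
  # P0..P1: "directly", "interacts"
  expect_equal(intervening_dep_words(s, tr, 1L, 5L), 2L)
  # P1..P2: only "and" in between, which does not count
  expect_equal(intervening_dep_words(s, tr, 5L, 7L), 0L)
  # adjacent pair
  expect_equal(intervening_dep_words(s, tr, 6L, 7L), 0L)
  # hand-labeled counts across the dependency fixtures
  wx <- worked_examples()
  hand <- list(
    # does, not, bind count; "to" excluded
    list(case = "rule1_neg_verb", t1 = 1L, t2 = 6L, n = 3L),
    # only "to" in between (case-marking, excluded)
    list(case = "rule2_binding_of_to", t1 = 3L, t2 = 5L, n = 0L),
    list(case = "rule2_neg_noun", t1 = 4L, t2 = 6L, n = 0L),
    list(case = "rule3_between", t1 = 4L, t2 = 6L, n = 0L),
    # "STAT3", "activate" count; "and" excluded
    list(case = "rule4_reject_dobj", t1 = 1L, t2 = 5L, n = 2L),
    # "is", "receptor" count; "a", "for" excluded
    list(case = "rule6_receptor_for", t1 = 1L, t2 = 6L, n = 2L)
  )
  for (h in hand) {
    case <- wx[[h$case]]
    tr <- collapse_ud(case$tree)
    expect_equal(intervening_dep_words(case$sentence, tr, h$t1, h$t2), h$n,
                 label = h$case)
  }
})

test_that("intervening count never exceeds span minus two", {
  gen <- synth_small()
  for (s in gen$corpus) {
    tr <- collapse_ud(gen$trees[[s$sentence_id]])
    cand <- enumerate_candidates(s)
    for (i in seq_len(nrow(cand))) {
      expect_lte(intervening_dep_words(s, tr, cand$t1[i], cand$t2[i]),
                 cand$span_tokens[i] - 2L)
    }
  }
})

test_that("collapsed fixture trees use only the dialect's label inventory", {
  inventory <- c("root", "nsubj", "nsubjpass", "dobj", "neg", "aux",
                 "auxpass", "cop", "det", "cc", "case", "punct", "advmod",
                 "amod", "nn", "appos")
  for (case in worked_examples()) {
    if (is.null(case$tree)) next
    labs <- collapse_ud(case$tree)$edges$label
    free <- labs[!grepl("^(prep_|conj_)", labs)]
    expect_true(all(free %in% inventory), label = case$name)
  }
})

test_that("root-to-token paths are unique, ordered and empty at the root", {
  tr <- collapse_ud(figure1_tree())
  p0 <- tree_path(tr, 1L)
  expect_equal(p0$label, "nsubj")
  expect_equal(p0$lemma, "protein0")  # lemmas come from the masked tokens
  expect_equal(nrow(tree_path(tr, 3L)), 0L)  # the root itself
  p2 <- tree_path(tr, 7L)
  expect_equal(p2$label, c("prep_with", "conj_and"))
  # exactly one path per token (tree property): path exists and terminates
  for (i in seq_len(nrow(tr$tokens))) {
    expect_true(is.data.frame(tree_path(tr, i)))
  }
})

test_that("the shipped six-tree CoNLL-U fixture parses and matches the code fixtures", {
  path <- system.file("extdata", "worked_trees.conllu", package = "ppirules")
  trees <- read_conllu(path)
  expect_length(trees, 6L)
  wx <- worked_examples()
  for (id in names(trees)) {
    name <- sub("^wx\\.", "", id)
    ref <- wx[[name]]$tree
    expect_equal(trees[[id]]$tokens$text, ref$tokens$text, label = id)
    a <- ref$edges[order(ref$edges$dependent), ]
    b <- trees[[id]]$edges[order(trees[[id]]$edges$dependent), ]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(b, a, label = id)
  }
})
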