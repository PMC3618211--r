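test_that("pipelining preserves tier-1 positives and forms the union of positives", {
  gen <- synth_small(seed = 61L, negation_rate = 0.2, distractor_rate = 0.3)
  inst <- gen$gold[, c("sentence_id", "e1", "e2")]
  rules <- rules_classifier(gen$corpus, gen$trees)
  # identity element: an always-negative tier 2 leaves tier 1 unchanged
  out0 <- pipeline(rules, always_negative_classifier(), inst)
  expect_equal(out0$label, predict_classifier(rules, inst))
  expect_true(all(is.na(out0$tier) | out0$tier == 1L))

  # a degraded-label external tier: union semantics vs brute force
  ext_preds <- perfect_and_degraded_predictions(gen$gold, flip_pos = 0.5,
                                                flip_neg = 0.05, seed = 9L)
  ext <- fixed_labels_classifier(ext_preds)
  out <- pipeline(rules, ext, inst)
  p_rules <- predict_classifier(rules, inst)
  p_ext <- predict_classifier(ext, inst)
  expect_equal(out$label == "positive",
               p_rules == "positive" | p_ext == "positive")
  # positive-preservation and monotone counts
  expect_true(all(out$label[p_rules == "positive"] == "positive"))
  gold <- gen$gold$gold
  tier1 <- oracle_counts(gold, p_rules)
  both <- oracle_counts(gold, out$label)
  expect_gte(both$tp, tier1$tp)
  expect_gte(both$fp, tier1$fp)
  # provenance: tier 2 fires exactly on tier-1 rejections it flips
  expect_true(all(out$tier[out$label == "positive" &
                             p_rules == "negative"] == 2L))
})

test_that("disjoint fixed tiers yield the sum of their positives", {
  inst <- data.frame(sentence_id = paste0("s", 1:10), e1 = "m1", e2 = "m2",
                     stringsAsFactors = FALSE)
  mk <- function(pos_idx) {
    data.frame(sentence_id = inst$sentence_id, e1 = "m1", e2 = "m2",
               label = ifelse(seq_len(10) %in% pos_idx, "positive",
                              "negative"), stringsAsFactors = FALSE)
  }
  t1 <- fixed_labels_classifier(mk(1:3), "a")
  t2 <- fixed_labels_classifier(mk(4:7), "b")
  out <- pipeline(t1, t2, inst)
  expect_equal(sum(out$label == "positive"), 7L)
  expect_equal(out$tier[1:3], rep(1L, 3))
  expect_equal(out$tier[4:7], rep(2L, 3 + 1))
  # swapping the tiers keeps the union but changes provenance
  out2 <- pipeline(t2, t1, inst)
  expect_equal(out2$label, out$label)
  expect_false(identical(out2$tier, out$tier))
})

test_that("dependency chains and their bigrams follow the tree structure", {
  gen <- synth_small(seed = 71L)
  s <- gen$corpus[[1]]
  tree <- collapse_ud(gen$trees[[s$sentence_id]])
  cand <- enumerate_candidates(s)
  ch <- extract_chains(tree, cand[1, ])
  expect_true(all(c("label", "lemma") %in% names(ch$forward)))
  # chain length equals the number of edges from root to the protein
  expect_equal(nrow(ch$forward), nrow(tree_path(tree, cand$t1[1])))
  # bigram counts: length-n chain has max(n-1, 0) bigrams
  for (n in c(0L, 1L, 2L, 3L, 5L)) {
    chain <- data.frame(label = rep("nsubj", n), lemma = rep("w", n),
                        stringsAsFactors = FALSE)
    expect_length(chain_bigrams(chain), max(n - 1L, 0L))
  }
  chain <- data.frame(label = c("prep_of", "conj_and", "nsubj"),
                      lemma = c("binding", "x", "y"))
  expect_equal(chain_bigrams(chain),
               c("prep_of/binding conj_and/x", "conj_and/x nsubj/y"))
  expect_equal(chain_bigrams(chain, render = "label"),
               c("prep_of conj_and", "conj_and nsubj"))
})

test_that("top-feature selection ranks by count difference with deterministic ties", {
  mk_cf <- function(fwd, bwd) {
    df <- data.frame(sentence_id = paste0("s", seq_along(fwd)), e1 = "m1",
                     e2 = "m2", fwd_len = 1L, bwd_len = 1L, offset = 1L,
                     stringsAsFactors = FALSE)
    df$forward_bigrams <- fwd
    df$backward_bigrams <- bwd
    df
  }
  # bigram "A": 5 forward, 1 backward -> score 4, ranks above "B" (3, 0)
  cf <- mk_cf(
    fwd = c(replicate(5, "A", simplify = FALSE),
            replicate(3, "B", simplify = FALSE)),
    bwd = c(list("A"), replicate(7, character(0), simplify = FALSE)))
  spec <- select_top_features(cf, n = 10)
  expect_equal(spec$top_forward, c("A", "B"))
  # all-equal counts: scores 0, tie broken by raw count then lexicographic
  cf2 <- mk_cf(fwd = list(c("z", "a"), "a"), bwd = list(c("z", "a"), "a"))
  spec2 <- select_top_features(cf2, n = 10)
  expect_equal(spec2$top_forward, c("a", "z"))
  # permutation invariance + brute-force oracle on a larger random corpus
  set.seed(23)
  grams <- sprintf("g%03d", 1:200)
  fwd <- replicate(120, sample(grams, sample(1:6, 1)), simplify = FALSE)
  bwd <- replicate(120, sample(grams, sample(1:6, 1)), simplify = FALSE)
  cf3 <- mk_cf(fwd, bwd)
  spec3 <- select_top_features(cf3, n = 100)
  perm <- sample(120)
  spec3p <- select_top_features(cf3[perm, ], n = 100)
  expect_equal(spec3p$top_forward, spec3$top_forward)
  expect_equal(spec3p$top_backward, spec3$top_backward)
  # oracle: explicit score table sort
  ftab <- table(unlist(fwd)); btab <- table(unlist(bwd))
  all_f <- names(ftab)
  score <- vapply(all_f, function(g) {
    as.integer(ftab[[g]]) -
      (if (g %in% names(btab)) as.integer(btab[[g]]) else 0L)
  }, integer(1))
  raw <- as.integer(ftab[all_f])
  oracle <- all_f[order(-score, -raw, all_f, method = "radix")][1:100]
  expect_equal(spec3$top_forward, oracle)
})

test_that("featurization has fixed dimension and correct indicators", {
  gen <- synth_small(seed = 81L)
  cf <- build_chain_features(gen$corpus, gen$trees)
  for (opts in list(c(FALSE, FALSE), c(TRUE, FALSE), c(FALSE, TRUE),
                    c(TRUE, TRUE))) {
    spec <- select_top_features(cf, n = 20, use_dep_lengths = opts[1],
                                use_offset_distance = opts[2])
    m <- featurize(cf, spec)
    expect_equal(ncol(m), length(spec$top_forward) +
                   length(spec$top_backward) + 2L * opts[1] + opts[2])
    expect_equal(nrow(m), nrow(cf))
  }
  # single-indicator instance
  spec1 <- structure(list(top_forward = "only/bigram x/y",
                          top_backward = character(0),
                          use_dep_lengths = FALSE,
                          use_offset_distance = FALSE),
                     class = "feature_spec")
  cf1 <- cf[1, ]
  cf1$forward_bigrams <- list("only/bigram x/y")
  cf1$backward_bigrams <- list(character(0))
  expect_equal(as.numeric(featurize(cf1, spec1)), 1)
  # adjacent proteins have offset distance 1
  adj <- cf[cf$offset == 1, ]
  if (nrow(adj) == 0) succeed() else expect_true(all(adj$offset == 1))
  # JSON round-trip of the spec
  spec <- select_top_features(cf, n = 5, use_dep_lengths = TRUE)
  tf <- tempfile(fileext = ".json")
  write_feature_spec(spec, tf)
  expect_equal(read_feature_spec(tf), spec)
})

test_that("the reference threshold classifier fits the F-optimal threshold", {
  feats <- matrix(c(3, 2, 2, 1, 0, 0), ncol = 1)
  labels <- c("positive", "positive", "positive", "negative", "negative",
              "negative")
  inst <- data.frame(sentence_id = paste0("s", 1:6), e1 = "m1", e2 = "m2",
                     stringsAsFactors = FALSE)
  featurizer <- function(instances) {
    feats[match(instances$sentence_id, inst$sentence_id), , drop = FALSE]
  }
  clf <- fit_classifier(reference_classifier(featurizer), inst, labels)
  # exhaustive search oracle
  best <- -1; best_thr <- NULL
  for (thr in 0:4) {
    pred <- feats[, 1] >= thr
    tp <- sum(pred & labels == "positive")
    fp <- sum(pred & labels == "negative")
    fn <- sum(!pred & labels == "positive")
    f <- if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    if (f > best + 1e-12) { best <- f; best_thr <- thr }
  }
  expect_equal(clf$state$threshold, best_thr)
  expect_equal(predict_classifier(clf, inst),
               ifelse(feats[, 1] >= best_thr, "positive", "negative"))
})
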