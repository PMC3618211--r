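# The eight-rule PPI classifier. A candidate pair is tested against the
# rules in ascending order and the first match wins (so rule order can only
# change the reported rule id, never the positive/negative decision, which
# is the OR over all rules). Rules 1-4 and 6 are dependency patterns over
# the collapsed dialect; rules 5, 7 and 8 are surface-lexical and run even
# when no parse is available.

#' Rule-engine configuration
#'
#' @param window_tokens Maximum surface span (token count from the first to
#'   the second protein, both inclusive) for the dependency rules 1-4 and
#'   the lexical rule 8. Default 7 (the seven-word window).
#' @param max_dep_words Maximum number of dependency-bearing words allowed
#'   between the two proteins for rules 1-4 (see
#'   [intervening_dep_words()]). Default 3.
#' @param rule4_form_requires_complex Rule 4 accepts the keyword "form"
#'   only when its direct object is "complex". Default \code{TRUE}.
#' @param enabled_rules Integer subset of 1:8.
#' @param rule2_preps Whitelist of prepositions accepted in rule 2's second
#'   slot; \code{rule2_wildcard = TRUE} accepts any \code{prep_X} with
#'   X != "of".
#' @param rule2_wildcard See above.
#' @param rule6_copula_only Restrict rule 6 to the copular analysis
#'   ("P0 is a receptor for P1"); default \code{FALSE} (any verb).
#' @param split_clauses Whether preprocessing splits multi-clause sentences.
#' @return List of class \code{rule_config}.
#' @export
rule_config <- function(window_tokens = 7L, max_dep_words = 3L,
                        rule4_form_requires_complex = TRUE,
                        enabled_rules = 1:8,
                        rule2_preps = c("to", "by", "with", "on", "for"),
                        rule2_wildcard = FALSE,
                        rule6_copula_only = FALSE,
                        split_clauses = TRUE) {
  stopifnot(window_tokens >= 2L, max_dep_words >= 0L,
            all(enabled_rules %in% 1:8))
  structure(list(window_tokens = as.integer(window_tokens),
                 max_dep_words = as.integer(max_dep_words),
                 rule4_form_requires_complex = rule4_form_requires_complex,
                 enabled_rules = sort(unique(as.integer(enabled_rules))),
                 rule2_preps = rule2_preps,
                 rule2_wildcard = rule2_wildcard,
                 rule6_copula_only = rule6_copula_only,
                 split_clauses = split_clauses),
            class = "rule_config")
}

match_result <- function(matched, rule_id = NA_integer_, trigger = NA_character_,
                         negated = FALSE, trace = character(0)) {
  stopifnot(!matched || (!is.na(rule_id) && !negated))
  structure(list(matched = matched, rule_id = rule_id, trigger = trigger,
                 negated = negated, trace = trace),
            class = "ppi_match")
}

#' @export
print.ppi_match <- function(x, ...) {
  if (x$matched) {
    cat("<ppi_match> positive (rule ", x$rule_id, ", trigger '", x$trigger,
        "')\n", sep = "")
  } else {
    cat("<ppi_match> negative",
        if (x$negated) " (pattern found but negated)", "\n", sep = "")
  }
  invisible(x)
}

# Keyword tokens of a tree (index, base lemma, category).
keyword_matches <- function(tree, lexicon) {
  hits <- lapply(seq_len(nrow(tree$tokens)), function(i) {
    km <- match_keyword(tree$tokens$text[i], tree$tokens$lemma[i], lexicon)
    if (is.null(km)) NULL else data.frame(index = i, lemma = km$lemma,
                                          category = km$category,
                                          stringsAsFactors = FALSE)
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (!length(hits)) {
    return(data.frame(index = integer(0), lemma = character(0),
                      category = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

# Shared window + dependency-word gate for the dependency rules.
window_ok <- function(pair, sentence, tree, config) {
  if (pair$span_tokens > config$window_tokens) return(FALSE)
  intervening_dep_words(sentence, tree, pair$t1, pair$t2) <= config$max_dep_words
}

#' Rule 1: subject - relation verb - object/prepositional object
#'
#' Matches when one protein is the nominal subject of a relation-keyword
#' verb and the other is its direct object or prepositional modifier
#' (conjunction-propagated edges count). Vetoed by a \code{neg} dependency
#' on the verb or the subject, and by the seven-word window /
#' three-dependency-word constraints.
#'
#' @param pair One row of [enumerate_candidates()].
#' @param sentence The \code{ppi_sentence}.
#' @param tree Aligned collapsed \code{dep_tree}.
#' @param config A [rule_config()].
#' @param lexicon A [load_default_lexicon()] lexicon.
#' @return A \code{ppi_match}.
#' @export
rule1 <- function(pair, sentence, tree, config, lexicon = load_default_lexicon()) {
  kw <- keyword_matches(tree, lexicon)
  prot <- c(pair$t1, pair$t2)
  negated <- FALSE
  for (i in seq_len(nrow(kw))) {
    v <- kw$index[i]
    subj <- intersect(dependents(tree, v, "nsubj"), prot)
    obj <- intersect(c(dependents(tree, v, "dobj"),
                       dependents(tree, v, "prep_*")), prot)
    for (s in subj) {
      o <- setdiff(obj, s)
      if (!length(o)) next
      if (has_negation(tree, v) || has_negation(tree, s)) {
        negated <- TRUE
        next
      }
      if (!window_ok(pair, sentence, tree, config)) next
      return(match_result(TRUE, 1L, kw$lemma[i],
                          trace = c(sprintf("nsubj(%s)=%s", kw$lemma[i],
                                            tree$tokens$text[s]),
                                    sprintf("obj(%s)=%s", kw$lemma[i],
                                            tree$tokens$text[o[1]]))))
    }
  }
  match_result(FALSE, negated = negated)
}

#' Rule 2: relation noun - of - first protein - preposition - second protein
#'
#' Matches "binding of P0 to P1"-type phrases: a keyword noun with a
#' \code{prep_of} edge to the earlier protein and a \code{prep_X} edge
#' (X in the configured whitelist) to the later one. Vetoed by negation on
#' the keyword noun or on its governing verb.
#' @inheritParams rule1
#' @return A \code{ppi_match}.
#' @export
rule2 <- function(pair, sentence, tree, config, lexicon = load_default_lexicon()) {
  kw <- keyword_matches(tree, lexicon)
  negated <- FALSE
  for (i in seq_len(nrow(kw))) {
    n <- kw$index[i]
    ofs <- dependents(tree, n, "prep_of")
    if (!(pair$t1 %in% ofs)) next
    others <- dependents(tree, n, "prep_*")
    others <- others[!(others %in% ofs)]
    if (!config$rule2_wildcard) {
      lab_ok <- vapply(others, function(d) {
        labs <- tree$edges$label[tree$edges$head == n & tree$edges$dependent == d]
        any(sub("^prep_", "", labs) %in% config$rule2_preps)
      }, logical(1))
      others <- others[lab_ok]
    }
    if (!(pair$t2 %in% others)) next
    if (negated_with_verb(tree, n)) {
      negated <- TRUE
      next
    }
    if (!window_ok(pair, sentence, tree, config)) next
    return(match_result(TRUE, 2L, kw$lemma[i],
                        trace = sprintf("prep_of+prep_X on '%s'", kw$lemma[i])))
  }
  match_result(FALSE, negated = negated)
}

#' Rule 3: relation noun - between/of - first protein - and - second protein
#'
#' Matches "interaction between P0 and P1": both proteins are reached from
#' a keyword noun via \code{prep_between}/\code{prep_of} (the second
#' typically through the propagated conjunct edge) or the second is the
#' \code{conj_and} conjunct of the first. Negation as rule 2.
#' @inheritParams rule1
#' @return A \code{ppi_match}.
#' @export
rule3 <- function(pair, sentence, tree, config, lexicon = load_default_lexicon()) {
  kw <- keyword_matches(tree, lexicon)
  negated <- FALSE
  for (i in seq_len(nrow(kw))) {
    n <- kw$index[i]
    reach <- c(dependents(tree, n, "prep_between"), dependents(tree, n, "prep_of"))
    if (!(pair$t1 %in% reach)) next
    second_ok <- pair$t2 %in% reach ||
      pair$t2 %in% dependents(tree, pair$t1, "conj_and")
    if (!second_ok) next
    if (negated_with_verb(tree, n)) {
      negated <- TRUE
      next
    }
    if (!window_ok(pair, sentence, tree, config)) next
    return(match_result(TRUE, 3L, kw$lemma[i],
                        trace = sprintf("prep_between/of on '%s'", kw$lemma[i])))
  }
  match_result(FALSE, negated = negated)
}

#' Rule 4: protein conjunction as subject of a relation verb
#'
#' Matches "P0 and P1 interact": the pair forms a \code{conj_and}
#' conjunction that is the nominal subject of a keyword verb. The match is
#' rejected when the verb participates in a \code{dobj} or \code{prep_*}
#' dependency (it then relates the subjects to something else), with one
#' exception: "form" is accepted iff its direct object is "complex".
#' Negation as rule 1.
#' @inheritParams rule1
#' @return A \code{ppi_match}.
#' @export
rule4 <- function(pair, sentence, tree, config, lexicon = load_default_lexicon()) {
  conj <- pair$t2 %in% dependents(tree, pair$t1, "conj_and") ||
    pair$t1 %in% dependents(tree, pair$t2, "conj_and")
  if (!conj) return(match_result(FALSE))
  kw <- keyword_matches(tree, lexicon)
  prot <- c(pair$t1, pair$t2)
  negated <- FALSE
  for (i in seq_len(nrow(kw))) {
    v <- kw$index[i]
    subj <- dependents(tree, v, "nsubj")
    if (!any(prot %in% subj)) next
    dobjs <- dependents(tree, v, "dobj", include_propagated = FALSE)
    preps <- dependents(tree, v, "prep_*", include_propagated = FALSE)
    involved <- length(dobjs) > 0L || length(preps) > 0L
    if (involved) {
      form_exception <- config$rule4_form_requires_complex &&
        kw$lemma[i] == "form" && length(preps) == 0L &&
        any(tree$tokens$lemma[dobjs] == "complex")
      if (!form_exception) next
    } else if (kw$lemma[i] == "form" && config$rule4_form_requires_complex) {
      next  # bare "form" without a "complex" object is not accepted
    }
    if (has_negation(tree, v) || any(vapply(intersect(prot, subj), function(s)
      has_negation(tree, s), logical(1)))) {
      negated <- TRUE
      next
    }
    if (!window_ok(pair, sentence, tree, config)) next
    return(match_result(TRUE, 4L, kw$lemma[i],
                        trace = sprintf("conj_and pair nsubj of '%s'",
                                        kw$lemma[i])))
  }
  match_result(FALSE, negated = negated)
}

rule5_nouns <- c("interaction", "complex", "heterodimer", "product", "assembly")

#' Rule 5: lexical "P0-P1 complex" / "P0/P1 heterodimer" pattern
#'
#' Pure token-sequence match: protein, separator ("-" or "/"), protein,
#' then a head noun in \{interaction, complex, heterodimer, product,
#' assembly\}. When a tree is available, a \code{neg} dependency on the
#' head noun or its governing verb vetoes the match.
#' @inheritParams rule1
#' @param tree Optional; \code{NULL} skips the negation check.
#' @return A \code{ppi_match}.
#' @export
rule5 <- function(pair, sentence, tree = NULL, config = rule_config(),
                  lexicon = NULL) {
  toks <- sentence$tokens
  if (pair$t2 - pair$t1 != 2L) return(match_result(FALSE))
  if (!(toks[pair$t1 + 1L] %in% c("-", "/"))) return(match_result(FALSE))
  head_idx <- pair$t2 + 1L
  if (head_idx > length(toks)) return(match_result(FALSE))
  noun <- tolower(toks[head_idx])
  noun <- sub("s$", "", noun)
  if (!(noun %in% rule5_nouns)) return(match_result(FALSE))
  if (!is.null(tree) && head_idx <= nrow(tree$tokens) &&
      negated_with_verb(tree, head_idx)) {
    return(match_result(FALSE, negated = TRUE))
  }
  match_result(TRUE, 5L, noun,
               trace = sprintf("lexical %s%s%s %s", toks[pair$t1],
                               toks[pair$t1 + 1L], toks[pair$t2], noun))
}

rule67_nouns <- c("receptor", "ligand", "substrate")

# Locate cue-noun token indices: the three single-word cues plus the
# "binding protein" bigram (index of "protein" reported as the cue head).
cue_noun_indices <- function(tokens) {
  lt <- tolower(tokens)
  singles <- which(sub("s$", "", lt) %in% rule67_nouns)
  bigram <- which(lt == "protein" & c("", lt[-length(lt)]) == "binding")
  sort(unique(c(singles, bigram)))
}

#' Rule 6: "P0 is a receptor for P1" (syntactic + lexical)
#'
#' The first protein is the subject of a verb whose complement is a cue
#' noun in \{receptor, ligand, substrate, binding protein\}, and the cue
#' noun has a \code{prep_for}/\code{prep_of} edge to the second protein.
#' In the copular analysis the cue noun heads the clause, so the subject
#' edge may attach to the noun itself. Negation as rule 1.
#' @inheritParams rule1
#' @return A \code{ppi_match}.
#' @export
rule6 <- function(pair, sentence, tree, config, lexicon = NULL) {
  cues <- cue_noun_indices(tree$tokens$text)
  prot <- c(pair$t1, pair$t2)
  negated <- FALSE
  for (cn in cues) {
    second <- intersect(c(dependents(tree, cn, "prep_for"),
                          dependents(tree, cn, "prep_of")), prot)
    if (!length(second)) next
    for (b in second) {
      a <- setdiff(prot, b)
      # copular: subject attaches to the cue noun
      cop_subject <- a %in% dependents(tree, cn, "nsubj")
      verb_link <- FALSE
      neg_here <- FALSE
      if (cop_subject) {
        neg_here <- has_negation(tree, cn) || has_negation(tree, a)
        verb_link <- TRUE
      } else if (!config$rule6_copula_only) {
        # non-copular: a verb with the protein subject and the cue noun as
        # its complement
        verbs <- which(vapply(seq_len(nrow(tree$tokens)), function(v) {
          a %in% dependents(tree, v, "nsubj") &&
            cn %in% c(dependents(tree, v, "dobj"),
                      dependents(tree, v, "attr"),
                      dependents(tree, v, "xcomp"),
                      dependents(tree, v, "acomp"))
        }, logical(1)))
        if (length(verbs)) {
          verb_link <- TRUE
          neg_here <- any(vapply(verbs, function(v) has_negation(tree, v),
                                 logical(1))) ||
            has_negation(tree, a) || has_negation(tree, cn)
        }
      }
      if (!verb_link) next
      if (neg_here) {
        negated <- TRUE
        next
      }
      return(match_result(TRUE, 6L, tolower(tree$tokens$text[cn]),
                          trace = sprintf("cue '%s' links %s to %s",
                                          tree$tokens$text[cn],
                                          tree$tokens$text[a],
                                          tree$tokens$text[b])))
    }
  }
  match_result(FALSE, negated = negated)
}

#' Rule 7: "P0 receptor (P1)" apposition pattern
#'
#' Token sequence: protein, cue noun (receptor/ligand/substrate or the
#' "binding protein" bigram), "(", protein, ")". No negation handling (the
#' pattern asserts a naming convention, not an event).
#' @inheritParams rule5
#' @return A \code{ppi_match}.
#' @export
rule7 <- function(pair, sentence, tree = NULL, config = rule_config(),
                  lexicon = NULL) {
  toks <- sentence$tokens
  lt <- tolower(toks)
  cue_end <- NA_integer_
  if (pair$t1 + 1L <= length(toks) &&
      sub("s$", "", lt[pair$t1 + 1L]) %in% rule67_nouns) {
    cue_end <- pair$t1 + 1L
  } else if (pair$t1 + 2L <= length(toks) &&
             lt[pair$t1 + 1L] == "binding" && lt[pair$t1 + 2L] == "protein") {
    cue_end <- pair$t1 + 2L
  }
  if (is.na(cue_end)) return(match_result(FALSE))
  if (cue_end + 2L > length(toks)) return(match_result(FALSE))
  if (toks[cue_end + 1L] != "(") return(match_result(FALSE))
  if (pair$t2 != cue_end + 2L) return(match_result(FALSE))
  if (pair$t2 + 1L > length(toks) || toks[pair$t2 + 1L] != ")") {
    return(match_result(FALSE))
  }
  match_result(TRUE, 7L, lt[cue_end],
               trace = sprintf("%s %s ( %s )", toks[pair$t1], toks[cue_end],
                               toks[pair$t2]))
}

#' Rule 8: "P0 binding domain/site on/in/within/of ... P1"
#'
#' Token sequence: protein, "binding domain" or "binding site", a
#' preposition in \{in, within, on, of\}, then the second protein within
#' the surface window (intervening noun-phrase tokens allowed, as in
#' "CD30L binding domain on the human CD30 molecule"). No negation
#' handling.
#' @inheritParams rule5
#' @return A \code{ppi_match}.
#' @export
rule8 <- function(pair, sentence, tree = NULL, config = rule_config(),
                  lexicon = NULL) {
  toks <- sentence$tokens
  lt <- tolower(toks)
  i <- pair$t1
  if (i + 3L > length(toks)) return(match_result(FALSE))
  if (lt[i + 1L] != "binding") return(match_result(FALSE))
  if (!(lt[i + 2L] %in% c("domain", "site"))) return(match_result(FALSE))
  if (!(lt[i + 3L] %in% c("in", "within", "on", "of"))) {
    return(match_result(FALSE))
  }
  if (pair$t2 <= i + 3L) return(match_result(FALSE))
  if (pair$span_tokens > config$window_tokens) return(match_result(FALSE))
  match_result(TRUE, 8L, paste("binding", lt[i + 2L]),
               trace = sprintf("%s binding %s %s ... %s", toks[i], lt[i + 2L],
                               lt[i + 3L], toks[pair$t2]))
}

#' Classify a candidate pair with the eight-rule cascade
#'
#' Applies the enabled rules in ascending id order and returns the first
#' match; if no rule matches, the pair is negative. Pairs of co-referent
#' mentions (\code{self_relation}) are never positive. When \code{tree} is
#' \code{NULL} (parse missing/failed) only the lexical rules 5, 7 and 8 are
#' applied and the negation check of rule 5 is skipped.
#'
#' @inheritParams rule1
#' @param tree Aligned \code{dep_tree} or \code{NULL}.
#' @return A \code{ppi_match} with \code{rule_id} set when matched and
#'   \code{negated = TRUE} when some rule's pattern was present but vetoed
#'   by negation.
#' @export
classify_pair <- function(pair, sentence, tree, config = rule_config(),
                          lexicon = load_default_lexicon()) {
  if (isTRUE(pair$self_relation)) {
    return(match_result(FALSE, trace = "self-relation pair"))
  }
  rule_fns <- list(rule1, rule2, rule3, rule4, rule5, rule6, rule7, rule8)
  lexical <- c(5L, 7L, 8L)
  negated <- FALSE
  for (r in config$enabled_rules) {
    if (is.null(tree) && !(r %in% lexical)) next
    res <- rule_fns[[r]](pair, sentence, tree, config, lexicon)
    if (res$matched) {
      res$rule_id <- r
      return(res)
    }
    negated <- negated || res$negated
  }
  match_result(FALSE, negated = negated)
}

#' Run the rule engine over a whole corpus
#'
#' Enumerates candidate pairs of every sentence with at least two mentions
#' and classifies each with [classify_pair()]. Sentences without an aligned
#' tree are classified with the lexical rules only.
#'
#' @param corpus A \code{ppi_corpus}.
#' @param trees Named list of \code{dep_tree} (names = sentence ids), e.g.
#'   from [read_conllu()]; trees are collapsed with [collapse_ud()] on the
#'   fly.
#' @param config A [rule_config()].
#' @param lexicon A [load_default_lexicon()] lexicon.
#' @return Predictions data frame: \code{sentence_id}, \code{e1}, \code{e2},
#'   \code{label}, \code{rule_id}, \code{trigger}, \code{negated}.
#' @export
extract_corpus <- function(corpus, trees, config = rule_config(),
                           lexicon = load_default_lexicon()) {
  rows <- list()
  for (s in corpus) {
    cand <- enumerate_candidates(s)
    if (!nrow(cand)) next
    tree <- trees[[s$sentence_id]]
    if (!is.null(tree)) tree <- collapse_ud(tree)
    for (i in seq_len(nrow(cand))) {
      res <- classify_pair(cand[i, ], s, tree, config, lexicon)
      rows[[length(rows) + 1L]] <- data.frame(
        sentence_id = s$sentence_id, e1 = cand$e1[i], e2 = cand$e2[i],
        label = if (res$matched) "positive" else "negative",
        rule_id = res$rule_id, trigger = res$trigger, negated = res$negated,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(sentence_id = character(0), e1 = character(0),
                      e2 = character(0), label = character(0),
                      rule_id = integer(0), trigger = character(0),
                      negated = logical(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Write / read a predictions table as TSV
#' @param predictions Data frame as returned by [extract_corpus()].
#' @param path TSV path.
#' @return \code{path} (write) or the predictions data frame (read).
#' @export
write_predictions_tsv <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions_tsv
#' @export
read_predictions_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
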