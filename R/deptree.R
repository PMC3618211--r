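# Dependency trees in the collapsed-Stanford label dialect the extraction
# rules are written in (prep_X, conj_and, neg). Universal Dependencies input
# is converted by collapse_ud(); rules never match raw UD labels.

#' Construct a dependency tree
#'
#' @param sentence_id Identifier aligning the tree to its masked sentence.
#' @param tokens Data frame with columns \code{index} (1-based, contiguous),
#'   \code{text}, \code{lemma}, \code{upos}; columns \code{is_protein} and
#'   \code{mask_label} are derived if absent.
#' @param edges Data frame with columns \code{head} (token index, 0 for the
#'   virtual root), \code{dependent}, \code{label}; optional logical column
#'   \code{propagated} (extra edges added by conjunction propagation).
#' @return Object of class \code{dep_tree}.
#' @export
dep_tree <- function(sentence_id, tokens, edges) {
  stopifnot(all(c("index", "text") %in% names(tokens)),
            all(c("head", "dependent", "label") %in% names(edges)))
  if (is.null(tokens$lemma)) tokens$lemma <- tolower(tokens$text)
  tokens$lemma <- ifelse(is.na(tokens$lemma) | tokens$lemma == "_",
                         tolower(tokens$text), tokens$lemma)
  if (is.null(tokens$upos)) tokens$upos <- guess_upos(tokens$text)
  tokens$is_protein <- grepl("^PROTEIN[0-9]+$", tokens$text)
  tokens$mask_label <- ifelse(tokens$is_protein, tokens$text, NA_character_)
  if (!identical(tokens$index, seq_len(nrow(tokens)))) {
    stop("token indices must be contiguous 1..n")
  }
  if (is.null(edges$propagated)) edges$propagated <- FALSE
  if (any(!nzchar(edges$label))) stop("empty dependency label")
  primary <- edges[!edges$propagated, , drop = FALSE]
  heads_per_dep <- table(primary$dependent)
  if (any(heads_per_dep > 1L)) {
    stop("token with multiple non-propagated heads: ",
         paste(names(heads_per_dep)[heads_per_dep > 1L], collapse = ", "))
  }
  root <- primary$dependent[primary$head == 0L]
  if (length(root) != 1L) stop("tree must have exactly one root")
  rownames(tokens) <- rownames(edges) <- NULL
  structure(list(sentence_id = sentence_id, tokens = tokens, edges = edges,
                 root = root),
            class = "dep_tree")
}

#' @export
print.dep_tree <- function(x, ...) {
  cat("<dep_tree> ", x$sentence_id, ": ",
      paste(x$tokens$text, collapse = " "), "\n", sep = "")
  e <- x$edges
  head_txt <- ifelse(e$head == 0L, "ROOT", x$tokens$text[e$head])
  cat(paste0("  ", head_txt, " -", e$label,
             ifelse(e$propagated, "*", ""), "-> ",
             x$tokens$text[e$dependent], collapse = "\n"), "\n")
  invisible(x)
}

# Coarse POS guess for hand-built fixture trees that omit the column.
guess_upos <- function(text) {
  lt <- tolower(text)
  ifelse(grepl("^PROTEIN[0-9]+$", text), "PROPN",
  ifelse(lt %in% c("the", "a", "an", "no", "this", "these"), "DET",
  ifelse(lt %in% c("of", "to", "by", "with", "on", "for", "in", "within",
                   "between", "from", "at"), "ADP",
  ifelse(lt %in% c("and", "or", "but"), "CCONJ",
  ifelse(lt %in% c("is", "are", "was", "were", "be", "been", "does", "do",
                   "did", "has", "have", "had", "can", "may"), "AUX",
  ifelse(lt %in% c("not", "n't", "never"), "PART",
  ifelse(grepl("^[[:punct:]]+$", text), "PUNCT", "X")))))))
}

#' Read dependency trees from CoNLL-U
#'
#' Parses 10-column CoNLL-U. Sentence ids are taken from
#' \code{# sent_id =} comments (falling back to a running number).
#' Multiword-token ranges and empty nodes are skipped; the enhanced
#' dependency column is ignored (collapsing is done by [collapse_ud()]).
#'
#' @param path CoNLL-U file path (or a character vector of lines).
#' @param corpus Optional \code{ppi_corpus}; when given, each tree is checked
#'   for token-count agreement with the masked sentence of the same id.
#' @return Named list of \code{dep_tree} (names = sentence ids).
#' @export
read_conllu <- function(path, corpus = NULL) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    unlist(strsplit(path, "\n", fixed = TRUE))
  }
  blocks <- split(lines, cumsum(!nzchar(trimws(lines))))
  trees <- list()
  counter <- 0L
  for (blk in blocks) {
    blk <- blk[nzchar(trimws(blk))]
    if (!length(blk)) next
    counter <- counter + 1L
    sid_line <- grep("^# sent_id *=", blk, value = TRUE)
    sid <- if (length(sid_line)) {
      trimws(sub("^# sent_id *=", "", sid_line[1]))
    } else {
      paste0("s", counter)
    }
    rows <- blk[!startsWith(blk, "#")]
    fields <- strsplit(rows, "\t", fixed = TRUE)
    ok <- vapply(fields, function(f) length(f) >= 8 && grepl("^[0-9]+$", f[1]),
                 logical(1))
    fields <- fields[ok]
    if (!length(fields)) next
    tokens <- data.frame(
      index = as.integer(vapply(fields, `[`, "", 1L)),
      text = vapply(fields, `[`, "", 2L),
      lemma = vapply(fields, `[`, "", 3L),
      upos = vapply(fields, `[`, "", 4L),
      stringsAsFactors = FALSE
    )
    edges <- data.frame(
      head = as.integer(vapply(fields, `[`, "", 7L)),
      dependent = tokens$index,
      label = vapply(fields, `[`, "", 8L),
      propagated = FALSE,
      stringsAsFactors = FALSE
    )
    if (!is.null(corpus)) {
      ids <- vapply(corpus, `[[`, "", "sentence_id")
      hit <- match(sid, ids)
      if (!is.na(hit) &&
          length(corpus[[hit]]$tokens) != nrow(tokens)) {
        stop("alignment error: sentence ", sid, " has ",
             length(corpus[[hit]]$tokens), " masked tokens but ",
             nrow(tokens), " CoNLL-U tokens")
      }
    }
    trees[[sid]] <- dep_tree(sid, tokens, edges)
  }
  trees
}

#' Collapse Universal Dependencies into the collapsed-Stanford dialect
#'
#' Conversions applied (everything else passes through unchanged, so the
#' function is idempotent and accepts already-collapsed input):
#' \itemize{
#'   \item \code{nmod:X} / \code{obl:X} (or bare \code{nmod}/\code{obl} with
#'     a \code{case} child X on the dependent) becomes \code{prep_X};
#'   \item \code{conj:and} (or \code{conj} with a \code{cc} child "and")
#'     becomes \code{conj_and}, and the second conjunct receives propagated
#'     copies of the first conjunct's incoming \code{nsubj}/\code{dobj}/
#'     \code{prep_*} edges, flagged \code{propagated};
#'   \item \code{advmod} "not"/"n't"/"never" and \code{det} "no" become
#'     \code{neg} edges.
#' }
#' @param tree A \code{dep_tree} (UD or already collapsed).
#' @return A \code{dep_tree} in the collapsed dialect.
#' @export
collapse_ud <- function(tree) {
  e <- tree$edges
  tok <- tree$tokens
  case_child <- function(node) {
    hits <- e$dependent[e$head == node & e$label == "case"]
    if (length(hits)) tolower(tok$text[hits[1]]) else NA_character_
  }
  cc_child <- function(node) {
    hits <- e$dependent[e$head == node & e$label == "cc"]
    if (length(hits)) tolower(tok$text[hits[1]]) else NA_character_
  }
  for (i in seq_len(nrow(e))) {
    lab <- e$label[i]
    if (grepl("^(nmod|obl):", lab)) {
      e$label[i] <- paste0("prep_", sub("^(nmod|obl):", "", lab))
    } else if (lab %in% c("nmod", "obl")) {
      cs <- case_child(e$dependent[i])
      if (!is.na(cs)) e$label[i] <- paste0("prep_", cs)
    } else if (grepl("^conj:", lab)) {
      e$label[i] <- paste0("conj_", sub("^conj:", "", lab))
    } else if (lab == "conj") {
      cc <- cc_child(e$dependent[i])
      if (!is.na(cc)) e$label[i] <- paste0("conj_", cc)
    } else if (lab == "advmod" &&
               tolower(tok$text[e$dependent[i]]) %in% c("not", "n't", "never")) {
      e$label[i] <- "neg"
    } else if (lab == "det" && tolower(tok$text[e$dependent[i]]) == "no") {
      e$label[i] <- "neg"
    }
  }
  # conjunction propagation to a fixpoint (handles conjunct chains)
  repeat {
    added <- FALSE
    conj <- e[grepl("^conj_", e$label), , drop = FALSE]
    for (i in seq_len(nrow(conj))) {
      h <- conj$head[i]; d <- conj$dependent[i]
      incoming <- e[e$dependent == h &
                      grepl("^(nsubj|dobj|prep_)", e$label), , drop = FALSE]
      for (j in seq_len(nrow(incoming))) {
        exists <- any(e$head == incoming$head[j] & e$dependent == d &
                        e$label == incoming$label[j])
        if (!exists) {
          e <- rbind(e, data.frame(head = incoming$head[j], dependent = d,
                                   label = incoming$label[j], propagated = TRUE,
                                   stringsAsFactors = FALSE))
          added <- TRUE
        }
      }
    }
    if (!added) break
  }
  tree$edges <- e
  tree
}

#' Dependents of a node matching a label pattern
#'
#' @param tree A \code{dep_tree}.
#' @param node Token index.
#' @param pattern Exact label (\code{"nsubj"}) or prefix wildcard
#'   (\code{"prep_*"}). \code{"nsubj"} also matches \code{"nsubjpass"}.
#' @param include_propagated Include conjunction-propagated edges
#'   (default \code{TRUE}).
#' @return Integer vector of dependent token indices in token order.
#' @export
dependents <- function(tree, node, pattern, include_propagated = TRUE) {
  e <- tree$edges
  if (!include_propagated) e <- e[!e$propagated, , drop = FALSE]
  if (!nzchar(pattern)) return(integer(0))
  hit <- if (endsWith(pattern, "*")) {
    startsWith(e$label, sub("\\*$", "", pattern))
  } else if (pattern == "nsubj") {
    e$label %in% c("nsubj", "nsubjpass")
  } else {
    e$label == pattern
  }
  sort(unique(e$dependent[hit & e$head == node]))
}

#' Is a node negated?
#'
#' @param tree A \code{dep_tree}.
#' @param node Token index.
#' @return \code{TRUE} iff the node has a \code{neg}-labeled dependent.
#' @export
has_negation <- function(tree, node) {
  length(dependents(tree, node, "neg")) > 0L
}

# Head chain from a node up to the root (primary edges only), excluding the
# node itself.
ancestors <- function(tree, node) {
  prim <- tree$edges[!tree$edges$propagated, , drop = FALSE]
  out <- integer(0)
  cur <- node
  repeat {
    h <- prim$head[prim$dependent == cur]
    if (!length(h) || h[1] == 0L) break
    if (h[1] %in% out) break  # cycle guard
    out <- c(out, h[1])
    cur <- h[1]
  }
  out
}

# Negation on the node itself or on its governing verb (the nearest verbal
# ancestor). Used by the noun-headed rules, where "no interaction of ..."
# and "... was not identified" must both veto a match.
negated_with_verb <- function(tree, node) {
  if (has_negation(tree, node)) return(TRUE)
  for (a in ancestors(tree, node)) {
    verbal <- tree$tokens$upos[a] %in% c("VERB", "AUX") ||
      length(dependents(tree, a, "nsubj")) > 0L
    if (verbal && has_negation(tree, a)) return(TRUE)
  }
  FALSE
}

#' Count dependency-bearing words between a protein pair
#'
#' Counts the tokens strictly between the two proteins (surface order) that
#' carry a content dependency: the token participates in at least one edge
#' whose label is outside the function-word set (\code{case}, \code{cc},
#' \code{punct}, \code{det}, \code{mark}) and the token's coarse POS is not
#' in \code{ADP, CCONJ, PUNCT, DET}. Prepositions absorbed by collapsing
#' ("with") and coordinations ("and") therefore do not count.
#'
#' @param sentence The \code{ppi_sentence} (for surface order; unused beyond
#'   argument symmetry, the token span comes from \code{t1}/\code{t2}).
#' @param tree Aligned \code{dep_tree}.
#' @param t1,t2 Token indices of the two proteins, \code{t1 < t2}.
#' @return Non-negative integer count.
#' @export
intervening_dep_words <- function(sentence, tree, t1, t2) {
  if (t2 - t1 < 2L) return(0L)
  between <- (t1 + 1L):(t2 - 1L)
  func_labels <- c("case", "cc", "punct", "det", "mark")
  e <- tree$edges
  content <- vapply(between, function(i) {
    touching <- e$label[e$head == i | e$dependent == i]
    any(!(touching %in% func_labels)) &&
      !(tree$tokens$upos[i] %in% c("ADP", "CCONJ", "PUNCT", "DET"))
  }, logical(1))
  sum(content)
}

#' Root-to-token dependency path
#'
#' The unique path from the tree root down to \code{node} over
#' non-propagated edges, as a data frame of (\code{label}, \code{lemma})
#' elements ordered root-first. An empty data frame when the node is the
#' root; a disconnected node yields an empty path flagged by attribute
#' \code{disconnected}.
#' @param tree A \code{dep_tree}.
#' @param node Token index.
#' @return Data frame with columns \code{label}, \code{lemma}.
#' @export
tree_path <- function(tree, node) {
  empty <- data.frame(label = character(0), lemma = character(0),
                      stringsAsFactors = FALSE)
  if (node == tree$root) return(empty)
  prim <- tree$edges[!tree$edges$propagated, , drop = FALSE]
  labels <- character(0)
  lemmas <- character(0)
  cur <- node
  steps <- 0L
  repeat {
    row <- which(prim$dependent == cur)
    if (!length(row) || prim$head[row[1]] == 0L) {
      return(structure(empty, disconnected = TRUE))
    }
    h <- prim$head[row[1]]
    labels <- c(prim$label[row[1]], labels)
    lemmas <- c(tree$tokens$lemma[cur], lemmas)
    if (h == tree$root) break
    cur <- h
    steps <- steps + 1L
    if (steps > nrow(prim)) stop("cycle in dependency tree")
  }
  data.frame(label = labels, lemma = lemmas, stringsAsFactors = FALSE)
}

#' Write dependency trees as CoNLL-U
#'
#' Emits 10-column CoNLL-U with a \code{# sent_id =} comment per sentence;
#' propagated edges are not representable in the basic-dependency column
#' and are dropped (they are regenerated by [collapse_ud()]).
#' @param trees Named list of \code{dep_tree}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_conllu <- function(trees, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (tree in trees) {
    writeLines(paste0("# sent_id = ", tree$sentence_id), con)
    prim <- tree$edges[!tree$edges$propagated, , drop = FALSE]
    for (i in seq_len(nrow(tree$tokens))) {
      row <- which(prim$dependent == i)
      head <- if (length(row)) prim$head[row[1]] else 0L
      lab <- if (length(row)) prim$label[row[1]] else "root"
      writeLines(paste(i, tree$tokens$text[i], tree$tokens$lemma[i],
                       tree$tokens$upos[i], "_", "_", head, lab, "_", "_",
                       sep = "\t"), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
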