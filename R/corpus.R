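# ---- tokenization ----------------------------------------------------------

#' Tokenize a masked sentence
#'
#' Whitespace tokenization with punctuation splitting: parentheses, commas,
#' semicolons and colons become their own tokens, a sentence-final period is
#' detached, and the separators "-" and "/" are split out only when they
#' directly join two protein placeholders (so hyphenated vocabulary such as
#' "up-regulated" stays one token while "PROTEIN0-PROTEIN1" becomes three).
#'
#' @param text Masked sentence string.
#' @return Character vector of tokens.
#' @export
tokenize_masked <- function(text) {
  t <- text
  t <- gsub("([(),;:])", " \\1 ", t)
  # separators between protein placeholders only
  t <- gsub("(PROTEIN[0-9]+)\\s*([-/])\\s*(PROTEIN[0-9]+)", "\\1 \\2 \\3", t)
  # sentence-final period
  t <- sub("\\.\\s*$", " .", t)
  toks <- strsplit(trimws(t), "\\s+")[[1]]
  toks[nzchar(toks)]
}

# ---- protein masking -------------------------------------------------------

#' Replace protein mentions with placeholder tokens
#'
#' Each mention span in the raw sentence is replaced by a placeholder
#' \code{PROTEINk}, with k assigned in order of first appearance (0-based, so
#' the first mention becomes \code{PROTEIN0}). Identical surface names at
#' different positions receive distinct labels. Character offsets are
#' recomputed on the masked text. Overlapping spans are resolved by keeping
#' the longest span and dropping spans contained in it (with a warning).
#'
#' @param raw_text Raw sentence string.
#' @param mentions Data frame with columns \code{mention_id}, \code{start},
#'   \code{end} (1-based inclusive character positions in \code{raw_text})
#'   and optionally \code{entity_key}.
#' @return List with \code{text} (masked sentence) and \code{mentions} (the
#'   input rows augmented with \code{surface}, \code{mask_label},
#'   \code{start}/\code{end} recomputed on the masked text).
#' @export
mask_proteins <- function(raw_text, mentions) {
  stopifnot(all(c("mention_id", "start", "end") %in% names(mentions)))
  m <- mentions[order(mentions$start, -mentions$end), , drop = FALSE]
  if (nrow(m) > 1L) {
    keep <- rep(TRUE, nrow(m))
    for (i in seq_len(nrow(m))[-1L]) {
      for (j in which(keep[seq_len(i - 1L)])) {
        if (m$start[i] >= m$start[j] && m$end[i] <= m$end[j]) {
          keep[i] <- FALSE
          warning("dropping mention '", substr(raw_text, m$start[i], m$end[i]),
                  "' contained in a longer mention span", call. = FALSE)
          break
        } else if (m$start[i] <= m$end[j]) {
          stop("overlapping (non-nested) mention spans cannot be masked")
        }
      }
    }
    m <- m[keep, , drop = FALSE]
  }
  m$surface <- substr(rep(raw_text, nrow(m)), m$start, m$end)
  m$mask_label <- paste0("PROTEIN", seq_len(nrow(m)) - 1L)
  if (is.null(m$entity_key)) m$entity_key <- normalize_entity_key(m$surface)

  pieces <- character(0)
  new_start <- integer(nrow(m))
  cursor <- 1L
  out_len <- 0L
  for (i in seq_len(nrow(m))) {
    before <- substr(raw_text, cursor, m$start[i] - 1L)
    pieces <- c(pieces, before, m$mask_label[i])
    new_start[i] <- out_len + nchar(before) + 1L
    out_len <- out_len + nchar(before) + nchar(m$mask_label[i])
    cursor <- m$end[i] + 1L
  }
  pieces <- c(pieces, substr(raw_text, cursor, nchar(raw_text)))
  masked <- paste(pieces, collapse = "")
  m$start <- new_start
  m$end <- new_start + nchar(m$mask_label) - 1L
  rownames(m) <- NULL
  list(text = masked, mentions = m)
}

#' Normalize a protein surface form into a corpus-wide entity key
#'
#' Case-folds and collapses whitespace/hyphen variation so that instances of
#' the same protein pair scattered across a corpus group into one relation.
#' @param surface Character vector of protein names.
#' @return Character vector of normalized keys.
#' @export
normalize_entity_key <- function(surface) {
  k <- tolower(surface)
  k <- gsub("[-\\s]+", "", k, perl = TRUE)
  k
}

#' Reverse protein masking
#'
#' Restores the raw sentence from a masked sentence and its mention table
#' (using the stored surfaces). \code{unmask(mask(x)) == x}.
#' @param masked_text Masked sentence string.
#' @param mentions Mention table as produced by [mask_proteins()].
#' @return The raw sentence string.
#' @export
unmask_proteins <- function(masked_text, mentions) {
  m <- mentions[order(mentions$start), , drop = FALSE]
  pieces <- character(0)
  cursor <- 1L
  for (i in seq_len(nrow(m))) {
    pieces <- c(pieces, substr(masked_text, cursor, m$start[i] - 1L), m$surface[i])
    cursor <- m$end[i] + 1L
  }
  paste(c(pieces, substr(masked_text, cursor, nchar(masked_text))), collapse = "")
}

# ---- annotated sentences ---------------------------------------------------

#' Construct an annotated sentence
#'
#' Masks the protein mentions, tokenizes, locates each placeholder's token
#' index, and canonicalizes the gold pair table. The result is the unit all
#' downstream modules operate on.
#'
#' @param sentence_id Identifier string.
#' @param raw_text Raw sentence.
#' @param mentions Mention data frame (see [mask_proteins()]).
#' @param gold_pairs Data frame with columns \code{e1}, \code{e2}
#'   (mention ids) and \code{label} in \code{c("positive","negative")}; may
#'   be empty.
#' @return An object of class \code{ppi_sentence}.
#' @export
annotated_sentence <- function(sentence_id, raw_text, mentions,
                               gold_pairs = empty_gold_pairs()) {
  masked <- mask_proteins(raw_text, mentions)
  toks <- tokenize_masked(masked$text)
  m <- masked$mentions
  m$token_index <- match(m$mask_label, toks)
  if (anyNA(m$token_index)) {
    stop("sentence ", sentence_id, ": placeholder token lost in tokenization")
  }
  gp <- canonicalize_pairs(gold_pairs)
  bad <- !(gp$e1 %in% m$mention_id) | !(gp$e2 %in% m$mention_id)
  if (any(bad)) {
    stop("sentence ", sentence_id, ": gold pair references unknown mention id: ",
         paste(unique(c(gp$e1[bad], gp$e2[bad])), collapse = ", "))
  }
  structure(
    list(sentence_id = sentence_id, raw_text = raw_text, text = masked$text,
         tokens = toks, mentions = m, gold_pairs = gp,
         candidate = nrow(m) >= 2L),
    class = "ppi_sentence"
  )
}

empty_gold_pairs <- function() {
  data.frame(e1 = character(0), e2 = character(0), label = character(0),
             stringsAsFactors = FALSE)
}

canonicalize_pairs <- function(gp) {
  if (nrow(gp) == 0L) return(empty_gold_pairs())
  stopifnot(all(c("e1", "e2", "label") %in% names(gp)))
  if (any(gp$e1 == gp$e2)) stop("gold pair references the same mention twice")
  swap <- gp$e1 > gp$e2
  tmp <- gp$e1[swap]; gp$e1[swap] <- gp$e2[swap]; gp$e2[swap] <- tmp
  gp <- gp[!duplicated(gp[c("e1", "e2")]), , drop = FALSE]
  stopifnot(all(gp$label %in% c("positive", "negative")))
  rownames(gp) <- NULL
  gp
}

#' @export
print.ppi_sentence <- function(x, ...) {
  cat("<ppi_sentence> ", x$sentence_id, ": \"", x$text, "\"\n",
      "  ", nrow(x$mentions), " mentions, ", nrow(x$gold_pairs),
      " gold pairs", if (!x$candidate) " (non-candidate)", "\n", sep = "")
  invisible(x)
}

# ---- parenthetical stripping ----------------------------------------------

#' Remove protein-free parenthetical remarks
#'
#' Deletes every maximal (top-level) balanced \code{(...)} region of the
#' masked sentence that contains no protein placeholder, together with its
#' parentheses. Regions containing a protein are kept verbatim, including
#' any nested parentheses. Unmatched parentheses are treated as literal
#' tokens and left in place. Never deletes a \code{PROTEINk} token.
#'
#' @param x A masked sentence string or a \code{ppi_sentence}.
#' @return Object of the same type with protein-free parentheticals removed
#'   (for a \code{ppi_sentence}, mention offsets and token indices are
#'   recomputed).
#' @export
strip_parentheticals <- function(x) UseMethod("strip_parentheticals")

#' @export
strip_parentheticals.character <- function(x) {
  chars <- strsplit(x, "")[[1]]
  n <- length(chars)
  depth <- 0L
  start <- 0L
  drop <- logical(n)
  i <- 1L
  while (i <= n) {
    if (chars[i] == "(") {
      if (depth == 0L) {
        # find the matching top-level close; unmatched "(" stays literal
        d <- 0L
        close <- 0L
        for (j in i:n) {
          if (chars[j] == "(") d <- d + 1L
          if (chars[j] == ")") {
            d <- d - 1L
            if (d == 0L) { close <- j; break }
          }
        }
        if (close > 0L) {
          region <- paste(chars[i:close], collapse = "")
          if (!grepl("PROTEIN[0-9]+", region)) drop[i:close] <- TRUE
          i <- close + 1L
          next
        }
      }
    }
    i <- i + 1L
  }
  out <- paste(chars[!drop], collapse = "")
  out <- gsub("[ \t]+", " ", out)
  out <- gsub(" +([.,;])", "\\1", out)
  trimws(out)
}

#' @export
strip_parentheticals.ppi_sentence <- function(x) {
  stripped <- strip_parentheticals(x$text)
  if (identical(stripped, x$text)) return(x)
  m <- x$mentions
  # placeholder labels are unique, so re-anchor spans on the stripped text
  m$start <- vapply(m$mask_label, function(lab) {
    as.integer(regexpr(paste0("\\b", lab, "\\b"), stripped))
  }, integer(1))
  if (any(m$start < 0L)) stop("parenthetical stripping lost a protein placeholder")
  m$end <- m$start + nchar(m$mask_label) - 1L
  toks <- tokenize_masked(stripped)
  m$token_index <- match(m$mask_label, toks)
  x$text <- stripped
  x$tokens <- toks
  x$mentions <- m
  x
}

# ---- clause splitting ------------------------------------------------------

#' Split a sentence into clauses
#'
#' A conservative heuristic: splits at sentence-medial semicolons, and at a
#' coordinating conjunction (\code{and}/\code{but}/\code{or}) immediately
#' preceded by a comma when both resulting sides contain at least one
#' protein placeholder and at least two tokens. When a dependency tree is
#' supplied, the comma+conjunction split additionally requires a token with
#' a subject (\code{nsubj*}) dependency on each side. If no split point
#' qualifies the sentence is returned unchanged (singleton list).
#'
#' Mentions and gold pairs are reassigned to the clause containing them;
#' gold pairs whose mentions fall into different clauses are dropped from
#' the clauses and reported in the \code{straddlers} attribute.
#'
#' @param sentence A \code{ppi_sentence}.
#' @param tree Optional \code{dep_tree} aligned to the sentence.
#' @param enabled Set \code{FALSE} to disable splitting entirely.
#' @return List of \code{ppi_sentence} clauses (ids suffixed \code{.c1},
#'   \code{.c2}, ... when split) with attribute \code{straddlers}: the gold
#'   pairs dropped because they straddle a clause boundary.
#' @export
split_clauses <- function(sentence, tree = NULL, enabled = TRUE) {
  toks <- sentence$tokens
  n <- length(toks)
  out_single <- structure(list(sentence), straddlers = empty_gold_pairs())
  if (!enabled || n == 0L) return(out_single)

  has_subject_side <- function(idx) {
    if (is.null(tree)) return(TRUE)
    any(grepl("^nsubj", tree$edges$label) &
          tree$edges$dependent %in% idx)
  }
  cut_after <- integer(0)  # clause ends at these token indices (cut token excluded)
  for (i in seq_len(n)) {
    if (toks[i] == ";" && i > 1L && i < n) {
      cut_after <- c(cut_after, i)
    } else if (tolower(toks[i]) %in% c("and", "but", "or") &&
               i > 2L && i < n && toks[i - 1L] == ",") {
      left <- seq_len(i - 2L)
      right <- (i + 1L):n
      if (any(grepl("^PROTEIN[0-9]+$", toks[left])) &&
          any(grepl("^PROTEIN[0-9]+$", toks[right])) &&
          length(left) >= 2L && length(right) >= 2L &&
          has_subject_side(left) && has_subject_side(right)) {
        cut_after <- c(cut_after, i)
      }
    }
  }
  if (length(cut_after) == 0L) return(out_single)

  cuts <- sort(unique(cut_after))
  bounds_lo <- c(1L, cuts + 1L)
  bounds_hi <- c(cuts - 1L, n)
  clauses <- list()
  m <- sentence$mentions
  clause_of_mention <- stats::setNames(rep(NA_integer_, nrow(m)), m$mention_id)
  seg_tokens <- list()
  for (k in seq_along(bounds_lo)) {
    span <- seq(bounds_lo[k], bounds_hi[k])
    # trim connective/punctuation remnants at the segment edges
    while (length(span) &&
           tolower(toks[span[1L]]) %in% c(",", ";", "and", "but", "or")) {
      span <- span[-1L]
    }
    while (length(span) && toks[span[length(span)]] %in% c(";", ",")) {
      span <- span[-length(span)]
    }
    seg_tokens[[k]] <- span
    in_clause <- m$mention_id[m$token_index %in% span]
    clause_of_mention[in_clause] <- k
  }
  gp <- sentence$gold_pairs
  for (k in seq_along(seg_tokens)) {
    span <- seg_tokens[[k]]
    if (length(span) == 0L) next
    ids <- m$mention_id[!is.na(clause_of_mention[m$mention_id]) &
                          clause_of_mention[m$mention_id] == k]
    keep_gp <- gp[gp$e1 %in% ids & gp$e2 %in% ids, , drop = FALSE]
    sub_m <- m[m$mention_id %in% ids, , drop = FALSE]
    raw_clause <- paste(toks[span], collapse = " ")
    # rebuild the clause as a fresh sentence over its own raw text
    surf <- sub_m$surface
    clause_raw <- raw_clause
    for (i in seq_len(nrow(sub_m))) {
      clause_raw <- sub(paste0("\\b", sub_m$mask_label[i], "\\b"), surf[i],
                        clause_raw)
    }
    men <- locate_mentions(clause_raw, sub_m)
    clauses[[length(clauses) + 1L]] <- annotated_sentence(
      paste0(sentence$sentence_id, ".c", k), clause_raw, men, keep_gp)
  }
  both <- !is.na(clause_of_mention[gp$e1]) & !is.na(clause_of_mention[gp$e2])
  strad <- gp[both & clause_of_mention[gp$e1] != clause_of_mention[gp$e2], ,
              drop = FALSE]
  structure(clauses, straddlers = strad)
}

# Re-locate mention surfaces in a rebuilt clause text (left-to-right, in
# token order), producing a fresh mention table with raw-text offsets.
locate_mentions <- function(clause_raw, sub_m) {
  sub_m <- sub_m[order(sub_m$token_index), , drop = FALSE]
  out <- data.frame(mention_id = sub_m$mention_id,
                    start = NA_integer_, end = NA_integer_,
                    entity_key = sub_m$entity_key,
                    stringsAsFactors = FALSE)
  cursor <- 1L
  for (i in seq_len(nrow(sub_m))) {
    pos <- regexpr(sub_m$surface[i], substr(clause_raw, cursor, nchar(clause_raw)),
                   fixed = TRUE)
    if (pos < 0L) stop("mention surface not found in rebuilt clause")
    out$start[i] <- cursor + as.integer(pos) - 1L
    out$end[i] <- out$start[i] + nchar(sub_m$surface[i]) - 1L
    cursor <- out$end[i] + 1L
  }
  out
}

# ---- candidate enumeration -------------------------------------------------

#' Enumerate candidate protein pairs of a sentence
#'
#' Returns all unordered mention pairs in surface order, with the inclusive
#' token span between them. The seven-word window is deliberately NOT
#' applied here: it is a rule-engine constraint, and lexical rules and ML
#' tiers must see every pair. Pairs of co-referent mentions (same
#' \code{entity_key}) are emitted but flagged \code{self_relation}.
#'
#' @param sentence A \code{ppi_sentence} with at least 2 mentions.
#' @return Data frame with columns \code{e1}, \code{e2} (mention ids,
#'   \code{e1} earlier in the sentence), \code{t1}, \code{t2} (token
#'   indices), \code{span_tokens} (token count from first to second,
#'   inclusive), \code{self_relation}.
#' @export
enumerate_candidates <- function(sentence) {
  m <- sentence$mentions
  if (nrow(m) < 2L) {
    return(data.frame(e1 = character(0), e2 = character(0),
                      t1 = integer(0), t2 = integer(0),
                      span_tokens = integer(0), self_relation = logical(0),
                      stringsAsFactors = FALSE))
  }
  m <- m[order(m$token_index), , drop = FALSE]
  idx <- utils::combn(nrow(m), 2L)
  data.frame(
    e1 = m$mention_id[idx[1L, ]],
    e2 = m$mention_id[idx[2L, ]],
    t1 = m$token_index[idx[1L, ]],
    t2 = m$token_index[idx[2L, ]],
    span_tokens = m$token_index[idx[2L, ]] - m$token_index[idx[1L, ]] + 1L,
    self_relation = m$entity_key[idx[1L, ]] == m$entity_key[idx[2L, ]],
    stringsAsFactors = FALSE
  )
}
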