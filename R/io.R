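# Corpus I/O: unified PPI-XML dialect, masked-sentence JSONL, standoff TSV.
#
# PPI-XML layout (the cross-corpus interchange dialect used by the major
# benchmark PPI corpora):
#   <corpus><document id=..>
#     <sentence id=.. text=..>
#       <entity id=.. charOffset="a-b" text=../>          (inclusive, 0-based)
#       <pair id=.. e1=.. e2=.. interaction="True|False"/>
#     </sentence>
#   </document></corpus>
# <interaction e1=.. e2=../> is accepted as an always-positive synonym of
# <pair interaction="True">.

#' Read a PPI corpus from unified PPI-XML
#'
#' @param path Path to (or literal string of) a PPI-XML document.
#' @param exhaustive If \code{TRUE} (the convention of exhaustively annotated
#'   corpora such as AIMed), candidate pairs not annotated in the file are
#'   materialized as gold-negative; if \code{FALSE} they are left unlabeled.
#' @return Object of class \code{ppi_corpus}: a list of [annotated_sentence()]
#'   objects in document order.
#' @export
read_ppi_corpus <- function(path, exhaustive = TRUE) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed PPI-XML: ", conditionMessage(e), call. = FALSE)
  })
  sentences <- list()
  for (sent in xml2::xml_find_all(doc, ".//sentence")) {
    sid <- xml2::xml_attr(sent, "id")
    text <- xml2::xml_attr(sent, "text")
    ents <- xml2::xml_find_all(sent, "./entity")
    mentions <- data.frame(
      mention_id = xml2::xml_attr(ents, "id"),
      start = integer(length(ents)), end = integer(length(ents)),
      stringsAsFactors = FALSE
    )
    for (i in seq_along(ents)) {
      off <- xml2::xml_attr(ents[[i]], "charOffset")
      if (is.na(off) || !grepl("^[0-9]+-[0-9]+$", off)) {
        stop("corpus-integrity error: sentence ", sid,
             ": entity ", mentions$mention_id[i],
             " has missing or unsupported charOffset '", off, "'")
      }
      ab <- as.integer(strsplit(off, "-", fixed = TRUE)[[1]])
      mentions$start[i] <- ab[1] + 1L   # 0-based inclusive -> 1-based inclusive
      mentions$end[i] <- ab[2] + 1L
      if (mentions$end[i] > nchar(text) || mentions$start[i] < 1L) {
        stop("corpus-integrity error: sentence ", sid, ": entity offset ",
             off, " outside sentence text")
      }
      declared <- xml2::xml_attr(ents[[i]], "text")
      actual <- substr(text, mentions$start[i], mentions$end[i])
      if (!is.na(declared) && declared != actual) {
        warning("sentence ", sid, ": entity text attribute '", declared,
                "' differs from span '", actual, "'", call. = FALSE)
      }
      key <- xml2::xml_attr(ents[[i]], "entityKey")
      if (!is.na(key)) {
        if (is.null(mentions$entity_key)) mentions$entity_key <- NA_character_
        mentions$entity_key[i] <- key
      }
    }
    pairs <- xml2::xml_find_all(sent, "./pair | ./interaction")
    gp <- data.frame(
      e1 = xml2::xml_attr(pairs, "e1"),
      e2 = xml2::xml_attr(pairs, "e2"),
      label = ifelse(
        xml2::xml_name(pairs) == "interaction" |
          tolower(ifelse(is.na(xml2::xml_attr(pairs, "interaction")), "true",
                         xml2::xml_attr(pairs, "interaction"))) == "true",
        "positive", "negative"),
      stringsAsFactors = FALSE
    )
    unknown <- setdiff(c(gp$e1, gp$e2), mentions$mention_id)
    if (length(unknown)) {
      stop("corpus-integrity error: sentence ", sid,
           ": pair references unknown entity id: ",
           paste(unknown, collapse = ", "))
    }
    s <- annotated_sentence(sid, text, mentions, gp)
    if (exhaustive && nrow(s$mentions) >= 2L) {
      cand <- enumerate_candidates(s)
      have <- paste(s$gold_pairs$e1, s$gold_pairs$e2)
      key <- canonicalize_pairs(data.frame(e1 = cand$e1, e2 = cand$e2,
                                           label = "negative",
                                           stringsAsFactors = FALSE))
      missing <- key[!(paste(key$e1, key$e2) %in% have), , drop = FALSE]
      s$gold_pairs <- rbind(s$gold_pairs, missing)
      rownames(s$gold_pairs) <- NULL
    }
    sentences[[length(sentences) + 1L]] <- s
  }
  structure(sentences, class = "ppi_corpus")
}

#' @export
print.ppi_corpus <- function(x, ...) {
  npair <- sum(vapply(x, function(s) nrow(s$gold_pairs), integer(1)))
  cat("<ppi_corpus> ", length(x), " sentences, ", npair, " gold pairs\n",
      sep = "")
  invisible(x)
}

#' Write a PPI corpus as unified PPI-XML
#'
#' Inverse of [read_ppi_corpus()]: offsets are emitted on the raw sentence
#' text as 0-based inclusive \code{charOffset} ranges.
#' @param corpus A \code{ppi_corpus}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_ppi_corpus <- function(corpus, path) {
  root <- xml2::xml_new_root("corpus")
  doc_node <- xml2::xml_add_child(root, "document", id = "d1")
  for (s in corpus) {
    sent <- xml2::xml_add_child(doc_node, "sentence", id = s$sentence_id,
                                text = s$raw_text)
    m <- s$mentions
    raw_spans <- raw_mention_spans(s)
    for (i in seq_len(nrow(m))) {
      xml2::xml_add_child(sent, "entity", id = m$mention_id[i],
                          charOffset = paste0(raw_spans$start[i] - 1L, "-",
                                              raw_spans$end[i] - 1L),
                          text = m$surface[i],
                          entityKey = m$entity_key[i])
    }
    gp <- s$gold_pairs
    for (i in seq_len(nrow(gp))) {
      xml2::xml_add_child(sent, "pair",
                          id = paste0(s$sentence_id, ".p", i),
                          e1 = gp$e1[i], e2 = gp$e2[i],
                          interaction = ifelse(gp$label[i] == "positive",
                                               "True", "False"))
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

# Mention spans on the *raw* text, recovered by walking the masked spans in
# order and accounting for the surface/placeholder length differences.
raw_mention_spans <- function(s) {
  m <- s$mentions[order(s$mentions$start), , drop = FALSE]
  shift <- 0L
  out <- data.frame(mention_id = m$mention_id, start = integer(nrow(m)),
                    end = integer(nrow(m)), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(m))) {
    out$start[i] <- m$start[i] + shift
    out$end[i] <- out$start[i] + nchar(m$surface[i]) - 1L
    shift <- shift + nchar(m$surface[i]) - nchar(m$mask_label[i])
  }
  out[match(s$mentions$mention_id, out$mention_id), , drop = FALSE]
}

#' Write masked sentences as JSONL
#'
#' One JSON object per line: \code{sentence_id}, \code{raw_text},
#' \code{text}, \code{tokens}, \code{mentions}, \code{gold_pairs}. This is
#' the interchange format consumed by the rule engine and evaluation
#' tooling, and the format the CoNLL-U parses align to.
#' @param corpus A \code{ppi_corpus}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_sentences_jsonl <- function(corpus, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in corpus) {
    writeLines(jsonlite::toJSON(
      list(sentence_id = s$sentence_id, raw_text = s$raw_text, text = s$text,
           tokens = s$tokens, mentions = s$mentions, gold_pairs = s$gold_pairs),
      auto_unbox = TRUE, dataframe = "rows"), con)
  }
  invisible(path)
}

#' Read masked sentences from JSONL
#' @param path JSONL path written by [write_sentences_jsonl()].
#' @return A \code{ppi_corpus}.
#' @export
read_sentences_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l, simplifyDataFrame = TRUE)
    gp <- if (length(x$gold_pairs)) as.data.frame(x$gold_pairs) else empty_gold_pairs()
    s <- structure(
      list(sentence_id = x$sentence_id, raw_text = x$raw_text, text = x$text,
           tokens = x$tokens, mentions = as.data.frame(x$mentions),
           gold_pairs = canonicalize_pairs(gp),
           candidate = nrow(as.data.frame(x$mentions)) >= 2L),
      class = "ppi_sentence")
    s
  })
  structure(out, class = "ppi_corpus")
}

#' Read a corpus from plain text plus standoff mention annotations
#'
#' Second input dialect: a sentences TSV (\code{sentence_id}, \code{text})
#' plus a standoff TSV (\code{sentence_id}, \code{start}, \code{end},
#' \code{surface}) with 0-based half-open character offsets. No gold pairs
#' are carried by this dialect.
#' @param sentences_path,standoff_path TSV paths.
#' @return A \code{ppi_corpus}.
#' @export
read_standoff_corpus <- function(sentences_path, standoff_path) {
  sents <- utils::read.delim(sentences_path, stringsAsFactors = FALSE)
  ann <- utils::read.delim(standoff_path, stringsAsFactors = FALSE)
  stopifnot(all(c("sentence_id", "text") %in% names(sents)),
            all(c("sentence_id", "start", "end") %in% names(ann)))
  out <- lapply(seq_len(nrow(sents)), function(i) {
    sid <- sents$sentence_id[i]
    a <- ann[ann$sentence_id == sid, , drop = FALSE]
    mentions <- data.frame(
      mention_id = paste0(sid, ".e", seq_len(nrow(a))),
      start = a$start + 1L,      # 0-based half-open -> 1-based inclusive
      end = a$end,
      stringsAsFactors = FALSE
    )
    annotated_sentence(sid, sents$text[i], mentions)
  })
  structure(out, class = "ppi_corpus")
}
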