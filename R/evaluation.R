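# Per-instance and per-relation precision/recall/F evaluation.
#
# An *instance* is one candidate pair occurrence in one sentence. A
# *relation* is the corpus-wide distinct protein pair (by normalized entity
# key): one predicted-positive instance makes the relation predicted
# positive, and one gold-positive instance makes it gold positive. MIpR
# ("minimum instances per relation") stratification keeps only relations
# with at least k instances; gold-positive relations must additionally have
# at least k gold-positive instances.

#' Precision/recall/F from confusion counts
#'
#' Precision = TP/(TP+FP), Recall = TP/(TP+FN),
#' F = 2 * Recall * Precision / (Recall + Precision). The 0/0 conventions:
#' precision is 0 when TP+FP = 0, recall is 0 when TP+FN = 0, F is 0 when
#' P+R = 0; hence all three are 0 whenever TP = 0.
#'
#' @param tp,fp,fn Non-negative counts.
#' @param level \code{"instance"} or \code{"relation"} (metadata only).
#' @return Object of class \code{eval_result}: list with \code{tp},
#'   \code{fp}, \code{fn}, \code{level}, \code{precision}, \code{recall},
#'   \code{f_score}.
#' @export
eval_result <- function(tp, fp, fn, level = c("instance", "relation")) {
  level <- match.arg(level)
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f_score <- if (precision + recall == 0) 0 else {
    2 * recall * precision / (recall + precision)
  }
  structure(list(tp = tp, fp = fp, fn = fn, level = level,
                 precision = precision, recall = recall, f_score = f_score),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> per-%s  TP=%d FP=%d FN=%d  P=%.3f R=%.3f F=%.3f\n",
              x$level, x$tp, x$fp, x$fn, x$precision, x$recall, x$f_score))
  invisible(x)
}

#' Flatten a corpus into a gold instance table
#'
#' One row per gold-labeled candidate pair, with the corpus-wide relation
#' key (canonical ordering of the two entity keys, so orientation never
#' matters).
#' @param corpus A \code{ppi_corpus}.
#' @param per_document If \code{TRUE}, scope relation identity to the
#'   document/sentence-id prefix instead of the whole corpus.
#' @return Data frame: \code{sentence_id}, \code{e1}, \code{e2},
#'   \code{relation_key}, \code{gold}.
#' @export
corpus_instances <- function(corpus, per_document = FALSE) {
  rows <- lapply(corpus, function(s) {
    gp <- s$gold_pairs
    if (!nrow(gp)) return(NULL)
    key <- vapply(seq_len(nrow(gp)), function(i) {
      k1 <- s$mentions$entity_key[s$mentions$mention_id == gp$e1[i]]
      k2 <- s$mentions$entity_key[s$mentions$mention_id == gp$e2[i]]
      relation_key(k1, k2)
    }, character(1))
    if (per_document) {
      key <- paste(sub("\\..*$", "", s$sentence_id), key, sep = "::")
    }
    data.frame(sentence_id = s$sentence_id, e1 = gp$e1, e2 = gp$e2,
               relation_key = key, gold = gp$label, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(sentence_id = character(0), e1 = character(0),
                      e2 = character(0), relation_key = character(0),
                      gold = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Canonical relation key of two entity keys
#' @param k1,k2 Entity key strings.
#' @return Single string, identical for either argument order.
#' @export
relation_key <- function(k1, k2) {
  paste(sort(c(k1, k2)), collapse = "|")
}

# Join predictions onto gold instances by (sentence_id, e1, e2); pairs are
# matched orientation-free. Gold instances without a prediction are treated
# as predicted negative; a prediction without a gold counterpart is an
# input-mismatch error.
join_predictions <- function(predictions, gold) {
  canon <- function(df) {
    swap <- df$e1 > df$e2
    tmp <- df$e1[swap]; df$e1[swap] <- df$e2[swap]; df$e2[swap] <- tmp
    df$key <- paste(df$sentence_id, df$e1, df$e2)
    df
  }
  g <- canon(gold)
  p <- canon(predictions)
  if (anyDuplicated(p$key)) stop("duplicate prediction for an instance")
  unknown <- setdiff(p$key, g$key)
  if (length(unknown)) {
    stop("input-mismatch: prediction without gold counterpart: ",
         paste(utils::head(unknown, 3), collapse = "; "))
  }
  g$pred <- p$label[match(g$key, p$key)]
  g$pred[is.na(g$pred)] <- "negative"
  g$key <- NULL
  g
}

#' Per-instance evaluation
#'
#' Counts TP (predicted positive, gold positive), FP (predicted positive,
#' gold negative) and FN (predicted negative, gold positive) over
#' instances.
#' @param predictions Predictions data frame (\code{sentence_id},
#'   \code{e1}, \code{e2}, \code{label}).
#' @param gold Gold instance table from [corpus_instances()].
#' @return An [eval_result()] at instance level.
#' @export
per_instance_eval <- function(predictions, gold) {
  j <- join_predictions(predictions, gold)
  eval_result(tp = sum(j$pred == "positive" & j$gold == "positive"),
              fp = sum(j$pred == "positive" & j$gold == "negative"),
              fn = sum(j$pred == "negative" & j$gold == "positive"),
              level = "instance")
}

#' Aggregate instance labels to relation labels
#'
#' One positive instance makes the relation positive, on both the gold and
#' the predicted side.
#' @param joined Instance table with columns \code{relation_key},
#'   \code{gold}, \code{pred}.
#' @return Data frame: \code{relation_key}, \code{gold}, \code{pred}
#'   (one row per distinct relation).
#' @export
aggregate_relations <- function(joined) {
  keys <- sort(unique(joined$relation_key))
  gold <- vapply(keys, function(k)
    any(joined$gold[joined$relation_key == k] == "positive"), logical(1))
  pred <- vapply(keys, function(k)
    any(joined$pred[joined$relation_key == k] == "positive"), logical(1))
  data.frame(relation_key = keys,
             gold = ifelse(gold, "positive", "negative"),
             pred = ifelse(pred, "positive", "negative"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-relation evaluation
#'
#' Applies [aggregate_relations()] and computes precision/recall/F over
#' distinct relations.
#' @inheritParams per_instance_eval
#' @return An [eval_result()] at relation level.
#' @export
per_relation_eval <- function(predictions, gold) {
  rel <- aggregate_relations(join_predictions(predictions, gold))
  eval_result(tp = sum(rel$pred == "positive" & rel$gold == "positive"),
              fp = sum(rel$pred == "positive" & rel$gold == "negative"),
              fn = sum(rel$pred == "negative" & rel$gold == "positive"),
              level = "relation")
}

#' MIpR stratification of a gold instance table
#'
#' Keeps a relation (and all its instances) iff it has at least \code{k}
#' instances; when \code{require_k_positive} and the relation is gold
#' positive, it must additionally have at least \code{k} gold-positive
#' instances. Gold-negative relations are filtered on total instance count
#' only. \code{k = 1} is the identity.
#'
#' @param gold Gold instance table from [corpus_instances()].
#' @param k Minimum instances per relation (>= 1).
#' @param require_k_positive Apply the positive-instance constraint to
#'   gold-positive relations (default \code{TRUE}).
#' @return The surviving subset of \code{gold}.
#' @export
filter_mipr <- function(gold, k, require_k_positive = TRUE) {
  stopifnot(k >= 1L)
  if (k == 1L) return(gold)
  counts <- table(gold$relation_key)
  pos_counts <- table(gold$relation_key[gold$gold == "positive"])
  keep_key <- vapply(names(counts), function(key) {
    n <- counts[[key]]
    npos <- if (key %in% names(pos_counts)) pos_counts[[key]] else 0L
    if (n < k) return(FALSE)
    if (require_k_positive && npos > 0L && npos < k) return(FALSE)
    TRUE
  }, logical(1))
  out <- gold[gold$relation_key %in% names(counts)[keep_key], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate predictions at both levels across MIpR strata
#'
#' @param predictions Predictions data frame.
#' @param gold Gold instance table.
#' @param mipr Integer vector of MIpR values.
#' @param require_k_positive See [filter_mipr()].
#' @return Data frame with one row per stratum: counts and metrics at both
#'   levels.
#' @export
evaluate_strata <- function(predictions, gold, mipr = 1L,
                            require_k_positive = TRUE) {
  rows <- lapply(mipr, function(k) {
    g <- filter_mipr(gold, k, require_k_positive)
    p <- predictions[paste(predictions$sentence_id, predictions$e1,
                           predictions$e2) %in%
                       paste(g$sentence_id, g$e1, g$e2), , drop = FALSE]
    ri <- per_instance_eval(p, g)
    rr <- per_relation_eval(p, g)
    rel <- aggregate_relations(join_predictions(p, g))
    data.frame(mipr = k,
               pos_relations = sum(rel$gold == "positive"),
               neg_relations = sum(rel$gold == "negative"),
               pos_instances = sum(g$gold == "positive"),
               neg_instances = sum(g$gold == "negative"),
               rel_tp = rr$tp, rel_fp = rr$fp,
               rel_precision = rr$precision, rel_recall = rr$recall,
               rel_f = rr$f_score,
               inst_tp = ri$tp, inst_fp = ri$fp,
               inst_precision = ri$precision, inst_recall = ri$recall,
               inst_f = ri$f_score)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a fixed-width comparison table across systems and MIpR strata
#'
#' @param results Named list: system name -> data frame from
#'   [evaluate_strata()]. Empty strata render as dashes.
#' @return Character vector of table lines (also printed invisibly usable
#'   with \code{cat}).
#' @export
pooled_report <- function(results) {
  fmt_num <- function(x) {
    ifelse(is.na(x), "-", formatC(round(x, 3), format = "g", digits = 3))
  }
  lines <- sprintf("%-4s %-12s %6s %6s %9s %8s %8s %7s %7s %9s %8s %8s",
                   "MIpR", "system", "relTP", "relFP", "relPrec", "relRec",
                   "relF", "insTP", "insFP", "insPrec", "insRec", "insF")
  all_mipr <- sort(unique(unlist(lapply(results, function(r) r$mipr))))
  for (k in all_mipr) {
    for (sys in names(results)) {
      r <- results[[sys]]
      row <- r[r$mipr == k, , drop = FALSE]
      if (!nrow(row) || (row$pos_relations + row$neg_relations) == 0) {
        lines <- c(lines, sprintf("%-4d %-12s %6s", k, sys,
                                  paste(rep("-", 10), collapse = " ")))
        next
      }
      lines <- c(lines, sprintf(
        "%-4d %-12s %6d %6d %9s %8s %8s %7d %7d %9s %8s %8s",
        k, sys, row$rel_tp, row$rel_fp, fmt_num(row$rel_precision),
        fmt_num(row$rel_recall), fmt_num(row$rel_f), row$inst_tp,
        row$inst_fp, fmt_num(row$inst_precision), fmt_num(row$inst_recall),
        fmt_num(row$inst_f)))
    }
  }
  lines
}
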