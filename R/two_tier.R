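# Two-tier extraction: any two classifiers pipelined so that instances
# rejected by the first tier are re-screened by the second, and the
# positives of either tier are final positives. Classifiers follow a small
# contract (fit/predict closures) so that rule-based, feature-threshold and
# precomputed-label tiers are interchangeable.

#' Construct a classifier satisfying the tier contract
#'
#' @param name Display name.
#' @param predict_fn \code{function(state, instances)} returning a character
#'   vector of \code{"positive"}/\code{"negative"} labels, one per row of
#'   \code{instances} (a data frame with id columns \code{sentence_id},
#'   \code{e1}, \code{e2} and arbitrary further columns). Must be
#'   deterministic given \code{state}.
#' @param fit_fn Optional \code{function(instances, labels)} returning the
#'   fitted state; rule-based classifiers ignore fitting.
#' @param state Initial (or pre-fitted) state.
#' @return Object of class \code{ppi_classifier}.
#' @export
ppi_classifier <- function(name, predict_fn, fit_fn = NULL, state = NULL) {
  structure(list(name = name, predict_fn = predict_fn, fit_fn = fit_fn,
                 state = state),
            class = "ppi_classifier")
}

#' @export
print.ppi_classifier <- function(x, ...) {
  cat("<ppi_classifier> ", x$name,
      if (is.null(x$fit_fn)) " (rule-based / fixed)" else "", "\n", sep = "")
  invisible(x)
}

#' Fit a classifier on labeled instances
#' @param clf A \code{ppi_classifier}.
#' @param instances Instance data frame.
#' @param labels Character vector of gold labels aligned to \code{instances}.
#' @return The classifier with fitted state.
#' @export
fit_classifier <- function(clf, instances, labels) {
  if (!is.null(clf$fit_fn)) clf$state <- clf$fit_fn(instances, labels)
  clf
}

#' Predict labels for instances
#' @param clf A (fitted) \code{ppi_classifier}.
#' @param instances Instance data frame.
#' @return Character vector of labels.
#' @export
predict_classifier <- function(clf, instances) {
  out <- clf$predict_fn(clf$state, instances)
  stopifnot(length(out) == nrow(instances),
            all(out %in% c("positive", "negative")))
  out
}

#' The rule engine as a tier classifier
#'
#' Precomputes rule-engine predictions for the corpus and serves them by
#' instance id; instances outside the corpus are negative.
#' @param corpus,trees,config,lexicon As in [extract_corpus()].
#' @return A \code{ppi_classifier}.
#' @export
rules_classifier <- function(corpus, trees, config = rule_config(),
                             lexicon = load_default_lexicon()) {
  preds <- extract_corpus(corpus, trees, config, lexicon)
  key <- paste(preds$sentence_id, pmin(preds$e1, preds$e2),
               pmax(preds$e1, preds$e2))
  lut <- stats::setNames(preds$label, key)
  ppi_classifier("rules", predict_fn = function(state, instances) {
    k <- paste(instances$sentence_id, pmin(instances$e1, instances$e2),
               pmax(instances$e1, instances$e2))
    out <- unname(state[k])
    out[is.na(out)] <- "negative"
    out
  }, state = lut)
}

#' A tier backed by a file (or data frame) of precomputed labels
#'
#' Splices in the output of an external system (same TSV schema as
#' [write_predictions_tsv()]) as a pipeline tier without reimplementing it.
#' @param predictions Data frame or TSV path.
#' @param name Display name.
#' @return A \code{ppi_classifier}.
#' @export
fixed_labels_classifier <- function(predictions, name = "external") {
  if (is.character(predictions)) predictions <- read_predictions_tsv(predictions)
  key <- paste(predictions$sentence_id,
               pmin(predictions$e1, predictions$e2),
               pmax(predictions$e1, predictions$e2))
  lut <- stats::setNames(predictions$label, key)
  ppi_classifier(name, predict_fn = function(state, instances) {
    k <- paste(instances$sentence_id, pmin(instances$e1, instances$e2),
               pmax(instances$e1, instances$e2))
    out <- unname(state[k])
    out[is.na(out)] <- "negative"
    out
  }, state = lut)
}

#' The always-negative classifier (pipeline identity element)
#' @return A \code{ppi_classifier} labeling everything negative.
#' @export
always_negative_classifier <- function() {
  ppi_classifier("always-negative", predict_fn = function(state, instances) {
    rep("negative", nrow(instances))
  })
}

#' Pipeline two classifiers
#'
#' Tier 1 labels every instance; instances it rejects are re-screened by
#' tier 2. The predicted-positive set is the union of tier-1 positives and
#' tier-2 positives among tier-1 negatives, so pipelining never flips a
#' tier-1 positive to negative. If tier 2 fails, its instances inherit the
#' tier-1 label (with a warning).
#'
#' @param tier1,tier2 Fitted \code{ppi_classifier}s.
#' @param instances Instance data frame (id columns \code{sentence_id},
#'   \code{e1}, \code{e2}).
#' @return \code{instances} with added columns \code{label} and \code{tier}
#'   (1 or 2 for the tier that produced a positive, \code{NA} for
#'   negatives).
#' @export
pipeline <- function(tier1, tier2, instances) {
  p1 <- predict_classifier(tier1, instances)
  label <- p1
  tier <- ifelse(p1 == "positive", 1L, NA_integer_)
  rejected <- which(p1 == "negative")
  if (length(rejected)) {
    p2 <- tryCatch(
      predict_classifier(tier2, instances[rejected, , drop = FALSE]),
      error = function(e) {
        warning("tier-2 classifier failed (", conditionMessage(e),
                "); rejected instances keep the tier-1 label", call. = FALSE)
        rep("negative", length(rejected))
      })
    hit <- rejected[p2 == "positive"]
    label[hit] <- "positive"
    tier[hit] <- 2L
  }
  out <- instances
  out$label <- label
  out$tier <- tier
  out
}

# ---- dependency-chain features ---------------------------------------------

#' Forward and backward dependency chains of a pair
#'
#' The forward chain is the root-to-first-protein path of the dependency
#' tree, the backward chain the root-to-second-protein path, both over
#' non-propagated edges, as (label, lemma) element tables.
#' @param tree A \code{dep_tree}.
#' @param pair A row of [enumerate_candidates()].
#' @return List with \code{forward} and \code{backward} chain data frames
#'   (see [tree_path()]).
#' @export
extract_chains <- function(tree, pair) {
  list(forward = tree_path(tree, pair$t1),
       backward = tree_path(tree, pair$t2))
}

#' Bigrams of a dependency chain
#'
#' Adjacent element pairs of the chain, each element rendered as
#' "label/lemma" (optionally labels or lemmas only). A chain with fewer
#' than two elements has no bigrams.
#' @param chain Chain data frame from [tree_path()].
#' @param render One of \code{"both"}, \code{"label"}, \code{"lemma"}.
#' @return Character vector of bigram strings.
#' @export
chain_bigrams <- function(chain, render = c("both", "label", "lemma")) {
  render <- match.arg(render)
  n <- nrow(chain)
  if (n < 2L) return(character(0))
  el <- switch(render,
               both = paste(chain$label, chain$lemma, sep = "/"),
               label = chain$label,
               lemma = chain$lemma)
  paste(el[-n], el[-1L], sep = " ")
}

#' Per-instance chain features of a corpus
#'
#' For every candidate pair of every parsed sentence: the forward/backward
#' chain bigrams, the two dependency lengths (edge counts of the chains)
#' and the surface offset distance (second minus first protein token
#' index; adjacent proteins have distance 1).
#' @param corpus A \code{ppi_corpus}.
#' @param trees Named list of \code{dep_tree}.
#' @param render Bigram rendering (see [chain_bigrams()]).
#' @return Data frame with id columns and list-columns
#'   \code{forward_bigrams}, \code{backward_bigrams}, plus \code{fwd_len},
#'   \code{bwd_len}, \code{offset}.
#' @export
build_chain_features <- function(corpus, trees, render = "both") {
  rows <- list()
  for (s in corpus) {
    cand <- enumerate_candidates(s)
    if (!nrow(cand)) next
    tree <- trees[[s$sentence_id]]
    if (!is.null(tree)) tree <- collapse_ud(tree)
    for (i in seq_len(nrow(cand))) {
      if (is.null(tree)) {
        fwd <- bwd <- data.frame(label = character(0), lemma = character(0))
      } else {
        ch <- extract_chains(tree, cand[i, ])
        fwd <- ch$forward
        bwd <- ch$backward
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sentence_id = s$sentence_id, e1 = cand$e1[i], e2 = cand$e2[i],
        fwd_len = nrow(fwd), bwd_len = nrow(bwd),
        offset = cand$t2[i] - cand$t1[i], stringsAsFactors = FALSE)
      rows[[length(rows)]]$forward_bigrams <- list(chain_bigrams(fwd, render))
      rows[[length(rows)]]$backward_bigrams <- list(chain_bigrams(bwd, render))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select the top-n forward and backward chain bigrams
#'
#' Forward bigrams are ranked by (occurrences in forward chains minus
#' occurrences of the same bigram in backward chains), descending;
#' backward bigrams symmetrically. Ties are broken by higher raw
#' same-direction count, then lexicographically, so selection is
#' deterministic and invariant to instance order.
#'
#' @param chain_features Data frame from [build_chain_features()].
#' @param n Number of bigrams kept per direction (default 100).
#' @param use_dep_lengths,use_offset_distance Include the two dependency
#'   lengths / the offset distance as extra features.
#' @return Object of class \code{feature_spec}.
#' @export
select_top_features <- function(chain_features, n = 100L,
                                use_dep_lengths = FALSE,
                                use_offset_distance = FALSE) {
  fcount <- table(unlist(chain_features$forward_bigrams))
  bcount <- table(unlist(chain_features$backward_bigrams))
  rank_side <- function(own, other) {
    grams <- names(own)
    if (!length(grams)) return(character(0))
    score <- as.integer(own) -
      as.integer(ifelse(grams %in% names(other), other[grams], 0L))
    ord <- order(-score, -as.integer(own), grams, method = "radix")
    grams[ord][seq_len(min(n, length(grams)))]
  }
  structure(list(top_forward = rank_side(fcount, bcount),
                 top_backward = rank_side(bcount, fcount),
                 use_dep_lengths = use_dep_lengths,
                 use_offset_distance = use_offset_distance),
            class = "feature_spec")
}

#' Serialize / load a feature specification as JSON
#' @param spec A \code{feature_spec}.
#' @param path JSON file path.
#' @return \code{path} (write) / a \code{feature_spec} (read).
#' @export
write_feature_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_spec
#' @export
read_feature_spec <- function(path) {
  x <- jsonlite::fromJSON(path)
  structure(list(top_forward = as.character(x$top_forward),
                 top_backward = as.character(x$top_backward),
                 use_dep_lengths = isTRUE(x$use_dep_lengths),
                 use_offset_distance = isTRUE(x$use_offset_distance)),
            class = "feature_spec")
}

#' Featurize instances under a feature specification
#'
#' Binary presence indicators for the selected forward and backward
#' bigrams (fixed dimension and column order given by the spec), followed
#' by the optional dependency-length and offset-distance columns.
#' @param chain_features Data frame from [build_chain_features()].
#' @param spec A \code{feature_spec}.
#' @return Numeric matrix, one row per instance.
#' @export
featurize <- function(chain_features, spec) {
  nf <- length(spec$top_forward)
  nb <- length(spec$top_backward)
  m <- matrix(0, nrow = nrow(chain_features),
              ncol = nf + nb + 2L * spec$use_dep_lengths +
                1L * spec$use_offset_distance)
  colnames(m) <- c(if (nf) paste0("f:", spec$top_forward),
                   if (nb) paste0("b:", spec$top_backward),
                   if (spec$use_dep_lengths) c("fwd_len", "bwd_len"),
                   if (spec$use_offset_distance) "offset")
  for (i in seq_len(nrow(chain_features))) {
    if (nf) m[i, seq_len(nf)] <-
        as.numeric(spec$top_forward %in% chain_features$forward_bigrams[[i]])
    if (nb) m[i, nf + seq_len(nb)] <-
        as.numeric(spec$top_backward %in% chain_features$backward_bigrams[[i]])
  }
  extra <- nf + nb
  if (spec$use_dep_lengths) {
    m[, extra + 1L] <- chain_features$fwd_len
    m[, extra + 2L] <- chain_features$bwd_len
    extra <- extra + 2L
  }
  if (spec$use_offset_distance) m[, extra + 1L] <- chain_features$offset
  m
}

#' Reference feature-count threshold classifier
#'
#' A deliberately simple deterministic stand-in for an ML tier: an
#' instance is positive when its count of active selected-bigram features
#' reaches a threshold. Fitting scans all thresholds and keeps the
#' smallest one maximizing training F.
#' @param featurizer \code{function(instances)} returning the bigram
#'   feature matrix for an instance data frame (e.g. a closure over
#'   [build_chain_features()] + [featurize()]).
#' @return A \code{ppi_classifier} (fit before use; unfitted state uses
#'   threshold 1).
#' @export
reference_classifier <- function(featurizer) {
  ppi_classifier(
    "feature-threshold",
    predict_fn = function(state, instances) {
      thr <- if (is.null(state)) 1L else state$threshold
      counts <- rowSums(featurizer(instances))
      ifelse(counts >= thr, "positive", "negative")
    },
    fit_fn = function(instances, labels) {
      counts <- rowSums(featurizer(instances))
      best_thr <- 1L
      best_f <- -1
      for (thr in seq(0L, max(counts, 1L) + 1L)) {
        pred <- counts >= thr
        res <- eval_result(tp = sum(pred & labels == "positive"),
                           fp = sum(pred & labels == "negative"),
                           fn = sum(!pred & labels == "positive"))
        if (res$f_score > best_f + 1e-12) {
          best_f <- res$f_score
          best_thr <- thr
        }
      }
      list(threshold = best_thr)
    })
}
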