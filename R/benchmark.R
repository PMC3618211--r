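# Published benchmark confusion counts of the rule-based system on the
# AIMed corpus (per MIpR stratum, both evaluation levels), shipped as data
# so the reported precision/recall/F figures can be recomputed from raw
# counts with the package's own metric implementation. Reproducing the
# counts themselves requires the external AIMed corpus and is out of scope
# for the bundled fixtures.

#' Benchmark confusion counts of the rule system (AIMed, by MIpR)
#'
#' @return Data frame with one row per MIpR stratum: gold relation and
#'   instance totals plus the rule system's TP/FP at relation and instance
#'   level.
#' @export
benchmark_counts <- function() {
  utils::read.delim(system.file("extdata", "benchmark_counts.tsv",
                                package = "ppirules"),
                    stringsAsFactors = FALSE)
}

#' Recompute benchmark precision/recall/F from the shipped counts
#'
#' Applies [eval_result()] (the package's precision/recall/F definitions)
#' to the raw TP/FP counts and gold totals of [benchmark_counts()], at both
#' evaluation levels. FN is the gold-positive total minus TP.
#' @return Data frame: \code{mipr}, \code{level}, \code{tp}, \code{fp},
#'   \code{fn}, \code{precision}, \code{recall}, \code{f_score}.
#' @export
recompute_benchmark_metrics <- function() {
  b <- benchmark_counts()
  rows <- list()
  for (i in seq_len(nrow(b))) {
    rel <- eval_result(b$rel_tp[i], b$rel_fp[i],
                       b$pos_relations[i] - b$rel_tp[i], level = "relation")
    ins <- eval_result(b$inst_tp[i], b$inst_fp[i],
                       b$pos_instances[i] - b$inst_tp[i], level = "instance")
    rows[[length(rows) + 1L]] <- data.frame(
      mipr = b$mipr[i], level = c("relation", "instance"),
      tp = c(rel$tp, ins$tp), fp = c(rel$fp, ins$fp), fn = c(rel$fn, ins$fn),
      precision = c(rel$precision, ins$precision),
      recall = c(rel$recall, ins$recall),
      f_score = c(rel$f_score, ins$f_score))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
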