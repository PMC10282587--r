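#' Default assembly ranking scheme
#'
#' The seven classic assembly-evaluation metrics with their optimization
#' directions and unit weights: N50 (higher better), percent difference
#' to the predicted genome size (lower better), mean scaffold length
#' (higher), scaffold count (lower), BUSCO single-copy complete genes
#' (higher), RNA and DNA read mapping rates (higher).
#'
#' @return data.frame with `metric`, `direction`
#'   (`higher_better`/`lower_better`), `weight`.
#' @export
default_rank_scheme <- function() {
  data.frame(
    metric = c("n50", "size_delta_pct", "mean_scaffold_len",
               "scaffold_count", "busco_single_complete", "rna_map_pct",
               "dna_map_pct"),
    direction = c("higher_better", "lower_better", "higher_better",
                  "lower_better", "higher_better", "higher_better",
                  "higher_better"),
    weight = 1)
}

#' Rank assemblies by weighted metric ranks
#'
#' Each metric column is ranked (1 = best in the metric's direction,
#' ties averaged), ranks are combined as a weighted sum, and assemblies
#' are ordered by ascending score (ties broken lexicographically by id).
#'
#' @param table data.frame of metrics; assembly ids either in an
#'   `assembly` column or as row names; remaining columns numeric.
#' @param scheme data.frame like [default_rank_scheme()]; every scheme
#'   metric must be a column of `table` and at least one weight must be
#'   positive.
#' @return Object of class `rank_result`: data.frame with `assembly`,
#'   one `rank_<metric>` column per metric, `score`, and `final_rank`,
#'   sorted best-first.
#' @export
rank_assemblies <- function(table, scheme = default_rank_scheme()) {
  table <- as.data.frame(table)
  if ("assembly" %in% names(table)) {
    ids <- as.character(table$assembly)
    table <- table[setdiff(names(table), "assembly")]
  } else {
    ids <- rownames(table)
  }
  if (anyDuplicated(ids)) stop("duplicate assembly ids")
  if (!all(c("metric", "direction", "weight") %in% names(scheme)))
    stop("scheme needs metric, direction and weight columns")
  if (all(scheme$weight == 0)) stop("all scheme weights are zero")
  if (any(scheme$weight < 0)) stop("negative weight")
  missing_m <- setdiff(scheme$metric, names(table))
  if (length(missing_m))
    stop("metric(s) missing from table: ", paste(missing_m, collapse = ", "))

  ranks <- sapply(seq_len(nrow(scheme)), function(i) {
    x <- table[[scheme$metric[i]]]
    if (any(is.na(x))) stop("missing values in metric ", scheme$metric[i])
    if (scheme$direction[i] == "higher_better") rank(-x) else rank(x)
  })
  ranks <- matrix(ranks, nrow = nrow(table))
  colnames(ranks) <- paste0("rank_", scheme$metric)
  score <- as.numeric(ranks %*% scheme$weight)
  out <- data.frame(assembly = ids, ranks, score = score)
  out <- out[order(out$score, out$assembly), , drop = FALSE]
  out$final_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("rank_result", "data.frame")
  out
}

#' @export
print.rank_result <- function(x, ...) {
  cat("rank_result: best assembly", x$assembly[1], "(score",
      format(x$score[1]), ")\n")
  print.data.frame(utils::head(x[c("assembly", "score", "final_rank")], 10))
  invisible(x)
}

#' Percent difference to the predicted genome size
#'
#' @param assembly_size Assembly length (bp).
#' @param predicted_size Predicted genome size (bp), e.g. from a k-mer
#'   profile; must be positive.
#' @return `100 * |assembly_size - predicted_size| / predicted_size`
#'   (smaller is better).
#' @export
size_delta_metric <- function(assembly_size, predicted_size) {
  if (any(predicted_size <= 0)) stop("predicted size must be positive")
  100 * abs(assembly_size - predicted_size) / predicted_size
}
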