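#' Rank features by a method's scores
#'
#' Average-tie ranking in the requested direction: `"ascending"` gives the
#' best (lowest) score rank 1 (used for enrichment q-values),
#' `"descending"` gives the highest score rank 1 (used for the weighted
#' ACE statistic and forest importance).
#'
#' @param scores named numeric vector of finite scores.
#' @param direction `"ascending"` or `"descending"`.
#' @return Named numeric vector of ranks.
#' @export
rank_method <- function(scores, direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  if (any(!is.finite(scores))) stop("scores must be finite")
  r <- if (direction == "ascending") rank(scores, ties.method = "average")
       else rank(-scores, ties.method = "average")
  setNames(as.numeric(r), names(scores))
}

#' Aggregate per-method ranks into a consensus rank
#'
#' Features missing from a method receive that method's maximum rank plus
#' one; the per-method ranks are then summed and the sums ranked ascending
#' with average ties. The consensus depends only on the per-method ranks,
#' so it is invariant to any monotone transform of a method's scores.
#'
#' @param rank_list named list of named rank vectors (one per method, e.g.
#'   `enrichment`, `ace`, `forest`); at least one must be nonempty.
#' @param features optional feature universe (defaults to the union of all
#'   ranked features).
#' @return Data frame sorted by consensus rank: `Rank`, `Feature`, one
#'   `rank_<method>` column per method, and `rank_sum`.
#' @export
consensus_rank <- function(rank_list, features = NULL) {
  rank_list <- rank_list[vapply(rank_list, length, integer(1)) > 0]
  if (length(rank_list) == 0) stop("at least one method must provide ranks")
  if (is.null(features))
    features <- sort(unique(unlist(lapply(rank_list, names))))
  filled <- lapply(rank_list, function(r) {
    penalty <- max(r) + 1
    out <- setNames(rep(penalty, length(features)), features)
    out[intersect(features, names(r))] <- r[intersect(features, names(r))]
    out
  })
  rank_sum <- Reduce(`+`, filled)
  out <- data.frame(Feature = features, stringsAsFactors = FALSE)
  for (m in names(filled)) out[[paste0("rank_", m)]] <- unname(filled[[m]])
  out$rank_sum <- unname(rank_sum)
  out$Rank <- rank(out$rank_sum, ties.method = "average")
  out <- out[order(out$Rank, out$Feature), ]
  rownames(out) <- NULL
  out[, c("Rank", "Feature", paste0("rank_", names(filled)), "rank_sum")]
}
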