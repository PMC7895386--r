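#' Patristic distance matrix between trait-positive and trait-negative genomes
#'
#' Computes the positives x negatives block of the patristic (sum of branch
#' lengths) distance matrix of a tree. This is the synthetic stand-in for
#' the alignment-derived distance matrices used with real data.
#'
#' Distances are rounded to 1e-8 substitutions/site: ultrametric trees
#' produce many exactly tied distances, and rounding keeps those ties exact
#' whether the tree was held in memory or round-tripped through newick, so
#' the deterministic tie-break of [select_pairs()] gives identical pairings.
#'
#' @param tree an [ape::phylo] tree.
#' @param positives,negatives leaf labels of the two groups.
#' @return Numeric matrix with positives as rows and negatives as columns.
#' @export
patristic_distances <- function(tree, positives, negatives) {
  stopifnot(all(c(positives, negatives) %in% tree$tip.label))
  d <- ape::cophenetic.phylo(tree)
  round(d[positives, negatives, drop = FALSE], 8)
}

#' Greedily pair each trait-positive genome with its closest unused negative
#'
#' Iteratively selects the globally minimal remaining distance cell, removes
#' that cell's row (positive) and column (negative), and repeats until every
#' positive genome is paired. Each positive therefore receives a distinct
#' negative partner, and the first selected pair attains the global minimum
#' distance. Ties are broken lexicographically by (positive accession,
#' negative accession) so the result is deterministic.
#'
#' @param d distance matrix: rows = positive accessions, columns = negative
#'   accessions, non-negative finite cells.
#' @return Data frame `positive`, `negative`, `distance` in selection order.
#' @export
select_pairs <- function(d) {
  if (is.null(dim(d)) || is.null(rownames(d)) || is.null(colnames(d)))
    stop("d must be a matrix with row and column names")
  if (ncol(d) < nrow(d))
    stop("fewer trait-negative candidates (", ncol(d),
         ") than trait-positive genomes (", nrow(d), ")")
  if (any(!is.finite(d)) || any(d < 0))
    stop("distances must be finite and non-negative")
  n <- nrow(d)
  pos <- character(n); neg <- character(n); dist <- numeric(n)
  for (k in seq_len(n)) {
    hits <- which(d == min(d), arr.ind = TRUE)
    # lexicographic tie-break on (positive, negative) accession
    ord <- order(rownames(d)[hits[, 1]], colnames(d)[hits[, 2]])
    i <- hits[ord[1], 1]; j <- hits[ord[1], 2]
    pos[k] <- rownames(d)[i]; neg[k] <- colnames(d)[j]; dist[k] <- d[i, j]
    d <- d[-i, -j, drop = FALSE]
  }
  data.frame(positive = pos, negative = neg, distance = dist,
             stringsAsFactors = FALSE)
}

#' Summarize pair distances
#'
#' @param pairs data frame from [select_pairs()] (or any data frame with a
#'   `distance` column).
#' @return A list: `median`, `mean`, `n`.
#' @export
summarize_pair_distances <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0) stop("no pairs to summarize")
  list(median = median(pairs$distance), mean = mean(pairs$distance),
       n = nrow(pairs))
}
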