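# Feature ids excluded by default from enrichment: the trait-defining
# marker enzymes/domains themselves (Rubisco, Prk), which are present in
# trait-positive genomes by construction. Both the bare ids and an "EC "
# prefix are recognized.
.DEFAULT_EXCLUDE <- c("2.7.1.19", "4.1.1.39",
                      "PF02788", "PF00016", "PF00101", "PF00485")

#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum test with average ranks for ties: the exact null distribution
#' is enumerated when `length(x) + length(y) <= 20` and there are no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used. Copy-number data are massively tied, so the
#' approximate path dominates in practice.
#'
#' @param x,y nonempty numeric vectors.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be nonempty")
  if (length(unique(c(x, y))) == 1) return(1)  # degenerate: no rank information
  exact <- (length(x) + length(y) <= 20) && !anyDuplicated(c(x, y))
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order (monotone step-up, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-feature copy-number enrichment between trait groups
#'
#' Compares each gene family's copy-number distribution between
#' trait-positive and trait-negative genomes with a Wilcoxon rank-sum test,
#' adjusting across all features (ECs and Pfams jointly) by
#' Benjamini-Hochberg. Genomes below the completeness threshold are
#' excluded first; the trait-defining marker features are excluded by
#' default since they are present in positives by construction. Features
#' never observed in any retained genome are dropped from the testing pool.
#'
#' @param genomes genome data frame with `accession`, `trait_status`,
#'   `completeness`.
#' @param matrix integer genomes x features copy-number matrix.
#' @param completeness_min completeness threshold in percent (default 95).
#' @param exclude_features feature ids to remove before testing.
#' @return Data frame sorted by ascending q with columns `Rank` (average
#'   ties), `Feature_Type`, `Feature`, `mean_Negative`, `mean_Positive`,
#'   `CV_Negative`, `CV_Positive` (SD/mean; `NaN` when the group mean is 0),
#'   `log2_ratio` (`Inf`/`-Inf` sentinels when one group mean is 0), `p`, `q`.
#' @export
run_enrichment <- function(genomes, matrix, completeness_min = 95,
                           exclude_features = .DEFAULT_EXCLUDE) {
  keep <- genomes$completeness >= completeness_min
  g <- genomes[keep, , drop = FALSE]
  pos <- g$accession[g$trait_status == "positive"]
  neg <- g$accession[g$trait_status == "negative"]
  if (length(pos) == 0 || length(neg) == 0)
    stop("a trait group is empty after the completeness filter")
  excl <- unique(c(exclude_features, paste("EC", exclude_features)))
  feats <- setdiff(colnames(matrix), excl)
  m <- matrix[c(pos, neg), feats, drop = FALSE]
  feats <- feats[colSums(m) > 0]                 # only features observed >= 1 time
  if (length(feats) == 0) stop("no observed features to test")
  mp <- matrix[pos, feats, drop = FALSE]
  mn <- matrix[neg, feats, drop = FALSE]
  mean_pos <- colMeans(mp); mean_neg <- colMeans(mn)
  cv <- function(m, mu) apply(m, 2, sd) / mu     # NaN where mean is 0
  p <- vapply(seq_along(feats),
              function(j) wilcoxon_rank_sum(mp[, j], mn[, j]), numeric(1))
  q <- bh_adjust(p)
  res <- data.frame(
    Feature_Type  = feature_types(feats),
    Feature       = feats,
    mean_Negative = unname(mean_neg),
    mean_Positive = unname(mean_pos),
    CV_Negative   = unname(cv(mn, mean_neg)),
    CV_Positive   = unname(cv(mp, mean_pos)),
    log2_ratio    = unname(log2(mean_pos / mean_neg)),
    p = p, q = q, stringsAsFactors = FALSE
  )
  res$Rank <- rank(res$q, ties.method = "average")
  res <- res[order(res$q, res$Feature), ]
  rownames(res) <- NULL
  res[, c("Rank", "Feature_Type", "Feature", "mean_Negative", "mean_Positive",
          "CV_Negative", "CV_Positive", "log2_ratio", "p", "q")]
}
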