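# Ancestral character estimation on similarity-selected subtrees:
# 2-state Mk trait likelihoods, Brownian-motion ancestral copy numbers,
# per-subtree Spearman/Wilcoxon testing, and the q-value-weighted
# sum-of-|r| summary used for ranking.

#' Enumerate candidate subtrees by leaf count
#'
#' Returns every internal node whose clade contains between `min_taxa` and
#' `max_taxa` leaves, with its leaf set.
#'
#' @param tree a rooted [ape::phylo] tree.
#' @param min_taxa,max_taxa inclusive leaf-count bounds (defaults 50, 300).
#' @return A list with one element per candidate: `node` (ape node number)
#'   and `leaves` (character vector of leaf labels). May be empty.
#' @export
enumerate_subtrees <- function(tree, min_taxa = 50, max_taxa = 300) {
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  leafsets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) leafsets[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    pa <- po$edge[e, 1]; ch <- po$edge[e, 2]
    leafsets[[pa]] <- c(leafsets[[pa]], leafsets[[ch]])
  }
  out <- list()
  for (v in (ntip + 1):(ntip + tree$Nnode)) {
    n <- length(leafsets[[v]])
    if (n >= min_taxa && n <= max_taxa)
      out[[length(out) + 1L]] <- list(node = v, leaves = leafsets[[v]])
  }
  out
}

#' Summary statistics of a (sub)tree for similarity scoring
#'
#' Computes the four quantities entering the subtree similarity score:
#' trait-positive leaf count `P`, trait-negative leaf count `N`, the
#' coefficient of variation `cv` of all edge lengths, and the maximum
#' root-to-tip height `h`.
#'
#' @param tree an [ape::phylo] tree.
#' @param traits named `"positive"`/`"negative"` vector covering the leaves.
#' @param node optional internal node; when given, statistics are computed
#'   on the clade rooted there.
#' @return A list `P`, `N`, `cv`, `h`.
#' @export
subtree_stats <- function(tree, traits, node = NULL) {
  sub <- if (is.null(node)) tree else ape::extract.clade(tree, node)
  lt <- traits[sub$tip.label]
  depths <- ape::node.depth.edgelength(sub)
  list(P = sum(lt == "positive"), N = sum(lt == "negative"),
       cv = sd(sub$edge.length) / mean(sub$edge.length),
       h = max(depths[seq_along(sub$tip.label)]))
}

#' Similarity score between a candidate subtree and a reference tree
#'
#' The four statistics are compared as absolute log-ratios and multiplied
#' into a single score
#' `s = exp(-(|ln(P_B/P_A)| + |ln(N_B/N_A)| + |ln(cv_B/cv_A)| + |ln(h_B/h_A)|))`,
#' which lies in `(0, 1]` and equals 1 only when all four statistics match.
#' The score is symmetric in the two trees.
#'
#' @param stats_b,stats_a lists from [subtree_stats()] for the candidate
#'   subtree and the reference tree; all eight values must be strictly
#'   positive, otherwise the score is undefined and an error is raised.
#' @return Similarity score in `(0, 1]`.
#' @export
score_subtree <- function(stats_b, stats_a) {
  v <- c(stats_b$P, stats_b$N, stats_b$cv, stats_b$h,
         stats_a$P, stats_a$N, stats_a$cv, stats_a$h)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("similarity score undefined: all statistics must be strictly positive")
  exp(-(abs(log(stats_b$P / stats_a$P)) + abs(log(stats_b$N / stats_a$N)) +
          abs(log(stats_b$cv / stats_a$cv)) + abs(log(stats_b$h / stats_a$h))))
}

# All descendant node numbers (internal + tips) of each node, self included.
.descendant_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  sets <- as.list(seq_len(ntip + tree$Nnode))
  for (e in seq_len(nrow(po$edge))) {
    pa <- po$edge[e, 1]; ch <- po$edge[e, 2]
    sets[[pa]] <- c(sets[[pa]], sets[[ch]])
  }
  sets
}

#' Greedily select disjoint subtrees by descending similarity score
#'
#' Repeatedly takes the highest-scoring candidate whose node set (the
#' candidate node and all its descendants, internal nodes and tips) is
#' disjoint from the node sets of already selected subtrees, until no
#' candidate remains. Nested candidates therefore exclude each other. Ties
#' in score are broken by ascending node number for determinism.
#'
#' @param tree the tree the candidates were enumerated on.
#' @param candidates data frame with columns `node` and `s` (scores).
#' @return The selected rows of `candidates`, in selection order.
#' @export
select_subtrees <- function(tree, candidates) {
  if (nrow(candidates) == 0) return(candidates)
  sets <- .descendant_sets(tree)
  ord <- order(-candidates$s, candidates$node)
  used <- logical(length(sets))
  take <- integer(0)
  for (i in ord) {
    nodes <- sets[[candidates$node[i]]]
    if (!any(used[nodes])) {
      used[nodes] <- TRUE
      take <- c(take, i)
    }
  }
  out <- candidates[take, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# symmetric 2-state transition matrix for the equal-rates Mk model
.p_er <- function(q, t) {
  e <- exp(-2 * q * t)
  matrix(c(0.5 + 0.5 * e, 0.5 - 0.5 * e, 0.5 - 0.5 * e, 0.5 + 0.5 * e), 2, 2)
}

#' Marginal ancestral state likelihoods under a 2-state equal-rates Mk model
#'
#' Fits the transition rate by maximum likelihood (Felsenstein pruning for
#' the likelihood; a coarse log-spaced grid over `[1e-8, 1e3]` followed by
#' bounded 1-D refinement) and computes marginal ancestral state
#' likelihoods at every internal node by a two-pass (down/up) algorithm,
#' which for this reversible model is identical to the re-rooting method.
#' Likelihoods are normalized to sum to 1 per node. If every leaf carries
#' the same state the computation short-circuits: that state has
#' likelihood 1 everywhere (the ML rate sits at the boundary 0).
#'
#' @param tree a rooted [ape::phylo] tree with positive branch lengths.
#' @param traits named `"positive"`/`"negative"` vector covering all leaves.
#' @return Data frame with one row per internal node: `node`,
#'   `lik_negative`, `lik_positive`; attributes `rate` (ML rate) and
#'   `loglik`.
#' @export
ace_discrete <- function(tree, traits) {
  ntip <- length(tree$tip.label)
  if (!all(tree$tip.label %in% names(traits)))
    stop("traits must cover all leaves")
  st <- match(traits[tree$tip.label], c("negative", "positive"))
  if (anyNA(st)) stop("traits must be 'positive' or 'negative'")
  nodes <- (ntip + 1):(ntip + tree$Nnode)
  if (length(unique(st)) == 1) {           # degenerate ML: rate at boundary
    lik <- matrix(0, tree$Nnode, 2)
    lik[, unique(st)] <- 1
    out <- data.frame(node = nodes, lik_negative = lik[, 1],
                      lik_positive = lik[, 2])
    attr(out, "rate") <- 0; attr(out, "loglik") <- 0
    return(out)
  }
  po <- ape::reorder.phylo(tree, "postorder")
  N <- ntip + tree$Nnode
  elen <- pmax(po$edge.length, 1e-9)
  down <- function(q) {
    D <- matrix(1, N, 2)
    D[cbind(seq_len(ntip), 3L - st)] <- 0
    logscale <- 0
    for (e in seq_len(nrow(po$edge))) {
      pa <- po$edge[e, 1]; ch <- po$edge[e, 2]
      D[pa, ] <- D[pa, ] * as.vector(.p_er(q, elen[e]) %*% D[ch, ])
      s <- sum(D[pa, ])
      if (s < 1e-100) { D[pa, ] <- D[pa, ] / s; logscale <- logscale + log(s) }
    }
    list(ll = log(sum(0.5 * D[ntip + 1L, ])) + logscale, D = D)
  }
  nll <- function(lq) -down(exp(lq))$ll
  grid <- seq(log(1e-8), log(1e3), length.out = 31)
  vals <- vapply(grid, nll, numeric(1))
  k <- which.min(vals)
  lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
  opt <- optimize(nll, c(lo, hi))
  q <- exp(opt$minimum)
  fit <- down(q)
  D <- fit$D
  # up pass: partial likelihoods of everything outside each node's clade,
  # seeded with the stationary root prior (1/2, 1/2)
  U <- matrix(NA_real_, N, 2)
  U[ntip + 1L, ] <- c(0.5, 0.5)
  pre <- rev(seq_len(nrow(po$edge)))          # parents before children
  kids <- split(seq_len(nrow(po$edge)), po$edge[, 1])
  PD <- t(vapply(seq_len(nrow(po$edge)),
                 function(e) as.vector(.p_er(q, elen[e]) %*% D[po$edge[e, 2], ]),
                 numeric(2)))
  for (e in pre) {
    pa <- po$edge[e, 1]; ch <- po$edge[e, 2]
    if (ch <= ntip) next
    m <- U[pa, ]
    for (e2 in kids[[as.character(pa)]])
      if (e2 != e) m <- m * PD[e2, ]
    u <- as.vector(t(.p_er(q, elen[e])) %*% m)
    U[ch, ] <- u / sum(u)
  }
  marg <- U[nodes, , drop = FALSE] * D[nodes, , drop = FALSE]
  marg <- marg / rowSums(marg)
  if (any(!is.finite(marg))) stop("non-finite ancestral likelihoods")
  out <- data.frame(node = nodes, lik_negative = marg[, 1],
                    lik_positive = marg[, 2])
  attr(out, "rate") <- q
  attr(out, "loglik") <- fit$ll
  out
}

#' Maximum-likelihood ancestral values under Brownian motion
#'
#' Computes the ML ancestral value of a continuous character at every
#' internal node under Brownian motion. The estimates solve the weighted
#' squared-change problem (edge weights = 1 / branch length), a sparse
#' linear system whose solution equals the re-rooted GLS/BM conditional
#' expectation at each node; one factorization serves any number of
#' characters, so `values` may be a matrix of features. Zero-length edges
#' are floored at 1e-9.
#'
#' @param tree a rooted [ape::phylo] tree.
#' @param values named numeric vector over leaves, or a matrix with leaf
#'   labels as row names (one column per character).
#' @return Matrix of ancestral values, internal node numbers as row names,
#'   one column per character.
#' @export
ace_continuous <- function(tree, values) {
  ntip <- length(tree$tip.label)
  x <- as.matrix(values)
  if (is.null(rownames(x))) stop("values must be named by leaf label")
  if (!all(tree$tip.label %in% rownames(x))) stop("values must cover all leaves")
  x <- x[tree$tip.label, , drop = FALSE]
  N <- ntip + tree$Nnode
  w <- 1 / pmax(tree$edge.length, 1e-9)
  pa <- tree$edge[, 1]; ch <- tree$edge[, 2]
  L <- Matrix::sparseMatrix(i = c(pa, ch, pa, ch), j = c(ch, pa, pa, ch),
                            x = c(-w, -w, w, w), dims = c(N, N))
  int <- (ntip + 1):N
  est <- Matrix::solve(L[int, int], -L[int, seq_len(ntip)] %*% x)
  est <- as.matrix(est)
  rownames(est) <- as.character(int)
  colnames(est) <- colnames(x)
  est
}

#' Correlate ancestral trait likelihoods with ancestral feature values
#'
#' For each feature: Spearman correlation (average-rank ties, asymptotic
#' t-approximation p-value) between trait-positive likelihood and ancestral
#' feature value across internal nodes, plus a Wilcoxon rank-sum comparison
#' of ancestral values between nodes classified trait-positive (likelihood
#' strictly > 0.5) and trait-negative. When either class is empty the
#' Wilcoxon p-value is recorded as `NA`.
#'
#' @param lik numeric vector of trait-positive likelihoods over internal
#'   nodes (length >= 4).
#' @param counts matrix of ancestral feature values, rows matching `lik`.
#' @return Data frame per feature: `Feature`, `r`, `p_corr`, `p_wilcox`.
#' @export
correlate_ancestral <- function(lik, counts) {
  counts <- as.matrix(counts)
  if (length(lik) < 4) stop("need at least 4 internal nodes")
  stopifnot(nrow(counts) == length(lik))
  pos <- lik > 0.5
  res <- lapply(seq_len(ncol(counts)), function(j) {
    y <- counts[, j]
    if (sd(y) == 0 || sd(lik) == 0) {
      r <- NA_real_; p_c <- NA_real_
    } else {
      ct <- suppressWarnings(cor.test(lik, y, method = "spearman",
                                      exact = FALSE))
      r <- unname(ct$estimate); p_c <- ct$p.value
    }
    p_w <- if (any(pos) && any(!pos)) wilcoxon_rank_sum(y[pos], y[!pos])
           else NA_real_
    c(r = r, p_corr = p_c, p_wilcox = p_w)
  })
  res <- do.call(rbind, res)
  data.frame(Feature = colnames(counts), r = res[, "r"],
             p_corr = res[, "p_corr"], p_wilcox = res[, "p_wilcox"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the ancestral character estimation stage
#'
#' Enumerates candidate subtrees, scores them against a reference tree,
#' greedily selects a disjoint set, and within each selected subtree
#' estimates ancestral trait likelihoods ([ace_discrete()]) and ancestral
#' copy numbers ([ace_continuous()]), correlating the two per feature.
#' p-values are Benjamini-Hochberg adjusted within each subtree,
#' separately for the correlation and Wilcoxon tests; a feature is
#' significant in a subtree when both q-values fall below `q_sig`.
#'
#' @param tree rooted tree over the analyzed genomes.
#' @param traits named leaf trait vector (`"positive"`/`"negative"`).
#' @param matrix genomes x features copy-number matrix.
#' @param reference reference statistics for the similarity score: a list
#'   from [subtree_stats()], or `NULL` to use the whole input tree.
#' @param min_taxa,max_taxa candidate subtree size bounds.
#' @param q_sig per-subtree dual significance threshold (default 0.001).
#' @return A list: `subtrees` (selected candidates with scores and sizes)
#'   and `results` (long data frame: `Subtree`, `Feature_Type`, `Feature`,
#'   `r`, `Significant`, `p_Correlation`, `q_Correlation`, `p_Wilcox`,
#'   `q_Wilcox`).
#' @export
run_ace <- function(tree, traits, matrix, reference = NULL,
                    min_taxa = 50, max_taxa = 300, q_sig = 0.001) {
  cands <- enumerate_subtrees(tree, min_taxa, max_taxa)
  if (length(cands) == 0)
    return(list(subtrees = data.frame(), results = data.frame()))
  ref <- if (is.null(reference)) subtree_stats(tree, traits) else reference
  cdf <- data.frame(node = vapply(cands, `[[`, integer(1), "node"))
  cdf$n_taxa <- vapply(cands, function(c) length(c$leaves), integer(1))
  cdf$s <- vapply(cands, function(c) {
    st <- subtree_stats(tree, traits, c$node)
    tryCatch(score_subtree(st, ref), error = function(e) NA_real_)
  }, numeric(1))
  cdf <- cdf[is.finite(cdf$s), , drop = FALSE]
  sel <- select_subtrees(tree, cdf)
  if (nrow(sel) == 0)
    return(list(subtrees = sel, results = data.frame()))
  results <- vector("list", nrow(sel))
  for (k in seq_len(nrow(sel))) {
    sub <- ape::extract.clade(tree, sel$node[k])
    lik <- ace_discrete(sub, traits[sub$tip.label])
    anc <- ace_continuous(sub, matrix[sub$tip.label, , drop = FALSE])
    cor_res <- correlate_ancestral(lik$lik_positive, anc)
    cor_res$q_corr <- bh_adjust(cor_res$p_corr)
    cor_res$q_wilcox <- bh_adjust(cor_res$p_wilcox)
    results[[k]] <- data.frame(
      Subtree = k,
      Feature_Type = feature_types(cor_res$Feature),
      Feature = cor_res$Feature,
      r = cor_res$r,
      Significant = as.integer(!is.na(cor_res$q_corr) &
                                 !is.na(cor_res$q_wilcox) &
                                 cor_res$q_corr < q_sig &
                                 cor_res$q_wilcox < q_sig),
      p_Correlation = cor_res$p_corr, q_Correlation = cor_res$q_corr,
      p_Wilcox = cor_res$p_wilcox, q_Wilcox = cor_res$q_wilcox,
      stringsAsFactors = FALSE
    )
  }
  list(subtrees = sel, results = do.call(rbind, results))
}

# q-value weight: ln(q_n + q_med) / ln(q_med), clamped to [0, 1]. q_med is
# clamped below 1 so the denominator cannot vanish in degenerate cases.
.q_weight <- function(q_n, q_med) {
  q_med <- min(max(q_med, 1e-300), 1 - 1e-12)
  w <- log(q_n + q_med) / log(q_med)
  pmin(pmax(w, 0), 1)
}

#' Summarize per-subtree correlations into the weighted |r| ranking
#'
#' Computes, per feature, the sum over subtrees of `|r|` down-weighted by
#' the correlation and Wilcoxon q-values relative to their medians:
#' each term is `|r| * w_c * w_W` with `w = ln(q_n + q_med) / ln(q_med)`
#' and the medians taken across all subtrees and features. Weights are
#' clamped to `[0, 1]`; subtree terms with undefined `r` or an undefined
#' Wilcoxon q (empty likelihood class) are omitted. Features absent from
#' every subtree receive 0 and hence the bottom ranks.
#'
#' @param ace_results `results` data frame from [run_ace()].
#' @param all_features optional feature universe to report (defaults to the
#'   features present in `ace_results`).
#' @return Data frame ranked by descending `sum_abs_rw` (average ties):
#'   `Rank`, `Feature_Type`, `Feature`, `sum_abs_rw`, `weighted_r` (mean
#'   contributing term), `n_subtrees`, `n_significant`.
#' @export
summarize_ace <- function(ace_results, all_features = NULL) {
  df <- ace_results
  if (is.null(all_features)) all_features <- unique(df$Feature)
  q_c_med <- median(df$q_Correlation, na.rm = TRUE)
  q_w_med <- median(df$q_Wilcox, na.rm = TRUE)
  ok <- !is.na(df$r) & !is.na(df$q_Correlation) & !is.na(df$q_Wilcox)
  d <- df[ok, , drop = FALSE]
  term <- abs(d$r) * .q_weight(d$q_Correlation, q_c_med) *
    .q_weight(d$q_Wilcox, q_w_med)
  sums <- tapply(term, d$Feature, sum)
  ns <- tapply(term, d$Feature, length)
  nsig <- tapply(df$Significant[ok], d$Feature, sum)
  out <- data.frame(
    Feature = all_features,
    sum_abs_rw = unname(ifelse(all_features %in% names(sums),
                               sums[all_features], 0)),
    n_subtrees = unname(ifelse(all_features %in% names(ns),
                               ns[all_features], 0L)),
    n_significant = unname(ifelse(all_features %in% names(nsig),
                                  nsig[all_features], 0L)),
    stringsAsFactors = FALSE
  )
  out$Feature_Type <- feature_types(out$Feature)
  out$weighted_r <- ifelse(out$n_subtrees > 0,
                           out$sum_abs_rw / out$n_subtrees, NA_real_)
  out$Rank <- rank(-out$sum_abs_rw, ties.method = "average")
  out <- out[order(out$Rank, out$Feature), ]
  rownames(out) <- NULL
  out[, c("Rank", "Feature_Type", "Feature", "sum_abs_rw", "weighted_r",
          "n_subtrees", "n_significant")]
}
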