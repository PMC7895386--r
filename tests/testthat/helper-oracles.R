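# Independent oracle implementations used across the suite. These are
# deliberately written as brute-force enumerations / direct formulas,
# not as calls into the package code they check.

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# group assignments of the pooled sample (feasible for n + m <= 10).
oracle_wilcoxon <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  idx <- utils::combn(n + m, n)
  stat <- apply(idx, 2, function(i) sum(r[i]))
  w_obs <- sum(r[seq_len(n)])
  # Mann-Whitney style two-sided p with symmetry cap
  p_low <- mean(stat <= w_obs)
  p_high <- mean(stat >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# Greedy iterative-global-minimum pairing, recomputed from scratch each
# iteration with explicit loops and lexicographic tie-breaks.
oracle_greedy_pairs <- function(d) {
  pos <- rownames(d); neg <- colnames(d)
  out <- NULL
  while (length(pos) > 0) {
    best <- NULL
    for (p in sort(pos)) for (q in sort(neg)) {
      if (is.null(best) || d[p, q] < best$val)
        best <- list(p = p, q = q, val = d[p, q])
    }
    out <- rbind(out, data.frame(positive = best$p, negative = best$q,
                                 distance = best$val,
                                 stringsAsFactors = FALSE))
    pos <- setdiff(pos, best$p); neg <- setdiff(neg, best$q)
  }
  out
}

# Marginal ancestral likelihoods for the 2-state equal-rates Mk model by
# exhaustive enumeration of all internal-state assignments at a given rate.
oracle_mk_marginal <- function(phy, states, q) {
  pm <- function(t) {
    e <- exp(-2 * q * t)
    matrix(c(0.5 + 0.5 * e, 0.5 - 0.5 * e, 0.5 - 0.5 * e, 0.5 + 0.5 * e), 2, 2)
  }
  ntip <- length(phy$tip.label); nnode <- phy$Nnode
  grids <- as.matrix(expand.grid(rep(list(1:2), nnode)))
  lik <- numeric(nrow(grids))
  for (g in seq_len(nrow(grids))) {
    st <- c(states[phy$tip.label], grids[g, ])
    L <- 0.5
    for (e in seq_len(nrow(phy$edge)))
      L <- L * pm(phy$edge.length[e])[st[phy$edge[e, 1]], st[phy$edge[e, 2]]]
    lik[g] <- L
  }
  marg <- matrix(0, nnode, 2)
  for (j in seq_len(nnode)) for (s in 1:2)
    marg[j, s] <- sum(lik[grids[, j] == s])
  marg / rowSums(marg)
}

# GLS oracle for BM ancestral values from the covariance of shared path
# lengths: mu = GLS mean; ahat_v = mu + S_v C^-1 (x - mu).
oracle_bm_gls <- function(phy, x) {
  ntip <- length(phy$tip.label)
  x <- x[phy$tip.label]
  dd <- ape::dist.nodes(phy)
  root <- ntip + 1L
  depth <- dd[root, ]
  # shared path length = depth of the MRCA
  mr <- ape::mrca(phy, full = TRUE)
  S <- matrix(depth[mr], nrow(mr), ncol(mr))
  C <- S[seq_len(ntip), seq_len(ntip)]
  one <- rep(1, ntip)
  Ci <- solve(C)
  mu <- as.numeric((one %*% Ci %*% x) / (one %*% Ci %*% one))
  nodes <- (ntip + 1):(ntip + phy$Nnode)
  est <- vapply(nodes, function(v)
    mu + as.numeric(S[v, seq_len(ntip)] %*% Ci %*% (x - mu)), numeric(1))
  setNames(est, as.character(nodes))
}

# Spearman correlation as rank-then-Pearson.
oracle_spearman <- function(a, b) cor(rank(a), rank(b))

# A small fixed-topology tree for hand-checked cases.
toy_tree <- function(newick) ape::read.tree(text = newick)

# Random count matrix with named rows/columns for io round trips.
random_feature_fixture <- function(n = 6, f = 4, seed = 1) {
  set.seed(seed)
  n_ec <- ceiling(f / 2)
  ids <- c(sprintf("%d.1.1.%d", rep_len(1:2, n_ec), seq_len(n_ec)),
           sprintf("PF%05d", seq_len(f - n_ec)))
  m <- matrix(rpois(n * f, 2), n, f,
              dimnames = list(sprintf("G%03d", seq_len(n)), ids))
  storage.mode(m) <- "integer"
  genomes <- data.frame(
    accession = rownames(m), relative = NA_character_, distance = NA_real_,
    subtree = NA_integer_,
    trait_status = sample(c("positive", "negative"), n, replace = TRUE),
    completeness = round(runif(n, 90, 100), 2),
    taxonomy = paste0("d__X;s__", rownames(m)),
    stringsAsFactors = FALSE)
  list(genomes = genomes, matrix = m)
}
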