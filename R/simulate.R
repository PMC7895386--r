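#' Configuration for the synthetic-data generator
#'
#' Bundles the parameters of the generative model used to test the pipeline:
#' a pure-birth (Yule) tree, a 2-state continuous-time Markov binary trait
#' evolved along it, and per-feature copy numbers whose latent log-mean
#' follows Brownian motion, shifted by `effect_beta` in trait-positive
#' lineages for the "linked" fraction of features.
#'
#' Defaults are the benchmark conditions used throughout the package's
#' recovery tests: 200 genomes, 300 features of which 10% are linked with a
#' log-scale effect of 1.5 (about a 4.5-fold copy-number ratio), trait
#' gain/loss rates 0.1/0.3 per substitution/site (stationary prevalence
#' 0.25, so trait-negatives outnumber positives and closest-relative
#' pairing is feasible).
#'
#' @param n_genomes number of leaves/genomes (>= 4).
#' @param birth_rate speciation rate of the pure-birth tree.
#' @param q01,q10 trait gain (negative to positive) and loss rates per unit
#'   branch length.
#' @param n_features number of gene-family features (split evenly between
#'   EC-style and Pfam-style identifiers).
#' @param frac_linked fraction of features in `[0, 1]` with trait-dependent
#'   expected copy number.
#' @param base_log_mean log expected copy number in the neutral state.
#' @param effect_beta shift added to the log expected copy number while a
#'   lineage is trait-positive (sign = enrichment/depletion).
#' @param bm_sigma2 variance rate of the neutral Brownian log-abundance
#'   process (per unit branch length).
#' @param co_prob probability that a copy of a linked feature is placed on
#'   the ORF adjacent to a trait-marker ORF (operon-like clustering) by
#'   [simulate_orfs()].
#' @param seed integer seed; every simulation function derives its stream
#'   from it, so identical configurations give identical output.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_genomes = 200, birth_rate = 1,
                              q01 = 0.1, q10 = 0.3,
                              n_features = 300, frac_linked = 0.1,
                              base_log_mean = 0, effect_beta = 1.5,
                              bm_sigma2 = 0.1, co_prob = 0.75, seed = 1L) {
  stopifnot(n_genomes >= 4, birth_rate > 0, q01 >= 0, q10 >= 0,
            n_features >= 1, frac_linked >= 0, frac_linked <= 1,
            bm_sigma2 >= 0, co_prob >= 0, co_prob <= 1)
  structure(list(n_genomes = as.integer(n_genomes), birth_rate = birth_rate,
                 q01 = q01, q10 = q10, n_features = as.integer(n_features),
                 frac_linked = frac_linked, base_log_mean = base_log_mean,
                 effect_beta = effect_beta, bm_sigma2 = bm_sigma2,
                 co_prob = co_prob, seed = as.integer(seed)),
            class = "sim_config")
}

# Derive a bounded sub-seed so each simulation stage has its own stream.
# LCG-style mixing spreads consecutive user seeds across the state space;
# a short burn-in decorrelates the first draws from the seed value.
.sub_seed <- function(seed, offset) {
  x <- (as.double(seed) * 1664525 + as.double(offset) * 1013904223) %% 2147483629
  as.integer(x)
}

.seed_stage <- function(seed, offset) {
  set.seed(.sub_seed(seed, offset))
  invisible(runif(20))
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Starts from a root with two lineages; while fewer than `n_genomes`
#' lineages exist, waits an exponential time with rate `k * birth_rate`
#' (`k` = current lineage count) and splits a uniformly chosen lineage.
#' Leaves are labelled `g001, g002, ...` in a fixed order, so the output is
#' deterministic for a fixed seed.
#'
#' @param config a [simulation_config()].
#' @return A rooted binary [ape::phylo] tree with `n_genomes` leaves and
#'   strictly positive branch lengths.
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genomes
  .seed_stage(config$seed, 1L)
  lambda <- config$birth_rate
  # Active lineages: provisional id, parent node id, birth time. The root
  # (id 0, time 0) starts two lineages; with k lineages the wait to the
  # next split is Exp(k * lambda) and a uniform lineage splits.
  id <- c(1L, 2L); parent <- c(0L, 0L); birth <- c(0, 0)
  int_id <- 0L; int_parent <- NA_integer_; int_birth <- NA_real_; int_end <- 0
  next_id <- 3L; t_now <- 0
  while (length(id) < n) {
    k <- length(id)
    t_now <- t_now + rexp(1, rate = k * lambda)
    i <- sample.int(k, 1)
    # lineage i becomes an internal node; two fresh lineages replace it
    int_id <- c(int_id, id[i]); int_parent <- c(int_parent, parent[i])
    int_birth <- c(int_birth, birth[i]); int_end <- c(int_end, t_now)
    id <- c(id[-i], next_id, next_id + 1L)
    parent <- c(parent[-i], int_id[length(int_id)], int_id[length(int_id)])
    birth <- c(birth[-i], t_now, t_now)
    next_id <- next_id + 2L
  }
  t_end <- t_now + rexp(1, rate = n * lambda)  # stem before the present
  ntip <- length(id)
  # ape numbering: tips 1..ntip, internal ntip+1.. in record order (root first,
  # splits in time order, so parents are always numbered before children)
  num <- integer(max(c(int_id, id)) + 1L)      # indexed by provisional id + 1
  num[id + 1L] <- seq_len(ntip)
  num[int_id + 1L] <- ntip + seq_along(int_id)
  edge <- matrix(0L, nrow = 2L * ntip - 2L, ncol = 2)
  elen <- numeric(2L * ntip - 2L)
  r <- 1L
  for (j in seq_along(int_id)[-1]) {           # root has no incoming edge
    edge[r, ] <- c(num[int_parent[j] + 1L], num[int_id[j] + 1L])
    elen[r] <- int_end[j] - int_birth[j]
    r <- r + 1L
  }
  for (j in seq_len(ntip)) {
    edge[r, ] <- c(num[parent[j] + 1L], num[id[j] + 1L])
    elen[r] <- t_end - birth[j]
    r <- r + 1L
  }
  phy <- structure(list(edge = edge, edge.length = elen,
                        tip.label = sprintf("g%03d", seq_len(ntip)),
                        Nnode = ntip - 1L),
                   class = "phylo")
  phy <- ape::reorder.phylo(phy, "cladewise")
  stopifnot(all(phy$edge.length > 0))
  phy
}

#' Evolve a binary trait along a tree
#'
#' Simulates a 2-state continuous-time Markov chain (gain rate `q01`,
#' loss rate `q10`) down the tree. The root state is drawn from the
#' stationary distribution `q01 / (q01 + q10)` unless fixed via
#' `root_state`. True internal states are returned so ancestral-state
#' recovery can be scored against the truth.
#'
#' @param tree an [ape::phylo] tree.
#' @param config a [simulation_config()].
#' @param root_state optional `"positive"`/`"negative"` to fix the root
#'   state (required when `q01 + q10 == 0`).
#' @return Character vector (`"positive"`/`"negative"`) over all nodes,
#'   named by tip label for leaves and by ape node number for internal
#'   nodes.
#' @export
simulate_trait <- function(tree, config, root_state = NULL) {
  stopifnot(inherits(config, "sim_config"))
  q01 <- config$q01; q10 <- config$q10
  if (q01 + q10 <= 0 && is.null(root_state))
    stop("q01 + q10 must be positive unless root_state is fixed")
  .seed_stage(config$seed, 2L)
  ntip <- length(tree$tip.label); nnode <- tree$Nnode
  state <- integer(ntip + nnode)  # 0 = negative, 1 = positive
  root <- ntip + 1L
  if (is.null(root_state)) {
    state[root] <- rbinom(1, 1, q01 / (q01 + q10))
  } else {
    state[root] <- as.integer(match.arg(root_state, c("negative", "positive")) == "positive")
  }
  # transition probabilities for a branch of length t
  p_trans <- function(from, t) {
    tot <- q01 + q10
    if (tot == 0) return(from)
    pi1 <- q01 / tot
    e <- exp(-tot * t)
    p1 <- pi1 + (from - pi1) * e  # P(state 1 at end | from)
    rbinom(length(t), 1, p1)
  }
  ord <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  for (e in seq_len(nrow(ord$edge))) {
    pa <- ord$edge[e, 1]; ch <- ord$edge[e, 2]
    state[ch] <- p_trans(state[pa], ord$edge.length[e])
  }
  lab <- c(tree$tip.label, as.character(root:(ntip + nnode)))
  setNames(ifelse(state == 1L, "positive", "negative"), lab)
}

#' Simulate gene-family copy numbers on a tree
#'
#' For each feature a latent log expected copy number evolves by Brownian
#' motion (variance `bm_sigma2` per unit branch length) from
#' `base_log_mean`; for a `frac_linked` fraction of features,
#' `effect_beta` is added at nodes whose lineage is trait-positive.
#' Observed leaf counts are Poisson draws around the exponentiated latent
#' value. Feature ids are split evenly between EC-style (`d.d.d.d`) and
#' Pfam-style (`PFxxxxx`) identifiers, and the linked ids are drawn from
#' both universes.
#'
#' @param tree an [ape::phylo] tree.
#' @param traits trait map from [simulate_trait()] covering all nodes.
#' @param config a [simulation_config()].
#' @return A list: `matrix` (integer leaves x features copy-number matrix),
#'   `linked` (character vector of trait-linked feature ids), `latent`
#'   (matrix of leaf latent log-means) — the ground truth sidecar.
#' @export
simulate_counts <- function(tree, traits, config) {
  stopifnot(inherits(config, "sim_config"))
  .seed_stage(config$seed, 3L)
  ntip <- length(tree$tip.label); nnode <- tree$Nnode
  nf <- config$n_features
  n_ec <- ceiling(nf / 2)
  ec_ids <- sprintf("%d.%d.%d.%d",
                    rep(1:6, length.out = n_ec),
                    rep(1:9, each = 6, length.out = n_ec),
                    ((seq_len(n_ec) - 1) %/% 54) %% 9 + 1,
                    seq_len(n_ec))
  pf_ids <- sprintf("PF9%04d", seq_len(nf - n_ec))  # PF9xxxx: clear of the
  # real marker domains (PF00016 etc.) excluded downstream by default
  ids <- c(ec_ids, pf_ids)
  n_linked <- round(config$frac_linked * nf)
  linked <- if (n_linked > 0) sort(sample(ids, n_linked)) else character(0)
  ord <- ape::reorder.phylo(tree, "cladewise")
  node_lab <- c(tree$tip.label, as.character((ntip + 1):(ntip + nnode)))
  pos <- traits[node_lab] == "positive"
  # latent BM values at every node, all features at once
  latent <- matrix(NA_real_, ntip + nnode, nf, dimnames = list(node_lab, ids))
  latent[ntip + 1L, ] <- config$base_log_mean
  for (e in seq_len(nrow(ord$edge))) {
    pa <- ord$edge[e, 1]; ch <- ord$edge[e, 2]; t <- ord$edge.length[e]
    latent[ch, ] <- latent[pa, ] + rnorm(nf, 0, sqrt(config$bm_sigma2 * t))
  }
  shift <- outer(pos, ids %in% linked) * config$effect_beta
  latent <- latent + shift
  leaf_latent <- latent[seq_len(ntip), , drop = FALSE]
  counts <- matrix(rpois(length(leaf_latent), exp(leaf_latent)),
                   nrow = ntip, dimnames = dimnames(leaf_latent))
  storage.mode(counts) <- "integer"
  list(matrix = counts, linked = linked, latent = leaf_latent)
}

#' Simulate ORF layouts for a set of genomes
#'
#' Distributes every feature copy of the count matrix onto ORFs placed on
#' 1-3 contigs per genome (the first contig is a chromosome; additional
#' contigs are plasmids or unknown molecules). Copies of `proximal_features`
#' are placed on an ORF adjacent to a randomly chosen trait-marker ORF with
#' probability `config$co_prob` (same contig and strand), which creates the
#' operon-like clustering probed by the proximity stage. Marker ORFs are
#' added to every genome listed in `marker_genomes`.
#'
#' @param genomes genome data frame (needs an `accession` column).
#' @param matrix integer copy-number matrix (rows = accessions).
#' @param config a [simulation_config()].
#' @param marker_features character vector of trait-marker feature ids
#'   (placed one copy each per marker genome).
#' @param marker_genomes accessions that receive marker ORFs (default: all).
#' @param proximal_features features whose copies co-locate with markers.
#' @return ORF data frame in the [read_orf_table()] layout.
#' @export
simulate_orfs <- function(genomes, matrix, config,
                          marker_features = character(0),
                          marker_genomes = genomes$accession,
                          proximal_features = character(0)) {
  stopifnot(inherits(config, "sim_config"))
  .seed_stage(config$seed, 4L)
  out <- vector("list", nrow(genomes))
  for (gi in seq_len(nrow(genomes))) {
    acc <- genomes$accession[gi]
    row <- if (acc %in% rownames(matrix)) matrix[acc, ] else
      setNames(integer(ncol(matrix)), colnames(matrix))
    has_marker <- acc %in% marker_genomes && length(marker_features) > 0
    total <- sum(row) + has_marker * length(marker_features)
    n_orfs <- max(20L, 3L * total)
    n_contig <- sample.int(3L, 1)
    contig_of <- sort(sample.int(n_contig, n_orfs, replace = TRUE))
    molecule <- c("chromosome", sample(c("plasmid", "unknown"), 2, replace = TRUE))
    # per-contig 0-based indices
    idx <- unlist(lapply(split(seq_along(contig_of), contig_of),
                         function(i) seq_along(i) - 1L), use.names = FALSE)
    strand <- sample(c("+", "-"), n_orfs, replace = TRUE)
    feats <- rep(list(character(0)), n_orfs)
    marker_orfs <- integer(0)
    if (has_marker) {
      # place markers adjacently on the chromosome (operon-like)
      chr <- which(contig_of == 1L)
      start <- sample(chr[seq_len(max(1, length(chr) - length(marker_features) + 1))], 1)
      marker_orfs <- start + seq_along(marker_features) - 1L
      st <- sample(c("+", "-"), 1)
      for (k in seq_along(marker_features)) {
        feats[[marker_orfs[k]]] <- c(feats[[marker_orfs[k]]], marker_features[k])
        strand[marker_orfs[k]] <- st
      }
    }
    for (f in names(row)[row > 0]) {
      for (cp in seq_len(row[[f]])) {
        if (f %in% proximal_features && length(marker_orfs) > 0 &&
            runif(1) < config$co_prob) {
          m <- marker_orfs[sample.int(length(marker_orfs), 1)]
          o <- if (m < n_orfs && contig_of[m + 1L] == contig_of[m]) m + 1L else m - 1L
          strand[o] <- strand[m]
        } else {
          o <- sample.int(n_orfs, 1)
        }
        feats[[o]] <- c(feats[[o]], f)
      }
    }
    out[[gi]] <- data.frame(
      genome = acc,
      contig = paste0(acc, "_c", contig_of),
      molecule = molecule[contig_of],
      index = idx,
      strand = strand,
      stringsAsFactors = FALSE
    )
    out[[gi]]$features <- feats
  }
  do.call(rbind, out)
}

#' Simulate a tblout-style marker hit table
#'
#' Emits one strong hit (E-value around 1e-50) per marker copy so the
#' trait-calling stage can be exercised end to end: trait-positive genomes
#' get hits for every marker, trait-negative genomes get a hit for a random
#' strict subset of markers with probability `partial_prob` (mimicking,
#' e.g., Rubisco-only genomes), and a small number of weak decoy hits above
#' the E-value threshold are added.
#'
#' @param genomes genome data frame with `accession` and `trait_status`.
#' @param config a [simulation_config()].
#' @param markers character vector of marker model names (>= 1).
#' @param partial_prob probability a trait-negative genome carries a strict
#'   subset of the markers.
#' @return Hit data frame in the [read_tblout()] layout.
#' @export
simulate_marker_hits <- function(genomes, config, markers = c("rubisco", "prk"),
                                 partial_prob = 0.2) {
  stopifnot(inherits(config, "sim_config"), length(markers) >= 1)
  .seed_stage(config$seed, 5L)
  rows <- list()
  for (gi in seq_len(nrow(genomes))) {
    acc <- genomes$accession[gi]
    if (genomes$trait_status[gi] == "positive") {
      got <- markers
    } else if (length(markers) > 1 && runif(1) < partial_prob) {
      got <- sample(markers, sample.int(length(markers) - 1L, 1))
    } else {
      got <- character(0)
    }
    for (m in got) {
      rows[[length(rows) + 1L]] <- data.frame(
        orf_id = paste0(acc, "|orf_", m), genome = acc, model_id = m,
        evalue = 10^runif(1, -80, -20), bitscore = runif(1, 100, 500),
        stringsAsFactors = FALSE)
    }
    if (runif(1) < 0.1) {  # weak decoy above threshold
      m <- sample(markers, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        orf_id = paste0(acc, "|orf_decoy"), genome = acc, model_id = m,
        evalue = 10^runif(1, -1, 1), bitscore = runif(1, 5, 20),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(orf_id = character(0), genome = character(0),
                      model_id = character(0), evalue = numeric(0),
                      bitscore = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Generate a complete synthetic dataset
#'
#' Runs [simulate_tree()], [simulate_trait()], [simulate_counts()],
#' [simulate_marker_hits()] and [simulate_orfs()] under one configuration
#' and, optionally, writes the feature table, newick tree, ORF table and a
#' ground-truth sidecar (linked features and true internal trait states) to
#' `dir`. Byte-identical outputs are produced for identical config + seed.
#'
#' @param config a [simulation_config()].
#' @param dir optional output directory (created if missing).
#' @param markers marker model names used for the hit table and ORF layout.
#' @return A list: `genomes`, `matrix`, `tree`, `traits`, `linked`,
#'   `latent`, `hits`, `orfs`, and (when written) `paths`.
#' @export
simulate_dataset <- function(config = simulation_config(), dir = NULL,
                             markers = c("rubisco", "prk")) {
  tree <- simulate_tree(config)
  traits <- simulate_trait(tree, config)
  cnt <- simulate_counts(tree, traits, config)
  leaf_traits <- traits[tree$tip.label]
  genomes <- data.frame(
    accession    = tree$tip.label,
    relative     = NA_character_,
    distance     = NA_real_,
    subtree      = NA_integer_,
    trait_status = unname(leaf_traits),
    completeness = 100,
    taxonomy     = paste0("d__Synthetica;s__", tree$tip.label),
    stringsAsFactors = FALSE
  )
  hits <- simulate_marker_hits(genomes, config, markers = markers)
  orfs <- simulate_orfs(genomes, cnt$matrix, config,
                        marker_features = markers,
                        marker_genomes = genomes$accession[genomes$trait_status == "positive"],
                        proximal_features = cnt$linked)
  res <- list(genomes = genomes, matrix = cnt$matrix, tree = tree,
              traits = traits, linked = cnt$linked, latent = cnt$latent,
              hits = hits, orfs = orfs)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      feature_table = file.path(dir, "feature_table.tsv"),
      tree          = file.path(dir, "tree.nwk"),
      orfs          = file.path(dir, "orfs.tsv"),
      truth_linked  = file.path(dir, "truth_linked_features.tsv"),
      truth_states  = file.path(dir, "truth_node_states.tsv")
    )
    write_feature_table(genomes, cnt$matrix, paths$feature_table)
    write_tree(tree, paths$tree)
    write_orf_table(orfs, paths$orfs)
    utils::write.table(data.frame(feature = cnt$linked), paths$truth_linked,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(node = names(traits), state = unname(traits)),
                       paths$truth_states, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    res$paths <- paths
  }
  res
}
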