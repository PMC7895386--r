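#' Configuration for a full pipeline run
#'
#' Collects inputs (either a [simulation_config()] or paths to a feature
#' table, newick tree, ORF table and optional hit table), stage thresholds
#' and the forest configuration. Input paths are validated at construction
#' time.
#'
#' @param sim optional [simulation_config()]; when given the pipeline
#'   generates its inputs instead of reading files.
#' @param feature_table,tree,orfs,hits input paths (ignored when `sim` is
#'   given; `hits` and `orfs` are optional).
#' @param out_dir optional directory for the stage output tables and the
#'   run manifest; no files are written when `NULL`.
#' @param markers marker model names required for a trait-positive call.
#' @param evalue_max marker hit E-value ceiling.
#' @param exclude_taxa taxonomy labels whose genomes are dropped at the
#'   classification stage.
#' @param completeness_min completeness threshold for the enrichment stage
#'   (percent; applies only there).
#' @param min_taxa,max_taxa candidate subtree size bounds for the ACE stage.
#' @param q_enrich,q_ace significance thresholds for enrichment q-values
#'   and the dual ACE test.
#' @param reference `"holdout"` analyses the smaller root clade as subtree
#'   0 and scores candidates in the remaining clade against it (falling
#'   back to `"full"` when the clade is degenerate); `"full"` scores
#'   candidates of the whole tree against the whole tree.
#' @param forest a [forest_config()].
#' @param exclude_features features excluded from enrichment and forest
#'   stages (defaults to the trait-marker enzymes/domains).
#' @param stages character vector of stages to run after data loading;
#'   subsets of `c("classify", "pair", "enrich", "ace", "forest",
#'   "consensus", "proximity")`. Consensus uses whichever method stages ran.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, feature_table = NULL, tree = NULL,
                            orfs = NULL, hits = NULL, out_dir = NULL,
                            markers = c("rubisco", "prk"), evalue_max = 0.01,
                            exclude_taxa = character(0),
                            completeness_min = 95,
                            min_taxa = 50, max_taxa = 300,
                            q_enrich = 0.05, q_ace = 0.001,
                            reference = c("holdout", "full"),
                            forest = forest_config(),
                            exclude_features = .DEFAULT_EXCLUDE,
                            stages = c("classify", "pair", "enrich", "ace",
                                       "forest", "consensus", "proximity")) {
  reference <- match.arg(reference)
  if (is.null(sim)) {
    for (p in c(feature_table, tree))
      if (is.null(p) || !file.exists(p))
        stop("input path missing or nonexistent: ", p)
    for (p in c(orfs, hits))
      if (!is.null(p) && !file.exists(p))
        stop("input path nonexistent: ", p)
  } else stopifnot(inherits(sim, "sim_config"))
  stopifnot(inherits(forest, "forest_config"), evalue_max > 0,
            completeness_min >= 0, completeness_min <= 100,
            min_taxa >= 4, max_taxa >= min_taxa,
            q_enrich > 0, q_enrich <= 1, q_ace > 0, q_ace <= 1)
  structure(list(sim = sim, feature_table = feature_table, tree = tree,
                 orfs = orfs, hits = hits, out_dir = out_dir,
                 markers = markers, evalue_max = evalue_max,
                 exclude_taxa = exclude_taxa,
                 completeness_min = completeness_min,
                 min_taxa = min_taxa, max_taxa = max_taxa,
                 q_enrich = q_enrich, q_ace = q_ace, reference = reference,
                 forest = forest, exclude_features = exclude_features,
                 stages = stages),
            class = "pipeline_config")
}

# Pick the held-out reference clade: the smaller root child, provided it
# has >= 4 leaves, both trait classes, and well-defined score statistics.
.holdout_reference <- function(tree, traits) {
  ntip <- length(tree$tip.label)
  root_children <- tree$edge[tree$edge[, 1] == ntip + 1L, 2]
  sizes <- vapply(root_children, function(v) {
    if (v <= ntip) 1L
    else length(ape::extract.clade(tree, v)$tip.label)
  }, integer(1))
  cand <- root_children[order(sizes)]
  for (v in cand) {
    if (v <= ntip) next
    size <- sizes[match(v, root_children)]
    if (size < 4 || size > ntip - 4) next
    st <- tryCatch(subtree_stats(tree, traits, v), error = function(e) NULL)
    ok <- !is.null(st) && all(is.finite(unlist(st))) && all(unlist(st) > 0)
    if (ok) return(list(node = v, stats = st))
  }
  NULL
}

#' Run the full trait-association pipeline
#'
#' Executes the stages on simulated or file inputs: trait classification
#' from marker hits, closest-relative pairing, copy-number enrichment,
#' ancestral character estimation on similarity-selected subtrees,
#' random-forest importance, consensus ranking, and marker proximity.
#' Stage outputs are returned (and written as TSV when `out_dir` is set)
#' together with a manifest recording thresholds, seeds and per-stage row
#' counts. All randomness flows from the seeds in the configuration, so a
#' re-run with the same configuration reproduces the outputs.
#'
#' @param config a [pipeline_config()].
#' @return A list with elements `genomes`, `pairs`, `enrichment`, `ace`,
#'   `ace_summary`, `forest`, `consensus`, `proximity` (those whose stage
#'   ran) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(package_version = as.character(utils::packageVersion("phylotraits")),
                   thresholds = list(evalue_max = config$evalue_max,
                                     completeness_min = config$completeness_min,
                                     min_taxa = config$min_taxa,
                                     max_taxa = config$max_taxa,
                                     q_enrich = config$q_enrich,
                                     q_ace = config$q_ace),
                   forest_seed = config$forest$seed,
                   stages = config$stages, rows = list())
  res <- list()

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$sim)) {
    dat <- simulate_dataset(config$sim, dir = config$out_dir,
                            markers = config$markers)
    genomes <- dat$genomes; mat <- dat$matrix; tree <- dat$tree
    orfs <- dat$orfs; hits <- dat$hits
    manifest$sim_seed <- config$sim$seed
  } else {
    ft <- read_feature_table(config$feature_table)
    genomes <- ft$genomes; mat <- ft$matrix
    tree <- read_tree(config$tree)
    orfs <- if (!is.null(config$orfs)) read_orf_table(config$orfs) else NULL
    hits <- if (!is.null(config$hits)) read_tblout(config$hits) else NULL
  }
  manifest$rows$genomes <- nrow(genomes)

  # --- classify -----------------------------------------------------------
  if ("classify" %in% config$stages && !is.null(hits)) {
    marker_hits <- lapply(config$markers, function(m)
      filter_hits(hits, marker_spec(m, evalue_max = config$evalue_max)))
    names(marker_hits) <- config$markers
    genomes <- call_trait_status(genomes, marker_hits,
                                 required_markers = config$markers,
                                 exclude_taxa = config$exclude_taxa)
    mat <- mat[genomes$accession, , drop = FALSE]
    manifest$rows$classified <- nrow(genomes)
  }
  n_pos <- sum(genomes$trait_status == "positive")
  if (n_pos == 0) stop("stage classify: no trait-positive genomes")

  # --- pair ---------------------------------------------------------------
  analyzed <- genomes
  if ("pair" %in% config$stages) {
    pos <- genomes$accession[genomes$trait_status == "positive"]
    neg <- genomes$accession[genomes$trait_status == "negative"]
    d <- patristic_distances(tree, pos, neg)
    pairs <- select_pairs(d)
    res$pairs <- pairs
    manifest$rows$pairs <- nrow(pairs)
    keep <- c(pairs$positive, pairs$negative)
    analyzed <- genomes[genomes$accession %in% keep, , drop = FALSE]
    idx_p <- match(pairs$positive, analyzed$accession)
    idx_n <- match(pairs$negative, analyzed$accession)
    analyzed$relative[idx_p] <- pairs$negative
    analyzed$relative[idx_n] <- pairs$positive
    analyzed$distance[idx_p] <- pairs$distance
    analyzed$distance[idx_n] <- pairs$distance
  }
  amat <- mat[analyzed$accession, , drop = FALSE]
  manifest$rows$analyzed <- nrow(analyzed)

  # --- enrich -------------------------------------------------------------
  if ("enrich" %in% config$stages) {
    res$enrichment <- run_enrichment(analyzed, amat,
                                     completeness_min = config$completeness_min,
                                     exclude_features = config$exclude_features)
    manifest$rows$enrichment <- nrow(res$enrichment)
  }

  # --- ace ----------------------------------------------------------------
  if ("ace" %in% config$stages) {
    atree <- ape::keep.tip(tree, analyzed$accession)
    traits <- setNames(analyzed$trait_status, analyzed$accession)
    excl <- unique(c(config$exclude_features,
                     paste("EC", config$exclude_features)))
    ace_mat <- amat[, setdiff(colnames(amat), excl), drop = FALSE]
    ref <- NULL; ref_clade <- NULL
    if (config$reference == "holdout") {
      ref_clade <- .holdout_reference(atree, traits)
      if (is.null(ref_clade)) manifest$reference <- "full (holdout degenerate)"
    }
    if (!is.null(ref_clade)) {
      manifest$reference <- "holdout"
      ref <- ref_clade$stats
      ref_tree <- ape::extract.clade(atree, ref_clade$node)
      # candidates come from the remainder of the tree
      cand_tree <- ape::drop.tip(atree, ref_tree$tip.label)
      ace_res <- run_ace(cand_tree, traits, ace_mat, reference = ref,
                         min_taxa = config$min_taxa,
                         max_taxa = config$max_taxa, q_sig = config$q_ace)
      # the reference clade itself is analyzed as subtree 0
      if (length(ref_tree$tip.label) >= 5) {
        lik0 <- ace_discrete(ref_tree, traits[ref_tree$tip.label])
        anc0 <- ace_continuous(ref_tree,
                               ace_mat[ref_tree$tip.label, , drop = FALSE])
        c0 <- correlate_ancestral(lik0$lik_positive, anc0)
        c0$q_corr <- bh_adjust(c0$p_corr)
        c0$q_wilcox <- bh_adjust(c0$p_wilcox)
        sub0 <- data.frame(
          Subtree = 0L, Feature_Type = feature_types(c0$Feature),
          Feature = c0$Feature, r = c0$r,
          Significant = as.integer(!is.na(c0$q_corr) & !is.na(c0$q_wilcox) &
                                     c0$q_corr < config$q_ace &
                                     c0$q_wilcox < config$q_ace),
          p_Correlation = c0$p_corr, q_Correlation = c0$q_corr,
          p_Wilcox = c0$p_wilcox, q_Wilcox = c0$q_wilcox,
          stringsAsFactors = FALSE)
        ace_res$results <- rbind(sub0, ace_res$results)
      }
      # record subtree membership
      analyzed$subtree <- NA_integer_
      analyzed$subtree[analyzed$accession %in% ref_tree$tip.label] <- 0L
      if (nrow(ace_res$subtrees) > 0)
        for (k in seq_len(nrow(ace_res$subtrees))) {
          lv <- ape::extract.clade(cand_tree, ace_res$subtrees$node[k])$tip.label
          analyzed$subtree[analyzed$accession %in% lv] <- k
        }
    } else {
      ace_res <- run_ace(atree, traits, ace_mat, reference = NULL,
                         min_taxa = config$min_taxa,
                         max_taxa = config$max_taxa, q_sig = config$q_ace)
      if (is.null(manifest$reference)) manifest$reference <- "full"
      analyzed$subtree <- NA_integer_
      if (nrow(ace_res$subtrees) > 0)
        for (k in seq_len(nrow(ace_res$subtrees))) {
          lv <- ape::extract.clade(atree, ace_res$subtrees$node[k])$tip.label
          analyzed$subtree[analyzed$accession %in% lv] <- k
        }
    }
    res$ace <- ace_res$results
    if (!is.null(res$ace) && nrow(res$ace) > 0)
      res$ace_summary <- summarize_ace(res$ace,
                                       all_features = colnames(ace_mat))
    manifest$rows$ace <- if (is.null(res$ace)) 0L else nrow(res$ace)
    manifest$rows$ace_subtrees <-
      length(unique(res$ace$Subtree[!is.na(res$ace$Subtree)]))
  }

  # --- forest -------------------------------------------------------------
  if ("forest" %in% config$stages) {
    fr <- run_forest(amat, analyzed$trait_status, config$forest,
                     exclude_features = config$exclude_features)
    res$forest <- fr$importance
    res$forest_accuracy <- fr$accuracy
    manifest$rows$forest <- nrow(fr$importance)
    manifest$forest_accuracy <- as.list(fr$accuracy)
  }

  # --- consensus ----------------------------------------------------------
  if ("consensus" %in% config$stages) {
    ranks <- list()
    if (!is.null(res$enrichment))
      ranks$enrichment <- rank_method(
        setNames(res$enrichment$q, res$enrichment$Feature), "ascending")
    if (!is.null(res$ace_summary))
      ranks$ace <- rank_method(
        setNames(res$ace_summary$sum_abs_rw, res$ace_summary$Feature),
        "descending")
    if (!is.null(res$forest))  # within-type ranks, as importances are
      ranks$forest <- setNames(res$forest$Rank, res$forest$Feature)
    cons <- consensus_rank(ranks)
    cons$Feature_Type <- feature_types(cons$Feature)
    if (!is.null(res$enrichment)) {
      i <- match(cons$Feature, res$enrichment$Feature)
      cons$mean_Negative <- res$enrichment$mean_Negative[i]
      cons$mean_Positive <- res$enrichment$mean_Positive[i]
    }
    if (!is.null(res$ace_summary))
      cons$weighted_r <- res$ace_summary$weighted_r[
        match(cons$Feature, res$ace_summary$Feature)]
    if (!is.null(res$forest))
      cons$Importance <- res$forest$Importance[
        match(cons$Feature, res$forest$Feature)]
    res$consensus <- cons
    manifest$rows$consensus <- nrow(cons)
  }

  # --- proximity ----------------------------------------------------------
  if ("proximity" %in% config$stages && !is.null(orfs)) {
    pos_acc <- analyzed$accession[analyzed$trait_status == "positive"]
    tuples <- orf_distances(orfs, config$markers, genomes = pos_acc)
    res$proximity <- summarize_proximity(tuples)
    manifest$rows$proximity <- nrow(res$proximity)
  }

  res$genomes <- analyzed
  res$manifest <- manifest

  # --- outputs ------------------------------------------------------------
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_table(analyzed, amat,
                        file.path(config$out_dir, "analyzed_genomes.tsv"))
    for (nm in c("enrichment", "ace", "ace_summary", "forest", "consensus",
                 "proximity"))
      if (!is.null(res[[nm]]))
        write_result_table(res[[nm]],
                           file.path(config$out_dir, paste0(nm, ".tsv")))
    mf <- file.path(config$out_dir, "manifest.tsv")
    flat <- unlist(manifest)
    utils::write.table(data.frame(key = names(flat), value = unname(flat)),
                       mf, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}
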