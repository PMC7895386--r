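#' Distances between feature ORFs and trait-marker ORFs
#'
#' For every contig of a trait-positive genome that carries at least one
#' marker ORF, computes the distance (absolute difference of ORF indices,
#' contigs treated as linear with no wrap-around) from each feature-bearing
#' ORF to each marker ORF, for all copies. The strand relation is `"Same"`
#' when both ORFs lie on the same strand. The trivial pairing of a marker
#' annotation with itself on the same ORF is excluded unless
#' `include_self = TRUE` (distances between different markers, e.g.
#' Rubisco to Prk, are always reported).
#'
#' @param orfs ORF data frame ([read_orf_table()] layout).
#' @param marker_features feature ids treated as trait markers.
#' @param genomes optional accessions to restrict to (the trait-positive
#'   genomes); default all genomes in `orfs`.
#' @param include_self keep feature==marker pairs on the same ORF
#'   (distance 0)?
#' @return Data frame of raw tuples: `Feature`, `Marker`, `Distance`,
#'   `Strand` (`Same`/`Opposite`), `Molecule`.
#' @export
orf_distances <- function(orfs, marker_features, genomes = NULL,
                          include_self = FALSE) {
  o <- orfs
  if (!is.null(genomes)) o <- o[o$genome %in% genomes, , drop = FALSE]
  out <- list()
  for (ctg in unique(o$contig)) {
    oc <- o[o$contig == ctg, , drop = FALSE]
    marker_rows <- which(vapply(oc$features,
                                function(f) any(f %in% marker_features),
                                logical(1)))
    if (length(marker_rows) == 0) next
    feat_rows <- which(lengths(oc$features) > 0)
    for (i in feat_rows) {
      for (f in oc$features[[i]]) {
        for (m in marker_rows) {
          for (mk in intersect(oc$features[[m]], marker_features)) {
            if (!include_self && i == m && f == mk) next
            out[[length(out) + 1L]] <- data.frame(
              Feature = f, Marker = mk,
              Distance = abs(oc$index[i] - oc$index[m]),
              Strand = if (oc$strand[i] == oc$strand[m]) "Same" else "Opposite",
              Molecule = oc$molecule[i],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(Feature = character(0), Marker = character(0),
                      Distance = integer(0), Strand = character(0),
                      Molecule = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Summarize feature-to-marker distances
#'
#' Groups the raw tuples by (feature, marker, strand relation) and reports
#' distance summaries and occurrence counts by molecule type. `frac_psm`
#' is the fraction of placed occurrences on plasmids,
#' `loc_psm / (loc_psm + loc_chr)`; when a feature occurs only on unknown
#' molecules (0/0) it is `NaN`.
#'
#' @param tuples data frame from [orf_distances()].
#' @return Data frame per (Feature, Marker, Strand): `minD`, `medD`,
#'   `maxD`, `meanD`, `Count`, `locChr`, `locPsm`, `locUnk`, `fracPsm`,
#'   sorted by increasing `medD` then decreasing `Count`.
#' @export
summarize_proximity <- function(tuples) {
  if (nrow(tuples) == 0)
    return(data.frame(Feature = character(0), Marker = character(0),
                      Strand = character(0), minD = numeric(0),
                      medD = numeric(0), maxD = numeric(0), meanD = numeric(0),
                      Count = integer(0), locChr = integer(0),
                      locPsm = integer(0), locUnk = integer(0),
                      fracPsm = numeric(0), stringsAsFactors = FALSE))
  key <- interaction(tuples$Feature, tuples$Marker, tuples$Strand, drop = TRUE)
  groups <- split(tuples, key)
  rows <- lapply(groups, function(g) {
    chr <- sum(g$Molecule == "chromosome"); psm <- sum(g$Molecule == "plasmid")
    data.frame(Feature = g$Feature[1], Marker = g$Marker[1],
               Strand = g$Strand[1],
               minD = min(g$Distance), medD = median(g$Distance),
               maxD = max(g$Distance), meanD = mean(g$Distance),
               Count = nrow(g), locChr = chr, locPsm = psm,
               locUnk = sum(g$Molecule == "unknown"),
               fracPsm = if (chr + psm > 0) psm / (chr + psm) else NaN,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$medD, -out$Count, out$Feature), ]
  rownames(out) <- NULL
  out
}
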