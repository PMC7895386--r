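#' Specification of a trait-marker homology search
#'
#' Describes how hits for one marker (e.g. Rubisco large subunit or Prk)
#' are filtered: an E-value ceiling and, optionally, a catalytic-residue
#' requirement at a fixed column of a reference alignment. The catalytic
#' filter is how form IV Rubisco-like proteins, which lack the catalytic
#' lysine, are removed.
#'
#' @param marker_name marker model name as it appears in the hit table.
#' @param evalue_max full-sequence E-value ceiling (default 0.01).
#' @param catalytic_column optional 1-based alignment column that must carry
#'   the catalytic residue.
#' @param required_residue single amino-acid letter required at
#'   `catalytic_column` (case-insensitive; a gap never matches).
#' @return A list of class `marker_spec`.
#' @export
marker_spec <- function(marker_name, evalue_max = 0.01,
                        catalytic_column = NULL, required_residue = NULL) {
  stopifnot(is.character(marker_name), length(marker_name) == 1,
            evalue_max > 0)
  if (!is.null(catalytic_column))
    stopifnot(catalytic_column >= 1, !is.null(required_residue),
              nchar(required_residue) == 1)
  structure(list(marker_name = marker_name, evalue_max = evalue_max,
                 catalytic_column = catalytic_column,
                 required_residue = required_residue),
            class = "marker_spec")
}

#' Filter homology hits by marker and E-value
#'
#' Retains hits whose model matches `spec$marker_name` and whose
#' full-sequence E-value is strictly below `spec$evalue_max`, preserving
#' input order.
#'
#' @param hits hit data frame from [read_tblout()].
#' @param spec a [marker_spec()].
#' @return Filtered hit data frame.
#' @export
filter_hits <- function(hits, spec) {
  stopifnot(inherits(spec, "marker_spec"))
  hits[hits$model_id == spec$marker_name & hits$evalue < spec$evalue_max, ,
       drop = FALSE]
}

#' Filter aligned sequences by a required catalytic residue
#'
#' Retains the sequences whose character at `spec$catalytic_column` equals
#' `spec$required_residue` (case-insensitive). Gap characters (`-` or `.`)
#' never match, so sequences lacking the catalytic position are removed.
#'
#' @param aligned named character vector of equal-width aligned sequences
#'   (e.g. from [read_alignment()]).
#' @param spec a [marker_spec()] with `catalytic_column` set.
#' @return Character vector of retained sequence ids.
#' @export
filter_catalytic_residue <- function(aligned, spec) {
  stopifnot(inherits(spec, "marker_spec"), !is.null(spec$catalytic_column))
  widths <- nchar(aligned)
  if (length(unique(widths)) > 1)
    stop("ragged alignment: sequence widths differ")
  if (unique(widths) < spec$catalytic_column)
    stop("alignment shorter than catalytic column")
  res <- toupper(substr(aligned, spec$catalytic_column, spec$catalytic_column))
  keep <- res == toupper(spec$required_residue) & !res %in% c("-", ".")
  names(aligned)[keep]
}

#' Call genome trait status from retained marker hits
#'
#' A genome is trait-positive if and only if it has at least one retained
#' hit for every required marker (e.g. both Rubisco and Prk for the Calvin
#' cycle). Genomes whose taxonomy string contains any of `exclude_taxa`
#' (e.g. Cyanobacteria, whose ancient divergence would bias the contrast)
#' are dropped from the output entirely.
#'
#' @param genomes genome data frame with `accession` and `taxonomy`.
#' @param marker_hits named list, one filtered hit data frame per marker.
#' @param required_markers marker names that must all be present.
#' @param exclude_taxa character vector of taxonomy labels; genomes whose
#'   taxonomy contains any of them (fixed-string match) are removed.
#' @return `genomes` with `trait_status` set and a `markers_found` column
#'   (comma-separated marker names), excluded taxa removed.
#' @export
call_trait_status <- function(genomes, marker_hits,
                              required_markers = names(marker_hits),
                              exclude_taxa = character(0)) {
  stopifnot(all(required_markers %in% names(marker_hits)))
  keep <- rep(TRUE, nrow(genomes))
  for (taxon in exclude_taxa)
    keep <- keep & !grepl(taxon, genomes$taxonomy, fixed = TRUE)
  out <- genomes[keep, , drop = FALSE]
  found <- vapply(out$accession, function(acc) {
    have <- vapply(required_markers,
                   function(m) acc %in% marker_hits[[m]]$genome, logical(1))
    paste(required_markers[have], collapse = ",")
  }, character(1))
  n_found <- vapply(strsplit(found, ","), function(x) sum(nzchar(x)), integer(1))
  out$trait_status <- ifelse(n_found == length(required_markers),
                             "positive", "negative")
  out$markers_found <- unname(found)
  rownames(out) <- NULL
  out
}

#' Flag genomes carrying a minimum number of distinct indicator features
#'
#' A genome is flagged if it carries at least `min_distinct` distinct
#' features from `photo_features` with copy number >= 1. Used to flag
#' photosynthetic genomes from reaction-center Pfam domains; multiple
#' copies of one family do not count as distinct families.
#'
#' @param matrix integer genomes x features copy-number matrix.
#' @param photo_features nonempty character vector of indicator feature ids.
#' @param min_distinct minimum number of distinct families (default 3).
#' @return Named logical vector over genomes.
#' @export
flag_photosynthetic <- function(matrix, photo_features, min_distinct = 3) {
  stopifnot(length(photo_features) > 0)
  present <- intersect(photo_features, colnames(matrix))
  if (length(present) == 0)
    return(setNames(rep(FALSE, nrow(matrix)), rownames(matrix)))
  n_distinct <- rowSums(matrix[, present, drop = FALSE] >= 1)
  setNames(n_distinct >= min_distinct, rownames(matrix))
}
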