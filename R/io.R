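# Mandatory leading columns of the genome feature table dialect.
.GENOME_COLUMNS <- c("Accession", "Relative", "Distance", "Subtree",
                     "CBB_status", "checkm_completeness", "gtdb_taxonomy")

#' Classify feature identifiers as EC numbers or Pfam accessions
#'
#' Feature ids beginning with `"PF"` are Pfam domains; ids made of four
#' dot-separated numeric fields (a `-` wildcard is allowed, and an optional
#' `"EC "` prefix is tolerated) are EC numbers. Anything else is rejected,
#' which keeps the two feature universes separable for the per-type
#' random-forest stage.
#'
#' @param ids character vector of feature identifiers.
#' @return Character vector of the same length with values `"EC"` or `"Pfam"`.
#' @examples
#' feature_types(c("1.1.1.1", "4.1.1.-", "PF00001"))
#' @export
feature_types <- function(ids) {
  out <- rep(NA_character_, length(ids))
  out[grepl("^PF", ids)] <- "Pfam"
  ec <- grepl("^(EC )?[0-9-]+(\\.[0-9-]+){3}$", ids)
  out[is.na(out) & ec] <- "EC"
  if (anyNA(out)) {
    bad <- ids[is.na(out)]
    stop("unrecognized feature id(s): ", paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  }
  out
}

#' Read a genome feature-count table
#'
#' Reads the tab-delimited dialect with seven mandatory leading columns
#' (`Accession`, `Relative`, `Distance`, `Subtree`, `CBB_status`,
#' `checkm_completeness`, `gtdb_taxonomy`) followed by one column per gene
#' family holding non-negative integer copy numbers. `CBB_status` is decoded
#' 0 = trait-negative, 1 = trait-positive. Files are read as UTF-8 with `.`
#' decimal separator; any newline convention is accepted.
#'
#' @param path path to a tab-delimited file with a header row.
#' @return A list with components:
#'   \describe{
#'     \item{genomes}{data frame with one row per genome: `accession`,
#'       `relative`, `distance`, `subtree`, `trait_status`
#'       (`"positive"`/`"negative"`), `completeness`, `taxonomy`.}
#'     \item{matrix}{integer matrix, genomes x features, with accessions as
#'       row names and feature ids as column names.}
#'     \item{types}{character vector tagging each feature `"EC"` or `"Pfam"`.}
#'   }
#' @seealso [write_feature_table()]
#' @export
read_feature_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(.GENOME_COLUMNS, names(df))
  if (length(missing) > 0)
    stop("feature table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  feat_cols <- setdiff(names(df), .GENOME_COLUMNS)
  mat <- NULL
  if (length(feat_cols) > 0) {
    mat <- as.matrix(df[, feat_cols, drop = FALSE])
    suppressWarnings(storage.mode(mat) <- "numeric")
    bad <- which(is.na(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-integer feature cell at row %d, column '%s'",
                   bad[1, 1], feat_cols[bad[1, 2]]))
    storage.mode(mat) <- "integer"
    rownames(mat) <- as.character(df$Accession)
  }
  if (anyDuplicated(df$Accession))
    stop("duplicate genome accession(s) in feature table")
  status <- as.integer(df$CBB_status)
  if (any(!status %in% c(0L, 1L)))
    stop("trait status column must contain only 0 (negative) or 1 (positive)")
  genomes <- data.frame(
    accession    = as.character(df$Accession),
    relative     = as.character(df$Relative),
    distance     = as.numeric(df$Distance),
    subtree      = suppressWarnings(as.integer(df$Subtree)),
    trait_status = ifelse(status == 1L, "positive", "negative"),
    completeness = as.numeric(df$checkm_completeness),
    taxonomy     = as.character(df$gtdb_taxonomy),
    stringsAsFactors = FALSE
  )
  if (any(genomes$completeness < 0 | genomes$completeness > 100, na.rm = TRUE))
    stop("completeness values must lie in [0, 100]")
  list(genomes = genomes, matrix = mat,
       types = if (is.null(mat)) character(0) else feature_types(colnames(mat)))
}

#' Write a genome feature-count table
#'
#' Inverse of [read_feature_table()]: writes the same tab-delimited dialect so
#' that a read/write round trip is the identity.
#'
#' @param genomes genome data frame as returned by [read_feature_table()].
#' @param matrix integer genomes x features matrix (row names = accessions).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(genomes, matrix, path) {
  stopifnot(is.data.frame(genomes))
  df <- data.frame(
    Accession            = genomes$accession,
    Relative             = genomes$relative,
    Distance             = genomes$distance,
    Subtree              = genomes$subtree,
    CBB_status           = as.integer(genomes$trait_status == "positive"),
    checkm_completeness  = genomes$completeness,
    gtdb_taxonomy        = genomes$taxonomy,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  if (!is.null(matrix)) {
    m <- matrix[match(genomes$accession, rownames(matrix)), , drop = FALSE]
    df <- cbind(df, as.data.frame(m, check.names = FALSE))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a rooted phylogenetic tree from a newick file
#'
#' Thin wrapper over [ape::read.tree()] that enforces the invariants the
#' pipeline relies on: a parsable tree with unique leaf labels and branch
#' lengths.
#'
#' @param path path to a newick file.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) {
  phy <- tryCatch(ape::read.tree(path), error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(phy))
    stop("unparsable newick in '", path, "'")
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) != 1) stop("expected a single tree in '", path, "'")
    phy <- phy[[1]]
  }
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf label(s): ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (is.null(phy$edge.length))
    stop("tree in '", path, "' has no branch lengths")
  phy
}

#' Write a tree to a newick file
#'
#' @param phy an [ape::phylo] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(phy, path) {
  ape::write.tree(phy, file = path, digits = 12)
  invisible(path)
}

#' Read a hmmer per-sequence hit table (tblout format)
#'
#' Parses the whitespace-delimited `--tblout` output of `hmmsearch`.
#' Comment lines (starting `#`) are skipped; the full-sequence E-value and
#' bit score columns (5 and 6) are used. Malformed data lines are skipped
#' with a single warning reporting their count.
#'
#' @param path path to a tblout file.
#' @param genome_from_orf function mapping an ORF/target identifier to its
#'   genome accession. The default takes the part before the first `|`,
#'   matching the `genome|orf` convention of the synthetic generator.
#' @return Data frame of hits: `orf_id`, `genome`, `model_id`, `evalue`,
#'   `bitscore`. Empty (zero-row) for a comment-only file.
#' @export
read_tblout <- function(path, genome_from_orf = function(x) sub("\\|.*$", "", x)) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  empty <- data.frame(orf_id = character(0), genome = character(0),
                      model_id = character(0), evalue = numeric(0),
                      bitscore = numeric(0), stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)
  fields <- strsplit(trimws(lines), "\\s+")
  ok <- vapply(fields, function(f) {
    length(f) >= 6 &&
      !is.na(suppressWarnings(as.numeric(f[5]))) &&
      !is.na(suppressWarnings(as.numeric(f[6]))) &&
      suppressWarnings(as.numeric(f[5])) > 0
  }, logical(1))
  if (any(!ok))
    warning(sum(!ok), " malformed tblout line(s) skipped")
  fields <- fields[ok]
  if (length(fields) == 0) return(empty)
  orf <- vapply(fields, `[`, character(1), 1)
  data.frame(
    orf_id   = orf,
    genome   = vapply(orf, genome_from_orf, character(1), USE.NAMES = FALSE),
    model_id = vapply(fields, `[`, character(1), 3),
    evalue   = vapply(fields, function(f) as.numeric(f[5]), numeric(1)),
    bitscore = vapply(fields, function(f) as.numeric(f[6]), numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Read an ORF location table
#'
#' The pipeline's own tab-delimited dialect: columns `genome`, `contig`,
#' `molecule` (`chromosome`/`plasmid`/`unknown`), `index` (0-based ordinal
#' position of the ORF along its contig), `strand` (`+`/`-`), and `features`
#' (comma-separated feature ids annotated on the ORF; empty for none).
#'
#' @param path path to a tab-delimited ORF table.
#' @return Data frame with the columns above (`features` as a list column of
#'   character vectors).
#' @seealso [write_orf_table()]
#' @export
read_orf_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8", na.strings = NULL,
                          colClasses = c(genome = "character", contig = "character",
                                         molecule = "character", index = "integer",
                                         strand = "character", features = "character"))
  need <- c("genome", "contig", "molecule", "index", "strand", "features")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("ORF table is missing column(s): ", paste(missing, collapse = ", "))
  if (any(df$index < 0)) stop("ORF index must be >= 0")
  if (anyDuplicated(df[, c("genome", "contig", "index")]))
    stop("duplicate (genome, contig, index) in ORF table")
  if (any(!df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(!df$molecule %in% c("chromosome", "plasmid", "unknown")))
    stop("molecule must be chromosome, plasmid or unknown")
  df$features <- lapply(strsplit(df$features, ","), function(x) x[nzchar(x)])
  df
}

#' Write an ORF location table
#'
#' @param orfs ORF data frame as returned by [read_orf_table()] or
#'   [simulate_orfs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_orf_table <- function(orfs, path) {
  out <- orfs
  out$features <- vapply(orfs$features, paste, character(1), collapse = ",")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a multiple sequence alignment from FASTA
#'
#' @param path path to an aligned FASTA file (all records the same width).
#' @return Named character vector of aligned sequences.
#' @export
read_alignment <- function(path) {
  aln <- Biostrings::readAAStringSet(path)
  setNames(as.character(aln), names(aln))
}

#' Write a stage result table as tab-separated text
#'
#' Generic TSV writer used for the enrichment, ACE, forest, consensus and
#' proximity output tables.
#'
#' @param df data frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
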