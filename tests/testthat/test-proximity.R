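make_contig <- function(genome, contig, molecule, feats, strands = NULL) {
  n <- length(feats)
  if (is.null(strands)) strands <- rep("+", n)
  df <- data.frame(genome = genome, contig = contig, molecule = molecule,
                   index = seq_len(n) - 1L, strand = strands,
                   stringsAsFactors = FALSE)
  df$features <- feats
  df
}

test_that("ORF distances are index differences on linear contigs", {
  feats <- rep(list(character(0)), 10)
  feats[[6]] <- "marker"                      # index 5
  feats[[4]] <- "PF00001"; feats[[10]] <- "PF00001"   # indices 3, 9
  orfs <- make_contig("G1", "c1", "chromosome", feats)
  tuples <- orf_distances(orfs, "marker")
  t_pf <- tuples[tuples$Feature == "PF00001", ]
  expect_setequal(t_pf$Distance, c(2, 4))
  # feature on a contig without a marker contributes nothing
  orfs2 <- rbind(orfs, make_contig("G1", "c2", "plasmid",
                                   list("PF00002", character(0))))
  tuples2 <- orf_distances(orfs2, "marker")
  expect_false("PF00002" %in% tuples2$Feature)
})

test_that("strand relation and molecule type are recorded", {
  feats <- list("marker", character(0), "PF00001", "PF00002")
  orfs <- make_contig("G1", "c1", "plasmid", feats,
                      strands = c("+", "+", "+", "-"))
  tuples <- orf_distances(orfs, "marker")
  expect_equal(tuples$Strand[tuples$Feature == "PF00001"], "Same")
  expect_equal(tuples$Strand[tuples$Feature == "PF00002"], "Opposite")
  expect_true(all(tuples$Molecule == "plasmid"))
})

test_that("marker self-pairs are excluded by default but marker pairs kept", {
  feats <- list("rubisco", "prk", character(0))
  orfs <- make_contig("G1", "c1", "chromosome", feats)
  tuples <- orf_distances(orfs, c("rubisco", "prk"))
  self <- tuples[tuples$Feature == tuples$Marker & tuples$Distance == 0, ]
  expect_equal(nrow(self), 0)
  cross <- tuples[tuples$Feature == "rubisco" & tuples$Marker == "prk", ]
  expect_equal(cross$Distance, 1)
  with_self <- orf_distances(orfs, c("rubisco", "prk"), include_self = TRUE)
  expect_true(any(with_self$Feature == with_self$Marker &
                    with_self$Distance == 0))
})

test_that("distances match an all-pairs brute-force oracle on random genomes", {
  set.seed(91)
  for (i in 1:10) {
    n <- 30
    feats <- lapply(seq_len(n), function(j)
      if (runif(1) < 0.4)
        sample(c("marker", sprintf("PF%05d", 1:5)), sample(1:2, 1))
      else character(0))
    orfs <- make_contig("G1", "c1",
                        sample(c("chromosome", "plasmid", "unknown"), 1), feats,
                        strands = sample(c("+", "-"), n, replace = TRUE))
    tuples <- orf_distances(orfs, "marker", include_self = TRUE)
    # brute force over all ORF pairs
    marker_idx <- which(vapply(feats, function(f) "marker" %in% f, logical(1)))
    expected <- 0L
    for (j in seq_len(n)) for (m in marker_idx)
      expected <- expected + length(feats[[j]])
    expect_equal(nrow(tuples), expected)
    for (row in sample(nrow(tuples), min(20, nrow(tuples)))) {
      tu <- tuples[row, ]
      ok <- any(vapply(which(vapply(feats, function(f) tu$Feature %in% f,
                                    logical(1))), function(j)
        any(abs(j - marker_idx) == tu$Distance), logical(1)))
      expect_true(ok)
    }
  }
})

test_that("reversing a contig leaves distances unchanged", {
  feats <- list("marker", character(0), "PF00001", character(0), "PF00001")
  orfs <- make_contig("G1", "c1", "chromosome", feats)
  rev_orfs <- orfs
  rev_orfs$index <- max(orfs$index) - orfs$index
  t1 <- orf_distances(orfs, "marker")
  t2 <- orf_distances(rev_orfs, "marker")
  expect_setequal(t1$Distance, t2$Distance)
})

test_that("proximity summaries aggregate by feature, marker and strand", {
  tuples <- data.frame(
    Feature = c("PF1", "PF1", "PF2"), Marker = "marker",
    Distance = c(2, 4, 1), Strand = "Same",
    Molecule = c("plasmid", "plasmid", "chromosome"),
    stringsAsFactors = FALSE)
  s <- summarize_proximity(tuples)
  pf1 <- s[s$Feature == "PF1", ]
  expect_equal(pf1$medD, 3)
  expect_equal(pf1$minD, 2); expect_equal(pf1$maxD, 4)
  expect_equal(pf1$Count, 2)
  expect_equal(pf1$fracPsm, 1)          # all on plasmids
  expect_equal(pf1$Count, pf1$locChr + pf1$locPsm + pf1$locUnk)
  unk <- summarize_proximity(data.frame(
    Feature = "PF3", Marker = "m", Distance = 1, Strand = "Same",
    Molecule = "unknown", stringsAsFactors = FALSE))
  expect_true(is.nan(unk$fracPsm))      # 0/0 placements
})
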