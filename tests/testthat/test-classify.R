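test_that("pairwise identity matches the stated scoring scheme", {
  expect_equal(pairwise_identity("ACDEFG", "ACDEFG"), 100)
  expect_equal(pairwise_identity("AAAA", "TTTT"), 0)
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGA"), 87.5)
  expect_equal(pairwise_identity("MKV", "MKV"),
               pairwise_identity("MKV", "MKV"))
  # symmetry
  set.seed(11)
  for (k in 1:5) {
    a <- random_peptide(sample(5:20, 1)); b <- random_peptide(sample(5:20, 1))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a),
                 tolerance = 1e-9)
  }
})

test_that("the alignment engine finds the optimal global score (DP oracle)", {
  set.seed(12)
  letters <- c("A", "C", "D", "E", "G", "K", "L", "S")
  smat <- diag(1, length(letters)); dimnames(smat) <- list(letters, letters)
  for (k in 1:15) {
    a <- random_peptide(sample(3:12, 1), letters)
    b <- random_peptide(sample(3:12, 1), letters)
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = smat, gapOpening = 0, gapExtension = 1)
    expect_equal(Biostrings::score(al), nw_score_oracle(a, b))
  }
})

test_that("identity matrix is symmetric with unit diagonal", {
  set.seed(13)
  tbl <- protein_tbl(paste0("p", 1:6),
                     vapply(1:6, function(i) random_peptide(sample(20:40, 1)),
                            character(1)))
  m <- identity_matrix(tbl)
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) == 100))
  expect_true(all(m >= 0 & m <= 100))
  expect_equal(m["p2", "p5"],
               pairwise_identity(tbl$sequence[2], tbl$sequence[5]),
               tolerance = 1e-9)
})

test_that("anchored alignment pads gap blocks and conserves cysteine columns", {
  cand <- tibble::tibble(
    id = c("a", "b"),
    sequence = c("CAACAACCAACACAACAAC",          # gaps 2,2,2,2,2
                 "CAAACAACCAACACAACAAC"),        # gaps 3,2,2,2,2
    c1 = c(1L, 1L), c2 = c(4L, 5L), c3 = c(7L, 8L), c4 = c(8L, 9L),
    c5 = c(11L, 12L), c6 = c(13L, 14L), c7 = c(16L, 17L), c8 = c(19L, 20L))
  aln <- build_anchored_alignment(cand)
  expect_equal(nchar(aln$aligned[["a"]]), 20)  # 8 + (3+2+2+2+2) + 1
  expect_equal(sum(strsplit(aln$aligned[["a"]], "")[[1]] == "-"), 1)
  g1_cols <- aln$block_map$column[aln$block_map$block == "g1"]
  expect_true(strsplit(aln$aligned[["a"]], "")[[1]][max(g1_cols)] == "-")
  cysmat <- as.matrix(aln)[, aln$block_map$block %in%
                             c("C1", "C2", "CC", "C7", "C8"), drop = FALSE]
  expect_true(all(cysmat == "C"))
})

test_that("anchored alignment of generated cohorts has the predicted width", {
  co <- generate_cohort(small_cohort_config(), seed = 17, stages = "proteins")
  scr <- run_screen(co$proteins)
  acc <- scr$candidates[scr$candidates$status == "accepted", ]
  aln <- build_anchored_alignment(acc)
  widths <- sapply(paste0("g", 1:5), function(g) max(acc[[g]]))
  expect_equal(nchar(aln$aligned[[1]]), 8 + sum(widths) + 1)
  m <- as.matrix(aln)
  cys_cols <- aln$block_map$block %in% c("C1", "C2", "CC", "C7", "C8")
  expect_true(all(m[, cys_cols] == "C"))
  one <- build_anchored_alignment(acc[1, ])
  expect_equal(nchar(one$aligned[[1]]), acc$motif_span[1])
})

test_that("CXC polarity follows the hydropathy sign", {
  expect_equal(cxc_polarity("L"), "hydrophobic")
  expect_equal(cxc_polarity("S"), "hydrophilic")
  expect_equal(cxc_polarity("G"), "hydrophilic")
})

test_that("type assignment follows the GPI / spacing / intron cascade", {
  profiles <- type_profiles()
  gpi_cand <- tibble::tibble(id = "g", gpi_positive = TRUE,
                             mature_sequence = NA_character_,
                             g1 = 3, g2 = 3, g3 = 3, g4 = 3, g5 = 3)
  expect_equal(assign_type(gpi_cand, profiles)$type, "G")
  t2 <- tibble::tibble(id = "t2", gpi_positive = FALSE,
                       mature_sequence = NA_character_,
                       g1 = 7, g2 = 12, g3 = 9, g4 = 22, g5 = 6)
  expect_equal(assign_type(t2, profiles)$type, "2")
  expect_equal(assign_type(t2, profiles,
                           gene_introns = tibble::tibble(id = "t2",
                                                         introns = 0L))$type,
               "2")
  weird <- tibble::tibble(id = "w", gpi_positive = FALSE,
                          mature_sequence = NA_character_,
                          g1 = 50, g2 = 50, g3 = 50, g4 = 50, g5 = 50)
  expect_equal(assign_type(weird, profiles)$type, "X")
})

test_that("intron evidence disambiguates spacing-compatible profiles", {
  profiles <- type_profiles()
  # craft two profiles with overlapping ranges differing in introns
  p2 <- profiles[profiles$type %in% c("2", "D"), ]
  p2$g1_min <- 6; p2$g1_max <- 10; p2$g2_min <- 11; p2$g2_max <- 16
  p2$g3_min <- 7; p2$g3_max <- 16; p2$g4_min <- 20; p2$g4_max <- 29
  p2$g5_min <- 5; p2$g5_max <- 14
  cand <- tibble::tibble(id = "c", gpi_positive = FALSE,
                         mature_sequence = NA_character_,
                         g1 = 8, g2 = 12, g3 = 10, g4 = 22, g5 = 6)
  both <- assign_type(cand, p2)  # ambiguous: lexicographic tie-break
  expect_equal(both$type, "2")
  with_introns <- assign_type(cand, p2,
                              gene_introns = tibble::tibble(id = "c",
                                                            introns = 1L))
  expect_equal(with_introns$type, "D")  # only D allows 1 intron
})

test_that("planted types are recovered on a clean synthetic cohort", {
  co <- generate_cohort(small_cohort_config(), seed = 19, stages = "proteins")
  scr <- run_screen(co$proteins)
  typed <- classify_candidates(scr)
  truth <- co$manifest$proteins
  expect_equal(typed$type, truth$class[match(typed$id, truth$id)])
})
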