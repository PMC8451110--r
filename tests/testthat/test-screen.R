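test_that("find_8cm recovers a planted motif with its gaps and CXC residue", {
  m <- find_8cm("CAACAACCAACACAACAAC")
  expect_equal(nrow(m), 1)
  expect_equal(as.integer(m[1, paste0("c", 1:8)]),
               c(1L, 4L, 7L, 8L, 11L, 13L, 16L, 19L))
  expect_equal(as.integer(m[1, paste0("g", 1:5)]), rep(2L, 5))
  expect_equal(m$cxc_x, "A")
  expect_equal(m$span, 19L)
})

test_that("find_8cm returns no matches without cysteines or below min length", {
  expect_equal(nrow(find_8cm(strrep("A", 30))), 0)
  expect_equal(nrow(find_8cm("CACCACCCACCACC")), 0)  # 14 aa, below minimum
})

test_that("find_8cm equals the exhaustive 8-subset oracle on random sequences", {
  set.seed(42)
  cfg <- screen_config()
  for (k in 1:40) {
    len <- sample(15:200, 1)
    # plant a controlled number of cysteines so multi-match cases arise
    # without a combinatorial blowup of the oracle
    n_cys <- min(sample(8:16, 1), len %/% 3)
    res <- sample(c("A", "G", "S", "T", "L", "V"), len, replace = TRUE)
    res[sample(len, n_cys)] <- "C"
    seq <- paste(res, collapse = "")
    got <- as.matrix(find_8cm(seq, cfg)[, paste0("c", 1:8)])
    want <- oracle_find_8cm(seq, cfg)
    expect_equal(sort_motifs(got), sort_motifs(want))
  }
})

test_that("detect_nss follows the hydrophobic-run rule and the override", {
  s <- paste0("M", strrep("L", 8), "A", strrep("K", 40))
  expect_equal(detect_nss(s), 10L)
  expect_true(is.na(detect_nss(strrep("K", 50))))
  long <- random_peptide(120)
  expect_equal(detect_nss(long, override = 24), 24L)
  expect_error(detect_nss(strrep("K", 20), override = 40), "outside")
})

test_that("detect_gpi follows the tail heuristic and the override", {
  s <- paste0(strrep("K", 60), "S", strrep("L", 24))
  omega <- detect_gpi(s)
  expect_equal(omega, 61L)
  expect_equal(nchar(s) - omega + 1L, 25L)  # 25 residues from the C-terminus
  expect_true(is.na(detect_gpi(paste0(strrep("K", 60), strrep("E", 25)))))
  expect_equal(detect_gpi(s, override = 7), 7L)
})

test_that("proline-rich call applies the length and P/H/G fraction thresholds", {
  mk <- function(linker) paste0(strrep("M", 5), linker, "CAA")
  seg15 <- "PPPHHHGGGPPPHHH"
  expect_true(is_proline_rich(mk(seg15), cleavage = 5, c1 = 5 + 15 + 1))
  expect_false(is_proline_rich(mk(strrep("A", 15)), 5, 21))
  seg20 <- paste0(strrep("P", 7), strrep("A", 13))  # fraction exactly 0.35
  expect_true(is_proline_rich(mk(seg20), 5, 26))
  cfg36 <- screen_config(prolinerich_phg_fraction = 0.36)
  expect_false(is_proline_rich(mk(seg20), 5, 26, cfg36))
})

test_that("screening funnel conserves counts and rejects duplicate ids", {
  co <- generate_cohort(small_cohort_config(), seed = 11, stages = "proteins")
  scr <- run_screen(co$proteins)
  rep <- tidyr::pivot_wider(scr$report, names_from = stage,
                            values_from = count)
  expect_equal(rep$input,
               rep$accepted + rep$no_8cm + rep$no_nss + rep$proline_rich +
                 rep$storage_like + rep$too_long)
  expect_error(run_screen(dplyr::bind_rows(co$proteins[1, ], co$proteins[1, ])),
               "duplicate")
})

test_that("empty input yields an all-zero report", {
  scr <- run_screen(protein_tbl(character(0), character(0)))
  expect_true(all(scr$report$count == 0))
})

test_that("a single well-formed precursor passes every stage", {
  co <- generate_cohort(small_cohort_config(), seed = 3, stages = "proteins")
  one <- co$proteins[1, ]  # a planted type-1 precursor
  scr <- run_screen(one)
  expect_equal(scr$candidates$status, "accepted")
  expect_equal(scr$candidates$exclusion_stage, "none")
})

test_that("screening is idempotent on accepted proteins", {
  co <- generate_cohort(small_cohort_config(), seed = 5, stages = "proteins")
  scr <- run_screen(co$proteins)
  acc_ids <- scr$candidates$id[scr$candidates$status == "accepted"]
  rescreen <- run_screen(co$proteins[co$proteins$id %in% acc_ids, ])
  expect_true(all(rescreen$candidates$status == "accepted"))
  expect_identical(
    rescreen$candidates$mature_sequence,
    scr$candidates$mature_sequence[match(rescreen$candidates$id,
                                         scr$candidates$id)])
})

test_that("decoys are excluded at their own stage, never later", {
  co <- generate_cohort(small_cohort_config(), seed = 9, stages = "proteins")
  scr <- run_screen(co$proteins)
  truth <- co$manifest$proteins
  cand <- scr$candidates
  stage_of <- cand$exclusion_stage[match(truth$id, cand$id)]
  expect_true(all(stage_of[truth$class == "cys_deficient"] == "no_8cm"))
  expect_true(all(stage_of[truth$class == "nss_lacking"] == "no_nss"))
  expect_true(all(stage_of[truth$class == "proline_rich"] == "proline_rich"))
  expect_true(all(stage_of[truth$class %in% c("1", "2", "D", "G")] == "none"))
})

test_that("GPI-positive candidates are retained, flagged and truncated", {
  co <- generate_cohort(small_cohort_config(), seed = 13, stages = "proteins")
  scr <- run_screen(co$proteins)
  truth <- co$manifest$proteins
  g_ids <- truth$id[truth$class == "G"]
  cand <- scr$candidates[match(g_ids, scr$candidates$id), ]
  expect_true(all(cand$status == "accepted"))
  expect_true(all(cand$gpi_positive))
  expect_equal(cand$gpi_omega, unname(truth$gpi_omega[match(g_ids, truth$id)]))
  # mature chain stops right before the omega site
  expect_equal(nchar(cand$mature_sequence),
               cand$gpi_omega - 1L - cand$nss_cleavage)
})

test_that("storage-like candidates are excluded by exemplar identity", {
  cfg <- small_cohort_config(
    decoys = c(cys_deficient = 1, nss_lacking = 1, proline_rich = 0,
               storage_like = 2))
  co <- generate_cohort(cfg, seed = 21, stages = "proteins")
  ex_path <- system.file("extdata", "storage_exemplars_synthetic.fasta",
                         package = "nsltpkit")
  scr <- run_screen(co$proteins,
                    screen_config(exclusion_exemplars = ex_path))
  truth <- co$manifest$proteins
  stage_of <- scr$candidates$exclusion_stage[match(truth$id, scr$candidates$id)]
  expect_true(all(stage_of[truth$class == "storage_like"] == "storage_like"))
  expect_true(all(stage_of[truth$class %in% c("1", "2", "D", "G")] == "none"))
})

test_that("the optional maturity-length filter excludes long mature chains", {
  co <- generate_cohort(small_cohort_config(), seed = 2, stages = "proteins")
  scr <- run_screen(co$proteins, screen_config(max_mature_length = 60))
  long_ones <- scr$candidates$exclusion_stage == "too_long"
  expect_true(any(long_ones))
  plain <- run_screen(co$proteins)
  mat_len <- nchar(plain$candidates$mature_sequence[
    match(scr$candidates$id[long_ones], plain$candidates$id)])
  expect_true(all(mat_len > 60))
})

test_that("annotation overrides steer NSS and GPI calls", {
  co <- generate_cohort(small_cohort_config(), seed = 4, stages = "proteins")
  one <- co$proteins[1, ]
  ann <- tibble::tibble(id = one$id, nss_cleavage = 5L, gpi_omega = NA)
  scr <- run_screen(one, annotations = ann)
  expect_equal(scr$candidates$nss_cleavage, 5L)
})
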