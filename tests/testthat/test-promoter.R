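test_that("upstream extraction is strand-aware and anchored at the ATG", {
  contig <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                  collapse = "")
  genome <- c(chr1 = contig)
  gplus <- gene_model_tbl("gp", "chr1", "+",
                          exons = list(data.frame(start = 2000, end = 2300)),
                          cds = list(data.frame(start = 2000, end = 2300)))
  pr <- extract_upstream(genome, gplus)
  expect_equal(pr$width, 1500)
  expect_equal(pr$promoter, substr(contig, 501, 2000))
  # minus-strand gene: extraction == revcomp of the mirrored plus case
  gminus <- gene_model_tbl("gm", "chr1", "-",
                           exons = list(data.frame(start = 5000, end = 5300)),
                           cds = list(data.frame(start = 5000, end = 5300)))
  pm <- extract_upstream(genome, gminus)
  expect_equal(pm$promoter,
               nsltpkit:::reverse_complement(substr(contig, 5301, 6800)))
  # truncation at the contig edge warns
  gedge <- gene_model_tbl("ge", "chr1", "+",
                          exons = list(data.frame(start = 100, end = 400)),
                          cds = list(data.frame(start = 100, end = 400)))
  expect_warning(pe <- extract_upstream(genome, gedge), "truncated")
  expect_equal(pe$width, 100)
  goff <- gene_model_tbl("go", "chrZ", "+",
                         exons = list(data.frame(start = 10, end = 310)),
                         cds = list(data.frame(start = 10, end = 310)))
  expect_error(extract_upstream(genome, goff), "absent from the genome")
})

test_that("palindromic consensus hits collapse to strand ±", {
  cat <- tibble::tibble(name = "G-box", consensus = "CACGTG",
                        category = "light")
  hits <- scan_promoter("AACACGTGAA", cat)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 3L)
  expect_equal(hits$strand, "±")
  expect_equal(nrow(scan_promoter("AACACGTGAA", cat[0, ])), 0)
})

test_that("scanning equals the naive IUPAC oracle on both strands", {
  set.seed(41)
  cat <- tibble::tibble(
    name = c("e1", "e2", "e3", "e4"),
    consensus = c("RCCGAC", "TGACG", "CAAT", "ATTKWCTTCA"),
    category = "stress")
  for (k in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE),
                 collapse = "")
    hits <- scan_promoter(seq, cat)
    for (e in seq_len(nrow(cat))) {
      fwd <- oracle_iupac_starts(seq, cat$consensus[e])
      rev_ <- oracle_iupac_starts(seq, revcomp_chr(cat$consensus[e]))
      got_f <- sort(hits$start[hits$element == cat$name[e] &
                                 hits$strand %in% c("+", "±")])
      got_r <- sort(hits$start[hits$element == cat$name[e] &
                                 hits$strand %in% c("-", "±")])
      expect_equal(got_f, sort(fwd))
      expect_equal(got_r, sort(rev_))
    }
  }
})

test_that("strand symmetry: scanning the reverse complement mirrors hits", {
  set.seed(43)
  cat <- cis_element_catalog()
  seq <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
               collapse = "")
  h1 <- scan_promoter(seq, cat)
  h2 <- scan_promoter(nsltpkit:::reverse_complement(seq), cat)
  flip <- function(h, L) {
    tibble::tibble(element = h$element,
                   start = L - h$end + 1L,
                   strand = ifelse(h$strand == "+", "-",
                                   ifelse(h$strand == "-", "+", "±")))
  }
  a <- dplyr::arrange(flip(h2, nchar(seq)), element, start, strand)
  b <- dplyr::arrange(h1[, c("element", "start", "strand")],
                      element, start, strand)
  expect_equal(a, b)
})

test_that("N in the sequence matches nothing", {
  cat <- tibble::tibble(name = "x", consensus = "ANT", category = "core")
  expect_equal(nrow(scan_promoter("ANTANT", cat)), 0)
  expect_equal(nrow(scan_promoter("AGTACT", cat)), 2)
  expect_error(scan_promoter("ACGT",
                             tibble::tibble(name = "bad", consensus = "AXZ",
                                            category = "core")),
               "malformed")
})

test_that("alphabet-disjoint planted elements are recovered with no spurious
           hits", {
  cat <- tibble::tibble(name = c("p1", "p2"),
                        consensus = c("ACACAC", "CAACCA"),
                        category = "stress")
  # all-G background; both elements need A/C and their reverse complements
  # need T, so only the planted footprints can ever match
  bg <- rep("G", 600)
  plant <- list(c(50, "ACACAC"), c(200, "CAACCA"), c(400, "ACACAC"))
  for (p in plant) {
    st <- as.integer(p[1])
    bg[st:(st + nchar(p[2]) - 1)] <- strsplit(p[2], "")[[1]]
  }
  hits <- scan_promoter(paste(bg, collapse = ""), cat)
  expect_equal(sort(hits$start), c(50L, 200L, 400L))
  expect_true(all(hits$strand == "+"))
  expect_equal(hits$element[order(hits$start)], c("p1", "p2", "p1"))
})

test_that("planted promoter elements in a generated cohort are all found", {
  co <- generate_cohort(small_cohort_config(), seed = 53,
                        stages = c("proteins", "genome"))
  pr <- extract_upstream(co$genome, co$genes)
  expect_true(all(pr$width == 1500))
  hits <- scan_promoters(pr, cis_element_catalog())
  tp <- co$manifest$promoters
  found <- mapply(function(gid, el, st, strnd) {
    any(hits$gene_id == gid & hits$element == el & hits$start == st &
          (hits$strand == strnd | hits$strand == "±"))
  }, tp$gene_id, tp$element, tp$start, tp$strand)
  expect_true(all(found))
})

test_that("organization comparison is a multiset equality", {
  a <- tibble::tibble(element = c("ABRE", "ABRE", "MBS"),
                      start = c(10L, 200L, 400L), strand = c("+", "+", "-"))
  b <- tibble::tibble(element = c("ABRE", "MBS"),
                      start = c(10L, 400L), strand = c("+", "-"))
  cmp <- compare_organization(a, b)
  expect_false(cmp$identical_organization)
  expect_setequal(cmp$shared_elements, c("ABRE", "MBS"))
  expect_equal(nrow(cmp$unique_a), 1)
  expect_equal(cmp$unique_a$start, 200L)
  expect_true(compare_organization(a, a)$identical_organization)
  shifted <- dplyr::mutate(a, start = start + 1L)
  cmp2 <- compare_organization(a, shifted)
  expect_false(cmp2$identical_organization)
  expect_setequal(cmp2$shared_elements, c("ABRE", "MBS"))
})
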