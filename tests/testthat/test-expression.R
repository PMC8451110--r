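mk_qpcr <- function(dct_by_cond, gene = "g1", n_tech = 2, ct_ref = 20) {
  rows <- list()
  for (cond in names(dct_by_cond)) {
    dcts <- dct_by_cond[[cond]]
    for (b in seq_along(dcts)) {
      for (tr in seq_len(n_tech)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          gene = gene, condition = cond, bio_rep = b, tech_rep = tr,
          ct_target = ct_ref + dcts[b], ct_reference = ct_ref)
      }
    }
  }
  dplyr::bind_rows(rows)
}

test_that("flat dCt gives RQ 1 everywhere and ns calls", {
  q <- mk_qpcr(list(control = c(2, 2, 2), heat = c(2, 2, 2)))
  r <- relative_quantity(q, "control")
  expect_equal(r$rq, c(1, 1))
  expect_equal(r$stars[r$condition == "heat"], "ns")
})

test_that("one extra cycle halves the relative quantity", {
  q <- mk_qpcr(list(control = c(2, 2, 2), cold = c(3, 3, 3)))
  r <- relative_quantity(q, "control")
  expect_equal(r$rq[r$condition == "cold"], 0.5)
})

test_that("the worked toy table gives RQ ~ 4 with a ** Welch call", {
  q <- mk_qpcr(list(control = c(2.0, 2.0, 2.0), drought = c(0.0, 0.1, -0.1)))
  r <- relative_quantity(q, "control")
  rq <- r$rq[r$condition == "drought"]
  expect_equal(rq, 2^(-(0 - 2)), tolerance = 0.01)   # = 4
  # independent Welch check
  p <- stats::t.test(c(0, 0.1, -0.1), c(2, 2, 2), var.equal = FALSE)$p.value
  expect_equal(r$p_value[r$condition == "drought"], p)
  expect_lt(p, 0.01)
  expect_equal(r$stars[r$condition == "drought"], "**")
})

test_that("the calibrator RQ is exactly 1 for every gene", {
  co <- generate_cohort(small_cohort_config(), seed = 61)
  r <- relative_quantity(co$qpcr, "control")
  expect_true(all(r$rq[r$condition == "control"] == 1))
})

test_that("missing calibrator errors; single replicate warns without p", {
  q <- mk_qpcr(list(cold = c(1, 1, 1)))
  expect_error(relative_quantity(q, "control"), "calibrator")
  q1 <- mk_qpcr(list(control = c(2, 2, 2), salt = 1.0))
  expect_warning(r <- relative_quantity(q1, "control"), "replicates")
  expect_true(is.na(r$p_value[r$condition == "salt"]))
  expect_equal(r$rq[r$condition == "salt"], 2)
})

test_that("technical replicates are averaged before dCt statistics", {
  q <- dplyr::bind_rows(
    tibble::tibble(gene = "g", condition = "control", bio_rep = rep(1:3, each = 2),
                   tech_rep = rep(1:2, 3),
                   ct_target = 22 + c(0.2, -0.2, 0.1, -0.1, 0.3, -0.3),
                   ct_reference = 20),
    tibble::tibble(gene = "g", condition = "cold", bio_rep = rep(1:3, each = 2),
                   tech_rep = rep(1:2, 3),
                   ct_target = 21 + c(0.5, -0.5, 0.2, -0.2, 0, 0),
                   ct_reference = 20))
  r <- relative_quantity(q, "control")
  # tech averages cancel the symmetric noise exactly
  expect_equal(r$rq[r$condition == "cold"], 2)
  expect_equal(r$n_bio, c(3, 3))
})

test_that("planted fold changes are recovered from generated Ct tables", {
  co <- generate_cohort(small_cohort_config(), seed = 67)
  r <- relative_quantity(co$qpcr, "control")
  j <- dplyr::inner_join(r, co$manifest$fold_changes,
                         by = c("gene", "condition"))
  j <- j[j$condition != "control", ]
  expect_true(all(abs(j$rq / j$fold_change - 1) < 0.35))
  expect_lt(mean(abs(j$rq / j$fold_change - 1)), 0.15)
})

test_that("heatmap transform is exact on the worked matrix and never NaN", {
  m <- matrix(c(0, 3, 3, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  h <- heatmap_matrix(m, z_score = FALSE, cluster_rows = FALSE)
  expect_equal(unname(h$matrix), matrix(c(0, 2, 2, 0), 2, 2, byrow = TRUE))
  mz <- rbind(zero = c(0, 0, 0), const = c(5, 5, 5), var = c(0, 3, 7))
  colnames(mz) <- c("a", "b", "c")
  hz <- heatmap_matrix(mz)
  expect_true(all(is.finite(hz$matrix)))
  expect_equal(unname(hz$matrix["zero", ]), c(0, 0, 0))
  expect_equal(unname(hz$matrix["const", ]), c(0, 0, 0))
})

test_that("row clustering only reorders rows", {
  set.seed(71)
  m <- matrix(stats::runif(40, 0, 50), 8, 5,
              dimnames = list(paste0("g", 1:8), paste0("t", 1:5)))
  h <- heatmap_matrix(m)
  expect_setequal(h$row_order, 1:8)
  expect_equal(dim(h$matrix), dim(m))
})

test_that("tissue specificity flags follow the fraction rule", {
  m <- rbind(spec = c(0, 0, 10, 0), flat = c(1, 1, 1, 1),
             off = c(0.2, 0.3, 0.1, 0.4))
  colnames(m) <- c("EMB", "ROO", "LEA", "CAR")
  f <- tissue_specificity_flags(m)
  expect_equal(f$specific_tissues[[1]], "LEA")
  expect_length(f$specific_tissues[[2]], 0)
  expect_true(f$not_expressed[3])
  expect_false(f$not_expressed[1])
  expect_error(tissue_specificity_flags(m[, 1, drop = FALSE]), "2 conditions")
})

test_that("the planted null tissue is reported unexpressed in the cohort", {
  co <- generate_cohort(small_cohort_config(), seed = 73)
  inf1 <- co$fpkm$INF1
  expect_true(all(inf1 == 0))
  f <- tissue_specificity_flags(co$fpkm)
  spec_truth <- co$manifest$specific_tissues
  for (i in seq_len(nrow(spec_truth))) {
    got <- f$specific_tissues[[match(spec_truth$gene[i], f$gene)]]
    planted <- spec_truth$tissues[[i]]
    if (length(planted) == 1) expect_true(planted %in% got)
  }
})
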