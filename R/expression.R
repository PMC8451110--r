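# Expression summaries: 2^-ddCt relative quantification of qRT-PCR tables
# with Welch significance calls, heatmap transforms of FPKM matrices, and
# tissue-specificity flags.

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged per biological sample; dCt =
#' Ct_target - Ct_reference; ddCt = dCt - mean calibrator dCt; the
#' per-condition relative quantity is `2^-(mean ddCt)` over biological
#' replicates (so the calibrator condition is exactly 1), with the standard
#' error taken over the per-replicate `2^-ddCt` values. Significance versus
#' the calibrator is a two-sided Welch t-test on the dCt values; stars
#' follow the usual convention (`**` p < 0.01, `*` p < 0.05, `ns`
#' otherwise).
#'
#' @param qpcr Long-format tibble with columns `gene`, `condition`,
#'   `bio_rep`, `tech_rep`, `ct_target`, `ct_reference`.
#' @param calibrator Calibrator condition label (e.g. `"control"`).
#' @return A tibble `gene`, `condition`, `n_bio`, `rq`, `se`, `p_value`,
#'   `stars`.
#' @export
relative_quantity <- function(qpcr, calibrator) {
  need <- c("gene", "condition", "bio_rep", "ct_target", "ct_reference")
  stopifnot(all(need %in% names(qpcr)))
  if (!all(is.finite(qpcr$ct_target)) || !all(is.finite(qpcr$ct_reference))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  # average technical replicates per biological sample
  dct <- qpcr |>
    dplyr::group_by(.data$gene, .data$condition, .data$bio_rep) |>
    dplyr::summarise(dct = mean(.data$ct_target - .data$ct_reference),
                     .groups = "drop")
  rows <- list()
  for (g in unique(dct$gene)) {
    dg <- dct[dct$gene == g, ]
    cal <- dg$dct[dg$condition == calibrator]
    if (length(cal) == 0) {
      stop("no calibrator condition '", calibrator, "' for gene '", g, "'",
           call. = FALSE)
    }
    for (cond in unique(dg$condition)) {
      x <- dg$dct[dg$condition == cond]
      ddct <- x - mean(cal)
      rq_reps <- 2^(-ddct)
      p <- NA_real_
      if (cond != calibrator) {
        if (length(x) < 2 || length(cal) < 2) {
          warning("gene '", g, "', condition '", cond,
                  "': fewer than 2 biological replicates; no p-value",
                  call. = FALSE)
        } else if (stats::sd(x) == 0 && stats::sd(cal) == 0) {
          # degenerate noise-free case: the Welch statistic is undefined
          p <- if (isTRUE(all.equal(mean(x), mean(cal)))) 1 else 0
        } else {
          p <- stats::t.test(x, cal, var.equal = FALSE)$p.value
        }
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene = g, condition = cond, n_bio = length(x),
        rq = 2^(-(mean(x) - mean(cal))),
        se = if (length(x) > 1) stats::sd(rq_reps) / sqrt(length(x)) else NA_real_,
        p_value = p,
        stars = dplyr::case_when(is.na(p) ~ NA_character_,
                                 p < 0.01 ~ "**",
                                 p < 0.05 ~ "*",
                                 TRUE ~ "ns"))
    }
  }
  dplyr::bind_rows(rows)
}

#' Heatmap-ready transform of an expression matrix
#'
#' Applies `log2(x + 1)` and optionally a per-row z-score (rows with zero
#' variance map to 0, never NaN); the row display order comes from
#' average-linkage clustering of the correlation distance `1 - cor`
#' (constant rows get distance 1 to everything). The transform never
#' produces non-finite values.
#'
#' @param expr A numeric matrix (genes x conditions) or a tibble whose
#'   first column holds gene ids.
#' @param log2_transform,z_score Toggles for the two transform stages.
#' @param cluster_rows Order rows by clustering (display only).
#' @return A list of class `ltp_heatmap`: `matrix` (transformed),
#'   `row_order`, `col_order`.
#' @export
heatmap_matrix <- function(expr, log2_transform = TRUE, z_score = TRUE,
                           cluster_rows = TRUE) {
  m <- as_expr_matrix(expr)
  if (any(m < 0)) stop("expression values must be non-negative", call. = FALSE)
  if (log2_transform) m <- log2(m + 1)
  if (z_score) {
    m <- t(apply(m, 1, function(r) {
      s <- stats::sd(r)
      if (!is.finite(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
    }))
  }
  row_order <- seq_len(nrow(m))
  if (cluster_rows && nrow(m) > 2) {
    cc <- suppressWarnings(stats::cor(t(m)))
    cc[!is.finite(cc)] <- 0
    hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
    row_order <- hc$order
  }
  structure(list(matrix = m, row_order = row_order,
                 col_order = seq_len(ncol(m))),
            class = "ltp_heatmap")
}

as_expr_matrix <- function(expr) {
  if (is.matrix(expr)) return(expr)
  ids <- expr[[1]]
  m <- as.matrix(expr[, -1, drop = FALSE])
  rownames(m) <- ids
  m
}

#' @export
autoplot.ltp_heatmap <- function(object, ...) {
  m <- object$matrix[object$row_order, , drop = FALSE]
  df <- tibble::tibble(
    gene = factor(rep(rownames(m), ncol(m)), levels = rev(rownames(m))),
    condition = factor(rep(colnames(m), each = nrow(m)), levels = colnames(m)),
    value = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$gene,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = NULL, y = NULL, fill = "expr") +
    ggplot2::theme_minimal()
}

#' Tissue-specificity flags
#'
#' A gene is *specific* to the tissues holding at least
#' `specificity_fraction` of its row total; genes with every value below
#' `min_expr` are flagged not expressed.
#'
#' @inheritParams heatmap_matrix
#' @param specificity_fraction Fraction of the row total calling a tissue
#'   specific (default 0.5).
#' @param min_expr Expression floor (default 1, in FPKM units).
#' @return A tibble `gene`, `specific_tissues` (list-column),
#'   `not_expressed`.
#' @export
tissue_specificity_flags <- function(expr, specificity_fraction = 0.5,
                                     min_expr = 1) {
  m <- as_expr_matrix(expr)
  if (ncol(m) < 2) stop("need at least 2 conditions", call. = FALSE)
  rows <- purrr::map(seq_len(nrow(m)), function(i) {
    r <- m[i, ]
    not_expr <- all(r < min_expr)
    spec <- character(0)
    if (!not_expr && sum(r) > 0) {
      spec <- colnames(m)[r / sum(r) >= specificity_fraction]
    }
    tibble::tibble(gene = rownames(m)[i], specific_tissues = list(spec),
                   not_expressed = not_expr)
  })
  dplyr::bind_rows(rows)
}
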