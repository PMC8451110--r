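# Gene-model context: intron counts and positions relative to the codon of
# the eighth motif cysteine, chromosome localization, tandem/segmental
# duplication calls.

# Map a 0-based transcript (CDS) coordinate to its 0-based genomic position,
# strand-aware.
cds_to_genomic <- function(cds, strand, t) {
  cds <- cds[order(cds$start), , drop = FALSE]
  lens <- cds$end - cds$start
  total <- sum(lens)
  if (t < 0 || t >= total) {
    stop("transcript coordinate ", t, " outside CDS (length ", total, ")",
         call. = FALSE)
  }
  if (strand == "-") {
    cds <- cds[rev(seq_len(nrow(cds))), , drop = FALSE]
    lens <- rev(lens)
  }
  cum <- cumsum(c(0, lens))
  k <- findInterval(t, cum, rightmost.closed = FALSE)
  off <- t - cum[k]
  if (strand == "+") cds$start[k] + off else cds$end[k] - 1 - off
}

#' Intron statistics relative to the eighth-cysteine codon
#'
#' For each gene, reports the intron count and each intron's offset in bp
#' from the first base of the codon encoding the eighth motif cysteine,
#' measured along the spliced coding sequence in transcript orientation
#' (negative = upstream of that codon). Spliced coordinates are the only
#' measure under which two introns can both sit within a few dozen bp of
#' the codon; the exon walk is strand-aware, so offsets are invariant under
#' coordinate reflection of the locus.
#'
#' @param genes A gene-model tibble ([gene_model_tbl()]).
#' @param cys8 Integer vector (recycled) of 1-based residue positions of the
#'   eighth motif cysteine in each gene's protein.
#' @return A tibble `gene_id`, `n_introns`, `offsets` (list-column of
#'   per-intron offsets in transcript order).
#' @export
intron_stats <- function(genes, cys8) {
  cys8 <- rep_len(as.integer(cys8), nrow(genes))
  rows <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    cds <- g$cds[[1]][order(g$cds[[1]]$start), , drop = FALSE]
    lens <- cds$end - cds$start
    if (g$strand == "-") lens <- rev(lens)       # transcript order
    cds_len <- sum(lens)
    t8 <- (cys8[i] - 1L) * 3L
    if (t8 + 3L > cds_len) {
      stop("eighth-cysteine codon of '", g$gene_id,
           "' lies beyond the CDS (protein/CDS mismatch)", call. = FALSE)
    }
    n_int <- length(lens) - 1L
    offsets <- if (n_int > 0) cumsum(lens)[seq_len(n_int)] - t8 else numeric(0)
    tibble::tibble(gene_id = g$gene_id, n_introns = n_int,
                   offsets = list(as.numeric(offsets)))
  })
  dplyr::bind_rows(rows)
}

#' Duplication-detection configuration
#'
#' @param identity_cutoff Minimum percent identity between the linked
#'   proteins for a pair to be considered duplicated.
#' @param max_intervening Maximum number of other family genes between a
#'   tandem pair on the chromosome.
#' @param window_bp Maximum genomic separation (bp) for a tandem call.
#' @return A list of class `dup_config`.
#' @export
dup_config <- function(identity_cutoff = 50, max_intervening = 5,
                       window_bp = 1e5) {
  structure(list(identity_cutoff = identity_cutoff,
                 max_intervening = max_intervening, window_bp = window_bp),
            class = "dup_config")
}

gene_spans <- function(genes) {
  tibble::tibble(
    gene_id = genes$gene_id,
    chromosome = genes$chromosome,
    start = vapply(genes$exons, function(e) min(e$start), numeric(1)),
    end = vapply(genes$exons, function(e) max(e$end), numeric(1))
  )
}

#' Detect tandem and segmental-candidate duplications
#'
#' A pair of family genes whose linked proteins share at least
#' `identity_cutoff` percent identity is called *tandem* when both genes lie
#' on the same chromosome, at most `max_intervening` family genes apart and
#' within `window_bp`; high-identity pairs failing the tandem geometry are
#' *segmental candidates* (true segmental assignment would need synteny
#' blocks, which is out of scope).
#'
#' @param genes A gene-model tibble.
#' @param identity A symmetric percent-identity matrix whose dimnames cover
#'   all `protein_id`s of `genes`.
#' @param config A [dup_config()].
#' @return A tibble of events: `gene_a`, `gene_b`, `kind` (`tandem` /
#'   `segmental_candidate`), `identity`, `separation_bp`, `intervening`.
#' @export
find_duplications <- function(genes, identity, config = dup_config()) {
  missing <- setdiff(genes$protein_id, rownames(identity))
  if (length(missing) > 0) {
    stop("identity matrix lacks rows for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  spans <- gene_spans(genes)
  placed <- !(is.na(spans$chromosome) | spans$chromosome %in% c("0", "chrUn"))
  rows <- list()
  n <- nrow(genes)
  for (i in seq_len(max(0, n - 1))) {
    for (j in (i + 1):n) {
      if (n < 2) break
      ident <- identity[genes$protein_id[i], genes$protein_id[j]]
      if (ident < config$identity_cutoff) next
      same_chr <- placed[i] && placed[j] &&
        spans$chromosome[i] == spans$chromosome[j]
      sep <- NA_real_; interv <- NA_integer_
      if (same_chr) {
        sep <- max(0, max(spans$start[i], spans$start[j]) -
                     min(spans$end[i], spans$end[j]))
        lo <- min(spans$start[i], spans$start[j])
        hi <- max(spans$start[i], spans$start[j])
        interv <- as.integer(sum(
          spans$chromosome == spans$chromosome[i] &
            spans$start > lo & spans$start < hi &
            !spans$gene_id %in% c(spans$gene_id[i], spans$gene_id[j])))
      }
      tandem <- same_chr && sep <= config$window_bp &&
        interv <= config$max_intervening
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene_a = genes$gene_id[i], gene_b = genes$gene_id[j],
        kind = if (tandem) "tandem" else "segmental_candidate",
        identity = ident, separation_bp = sep, intervening = interv)
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(gene_a = character(), gene_b = character(),
                          kind = character(), identity = numeric(),
                          separation_bp = numeric(), intervening = integer()))
  }
  dplyr::bind_rows(rows)
}

#' Tandem clusters by transitive closure
#'
#' Groups genes connected by tandem duplication events into clusters
#' (union-find closure); clusters partition the tandem genes.
#'
#' @param events Event tibble from [find_duplications()].
#' @return A tibble `gene_id`, `cluster` (integer cluster ids).
#' @export
tandem_clusters <- function(events) {
  ev <- events[events$kind == "tandem", ]
  ids <- unique(c(ev$gene_a, ev$gene_b))
  if (length(ids) == 0) {
    return(tibble::tibble(gene_id = character(), cluster = integer()))
  }
  parent <- stats::setNames(ids, ids)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (k in seq_len(nrow(ev))) {
    ra <- find(ev$gene_a[k]); rb <- find(ev$gene_b[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(ids, find, character(1))
  tibble::tibble(gene_id = ids,
                 cluster = as.integer(factor(roots, levels = unique(roots))))
}

#' Chromosome map of family genes
#'
#' Groups genes by chromosome, ordered by start coordinate. Genes without a
#' placement (`NA`, `"0"` or `"chrUn"`) are listed under `chrUn` and flagged
#' unplaced.
#'
#' @param genes A gene-model tibble.
#' @return A tibble `chromosome`, `n`, `genes` (list-column of ordered gene
#'   ids), `placed`; the per-chromosome counts plus the `chrUn` row account
#'   for every input gene.
#' @export
chromosome_map <- function(genes) {
  if (nrow(genes) == 0) {
    return(tibble::tibble(chromosome = character(), n = integer(),
                          genes = list(), placed = logical()))
  }
  spans <- gene_spans(genes)
  spans$chromosome[is.na(spans$chromosome) |
                     spans$chromosome %in% c("0", "chrUn")] <- "chrUn"
  spans <- spans[order(spans$chromosome != "chrUn", spans$chromosome,
                       spans$start), ]
  out <- spans |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::summarise(n = dplyr::n(), genes = list(.data$gene_id),
                     .groups = "drop") |>
    dplyr::mutate(placed = .data$chromosome != "chrUn") |>
    dplyr::arrange(dplyr::desc(.data$placed), .data$chromosome)
  out
}
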