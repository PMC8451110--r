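# Promoter analysis: extraction of ~1.5 kb upstream regions (anchored at
# the translation start) and double-stranded IUPAC consensus scanning.

#' Load a cis-element catalog
#'
#' @param path Optional YAML path; defaults to the packaged PlantCARE-style
#'   catalog. Each element has a `name`, an IUPAC `consensus` and a
#'   `category` (stress / hormone / light / development / core).
#' @return A tibble `name`, `consensus`, `category`.
#' @export
cis_element_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cis_elements.yaml", package = "nsltpkit",
                        mustWork = TRUE)
  }
  y <- yaml::read_yaml(path)
  out <- dplyr::bind_rows(purrr::map(y$elements, tibble::as_tibble))
  validate_catalog(out)
  out
}

validate_catalog <- function(catalog) {
  stopifnot(all(c("name", "consensus") %in% names(catalog)))
  bad <- !grepl("^[ACGTRYSWKMBDHVN]+$", catalog$consensus)
  if (any(bad)) {
    stop("malformed IUPAC consensus for: ",
         paste(catalog$name[bad], collapse = ", "), call. = FALSE)
  }
  invisible(catalog)
}

reverse_complement <- function(x) {
  vapply(x, function(s) {
    paste(rev(unname(DNA_COMPLEMENT[aa_residues(s)])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

iupac_regex <- function(consensus) {
  paste(vapply(aa_residues(consensus), function(ch) {
    opts <- IUPAC_DNA[[ch]]
    if (length(opts) == 1) opts else paste0("[", paste(opts, collapse = ""), "]")
  }, character(1)), collapse = "")
}

overlapping_starts <- function(sequence, regex) {
  m <- gregexpr(paste0("(?=", regex, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Extract the upstream (promoter) region of a gene
#'
#' Strand-aware extraction of the `length` bp immediately upstream of the
#' translation start (the first CDS base): for `+` genes the window
#' `[TSS - length, TSS)`; for `-` genes the reverse complement of
#' `(TSS, TSS + length]`. Windows extending past the contig edge are
#' truncated with a warning.
#'
#' @param genome Named character vector or `Biostrings::DNAStringSet` of
#'   contig sequences.
#' @param genes A gene-model tibble.
#' @param length Window length in bp (default 1500).
#' @return A tibble `gene_id`, `promoter`, `width`, `truncated`.
#' @export
extract_upstream <- function(genome, genes, length = 1500) {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  rows <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    if (!g$chromosome %in% names(genome)) {
      stop("gene '", g$gene_id, "' lies on contig '", g$chromosome,
           "' absent from the genome", call. = FALSE)
    }
    contig <- genome[[g$chromosome]]
    clen <- nchar(contig)
    cds <- g$cds[[1]]
    truncated <- FALSE
    if (g$strand == "+") {
      tss <- min(cds$start)            # 0-based first CDS base
      from <- tss - length
      if (from < 0) { from <- 0; truncated <- TRUE }
      prom <- substr(contig, from + 1, tss)
    } else {
      tss <- max(cds$end)              # 0-based position just after CDS
      to <- tss + length
      if (to > clen) { to <- clen; truncated <- TRUE }
      prom <- reverse_complement(substr(contig, tss + 1, to))
    }
    if (truncated) {
      warning("promoter of '", g$gene_id, "' truncated at the contig edge (",
              nchar(prom), " bp)", call. = FALSE)
    }
    tibble::tibble(gene_id = g$gene_id, promoter = prom,
                   width = nchar(prom), truncated = truncated)
  })
  dplyr::bind_rows(rows)
}

#' Scan a sequence for cis-elements
#'
#' Reports every position and strand where an element's IUPAC consensus
#' matches (overlapping matches included; `N` in the sequence matches
#' nothing). A palindromic consensus matching the same footprint on both
#' strands is collapsed to strand `"±"`. Output is sorted by start,
#' then element name.
#'
#' @param sequence A promoter sequence over `ACGTN` (single string).
#' @param catalog A catalog tibble ([cis_element_catalog()]).
#' @return A tibble `element`, `start`, `end` (1-based within the
#'   sequence), `strand` (`+`/`-`/`±`), `match` (the matched
#'   substring on the forward strand).
#' @export
scan_promoter <- function(sequence, catalog = cis_element_catalog()) {
  validate_catalog(catalog)
  stopifnot(grepl("^[ACGTN]*$", sequence))
  rows <- list()
  for (k in seq_len(nrow(catalog))) {
    cons <- catalog$consensus[k]
    w <- nchar(cons)
    fwd <- overlapping_starts(sequence, iupac_regex(cons))
    rev_ <- overlapping_starts(sequence, iupac_regex(reverse_complement(cons)))
    both <- intersect(fwd, rev_)
    strands <- c(rep("+", length(setdiff(fwd, both))),
                 rep("-", length(setdiff(rev_, both))),
                 rep("±", length(both)))
    starts <- c(setdiff(fwd, both), setdiff(rev_, both), both)
    if (length(starts) == 0) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      element = catalog$name[k], start = starts, end = starts + w - 1L,
      strand = strands,
      match = substr(rep(sequence, length(starts)), starts, starts + w - 1L))
  }
  if (length(rows) == 0) {
    return(tibble::tibble(element = character(), start = integer(),
                          end = integer(), strand = character(),
                          match = character()))
  }
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$start, .data$element)
}

#' Scan many promoters
#'
#' @param promoters Tibble `gene_id`, `promoter` (from [extract_upstream()]).
#' @inheritParams scan_promoter
#' @return Hit tibble as [scan_promoter()] with a leading `gene_id` column.
#' @export
scan_promoters <- function(promoters, catalog = cis_element_catalog()) {
  dplyr::bind_rows(purrr::map(seq_len(nrow(promoters)), function(i) {
    hits <- scan_promoter(promoters$promoter[i], catalog)
    if (nrow(hits) > 0) hits$gene_id <- promoters$gene_id[i]
    hits
  })) |> dplyr::relocate(dplyr::any_of("gene_id"))
}

#' Per-gene element count matrix
#'
#' @param hits Hit tibble from [scan_promoters()].
#' @return A wide tibble: one row per gene, one column per element, counts.
#' @export
element_counts <- function(hits) {
  hits |>
    dplyr::count(.data$gene_id, .data$element) |>
    tidyr::pivot_wider(names_from = "element", values_from = "n",
                       values_fill = 0L)
}

#' Compare the cis-element organization of two promoters
#'
#' Two promoters have *identical organization* when their hit multisets of
#' (element, start, strand) are equal.
#'
#' @param hits_a,hits_b Hit tibbles from [scan_promoter()] computed with the
#'   same catalog.
#' @return A list with `shared_elements`, `unique_a`, `unique_b`
#'   (occurrence-level multiset differences) and `identical_organization`.
#' @export
compare_organization <- function(hits_a, hits_b) {
  keyed <- function(h) {
    h |>
      dplyr::count(.data$element, .data$start, .data$strand, name = "n")
  }
  a <- keyed(hits_a); b <- keyed(hits_b)
  j <- dplyr::full_join(a, b, by = c("element", "start", "strand"),
                        suffix = c("_a", "_b")) |>
    dplyr::mutate(n_a = tidyr::replace_na(.data$n_a, 0L),
                  n_b = tidyr::replace_na(.data$n_b, 0L))
  list(
    shared_elements = sort(intersect(unique(hits_a$element),
                                     unique(hits_b$element))),
    unique_a = j |> dplyr::filter(.data$n_a > .data$n_b) |>
      dplyr::mutate(n = .data$n_a - .data$n_b) |>
      dplyr::select("element", "start", "strand", "n"),
    unique_b = j |> dplyr::filter(.data$n_b > .data$n_a) |>
      dplyr::mutate(n = .data$n_b - .data$n_a) |>
      dplyr::select("element", "start", "strand", "n"),
    identical_organization = all(j$n_a == j$n_b)
  )
}
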