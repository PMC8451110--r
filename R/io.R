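#' Build a protein table
#'
#' Constructs and validates the tibble of candidate proteins used throughout
#' the screening pipeline: one row per protein with a unique `id`, an
#' uppercase amino-acid `sequence` (20 standard letters plus `X`), a free-text
#' `source` label (e.g. `"barley"`, `"qingke"`) and a `description`.
#'
#' @param id Character vector of unique protein identifiers.
#' @param sequence Character vector of amino-acid sequences.
#' @param source Source label(s), recycled.
#' @param description Free-text description(s), recycled.
#' @return A tibble with columns `id`, `sequence`, `source`, `description`.
#' @export
protein_tbl <- function(id, sequence, source = NA_character_,
                        description = NA_character_) {
  if (anyDuplicated(id)) {
    stop("protein ids must be unique", call. = FALSE)
  }
  sequence <- toupper(sequence)
  purrr::walk2(sequence, id, function(s, i) {
    if (grepl("\\s", s)) stop("sequence for '", i, "' contains whitespace",
                              call. = FALSE)
    assert_protein_sequence(s, arg = i)
  })
  tibble::tibble(id = as.character(id), sequence = sequence,
                 source = rep_len(as.character(source), length(id)),
                 description = rep_len(as.character(description), length(id)))
}

#' Read a protein FASTA file into a tibble
#'
#' @param path Path to a (multi-)FASTA file of protein sequences.
#' @param source Source label attached to every record.
#' @return A tibble as produced by [protein_tbl()].
#' @export
read_protein_fasta <- function(path, source = NA_character_) {
  ss <- Biostrings::readAAStringSet(path)
  nm <- names(ss)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), NA_character_)
  protein_tbl(id = id, sequence = unname(as.character(ss)),
              source = source, description = desc)
}

#' Write sequences to FASTA
#'
#' @param tbl A tibble with `id` and a sequence column.
#' @param path Output file path.
#' @param sequence_col Name of the sequence column.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(tbl, path, sequence_col = "sequence") {
  seqs <- tbl[[sequence_col]]
  lines <- character(0)
  for (i in seq_len(nrow(tbl))) {
    lines <- c(lines, paste0(">", tbl$id[i]),
               gsub("(.{60})", "\\1\n", seqs[i]))
  }
  writeLines(lines, path)
  invisible(path)
}

# Gene models ---------------------------------------------------------------

#' Build a gene-model table
#'
#' One row per gene. Exon and CDS intervals are stored as list-columns of
#' data frames with 0-based half-open `start`/`end` coordinates on the
#' forward strand, sorted and non-overlapping; all user-facing I/O (GFF3,
#' reports) is 1-based inclusive.
#'
#' @param gene_id,protein_id Character vectors (protein linkage optional).
#' @param chromosome Chromosome name; `NA` or `"0"` means unplaced.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds Lists of data frames with columns `start`, `end`
#'   (0-based half-open).
#' @return A tibble of gene models.
#' @export
gene_model_tbl <- function(gene_id, chromosome, strand, exons, cds,
                           protein_id = gene_id) {
  stopifnot(length(gene_id) == length(chromosome),
            all(strand %in% c("+", "-")))
  check_iv <- function(iv, gid, what) {
    iv <- iv[order(iv$start), , drop = FALSE]
    if (any(iv$end <= iv$start)) {
      stop(what, " intervals of '", gid, "' must be non-empty", call. = FALSE)
    }
    if (nrow(iv) > 1 && any(iv$start[-1] < iv$end[-nrow(iv)])) {
      stop(what, " intervals of '", gid, "' overlap", call. = FALSE)
    }
    iv
  }
  exons <- purrr::map2(exons, gene_id, check_iv, what = "exon")
  cds <- purrr::map2(cds, gene_id, check_iv, what = "CDS")
  purrr::walk2(cds, gene_id, function(iv, gid) {
    if (sum(iv$end - iv$start) %% 3L != 0L) {
      stop("CDS length of '", gid, "' is not divisible by 3", call. = FALSE)
    }
  })
  tibble::tibble(gene_id = as.character(gene_id),
                 protein_id = as.character(protein_id),
                 chromosome = as.character(chromosome),
                 strand = strand, exons = exons, cds = cds)
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene`/`mRNA`/`exon`/`CDS` features (via `rtracklayer`) into the
#' package's gene-model tibble. GFF3 coordinates (1-based inclusive) are
#' converted to the internal 0-based half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @return A gene-model tibble (see [gene_model_tbl()]).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  genes <- df[df$type == "gene", , drop = FALSE]
  out <- purrr::map(seq_len(nrow(genes)), function(i) {
    gid <- genes$ID[i]
    mrna <- df[df$type == "mRNA" & vapply(df$Parent, function(p) any(p == gid), logical(1)), ]
    parent_ids <- c(gid, mrna$ID)
    is_child <- vapply(df$Parent, function(p) any(p %in% parent_ids), logical(1))
    ex <- df[df$type == "exon" & is_child, , drop = FALSE]
    cd <- df[df$type == "CDS" & is_child, , drop = FALSE]
    if (nrow(ex) == 0) ex <- cd
    list(gene_id = gid,
         chromosome = as.character(genes$seqnames[i]),
         strand = as.character(genes$strand[i]),
         exons = data.frame(start = ex$start - 1L, end = ex$end),
         cds = data.frame(start = cd$start - 1L, end = cd$end))
  })
  gene_model_tbl(
    gene_id = purrr::map_chr(out, "gene_id"),
    chromosome = purrr::map_chr(out, "chromosome"),
    strand = purrr::map_chr(out, "strand"),
    exons = purrr::map(out, "exons"),
    cds = purrr::map(out, "cds")
  )
}

#' Write gene models to GFF3
#'
#' @param genes A gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- g$exons[[1]]; cd <- g$cds[[1]]
    span <- range(c(ex$start, cd$start, ex$end, cd$end))
    rid <- paste0(g$gene_id, ".m1")
    fmt <- function(type, start0, end0, id = NULL, parent = NULL) {
      attrs <- c(if (!is.null(id)) paste0("ID=", id),
                 if (!is.null(parent)) paste0("Parent=", parent))
      sprintf("%s\tnsltpkit\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$chromosome, type, start0 + 1L, end0, g$strand,
              paste(attrs, collapse = ";"))
    }
    lines <- c(lines,
               fmt("gene", span[1], span[2], id = g$gene_id),
               fmt("mRNA", span[1], span[2], id = rid, parent = g$gene_id),
               unlist(lapply(seq_len(nrow(ex)), function(j)
                 fmt("exon", ex$start[j], ex$end[j], parent = rid))),
               unlist(lapply(seq_len(nrow(cd)), function(j)
                 fmt("CDS", cd$start[j], cd$end[j], parent = rid))))
  }
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
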