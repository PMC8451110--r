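# Type assignment (Edstam scheme: 1/2/C/D/E/F/G/X) from GPI status,
# cysteine spacing, intron evidence and identity to exemplars; plus the
# cysteine-anchored 8CM alignment and CXC polarity summary.

#' Load nsLTP type profiles
#'
#' Reads the per-type classification profiles: allowed ranges for the five
#' free inter-cysteine gaps, expected intron counts, and whether the type
#' carries a GPI anchor. The packaged default is editable configuration
#' (the discriminating thresholds are not published); pass your own YAML to
#' override.
#'
#' @param path Optional YAML path; defaults to the packaged profile set.
#' @return A tibble with columns `type`, `g1_min`..`g5_max`, `introns`
#'   (list-column of allowed counts) and `gpi`.
#' @export
type_profiles <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "type_profiles.yaml", package = "nsltpkit",
                        mustWork = TRUE)
  }
  y <- yaml::read_yaml(path)
  rows <- purrr::map(y$types, function(p) {
    stopifnot(!is.null(p$type), length(p$g1) == 2)
    tibble::tibble(
      type = as.character(p$type),
      g1_min = p$g1[1], g1_max = p$g1[2], g2_min = p$g2[1], g2_max = p$g2[2],
      g3_min = p$g3[1], g3_max = p$g3[2], g4_min = p$g4[1], g4_max = p$g4[2],
      g5_min = p$g5[1], g5_max = p$g5[2],
      introns = list(as.integer(p$introns)), gpi = isTRUE(p$gpi))
  })
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out$type)) stop("duplicate type labels in profiles",
                                    call. = FALSE)
  out
}

#' Percent identity from a global alignment
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0 and linear
#' gap penalty -1; identity is the number of identical aligned pairs over
#' the number of alignment columns, in percent. Symmetric by construction.
#'
#' @param a,b Protein sequences (single strings).
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b) {
  assert_protein_sequence(a, "a"); assert_protein_sequence(b, "b")
  letters <- union(unique(aa_residues(a)), unique(aa_residues(b)))
  mat <- diag(1, length(letters))
  dimnames(mat) <- list(letters, letters)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 1)
  pa <- aa_residues(as.character(Biostrings::alignedPattern(al)))
  sa <- aa_residues(as.character(Biostrings::alignedSubject(al)))
  100 * sum(pa == sa & pa != "-") / length(pa)
}

#' Symmetric identity matrix for a protein cohort
#'
#' @param proteins Tibble with `id` and a sequence column.
#' @param sequence_col Column holding the sequences to compare.
#' @return A symmetric percent-identity matrix with unit (= 100) diagonal.
#' @export
identity_matrix <- function(proteins, sequence_col = "sequence") {
  n <- nrow(proteins)
  seqs <- proteins[[sequence_col]]
  m <- matrix(100, n, n, dimnames = list(proteins$id, proteins$id))
  if (n < 2) return(m)
  letters <- unique(unlist(strsplit(seqs, "", fixed = TRUE)))
  smat <- diag(1, length(letters))
  dimnames(smat) <- list(letters, letters)
  for (j in 2:n) {
    pats <- Biostrings::AAStringSet(seqs[seq_len(j - 1)])
    al <- Biostrings::pairwiseAlignment(
      pats, Biostrings::AAString(seqs[j]), type = "global",
      substitutionMatrix = smat, gapOpening = 0, gapExtension = 1)
    pa <- as.character(Biostrings::alignedPattern(al))
    sa <- as.character(Biostrings::alignedSubject(al))
    ident <- vapply(seq_along(pa), function(k) {
      x <- aa_residues(pa[k]); y <- aa_residues(sa[k])
      100 * sum(x == y & x != "-") / length(x)
    }, numeric(1))
    m[seq_len(j - 1), j] <- m[j, seq_len(j - 1)] <- ident
  }
  m
}

#' Cysteine-anchored alignment of 8CM motifs
#'
#' Aligns motif regions by their conserved blocks: each inter-cysteine gap
#' segment is right-padded with `-` to the block's maximum width, so the
#' eight cysteine columns (and the CXC `X` column) line up perfectly in
#' every row. Column count = 8 + sum of maximal gap widths + 1.
#'
#' @param candidates Tibble with `id`, `sequence` and canonical motif
#'   columns `c1`..`c8` (as produced by [run_screen()]).
#' @return An object of class `anchored_alignment`: list with `ids`,
#'   `aligned` (named equal-length strings) and `block_map` (tibble mapping
#'   each column to its block: C1, g1, C2, g2, CC, g3, CXC, g4, C7, g5, C8).
#' @export
build_anchored_alignment <- function(candidates) {
  stopifnot(nrow(candidates) >= 1,
            all(c("c1", "c8", "sequence") %in% names(candidates)))
  cpos <- as.matrix(candidates[, paste0("c", 1:8)])
  segs <- purrr::map(seq_len(nrow(candidates)), function(i) {
    s <- candidates$sequence[i]; p <- cpos[i, ]
    list(g1 = substr(s, p[1] + 1, p[2] - 1), g2 = substr(s, p[2] + 1, p[3] - 1),
         g3 = substr(s, p[4] + 1, p[5] - 1), x = substr(s, p[5] + 1, p[5] + 1),
         g4 = substr(s, p[6] + 1, p[7] - 1), g5 = substr(s, p[7] + 1, p[8] - 1))
  })
  wmax <- vapply(c("g1", "g2", "g3", "g4", "g5"), function(g)
    max(vapply(segs, function(x) nchar(x[[g]]), integer(1))), integer(1))
  pad <- function(x, w) paste0(x, strrep("-", w - nchar(x)))
  aligned <- vapply(segs, function(x) {
    paste0("C", pad(x$g1, wmax[1]), "C", pad(x$g2, wmax[2]), "CC",
           pad(x$g3, wmax[3]), "C", x$x, "C", pad(x$g4, wmax[4]), "C",
           pad(x$g5, wmax[5]), "C")
  }, character(1))
  names(aligned) <- candidates$id
  blocks <- c("C1", rep("g1", wmax[1]), "C2", rep("g2", wmax[2]),
              "CC", "CC", rep("g3", wmax[3]), "CXC", "CXC", "CXC",
              rep("g4", wmax[4]), "C7", rep("g5", wmax[5]), "C8")
  structure(list(ids = candidates$id, aligned = aligned,
                 block_map = tibble::tibble(column = seq_along(blocks),
                                            block = blocks)),
            class = "anchored_alignment")
}

#' @export
print.anchored_alignment <- function(x, ...) {
  cat("Cysteine-anchored 8CM alignment:", length(x$ids), "sequences x",
      nchar(x$aligned[[1]]), "columns\n")
  utils::head(x$aligned)
  invisible(x)
}

#' @export
as.matrix.anchored_alignment <- function(x, ...) {
  do.call(rbind, lapply(x$aligned, function(s) aa_residues(s)))
}

#' Polarity of the CXC middle residue
#'
#' @param x Single residue letter(s).
#' @return `"hydrophobic"` when the Kyte-Doolittle value is positive,
#'   `"hydrophilic"` otherwise.
#' @export
cxc_polarity <- function(x) {
  ifelse(residue_kd(x) > 0, "hydrophobic", "hydrophilic")
}

#' Assign nsLTP types
#'
#' Rule cascade: (1) GPI-positive candidates are type G; (2) otherwise the
#' candidate types are those profiles whose five gap ranges all contain the
#' spacing vector and whose intron expectation matches the gene model when
#' intron evidence is available; (3) ties are broken by highest mean
#' identity to the type's exemplars, then by the lexicographically smallest
#' label; (4) with no candidate type (and no exemplar at or above the
#' identity threshold) the protein is typed X. Confidence is the mean
#' exemplar identity, 0 when typed by rules alone.
#'
#' @param candidates Tibble with `id`, `g1`..`g5`, `gpi_positive` and (when
#'   exemplars are used) `mature_sequence` (e.g. `tidy()` of [run_screen()]).
#' @param profiles A profile tibble from [type_profiles()].
#' @param gene_introns Optional tibble `id`, `introns` linking each protein
#'   to its gene-model intron count; classification degrades gracefully to
#'   spacing + identity without it.
#' @param exemplars Optional tibble `id`, `type`, `sequence` of typed
#'   exemplar proteins.
#' @param identity_threshold Minimum exemplar identity (percent) for an
#'   identity-only call.
#' @return Tibble `id`, `type`, `confidence`.
#' @export
assign_type <- function(candidates, profiles = type_profiles(),
                        gene_introns = NULL, exemplars = NULL,
                        identity_threshold = 30) {
  mean_ident <- function(seq, type) {
    ex <- exemplars[exemplars$type == type, ]
    if (is.null(exemplars) || nrow(ex) == 0 || is.na(seq)) return(NA_real_)
    mean(vapply(ex$sequence, pairwise_identity, numeric(1), b = seq))
  }
  rows <- purrr::map(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    if (isTRUE(cand$gpi_positive)) {
      conf <- mean_ident(cand$mature_sequence, "G")
      return(tibble::tibble(id = cand$id, type = "G",
                            confidence = ifelse(is.na(conf), 0, conf)))
    }
    gaps <- as.numeric(cand[, paste0("g", 1:5)])
    in_range <- vapply(seq_len(nrow(profiles)), function(j) {
      p <- profiles[j, ]
      all(gaps >= c(p$g1_min, p$g2_min, p$g3_min, p$g4_min, p$g5_min)) &&
        all(gaps <= c(p$g1_max, p$g2_max, p$g3_max, p$g4_max, p$g5_max))
    }, logical(1))
    hits <- profiles$type[in_range]
    if (!is.null(gene_introns) && cand$id %in% gene_introns$id) {
      n_introns <- gene_introns$introns[match(cand$id, gene_introns$id)]
      ok <- vapply(hits, function(tp) {
        n_introns %in% profiles$introns[[match(tp, profiles$type)]]
      }, logical(1))
      hits <- hits[ok]
    }
    if (length(hits) == 1) {
      conf <- mean_ident(cand$mature_sequence, hits)
      return(tibble::tibble(id = cand$id, type = hits,
                            confidence = ifelse(is.na(conf), 0, conf)))
    }
    if (length(hits) > 1) {
      idents <- vapply(hits, function(tp) mean_ident(cand$mature_sequence, tp),
                       numeric(1))
      if (all(is.na(idents))) {
        pick <- sort(hits)[1]
        return(tibble::tibble(id = cand$id, type = pick, confidence = 0))
      }
      best <- which(idents == max(idents, na.rm = TRUE))
      pick <- sort(hits[best])[1]
      return(tibble::tibble(id = cand$id, type = pick,
                            confidence = max(idents, na.rm = TRUE)))
    }
    # No spacing/intron candidate: fall back to exemplar identity, else X.
    if (!is.null(exemplars) && nrow(exemplars) > 0 &&
        !is.na(cand$mature_sequence)) {
      types <- unique(exemplars$type)
      idents <- vapply(types, function(tp) mean_ident(cand$mature_sequence, tp),
                       numeric(1))
      if (max(idents, na.rm = TRUE) >= identity_threshold) {
        best <- which(idents == max(idents, na.rm = TRUE))
        return(tibble::tibble(id = cand$id, type = sort(types[best])[1],
                              confidence = max(idents, na.rm = TRUE)))
      }
    }
    tibble::tibble(id = cand$id, type = "X", confidence = 0)
  })
  dplyr::bind_rows(rows)
}

#' Typed catalog of accepted nsLTPs
#'
#' Convenience wrapper: takes a screening result, assigns types and returns
#' the catalog table (id, type, confidence, spacing vector, CXC residue and
#' polarity).
#'
#' @param screen An `ltp_screen` object (or its candidate tibble).
#' @inheritParams assign_type
#' @return A tibble, one row per accepted protein.
#' @export
classify_candidates <- function(screen, profiles = type_profiles(),
                                gene_introns = NULL, exemplars = NULL,
                                identity_threshold = 30) {
  cand <- if (inherits(screen, "ltp_screen")) screen$candidates else screen
  acc <- cand[cand$status == "accepted", ]
  typed <- assign_type(acc, profiles, gene_introns, exemplars,
                       identity_threshold)
  dplyr::left_join(typed,
                   acc[, c("id", "g1", "g2", "g3", "g4", "g5", "cxc_x")],
                   by = "id") |>
    dplyr::mutate(polarity = cxc_polarity(.data$cxc_x))
}
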