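# Screening funnel: candidate proteins -> accepted nsLTPs with per-stage
# accounting. Stages run in the study order: 8CM presence, N-terminal signal
# sequence, GPI flagging (retained), proline-rich exclusion, storage-protein
# exclusion, optional maturity-length cut.

#' Screening configuration
#'
#' Thresholds of the nsLTP screening funnel. The gap bounds delimit the five
#' free inter-cysteine spacings of the eight-cysteine motif
#' `C-Xn-C-Xn-CC-Xn-CXC-Xn-C-Xn-C` (the `CC` adjacency and the single `X` of
#' `CXC` are structural, not free). Defaults are deliberately generous so
#' that every architecture observed in the barley/Qingke catalog passes; all
#' of them are configuration, not biology.
#'
#' @param gap_bounds 5x2 matrix (rows g1..g5) of min/max residues strictly
#'   between consecutive motif cysteines.
#' @param max_span Maximum motif span (first to eighth cysteine, inclusive).
#' @param nss_window,nss_min_hydrophobic_run,nss_kd_threshold Signal-peptide
#'   heuristic: search the first `nss_window` residues for a hydrophobic run
#'   of at least `nss_min_hydrophobic_run` consecutive residues with mean
#'   Kyte-Doolittle hydropathy >= `nss_kd_threshold`, beginning within the
#'   first 12 residues.
#' @param gpi_tail_length,gpi_kd_threshold GPI heuristic: the C-terminal
#'   `gpi_tail_length` residues must average at least `gpi_kd_threshold` on
#'   the Kyte-Doolittle scale, with an omega-site candidate (S/G/A/N/D/C)
#'   20-30 residues from the C-terminus.
#' @param prolinerich_min_len,prolinerich_phg_fraction Proline-rich call on
#'   the segment strictly between the signal cleavage site and the first
#'   motif cysteine.
#' @param exclusion_exemplars Optional FASTA path (or protein tibble) of
#'   storage-protein/inhibitor exemplars.
#' @param exclusion_identity_cutoff Percent global-alignment identity to any
#'   exemplar at or above which a candidate is excluded as storage-like.
#' @param max_mature_length Optional integer; when set, mature sequences
#'   longer than this are excluded (off by default: catalogued mature
#'   lengths reach 200 aa).
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(gap_bounds = rbind(c(2, 40), c(2, 50), c(2, 60),
                                             c(2, 50), c(2, 40)),
                          max_span = 160,
                          nss_window = 45, nss_min_hydrophobic_run = 8,
                          nss_kd_threshold = 1.5,
                          gpi_tail_length = 25, gpi_kd_threshold = 1.0,
                          prolinerich_min_len = 15,
                          prolinerich_phg_fraction = 0.35,
                          exclusion_exemplars = NULL,
                          exclusion_identity_cutoff = 30,
                          max_mature_length = NULL) {
  gap_bounds <- matrix(as.numeric(gap_bounds), ncol = 2)
  stopifnot(nrow(gap_bounds) == 5, all(gap_bounds > 0),
            all(gap_bounds[, 1] <= gap_bounds[, 2]),
            max_span > 0, prolinerich_phg_fraction >= 0,
            prolinerich_phg_fraction <= 1)
  structure(list(gap_bounds = gap_bounds, max_span = max_span,
                 nss_window = nss_window,
                 nss_min_hydrophobic_run = nss_min_hydrophobic_run,
                 nss_kd_threshold = nss_kd_threshold,
                 gpi_tail_length = gpi_tail_length,
                 gpi_kd_threshold = gpi_kd_threshold,
                 prolinerich_min_len = prolinerich_min_len,
                 prolinerich_phg_fraction = prolinerich_phg_fraction,
                 exclusion_exemplars = exclusion_exemplars,
                 exclusion_identity_cutoff = exclusion_identity_cutoff,
                 max_mature_length = max_mature_length),
            class = "screen_config")
}

#' Find eight-cysteine motifs (8CM)
#'
#' Enumerates every cysteine 8-tuple of a protein that satisfies the 8CM
#' architecture: C3/C4 adjacent (the `CC` block), exactly one residue between
#' C5 and C6 (the `CXC` block), the five free gaps within the configured
#' bounds, and total span at most `max_span`.
#'
#' @param sequence A protein sequence (single string).
#' @param config A [screen_config()].
#' @return A tibble with one row per match, ordered by `start` then `span`:
#'   columns `start`, `end`, `span`, `c1`..`c8` (1-based cysteine positions),
#'   `g1`..`g5` (free gap lengths) and `cxc_x` (the CXC middle residue).
#' @examples
#' find_8cm("CAACAACCAACACAACAAC")
#' @export
find_8cm <- function(sequence, config = screen_config()) {
  assert_protein_sequence(sequence)
  empty <- tibble::tibble(start = integer(), end = integer(), span = integer(),
                          c1 = integer(), c2 = integer(), c3 = integer(),
                          c4 = integer(), c5 = integer(), c6 = integer(),
                          c7 = integer(), c8 = integer(),
                          g1 = integer(), g2 = integer(), g3 = integer(),
                          g4 = integer(), g5 = integer(), cxc_x = character())
  if (nchar(sequence) < 15) return(empty)
  res <- aa_residues(sequence)
  cys <- which(res == "C")
  if (length(cys) < 8) return(empty)
  gb <- config$gap_bounds
  # CC block: adjacent cysteine pairs (C3, C4)
  cc <- cys[which(diff(cys) == 1L)]
  rows <- list()
  for (c3 in cc) {
    c4 <- c3 + 1L
    # CXC block: cysteines two apart, after C4
    c5s <- cys[cys > c4 & (cys + 2L) %in% cys &
                 (cys - c4 - 1L) >= gb[3, 1] & (cys - c4 - 1L) <= gb[3, 2]]
    for (c5 in c5s) {
      c6 <- c5 + 2L
      c2s <- cys[cys < c3 & (c3 - cys - 1L) >= gb[2, 1] &
                   (c3 - cys - 1L) <= gb[2, 2]]
      c7s <- cys[cys > c6 & (cys - c6 - 1L) >= gb[4, 1] &
                   (cys - c6 - 1L) <= gb[4, 2]]
      for (c2 in c2s) {
        c1s <- cys[cys < c2 & (c2 - cys - 1L) >= gb[1, 1] &
                     (c2 - cys - 1L) <= gb[1, 2]]
        for (c7 in c7s) {
          c8s <- cys[cys > c7 & (cys - c7 - 1L) >= gb[5, 1] &
                       (cys - c7 - 1L) <= gb[5, 2]]
          for (c1 in c1s) {
            for (c8 in c8s) {
              if (c8 - c1 + 1L <= config$max_span) {
                rows[[length(rows) + 1L]] <-
                  c(c1, c2, c3, c4, c5, c6, c7, c8)
              }
            }
          }
        }
      }
    }
  }
  if (length(rows) == 0) return(empty)
  m <- do.call(rbind, rows)
  out <- tibble::tibble(
    start = as.integer(m[, 1]), end = as.integer(m[, 8]),
    span = as.integer(m[, 8] - m[, 1] + 1L),
    c1 = as.integer(m[, 1]), c2 = as.integer(m[, 2]), c3 = as.integer(m[, 3]),
    c4 = as.integer(m[, 4]), c5 = as.integer(m[, 5]), c6 = as.integer(m[, 6]),
    c7 = as.integer(m[, 7]), c8 = as.integer(m[, 8]),
    g1 = as.integer(m[, 2] - m[, 1] - 1L), g2 = as.integer(m[, 3] - m[, 2] - 1L),
    g3 = as.integer(m[, 5] - m[, 4] - 1L), g4 = as.integer(m[, 7] - m[, 6] - 1L),
    g5 = as.integer(m[, 8] - m[, 7] - 1L),
    cxc_x = res[m[, 5] + 1L]
  )
  dplyr::arrange(out, .data$start, .data$span)
}

#' Canonical 8CM match
#'
#' When several motifs exist the canonical one is the leftmost start, then
#' the smallest span.
#'
#' @inheritParams find_8cm
#' @return A one-row tibble (as [find_8cm()]) or `NULL` when no motif.
#' @export
canonical_8cm <- function(sequence, config = screen_config()) {
  m <- find_8cm(sequence, config)
  if (nrow(m) == 0) return(NULL)
  m[1, ]
}

#' Detect an N-terminal signal sequence (NSS)
#'
#' Hydrophobicity heuristic standing in for neural signal-peptide
#' predictors; an externally computed cleavage site can be injected through
#' `override` and is returned verbatim. The heuristic searches the first
#' `nss_window` residues for a hydrophobic run (length >=
#' `nss_min_hydrophobic_run`, mean Kyte-Doolittle >= `nss_kd_threshold`)
#' beginning within the first 12 residues; the cleavage site is the first
#' A/G/S/C after the run's end. The mature chain starts at cleavage + 1.
#'
#' @inheritParams find_8cm
#' @param override Optional 1-based cleavage position from an external tool.
#' @return Integer cleavage position, or `NA` when no signal is found.
#' @export
detect_nss <- function(sequence, config = screen_config(), override = NULL) {
  assert_protein_sequence(sequence)
  n <- nchar(sequence)
  if (!is.null(override) && !is.na(override)) {
    override <- as.integer(override)
    if (override < 1L || override > n) {
      stop("NSS override position ", override,
           " is outside the sequence (length ", n, ")", call. = FALSE)
    }
    return(override)
  }
  res <- aa_residues(sequence)
  kd <- residue_kd(res)
  win <- min(config$nss_window, n)
  minrun <- config$nss_min_hydrophobic_run
  run_end <- NA_integer_
  for (s in seq_len(min(12L, win))) {
    if (!is.na(run_end)) break
    e_max <- win
    e_min <- s + minrun - 1L
    if (e_min > e_max) next
    for (e in e_min:e_max) {
      if (mean(kd[s:e]) >= config$nss_kd_threshold) {
        run_end <- e
        break
      }
    }
  }
  if (is.na(run_end)) return(NA_integer_)
  after <- which(res %in% c("A", "G", "S", "C"))
  after <- after[after > run_end & after < n]
  if (length(after) == 0) return(NA_integer_)
  after[1]
}

#' Detect a C-terminal GPI-anchor signal
#'
#' Hydrophobicity heuristic with external override: the C-terminal
#' `gpi_tail_length` residues must average at least `gpi_kd_threshold`
#' (Kyte-Doolittle) and an omega-site candidate (S/G/A/N/D/C) must lie 20-30
#' residues from the C-terminus. When several candidates qualify the most
#' C-terminal one is returned, keeping the longest possible mature chain.
#'
#' @inheritParams detect_nss
#' @param override Optional 1-based omega-site position.
#' @return Integer omega position, or `NA` when no GPI signal is found.
#' @export
detect_gpi <- function(sequence, config = screen_config(), override = NULL) {
  assert_protein_sequence(sequence)
  n <- nchar(sequence)
  if (!is.null(override) && !is.na(override)) return(as.integer(override))
  tail_len <- config$gpi_tail_length
  if (n < tail_len) return(NA_integer_)
  res <- aa_residues(sequence)
  kd <- residue_kd(res)
  if (mean(kd[(n - tail_len + 1L):n]) < config$gpi_kd_threshold) {
    return(NA_integer_)
  }
  dist <- n - seq_len(n) + 1L  # residues from the C-terminus, inclusive
  cand <- which(res %in% c("S", "G", "A", "N", "D", "C") &
                  dist >= 20L & dist <= 30L)
  if (length(cand) == 0) return(NA_integer_)
  max(cand)
}

#' Proline/histidine/glycine-rich call
#'
#' A candidate is proline-rich when the segment strictly between the NSS
#' cleavage site and the first motif cysteine is at least
#' `prolinerich_min_len` residues long and its P+H+G fraction is at least
#' `prolinerich_phg_fraction`.
#'
#' @inheritParams find_8cm
#' @param cleavage 1-based NSS cleavage position.
#' @param c1 1-based position of the first motif cysteine.
#' @return Logical.
#' @export
is_proline_rich <- function(sequence, cleavage, c1,
                            config = screen_config()) {
  assert_protein_sequence(sequence)
  stopifnot(cleavage >= 1)
  if (c1 - cleavage - 1L < config$prolinerich_min_len) return(FALSE)
  seg <- aa_residues(substr(sequence, cleavage + 1L, c1 - 1L))
  mean(seg %in% c("P", "H", "G")) >= config$prolinerich_phg_fraction
}

#' Run the full screening funnel
#'
#' Applies the family-identification stages in order: 8CM presence, NSS
#' presence, GPI detection (GPI-positive candidates are retained and
#' flagged), proline-rich exclusion, storage-protein exclusion by global
#' identity to exemplars, and the optional maturity-length cut. Mature
#' sequences start after the NSS cleavage site and, for GPI-positive
#' candidates, stop at the residue before the omega site.
#'
#' @param proteins A protein tibble ([protein_tbl()]).
#' @param config A [screen_config()].
#' @param annotations Optional tibble with columns `id` and any of
#'   `nss_cleavage`, `gpi_omega`; externally predicted calls that override
#'   the heuristics.
#' @return An object of class `ltp_screen`: a list with `candidates` (one
#'   row per input protein with its screening state) and `report` (funnel
#'   accounting; input = accepted + sum of stage exclusions).
#' @export
run_screen <- function(proteins, config = screen_config(),
                       annotations = NULL) {
  if (anyDuplicated(proteins$id)) {
    stop("duplicate protein ids in input", call. = FALSE)
  }
  stages <- c("no_8cm", "no_nss", "proline_rich", "storage_like", "too_long")
  if (nrow(proteins) == 0) {
    report <- tibble::tibble(stage = c("input", stages, "accepted"),
                             count = 0L)
    return(structure(list(candidates = tibble::tibble(), report = report),
                     class = "ltp_screen"))
  }
  ann <- function(id, col) {
    if (is.null(annotations) || !col %in% names(annotations)) return(NULL)
    v <- annotations[[col]][match(id, annotations$id)]
    if (length(v) == 0 || is.na(v)) NULL else v
  }
  exemplars <- config$exclusion_exemplars
  if (is.character(exemplars) && length(exemplars) == 1) {
    exemplars <- read_protein_fasta(exemplars, source = "exemplar")
  }
  rows <- purrr::map(seq_len(nrow(proteins)), function(i) {
    p <- proteins[i, ]
    out <- list(id = p$id, source = p$source, sequence = p$sequence,
                status = "excluded", exclusion_stage = NA_character_,
                nss_cleavage = NA_integer_, gpi_omega = NA_integer_,
                gpi_positive = FALSE, mature_sequence = NA_character_,
                c1 = NA_integer_, c2 = NA_integer_, c3 = NA_integer_,
                c4 = NA_integer_, c5 = NA_integer_, c6 = NA_integer_,
                c7 = NA_integer_, c8 = NA_integer_,
                motif_start = NA_integer_, motif_span = NA_integer_,
                g1 = NA_integer_, g2 = NA_integer_, g3 = NA_integer_,
                g4 = NA_integer_, g5 = NA_integer_, cxc_x = NA_character_)
    m <- if (nchar(p$sequence) >= 15) canonical_8cm(p$sequence, config) else NULL
    if (is.null(m)) {
      out$exclusion_stage <- "no_8cm"
      return(out)
    }
    out[paste0("c", 1:8)] <- as.list(as.integer(m[1, paste0("c", 1:8)]))
    out[c("motif_start", "motif_span")] <- list(m$start, m$span)
    out[c("g1", "g2", "g3", "g4", "g5")] <-
      as.list(as.integer(m[1, c("g1", "g2", "g3", "g4", "g5")]))
    out$cxc_x <- m$cxc_x
    cleavage <- detect_nss(p$sequence, config, override = ann(p$id, "nss_cleavage"))
    if (is.na(cleavage)) {
      out$exclusion_stage <- "no_nss"
      return(out)
    }
    out$nss_cleavage <- cleavage
    omega <- detect_gpi(p$sequence, config, override = ann(p$id, "gpi_omega"))
    out$gpi_omega <- omega
    out$gpi_positive <- !is.na(omega)
    if (cleavage < m$c1 &&
        is_proline_rich(p$sequence, cleavage, m$c1, config)) {
      out$exclusion_stage <- "proline_rich"
      return(out)
    }
    mature_end <- if (!is.na(omega)) omega - 1L else nchar(p$sequence)
    mature <- substr(p$sequence, cleavage + 1L, mature_end)
    out$mature_sequence <- mature
    if (!is.null(exemplars) && nrow(exemplars) > 0) {
      idents <- vapply(exemplars$sequence, pairwise_identity, numeric(1),
                       b = mature)
      if (any(idents >= config$exclusion_identity_cutoff)) {
        out$exclusion_stage <- "storage_like"
        return(out)
      }
    }
    if (!is.null(config$max_mature_length) &&
        nchar(mature) > config$max_mature_length) {
      out$exclusion_stage <- "too_long"
      return(out)
    }
    out$status <- "accepted"
    out$exclusion_stage <- "none"
    out
  })
  candidates <- dplyr::bind_rows(rows)
  counts <- vapply(stages, function(s) sum(candidates$exclusion_stage == s),
                   integer(1))
  report <- tibble::tibble(
    stage = c("input", stages, "accepted"),
    count = c(nrow(candidates), counts,
              sum(candidates$status == "accepted"))
  )
  structure(list(candidates = candidates, report = report),
            class = "ltp_screen")
}

#' @export
print.ltp_screen <- function(x, ...) {
  cat("nsLTP screening funnel\n")
  print(x$report)
  invisible(x)
}

#' Tidy a screening result
#'
#' @param x An `ltp_screen` object.
#' @param ... Unused.
#' @return The per-protein candidate tibble.
#' @importFrom generics tidy
#' @export
tidy.ltp_screen <- function(x, ...) x$candidates

#' One-row summary of a screening result
#'
#' @param x An `ltp_screen` object.
#' @param ... Unused.
#' @return A one-row tibble with the funnel counts.
#' @importFrom generics glance
#' @export
glance.ltp_screen <- function(x, ...) {
  tidyr::pivot_wider(x$report, names_from = "stage", values_from = "count")
}

#' Funnel bar chart of a screening result
#'
#' @param object An `ltp_screen` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ltp_screen <- function(object, ...) {
  rep <- object$report
  rep$stage <- factor(rep$stage, levels = rep$stage)
  ggplot2::ggplot(rep, ggplot2::aes(x = .data$stage, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "proteins",
                  title = "nsLTP screening funnel") +
    ggplot2::theme_minimal()
}
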