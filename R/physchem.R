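# Closed-form physicochemical profiling (ExPASy ProtParam conventions):
# average-mass molecular weight, Bjellqvist pI by bisection, Guruprasad
# instability index, Ikai aliphatic index, Kyte-Doolittle GRAVY.

#' Molecular weight of a protein (average masses)
#'
#' Sum of average residue masses plus one water for the free termini.
#'
#' @param sequence Protein sequence (single string; `X` allowed, treated as
#'   the mean residue mass).
#' @return Mass in Da.
#' @examples
#' molecular_weight("G")  # free glycine, 75.07 Da
#' @export
molecular_weight <- function(sequence) {
  assert_protein_sequence(sequence)
  sum(residue_mass(aa_residues(sequence))) + WATER_MASS
}

#' Net charge at a given pH
#'
#' Henderson-Hasselbalch sum over the N-terminus, H, K, R (positive) and the
#' C-terminus, D, E, C, Y (negative), with the Bjellqvist pKa set.
#'
#' @inheritParams molecular_weight
#' @param pH pH value in `[0, 14]`.
#' @return Signed net charge.
#' @export
net_charge <- function(sequence, pH) {
  assert_protein_sequence(sequence)
  stopifnot(pH >= 0, pH <= 14)
  res <- aa_residues(sequence)
  pka <- PKA_BJELLQVIST
  pos <- 1 / (1 + 10^(pH - pka$nterm))
  for (r in names(pka$positive)) {
    n <- sum(res == r)
    if (n > 0) pos <- pos + n / (1 + 10^(pH - pka$positive[[r]]))
  }
  neg <- 1 / (1 + 10^(pka$cterm - pH))
  for (r in names(pka$negative)) {
    n <- sum(res == r)
    if (n > 0) neg <- neg + n / (1 + 10^(pka$negative[[r]] - pH))
  }
  pos - neg
}

#' Theoretical isoelectric point
#'
#' Bisection of [net_charge()] on the bracket `[0, 14]` to `|charge| < 1e-4`
#' (at most 100 iterations); the termini guarantee a zero crossing.
#'
#' @inheritParams molecular_weight
#' @return pH at which the net charge vanishes.
#' @export
isoelectric_point <- function(sequence) {
  assert_protein_sequence(sequence)
  lo <- 0; hi <- 14
  for (i in seq_len(100)) {
    mid <- (lo + hi) / 2
    q <- net_charge(sequence, mid)
    if (abs(q) < 1e-4) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Guruprasad instability index
#'
#' `(10 / L) * sum` of dipeptide instability weights over consecutive
#' residue pairs.
#'
#' @inheritParams molecular_weight
#' @return Dimensionless instability index (> 40 conventionally unstable).
#' @export
instability_index <- function(sequence) {
  assert_protein_sequence(sequence)
  res <- aa_residues(sequence)
  L <- length(res)
  if (L < 2) stop("instability index needs at least 2 residues", call. = FALSE)
  (10 / L) * sum(diwv_weight(res[-L], res[-1]))
}

#' Ikai aliphatic index
#'
#' `X(Ala) + 2.9 X(Val) + 3.9 (X(Ile) + X(Leu))` with `X` the mole percent
#' of each residue.
#'
#' @inheritParams molecular_weight
#' @return Dimensionless aliphatic index.
#' @export
aliphatic_index <- function(sequence) {
  assert_protein_sequence(sequence)
  res <- aa_residues(sequence)
  mp <- function(r) 100 * mean(res == r)
  mp("A") + 2.9 * mp("V") + 3.9 * (mp("I") + mp("L"))
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues (`X` contributes 0).
#'
#' @inheritParams molecular_weight
#' @return GRAVY value; positive means hydrophobic.
#' @export
gravy <- function(sequence) {
  assert_protein_sequence(sequence)
  mean(residue_kd(aa_residues(sequence)))
}

#' Physicochemical profile of a protein cohort
#'
#' @param proteins A tibble with `id` and a sequence column.
#' @param sequence_col Which column to profile (e.g. `"sequence"` for the
#'   precursor or `"mature_sequence"` for the mature chain).
#' @return A tibble with `id`, `length`, `mw`, `pi`, `instability`,
#'   `aliphatic`, `gravy` (plus `source` if present in the input).
#' @export
physchem_profile <- function(proteins, sequence_col = "sequence") {
  seqs <- proteins[[sequence_col]]
  out <- tibble::tibble(
    id = proteins$id,
    length = nchar(seqs),
    mw = vapply(seqs, molecular_weight, numeric(1)),
    pi = vapply(seqs, isoelectric_point, numeric(1)),
    instability = vapply(seqs, instability_index, numeric(1)),
    aliphatic = vapply(seqs, aliphatic_index, numeric(1)),
    gravy = vapply(seqs, gravy, numeric(1))
  )
  if ("source" %in% names(proteins)) out$source <- proteins$source
  out
}

#' Summarize a cohort of physicochemical profiles
#'
#' Per-group and combined mean/min/max of each numeric metric. `mean_reported`
#' applies the catalog's printed precision: masses to the nearest Da, pI to
#' 2 decimals, lengths to the nearest integer, other indices to 2 decimals.
#'
#' @param profiles A tibble of per-protein metrics (any numeric columns,
#'   e.g. from [physchem_profile()] or [load_table1()]).
#' @param group Optional name of a grouping column (e.g. `"source"`); a
#'   `"combined"` group over all rows is always included.
#' @return A long tibble with `group`, `metric`, `mean`, `mean_reported`,
#'   `min`, `max`.
#' @export
summarize_cohort <- function(profiles, group = NULL) {
  if (nrow(profiles) == 0) stop("empty cohort", call. = FALSE)
  num_cols <- names(profiles)[vapply(profiles, is.numeric, logical(1))]
  one <- function(df, label) {
    tibble::tibble(
      group = label,
      metric = num_cols,
      mean = vapply(num_cols, function(cc) mean(df[[cc]]), numeric(1),
                    USE.NAMES = FALSE),
      min = vapply(num_cols, function(cc) min(df[[cc]]), numeric(1),
                   USE.NAMES = FALSE),
      max = vapply(num_cols, function(cc) max(df[[cc]]), numeric(1),
                   USE.NAMES = FALSE)
    )
  }
  res <- one(profiles, "combined")
  if (!is.null(group)) {
    for (g in unique(profiles[[group]])) {
      res <- dplyr::bind_rows(res, one(profiles[profiles[[group]] == g, ], g))
    }
  }
  digits <- function(metric) {
    dplyr::case_when(metric %in% c("mw", "mass") ~ 0,
                     metric %in% c("aa", "length") ~ 0,
                     TRUE ~ 2)
  }
  res$mean_reported <- round(res$mean, digits(res$metric))
  res[, c("group", "metric", "mean", "mean_reported", "min", "max")]
}

#' Load the packaged barley/Qingke nsLTP catalog
#'
#' The packaged physicochemical catalog of the 40 barley and 35 Qingke
#' family members (gene, source, type, chromosome, mature length, pI, mass,
#' instability index, aliphatic index, GRAVY).
#'
#' @return A tibble with 75 rows.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_catalog.tsv", package = "nsltpkit",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    gene = "c", source = "c", type = "c", chromosome = "c",
                    .default = "d"))
}
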