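# Physicochemical scale tables used across the package.
#
# Sources:
#   - Kyte & Doolittle (1982) J Mol Biol 157:105-132 (hydropathy).
#   - Guruprasad, Reddy & Pandit (1990) Protein Eng 4:155-161 (dipeptide
#     instability weight values, DIWV).
#   - Bjellqvist et al. (1993) Electrophoresis 14:1023-1031 (pKa set used by
#     the ExPASy Compute pI/Mw tool).
#   - IUPAC-IUB average residue masses (Da).

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

WATER_MASS <- 18.01528

# Average residue masses (Da): free amino acid mass minus one water.
AA_MASS <- c(
  A = 71.0788,  C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519,  H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167,  Q = 128.1307, R = 156.1875,
  S = 87.0782,  T = 101.1051, V = 99.1326,  W = 186.2132, Y = 163.1760
)

# Kyte-Doolittle hydropathy values.
KD_HYDROPATHY <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

# Bjellqvist pKa set: termini plus ionizable side chains.
PKA_BJELLQVIST <- list(
  nterm = 7.5, cterm = 3.55,
  positive = c(H = 5.98, K = 10.0, R = 12.0),
  negative = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
)

# Guruprasad dipeptide instability weight values (DIWV), 20 x 20.
# Rows: first residue of the dipeptide; columns: second residue.
# Column/row order: A C D E F G H I K L M N P Q R S T V W Y.
DIWV <- local({
  ord <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  m <- matrix(c(
      1.0,  44.9,  -7.5,   1.0,   1.0,   1.0,  -7.5,   1.0,   1.0,   1.0,   1.0,   1.0,  20.3,   1.0,   1.0,   1.0,   1.0,   1.0,   1.0,   1.0,
      1.0,   1.0,  20.3,   1.0,   1.0,   1.0,  33.6,   1.0,   1.0,  20.3,  33.6,   1.0,  20.3,  -6.5,   1.0,   1.0,  33.6,  -6.5,  24.7,   1.0,
      1.0,   1.0,   1.0,   1.0,  -6.5,   1.0,   1.0,   1.0,  -7.5,   1.0,   1.0,   1.0,   1.0,   1.0,  -6.5,  20.3, -14.0,   1.0,   1.0,   1.0,
      1.0,  44.9,  20.3,  33.6,   1.0,   1.0,  -6.5,  20.3,   1.0,   1.0,   1.0,   1.0,  20.3,  20.3,   1.0,  20.3,   1.0,   1.0, -14.0,   1.0,
      1.0,   1.0,  13.3,   1.0,   1.0,   1.0,   1.0,   1.0, -14.0,   1.0,   1.0,   1.0,  20.3,   1.0,   1.0,   1.0,   1.0,   1.0,   1.0,  33.6,
     -7.5,   1.0,   1.0,  -6.5,   1.0,  13.3,   1.0,  -7.5,  -7.5,   1.0,   1.0,  -7.5,   1.0,   1.0,   1.0,   1.0,  -7.5,   1.0,  13.3,  -7.5,
      1.0,   1.0,   1.0,   1.0,  -9.4,  -9.4,   1.0,  44.9,  24.7,   1.0,   1.0,  24.7,  -1.9,   1.0,   1.0,   1.0,  -6.5,   1.0,  -1.9,  44.9,
      1.0,   1.0,   1.0,  44.9,   1.0,   1.0,  13.3,   1.0,  -7.5,  20.3,   1.0,   1.0,  -1.9,   1.0,   1.0,   1.0,   1.0,  -7.5,   1.0,   1.0,
      1.0,   1.0,   1.0,   1.0,   1.0,  -7.5,   1.0,  -7.5,   1.0,  -7.5,  33.6,   1.0,  -6.5,  24.6,  33.6,   1.0,   1.0,  -7.5,   1.0,   1.0,
      1.0,   1.0,   1.0,   1.0,   1.0,   1.0,   1.0,   1.0,  -7.5,   1.0,   1.0,   1.0,  20.3,  33.6,  20.3,   1.0,   1.0,   1.0,  24.7,   1.0,
     13.3,   1.0,   1.0,   1.0,   1.0,   1.0,  58.3,   1.0,   1.0,   1.0,  -1.9,   1.0,  44.9,  -6.5,  -6.5,  44.9,  -1.9,   1.0,   1.0,  24.7,
      1.0,  -1.9,   1.0,   1.0, -14.0, -14.0,   1.0,  44.9,  24.7,   1.0,   1.0,   1.0,  -1.9,  -6.5,   1.0,   1.0,  -7.5,   1.0,  -9.4,   1.0,
     20.3,  -6.5,  -6.5,  18.4,  20.3,   1.0,   1.0,   1.0,   1.0,   1.0,  -6.5,   1.0,  20.3,  20.3,  -6.5,  20.3,   1.0,  20.3,  -1.9,   1.0,
      1.0,  -6.5,  20.3,  20.3,  -6.5,   1.0,   1.0,   1.0,   1.0,   1.0,   1.0,   1.0,  20.3,  20.3,   1.0,  44.9,   1.0,  -6.5,   1.0,  -6.5,
      1.0,   1.0,   1.0,   1.0,   1.0,  -7.5,  20.3,   1.0,   1.0,   1.0,   1.0,  13.3,  20.3,  20.3,  58.3,  44.9,   1.0,   1.0,  58.3,  -6.5,
      1.0,  33.6,   1.0,  20.3,   1.0,   1.0,   1.0,   1.0,   1.0,   1.0,   1.0,   1.0,  44.9,  20.3,  20.3,  20.3,   1.0,   1.0,   1.0,   1.0,
      1.0,   1.0,   1.0,  20.3,  13.3,  -7.5,   1.0,   1.0,   1.0,   1.0,   1.0, -14.0,   1.0,  -6.5,   1.0,   1.0,   1.0,   1.0, -14.0,   1.0,
      1.0,   1.0, -14.0,   1.0,   1.0,  -7.5,   1.0,   1.0,  -1.9,   1.0,   1.0,   1.0,  20.3,   1.0,   1.0,   1.0,  -7.5,   1.0,   1.0,  -6.5,
    -14.0,   1.0,   1.0,   1.0,   1.0,  -9.4,  24.7,   1.0,   1.0,  13.3,  24.7,  13.3,   1.0,   1.0,   1.0,   1.0, -14.0,  -7.5,   1.0,   1.0,
     24.7,   1.0,  24.7,  -6.5,   1.0,  -7.5,  13.3,   1.0,   1.0,   1.0,  44.9,   1.0,  13.3,   1.0, -15.9,   1.0,  -7.5,   1.0,  -9.4,  13.3
  ), nrow = 20, byrow = TRUE, dimnames = list(ord, ord))
  m
})

# IUPAC nucleotide degeneracy codes.
IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

DNA_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' Physicochemical scale tables
#'
#' Returns the residue-level lookup tables the package computes with:
#' average residue masses (Da), the Bjellqvist pKa set used by
#' ExPASy-style pI computation, Kyte-Doolittle hydropathy values, and the
#' Guruprasad dipeptide instability weights (DIWV, 400 entries).
#'
#' Residues coded `X` (unknown) fall back to neutral values: mass = mean of
#' the 20 standard residue masses, hydropathy 0, DIWV 1.0.
#'
#' @return A named list with elements `mass`, `pka`, `hydropathy`, `diwv`.
#' @examples
#' scale_tables()$hydropathy[["A"]]
#' @export
scale_tables <- function() {
  list(mass = AA_MASS, pka = PKA_BJELLQVIST,
       hydropathy = KD_HYDROPATHY, diwv = DIWV)
}

# Residue vector helpers with documented X fallback -------------------------

aa_residues <- function(sequence) {
  strsplit(sequence, "", fixed = TRUE)[[1]]
}

residue_mass <- function(residues) {
  m <- AA_MASS[residues]
  m[residues == "X"] <- mean(AA_MASS)
  unname(m)
}

residue_kd <- function(residues) {
  k <- KD_HYDROPATHY[residues]
  k[residues == "X"] <- 0
  unname(k)
}

diwv_weight <- function(first, second) {
  w <- numeric(length(first))
  known <- first %in% rownames(DIWV) & second %in% colnames(DIWV)
  w[known] <- DIWV[cbind(first[known], second[known])]
  w[!known] <- 1.0  # X fallback
  w
}

assert_protein_sequence <- function(sequence, arg = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      !nzchar(sequence)) {
    stop(sprintf("`%s` must be a single non-empty string", arg), call. = FALSE)
  }
  bad <- setdiff(unique(aa_residues(sequence)), c(AA_LETTERS, "X"))
  if (length(bad) > 0) {
    stop(sprintf("`%s` contains illegal residue letters: %s",
                 arg, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(sequence)
}
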