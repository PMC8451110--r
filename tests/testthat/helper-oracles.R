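# Independent oracles used to validate the package's scanners and aligners.

# Exhaustive 8-subset enumeration over cysteine positions: the brute-force
# counterpart of find_8cm.
oracle_find_8cm <- function(sequence, config = screen_config()) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  cys <- which(res == "C")
  cols <- c("c1", "c2", "c3", "c4", "c5", "c6", "c7", "c8")
  if (length(res) < 15 || length(cys) < 8) {
    return(matrix(integer(0), ncol = 8, dimnames = list(NULL, cols)))
  }
  combos <- utils::combn(cys, 8)
  gb <- config$gap_bounds
  ok <- apply(combos, 2, function(p) {
    p[4] == p[3] + 1 && p[6] == p[5] + 2 &&
      all(c(p[2] - p[1], p[3] - p[2], p[5] - p[4], p[7] - p[6],
            p[8] - p[7]) - 1 >= gb[, 1]) &&
      all(c(p[2] - p[1], p[3] - p[2], p[5] - p[4], p[7] - p[6],
            p[8] - p[7]) - 1 <= gb[, 2]) &&
      p[8] - p[1] + 1 <= config$max_span
  })
  m <- t(combos[, ok, drop = FALSE])
  colnames(m) <- cols
  m[order(m[, 1], m[, 8] - m[, 1]), , drop = FALSE]
}

# Tiny Needleman-Wunsch DP: optimal global score with match +1, mismatch 0,
# linear gap -1. Independent of Biostrings.
nw_score_oracle <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -(0:n); S[1, ] <- -(0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      S[i + 1, j + 1] <- max(S[i, j] + (x[i] == y[j]),
                             S[i, j + 1] - 1, S[i + 1, j] - 1)
    }
  }
  S[n + 1, m + 1]
}

# Naive position-by-position IUPAC scan (single strand).
iupac_tbl <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_iupac_starts <- function(sequence, consensus) {
  s <- strsplit(sequence, "", fixed = TRUE)[[1]]
  p <- strsplit(consensus, "", fixed = TRUE)[[1]]
  w <- length(p)
  if (length(s) < w) return(integer(0))
  hits <- integer(0)
  for (st in seq_len(length(s) - w + 1)) {
    if (all(vapply(seq_len(w), function(k) s[st + k - 1] %in% iupac_tbl[[p[k]]],
                   logical(1)))) {
      hits <- c(hits, st)
    }
  }
  hits
}

revcomp_chr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  vapply(x, function(s) {
    paste(rev(unname(comp[strsplit(s, "", fixed = TRUE)[[1]]])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

random_peptide <- function(len, letters = c("A", "C", "D", "E", "F", "G", "H",
                                            "I", "K", "L", "M", "N", "P", "Q",
                                            "R", "S", "T", "V", "W", "Y")) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

# Compact cohort configuration for fast tests.
small_cohort_config <- function(...) {
  defaults <- list(
    type_counts = c(`1` = 3, `2` = 2, D = 2, G = 2),
    decoys = c(cys_deficient = 4, nss_lacking = 2, proline_rich = 1,
               storage_like = 0),
    chr_layout = list(`1` = c(1, 1, 2), `2` = c(2, 3), D = c(4, 4),
                      G = c(5, 0)),
    tandem_specs = list(list(type = "D", members = 1:2, gap_bp = 15000)),
    segmental_spec = list(type = "1", a = 1, b = 3),
    intergenic_bp = 20000,
    d_intron_count = 1)
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

# Canonical row order for comparing motif tables with the oracle.
sort_motifs <- function(m) {
  m <- matrix(as.integer(m), ncol = 8)
  m[do.call(order, split(m, col(m))), , drop = FALSE]
}
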