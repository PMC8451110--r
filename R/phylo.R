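# Distance phylogeny: p-distances from the anchored alignment and a
# neighbour-joining implementation (Saitou & Nei agglomeration) with
# column-bootstrap support values.

#' p-distance matrix from an alignment
#'
#' For each pair of rows, the proportion of mismatching residues over the
#' compared columns. Under `deletion = "pairwise"` (default) columns where
#' either row holds a gap are dropped per pair; `"complete"` drops columns
#' with a gap in any row once for all pairs.
#'
#' @param alignment An `anchored_alignment`, a character matrix (rows =
#'   sequences) or a named character vector of equal-length aligned strings.
#' @param deletion `"pairwise"` or `"complete"`.
#' @return A symmetric distance matrix with zero diagonal.
#' @export
p_distance <- function(alignment, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  m <- alignment_matrix(alignment)
  if (nrow(m) < 2) stop("p_distance needs at least 2 rows", call. = FALSE)
  if (deletion == "complete") {
    keep <- colSums(m == "-") == 0
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok)) {
        stop("no comparable columns between '", rownames(m)[i], "' and '",
             rownames(m)[j], "'", call. = FALSE)
      }
      d[i, j] <- d[j, i] <- mean(m[i, ok] != m[j, ok])
    }
  }
  d
}

alignment_matrix <- function(alignment) {
  if (inherits(alignment, "anchored_alignment")) {
    return(as.matrix(alignment))
  }
  if (is.matrix(alignment)) return(alignment)
  if (is.character(alignment)) {
    stopifnot(length(unique(nchar(alignment))) == 1)
    m <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
    rownames(m) <- names(alignment) %||% paste0("seq", seq_along(alignment))
    return(m)
  }
  stop("unsupported alignment representation", call. = FALSE)
}

#' Neighbour-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q-criterion
#' `Q(i,j) = (n-2) d(i,j) - R_i - R_j`. Ties are broken by smallest Q then
#' by the lexicographically smallest label pair; negative branch lengths
#' are clamped to 0. The result is the exact tree metric for additive
#' input distances.
#'
#' @param d A symmetric distance matrix with labelled rows/columns.
#' @return An unrooted `ape::phylo` tree (trifurcating root). For n = 2 the
#'   unique two-leaf tree is returned with a warning.
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  labels <- rownames(d) %||% paste0("t", seq_len(nrow(d)))
  n <- nrow(d)
  if (n < 2) stop("nj_tree needs at least 2 taxa", call. = FALSE)
  if (n == 2) {
    warning("only 2 taxa: returning the unique two-leaf tree")
    nwk <- sprintf("(%s:%.12g,%s:%.12g);", labels[1], d[1, 2] / 2,
                   labels[2], d[1, 2] / 2)
    return(ape::read.tree(text = nwk))
  }
  # Each active node carries its newick subtree string.
  sub <- labels
  D <- d
  dimnames(D) <- list(sub, sub)
  key <- labels  # sort keys: smallest leaf label within each subtree
  while (nrow(D) > 3) {
    m <- nrow(D)
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ord <- order(key[cand[, 1]], key[cand[, 2]])
    i <- cand[ord[1], 1]; j <- cand[ord[1], 2]
    li <- max(0, D[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2)))
    lj <- max(0, D[i, j] / 2 + (R[j] - R[i]) / (2 * (m - 2)))
    newsub <- sprintf("(%s:%.12g,%s:%.12g)", sub[i], li, sub[j], lj)
    newkey <- min(key[i], key[j])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    sub <- c(sub[keep], newsub)
    key <- c(key[keep], newkey)
    dimnames(D2) <- NULL
    D <- D2
  }
  # Final three nodes: closed-form star branch lengths.
  x <- max(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  y <- max(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  z <- max(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);", sub[1], x, sub[2], y, sub[3], z)
  ape::read.tree(text = nwk)
}

#' Bootstrap support for a neighbour-joining tree
#'
#' Builds the reference NJ tree from the full alignment, then resamples
#' alignment columns with replacement `n_replicates` times, rebuilds the NJ
#' tree per replicate, and reports for each internal edge of the reference
#' tree the percentage of replicates containing the same bipartition.
#' Deterministic for a fixed seed.
#'
#' @inheritParams p_distance
#' @param n_replicates Number of bootstrap replicates (e.g. 1000).
#' @param seed Integer RNG seed.
#' @return The reference `ape::phylo` tree with supports (percent) in
#'   `node.label`.
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000, seed = 1,
                              deletion = "pairwise") {
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  m <- alignment_matrix(alignment)
  if (nrow(m) < 4) stop("bootstrap needs at least 4 rows", call. = FALSE)
  ref <- nj_tree(p_distance(m, deletion))
  set.seed(as.integer(seed))
  boot <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    boot[[b]] <- nj_tree(p_distance(m[, cols, drop = FALSE], deletion))
  }
  counts <- ape::prop.clades(ref, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0
  ref$node.label <- round(100 * counts / n_replicates, 1)
  ref
}
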