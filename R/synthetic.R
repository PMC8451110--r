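# Synthetic cohort generator: proteomes, genomes, promoters and expression
# tables with a ground-truth manifest, emulating a genome-wide nsLTP survey
# so that every pipeline stage is testable without external downloads.
# Backgrounds are i.i.d. uniform ACGT and back-translation uses a fixed
# most-frequent-codon table: adequate for coordinate and scanning tests,
# not biological realism.

SIGNAL_LETTERS <- c("L", "V", "I", "F")
GAP_LETTERS <- c("A", "G", "S", "T", "N", "Q", "E", "K", "L", "V", "I", "D", "R")
HYDROPHILIC_LETTERS <- c("K", "E", "N", "D", "Q", "T", "S")
CXC_PHILIC <- c("S", "T", "N", "Q", "E", "D", "K", "R", "G")
CXC_PHOBIC <- c("L", "I", "V", "F", "A", "M")

CODON_TABLE <- c(
  A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC", G = "GGC",
  H = "CAC", I = "ATC", K = "AAG", L = "CTG", M = "ATG", N = "AAC",
  P = "CCG", Q = "CAG", R = "CGT", S = "TCC", T = "ACC", V = "GTG",
  W = "TGG", Y = "TAC")

# Table-1-style chromosome layout per type (0 = unplaced).
DEFAULT_CHR_LAYOUT <- list(
  `1` = c(2, 2, 2, 3, 3, 3, 3, 3, 3, 3, 4, 4, 5, 5, 7, 5),
  `2` = c(1, 1, 2, 4, 4),
  D = c(1, 2, 2, 2, 2, 2, 2, 4, 7, 5, 7),
  G = c(1, 2, 4, 5, 5, 5, 0, 6))

#' Synthetic-cohort configuration
#'
#' Defaults mirror the study conditions of a barley-scale nsLTP survey:
#' 16/5/11/8 true genes of types 1/2/D/G, decoys 107 cysteine-deficient + 11
#' signal-less + 2 proline-rich, a Table-1-style chromosome layout (11 genes
#' on chr2, one on chr6, one unplaced), two 3-gene tandem clusters (six
#' tandem pairs) plus one cross-chromosome segmental pair, an intron plan of
#' 1/0/(3 genes)/2 introns for types 1/2/D/G at offsets +30/-/-9/(+12, +60)
#' bp from the first base of the eighth-cysteine codon, 1.5 kb promoters
#' with planted cis-elements, and qPCR fold changes at sigma = 0.1 Ct with
#' 3 biological x 3 technical replicates.
#'
#' @param type_counts Named counts of true genes per type.
#' @param decoys Named counts per decoy class (`cys_deficient`,
#'   `nss_lacking`, `proline_rich`, `storage_like`).
#' @param profiles Type-profile tibble ([type_profiles()]); spacing is
#'   sampled uniformly inside each type's gap ranges.
#' @param intron_plan Named list of intron offsets (bp from the
#'   eighth-cysteine codon start, transcript orientation) per type.
#' @param d_intron_count How many type-D genes receive the type-D intron
#'   plan (the rest get none).
#' @param chr_layout Named list of chromosome assignments per type.
#' @param tandem_specs List of tandem-cluster specs: each a list with
#'   `type`, `members` (indices within that type) and `gap_bp`.
#' @param segmental_spec A list `type`, `a`, `b`: two member indices made
#'   near-identical but left on their (different) chromosomes.
#' @param copy_mutation_rate Point-mutation rate applied to cluster /
#'   segmental copies of their founder.
#' @param intergenic_bp,cluster_gap_bp Spacer lengths between genes.
#' @param promoter_bp Promoter window length.
#' @param planted_elements_per_gene Number of randomly planted catalog
#'   elements per promoter (core TATA/CAAT elements are always planted).
#' @param catalog Cis-element catalog used for planting.
#' @param qpcr_conditions Condition labels; the first is the calibrator.
#' @param fold_levels Fold-change levels sampled per gene x condition.
#' @param ct_sigma Biological Ct noise (cycles); `tech_sigma` the technical
#'   replicate noise.
#' @param n_bio,n_tech Replicate structure.
#' @param tissues FPKM tissue labels; `null_tissue` is planted unexpressed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(type_counts = c(`1` = 16, `2` = 5, D = 11, G = 8),
                          decoys = c(cys_deficient = 107, nss_lacking = 11,
                                     proline_rich = 2, storage_like = 0),
                          profiles = type_profiles(),
                          intron_plan = list(`1` = 30, `2` = numeric(0),
                                             D = -9, G = c(12, 60)),
                          d_intron_count = 3,
                          chr_layout = DEFAULT_CHR_LAYOUT,
                          tandem_specs = list(
                            list(type = "D", members = 2:4, gap_bp = 20000),
                            list(type = "1", members = 5:7, gap_bp = 20000)),
                          segmental_spec = list(type = "1", a = 12, b = 13),
                          copy_mutation_rate = 0.05,
                          intergenic_bp = 150000, cluster_gap_bp = 20000,
                          promoter_bp = 1500,
                          planted_elements_per_gene = 3,
                          catalog = cis_element_catalog(),
                          qpcr_conditions = c("control", "cold", "drought",
                                              "salt"),
                          fold_levels = c(0.25, 0.5, 2, 4),
                          ct_sigma = 0.1, tech_sigma = 0.05,
                          n_bio = 3, n_tech = 3,
                          tissues = c("EMB", "ROO1", "LEA", "INF1", "INF2",
                                      "NOD", "CAR5", "CAR15", "ETI", "LEM",
                                      "LOD", "PAL", "EPI", "RAC", "ROO2",
                                      "SEN"),
                          null_tissue = "INF1") {
  stopifnot(all(type_counts >= 0), all(decoys >= 0))
  for (tp in names(intron_plan)) {
    offs <- intron_plan[[tp]]
    if (length(offs) > 0 && (any(offs < -9) || any(offs > 104))) {
      stop("intron offsets must lie within [-9, 104] bp of the ",
           "eighth-cysteine codon", call. = FALSE)
    }
  }
  structure(as.list(environment()), class = "cohort_config")
}

rand_str <- function(n, letters) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

sample1 <- function(x) x[sample.int(length(x), 1)]

# Point-mutate a protein, never touching cysteines and never creating one;
# `protect` shields extra positions (e.g. planted cleavage/omega sites).
mutate_protein <- function(sequence, rate, protect = integer(0)) {
  res <- aa_residues(sequence)
  mutable <- setdiff(which(res != "C"), protect)
  hit <- mutable[stats::runif(length(mutable)) < rate]
  for (i in hit) {
    res[i] <- sample1(setdiff(AA_LETTERS, c("C", res[i])))
  }
  paste(res, collapse = "")
}

# Build one true nsLTP protein of the given type; returns sequence + truth.
build_true_protein <- function(type, profiles) {
  p <- profiles[profiles$type == type, ]
  k <- sample(8:11, 1)
  signal <- rand_str(k, SIGNAL_LETTERS)
  nss_res <- sample1(c("A", "G", "S"))
  linker <- rand_str(sample(4:8, 1), c("T", "N", "Q", "E", "K"))
  gaps <- vapply(1:5, function(g) {
    sample(seq(p[[paste0("g", g, "_min")]], p[[paste0("g", g, "_max")]]), 1)
  }, numeric(1))
  cxc <- if (type == "1") sample1(CXC_PHILIC) else sample1(CXC_PHOBIC)
  motif <- paste0("C", rand_str(gaps[1], GAP_LETTERS),
                  "C", rand_str(gaps[2], GAP_LETTERS),
                  "CC", rand_str(gaps[3], GAP_LETTERS),
                  "C", cxc, "C", rand_str(gaps[4], GAP_LETTERS),
                  "C", rand_str(gaps[5], GAP_LETTERS), "C")
  tail_seq <- if (type == "G") {
    paste0("S", rand_str(24, SIGNAL_LETTERS))
  } else {
    rand_str(sample(10:14, 1), HYDROPHILIC_LETTERS)
  }
  seq <- paste0("M", signal, nss_res, linker, motif, tail_seq)
  prefix <- 1L + k + 1L + nchar(linker)
  c1 <- prefix + 1L
  cys <- cumsum(c(c1, gaps[1] + 1, gaps[2] + 1, 1, gaps[3] + 1, 2,
                  gaps[4] + 1, gaps[5] + 1))
  list(sequence = seq, nss_cleavage = k + 2L,
       gpi_omega = if (type == "G") nchar(seq) - 24L else NA_integer_,
       cys = as.integer(cys), gaps = as.integer(gaps), cxc = cxc)
}

build_decoy <- function(class, profiles, exemplar = NULL) {
  k <- sample(8:11, 1)
  signal <- rand_str(k, SIGNAL_LETTERS)
  nss_res <- sample1(c("A", "G", "S"))
  motif_of <- function(type) {
    p <- profiles[profiles$type == type, ]
    gaps <- vapply(1:5, function(g) {
      sample(seq(p[[paste0("g", g, "_min")]], p[[paste0("g", g, "_max")]]), 1)
    }, numeric(1))
    paste0("C", rand_str(gaps[1], GAP_LETTERS), "C",
           rand_str(gaps[2], GAP_LETTERS), "CC", rand_str(gaps[3], GAP_LETTERS),
           "C", sample1(CXC_PHOBIC), "C", rand_str(gaps[4], GAP_LETTERS),
           "C", rand_str(gaps[5], GAP_LETTERS), "C")
  }
  tp <- sample1(profiles$type[profiles$type %in% c("1", "2", "D")])
  switch(class,
    cys_deficient = paste0("M", signal, nss_res,
                           rand_str(sample(60:120, 1),
                                    setdiff(GAP_LETTERS, "C"))),
    nss_lacking = paste0("M", rand_str(20, HYDROPHILIC_LETTERS), motif_of(tp),
                         rand_str(10, HYDROPHILIC_LETTERS)),
    proline_rich = {
      phg <- sample(c(rep(c("P", "H", "G"), 4), rand_str(8, c("T", "N", "Q")) |>
                        aa_residues()))
      paste0("M", signal, nss_res, paste(phg, collapse = ""), motif_of(tp),
             rand_str(10, HYDROPHILIC_LETTERS))
    },
    storage_like = {
      block <- mutate_protein(exemplar, 0.10)
      paste0("M", signal, nss_res, rand_str(5, c("T", "N", "Q")), motif_of(tp),
             block)
    },
    stop("unknown decoy class: ", class))
}

back_translate <- function(protein) {
  paste(c(CODON_TABLE[aa_residues(protein)], "TAA"), collapse = "")
}

#' Generate a synthetic survey cohort
#'
#' Emits a candidate proteome (true nsLTPs plus decoys), a genome with gene
#' models, promoters with planted cis-elements, an FPKM tissue matrix and a
#' long-format qPCR Ct table, together with a ground-truth manifest
#' cross-referencing all of it. All randomness flows from `seed` through
#' fixed per-stage substreams (proteins, genome, promoters, expression), so
#' the same seed gives an identical bundle and adding one stage never
#' perturbs another.
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed.
#' @param stages Which stages to build: `"proteins"` is always built;
#'   dropping `"genome"` (with its promoters) or `"expression"` skips that
#'   stage, which never changes another stage's output.
#' @return A list of class `ltp_cohort` with elements `proteins`, `genome`,
#'   `genes`, `fpkm`, `qpcr`, `manifest`, `config`, `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1,
                            stages = c("proteins", "genome", "expression")) {
  seed <- as.integer(seed)

  ## --- proteins ---------------------------------------------------------
  set.seed(seed + 101L)
  truths <- list(); seqs <- character(0); ids <- character(0)
  classes <- character(0)
  type_index <- list()
  for (tp in names(config$type_counts)) {
    n <- config$type_counts[[tp]]
    if (n == 0) next
    label <- if (tp %in% c("1", "2")) tp else tolower(tp)
    idx <- integer(0)
    for (i in seq_len(n)) {
      b <- build_true_protein(tp, config$profiles)
      id <- sprintf("simLTP%s.%02d", label, i)
      ids <- c(ids, id); seqs <- c(seqs, b$sequence)
      classes <- c(classes, tp)
      truths[[id]] <- b
      idx <- c(idx, length(ids))
    }
    type_index[[tp]] <- idx
  }
  # Tandem clusters and the segmental pair: members are mutated copies of
  # their founder so that duplication geometry and identity both hold.
  copy_of <- stats::setNames(rep(NA_character_, length(ids)), ids)
  cluster_id <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  for (ci in seq_along(config$tandem_specs)) {
    spec <- config$tandem_specs[[ci]]
    members <- type_index[[spec$type]][spec$members]
    founder <- members[1]
    keep <- function(i) stats::na.omit(c(truths[[ids[i]]]$nss_cleavage,
                                         truths[[ids[i]]]$gpi_omega))
    for (m in members) {
      cluster_id[m] <- ci
      if (m != founder) {
        seqs[m] <- mutate_protein(seqs[founder], config$copy_mutation_rate,
                                  protect = keep(founder))
        truths[[ids[m]]] <- truths[[ids[founder]]]
        truths[[ids[m]]]$sequence <- seqs[m]
        copy_of[m] <- ids[founder]
      }
    }
  }
  if (!is.null(config$segmental_spec)) {
    sp <- config$segmental_spec
    a <- type_index[[sp$type]][sp$a]; b <- type_index[[sp$type]][sp$b]
    seqs[b] <- mutate_protein(
      seqs[a], config$copy_mutation_rate,
      protect = stats::na.omit(c(truths[[ids[a]]]$nss_cleavage,
                                 truths[[ids[a]]]$gpi_omega)))
    truths[[ids[b]]] <- truths[[ids[a]]]
    truths[[ids[b]]]$sequence <- seqs[b]
    copy_of[b] <- ids[a]
  }
  exemplar <- NULL
  if (config$decoys[["storage_like"]] > 0) {
    ex_tbl <- read_protein_fasta(
      system.file("extdata", "storage_exemplars_synthetic.fasta",
                  package = "nsltpkit", mustWork = TRUE))
    exemplar <- ex_tbl$sequence[1]
  }
  for (cls in names(config$decoys)) {
    n <- config$decoys[[cls]]
    for (i in seq_len(n)) {
      id <- sprintf("decoy_%s.%03d", cls, i)
      ids <- c(ids, id)
      seqs <- c(seqs, build_decoy(cls, config$profiles, exemplar))
      classes <- c(classes, cls)
    }
  }
  proteins <- protein_tbl(ids, seqs, source = "synthetic",
                          description = classes)
  n_true <- sum(config$type_counts)
  truth_proteins <- tibble::tibble(
    id = ids, class = classes,
    nss_cleavage = c(vapply(ids[seq_len(n_true)],
                            function(i) truths[[i]]$nss_cleavage, integer(1)),
                     rep(NA_integer_, length(ids) - n_true)),
    gpi_omega = c(vapply(ids[seq_len(n_true)],
                         function(i) truths[[i]]$gpi_omega, integer(1)),
                  rep(NA_integer_, length(ids) - n_true)),
    cys = c(lapply(ids[seq_len(n_true)], function(i) truths[[i]]$cys),
            rep(list(NULL), length(ids) - n_true)),
    gaps = c(lapply(ids[seq_len(n_true)], function(i) truths[[i]]$gaps),
             rep(list(NULL), length(ids) - n_true)),
    cluster = as.integer(c(cluster_id[seq_len(n_true)],
                           rep(NA, length(ids) - n_true))),
    copy_of = c(copy_of[seq_len(n_true)], rep(NA, length(ids) - n_true)))

  true_ids <- ids[seq_len(n_true)]
  genome <- NULL; genes <- NULL
  truth_genes <- tibble::tibble()
  truth_promoters <- tibble::tibble()
  fpkm <- NULL; qpcr <- NULL
  fc_rows <- list(); spec_rows <- list()

  ## --- genome + gene models --------------------------------------------
  if ("genome" %in% stages) {
  set.seed(seed + 202L)
  chr_of <- character(n_true); gap_before <- numeric(n_true)
  for (tp in names(config$type_counts)) {
    idx <- type_index[[tp]]
    layout <- config$chr_layout[[tp]]
    if (is.null(layout)) layout <- rep(1:7, length.out = length(idx))
    layout <- rep(layout, length.out = length(idx))
    chr_of[idx] <- ifelse(layout == 0, "chrUn", paste0("chr", layout))
    gap_before[idx] <- config$intergenic_bp
  }
  for (spec in config$tandem_specs) {
    members <- type_index[[spec$type]][spec$members]
    gap_before[members[-1]] <- spec$gap_bp
  }
  # intron plan per gene
  d_idx <- type_index[["D"]]
  intron_offsets <- vector("list", n_true)
  for (tp in names(config$type_counts)) {
    for (pos in seq_along(type_index[[tp]])) {
      g <- type_index[[tp]][pos]
      offs <- config$intron_plan[[tp]] %||% numeric(0)
      if (tp == "D" && pos > config$d_intron_count) offs <- numeric(0)
      intron_offsets[[g]] <- offs
    }
  }
  gene_order <- order(match(chr_of, c(paste0("chr", 1:7), "chrUn")),
                      seq_len(n_true))
  bodies <- vector("list", n_true)
  for (g in seq_len(n_true)) {
    cds <- back_translate(seqs[g])
    t8 <- (truths[[ids[g]]]$cys[8] - 1L) * 3L
    offs <- sort(intron_offsets[[g]])
    pts <- t8 + offs
    if (any(pts <= 0 | pts >= nchar(cds))) {
      stop("intron offset beyond the CDS for gene ", ids[g], call. = FALSE)
    }
    # split CDS at pts (0-based cut points), insert intron sequences
    cuts <- c(0, pts, nchar(cds))
    segs <- substring(cds, head(cuts, -1) + 1, cuts[-1])
    introns <- vapply(seq_len(max(0, length(segs) - 1)), function(i)
      paste0("GT", rand_str(sample(60:140, 1), c("A", "C", "G", "T")), "AG"),
      character(1))
    body <- segs[1]
    cds_iv <- data.frame(start = 0, end = nchar(segs[1]))
    for (i in seq_along(introns)) {
      body <- paste0(body, introns[i], segs[i + 1])
      st <- nchar(body) - nchar(segs[i + 1])
      cds_iv <- rbind(cds_iv, data.frame(start = st, end = nchar(body)))
    }
    bodies[[g]] <- list(body = body, cds_iv = cds_iv)
  }
  strands <- ifelse(seq_len(n_true) %% 2L == 1L, "+", "-")
  prom_bp <- config$promoter_bp
  # intergenic spacers drawn here so the promoter substream below never
  # shifts the genome backbone
  spacers <- lapply(seq_len(n_true), function(g)
    rand_str(gap_before[g], c("A", "C", "G", "T")))

  ## --- promoters (separate substream) -----------------------------------
  set.seed(seed + 303L)
  catalog <- config$catalog
  core <- catalog[catalog$name %in% c("TATA-box", "CAAT-box"), ]
  pool <- catalog[!catalog$name %in% c("TATA-box", "CAAT-box"), ]
  instantiate <- function(consensus) {
    paste(vapply(aa_residues(consensus), function(ch) sample1(IUPAC_DNA[[ch]]),
                 character(1)), collapse = "")
  }
  prom_rows <- list()
  promoters <- character(n_true)
  for (g in seq_len(n_true)) {
    prom <- aa_residues(rand_str(prom_bp, c("A", "C", "G", "T")))
    plants <- dplyr::bind_rows(
      tibble::tibble(name = core$name, consensus = core$consensus,
                     start = c(prom_bp - 79L, prom_bp - 199L)),
      {
        picks <- pool[sample.int(nrow(pool), config$planted_elements_per_gene), ]
        tibble::tibble(name = picks$name, consensus = picks$consensus,
                       start = NA_integer_)
      })
    occupied <- cbind(plants$start[1:2], plants$start[1:2] +
                        nchar(plants$consensus[1:2]) - 1L)
    for (k in seq_len(nrow(plants))) {
      w <- nchar(plants$consensus[k])
      if (is.na(plants$start[k])) {
        repeat {
          st <- sample(50:(prom_bp - 300), 1)
          if (all(st + w - 1 < occupied[, 1] - 1 | st > occupied[, 2] + 1)) break
        }
        plants$start[k] <- st
        occupied <- rbind(occupied, c(st, st + w - 1L))
      }
      strand <- if (k <= 2) "+" else sample1(c("+", "-"))
      inst <- instantiate(plants$consensus[k])
      planted <- if (strand == "+") inst else reverse_complement(inst)
      prom[plants$start[k]:(plants$start[k] + w - 1L)] <- aa_residues(planted)
      prom_rows[[length(prom_rows) + 1]] <- tibble::tibble(
        gene_id = ids[g], element = plants$name[k],
        start = as.integer(plants$start[k]), strand = strand)
    }
    promoters[g] <- paste(prom, collapse = "")
  }
  truth_promoters <- dplyr::bind_rows(prom_rows)

  # assemble chromosomes
  chrom_names <- unique(chr_of[gene_order])
  genome <- stats::setNames(rep("", length(chrom_names)), chrom_names)
  gene_rows <- list()
  for (g in gene_order) {
    chr <- chr_of[g]
    locus <- paste0(promoters[g], bodies[[g]]$body)
    cds_iv <- bodies[[g]]$cds_iv
    cds_iv$start <- cds_iv$start + prom_bp
    cds_iv$end <- cds_iv$end + prom_bp
    if (strands[g] == "-") {
      L <- nchar(locus)
      locus <- reverse_complement(locus)
      cds_iv <- data.frame(start = L - cds_iv$end, end = L - cds_iv$start)
      cds_iv <- cds_iv[order(cds_iv$start), , drop = FALSE]
    }
    offset <- nchar(genome[[chr]]) + gap_before[g]
    genome[[chr]] <- paste0(genome[[chr]], spacers[[g]], locus)
    cds_iv$start <- cds_iv$start + offset
    cds_iv$end <- cds_iv$end + offset
    gene_rows[[length(gene_rows) + 1]] <- list(
      gene_id = ids[g], chromosome = chr, strand = strands[g],
      exons = cds_iv, cds = cds_iv)
  }
  genes <- gene_model_tbl(
    gene_id = purrr::map_chr(gene_rows, "gene_id"),
    chromosome = purrr::map_chr(gene_rows, "chromosome"),
    strand = purrr::map_chr(gene_rows, "strand"),
    exons = purrr::map(gene_rows, "exons"),
    cds = purrr::map(gene_rows, "cds"))
  genes <- genes[match(true_ids, genes$gene_id), ]
  truth_genes <- tibble::tibble(
    gene_id = true_ids, chromosome = chr_of, strand = strands,
    n_introns = vapply(intron_offsets, length, integer(1)),
    intron_offsets = intron_offsets,
    cluster = as.integer(cluster_id[seq_len(n_true)]),
    copy_of = unname(copy_of[seq_len(n_true)]))
  }

  ## --- expression --------------------------------------------------------
  if ("expression" %in% stages) {
  set.seed(seed + 404L)
  tissues <- config$tissues
  fpkm_m <- matrix(stats::runif(n_true * length(tissues), 0.1, 2),
                   nrow = n_true, dimnames = list(true_ids, tissues))
  for (g in seq_len(n_true)) {
    tp <- classes[g]
    if (tp %in% c("1", "2")) {
      pick <- sample(setdiff(tissues, config$null_tissue),
                     sample(1:2, 1))
      fpkm_m[g, pick] <- stats::runif(length(pick), 50, 200)
      spec_rows[[length(spec_rows) + 1]] <-
        tibble::tibble(gene = true_ids[g], tissues = list(pick))
    } else {
      fpkm_m[g, setdiff(tissues, config$null_tissue)] <-
        stats::runif(length(tissues) - 1, 2, 10)
    }
  }
  fpkm_m[, config$null_tissue] <- 0
  fpkm <- tibble::tibble(gene = true_ids) |>
    dplyr::bind_cols(tibble::as_tibble(fpkm_m))

  qpcr_genes <- true_ids[type_index[["1"]] %||% seq_len(min(8, n_true))]
  conds <- config$qpcr_conditions
  qp_rows <- list()
  for (g in qpcr_genes) {
    base_dct <- stats::runif(1, 3, 6)
    for (cond in conds) {
      fc <- if (cond == conds[1]) 1 else sample1(config$fold_levels)
      fc_rows[[length(fc_rows) + 1]] <-
        tibble::tibble(gene = g, condition = cond, fold_change = fc)
      for (b in seq_len(config$n_bio)) {
        dct_bio <- base_dct - log2(fc) + stats::rnorm(1, 0, config$ct_sigma)
        for (tr in seq_len(config$n_tech)) {
          ct_ref <- 20 + stats::rnorm(1, 0, config$tech_sigma)
          qp_rows[[length(qp_rows) + 1]] <- tibble::tibble(
            gene = g, condition = cond, bio_rep = b, tech_rep = tr,
            ct_target = ct_ref + dct_bio + stats::rnorm(1, 0, config$tech_sigma),
            ct_reference = ct_ref)
        }
      }
    }
  }
  qpcr <- dplyr::bind_rows(qp_rows)
  }
  manifest <- list(proteins = truth_proteins, genes = truth_genes,
                   promoters = truth_promoters,
                   fold_changes = dplyr::bind_rows(fc_rows),
                   specific_tissues = dplyr::bind_rows(spec_rows))
  structure(list(proteins = proteins, genome = genome, genes = genes,
                 fpkm = fpkm, qpcr = qpcr, manifest = manifest,
                 config = config, seed = seed),
            class = "ltp_cohort")
}

#' Point-mutate the proteins of a cohort
#'
#' Robustness helper: mutates non-cysteine residues at the given rate
#' (cysteines are never touched and never created, so planted motifs keep
#' their backbone), leaving the manifest untouched.
#'
#' @param cohort An `ltp_cohort`.
#' @param rate Per-residue mutation probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The cohort with mutated protein sequences.
#' @export
mutate_cohort <- function(cohort, rate, seed = 1) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(cohort)
  set.seed(as.integer(seed))
  cohort$proteins$sequence <-
    vapply(cohort$proteins$sequence, mutate_protein, character(1),
           rate = rate, USE.NAMES = FALSE)
  cohort
}

#' Write a cohort bundle to disk
#'
#' Emits `proteins.faa`, `genome.fa`, `genes.gff3`, `fpkm.tsv`, `qpcr.tsv`
#' and the manifest tables as TSV under `dir`.
#'
#' @param cohort An `ltp_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(cohort$proteins, file.path(dir, "proteins.faa"))
  writeLines(unlist(purrr::imap(cohort$genome, function(s, nm)
    c(paste0(">", nm), gsub("(.{80})", "\\1\n", s)))),
    file.path(dir, "genome.fa"))
  write_gff3(cohort$genes, file.path(dir, "genes.gff3"))
  readr::write_tsv(cohort$fpkm, file.path(dir, "fpkm.tsv"))
  readr::write_tsv(cohort$qpcr, file.path(dir, "qpcr.tsv"))
  readr::write_tsv(cohort$manifest$fold_changes,
                   file.path(dir, "truth_fold_changes.tsv"))
  readr::write_tsv(cohort$manifest$promoters,
                   file.path(dir, "truth_promoters.tsv"))
  invisible(dir)
}
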