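# Synthetic-data generator: every input the pipeline consumes, with planted
# ground truth, so all stages are testable without any download. The
# defaults emulate the shape of a real woody-plant bHLH cohort: 95 family
# members, binding categories 24/13/3/55, eight chromosomes plus scaffolds
# (78 + 17 genes), nine tandem pairs, five tissues, and a low-temperature
# treatment series with 62 effectively expressed genes of which 6 go up
# 2-5x and 4 go down.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Frame positions that carry the canonical conserved residues (the 23
# landmark positions), and the five highly conserved ones.
CONSERVED_POSITIONS <- c(
  `8` = "H", `11` = "A", `12` = "E", `13` = "R", `15` = "R", `16` = "R",
  `19` = "I", `20` = "N", `22` = "R", `26` = "L", `29` = "L", `30` = "V",
  `31` = "P", `44` = "K", `45` = "D", `48` = "A", `49` = "S", `51` = "L",
  `54` = "A", `55` = "I", `57` = "Y", `59` = "K", `61` = "L"
)
HIGHLY_CONSERVED_POSITIONS <- c(15, 16, 26, 31, 61)

#' Template 61-residue domain
#'
#' Landmark positions carry their canonical residues; the remaining
#' positions carry arbitrary but fixed filler. The template's basic region
#' holds exactly four basic residues (His-8, Arg-13, Arg-15, Arg-16), so
#' unmodified it classifies as non-DNA-binding; category-specific residues
#' are layered on top by the generator.
#'
#' @return character vector of length 61.
#' @export
domain_template <- function() {
  tpl <- c("A", "E", "N", "S", "Q", "T", "G", "H", "S", "E", "A", "E",
           "R", "Q", "R", "R", "E",
           "N", "I", "N", "E", "R", "M", "K", "T", "L", "Q", "S", "L",
           "V", "P",
           "G", "S", "T", "D", "N", "E", "A", "S", "G", "P", "K", "S",
           "K", "D",
           "M", "L", "A", "S", "V", "L", "Q", "E", "A", "I", "Q", "Y",
           "V", "K", "E", "L")
  stopifnot(length(tpl) == 61,
            all(tpl[as.integer(names(CONSERVED_POSITIONS))] ==
                  unname(CONSERVED_POSITIONS)))
  tpl
}

# Frame positions the binding rules read (basic region + rule positions);
# the domain-noise process never touches these.
rule_sensitive_positions <- function() {
  c(1:17)
}

# One planted domain for a binding category: template + category residues +
# background noise at free positions.
plant_domain <- function(category, noise_free = 0.7, noise_cons = 0.05) {
  tpl <- domain_template()
  d <- tpl
  if (category == "G_BOX") {
    d[c(5, 9)] <- c("R", "K")                 # 6 basic total; 8/12/15/16 ok
  } else if (category == "E_BOX_NON_G") {
    d[8] <- "S"                               # breaks the G-box rule
    d[c(2, 5, 9)] <- c("K", "R", "K")         # restores 6 basic residues
  } else if (category == "NON_E_BOX") {
    d[12] <- "A"                              # breaks the E-box rule
    d[c(5, 9)] <- c("R", "K")
  } else if (category != "NON_DNA") {
    stop("unknown category ", category)
  }
  cons_pos <- as.integer(names(CONSERVED_POSITIONS))
  free_pos <- setdiff(18:61, cons_pos)
  mutate <- function(pos, p) {
    hit <- pos[runif(length(pos)) < p]
    d[hit] <<- sample(AA_LETTERS, length(hit), replace = TRUE)
  }
  mutate(free_pos, noise_free)
  mutate(setdiff(cons_pos, rule_sensitive_positions()), noise_cons)
  d
}

#' Seed alignment for the packaged domain PSSM
#'
#' A deterministic block of near-template domain cores (one per binding
#' category mix), used to build the default scanning PSSM. Generated under
#' an internal fixed seed so the PSSM is identical across sessions.
#'
#' @param n number of rows (default 24).
#' @return character vector of aligned 61-letter rows.
#' @export
bhlh_seed_alignment <- function(n = 24) {
  with_seed(20210762, {
    cats <- rep(c("G_BOX", "E_BOX_NON_G", "NON_E_BOX", "NON_DNA"),
                length.out = n)
    vapply(cats, function(cat) paste(plant_domain(cat), collapse = ""), "")
  })
}

#' Default scanning PSSM built from the packaged seed alignment
#'
#' @return a [build_pssm()] object of width 61.
#' @export
default_pssm <- function() {
  build_pssm(bhlh_seed_alignment())
}

# Uniform-synonymous back-translation of a protein, plus a TAA stop.
back_translate <- function(protein) {
  aa2codons <- split(names(Biostrings::GENETIC_CODE),
                     unname(Biostrings::GENETIC_CODE))
  chars <- seq_chars(protein)
  codons <- vapply(chars, function(a) {
    opts <- aa2codons[[a]]
    opts[sample.int(length(opts), 1)]
  }, "")
  paste0(paste(codons, collapse = ""), "TAA")
}

# Truncated log-normal FPKM draw: mean * exp(sdlog * Z), redrawn until the
# value lies inside [lo, hi]. Truncation pins every cell to its planted
# class (expressed / silent / fold band) for every seed.
rlnorm_trunc <- function(mean, sdlog, lo = 0, hi = Inf) {
  for (i in 1:100) {
    x <- mean * exp(rnorm(1, 0, sdlog))
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

#' Family generation spec
#'
#' @param n_genes family size (default 95).
#' @param category_counts planted binding-category counts, summing to
#'   `n_genes` (default G-box 24, non-G-box E-box 13, non-E-box 3,
#'   non-DNA 55).
#' @param n_chromosomes chromosomes (default 8; 17 genes go to scaffolds).
#' @param chr_counts family genes per chromosome (default
#'   12/18/2/8/10/12/11/5, plus 17 scaffold genes).
#' @param tandem_clusters tandem pairs per location (default one on chr1,
#'   two on chr5, three on chr6, two on chr7, one on a scaffold: 9 pairs).
#' @param tissues tissue panel (default bud, fruit, leaf, stem, root).
#' @param tissue_counts planted tissue categories: all five tissues 53,
#'   none 2, fruit-only 2, root-only 7; the rest split over 3- and
#'   4-tissue patterns.
#' @param n_expressed genes effectively expressed in the treatment series
#'   (default 62).
#' @param n_up,n_down planted up- (2-5x) and down-regulated genes
#'   (default 6 and 4).
#' @param sigma log-normal noise sdlog for FPKM (default 0.2).
#' @param seed RNG seed (default 1).
#' @return list of class `family_spec`.
#' @export
family_spec <- function(n_genes = 95,
                        category_counts = c(G_BOX = 24, E_BOX_NON_G = 13,
                                            NON_E_BOX = 3, NON_DNA = 55),
                        n_chromosomes = 8,
                        chr_counts = c(12, 18, 2, 8, 10, 12, 11, 5),
                        tandem_clusters = c(chr1 = 1, chr5 = 2, chr6 = 3,
                                            chr7 = 2, scaffold1 = 1),
                        tissues = c("bud", "fruit", "leaf", "stem", "root"),
                        tissue_counts = c(all = 53, none = 2, fruit_only = 2,
                                          root_only = 7),
                        n_expressed = 62, n_up = 6, n_down = 4,
                        sigma = 0.2, seed = 1) {
  stopifnot(sum(category_counts) == n_genes,
            length(chr_counts) == n_chromosomes,
            sum(chr_counts) <= n_genes,
            sum(tissue_counts) <= n_genes,
            n_up + n_down <= n_expressed, n_expressed <= n_genes)
  structure(as.list(environment()), class = "family_spec")
}

#' Generate a full synthetic family bundle
#'
#' Proteins (each with exactly one planted 61-residue domain satisfying its
#' assigned binding category), back-translated CDSs, a gene map with
#' planted tandem clusters and non-family filler genes, tissue and
#' low-temperature FPKM matrices realizing the planted archetypes under
#' truncated log-normal noise, promoters with planted cis-element motifs,
#' and truth tables for every planted label.
#'
#' @param spec a [family_spec()].
#' @return list: proteins, cds, genes (family + filler), fpkm_tissue,
#'   fpkm_treatment, promoters, motifs, truth (list of truth tables).
#' @export
generate_family <- function(spec = family_spec()) {
  with_seed(spec$seed, generate_family_impl(spec))
}

generate_family_impl <- function(spec) {
  n <- spec$n_genes
  ids <- sprintf("synbHLH%02d", seq_len(n))

  # --- planted binding categories and domains -----------------------------
  categories <- sample(rep(names(spec$category_counts),
                           spec$category_counts))
  names(categories) <- ids
  domains <- t(vapply(categories, plant_domain, character(61)))
  rownames(domains) <- ids

  # --- proteins: background flanks around the planted domain -------------
  flank <- function(len) paste(sample(AA_LETTERS, len, replace = TRUE),
                               collapse = "")
  n_left <- sample(60:120, n, replace = TRUE)
  n_right <- sample(80:150, n, replace = TRUE)
  proteins <- setNames(vapply(seq_len(n), function(i) {
    paste0(flank(n_left[i]), paste(domains[i, ], collapse = ""),
           flank(n_right[i]))
  }, ""), ids)
  domain_start <- setNames(n_left + 1L, ids)

  # --- coding sequences ---------------------------------------------------
  cds <- setNames(vapply(proteins, back_translate, ""), ids)

  # --- gene map with planted tandem clusters ------------------------------
  chroms <- c(paste0("chr", seq_len(spec$n_chromosomes)),
              paste0("scaffold", 1:6))
  counts <- c(spec$chr_counts, scaffold_split(n - sum(spec$chr_counts), 6))
  gene_rows <- list()
  filler_rows <- list()
  tandem_truth <- list()
  idx <- 0
  filler_id <- 0
  for (ci in seq_along(chroms)) {
    chr <- chroms[ci]
    k <- counts[ci]
    if (k == 0) next
    members <- ids[(idx + 1):(idx + k)]
    idx <- idx + k
    n_clusters <- unname(spec$tandem_clusters[chr])
    if (is.na(n_clusters)) n_clusters <- 0
    if (2 * n_clusters > k) stop("more tandem clusters than genes on ", chr)
    pos <- 50000
    i <- 1
    cluster_left <- n_clusters
    while (i <= k) {
      gid <- members[i]
      gene_rows[[length(gene_rows) + 1]] <- data.frame(
        gene_id = gid, chromosome = chr, start = pos,
        end = pos + sample(1500:3000, 1), strand = sample(c("+", "-"), 1),
        stringsAsFactors = FALSE
      )
      if (cluster_left > 0 && i + 1 <= k) {
        # partner immediately downstream, within the tandem distance
        partner <- members[i + 1]
        ppos <- pos + sample(20000:60000, 1)
        gene_rows[[length(gene_rows) + 1]] <- data.frame(
          gene_id = partner, chromosome = chr, start = ppos,
          end = ppos + sample(1500:3000, 1),
          strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE
        )
        sorted <- sort(c(gid, partner))
        tandem_truth[[length(tandem_truth) + 1]] <- data.frame(
          gene_a = sorted[1], gene_b = sorted[2], chromosome = chr,
          stringsAsFactors = FALSE
        )
        cluster_left <- cluster_left - 1
        i <- i + 2
        pos <- ppos
      } else {
        i <- i + 1
      }
      # two filler genes, then the next family gene far downstream
      for (f in 1:2) {
        filler_id <- filler_id + 1
        fpos <- pos + 120000 * f
        filler_rows[[length(filler_rows) + 1]] <- data.frame(
          gene_id = sprintf("filler%03d", filler_id), chromosome = chr,
          start = fpos, end = fpos + 2000, strand = "+",
          stringsAsFactors = FALSE
        )
      }
      pos <- pos + 400000
    }
  }
  genes <- validate_gene_models(
    do.call(rbind, c(gene_rows, filler_rows, list(make.row.names = FALSE)))
  )
  tandem_truth <- do.call(rbind, tandem_truth)
  tandem_truth <- tandem_truth[order(tandem_truth$gene_a), , drop = FALSE]
  rownames(tandem_truth) <- NULL

  # --- tissue FPKM matrix -------------------------------------------------
  tissues <- spec$tissues
  tc <- spec$tissue_counts
  n_partial <- n - sum(tc)
  tissue_cat <- c(
    rep("all_tissues", tc["all"]), rep("none", tc["none"]),
    rep("single:fruit", tc["fruit_only"]), rep("single:root", tc["root_only"]),
    rep("partial", n_partial)
  )
  tissue_cat <- sample(tissue_cat)       # shuffle over gene ids
  names(tissue_cat) <- ids
  base_expr <- setNames(runif(n, 3, 30), ids)
  fpkm_tissue <- matrix(0, nrow = n, ncol = length(tissues),
                        dimnames = list(ids, tissues))
  for (g in ids) {
    on <- switch(tissue_cat[[g]],
      all_tissues = tissues,
      none = character(0),
      `single:fruit` = "fruit",
      `single:root` = "root",
      partial = sample(tissues, sample(3:4, 1))
    )
    if (tissue_cat[[g]] == "partial") {
      tissue_cat[[g]] <- paste0(length(on), "_of_", length(tissues))
    }
    for (t in tissues) {
      fpkm_tissue[g, t] <- if (t %in% on) {
        rlnorm_trunc(base_expr[[g]], spec$sigma, lo = 1.5)
      } else {
        rlnorm_trunc(0.2, spec$sigma, hi = 0.8)
      }
    }
  }

  # --- low-temperature treatment FPKM matrix ------------------------------
  conditions <- c("control", "chill_8h", "chill_5d", "freeze_1h")
  expressed <- sample(ids, spec$n_expressed)
  silent <- setdiff(ids, expressed)
  up_genes <- sample(expressed, spec$n_up)
  down_genes <- sample(setdiff(expressed, up_genes), spec$n_down)
  flat <- setdiff(expressed, c(up_genes, down_genes))
  fpkm_treat <- matrix(0, nrow = n, ncol = length(conditions),
                       dimnames = list(ids, conditions))
  pseudo <- 0.1
  for (g in silent) {
    fpkm_treat[g, ] <- vapply(conditions, function(cd)
      rlnorm_trunc(0.15, spec$sigma, hi = 0.8), 0)
  }
  fc_bounds <- function(ctrl, lo_fc, hi_fc) {
    # FPKM bounds such that (x + pseudo) / (ctrl + pseudo) is in
    # [lo_fc, hi_fc]
    c(lo_fc * (ctrl + pseudo) - pseudo, hi_fc * (ctrl + pseudo) - pseudo)
  }
  for (g in flat) {
    ctrl <- rlnorm_trunc(runif(1, 3, 20), spec$sigma, lo = 1.5)
    fpkm_treat[g, "control"] <- ctrl
    b <- fc_bounds(ctrl, 0.6, 1.7)
    for (cd in conditions[-1]) {
      fpkm_treat[g, cd] <- rlnorm_trunc(ctrl, spec$sigma,
                                        lo = max(b[1], 0), hi = b[2])
    }
  }
  for (g in up_genes) {
    ctrl <- rlnorm_trunc(runif(1, 3, 8), spec$sigma, lo = 1.5)
    fpkm_treat[g, "control"] <- ctrl
    target <- runif(1, 2.6, 4.4)
    for (cd in c("chill_8h", "chill_5d")) {
      b <- fc_bounds(ctrl, 2.2, 4.8)
      fpkm_treat[g, cd] <- rlnorm_trunc(target * ctrl, spec$sigma,
                                        lo = b[1], hi = b[2])
    }
    b <- fc_bounds(ctrl, 0.6, 1.7)
    fpkm_treat[g, "freeze_1h"] <- rlnorm_trunc(ctrl, spec$sigma,
                                               lo = max(b[1], 0), hi = b[2])
  }
  for (g in down_genes) {
    ctrl <- rlnorm_trunc(runif(1, 12, 25), spec$sigma, lo = 8)
    fpkm_treat[g, "control"] <- ctrl
    target <- runif(1, 1 / 4.4, 1 / 2.6)
    for (cd in c("chill_8h", "chill_5d")) {
      b <- fc_bounds(ctrl, 1 / 4.8, 1 / 2.2)
      fpkm_treat[g, cd] <- rlnorm_trunc(target * ctrl, spec$sigma,
                                        lo = max(b[1], 0), hi = b[2])
    }
    b <- fc_bounds(ctrl, 0.6, 1.7)
    fpkm_treat[g, "freeze_1h"] <- rlnorm_trunc(ctrl, spec$sigma,
                                               lo = max(b[1], 0), hi = b[2])
  }

  # --- promoters with planted motifs --------------------------------------
  motifs <- read_motifs()
  prom <- generate_promoters(ids, motifs, length_bp = 1500)

  list(
    proteins = proteins, cds = cds, genes = genes,
    fpkm_tissue = fpkm_tissue, fpkm_treatment = fpkm_treat,
    promoters = prom$promoters, motifs = motifs,
    truth = list(
      categories = data.frame(gene_id = ids, category = unname(categories),
                              stringsAsFactors = FALSE),
      domain_start = data.frame(gene_id = ids,
                                start = unname(domain_start),
                                stringsAsFactors = FALSE),
      tandem_pairs = tandem_truth,
      tissue_category = data.frame(gene_id = ids,
                                   category = unname(tissue_cat),
                                   stringsAsFactors = FALSE),
      expressed_genes = sort(expressed),
      up_genes = sort(up_genes),
      down_genes = sort(down_genes),
      motif_counts = prom$truth_counts,
      motif_positions = prom$truth_positions
    )
  )
}

# 17 scaffold genes over 6 scaffolds by default.
scaffold_split <- function(total, k) {
  base <- rep(total %/% k, k)
  extra <- total %% k
  if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1
  base
}

# Position-by-position IUPAC matcher -- the generator's independent
# reference for motif truth counts (deliberately not sharing code with
# scan_promoter's regex route). Column-wise vectorized over windows.
naive_motif_hits <- function(seqstr, pattern) {
  chars <- seq_chars(seqstr)
  pat <- seq_chars(toupper(pattern))
  L <- length(pat)
  n_win <- length(chars) - L + 1
  if (n_win < 1) return(integer(0))
  ok <- rep(TRUE, n_win)
  for (j in seq_len(L)) {
    cj <- chars[j:(j + n_win - 1)]
    ok <- ok & cj != "N" & cj %in% IUPAC_SETS[[pat[j]]]
  }
  which(ok)
}

# Generate promoters: motif-free background (all packaged motifs scrubbed
# on both strands), then planted motif instances at recorded positions.
generate_promoters <- function(ids, motifs, length_bp = 1500) {
  promoters <- character(length(ids))
  names(promoters) <- ids
  truth_positions <- list()
  counts <- matrix(0L, nrow = length(ids), ncol = nrow(motifs),
                   dimnames = list(ids, motifs$name))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (g in ids) {
    chars <- sample(DNA_LETTERS, length_bp, replace = TRUE)
    # scrub accidental hits of any motif, both strands, flipping the first
    # base of every hit until the background is motif-free
    for (iter in 1:50) {
      flip <- integer(0)
      fwd <- paste(chars, collapse = "")
      rev <- paste(unname(comp[rev(chars)]), collapse = "")
      for (i in seq_len(nrow(motifs))) {
        h <- naive_motif_hits(fwd, motifs$pattern[i])
        flip <- c(flip, h)
        h <- naive_motif_hits(rev, motifs$pattern[i])
        flip <- c(flip, length_bp - h + 1)
      }
      if (length(flip) == 0) break
      flip <- unique(flip)
      chars[flip] <- vapply(chars[flip], function(b)
        sample(setdiff(DNA_LETTERS, b), 1), "")
    }
    seqstr <- paste(chars, collapse = "")
    # plant 0-2 instances of each motif at spaced positions
    n_plant <- sample(0:2, nrow(motifs), replace = TRUE)
    slots <- sample(seq(10, length_bp - 20, by = 25))
    si <- 0
    for (i in seq_len(nrow(motifs))) {
      if (n_plant[i] == 0) next
      pat <- motifs$pattern[i]
      for (r in seq_len(n_plant[i])) {
        si <- si + 1
        pos <- slots[si]
        inst <- paste(vapply(seq_chars(pat), function(code) {
          set <- IUPAC_SETS[[code]]
          set[sample.int(length(set), 1)]
        }, ""), collapse = "")
        substr(seqstr, pos, pos + nchar(inst) - 1) <- inst
        truth_positions[[length(truth_positions) + 1]] <- data.frame(
          gene = g, motif = motifs$name[i], position = pos, strand = "+",
          stringsAsFactors = FALSE
        )
      }
    }
    promoters[[g]] <- seqstr
    # truth counts by the naive matcher on the final sequence
    for (i in seq_len(nrow(motifs))) {
      n_f <- length(naive_motif_hits(seqstr, motifs$pattern[i]))
      n_r <- length(naive_motif_hits(revcomp(seqstr), motifs$pattern[i]))
      counts[g, motifs$name[i]] <- n_f + n_r
    }
  }
  tp <- if (length(truth_positions) > 0) {
    do.call(rbind, truth_positions)
  } else {
    data.frame(gene = character(0), motif = character(0),
               position = integer(0), strand = character(0))
  }
  list(promoters = promoters, truth_counts = counts, truth_positions = tp)
}

#' Synthetic proteins with a planted domain for scanner calibration
#'
#' Each protein is background (uniform residues) with one near-template
#' domain planted at a recorded offset.
#'
#' @param n number of proteins (default 100).
#' @param length_aa protein length (default 400).
#' @param seed RNG seed.
#' @return list: proteins (named vector), truth (data.frame gene_id,
#'   start, category).
#' @export
generate_scan_cohort <- function(n = 100, length_aa = 400, seed = 1) {
  with_seed(seed, {
    ids <- sprintf("scan%03d", seq_len(n))
    cats <- sample(names(family_spec()$category_counts), n, replace = TRUE)
    starts <- sample(seq_len(length_aa - 61 + 1), n, replace = TRUE)
    proteins <- setNames(vapply(seq_len(n), function(i) {
      bg <- sample(AA_LETTERS, length_aa, replace = TRUE)
      bg[starts[i]:(starts[i] + 60)] <- plant_domain(cats[i])
      paste(bg, collapse = "")
    }, ""), ids)
    list(proteins = proteins,
         truth = data.frame(gene_id = ids, start = starts, category = cats,
                            stringsAsFactors = FALSE))
  })
}

#' Aligned-domain cohort with exact planted consensus ratios
#'
#' Builds a 61-column cohort in which a chosen set of positions has a
#' planted modal-residue count (so consensus ratios are exact by
#' construction, not just in expectation): by default the 23 landmark
#' positions exceed the 0.5 conservation threshold, of which the five
#' canonical positions exceed 0.9, and every other position stays below
#' 0.5.
#'
#' @param n number of domains (default 95).
#' @param seed RNG seed.
#' @param high_ratio planted ratio at highly conserved positions
#'   (default 0.95).
#' @param mid_ratio planted ratio at the other conserved positions
#'   (default 0.7).
#' @param low_max maximum modal count fraction elsewhere (default 0.42).
#' @return list: domains (n x 61 matrix), truth (data.frame position,
#'   label, modal, planted_count).
#' @export
generate_consensus_cohort <- function(n = 95, seed = 1, high_ratio = 0.95,
                                      mid_ratio = 0.7, low_max = 0.42) {
  with_seed(seed, {
    tpl <- domain_template()
    cons <- as.integer(names(CONSERVED_POSITIONS))
    mat <- matrix("", nrow = n, ncol = 61)
    truth <- data.frame(position = 1:61, label = "none", modal = tpl,
                        planted_count = 0L, stringsAsFactors = FALSE)
    for (p in 1:61) {
      if (p %in% HIGHLY_CONSERVED_POSITIONS) {
        k <- ceiling(high_ratio * n)
        label <- "highly_conserved"
      } else if (p %in% cons) {
        k <- ceiling(mid_ratio * n)
        label <- "conserved"
      } else {
        k <- floor(low_max * n)
        label <- "none"
      }
      modal <- tpl[p]
      others <- setdiff(AA_LETTERS, modal)
      # remaining residues spread so no other letter reaches the modal count
      rest <- sample(rep(others, length.out = max(n - k, 0)))
      col <- sample(c(rep(modal, k), rest))
      mat[, p] <- col
      truth$label[p] <- label
      truth$planted_count[p] <- k
    }
    rownames(mat) <- sprintf("cons%03d", seq_len(n))
    colnames(mat) <- 1:61
    list(domains = mat, truth = truth)
  })
}

#' Evolve a codon-sequence pair at a planted dN/dS
#'
#' An ancestor of `n_codons` sense codons is drawn uniformly; one lineage
#' accumulates substitutions proposed by a Poisson process at `t_sub`
#' expected proposals per nucleotide site, each proposal picking a uniform
#' site and alternative base. Proposals creating a stop codon are
#' rejected; nonsynonymous proposals are accepted with relative rate
#' `omega` (for omega <= 1: accepted with probability omega; for
#' omega > 1: synonymous proposals are instead accepted with probability
#' 1/omega). Realized accepted counts are recorded as truth.
#'
#' @param n_codons number of codons (>= 10).
#' @param t_sub expected proposals per site (default 0.2).
#' @param omega planted dN/dS acceptance ratio (> 0).
#' @param seed RNG seed.
#' @return list: cds_a, cds_b (strings), truth (list with
#'   n_syn_substitutions, n_nonsyn_substitutions, n_proposals).
#' @export
evolve_codon_pair <- function(n_codons, t_sub = 0.2, omega = 1, seed = 1) {
  stopifnot(n_codons >= 10, omega > 0, t_sub >= 0)
  with_seed(seed, {
    sense <- rownames(codon_site_table())
    anc <- sample(sense, n_codons, replace = TRUE)
    chars <- seq_chars(paste(anc, collapse = ""))
    L <- length(chars)
    n_prop <- rpois(1, t_sub * L)
    n_syn <- 0; n_nonsyn <- 0
    p_syn <- min(1, 1 / omega)
    p_nonsyn <- min(1, omega)
    if (n_prop > 0) {
      for (e in seq_len(n_prop)) {
        site <- sample.int(L, 1)
        base <- sample(setdiff(DNA_LETTERS, chars[site]), 1)
        ci <- (site - 1) %/% 3
        old_codon <- paste(chars[(ci * 3 + 1):(ci * 3 + 3)], collapse = "")
        new <- chars
        new[site] <- base
        new_codon <- paste(new[(ci * 3 + 1):(ci * 3 + 3)], collapse = "")
        if (codon_aa(new_codon) == "*") next
        syn <- codon_aa(new_codon) == codon_aa(old_codon)
        p_acc <- if (syn) p_syn else p_nonsyn
        if (runif(1) <= p_acc) {
          chars <- new
          if (syn) n_syn <- n_syn + 1 else n_nonsyn <- n_nonsyn + 1
        }
      }
    }
    list(cds_a = paste(anc, collapse = ""),
         cds_b = paste(chars, collapse = ""),
         truth = list(n_syn_substitutions = n_syn,
                      n_nonsyn_substitutions = n_nonsyn,
                      n_proposals = n_prop))
  })
}

#' Write a generated bundle to a directory
#'
#' Plain-text artifacts: proteins.fa, cds.fa, genes.tsv, fpkm_tissue.tsv,
#' fpkm_treatment.tsv, promoters.fa, and `truth_*` TSV tables.
#'
#' @param bundle result of [generate_family()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bundle$proteins, file.path(dir, "proteins.fa"))
  write_fasta(bundle$cds, file.path(dir, "cds.fa"))
  write_gene_models(bundle$genes, file.path(dir, "genes.tsv"))
  write_fpkm(bundle$fpkm_tissue, file.path(dir, "fpkm_tissue.tsv"))
  write_fpkm(bundle$fpkm_treatment, file.path(dir, "fpkm_treatment.tsv"))
  write_fasta(bundle$promoters, file.path(dir, "promoters.fa"))
  tt <- bundle$truth
  write.table(tt$categories, file.path(dir, "truth_categories.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tt$domain_start, file.path(dir, "truth_domain_start.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tt$tandem_pairs, file.path(dir, "truth_tandem_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tt$tissue_category, file.path(dir, "truth_tissue_category.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(tt$expressed_genes, file.path(dir, "truth_expressed_genes.txt"))
  writeLines(tt$up_genes, file.path(dir, "truth_up_genes.txt"))
  writeLines(tt$down_genes, file.path(dir, "truth_down_genes.txt"))
  invisible(dir)
}
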