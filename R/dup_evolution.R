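# Tandem-duplication detection, Nei-Gojobori (1986) Ka/Ks with
# Jukes-Cantor correction, selection labels, and molecular-clock divergence
# dating (T = Ks / (2 * lambda), lambda = 1.5e-8 substitutions/site/year
# for dicots, reported in Mya).

#' Tandem-duplication criteria
#'
#' The literature rarely states explicit criteria; common practice is used
#' as the default: same chromosome, at most one intervening gene, and
#' start-to-start distance at most 100 kb. Both knobs are reported in the
#' output so analyses are self-describing.
#'
#' @param max_intervening_genes maximum genes between the pair (default 1).
#' @param max_distance_bp maximum start-to-start distance (default 1e5).
#' @return object of class `tandem_criteria`.
#' @export
tandem_criteria <- function(max_intervening_genes = 1,
                            max_distance_bp = 100000) {
  stopifnot(max_intervening_genes >= 0, max_distance_bp >= 0)
  structure(list(max_intervening_genes = max_intervening_genes,
                 max_distance_bp = max_distance_bp),
            class = "tandem_criteria")
}

#' Find tandem-duplicate pairs of family members
#'
#' Unordered pairs of family genes on the same chromosome whose rank gap
#' (number of intervening genes) and start-to-start distance both fall
#' within the criteria. Each pair appears once, ids in lexicographic order.
#'
#' @param genes gene-model data.frame with per-chromosome ranks (from
#'   [read_gene_models()] / [validate_gene_models()]). May include
#'   non-family genes, which count as intervening.
#' @param family_ids ids of the family members.
#' @param criteria a [tandem_criteria()].
#' @return data.frame: gene_a, gene_b, chromosome, distance_bp,
#'   intervening_genes.
#' @export
find_tandem_pairs <- function(genes, family_ids,
                              criteria = tandem_criteria()) {
  missing <- setdiff(family_ids, genes$gene_id)
  if (length(missing) > 0) {
    stop("family id(s) absent from gene set: ",
         paste(missing, collapse = ", "))
  }
  fam <- genes[genes$gene_id %in% family_ids, , drop = FALSE]
  out <- list()
  for (chr in unique(fam$chromosome)) {
    g <- fam[fam$chromosome == chr, , drop = FALSE]
    if (nrow(g) < 2) next
    g <- g[order(g$rank), ]
    for (i in seq_len(nrow(g) - 1)) {
      for (j in (i + 1):nrow(g)) {
        intervening <- g$rank[j] - g$rank[i] - 1
        dist <- abs(g$start[j] - g$start[i])
        if (intervening <= criteria$max_intervening_genes &&
            dist <= criteria$max_distance_bp) {
          ids <- sort(c(g$gene_id[i], g$gene_id[j]))
          out[[length(out) + 1]] <- data.frame(
            gene_a = ids[1], gene_b = ids[2], chromosome = chr,
            distance_bp = dist, intervening_genes = intervening,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      chromosome = character(0), distance_bp = numeric(0),
                      intervening_genes = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$gene_a, res$gene_b), , drop = FALSE]
}

#' Globally align two protein sequences
#'
#' Needleman-Wunsch via Biostrings, BLOSUM62; convenience for building the
#' protein alignment that guides [codon_align()].
#'
#' @param a,b protein sequence strings.
#' @return character vector of the two aligned rows (with `-` gaps).
#' @export
align_protein_pair <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a[[1]]), Biostrings::AAString(b[[1]]),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global"
  )
  c(as.character(Biostrings::alignedPattern(al)),
    as.character(Biostrings::alignedSubject(al)))
}

#' Expand a protein alignment into a codon alignment
#'
#' Each protein alignment column becomes a codon column; gaps become
#' three-base gaps. The CDS translations (terminal stop codon allowed and
#' dropped) must equal the ungapped alignment rows.
#'
#' @param cds_a,cds_b in-frame coding sequences.
#' @param protein_alignment character vector of two equal-length aligned
#'   protein rows.
#' @return character vector of two aligned codon sequences.
#' @export
codon_align <- function(cds_a, cds_b, protein_alignment) {
  stopifnot(length(protein_alignment) == 2)
  expand_one <- function(cds, row, which) {
    cds <- cds[[1]]
    aa <- translate_cds(cds)
    if (substring(aa, nchar(aa)) == "*") {
      aa <- substring(aa, 1, nchar(aa) - 1)
      cds <- substring(cds, 1, nchar(cds) - 3)
    }
    ungapped <- gsub("-", "", row, fixed = TRUE)
    if (aa != ungapped) {
      diff <- which(seq_chars(aa)[seq_len(min(nchar(aa), nchar(ungapped)))] !=
                      seq_chars(ungapped)[seq_len(min(nchar(aa), nchar(ungapped)))])
      stop("CDS translation does not match protein alignment row ", which,
           " (first mismatch at residue ",
           if (length(diff) > 0) diff[1] else nchar(ungapped) + 1, ")")
    }
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    cols <- seq_chars(row)
    out <- character(length(cols))
    k <- 0
    for (i in seq_along(cols)) {
      if (cols[i] == "-") {
        out[i] <- "---"
      } else {
        k <- k + 1
        out[i] <- codons[k]
      }
    }
    paste(out, collapse = "")
  }
  c(expand_one(cds_a, protein_alignment[1], 1),
    expand_one(cds_b, protein_alignment[2], 2))
}

# --- NG86 internals -------------------------------------------------------

codon_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

ng_env <- new.env(parent = emptyenv())

# Synonymous/nonsynonymous site counts per codon: each of the 9 single-base
# mutants contributes 1/3 of a site to S (same amino acid) or N
# (different), except mutations to stop codons, which are excluded and
# shrink the codon's total below 3.
codon_site_table <- function() {
  if (!is.null(ng_env$sites)) return(ng_env$sites)
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  m <- matrix(0, nrow = length(sense), ncol = 2,
              dimnames = list(sense, c("S", "N")))
  for (codon in sense) {
    aa <- codon_aa(codon)
    chars <- seq_chars(codon)
    for (p in 1:3) {
      for (b in setdiff(DNA_LETTERS, chars[p])) {
        mut <- chars
        mut[p] <- b
        mut_aa <- codon_aa(paste(mut, collapse = ""))
        if (mut_aa == "*") next
        if (mut_aa == aa) m[codon, "S"] <- m[codon, "S"] + 1 / 3
        else m[codon, "N"] <- m[codon, "N"] + 1 / 3
      }
    }
  }
  ng_env$sites <- m
  m
}

# Synonymous/nonsynonymous difference counts between two sense codons,
# averaged over all minimal mutational pathways. Pathways passing through a
# stop codon are excluded; in the rare case that every pathway is blocked,
# all pathways are used with stop-involving steps counted nonsynonymous.
codon_diff_counts <- function(a, b) {
  if (a == b) return(c(S = 0, N = 0))
  key <- paste(sort(c(a, b)), collapse = "|")
  if (!is.null(ng_env$diffs[[key]])) return(ng_env$diffs[[key]])
  pos <- which(seq_chars(a) != seq_chars(b))
  perms <- permutations_of(pos)
  walk <- function(order, allow_stop) {
    cur <- seq_chars(a)
    tgt <- seq_chars(b)
    s <- 0; n <- 0
    for (p in order) {
      nxt <- cur
      nxt[p] <- tgt[p]
      aa1 <- codon_aa(paste(cur, collapse = ""))
      aa2 <- codon_aa(paste(nxt, collapse = ""))
      if (aa2 == "*" && !allow_stop) return(NULL)
      if (aa1 == aa2 && aa1 != "*") s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(s, n)
  }
  counts <- Filter(Negate(is.null), lapply(perms, walk, allow_stop = FALSE))
  if (length(counts) == 0) {
    counts <- lapply(perms, walk, allow_stop = TRUE)
  }
  mat <- do.call(rbind, counts)
  out <- c(S = mean(mat[, 1]), N = mean(mat[, 2]))
  if (is.null(ng_env$diffs)) ng_env$diffs <- list()
  ng_env$diffs[[key]] <- out
  out
}

permutations_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) {
      out[[length(out) + 1]] <- c(x[i], rest)
    }
  }
  out
}

#' Jukes-Cantor multiple-hit correction
#'
#' `d = -(3/4) * log(1 - (4/3) * p)`; undefined (NA) when p >= 3/4.
#'
#' @param p proportion of differing sites.
#' @return corrected distance, or NA when saturated.
#' @export
jukes_cantor <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

#' Nei-Gojobori (1986) Ka/Ks on an aligned codon pair
#'
#' Counts synonymous/nonsynonymous sites per codon by enumerating the nine
#' single-base mutants (stop mutants excluded), averages site counts over
#' the two sequences, counts differences by averaging over all minimal
#' mutational pathways between differing codons (pathways through stop
#' codons excluded), and applies the Jukes-Cantor correction to pN and pS.
#' Gap-containing and non-canonical codon columns are skipped. A saturated
#' proportion (p >= 3/4) leaves the corresponding rate undefined (NA) --
#' this mirrors real duplicate pairs for which only Ka is reported.
#'
#' @param pair character vector of two aligned, equal-length codon
#'   sequences (lengths multiples of 3, `-` for gaps).
#' @return list: ka, ks, pn, ps, nd, sd, n_sites, s_sites, n_codons
#'   (comparable codons).
#' @export
nei_gojobori <- function(pair) {
  stopifnot(length(pair) == 2, nchar(pair[1]) == nchar(pair[2]),
            nchar(pair[1]) %% 3 == 0)
  starts <- seq(1, nchar(pair[1]), 3)
  ca <- substring(pair[1], starts, starts + 2)
  cb <- substring(pair[2], starts, starts + 2)
  sites <- codon_site_table()
  sense <- rownames(sites)
  ok <- ca %in% sense & cb %in% sense
  if (!any(ok)) stop("no comparable (gap-free, sense) codon columns")
  ca <- ca[ok]; cb <- cb[ok]

  s_sites <- (sum(sites[ca, "S"]) + sum(sites[cb, "S"])) / 2
  n_sites <- (sum(sites[ca, "N"]) + sum(sites[cb, "N"])) / 2
  sd <- 0; nd <- 0
  for (i in seq_along(ca)) {
    d <- codon_diff_counts(ca[i], cb[i])
    sd <- sd + d[["S"]]
    nd <- nd + d[["N"]]
  }
  ps <- if (s_sites > 0) sd / s_sites else NA_real_
  pn <- if (n_sites > 0) nd / n_sites else NA_real_
  list(ka = if (is.na(pn)) NA_real_ else jukes_cantor(pn),
       ks = if (is.na(ps)) NA_real_ else jukes_cantor(ps),
       pn = pn, ps = ps, nd = nd, sd = sd,
       n_sites = n_sites, s_sites = s_sites, n_codons = length(ca))
}

#' Selection-regime label from Ka/Ks
#'
#' Below the neutral band means purifying selection, above means positive
#' selection, inside means neutral; an undefined ratio (e.g. saturated Ks)
#' is `undetermined`.
#'
#' @param ka_ks Ka/Ks ratio (may be NA).
#' @param neutral_band numeric length-2 band around 1 (default
#'   `c(0.95, 1.05)`).
#' @return one of "purifying", "neutral", "positive", "undetermined".
#' @export
selection_label <- function(ka_ks, neutral_band = c(0.95, 1.05)) {
  if (is.na(ka_ks)) return("undetermined")
  if (ka_ks < neutral_band[1]) return("purifying")
  if (ka_ks > neutral_band[2]) return("positive")
  "neutral"
}

#' Molecular-clock divergence time
#'
#' `T = Ks / (2 * lambda)`, reported in Mya. At the default dicot clock
#' rate lambda = 1.5e-8 substitutions/site/year this is `Ks / 0.03` Mya.
#'
#' @param ks synonymous substitution rate (may be NA).
#' @param lambda_rate substitutions/site/year (default 1.5e-8).
#' @return divergence time in Mya (NA when ks is NA).
#' @export
divergence_time <- function(ks, lambda_rate = 1.5e-8) {
  stopifnot(lambda_rate > 0)
  if (any(!is.na(ks) & ks < 0)) stop("negative ks")
  ks / (2 * lambda_rate) / 1e6
}

#' Ka/Ks, selection and dating for duplicate pairs
#'
#' End-to-end convenience: for each pair, align the translated proteins,
#' expand to a codon alignment, run [nei_gojobori()], label selection and
#' date divergence.
#'
#' @param pairs data.frame with columns gene_a, gene_b (e.g. from
#'   [find_tandem_pairs()]).
#' @param cds named character vector of coding sequences covering all pair
#'   members.
#' @param lambda_rate clock rate for [divergence_time()].
#' @param neutral_band band for [selection_label()].
#' @return data.frame: gene_a, gene_b, ka, ks, ka_ks, divergence_time_mya,
#'   selection_label.
#' @export
duplicate_pair_table <- function(pairs, cds, lambda_rate = 1.5e-8,
                                 neutral_band = c(0.95, 1.05)) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    if (!a %in% names(cds) || !b %in% names(cds)) {
      stop("missing CDS for pair ", a, "-", b)
    }
    strip_stop <- function(s) {
      aa <- translate_cds(s)
      if (substring(aa, nchar(aa)) == "*") substring(s, 1, nchar(s) - 3) else s
    }
    pa <- translate_cds(strip_stop(cds[[a]]))
    pb <- translate_cds(strip_stop(cds[[b]]))
    aln <- align_protein_pair(pa, pb)
    cod <- codon_align(cds[[a]], cds[[b]], aln)
    ng <- nei_gojobori(cod)
    ka_ks <- if (!is.na(ng$ka) && !is.na(ng$ks) && ng$ks > 0)
      ng$ka / ng$ks else NA_real_
    data.frame(
      gene_a = a, gene_b = b, ka = ng$ka, ks = ng$ks, ka_ks = ka_ks,
      divergence_time_mya = if (is.na(ng$ks)) NA_real_
        else divergence_time(ng$ks, lambda_rate),
      selection_label = selection_label(ka_ks, neutral_band),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
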