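# Independent oracles and shared fixtures for the test suite. Oracles are
# deliberately written with different logic (and often different
# primitives) than the implementation paths they check.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

# --- window-score oracle: per-letter accumulation ------------------------
# Accumulates the score of a single window letter-by-letter with explicit
# indexing (no vectorized sweep).
oracle_window_score <- function(sequence, pssm, start) {
  chars <- strsplit(sequence, "")[[1]]
  total <- 0
  for (p in seq_len(pssm$length)) {
    total <- total + pssm$scores[chars[start + p - 1], p]
  }
  total
}

# --- NG86 oracles --------------------------------------------------------
GC <- Biostrings::GENETIC_CODE
SENSE_CODONS <- names(GC)[GC != "*"]

# Site counts of one codon by direct enumeration of the 9 mutants.
oracle_codon_sites <- function(codon) {
  b <- strsplit(codon, "")[[1]]
  s <- 0; n <- 0
  for (p in 1:3) {
    for (alt in setdiff(c("A", "C", "G", "T"), b[p])) {
      mut <- b; mut[p] <- alt
      maa <- GC[[paste(mut, collapse = "")]]
      if (maa == "*") next
      if (maa == GC[[codon]]) s <- s + 1 / 3 else n <- n + 1 / 3
    }
  }
  c(S = s, N = n)
}

# Difference counts between two sense codons: recursive enumeration of all
# orders of applying the differing positions, discarding stop-crossing
# paths (all paths with stop steps counted nonsynonymous if none survive).
oracle_codon_diffs <- function(a, b) {
  if (a == b) return(c(S = 0, N = 0))
  paths <- list()
  recurse <- function(cur, steps) {
    if (cur == b) {
      paths[[length(paths) + 1]] <<- steps
      return()
    }
    ca <- strsplit(cur, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    for (p in which(ca != cb)) {
      nxt <- ca; nxt[p] <- cb[p]
      nxt <- paste(nxt, collapse = "")
      recurse(nxt, c(steps, paste(cur, nxt)))
    }
  }
  recurse(a, character(0))
  classify_path <- function(steps) {
    s <- 0; n <- 0; blocked <- FALSE
    for (st in steps) {
      cods <- strsplit(st, " ")[[1]]
      a1 <- GC[[cods[1]]]; a2 <- GC[[cods[2]]]
      if (a2 == "*") blocked <- TRUE
      if (a1 == a2 && a1 != "*") s <- s + 1 else n <- n + 1
    }
    list(s = s, n = n, blocked = blocked)
  }
  cls <- lapply(paths, classify_path)
  open <- Filter(function(x) !x$blocked, cls)
  use <- if (length(open) > 0) open else cls
  c(S = mean(vapply(use, `[[`, 0, "s")),
    N = mean(vapply(use, `[[`, 0, "n")))
}

# --- naive motif oracle --------------------------------------------------
# Double loop, no vectorization, no regex.
oracle_motif_positions <- function(seqstr, pattern, iupac) {
  chars <- strsplit(seqstr, "")[[1]]
  pat <- strsplit(toupper(pattern), "")[[1]]
  out <- integer(0)
  if (length(chars) < length(pat)) return(out)
  for (s in 1:(length(chars) - length(pat) + 1)) {
    ok <- TRUE
    for (j in seq_along(pat)) {
      ch <- chars[s + j - 1]
      if (ch == "N" || !(ch %in% iupac[[pat[j]]])) { ok <- FALSE; break }
    }
    if (ok) out <- c(out, s)
  }
  out
}

IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# --- brute-force tandem filter -------------------------------------------
oracle_tandem_pairs <- function(genes, family_ids, max_intervening = 1,
                                max_dist = 100000) {
  fam <- genes[genes$gene_id %in% family_ids, ]
  out <- list()
  if (nrow(fam) >= 2) {
    for (i in 1:(nrow(fam) - 1)) {
      for (j in (i + 1):nrow(fam)) {
        if (fam$chromosome[i] != fam$chromosome[j]) next
        if (abs(fam$rank[i] - fam$rank[j]) - 1 > max_intervening) next
        if (abs(fam$start[i] - fam$start[j]) > max_dist) next
        ids <- sort(c(fam$gene_id[i], fam$gene_id[j]))
        out[[length(out) + 1]] <- paste(ids, collapse = "|")
      }
    }
  }
  as.character(sort(unlist(out)))
}

# --- pI grid-search oracle (vectorized over the pH grid) -----------------
oracle_pi_grid <- function(seq, step = 1e-4) {
  chars <- strsplit(seq, "")[[1]]
  pos_pk <- c(K = 10.0, R = 12.0, H = 5.98)
  neg_pk <- c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
  nt_by <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
             E = 7.7)
  ct_by <- c(D = 4.55, E = 4.75)
  nt <- if (chars[1] %in% names(nt_by)) nt_by[[chars[1]]] else 7.5
  ct <- if (chars[length(chars)] %in% names(ct_by))
    ct_by[[chars[length(chars)]]] else 3.55
  pos <- c(nt, unname(pos_pk[chars[chars %in% names(pos_pk)]]))
  neg <- c(ct, unname(neg_pk[chars[chars %in% names(neg_pk)]]))
  pH <- seq(0, 14, by = step)
  charge <- rep(0, length(pH))
  for (pk in pos) charge <- charge + 1 / (1 + 10^(pH - pk))
  for (pk in neg) charge <- charge - 1 / (1 + 10^(pk - pH))
  pH[which.min(abs(charge))]
}

# --- shared small bundle -------------------------------------------------
# A scaled-down family spec for unit tests (fast); the full default spec is
# exercised in the acceptance tests.
small_spec <- function(seed = 42) {
  family_spec(
    n_genes = 20,
    category_counts = c(G_BOX = 6, E_BOX_NON_G = 4, NON_E_BOX = 3,
                        NON_DNA = 7),
    n_chromosomes = 3, chr_counts = c(6, 5, 4),
    tandem_clusters = c(chr1 = 1, chr2 = 1),
    tissue_counts = c(all = 8, none = 2, fruit_only = 2, root_only = 3),
    n_expressed = 12, n_up = 3, n_down = 2,
    seed = seed
  )
}

small_bundle_cache <- new.env()
small_bundle <- function() {
  if (is.null(small_bundle_cache$b)) {
    small_bundle_cache$b <- generate_family(small_spec())
  }
  small_bundle_cache$b
}
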