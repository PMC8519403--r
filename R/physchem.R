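# ProtParam-style physicochemical panel computed from sequence alone.
# Conventions follow the ExPASy tool: average (not monoisotopic) residue
# masses, the Bjellqvist pKa set for pI, Kyte-Doolittle hydropathy for
# GRAVY, the Guruprasad DIWV table for the instability index (full 400
# entries shipped in inst/extdata with provenance), Ikai's aliphatic index,
# and charged-residue counts excluding histidine.

# Average residue masses (Da) of amino-acid residues in a peptide chain
# (i.e. amino acid minus water), ExPASy values.
AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_AVG_MASS <- 18.01524

# Kyte & Doolittle (1982) hydropathy values.
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Bjellqvist pKa set as used by ExPASy. N-terminal pKa depends on the first
# residue, and the C-terminal pKa is adjusted when the last residue is D/E.
PKA_POSITIVE <- c(K = 10.0, R = 12.0, H = 5.98)
PKA_NEGATIVE <- c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
PKA_NTERM_DEFAULT <- 7.5
PKA_NTERM_BY_RESIDUE <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82,
                          V = 7.44, E = 7.7)
PKA_CTERM_DEFAULT <- 3.55
PKA_CTERM_BY_RESIDUE <- c(D = 4.55, E = 4.75)

# DIWV dipeptide weights, loaded lazily from the shipped table.
diwv_env <- new.env(parent = emptyenv())
diwv_table <- function() {
  if (is.null(diwv_env$m)) {
    path <- system.file("extdata", "diwv_guruprasad.tsv", package = "famchar",
                        mustWork = TRUE)
    df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1])
    rownames(m) <- df$aa
    colnames(m) <- names(df)[-1]
    diwv_env$m <- m
  }
  diwv_env$m
}

check_canonical <- function(p, ignore_x = FALSE, min_length = 1) {
  s <- p[[1]]
  if (is.na(s) || nchar(s) == 0) stop("empty sequence")
  chars <- seq_chars(s)
  if (ignore_x) chars <- chars[chars != "X"]
  bad <- setdiff(unique(chars), AA_LETTERS)
  if (length(bad) > 0) {
    stop("non-canonical letter(s): ", paste(bad, collapse = ", "))
  }
  if (length(chars) < min_length) {
    stop("sequence shorter than ", min_length, " after filtering")
  }
  chars
}

#' Molecular weight (kDa)
#'
#' Sum of average residue masses plus one water, divided by 1000 --
#' ProtParam's average molecular weight.
#'
#' @param p protein sequence (string or length-1 named vector).
#' @param ignore_x drop sentinel `X` residues before computing.
#' @return weight in kDa.
#' @export
molecular_weight <- function(p, ignore_x = FALSE) {
  chars <- check_canonical(p, ignore_x)
  (sum(AA_AVG_MASS[chars]) + WATER_AVG_MASS) / 1000
}

# Net charge at a given pH vector under the Bjellqvist model; vectorized
# over pH for the grid oracle.
net_charge <- function(chars, pH) {
  first <- chars[1]
  last <- chars[length(chars)]
  nterm_pka <- unname(PKA_NTERM_BY_RESIDUE[first])
  if (is.na(nterm_pka)) nterm_pka <- PKA_NTERM_DEFAULT
  cterm_pka <- unname(PKA_CTERM_BY_RESIDUE[last])
  if (is.na(cterm_pka)) cterm_pka <- PKA_CTERM_DEFAULT

  pos_pkas <- c(nterm_pka, unname(PKA_POSITIVE[chars[chars %in% names(PKA_POSITIVE)]]))
  neg_pkas <- c(cterm_pka, unname(PKA_NEGATIVE[chars[chars %in% names(PKA_NEGATIVE)]]))

  pos <- vapply(pH, function(x) sum(1 / (1 + 10^(x - pos_pkas))), 0)
  neg <- vapply(pH, function(x) sum(1 / (1 + 10^(neg_pkas - x))), 0)
  pos - neg
}

#' Theoretical isoelectric point
#'
#' pH at which the net charge of the Bjellqvist/ExPASy charge model
#' (N-terminus, C-terminus, and the D, E, C, Y, H, K, R side chains) is
#' zero, found by bisection on \[0, 14\].
#'
#' @inheritParams molecular_weight
#' @param tol bisection tolerance in pH units (default 1e-6, well past the
#'   1e-3 reporting precision, so the net charge at the returned pI is
#'   negligible).
#' @return pI in pH units.
#' @export
isoelectric_point <- function(p, tol = 1e-6, ignore_x = FALSE) {
  chars <- check_canonical(p, ignore_x)
  lo <- 0; hi <- 14
  while (hi - lo > tol / 2) {
    mid <- (lo + hi) / 2
    if (net_charge(chars, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues; negative values mean
#' a hydrophilic protein.
#'
#' @inheritParams molecular_weight
#' @return GRAVY score.
#' @export
gravy <- function(p, ignore_x = FALSE) {
  chars <- check_canonical(p, ignore_x)
  mean(KYTE_DOOLITTLE[chars])
}

#' Instability index (Guruprasad)
#'
#' `II = (10 / L) * sum(DIWV(s[i], s[i+1]))` over adjacent residue pairs;
#' below 40 predicts a stable protein.
#'
#' @inheritParams molecular_weight
#' @return list with `instability_index` and `stability` ("stable" when
#'   II < 40, else "unstable").
#' @export
instability_index <- function(p, ignore_x = FALSE) {
  chars <- check_canonical(p, ignore_x, min_length = 2)
  w <- diwv_table()
  L <- length(chars)
  ii <- 10 / L * sum(w[cbind(chars[-L], chars[-1])])
  list(instability_index = ii,
       stability = if (ii < 40) "stable" else "unstable")
}

#' Aliphatic index (Ikai)
#'
#' `AI = X_Ala + 2.9 * X_Val + 3.9 * (X_Ile + X_Leu)` with X in mole
#' percent.
#'
#' @inheritParams molecular_weight
#' @return aliphatic index.
#' @export
aliphatic_index <- function(p, ignore_x = FALSE) {
  chars <- check_canonical(p, ignore_x)
  x <- 100 * table(factor(chars, levels = AA_LETTERS)) / length(chars)
  unname(x["A"] + 2.9 * x["V"] + 3.9 * (x["I"] + x["L"]))
}

#' Charged-residue counts
#'
#' Negative = Asp + Glu, positive = Arg + Lys; histidine is not counted,
#' per the ProtParam convention.
#'
#' @inheritParams molecular_weight
#' @return named integer vector `c(n_neg, n_pos)`.
#' @export
charged_counts <- function(p, ignore_x = FALSE) {
  s <- p[[1]]
  chars <- seq_chars(s)
  if (ignore_x) chars <- chars[chars != "X"]
  c(n_neg = sum(chars %in% c("D", "E")),
    n_pos = sum(chars %in% c("R", "K")))
}

#' Full physicochemical panel for a protein collection
#'
#' @param proteins named character vector of protein sequences.
#' @param cds optional named character vector of matching CDSs, used only
#'   to report CDS length.
#' @param ignore_x drop sentinel `X` residues before computing.
#' @return data.frame, one row per protein: id, cds_length, length_aa,
#'   mw_kda, pi, n_neg, n_pos, gravy, instability_index, stability,
#'   aliphatic_index.
#' @export
physchem_panel <- function(proteins, cds = NULL, ignore_x = FALSE) {
  rows <- lapply(names(proteins), function(id) {
    s <- proteins[[id]]
    inst <- instability_index(s, ignore_x)
    cc <- charged_counts(s, ignore_x)
    data.frame(
      id = id,
      cds_length = if (!is.null(cds) && id %in% names(cds))
        nchar(cds[[id]]) else NA_integer_,
      length_aa = nchar(s),
      mw_kda = molecular_weight(s, ignore_x),
      pi = isoelectric_point(s, ignore_x = ignore_x),
      n_neg = cc[["n_neg"]],
      n_pos = cc[["n_pos"]],
      gravy = gravy(s, ignore_x),
      instability_index = inst$instability_index,
      stability = inst$stability,
      aliphatic_index = aliphatic_index(s, ignore_x),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
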