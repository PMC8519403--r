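# IUPAC cis-element motif scanning over promoter sequences. Exact IUPAC
# matching only -- no position-weight matrices and no database lookups; the
# motif set is an editable TSV the user controls.

#' Read a motif definition TSV
#'
#' Columns: name, pattern (IUPAC nucleotide string), category, and a free
#' citation column. A default file with literature-sourced core motifs
#' (E-box CANNTG, G-box CACGTG, ABRE, ...) ships in `inst/extdata`.
#'
#' @param path TSV path; default is the packaged motif file.
#' @return data.frame of motif definitions.
#' @export
read_motifs <- function(path = system.file("extdata", "cis_motifs.tsv",
                                           package = "famchar",
                                           mustWork = TRUE)) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("name", "pattern") %in% names(df))) {
    stop("motif TSV must have columns name, pattern")
  }
  df$pattern <- toupper(df$pattern)
  for (i in seq_len(nrow(df))) {
    bad <- bad_letters(df$pattern[i], names(IUPAC_SETS))
    if (length(bad) > 0) {
      stop("illegal IUPAC code ", paste(bad, collapse = ", "),
           " in motif ", df$name[i])
    }
  }
  if (is.null(df$category)) df$category <- "other"
  df
}

# Compile an IUPAC pattern to a perl regex of character classes. N in the
# pattern matches any of ACGT but never an N in the subject, because the
# classes never contain N.
iupac_regex <- function(pattern) {
  chars <- seq_chars(toupper(pattern))
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad) > 0) {
    stop("illegal IUPAC code(s): ", paste(bad, collapse = ", "))
  }
  paste0(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 1) set else paste0("[", paste(set, collapse = ""), "]")
  }, ""), collapse = "")
}

#' Scan one promoter for IUPAC motifs
#'
#' All (possibly overlapping) match positions of each motif are reported on
#' the forward strand and, when `both_strands`, on the reverse complement.
#' Positions are 1-based on the given strand. An `N` in the promoter
#' matches nothing.
#'
#' @param promoter promoter sequence (string over ACGTN, or a length-1
#'   named vector).
#' @param motifs data.frame from [read_motifs()] (needs name, pattern).
#' @param both_strands scan the reverse complement too (default TRUE).
#' @param gene gene id for the output (defaults to the promoter's name).
#' @return data.frame: gene, motif, position, strand.
#' @export
scan_promoter <- function(promoter, motifs, both_strands = TRUE,
                          gene = names(promoter) %||% "promoter") {
  seqstr <- toupper(promoter[[1]])
  bad <- bad_letters(seqstr, c(DNA_LETTERS, "N"))
  if (length(bad) > 0) {
    stop("promoter has letters outside ACGTN: ", paste(bad, collapse = ", "))
  }
  strands <- if (both_strands) c("+", "-") else "+"
  rows <- list()
  for (i in seq_len(nrow(motifs))) {
    rx <- paste0("(?=", iupac_regex(motifs$pattern[i]), ")")
    for (strand in strands) {
      subj <- if (strand == "+") seqstr else revcomp(seqstr)
      m <- gregexpr(rx, subj, perl = TRUE)[[1]]
      pos <- as.integer(m[m > 0])
      if (length(pos) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        gene = gene, motif = motifs$name[i], position = pos,
        strand = strand, stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene = character(0), motif = character(0),
                      position = integer(0), strand = character(0)))
  }
  do.call(rbind, rows)
}

#' Scan a promoter collection and tabulate per-gene counts
#'
#' @param promoters named character vector of promoter sequences.
#' @inheritParams scan_promoter
#' @return list with `hits` (long data.frame) and `counts` (genes x motifs
#'   integer matrix).
#' @export
scan_promoters <- function(promoters, motifs, both_strands = TRUE) {
  hits <- do.call(rbind, c(lapply(names(promoters), function(g) {
    scan_promoter(promoters[[g]], motifs, both_strands, gene = g)
  }), list(make.row.names = FALSE)))
  counts <- matrix(0L, nrow = length(promoters), ncol = nrow(motifs),
                   dimnames = list(names(promoters), motifs$name))
  if (nrow(hits) > 0) {
    tab <- table(factor(hits$gene, levels = names(promoters)),
                 factor(hits$motif, levels = motifs$name))
    counts[] <- as.integer(tab)
  }
  list(hits = hits, counts = counts)
}
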