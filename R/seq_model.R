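# Core records and readers/writers: protein/CDS FASTA, gene-model tables.
#
# Collections of sequences are represented as named character vectors
# (names = record ids, values = upper-case sequences); gene models as a
# data.frame with one row per gene. Coordinates are 1-based inclusive
# (GFF3 convention) throughout the package.

PROTEIN_AMBIGUITY <- c("X", "B", "Z", "J", "U", "O")
DNA_AMBIGUITY <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

#' Read a FASTA file of protein or coding sequences
#'
#' Sequences are upper-cased and validated against the canonical alphabet
#' (20 amino acids, or ACGT for `type = "cds"`). Duplicate ids are an error.
#' Ambiguity codes (X, B, Z, ... / N, R, Y, ...) are rejected by default;
#' with `permissive = TRUE` they are mapped to the sentinel letter `X`
#' (protein) or `N` (CDS), which downstream scores must exclude explicitly.
#'
#' @param path path to a FASTA file.
#' @param type `"protein"` or `"cds"`.
#' @param permissive map ambiguity codes to a sentinel instead of erroring.
#' @return named character vector of sequences (names are record ids).
#' @export
read_fasta <- function(path, type = c("protein", "cds"), permissive = FALSE) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids

  alphabet <- if (type == "protein") AA_LETTERS else DNA_LETTERS
  ambiguity <- if (type == "protein") PROTEIN_AMBIGUITY else DNA_AMBIGUITY
  sentinel <- if (type == "protein") "X" else "N"
  for (i in seq_along(seqs)) {
    if (nchar(seqs[[i]]) == 0) stop("empty sequence for id ", ids[i])
    bad <- bad_letters(seqs[[i]], alphabet)
    if (length(bad) == 0) next
    if (permissive && all(bad %in% ambiguity)) {
      chars <- seq_chars(seqs[[i]])
      chars[chars %in% ambiguity] <- sentinel
      seqs[[i]] <- paste(chars, collapse = "")
    } else {
      stop("illegal character(s) ", paste(bad, collapse = ", "),
           " in record '", ids[i], "' (near line ",
           fasta_record_line(path, ids[i]), ")")
    }
  }
  seqs
}

# Line number of the header of a record, for error messages.
fasta_record_line <- function(path, id) {
  lines <- readLines(path, warn = FALSE)
  hit <- grep(paste0("^>", id, "(\\s|$)"), lines)
  if (length(hit) == 0) NA_integer_ else hit[1]
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(length(seqs) > 0, !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read gene models from GFF3 or a simple TSV table
#'
#' GFF3 input (`.gff`/`.gff3`, parsed with rtracklayer) keeps `gene`
#' features; TSV input needs columns gene_id, chromosome, start, end and an
#' optional strand. Coordinates are 1-based inclusive. A per-chromosome
#' `rank` (ordinal position by ascending start) is assigned on read.
#'
#' @param path path to a GFF3 or TSV file.
#' @return data.frame with columns gene_id, chromosome, start, end, strand,
#'   rank. Strand is carried as metadata; no computation here uses it.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("reading GFF3 requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "gene"]
    gdf <- as.data.frame(gr)
    id <- gdf$ID
    if (is.null(id)) id <- gdf$Name
    df <- data.frame(
      gene_id = as.character(id),
      chromosome = as.character(gdf$seqnames),
      start = gdf$start,
      end = gdf$end,
      strand = as.character(gdf$strand),
      stringsAsFactors = FALSE
    )
    df$strand[!df$strand %in% c("+", "-")] <- "+"
  } else {
    df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                     comment.char = "#")
    need <- c("gene_id", "chromosome", "start", "end")
    if (!all(need %in% names(df))) {
      stop("TSV gene table must have columns: ", paste(need, collapse = ", "))
    }
    if (is.null(df$strand)) df$strand <- "+"
    df <- df[, c("gene_id", "chromosome", "start", "end", "strand")]
  }
  validate_gene_models(df)
}

# Validate coordinates/ids and (re)assign per-chromosome ranks.
validate_gene_models <- function(df) {
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- which(is.na(df$start) | is.na(df$end))
  if (length(bad) > 0) stop("unparseable coordinates at row ", bad[1])
  bad <- which(df$start > df$end)
  if (length(bad) > 0) {
    stop("start > end at row ", bad[1], " (gene ", df$gene_id[bad[1]], ")")
  }
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id: ", df$gene_id[duplicated(df$gene_id)][1])
  }
  df <- df[order(df$chromosome, df$start, df$gene_id), , drop = FALSE]
  df$rank <- stats::ave(df$start, df$chromosome,
                        FUN = function(x) seq_along(x))
  df$rank <- as.integer(df$rank)
  rownames(df) <- NULL
  df
}

#' Write gene models as TSV
#'
#' @param genes gene-model data.frame (as from [read_gene_models()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  write.table(genes[, c("gene_id", "chromosome", "start", "end", "strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a coding sequence collection
#'
#' Checks length divisibility by 3, length >= 3, and absence of internal
#' stop codons (a final stop codon is allowed and commonly present).
#'
#' @param cds named character vector of CDS strings.
#' @return `cds`, invisibly, or an error naming the offending gene.
#' @export
validate_cds <- function(cds) {
  for (i in seq_along(cds)) {
    s <- cds[[i]]
    id <- names(cds)[i]
    if (nchar(s) < 3 || nchar(s) %% 3 != 0) {
      stop("CDS length of ", id, " is not a positive multiple of 3")
    }
    aa <- translate_cds(s)
    internal <- substr(aa, 1, nchar(aa) - 1)
    if (grepl("*", internal, fixed = TRUE)) {
      stop("internal stop codon in CDS of ", id)
    }
  }
  invisible(cds)
}
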