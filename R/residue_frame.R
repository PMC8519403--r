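# The 61-position bHLH reference frame: basic region, helix 1, loop,
# helix 2. Extracted domain hits are fitted onto this frame (length
# differences absorbed inside the loop, whose length is the variable part
# of the domain), and per-position consensus conservation is computed on
# the framed columns.

#' The 61-position domain reference frame
#'
#' Four contiguous regions covering positions 1..61: basic 1-17, helix1
#' 18-31, loop 32-45, helix2 46-61. The boundaries place every canonical
#' landmark residue in its named region (e.g. His-8...Arg-16 basic,
#' Ile-19...Pro-31 helix 1, Lys-44/Asp-45 loop, Ala-48...Leu-61 helix 2)
#' and are overridable because no published coordinate table fixes them.
#'
#' @param length frame length (default 61).
#' @param regions data.frame with columns name, start, end; must tile
#'   1..length exactly with names basic, helix1, loop, helix2.
#' @return object of class `reference_frame`.
#' @export
reference_frame <- function(length = 61,
                            regions = data.frame(
                              name = c("basic", "helix1", "loop", "helix2"),
                              start = c(1, 18, 32, 46),
                              end = c(17, 31, 45, 61)
                            )) {
  stopifnot(identical(sort(regions$name),
                      sort(c("basic", "helix1", "loop", "helix2"))))
  regions <- regions[order(regions$start), ]
  if (regions$start[1] != 1 || regions$end[nrow(regions)] != length ||
      any(regions$start[-1] != regions$end[-nrow(regions)] + 1)) {
    stop("regions must tile 1..length contiguously")
  }
  structure(list(length = length, regions = regions),
            class = "reference_frame")
}

# Region name of each frame position, as a character vector of length
# frame$length.
frame_region_of <- function(frame) {
  out <- character(frame$length)
  for (i in seq_len(nrow(frame$regions))) {
    r <- frame$regions[i, ]
    out[r$start:r$end] <- r$name
  }
  out
}

# Positions of a named region.
frame_region_positions <- function(frame, name) {
  r <- frame$regions[frame$regions$name == name, ]
  if (nrow(r) != 1) stop("no region named ", name)
  r$start:r$end
}

#' Fit a domain hit onto the reference frame
#'
#' Residues outside the loop map position-to-position; a length mismatch
#' (within `loop_slack`) is absorbed inside the loop, either as gap
#' characters (shorter hits) or by dropping loop residues (longer hits).
#' Among all order-preserving placements of the loop residues, the one with
#' the highest summed anchor-profile score over its loop columns is chosen
#' (first in lexicographic order on ties), so the fit is exhaustive and
#' oracle-checkable rather than heuristic.
#'
#' @param hit a 1-row hit data.frame (from [scan_protein()]) or a plain
#'   domain sequence string.
#' @param frame a [reference_frame()].
#' @param anchor_profile a [build_pssm()] PSSM of width `frame$length` used
#'   to score loop placements.
#' @param loop_slack maximum allowed |length - frame length| (default 6).
#' @param id protein id when `hit` is a bare string.
#' @return character vector of length `frame$length` over the amino-acid
#'   letters plus `"-"`, with attribute `protein_id`.
#' @export
align_to_frame <- function(hit, frame = reference_frame(),
                           anchor_profile = NULL, loop_slack = 6,
                           id = NULL) {
  if (is.data.frame(hit)) {
    seqstr <- hit$domain_sequence[1]
    id <- id %||% hit$protein_id[1]
  } else {
    seqstr <- hit[[1]]
    id <- id %||% names(hit) %||% "domain"
  }
  chars <- seq_chars(seqstr)
  hl <- length(chars)
  fl <- frame$length
  d <- hl - fl
  if (abs(d) > loop_slack) {
    stop("hit length ", hl, " outside the allowed loop slack (frame ",
         fl, " +/- ", loop_slack, ")")
  }
  loop <- frame_region_positions(frame, "loop")
  n_loop <- length(loop)
  pre <- seq_len(min(loop) - 1)           # frame positions before the loop
  post <- seq(max(loop) + 1, fl)          # frame positions after the loop

  out <- character(fl)
  out[pre] <- chars[pre]
  out[post] <- chars[(hl - length(post) + 1):hl]
  mid <- chars[setdiff(seq_len(hl), c(pre, (hl - length(post) + 1):hl))]
  m <- length(mid)                        # loop residues available

  if (d == 0) {
    out[loop] <- mid
  } else if (d < 0) {
    # place the m residues into n_loop columns; gaps fill the rest
    if (is.null(anchor_profile)) stop("anchor_profile needed for gapped fit")
    placements <- combn(n_loop, m)
    sc <- score_loop_placements(anchor_profile, loop, mid, placements)
    pick <- placements[, which.max(sc)]
    out[loop] <- "-"
    out[loop[pick]] <- mid
  } else {
    # keep n_loop of the m residues, in order; the rest are trimmed
    if (is.null(anchor_profile)) stop("anchor_profile needed for trimmed fit")
    keeps <- combn(m, n_loop)
    sc <- apply(keeps, 2, function(k) {
      sum(anchor_profile$scores[cbind(match(mid[k], AA_LETTERS), loop)])
    })
    pick <- keeps[, which.max(sc)]
    out[loop] <- mid[pick]
  }
  attr(out, "protein_id") <- id
  out
}

# Score each column-choice placement: residues `mid` go to loop columns
# loop[placements[, j]] in order.
score_loop_placements <- function(pssm, loop, mid, placements) {
  ri <- match(mid, AA_LETTERS)
  apply(placements, 2, function(cols) {
    sum(pssm$scores[cbind(ri, loop[cols])])
  })
}

#' Fit many hits onto the frame
#'
#' @param hits hit data.frame (one row per domain).
#' @inheritParams align_to_frame
#' @return character matrix, one row per domain (rownames = protein ids),
#'   `frame$length` columns.
#' @export
align_domains <- function(hits, frame = reference_frame(),
                          anchor_profile = NULL, loop_slack = 6) {
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    align_to_frame(hits[i, ], frame, anchor_profile, loop_slack)
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- hits$protein_id
  colnames(mat) <- seq_len(frame$length)
  mat
}

#' Per-position consensus profile of framed domains
#'
#' For each frame position: the modal residue over non-gap entries (ties
#' broken alphabetically) and the consensus ratio, i.e. the fraction of
#' non-gap sequences carrying the modal residue.
#'
#' @param domains character matrix from [align_domains()] (rows = domains).
#' @param frame the [reference_frame()] the domains live in.
#' @return data.frame: position, region, modal, ratio, n_nongap,
#'   n_sequences.
#' @export
consensus <- function(domains, frame = reference_frame()) {
  if (is.null(dim(domains))) domains <- matrix(domains, nrow = 1)
  if (nrow(domains) == 0) stop("empty domain collection")
  region <- frame_region_of(frame)
  out <- lapply(seq_len(ncol(domains)), function(p) {
    col <- domains[, p]
    col <- col[col != "-"]
    if (length(col) == 0) {
      return(data.frame(position = p, region = region[p], modal = NA,
                        ratio = NA_real_, n_nongap = 0L,
                        n_sequences = nrow(domains)))
    }
    tab <- table(factor(col, levels = AA_LETTERS))
    modal <- AA_LETTERS[which.max(tab)]   # which.max: first max, i.e.
    data.frame(position = p, region = region[p], modal = modal,
               ratio = as.numeric(max(tab)) / length(col),
               n_nongap = length(col), n_sequences = nrow(domains))
  })
  do.call(rbind, out)
}

#' Conservation calls from a consensus profile
#'
#' Strict thresholds, following the ">50% / >90% consensus ratio"
#' convention: `highly_conserved` when ratio > `highly_threshold`,
#' `conserved` when ratio > `conserved_threshold`, else `none`. A ratio of
#' exactly 0.5 is therefore *not* conserved.
#'
#' @param profile data.frame from [consensus()].
#' @param conserved_threshold default 0.5.
#' @param highly_threshold default 0.9.
#' @return `profile` with an added `label` column.
#' @export
conserved_calls <- function(profile, conserved_threshold = 0.5,
                            highly_threshold = 0.9) {
  if (!(conserved_threshold > 0 && conserved_threshold < highly_threshold &&
        highly_threshold <= 1)) {
    stop("need 0 < conserved_threshold < highly_threshold <= 1")
  }
  label <- rep("none", nrow(profile))
  label[!is.na(profile$ratio) & profile$ratio > conserved_threshold] <- "conserved"
  label[!is.na(profile$ratio) & profile$ratio > highly_threshold] <- "highly_conserved"
  profile$label <- label
  profile
}

#' Write framed domains as aligned FASTA (61 columns)
#'
#' @param domains character matrix from [align_domains()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_aligned_domains <- function(domains, path) {
  seqs <- apply(domains, 1, paste, collapse = "")
  write_fasta(seqs, path)
}
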