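# Residue-rule DNA-binding classification of framed bHLH domains.
#
# The decision tree mirrors the classical basic-region criteria: fewer than
# six basic residues (Arg/Lys/His) in the basic region means no DNA
# binding; Glu-12 plus Arg-15 license E-box binding; His/Lys-8, Glu-12 and
# Arg-16 together license the G-box subtype. Positions are in the package's
# 61-position frame (the equivalent Arabidopsis-frame numbers are offset by
# one and are not separately encoded).

BINDING_CATEGORIES <- c("G_BOX", "E_BOX_NON_G", "NON_E_BOX", "NON_DNA")

#' DNA-binding rule configuration
#'
#' @param basic_region region name whose residue content is counted
#'   (default `"basic"`).
#' @param basic_letters residues counted as basic (default Arg, Lys, His;
#'   the literature never enumerates the set, so it is overridable).
#' @param min_basic_count minimum basic-residue count for DNA binding
#'   (default 6, i.e. "less than six" residues means non-DNA-binding).
#' @param ebox_required named list: frame position -> allowed residue set
#'   for E-box binding (default Glu at 12, Arg at 15).
#' @param gbox_required named list for the G-box subtype (default His or
#'   Lys at 8, Glu at 12, Arg at 16).
#' @return object of class `rule_config`.
#' @export
rule_config <- function(basic_region = "basic",
                        basic_letters = c("R", "K", "H"),
                        min_basic_count = 6,
                        ebox_required = list(`12` = "E", `15` = "R"),
                        gbox_required = list(`8` = c("H", "K"), `12` = "E",
                                             `16` = "R")) {
  stopifnot(min_basic_count >= 1)
  structure(list(basic_region = basic_region, basic_letters = basic_letters,
                 min_basic_count = min_basic_count,
                 ebox_required = ebox_required,
                 gbox_required = gbox_required),
            class = "rule_config")
}

# Do all rule positions carry an allowed residue? A gap at a rule position
# fails that rule (an absent residue cannot contact DNA).
rules_pass <- function(residues, required) {
  for (pos in names(required)) {
    p <- as.integer(pos)
    if (p < 1 || p > length(residues)) stop("rule position ", p,
                                            " outside the frame")
    if (!(residues[p] %in% required[[pos]])) return(FALSE)
  }
  TRUE
}

#' Classify one framed domain into the DNA-binding taxonomy
#'
#' Decision tree: (1) count basic-region residues in `basic_letters` (gaps
#' count 0); below `min_basic_count` the domain is `NON_DNA`. (2) Otherwise
#' a failed E-box rule position gives `NON_E_BOX`. (3) Otherwise all G-box
#' positions passing gives `G_BOX`, (4) else `E_BOX_NON_G`.
#'
#' @param domain character vector of frame length (from
#'   [align_to_frame()]), or one row of an [align_domains()] matrix.
#' @param rules a [rule_config()].
#' @param frame the [reference_frame()] the rules refer to.
#' @return one of `"G_BOX"`, `"E_BOX_NON_G"`, `"NON_E_BOX"`, `"NON_DNA"`.
#' @export
classify_binding <- function(domain, rules = rule_config(),
                             frame = reference_frame()) {
  residues <- as.character(domain)
  if (length(residues) != frame$length) {
    stop("domain length ", length(residues), " does not match the frame")
  }
  basic_pos <- frame_region_positions(frame, rules$basic_region)
  n_basic <- sum(residues[basic_pos] %in% rules$basic_letters)
  if (n_basic < rules$min_basic_count) return("NON_DNA")
  if (!rules_pass(residues, rules$ebox_required)) return("NON_E_BOX")
  if (rules_pass(residues, rules$gbox_required)) return("G_BOX")
  "E_BOX_NON_G"
}

#' Classify a matrix of framed domains
#'
#' @param domains character matrix from [align_domains()].
#' @inheritParams classify_binding
#' @return data.frame: protein_id, basic_count, ebox_pass, gbox_pass,
#'   category.
#' @export
classify_domains <- function(domains, rules = rule_config(),
                             frame = reference_frame()) {
  basic_pos <- frame_region_positions(frame, rules$basic_region)
  out <- lapply(seq_len(nrow(domains)), function(i) {
    res <- domains[i, ]
    data.frame(
      protein_id = rownames(domains)[i] %||% paste0("domain", i),
      basic_count = sum(res[basic_pos] %in% rules$basic_letters),
      ebox_pass = rules_pass(res, rules$ebox_required),
      gbox_pass = rules_pass(res, rules$gbox_required),
      category = classify_binding(res, rules, frame),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Category counts and printed-table percentages
#'
#' Percentages are `100 * count / n`, rounded half-away-from-zero to two
#' decimals, plus a DNA-binding total row (all categories except
#' `NON_DNA`).
#'
#' @param labels character vector of categories (values in
#'   `BINDING_CATEGORIES`), or a named numeric vector of per-category
#'   counts.
#' @return data.frame: category, count, percent; categories ordered
#'   G_BOX, E_BOX_NON_G, NON_E_BOX, DNA_BINDING_TOTAL, NON_DNA.
#' @export
summarize_categories <- function(labels) {
  if (is.numeric(labels)) {
    counts <- labels[BINDING_CATEGORIES]
    counts[is.na(counts)] <- 0
    names(counts) <- BINDING_CATEGORIES
  } else {
    if (length(labels) == 0) stop("empty label collection")
    bad <- setdiff(unique(labels), BINDING_CATEGORIES)
    if (length(bad) > 0) stop("unknown category: ", paste(bad, collapse = ", "))
    counts <- table(factor(labels, levels = BINDING_CATEGORIES))
    counts <- setNames(as.numeric(counts), BINDING_CATEGORIES)
  }
  n <- sum(counts)
  if (n == 0) stop("no labels to summarize")
  dna_total <- sum(counts[c("G_BOX", "E_BOX_NON_G", "NON_E_BOX")])
  out <- data.frame(
    category = c("G_BOX", "E_BOX_NON_G", "NON_E_BOX", "DNA_BINDING_TOTAL",
                 "NON_DNA"),
    count = unname(c(counts["G_BOX"], counts["E_BOX_NON_G"],
                     counts["NON_E_BOX"], dna_total, counts["NON_DNA"])),
    stringsAsFactors = FALSE
  )
  out$percent <- proportion_percent(out$count, n)
  attr(out, "n_total") <- n
  rownames(out) <- NULL
  out
}
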