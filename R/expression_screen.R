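# FPKM expression screening: effective-expression filtering (FPKM > 1),
# tissue-specificity tabulation, fold-change candidate screening against a
# control condition, hierarchical profile clustering, and 2^-ddCt qPCR
# relative expression.

#' Read an FPKM matrix from TSV
#'
#' Genes in rows (first column = gene id), conditions in the header row.
#'
#' @param path TSV path.
#' @return numeric matrix, rownames = genes, colnames = conditions.
#' @export
read_fpkm <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  validate_fpkm(m)
}

validate_fpkm <- function(m) {
  if (any(is.na(m))) stop("FPKM matrix has missing values")
  if (any(m < 0)) stop("FPKM values must be non-negative")
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(m))) stop("duplicate condition ids")
  m
}

#' Write an FPKM matrix as TSV
#'
#' @param m numeric matrix (genes x conditions).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fpkm <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Effective-expression filter
#'
#' An entry is effectively expressed when FPKM is strictly greater than
#' the threshold; FPKM exactly 1.0 is *not* expressed under the default.
#'
#' @param m FPKM matrix.
#' @param threshold default 1.0.
#' @return logical matrix of the same shape.
#' @export
effective_expression <- function(m, threshold = 1.0) {
  stopifnot(threshold >= 0)
  m > threshold
}

#' Tissue-specificity categories
#'
#' Per gene, from the number of tissues passing [effective_expression()]:
#' `"all_tissues"`, `"none"`, `"single:<tissue>"`, or `"<k>_of_<n>"`.
#'
#' @param m FPKM matrix over tissue conditions (>= 2 tissues).
#' @param threshold effective-expression threshold.
#' @return named character vector, one category per gene.
#' @export
tissue_specificity <- function(m, threshold = 1.0) {
  if (ncol(m) < 2) stop("need >= 2 tissues")
  expr <- effective_expression(m, threshold)
  k <- rowSums(expr)
  n <- ncol(m)
  out <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    out[i] <- if (k[i] == 0) "none"
    else if (k[i] == n) "all_tissues"
    else if (k[i] == 1) paste0("single:", colnames(m)[which(expr[i, ])])
    else paste0(k[i], "_of_", n)
  }
  names(out) <- rownames(m)
  out
}

#' Fold-change candidate screen against a control condition
#'
#' Per gene and non-control condition, `FC = (FPKM + pseudo) /
#' (FPKM_control + pseudo)`. A gene is selected up if any FC >= `min_fc`,
#' down if any 1/FC >= `min_fc`; direction goes to the larger deviation.
#' `within_band` flags whether the best fold change lies inside
#' \[`min_fc`, `max_fc`\] (the 2-5x band is annotated, not used to
#' exclude). Selected genes must also pass [effective_expression()] in the
#' control or in a passing condition.
#'
#' @param m FPKM matrix with the control among its columns.
#' @param control_condition column name of the untreated control.
#' @param min_fc minimum fold change (default 2).
#' @param max_fc upper edge of the annotated band (default 5).
#' @param pseudo pseudocount added to numerator and denominator
#'   (default 0.1 FPKM; zero FPKM is common and the ratio must stay
#'   finite).
#' @param threshold effective-expression threshold (default 1).
#' @return data.frame: gene, direction ("up"/"down"),
#'   max_abs_fold_change, conditions_passing (comma-joined), within_band.
#' @export
fold_change_screen <- function(m, control_condition, min_fc = 2.0,
                               max_fc = 5.0, pseudo = 0.1, threshold = 1.0) {
  if (!control_condition %in% colnames(m)) {
    stop("control condition '", control_condition, "' absent")
  }
  stopifnot(pseudo > 0, min_fc >= 1)
  treat <- setdiff(colnames(m), control_condition)
  expr <- effective_expression(m, threshold)
  rows <- list()
  for (g in rownames(m)) {
    fc <- (m[g, treat] + pseudo) / (m[g, control_condition] + pseudo)
    up_pass <- names(fc)[fc >= min_fc]
    down_pass <- names(fc)[1 / fc >= min_fc]
    if (length(up_pass) == 0 && length(down_pass) == 0) next
    up_mag <- if (length(up_pass) > 0) max(fc[up_pass]) else -Inf
    down_mag <- if (length(down_pass) > 0) max(1 / fc[down_pass]) else -Inf
    direction <- if (up_mag >= down_mag) "up" else "down"
    passing <- if (direction == "up") up_pass else down_pass
    mag <- max(up_mag, down_mag)
    involved <- c(control_condition, passing)
    if (!any(expr[g, involved])) next
    rows[[length(rows) + 1]] <- data.frame(
      gene = g, direction = direction, max_abs_fold_change = mag,
      conditions_passing = paste(passing, collapse = ","),
      within_band = mag <= max_fc,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    return(data.frame(gene = character(0), direction = character(0),
                      max_abs_fold_change = numeric(0),
                      conditions_passing = character(0),
                      within_band = logical(0)))
  }
  do.call(rbind, rows)
}

#' Hierarchical clustering of expression profiles
#'
#' Average-linkage agglomerative clustering on distance `1 - Pearson
#' correlation` of `log2(FPKM + pseudo)` profiles, cut to `k` groups --
#' the procedure behind the usual expression heat-map row dendrogram.
#' Genes with a constant profile (undefined correlation) fall back to a
#' per-condition RMS Euclidean distance on the log scale, with a message.
#'
#' @param m FPKM matrix.
#' @param k number of groups (default 4).
#' @param pseudo log pseudocount (default 0.1).
#' @return named integer vector of group ids (1..k).
#' @export
cluster_profiles <- function(m, k = 4, pseudo = 0.1) {
  stopifnot(k >= 2, nrow(m) >= k)
  lm <- log2(m + pseudo)
  cc <- suppressWarnings(stats::cor(t(lm)))
  d <- 1 - cc
  if (any(is.na(d))) {
    message("constant profile(s) present; using Euclidean fallback for ",
            "their distances")
    eu <- as.matrix(stats::dist(lm)) / sqrt(ncol(lm))
    d[is.na(d)] <- eu[is.na(d)]
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  stats::cutree(hc, k = k)
}

#' qPCR relative expression by 2^-ddCt
#'
#' `dCt = Ct_target - Ct_reference` per measurement; `ddCt = dCt_sample -
#' dCt_control`; fold = `2^-ddCt`. The reference gene is typically a
#' housekeeping control such as PP2A.
#'
#' @param sample,control lists or 1-row data.frames with fields `gene`,
#'   `ct_target`, `ct_reference` (Ct values in cycles, inside (0, 50)).
#' @return relative expression fold.
#' @export
relative_expression <- function(sample, control) {
  get <- function(x, f) {
    v <- x[[f]]
    if (is.null(v)) stop("missing field ", f)
    v
  }
  if (get(sample, "gene") != get(control, "gene")) {
    stop("sample and control measure different genes")
  }
  cts <- c(get(sample, "ct_target"), get(sample, "ct_reference"),
           get(control, "ct_target"), get(control, "ct_reference"))
  if (any(cts <= 0 | cts >= 50)) stop("Ct values must lie in (0, 50)")
  d_sample <- cts[1] - cts[2]
  d_control <- cts[3] - cts[4]
  2^(-(d_sample - d_control))
}

#' Aggregate replicate Ct values and compute relative expression
#'
#' Technical/biological replicates are averaged (mean Ct, with SD carried
#' for error bars) before the ddCt computation; at least `min_reps`
#' replicates per (gene, condition) are required.
#'
#' @param ct_table data.frame with columns gene, condition, ct_target,
#'   ct_reference (one row per replicate).
#' @param control_condition name of the control condition.
#' @param min_reps minimum replicates (default 3).
#' @return data.frame: gene, condition, fold, dct_sd.
#' @export
relative_expression_table <- function(ct_table, control_condition,
                                      min_reps = 3) {
  need <- c("gene", "condition", "ct_target", "ct_reference")
  if (!all(need %in% names(ct_table))) {
    stop("ct table must have columns: ", paste(need, collapse = ", "))
  }
  rows <- list()
  for (g in unique(ct_table$gene)) {
    sub <- ct_table[ct_table$gene == g, ]
    ctrl <- sub[sub$condition == control_condition, ]
    if (nrow(ctrl) < min_reps) {
      stop("gene ", g, " has fewer than ", min_reps,
           " control replicates")
    }
    ctrl_m <- list(gene = g, ct_target = mean(ctrl$ct_target),
                   ct_reference = mean(ctrl$ct_reference))
    for (cond in setdiff(unique(sub$condition), control_condition)) {
      s <- sub[sub$condition == cond, ]
      if (nrow(s) < min_reps) {
        stop("gene ", g, ", condition ", cond, ": fewer than ",
             min_reps, " replicates")
      }
      samp <- list(gene = g, ct_target = mean(s$ct_target),
                   ct_reference = mean(s$ct_reference))
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, condition = cond,
        fold = relative_expression(samp, ctrl_m),
        dct_sd = stats::sd(s$ct_target - s$ct_reference),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
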