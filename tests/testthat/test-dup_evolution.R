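# Tandem detection, codon alignment, NG86 Ka/Ks, dating.

tiny_map <- function() {
  validate_gene_models(data.frame(
    gene_id = c("a", "b", "c", "d", "x1"),
    chromosome = c("chr1", "chr1", "chr1", "chr2", "chr1"),
    start = c(1000, 21000, 3.2e6, 5000, 11000),
    end = c(2000, 22000, 3.201e6, 6000, 12000),
    strand = "+"
  ))
}

test_that("tandem rules: adjacency and distance both bind", {
  g <- tiny_map()
  # a and b are 20 kb apart with one intervening non-family gene (x1)
  pairs <- find_tandem_pairs(g, c("a", "b", "c", "d"))
  expect_equal(nrow(pairs), 1L)
  expect_identical(c(pairs$gene_a, pairs$gene_b), c("a", "b"))
  expect_equal(pairs$intervening_genes, 1L)
  # c is 3.2 Mb away: excluded by distance even on the same chromosome
  strict <- find_tandem_pairs(g, c("a", "b"),
                              tandem_criteria(max_intervening_genes = 0))
  expect_equal(nrow(strict), 0L)   # x1 intervenes
  expect_error(find_tandem_pairs(g, c("a", "zz")), "absent.*zz")
})

test_that("tandem detection equals the brute-force all-pairs filter", {
  set.seed(53)
  for (rep in 1:15) {
    n <- sample(8:25, 1)
    g <- validate_gene_models(data.frame(
      gene_id = paste0("g", 1:n),
      chromosome = sample(paste0("chr", 1:3), n, replace = TRUE),
      start = sample.int(5e5, n), end = 0, strand = "+"
    ) |> transform(end = start + 1000))
    fam <- sample(g$gene_id, max(2, n %/% 2))
    got <- find_tandem_pairs(g, fam)
    expect_identical(sort(paste(got$gene_a, got$gene_b, sep = "|")),
                     oracle_tandem_pairs(g, fam))
  }
})

test_that("planted tandem clusters are recovered exactly", {
  b <- small_bundle()
  pairs <- find_tandem_pairs(b$genes, names(b$proteins))
  expect_identical(pairs[, c("gene_a", "gene_b")],
                   b$truth$tandem_pairs[, c("gene_a", "gene_b")])
})

test_that("codon alignment expands protein columns to codons", {
  cds <- c(a = "ATGAAACCC", b = "ATGCCC")
  aln <- c("MKP", "M-P")
  cod <- codon_align(cds["a"], cds["b"], aln)
  expect_identical(cod, c("ATGAAACCC", "ATG---CCC"))
  # identity case
  cod2 <- codon_align(cds["a"], cds["a"], c("MKP", "MKP"))
  expect_identical(cod2[1], cod2[2])
  # terminal stop codons are tolerated and dropped
  cod3 <- codon_align(c(a = "ATGAAACCCTAA"), cds["b"], aln)
  expect_identical(cod3[1], "ATGAAACCC")
  expect_error(codon_align(cds["a"], cds["b"], c("MKP", "MAP")),
               "mismatch.*2")
})

test_that("NG86 basics: identity, single synonymous difference", {
  ng <- nei_gojobori(c("ATGAAACCC", "ATGAAACCC"))
  expect_equal(ng$ka, 0)
  expect_equal(ng$ks, 0)
  # TTT vs TTC: one synonymous difference
  ng2 <- nei_gojobori(c("TTT", "TTC"))
  expect_equal(ng2$sd, 1)
  expect_equal(ng2$nd, 0)
  expect_equal(ng2$s_sites, 1 / 3)
  expect_equal(ng2$ps, 1 / ng2$s_sites)
  expect_true(is.na(ng2$ks))     # saturated: Jukes-Cantor undefined
  expect_error(nei_gojobori(c("---", "---")), "no comparable")
})

test_that("NG86 is symmetric and skips gap columns", {
  set.seed(59)
  ep <- evolve_codon_pair(40, t_sub = 0.3, omega = 0.5, seed = 7)
  ab <- nei_gojobori(c(ep$cds_a, ep$cds_b))
  ba <- nei_gojobori(c(ep$cds_b, ep$cds_a))
  expect_equal(ab[c("ka", "ks", "nd", "sd", "n_sites", "s_sites")],
               ba[c("ka", "ks", "nd", "sd", "n_sites", "s_sites")])
  gapped <- c(paste0("---", ep$cds_a), paste0("---", ep$cds_b))
  expect_equal(nei_gojobori(gapped)$n_codons, ab$n_codons)
})

test_that("site and difference counts match enumeration oracles", {
  set.seed(61)
  # sites: every sense codon
  sites <- famchar:::codon_site_table()
  for (codon in sample(SENSE_CODONS, 20)) {
    o <- oracle_codon_sites(codon)
    expect_equal(unname(sites[codon, "S"]), unname(o["S"]), tolerance = 1e-12)
    expect_equal(unname(sites[codon, "N"]), unname(o["N"]), tolerance = 1e-12)
    # stop-excluded fraction: S + N <= 3
    expect_lte(sites[codon, "S"] + sites[codon, "N"], 3 + 1e-12)
  }
  # differences: random sense-codon pairs, including 2- and 3-base diffs
  for (i in 1:60) {
    a <- sample(SENSE_CODONS, 1); b <- sample(SENSE_CODONS, 1)
    got <- famchar:::codon_diff_counts(a, b)
    want <- oracle_codon_diffs(a, b)
    expect_equal(unname(got["S"]), unname(want["S"]), tolerance = 1e-12)
    expect_equal(unname(got["N"]), unname(want["N"]), tolerance = 1e-12)
  }
})

test_that("selection labels follow the neutral band", {
  expect_identical(selection_label(0.270), "purifying")
  expect_identical(selection_label(0.949), "purifying")
  expect_identical(selection_label(1.0), "neutral")
  expect_identical(selection_label(1.3), "positive")
  expect_identical(selection_label(NA_real_), "undetermined")
})

test_that("divergence dating: closed form, linearity, rate scaling", {
  expect_equal(divergence_time(0.03), 1.0)
  expect_equal(divergence_time(0), 0)
  expect_equal(divergence_time(1.92), 64.0)
  ks <- runif(5)
  expect_equal(divergence_time(2 * ks), 2 * divergence_time(ks))
  expect_equal(divergence_time(ks, 3e-8), divergence_time(ks) / 2)
  expect_error(divergence_time(-0.1), "negative")
})

test_that("the pair table runs end-to-end on planted tandem pairs", {
  b <- small_bundle()
  pairs <- b$truth$tandem_pairs
  tab <- duplicate_pair_table(pairs, b$cds)
  expect_equal(nrow(tab), nrow(pairs))
  # independently generated genes are far diverged; labels are defined
  expect_true(all(tab$selection_label %in%
                    c("purifying", "neutral", "positive", "undetermined")))
  defined <- !is.na(tab$ks)
  expect_equal(tab$divergence_time_mya[defined],
               tab$ks[defined] / 0.03)
})
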