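# Synthetic-data generator: determinism, planted truth, validators.

test_that("generation is deterministic under a fixed seed", {
  b1 <- generate_family(small_spec(seed = 99))
  b2 <- generate_family(small_spec(seed = 99))
  expect_identical(b1$proteins, b2$proteins)
  expect_identical(b1$cds, b2$cds)
  expect_identical(b1$genes, b2$genes)
  expect_identical(b1$fpkm_treatment, b2$fpkm_treatment)
  expect_identical(b1$promoters, b2$promoters)
  expect_identical(b1$truth, b2$truth)
  b3 <- generate_family(small_spec(seed = 100))
  expect_false(identical(b1$proteins, b3$proteins))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  x1 <- runif(1)
  set.seed(123)
  invisible(generate_family(small_spec()))
  expect_identical(runif(1), x1)
})

test_that("category truth matches the spec counts by construction", {
  b <- small_bundle()
  spec <- small_spec()
  counts <- table(b$truth$categories$category)
  expect_equal(as.vector(counts[names(spec$category_counts)]),
               unname(spec$category_counts))
  expect_identical(as.integer(sum(counts)), length(b$proteins))
})

test_that("planted domains classify to their planted categories directly", {
  b <- small_bundle()
  truth <- b$truth$categories
  for (i in seq_len(nrow(truth))) {
    id <- truth$gene_id[i]
    start <- b$truth$domain_start$start[b$truth$domain_start$gene_id == id]
    dom <- strsplit(substring(b$proteins[[id]], start, start + 60), "")[[1]]
    expect_identical(classify_binding(dom), truth$category[i])
  }
})

test_that("CDSs back-translate their proteins", {
  b <- small_bundle()
  expect_silent(validate_cds(b$cds))
  for (id in names(b$proteins)[1:5]) {
    aa <- famchar:::translate_cds(b$cds[[id]])
    expect_identical(substring(aa, 1, nchar(aa) - 1), b$proteins[[id]])
    expect_identical(substring(aa, nchar(aa)), "*")
  }
})

test_that("gene maps validate and cover the configured chromosomes", {
  b <- small_bundle()
  fam <- b$genes[b$genes$gene_id %in% names(b$proteins), ]
  spec <- small_spec()
  chr_tab <- table(fam$chromosome)
  expect_equal(unname(chr_tab[paste0("chr", 1:3)]),
               unname(as.table(spec$chr_counts)[1:3]),
               ignore_attr = TRUE)
  expect_silent(validate_gene_models(b$genes))
})

test_that("FPKM matrices validate and realize planted archetypes", {
  b <- small_bundle()
  expect_silent(famchar:::validate_fpkm(b$fpkm_tissue))
  expect_silent(famchar:::validate_fpkm(b$fpkm_treatment))
  expect_identical(colnames(b$fpkm_treatment),
                   c("control", "chill_8h", "chill_5d", "freeze_1h"))
})

test_that("bundle writing round-trips through the plain-text formats", {
  b <- small_bundle()
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  expect_identical(read_fasta(file.path(dir, "proteins.fa"), "protein"),
                   b$proteins)
  expect_identical(read_fasta(file.path(dir, "cds.fa"), "cds"), b$cds)
  g <- read_gene_models(file.path(dir, "genes.tsv"))
  expect_identical(g, b$genes)
  m <- read_fpkm(file.path(dir, "fpkm_treatment.tsv"))
  expect_equal(m, b$fpkm_treatment, tolerance = 1e-8)
})

test_that("infeasible specs are rejected", {
  expect_error(family_spec(n_genes = 10,
                           category_counts = c(G_BOX = 5, E_BOX_NON_G = 4,
                                               NON_E_BOX = 3, NON_DNA = 5)))
  expect_error(generate_family(
    family_spec(n_genes = 8,
                category_counts = c(G_BOX = 2, E_BOX_NON_G = 2,
                                    NON_E_BOX = 2, NON_DNA = 2),
                n_chromosomes = 1, chr_counts = 4,
                tandem_clusters = c(chr1 = 3),
                tissue_counts = c(all = 4, none = 1, fruit_only = 1,
                                  root_only = 1),
                n_expressed = 5, n_up = 1, n_down = 1)),
    "tandem")
})

test_that("evolved codon pairs honor their truth bookkeeping", {
  ep0 <- evolve_codon_pair(50, t_sub = 0, omega = 1, seed = 5)
  expect_identical(ep0$cds_a, ep0$cds_b)
  ng <- nei_gojobori(c(ep0$cds_a, ep0$cds_b))
  expect_equal(ng$ka, 0); expect_equal(ng$ks, 0)

  ep <- evolve_codon_pair(100, t_sub = 0.3, omega = 0.5, seed = 11)
  diff_nt <- sum(strsplit(ep$cds_a, "")[[1]] != strsplit(ep$cds_b, "")[[1]])
  total <- ep$truth$n_syn_substitutions + ep$truth$n_nonsyn_substitutions
  expect_lte(diff_nt, total)          # back-mutations can hide events
  expect_gt(total, 0)
  expect_error(evolve_codon_pair(5, 0.1, 1), "n_codons")
})
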