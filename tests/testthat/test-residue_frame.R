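# Frame fitting, consensus ratios, conservation calls.

test_that("frame construction validates its region tiling", {
  fr <- reference_frame()
  expect_equal(fr$length, 61)
  expect_identical(famchar:::frame_region_positions(fr, "loop"), 32:45)
  bad <- data.frame(name = c("basic", "helix1", "loop", "helix2"),
                    start = c(1, 18, 33, 46), end = c(17, 31, 45, 61))
  expect_error(reference_frame(61, bad), "tile")
})

test_that("a length-61 hit maps identically onto the frame", {
  fr <- reference_frame()
  tpl <- paste(domain_template(), collapse = "")
  aligned <- align_to_frame(tpl, fr, default_pssm())
  expect_identical(as.character(aligned), domain_template())
  expect_false(any(aligned == "-"))
})

test_that("short hits gap only inside the loop; flanks map through", {
  fr <- reference_frame()
  pssm <- default_pssm()
  tpl <- domain_template()
  short <- paste(tpl[-c(35, 40)], collapse = "")   # drop 2 loop residues
  aligned <- align_to_frame(short, fr, pssm)
  gaps <- which(aligned == "-")
  expect_length(gaps, 2)
  expect_true(all(gaps >= 32 & gaps <= 45))
  expect_identical(as.character(aligned[c(1:31, 46:61)]),
                   tpl[c(1:31, 46:61)])
})

test_that("long hits are trimmed inside the loop at the best placement", {
  fr <- reference_frame()
  pssm <- default_pssm()
  tpl <- domain_template()
  # insert 3 junk residues into the loop
  long <- c(tpl[1:38], c("W", "W", "W"), tpl[39:61])
  aligned <- align_to_frame(paste(long, collapse = ""), fr, pssm)
  expect_length(aligned, 61)
  expect_identical(as.character(aligned[c(1:31, 46:61)]),
                   tpl[c(1:31, 46:61)])
  # oracle: recursive enumeration of all order-preserving keeps
  mid <- long[32:48]
  keep_sets <- combn(length(mid), 14)
  best <- -Inf
  for (j in seq_len(ncol(keep_sets))) {
    kept <- mid[keep_sets[, j]]
    sc <- sum(pssm$scores[cbind(match(kept, famchar:::AA_LETTERS), 32:45)])
    best <- max(best, sc)
  }
  got <- sum(pssm$scores[cbind(match(aligned[32:45], famchar:::AA_LETTERS),
                               32:45)])
  expect_equal(got, best, tolerance = 1e-10)
  # the junk residues themselves should have been the ones trimmed
  expect_identical(as.character(aligned[32:45]), tpl[32:45])
})

test_that("hits outside the loop slack are rejected", {
  fr <- reference_frame()
  expect_error(align_to_frame(random_protein(70), fr, default_pssm()),
               "slack")
})

test_that("consensus handles unanimity and alphabetical tie-breaks", {
  mat <- matrix("A", nrow = 10, ncol = 61)
  mat[, 15] <- "R"
  mat[, 20] <- rep(c("R", "K"), 5)
  prof <- consensus(mat)
  expect_equal(prof$ratio[15], 1.0)
  expect_identical(prof$modal[15], "R")
  expect_equal(prof$ratio[20], 0.5)
  expect_identical(prof$modal[20], "K")  # K before R alphabetically
  expect_identical(prof$region[15], "basic")
})

test_that("consensus ratios match brute-force recounting and ignore order", {
  coh <- generate_consensus_cohort(n = 40, seed = 3)
  prof <- consensus(coh$domains)
  for (p in c(1, 15, 26, 33, 61)) {
    col <- coh$domains[, p]
    counts <- table(col[col != "-"])
    expect_equal(prof$ratio[p], max(counts) / sum(counts))
  }
  perm <- sample(nrow(coh$domains))
  expect_equal(consensus(coh$domains[perm, ])$ratio, prof$ratio)
})

test_that("gap columns are excluded from the consensus denominator", {
  mat <- matrix("L", nrow = 4, ncol = 61)
  mat[1:2, 40] <- "-"
  prof <- consensus(mat)
  expect_equal(prof$n_nongap[40], 2L)
  expect_equal(prof$ratio[40], 1.0)
})

test_that("conservation calls use strict thresholds", {
  prof <- data.frame(position = 1:4, region = "basic", modal = "R",
                     ratio = c(0.95, 0.5, 0.51, 0.9),
                     n_nongap = 10, n_sequences = 10)
  calls <- conserved_calls(prof)
  expect_identical(calls$label,
                   c("highly_conserved", "none", "conserved", "conserved"))
  expect_error(conserved_calls(prof, 0.9, 0.5), "conserved_threshold")
  # monotonicity: raising thresholds never adds labels
  stricter <- conserved_calls(prof, 0.6, 0.96)
  rank <- function(l) match(l, c("none", "conserved", "highly_conserved"))
  expect_true(all(rank(stricter$label) <= rank(calls$label)))
})

test_that("planted cohort yields 23 conserved positions, 5 highly", {
  coh <- generate_consensus_cohort(n = 95, seed = 8)
  calls <- conserved_calls(consensus(coh$domains))
  expect_equal(sum(calls$label != "none"), 23)
  expect_equal(sum(calls$label == "highly_conserved"), 5)
  expect_identical(which(calls$label == "highly_conserved"),
                   c(15L, 16L, 26L, 31L, 61L))
  expect_identical(calls$label, coh$truth$label)
})
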