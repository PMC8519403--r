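# FPKM screening rules, clustering, and qPCR relative expression.

demo_matrix <- function() {
  m <- rbind(
    g1 = c(10, 40, 12, 9),     # up 4x in t1
    g2 = c(10, 2, 11, 10),     # down 5x in t1
    g3 = c(5, 6, 5, 4),        # flat
    g4 = c(0.2, 0.4, 0.3, 0.2) # silent: fold noise but never expressed
  )
  colnames(m) <- c("control", "t1", "t2", "t3")
  m
}

test_that("effective expression is strictly greater-than", {
  m <- matrix(c(1.0, 2.5, 0, 1.0001), 2, 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  e <- effective_expression(m)
  expect_identical(as.vector(e), c(FALSE, TRUE, FALSE, TRUE))
  expect_true(effective_expression(matrix(1.0), threshold = 0.5)[1])
})

test_that("tissue specificity categories cover all cases", {
  m <- rbind(
    g1 = c(5, 5, 5, 5, 5),
    g2 = c(0.2, 0.1, 0.3, 0.2, 0.1),
    g3 = c(0.2, 0.1, 0.3, 0.2, 9),
    g4 = c(4, 6, 0.2, 3, 2)
  )
  colnames(m) <- c("bud", "fruit", "leaf", "stem", "root")
  ts <- tissue_specificity(m)
  expect_identical(unname(ts),
                   c("all_tissues", "none", "single:root", "4_of_5"))
  expect_error(tissue_specificity(m[, 1, drop = FALSE]), ">= 2")
})

test_that("fold-change screen follows the worked examples", {
  sc <- fold_change_screen(demo_matrix(), "control")
  expect_setequal(sc$gene, c("g1", "g2"))
  up <- sc[sc$gene == "g1", ]
  expect_identical(up$direction, "up")
  expect_equal(up$max_abs_fold_change, 40.1 / 10.1, tolerance = 1e-9)
  expect_true(up$within_band)
  expect_identical(up$conditions_passing, "t1")
  down <- sc[sc$gene == "g2", ]
  expect_identical(down$direction, "down")
  expect_gt(down$max_abs_fold_change, 4.5)
  expect_true(down$within_band)
  expect_error(fold_change_screen(demo_matrix(), "nope"), "absent")
})

test_that("silent genes cannot be screened in; sets are disjoint", {
  sc <- fold_change_screen(demo_matrix(), "control")
  expect_false("g4" %in% sc$gene)
  expect_length(intersect(sc$gene[sc$direction == "up"],
                          sc$gene[sc$direction == "down"]), 0)
  # gene order invariance
  m2 <- demo_matrix()[c(3, 1, 4, 2), ]
  sc2 <- fold_change_screen(m2, "control")
  expect_setequal(sc$gene, sc2$gene)
})

test_that("planted treatment matrix yields the exact screen sets", {
  b <- small_bundle()
  expr <- effective_expression(b$fpkm_treatment)
  expect_equal(sum(rowSums(expr) > 0), small_spec()$n_expressed)
  expect_setequal(rownames(expr)[rowSums(expr) > 0],
                  b$truth$expressed_genes)
  sc <- fold_change_screen(b$fpkm_treatment, "control")
  expect_setequal(sc$gene[sc$direction == "up"], b$truth$up_genes)
  expect_setequal(sc$gene[sc$direction == "down"], b$truth$down_genes)
  expect_true(all(sc$within_band))
})

test_that("planted tissue matrix is tallied exactly", {
  b <- small_bundle()
  ts <- tissue_specificity(b$fpkm_tissue)
  truth <- b$truth$tissue_category
  expect_identical(unname(ts[truth$gene_id]), truth$category)
})

test_that("profile clustering: identical profiles, singletons, relabeling", {
  set.seed(67)
  base <- matrix(rlnorm(5 * 6, 1, 1), 5, 6,
                 dimnames = list(paste0("g", 1:5), paste0("c", 1:6)))
  base["g2", ] <- base["g1", ] * 2        # identical profile shape
  cl <- cluster_profiles(base, k = 3)
  expect_equal(cl[["g1"]], cl[["g2"]])
  expect_length(unique(cluster_profiles(base, k = 5)), 5)
  # permutation invariance up to relabeling
  perm <- sample(5)
  cl2 <- cluster_profiles(base[perm, ], k = 3)
  same <- outer(cl, cl, "==")
  same2 <- outer(cl2[names(cl)], cl2[names(cl)], "==")
  expect_identical(same, same2)
})

test_that("planted archetypes are recovered by clustering", {
  set.seed(71)
  arch <- rbind(c(1, 1, 8, 8), c(8, 8, 1, 1), c(1, 8, 1, 8), c(8, 1, 8, 1))
  ok <- 0
  for (rep in 1:10) {
    genes <- lapply(1:20, function(i) {
      a <- arch[(i - 1) %% 4 + 1, ]
      a * exp(rnorm(4, 0, 0.05))
    })
    m <- do.call(rbind, genes)
    dimnames(m) <- list(paste0("g", 1:20), paste0("c", 1:4))
    cl <- cluster_profiles(m, k = 4)
    planted <- rep(1:4, 5)
    ok <- ok + as.integer(all(outer(cl, cl, "==") ==
                                outer(planted, planted, "==")))
  }
  expect_gte(ok, 9)
})

test_that("constant profiles fall back to Euclidean with a message", {
  m <- rbind(g1 = c(2, 2, 2), g2 = c(1, 5, 9), g3 = c(2, 6, 10))
  colnames(m) <- paste0("c", 1:3)
  expect_message(cl <- cluster_profiles(m, k = 2), "Euclidean")
  expect_equal(cl[["g2"]], cl[["g3"]])
})

test_that("2^-ddCt relative expression follows its closed form", {
  s <- list(gene = "g", ct_target = 20, ct_reference = 15)
  expect_equal(relative_expression(s, s), 1.0)
  s2 <- list(gene = "g", ct_target = 19, ct_reference = 15)
  expect_equal(relative_expression(s2, s), 2.0)
  s3 <- list(gene = "g", ct_target = 20 + log2(10), ct_reference = 15)
  expect_equal(relative_expression(s3, s), 0.1, tolerance = 1e-9)
  expect_error(relative_expression(list(gene = "a", ct_target = 1,
                                        ct_reference = 1), s), "different")
  expect_error(relative_expression(list(gene = "g", ct_target = 55,
                                        ct_reference = 15), s), "Ct values")
})

test_that("replicate tables are averaged before ddCt", {
  ct <- data.frame(
    gene = "g",
    condition = rep(c("control", "cold"), each = 3),
    ct_target = c(20, 20.2, 19.8, 18, 18.2, 17.8),
    ct_reference = c(15, 15.1, 14.9, 15, 15.1, 14.9)
  )
  tab <- relative_expression_table(ct, "control")
  expect_equal(tab$fold, 2^2, tolerance = 1e-9)  # mean dCt drops by 2
  expect_error(relative_expression_table(ct[-1, ], "control"), "fewer")
})
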