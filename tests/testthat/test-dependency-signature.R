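test_that("dependent-line counting is strict on the threshold", {
  m <- matrix(c(0.9, 0.6, 0.5, 0.1, 0.4), 1,
              dimnames = list("EIF2AK4", paste0("L", 1:5)))
  expect_equal(count_dependent(m, "EIF2AK4"), 2)  # 0.5 is not > 0.5
  expect_equal(count_dependent(matrix(0, 1, 5,
                                      dimnames = list("EIF2AK4", NULL)),
                               "EIF2AK4"), 0)
  expect_error(count_dependent(m, "ABSENT"), "not present")
  expect_error(count_dependent(m, "EIF2AK4", threshold = 1), "in \\(0,1\\)")
})

test_that("extreme-group selection orders scores and matches tissues", {
  scores <- stats::setNames(c(-2, -1, 0, 1), paste0("L", 1:4))
  tissues <- stats::setNames(rep("skin", 4), paste0("L", 1:4))
  g <- select_extreme_lines(scores, tissues, 2, 2)
  expect_equal(g$top, c("L1", "L2"))
  expect_equal(g$bottom, c("L4", "L3"))  # least dependent first
  expect_true(all(g$shortfall == 0))

  # a tissue present only in the top group: shortfall reported, pool fill
  scores2 <- stats::setNames(c(-3, -2, 0.5, 1, 1.5), paste0("L", 1:5))
  tissues2 <- stats::setNames(c("liver", "liver", "skin", "skin", "skin"),
                              paste0("L", 1:5))
  g2 <- select_extreme_lines(scores2, tissues2, 2, 2)
  expect_equal(g2$top, c("L1", "L2"))
  expect_equal(sum(g2$shortfall), 2)     # no liver lines left to match
  expect_length(g2$bottom, 2)            # back-filled globally
  expect_equal(g2$bottom, c("L5", "L4"))

  expect_error(select_extreme_lines(scores, tissues, 3, 2), "exceeds")
  expect_error(select_extreme_lines(unname(scores), tissues, 2, 2), "named")
})

test_that("signature derivation recovers planted genes with correct directions", {
  for (s in 1:3) {
    coh <- simulate_dependency_cohort(dependency_cohort_config(seed = s))
    grp <- select_extreme_lines(coh$scores[coh$target_gene, ], coh$tissues,
                                n_top = 60, n_bottom = 60)
    sig <- derive_signature(coh$expr, grp, size = 56)
    expect_length(sig$genes, 56)
    planted <- coh$signature_truth$gene
    expect_gte(sum(sig$genes %in% planted), 50)
    # recovered directions agree with the planted ones
    shared <- intersect(sig$genes, planted)
    truth_dir <- with(coh$signature_truth, stats::setNames(direction, gene))
    expect_true(all(sig$direction[shared] == truth_dir[shared]))
  }
})

test_that("null cohorts yield flagged short signatures", {
  coh <- simulate_dependency_cohort(
    dependency_cohort_config(n_lines = 60, n_genes = 500, n_signature = 20,
                             delta = 0, seed = 6))
  grp <- list(top = names(coh$truth_lines)[coh$truth_lines][1:10],
              bottom = names(coh$truth_lines)[!coh$truth_lines][1:10])
  sig <- derive_signature(coh$expr, grp, size = 20)
  expect_true(sig$flagged_short)
  expect_lt(length(sig$genes), 20)
})

test_that("constant genes are never selected and derivation is order-invariant", {
  set.seed(8)
  expr <- matrix(rnorm(200 * 30), 200, 30,
                 dimnames = list(sprintf("g%03d", 1:200), sprintf("L%02d", 1:30)))
  expr[1:10, 1:15] <- expr[1:10, 1:15] + 3
  expr["g050", ] <- 1  # identical in both groups
  grp <- list(top = colnames(expr)[1:15], bottom = colnames(expr)[16:30])
  sig <- derive_signature(expr, grp, size = 10)
  expect_false("g050" %in% sig$genes)

  perm_r <- sample(nrow(expr)); perm_c <- sample(ncol(expr))
  sig_p <- derive_signature(expr[perm_r, perm_c], grp, size = 10)
  expect_setequal(sig$genes, sig_p$genes)
  expect_equal(sig$direction[sort(sig$genes)], sig_p$direction[sort(sig$genes)])
})

test_that("projection classifies by strict sign-agreement fraction", {
  genes <- sprintf("g%02d", 1:56)
  sig <- structure(list(target = "EIF2AK4", genes = genes,
                        direction = stats::setNames(rep(1L, 56), genes),
                        stats = NULL, flagged_short = FALSE, metadata = list()),
                   class = "dependency_signature")
  # two tumors; z-scores are symmetric, so tumor A agrees where A > B
  a <- c(rep(1, 45), rep(-1, 11))
  expr <- cbind(A = a, B = -a)
  rownames(expr) <- genes
  res <- project_signature(sig, expr)
  expect_equal(res$match_fraction[res$tumor_id == "A"], 45 / 56)
  expect_true(res$dependent[res$tumor_id == "A"])    # 0.8036 > 0.8
  expect_equal(res$match_fraction[res$tumor_id == "B"], 11 / 56)
  expect_false(res$dependent[res$tumor_id == "B"])

  # a fraction of exactly 0.8 is NOT dependent (strict inequality)
  sig5 <- structure(list(target = "X", genes = genes[1:5],
                         direction = stats::setNames(rep(1L, 5), genes[1:5]),
                         stats = NULL, flagged_short = FALSE, metadata = list()),
                    class = "dependency_signature")
  a5 <- c(rep(1, 4), -1)
  expr5 <- cbind(A = a5, B = -a5); rownames(expr5) <- genes[1:5]
  res5 <- project_signature(sig5, expr5)
  expect_equal(res5$match_fraction[1], 0.8)
  expect_false(res5$dependent[1])

  # a perfect tumor matches with fraction 1
  expr_all <- cbind(A = rep(1, 5), B = rep(-1, 5)); rownames(expr_all) <- genes[1:5]
  res_all <- project_signature(sig5, expr_all)
  expect_equal(res_all$match_fraction[1], 1)
  expect_true(res_all$dependent[1])

  expect_error(project_signature(sig5, expr5[, 1, drop = FALSE]), "cohort of 1")
  expect_error(project_signature(sig, expr5), "fewer than half")
})

test_that("DepMap-portal-layout CSVs round-trip through the reader", {
  coh <- simulate_dependency_cohort(
    dependency_cohort_config(n_lines = 20, n_genes = 50, n_signature = 10,
                             seed = 12))
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(gene = rownames(coh$probs), coh$probs, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  back <- read_depmap_csv(path)
  expect_equal(back, coh$probs, tolerance = 1e-12)
  expect_equal(count_dependent(back, coh$target_gene),
               count_dependent(coh$probs, coh$target_gene))
})
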