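test_that("log normalisation follows the CPM and median-centering conventions", {
  # library size 10^6 makes CPM equal the raw count
  counts <- matrix(c(1000, rep(999000 / 9, 9)), 10, 1)
  m <- tiny_omics(counts, days = 0)
  out <- normalize_log(m)
  expect_equal(out$values[1, 1], log2(1000 + 0.5), tolerance = 1e-12)
  expect_true(out$log_scale)

  # all-equal intensity column: median centering leaves zeros
  intens <- matrix(rep(8, 5), 5, 1)
  p <- tiny_omics(intens, days = 0, omic = "protein")
  expect_equal(unname(normalize_log(p)$values[, 1]), rep(0, 5))

  # doubling every count in a sample leaves its CPM column unchanged
  x <- matrix(rpois(20, 40) + 1, 10, 2)
  x2 <- x; x2[, 2] <- x2[, 2] * 2
  a <- normalize_log(tiny_omics(x, days = c(0, 0)))
  b <- normalize_log(tiny_omics(x2, days = c(0, 0)))
  expect_equal(a$values[, 2], b$values[, 2], tolerance = 1e-12)

  expect_error(normalize_log(tiny_omics(matrix(0, 3, 1), days = 0)),
               "zero library size")
  expect_error(normalize_log(tiny_omics(matrix(c(1, -2, 3), 3, 1), days = 0,
                                        omic = "protein", log_scale = FALSE)),
               "positive")
})

test_that("moderated t matches hand-computed and limiting cases", {
  # identical group means: log2FC = 0, t = 0, p = 1
  v <- matrix(c(1, 2, 1, 2), 1, 4)
  m <- tiny_omics(v, days = c(0, 0, 1, 1), log_scale = TRUE)
  res <- moderated_ttest(m, 1)
  expect_equal(res$log2FC, 0)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  # hand-computed shrunken statistic: 0,0 vs 2,2 with fixed prior
  # s2 = 0, d = 2, prior (d0 = 2, s0^2 = 0.5):
  # stilde2 = (2*0.5 + 2*0)/4 = 0.25; se = sqrt(0.25 * (1/2 + 1/2)) = 0.5
  # t = 2 / 0.5 = 4 on 4 df
  v <- matrix(c(0, 0, 2, 2), 1, 4)
  m <- tiny_omics(v, days = c(0, 0, 1, 1), log_scale = TRUE)
  res <- moderated_ttest(m, 1, prior = c(d0 = 2, s0sq = 0.5))
  expect_equal(res$log2FC, 2)
  expect_equal(res$t, 4, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-4, df = 4), tolerance = 1e-12)

  # d0 -> 0 limit recovers the ordinary pooled-variance two-sample t
  set.seed(1)
  v <- matrix(rnorm(30), 5, 6)
  m <- tiny_omics(v, days = c(0, 0, 0, 2, 2, 2), log_scale = TRUE)
  res <- moderated_ttest(m, 2, prior = c(d0 = 0, s0sq = 1))
  for (i in 1:5) {
    tt <- t.test(v[i, 4:6], v[i, 1:3], var.equal = TRUE)
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-9)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-9)
  }

  expect_error(moderated_ttest(m, 5), "not present")
  m1 <- tiny_omics(matrix(rnorm(10), 5, 2), days = c(0, 2), log_scale = TRUE)
  expect_error(moderated_ttest(m1, 2), "2 replicates")
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, NA)), "missing")
  expect_error(bh_adjust(c(0.1, 1.4)), "in \\[0,1\\]")

  set.seed(3)
  for (i in 1:50) {
    p <- runif(sample(1:100, 1))
    expect_equal(bh_adjust(p), naive_bh(p), tolerance = 0)
  }
})

test_that("deregulation calls respect the FDR and fold-change cutoffs", {
  tab <- data.frame(feature_id = paste0("g", 1:5), day = 1,
                    log2FC = c(1.5, 0.9, -2, -0.5, 3),
                    t = 0, p = 0,
                    q = c(0.04, 0.04, 0.01, 0.2, 0.06))
  out <- call_deregulated(tab, q_max = 0.05, lfc_min = 1)
  expect_equal(out$call, c("up", "none", "down", "none", "none"))
  # hand enumeration: 2 features survive the transcript cutoffs
  expect_equal(sum(out$call != "none"), 2)
  # without the fold-change cutoff the q <= 0.05 features all survive
  out0 <- call_deregulated(tab, q_max = 0.05, lfc_min = 0)
  expect_equal(sum(out0$call != "none"), 3)
})

test_that("direction enrichment equals exact hypergeometric enumeration", {
  mk <- function(up_in, down_in, up_out, down_out) {
    ids <- paste0("g", seq_len(up_in + down_in + up_out + down_out))
    data.frame(feature_id = ids, day = 1, log2FC = 1,
               t = 0, p = 0, q = 0,
               call = c(rep("up", up_in), rep("down", down_in),
                        rep("up", up_out), rep("down", down_out)))
  }
  tab <- mk(8, 2, 2, 8)
  res <- direction_enrichment_test(tab, paste0("g", 1:10), 1)
  expect_equal(res$odds_ratio, 16)
  expect_equal(res$p, fisher_enum_p(res$counts), tolerance = 1e-12)

  # equal up/down proportions in both strata: p = 1
  res_eq <- direction_enrichment_test(mk(5, 5, 5, 5), paste0("g", 1:10), 1)
  expect_equal(res_eq$p, 1)

  # disjoint annotation: empty margin flagged
  res_na <- direction_enrichment_test(tab, c("absent1", "absent2"), 1)
  expect_true(res_na$empty_margin)
  expect_equal(res_na$p, 1)
  expect_true(is.na(res_na$odds_ratio))

  # Fisher p equals enumeration on random small tables
  set.seed(8)
  for (i in 1:40) {
    counts <- matrix(sample(0:15, 4, replace = TRUE), 2, 2)
    if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) next
    expect_equal(fisher.test(counts)$p.value, fisher_enum_p(counts),
                 tolerance = 1e-9)
  }
})

test_that("cross-omics fold-change correlation handles exact cases", {
  mk <- function(lfc) data.frame(feature_id = paste0("g", seq_along(lfc)),
                                 day = 2, log2FC = lfc, t = 0, p = 0, q = 0,
                                 call = "up")
  tx <- mk(c(1, 2, 3, 4))
  expect_equal(crossomics_fc_correlation(tx, mk(c(1, 2, 3, 4)), 2)$r, 1)
  expect_equal(crossomics_fc_correlation(tx, mk(-c(1, 2, 3, 4)), 2)$r, -1)
  tx2 <- mk(c(1, 2)); expect_error(crossomics_fc_correlation(tx2, tx2, 2),
                                   "fewer than 3")
})

test_that("PCA scores behave like the singular value decomposition", {
  set.seed(2)
  v <- matrix(rnorm(30), 5, 6)
  v[, 6] <- v[, 5]  # duplicated sample
  m <- tiny_omics(v, days = c(0, 0, 1, 1, 2, 2), log_scale = TRUE)
  sc <- pca_scores(m, 2)
  expect_equal(sc$scores[5, ], sc$scores[6, ], tolerance = 1e-9)

  # rank-1 matrix: PC1 explains everything
  r1 <- outer(rnorm(4), rnorm(3))
  m1 <- tiny_omics(r1, days = c(0, 1, 2), log_scale = TRUE)
  expect_equal(pca_scores(m1, 1)$explained[1], 1, tolerance = 1e-9)

  # 3x3 toy case against a direct SVD of the centred matrix
  x <- matrix(c(1, 2, 3, 2, 4, 1, 0, 1, 5), 3, 3)
  m3 <- tiny_omics(x, days = c(0, 1, 2), log_scale = TRUE)
  sc3 <- pca_scores(m3, 2)
  xc <- t(x) - colMeans(t(x))[col(t(x))]
  xc <- scale(t(x), center = TRUE, scale = FALSE)
  sv <- svd(xc)
  manual <- sv$u %*% diag(sv$d)
  for (j in 1:2) {
    expect_equal(abs(sc3$scores[, j]), abs(manual[, j]), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  expect_error(pca_scores(m3, 5), "n_pc")
})
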