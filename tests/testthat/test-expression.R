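make_expr <- function(values, times = NULL, tissues = NULL, lengths = NULL) {
  design <- design_rows(colnames(values))
  gl <- if (is.null(lengths)) {
    stats::setNames(rep(1000, nrow(values)), rownames(values))
  } else lengths
  expression_matrix(values, design, gl)
}

design_rows <- function(ids) triptofunnel:::design_from_sample_ids(ids)

test_that("RPKM matches the plug-in definition and an element-wise oracle", {
  v <- matrix(c(10, rep(0, 3)), nrow = 2, dimnames =
                list(c("g1", "g2"), c("CC_000_r1", "CC_000_r2")))
  v[2, 1] <- 999990  # library 1: 1e6 total
  v[1, 2] <- 5; v[2, 2] <- 15
  m <- make_expr(v, lengths = c(g1 = 1000, g2 = 500))
  r <- compute_rpkm(m)
  expect_equal(r$values["g1", 1], 10)   # 1e9 * 10 / (1000 * 1e6)
  expect_equal(r$values["g1", 2] == 0, FALSE)
  expect_equal(compute_rpkm(m)$values["g2", 1],
               1e9 * 999990 / (500 * 1e6))

  set.seed(11)
  v2 <- matrix(rpois(120, 40), 20, 6,
               dimnames = list(sprintf("g%02d", 1:20),
                               sprintf("CC_%03d_r%d", rep(c(0, 4, 8), 2),
                                       rep(1:2, each = 3))))
  gl <- stats::setNames(sample(500:3000, 20), rownames(v2))
  m2 <- make_expr(v2, lengths = gl)
  r2 <- compute_rpkm(m2)
  for (i in seq_len(20)) for (j in seq_len(6)) {
    expect_equal(r2$values[i, j],
                 1e9 * v2[i, j] / (gl[[i]] * sum(v2[, j])))
  }
  # zero counts give zero RPKM; zero library errors with the sample name
  expect_equal(unname(r2$values[v2 == 0]), rep(0, sum(v2 == 0)))
  v3 <- v2; v3[, 2] <- 0
  expect_error(compute_rpkm(make_expr(v3, lengths = gl)), "CC_004_r1")
})

test_that("RPKM is invariant to scaling one sample's counts and library together", {
  set.seed(12)
  v <- matrix(rpois(60, 30) + 1, 10, 6,
              dimnames = list(sprintf("g%02d", 1:10),
                              sprintf("CM_%03d_r%d", rep(c(0, 4, 8), 2),
                                      rep(1:2, each = 3))))
  m <- make_expr(v)
  r1 <- compute_rpkm(m)$values[, 3]
  v[, 3] <- v[, 3] * 7
  r2 <- compute_rpkm(make_expr(v))$values[, 3]
  expect_equal(r1, r2)
})

test_that("differential expression reproduces the pooled-variance t-test", {
  ids <- c(sprintf("CM_004_r%d", 1:3), sprintf("CC_004_r%d", 1:3))
  # identical groups: fold 1, not significant
  v <- matrix(rep(c(4, 6, 8), 2), nrow = 1,
              dimnames = list("g1", ids))
  de <- differential_expression(make_expr(v), time_points_h = 4)
  expect_equal(de$fold_change, 1)
  expect_false(de$significant)
  # exact 2x with zero within-group variance: degenerate p = 0
  v2 <- matrix(c(20, 20, 20, 10, 10, 10), nrow = 1,
               dimnames = list("g1", ids))
  de2 <- differential_expression(make_expr(v2), time_points_h = 4,
                                 alpha = 1e-12, min_fold = 1.5)
  expect_equal(de2$p_value, 0)
  expect_true(de2$significant)
  expect_equal(de2$fold_change, 21 / 11)  # pseudocount-protected mean ratio
  # toy 3v3 equals both the hand pooled-variance formula and t.test
  a <- c(5.1, 6.3, 4.8); b <- c(3.2, 2.9, 3.9)
  v3 <- matrix(c(a, b), nrow = 1, dimnames = list("g1", ids))
  de3 <- differential_expression(make_expr(v3), time_points_h = 4)
  la <- log2(a + 1); lb <- log2(b + 1)
  sp <- sqrt(((2) * var(la) + (2) * var(lb)) / 4)
  t_hand <- (mean(la) - mean(lb)) / (sp * sqrt(2 / 3))
  p_hand <- 2 * pt(-abs(t_hand), 4)
  expect_equal(de3$p_value, p_hand, tolerance = 1e-12)
  expect_equal(de3$p_value,
               t.test(la, lb, var.equal = TRUE)$p.value, tolerance = 1e-12)
})

test_that("DE results are invariant to gene order and calibrated under the null", {
  set.seed(13)
  ids <- c(sprintf("CM_004_r%d", 1:3), sprintf("CC_004_r%d", 1:3))
  v <- matrix(2^rnorm(2000 * 6, mean = 6, sd = 1) - 1, 2000, 6,
              dimnames = list(sprintf("g%04d", 1:2000), ids))
  m <- make_expr(v)
  de <- differential_expression(m, 4, alpha = 0.05, min_fold = 1)
  perm <- sample(nrow(v))
  de_p <- differential_expression(make_expr(v[perm, ]), 4, 0.05, 1)
  expect_equal(de_p$p_value[match(de$gene_id, de_p$gene_id)], de$p_value)
  ks <- suppressWarnings(stats::ks.test(de$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
  # missing condition errors, listing the time point
  expect_error(differential_expression(m, 12), "12")
})

test_that("tissue dominance implements argmax plus ratio-to-median", {
  ids <- c("root_bark", "leaf", "stem", "flower")
  v <- rbind(dominant = c(10, 1, 1, 1),
             uniform = c(5, 5, 5, 5),
             max_but_weak = c(6, 5, 5, 5))
  colnames(v) <- ids
  m <- make_expr(v)
  flags <- tissue_dominance(m, "root_bark", min_ratio = 2)
  expect_true(flags[["dominant"]])
  expect_false(flags[["uniform"]])
  expect_false(flags[["max_but_weak"]])
  # brute-force re-evaluation of the stated rule on a random panel
  set.seed(14)
  v2 <- matrix(rexp(50 * 4, 1 / 20), 50, 4,
               dimnames = list(sprintf("g%02d", 1:50), ids))
  f2 <- tissue_dominance(make_expr(v2), "root_bark", 2)
  for (i in seq_len(50)) {
    foc <- v2[i, 1]; oth <- v2[i, -1]
    expect_identical(unname(f2[i]),
                     foc > max(oth) && (foc + 1) / (median(oth) + 1) >= 2)
  }
  expect_error(tissue_dominance(make_expr(v2[, 1, drop = FALSE])), "two tissues")
})

test_that("profile normalization yields exact row z-scores", {
  ids <- sprintf("CC_%03d_r1", c(0, 4, 8, 12))
  v <- matrix(c(1, 1, 1, 1,
                2, 4, 8, 16,
                5, 1, 9, 2), 3, 4, byrow = TRUE,
              dimnames = list(c("const", "mono", "mix"), ids))
  z <- normalize_profiles(make_expr(v))
  expect_equal(unname(z["const", ]), rep(0, 4))
  expect_identical(attr(z, "constant_rows"), "const")
  for (g in c("mono", "mix")) {
    expect_lt(abs(mean(z[g, ])), 1e-9)
    expect_lt(abs(sd(z[g, ]) - 1), 1e-9)
  }
  # monotone rows stay monotone
  set.seed(15)
  for (k in 1:20) {
    row <- sort(rexp(8, 1 / 50))
    zz <- normalize_profiles(matrix(row, 1, dimnames = list("g", NULL)))
    expect_false(is.unsorted(zz[1, ]))
  }
})
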