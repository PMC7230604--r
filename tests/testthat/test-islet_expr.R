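make_eset <- function(values_nd, values_t2d, gene = "G1") {
  n1 <- length(values_nd); n2 <- length(values_t2d)
  m <- matrix(c(values_nd, values_t2d), nrow = 1,
              dimnames = list(gene, c(sprintf("ND%02d", seq_len(n1)),
                                      sprintf("T2D%02d", seq_len(n2)))))
  expression_set(m, stats::setNames(rep(c("ND", "T2D"), c(n1, n2)),
                                    colnames(m)))
}

test_that("omnibus normality statistic matches frozen reference values", {
  # reference statistics computed independently with an established
  # implementation of the D'Agostino-Pearson K2 test
  v1 <- c(2.1, 3.4, 1.9, 5.6, 4.4, 3.3, 2.8, 4.9, 3.7, 2.2, 6.1, 3.0,
          4.1, 2.5, 3.9, 5.2, 1.4, 3.6, 4.7, 2.9)
  r1 <- dagostino_pearson_test(v1)
  expect_equal(r1$statistic, 0.652787239971, tolerance = 1e-9)
  expect_equal(r1$p_value, 0.721521126394, tolerance = 1e-9)
  expect_equal(r1$z_skew, 0.521900738951, tolerance = 1e-9)
  expect_equal(r1$z_kurt, -0.616771317956, tolerance = 1e-9)

  v2 <- c(0.5, 0.7, 0.6, 0.8, 0.55, 12.0, 0.65, 0.75, 0.62, 0.58,
          0.71, 0.66, 9.5, 0.6, 0.68, 0.72, 0.59, 0.63, 0.61, 0.69,
          0.7, 0.64)
  r2 <- dagostino_pearson_test(v2)
  expect_equal(r2$statistic, 34.660915347276, tolerance = 1e-9)
  expect_equal(r2$z_skew, 4.599537768968, tolerance = 1e-9)
  expect_equal(r2$z_kurt, 3.674937776223, tolerance = 1e-9)
  expect_lt(r2$p_value, 1e-6)
  expect_error(dagostino_pearson_test(1:5), "n >= 8")
})

test_that("the gate picks t for normal data and Mann-Whitney for skewed", {
  set.seed(2)
  normal <- compare_expression(
    make_eset(rnorm(30, 8), rnorm(12, 8)), "G1")
  expect_equal(normal$test_used, "t")
  skewed <- compare_expression(
    make_eset(2^rexp(30, 0.2), 2^rexp(12, 0.2)), "G1",
    log_transform = FALSE)
  expect_equal(skewed$test_used, "mann-whitney")
  # below the minimum per-group n the nonparametric branch is forced
  small <- compare_expression(make_eset(rnorm(5, 8), rnorm(5, 8)), "G1")
  expect_equal(small$test_used, "mann-whitney")
})

test_that("identical groups give p near 1 and equal means", {
  v <- c(3.2, 4.1, 2.8, 5.0, 3.7, 4.4, 3.1, 2.9, 4.8, 3.5)
  r <- compare_expression(make_eset(v, v), "G1")
  expect_equal(r$p_value, 1, tolerance = 0.01)
  expect_equal(r$group_means[["ND"]], r$group_means[["T2D"]])
  expect_error(compare_expression(make_eset(v, v), "missing"), "missing")
})

test_that("the comparison is invariant to sample order and label swap", {
  set.seed(4)
  a <- rnorm(20, 5); b <- rnorm(12, 6)
  r1 <- compare_expression(make_eset(a, b), "G1")
  es <- make_eset(a, b)
  perm <- sample(ncol(es$values))
  es2 <- expression_set(es$values[, perm, drop = FALSE],
                        stats::setNames(as.character(es$group)[perm],
                                        colnames(es$values)[perm]))
  r2 <- compare_expression(es2, "G1")
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$statistic, r2$statistic)
  # swapping which group is which flips only the sign of t
  es3 <- make_eset(b, a)
  r3 <- compare_expression(es3, "G1")
  expect_equal(r3$p_value, r1$p_value)
  expect_equal(abs(r3$statistic), abs(r1$statistic))
})

test_that("type-I error of the gated procedure is calibrated at the null", {
  sim <- simulate_expression(77L, n_null_genes = 400L,
                             base_log2 = c(DUMMY = 5),
                             effect_log2 = c(DUMMY = 0))
  genes <- grep("^NULL", rownames(sim$eset$values), value = TRUE)
  res <- compare_expression_table(sim$eset, genes)
  rate <- mean(res$p_value < 0.05)
  tol <- 2 * sqrt(0.05 * 0.95 / length(genes))
  expect_lt(abs(rate - 0.05), tol + 1e-9)
})

test_that("a planted two-SD shift at 63 vs 12 is detected with high power", {
  set.seed(88)
  hits <- vapply(1:200, function(i) {
    compare_expression(make_eset(rnorm(63, 5), rnorm(12, 7)), "G1",
                       log_transform = FALSE)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("ranking orders genes by reference-group mean with stable ties", {
  m <- rbind(A = rep(8, 10), B = rep(4, 10), M = rep(6, 10))
  colnames(m) <- sprintf("S%02d", 1:10)
  es <- expression_set(m, stats::setNames(rep(c("ND", "T2D"), c(6, 4)),
                                          colnames(m)))
  r <- rank_mean_expression(es, c("A", "B"), marker = "M")
  expect_equal(r$gene, c("A", "M", "B"))
  expect_equal(r$is_marker, c(FALSE, TRUE, FALSE))
  # all-equal means fall back to alphabetical order
  m2 <- m; m2[] <- 5
  es2 <- expression_set(m2, es$group)
  expect_equal(rank_mean_expression(es2, c("B", "A"), "M")$gene,
               c("A", "B", "M"))
  expect_error(rank_mean_expression(es, c("A", "ZZ"), "M"), "ZZ")
})

test_that("the simulated islet matrix recovers the planted ordering and shift", {
  sim <- simulate_expression(123L)
  r <- rank_mean_expression(sim$eset, c("ASAH1", "HSD17B12", "FES", "LRP4"),
                            marker = "KCNJ11")
  expect_setequal(r$gene[1:2], c("ASAH1", "HSD17B12"))
  expect_equal(r$gene[3], "KCNJ11")
  expect_setequal(r$gene[4:5], c("FES", "LRP4"))
  cmp <- compare_expression(sim$eset, "HSD17B12")
  expect_lt(cmp$p_value, 0.05)
  expect_equal(unname(cmp$direction), -1)
})
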