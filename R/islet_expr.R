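# Two-group expression comparison with a D'Agostino-Pearson normality gate
# (Student's t when both groups look normal, Mann-Whitney otherwise) and
# mean-expression ranking of candidate genes against a marker gene.

#' Construct an expression matrix with group labels
#'
#' @param values Gene x sample numeric matrix (FPKM or log2-CPM) with row
#'   and column names; no missing cells, no duplicate gene symbols.
#' @param group Named character/factor mapping every sample to `"ND"` or
#'   `"T2D"` (any two levels are accepted; the first level encountered is
#'   treated as reference).
#' @return An `expression_set` object (list with `values`, `group`).
#' @export
expression_set <- function(values, group) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (anyDuplicated(rownames(values))) stop("duplicate gene symbols")
  if (anyNA(values)) stop("expression matrix has missing cells")
  group <- group[colnames(values)]
  if (anyNA(group) || anyNA(names(group)))
    stop("every sample needs a group label")
  group <- stats::setNames(factor(as.character(group)), colnames(values))
  structure(list(values = values, group = group),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("<expression_set> %d gene(s) x %d sample(s) [%s]\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s:%d", levels(x$group), table(x$group)),
                    collapse = ", ")))
  invisible(x)
}

#' Read an expression matrix and sample-group map from TSV
#'
#' @param matrix_path Gene x sample TSV; first column `gene`.
#' @param group_path Two-column TSV `sample`, `group`.
#' @return An [expression_set()].
#' @export
read_expression <- function(matrix_path, group_path) {
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  gm <- utils::read.delim(group_path, stringsAsFactors = FALSE,
                          comment.char = "#")
  group <- stats::setNames(gm$group, gm$sample)
  expression_set(m, group)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino skewness z and the Anscombe-Glynn kurtosis z
#' into the omnibus statistic `K2 = z_skew^2 + z_kurt^2`, referred to a
#' chi-squared distribution with 2 df. Requires n >= 8 (the kurtosis
#' approximation needs it; results are approximate below n = 20).
#'
#' @param x Numeric vector, n >= 8.
#' @return List with `statistic` (K2), `p_value`, `z_skew`, `z_kurt`.
#' @export
dagostino_pearson_test <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance")
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)

  # skewness component (D'Agostino 1970)
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis component (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z_kurt <- ((1 - 2 / (9 * A)) -
             ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  k2 <- z_skew^2 + z_kurt^2
  list(statistic = k2,
       p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z_skew, z_kurt = z_kurt)
}

#' Normality-gated two-group comparison of one gene
#'
#' Tests the gene's expression between the two sample groups. When both
#' groups have at least `min_n_normality` samples and both pass the
#' D'Agostino-Pearson normality test at `alpha_normality`, a two-sided
#' Student's t-test (equal variances) is used; otherwise a two-sided
#' Mann-Whitney (Wilcoxon rank-sum) test. FPKM values are compared on the
#' log2(FPKM + 1) scale by default.
#'
#' @param eset An [expression_set()].
#' @param gene Gene symbol.
#' @param alpha_normality Significance level of the normality gate.
#' @param log_transform Compare on log2(x + 1) scale (default `TRUE`).
#' @param min_n_normality Minimum per-group n for the gate to be applied;
#'   below it the nonparametric test is forced.
#' @return List with `gene`, `test_used` (`"t"` or `"mann-whitney"`),
#'   `statistic`, `p_value`, `group_means` (on the analysis scale) and
#'   `direction` (sign of second-level mean minus first-level mean).
#' @export
compare_expression <- function(eset, gene, alpha_normality = 0.05,
                               log_transform = TRUE, min_n_normality = 8L) {
  stopifnot(inherits(eset, "expression_set"))
  if (!(gene %in% rownames(eset$values))) stop("gene not found: ", gene)
  lv <- levels(eset$group)
  if (length(lv) != 2L) stop("exactly two groups are required")
  v <- eset$values[gene, ]
  if (log_transform) v <- log2(v + 1)
  g1 <- v[eset$group == lv[1]]
  g2 <- v[eset$group == lv[2]]
  if (length(g1) < 2L || length(g2) < 2L)
    stop("both groups need at least 2 samples")
  gate_ok <- length(g1) >= min_n_normality && length(g2) >= min_n_normality &&
    stats::sd(g1) > 0 && stats::sd(g2) > 0
  normal <- gate_ok &&
    dagostino_pearson_test(g1)$p_value >= alpha_normality &&
    dagostino_pearson_test(g2)$p_value >= alpha_normality
  if (normal) {
    ht <- stats::t.test(g1, g2, var.equal = TRUE)
    test_used <- "t"
  } else {
    ht <- stats::wilcox.test(g1, g2, exact = FALSE, correct = TRUE)
    test_used <- "mann-whitney"
  }
  means <- stats::setNames(c(mean(g1), mean(g2)), lv)
  list(gene = gene, test_used = test_used,
       statistic = unname(ht$statistic), p_value = ht$p.value,
       group_means = means,
       direction = sign(means[[2]] - means[[1]]))
}

#' Compare several genes
#'
#' Runs [compare_expression()] per gene; optionally adds a
#' Benjamini-Hochberg adjusted column.
#'
#' @param eset An [expression_set()].
#' @param genes Gene symbols.
#' @param adjust Add a BH-adjusted `fdr` column (default `FALSE`; the
#'   single-gene workflow reports unadjusted p-values).
#' @param ... Passed to [compare_expression()].
#' @return Data.frame, one row per gene.
#' @export
compare_expression_table <- function(eset, genes, adjust = FALSE, ...) {
  rows <- lapply(genes, function(g) {
    r <- compare_expression(eset, g, ...)
    data.frame(gene = g, test_used = r$test_used, statistic = r$statistic,
               p_value = r$p_value,
               mean_1 = r$group_means[[1]], mean_2 = r$group_means[[2]],
               direction = r$direction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  lv <- levels(eset$group)
  names(out)[names(out) == "mean_1"] <- paste0("mean_", lv[1])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", lv[2])
  if (adjust) out$fdr <- bh_fdr(out$p_value)
  out
}

#' Rank genes by mean expression in the reference group
#'
#' Sorts the given genes by descending mean expression across the
#' reference-group samples only (first factor level, typically the
#' nondiabetic donors), ties broken by symbol. The marker gene is included
#' and flagged for reference.
#'
#' @param eset An [expression_set()].
#' @param genes Gene symbols to rank.
#' @param marker Marker gene symbol (e.g. an islet functional marker such
#'   as KCNJ11).
#' @param reference_group Group level over which means are taken; default
#'   the first level.
#' @return Data.frame with columns `gene`, `mean_expression`, `is_marker`,
#'   sorted by descending mean.
#' @export
rank_mean_expression <- function(eset, genes, marker,
                                 reference_group = levels(eset$group)[1]) {
  stopifnot(inherits(eset, "expression_set"))
  all_genes <- unique(c(genes, marker))
  missing <- setdiff(all_genes, rownames(eset$values))
  if (length(missing) > 0L)
    stop("gene(s) not found: ", paste(missing, collapse = ", "))
  sel <- eset$group == reference_group
  means <- rowMeans(eset$values[all_genes, sel, drop = FALSE])
  out <- data.frame(gene = all_genes, mean_expression = unname(means),
                    is_marker = all_genes == marker,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_expression, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
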