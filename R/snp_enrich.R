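# Over-representation testing of a query SNP set against annotation-term
# sets, with a choice of null (hypergeometric, binomial approximation, or
# Fisher's exact test), finite-population z-scores and Benjamini-Hochberg
# FDR across all tested terms.

#' Construct an annotation set
#'
#' @param term_id Term identifier.
#' @param annotated Character vector of entity IDs annotated to the term.
#' @param term_name Human-readable term name (defaults to `term_id`).
#' @return An `annotation_set` object.
#' @export
annotation_set <- function(term_id, annotated, term_name = term_id) {
  stopifnot(is.character(term_id), length(term_id) == 1L)
  structure(list(term_id = term_id, term_name = term_name,
                 annotated = unique(as.character(annotated))),
            class = "annotation_set")
}

#' Read annotation sets from a two-column TSV
#'
#' @param path TSV with columns `term_id` and `entity_id` (header required);
#'   an optional `term_name` column supplies display names.
#' @return List of [annotation_set()] objects.
#' @export
read_annotation_sets <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("term_id", "entity_id") %in% names(tab)))
  ids <- unique(tab$term_id)
  lapply(ids, function(id) {
    rows <- tab[tab$term_id == id, , drop = FALSE]
    nm <- if ("term_name" %in% names(tab)) rows$term_name[1] else id
    annotation_set(id, rows$entity_id, nm)
  })
}

#' Term over-representation test for a SNP set
#'
#' For each annotation set, tests whether the query overlaps the term's
#' annotated entities more than expected under sampling without replacement
#' from the universe. The p-value is the upper tail P(X >= x) under the
#' chosen null; the z-score always uses the finite-population
#' (hypergeometric) variance
#' \deqn{z = (x - nK/N) / \sqrt{nK/N \cdot (N-K)/N \cdot (N-n)/(N-1)}}
#' so it is consistent with the default null. Terms with zero variance
#' (K = 0, or K = N with n = N) get p = 1, z = 0 and `degenerate = TRUE`.
#'
#' @param query Character vector of entity IDs (subset of `universe`).
#' @param annotations List of [annotation_set()] objects; each set's
#'   entities must lie in `universe`.
#' @param universe Character vector: the background universe.
#' @param method `"hypergeometric"` (default), `"binomial"` (approximation
#'   with success probability K/N) or `"fisher"` (one-sided exact test).
#' @return Data.frame sorted by p ascending with columns `term_id`,
#'   `term_name`, `x`, `n`, `K`, `N`, `expected`, `z_score`, `p_value`,
#'   `fdr`, `degenerate`, `overlap_ids` (`; `-joined).
#' @export
enrich_terms <- function(query, annotations, universe,
                         method = c("hypergeometric", "binomial", "fisher")) {
  method <- match.arg(method)
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (length(universe) < 2L) stop("universe must contain at least 2 entities")
  extra <- setdiff(query, universe)
  if (length(extra) > 0L)
    stop("query entities outside the universe: ",
         paste(extra, collapse = ", "))
  N <- length(universe)
  n <- length(query)
  rows <- lapply(annotations, function(a) {
    ann <- unique(a$annotated)
    extra <- setdiff(ann, universe)
    if (length(extra) > 0L)
      stop("annotation '", a$term_id, "' has entities outside the universe: ",
           paste(extra, collapse = ", "))
    K <- length(ann)
    overlap <- intersect(query, ann)
    x <- length(overlap)
    expected <- n * K / N
    v <- expected * (N - K) / N * (N - n) / (N - 1)
    degenerate <- v <= 0
    if (degenerate) {
      p <- 1
      z <- 0
    } else {
      z <- (x - expected) / sqrt(v)
      p <- switch(method,
        hypergeometric = stats::phyper(x - 1L, K, N - K, n,
                                       lower.tail = FALSE),
        binomial = stats::pbinom(x - 1L, n, K / N, lower.tail = FALSE),
        fisher = stats::fisher.test(
          matrix(c(x, n - x, K - x, N - K - n + x), nrow = 2L),
          alternative = "greater")$p.value)
    }
    data.frame(term_id = a$term_id, term_name = a$term_name,
               x = x, n = n, K = K, N = N, expected = expected,
               z_score = z, p_value = p, degenerate = degenerate,
               overlap_ids = paste(sort(overlap), collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$fdr <- bh_fdr(out$p_value)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("term_id", "term_name", "x", "n", "K", "N", "expected",
          "z_score", "p_value", "fdr", "degenerate", "overlap_ids")]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, preserving input order.
#'
#' @param p_values Numeric vector of probabilities in \[0, 1\].
#' @return Adjusted values in \[0, 1\], same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
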