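# Information-content semantic similarity over an annotation ontology:
# true-path annotation propagation, term IC, most-informative-common-
# ancestor (MICA) term similarity with Lin normalization, best-match entity
# combiners, and the partner-count summary used to flag entities that are
# similar to many others.

#' Construct and validate an ontology DAG
#'
#' Terms with child-to-parent is-a links and direct entity annotations.
#' Validation enforces acyclicity, a unique root reachable from every term,
#' and that every annotated term exists.
#'
#' @param edges Data.frame with columns `child`, `parent` (term IDs).
#' @param annotations Data.frame with columns `entity`, `term`: direct
#'   annotations; the true-path rule (annotation to a term implies
#'   annotation to all its ancestors) is applied by consumers.
#' @return An `ontology_dag` object with elements `terms`, `edges`,
#'   `annotations`, `ancestors` (per-term ancestor closures including the
#'   term itself) and `root`.
#' @export
ontology_dag <- function(edges, annotations) {
  stopifnot(all(c("child", "parent") %in% names(edges)),
            all(c("entity", "term") %in% names(annotations)))
  edges <- unique(data.frame(child = as.character(edges$child),
                             parent = as.character(edges$parent),
                             stringsAsFactors = FALSE))
  terms <- sort(unique(c(edges$child, edges$parent)))
  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                     directed = TRUE,
                                     vertices = data.frame(name = terms))
  if (!igraph::is_dag(g)) stop("ontology contains a cycle")
  roots <- terms[igraph::degree(g, mode = "out") == 0L]
  if (length(roots) != 1L)
    stop("ontology must have exactly one root; found: ",
         paste(roots, collapse = ", "))
  anc <- lapply(terms, function(t)
    names(igraph::subcomponent(g, t, mode = "out")))
  names(anc) <- terms
  if (!all(vapply(anc, function(a) roots %in% a, logical(1))))
    stop("root is not reachable from every term")
  bad <- setdiff(unique(as.character(annotations$term)), terms)
  if (length(bad) > 0L)
    stop("annotations reference unknown term(s): ",
         paste(bad, collapse = ", "))
  annotations <- unique(data.frame(entity = as.character(annotations$entity),
                                   term = as.character(annotations$term),
                                   stringsAsFactors = FALSE))
  structure(list(terms = terms, edges = edges, annotations = annotations,
                 ancestors = anc, root = roots),
            class = "ontology_dag")
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("<ontology_dag> %d terms, %d edges, %d entities (root %s)\n",
              length(x$terms), nrow(x$edges),
              length(unique(x$annotations$entity)), x$root))
  invisible(x)
}

#' Read an ontology from edge-list and annotation TSVs
#'
#' @param edge_path TSV with columns `child`, `parent`.
#' @param annotation_path TSV with columns `entity`, `term`.
#' @return An [ontology_dag()].
#' @export
read_ontology <- function(edge_path, annotation_path) {
  ontology_dag(utils::read.delim(edge_path, stringsAsFactors = FALSE,
                              comment.char = "#"),
               utils::read.delim(annotation_path, stringsAsFactors = FALSE,
                              comment.char = "#"))
}

#' Information content of every term
#'
#' Direct annotations are propagated to all ancestors (true-path rule);
#' the frequency of a term is the fraction of annotated entities annotated
#' at or below it, and `ic = -log10(frequency)`. The root, which covers all
#' entities, has IC 0, and IC never decreases from parent to child.
#'
#' @param dag An [ontology_dag()].
#' @return A `term_ic` object: named numeric vector of ICs with attributes
#'   `counts` (propagated entity counts) and `n_entities`.
#' @export
compute_ic <- function(dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  entities <- unique(dag$annotations$entity)
  if (length(entities) == 0L) stop("ontology has no annotated entities")
  # propagated annotation: entity e covers term t iff t is an ancestor of
  # one of e's direct terms
  covered <- lapply(split(dag$annotations$term, dag$annotations$entity),
                    function(ts) unique(unlist(dag$ancestors[ts])))
  counts <- table(factor(unlist(covered), levels = dag$terms))
  counts <- as.integer(counts)
  names(counts) <- dag$terms
  freq <- counts / length(entities)
  ic <- ifelse(counts > 0L, -log10(freq), Inf)
  structure(ic, counts = counts, n_entities = length(entities),
            class = "term_ic")
}

#' MICA term similarity
#'
#' The most informative common ancestor (MICA) of two terms is the common
#' ancestor (the terms themselves included) of maximal IC. The default
#' score is the Lin normalization `2 ic(MICA) / (ic(t1) + ic(t2))`, which
#' lies in \[0, 1\] and is defined as 0 when the denominator is 0 (both
#' terms at the root); `normalize = FALSE` returns the raw Resnik score
#' `ic(MICA)` instead.
#'
#' @param t1,t2 Term IDs.
#' @param dag An [ontology_dag()].
#' @param ic A [compute_ic()] result.
#' @param normalize Lin normalization (default) or raw Resnik IC.
#' @return Similarity score.
#' @export
term_similarity <- function(t1, t2, dag, ic, normalize = TRUE) {
  if (!(t1 %in% dag$terms) || !(t2 %in% dag$terms))
    stop("unknown term: ", paste(setdiff(c(t1, t2), dag$terms),
                                 collapse = ", "))
  common <- intersect(dag$ancestors[[t1]], dag$ancestors[[t2]])
  ic_common <- unclass(ic)[common]
  ic_common <- ic_common[is.finite(ic_common)]
  mica <- if (length(ic_common) > 0L) max(ic_common) else 0
  if (!normalize) return(unname(mica))
  denom <- unclass(ic)[[t1]] + unclass(ic)[[t2]]
  if (!is.finite(denom) || denom <= 0) return(0)
  unname(2 * mica / denom)
}

#' Entity similarity from annotation profiles
#'
#' From the pairwise term-similarity matrix `S` between the two entities'
#' direct annotation profiles: `best-match-average` averages each term's
#' best match over both directions, `maximum` is the matrix maximum and
#' `complete` is the most conservative, the minimum over the row-wise best
#' matches of both directions.
#'
#' @param e1,e2 Entity IDs with at least one direct annotation each.
#' @param dag An [ontology_dag()].
#' @param ic A [compute_ic()] result.
#' @param combine One of `"best-match-average"`, `"maximum"`, `"complete"`.
#' @return Similarity in \[0, 1\].
#' @export
entity_similarity <- function(e1, e2, dag, ic,
                              combine = c("best-match-average", "maximum",
                                          "complete")) {
  combine <- match.arg(combine)
  prof <- split(dag$annotations$term, dag$annotations$entity)
  for (e in c(e1, e2))
    if (is.null(prof[[e]]) || length(prof[[e]]) == 0L)
      stop("entity without annotations: ", e)
  p1 <- unique(prof[[e1]]); p2 <- unique(prof[[e2]])
  S <- outer(seq_along(p1), seq_along(p2),
             Vectorize(function(i, j) term_similarity(p1[i], p2[j], dag, ic)))
  best_rows <- apply(S, 1L, max)
  best_cols <- apply(S, 2L, max)
  switch(combine,
         "best-match-average" = mean(c(best_rows, best_cols)),
         "maximum" = max(S),
         "complete" = min(min(best_rows), min(best_cols)))
}

#' Pairwise entity similarity matrix
#'
#' Symmetric matrix of [entity_similarity()] scores; the diagonal is 1 for
#' every annotated entity.
#'
#' @param dag An [ontology_dag()].
#' @param ic A [compute_ic()] result (computed from `dag` if omitted).
#' @param entities Entities to include (default: all annotated entities,
#'   sorted).
#' @param combine Combiner passed to [entity_similarity()].
#' @return Numeric matrix with entity dimnames.
#' @export
similarity_matrix <- function(dag, ic = compute_ic(dag), entities = NULL,
                              combine = "best-match-average") {
  if (is.null(entities)) entities <- sort(unique(dag$annotations$entity))
  m <- diag(1, length(entities))
  dimnames(m) <- list(entities, entities)
  if (length(entities) >= 2L) {
    for (i in seq_len(length(entities) - 1L)) {
      for (j in seq(i + 1L, length(entities))) {
        s <- entity_similarity(entities[i], entities[j], dag, ic,
                               combine = combine)
        m[i, j] <- s
        m[j, i] <- s
      }
    }
  }
  m
}

#' Similarity partner counts
#'
#' For each entity, the number of OTHER entities whose similarity score is
#' strictly above `threshold`, and the subset reaching `min_partners`
#' partners (the study's rule: score above 0.5 with at least five other
#' SNPs).
#'
#' @param matrix Symmetric similarity matrix with entity dimnames.
#' @param threshold Score threshold in \[0, 1\] (strict inequality).
#' @param min_partners Minimum partner count for the qualifying subset.
#' @return List with `counts` (named integer vector) and `qualifying`
#'   (character vector of entity IDs).
#' @export
similarity_partner_counts <- function(matrix, threshold = 0.5,
                                      min_partners = 5L) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix),
            threshold >= 0, threshold <= 1, min_partners >= 0L)
  counts <- vapply(seq_len(nrow(matrix)), function(i)
    sum(matrix[i, -i] > threshold), integer(1))
  names(counts) <- rownames(matrix)
  list(counts = counts,
       qualifying = names(counts)[counts >= min_partners])
}

#' Write a similarity matrix as TSV
#'
#' @param matrix Similarity matrix with entity dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(matrix, path) {
  df <- data.frame(entity = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
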