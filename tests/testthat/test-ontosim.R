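# Toy DAG used throughout:          R
#                                  / \
#                                 A   B
#                                / \   \
#                               C   D   E
toy_dag <- function(annotations = NULL) {
  edges <- data.frame(child = c("A", "B", "C", "D", "E"),
                      parent = c("R", "R", "A", "A", "B"))
  if (is.null(annotations))
    annotations <- data.frame(entity = c("e1", "e2", "e3", "e4"),
                              term = c("C", "D", "E", "B"))
  ontology_dag(edges, annotations)
}

test_that("DAG validation rejects cycles, multiple roots, unknown terms", {
  expect_error(ontology_dag(
    data.frame(child = c("A", "B"), parent = c("B", "A")),
    data.frame(entity = "e", term = "A")), "cycle")
  expect_error(ontology_dag(
    data.frame(child = c("A", "B"), parent = c("R1", "R2")),
    data.frame(entity = "e", term = "A")), "root")
  expect_error(ontology_dag(
    data.frame(child = "A", parent = "R"),
    data.frame(entity = "e", term = "ZZZ")), "unknown term")
})

test_that("IC is zero at the root and follows propagated frequencies", {
  dag <- toy_dag()
  ic <- compute_ic(dag)
  expect_equal(unname(unclass(ic)["R"]), 0)
  # C annotates 1 of 4 entities
  expect_equal(unname(unclass(ic)["C"]), -log10(1 / 4))
  # A covers e1 (via C) and e2 (via D)
  expect_equal(unname(unclass(ic)["A"]), -log10(2 / 4))
  # B covers e3 (via E) and e4 (direct)
  expect_equal(unname(unclass(ic)["B"]), -log10(2 / 4))
})

test_that("a leaf annotated by 1 of 10 entities has IC exactly 1", {
  edges <- data.frame(child = sprintf("L%d", 1:10), parent = "R")
  anns <- data.frame(entity = sprintf("e%d", 1:10),
                     term = sprintf("L%d", 1:10))
  ic <- compute_ic(ontology_dag(edges, anns))
  expect_equal(unname(unclass(ic)["L1"]), 1.0)
})

test_that("IC is monotone non-decreasing from parent to child", {
  for (seed in 1:20) {
    sim <- simulate_ontology(seed, n_terms = 12L, n_entities = 5L)
    dag <- ontology_dag(sim$edges, sim$annotations)
    ic <- compute_ic(dag)
    v <- unclass(ic)
    for (k in seq_len(nrow(dag$edges))) {
      child_ic <- v[[dag$edges$child[k]]]
      parent_ic <- v[[dag$edges$parent[k]]]
      if (is.finite(child_ic))
        expect_gte(child_ic, parent_ic)
    }
  }
})

test_that("term self-similarity is 1 and root-only common ancestry gives 0", {
  dag <- toy_dag()
  ic <- compute_ic(dag)
  expect_equal(term_similarity("C", "C", dag, ic), 1.0)
  # C and E share only the root
  expect_equal(term_similarity("C", "E", dag, ic), 0.0)
})

test_that("MICA matches the exhaustive common-ancestor scan on the toy DAG", {
  dag <- toy_dag()
  ic <- compute_ic(dag)
  # C vs D: common ancestors {A, R}; MICA = A
  icv <- unclass(ic)
  expected <- 2 * icv[["A"]] / (icv[["C"]] + icv[["D"]])
  expect_equal(term_similarity("C", "D", dag, ic), expected)
  # raw Resnik score behind the flag
  expect_equal(term_similarity("C", "D", dag, ic, normalize = FALSE),
               icv[["A"]])
  expect_error(term_similarity("C", "nope", dag, ic), "unknown term")
})

test_that("on a chain DAG every pair's MICA is the shallower term", {
  edges <- data.frame(child = c("A", "B", "C"), parent = c("R", "A", "B"))
  anns <- data.frame(entity = c("e1", "e2", "e3"), term = c("A", "B", "C"))
  dag <- ontology_dag(edges, anns)
  ic <- compute_ic(dag)
  icv <- unclass(ic)
  expect_equal(term_similarity("B", "C", dag, ic),
               2 * icv[["B"]] / (icv[["B"]] + icv[["C"]]))
  expect_equal(term_similarity("A", "C", dag, ic),
               2 * icv[["A"]] / (icv[["A"]] + icv[["C"]]))
})

test_that("identical profiles score 1 and root-only relatives score 0", {
  dag <- toy_dag(data.frame(entity = c("e1", "e1", "e2", "e2", "e3"),
                            term = c("C", "D", "C", "D", "E")))
  ic <- compute_ic(dag)
  expect_equal(entity_similarity("e1", "e2", dag, ic), 1.0)
  # e3 (E, under B) shares only the root with e1's profile
  expect_equal(entity_similarity("e1", "e3", dag, ic), 0.0)
  expect_error(entity_similarity("e1", "zz", dag, ic), "zz")
})

test_that("a 3x2-profile pair matches the hand-enumerated best-match scores", {
  dag <- toy_dag(data.frame(entity = c("x", "x", "x", "y", "y"),
                            term = c("C", "D", "E", "D", "B")))
  ic <- compute_ic(dag)
  icv <- unclass(ic)
  lin <- function(t1, t2) term_similarity(t1, t2, dag, ic)
  S <- rbind(c(lin("C", "D"), lin("C", "B")),
             c(lin("D", "D"), lin("D", "B")),
             c(lin("E", "D"), lin("E", "B")))
  bma <- mean(c(apply(S, 1, max), apply(S, 2, max)))
  expect_equal(entity_similarity("x", "y", dag, ic), bma)
  expect_equal(entity_similarity("x", "y", dag, ic, combine = "maximum"),
               max(S))
  expect_equal(entity_similarity("x", "y", dag, ic, combine = "complete"),
               min(min(apply(S, 1, max)), min(apply(S, 2, max))))
})

test_that("combiners are bounded (complete <= bma <= maximum) and symmetric", {
  for (seed in 1:15) {
    sim <- simulate_ontology(seed, n_terms = 12L, n_entities = 4L,
                             annotation_rate = 3L)
    dag <- ontology_dag(sim$edges, sim$annotations)
    ic <- compute_ic(dag)
    ents <- unique(sim$annotations$entity)
    pairs <- utils::combn(ents, 2L)
    for (k in seq_len(ncol(pairs))) {
      e1 <- pairs[1, k]; e2 <- pairs[2, k]
      cmpl <- entity_similarity(e1, e2, dag, ic, combine = "complete")
      bma <- entity_similarity(e1, e2, dag, ic)
      mx <- entity_similarity(e1, e2, dag, ic, combine = "maximum")
      expect_lte(cmpl, bma + 1e-12)
      expect_lte(bma, mx + 1e-12)
      expect_true(all(c(cmpl, bma, mx) >= 0 & c(cmpl, bma, mx) <= 1))
      expect_equal(bma, entity_similarity(e2, e1, dag, ic))
    }
  }
})

test_that("implementation matches the generator's enumeration oracle", {
  for (seed in 1:30) {
    sim <- simulate_ontology(seed, n_terms = 15L, n_entities = 5L)
    dag <- ontology_dag(sim$edges, sim$annotations)
    ic <- compute_ic(dag)
    expect_equal(unclass(ic)[names(sim$truth_ic)],
                 sim$truth_ic, tolerance = 1e-9)
    for (k in seq_len(nrow(sim$truth_sim))) {
      row <- sim$truth_sim[k, ]
      expect_equal(
        entity_similarity(row$e1, row$e2, dag, ic, combine = row$combine),
        row$score, tolerance = 1e-9)
    }
  }
})

test_that("similarity matrix is symmetric with unit diagonal", {
  sim <- simulate_ontology(42L, n_terms = 12L, n_entities = 5L)
  dag <- ontology_dag(sim$edges, sim$annotations)
  m <- similarity_matrix(dag)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, nrow(m)))
  expect_true(all(m >= 0 & m <= 1))
})

test_that("partner counts use strict thresholds and match a recount", {
  m <- matrix(0.9, 3, 3); diag(m) <- 1
  dimnames(m) <- list(letters[1:3], letters[1:3])
  pc <- similarity_partner_counts(m, 0.5, 2L)
  expect_equal(unname(pc$counts), c(2L, 2L, 2L))
  expect_setequal(pc$qualifying, letters[1:3])
  # identity matrix: off-diagonal 0 is NOT strictly above 0 threshold
  id <- diag(1, 4); dimnames(id) <- list(letters[1:4], letters[1:4])
  expect_length(similarity_partner_counts(id, 0, 1L)$qualifying, 0L)
  # random symmetric matrix vs brute-force double loop
  set.seed(5)
  r <- matrix(runif(100), 10)
  r <- (r + t(r)) / 2; diag(r) <- 1
  dimnames(r) <- list(sprintf("s%d", 1:10), sprintf("s%d", 1:10))
  pc2 <- similarity_partner_counts(r, 0.5, 3L)
  expect_equal(pc2$counts, oracle_partner_counts(r, 0.5))
  # invariant to entity reordering
  perm <- sample(10)
  pc3 <- similarity_partner_counts(r[perm, perm], 0.5, 3L)
  expect_equal(pc3$counts[names(pc2$counts)], pc2$counts)
})

test_that("ontology TSV round-trip preserves the DAG", {
  d <- withr::local_tempdir()
  sim <- simulate_ontology(9L, dir = d)
  dag <- read_ontology(file.path(d, "ontology_edges.tsv"),
                       file.path(d, "ontology_annotations.tsv"))
  dag2 <- ontology_dag(sim$edges, sim$annotations)
  expect_setequal(dag$terms, dag2$terms)
  expect_equal(compute_ic(dag)[dag2$terms], compute_ic(dag2)[dag2$terms])
})
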