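#!/usr/bin/env Rscript
# Stage 3 — semantic similarity between annotated entities.
#
# The original analysis scored SNP-SNP relatedness over the trait
# ontology's annotation profiles; that annotation snapshot is not
# available offline, so this driver runs the same machinery on a simulated
# ontology with enumeration-verified ground truth: IC per term, MICA-based
# Lin similarity, best-match-average combiner, and the partner-count rule
# (score > 0.5 with >= 5 partners).

suppressMessages(library(pleioband))
dir.create("results", showWarnings = FALSE)

sim <- simulate_ontology(seed = 1L, n_terms = 40L, n_entities = 20L,
                         branching = 2L, annotation_rate = 3L)
dag <- ontology_dag(sim$edges, sim$annotations)
ic <- compute_ic(dag)
m <- similarity_matrix(dag, ic, combine = "best-match-average")
pc <- similarity_partner_counts(m, threshold = 0.5, min_partners = 5L)

cat(sprintf("ontology: %d terms, %d entities; IC range [0, %.3f]\n",
            length(dag$terms), nrow(m), max(unclass(ic)[is.finite(unclass(ic))])))
cat(sprintf("%d of %d entities have similarity > 0.5 with >= 5 others: %s\n",
            length(pc$qualifying), nrow(m),
            paste(pc$qualifying, collapse = ", ")))
write_similarity_matrix(m, file.path("results", "similarity_matrix.tsv"))
utils::write.table(
  data.frame(entity = names(pc$counts), partners = unname(pc$counts),
             qualifying = names(pc$counts) %in% pc$qualifying),
  file.path("results", "similarity_partners.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/similarity_matrix.tsv, similarity_partners.tsv\n")
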