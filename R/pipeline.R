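# End-to-end orchestration: catalog -> phenotype assignment -> significance
# filter -> region sets -> Venn partition -> shared-region selection ->
# SNP-clusters -> gene list, with optional enrichment, similarity,
# variant-burden and expression stages. Later stages run only when their
# inputs are configured; every count in the report is recomputed from the
# stage outputs it summarizes.

#' Build a validated pipeline configuration
#'
#' All thresholds of the workflow in one place. Unknown fields are
#' rejected.
#'
#' @param catalog Either a path to a catalog TSV or a parsed association
#'   data.frame.
#' @param queries Phenotype trait queries (default [uaediab_phenotypes()]).
#' @param alpha Significance filter level (default 0.05).
#' @param min_phenotypes Minimum phenotypes sharing a region (default 4).
#' @param required_group Anchor group every selected cell must contain
#'   (default `"T1D/T2D"`; `NULL` disables).
#' @param alias_map Gene alias map (default [default_alias_map()]).
#' @param enrichment Optional list: `annotations` (list of
#'   [annotation_set()]), `universe`, `method`.
#' @param similarity Optional list: `dag` (an [ontology_dag()]),
#'   `combine`, `threshold`, `min_partners`.
#' @param variants Optional list: `vcf_paths` (named), `intervals`
#'   (data.frame), `exclusion_max`.
#' @param expression Optional list: `eset` (an [expression_set()]),
#'   `genes`, `marker`.
#' @param seed Integer seed recorded in the report (the core stages are
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(catalog, queries = uaediab_phenotypes(),
                            alpha = 0.05, min_phenotypes = 4L,
                            required_group = "T1D/T2D",
                            alias_map = default_alias_map(),
                            enrichment = NULL, similarity = NULL,
                            variants = NULL, expression = NULL,
                            seed = 1L) {
  check_keys <- function(x, allowed, what) {
    bad <- setdiff(names(x), allowed)
    if (length(bad) > 0L)
      stop("unknown ", what, " field(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(enrichment))
    check_keys(enrichment, c("annotations", "universe", "method"),
               "enrichment")
  if (!is.null(similarity))
    check_keys(similarity, c("dag", "combine", "threshold", "min_partners"),
               "similarity")
  if (!is.null(variants))
    check_keys(variants, c("vcf_paths", "intervals", "exclusion_max"),
               "variants")
  if (!is.null(expression))
    check_keys(expression, c("eset", "genes", "marker"), "expression")
  structure(list(catalog = catalog, queries = queries, alpha = alpha,
                 min_phenotypes = min_phenotypes,
                 required_group = required_group, alias_map = alias_map,
                 enrichment = enrichment, similarity = similarity,
                 variants = variants, expression = expression, seed = seed),
            class = "pipeline_config")
}

#' Run the workflow end to end
#'
#' Runs the stages in order and returns a report whose headline numbers
#' (region, SNP and gene counts) are recomputed from the returned stage
#' outputs. Optional stages are skipped (and recorded as skipped) when
#' their inputs are absent.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list with elements `grouped`, `n_filtered`,
#'   `region_sets`, `partition`, `shared_regions`, `clusters`, `genes`,
#'   `genes_unmerged`, `enrichment`, `similarity`, `variants`,
#'   `expression`, `skipped`, `params`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  associations <- if (is.character(config$catalog))
    parse_catalog(config$catalog) else config$catalog

  grouped <- assign_phenotype_groups(associations, config$queries)
  grouped_sig <- lapply(grouped[setdiff(names(grouped), "unassigned")],
                        function(df)
                          suppressWarnings(filter_significant(df,
                                                              config$alpha)))
  if (all(vapply(grouped_sig, nrow, integer(1)) == 0L))
    stop("region stage: no assigned associations survive the filter")

  region_sets <- regions_per_phenotype(grouped_sig)
  partition <- venn_partition(region_sets)
  shared <- select_shared_regions(partition, config$min_phenotypes,
                                  config$required_group)
  filtered_all <- do.call(rbind, grouped_sig)
  filtered_all <- filtered_all[!duplicated(
    paste(filtered_all$snp_id, filtered_all$trait, filtered_all$source_row)),
    , drop = FALSE]
  clusters <- extract_snp_clusters(shared, filtered_all)
  genes <- collect_genes(clusters, config$alias_map)
  genes_unmerged <- collect_genes(clusters, alias_map = character(0))

  skipped <- character(0)
  enr <- sim <- var_res <- expr_res <- NULL
  if (!is.null(config$enrichment)) {
    e <- config$enrichment
    query <- unique(unlist(lapply(clusters, `[[`, "snps")))
    enr <- enrich_terms(query, e$annotations, e$universe,
                        method = if (is.null(e$method)) "hypergeometric"
                        else e$method)
  } else skipped <- c(skipped, "enrichment")
  if (!is.null(config$similarity)) {
    s <- config$similarity
    ic <- compute_ic(s$dag)
    m <- similarity_matrix(s$dag, ic,
                           combine = if (is.null(s$combine))
                             "best-match-average" else s$combine)
    sim <- similarity_partner_counts(
      m,
      threshold = if (is.null(s$threshold)) 0.5 else s$threshold,
      min_partners = if (is.null(s$min_partners)) 5L else s$min_partners)
    sim$matrix <- m
  } else skipped <- c(skipped, "similarity")
  if (!is.null(config$variants)) {
    v <- config$variants
    counts <- count_snps_per_gene(v$vcf_paths, v$intervals)
    thr <- median_threshold(counts, exclusion_max =
                              if (is.null(v$exclusion_max)) 1L
                              else v$exclusion_max)
    var_res <- list(counts = counts, threshold = thr,
                    candidates = select_candidate_genes(counts, thr))
  } else skipped <- c(skipped, "variants")
  if (!is.null(config$expression)) {
    x <- config$expression
    expr_res <- list(
      tests = compare_expression_table(x$eset, x$genes),
      ranking = rank_mean_expression(x$eset, x$genes, x$marker))
  } else skipped <- c(skipped, "expression")

  structure(list(
    grouped = grouped,
    n_filtered = vapply(grouped_sig, nrow, integer(1)),
    region_sets = region_sets, partition = partition,
    shared_regions = shared, clusters = clusters,
    genes = genes, genes_unmerged = genes_unmerged,
    enrichment = enr, similarity = sim, variants = var_res,
    expression = expr_res, skipped = skipped,
    params = config[c("alpha", "min_phenotypes", "required_group", "seed")]),
    class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  n_snps <- length(unique(unlist(lapply(x$clusters, `[[`, "snps"))))
  cat("<pipeline_report>\n")
  cat(sprintf("  regions per phenotype: %s\n",
              paste(sprintf("%s=%d", names(x$region_sets),
                            lengths(x$region_sets)), collapse = ", ")))
  cat(sprintf("  shared regions (>=%d phenotypes%s): %d [%s]\n",
              x$params$min_phenotypes,
              if (is.null(x$params$required_group)) "" else
                paste0(", anchored on ", x$params$required_group),
              length(x$shared_regions),
              paste(x$shared_regions, collapse = ", ")))
  cat(sprintf("  SNPs across clusters: %d\n", n_snps))
  cat(sprintf("  reported genes: %d (alias-merged), %d (unmerged)\n",
              length(x$genes), length(x$genes_unmerged)))
  if (!is.null(x$variants))
    cat(sprintf("  variant stage: pooled median threshold %.1f, %d candidate gene(s)\n",
                x$variants$threshold, length(x$variants$candidates)))
  if (!is.null(x$similarity))
    cat(sprintf("  similarity stage: %d entities qualifying\n",
                length(x$similarity$qualifying)))
  if (length(x$skipped) > 0L)
    cat("  skipped stages:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Write the shared-region and cluster reports as TSVs
#'
#' Writes the shared-region report (region, phenotype combination, number
#' of SNPs), the SNP-cluster table and the gene list.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  part_df <- as.data.frame(report$partition)
  combo_of <- stats::setNames(part_df$combo, part_df$region)
  shared_df <- data.frame(
    region = vapply(report$clusters, `[[`, "", "region"),
    combo = combo_of[vapply(report$clusters, `[[`, "", "region")],
    n_snps = vapply(report$clusters, function(cl) length(cl$snps),
                    integer(1)), stringsAsFactors = FALSE)
  utils::write.table(shared_df, file.path(dir, "shared_regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cluster_df <- do.call(rbind, lapply(report$clusters, function(cl)
    data.frame(region = cl$region, snp_id = cl$snps,
               stringsAsFactors = FALSE)))
  utils::write.table(cluster_df, file.path(dir, "snp_clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(report$genes, file.path(dir, "genes.txt"))
  utils::write.table(part_df, file.path(dir, "partition_cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
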