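# Cytoband region sets per phenotype, the exclusive Venn partition, shared
# region selection, SNP-cluster extraction and gene collection. Intersection
# is at cytoband-label granularity (exact string equality); sub-bands are
# never merged with parent bands.

# Canonical key for a phenotype combination: sorted, "+"-joined.
.combo_key <- function(groups) paste(sort(unique(groups)), collapse = "+")

# chromosome-then-band ordering of cytoband labels ("11p11.2" < "15q26.1";
# X/Y after numerics)
.order_regions <- function(regions) {
  if (length(regions) == 0L) return(character(0))
  chrom <- sub("^([0-9XYxy]+)[pq].*$", "\\1", regions)
  num <- suppressWarnings(as.integer(chrom))
  num[is.na(num)] <- 100L + match(toupper(chrom[is.na(num)]), c("X", "Y"))
  regions[order(num, regions)]
}

#' Cytoband sets per phenotype group
#'
#' A cytoband enters a group's set iff at least one of the group's
#' (already filtered) associations lies in it.
#'
#' @param grouped Named list of association data.frames, as from
#'   [assign_phenotype_groups()]; a `"unassigned"` element is ignored.
#' @return Named list mapping group name to a character vector of distinct
#'   cytoband labels.
#' @export
regions_per_phenotype <- function(grouped) {
  grouped <- grouped[setdiff(names(grouped), "unassigned")]
  lapply(grouped, function(df) {
    r <- unique(df$cytoband)
    r[nzchar(r)]
  })
}

#' Exclusive Venn partition of cytoband sets
#'
#' Assigns every cytoband appearing in any input set to the cell of exactly
#' the groups whose sets contain it. Cells are pairwise disjoint and empty
#' cells are omitted.
#'
#' @param region_sets Named list of cytoband character vectors (one element
#'   per group, distinct names).
#' @return A `venn_partition` object: a named list of cytoband vectors,
#'   keyed by the `+`-joined (alphabetical) phenotype combination, with a
#'   `groups` attribute.
#' @export
venn_partition <- function(region_sets) {
  stopifnot(length(region_sets) >= 1L)
  groups <- names(region_sets)
  if (is.null(groups) || any(!nzchar(groups)))
    stop("region sets must be named by group")
  if (anyDuplicated(groups)) stop("duplicate group names")
  all_regions <- unique(unlist(region_sets, use.names = FALSE))
  membership <- vapply(all_regions, function(r) {
    .combo_key(groups[vapply(region_sets, function(s) r %in% s, logical(1))])
  }, character(1))
  cells <- split(all_regions, membership)
  cells <- lapply(cells, .order_regions)
  # conservation check: disjoint cells covering every input region
  stopifnot(sum(lengths(cells)) == length(all_regions),
            !anyDuplicated(unlist(cells)))
  structure(cells, groups = groups, class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("<venn_partition> over groups:",
      paste(attr(x, "groups"), collapse = ", "), "\n")
  for (k in names(x))
    cat(sprintf("  [%s] %d region(s)\n", k, length(x[[k]])))
  invisible(x)
}

#' Partition cells as a data.frame
#'
#' @param x A [venn_partition()].
#' @param ... Unused.
#' @return Data.frame with columns `combo`, `n_phenotypes`, `region`.
#' @export
as.data.frame.venn_partition <- function(x, ...) {
  out <- do.call(rbind, lapply(names(x), function(k) {
    data.frame(combo = k,
               n_phenotypes = length(strsplit(k, "+", fixed = TRUE)[[1]]),
               region = x[[k]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Select regions shared by at least k phenotypes
#'
#' Union of partition cells whose phenotype combination has size at least
#' `min_phenotypes` and, when `required_group` is given, contains that
#' group (the "anchored" constraint: in the study every reported cell
#' includes the diabetes group).
#'
#' @param partition A [venn_partition()].
#' @param min_phenotypes Minimum number of phenotypes sharing a region.
#' @param required_group Optional group label every selected cell must
#'   contain; `NULL` to disable.
#' @return Character vector of cytoband labels in chromosome-band order.
#' @export
select_shared_regions <- function(partition, min_phenotypes = 4L,
                                  required_group = "T1D/T2D") {
  stopifnot(inherits(partition, "venn_partition"), min_phenotypes >= 1L)
  groups <- attr(partition, "groups")
  if (!is.null(required_group) && !(required_group %in% groups))
    stop("required_group '", required_group,
         "' is not among the partition's groups")
  keep <- vapply(names(partition), function(k) {
    combo <- strsplit(k, "+", fixed = TRUE)[[1]]
    length(combo) >= min_phenotypes &&
      (is.null(required_group) || required_group %in% combo)
  }, logical(1))
  .order_regions(unlist(partition[keep], use.names = FALSE))
}

#' Extract SNP-clusters for selected regions
#'
#' One cluster per selected cytoband holding the distinct SNPs (by rsID)
#' whose cytoband equals the region, with the union of their mapped and
#' reported genes. Regions with no associations are omitted. Band/position
#' disagreements are not resolved: the band column is trusted.
#'
#' @param regions Character vector of selected cytoband labels.
#' @param associations Phenotype-assigned, significance-filtered
#'   association data.frame.
#' @return A list of `snp_cluster` objects (fields `region`, `snps`,
#'   `mapped_genes`, `reported_genes`), ordered by chromosome then band.
#' @export
extract_snp_clusters <- function(regions, associations) {
  regions <- .order_regions(unique(regions))
  out <- list()
  for (r in regions) {
    hits <- associations[associations$cytoband == r, , drop = FALSE]
    if (nrow(hits) == 0L) next
    snps <- unique(hits$snp_id)
    mg <- sort(unique(unlist(lapply(hits$mapped_genes, .split_genes))))
    rg_by_snp <- lapply(split(hits$reported_genes, hits$snp_id),
                        function(v) unique(unlist(lapply(v, .split_genes))))
    rg <- sort(unique(unlist(rg_by_snp)))
    out[[r]] <- structure(list(region = r, snps = snps, mapped_genes = mg,
                               reported_genes = rg), class = "snp_cluster")
  }
  unname(out[.order_regions(names(out))])
}

#' @export
print.snp_cluster <- function(x, ...) {
  cat(sprintf("<snp_cluster> %s: %d SNP(s), %d reported gene(s)\n",
              x$region, length(x$snps), length(x$reported_genes)))
  invisible(x)
}

#' Default gene alias map
#'
#' Ships with the single merge `TCF2 -> HNF1B` (TCF2 is the legacy symbol
#' of HNF1B); extend as needed.
#'
#' @return Named character vector mapping alias to canonical symbol.
#' @export
default_alias_map <- function() c(TCF2 = "HNF1B")

#' Collect distinct reported genes across clusters
#'
#' Distinct canonicalized reported-gene symbols across clusters, sentinel
#' excluded, in deterministic order (by region of first appearance, then
#' symbol within region).
#'
#' @param clusters List of clusters from [extract_snp_clusters()].
#' @param alias_map Named character vector mapping alias symbols to their
#'   canonical symbol; may be empty. See [default_alias_map()].
#' @return Character vector of gene symbols.
#' @export
collect_genes <- function(clusters, alias_map = default_alias_map()) {
  seen <- character(0)
  for (cl in clusters) {
    g <- cl$reported_genes
    hit <- g %in% names(alias_map)
    g[hit] <- unname(alias_map[g[hit]])
    seen <- c(seen, sort(unique(g)))
  }
  seen[!duplicated(seen)]
}

#' Report band/position disagreements
#'
#' Flags associations whose cytoband's chromosome prefix disagrees with the
#' record's chromosome column (e.g. a band labelled `6q21` at a position on
#' another arm cannot be detected without a band track, but a band on the
#' wrong chromosome can). The pipeline trusts the band column; this report
#' only surfaces suspect rows.
#'
#' @param associations Association data.frame.
#' @return Data.frame of suspect rows (possibly empty).
#' @export
band_position_warnings <- function(associations) {
  band_chrom <- sub("^([0-9XYxy]+)[pq].*$", "\\1", associations$cytoband)
  bad <- nzchar(associations$chromosome) &
    band_chrom != as.character(associations$chromosome)
  associations[bad, , drop = FALSE]
}
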