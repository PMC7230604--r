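# Per-gene SNV counting from VCFs over a gene-interval panel, the pooled
# median threshold, and the every-sample candidate-gene rule.

#' Read gene intervals
#'
#' Reads a gene-interval panel either as 1-based inclusive TSV (columns
#' `gene`, `chromosome`, `start`, `end`) or as 4-column BED
#' (chrom, 0-based half-open start, end, name), converted internally to
#' 1-based inclusive coordinates.
#'
#' @param path Interval file.
#' @param format `"tsv"` (default) or `"bed"`.
#' @return Data.frame with columns `gene`, `chromosome`, `start`, `end`
#'   (1-based, both ends inclusive).
#' @export
read_gene_intervals <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             comment.char = "#")
    stopifnot(all(c("gene", "chromosome", "start", "end") %in% names(tab)))
  } else {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                             comment.char = "#",
                             col.names = c("chromosome", "start", "end",
                                           "gene"))
    tab$start <- tab$start + 1L  # BED is 0-based half-open
    tab <- tab[, c("gene", "chromosome", "start", "end")]
  }
  stopifnot(all(tab$start <= tab$end))
  tab
}

# GRanges for a gene-interval data.frame
.interval_granges <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$chromosome,
    ranges = IRanges::IRanges(start = intervals$start, end = intervals$end),
    gene = intervals$gene)
}

#' Count SNVs per gene per sample
#'
#' Counts, for every sample VCF and every panel gene, the variant sites
#' that (a) are single-nucleotide substitutions — 1 bp REF and at least one
#' 1 bp non-symbolic ALT allele — (b) fall within one of the gene's
#' intervals (1-based, ends inclusive), and (c) carry a FILTER of `PASS`
#' or `.`. Multi-allelic records count once per site; genotype status is
#' ignored (a site counts once whether het or hom). Genes with no passing
#' SNV get an explicit 0.
#'
#' @param vcf_paths Named character vector mapping sample ID to VCF path.
#' @param intervals Data.frame as from [read_gene_intervals()]; several
#'   intervals per gene are allowed and summed.
#' @param keep_filters FILTER values accepted (default `PASS` and `.`).
#' @param snv_only Count only single-nucleotide substitutions (default);
#'   set to `FALSE` to count indels as well.
#' @return A `sample_variant_counts` object: gene x sample integer matrix.
#' @export
count_snps_per_gene <- function(vcf_paths, intervals,
                                keep_filters = c("PASS", "."),
                                snv_only = TRUE) {
  stopifnot(length(vcf_paths) >= 1L, !is.null(names(vcf_paths)),
            all(nzchar(names(vcf_paths))))
  genes <- unique(intervals$gene)
  gr <- .interval_granges(intervals)
  counts <- matrix(0L, nrow = length(genes), ncol = length(vcf_paths),
                   dimnames = list(genes, names(vcf_paths)))
  for (s in names(vcf_paths)) {
    vcf <- VariantAnnotation::readVcf(vcf_paths[[s]])
    rr <- SummarizedExperiment::rowRanges(vcf)
    vcf_chroms <- unique(as.character(GenomicRanges::seqnames(rr)))
    panel_chroms <- unique(intervals$chromosome)
    if (length(vcf_chroms) > 0L &&
        xor(any(grepl("^chr", vcf_chroms)),
            any(grepl("^chr", panel_chroms))))
      stop("chromosome naming mismatch between VCF and panel ",
           "(e.g. 'chr1' vs '1'); normalize one of them (sample ", s, ")")
    keep <- rr$FILTER %in% keep_filters
    if (snv_only) {
      ref1 <- GenomicRanges::width(rr) == 1L
      alt1 <- vapply(VariantAnnotation::alt(vcf), function(a) {
        a <- as.character(a)
        any(nchar(a) == 1L & !grepl("[^ACGTNacgtn]", a))
      }, logical(1))
      keep <- keep & ref1 & alt1
    }
    rr <- rr[keep]
    if (length(rr) == 0L) next
    hits <- GenomicRanges::findOverlaps(rr, gr)
    if (length(hits) == 0L) next
    # one count per distinct site per gene
    df <- unique(data.frame(
      site = paste0(as.character(GenomicRanges::seqnames(rr))[S4Vectors::queryHits(hits)],
                    ":", GenomicRanges::start(rr)[S4Vectors::queryHits(hits)]),
      gene = gr$gene[S4Vectors::subjectHits(hits)],
      stringsAsFactors = FALSE))
    tab <- table(factor(df$gene, levels = genes))
    counts[, s] <- counts[, s] + as.integer(tab)
  }
  structure(counts, class = c("sample_variant_counts", class(counts)))
}

#' @export
print.sample_variant_counts <- function(x, ...) {
  cat(sprintf("<sample_variant_counts> %d gene(s) x %d sample(s)\n",
              nrow(x), ncol(x)))
  print(unclass(x))
  invisible(x)
}

#' Pooled median SNV count after excluding low counts
#'
#' Pools the per-gene counts of all samples, drops counts at or below
#' `exclusion_max` (default 1: genes with a single SNP are considered
#' uninformative) and returns the median of the remaining pool, with
#' midpoint interpolation for even pool sizes.
#'
#' @param counts A [count_snps_per_gene()] matrix (or any gene x sample
#'   matrix of non-negative integers).
#' @param exclusion_max Counts less than or equal to this value are dropped
#'   from the pool.
#' @return The pooled median (integer or half-integer).
#' @export
median_threshold <- function(counts, exclusion_max = 1L) {
  pool <- as.vector(unclass(counts))
  pool <- pool[pool > exclusion_max]
  if (length(pool) == 0L)
    stop("no informative genes: all counts <= ", exclusion_max)
  stats::median(pool)
}

#' Candidate genes present at high SNV rate in every sample
#'
#' Genes whose SNV count reaches `threshold` in EVERY sample, ordered by
#' descending minimum count across samples, ties broken by symbol.
#'
#' @param counts A [count_snps_per_gene()] matrix.
#' @param threshold Minimum per-sample count (typically the
#'   [median_threshold()]).
#' @return Character vector of gene symbols.
#' @export
select_candidate_genes <- function(counts, threshold) {
  stopifnot(threshold >= 0)
  m <- unclass(counts)
  if (length(m) == 0L || nrow(m) == 0L) return(character(0))
  min_count <- apply(m, 1L, min)
  keep <- min_count >= threshold
  genes <- rownames(m)[keep]
  genes[order(-min_count[keep], genes)]
}

#' Write a gene-by-sample count table as TSV
#'
#' @param counts A [count_snps_per_gene()] matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), unclass(counts),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
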