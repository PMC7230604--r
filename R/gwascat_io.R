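# Parsing of GWAS-catalog-style association tables, phenotype-group
# assignment under configurable trait queries, and the significance filter.

#' Default column dialect for catalog files
#'
#' Column-name map for the NHGRI-EBI GWAS Catalog association download
#' format. Override individual entries for files with different headers.
#'
#' @return Named character vector mapping logical fields to header names.
#' @export
catalog_dialect <- function() {
  c(snp_id = "SNPS",
    cytoband = "REGION",
    chromosome = "CHR_ID",
    position = "CHR_POS",
    mapped_genes = "MAPPED_GENE",
    reported_genes = "REPORTED GENE(S)",
    trait = "DISEASE/TRAIT",
    p_value = "P-VALUE")
}

# Sentinel spellings in the reported-gene field, compared case-insensitively.
.not_reported <- function(x) tolower(trimws(x)) %in% c("not reported", "")

# Split a multi-gene cell on ";" and ",", trim, drop sentinel tokens.
.split_genes <- function(x) {
  if (is.na(x) || .not_reported(x)) return(character(0))
  toks <- trimws(unlist(strsplit(x, "[;,]")))
  toks[!.not_reported(toks)]
}

# Split a multi-SNP cell on ";", "," and the " x " haplotype separator.
.split_snps <- function(x) {
  toks <- trimws(unlist(strsplit(x, ";|,| x ")))
  toks[nzchar(toks)]
}

.norm_ws <- function(x) tolower(trimws(gsub("[[:space:]]+", " ", x)))

#' Construct a phenotype trait query
#'
#' A phenotype group together with the trait strings that define it.
#'
#' @param group_name Nonempty group label.
#' @param trait_terms Character vector of trait strings (no duplicates).
#' @param match_mode `"exact"` for exact case-insensitive,
#'   whitespace-normalized equality (default) or `"substring"` for
#'   case-insensitive substring containment.
#' @return A `trait_query` object.
#' @export
#' @examples
#' trait_query("diabetes", c("type 1 diabetes", "type 2 diabetes"))
trait_query <- function(group_name, trait_terms,
                        match_mode = c("exact", "substring")) {
  match_mode <- match.arg(match_mode)
  stopifnot(is.character(group_name), length(group_name) == 1L,
            nzchar(group_name), is.character(trait_terms),
            length(trait_terms) >= 1L)
  if (anyDuplicated(.norm_ws(trait_terms)))
    stop("duplicate trait terms in group '", group_name, "'")
  structure(list(group_name = group_name, trait_terms = trait_terms,
                 match_mode = match_mode),
            class = "trait_query")
}

#' @export
print.trait_query <- function(x, ...) {
  cat(sprintf("<trait_query> %s (%s): %s\n", x$group_name, x$match_mode,
              paste(x$trait_terms, collapse = "; ")))
  invisible(x)
}

#' Parse a GWAS-catalog-style association table
#'
#' Reads a tab-separated association table and normalizes it into one record
#' per single SNP. Rows whose SNP field lists several SNPs (separated by
#' `;`, `,` or the haplotype notation `" x "`) are split into one record per
#' SNP, duplicating the row's other fields. Rows with an empty or missing
#' SNP field are skipped and counted in the `skipped` attribute. SNP
#' identifiers not matching `rs[0-9]+` are kept but flagged in the
#' `nonstandard_id` column. Gene fields are split on `;`/`,`; the catalog's
#' "Not Reported" sentinel (any case) is dropped from gene lists and the
#' `reported_genes` column left empty for such rows.
#'
#' @param path Path to the TSV file (UTF-8, one header row).
#' @param dialect Named map from logical fields to header names; see
#'   [catalog_dialect()].
#' @return A data.frame of associations with columns `snp_id`, `chromosome`,
#'   `position`, `cytoband`, `mapped_genes`, `reported_genes` (both
#'   `; `-joined), `trait`, `p_value`, `source_row`, `nonstandard_id`;
#'   attribute `skipped` counts malformed rows.
#' @export
parse_catalog <- function(path, dialect = catalog_dialect()) {
  if (!file.exists(path)) stop("cannot read catalog file: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           colClasses = "character", quote = "",
                           stringsAsFactors = FALSE)
  required <- catalog_dialect()
  dialect <- c(dialect, required[setdiff(names(required), names(dialect))])
  missing_cols <- setdiff(unname(dialect[names(required)]), names(tab))
  if (length(missing_cols) > 0L)
    stop("catalog is missing required column(s): ",
         paste(missing_cols, collapse = ", "))

  skipped <- 0L
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    snps <- .split_snps(tab[[dialect[["snp_id"]]]][i])
    if (length(snps) == 0L) { skipped <- skipped + 1L; next }
    pos <- suppressWarnings(as.integer(tab[[dialect[["position"]]]][i]))
    if (!is.na(pos) && pos <= 0L) { skipped <- skipped + 1L; next }
    p <- suppressWarnings(as.numeric(tab[[dialect[["p_value"]]]][i]))
    if (!is.na(p) && (p < 0 || p > 1)) { skipped <- skipped + 1L; next }
    mg <- .split_genes(tab[[dialect[["mapped_genes"]]]][i])
    rg <- .split_genes(tab[[dialect[["reported_genes"]]]][i])
    out[[i]] <- data.frame(
      snp_id = snps,
      chromosome = tab[[dialect[["chromosome"]]]][i],
      position = pos,
      cytoband = trimws(tab[[dialect[["cytoband"]]]][i]),
      mapped_genes = paste(mg, collapse = "; "),
      reported_genes = paste(rg, collapse = "; "),
      trait = tab[[dialect[["trait"]]]][i],
      p_value = p,
      source_row = i,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(snp_id = character(0), chromosome = character(0),
                      position = integer(0), cytoband = character(0),
                      mapped_genes = character(0),
                      reported_genes = character(0), trait = character(0),
                      p_value = numeric(0), source_row = integer(0),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res$nonstandard_id <- !grepl("^rs[0-9]+$", res$snp_id)
  attr(res, "skipped") <- skipped
  res
}

#' Assign associations to phenotype groups
#'
#' Matches each association's trait string against the configured trait
#' queries. An association may fall under several groups; associations that
#' match no query are returned under the reserved `"unassigned"` key.
#'
#' @param associations Data.frame from [parse_catalog()].
#' @param queries List of [trait_query()] objects.
#' @return Named list of association data.frames, one per group plus
#'   `"unassigned"`.
#' @export
assign_phenotype_groups <- function(associations, queries) {
  stopifnot(length(queries) > 0L)
  if (any(vapply(queries, function(q) q$group_name, "") == "unassigned"))
    stop("'unassigned' is a reserved group name")
  trait_norm <- .norm_ws(associations$trait)
  hit_any <- rep(FALSE, nrow(associations))
  out <- list()
  for (q in queries) {
    terms <- .norm_ws(q$trait_terms)
    hit <- if (q$match_mode == "exact") {
      trait_norm %in% terms
    } else {
      Reduce(`|`, lapply(terms, function(t) grepl(t, trait_norm, fixed = TRUE)),
             accumulate = FALSE)
    }
    hit_any <- hit_any | hit
    out[[q$group_name]] <- associations[hit, , drop = FALSE]
  }
  out[["unassigned"]] <- associations[!hit_any, , drop = FALSE]
  out
}

#' Filter associations on reported p-value
#'
#' Keeps records whose association p-value is strictly below `alpha`.
#' Records with a missing p-value are dropped and counted in the
#' `n_missing_p` attribute (with a warning when any are dropped).
#'
#' @param associations Data.frame of associations.
#' @param alpha Significance level in (0, 1]; default 0.05.
#' @return Filtered data.frame with attribute `n_missing_p`.
#' @export
filter_significant <- function(associations, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha > 1)
    stop("alpha must be a single value in (0, 1]")
  miss <- is.na(associations$p_value)
  keep <- !miss & associations$p_value < alpha
  if (any(miss))
    warning(sum(miss), " association(s) dropped for missing p-value")
  out <- associations[keep, , drop = FALSE]
  attr(out, "n_missing_p") <- sum(miss)
  out
}

#' Write normalized associations as TSV
#'
#' Fixed column order for downstream stages.
#'
#' @param associations Data.frame from [parse_catalog()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(associations, path) {
  cols <- c("snp_id", "chromosome", "position", "cytoband", "mapped_genes",
            "reported_genes", "trait", "p_value", "source_row")
  utils::write.table(associations[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
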