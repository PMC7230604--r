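# Independent brute-force oracles used across the suite. These deliberately
# share no code with the implementation they check.

# Exclusive Venn membership by exhaustive scan of all 2^G - 1 phenotype
# combinations per region.
oracle_venn <- function(region_sets) {
  groups <- names(region_sets)
  all_regions <- unique(unlist(region_sets))
  combos <- unlist(lapply(seq_along(groups), function(k)
    utils::combn(groups, k, simplify = FALSE)), recursive = FALSE)
  out <- list()
  for (r in all_regions) {
    for (combo in combos) {
      inside <- all(vapply(combo, function(g) r %in% region_sets[[g]],
                           logical(1)))
      outside <- all(vapply(setdiff(groups, combo),
                            function(g) !(r %in% region_sets[[g]]),
                            logical(1)))
      if (inside && outside) {
        key <- paste(sort(combo), collapse = "+")
        out[[key]] <- c(out[[key]], r)
        break
      }
    }
  }
  out
}

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# C(N, n) draws.
oracle_hyper_tail <- function(N, K, n, x) {
  draws <- utils::combn(N, n, simplify = FALSE)
  hits <- vapply(draws, function(d) sum(d <= K) >= x, logical(1))
  mean(hits)
}

# Partner counts by direct double loop.
oracle_partner_counts <- function(m, threshold) {
  out <- integer(nrow(m))
  for (i in seq_len(nrow(m))) {
    k <- 0L
    for (j in seq_len(ncol(m)))
      if (j != i && m[i, j] > threshold) k <- k + 1L
    out[i] <- k
  }
  stats::setNames(out, rownames(m))
}

# Write a data.frame in the default catalog dialect to a temp TSV.
write_catalog_fixture <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Minimal catalog-dialect data.frame builder.
catalog_row <- function(snps, region = "1p11.1", chrom = "1", pos = "1000",
                        mapped = "GENE1", reported = "GENE1",
                        trait = "type 2 diabetes", p = "1e-8") {
  data.frame(SNPS = snps, REGION = region, CHR_ID = chrom, CHR_POS = pos,
             MAPPED_GENE = mapped, `REPORTED GENE(S)` = reported,
             `DISEASE/TRAIT` = trait, `P-VALUE` = p,
             check.names = FALSE, stringsAsFactors = FALSE)
}
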