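# Generators for every input the pipeline consumes: the embedded-study
# fixture catalog, simulated catalogs with planted sharing structure,
# random annotation ontologies with enumeration-oracle truth, VCFs with
# planted per-gene SNV counts, and expression matrices with planted group
# shifts. All generators are deterministic given their seed and return
# their ground truth alongside the data.

.generator_version <- "pleioband-generators/1.0"

# run code under a temporary RNG seed without disturbing the caller's stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.write_tsv_with_header <- function(df, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s seed=%s", .generator_version, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# first trait term of each default phenotype group, by group name
.group_terms <- function() {
  qs <- uaediab_phenotypes()
  stats::setNames(lapply(qs, function(q) q$trait_terms),
                  vapply(qs, function(q) q$group_name, ""))
}

#' Embedded-study fixture catalog
#'
#' Builds a miniature association catalog that reconstructs the study's
#' cytoband structure exactly: (a) the 46 shared-region SNPs with their
#' bands, positions and reported genes, assigned trait strings realizing
#' their band's phenotype membership; (b) one association per
#' (band, phenotype) membership pair for every other study band, with
#' synthetic rsIDs, so the full published partition is reconstructable;
#' and (c) decoy rows in bands absent from the study lists, none of which
#' survives phenotype assignment plus the significance filter into a
#' multi-phenotype cell.
#'
#' @param n_decoys Number of decoy rows (cycled over four kinds:
#'   non-significant p, unmatched trait, missing p, and significant
#'   single-phenotype obesity rows).
#' @param path Optional path; when given the catalog is also written as a
#'   GWAS-catalog-dialect TSV with a generator header line.
#' @return Data.frame in the default catalog dialect (columns of
#'   [catalog_dialect()]).
#' @export
fixture_catalog <- function(n_decoys = 12L, path = NULL) {
  terms <- .group_terms()
  cells <- .uaediab_region_cells()
  snp_tab <- uaediab_shared_snps()
  shared_regions <- unique(snp_tab$region)

  # membership (cell order) per shared region
  shared_membership <- list()
  for (cl in cells)
    for (r in intersect(cl$regions, shared_regions))
      shared_membership[[r]] <- cl$groups

  rows <- list()
  add_row <- function(snp, region, chrom, pos, mapped, reported, trait, p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      SNPS = snp, REGION = region, CHR_ID = chrom, CHR_POS = pos,
      MAPPED_GENE = mapped, `REPORTED GENE(S)` = reported,
      `DISEASE/TRAIT` = trait, `P-VALUE` = p,
      check.names = FALSE, stringsAsFactors = FALSE)
  }

  # (a) the 46 shared-region SNPs, traits cycled over the band's phenotypes
  for (r in shared_regions) {
    sub <- snp_tab[snp_tab$region == r, , drop = FALSE]
    groups <- shared_membership[[r]]
    for (i in seq_len(nrow(sub))) {
      g <- groups[((i - 1L) %% length(groups)) + 1L]
      add_row(sub$snp_id[i], r, sub$chromosome[i],
              as.character(sub$position[i]), sub$mapped_gene[i],
              sub$reported_gene[i], terms[[g]][1],
              sprintf("%.0e", 10^-(6 + (i %% 5))))
    }
    # coverage rows: phenotypes of the band not yet drawn (bands with fewer
    # SNPs than member phenotypes), re-using the band's first SNP
    if (nrow(sub) < length(groups)) {
      for (g in groups[seq(nrow(sub) + 1L, length(groups))])
        add_row(sub$snp_id[1], r, sub$chromosome[1],
                as.character(sub$position[1]), sub$mapped_gene[1],
                sub$reported_gene[1], terms[[g]][1], "1e-9")
    }
  }

  # (b) one association per membership pair of every non-shared band
  memb <- uaediab_region_memberships()
  memb <- memb[!(memb$region %in% shared_regions), , drop = FALSE]
  for (k in seq_len(nrow(memb))) {
    r <- memb$region[k]
    chrom <- sub("^([0-9XYxy]+)[pq].*$", "\\1", r)
    add_row(sprintf("rs9%06d", k), r, chrom,
            as.character(1000000L + 1000L * k), sprintf("SYNGENE%d", k),
            sprintf("SYNGENE%d", k), terms[[memb$group[k]]][1], "2e-8")
  }

  # (c) decoys in bands the study lists never mention
  decoy_bands <- setdiff(
    c("21q21.1", "5p15.33", "3p21.31", "19p13.3", "22q11.21", "16q22.1",
      "4q13.3", "2q37.3", "18p11.32", "10p11.21", "20q13.33", "14q13.2",
      "6p12.3", "7q21.11", "9p13.3", "15q21.3"),
    uaediab_region_memberships()$region)
  if (n_decoys > 0L) {
    for (d in seq_len(n_decoys)) {
      band <- decoy_bands[((d - 1L) %% length(decoy_bands)) + 1L]
      chrom <- sub("^([0-9XYxy]+)[pq].*$", "\\1", band)
      kind <- (d - 1L) %% 4L
      if (kind == 0L) {        # matching trait, not significant
        add_row(sprintf("rs8%06d", d), band, chrom, "500000", "DECOY",
                "DECOY", "obesity", "0.2")
      } else if (kind == 1L) { # unmatched trait
        add_row(sprintf("rs8%06d", d), band, chrom, "500000", "DECOY",
                "DECOY", "Height", "1e-10")
      } else if (kind == 2L) { # missing p-value
        add_row(sprintf("rs8%06d", d), band, chrom, "500000", "DECOY",
                "DECOY", "obesity", "")
      } else {                 # significant, single phenotype only
        add_row(sprintf("rs8%06d", d), band, chrom, "500000", "DECOY",
                "DECOY", "body mass index", "3e-9")
      }
    }
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path)) .write_tsv_with_header(out, path, seed = "none")
  out
}

#' Simulate a catalog with planted sharing structure
#'
#' Plants, for each requested phenotype-combination size k, a given number
#' of synthetic cytobands whose associations cover exactly k of the
#' phenotype groups; the truth table lists every band's combination.
#'
#' @param seed Integer seed.
#' @param planted Named integer vector: `planted[["k"]]` bands shared by
#'   exactly k phenotypes (k up to `n_phenotypes`).
#' @param n_phenotypes Number of synthetic phenotype groups (traits
#'   `"trait G1"` ... matched by the returned queries).
#' @param n_decoys Decoy rows that fail the significance filter.
#' @param path Optional TSV output path.
#' @return List with `catalog` (data.frame), `truth` (data.frame `region`,
#'   `combo`), and `queries` (list of [trait_query()]).
#' @export
simulate_catalog <- function(seed, planted = c("1" = 4L, "2" = 3L, "4" = 3L),
                             n_phenotypes = 5L, n_decoys = 5L, path = NULL) {
  stopifnot(n_phenotypes >= 1L, all(planted >= 0L),
            all(as.integer(names(planted)) <= n_phenotypes))
  groups <- sprintf("G%d", seq_len(n_phenotypes))
  .with_seed(seed, {
    rows <- list()
    truth <- list()
    band_idx <- 0L
    for (kk in names(planted)) {
      k <- as.integer(kk)
      for (j in seq_len(planted[[kk]])) {
        band_idx <- band_idx + 1L
        band <- sprintf("%dq%d.%d", (band_idx %% 22L) + 1L,
                        (band_idx %% 4L) + 1L, (band_idx %% 3L) + 1L)
        combo <- sort(sample(groups, k))
        for (g in combo) {
          rows[[length(rows) + 1L]] <- data.frame(
            SNPS = sprintf("rs5%06d", length(rows) + 1L), REGION = band,
            CHR_ID = sub("q.*$", "", band),
            CHR_POS = as.character(10000L * band_idx + length(rows)),
            MAPPED_GENE = sprintf("SIMGENE%d", band_idx),
            `REPORTED GENE(S)` = sprintf("SIMGENE%d", band_idx),
            `DISEASE/TRAIT` = paste("trait", g), `P-VALUE` = "1e-8",
            check.names = FALSE, stringsAsFactors = FALSE)
        }
        truth[[length(truth) + 1L]] <- data.frame(
          region = band, combo = paste(combo, collapse = "+"),
          stringsAsFactors = FALSE)
      }
    }
    for (d in seq_len(n_decoys)) {
      rows[[length(rows) + 1L]] <- data.frame(
        SNPS = sprintf("rs6%06d", d), REGION = sprintf("%dp9.9", d %% 22L + 1L),
        CHR_ID = as.character(d %% 22L + 1L), CHR_POS = "100",
        MAPPED_GENE = "DECOY", `REPORTED GENE(S)` = "DECOY",
        `DISEASE/TRAIT` = paste("trait", groups[1]), `P-VALUE` = "0.5",
        check.names = FALSE, stringsAsFactors = FALSE)
    }
    catalog <- if (length(rows) > 0L) do.call(rbind, rows) else
      fixture_catalog(0L)[0L, ]
    rownames(catalog) <- NULL
    if (!is.null(path)) .write_tsv_with_header(catalog, path, seed)
    list(catalog = catalog,
         truth = if (length(truth) > 0L) do.call(rbind, truth) else
           data.frame(region = character(0), combo = character(0)),
         queries = lapply(groups, function(g)
           trait_query(g, paste("trait", g))))
  })
}

# ---- independent enumeration oracle for the ontology stage ----------------
# Straightforward recursive enumeration, deliberately sharing no code with
# the ontosim module: used only to produce truth files.

.naive_ancestors <- function(term, edges) {
  out <- term
  parents <- edges$parent[edges$child == term]
  for (p in parents) out <- c(out, .naive_ancestors(p, edges))
  unique(out)
}

.naive_ic <- function(edges, annotations) {
  terms <- unique(c(edges$child, edges$parent))
  entities <- unique(annotations$entity)
  cover <- sapply(terms, function(t) {
    sum(vapply(entities, function(e) {
      direct <- annotations$term[annotations$entity == e]
      any(vapply(direct, function(d) t %in% .naive_ancestors(d, edges),
                 logical(1)))
    }, logical(1)))
  })
  ic <- rep(Inf, length(terms))
  ic[cover > 0] <- -log10(cover[cover > 0] / length(entities))
  stats::setNames(ic, terms)
}

.naive_term_sim <- function(t1, t2, edges, ic) {
  common <- intersect(.naive_ancestors(t1, edges), .naive_ancestors(t2, edges))
  vals <- ic[common][is.finite(ic[common])]
  mica <- if (length(vals) > 0L) max(vals) else 0
  denom <- ic[[t1]] + ic[[t2]]
  if (!is.finite(denom) || denom <= 0) return(0)
  2 * mica / denom
}

.naive_entity_sim <- function(e1, e2, edges, annotations, ic, combine) {
  p1 <- unique(annotations$term[annotations$entity == e1])
  p2 <- unique(annotations$term[annotations$entity == e2])
  S <- matrix(0, length(p1), length(p2))
  for (i in seq_along(p1))
    for (j in seq_along(p2))
      S[i, j] <- .naive_term_sim(p1[i], p2[j], edges, ic)
  br <- apply(S, 1L, max); bc <- apply(S, 2L, max)
  switch(combine,
         "best-match-average" = mean(c(br, bc)),
         "maximum" = max(S),
         "complete" = min(min(br), min(bc)))
}

#' Simulate an annotation ontology with enumeration-oracle truth
#'
#' Generates a random rooted DAG (every non-root term draws 1 to
#' `branching` parents among earlier terms, so the first term is the
#' unique root), annotates entities to random terms, and computes ground
#' truth — per-term IC and all pairwise entity similarities for the three
#' combiners — by an independent brute-force enumeration.
#'
#' @param seed Integer seed.
#' @param n_terms Number of terms (>= 2).
#' @param n_entities Number of annotated entities.
#' @param branching Maximum parents per term.
#' @param annotation_rate Direct annotations per entity.
#' @param dir Optional directory; when given, writes `ontology_edges.tsv`
#'   and `ontology_annotations.tsv` with generator headers.
#' @return List with `edges`, `annotations` (data.frames), `truth_ic`
#'   (named numeric) and `truth_sim` (data.frame `e1`, `e2`, `combine`,
#'   `score`).
#' @export
simulate_ontology <- function(seed, n_terms = 15L, n_entities = 6L,
                              branching = 2L, annotation_rate = 2L,
                              dir = NULL) {
  stopifnot(n_terms >= 2L, n_entities >= 1L, branching >= 1L,
            annotation_rate >= 1L)
  .with_seed(seed, {
    terms <- sprintf("T%03d", seq_len(n_terms))
    edges <- do.call(rbind, lapply(2:n_terms, function(i) {
      n_par <- sample.int(min(branching, i - 1L), 1L)
      data.frame(child = terms[i],
                 parent = terms[sample.int(i - 1L, n_par)],
                 stringsAsFactors = FALSE)
    }))
    entities <- sprintf("E%02d", seq_len(n_entities))
    annotations <- do.call(rbind, lapply(entities, function(e) {
      data.frame(entity = e,
                 term = sample(terms, min(annotation_rate, n_terms)),
                 stringsAsFactors = FALSE)
    }))
    truth_ic <- .naive_ic(edges, annotations)
    pairs <- if (n_entities >= 2L) utils::combn(entities, 2L) else
      matrix(character(0), nrow = 2L)
    truth_sim <- do.call(rbind, lapply(
      c("best-match-average", "maximum", "complete"),
      function(cmb) {
        if (ncol(pairs) == 0L)
          return(data.frame(e1 = character(0), e2 = character(0),
                            combine = character(0), score = numeric(0)))
        data.frame(e1 = pairs[1, ], e2 = pairs[2, ], combine = cmb,
                   score = vapply(seq_len(ncol(pairs)), function(k)
                     .naive_entity_sim(pairs[1, k], pairs[2, k], edges,
                                       annotations, truth_ic, cmb),
                     numeric(1)),
                   stringsAsFactors = FALSE)
      }))
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      .write_tsv_with_header(edges, file.path(dir, "ontology_edges.tsv"),
                             seed)
      .write_tsv_with_header(annotations,
                             file.path(dir, "ontology_annotations.tsv"),
                             seed)
    }
    list(edges = edges, annotations = annotations, truth_ic = truth_ic,
         truth_sim = truth_sim)
  })
}

#' Simulate per-sample VCFs with planted per-gene SNV counts
#'
#' Writes one VCF 4.2 per sample containing exactly the planted number of
#' passing single-nucleotide substitutions inside each gene's interval,
#' plus configurable within-interval indels, filtered records and
#' out-of-interval decoy SNVs — none of which should be counted under the
#' default rules.
#'
#' @param seed Integer seed.
#' @param planted_counts Gene x sample integer matrix of SNV counts to
#'   plant (default: the embedded two-patient NGS counts).
#' @param dir Output directory for the VCFs and interval table.
#' @param interval_length Length of each gene interval (bp).
#' @param n_indels Indels planted per sample inside intervals.
#' @param n_filtered Non-PASS SNVs planted per sample inside intervals.
#' @param n_outside Decoy SNVs planted per sample between intervals.
#' @return List with `vcf_paths` (named), `intervals` (data.frame),
#'   `interval_path` and `truth` (the planted matrix).
#' @export
simulate_vcf <- function(seed, planted_counts = NULL, dir = tempfile("vcfs"),
                         interval_length = 2000L, n_indels = 2L,
                         n_filtered = 2L, n_outside = 3L) {
  if (is.null(planted_counts)) {
    ngs <- uaediab_ngs_counts()
    planted_counts <- as.matrix(ngs[, c("patient1", "patient2")])
    rownames(planted_counts) <- ngs$gene
  }
  stopifnot(is.matrix(planted_counts), all(planted_counts >= 0L),
            max(planted_counts) < interval_length / 2)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- rownames(planted_counts)
  samples <- colnames(planted_counts)
  gap <- 10L * interval_length
  intervals <- data.frame(
    gene = genes, chromosome = "1",
    start = gap * seq_along(genes) + 1L,
    end = gap * seq_along(genes) + interval_length,
    stringsAsFactors = FALSE)
  interval_path <- file.path(dir, "gene_intervals.tsv")
  .write_tsv_with_header(intervals, interval_path, seed)

  bases <- c("A", "C", "G", "T")
  .with_seed(seed, {
    vcf_paths <- character(0)
    for (s in samples) {
      recs <- list()
      emit <- function(pos, ref, alt, filter) {
        recs[[length(recs) + 1L]] <<- sprintf(
          "1\t%d\t.\t%s\t%s\t60\t%s\t.", pos, ref, alt, filter)
      }
      for (gi in seq_along(genes)) {
        k <- planted_counts[genes[gi], s]
        lo <- intervals$start[gi]; hi <- intervals$end[gi]
        used <- integer(0)
        if (k > 0L) {
          # first planted site sits exactly at the interval start: inclusive
          # lower bound is load-bearing for the counting rule
          pos <- c(lo, if (k > 1L) sample((lo + 1L):hi, k - 1L))
          used <- pos
          for (p in pos) {
            ref <- sample(bases, 1L)
            emit(p, ref, sample(setdiff(bases, ref), 1L), "PASS")
          }
        }
        if (gi <= n_indels) { # 2-bp deletion inside the interval
          p <- setdiff((lo + 1L):(hi - 1L), used)[1]
          emit(p, paste0(sample(bases, 1L), sample(bases, 1L)),
               sample(bases, 1L), "PASS")
        }
        if (gi <= n_filtered) { # SNV failing the default FILTER rule
          p <- setdiff((lo + 1L):(hi - 1L), used)[2]
          ref <- sample(bases, 1L)
          emit(p, ref, sample(setdiff(bases, ref), 1L), "q10")
        }
      }
      for (d in seq_len(n_outside)) { # SNVs between intervals
        p <- gap * d - 5L * d
        ref <- sample(bases, 1L)
        emit(p, ref, sample(setdiff(bases, ref), 1L), "PASS")
      }
      lines <- unlist(recs)
      pos <- as.integer(vapply(strsplit(lines, "\t"), `[[`, "", 2L))
      lines <- lines[order(pos)]
      path <- file.path(dir, paste0(s, ".vcf"))
      writeLines(c("##fileformat=VCFv4.2",
                   sprintf("##source=%s seed=%s", .generator_version, seed),
                   "##contig=<ID=1>",
                   "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                   lines), path)
      vcf_paths[s] <- path
    }
    list(vcf_paths = vcf_paths, intervals = intervals,
         interval_path = interval_path, truth = planted_counts)
  })
}

#' Simulate an islet-style expression matrix with planted effects
#'
#' Log-normal FPKM values for a nondiabetic and a diabetic donor group
#' (defaults: 63 vs 12, the study's islet cohort sizes), with planted
#' per-gene baseline log2 means (driving the mean-expression ranking) and
#' planted log2 group shifts for the diabetic group.
#'
#' @param seed Integer seed.
#' @param n_nd,n_t2d Group sizes.
#' @param base_log2 Named numeric: baseline log2-FPKM mean per gene.
#'   The default plants the study ordering — ASAH1 and HSD17B12 high,
#'   the KCNJ11 marker intermediate, FES and LRP4 low.
#' @param effect_log2 Named numeric: log2 shift added to the diabetic
#'   group (default: HSD17B12 down by 1).
#' @param noise_sd Between-sample SD on the log2 scale.
#' @param n_null_genes Extra null genes (no shift) appended for
#'   calibration experiments.
#' @param dir Optional directory: writes `expression_matrix.tsv` and
#'   `sample_groups.tsv`.
#' @return List with `eset` (an [expression_set()]) and `truth`
#'   (data.frame `gene`, `base_log2`, `effect_log2`).
#' @export
simulate_expression <- function(seed, n_nd = 63L, n_t2d = 12L,
                                base_log2 = c(ASAH1 = 8, HSD17B12 = 7.5,
                                              KCNJ11 = 5.5, FES = 3,
                                              LRP4 = 2.5),
                                effect_log2 = c(HSD17B12 = -1),
                                noise_sd = 1, n_null_genes = 0L,
                                dir = NULL) {
  stopifnot(n_nd >= 2L, n_t2d >= 2L, noise_sd >= 0)
  if (n_null_genes > 0L) {
    nulls <- stats::setNames(rep(5, n_null_genes),
                             sprintf("NULL%04d", seq_len(n_null_genes)))
    base_log2 <- c(base_log2, nulls)
  }
  genes <- names(base_log2)
  eff <- stats::setNames(rep(0, length(genes)), genes)
  eff[names(effect_log2)] <- effect_log2
  samples <- c(sprintf("ND%03d", seq_len(n_nd)),
               sprintf("T2D%03d", seq_len(n_t2d)))
  group <- stats::setNames(rep(c("ND", "T2D"), c(n_nd, n_t2d)), samples)
  .with_seed(seed, {
    log2fpkm <- matrix(stats::rnorm(length(genes) * length(samples),
                                    sd = noise_sd),
                       nrow = length(genes),
                       dimnames = list(genes, samples))
    log2fpkm <- log2fpkm + base_log2
    log2fpkm[, group == "T2D"] <- log2fpkm[, group == "T2D"] + eff
    values <- 2^log2fpkm
    eset <- expression_set(values, group)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      .write_tsv_with_header(
        data.frame(gene = genes, values, check.names = FALSE),
        file.path(dir, "expression_matrix.tsv"), seed)
      .write_tsv_with_header(
        data.frame(sample = samples, group = unname(group)),
        file.path(dir, "sample_groups.tsv"), seed)
    }
    list(eset = eset,
         truth = data.frame(gene = genes, base_log2 = unname(base_log2),
                            effect_log2 = unname(eff),
                            stringsAsFactors = FALSE))
  })
}
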