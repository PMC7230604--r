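# Shared fixture: the parsed, assigned, filtered embedded catalog.
fixture_pipeline_state <- local({
  state <- NULL
  function() {
    if (is.null(state)) {
      tf <- tempfile(fileext = ".tsv")
      fixture_catalog(path = tf)
      assoc <- parse_catalog(tf)
      grouped <- assign_phenotype_groups(assoc, uaediab_phenotypes())
      grouped <- grouped[setdiff(names(grouped), "unassigned")]
      grouped <- lapply(grouped, function(df)
        suppressWarnings(filter_significant(df, 0.05)))
      state <<- list(assoc = assoc, grouped = grouped,
                     region_sets = regions_per_phenotype(grouped))
      state$partition <- venn_partition(state$region_sets)
      state <<- state
      unlink(tf)
    }
    state
  }
})

test_that("a region enters a phenotype set once regardless of SNP count", {
  grouped <- list(
    diabetes = data.frame(snp_id = c("rs1", "rs2"),
                          cytoband = c("11p11.2", "11p11.2")),
    obesity = data.frame(snp_id = "rs3", cytoband = "9q34.2"))
  sets <- regions_per_phenotype(grouped)
  expect_equal(sets$diabetes, "11p11.2")
  expect_equal(sets$obesity, "9q34.2")
})

test_that("the fixture's diabetes set contains all eight shared bands", {
  st <- fixture_pipeline_state()
  shared8 <- c("8p22", "1q32.3", "12q24.13", "7p15.2",
               "11p11.2", "6q21", "17q12", "15q26.1")
  expect_true(all(shared8 %in% st$region_sets[["T1D/T2D"]]))
})

test_that("partition reproduces the published four-phenotype cells", {
  st <- fixture_pipeline_state()
  p <- st$partition
  key <- function(...) paste(sort(c(...)), collapse = "+")
  expect_setequal(
    p[[key("BMI/obesity", "dyslipidemia", "hypertension", "T1D/T2D")]],
    c("8p22", "1q32.3", "12q24.13", "7p15.2"))
  expect_setequal(
    p[[key("BMI/obesity", "dyslipidemia", "sleep apnea", "T1D/T2D")]],
    c("11p11.2", "6q21", "17q12"))
  expect_equal(
    p[[key("BMI/obesity", "hypertension", "sleep apnea", "T1D/T2D")]],
    "15q26.1")
})

test_that("partition cells are disjoint and conserve the input regions", {
  st <- fixture_pipeline_state()
  cells <- unlist(st$partition, use.names = FALSE)
  expect_false(anyDuplicated(cells) > 0)
  expect_setequal(cells, unique(unlist(st$region_sets)))
})

test_that("a single region set yields one cell equal to that set", {
  p <- venn_partition(list(g1 = c("1p11.1", "2q22.2")))
  expect_equal(names(p), "g1")
  expect_setequal(p[["g1"]], c("1p11.1", "2q22.2"))
})

test_that("duplicate group names are fatal", {
  sets <- list(a = "1p1", a = "2p1")
  expect_error(venn_partition(sets), "duplicate")
})

test_that("partition agrees with the exhaustive-combination oracle", {
  regions <- sprintf("%dq1.1", 1:10)
  for (seed in 1:25) {
    set.seed(seed)
    G <- sample(2:6, 1)
    sets <- stats::setNames(lapply(seq_len(G), function(i)
      sample(regions, sample(0:10, 1))), sprintf("g%d", seq_len(G)))
    sets <- sets[lengths(sets) > 0 | seq_along(sets) == 1]
    if (all(lengths(sets) == 0)) next
    got <- venn_partition(sets)
    want <- oracle_venn(sets)
    expect_setequal(names(got), names(want))
    for (k in names(want)) expect_setequal(got[[k]], want[[k]])
  }
})

test_that("shared-region selection is anchored, thresholded and monotone", {
  st <- fixture_pipeline_state()
  sel4 <- select_shared_regions(st$partition, 4L, "T1D/T2D")
  expect_length(sel4, 8L)
  expect_setequal(sel4, c("8p22", "1q32.3", "12q24.13", "7p15.2",
                          "11p11.2", "6q21", "17q12", "15q26.1"))
  # no five-phenotype cell exists
  expect_length(select_shared_regions(st$partition, 5L, "T1D/T2D"), 0L)
  # min 1 without anchor returns every region
  all_regions <- select_shared_regions(st$partition, 1L, NULL)
  expect_setequal(all_regions, unique(unlist(st$region_sets)))
  # monotonicity in min_phenotypes
  lens <- vapply(1:5, function(k)
    length(select_shared_regions(st$partition, k, "T1D/T2D")), integer(1))
  expect_true(all(diff(lens) <= 0))
  expect_error(select_shared_regions(st$partition, 4L, "nope"),
               "required_group")
})

test_that("clusters hold the 46 distinct SNPs and conserve assignments", {
  st <- fixture_pipeline_state()
  sel <- select_shared_regions(st$partition, 4L, "T1D/T2D")
  filtered <- unique(do.call(rbind, st$grouped))
  clusters <- extract_snp_clusters(sel, filtered)
  expect_length(clusters, 8L)
  all_snps <- unlist(lapply(clusters, `[[`, "snps"))
  expect_length(unique(all_snps), 46L)
  # each SNP appears in exactly one cluster
  expect_false(anyDuplicated(all_snps) > 0)
  by_region <- stats::setNames(clusters,
                               vapply(clusters, `[[`, "", "region"))
  expect_length(by_region[["15q26.1"]]$snps, 8L)
  # every filtered association in a selected region landed in its cluster
  in_sel <- filtered[filtered$cytoband %in% sel, ]
  for (r in unique(in_sel$cytoband))
    expect_setequal(by_region[[r]]$snps,
                    unique(in_sel$snp_id[in_sel$cytoband == r]))
})

test_that("regions absent from the catalog yield no cluster", {
  clusters <- extract_snp_clusters(
    c("1p11.1", "9q99.9"),
    data.frame(snp_id = "rs1", cytoband = "1p11.1",
               mapped_genes = "A", reported_genes = "A",
               stringsAsFactors = FALSE))
  expect_length(clusters, 1L)
  expect_equal(clusters[[1]]$region, "1p11.1")
})

test_that("gene collection merges aliases and splits multi-gene cells", {
  st <- fixture_pipeline_state()
  sel <- select_shared_regions(st$partition, 4L, "T1D/T2D")
  filtered <- unique(do.call(rbind, st$grouped))
  clusters <- extract_snp_clusters(sel, filtered)
  merged <- collect_genes(clusters)                      # TCF2 -> HNF1B
  unmerged <- collect_genes(clusters, alias_map = character(0))
  expect_length(merged, 34L)
  expect_length(unmerged, 35L)
  expect_true("TCF2" %in% unmerged)
  expect_false("TCF2" %in% merged)
  # the FURIN, FES cell contributes two symbols
  expect_true(all(c("FURIN", "FES") %in% merged))
  # sentinel never becomes a symbol
  expect_false(any(grepl("not reported", tolower(merged))))
})

test_that("band/position disagreement report flags suspect rows", {
  df <- rbind(catalog_row("rs1", region = "6q21", chrom = "6"),
              catalog_row("rs2", region = "6q21", chrom = "11"))
  assoc <- parse_catalog(write_catalog_fixture(df))
  sus <- band_position_warnings(assoc)
  expect_equal(sus$snp_id, "rs2")
})
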