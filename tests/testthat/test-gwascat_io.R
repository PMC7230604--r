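test_that("multi-SNP rows are split into one record per SNP, sharing fields", {
  df <- rbind(catalog_row("rs111; rs222", trait = "obesity"),
              catalog_row("rs1 x rs2", region = "2q22.2", trait = "snoring"),
              catalog_row("rs7, rs8, rs9", region = "3p21.1"))
  assoc <- parse_catalog(write_catalog_fixture(df))
  expect_equal(nrow(assoc), 7L)
  expect_equal(attr(assoc, "skipped"), 0L)
  first <- assoc[assoc$source_row == 1L, ]
  expect_equal(first$snp_id, c("rs111", "rs222"))
  expect_equal(unique(first$trait), "obesity")
  expect_equal(unique(first$cytoband), "1p11.1")
  # splitting conserves the (trait, region) multiset per source row
  tokens_per_row <- c(2L, 2L, 3L)
  expect_equal(as.integer(table(assoc$source_row)), tokens_per_row)
})

test_that("a header-only file parses to an empty record set", {
  assoc <- parse_catalog(write_catalog_fixture(catalog_row("rs1")[0L, ]))
  expect_equal(nrow(assoc), 0L)
  expect_equal(attr(assoc, "skipped"), 0L)
})

test_that("embedded fixture carries the known record for rs2176598", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  fixture_catalog(path = tf)
  assoc <- parse_catalog(tf)
  rec <- assoc[assoc$snp_id == "rs2176598", ]
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$cytoband, "11p11.2")
  expect_equal(rec$position, 43842728L)
  expect_equal(rec$chromosome, "11")
  expect_equal(rec$reported_genes, "HSD17B12")
})

test_that("missing required columns and unreadable files are fatal", {
  df <- catalog_row("rs1")
  df[["P-VALUE"]] <- NULL
  expect_error(parse_catalog(write_catalog_fixture(df)), "P-VALUE")
  expect_error(parse_catalog(tempfile("nonexistent")), "cannot read")
})

test_that("malformed rows are skipped and counted", {
  df <- rbind(catalog_row("rs1"), catalog_row(""), catalog_row("rs3"))
  assoc <- parse_catalog(write_catalog_fixture(df))
  expect_equal(nrow(assoc), 2L)
  expect_equal(attr(assoc, "skipped"), 1L)
})

test_that("non-rs identifiers are kept but flagged", {
  df <- rbind(catalog_row("rs10"), catalog_row("chr6:3133:D"))
  assoc <- parse_catalog(write_catalog_fixture(df))
  expect_equal(assoc$nonstandard_id, c(FALSE, TRUE))
})

test_that("phenotype assignment is exact, case-insensitive, multi-group", {
  df <- rbind(catalog_row("rs1", trait = "Type 2 diabetes"),
              catalog_row("rs2", trait = "SNORING"),
              catalog_row("rs3", trait = "Height"),
              catalog_row("rs4", trait = "  body  mass index "))
  assoc <- parse_catalog(write_catalog_fixture(df))
  grouped <- assign_phenotype_groups(assoc, uaediab_phenotypes())
  expect_equal(grouped[["T1D/T2D"]]$snp_id, "rs1")
  expect_equal(grouped[["sleep apnea"]]$snp_id, "rs2")
  expect_equal(grouped[["BMI/obesity"]]$snp_id, "rs4")
  expect_equal(grouped[["unassigned"]]$snp_id, "rs3")
  # exact mode must not substring-match
  expect_equal(nrow(grouped[["hypertension"]]), 0L)
})

test_that("substring mode broadens matching when opted in", {
  df <- catalog_row("rs1", trait = "obesity-related traits")
  assoc <- parse_catalog(write_catalog_fixture(df))
  exact <- assign_phenotype_groups(assoc, list(trait_query("ob", "obesity")))
  sub <- assign_phenotype_groups(
    assoc, list(trait_query("ob", "obesity", match_mode = "substring")))
  expect_equal(nrow(exact[["ob"]]), 0L)
  expect_equal(sub[["ob"]]$snp_id, "rs1")
})

test_that("assignment is order-independent up to within-group order", {
  df <- do.call(rbind, lapply(1:6, function(i)
    catalog_row(sprintf("rs%d", i),
                trait = c("obesity", "snoring", "hypertension")[i %% 3 + 1])))
  assoc <- parse_catalog(write_catalog_fixture(df))
  g1 <- assign_phenotype_groups(assoc, uaediab_phenotypes())
  g2 <- assign_phenotype_groups(assoc[sample(nrow(assoc)), ],
                                uaediab_phenotypes())
  for (k in names(g1))
    expect_setequal(g1[[k]]$snp_id, g2[[k]]$snp_id)
})

test_that("significance filter is strict and counts missing p-values", {
  df <- rbind(catalog_row("rs1", p = "0.04"),
              catalog_row("rs2", p = "0.05"),
              catalog_row("rs3", p = ""))
  assoc <- parse_catalog(write_catalog_fixture(df))
  expect_warning(kept <- filter_significant(assoc, 0.05), "missing p-value")
  expect_equal(kept$snp_id, "rs1")
  expect_equal(attr(kept, "n_missing_p"), 1L)
  # alpha = 1 drops exactly the missing-p records
  expect_warning(all_kept <- filter_significant(assoc, 1.0))
  expect_equal(all_kept$snp_id, c("rs1", "rs2"))
  expect_error(filter_significant(assoc, 0), "alpha")
  expect_error(filter_significant(assoc, 1.5), "alpha")
})

test_that("gene cells split on separators and drop the sentinel", {
  df <- rbind(catalog_row("rs1", reported = "FURIN, FES"),
              catalog_row("rs2", reported = "Not Reported"),
              catalog_row("rs3", reported = "Not reported"),
              catalog_row("rs4", reported = "A1; B2"))
  assoc <- parse_catalog(write_catalog_fixture(df))
  expect_equal(assoc$reported_genes,
               c("FURIN; FES", "", "", "A1; B2"))
})
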