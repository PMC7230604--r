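# Reference tables from the UAEDIAB cross-phenotype study, embedded so the
# whole pipeline runs offline: the five phenotype trait vocabularies, the
# cytoband -> phenotype-combination membership lists, the 46-SNP table for the
# eight shared regions, the targeted-NGS per-gene SNV counts for the two
# sequenced patients, and the trait-annotation sets used by the enrichment
# demo. All gene/SNP identifiers are verbatim catalog symbols.

#' Default phenotype trait queries
#'
#' The five UAEDIAB phenotype groups with their GWAS-catalog trait
#' vocabularies: diabetes (T1D/T2D), obesity/BMI, dyslipidemia (lipid
#' measurements), obstructive sleep apnea, and hypertension (blood-pressure
#' traits). Matching is exact, case-insensitive and whitespace-normalized by
#' default (see [trait_query()]).
#'
#' @return A list of `trait_query` objects, one per phenotype group.
#' @seealso [assign_phenotype_groups()]
#' @export
#' @examples
#' names(uaediab_phenotypes())
uaediab_phenotypes <- function() {
  list(
    trait_query("T1D/T2D", c("type 1 diabetes", "type 2 diabetes")),
    trait_query("BMI/obesity", c("obesity", "body mass index")),
    trait_query("dyslipidemia", c(
      "triglyceride levels", "triglycerides", "lipid traits",
      "HDL cholesterol-triglycerides", "LDL cholesterol levels",
      "HDL cholesterol levels", "total cholesterol levels"
    )),
    trait_query("sleep apnea", c(
      "snoring", "obstructive sleep apnea", "apnea-hypopnea index",
      "average oxygen saturation during sleep",
      "average respiratory event duration"
    )),
    trait_query("hypertension", c(
      "systolic blood pressure", "diastolic blood pressure", "hypertension"
    ))
  )
}

# Cytoband membership cells: each element is one exclusive Venn cell as
# published, a phenotype combination plus its cytoband list. Two bands
# (11p15.4, 11p15.5) appear in more than one published cell; an exclusive
# partition cannot hold both placements, so consumers that need one
# membership per band take the union of the cells listing it (see
# uaediab_region_memberships).
.uaediab_region_cells <- function() {
  BMI <- "BMI/obesity"; DYS <- "dyslipidemia"; HTN <- "hypertension"
  OSA <- "sleep apnea"; DM <- "T1D/T2D"
  cells <- list(
    list(groups = c(BMI, DYS, HTN, DM),
         regions = c("8p22", "1q32.3", "12q24.13", "7p15.2")),
    list(groups = c(BMI, DYS, OSA, DM),
         regions = c("11p11.2", "6q21", "17q12")),
    list(groups = c(BMI, HTN, OSA, DM),
         regions = "15q26.1"),
    list(groups = c(BMI, DYS, DM),
         regions = c("16q12.2", "19q13.32", "16p11.2", "5q13.3", "11p15.4",
                     "10p13", "16q23.2", "18q21.32", "18q11.2", "6p22.3",
                     "2p23.3", "19q13.11", "10p15.1", "22q12.3", "15q15.1",
                     "1p31.3", "19p13.2", "2q36.3", "11p15.1", "12q24.12",
                     "12q24.11", "11q13.1", "2q24.3", "1p32.3", "1q21.3",
                     "10q25.2", "6p21.32", "6p21.1", "6q23.3", "17p13.2",
                     "10q21.3", "12q24.31", "3p25.2", "3q21.1")),
    list(groups = c(DYS, HTN, DM),
         regions = c("10q23.33", "1q41", "1q43", "6p21.33", "8q24.12")),
    list(groups = c(BMI, HTN, DM),
         regions = c("16p12.3", "1p13.2")),
    list(groups = c(BMI, OSA, DM),
         regions = c("1q32.1", "1q42.2", "11q13.4")),
    list(groups = c(DYS, DM),
         regions = c("6q13", "6q27", "20q13.12", "1q42.13", "5q11.2",
                     "4p16.3", "6q24.1", "12p13.31", "9q34.2", "8q24.3",
                     "17p13.1", "9p24.2", "22q12.2", "1p34.3", "7q32.2",
                     "1p22.1", "2q33.2")),
    list(groups = c(BMI, DM),
         regions = c("6q23.1", "10q22.3", "8q21.13", "2p25.3", "4p12",
                     "12q13.12", "14q31.1", "3q27.2", "2p16.1", "9p21.1",
                     "4q28.2", "17q21.32", "18q12.3", "1p21.3", "9q22.31",
                     "15q14", "9q22.2", "5q33.2", "14q11.2", "3p14.1",
                     "12q12", "8q22.3", "21q22.3", "2p23.2", "17p11.2",
                     "2q21.3", "9q31.3", "10q26.13", "17p13.3", "11p15.5",
                     "11q13.3", "8q24.21", "7q36.3", "1p12", "3q23",
                     "6p21.2", "7p12.1", "9p24.1", "14q24.1", "18p11.21",
                     "13q31.1", "5q21.1", "2p21", "12p12.1", "7p14.3",
                     "8q22.1", "9p21.3")),
    list(groups = c(HTN, DM),
         regions = c("5q31.1", "18p11.31", "7q22.1", "21q22.11", "8p11.21",
                     "9q21.32")),
    list(groups = c(OSA, DM), regions = "2p24.3"),
    list(groups = DM,
         regions = c("8q24.11", "11q14.3", "4q35.1", "6q12", "17q21.33",
                     "3q26.2", "17q11.2", "4q22.2", "22q13.33", "7p21.2",
                     "5q22.2", "3q13.31", "11p12", "15q22.2", "2q23.3",
                     "11q24.3", "3q26.33", "1q32.2", "10q26.3", "19q13.2",
                     "4q32.3", "14q32.2", "2q24.2", "7q32.1", "9q34.3",
                     "3p24.3", "Xq28", "2q33.1", "3q27.3", "13q21.31",
                     "6q25.1", "13q14.13", "13q21.33", "13q22.1", "16p13.12",
                     "20q11.21", "1q21.2", "5q14.2", "20p12.2", "2q14.3",
                     "14q23.1", "15q24.3", "12q13.2", "1p22.3", "6q15",
                     "16p13.13", "18q22.2", "2q11.2", "5p13.2", "15q25.1",
                     "4q27", "4p15.2", "6q22.32", "10q23.31", "17q21.1",
                     "17q21.2", "20p13", "13q22.2", "7p15.1", "10q24.2",
                     "10q26.11", "13q12.12", "8q24.22", "11p15.4", "11p15.5",
                     "3p23", "12q21.2", "1p22.2", "12q21.1", "2q12.1",
                     "10q22.1", "3q12.3", "9p23", "9q21.31", "12q14.3",
                     "4p16.1", "4q31.3", "6p24.3", "13q12.13", "12p11.22",
                     "2p23.1", "7p14.1", "8q13.2", "12p11.21", "2p16.2",
                     "10q26.12", "16q24.1", "3p14.3", "20q13.31"))
  )
  cells
}

#' Published cytoband Venn cells of the study
#'
#' The published exclusive Venn cells: one row per cytoband occurrence, with
#' the phenotype combination (`+`-joined, alphabetical) it was listed under.
#' Two bands appear under two combinations each — a defect of the published
#' lists that an exclusive partition cannot represent; see
#' [uaediab_region_memberships()] for the reconciled per-band membership.
#'
#' @return A data.frame with columns `region` and `combo`.
#' @export
uaediab_region_cells <- function() {
  cells <- .uaediab_region_cells()
  do.call(rbind, lapply(cells, function(cl) {
    data.frame(region = cl$regions,
               combo = paste(sort(cl$groups), collapse = "+"),
               stringsAsFactors = FALSE)
  }))
}

#' Per-cytoband phenotype memberships of the study
#'
#' One row per (cytoband, phenotype) pair. A band listed under several
#' published Venn cells receives the union of those cells' phenotypes, the
#' only membership assignment consistent with set semantics.
#'
#' @return A data.frame with columns `region` and `group`.
#' @export
uaediab_region_memberships <- function() {
  cells <- .uaediab_region_cells()
  pairs <- do.call(rbind, lapply(cells, function(cl) {
    expand.grid(region = cl$regions, group = cl$groups,
                stringsAsFactors = FALSE)
  }))
  pairs <- unique(pairs)
  pairs[order(pairs$region, pairs$group), , drop = FALSE]
}

#' SNPs of the eight shared cytobands
#'
#' The 46 catalog SNPs located in the eight cytobands shared by at least four
#' phenotype groups, with mapped genes, band, genomic location and the
#' catalog's reported gene field (including its `Not Reported` sentinel
#' spellings, kept verbatim).
#'
#' @return A data.frame with columns `snp_id`, `mapped_gene`, `region`,
#'   `chromosome`, `position`, `reported_gene`.
#' @export
uaediab_shared_snps <- function() {
  raw <- c(
    "rs3817334|MTCH2|11p11.2|11:47629441|MTCH2",
    "rs7124681|CELF1|11p11.2|11:47508395|CUGBP1",
    "rs11066280|HECTD4|12q24.13|12:112379979|HECTD4",
    "rs4430796|HNF1B|17q12|17:37738049|HNF1B",
    "rs2176598|HSD17B12|11p11.2|11:43842728|HSD17B12",
    "rs17696736|NAA25|12q24.13|12:112049014|Not Reported",
    "rs2028299|AP3S2|15q26.1|15:89831025|AP3S2",
    "rs9400239|FOXO3|6q21|6:108656460|FOXO3",
    "rs17126232|AC124242.3|8p22|8:18120141|ASAH1",
    "rs6990042|SGCZ|8p22|8:14316465|SGCZ",
    "rs10742752|AC103855.3|11p11.2|11:45416824|SYT13",
    "rs17630235|TRAFD1, HECTD4|12q24.13|12:112153882|Not reported",
    "rs1439620|AC013394.1, LINC01578|15q26.1|15:92886416|LOC100507217",
    "rs12150665|GGNBP2|17q12|17:36558947|GGNBP2",
    "rs3800229|FOXO3|6q21|6:108675760|FOXO3",
    "rs35424364|CCDC162P|6q21|6:109322403|C6ORF183, CCDC162P",
    "rs1495741|PSD3, NAT2|8p22|8:18415371|NAT2",
    "rs10838738|MTCH2|11p11.2|11:47641497|MTCH2",
    "rs326214|MADD|11p11.2|11:47276809|LRP4",
    "rs74472562|TSPAN18|11p11.2|11:44741205|RP11-45A12.2, TSPAN18",
    "rs1061810|HSD17B12, AC087521.2, AC087521.4|11p11.2|11:43856384|HSD17B12",
    "rs936674|AC091078.1|15q26.1|15:93360368|RP11-266O8.1",
    "rs148024591|AC091078.1|15q26.1|15:93371222|RP11-266O8.1",
    "rs2521501|FES|15q26.1|15:90894158|FURIN, FES",
    "rs8042680|PRC1, PRC1-AS1|15q26.1|15:90978107|PRC1",
    "rs12899811|VPS33B|15q26.1|15:91000846|PRC1",
    "rs79548680|RCCD1|15q26.1|15:90962549|PRC1",
    "rs1877031|STARD3|17q12|17:39657827|STARD3",
    "rs4796285|AC243830.1, LHX1-DT|17q12|17:36824731|Not reported",
    "rs10908278|HNF1B|17q12|17:37739961|HNF1B, TCF2",
    "rs1704198|AC096639.1|1q32.3|1:213737151|PROX1",
    "rs340839|PROX1|1q32.3|1:213988477|PROX1",
    "rs7526425|AC105275.1, SLC30A1, RD3|1q32.3|1:211527316|SLC30A1",
    "rs2075423|PROX1-AS1|1q32.3|1:213981376|PROX1",
    "rs884366|CCDC162P|6q21|6:109252892|LOC100996634",
    "rs149358103|RPS27AP11, LINC02541|6q21|6:11358684|SOCS5P5, MARCKS",
    "rs10261878|AC010719.1, AC018706.1|7p15.2|7:25910925|NFE2L3, MIR148A",
    "rs4719841|NFE2L3, MIR148A|7p15.2|7:25957916|MIR148A",
    "rs4722551|NFE2L3, MIR148A|7p15.2|7:25952206|MIR148A",
    "rs6969780|HOXA3, HOXA-AS2|7p15.2|7:27119517|HOXA3",
    "rs10279895|HNRNPA1P73, RPL35P4|7p15.2|7:27288591|EVX1, HOXA",
    "rs7804356|SKAP2|7p15.2|7:26852046|Not reported",
    "rs4921914|PSD3, NAT2|8p22|8:18414928|NAT2",
    "rs1961456|NAT2|8p22|8:18398199|NAT2",
    "rs115706913|SGCZ|8p22|8:14224308|Not Reported",
    "rs2946504|TRMT9B|8p22|8:12954071|KIAA1456"
  )
  parts <- strsplit(raw, "|", fixed = TRUE)
  loc <- vapply(parts, `[[`, "", 4L)
  loc2 <- strsplit(loc, ":", fixed = TRUE)
  data.frame(
    snp_id = vapply(parts, `[[`, "", 1L),
    mapped_gene = vapply(parts, `[[`, "", 2L),
    region = vapply(parts, `[[`, "", 3L),
    chromosome = vapply(loc2, `[[`, "", 1L),
    position = as.integer(vapply(loc2, `[[`, "", 2L)),
    reported_gene = vapply(parts, `[[`, "", 5L),
    stringsAsFactors = FALSE
  )
}

#' Targeted-NGS per-gene SNV counts for the two sequenced patients
#'
#' Per-gene single-nucleotide-variant counts obtained by targeted
#' next-generation sequencing of two diabetic patients over a 20-gene panel
#' drawn from the shared regions. Zeros are explicit (PRC1 had no passing
#' SNV in either patient).
#'
#' @return A data.frame with columns `gene`, `patient1`, `patient2`.
#' @export
uaediab_ngs_counts <- function() {
  genes <- c("ASAH1", "LRP4", "FES", "HSD17B12", "HNF1B", "HECTD4", "SH2B3",
             "NAT2", "SGCZ", "FURIN", "GGNBP2", "TSPAN18", "ALDH2", "STARD3",
             "MTCH2", "NDUFS3", "PRC1", "PTPN11", "CELF1", "NAA25")
  p1 <- c(20, 8, 9, 7, 4, 2, 4, 4, 3, 3, 5, 2, 1, 1, 1, 1, 0, 1, 3, 2)
  p2 <- c(16, 7, 6, 4, 4, 6, 4, 2, 1, 1, 1, 2, 1, 1, 2, 1, 0, 0, 0, 0)
  data.frame(gene = genes, patient1 = as.integer(p1), patient2 = as.integer(p2),
             stringsAsFactors = FALSE)
}

#' Trait-annotation sets over the 46 shared-region SNPs
#'
#' Ontology-trait annotation sets over the 46 shared-region SNPs, as used by
#' the enrichment demonstration: each term with the subset of the 46 SNPs
#' annotated to it. Suitable as `annotations` for [enrich_terms()] with the
#' 46 SNPs as universe.
#'
#' @return A data.frame with columns `term_id`, `term_name`, `snp_id` (one
#'   row per term/SNP pair).
#' @export
uaediab_trait_annotations <- function() {
  sets <- list(
    "Metabolic Disease" = c("rs1061810", "rs10908278", "rs11066280",
      "rs12899811", "rs149358103", "rs1704198", "rs17126232", "rs17696736",
      "rs2028299", "rs2075423", "rs2946504", "rs4430796", "rs7804356",
      "rs79548680", "rs8042680"),
    "Diabetes Mellitus" = c("rs1061810", "rs10908278", "rs12899811",
      "rs149358103", "rs17696736", "rs2028299", "rs2075423", "rs2946504",
      "rs4430796", "rs7804356", "rs79548680", "rs8042680"),
    "Body Mass Index" = c("rs10261878", "rs10742752", "rs10838738",
      "rs12150665", "rs1439620", "rs17630235", "rs2176598", "rs3800229",
      "rs3817334", "rs6990042", "rs7124681", "rs936674", "rs9400239"),
    "Sleep Apnea" = c("rs148024591", "rs35424364", "rs4796285", "rs74472562"),
    "Type II Diabetes Mellitus" = c("rs1061810", "rs10908278", "rs12899811",
      "rs2946504", "rs149358103", "rs8042680", "rs2028299", "rs2075423",
      "rs4430796", "rs79548680"),
    "Hypertension" = c("rs10279895", "rs11066280", "rs115706913",
      "rs2521501", "rs6969780"),
    "Triglyceride Measurement" = c("rs11066280", "rs1495741", "rs340839",
      "rs4719841", "rs4722551", "rs4921914"),
    "Lipid Measurement" = c("rs11066280", "rs1495741", "rs1877031",
      "rs326214", "rs340839", "rs4719841", "rs4722551", "rs4921914",
      "rs884366"),
    "Blood Pressure" = c("rs10279895", "rs11066280", "rs17696736",
      "rs2521501", "rs6969780"),
    "Obesity" = c("rs1704198", "rs17126232")
  )
  out <- do.call(rbind, lapply(seq_along(sets), function(i) {
    data.frame(term_id = sprintf("TRAIT:%04d", i),
               term_name = names(sets)[i],
               snp_id = sets[[i]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
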