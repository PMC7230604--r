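---
title: "pleioband: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pleioband: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pleioband` implements an integrative phenotype–genotype workflow: it
mines a GWAS-catalog-style association table for SNPs linked to a set of
clinical phenotype groups, intersects the cytobands those SNPs occupy,
and carries the shared SNP-clusters through enrichment, semantic
similarity, patient variant-burden and expression-comparison stages.
This vignette documents the model each stage implements, the parameters
that matter, the synthetic-data generators, and the design decisions
taken where the procedure was genuinely open.

## 1. Catalog mining and phenotype assignment

The unit record is one SNP–trait association: rsID, chromosome,
position, cytoband, mapped/reported genes, free-text trait, p-value.
Catalog rows listing several SNPs in one field (separators `;`, `,`, or
the haplotype notation `" x "`) are split into one record per SNP with
the row's other fields duplicated, so downstream set arithmetic is per
SNP. Rows without a usable SNP identifier are skipped and counted rather
than guessed at.

Phenotype groups are defined by trait vocabularies
(`uaediab_phenotypes()` ships the five study groups: diabetes (T1D/T2D),
obesity/BMI, dyslipidemia, obstructive sleep apnea, hypertension).
**Matching is exact, case-insensitive and whitespace-normalized by
default.** Substring matching is available but opt-in: trait strings in
public catalogs are noisy, and substring matching silently broadens a
group (e.g. "obesity" would capture "abdominal obesity-related traits").
An association may belong to several groups; unmatched associations are
kept under a reserved `unassigned` key so nothing disappears silently.

The significance filter keeps associations with p **strictly** below
`alpha` (default 0.05). The source catalogs report per-study association
p-values and do not define any further adjustment, so none is applied;
`alpha` is a plain threshold on the reported value. Records with a
missing p-value cannot be compared against `alpha` and are dropped with
a counted warning.

## 2. Cytoband intersection and the exclusive Venn partition

Intersection is at **cytoband-label granularity**: two associations
share a region iff their band strings are equal. Sub-bands are never
merged into parent bands (11p11.2 ≠ 11p11) — the procedure follows the
catalog's own region column and re-deriving bands from coordinates would
require a genome-build-specific band track. Band/position disagreements
(a band whose chromosome prefix contradicts the record's chromosome
column) are surfaced by `band_position_warnings()` but never resolved:
the band column is trusted.

The partition assigns every band to the cell of exactly the groups whose
region sets contain it. Two invariants are asserted on every run: cells
are pairwise disjoint, and their union equals the union of the inputs.
Shared regions are the union of cells with at least `min_phenotypes`
groups (default 4) that contain the `required_group` anchor (default the
diabetes group, matching the study design in which every reported cell
includes diabetes). Output ordering is deterministic everywhere —
regions by chromosome then band string, genes by region of first
appearance then symbol — so golden-file comparisons are stable.

Gene collection works on the reported-gene column, splits multi-gene
cells, drops the catalog's "Not Reported" sentinel in any case variant,
and canonicalizes through an explicit alias map. The default map
contains the single merge TCF2 → HNF1B: TCF2 is the legacy symbol of
HNF1B and both spellings occur in the embedded tables. Keeping the map
tiny and user-extensible makes alias handling auditable; with it the
embedded tables yield 34 distinct genes, without it 35.

### A defect in the embedded region lists

The embedded per-cell band lists contain two bands (11p15.4 and
11p15.5) that are each printed under **two** different phenotype
combinations. An exclusive partition cannot place one label in two
cells. The package resolves this the only way consistent with set
semantics: a band's membership is the **union** of the cells listing it
(`uaediab_region_memberships()`), so 11p15.4 carries
{BMI/obesity, dyslipidemia, diabetes} and 11p15.5
{BMI/obesity, diabetes}, and the diabetes-only cell of the
re-partitioned lists holds 87 bands rather than the printed 89. The raw
printed cells remain available verbatim via `uaediab_region_cells()`.
The same lists also sum to 212 printed band occurrences (210 distinct),
so no exclusive partition can reproduce every printed marginal at once;
the discrepancy is surfaced by the test suite rather than papered over.

## 3. Enrichment

`enrich_terms()` tests a query SNP set against annotation-term sets over
an explicit background universe. The universe is a required input, not a
default: enrichment p-values are meaningless without knowing what the
query was drawn from, and the original web-service analyses did not
state theirs. The default null is hypergeometric (sampling without
replacement); a binomial approximation (success probability K/N) and
one-sided Fisher are exposed for comparison — the one-sided Fisher p
equals the hypergeometric tail on the same 2×2 table, which the suite
asserts. Testing is one-sided (over-representation only). The z-score
always uses the finite-population hypergeometric variance so it stays
consistent with the default null even when the binomial method is
chosen. Degenerate terms (K = 0, or no free variance) report p = 1,
z = 0 and a flag instead of NaN. FDR is Benjamini–Hochberg across all
terms tested in one call; the original analysis did not name its
adjustment, and BH is the field default.

## 4. Ontology semantic similarity

Annotations obey the true-path rule: an entity annotated to a term is
annotated to all its ancestors. This is required for the
most-informative-common-ancestor (MICA) to be well defined. Term
information content is ic(t) = −log₁₀(fraction of annotated entities at
or below t); the root covers everything and has IC 0, and IC is
monotone non-decreasing from parent to child (asserted property).

Raw MICA IC (Resnik) is unbounded, but the partner-count rule operates
on a [0, 1] scale, so the default term score is the Lin normalization
2·ic(MICA)/(ic(t₁)+ic(t₂)), defined as 0 when the denominator is 0
(both terms at the root); the raw Resnik score is available behind
`normalize = FALSE`. Entity scores combine the pairwise term-similarity
matrix between two annotation profiles by **best-match average** (mean
of each term's best match over both directions), **maximum** (matrix
max), or **complete** — defined here, since the name is used in the
field without a fixed definition, as the minimum over the directional
row-wise best matches, the most conservative of the three. The suite
asserts complete ≤ best-match-average ≤ maximum and symmetry on random
DAGs.

The partner-count summary counts, per entity, the *other* entities with
similarity **strictly** above the threshold (default 0.5, mirroring a
"more than 0.5" rule) and reports the subset with at least
`min_partners` (default 5) partners. Whether entities are SNPs or genes
is immaterial to the mathematics; the annotation universe is whatever
the caller supplies.

## 5. Variant burden and the median-threshold rule

`count_snps_per_gene()` counts variant **sites**, not genotypes: a
passing record contributes one count whether heterozygous or homozygous.
Default rules: REF of 1 bp and at least one non-symbolic 1 bp ALT
(SNV-only; indel counting is opt-in because the selection rule is
defined over SNPs), FILTER of `PASS` or `.`, position within a gene
interval with 1-based inclusive ends (BED input is converted from
0-based half-open on read). Multi-allelic records count once per site.
Chromosome-style mismatches between VCF and panel (`chr1` vs `1`) abort
with a normalization hint instead of silently counting nothing.

The candidate threshold pools all per-gene counts across samples, drops
counts ≤ 1 (a single SNP in a gene is treated as uninformative), and
takes the median with midpoint interpolation for even pool sizes. On the
embedded two-patient panel this gives 4; without the exclusion the
pooled median drops to 3, so the exclusion is load-bearing. Candidates
must reach the threshold in **every** sample. Note the rule as printed
does not uniquely select the four genes the study names: the embedded
count table also qualifies HNF1B and SH2B3 at exactly 4/4. The selection
returns all qualifying genes, ordered by descending minimum count then
symbol, and the discrepancy is documented rather than resolved; the
panel membership itself is an explicit input, since six panel genes do
not appear in the shared-region gene list and no membership rule was
stated.

## 6. Expression comparison

The comparison runs on log₂(FPKM+1) by default (the raw scale is
available): FPKM distributions are heavily right-skewed and the study
compared them without stating a transform, so the package takes the
field-standard variance-stabilizing choice and documents it. The
normality gate is the D'Agostino–Pearson K² omnibus test (skewness and
kurtosis z-statistics squared and summed, χ² with 2 df), implemented
in-package from the standard formulas because no installed R package
provides it; it is checked against frozen reference values from an
established external implementation. The gate needs a minimum per-group
n — the kurtosis approximation is undefined below n = 8 — so groups
smaller than `min_n_normality = 8` force the nonparametric branch. When
both groups pass at `alpha_normality` (default 0.05) a two-sided
Student's t-test (equal variances) runs, otherwise a two-sided
Mann–Whitney. No sidedness was stated in the source design, so tests
are two-sided; no multiple-testing correction is applied by default
because the stage is used on a handful of named candidates (BH is one
flag away). The report includes the signed direction of the
second-group mean, because the source material itself is contradictory
about one gene's direction and the user should see the sign, not a
label.

Ranking uses the mean over the **reference group only** (nondiabetic
donors), ties broken alphabetically, with the marker gene flagged.

## 7. What the generators emulate — and what they do not

* `fixture_catalog()` rebuilds the study's catalog structure exactly:
  the 46 shared-region SNPs with real rsIDs, bands, positions and
  reported genes, trait strings drawn verbatim from the five group
  vocabularies so the default queries match them, one synthetic
  association per (band, phenotype) membership for every other study
  band, and decoys (non-significant, unmatched-trait, missing-p, and
  single-phenotype rows) that must not reach any multi-phenotype cell.
* `simulate_catalog()` plants bands shared by exactly k groups with a
  truth table, for oracle-checked recovery tests.
* `simulate_ontology()` builds a random rooted DAG (term 1 is the unique
  root; later terms draw 1–`branching` parents among earlier terms) and
  computes truth IC and pairwise similarities by an independent
  brute-force enumeration that shares no code with the main
  implementation.
* `simulate_vcf()` writes valid VCF 4.2 per sample with the planted
  per-gene SNV counts inside each gene's interval — the first planted
  site sits exactly on the interval start to pin the inclusive-bound
  convention — plus indels, non-PASS records and off-target sites that
  the default rules must ignore.
* `simulate_expression()` draws log-normal FPKM for 63 nondiabetic vs
  12 diabetic donors (the islet cohort sizes) with planted baseline
  means (ASAH1 ≈ HSD17B12 > KCNJ11 > FES ≈ LRP4, log₂ scale, SD 1 —
  chosen to give clearly separated rank strata at realistic FPKM
  magnitudes) and a planted −1 log₂ shift of HSD17B12 in the diabetic
  group, the direction the study's differential-expression result
  reports.

All generators are deterministic given `seed` and restore the caller's
RNG stream. What they do **not** emulate: linkage disequilibrium and
realistic allele frequencies, read-level sequencing error, catalog
trait-string noise, correlated genes, or the 2019 annotation snapshots
behind the original enrichment z/p/FDR values and partner counts — so
passing tests demonstrate the machinery is correct on known-truth data,
not that those snapshot-dependent numbers are recovered.

## 8. Numerical choices and test scales

Strict inequalities follow the source rules ("p < 0.05", "score more
than 0.5"); medians interpolate midpoints; all orderings have explicit
tie-breaks; degenerate enrichment terms and zero-IC denominators return
flagged finite values rather than NaN. The test suite sizes are the
package's own choices for exhaustive verifiability: enumeration oracles
run at universes ≤ 12 (tolerance 1e-12 against the exhaustive-draw
tail), ontology oracles on 100 random 12-term DAGs (1e-9), the Venn
oracle over all 2^G combinations for G ≤ 6, type-I calibration on 1000
null genes at the 63 vs 12 cohort sizes (within two binomial standard
deviations of 0.05), and power at a planted two-SD shift over 500
replicates (≥ 90%).

## 9. Known limitations

Cytoband-granularity intersection inherits the catalog's band labels,
including their errors; no LD-aware clumping or physical-distance
clustering is attempted. The enrichment and similarity stages are only
as good as the annotation sets supplied. The embedded-table defects
described above (duplicated bands across Venn cells; tie genes at the
burden threshold) are reported faithfully instead of being corrected,
because any correction would be a guess about the source data.
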