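vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    paste0('##INFO=<ID=CSQ,Number=.,Type=String,Description="Format: ',
           "Allele|SYMBOL|Consequence|IMPACT|SIFT|PolyPhen|GMAF|EUR_MAF", '">'),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

write_vcf_lines <- function(lines, samples = "S1") {
  p <- tempfile(fileext = ".vcf")
  writeLines(c(vcf_header(samples), lines), p)
  p
}

test_that("a single-sample VCF ingests genotypes as encoded", {
  p <- write_vcf_lines(c(
    "1\t100\trs1\tA\tG\t.\tPASS\tCSQ=G|GENE1|missense_variant|MODERATE|deleterious(0)|benign(0.1)|0.001|0.002\tGT\t0/1",
    "2\t200\t.\tC\tT\t.\tPASS\t.\tGT\t1/1",
    "X\t300\t.\tG\tA\t.\tPASS\t.\tGT\t1"))
  fam <- read_family_vcf(p, c(S1 = "child"))
  expect_equal(nrow(fam), 3)
  expect_equal(fam$gt_child, c("0/1", "1/1", "1"))
  expect_equal(fam$gene[1], "GENE1")
  expect_equal(fam$sift[1], "deleterious")
  expect_equal(fam$maf_eur[1], 0.002)
  expect_equal(fam$id[1], "rs1")
  expect_true(all(is.na(fam$maf_global[2:3])))   # no annotation: missing, not 0
})

test_that("multi-allelic records split into per-allele rows on ingest", {
  p <- write_vcf_lines(
    "1\t100\t.\tG\tA,T\t.\tPASS\t.\tGT\t1/2")
  fam <- read_family_vcf(p, c(S1 = "child"))
  expect_equal(nrow(fam), 2)
  expect_equal(fam$alt, c("A", "T"))
  expect_equal(fam$gt_child, c("1/0", "0/1"))
  expect_equal(fam$ref, c("G", "G"))
})

test_that("a header-only VCF gives an empty family with valid samples", {
  p <- write_vcf_lines(character(0))
  fam <- read_family_vcf(p, c(S1 = "child"))
  expect_equal(nrow(fam), 0)
  expect_equal(family_samples(fam)$role, "child")
})

test_that("configuration errors name the problem", {
  p <- write_vcf_lines("1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1")
  expect_error(read_family_vcf(p, c(NOSUCH = "child")), "NOSUCH")
  expect_error(read_family_vcf(p, c(S1 = "child", S1 = "mother")),
               "same sample")
  expect_error(read_family_vcf(p, c(S1 = "child", S2 = "child")), "same role")
  expect_error(read_family_vcf(p, c(S1 = "uncle")), "roles")
})

test_that("sites absent from one per-sample VCF are missing, not hom_ref", {
  p1 <- write_vcf_lines(c("1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t1/1",
                          "1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0/1"), "KID")
  p2 <- write_vcf_lines("1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1", "MUM")
  fam <- read_family_vcf(c(p1, p2), c(KID = "child", MUM = "mother"))
  expect_equal(nrow(fam), 2)
  expect_equal(fam$gt_mother, c("0/1", NA))
  expect_true(gt_is_missing(fam$gt_mother[2]))
})

test_that("a sidecar annotation file overrides CSQ parsing", {
  sc <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    chrom = "1", pos = 100L, ref = "A", alt = "G", gene = "ATP8B1",
    consequence = "missense_variant", impact = "MODERATE",
    sift = "tolerated", polyphen = "benign", GMAF = 0.0016, EUR_MAF = 0.0043), sc)
  p <- write_vcf_lines("1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1")
  fam <- read_family_vcf(p, c(S1 = "child"),
                         config = annotation_config(sidecar = sc))
  expect_equal(fam$gene, "ATP8B1")
  expect_equal(fam$maf_global, 0.0016)
})

test_that("write then read preserves every variant and genotype", {
  sf <- simulate_family(pedigree_trio(0, child_sex = "M"),
                        spectrum_params(n_sites = 300), seed = 31)
  fam <- sf$family
  s <- family_samples(fam)
  p <- tempfile(fileext = ".vcf")
  write_family_vcf(fam, p)
  back <- read_family_vcf(p, stats::setNames(s$role, s$sample_id),
                          sexes = stats::setNames(s$sex, s$sample_id))
  a <- as.data.frame(tibble::as_tibble(fam))
  b <- as.data.frame(tibble::as_tibble(back))[, names(a)]
  expect_equal(a, b, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("multi-allelic emission collapses and splits back losslessly", {
  fam <- make_family(c("0/1", "0/1", "1/1"),
                     c("0/1", "0/0", "0/0"),
                     c("0/0", "0/1", "1/1"),
                     chrom = "5", pos = c(100L, 100L, 200L),
                     ref = "G", alt = c("A", "T", "C"),
                     maf_global = 0.01, maf_eur = 0.01)
  p <- tempfile(fileext = ".vcf")
  write_family_vcf(fam, p, collapse_multiallelic = TRUE)
  raw <- readLines(p)
  expect_equal(sum(!startsWith(raw, "#")), 2)   # two records: pos 100 + 200
  expect_true(any(grepl("\tA,T\t", raw)))
  back <- read_family_vcf(p, c(C = "child", M = "mother", F = "father"))
  expect_equal(variant_key(back), variant_key(fam))
  # genotypes survive up to allele order within the unphased call
  # (splitting a joint 1/2 call is positional: 1/0 and 0/1)
  for (col in c("gt_child", "gt_mother", "gt_father")) {
    expect_equal(gt_class(back[[col]]), gt_class(fam[[col]]), label = col)
    expect_equal(gt_alt_count(back[[col]]), gt_alt_count(fam[[col]]))
  }
})

test_that("variant tables are written sorted with dots for missing", {
  tbl <- tibble::tibble(
    chrom = c("10", "2", "X"), pos = c(5L, 7L, 1L), ref = "A", alt = "G",
    gene = c(NA, "ABCB11", "FAM104B"), gt_child = "0/1",
    maf_global = c(0.1, NA, 0.2))
  p <- tempfile(fileext = ".tsv")
  write_variant_table(tbl, p)
  out <- readr::read_tsv(p, show_col_types = FALSE, na = ".")
  expect_equal(as.character(out$chrom), c("2", "10", "X"))
  expect_true(is.na(out$gene[2]) && is.na(out$maf_global[1]))
  lines <- readLines(p)
  expect_length(lines, 4)   # header + 3 rows
  # empty table still writes a header
  write_variant_table(tbl[0, ], p)
  expect_length(readLines(p), 1)
})

test_that("a malformed VCF fails with a parse error naming the file", {
  p <- tempfile(fileext = ".vcf")
  writeLines(c("not a vcf at all", "x\ty"), p)
  expect_error(suppressWarnings(read_family_vcf(p, c(S1 = "child"))),
               "parse|VCF")
})
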