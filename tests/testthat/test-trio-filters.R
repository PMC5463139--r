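DIPLOID <- c("0/0", "0/1", "1/1")

# All 27 diploid trio combinations in one family (one variant per combo).
trio_grid <- tidyr::expand_grid(child = DIPLOID, mother = DIPLOID,
                                father = DIPLOID)

test_that("recessive calls match the exhaustive trio truth table", {
  fam <- make_family(trio_grid$child, trio_grid$mother, trio_grid$father)
  keys <- variant_key(fam)
  # hand-enumerated truth: with unaffected parents the only recessive
  # pattern is child 1/1 with both parents 0/1
  expected <- keys[trio_grid$child == "1/1" &
                     trio_grid$mother == "0/1" & trio_grid$father == "0/1"]
  expect_setequal(classify_recessive(fam), expected)
  expect_length(expected, 1)
})

test_that("de novo calls match the exhaustive trio truth table", {
  fam <- make_family(trio_grid$child, trio_grid$mother, trio_grid$father)
  keys <- variant_key(fam)
  expected <- keys[trio_grid$child == "0/1" &
                     trio_grid$mother == "0/0" & trio_grid$father == "0/0"]
  expect_setequal(classify_dominant(fam, "de_novo"), expected)
})

test_that("affected-parent dominant calls match the truth table", {
  fam <- make_family(trio_grid$child, trio_grid$mother, trio_grid$father,
                     mother_affected = TRUE)
  keys <- variant_key(fam)
  # child het, affected mother a carrier (0/1 or 1/1), unaffected father 0/0
  expected <- keys[trio_grid$child == "0/1" &
                     trio_grid$mother %in% c("0/1", "1/1") &
                     trio_grid$father == "0/0"]
  expect_setequal(classify_dominant(fam, "affected_parent"), expected)
  expect_length(expected, 2)
})

test_that("missing genotypes disqualify rather than impute", {
  fam <- make_family(c("1/1", "1/1", "0/1"),
                     c("0/1", "./.", "./."),
                     c("./.", "0/1", "0/0"))
  expect_length(classify_recessive(fam), 0)
  expect_length(classify_dominant(fam, "de_novo"), 0)
})

test_that("hemizygous X cases follow homozygous-equivalent rules", {
  # male child: alt hemizygote with het mother qualifies; the father's X is
  # irrelevant to a son unless he is an unaffected alt hemizygote (excluded)
  fam <- make_family(c("1", "1", "1", "0"),
                     c("0/1", "0/1", "0/0", "0/1"),
                     c("0", "1", "0", "0"),
                     chrom = "X")
  keys <- variant_key(fam)
  expect_setequal(classify_recessive(fam), keys[1])
  # female child 1/1 on X needs a transmitting father, but an unaffected
  # hemizygous-alt father is homozygous-equivalent, hence excluded
  fam_f <- make_family("1/1", "0/1", "1", chrom = "X")
  expect_length(classify_recessive(fam_f), 0)
})

test_that("duo recessive accepts het parent and excludes homozygous parent", {
  fam <- make_family(c("1/1", "1/1", "1/1", "0/1"),
                     gt_mother = c("0/1", "1/1", "0/0", "0/1"))
  expect_setequal(classify_recessive(fam), variant_key(fam)[1])
})

test_that("segregation preconditions are enforced", {
  fam <- make_family("0/1")
  expect_error(classify_recessive(fam), "parent")
  expect_error(classify_dominant(fam, "de_novo"), "parent")
  fam2 <- make_family("0/1", "0/1", "0/0")
  expect_error(classify_dominant(fam2, "affected_parent"), "affected")
})

test_that("compound heterozygotes require trans parental origin in one gene", {
  fam <- make_family(
    gt_child  = c("0/1", "0/1", "0/1", "0/1", "0/1", "0/1"),
    gt_mother = c("0/1", "0/0", "0/1", "0/1", "0/1", "0/1"),
    gt_father = c("0/0", "0/1", "0/1", "0/0", "0/0", "0/0"),
    gene = c("G1", "G1", "G1", "G2", "G3", "G3"))
  keys <- variant_key(fam)
  pairs <- find_compound_het(fam)
  # G1: v1 maternal, v2 paternal -> one pair; v3 carried by both parents
  # never pairs; G2 has one variant; G3 variants are cis (both maternal)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$gene, "G1")
  expect_setequal(c(pairs$key_maternal, pairs$key_paternal), keys[1:2])
})

test_that("compound het agrees with a brute-force origin enumeration", {
  set.seed(42)
  for (rep in 1:20) {
    n <- 12
    fam <- make_family(
      gt_child  = sample(DIPLOID, n, replace = TRUE),
      gt_mother = sample(c(DIPLOID, "./."), n, replace = TRUE),
      gt_father = sample(c(DIPLOID, "./."), n, replace = TRUE),
      gene = sample(c("A", "B", "C"), n, replace = TRUE))
    keys <- variant_key(fam)
    # independent oracle: explicit loops over all variant pairs
    oracle <- list()
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      gi <- fam$gene[i]; gj <- fam$gene[j]
      if (gi != gj) next
      ok <- function(k) {
        cm <- gt_class(fam$gt_mother[k]); cf <- gt_class(fam$gt_father[k])
        gt_class(fam$gt_child[k]) == "het" &&
          cm != "missing" && cf != "missing" &&
          cm != "hom_alt" && cf != "hom_alt"
      }
      origin <- function(k) {
        m <- gt_class(fam$gt_mother[k]) %in% c("het", "hom_alt")
        f <- gt_class(fam$gt_father[k]) %in% c("het", "hom_alt")
        if (m && !f) "M" else if (f && !m) "F" else "none"
      }
      if (ok(i) && ok(j) && origin(i) != "none" && origin(j) != "none" &&
          origin(i) != origin(j)) {
        oracle[[length(oracle) + 1]] <- sort(c(keys[i], keys[j]))
      }
    }
    got <- find_compound_het(fam)
    got_pairs <- purrr::map2(got$key_maternal, got$key_paternal,
                             ~ sort(c(.x, .y)))
    expect_setequal(got_pairs, oracle)
  }
})

test_that("compound het on a duo is a phase-undetermined error", {
  fam <- make_family(c("0/1", "0/1"), gt_mother = c("0/1", "0/0"))
  expect_error(find_compound_het(fam), "phase")
})

test_that("cascade counts recover an injected ladder exactly", {
  sf <- simulate_family(pedigree_trio(0), spectrum_params(n_sites = 1500),
                        inject = standard_injection(), seed = 7)
  counts <- cascade_counts(sf$family)
  expect_equal(counts$recessive_homozygous, 10)
  expect_equal(counts$rare, 4)
  expect_equal(counts$nonsynonymous, 3)
  expect_equal(counts$deleterious_in_silico, 2)
  expect_equal(counts$total_variants, counts$snps + counts$indels)
})

test_that("cascade on degenerate inputs is all zero", {
  empty <- make_family(character(0), character(0), character(0))
  cz <- cascade_counts(empty)
  expect_equal(cz$total_variants, 0)
  expect_equal(cz$deleterious_in_silico, 0)
  hets <- make_family(rep("0/1", 5), "0/1", "0/1")
  expect_equal(cascade_counts(hets)$recessive_homozygous, 0)
})

test_that("cascade stages are monotone on random families", {
  for (seed in 1:5) {
    sf <- simulate_family(pedigree_trio(0), spectrum_params(n_sites = 600),
                          seed = seed)
    cc <- cascade_counts(sf$family)
    expect_true(cc$recessive_homozygous >= cc$rare)
    expect_true(cc$rare >= cc$nonsynonymous)
    expect_true(cc$nonsynonymous >= cc$deleterious_in_silico)
  }
})
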