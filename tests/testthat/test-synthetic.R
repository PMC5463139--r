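test_that("spectrum construction honours its parameters", {
  all_rare <- simulate_spectrum(
    spectrum_params(n_sites = 200, rare_fraction = 1,
                    rare_maf_range = c(1e-4, 1e-2)), seed = 1)
  expect_true(all(all_rare$maf_global < 0.01))
  chr1 <- simulate_spectrum(
    spectrum_params(n_sites = 100, chromosome_weights = c(`1` = 1)), seed = 2)
  expect_true(all(chr1$chrom == "1"))
  # positions strictly increasing within chromosome
  sp <- simulate_spectrum(spectrum_params(n_sites = 3000), seed = 3)
  by_chr <- split(sp$pos, sp$chrom)
  expect_true(all(purrr::map_lgl(by_chr, ~ all(diff(.x) > 0))))
  expect_true(all(sp$maf_eur > 0 & sp$maf_eur < 1))
  expect_identical(sp, simulate_spectrum(spectrum_params(n_sites = 3000), seed = 3))
})

test_that("empirical rare fraction matches the mixture weight", {
  sp <- simulate_spectrum(spectrum_params(n_sites = 10000, rare_fraction = 0.6),
                          seed = 4)
  obs <- sum(sp$maf_global < 0.01)
  ci <- stats::binom.test(obs, 10000, 0.6)$p.value
  expect_gt(ci, 1e-4)
})

test_that("pedigree kinship recursion matches textbook values", {
  expect_equal(pedigree_trio(0)$kinship, 0)
  expect_equal(pedigree_trio(1 / 4)$kinship, 1 / 4)
  expect_equal(pedigree_trio(1 / 16)$kinship, 1 / 16)
  expect_equal(pedigree_trio(1 / 64)$kinship, 1 / 64)
  sibs <- pedigree_trio(1 / 4)$members
  expect_equal(kinship_coefficient(sibs, "F1", "F1"), 1 / 2)  # non-inbred self
  expect_equal(kinship_coefficient(sibs, "GF", "F1"), 1 / 4)  # parent-child
})

test_that("pedigree validation rejects malformed graphs", {
  bad <- tibble::tibble(id = c("A", "B"), father = c("B", "A"),
                        mother = c("B", "A"), sex = c("M", "F"))
  expect_error(pedigree_spec(bad, "A", "B"), "cycle|both parents|female")
  half <- tibble::tibble(id = "A", father = "X", mother = NA, sex = "M")
  expect_error(pedigree_spec(half, "A", "A"), "both parents")
  ok <- pedigree_trio(0)
  expect_error(
    pedigree_spec(ok$members, "F1", "M1", "C1", kinship_label = 1 / 16),
    "kinship")
})

test_that("gene drop is Mendelian-consistent and respects the X", {
  sf <- simulate_family(pedigree_trio(0, child_sex = "M"),
                        spectrum_params(n_sites = 3000), seed = 12)
  fam <- sf$family
  auto <- fam$chrom != "X"
  cc <- gt_alt_count(fam$gt_child)
  cm <- gt_alt_count(fam$gt_mother)
  cf <- gt_alt_count(fam$gt_father)
  # autosomes: child must receive one allele from each parent
  ok <- (cc - pmax(0, cm - 1) - pmax(0, cf - 1) >= 0) &
    (cc <= pmin(1, cm) + pmin(1, cf))
  expect_true(all(ok[auto]))
  # male child: hemizygous on X, allele drawn from the mother
  x <- which(fam$chrom == "X")
  expect_true(all(fam$gt_child[x] %in% c("0", "1")))
  expect_true(all(fam$gt_father[x] %in% c("0", "1")))
  expect_true(all(cc[x] <= pmin(1, cm[x])))
})

test_that("founder genotypes sit in Hardy-Weinberg proportions", {
  sites <- tibble::tibble(chrom = "1", pos = seq_len(20000),
                          maf_eur = 0.3)
  grid <- gene_drop(pedigree_trio(0), sites, seed = 13)
  counts <- table(factor(grid$F1, levels = c("0/0", "0/1", "1/1")))
  p <- 0.3
  expect_gt(stats::chisq.test(counts, p = c((1 - p)^2, 2 * p * (1 - p), p^2))$p.value,
            1e-4)
})

test_that("unrelated founders are independent; siblings share excess", {
  sites <- tibble::tibble(chrom = "1", pos = seq_len(10000), maf_eur = 0.005)
  unrel <- gene_drop(pedigree_trio(0), sites, seed = 14)
  tab <- table(gt_is_carrier(unrel$F1), gt_is_carrier(unrel$M1))
  expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 1e-4)
  sib <- gene_drop(pedigree_trio(1 / 4), sites, seed = 15)
  f_carrier <- gt_is_carrier(sib$F1)
  # sharing of a rare allele between siblings ~ 1/2, far above the
  # Hardy-Weinberg expectation of ~1%
  shared <- mean(gt_is_carrier(sib$M1)[f_carrier])
  expect_gt(shared, 10 * expected_sharing_probability(0.005))
})

test_that("empirical kinship matches the pedigree label", {
  sites <- tibble::tibble(chrom = "1", pos = seq_len(20000), maf_eur = 0.35)
  for (phi in c(0, 1 / 16, 1 / 4)) {
    grid <- gene_drop(pedigree_trio(phi), sites, seed = 16 + round(64 * phi))
    r <- stats::cor(gt_alt_count(grid$F1), gt_alt_count(grid$M1))
    expect_lt(abs(r / 2 - phi), 0.02)
  }
})

test_that("site annotation assigns genes by interval and labels by mixture", {
  gm <- tibble::tibble(gene = c("ATP8B1", "OTHER"), chrom = c("18", "18"),
                       start = c(100L, 500L), end = c(200L, 600L))
  sites <- tibble::tibble(chrom = "18", pos = c(150L, 550L, 900L),
                          maf_eur = 0.01, maf_global = 0.01)
  forced <- tibble::tibble(consequence = "missense_variant", impact = "MODERATE",
                           sift = "deleterious", polyphen = "probably_damaging",
                           prob = 1)
  ann <- annotate_sites(sites, gm, forced, seed = 17)
  expect_equal(ann$gene, c("ATP8B1", "OTHER", NA))
  expect_equal(ann$consequence[3], "intergenic_variant")
  genic <- !is.na(ann$gene)
  expect_true(all(is_deleterious_in_silico(ann$sift[genic], ann$polyphen[genic],
                                           ann$impact[genic])))
  overlapping <- tibble::tibble(gene = c("A", "B"), chrom = "1",
                                start = c(1L, 50L), end = c(100L, 120L))
  expect_error(annotate_sites(sites |> dplyr::mutate(chrom = "1"),
                              overlapping, forced), "overlap")
})

test_that("label frequencies follow the configured distribution", {
  labels <- default_label_distribution()
  sites <- simulate_spectrum(spectrum_params(n_sites = 10000), seed = 18)
  ann <- annotate_sites(sites, labels = labels, seed = 19)
  genic <- !is.na(ann$gene)
  obs <- table(factor(ann$consequence[genic], levels = unique(labels$consequence)))
  probs <- tapply(labels$prob, factor(labels$consequence,
                                      levels = unique(labels$consequence)), sum)
  expect_gt(stats::chisq.test(obs, p = probs)$p.value, 1e-4)
})

test_that("injection with an all-zero spec changes nothing", {
  sf0 <- simulate_family(pedigree_trio(0), spectrum_params(n_sites = 300),
                         seed = 20)
  out <- inject_ground_truth(sf0$family, injection_spec(), seed = 21)
  expect_equal(nrow(out$manifest), 0)
  expect_equal(tibble::as_tibble(out$family)[c("gene", "gt_child")],
               tibble::as_tibble(sf0$family)[c("gene", "gt_child")])
})

test_that("injection fails loudly when sites run out", {
  sf <- simulate_family(pedigree_trio(0), spectrum_params(n_sites = 20),
                        seed = 22)
  expect_error(
    inject_ground_truth(sf$family, injection_spec(recessive_total = 1000),
                        seed = 1),
    "required")
  expect_error(injection_spec(recessive_total = 1, recessive_rare = 2),
               "ladder")
})

test_that("the pipeline recovers injected truth exactly", {
  sf <- simulate_family(pedigree_trio(0), spectrum_params(n_sites = 1500),
                        inject = standard_injection(), seed = 23)
  fam <- sf$family
  man <- sf$manifest
  expect_setequal(classify_recessive(fam),
                  man$key[man$class == "recessive_homozygous"])
  pairs <- find_compound_het(fam)
  expect_setequal(c(pairs$key_maternal, pairs$key_paternal),
                  man$key[man$class == "compound_het_member"])
  rep <- scan_panels(fam)
  gs <- load_gene_sets()
  hits <- man[man$class == "panel_hit", ]
  expected_rows <- purrr::map_dfr(seq_len(nrow(hits)), function(i) {
    tibble::tibble(key = hits$key[i],
                   category = gs$category[gs$gene == hits$gene[i]])
  })
  expect_setequal(paste(rep$key, rep$category),
                  paste(expected_rows$key, expected_rows$category))
})

test_that("simulation is fully deterministic under a fixed seed", {
  a <- simulate_family(pedigree_trio(1 / 16), spectrum_params(n_sites = 400),
                       inject = injection_spec(recessive_total = 2,
                                               recessive_rare = 1),
                       seed = 24)
  b <- simulate_family(pedigree_trio(1 / 16), spectrum_params(n_sites = 400),
                       inject = injection_spec(recessive_total = 2,
                                               recessive_rare = 1),
                       seed = 24)
  expect_identical(tibble::as_tibble(a$family), tibble::as_tibble(b$family))
  expect_identical(a$manifest, b$manifest)
})
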