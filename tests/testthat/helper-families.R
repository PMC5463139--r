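# Build a small family table by hand: one row per element of gt_child,
# annotation vectors recycled. Parents are included only when given.
make_family <- function(gt_child, gt_mother = NULL, gt_father = NULL,
                        gene = "GENEX", consequence = "missense_variant",
                        impact = "MODERATE", sift = NA_character_,
                        polyphen = NA_character_, maf_global = NA_real_,
                        maf_eur = NA_real_, chrom = "1",
                        pos = NULL, ref = "A", alt = "G",
                        mother_affected = FALSE, father_affected = FALSE) {
  n <- length(gt_child)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  tbl <- tibble::tibble(
    chrom = rep_len(chrom, n), pos = as.integer(pos),
    ref = rep_len(ref, n), alt = rep_len(alt, n), id = NA_character_,
    gene = rep_len(gene, n), consequence = rep_len(consequence, n),
    impact = rep_len(impact, n), sift = rep_len(sift, n),
    polyphen = rep_len(polyphen, n),
    maf_global = rep_len(maf_global, n), maf_eur = rep_len(maf_eur, n),
    gt_child = gt_child
  )
  samples <- tibble::tibble(sample_id = "C", role = "child",
                            affected = TRUE, sex = NA_character_)
  if (!is.null(gt_mother)) {
    tbl$gt_mother <- rep_len(gt_mother, n)
    samples <- dplyr::bind_rows(samples, tibble::tibble(
      sample_id = "M", role = "mother", affected = mother_affected, sex = "F"))
  }
  if (!is.null(gt_father)) {
    tbl$gt_father <- rep_len(gt_father, n)
    samples <- dplyr::bind_rows(samples, tibble::tibble(
      sample_id = "F", role = "father", affected = father_affected, sex = "M"))
  }
  family_genotypes(tbl, samples)
}

# Standard injection used by the exact-recovery fixtures.
standard_injection <- function() {
  injection_spec(
    recessive_total = 10, recessive_rare = 4, recessive_nonsyn = 3,
    recessive_deleterious = 2, compound_het_pairs = 2,
    panel_hits = c(cholestatic_disease = 1, bile_acid_metabolism = 1,
                   lipid_metabolism = 1))
}
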