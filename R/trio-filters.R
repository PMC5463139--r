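gt_ploidy <- function(gt) {
  vapply(gt, function(g) {
    if (is.na(g)) return(NA_integer_)
    length(strsplit(chartr("|", "/", g), "/", fixed = TRUE)[[1]])
  }, integer(1), USE.NAMES = FALSE)
}

# TRUE where an unaffected parent is homozygous (or hemizygous) alternate.
# Such variants are never reported, whatever else they satisfy.
parental_homozygote_excluded <- function(fam) {
  excl <- rep(FALSE, nrow(fam))
  for (p in parent_roles(fam)) {
    if (!role_affected(fam, p)) {
      excl <- excl | gt_is_hom_alt(fam[[paste0("gt_", p)]])
    }
  }
  excl
}

#' Recessive homozygous segregation
#'
#' Returns the identity keys of variants compatible with autosomal (or
#' X-linked) recessive inheritance. Trio mode: child homozygous alternate
#' and both parents heterozygous carriers. Duo mode (one parent available):
#' child homozygous alternate and the available parent a carrier but not
#' homozygous. A hemizygous alternate call (male X) counts as
#' homozygous-equivalent, so a hemizygous child qualifies through a
#' heterozygous mother; the father's X does not reach a son, so for a
#' hemizygous child the father is only required to be genotyped and not an
#' unaffected homozygote. Variants homozygous alternate in any unaffected
#' parent are excluded outright, and a missing parental genotype disqualifies
#' the variant (conservative: no imputation).
#'
#' @param fam A [family_genotypes()] object with at least one parent.
#' @return Character vector of variant keys (see [variant_key()]).
#' @export
classify_recessive <- function(fam) {
  parents <- parent_roles(fam)
  if (length(parents) == 0) {
    rlang::abort(paste("classify_recessive(): no parents in family;",
                       "segregation filtering needs a trio or duo",
                       "(use the cascade on single samples without it)"))
  }
  child_gt <- fam$gt_child
  pass <- gt_is_hom_alt(child_gt)
  child_hemi <- !is.na(gt_ploidy(child_gt)) & gt_ploidy(child_gt) == 1
  for (p in parents) {
    pgt <- fam[[paste0("gt_", p)]]
    req <- if (p == "father") {
      # a son's alt allele cannot come from the father's X
      ifelse(child_hemi, !gt_is_missing(pgt), gt_is_het(pgt))
    } else {
      gt_is_het(pgt)
    }
    pass <- pass & req
  }
  pass <- pass & !parental_homozygote_excluded(fam)
  variant_key(fam)[pass]
}

#' Dominant / de novo segregation
#'
#' `mode = "affected_parent"`: child heterozygous and the carrier parents
#' are exactly the affected ones — every affected parent carries the variant
#' and every unaffected parent is homozygous reference. Requires at least
#' one parent flagged affected. `mode = "de_novo"`: child heterozygous and
#' every available parent homozygous reference. In both modes a missing
#' parental genotype disqualifies the variant, and the unaffected-parent
#' homozygote exclusion applies.
#'
#' @param fam A [family_genotypes()] object with at least one parent.
#' @param mode `"affected_parent"` or `"de_novo"`.
#' @return Character vector of variant keys.
#' @export
classify_dominant <- function(fam, mode = c("affected_parent", "de_novo")) {
  mode <- match.arg(mode)
  parents <- parent_roles(fam)
  if (length(parents) == 0) {
    rlang::abort("classify_dominant(): no parents in family")
  }
  pass <- gt_is_het(fam$gt_child)
  if (mode == "de_novo") {
    for (p in parents) {
      pass <- pass & gt_is_hom_ref(fam[[paste0("gt_", p)]])
    }
  } else {
    affected <- parents[purrr::map_lgl(parents, ~ role_affected(fam, .x))]
    if (length(affected) == 0) {
      rlang::abort(paste("classify_dominant(mode = 'affected_parent'):",
                         "no parent is flagged affected; use mode = 'de_novo'",
                         "for unaffected parents"))
    }
    for (p in parents) {
      pgt <- fam[[paste0("gt_", p)]]
      pass <- pass & if (p %in% affected) gt_is_carrier(pgt) else gt_is_hom_ref(pgt)
    }
  }
  pass <- pass & !parental_homozygote_excluded(fam)
  variant_key(fam)[pass]
}

#' Compound heterozygote detection by parental origin
#'
#' Finds pairs of distinct heterozygous child variants in the same gene that
#' are in trans by parental origin: one carried by exactly the mother, the
#' other by exactly the father. All qualifying unordered pairs per gene are
#' returned. Pairs are dropped when either member is homozygous alternate in
#' an unaffected parent, and variants with a missing parental genotype
#' cannot be assigned an origin and never pair. Requires both parents:
#' with a single parent the phase is undetermined, which is an error rather
#' than a silent empty result.
#'
#' @param fam A [family_genotypes()] object with both parents.
#' @return A tibble with columns `gene`, `key_maternal`, `key_paternal`.
#' @export
find_compound_het <- function(fam) {
  if (!all(c("mother", "father") %in% roles_present(fam))) {
    rlang::abort(paste("find_compound_het(): phase-undetermined —",
                       "both parents are required to assign parental origin"))
  }
  m_carrier <- gt_is_carrier(fam$gt_mother)
  f_carrier <- gt_is_carrier(fam$gt_father)
  usable <- gt_is_het(fam$gt_child) &
    !gt_is_missing(fam$gt_mother) & !gt_is_missing(fam$gt_father) &
    !is.na(fam$gene) & nzchar(fam$gene) &
    !parental_homozygote_excluded(fam)
  maternal <- usable & m_carrier & !f_carrier
  paternal <- usable & f_carrier & !m_carrier

  keys <- variant_key(fam)
  cand <- tibble::tibble(
    gene = fam$gene[maternal | paternal],
    key = keys[maternal | paternal],
    origin = ifelse(maternal[maternal | paternal], "mother", "father")
  )
  pairs <- cand |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_modify(function(g, key_) {
      mk <- g$key[g$origin == "mother"]
      fk <- g$key[g$origin == "father"]
      if (length(mk) == 0 || length(fk) == 0) {
        return(tibble::tibble(key_maternal = character(), key_paternal = character()))
      }
      tidyr::expand_grid(key_maternal = mk, key_paternal = fk)
    }) |>
    dplyr::ungroup()
  pairs
}

#' Filter cascade counts
#'
#' Reproduces the per-child count ladder of a family-based exome screen:
#' recessive homozygous candidates, of those the rare ones (population MAF
#' below `threshold` or missing), of those the nonsynonymous /
#' splice-affecting ones, of those the in-silico deleterious ones. Each
#' stage filters the survivors of the previous stage, so the counts are
#' monotone non-increasing. `total_variants`, `snps` and `indels` count all
#' variants carried by the child (SNP = single-base ref and alt).
#'
#' @param fam A [family_genotypes()] object (trio or duo).
#' @param threshold Rarity cutoff, see [is_rare()]. Default `0.01`.
#' @param population Population whose MAF drives rarity (default `GLOBAL`).
#' @return A one-row tibble of class `cascade_counts` with columns
#'   `total_variants`, `snps`, `indels`, `recessive_homozygous`, `rare`,
#'   `nonsynonymous`, `deleterious_in_silico`, `rarity_threshold`,
#'   `population`.
#' @export
cascade_counts <- function(fam, threshold = 0.01, population = "GLOBAL") {
  carried <- gt_is_carrier(fam$gt_child)
  is_snp <- nchar(fam$ref) == 1 & nchar(fam$alt) == 1
  rec_keys <- classify_recessive(fam)
  rec <- variant_key(fam) %in% rec_keys
  maf <- maf_column(fam, population)
  rare <- rec & is_rare(maf, threshold)
  nonsyn <- rare & is_nonsynonymous(fam$consequence, fam$impact)
  delet <- nonsyn & is_deleterious_in_silico(fam$sift, fam$polyphen, fam$impact)
  out <- tibble::tibble(
    total_variants = sum(carried),
    snps = sum(carried & is_snp),
    indels = sum(carried & !is_snp),
    recessive_homozygous = sum(rec),
    rare = sum(rare),
    nonsynonymous = sum(nonsyn),
    deleterious_in_silico = sum(delet),
    rarity_threshold = threshold,
    population = population
  )
  class(out) <- c("cascade_counts", class(out))
  out
}

#' Per-member variant totals
#'
#' Counts, for each family member, the variants it carries, split into SNPs
#' and indels — the per-person summary columns of a family report.
#'
#' @param fam A [family_genotypes()] object.
#' @return A tibble with columns `role`, `sample_id`, `variants`, `snps`,
#'   `indels`.
#' @export
member_variant_counts <- function(fam) {
  samples <- family_samples(fam)
  is_snp <- nchar(fam$ref) == 1 & nchar(fam$alt) == 1
  purrr::map_dfr(seq_len(nrow(samples)), function(i) {
    carried <- gt_is_carrier(fam[[paste0("gt_", samples$role[i])]])
    tibble::tibble(role = samples$role[i], sample_id = samples$sample_id[i],
                   variants = sum(carried), snps = sum(carried & is_snp),
                   indels = sum(carried & !is_snp))
  })
}
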