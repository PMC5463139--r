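KARYOTYPE_ORDER <- c(as.character(1:22), "X", "Y", "MT")

ROLES <- c("child", "mother", "father")

#' Construct a family genotype table
#'
#' The central container: one row per bi-allelic variant with its annotation,
#' plus one genotype column per family member, named `gt_child`, `gt_mother`,
#' `gt_father` by role. A family has exactly one child and zero, one or two
#' parents; roles are unique. Sample metadata (`sample_id`, `role`,
#' `affected`, `sex`) live in the `samples` attribute, retrievable with
#' [family_samples()].
#'
#' @param variants A data frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (and typically `id`, `gene`, `consequence`, `impact`, `sift`,
#'   `polyphen`, `maf_*`) plus one `gt_<role>` column per sample.
#' @param samples A data frame with columns `sample_id`, `role` (one of
#'   `child`, `mother`, `father`), `affected` (logical) and optionally `sex`
#'   (`"M"`, `"F"` or `NA`).
#' @return A tibble of class `family_genotypes`, sorted in karyotype order.
#' @export
family_genotypes <- function(variants, samples) {
  samples <- tibble::as_tibble(samples)
  if (!"sex" %in% names(samples)) samples$sex <- NA_character_
  if (!"affected" %in% names(samples)) {
    samples$affected <- samples$role == "child"
  }
  stopifnot(all(c("sample_id", "role", "affected") %in% names(samples)))
  if (anyDuplicated(samples$role)) {
    rlang::abort("family_genotypes(): duplicate roles in `samples`")
  }
  if (!all(samples$role %in% ROLES)) {
    rlang::abort(paste0("family_genotypes(): roles must be among ",
                        paste(ROLES, collapse = ", ")))
  }
  if (sum(samples$role == "child") != 1) {
    rlang::abort("family_genotypes(): exactly one sample must have role 'child'")
  }
  variants <- tibble::as_tibble(variants)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  gt_cols <- paste0("gt_", samples$role)
  missing_cols <- setdiff(gt_cols, names(variants))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("family_genotypes(): missing genotype column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  variants <- sort_karyotype(variants)
  new_family_genotypes(variants, samples)
}

new_family_genotypes <- function(variants, samples) {
  structure(variants,
            samples = samples,
            class = c("family_genotypes", class(tibble::tibble())))
}

#' @rdname family_genotypes
#' @param fam A `family_genotypes` object.
#' @export
family_samples <- function(fam) {
  s <- attr(fam, "samples", exact = TRUE)
  if (is.null(s)) rlang::abort("not a family_genotypes object (no samples attribute)")
  s
}

#' @export
print.family_genotypes <- function(x, ...) {
  s <- family_samples(x)
  cat("# family_genotypes: ", nrow(x), " variants; ",
      paste0(s$role, " (", s$sample_id, ifelse(s$affected, ", affected", ""), ")",
             collapse = ", "), "\n", sep = "")
  NextMethod()
}

roles_present <- function(fam) {
  intersect(ROLES, family_samples(fam)$role)
}

parent_roles <- function(fam) setdiff(roles_present(fam), "child")

role_affected <- function(fam, role) {
  s <- family_samples(fam)
  s$affected[s$role == role]
}

#' Variant identity keys
#'
#' The cross-sample matching identity of a post-split variant is the tuple
#' `(chrom, pos, ref, alt)`, rendered as `"chrom:pos:ref:alt"`.
#'
#' @param tbl A data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return Character vector of keys.
#' @export
variant_key <- function(tbl) {
  paste(tbl$chrom, tbl$pos, tbl$ref, tbl$alt, sep = ":")
}

# Karyotype chromosome order: 1..22, X, Y, MT, then anything else as given.
karyotype_rank <- function(chrom) {
  r <- match(chrom, KARYOTYPE_ORDER)
  r[is.na(r)] <- length(KARYOTYPE_ORDER) + 1
  r
}

sort_karyotype <- function(tbl) {
  tbl[order(karyotype_rank(tbl$chrom), tbl$pos, tbl$ref, tbl$alt), , drop = FALSE]
}

# Re-attach class/samples after dplyr verbs (which strip custom attributes).
restore_family <- function(tbl, fam) {
  new_family_genotypes(tibble::as_tibble(tbl), family_samples(fam))
}
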