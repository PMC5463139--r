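#' Genotype classification helpers
#'
#' Genotypes are stored as VCF-style strings over post-split allele indices:
#' `"0/0"`, `"0/1"`, `"1/1"` for diploid calls, `"0"`/`"1"` for hemizygous
#' calls (male X), and `"./."` or `"."` for missing. Phased separators (`|`)
#' are accepted and treated as unphased. `gt_class()` maps each genotype to
#' exactly one of `hom_ref`, `het`, `hom_alt`, `missing`; a hemizygous alt
#' call is classified `hom_alt` (homozygous-equivalent), which is how it is
#' treated by the recessive model and the parental-homozygote exclusion.
#'
#' @param gt Character vector of genotype strings.
#' @return `gt_class()`: a character vector over
#'   `c("hom_ref", "het", "hom_alt", "missing")`. The predicates return
#'   logical vectors; `gt_is_carrier()` is true for `het` and `hom_alt`
#'   (at least one alternate allele) and never for `missing`.
#' @examples
#' gt_class(c("0/0", "0/1", "1/1", "./.", "1"))
#' gt_is_carrier(c("0/1", "0/0", "1", "."))
#' @export
gt_class <- function(gt) {
  u <- unique(gt)
  cls <- vapply(u, gt_class_one, character(1), USE.NAMES = FALSE)
  cls[match(gt, u)]
}

gt_class_one <- function(g) {
  if (is.na(g)) return("missing")
  alleles <- strsplit(chartr("|", "/", g), "/", fixed = TRUE)[[1]]
  if (length(alleles) == 0 || any(alleles == "." | alleles == "")) {
    return("missing")
  }
  n_alt <- sum(alleles != "0")
  if (n_alt == 0) {
    "hom_ref"
  } else if (n_alt == length(alleles)) {
    "hom_alt"
  } else {
    "het"
  }
}

#' @rdname gt_class
#' @export
gt_is_carrier <- function(gt) gt_class(gt) %in% c("het", "hom_alt")

#' @rdname gt_class
#' @export
gt_is_hom_alt <- function(gt) gt_class(gt) == "hom_alt"

#' @rdname gt_class
#' @export
gt_is_het <- function(gt) gt_class(gt) == "het"

#' @rdname gt_class
#' @export
gt_is_hom_ref <- function(gt) gt_class(gt) == "hom_ref"

#' @rdname gt_class
#' @export
gt_is_missing <- function(gt) gt_class(gt) == "missing"

#' Count alternate alleles in genotype strings
#'
#' Counts non-reference allele indices (any index other than `0`) per
#' genotype; genotypes containing a missing allele yield `NA`. Used by the
#' allele-conservation property of [split_multiallelic()].
#'
#' @param gt Character vector of genotype strings (any allele indices).
#' @return Integer vector.
#' @export
gt_alt_count <- function(gt) {
  vapply(gt, function(g) {
    if (is.na(g)) return(NA_integer_)
    alleles <- strsplit(chartr("|", "/", g), "/", fixed = TRUE)[[1]]
    if (length(alleles) == 0 || any(alleles == "." | alleles == "")) {
      return(NA_integer_)
    }
    sum(alleles != "0")
  }, integer(1), USE.NAMES = FALSE)
}

#' Split a multi-allelic VCF record into bi-allelic records
#'
#' One record with `k` alternate alleles becomes `k` bi-allelic records, in
#' input ALT order. In the record for alternate allele `k`, genotype allele
#' index `k` is remapped to `1` and every other non-reference index to `0`
#' (reference-equivalent for that record); missing alleles stay missing. The
#' total alternate-allele count of each sample is conserved across the output
#' records.
#'
#' @param chrom,pos,ref Site coordinates and reference allele.
#' @param alts Character vector of alternate alleles (length >= 1).
#' @param gts Named character vector of genotype strings over allele indices
#'   `0..length(alts)` (names are sample ids). May be empty.
#' @return A list with one element per alternate allele, each a list with
#'   fields `chrom`, `pos`, `ref`, `alt` and `gts` (remapped genotypes).
#' @examples
#' split_multiallelic("1", 100, "G", c("A", "T"), c(S1 = "1/2"))
#' @export
split_multiallelic <- function(chrom, pos, ref, alts, gts = character(0)) {
  if (length(alts) < 1) {
    rlang::abort("split_multiallelic(): at least one alternate allele is required")
  }
  purrr::map(seq_along(alts), function(k) {
    remapped <- vapply(gts, function(g) {
      if (is.na(g)) return(NA_character_)
      sep <- if (grepl("|", g, fixed = TRUE)) "|" else "/"
      alleles <- strsplit(chartr("|", "/", g), "/", fixed = TRUE)[[1]]
      out <- vapply(alleles, function(a) {
        if (a == "." || a == "") "." else if (a == as.character(k)) "1" else "0"
      }, character(1))
      paste(out, collapse = sep)
    }, character(1))
    names(remapped) <- names(gts)
    list(chrom = chrom, pos = pos, ref = ref, alt = alts[[k]], gts = remapped)
  })
}
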