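#' Annotation configuration
#'
#' Declares how functional annotations are attached to variants: either a
#' VEP-style `CSQ` INFO field whose `|`-separated subfields are listed in
#' `csq_fields`, or a tab-delimited sidecar file keyed by
#' `chrom, pos, ref, alt`. `populations` maps population names (at least
#' `GLOBAL` and `EUR`) to the CSQ subfield / sidecar column holding that
#' population's minor allele frequency.
#'
#' The default layout matches what [write_family_vcf()] emits, so
#' synthetic families round-trip without extra configuration.
#'
#' @param csq_field Name of the INFO key carrying the annotation payload.
#' @param csq_fields Character vector naming the `|`-separated subfields, in
#'   order. Recognised names: `Allele`, `SYMBOL`, `Consequence`, `IMPACT`,
#'   `SIFT`, `PolyPhen`, plus the frequency fields named in `populations`.
#' @param populations Named character vector: population name -> field name.
#' @param sidecar Optional path to a tab-delimited annotation file with
#'   columns `chrom, pos, ref, alt, gene, consequence, impact, sift,
#'   polyphen` and one column per entry of `populations`. When set, the
#'   sidecar takes precedence over the CSQ field.
#' @return An object of class `annotation_config`.
#' @export
annotation_config <- function(csq_field = "CSQ",
                              csq_fields = c("Allele", "SYMBOL", "Consequence",
                                             "IMPACT", "SIFT", "PolyPhen",
                                             "GMAF", "EUR_MAF"),
                              populations = c(GLOBAL = "GMAF", EUR = "EUR_MAF"),
                              sidecar = NULL) {
  if (is.null(names(populations)) || any(!nzchar(names(populations)))) {
    rlang::abort("annotation_config(): `populations` must be a named vector")
  }
  structure(
    list(csq_field = csq_field, csq_fields = csq_fields,
         populations = populations, sidecar = sidecar),
    class = "annotation_config"
  )
}

# Severity order used to pick one transcript annotation per variant;
# higher is more severe. Ties keep the first-listed block.
impact_severity <- function(impact) {
  ranks <- c(HIGH = 4, MODERATE = 3, LOW = 2, MODIFIER = 1, UNKNOWN = 0)
  out <- ranks[impact]
  out[is.na(out)] <- 0
  unname(out)
}

SIFT_LABELS <- c("deleterious", "deleterious_low_confidence",
                 "tolerated", "tolerated_low_confidence")
POLYPHEN_LABELS <- c("probably_damaging", "possibly_damaging", "benign")
IMPACT_LABELS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

# Strip a trailing "(score)" from VEP SIFT/PolyPhen labels and validate
# against the known label set; anything unrecognised becomes NA (missing).
parse_predictor_label <- function(x, labels) {
  x <- stringr::str_trim(stringr::str_remove(x, "\\(.*\\)$"))
  x[!x %in% labels] <- NA_character_
  x
}

parse_maf_value <- function(x) {
  if (is.na(x) || !nzchar(x) || x %in% c(".", "-", "—")) {
    return(NA_real_)
  }
  val <- suppressWarnings(as.numeric(x))
  if (is.na(val) || val < 0 || val > 1) {
    rlang::warn(paste0("unparseable allele frequency '", x, "' treated as missing"))
    return(NA_real_)
  }
  val
}

empty_annotation <- function(config) {
  maf <- rep(NA_real_, length(config$populations))
  names(maf) <- names(config$populations)
  list(gene = NA_character_, consequence = NA_character_, impact = "UNKNOWN",
       sift = NA_character_, polyphen = NA_character_, maf = as.list(maf))
}

#' Parse one VEP-style annotation payload
#'
#' Parses the `CSQ` payload of a single variant (one or more comma-separated
#' transcript blocks of `|`-separated subfields) into a flat annotation.
#' When several transcript blocks are present, the block with the most severe
#' impact (`HIGH > MODERATE > LOW > MODIFIER > UNKNOWN`) is kept; ties keep
#' the first listed. When `allele` is given and the layout has an `Allele`
#' subfield, only blocks for that alternate allele are considered.
#'
#' The parser is total: unknown labels, absent fields, and unparseable
#' frequencies become missing (`NA`) or `UNKNOWN`, never a default such as
#' `0.0`; SIFT/PolyPhen score suffixes like `"tolerated(0.61)"` are stripped.
#'
#' @param raw The raw payload string (the value of the CSQ INFO key), or `NA`.
#' @param config An [annotation_config()].
#' @param allele Optional alternate allele used to select allele-specific
#'   transcript blocks.
#' @return A list with fields `gene`, `consequence`, `impact`, `sift`,
#'   `polyphen` and `maf` (named list, population -> frequency or `NA`).
#' @examples
#' cfg <- annotation_config()
#' parse_annotation("A|ATP8B1|missense_variant|MODERATE|tolerated_low_confidence(0.2)|benign(0.01)|0.0016|0.0043", cfg)
#' @export
parse_annotation <- function(raw, config = annotation_config(), allele = NULL) {
  if (is.null(raw) || length(raw) == 0 || is.na(raw) || !nzchar(raw)) {
    return(empty_annotation(config))
  }
  blocks <- strsplit(raw, ",", fixed = TRUE)[[1]]
  fields <- config$csq_fields
  parsed <- purrr::map(blocks, function(b) {
    vals <- strsplit(b, "|", fixed = TRUE)[[1]]
    length(vals) <- length(fields)          # pad short blocks with NA
    names(vals) <- fields
    vals
  })
  if (!is.null(allele) && "Allele" %in% fields) {
    keep <- purrr::map_lgl(parsed, ~ !is.na(.x[["Allele"]]) && .x[["Allele"]] == allele)
    if (any(keep)) parsed <- parsed[keep]
  }
  sev <- purrr::map_dbl(parsed, function(v) {
    imp <- v[["IMPACT"]]
    if (is.null(imp) || is.na(imp)) 0 else impact_severity(imp)
  })
  v <- parsed[[which.max(sev)]]             # which.max keeps the first tie

  field_or_na <- function(name) {
    if (!name %in% names(v) || is.null(v[[name]]) || is.na(v[[name]]) || !nzchar(v[[name]])) {
      NA_character_
    } else {
      v[[name]]
    }
  }
  impact <- field_or_na("IMPACT")
  if (is.na(impact) || !impact %in% IMPACT_LABELS) impact <- "UNKNOWN"
  maf <- purrr::map(config$populations, ~ parse_maf_value(field_or_na(.x)))
  names(maf) <- names(config$populations)
  list(
    gene = field_or_na("SYMBOL"),
    consequence = field_or_na("Consequence"),
    impact = impact,
    sift = parse_predictor_label(field_or_na("SIFT"), SIFT_LABELS),
    polyphen = parse_predictor_label(field_or_na("PolyPhen"), POLYPHEN_LABELS),
    maf = maf
  )
}

# Consequence terms considered protein-altering (always nonsynonymous).
PROTEIN_ALTERING_TERMS <- c(
  "missense_variant", "stop_gained", "stop_lost", "start_lost",
  "frameshift_variant", "inframe_insertion", "inframe_deletion",
  "protein_altering_variant", "transcript_ablation", "incomplete_terminal_codon_variant"
)
# Splice terms that rescue an otherwise excluded variant.
SPLICE_TERMS_ALWAYS <- c("splice_donor_variant", "splice_acceptor_variant")
SPLICE_TERMS_MODERATE <- "splice_region_variant"

#' Nonsynonymous / splice-affecting filter
#'
#' Keeps protein-altering consequences (missense, stop gained/lost, start
#' lost, frameshift, inframe indels, protein-altering) and splice-affecting
#' ones: `splice_donor_variant` and `splice_acceptor_variant` always,
#' `splice_region_variant` only when the impact is `MODERATE` or `HIGH`
#' (LOW-impact near-splice synonymous calls would otherwise flood the
#' reports). Synonymous, intronic, UTR, intergenic and other
#' MODIFIER-impact terms are excluded. A consequence may combine several
#' `&`-separated terms; any qualifying term keeps the variant.
#'
#' @param consequence Character vector of consequence terms.
#' @param impact Character vector of impact labels, recycled to match.
#' @return Logical vector.
#' @examples
#' is_nonsynonymous("missense_variant", "MODERATE")
#' is_nonsynonymous("synonymous_variant", "LOW")
#' is_nonsynonymous("splice_acceptor_variant&synonymous_variant", "HIGH")
#' @export
is_nonsynonymous <- function(consequence, impact = "UNKNOWN") {
  n <- max(length(consequence), length(impact))
  consequence <- rep_len(consequence, n)
  impact <- rep_len(impact, n)
  purrr::map2_lgl(consequence, impact, function(cons, imp) {
    if (is.na(cons)) return(FALSE)
    terms <- strsplit(cons, "&", fixed = TRUE)[[1]]
    if (any(terms %in% c(PROTEIN_ALTERING_TERMS, SPLICE_TERMS_ALWAYS))) {
      return(TRUE)
    }
    if (any(terms %in% SPLICE_TERMS_MODERATE) &&
        impact_severity(imp) >= impact_severity("MODERATE")) {
      return(TRUE)
    }
    FALSE
  })
}

#' In-silico deleteriousness filter
#'
#' A variant is deleterious in silico when SIFT calls it deleterious
#' (including low-confidence), or PolyPhen calls it probably or possibly
#' damaging, or its annotated impact is `HIGH` (e.g. a nonsense variant, for
#' which SIFT/PolyPhen emit no score). Missing predictors contribute
#' `FALSE`, so a fully unannotated variant is not deleterious.
#'
#' @param sift,polyphen,impact Character vectors of predictor labels,
#'   recycled to a common length.
#' @return Logical vector.
#' @examples
#' is_deleterious_in_silico("deleterious", "possibly_damaging", "MODERATE")
#' is_deleterious_in_silico(NA, NA, "HIGH")
#' is_deleterious_in_silico("tolerated", "benign", "MODERATE")
#' @export
is_deleterious_in_silico <- function(sift, polyphen, impact) {
  n <- max(length(sift), length(polyphen), length(impact))
  sift <- rep_len(sift, n)
  polyphen <- rep_len(polyphen, n)
  impact <- rep_len(impact, n)
  sift %in% c("deleterious", "deleterious_low_confidence") |
    polyphen %in% c("probably_damaging", "possibly_damaging") |
    impact %in% "HIGH"
}

#' Rarity filter on a population minor allele frequency
#'
#' True when the selected population's MAF is strictly below `threshold` or
#' missing: a variant absent from the reference panel is treated as novel,
#' hence rare (the convention under which unannotated candidates are still
#' reported).
#'
#' @param maf Numeric vector of frequencies in `[0, 1]`, `NA` = missing.
#' @param threshold Rarity cutoff in `(0, 1]` (default 0.01, i.e. MAF < 1%).
#' @return Logical vector.
#' @examples
#' is_rare(c(0.0016, 0.408, NA), threshold = 0.01)
#' @export
is_rare <- function(maf, threshold = 0.01) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      is.na(threshold) || threshold <= 0 || threshold > 1) {
    rlang::abort("is_rare(): `threshold` must be a single value in (0, 1]")
  }
  is.na(maf) | maf < threshold
}

# Resolve a population name to the maf_<pop> column of a family table.
maf_column <- function(tbl, population) {
  col <- paste0("maf_", tolower(population))
  if (!col %in% names(tbl)) {
    rlang::abort(paste0(
      "unknown population '", population, "': no column `", col, "` ",
      "(available: ",
      paste(sub("^maf_", "", grep("^maf_", names(tbl), value = TRUE)), collapse = ", "),
      ")"
    ))
  }
  tbl[[col]]
}
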