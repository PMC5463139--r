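PANEL_CATEGORIES <- c("cholestatic_disease", "bile_acid_metabolism",
                      "bile_secretion_transport", "liver_disease_other",
                      "lipid_metabolism")

#' Load gene panels from symbol lists
#'
#' Reads plain-text gene lists (one symbol per line, `#` comments and blank
#' lines ignored); symbols are trimmed, uppercased and deduplicated. The
#' five panel categories cover genes implicated in cholestatic liver
#' disease, bile acid metabolism, bile secretion and transport, other liver
#' disease, and lipid metabolism; users supply their own database snapshots
#' as files, and the package ships small illustrative lists
#' (see [default_gene_set_paths()]).
#'
#' @param paths Named character vector: category -> file path. Names must be
#'   among `r paste(PANEL_CATEGORIES, collapse = ", ")`.
#' @return A tibble with columns `category` and `gene`.
#' @export
load_gene_sets <- function(paths = default_gene_set_paths()) {
  if (is.null(names(paths)) || !all(names(paths) %in% PANEL_CATEGORIES)) {
    rlang::abort(paste0("load_gene_sets(): names(paths) must be panel categories (",
                        paste(PANEL_CATEGORIES, collapse = ", "), ")"))
  }
  purrr::imap_dfr(paths, function(path, category) {
    if (!file.exists(path)) {
      rlang::abort(paste0("load_gene_sets(): cannot read gene list '", path, "'"))
    }
    lines <- readLines(path, warn = FALSE)
    lines <- stringr::str_trim(stringr::str_remove(lines, "#.*$"))
    genes <- unique(toupper(lines[nzchar(lines)]))
    if (length(genes) == 0) {
      rlang::warn(paste0("gene list '", path, "' (", category, ") is empty"))
    }
    tibble::tibble(category = category, gene = genes)
  })
}

#' @rdname load_gene_sets
#' @export
default_gene_set_paths <- function() {
  dir <- system.file("extdata", "genesets", package = "triokin")
  paths <- file.path(dir, paste0(PANEL_CATEGORIES, ".txt"))
  names(paths) <- PANEL_CATEGORIES
  paths
}

#' Scan filtered variants against gene panels
#'
#' Reports every child-carried variant whose gene belongs to a panel, under
#' every category containing that gene (a gene in two panels yields two
#' rows). A variant is reported when it is nonsynonymous or splice-affecting
#' ([is_nonsynonymous()]), not homozygous alternate in any unaffected
#' parent, and either rare ([is_rare()]) or explicitly whitelisted as a
#' reportable common polymorphism (`common_whitelist`, keyed by
#' `GENE:proteinchange`-free variant key or by gene symbol) — the route by
#' which a well-known common risk polymorphism stays in the report despite
#' its frequency. Each row records which family members carry the variant,
#' in `"patient and father"` style.
#'
#' @param fam A [family_genotypes()] object.
#' @param gene_sets A tibble from [load_gene_sets()].
#' @param threshold,population Rarity settings, as in [cascade_counts()].
#' @param common_whitelist Character vector of variant keys
#'   (`"chrom:pos:ref:alt"`) and/or gene symbols exempted from the rarity
#'   filter.
#' @return A tibble of class `candidate_report`: columns `category`, `key`,
#'   `chrom`, `pos`, `ref`, `alt`, `gene`, `consequence`, `impact`, `sift`,
#'   `polyphen`, the `maf_*` columns, `rare`, `whitelisted`, `carriers`,
#'   plus the family's `gt_*` columns.
#' @export
scan_panels <- function(fam, gene_sets = load_gene_sets(),
                        threshold = 0.01, population = "GLOBAL",
                        common_whitelist = character(0)) {
  maf <- maf_column(fam, population)
  keys <- variant_key(fam)
  gene_up <- toupper(ifelse(is.na(fam$gene), "", fam$gene))
  rare <- is_rare(maf, threshold)
  whitelisted <- keys %in% common_whitelist | gene_up %in% toupper(common_whitelist)
  eligible <- gt_is_carrier(fam$gt_child) &
    is_nonsynonymous(fam$consequence, fam$impact) &
    !parental_homozygote_excluded(fam) &
    (rare | whitelisted)

  carriers_of <- function(i) {
    who <- c("patient", parent_roles(fam))
    cols <- c("gt_child", paste0("gt_", parent_roles(fam)))
    carrier <- purrr::map_lgl(cols, ~ gt_is_carrier(fam[[.x]][i]))
    paste(who[carrier], collapse = " and ")
  }

  rows <- purrr::map_dfr(which(eligible), function(i) {
    cats <- gene_sets$category[gene_sets$gene == gene_up[i]]
    if (length(cats) == 0) return(NULL)
    base <- tibble::as_tibble(fam)[i, , drop = FALSE]
    tidyr::expand_grid(category = cats, tibble::tibble(key = keys[i])) |>
      dplyr::bind_cols(base[rep(1, length(cats)), , drop = FALSE]) |>
      dplyr::mutate(rare = rare[i], whitelisted = whitelisted[i],
                    carriers = carriers_of(i))
  })
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(category = character(), key = character(),
                           chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           gene = character(), carriers = character())
  }
  class(rows) <- c("candidate_report", class(rows))
  rows
}
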