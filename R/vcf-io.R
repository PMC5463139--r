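#' Read one family's variants from VCF
#'
#' Reads one multi-sample VCF or several per-sample VCFs, splits
#' multi-allelic records into bi-allelic ones on ingest, parses VEP-style
#' `CSQ` annotations (or an annotation sidecar), and assembles a
#' [family_genotypes()] table over the union of sites. A sample lacking a
#' record at a site gets a missing genotype — *not* `hom_ref` — because
#' per-sample VCFs rarely emit reference calls and assuming `hom_ref` would
#' inflate recessive candidates; sites explicitly called `0/0` are `hom_ref`.
#'
#' @param paths Character vector of VCF paths (plain or gzip).
#' @param roles Named character vector mapping sample id -> role
#'   (`child`, `mother`, `father`). Every mapped id must exist in the VCFs.
#' @param config An [annotation_config()].
#' @param affected Optional named logical vector by sample id; defaults to
#'   `TRUE` for the child and `FALSE` for parents.
#' @param sexes Optional named character vector (`"M"`/`"F"`) by sample id.
#' @return A [family_genotypes()] tibble.
#' @export
read_family_vcf <- function(paths, roles, config = annotation_config(),
                            affected = NULL, sexes = NULL) {
  roles <- unlist(roles)
  if (anyDuplicated(roles)) {
    rlang::abort("read_family_vcf(): two samples mapped to the same role")
  }
  if (anyDuplicated(names(roles))) {
    rlang::abort("read_family_vcf(): two roles mapped to the same sample")
  }
  if (!all(roles %in% ROLES)) {
    rlang::abort(paste0("read_family_vcf(): roles must be among ",
                        paste(ROLES, collapse = ", ")))
  }
  tables <- purrr::map(paths, read_one_vcf, config = config)
  seen_samples <- unique(unlist(purrr::map(tables, ~ attr(.x, "vcf_samples"))))
  unknown <- setdiff(names(roles), seen_samples)
  if (length(unknown) > 0) {
    rlang::abort(paste0("read_family_vcf(): sample id(s) not found in VCF(s): ",
                        paste(unknown, collapse = ", ")))
  }

  ann_cols <- c("id", "gene", "consequence", "impact", "sift", "polyphen",
                paste0("maf_", tolower(names(config$populations))))
  merged <- purrr::reduce(tables, function(a, b) {
    both <- intersect(setdiff(names(a), c("chrom", "pos", "ref", "alt")), names(b))
    out <- dplyr::full_join(a, b, by = c("chrom", "pos", "ref", "alt"),
                            suffix = c("", ".y"))
    for (col in both) {
      ycol <- paste0(col, ".y")
      out[[col]] <- dplyr::coalesce(out[[col]], out[[ycol]])
      out[[ycol]] <- NULL
    }
    out
  })

  samples <- tibble::tibble(
    sample_id = names(roles),
    role = unname(roles),
    affected = if (is.null(affected)) unname(roles) == "child"
               else unname(affected[names(roles)]),
    sex = if (is.null(sexes)) NA_character_ else unname(sexes[names(roles)])
  )
  samples$affected[is.na(samples$affected)] <- samples$role[is.na(samples$affected)] == "child"

  for (i in seq_len(nrow(samples))) {
    src <- paste0("gt.", samples$sample_id[i])
    dst <- paste0("gt_", samples$role[i])
    merged[[dst]] <- if (src %in% names(merged)) merged[[src]] else NA_character_
  }
  merged <- merged[, c("chrom", "pos", "ref", "alt",
                       intersect(ann_cols, names(merged)),
                       paste0("gt_", samples$role)), drop = FALSE]
  family_genotypes(merged, samples)
}

# Read a single VCF into a tibble with gt.<sample_id> columns.
read_one_vcf <- function(path, config) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) {
      rlang::abort(paste0("failed to parse VCF '", path, "': ", conditionMessage(e)))
    }
  )
  vcf_samples <- colnames(vcf@gt)
  vcf_samples <- vcf_samples[vcf_samples != "FORMAT"]
  maf_cols <- paste0("maf_", tolower(names(config$populations)))

  n <- nrow(vcf@fix)
  if (is.null(n) || n == 0) {
    out <- tibble::tibble(chrom = character(), pos = integer(), ref = character(),
                          alt = character(), id = character(),
                          gene = character(), consequence = character(),
                          impact = character(), sift = character(),
                          polyphen = character())
    for (mc in maf_cols) out[[mc]] <- numeric()
    for (s in vcf_samples) out[[paste0("gt.", s)]] <- character()
    attr(out, "vcf_samples") <- vcf_samples
    return(out)
  }

  fix <- vcf@fix
  gt <- if (length(vcf_samples) > 0) vcfR::extract.gt(vcf, element = "GT") else NULL
  sidecar <- if (!is.null(config$sidecar)) read_annotation_sidecar(config) else NULL

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    gts <- if (is.null(gt)) character(0) else {
      g <- gt[i, , drop = TRUE]
      names(g) <- vcf_samples
      g
    }
    raw_csq <- extract_info_field(fix[i, "INFO"], config$csq_field)
    split_recs <- split_multiallelic(fix[i, "CHROM"], as.integer(fix[i, "POS"]),
                                     fix[i, "REF"], alts, gts)
    rows[[i]] <- purrr::map_dfr(split_recs, function(rec) {
      ann <- if (!is.null(sidecar)) {
        lookup_sidecar(sidecar, rec, config)
      } else {
        parse_annotation(raw_csq, config, allele = rec$alt)
      }
      row <- tibble::tibble(
        chrom = unname(rec$chrom), pos = unname(rec$pos),
        ref = unname(rec$ref), alt = unname(rec$alt),
        id = if (is.na(fix[i, "ID"]) || fix[i, "ID"] == ".") NA_character_
             else unname(fix[i, "ID"]),
        gene = ann$gene, consequence = ann$consequence, impact = ann$impact,
        sift = ann$sift, polyphen = ann$polyphen
      )
      for (p in names(config$populations)) {
        row[[paste0("maf_", tolower(p))]] <- ann$maf[[p]]
      }
      for (s in names(rec$gts)) row[[paste0("gt.", s)]] <- unname(rec$gts[[s]])
      row
    })
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "vcf_samples") <- vcf_samples
  out
}

extract_info_field <- function(info, key) {
  if (is.na(info)) return(NA_character_)
  m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]*)"))[, 2]
  m
}

read_annotation_sidecar <- function(config) {
  sc <- readr::read_tsv(config$sidecar, show_col_types = FALSE,
                        na = c("", ".", "NA"))
  needed <- c("chrom", "pos", "ref", "alt")
  if (!all(needed %in% names(sc))) {
    rlang::abort("annotation sidecar must have columns chrom, pos, ref, alt")
  }
  sc$chrom <- as.character(sc$chrom)
  sc
}

lookup_sidecar <- function(sidecar, rec, config) {
  hit <- sidecar[sidecar$chrom == rec$chrom & sidecar$pos == rec$pos &
                 sidecar$ref == rec$ref & sidecar$alt == rec$alt, , drop = FALSE]
  ann <- empty_annotation(config)
  if (nrow(hit) == 0) return(ann)
  hit <- hit[1, ]
  get_chr <- function(col, labels = NULL) {
    if (!col %in% names(hit) || is.na(hit[[col]])) return(NA_character_)
    v <- as.character(hit[[col]])
    if (!is.null(labels)) parse_predictor_label(v, labels) else v
  }
  ann$gene <- get_chr("gene")
  ann$consequence <- get_chr("consequence")
  imp <- get_chr("impact")
  ann$impact <- if (is.na(imp) || !imp %in% IMPACT_LABELS) "UNKNOWN" else imp
  ann$sift <- get_chr("sift", SIFT_LABELS)
  ann$polyphen <- get_chr("polyphen", POLYPHEN_LABELS)
  for (p in names(config$populations)) {
    col <- config$populations[[p]]
    ann$maf[[p]] <- if (col %in% names(hit) && !is.na(hit[[col]])) {
      as.numeric(hit[[col]])
    } else {
      NA_real_
    }
  }
  ann
}

#' Write a family to VCF
#'
#' Emits a plain-text VCF 4.2 whose `CSQ` INFO field follows `config`, so
#' [read_family_vcf()] with the same config round-trips the table exactly.
#' With `collapse_multiallelic = TRUE`, rows sharing `(chrom, pos, ref)` are
#' merged back into one multi-allelic record (allele indices recombined),
#' which exercises the reader's splitting path.
#'
#' @param fam A [family_genotypes()] object.
#' @param path Output path.
#' @param config An [annotation_config()].
#' @param collapse_multiallelic Merge rows at the same site into one record.
#' @return `path`, invisibly.
#' @export
write_family_vcf <- function(fam, path, config = annotation_config(),
                             collapse_multiallelic = FALSE) {
  samples <- family_samples(fam)
  tbl <- sort_karyotype(tibble::as_tibble(fam))

  csq_of_row <- function(row, allele) {
    vals <- purrr::map_chr(config$csq_fields, function(f) {
      v <- switch(f,
        Allele = allele,
        SYMBOL = row$gene,
        Consequence = row$consequence,
        IMPACT = if (identical(row$impact, "UNKNOWN")) NA_character_ else row$impact,
        SIFT = row$sift,
        PolyPhen = row$polyphen,
        {
          p <- names(config$populations)[match(f, config$populations)]
          if (!is.na(p)) {
            m <- row[[paste0("maf_", tolower(p))]]
            if (is.na(m)) NA_character_ else sprintf("%.12g", m)
          } else {
            NA_character_
          }
        }
      )
      if (is.null(v) || is.na(v)) "" else v
    })
    paste(vals, collapse = "|")
  }

  gt_cols <- paste0("gt_", samples$role)
  fmt_gt <- function(g) ifelse(is.na(g), "./.", g)

  if (collapse_multiallelic) {
    grp <- split(seq_len(nrow(tbl)),
                 factor(paste(tbl$chrom, tbl$pos, tbl$ref, sep = ":"),
                        levels = unique(paste(tbl$chrom, tbl$pos, tbl$ref, sep = ":"))))
    lines <- purrr::map_chr(grp, function(idx) {
      sub <- tbl[idx, , drop = FALSE]
      alts <- sub$alt
      csq <- paste(purrr::map_chr(seq_along(idx),
                                  ~ csq_of_row(sub[.x, ], alts[.x])), collapse = ",")
      gts <- purrr::map_chr(gt_cols, function(col) {
        combine_split_gts(purrr::set_names(sub[[col]], seq_along(alts)))
      })
      id <- stats::na.omit(sub$id)
      paste(c(sub$chrom[1], sub$pos[1],
              if (length(id) > 0) id[1] else ".",
              sub$ref[1], paste(alts, collapse = ","), ".", "PASS",
              paste0(config$csq_field, "=", csq), "GT", gts),
            collapse = "\t")
    })
  } else {
    lines <- purrr::map_chr(seq_len(nrow(tbl)), function(i) {
      row <- tbl[i, ]
      gts <- purrr::map_chr(gt_cols, ~ fmt_gt(row[[.x]]))
      paste(c(row$chrom, row$pos, ifelse(is.na(row$id), ".", row$id),
              row$ref, row$alt, ".", "PASS",
              paste0(config$csq_field, "=", csq_of_row(row, row$alt)), "GT", gts),
            collapse = "\t")
    })
  }

  header <- c(
    "##fileformat=VCFv4.2",
    paste0('##INFO=<ID=', config$csq_field,
           ',Number=.,Type=String,Description="Consequence annotations. Format: ',
           paste(config$csq_fields, collapse = "|"), '">'),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples$sample_id), collapse = "\t")
  )
  writeLines(c(header, lines), path)
  invisible(path)
}

# Rebuild a joint multi-allelic GT from the per-alt bi-allelic genotypes
# produced by splitting (inverse of split_multiallelic for consistent input).
combine_split_gts <- function(per_alt) {
  if (all(is.na(per_alt))) return("./.")
  first <- per_alt[!is.na(per_alt)][1]
  sep <- if (grepl("|", first, fixed = TRUE)) "|" else "/"
  ploidy <- length(strsplit(chartr("|", "/", first), "/", fixed = TRUE)[[1]])
  if (any(purrr::map_lgl(per_alt, ~ is.na(.x) || grepl(".", .x, fixed = TRUE)))) {
    return(paste(rep(".", ploidy), collapse = sep))
  }
  counts <- purrr::imap_int(per_alt, function(g, k) {
    sum(strsplit(chartr("|", "/", g), "/", fixed = TRUE)[[1]] == "1")
  })
  alleles <- rep(names(per_alt), counts)
  if (length(alleles) > ploidy) {
    rlang::abort("combine_split_gts(): alt alleles exceed ploidy; split records inconsistent")
  }
  alleles <- c(rep("0", ploidy - length(alleles)), sort(alleles))
  paste(alleles, collapse = sep)
}

#' Write a variant report table
#'
#' Writes a TSV with a deterministic column order (coordinates, annotation,
#' allele frequencies, per-sample genotypes, then any extra label columns),
#' sorted by chromosome in karyotype order (1-22, X, Y, MT) then position.
#' Missing values are printed as `"."`.
#'
#' @param tbl A data frame with at least `chrom`, `pos`, `ref`, `alt`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(tbl, path) {
  tbl <- sort_karyotype(tibble::as_tibble(tbl))
  lead <- c("chrom", "pos", "id", "ref", "alt", "gene", "consequence",
            "impact", "sift", "polyphen")
  maf_cols <- sort(grep("^maf_", names(tbl), value = TRUE))
  gt_cols <- grep("^gt_", names(tbl), value = TRUE)
  ordered <- c(intersect(lead, names(tbl)), maf_cols, gt_cols,
               setdiff(names(tbl), c(lead, maf_cols, gt_cols)))
  readr::write_tsv(tbl[, ordered, drop = FALSE], path, na = ".")
  invisible(path)
}
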