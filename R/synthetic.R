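# Approximate chromosome lengths (bp), autosomes 1-22 plus X. The generator
# never places sites on Y: the sharing statistic excludes it and exome
# content there is negligible.
CHROM_LENGTHS <- c(
  `1` = 249e6, `2` = 243e6, `3` = 198e6, `4` = 191e6, `5` = 181e6,
  `6` = 171e6, `7` = 159e6, `8` = 146e6, `9` = 141e6, `10` = 136e6,
  `11` = 135e6, `12` = 134e6, `13` = 115e6, `14` = 107e6, `15` = 103e6,
  `16` = 90e6, `17` = 81e6, `18` = 78e6, `19` = 59e6, `20` = 63e6,
  `21` = 48e6, `22` = 51e6, X = 155e6
)

#' Site-frequency-spectrum parameters
#'
#' Describes the synthetic exome's allele-frequency spectrum: a
#' two-component mixture with a heavy rare tail (`rare_fraction` of sites
#' drawn log-uniformly from `rare_maf_range`) and a bounded unimodal common
#' component (scaled Beta on `common_maf_range`). `EUR` frequencies are the
#' `GLOBAL` ones perturbed by bounded multiplicative noise
#' (log-uniform on `[1/(1+eur_noise), 1+eur_noise]`, clipped to (0,1)), so
#' population-selection code paths see genuinely discordant panels.
#'
#' The default rare band sits just below the 1% rarity cutoff
#' (`c(0.002, 0.0099)`, sampled uniformly) rather than extending into the
#' sub-0.1% tail of a real exome: a desk-scale site count must still leave
#' each simulated parent a workable number of carried rare variants (about
#' 50 at 5,000 sites) for sharing statistics to be informative, where a real
#' exome achieves that through millions of sites.
#'
#' @param n_sites Number of variant sites (>= 1).
#' @param rare_fraction Proportion of sites in the rare component
#'   (default 0.8, a rare-heavy exome-like spectrum).
#' @param rare_maf_range Frequency range of the rare component
#'   (default `c(0.002, 0.0099)`, uniform).
#' @param common_maf_range Range of the common component (default
#'   `c(0.01, 0.5)`).
#' @param common_shape Beta shape parameters of the common component
#'   (default `c(1.2, 3)`: unimodal, skewed toward lower frequencies).
#' @param chromosome_weights Named numeric vector over chromosomes 1-22, X
#'   allocating sites; default proportional to chromosome length.
#' @param eur_noise Bound of the EUR-vs-GLOBAL multiplicative discordance
#'   (default 0.2).
#' @param indel_fraction Fraction of sites emitted with multi-base alleles,
#'   to exercise SNP/indel bookkeeping (default 0.03).
#' @return An object of class `spectrum_params`.
#' @export
spectrum_params <- function(n_sites = 5000, rare_fraction = 0.8,
                            rare_maf_range = c(0.002, 0.0099),
                            common_maf_range = c(0.01, 0.5),
                            common_shape = c(1.2, 3),
                            chromosome_weights = NULL,
                            eur_noise = 0.2, indel_fraction = 0.03) {
  stopifnot(n_sites >= 1, rare_fraction >= 0, rare_fraction <= 1,
            all(rare_maf_range > 0), all(rare_maf_range < 1),
            all(common_maf_range > 0), all(common_maf_range < 1),
            indel_fraction >= 0, indel_fraction < 1)
  if (is.null(chromosome_weights)) {
    chromosome_weights <- CHROM_LENGTHS / sum(CHROM_LENGTHS)
  }
  if (is.null(names(chromosome_weights)) ||
      !all(names(chromosome_weights) %in% names(CHROM_LENGTHS))) {
    rlang::abort("spectrum_params(): chromosome_weights must be named over 1-22, X")
  }
  structure(list(n_sites = n_sites, rare_fraction = rare_fraction,
                 rare_maf_range = rare_maf_range,
                 common_maf_range = common_maf_range,
                 common_shape = common_shape,
                 chromosome_weights = chromosome_weights,
                 eur_noise = eur_noise, indel_fraction = indel_fraction),
            class = "spectrum_params")
}

#' Simulate a site table with population allele frequencies
#'
#' Draws `n_sites` bi-allelic sites across the chromosomes, strictly
#' increasing in position within each chromosome, with `GLOBAL` and `EUR`
#' minor allele frequencies per [spectrum_params()].
#'
#' @param params A [spectrum_params()] object.
#' @param seed Optional integer for reproducibility.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`,
#'   `maf_global`, `maf_eur`, sorted in karyotype order.
#' @export
simulate_spectrum <- function(params = spectrum_params(), seed = NULL) {
  run <- function() {
    w <- params$chromosome_weights / sum(params$chromosome_weights)
    counts <- as.vector(stats::rmultinom(1, params$n_sites, w))
    names(counts) <- names(w)
    sites <- purrr::imap_dfr(counts[counts > 0], function(k, chrom) {
      tibble::tibble(
        chrom = chrom,
        pos = sort(sample.int(CHROM_LENGTHS[[chrom]] - 10L, k))
      )
    })
    n <- nrow(sites)
    bases <- c("A", "C", "G", "T")
    sites$ref <- sample(bases, n, replace = TRUE)
    sites$alt <- purrr::map_chr(sites$ref, ~ sample(setdiff(bases, .x), 1))
    if (params$indel_fraction > 0) {
      ind <- which(stats::runif(n) < params$indel_fraction)
      ins <- ind[seq_along(ind) %% 2 == 0]
      del <- setdiff(ind, ins)
      sites$alt[ins] <- paste0(sites$alt[ins], "A")
      sites$ref[del] <- paste0(sites$ref[del], "C")
      sites$alt[del] <- substr(sites$ref[del], 1, 1)
    }
    is_rare_site <- stats::runif(n) < params$rare_fraction
    lo <- params$rare_maf_range[1]; hi <- params$rare_maf_range[2]
    maf <- numeric(n)
    maf[is_rare_site] <- stats::runif(sum(is_rare_site), lo, hi)
    clo <- params$common_maf_range[1]; chi <- params$common_maf_range[2]
    maf[!is_rare_site] <- clo + (chi - clo) *
      stats::rbeta(sum(!is_rare_site), params$common_shape[1], params$common_shape[2])
    noise <- exp(stats::runif(n, -log(1 + params$eur_noise), log(1 + params$eur_noise)))
    sites$maf_global <- maf
    sites$maf_eur <- pmin(pmax(maf * noise, 1e-6), 1 - 1e-6)
    sort_karyotype(sites)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Pedigree specification
#'
#' An explicit founder/offspring graph, with sexes, from which related or
#' unrelated parent pairs (and their child) are generated by gene dropping.
#' Founders have no parents; every non-founder has exactly two parents of
#' opposite sex already present in the table. The kinship coefficient of the
#' emitted parent pair is computed from the graph and checked against
#' `kinship_label` when one is declared.
#'
#' @param members A data frame with columns `id`, `father`, `mother`
#'   (`NA` for founders) and `sex` (`"M"`/`"F"`).
#' @param father,mother,child Ids of the emitted samples (`child` optional).
#' @param kinship_label Optional declared kinship coefficient of
#'   (`father`, `mother`); validated against the graph.
#' @return An object of class `pedigree_spec`.
#' @export
pedigree_spec <- function(members, father, mother, child = NULL,
                          kinship_label = NULL) {
  members <- tibble::as_tibble(members)
  stopifnot(all(c("id", "father", "mother", "sex") %in% names(members)))
  if (anyDuplicated(members$id)) rlang::abort("pedigree_spec(): duplicate ids")
  non_founder <- !is.na(members$father) | !is.na(members$mother)
  if (any(non_founder & (is.na(members$father) | is.na(members$mother)))) {
    rlang::abort("pedigree_spec(): every non-founder needs both parents")
  }
  refs <- c(stats::na.omit(members$father), stats::na.omit(members$mother))
  if (!all(refs %in% members$id)) {
    rlang::abort("pedigree_spec(): parent id not present in members")
  }
  fa_sex <- members$sex[match(stats::na.omit(members$father), members$id)]
  mo_sex <- members$sex[match(stats::na.omit(members$mother), members$id)]
  if (any(fa_sex != "M") || any(mo_sex != "F")) {
    rlang::abort("pedigree_spec(): fathers must be male and mothers female")
  }
  depth <- pedigree_depth(members)   # also detects cycles
  for (s in c(father, mother, child)) {
    if (!s %in% members$id) rlang::abort(paste0("pedigree_spec(): unknown id '", s, "'"))
  }
  if (members$sex[members$id == father] != "M" ||
      members$sex[members$id == mother] != "F") {
    rlang::abort("pedigree_spec(): emitted father must be male, mother female")
  }
  phi <- kinship_coefficient(members, father, mother)
  if (!is.null(kinship_label) && abs(phi - kinship_label) > 1e-9) {
    rlang::abort(sprintf(
      "pedigree_spec(): declared kinship %.5f differs from graph kinship %.5f",
      kinship_label, phi))
  }
  structure(list(members = members, father = father, mother = mother,
                 child = child, kinship = phi, depth = depth),
            class = "pedigree_spec")
}

# Generation depth of each member (founders 0); aborts on cycles.
pedigree_depth <- function(members) {
  depth <- stats::setNames(rep(NA_real_, nrow(members)), members$id)
  depth[is.na(members$father) & is.na(members$mother)] <- 0
  for (iter in seq_len(nrow(members) + 1)) {
    todo <- which(is.na(depth))
    if (length(todo) == 0) return(depth)
    progressed <- FALSE
    for (i in todo) {
      df <- depth[members$father[i]]; dm <- depth[members$mother[i]]
      if (!is.na(df) && !is.na(dm)) {
        depth[members$id[i]] <- max(df, dm) + 1
        progressed <- TRUE
      }
    }
    if (!progressed) rlang::abort("pedigree contains a cycle or unresolved parent")
  }
  depth
}

#' Kinship coefficient from a pedigree
#'
#' The probability that one allele drawn at random from each of two pedigree
#' members is identical by descent, computed by the classical recursion
#' (founders unrelated and non-inbred): siblings 1/4, first cousins 1/16,
#' second cousins 1/64.
#'
#' @param members A pedigree member table (see [pedigree_spec()]).
#' @param a,b Member ids.
#' @return The kinship coefficient.
#' @export
kinship_coefficient <- function(members, a, b) {
  depth <- pedigree_depth(members)
  fa <- stats::setNames(members$father, members$id)
  mo <- stats::setNames(members$mother, members$id)
  memo <- new.env(parent = emptyenv())
  phi <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- paste(sort(c(i, j)), collapse = "\r")
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      0.5 * (1 + phi(fa[[i]], mo[[i]]))
    } else {
      # recurse on the later-generation member; equal depths mean neither
      # is an ancestor of the other, so either choice is valid
      if (depth[[i]] < depth[[j]]) { tmp <- i; i <- j; j <- tmp }
      if (depth[[i]] == 0) 0 else 0.5 * (phi(fa[[i]], j) + phi(mo[[i]], j))
    }
    memo[[key]] <- val
    val
  }
  phi(a, b)
}

#' Ready-made trio pedigrees at standard kinship levels
#'
#' Builds the trio pedigrees used throughout the package's simulations:
#' parents unrelated (`kinship = 0`), second cousins (1/64, i.e. parents
#' sharing a great-grandparent couple), first cousins (1/16), or full
#' siblings (1/4). The emitted samples are the parent pair `F1`, `M1` and
#' their child `C1`.
#'
#' @param kinship One of `0`, `1/64`, `1/16`, `1/4`.
#' @param child_sex `"F"` (default) or `"M"` (to exercise hemizygous X).
#' @return A [pedigree_spec()].
#' @export
pedigree_trio <- function(kinship = 0, child_sex = "F") {
  founder <- function(id, sex) tibble::tibble(id = id, father = NA_character_,
                                              mother = NA_character_, sex = sex)
  offspring <- function(id, fa, mo, sex) tibble::tibble(id = id, father = fa,
                                                        mother = mo, sex = sex)
  members <- if (isTRUE(all.equal(kinship, 0))) {
    dplyr::bind_rows(founder("F1", "M"), founder("M1", "F"))
  } else if (isTRUE(all.equal(kinship, 1 / 4))) {
    dplyr::bind_rows(founder("GF", "M"), founder("GM", "F"),
                     offspring("F1", "GF", "GM", "M"),
                     offspring("M1", "GF", "GM", "F"))
  } else if (isTRUE(all.equal(kinship, 1 / 16))) {
    dplyr::bind_rows(founder("GGF", "M"), founder("GGM", "F"),
                     founder("W1", "F"), founder("H2", "M"),
                     offspring("S1", "GGF", "GGM", "M"),
                     offspring("S2", "GGF", "GGM", "F"),
                     offspring("F1", "S1", "W1", "M"),
                     offspring("M1", "H2", "S2", "F"))
  } else if (isTRUE(all.equal(kinship, 1 / 64))) {
    dplyr::bind_rows(founder("G3F", "M"), founder("G3M", "F"),
                     founder("WA", "F"), founder("HB", "M"),
                     founder("WAA", "F"), founder("HBB", "M"),
                     offspring("A", "G3F", "G3M", "M"),
                     offspring("B", "G3F", "G3M", "F"),
                     offspring("AA", "A", "WA", "M"),
                     offspring("BB", "HB", "B", "F"),
                     offspring("F1", "AA", "WAA", "M"),
                     offspring("M1", "HBB", "BB", "F"))
  } else {
    rlang::abort("pedigree_trio(): kinship must be one of 0, 1/64, 1/16, 1/4")
  }
  members <- dplyr::bind_rows(members, offspring("C1", "F1", "M1", child_sex))
  pedigree_spec(members, father = "F1", mother = "M1", child = "C1",
                kinship_label = kinship)
}

#' Gene-drop genotypes through a pedigree
#'
#' Simulates genotypes at independent sites: founder haplotype alleles are
#' Bernoulli(MAF) under Hardy-Weinberg equilibrium, and each transmission
#' passes one uniformly chosen allele from each parent. X-chromosome
#' transmission respects sex: fathers pass their single X to daughters only,
#' sons are hemizygous for a maternal allele. Founder frequencies are taken
#' from `maf_col` — by default the EUR panel, the population against which
#' sharing expectations are evaluated.
#'
#' @param pedigree A [pedigree_spec()].
#' @param sites A site tibble (from [simulate_spectrum()] or hand-built)
#'   with `chrom` and the `maf_col` column.
#' @param maf_col Column of `sites` holding founder allele frequencies.
#' @param seed Optional integer.
#' @return A named list: for each emitted sample id, a character vector of
#'   genotype strings aligned with `sites` rows.
#' @export
gene_drop <- function(pedigree, sites, maf_col = "maf_eur", seed = NULL) {
  stopifnot(inherits(pedigree, "pedigree_spec"))
  run <- function() {
    members <- pedigree$members
    n <- nrow(sites)
    p <- sites[[maf_col]]
    is_x <- sites$chrom == "X"
    sex <- stats::setNames(members$sex, members$id)
    haps <- new.env(parent = emptyenv())
    ord <- members$id[order(pedigree$depth[members$id])]
    for (id in ord) {
      i <- match(id, members$id)
      if (is.na(members$father[i])) {
        mat <- stats::rbinom(n, 1, p)
        pat <- stats::rbinom(n, 1, p)
        if (sex[[id]] == "M") pat[is_x] <- NA_integer_
      } else {
        fh <- haps[[members$father[i]]]
        mh <- haps[[members$mother[i]]]
        pick_f <- stats::runif(n) < 0.5
        pat <- ifelse(pick_f, fh$mat, fh$pat)
        pick_m <- stats::runif(n) < 0.5
        mat <- ifelse(pick_m, mh$mat, mh$pat)
        if (sex[[id]] == "M") {
          pat[is_x] <- NA_integer_          # sons: no paternal X
        } else {
          pat[is_x] <- fh$mat[is_x]         # daughters: father's single X
        }
      }
      haps[[id]] <- list(mat = mat, pat = pat)
    }
    emitted <- stats::na.omit(c(pedigree$father, pedigree$mother, pedigree$child))
    out <- purrr::map(stats::setNames(emitted, emitted), function(id) {
      h <- haps[[id]]
      gt <- paste(pmin(h$mat, h$pat), pmax(h$mat, h$pat), sep = "/")
      if (sex[[id]] == "M" && any(is_x)) gt[is_x] <- as.character(h$mat[is_x])
      gt
    })
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Default synthetic gene model
#'
#' Tiles every chromosome with 1 Mb gene intervals named `G<chrom>_<i>`,
#' then renames the tiles containing well-known cholestasis / liver /
#' drug-metabolism loci to their gene symbols (approximate canonical
#' positions), so panel scans have realistic targets.
#'
#' @return A tibble with columns `gene`, `chrom`, `start`, `end`.
#' @export
default_gene_model <- function() {
  tiles <- purrr::imap_dfr(CHROM_LENGTHS, function(len, chrom) {
    starts <- seq(1, len, by = 1e6)
    tibble::tibble(gene = sprintf("G%s_%04d", chrom, seq_along(starts)),
                   chrom = chrom, start = starts,
                   end = pmin(starts + 1e6 - 1, len))
  })
  known <- tibble::tribble(
    ~gene,      ~chrom, ~pos,
    "ABCB11",   "2",    169.8e6,
    "ABCB4",    "7",    87.0e6,
    "AKR1D1",   "7",    137.8e6,
    "NAT2",     "8",    18.2e6,
    "CYP7A1",   "8",    59.4e6,
    "CYP7B1",   "8",    65.5e6,
    "TJP2",     "9",    71.7e6,
    "BAAT",     "9",    104.1e6,
    "RXRA",     "9",    137.2e6,
    "AKR1C1",   "10",   5.0e6,
    "CYP2C19",  "10",   94.5e6,
    "CYP2C9",   "10",   96.7e6,
    "KRT8",     "12",   53.3e6,
    "ABCC4",    "13",   95.7e6,
    "HSD3B7",   "16",   30.9e6,
    "PEMT",     "17",   17.4e6,
    "ATP8B1",   "18",   55.3e6,
    "FAM104B",  "X",    55.2e6
  )
  for (i in seq_len(nrow(known))) {
    hit <- tiles$chrom == known$chrom[i] &
      tiles$start <= known$pos[i] & tiles$end >= known$pos[i]
    tiles$gene[hit] <- known$gene[i]
  }
  tiles
}

#' Default annotation label mixture
#'
#' The categorical distribution from which genic sites draw their
#' (consequence, impact, SIFT, PolyPhen) labels: an exome-like mixture of
#' missense (with a deleterious minority), synonymous, nonsense, splice and
#' non-coding calls.
#'
#' @return A tibble with columns `consequence`, `impact`, `sift`,
#'   `polyphen`, `prob` (probabilities summing to 1).
#' @export
default_label_distribution <- function() {
  tibble::tribble(
    ~consequence,              ~impact,    ~sift,                        ~polyphen,           ~prob,
    "missense_variant",        "MODERATE", "tolerated",                  "benign",            0.250,
    "missense_variant",        "MODERATE", "deleterious",                "probably_damaging", 0.050,
    "missense_variant",        "MODERATE", "deleterious_low_confidence", "possibly_damaging", 0.030,
    "missense_variant",        "MODERATE", "tolerated_low_confidence",   "benign",            0.070,
    "synonymous_variant",      "LOW",      NA,                           NA,                  0.250,
    "stop_gained",             "HIGH",     NA,                           NA,                  0.010,
    "splice_region_variant",   "LOW",      NA,                           NA,                  0.040,
    "splice_acceptor_variant", "HIGH",     NA,                           NA,                  0.005,
    "intron_variant",          "MODIFIER", NA,                           NA,                  0.200,
    "3_prime_UTR_variant",     "MODIFIER", NA,                           NA,                  0.095
  )
}

#' Annotate simulated sites with genes and functional labels
#'
#' Assigns each site the gene whose interval contains it (intervals must not
#' overlap within a chromosome) and draws consequence/impact/SIFT/PolyPhen
#' labels from `labels`; sites outside every interval get an empty gene and
#' an `intergenic_variant` / `MODIFIER` annotation.
#'
#' @param sites A site tibble (see [simulate_spectrum()]).
#' @param gene_model A tibble `gene`, `chrom`, `start`, `end`
#'   (default [default_gene_model()]).
#' @param labels A label-distribution tibble
#'   (default [default_label_distribution()]).
#' @param seed Optional integer.
#' @return `sites` with columns `gene`, `consequence`, `impact`, `sift`,
#'   `polyphen` added.
#' @export
annotate_sites <- function(sites, gene_model = default_gene_model(),
                           labels = default_label_distribution(), seed = NULL) {
  stopifnot(abs(sum(labels$prob) - 1) < 1e-6)
  run <- function() {
    genes <- rep(NA_character_, nrow(sites))
    for (chrom in unique(sites$chrom)) {
      gm <- gene_model[gene_model$chrom == chrom, , drop = FALSE]
      if (nrow(gm) == 0) next
      gm <- gm[order(gm$start), , drop = FALSE]
      if (any(gm$start[-1] <= gm$end[-nrow(gm)])) {
        rlang::abort(paste0("annotate_sites(): overlapping gene intervals on chromosome ",
                            chrom))
      }
      rows <- which(sites$chrom == chrom)
      idx <- findInterval(sites$pos[rows], gm$start)
      ok <- idx >= 1 & idx <= nrow(gm)
      ok[ok] <- sites$pos[rows][ok] <= gm$end[idx[ok]]
      genes[rows[ok]] <- gm$gene[idx[ok]]
    }
    draw <- sample.int(nrow(labels), nrow(sites), replace = TRUE, prob = labels$prob)
    out <- sites
    out$gene <- genes
    out$consequence <- ifelse(is.na(genes), "intergenic_variant", labels$consequence[draw])
    out$impact <- ifelse(is.na(genes), "MODIFIER", labels$impact[draw])
    out$sift <- ifelse(is.na(genes), NA_character_, labels$sift[draw])
    out$polyphen <- ifelse(is.na(genes), NA_character_, labels$polyphen[draw])
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
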