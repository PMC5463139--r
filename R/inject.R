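#' Ground-truth injection specification
#'
#' Counts of variants to inject into a synthetic family so that downstream
#' filters have exactly known answers. The recessive counts form a nested
#' ladder mirroring the filter cascade: of `recessive_total` recessive
#' homozygous variants, `recessive_rare` are rare, of which
#' `recessive_nonsyn` are nonsynonymous, of which `recessive_deleterious`
#' are deleterious in silico.
#'
#' @param recessive_total,recessive_rare,recessive_nonsyn,recessive_deleterious
#'   The recessive-homozygous ladder (each <= the previous).
#' @param compound_het_pairs Number of in-trans pairs to inject (each pair:
#'   two rare deleterious missense variants in one gene, one per parent).
#' @param de_novo Number of de novo heterozygous variants.
#' @param panel_hits Named integer vector: panel category -> number of rare
#'   missense heterozygous hits to inject in that category's genes.
#' @return An object of class `injection_spec`.
#' @export
injection_spec <- function(recessive_total = 0, recessive_rare = 0,
                           recessive_nonsyn = 0, recessive_deleterious = 0,
                           compound_het_pairs = 0, de_novo = 0,
                           panel_hits = integer(0)) {
  if (!(recessive_total >= recessive_rare &&
        recessive_rare >= recessive_nonsyn &&
        recessive_nonsyn >= recessive_deleterious &&
        recessive_deleterious >= 0)) {
    rlang::abort("injection_spec(): recessive counts must be a non-increasing ladder")
  }
  if (length(panel_hits) > 0 &&
      (is.null(names(panel_hits)) || !all(names(panel_hits) %in% PANEL_CATEGORIES))) {
    rlang::abort("injection_spec(): panel_hits must be named by panel category")
  }
  structure(list(recessive_total = recessive_total,
                 recessive_rare = recessive_rare,
                 recessive_nonsyn = recessive_nonsyn,
                 recessive_deleterious = recessive_deleterious,
                 compound_het_pairs = compound_het_pairs,
                 de_novo = de_novo, panel_hits = panel_hits),
            class = "injection_spec")
}

RARE_INJECT_MAF <- c(1e-4, 9e-3)     # safely below the 0.01 default cutoff
COMMON_INJECT_MAF <- c(0.05, 0.40)

#' Inject ground-truth variants into a family
#'
#' Overwrites genotypes and annotations at randomly chosen autosomal sites
#' to realise each class of [injection_spec()] exactly, and returns a truth
#' manifest for assertions. After injection, background sites that happen to
#' satisfy a monitored pattern are demoted so the recovered sets equal the
#' manifest *exactly*: coincidental recessive-homozygous genotypes are
#' softened to heterozygous (Mendelian-consistent, since both parents are
#' carriers there), and coincidental compound-het or panel matches are
#' detached by renaming the background variant's gene to a private symbol.
#' This exclusivity is a fixture property for exact end-to-end oracles, not
#' a biological claim.
#'
#' @param fam A [family_genotypes()] object (trio or duo).
#' @param spec An [injection_spec()].
#' @param gene_sets Panel table used for panel hits and sanitisation
#'   (default [load_gene_sets()]).
#' @param threshold,population Rarity settings the fixture should be exact
#'   under (defaults 0.01, `GLOBAL`).
#' @param seed Optional integer.
#' @return A list with `family` (modified [family_genotypes()]) and
#'   `manifest` (tibble: `key`, `class`, `gene`, `rare`, `nonsynonymous`,
#'   `deleterious`, `pair_id`, `category`).
#' @export
inject_ground_truth <- function(fam, spec, gene_sets = load_gene_sets(),
                                threshold = 0.01, population = "GLOBAL",
                                seed = NULL) {
  stopifnot(inherits(spec, "injection_spec"))
  run <- function() {
    tbl <- tibble::as_tibble(fam)
    samples <- family_samples(fam)
    parents <- intersect(c("mother", "father"), samples$role)
    trio <- length(parents) == 2
    maf_cols <- grep("^maf_", names(tbl), value = TRUE)

    n_needed <- spec$recessive_total + 2 * spec$compound_het_pairs +
      spec$de_novo + sum(spec$panel_hits)
    if (n_needed == 0) {
      return(list(family = fam, manifest = tibble::tibble(
        key = character(), class = character(), gene = character(),
        rare = logical(), nonsynonymous = logical(), deleterious = logical(),
        pair_id = integer(), category = character())))
    }
    autosomal <- which(tbl$chrom %in% as.character(1:22))
    if (length(autosomal) < n_needed) {
      rlang::abort(sprintf(
        "inject_ground_truth(): %d autosomal sites available but %d required",
        length(autosomal), n_needed))
    }
    chosen <- sample(autosomal, n_needed)
    pool <- split(chosen, rep.int(
      c("recessive", "compound", "de_novo", "panel"),
      c(spec$recessive_total, 2 * spec$compound_het_pairs,
        spec$de_novo, sum(spec$panel_hits))))

    set_maf <- function(i, rare) {
      rng <- if (rare) RARE_INJECT_MAF else COMMON_INJECT_MAF
      for (mc in maf_cols) tbl[[mc]][i] <<- stats::runif(1, rng[1], rng[2])
    }
    set_labels <- function(i, nonsyn, delet) {
      tbl$consequence[i] <<- if (nonsyn) "missense_variant" else "synonymous_variant"
      tbl$impact[i] <<- if (nonsyn) "MODERATE" else "LOW"
      tbl$sift[i] <<- if (delet) "deleterious" else "tolerated"
      tbl$polyphen[i] <<- if (delet) "probably_damaging" else "benign"
    }
    set_gts <- function(i, child, mother = NULL, father = NULL) {
      tbl$gt_child[i] <<- child
      if ("mother" %in% parents && !is.null(mother)) tbl$gt_mother[i] <<- mother
      if ("father" %in% parents && !is.null(father)) tbl$gt_father[i] <<- father
    }

    manifest <- list()
    add_manifest <- function(i, class, rare = NA, nonsyn = NA, delet = NA,
                             pair_id = NA_integer_, category = NA_character_) {
      manifest[[length(manifest) + 1]] <<- tibble::tibble(
        key = variant_key(tbl[i, ]), class = class, gene = tbl$gene[i],
        rare = rare, nonsynonymous = nonsyn, deleterious = delet,
        pair_id = pair_id, category = category)
    }

    for (k in seq_len(spec$recessive_total)) {
      i <- pool$recessive[k]
      rare <- k <= spec$recessive_rare
      nonsyn <- k <= spec$recessive_nonsyn
      delet <- k <= spec$recessive_deleterious
      tbl$gene[i] <- sprintf("TRUTHR%02d", k)
      set_maf(i, rare)
      set_labels(i, nonsyn, delet)
      set_gts(i, "1/1", "0/1", "0/1")
      add_manifest(i, "recessive_homozygous", rare, nonsyn, delet)
    }

    for (j in seq_len(spec$compound_het_pairs)) {
      if (!trio) rlang::abort("inject_ground_truth(): compound-het injection needs a trio")
      i1 <- pool$compound[2 * j - 1]; i2 <- pool$compound[2 * j]
      g <- sprintf("TRUTHCH%02d", j)
      for (i in c(i1, i2)) {
        tbl$gene[i] <- g
        set_maf(i, TRUE)
        set_labels(i, TRUE, TRUE)
      }
      set_gts(i1, "0/1", mother = "0/1", father = "0/0")
      set_gts(i2, "0/1", mother = "0/0", father = "0/1")
      add_manifest(i1, "compound_het_member", TRUE, TRUE, TRUE, pair_id = j)
      add_manifest(i2, "compound_het_member", TRUE, TRUE, TRUE, pair_id = j)
    }

    for (k in seq_len(spec$de_novo)) {
      i <- pool$de_novo[k]
      tbl$gene[i] <- sprintf("TRUTHDN%02d", k)
      set_maf(i, TRUE)
      set_labels(i, TRUE, TRUE)
      set_gts(i, "0/1", "0/0", "0/0")
      add_manifest(i, "de_novo", TRUE, TRUE, TRUE)
    }

    if (sum(spec$panel_hits) > 0) {
      slot <- 0
      for (cat in names(spec$panel_hits)) {
        genes <- gene_sets$gene[gene_sets$category == cat]
        if (spec$panel_hits[[cat]] > length(genes)) {
          rlang::abort(paste0("inject_ground_truth(): category ", cat,
                              " has fewer genes than requested hits"))
        }
        for (k in seq_len(spec$panel_hits[[cat]])) {
          slot <- slot + 1
          i <- pool$panel[slot]
          tbl$gene[i] <- genes[k]
          set_maf(i, TRUE)
          set_labels(i, TRUE, FALSE)
          carrier_parent <- parents[1 + (slot %% length(parents))]
          set_gts(i, "0/1",
                  mother = if ("mother" %in% parents) {
                    if (carrier_parent == "mother") "0/1" else "0/0"
                  },
                  father = if ("father" %in% parents) {
                    if (carrier_parent == "father") "0/1" else "0/0"
                  })
          add_manifest(i, "panel_hit", TRUE, TRUE, FALSE, category = cat)
        }
      }
    }

    manifest <- if (length(manifest) > 0) dplyr::bind_rows(manifest) else
      tibble::tibble(key = character(), class = character(), gene = character(),
                     rare = logical(), nonsynonymous = logical(),
                     deleterious = logical(), pair_id = integer(),
                     category = character())

    fam2 <- new_family_genotypes(tbl, samples)
    fam2 <- sanitize_background(fam2, manifest, gene_sets, threshold, population)
    list(family = fam2, manifest = manifest)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Demote background sites that coincidentally match a monitored pattern so
# recovered sets equal the manifest exactly. Gene renames are always safe;
# genotype softening is only applied where it stays Mendelian-consistent.
sanitize_background <- function(fam, manifest, gene_sets, threshold, population) {
  tbl <- tibble::as_tibble(fam)
  samples <- family_samples(fam)
  keys <- variant_key(tbl)
  truth_keys <- manifest$key

  rec_keys <- classify_recessive(fam)
  stray <- setdiff(rec_keys, truth_keys[manifest$class == "recessive_homozygous"])
  if (length(stray) > 0) {
    rows <- match(stray, keys)
    hemi <- gt_ploidy(tbl$gt_child[rows]) == 1
    tbl$gt_child[rows] <- ifelse(hemi, "0", "0/1")
  }
  fam <- new_family_genotypes(tbl, samples)

  if (all(c("mother", "father") %in% samples$role)) {
    ch <- find_compound_het(fam)
    truth_pairs <- manifest$key[manifest$class == "compound_het_member"]
    bad <- unique(c(ch$key_maternal[!(ch$key_maternal %in% truth_pairs &
                                        ch$key_paternal %in% truth_pairs)],
                    ch$key_paternal[!(ch$key_maternal %in% truth_pairs &
                                        ch$key_paternal %in% truth_pairs)]))
    bad <- setdiff(bad, truth_keys)
    if (length(bad) > 0) {
      rows <- match(bad, keys)
      tbl$gene[rows] <- sprintf("BG%06d", rows)
      fam <- new_family_genotypes(tbl, samples)
    }
  }

  report <- scan_panels(fam, gene_sets, threshold, population)
  stray <- setdiff(unique(report$key), truth_keys[manifest$class == "panel_hit"])
  if (length(stray) > 0) {
    rows <- match(stray, keys)
    tbl$gene[rows] <- sprintf("BG%06d", rows)
    fam <- new_family_genotypes(tbl, samples)
  }
  fam
}

#' Simulate an annotated synthetic family
#'
#' The one-call generator: draws a site-frequency spectrum (or reuses a
#' supplied site table, e.g. to put several families on one population
#' panel), annotates sites with genes and functional labels, gene-drops
#' genotypes through the pedigree, and optionally injects ground-truth
#' variants.
#'
#' @param pedigree A [pedigree_spec()] (e.g. [pedigree_trio()]).
#' @param spectrum A [spectrum_params()]; ignored when `sites` is given.
#' @param sites Optional pre-built site table (annotated or not).
#' @param gene_model,labels Passed to [annotate_sites()]; annotation is
#'   skipped when `sites` already carries a `gene` column.
#' @param inject Optional [injection_spec()].
#' @param gene_sets Panel table for injection (default package lists).
#' @param affected Named logical by role (default: child `TRUE`).
#' @param seed Optional integer driving the whole simulation.
#' @return A list of class `synthetic_family`: `family`
#'   (a [family_genotypes()]), `manifest` (truth tibble, empty when nothing
#'   injected), `pedigree`, and `sites`.
#' @export
simulate_family <- function(pedigree = pedigree_trio(0),
                            spectrum = spectrum_params(),
                            sites = NULL, gene_model = default_gene_model(),
                            labels = default_label_distribution(),
                            inject = NULL, gene_sets = NULL,
                            affected = NULL, seed = NULL) {
  run <- function() {
    if (is.null(sites)) sites <- simulate_spectrum(spectrum)
    if (!"gene" %in% names(sites)) {
      sites <- annotate_sites(sites, gene_model, labels)
    }
    grid <- gene_drop(pedigree, sites)
    roles <- c(father = pedigree$father, mother = pedigree$mother,
               child = pedigree$child)
    roles <- roles[!is.na(roles)]
    tbl <- sites
    tbl$id <- NA_character_
    for (r in names(roles)) tbl[[paste0("gt_", r)]] <- grid[[roles[[r]]]]
    members <- pedigree$members
    samples <- tibble::tibble(
      sample_id = unname(roles), role = names(roles),
      affected = if (is.null(affected)) names(roles) == "child"
                 else unname(affected[names(roles)]),
      sex = members$sex[match(roles, members$id)]
    )
    if (!"child" %in% samples$role) {
      # pair-only pedigree: emit an ungenotyped placeholder child so the
      # container invariant (exactly one child) holds
      tbl$gt_child <- NA_character_
      samples <- dplyr::bind_rows(samples, tibble::tibble(
        sample_id = "placeholder_child", role = "child",
        affected = FALSE, sex = NA_character_))
    }
    fam <- family_genotypes(tbl, samples)
    if (is.null(inject)) {
      manifest <- tibble::tibble(key = character(), class = character())
    } else {
      gs <- if (is.null(gene_sets)) load_gene_sets() else gene_sets
      res <- inject_ground_truth(fam, inject, gene_sets = gs)
      fam <- res$family
      manifest <- res$manifest
    }
    structure(list(family = fam, manifest = manifest,
                   pedigree = pedigree, sites = sites),
              class = "synthetic_family")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat("# synthetic_family: kinship(parents) =", format(x$pedigree$kinship),
      "\n")
  print(x$family)
  if (nrow(x$manifest) > 0) {
    cat("# truth manifest:", nrow(x$manifest), "injected variants\n")
  }
  invisible(x)
}
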