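#' Hardy-Weinberg carrier probability
#'
#' The probability that an unrelated individual drawn from a population in
#' Hardy-Weinberg equilibrium carries at least one copy of an allele of
#' frequency `maf`: `1 - (1 - maf)^2`, approximately `2 * maf` for rare
#' alleles. This is the per-variant expectation against which observed
#' parental sharing is compared.
#'
#' @param maf Numeric vector of allele frequencies, each strictly in (0, 1).
#' @return Numeric vector of carrier probabilities.
#' @examples
#' expected_sharing_probability(c(0.01, 0.5))
#' @export
expected_sharing_probability <- function(maf) {
  if (any(is.na(maf)) || any(maf <= 0) || any(maf >= 1)) {
    rlang::abort("expected_sharing_probability(): maf must lie strictly in (0, 1)")
  }
  1 - (1 - maf)^2
}

#' Father-carried rare variants eligible for sharing resampling
#'
#' Selects the variants the resampling statistic draws from: carried by the
#' father, on chromosomes 1-22 or X (never Y), with a known population MAF
#' strictly between 0 and `threshold`. Variants with missing or zero MAF are
#' excluded because their Hardy-Weinberg expectation is zero, which would
#' degenerate the ratio.
#'
#' @param fam A [family_genotypes()] object with both parents.
#' @param threshold MAF cutoff (one of 0.01, 0.02, 0.05, 0.1 in the standard
#'   screen, or any value in (0, 1]).
#' @param population Population whose MAF is used (default `EUR`).
#' @return A tibble with columns `chrom`, `key`, `maf`, `mother_carrier`.
#' @export
eligible_father_variants <- function(fam, threshold = 0.01, population = "EUR") {
  if (!all(c("mother", "father") %in% roles_present(fam))) {
    rlang::abort(paste("eligible_father_variants(): the sharing statistic is",
                       "defined on a parent pair; both mother and father are required"))
  }
  maf <- maf_column(fam, population)
  keep <- gt_is_carrier(fam$gt_father) & fam$chrom != "Y" &
    !is.na(maf) & maf > 0 & maf < threshold
  tibble::tibble(
    chrom = fam$chrom[keep],
    key = variant_key(fam)[keep],
    maf = maf[keep],
    mother_carrier = gt_is_carrier(fam$gt_mother[keep])
  )
}

#' One resampling repetition of the sharing statistic
#'
#' From each chromosome that has eligible father-carried rare variants,
#' exactly one variant is drawn uniformly (chromosomes with none are
#' skipped, so at most 23 variants: chromosomes 1-22 and X). `expected` sums
#' the Hardy-Weinberg carrier probabilities of the sampled variants;
#' `observed` counts how many of them the mother carries (identical
#' `chrom:pos:ref:alt` allele).
#'
#' @param eligible A tibble from [eligible_father_variants()].
#' @return A one-row tibble: `n_sampled`, `expected`, `observed`, and a
#'   list-column `sampled_keys`.
#' @export
run_repetition <- function(eligible) {
  idx <- unlist(lapply(split(seq_len(nrow(eligible)), eligible$chrom),
                       function(rows) {
                         if (length(rows) == 1) rows else sample(rows, 1)
                       }), use.names = FALSE)
  tibble::tibble(
    n_sampled = length(idx),
    expected = sum(expected_sharing_probability(eligible$maf[idx])),
    observed = sum(eligible$mother_carrier[idx]),
    sampled_keys = list(eligible$key[idx])
  )
}

#' Rare-variant-sharing consanguinity statistic for a parent pair
#'
#' Screens a mother-father pair for cryptic relatedness. For each requested
#' MAF threshold, `n_reps` repetitions each draw one father-carried rare
#' variant per chromosome (Y excluded) and compare the number the mother
#' actually carries (observed) with the Hardy-Weinberg expectation for an
#' unrelated pair (expected, `1 - (1 - maf)^2` summed over the sample). The
#' family-level scalar is the pooled ratio `sum(observed) / sum(expected)`
#' across repetitions: about 1 for unrelated parents, and far above 1 when
#' the parents share recent ancestry, because identity by descent makes the
#' father's very rare alleles turn up in the mother far more often than
#' their population frequency predicts. Per-repetition ratios (unstable for
#' very rare variants, and undefined when a repetition's expectation is
#' zero) are kept for distribution plots.
#'
#' @param fam A [family_genotypes()] object with both parents.
#' @param thresholds Numeric vector of MAF cutoffs (default
#'   `c(0.01, 0.02, 0.05, 0.1)`).
#' @param n_reps Repetitions per threshold (default 100).
#' @param population Population MAF to use (default `EUR`).
#' @param seed Optional integer; when given, results are reproducible
#'   bit-for-bit.
#' @return An object of class `consanguinity_result`: a list with
#'   `pooled` (tibble: `threshold`, `n_reps`, `sum_observed`,
#'   `sum_expected`, `pooled_ratio`, `n_eligible`) and `repetitions`
#'   (tibble: `threshold`, `rep`, `n_sampled`, `expected`, `observed`,
#'   `ratio`). Use [tidy()] / [glance()] / [ggplot2::autoplot()].
#' @export
consanguinity_ratio <- function(fam, thresholds = c(0.01, 0.02, 0.05, 0.1),
                                n_reps = 100, population = "EUR", seed = NULL) {
  run <- function() {
    per_threshold <- purrr::map(thresholds, function(th) {
      eligible <- eligible_father_variants(fam, th, population)
      reps <- purrr::map_dfr(seq_len(n_reps), function(r) {
        rep_row <- run_repetition(eligible)
        rep_row$sampled_keys <- NULL
        dplyr::mutate(rep_row, rep = r, .before = 1)
      })
      reps$ratio <- ifelse(reps$expected > 0, reps$observed / reps$expected, NA_real_)
      sum_exp <- sum(reps$expected)
      pooled <- tibble::tibble(
        threshold = th, n_reps = n_reps,
        sum_observed = sum(reps$observed), sum_expected = sum_exp,
        pooled_ratio = if (sum_exp > 0) sum(reps$observed) / sum_exp else NA_real_,
        n_eligible = nrow(eligible)
      )
      if (sum_exp == 0) {
        rlang::warn(paste0("consanguinity_ratio(): no eligible variants at threshold ",
                           th, "; pooled ratio undefined"))
      }
      list(pooled = pooled, reps = dplyr::mutate(reps, threshold = th, .before = 1))
    })
    structure(
      list(pooled = purrr::map_dfr(per_threshold, "pooled"),
           repetitions = purrr::map_dfr(per_threshold, "reps"),
           population = population, seed = seed),
      class = "consanguinity_result"
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.consanguinity_result <- function(x, ...) {
  cat("# consanguinity_result (population ", x$population, ")\n", sep = "")
  print(x$pooled)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-repetition sharing ratios
#'
#' @param x A `consanguinity_result`.
#' @param ... Unused.
#' @return The per-repetition tibble (`threshold`, `rep`, `n_sampled`,
#'   `expected`, `observed`, `ratio`).
#' @exportS3Method generics::tidy
#' @export
tidy.consanguinity_result <- function(x, ...) x$repetitions

#' One-row-per-threshold summary of a consanguinity screen
#'
#' @param x A `consanguinity_result`.
#' @param ... Unused.
#' @return The pooled tibble, one row per MAF threshold.
#' @exportS3Method generics::glance
#' @export
glance.consanguinity_result <- function(x, ...) x$pooled

#' Plot the distribution of per-repetition sharing ratios
#'
#' Histograms of observed/expected sharing ratios, one facet per MAF
#' threshold, with the pooled ratio marked — the usual way to show one
#' family's pair against an unrelated baseline.
#'
#' @param object A `consanguinity_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.consanguinity_result <- function(object, ...) {
  reps <- dplyr::filter(object$repetitions, !is.na(.data$ratio))
  ggplot2::ggplot(reps, ggplot2::aes(x = .data$ratio)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "grey20") +
    ggplot2::geom_vline(data = object$pooled,
                        ggplot2::aes(xintercept = .data$pooled_ratio),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap(~threshold, scales = "free",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "observed / expected shared rare variants (per repetition)",
                  y = "repetitions",
                  title = "Rare-variant sharing between parents",
                  subtitle = "dashed line: pooled ratio (~1 expected for unrelated parents)")
}

#' Pair two fathers from different families as a pseudo parent pair
#'
#' Builds the inter-family null comparison: the father of one family plays
#' "father" and the father of another plays "mother", over the union of
#' their sites (sites absent from one sample are missing, hence not
#' carried). Running [consanguinity_ratio()] on such pairs yields the
#' unrelated-population baseline distribution.
#'
#' @param fam_a,fam_b Two [family_genotypes()] objects from distinct
#'   families, each with a father.
#' @return A [family_genotypes()] object whose `father` is `fam_a`'s father
#'   and whose `mother` is `fam_b`'s father.
#' @export
pair_fathers <- function(fam_a, fam_b) {
  sa <- family_samples(fam_a); sb <- family_samples(fam_b)
  if (!"father" %in% sa$role || !"father" %in% sb$role) {
    rlang::abort("pair_fathers(): both families must include a father")
  }
  id_a <- sa$sample_id[sa$role == "father"]
  id_b <- sb$sample_id[sb$role == "father"]
  if (identical(tibble::as_tibble(fam_a)[c("chrom", "pos", "ref", "alt", "gt_father")],
                tibble::as_tibble(fam_b)[c("chrom", "pos", "ref", "alt", "gt_father")])) {
    rlang::abort("pair_fathers(): cannot pair a father with himself")
  }
  if (identical(id_a, id_b)) {
    id_a <- paste0(id_a, "_a")
    id_b <- paste0(id_b, "_b")
  }
  ann_cols <- setdiff(names(fam_a), grep("^gt_", names(fam_a), value = TRUE))
  a <- tibble::as_tibble(fam_a)[, c(ann_cols, "gt_father")]
  names(a)[names(a) == "gt_father"] <- "gt_father_a"
  b_ann <- setdiff(names(fam_b), grep("^gt_", names(fam_b), value = TRUE))
  b <- tibble::as_tibble(fam_b)[, c(b_ann, "gt_father")]
  names(b)[names(b) == "gt_father"] <- "gt_father_b"
  key_cols <- c("chrom", "pos", "ref", "alt")
  merged <- dplyr::full_join(a, b, by = key_cols, suffix = c("", ".y"))
  for (col in setdiff(intersect(ann_cols, b_ann), key_cols)) {
    ycol <- paste0(col, ".y")
    if (ycol %in% names(merged)) {
      merged[[col]] <- dplyr::coalesce(merged[[col]], merged[[ycol]])
      merged[[ycol]] <- NULL
    }
  }
  merged$gt_father <- merged$gt_father_a
  merged$gt_mother <- merged$gt_father_b
  merged$gt_child <- NA_character_
  merged$gt_father_a <- NULL
  merged$gt_father_b <- NULL
  family_genotypes(
    merged,
    tibble::tibble(
      sample_id = c("pseudo_child", id_a, id_b),
      role = c("child", "father", "mother"),
      affected = c(FALSE, FALSE, FALSE),
      sex = c(NA_character_, "M", "M")
    )
  )
}

#' Inter-family baseline of sharing ratios
#'
#' Runs [consanguinity_ratio()] on every unordered pair of fathers from
#' distinct families (via [pair_fathers()]). Because fathers of different
#' families are expected to be unrelated, the resulting pooled ratios show
#' what the statistic looks like in the wider population; a family's
#' mother-father ratio far outside this distribution indicates relatedness.
#'
#' @param fams List of two or more [family_genotypes()] objects with
#'   fathers, from distinct families.
#' @param thresholds,n_reps,population,seed As in [consanguinity_ratio()].
#' @return A tibble: one row per father pair and threshold, with columns
#'   `family_a`, `family_b` and the pooled summary columns.
#' @export
interfamily_baseline <- function(fams, thresholds = c(0.01, 0.02, 0.05, 0.1),
                                 n_reps = 100, population = "EUR", seed = NULL) {
  if (length(fams) < 2) {
    rlang::abort("interfamily_baseline(): at least two fathers are required")
  }
  ids <- names(fams)
  if (is.null(ids)) ids <- as.character(seq_along(fams))
  combos <- utils::combn(seq_along(fams), 2)
  run <- function() {
    purrr::map_dfr(seq_len(ncol(combos)), function(j) {
      i1 <- combos[1, j]; i2 <- combos[2, j]
      res <- consanguinity_ratio(pair_fathers(fams[[i1]], fams[[i2]]),
                                 thresholds = thresholds, n_reps = n_reps,
                                 population = population)
      dplyr::mutate(res$pooled, family_a = ids[i1], family_b = ids[i2],
                    .before = 1)
    })
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
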