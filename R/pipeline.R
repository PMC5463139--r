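CONFIG_KEYS <- c("families", "annotation", "gene_sets", "rarity_threshold",
                 "population", "dominant_mode", "common_whitelist",
                 "consanguinity", "seed", "out_dir")
FAMILY_KEYS <- c("id", "vcf", "roles", "affected", "sexes")
CONSANGUINITY_KEYS <- c("thresholds", "reps", "population")

#' Validate and resolve a run configuration
#'
#' Reads a YAML (or JSON) configuration describing one or more families and
#' the filter settings, applies defaults, and fails hard on unknown keys,
#' duplicate family ids, duplicate roles, or missing files. The resolved
#' configuration drives [run_pipeline()].
#'
#' Recognised top-level keys: `families` (list of `id`, `vcf`, `roles`,
#' optional `affected`, `sexes`), `annotation` (arguments for
#' [annotation_config()]), `gene_sets` (category -> path; defaults to the
#' packaged lists), `rarity_threshold` (default 0.01), `population`
#' (default `GLOBAL`), `dominant_mode` (`de_novo` default, or
#' `affected_parent`), `common_whitelist`, `consanguinity`
#' (`thresholds`, `reps`, `population`), `seed` (default 1), `out_dir`.
#'
#' @param path Path to the YAML/JSON configuration file.
#' @return A list of class `run_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("config file not found: ", path))
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, CONFIG_KEYS, "top level")
  if (is.null(cfg$families) || length(cfg$families) == 0) {
    rlang::abort("config: `families` must list at least one family")
  }
  cfg$rarity_threshold <- cfg$rarity_threshold %||% 0.01
  if (!is.numeric(cfg$rarity_threshold) || cfg$rarity_threshold <= 0 ||
      cfg$rarity_threshold > 1) {
    rlang::abort("config: `rarity_threshold` must be a number in (0, 1]")
  }
  cfg$population <- cfg$population %||% "GLOBAL"
  cfg$dominant_mode <- cfg$dominant_mode %||% "de_novo"
  if (!cfg$dominant_mode %in% c("de_novo", "affected_parent")) {
    rlang::abort("config: `dominant_mode` must be 'de_novo' or 'affected_parent'")
  }
  cfg$common_whitelist <- as.character(cfg$common_whitelist %||% character(0))
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$out_dir <- cfg$out_dir %||% "triokin_run"
  cons <- cfg$consanguinity %||% list()
  check_keys(cons, CONSANGUINITY_KEYS, "consanguinity")
  cfg$consanguinity <- list(
    thresholds = as.numeric(cons$thresholds %||% c(0.01, 0.02, 0.05, 0.1)),
    reps = as.integer(cons$reps %||% 100L),
    population = cons$population %||% "EUR"
  )
  cfg$annotation <- do.call(annotation_config, cfg$annotation %||% list())
  if (!is.null(cfg$gene_sets)) {
    paths <- unlist(cfg$gene_sets)
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0) {
      rlang::abort(paste0("config: gene list file(s) not found: ",
                          paste(missing, collapse = ", ")))
    }
    cfg$gene_sets <- paths
  }

  ids <- purrr::map_chr(cfg$families, ~ as.character(.x$id %||% NA))
  if (anyNA(ids)) rlang::abort("config: every family needs an `id`")
  if (anyDuplicated(ids)) rlang::abort("config: family ids must be unique")
  cfg$families <- purrr::map(cfg$families, function(f) {
    check_keys(f, FAMILY_KEYS, paste0("family '", f$id, "'"))
    if (is.null(f$vcf) || is.null(f$roles)) {
      rlang::abort(paste0("config: family '", f$id, "' needs `vcf` and `roles`"))
    }
    f$vcf <- as.character(unlist(f$vcf))
    missing <- f$vcf[!file.exists(f$vcf)]
    if (length(missing) > 0) {
      rlang::abort(paste0("config: family '", f$id, "': VCF not found: ",
                          paste(missing, collapse = ", ")))
    }
    roles <- unlist(f$roles)
    if (anyDuplicated(roles)) {
      rlang::abort(paste0("config: family '", f$id,
                          "': two samples mapped to role '",
                          roles[duplicated(roles)][1], "'"))
    }
    if (!all(roles %in% ROLES)) {
      rlang::abort(paste0("config: family '", f$id, "': unknown role '",
                          setdiff(roles, ROLES)[1], "'"))
    }
    f$roles <- roles
    f$affected <- if (is.null(f$affected)) NULL else unlist(f$affected)
    f$sexes <- if (is.null(f$sexes)) NULL else unlist(f$sexes)
    f
  })
  structure(cfg, class = "run_config")
}

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0) {
    rlang::abort(paste0("config: unknown key '", unknown[1], "' at ", where,
                        " (allowed: ", paste(allowed, collapse = ", "), ")"))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full family-filtering pipeline
#'
#' For each configured family: ingest the VCF(s), write the per-member and
#' cascade counts (`cascade_counts.tsv`), segregation-labelled variant
#' tables (`recessive.tsv`, `dominant.tsv`, `compound_het.tsv` when both
#' parents are available), the gene-panel candidate report
#' (`candidates.tsv`), and — when both parents are present — the
#' consanguinity screen (`consanguinity.json` plus `consanguinity_reps.tsv`
#' for distribution plots). A cohort `summary.json` aggregates per-family
#' counts with a mean row over children, and `run.log` records the seed,
#' package version and configuration hash. Output payloads are
#' byte-identical across reruns with the same configuration and seed.
#' Failures are isolated per family; the run fails only if every family
#' fails.
#'
#' @param config A `run_config` from [validate_config()], or a path to one.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gene_sets <- if (is.null(config$gene_sets)) load_gene_sets()
               else load_gene_sets(config$gene_sets)

  results <- purrr::imap(config$families, function(fcfg, i) {
    tryCatch({
      fam_dir <- file.path(out_dir, fcfg$id)
      dir.create(fam_dir, recursive = TRUE, showWarnings = FALSE)
      fam <- read_family_vcf(fcfg$vcf, fcfg$roles, config$annotation,
                             affected = fcfg$affected, sexes = fcfg$sexes)
      trio <- all(c("mother", "father") %in% roles_present(fam))

      counts <- cascade_counts(fam, config$rarity_threshold, config$population)
      members <- member_variant_counts(fam)
      readr::write_tsv(dplyr::bind_cols(family = fcfg$id, counts),
                       file.path(fam_dir, "cascade_counts.tsv"))
      readr::write_tsv(dplyr::bind_cols(family = fcfg$id, members),
                       file.path(fam_dir, "member_counts.tsv"))

      keys <- variant_key(fam)
      rec <- classify_recessive(fam)
      write_variant_table(tibble::as_tibble(fam)[keys %in% rec, ],
                          file.path(fam_dir, "recessive.tsv"))
      dom <- tryCatch(classify_dominant(fam, config$dominant_mode),
                      error = function(e) character(0))
      write_variant_table(tibble::as_tibble(fam)[keys %in% dom, ],
                          file.path(fam_dir, "dominant.tsv"))
      if (trio) {
        readr::write_tsv(find_compound_het(fam),
                         file.path(fam_dir, "compound_het.tsv"))
      }

      candidates <- scan_panels(fam, gene_sets, config$rarity_threshold,
                                config$population, config$common_whitelist)
      write_variant_table(candidates, file.path(fam_dir, "candidates.tsv"))

      cons_pooled <- NULL
      if (trio) {
        res <- consanguinity_ratio(
          fam, thresholds = config$consanguinity$thresholds,
          n_reps = config$consanguinity$reps,
          population = config$consanguinity$population,
          seed = config$seed + i)
        jsonlite::write_json(
          list(family = fcfg$id, population = res$population,
               pooled = res$pooled, repetitions = res$repetitions),
          file.path(fam_dir, "consanguinity.json"),
          auto_unbox = TRUE, digits = NA, dataframe = "columns")
        readr::write_tsv(res$repetitions,
                         file.path(fam_dir, "consanguinity_reps.tsv"))
        cons_pooled <- res$pooled
      }
      list(id = fcfg$id, ok = TRUE, counts = counts, members = members,
           n_candidates = nrow(candidates), trio = trio,
           consanguinity = cons_pooled)
    }, error = function(e) {
      list(id = fcfg$id, ok = FALSE, error = conditionMessage(e))
    })
  })

  ok <- purrr::map_lgl(results, "ok")
  if (!any(ok)) {
    rlang::abort(paste0("run_pipeline(): all families failed; first error: ",
                        results[[1]]$error))
  }
  good <- results[ok]
  cascade_all <- purrr::map_dfr(good, ~ dplyr::bind_cols(family = .x$id, .x$counts))
  summary <- list(
    n_families = length(results),
    n_failed = sum(!ok),
    failed = purrr::map(results[!ok], ~ list(id = .x$id, error = .x$error)),
    rarity_threshold = config$rarity_threshold,
    population = config$population,
    families = purrr::map(good, function(r) {
      list(id = r$id, trio = r$trio,
           cascade = as.list(r$counts[1, ]),
           n_candidates = r$n_candidates,
           consanguinity_pooled = if (is.null(r$consanguinity)) NULL
                                  else r$consanguinity)
    }),
    mean_child = list(
      total_variants = mean(cascade_all$total_variants),
      snps = mean(cascade_all$snps),
      indels = mean(cascade_all$indels),
      recessive_homozygous = mean(cascade_all$recessive_homozygous)
    )
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  writeLines(c(
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("triokin_version: ", as.character(utils::packageVersion("triokin"))),
    paste0("seed: ", config$seed),
    paste0("config_hash: ", rlang::hash(unclass(config)))
  ), file.path(out_dir, "run.log"))
  invisible(out_dir)
}
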