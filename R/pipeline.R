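#' Configuration for a full pipeline run
#'
#' @param spec A [synth_spec()] describing the synthetic input cohort, or
#'   `NULL` when `cohort` is supplied directly to [run_all()].
#' @param out_dir Output directory (created if absent).
#' @param stages Stages to execute, in order, from `simulate`, `prep`,
#'   `latents`, `associate`, `match`, `mediate`.
#' @param max_pcs,max_modes Dimensionality caps for the latent stage.
#' @param n_boot,ci_level Bootstrap settings for the mediation stage.
#' @param fdr_level FDR level recorded with the outputs.
#' @param missing_rate Missingness injected into the simulated cohort
#'   before complete-case filtering (exercises attrition reporting).
#' @param heart_m1 Fixed first mediator for the multiple-mediation
#'   campaign.
#' @param seed Master seed; every stochastic stage derives a child seed
#'   from it.
#' @return A `run_config` list.
#' @export
run_config <- function(spec = synth_spec(), out_dir = tempfile("hbaxis_run"),
                       stages = c("simulate", "prep", "latents",
                                  "associate", "match", "mediate"),
                       max_pcs = 6L, max_modes = 6L, n_boot = 500L,
                       ci_level = 0.95, fdr_level = 0.05,
                       missing_rate = 0.02, heart_m1 = "heart_pc2",
                       seed = 1L) {
  structure(list(spec = spec, out_dir = out_dir, stages = stages,
                 max_pcs = max_pcs, max_modes = max_modes,
                 n_boot = n_boot, ci_level = ci_level,
                 fdr_level = fdr_level, missing_rate = missing_rate,
                 heart_m1 = heart_m1, seed = as.integer(seed)),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a cohort written by the pipeline
#'
#' @param data_path,dict_path Paths to the table TSV and dictionary TSV.
#' @return A [cohort_table].
#' @export
read_cohort <- function(data_path, dict_path) {
  data <- utils::read.delim(data_path, stringsAsFactors = FALSE)
  dict <- utils::read.delim(dict_path, stringsAsFactors = FALSE)
  cohort_table(data, dict)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> prep -> latents -> associate -> match -> mediate
#' on a synthetic or supplied cohort, writing every artifact (TSV tables,
#' model summaries as JSON, a manifest) into the configured output
#' directory. Downstream association and mediation tables are emitted in
#' both raw and deconfounded variants (`_raw` / `_deconf` suffixes). The
#' run is deterministic under the configured seed.
#'
#' @param config A [run_config()].
#' @param cohort Optional [cohort_table] to analyse instead of
#'   simulating one.
#' @return A `run_manifest`: per-stage records (rows retained, artifacts
#'   written), package version, config hash, and seed.
#' @export
run_all <- function(config = run_config(), cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  manifest <- list()
  note <- function(stage, n, artifacts = character(0)) {
    manifest[[stage]] <<- list(stage = stage, n_subjects = n,
                               artifacts = artifacts)
  }
  truth <- NULL

  if ("simulate" %in% stages) {
    if (is.null(config$spec)) stop("simulate stage needs config$spec",
                                   call. = FALSE)
    sim <- generate_cohort(config$spec)
    cohort <- sim$cohort
    truth <- sim$truth
    if (config$missing_rate > 0) {
      cohort <- inject_missingness(cohort, config$missing_rate,
                                   seed = child_seed(config$seed, 11))
    }
    write_tsv(cohort_data(cohort), file.path(config$out_dir, "cohort.tsv"))
    write_tsv(dictionary(cohort), file.path(config$out_dir, "dict.tsv"))
    jsonlite::write_json(
      list(paths = as.list(truth$paths),
           implied = as.list(truth$implied)),
      file.path(config$out_dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA)
    note("simulate", nrow(cohort_data(cohort)),
         c("cohort.tsv", "dict.tsv", "ground_truth.json"))
  }
  if (is.null(cohort)) stop("no cohort: supply one or enable simulate",
                            call. = FALSE)

  prepared <- cohort
  if ("prep" %in% stages) {
    prepared <- transform_cognitive(prepared)
    prepared <- aggregate_vrf_count(prepared)
    cc <- complete_case_filter(prepared)
    prepared <- cc$cohort
    write_tsv(cohort_data(prepared),
              file.path(config$out_dir, "prepared.tsv"))
    jsonlite::write_json(unclass(cc$report),
                         file.path(config$out_dir, "prep_report.json"),
                         auto_unbox = TRUE, digits = NA)
    note("prep", nrow(cohort_data(prepared)),
         c("prepared.tsv", "prep_report.json"))
  }

  scores_raw <- scores_deconf <- NULL
  if ("latents" %in% stages) {
    lat <- derive_latents(prepared, max_pcs = config$max_pcs,
                          max_modes = config$max_modes,
                          seed = child_seed(config$seed, 12))
    scores_raw <- lat$scores
    conf_cols <- role_columns(prepared, "confounder")
    scores_deconf <- deconfound(scores_raw,
                                cohort_data(prepared)[, conf_cols,
                                                      drop = FALSE])
    write_tsv(scores_raw, file.path(config$out_dir, "scores_raw.tsv"))
    write_tsv(scores_deconf, file.path(config$out_dir, "scores_deconf.tsv"))
    jsonlite::write_json(
      lapply(lat$models, summarize_model),
      file.path(config$out_dir, "models.json"), auto_unbox = TRUE,
      digits = NA)
    note("latents", nrow(scores_raw),
         c("scores_raw.tsv", "scores_deconf.tsv", "models.json"))
  }

  covs <- cohort_data(prepared)[, c("age", "sex"), drop = FALSE]
  if ("associate" %in% stages) {
    if (is.null(scores_raw)) stop("associate needs the latents stage",
                                  call. = FALSE)
    for (variant in c("raw", "deconf")) {
      sc <- if (variant == "raw") scores_raw else scores_deconf
      assoc <- pairwise_latent_models(sc, covs)
      write_tsv(assoc, file.path(config$out_dir,
                                 paste0("assoc_", variant, ".tsv")))
    }
    note("associate", nrow(scores_raw),
         c("assoc_raw.tsv", "assoc_deconf.tsv"))
  }

  if ("match" %in% stages) {
    md <- cohort_data(prepared)
    if (!"vrf_count" %in% names(md)) {
      stop("match stage needs vrf_count (prep stage)", call. = FALSE)
    }
    md <- md[md$vrf_count >= 4 | md$vrf_count == 0, , drop = FALSE]
    md$exposed <- as.integer(md$vrf_count >= 4)
    ps <- estimate_propensity(md, "exposed",
                              c("age", "head_size", "bsa"))
    pairs <- match_nearest(md, "exposed", ps$propensity,
                           balance_covariates = c("age", "head_size",
                                                  "bsa"))
    outcome_cols <- role_columns(prepared, c("cognitive", "heart_feature",
                                             "brain_volume", "brain_fa",
                                             "brain_md", "brain_wmh"))
    cmp <- paired_compare(md, pairs, outcome_cols)
    write_tsv(pairs$pairs, file.path(config$out_dir, "pairs.tsv"))
    write_tsv(cmp, file.path(config$out_dir, "compare.tsv"))
    note("match", 2L * nrow(pairs$pairs), c("pairs.tsv", "compare.tsv"))
  }

  if ("mediate" %in% stages) {
    if (is.null(scores_raw)) stop("mediate needs the latents stage",
                                  call. = FALSE)
    for (variant in c("raw", "deconf")) {
      sc <- if (variant == "raw") scores_raw else scores_deconf
      med_data <- cbind(as.data.frame(sc), covs)
      single <- run_campaign(med_data, "latent_single",
                             n_boot = config$n_boot,
                             ci_level = config$ci_level,
                             seed = child_seed(config$seed, 13))
      write_tsv(single, file.path(config$out_dir,
                                  paste0("med_latent_single_", variant,
                                         ".tsv")))
      if (config$heart_m1 %in% names(med_data)) {
        multi <- run_campaign(med_data, "latent_multiple",
                              m1 = config$heart_m1,
                              n_boot = config$n_boot,
                              ci_level = config$ci_level,
                              seed = child_seed(config$seed, 14))
        write_tsv(multi, file.path(config$out_dir,
                                   paste0("med_latent_multiple_", variant,
                                          ".tsv")))
      }
    }
    note("mediate", nrow(scores_raw),
         grep("^med_", list.files(config$out_dir), value = TRUE))
  }

  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "spec")],
                               auto_unbox = TRUE, force = TRUE)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest_obj <- structure(
    list(package_version = as.character(utils::packageVersion("hbaxis")),
         seed = config$seed,
         config_hash = unname(tools::md5sum(tf)),
         stages = manifest),
    class = "run_manifest")
  unlink(tf)
  jsonlite::write_json(unclass(manifest_obj),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest_obj
}

summarize_model <- function(m) {
  out <- list(kind = m$kind, n_components = m$n_components)
  if (m$kind == "cfa") {
    out$loadings <- as.list(m$loadings)
    out$uniquenesses <- as.list(m$uniquenesses)
    out$determinacy <- m$determinacy
  } else if (m$kind == "pca") {
    out$variance_explained <- m$variance_explained
    out$cv <- m$fit_meta$cv
  } else if (m$kind == "cca") {
    out$canonical_correlations <- m$canonical_correlations
    out$cv <- m$fit_meta$cv
  }
  out
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("hbaxis run (package", x$package_version, ", seed", x$seed, ")\n")
  for (s in x$stages) {
    cat(sprintf("  %-10s n=%-6d %s\n", s$stage, s$n_subjects,
                paste(s$artifacts, collapse = ", ")))
  }
  invisible(x)
}
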