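imaging_latents <- function(latents) {
  latents[grepl("^(heart_|brain_|atrophy$|gmv$|wmh$|gFA$|gMD$)", latents)]
}

campaign_row <- function(fit, mediator_label, topology) {
  ci <- fit$boot$ci
  ind <- fit$indirect_total
  data.frame(
    mediator = mediator_label, topology = topology,
    a = fit$paths[["a"]],
    a2 = if ("a2" %in% names(fit$paths)) fit$paths[["a2"]] else NA_real_,
    d21 = if ("d21" %in% names(fit$paths)) fit$paths[["d21"]] else NA_real_,
    b1 = fit$paths[["b1"]],
    b2 = if ("b2" %in% names(fit$paths)) fit$paths[["b2"]] else NA_real_,
    c_prime = fit$paths[["c_prime"]], c_total = fit$paths[["c_total"]],
    indirect = ind,
    ind_lower = ci["indirect_total", "lower"],
    ind_upper = ci["indirect_total", "upper"],
    ind_m1 = fit$indirect[["ind_m1"]],
    ind_m1_lower = ci["ind_m1", "lower"],
    ind_m1_upper = ci["ind_m1", "upper"],
    ind_m2 = if ("ind_m2" %in% names(fit$indirect))
      fit$indirect[["ind_m2"]] else NA_real_,
    ind_m2_lower = if ("ind_m2" %in% rownames(ci))
      ci["ind_m2", "lower"] else NA_real_,
    ind_m2_upper = if ("ind_m2" %in% rownames(ci))
      ci["ind_m2", "upper"] else NA_real_,
    percent_mediated = fit$percent_mediated,
    direct_lower = ci["c_prime", "lower"],
    direct_upper = ci["c_prime", "upper"],
    complete_mediation = ci["c_prime", "lower"] <= 0 &
      ci["c_prime", "upper"] >= 0 &
      (ci["indirect_total", "lower"] > 0 | ci["indirect_total", "upper"] < 0),
    p = fit$boot$p[["indirect_total"]],
    stringsAsFactors = FALSE)
}

#' Run one of the four mediation campaigns
#'
#' The campaigns mirror the stages of a latent heart-brain mediation
#' analysis:
#'
#' * `latent_single` — the exposure-outcome association (gVRF -> g by
#'   default) with each imaging latent, one at a time, as the sole
#'   mediator.
#' * `latent_multiple` — a fixed heart mediator (`m1`, latent myocardial
#'   intensity by default) paired with each brain latent as the second
#'   mediator, fitted both as parallel and as sequential multiple
#'   mediation.
#' * `vrf_exam_pairs` — every (VRF indicator, cognitive exam) pair as
#'   exposure and outcome, each model additionally controlling for all
#'   other VRFs, with each imaging latent as sole mediator.
#' * `individual_features` — every heart and brain feature (z-scored) as
#'   sole mediator of the exposure-outcome association.
#'
#' Every model always controls for age and sex. Mediator significance is
#' judged by the bootstrap CI for the indirect effect excluding zero;
#' BH-FDR q-values are computed within the campaign over the
#' normal-approximation bootstrap p-values, and rows are sorted by
#' indirect effect.
#'
#' @param data Data.frame holding latent scores (and, for the
#'   `vrf_exam_pairs` / `individual_features` campaigns, the prepared
#'   feature columns), plus age and sex.
#' @param campaign One of `"latent_single"`, `"latent_multiple"`,
#'   `"vrf_exam_pairs"`, `"individual_features"`.
#' @param x,y Exposure and outcome (defaults `"gVRF"` and `"g"`).
#' @param mediators Mediator columns; defaults to every imaging latent
#'   (or every feature column for `individual_features`).
#' @param m1 Fixed first mediator for `latent_multiple`.
#' @param vrfs,exams Exposure/outcome pools for `vrf_exam_pairs`.
#' @param covariates Baseline covariates (always age and sex).
#' @param n_boot,ci_level Bootstrap settings per model.
#' @param seed Base seed; each model uses a deterministic child seed.
#' @return Data.frame with one row per fitted model (per mediator and,
#'   for `latent_multiple`, per topology), sorted by indirect effect,
#'   with `q` added within the campaign.
#' @export
run_campaign <- function(data, campaign, x = "gVRF", y = "g",
                         mediators = NULL, m1 = "heart_pc2",
                         vrfs = NULL, exams = NULL,
                         covariates = c("age", "sex"),
                         n_boot = 1000L, ci_level = 0.95, seed = 1L) {
  campaign <- match.arg(campaign, c("latent_single", "latent_multiple",
                                    "vrf_exam_pairs",
                                    "individual_features"))
  data <- as.data.frame(data)
  rows <- list()
  i <- 0L
  boot_one <- function(...) {
    i <<- i + 1L
    bootstrap_mediation(..., n_boot = n_boot, ci_level = ci_level,
                        seed = child_seed(seed, i))
  }

  if (campaign == "latent_single") {
    mediators <- mediators %||% imaging_latents(setdiff(names(data),
                                                        c(x, y, covariates)))
    for (m in mediators) {
      fit <- boot_one(data, x, y, m, covariates)
      rows[[length(rows) + 1L]] <- campaign_row(fit, m, "single")
    }
  } else if (campaign == "latent_multiple") {
    assert_cols(data, m1)
    mediators <- mediators %||% {
      lat <- imaging_latents(setdiff(names(data), c(x, y, covariates)))
      lat[grepl("^(brain_|atrophy$|gmv$|wmh$|gFA$|gMD$)", lat)]
    }
    for (m2 in setdiff(mediators, m1)) {
      for (topo in c("parallel", "sequential")) {
        fit <- boot_one(data, x, y, c(m1, m2), covariates,
                        topology = topo)
        rows[[length(rows) + 1L]] <-
          campaign_row(fit, paste(m1, m2, sep = "+"), topo)
      }
    }
  } else if (campaign == "vrf_exam_pairs") {
    vrfs <- vrfs %||% grep("^vrf_(htn|diab|chol|pack_years|sbp|dbp|bmi|whr)$",
                           names(data), value = TRUE)
    exams <- exams %||% grep("^cog_", names(data), value = TRUE)
    mediators <- mediators %||% imaging_latents(setdiff(names(data),
                                                        c(covariates)))
    if (!length(vrfs) || !length(exams)) {
      stop("vrf_exam_pairs needs VRF and cognitive exam columns",
           call. = FALSE)
    }
    # standardize continuous VRFs and exams so betas are comparable;
    # binary indicators stay on their natural 0/1 scale
    zcol <- function(cl) {
      if (length(unique(data[[cl]])) > 2) std1(data[[cl]], cl) else
        data[[cl]]
    }
    for (cl in c(vrfs, exams)) data[[paste0(".z_", cl)]] <- zcol(cl)
    for (v in vrfs) {
      others <- paste0(".z_", setdiff(vrfs, v))
      for (ex in exams) {
        for (m in mediators) {
          fit <- boot_one(data, paste0(".z_", v), paste0(".z_", ex), m,
                          covariates, extra_controls = others)
          row <- campaign_row(fit, m, "single")
          row$exposure <- v; row$outcome <- ex
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
  } else {  # individual_features
    mediators <- mediators %||% grep("^(hrt_|brn_)", names(data),
                                     value = TRUE)
    if (!length(mediators)) {
      stop("individual_features needs hrt_/brn_ feature columns or an ",
           "explicit mediator list", call. = FALSE)
    }
    for (m in mediators) {
      zname <- paste0(".z_", m)
      data[[zname]] <- std1(data[[m]], m)
      fit <- boot_one(data, x, y, zname, covariates)
      rows[[length(rows) + 1L]] <- campaign_row(fit, m, "single")
    }
  }

  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out <- out[order(out$indirect), ]
  rownames(out) <- NULL
  attr(out, "campaign") <- campaign
  out
}
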