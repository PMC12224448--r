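#' Default heart feature-block structure
#'
#' Three latent dimensions of cardiac structure, in the spirit of CMR
#' radiomics summaries: myocardial/ventricular size, myocardial imaging
#' intensity, and myocardial texture. Each latent carries a named vector of
#' standardized loadings on its features; feature columns are prefixed
#' `hrt_` in the generated table.
#'
#' @return Named list mapping latent name to a named numeric loading vector.
#' @export
default_heart_structure <- function() {
  list(
    size = c(lvedv = 0.85, lvesv = 0.80, lvm = 0.78, sv = 0.75,
             rvedv = 0.70, rvesv = 0.65),
    intensity = c(int_mean_es = 0.85, int_mean_ed = 0.80,
                  int_median_es = 0.78, int_p10_es = 0.72,
                  int_energy_ed = 0.68),
    texture = c(tex_contrast = 0.78, tex_uniformity = -0.70,
                tex_busyness = 0.70, tex_zonesize = 0.66,
                tex_dependence = 0.62)
  )
}

#' Default brain feature-block structure
#'
#' Three latent dimensions of brain structure: global/subcortical volume
#' (on which white-matter hyperintensity volume loads negatively),
#' tract-averaged fractional anisotropy, and tract-averaged mean
#' diffusivity. Corticospinal and cingulate tracts get the lowest FA/MD
#' loadings and the thalamic radiations the highest, the pattern typically
#' seen for general white-matter factors. Columns are prefixed `brn_`.
#'
#' @return Named list mapping latent name to a named numeric loading vector.
#' @export
default_brain_structure <- function() {
  list(
    vol = c(tbv = 0.88, gmv = 0.85, thal_l = 0.72, thal_r = 0.70,
            hippo = 0.60, wmh = -0.45),
    fa = c(fa_atr_l = 0.80, fa_atr_r = 0.78, fa_slf = 0.74, fa_ilf = 0.70,
           fa_cst = 0.45, fa_cing = 0.40),
    md = c(md_atr_l = 0.78, md_atr_r = 0.76, md_slf = 0.72, md_ilf = 0.68,
           md_cst = 0.45, md_cing = 0.40)
  )
}

#' Specify a synthetic cohort
#'
#' Defines the generative model for [generate_cohort()]: a standardized
#' linear latent system with a general vascular-risk factor (gVRF), latent
#' heart and brain structural dimensions, and general cognitive function
#' (g), connected by structural paths
#' `gVRF -(a)-> heart mediator -(d)-> brain mediator -(b2)-> g`,
#' `heart mediator -(b1)-> g`, and a direct path `gVRF -(c)-> g`.
#' All latents have unit variance and all loadings are standardized, so
#' path coefficients are standardized regression coefficients.
#'
#' Shared heart-brain axes couple a heart latent to a brain latent so that
#' the *feature-level* canonical correlation between the two blocks matches
#' the requested target: the latent-level coupling is inflated by the
#' factor-score determinacies of the two latents
#' (`r_latent = r_target / (rho_heart * rho_brain)`), which compensates for
#' the attenuation incurred when latents are measured through noisy
#' indicators. Targets that would require a latent coupling of 1 or more
#' are rejected as unrealizable.
#'
#' @param n_subjects Number of subjects (at least twice the number of
#'   latents).
#' @param seed Integer seed; identical specs generate byte-identical
#'   tables.
#' @param age_range Two numbers, years; age is drawn uniformly.
#' @param sex_ratio Proportion female in `[0, 1]` (sex coded 1 = female).
#' @param vrf_loadings Named loadings of the 8 VRF indicators
#'   (`htn`, `diab`, `chol`, `pack_years`, `sbp`, `dbp`, `bmi`, `whr`) on
#'   gVRF.
#' @param binary_thresholds Named liability cutpoints for the three binary
#'   diagnoses (`htn`, `diab`, `chol`); with no age/sex effects the
#'   prevalence of each diagnosis is `1 - pnorm(threshold)`.
#' @param cog_loadings Named loadings of the four cognitive tests (`vnr`,
#'   `vismem`, `rt`, `prosmem`) on g. Reaction time is stored as
#'   `exp(mu - sigma * core)` so that a natural-log transform restores a
#'   (negatively g-loaded) normal score; visual memory is zero-inflated and
#'   then exponentiated.
#' @param vismem_zero_mass Point mass at zero errors for the visual-memory
#'   test.
#' @param heart_structure,brain_structure Feature-block structures; see
#'   [default_heart_structure()].
#' @param shared_axes List of axes, each a list with elements `heart`
#'   (heart latent name), `brain` (brain latent name), and `r` (target
#'   feature-level canonical correlation in `[0, 1)`).
#' @param heart_mediator,brain_mediator Names of the latents carrying the
#'   structural paths.
#' @param path_a,path_d,path_b1,path_b2,path_c_direct Standardized
#'   structural path coefficients.
#' @param age_effects,sex_effects Named per-variable-class slopes
#'   (`vrf`, `cognitive`, `heart`, `brain`) added to every indicator of the
#'   class, per SD of age and per unit of centered sex respectively.
#' @param confounder_effects Named slopes: `head_size_brain` (head size on
#'   brain features) and `bsa_heart` (body surface area on heart features),
#'   per SD of the confounder.
#' @param noise_sd Named per-block multipliers of the unique (residual)
#'   indicator noise; at the default 1 every indicator core has unit
#'   variance so loadings are exactly standardized.
#'
#' @return An object of class `synth_spec`.
#' @seealso [generate_cohort()], [implied_effects()]
#' @export
synth_spec <- function(n_subjects = 5000L,
                       seed = 1L,
                       age_range = c(45, 80),
                       sex_ratio = 0.52,
                       vrf_loadings = c(htn = 0.60, diab = 0.35, chol = 0.40,
                                        pack_years = 0.30, sbp = 0.55,
                                        dbp = 0.50, bmi = 0.75, whr = 0.65),
                       binary_thresholds = c(htn = stats::qnorm(0.72),
                                             diab = stats::qnorm(0.94),
                                             chol = stats::qnorm(0.82)),
                       cog_loadings = c(vnr = 0.70, vismem = 0.50,
                                        rt = 0.55, prosmem = 0.45),
                       vismem_zero_mass = 0.3,
                       heart_structure = default_heart_structure(),
                       brain_structure = default_brain_structure(),
                       shared_axes = list(
                         list(heart = "size", brain = "vol", r = 0.70),
                         list(heart = "intensity", brain = "fa", r = 0.45),
                         list(heart = "texture", brain = "md", r = 0.30)),
                       heart_mediator = "intensity",
                       brain_mediator = "vol",
                       path_a = -0.55,
                       path_d = 0.40,
                       path_b1 = 0.078,
                       path_b2 = 0.02,
                       path_c_direct = 0.01,
                       age_effects = c(vrf = 0.15, cognitive = -0.20,
                                       heart = -0.10, brain = -0.25),
                       sex_effects = c(vrf = -0.10, cognitive = 0.05,
                                       heart = -0.20, brain = -0.10),
                       confounder_effects = c(head_size_brain = 0.35,
                                              bsa_heart = 0.30),
                       noise_sd = c(vrf = 1, cognitive = 1,
                                    heart = 1, brain = 1)) {
  spec <- structure(
    list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
         age_range = age_range, sex_ratio = sex_ratio,
         vrf_loadings = vrf_loadings,
         binary_thresholds = binary_thresholds,
         cog_loadings = cog_loadings, vismem_zero_mass = vismem_zero_mass,
         heart_structure = heart_structure,
         brain_structure = brain_structure,
         shared_axes = shared_axes,
         heart_mediator = heart_mediator, brain_mediator = brain_mediator,
         path_a = path_a, path_d = path_d, path_b1 = path_b1,
         path_b2 = path_b2, path_c_direct = path_c_direct,
         age_effects = age_effects, sex_effects = sex_effects,
         confounder_effects = confounder_effects, noise_sd = noise_sd),
    class = "synth_spec")
  validate_synth_spec(spec)
  spec
}

validate_synth_spec <- function(spec) {
  if (!is_number(spec$n_subjects) || spec$n_subjects <= 0) {
    stop("n_subjects must be a positive integer", call. = FALSE)
  }
  n_latents <- 2L + length(spec$heart_structure) + length(spec$brain_structure)
  if (spec$n_subjects < 2L * n_latents) {
    stop("n_subjects must be at least twice the number of latents (",
         2L * n_latents, ")", call. = FALSE)
  }
  all_load <- c(spec$vrf_loadings, spec$cog_loadings,
                unlist(spec$heart_structure), unlist(spec$brain_structure))
  if (!all(is.finite(all_load))) stop("all loadings must be finite", call. = FALSE)
  if (any(abs(all_load) >= 1)) {
    stop("standardized loadings must lie strictly inside (-1, 1)", call. = FALSE)
  }
  req <- c("htn", "diab", "chol", "pack_years", "sbp", "dbp", "bmi", "whr")
  if (!setequal(names(spec$vrf_loadings), req)) {
    stop("vrf_loadings must be named: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!setequal(names(spec$cog_loadings), c("vnr", "vismem", "rt", "prosmem"))) {
    stop("cog_loadings must be named vnr, vismem, rt, prosmem", call. = FALSE)
  }
  if (!setequal(names(spec$binary_thresholds), c("htn", "diab", "chol"))) {
    stop("binary_thresholds must be named htn, diab, chol", call. = FALSE)
  }
  for (ax in spec$shared_axes) {
    if (!ax$heart %in% names(spec$heart_structure) ||
        !ax$brain %in% names(spec$brain_structure)) {
      stop("shared axis refers to unknown latent '", ax$heart, "'/'",
           ax$brain, "'", call. = FALSE)
    }
    if (!is_number(ax$r) || ax$r < 0 || ax$r >= 1) {
      stop("shared-axis target correlations must lie in [0, 1)", call. = FALSE)
    }
  }
  uses_heart <- spec$path_a != 0 || spec$path_b1 != 0 || spec$path_d != 0
  if (uses_heart && !spec$heart_mediator %in% names(spec$heart_structure)) {
    stop("heart_mediator must name a heart latent", call. = FALSE)
  }
  uses_brain <- spec$path_d != 0 || spec$path_b2 != 0
  if (uses_brain && !spec$brain_mediator %in% names(spec$brain_structure)) {
    stop("brain_mediator must name a brain latent", call. = FALSE)
  }
  # resolving the latent system performs the realizability checks
  latent_system(spec)
  invisible(spec)
}

# factor-score determinacy of a latent measured through its own loading
# vector (block-diagonal structure, unit indicator variances)
block_determinacy <- function(loadings) {
  s <- sum(loadings^2 / (1 - loadings^2))
  sqrt(s / (1 + s))
}

# Resolve the structural system implied by a spec: coefficients of each
# brain latent on the heart latents (structural path d plus calibrated
# shared-axis couplings), residual SDs keeping every latent at unit
# variance, and the residual variance of g.
latent_system <- function(spec) {
  hn <- names(spec$heart_structure)
  bn <- names(spec$brain_structure)
  B <- matrix(0, nrow = length(bn), ncol = length(hn),
              dimnames = list(bn, hn))
  if (spec$brain_mediator %in% bn && spec$heart_mediator %in% hn) {
    B[spec$brain_mediator, spec$heart_mediator] <-
      B[spec$brain_mediator, spec$heart_mediator] + spec$path_d
  }
  for (ax in spec$shared_axes) {
    if (ax$r == 0) next
    rho <- block_determinacy(spec$heart_structure[[ax$heart]]) *
      block_determinacy(spec$brain_structure[[ax$brain]])
    r_lat <- ax$r / rho
    if (r_lat >= 1) {
      stop("shared-axis target ", ax$r, " between '", ax$heart, "' and '",
           ax$brain, "' is not realizable: would need latent coupling ",
           round(r_lat, 3), call. = FALSE)
    }
    B[ax$brain, ax$heart] <- B[ax$brain, ax$heart] + r_lat
  }
  brain_resid_var <- 1 - rowSums(B^2)
  if (any(brain_resid_var <= 0)) {
    bad <- bn[brain_resid_var <= 0]
    stop("brain latent(s) over-determined (implied variance >= 1): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  # effective heart-mediator -> brain-mediator coefficient
  d_eff <- if (spec$brain_mediator %in% bn && spec$heart_mediator %in% hn) {
    B[spec$brain_mediator, spec$heart_mediator]
  } else 0
  a <- spec$path_a; b1 <- spec$path_b1; b2 <- spec$path_b2
  cdir <- spec$path_c_direct
  g_var <- b1^2 + b2^2 + cdir^2 +
    2 * (b1 * b2 * d_eff + b1 * cdir * a + b2 * cdir * a * d_eff)
  if (g_var >= 1) {
    stop("structural paths imply g variance >= 1 (", round(g_var, 3),
         "); reduce path coefficients", call. = FALSE)
  }
  list(brain_coef = B, brain_resid_sd = sqrt(brain_resid_var),
       d_eff = d_eff, g_resid_sd = sqrt(1 - g_var))
}

#' Closed-form true effects implied by a synthetic-cohort spec
#'
#' Path-tracing in the standardized linear latent system: the total
#' gVRF -> g effect is the direct path plus the product of coefficients
#' along each indirect route (`a*b1` through the heart mediator and
#' `a*d*b2` through the heart-then-brain chain, where `d` is the effective
#' heart-to-brain coefficient after any shared-axis coupling between the
#' two mediators).
#'
#' @param spec A [synth_spec()].
#' @return Named numeric vector with elements `direct`, `indirect_heart`,
#'   `indirect_heart_brain`, and `total`.
#' @export
implied_effects <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  sys <- latent_system(spec)
  ih <- spec$path_a * spec$path_b1
  ihb <- spec$path_a * sys$d_eff * spec$path_b2
  c(direct = spec$path_c_direct,
    indirect_heart = ih,
    indirect_heart_brain = ihb,
    total = spec$path_c_direct + ih + ihb)
}

# native-unit affine maps (center, scale) applied to unit-variance cores
native_affine <- function() {
  list(
    vrf_sbp = c(138, 18), vrf_dbp = c(82, 10), vrf_bmi = c(25.0, 4.3),
    cog_vnr = c(7.2, 2.0), cog_prosmem = c(3.2, 0.8),
    hrt_lvedv = c(158, 34), hrt_lvesv = c(66, 20), hrt_lvm = c(90, 18),
    hrt_sv = c(92, 18), hrt_rvedv = c(168, 36), hrt_rvesv = c(78, 22),
    brn_tbv = c(1150000, 110000), brn_gmv = c(620000, 48000),
    brn_thal_l = c(7800, 800), brn_thal_r = c(7700, 780),
    brn_hippo = c(3900, 450),
    brn_fa_atr_l = c(0.45, 0.03), brn_fa_atr_r = c(0.45, 0.03),
    brn_fa_slf = c(0.44, 0.03), brn_fa_ilf = c(0.46, 0.03),
    brn_fa_cst = c(0.55, 0.03), brn_fa_cing = c(0.41, 0.03),
    brn_md_atr_l = c(8e-4, 4e-5), brn_md_atr_r = c(8e-4, 4e-5),
    brn_md_slf = c(7.8e-4, 4e-5), brn_md_ilf = c(8.2e-4, 4e-5),
    brn_md_cst = c(7.5e-4, 4e-5), brn_md_cing = c(8.5e-4, 4e-5)
  )
}

brain_role_for <- function(base) {
  if (base == "wmh") return("brain_wmh")
  if (startsWith(base, "fa_")) return("brain_fa")
  if (startsWith(base, "md_")) return("brain_md")
  "brain_volume"
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws subjects from the latent system defined by a [synth_spec()]:
#' unit-variance latents connected by the structural paths, feature blocks
#' built from standardized loadings plus unique noise, age/sex effects on
#' every variable class, head-size effects on brain features and
#' body-surface-area effects on heart features, and native-unit marginal
#' scales for the familiar variables (blood pressure in mmHg, volumes in
#' mL or mm^3, reaction time as an exponentiated normal so that a log
#' transform restores normality, zero-inflated visual-memory errors, and
#' pack-years left-censored at zero).
#'
#' @param spec A [synth_spec()].
#' @return A list with components `cohort` (a [cohort_table]) and `truth`
#'   (a `ground_truth` object holding per-subject latent scores, true
#'   loadings, structural paths, and the [implied_effects()] oracle).
#' @examples
#' out <- generate_cohort(synth_spec(n_subjects = 200, seed = 42))
#' dim(cohort_data(out$cohort))
#' out$truth$implied
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  validate_synth_spec(spec)
  sys <- latent_system(spec)
  n <- spec$n_subjects
  withr::with_seed(spec$seed, {
    age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    z_age <- (age - mean(spec$age_range)) /
      (diff(spec$age_range) / sqrt(12))
    sex <- stats::rbinom(n, 1L, spec$sex_ratio)
    sex_c <- sex - spec$sex_ratio
    head_size <- 1.02 - 0.04 * sex + stats::rnorm(n, 0, 0.07)
    bsa <- 2.02 - 0.22 * sex + stats::rnorm(n, 0, 0.15)
    z_head <- std1(head_size, "head_size")
    z_bsa <- std1(bsa, "bsa")

    gvrf <- stats::rnorm(n)
    hn <- names(spec$heart_structure)
    heart_lat <- matrix(stats::rnorm(n * length(hn)), n,
                        dimnames = list(NULL, hn))
    if (spec$heart_mediator %in% hn) {
      a <- spec$path_a
      heart_lat[, spec$heart_mediator] <-
        a * gvrf + sqrt(1 - a^2) * heart_lat[, spec$heart_mediator]
    }
    bn <- names(spec$brain_structure)
    brain_eps <- matrix(stats::rnorm(n * length(bn)), n,
                        dimnames = list(NULL, bn))
    brain_lat <- heart_lat %*% t(sys$brain_coef) +
      brain_eps %*% diag(sys$brain_resid_sd, length(bn))
    colnames(brain_lat) <- bn

    g_sys <- spec$path_c_direct * gvrf
    if (spec$heart_mediator %in% hn) {
      g_sys <- g_sys + spec$path_b1 * heart_lat[, spec$heart_mediator]
    }
    if (spec$brain_mediator %in% bn) {
      g_sys <- g_sys + spec$path_b2 * brain_lat[, spec$brain_mediator]
    }
    g <- g_sys + sys$g_resid_sd * stats::rnorm(n)

    eff <- function(class) {
      spec$age_effects[[class]] * z_age + spec$sex_effects[[class]] * sex_c
    }
    core_of <- function(lam, latent, class, extra = 0) {
      lam * latent +
        sqrt(max(0, 1 - lam^2)) * spec$noise_sd[[class]] * stats::rnorm(n) +
        eff(class) + extra
    }

    cols <- list()
    roles <- character(); types <- character(); transforms <- character()
    add_col <- function(name, values, role, type = "continuous",
                        transform = "none") {
      cols[[name]] <<- values
      roles[name] <<- role; types[name] <<- type
      transforms[name] <<- transform
    }

    # --- vascular risk factors -------------------------------------------
    thr <- spec$binary_thresholds
    for (b in c("htn", "diab", "chol")) {
      liab <- core_of(spec$vrf_loadings[[b]], gvrf, "vrf")
      add_col(paste0("vrf_", b), as.integer(liab > thr[[b]]),
              "vrf_binary", "binary")
    }
    py_core <- core_of(spec$vrf_loadings[["pack_years"]], gvrf, "vrf")
    py_cut <- stats::qnorm(0.65)  # ~35% ever-smokers at baseline
    add_col("vrf_pack_years", ifelse(py_core > py_cut,
                                     (py_core - py_cut) * 12, 0),
            "vrf_continuous")
    aff <- native_affine()
    for (v in c("sbp", "dbp", "bmi")) {
      core <- core_of(spec$vrf_loadings[[v]], gvrf, "vrf")
      m <- aff[[paste0("vrf_", v)]]
      add_col(paste0("vrf_", v), m[1] + m[2] * core, "vrf_continuous")
    }
    whr_core <- core_of(spec$vrf_loadings[["whr"]], gvrf, "vrf")
    add_col("vrf_whr", ifelse(sex == 1, 0.825, 0.885) + 0.065 * whr_core,
            "vrf_continuous")

    # --- cognitive tests --------------------------------------------------
    cog_core <- lapply(c(vnr = "vnr", vismem = "vismem", rt = "rt",
                         prosmem = "prosmem"),
                       function(t) core_of(spec$cog_loadings[[t]], g,
                                           "cognitive"))
    add_col("cog_vnr", aff$cog_vnr[1] + aff$cog_vnr[2] * cog_core$vnr,
            "cognitive")
    zmask <- stats::runif(n) < spec$vismem_zero_mass
    vis <- round(exp(1.1 - 0.75 * cog_core$vismem))
    vis[zmask] <- 0
    add_col("cog_vismem", vis, "cognitive", transform = "ln1p")
    add_col("cog_rt", exp(6.35 - 0.18 * cog_core$rt), "cognitive",
            transform = "ln")
    add_col("cog_prosmem",
            aff$cog_prosmem[1] + aff$cog_prosmem[2] * cog_core$prosmem,
            "cognitive")

    # --- heart features ---------------------------------------------------
    for (l in hn) {
      lam <- spec$heart_structure[[l]]
      for (f in names(lam)) {
        core <- core_of(lam[[f]], heart_lat[, l], "heart",
                        extra = spec$confounder_effects[["bsa_heart"]] * z_bsa)
        nm <- paste0("hrt_", f)
        m <- aff[[nm]]
        add_col(nm, if (is.null(m)) core else m[1] + m[2] * core,
                "heart_feature")
      }
    }

    # --- brain features ---------------------------------------------------
    for (l in bn) {
      lam <- spec$brain_structure[[l]]
      for (f in names(lam)) {
        core <- core_of(lam[[f]], brain_lat[, l], "brain",
                        extra = spec$confounder_effects[["head_size_brain"]] *
                          z_head)
        nm <- paste0("brn_", f)
        if (f == "wmh") {
          add_col(nm, exp(7.8 + 0.9 * core), brain_role_for(f))
        } else {
          m <- aff[[nm]]
          add_col(nm, if (is.null(m)) core else m[1] + m[2] * core,
                  brain_role_for(f))
        }
      }
    }

    add_col("age", age, "covariate")
    add_col("sex", sex, "covariate", "binary")
    add_col("head_size", head_size, "confounder")
    add_col("bsa", bsa, "confounder")

    data <- data.frame(subject_id = sprintf("S%06d", seq_len(n)), cols,
                       check.names = FALSE, stringsAsFactors = FALSE)
    dict <- data.frame(column = names(cols), role = unname(roles),
                       type = unname(types), transform = unname(transforms),
                       stringsAsFactors = FALSE)
    cohort <- cohort_table(data, dict,
                           provenance = sprintf("generate_cohort(seed=%d)",
                                                spec$seed))
    truth <- structure(
      list(latents = data.frame(subject_id = data$subject_id,
                                gvrf = gvrf, g = g,
                                stats::setNames(as.data.frame(heart_lat),
                                                paste0("heart_", hn)),
                                stats::setNames(as.data.frame(brain_lat),
                                                paste0("brain_", bn)),
                                stringsAsFactors = FALSE),
           loadings = list(vrf = spec$vrf_loadings,
                           cog = spec$cog_loadings,
                           heart = spec$heart_structure,
                           brain = spec$brain_structure),
           paths = c(a = spec$path_a, d = spec$path_d,
                     d_eff = sys$d_eff, b1 = spec$path_b1,
                     b2 = spec$path_b2, c_direct = spec$path_c_direct),
           brain_coef = sys$brain_coef,
           implied = implied_effects(spec)),
      class = "ground_truth")
    list(cohort = cohort, truth = truth)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth for", nrow(x$latents), "subjects\n")
  cat("Structural paths:\n")
  print(round(x$paths, 4))
  cat("Implied effects (path tracing):\n")
  print(round(x$implied, 4))
  invisible(x)
}

#' Inject missing values completely at random
#'
#' Sets each non-covariate, non-confounder cell missing independently with
#' the given probability, to exercise complete-case filtering.
#'
#' @param cohort A [cohort_table].
#' @param rate Missingness probability in `[0, 1)`.
#' @param seed Integer seed; the missingness mask is reproducible.
#' @return The cohort with `NA`s injected and provenance updated.
#' @export
inject_missingness <- function(cohort, rate, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!is_number(rate) || rate < 0 || rate >= 1) {
    stop("rate must lie in [0, 1)", call. = FALSE)
  }
  if (rate == 0) return(cohort)
  dict <- dictionary(cohort)
  targets <- dict$column[!dict$role %in% c("covariate", "confounder")]
  data <- cohort_data(cohort)
  withr::with_seed(seed, {
    mask <- matrix(stats::runif(nrow(data) * length(targets)) < rate,
                   nrow = nrow(data))
  })
  for (j in seq_along(targets)) {
    data[[targets[j]]][mask[, j]] <- NA
  }
  cohort_table(data, dict,
               provenance = c(provenance(cohort),
                              sprintf("inject_missingness(rate=%g, seed=%d)",
                                      rate, as.integer(seed))))
}
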