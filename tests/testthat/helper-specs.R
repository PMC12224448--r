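# shared fixture builders: small, effect-free specs so structural
# properties can be checked without age/sex/confounder contamination

zero_effects <- c(vrf = 0, cognitive = 0, heart = 0, brain = 0)
no_confounding <- c(head_size_brain = 0, bsa_heart = 0)

# minimal two-block spec with configurable structural paths
lean_spec <- function(n, seed, a = 0, b1 = 0, b2 = 0, d = 0, c_dir = 0,
                      axes = list(),
                      heart = list(intensity = c(i1 = 0.8, i2 = 0.75,
                                                 i3 = 0.7)),
                      brain = list(vol = c(v1 = 0.8, v2 = 0.75,
                                           v3 = 0.7)),
                      ...) {
  synth_spec(n_subjects = n, seed = seed,
             heart_structure = heart, brain_structure = brain,
             shared_axes = axes,
             heart_mediator = names(heart)[1],
             brain_mediator = names(brain)[1],
             path_a = a, path_b1 = b1, path_b2 = b2, path_d = d,
             path_c_direct = c_dir,
             age_effects = zero_effects, sex_effects = zero_effects,
             confounder_effects = no_confounding, ...)
}

# mediation frame on the true latent scores of a lean cohort
med_frame <- function(out) {
  lat <- out$truth$latents
  d <- cohort_data(out$cohort)
  data.frame(x = lat$gvrf,
             m1 = lat[[grep("^heart_", names(lat), value = TRUE)[1]]],
             m2 = lat[[grep("^brain_", names(lat), value = TRUE)[1]]],
             y = lat$g, age = d$age, sex = d$sex)
}

# hand-built cohort for prep-level unit tests
mini_cohort <- function(df, roles, transforms = NULL) {
  dict <- data.frame(column = setdiff(names(df), "subject_id"),
                     role = roles, stringsAsFactors = FALSE)
  if (!is.null(transforms)) dict$transform <- transforms
  cohort_table(df, dict)
}
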