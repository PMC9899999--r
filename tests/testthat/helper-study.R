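# Assemble the v1 - v3 static change-feature matrix for a cohort via the
# full post-processing + static FNC chain.
cohort_static_deltas <- function(cohort, postproc_cfg = postproc_config()) {
  clean <- lapply(cohort$timecourses, postprocess, config = postproc_cfg)
  feats <- lapply(clean, function(tc)
    vectorize_upper(zscore_fnc(compute_sfnc(tc))))
  subjects <- unique(vapply(cohort$timecourses, `[[`, "", "subject_id"))
  ds <- t(vapply(subjects, function(s)
    delta_features(feats[[paste0(s, "_v1")]], feats[[paste0(s, "_v3")]]),
    numeric(length(feats[[1]]))))
  rownames(ds) <- subjects
  list(delta_static = ds, clean = clean, subjects = subjects)
}

# Measured v1 - v3 dynamism change features via the dFNC + meta-state chain.
cohort_dynamism_deltas <- function(clean, subjects, dfnc_cfg, k = 5,
                                   seed = 11) {
  wf <- lapply(clean, compute_dfnc, config = dfnc_cfg)
  gd <- global_dynamism(wf, k = k, seed = seed)
  delta_dynamism(gd$dynamism, subjects)
}

# Study conditions for the planted static-effect recovery cohort:
# 50 subjects, 20 ICNs, one latent state, 10 planted edges, oracle R2 0.4.
recovery_conditions <- function(cohort_seed) {
  p_feat <- 20 * 19 / 2
  set.seed(2024)
  planted <- sample(p_feat, 10)
  eff <- rep(30, 10)
  names(eff) <- planted
  list(planted = planted,
       config = cohort_config(n_subjects = 50, n_icns = 20,
                              n_timepoints = 400, n_latent_states = 1,
                              effect_static = eff, target_r2 = 0.4,
                              static_delta_sd = 0.2, seed = cohort_seed))
}

# Study conditions for the static-vs-combined contrast cohorts: 50
# subjects, 15 ICNs, three latent states with subject-varying dwell, a
# moderate planted static effect and (optionally) planted dynamism
# effects on switching and travelled distance.
contrast_conditions <- function(cohort_seed, with_dynamism) {
  p_feat <- 15 * 14 / 2
  set.seed(77)
  planted <- sample(p_feat, 8)
  eff <- rep(10, 8)
  names(eff) <- planted
  dyn_eff <- if (with_dynamism) c(0, 6, 0, 1.5) else NULL
  cohort_config(n_subjects = 50, n_icns = 15, n_timepoints = 400,
                n_latent_states = 3, state_dwell = 35, dwell_log_sd = 1.2,
                effect_static = eff, effect_dynamism = dyn_eff,
                target_r2 = 0.5, static_delta_sd = 0.2, seed = cohort_seed)
}
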