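#' Write one scan's time courses (and motion) as delimited text
#'
#' Tab-separated matrix with a header row of ICN labels; the motion matrix
#' goes to a sibling file with suffix `_motion.tsv`.
#'
#' @param tc An [icn_timecourses()] object.
#' @param path Output path for the time-course matrix (`.tsv`).
#' @return Invisibly, the paths written.
#' @export
write_timecourses <- function(tc, path) {
  stopifnot_tc(tc)
  utils::write.table(tc$data, path, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  motion_path <- sub("\\.tsv$", "_motion.tsv", path)
  if (motion_path == path) motion_path <- paste0(path, "_motion.tsv")
  utils::write.table(tc$motion, motion_path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(c(data = path, motion = motion_path))
}

#' Read a time-course matrix from delimited text
#'
#' Expects a header row of ICN labels and a rectangular numeric body;
#' ragged rows, non-numeric cells and missing values are rejected with the
#' offending coordinates.
#'
#' @param path Path to the tab-separated time-course file.
#' @param motion_path Optional path to the T x 6 motion file (no header).
#' @param tr_seconds Sampling interval to record.
#' @param subject_id,session_id Identifiers to record.
#' @param expected_labels Optional ICN label vector that the header must
#'   match exactly.
#' @return An [icn_timecourses()] object.
#' @export
read_timecourses <- function(path, motion_path = NULL, tr_seconds = 0.745,
                             subject_id = "S01", session_id = "v1",
                             expected_labels = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  nf <- utils::count.fields(path, sep = "\t")
  if (length(unique(nf)) != 1L)
    stop(sprintf("ragged rows in %s: rows have %s fields", path,
                 paste(unique(nf), collapse = "/")))
  header <- strsplit(readLines(path, n = 1L), "\t")[[1L]]
  if (any(!is.na(suppressWarnings(as.numeric(header)))))
    stop(sprintf("missing header of ICN labels in %s", path))
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  m <- suppressWarnings(matrix(as.numeric(as.matrix(raw)), nrow(raw),
                               ncol(raw), dimnames = list(NULL, header)))
  bad <- which(is.na(m), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric or missing cell(s) in %s, first at row %d, column %d (%s)",
                 path, bad[1L, 1L], bad[1L, 2L], header[bad[1L, 2L]]))
  if (!is.null(expected_labels) && !identical(header, expected_labels))
    stop(sprintf("ICN header of %s does not match the expected label table",
                 path))
  motion <- NULL
  if (!is.null(motion_path)) {
    motion <- as.matrix(utils::read.delim(motion_path, header = FALSE))
    if (anyNA(motion)) stop(sprintf("missing values in motion file %s",
                                    motion_path))
  }
  icn_timecourses(m, motion, tr_seconds, subject_id, session_id)
}

#' Write a generated cohort to a directory
#'
#' One time-course file and one motion file per scan, a phenotype CSV, and
#' the ground truth (planted effects, signal, oracle R-squared) as JSON.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(cohort$timecourses))
    write_timecourses(cohort$timecourses[[key]],
                      file.path(dir, paste0(key, ".tsv")))
  write.csv(cohort$phenotype, file.path(dir, "phenotype.csv"),
            row.names = FALSE)
  gt <- cohort$ground_truth
  slim <- list(effect_static = gt$effect_static,
               effect_dynamism = gt$effect_dynamism,
               signal = gt$signal, pct_change = gt$pct_change,
               noise_sd = gt$noise_sd, oracle_r2 = gt$oracle_r2,
               delta_dynamism = gt$delta_dynamism)
  jsonlite::write_json(slim, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

#' Run the full simulation-to-prediction pipeline
#'
#' Chains every stage on a synthetic cohort: generation, per-scan
#' post-processing, static FNC (z-scored, vectorized, v1 - v3 change
#' features), sliding-window dynamic FNC, meta-state dynamism, the
#' static-only and combined PLS prediction runs on identical CV
#' partitions, their comparison, optional confound regression and
#' permutation testing, and the weight-map anatomy. Stage seeds are
#' derived deterministically from the master seed; a manifest of stage
#' parameters and seeds is returned (and written as JSON when
#' `output_dir` is given), so the same configuration and seed reproduce
#' the same summary bit for bit.
#'
#' @param cohort_cfg A [cohort_config()].
#' @param postproc_cfg A [postproc_config()].
#' @param dfnc_cfg A [dfnc_config()].
#' @param k,fuzziness Meta-state pattern settings (see [fit_patterns()]).
#' @param folds,repetitions,n_components,select Prediction harness
#'   settings (see [repeated_cv()]).
#' @param dynamic Run the dynamic branch (dFNC + dynamism)? When `FALSE`,
#'   requesting the combined feature set is an error.
#' @param feature_sets Character subset of `c("static", "combined")`.
#' @param run_deconfound Regress phenotype covariates out of the features
#'   before prediction.
#' @param n_perm Permutations for the significance test of the static
#'   model (0 skips the test).
#' @param perm_repetitions CV repetitions per permutation.
#' @param seed Master seed.
#' @param output_dir Optional directory for the JSON summary and manifest.
#' @return A list with the cohort, feature tables, per-feature-set
#'   [repeated_cv()] results, the static-vs-combined comparison, optional
#'   permutation test, weight summaries, and the manifest.
#' @export
run_pipeline <- function(cohort_cfg = cohort_config(),
                         postproc_cfg = postproc_config(),
                         dfnc_cfg = dfnc_config(),
                         k = 5L, fuzziness = 2,
                         folds = 10L, repetitions = 100L,
                         n_components = 10L, select = "cv",
                         dynamic = TRUE,
                         feature_sets = c("static", "combined"),
                         run_deconfound = FALSE,
                         n_perm = 0L, perm_repetitions = 5L,
                         seed = 1L, output_dir = NULL) {
  feature_sets <- match.arg(feature_sets, several.ok = TRUE)
  if (!dynamic && "combined" %in% feature_sets)
    stop("combined feature set requires the dynamic stage to be enabled")
  seeds <- list(cohort = derive_seed(seed, 0L),
                patterns = derive_seed(seed, 1000L),
                cv = derive_seed(seed, 2000L),
                perm = derive_seed(seed, 3000L))
  cohort_cfg$seed <- seeds$cohort
  manifest <- list(seed = seed, stage_seeds = seeds,
                   cohort = unclass(cohort_cfg)[
                     c("n_subjects", "n_icns", "n_timepoints", "tr_seconds",
                       "n_latent_states", "state_dwell", "noise_sd",
                       "spike_rate")],
                   postproc = unclass(postproc_cfg),
                   dfnc = unclass(dfnc_cfg),
                   prediction = list(folds = folds, repetitions = repetitions,
                                     n_components = n_components,
                                     select = select, k = k,
                                     fuzziness = fuzziness,
                                     deconfound = run_deconfound,
                                     n_perm = n_perm))

  cohort <- generate_cohort(cohort_cfg)
  clean <- lapply(cohort$timecourses, postprocess, config = postproc_cfg)

  feats <- lapply(clean, function(tc)
    vectorize_upper(zscore_fnc(compute_sfnc(tc))))
  subjects <- unique(vapply(cohort$timecourses, `[[`, "", "subject_id"))
  delta_static <- t(vapply(subjects, function(s)
    delta_features(feats[[paste0(s, "_v1")]], feats[[paste0(s, "_v3")]]),
    numeric(length(feats[[1L]]))))
  rownames(delta_static) <- subjects

  ddyn <- NULL
  dyn_out <- NULL
  if (dynamic) {
    wfnc <- lapply(clean, compute_dfnc, config = dfnc_cfg)
    dyn_out <- global_dynamism(wfnc, k = k, fuzziness = fuzziness,
                               seed = seeds$patterns)
    ddyn <- delta_dynamism(dyn_out$dynamism, subjects)
  }

  y <- percentage_change(cohort$phenotype$score_v1,
                         cohort$phenotype$score_v3)

  tables <- list()
  if ("static" %in% feature_sets)
    tables$static <- build_feature_table(delta_static)
  if ("combined" %in% feature_sets)
    tables$combined <- build_feature_table(delta_static, ddyn)
  if (run_deconfound) {
    covars <- cohort$phenotype[, c("age", "sex", "current_mA",
                                   "treatment_number", "pulse_width_ms")]
    tables <- lapply(tables, deconfound, covariates = covars)
  }

  results <- lapply(tables, function(tab)
    repeated_cv(tab, y, folds = folds, repetitions = repetitions,
                n_components = n_components, select = select,
                seed = seeds$cv))

  comparison <- NULL
  if (all(c("static", "combined") %in% names(results)))
    comparison <- compare_models(results$static, results$combined)

  perm <- NULL
  if (n_perm > 0L && "static" %in% names(results))
    perm <- permutation_test(tables$static, y, folds = folds,
                             repetitions = perm_repetitions,
                             n_components = n_components, select = select,
                             n_perm = n_perm, seed = seeds$perm,
                             observed_mean_r =
                               mean(results$static$per_repetition_r))

  weights <- lapply(results, aggregate_weights)
  domain_tab <- icn_domain_table(cohort_cfg$n_icns)
  p_static <- cohort_cfg$n_icns * (cohort_cfg$n_icns - 1L) / 2L
  domains <- lapply(weights, function(w)
    domain_summary(w$mean_weight[seq_len(p_static)], domain_tab))

  summary <- list(
    mean_r = lapply(results, function(r) mean(r$per_repetition_r)),
    sd_r = lapply(results, function(r) sd(r$per_repetition_r)),
    mean_R2 = lapply(results, function(r) mean(r$per_repetition_R2)),
    comparison = comparison[c("t", "p")],
    permutation_p = if (is.null(perm)) NULL else perm$p_value,
    oracle_r2 = cohort$ground_truth$oracle_r2)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$outputs <- c("summary.json", "manifest.json")
  }

  list(cohort = cohort, features = tables, results = results,
       comparison = comparison, permutation = perm, dynamism = dyn_out,
       weights = weights, domain_summaries = domains,
       summary = summary, manifest = manifest)
}
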