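#' Pipeline configuration
#'
#' Collects every stage constant in one place. The statistical defaults are
#' the reference workflow's: 1 mm resampling, 64 grey-level bins, ICC >= 0.80
#' robustness screen, |Spearman| > 0.70 redundancy threshold, 1000 bootstrap
#' resamples at alpha 0.05 with majority selection, backward logistic
#' retention at p < 0.20 capped at three variables, and a stratified
#' training/validation split. The phantom-population and outcome-generator
#' settings define the demo study conditions (see the methods vignette).
#'
#' @param n_patients Cohort size.
#' @param n_icc_cases Subgroup re-contoured by every reader for the
#'   robustness screen.
#' @param n_readers Readers emulated in that subgroup.
#' @param perturb_mm Contour perturbation scale (mm) between readers.
#' @param spacing_mm,n_bins Extraction settings.
#' @param icc_threshold,spearman_threshold,B,alpha,p_retain,max_vars
#'   Selection/model constants.
#' @param train_fraction Fraction assigned to the training cohort
#'   (stratified by outcome).
#' @param radius_range,lobulation_range,noise_sd_range,core_fraction Phantom
#'   population settings (mm, fraction, intensity units, fraction).
#' @param true_coefficients,target_rate,necrosis_prevalence,censoring_rate
#'   Outcome generator settings; the surface-to-volume coefficient is set so
#'   the planted radiomic effect is about 1.5 log-odds per population SD.
#' @param seed Master seed; each stage derives its own child seed.
#' @return An `edr_config` list.
#' @export
edr_config <- function(n_patients = 60,
                       n_icc_cases = 10,
                       n_readers = 3,
                       perturb_mm = 0.5,
                       spacing_mm = 1.0,
                       n_bins = 64,
                       icc_threshold = 0.80,
                       spearman_threshold = 0.70,
                       B = 1000,
                       alpha = 0.05,
                       p_retain = 0.20,
                       max_vars = 3,
                       train_fraction = 0.64,
                       radius_range = c(6, 13),
                       lobulation_range = c(0, 0.35),
                       noise_sd_range = c(2, 7),
                       core_fraction = 0.2,
                       true_coefficients = c(ca199_u_ml = 0.000964,
                                             necrosis = 0.86465,
                                             morph.surf_to_vol_ratio = -18),
                       target_rate = 0.265,
                       necrosis_prevalence = 0.18,
                       censoring_rate = 0.15,
                       seed = 1L) {
  structure(as.list(environment()), class = "edr_config")
}

# one phantom per patient: lobulated spheres with varying size/irregularity
# and per-case noise level (between-patient texture heterogeneity), necrotic
# core present for the "necrosis" subgroup
generate_phantom_population <- function(config) {
  set.seed(child_seed(config$seed, "population"))
  n <- config$n_patients
  radius <- runif(n, config$radius_range[1], config$radius_range[2])
  lob <- runif(n, config$lobulation_range[1], config$lobulation_range[2])
  noise <- runif(n, config$noise_sd_range[1], config$noise_sd_range[2])
  necrosis <- rbinom(n, 1, config$necrosis_prevalence)
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- phantom_spec(shape_kind = "lobulated", radius_mm = radius[i],
                       lobulation_amplitude = lob[i],
                       necrotic_core = necrosis[i] == 1,
                       core_fraction = config$core_fraction,
                       voxel_spacing_mm = config$spacing_mm,
                       noise_sd = noise[i],
                       seed = child_seed(config$seed, "phantom", i))
    cases[[i]] <- make_phantom(sp)
  }
  names(cases) <- sprintf("pt%03d", seq_len(n))
  list(cases = cases,
       clinical = tibble(patient_id = names(cases), necrosis = necrosis))
}

# robustness screen on a re-contoured subgroup
pipeline_icc_stage <- function(cases, config) {
  sub <- cases[seq_len(min(config$n_icc_cases, length(cases)))]
  rows <- purrr::imap(sub, function(cs, id) {
    variants <- make_reader_variants(cs$mask, n_readers = config$n_readers,
                                     perturb_mm = config$perturb_mm,
                                     seed = child_seed(config$seed, "readers",
                                                       match(id, names(sub))))
    purrr::imap(variants, function(v, r) {
      extract_all(cs$volume, v, spacing_mm = config$spacing_mm,
                  n_bins = config$n_bins, id = id) |>
        dplyr::mutate(.reader = paste0("reader", r), .case = id,
                      .before = 1) |>
        dplyr::select(-"case")
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  icc_screen(rows, threshold = config$icc_threshold)
}

# selection + model building; sees the training cohort only
pipeline_fit <- function(train, radiomic_candidates, config) {
  cand_all <- c(radiomic_candidates, "ca199_u_ml", "necrosis")
  red <- redundancy_filter(train[cand_all], train$edr,
                           threshold = config$spearman_threshold)
  reps <- red$feature[red$selected]
  rank <- bootstrap_rank(train, outcome = "edr", candidates = reps,
                         B = config$B, alpha = config$alpha,
                         seed = child_seed(config$seed, "bootstrap"))
  sel <- rank$variable[rank$selected]
  if (length(sel) == 0) sel <- head(rank$variable, config$max_vars)
  model <- fit_backward_logistic(train, outcome = "edr", candidates = sel,
                                 p_retain = config$p_retain,
                                 max_vars = config$max_vars)
  model <- calibrate_cutoff(model, train, outcome = "edr")
  list(redundancy = red, ranking = rank, model = model)
}

pipeline_evaluate <- function(model, cohort) {
  risk <- classify_risk(model, cohort)
  data <- dplyr::bind_cols(cohort, risk)
  res <- list(auc = auc_mw(risk$p_index, cohort$edr))
  if (length(unique(risk$risk_group)) == 2 && sum(data$event) > 0) {
    res$stratification <- evaluate_stratification(data)
  }
  res$data <- data
  res
}

#' Run the full pipeline on a simulated study
#'
#' Generates the phantom population, extracts the radiomic feature table,
#' screens features for delineation robustness on a re-contoured subgroup,
#' simulates the clinical outcome, splits the cohort into training and
#' validation strata, runs the selection cascade and model fit on the
#' training cohort only, freezes the model and its Youden cutoff, and
#' evaluates discrimination and risk stratification on both cohorts. The
#' validation cohort is never visible to any selection or fitting step.
#'
#' @param config An [edr_config()].
#' @param out_dir Optional directory for run artifacts (feature table,
#'   cohort, model JSON, metrics JSON, run log).
#' @return A list with `features`, `icc`, `cohort`, `split`, `selection`,
#'   `model`, `train_eval`, `valid_eval`, `config`.
#' @export
run_pipeline <- function(config = edr_config(), out_dir = NULL) {
  stopifnot(inherits(config, "edr_config"))
  log_lines <- character(0)
  logf <- function(stage, ...) {
    msg <- jsonlite::toJSON(list(stage = stage, ...), auto_unbox = TRUE)
    log_lines <<- c(log_lines, as.character(msg))
  }
  logf("config", config = config[setdiff(names(config), "true_coefficients")],
       true_coefficients = as.list(config$true_coefficients))

  pop <- generate_phantom_population(config)
  features <- extract_cohort(pop$cases, spacing_mm = config$spacing_mm,
                             n_bins = config$n_bins)
  logf("extract", n_cases = nrow(features), n_features = ncol(features) - 1)

  icc <- pipeline_icc_stage(pop$cases, config)
  robust <- icc$feature[icc$pass]
  logf("icc", n_pass = length(robust), n_total = nrow(icc))

  fv <- features |>
    dplyr::rename(patient_id = "case") |>
    dplyr::left_join(pop$clinical, by = "patient_id")
  sim_spec <- cohort_sim_spec(
    n_patients = config$n_patients,
    true_coefficients = config$true_coefficients,
    target_rate = config$target_rate,
    necrosis_prevalence = config$necrosis_prevalence,
    censoring_rate = config$censoring_rate,
    seed = child_seed(config$seed, "outcome"))
  cohort <- simulate_cohort(sim_spec, feature_values = fv) |>
    dplyr::select(-"patient_id") |>
    dplyr::bind_cols(fv[setdiff(names(fv), c(names(config$true_coefficients),
                                             "ca199_u_ml", "necrosis"))]) |>
    dplyr::relocate("patient_id")
  logf("cohort", n = nrow(cohort), edr_rate = mean(cohort$edr))

  split <- stratified_split(cohort$edr, config$train_fraction,
                            seed = child_seed(config$seed, "split"))
  train <- cohort[split == "train", ]
  valid <- cohort[split == "valid", ]
  logf("split", n_train = nrow(train), n_valid = nrow(valid),
       edr_train = mean(train$edr), edr_valid = mean(valid$edr))

  selection <- pipeline_fit(train, robust, config)
  model <- selection$model
  logf("model", variables = model$variables, cutoff = model$cutoff,
       training_auc = model$training_auc)

  train_eval <- pipeline_evaluate(model, train)
  valid_eval <- pipeline_evaluate(model, valid)
  logf("evaluate", train_auc = train_eval$auc, valid_auc = valid_eval$auc)

  out <- list(features = features, icc = icc, cohort = cohort, split = split,
              selection = selection[c("redundancy", "ranking")],
              model = model, train_eval = train_eval,
              valid_eval = valid_eval, config = config, log = log_lines)
  if (!is.null(out_dir)) write_run_dir(out, out_dir)
  out
}

#' Stratified training/validation split
#'
#' @param outcome Binary outcome vector.
#' @param train_fraction Fraction per stratum assigned to training.
#' @param seed Integer seed.
#' @return Character vector `"train"`/`"valid"` per subject.
#' @export
stratified_split <- function(outcome, train_fraction = 0.64, seed = 1L) {
  set.seed(as.integer(seed))
  split <- rep("valid", length(outcome))
  for (cls in unique(outcome)) {
    idx <- which(outcome == cls)
    n_tr <- round(length(idx) * train_fraction)
    split[sample(idx, n_tr)] <- "train"
  }
  split
}

write_run_dir <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(res$features, file.path(out_dir, "features.csv"),
            row.names = FALSE)
  write.csv(res$cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  m <- res$model
  jsonlite::write_json(
    list(variables = m$variables, intercept = m$intercept,
         coefficients = as.list(m$coefficients), cutoff = m$cutoff,
         training_auc = m$training_auc, overall_fit_p = m$overall_fit_p,
         n = m$n, method = m$method),
    file.path(out_dir, "model.json"), auto_unbox = TRUE, digits = NA)
  metrics <- list(train_auc = res$train_eval$auc,
                  valid_auc = res$valid_eval$auc)
  for (side in c("train_eval", "valid_eval")) {
    st <- res[[side]]$stratification
    if (!is.null(st)) {
      metrics[[paste0(sub("_eval", "", side), "_hr")]] <- st$hazard_ratio$hr
      metrics[[paste0(sub("_eval", "", side), "_logrank_p")]] <-
        st$log_rank$p_value
    }
  }
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(res$log, file.path(out_dir, "run_log.jsonl"))
  invisible(out_dir)
}

#' Write a small demo bundle (phantom NIfTI pairs plus a cohort CSV)
#'
#' @param seed Integer seed.
#' @param dir Output directory.
#' @param n_cases Number of phantom pairs to write.
#' @return Invisibly, the paths written.
#' @export
make_demo_fixtures <- function(seed = 1L, dir = tempfile("edrisk_demo"),
                               n_cases = 3) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (i in seq_len(n_cases)) {
    ph <- make_phantom(phantom_spec(
      shape_kind = "lobulated", radius_mm = 6 + 2 * i,
      lobulation_amplitude = 0.1 * (i - 1), necrotic_core = i %% 2 == 0,
      noise_sd = 4, seed = child_seed(seed, "demo", i)))
    vp <- file.path(dir, sprintf("case%02d_volume.nii.gz", i))
    mp <- file.path(dir, sprintf("case%02d_mask.nii.gz", i))
    write_pair(ph$volume, ph$mask, vp, mp)
    paths <- c(paths, vp, mp)
  }
  spec <- cohort_sim_spec(n_patients = 20, seed = child_seed(seed, "demo_cohort"),
                          true_coefficients = c(ca199_u_ml = 0.000964,
                                                necrosis = 0.86465))
  cohort <- simulate_cohort(spec)
  cp <- file.path(dir, "cohort.csv")
  write.csv(cohort[c("patient_id", "ca199_u_ml", "necrosis", "edr",
                     "time_months", "event")], cp, row.names = FALSE)
  invisible(c(paths, cp))
}
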