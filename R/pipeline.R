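# Configuration-driven orchestration of the full study replica:
# simulate -> hierarchy -> train -> stratified associations -> heatmaps ->
# prediction. Every stage draws its seed deterministically from the root
# seed and the stage name, so stages are independently reproducible.

#' Default run configuration
#'
#' A nested list (serialisable as YAML) describing one full run. All seeds
#' derive from `seed`; any field can be overridden.
#'
#' @param n subjects at age 9.
#' @param n_vertices template vertex count.
#' @param latent_dim number of latent traits.
#' @param epochs training epochs.
#' @param seed root seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n = 400, n_vertices = 1024, latent_dim = 32,
                       epochs = 30, seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    cohort = list(n_subjects = n, n_vertices = n_vertices, regions = "nose_tip",
                  slope = 1.0, attenuation_13y = 0.3, growth_mm = 4,
                  noise_sd_mm = 0.25, n_modes = 24),
    encoder = list(latent_dim = latent_dim, epochs = epochs,
                   batch_size = 16, lr = 5e-3, lr_decay = 0.98, K = 6),
    strata = list(list(tier = "2b", level_band = ">0",
                       ethnicity = "multi-ethnic", age_group = "9y")),
    prediction = list(tier = "2b", min_level = 2, ethnicity = "dutch",
                      k = 5)),
    class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the [run_config()] fields.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- run_config()
  user <- yaml::read_yaml(path)
  modify <- function(base, new) {
    for (nm in names(new)) {
      base[[nm]] <- if (is.list(new[[nm]]) && is.list(base[[nm]]) &&
                          !is.null(names(new[[nm]])))
        modify(base[[nm]], new[[nm]]) else new[[nm]]
    }
    base
  }
  structure(modify(unclass(cfg), user), class = "run_config")
}

#' Deterministic per-stage seed
#'
#' @param root root seed.
#' @param stage stage name.
#' @return Integer seed below 2^31.
#' @export
stage_seed <- function(root, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(root) * 7919 + h) %% 2147483647)
}

#' Run the full analysis pipeline
#'
#' Executes simulate, hierarchy, train, associate, heatmap and predict in
#' dependency order and writes stage outputs plus a manifest (file, md5,
#' stage) under `out_dir`. Identical configurations and seeds reproduce
#' identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @param skip_prediction omit the prediction stage?
#' @param verbose print stage progress?
#' @return A list with the cohort, model, association tables, heatmaps,
#'   prediction report and the manifest tibble.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("run"),
                         skip_prediction = FALSE, verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  t0 <- Sys.time()
  say("stage: simulate")
  cc <- config$cohort
  cohort <- simulate_cohort(
    n = cc$n_subjects, n_vertices = cc$n_vertices, regions = cc$regions,
    slope = cc$slope, attenuation_13y = cc$attenuation_13y,
    growth_mm = cc$growth_mm, noise_sd_mm = cc$noise_sd_mm,
    n_modes = cc$n_modes, seed = stage_seed(config$seed, "simulate"))
  utils::write.csv(cohort$covariates, file.path(out_dir, "covariates.csv"),
                   row.names = FALSE)

  say("stage: hierarchy")
  hier <- build_hierarchy(cohort$faces_9y$template)

  say("stage: train")
  ec <- config$encoder
  model <- train_face_model(
    cohort$faces_9y,
    encoder_config(latent_dim = ec$latent_dim, epochs = ec$epochs,
                   batch_size = ec$batch_size, lr = ec$lr,
                   lr_decay = ec$lr_decay, K = ec$K,
                   seed = stage_seed(config$seed, "train")),
    hierarchy = hier)

  say("stage: associate")
  assoc <- lapply(config$strata, function(s) {
    spec <- stratum_spec(tier = s$tier, level_band = s$level_band,
                         ethnicity = s$ethnicity, age_group = s$age_group)
    a <- run_stratified_analysis(cohort, model, spec)
    nm <- sprintf("assoc_tier%s_%s_%s.tsv", s$tier, s$ethnicity, s$age_group)
    write_assoc_tsv(a, file.path(out_dir, nm))
    a
  })

  say("stage: heatmap")
  heatmaps <- lapply(seq_along(assoc), function(i) {
    hm <- assoc_heatmap(model, assoc[[i]], use = "fdr")
    if (is.null(hm)) hm <- assoc_heatmap(model, assoc[[i]], use = "nominal")
    if (!is.null(hm))
      export_heatmap(model$template, hm$scalar,
                     file.path(out_dir, sprintf("heatmap_%d.ply", i)))
    hm
  })

  prediction <- NULL
  if (!skip_prediction) {
    say("stage: predict")
    pc <- config$prediction
    spec <- stratum_spec(tier = pc$tier,
                         level_band = paste0(">", pc$min_level - 1),
                         ethnicity = pc$ethnicity, age_group = "9y")
    grp <- stratum_groups(cohort$covariates, spec)
    ids <- c(grp$control, grp$exposed)
    Z <- encode_faces(model, cohort$faces_9y)[ids, , drop = FALSE]
    cov <- cohort$covariates[match(ids, cohort$covariates$subject_id), ]
    prediction <- compare_models(cov, Z, ids %in% grp$exposed, k = pc$k,
                                 seed = stage_seed(config$seed, "predict"))
    write_prediction_report(prediction, file.path(out_dir, "prediction"))
  }

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- tibble::tibble(
    file = sub(paste0("^", out_dir, "/?"), "", files),
    md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  say(sprintf("done in %.1f s", as.numeric(Sys.time() - t0, units = "secs")))
  list(cohort = cohort, hierarchy = hier, model = model,
       associations = assoc, heatmaps = heatmaps, prediction = prediction,
       manifest = manifest, out_dir = out_dir)
}

#' Replicability of the pipeline across independent trainings
#'
#' Trains `n_runs` auto-encoders with distinct seeds on the same simulated
#' cohort, runs the same stratified association for each, builds each run's
#' combined significant-trait heatmap, and reports the pairwise Pearson
#' correlations of the per-vertex heatmap scalars plus the significant-trait
#' count per run.
#'
#' @param config a [run_config()].
#' @param n_runs number of independent trainings (>= 2).
#' @param use `"fdr"` or `"nominal"` trait selection for the heatmaps.
#' @return List with `correlations` (tibble of run pairs), `n_significant`
#'   per run, and the per-run heatmap scalars.
#' @export
replicate_trainings <- function(config = run_config(), n_runs = 3L,
                                use = "fdr") {
  stopifnot(n_runs >= 2)
  cc <- config$cohort
  cohort <- simulate_cohort(
    n = cc$n_subjects, n_vertices = cc$n_vertices, regions = cc$regions,
    slope = cc$slope, attenuation_13y = cc$attenuation_13y,
    growth_mm = cc$growth_mm, noise_sd_mm = cc$noise_sd_mm,
    n_modes = cc$n_modes, seed = stage_seed(config$seed, "simulate"))
  hier <- build_hierarchy(cohort$faces_9y$template)
  s <- config$strata[[1]]
  spec <- stratum_spec(tier = s$tier, level_band = s$level_band,
                       ethnicity = s$ethnicity, age_group = s$age_group)
  ec <- config$encoder
  runs <- lapply(seq_len(n_runs), function(r) {
    model <- train_face_model(
      cohort$faces_9y,
      encoder_config(latent_dim = ec$latent_dim, epochs = ec$epochs,
                     batch_size = ec$batch_size, lr = ec$lr,
                     lr_decay = ec$lr_decay, K = ec$K,
                     seed = stage_seed(config$seed, paste0("train", r))),
      hierarchy = hier)
    assoc <- run_stratified_analysis(cohort, model, spec)
    hm <- assoc_heatmap(model, assoc, use = use)
    list(n_significant = sum(assoc$significant),
         scalar = if (is.null(hm)) rep(0, nrow(cohort$faces_9y$template$vertices))
                  else hm$scalar)
  })
  pairs <- utils::combn(n_runs, 2)
  correlations <- tibble::tibble(
    run_a = pairs[1, ], run_b = pairs[2, ],
    correlation = apply(pairs, 2, function(pr)
      cor(runs[[pr[1]]]$scalar, runs[[pr[2]]]$scalar)))
  list(correlations = correlations,
       n_significant = vapply(runs, `[[`, 1, "n_significant"),
       scalars = lapply(runs, `[[`, "scalar"))
}
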