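#' Default pipeline configuration
#'
#' Assembles the whole-pipeline configuration: simulation settings (used by
#' [run_simulate()]), quality thresholds and model options. Serialized
#' verbatim (YAML) into every output directory, and hashed so each output
#' file can carry the configuration it came from.
#'
#' @param seed master seed.
#' @param ... overrides for any top-level field.
#' @return A list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    simulate = list(n_farms = 4L, n_mobs = 8L, cows_per_mob = 12L,
                    days = 10L, fix_interval = 300L, dropout_rate = 0.05,
                    outlier_rate = 0,
                    terrain = list(n = 96L, cellsize = 16, relief = 180,
                                   smoothness = 8)),
    thresholds = list(fix_interval = 300L, min_rate = 0.75,
                      min_days = 7L, max_days = 28L, slope_gate_deg = 8,
                      rare_genotype = 0.05,
                      speed_max = 2.5, spike_speed = 1.5,
                      turn_min_deg = 150, tz = "UTC"),
    model = list(glmm_mode = "binomial", alpha = 0.05,
                 select_random = TRUE))
  over <- list(...)
  cfg[names(over)] <- over
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  th <- cfg$thresholds
  if (th$min_rate <= 0 || th$min_rate > 1)
    stop("thresholds$min_rate must be in (0, 1]", call. = FALSE)
  if (th$min_days < 1 || th$max_days < th$min_days)
    stop("thresholds$min_days/max_days out of range", call. = FALSE)
  if (th$slope_gate_deg < 0 || th$slope_gate_deg >= 90)
    stop("thresholds$slope_gate_deg out of range", call. = FALSE)
  if (th$rare_genotype < 0 || th$rare_genotype >= 1)
    stop("thresholds$rare_genotype out of range", call. = FALSE)
  if (any(c(th$speed_max, th$spike_speed) <= 0))
    stop("outlier speed thresholds must be positive", call. = FALSE)
  if (!cfg$model$glmm_mode %in% c("binomial", "logit-lmm"))
    stop("model$glmm_mode must be 'binomial' or 'logit-lmm'", call. = FALSE)
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config()`: a validated `pipeline_config`;
#'   `write_config()`: `path`, invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config(seed = cfg$seed %||% 1L)
  for (k in intersect(names(cfg), c("simulate", "thresholds", "model")))
    base[[k]] <- utils::modifyList(base[[k]], as.list(cfg[[k]]))
  validate_config(base)
  class(base) <- "pipeline_config"
  base
}

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  rlang::hash(unclass(config))
}

write_stage_csv <- function(df, path, hash) {
  writeLines(sprintf("# grazemix config_hash=%s", hash), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

read_stage_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Simulate a herd and write the raw inputs
#'
#' Generates terrain, herd metadata, genotypes and GPS trajectories and
#' writes `fixes.csv`, `dem.asc`, `metadata.csv`, `ground_truth.csv` and
#' `config.yaml` into `outdir`.
#'
#' @param config a `pipeline_config`.
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with the simulated objects and file paths.
#' @export
run_simulate <- function(config, outdir) {
  validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  s <- config$simulate
  scfg <- sim_config(seed = config$seed, n_farms = s$n_farms,
                     n_mobs = s$n_mobs, cows_per_mob = s$cows_per_mob,
                     days = s$days, fix_interval = s$fix_interval,
                     dropout_rate = s$dropout_rate,
                     outlier_rate = s$outlier_rate %||% 0,
                     terrain = s$terrain)
  dem <- generate_dem(scfg)
  metadata <- simulate_herd(scfg)
  fixes <- simulate_trajectories(metadata, dem, scfg)
  gt <- sim_ground_truth(fixes)
  paths <- list(fixes = file.path(outdir, "fixes.csv"),
                dem = file.path(outdir, "dem.asc"),
                metadata = file.path(outdir, "metadata.csv"),
                ground_truth = file.path(outdir, "ground_truth.csv"),
                config = file.path(outdir, "config.yaml"))
  write_fixes(fixes, paths$fixes, config_hash = hash)
  write_dem(dem, paths$dem)
  write_stage_csv(metadata, paths$metadata, hash)
  write_stage_csv(gt, paths$ground_truth, hash)
  write_config(config, paths$config)
  invisible(list(dem = dem, metadata = metadata, fixes = fixes,
                 ground_truth = gt, paths = paths, hash = hash))
}

#' Compute daily behaviours and per-cow profiles from raw inputs
#'
#' Reads fixes, DEM and metadata from `indir` (as written by
#' [run_simulate()] or assembled by hand), cleans trajectories, annotates
#' terrain, computes the eleven daily behaviours, applies the day-rate,
#' terrain-window and minimum-days filters, and writes `daily.csv`,
#' `profiles.csv` and a `qc.yaml` filter log into `outdir`.
#'
#' @param config a `pipeline_config`.
#' @param indir directory holding `fixes.csv`, `dem.asc`, `metadata.csv`.
#' @param outdir output directory (default `indir`).
#' @return Invisibly, a list with `daily`, `retained`, `profiles`, `qc`.
#' @export
run_metrics <- function(config, indir, outdir = indir) {
  validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  hash <- config_hash(config)
  fixes <- read_fixes(file.path(indir, "fixes.csv"))
  dem <- read_dem(file.path(indir, "dem.asc"))
  metadata <- read_stage_csv(file.path(indir, "metadata.csv"))

  traj <- build_trajectory(fixes, gap_tolerance = 2 * th$fix_interval)
  flags <- detect_outliers(traj, speed_max = th$speed_max,
                           spike_speed = th$spike_speed,
                           turn_min_deg = th$turn_min_deg)
  traj <- remove_and_rebuild(traj, flags)
  ann <- annotate_fixes(traj, dem)
  daily <- daily_behaviours(ann, metadata, tz = th$tz)
  daily <- filter_days(daily, fix_interval = th$fix_interval,
                       min_rate = th$min_rate)
  retained <- select_window(daily, min_days = th$min_days,
                            max_days = th$max_days,
                            slope_gate_deg = th$slope_gate_deg)
  profiles <- aggregate_profiles(retained, metadata)
  qc <- list(config_hash = hash,
             n_fixes_read = nrow(fixes),
             n_outlier_fixes_removed = sum(flags),
             day_filter = attr(daily, "day_filter"),
             selection = attr(retained, "selection"),
             n_cow_days_retained = nrow(retained),
             n_cows_profiled = nrow(profiles))
  write_stage_csv(daily, file.path(outdir, "daily.csv"), hash)
  write_stage_csv(profiles, file.path(outdir, "profiles.csv"), hash)
  yaml::write_yaml(qc, file.path(outdir, "qc.yaml"))
  invisible(list(daily = daily, retained = retained, profiles = profiles,
                 qc = qc))
}

#' Run correlations and the association suite on computed behaviours
#'
#' Reads `daily.csv`, `profiles.csv` and `metadata.csv`, computes the
#' behaviour correlation matrix and the full variant/genotype mixed-model
#' suite, and writes `correlations.csv`, `models.json`, `posthoc.csv` and
#' a human-readable `report.md`.
#'
#' @param config a `pipeline_config`.
#' @param indir directory with the metrics outputs.
#' @param outdir output directory (default `indir`).
#' @return Invisibly, a list with `correlations` and `association`.
#' @export
run_associate <- function(config, indir, outdir = indir) {
  validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  daily <- read_stage_csv(file.path(indir, "daily.csv"))
  profiles <- read_stage_csv(file.path(indir, "profiles.csv"))
  metadata <- read_stage_csv(file.path(indir, "metadata.csv"))
  if (dplyr::n_distinct(metadata$genotype) < 2)
    stop("fewer than 2 genotype groups in metadata", call. = FALSE)

  corr <- correlation_matrix(profiles)
  retained <- dplyr::filter(daily, .data$valid)
  assoc <- run_association_suite(
    retained, metadata, glmm_mode = config$model$glmm_mode,
    alpha = config$model$alpha,
    random_structure = if (isTRUE(config$model$select_random)) NULL
    else c("cow_id", "mob"),
    rare_threshold = config$thresholds$rare_genotype)

  write_stage_csv(corr, file.path(outdir, "correlations.csv"), hash)
  models <- list(config_hash = hash,
                 n_cows = assoc$n_cows,
                 rare_genotypes = assoc$rare_genotypes,
                 random = assoc$random,
                 variants = assoc$variants,
                 genotype = assoc$genotype)
  jsonlite::write_json(models, file.path(outdir, "models.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  ph <- purrr::imap_dfr(assoc$posthoc, function(p, b)
    dplyr::mutate(p$letters, behaviour = b, .before = 1))
  if (nrow(ph) == 0)
    ph <- tibble::tibble(behaviour = character(), group = character(),
                         letters = character())
  write_stage_csv(ph, file.path(outdir, "posthoc.csv"), hash)
  writeLines(association_report(assoc, corr, hash),
             file.path(outdir, "report.md"))
  invisible(list(correlations = corr, association = assoc))
}

#' Run the whole pipeline (simulate, metrics, associate)
#'
#' @param config a `pipeline_config`.
#' @param outdir output directory.
#' @return Invisibly, the list returned by [run_associate()] plus the
#'   earlier stage results.
#' @export
run_pipeline <- function(config, outdir) {
  sim <- run_simulate(config, outdir)
  met <- run_metrics(config, outdir)
  ass <- run_associate(config, outdir)
  invisible(c(sim[c("metadata", "ground_truth")], met, ass))
}

association_report <- function(assoc, corr, hash) {
  fmt_p <- function(p) ifelse(is.na(p), "-", sprintf("%.3f", p))
  lines <- c(
    "# Grazing-personality association report", "",
    sprintf("config hash: `%s`", hash),
    sprintf("cows analysed: %d (rare genotypes excluded: %s)",
            assoc$n_cows,
            if (length(assoc$rare_genotypes)) paste(assoc$rare_genotypes,
                                                    collapse = ", ")
            else "none"),
    sprintf("bounded-response mode: %s", assoc$glmm_mode), "",
    "P-values are reported per behaviour; no adjustment is applied",
    "across the eleven behaviours.", "",
    "## Behaviour correlations (Pearson, pairwise complete)", "",
    "| behaviour 1 | behaviour 2 | r | p | n |", "|---|---|---|---|---|",
    sprintf("| %s | %s | %.2f%s | %.3g | %d |",
            corr$behaviour1, corr$behaviour2, corr$r, corr$stars, corr$p,
            corr$n), "",
    "## Variant presence/absence (dominance) models", "",
    "| behaviour | variant | marginal mean (SE) | P | age-class P | random |",
    "|---|---|---|---|---|---|")
  va <- dplyr::left_join(assoc$variants, assoc$random, by = "behaviour")
  lines <- c(lines, sprintf(
    "| %s | %s | %.3g (+-%.2g) | %s | %s | %s |",
    va$behaviour, va$variant, va$mm_present, va$mm_se,
    fmt_p(va$p_value), fmt_p(va$age_p), va$random_label))
  lines <- c(lines, "", "## Genotype models", "",
             "| behaviour | P | age-class retained | residuals pass |",
             "|---|---|---|---|",
             sprintf("| %s | %s | %s | %s |", assoc$genotype$behaviour,
                     fmt_p(assoc$genotype$p_value),
                     assoc$genotype$age_included,
                     assoc$genotype$resid_pass))
  if (length(assoc$posthoc) > 0) {
    lines <- c(lines, "", "## Post-hoc letters (BH-adjusted)")
    for (b in names(assoc$posthoc)) {
      lt <- assoc$posthoc[[b]]$letters
      lines <- c(lines, "", sprintf("### %s", b),
                 "| group | letters |", "|---|---|",
                 sprintf("| %s | %s |", lt$group, lt$letters))
    }
  }
  lines
}
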