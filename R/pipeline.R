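#' Default pipeline configuration
#'
#' A complete run configuration for the synthetic study: a training
#' world of 15 cities (about 18 samples each), 8 mystery cities, species
#' rank, CSS at the 50th percentile with the 100-read / more-than-one
#' -sample filter, the multi-task Lasso regression and the weighted
#' multinomial classifier evaluated under nested 10-fold and
#' leave-one-city-out CV, and the ambiguity-based novelty detector.
#' Override any entry by passing a partial list to [run_pipeline()].
#'
#' @return nested list of configuration defaults.
#' @export
default_config <- function() {
  list(
    simulation = list(
      n_train_cities = 15, n_mystery_cities = 8, samples_per_city = 18,
      n_species = 200, n_genera = 60, n_families = 25,
      n_informative = 10, lat_slope = 0.05, long_slope = 0.02,
      city_effect_sd = 1, zero_inflation_prob = 0.05,
      library_size_range = c(5e4, 2e5), batch_shift = 6),
    input = NULL,                 # list(counts =, metadata =) instead
    rank = "species",
    normalization = list(css_percentile = 0.5, scale_constant = 1000,
                         min_reads = 100, min_samples_exceed = 1),
    models = c("regression", "classification"),
    n_outer = 10, n_inner = 10,
    include_batch_city = FALSE,
    seed = 1,
    outdir = NULL)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null"), f)
  unname(tools::md5sum(f))
}

#' Run the full source-attribution pipeline
#'
#' Orchestrates simulate (or load) -> filter -> CSS-normalize -> fit and
#' cross-validate the origin models -> score mystery samples -> build
#' the ambiguity dataset and novelty detector -> flag mystery samples,
#' and writes metrics JSON, prediction/ambiguity CSVs and a markdown
#' report to `outdir` (when set). Identical config and seed give
#' byte-identical metrics output.
#'
#' @param config partial configuration list (merged over
#'   [default_config()]) or the path to a YAML file of one. Exactly one
#'   of `simulation` and `input` must be active; set
#'   `simulation = NULL` and `input = list(counts =, metadata =)` to run
#'   on files (wide-TSV counts, CSV metadata; no mystery stage).
#' @param seed overrides `config$seed` when given.
#' @param outdir overrides `config$outdir`; `NULL` writes nothing.
#' @return list of class `pipeline_run`: config (with hash and seed),
#'   evaluation results per model and CV design, mystery scores,
#'   ambiguity records, novelty LOO evaluation and mystery flags.
#' @export
run_pipeline <- function(config = list(), seed = NULL, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (is.null(cfg$simulation) == is.null(cfg$input))
    stop("exactly one of `simulation` and `input` must be set")
  if (!is.null(cfg$input)) {
    for (p in unlist(cfg$input))
      if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  # the hash identifies the scientific configuration, not where the
  # artifacts land
  cfg$hash <- config_hash(cfg[setdiff(names(cfg), c("hash", "outdir"))])
  seed <- cfg$seed

  # ---- data ----
  if (!is.null(cfg$simulation)) {
    sim <- cfg$simulation
    batchy <- isTRUE(cfg$include_batch_city)
    world <- generate_world(sim$n_train_cities, sim$n_mystery_cities,
                            sim$samples_per_city, seed = seed,
                            n_single_end = as.integer(batchy),
                            n_single_end_mystery = as.integer(
                              batchy && sim$n_mystery_cities > 0))
    truth <- synthetic_truth(
      n_species = sim$n_species, n_genera = sim$n_genera,
      n_families = sim$n_families, n_informative = sim$n_informative,
      lat_slope = sim$lat_slope, long_slope = sim$long_slope,
      city_effect_sd = sim$city_effect_sd,
      zero_inflation_prob = sim$zero_inflation_prob,
      library_size_range = sim$library_size_range,
      batch_shift = sim$batch_shift, seed = seed + 1)
    train_data <- if (batchy) generate_batch_city(world$train, truth)
                  else generate_counts(world$train, truth)
    table <- train_data[[cfg$rank]]
    metadata <- train_data$metadata
    mystery <- if (nrow(world$mystery)) {
      md <- if (batchy) generate_batch_city(world$mystery, truth)
            else generate_counts(world$mystery, truth)
      list(table = md[[cfg$rank]], metadata = md$metadata)
    }
  } else {
    table <- load_abundance(cfg$input$counts, format = "wide_tsv")
    metadata <- read_metadata(cfg$input$metadata)
    mystery <- NULL
    truth <- NULL
  }

  # ---- filter + normalize (taxa chosen on training data only) ----
  np <- cfg$normalization
  params <- css_params(np$css_percentile, np$scale_constant,
                       np$min_reads, np$min_samples_exceed)
  table <- filter_taxa(table, np$min_reads, np$min_samples_exceed)
  norm <- css_normalize(table, params)
  if (!is.null(mystery)) {
    keep <- intersect(colnames(table$counts),
                      colnames(mystery$table$counts))
    myst_tab <- taxa_count_table(
      mystery$table$counts[, keep, drop = FALSE],
      mystery$table$taxonomy[
        match(keep, mystery$table$taxonomy$taxon_id), , drop = FALSE],
      rank = mystery$table$rank)
    myst_norm <- css_normalize(myst_tab, params)
  }

  # ---- cross-validated evaluation ----
  evaluations <- list()
  for (m in cfg$models) {
    evaluations[[m]] <- list(
      nested = nested_cv(norm, metadata, model = m,
                         n_outer = cfg$n_outer, n_inner = cfg$n_inner,
                         seed = seed),
      l1co = l1co_cv(norm, metadata, model = m,
                     n_inner = cfg$n_inner, seed = seed))
  }

  # ---- final models + mystery predictions ----
  fm_all <- suppressWarnings(make_features(norm))
  panel <- city_panel_from_metadata(metadata)
  mystery_scores <- NULL
  mystery_preds <- list()
  final_models <- list()
  for (m in cfg$models) {
    final_models[[m]] <- fit_origin_model(
      m, fm_all, metadata, cfg$n_inner, seed = seed)
    if (!is.null(mystery)) {
      fm_my <- make_features(myst_norm, scaler = fm_all$scaler)
      p <- predict_origin(final_models[[m]], fm_my,
                          city_panel = if (m == "regression") NULL
                                       else panel)
      mystery_preds[[m]] <- p
      mystery_scores[[m]] <- score_predictions(p, mystery$metadata)
    }
  }

  # ---- novelty detection ----
  novelty <- NULL
  if ("classification" %in% cfg$models) {
    records <- build_ambiguity_dataset(norm, metadata, seed = seed,
                                       n_outer = cfg$n_outer,
                                       n_inner = cfg$n_inner)
    nov_model <- fit_kde_bayes(records)
    loo <- evaluate_novelty_loo(records)
    flags <- NULL
    if (!is.null(mystery)) {
      fm_my <- make_features(myst_norm, scaler = fm_all$scaler)
      flags <- flag_new_origin(nov_model, final_models$classification,
                               fm_my)
    }
    novelty <- list(records = records, model = nov_model, loo = loo,
                    mystery_flags = flags)
  }

  run <- structure(list(config = cfg,
                        metadata = metadata,
                        evaluations = evaluations,
                        mystery_scores = mystery_scores,
                        mystery_predictions = mystery_preds,
                        novelty = novelty,
                        final_models = final_models),
                   class = "pipeline_run")
  if (!is.null(cfg$outdir)) write_run(run, cfg$outdir)
  run
}

metrics_list <- function(run) {
  ev <- lapply(run$evaluations, function(designs)
    lapply(designs, function(d) {
      r <- d$result
      r[c("mse_latitude", "mse_longitude", "mse_total",
          "r2_latitude", "r2_longitude", "accuracy")]
    }))
  my <- lapply(run$mystery_scores, function(r)
    r[c("mse_latitude", "mse_longitude", "mse_total",
        "r2_latitude", "r2_longitude", "accuracy")])
  nov <- if (!is.null(run$novelty)) {
    fl <- run$novelty$mystery_flags
    c(run$novelty$loo[c("accuracy", "sensitivity", "specificity")],
      list(mystery_flagged_new = if (!is.null(fl)) sum(fl$flag_new),
           mystery_n = if (!is.null(fl)) nrow(fl)))
  }
  list(config_hash = run$config$hash, seed = run$config$seed,
       cross_validation = ev, mystery = my, novelty = nov)
}

write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("# config %s seed %d", run$config$hash,
                   run$config$seed)
  jsonlite::write_json(metrics_list(run),
                       file.path(outdir, "metrics.json"),
                       auto_unbox = TRUE, digits = 10, null = "null",
                       pretty = TRUE)
  wcsv <- function(df, file) {
    con <- file(file.path(outdir, file), "w")
    writeLines(stamp, con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  for (m in names(run$evaluations)) {
    wcsv(run$evaluations[[m]]$nested$predictions,
         sprintf("predictions_nested_%s.csv", m))
    wcsv(run$evaluations[[m]]$l1co$predictions,
         sprintf("predictions_l1co_%s.csv", m))
  }
  if (!is.null(run$novelty)) {
    wcsv(run$novelty$records, "ambiguity_records.csv")
    if (!is.null(run$novelty$mystery_flags))
      wcsv(run$novelty$mystery_flags, "mystery_flags.csv")
  }
  writeLines(report_md(run), file.path(outdir, "report.md"))
  invisible(outdir)
}

report_md <- function(run) {
  fmt <- function(x) formatC(x, format = "f", digits = 2)
  lines <- c(
    "# Source attribution run report", "",
    sprintf("config hash: `%s`; seed: %d", run$config$hash,
            run$config$seed),
    sprintf("rank: %s; models: %s", run$config$rank,
            paste(run$config$models, collapse = ", ")), "",
    "## Cross-validated coordinate error (MSE, squared degrees)", "",
    "| model | design | lat MSE | long MSE | total | accuracy |",
    "|---|---|---|---|---|---|")
  for (m in names(run$evaluations))
    for (d in names(run$evaluations[[m]])) {
      r <- run$evaluations[[m]][[d]]$result
      lines <- c(lines, sprintf(
        "| %s | %s | %s | %s | %s | %s |", m, d,
        fmt(r$mse_latitude), fmt(r$mse_longitude), fmt(r$mse_total),
        if (is.na(r$accuracy)) "-" else fmt(r$accuracy)))
    }
  if (!is.null(run$mystery_scores)) {
    lines <- c(lines, "", "## Mystery (new-origin) samples", "",
               "| model | lat MSE | long MSE | total |",
               "|---|---|---|---|")
    for (m in names(run$mystery_scores)) {
      r <- run$mystery_scores[[m]]
      lines <- c(lines, sprintf("| %s | %s | %s | %s |", m,
                                fmt(r$mse_latitude),
                                fmt(r$mse_longitude),
                                fmt(r$mse_total)))
    }
  }
  if (!is.null(run$novelty)) {
    l <- run$novelty$loo
    lines <- c(lines, "", "## Novelty detection", "", sprintf(
      "LOO accuracy %s (sensitivity %s, specificity %s)",
      fmt(l$accuracy), fmt(l$sensitivity), fmt(l$specificity)))
    fl <- run$novelty$mystery_flags
    if (!is.null(fl))
      lines <- c(lines, sprintf(
        "Mystery samples flagged as new origin: %d of %d (%s)",
        sum(fl$flag_new), nrow(fl), fmt(mean(fl$flag_new))))
  }
  lines
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(paste(report_md(x), collapse = "\n"), "\n")
  invisible(x)
}
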