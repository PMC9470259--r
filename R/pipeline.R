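# End-to-end pipeline: generate/load -> profile -> summarize -> fit

#' Pipeline run configuration
#'
#' A fully serializable description of one pipeline run; a run is
#' reproducible from its persisted configuration alone.
#'
#' @param output_dir Output directory for the artifact bundle.
#' @param n_environments Number of environments (>= 1).
#' @param master_seed Master seed of the environment set.
#' @param genome_dir Optional directory of genome files with a manifest
#'   (see [write_genome_set()]); when `NULL`, genomes are generated.
#' @param generator A [generator_config()] (used when `genome_dir` is NULL).
#' @param limits An [exec_limits()].
#' @param fit_models Fit the GLM suite after profiling (default TRUE).
#' @param verbosity 0 = quiet, 1 = progress messages to stderr.
#' @return A list of class `dg_runconfig`.
#' @export
pipeline_config <- function(output_dir, n_environments = 50,
                            master_seed = 42, genome_dir = NULL,
                            generator = generator_config(),
                            limits = exec_limits(), fit_models = TRUE,
                            verbosity = 1) {
  if (n_environments < 1) stop("n_environments must be >= 1")
  structure(list(output_dir = output_dir,
                 n_environments = as.integer(n_environments),
                 master_seed = master_seed,
                 genome_dir = genome_dir,
                 generator = generator,
                 limits = limits,
                 fit_models = isTRUE(fit_models),
                 verbosity = verbosity),
            class = "dg_runconfig")
}

#' Persist / load a run configuration (YAML)
#'
#' @param config A `dg_runconfig`.
#' @param path YAML file path.
#' @return `path` (write) or the configuration (read).
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$generator <- unclass(x$generator)
  x$generator$payload_mix <- as.list(x$generator$payload_mix)
  x$limits <- unclass(x$limits)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  gen <- x$generator
  config <- pipeline_config(
    output_dir = x$output_dir,
    n_environments = x$n_environments,
    master_seed = x$master_seed,
    genome_dir = x$genome_dir,
    generator = generator_config(
      n_genomes = gen$n_genomes,
      genome_length = gen$genome_length,
      payload_mix = unlist(gen$payload_mix),
      payload_range = unlist(gen$payload_range),
      loop_io_prob = gen$loop_io_prob,
      seed = gen$seed,
      master_seed = gen$master_seed),
    limits = exec_limits(x$limits$max_cycles, x$limits$min_offspring_length,
                         x$limits$require_copied_fraction),
    fit_models = x$fit_models,
    verbosity = x$verbosity)
  config
}

pipe_log <- function(config, stage, ...) {
  if (isTRUE(config$verbosity >= 1))
    message("[", format(Sys.time(), "%H:%M:%S"), "] ", stage, ": ", ...)
}

#' Run the full plasticity pipeline
#'
#' Executes generate/load -> profile -> summarize -> fit and writes the
#' artifact bundle to `config$output_dir`: the persisted configuration
#' (`run_config.yml`), generated genomes with a manifest (`genomes/`),
#' per-record profiles (`profiles.csv`, one row per genome x environment),
#' the per-genome summary (`summary.csv`), quadrant proportions
#' (`quadrants.csv`), and the model reports (`models.json`). Any stage
#' failure aborts with a stage-named diagnostic.
#'
#' @param config A [pipeline_config()] or the path of a YAML file written
#'   by [write_run_config()].
#' @return Invisibly, a list with the population, summary, models and the
#'   artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "dg_runconfig"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(config = file.path(config$output_dir, "run_config.yml"))
  write_run_config(config, paths$config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  genomes <- stage("generate", {
    if (!is.null(config$genome_dir)) {
      pipe_log(config, "load", "reading genomes from ", config$genome_dir)
      read_genome_set(config$genome_dir)
    } else {
      pipe_log(config, "generate", config$generator$n_genomes,
               " genomes, seed ", config$generator$seed)
      gs <- sample_genomes(config$generator, config$limits)
      paths$genomes <- file.path(config$output_dir, "genomes")
      write_genome_set(gs, paths$genomes)
      gs
    }
  })

  envs <- stage("environments",
                environment_set(config$n_environments, config$master_seed))

  population <- stage("profile", {
    pipe_log(config, "profile", length(genomes), " genomes x ",
             nrow(envs), " environments")
    profile_population(genomes, envs, config$limits)
  })

  summary_obj <- stage("summarize", population_summary(population))

  stage("write", {
    rec <- record_table(population)
    paths$profiles <- file.path(config$output_dir, "profiles.csv")
    write.csv(rec, paths$profiles, row.names = FALSE)
    paths$summary <- file.path(config$output_dir, "summary.csv")
    write.csv(summary_obj$table, paths$summary, row.names = FALSE)
    paths$quadrants <- file.path(config$output_dir, "quadrants.csv")
    write.csv(data.frame(quadrant = names(summary_obj$quadrants),
                         proportion = as.numeric(summary_obj$quadrants),
                         count = as.numeric(summary_obj$quadrant_counts)),
              paths$quadrants, row.names = FALSE)
  })

  models <- NULL
  if (config$fit_models) {
    models <- stage("fit", {
      pipe_log(config, "fit", "model suite")
      suppressWarnings(plasticity_models(population))
    })
    stage("report", {
      rep <- models_report(models)
      paths$models <- file.path(config$output_dir, "models.json")
      jsonlite::write_json(
        list(report = rep, skipped = as.list(models$skipped),
             n_profiles = models$n_profiles, n_records = models$n_records),
        paths$models, auto_unbox = TRUE, digits = NA)
    })
  }

  pipe_log(config, "done", "artifacts in ", config$output_dir)
  invisible(list(population = population, summary = summary_obj,
                 models = models, paths = paths))
}
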