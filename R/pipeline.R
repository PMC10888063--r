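#' Run configuration for the end-to-end pipeline
#'
#' Collects file paths and tunable parameters for the five pipeline stages.
#' Any field left NULL keeps its default; input paths default to files named
#' by the simulate stage inside `out_dir`.
#'
#' @param out_dir Directory for all pipeline artifacts.
#' @param seed Master seed; every stage derives its randomness from it.
#' @param tau Efficacy-coefficient range parameter in (0, 100\].
#' @param quantile QRM quantile in (0, 1).
#' @param min_chars Corpus filter threshold (characters).
#' @param min_char_len,min_frequency Vocabulary filters.
#' @param dim,window,epochs Embedding hyperparameters.
#' @param scenario A [scenario_config()] for the simulate stage (its seed is
#'   overridden by `seed`).
#' @param survey_year Year whose index is validated against the survey; NULL
#'   uses the scenario's survey year.
#' @param nboot QRM bootstrap resamples.
#' @param max_words Optional POD size cap.
#' @param alpha_threshold Optional POD relevance threshold.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("cadi_run_"), seed = 1L, tau = 40,
                       quantile = 0.5, min_chars = 15L, min_char_len = 2L,
                       min_frequency = 5L, dim = 100L, window = 5L,
                       epochs = 20L, scenario = NULL, survey_year = NULL,
                       nboot = 200L, max_words = NULL, alpha_threshold = NULL) {
  if (tau <= 0 || tau > 100) stop("'tau' must lie in (0, 100]")
  if (quantile <= 0 || quantile >= 1) stop("'quantile' must lie in (0, 1)")
  if (is.null(scenario)) scenario <- scenario_config(seed = seed)
  scenario$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), tau = tau,
                 quantile = quantile, min_chars = min_chars,
                 min_char_len = min_char_len, min_frequency = min_frequency,
                 dim = dim, window = window, epochs = epochs,
                 scenario = scenario, survey_year = survey_year,
                 nboot = nboot, max_words = max_words,
                 alpha_threshold = alpha_threshold),
            class = "run_config")
}

#' Load a run configuration from a JSON or YAML file
#'
#' The file may set any argument of [run_config()]; scenario parameters go
#' under a `scenario` mapping (arguments of [scenario_config()]).
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  sc <- NULL
  if (!is.null(cfg$scenario)) {
    sc <- do.call(scenario_config, c(cfg$scenario,
                                     if (is.null(cfg$scenario$seed))
                                       list(seed = cfg$seed %||% 1L)))
    cfg$scenario <- NULL
  }
  do.call(run_config, c(cfg, if (!is.null(sc)) list(scenario = sc)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_stage <- function(stage, rows_in, rows_out, elapsed) {
  message(sprintf("[%s] rows in: %s, rows out: %s, elapsed: %.2fs",
                  stage, rows_in, rows_out, elapsed))
}

pipeline_paths <- function(out_dir) {
  file.path(out_dir, c(
    corpus = "corpus.csv", trends = "trends.csv",
    population = "population.csv", penetration = "penetration.csv",
    covariates = "covariates.csv", survey = "survey.csv", pod = "pod.csv",
    cadi = "cadi.csv", validation = "validation.json",
    regression_table = "regression.csv", regression = "regression.json"
  )) |> setNames(c("corpus", "trends", "population", "penetration",
                   "covariates", "survey", "pod", "cadi", "validation",
                   "regression_table", "regression"))
}

stage_simulate <- function(config, paths) {
  t0 <- proc.time()[3]
  sim <- simulate_scenario(config$scenario)
  write_table(sim$corpus, paths["corpus"])
  national <- cbind(region = "NATIONAL", sim$trends$national)
  trends <- rbind(sim$trends$regional,
                  national[, c("region", "word", "date", "value")])
  write_table(trends, paths["trends"])
  write_table(sim$population, paths["population"])
  write_table(sim$penetration, paths["penetration"])
  write_table(sim$covariates, paths["covariates"])
  write_table(sim$survey, paths["survey"])
  log_stage("simulate", 0, nrow(trends), proc.time()[3] - t0)
  sim$survey_year
}

stage_build_pod <- function(config, paths) {
  t0 <- proc.time()[3]
  corpus <- read_corpus_csv(paths["corpus"])
  pod <- build_pod(corpus, min_chars = config$min_chars,
                   min_char_len = config$min_char_len,
                   min_frequency = config$min_frequency, dim = config$dim,
                   window = config$window, epochs = config$epochs,
                   seed = config$seed, max_words = config$max_words,
                   alpha_threshold = config$alpha_threshold)
  write_table(as.data.frame(pod)[, c("word", "alpha", "frequency")],
              paths["pod"])
  log_stage("build-pod", nrow(corpus), nrow(pod), proc.time()[3] - t0)
  pod
}

stage_compute <- function(config, paths) {
  t0 <- proc.time()[3]
  trends <- read_trends_csv(paths["trends"])
  pod <- read_pod_csv(paths["pod"])
  population <- read_population_csv(paths["population"])
  penetration <- read_penetration_csv(paths["penetration"])
  national <- trends[trends$region == "NATIONAL", c("word", "date", "value")]
  regional <- trends[trends$region != "NATIONAL", ]
  beta <- aggregate_national_trends(national)
  # only dictionary words with national trend coverage can be weighted
  covered <- intersect(pod$word, unique(beta$word))
  if (length(covered) < nrow(pod)) {
    message("compute: dropping ", nrow(pod) - length(covered),
            " dictionary word(s) without trend data")
  }
  if (length(covered) == 0L) stop("no dictionary word has trend data")
  pod <- pod[pod$word %in% covered, , drop = FALSE]
  gamma <- aggregate_regional_trends(regional[regional$word %in% covered, ])
  weights <- compute_weights(pod, beta[beta$word %in% covered, ])
  adjusted <- population_adjust(gamma, population)
  cadi <- compute_cadi(adjusted, weights, tau = config$tau)
  cadi <- penetration_adjust(cadi, penetration)
  write_table(cadi, paths["cadi"])
  log_stage("compute", nrow(trends), nrow(cadi), proc.time()[3] - t0)
  cadi
}

stage_validate <- function(config, paths, survey_year) {
  t0 <- proc.time()[3]
  cadi <- read_cadi_csv(paths["cadi"])
  survey <- read_survey_csv(paths["survey"])
  val <- validate_cadi(cadi, survey, survey_year)
  out <- list(
    year = survey_year,
    n = val$report$n,
    pearson = val$report$pearson,
    kendall = val$report$kendall,
    spearman = val$report$spearman,
    p_values = as.list(val$report$p_values),
    prevalence = as.list(val$prevalence)
  )
  jsonlite::write_json(out, paths["validation"], auto_unbox = TRUE, digits = NA)
  log_stage("validate", nrow(survey), 1, proc.time()[3] - t0)
  val
}

stage_regress <- function(config, paths) {
  t0 <- proc.time()[3]
  cadi <- read_cadi_csv(paths["cadi"])
  covariates <- read_covariates_csv(paths["covariates"])
  panel <- merge(covariates, cadi[, c("region", "year", "cadi")],
                 by = c("region", "year"))
  if (nrow(panel) == 0L) stop("no (region, year) overlap between covariates and CADI")
  analysis <- run_full_analysis(panel, quantile = config$quantile,
                                nboot = config$nboot, seed = config$seed)
  write_table(analysis$table, paths["regression_table"])
  full <- lapply(analysis$results, function(kind) {
    lapply(kind, function(res) {
      if (is.null(res)) return(NULL)
      list(coefficients = as.list(res$coefficients),
           std_errors = as.list(res$std_errors),
           p_values = as.list(res$p_values),
           r_squared = res$r_squared, n = res$n,
           model_kind = res$model_kind, quantile = res$quantile)
    })
  })
  jsonlite::write_json(list(threshold = analysis$threshold, models = full),
                       paths["regression"], auto_unbox = TRUE, digits = NA,
                       na = "null")
  log_stage("regress", nrow(panel), nrow(analysis$table), proc.time()[3] - t0)
  analysis
}

#' Run the full pipeline: simulate, build-pod, compute, validate, regress
#'
#' Executes the five stages in dependency order, writing every artifact
#' under `config$out_dir` and logging stage timings and row counts to
#' standard error. Rerunning with an identical configuration reproduces
#' byte-identical outputs. Stages communicate only through the files they
#' write, so each stage can also be run standalone from the command line.
#'
#' @param config A [run_config()] (or path to a JSON/YAML config file).
#' @param stages Subset of stages to run (in order); earlier artifacts must
#'   already exist when a stage is skipped.
#' @return Invisibly, the named vector of artifact paths.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "build-pod", "compute",
                                    "validate", "regress")) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- pipeline_paths(config$out_dir)
  survey_year <- config$survey_year
  run <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if ("simulate" %in% stages) {
    sy <- run("simulate", stage_simulate(config, paths))
    if (is.null(survey_year)) survey_year <- sy
  }
  if (is.null(survey_year)) {
    survey_year <- config$scenario$years[
      which.min(abs(config$scenario$years - 2020L))]
  }
  if ("build-pod" %in% stages) run("build-pod", stage_build_pod(config, paths))
  if ("compute" %in% stages) run("compute", stage_compute(config, paths))
  if ("validate" %in% stages) run("validate", stage_validate(config, paths, survey_year))
  if ("regress" %in% stages) run("regress", stage_regress(config, paths))
  invisible(paths)
}
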