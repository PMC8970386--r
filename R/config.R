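#' Default pipeline configuration
#'
#' All tunable constants of the pipeline in one nested list.  The
#' spectral chain constants (0.1-70 Hz order-8 Butterworth, 150-s epoch,
#' 2-s segments stepped by 1 s, half-Hz resolution capped at 45 Hz, two
#' principal components per channel pair) are the method's defining
#' parameters; the remaining entries (GA and SVM hyper-parameters,
#' estimator choices) are documented design choices.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    filter = list(low_hz = 0.1, high_hz = 70, order = 8, zero_phase = TRUE),
    epoch = list(duration_s = 150, start_s = 0),
    segment = list(length_s = 2, step_s = 1),
    spectral = list(estimator = "median"),
    pca = list(n_components = 2, ranking = "auc"),
    ga = list(population = 50, generations = 100, crossover_p = 0.5,
              mutation_p = 0.01, elitism = 2, init_density = 0.1,
              tournament_k = 3, cv_folds = 5, parsimony = 0.01,
              patience = 8, min_improve = 0.002),
    svm = list(cost = 1),
    model = list(min_per_class = 4),
    ci_level = 0.95,
    seed = 1L
  )
}

#' Load a configuration file
#'
#' Reads a YAML (or JSON) configuration and merges it over the defaults;
#' unspecified keys keep their default values.
#'
#' @param path YAML/JSON file path.
#' @return Nested configuration list.
#' @export
load_config <- function(path) {
  user <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  modifyList(default_config(), user)
}

# stable short fingerprint of a configuration for run logs
config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% .Machine$integer.max)
}
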