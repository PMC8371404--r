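slider_columns <- c("participant_id", "experiment", "probe", "scenario",
                    "domain_size", "prior_type", "state_index",
                    "slider_label", "raw_value", "response_time_s", "seed")

#' Write a slider dataset to CSV
#'
#' UTF-8, comma-separated, header row, decimal point; state indices use
#' the bitmask encoding (schema version 1.0).
#'
#' @param data A slider dataset.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_slider_csv <- function(data, path) {
  miss <- setdiff(slider_columns, names(data))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  utils::write.csv(data[, slider_columns], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a slider dataset from CSV
#'
#' Validates the schema: all columns present, raw values in \[0, 1\],
#' no duplicate (participant, item, slider) keys.  Errors name the
#' offending row.
#'
#' @param path CSV file path.
#' @return A slider dataset (empty file gives an empty dataset with the
#'   schema, with a warning).
#' @export
read_slider_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(data) == 0) {
    warning("empty slider file: ", path)
    empty <- data.frame(participant_id = character(), experiment = integer(),
                        probe = character(), scenario = character(),
                        domain_size = integer(), prior_type = character(),
                        state_index = integer(), slider_label = character(),
                        raw_value = numeric(), response_time_s = numeric(),
                        seed = integer(), stringsAsFactors = FALSE)
    attr(empty, "schema_version") <- "1.0"
    return(empty)
  }
  miss <- setdiff(slider_columns, names(data))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(is.na(data$raw_value) | data$raw_value < 0 | data$raw_value > 1)
  if (length(bad) > 0)
    stop("raw_value outside [0, 1] at row ", bad[1])
  key <- paste(item_key(data), data$state_index, data$slider_label)
  dup <- which(duplicated(key))
  if (length(dup) > 0)
    stop("duplicate (participant, item, slider) record at row ", dup[1])
  attr(data, "schema_version") <- "1.0"
  data
}

#' Read a run configuration file
#'
#' YAML or JSON (by extension), with blocks `model` (variant, p, alpha,
#' cost_per_word, include_null, k), `mcmc` (chains, iterations,
#' warmup_frac, thin, seed) and `design` ([experiment_design()] fields).
#' Unknown blocks or keys are rejected.
#'
#' @param path Configuration file path.
#' @return Named list of configuration blocks.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  allowed <- list(
    model = c("variant", "p", "alpha", "cost_per_word", "include_null", "k"),
    mcmc = c("chains", "iterations", "warmup_frac", "thin", "seed",
             "init_jitter"),
    design = c("experiment", "probe", "domain_sizes", "scenarios",
               "prior_type", "n_participants"),
    paths = c("input", "output"))
  bad_blocks <- setdiff(names(cfg), names(allowed))
  if (length(bad_blocks) > 0)
    stop("unknown config block(s): ", paste(bad_blocks, collapse = ", "))
  for (b in names(cfg)) {
    bad <- setdiff(names(cfg[[b]]), allowed[[b]])
    if (length(bad) > 0)
      stop("unknown key(s) in block `", b, "`: ", paste(bad, collapse = ", "))
  }
  cfg
}

#' Named prediction presets for the exhaustivity curves
#'
#' Five standard panel configurations of the model's exhaustivity
#' predictions as a function of domain size:
#'
#' * `A`: binomial success probability p in \{0.1, 0.5, 0.8\}, alpha = 3.
#' * `B`: cost per word in \{0, 0.5, 1\} at p = 0.5, alpha = 3.
#' * `C`: with and without exclusive alternatives (p = 0.5, alpha = 3).
#' * `D`: the collapsed two-state/two-alternative model vs the full model.
#' * `E`: the collapsed model with constant (domain-size-independent)
#'   state priors — the only configuration with a flat curve.
#'
#' @param preset One of `"A"`..`"E"`, or `NULL` to pass a grid directly.
#' @param k Domain sizes (default 2:8).
#' @param p,alpha,cost_per_word,variant Grid values used when
#'   `preset = NULL`.
#' @return List with `table` (see [exhaustivity_table()]) and `figure`
#'   (a ggplot of E(k) curves).
#' @export
predict_curves <- function(preset = "A", k = 2:8, p = 0.5, alpha = 3,
                           cost_per_word = 0, variant = "focus_only") {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("A", "B", "C", "D", "E"))
    tab <- switch(preset,
      A = exhaustivity_table(k = k, p = c(0.1, 0.5, 0.8), alpha = 3),
      B = exhaustivity_table(k = k, cost_per_word = c(0, 0.5, 1)),
      C = exhaustivity_table(k = k,
                             variant = c("focus_only", "focus_plus_exclusives")),
      D = exhaustivity_table(k = k,
                             variant = c("focus_only", "collapsed_two_state")),
      E = exhaustivity_table(k = k, variant = "collapsed_constant_prior"))
  } else {
    if (length(k) == 0) stop("empty domain-size grid")
    tab <- exhaustivity_table(k = k, p = p, alpha = alpha,
                              cost_per_word = cost_per_word,
                              variant = variant)
  }
  if (nrow(tab) == 0) stop("empty prediction grid")
  tab$curve <- paste0(tab$variant, ", p=", tab$p, ", cost=", tab$cost_per_word)
  fig <- ggplot2::ggplot(tab, ggplot2::aes(x = k, y = exhaustivity,
                                           color = curve)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "domain size k", y = "exhaustivity E(k)",
                  color = NULL) +
    ggplot2::theme_minimal()
  list(table = tab[, c("variant", "k", "p", "alpha", "cost_per_word",
                       "exhaustivity")],
       figure = fig)
}

#' Write a prediction table to CSV or JSON
#'
#' @param table Prediction table (e.g. from [predict_curves()]).
#' @param path Output path ending in `.csv` or `.json`.
#' @return The path, invisibly.
#' @export
write_predictions <- function(table, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(table, path, dataframe = "rows", digits = NA)
  } else {
    utils::write.csv(table, path, row.names = FALSE)
  }
  invisible(path)
}
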