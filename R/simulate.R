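#' Design of a slider-rating experiment arm
#'
#' Experiment 1 shows one slider per state: `2^k` sliders in prior-probe
#' items and `2^(k-1)` (the focus-compatible states) in posterior-probe
#' items, for domain sizes k in \{2, 3, 4\}.  Experiment 2 always shows two
#' sliders — the exhaustive state ("X acted and the other friends did not")
#' and the pooled non-exhaustive state ("X and at least one of the other
#' friends acted") — and additionally manipulates the prior wording
#' ("usually none/some/all of his friends ..."); the "none" and "all" arms
#' run at domain size 2 with a single item per participant.
#'
#' Default arm sizes are the post-exclusion participant counts of the
#' emulated designs: Experiment 1, 30 (prior) / 66 (posterior);
#' Experiment 2, 49/82 ("none"), 65/60 ("some"), 28/63 ("all").
#'
#' @param experiment 1 or 2.
#' @param probe `"prior"` or `"posterior"`.
#' @param domain_sizes Subset of 2:4 (must be exactly 2 for the "none" and
#'   "all" prior types).
#' @param scenarios Character vector of scenario tags; each participant's
#'   items get distinct scenarios.
#' @param prior_type `"none"`, `"some"` or `"all"` (experiment 1 is always
#'   `"some"`).
#' @param n_participants Number of participants in the arm (default from
#'   the emulated design).
#' @return A list of class `experiment_design`.
#' @export
experiment_design <- function(experiment = 1, probe = c("prior", "posterior"),
                              domain_sizes = 2:4,
                              scenarios = c("vacation", "halloween_party",
                                            "movie_night"),
                              prior_type = "some", n_participants = NULL) {
  probe <- match.arg(probe)
  experiment <- as.integer(experiment)
  if (!experiment %in% 1:2) stop("`experiment` must be 1 or 2")
  if (!prior_type %in% c("none", "some", "all"))
    stop("`prior_type` must be one of none/some/all")
  if (experiment == 1L && prior_type != "some")
    stop("experiment 1 uses the \"some\" prior wording only")
  domain_sizes <- sort(unique(as.integer(domain_sizes)))
  if (!all(domain_sizes %in% 2:4))
    stop("`domain_sizes` must be a subset of 2:4")
  if (prior_type %in% c("none", "all") && !identical(domain_sizes, 2L))
    stop("prior type \"", prior_type, "\" runs at domain size 2 only")
  items <- length(domain_sizes)
  if (items > length(scenarios))
    stop("need at least one scenario per item")
  if (is.null(n_participants))
    n_participants <- default_arm_size(experiment, probe, prior_type)
  structure(list(experiment = experiment, probe = probe,
                 domain_sizes = domain_sizes, scenarios = scenarios,
                 prior_type = prior_type,
                 n_participants = as.integer(n_participants),
                 items_per_participant = items),
            class = "experiment_design")
}

default_arm_size <- function(experiment, probe, prior_type) {
  if (experiment == 1L) {
    if (probe == "prior") 30L else 66L
  } else {
    sizes <- list(none = c(prior = 49L, posterior = 82L),
                  some = c(prior = 65L, posterior = 60L),
                  all = c(prior = 28L, posterior = 63L))
    sizes[[prior_type]][[probe]]
  }
}

#' Response behavior of simulated participants
#'
#' Three response modes:
#'
#' * `model_normalized`: each slider is drawn through the kappa-logit-normal
#'   channel around the participant's model belief; slider sums scatter
#'   around 1.
#' * `non_normalizing`: as above but centered on a compressed belief
#'   `Q^compress` (default square root), so every slider is rated on an
#'   absolute plausibility scale and raw sums grow with the number of
#'   sliders, as untrained raters do on one-slider-per-state displays.
#' * `constant_null`: the exhaustive-state slider sits at a constant
#'   `level` (plus truncated noise) for every domain size and prior
#'   wording, all other sliders at `other_level` — the
#'   constant-exhaustivity null behavior.
#'
#' @param mode One of the three modes above.
#' @param level Constant exhaustive-state raw value for `constant_null`.
#' @param other_level Raw value of the remaining sliders for
#'   `constant_null`.
#' @param noise Response noise standard deviation for `constant_null`
#'   (responses clipped to \[0, 1\]).
#' @param compress Compression exponent of the `non_normalizing` mode.
#' @param rt_meanlog,rt_sdlog Log-normal response-time parameters (median
#'   `exp(rt_meanlog)` seconds, default 40 s).
#' @param fast_frac Fraction of extra injected participants with one item
#'   answered in under 15 s.
#' @param allzero_frac Fraction of extra injected participants with one
#'   all-zero item.
#' @return A list of class `response_behavior`.
#' @export
response_behavior <- function(mode = c("model_normalized", "non_normalizing",
                                       "constant_null"),
                              level = 0.9, other_level = 0.2, noise = 0.05,
                              compress = 0.5, rt_meanlog = log(40),
                              rt_sdlog = 0.4, fast_frac = 0,
                              allzero_frac = 0) {
  mode <- match.arg(mode)
  if (level < 0 || level > 1) stop("`level` must lie in [0, 1]")
  if (other_level < 0 || other_level > 1)
    stop("`other_level` must lie in [0, 1]")
  stopifnot(noise >= 0, compress > 0, fast_frac >= 0, allzero_frac >= 0)
  structure(list(mode = mode, level = level, other_level = other_level,
                 noise = noise, compress = compress, rt_meanlog = rt_meanlog,
                 rt_sdlog = rt_sdlog, fast_frac = fast_frac,
                 allzero_frac = allzero_frac),
            class = "response_behavior")
}

#' Hyperparameter presets for the prior-wording manipulations
#'
#' Population size-class means calibrated so that the population-mean
#' exhaustive-state share of the focus-compatible prior mass at domain
#' size 2 is 0.73 ("usually none of his friends ..."), 0.53 ("some", the
#' default wording) and 0.30 ("all").  Under the independent-acting
#' parameterization that share is `1 - p`, so the presets use acting
#' probabilities 0.27, 0.47 and 0.70; the "some" preset coincides with the
#' generator default.
#'
#' @param prior_type `"none"`, `"some"` or `"all"`.
#' @param domain_sizes Domain sizes to provide means for (2 only for
#'   "none"/"all").
#' @return A [prior_hyperparams()] object with attribute `prior_type`.
#' @export
prior_type_hyperparams <- function(prior_type, domain_sizes = NULL) {
  p_act <- switch(prior_type, none = 0.27, some = 0.47, all = 0.70,
                  stop("`prior_type` must be one of none/some/all"))
  if (is.null(domain_sizes))
    domain_sizes <- if (prior_type == "some") 2:4 else 2L
  if (prior_type %in% c("none", "all") && !identical(as.integer(domain_sizes), 2L))
    stop("prior type \"", prior_type, "\" is defined at domain size 2 only")
  hp <- prior_hyperparams(mu = default_mu(as.integer(domain_sizes), p = p_act))
  attr(hp, "prior_type") <- prior_type
  hp
}

bundled_names <- function() {
  path <- system.file("extdata", "first_names.txt", package = "rsafocus")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "first_names.txt")
  readLines(path)
}

#' Generate a synthetic slider dataset
#'
#' Draws a complete slider dataset for one experiment arm from the
#' hierarchical generative model (or from a behavioral null model, see
#' [response_behavior()]).  One record per participant x item x slider;
#' individual names are drawn per item from a bundled list of frequent
#' first names and alphabetized, with the mentioned individual always the
#' alphabetically first (bit 0), so the exhaustive state is index 1.
#'
#' @param design An [experiment_design()].
#' @param hyper Hyperparameters ([prior_hyperparams()] for prior probes,
#'   [posterior_hyperparams()] for posterior probes).  Defaults to the
#'   preset of the design's prior type.
#' @param behavior A [response_behavior()].
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return Data frame with columns `participant_id`, `experiment`, `probe`,
#'   `scenario`, `domain_size`, `prior_type`, `state_index` (NA for the
#'   pooled non-exhaustive slider of experiment 2), `slider_label`,
#'   `raw_value`, `response_time_s`, `seed` (schema version in attribute
#'   `schema_version`).
#' @export
generate_dataset <- function(design, hyper = NULL,
                             behavior = response_behavior(), seed = 1) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(behavior, "response_behavior"))
  if (is.null(hyper)) {
    base <- prior_type_hyperparams(design$prior_type, design$domain_sizes)
    hyper <- if (design$probe == "posterior")
      posterior_hyperparams(kappa = base$kappa, sigma2 = base$sigma2,
                            w = base$w, mu = base$mu)
    else base
  }
  for (k in design$domain_sizes)
    if (is.null(hyper$mu[[as.character(k)]]))
      stop("hyperparameters provide no mu for domain size ", k)
  if (design$probe == "posterior" && behavior$mode == "model_normalized" &&
      is.null(hyper$mu_alpha))
    stop("posterior probes need posterior_hyperparams (mu_alpha missing)")
  set.seed(as.integer(seed))
  names_pool <- bundled_names()

  n_clean <- design$n_participants
  n_fast <- round(behavior$fast_frac * n_clean)
  n_zero <- round(behavior$allzero_frac * n_clean)
  total <- n_clean + n_fast + n_zero
  rows <- vector("list", total)
  for (j in seq_len(total)) {
    pid <- sprintf("P%03d", j)
    flaw <- if (j <= n_clean) "none"
            else if (j <= n_clean + n_fast) "fast" else "allzero"
    scen <- sample(design$scenarios, design$items_per_participant)
    alpha_j <- if (design$probe == "posterior" && !is.null(hyper$mu_alpha))
      stats::rgamma(1, hyper$mu_alpha^2 / hyper$sigma2_alpha,
                    rate = hyper$mu_alpha / hyper$sigma2_alpha) else NA_real_
    flaw_item <- sample(design$items_per_participant, 1)
    items <- vector("list", design$items_per_participant)
    for (it in seq_along(design$domain_sizes)) {
      k <- design$domain_sizes[it]
      nm <- sort(sample(names_pool, k))
      p_jk <- as.vector(rdirichlet(1, hyper$w * hyper$mu[[as.character(k)]]))
      sl <- simulate_item(design, behavior, hyper, k, nm, p_jk, alpha_j)
      rt <- stats::rlnorm(1, behavior$rt_meanlog, behavior$rt_sdlog)
      if (flaw == "fast" && it == flaw_item) rt <- stats::runif(1, 5, 14.5)
      if (flaw == "allzero" && it == flaw_item) sl$raw_value <- 0
      items[[it]] <- data.frame(
        participant_id = pid, experiment = design$experiment,
        probe = design$probe, scenario = scen[it], domain_size = k,
        prior_type = design$prior_type, state_index = sl$state_index,
        slider_label = sl$slider_label, raw_value = sl$raw_value,
        response_time_s = rt, seed = as.integer(seed),
        stringsAsFactors = FALSE)
    }
    rows[[j]] <- do.call(rbind, items)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "schema_version") <- "1.0"
  out
}

simulate_item <- function(design, behavior, hyper, k, nm, p_jk, alpha_j) {
  two_slider <- design$experiment == 2L
  if (two_slider) {
    state_index <- c(1L, NA_integer_)
    slider_label <- c(nm[1], "pooled_nonexh")
  } else if (design$probe == "prior") {
    state_index <- 0:(2^k - 1L)
    slider_label <- vapply(state_index, function(i) {
      who <- decode_target_set(i, nm)
      if (length(who) == 0) "nobody" else paste(who, collapse = "+")
    }, character(1))
  } else {
    state_index <- 2L * seq_len(2^(k - 1L)) - 1L
    slider_label <- vapply(state_index, function(i)
      paste(decode_target_set(i, nm), collapse = "+"), character(1))
  }

  if (behavior$mode == "constant_null") {
    base <- ifelse(!is.na(state_index) & state_index == 1L,
                   behavior$level, behavior$other_level)
    raw <- clamp01(base + stats::rnorm(length(base), 0, behavior$noise))
    return(data.frame(state_index = state_index, slider_label = slider_label,
                      raw_value = raw, stringsAsFactors = FALSE))
  }

  Qfull <- expand_size_probs(p_jk, k)
  if (design$probe == "prior") {
    Q <- if (two_slider) {
      Qc <- condition_on_focus(Qfull)   # one performer already known
      c(Qc["1"], 1 - Qc["1"])
    } else Qfull
  } else {
    Qc <- condition_on_focus(Qfull)
    Qpost <- rsa_bridge(Qc, alpha_j)
    Q <- if (two_slider) c(Qpost["1"], 1 - Qpost["1"]) else Qpost
  }
  target <- if (behavior$mode == "non_normalizing") Q^behavior$compress else Q
  raw <- stats::plogis(stats::rnorm(length(target),
                                    hyper$kappa * stats::qlogis(clip_unit(target)),
                                    sqrt(hyper$sigma2)))
  data.frame(state_index = state_index, slider_label = slider_label,
             raw_value = raw, stringsAsFactors = FALSE)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Generate a constant-exhaustivity null dataset
#'
#' Convenience wrapper for the `constant_null` response mode: the raw
#' exhaustive-state slider is `level` (plus truncated noise) independently
#' of domain size and prior wording; all other sliders sit at
#' `other_level`.  With `noise = 0` the dataset is exactly deterministic,
#' which isolates the normalization artifact: constant raw values divided
#' by a sum that grows with the slider count yield a strictly decreasing
#' normalized exhaustivity.
#'
#' @param design An [experiment_design()].
#' @param level Exhaustive-state raw value.
#' @param noise Truncated-normal noise standard deviation.
#' @param seed Integer seed.
#' @param other_level Raw value of the remaining sliders.
#' @return A slider dataset (see [generate_dataset()]).
#' @export
generate_constant_null_dataset <- function(design, level = 0.9, noise = 0,
                                           seed = 1, other_level = 0.2) {
  generate_dataset(design,
                   behavior = response_behavior("constant_null", level = level,
                                                other_level = other_level,
                                                noise = noise),
                   seed = seed)
}
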