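#' MCMC sampler configuration
#'
#' Desk-scale defaults: 4 chains of 2,000 iterations each, the first half
#' warmup, thinning factor 5 (so 200 kept draws per chain).  Survey-scale
#' runs (e.g. 50,000 iterations) are available by raising `iterations`.
#'
#' @param chains Number of chains.
#' @param iterations Total iterations per chain (warmup included).
#' @param warmup_frac Fraction of iterations used as adaptation/warmup.
#' @param thin Thinning factor applied after warmup.
#' @param seed Integer seed; the whole fit is reproducible from it.
#' @param init_jitter Scale of the random overdispersion of chain initial
#'   values.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4, iterations = 2000, warmup_frac = 0.5,
                        thin = 5, seed = 1, init_jitter = 0.5) {
  stopifnot(chains >= 1, iterations >= 20, warmup_frac > 0, warmup_frac < 1,
            thin >= 1)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup_frac = warmup_frac, thin = as.integer(thin),
                 seed = as.integer(seed), init_jitter = init_jitter),
            class = "mcmc_config")
}

# Arrange one probe's records into the flat item/slider layout the compiled
# samplers expect.  Sliders are ordered by state index within item.
prepare_slider_data <- function(data, probe, response) {
  need <- c("participant_id", "probe", "domain_size", "scenario",
            "state_index", "raw_value")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  data <- data[data$probe == probe, , drop = FALSE]
  if (nrow(data) == 0) stop("no ", probe, "-probe records in the data")
  val <- response_column(data, response)
  if (any(val < 0 | val > 1)) stop("responses must lie in [0, 1]")
  key <- item_key(data)
  ord <- order(data$participant_id, data$domain_size, data$state_index)
  data <- data[ord, , drop = FALSE]
  val <- val[ord]
  key <- key[ord]
  items <- !duplicated(key)
  item_id <- cumsum(items)
  tab <- data.frame(key = key[items],
                    participant_id = data$participant_id[items],
                    domain_size = as.integer(data$domain_size[items]),
                    scenario = data$scenario[items],
                    stringsAsFactors = FALSE)
  n_per <- as.vector(table(item_id))
  expected <- if (probe == "prior") 2^tab$domain_size else 2^(tab$domain_size - 1L)
  if (any(n_per != expected))
    stop("item(s) with unexpected slider count (need one slider per ",
         if (probe == "prior") "state" else "compatible state", "): ",
         paste(tab$key[n_per != expected], collapse = ", "))
  if (probe == "posterior" && any(bitwAnd(data$state_index, 1L) != 1L))
    stop("posterior-probe states must contain the mentioned individual (odd state index)")
  list(data = data, y = stats::qlogis(clip_unit(val)), item_id = item_id,
       items = tab, off = c(0L, cumsum(n_per)),
       msize = state_size(data$state_index))
}

run_chains <- function(cfg, runner) {
  set.seed(cfg$seed)
  n_warm <- as.integer(round(cfg$iterations * cfg$warmup_frac))
  lapply(seq_len(cfg$chains), function(ch) runner(n_warm))
}

#' Fit the hierarchical prior-belief model
#'
#' Samples the joint posterior of `kappa`, `w`, `sigma2`, the population
#' size-class means `mu_k` and the per-participant beliefs `p_jk` from
#' prior-probe slider data (one slider per state, as in the one-slider-per-
#' state design) with an adaptive random-walk Metropolis sampler.
#'
#' @param data Slider dataset containing prior-probe records.
#' @param cfg An [mcmc_config()].
#' @param response `"raw"` to model the recorded slider values directly
#'   (the response scale of the generative model), `"normalized"` to model
#'   per-item normalized values.
#' @return An object of class `rsa_fit` with per-chain draws of all free
#'   parameters, split potential-scale-reduction factors, acceptance rate
#'   and the configuration echo.  A fit with any R-hat above 1.05 is
#'   flagged (`converged = FALSE`) but still returned.
#' @export
fit_prior_model <- function(data, cfg = mcmc_config(), response = "raw") {
  prep <- prepare_slider_data(data, "prior", response)
  uk <- sort(unique(prep$items$domain_size))
  kslot <- match(prep$items$domain_size, uk) - 1L
  res <- run_chains(cfg, function(n_warm) {
    mcmc_prior_cpp(prep$items$domain_size, kslot, prep$off, prep$y,
                   prep$msize, uk, cfg$iterations, n_warm, cfg$thin,
                   cfg$init_jitter)
  })
  par_names <- c("kappa", "w", "sigma2",
                 unlist(lapply(uk, function(k)
                   sprintf("mu%d[%d]", k, 0:k))),
                 unlist(lapply(seq_len(nrow(prep$items)), function(i)
                   sprintf("p[%s,k=%d][%d]", prep$items$participant_id[i],
                           prep$items$domain_size[i],
                           0:prep$items$domain_size[i]))))
  build_fit(res, par_names, prep, cfg, model = "prior",
            response = response, uk = uk, fixed = NULL)
}

#' Fit the hierarchical posterior-belief model
#'
#' Samples `kappa`, `sigma2`, the rationality hyperparameters `mu_alpha`
#' and `sigma2_alpha`, per-participant rationalities `alpha_j` (shared
#' across a participant's items) and per-item beliefs `p_jk` from
#' posterior-probe slider data (one slider per focus-compatible state).
#' The concentration `w` and size-class means `mu_k` are fixed, normally at
#' the posterior means of a prior-model fit (see [prior_fit_means()]).
#'
#' @param data Slider dataset containing posterior-probe records.
#' @param fixed List with elements `w` (scalar) and `mu` (named list of
#'   size-class probability vectors by domain size).
#' @param cfg An [mcmc_config()].
#' @param response As in [fit_prior_model()].
#' @return An `rsa_fit` object (see [fit_prior_model()]).
#' @export
fit_posterior_model <- function(data, fixed, cfg = mcmc_config(),
                                response = "raw") {
  if (is.null(fixed$w) || is.null(fixed$mu))
    stop("`fixed` must supply `w` and `mu` (e.g. from prior_fit_means())")
  prep <- prepare_slider_data(data, "posterior", response)
  uk <- sort(unique(prep$items$domain_size))
  for (k in uk)
    if (is.null(fixed$mu[[as.character(k)]]))
      stop("`fixed$mu` has no entry for domain size ", k)
  kslot <- match(prep$items$domain_size, uk) - 1L
  parts <- unique(prep$items$participant_id)
  part_idx <- match(prep$items$participant_id, parts) - 1L
  mu_fixed <- lapply(uk, function(k) fixed$mu[[as.character(k)]])
  res <- run_chains(cfg, function(n_warm) {
    mcmc_post_cpp(prep$items$domain_size, kslot, part_idx, prep$off, prep$y,
                  uk, mu_fixed, fixed$w, length(parts),
                  cfg$iterations, n_warm, cfg$thin, cfg$init_jitter)
  })
  par_names <- c("kappa", "sigma2", "mu_alpha", "sigma2_alpha",
                 sprintf("alpha[%s]", parts),
                 unlist(lapply(seq_len(nrow(prep$items)), function(i)
                   sprintf("p[%s,k=%d][%d]", prep$items$participant_id[i],
                           prep$items$domain_size[i],
                           0:prep$items$domain_size[i]))))
  build_fit(res, par_names, prep, cfg, model = "posterior",
            response = response, uk = uk,
            fixed = list(w = fixed$w, mu = fixed$mu), parts = parts)
}

build_fit <- function(res, par_names, prep, cfg, model, response, uk,
                      fixed, parts = NULL) {
  draws <- lapply(res, `[[`, "draws")
  for (d in seq_along(draws)) colnames(draws[[d]]) <- par_names
  mu_pred <- lapply(res, `[[`, "mu_pred")
  rhat <- vapply(par_names, function(nm)
    split_rhat(lapply(draws, function(d) d[, nm])), numeric(1))
  hyper_names <- par_names[!grepl("^(p|alpha)\\[", par_names)]
  fit <- structure(list(
    model = model, draws = draws, mu_pred = mu_pred,
    par_names = par_names,
    index = data.frame(prep$data,
                       y = prep$y, item = prep$item_id,
                       slider_col = seq_along(prep$y)),
    items = prep$items, uk = uk, fixed = fixed, participants = parts,
    response = response,
    diagnostics = list(
      rhat = rhat,
      max_rhat = max(rhat, na.rm = TRUE),
      max_rhat_hyper = max(rhat[hyper_names], na.rm = TRUE),
      divergences = 0L,
      accept_rate = mean(vapply(res, `[[`, numeric(1), "accept_rate")),
      converged = all(rhat < 1.05, na.rm = TRUE)),
    config = cfg), class = "rsa_fit")
  if (!fit$diagnostics$converged)
    warning("fit flagged as non-converged: max split R-hat = ",
            round(fit$diagnostics$max_rhat, 3))
  fit
}

#' @export
print.rsa_fit <- function(x, ...) {
  kept <- nrow(x$draws[[1]])
  cat("<rsa_fit>", x$model, "-belief model: ", length(x$draws), "chains x",
      kept, "kept draws,", length(x$par_names), "parameters\n")
  cat("  max split R-hat:", round(x$diagnostics$max_rhat, 4),
      if (x$diagnostics$converged) "(converged)" else "(NOT converged)",
      "- hyperparameters only:", round(x$diagnostics$max_rhat_hyper, 4), "\n")
  cat("  mean acceptance rate:", round(x$diagnostics$accept_rate, 3), "\n")
  hy <- if (x$model == "prior") c("kappa", "w", "sigma2")
        else c("kappa", "sigma2", "mu_alpha", "sigma2_alpha")
  m <- vapply(hy, function(nm) mean(pooled_draws(x, nm)), numeric(1))
  cat("  hyperparameter means:",
      paste(sprintf("%s=%.3g", hy, m), collapse = ", "), "\n")
  invisible(x)
}

#' Pool a parameter's draws across chains
#'
#' @param fit An `rsa_fit`.
#' @param par Parameter name (see `fit$par_names`).
#' @return Numeric vector of pooled kept draws.
#' @export
pooled_draws <- function(fit, par) {
  if (!par %in% fit$par_names) stop("unknown parameter: ", par)
  unlist(lapply(fit$draws, function(d) d[, par]), use.names = FALSE)
}

#' Posterior means of the hyperparameters carried into the posterior model
#'
#' @param fit A converged prior-model `rsa_fit`.
#' @return List with `w` and `mu` (named list by domain size) at their
#'   posterior means (each `mu_k` renormalized).
#' @export
prior_fit_means <- function(fit) {
  stopifnot(inherits(fit, "rsa_fit"), fit$model == "prior")
  mu <- lapply(fit$uk, function(k) {
    m <- vapply(0:k, function(c) mean(pooled_draws(fit, sprintf("mu%d[%d]", k, c))),
                numeric(1))
    m / sum(m)
  })
  names(mu) <- fit$uk
  list(w = mean(pooled_draws(fit, "w")), mu = mu)
}

#' Split potential-scale-reduction factor
#'
#' Each chain is split in half and the usual between/within variance ratio
#' is computed over the resulting 2m sequences.
#'
#' @param chains List of numeric vectors (one per chain).
#' @return The split R-hat (NA for constant draws).
#' @export
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    n <- length(x) %/% 2L
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Highest-density interval of a sample
#'
#' Shortest interval containing the requested posterior mass.
#'
#' @param x Numeric sample.
#' @param prob Mass to cover (default 0.95).
#' @return Named vector `c(lower, upper)`.
#' @export
hdi <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2) stop("need at least two finite values")
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m])
}
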