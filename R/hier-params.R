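#' Hyperparameters of the prior-belief slider model
#'
#' The hierarchical model for prior-probe slider data: population mean
#' size-class probabilities `mu_k` (length `k + 1`, over target-set sizes
#' `0..k`) with Dirichlet concentration `w`, an endpoint-aversion
#' coefficient `kappa` acting multiplicatively on the logit scale, and a
#' logit-normal response variance `sigma2`.
#'
#' @param kappa Positive logit-scale coefficient; 1 means slider values map
#'   linearly (in logit space) onto beliefs.
#' @param w Positive Dirichlet concentration of participant beliefs around
#'   `mu_k`; larger values mean a more homogeneous population.
#' @param sigma2 Positive response variance on the logit scale.
#' @param mu Named list of size-class probability vectors, one per domain
#'   size (names are the `k` values, each vector of length `k + 1` summing
#'   to 1).
#' @return A list of class `prior_hyperparams`.
#' @export
prior_hyperparams <- function(kappa = 1, w = 20, sigma2 = 0.25,
                              mu = default_mu(2:4)) {
  stopifnot(kappa > 0, w > 0, sigma2 > 0, is.list(mu), length(mu) > 0)
  for (nm in names(mu)) {
    k <- as.integer(nm)
    if (length(mu[[nm]]) != k + 1L)
      stop("mu[['", nm, "']] must have length ", k + 1L)
    check_prior(mu[[nm]])
  }
  structure(list(kappa = kappa, w = w, sigma2 = sigma2, mu = mu),
            class = "prior_hyperparams")
}

#' Size-class probabilities from an individual-level acting probability
#'
#' Binomial distribution over target-set sizes `0..k` when each individual
#' acts independently with probability `p`.
#'
#' @param k Domain size.
#' @param p Acting probability in (0, 1).
#' @return Probability vector of length `k + 1`.
#' @export
binomial_size_probs <- function(k, p) {
  stats::dbinom(0:k, k, p)
}

# default population means: independent acting probability 0.47, under
# which the exhaustive-state share of the focus-compatible prior mass at
# k = 2 is 1 - p = 0.53 (the mid-scale "usually, some" reading)
default_mu <- function(domain_sizes, p = 0.47) {
  mu <- lapply(domain_sizes, binomial_size_probs, p = p)
  names(mu) <- domain_sizes
  mu
}

#' Hyperparameters of the posterior-belief slider model
#'
#' Extends the prior-belief model by a population distribution of the
#' listener's soft-max rationality: `alpha_j ~ Gamma` with mean `mu_alpha`
#' and variance `sigma2_alpha` (shape `mu_alpha^2 / sigma2_alpha`, rate
#' `mu_alpha / sigma2_alpha`).  The concentration `w` and size-class means
#' `mu_k` are carried over (fixed) from a prior-model fit.
#'
#' @param mu_alpha Positive population mean of `alpha_j`.
#' @param sigma2_alpha Positive population variance of `alpha_j`.
#' @param kappa,sigma2,w,mu As in [prior_hyperparams()].
#' @return A list of class `posterior_hyperparams`.
#' @export
posterior_hyperparams <- function(mu_alpha = 3, sigma2_alpha = 1, kappa = 1,
                                  sigma2 = 0.25, w = 20,
                                  mu = default_mu(2:4)) {
  stopifnot(mu_alpha > 0, sigma2_alpha > 0)
  base <- prior_hyperparams(kappa, w, sigma2, mu)
  structure(c(list(mu_alpha = mu_alpha, sigma2_alpha = sigma2_alpha),
              unclass(base)),
            class = "posterior_hyperparams")
}

#' Logit-scale response location for a belief value
#'
#' The location of the logit-normal response channel:
#' `kappa * logit(q)`.  `kappa = 1` is the identity in logit space;
#' `kappa < 1` compresses responses away from the endpoints (endpoint
#' aversion), `kappa > 1` stretches them toward the endpoints.
#'
#' @param q Belief probability; must lie strictly inside (0, 1) (slider
#'   values are clipped with [clip_unit()] before use).
#' @param kappa Logit-scale coefficient.
#' @return `kappa * logit(q)`.
#' @export
slider_link <- function(q, kappa) {
  if (any(q <= 0 | q >= 1)) stop("`q` must lie strictly inside (0, 1)")
  kappa * stats::qlogis(q)
}

#' Clip slider values into the open unit interval
#'
#' Responses of exactly 0 or 1 have no finite logit; they are clipped to
#' `eps` and `1 - eps` before the logit transform.
#'
#' @param x Numeric vector in \[0, 1\].
#' @param eps Clipping margin (default 1e-3).
#' @return Clipped vector.
#' @export
clip_unit <- function(x, eps = 1e-3) {
  pmin(pmax(x, eps), 1 - eps)
}

ldirichlet <- function(x, alpha) {
  sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

linvgamma <- function(x, shape, scale) {
  shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x
}

item_key <- function(data) {
  paste(data$participant_id, data$probe, data$prior_type, data$domain_size,
        data$scenario, sep = "|")
}

#' Joint log density of the prior-belief model
#'
#' Sum of the hyperprior, Dirichlet population, and logit-normal response
#' log densities for a prior-probe slider dataset at the given parameter
#' values (natural scale, no transform Jacobians).  Used as a readable
#' reference for the compiled sampler's target.
#'
#' @param data Prior-probe slider records (one slider per state).
#' @param params List with `kappa`, `w`, `sigma2`, `mu` (named list by
#'   domain size) and `beliefs`: a named list, keyed by the item key
#'   `participant|probe|prior_type|k|scenario`, of size-class probability
#'   vectors `p_jk` (length `k + 1`).
#' @param response Column to treat as the modeled response: `"raw"` for
#'   model-scale values or `"normalized"` (requires
#'   [normalize_responses()] first).
#' @return The joint log density (finite for interior parameter values).
#' @export
prior_model_logdensity <- function(data, params, response = "raw") {
  val <- response_column(data, response)
  if (any(val < 0 | val > 1)) stop("responses must lie in [0, 1]")
  lp <- stats::dgamma(params$kappa, 5, rate = 5, log = TRUE) +
    stats::dgamma(params$w, 2, rate = 0.1, log = TRUE) +
    linvgamma(params$sigma2, 1, 1)
  for (nm in names(params$mu))
    lp <- lp + ldirichlet(params$mu[[nm]], rep(1, as.integer(nm) + 1L))
  keys <- item_key(data)
  for (key in unique(keys)) {
    rows <- which(keys == key)
    k <- data$domain_size[rows[1]]
    p <- params$beliefs[[key]]
    if (is.null(p)) stop("no beliefs supplied for item ", key)
    lp <- lp + ldirichlet(p, params$w * params$mu[[as.character(k)]])
    m <- state_size(data$state_index[rows])
    Q <- p[m + 1L] / choose(k, m)
    lp <- lp + sum(stats::dnorm(stats::qlogis(clip_unit(val[rows])),
                                slider_link(clip_unit(Q), params$kappa),
                                sqrt(params$sigma2), log = TRUE))
  }
  lp
}

#' Joint log density of the posterior-belief model
#'
#' As [prior_model_logdensity()] for posterior-probe data (sliders over
#' focus-compatible states), with per-participant rationalities `alpha_j`
#' and the RSA bridge linking prior to posterior beliefs; `w` and `mu` act
#' as fixed constants carried from a prior fit (no hyperprior term).
#'
#' @param data Posterior-probe slider records.
#' @param params List with `kappa`, `sigma2`, `mu_alpha`, `sigma2_alpha`,
#'   fixed `w` and `mu`, `alpha` (named by participant id) and `beliefs`
#'   (named list by item key of size-class vectors).
#' @param response As in [prior_model_logdensity()].
#' @return The joint log density.
#' @export
posterior_model_logdensity <- function(data, params, response = "raw") {
  val <- response_column(data, response)
  if (any(val < 0 | val > 1)) stop("responses must lie in [0, 1]")
  lp <- stats::dgamma(params$kappa, 5, rate = 5, log = TRUE) +
    linvgamma(params$sigma2, 1, 1) +
    stats::dgamma(params$mu_alpha, 5, rate = 5, log = TRUE) +
    linvgamma(params$sigma2_alpha, 1, 1)
  shape <- params$mu_alpha^2 / params$sigma2_alpha
  rate <- params$mu_alpha / params$sigma2_alpha
  for (j in names(params$alpha))
    lp <- lp + stats::dgamma(params$alpha[[j]], shape, rate = rate, log = TRUE)
  keys <- item_key(data)
  for (key in unique(keys)) {
    rows <- which(keys == key)
    k <- data$domain_size[rows[1]]
    j <- as.character(data$participant_id[rows[1]])
    p <- params$beliefs[[key]]
    if (is.null(p)) stop("no beliefs supplied for item ", key)
    lp <- lp + ldirichlet(p, params$w * params$mu[[as.character(k)]])
    Qfull <- expand_size_probs(p, k)
    Qc <- condition_on_focus(Qfull)
    Qpost <- rsa_bridge(Qc, params$alpha[[j]])
    ord <- match(data$state_index[rows], as.integer(names(Qpost)))
    if (anyNA(ord)) stop("posterior-probe states must be focus-compatible")
    lp <- lp + sum(stats::dnorm(stats::qlogis(clip_unit(val[rows])),
                                slider_link(clip_unit(Qpost[ord]), params$kappa),
                                sqrt(params$sigma2), log = TRUE))
  }
  lp
}

response_column <- function(data, response = c("raw", "normalized")) {
  response <- match.arg(response)
  if (response == "normalized") {
    if (is.null(data$normalized_value))
      stop("no `normalized_value` column; run normalize_responses() first")
    data$normalized_value
  } else {
    data$raw_value
  }
}
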