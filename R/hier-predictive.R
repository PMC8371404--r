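#' Vectorized RSA bridge over many belief vectors
#'
#' Row-wise version of [rsa_bridge()] under the default focus-only plus
#' null, zero-cost lexicon: maps size-class beliefs and per-row
#' rationalities to posterior beliefs over the focus-compatible states.
#'
#' @param pmat Matrix (rows = participants) of size-class probabilities,
#'   `k + 1` columns.
#' @param alpha Vector of nonnegative rationalities, one per row.
#' @param k Domain size.
#' @return Matrix (rows x `2^(k-1)`) of posterior beliefs over compatible
#'   states in ascending state-index order; rows sum to 1.
#' @export
rsa_bridge_matrix <- function(pmat, alpha, k) {
  pmat <- as.matrix(pmat)
  stopifnot(ncol(pmat) == k + 1, length(alpha) == nrow(pmat))
  states <- 0:(2^k - 1L)
  m <- state_size(states)
  Qf <- pmat[, m + 1L, drop = FALSE] / rep(choose(k, m), each = nrow(pmat))
  lq <- log(Qf)
  lmass <- matrix(NA_real_, nrow(pmat), 2^k - 1L)
  for (e in seq_len(2^k - 1L)) {
    sup <- which(bitwAnd(states, e) == e)
    lmass[, e] <- log(rowSums(Qf[, sup, drop = FALSE]))
  }
  compat <- states[bitwAnd(states, 1L) == 1L]
  W <- matrix(NA_real_, nrow(pmat), length(compat))
  for (ii in seq_along(compat)) {
    i <- compat[ii]
    den <- exp(alpha * lq[, i + 1L])            # null message, mass 1
    subs <- which(bitwAnd(i, seq_len(2^k - 1L)) == seq_len(2^k - 1L))
    for (e in subs)
      den <- den + exp(alpha * (lq[, i + 1L] - lmass[, e]))
    num <- exp(alpha * (lq[, i + 1L] - lmass[, 1L]))
    W[, ii] <- num / den * Qf[, i + 1L]
  }
  out <- W / rowSums(W)
  colnames(out) <- compat
  out
}

#' Posterior-predictive highest-density intervals for population averages
#'
#' Draws replicated cohorts from the fitted model's posterior predictive
#' distribution and returns, per domain size and state, the 95% (by
#' default) highest-density interval of the population-average slider
#' value.
#'
#' @param fit An `rsa_fit` from [fit_prior_model()] or
#'   [fit_posterior_model()].
#' @param n_draws Number of posterior-predictive cohort replicates (at
#'   least 100).
#' @param prob Interval mass.
#' @param n_participants Cohort size per domain size; defaults to the
#'   number of fitted items per domain size.
#' @return Data frame with `domain_size`, `state_index`, predictive `mean`,
#'   `lower` and `upper`.
#' @export
posterior_predictive_hdi <- function(fit, n_draws = 2000, prob = 0.95,
                                     n_participants = NULL) {
  stopifnot(inherits(fit, "rsa_fit"))
  if (n_draws < 100) stop("`n_draws` must be at least 100")
  all_draws <- do.call(rbind, fit$draws)
  pick <- sample.int(nrow(all_draws), n_draws, replace = TRUE)
  kappa <- all_draws[pick, "kappa"]
  sigma <- sqrt(all_draws[pick, "sigma2"])
  out <- list()
  for (k in fit$uk) {
    npart <- if (is.null(n_participants))
      sum(fit$items$domain_size == k) else n_participants
    if (fit$model == "prior") {
      w <- all_draws[pick, "w"]
      mu <- all_draws[pick, sprintf("mu%d[%d]", k, 0:k), drop = FALSE]
      states <- 0:(2^k - 1L)
      msz <- state_size(states)
      cohort <- matrix(NA_real_, n_draws, length(states))
      for (d in seq_len(n_draws)) {
        p <- rdirichlet(npart, w[d] * mu[d, ])
        Q <- p[, msz + 1L, drop = FALSE] / rep(choose(k, msz), each = npart)
        resp <- stats::plogis(stats::rnorm(length(Q),
                                           kappa[d] * stats::qlogis(Q),
                                           sigma[d]))
        cohort[d, ] <- colMeans(matrix(resp, npart))
      }
    } else {
      mu_a <- all_draws[pick, "mu_alpha"]
      s2_a <- all_draws[pick, "sigma2_alpha"]
      mu_k <- fit$fixed$mu[[as.character(k)]]
      states <- 2L * seq_len(2^(k - 1L)) - 1L
      cohort <- matrix(NA_real_, n_draws, length(states))
      for (d in seq_len(n_draws)) {
        p <- rdirichlet(npart, fit$fixed$w * mu_k)
        a <- stats::rgamma(npart, mu_a[d]^2 / s2_a[d],
                           rate = mu_a[d] / s2_a[d])
        Q <- rsa_bridge_matrix(p, a, k)
        resp <- stats::plogis(stats::rnorm(length(Q),
                                           kappa[d] * stats::qlogis(Q),
                                           sigma[d]))
        cohort[d, ] <- colMeans(matrix(resp, npart))
      }
    }
    iv <- apply(cohort, 2L, hdi, prob = prob)
    out[[as.character(k)]] <- data.frame(
      domain_size = k, state_index = states,
      mean = colMeans(cohort), lower = iv["lower", ], upper = iv["upper", ])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Posterior-predictive p-values for exhaustive-state responses
#'
#' For every participant-item, the observed exhaustive-state slider value
#' is compared with its posterior-predictive distribution under that
#' participant's fitted parameters; the two-sided p-value doubles the
#' smaller tail (capped at 1).  A small fraction of values below 0.05 is
#' expected under a well-fitting model.
#'
#' @param fit An `rsa_fit`.
#' @param data Optional dataset for validation; the fit's stored responses
#'   are used.
#' @return List of class `ppp_result` with `table` (one row per item:
#'   observed value and `p_value`) and `fraction_below_0.05`.
#' @export
posterior_predictive_pvalues <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "rsa_fit"))
  if (!is.null(data) && nrow(data[data$probe == sub("_.*", "", fit$model), ]) == 0)
    stop("`data` has no records for the fitted probe")
  all_draws <- do.call(rbind, fit$draws)
  all_pred <- do.call(rbind, fit$mu_pred)
  sigma <- sqrt(all_draws[, "sigma2"])
  idx <- fit$index
  rows <- list()
  for (i in seq_len(nrow(fit$items))) {
    sel <- which(idx$item == i & idx$state_index == 1L)
    if (length(sel) != 1L) {
      warning("item ", fit$items$key[i],
              " has no exhaustive-state response; skipped")
      next
    }
    obs <- idx$y[sel]
    rep_y <- stats::rnorm(nrow(all_pred), all_pred[, idx$slider_col[sel]], sigma)
    p_lo <- mean(rep_y <= obs)
    p_hi <- mean(rep_y >= obs)
    rows[[length(rows) + 1L]] <- data.frame(
      participant_id = fit$items$participant_id[i],
      domain_size = fit$items$domain_size[i],
      scenario = fit$items$scenario[i],
      observed = stats::plogis(obs),
      p_value = min(1, 2 * min(p_lo, p_hi)))
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab,
                 fraction_below_0.05 = mean(tab$p_value < 0.05)),
            class = "ppp_result")
}

#' @export
print.ppp_result <- function(x, ...) {
  cat("<ppp_result>", nrow(x$table), "exhaustive-state responses;",
      sprintf("%.1f%%", 100 * x$fraction_below_0.05), "with p < 0.05\n")
  invisible(x)
}
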