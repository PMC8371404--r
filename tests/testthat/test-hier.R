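# independently coded brute-force densities used as oracles below
oracle_prior_density <- function(data, params) {
  ld_dir <- function(x, a)
    lgamma(sum(a)) - sum(lgamma(a)) + sum((a - 1) * log(x))
  ld_norm <- function(x, m, v) -0.5 * log(2 * pi * v) - (x - m)^2 / (2 * v)
  ld_gamma <- function(x, sh, ra)
    sh * log(ra) - lgamma(sh) + (sh - 1) * log(x) - ra * x
  lp <- ld_gamma(params$kappa, 5, 5) + ld_gamma(params$w, 2, 0.1) +
    (-(1 + 1) * log(params$sigma2) - 1 / params$sigma2 - lgamma(1))
  for (nm in names(params$mu))
    lp <- lp + ld_dir(params$mu[[nm]], rep(1, as.integer(nm) + 1))
  keys <- paste(data$participant_id, data$probe, data$prior_type,
                data$domain_size, data$scenario, sep = "|")
  for (key in unique(keys)) {
    rw <- keys == key
    k <- data$domain_size[rw][1]
    p <- params$beliefs[[key]]
    lp <- lp + ld_dir(p, params$w * params$mu[[as.character(k)]])
    for (r in which(rw)) {
      m <- sum(as.integer(intToBits(data$state_index[r])))
      Q <- min(max(p[m + 1] / choose(k, m), 1e-3), 1 - 1e-3)
      obs <- min(max(data$raw_value[r], 1e-3), 1 - 1e-3)
      lp <- lp + ld_norm(log(obs / (1 - obs)),
                         params$kappa * log(Q / (1 - Q)), params$sigma2)
    }
  }
  lp
}

test_that("prior-model log density matches a brute-force oracle on toy data", {
  dat <- tiny_prior_dataset(n = 2)
  keys <- unique(paste(dat$participant_id, dat$probe, dat$prior_type,
                       dat$domain_size, dat$scenario, sep = "|"))
  set.seed(5)
  beliefs <- lapply(keys, function(key) {
    k <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]][4])
    as.vector(rsafocus:::rdirichlet(1, rep(2, k + 1)))
  })
  names(beliefs) <- keys
  params <- list(kappa = 1.1, w = 15, sigma2 = 0.3,
                 mu = list("2" = c(0.3, 0.5, 0.2),
                           "3" = c(0.2, 0.4, 0.3, 0.1)),
                 beliefs = beliefs)
  expect_equal(prior_model_logdensity(dat, params),
               oracle_prior_density(dat, params), tolerance = 1e-8)
  expect_true(is.finite(prior_model_logdensity(dat, params)))
  # density falls as the response variance collapses on nonzero residuals
  params_small <- params; params_small$sigma2 <- 1e-5
  expect_lt(prior_model_logdensity(dat, params_small),
            prior_model_logdensity(dat, params))
})

test_that("posterior-model log density is finite, bridge-consistent, and rejects bad input", {
  dat <- tiny_posterior_dataset(n = 2)
  keys <- unique(paste(dat$participant_id, dat$probe, dat$prior_type,
                       dat$domain_size, dat$scenario, sep = "|"))
  set.seed(6)
  beliefs <- lapply(keys, function(key) {
    k <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]][4])
    as.vector(rsafocus:::rdirichlet(1, rep(2, k + 1)))
  })
  names(beliefs) <- keys
  alph <- as.list(setNames(c(2, 4), unique(dat$participant_id)))
  params <- list(kappa = 1, sigma2 = 0.25, mu_alpha = 3, sigma2_alpha = 1,
                 w = 20,
                 mu = list("2" = c(0.3, 0.5, 0.2),
                           "3" = c(0.2, 0.4, 0.3, 0.1)),
                 alpha = alph, beliefs = beliefs)
  lp <- posterior_model_logdensity(dat, params)
  expect_true(is.finite(lp))
  bad <- dat; bad$raw_value[1] <- 1.4
  expect_error(posterior_model_logdensity(bad, params), "\\[0, 1\\]")
})

test_that("the alpha population distribution has the stated mean and variance", {
  set.seed(7)
  mu_a <- 3; s2_a <- 1.5
  x <- rgamma(1e5, mu_a^2 / s2_a, rate = mu_a / s2_a)
  expect_equal(mean(x), mu_a, tolerance = 0.02)
  expect_equal(var(x), s2_a, tolerance = 0.05)
})

test_that("the slider link is linear in logit space with slope kappa", {
  expect_equal(slider_link(0.5, 3), 0)
  expect_equal(slider_link(0.9, 1), qlogis(0.9))
  expect_equal(slider_link(0.9, 2), 2 * qlogis(0.9))
  expect_error(slider_link(0, 1), "strictly inside")
  expect_equal(clip_unit(c(-1, 0.5, 2)), c(1e-3, 0.5, 1 - 1e-3))
})

test_that("prior-model fits are seed-reproducible and recover generating values", {
  mu_true <- list("2" = binomial_size_probs(2, 0.4),
                  "3" = binomial_size_probs(3, 0.4))
  hp <- prior_hyperparams(kappa = 1, w = 20, sigma2 = 0.25, mu = mu_true)
  dat <- generate_dataset(
    experiment_design(1, "prior", domain_sizes = 2:3, n_participants = 20),
    hyper = hp, seed = 23)
  cfg <- mcmc_config(chains = 2, iterations = 1200, seed = 31)
  f1 <- suppressWarnings(fit_prior_model(dat, cfg))
  f2 <- suppressWarnings(fit_prior_model(dat, cfg))
  expect_identical(f1$draws, f2$draws)
  expect_equal(length(unique(vapply(f1$draws, nrow, integer(1)))), 1L)
  expect_true(all(is.finite(f1$diagnostics$rhat)))
  expect_named(f1$diagnostics$rhat, f1$par_names, ignore.order = TRUE)
  # generating hyperparameters inside their 95% HDIs
  for (chk in list(c("kappa", 1), c("w", 20), c("sigma2", 0.25))) {
    iv <- hdi(pooled_draws(f1, chk[1]))
    expect_gt(as.numeric(chk[2]), iv[1] - 1e-12)
    expect_lt(as.numeric(chk[2]), iv[2] + 1e-12)
  }
  expect_error(fit_prior_model(dat[0, ]), "no prior-probe records")
})

test_that("posterior-model fits are seed-reproducible and need fixed hyperparameters", {
  mu_true <- list("2" = binomial_size_probs(2, 0.4))
  hp <- posterior_hyperparams(mu_alpha = 3, sigma2_alpha = 1,
                              kappa = 1, sigma2 = 0.25, w = 20, mu = mu_true)
  dat <- generate_dataset(
    experiment_design(1, "posterior", domain_sizes = 2, n_participants = 15),
    hyper = hp, seed = 22)
  expect_error(fit_posterior_model(dat, list()), "fixed")
  cfg <- mcmc_config(chains = 2, iterations = 800, seed = 32)
  f1 <- suppressWarnings(fit_posterior_model(dat, list(w = 20, mu = mu_true), cfg))
  f2 <- suppressWarnings(fit_posterior_model(dat, list(w = 20, mu = mu_true), cfg))
  expect_identical(f1$draws, f2$draws)
  expect_true(all(c("mu_alpha", "sigma2_alpha") %in% f1$par_names))
  expect_true(all(startsWith(
    grep("^alpha", f1$par_names, value = TRUE), "alpha[P")))
})

test_that("participants with consistently high exhaustive sliders get larger alpha", {
  # two artificial participants at k = 2: one answering like a confident
  # exhaustive interpreter, one hedging toward the non-exhaustive state
  mk <- function(pid, exh) {
    data.frame(participant_id = pid, experiment = 1, probe = "posterior",
               scenario = c("s1", "s1"), domain_size = 2,
               prior_type = "some", state_index = c(1L, 3L),
               slider_label = c("A", "A+B"), raw_value = c(exh, 1 - exh),
               response_time_s = 40, seed = 0)
  }
  dat <- rbind(mk("HI", 0.95), mk("LO", 0.60))
  fixed <- list(w = 20, mu = list("2" = binomial_size_probs(2, 0.47)))
  fit <- suppressWarnings(fit_posterior_model(
    dat, fixed, mcmc_config(chains = 2, iterations = 1000, seed = 33)))
  expect_gt(mean(pooled_draws(fit, "alpha[HI]")),
            mean(pooled_draws(fit, "alpha[LO]")))
})

test_that("split R-hat separates mixed from unmixed chains", {
  set.seed(8)
  good <- replicate(4, rnorm(200), simplify = FALSE)
  bad <- list(rnorm(200), rnorm(200) + 5, rnorm(200), rnorm(200) - 5)
  expect_lt(split_rhat(good), 1.05)
  expect_gt(split_rhat(bad), 1.5)
})

test_that("hdi returns the shortest covering interval", {
  set.seed(9)
  x <- c(rnorm(5000), rnorm(200, 10))
  iv <- hdi(x, 0.9)
  expect_lt(iv["upper"], 5)          # excludes the minor mode
  expect_lt(iv["lower"], iv["upper"])
  xs <- sort(rnorm(1000))
  iv2 <- hdi(xs, 0.5)
  expect_lte(sum(xs >= iv2[1] & xs <= iv2[2]) / 1000 - 0.5, 0.01)
})
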