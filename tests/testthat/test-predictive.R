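# a small shared prior fit for the predictive checks
small_prior_fit <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      dat <- generate_dataset(
        experiment_design(1, "prior", domain_sizes = 2:3,
                          n_participants = 15),
        hyper = prior_hyperparams(mu = list("2" = binomial_size_probs(2, 0.4),
                                            "3" = binomial_size_probs(3, 0.4))),
        seed = 61)
      fit <<- suppressWarnings(
        fit_prior_model(dat, mcmc_config(chains = 2, iterations = 1500,
                                         seed = 62)))
    }
    fit
  }
})

test_that("posterior-predictive intervals are proper and bracket the data means", {
  fit <- small_prior_fit()
  set.seed(63)
  iv <- posterior_predictive_hdi(fit, n_draws = 400)
  expect_true(all(iv$lower <= iv$upper))
  expect_equal(nrow(iv), 4 + 8)
  expect_error(posterior_predictive_hdi(fit, n_draws = 50), "at least 100")
  # the observed population means of model-generated data fall inside most
  # of their own intervals
  obs <- tapply(fit$index$raw_value,
                list(fit$index$domain_size, fit$index$state_index), mean)
  inside <- mapply(function(k, s, lo, hi) {
    m <- obs[as.character(k), as.character(s)]
    m >= lo & m <= hi
  }, iv$domain_size, iv$state_index, iv$lower, iv$upper)
  expect_gte(mean(inside), 0.8)
})

test_that("posterior-predictive p-values are calibrated on model-generated data", {
  fit <- small_prior_fit()
  set.seed(64)
  pp <- posterior_predictive_pvalues(fit)
  expect_true(all(pp$table$p_value >= 0 & pp$table$p_value <= 1))
  expect_equal(nrow(pp$table), nrow(fit$items))
  expect_lte(pp$fraction_below_0.05, 0.2)
  # a response at the predictive median is unsurprising
  med_item <- 1L
  sel <- fit$index$item == med_item & fit$index$state_index == 1L
  all_pred <- do.call(rbind, fit$mu_pred)
  fit2 <- fit
  fit2$index$y[sel] <- median(all_pred[, fit$index$slider_col[sel]])
  pp2 <- posterior_predictive_pvalues(fit2)
  expect_gt(pp2$table$p_value[med_item], 0.5)
})
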