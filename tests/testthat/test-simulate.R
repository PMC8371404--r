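test_that("designs validate their combinations and default to the documented arm sizes", {
  d1 <- experiment_design(1, "prior")
  expect_equal(d1$n_participants, 30L)
  expect_equal(experiment_design(1, "posterior")$n_participants, 66L)
  expect_equal(experiment_design(2, "prior", domain_sizes = 2,
                                 prior_type = "none")$n_participants, 49L)
  expect_equal(experiment_design(2, "posterior", domain_sizes = 2,
                                 prior_type = "all")$n_participants, 63L)
  expect_equal(experiment_design(2, "prior", domain_sizes = 2,
                                 prior_type = "none")$items_per_participant, 1L)
  expect_error(experiment_design(2, "prior", domain_sizes = 2:4,
                                 prior_type = "all"), "domain size 2 only")
  expect_error(experiment_design(1, "prior", prior_type = "all"), "some")
})

test_that("slider counts per item follow the two experiment designs", {
  d <- generate_dataset(experiment_design(1, "prior", n_participants = 3),
                        seed = 1)
  counts <- table(d$domain_size[d$participant_id == "P001"])
  expect_equal(as.integer(counts[c("2", "3", "4")]), c(4L, 8L, 16L))
  d <- generate_dataset(experiment_design(1, "posterior", n_participants = 3),
                        seed = 1)
  counts <- table(d$domain_size[d$participant_id == "P001"])
  expect_equal(as.integer(counts[c("2", "3", "4")]), c(2L, 4L, 8L))
  d <- generate_dataset(experiment_design(2, "prior", n_participants = 3),
                        seed = 1)
  expect_true(all(table(paste(d$participant_id, d$domain_size)) == 2))
  expect_setequal(unique(d$slider_label[is.na(d$state_index)]),
                  "pooled_nonexh")
})

test_that("identical seeds give byte-identical datasets, different seeds differ", {
  des <- experiment_design(1, "prior", n_participants = 4)
  a <- generate_dataset(des, seed = 77)
  b <- generate_dataset(des, seed = 77)
  c <- generate_dataset(des, seed = 78)
  expect_identical(a, b)
  expect_false(identical(a$raw_value, c$raw_value))
})

test_that("prior-wording presets give exhaustive-state priors 0.73 / 0.53 / 0.30 at k = 2", {
  shares <- vapply(c("none", "some", "all"), function(pt) {
    hp <- prior_type_hyperparams(pt, 2)
    Q <- expand_size_probs(hp$mu[["2"]], 2)
    unname(condition_on_focus(Q)["1"])
  }, numeric(1))
  expect_equal(unname(shares), c(0.73, 0.53, 0.30), tolerance = 1e-12)
  expect_true(all(diff(shares) < 0))   # none > some > all
  # the "some" preset is the generator default
  expect_equal(prior_type_hyperparams("some", 2:4)$mu,
               prior_hyperparams()$mu)
  expect_error(prior_type_hyperparams("all", 4), "domain size 2")
  expect_error(prior_type_hyperparams("weird"), "none/some/all")
})

test_that("model-scale responses track the generating beliefs with unit slope", {
  hp <- prior_hyperparams(kappa = 1, w = 200, sigma2 = 0.05,
                          mu = list("3" = binomial_size_probs(3, 0.4)))
  d <- generate_dataset(experiment_design(1, "prior", domain_sizes = 3,
                                          n_participants = 60),
                        hyper = hp, seed = 5)
  d <- normalize_responses(d)
  Q <- expand_size_probs(binomial_size_probs(3, 0.4), 3)
  obs <- tapply(d$normalized_value, d$state_index, mean)
  fitln <- stats::lm(qlogis(clip_unit(obs)) ~ qlogis(Q))
  expect_equal(unname(coef(fitln)[2]), 1, tolerance = 0.1)
})

test_that("non-normalizing responses make raw sums grow with the slider count", {
  des <- experiment_design(1, "prior", n_participants = 25)
  d <- generate_dataset(des, behavior = response_behavior("non_normalizing"),
                        seed = 14)
  sums <- tapply(d$raw_value, list(rsafocus:::item_key(d)), sum)
  ks <- tapply(d$domain_size, list(rsafocus:::item_key(d)), `[`, 1L)
  mean_by_k <- tapply(sums, ks, mean)
  expect_true(all(diff(mean_by_k[c("2", "3", "4")]) > 0))
  expect_gt(mean_by_k[["2"]], 1)
})

test_that("two-slider model-based data keep raw sums near one", {
  des <- experiment_design(2, "posterior", n_participants = 40)
  d <- generate_dataset(des, seed = 15)
  sums <- tapply(d$raw_value, list(rsafocus:::item_key(d)), sum)
  ks <- tapply(d$domain_size, list(rsafocus:::item_key(d)), `[`, 1L)
  mean_by_k <- tapply(sums, ks, mean)
  expect_true(all(mean_by_k >= 0.9 & mean_by_k <= 1.2))
})

test_that("constant-null data hold the exhaustive slider at the level for every k", {
  des <- experiment_design(1, "posterior", n_participants = 10)
  d0 <- generate_constant_null_dataset(des, level = 0.9, noise = 0, seed = 3)
  exh <- d0$state_index == 1L
  expect_true(all(d0$raw_value[exh] == 0.9))
  expect_true(all(d0$raw_value[!exh] == 0.2))
  dn <- generate_constant_null_dataset(des, level = 0.7, noise = 0.05,
                                       seed = 4)
  m <- tapply(dn$raw_value[dn$state_index == 1L],
              dn$domain_size[dn$state_index == 1L], mean)
  expect_true(all(abs(m - 0.7) < 0.05))
  # Monte-Carlo: the empirical mean matches the level within 3 SEs
  big <- generate_constant_null_dataset(
    experiment_design(2, "posterior", n_participants = 5000),
    level = 0.6, noise = 0.05, seed = 5)
  x <- big$raw_value[which(big$state_index == 1L)]
  expect_lt(abs(mean(x) - 0.6), 3 * sd(x) / sqrt(length(x)))
})

test_that("injected fast and all-zero participants appear on top of the clean arm", {
  des <- experiment_design(1, "prior", n_participants = 10)
  d <- generate_dataset(des,
                        behavior = response_behavior(fast_frac = 0.2,
                                                     allzero_frac = 0.1),
                        seed = 6)
  expect_equal(length(unique(d$participant_id)), 13L)
  rt <- tapply(d$response_time_s, rsafocus:::item_key(d), min)
  expect_equal(sum(tapply(rt, sub("\\|.*", "", names(rt)), min) < 15), 2L)
  zero <- tapply(d$raw_value, rsafocus:::item_key(d),
                 function(v) all(v == 0))
  expect_equal(length(unique(sub("\\|.*", "", names(zero)[zero]))), 1L)
})
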