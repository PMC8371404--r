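test_that("lexicon variants contain the documented expressions and costs", {
  expect_equal(nrow(build_lexicon(3, include_null = FALSE)$denot), 7)
  expect_equal(nrow(build_lexicon(3)$denot), 8)
  expect_equal(nrow(build_lexicon(3, "collapsed_two_state")$denot), 2)
  # every nonempty subset as focus and as exclusive: 2 * (2^2 - 1) = 6
  expect_equal(nrow(build_lexicon(2, "focus_plus_exclusives",
                                  include_null = FALSE)$denot), 6)
  lex <- build_lexicon(3, "focus_plus_exclusives", cost_per_word = 0.5)
  expr <- lex$expressions
  expect_equal(expr$cost[expr$kind == "focus"],
               0.5 * state_size(expr$mentioned[expr$kind == "focus"]))
  expect_equal(expr$cost[expr$kind == "exclusive"],
               0.5 * (state_size(expr$mentioned[expr$kind == "exclusive"]) + 1))
  expect_equal(expr$cost[expr$kind == "null"], 0)
  expect_error(build_lexicon(3, "unheard_of"), "variant")
})

test_that("denotations follow at-least semantics for focus, identity for exclusives", {
  lex <- build_lexicon(2, "focus_plus_exclusives")
  sAB <- 3L; sA <- 1L
  expect_true(denotation(lex, "focus[A]", sAB))
  expect_false(denotation(lex, "only[A]", sAB))
  expect_true(denotation(lex, "only[A]", sA))
  expect_false(denotation(lex, "focus[A+B]", sA))
  expect_true(denotation(lex, "null", 0L))
})

test_that("listener and speaker tables reproduce hand-computed values at k = 2", {
  lex <- build_lexicon(2)
  prior <- binomial_prior(2, 0.5)
  L0 <- literal_listener(lex, prior)
  expect_equal(rowSums(L0), setNames(rep(1, 4), rownames(L0)))
  expect_equal(unname(L0["focus[A]", c("1", "3")]), c(0.5, 0.5))
  expect_equal(unname(L0["null", ]), prior)
  S1 <- speaker(L0, 3, lex)
  # state {A}: candidates focus[A] (1/2) and null (1/4); cubes 8 : 1
  expect_equal(unname(S1["1", "focus[A]"]), 8 / 9)
  # state {A,B}: candidates focus A/B (1/2), focus AB (1), null (1/4)
  expect_equal(unname(S1["3", "focus[A]"]), 8 / 81)
  expect_equal(rowSums(S1), setNames(rep(1, 4), rownames(S1)))
  L2 <- pragmatic_listener(S1, prior)
  expect_equal(unname(L2["focus[A]", "1"]), 0.9)
  expect_equal(rowSums(L2), setNames(rep(1, 4), rownames(L2)))
})

test_that("a noiseless alpha = 0 speaker picks uniformly among true expressions", {
  lex <- build_lexicon(2)
  L0 <- literal_listener(lex, binomial_prior(2, 0.5))
  S1 <- speaker(L0, 0, lex)
  expect_equal(unname(S1["1", ]), c(1 / 2, 0, 0, 1 / 2))    # focus[A], null
  expect_equal(unname(S1["3", ]), rep(1 / 4, 4))
  # alpha = 0 without a null message conditions the prior on the denotation
  lex0 <- build_lexicon(2, include_null = FALSE)
  prior <- binomial_prior(2, 0.3)
  S1n <- speaker(literal_listener(lex0, prior), 0, lex0,
                 allow_empty_states = TRUE)   # the empty-set state asserts nothing
  L2 <- pragmatic_listener(S1n, prior)
  denom <- prior[2] / 1 + prior[4] / 3          # foc[A] true in {A}, {A,B}
  expect_equal(unname(L2["focus[A]", "1"]), (prior[2] / 1) / denom,
               tolerance = 1e-12)
})

test_that("speaker errors when some state has no true expression", {
  lex <- build_lexicon(2, include_null = FALSE)  # empty set state uncovered
  L0 <- literal_listener(lex, binomial_prior(2, 0.5))
  expect_error(speaker(L0, 1, lex), "no true expression")
})

test_that("full-matrix exhaustivity equals the closed form on the whole grid", {
  expect_equal(exhaustivity(2, rsa_params(alpha = 3, p = 0.5)), 0.9)
  expect_equal(exhaustivity(2, rsa_params(alpha = 0, p = 0.5)), 2 / 3)
  expect_equal(exhaustivity(4, rsa_params(alpha = 3, p = 0.5)), 0.9^3)
  for (k in 2:6) for (p in c(0.1, 0.5, 0.8)) for (a in c(0, 1, 3)) {
    expect_lt(abs(exhaustivity(k, rsa_params(alpha = a, p = p)) -
                  closed_form_exhaustivity(k, p, a)), 1e-10)
  }
})

test_that("exhaustivity declines in domain size and in the success probability", {
  for (p in c(0.1, 0.5, 0.8)) for (a in c(0, 1, 3)) {
    E <- vapply(2:6, function(k) exhaustivity(k, rsa_params(alpha = a, p = p)),
                numeric(1))
    expect_true(all(diff(E) < 0))
  }
  for (k in 2:5) for (a in c(0, 1, 3)) {
    E <- vapply(c(0.1, 0.5, 0.8), function(p)
      exhaustivity(k, rsa_params(alpha = a, p = p)), numeric(1))
    expect_true(all(diff(E) < 0))
  }
})

test_that("cost, exclusives and collapsed variants lower exhaustivity; constant-prior is flat", {
  E0 <- vapply(2:5, function(k) exhaustivity(k), numeric(1))
  for (cpw in c(0.5, 1)) {
    Ec <- vapply(2:5, function(k)
      exhaustivity(k, rsa_params(cost_per_word = cpw)), numeric(1))
    expect_true(all(Ec[-1] <= E0[-1]))
    expect_true(any(Ec[-1] < E0[-1]))
  }
  Ex <- vapply(2:5, function(k)
    exhaustivity(k, variant = "focus_plus_exclusives"), numeric(1))
  expect_true(all(Ex <= E0))
  Ecl <- vapply(3:5, function(k)
    exhaustivity(k, variant = "collapsed_two_state"), numeric(1))
  expect_true(all(Ecl < E0[-1]))
  Ecp <- vapply(2:6, function(k)
    exhaustivity(k, variant = "collapsed_constant_prior"), numeric(1))
  expect_equal(Ecp, rep(Ecp[1], 5))
})

test_that("the two-state Bayes relation matches its limits and the full model", {
  expect_equal(k2_posterior(1, 0.5), 0.5)
  expect_equal(k2_posterior(0, 0.3), 1)
  expect_equal(k2_posterior(0.2, 0), 0)
  expect_equal(k2_posterior(0.2, 1), 1)
  expect_equal(k2_posterior(1 / 9, 0.5), 0.9)
  # feeding the speaker probability ratio reproduces the pragmatic listener
  set.seed(99)
  for (r in 1:20) {
    p <- runif(1, 0.05, 0.95); a <- runif(1, 0, 5)
    lex <- build_lexicon(2)
    prior <- binomial_prior(2, p)
    S1 <- speaker(literal_listener(lex, prior), a, lex)
    ratio <- S1["3", "focus[A]"] / S1["1", "focus[A]"]
    prior_exh <- prior[2] / (prior[2] + prior[4])
    L2 <- pragmatic_listener(S1, prior)
    expect_equal(k2_posterior(ratio, prior_exh),
                 unname(L2["focus[A]", "1"] / (L2["focus[A]", "1"] +
                                               L2["focus[A]", "3"])),
                 tolerance = 1e-10)
  }
})

test_that("the RSA bridge reproduces the pragmatic listener over compatible states", {
  expect_equal(unname(rsa_bridge(c(0.5, 0.5), 3)), c(0.9, 0.1))
  expect_equal(unname(rsa_bridge(c(1, 0), 3)), c(1, 0))
  for (k in 2:4) for (p in c(0.3, 0.5)) {
    Qc <- condition_on_focus(binomial_prior(k, p))
    br <- rsa_bridge(Qc, 3, Q_full = binomial_prior(k, p))
    expect_equal(unname(br["1"]), exhaustivity(k, rsa_params(p = p)),
                 tolerance = 1e-12)
  }
  # with alpha = 0 the soft-max speaker picks uniformly among true
  # expressions, so each compatible state is reweighted by 1 / #true(i)
  Qf <- expand_size_probs(c(0.2, 0.5, 0.3), 2)
  br0 <- rsa_bridge(condition_on_focus(Qf), 0, Q_full = Qf)
  w0 <- c(Qf[2] / 2, Qf[4] / 4)   # {A}: focus[A] + null; {A,B}: 3 foci + null
  expect_equal(unname(br0), w0 / sum(w0), tolerance = 1e-12)
})

test_that("vectorized bridge agrees with the scalar bridge", {
  set.seed(4)
  for (k in 2:4) {
    pm <- rsafocus:::rdirichlet(5, rep(2, k + 1))
    al <- runif(5, 0, 4)
    B <- rsa_bridge_matrix(pm, al, k)
    for (r in 1:5) {
      Qc <- condition_on_focus(expand_size_probs(pm[r, ], k))
      expect_equal(unname(B[r, ]),
                   unname(rsa_bridge(Qc, al[r],
                                     Q_full = expand_size_probs(pm[r, ], k))),
                   tolerance = 1e-10)
    }
  }
})

test_that("prediction tables cover the requested grid", {
  tab <- exhaustivity_table(k = 2:4, p = c(0.1, 0.5), alpha = c(1, 3))
  expect_equal(nrow(tab), 3 * 2 * 2)
  expect_true(all(tab$exhaustivity > 0 & tab$exhaustivity < 1))
})
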