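test_that("target sets encode to the documented bitmask indices", {
  d <- rsa_domain(c("Audrey", "Bob", "Dale"))
  expect_equal(encode_target_set(c("Audrey", "Bob", "Dale"), d), 7L)
  expect_equal(encode_target_set(character(), d), 0L)
  expect_equal(encode_target_set("Dale", d), 4L)
  expect_equal(encode_target_set(c("Audrey", "Dale"), d), 5L)
  expect_equal(decode_target_set(5L, d), c("Audrey", "Dale"))
  expect_equal(decode_target_set(0L, d), character())
  expect_equal(decode_target_set(7L, d), d$labels)
  expect_error(encode_target_set("Zelda", d), "Zelda")
  expect_error(decode_target_set(8L, d), "2\\^k")
})

test_that("decode is the exact inverse of encode for every subset, k <= 8", {
  for (k in c(2, 3, 5, 8)) {
    d <- rsa_domain(k = k)
    for (i in 0:(2^k - 1)) {
      expect_identical(encode_target_set(decode_target_set(i, d), d),
                       as.integer(i))
    }
  }
})

test_that("state_size counts set bits", {
  expect_equal(state_size(c(0, 1, 2, 3, 7, 255)), c(0, 1, 1, 2, 3, 8))
})

test_that("binomial prior assigns p^m (1-p)^(k-m) per state and normalizes", {
  expect_equal(binomial_prior(2, 0.5), rep(0.25, 4))
  pr <- binomial_prior(3, 0.1)
  expect_equal(pr[1], 0.729)          # empty set: (1-p)^3
  expect_equal(pr[2], 0.081)          # one actor: p (1-p)^2
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  for (p in c(0.1, 0.5, 0.8)) {
    pr <- binomial_prior(4, p)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    m <- state_size(0:15)
    expect_equal(pr, p^m * (1 - p)^(4 - m))
  }
  expect_error(binomial_prior(3, 0), "strictly between")
  expect_error(binomial_prior(3, 1), "strictly between")
})

test_that("back-off prior mixes toward uniform", {
  pr <- c(1, 0, 0, 0)
  expect_equal(backoff_prior(pr, 0), pr)
  expect_equal(backoff_prior(pr, 1), rep(0.25, 4))
  expect_equal(backoff_prior(pr, 0.5), c(0.625, 0.125, 0.125, 0.125))
  expect_error(backoff_prior(pr, 1.5), "\\[0, 1\\]")
})

test_that("size-class expansion splits mass equally within sizes and conserves it", {
  Q <- expand_size_probs(c(0.4, 0.3, 0.2, 0.1), 3)
  expect_equal(Q[encode_target_set(c("A", "B"), rsa_domain(k = 3)) + 1],
               0.2 / 3)
  expect_equal(expand_size_probs(c(0, 1, 0), 2), c(0, 0.5, 0.5, 0))
  for (k in 2:8) {
    ps <- rep(1 / (k + 1), k + 1)
    expect_equal(sum(expand_size_probs(ps, k)), 1, tolerance = 1e-12)
    set.seed(k)
    ps <- as.vector(rsafocus:::rdirichlet(1, rep(1, k + 1)))
    expect_equal(sum(expand_size_probs(ps, k)), 1, tolerance = 1e-12)
  }
  expect_error(expand_size_probs(c(0.5, 0.5), 2), "length")
})

test_that("conditioning on the focus keeps exactly the compatible half", {
  Qc <- condition_on_focus(rep(0.25, 4))
  expect_equal(unname(Qc), c(0.5, 0.5))
  expect_equal(names(Qc), c("1", "3"))
  expect_length(condition_on_focus(binomial_prior(4, 0.3)), 8)
  Q <- c(0.7, 0.3, 0, 0)   # mass on empty set and {A} only
  expect_equal(unname(condition_on_focus(Q)), c(1, 0))
})
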