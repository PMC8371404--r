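# small deterministic fixtures used across test files

tiny_prior_dataset <- function(seed = 11, n = 6, domain_sizes = 2:3) {
  generate_dataset(
    experiment_design(1, "prior", domain_sizes = domain_sizes,
                      n_participants = n),
    hyper = prior_hyperparams(mu = lapply(stats::setNames(domain_sizes,
                                                          domain_sizes),
                                          binomial_size_probs, p = 0.4)),
    seed = seed)
}

tiny_posterior_dataset <- function(seed = 12, n = 6, domain_sizes = 2:3) {
  mu <- lapply(stats::setNames(domain_sizes, domain_sizes),
               binomial_size_probs, p = 0.4)
  generate_dataset(
    experiment_design(1, "posterior", domain_sizes = domain_sizes,
                      n_participants = n),
    hyper = posterior_hyperparams(mu = mu),
    seed = seed)
}
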