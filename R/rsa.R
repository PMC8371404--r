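#' Literal listener distribution
#'
#' The literal listener conditions the state prior on the literal truth of
#' the heard expression: `L0(s | e)` is proportional to `denot(e, s) p(s)`,
#' row-normalized over states.  Expressions true in no positive-prior state
#' get an all-zero row, recorded in the `empty_rows` attribute.
#'
#' @param lexicon An [build_lexicon()] object.
#' @param prior Normalized prior vector over the lexicon's states.
#' @return Matrix (expressions x states) of class `rsa_table`, each
#'   non-empty row summing to 1.
#' @export
literal_listener <- function(lexicon, prior) {
  stopifnot(inherits(lexicon, "rsa_lexicon"))
  check_prior(prior)
  if (length(prior) != ncol(lexicon$denot))
    stop("prior length does not match the lexicon's state space")
  num <- sweep(lexicon$denot, 2L, prior, `*`)
  mass <- rowSums(num)
  empty <- mass <= 0
  L0 <- num / ifelse(mass > 0, mass, 1)
  L0[empty, ] <- 0
  structure(L0, empty_rows = which(empty), class = c("rsa_table", "matrix"))
}

#' Speaker utility of an expression in a state
#'
#' Informativity minus cost: `U(e, s) = log L0(s | e) - C(e)`, with `-Inf`
#' for expressions false (or uninterpretable) in the state.
#'
#' @param L0 Literal-listener matrix from [literal_listener()].
#' @param lexicon The lexicon that produced `L0` (for costs).
#' @return Matrix of utilities (expressions x states); entries may be
#'   `-Inf`.
#' @export
speaker_utility <- function(L0, lexicon) {
  U <- suppressWarnings(log(L0)) - lexicon$cost
  U[L0 <= 0] <- -Inf
  U
}

#' Soft-max rational speaker distribution
#'
#' `S1(e | s)` is proportional to `exp(alpha * U(e, s))` over the lexicon's
#' expressions, i.e. `L0(s | e)^alpha * exp(-alpha * C(e))` for true
#' expressions and 0 for false ones.  `alpha = 0` picks uniformly among the
#' true expressions; large `alpha` approaches the utility-maximizing
#' speaker.
#'
#' @param L0 Literal-listener matrix from [literal_listener()].
#' @param alpha Nonnegative finite decision-noise parameter.  Values above
#'   100 are accepted with a warning; the strictly optimal speaker
#'   (`alpha = Inf`) is not represented.
#' @param lexicon The lexicon that produced `L0`.
#' @param allow_empty_states If `TRUE`, states in which no expression is
#'   assertable get an all-zero row (recorded in the `empty_rows`
#'   attribute) instead of raising an error; useful when such states carry
#'   no posterior weight downstream.
#' @return Matrix (states x expressions) of class `rsa_table`, each row
#'   summing to 1.
#' @export
speaker <- function(L0, alpha, lexicon, allow_empty_states = FALSE) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || !is.finite(alpha))
    stop("`alpha` must be a finite nonnegative number")
  if (alpha > 100)
    warning("alpha > 100: treating as a near-optimal speaker; alpha = Inf is not represented")
  # exp(alpha * U) with U = log L0 - C, written without exponentiating -Inf
  W <- t(L0^alpha * exp(-alpha * lexicon$cost) * (L0 > 0))
  norm <- rowSums(W)
  if (any(norm <= 0)) {
    bad <- colnames(lexicon$denot)[norm <= 0]
    if (!allow_empty_states)
      stop("no true expression available in state(s): ",
           paste(bad, collapse = ", "))
    norm[norm <= 0] <- 1
  }
  structure(W / norm, empty_rows = which(rowSums(W) <= 0),
            class = c("rsa_table", "matrix"))
}

#' Pragmatic listener distribution
#'
#' Bayesian inversion of the speaker: `L2(s | e)` proportional to
#' `S1(e | s) p(s)`, row-normalized over states.  Expressions the speaker
#' never produces get an all-zero row, recorded in `empty_rows`.
#'
#' @param S1 Speaker matrix from [speaker()] (states x expressions).
#' @param prior Normalized prior vector over states.
#' @return Matrix (expressions x states) of class `rsa_table`.
#' @export
pragmatic_listener <- function(S1, prior) {
  check_prior(prior)
  num <- t(S1 * prior)            # expressions x states
  mass <- rowSums(num)
  empty <- mass <= 0
  L2 <- num / ifelse(mass > 0, mass, 1)
  L2[empty, ] <- 0
  structure(L2, empty_rows = which(empty), class = c("rsa_table", "matrix"))
}

#' Parameters of the forward RSA model
#'
#' @param alpha Soft-max decision noise (>= 0, finite).
#' @param p Success probability of the binomial state prior, in (0, 1).
#' @param cost_per_word Nonnegative cost per mentioned word.
#' @return A list of class `rsa_params`.
#' @export
rsa_params <- function(alpha = 3, p = 0.5, cost_per_word = 0) {
  if (!is.numeric(p) || p <= 0 || p >= 1) stop("`p` must lie in (0, 1)")
  if (!is.numeric(alpha) || alpha < 0 || !is.finite(alpha))
    stop("`alpha` must be finite and nonnegative")
  if (!is.numeric(cost_per_word) || cost_per_word < 0)
    stop("`cost_per_word` must be nonnegative")
  structure(list(alpha = alpha, p = p, cost_per_word = cost_per_word),
            class = "rsa_params")
}

#' Exhaustivity of a narrow-focus expression by full matrix computation
#'
#' Builds the prior, lexicon and listener/speaker matrices for the chosen
#' variant and returns the pragmatic listener's probability of the
#' exhaustive state (only the mentioned individual acted) given the focus
#' expression naming one individual.  The mentioned individual is
#' canonically the first alphabetical name (bit 0), so the exhaustive state
#' has index 1.
#'
#' @param k Domain size (>= 2).
#' @param params An [rsa_params()] object (or a list with `alpha`, `p`,
#'   `cost_per_word`).
#' @param variant Lexicon variant, see [build_lexicon()].
#' @param include_null Include the null expression (full variants only;
#'   default `TRUE`, the convention under which the closed form
#'   [closed_form_exhaustivity()] is reproduced exactly).
#' @return Exhaustivity probability `E(k)` in \[0, 1\].
#' @export
exhaustivity <- function(k, params = rsa_params(), variant = "focus_only",
                         include_null = TRUE) {
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be at least 2")
  domain <- rsa_domain(k = k)
  lex <- build_lexicon(domain, variant, params$cost_per_word, include_null)
  prior <- collapsed_or_full_prior(lex, k, params$p)
  L0 <- literal_listener(lex, prior)
  S1 <- speaker(L0, params$alpha, lex)
  L2 <- pragmatic_listener(S1, prior)
  if (lex$state_space == "collapsed") {
    unname(L2["focus[mentioned]", "exhaustive"])
  } else {
    foc <- which(lex$expressions$kind == "focus" & lex$expressions$mentioned == 1L)
    unname(L2[foc, "1"])
  }
}

collapsed_or_full_prior <- function(lex, k, p) {
  if (lex$state_space != "collapsed") return(binomial_prior(lex$domain, p))
  if (lex$variant == "collapsed_constant_prior") return(c(0.5, 0.5))
  # pooled prior: binomial masses of the compatible states (those containing
  # the mentioned individual), exhaustive vs all larger target sets
  full <- binomial_prior(lex$domain, p)
  compat <- condition_on_focus(full)
  exh <- unname(compat["1"])
  c(exh, 1 - exh)
}

#' Closed-form exhaustivity under the default convention
#'
#' Under a binomial state prior with success probability `p`, a focus-only
#' lexicon with a costless null message and zero costs, exhaustivity obeys
#' `E(k) = E(2)^(k-1)` with
#' `E(2) = 1 / (1 + (1 + p^-alpha)^-1 * p / (1 - p))`, strictly decreasing
#' in `k` for finite `alpha`.
#'
#' @param k Domain size (>= 2).
#' @param p Binomial success probability in (0, 1).
#' @param alpha Nonnegative decision noise.
#' @return Exhaustivity `E(k)`.
#' @export
closed_form_exhaustivity <- function(k, p, alpha) {
  if (!is.numeric(p) || any(p <= 0) || any(p >= 1))
    stop("`p` must lie in (0, 1)")
  if (any(k < 2)) stop("`k` must be at least 2")
  if (any(alpha < 0)) stop("`alpha` must be nonnegative")
  E2 <- 1 / (1 + (1 + p^(-alpha))^(-1) * p / (1 - p))
  E2^(k - 1)
}

#' Two-individual posterior exhaustivity from Bayes' theorem
#'
#' At domain size 2 only the exhaustive state `s_A` and the non-exhaustive
#' state `s_AB` survive the focus utterance, and Bayes' theorem reduces to
#' `p(s_A | foc_A) = 1 / (1 + r * (1 - p(s_A)) / p(s_A))` where `r` is the
#' speaker's relative probability of producing the focus in the
#' non-exhaustive state (the ratio `S1(foc | s_AB) / S1(foc | s_A)`).  If
#' `r` decreases as the prior grows, the posterior is strictly increasing
#' in the prior - the model-independent consistency condition tested by the
#' pipeline's [k2_consistency_check()].
#'
#' @param speaker_prob_nonexh The speaker term `r` in \[0, 1\].
#' @param prior_exh Prior probability of the exhaustive state.  The
#'   endpoints 0 and 1 return the forced limits 0 and 1.
#' @return Posterior exhaustivity in \[0, 1\].
#' @export
k2_posterior <- function(speaker_prob_nonexh, prior_exh) {
  if (any(speaker_prob_nonexh < 0 | speaker_prob_nonexh > 1))
    stop("`speaker_prob_nonexh` must lie in [0, 1]")
  if (any(prior_exh < 0 | prior_exh > 1))
    stop("`prior_exh` must lie in [0, 1]")
  out <- ifelse(prior_exh == 0, 0,
         ifelse(prior_exh == 1, 1,
                1 / (1 + speaker_prob_nonexh * (1 - prior_exh) / prior_exh)))
  unname(out)
}

#' RSA bridge from prior to posterior beliefs over compatible states
#'
#' The link used by the hierarchical posterior-belief model: a listener
#' with soft-max rationality `alpha_j` updates their prior over the states
#' compatible with the focus utterance by the speaker's probability of
#' producing that utterance, `Q_post(i)` proportional to
#' `S1(foc | i) Q_prior(i)`, renormalized over compatible states.
#'
#' The speaker matrix needs a prior over the full state space; given only
#' the compatible-state vector, the full prior is reconstructed by letting
#' the mentioned individual act with probability 1/2 independently of the
#' remaining individuals' pattern (for a uniform compatible prior at
#' `k = 2` this is the uniform full prior).  Pass `Q_full` to override.
#'
#' @param Q_prior Normalized belief vector over the `2^(k-1)` compatible
#'   states (ascending state index).
#' @param alpha_j Nonnegative soft-max rationality of the listener's
#'   assumed speaker.
#' @param variant,cost_per_word,include_null Lexicon configuration, as in
#'   [build_lexicon()] (full-state variants only).
#' @param Q_full Optional full-state prior of length `2^k` replacing the
#'   reconstruction.
#' @return Normalized posterior vector over compatible states.
#' @export
rsa_bridge <- function(Q_prior, alpha_j, variant = "focus_only",
                       cost_per_word = 0, include_null = TRUE,
                       Q_full = NULL) {
  nc <- length(Q_prior)
  k <- as.integer(log2(nc)) + 1L
  if (2^(k - 1L) != nc) stop("`Q_prior` must have length 2^(k-1)")
  check_prior(Q_prior)
  if (is.null(Q_full)) {
    Q_full <- numeric(2^k)
    compat <- which(bitwAnd(0:(2^k - 1L), 1L) == 1L)
    Q_full[compat] <- Q_prior / 2
    Q_full[compat - 1L] <- Q_prior / 2   # mirror state without the mentioned bit
  }
  if (!is.numeric(alpha_j) || length(alpha_j) != 1L || alpha_j < 0)
    stop("`alpha_j` must be nonnegative")
  lex <- build_lexicon(rsa_domain(k = k), variant, cost_per_word, include_null)
  L0 <- literal_listener(lex, Q_full)
  foc <- which(lex$expressions$kind == "focus" & lex$expressions$mentioned == 1L)
  compat <- which(bitwAnd(0:(2^k - 1L), 1L) == 1L)
  # soft-max speaker probability of the focus, per compatible state; states
  # carrying zero prior mass contribute zero posterior weight and their
  # (undefined) speaker row is never needed
  num <- t(L0^alpha_j * exp(-alpha_j * lex$cost) * (L0 > 0))
  S1foc <- rep(0, length(compat))
  pos <- Q_prior > 0
  norm <- rowSums(num[compat, , drop = FALSE])
  S1foc[pos] <- num[compat[pos], foc] / norm[pos]
  w <- S1foc * Q_prior
  if (sum(w) <= 0) stop("speaker never produces the focus in any compatible state")
  out <- w / sum(w)
  names(out) <- compat - 1L
  out
}

#' Exhaustivity prediction table over a parameter grid
#'
#' Evaluates [exhaustivity()] over the cross product of domain sizes,
#' binomial success probabilities, decision-noise values and cost settings
#' for one or more lexicon variants.
#'
#' @param k Integer vector of domain sizes.
#' @param p Numeric vector of binomial success probabilities.
#' @param alpha Numeric vector of decision-noise values.
#' @param cost_per_word Numeric vector of per-word costs.
#' @param variant Character vector of lexicon variants.
#' @param include_null Null-message convention (full variants).
#' @return Data frame with columns `variant`, `k`, `p`, `alpha`,
#'   `cost_per_word`, `exhaustivity`.
#' @export
exhaustivity_table <- function(k = 2:8, p = 0.5, alpha = 3, cost_per_word = 0,
                               variant = "focus_only", include_null = TRUE) {
  grid <- expand.grid(variant = variant, k = k, p = p, alpha = alpha,
                      cost_per_word = cost_per_word,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid$exhaustivity <- vapply(seq_len(nrow(grid)), function(r) {
    exhaustivity(grid$k[r],
                 rsa_params(alpha = grid$alpha[r], p = grid$p[r],
                            cost_per_word = grid$cost_per_word[r]),
                 variant = grid$variant[r], include_null = include_null)
  }, numeric(1))
  grid
}
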