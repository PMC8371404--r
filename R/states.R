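#' Domain of contextually relevant individuals
#'
#' A domain is the set of individuals a wh-question ranges over ("Which of
#' Audrey, Bob, Dale danced?").  Partial states are subsets of the domain
#' (the individuals who performed the action), encoded as bitmasks with the
#' first alphabetical name at the least-significant bit, so that for
#' \{Audrey, Bob, Dale\} the subset \{Audrey\} is state 1, \{Bob\} is 2,
#' \{Dale\} is 4 and the full set is 7.
#'
#' @param labels Character vector of distinct individual names.  If missing,
#'   `k` generic labels `A`, `B`, ... are used.
#' @param k Integer number of individuals (only needed when `labels` is
#'   missing).
#' @return An object of class `rsa_domain` with fields `k` and `labels`
#'   (sorted alphabetically).
#' @examples
#' d <- rsa_domain(c("Audrey", "Bob", "Dale"))
#' encode_target_set(c("Audrey", "Dale"), d)  # 5
#' @export
rsa_domain <- function(labels = NULL, k = NULL) {
  if (is.null(labels)) {
    if (is.null(k)) stop("supply either `labels` or `k`")
    k <- as.integer(k)
    if (k < 1) stop("domain size `k` must be at least 1")
    labels <- make_generic_labels(k)
  }
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("domain labels must be unique")
  labels <- sort(labels)
  structure(list(k = length(labels), labels = labels), class = "rsa_domain")
}

make_generic_labels <- function(k) {
  if (k <= 26L) LETTERS[seq_len(k)] else sprintf("I%02d", seq_len(k))
}

#' @export
print.rsa_domain <- function(x, ...) {
  cat("<rsa_domain> k =", x$k, ":", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

as_domain <- function(domain) {
  if (inherits(domain, "rsa_domain")) return(domain)
  if (is.numeric(domain) && length(domain) == 1L) return(rsa_domain(k = domain))
  rsa_domain(domain)
}

#' Number of set bits of a state index
#'
#' The size of the target set `B_i`, i.e. how many individuals act in
#' state `i`.
#'
#' @param i Vector of state indices (0-based bitmasks).
#' @return Integer vector of set-bit counts.
#' @export
state_size <- function(i) {
  i <- as.integer(i)
  n <- integer(length(i))
  while (any(i > 0L)) {
    n <- n + (i %% 2L)
    i <- i %/% 2L
  }
  n
}

#' Encode a subset of the domain as a state index
#'
#' Individuals are mapped to bit positions in alphabetical order, the first
#' name at the least-significant bit.
#'
#' @param subset Character vector of names (possibly empty).
#' @param domain An [rsa_domain()] (or label vector / integer size).
#' @return Integer state index in `0:(2^k - 1)`.
#' @export
encode_target_set <- function(subset, domain) {
  domain <- as_domain(domain)
  subset <- as.character(subset)
  unknown <- setdiff(subset, domain$labels)
  if (length(unknown) > 0L)
    stop("unknown label(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(subset)) stop("subset contains duplicate labels")
  pos <- match(subset, domain$labels) - 1L
  as.integer(sum(2^pos))
}

#' Decode a state index into the subset of acting individuals
#'
#' Inverse of [encode_target_set()].
#'
#' @param i Integer state index in `0:(2^k - 1)`.
#' @param domain An [rsa_domain()] (or label vector / integer size).
#' @return Character vector of names (empty for `i = 0`).
#' @export
decode_target_set <- function(i, domain) {
  domain <- as_domain(domain)
  i <- as.integer(i)
  if (length(i) != 1L || is.na(i) || i < 0L || i >= 2^domain$k)
    stop("state index must lie in [0, 2^k - 1]")
  domain$labels[bitwAnd(i, 2^(seq_len(domain$k) - 1L)) > 0L]
}

#' Binomial prior over partial states
#'
#' Each individual acts independently with probability `p`, so the state
#' with target-set size `m` has prior mass `p^m (1-p)^(k-m)`; summing over
#' the `choose(k, m)` states of each size recovers the binomial
#' distribution of sizes.
#'
#' @param domain An [rsa_domain()] (or label vector / integer size).
#' @param p Success probability in (0, 1).
#' @return Numeric vector of length `2^k` over state indices `0:(2^k - 1)`,
#'   summing to 1.
#' @export
binomial_prior <- function(domain, p) {
  domain <- as_domain(domain)
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
    stop("`p` must lie strictly between 0 and 1")
  k <- domain$k
  m <- state_size(0:(2^k - 1L))
  prior <- p^m * (1 - p)^(k - m)
  prior / sum(prior)
}

#' Mix a state prior with a uniform back-off prior
#'
#' Convex mixture `weight * uniform + (1 - weight) * prior`, the limiting
#' case `weight = 1` being a pure uniform back-off under which listeners
#' discard an implausibly extreme ("wonky") prior.
#'
#' @param prior Normalized prior vector over states.
#' @param weight Mixture weight in \[0, 1\].
#' @return Normalized prior vector of the same length.
#' @export
backoff_prior <- function(prior, weight) {
  check_prior(prior)
  if (!is.numeric(weight) || length(weight) != 1L || weight < 0 || weight > 1)
    stop("`weight` must lie in [0, 1]")
  weight / length(prior) + (1 - weight) * prior
}

check_prior <- function(prior, tol = 1e-8) {
  if (!is.numeric(prior) || any(prior < -1e-12))
    stop("prior must be a nonnegative numeric vector")
  if (abs(sum(prior) - 1) > tol)
    stop("prior must sum to 1 (sum = ", format(sum(prior)), ")")
  invisible(prior)
}

#' Expand size-class probabilities into a full state prior
#'
#' The hierarchical slider model parameterizes beliefs by the probability of
#' each target-set size `0..k` (states of equal size being conceptually
#' indistinguishable); a full-state prior is obtained by splitting each size
#' mass equally over the `choose(k, m)` states of that size.
#'
#' @param p_sizes Probability vector of length `k + 1` over sizes `0..k`.
#' @param k Domain size.
#' @return Prior vector of length `2^k` over state indices.
#' @export
expand_size_probs <- function(p_sizes, k) {
  k <- as.integer(k)
  if (length(p_sizes) != k + 1L)
    stop("`p_sizes` must have length k + 1 = ", k + 1L)
  check_prior(p_sizes)
  m <- state_size(0:(2^k - 1L))
  p_sizes[m + 1L] / choose(k, m)
}

#' Condition a state prior on the focus utterance's mentioned individual
#'
#' Restricts to the `2^(k-1)` states whose target set contains the mentioned
#' individual and renormalizes.  By the canonical encoding the mentioned
#' individual occupies bit 0, so compatible states are the odd indices and
#' the exhaustive state is index 1.
#'
#' @param Q Normalized prior vector of length `2^k`.
#' @param mentioned_bit Bit position of the mentioned individual (default 0,
#'   the canonical first-alphabetical convention).
#' @return Named numeric vector over compatible state indices, summing to 1.
#' @export
condition_on_focus <- function(Q, mentioned_bit = 0L) {
  check_prior(Q)
  k <- log2(length(Q))
  if (k != round(k)) stop("`Q` must have length 2^k")
  idx <- which(bitwAnd(0:(length(Q) - 1L), as.integer(2^mentioned_bit)) > 0L)
  mass <- sum(Q[idx])
  if (mass <= 0) stop("no probability mass on states compatible with the focus")
  out <- Q[idx] / mass
  names(out) <- idx - 1L
  out
}
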