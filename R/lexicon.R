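#' Build an utterance lexicon for a domain
#'
#' The lexicon holds the alternative expressions a speaker may choose from,
#' their denotations over partial states and their costs.  Four variants are
#' supported:
#'
#' * `focus_only`: one narrow-focus expression per nonempty subset of the
#'   domain ("BOB danced", "BOB and DALE danced", ...), with at-least
#'   semantics: the expression mentioning `B` is true in every state whose
#'   target set contains `B`.
#' * `focus_plus_exclusives`: additionally one exclusive per nonempty subset
#'   ("Only BOB danced"), true exactly in the state whose target set equals
#'   the mentioned set.
#' * `collapsed_two_state`: the two-state, two-alternative reduction in
#'   which the listener distinguishes only the exhaustive state (only the
#'   mentioned individual acted) from a single pooled non-exhaustive state;
#'   the two expressions are the focus answer (true in both states) and the
#'   overt non-exhaustive description (true only in the pooled state).
#' * `collapsed_constant_prior`: same expressions and states as
#'   `collapsed_two_state`; downstream code fixes both state priors at 1/2
#'   regardless of domain size.
#'
#' Costs are `cost_per_word` times the number of mentioned names, plus one
#' word for exclusives; the null expression is free.
#'
#' @param domain An [rsa_domain()] (or label vector / integer size).
#' @param variant One of `"focus_only"`, `"focus_plus_exclusives"`,
#'   `"collapsed_two_state"`, `"collapsed_constant_prior"`.
#' @param cost_per_word Nonnegative cost per mentioned word (default 0; a
#'   pilot with lengthened names showed no cost effect, so zero is the
#'   default across the package).
#' @param include_null Include a costless null expression true in every
#'   state (default `TRUE`; see the methods vignette for why the null
#'   message is part of the default convention).
#' @return An object of class `rsa_lexicon`: a list with the denotation
#'   matrix `denot` (expressions x states), `cost`, expression metadata and
#'   the state space ("full": `2^k` bitmask states; "collapsed": exhaustive
#'   and pooled non-exhaustive).
#' @export
build_lexicon <- function(domain, variant = "focus_only", cost_per_word = 0,
                          include_null = TRUE) {
  domain <- as_domain(domain)
  variants <- c("focus_only", "focus_plus_exclusives",
                "collapsed_two_state", "collapsed_constant_prior")
  if (!is.character(variant) || length(variant) != 1L || !variant %in% variants)
    stop("unknown lexicon variant: ", paste(variant, collapse = ", "))
  if (!is.numeric(cost_per_word) || cost_per_word < 0)
    stop("`cost_per_word` must be nonnegative")
  k <- domain$k

  if (variant %in% c("collapsed_two_state", "collapsed_constant_prior")) {
    # states: 1 = exhaustive ("A acted and no one else"),
    #         2 = pooled non-exhaustive ("A and at least one other acted")
    denot <- rbind(focus = c(1, 1), collapsed_nonexh = c(0, 1))
    cost <- c(cost_per_word * 1, cost_per_word * k)
    expr <- data.frame(kind = c("focus", "collapsed_nonexh"),
                       mentioned = c(1L, 2L^k - 1L),
                       label = c("focus[mentioned]", "focus[mentioned + others]"),
                       cost = cost, stringsAsFactors = FALSE)
    states <- c("exhaustive", "non_exhaustive")
  } else {
    states <- 0:(2^k - 1L)
    subsets <- 1:(2^k - 1L)
    kinds <- rep("focus", length(subsets))
    masks <- subsets
    if (variant == "focus_plus_exclusives") {
      kinds <- c(kinds, rep("exclusive", length(subsets)))
      masks <- c(masks, subsets)
    }
    if (include_null) {
      kinds <- c(kinds, "null")
      masks <- c(masks, 0L)
    }
    denot <- matrix(0, nrow = length(kinds), ncol = length(states))
    cost <- numeric(length(kinds))
    for (e in seq_along(kinds)) {
      denot[e, ] <- switch(kinds[e],
        focus = as.numeric(bitwAnd(states, masks[e]) == masks[e]),
        exclusive = as.numeric(states == masks[e]),
        null = rep(1, length(states)))
      nwords <- state_size(masks[e])
      cost[e] <- switch(kinds[e],
        focus = cost_per_word * nwords,
        exclusive = cost_per_word * (nwords + 1),
        null = 0)
    }
    label <- vapply(seq_along(kinds), function(e) {
      who <- paste(decode_target_set(masks[e], domain), collapse = "+")
      switch(kinds[e], focus = paste0("focus[", who, "]"),
             exclusive = paste0("only[", who, "]"), null = "null")
    }, character(1))
    expr <- data.frame(kind = kinds, mentioned = masks, label = label,
                       cost = cost, stringsAsFactors = FALSE)
  }
  rownames(denot) <- expr$label
  colnames(denot) <- as.character(states)
  structure(list(domain = domain, variant = variant, denot = denot,
                 cost = expr$cost, expressions = expr,
                 include_null = include_null,
                 state_space = if (startsWith(variant, "collapsed"))
                   "collapsed" else "full"),
            class = "rsa_lexicon")
}

#' @export
print.rsa_lexicon <- function(x, ...) {
  cat("<rsa_lexicon>", x$variant, "over k =", x$domain$k, ":",
      nrow(x$denot), "expressions,", ncol(x$denot), "states\n")
  invisible(x)
}

#' Truth value of an expression in a state
#'
#' Focus expressions have at-least semantics (true whenever the mentioned
#' set is contained in the target set), exclusives are true exactly in the
#' state equal to the mentioned set, and the null expression is true
#' everywhere.
#'
#' @param lexicon An [build_lexicon()] object.
#' @param expression Row index into the lexicon, or an expression label.
#' @param i State index (bitmask for full state spaces; 1 or 2 for
#'   collapsed ones, or `"exhaustive"`/`"non_exhaustive"`).
#' @return Logical truth value.
#' @export
denotation <- function(lexicon, expression, i) {
  stopifnot(inherits(lexicon, "rsa_lexicon"))
  e <- resolve_expression(lexicon, expression)
  j <- if (is.character(i)) match(i, c("exhaustive", "non_exhaustive"))
       else if (lexicon$state_space == "full") as.integer(i) + 1L
       else as.integer(i)
  if (is.na(j) || j < 1L || j > ncol(lexicon$denot)) stop("state out of range")
  lexicon$denot[e, j] > 0
}

resolve_expression <- function(lexicon, expression) {
  if (is.character(expression)) {
    e <- match(expression, lexicon$expressions$label)
    if (is.na(e)) stop("unknown expression label: ", expression)
    e
  } else {
    e <- as.integer(expression)
    if (e < 1L || e > nrow(lexicon$denot)) stop("expression index out of range")
    e
  }
}
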