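#' Apply participant exclusion rules
#'
#' A participant is excluded when they took less than 15 seconds on at
#' least one item, or assigned the value 0 to every slider of an item.
#'
#' @param data A slider dataset.
#' @param min_time_s Exclusion threshold on per-item response time.
#' @return List of class `exclusion_result`: `data` (retained records),
#'   `report` (counts per reason) and `excluded` (ids per reason).
#' @export
apply_exclusions <- function(data, min_time_s = 15) {
  if (is.null(data$response_time_s))
    stop("missing `response_time_s` column")
  keys <- item_key(data)
  rt <- tapply(data$response_time_s, keys, min)
  zero <- tapply(data$raw_value, keys, function(v) all(v == 0))
  pid_of <- tapply(data$participant_id, keys, `[`, 1L)
  fast_pid <- unique(pid_of[rt < min_time_s])
  zero_pid <- setdiff(unique(pid_of[zero]), fast_pid)
  drop <- union(fast_pid, zero_pid)
  keep <- !(data$participant_id %in% drop)
  structure(list(
    data = data[keep, , drop = FALSE],
    report = data.frame(
      reason = c("fast_item", "all_zero_item", "retained"),
      n_participants = c(length(fast_pid), length(zero_pid),
                         length(unique(data$participant_id[keep])))),
    excluded = list(fast_item = fast_pid, all_zero_item = zero_pid)),
    class = "exclusion_result")
}

#' @export
print.exclusion_result <- function(x, ...) {
  cat("<exclusion_result>\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Normalize slider responses within items
#'
#' Adds a `normalized_value` column: each raw value divided by the sum of
#' its item's raw values, so that every item's normalized values sum to 1.
#' This is the same row normalization the listener matrices require, and
#' it is where a decreasing "exhaustivity" can arise artifactually: a
#' constant raw exhaustive-state value divided by a raw sum that grows
#' with the number of presented sliders decreases mechanically.
#'
#' @param data A slider dataset (exclusions applied; items summing to zero
#'   are an error).
#' @return The dataset with a `normalized_value` column.
#' @export
normalize_responses <- function(data) {
  keys <- item_key(data)
  sums <- tapply(data$raw_value, keys, sum)
  if (any(sums <= 0))
    stop("item(s) with zero raw sum (apply exclusions first): ",
         paste(names(sums)[sums <= 0], collapse = ", "))
  data$normalized_value <- data$raw_value / as.vector(sums[keys])
  data
}

#' Summarize exhaustivity by condition
#'
#' Per (domain size, prior type): the mean normalized and mean raw
#' exhaustive-state slider value (the exhaustive state being index 1, the
#' singleton of the mentioned individual), the mean per-item raw slider
#' sum, and participant counts.
#'
#' @param data A slider dataset with normalized values (see
#'   [normalize_responses()]).
#' @return Data frame of class `exhaustivity_summary`.
#' @export
summarize_exhaustivity <- function(data) {
  if (is.null(data$normalized_value)) data <- normalize_responses(data)
  keys <- item_key(data)
  conds <- unique(data[, c("domain_size", "prior_type"), drop = FALSE])
  conds <- conds[order(conds$prior_type, conds$domain_size), , drop = FALSE]
  out <- lapply(seq_len(nrow(conds)), function(r) {
    sel <- data$domain_size == conds$domain_size[r] &
      data$prior_type == conds$prior_type[r]
    exh <- sel & !is.na(data$state_index) & data$state_index == 1L
    if (!any(exh)) {
      warning("no exhaustive-state responses for k = ",
              conds$domain_size[r], ", prior type ", conds$prior_type[r],
              "; condition omitted")
      return(NULL)
    }
    sums <- tapply(data$raw_value[sel], keys[sel], sum)
    data.frame(domain_size = conds$domain_size[r],
               prior_type = conds$prior_type[r],
               mean_normalized_exh = mean(data$normalized_value[exh]),
               mean_raw_exh = mean(data$raw_value[exh]),
               mean_raw_sum = mean(sums),
               n_participants = length(unique(data$participant_id[sel])))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("exhaustivity_summary", "data.frame")
  res
}

#' One-way analysis of variance on exhaustive-state responses
#'
#' Aggregates each participant's exhaustive-state values to one mean per
#' factor level and runs a one-way ANOVA of that per-participant value on
#' the factor.
#'
#' @param data A slider dataset (normalized values added if missing).
#' @param factor One of `"domain_size"`, `"prior_type"`, `"scenario"`.
#' @param response `"normalized"` or `"raw"`.
#' @return List of class `effect_test`: factor, response, `F`, `p_value`,
#'   level means and the per-participant table.
#' @export
effect_test <- function(data, factor = c("domain_size", "prior_type",
                                         "scenario"),
                        response = c("normalized", "raw")) {
  factor <- match.arg(factor)
  response <- match.arg(response)
  if (response == "normalized" && is.null(data$normalized_value))
    data <- normalize_responses(data)
  exh <- !is.na(data$state_index) & data$state_index == 1L
  d <- data[exh, , drop = FALSE]
  val <- if (response == "normalized") d$normalized_value else d$raw_value
  agg <- stats::aggregate(val,
                          list(participant_id = d$participant_id,
                               level = d[[factor]]), mean)
  names(agg)[3] <- "value"
  if (length(unique(agg$level)) < 2)
    stop("factor `", factor, "` has fewer than 2 levels")
  fit <- stats::aov(value ~ factor(level), data = agg)
  tab <- summary(fit)[[1]]
  structure(list(factor = factor, response = response,
                 F_statistic = tab[["F value"]][1],
                 p_value = tab[["Pr(>F)"]][1],
                 level_means = tapply(agg$value, agg$level, mean),
                 table = agg),
            class = "effect_test")
}

#' @export
print.effect_test <- function(x, ...) {
  cat(sprintf("<effect_test> %s on %s exhaustive-state values: F = %.3f, p = %.3g\n",
              x$factor, x$response, x$F_statistic, x$p_value))
  print(round(x$level_means, 4))
  invisible(x)
}

#' Bayes-consistency check at domain size 2
#'
#' At domain size 2 any account based on Bayes' theorem with a speaker term
#' that does not increase with the prior predicts posterior exhaustivity to
#' be strictly increasing in prior exhaustivity.  Given exhaustivity
#' summaries of prior- and posterior-probe arms over at least two prior
#' wordings, the check reports (a) whether the observed posteriors are
#' ordered consistently with the observed priors, (b) the implied speaker
#' probabilities obtained by inverting the two-state Bayes relation (values
#' outside \[0, 1\] are flagged, not clamped), and (c) whether those
#' implied speaker terms are non-increasing in the prior.  The verdict is
#' `"consistent"` only if all three hold, `"inconclusive"` when the priors
#' are too close to order.
#'
#' @param prior_summary,posterior_summary [summarize_exhaustivity()] tables
#'   containing domain-size-2 rows for the same prior types.
#' @param tol Minimal prior separation treated as a real difference.
#' @return List of class `k2_consistency`: the merged table with implied
#'   speaker terms and the verdict.
#' @export
k2_consistency_check <- function(prior_summary, posterior_summary,
                                 tol = 0.01) {
  pri <- prior_summary[prior_summary$domain_size == 2L, , drop = FALSE]
  post <- posterior_summary[posterior_summary$domain_size == 2L, , drop = FALSE]
  tab <- merge(pri[, c("prior_type", "mean_normalized_exh")],
               post[, c("prior_type", "mean_normalized_exh")],
               by = "prior_type", suffixes = c("_prior", "_posterior"))
  if (nrow(tab) < 2)
    stop("need domain-size-2 summaries for at least 2 prior types")
  names(tab) <- c("prior_type", "prior_exh", "posterior_exh")
  tab <- tab[order(tab$prior_exh), , drop = FALSE]
  # invert p(sA|focA) = 1 / (1 + r (1-q)/q) for the speaker term r
  tab$implied_speaker <- (1 / tab$posterior_exh - 1) *
    tab$prior_exh / (1 - tab$prior_exh)
  if (max(tab$prior_exh) - min(tab$prior_exh) < tol) {
    verdict <- "inconclusive"
  } else {
    increasing <- all(diff(tab$posterior_exh) > 0)
    speaker_ok <- all(tab$implied_speaker >= 0 & tab$implied_speaker <= 1) &&
      all(diff(tab$implied_speaker) <= 0)
    verdict <- if (increasing && speaker_ok) "consistent" else "inconsistent"
  }
  structure(list(table = tab, verdict = verdict, tol = tol),
            class = "k2_consistency")
}

#' @export
print.k2_consistency <- function(x, ...) {
  cat("<k2_consistency> verdict:", x$verdict, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Compare model predictions with observed summaries and predictive bands
#'
#' Joins a model prediction table, an observed exhaustivity summary and a
#' posterior-predictive HDI table on domain size and reports, per
#' condition, the observed mean, the predicted value and whether the
#' observation falls inside its interval.
#'
#' @param predictions Data frame with `k` (or `domain_size`) and
#'   `exhaustivity` columns, e.g. from [exhaustivity_table()].
#' @param summary An [summarize_exhaustivity()] table.
#' @param hdis A [posterior_predictive_hdi()] table (exhaustive-state rows,
#'   `state_index == 1`, are used).
#' @return Data frame of class `model_data_comparison` with an
#'   `inside_hdi` flag per condition and an `n_inside` attribute.
#' @export
compare_model_data <- function(predictions, summary, hdis) {
  if (nrow(predictions) == 0) stop("empty prediction table")
  kcol <- if ("k" %in% names(predictions)) "k" else "domain_size"
  hd <- hdis[hdis$state_index == 1L, , drop = FALSE]
  out <- summary
  out$predicted <- predictions$exhaustivity[
    match(out$domain_size, predictions[[kcol]])]
  out$lower <- hd$lower[match(out$domain_size, hd$domain_size)]
  out$upper <- hd$upper[match(out$domain_size, hd$domain_size)]
  missing_k <- out$domain_size[is.na(out$predicted) | is.na(out$lower)]
  if (length(missing_k) > 0)
    stop("no prediction or interval for domain size(s): ",
         paste(unique(missing_k), collapse = ", "))
  out$inside_hdi <- out$mean_normalized_exh >= out$lower &
    out$mean_normalized_exh <= out$upper
  attr(out, "n_inside") <- sum(out$inside_hdi)
  class(out) <- c("model_data_comparison", "data.frame")
  out
}
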