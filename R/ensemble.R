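#' Flatten one replicate's results into a record row
#'
#' @param fraction subset fraction in `(0, 1]`.
#' @param replicate_index replicate index.
#' @param fit a `gmyc_fit`.
#' @param metrics optionally, the matching [run_metrics()].
#' @param n_sequences number of sequences analysed in this replicate.
#' @return a one-row data.frame (a `ReplicateRecord`).
#' @export
replicate_record <- function(fraction, replicate_index, fit, metrics = NULL,
                             n_sequences = ape::Ntip(fit$tree)) {
  row <- data.frame(fraction = fraction, replicate = replicate_index,
                    n_sequences = n_sequences,
                    entities = fit$n_entities, clusters = fit$n_clusters,
                    singletons = fit$n_singletons,
                    logL = fit$logL, null_logL = fit$null_logL,
                    LR = fit$LR, p_value = fit$p_value,
                    threshold = fit$params$threshold)
  if (!is.null(metrics)) {
    row <- cbind(row, data.frame(
      y_count = metrics$y_count, n_count = metrics$n_count,
      m_incl = metrics$m_incl, m_excl = metrics$m_excl,
      sr_incl = metrics$sr_incl, sr_excl = metrics$sr_excl,
      singleton_pct = metrics$singleton_pct,
      exact_match_incidence = metrics$exact_match_incidence))
  }
  row
}

#' Summarise replicate records per fraction and statistic
#'
#' For every subset fraction and every numeric statistic: arithmetic mean,
#' sample standard deviation (n - 1 denominator) and a t-based 95%
#' confidence interval on the mean. With a single replicate the sd and CI
#' are reported as `NA`.
#'
#' @param records data.frame of rows from [replicate_record()] (or any
#'   data.frame with `fraction` plus numeric statistic columns).
#' @param conf confidence level, default 0.95.
#' @return a long-format data.frame of class `ensemble_summary`:
#'   `fraction`, `statistic`, `mean`, `sd`, `n`, `ci_low`, `ci_high`,
#'   plus `n_sequences` when present in the input.
#' @export
summarize_replicates <- function(records, conf = 0.95) {
  if (is.null(records) || nrow(records) == 0L)
    stop_gmyc("no replicate records to summarise", class = "empty_input_error")
  stats_cols <- setdiff(names(records)[vapply(records, is.numeric, TRUE)],
                        c("fraction", "replicate"))
  out <- list()
  for (f in sort(unique(records$fraction))) {
    sub <- records[records$fraction == f, , drop = FALSE]
    for (sc in stats_cols) {
      v <- sub[[sc]]
      v <- v[!is.na(v)]
      n <- length(v)
      if (n == 0L) next
      mu <- mean(v)
      sdv <- if (n > 1L) stats::sd(v) else NA_real_
      if (n > 1L) {
        half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * sdv / sqrt(n)
        ci <- c(mu - half, mu + half)
      } else ci <- c(NA_real_, NA_real_)
      out[[length(out) + 1L]] <- data.frame(
        fraction = f, statistic = sc, mean = mu, sd = sdv, n = n,
        ci_low = ci[1], ci_high = ci[2],
        n_sequences = if ("n_sequences" %in% names(records))
          max(sub$n_sequences) else NA_real_)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("ensemble_summary", "data.frame")
  res
}

#' Accumulation-curve table for clusters or entities
#'
#' Species-count estimates as a function of sample size, with the 95%
#' confidence band, ordered by increasing sample size. Both the subset
#' fraction and the absolute sequence count are emitted. An optional loess
#' smooth (display parity with generic plot smoothers; the raw means and
#' t-CIs remain the inferential quantities) is added when `smooth = TRUE`
#' and at least 4 fractions are available.
#'
#' @param summary an [summarize_replicates()] result.
#' @param statistic `"clusters"` or `"entities"`.
#' @param smooth add a `smoothed` column (loess, locally quadratic as in
#'   the usual plot smoothers, span 0.75).
#' @return data.frame `fraction`, `n_sequences`, `mean`, `sd`, `n`,
#'   `ci_low`, `ci_high` (and `smoothed`).
#' @export
accumulation_curve <- function(summary, statistic = c("clusters", "entities"),
                               smooth = FALSE) {
  statistic <- match.arg(statistic)
  cur <- summary[summary$statistic == statistic, , drop = FALSE]
  if (nrow(cur) == 0L)
    stop_gmyc("statistic '", statistic, "' not present in summary",
              class = "validation_error")
  if (nrow(cur) == 1L)
    warning("only one fraction available: degenerate single-point curve")
  cur <- cur[order(cur$fraction), , drop = FALSE]
  out <- data.frame(fraction = cur$fraction,
                    n_sequences = cur$n_sequences,
                    mean = cur$mean, sd = cur$sd, n = cur$n,
                    ci_low = cur$ci_low, ci_high = cur$ci_high,
                    row.names = NULL)
  if (smooth && nrow(out) >= 4L) {
    span <- if (nrow(out) < 7L) 1 else 0.75
    fit <- stats::loess(mean ~ fraction, data = out, span = span, degree = 2)
    out$smoothed <- stats::predict(fit, out$fraction)
  }
  out
}
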