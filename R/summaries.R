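#' Posterior mean and 95% equal-tailed credible interval
#'
#' Pools the post-warmup draws of all chains and returns the arithmetic mean
#' together with the 2.5th and 97.5th percentiles. Equal-tailed (quantile)
#' intervals are used rather than HPD so that credible intervals commute
#' exactly with monotone transforms such as `exp()`.
#'
#' @param draws A `posterior_draws` object.
#' @param parameter Parameter name.
#' @param prob Interval mass (default 0.95).
#' @return Named numeric vector `c(mean, ci_low, ci_high)`.
#' @export
summarize_parameter <- function(draws, parameter, prob = 0.95) {
  x <- extract_draws(draws, parameter)
  if (length(x) < 100L)
    warning("fewer than 100 draws; the interval is unstable")
  a <- (1 - prob) / 2
  q <- stats::quantile(x, c(a, 1 - a), names = FALSE, type = 7)
  c(mean = mean(x), ci_low = q[1], ci_high = q[2])
}

#' Exponentiate a log-scale summary to the ratio scale
#'
#' Componentwise `exp()`; because the credible interval is equal-tailed, the
#' exponentiated endpoints are the equal-tailed interval of the
#' exponentiated parameter.
#'
#' @param log_summary Numeric vector `c(mean, ci_low, ci_high)` on the log
#'   scale.
#' @return The same three components exponentiated.
#' @export
to_ratio_scale <- function(log_summary) {
  if (length(log_summary) != 3L) stop("expected c(mean, ci_low, ci_high)")
  if (any(!is.finite(log_summary))) stop("log summary must be finite")
  out <- exp(log_summary)
  names(out) <- c("ratio_mean", "ratio_ci_low", "ratio_ci_high")
  out
}

#' Population-effect report on the log and ratio scales
#'
#' Summarises the three population treatment effects of a fitted model —
#' pot type (`mu_beta1`), nutrients (`mu_beta2`) and their interaction
#' (`mu_beta3`) — as posterior means and 95% credible intervals on the
#' natural-log scale and exponentiated to the multiplicative (ratio) scale.
#' An effect is flagged when its 95% interval excludes the null (0 on the
#' log scale, equivalently 1 on the ratio scale).
#'
#' @param fit A `phlm_fit` (or any `posterior_draws` containing the three
#'   `mu_beta*` parameters).
#' @param response_label Label for the response column of the report;
#'   defaults to the fit's response.
#' @return A data.frame of class `effect_report` with one row per effect and
#'   columns on both scales plus `excludes_null`.
#' @export
effect_report <- function(fit, response_label = NULL) {
  if (is.null(response_label))
    response_label <- if (!is.null(fit$spec)) fit$spec$response else ""
  effects <- c("Type of pots" = "mu_beta1", "Nutrients" = "mu_beta2",
               "Type of pots x nutrients" = "mu_beta3")
  missing <- setdiff(effects, fit$parameters)
  if (length(missing))
    stop("fit does not contain: ", paste(missing, collapse = ", "))
  rows <- lapply(seq_along(effects), function(i) {
    s <- summarize_parameter(fit, effects[[i]])
    r <- to_ratio_scale(s)
    data.frame(response = response_label, effect = names(effects)[i],
               parameter = effects[[i]],
               log_mean = s[["mean"]], log_ci_low = s[["ci_low"]],
               log_ci_high = s[["ci_high"]],
               ratio_mean = r[["ratio_mean"]], ratio_ci_low = r[["ratio_ci_low"]],
               ratio_ci_high = r[["ratio_ci_high"]],
               excludes_null = s[["ci_low"]] > 0 || s[["ci_high"]] < 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("effect_report", class(out))
  out
}

#' @export
print.effect_report <- function(x, digits = 4, ...) {
  cat("Effect of pot type and nutrient treatment",
      if (nzchar(x$response[1])) paste0(" (", x$response[1], ")"), "\n", sep = "")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-26s %s%.4f (%.4f)  95%% CI [%.4f, %.4f] ([%.4f, %.4f])\n",
                x$effect[i], if (x$excludes_null[i]) "* " else "  ",
                x$ratio_mean[i], x$log_mean[i],
                x$ratio_ci_low[i], x$ratio_ci_high[i],
                x$log_ci_low[i], x$log_ci_high[i]))
  }
  cat("  ratio scale shown first; (natural-log scale) in brackets;",
      "* = 95% CI excludes the null\n")
  invisible(x)
}

#' Write an effect report as TSV
#'
#' Full machine precision; display rounding is left to [print.effect_report()].
#'
#' @param report An `effect_report`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
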