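# Heterogeneity, pleiotropy, instrument-strength and influence diagnostics.

#' Cochran's Q heterogeneity test
#'
#' `Q = sum(w_j * (ratio_j - beta_ivw_fixed)^2)` with the first-order IVW
#' weights, referred to a chi-square distribution with J - 1 degrees of
#' freedom.  A p-value below `q_alpha` selects the multiplicative
#' random-effects IVW model for reporting.
#'
#' @param instruments A harmonized instrument tibble (at least 2 rows).
#' @param q_alpha Significance level of the model-selection rule.
#' @return A one-row tibble with `Q`, `df`, `pvalue` and `model_selected`
#'   (`"fixed"` or `"random"`).
#' @export
cochran_q <- function(instruments, q_alpha = 0.05) {
  check_instruments(instruments, 2, "cochran_q")
  r <- wald_ratios(instruments)
  beta <- sum(r$weight * r$wald_ratio) / sum(r$weight)
  Q <- sum(r$weight * (r$wald_ratio - beta)^2)
  df <- nrow(r) - 1L
  p <- pchisq(Q, df, lower.tail = FALSE)
  tibble::tibble(
    Q = Q, df = df, pvalue = p,
    model_selected = if (p < q_alpha) "random" else "fixed"
  )
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Re-exports the intercept row of [mr_egger()]; an intercept t-test p-value
#' below `alpha` raises the pleiotropy flag.
#'
#' @param instruments A harmonized instrument tibble (at least 3 rows).
#' @param alpha Flagging level.
#' @return A one-row tibble with `intercept`, `se`, `pvalue`,
#'   `pleiotropy_flag`.
#' @export
egger_intercept_test <- function(instruments, alpha = 0.05) {
  fit <- mr_egger(instruments)
  ic <- fit[fit$method == "egger_intercept", ]
  tibble::tibble(
    intercept = ic$beta, se = ic$se, pvalue = ic$pvalue,
    pleiotropy_flag = ic$pvalue < alpha
  )
}

#' Leave-one-out influence analysis
#'
#' Refits the (auto-model) IVW estimate J times, omitting each instrument in
#' turn.  An omission is flagged when it flips the sign of the estimate or
#' moves it outside the full-set confidence interval.
#'
#' @param instruments A harmonized instrument tibble (at least 3 rows).
#' @param model IVW model passed through to [mr_ivw()].
#' @return A tibble with one row per omitted instrument (`dropped_id`,
#'   `n_snps`, `beta`, `se`, `ci_low`, `ci_high`, `pvalue`, `flagged`); the
#'   full-set estimate is attached as `attr(, "full")`.
#' @export
leave_one_out <- function(instruments, model = "auto") {
  check_instruments(instruments, 3, "leave_one_out")
  J <- nrow(instruments)
  full <- mr_ivw(instruments, model = model)
  rows <- purrr::map_dfr(seq_len(J), function(j) {
    est <- mr_ivw(instruments[-j, , drop = FALSE], model = model)
    tibble::tibble(
      dropped_id = instruments$variant_id[j],
      n_snps = est$n_snps, beta = est$beta, se = est$se,
      ci_low = est$ci_low, ci_high = est$ci_high, pvalue = est$pvalue
    )
  })
  rows$flagged <- sign(rows$beta) != sign(full$beta) |
    rows$beta < full$ci_low | rows$beta > full$ci_high
  attr(rows, "full") <- full
  rows
}

#' Per-instrument F statistics
#'
#' Instrument strength from summary data: `F_j = (gamma_j / se_gamma_j)^2`.
#' By the usual rule of thumb no weak instrument is present when every F
#' exceeds 10; `weak_flag` is therefore raised when `min(F) <= 10`.
#'
#' @param instruments A harmonized instrument tibble.
#' @return A tibble (`variant_id`, `f`) with `min_f`, `mean_f` and
#'   `weak_flag` in `attr(, "summary")`.
#' @export
f_statistics <- function(instruments) {
  check_instruments(instruments, 1, "f_statistics")
  f <- (instruments$gamma / instruments$se_gamma)^2
  out <- tibble::tibble(variant_id = instruments$variant_id, f = f)
  attr(out, "summary") <- list(
    min_f = min(f), mean_f = mean(f), weak_flag = min(f) <= 10
  )
  out
}

#' Full diagnostic panel for one instrument set
#'
#' Runs the heterogeneity, pleiotropy, instrument-strength and leave-one-out
#' diagnostics and collects them with a one-row summary used by the pipeline
#' reports.
#'
#' @param instruments A harmonized instrument tibble (at least 3 rows).
#' @return A list of class `mr_diagnostics` with elements `heterogeneity`,
#'   `egger_intercept`, `f_statistics`, `leave_one_out` and `summary`.
#' @export
mr_diagnostics <- function(instruments) {
  het <- cochran_q(instruments)
  egger <- egger_intercept_test(instruments)
  f <- f_statistics(instruments)
  fsum <- attr(f, "summary")
  loo <- leave_one_out(instruments)
  structure(
    list(
      heterogeneity = het,
      egger_intercept = egger,
      f_statistics = f,
      leave_one_out = loo,
      summary = tibble::tibble(
        n_snps = nrow(instruments),
        Q = het$Q, Q_df = het$df, Q_p = het$pvalue,
        model_selected = het$model_selected,
        egger_intercept = egger$intercept,
        egger_intercept_p = egger$pvalue,
        pleiotropy_flag = egger$pleiotropy_flag,
        min_f = fsum$min_f, mean_f = fsum$mean_f,
        weak_instrument_flag = fsum$weak_flag,
        loo_flagged = sum(loo$flagged)
      )
    ),
    class = "mr_diagnostics"
  )
}
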