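# Broom-style tidiers, print methods and ggplot2 graphics for the result
# objects.

#' @exportS3Method generics::tidy
tidy.mr_pair <- function(x, ...) {
  if (x$status != "ok") {
    return(tibble::tibble(
      method = character(), n_snps = integer(), beta = double(),
      se = double(), ci_low = double(), ci_high = double(),
      pvalue = double(), or = double(), or_ci_low = double(),
      or_ci_high = double(), notes = character()
    ))
  }
  tibble::as_tibble(x$estimates)
}

#' @exportS3Method generics::glance
glance.mr_pair <- function(x, ...) {
  base <- tibble::tibble(
    exposure = x$exposure_label,
    outcome = x$outcome_label,
    status = x$status,
    n_instruments = x$n_instruments
  )
  if (x$status != "ok") {
    return(base)
  }
  ivw <- x$estimates[startsWith(x$estimates$method, "ivw"), ][1, ]
  d <- x$diagnostics$summary
  dplyr::bind_cols(base, tibble::tibble(
    ivw_model = sub("^ivw_", "", ivw$method),
    beta = ivw$beta, se = ivw$se, pvalue = ivw$pvalue,
    or = ivw$or, or_ci_low = ivw$or_ci_low, or_ci_high = ivw$or_ci_high,
    Q_p = d$Q_p, egger_intercept_p = d$egger_intercept_p,
    min_f = d$min_f, weak_instrument_flag = d$weak_instrument_flag
  ))
}

#' @exportS3Method generics::tidy
tidy.mr_presso <- function(x, ...) {
  tibble::as_tibble(x$estimates)
}

#' @exportS3Method generics::glance
glance.mr_presso <- function(x, ...) {
  tibble::tibble(
    global_rss = x$global_rss,
    global_p = x$global_p,
    n_outliers = length(x$outlier_ids),
    distortion_p = x$distortion_p,
    n_sim = x$n_sim
  )
}

#' @exportS3Method generics::tidy
tidy.mr_diagnostics <- function(x, ...) {
  x$summary
}

#' @export
print.mr_pair <- function(x, ...) {
  cat(sprintf(
    "<mr_pair> %s -> %s  [%s, %d instruments]\n",
    x$exposure_label, x$outcome_label, x$status, x$n_instruments
  ))
  if (x$status == "ok") {
    print(tibble::as_tibble(
      x$estimates[, c("method", "n_snps", "or", "or_ci_low", "or_ci_high", "pvalue")]
    ))
  }
  invisible(x)
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf(
    "<mr_presso> global RSS %.4g (p = %.4g), %d outlier(s), distortion p = %s\n",
    x$global_rss, x$global_p, length(x$outlier_ids),
    format(x$distortion_p, digits = 3)
  ))
  print(x$estimates[, c("method", "n_snps", "beta", "se", "pvalue", "notes")])
  invisible(x)
}

#' @export
print.mr_bidirectional <- function(x, ...) {
  cat(sprintf(
    "<mr_bidirectional> %d direction(s)%s\n", length(x$runs),
    if (x$any_failed) " (some under-instrumented)" else ""
  ))
  print(x$summary)
  invisible(x)
}

#' Forest plot of the estimator panel for one analysis
#'
#' @param object An `mr_pair` from [run_pair()].
#' @param ... Unused.
#' @return A ggplot: odds ratios with 95% confidence intervals per method.
#' @exportS3Method ggplot2::autoplot
autoplot.mr_pair <- function(object, ...) {
  if (object$status != "ok") {
    abort("Nothing to plot: pair is under-instrumented.",
      class = "bimr_error_under_instrumented"
    )
  }
  est <- tibble::as_tibble(object$estimates)
  est <- est[est$method != "egger_intercept", ]
  est$method <- factor(est$method, levels = rev(unique(est$method)))
  ggplot2::ggplot(est, ggplot2::aes(x = .data$or, y = .data$method)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$or_ci_low, xmax = .data$or_ci_high),
      height = 0.2
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Odds ratio (95% CI)", y = NULL,
      title = sprintf("%s → %s", object$exposure_label, object$outcome_label)
    ) +
    ggplot2::theme_minimal()
}

#' Scatter plot of instrument effects with fitted slopes
#'
#' Outcome effects against exposure effects, one point per instrument with
#' +/- 1 SE bars, overlaid with the IVW (through the origin) and Egger
#' (free intercept) fits.
#'
#' @param instruments A harmonized instrument tibble.
#' @return A ggplot.
#' @export
plot_scatter <- function(instruments) {
  check_instruments(instruments, 3, "plot_scatter")
  ivw <- mr_ivw(instruments)
  egger <- mr_egger(instruments)
  slope <- egger$beta[egger$method == "egger_slope"]
  intercept <- egger$beta[egger$method == "egger_intercept"]
  df <- tibble::as_tibble(instruments)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gamma, y = .data$Gamma)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$Gamma - .data$se_Gamma,
        ymax = .data$Gamma + .data$se_Gamma
      ),
      width = 0, colour = "grey60"
    ) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(
        xmin = .data$gamma - .data$se_gamma,
        xmax = .data$gamma + .data$se_gamma
      ),
      height = 0, colour = "grey60"
    ) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = 0, slope = ivw$beta, colour = "#2166ac") +
    ggplot2::geom_abline(intercept = intercept, slope = slope, colour = "#b2182b", linetype = "dashed") +
    ggplot2::labs(
      x = "Effect on exposure (log odds)",
      y = "Effect on outcome (log odds)",
      caption = "solid: IVW; dashed: MR-Egger"
    ) +
    ggplot2::theme_minimal()
}

#' Leave-one-out forest plot
#'
#' @param loo A leave-one-out table from [leave_one_out()].
#' @return A ggplot of the IVW estimate with each instrument omitted.
#' @export
plot_leave_one_out <- function(loo) {
  full <- attr(loo, "full")
  df <- tibble::as_tibble(loo)
  df$dropped_id <- factor(df$dropped_id, levels = rev(df$dropped_id))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, y = .data$dropped_id)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "IVW estimate omitting variant (log odds)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(full)) {
    p <- p + ggplot2::geom_vline(
      xintercept = full$beta,
      linetype = "dashed", colour = "grey40"
    )
  }
  p
}
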