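# Shared internal helpers: the causal-estimate row constructor, seeded
# evaluation, and small assertions used across estimators.

# Two-sided p with a floor so reported p stays in (0, 1].
two_sided_p <- function(stat, df = NULL) {
  p <- if (is.null(df)) 2 * pnorm(-abs(stat)) else 2 * pt(-abs(stat), df)
  pmax(p, 1e-300)
}

# One-row causal-estimate tibble shared by every estimator.  Wald CI on the
# log-odds scale (normal reference, or t when `df` is supplied), with the
# odds-ratio transform applied only at this reporting layer.
new_estimate <- function(method, beta, se, n_snps, df = NULL, notes = NA_character_) {
  crit <- if (is.null(df)) qnorm(0.975) else qt(0.975, df)
  ci_low <- beta - crit * se
  ci_high <- beta + crit * se
  out <- tibble::tibble(
    method = method,
    n_snps = as.integer(n_snps),
    beta = beta,
    se = se,
    ci_low = ci_low,
    ci_high = ci_high,
    pvalue = two_sided_p(beta / se, df),
    or = exp(beta),
    or_ci_low = exp(ci_low),
    or_ci_high = exp(ci_high),
    notes = notes
  )
  class(out) <- c("mr_estimate", class(out))
  out
}

# Evaluate `code` under a temporary RNG seed when one is given; leave the
# session RNG stream untouched either way (withr restores state).
with_seed_if <- function(seed, code) {
  if (is.null(seed)) {
    code
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

check_instruments <- function(instruments, min_n, method) {
  needed <- c("variant_id", "gamma", "se_gamma", "Gamma", "se_Gamma")
  missing <- setdiff(needed, names(instruments))
  if (length(missing) > 0) {
    abort(paste0(
      "`instruments` is missing column(s): ", paste(missing, collapse = ", "),
      " (expected a harmonized instrument table)."
    ), class = "bimr_error_columns")
  }
  if (nrow(instruments) < min_n) {
    abort(sprintf(
      "%s needs at least %d instruments but received %d.",
      method, min_n, nrow(instruments)
    ), class = "bimr_error_insufficient_instruments")
  }
  if (any(instruments$se_gamma <= 0) || any(instruments$se_Gamma <= 0)) {
    abort("All instrument standard errors must be strictly positive.",
      class = "bimr_error_invalid_se"
    )
  }
  invisible(instruments)
}

# Chromosome sort key: numeric chromosomes first in numeric order, then
# non-numeric labels (X, Y, MT, ...) lexicographically.
chromosome_order <- function(chromosome, position) {
  num <- suppressWarnings(as.numeric(chromosome))
  order(is.na(num), num, chromosome, position)
}
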