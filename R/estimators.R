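# Causal-effect estimators on a harmonized instrument set: per-SNP Wald
# ratios, fixed/random IVW, simple and weighted medians, MR-Egger,
# MR-PRESSO, robust adjusted profile score (Huber), and the summary-data
# genetic risk score.

#' Per-variant Wald ratio estimates
#'
#' The Wald ratio for one SNP is the outcome effect divided by the exposure
#' effect; its first-order standard error is `se_Gamma / |gamma|` (the
#' exposure-side variance term is ignored, the convention underlying the IVW
#' weights), and the IVW weight is the inverse squared SE.
#'
#' @param instruments A harmonized instrument tibble (see [harmonize()] or
#'   [simulate_instruments()]).
#' @return A tibble with columns `variant_id`, `wald_ratio`, `se_ratio`,
#'   `weight`.
#' @export
wald_ratios <- function(instruments) {
  check_instruments(instruments, 1, "wald_ratios")
  zero <- instruments$gamma == 0
  if (any(zero)) {
    abort(paste0(
      "Degenerate instrument(s) with zero exposure effect: ",
      paste(instruments$variant_id[zero], collapse = ", ")
    ), class = "bimr_error_degenerate_instrument")
  }
  se_ratio <- instruments$se_Gamma / abs(instruments$gamma)
  tibble::tibble(
    variant_id = instruments$variant_id,
    wald_ratio = instruments$Gamma / instruments$gamma,
    se_ratio = se_ratio,
    weight = se_ratio^-2
  )
}

#' Inverse-variance-weighted causal estimate
#'
#' Combines per-SNP Wald ratios by inverse-variance meta-analysis:
#' `beta = sum(w * ratio) / sum(w)` with `w = se_ratio^-2`.  The fixed-effect
#' SE is `sum(w)^-0.5`; the multiplicative random-effects SE inflates it by
#' `max(1, sqrt(Q / (J - 1)))` where Q is Cochran's heterogeneity statistic.
#' Under `model = "auto"` the random-effects model is used when the Q test
#' p-value is below `q_alpha`, mirroring the usual reporting rule.
#'
#' @param instruments A harmonized instrument tibble.
#' @param model `"auto"` (default), `"fixed"` or `"random"`.
#' @param q_alpha Heterogeneity significance level driving the auto choice.
#' @param allow_single Permit a single-instrument fixed-effect estimate
#'   (which is just its Wald ratio); off by default.
#' @return A one-row causal-estimate tibble (class `mr_estimate`) with the
#'   effect on the log-odds scale, SE, 95% Wald CI, two-sided normal p, and
#'   the odds-ratio transform.  Heterogeneity details are attached as
#'   `attr(, "heterogeneity")`.
#' @export
mr_ivw <- function(instruments, model = c("auto", "fixed", "random"),
                   q_alpha = 0.05, allow_single = FALSE) {
  model <- match.arg(model)
  min_n <- if (allow_single && model == "fixed") 1 else 2
  check_instruments(instruments, min_n, "mr_ivw")
  r <- wald_ratios(instruments)
  J <- nrow(r)
  w <- r$weight
  beta <- sum(w * r$wald_ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  if (J >= 2) {
    Q <- sum(w * (r$wald_ratio - beta)^2)
    df <- J - 1
    q_p <- pchisq(Q, df, lower.tail = FALSE)
  } else {
    Q <- NA_real_
    df <- NA_integer_
    q_p <- NA_real_
  }
  model_used <- switch(model,
    fixed = "fixed",
    random = "random",
    auto = if (J >= 2 && q_p < q_alpha) "random" else "fixed"
  )
  se <- if (model_used == "random") se_fixed * max(1, sqrt(Q / df)) else se_fixed
  est <- new_estimate(
    paste0("ivw_", model_used), beta, se, J,
    notes = sprintf("Q=%.6g; Q_df=%s; Q_p=%.4g", Q, df, q_p)
  )
  attr(est, "heterogeneity") <- list(
    Q = Q, df = df, pvalue = q_p, model_selected = model_used
  )
  est
}

# Interpolated weighted median: the 50th percentile of the weighted
# empirical distribution of b, at standardized cumulative weights
# p_j = (S_j - w_j / 2) / S_total.
weighted_median_point <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o]
  S <- cumsum(w)
  p <- (S - w / 2) / S[length(S)]
  if (0.5 <= p[1]) {
    return(b[1])
  }
  if (0.5 >= p[length(p)]) {
    return(b[length(b)])
  }
  stats::approx(p, b, xout = 0.5, ties = "ordered")$y
}

#' Simple- and weighted-median causal estimates
#'
#' The simple median is the sample median of the Wald ratios; the weighted
#' median is the interpolated 50th percentile of their inverse-variance
#' weighted empirical distribution.  Both are consistent when at least half
#' of the (weight in the) instruments is valid.  The SE comes from a seeded
#' parametric bootstrap: each Wald ratio is resampled from
#' `Normal(ratio_j, se_ratio_j)` and the median recomputed.
#'
#' @param instruments A harmonized instrument tibble (at least 3 rows).
#' @param weighted Use inverse-variance weights (`TRUE`) or equal weights.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed for the bootstrap; `NULL` uses the session RNG.
#' @return A one-row `mr_estimate` tibble.
#' @export
mr_median <- function(instruments, weighted = TRUE, n_boot = 1000,
                      seed = NULL) {
  check_instruments(instruments, 3, "mr_median")
  r <- wald_ratios(instruments)
  J <- nrow(r)
  w <- if (weighted) r$weight else rep(1, J)
  point <- if (weighted) {
    weighted_median_point(r$wald_ratio, w)
  } else {
    median(r$wald_ratio)
  }
  boots <- with_seed_if(seed, {
    vapply(seq_len(n_boot), function(i) {
      bb <- rnorm(J, r$wald_ratio, r$se_ratio)
      if (weighted) weighted_median_point(bb, w) else median(bb)
    }, numeric(1))
  })
  new_estimate(
    if (weighted) "weighted_median" else "simple_median",
    point, sd(boots), J,
    notes = sprintf("n_boot=%d", n_boot)
  )
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with an
#' intercept, weights `se_Gamma^-2`, after orienting every exposure effect
#' to be non-negative (flipping the sign of both coordinates where needed —
#' Egger is the one estimator here that is not invariant to allele
#' recoding).  The slope estimates the causal effect under the InSIDE
#' assumption; the intercept estimates average directional pleiotropy.
#' Standard errors carry a multiplicative overdispersion scale
#' `max(1, sqrt(RSS / (J - 2)))` and p-values use a t reference with J - 2
#' degrees of freedom.
#'
#' @param instruments A harmonized instrument tibble (at least 3 rows).
#' @return A two-row `mr_estimate` tibble (`egger_slope`, `egger_intercept`)
#'   with fit details in `attr(, "egger")`.
#' @export
mr_egger <- function(instruments) {
  check_instruments(instruments, 3, "mr_egger")
  J <- nrow(instruments)
  s <- ifelse(instruments$gamma < 0, -1, 1)
  g <- instruments$gamma * s
  G <- instruments$Gamma * s
  w <- instruments$se_Gamma^-2
  X <- cbind(1, g)
  A <- crossprod(X, w * X)
  coef <- unname(drop(solve(A, crossprod(X, w * G))))
  rss <- sum(w * (G - drop(X %*% coef))^2)
  df <- J - 2
  scale <- max(1, sqrt(rss / df))
  ses <- unname(sqrt(diag(solve(A)))) * scale
  out <- dplyr::bind_rows(
    new_estimate("egger_slope", coef[2], ses[2], J, df = df),
    new_estimate("egger_intercept", coef[1], ses[1], J, df = df)
  )
  class(out) <- c("mr_estimate", class(out)[class(out) != "mr_estimate"])
  attr(out, "egger") <- list(rss = rss, df = df, scale = scale)
  out
}

# Fixed-effect IVW slope of Gamma on gamma leaving each SNP out in turn,
# computed from running totals (weights u = se_Gamma^-2).
loo_ivw_slopes <- function(g, G, u) {
  t1 <- sum(u * g * G)
  t2 <- sum(u * g^2)
  (t1 - u * g * G) / (t2 - u * g^2)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Simulation-based pleiotropy screen.  The observed per-SNP residual is
#' `RSS_j = u_j * (Gamma_j - b_(-j) * gamma_j)^2` with `u_j = se_Gamma^-2`
#' and `b_(-j)` the leave-one-out fixed-effect IVW slope; the global
#' statistic is their sum.  The null distribution is built by parametric
#' simulation — `Gamma*_j ~ Normal(b_(-j) * gamma_j, se_Gamma_j)` and
#' `gamma*_j ~ Normal(gamma_j, se_gamma_j)` — recomputing the leave-one-out
#' slopes and RSS within every replicate.  The global test reports the
#' +1-corrected empirical tail probability; the outlier test compares each
#' `RSS_j` with its simulated counterparts at the Bonferroni-corrected level
#' `outlier_alpha / J`; the corrected estimate is fixed-effect IVW on the
#' unflagged instruments; and the distortion test compares the relative
#' shift `(b_raw - b_corrected) / b_corrected` with its distribution under
#' random outlier assignment.
#'
#' @param instruments A harmonized instrument tibble (at least 4 rows).
#' @param n_sim Number of simulation replicates (at least 100).
#' @param outlier_alpha Nominal level of the outlier test before Bonferroni
#'   correction.
#' @param seed Integer seed; `NULL` uses the session RNG.
#' @return An object of class `mr_presso`: a list with `global_rss`,
#'   `global_p`, `outliers` (per-SNP RSS, empirical p and flag),
#'   `outlier_ids`, `distortion_p`, `n_sim`, `seed`, and `estimates` — a
#'   two-row `mr_estimate` tibble (`presso_raw`, `presso_corrected`).
#' @export
mr_presso <- function(instruments, n_sim = 1000, outlier_alpha = 0.05,
                      seed = NULL) {
  check_instruments(instruments, 4, "mr_presso")
  if (n_sim < 100) {
    abort("mr_presso needs n_sim >= 100.", class = "bimr_error_config")
  }
  J <- nrow(instruments)
  g <- instruments$gamma
  G <- instruments$Gamma
  sg <- instruments$se_gamma
  sG <- instruments$se_Gamma
  u <- sG^-2
  b_loo <- loo_ivw_slopes(g, G, u)
  rss_j <- u * (G - b_loo * g)^2
  rss_obs <- sum(rss_j)

  res <- with_seed_if(seed, {
    gs <- matrix(rnorm(n_sim * J, rep(g, each = n_sim), rep(sg, each = n_sim)),
      n_sim, J
    )
    Gs <- matrix(
      rnorm(n_sim * J, rep(b_loo * g, each = n_sim), rep(sG, each = n_sim)),
      n_sim, J
    )
    U <- matrix(u, n_sim, J, byrow = TRUE)
    t1 <- rowSums(U * gs * Gs)
    t2 <- rowSums(U * gs^2)
    b_star <- (t1 - U * gs * Gs) / (t2 - U * gs^2)
    rss_star_j <- U * (Gs - b_star * gs)^2
    global_p <- (1 + sum(rowSums(rss_star_j) >= rss_obs)) / (n_sim + 1)
    outlier_p <- (1 + colSums(rss_star_j >= matrix(rss_j, n_sim, J, byrow = TRUE))) /
      (n_sim + 1)
    flagged <- outlier_p < outlier_alpha / J

    raw <- mr_ivw(instruments, model = "fixed")
    raw$method <- "presso_raw"
    raw$notes <- sprintf("global_p=%.4g", global_p)
    if (all(flagged)) {
      abort("MR-PRESSO flagged every instrument; no corrected estimate.",
        class = "bimr_error_degenerate_correction"
      )
    }
    if (any(flagged)) {
      corrected <- mr_ivw(instruments[!flagged, , drop = FALSE],
        model = "fixed", allow_single = TRUE
      )
      corrected$method <- "presso_corrected"
      n_out <- sum(flagged)
      d_obs <- (raw$beta - corrected$beta) / corrected$beta
      d_star <- vapply(seq_len(n_sim), function(i) {
        drop_idx <- sample.int(J, n_out)
        keep <- setdiff(seq_len(J), drop_idx)
        b_sub <- sum(u[keep] * g[keep] * G[keep]) / sum(u[keep] * g[keep]^2)
        (raw$beta - b_sub) / b_sub
      }, numeric(1))
      distortion_p <- (1 + sum(abs(d_star) >= abs(d_obs))) / (n_sim + 1)
      corrected$notes <- sprintf(
        "outliers_removed=%s; distortion_p=%.4g",
        paste(instruments$variant_id[flagged], collapse = ","), distortion_p
      )
    } else {
      corrected <- raw
      corrected$method <- "presso_corrected"
      corrected$notes <- "no outliers flagged"
      distortion_p <- NA_real_
    }
    list(
      global_p = global_p, outlier_p = outlier_p, flagged = flagged,
      raw = raw, corrected = corrected, distortion_p = distortion_p
    )
  })

  estimates <- dplyr::bind_rows(res$raw, res$corrected)
  class(estimates) <- c("mr_estimate", class(estimates)[class(estimates) != "mr_estimate"])
  structure(
    list(
      global_rss = rss_obs,
      global_p = res$global_p,
      outliers = tibble::tibble(
        variant_id = instruments$variant_id,
        rss = rss_j,
        pvalue = res$outlier_p,
        flagged = res$flagged
      ),
      outlier_ids = instruments$variant_id[res$flagged],
      distortion_p = res$distortion_p,
      n_sim = n_sim,
      seed = seed,
      estimates = estimates
    ),
    class = "mr_presso"
  )
}

huber_psi <- function(t, k) pmin(pmax(t, -k), k)

huber_rho <- function(t, k) {
  ifelse(abs(t) <= k, t^2 / 2, k * abs(t) - k^2 / 2)
}

# E[psi(Z)^2] = E[min(Z^2, k^2)] under Z ~ N(0, 1); calibrates the
# overdispersion profile.
huber_psi2_expectation <- function(k) {
  (2 * pnorm(k) - 1) - 2 * k * stats::dnorm(k) + 2 * k^2 * pnorm(-k)
}

#' Robust adjusted profile score (MR-RAPS) estimate
#'
#' Solves the robust profile-score estimating equation
#' `sum_j psi(t_j(beta)) * dt_j/dbeta = 0` where
#' `t_j = (Gamma_j - beta * gamma_j) / sqrt(se_Gamma_j^2 + beta^2 *
#' se_gamma_j^2 + tau2)` and `psi` is the Huber score with tuning constant
#' `huber_k`.  Unlike IVW this profiles out the exposure-side measurement
#' error, and the bounded influence function limits the leverage of
#' idiosyncratically pleiotropic variants.  With `overdispersion = TRUE` a
#' systematic-pleiotropy variance `tau2` is profiled jointly by matching the
#' mean squared Huber score to its standard-normal expectation.  The root is
#' found by bracketed root finding seeded at the IVW estimate, with a dense
#' grid scan over the integrated Huber loss as fallback; the SE uses the
#' sandwich form of the estimating equation.
#'
#' @param instruments A harmonized instrument tibble (at least 3 rows).
#' @param huber_k Huber tuning constant (1.345 gives 95% Gaussian
#'   efficiency).
#' @param overdispersion Profile a nonnegative systematic-pleiotropy
#'   variance `tau2` jointly with `beta`.
#' @return A one-row `mr_estimate` tibble; `attr(, "raps")` records `tau2`
#'   and convergence details.
#' @export
mr_raps <- function(instruments, huber_k = 1.345, overdispersion = FALSE) {
  check_instruments(instruments, 3, "mr_raps")
  J <- nrow(instruments)
  g <- instruments$gamma
  G <- instruments$Gamma
  sg2 <- instruments$se_gamma^2
  sG2 <- instruments$se_Gamma^2

  score <- function(beta, tau2) {
    s2 <- sG2 + beta^2 * sg2 + tau2
    s <- sqrt(s2)
    t <- (G - beta * g) / s
    dt <- -g / s - t * beta * sg2 / s2
    sum(huber_psi(t, huber_k) * dt)
  }
  objective <- function(beta, tau2) {
    s <- sqrt(sG2 + beta^2 * sg2 + tau2)
    sum(huber_rho((G - beta * g) / s, huber_k))
  }

  solve_beta <- function(tau2) {
    ivw <- mr_ivw(instruments, model = "fixed")
    half <- max(10 * ivw$se, 0.25)
    lo <- ivw$beta - half
    hi <- ivw$beta + half
    for (i in 1:12) {
      if (sign(score(lo, tau2)) != sign(score(hi, tau2))) break
      half <- half * 2
      lo <- ivw$beta - half
      hi <- ivw$beta + half
    }
    if (sign(score(lo, tau2)) != sign(score(hi, tau2))) {
      return(uniroot(score, c(lo, hi), tau2 = tau2, tol = 1e-12)$root)
    }
    # Grid fallback: locate the loss minimizer, then bracket locally.
    grid <- seq(lo, hi, length.out = 4001)
    vals <- vapply(grid, objective, numeric(1), tau2 = tau2)
    i <- which.min(vals)
    if (i == 1 || i == length(grid)) {
      abort(sprintf(
        "mr_raps did not converge: no score sign change over [%.4g, %.4g].",
        lo, hi
      ), class = "bimr_error_nonconvergence")
    }
    if (sign(score(grid[i - 1], tau2)) != sign(score(grid[i + 1], tau2))) {
      uniroot(score, c(grid[i - 1], grid[i + 1]), tau2 = tau2, tol = 1e-12)$root
    } else {
      grid[i]
    }
  }

  tau2 <- 0
  beta <- solve_beta(tau2)
  if (overdispersion) {
    c_k <- huber_psi2_expectation(huber_k)
    mean_psi2 <- function(tau2, beta) {
      s <- sqrt(sG2 + beta^2 * sg2 + tau2)
      mean(huber_psi((G - beta * g) / s, huber_k)^2)
    }
    for (iter in 1:50) {
      f0 <- mean_psi2(0, beta) - c_k
      if (f0 <= 0) {
        tau2_new <- 0
      } else {
        upper <- stats::var(G - beta * g) + max(sG2)
        while (mean_psi2(upper, beta) - c_k > 0) upper <- upper * 4
        tau2_new <- uniroot(function(x) mean_psi2(x, beta) - c_k,
          c(0, upper),
          tol = 1e-12
        )$root
      }
      beta_new <- solve_beta(tau2_new)
      done <- abs(beta_new - beta) < 1e-10 && abs(tau2_new - tau2) < 1e-12
      beta <- beta_new
      tau2 <- tau2_new
      if (done) break
    }
  }

  # Sandwich SE: se = sqrt(B) / |A| with A = -dg/dbeta at the root and
  # B = sum of squared per-SNP score contributions.
  h <- 1e-6 * (1 + abs(beta))
  A <- -(score(beta + h, tau2) - score(beta - h, tau2)) / (2 * h)
  s2 <- sG2 + beta^2 * sg2 + tau2
  s <- sqrt(s2)
  t <- (G - beta * g) / s
  dt <- -g / s - t * beta * sg2 / s2
  B <- sum((huber_psi(t, huber_k) * dt)^2)
  se <- sqrt(B) / abs(A)

  est <- new_estimate("raps", beta, se, J,
    notes = sprintf("huber_k=%.4g; tau2=%.4g", huber_k, tau2)
  )
  attr(est, "raps") <- list(tau2 = tau2, huber_k = huber_k)
  est
}

#' Genetic risk score causal estimate from summary statistics
#'
#' For uncorrelated score variants with weights `omega` (effects on the
#' intermediate trait) and outcome effects `beta_out` with standard errors
#' `se_out`, the causal effect of the score-weighted exposure is
#' `alpha = sum(omega * beta * se^-2) / sum(omega^2 * se^-2)` with standard
#' error `sqrt(1 / sum(omega^2 * se^-2))`.  Taking `omega` as the exposure
#' effects reduces this to weighted regression through the origin, i.e. the
#' fixed-effect IVW estimate.
#'
#' @param omega Numeric vector of per-variant score weights.
#' @param beta_out Numeric vector of per-variant outcome effects.
#' @param se_out Numeric vector of positive outcome standard errors.
#' @return A one-row `mr_estimate` tibble (method `grs`).
#' @seealso [mr_grs()] for the instrument-table interface.
#' @export
grs_summary <- function(omega, beta_out, se_out) {
  if (length(omega) < 1 || length(beta_out) != length(omega) ||
    length(se_out) != length(omega)) {
    abort("omega, beta_out and se_out must have equal length >= 1.",
      class = "bimr_error_config"
    )
  }
  if (any(se_out <= 0)) {
    abort("All se_out must be strictly positive.",
      class = "bimr_error_invalid_se"
    )
  }
  denom <- sum(omega^2 / se_out^2)
  if (denom == 0) {
    abort("Degenerate weights: sum(omega^2 / se_out^2) is zero.",
      class = "bimr_error_degenerate_weights"
    )
  }
  alpha <- sum(omega * beta_out / se_out^2) / denom
  new_estimate("grs", alpha, sqrt(1 / denom), length(omega))
}

#' Genetic risk score estimate from a harmonized instrument table
#'
#' Applies [grs_summary()] with the exposure effects as score weights and
#' the harmonized outcome effects as responses.
#'
#' @inheritParams wald_ratios
#' @return A one-row `mr_estimate` tibble.
#' @export
mr_grs <- function(instruments) {
  check_instruments(instruments, 1, "mr_grs")
  grs_summary(instruments$gamma, instruments$Gamma, instruments$se_Gamma)
}

#' Run a panel of causal estimators
#'
#' Convenience wrapper running any subset of the estimators on one
#' instrument set and binding the resulting rows.
#'
#' @param instruments A harmonized instrument tibble.
#' @param methods Subset of `"ivw"`, `"median_simple"`, `"median_weighted"`,
#'   `"egger"`, `"presso"`, `"raps"`, `"grs"`.
#' @param n_sim,n_boot Replicates for MR-PRESSO and the median bootstrap.
#' @param seed Base integer seed; stochastic methods use fixed offsets from
#'   it so each draws an independent, reproducible stream.
#' @return An `mr_estimate` tibble, one row per fitted quantity; the full
#'   MR-PRESSO object, when run, is attached as `attr(, "presso")`.
#' @export
mr_all <- function(instruments,
                   methods = c(
                     "ivw", "median_simple", "median_weighted",
                     "egger", "presso", "raps", "grs"
                   ),
                   n_sim = 1000, n_boot = 1000, seed = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  seed_of <- function(offset) if (is.null(seed)) NULL else as.integer(seed) + offset
  rows <- list()
  presso <- NULL
  for (m in methods) {
    rows[[m]] <- switch(m,
      ivw = mr_ivw(instruments, model = "auto"),
      median_simple = mr_median(instruments,
        weighted = FALSE,
        n_boot = n_boot, seed = seed_of(1L)
      ),
      median_weighted = mr_median(instruments,
        weighted = TRUE,
        n_boot = n_boot, seed = seed_of(2L)
      ),
      egger = mr_egger(instruments),
      presso = {
        presso <- mr_presso(instruments, n_sim = n_sim, seed = seed_of(3L))
        presso$estimates
      },
      raps = mr_raps(instruments),
      grs = mr_grs(instruments)
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mr_estimate", class(out)[class(out) != "mr_estimate"])
  attr(out, "presso") <- presso
  out
}
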