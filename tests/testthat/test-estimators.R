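# Estimator algebra against independent oracles.

test_that("Wald ratios equal elementwise division with first-order SEs", {
  inst <- tibble::tibble(
    variant_id = c("a", "b"),
    gamma = c(1, 2), se_gamma = c(0.1, 0.1),
    Gamma = c(0.3, 0), se_Gamma = c(0.1, 0.1)
  )
  r <- wald_ratios(inst)
  expect_equal(r$wald_ratio, c(0.3, 0))
  expect_equal(r$se_ratio, c(0.1, 0.05))
  expect_equal(r$weight, r$se_ratio^-2)

  set.seed(31)
  inst2 <- random_instruments(10)
  r2 <- wald_ratios(inst2)
  for (j in 1:10) {
    expect_equal(r2$wald_ratio[j], inst2$Gamma[j] / inst2$gamma[j])
    expect_equal(r2$se_ratio[j], inst2$se_Gamma[j] / abs(inst2$gamma[j]))
  }

  inst$gamma[1] <- 0
  expect_error(wald_ratios(inst), class = "bimr_error_degenerate_instrument")
})

test_that("IVW equals weighted least squares through the origin", {
  set.seed(32)
  inst <- random_instruments(25)
  est <- mr_ivw(inst, model = "fixed")
  # oracle: normal equations of WLS of Gamma on gamma, weights se_Gamma^-2
  w <- inst$se_Gamma^-2
  beta_wls <- sum(w * inst$gamma * inst$Gamma) / sum(w * inst$gamma^2)
  se_wls <- sqrt(1 / sum(w * inst$gamma^2))
  expect_equal(est$beta, beta_wls, tolerance = 1e-12)
  expect_equal(est$se, se_wls, tolerance = 1e-12)
})

test_that("IVW reduces correctly in degenerate cases", {
  # equal weights: plain mean of ratios
  inst <- tibble::tibble(
    variant_id = c("a", "b", "c"),
    gamma = 1, se_gamma = 0.01,
    Gamma = c(0.1, 0.2, 0.3), se_Gamma = 0.1
  )
  expect_equal(mr_ivw(inst, model = "fixed")$beta, 0.2)
  # single instrument via explicit override: its Wald ratio and SE
  one <- inst[1, ]
  est1 <- mr_ivw(one, model = "fixed", allow_single = TRUE)
  expect_equal(est1$beta, 0.1)
  expect_equal(est1$se, 0.1)
  expect_error(mr_ivw(one), class = "bimr_error_insufficient_instruments")
})

test_that("random-effects SE is the fixed SE inflated by sqrt(Q/df), floored at 1", {
  set.seed(33)
  for (i in 1:20) {
    inst <- random_instruments(12)
    if (i %% 2 == 0) inst$Gamma <- inst$Gamma + rnorm(12, 0, 0.1) # heterogeneity
    fx <- mr_ivw(inst, model = "fixed")
    rnd <- mr_ivw(inst, model = "random")
    het <- attr(fx, "heterogeneity")
    expect_equal(rnd$beta, fx$beta)
    expect_equal(rnd$se, fx$se * max(1, sqrt(het$Q / het$df)), tolerance = 1e-12)
    expect_gte(rnd$se, fx$se)
    if (het$Q <= het$df) expect_equal(rnd$se, fx$se)
    # auto follows the Q-test rule
    auto <- mr_ivw(inst, model = "auto")
    expect_equal(
      auto$method,
      if (het$pvalue < 0.05) "ivw_random" else "ivw_fixed"
    )
  }
})

test_that("simple median is the middle order statistic; equal weights reduce", {
  inst <- tibble::tibble(
    variant_id = c("a", "b", "c"),
    gamma = 1, se_gamma = 0.01,
    Gamma = c(0.1, 0.2, 0.9), se_Gamma = 0.05
  )
  expect_equal(mr_median(inst, weighted = FALSE, n_boot = 100, seed = 1)$beta, 0.2)
  # equal weights: weighted median equals simple median exactly
  expect_equal(
    mr_median(inst, weighted = TRUE, n_boot = 100, seed = 1)$beta, 0.2
  )
  set.seed(34)
  inst2 <- random_instruments(8)
  inst2$se_Gamma <- 0.02 * abs(inst2$gamma) # constant se_ratio => equal weights
  expect_equal(
    mr_median(inst2, weighted = TRUE, n_boot = 100, seed = 1)$beta,
    mr_median(inst2, weighted = FALSE, n_boot = 100, seed = 1)$beta
  )
})

test_that("weighted median matches a fine-grid weighted-CDF oracle", {
  set.seed(35)
  inst <- random_instruments(5)
  got <- mr_median(inst, weighted = TRUE, n_boot = 100, seed = 1)$beta
  r <- wald_ratios(inst)
  o <- order(r$wald_ratio)
  b <- r$wald_ratio[o]
  w <- r$weight[o]
  p <- (cumsum(w) - w / 2) / sum(w)
  # oracle: evaluate the piecewise-linear interpolated CDF on a dense grid
  grid <- seq(min(b), max(b), length.out = 200001)
  cdf <- approx(b, p, xout = grid, rule = 2, ties = "ordered")$y
  oracle <- grid[which.min(abs(cdf - 0.5))]
  expect_equal(got, oracle, tolerance = 1e-4)
})

test_that("median bootstrap SE is seeded and reproducible", {
  set.seed(36)
  inst <- random_instruments(10)
  a <- mr_median(inst, weighted = TRUE, n_boot = 200, seed = 9)
  b <- mr_median(inst, weighted = TRUE, n_boot = 200, seed = 9)
  expect_identical(a$se, b$se)
  expect_error(
    mr_median(inst[1:2, ], n_boot = 100, seed = 1),
    class = "bimr_error_insufficient_instruments"
  )
})

test_that("Egger recovers exact lines and matches the normal-equation oracle", {
  exact <- exact_instruments(6, alpha = 0.5, intercept = 0)
  fit <- mr_egger(exact)
  expect_equal(fit$beta[fit$method == "egger_slope"], 0.5, tolerance = 1e-10)
  expect_equal(fit$beta[fit$method == "egger_intercept"], 0, tolerance = 1e-10)
  expect_equal(attr(fit, "egger")$rss, 0, tolerance = 1e-12)

  affine <- exact_instruments(6, alpha = 0.5, intercept = 0.02)
  fit2 <- mr_egger(affine)
  expect_equal(fit2$beta[fit2$method == "egger_intercept"], 0.02, tolerance = 1e-10)

  set.seed(37)
  inst <- random_instruments(15)
  inst$gamma[3] <- -inst$gamma[3] # exercise the orientation step
  fit3 <- mr_egger(inst)
  # oracle: closed-form 2x2 weighted normal equations after orientation
  s <- sign(inst$gamma)
  g <- abs(inst$gamma)
  G <- inst$Gamma * s
  w <- inst$se_Gamma^-2
  sw <- sum(w)
  sx <- sum(w * g)
  sxx <- sum(w * g^2)
  sy <- sum(w * G)
  sxy <- sum(w * g * G)
  det <- sw * sxx - sx^2
  slope <- (sw * sxy - sx * sy) / det
  intercept <- (sxx * sy - sx * sxy) / det
  expect_equal(fit3$beta[fit3$method == "egger_slope"], slope, tolerance = 1e-10)
  expect_equal(fit3$beta[fit3$method == "egger_intercept"], intercept, tolerance = 1e-10)
  rss <- sum(w * (G - intercept - slope * g)^2)
  scale <- max(1, sqrt(rss / (15 - 2)))
  expect_equal(
    fit3$se[fit3$method == "egger_slope"],
    sqrt(sw / det) * scale,
    tolerance = 1e-10
  )
  expect_error(mr_egger(inst[1:2, ]), class = "bimr_error_insufficient_instruments")
})

test_that("Egger p-values use a t reference with J - 2 degrees of freedom", {
  set.seed(38)
  inst <- random_instruments(8)
  fit <- mr_egger(inst)
  slope <- fit[fit$method == "egger_slope", ]
  expect_equal(slope$pvalue, 2 * pt(-abs(slope$beta / slope$se), 6))
})

test_that("RAPS returns the exact root on residual-free data", {
  exact <- exact_instruments(6, alpha = 0.37)
  est <- mr_raps(exact)
  expect_equal(est$beta, 0.37, tolerance = 1e-8)
})

test_that("RAPS agrees with IVW on clean data and with a grid-search oracle", {
  set.seed(39)
  sim <- simulate_instruments(sim_config(n_snps = 30, seed = 101))
  ivw <- mr_ivw(sim$instruments, model = "fixed")
  raps <- mr_raps(sim$instruments)
  expect_lt(
    abs(raps$beta - ivw$beta),
    2 * sqrt(raps$se^2 + ivw$se^2)
  )
  # the root minimizes the integrated Huber loss over a dense grid
  inst <- sim$instruments
  k <- 1.345
  loss <- function(beta) {
    s <- sqrt(inst$se_Gamma^2 + beta^2 * inst$se_gamma^2)
    t <- (inst$Gamma - beta * inst$gamma) / s
    sum(ifelse(abs(t) <= k, t^2 / 2, k * abs(t) - k^2 / 2))
  }
  grid <- seq(-2, 2, length.out = 80001)
  oracle <- grid[which.min(vapply(grid, loss, numeric(1)))]
  expect_equal(raps$beta, oracle, tolerance = 1e-3)
})

test_that("RAPS overdispersion profiles a nonnegative tau2", {
  set.seed(40)
  sim <- simulate_instruments(sim_config(
    n_snps = 40, seed = 102,
    pleiotropy = "balanced", pleiotropy_sd = 0.05
  ))
  est <- mr_raps(sim$instruments, overdispersion = TRUE)
  expect_gt(attr(est, "raps")$tau2, 0)
  clean <- simulate_instruments(sim_config(n_snps = 40, seed = 103))
  est2 <- mr_raps(clean$instruments, overdispersion = TRUE)
  expect_gte(attr(est2, "raps")$tau2, 0)
})

test_that("GRS reduces to the single-variant case and validates inputs", {
  est <- grs_summary(1, 0.3, 0.1)
  expect_equal(est$beta, 0.3)
  expect_equal(est$se, 0.1)
  expect_error(grs_summary(numeric(0), numeric(0), numeric(0)),
    class = "bimr_error_config"
  )
  expect_error(grs_summary(1, 0.3, 0), class = "bimr_error_invalid_se")
  expect_error(grs_summary(0, 0.3, 0.1), class = "bimr_error_degenerate_weights")
})

test_that("GRS with exposure weights equals fixed-effect IVW identically", {
  set.seed(41)
  for (i in 1:25) {
    inst <- random_instruments(sample(3:40, 1))
    grs <- grs_summary(inst$gamma, inst$Gamma, inst$se_Gamma)
    ivw <- mr_ivw(inst, model = "fixed")
    expect_equal(grs$beta, ivw$beta, tolerance = 1e-12)
    expect_equal(grs$se, ivw$se, tolerance = 1e-12)
  }
})

test_that("all estimators are equivariant to rescaling the outcome", {
  set.seed(42)
  inst <- random_instruments(15)
  scaled <- inst
  c0 <- 3.7
  scaled$Gamma <- inst$Gamma * c0
  scaled$se_Gamma <- inst$se_Gamma * c0
  pairs <- list(
    list(mr_ivw(inst, model = "fixed"), mr_ivw(scaled, model = "fixed")),
    list(mr_ivw(inst, model = "random"), mr_ivw(scaled, model = "random")),
    list(
      mr_median(inst, weighted = TRUE, n_boot = 200, seed = 7),
      mr_median(scaled, weighted = TRUE, n_boot = 200, seed = 7)
    ),
    list(
      mr_median(inst, weighted = FALSE, n_boot = 200, seed = 7),
      mr_median(scaled, weighted = FALSE, n_boot = 200, seed = 7)
    ),
    list(mr_raps(inst), mr_raps(scaled)),
    list(mr_grs(inst), mr_grs(scaled))
  )
  for (p in pairs) {
    expect_equal(p[[2]]$beta, c0 * p[[1]]$beta, tolerance = 1e-6)
    expect_equal(p[[2]]$se, c0 * p[[1]]$se, tolerance = 1e-6)
  }
  egger1 <- mr_egger(inst)
  egger2 <- mr_egger(scaled)
  expect_equal(egger2$beta, c0 * egger1$beta, tolerance = 1e-10)
})

test_that("estimate rows are internally consistent", {
  set.seed(43)
  inst <- random_instruments(10)
  est <- mr_all(inst, methods = c("ivw", "egger", "grs"), seed = 1)
  expect_true(all(est$ci_low <= est$beta & est$beta <= est$ci_high))
  expect_true(all(est$pvalue > 0 & est$pvalue <= 1))
  expect_equal(est$or, exp(est$beta))
  expect_equal(est$or_ci_low, exp(est$ci_low))
})
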