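# Synthetic two-trait GWAS summary statistics with known ground truth.
#
# The generator works at summary level only: true exposure effects gamma_j,
# true outcome effects Gamma_j = alpha * gamma_j + pleiotropy, and observed
# effects drawn around the truth at the reported standard errors.  One seed
# governs a fixed draw order (gamma, SEs, pleiotropy, exposure noise,
# outcome noise, outlier subset, allele frequencies), so identical configs
# reproduce byte-identical output.

#' Simulation configuration for synthetic instrument sets
#'
#' Defaults describe a strongly instrumented polygenic exposure: J = 25
#' independent instruments with effects around 0.15 (log-odds per allele,
#' spread 0.05), exposure-side standard errors of 0.005-0.01 (per-SNP F of
#' several hundred, as in large GWAS meta-analyses), outcome-side standard
#' errors of 0.01-0.02, a causal effect of 0.2 on the log-odds scale, no
#' pleiotropy and no outliers unless asked for.
#'
#' @param n_snps Number of instruments J (at least 2).
#' @param alpha_true True causal effect, log-odds per log-odds.
#' @param gamma_mean,gamma_sd Mean and spread of the true exposure effects.
#' @param se_gamma_range,se_Gamma_range Uniform ranges for the per-SNP
#'   standard errors (strictly positive).
#' @param pleiotropy Regime: `"none"`, `"balanced"` (mean-zero direct
#'   effects), `"directional"` (nonzero mean), or `"inside_violation"`
#'   (direct effects correlated with instrument strength, breaking InSIDE).
#' @param pleiotropy_sd,pleiotropy_mean Spread and offset of the per-SNP
#'   direct effects.
#' @param inside_rho Correlation between direct effects and centred
#'   exposure effects under `"inside_violation"`.
#' @param outlier_fraction Fraction of instruments receiving an additive
#'   outcome shift, in \[0, 0.5).
#' @param outlier_scale Outlier shift in multiples of the outcome SE.
#' @param maf_range Uniform range of simulated allele frequencies.
#' @param observation_noise When `FALSE` the observed effects equal the
#'   truth exactly (the noiseless limit used to check estimator algebra);
#'   reported SEs are unchanged.
#' @param seed Integer seed; `NULL` uses the session RNG stream.
#' @return A validated list of class `mr_sim_config`.
#' @export
sim_config <- function(n_snps = 25, alpha_true = 0.2,
                       gamma_mean = 0.15, gamma_sd = 0.05,
                       se_gamma_range = c(0.005, 0.01),
                       se_Gamma_range = c(0.01, 0.02),
                       pleiotropy = c("none", "balanced", "directional", "inside_violation"),
                       pleiotropy_sd = 0, pleiotropy_mean = 0,
                       inside_rho = 0.7,
                       outlier_fraction = 0, outlier_scale = 5,
                       maf_range = c(0.01, 0.5),
                       observation_noise = TRUE,
                       seed = NULL) {
  pleiotropy <- match.arg(pleiotropy)
  stopifnot(
    n_snps >= 2, is.numeric(alpha_true),
    gamma_sd > 0,
    length(se_gamma_range) == 2, all(se_gamma_range > 0),
    diff(se_gamma_range) >= 0,
    length(se_Gamma_range) == 2, all(se_Gamma_range > 0),
    diff(se_Gamma_range) >= 0,
    pleiotropy_sd >= 0,
    inside_rho >= -1, inside_rho <= 1,
    outlier_fraction >= 0, outlier_fraction < 0.5,
    outlier_scale >= 0,
    length(maf_range) == 2, all(maf_range > 0), all(maf_range < 1),
    is.logical(observation_noise)
  )
  structure(
    list(
      n_snps = as.integer(n_snps), alpha_true = alpha_true,
      gamma_mean = gamma_mean, gamma_sd = gamma_sd,
      se_gamma_range = se_gamma_range, se_Gamma_range = se_Gamma_range,
      pleiotropy = pleiotropy, pleiotropy_sd = pleiotropy_sd,
      pleiotropy_mean = pleiotropy_mean, inside_rho = inside_rho,
      outlier_fraction = outlier_fraction, outlier_scale = outlier_scale,
      maf_range = maf_range, observation_noise = observation_noise,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "mr_sim_config"
  )
}

# Core draw, assuming the RNG state is already set.
simulate_core <- function(config) {
  J <- config$n_snps
  gamma_t <- rnorm(J, config$gamma_mean, config$gamma_sd)
  se_g <- runif(J, config$se_gamma_range[1], config$se_gamma_range[2])
  se_G <- runif(J, config$se_Gamma_range[1], config$se_Gamma_range[2])
  u <- switch(config$pleiotropy,
    none = rep(0, J),
    balanced = rnorm(J, 0, config$pleiotropy_sd),
    directional = rnorm(J, config$pleiotropy_mean, config$pleiotropy_sd),
    inside_violation = {
      rho <- config$inside_rho
      rho * config$pleiotropy_sd * (gamma_t - config$gamma_mean) / config$gamma_sd +
        sqrt(1 - rho^2) * rnorm(J, 0, config$pleiotropy_sd) +
        config$pleiotropy_mean
    }
  )
  Gamma_t <- config$alpha_true * gamma_t + u
  if (config$observation_noise) {
    g_hat <- rnorm(J, gamma_t, se_g)
    G_hat <- rnorm(J, Gamma_t, se_G)
  } else {
    g_hat <- gamma_t
    G_hat <- Gamma_t
  }
  n_out <- floor(config$outlier_fraction * J)
  outlier_idx <- if (n_out > 0) sample.int(J, n_out) else integer(0)
  G_hat[outlier_idx] <- G_hat[outlier_idx] + config$outlier_scale * se_G[outlier_idx]
  eaf <- runif(J, config$maf_range[1], config$maf_range[2])
  ids <- sprintf("iv_%03d", seq_len(J))
  instruments <- tibble::tibble(
    variant_id = ids,
    gamma = g_hat, se_gamma = se_g,
    Gamma = G_hat, se_Gamma = se_G,
    eaf_exposure = eaf, eaf_outcome = eaf,
    flipped = FALSE
  )
  class(instruments) <- c("mr_instruments", class(instruments))
  truth <- list(
    alpha_true = config$alpha_true,
    gamma_true = gamma_t, Gamma_true = Gamma_t,
    pleiotropy = u,
    outlier_ids = ids[sort(outlier_idx)],
    config = config
  )
  list(instruments = instruments, truth = truth)
}

#' Simulate a harmonized instrument set with known truth
#'
#' Draws true exposure effects, standard errors, per-SNP pleiotropy for the
#' configured regime, outcome effects `alpha_true * gamma + pleiotropy`,
#' observed effects around the truth, and an optional contaminated outlier
#' subset whose observed outcome effects are shifted by
#' `outlier_scale * se_Gamma`.
#'
#' @param config A [sim_config()].
#' @return A list of class `mr_sim`: `instruments` (a harmonized instrument
#'   tibble ready for the estimators) and `truth` (true effects, pleiotropy,
#'   outlier ids and the config).
#' @examples
#' sim <- simulate_instruments(sim_config(n_snps = 30, seed = 7))
#' mr_ivw(sim$instruments)
#' @export
simulate_instruments <- function(config = sim_config()) {
  stopifnot(inherits(config, "mr_sim_config"))
  out <- with_seed_if(config$seed, simulate_core(config))
  structure(out, class = "mr_sim")
}

nonpalindromic_pairs <- matrix(
  c(
    "A", "C", "A", "G", "C", "A", "C", "T",
    "G", "A", "G", "T", "T", "C", "T", "G"
  ),
  ncol = 2, byrow = TRUE
)

# z threshold corresponding to a two-sided tail p.
z_for_p <- function(p) qnorm(p / 2, lower.tail = FALSE)

#' Simulate raw exposure/outcome summary tables with planted QC violations
#'
#' Wraps [simulate_instruments()] into full summary-statistic tables so the
#' whole pipeline — read, select, harmonize, estimate — runs end to end on
#' known truth.  Beyond the clean instruments the tables can plant, in known
#' numbers: sub-threshold decoy SNPs, palindromic instruments, LD satellites
#' tagging each instrument (larger p, r-squared above the clumping cutoff,
#' within the window), rare variants failing the MAF filter, and instruments
#' on a confounder exclusion list.  Each planted violator fails exactly one
#' selection stage, so the expected audit is part of the returned truth.
#'
#' Observed exposure effects of planted significant SNPs are redrawn until
#' genome-wide significant (significance-truncated instrument strength —
#' the analogue of instruments being ascertained by their discovery GWAS);
#' satellite SEs are 1.25 times their index SNP's, which guarantees the
#' index has the smaller p-value.  All p-values satisfy
#' `p = 2 * pnorm(-|beta| / se)`.
#'
#' @param config A [sim_config()]; its seed governs the whole construction.
#' @param n_decoys Sub-threshold SNPs (fail the significance filter).
#' @param n_palindromic Significant A/T / C/G instruments (dropped at the
#'   palindrome stage).
#' @param n_low_maf Significant instruments with MAF 0.005 (fail the MAF
#'   filter).
#' @param n_excluded Significant instruments placed on the exclusion list.
#' @param satellites_per_instrument LD satellites planted around each clean
#'   instrument (removed by clumping).
#' @param satellite_r2 Pairwise r-squared between block members.
#' @param satellite_window_kb Maximum satellite distance from its index.
#' @param sig_threshold Significance level the planted instruments are
#'   guaranteed to reach.
#' @param n_sample Sample-size column value written to both tables.
#' @return A list of class `mr_sim_tables`: `exposure` and `outcome`
#'   variant-association tibbles, `ld` (an [ld_matrix()] over the linked
#'   SNPs), `exclusion_list`, and `truth` — including `instrument_ids` (the
#'   clean set a correct selection recovers) and `expected_audit`.
#' @export
simulate_raw_tables <- function(config = sim_config(),
                                n_decoys = 20, n_palindromic = 0,
                                n_low_maf = 0, n_excluded = 0,
                                satellites_per_instrument = 0,
                                satellite_r2 = 0.95,
                                satellite_window_kb = 100,
                                sig_threshold = 5e-8,
                                n_sample = 50000) {
  stopifnot(inherits(config, "mr_sim_config"))
  with_seed_if(config$seed, {
    core <- simulate_core(config)
    inst <- core$instruments
    J <- nrow(inst)
    z_min <- z_for_p(sig_threshold)

    # Planted instruments must reach genome-wide significance — the
    # analogue of instruments being ascertained by their discovery GWAS.
    # The observed effect is drawn from Normal(gamma_true, se) conditioned
    # on |z| exceeding the threshold (exact two-tailed truncated sampling);
    # satellites use se * 1.25, so their z must clear the threshold too.
    guard <- if (satellites_per_instrument > 0) 1.25 else 1
    ensure_significant <- function(g_hat, gamma_t, se) {
      for (i in seq_along(g_hat)) {
        lo <- z_min * se[i] * guard
        if (abs(g_hat[i]) > lo) next
        p_neg <- pnorm(-lo, gamma_t[i], se[i])
        p_pos <- pnorm(lo, gamma_t[i], se[i], lower.tail = FALSE)
        tot <- p_neg + p_pos
        if (tot < 1e-300) {
          g_hat[i] <- sign(gamma_t[i] + .Machine$double.eps) * lo * 1.001
          next
        }
        u <- runif(1) * tot
        g_hat[i] <- if (u <= p_neg) {
          qnorm(max(u, 1e-320), gamma_t[i], se[i])
        } else {
          qnorm(max(tot - u, 1e-320), gamma_t[i], se[i], lower.tail = FALSE)
        }
      }
      g_hat
    }
    inst$gamma <- ensure_significant(
      inst$gamma,
      core$truth$gamma_true, inst$se_gamma
    )

    # Extra significant instruments that fail exactly one later QC stage.
    extra_instrument <- function(id, eaf, palindromic = FALSE) {
      gamma_t <- rnorm(1, config$gamma_mean, config$gamma_sd)
      se_g <- runif(1, config$se_gamma_range[1], config$se_gamma_range[2])
      se_G <- runif(1, config$se_Gamma_range[1], config$se_Gamma_range[2])
      g_hat <- ensure_significant(rnorm(1, gamma_t, se_g), gamma_t, se_g)
      G_hat <- rnorm(1, config$alpha_true * gamma_t, se_G)
      alleles <- if (palindromic) {
        unlist(sample(list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C")), 1))
      } else {
        nonpalindromic_pairs[sample.int(8, 1), ]
      }
      tibble::tibble(
        variant_id = id, gamma = g_hat, se_gamma = se_g,
        Gamma = G_hat, se_Gamma = se_G, eaf = eaf,
        effect_allele = alleles[1], other_allele = alleles[2]
      )
    }

    draw_eaf <- function(n) runif(n, config$maf_range[1], config$maf_range[2])
    pal <- purrr::map_dfr(seq_len(n_palindromic), function(i) {
      extra_instrument(sprintf("pal_%02d", i), draw_eaf(1), palindromic = TRUE)
    })
    lowmaf <- purrr::map_dfr(seq_len(n_low_maf), function(i) {
      extra_instrument(sprintf("lowmaf_%02d", i), 0.005)
    })
    excl <- purrr::map_dfr(seq_len(n_excluded), function(i) {
      extra_instrument(sprintf("excl_%02d", i), draw_eaf(1))
    })

    # Clean instruments get nonpalindromic alleles.
    core_alleles <- nonpalindromic_pairs[sample.int(8, J, replace = TRUE), , drop = FALSE]
    core_tab <- tibble::tibble(
      variant_id = inst$variant_id,
      gamma = inst$gamma, se_gamma = inst$se_gamma,
      Gamma = inst$Gamma, se_Gamma = inst$se_Gamma,
      eaf = inst$eaf_exposure,
      effect_allele = core_alleles[, 1], other_allele = core_alleles[, 2]
    )

    # Satellites: same observed exposure effect as their index, se * 1.25
    # (strictly larger p), within the clumping window, r2 = satellite_r2.
    sats <- purrr::map_dfr(seq_len(J), function(i) {
      if (satellites_per_instrument == 0) {
        return(NULL)
      }
      purrr::map_dfr(seq_len(satellites_per_instrument), function(k) {
        se_g <- core_tab$se_gamma[i] * 1.25
        se_G <- runif(1, config$se_Gamma_range[1], config$se_Gamma_range[2])
        tibble::tibble(
          variant_id = sprintf("%s_sat%d", core_tab$variant_id[i], k),
          gamma = core_tab$gamma[i], se_gamma = se_g,
          Gamma = rnorm(1, config$alpha_true * core$truth$gamma_true[i], se_G),
          se_Gamma = se_G, eaf = draw_eaf(1),
          effect_allele = nonpalindromic_pairs[sample.int(8, 1), 1],
          other_allele = nonpalindromic_pairs[sample.int(8, 1), 2]
        )
      })
    })
    if (nrow(sats) > 0) {
      fix <- sats$effect_allele == sats$other_allele |
        is_palindromic(sats$effect_allele, sats$other_allele)
      sats$other_allele[fix] <- ifelse(sats$effect_allele[fix] %in% c("A", "T"), "C", "A")
    }

    decoys <- if (n_decoys > 0) {
      se_g <- runif(n_decoys, config$se_gamma_range[1], config$se_gamma_range[2])
      z <- runif(n_decoys, 0, 4.5) * sample(c(-1, 1), n_decoys, replace = TRUE)
      al <- nonpalindromic_pairs[sample.int(8, n_decoys, replace = TRUE), , drop = FALSE]
      tibble::tibble(
        variant_id = sprintf("decoy_%02d", seq_len(n_decoys)),
        gamma = z * se_g, se_gamma = se_g,
        Gamma = rnorm(n_decoys, 0, 0.02), se_Gamma = rep(0.02, n_decoys),
        eaf = draw_eaf(n_decoys),
        effect_allele = al[, 1], other_allele = al[, 2]
      )
    } else {
      NULL
    }

    blocks <- dplyr::bind_rows(core_tab, pal, lowmaf, excl, decoys)
    # One genomic block per non-satellite SNP: chromosomes cycle 1..22,
    # blocks on the same chromosome 5 Mb apart (outside any 500 kb window).
    b <- seq_len(nrow(blocks))
    blocks$chromosome <- as.character(((b - 1) %% 22) + 1)
    blocks$position <- as.integer(1e6 + ((b - 1) %/% 22) * 5e6)
    if (nrow(sats) > 0) {
      idx <- match(sub("_sat\\d+$", "", sats$variant_id), blocks$variant_id)
      k <- as.integer(sub("^.*_sat", "", sats$variant_id))
      sats$chromosome <- blocks$chromosome[idx]
      sats$position <- as.integer(
        blocks$position[idx] + k * min(satellite_window_kb * 1000 / (satellites_per_instrument + 1), 2e4)
      )
    }
    all_snps <- dplyr::bind_rows(blocks, sats)

    p_from <- function(beta, se) pmax(2 * pnorm(-abs(beta) / se), 1e-300)
    exposure <- tibble::tibble(
      variant_id = all_snps$variant_id,
      chromosome = all_snps$chromosome,
      position = all_snps$position,
      effect_allele = all_snps$effect_allele,
      other_allele = all_snps$other_allele,
      eaf = all_snps$eaf,
      beta = all_snps$gamma,
      se = all_snps$se_gamma,
      pvalue = p_from(all_snps$gamma, all_snps$se_gamma),
      n = n_sample
    )
    outcome <- exposure
    outcome$beta <- all_snps$Gamma
    outcome$se <- all_snps$se_Gamma
    outcome$pvalue <- p_from(all_snps$Gamma, all_snps$se_Gamma)

    # LD: block-diagonal, satellites linked to their index and each other.
    sat_ids <- if ("variant_id" %in% names(sats)) sats$variant_id else character()
    linked_ids <- c(core_tab$variant_id, sat_ids)
    m <- matrix(0, length(linked_ids), length(linked_ids),
      dimnames = list(linked_ids, linked_ids)
    )
    if (nrow(sats) > 0) {
      for (i in seq_len(J)) {
        members <- c(
          core_tab$variant_id[i],
          sats$variant_id[startsWith(sats$variant_id, paste0(core_tab$variant_id[i], "_sat"))]
        )
        jj <- match(members, linked_ids)
        m[jj, jj] <- satellite_r2
      }
    }
    diag(m) <- 1
    ld <- ld_matrix(linked_ids, m)

    truth <- core$truth
    truth$instrument_ids <- core_tab$variant_id
    ids_of <- function(df) {
      if ("variant_id" %in% names(df)) df[["variant_id"]] else character()
    }
    truth$palindromic_ids <- ids_of(pal)
    truth$low_maf_ids <- ids_of(lowmaf)
    truth$excluded_ids <- ids_of(excl)
    truth$satellite_ids <- ids_of(sats)
    truth$decoy_ids <- if (is.null(decoys)) character() else decoys$variant_id
    n_total <- nrow(all_snps)
    kept <- c(
      n_total,
      n_total - n_decoys,
      n_total - n_decoys - n_palindromic,
      J + n_low_maf + n_excluded,
      J + n_excluded,
      J
    )
    truth$expected_audit <- tibble::tibble(
      stage = c("input", "significance", "nonpalindromic", "ld_clump", "maf", "exclusions"),
      kept = as.integer(kept),
      dropped = as.integer(c(0, -diff(kept)))
    )

    structure(
      list(
        exposure = exposure, outcome = outcome, ld = ld,
        exclusion_list = truth$excluded_ids, truth = truth
      ),
      class = "mr_sim_tables"
    )
  })
}

#' Write simulated summary tables to disk
#'
#' Emits the exposure and outcome tables in the TSV dialect
#' [read_summary_table()] reads, the LD matrix in long format, the exclusion
#' list, and the truth record as JSON.
#'
#' @param sim An `mr_sim_tables` object from [simulate_raw_tables()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_sim_tables <- function(sim, dir) {
  stopifnot(inherits(sim, "mr_sim_tables"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    exposure = file.path(dir, "exposure.tsv"),
    outcome = file.path(dir, "outcome.tsv"),
    ld = file.path(dir, "ld.tsv"),
    exclusions = file.path(dir, "exclusions.txt"),
    truth = file.path(dir, "truth.json")
  )
  as_canonical <- function(tab) {
    stats::setNames(
      tab[c(
        "variant_id", "chromosome", "position", "effect_allele",
        "other_allele", "eaf", "beta", "se", "pvalue", "n"
      )],
      c("SNP", "CHR", "BP", "EA", "NEA", "EAF", "BETA", "SE", "P", "N")
    )
  }
  readr::write_tsv(as_canonical(sim$exposure), paths["exposure"])
  readr::write_tsv(as_canonical(sim$outcome), paths["outcome"])
  ld_long <- which(upper.tri(sim$ld$r2) & sim$ld$r2 > 0, arr.ind = TRUE)
  readr::write_tsv(
    tibble::tibble(
      id1 = sim$ld$variant_ids[ld_long[, 1]],
      id2 = sim$ld$variant_ids[ld_long[, 2]],
      r2 = sim$ld$r2[ld_long]
    ),
    paths["ld"]
  )
  writeLines(sim$exclusion_list, paths["exclusions"])
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
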