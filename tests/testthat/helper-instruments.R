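# Shared fixtures built in code: random instrument sets and tiny summary
# tables written to tempfiles.

# Random harmonized instrument tibble drawn from the session RNG (callers
# seed via set.seed / withr::local_seed).
random_instruments <- function(J = 10, alpha = 0.2) {
  gamma <- rnorm(J, 0.15, 0.05)
  gamma[gamma == 0] <- 0.01
  se_gamma <- runif(J, 0.005, 0.02)
  se_Gamma <- runif(J, 0.01, 0.05)
  tibble::tibble(
    variant_id = sprintf("rs%04d", seq_len(J)),
    gamma = gamma,
    se_gamma = se_gamma,
    Gamma = alpha * gamma + rnorm(J, 0, se_Gamma),
    se_Gamma = se_Gamma
  )
}

# Instrument set with exact, noise-free proportionality Gamma = alpha*gamma.
exact_instruments <- function(J = 5, alpha = 0.5, intercept = 0) {
  gamma <- seq(0.05, 0.3, length.out = J)
  tibble::tibble(
    variant_id = sprintf("rs%03d", seq_len(J)),
    gamma = gamma,
    se_gamma = rep(0.01, J),
    Gamma = intercept + alpha * gamma,
    se_Gamma = seq(0.01, 0.03, length.out = J)
  )
}

write_assoc_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  canonical <- c(
    variant_id = "SNP", chromosome = "CHR", position = "BP",
    effect_allele = "EA", other_allele = "NEA", eaf = "EAF",
    beta = "BETA", se = "SE", pvalue = "P", n = "N"
  )
  names(df) <- ifelse(names(df) %in% names(canonical),
    canonical[names(df)], names(df)
  )
  readr::write_tsv(df, path)
  path
}

# A small well-formed association table.
demo_assoc <- function(n = 5) {
  tibble::tibble(
    variant_id = sprintf("rs%d", seq_len(n)),
    chromosome = as.character(rep_len(1:3, n)),
    position = seq_len(n) * 100000L,
    effect_allele = rep_len(c("A", "C", "G", "T", "A"), n),
    other_allele = rep_len(c("G", "T", "A", "C", "C"), n),
    eaf = seq(0.1, 0.5, length.out = n),
    beta = seq(0.05, 0.25, length.out = n),
    se = rep(0.01, n),
    pvalue = rep(1e-10, n),
    n = rep(10000L, n)
  )
}
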