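# Instrument selection: the five screening stages and their audit.

test_that("significance filter matches a linear-scan oracle", {
  set.seed(11)
  df <- demo_assoc(100)
  df$variant_id <- sprintf("rs%d", 1:100)
  df$pvalue <- runif(100)
  kept <- filter_significance(df, 0.3)
  oracle <- df[sapply(df$pvalue, function(p) p < 0.3), ]
  expect_equal(kept, oracle)
  expect_equal(nrow(filter_significance(df, 1 - 1e-12)), sum(df$pvalue < 1 - 1e-12))
})

test_that("MAF filter is symmetric in eaf and drops missing frequencies", {
  df <- demo_assoc(4)
  df$eaf <- c(0.995, 0.5, NA, 0.009)
  kept <- filter_maf(df, 0.01)
  expect_equal(kept$variant_id, "rs2") # 0.995 -> MAF 0.005; NA conservative
  set.seed(12)
  df2 <- demo_assoc(50)
  df2$variant_id <- sprintf("rs%d", 1:50)
  df2$eaf <- runif(50)
  oracle <- df2[!is.na(df2$eaf) & pmin(df2$eaf, 1 - df2$eaf) > 0.05, ]
  expect_equal(filter_maf(df2, 0.05), oracle)
})

test_that("greedy clumping keeps the lowest-p index within linked windows", {
  df <- demo_assoc(2)
  df$chromosome <- c("1", "1")
  df$position <- c(100000L, 110000L)
  df$pvalue <- c(1e-10, 1e-9)
  ld <- ld_matrix(df$variant_id, matrix(c(1, 0.9, 0.9, 1), 2))
  out <- ld_clump(df, ld, clump_r2 = 0.01, clump_window_kb = 500)
  expect_equal(out$variant_id, "rs1")

  # same r2 but 600 kb apart: both survive a 500 kb window
  df$position <- c(100000L, 700000L)
  out2 <- ld_clump(df, ld, clump_r2 = 0.01, clump_window_kb = 500)
  expect_equal(nrow(out2), 2)
})

test_that("clumping equals an explicit-loop greedy oracle on random blocks", {
  greedy_oracle <- function(df, r2mat, r2_thresh, window_bp) {
    remaining <- df
    kept <- character()
    while (nrow(remaining) > 0) {
      o <- order(remaining$pvalue, remaining$position, remaining$variant_id)
      idx <- remaining$variant_id[o[1]]
      kept <- c(kept, idx)
      irow <- remaining[remaining$variant_id == idx, ]
      linked <- vapply(seq_len(nrow(remaining)), function(k) {
        row <- remaining[k, ]
        if (row$variant_id == idx) {
          return(TRUE)
        }
        same <- row$chromosome == irow$chromosome &&
          abs(row$position - irow$position) <= window_bp
        same && r2mat[idx, row$variant_id] >= r2_thresh
      }, logical(1))
      remaining <- remaining[!linked, ]
    }
    sort(kept)
  }
  for (seed in 1:5) {
    set.seed(seed)
    n <- 20
    df <- demo_assoc(n)
    df$variant_id <- sprintf("rs%02d", 1:n)
    df$chromosome <- "1"
    df$position <- sort(sample.int(2e6, n))
    df$pvalue <- runif(n, 1e-12, 1e-6)
    # random block LD
    m <- diag(n)
    block <- sample(1:4, n, replace = TRUE)
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (block[i] == block[j]) m[i, j] <- m[j, i] <- runif(1, 0.5, 1)
      }
    }
    dimnames(m) <- list(df$variant_id, df$variant_id)
    ld <- ld_matrix(df$variant_id, m)
    got <- ld_clump(df, ld, clump_r2 = 0.6, clump_window_kb = 500)
    expect_equal(sort(got$variant_id), greedy_oracle(df, m, 0.6, 5e5))
    # retained set is pairwise independent
    for (i in seq_len(nrow(got))) {
      for (j in seq_len(nrow(got))) {
        if (i >= j) next
        within <- got$chromosome[i] == got$chromosome[j] &&
          abs(got$position[i] - got$position[j]) <= 5e5
        expect_false(within && m[got$variant_id[i], got$variant_id[j]] >= 0.6)
      }
    }
  }
})

test_that("clumping without an LD matrix treats all pairs as unlinked", {
  df <- demo_assoc(3)
  df$chromosome <- "1"
  df$position <- c(1e5L, 2e5L, 3e5L)
  expect_warning(out <- ld_clump(df, NULL), "unlinked")
  expect_equal(nrow(out), 3)
})

test_that("clumping requires positions and breaks p ties deterministically", {
  df <- demo_assoc(2)
  df$position <- c(NA_integer_, 2L)
  expect_error(ld_clump(df, NULL), class = "bimr_error_missing_position")

  df2 <- demo_assoc(2)
  df2$chromosome <- c("1", "1")
  df2$position <- c(200000L, 100000L)
  df2$pvalue <- c(1e-10, 1e-10)
  ld <- ld_matrix(df2$variant_id, matrix(c(1, 0.9, 0.9, 1), 2))
  out <- suppressWarnings(ld_clump(df2, ld))
  expect_equal(out$variant_id, "rs2") # tie -> smaller position wins
})

test_that("exclusion lists are removed as an exact set difference", {
  expect_equal(apply_exclusions(demo_assoc(3), character()), demo_assoc(3), ignore_attr = TRUE)
  df <- demo_assoc(3)
  out <- apply_exclusions(df, c("rs2", "rs_absent"))
  expect_equal(out$variant_id, c("rs1", "rs3"))
  expect_equal(attr(out, "removed"), "rs2")

  set.seed(13)
  ids <- sprintf("rs%03d", sample.int(999, 50))
  df2 <- demo_assoc(50)
  df2$variant_id <- ids
  excl <- sample(ids, 10)
  expect_setequal(
    apply_exclusions(df2, excl)$variant_id,
    setdiff(ids, excl)
  )
})

test_that("a confounder-associated variant on the list shrinks the set by one", {
  df <- demo_assoc(5)
  df$variant_id[3] <- "rs3999544" # smoking-associated
  out <- apply_exclusions(df, c("rs3999544"))
  expect_equal(nrow(out), nrow(df) - 1)
})

test_that("exclusion files support comments and blank lines", {
  path <- tempfile()
  writeLines(c("# smoking", "rs3999544", "", "rs55781567 # also smoking"), path)
  expect_equal(read_exclusion_list(path), c("rs3999544", "rs55781567"))
})

test_that("selection stages are contractions with a monotone audit", {
  sim <- simulate_raw_tables(sim_config(n_snps = 10, seed = 21),
    n_decoys = 8, n_palindromic = 2, n_low_maf = 1, n_excluded = 1,
    satellites_per_instrument = 1
  )
  sel <- select_instruments(
    sim$exposure,
    selection_config(exclusion_list = sim$exclusion_list),
    ld = sim$ld
  )
  audit <- selection_audit(sel)
  expect_true(all(diff(audit$kept) <= 0))
  expect_true(all(sel$variant_id %in% sim$exposure$variant_id))
  expect_equal(audit$kept[1] - audit$kept[6], sum(audit$dropped))
})

test_that("significance and MAF filters commute; clumping order is honoured", {
  set.seed(14)
  df <- demo_assoc(40)
  df$variant_id <- sprintf("rs%02d", 1:40)
  df$pvalue <- 10^runif(40, -12, -4)
  df$eaf <- runif(40, 0.001, 0.999)
  a <- filter_maf(filter_significance(df, 5e-8), 0.01)
  b <- filter_significance(filter_maf(df, 0.01), 5e-8)
  expect_equal(a, b)
})

test_that("an all-passing table returns unchanged with a constant audit", {
  df <- demo_assoc(5)
  df$effect_allele <- rep("A", 5)
  df$other_allele <- rep("G", 5)
  sel <- suppressWarnings(select_instruments(df, selection_config()))
  expect_equal(nrow(sel), 5)
  expect_equal(unique(selection_audit(sel)$kept), 5L)
})

test_that("selection config validates and round-trips through JSON", {
  expect_error(selection_config(p_threshold = 0))
  expect_error(selection_config(maf_min = 0.5))
  cfg <- selection_config(exclusion_list = c("rs1", "rs2"))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::fromJSON(path)
  cfg2 <- do.call(selection_config, back)
  expect_equal(cfg2$p_threshold, 5e-8)
  expect_equal(cfg2$clump_r2, 0.01)
  expect_equal(cfg2$clump_window_kb, 500)
  expect_equal(cfg2$maf_min, 0.01)
  expect_equal(cfg2, cfg, tolerance = 1e-12)
})

test_that("LD matrices read from square and long formats agree", {
  ids <- c("rs1", "rs2", "rs3")
  m <- matrix(c(1, 0.5, 0, 0.5, 1, 0.2, 0, 0.2, 1), 3, dimnames = list(ids, ids))
  square <- tempfile(fileext = ".tsv")
  readr::write_tsv(
    tibble::as_tibble(cbind(data.frame(id = ids), as.data.frame(m))),
    square
  )
  long <- tempfile(fileext = ".tsv")
  readr::write_tsv(
    tibble::tibble(
      id1 = c("rs1", "rs2"), id2 = c("rs2", "rs3"), r2 = c(0.5, 0.2)
    ),
    long
  )
  a <- read_ld_matrix(square)
  b <- read_ld_matrix(long)
  expect_equal(a$r2[a$variant_ids, a$variant_ids], b$r2[a$variant_ids, a$variant_ids])
  expect_error(ld_matrix(ids, matrix(c(1, 0.5, 0, 0, 1, 0, 0, 0.3, 1), 3)),
    class = "bimr_error_ld"
  )
})
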