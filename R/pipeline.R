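# Orchestration: one exposure->outcome analysis, and the bidirectional
# matrix over a plan of trait pairs, with a report bundle per pair.

default_methods <- c(
  "ivw", "median_simple", "median_weighted", "egger", "presso", "raps", "grs"
)

#' Run one exposure-to-outcome MR analysis
#'
#' Selects instruments on the exposure table, looks them up in the outcome
#' table (variants absent from it are dropped and logged; no proxy search),
#' harmonizes alleles, then runs the requested estimators and the full
#' diagnostic panel.  The auto-model IVW row is labelled the primary
#' analysis and the genetic risk score the secondary validation.  Pairs
#' retaining fewer than three instruments are not analysed; an explicit
#' under-instrumented record is returned instead.
#'
#' @param exposure,outcome Variant-association tables (tibbles from
#'   [read_summary_table()] / [simulate_raw_tables()]), or paths to files
#'   readable by [read_summary_table()].
#' @param selection A [selection_config()] applied to the exposure table.
#' @param ld Optional [ld_matrix()] for clumping.
#' @param methods Estimators to run; see [mr_all()].
#' @param n_sim,n_boot Replicates for MR-PRESSO and the median bootstrap.
#' @param seed Base integer seed for the stochastic methods.
#' @param exposure_label,outcome_label Labels used in reports.
#' @param output_dir When given, the report bundle is written there:
#'   `estimates.tsv`, `per_snp.tsv`, `diagnostics.tsv`,
#'   `leave_one_out.tsv`, `audit.json` and `run.log`.
#' @return An object of class `mr_pair`: a list with `status`
#'   (`"ok"` or `"under_instrumented"`), `estimates`, `instruments`,
#'   `diagnostics`, `audit`, `harmonization`, `seeds` and the labels.
#' @export
run_pair <- function(exposure, outcome, selection = selection_config(),
                     ld = NULL, methods = default_methods,
                     n_sim = 1000, n_boot = 1000, seed = 1,
                     exposure_label = "exposure", outcome_label = "outcome",
                     output_dir = NULL) {
  if (is.character(exposure)) exposure <- read_summary_table(exposure, trait_label = exposure_label)
  if (is.character(outcome)) outcome <- read_summary_table(outcome, trait_label = outcome_label)

  selected <- select_instruments(exposure, selection, ld)
  audit <- selection_audit(selected)
  harm <- harmonize(selected, outcome)
  harm_report <- load_report(harm)

  res <- list(
    exposure_label = exposure_label,
    outcome_label = outcome_label,
    selection = selection,
    seeds = list(base = seed),
    audit = audit,
    harmonization = harm_report,
    harmonization_drops = harmonization_drops(harm),
    instruments = harm
  )
  if (nrow(harm) < 3) {
    res$status <- "under_instrumented"
    res$n_instruments <- nrow(harm)
    res$estimates <- NULL
    res$diagnostics <- NULL
    class(res) <- "mr_pair"
    if (!is.null(output_dir)) write_pair_bundle(res, output_dir)
    return(res)
  }

  estimates <- mr_all(harm,
    methods = methods, n_sim = n_sim,
    n_boot = n_boot, seed = seed
  )
  estimates$role <- dplyr::case_when(
    startsWith(estimates$method, "ivw") ~ "primary",
    estimates$method == "grs" ~ "secondary validation",
    TRUE ~ "sensitivity"
  )
  diagnostics <- mr_diagnostics(harm)

  res$status <- "ok"
  res$n_instruments <- nrow(harm)
  res$estimates <- estimates
  res$presso <- attr(estimates, "presso")
  res$diagnostics <- diagnostics
  class(res) <- "mr_pair"
  if (!is.null(output_dir)) write_pair_bundle(res, output_dir)
  res
}

per_snp_table <- function(pair) {
  inst <- pair$instruments
  r <- wald_ratios(inst)
  f <- f_statistics(inst)
  out <- dplyr::left_join(
    dplyr::left_join(tibble::as_tibble(inst), r, by = "variant_id"),
    f,
    by = "variant_id"
  )
  if (!is.null(pair$presso)) {
    out <- dplyr::left_join(
      out,
      stats::setNames(
        pair$presso$outliers,
        c("variant_id", "presso_rss", "presso_p", "presso_outlier")
      ),
      by = "variant_id"
    )
  }
  out
}

# Report bundle for one pair.  Log lines are timestamp-free so identical
# runs produce byte-identical bundles.
write_pair_bundle <- function(pair, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- pair$selection
  audit_json <- list(
    exposure = pair$exposure_label,
    outcome = pair$outcome_label,
    status = pair$status,
    n_instruments = pair$n_instruments,
    selection = unclass(cfg),
    seeds = pair$seeds,
    stages = pair$audit,
    harmonization = pair$harmonization
  )
  jsonlite::write_json(audit_json, file.path(dir, "audit.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  log_lines <- c(
    sprintf("pair: %s -> %s", pair$exposure_label, pair$outcome_label),
    sprintf("status: %s", pair$status),
    sprintf("n_instruments: %d", pair$n_instruments),
    sprintf(
      "selection: p_threshold=%g clump_r2=%g clump_window_kb=%g maf_min=%g n_excluded=%d",
      cfg$p_threshold, cfg$clump_r2, cfg$clump_window_kb, cfg$maf_min,
      length(cfg$exclusion_list)
    ),
    sprintf("seed: %s", pair$seeds$base),
    sprintf(
      "stage %s: kept=%d dropped=%d",
      pair$audit$stage, pair$audit$kept, pair$audit$dropped
    )
  )
  writeLines(log_lines, file.path(dir, "run.log"))
  if (pair$status != "ok") {
    return(invisible(dir))
  }
  readr::write_tsv(
    tibble::as_tibble(pair$estimates),
    file.path(dir, "estimates.tsv")
  )
  readr::write_tsv(per_snp_table(pair), file.path(dir, "per_snp.tsv"))
  readr::write_tsv(
    pair$diagnostics$summary,
    file.path(dir, "diagnostics.tsv")
  )
  readr::write_tsv(
    pair$diagnostics$leave_one_out,
    file.path(dir, "leave_one_out.tsv")
  )
  invisible(dir)
}

#' Build a bidirectional analysis plan
#'
#' @param pairs A list of pairs; each pair is a list with
#'   `exposure_label`, `exposure_path`, `outcome_label`, `outcome_path` and
#'   optionally `ld_path` and `exclusion_path` per direction
#'   (`exclusion_path` applies to the forward direction,
#'   `reverse_exclusion_path` to the reverse).
#' @param selection A [selection_config()] shared by all pairs.
#' @param methods Estimators to run.
#' @param n_sim,n_boot,seed Stochastic-method settings.
#' @return A list of class `mr_plan`.
#' @export
analysis_plan <- function(pairs, selection = selection_config(),
                          methods = default_methods,
                          n_sim = 1000, n_boot = 1000, seed = 1) {
  labels <- unlist(lapply(pairs, function(p) {
    stopifnot(
      !is.null(p$exposure_label), !is.null(p$exposure_path),
      !is.null(p$outcome_label), !is.null(p$outcome_path)
    )
    paste(p$exposure_label, p$outcome_label, sep = "->")
  }))
  if (anyDuplicated(labels) > 0) {
    abort("Plan pairs must have unique label combinations.",
      class = "bimr_error_config"
    )
  }
  structure(
    list(
      pairs = pairs, selection = unclass(selection), methods = methods,
      n_sim = n_sim, n_boot = n_boot, seed = seed
    ),
    class = "mr_plan"
  )
}

#' Read / write an analysis plan as JSON
#'
#' @param path JSON file path.
#' @return `read_plan()` returns an `mr_plan`; `write_plan()` returns the
#'   path invisibly.
#' @export
read_plan <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  sel_args <- lapply(raw$selection, function(x) if (is.list(x)) unlist(x) else x)
  sel_args$exclusion_list <- as.character(sel_args$exclusion_list %||% character())
  analysis_plan(
    pairs = raw$pairs,
    selection = do.call(selection_config, sel_args),
    methods = unlist(raw$methods),
    n_sim = raw$n_sim %||% 1000,
    n_boot = raw$n_boot %||% 1000,
    seed = raw$seed %||% 1
  )
}

#' @rdname read_plan
#' @param plan An `mr_plan`.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "mr_plan"))
  jsonlite::write_json(unclass(plan), path,
    auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  invisible(path)
}

#' Run the full bidirectional analysis matrix
#'
#' Executes [run_pair()] for every planned pair in both directions.  Each
#' direction is an independent selection run: the forward analysis clumps
#' the exposure table, the reverse analysis clumps the outcome table.  A
#' top-level summary holds one row per direction and method, copied (never
#' recomputed) from the pair reports.
#'
#' @param plan An [analysis_plan()] or path to a plan JSON.
#' @param output_dir Optional directory; each direction writes its bundle
#'   under `<exposure>_to_<outcome>/` plus a top-level `summary.tsv`.
#' @return An object of class `mr_bidirectional`: list with `runs` (named
#'   list of `mr_pair` objects), `summary` tibble, and `any_failed`.
#' @export
run_bidirectional <- function(plan, output_dir = NULL) {
  if (is.character(plan)) plan <- read_plan(plan)
  stopifnot(inherits(plan, "mr_plan"))
  selection_base <- do.call(selection_config, plan$selection[names(plan$selection) != "exclusion_list"])

  runs <- list()
  for (p in plan$pairs) {
    directions <- list(
      forward = list(
        exp_label = p$exposure_label, exp_path = p$exposure_path,
        out_label = p$outcome_label, out_path = p$outcome_path,
        ld = p$ld_path, excl = p$exclusion_path
      ),
      reverse = list(
        exp_label = p$outcome_label, exp_path = p$outcome_path,
        out_label = p$exposure_label, out_path = p$exposure_path,
        ld = p$reverse_ld_path, excl = p$reverse_exclusion_path
      )
    )
    for (d in directions) {
      sel <- selection_base
      sel$exclusion_list <- c(
        plan$selection$exclusion_list %||% character(),
        if (!is.null(d$excl)) read_exclusion_list(d$excl) else character()
      )
      ld <- if (!is.null(d$ld)) read_ld_matrix(d$ld) else NULL
      tag <- paste0(d$exp_label, "_to_", d$out_label)
      dir <- if (is.null(output_dir)) NULL else file.path(output_dir, tag)
      runs[[tag]] <- run_pair(
        exposure = d$exp_path, outcome = d$out_path,
        selection = sel, ld = ld, methods = plan$methods,
        n_sim = plan$n_sim, n_boot = plan$n_boot, seed = plan$seed,
        exposure_label = d$exp_label, outcome_label = d$out_label,
        output_dir = dir
      )
    }
  }

  summary <- purrr::map_dfr(runs, function(r) {
    if (r$status != "ok") {
      return(tibble::tibble(
        exposure = r$exposure_label, outcome = r$outcome_label,
        status = r$status, method = NA_character_
      ))
    }
    dplyr::mutate(tibble::as_tibble(r$estimates),
      exposure = r$exposure_label, outcome = r$outcome_label,
      status = "ok", .before = 1
    )
  })
  any_failed <- any(vapply(runs, function(r) r$status != "ok", logical(1)))
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(summary, file.path(output_dir, "summary.tsv"))
  }
  structure(
    list(runs = runs, summary = summary, any_failed = any_failed),
    class = "mr_bidirectional"
  )
}
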