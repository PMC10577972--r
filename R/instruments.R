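# Instrument selection: significance, palindrome, LD-clump, MAF and
# confounder-exclusion filters, applied in a fixed order with a per-stage
# audit.

#' Instrument-selection configuration
#'
#' Bundles the five screening thresholds.  Defaults are the conventional
#' genome-wide settings: p < 5e-8, pairwise LD r-squared < 0.01 within a
#' +/- 500 kb window, minor allele frequency > 0.01, and a user-supplied
#' confounder exclusion list (no online lookup is performed).
#'
#' @param p_threshold Genome-wide significance cutoff (exclusive), in (0, 1).
#' @param clump_r2 LD r-squared at or above which two variants are treated as
#'   linked, in \[0, 1\].
#' @param clump_window_kb Half-width of the clumping window in kilobases;
#'   the index variant claims neighbours within +/- this distance.
#' @param maf_min Minimum minor allele frequency (exclusive), in \[0, 0.5).
#' @param exclusion_list Character vector of variant ids associated with
#'   confounders, to be removed.
#' @return A validated list of class `mr_selection_config`.
#' @examples
#' selection_config(exclusion_list = c("rs3999544", "rs55781567"))
#' @export
selection_config <- function(p_threshold = 5e-8, clump_r2 = 0.01,
                             clump_window_kb = 500, maf_min = 0.01,
                             exclusion_list = character()) {
  stopifnot(
    is.numeric(p_threshold), length(p_threshold) == 1,
    p_threshold > 0, p_threshold < 1,
    is.numeric(clump_r2), clump_r2 >= 0, clump_r2 <= 1,
    is.numeric(clump_window_kb), clump_window_kb > 0,
    is.numeric(maf_min), maf_min >= 0, maf_min < 0.5,
    is.character(exclusion_list)
  )
  structure(
    list(
      p_threshold = p_threshold, clump_r2 = clump_r2,
      clump_window_kb = clump_window_kb, maf_min = maf_min,
      exclusion_list = exclusion_list
    ),
    class = "mr_selection_config"
  )
}

#' Keep genome-wide significant associations
#'
#' @param records A variant-association tibble with a `pvalue` column.
#' @param p_threshold Exclusive p-value cutoff.
#' @return The records with `pvalue < p_threshold`, input order preserved.
#' @export
filter_significance <- function(records, p_threshold = 5e-8) {
  dplyr::filter(records, .data$pvalue < p_threshold)
}

#' Keep common variants by minor allele frequency
#'
#' MAF is `min(eaf, 1 - eaf)`.  Records without an allele frequency fail the
#' filter conservatively.
#'
#' @param records A variant-association tibble with an `eaf` column.
#' @param maf_min Exclusive MAF cutoff.
#' @return The records with `min(eaf, 1 - eaf) > maf_min`.
#' @export
filter_maf <- function(records, maf_min = 0.01) {
  dplyr::filter(
    records,
    !is.na(.data$eaf) & pmin(.data$eaf, 1 - .data$eaf) > maf_min
  )
}

#' Construct a pairwise LD matrix object
#'
#' @param variant_ids Character vector of variant ids, in matrix order.
#' @param r2 Square symmetric matrix of pairwise r-squared values in
#'   \[0, 1\]; the diagonal is forced to 1.
#' @return An object of class `mr_ld`.
#' @export
ld_matrix <- function(variant_ids, r2) {
  r2 <- as.matrix(r2)
  stopifnot(
    nrow(r2) == ncol(r2), length(variant_ids) == nrow(r2),
    all(r2 >= -1e-12), all(r2 <= 1 + 1e-12)
  )
  if (max(abs(r2 - t(r2))) > 1e-8) {
    abort("LD matrix must be symmetric.", class = "bimr_error_ld")
  }
  r2 <- (r2 + t(r2)) / 2
  diag(r2) <- 1
  dimnames(r2) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = variant_ids, r2 = r2), class = "mr_ld")
}

#' Read an LD matrix from delimited text
#'
#' Accepts either a square matrix with a header row of variant ids (an
#' optional leading id column is tolerated) or long-format triples
#' `id1, id2, r2`.  Pairs absent from the file are unlinked (r-squared 0).
#'
#' @param path Path to a tab- or comma-delimited file.
#' @return An `mr_ld` object.
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "bimr_error_io")
  }
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  raw <- readr::read_delim(path,
    delim = delim, col_types = readr::cols(), progress = FALSE
  )
  looks_long <- ncol(raw) == 3 && is.character(raw[[1]]) &&
    is.character(raw[[2]]) && is.numeric(raw[[3]])
  if (looks_long) {
    ids <- sort(unique(c(raw[[1]], raw[[2]])))
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    m[cbind(match(raw[[1]], ids), match(raw[[2]], ids))] <- raw[[3]]
    m[cbind(match(raw[[2]], ids), match(raw[[1]], ids))] <- raw[[3]]
    return(ld_matrix(ids, m))
  }
  if (is.character(raw[[1]])) {
    ids <- names(raw)[-1]
    m <- as.matrix(raw[, -1])
  } else {
    ids <- names(raw)
    m <- as.matrix(raw)
  }
  ld_matrix(ids, m)
}

# r2 between one id and a set of ids; absent pairs are unlinked.
ld_lookup <- function(ld, id, ids) {
  if (is.null(ld)) {
    return(rep(0, length(ids)))
  }
  i <- match(id, ld$variant_ids)
  j <- match(ids, ld$variant_ids)
  out <- rep(0, length(ids))
  hit <- !is.na(j)
  if (!is.na(i) && any(hit)) out[hit] <- ld$r2[i, j[hit]]
  out
}

#' Greedy LD clumping
#'
#' Repeatedly takes the unclaimed variant with the smallest p-value as the
#' index (ties broken by smaller position, then variant id), then removes
#' all unclaimed variants on the same chromosome within the window whose
#' r-squared with the index is at or above `clump_r2`.  The retained indices
#' are pairwise independent: no pair is simultaneously within the window and
#' at or above the r-squared cutoff.
#'
#' @param records Variant associations with `chromosome`, `position` and
#'   `pvalue` columns.
#' @param ld An [ld_matrix()] object, or `NULL`; pairs absent from it are
#'   treated as unlinked (a warning notes distance-only behaviour).
#' @param clump_r2,clump_window_kb See [selection_config()].
#' @return The index variants, sorted by chromosome then position.
#' @export
ld_clump <- function(records, ld = NULL, clump_r2 = 0.01,
                     clump_window_kb = 500) {
  if (nrow(records) == 0) {
    return(records)
  }
  if (anyNA(records$chromosome) || anyNA(records$position)) {
    abort("LD clumping needs chromosome and position for every record.",
      class = "bimr_error_missing_position"
    )
  }
  if (is.null(ld)) {
    warn("No LD matrix supplied: all pairs treated as unlinked (r2 = 0).")
  }
  n <- nrow(records)
  ord <- order(records$pvalue, records$position, records$variant_id)
  claimed <- rep(FALSE, n)
  keep <- rep(FALSE, n)
  window_bp <- clump_window_kb * 1000
  for (i in ord) {
    if (claimed[i]) next
    keep[i] <- TRUE
    claimed[i] <- TRUE
    near <- which(!claimed &
      records$chromosome == records$chromosome[i] &
      abs(records$position - records$position[i]) <= window_bp)
    if (length(near) > 0) {
      r2 <- ld_lookup(ld, records$variant_id[i], records$variant_id[near])
      claimed[near[r2 >= clump_r2]] <- TRUE
    }
  }
  out <- records[keep, , drop = FALSE]
  out[chromosome_order(out$chromosome, out$position), , drop = FALSE]
}

#' Remove confounder-associated variants
#'
#' @param records A variant-association tibble.
#' @param exclusion_list Character vector of variant ids to remove.
#' @return The records not on the list; removed ids in `attr(, "removed")`.
#' @export
apply_exclusions <- function(records, exclusion_list = character()) {
  removed <- intersect(records$variant_id, exclusion_list)
  out <- dplyr::filter(records, !.data$variant_id %in% exclusion_list)
  attr(out, "removed") <- removed
  out
}

#' Read a variant exclusion list
#'
#' One variant id per line; `#` starts a comment, blank lines are ignored.
#'
#' @param path Path to a plain-text file.
#' @return Character vector of variant ids.
#' @export
read_exclusion_list <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Select genetic instruments
#'
#' Applies the five-stage screen in a fixed order — genome-wide significance,
#' palindrome removal, greedy LD clumping, MAF filter, confounder-exclusion
#' list — and records the count surviving each stage in an audit table.
#'
#' @param records An exposure variant-association tibble from
#'   [read_summary_table()].
#' @param config A [selection_config()].
#' @param ld An optional [ld_matrix()] passed to [ld_clump()].
#' @return The surviving records; the audit tibble (`stage`, `kept`,
#'   `dropped`) is available via [selection_audit()].
#' @export
select_instruments <- function(records, config = selection_config(),
                               ld = NULL) {
  stopifnot(inherits(config, "mr_selection_config"))
  s1 <- filter_significance(records, config$p_threshold)
  s2 <- s1[!is_palindromic(s1$effect_allele, s1$other_allele), , drop = FALSE]
  s3 <- ld_clump(s2, ld, config$clump_r2, config$clump_window_kb)
  s4 <- filter_maf(s3, config$maf_min)
  s5 <- apply_exclusions(s4, config$exclusion_list)
  counts <- c(
    input = nrow(records), significance = nrow(s1),
    nonpalindromic = nrow(s2), ld_clump = nrow(s3),
    maf = nrow(s4), exclusions = nrow(s5)
  )
  audit <- tibble::tibble(
    stage = names(counts),
    kept = as.integer(counts),
    dropped = as.integer(c(0, -diff(counts)))
  )
  attr(s5, "audit") <- audit
  attr(s5, "selection_config") <- config
  s5
}

#' Per-stage audit of an instrument selection
#'
#' @param x Output of [select_instruments()].
#' @return A tibble with columns `stage`, `kept`, `dropped`.
#' @export
selection_audit <- function(x) {
  attr(x, "audit")
}
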