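# Reading, validating and harmonizing GWAS summary-statistic tables.

# Canonical column names of the TSV dialect; a user column map overrides any
# subset of the file-side names.
default_column_map <- c(
  variant_id = "SNP", chromosome = "CHR", position = "BP",
  effect_allele = "EA", other_allele = "NEA", eaf = "EAF",
  beta = "BETA", se = "SE", pvalue = "P", n = "N"
)

mandatory_fields <- c(
  "variant_id", "effect_allele", "other_allele", "beta", "se", "pvalue"
)

#' Read a GWAS summary-statistic table
#'
#' Reads a delimited per-variant association table (tab-separated by default;
#' comma is autodetected), validates each row, and returns a tibble of
#' variant associations.  Rows failing validation are dropped and counted per
#' reason in the attached load report; duplicated variant ids keep the record
#' with the smallest p-value.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping field names
#'   (`variant_id`, `chromosome`, `position`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`) to the column names
#'   used in the file.  Only names that differ from the canonical
#'   `SNP, CHR, BP, EA, NEA, EAF, BETA, SE, P, N` need to be given.
#' @param trait_label Optional label recorded on the returned table.
#' @param delim Field delimiter; `NULL` (default) autodetects tab vs comma.
#'
#' @return A tibble with columns `variant_id`, `chromosome`, `position`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`.
#'   The load report is available via [load_report()].
#'
#' @details Effect sizes are interpreted as log odds ratios for binary
#'   traits; conversion to odds ratios happens only when estimates are
#'   reported.  Validation requires distinct A/C/G/T alleles, `se > 0`,
#'   `pvalue` in (0, 1], and `eaf` in \[0, 1\] when present.
#'
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "SNP\tCHR\tBP\tEA\tNEA\tEAF\tBETA\tSE\tP\tN",
#'   "rs1\t1\t1000\tA\tG\t0.30\t0.12\t0.02\t2e-9\t50000"
#' ), tf)
#' read_summary_table(tf, trait_label = "exposure")
#' @export
read_summary_table <- function(path, column_map = NULL, trait_label = NULL,
                               delim = NULL) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "bimr_error_io")
  }
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- readr::read_delim(path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, trim_ws = TRUE
  )

  map <- default_column_map
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(map))
    if (length(bad) > 0) {
      abort(paste0("Unknown column_map field(s): ", paste(bad, collapse = ", ")),
        class = "bimr_error_config"
      )
    }
    map[names(column_map)] <- column_map
  }
  missing_cols <- map[mandatory_fields][!map[mandatory_fields] %in% names(raw)]
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Mandatory column(s) not found in ", path, ": ",
      paste(missing_cols, collapse = ", "),
      ". Supply a `column_map` matching the file header."
    ), class = "bimr_error_config")
  }

  pick <- function(field, parse = identity) {
    col <- map[[field]]
    if (col %in% names(raw)) parse(raw[[col]]) else rep(NA, nrow(raw))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  tab <- tibble::tibble(
    variant_id = pick("variant_id", as.character),
    chromosome = pick("chromosome", as.character),
    position = pick("position", function(x) as.integer(num(x))),
    effect_allele = toupper(pick("effect_allele", as.character)),
    other_allele = toupper(pick("other_allele", as.character)),
    eaf = pick("eaf", num),
    beta = pick("beta", num),
    se = pick("se", num),
    pvalue = pick("pvalue", num),
    n = pick("n", num)
  )

  valid_allele <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")
  reason <- dplyr::case_when(
    is.na(tab$variant_id) | tab$variant_id == "" ~ "missing_variant_id",
    !valid_allele(tab$effect_allele) | !valid_allele(tab$other_allele) ~ "invalid_allele",
    tab$effect_allele == tab$other_allele ~ "identical_alleles",
    is.na(tab$beta) ~ "missing_beta",
    is.na(tab$se) | tab$se <= 0 ~ "nonpositive_se",
    is.na(tab$pvalue) | tab$pvalue <= 0 | tab$pvalue > 1 ~ "invalid_pvalue",
    !is.na(tab$eaf) & (tab$eaf < 0 | tab$eaf > 1) ~ "invalid_eaf",
    TRUE ~ NA_character_
  )
  kept <- tab[is.na(reason), , drop = FALSE]
  dropped_reasons <- reason[!is.na(reason)]

  # Duplicate variant ids: keep the smallest p-value (ties: first occurrence).
  if (anyDuplicated(kept$variant_id) > 0) {
    ord <- order(kept$pvalue, seq_len(nrow(kept)))
    dup <- duplicated(kept$variant_id[ord])
    drop_idx <- sort(ord[dup])
    dropped_reasons <- c(dropped_reasons, rep("duplicate_variant_id", length(drop_idx)))
    kept <- kept[-drop_idx, , drop = FALSE]
  }

  if (nrow(kept) == 0) {
    abort(paste0("No valid rows in ", path, " after validation."),
      class = "bimr_error_empty_input"
    )
  }

  by_reason <- as.list(table(dropped_reasons))
  attr(kept, "load_report") <- list(
    read = nrow(tab), kept = nrow(kept),
    dropped = nrow(tab) - nrow(kept),
    dropped_by_reason = by_reason
  )
  attr(kept, "trait_label") <- trait_label
  kept
}

#' Retrieve the load/harmonization report attached to a table
#'
#' @param x A table returned by [read_summary_table()] or [harmonize()].
#' @return A list of counts (`read`/`pairs`, `kept`, `dropped`,
#'   `dropped_by_reason`).
#' @export
load_report <- function(x) {
  attr(x, "load_report") %||% attr(x, "report")
}

#' Is an allele pair palindromic?
#'
#' A palindromic (ambiguous-strand) SNP carries complementary alleles — A/T
#' or C/G — so forward and reverse strand reads show the same base pair and
#' strand orientation cannot be resolved from the alleles alone.
#'
#' @param effect_allele,other_allele Character vectors of single bases
#'   (A, C, G or T).
#' @return Logical vector: `TRUE` where the unordered pair is \{A,T\} or
#'   \{C,G\}.
#' @examples
#' is_palindromic(c("A", "A"), c("T", "G"))
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  ea <- toupper(effect_allele)
  oa <- toupper(other_allele)
  ok <- ea %in% c("A", "C", "G", "T") & oa %in% c("A", "C", "G", "T")
  if (!all(ok)) {
    abort("Alleles must be single bases A, C, G or T.",
      class = "bimr_error_invalid_allele"
    )
  }
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

allele_complement <- function(x) chartr("ACGT", "TGCA", x)

#' Harmonize exposure and outcome associations to a shared effect allele
#'
#' Pairs each exposure variant with its outcome record and aligns the outcome
#' effect to the exposure effect allele.  Matching is attempted directly,
#' after swapping effect/other alleles (outcome beta negated, allele
#' frequency complemented), and after strand complementation (both with and
#' without a swap).  Palindromic pairs are always dropped — never rescued by
#' allele-frequency inference — as are variants absent from the outcome table
#' or with irreconcilable alleles.
#'
#' @param exposure,outcome Variant-association tables as returned by
#'   [read_summary_table()].
#' @return A tibble of harmonized instruments with columns `variant_id`,
#'   `chromosome`, `position`, `effect_allele`, `other_allele` (exposure
#'   orientation), `gamma`, `se_gamma` (exposure effect and SE), `Gamma`,
#'   `se_Gamma` (aligned outcome effect and SE), `eaf_exposure`,
#'   `eaf_outcome`, `pvalue_exposure`, `flipped` (outcome alleles were
#'   swapped) and `strand_flipped` (match required strand complementation).
#'   Dropped variants and one reason code each are recorded in
#'   `attr(, "drops")`; counts in the report returned by [load_report()].
#' @export
harmonize <- function(exposure, outcome) {
  for (tab in list(exposure, outcome)) {
    missing <- setdiff(
      c("variant_id", "effect_allele", "other_allele", "beta", "se"),
      names(tab)
    )
    if (length(missing) > 0) {
      abort(paste0("Table lacks column(s): ", paste(missing, collapse = ", ")),
        class = "bimr_error_columns"
      )
    }
  }
  out_cols <- tibble::tibble(
    variant_id = outcome$variant_id,
    ea_out = toupper(outcome$effect_allele),
    oa_out = toupper(outcome$other_allele),
    beta_out = outcome$beta,
    se_out = outcome$se,
    eaf_out = if ("eaf" %in% names(outcome)) outcome$eaf else NA_real_
  )
  joined <- dplyr::inner_join(exposure, out_cols, by = "variant_id")
  missing_ids <- setdiff(exposure$variant_id, outcome$variant_id)

  ea_x <- toupper(joined$effect_allele)
  oa_x <- toupper(joined$other_allele)
  ea_c <- allele_complement(joined$ea_out)
  oa_c <- allele_complement(joined$oa_out)

  status <- dplyr::case_when(
    is_palindromic(ea_x, oa_x) | is_palindromic(joined$ea_out, joined$oa_out) ~ "palindromic",
    joined$ea_out == ea_x & joined$oa_out == oa_x ~ "direct",
    joined$ea_out == oa_x & joined$oa_out == ea_x ~ "swap",
    ea_c == ea_x & oa_c == oa_x ~ "strand",
    ea_c == oa_x & oa_c == ea_x ~ "strand_swap",
    TRUE ~ "allele_mismatch"
  )
  keep <- status %in% c("direct", "swap", "strand", "strand_swap")
  flipped <- status %in% c("swap", "strand_swap")
  strand_flipped <- status %in% c("strand", "strand_swap")

  kept <- tibble::tibble(
    variant_id = joined$variant_id,
    chromosome = if ("chromosome" %in% names(joined)) joined$chromosome else NA_character_,
    position = if ("position" %in% names(joined)) joined$position else NA_integer_,
    effect_allele = ea_x,
    other_allele = oa_x,
    gamma = joined$beta,
    se_gamma = joined$se,
    Gamma = ifelse(flipped, -joined$beta_out, joined$beta_out),
    se_Gamma = joined$se_out,
    eaf_exposure = if ("eaf" %in% names(joined)) joined$eaf else NA_real_,
    eaf_outcome = ifelse(flipped, 1 - joined$eaf_out, joined$eaf_out),
    pvalue_exposure = if ("pvalue" %in% names(joined)) joined$pvalue else NA_real_,
    flipped = flipped,
    strand_flipped = strand_flipped
  )[keep, , drop = FALSE]

  drops <- dplyr::bind_rows(
    tibble::tibble(
      variant_id = missing_ids,
      reason = rep("missing_in_outcome", length(missing_ids))
    ),
    tibble::tibble(
      variant_id = joined$variant_id[!keep],
      reason = status[!keep]
    )
  )
  attr(kept, "drops") <- drops
  attr(kept, "report") <- list(
    pairs = nrow(exposure), kept = nrow(kept), dropped = nrow(drops),
    dropped_by_reason = as.list(table(drops$reason)),
    strand_complemented = sum(strand_flipped & keep)
  )
  class(kept) <- c("mr_instruments", class(kept))
  kept
}

#' Variants dropped during harmonization, with reason codes
#'
#' @param x A harmonized table from [harmonize()].
#' @return A tibble with columns `variant_id` and `reason`
#'   (`missing_in_outcome`, `palindromic`, `allele_mismatch`).
#' @export
harmonization_drops <- function(x) {
  attr(x, "drops")
}
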