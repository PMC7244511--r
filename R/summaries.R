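#' Dataset-level summary counts and percentages
#'
#' `dataset_summary()` is the pure arithmetic: given the number of
#' identified sites, localized sites and localized sites quantified in at
#' least two replicates, it reports the percentages (rounded to the nearest
#' integer) with division guards — a zero denominator yields `NA`, never 0.
#' `summarize_dataset()` derives those counts from a site table: a site is
#' "localized" at `loc_min` and "quantified in >= 2 replicates" when its
#' non-missing ratios cover at least two distinct replicate ids.
#'
#' @param n_identified,n_localized,n_quant_min2 Non-negative counts.
#' @param table A [site_table()].
#' @param loc_min Localization threshold, default 0.75.
#' @return A one-row tibble: `n_identified`, `n_localized`, `pct_localized`,
#'   `n_quant_min2`, `pct_quant_min2`.
#' @examples
#' dataset_summary(16633, 11493, 8441) # 69% localized, 73% in >= 2 reps
#' @export
dataset_summary <- function(n_identified, n_localized, n_quant_min2) {
  for (v in c(n_identified, n_localized, n_quant_min2)) {
    assert_scalar_num(v, "count", lower = 0)
  }
  pct <- function(num, den) {
    if (den <= 0) NA_real_ else round(100 * num / den)
  }
  tibble::tibble(
    n_identified = n_identified,
    n_localized = n_localized,
    pct_localized = pct(n_localized, n_identified),
    n_quant_min2 = n_quant_min2,
    pct_quant_min2 = pct(n_quant_min2, n_localized)
  )
}

#' @rdname dataset_summary
#' @export
summarize_dataset <- function(table, loc_min = 0.75) {
  samples <- sample_info(table)
  ratios <- site_ratios(table)
  is_loc <- !is.na(table$loc_prob) & table$loc_prob >= loc_min
  reps <- samples$replicate[match(colnames(ratios), samples$sample_id)]
  n_reps_obs <- apply(ratios, 1L, function(r) {
    length(unique(reps[!is.na(r)]))
  })
  dataset_summary(nrow(table), sum(is_loc), sum(is_loc & n_reps_obs >= 2L))
}

#' Normalize targeted-MS intensities to a spiked standard
#'
#' Per sample, each target intensity is divided by the summed intensity of
#' the standard peptides of that sample; log2 treatment/control ratios are
#' computed on the normalized values when sample pairs are given.
#'
#' @param target Named numeric vector of target-peptide intensities, one per
#'   sample.
#' @param standards Numeric matrix or data frame of standard-peptide
#'   intensities (rows = standard peptides, columns = samples, column names
#'   matching `target`).
#' @param treatment,control Optional equal-length character vectors of
#'   sample names; row `i` of the returned `ratios` is
#'   `log2(normalized[treatment[i]] / normalized[control[i]])`.
#' @return A list with `normalized` (tibble: `sample`, `target`,
#'   `standard_sum`, `normalized`) and `ratios` (tibble or `NULL`).
#' @export
prm_normalize <- function(target, standards, treatment = NULL,
                          control = NULL) {
  standards <- as.matrix(standards)
  if (is.null(names(target)) || is.null(colnames(standards))) {
    stopf("`target` and `standards` columns must be named by sample")
  }
  miss <- setdiff(names(target), colnames(standards))
  if (length(miss) > 0L) {
    stopf("no standard intensities for sample(s): %s",
          paste(miss, collapse = ", "))
  }
  sums <- colSums(standards[, names(target), drop = FALSE])
  bad <- names(target)[sums <= 0]
  if (length(bad) > 0L) {
    stopf("summed standard intensity is not positive in sample(s): %s",
          paste(bad, collapse = ", "))
  }
  normalized <- tibble::tibble(
    sample = names(target),
    target = unname(target),
    standard_sum = unname(sums),
    normalized = unname(target / sums)
  )
  ratios <- NULL
  if (!is.null(treatment) || !is.null(control)) {
    if (length(treatment) != length(control)) {
      stopf("`treatment` and `control` must have equal length")
    }
    idx_t <- match(treatment, normalized$sample)
    idx_c <- match(control, normalized$sample)
    if (anyNA(idx_t) || anyNA(idx_c)) {
      stopf("ratio samples must appear in `target`")
    }
    ratios <- tibble::tibble(
      treatment = treatment, control = control,
      log2_ratio = log2(normalized$normalized[idx_t] /
                          normalized$normalized[idx_c])
    )
  }
  list(normalized = normalized, ratios = ratios)
}

#' Per-site normalized MS1 quantification with two-stage errors
#'
#' Peptide intensities distinctive for one site class are summed per
#' measurement (experiment x technical replicate) and normalized by the
#' total summed intensity of that measurement. Mean and standard error are
#' then taken in two stages: first across technical replicates within each
#' experiment, then across experiments.
#'
#' @param data Tibble with columns `site`, `experiment`, `tech_rep`,
#'   `intensity` (one row per peptide observation; every peptide row maps to
#'   exactly one site class).
#' @return Tibble with one row per site: `mean`, `sem`, `n_experiments`.
#'   Measurements whose total intensity is zero are excluded with a warning.
#' @export
ms1_site_quant <- function(data) {
  need <- c("site", "experiment", "tech_rep", "intensity")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) {
    stopf("`data` is missing column(s): %s", paste(miss, collapse = ", "))
  }
  totals <- data |>
    dplyr::group_by(.data$experiment, .data$tech_rep) |>
    dplyr::summarise(total = sum(.data$intensity), .groups = "drop")
  dead <- totals[totals$total <= 0, ]
  if (nrow(dead) > 0L) {
    warn(sprintf("excluding %d measurement(s) with zero total intensity",
                 nrow(dead)))
    totals <- totals[totals$total > 0, ]
  }
  site_sums <- data |>
    dplyr::group_by(.data$experiment, .data$tech_rep, .data$site) |>
    dplyr::summarise(sum_int = sum(.data$intensity), .groups = "drop")
  # a site absent from a measurement contributes fraction 0
  frac <- tidyr::crossing(totals, site = unique(data$site)) |>
    dplyr::left_join(site_sums, by = c("experiment", "tech_rep", "site")) |>
    dplyr::mutate(frac = dplyr::coalesce(.data$sum_int, 0) / .data$total)
  per_exp <- frac |>
    dplyr::group_by(.data$site, .data$experiment) |>
    dplyr::summarise(exp_mean = mean(.data$frac), .groups = "drop")
  per_exp |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(
      mean = mean(.data$exp_mean),
      sem = if (dplyr::n() > 1L) {
        sd(.data$exp_mean) / sqrt(dplyr::n())
      } else {
        NA_real_
      },
      n_experiments = dplyr::n(),
      .groups = "drop"
    )
}
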