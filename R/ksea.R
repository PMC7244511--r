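#' Map quantified phosphopeptides to kinase groups
#'
#' A phosphopeptide is attributed to a kinase group when any of its
#' localized sites is annotated for that group in the kinase-substrate
#' table (kinase isoforms are expected to be grouped already, e.g.
#' Akt1/Akt2 -> AKT). A peptide may map to several groups; within a group a
#' peptide is counted once even when several isoforms annotate it.
#'
#' @param data Tibble with one row per quantified phosphopeptide site:
#'   columns `protein_id`, `position`, a fold-change column (`fc_col`) and
#'   optionally `loc_prob` (rows below `loc_min` are not mapped) and
#'   `peptide_id` (defaults to `protein_id` + `position`).
#' @param ks Kinase-substrate tibble as from [read_kinase_substrates()].
#' @param fc_col Name of the log2 fold-change column; default `"fc"`.
#' @param loc_min Localization threshold applied when `loc_prob` is present.
#' @return Tibble with columns `kinase_group`, `peptide_id`, `fc` (one row
#'   per mapped, deduplicated peptide).
#' @export
map_substrates <- function(data, ks, fc_col = "fc", loc_min = 0.75) {
  need <- c("protein_id", "position", fc_col)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) {
    stopf("`data` is missing column(s): %s", paste(miss, collapse = ", "))
  }
  d <- tibble::as_tibble(data)
  if (!"peptide_id" %in% names(d)) {
    d$peptide_id <- paste(d$protein_id, d$position, sep = "@")
  }
  if ("loc_prob" %in% names(d)) {
    d <- d[!is.na(d$loc_prob) & d$loc_prob >= loc_min, , drop = FALSE]
  }
  d <- d[!is.na(d[[fc_col]]), , drop = FALSE]
  d$fc <- d[[fc_col]]
  dplyr::inner_join(
    d[, c("protein_id", "position", "peptide_id", "fc")],
    ks[, c("kinase_group", "substrate_protein", "substrate_position")],
    by = c(protein_id = "substrate_protein", position = "substrate_position"),
    relationship = "many-to-many"
  ) |>
    dplyr::distinct(.data$kinase_group, .data$peptide_id,
                    .keep_all = TRUE) |>
    dplyr::select("kinase_group", "peptide_id", "fc")
}

#' Kinase-substrate enrichment scores
#'
#' For each kinase group with at least `min_substrates` mapped substrate
#' peptides, the normalized kinase score is the z-score-type statistic
#' `(s_bar - p_bar) * sqrt(m) / sigma`, where `s_bar` is the mean log2
#' fold-change of the kinase's substrates, `p_bar` the mean over all
#' quantified phosphopeptides, `m` the substrate count and `sigma` the
#' (sample) standard deviation of all fold-changes.
#'
#' @param substrates Tibble from [map_substrates()] (columns `kinase_group`,
#'   `fc`), or a named list of numeric fold-change vectors.
#' @param all_fc Numeric vector of fold-changes of all quantified
#'   phosphopeptides (the background).
#' @param min_substrates Minimum substrate count per reported kinase;
#'   default 5.
#' @return Tibble sorted by score: `kinase_group`, `m`, `s_mean`, `p_mean`,
#'   `sigma`, `score`.
#' @export
ksea_scores <- function(substrates, all_fc, min_substrates = 5L) {
  if (is.list(substrates) && !is.data.frame(substrates)) {
    substrates <- purrr::imap_dfr(substrates, function(fc, grp) {
      tibble::tibble(kinase_group = grp, fc = fc)
    })
  }
  all_fc <- all_fc[!is.na(all_fc)]
  if (length(all_fc) < 2L) stopf("need >= 2 background fold-changes")
  if (!all(is.finite(all_fc))) stopf("fold-changes must be finite")
  sigma <- sd(all_fc)
  if (sigma == 0) stopf("all fold-changes are identical (sigma = 0)")
  p_mean <- mean(all_fc)
  substrates |>
    dplyr::group_by(.data$kinase_group) |>
    dplyr::summarise(m = dplyr::n(), s_mean = mean(.data$fc),
                     .groups = "drop") |>
    dplyr::filter(.data$m >= min_substrates) |>
    dplyr::mutate(
      p_mean = p_mean, sigma = sigma,
      score = (.data$s_mean - p_mean) * sqrt(.data$m) / sigma
    ) |>
    dplyr::arrange(dplyr::desc(.data$score))
}
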