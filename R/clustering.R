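#' Impute missing profile entries from a downshifted normal
#'
#' Per column with observed mean `mu` and standard deviation `sigma`,
#' missing entries are drawn from `Normal(mu - downshift*sigma,
#' (width*sigma)^2)` — the standard model for values missing because a
#' peptide's abundance fell below the detection limit. Observed entries are
#' untouched and the result is deterministic given `seed`.
#'
#' @param mat Numeric matrix (rows = peptides/proteins, columns =
#'   conditions) with `NA` for missing entries; each column needs at least
#'   two observed values.
#' @param downshift Downshift in multiples of the column SD; default 2.
#' @param width Width of the imputation distribution in multiples of the
#'   column SD; default 0.3.
#' @param seed Integer seed, or `NULL` to use the caller's RNG stream.
#' @return The matrix with missing entries filled in.
#' @export
impute_missing <- function(mat, downshift = 2, width = 0.3, seed = NULL) {
  mat <- as.matrix(mat)
  assert_scalar_num(downshift, "downshift", lower = 0)
  assert_scalar_num(width, "width", lower = 0)
  n_obs <- colSums(!is.na(mat))
  bad <- colnames(mat) %||% as.character(seq_len(ncol(mat)))
  dead <- which(n_obs == 0L)
  if (length(dead) > 0L) {
    stopf("column(s) fully missing: %s", paste(bad[dead], collapse = ", "))
  }
  thin <- which(n_obs < 2L)
  if (length(thin) > 0L) {
    stopf("column(s) with fewer than 2 observed values: %s",
          paste(bad[thin], collapse = ", "))
  }
  with_seed_opt(seed, {
    for (j in seq_len(ncol(mat))) {
      miss <- which(is.na(mat[, j]))
      if (length(miss) == 0L) next
      mu <- mean(mat[, j], na.rm = TRUE)
      sigma <- sd(mat[, j], na.rm = TRUE)
      mat[miss, j] <- rnorm(length(miss), mean = mu - downshift * sigma,
                            sd = width * sigma)
    }
    mat
  })
}

#' Filter profiles on fold change and adjusted significance
#'
#' Keeps rows showing at least one condition with `|log2 fold-change|`
#' above `threshold` whose adjusted p value in that same condition passes
#' the condition's significance level (e.g. 0.05 for one dataset's columns
#' and 0.01 for another's).
#'
#' @param mat Numeric matrix of log2 fold-changes.
#' @param p_adjust Matrix of adjusted p values, same dimensions as `mat`.
#' @param threshold Minimum absolute log2 fold-change; default 0.58.
#' @param alpha Significance level(s); scalar or one per column of `mat`.
#' @return The row subset of `mat` passing the filter.
#' @export
filter_min_fc <- function(mat, p_adjust, threshold = 0.58, alpha = 0.05) {
  mat <- as.matrix(mat)
  p_adjust <- as.matrix(p_adjust)
  if (!all(dim(mat) == dim(p_adjust))) {
    stopf("`mat` and `p_adjust` must have identical dimensions")
  }
  assert_scalar_num(threshold, "threshold", lower = 0, strict = TRUE)
  if (length(alpha) == 1L) alpha <- rep(alpha, ncol(mat))
  if (length(alpha) != ncol(mat)) {
    stopf("`alpha` must be scalar or one value per column")
  }
  pass <- abs(mat) > threshold &
    sweep(p_adjust, 2L, alpha, `<`) &
    !is.na(mat) & !is.na(p_adjust)
  mat[rowSums(pass, na.rm = TRUE) > 0L, , drop = FALSE]
}

#' Hierarchical clustering on correlation distance with Ward linkage
#'
#' Rows are clustered on the distance `1 - Pearson r` between their
#' profiles with Ward's minimum-variance criterion (Ward.D2 form: the
#' Lance-Williams update on squared distances), and the tree is cut into
#' `k` clusters. A row-wise z-scored copy of the matrix is returned for
#' heatmap-style visualization.
#'
#' @param mat Complete numeric matrix (impute first); >= 2 columns.
#' @param k Number of clusters (>= 1).
#' @return A list of class `hier_clust`: `assignment` (tibble `row_id`,
#'   `cluster`), `tree` (an `hclust`), `k`, and `zscores` (matrix).
#' @export
hier_cluster <- function(mat, k) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stopf("need >= 2 columns to correlate profiles")
  if (anyNA(mat)) stopf("`mat` contains missing values; impute first")
  if (k < 1L || k > nrow(mat)) stopf("`k` must lie in [1, nrow(mat)]")
  ids <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  row_sd <- apply(mat, 1L, sd)
  if (any(row_sd == 0)) {
    stopf("constant row(s) have undefined correlation: %s",
          paste(ids[row_sd == 0], collapse = ", "))
  }
  d <- as.dist(1 - cor(t(mat)))
  tree <- hclust(d, method = "ward.D2")
  cluster <- cutree(tree, k = k)
  z <- (mat - rowMeans(mat)) / row_sd
  structure(list(
    assignment = tibble::tibble(row_id = ids, cluster = unname(cluster)),
    tree = tree, k = as.integer(k), zscores = z
  ), class = "hier_clust")
}

#' Proximity-labeling enrichment classification
#'
#' Filters proteins lacking at least `min_ratios` quantified SILAC ratios in
#' any biological replicate and control dimension, averages the log10
#' ratios per control dimension, partitions the proteins into `k` groups by
#' the squared-Euclidean (k-means) criterion with a seeded best-of-25
#' initialization, and declares enriched the group whose centroid is
#' maximal in relation to both controls.
#'
#' @param data Long tibble with columns `protein_id`, `replicate`,
#'   `control` (one of two control-dimension ids) and `log10_ratio`
#'   (`NA` = not quantified).
#' @param k Number of groups; must not exceed the number of proteins kept.
#' @param seed Integer seed for the k-means initialization.
#' @param min_ratios Minimum quantified ratios per (protein, replicate,
#'   control); default 3.
#' @param n_restarts Random restarts for k-means; default 25.
#' @return A list of class `proximity_enrich`: `proteins` (tibble:
#'   `protein_id`, mean per control dimension, `cluster`, `enriched`),
#'   `centers` (k x 2 matrix), `enriched_cluster` (integer or `NA`),
#'   `dropped` (character vector of filtered-out proteins).
#' @export
proximity_enrich <- function(data, k = 3L, seed = 1L, min_ratios = 3L,
                             n_restarts = 25L) {
  need <- c("protein_id", "replicate", "control", "log10_ratio")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) {
    stopf("`data` is missing column(s): %s", paste(miss, collapse = ", "))
  }
  dims <- sort(unique(data$control))
  if (length(dims) != 2L) {
    stopf("expected exactly two control dimensions, found %d", length(dims))
  }
  counts <- data |>
    dplyr::group_by(.data$protein_id, .data$replicate, .data$control) |>
    dplyr::summarise(n = sum(!is.na(.data$log10_ratio)), .groups = "drop")
  # every (replicate, control) cell must reach min_ratios
  ok <- counts |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(keep = all(.data$n >= min_ratios), .groups = "drop")
  kept <- ok$protein_id[ok$keep]
  dropped <- ok$protein_id[!ok$keep]
  if (length(kept) < k) {
    stopf("k = %d exceeds the %d protein(s) passing the ratio filter",
          k, length(kept))
  }
  means <- data |>
    dplyr::filter(.data$protein_id %in% kept) |>
    dplyr::group_by(.data$protein_id, .data$control) |>
    dplyr::summarise(m = mean(.data$log10_ratio, na.rm = TRUE),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "control", values_from = "m")
  X <- as.matrix(means[, dims])
  rownames(X) <- means$protein_id
  n_distinct <- nrow(unique(X))
  if (n_distinct < k) {
    warn(sprintf("only %d distinct profiles; using k = %d", n_distinct,
                 n_distinct))
    k <- n_distinct
  }
  km <- with_seed_opt(seed, kmeans(X, centers = k, nstart = n_restarts))
  top1 <- which.max(km$centers[, 1L])
  top2 <- which.max(km$centers[, 2L])
  enriched_cluster <- if (top1 == top2) unname(top1) else NA_integer_
  if (is.na(enriched_cluster)) {
    warn("no group is maximal in both control dimensions; enriched set empty")
  }
  proteins <- tibble::tibble(
    protein_id = means$protein_id,
    !!dims[1L] := X[, 1L], !!dims[2L] := X[, 2L],
    cluster = unname(km$cluster),
    enriched = !is.na(enriched_cluster) & km$cluster == enriched_cluster
  )
  structure(list(proteins = proteins, centers = km$centers,
                 enriched_cluster = enriched_cluster, dropped = dropped),
            class = "proximity_enrich")
}
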