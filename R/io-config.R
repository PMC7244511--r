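#' Pipeline run configuration
#'
#' Bundles the analysis thresholds, the random seed and any file paths into
#' one validated list, with defaults matching the package's standard
#' workflow: fold-change cutoff 1.5, significance level 0.05, localization
#' threshold 0.75, motif search with minimum occurrence 10 at p < 1e-6,
#' kinase scores for >= 5 mapped substrates, and downshifted-normal
#' imputation (downshift 2 sigma, width 0.3 sigma).
#'
#' Configurations round-trip through a plain `key = value` text file
#' (`#` starts a comment; keys not listed here are kept as character paths).
#'
#' @param fc_min Minimum fold change (linear scale, > 1) for a regulation call.
#' @param alpha Significance level on the (adjusted) p value.
#' @param loc_prob_min Localization-probability threshold for "localized".
#' @param motif_p_cutoff Binomial p-value cutoff per motif-fixing step.
#' @param motif_min_occurrence Minimum foreground support per motif.
#' @param ksea_min_substrates Minimum mapped substrates per reported kinase.
#' @param impute_downshift,impute_width Downshift and width of the imputation
#'   distribution, in multiples of the column SD.
#' @param seed Integer random seed.
#' @param paths Named character vector/list of file paths.
#' @param path File to read from or write to.
#' @param config A `run_config` object.
#' @return `run_config()` and `read_run_config()` return a `run_config`
#'   (named list); `write_run_config()` returns `path` invisibly.
#' @export
run_config <- function(fc_min = 1.5, alpha = 0.05, loc_prob_min = 0.75,
                       motif_p_cutoff = 1e-6, motif_min_occurrence = 10L,
                       ksea_min_substrates = 5L, impute_downshift = 2,
                       impute_width = 0.3, seed = 1L, paths = list()) {
  assert_scalar_num(fc_min, "fc_min", lower = 1, strict = TRUE)
  assert_scalar_num(alpha, "alpha", lower = 0, upper = 1, strict = TRUE)
  assert_scalar_num(loc_prob_min, "loc_prob_min", lower = 0, upper = 1)
  assert_scalar_num(motif_p_cutoff, "motif_p_cutoff", lower = 0, upper = 1,
                    strict = TRUE)
  assert_scalar_num(motif_min_occurrence, "motif_min_occurrence", lower = 1)
  assert_scalar_num(ksea_min_substrates, "ksea_min_substrates", lower = 1)
  assert_scalar_num(impute_downshift, "impute_downshift", lower = 0)
  assert_scalar_num(impute_width, "impute_width", lower = 0)
  assert_scalar_num(seed, "seed")
  structure(list(
    fc_min = fc_min, alpha = alpha, loc_prob_min = loc_prob_min,
    motif_p_cutoff = motif_p_cutoff,
    motif_min_occurrence = as.integer(motif_min_occurrence),
    ksea_min_substrates = as.integer(ksea_min_substrates),
    impute_downshift = impute_downshift, impute_width = impute_width,
    seed = as.integer(seed), paths = as.list(paths)
  ), class = "run_config")
}

NUMERIC_CONFIG_KEYS <- c("fc_min", "alpha", "loc_prob_min", "motif_p_cutoff",
                         "motif_min_occurrence", "ksea_min_substrates",
                         "impute_downshift", "impute_width", "seed")

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- which(lengths(kv) != 2L)
  if (length(bad) > 0L) {
    stopf("config line %d is not of the form 'key = value'", bad[1L])
  }
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  args <- list()
  paths <- list()
  for (i in seq_along(keys)) {
    if (keys[i] %in% NUMERIC_CONFIG_KEYS) {
      args[[keys[i]]] <- as.numeric(vals[i])
    } else {
      paths[[keys[i]]] <- vals[i]
    }
  }
  do.call(run_config, c(args, list(paths = paths)))
}

#' @rdname run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  num <- vapply(NUMERIC_CONFIG_KEYS, function(k) {
    format(config[[k]], digits = 15)
  }, "")
  lines <- paste(NUMERIC_CONFIG_KEYS, "=", num)
  if (length(config$paths) > 0L) {
    lines <- c(lines, paste(names(config$paths), "=",
                            unlist(config$paths, use.names = FALSE)))
  }
  writeLines(lines, path)
  invisible(path)
}
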