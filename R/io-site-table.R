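#' Phosphosite quantification tables
#'
#' A site table holds one row per quantified phosphosite in the dialect of a
#' MaxQuant "Phospho (STY) sites" export: identity columns (protein accession,
#' gene, 1-based residue position, phosphoacceptor residue), the localization
#' probability, the +/-7-residue sequence window (15 characters, site at
#' position 8, terminal overhang padded with `_`), and one numeric column of
#' log2 SILAC ratios per sample. Sample columns are named
#' `<treatment>_<replicate>_<label>` and that metadata is kept as a `samples`
#' attribute (a tibble with columns `sample_id`, `treatment`, `replicate`,
#' `label`).
#'
#' `site_table()` validates a plain tibble and stamps the class;
#' `sample_info()` returns the sample-metadata tibble; `site_ratios()` returns
#' the ratio columns as a numeric matrix (rows in table order).
#'
#' @param x A data frame with columns `protein_id`, `gene`, `position`,
#'   `residue`, `loc_prob`, `window`, plus one numeric column per sample.
#' @param samples Optional sample-metadata tibble; by default it is parsed
#'   from the ratio column names.
#' @return `site_table()` returns a validated `site_tbl` (a tibble);
#'   `sample_info()` a tibble; `site_ratios()` a numeric matrix.
#' @examples
#' tbl <- site_table(tibble::tibble(
#'   protein_id = "P1", gene = "G1", position = 8L, residue = "S",
#'   loc_prob = 0.99, window = "AAAAAAASAAAAAAA",
#'   IGF_1_L = 0.5, IGF_2_M = 0.4
#' ))
#' sample_info(tbl)
#' @export
site_table <- function(x, samples = NULL) {
  core <- c("protein_id", "gene", "position", "residue", "loc_prob", "window")
  missing_cols <- setdiff(core, names(x))
  if (length(missing_cols) > 0L) {
    stopf("site table is missing mandatory column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  x <- tibble::as_tibble(x)
  ratio_cols <- setdiff(names(x), core)
  if (is.null(samples)) {
    samples <- parse_sample_names(ratio_cols)
  } else {
    samples <- tibble::as_tibble(samples)
    extra <- setdiff(ratio_cols, samples$sample_id)
    if (length(extra) > 0L) {
      stopf("ratio column(s) absent from sample metadata: %s",
            paste(extra, collapse = ", "))
    }
  }
  bad_window <- which(nchar(x$window) != WINDOW_WIDTH)
  if (length(bad_window) > 0L) {
    stopf("row %d: sequence window must have exactly %d characters (got %d)",
          bad_window[1L], WINDOW_WIDTH, nchar(x$window[bad_window[1L]]))
  }
  centre <- substr(x$window, WINDOW_CENTER, WINDOW_CENTER)
  bad_centre <- which(centre != x$residue)
  if (length(bad_centre) > 0L) {
    stopf("row %d: window centre '%s' does not match residue '%s'",
          bad_centre[1L], centre[bad_centre[1L]], x$residue[bad_centre[1L]])
  }
  if (any(!x$residue %in% c("S", "T", "Y"))) {
    stopf("row %d: residue must be one of S, T, Y",
          which(!x$residue %in% c("S", "T", "Y"))[1L])
  }
  bad_pos <- which(!is.na(x$position) & x$position < 1L)
  if (length(bad_pos) > 0L) {
    stopf("row %d: position must be >= 1", bad_pos[1L])
  }
  bad_lp <- which(!is.na(x$loc_prob) & (x$loc_prob < 0 | x$loc_prob > 1))
  if (length(bad_lp) > 0L) {
    stopf("row %d: localization probability outside [0, 1]", bad_lp[1L])
  }
  for (col in ratio_cols) x[[col]] <- as.numeric(x[[col]])
  attr(x, "samples") <- samples
  class(x) <- unique(c("site_tbl", class(x)))
  x
}

parse_sample_names <- function(ids) {
  if (length(ids) == 0L) {
    return(tibble::tibble(sample_id = character(), treatment = character(),
                          replicate = character(), label = character()))
  }
  parts <- strsplit(ids, "_", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad) > 0L) {
    stopf("sample column '%s' is not of the form <treatment>_<replicate>_<label>",
          ids[bad[1L]])
  }
  tibble::tibble(
    sample_id = ids,
    treatment = vapply(parts, `[`, "", 1L),
    replicate = vapply(parts, `[`, "", 2L),
    label     = vapply(parts, `[`, "", 3L)
  )
}

#' @rdname site_table
#' @export
sample_info <- function(x) {
  s <- attr(x, "samples")
  if (is.null(s)) stopf("`x` carries no sample metadata; is it a site table?")
  s
}

#' @rdname site_table
#' @export
site_ratios <- function(x) {
  ids <- sample_info(x)$sample_id
  m <- as.matrix(x[, ids, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

# external header <-> internal column names
SITE_HEADER <- c(protein_id = "Protein", gene = "Gene", position = "Position",
                 residue = "Amino acid", loc_prob = "Localization prob",
                 window = "Sequence window")

#' Read and write phosphosite tables
#'
#' Tab-separated with header `Protein`, `Gene`, `Position`, `Amino acid`,
#' `Localization prob`, `Sequence window`, then one ratio column per sample
#' named `<treatment>_<replicate>_<label>`. Empty cells and `NA` are read as
#' missing; unparseable numeric cells become missing values with a warning;
#' missing ratios are written back as empty cells. Row order is preserved and
#' no rows are dropped.
#'
#' @param path Path to a tab-separated site table.
#' @param x A `site_tbl` as returned by [site_table()].
#' @return `read_site_table()` returns a `site_tbl`; `write_site_table()`
#'   returns `path` invisibly.
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  missing_cols <- setdiff(unname(SITE_HEADER), names(raw))
  if (length(missing_cols) > 0L) {
    stopf("site table %s is missing mandatory column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  }
  out <- tibble::tibble(
    protein_id = raw[[SITE_HEADER[["protein_id"]]]],
    gene       = raw[[SITE_HEADER[["gene"]]]],
    position   = parse_num(raw[[SITE_HEADER[["position"]]]], integer = TRUE),
    residue    = raw[[SITE_HEADER[["residue"]]]],
    loc_prob   = parse_num(raw[[SITE_HEADER[["loc_prob"]]]]),
    window     = raw[[SITE_HEADER[["window"]]]]
  )
  ratio_cols <- setdiff(names(raw), unname(SITE_HEADER))
  for (col in ratio_cols) out[[col]] <- parse_num(raw[[col]])
  site_table(out)
}

# "" and "NA" -> NA; anything else unparseable -> NA (same convention)
parse_num <- function(x, integer = FALSE) {
  x[x %in% c("", "NA", "NaN")] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  if (integer) out <- as.integer(out)
  out
}

#' @rdname read_site_table
#' @export
write_site_table <- function(x, path) {
  ids <- sample_info(x)$sample_id
  out <- x[, c(names(SITE_HEADER), ids)]
  names(out)[seq_along(SITE_HEADER)] <- unname(SITE_HEADER)
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a kinase-substrate annotation table
#'
#' Tab-separated with columns `KINASE`, `KIN_GROUP`, `SUB_ACC`, `SUB_MOD_RSD`
#' (PhosphoSitePlus-like; `SUB_MOD_RSD` is residue letter + position, e.g.
#' `S473`). Rows that duplicate a (kinase group, substrate accession,
#' position) triple collapse to one row.
#'
#' @param path Path to the annotation table.
#' @return A tibble with columns `kinase`, `kinase_group`,
#'   `substrate_protein`, `substrate_position`, `substrate_residue`.
#' @export
read_kinase_substrates <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("KINASE", "KIN_GROUP", "SUB_ACC", "SUB_MOD_RSD")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stopf("kinase-substrate table is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  rsd <- raw$SUB_MOD_RSD
  ok <- grepl("^[STY][0-9]+$", rsd)
  if (any(!ok)) {
    stopf("row %d: SUB_MOD_RSD '%s' is not <residue><position>",
          which(!ok)[1L], rsd[which(!ok)[1L]])
  }
  tibble::tibble(
    kinase = raw$KINASE,
    kinase_group = raw$KIN_GROUP,
    substrate_protein = raw$SUB_ACC,
    substrate_position = as.integer(sub("^[STY]", "", rsd)),
    substrate_residue = substr(rsd, 1L, 1L)
  ) |>
    dplyr::distinct(.data$kinase_group, .data$substrate_protein,
                    .data$substrate_position, .keep_all = TRUE)
}
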