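#' Extract phosphosite sequence windows
#'
#' Returns the +/- `half_width` residue context around each site as a
#' fixed-length window (site centered); positions running past a protein
#' terminus are padded with `_`.
#'
#' @param sequences Named character vector of protein sequences (as from
#'   [read_fasta()]).
#' @param sites Data frame with columns `protein_id` and `position`
#'   (1-based).
#' @param half_width Residues on either side of the site; default 7
#'   (15-mer windows).
#' @return A tibble with columns `protein_id`, `position`, `window`.
#' @export
extract_windows <- function(sequences, sites, half_width = 7L) {
  if (!all(c("protein_id", "position") %in% names(sites))) {
    stopf("`sites` needs columns protein_id and position")
  }
  seq_of <- sequences[sites$protein_id]
  if (anyNA(names(seq_of)) || any(is.na(seq_of))) {
    bad <- which(is.na(seq_of))[1L]
    stopf("no sequence for accession '%s'", sites$protein_id[bad])
  }
  n <- nrow(sites)
  windows <- character(n)
  for (i in seq_len(n)) {
    s <- seq_of[[i]]
    pos <- sites$position[i]
    len <- nchar(s)
    if (is.na(pos) || pos < 1L || pos > len) {
      stopf("site position %s out of bounds for %s (length %d)",
            pos, sites$protein_id[i], len)
    }
    lo <- pos - half_width
    hi <- pos + half_width
    core <- substr(s, max(1L, lo), min(len, hi))
    pad_l <- strrep(WINDOW_PAD, max(0L, 1L - lo))
    pad_r <- strrep(WINDOW_PAD, max(0L, hi - len))
    windows[i] <- paste0(pad_l, core, pad_r)
  }
  tibble::tibble(protein_id = sites$protein_id, position = sites$position,
                 window = windows)
}

#' Parse phosphorylation-marked windows
#'
#' Windows are accepted as plain text with one window per line; a lowercase
#' letter marks a phosphorylated position. Returns the uppercased window
#' plus the marked positions (1-based; the centre of a 15-mer is position 8).
#' When a window carries no lowercase letters the centre alone is assumed
#' phosphorylated.
#'
#' @param x Character vector of windows.
#' @param path Path to a text file of windows, one per line.
#' @return A tibble with columns `window` (uppercase) and `marks` (list of
#'   integer vectors).
#' @export
parse_windows <- function(x) {
  centre <- (nchar(x) + 1L) %/% 2L
  marks <- lapply(seq_along(x), function(i) {
    chars <- strsplit(x[i], "", fixed = TRUE)[[1L]]
    m <- which(chars %in% letters)
    if (length(m) == 0L) m <- centre[i]
    as.integer(m)
  })
  tibble::tibble(window = toupper(x), marks = marks)
}

#' @rdname parse_windows
#' @export
read_windows <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  parse_windows(lines[lines != ""])
}

#' Iterative position-specific motif enrichment (motif-X style)
#'
#' Starting from all foreground windows of one central residue class (S and
#' T are analysed separately and merged in reporting), the algorithm
#' repeatedly scores every not-yet-fixed (offset, residue) pair by the exact
#' binomial tail probability of observing at least the foreground count
#' given the background frequency at that offset (frequencies computed over
#' non-`_` characters), fixes the most significant pair if it passes both
#' the p-value cutoff and the minimum-occurrence support, and drops
#' non-matching windows from both sets. When no further pair passes, the
#' accumulated pattern is emitted as one motif, its foreground matches are
#' removed, and the search restarts until no motif passes. Residues unseen
#' in the current background at an offset receive a half pseudo-count so
#' the binomial tail never degenerates to an artificial zero.
#'
#' Ties on the minimal p value break deterministically: smaller `|offset|`,
#' then lower offset, then alphabetical residue.
#'
#' @param foreground,background Character vectors of equal-width windows
#'   (uppercase, `_`-padded), e.g. the `window` column of a site table.
#' @param min_occurrence Minimum foreground support for a fixed position
#'   (default 10).
#' @param p_cutoff Binomial p-value cutoff per fixing step (default 1e-6).
#' @return A tibble with one row per motif: `pattern` (e.g. `R.R..S`,
#'   trimmed to the fixed span), `center`, `fixed` (list of tibbles
#'   offset/residue), `fg_matches`, `fg_size`, `bg_matches`, `bg_size`,
#'   `fold_enrichment`, `step_p` (list of per-step p values).
#' @export
motifx_enrich <- function(foreground, background, min_occurrence = 10L,
                          p_cutoff = 1e-6) {
  if (length(foreground) == 0L) stopf("`foreground` is empty")
  if (length(background) == 0L) stopf("`background` is empty")
  width <- unique(nchar(c(foreground, background)))
  if (length(width) != 1L) stopf("all windows must share one width")
  centre <- (width + 1L) %/% 2L

  res <- list()
  for (ctr_res in c("S", "T")) {
    fg <- foreground[substr(foreground, centre, centre) == ctr_res]
    bg <- background[substr(background, centre, centre) == ctr_res]
    if (length(fg) == 0L || length(bg) == 0L) next
    res <- c(res, motifx_one_class(fg, bg, ctr_res, centre, width,
                                   min_occurrence, p_cutoff))
  }
  if (length(res) == 0L) {
    return(tibble::tibble(pattern = character(), center = character(),
                          fixed = list(), fg_matches = integer(),
                          fg_size = integer(), bg_matches = integer(),
                          bg_size = integer(), fold_enrichment = double(),
                          step_p = list()))
  }
  dplyr::bind_rows(res)
}

motifx_one_class <- function(fg, bg, ctr_res, centre, width,
                             min_occurrence, p_cutoff) {
  out <- list()
  fg_pool <- fg
  repeat {
    if (length(fg_pool) == 0L) break
    fg_size <- length(fg_pool)
    bg_size <- length(bg)
    fg_cur <- fg_pool
    bg_cur <- bg
    fixed <- tibble::tibble(offset = integer(), residue = character())
    step_p <- double()
    repeat {
      best <- motifx_best_pair(fg_cur, bg_cur, centre, fixed,
                               min_occurrence, p_cutoff)
      if (is.null(best)) break
      fixed <- dplyr::bind_rows(fixed, tibble::tibble(
        offset = best$offset, residue = best$residue))
      step_p <- c(step_p, best$p)
      at <- centre + best$offset
      fg_cur <- fg_cur[substr(fg_cur, at, at) == best$residue]
      bg_cur <- bg_cur[substr(bg_cur, at, at) == best$residue]
    }
    if (nrow(fixed) == 0L) break
    pattern <- motif_pattern_string(fixed, ctr_res, centre, width)
    bg_matches <- sum(matches_motif(bg, fixed, centre))
    fg_rate <- length(fg_cur) / fg_size
    bg_rate <- bg_matches / bg_size
    out[[length(out) + 1L]] <- tibble::tibble(
      pattern = pattern, center = ctr_res, fixed = list(fixed),
      fg_matches = length(fg_cur), fg_size = fg_size,
      bg_matches = bg_matches, bg_size = bg_size,
      fold_enrichment = if (bg_rate > 0) fg_rate / bg_rate else Inf,
      step_p = list(step_p)
    )
    fg_pool <- fg_pool[!matches_motif(fg_pool, fixed, centre)]
  }
  out
}

# most significant unfixed (offset, residue); NULL when none passes
motifx_best_pair <- function(fg, bg, centre, fixed, min_occurrence,
                             p_cutoff) {
  width <- nchar(fg[1L])
  offsets <- setdiff(seq_len(width) - centre, c(0L, fixed$offset))
  best <- NULL
  for (off in offsets) {
    at <- centre + off
    fg_chars <- substr(fg, at, at)
    bg_chars <- substr(bg, at, at)
    fg_valid <- fg_chars != WINDOW_PAD
    bg_valid <- bg_chars != WINDOW_PAD
    n_bg <- sum(bg_valid)
    if (n_bg == 0L) {
      stopf("background has no informative characters at offset %+d", off)
    }
    n_fg <- sum(fg_valid)
    if (n_fg == 0L) next
    tab <- table(fg_chars[fg_valid])
    for (res in names(tab)) {
      k <- as.integer(tab[[res]])
      if (k < min_occurrence) next
      # half pseudo-count for residues unseen in the (possibly shrunken)
      # background, so the binomial tail never degenerates to 0
      p_bg <- max(sum(bg_chars == res), 0.5) / n_bg
      p <- pbinom(k - 1L, n_fg, p_bg, lower.tail = FALSE)
      if (p >= p_cutoff) next
      cand <- list(offset = off, residue = res, p = p, k = k)
      if (is.null(best) || motifx_pair_beats(cand, best)) best <- cand
    }
  }
  best
}

# tie-break: smaller p, then smaller |offset|, then lower offset, then
# alphabetical residue
motifx_pair_beats <- function(a, b) {
  if (a$p != b$p) return(a$p < b$p)
  if (abs(a$offset) != abs(b$offset)) return(abs(a$offset) < abs(b$offset))
  if (a$offset != b$offset) return(a$offset < b$offset)
  a$residue < b$residue
}

matches_motif <- function(windows, fixed, centre) {
  ok <- rep(TRUE, length(windows))
  for (i in seq_len(nrow(fixed))) {
    at <- centre + fixed$offset[i]
    ok <- ok & substr(windows, at, at) == fixed$residue[i]
  }
  ok
}

motif_pattern_string <- function(fixed, ctr_res, centre, width) {
  chars <- rep(".", width)
  chars[centre] <- ctr_res
  chars[centre + fixed$offset] <- fixed$residue
  span <- range(c(centre, centre + fixed$offset))
  paste(chars[span[1L]:span[2L]], collapse = "")
}

#' Classify windows by the basophilic phosphorylation motifs
#'
#' The classical basophilic motif requires arginine at offsets -5 and -3
#' from the phosphorylated central S/T; the extended motif additionally
#' requires a phosphorylated S/T at +3. Extended takes precedence; the
#' padding character `_` never matches; a window whose centre is not marked
#' as phosphorylated is `none`.
#'
#' @param window Character vector of 15-mer windows. Lowercase letters are
#'   read as phosphorylation marks (see [parse_windows()]); when `marks` is
#'   supplied it overrides the case convention.
#' @param marks Optional list of integer vectors of marked positions
#'   (1-based, centre = 8).
#' @return Character vector with values `"classical"`, `"extended"` or
#'   `"none"`.
#' @export
annotate_basophilic <- function(window, marks = NULL) {
  parsed <- parse_windows(window)
  if (!is.null(marks)) parsed$marks <- marks
  w <- parsed$window
  centre <- WINDOW_CENTER
  bad <- which(!substr(w, centre, centre) %in% c("S", "T"))
  if (length(bad) > 0L) {
    stopf("window %d: centre residue '%s' is not S or T", bad[1L],
          substr(w[bad[1L]], centre, centre))
  }
  vapply(seq_along(w), function(i) {
    m <- parsed$marks[[i]]
    if (!centre %in% m) return("none")
    classical <- substr(w[i], centre - 5L, centre - 5L) == "R" &&
      substr(w[i], centre - 3L, centre - 3L) == "R"
    if (!classical) return("none")
    plus3 <- substr(w[i], centre + 3L, centre + 3L)
    if (plus3 %in% c("S", "T") && (centre + 3L) %in% m) return("extended")
    "classical"
  }, "")
}

#' Three-set overlap counts of annotated peptide groups
#'
#' Standard intersection counts for three peptide groups (each a character
#' vector of unique keys, e.g. sequence plus mark positions).
#'
#' @param g1,g2,g3 Character vectors of peptide keys.
#' @return A one-row tibble with the set sizes (`n1`, `n2`, `n3`), the
#'   pairwise intersection counts (`n12`, `n13`, `n23`) and the triple
#'   intersection (`n123`).
#' @export
group_peptides <- function(g1, g2, g3) {
  g1 <- unique(g1); g2 <- unique(g2); g3 <- unique(g3)
  tibble::tibble(
    n1 = length(g1), n2 = length(g2), n3 = length(g3),
    n12 = length(intersect(g1, g2)),
    n13 = length(intersect(g1, g3)),
    n23 = length(intersect(g2, g3)),
    n123 = length(intersect(intersect(g1, g2), g3))
  )
}
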