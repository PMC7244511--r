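#' Specification for a synthetic phosphoproteomics experiment
#'
#' Describes a triple-label ratio experiment with a label switch: a synthetic
#' proteome hosting phosphosites, a fraction of sites carrying planted
#' treatment effects (concentrated on basophilic-motif sites), per-replicate
#' Gaussian noise, label-configuration offsets, abundance-dependent missing
#' values and localization probabilities. The defaults emulate the design of
#' a three-replicate SILAC study of growth-factor stimulation (`IGF`) and
#' pathway inhibition (`LY`) against a common control, with the treatments
#' rotated over isotope labels between replicates.
#'
#' @param n_proteins Number of synthetic proteins.
#' @param n_sites Number of phosphosites (spread evenly over proteins).
#' @param fraction_regulated Fraction of sites given a true treatment effect.
#' @param effects Named log2 effect sizes per treatment, e.g.
#'   `c(IGF = 1, LY = -1)`.
#' @param noise_sd Residual SD of a single log2 ratio observation.
#' @param n_replicates Number of biological replicates (>= 2).
#' @param label_scheme List of named character vectors, one per replicate,
#'   mapping treatment -> isotope label (the label switch). Must cover
#'   `control` and every treatment in `effects`.
#' @param label_offsets Named numeric, additive log2 bias per isotope label
#'   carried by the treatment channel (labeling bias).
#' @param missing_mu,missing_s Location and scale of the logistic
#'   missing-at-low-abundance mechanism on the latent abundance scale.
#' @param frac_classical,frac_extended Fractions of *regulated* sites planted
#'   with the classical (R at -5/-3) and extended (additionally S at +3)
#'   basophilic motif.
#' @param frac_nonlocalized Fraction of sites drawn with localization
#'   probability below 0.75.
#' @param background Residue frequencies for sequence generation (named,
#'   sums to 1); default uniform over the 20 standard amino acids.
#' @param seed Integer seed; all generators are fully determined by
#'   (spec, seed).
#' @return A `phospho_sim_spec` (named list).
#' @export
phospho_sim_spec <- function(n_proteins = 200L, n_sites = 1000L,
                             fraction_regulated = 0.1,
                             effects = c(IGF = 1, LY = -1),
                             noise_sd = 0.3, n_replicates = 3L,
                             label_scheme = NULL,
                             label_offsets = c(L = 0, M = 0, H = 0),
                             missing_mu = -1.5, missing_s = 0.6,
                             frac_classical = 0.3, frac_extended = 0.15,
                             frac_nonlocalized = 0.31,
                             background = NULL, seed = 1L) {
  if (is.null(background)) {
    background <- setNames(rep(1 / length(AA_ALPHABET), length(AA_ALPHABET)),
                           AA_ALPHABET)
  }
  if (abs(sum(background) - 1) > 1e-8) {
    stopf("`background` frequencies must sum to 1")
  }
  if (is.null(names(effects)) || any(names(effects) == "")) {
    stopf("`effects` must be named by treatment")
  }
  if (n_replicates < 2L) stopf("`n_replicates` must be >= 2")
  for (f in c(fraction_regulated, frac_classical, frac_extended,
              frac_nonlocalized)) {
    assert_scalar_num(f, "fraction", lower = 0, upper = 1)
  }
  if (frac_classical + frac_extended > 1) {
    stopf("motif fractions of regulated sites must sum to <= 1")
  }
  if (!all(is.finite(effects))) stopf("effect sizes must be finite")
  if (is.null(label_scheme)) {
    label_scheme <- default_label_scheme(names(effects), n_replicates)
  }
  if (length(label_scheme) != n_replicates) {
    stopf("`label_scheme` must have one entry per replicate (%d != %d)",
          length(label_scheme), n_replicates)
  }
  for (r in seq_along(label_scheme)) {
    need <- c("control", names(effects))
    if (!all(need %in% names(label_scheme[[r]]))) {
      stopf("label scheme for replicate %d must map all of: %s", r,
            paste(need, collapse = ", "))
    }
  }
  structure(list(
    n_proteins = as.integer(n_proteins), n_sites = as.integer(n_sites),
    fraction_regulated = fraction_regulated, effects = effects,
    noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
    label_scheme = label_scheme, label_offsets = label_offsets,
    missing_mu = missing_mu, missing_s = missing_s,
    frac_classical = frac_classical, frac_extended = frac_extended,
    frac_nonlocalized = frac_nonlocalized,
    background = background, seed = as.integer(seed)
  ), class = "phospho_sim_spec")
}

# rotate treatments over labels L/M/H between replicates ("label switch")
default_label_scheme <- function(treatments, n_replicates) {
  chan <- c("control", treatments)
  labels <- c("L", "M", "H")[seq_along(chan)]
  lapply(seq_len(n_replicates), function(r) {
    rot <- ((seq_along(chan) + r - 2L) %% length(chan)) + 1L
    setNames(labels[rot], chan)
  })
}

#' Generate a synthetic proteome with designated phosphosites
#'
#' Sites are spaced along each protein so their +/-7 windows never overlap.
#' A configured fraction of sites is flagged as regulated; among those,
#' fractions carry the planted classical basophilic motif (R at -5 and -3
#' relative to the central S/T) or the extended motif (additionally S at +3).
#' Regulated sites without a planted motif are rejection-sampled so they do
#' not match the classical pattern by accident (keeping the planted
#' foreground enrichment interpretable); unregulated sites follow the
#' background frequencies untouched.
#'
#' @param spec A [phospho_sim_spec()].
#' @return A list with `sequences` (named character vector, FASTA-ready) and
#'   `sites` (ground-truth tibble: `protein_id`, `gene`, `position`,
#'   `residue`, `regulated`, `motif_class`).
#' @export
simulate_proteome <- function(spec) {
  stopifnot(inherits(spec, "phospho_sim_spec"))
  with_seed_opt(spec$seed, {
    n_prot <- spec$n_proteins
    n_sites <- spec$n_sites
    per_prot <- ceiling(n_sites / n_prot)
    gap <- 40L
    prot_len <- per_prot * gap + 20L
    if (prot_len < 15L) stopf("proteins too short to host the requested sites")

    aa <- names(spec$background)
    freq <- as.numeric(spec$background)

    # site bookkeeping before sequence draw
    site_protein <- rep(seq_len(n_prot), each = per_prot)[seq_len(n_sites)]
    site_index <- rep(seq_len(per_prot), times = n_prot)[seq_len(n_sites)]
    position <- 20L + (site_index - 1L) * gap

    n_reg <- round(spec$fraction_regulated * n_sites)
    regulated <- rep(FALSE, n_sites)
    if (n_reg > 0L) regulated[sample.int(n_sites, n_reg)] <- TRUE
    motif_class <- rep("none", n_sites)
    reg_idx <- which(regulated)
    n_ext <- round(spec$frac_extended * length(reg_idx))
    n_cls <- round(spec$frac_classical * length(reg_idx))
    if (n_ext + n_cls > length(reg_idx)) n_cls <- length(reg_idx) - n_ext
    motif_sites <- sample(reg_idx, n_ext + n_cls)
    motif_class[head(motif_sites, n_ext)] <- "extended"
    motif_class[tail(motif_sites, n_cls)] <- "classical"

    sequences <- vapply(seq_len(n_prot), function(p) {
      paste(sample(aa, prot_len, replace = TRUE, prob = freq), collapse = "")
    }, "")
    names(sequences) <- sprintf("SYN%04d", seq_len(n_prot))

    put <- function(seqs, p, pos, res) {
      s <- seqs[[p]]
      substr(s, pos, pos) <- res
      seqs[[p]] <- s
      seqs
    }
    for (i in seq_len(n_sites)) {
      p <- site_protein[i]
      pos <- position[i]
      sequences <- put(sequences, p, pos, "S")
      if (motif_class[i] %in% c("classical", "extended")) {
        sequences <- put(sequences, p, pos - 5L, "R")
        sequences <- put(sequences, p, pos - 3L, "R")
        if (motif_class[i] == "extended") {
          sequences <- put(sequences, p, pos + 3L, "S")
        }
      } else if (regulated[i]) {
        # avoid accidental classical matches among non-motif regulated sites
        non_r <- setdiff(aa, "R")
        fr <- freq[match(non_r, aa)]
        while (substr(sequences[[p]], pos - 5L, pos - 5L) == "R" &&
               substr(sequences[[p]], pos - 3L, pos - 3L) == "R") {
          sequences <- put(sequences, p, pos - 3L,
                           sample(non_r, 1L, prob = fr))
        }
      }
    }

    sites <- tibble::tibble(
      protein_id = names(sequences)[site_protein],
      gene = sub("^SYN", "Gene", names(sequences)[site_protein]),
      position = position,
      residue = "S",
      regulated = regulated,
      motif_class = motif_class
    )
    list(sequences = sequences, sites = sites)
  })
}

#' Simulate a multiplexed phosphoproteomics ratio experiment
#'
#' Per site and sample, the observed log2 ratio is the site's true treatment
#' effect (0 for unregulated sites), plus the additive bias of the isotope
#' label carrying that treatment in that replicate, plus Gaussian noise.
#' Missing values are injected with probability
#' `plogis(-(abundance - missing_mu) / missing_s)` from a latent standard
#' normal abundance per site, i.e. preferentially at low abundance.
#' Localization probabilities are drawn so that a configured fraction falls
#' below 0.75.
#'
#' @param spec A [phospho_sim_spec()].
#' @param proteome Result of [simulate_proteome()] with the same spec.
#' @return A list with `table` (a [site_table()]) and `truth` (ground-truth
#'   tibble with one row per site: true effect per treatment, motif class,
#'   latent abundance).
#' @export
simulate_phospho_experiment <- function(spec, proteome) {
  stopifnot(inherits(spec, "phospho_sim_spec"))
  sites <- proteome$sites
  n <- nrow(sites)
  treatments <- names(spec$effects)

  samples <- purrr::map_dfr(seq_len(spec$n_replicates), function(r) {
    scheme <- spec$label_scheme[[r]]
    tibble::tibble(
      treatment = treatments,
      replicate = as.character(r),
      label = unname(scheme[treatments])
    )
  })
  samples$sample_id <- paste(samples$treatment, samples$replicate,
                             samples$label, sep = "_")

  with_seed_opt(spec$seed + 1L, {
    truth_effect <- matrix(0, n, length(treatments),
                           dimnames = list(NULL, treatments))
    for (tr in treatments) {
      truth_effect[sites$regulated, tr] <- spec$effects[[tr]]
    }
    abundance <- rnorm(n)
    loc_prob <- ifelse(runif(n) < spec$frac_nonlocalized,
                       runif(n, 0.2, 0.7499), runif(n, 0.75, 1))

    ratios <- matrix(NA_real_, n, nrow(samples),
                     dimnames = list(NULL, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      tr <- samples$treatment[j]
      off <- spec$label_offsets[[samples$label[j]]] %||% 0
      vals <- truth_effect[, tr] + off + rnorm(n, sd = spec$noise_sd)
      miss <- runif(n) < stats::plogis(-(abundance - spec$missing_mu) /
                                         spec$missing_s)
      vals[miss] <- NA_real_
      ratios[, j] <- vals
    }

    windows <- extract_windows(proteome$sequences,
                               sites[, c("protein_id", "position")])
    tbl <- tibble::tibble(
      protein_id = sites$protein_id, gene = sites$gene,
      position = sites$position, residue = sites$residue,
      loc_prob = loc_prob, window = windows$window
    )
    tbl <- dplyr::bind_cols(tbl, tibble::as_tibble(ratios))
    truth <- dplyr::bind_cols(
      sites,
      tibble::as_tibble(truth_effect) |>
        rlang::set_names(paste0("effect_", treatments)),
      tibble::tibble(abundance = abundance, loc_prob = loc_prob)
    )
    list(table = site_table(tbl, samples = samples), truth = truth)
  })
}
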