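# shared fixture builders (all data generated in code)

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# random 15-mer with a given centre residue
random_window <- function(centre = "S") {
  w <- sample(AA20, 15, replace = TRUE)
  w[8] <- centre
  paste(w, collapse = "")
}

random_windows <- function(n, centre = "S") {
  vapply(seq_len(n), function(i) random_window(centre), "")
}

# small site table with explicit ratios; samples parsed from column names
make_site_table <- function(n = 6, sample_ids = c("IGF_1_L", "IGF_2_M"),
                            seed = 1) {
  withr::with_seed(seed, {
    tbl <- tibble::tibble(
      protein_id = sprintf("P%02d", seq_len(n)),
      gene = sprintf("G%02d", seq_len(n)),
      position = sample(8:100, n),
      residue = sample(c("S", "T"), n, replace = TRUE),
      loc_prob = round(runif(n), 3),
      window = vapply(seq_len(n), function(i) random_window(), "")
    )
    tbl$window <- vapply(seq_len(n), function(i) {
      w <- strsplit(tbl$window[i], "")[[1]]
      w[8] <- tbl$residue[i]
      paste(w, collapse = "")
    }, "")
    for (sid in sample_ids) tbl[[sid]] <- round(rnorm(n), 4)
    site_table(tbl)
  })
}

# brute-force BH step-up: adj(i) = min over {j: p_j >= p_i} of p_j * m / rank_j
bh_oracle <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    cand <- which(p >= p[i] | seq_len(m) == i)
    min(1, min(p[cand] * m / r[cand]))
  }, 0)
}

# O(n^3) Ward agglomeration (Ward.D2 form: Lance-Williams on squared
# distances, merge criterion on the unsquared updated distance)
ward_oracle <- function(d0) {
  d2 <- as.matrix(d0)^2
  n <- nrow(d2)
  active <- seq_len(n)
  sizes <- rep(1, n)
  id <- -seq_len(n)          # hclust convention: negative = singleton
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA)
    best_d <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        dij <- sqrt(d2[active[ii], active[jj]])
        if (dij < best_d) {
          best_d <- dij
          best <- c(ii, jj)
        }
      }
    }
    i <- active[best[1]]; j <- active[best[2]]
    merges[step, ] <- sort(c(id[i], id[j]))
    heights[step] <- best_d
    ni <- sizes[i]; nj <- sizes[j]
    for (kk in active) {
      if (kk == i || kk == j) next
      nk <- sizes[kk]
      d2[i, kk] <- d2[kk, i] <-
        ((ni + nk) * d2[i, kk] + (nj + nk) * d2[j, kk] -
           nk * d2[i, j]) / (ni + nj + nk)
    }
    sizes[i] <- ni + nj
    id[i] <- step
    active <- setdiff(active, j)
  }
  list(merge = merges, height = heights)
}

# best-permutation accuracy of a clustering against planted labels
partition_accuracy <- function(assigned, truth) {
  labs_a <- unique(assigned)
  labs_t <- unique(truth)
  perms <- combinat_perms(labs_t)
  best <- 0
  for (p in perms) {
    mapped <- p[match(assigned, labs_a)]
    best <- max(best, mean(mapped == truth))
  }
  best
}

combinat_perms <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in combinat_perms(x[-i])) out <- c(out, list(c(x[i], rest)))
  }
  out
}

# leaves joined at each merge step, for comparing agglomeration traces
merge_leafsets <- function(merge) {
  n <- nrow(merge) + 1
  sets <- vector("list", nrow(merge))
  for (s in seq_len(nrow(merge))) {
    grab <- function(v) if (v < 0) -v else sets[[v]]
    sets[[s]] <- sort(c(grab(merge[s, 1]), grab(merge[s, 2])))
  }
  sets
}
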