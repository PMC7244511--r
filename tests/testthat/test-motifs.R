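test_that("window extraction pads past termini with underscores", {
  seqs <- c(P1 = "MKRSTAYLWQPDEFGHIKLM")
  w8 <- extract_windows(seqs, tibble::tibble(protein_id = "P1",
                                             position = 8L))
  expect_equal(nchar(w8$window), 15L)
  expect_equal(w8$window, unname(substr(seqs, 1, 15)))
  w3 <- extract_windows(seqs, tibble::tibble(protein_id = "P1",
                                             position = 3L))
  expect_equal(w3$window, paste0("_____", substr(seqs, 1, 10)))
  expect_error(
    extract_windows(seqs, tibble::tibble(protein_id = "P1", position = 99L)),
    "out of bounds.*P1"
  )
})

test_that("the filamin insert site yields its extended-motif window", {
  # a d20-like fragment holding the doubly phosphorylatable insert
  insert <- "TTHTVPRERLGSFGSITRQQA"
  seqs <- c(FLNC = insert)
  pos <- as.integer(regexpr("RERLGS", insert)) + 5L  # the first insert serine
  w <- extract_windows(seqs, tibble::tibble(protein_id = "FLNC",
                                            position = pos))
  expect_true(grepl("RERLGSFGS", w$window))
  expect_equal(substr(w$window, 8, 8), "S")
  expect_equal(annotate_basophilic(w$window, marks = list(c(8L, 11L))),
               "extended")
})

test_that("lowercase letters in plain-text windows mark phosphosites", {
  parsed <- parse_windows(c("AAAAAAAsAAAAAAA", "AAAAAAASAAtAAAA"))
  expect_equal(parsed$window, c("AAAAAAASAAAAAAA", "AAAAAAASAATAAAA"))
  expect_equal(parsed$marks, list(8L, 11L))
  path <- withr::local_tempfile()
  writeLines(c("RARAAAAsAAAAAAA", ""), path)
  expect_equal(nrow(read_windows(path)), 1)
})

test_that("basophilic annotation follows the positional rules", {
  base <- strsplit("AAAAAAASAAAAAAA", "")[[1]]
  mk <- function(edits) {
    w <- base
    for (nm in names(edits)) w[as.integer(nm)] <- edits[[nm]]
    paste(w, collapse = "")
  }
  classical <- mk(c("3" = "R", "5" = "R"))
  expect_equal(annotate_basophilic(classical, list(8L)), "classical")
  with_s3 <- mk(c("3" = "R", "5" = "R", "11" = "S"))
  expect_equal(annotate_basophilic(with_s3, list(8L)), "classical")
  expect_equal(annotate_basophilic(with_s3, list(c(8L, 11L))), "extended")
  no_r5 <- mk(c("5" = "R", "11" = "S"))
  expect_equal(annotate_basophilic(no_r5, list(c(8L, 11L))), "none")
  # '_' never matches, unmarked centre is none
  padded <- mk(c("3" = "_", "5" = "R"))
  expect_equal(annotate_basophilic(padded, list(8L)), "none")
  expect_equal(annotate_basophilic(classical, list(3L)), "none")
  expect_error(annotate_basophilic(mk(c("8" = "A")), list(8L)), "centre")
})

test_that("annotation agrees with a regex oracle on random windows", {
  withr::with_seed(17, {
    n <- 10000
    wins <- random_windows(n)
    # enrich arginines so the motif occurs
    wins <- vapply(wins, function(w) {
      ch <- strsplit(w, "")[[1]]
      ch[sample(c(3, 5), 1)] <- "R"
      if (runif(1) < 0.5) ch[c(3, 5)] <- "R"
      if (runif(1) < 0.5) ch[11] <- "S"
      paste(ch, collapse = "")
    }, "", USE.NAMES = FALSE)
    marks <- lapply(seq_len(n), function(i) {
      m <- 8L
      if (runif(1) < 0.5) m <- c(m, 11L)
      m
    })
  })
  got <- annotate_basophilic(wins, marks)
  oracle <- vapply(seq_len(n), function(i) {
    if (!grepl("^..R.R..[ST]", wins[i])) return("none")
    if (grepl("^..R.R..[ST]..[ST]", wins[i]) && 11L %in% marks[[i]]) {
      return("extended")
    }
    "classical"
  }, "")
  expect_equal(got, oracle)
})

test_that("a null foreground yields no motifs", {
  withr::with_seed(23, bg <- random_windows(2000))
  fg <- bg[1:500]
  res <- motifx_enrich(fg, bg, min_occurrence = 10, p_cutoff = 1e-6)
  expect_equal(nrow(res), 0)
})

test_that("a planted arginine motif is recovered as the sole motif", {
  withr::with_seed(29, {
    bg <- random_windows(500)
    fg <- vapply(1:200, function(i) {
      ch <- strsplit(random_window(), "")[[1]]
      ch[5] <- "R"    # offset -3
      paste(ch, collapse = "")
    }, "")
  })
  res <- motifx_enrich(fg, bg, min_occurrence = 10, p_cutoff = 1e-6)
  expect_equal(nrow(res), 1)
  expect_equal(res$fixed[[1]]$offset, -3L)
  expect_equal(res$fixed[[1]]$residue, "R")
  # fold enrichment within the 99% binomial envelope of 1/f(R) = 20
  bg_band <- qbinom(c(0.005, 0.995), 500, 0.05)
  fold_band <- (res$fg_matches / res$fg_size) /
    (rev(bg_band) / res$bg_size)
  expect_gte(res$fold_enrichment, fold_band[1])
  expect_lte(res$fold_enrichment, fold_band[2])
  # support and significance invariants
  expect_gte(res$fg_matches, 10)
  expect_true(all(res$step_p[[1]] < 1e-6))
})

test_that("the first fixing step uses the exact binomial tail", {
  withr::with_seed(31, {
    # background with exactly 5/100 R at offset -3
    bg <- random_windows(100)
    bg <- vapply(seq_along(bg), function(i) {
      ch <- strsplit(bg[i], "")[[1]]
      ch[5] <- if (i <= 5) "R" else sample(setdiff(AA20, "R"), 1)
      paste(ch, collapse = "")
    }, "")
    fg <- vapply(1:10, function(i) {
      ch <- strsplit(bg[sample(100, 1)], "")[[1]]
      ch[5] <- "R"
      paste(ch, collapse = "")
    }, "")
  })
  res <- motifx_enrich(fg, bg, min_occurrence = 10, p_cutoff = 1e-6)
  hit <- which(vapply(res$fixed, function(f) {
    any(f$offset == -3 & f$residue == "R")
  }, TRUE))
  expect_length(hit, 1)
  # P(X >= 10 | n = 10, p = 0.05) = 0.05^10
  expect_equal(res$step_p[[hit]][1], 0.05^10, tolerance = 1e-12)
})

test_that("motif search is deterministic and makes progress", {
  withr::with_seed(37, {
    bg <- random_windows(600)
    fg <- c(
      vapply(1:60, function(i) {
        ch <- strsplit(random_window(), "")[[1]]
        ch[c(3, 5)] <- "R"
        paste(ch, collapse = "")
      }, ""),
      vapply(1:60, function(i) {
        ch <- strsplit(random_window(), "")[[1]]
        ch[9] <- "P"
        paste(ch, collapse = "")
      }, ""),
      random_windows(80)
    )
  })
  res1 <- motifx_enrich(fg, bg, min_occurrence = 10, p_cutoff = 1e-6)
  res2 <- motifx_enrich(fg, bg, min_occurrence = 10, p_cutoff = 1e-6)
  expect_identical(res1, res2)
  expect_gt(nrow(res1), 1)
  expect_false(any(duplicated(res1$pattern)))
  expect_true(all(res1$fg_matches >= 10))
  expect_true(all(unlist(res1$step_p) < 1e-6))
})

test_that("three-set overlaps match direct set algebra", {
  d <- group_peptides(c("a", "b"), c("c", "d", "e"), c("f", "g", "h", "i"))
  expect_equal(unlist(d[c("n12", "n13", "n23", "n123")]),
               c(n12 = 0, n13 = 0, n23 = 0, n123 = 0))
  s <- group_peptides(letters[1:4], letters[1:4], letters[1:4])
  expect_true(all(unlist(s) == 4))
  withr::with_seed(41, {
    g1 <- sample(letters, 10); g2 <- sample(letters, 12)
    g3 <- sample(letters, 8)
  })
  got <- group_peptides(g1, g2, g3)
  expect_equal(got$n12, length(intersect(g1, g2)))
  expect_equal(got$n123, length(Reduce(intersect, list(g1, g2, g3))))
})
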