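test_that("imputation touches only missing entries and honours the seed", {
  withr::with_seed(3, m <- matrix(rnorm(60), 20, 3))
  expect_identical(impute_missing(m, seed = 1), m)   # nothing missing
  m_na <- m
  m_na[c(1, 5, 25, 41)] <- NA
  out1 <- impute_missing(m_na, seed = 1)
  out2 <- impute_missing(m_na, seed = 1)
  expect_identical(out1, out2)
  obs <- !is.na(m_na)
  expect_identical(out1[obs], m_na[obs])   # observed entries bit-exact
  expect_false(anyNA(out1))
})

test_that("width zero collapses the imputation to mu - 2 sigma", {
  withr::with_seed(4, m <- matrix(rnorm(40, mean = 2), 20, 2))
  m[c(1, 3)] <- NA
  m[22] <- NA
  out <- impute_missing(m, downshift = 2, width = 0, seed = 9)
  mu1 <- mean(m[, 1], na.rm = TRUE); s1 <- sd(m[, 1], na.rm = TRUE)
  mu2 <- mean(m[, 2], na.rm = TRUE); s2 <- sd(m[, 2], na.rm = TRUE)
  expect_equal(out[c(1, 3)], rep(mu1 - 2 * s1, 2))
  expect_equal(out[22], mu2 - 2 * s2)
})

test_that("imputed values match the downshifted-normal moments", {
  withr::with_seed(5, {
    col <- rnorm(400, mean = 1, sd = 2)
    m <- cbind(c(col, rep(NA, 10000)), rnorm(10400))
  })
  out <- impute_missing(m, downshift = 2, width = 0.3, seed = 11)
  mu <- mean(col); sigma <- sd(col)
  imp <- out[401:10400, 1]
  expect_lt(abs(mean(imp) - (mu - 2 * sigma)),
            3 * 0.3 * sigma / sqrt(10000))
  expect_lt(abs(sd(imp) - 0.3 * sigma) / (0.3 * sigma), 0.03)
})

test_that("fully missing columns are refused by name", {
  m <- cbind(a = c(1, 2, 3), b = NA_real_)
  expect_error(impute_missing(m), "fully missing.*b")
})

test_that("fold-change filtering matches a brute-force row filter", {
  m1 <- rbind(c(0.5, -0.58), c(0.59, 0.1))
  p1 <- rbind(c(0.001, 0.001), c(0.04, 0.9))
  got <- filter_min_fc(m1, p1, threshold = 0.58, alpha = 0.05)
  expect_equal(nrow(got), 1)          # |entries| <= 0.58 everywhere -> out
  expect_equal(got[1, ], m1[2, ])     # 0.59 with adj p 0.04 -> kept
  withr::with_seed(6, {
    m <- matrix(rnorm(200, sd = 0.5), 50, 4)
    p <- matrix(runif(200), 50, 4)
  })
  alpha <- c(0.05, 0.05, 0.01, 0.01)
  got <- filter_min_fc(m, p, threshold = 0.58, alpha = alpha)
  keep <- vapply(seq_len(nrow(m)), function(i) {
    any(abs(m[i, ]) > 0.58 & p[i, ] < alpha)
  }, TRUE)
  expect_equal(got, m[keep, , drop = FALSE])
})

test_that("correlation distance drives the merge order", {
  m <- rbind(a = c(1, 2, 3, 4),
             b = c(2, 4, 6, 8) + 1,    # positive affine image of a
             c = c(4, 3, 2, 1),        # anti-correlated
             d = c(1.1, 2.2, 2.9, 4.3))
  cl <- hier_cluster(m, k = 2)
  d_ab <- 1 - cor(m["a", ], m["b", ])
  expect_equal(d_ab, 0, tolerance = 1e-12)
  first <- merge_leafsets(cl$tree$merge)[[1]]
  expect_equal(first, c(1, 2))       # zero-distance pair merges first
  expect_equal(1 - cor(m["a", ], m["c", ]), 2)
  last <- merge_leafsets(cl$tree$merge)[[3]]
  expect_true(3 %in% last)            # the anti-correlated row joins last
  expect_equal(cl$assignment$cluster[1], cl$assignment$cluster[2])
  expect_error(hier_cluster(rbind(m, e = c(1, 1, 1, 1)), 2), "constant.*e")
})

test_that("Ward merges equal an O(n^3) Lance-Williams oracle", {
  withr::with_seed(7, {
    for (trial in 1:5) {
      m <- matrix(rnorm(24), 6, 4)
      cl <- hier_cluster(m, k = 3)
      oracle <- ward_oracle(as.dist(1 - cor(t(m))))
      expect_equal(merge_leafsets(cl$tree$merge),
                   merge_leafsets(oracle$merge))
      expect_equal(cl$tree$height, oracle$height, tolerance = 1e-10)
    }
  })
})

test_that("clustering is invariant to row order up to relabelling", {
  withr::with_seed(8, m <- matrix(rnorm(40), 10, 4))
  rownames(m) <- paste0("r", 1:10)
  cl1 <- hier_cluster(m, k = 3)
  perm <- sample(10)
  cl2 <- hier_cluster(m[perm, ], k = 3)
  a1 <- cl1$assignment$cluster[match(rownames(m), cl1$assignment$row_id)]
  a2 <- cl2$assignment$cluster[match(rownames(m), cl2$assignment$row_id)]
  expect_equal(partition_accuracy(a2, a1), 1)
})

test_that("row-wise z-scores accompany the assignment", {
  withr::with_seed(9, m <- matrix(rnorm(40), 10, 4))
  cl <- hier_cluster(m, k = 2)
  expect_equal(unname(rowMeans(cl$zscores)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(cl$zscores, 1, sd)), rep(1, 10),
               tolerance = 1e-12)
})

test_that("two-stage clustering recovers planted profile groups", {
  # a coherent background profile plus one downregulated supercluster
  # holding 4 subprofiles; signal-to-noise 3 per condition
  withr::with_seed(10, {
    sd_n <- 1 / 3
    profiles <- list(c(-1, -1, 1.2, 0, 0, 0), c(-1, -1, 0, 1.2, 0, 0),
                     c(-1, -1, 0, 0, 1.2, 0), c(-1, -1, 0, 0, 0, 1.2))
    reg <- do.call(rbind, lapply(1:4, function(g) {
      matrix(rep(profiles[[g]], each = 30), 30, 6)
    })) + rnorm(120 * 6, sd = sd_n)
    bg <- matrix(rep(c(1, 1, 0, 0, 0, 0), each = 200), 200, 6) +
      rnorm(200 * 6, sd = sd_n)
    m <- rbind(reg, bg)
    rownames(m) <- c(paste0("reg", 1:120), paste0("bg", 1:200))
    truth_sub <- rep(1:4, each = 30)
  })
  stage1 <- hier_cluster(m, k = 2)
  reg_cluster <- stage1$assignment$cluster[1]
  stage1_rows <- stage1$assignment$row_id[
    stage1$assignment$cluster == reg_cluster]
  expect_gte(mean(grepl("^reg", stage1_rows)), 0.9)
  stage2 <- hier_cluster(m[intersect(stage1_rows, rownames(m)[1:120]), ],
                         k = 4)
  acc <- partition_accuracy(
    stage2$assignment$cluster,
    truth_sub[match(stage2$assignment$row_id, rownames(m))]
  )
  expect_gte(acc, 0.9)
})

test_that("proximity filtering needs three ratios per replicate cell", {
  d <- tidyr::crossing(protein_id = c("A", "B"),
                       replicate = c("r1", "r2"),
                       control = c("c1", "c2"),
                       obs = 1:3) |>
    dplyr::mutate(log10_ratio = 1)
  d$log10_ratio[d$protein_id == "B" & d$replicate == "r1" & d$obs == 3] <- NA
  got <- suppressWarnings(proximity_enrich(d, k = 1, seed = 1))
  expect_equal(got$proteins$protein_id, "A")
  expect_equal(got$dropped, "B")
  expect_error(proximity_enrich(d, k = 5, seed = 1), "exceeds")
})

test_that("planted blobs are recovered and the doubly-high group enriched", {
  withr::with_seed(12, {
    centers <- rbind(c(1.5, 1.5), c(-1, 0.5), c(0.5, -1))
    rows <- purrr::map_dfr(1:30, function(i) {
      g <- ((i - 1) %% 3) + 1
      tidyr::crossing(replicate = c("r1", "r2"), control = c("c1", "c2"),
                      obs = 1:3) |>
        dplyr::mutate(
          protein_id = sprintf("P%02d", i),
          log10_ratio = centers[g, match(control, c("c1", "c2"))] +
            rnorm(dplyr::n(), sd = 0.1),
          truth = g
        )
    })
  })
  got <- proximity_enrich(rows, k = 3, seed = 4)
  truth <- ((seq_len(30) - 1) %% 3) + 1   # planted group of P01..P30
  assigned <- got$proteins$cluster[match(sprintf("P%02d", 1:30),
                                         got$proteins$protein_id)]
  expect_equal(partition_accuracy(assigned, truth), 1)
  enriched_truth <- got$proteins$protein_id[got$proteins$enriched]
  expect_setequal(enriched_truth, sprintf("P%02d", seq(1, 30, by = 3)))
})

test_that("identical proteins collapse to one deterministic group", {
  d <- tidyr::crossing(protein_id = sprintf("P%d", 1:5),
                       replicate = "r1", control = c("c1", "c2"),
                       obs = 1:3) |>
    dplyr::mutate(log10_ratio = 2)
  expect_warning(got <- proximity_enrich(d, k = 3, seed = 1), "distinct")
  expect_equal(length(unique(got$proteins$cluster)), 1)
  expect_true(all(got$proteins$enriched))
  got2 <- suppressWarnings(proximity_enrich(d, k = 3, seed = 1))
  expect_identical(got$proteins, got2$proteins)
})
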