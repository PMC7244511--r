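test_that("variance moderation averages with the median", {
  expect_equal(as.numeric(moderate_variances(c(1, 2, 3))), c(1.5, 2, 2.5))
  expect_equal(as.numeric(moderate_variances(rep(0.7, 5))), rep(0.7, 5))
  withr::with_seed(1, s2 <- rchisq(10000, 3))
  out <- moderate_variances(s2)
  expect_equal(mean(out), (mean(s2) + median(s2)) / 2, tolerance = 1e-12)
  # exact affine relation to the median, and rank preservation
  expect_equal(as.numeric(out) - median(s2), (s2 - median(s2)) / 2)
  expect_equal(cor(s2, as.numeric(out), method = "spearman"), 1)
  # undefined variances take the median and are flagged
  mixed <- moderate_variances(c(1, NA, 3))
  expect_equal(as.numeric(mixed), c(1.5, 2, 2.5))
  expect_equal(attr(mixed, "imputed"), c(FALSE, TRUE, FALSE))
  expect_error(moderate_variances(numeric()), "empty")
})

test_that("BH adjustment matches the step-up oracle and its properties", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(5, {
    for (i in 1:20) {
      p <- runif(sample(3:40, 1))^sample(1:3, 1)
      adj <- bh_adjust(p)
      expect_equal(adj, bh_oracle(p))
      expect_gte(min(adj - p), 0)                   # adjusted >= raw
      expect_true(all(diff(adj[order(p)]) >= 0))    # monotone in rank
    }
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("OLS reduces to the mean in a balanced single-label design", {
  tbl <- site_table(tibble::tibble(
    protein_id = "P1", gene = "G1", position = 10L, residue = "S",
    loc_prob = 0.99, window = "AAAAAAASAAAAAAA",
    IGF_1_L = 0.5, IGF_2_L = 0.7, IGF_3_L = 0.6
  ))
  fit <- fit_ratio_model(tbl)
  expect_equal(fit$estimate, 0.6)
  expect_equal(fit$df, 2L)
  expect_equal(fit$s2, var(c(0.5, 0.7, 0.6)))
})

test_that("per-site estimates equal the normal-equations oracle", {
  withr::with_seed(13, {
    spec <- phospho_sim_spec(n_proteins = 4, n_sites = 20,
                             n_replicates = 4, missing_mu = -30, seed = 13)
    sim <- simulate_phospho_experiment(spec, simulate_proteome(spec))
  })
  fits <- fit_ratio_model(sim$table)
  samples <- sample_info(sim$table)
  # oracle design: IGF, LY indicators plus non-reference label columns
  labs <- sort(unique(samples$label))
  X <- cbind(IGF = as.numeric(samples$treatment == "IGF"),
             LY = as.numeric(samples$treatment == "LY"))
  for (lb in labs[-1]) {
    X <- cbind(X, as.numeric(samples$label == lb))
  }
  Y <- site_ratios(sim$table)
  for (i in seq_len(nrow(Y))) {
    beta <- solve(t(X) %*% X, t(X) %*% Y[i, ])
    res <- Y[i, ] - X %*% beta
    s2 <- sum(res^2) / (nrow(X) - ncol(X))
    f_igf <- fits[fits$contrast == "IGF", ][i, ]
    expect_equal(f_igf$estimate, beta[1], tolerance = 1e-10)
    expect_equal(f_igf$s2, s2, tolerance = 1e-10)
  }
})

test_that("sites with too few observations are untestable, not dropped", {
  tbl <- make_site_table(n = 4, sample_ids = c("IGF_1_L", "IGF_2_M",
                                               "IGF_3_H"), seed = 2)
  tbl$IGF_2_M[1] <- NA
  tbl$IGF_3_H[1] <- NA    # one observation left
  tbl$IGF_1_L[2] <- NA
  tbl$IGF_2_M[2] <- NA
  tbl$IGF_3_H[2] <- NA    # nothing left
  fits <- fit_ratio_model(tbl)
  expect_equal(nrow(fits), 4)
  expect_false(any(fits$testable[1:2]))
  expect_true(all(is.na(fits$p_value[1:2])))
  expect_error(fit_ratio_model(tbl, contrasts = "MK"), "contrast")
})

test_that("the moderated test is calibrated under the null", {
  spec <- phospho_sim_spec(n_proteins = 250, n_sites = 1000,
                           fraction_regulated = 0, missing_mu = -30,
                           frac_nonlocalized = 0, seed = 21)
  sim <- simulate_phospho_experiment(spec, simulate_proteome(spec))
  f <- subset(fit_ratio_model(sim$table), contrast == "IGF" & testable)
  rate <- mean(f$p_value < 0.05)
  se2 <- 2 * sqrt(0.05 * 0.95 / nrow(f))
  expect_lt(abs(rate - 0.05), se2 + 0.01)
  # BH-adjusted rejections under the null stay within the FDR budget
  expect_lte(mean(f$p_adjust < 0.05), 0.05 + se2)
})

test_that("moderation beats the per-site t test at matched seeds", {
  spec <- phospho_sim_spec(n_proteins = 300, n_sites = 1500,
                           fraction_regulated = 0.5,
                           effects = c(IGF = 0.6, LY = -0.6),
                           noise_sd = 0.3, missing_mu = -30,
                           frac_nonlocalized = 0, seed = 22)
  sim <- simulate_phospho_experiment(spec, simulate_proteome(spec))
  mod <- subset(fit_ratio_model(sim$table), contrast == "IGF")
  unm <- subset(fit_ratio_model(sim$table, p_method = "t"), contrast == "IGF")
  # plain per-site t: same estimate and design, raw variance in place of
  # the moderated one (t_mod * sqrt(s2_mod / s2) undoes the moderation)
  t_raw <- unm$t * sqrt(unm$s2_mod / unm$s2)
  p_raw <- 2 * pt(-abs(t_raw), unm$df)
  truth <- sim$truth$regulated[match(paste(mod$protein_id, mod$position),
                                     paste(sim$truth$protein_id,
                                           sim$truth$position))]
  power_mod <- mean(mod$p_value[truth] < 0.05, na.rm = TRUE)
  power_raw <- mean(p_raw[truth] < 0.05, na.rm = TRUE)
  expect_gt(power_mod, power_raw)
})

test_that("regulation calls apply the fold-change and significance gates", {
  fits <- tibble::tibble(
    estimate = c(0.60, 0.50, -0.70, 0.9, NA),
    p_value = c(0.04, 0.001, 0.01, 0.2, NA),
    p_adjust = c(0.04, 0.001, 0.01, 0.2, NA)
  )
  called <- call_regulated(fits, fc_min = 1.5, alpha = 0.05)
  expect_equal(as.character(called$regulation),
               c("up", "none", "down", "none", "untestable"))
  # brute-force filter oracle on a simulated fit table
  spec <- phospho_sim_spec(n_proteins = 50, n_sites = 200, seed = 30)
  sim <- simulate_phospho_experiment(spec, simulate_proteome(spec))
  f <- call_regulated(fit_ratio_model(sim$table), fc_min = 1.5,
                      alpha = 0.05)
  oracle <- ifelse(is.na(f$p_adjust), "untestable",
            ifelse(f$estimate >= log2(1.5) & f$p_adjust < 0.05, "up",
            ifelse(f$estimate <= -log2(1.5) & f$p_adjust < 0.05, "down",
                   "none")))
  expect_equal(as.character(f$regulation), oracle)
})

test_that("localization partitioning uses the inclusive 0.75 boundary", {
  tbl <- make_site_table(n = 4, seed = 3)
  tbl$loc_prob <- c(0.75, 0.7499, NA, 0.9)
  parts <- filter_localized(site_table(tbl))
  expect_equal(parts$localized$loc_prob, c(0.75, 0.9))
  expect_equal(nrow(parts$localized) + nrow(parts$putative), 4)
  expect_true(all(is.na(parts$putative$loc_prob) |
                    parts$putative$loc_prob < 0.75))
})
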