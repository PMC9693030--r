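test_that("regional summaries match hand-computed statistics", {
  lobes <- array(0L, c(8, 8, 8)); lobes[2:7, 2:7, 2:7] <- 1L
  lobes[2:7, 2:7, 2] <- 2L; lobes[2, 2, 3] <- 3L; lobes[3, 2, 3] <- 4L
  lobes[4, 2, 3] <- 5L
  # constant map: mean = c, sd = 0, rms = |c|, entropy = 0
  cmap <- lm_volume(array(2.5, c(8, 8, 8)))
  s <- region_summary(cmap, lobes, "RUL", "J")
  expect_equal(s$mean, 2.5); expect_equal(s$std, 0)
  expect_equal(s$rms, 2.5); expect_equal(s$entropy, 0)
  # values {1, 3} equally: mean 2, rms sqrt(5)
  m2 <- lm_volume(array(0, c(8, 8, 8)))
  sel <- which(lobes == 2)
  m2$data[sel] <- rep(c(1, 3), length.out = length(sel))
  s2 <- region_summary(m2, lobes, "RML", "J")
  expect_equal(s2$mean, 2)
  expect_equal(s2$rms, sqrt(5))
  # rms^2 = mean^2 + population variance (internal consistency)
  n <- s2$n_valid
  expect_equal(s2$rms^2, s2$mean^2 + s2$std^2 * (n - 1) / n, tolerance = 1e-12)
  # uniform histogram over all 64 bins: entropy = 6 bits
  vals <- (seq_len(64) - 0.5) / 64 * 4
  expect_equal(shannon_entropy(rep(vals, 3), c(0, 4), 64L), 6)
  expect_lte(shannon_entropy(stats::runif(1000, 0, 4), c(0, 4), 64L), 6)
  # empty region errors
  empty_map <- lm_volume(array(NA_real_, c(8, 8, 8)))
  expect_error(region_summary(empty_map, lobes, "LUNG", "J"), "valid")
})

test_that("stage trends are classified correctly with Spearman effect size", {
  tab <- data.frame(stage = rep(0:4, each = 3),
                    region = "LUNG", measure = "J_mean",
                    value = rep(c(1.8, 1.6, 1.4, 1.2, 1.05), each = 3) +
                      rep(c(-0.01, 0, 0.01), 5))
  tr <- stage_trend(tab, "J_mean")
  expect_equal(tr$direction, "decreasing")
  expect_lt(tr$spearman_rho, 0)
  expect_equal(unname(tr$group_means), c(1.8, 1.6, 1.4, 1.2, 1.05),
               tolerance = 1e-12)
  # identical groups: no trend, rho = 0
  tab2 <- tab; tab2$value <- 1
  tr2 <- stage_trend(tab2, "J_mean")
  expect_equal(tr2$direction, "none")
  expect_equal(tr2$spearman_rho, 0)
  expect_error(stage_trend(tab[tab$stage == 0, ], "J_mean"), "two stage")
})

test_that("trend detection power is high under the cohort design conditions", {
  rate <- trend_detection_rate(n_sims = 100, n_per_stage = 10,
                               stage_means = c(1.8, 1.6, 1.4, 1.2, 1.05),
                               noise_sd = 0.05, seed = 11)
  expect_gte(rate, 0.95)
})

test_that("Bland-Altman limits follow the 1.96 SD convention", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 4)
  ba <- bland_altman(x, y)
  expect_equal(ba$mean_diff, 0); expect_equal(ba$sd_diff, 0)
  expect_equal(ba$loa_low, 0); expect_equal(ba$loa_high, 0)
  # constant difference 0.2: limits collapse onto the mean difference
  ba2 <- bland_altman(x + 0.2, x)
  expect_equal(ba2$mean_diff, 0.2)
  expect_equal(ba2$loa_low, 0.2); expect_equal(ba2$loa_high, 0.2)
  # Gaussian differences: ~95% of points inside the limits
  set.seed(13)
  d <- stats::rnorm(10000, 0, 0.3)
  ba3 <- bland_altman(d, rep(0, 10000))
  frac_in <- mean(ba3$diffs >= ba3$loa_low & ba3$diffs <= ba3$loa_high)
  expect_gt(frac_in, 0.94); expect_lt(frac_in, 0.96)
  # antisymmetry: swapping methods negates the mean and swaps/negates limits
  set.seed(14)
  a <- stats::rnorm(50, 1.4, 0.1); b <- stats::rnorm(50, 1.5, 0.1)
  f <- bland_altman(a, b); r <- bland_altman(b, a)
  expect_equal(f$mean_diff, -r$mean_diff)
  expect_equal(f$loa_low, -r$loa_high)
  expect_equal(f$loa_high, -r$loa_low)
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("cohort analysis emits the full measurement table and trend reports", {
  co <- make_cohort(2, c(1.6, 1.2), noise_sd = 0.02, seed = 3,
                    shape = c(48, 48, 48), images = FALSE)
  res <- cohort_run(co, methods = "oracle")
  # 2 stages x 2 subjects x 6 regions x 6 measures
  expect_equal(nrow(res$table), 2 * 2 * 6 * 6)
  expect_setequal(unique(res$table$region),
                  c("LUNG", "RUL", "RML", "RLL", "LUL", "LLL"))
  expect_setequal(unique(res$table$measure),
                  c("J_mean", "J_std", "J_entropy", "J_rms", "ADI_mean",
                    "SRI_entropy"))
  expect_equal(nrow(res$exclusions), 0)
  tr <- res$trends[["oracle.J_mean"]]
  expect_equal(tr$direction, "decreasing")
  # identical methods collapse Bland-Altman limits to zero width
  co2 <- lapply(co, function(s) { s$external_dvfs <- list(dup = s$true_dvf); s })
  res2 <- cohort_run(co2, methods = c("oracle", "dup"))
  ba <- res2$bland_altman[["oracle_vs_dup"]]
  expect_equal(ba$mean_diff, 0, tolerance = 1e-12)
  expect_equal(ba$loa_high - ba$loa_low, 0, tolerance = 1e-12)
})

test_that("failed subjects are excluded with a reason and the run continues", {
  co <- make_cohort(1, c(1.6, 1.2), noise_sd = 0, seed = 3,
                    shape = c(48, 48, 48), images = FALSE)
  co[[1]]$true_dvf <- NULL # break one subject
  res <- cohort_run(co, methods = "oracle")
  expect_equal(nrow(res$exclusions), 1)
  expect_equal(res$exclusions$subject_id, co[[1]]$id)
  expect_equal(length(unique(res$table$subject_id)), 1)
})
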