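test_that("peak finding locates strict local maxima", {
  mono <- tibble::tibble(time = 0:10, host_total = (0:10) * 1e4)
  expect_equal(nrow(find_host_peaks(mono)), 0)

  d <- tibble::tibble(time = 0:4, host_total = c(1, 3, 2, 5, 4) * 1e5)
  pk <- find_host_peaks(d, min_prominence = 0, min_separation = 0)
  expect_equal(pk$time, c(1, 3))
  expect_equal(pk$value, c(3e5, 5e5))

  # sampled sine: crests within one sample of the analytic maxima
  tt <- seq(0, 100, by = 0.5)
  sine <- tibble::tibble(time = tt, host_total = 1e5 * (2 + sin(tt / 4)))
  pk <- find_host_peaks(sine, min_prominence = 1e4, min_separation = 10)
  crests <- 4 * (pi / 2 + 2 * pi * (0:3))
  crests <- crests[crests <= 100]
  expect_equal(nrow(pk), length(crests))
  expect_true(all(abs(pk$time - crests) <= 0.5 + 1e-9))
})

test_that("peak prominence and separation filters apply", {
  # a small bump riding on a large peak is filtered by prominence
  d <- tibble::tibble(
    time = 0:8,
    host_total = c(0, 5, 1, 1.2, 1, 8, 2, 2.1, 0) * 1e4)
  all_pk <- find_host_peaks(d, min_prominence = 0, min_separation = 0)
  expect_equal(all_pk$time, c(1, 3, 5, 7))
  prom_pk <- find_host_peaks(d, min_prominence = 3e4, min_separation = 0)
  expect_equal(prom_pk$time, c(1, 5))
  # separation keeps the higher of two close peaks
  close_pk <- find_host_peaks(d, min_prominence = 0, min_separation = 3)
  expect_true(5 %in% close_pk$time)
  expect_false(7 %in% close_pk$time)
})

test_that("window medians summarize the final 500 hours", {
  expect_equal(window_median(1:600, rep(7, 600), t_end = 600), 7)
  expect_equal(window_median(1:1000, rep(c(0, 1), 500), t_end = 1000), 0.5)
  # linear ramp: median over the window is its midpoint value
  tt <- seq(0, 1000, by = 1)
  expect_equal(window_median(tt, tt * 2, t_end = 1000), 1501)
  expect_warning(out <- window_median(1:400, 1:400, t_end = 1000),
                 "undefined")
  expect_true(is.na(out))
})

test_that("stability requires a long run strictly above threshold", {
  expect_true(is_stable(0:200, rep(3.2e5, 201)))
  expect_false(is_stable(0:50, rep(3.2e5, 51)))
  # exactly at the threshold never counts (strict inequality)
  expect_false(is_stable(0:200, rep(3e5, 201)))
  # interior dips break the series into sub-threshold-length runs
  v <- rep(3.2e5, 201)
  v[c(51, 151)] <- 2.9e5 # runs of 49 h, 98 h, 49 h
  expect_false(is_stable(0:200, v))
  # monotone: raising a value never flips stable to unstable
  v2 <- v
  v2[51] <- 3.3e5 # first run now spans 149 h
  expect_true(is_stable(0:200, v2))
})

test_that("outcome classification partitions replicates", {
  # locus cannot fill without acquisition: completed but unfilled
  unfilled <- summarize_replicate(
    simulate_coevolution(sim_params(q = 0, mu = 0, t_end = 200), seed = 1),
    window = 100)
  # without adsorption the virus decays out: viral extinction
  extinct <- summarize_replicate(
    simulate_coevolution(sim_params(phi = 0, t_end = 300), seed = 1),
    window = 100)
  both <- dplyr::bind_rows(unfilled, extinct)
  cls <- classify_outcomes(both)
  expect_equal(sum(cls$n), 2L)
  expect_equal(cls$n[cls$class == "unfilled_locus"], 1L)
  expect_equal(cls$n[cls$class == "viral_extinction"], 1L)
  # the pre-fill extinction is excluded from population averages
  expect_equal(cls$excluded[cls$class == "viral_extinction"], 1L)
})

test_that("Spearman tables recover monotone relationships", {
  d <- data.frame(x = 1:20, up = (1:20)^2, down = -(1:20), flat = 1)
  tab <- spearman_table(d, "x", c("up", "down", "flat"))
  expect_equal(tab$rho[tab$y == "up"], 1)
  expect_equal(tab$rho[tab$y == "down"], -1)
  expect_true(is.na(tab$rho[tab$y == "flat"]))
})

test_that("AIC comparison picks the generating model", {
  lin <- data.frame(x = 1:12, y = 3 + 2 * (1:12) + rnorm(12, sd = 1e-8))
  fit <- linear_vs_quadratic_aic(lin, x, y)
  expect_equal(fit$choice, "linear")

  par <- data.frame(x = seq(-3, 3, 0.5))
  par$y <- 1 + (par$x - 0.5)^2
  fitq <- linear_vs_quadratic_aic(par, x, y)
  expect_equal(fitq$choice, "quadratic")
  expect_lt(fitq$aic_quadratic, fitq$aic_linear)

  # noisy unimodal data, fixed seed; cross-check the decision against the
  # RSS computed directly and against R's AIC difference
  set.seed(42)
  nz <- data.frame(x = runif(40, -2, 2))
  nz$y <- 2 - (nz$x)^2 + rnorm(40, sd = 0.3)
  fitn <- linear_vs_quadratic_aic(nz, x, y)
  expect_equal(fitn$choice, "quadratic")
  rss_lin <- sum(resid(lm(y ~ x, nz))^2)
  expect_equal(tidy(fitn)$rss[1], rss_lin, tolerance = 1e-10)
  aic_r <- AIC(lm(y ~ x + I(x^2), nz)) - AIC(lm(y ~ x, nz))
  expect_equal(fitn$delta_aic, aic_r, tolerance = 1e-8)

  expect_error(linear_vs_quadratic_aic(data.frame(x = 1:3, y = 1:3), x, y),
               "at least 4")
  expect_error(
    linear_vs_quadratic_aic(data.frame(x = rep(1, 9), y = 1:9), x, y),
    "degenerate")
})

test_that("unbalanced ANOVA behaves at the extremes", {
  same <- data.frame(g = rep(c("a", "b", "c"), times = c(3, 4, 5)),
                     v = c(1, 2, 3, 1, 2, 3, 2, 1, 2, 3, 1, 2))
  res <- unbalanced_anova_pairwise(same, v, g)
  expect_gt(glance(res)$p_value, 0.5)

  apart <- data.frame(g = rep(c("a", "b"), c(3, 5)),
                      v = c(rep(0, 3), rep(10, 5)))
  # zero within-group variance: the F test degenerates toward p = 0
  suppressWarnings(res2 <- unbalanced_anova_pairwise(apart, v, g))
  expect_lt(glance(res2)$p_value, 1e-10)

  tiny <- data.frame(g = rep(c("a", "b", "c"), c(4, 4, 1)),
                     v = c(rnorm(8), 5))
  expect_warning(res3 <- unbalanced_anova_pairwise(tiny, v, g),
                 "excluding")
  expect_equal(glance(res3)$n_groups, 2L)
})

test_that("ANOVA type-I error is calibrated under the null", {
  set.seed(7)
  rejections <- 0L
  trials <- 1000L
  for (i in seq_len(trials)) {
    d <- data.frame(g = rep(c("a", "b", "c"), times = c(6, 9, 12)),
                    v = rnorm(27))
    if (glance(unbalanced_anova_pairwise(d, v, g))$p_value < 0.05) {
      rejections <- rejections + 1L
    }
  }
  # binomial(1000, 0.05): 3 SE band around 50
  expect_gt(rejections, 50 - 3 * sqrt(1000 * 0.05 * 0.95))
  expect_lt(rejections, 50 + 3 * sqrt(1000 * 0.05 * 0.95))
})

test_that("subsampling recovers direct and known proportions", {
  summaries <- tibble::tibble(
    median_pdi = c(rep(0.05, 40), rep(0.55, 60)),
    stable = c(rep(c(TRUE, FALSE), 20), rep(TRUE, 60)),
    outcome = rep(c("completed", "viral_extinction"), 50)
  )
  # one subsample of everything reproduces the direct proportions
  direct <- subsample_compare(summaries, n_sub = 100, reps = 1, seed = 1)
  expect_equal(direct$bins$mean_prop_stable,
               c(0.5, 1))
  expect_equal(direct$bins$mean_prop_extinct, c(0.5, 0.5))

  # homogeneous summaries give identical bin means in every subsample
  homo <- tibble::tibble(median_pdi = rep(0.05, 50),
                         stable = rep(TRUE, 50),
                         outcome = rep("completed", 50))
  hs <- subsample_compare(homo, n_sub = 20, reps = 5, seed = 1)
  expect_equal(nrow(hs$bins), 1L)
  expect_equal(hs$bins$mean_prop_stable, 1)

  # two-bin fixture: subsample means near the truth (binomial error)
  est <- subsample_compare(summaries, n_sub = 30, reps = 400, seed = 2)
  se <- sqrt(0.5 * 0.5 / 12) / sqrt(400) * 3
  expect_lt(abs(est$bins$mean_prop_stable[1] - 0.5), max(3 * se, 0.05))
  expect_error(subsample_compare(summaries, n_sub = 500, reps = 1),
               "exceeds")
})

test_that("replicate summaries expose window medians and peak PDI", {
  traj <- simulate_coevolution(sim_params(t_end = 300), seed = 31)
  s <- summarize_replicate(traj, window = 150)
  expect_equal(nrow(s), 1L)
  m <- trajectory_metrics(traj,
                          times = traj$totals$time[traj$totals$time > 150])
  expect_equal(s$median_pdi, median(m$pdi))
  expect_equal(s$median_hvi, median(m$hvi))
  pk <- s$peaks[[1]]
  if (nrow(pk) > 0) {
    # peak times are a subset of recorded times with PDI evaluated there
    expect_true(all(pk$time %in% traj$totals$time))
    full <- trajectory_metrics(traj, times = pk$time)
    expect_equal(pk$pdi, full$pdi)
  }
})

test_that("run_sweep fans out conditions deterministically", {
  grid <- tibble::tibble(P = c(5, 10))
  sw <- run_sweep(grid, replicates = 2,
                  base_params = sim_params(t_end = 60), seed = 5,
                  window = 30)
  expect_equal(nrow(sw), 4L)
  expect_equal(sw$P, c(5L, 5L, 10L, 10L))
  sw2 <- run_sweep(grid, replicates = 2,
                   base_params = sim_params(t_end = 60), seed = 5,
                   window = 30)
  expect_equal(sw$median_pdi, sw2$median_pdi)
  expect_error(run_sweep(tibble::tibble(bogus = 1), replicates = 1),
               "unknown parameter")
})
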