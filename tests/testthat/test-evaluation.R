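test_that("bias, MAE and RMSE behave as signed, absolute and quadratic means", {
  th <- c(-1, 0, 1, 2)
  expect_equal(bias(th, th), 0)
  expect_equal(bias(th + 0.5, th), 0.5)
  expect_equal(bias(th + c(1, -1, 1, -1), th), 0)
  expect_equal(mae(th + c(1, -1, 1, -1), th), 1)
  expect_equal(rmse(th + c(1, -1, 1, -1), th), 1)
  expect_equal(rmse(th - 0.3, th), 0.3)
  expect_equal(mae(th - 0.3, th), 0.3)
  expect_error(bias(1:3, 1:4), "equal-length")
  set.seed(1)
  for (rep in 1:20) {
    e <- rnorm(50)
    t0 <- rnorm(50)
    expect_gte(mae(t0 + e, t0), abs(bias(t0 + e, t0)))
    expect_gte(rmse(t0 + e, t0), mae(t0 + e, t0))
    # rmse^2 = bias^2 + variance of deviations (population variance)
    expect_equal(rmse(t0 + e, t0)^2,
                 bias(t0 + e, t0)^2 + mean((e - mean(e))^2),
                 tolerance = 1e-12)
  }
})

test_that("conditional statistics recombine to the overall values", {
  set.seed(2)
  admin <- data.frame(theta_true = runif(400, -3, 3))
  admin$theta_hat <- admin$theta_true + rnorm(400, 0, 0.3)
  admin$see <- runif(400, 0.25, 0.35)
  admin$n_items <- sample(10:30, 400, replace = TRUE)
  cs <- conditional_stats(admin)
  w <- cs$by_bin$n
  expect_equal(sum(w * cs$by_bin$cbias) / sum(w), cs$overall$bias)
  expect_equal(sqrt(sum(w * cs$by_bin$crmse^2) / sum(w)), cs$overall$rmse)
  expect_equal(sum(w), cs$overall$n)
  # all simulees in one bin: conditional equals overall
  one <- conditional_stats(admin, edges = c(-10, 10), open_ends = FALSE)
  expect_equal(nrow(one$by_bin), 1L)
  expect_equal(one$by_bin$cbias, cs$overall$bias)
  expect_equal(one$by_bin$crmse, cs$overall$rmse)
})

test_that("a sign-switching error field shows up in the bins but cancels overall", {
  th <- seq(-1.95, 1.95, length.out = 400)
  admin <- data.frame(theta_true = th,
                      theta_hat = th + ifelse(th < 0, 0.2, -0.2),
                      see = 0.3, n_items = 20)
  cs <- conditional_stats(admin, edges = c(-1, 0, 1), open_ends = TRUE)
  expect_equal(cs$overall$bias, 0, tolerance = 1e-12)
  expect_equal(cs$by_bin$cbias, c(0.2, 0.2, -0.2, -0.2))
  expect_equal(cs$by_bin$cmae, rep(0.2, 4))
})

test_that("empty bins are absent, not zero", {
  admin <- data.frame(theta_true = c(0.1, 0.2), theta_hat = c(0.1, 0.2),
                      see = 0.3, n_items = 10)
  cs <- conditional_stats(admin, edges = c(-2, -1, 0, 1, 2))
  expect_equal(as.character(cs$by_bin$bin), "[0,1)")
})

test_that("CSEM at a fixed theta is the replicate RMSE", {
  admin <- data.frame(theta_true = rep(-1, 6),
                      theta_hat = -1 + c(0.3, -0.3, 0.3, -0.3, 0.3, -0.3))
  expect_equal(csem_at_theta(admin), 0.3)
  exact <- data.frame(theta_true = rep(-1, 5), theta_hat = rep(-1, 5))
  expect_equal(csem_at_theta(exact), 0)
  mixed <- data.frame(theta_true = c(-1, 0), theta_hat = c(-1, 0))
  expect_error(csem_at_theta(mixed), "single true theta")
})

test_that("replicated fixed-length CAT at one theta ties the CSEM to the analytic SEE", {
  cfg <- cat_config(
    estimation = estimation_settings("MLEF"),
    termination = termination_settings("fixed_length", fixed_length = 25),
    n_simulees = 400L, pool_size = 150L,
    seeds = list(pool = 61L, simulees = 62L, responses = 63L,
                 selection = 64L))
  sm <- generate_simulees(400, dist_spec("constant", value = -1), seed = 62)
  sim <- run_simulation(cfg, simulees = sm)
  csem <- csem_at_theta(sim$admin)
  expect_equal(csem, mean(sim$admin$see), tolerance = 0.15)
})

test_that("the overlap index matches its closed-form anchors", {
  # all p examinees share one k-item form
  expect_equal(overlap_index(c(4, 4, 4), p = 4, k = 3), 1)
  # pairwise disjoint forms
  expect_equal(overlap_index(c(1, 1, 1, 1, 1, 1), p = 3, k = 2), 0)
  # three forms {1,2}, {1,3}, {2,3}
  expect_equal(overlap_index(c(2, 2, 2), p = 3, k = 2), 0.5)
  expect_error(overlap_index(c(1, 1), p = 1, k = 2), "fewer than 2")
})

test_that("the exposure-rate formula equals brute-force pairwise overlap exactly", {
  expect_equal(pairwise_overlap(list(c(1, 2), c(1, 2)))$mean, 1)
  expect_equal(pairwise_overlap(list(c(1, 2), c(3, 4)))$mean, 0)
  set.seed(5)
  for (rep in 1:100) {
    p <- sample(3:8, 1)
    k <- sample(2:4, 1)
    J <- k + sample(1:8, 1)
    forms <- lapply(seq_len(p), function(i) sample.int(J, k))
    counts <- tabulate(unlist(forms), nbins = J)
    bf <- pairwise_overlap(forms)
    expect_equal(overlap_index(counts, p = p, k = k), bf$mean,
                 tolerance = 1e-12)
    expect_gte(bf$max, bf$mean)
  }
})

test_that("variable-length runs refuse the fixed-length overlap formula", {
  cfg <- small_config()
  sim <- run_simulation(cfg)
  if (length(unique(sim$admin$n_items)) > 1) {
    expect_error(overlap_index(sim), "pairwise_overlap")
    expect_true(pairwise_overlap(sim)$mean >= 0)
  } else {
    succeed("run happened to be fixed length")
  }
})

test_that("security summary computes the five exposure diagnostics", {
  cfg <- small_config(
    termination = termination_settings("fixed_length", fixed_length = 4))
  sim <- run_simulation(cfg)
  ss <- security_summary(sim)
  expect_equal(sum(sim$usage$exposure_count), sum(sim$admin$n_items))
  expect_equal(ss$max_exposure_rate, max(sim$usage$exposure_count) / 20)
  expect_equal(ss$pct_unused, 100 * mean(sim$usage$exposure_count == 0))
  # conditioning can only sharpen the maximum exposure
  expect_gte(max(ss$conditional_max_exposure), ss$max_exposure_rate - 1e-12)
  expect_true(all(ss$conditional_max_exposure >= 0 &
                    ss$conditional_max_exposure <= 1))
  expect_true(ss$pct_unused >= 0 && ss$pct_unused <= 100)

  # single simulee: every administered item has exposure rate 1
  one <- small_config(
    n_simulees = 1L,
    termination = termination_settings("fixed_length", fixed_length = 4))
  s1 <- run_simulation(one)
  expect_equal(max(security_summary(s1)$max_exposure_rate), 1)

  # exposure proportional to a gives correlation 1 (constructed usage)
  fake <- sim
  fake$usage$exposure_count <- round(100 * fake$pool$a)
  expect_equal(security_summary(fake)$cor_a_exposure,
               cor(fake$pool$a, round(100 * fake$pool$a)), tolerance = 1e-12)
  # equal use: sd of exposure rates is 0, nothing unused
  fake$usage$exposure_count <- rep(5L, nrow(fake$pool))
  fake$usage$exposure_rate <- rep(0.25, nrow(fake$pool))
  s <- security_summary(fake)
  expect_equal(s$sd_exposure_rate, 0)
  expect_equal(s$pct_unused, 0)
})

test_that("ordered-form counting is exact and renders scientific notation", {
  expect_equal(format(count_possible_forms(3, 2)), "6")
  expect_equal(format(count_possible_forms(7, 1)), "7")
  expect_equal(format(count_possible_forms(10, 10)), format(factorial(10),
                                                            scientific = FALSE))
  # full check against exact double arithmetic wherever doubles are exact
  for (J in c(5, 9, 13, 17)) {
    for (k in seq_len(J)) {
      expect_equal(as.numeric(format(count_possible_forms(J, k))),
                   prod(seq(J - k + 1, J)))
    }
  }
  # 30 items from a 500-item pool (frozen from independent big-integer
  # arithmetic)
  big <- count_possible_forms(500, 30)
  expect_equal(format(big),
    "383359238919971473236395944410456416781406059533151364180041072327524352000000000")
  expect_equal(format_sci(big), "3.83359E+80")
  expect_equal(format_sci(count_possible_forms(3, 2)), "6.00000E+0")
  expect_error(count_possible_forms(5, 6), "<=")
})
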