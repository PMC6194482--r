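test_that("fixed-length administration honours the length contract", {
  cfg <- small_config(
    termination = termination_settings("fixed_length", fixed_length = 5))
  sim <- run_simulation(cfg)
  expect_true(all(sim$admin$n_items == 5L))
  expect_true(all(sim$admin$termination_reason == "fixed_length_met"))
  expect_true(all(nchar(sim$admin$responses) == 5L))
})

test_that("a trivially satisfiable SEE threshold stops at min_items", {
  cfg <- small_config(
    termination = termination_settings("variable", see_threshold = 10,
                                       min_items = 1L))
  sim <- run_simulation(cfg)
  expect_true(all(sim$admin$n_items == 1L))
  expect_true(all(sim$admin$termination_reason == "see_met"))
})

test_that("identical seeds and config reproduce the run bit for bit", {
  cfg <- small_config()
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_identical(s1$admin, s2$admin)
  expect_identical(s1$usage, s2$usage)
})

test_that("per-simulee records do not depend on batch order", {
  cfg <- small_config()
  pool <- generate_item_pool(40, seed = 201)
  sm <- generate_simulees(20, seed = 202)
  fwd <- run_simulation(cfg, pool, sm)
  rev_sm <- sm[rev(seq_len(nrow(sm))), ]
  bwd <- run_simulation(cfg, pool, rev_sm)
  b <- bwd$admin[match(fwd$admin$simulee_id, bwd$admin$simulee_id), ]
  rownames(b) <- NULL
  expect_equal(fwd$admin, b)
})

test_that("exposure counts conserve the administered totals", {
  cfg <- small_config(
    n_simulees = 2L,
    termination = termination_settings("fixed_length", fixed_length = 3))
  sim <- run_simulation(cfg, generate_item_pool(10, seed = 1))
  expect_equal(sum(sim$usage$exposure_count), 6L)
  big <- run_simulation(small_config())
  expect_equal(sum(big$usage$exposure_count), sum(big$admin$n_items))
  expect_equal(nrow(big$usage), 40L)  # zero-exposure items included
})

test_that("no item is administered twice to the same simulee", {
  sim <- run_simulation(small_config())
  for (r in sim$records) expect_false(anyDuplicated(r$items) > 0)
})

test_that("SEE-met terminations are tight: below threshold at the end, not before", {
  cfg <- small_config(n_simulees = 30L, pool_size = 80L)
  sim <- run_simulation(cfg)
  thr <- cfg$termination$see_threshold
  for (r in sim$records) {
    if (r$termination_reason != "see_met") next
    expect_lt(r$see, thr)
    pl <- sim$pool
    sees <- vapply(seq_len(r$n_items), function(t)
      see_from_tif(test_info(r$trajectory[t], pl[r$items[1:t], , drop = FALSE])),
      numeric(1))
    if (r$n_items > cfg$termination$min_items)
      expect_gte(sees[r$n_items - 1], thr)
  }
})

test_that("raising the SEE threshold never lengthens any test under the same seeds", {
  loose <- small_config(
    termination = termination_settings("variable", see_threshold = 0.4))
  tight <- small_config(
    termination = termination_settings("variable", see_threshold = 0.3))
  l <- run_simulation(loose)$admin
  t <- run_simulation(tight)$admin
  expect_true(all(l$n_items <= t$n_items))
})

test_that("small pools exhaust cleanly and tiny fixed lengths are validated", {
  cfg <- small_config(
    n_simulees = 3L, pool_size = 5L,
    termination = termination_settings("variable", see_threshold = 1e-6,
                                       max_items = 50L))
  sim <- run_simulation(cfg)
  expect_true(all(sim$admin$n_items == 5L))
  expect_true(all(sim$admin$termination_reason == "pool_exhausted"))
  bad <- small_config(
    pool_size = 5L,
    termination = termination_settings("fixed_length", fixed_length = 10))
  expect_error(run_simulation(bad), "pool smaller")
})

test_that("the max-items cap fires with its own reason", {
  cfg <- small_config(
    n_simulees = 5L, pool_size = 60L,
    termination = termination_settings("variable", see_threshold = 1e-4,
                                       max_items = 8L))
  sim <- run_simulation(cfg)
  expect_true(all(sim$admin$n_items == 8L))
  expect_true(all(sim$admin$termination_reason == "max_items"))
})

test_that("the score-consistency rule terminates once the estimate settles", {
  cfg <- small_config(
    n_simulees = 10L, pool_size = 80L,
    termination = termination_settings("variable", see_threshold = 1e-4,
                                       max_items = 50L,
                                       consistency_delta = 0.05,
                                       consistency_count = 2L))
  sim <- run_simulation(cfg)
  expect_true(any(sim$admin$termination_reason == "consistency_met"))
  for (r in sim$records) {
    if (r$termination_reason != "consistency_met") next
    d <- abs(diff(r$trajectory))
    n <- length(d)
    expect_true(all(d[(n - 1):n] < 0.05))
  }
})

test_that("every administered item lies in the randomesque top k of its step", {
  cfg <- small_config(n_simulees = 15L, pool_size = 60L)
  pool <- generate_item_pool(60, seed = 301)
  sim <- run_simulation(cfg, pool)
  ss <- cfg$selection
  for (r in sim$records) {
    avail <- rep(TRUE, nrow(pool))
    th <- r$theta_init
    for (t in seq_len(r$n_items)) {
      cand <- which(avail)
      ranked <- rank_candidates(th, pool[cand, , drop = FALSE], ss,
                                cfg$model)
      topk <- cand[ranked[seq_len(min(ss$randomesque_k, length(ranked)))]]
      expect_true(r$items[t] %in% topk)
      avail[r$items[t]] <- FALSE
      th <- r$trajectory[t]
    }
  }
})

test_that("admin log, usage table and response matrix round-trip and conserve counts", {
  cfg <- small_config()
  sim <- run_simulation(cfg)
  tmp <- withr::local_tempfile()
  write_admin_log(sim, tmp)
  back <- read_admin_log(tmp)
  expect_identical(back$simulee_id, sim$admin$simulee_id)
  expect_identical(back$item_ids, sim$admin$item_ids)
  expect_identical(back$responses, sim$admin$responses)
  expect_equal(back$theta_hat, sim$admin$theta_hat, tolerance = 1e-10)
  expect_equal(back$see, sim$admin$see, tolerance = 1e-10)

  tmp2 <- withr::local_tempfile()
  write_usage(sim$usage, tmp2)
  u <- read_usage(tmp2)
  expect_equal(nrow(u), nrow(sim$pool))
  expect_equal(u$exposure_count, sim$usage$exposure_count)

  tmp3 <- withr::local_tempfile()
  write_response_matrix(sim, tmp3)
  m <- utils::read.delim(tmp3, check.names = FALSE)
  expect_equal(dim(m), c(20L, 41L))
  expect_equal(sum(is.na(m[, -1])), 20L * 40L - sum(sim$admin$n_items))
})

test_that("configuration files map onto the settings constructors", {
  tmp <- withr::local_tempfile()
  writeLines(c(
    "# reference design, scaled down",
    "[model]", "D = 1.7",
    "[estimation]", 'method = "MLEF"', "fence_lower = -3.5",
    "fence_upper = 3.5", "jump_limit = 1", "jump_limit_items = 5",
    "theta_range = -4, 4",
    "[selection]", 'criterion = "MFI"',
    'exposure_control = "randomesque"', "randomesque_k = 5",
    "[termination]", 'mode = "variable"', "see_threshold = 0.3",
    "max_items = 50",
    "[initial_theta]", 'family = "uniform"', "min = -0.5", "max = 0.5",
    "[run]", "n_simulees = 10", "pool_size = 40",
    "[seeds]", "pool = 1", "simulees = 2", "responses = 3",
    "selection = 4"), tmp)
  cfg <- read_cat_config(tmp)
  expect_equal(cfg$estimation$method, "MLEF")
  expect_equal(cfg$estimation$jump_limit, 1)
  expect_equal(cfg$estimation$theta_range, c(-4, 4))
  expect_equal(cfg$selection$randomesque_k, 5L)
  expect_equal(cfg$termination$see_threshold, 0.3)
  expect_equal(cfg$n_simulees, 10L)
  expect_equal(cfg$seeds$pool, 1L)
  sim <- run_simulation(cfg)
  expect_equal(nrow(sim$admin), 10L)
})

test_that("the interim trace exports one row per administered item", {
  cfg <- small_config(n_simulees = 4L)
  sim <- run_simulation(cfg)
  tmp <- withr::local_tempfile()
  write_trace(sim, tmp)
  tr <- utils::read.delim(tmp)
  expect_equal(nrow(tr), sum(sim$admin$n_items))
  expect_equal(as.integer(table(tr$simulee_id)[sim$admin$simulee_id]),
               sim$admin$n_items)
})
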