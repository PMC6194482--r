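#' Settings for test termination
#'
#' @param mode `"variable"` (stop on a precision or consistency rule,
#'   subject to `min_items`/`max_items`) or `"fixed_length"`.
#' @param fixed_length test length for fixed-length mode.
#' @param see_threshold stop once the interim SEE falls below this value.
#' @param min_items,max_items bounds on the administered length;
#'   `max_items` is a hard cap with its own termination reason.
#' @param consistency_delta optional score-consistency rule: stop after the
#'   interim estimate has moved by less than this for
#'   `consistency_count` consecutive items. `NULL` disables the rule.
#' @param consistency_count consecutive small moves required.
#' @return a list of class `termination_settings`.
#' @export
termination_settings <- function(mode = c("variable", "fixed_length"),
                                 fixed_length = NULL,
                                 see_threshold = 0.3,
                                 min_items = 1L, max_items = 50L,
                                 consistency_delta = NULL,
                                 consistency_count = 3L) {
  mode <- match.arg(mode)
  if (mode == "fixed_length") {
    if (is.null(fixed_length) || fixed_length < 1)
      stop("fixed-length mode requires `fixed_length` >= 1")
    fixed_length <- as.integer(fixed_length)
  }
  if (see_threshold <= 0) stop("`see_threshold` must be > 0")
  if (min_items < 1 || max_items < min_items)
    stop("need 1 <= min_items <= max_items")
  if (!is.null(consistency_delta) && consistency_delta <= 0)
    stop("`consistency_delta` must be positive or NULL")
  structure(list(mode = mode, fixed_length = fixed_length,
                 see_threshold = see_threshold,
                 min_items = as.integer(min_items),
                 max_items = as.integer(max_items),
                 consistency_delta = consistency_delta,
                 consistency_count = as.integer(consistency_count)),
            class = "termination_settings")
}

#' Full configuration of one CAT simulation condition
#'
#' The defaults reproduce the engine's reference design: a 2PL pool, MFI
#' selection with randomesque-of-5 exposure control, variable length
#' terminating at SEE < 0.3 with a 50-item cap, maximum likelihood
#' estimation with fences at +/-3.5, an initial interim score drawn
#' uniformly from (-0.5, 0.5), and an estimate jump limited to 1 for the
#' first 5 items.
#'
#' @param model a [model_settings()].
#' @param estimation an [estimation_settings()].
#' @param selection a [selection_settings()].
#' @param termination a [termination_settings()].
#' @param initial_theta a [dist_spec()] (or single number) for each
#'   simulee's initial interim score; drawn from the simulee's selection
#'   substream.
#' @param n_simulees number of simulees generated when none are supplied to
#'   [run_simulation()].
#' @param pool_size pool size generated when no pool is supplied.
#' @param seeds named list of the four independent master seeds: `pool`,
#'   `simulees`, `responses`, `selection`.
#' @param outputs optional named list of output paths (`admin_log`,
#'   `usage`, `response_matrix`); written by [run_simulation()] when set.
#' @return a list of class `cat_config`.
#' @export
cat_config <- function(model = model_settings(),
                       estimation = estimation_settings(
                         "MLEF", jump_limit = 1, jump_limit_items = 5L),
                       selection = selection_settings(
                         "MFI", "randomesque", randomesque_k = 5L),
                       termination = termination_settings(),
                       initial_theta = dist_spec("uniform", min = -0.5,
                                                 max = 0.5),
                       n_simulees = 5000L, pool_size = 300L,
                       seeds = list(pool = 101L, simulees = 102L,
                                    responses = 103L, selection = 104L),
                       outputs = list()) {
  stopifnot(inherits(model, "model_settings"),
            inherits(estimation, "estimation_settings"),
            inherits(selection, "selection_settings"),
            inherits(termination, "termination_settings"))
  need <- c("pool", "simulees", "responses", "selection")
  if (!all(need %in% names(seeds)))
    stop("`seeds` must name all four streams: ", paste(need, collapse = ", "))
  structure(list(model = model, estimation = estimation,
                 selection = selection, termination = termination,
                 initial_theta = initial_theta,
                 n_simulees = as.integer(n_simulees),
                 pool_size = as.integer(pool_size),
                 seeds = lapply(seeds, as.integer), outputs = outputs),
            class = "cat_config")
}

# stable per-simulee substream key: the integer embedded in the id when
# there is one (ids from generate_simulees), else a string hash -- so a
# simulee's record does not depend on its position in the batch
.sim_key <- function(id) {
  digits <- gsub("\\D", "", id)
  if (nzchar(digits) && nchar(digits) < 10) return(as.integer(digits))
  h <- 0
  for (u in utf8ToInt(id)) h <- (h * 131 + u) %% 2147483629
  as.integer(h)
}

# fast subset of a pool stored as a plain list of parallel vectors
.pl_sub <- function(pl, idx) {
  out <- list(id = pl$id[idx], a = pl$a[idx], b = pl$b[idx], c = pl$c[idx])
  if (!is.null(pl$content)) out$content <- pl$content[idx]
  out
}

.as_plist <- function(pool) {
  list(id = pool$id, a = pool$a, b = pool$b, c = pool$c,
       content = pool$content)
}

#' Administer one adaptive test
#'
#' Runs the three-step CAT loop for a single simulee: select an item under
#' the configured criterion, exposure control and content balancing; draw a
#' scored response at the simulee's true theta; re-estimate the interim
#' ability under the update restrictions; and check the termination policy.
#'
#' @param simulee a list or one-row data frame with `id` and `theta_true`.
#' @param pool the item pool.
#' @param config a [cat_config()].
#' @param sim_index optional integer key for the simulee's response and
#'   selection substreams (derived from the master seeds); defaults to a
#'   stable key computed from the simulee id, so a record does not depend
#'   on the simulee's position in the batch.
#' @return an `admin_record` list: ids and responses of the administered
#'   items in order, the interim estimate trajectory, final estimate and
#'   SEE, the SEE evaluated at the true theta (`true_see`), the termination
#'   reason (`see_met`, `max_items`, `fixed_length_met`, `consistency_met`
#'   or `pool_exhausted`) and any flags.
#' @export
administer_one <- function(simulee, pool, config, sim_index = NULL) {
  pl <- if (is.data.frame(pool)) .as_plist(pool) else pool
  if (is.null(sim_index)) sim_index <- .sim_key(as.character(simulee$id))
  resp_stream <- rng_stream(derive_seed(config$seeds$responses, sim_index))
  sel_stream <- rng_stream(derive_seed(config$seeds$selection, sim_index))
  .administer_impl(as.character(simulee$id), as.numeric(simulee$theta_true),
                   pl, config, resp_stream, sel_stream)
}

.administer_impl <- function(sim_id, theta_true, pl, config,
                             resp_stream, sel_stream) {
  est <- config$estimation
  sel <- config$selection
  term <- config$termination
  model <- config$model
  J <- length(pl$a)
  K <- .sh_K_vector(data.frame(id = pl$id), sel$sh_control)
  sh_on <- sel$exposure_control == "sympson_hetter"
  # canonical order: content filter -> ranking -> randomesque pick -> S-H
  # filter; under S-H control the randomesque pick width still applies
  # (randomesque_k = 1 gives the pure criterion pick)
  k_pick <- if (sel$exposure_control == "none") 1L else sel$randomesque_k

  available <- rep(TRUE, J)
  eligible <- rep(TRUE, J)
  items <- integer(0)
  responses <- integer(0)
  trajectory <- numeric(0)
  picked <- integer(0)     # every selection event incl. SH rejections
  flags <- character(0)
  reason <- NA_character_
  consec <- 0L

  theta <- stream_do(sel_stream, function() draw_dist(1, config$initial_theta))
  theta <- min(max(theta, est$theta_range[1]), est$theta_range[2])
  theta_init <- theta

  repeat {
    # --- item selection: content filter -> ranking -> randomesque -> S-H
    chosen <- NA_integer_
    repeat {
      cand <- which(available & eligible)
      exhausted <- length(cand) == 0L
      if (exhausted) cand <- which(available)  # S-H rejected everything left
      if (length(cand) == 0L) break            # true pool exhaustion
      cand_items <- .pl_sub(pl, cand)
      pos <- stream_do(sel_stream, function() {
        if (!is.null(sel$content_targets)) {
          constrained_content_pick(theta, cand_items,
                                   pl$content[items], sel, model)$position
        } else {
          ranked <- rank_candidates(theta, cand_items, sel, model)
          pick_randomesque(ranked, k_pick)
        }
      })
      this <- cand[pos]
      picked <- c(picked, this)
      if (exhausted) {
        chosen <- this
        flags <- c(flags, "sh_exhausted")
        break
      }
      if (!sh_on || stream_do(sel_stream, function()
        sympson_hetter_filter(K[this]))) {
        chosen <- this
        break
      }
      eligible[this] <- FALSE
    }
    if (is.na(chosen)) {                  # true pool exhaustion
      reason <- "pool_exhausted"
      break
    }

    # --- response
    available[chosen] <- FALSE
    x <- stream_do(resp_stream, function()
      draw_response(theta_true, .pl_sub(pl, chosen), model$D))
    items <- c(items, chosen)
    responses <- c(responses, x)
    n <- length(items)
    admin_items <- .pl_sub(pl, items)

    # --- interim estimation with update restrictions
    fit <- estimate_theta(admin_items, responses, est, model, start = theta)
    if (!fit$finite) flags <- c(flags, "nonfinite_mle")
    prev <- theta
    theta <- apply_update_rules(prev, fit$theta_hat, n, est)
    trajectory <- c(trajectory, theta)
    see <- if (est$method == "EAP") fit$see
    else see_from_tif(test_info(theta, admin_items, model$D),
                      model$see_convention)

    # --- termination policy
    if (term$mode == "fixed_length") {
      if (n >= term$fixed_length) { reason <- "fixed_length_met"; break }
    } else {
      if (n >= 2 && abs(theta - prev) <
          (if (is.null(term$consistency_delta)) -Inf
           else term$consistency_delta)) consec <- consec + 1L
      else consec <- 0L
      if (n >= term$min_items && see < term$see_threshold) {
        reason <- "see_met"; break
      }
      if (!is.null(term$consistency_delta) && n >= term$min_items &&
          consec >= term$consistency_count) {
        reason <- "consistency_met"; break
      }
      if (n >= term$max_items) { reason <- "max_items"; break }
    }
    if (all(!available)) { reason <- "pool_exhausted"; break }
  }

  n <- length(items)
  admin_items <- if (n > 0) .pl_sub(pl, items) else list(a = numeric(0))
  true_see <- if (n > 0)
    see_from_tif(test_info(theta_true, admin_items, model$D),
                 model$see_convention) else NA_real_
  structure(list(simulee_id = sim_id, theta_true = theta_true,
                 theta_init = theta_init, n_items = n,
                 items = items, item_ids = pl$id[items],
                 responses = responses, trajectory = trajectory,
                 theta_hat = if (n > 0) trajectory[n] else theta_init,
                 see = if (n > 0) see else NA_real_,
                 true_see = true_see, termination_reason = reason,
                 flags = unique(flags), picked = picked),
            class = "admin_record")
}

#' Run a batch CAT simulation
#'
#' Administers every simulee independently (each from its own derived
#' response and selection substreams, so results are invariant to simulee
#' order), aggregates per-item usage, and writes any configured output
#' files.
#'
#' @param config a [cat_config()].
#' @param pool item pool; generated from the config's pool seed and the
#'   reference design (`pool_size` items, a ~ U(0.5, 1.2), b ~ U(-3, 3),
#'   c = 0) when `NULL`.
#' @param simulees simulee table; generated from the simulee seed
#'   (`n_simulees` draws from N(0, 1)) when `NULL`.
#' @return a list of class `cat_sim` with elements `records` (list of
#'   `admin_record`), `admin` (one-row-per-simulee data frame), `usage`
#'   (per-item exposure table covering the whole pool, zero-exposure items
#'   included), `pool`, `simulees`, `config`.
#' @export
run_simulation <- function(config, pool = NULL, simulees = NULL) {
  stopifnot(inherits(config, "cat_config"))
  if (is.null(pool))
    pool <- generate_item_pool(config$pool_size, seed = config$seeds$pool)
  validate_item_pool(pool)
  if (is.null(simulees))
    simulees <- generate_simulees(config$n_simulees,
                                  seed = config$seeds$simulees)
  term <- config$termination
  if (term$mode == "fixed_length" && term$fixed_length > nrow(pool))
    stop("pool smaller than the configured fixed length")
  pl <- .as_plist(pool)
  n_sim <- nrow(simulees)
  records <- vector("list", n_sim)
  for (i in seq_len(n_sim)) {
    key <- .sim_key(simulees$id[i])
    records[[i]] <- .administer_impl(
      simulees$id[i], simulees$theta_true[i], pl, config,
      rng_stream(derive_seed(config$seeds$responses, key)),
      rng_stream(derive_seed(config$seeds$selection, key)))
  }
  usage <- .usage_table(records, pool, n_sim)
  admin <- .admin_frame(records)
  out <- structure(list(records = records, admin = admin, usage = usage,
                        pool = pool, simulees = simulees, config = config),
                   class = "cat_sim")
  paths <- config$outputs
  if (!is.null(paths$admin_log)) write_admin_log(out, paths$admin_log)
  if (!is.null(paths$usage)) write_usage(out$usage, paths$usage)
  if (!is.null(paths$response_matrix))
    write_response_matrix(out, paths$response_matrix)
  out
}

.usage_table <- function(records, pool, n_sim) {
  J <- nrow(pool)
  counts <- integer(J)
  sel_counts <- integer(J)
  for (r in records) {
    counts[r$items] <- counts[r$items] + 1L
    t_sel <- tabulate(r$picked, nbins = J)
    sel_counts <- sel_counts + t_sel
  }
  data.frame(id = pool$id, exposure_count = counts,
             exposure_rate = counts / n_sim,
             selection_count = sel_counts,
             retirement_days = 0L, stringsAsFactors = FALSE)
}

.admin_frame <- function(records) {
  data.frame(
    simulee_id = vapply(records, `[[`, character(1), "simulee_id"),
    theta_true = vapply(records, `[[`, numeric(1), "theta_true"),
    n_items = vapply(records, `[[`, integer(1), "n_items"),
    theta_hat = vapply(records, `[[`, numeric(1), "theta_hat"),
    see = vapply(records, `[[`, numeric(1), "see"),
    true_see = vapply(records, `[[`, numeric(1), "true_see"),
    termination_reason = vapply(records, `[[`, character(1),
                                "termination_reason"),
    theta_init = vapply(records, `[[`, numeric(1), "theta_init"),
    responses = vapply(records, function(r)
      paste(r$responses, collapse = ""), character(1)),
    item_ids = vapply(records, function(r)
      paste(r$item_ids, collapse = ","), character(1)),
    flags = vapply(records, function(r)
      paste(r$flags, collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
}

#' @export
print.cat_sim <- function(x, ...) {
  len <- x$admin$n_items
  cat(sprintf("CAT simulation: %d simulees, pool of %d items\n",
              nrow(x$admin), nrow(x$pool)))
  cat(sprintf("  mean test length %.2f (range %d-%d)\n",
              mean(len), min(len), max(len)))
  cat(sprintf("  max exposure rate %.3f; unused items %d (%.1f%%)\n",
              max(x$usage$exposure_rate),
              sum(x$usage$exposure_count == 0),
              100 * mean(x$usage$exposure_count == 0)))
  tab <- table(x$admin$termination_reason)
  cat("  termination:", paste(sprintf("%s=%d", names(tab), tab),
                              collapse = ", "), "\n")
  invisible(x)
}
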