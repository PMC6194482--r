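#' Settings for interim and final ability estimation
#'
#' @param method `"MLE"` (Newton-Raphson maximum likelihood), `"MLEF"` (MLE
#'   with fences: the likelihood is augmented with two imaginary items at
#'   the fences so every response pattern, including all-correct and
#'   all-incorrect, has a finite interior maximum), `"MAP"` (normal-prior
#'   posterior mode) or `"EAP"` (posterior mean by fixed-point quadrature).
#' @param prior_mean,prior_sd normal prior for MAP/EAP (`prior_sd > 0`).
#' @param fence_lower,fence_upper fence locations for MLEF
#'   (`fence_lower < fence_upper`).
#' @param fence_a discrimination of the two imaginary fence items on the
#'   D-scaled metric.
#' @param theta_range closed interval every reported estimate is clamped
#'   into.
#' @param jump_limit maximum allowed change of the interim estimate per
#'   item, or `NULL` for no restriction.
#' @param jump_limit_items number of initial items the jump limit applies
#'   to.
#' @param nr_tolerance Newton-Raphson convergence tolerance on the step
#'   size.
#' @param nr_max_iterations Newton-Raphson iteration cap before the bounded
#'   grid-search fallback takes over.
#' @param quadrature_points,quadrature_range EAP quadrature design: evenly
#'   spaced points spanning the range.
#' @return a list of class `estimation_settings`.
#' @export
estimation_settings <- function(method = c("MLE", "MLEF", "MAP", "EAP"),
                                prior_mean = 0, prior_sd = 1,
                                fence_lower = -3.5, fence_upper = 3.5,
                                fence_a = 1,
                                theta_range = c(-4, 4),
                                jump_limit = NULL, jump_limit_items = 0L,
                                nr_tolerance = 1e-4,
                                nr_max_iterations = 50L,
                                quadrature_points = 81L,
                                quadrature_range = c(-4.5, 4.5)) {
  method <- match.arg(method)
  if (prior_sd <= 0) stop("`prior_sd` must be > 0")
  if (fence_lower >= fence_upper) stop("`fence_lower` must be < `fence_upper`")
  if (length(theta_range) != 2L || theta_range[1] >= theta_range[2])
    stop("`theta_range` must be a non-degenerate interval")
  if (!is.null(jump_limit) && jump_limit <= 0)
    stop("`jump_limit` must be positive or NULL")
  if (nr_tolerance <= 0 || nr_max_iterations < 1)
    stop("invalid Newton-Raphson controls")
  structure(list(method = method, prior_mean = prior_mean,
                 prior_sd = prior_sd, fence_lower = fence_lower,
                 fence_upper = fence_upper, fence_a = fence_a,
                 theta_range = theta_range, jump_limit = jump_limit,
                 jump_limit_items = as.integer(jump_limit_items),
                 nr_tolerance = nr_tolerance,
                 nr_max_iterations = as.integer(nr_max_iterations),
                 quadrature_points = as.integer(quadrature_points),
                 quadrature_range = quadrature_range),
            class = "estimation_settings")
}

# probability clipping applied inside likelihood computations only
.clip_p <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)

#' Bernoulli log-likelihood of a response pattern
#'
#' sum(x log P + (1 - x) log(1 - P)) with response probabilities clipped to
#' \[1e-12, 1 - 1e-12\] so the value is always finite. Vectorised over
#' `theta`.
#'
#' @param theta ability value(s).
#' @param items administered items (`item_pool` rows).
#' @param responses 0/1 vector, same length as the item list.
#' @param D logistic scaling constant.
#' @return log-likelihood value(s), one per element of `theta`.
#' @export
loglik <- function(theta, items, responses, D = 1.7) {
  n <- if (is.data.frame(items)) nrow(items) else length(items$a)
  if (length(responses) != n)
    stop("`responses` and `items` must have the same length")
  if (n == 0L) stop("at least one answered item is required")
  vapply(theta, function(th) {
    p <- .clip_p(irt_prob(th, items, D))
    sum(responses * log(p) + (1 - responses) * log(1 - p))
  }, numeric(1))
}

# score (d loglik / d theta): sum D a (x - P) (P - c) / ((1 - c) P)
.score <- function(theta, items, responses, D) {
  p <- .clip_p(irt_prob(theta, items, D))
  cc <- if (is.null(items$c)) rep(0, length(p)) else items$c
  sum(D * items$a * (responses - p) * (p - cc) / ((1 - cc) * p))
}

# Newton-Raphson (Fisher-scoring curvature) maximiser with per-step clamp
# and a bounded grid + golden-section fallback; `penalty_prec` > 0 adds a
# normal log-prior with that precision.
.nr_maximize <- function(items, responses, settings, D, start,
                         penalty_prec = 0, penalty_mean = 0,
                         search_range = settings$theta_range) {
  th <- start
  iters <- 0L
  converged <- FALSE
  fallback <- FALSE
  for (i in seq_len(settings$nr_max_iterations)) {
    iters <- i
    g <- .score(th, items, responses, D) + penalty_prec * (penalty_mean - th)
    h <- test_info(th, items, D) + penalty_prec
    if (!is.finite(g) || !is.finite(h) || h < 1e-10) {
      fallback <- TRUE
      break
    }
    step <- max(-1, min(1, g / h))
    th <- th + step
    if (abs(step) < settings$nr_tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged) fallback <- TRUE
  if (fallback) {
    obj <- function(t) loglik(t, items, responses, D) -
      penalty_prec * (t - penalty_mean)^2 / 2
    grid <- seq(search_range[1], search_range[2], by = 0.01)
    best <- grid[which.max(obj(grid))]
    opt <- stats::optimize(obj, lower = max(search_range[1], best - 0.01),
                           upper = min(search_range[2], best + 0.01),
                           maximum = TRUE, tol = 1e-6)
    th <- opt$maximum
  }
  list(theta = th, iterations = iters, converged = converged,
       fallback = fallback)
}

.estimate_result <- function(theta_raw, items, settings, model,
                             nr_iterations = 0L, converged = TRUE,
                             finite = TRUE, see = NULL) {
  rng <- settings$theta_range
  theta_hat <- min(max(theta_raw, rng[1]), rng[2])
  clamped <- !identical(theta_hat, theta_raw) || !finite
  if (is.null(see)) {
    n <- if (is.data.frame(items)) nrow(items) else length(items$a)
    see <- if (n > 0L)
      see_from_tif(test_info(theta_hat, items, model$D), model$see_convention)
    else settings$prior_sd
  }
  structure(list(theta_hat = theta_hat, see = see,
                 nr_iterations = as.integer(nr_iterations),
                 converged = converged, clamped = clamped, finite = finite),
            class = "theta_estimate")
}

#' @export
print.theta_estimate <- function(x, ...) {
  cat(sprintf("theta_hat = %.4f (SEE %.4f)%s%s%s\n", x$theta_hat, x$see,
              if (x$nr_iterations > 0)
                sprintf(", %d NR iterations", x$nr_iterations) else "",
              if (!x$converged) ", NOT converged (fallback/flagged)" else "",
              if (x$clamped) ", clamped" else ""))
  invisible(x)
}

#' Maximum likelihood ability estimate (Newton-Raphson)
#'
#' Maximises the Bernoulli log-likelihood by Newton-Raphson from `start`
#' with Fisher-scoring curvature, a per-iteration step clamp of 1, and a
#' bounded grid-search fallback if the iteration fails to converge. The
#' result is clamped into `theta_range`.
#'
#' An all-correct or all-incorrect response pattern has no finite maximiser;
#' the result is then the corresponding `theta_range` boundary with
#' `finite = FALSE`, `converged = FALSE` and `clamped = TRUE` so the caller
#' can decide its own fallback.
#'
#' @param items administered items.
#' @param responses 0/1 responses, one per item.
#' @param settings an [estimation_settings()].
#' @param model a [model_settings()].
#' @param start starting value for the iteration.
#' @return a `theta_estimate`: `theta_hat`, `see` (1/sqrt of the test
#'   information of the administered items at `theta_hat`), `nr_iterations`,
#'   `converged`, `clamped`, `finite`.
#' @export
estimate_mle <- function(items, responses, settings = estimation_settings("MLE"),
                         model = model_settings(), start = 0) {
  n <- if (is.data.frame(items)) nrow(items) else length(items$a)
  if (n < 1L || length(responses) != n)
    stop("need >= 1 answered item with matching responses")
  if (all(responses == 1) || all(responses == 0)) {
    boundary <- if (all(responses == 1)) settings$theta_range[2]
    else settings$theta_range[1]
    return(.estimate_result(if (responses[1] == 1) Inf else -Inf,
                            items, settings, model,
                            nr_iterations = 0L, converged = FALSE,
                            finite = FALSE,
                            see = see_from_tif(
                              test_info(boundary, items, model$D),
                              model$see_convention)))
  }
  fit <- .nr_maximize(items, responses, settings, model$D, start)
  .estimate_result(fit$theta, items, settings, model,
                   nr_iterations = fit$iterations,
                   converged = fit$converged, finite = TRUE)
}

#' Maximum likelihood estimation with fences
#'
#' MLE on the likelihood augmented with two imaginary 2PL items located at
#' the fences -- one at `fence_lower` scored correct, one at `fence_upper`
#' scored incorrect -- which guarantees a finite maximum strictly inside
#' `(fence_lower, fence_upper)` for every response pattern. The reported SEE
#' uses the real administered items only.
#'
#' @inheritParams estimate_mle
#' @return a `theta_estimate`.
#' @export
estimate_mlef <- function(items, responses,
                          settings = estimation_settings("MLEF"),
                          model = model_settings(), start = 0) {
  n <- if (is.data.frame(items)) nrow(items) else length(items$a)
  if (n < 1L || length(responses) != n)
    stop("need >= 1 answered item with matching responses")
  aug <- list(a = c(items$a, settings$fence_a, settings$fence_a),
              b = c(items$b, settings$fence_lower, settings$fence_upper),
              c = c(if (is.null(items$c)) rep(0, n) else items$c, 0, 0))
  aug_resp <- c(responses, 1L, 0L)
  rng <- range(c(settings$theta_range, settings$fence_lower,
                 settings$fence_upper))
  fit <- .nr_maximize(aug, aug_resp, settings, model$D, start,
                      search_range = rng)
  .estimate_result(fit$theta, items, settings, model,
                   nr_iterations = fit$iterations,
                   converged = fit$converged, finite = TRUE)
}

#' Maximum a posteriori ability estimate
#'
#' Newton-Raphson on the log-likelihood plus a normal log-prior; finite for
#' every response pattern. With zero answered items the prior mean is
#' returned (used for the initial-score path).
#'
#' @inheritParams estimate_mle
#' @return a `theta_estimate`.
#' @export
estimate_map <- function(items, responses,
                         settings = estimation_settings("MAP"),
                         model = model_settings(), start = NULL) {
  n <- if (is.data.frame(items)) nrow(items) else length(items$a)
  if (n == 0L)
    return(.estimate_result(settings$prior_mean, items, settings, model,
                            see = settings$prior_sd))
  if (length(responses) != n) stop("`responses` length mismatch")
  if (is.null(start)) start <- settings$prior_mean
  prec <- 1 / settings$prior_sd^2
  fit <- .nr_maximize(items, responses, settings, model$D, start,
                      penalty_prec = prec, penalty_mean = settings$prior_mean)
  .estimate_result(fit$theta, items, settings, model,
                   nr_iterations = fit$iterations,
                   converged = fit$converged, finite = TRUE)
}

#' Expected a posteriori ability estimate
#'
#' Posterior mean over a fixed-point quadrature grid (default 81 evenly
#' spaced points on \[-4.5, 4.5\]) with normal prior weights. The `see`
#' field carries the posterior standard deviation. Defined for zero
#' answered items (returns the prior mean).
#'
#' @inheritParams estimate_mle
#' @return a `theta_estimate` with `see` = posterior SD.
#' @export
estimate_eap <- function(items, responses,
                         settings = estimation_settings("EAP"),
                         model = model_settings()) {
  n <- if (is.data.frame(items)) nrow(items) else length(items$a)
  grid <- seq(settings$quadrature_range[1], settings$quadrature_range[2],
              length.out = settings$quadrature_points)
  w <- stats::dnorm(grid, settings$prior_mean, settings$prior_sd)
  if (n > 0L) {
    if (length(responses) != n) stop("`responses` length mismatch")
    ll <- loglik(grid, items, responses, model$D)
    w <- w * exp(ll - max(ll))
  }
  w <- w / sum(w)
  mu <- sum(w * grid)
  sd <- sqrt(sum(w * (grid - mu)^2))
  .estimate_result(mu, items, settings, model, see = sd)
}

#' Estimate ability with the configured method
#'
#' Dispatches to [estimate_mle()], [estimate_mlef()], [estimate_map()] or
#' [estimate_eap()] according to `settings$method`.
#'
#' @inheritParams estimate_mle
#' @return a `theta_estimate`.
#' @export
estimate_theta <- function(items, responses, settings, model = model_settings(),
                           start = 0) {
  switch(settings$method,
    MLE  = estimate_mle(items, responses, settings, model, start),
    MLEF = estimate_mlef(items, responses, settings, model, start),
    MAP  = estimate_map(items, responses, settings, model, start),
    EAP  = estimate_eap(items, responses, settings, model)
  )
}

#' Apply the engine's interim-update restrictions
#'
#' If the jump limit is active (the number of administered items is at most
#' `jump_limit_items`), the raw estimate is clamped into
#' `previous_theta +/- jump_limit`; the result is then clamped into
#' `theta_range`.
#'
#' @param previous_theta the interim estimate before the current item.
#' @param raw_estimate the new unrestricted estimate.
#' @param items_administered number of items administered so far (>= 1).
#' @param settings an [estimation_settings()].
#' @return the restricted estimate.
#' @export
apply_update_rules <- function(previous_theta, raw_estimate,
                               items_administered, settings) {
  th <- raw_estimate
  if (!is.null(settings$jump_limit) &&
      items_administered <= settings$jump_limit_items) {
    th <- min(max(th, previous_theta - settings$jump_limit),
              previous_theta + settings$jump_limit)
  }
  min(max(th, settings$theta_range[1]), settings$theta_range[2])
}
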