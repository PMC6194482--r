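# Independent oracles used across the suite. These deliberately avoid the
# package's own likelihood/estimation code paths: probabilities and
# log-likelihoods are recomputed from the 3PL formula with plain matrix
# arithmetic, and maximisers are located by dense grid search.

# naive per-item log-likelihood loop (scalar theta)
naive_loglik <- function(theta, a, b, cc, x, D) {
  tot <- 0
  for (i in seq_along(a)) {
    p <- cc[i] + (1 - cc[i]) / (1 + exp(-D * a[i] * (theta - b[i])))
    p <- min(max(p, 1e-12), 1 - 1e-12)
    tot <- tot + if (x[i] == 1) log(p) else log(1 - p)
  }
  tot
}

# vectorised grid log-likelihood: rows = grid points, independent matrix path
grid_loglik <- function(grid, a, b, cc, x, D) {
  z <- sweep(outer(grid, b, "-"), 2, D * a, "*")
  p <- sweep(1 / (1 + exp(-z)), 2, 1 - cc, "*")
  p <- sweep(p, 2, cc, "+")
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ll <- numeric(length(grid))
  if (any(x == 1)) ll <- ll + rowSums(log(p[, x == 1, drop = FALSE]))
  if (any(x == 0)) ll <- ll + rowSums(log(1 - p[, x == 0, drop = FALSE]))
  ll
}

# argmax of an objective over a dense grid
grid_argmax <- function(obj, lower = -6, upper = 6, step = 1e-4) {
  g <- seq(lower, upper, by = step)
  g[which.max(obj(g))]
}

# grid-search maximiser of the (optionally normal-penalised) log-likelihood
grid_mle <- function(a, b, cc, x, D, lower = -6, upper = 6, step = 1e-4,
                     prior_mean = NULL, prior_sd = NULL) {
  g <- seq(lower, upper, by = step)
  ll <- grid_loglik(g, a, b, cc, x, D)
  if (!is.null(prior_mean)) ll <- ll - (g - prior_mean)^2 / (2 * prior_sd^2)
  g[which.max(ll)]
}

# dense-quadrature EAP oracle
grid_eap <- function(a, b, cc, x, D, prior_mean = 0, prior_sd = 1,
                     lower = -8, upper = 8, n = 20001) {
  g <- seq(lower, upper, length.out = n)
  ll <- grid_loglik(g, a, b, cc, x, D)
  w <- dnorm(g, prior_mean, prior_sd) * exp(ll - max(ll))
  w <- w / sum(w)
  sum(w * g)
}

# random small estimation case under the reference item-parameter design
random_case <- function(n_items = sample(2:10, 1), force_mixed = TRUE) {
  a <- runif(n_items, 0.5, 1.5)
  b <- runif(n_items, -2.5, 2.5)
  x <- rbinom(n_items, 1, 0.5)
  if (force_mixed && length(unique(x)) == 1L) x[1] <- 1L - x[1]
  list(a = a, b = b, cc = rep(0, n_items), x = x,
       pool = item_pool(a = a, b = b, c = 0))
}

# small fixed pools shared by several tests
tiny_pool <- function() item_pool(a = c(1, 1.2, 0.8), b = c(0, 2, 0), c = 0,
                                  id = c("I001", "I002", "I003"))

# quick config for engine tests: small pool, cheap termination; overrides win
small_config <- function(...) {
  base <- list(n_simulees = 20L, pool_size = 40L,
               seeds = list(pool = 201L, simulees = 202L,
                            responses = 203L, selection = 204L))
  args <- utils::modifyList(base, list(...))
  do.call(cat_config, args)
}
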