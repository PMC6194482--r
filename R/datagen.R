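#' Specify a sampling distribution for data generation
#'
#' Distribution families available for generating true abilities, item
#' parameters and initial interim scores: normal (mean, sd), uniform
#' (min < max), beta (shape1, shape2 > 0, with optional location/scale so a
#' bounded parameter such as a discrimination can be generated on any
#' interval) and constant (every draw equals `value`; supports designs that
#' replicate thousands of simulees at one fixed theta).
#'
#' @param family one of `"normal"`, `"uniform"`, `"beta"`, `"constant"`.
#' @param mean,sd normal parameters (`sd > 0`).
#' @param min,max uniform bounds (`min < max`, or `min == max` for a point).
#' @param shape1,shape2 beta shapes (> 0).
#' @param location,scale affine transform applied to beta draws; default
#'   support (0, 1).
#' @param value the constant for `family = "constant"`.
#' @return a list of class `dist_spec`.
#' @export
dist_spec <- function(family = c("normal", "uniform", "beta", "constant"),
                      mean = 0, sd = 1, min = 0, max = 1,
                      shape1 = 1, shape2 = 1, location = 0, scale = 1,
                      value = 0) {
  family <- match.arg(family)
  spec <- switch(family,
    normal = {
      if (!is.finite(sd) || sd <= 0) stop("normal `sd` must be > 0")
      list(family = family, mean = mean, sd = sd)
    },
    uniform = {
      if (!is.finite(min) || !is.finite(max) || min > max)
        stop("uniform requires finite `min` <= `max`")
      list(family = family, min = min, max = max)
    },
    beta = {
      if (shape1 <= 0 || shape2 <= 0) stop("beta shapes must be > 0")
      list(family = family, shape1 = shape1, shape2 = shape2,
           location = location, scale = scale)
    },
    constant = list(family = family, value = value)
  )
  structure(spec, class = "dist_spec")
}

#' Draw from a distribution specification
#'
#' Uses the current RNG state; wrap in [stream_do()] (or call the
#' `generate_*` functions, which do) for named-stream reproducibility.
#'
#' @param n number of draws.
#' @param spec a [dist_spec()]; a single number is promoted to a constant.
#' @return numeric vector of length `n`.
#' @export
draw_dist <- function(n, spec) {
  if (is.numeric(spec) && length(spec) == 1L)
    spec <- dist_spec("constant", value = spec)
  if (!inherits(spec, "dist_spec")) stop("`spec` must be a dist_spec")
  switch(spec$family,
    normal   = stats::rnorm(n, spec$mean, spec$sd),
    uniform  = stats::runif(n, spec$min, spec$max),
    beta     = spec$location + spec$scale * stats::rbeta(n, spec$shape1, spec$shape2),
    constant = rep(spec$value, n)
  )
}

#' Generate simulees
#'
#' Draws `n` simulated examinees with known true abilities from `theta`
#' (default standard normal). Ids are zero-padded sequential integers so
#' lexical and numeric order agree.
#'
#' @param n number of simulees (>= 1).
#' @param theta a [dist_spec()] for the true-theta distribution.
#' @param seed optional integer seed for a dedicated simulee stream; when
#'   `NULL` the current RNG state is used.
#' @return a data frame of class `simulee_set` with columns `id`,
#'   `theta_true`.
#' @export
generate_simulees <- function(n, theta = dist_spec("normal", 0, 1),
                              seed = NULL) {
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1")
  n <- as.integer(n)
  draw <- function() draw_dist(n, theta)
  th <- if (is.null(seed)) draw() else stream_do(rng_stream(seed), draw)
  out <- data.frame(id = sprintf("S%0*d", max(4L, nchar(n)), seq_len(n)),
                    theta_true = th, stringsAsFactors = FALSE)
  class(out) <- c("simulee_set", "data.frame")
  out
}

#' Generate a calibrated item pool from parameter distributions
#'
#' Each parameter is drawn independently; `c` defaults to the constant 0
#' (2PL). Draws violating the item-parameter invariants (a <= 0, c outside
#' \[0, 1)) are an error, not silently clipped: fix the spec instead.
#'
#' @param n pool size (>= 1).
#' @param a,b,c [dist_spec()]s (or single numbers) for discrimination,
#'   difficulty, guessing.
#' @param content optional character vector of content-area labels assigned
#'   cyclically, or a vector of length `n`.
#' @param seed optional integer seed for a dedicated pool stream.
#' @return an `item_pool`.
#' @export
generate_item_pool <- function(n,
                               a = dist_spec("uniform", min = 0.5, max = 1.2),
                               b = dist_spec("uniform", min = -3, max = 3),
                               c = 0, content = NULL, seed = NULL) {
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1")
  n <- as.integer(n)
  draw <- function() list(a = draw_dist(n, a), b = draw_dist(n, b),
                          c = draw_dist(n, c))
  par <- if (is.null(seed)) draw() else stream_do(rng_stream(seed), draw)
  if (any(par$a <= 0))
    stop("discrimination spec produced a <= 0; choose a positive-support spec")
  if (any(par$c < 0 | par$c >= 1))
    stop("guessing spec produced c outside [0, 1)")
  if (!is.null(content) && length(content) != n)
    content <- rep_len(content, n)
  item_pool(a = par$a, b = par$b, c = par$c, content = content)
}

#' Read / write simulee tables as tab-delimited text
#'
#' Plain TSV with header `id  theta_true`.
#'
#' @param path file path.
#' @param simulees a simulee table as from [generate_simulees()].
#' @return `read_simulees` returns a `simulee_set`; `write_simulees`
#'   returns `path` invisibly.
#' @export
read_simulees <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(id = "character"))
  if (anyDuplicated(df$id)) stop("simulee ids must be unique")
  class(df) <- c("simulee_set", "data.frame")
  df
}

#' @rdname read_simulees
#' @export
write_simulees <- function(simulees, path) {
  utils::write.table(simulees, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
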