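#' Model settings for the logistic IRT response function
#'
#' @param D positive logistic scaling constant. 1.7 makes the logistic curve
#'   approximate the normal ogive and is the convention the engine's default
#'   design is calibrated to.
#' @param see_convention `"sqrt"` computes the standard error of estimation
#'   as 1/sqrt(TIF) (the standard identity, the default); `"reciprocal"`
#'   computes the literal 1/TIF, provided for comparison only.
#' @return a list of class `model_settings`.
#' @export
model_settings <- function(D = 1.7, see_convention = c("sqrt", "reciprocal")) {
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D <= 0)
    stop("`D` must be a single positive number")
  structure(list(D = D, see_convention = match.arg(see_convention)),
            class = "model_settings")
}

# exponent clamp: exp(700) is the largest safely representable magnitude
.clamp_exp <- function(z) pmin(pmax(z, -700), 700)

#' 3PL item response function
#'
#' Probability of a correct response under the three-parameter logistic
#' model, P(theta) = c + (1 - c) / (1 + exp(-D a (theta - b))). With c = 0
#' this is the 2PL model; there is a single code path.
#'
#' Vectorised over items for a scalar `theta`, or over `theta` for a single
#' item.
#'
#' @param theta ability value(s) on the theta scale; must be finite.
#' @param items an `item_pool` (or any list with numeric `a`, `b`, `c`).
#' @param D logistic scaling constant.
#' @return probabilities in (c, 1).
#' @export
irt_prob <- function(theta, items, D = 1.7) {
  if (!all(is.finite(theta))) stop("`theta` must be finite")
  cc <- if (is.null(items$c)) 0 else items$c
  z <- .clamp_exp(D * items$a * (outer_theta(theta, items$b)))
  cc + (1 - cc) / (1 + exp(-z))
}

# theta - b with standard recycling; kept separate so both scalar-theta and
# scalar-item vectorisation share one rule
outer_theta <- function(theta, b) theta - b

#' Fisher information of an item
#'
#' I(theta) = D^2 a^2 (Q/P) ((P - c)/(1 - c))^2 with P the 3PL response
#' probability and Q = 1 - P; reduces to D^2 a^2 P Q for c = 0, maximised at
#' theta = b with value D^2 a^2 / 4.
#'
#' @inheritParams irt_prob
#' @return nonnegative information value(s).
#' @export
item_info <- function(theta, items, D = 1.7) {
  p <- irt_prob(theta, items, D)
  cc <- if (is.null(items$c)) 0 else items$c
  (D * items$a)^2 * ((1 - p) / p) * ((p - cc) / (1 - cc))^2
}

#' Test information function
#'
#' Sum of item informations over a set of items; additive by construction,
#' zero for an empty set. Vectorised over `theta`.
#'
#' @param theta ability value(s).
#' @param items an `item_pool` (possibly zero rows).
#' @param D logistic scaling constant.
#' @return nonnegative value(s), one per element of `theta`.
#' @export
test_info <- function(theta, items, D = 1.7) {
  n <- if (is.data.frame(items)) nrow(items) else length(items$a)
  if (n == 0L) return(rep(0, length(theta)))
  vapply(theta, function(th) sum(item_info(th, items, D)), numeric(1))
}

#' Standard error of estimation from test information
#'
#' @param tif positive test information value(s).
#' @param convention `"sqrt"` for 1/sqrt(TIF) (default), `"reciprocal"` for
#'   the literal 1/TIF (comparison only; see [model_settings()]).
#' @return positive SEE value(s), strictly decreasing in `tif`.
#' @export
see_from_tif <- function(tif, convention = c("sqrt", "reciprocal")) {
  convention <- match.arg(convention)
  if (any(!is.finite(tif) | tif <= 0))
    stop("SEE is undefined for non-positive test information")
  if (convention == "sqrt") 1 / sqrt(tif) else 1 / tif
}

#' Draw Bernoulli item responses
#'
#' Samples scored responses (1 = correct) with probability given by the item
#' response function at the examinee's true theta. Uses the current RNG
#' state; wrap in [stream_do()] for named-stream reproducibility.
#'
#' @inheritParams irt_prob
#' @return integer vector of 0/1 responses, one per item.
#' @export
draw_response <- function(theta, items, D = 1.7) {
  p <- irt_prob(theta, items, D)
  as.integer(stats::runif(length(p)) < p)
}
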