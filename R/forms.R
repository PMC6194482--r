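#' Count the possible adaptive test forms
#'
#' The number of ordered k-item selections from a J-item pool,
#' J! / (J - k)!, computed exactly with arbitrary-precision integer
#' arithmetic (a base-1e9 digit vector; each partial product stays well
#' inside the exact-double range). The count explodes combinatorially --
#' 30 items from a 500-item pool already allow about 3.8e80 forms -- which
#' is why adaptive programs are evaluated by simulation rather than by
#' enumerating forms.
#'
#' @param J pool size.
#' @param k test length (`k <= J`).
#' @return an object of class `bigint`; use [format()] for the exact
#'   decimal string and [format_sci()] for scientific notation.
#' @export
count_possible_forms <- function(J, k) {
  if (k > J) stop("`k` must be <= `J`")
  if (k < 1 || J < 1) stop("`J` and `k` must be >= 1")
  d <- 1  # little-endian base-1e9 digits
  for (m in seq.int(J - k + 1, J)) {
    d <- d * m
    carry <- 0
    for (i in seq_along(d)) {
      x <- d[i] + carry
      d[i] <- x %% 1e9
      carry <- x %/% 1e9
    }
    while (carry > 0) {
      d <- c(d, carry %% 1e9)
      carry <- carry %/% 1e9
    }
  }
  structure(list(digits = d), class = "bigint")
}

#' @export
format.bigint <- function(x, ...) {
  d <- rev(x$digits)
  paste0(format(d[1], scientific = FALSE),
         paste(sprintf("%09.0f", d[-1]), collapse = ""))
}

#' @export
print.bigint <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Render an exact integer in scientific notation
#'
#' Six significant digits by default, in the `3.83359E+80` style.
#'
#' @param x a `bigint` from [count_possible_forms()].
#' @param sig number of significant digits.
#' @return a character scalar.
#' @export
format_sci <- function(x, sig = 6) {
  s <- format(x)
  expo <- nchar(s) - 1L
  if (nchar(s) <= sig)
    mant <- as.numeric(s) / 10^expo
  else {
    head <- as.numeric(substr(s, 1, sig + 1L))
    mant <- round(head / 10) / 10^(sig - 1L)
    if (mant >= 10) {  # rounding carried into a new leading digit
      mant <- mant / 10
      expo <- expo + 1L
    }
  }
  sprintf("%.*fE+%d", sig - 1L, mant, expo)
}
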