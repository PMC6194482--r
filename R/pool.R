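#' Construct a calibrated item pool
#'
#' An item pool is a data frame with one row per item and columns `id`
#' (unique label), `a` (discrimination, > 0), `b` (difficulty, theta scale),
#' `c` (pseudo-guessing probability, in \[0, 1); 0 gives the 2PL special
#' case) and optionally `content` (categorical area label used by content
#' balancing).
#'
#' @param a numeric vector of discriminations.
#' @param b numeric vector of difficulties.
#' @param c numeric vector (or scalar) of pseudo-guessing parameters.
#' @param id item labels; defaults to zero-padded sequential integers.
#' @param content optional character vector of content-area labels.
#' @return a data frame of class `item_pool`.
#' @export
item_pool <- function(a, b, c = 0, id = NULL, content = NULL) {
  n <- length(a)
  if (length(b) != n) stop("`a` and `b` must have the same length")
  c <- rep_len(c, n)
  if (is.null(id)) id <- sprintf("I%0*d", max(3L, nchar(n)), seq_len(n))
  id <- as.character(id)
  pool <- data.frame(id = id, a = as.numeric(a), b = as.numeric(b),
                     c = as.numeric(c), stringsAsFactors = FALSE)
  if (!is.null(content)) pool$content <- as.character(rep_len(content, n))
  class(pool) <- c("item_pool", "data.frame")
  validate_item_pool(pool)
  pool
}

#' Validate an item pool
#'
#' @param pool an `item_pool` or compatible data frame.
#' @return the pool, invisibly, or an error describing the first violation.
#' @export
validate_item_pool <- function(pool) {
  req <- c("id", "a", "b", "c")
  miss <- setdiff(req, names(pool))
  if (length(miss)) stop("item pool is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(pool$id)) stop("item ids must be unique within a pool")
  if (!all(is.finite(pool$a)) || any(pool$a <= 0))
    stop("all discriminations `a` must be finite and > 0")
  if (!all(is.finite(pool$b))) stop("all difficulties `b` must be finite")
  if (!all(is.finite(pool$c)) || any(pool$c < 0 | pool$c >= 1))
    stop("all guessing parameters `c` must lie in [0, 1)")
  invisible(pool)
}

#' @export
print.item_pool <- function(x, ...) {
  cat(sprintf("Item pool: %d items (a in [%.3f, %.3f], b in [%.3f, %.3f]%s)\n",
              nrow(x), min(x$a), max(x$a), min(x$b), max(x$b),
              if (any(x$c > 0)) sprintf(", 3PL: max c = %.3f", max(x$c))
              else ", 2PL"))
  if (!is.null(x$content))
    cat("Content areas:", paste(sort(unique(x$content)), collapse = ", "), "\n")
  print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more items\n")
  invisible(x)
}

#' Read / write item pools as tab-delimited text
#'
#' Plain TSV with a header row `id  a  b  c  [content]`.
#'
#' @param path file path.
#' @param pool an `item_pool`.
#' @return `read_item_pool` returns an `item_pool`; `write_item_pool`
#'   returns `path` invisibly.
#' @export
read_item_pool <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(id = "character"))
  if (is.null(df$c)) df$c <- 0
  item_pool(a = df$a, b = df$b, c = df$c, id = df$id, content = df$content)
}

#' @rdname read_item_pool
#' @export
write_item_pool <- function(pool, path) {
  validate_item_pool(pool)
  utils::write.table(pool, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
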