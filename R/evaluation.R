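#' Measurement-precision summary statistics
#'
#' `bias` is the mean signed deviation of the estimated from the true
#' ability (systematic error); `mae` the mean absolute deviation (total
#' error, no cancellation); `rmse` the root mean squared deviation. All
#' average over simulees.
#'
#' @param theta_hat estimated abilities.
#' @param theta_true true abilities, same length.
#' @return a single number.
#' @export
bias <- function(theta_hat, theta_true) {
  .check_pair(theta_hat, theta_true)
  mean(theta_hat - theta_true)
}

#' @rdname bias
#' @export
mae <- function(theta_hat, theta_true) {
  .check_pair(theta_hat, theta_true)
  mean(abs(theta_hat - theta_true))
}

#' @rdname bias
#' @export
rmse <- function(theta_hat, theta_true) {
  .check_pair(theta_hat, theta_true)
  sqrt(mean((theta_hat - theta_true)^2))
}

.check_pair <- function(a, b) {
  if (length(a) == 0L || length(a) != length(b))
    stop("need two equal-length nonempty vectors")
}

#' Bin abilities on the theta scale
#'
#' Half-open intervals `[low, high)` between consecutive edges. With
#' `open_ends = TRUE` the extremes are open-ended (`theta < first edge` and
#' `theta >= last edge` become their own bins); otherwise values outside
#' the edges are dropped (`NA` bin).
#'
#' @param theta numeric vector.
#' @param edges strictly increasing bin edges (default the conventional
#'   unit edges -2..2).
#' @param open_ends include open-ended extreme bins?
#' @return a factor of bin labels, `NA` for dropped values.
#' @export
theta_bin <- function(theta, edges = c(-2, -1, 0, 1, 2), open_ends = TRUE) {
  if (is.unsorted(edges, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  brk <- if (open_ends) c(-Inf, edges, Inf) else edges
  cut(theta, breaks = brk, right = FALSE, include.lowest = FALSE)
}

#' Conditional precision statistics by true-theta bin
#'
#' Assigns each simulee to a bin by true theta and computes, per bin, the
#' conditional bias (CBIAS), MAE (CMAE), RMSE (CRMSE), mean final SEE
#' (CSEE) and mean test length, plus the overall statistics. Empty bins are
#' absent from the table (not reported as zero). The count-weighted mean of
#' CBIAS over bins reproduces the overall bias exactly; likewise the
#' count-weighted mean of CRMSE^2 reproduces the overall RMSE^2.
#'
#' @param admin an admin data frame (the `admin` element of a `cat_sim`, or
#'   from [read_admin_log()]): columns `theta_true`, `theta_hat`, `see`,
#'   `n_items`.
#' @param edges bin edges on the theta scale.
#' @param open_ends include open-ended extreme bins (see [theta_bin()]).
#' @return a list of class `precision_summary`: `overall` (bias, mae,
#'   rmse, mean_see, mean_length, n) and `by_bin` (one row per nonempty
#'   bin).
#' @export
conditional_stats <- function(admin, edges = c(-2, -1, 0, 1, 2),
                              open_ends = TRUE) {
  if (nrow(admin) == 0L) stop("no administration records")
  bin <- theta_bin(admin$theta_true, edges, open_ends)
  keep <- !is.na(bin)
  a <- admin[keep, ]
  bin <- droplevels(bin[keep])
  per <- lapply(split(a, bin), function(g) {
    data.frame(n = nrow(g),
               cbias = bias(g$theta_hat, g$theta_true),
               cmae = mae(g$theta_hat, g$theta_true),
               crmse = rmse(g$theta_hat, g$theta_true),
               csee = mean(g$see),
               mean_length = mean(g$n_items))
  })
  by_bin <- cbind(bin = names(per), do.call(rbind, per))
  rownames(by_bin) <- NULL
  structure(list(
    overall = data.frame(n = nrow(a),
                         bias = bias(a$theta_hat, a$theta_true),
                         mae = mae(a$theta_hat, a$theta_true),
                         rmse = rmse(a$theta_hat, a$theta_true),
                         mean_see = mean(a$see),
                         mean_length = mean(a$n_items)),
    by_bin = by_bin, edges = edges), class = "precision_summary")
}

#' @export
print.precision_summary <- function(x, digits = 4, ...) {
  cat("Overall precision:\n")
  print(format(x$overall, digits = digits), row.names = FALSE)
  cat("\nConditional (by true-theta bin):\n")
  print(format(x$by_bin, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Conditional standard error of measurement at a fixed theta
#'
#' The CSEM point estimate at one true theta: the RMSE over replicate
#' simulees who all share that true value.
#'
#' @param admin admin frame whose simulees all share one `theta_true`.
#' @param tolerance allowed spread of `theta_true` before erroring.
#' @return the CSEM (a nonnegative number).
#' @export
csem_at_theta <- function(admin, tolerance = 1e-9) {
  if (diff(range(admin$theta_true)) > tolerance)
    stop("all records must share a single true theta; use conditional_stats for mixed designs")
  rmse(admin$theta_hat, admin$theta_true)
}

#' Average test-overlap index for fixed-length CAT
#'
#' The expected proportion of items shared by two randomly chosen
#' examinees' forms, computed from exposure rates:
#' T = p sum(r_j^2) / (k (p - 1)) - 1 / (p - 1), with r_j the exposure
#' proportion (count / p), p the number of fixed-length forms and k the
#' form length. Equals the mean pairwise overlap
#' ([pairwise_overlap()]) exactly. Identical forms give 1; pairwise
#' disjoint forms give 0.
#'
#' Variable-length runs are refused (the formula presumes a single k); use
#' [pairwise_overlap()] there.
#'
#' @param x a `cat_sim` from a fixed-length run, or a vector of per-item
#'   exposure counts.
#' @param p number of examinees (required for a count vector).
#' @param k test length (required for a count vector).
#' @return the overlap index.
#' @export
overlap_index <- function(x, p = NULL, k = NULL) {
  if (inherits(x, "cat_sim")) {
    len <- x$admin$n_items
    if (length(unique(len)) != 1L)
      stop("overlap_index requires fixed-length forms; use pairwise_overlap for variable-length runs")
    return(overlap_index(x$usage$exposure_count, p = nrow(x$admin),
                         k = len[1]))
  }
  if (is.null(p) || is.null(k)) stop("`p` and `k` are required")
  if (p < 2) stop("overlap is undefined for fewer than 2 examinees")
  r <- x / p
  p * sum(r^2) / (k * (p - 1)) - 1 / (p - 1)
}

#' Brute-force pairwise test overlap
#'
#' Mean (and maximum) over all examinee pairs of the shared-item count
#' divided by the form length (fixed length) or by the mean form length
#' (variable length). The mean equals [overlap_index()] exactly on
#' fixed-length runs; the maximum surfaces the most severe overlap cases
#' that the average can mask.
#'
#' @param forms a `cat_sim`, or a list of per-examinee administered item-id
#'   vectors.
#' @return list with `mean` and `max` overlap.
#' @export
pairwise_overlap <- function(forms) {
  if (inherits(forms, "cat_sim"))
    forms <- lapply(forms$records, `[[`, "items")
  p <- length(forms)
  if (p < 2) stop("need at least 2 forms")
  k <- mean(lengths(forms))
  tot <- 0
  mx <- 0
  for (i in seq_len(p - 1)) {
    for (j in seq.int(i + 1, p)) {
      ov <- length(intersect(forms[[i]], forms[[j]])) / k
      tot <- tot + ov
      if (ov > mx) mx <- ov
    }
  }
  list(mean = tot / (p * (p - 1) / 2), max = mx)
}

#' Test-security summary
#'
#' The five exposure diagnostics: maximum item exposure rate; conditional
#' maximum exposure within each true-theta bin (max over items of
#' administrations to that bin's simulees divided by the bin count);
#' percentage of pool items never administered; standard deviation of the
#' exposure rates; and the Pearson correlation between the items'
#' discrimination (a) parameters and their exposure counts.
#'
#' @param sim a `cat_sim`.
#' @param edges theta bin edges for the conditional maximum.
#' @param open_ends see [theta_bin()].
#' @return a list of class `security_summary`.
#' @export
security_summary <- function(sim, edges = c(-2, -1, 0, 1, 2),
                             open_ends = TRUE) {
  stopifnot(inherits(sim, "cat_sim"))
  usage <- sim$usage
  J <- nrow(usage)
  bin <- theta_bin(sim$admin$theta_true, edges, open_ends)
  cond <- vapply(levels(bin), function(lv) {
    idx <- which(!is.na(bin) & bin == lv)
    if (length(idx) == 0L) return(NA_real_)
    counts <- integer(J)
    for (i in idx) {
      it <- sim$records[[i]]$items
      counts[it] <- counts[it] + 1L
    }
    max(counts) / length(idx)
  }, numeric(1))
  a_cor <- if (stats::sd(usage$exposure_count) == 0) NA_real_
  else stats::cor(sim$pool$a, usage$exposure_count)
  structure(list(
    max_exposure_rate = max(usage$exposure_rate),
    max_exposure_count = max(usage$exposure_count),
    conditional_max_exposure = cond[!is.na(cond)],
    pct_unused = 100 * mean(usage$exposure_count == 0),
    n_unused = sum(usage$exposure_count == 0),
    sd_exposure_rate = stats::sd(usage$exposure_rate),
    cor_a_exposure = a_cor), class = "security_summary")
}

#' @export
print.security_summary <- function(x, ...) {
  cat(sprintf("Max exposure rate: %.3f (count %d)\n",
              x$max_exposure_rate, x$max_exposure_count))
  cat(sprintf("Unused items: %d (%.1f%% of pool)\n", x$n_unused,
              x$pct_unused))
  cat(sprintf("SD of exposure rates: %.4f\n", x$sd_exposure_rate))
  cat(sprintf("cor(a, exposure): %.3f\n", x$cor_a_exposure))
  cat("Conditional max exposure by theta bin:\n")
  print(round(x$conditional_max_exposure, 3))
  invisible(x)
}
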