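#' Settings for item selection, exposure control and content balancing
#'
#' @param criterion `"MFI"` (maximized Fisher information at the current
#'   interim estimate) or `"b_matching"` (minimise |b - theta_hat|,
#'   ignoring discrimination).
#' @param exposure_control `"none"`, `"randomesque"` (administer a random
#'   pick among the `randomesque_k` best-ranked candidates) or
#'   `"sympson_hetter"` (administer the selected item with item-specific
#'   probability K_j).
#' @param randomesque_k number of best-ranked candidates the randomesque
#'   pick draws from. Also applies under Sympson-Hetter control (the
#'   engine's canonical order is content filter, then criterion ranking,
#'   then randomesque pick, then the Sympson-Hetter filter); set it to 1
#'   there for a pure criterion pick.
#' @param sh_target_rate target maximum exposure rate for Sympson-Hetter
#'   calibration, in (0, 1].
#' @param sh_control optional data frame `id`, `K` of Sympson-Hetter
#'   control probabilities (from [calibrate_sympson_hetter()] or
#'   [read_sh_table()]); items not listed get K = 1.
#' @param content_targets optional named numeric vector of target content
#'   proportions (must sum to 1); enables constrained-CAT content
#'   balancing.
#' @return a list of class `selection_settings`.
#' @export
selection_settings <- function(criterion = c("MFI", "b_matching"),
                               exposure_control = c("none", "randomesque",
                                                    "sympson_hetter"),
                               randomesque_k = 5L,
                               sh_target_rate = 0.2,
                               sh_control = NULL,
                               content_targets = NULL) {
  criterion <- match.arg(criterion)
  exposure_control <- match.arg(exposure_control)
  if (randomesque_k < 1) stop("`randomesque_k` must be >= 1")
  if (sh_target_rate <= 0 || sh_target_rate > 1)
    stop("`sh_target_rate` must be in (0, 1]")
  if (!is.null(content_targets)) {
    if (is.null(names(content_targets)) || any(content_targets < 0) ||
        abs(sum(content_targets) - 1) > 1e-8)
      stop("`content_targets` must be named, nonnegative, and sum to 1")
  }
  structure(list(criterion = criterion, exposure_control = exposure_control,
                 randomesque_k = as.integer(randomesque_k),
                 sh_target_rate = sh_target_rate, sh_control = sh_control,
                 content_targets = content_targets),
            class = "selection_settings")
}

#' Rank candidate items under the selection criterion
#'
#' MFI ranks by descending Fisher information at `theta_hat`; b-matching by
#' ascending |b - theta_hat|. Ties are broken by ascending item id, so the
#' ranking is deterministic.
#'
#' @param theta_hat current interim ability estimate.
#' @param available candidate items (`item_pool` rows).
#' @param settings a [selection_settings()].
#' @param model a [model_settings()].
#' @return integer vector of row positions into `available`, best first.
#' @export
rank_candidates <- function(theta_hat, available, settings,
                            model = model_settings()) {
  n <- if (is.data.frame(available)) nrow(available) else length(available$a)
  if (n == 0L) stop("candidate set is empty: item pool exhausted")
  key <- switch(settings$criterion,
    MFI        = -item_info(theta_hat, available, model$D),
    b_matching = abs(available$b - theta_hat))
  order(key, available$id)
}

#' Randomesque pick among the top-ranked candidates
#'
#' Uniform random choice among the top `min(k, length(ranked))` entries.
#' Uses the current RNG state; the engine wraps this in its selection
#' stream.
#'
#' @param ranked ranking as returned by [rank_candidates()] (best first).
#' @param k number of best candidates to draw from.
#' @return one element of `ranked`.
#' @export
pick_randomesque <- function(ranked, k) {
  if (length(ranked) == 0L) stop("candidate set is empty")
  k <- min(as.integer(k), length(ranked))
  ranked[sample.int(k, 1L)]
}

#' Sympson-Hetter administration filter
#'
#' A selected item is administered with its control probability K_j. On a
#' FALSE the engine marks the item ineligible for the current examinee and
#' re-selects; if every item becomes ineligible the last candidate is
#' administered anyway and the record flagged.
#'
#' @param K control probability in (0, 1].
#' @return logical: administer the item?
#' @export
sympson_hetter_filter <- function(K) {
  stats::runif(1) <= K
}

# per-item K vector aligned with a pool, defaulting to 1
.sh_K_vector <- function(pool, sh_control) {
  K <- rep(1, nrow(pool))
  if (!is.null(sh_control)) {
    m <- match(pool$id, as.character(sh_control$id))
    K[!is.na(m)] <- sh_control$K[m[!is.na(m)]]
  }
  if (any(K <= 0 | K > 1)) stop("Sympson-Hetter K values must be in (0, 1]")
  K
}

#' Calibrate Sympson-Hetter control probabilities
#'
#' Iterative calibration: run a full simulation, observe each item's
#' selection probability P(S_j) (selections include administrations and
#' Sympson-Hetter rejections), update
#' K_j <- min(1, target / P(S_j)) (items never selected keep K_j = 1), and
#' repeat. Each cycle uses fresh administration seeds derived from the
#' configured selection seed so the fixed point is approached rather than
#' replayed.
#'
#' @param config a [cat_config()] whose selection settings use
#'   Sympson-Hetter exposure control.
#' @param pool the item pool.
#' @param simulees simulee table used for the calibration runs.
#' @param cycles number of calibration rounds; 0 returns the identity table
#'   (all K = 1).
#' @return data frame `id`, `K` (one row per pool item).
#' @export
calibrate_sympson_hetter <- function(config, pool, simulees, cycles) {
  validate_item_pool(pool)
  target <- config$selection$sh_target_rate
  K <- data.frame(id = pool$id, K = rep(1, nrow(pool)),
                  stringsAsFactors = FALSE)
  if (cycles < 1) return(K)
  for (cyc in seq_len(cycles)) {
    cfg <- config
    cfg$selection$sh_control <- K
    cfg$seeds$responses <- derive_seed(config$seeds$responses, cyc)
    cfg$seeds$selection <- derive_seed(config$seeds$selection, cyc)
    sim <- run_simulation(cfg, pool, simulees)
    ps <- sim$usage$selection_count / nrow(simulees)
    K$K <- ifelse(ps == 0, 1, pmin(1, target / ps))
  }
  K
}

#' Restrict candidates to the most deficient content area
#'
#' Constrained-CAT content balancing: compute the administered proportion
#' per content area, find the area with the largest target-minus-current
#' deficit (ties broken alphabetically), and return the candidate positions
#' in that area. If the deficit area has no remaining items, all
#' candidates are returned and the fallback is flagged.
#'
#' @param available candidate items (must carry a `content` column).
#' @param administered_content character vector of content labels of the
#'   items administered so far.
#' @param settings a [selection_settings()] with `content_targets`.
#' @return list with `positions` (integer positions into `available`) and
#'   `fallback` (logical).
#' @export
content_deficit_filter <- function(available, administered_content, settings) {
  targets <- settings$content_targets
  if (is.null(targets)) stop("`content_targets` not set")
  if (is.null(available$content) || anyNA(available$content))
    stop("every item must carry a content label for content balancing")
  n_avail <- length(available$content)
  areas <- sort(names(targets))
  n_admin <- length(administered_content)
  current <- if (n_admin == 0) stats::setNames(rep(0, length(areas)), areas)
  else table(factor(administered_content, levels = areas)) / n_admin
  deficit <- targets[areas] - as.numeric(current[areas])
  pick_area <- areas[which.max(deficit)]  # which.max takes first = alphabetical tie-break
  pos <- which(available$content == pick_area)
  if (length(pos) == 0L) list(positions = seq_len(n_avail), fallback = TRUE)
  else list(positions = pos, fallback = FALSE)
}

#' Content-balanced candidate pick
#'
#' Applies [content_deficit_filter()], then the criterion ranking and the
#' randomesque pick within the restricted area (Sympson-Hetter filtering,
#' when enabled, is applied by the engine after this pick).
#'
#' @param theta_hat current interim estimate.
#' @param available candidate items.
#' @param administered_content content labels administered so far.
#' @param settings a [selection_settings()] with `content_targets`.
#' @param model a [model_settings()].
#' @return list with `position` (into `available`) and `fallback`.
#' @export
constrained_content_pick <- function(theta_hat, available,
                                     administered_content, settings,
                                     model = model_settings()) {
  filt <- content_deficit_filter(available, administered_content, settings)
  sub <- if (is.data.frame(available))
    available[filt$positions, , drop = FALSE]
  else lapply(available, `[`, filt$positions)
  ranked <- rank_candidates(theta_hat, sub, settings, model)
  k <- if (settings$exposure_control == "randomesque")
    settings$randomesque_k else 1L
  pick <- pick_randomesque(ranked, k)
  list(position = filt$positions[pick], fallback = filt$fallback)
}

#' Read / write Sympson-Hetter control tables
#'
#' Plain TSV with header `id  K`.
#'
#' @param path file path.
#' @param sh_table data frame `id`, `K`.
#' @return `read_sh_table` returns the table; `write_sh_table` returns
#'   `path` invisibly.
#' @export
read_sh_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(id = "character"))
  if (any(df$K <= 0 | df$K > 1)) stop("K values must be in (0, 1]")
  df
}

#' @rdname read_sh_table
#' @export
write_sh_table <- function(sh_table, path) {
  utils::write.table(sh_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
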