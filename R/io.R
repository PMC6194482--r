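#' Write / read the test-administration log
#'
#' One row per simulee: id, true theta, test length, final estimate, final
#' SEE, the SEE evaluated at the true theta over the administered items
#' (`true_see`), the termination reason, the initial interim score, any
#' flags, the response string, and the ordered comma-separated item-id
#' list. Tab-delimited with a header.
#'
#' @param sim a `cat_sim` from [run_simulation()] (or its `admin` frame).
#' @param path file path.
#' @return `write_admin_log` returns `path` invisibly; `read_admin_log`
#'   returns the admin data frame.
#' @export
write_admin_log <- function(sim, path) {
  admin <- if (inherits(sim, "cat_sim")) sim$admin else sim
  if (nrow(admin) == 0L) stop("no administration records to write")
  cols <- c("simulee_id", "theta_true", "n_items", "theta_hat", "see",
            "true_see", "termination_reason", "theta_init", "flags",
            "responses", "item_ids")
  utils::write.table(admin[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_admin_log
#' @export
read_admin_log <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(simulee_id = "character",
                                   responses = "character",
                                   item_ids = "character",
                                   flags = "character",
                                   termination_reason = "character"),
                    na.strings = "NA")
}

#' Write / read the per-item usage (exposure) table
#'
#' One row per pool item, zero-exposure items included: item id, exposure
#' count, exposure rate, selection count (selections include
#' Sympson-Hetter rejections) and the retirement-days placeholder column
#' (always 0; item retirement is not scheduled by this engine).
#'
#' @param usage the `usage` element of a `cat_sim`.
#' @param path file path.
#' @return `write_usage` returns `path` invisibly; `read_usage` the table.
#' @export
write_usage <- function(usage, path) {
  utils::write.table(usage, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_usage
#' @export
read_usage <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(id = "character"))
}

#' Write the full response matrix
#'
#' Simulees x full pool; cells are 0/1 for administered items and NA
#' otherwise, so each row's non-NA count equals the simulee's test length.
#'
#' @param sim a `cat_sim`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_response_matrix <- function(sim, path) {
  stopifnot(inherits(sim, "cat_sim"))
  J <- nrow(sim$pool)
  m <- matrix(NA_integer_, nrow = length(sim$records), ncol = J,
              dimnames = list(NULL, sim$pool$id))
  for (i in seq_along(sim$records)) {
    r <- sim$records[[i]]
    m[i, r$items] <- r$responses
  }
  df <- data.frame(simulee_id = sim$admin$simulee_id, m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the interim-estimation trace
#'
#' One row per administered item per simulee: simulee id, step index, item
#' id, response, and the interim theta estimate after that item (the
#' Newton-Raphson result after the update restrictions).
#'
#' @param sim a `cat_sim`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(sim, path) {
  stopifnot(inherits(sim, "cat_sim"))
  rows <- lapply(sim$records, function(r) {
    if (r$n_items == 0L) return(NULL)
    data.frame(simulee_id = r$simulee_id, step = seq_len(r$n_items),
               item_id = r$item_ids, response = r$responses,
               theta_interim = r$trajectory, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- run-configuration files -------------------------------------------

# parse one scalar: quoted string, none/true/false, number, or bare word
.cfg_value <- function(s) {
  s <- trimws(s)
  if (grepl(",", s, fixed = TRUE))
    return(unlist(lapply(strsplit(s, ",")[[1]], .cfg_value)))
  if (grepl('^".*"$', s) || grepl("^'.*'$", s))
    return(substr(s, 2, nchar(s) - 1))
  if (s %in% c("none", "null")) return(NULL)
  if (s == "true") return(TRUE)
  if (s == "false") return(FALSE)
  n <- suppressWarnings(as.numeric(s))
  if (!is.na(n)) return(n)
  s
}

#' Read a run-configuration file
#'
#' Flat sectioned key = value text (a TOML subset): `[model]`,
#' `[estimation]`, `[selection]`, `[termination]`, `[initial_theta]`,
#' `[run]` (`n_simulees`, `pool_size`), `[seeds]` and `[outputs]` sections,
#' with `#` comments, quoted strings, numbers, `true`/`false`, `none`, and
#' comma-separated pairs for intervals (e.g. `theta_range = -4, 4`). Keys
#' are the arguments of the corresponding settings constructors.
#'
#' @param path file path.
#' @return a [cat_config()].
#' @export
read_cat_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- NA_character_
  cfg <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      cfg[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.na(section)) stop("config key outside any [section]: ", ln)
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- .cfg_value(paste(kv[-1], collapse = "="))
      cfg[[section]][key] <- list(val)  # keeps NULLs
    } else stop("unparseable config line: ", ln)
  }
  build <- function(fn, args) do.call(fn, args %||% list())
  args <- function(section, fn) {
    a <- cfg[[section]] %||% list()
    a[intersect(names(a), names(formals(fn)))]
  }
  init <- cfg$initial_theta
  config <- cat_config(
    model = build(model_settings, args("model", model_settings)),
    estimation = build(estimation_settings,
                       args("estimation", estimation_settings)),
    selection = build(selection_settings,
                      args("selection", selection_settings)),
    termination = build(termination_settings,
                        args("termination", termination_settings)),
    initial_theta = if (is.null(init)) dist_spec("uniform", min = -0.5,
                                                 max = 0.5)
    else build(dist_spec, init),
    n_simulees = cfg$run$n_simulees %||% 5000L,
    pool_size = cfg$run$pool_size %||% 300L,
    seeds = utils::modifyList(list(pool = 101L, simulees = 102L,
                                   responses = 103L, selection = 104L),
                              cfg$seeds %||% list()),
    outputs = cfg$outputs %||% list())
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a
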