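# One-parameter bifurcation scans and config-driven runs.

#' Sweep a parameter and track steady-state branches
#'
#' Enumerates and classifies all steady states at each grid value of one
#' parameter, tracks branches, and brackets fold (saddle-node) points where
#' the branch count changes, refining each bracket by bisection on the root
#' count.
#'
#' @param params a [kpr_params()] object.
#' @param name parameter to sweep (e.g. `"L1"`, `"nu1"`, `"ST"`).
#' @param grid numeric vector of parameter values (log-spaced recommended).
#' @param refine_rel relative width to which fold brackets are refined by
#'   bisection (default `1e-3`).
#' @return An object of class `kpr_scan`: list with `points` (tibble:
#'   `value`, `branch`, `S`, `CN`, `stability`, `stable`, `n_states`) and
#'   `folds` (tibble of refined parameter intervals where the steady-state
#'   count changes).
#' @examples
#' \donttest{
#' sc <- scan_parameter(example_params("fig2"), "L1",
#'                      10^seq(-4, 1, length.out = 60))
#' sc$folds
#' autoplot(sc)
#' }
#' @export
scan_parameter <- function(params, name, grid, refine_rel = 1e-3) {
  stopifnot(inherits(params, "kpr_params"), is.character(name), length(name) == 1L)
  count_at <- function(v) {
    p <- do.call(update_params, c(list(params), stats::setNames(list(v), name)))
    ss <- if (p$agonist_only) enumerate_steady_states(p)
          else antagonist_steady_states(p)
    nrow(ss)
  }
  states_at <- function(v) {
    p <- do.call(update_params, c(list(params), stats::setNames(list(v), name)))
    ss <- if (p$agonist_only) enumerate_steady_states(p)
          else antagonist_steady_states(p)
    classify_steady_states(ss, p)
  }
  CN_col <- paste0("C", params$N)
  prev_S <- NULL; prev_id <- NULL; next_id <- 1L
  rows <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    ss <- states_at(grid[i])
    S <- ss$S
    if (is.null(prev_S)) {
      ids <- seq_along(S); next_id <- length(S) + 1L
    } else {
      ids <- integer(length(S)); avail <- seq_along(prev_S)
      for (k in order(S)) {
        if (length(avail)) {
          pick <- avail[which.min(abs(log(S[k]) - log(prev_S[avail])))]
          ids[k] <- prev_id[pick]; avail <- setdiff(avail, pick)
        } else {
          ids[k] <- next_id; next_id <- next_id + 1L
        }
      }
    }
    prev_S <- S; prev_id <- ids
    rows[[i]] <- tibble::tibble(value = grid[i], branch = ids, S = S,
                                CN = ss[[CN_col]],
                                stability = ss$stability,
                                stable = grepl("^stable", ss$stability),
                                n_states = nrow(ss))
  }
  points <- dplyr::bind_rows(rows)
  counts <- dplyr::distinct(points[, c("value", "n_states")])
  folds <- list()
  for (i in seq_len(nrow(counts) - 1L)) {
    if (counts$n_states[i] != counts$n_states[i + 1L]) {
      lo <- counts$value[i]; hi <- counts$value[i + 1L]
      n_lo <- counts$n_states[i]
      while ((hi - lo) / max(abs(hi), abs(lo)) > refine_rel) {
        mid <- sqrt(lo * hi)
        if (count_at(mid) == n_lo) lo <- mid else hi <- mid
      }
      folds[[length(folds) + 1L]] <-
        tibble::tibble(lower = lo, upper = hi,
                       count_below = counts$n_states[i],
                       count_above = counts$n_states[i + 1L])
    }
  }
  structure(list(points = points,
                 folds = if (length(folds)) dplyr::bind_rows(folds)
                         else tibble::tibble(lower = numeric(0), upper = numeric(0),
                                             count_below = integer(0),
                                             count_above = integer(0)),
                 parameter = name, params = params),
            class = "kpr_scan")
}

#' @export
print.kpr_scan <- function(x, ...) {
  cat(sprintf("<kpr_scan> %s over [%g, %g], %d grid points, %d fold interval(s)\n",
              x$parameter, min(x$points$value), max(x$points$value),
              length(unique(x$points$value)), nrow(x$folds)))
  invisible(x)
}

#' Run a config-driven analysis bundle
#'
#' Reads a config file (YAML or JSON) with a `model` block (the parameter
#' keys of [kpr_params()]) and optional task blocks, runs the requested
#' analyses, and writes deterministic CSV artifacts plus a `manifest.json`
#' recording parameters, seed and package version.
#'
#' Recognized task blocks:
#' \describe{
#'   \item{`steady_states: true`}{enumerate + classify; writes
#'     `states.csv` with columns `S,C0..CN,residual,stability`.}
#'   \item{`scan: {name, from, to, n}`}{log-spaced [scan_parameter()] sweep;
#'     writes `scan.csv` and `folds.csv`.}
#'   \item{`simulate: {t_end, n_starts}`}{seeded multistart integration
#'     ([basin_sample()]); writes `basins.csv`.}
#'   \item{`response: {l1_from, l1_to, n}`}{[response_function()] over a
#'     log-spaced `L1` grid; writes `response.csv`.}
#' }
#'
#' @param config path to the config file.  A `seed` key is required when a
#'   `simulate` block is present.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a named list of the written file paths.
#' @export
run_config <- function(config, out_dir = ".") {
  cfg <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else yaml::read_yaml(config)
  if (is.null(cfg$model))
    stop("config is missing required key: model", call. = FALSE)
  names(cfg$model)[names(cfg$model) %in% c("FALSE", "no")] <- "N"
  # same YAML 1.1 pitfall for the grid-size key `n` in task blocks
  for (blk in c("scan", "response")) {
    if (is.null(cfg[[blk]])) next
    names(cfg[[blk]])[names(cfg[[blk]]) %in% c("FALSE", "no")] <- "n"
  }
  params <- do.call(kpr_params, cfg$model)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- list()
  put <- function(df, file) {
    path <- file.path(out_dir, file)
    utils::write.csv(df, path, row.names = FALSE)
    written[[file]] <<- path
  }
  if (isTRUE(cfg$steady_states)) {
    ss <- if (params$agonist_only) enumerate_steady_states(params)
          else antagonist_steady_states(params)
    put(as.data.frame(classify_steady_states(ss, params)), "states.csv")
  }
  if (!is.null(cfg$scan)) {
    for (k in c("name", "from", "to", "n"))
      if (is.null(cfg$scan[[k]]))
        stop("config is missing required key: scan.", k, call. = FALSE)
    sc <- scan_parameter(params, cfg$scan$name,
                         10^seq(log10(cfg$scan$from), log10(cfg$scan$to),
                                length.out = cfg$scan$n))
    put(as.data.frame(sc$points), "scan.csv")
    put(as.data.frame(sc$folds), "folds.csv")
  }
  if (!is.null(cfg$simulate)) {
    if (is.null(cfg$seed))
      stop("config is missing required key: seed (needed by simulate)",
           call. = FALSE)
    b <- basin_sample(params,
                      n_starts = cfg$simulate$n_starts %||% 20L,
                      seed = cfg$seed)
    put(as.data.frame(b), "basins.csv")
  }
  if (!is.null(cfg$response)) {
    for (k in c("l1_from", "l1_to", "n"))
      if (is.null(cfg$response[[k]]))
        stop("config is missing required key: response.", k, call. = FALSE)
    rc <- response_function(params,
                            L1_grid = 10^seq(log10(cfg$response$l1_from),
                                             log10(cfg$response$l1_to),
                                             length.out = cfg$response$n))
    put(as.data.frame(rc), "response.csv")
  }
  manifest <- list(
    package = "tcrkpr",
    version = as.character(utils::packageVersion("tcrkpr")),
    config = normalizePath(config),
    seed = cfg$seed,
    model = params[setdiff(names(params), "agonist_only")])
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written[["manifest.json"]] <- mpath
  invisible(written)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
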