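#' Parameter set for the TCR phosphorylation / SHP-1 feedback model
#'
#' Bundles the rate constants and conserved totals that define one instance
#' of the mass-action model of early T-cell activation.  TCR complexes bound
#' to agonist (concentrations `C0..CN`) or antagonist (`D0..DN`) are
#' phosphorylated sequentially on `N` sites; the phosphatase SHP-1 (active
#' concentration `S`) is activated by the singly phosphorylated complexes and
#' dephosphorylates all of them, closing a negative feedback loop.
#'
#' All units are arbitrary (concentration and time), matching the convention
#' of the underlying model; no unit conversion is applied.
#'
#' @param alpha SHP-1 activation rate constant (per concentration per time).
#' @param beta SHP-1 deactivation rate (per time).
#' @param gamma dephosphorylation rate constant of SHP-1 acting on receptor
#'   complexes (per concentration per time).
#' @param phi phosphorylation rate (per time).
#' @param b basal (SHP-1 independent) dephosphorylation rate (per time).
#'   May be zero; the three-steady-state worked example uses `b = 0`.
#' @param kappa ligand-receptor binding rate constant (per concentration per
#'   time).
#' @param nu1 dissociation rate of the agonist from the receptor (per time).
#'   Its reciprocal is the agonist dissociation time.
#' @param nu2 dissociation rate of the antagonist (per time).  Ignored when
#'   `L2 = 0`.
#' @param L1 total agonist concentration (must be positive).
#' @param L2 total antagonist concentration; `L2 = 0` selects the
#'   agonist-only model in which the `D` chain is inert.
#' @param R total receptor concentration.
#' @param ST total SHP-1 concentration.
#' @param N number of phosphorylation sites (positive integer).
#'
#' @return An object of class `kpr_params`: a named list with the fields
#'   above plus the derived flag `agonist_only`.
#' @examples
#' # parameters for which the N = 3 model has three positive steady states
#' p <- kpr_params(kappa = 2e-4, nu1 = 1e-4, L1 = 1, R = 1, ST = 10, N = 3)
#' p
#' @seealso [enumerate_steady_states()], [read_params()]
#' @export
kpr_params <- function(alpha = 1, beta = 1, gamma = 1, phi = 1, b = 0,
                       kappa, nu1, nu2 = 0, L1, L2 = 0, R, ST, N = 3) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a finite numeric scalar", call. = FALSE)
    as.numeric(x)
  }
  p <- list(alpha = num1(alpha, "alpha"), beta = num1(beta, "beta"),
            gamma = num1(gamma, "gamma"), phi = num1(phi, "phi"),
            b = num1(b, "b"), kappa = num1(kappa, "kappa"),
            nu1 = num1(nu1, "nu1"), nu2 = num1(nu2, "nu2"),
            L1 = num1(L1, "L1"), L2 = num1(L2, "L2"),
            R = num1(R, "R"), ST = num1(ST, "ST"), N = num1(N, "N"))
  for (nm in c("beta", "gamma", "phi", "kappa", "nu1"))
    if (p[[nm]] <= 0) stop("'", nm, "' must be strictly positive", call. = FALSE)
  # alpha = 0 switches off the SHP-1 feedback entirely: the kinetic
  # proofreading limit, admitted as a documented special case
  if (p$alpha < 0) stop("'alpha' must be non-negative", call. = FALSE)
  if (p$alpha == 0 && !isTRUE(getOption("tcrkpr.quiet", FALSE)))
    message("alpha = 0: kinetic proofreading limit (no phosphatase feedback)")
  if (p$b < 0) stop("'b' must be non-negative", call. = FALSE)
  if (p$L1 <= 0) stop("'L1' must be strictly positive", call. = FALSE)
  if (p$L2 < 0) stop("'L2' must be non-negative", call. = FALSE)
  if (p$L2 > 0 && p$nu2 <= 0)
    stop("'nu2' must be strictly positive when L2 > 0", call. = FALSE)
  if (p$R <= 0 || p$ST <= 0) stop("'R' and 'ST' must be strictly positive", call. = FALSE)
  if (p$N < 1 || p$N != round(p$N)) stop("'N' must be a positive integer", call. = FALSE)
  p$N <- as.integer(p$N)
  p$agonist_only <- p$L2 == 0
  if (p$b == 0 && !isTRUE(getOption("tcrkpr.quiet", FALSE)))
    message("b = 0: basal dephosphorylation switched off ",
            "(admissible limiting case of the model)")
  structure(p, class = "kpr_params")
}

#' @export
print.kpr_params <- function(x, ...) {
  cat("<kpr_params> sequential TCR phosphorylation with SHP-1 feedback\n")
  cat(sprintf("  N = %d sites, %s\n", x$N,
              if (x$agonist_only) "agonist only (L2 = 0)" else "agonist + antagonist"))
  cat(sprintf("  rates: alpha=%g beta=%g gamma=%g phi=%g b=%g kappa=%g nu1=%g nu2=%g\n",
              x$alpha, x$beta, x$gamma, x$phi, x$b, x$kappa, x$nu1, x$nu2))
  cat(sprintf("  totals: L1=%g L2=%g R=%g ST=%g\n", x$L1, x$L2, x$R, x$ST))
  invisible(x)
}

#' Modify fields of a parameter set
#'
#' Returns a copy of `params` with the named fields replaced, re-running all
#' validity checks.
#'
#' @param params a [kpr_params()] object.
#' @param ... named fields to replace (e.g. `L1 = 10`, `nu1 = 1e-3`).
#' @return A new `kpr_params` object.
#' @examples
#' p <- kpr_params(kappa = 2e-4, nu1 = 1e-4, L1 = 1, R = 1, ST = 10)
#' update_params(p, ST = 0.1)
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "kpr_params"))
  repl <- list(...)
  bad <- setdiff(names(repl), setdiff(names(params), "agonist_only"))
  if (length(bad)) stop("unknown parameter field(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  args <- params[setdiff(names(params), "agonist_only")]
  args[names(repl)] <- repl
  do.call(kpr_params, args)
}

#' Concentration state of the model
#'
#' A state holds the active SHP-1 concentration `S` and the chains of bound
#' complex concentrations `C0..CN` (agonist) and, when present, `D0..DN`
#' (antagonist).
#'
#' @param S active SHP-1 concentration (scalar).
#' @param C numeric vector of length `N + 1` with the agonist-bound complex
#'   concentrations `C0..CN`, indexed by number of phosphorylations.
#' @param D optional numeric vector of length `N + 1` with the antagonist
#'   chain `D0..DN`; omit (or `NULL`) for agonist-only states.
#' @return An object of class `kpr_state`.
#' @examples
#' kpr_state(S = 1.1769, C = c(0.1570, 0.1334, 0.1133, 0.0963))
#' @export
kpr_state <- function(S, C, D = NULL) {
  stopifnot(is.numeric(S), length(S) == 1L, is.numeric(C), length(C) >= 2L)
  if (!is.null(D) && length(D) != length(C))
    stop("C and D must have the same length", call. = FALSE)
  structure(list(S = as.numeric(S), C = as.numeric(C),
                 D = if (is.null(D)) NULL else as.numeric(D)),
            class = "kpr_state")
}

#' @export
print.kpr_state <- function(x, ...) {
  N <- length(x$C) - 1L
  cat(sprintf("<kpr_state> N = %d\n  S = %.6g\n  C = (%s)\n", N, x$S,
              paste(signif(x$C, 6), collapse = ", ")))
  if (!is.null(x$D)) cat(sprintf("  D = (%s)\n", paste(signif(x$D, 6), collapse = ", ")))
  invisible(x)
}

# ---- internal packing between kpr_state and plain numeric vectors ----------

state_to_vec <- function(state) {
  c(S = state$S,
    stats::setNames(state$C, paste0("C", seq_along(state$C) - 1L)),
    if (!is.null(state$D)) stats::setNames(state$D, paste0("D", seq_along(state$D) - 1L)))
}

vec_to_state <- function(y, N, with_D) {
  C <- y[2:(N + 2)]
  D <- if (with_D) y[(N + 3):(2 * N + 3)] else NULL
  kpr_state(S = unname(y[1]), C = unname(C), D = unname(D))
}

check_dims <- function(params, state) {
  if (length(state$C) != params$N + 1L)
    stop("state C-chain has length ", length(state$C),
         " but params imply ", params$N + 1L, call. = FALSE)
  if (!is.null(state$D) && length(state$D) != params$N + 1L)
    stop("state D-chain has length ", length(state$D),
         " but params imply ", params$N + 1L, call. = FALSE)
  invisible(TRUE)
}

#' Read and write parameter sets
#'
#' Parameter sets are stored as flat key/value files, JSON or YAML, with keys
#' `alpha, beta, gamma, phi, b, kappa, nu1, nu2, L1, L2, R, ST, N`.
#'
#' @param path file path; format is chosen by extension (`.json` vs
#'   `.yaml`/`.yml`).
#' @return [read_params()] returns a `kpr_params` object; [write_params()]
#'   returns `path` invisibly.
#' @examples
#' cfg <- system.file("extdata", "example_text_3steady.yaml", package = "tcrkpr")
#' read_params(cfg)
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$model)) raw <- raw$model
  # YAML 1.1 parses a bare key `N` as boolean FALSE; accept it anyway
  names(raw)[names(raw) %in% c("FALSE", "no")] <- "N"
  keys <- c("alpha", "beta", "gamma", "phi", "b", "kappa", "nu1", "nu2",
            "L1", "L2", "R", "ST", "N")
  missing_keys <- setdiff(c("kappa", "nu1", "L1", "R", "ST"), names(raw))
  if (length(missing_keys))
    stop("config is missing required key(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(raw), keys)
  if (length(extra))
    stop("config has unknown key(s): ", paste(extra, collapse = ", "), call. = FALSE)
  do.call(kpr_params, raw[intersect(keys, names(raw))])
}

#' @param params a [kpr_params()] object.
#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "kpr_params"))
  x <- params[setdiff(names(params), "agonist_only")]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Read and write model states as CSV
#'
#' States are one-row (or multi-row) CSV tables with header
#' `S,C0..CN[,D0..DN]`.
#'
#' @param path CSV file path.
#' @return [read_states()] returns a list of `kpr_state` objects;
#'   [write_states()] returns `path` invisibly.
#' @export
read_states <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  cn <- grep("^C[0-9]+$", names(df), value = TRUE)
  dn <- grep("^D[0-9]+$", names(df), value = TRUE)
  if (!"S" %in% names(df) || length(cn) < 2L)
    stop("state CSV must have columns S, C0..CN", call. = FALSE)
  cn <- cn[order(as.integer(sub("^C", "", cn)))]
  dn <- dn[order(as.integer(sub("^D", "", dn)))]
  lapply(seq_len(nrow(df)), function(i) {
    kpr_state(S = df$S[i], C = as.numeric(df[i, cn]),
              D = if (length(dn)) as.numeric(df[i, dn]) else NULL)
  })
}

#' @param states a `kpr_state` or list of them.
#' @rdname read_states
#' @export
write_states <- function(states, path) {
  if (inherits(states, "kpr_state")) states <- list(states)
  rows <- lapply(states, function(s) as.data.frame(t(state_to_vec(s))))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Bundled example parameter sets
#'
#' Named parameter sets used throughout the documentation and tests:
#' \describe{
#'   \item{`text_3steady`}{the worked example with three positive steady
#'     states: `alpha = beta = gamma = phi = L1 = R = 1`, `b = 0`,
#'     `ST = 10`, `kappa = 2e-4`, `nu1 = 1e-4`, `N = 3`.}
#'   \item{`fig2`}{the ligand-sweep (fold bifurcation) setting with
#'     `nu1 = 1` and otherwise the same constants.}
#'   \item{`fig3`}{the dose-response setting showing linear, decreasing,
#'     increasing and saturation regimes of `log C3` vs `log L1`.}
#'   \item{`fig4`}{the setting in which `C3` has an interior maximum as a
#'     function of the dissociation rate `nu1`.}
#' }
#'
#' @param name one of `"text_3steady"`, `"fig2"`, `"fig3"`, `"fig4"`.
#' @return A `kpr_params` object.
#' @examples
#' example_params("text_3steady")
#' @export
example_params <- function(name = c("text_3steady", "fig2", "fig3", "fig4")) {
  name <- match.arg(name)
  file <- system.file("extdata", paste0("example_", name, ".yaml"),
                      package = "tcrkpr", mustWork = TRUE)
  read_params(file)
}
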