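# Time integration with feasibility diagnostics.

#' Integrate the model kinetics
#'
#' Integrates the full mass-action system with a stiff-capable adaptive
#' solver (`deSolve::ode`, `lsoda`, analytic Jacobian).  When `t_end` is
#' `NULL` the integration proceeds in doubling time chunks until the
#' right-hand-side norm drops below `conv_tol` times the state scale or the
#' time horizon `t_max` is reached; the rates of interest span many orders
#' of magnitude, so a fixed horizon would be wasteful at one end and
#' insufficient at the other.
#'
#' @param params a [kpr_params()] object.
#' @param init initial [kpr_state()] in the closed feasible region.
#' @param t_end integration end time, or `NULL` for adaptive termination.
#' @param n_save number of saved time points per chunk (default 101).
#' @param rtol,atol relative / absolute error tolerances (defaults `1e-9`,
#'   `1e-12`).
#' @param conv_tol convergence threshold on `||rhs||` relative to the state
#'   scale (default `1e-10`).
#' @param t_max horizon for adaptive termination (default `1e6` model time
#'   units).
#' @return A tibble of class `kpr_trajectory` with columns `t`, `S`,
#'   `C0..CN[, D0..DN]`.  Attributes: `params`, `converged`, `terminal`
#'   (terminal `kpr_state`), `rhs_norm` (terminal), `min_margins` (named
#'   vector of the minimum feasibility margins along the path).
#' @examples
#' p <- kpr_params(kappa = 2e-4, nu1 = 1e-4, L1 = 1, R = 1, ST = 10, N = 3)
#' tr <- integrate_model(p, kpr_state(S = 0, C = c(0.5, 0, 0, 0)))
#' attr(tr, "converged")
#' @export
integrate_model <- function(params, init, t_end = NULL, n_save = 101L,
                            rtol = 1e-9, atol = 1e-12, conv_tol = 1e-10,
                            t_max = 1e6) {
  stopifnot(inherits(params, "kpr_params"), inherits(init, "kpr_state"))
  check_dims(params, init)
  with_D <- !is.null(init$D)
  if (!with_D && params$L2 > 0)
    stop("params have L2 > 0 but the initial state has no D chain", call. = FALSE)
  y0 <- state_to_vec(init)
  f <- function(t, y, parms) list(rhs_vec(params, y, with_D))
  jac <- function(t, y, parms)
    jacobian_matrix(params, vec_to_state(y, params$N, with_D))
  run <- function(y, times) {
    deSolve::ode(y = y, times = times, func = f, parms = NULL,
                 jacfunc = jac, jactype = "fullusr", method = "lsoda",
                 rtol = rtol, atol = atol)
  }
  rhs_norm <- function(y) sqrt(sum(rhs_vec(params, y, with_D)^2))
  scale_of <- function(y) max(1, max(abs(y)))

  pieces <- list()
  t0 <- 0
  y <- y0
  converged <- FALSE
  if (!is.null(t_end)) {
    sol <- run(y, seq(0, t_end, length.out = n_save))
    pieces[[1]] <- sol
    y <- sol[nrow(sol), -1]
    converged <- rhs_norm(y) < conv_tol * scale_of(y)
  } else {
    chunk <- 10
    repeat {
      sol <- run(y, seq(t0, min(t0 + chunk, t_max), length.out = n_save))
      pieces[[length(pieces) + 1L]] <- if (length(pieces)) sol[-1, , drop = FALSE] else sol
      y <- sol[nrow(sol), -1]
      t0 <- sol[nrow(sol), 1]
      if (rhs_norm(y) < conv_tol * scale_of(y)) { converged <- TRUE; break }
      if (t0 >= t_max) break
      chunk <- chunk * 4
    }
  }
  m <- do.call(rbind, pieces)
  df <- tibble::as_tibble(as.data.frame(m))
  names(df)[1] <- "t"
  term <- vec_to_state(y, params$N, with_D)
  # minimum feasibility margins over the saved path
  Ccols <- paste0("C", 0:params$N)
  Dsum <- if (with_D) rowSums(df[paste0("D", 0:params$N)]) else 0
  mins <- c(S = min(df$S), ST_minus_S = min(params$ST - df$S),
            unbound_L1 = min(params$L1 - rowSums(df[Ccols])),
            unbound_L2 = min(params$L2 - Dsum),
            unbound_R = min(params$R - rowSums(df[Ccols]) - Dsum),
            chain_min = min(as.matrix(df[c(Ccols, if (with_D) paste0("D", 0:params$N))])))
  attr(df, "params") <- params
  attr(df, "converged") <- converged
  attr(df, "terminal") <- term
  attr(df, "rhs_norm") <- rhs_norm(y)
  attr(df, "min_margins") <- mins
  class(df) <- c("kpr_trajectory", class(df))
  df
}

#' Draw random states from the feasible region
#'
#' Samples states uniformly in a margin-respecting way: the bound totals
#' are drawn uniformly subject to the conservation caps and split across
#' the chain by a uniform simplex draw; `S` is uniform on `(0, ST)`.
#'
#' @param params a [kpr_params()] object.
#' @param n number of states.
#' @return A list of `kpr_state` objects.
#' @keywords internal
sample_feasible_states <- function(params, n) {
  N <- params$N
  with_D <- params$L2 > 0
  lapply(seq_len(n), function(i) {
    sig1 <- stats::runif(1, 0, min(params$L1, params$R))
    w <- stats::rexp(N + 1L); C <- sig1 * w / sum(w)
    D <- NULL
    if (with_D) {
      sig2 <- stats::runif(1, 0, min(params$L2, params$R - sig1))
      w <- stats::rexp(N + 1L); D <- sig2 * w / sum(w)
    }
    kpr_state(S = stats::runif(1, 0, params$ST), C = C, D = D)
  })
}

#' Multistart basin-of-attraction sample
#'
#' Integrates from `n_starts` random feasible initial states and matches
#' each terminal state to the nearest enumerated steady state.  With the
#' seed fixed the table is reproducible.
#'
#' @param params a [kpr_params()] object (agonist-only for the enumeration
#'   step).
#' @param n_starts number of random starts (default 20).
#' @param seed integer seed (mandatory, for reproducibility).
#' @param match_tol relative distance below which a terminal state is
#'   considered to have reached an enumerated state (default `1e-4`).
#' @param ... passed to [integrate_model()].
#' @return A tibble of class `kpr_basins` with one row per start: `start`,
#'   `converged`, `state` (index into the enumerated table by ascending
#'   `S`, or `NA` if unmatched), `distance`, `t_used`.  Attribute
#'   `steady_states` holds the enumerated table.
#' @examples
#' \donttest{
#' p <- kpr_params(kappa = 2e-4, nu1 = 1e-4, L1 = 1, R = 1, ST = 10, N = 3)
#' basin_sample(p, n_starts = 8, seed = 1)
#' }
#' @export
basin_sample <- function(params, n_starts = 20L, seed, match_tol = 1e-4, ...) {
  stopifnot(inherits(params, "kpr_params"))
  if (missing(seed)) stop("a seed is required for reproducibility", call. = FALSE)
  set.seed(seed)
  ss <- if (params$agonist_only) enumerate_steady_states(params)
        else antagonist_steady_states(params)
  targets <- as.matrix(ss[, c("S", grep("^[CD][0-9]+$", names(ss), value = TRUE))])
  starts <- sample_feasible_states(params, n_starts)
  rows <- purrr::map(seq_along(starts), function(i) {
    tr <- integrate_model(params, starts[[i]], ...)
    y <- state_to_vec(attr(tr, "terminal"))
    d <- sqrt(rowSums(sweep(targets, 2, y)^2))
    scale <- max(1, sqrt(sum(y^2)))
    hit <- which.min(d)
    tibble::tibble(start = i, converged = attr(tr, "converged"),
                   state = if (d[hit] / scale < match_tol &&
                               attr(tr, "converged")) hit else NA_integer_,
                   distance = d[hit] / scale,
                   t_used = max(tr$t))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "steady_states") <- ss
  class(out) <- c("kpr_basins", class(out))
  out
}

#' Detect damped oscillations along a trajectory
#'
#' An observable shows damped oscillation when its derivative changes sign
#' at least twice and the successive extremum amplitudes (distance from the
#' terminal value) decay roughly geometrically.
#'
#' @param trajectory a `kpr_trajectory` from [integrate_model()].
#' @param observable column to examine (default `"S"`).
#' @param decay_tol extremum-amplitude ratios must stay below this bound
#'   (default 1, i.e. strictly decaying on the median).
#' @return `TRUE`, `FALSE`, or `NA` when the trajectory is too short to
#'   decide.  Attributes `n_extrema` and `amplitude_ratios`.
#' @examples
#' \donttest{
#' p <- kpr_params(alpha = 0.1, gamma = 10, phi = 0.1, kappa = 2e-4,
#'                 nu1 = 1e-4, L1 = 1, R = 1, ST = 100, N = 1)
#' osc <- find_damped_oscillation_params(p)
#' sig <- solve_sigma(osc$params)$sigma1
#' tr <- integrate_model(osc$params, kpr_state(S = 0, C = c(sig, 0)))
#' oscillation_diagnostic(tr)  # TRUE: damped ringing in S
#' }
#' @export
oscillation_diagnostic <- function(trajectory, observable = "S",
                                   decay_tol = 1) {
  stopifnot(inherits(trajectory, "kpr_trajectory"))
  x <- trajectory[[observable]]
  if (length(x) < 5L) return(NA)
  final <- x[length(x)]
  dx <- diff(x)
  dx <- dx[dx != 0]
  if (length(dx) < 2L) return(NA)
  flips <- which(diff(sign(dx)) != 0)
  n_ext <- length(flips)
  if (n_ext < 2L) {
    out <- FALSE
    attr(out, "n_extrema") <- n_ext
    attr(out, "amplitude_ratios") <- numeric(0)
    return(out)
  }
  amp <- abs(x[flips + 1L] - final)
  amp <- amp[amp > 0]
  ratios <- if (length(amp) >= 2L) amp[-1] / amp[-length(amp)] else numeric(0)
  out <- n_ext >= 2L && length(ratios) >= 1L &&
    stats::median(ratios) < decay_tol && ratios[length(ratios)] < 1
  attr(out, "n_extrema") <- n_ext
  attr(out, "amplitude_ratios") <- ratios
  out
}
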