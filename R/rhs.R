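# Mass-action right-hand sides of the full, summed and limiting systems.
#
# Full system (agonist chain C0..CN, antagonist chain D0..DN, active SHP-1 S):
#   S'  = alpha (C1 + D1)(ST - S) - beta S
#   C0' = kappa (L1 - sum C)(R - sum C - sum D) + (b + gamma S) C1 - (phi + nu1) C0
#   Cj' = phi C_{j-1} + (b + gamma S) C_{j+1} - (phi + b + gamma S + nu1) Cj
#   CN' = phi C_{N-1} - (b + gamma S + nu1) CN
# and the analogous D equations with (L2, nu2).

rhs_chain <- function(y, S, unbound_term, phi, bg, nu) {
  # y = chain c(X0..XN); bg = b + gamma*S
  N <- length(y) - 1L
  dy <- numeric(N + 1L)
  dy[1] <- unbound_term + bg * y[2] - (phi + nu) * y[1]
  if (N >= 2L) {
    j <- 2:N   # interior indices X1..X_{N-1}
    dy[j] <- phi * y[j - 1L] + bg * y[j + 1L] - (phi + bg + nu) * y[j]
  }
  dy[N + 1L] <- phi * y[N] - (bg + nu) * y[N + 1L]
  dy
}

# plain-vector right-hand side used by the integrator and the Jacobian check
rhs_vec <- function(params, y, with_D) {
  N <- params$N
  S <- y[1]
  C <- y[2:(N + 2)]
  D <- if (with_D) y[(N + 3):(2 * N + 3)] else numeric(N + 1L)
  bg <- params$b + params$gamma * S
  free_R <- params$R - sum(C) - sum(D)
  dS <- params$alpha * (C[2] + D[2]) * (params$ST - S) - params$beta * S
  dC <- rhs_chain(C, S, params$kappa * (params$L1 - sum(C)) * free_R,
                  params$phi, bg, params$nu1)
  if (with_D) {
    dD <- rhs_chain(D, S, params$kappa * (params$L2 - sum(D)) * free_R,
                    params$phi, bg, params$nu2)
    c(dS, dC, dD)
  } else {
    c(dS, dC)
  }
}

#' Time derivatives of the full mass-action system
#'
#' Evaluates the right-hand side of the model at a state: SHP-1 activation by
#' singly phosphorylated complexes, sequential phosphorylation at rate `phi`,
#' dephosphorylation at rate `b + gamma * S`, ligand binding at rate `kappa`
#' and dissociation at `nu1` (agonist) / `nu2` (antagonist).
#'
#' @param params a [kpr_params()] object.
#' @param state a [kpr_state()] whose chain lengths match `params$N`.  For
#'   agonist-only instances the `D` chain may be omitted.
#' @return A `kpr_state` holding the time derivatives, with attribute
#'   `"flags"` noting diagnostic conditions (currently `S > ST`).
#' @examples
#' p <- kpr_params(kappa = 2e-4, nu1 = 1e-4, L1 = 1, R = 1, ST = 10, N = 3)
#' s <- kpr_state(S = 1.1769, C = c(0.1570, 0.1334, 0.1133, 0.0963))
#' rhs_full(p, s)  # near zero: s is (approximately) a steady state
#' @export
rhs_full <- function(params, state) {
  stopifnot(inherits(params, "kpr_params"), inherits(state, "kpr_state"))
  check_dims(params, state)
  with_D <- !is.null(state$D)
  if (!with_D && params$L2 > 0)
    stop("params have L2 > 0 but the state has no D chain", call. = FALSE)
  y <- c(state$S, state$C, if (with_D) state$D)
  dy <- rhs_vec(params, y, with_D)
  out <- vec_to_state(dy, params$N, with_D)
  flags <- character(0)
  if (state$S > params$ST) flags <- c(flags, "S_exceeds_ST")
  attr(out, "flags") <- flags
  out
}

#' Dynamics of the total bound-ligand concentrations
#'
#' The totals `Sigma1 = sum(Cj)` and `Sigma2 = sum(Dj)` obey a closed planar
#' system: `Sigma1' = kappa (L1 - Sigma1)(R - Sigma1 - Sigma2) - nu1 Sigma1`
#' and the analogous equation for `Sigma2`.  This is the competitive system
#' whose unique equilibrium fixes the bound totals at any steady state.
#'
#' @param params a [kpr_params()] object.
#' @param sigma1,sigma2 total bound agonist / antagonist concentrations;
#'   must satisfy `0 <= sigma1 <= L1`, `0 <= sigma2 <= L2`,
#'   `sigma1 + sigma2 <= R`.
#' @return Named numeric vector `c(dsigma1, dsigma2)`.
#' @examples
#' p <- kpr_params(kappa = 2e-4, nu1 = 1e-4, L1 = 1, R = 1, ST = 10, N = 3)
#' rhs_sigma(p, 0.5, 0)  # Sigma* = 1/2 is the bound-total equilibrium
#' @export
rhs_sigma <- function(params, sigma1, sigma2 = 0) {
  stopifnot(inherits(params, "kpr_params"))
  if (sigma1 < 0 || sigma1 > params$L1)
    stop("sigma1 must lie in [0, L1]", call. = FALSE)
  if (sigma2 < 0 || sigma2 > max(params$L2, 0))
    stop("sigma2 must lie in [0, L2]", call. = FALSE)
  if (sigma1 + sigma2 > params$R)
    stop("sigma1 + sigma2 must not exceed R", call. = FALSE)
  free_R <- params$R - sigma1 - sigma2
  c(dsigma1 = params$kappa * (params$L1 - sigma1) * free_R - params$nu1 * sigma1,
    dsigma2 = params$kappa * (params$L2 - sigma2) * free_R - params$nu2 * sigma2)
}

#' Time derivatives of the limiting system on the invariant bound-total set
#'
#' On the omega-limit set the bound totals take their equilibrium values
#' `Sigma1*`, `Sigma2*`, and `C0`, `D0` can be eliminated.  The resulting
#' system in `(S, C1..CN, D1..DN)` is evaluated here.  For `N = 1` the
#' dedicated two-equation form `S' = alpha C1 (ST - S) - beta S`,
#' `C1' = phi Sigma* - (phi + b + gamma S + nu1) C1` is used (per chain).
#'
#' @param params a [kpr_params()] object.
#' @param sigma1_star,sigma2_star equilibrium bound totals, normally from
#'   [solve_sigma()].
#' @param reduced_state named list with `S` (scalar), `C` (length `N`,
#'   entries `C1..CN`) and optionally `D` (length `N`).
#' @return Named list with derivatives `S`, `C` and (if present) `D`.
#' @export
rhs_limiting <- function(params, sigma1_star, sigma2_star = 0, reduced_state) {
  stopifnot(inherits(params, "kpr_params"))
  N <- params$N
  S <- reduced_state$S
  C <- reduced_state$C
  D <- reduced_state$D
  if (length(C) != N) stop("reduced C-chain must have length N", call. = FALSE)
  if (!is.null(D) && length(D) != N)
    stop("reduced D-chain must have length N", call. = FALSE)
  bg <- params$b + params$gamma * S
  chain <- function(x, sigma_star, nu) {
    dx <- numeric(N)
    if (N == 1L) {
      dx[1] <- params$phi * sigma_star - (params$phi + bg + nu) * x[1]
      return(dx)
    }
    dx[1] <- params$phi * sigma_star + (bg - params$phi) * x[2] -
      (2 * params$phi + bg + nu) * x[1] -
      params$phi * if (N >= 3L) sum(x[3:N]) else 0
    if (N >= 3L) {
      j <- 2:(N - 1L)
      dx[j] <- params$phi * x[j - 1L] + bg * x[j + 1L] - (params$phi + bg + nu) * x[j]
    }
    dx[N] <- params$phi * x[N - 1L] - (bg + nu) * x[N]
    dx
  }
  D1 <- if (is.null(D)) 0 else D[1]
  out <- list(S = params$alpha * (C[1] + D1) * (params$ST - S) - params$beta * S,
              C = chain(C, sigma1_star, params$nu1))
  if (!is.null(D)) out$D <- chain(D, sigma2_star, params$nu2)
  out
}

#' Feasibility margins of a state
#'
#' The biologically feasible region is the open set where all concentrations
#' and conservation-law slacks are strictly positive.  The six margins are
#' `S`, `ST - S`, `L1 - sum(Cj)` (unbound agonist), `L2 - sum(Dj)` (unbound
#' antagonist), `R - sum(Cj + Dj)` (unbound receptor) and the smallest chain
#' entry `min(Cj, Dj)`.
#'
#' @param params a [kpr_params()] object.
#' @param state a [kpr_state()].
#' @param tol absolute tolerance for boundary classification (default
#'   `1e-10`).
#' @return A tibble with columns `margin` and `value`, plus attribute
#'   `"classification"` in `c("interior", "boundary", "outside")`.
#' @examples
#' p <- kpr_params(kappa = 2e-4, nu1 = 1e-4, L1 = 1, R = 1, ST = 10, N = 3)
#' s <- kpr_state(S = 1.1769, C = c(0.1570, 0.1334, 0.1133, 0.0963))
#' feasibility(p, s)
#' @export
feasibility <- function(params, state, tol = 1e-10) {
  stopifnot(inherits(params, "kpr_params"), inherits(state, "kpr_state"))
  check_dims(params, state)
  with_D <- !is.null(state$D) && params$L2 > 0
  chain_min <- min(c(state$C, if (with_D) state$D))
  m <- c(S = state$S,
         ST_minus_S = params$ST - state$S,
         unbound_L1 = params$L1 - sum(state$C),
         # the antagonist slack only constrains two-ligand instances
         unbound_L2 = if (with_D) params$L2 - sum(state$D) else NA_real_,
         unbound_R = params$R - sum(state$C) -
           sum(if (is.null(state$D)) 0 else state$D),
         chain_min = chain_min)
  m <- m[!is.na(m)]
  cls <- if (any(m < -tol)) "outside" else if (any(abs(m) <= tol)) "boundary" else "interior"
  out <- tibble::tibble(margin = names(m), value = unname(m))
  attr(out, "classification") <- cls
  out
}
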