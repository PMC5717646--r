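# Steady-state enumeration.
#
# At a steady state the bound totals Sigma1* = sum(Cj), Sigma2* = sum(Dj)
# solve a scalar equation with a unique root.  With the totals fixed, the
# chain equations are a linear recurrence in j, so every Cj is (Sigma1*
# times) a rational function of S alone; substituting into the SHP-1 balance
# alpha C1 (ST - S) = beta S and clearing denominators yields a single
# polynomial p(S) of degree N + 1 whose positive roots are in one-to-one
# correspondence with the positive steady states (agonist-only case).

#' Equilibrium totals of bound agonist and antagonist
#'
#' Solves the steady-state equations of the closed planar system for the
#' bound totals.  The sum `Sigma1* + Sigma2*` solves a scalar equation whose
#' left side is decreasing and right side increasing on
#' `[0, min(L1 + L2, R)]`, so the root is unique; the individual totals then
#' follow in closed form.  In the agonist-only case the quadratic
#' `kappa (L1 - Sigma)(R - Sigma) = nu1 Sigma` is solved directly, taking
#' the root in `[0, min(L1, R)]`.
#'
#' @param params a [kpr_params()] object.
#' @param tol relative tolerance of the bracketed root solve (default
#'   `1e-12`).
#' @return A list of class `kpr_sigma` with elements `sigma1`, `sigma2`,
#'   `sigma_total` and `residuals` (the two steady-state balance residuals).
#' @examples
#' p <- kpr_params(kappa = 2e-4, nu1 = 1e-4, L1 = 1, R = 1, ST = 10, N = 3)
#' solve_sigma(p)$sigma1  # = 1/2
#' @export
solve_sigma <- function(params, tol = 1e-12) {
  stopifnot(inherits(params, "kpr_params"))
  k <- params$kappa
  if (params$agonist_only) {
    # kappa (L1 - s)(R - s) = nu1 s  =>  k s^2 - (k(L1+R) + nu1) s + k L1 R = 0
    bq <- k * (params$L1 + params$R) + params$nu1
    disc <- bq^2 - 4 * k^2 * params$L1 * params$R
    s <- (bq - sqrt(disc)) / (2 * k)   # smaller root lies in [0, min(L1, R)]
    sig <- list(sigma1 = s, sigma2 = 0, sigma_total = s)
  } else {
    upper <- min(params$L1 + params$L2, params$R)
    f <- function(s) {
      k * (params$L1 + params$L2 - s) -
        (k * params$L1 * params$nu1 / (k * (params$R - s) + params$nu1) +
           k * params$L2 * params$nu2 / (k * (params$R - s) + params$nu2))
    }
    root <- stats::uniroot(f, lower = 0, upper = upper, tol = tol * max(upper, 1))
    s <- root$root
    freeR <- params$R - s
    sig <- list(
      sigma1 = k * params$L1 * freeR / (k * freeR + params$nu1),
      sigma2 = k * params$L2 * freeR / (k * freeR + params$nu2))
    sig$sigma_total <- sig$sigma1 + sig$sigma2
  }
  res <- rhs_sigma(params, sig$sigma1, sig$sigma2)
  structure(c(sig, list(residuals = res)), class = "kpr_sigma")
}

# ---- polynomial helpers (coefficient vectors, ascending degree) ------------

poly_mul <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) out[i:(i + length(b) - 1L)] <-
      out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

poly_add <- function(a, b) {
  n <- max(length(a), length(b))
  c(a, numeric(n - length(a))) + c(b, numeric(n - length(b)))
}

poly_eval <- function(coef, x) {
  # Horner, vectorized in x
  out <- rep(coef[length(coef)], length(x))
  for (k in rev(seq_len(length(coef) - 1L))) out <- out * x + coef[k]
  out
}

poly_deriv <- function(coef) {
  if (length(coef) <= 1L) return(0)
  coef[-1] * seq_len(length(coef) - 1L)
}

# Back-substitution chain: with X_N normalized to 1, the steady-state
# recurrence gives X_j = u_j(S), a polynomial of degree N - j (u_0 has
# degree N).  `nu` selects the ligand (nu1 for C, nu2 for D).
chain_u_polys <- function(params, nu = params$nu1) {
  N <- params$N
  phi <- params$phi
  lin_bg  <- c(params$b, params$gamma)             # b + gamma S
  lin_bgn <- c(params$b + nu, params$gamma)        # b + gamma S + nu
  lin_all <- c(phi + params$b + nu, params$gamma)  # phi + b + gamma S + nu
  u <- vector("list", N + 1L)  # u[[j + 1]] is u_j
  u[[N + 1L]] <- 1
  u[[N]] <- lin_bgn / phi
  if (N >= 2L) {
    for (j in (N - 1L):1L) {
      u[[j]] <- (poly_mul(lin_all, u[[j + 1L]]) - c(poly_mul(lin_bg, u[[j + 2L]]), 0)) / phi
    }
  }
  U <- Reduce(poly_add, u)
  list(u = u, U = U)
}

# printed closed-form coefficients (ascending), N <= 3, agonist-only.
# The N = 3 forms are the published ones reconciled against elimination:
# a1's beta-term carries no gamma factor and its nu1(phi+b+nu1) sub-term a
# factor phi; a3's first term is 2 gamma^2 (b + nu1).
printed_coefficients <- function(params, sigma_star) {
  al <- params$alpha; be <- params$beta; ga <- params$gamma
  ph <- params$phi; b <- params$b; n1 <- params$nu1; ST <- params$ST
  Sg <- sigma_star
  bn <- b + n1
  switch(params$N,
    # N = 1: beta gamma S^2 + [beta(phi + b + nu1) + alpha phi Sigma*] S
    #        - alpha phi Sigma* ST
    c(-al * ph * Sg * ST,
      be * (ph + b + n1) + al * ph * Sg,
      be * ga),
    # N = 2
    c(-al * ST * bn * ph * Sg,
      be * (b * (ph + b + n1) + n1 * (2 * ph + b + n1) + ph^2) +
        al * bn * ph * Sg - al * ga * ST * ph * Sg,
      be * ga * (ph + 2 * b + 2 * n1) + al * ga * ph * Sg,
      be * ga^2),
    # N = 3
    c(-(bn^2 + ph * n1) * al * ph * Sg * ST,
      be * ((ph + b + n1) * (bn^2 + ph * n1) + ph * n1 * (ph + b + n1) +
              ph^2 * bn + ph^3) +
        (bn^2 + n1 * ph) * al * ph * Sg - 2 * bn * al * ga * ph * Sg * ST,
      be * ga * (b * bn + n1 * (ph + b + n1) + 2 * (ph + b + n1) * bn +
                   ph * n1 + ph^2) +
        2 * bn * al * ga * ph * Sg - ga^2 * al * ph * Sg * ST,
      be * ga^2 * (3 * bn + ph) + ga^2 * al * ph * Sg,
      be * ga^3))
}

#' The steady-state polynomial in the active SHP-1 concentration
#'
#' Builds the degree `N + 1` polynomial `p(S)` whose positive roots are the
#' steady-state values of `S` in the agonist-only model.  Two routes are
#' available: exact elimination along the back-substitution chain
#' (`p(S) = phi^N [beta S U(S) - alpha Sigma* u1(S) (ST - S)]`, where
#' `u_j(S)` is the chain profile normalized to `u_N = 1` and `U = sum u_j`),
#' and, for `N <= 3`, the published closed-form coefficients.  When both are
#' computed they must agree (after normalizing the leading coefficient) to
#' relative `1e-9`, guarding against transcription errors.
#'
#' @param params a [kpr_params()] object with `L2 = 0`.
#' @param sigma a `kpr_sigma` from [solve_sigma()]; computed if missing.
#' @param route `"both"` (default; closed forms checked against elimination
#'   for `N <= 3`), `"elimination"` or `"printed"` (`N <= 3` only).
#' @return An object of class `kpr_spoly`: list with `coefficients`
#'   (ascending, length `N + 2`), `provenance`, `sign_changes` (Descartes
#'   bound on the number of positive roots) and `params`.
#' @examples
#' p <- kpr_params(kappa = 2e-4, nu1 = 1e-4, L1 = 1, R = 1, ST = 10, N = 3)
#' sp <- s_polynomial(p)
#' sp$sign_changes  # 3: one or three positive steady states
#' @export
s_polynomial <- function(params, sigma = solve_sigma(params),
                         route = c("both", "elimination", "printed")) {
  stopifnot(inherits(params, "kpr_params"))
  if (!params$agonist_only)
    stop("the S-polynomial is defined for the agonist-only model (L2 = 0)",
         call. = FALSE)
  route <- match.arg(route)
  N <- params$N
  sg <- sigma$sigma1

  elim <- function() {
    ch <- chain_u_polys(params)
    # p = phi^N [ beta S U - alpha Sigma* u1 (ST - S) ]
    pS_U <- c(0, ch$U)                           # S * U(S)
    u1 <- ch$u[[2]]
    term2 <- poly_add(params$ST * u1, -c(0, u1)) # u1 * (ST - S)
    params$phi^N * poly_add(params$beta * pS_U, -params$alpha * sg * term2)
  }

  if (route == "printed" && N > 3L)
    stop("closed-form coefficients are only available for N <= 3", call. = FALSE)
  coef_elim <- if (route != "printed") elim() else NULL
  coef_prn <- if (N <= 3L && route != "elimination") printed_coefficients(params, sg) else NULL

  if (!is.null(coef_elim) && !is.null(coef_prn)) {
    # both routes are monic up to the same positive leading coefficient
    rel <- abs(coef_elim - coef_prn) / pmax(abs(coef_elim), abs(coef_prn), 1e-300)
    rel[coef_elim == 0 & coef_prn == 0] <- 0
    if (max(rel) > 1e-9)
      stop("closed-form and elimination coefficients disagree (max rel diff ",
           format(max(rel)), ")", call. = FALSE)
  }
  coef <- if (is.null(coef_elim)) coef_prn else coef_elim
  prov <- if (route == "printed") "printed-formula" else "eliminated"
  sgn <- sign(coef[coef != 0])
  structure(list(coefficients = coef, provenance = prov,
                 sign_changes = sum(diff(sgn) != 0), sigma = sigma,
                 params = params),
            class = "kpr_spoly")
}

#' @export
print.kpr_spoly <- function(x, ...) {
  cat(sprintf("<kpr_spoly> degree %d (%s), %d sign change(s)\n",
              length(x$coefficients) - 1L, x$provenance, x$sign_changes))
  cat("  coefficients (ascending):", format(x$coefficients, digits = 6), "\n")
  invisible(x)
}

#' Positive real roots of the steady-state polynomial
#'
#' Finds all roots with [polyroot()], polishes real candidates by Newton
#' iteration, filters to the positive axis, and merges near-multiple roots.
#' The number of positive roots never exceeds the Descartes sign-change
#' bound of the coefficient sequence.
#'
#' @param poly a `kpr_spoly` from [s_polynomial()], or a bare numeric
#'   coefficient vector in ascending degree.
#' @param merge_tol roots closer than `merge_tol` times the largest root
#'   magnitude are merged and reported with multiplicity (default `1e-8`).
#' @return A tibble with columns `root`, `multiplicity`, `residual` (the
#'   Newton residual `|p(S)/p'(S)|` relative to the root scale) and
#'   `near_multiple` (condition flag).
#' @examples
#' positive_roots(c(-2, 3, -1))  # (1 - S)(2 - S) sign-flipped: roots 1, 2
#' @export
positive_roots <- function(poly, merge_tol = 1e-8) {
  coef <- if (inherits(poly, "kpr_spoly")) poly$coefficients else as.numeric(poly)
  coef <- coef[seq_len(max(which(coef != 0)))]   # strip trailing zeros
  if (length(coef) < 2L) stop("polynomial must have positive degree", call. = FALSE)
  scale <- max(abs(coef))
  rts <- polyroot(coef / scale)
  mag <- max(Mod(rts), 1e-300)
  dcoef <- poly_deriv(coef)
  newton <- function(x) {
    for (i in 1:50) {
      fx <- poly_eval(coef, x); dfx <- poly_eval(dcoef, x)
      if (dfx == 0) break
      step <- fx / dfx
      x <- x - step
      if (abs(step) < 1e-15 * max(abs(x), mag)) break
    }
    x
  }
  real <- Re(rts[abs(Im(rts)) < 1e-7 * mag])
  real <- vapply(real, newton, numeric(1))
  pos <- sort(real[real > 1e-14 * mag])
  if (!length(pos))
    return(tibble::tibble(root = numeric(0), multiplicity = integer(0),
                          residual = numeric(0), near_multiple = logical(0)))
  # merge clusters closer than merge_tol * scale
  grp <- cumsum(c(1, diff(pos) > merge_tol * mag))
  agg <- tapply(pos, grp, mean)
  mult <- as.integer(table(grp))
  resid <- vapply(agg, function(x) {
    dfx <- poly_eval(dcoef, x)
    if (dfx == 0) Inf else abs(poly_eval(coef, x) / dfx) / max(abs(x), mag)
  }, numeric(1))
  out <- tibble::tibble(root = as.numeric(agg), multiplicity = mult,
                        residual = as.numeric(resid),
                        near_multiple = mult > 1L | resid > 1e-10)
  if (inherits(poly, "kpr_spoly") && nrow(out) > poly$sign_changes)
    warning("more positive roots than the Descartes bound; numerical trouble")
  out
}

#' Reconstruct a full steady state from a root of the S-polynomial
#'
#' Given a positive root `S*` of the steady-state polynomial, the chain
#' coordinates follow from the back-substitution recurrences:
#' `CN = Sigma* / U(S*)`, `Cj = CN u_j(S*)` for `j >= 1`, and
#' `C0 = Sigma* - (C1 + ... + CN)`.  The SHP-1 balance
#' `C1 = beta S* / (alpha (ST - S*))` is verified as a consistency check,
#' as is the full right-hand-side residual.
#'
#' @param params a [kpr_params()] object with `L2 = 0`.
#' @param sigma a `kpr_sigma` from [solve_sigma()].
#' @param s_root a positive root of the S-polynomial, in `(0, ST)`.
#' @param residual_tol residual threshold (relative to the state scale)
#'   beyond which the root is rejected as spurious (default `1e-8`).
#' @return A `kpr_state` with attributes `residual` (norm of [rhs_full()])
#'   and `s_root`, or `NULL` (with a warning) if any coordinate is
#'   non-positive.
#' @export
backsubstitute <- function(params, sigma, s_root, residual_tol = 1e-8) {
  stopifnot(inherits(params, "kpr_params"))
  if (!(s_root > 0 && s_root < params$ST))
    stop("s_root must lie in (0, ST)", call. = FALSE)
  ch <- chain_u_polys(params)
  uj <- vapply(ch$u, poly_eval, numeric(1), x = s_root)
  Uval <- poly_eval(ch$U, s_root)
  CN <- sigma$sigma1 / Uval
  C <- CN * uj          # C0..CN via the chain profile
  C[1] <- sigma$sigma1 - sum(C[-1])
  if (any(C <= 0)) {
    warning("root ", format(s_root), " rejected: non-positive chain coordinate")
    return(NULL)
  }
  # SHP-1 balance consistency
  c1_expected <- params$beta * s_root / (params$alpha * (params$ST - s_root))
  st <- kpr_state(S = s_root, C = C)
  resid <- sqrt(sum(unlist(state_to_vec(rhs_full(params, st)))^2))
  scale <- max(1, abs(s_root), max(C))
  if (resid > residual_tol * scale) {
    warning("root ", format(s_root), " rejected: residual ", format(resid))
    return(NULL)
  }
  attr(st, "residual") <- resid
  attr(st, "s_root") <- s_root
  attr(st, "c1_check") <- abs(C[2] - c1_expected) / max(c1_expected, 1e-300)
  st
}

#' Enumerate all positive steady states of the agonist-only model
#'
#' Solves the bound-total equation, builds the degree `N + 1` steady-state
#' polynomial in `S`, takes its positive roots and back-substitutes each to
#' a full state.  For `N = 1` and `N = 2` there is exactly one positive
#' steady state; for `N = 3` there are between one and three.
#'
#' @param params a [kpr_params()] object with `L2 = 0`.  For the
#'   two-ligand model use [antagonist_steady_states()].
#' @param route polynomial construction route, see [s_polynomial()].
#' @return A tibble of class `kpr_steady_states`, one row per steady state
#'   sorted by ascending `S`, with columns `S`, `C0..CN` and `residual`.
#'   Attributes: `params`, `sigma`, `polynomial`.
#' @examples
#' p <- kpr_params(kappa = 2e-4, nu1 = 1e-4, L1 = 1, R = 1, ST = 10, N = 3)
#' enumerate_steady_states(p)  # three states; compare S = 1.1769 etc.
#' @export
enumerate_steady_states <- function(params, route = "both") {
  stopifnot(inherits(params, "kpr_params"))
  if (!params$agonist_only)
    stop("enumerate_steady_states() handles the agonist-only model; ",
         "use antagonist_steady_states() when L2 > 0", call. = FALSE)
  sigma <- solve_sigma(params)
  if (params$alpha == 0) {
    # kinetic proofreading limit: S* = 0 on the boundary, chain profile at S = 0
    ch <- chain_u_polys(params)
    uj <- vapply(ch$u, poly_eval, numeric(1), x = 0)
    C <- sigma$sigma1 * uj / poly_eval(ch$U, 0)
    st <- kpr_state(S = 0, C = C)
    resid <- sqrt(sum(unlist(state_to_vec(rhs_full(params, st)))^2))
    out <- tibble::as_tibble(c(as.list(state_to_vec(st)), list(residual = resid)))
    attr(out, "params") <- params
    attr(out, "sigma") <- sigma
    class(out) <- c("kpr_steady_states", class(out))
    return(out)
  }
  poly <- s_polynomial(params, sigma, route = route)
  roots <- positive_roots(poly)
  roots <- roots[roots$root < params$ST, , drop = FALSE]
  states <- purrr::compact(purrr::map(roots$root, function(r) {
    backsubstitute(params, sigma, r)
  }))
  if (!length(states))
    stop("no positive steady state found; existence is guaranteed, so this ",
         "indicates a numerical failure", call. = FALSE)
  rows <- purrr::map(states, function(st) {
    v <- as.list(state_to_vec(st))
    v$residual <- attr(st, "residual")
    tibble::as_tibble(v)
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$S)
  attr(out, "params") <- params
  attr(out, "sigma") <- sigma
  attr(out, "polynomial") <- poly
  class(out) <- c("kpr_steady_states", class(out))
  out
}

#' Parameter family exhibiting three steady states in the scaling limit
#'
#' Constructs the member of the scaling family `ST = sbar_T / epsilon`,
#' `nu1 = nubar_1 * epsilon^4`, with `kappa` rescaled so that `nu1 / kappa`
#' (and hence the bound total `Sigma*`) is unchanged.  For sufficiently
#' small `epsilon` the resulting quartic (`N = 3`, `b = 0`) satisfies
#' `p(1) < 0` and `p(epsilon^2) > 0` and has three positive roots.
#'
#' @param epsilon positive scaling parameter; small values put the instance
#'   in the three-steady-state regime.
#' @param sbar_T,nubar_1 scale constants for `ST` and `nu1`.
#' @param base_params template parameters (must have `b = 0`); defaults to
#'   the three-steady-state worked example with `N = 3`.
#' @return A `kpr_params` object.
#' @examples
#' \donttest{
#' p <- epsilon_family(0.05)
#' nrow(enumerate_steady_states(p))  # 3
#' }
#' @export
epsilon_family <- function(epsilon, sbar_T = 1, nubar_1 = 1e-4,
                           base_params = kpr_params(kappa = 2e-4, nu1 = 1e-4,
                                                    L1 = 1, R = 1, ST = 1,
                                                    N = 3, b = 0)) {
  stopifnot(epsilon > 0)
  if (base_params$b != 0)
    stop("the scaling construction requires b = 0", call. = FALSE)
  nu1_new <- nubar_1 * epsilon^4
  update_params(base_params,
                ST = sbar_T / epsilon,
                nu1 = nu1_new,
                kappa = base_params$kappa * nu1_new / base_params$nu1)
}
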