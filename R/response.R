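# Steady-state parametrization a+ r+^j + a- r-^j, the dose-response
# function log CN = F(log L1, nu1), its asymptotics, and the antagonist
# (two-ligand) steady-state solver.

#' Characteristic roots of the steady-state chain recurrence
#'
#' At a steady state the chain equations form a linear difference equation
#' in `j` with characteristic equation
#' `phi + (b + gamma S) r^2 - (phi + b + gamma S + nu) r = 0`.  Its roots
#' satisfy `r- < 1 < r+`, and the chain profile is
#' `Cj = a+ r+^j + a- r-^j`.
#'
#' @param params a [kpr_params()] object.
#' @param S active SHP-1 concentration; `b + gamma * S` must be positive.
#' @param nu dissociation rate; defaults to `nu1` (use `nu2` for the
#'   antagonist chain).
#' @return Named numeric vector `c(r_minus, r_plus)`.
#' @examples
#' p <- kpr_params(kappa = 2e-4, nu1 = 1e-4, L1 = 1, R = 1, ST = 10, N = 3)
#' characteristic_roots(p, S = 1)
#' @export
characteristic_roots <- function(params, S, nu = params$nu1) {
  stopifnot(inherits(params, "kpr_params"))
  bg <- params$b + params$gamma * S
  if (bg <= 0)
    stop("b + gamma * S must be positive (degenerate quadratic)", call. = FALSE)
  tr <- params$phi + bg + nu
  # discriminant written as (phi - bg - nu)^2 + 4 phi nu: manifestly
  # non-negative and free of cancellation
  d <- params$phi - bg - nu
  sq <- sqrt(d * d + 4 * params$phi * nu)
  # evaluate the smaller root via the product identity to avoid cancellation
  r_plus <- (tr + sq) / (2 * bg)
  r_minus <- params$phi / (bg * r_plus)
  c(r_minus = r_minus, r_plus = r_plus)
}

#' Coefficients of the steady-state chain profile
#'
#' Solves the boundary equations of the chain recurrence for the
#' coefficients `a-`, `a+` of `Cj = a+ r+^j + a- r-^j`, given the bound
#' total `Sigma*` and the phosphatase level `S`.  Both coefficients are
#' positive; the bracketed products `A` and `B` satisfy `A > 0`, `A > B`,
#' and the factor identity
#' `[phi - (b+gamma S+nu) r-][phi - (b+gamma S+nu) r+] = -phi^2 nu / (b+gamma S)`
#' guarantees solvability.
#'
#' @inheritParams characteristic_roots
#' @param sigma_star the bound total `Sigma*` for this chain, normally from
#'   [solve_sigma()].
#' @return An object of class `kpr_parametrization`: list with `r_minus`,
#'   `r_plus`, `a_minus`, `a_plus`, `A`, `B`, `C_star` (`beta/alpha`), `S`,
#'   `nu` and the reconstructed chain `C` (`C0..CN`).
#' @examples
#' p <- kpr_params(kappa = 2e-4, nu1 = 1e-4, L1 = 1, R = 1, ST = 10, N = 3)
#' pr <- solve_coefficients(p, S = 1.1769, sigma_star = 0.5)
#' pr$C  # chain profile at this S
#' @export
solve_coefficients <- function(params, S, sigma_star, nu = params$nu1) {
  r <- characteristic_roots(params, S, nu)
  rm <- r[["r_minus"]]; rp <- r[["r_plus"]]
  bg <- params$b + params$gamma * S
  N <- params$N
  # fm = phi - (bg + nu) r- > 0 suffers cancellation when nu is small;
  # rewrite via fm = phi (d + sq) / (2 bg r+), with the d < 0 branch
  # expressed through the conjugate
  d <- params$phi - bg - nu
  sq <- sqrt(d * d + 4 * params$phi * nu)
  half <- if (d >= 0) (d + sq) / 2 else 2 * params$phi * nu / (sq - d)
  fm <- params$phi * half / (bg * rp)  # > 0
  fp <- params$phi - (bg + nu) * rp   # < 0
  A <- (bg * rm - (params$phi + nu)) * fp
  B <- (bg * rp - (params$phi + nu)) * fm
  a_minus <- -nu * sigma_star * fp / (A - B * (rm / rp)^(N - 1))
  a_plus <- -a_minus * (rm / rp)^(N - 1) * fm / fp
  j <- 0:N
  C <- a_plus * rp^j + a_minus * rm^j
  structure(list(r_minus = rm, r_plus = rp, a_minus = a_minus,
                 a_plus = a_plus, A = A, B = B,
                 C_star = params$beta / params$alpha, S = S, nu = nu, C = C),
            class = "kpr_parametrization")
}

# C1 (and the full chain) as a function of S for one ligand chain, via the
# polynomial back-substitution profile; numerically stable for extreme S.
chain_profile_at <- function(ch, sigma_star, S) {
  uj <- vapply(ch$u, poly_eval, numeric(1), x = S)
  Uval <- poly_eval(ch$U, S)
  sigma_star * uj / Uval
}

#' Steady states by scalar self-consistency in S
#'
#' Enumerates steady states by substituting the chain profiles
#' `C1(S)` (and `D1(S)` when an antagonist is present) into the SHP-1
#' balance `alpha (C1 + D1)(ST - S) = beta S` and locating every root of
#' the resulting scalar equation by a dense sign scan over `(0, ST)` on a
#' log-spaced grid followed by bisection.  This is the route used for the
#' two-ligand model, where no single-polynomial reduction is available; for
#' `L2 = 0` it reproduces the polynomial route and serves as an independent
#' cross-check.
#'
#' @param params a [kpr_params()] object with `L2 > 0` (two ligands) or
#'   `L2 = 0` (reduces to the agonist-only enumeration).
#' @param n_grid number of scan points on `(0, ST)` (default `1e4`); dense
#'   enough that no branch of up to three solutions is missed.
#' @return A tibble of class `kpr_steady_states`, one row per steady state
#'   sorted by ascending `S`, with columns `S`, `C0..CN`, (`D0..DN`,)
#'   `CN_DN` (the activation readout `CN + DN`) and `residual`.
#' @examples
#' p <- kpr_params(kappa = 2e-4, nu1 = 1e-4, nu2 = 1e-2, L1 = 1, L2 = 0.5,
#'                 R = 1, ST = 10, N = 3)
#' antagonist_steady_states(p)
#' @export
antagonist_steady_states <- function(params, n_grid = 1e4) {
  stopifnot(inherits(params, "kpr_params"))
  sigma <- solve_sigma(params)
  with_D <- params$L2 > 0
  chC <- chain_u_polys(params, params$nu1)
  chD <- if (with_D) chain_u_polys(params, params$nu2)
  g <- function(S) {
    C1 <- chain_profile_at(chC, sigma$sigma1, S)[2]
    D1 <- if (with_D) chain_profile_at(chD, sigma$sigma2, S)[2] else 0
    params$alpha * (C1 + D1) * (params$ST - S) - params$beta * S
  }
  # log-spaced scan covering 12 decades below ST, plus approach to ST itself
  s_grid <- unique(sort(c(params$ST * 10^seq(-12, -0.001, length.out = n_grid),
                          params$ST * (1 - 10^seq(-9, -0.3, length.out = 50)))))
  vals <- vapply(s_grid, g, numeric(1))
  idx <- which(diff(sign(vals)) != 0)
  roots <- vapply(idx, function(i) {
    stats::uniroot(g, lower = s_grid[i], upper = s_grid[i + 1],
                   tol = 1e-14 * params$ST)$root
  }, numeric(1))
  if (!length(roots))
    stop("no steady state found by the fixed-point scan; existence is ",
         "guaranteed, so this indicates a numerical failure", call. = FALSE)
  rows <- purrr::map(roots, function(S) {
    C <- chain_profile_at(chC, sigma$sigma1, S)
    D <- if (with_D) chain_profile_at(chD, sigma$sigma2, S) else NULL
    if (any(C <= 0) || (!is.null(D) && any(D <= 0))) return(NULL)
    st <- kpr_state(S = S, C = C, D = D)
    resid <- sqrt(sum(unlist(state_to_vec(rhs_full(params, st)))^2))
    v <- as.list(state_to_vec(st))
    v$CN_DN <- C[params$N + 1L] + if (is.null(D)) 0 else D[params$N + 1L]
    v$residual <- resid
    tibble::as_tibble(v)
  })
  out <- dplyr::arrange(dplyr::bind_rows(purrr::compact(rows)), .data$S)
  attr(out, "params") <- params
  attr(out, "sigma") <- sigma
  class(out) <- c("kpr_steady_states", class(out))
  out
}

#' Dose-response surface of the maximally phosphorylated complex
#'
#' Computes the (possibly multi-valued) response function
#' `log10 CN = F(log10 L1, nu1)` by enumerating all steady states of the
#' agonist-only model at each grid point and labelling their stability.
#' Branches are stitched across the grid by nearest-neighbour matching in
#' `S`; fold points show up as births/deaths of branches.
#'
#' @param params a [kpr_params()] object with `L2 = 0`; its `L1` and `nu1`
#'   are overridden by the grids.
#' @param L1_grid vector of agonist concentrations (log-spaced
#'   recommended).  Defaults to the single value in `params`.
#' @param nu1_grid vector of dissociation rates; defaults to the single
#'   value in `params`.
#' @return A tibble of class `kpr_response` with columns `L1`, `nu1`,
#'   `logL1`, `branch`, `S`, `CN`, `logCN`, `stability`, `stable`.
#' @examples
#' \donttest{
#' p <- example_params("fig3")
#' rc <- response_function(p, L1_grid = 10^seq(-2, 8, length.out = 80))
#' autoplot(rc)
#' }
#' @export
response_function <- function(params, L1_grid = params$L1,
                              nu1_grid = params$nu1) {
  stopifnot(inherits(params, "kpr_params"))
  if (!params$agonist_only)
    stop("response_function() is defined for the agonist-only model", call. = FALSE)
  grid <- tidyr::expand_grid(nu1 = nu1_grid, L1 = L1_grid)
  CN_col <- paste0("C", params$N)
  prev_S <- NULL; prev_id <- NULL; next_id <- 1L
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    pi <- update_params(params, L1 = grid$L1[i], nu1 = grid$nu1[i])
    ss <- classify_steady_states(enumerate_steady_states(pi))
    S <- ss$S
    # nearest-neighbour branch continuation in S (log scale)
    if (is.null(prev_S) || grid$nu1[i] != grid$nu1[max(i - 1, 1)]) {
      ids <- seq_len(length(S)) + next_id - 1L
      next_id <- next_id + length(S)
    } else {
      ids <- integer(length(S))
      avail <- seq_along(prev_S)
      for (k in order(S)) {
        if (length(avail)) {
          d <- abs(log(S[k]) - log(prev_S[avail]))
          pick <- avail[which.min(d)]
          ids[k] <- prev_id[pick]
          avail <- setdiff(avail, pick)
        } else {
          ids[k] <- next_id
          next_id <- next_id + 1L
        }
      }
    }
    prev_S <- S; prev_id <- ids
    rows[[i]] <- tibble::tibble(
      L1 = grid$L1[i], nu1 = grid$nu1[i], logL1 = log10(grid$L1[i]),
      branch = ids, S = S, CN = ss[[CN_col]], logCN = log10(ss[[CN_col]]),
      stability = ss$stability,
      stable = grepl("^stable", ss$stability))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "params") <- params
  class(out) <- c("kpr_response", class(out))
  out
}

#' Small-ligand (kinetic proofreading) approximation of the response
#'
#' For `L1` much smaller than `R` the phosphatase stays nearly inactive and
#' the response is linear in `L1`:
#' `CN ~ {r-^N (1 - r-/r+) / (1 - (r-/r+)^(N+1)) * kappa R/(kappa R + nu1)} L1 (1 + q L1/R)`
#' with the characteristic roots evaluated in the limit `S -> 0` and the
#' correction factor bounded by `-1/4 < q < 0`.  On log-log axes this is a
#' line of slope one.  Because `q` is only bounded, the result is reported
#' as the `q = 0` leading term together with the `q = -1/4` end of the
#' bracket.
#'
#' @param params a [kpr_params()] object with `L2 = 0`.
#' @param L1 agonist concentration(s), ideally `<< R`.
#' @return A tibble with columns `L1`, `estimate` (`q = 0`), `lower`
#'   (`q = -1/4`) and `prefactor`.
#' @examples
#' p <- example_params("fig3")
#' asymptotic_small_L1(p, L1 = c(1, 10))
#' @export
asymptotic_small_L1 <- function(params, L1) {
  stopifnot(inherits(params, "kpr_params"))
  N <- params$N
  if (params$b > 0) {
    r <- characteristic_roots(params, S = 0)
    rr <- r[["r_minus"]] / r[["r_plus"]]
    shape <- r[["r_minus"]]^N * (1 - rr) / (1 - rr^(N + 1))
  } else {
    # b = 0, S -> 0: r+ -> Inf and the shape factor degenerates to r-^N
    shape <- (params$phi / (params$phi + params$nu1))^N
  }
  kR <- params$kappa * params$R
  pref <- shape * kR / (kR + params$nu1)
  tibble::tibble(L1 = L1,
                 estimate = pref * L1,
                 lower = pref * L1 * (1 - L1 / (4 * params$R)),
                 prefactor = pref)
}

#' Intermediate-regime approximation of the response
#'
#' In the regime where the activated phosphatase is well away from both `0`
#' and `ST` (large `ST`, small `L1/R`), the response obeys
#' `CN ~ (phi beta / (alpha gamma ST))^(N/2) ((kappa R + nu1)/(kappa R))^(N/2 - 1) L1^(1 - N/2)`.
#' For `N > 2` the exponent of `L1` is negative, so the response decreases
#' with ligand; the factor `((kappa R + nu1)/kappa R)^(N/2 - 1)` makes it
#' increasing in `nu1`.  The smallness parameters
#' `eta = (phi + nu1)/(b + gamma S)`, `eta' = max(eta, b/(gamma S))`,
#' `eta'' = max(eta', L1/R)` quantify the approximation error.
#'
#' @param params a [kpr_params()] object with `L2 = 0`, `kappa * R >= 1`.
#' @param L1 agonist concentration(s) with `L1 <= R`.
#' @param regime_tol value of `eta''` above which the `regime_ok` flag is
#'   dropped (default 0.25).
#' @return A tibble with columns `L1`, `estimate`, `S_est` (leading-order
#'   phosphatase level), `eta`, `eta_prime`, `eta_dblprime`, `regime_ok`.
#' @examples
#' p <- example_params("fig3")
#' asymptotic_intermediate(p, L1 = 10)
#' @export
asymptotic_intermediate <- function(params, L1, regime_tol = 0.25) {
  stopifnot(inherits(params, "kpr_params"))
  kR <- params$kappa * params$R
  if (kR < 1) stop("the intermediate-regime estimate assumes kappa * R >= 1",
                   call. = FALSE)
  if (any(L1 > params$R)) stop("the estimate assumes L1 <= R", call. = FALSE)
  N <- params$N
  C_star <- params$beta / params$alpha
  sigma1 <- kR * L1 / (kR + params$nu1)
  S_est <- sqrt(params$phi * params$ST * sigma1 / (C_star * params$gamma))
  est <- (params$phi * params$beta / (params$alpha * params$gamma * params$ST))^(N / 2) *
    ((kR + params$nu1) / kR)^(N / 2 - 1) * L1^(1 - N / 2)
  eta <- (params$phi + params$nu1) / (params$b + params$gamma * S_est)
  eta_p <- pmax(eta, params$b / (params$gamma * S_est))
  eta_pp <- pmax(eta_p, L1 / params$R)
  tibble::tibble(L1 = L1, estimate = est, S_est = S_est, eta = eta,
                 eta_prime = eta_p, eta_dblprime = eta_pp,
                 regime_ok = eta_pp < regime_tol)
}

#' Intermediate-regime approximation with an antagonist
#'
#' With both ligands present the intermediate-regime estimate for the
#' activation readout `CN + DN` is obtained from the agonist-only formula
#' by replacing the effective bound total `kappa R L1/(kappa R + nu1)` by
#' `kappa R L1/(kappa R + nu1) + kappa R L2/(kappa R + nu2)`:
#' `CN + DN ~ (phi C*/(gamma ST))^(N/2) Sigma_eff^(1 - N/2)`.  For `N > 2`
#' this is decreasing in `L2` at fixed `L1`: more antagonist lowers the
#' response to the agonist, through the shared SHP-1 feedback.
#'
#' @param params a [kpr_params()] object (with `L2 = 0` this reduces
#'   exactly to [asymptotic_intermediate()]).
#' @return A tibble with columns `sigma_eff`, `estimate`, `S_est`, `eta`.
#' @examples
#' p <- kpr_params(alpha = 1, beta = 5e2, gamma = 1.2e-6, phi = 9e-2,
#'                 b = 4e-2, kappa = 1e-4, nu1 = 1e-2, nu2 = 1e-1,
#'                 L1 = 10, L2 = 100, R = 3e4, ST = 6e5, N = 3)
#' antagonist_asymptotics(p)
#' @export
antagonist_asymptotics <- function(params) {
  stopifnot(inherits(params, "kpr_params"))
  kR <- params$kappa * params$R
  C_star <- params$beta / params$alpha
  sigma_eff <- kR * params$L1 / (kR + params$nu1) +
    kR * params$L2 / (kR + params$nu2)
  est <- (params$phi * C_star / (params$gamma * params$ST))^(params$N / 2) *
    sigma_eff^(1 - params$N / 2)
  S_est <- sqrt(params$phi * params$ST * sigma_eff / (C_star * params$gamma))
  eta <- (params$phi + max(params$nu1, params$nu2)) /
    (params$b + params$gamma * S_est)
  tibble::tibble(sigma_eff = sigma_eff, estimate = est, S_est = S_est,
                 eta = eta)
}
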