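# Linearization and eigenvalue classification of steady states.

#' Analytic Jacobian of the full system
#'
#' Partial derivatives of the mass-action right-hand side with respect to
#' the state `(S, C0..CN[, D0..DN])`, evaluated analytically.
#'
#' @param params a [kpr_params()] object.
#' @param state a [kpr_state()].
#' @return A square numeric matrix of size `1 + (N + 1)` (agonist-only) or
#'   `1 + 2(N + 1)` (two ligands), with dimnames matching the state layout.
#' @examples
#' p <- kpr_params(kappa = 2e-4, nu1 = 1e-4, L1 = 1, R = 1, ST = 10, N = 3)
#' s <- kpr_state(S = 1.1769, C = c(0.1570, 0.1334, 0.1133, 0.0963))
#' eigen(jacobian_matrix(p, s))$values
#' @export
jacobian_matrix <- function(params, state) {
  stopifnot(inherits(params, "kpr_params"), inherits(state, "kpr_state"))
  check_dims(params, state)
  N <- params$N
  with_D <- !is.null(state$D)
  S <- state$S
  C <- state$C
  D <- if (with_D) state$D else numeric(N + 1L)
  n <- 1L + (N + 1L) * (1L + with_D)
  J <- matrix(0, n, n)
  iS <- 1L
  iC <- 2L:(N + 2L)
  iD <- if (with_D) (N + 3L):(2L * N + 3L) else integer(0)
  bg <- params$b + params$gamma * S
  free_R <- params$R - sum(C) - sum(D)

  # S row: S' = alpha (C1 + D1)(ST - S) - beta S
  J[iS, iS] <- -params$alpha * (C[2] + D[2]) - params$beta
  J[iS, iC[2]] <- params$alpha * (params$ST - S)
  if (with_D) J[iS, iD[2]] <- params$alpha * (params$ST - S)

  chain_block <- function(idx, X, L, nu) {
    # X0 row: binding term kappa (L - sum X)(R - sumC - sumD)
    unboundL <- L - sum(X)
    J[idx[1], idx] <<- J[idx[1], idx] - params$kappa * (free_R + unboundL)
    other <- setdiff(c(iC, iD), idx)
    J[idx[1], other] <<- J[idx[1], other] - params$kappa * unboundL
    J[idx[1], idx[1]] <<- J[idx[1], idx[1]] - (params$phi + nu)
    J[idx[1], idx[2]] <<- J[idx[1], idx[2]] + bg
    J[idx[1], iS] <<- J[idx[1], iS] + params$gamma * X[2]
    if (N >= 2L) {
      for (j in 1:(N - 1L)) {     # rows X1..X_{N-1}
        r <- idx[j + 1L]
        J[r, idx[j]] <<- params$phi
        J[r, idx[j + 2L]] <<- bg
        J[r, r] <<- -(params$phi + bg + nu)
        J[r, iS] <<- params$gamma * (X[j + 2L] - X[j + 1L])
      }
    }
    r <- idx[N + 1L]
    J[r, idx[N]] <<- J[r, idx[N]] + params$phi
    J[r, r] <<- J[r, r] - (bg + nu)
    J[r, iS] <<- J[r, iS] - params$gamma * X[N + 1L]
  }
  chain_block(iC, C, params$L1, params$nu1)
  if (with_D) chain_block(iD, D, params$L2, params$nu2)
  nm <- c("S", paste0("C", 0:N), if (with_D) paste0("D", 0:N))
  dimnames(J) <- list(nm, nm)
  J
}

#' Classify the stability of a steady state
#'
#' Computes the eigenvalues of the analytic Jacobian at a steady state and
#' assigns a class label from their sign pattern: `stable-node` /
#' `stable-focus` (all real parts negative, dominant pair real / complex),
#' `saddle` (mixed signs), `unstable` (all positive), or `marginal` when
#' some real part is within tolerance of zero (never silently reported as
#' stable).
#'
#' @param params a [kpr_params()] object.
#' @param state a [kpr_state()] at (numerical) steady state.
#' @param tol relative marginality tolerance, scaled by the largest
#'   `|Re(lambda)|` (default `1e-8`).
#' @return An object of class `kpr_stability`: list with `eigenvalues`
#'   (complex, by decreasing real part), `class`, `unstable_dim` (number of
#'   eigenvalues with real part above `+tol`), and `oscillatory` (dominant
#'   eigenvalue pair is non-real).
#' @examples
#' p <- kpr_params(kappa = 2e-4, nu1 = 1e-4, L1 = 1, R = 1, ST = 10, N = 3)
#' ss <- enumerate_steady_states(p)
#' classify(p, kpr_state(S = ss$S[3], C = as.numeric(ss[3, paste0("C", 0:3)])))
#' @export
classify <- function(params, state, tol = 1e-8) {
  J <- jacobian_matrix(params, state)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  scale <- max(abs(Re(ev)), 1e-300)
  margin <- tol * scale
  re <- Re(ev)
  cls <- if (any(abs(re) < margin)) {
    "marginal"
  } else if (all(re < 0)) {
    if (abs(Im(ev[1])) > 0) "stable-focus" else "stable-node"
  } else if (all(re > 0)) {
    "unstable"
  } else {
    "saddle"
  }
  structure(list(eigenvalues = ev, class = cls,
                 unstable_dim = sum(re > margin),
                 oscillatory = abs(Im(ev[1])) > 0),
            class = "kpr_stability")
}

#' @export
print.kpr_stability <- function(x, ...) {
  cat(sprintf("<kpr_stability> %s (unstable-manifold dim %d%s)\n", x$class,
              x$unstable_dim, if (x$oscillatory) ", oscillatory" else ""))
  cat("  eigenvalues:", format(x$eigenvalues, digits = 4), "\n")
  invisible(x)
}

#' Append stability labels to an enumerated steady-state table
#'
#' @param steady_states a `kpr_steady_states` tibble from
#'   [enumerate_steady_states()] or [antagonist_steady_states()].
#' @param params parameters; taken from the table's attribute by default.
#' @inheritParams classify
#' @return The input tibble with added columns `stability`, `unstable_dim`,
#'   `oscillatory` and `max_re` (largest eigenvalue real part).
#' @examples
#' p <- kpr_params(kappa = 2e-4, nu1 = 1e-4, L1 = 1, R = 1, ST = 10, N = 3)
#' classify_steady_states(enumerate_steady_states(p))
#' @export
classify_steady_states <- function(steady_states,
                                   params = attr(steady_states, "params"),
                                   tol = 1e-8) {
  stopifnot(inherits(steady_states, "kpr_steady_states"))
  reports <- purrr::map(seq_len(nrow(steady_states)), function(i) {
    classify(params, row_to_state(steady_states[i, ], params), tol = tol)
  })
  steady_states$stability <- purrr::map_chr(reports, "class")
  steady_states$unstable_dim <- purrr::map_int(reports, "unstable_dim")
  steady_states$oscillatory <- purrr::map_lgl(reports, "oscillatory")
  steady_states$max_re <- purrr::map_dbl(reports, ~ max(Re(.x$eigenvalues)))
  attr(steady_states, "reports") <- reports
  steady_states
}

# tibble row -> kpr_state
row_to_state <- function(row, params) {
  N <- params$N
  C <- as.numeric(row[paste0("C", 0:N)])
  dn <- paste0("D", 0:N)
  D <- if (all(dn %in% names(row))) as.numeric(row[dn]) else NULL
  kpr_state(S = row$S[[1]], C = C, D = D)
}

#' Construct a damped-oscillation parameter regime (N = 1)
#'
#' For `N = 1` every solution converges to the unique steady state, but the
#' approach can be oscillatory.  The linearization has complex eigenvalues
#' exactly when its characteristic discriminant is negative; imposing the
#' balance `alpha C1 + beta = phi + b + gamma S + nu1` at the steady state
#' reduces the discriminant to `-4 alpha gamma (ST - S) C1 < 0`.  This
#' function solves that balance self-consistently by bisection in `beta`
#' (inner solve: the unique steady state given `beta`; outer: the balance
#' residual), following the continuity argument that the left side is
#' smaller for small `alpha, beta` and larger for large `beta`.
#'
#' @param template a [kpr_params()] object with `N = 1`, `L2 = 0`.  `beta`
#'   is treated as the free parameter.
#' @param beta_range search interval for `beta` on a log scale.
#' @return A list with `params` (the template with the solved `beta`),
#'   `state` (the steady state), `report` (its [classify()] output on the
#'   full system), `limiting_eigenvalues` (eigenvalue pair of the 2x2
#'   limiting-system linearization) and `discriminant` of its
#'   characteristic equation, or `NULL` if no sign change of the balance
#'   residual is found on `beta_range`.
#' @examples
#' \donttest{
#' p <- kpr_params(alpha = 0.1, gamma = 10, phi = 0.1, kappa = 2e-4,
#'                 nu1 = 1e-4, L1 = 1, R = 1, ST = 100, N = 1)
#' osc <- find_damped_oscillation_params(p)
#' osc$limiting_eigenvalues  # complex pair with negative real part
#' }
#' @export
find_damped_oscillation_params <- function(template,
                                           beta_range = c(1e-6, 1e4)) {
  stopifnot(inherits(template, "kpr_params"))
  if (template$N != 1L || !template$agonist_only)
    stop("the damped-oscillation construction requires N = 1, L2 = 0",
         call. = FALSE)
  balance <- function(beta) {
    p <- update_params(template, beta = beta)
    ss <- enumerate_steady_states(p)
    S <- ss$S[1]; C1 <- ss$C1[1]
    p$alpha * C1 + beta - (p$phi + p$b + p$gamma * S + p$nu1)
  }
  grid <- 10^seq(log10(beta_range[1]), log10(beta_range[2]), length.out = 60)
  vals <- vapply(grid, balance, numeric(1))
  sgn <- which(diff(sign(vals)) != 0)
  if (!length(sgn)) return(NULL)
  root <- stats::uniroot(balance, lower = grid[sgn[1]], upper = grid[sgn[1] + 1],
                         tol = 1e-12 * grid[sgn[1] + 1])
  params <- update_params(template, beta = root$root)
  ss <- enumerate_steady_states(params)
  state <- row_to_state(ss[1, ], params)
  # 2x2 linearization of the limiting system (S, C1) at the steady state
  S <- state$S; C1 <- state$C[2]
  J2 <- matrix(c(-params$alpha * C1 - params$beta, -params$gamma * C1,
                 params$alpha * (params$ST - S),
                 -(params$phi + params$b + params$gamma * S + params$nu1)),
               2L, 2L)
  ev2 <- eigen(J2, only.values = TRUE)$values
  disc <- (sum(diag(J2)))^2 - 4 * det(J2)
  list(params = params, state = state, report = classify(params, state),
       limiting_eigenvalues = ev2, discriminant = disc)
}
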