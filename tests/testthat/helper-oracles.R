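# Shared fixtures and independent oracles.

# the worked three-steady-state example parameters
params_3steady <- function() {
  kpr_params(alpha = 1, beta = 1, gamma = 1, phi = 1, b = 0, kappa = 2e-4,
             nu1 = 1e-4, L1 = 1, R = 1, ST = 10, N = 3)
}

# printed steady-state coordinates (S, C0, C1, C2, C3), sorted by S
printed_states <- function() {
  rbind(c(0.0005, 0.0001, 0.0001, 0.0003, 0.4996),
        c(0.2860, 0.0085, 0.0294, 0.1028, 0.3593),
        c(1.1769, 0.1570, 0.1334, 0.1133, 0.0963))
}

# random valid parameter draw over wide log-uniform ranges
random_params <- function(N = sample(1:4, 1), b_zero = NA, L2 = 0) {
  b <- if (isTRUE(b_zero)) 0 else if (isFALSE(b_zero)) 10^stats::runif(1, -2, 0)
       else sample(c(0, 10^stats::runif(1, -2, 0)), 1)
  kpr_params(alpha = 10^stats::runif(1, -2, 1), beta = 10^stats::runif(1, -2, 2),
             gamma = 10^stats::runif(1, -2, 1), phi = 10^stats::runif(1, -2, 1),
             b = b, kappa = 10^stats::runif(1, -4, 0),
             nu1 = 10^stats::runif(1, -4, 0),
             nu2 = 10^stats::runif(1, -4, 0),
             L1 = 10^stats::runif(1, -1, 1), L2 = L2,
             R = 10^stats::runif(1, -1, 1), ST = 10^stats::runif(1, 0, 2), N = N)
}

# random feasible state (margin-respecting)
random_state <- function(params) {
  N <- params$N
  sig1 <- stats::runif(1, 0, min(params$L1, params$R) * 0.9)
  w <- stats::rexp(N + 1); C <- sig1 * w / sum(w)
  D <- NULL
  if (params$L2 > 0) {
    sig2 <- stats::runif(1, 0, 0.9 * min(params$L2, params$R - sig1))
    w <- stats::rexp(N + 1); D <- sig2 * w / sum(w)
  }
  kpr_state(S = stats::runif(1, 0, params$ST), C = C, D = D)
}

# brute-force positive-root oracle: dense evaluation + sign-change bisection
bisect_roots <- function(coef, upper, n = 20000L) {
  f <- function(x) vapply(x, function(xx) sum(coef * xx^(seq_along(coef) - 1)),
                          numeric(1))
  xs <- seq(1e-12, upper, length.out = n)
  ys <- f(xs)
  idx <- which(diff(sign(ys)) != 0)
  vapply(idx, function(i)
    stats::uniroot(f, lower = xs[i], upper = xs[i + 1], tol = 1e-14)$root,
    numeric(1))
}

# central finite-difference Jacobian of the full right-hand side
fd_jacobian <- function(params, state, h_rel = 1e-6) {
  y0 <- unname(unlist(state[c("S", "C", "D")]))
  with_D <- !is.null(state$D)
  unpack <- function(y) {
    N <- params$N
    kpr_state(S = y[1], C = y[2:(N + 2)],
              D = if (with_D) y[(N + 3):(2 * N + 3)] else NULL)
  }
  f <- function(y) unlist(state_vec_of(rhs_full(params, unpack(y))))
  n <- length(y0)
  J <- matrix(0, n, n)
  for (k in seq_len(n)) {
    h <- h_rel * max(abs(y0[k]), 1)
    yp <- y0; yp[k] <- yp[k] + h
    ym <- y0; ym[k] <- ym[k] - h
    J[, k] <- (f(yp) - f(ym)) / (2 * h)
  }
  J
}

# flatten a kpr_state into the (S, C, D) ordering used by the Jacobian
state_vec_of <- function(state) {
  c(state$S, state$C, state$D)
}
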