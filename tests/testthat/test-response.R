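fig3_params <- function() {
  kpr_params(alpha = 1, beta = 5e2, gamma = 1.2e-6, phi = 9e-2, b = 4e-2,
             kappa = 1e-4, nu1 = 1e-2, L1 = 1, R = 3e4, ST = 6e5, N = 3)
}

fig4_params <- function() {
  kpr_params(alpha = 1e-1, beta = 10, gamma = 1e-4, phi = 1e-2, b = 1e-2,
             kappa = 1e-6, nu1 = 1e-2, L1 = 1e3, R = 1e5, ST = 1e7, N = 3)
}

test_that("characteristic roots: closed form, bounds and Vieta relations", {
  set.seed(83)
  for (i in 1:30) {
    p <- random_params()
    S <- stats::runif(1, 0, p$ST)
    r <- characteristic_roots(p, S)
    bg <- p$b + p$gamma * S
    expect_lt(r[["r_minus"]], 1)
    expect_gt(r[["r_plus"]], 1)
    # sharper bound used in the intermediate regime
    expect_lt(r[["r_minus"]], p$phi / (p$phi + p$nu1))
    # Vieta: product phi/bg, sum (phi + bg + nu1)/bg
    expect_equal(r[["r_minus"]] * r[["r_plus"]], p$phi / bg, tolerance = 1e-10)
    expect_equal(r[["r_minus"]] + r[["r_plus"]],
                 (p$phi + bg + p$nu1) / bg, tolerance = 1e-10)
    # each root satisfies the characteristic equation
    for (root in r)
      expect_equal(p$phi + bg * root^2 - (p$phi + bg + p$nu1) * root, 0,
                   tolerance = 1e-9 * (p$phi + bg + p$nu1))
  }
  # nu = 0 factorizes the quadratic into roots {phi/bg, 1}
  p <- kpr_params(b = 0.5, kappa = 1e-3, nu1 = 1e-2, L1 = 1, R = 1, ST = 2,
                  N = 3, phi = 2)
  r0 <- characteristic_roots(p, S = 1, nu = 0)
  expect_equal(sort(unname(r0)), sort(c(1, p$phi / (p$b + p$gamma))),
               tolerance = 1e-12)
  # degenerate case b + gamma S = 0
  pb0 <- kpr_params(b = 0, kappa = 1e-3, nu1 = 1e-2, L1 = 1, R = 1, ST = 2)
  expect_error(characteristic_roots(pb0, S = 0), "degenerate")
})

test_that("chain coefficients: positivity, factor identity and cross-checks", {
  set.seed(89)
  for (i in 1:50) {
    p <- random_params(N = sample(1:5, 1))
    S <- stats::runif(1, 0, p$ST)
    sg <- solve_sigma(p)
    pr <- solve_coefficients(p, S, sg$sigma1)
    expect_gt(pr$a_minus, 0)
    expect_gt(pr$a_plus, 0)
    expect_gt(pr$A, 0)
    expect_gt(pr$A, pr$B)
    # factor identity: product of the two boundary factors
    bg <- p$b + p$gamma * S
    fm <- p$phi - (bg + p$nu1) * pr$r_minus
    fp <- p$phi - (bg + p$nu1) * pr$r_plus
    target <- -p$phi^2 * p$nu1 / bg
    # residual measured against the factor magnitudes (the product itself
    # is tiny when nu1 is small)
    expect_lt(abs(fm * fp - target), 1e-12 * abs(fp) * max(abs(fm), p$phi))
    # alternative a+ relation through the summed profile
    ap2 <- -pr$a_minus * (pr$r_minus / pr$r_plus)^(p$N + 1) *
      (pr$r_plus - 1) / (pr$r_minus - 1)
    expect_equal(pr$a_plus, ap2, tolerance = 1e-7)
    # the profile sums to the bound total
    expect_equal(sum(pr$C), sg$sigma1, tolerance = 1e-9)
  }
})

test_that("parametrization and polynomial routes give identical chains", {
  p <- params_3steady()
  ss <- enumerate_steady_states(p)
  sg <- solve_sigma(p)
  for (i in seq_len(nrow(ss))) {
    pr <- solve_coefficients(p, ss$S[i], sg$sigma1)
    expect_equal(pr$C, as.numeric(ss[i, 2:5]), tolerance = 1e-9)
  }
})

test_that("dose response at the multi-regime parameters", {
  p <- fig3_params()
  grid <- 10^seq(-2, 8, length.out = 100)
  rc <- response_function(p, L1_grid = grid)
  expect_true(all(rc$branch == 1))   # monostable throughout here
  # slope one over the lowest decade
  low <- rc[rc$L1 <= 10^-1, ]
  slope <- stats::coef(stats::lm(logCN ~ logL1, data = low))[2]
  expect_lt(abs(slope - 1), 0.05)
  # a strictly decreasing interval exists, then increase, then saturation
  d <- diff(rc$logCN)
  expect_true(any(d < -1e-8))
  first_dec <- min(which(d < -1e-8))
  expect_true(any(d[first_dec:length(d)] > 1e-8))
  tail_slope <- (rc$logCN[100] - rc$logCN[95]) / (rc$logL1[100] - rc$logL1[95])
  expect_lt(abs(tail_slope), 1e-3)   # saturated
})

test_that("response has an interior optimum in the dissociation rate", {
  p <- fig4_params()
  nu_grid <- 10^seq(-4, 1, length.out = 40)
  cn <- vapply(nu_grid, function(nv)
    max(enumerate_steady_states(update_params(p, nu1 = nv))$C3), numeric(1))
  im <- which.max(cn)
  expect_gt(im, 1)
  expect_lt(im, length(cn))
  expect_gt(cn[im], cn[1])
  expect_gt(cn[im], cn[length(cn)])
})

test_that("small-ligand approximation: slope one and vanishing relative error", {
  p <- fig3_params()
  L1s <- 10^seq(-3, 0, length.out = 7)
  est <- asymptotic_small_L1(p, L1s)
  # exactly linear in L1 at leading order: log-log slope 1
  sl <- diff(log10(est$estimate)) / diff(log10(L1s))
  expect_equal(sl, rep(1, 6), tolerance = 1e-10)
  # q-bracket: the lower end is below the q = 0 value
  expect_true(all(est$lower < est$estimate))
  # error against the full solver shrinks as L1 -> 0, below 5% at L1 = 1
  err <- vapply(L1s, function(L) {
    ex <- max(enumerate_steady_states(update_params(p, L1 = L))$C3)
    abs(asymptotic_small_L1(p, L)$estimate / ex - 1)
  }, numeric(1))
  expect_lt(err[length(err)], 0.05)
  expect_lt(err[1], err[length(err)])
})

test_that("intermediate-regime approximation: exponents and nu1 dependence", {
  p <- fig3_params()
  # N = 3: estimate proportional to L1^(-1/2), hence decreasing
  a <- asymptotic_intermediate(p, c(100, 400))
  expect_equal(a$estimate[1] / a$estimate[2], sqrt(400 / 100),
               tolerance = 1e-12)
  # N = 2: independent of L1
  p2 <- update_params(p, N = 2)
  a2 <- asymptotic_intermediate(p2, c(100, 400))
  expect_equal(a2$estimate[1], a2$estimate[2], tolerance = 1e-12)
  # increasing in nu1 for N = 3 through ((kappa R + nu1)/kappa R)^(1/2)
  vals <- vapply(c(1e-3, 1e-2, 1e-1), function(nv)
    asymptotic_intermediate(update_params(p, nu1 = nv), 100)$estimate,
    numeric(1))
  expect_true(all(diff(vals) > 0))
  # preconditions
  expect_error(asymptotic_intermediate(update_params(p, kappa = 1e-9), 1),
               "kappa")
  expect_error(asymptotic_intermediate(p, 1e9), "L1")
})

test_that("intermediate approximation error and the large-ST contract", {
  p <- fig3_params()
  relerr <- function(params, L1) {
    ex <- max(enumerate_steady_states(update_params(params, L1 = L1))$C3)
    abs(asymptotic_intermediate(update_params(params, L1 = L1), L1)$estimate /
          ex - 1)
  }
  e0 <- relerr(p, 1e3)
  e1 <- relerr(update_params(p, ST = 6e6), 1e2)   # ST x10, L1 /10
  expect_lt(e1, e0)
  # deep in the regime the estimate is accurate to a few percent
  deep <- update_params(p, ST = 6e7)
  a <- asymptotic_intermediate(deep, 100)
  expect_true(a$regime_ok)
  expect_lt(relerr(deep, 100), 0.05)
})

test_that("two-ligand steady states: limits, roots and the antagonist effect", {
  p <- params_3steady()
  # the scan route on an agonist-only instance reproduces the polynomial route
  a0 <- antagonist_steady_states(p)
  ss <- enumerate_steady_states(p)
  expect_equal(a0$S, ss$S, tolerance = 1e-9)
  # a vanishing antagonist dose recovers the agonist-only states continuously
  a_eps <- antagonist_steady_states(update_params(p, L2 = 1e-8, nu2 = 1e-4))
  expect_equal(a_eps$S, ss$S, tolerance = 1e-4)
  # r-/r+ of the two chains differ only through nu1 vs nu2
  pd <- kpr_params(alpha = 1, beta = 5e2, gamma = 1.2e-6, phi = 9e-2,
                   b = 4e-2, kappa = 1e-4, nu1 = 1e-2, nu2 = 1e-1,
                   L1 = 100, L2 = 200, R = 3e4, ST = 6e7, N = 3)
  S <- antagonist_steady_states(pd)$S[1]
  rC <- characteristic_roots(pd, S, nu = pd$nu1)
  rD <- characteristic_roots(pd, S, nu = pd$nu2)
  rD_as_C <- characteristic_roots(update_params(pd, nu1 = pd$nu2), S)
  expect_equal(unname(rD), unname(rD_as_C), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(rC[["r_minus"]], rD[["r_minus"]])))
  # every returned state is a steady state of the coupled system
  # (residual scaled by the state magnitude)
  a <- antagonist_steady_states(pd)
  expect_true(all(a$residual < 1e-8 * pmax(1, a$S)))
})

test_that("more antagonist lowers the response to the agonist (N = 3)", {
  pd <- kpr_params(alpha = 1, beta = 5e2, gamma = 1.2e-6, phi = 9e-2,
                   b = 4e-2, kappa = 1e-4, nu1 = 1e-2, nu2 = 1e-1,
                   L1 = 100, L2 = 0, R = 3e4, ST = 6e7, N = 3)
  exact <- vapply(c(100, 200, 400), function(L2)
    max(antagonist_steady_states(update_params(pd, L2 = L2))$CN_DN),
    numeric(1))
  expect_true(all(diff(exact) < 0))
  approx <- vapply(c(100, 200, 400), function(L2)
    antagonist_asymptotics(update_params(pd, L2 = L2))$estimate, numeric(1))
  expect_true(all(diff(approx) < 0))   # same sign as the exact computation
})

test_that("antagonist asymptotics: reduction, symmetry and accuracy", {
  pd <- kpr_params(alpha = 1, beta = 5e2, gamma = 1.2e-6, phi = 9e-2,
                   b = 4e-2, kappa = 1e-4, nu1 = 1e-2, nu2 = 1e-1,
                   L1 = 100, L2 = 200, R = 3e4, ST = 6e7, N = 3)
  # L2 = 0 reduces exactly to the agonist-only intermediate estimate
  p0 <- update_params(pd, L2 = 0)
  expect_equal(antagonist_asymptotics(p0)$estimate,
               asymptotic_intermediate(p0, p0$L1)$estimate, tolerance = 1e-12)
  # symmetric ligands: depends on L1 + L2 only
  psym <- update_params(pd, nu2 = pd$nu1, L1 = 120, L2 = 180)
  psym2 <- update_params(pd, nu2 = pd$nu1, L1 = 200, L2 = 100)
  expect_equal(antagonist_asymptotics(psym)$estimate,
               antagonist_asymptotics(psym2)$estimate, tolerance = 1e-12)
  # accuracy against the exact two-ligand solver at a validated point
  ex <- max(antagonist_steady_states(pd)$CN_DN)
  expect_lt(abs(antagonist_asymptotics(pd)$estimate / ex - 1), 0.10)
})

test_that("response branches coincide with the enumeration at each point", {
  p <- params_3steady()
  grid <- 10^seq(-0.5, 1, length.out = 12)   # crosses the fold
  rc <- response_function(p, L1_grid = grid)
  for (L in grid) {
    ss <- enumerate_steady_states(update_params(p, L1 = L))
    here <- rc[rc$L1 == L, ]
    expect_equal(sort(here$S), ss$S, tolerance = 1e-10)
    expect_true(all(here$branch %in% 1:3))
  }
})
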