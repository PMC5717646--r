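test_that("bound-total equation: closed-form agonist case and symmetry", {
  # kappa (1 - s)(1 - s) = nu1 s with nu1/kappa = 1/2: 2 s^2 - 5 s + 2 = 0,
  # root in [0, 1] is exactly 1/2
  p <- params_3steady()
  sg <- solve_sigma(p)
  expect_equal(sg$sigma1, 0.5, tolerance = 1e-14)
  expect_lt(max(abs(sg$residuals)), 1e-12)
  # symmetric ligands split the bound total equally
  ps <- kpr_params(kappa = 1e-3, nu1 = 1e-2, nu2 = 1e-2, L1 = 0.7, L2 = 0.7,
                   R = 1, ST = 5, N = 2)
  sgs <- solve_sigma(ps)
  expect_equal(sgs$sigma1, sgs$sigma2, tolerance = 1e-10)
  # printed steady states: C0..C3 sum to Sigma* within the printed precision
  for (i in 1:3) expect_lt(abs(sum(printed_states()[i, -1]) - 0.5), 1e-3)
})

test_that("bound-total equation is monotone on the bracket (uniqueness)", {
  set.seed(5)
  for (i in 1:10) {
    p <- random_params(L2 = 0.5)
    k <- p$kappa
    lhs <- function(s) k * (p$L1 + p$L2 - s)
    rhs <- function(s) k * p$L1 * p$nu1 / (k * (p$R - s) + p$nu1) +
      k * p$L2 * p$nu2 / (k * (p$R - s) + p$nu2)
    s <- seq(0, min(p$L1 + p$L2, p$R), length.out = 50)
    expect_true(all(diff(lhs(s)) < 0))
    expect_true(all(diff(rhs(s)) > 0))
  }
})

test_that("S-polynomial signs: worked example and small-N patterns", {
  p <- params_3steady()
  sp <- s_polynomial(p)
  expect_identical(sp$sign_changes, 3L)  # one or three positive roots
  expect_lt(sp$coefficients[1], 0)
  expect_gt(sp$coefficients[5], 0)
  # N = 2: sign pattern is (-, -, +, +) or (-, +, +, +)
  set.seed(23)
  for (i in 1:25) {
    p2 <- random_params(N = 2)
    sgn <- sign(s_polynomial(p2)$coefficients)
    expect_equal(sgn[1], -1)
    expect_true(all(sgn[3:4] == 1))
  }
  # N = 1: negative at S = 0, positive leading term
  p1 <- random_params(N = 1)
  co <- s_polynomial(p1)$coefficients
  expect_lt(co[1], 0)
  expect_gt(co[3], 0)
})

test_that("closed-form and elimination coefficients agree for N = 1, 2, 3", {
  set.seed(29)
  for (i in 1:30) {
    p <- random_params(N = sample(1:3, 1))
    a_el <- s_polynomial(p, route = "elimination")$coefficients
    a_pr <- s_polynomial(p, route = "printed")$coefficients
    expect_equal(a_pr, a_el, tolerance = 1e-11)
  }
  # and route = "both" enforces the agreement internally
  expect_s3_class(s_polynomial(params_3steady(), route = "both"), "kpr_spoly")
})

test_that("positive root finder: constructed factorization and random quartics", {
  # (S - 1)(S - 2)(S + 3)(S + 4) = S^4 + 4 S^3 - 7 S^2 - 22 S + 24
  coef <- c(24, -22, -7, 4, 1)
  r <- positive_roots(coef)
  expect_equal(r$root, c(1, 2), tolerance = 1e-12)
  expect_equal(r$multiplicity, c(1L, 1L))
  # random quartics vs dense-evaluation bisection oracle
  set.seed(31)
  for (i in 1:20) {
    coef <- stats::rnorm(5)
    coef[5] <- coef[5] + sign(coef[5]) * 0.5  # keep leading term away from 0
    got <- positive_roots(coef)
    want <- bisect_roots(coef, upper = 10 + 10 * max(abs(coef)) / abs(coef[5]))
    simple <- got$root[got$multiplicity == 1L]
    expect_equal(sort(simple), sort(want), tolerance = 1e-7)
  }
})

test_that("worked example: quartic has the three printed roots", {
  p <- params_3steady()
  r <- positive_roots(s_polynomial(p))
  expect_equal(nrow(r), 3L)
  expect_equal(r$root, c(0.0005, 0.2860, 1.1769), tolerance = 2e-3)
})

test_that("back-substitution reproduces the printed coordinates", {
  p <- params_3steady()
  sg <- solve_sigma(p)
  roots <- positive_roots(s_polynomial(p))$root
  st_hi <- backsubstitute(p, sg, max(roots))
  expect_equal(st_hi$C, c(0.1570, 0.1334, 0.1133, 0.0963), tolerance = 5e-3)
  st_lo <- backsubstitute(p, sg, min(roots))
  expect_equal(st_lo$C[4], 0.4996, tolerance = 1e-3)
  # reconstructed state is a steady state of the full system
  expect_lt(attr(st_hi, "residual"), 1e-8)
  expect_lt(attr(st_hi, "c1_check"), 1e-8)
  expect_error(backsubstitute(p, sg, 11), "ST")
})

test_that("enumeration: three states at the worked example, one at small ST", {
  p <- params_3steady()
  ss <- enumerate_steady_states(p)
  expect_equal(nrow(ss), 3L)
  expect_equal(as.matrix(ss[, 1:5]), printed_states(),
               tolerance = 5e-4, ignore_attr = TRUE)
  expect_true(all(ss$residual < 1e-8))
  # small total phosphatase: all coefficients beyond a0 positive, one root
  ss1 <- enumerate_steady_states(update_params(p, ST = 0.1))
  expect_equal(nrow(ss1), 1L)
  # every state strictly inside the feasible region
  for (i in seq_len(nrow(ss))) {
    f <- feasibility(p, kpr_state(S = ss$S[i], C = as.numeric(ss[i, 2:5])))
    expect_identical(attr(f, "classification"), "interior")
  }
})

test_that("uniqueness for N = 1 and N = 2 over randomized parameters", {
  set.seed(37)
  for (N in 1:2) {
    for (i in 1:50) {
      p <- random_params(N = N)
      expect_identical(nrow(enumerate_steady_states(p)), as.integer(1))
    }
  }
})

test_that("root count never exceeds the Descartes bound (N = 3 randomized)", {
  set.seed(41)
  for (i in 1:40) {
    p <- random_params(N = 3)
    sp <- s_polynomial(p)
    n <- nrow(positive_roots(sp))
    expect_lte(n, sp$sign_changes)
    expect_lte(n, 3L)
  }
})

test_that("polynomial route agrees with direct multistart root solve", {
  # independent oracle: Newton on the full rhs from many starting points
  p <- params_3steady()
  ss <- enumerate_steady_states(p)
  f <- function(y) c(rhs_full(p, kpr_state(S = y[1], C = y[2:5]))$S,
                     rhs_full(p, kpr_state(S = y[1], C = y[2:5]))$C)
  set.seed(43)
  found <- c()
  for (i in 1:40) {
    y <- c(stats::runif(1, 0, 10), stats::runif(4, 0, 0.3))
    for (it in 1:200) {
      J <- jacobian_matrix(p, kpr_state(S = y[1], C = y[2:5]))
      step <- tryCatch(solve(J, f(y)), error = function(e) NULL)
      if (is.null(step)) break
      y <- y - step
      if (max(abs(step)) < 1e-13) break
    }
    if (max(abs(f(y))) < 1e-10 && all(y > 0) && y[1] < p$ST)
      found <- c(found, y[1])
  }
  found <- sort(unique(round(found, 8)))
  expect_equal(found, ss$S, tolerance = 1e-6)
})

test_that("scaling family: three roots and the sign certificates for small eps", {
  for (eps in c(0.1, 0.05, 0.02)) {
    p <- epsilon_family(eps)
    co <- s_polynomial(p)$coefficients
    peval <- function(x) sum(co * x^(seq_along(co) - 1))
    expect_lt(peval(1), 0)
    expect_gt(peval(eps^2), 0)
    expect_equal(nrow(enumerate_steady_states(p)), 3L)
  }
  # without scaling (eps = 1) the benign base instance is monostable
  expect_equal(nrow(enumerate_steady_states(epsilon_family(1))), 1L)
  # kappa is rescaled so the bound total is unchanged
  expect_equal(solve_sigma(epsilon_family(0.05))$sigma1,
               solve_sigma(epsilon_family(1))$sigma1, tolerance = 1e-12)
})

test_that("enumeration refuses two-ligand instances and degenerate input", {
  p <- kpr_params(kappa = 1e-3, nu1 = 1e-2, nu2 = 1e-2, L1 = 1, L2 = 0.5,
                  R = 1, ST = 5, N = 2)
  expect_error(enumerate_steady_states(p), "antagonist_steady_states")
})
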