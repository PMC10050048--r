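# Update schemes: trust-radius table, trust-region subproblem (bisection
# oracle, KKT), approximated line search (grid-search oracle), and driver
# contracts.

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("trust-radius update reproduces the three enumerated cases", {
  up <- trust_radius_update(Q = -10, S_old = 100, S_new = 91, R = 2, dmax = 2)
  expect_equal(up$rho, 0.9)
  expect_true(up$accept)
  expect_equal(up$R, 2)       # 2 * 5/4 = 2.5 capped at |d|max = 2
  up <- trust_radius_update(Q = -10, S_old = 100, S_new = 99, R = 2, dmax = 2)
  expect_equal(up$rho, 0.1)
  expect_equal(up$R, 1)       # rho < 0.25 -> halve
  up <- trust_radius_update(Q = -10, S_old = 100, S_new = 95, R = 1, dmax = 2)
  expect_equal(up$rho, 0.5)
  expect_equal(up$R, 1)       # otherwise unchanged
  # an increase always rejects and halves, whatever rho says
  up <- trust_radius_update(Q = 1e-16, S_old = 100, S_new = 101, R = 1, dmax = 2)
  expect_false(up$accept)
  expect_equal(up$R, 0.5)
})

test_that("trust-region step: interior Newton case and boundary bisection
           oracle", {
  B <- diag(c(1, 4)); g <- c(0.1, 0.1)
  st <- tro_step(g, B, R = 1)
  expect_equal(st$lambda, 0)
  expect_equal(st$d, -solve(B, g), tolerance = 1e-12)
  # constrained case against a plain bisection on |d(lambda)| = R
  g <- c(1, 1); R <- 0.5
  st <- tro_step(g, B, R)
  phi <- function(l) sqrt(sum((solve(B + l * diag(2), g))^2)) - R
  lo <- 0; hi <- 10
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (phi(mid) > 0) lo <- mid else hi <- mid
  }
  expect_equal(st$lambda, (lo + hi) / 2, tolerance = 1e-8)
  expect_equal(sqrt(sum(st$d^2)), R, tolerance = 1e-8)
  expect_lte(st$Q, 0)
})

test_that("trust-region steps satisfy the KKT conditions on random
           indefinite models", {
  set.seed(31)
  for (i in 1:12) {
    n <- 6
    M <- matrix(stats::rnorm(n * n), n); B <- (M + t(M)) / 2
    g <- stats::rnorm(n)
    R <- stats::runif(1, 0.1, 2)
    st <- tro_step(g, B, R)
    expect_lte(sqrt(sum(st$d^2)), R + 1e-10)
    expect_gte(st$lambda, 0)
    expect_lt(abs(st$lambda * (sqrt(sum(st$d^2)) - R)), 1e-8)
    expect_lte(st$Q, 1e-12)   # model never predicts an increase
    # stationarity of the shifted model
    expect_lt(max(abs((B + st$lambda * diag(n)) %*% st$d + g)), 1e-6)
  }
})

test_that("the hard case is resolved on the boundary", {
  B <- diag(c(-2, 1, 3))
  g <- c(0, 0.5, 0.5)          # no component along the lowest eigenvector
  st <- tro_step(g, B, R = 1)
  expect_true(st$hard)
  expect_equal(sqrt(sum(st$d^2)), 1, tolerance = 1e-10)
  expect_equal(st$lambda, 2, tolerance = 1e-10)
  expect_lte(st$Q, 0)
})

test_that("ALS: stationary input, unit direction, closed-form step length
           against a grid search", {
  ents <- lapply(list(fix_h2(), fix_hf()), function(m) {
    v <- molecule_properties(m, mndo_pset)
    training_entry(m, hf = v$hf + 2, ie = v$ie - 0.2, dip = v$dip)
  })
  r <- evaluate_objective(ents, mndo_pset, order = 2)
  # absent-element rows make the curvature matrix singular; the documented
  # pseudo-inverse fallback applies
  expect_warning(st <- als_step(r$gradient, modified_hessian(r$H), r, cap = 2),
                 "pseudo-inverse")
  expect_equal(sqrt(sum(st$dhat^2)), 1, tolerance = 1e-12)
  # surrogate on a dense grid
  res <- r$residuals$ref - r$residuals$value
  w2 <- r$residuals$weight^2
  tv <- as.vector(r$jacobian %*% st$dhat)
  Stilde <- function(k) sum(w2 * (res - k * tv)^2)
  ks <- seq(0, 2, by = 1e-4)
  kgrid <- ks[which.min(vapply(ks, Stilde, 0))]
  expect_lt(abs(st$k - kgrid), 2e-4)
  # zero gradient gives a zero step
  st0 <- als_step(0 * r$gradient, diag(37), r, cap = 2)
  expect_equal(sum(abs(st0$d)), 0)
})

test_that("driver contracts: monotone accepted S, immediate termination at
           a perfect fit, rejected steps never move the parameters", {
  mols <- list(fix_h2(), fix_hf())
  entries <- generate_reference_data(mols, mndo_pset, geo = FALSE)
  # start exactly at the generating parameters: g ~ 0, stop at once
  opt0 <- optimize_parameters(entries, mndo_pset, method = "tro",
                              hessian = "pm7", maxiter = 10, gtol = 1e-4)
  expect_lte(nrow(opt0$trace) %||% 0L, 1L)
  expect_lt(opt0$S, 1e-10)
  # perturbed start: every accepted step decreases S
  fl <- flatten_parameters(mndo_pset)
  set.seed(8)
  p1 <- fl$p * stats::runif(37, 0.995, 1.005)
  opt <- optimize_parameters(entries, unflatten_parameters(p1, mndo_pset),
                             method = "tro", hessian = "abs", maxiter = 15,
                             R0 = 0.05, dmax = 2)
  tr <- opt$trace
  acc <- tr$S[tr$accepted]
  expect_true(all(diff(acc) < 0))
  expect_lt(opt$S, tr$S[1])
})
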