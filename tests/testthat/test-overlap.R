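# Slater-overlap engine against an independent prolate-spheroidal
# quadrature oracle (Gauss-Legendre x Gauss-Laguerre), plus limiting and
# symmetry behaviour.

quad_overlap <- function(na, ka, za, nb, kb, zb, R) {
  gl <- pracma::gaussLegendre(100, -1, 1)
  glx <- pracma::gaussLaguerre(100, 0)
  Rh <- R / 2
  nrad <- function(n, z) (2 * z)^(n + 0.5) / sqrt(factorial(2 * n))
  angn <- (if (ka == "s") 1 / sqrt(4 * pi) else sqrt(3 / (4 * pi))) *
    (if (kb == "s") 1 / sqrt(4 * pi) else sqrt(3 / (4 * pi)))
  phif <- if (ka == "pi") pi else 2 * pi
  tot <- 0
  for (i in seq_along(glx$x)) {
    t <- glx$x[i]; wx <- glx$w[i]
    xi <- 1 + t
    eta <- gl$x; we <- gl$w
    ra <- Rh * (xi + eta); rb <- Rh * (xi - eta)
    zA <- Rh * (1 + xi * eta); zB <- Rh * (xi * eta - 1)
    perp2 <- Rh^2 * (xi^2 - 1) * (1 - eta^2)
    fa <- switch(ka, s = if (na == 1) 1 else ra, sig = zA,
                 pi = sqrt(pmax(perp2, 0)))
    fb <- switch(kb, s = if (nb == 1) 1 else rb, sig = zB,
                 pi = sqrt(pmax(perp2, 0)))
    tot <- tot + wx * sum(we * fa * fb * exp(-za * ra - zb * rb + t) *
                            (xi^2 - eta^2))
  }
  nrad(na, za) * nrad(nb, zb) * angn * phif * Rh^3 * tot
}

jet1 <- function() mndopt:::.jet_scalar_basis()

ovl <- function(na, ka, za, nb, kb, zb, Rbohr) {
  B <- jet1()
  mndopt:::sto_overlap_entry(B, na, ka, mndopt:::jet_const(B, za),
                             nb, kb, mndopt:::jet_const(B, zb),
                             mndopt:::jet_const(B, Rbohr))[1]
}

test_that("overlaps match 2-D quadrature of the Slater product to 1e-8", {
  skip_if_not_installed("pracma")
  a0 <- mndo_units$bohr
  cases <- list(
    list(1L, "s", 1.331967, 1L, "s", 1.331967, 0.74 / a0),
    list(1L, "s", 1.331967, 2L, "s", 1.787537, 1.10 / a0),
    list(1L, "s", 1.331967, 2L, "sig", 1.787537, 1.10 / a0),
    list(2L, "s", 2.255614, 2L, "s", 1.787537, 1.30 / a0),
    list(2L, "s", 1.787537, 2L, "sig", 2.699905, 1.20 / a0),
    list(2L, "sig", 1.787537, 2L, "sig", 2.699905, 1.20 / a0),
    list(2L, "sig", 1.787537, 2L, "s", 2.699905, 1.20 / a0),
    list(2L, "pi", 1.787537, 2L, "pi", 2.699905, 1.20 / a0),
    list(2L, "pi", 2.255614, 2L, "pi", 2.255614, 1.05 / a0))
  for (cs in cases) {
    got <- ovl(cs[[1]], cs[[2]], cs[[3]], cs[[4]], cs[[5]], cs[[6]], cs[[7]])
    want <- quad_overlap(cs[[1]], cs[[2]], cs[[3]], cs[[4]], cs[[5]],
                         cs[[6]], cs[[7]])
    expect_lt(abs(got - want), 1e-8)
  }
})

test_that("overlap decays at large separation and is symmetric under swap", {
  a0 <- mndo_units$bohr
  expect_lt(abs(ovl(2L, "s", 1.8, 2L, "s", 2.7, 1e3 / a0)), 1e-12)
  # swapping atoms transposes the block: s-sig picks up the sign of the
  # sigma lobe orientation, pi-pi and s-s are symmetric
  expect_equal(ovl(2L, "s", 1.8, 2L, "s", 2.7, 2.3),
               ovl(2L, "s", 2.7, 2L, "s", 1.8, 2.3), tolerance = 1e-12)
  expect_equal(ovl(2L, "s", 1.8, 2L, "sig", 2.7, 2.3),
               -ovl(2L, "sig", 2.7, 2L, "s", 1.8, 2.3), tolerance = 1e-12)
  expect_equal(ovl(2L, "pi", 1.8, 2L, "pi", 2.7, 2.3),
               ovl(2L, "pi", 2.7, 2L, "pi", 1.8, 2.3), tolerance = 1e-12)
})

test_that("zeta and distance derivatives agree with the FD oracle, including
           the series-safe near-degenerate branch", {
  Bz <- mndopt:::jet_basis(list(list(vars = c("za", "zb", "R"), cap = 2L)))
  cases <- list(c(1.787537, 2.699905, 2.3),
                c(1.8, 1.8 + 1e-9, 2.0),   # degenerate branch
                c(1.331967, 1.124161, 1.6))
  for (cs in cases) {
    S <- mndopt:::sto_overlap_entry(Bz, 2L, "sig",
                                    mndopt:::jet_var(Bz, "za", cs[1]),
                                    2L, "sig",
                                    mndopt:::jet_var(Bz, "zb", cs[2]),
                                    mndopt:::jet_var(Bz, "R", cs[3]))
    f <- function(za) ovl(2L, "sig", za, 2L, "sig", cs[2], cs[3])
    fd1 <- fd_oracle(f, cs[1], h = 1e-4, order = 1)
    expect_lt(abs(mndopt:::jet_deriv(Bz, S, c(za = 1)) - fd1$value),
              1e-6 * max(1, abs(fd1$value)))
    fd2 <- fd_oracle(f, cs[1], h = 5e-3, order = 2)
    expect_lt(abs(mndopt:::jet_deriv(Bz, S, c(za = 2)) - fd2$value),
              1e-5 * max(1, abs(fd2$value)))
    g <- function(R) ovl(2L, "sig", cs[1], 2L, "sig", cs[2], R)
    fdR <- fd_oracle(g, cs[3], h = 1e-4, order = 1)
    expect_lt(abs(mndopt:::jet_deriv(Bz, S, c(R = 1)) - fdR$value), 1e-7)
  }
})
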