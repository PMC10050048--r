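# Two-electron multipole model, core attraction, resonance and core-core
# repulsion: limiting behaviour, symmetry/invariance, and analytic
# derivatives against the FD oracle.

mi_of <- function(mol, mode = "val", pset = mndo_pset)
  mndopt:::molecule_integrals(mol, pset, mode)

test_that("two-center (ss|ss) approaches the Coulomb limit at large R", {
  m <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 100)), name = "hh100")
  mi <- mi_of(m)
  w <- mi$pairs[[1]]$tens[["0"]]$J[1, 1]
  expect_lt(abs(w - mndo_units$e2 / 100) / (mndo_units$e2 / 100), 1e-3)
})

test_that("one-center integrals are the fixed constants with zero zeta
           derivative", {
  m <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)), name = "h2")
  mi <- mi_of(m, "param")
  oc <- mndopt:::one_center_tensor("H")
  expect_equal(oc[1, 1], element_constants("H")$g_ss)
  # zeta derivative tags of the H-H pair exist but the monopole (ss|ss)
  # element is zeta-independent
  k <- which(mi$act$name == "H.zeta_s")
  tq <- mi$pairs[[1]]$tens[[mndopt:::.tag_q(k)]]
  if (!is.null(tq)) expect_lt(abs(tq$J[1, 1]), 1e-14)
  occ <- mndopt:::one_center_tensor("C")
  expect_equal(occ[1, 1], element_constants("C")$g_ss)
  expect_equal(occ[6, 6], element_constants("C")$g_pp)   # (px px|px px)
  expect_equal(occ[1, 6], element_constants("C")$g_sp)   # (ss|px px)
  expect_equal(occ[2, 2], element_constants("C")$h_sp)   # (s px|s px)
})

test_that("pair two-electron derivatives match the FD oracle on random
           CHNOF geometries", {
  set.seed(11)
  elems <- c("C", "N", "O", "F", "H")
  for (trial in 1:6) {
    e1 <- sample(elems, 1); e2 <- sample(elems, 1)
    rv <- stats::rnorm(3); rv <- rv / sqrt(sum(rv^2)) * stats::runif(1, 1.0, 1.8)
    nel <- sum(mndopt:::.core_charge[c(e1, e2)])
    m <- molecule(c(e1, e2), rbind(c(0, 0, 0), rv), name = "pair",
                  mult = 1L + nel %% 2L)
    mi <- mi_of(m, "full")
    p <- mi$pairs[[1]]
    # pick a zeta parameter present on the pair
    kz <- mi$idx_zeta[1]
    tag <- mndopt:::.tag_q(kz)
    if (is.null(p$tens[[tag]])) next
    qel <- mi$act$element[kz]; qf <- mi$act$field[kz]
    # FD over the two-electron matrix
    f <- function(z) {
      ps <- mndo_pset
      ps[[qel]][[qf]] <- z
      mi2 <- mndopt:::molecule_integrals(m, ps, "val")
      mi2$pairs[[1]]$tens[["0"]]$J
    }
    z0 <- mndo_pset[[qel]][[qf]]
    h <- 1e-5
    fd <- (f(z0 + h) - f(z0 - h)) / (2 * h)
    expect_lt(max(abs(p$tens[[tag]]$J - fd)), 1e-6)
    # Cartesian derivative vs FD over the z displacement
    g <- function(z) {
      co <- m$coords; co[2, 3] <- z
      m2 <- molecule(m$elements, co, mult = m$mult, name = "p2")
      mndopt:::molecule_integrals(m2, mndo_pset, "val")$pairs[[1]]$tens[["0"]]$J
    }
    fdz <- (g(rv[3] + h) - g(rv[3] - h)) / (2 * h)
    expect_lt(max(abs(p$tens[["t3"]]$J - fdz)), 1e-6)
  }
})

test_that("scalar pair quantities are invariant under rigid rotation", {
  m <- fix_h2o_dist()
  mr <- rotate_molecule(m)
  mi1 <- mi_of(m); mi2 <- mi_of(mr)
  for (k in seq_along(mi1$pairs)) {
    W1 <- mi1$pairs[[k]]$tens[["0"]]$J
    W2 <- mi2$pairs[[k]]$tens[["0"]]$J
    # traces of the Coulomb blocks are rotational scalars
    expect_lt(abs(sum(diag(W1)) - sum(diag(W2))), 1e-10)
    expect_lt(abs(W1[1, 1] - W2[1, 1]), 1e-10)
    expect_lt(abs(mi1$pairs[[k]]$crf[["0"]] - mi2$pairs[[k]]$crf[["0"]]), 1e-10)
  }
  H1 <- mndopt:::core_hamiltonian(mi1)
  H2 <- mndopt:::core_hamiltonian(mi2)
  expect_lt(abs(sum(diag(H1)) - sum(diag(H2))), 1e-10)
})

test_that("Cartesian derivative blocks respect translation invariance", {
  # the pair tensors are functions of R_j - R_i only; moving both atoms
  # together leaves every block unchanged
  m <- fix_h2o_dist()
  co2 <- m$coords + matrix(rep(c(0.31, -0.12, 0.55), each = 3), 3, 3)
  m2 <- molecule(m$elements, co2, name = "shift")
  mi1 <- mi_of(m, "grad"); mi2 <- mi_of(m2, "grad")
  for (k in seq_along(mi1$pairs))
    expect_lt(max(abs(mi1$pairs[[k]]$tens[["t1"]]$J -
                        mi2$pairs[[k]]$tens[["t1"]]$J)), 1e-12)
})

test_that("resonance derivative structure: d beta / d beta_s is exactly S/2", {
  m <- fix_hf()
  mi <- mi_of(m, "param")
  kb <- which(mi$act$name == "H.beta_s")
  dH <- mndopt:::dH_dq(mi, kb)
  S <- mi$pairs[[1]]$tens[["0"]]$S   # F block x H block
  # H s orbital is index 5 (F carries 4 orbitals)
  expect_equal(dH[1:4, 5], as.vector(S[, 1]) / 2, tolerance = 1e-14)
  # mixed second derivative d2 beta / d beta_s d zeta_s = dS/dzeta / 2
  kz <- which(mi$act$name == "H.zeta_s")
  d2H <- mndopt:::d2H_dq(mi, kb, kz)
  Sq <- mi$pairs[[1]]$tens[[mndopt:::.tag_q(kz)]]$S
  expect_equal(d2H[1:4, 5], as.vector(Sq[, 1]) / 2, tolerance = 1e-12)
})

test_that("core-core repulsion: separable alpha derivatives and limits", {
  m <- molecule(c("N", "H"), rbind(c(0, 0, 0), c(0, 0, 1.01)), mult = 1L,
                name = "nh")
  mi <- mi_of(m, "param")
  p <- mi$pairs[[1]]
  ka <- which(mi$act$name == "N.alpha"); kh <- which(mi$act$name == "H.alpha")
  # mixed alpha-alpha cross derivative vanishes exactly (the two
  # exponentials separate)
  cross <- p$crf[[mndopt:::.tag_qq(ka, kh)]]
  expect_lt(abs(cross), 1e-12)
  # first derivative vs FD
  f <- function(a) {
    ps <- mndo_pset; ps$N$alpha <- a
    mndopt:::molecule_integrals(m, ps, "val")$pairs[[1]]$crf[["0"]]
  }
  fd <- fd_oracle(f, mndo_pset$N$alpha, h = 1e-5)
  expect_lt(abs(p$crf[[mndopt:::.tag_q(ka)]] - fd$value), 1e-8)
  # alpha -> infinity limit: V -> Z_A Z_B (ss|ss)
  psbig <- mndo_pset; psbig$N$alpha <- 60; psbig$H$alpha <- 60
  vbig <- mndopt:::molecule_integrals(m, psbig, "val")$pairs[[1]]$crf[["0"]]
  zz <- mndopt:::.core_charge[["N"]] * mndopt:::.core_charge[["H"]]
  g00 <- mndopt:::molecule_integrals(m, psbig, "val")$pairs[[1]]$tens[["0"]]$J[1, 1]
  expect_lt(abs(vbig - zz * g00), 1e-8)
})
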