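# Two-center two-electron integrals in the MNDO point-multipole model.
#
# Each one-center charge distribution mu*nu is represented by a point-charge
# configuration carrying its leading multipole moment: (ss) a monopole,
# (sp_a) a dipole of charges +-e/2 at +-D1 along a, (p_a p_a) a monopole
# plus a linear quadrupole (+e/4 at +-2 D2 along a, -e/2 at the center), and
# (p_a p_b) a square quadrupole of charges +-e/4 at (+-D2, +-D2) in the ab
# plane.  Charges i, j on different centers interact through the damped
# Coulomb kernel  e^2 / sqrt(r_ij^2 + (rho_A + rho_B)^2)  where each rho is
# the Klopman additive term of the multipole order of its distribution.
# rho_0 follows from G_ss in closed form; rho_1 and rho_2 are defined
# implicitly by requiring that the one-center limits of the dipole-dipole
# and linear-quadrupole self-interactions reproduce H_sp and G_pp - G_p2
# (the calibration that reproduces the original published MNDO results; see
# the methods vignette).  The implicit roots are propagated through the jet
# arithmetic by Newton iteration, which yields their analytic zeta
# derivatives.

.e2 <- 14.399645
.a0 <- 0.52917721

# multipole distances in Angstrom; zs, zp are jets in bohr^-1
mp_D1 <- function(B, n, zs, zp) {
  num <- jpowr(B, 4 * jmul(B, zs, zp), n + 0.5)
  den <- jpowr(B, zs + zp, 2 * n + 2)
  (.a0 * (2 * n + 1) / sqrt(3)) * jmul(B, num, jinv(B, den))
}

mp_D2 <- function(B, n, zp) {
  (.a0 * sqrt((2 * n + 1) * (2 * n + 2) / 20)) * jinv(B, zp)
}

# dipole-dipole and square-quadrupole one-center self-interactions (eV)
.dip_self <- function(B, rho1, D1) {
  .e2 * (0.25 * jinv(B, rho1) -
           0.5 * jinvsqrt(B, 4 * jmul(B, D1, D1) + 4 * jmul(B, rho1, rho1)))
}
.quad_self <- function(B, rho2, D2) {
  D22 <- jmul(B, D2, D2); r22 <- jmul(B, rho2, rho2)
  .e2 * ((3 / 16) * jinv(B, rho2) +
           0.125 * jinvsqrt(B, 16 * D22 + 4 * r22) -
           0.5 * jinvsqrt(B, 4 * D22 + 4 * r22))
}

# solve self(rho, D) = target for rho; D is a jet, target a number.
# Root found on values, then Newton-iterated in jet space (exact analytic
# propagation of the zeta dependence through D).
.solve_rho <- function(B, self_fun, D, target) {
  Dv <- .jval(D)[1]
  fval <- function(r) {
    B1 <- .jet_scalar_basis()
    v <- self_fun(B1, jet_const(B1, r), jet_const(B1, Dv))
    v[1] - target
  }
  # bracket: self-interaction decreases monotonically from +Inf
  lo <- 1e-4; hi <- 50
  root <- stats::uniroot(function(r) fval(r), c(lo, hi), tol = 1e-14)$root
  # slope d(self)/drho at the root via a 1-variable jet
  Br <- .jet_rho_basis()
  fr <- self_fun(Br, jet_var(Br, "rho", root), jet_const(Br, Dv))
  slope <- jet_deriv(Br, fr, c(rho = 1))
  rho <- jet_const(B, root)
  if (B$maxord > 0L) {
    for (it in 1:3) {
      res <- self_fun(B, rho, D) - jet_const(B, target)
      rho <- rho - res / slope
    }
  }
  rho
}

.mndopt_env <- new.env(parent = emptyenv())
.jet_scalar_basis <- function() {
  if (is.null(.mndopt_env$B1)) .mndopt_env$B1 <- jet_basis(list())
  .mndopt_env$B1
}
.jet_rho_basis <- function() {
  if (is.null(.mndopt_env$Brho))
    .mndopt_env$Brho <- jet_basis(list(list(vars = "rho", cap = 1L)))
  .mndopt_env$Brho
}

# Multipole data for one atom: distances (Angstrom) and additive terms, as
# jets in the supplied basis.  zs/zp jets (zp NULL for hydrogen).
atom_multipole_data <- function(B, element, zs, zp = NULL) {
  cst <- element_constants(element)
  rho0 <- jet_const(B, .e2 / (2 * cst$g_ss))
  if (is.null(zp)) {
    return(list(element = element, has_p = FALSE, rho0 = rho0))
  }
  D1 <- mp_D1(B, cst$n, zs, zp)
  D2 <- mp_D2(B, cst$n, zp)
  rho1 <- .solve_rho(B, .dip_self, D1, cst$h_sp)
  rho2 <- .solve_rho(B, .quad_self, D2, cst$g_pp - cst$g_p2)
  list(element = element, has_p = TRUE, rho0 = rho0,
       D1 = D1, D2 = D2, rho1 = rho1, rho2 = rho2)
}

# Point-charge configuration of an atom's distributions, in the local frame.
# Returns flattened charge data: part id, weight, offsets [nslot, nchg, 3],
# additive term jets per charge; plus the part composition of each of the
# 16 orbital-product labels (s px py pz outer square, column-major pairs).
.atom_config <- function(B, mp) {
  zero <- jet_const(B, 0)
  if (!mp$has_p) {
    offs <- array(0, c(B$n, 1L, 3L))
    return(list(nchg = 1L, w = 1, part_of = 1L,
                offs = offs, rho = matrix(mp$rho0, B$n, 1L),
                comp = list(`1` = 1L), nparts = 1L))
  }
  # parts: 1 mono, 2:4 dip x/y/z, 5:7 linquad x/y/z, 8:10 sqquad xy/xz/yz
  w <- c(1,
         rep(c(0.5, -0.5), 3),
         rep(c(0.25, 0.25, -0.5), 3),
         rep(c(0.25, -0.25, -0.25, 0.25), 3))
  part_of <- c(1L, rep(2:4, each = 2L), rep(5:7, each = 3L), rep(8:10, each = 4L))
  nchg <- length(w)
  offs <- array(0, c(B$n, nchg, 3L))
  k <- 2L
  for (ax in 1:3) {           # dipoles
    offs[, k, ax] <- mp$D1; offs[, k + 1L, ax] <- -mp$D1
    k <- k + 2L
  }
  for (ax in 1:3) {           # linear quadrupoles
    offs[, k, ax] <- 2 * mp$D2; offs[, k + 1L, ax] <- -2 * mp$D2
    k <- k + 3L               # third charge at origin
  }
  sqax <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  for (s in 1:3) {            # square quadrupoles
    a <- sqax[[s]][1]; b <- sqax[[s]][2]
    offs[, k, a] <- mp$D2;  offs[, k, b] <- mp$D2
    offs[, k + 1L, a] <- mp$D2;  offs[, k + 1L, b] <- -mp$D2
    offs[, k + 2L, a] <- -mp$D2; offs[, k + 2L, b] <- mp$D2
    offs[, k + 3L, a] <- -mp$D2; offs[, k + 3L, b] <- -mp$D2
    k <- k + 4L
  }
  rho_part <- list(mp$rho0, mp$rho1, mp$rho1, mp$rho1,
                   mp$rho2, mp$rho2, mp$rho2, mp$rho2, mp$rho2, mp$rho2)
  rho <- matrix(0, B$n, nchg)
  for (i in seq_len(nchg)) rho[, i] <- rho_part[[part_of[i]]]
  # orbital-product composition: labels (mu, nu) column-major in 1..4
  comp <- vector("list", 16L)
  dipix <- c(2L, 3L, 4L); lqix <- c(5L, 6L, 7L)
  sqix <- matrix(0L, 4, 4)
  sqix[2, 3] <- sqix[3, 2] <- 8L; sqix[2, 4] <- sqix[4, 2] <- 9L
  sqix[3, 4] <- sqix[4, 3] <- 10L
  for (mu in 1:4) for (nu in 1:4) {
    id <- (nu - 1L) * 4L + mu
    if (mu == 1L && nu == 1L) comp[[id]] <- 1L
    else if (mu == 1L) comp[[id]] <- dipix[nu - 1L]
    else if (nu == 1L) comp[[id]] <- dipix[mu - 1L]
    else if (mu == nu) comp[[id]] <- c(1L, lqix[mu - 1L])
    else comp[[id]] <- sqix[mu, nu]
  }
  list(nchg = nchg, w = w, part_of = part_of, offs = offs, rho = rho,
       comp = comp, nparts = 10L)
}

# Local-frame two-electron tensor between atoms A (origin) and B (at
# (0, 0, R)): array [nslot, npairA, npairB] over orbital-product labels.
pair_twoel_local <- function(B, mpA, mpB, R) {
  cA <- .atom_config(B, mpA)
  cB <- .atom_config(B, mpB)
  nA <- cA$nchg; nB <- cB$nchg
  ai <- rep(seq_len(nA), times = nB)
  bi <- rep(seq_len(nB), each = nA)
  m <- length(ai)
  dx <- matrix(cA$offs[, ai, 1], B$n, m) - matrix(cB$offs[, bi, 1], B$n, m)
  dy <- matrix(cA$offs[, ai, 2], B$n, m) - matrix(cB$offs[, bi, 2], B$n, m)
  zB <- matrix(cB$offs[, bi, 3], B$n, m)
  zB <- zB + matrix(R, B$n, m)
  dz <- matrix(cA$offs[, ai, 3], B$n, m) - zB
  rho <- matrix(cA$rho[, ai], B$n, m) + matrix(cB$rho[, bi], B$n, m)
  d2 <- jmul(B, dx, dx) + jmul(B, dy, dy) + jmul(B, dz, dz) +
    jmul(B, rho, rho)
  inter <- .e2 * jinvsqrt(B, d2)
  wcol <- cA$w[ai] * cB$w[bi]
  inter <- inter * matrix(wcol, B$n, m, byrow = TRUE)
  # accumulate into part-pair interactions
  ppid <- (cA$part_of[ai] - 1L) * cB$nparts + cB$part_of[bi]
  ind <- matrix(0, m, cA$nparts * cB$nparts)
  ind[cbind(seq_len(m), ppid)] <- 1
  partint <- inter %*% ind                     # [nslot, npartA*npartB]
  npA <- length(cA$comp); npB <- length(cB$comp)
  W <- array(0, c(B$n, npA, npB))
  for (a in seq_len(npA)) for (b in seq_len(npB)) {
    acc <- 0
    for (pa in cA$comp[[a]]) for (pb in cB$comp[[b]])
      acc <- acc + partint[, (pa - 1L) * cB$nparts + pb]
    W[, a, b] <- acc
  }
  W
}

# One-center two-electron tensor (constants; eV) for an element, as a
# [npair x npair] matrix over orbital-product labels.
one_center_tensor <- function(element) {
  cst <- element_constants(element)
  if (cst$nbasis == 1L) return(matrix(cst$g_ss, 1, 1))
  G <- array(0, c(4, 4, 4, 4))
  hpp <- 0.5 * (cst$g_pp - cst$g_p2)
  for (p in 2:4) {
    G[1, 1, p, p] <- G[p, p, 1, 1] <- cst$g_sp
    G[1, p, 1, p] <- G[p, 1, 1, p] <- G[1, p, p, 1] <- G[p, 1, p, 1] <- cst$h_sp
    G[p, p, p, p] <- cst$g_pp
    for (q in 2:4) if (q != p) {
      G[p, p, q, q] <- cst$g_p2
      G[p, q, p, q] <- G[p, q, q, p] <- hpp
    }
  }
  G[1, 1, 1, 1] <- cst$g_ss
  matrix(G, 16, 16)   # [(mu,nu) column-major, (la,si) column-major]
}
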