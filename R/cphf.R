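# First- and second-order coupled-perturbed Hartree-Fock in the
# orthogonalized NDDO basis, for perturbations by semi-empirical parameters.
#
# The occupied-virtual response equations
#   (eps_j - eps_i) x_ij - R_ij(x) = Fq_ij
# couple both spins through the Coulomb part of the response operator.  At
# the problem sizes this package targets (tens of occupied-virtual pairs)
# the coupled operator is assembled densely once per molecule and
# LU-factorized; every first-order right-hand side (one per parameter) and
# every second-order right-hand side (one per parameter pair) reuses the
# factorization.  The full first-order rotation matrices x (not only their
# occupied-virtual blocks) are recovered by direct substitution, as required
# by the second-order equations.
#
# Degenerate orbital pairs with equal occupancy carry no response coupling
# for totally symmetric (parameter) perturbations -- the coupling matrix
# element vanishes by symmetry -- and their x element is set to zero; the
# density-level quantities are gauge invariant under rotations inside such
# degenerate blocks, which the test suite verifies.  A degeneracy across
# the occupied/virtual boundary is a genuine singularity and raises an
# error.

.deg_tol <- 1e-6

#' Create a CPHF context for a converged SCF state
#'
#' Builds and factorizes the coupled response operator.
#'
#' @param scf A converged `scf_state`.
#' @return An object of class `cphf_context`.
#' @export
cphf_context <- function(scf) {
  mi <- scf$mi
  spins <- if (scf$is_rhf) "a" else c("a", "b")
  nocc <- c(a = scf$na, b = scf$nb)
  nbf <- mi$nbf
  blocks <- list()
  for (s in spins) {
    no <- nocc[[s]]; nv <- nbf - no
    if (no == 0L || nv == 0L) {
      blocks[[s]] <- list(no = no, nv = nv, dim = 0L)
      next
    }
    eo <- scf$eps[[s]][seq_len(no)]
    ev <- scf$eps[[s]][no + seq_len(nv)]
    if (min(ev) - max(eo) < .deg_tol)
      stop("degenerate occupied/virtual orbitals: response ill-defined")
    de <- as.vector(outer(-eo, ev, "+"))  # eps_j - eps_i, i occ fast? see below
    blocks[[s]] <- list(no = no, nv = nv, dim = no * nv, de = de)
  }
  dims <- vapply(blocks, function(b) b$dim, 0L)
  tot <- sum(dims)
  off <- cumsum(c(0L, dims))[seq_along(dims)]
  names(off) <- names(blocks)

  dP_of <- function(uvec) {
    # density response of each spin for stacked ov coefficients
    out <- list()
    for (si in seq_along(spins)) {
      s <- spins[si]; b <- blocks[[s]]
      if (b$dim == 0L) { out[[s]] <- matrix(0, nbf, nbf); next }
      x <- matrix(uvec[off[[s]] + seq_len(b$dim)], b$no, b$nv)
      Co <- scf$C[[s]][, seq_len(b$no), drop = FALSE]
      Cv <- scf$C[[s]][, b$no + seq_len(b$nv), drop = FALSE]
      Tm <- Cv %*% t(x) %*% t(Co)
      out[[s]] <- -(Tm + t(Tm))
    }
    if (scf$is_rhf) out$b <- out$a
    out
  }

  R_mo_ov <- function(dP) {
    # MO-basis response matrices restricted to the ov blocks, stacked
    dPt <- dP$a + dP$b
    Jr <- J_of(mi, "0", dPt)
    res <- numeric(tot)
    for (s in spins) {
      b <- blocks[[s]]
      if (b$dim == 0L) next
      Rs <- Jr - K_of(mi, "0", dP[[s]])
      Rmo <- t(scf$C[[s]]) %*% Rs %*% scf$C[[s]]
      res[off[[s]] + seq_len(b$dim)] <-
        as.vector(Rmo[seq_len(b$no), b$no + seq_len(b$nv), drop = FALSE])
    }
    res
  }

  devec <- unlist(lapply(spins, function(s) blocks[[s]]$de))
  if (is.null(devec)) devec <- numeric(0)
  A <- diag(devec, tot, tot)
  for (k in seq_len(tot)) {
    u <- numeric(tot); u[k] <- 1
    A[, k] <- A[, k] - R_mo_ov(dP_of(u))
  }
  lu <- if (tot > 0L) qr(A) else NULL  # dense, deterministic
  if (!is.null(lu) && lu$rank < tot)
    stop("singular response operator (degenerate partially occupied ",
         "shell?) for molecule '", scf$mol$name, "'")
  structure(list(scf = scf, mi = mi, spins = spins, blocks = blocks,
                 off = off, tot = tot, lu = lu,
                 dP_of = dP_of, R_mo_ov = R_mo_ov),
            class = "cphf_context")
}

# static AO Fock derivative for an active electronic parameter index k
static_fock_deriv <- function(ctx, k) {
  scf <- ctx$scf; mi <- ctx$mi
  dH <- dH_dq(mi, k)
  tag <- .tag_q(k)
  out <- list()
  Jq <- J_of(mi, tag, scf$P)
  for (s in ctx$spins)
    out[[s]] <- dH + Jq - K_of(mi, tag, scf$Pspin[[s]])
  if (scf$is_rhf) out$b <- out$a
  out
}

# full rotation matrix from a symmetric MO matrix G = (Fq + Rq) and the
# ov solution; degenerate same-occupancy pairs are zeroed
.full_x <- function(ctx, s, Gmo, x_ov) {
  scf <- ctx$scf
  b <- ctx$blocks[[s]]
  eps <- scf$eps[[s]]
  n <- length(eps)
  de <- outer(eps, eps, function(a, bb) bb - a)   # de[i,j] = eps_j - eps_i
  x <- matrix(0, n, n)
  nd <- abs(de) > .deg_tol
  x[nd] <- Gmo[nd] / de[nd]
  # enforce the solved ov block (self-consistent response included)
  if (b$dim > 0L) {
    occ <- seq_len(b$no); vir <- b$no + seq_len(b$nv)
    x[occ, vir] <- x_ov
    x[vir, occ] <- -t(x_ov)
  }
  x
}

#' Solve the first-order CPHF equations for one parameter
#'
#' @param ctx A `cphf_context`.
#' @param k Index into the molecule's active parameter table (electronic
#'   parameters; alpha and E_isol perturbations return zero response).
#' @return A list with per-spin static AO derivatives `Fq`, MO matrices
#'   `Fq_mo`, response `Rq_mo`, full rotation matrices `x`, the solved
#'   occupied-virtual blocks `x_ov`, density derivatives `dP` (per spin and
#'   `tot`), and `deps` (orbital-energy first derivatives).
#' @export
cphf_first_order <- function(ctx, k) {
  scf <- ctx$scf
  q <- .actq(ctx$mi, k)
  zero <- matrix(0, ctx$mi$nbf, ctx$mi$nbf)
  if (!q$field %in% .electronic_fields) {
    zl <- list(a = zero, b = zero)
    return(list(k = k, Fq = zl, Fq_mo = zl, Rq_mo = zl, x = zl,
                x_ov = NULL,
                dP = list(a = zero, b = zero, tot = zero),
                deps = list(a = numeric(ctx$mi$nbf), b = numeric(ctx$mi$nbf))))
  }
  Fq <- static_fock_deriv(ctx, k)
  Fq_mo <- list()
  rhs <- numeric(ctx$tot)
  for (s in ctx$spins) {
    Fq_mo[[s]] <- t(scf$C[[s]]) %*% Fq[[s]] %*% scf$C[[s]]
    b <- ctx$blocks[[s]]
    if (b$dim > 0L)
      rhs[ctx$off[[s]] + seq_len(b$dim)] <-
        as.vector(Fq_mo[[s]][seq_len(b$no), b$no + seq_len(b$nv), drop = FALSE])
  }
  u <- if (ctx$tot > 0L) solve(ctx$lu, rhs) else numeric(0)
  dP <- ctx$dP_of(u)
  dPt <- dP$a + dP$b
  Jr <- J_of(ctx$mi, "0", dPt)
  Rq_mo <- list(); x <- list(); x_ov <- list(); deps <- list()
  for (s in ctx$spins) {
    Rs <- Jr - K_of(ctx$mi, "0", dP[[s]])
    Rq_mo[[s]] <- t(scf$C[[s]]) %*% Rs %*% scf$C[[s]]
    b <- ctx$blocks[[s]]
    xov <- if (b$dim > 0L)
      matrix(u[ctx$off[[s]] + seq_len(b$dim)], b$no, b$nv) else
        matrix(0, b$no, b$nv)
    G <- Fq_mo[[s]] + Rq_mo[[s]]
    x[[s]] <- .full_x(ctx, s, G, xov)
    x_ov[[s]] <- xov
    deps[[s]] <- diag(G)
  }
  if (scf$is_rhf) {
    Fq_mo$b <- Fq_mo$a; Rq_mo$b <- Rq_mo$a; x$b <- x$a
    x_ov$b <- x_ov$a; deps$b <- deps$a
  }
  list(k = k, Fq = Fq, Fq_mo = Fq_mo, Rq_mo = Rq_mo, x = x, x_ov = x_ov,
       dP = list(a = dP$a, b = dP$b, tot = dPt), deps = deps)
}

# first-order coefficient products entering the second-order density
# derivative.  Derived from d2C = C gamma with dC = C x: the
# gamma-independent part of d2P is
#   C_v Y_vo C_o' + C_o Y_vo' C_v' + C_o Y_oo C_o' + C (Z + Z') C'
# with Y = x1 x2 + x2 x1 (symmetric) and Z = x1[,occ] x2[,occ]'.  The
# symmetric part of gamma (fixed by the orthonormality condition) enters
# only through the virtual rows of Y; letting the first sum run over all
# orbitals would double-count the occupied-occupied block and break
# Tr(d2P) = 0.
.sigma_matrix <- function(ctx, s, x1, x2) {
  scf <- ctx$scf
  C <- scf$C[[s]]
  b <- ctx$blocks[[s]]
  occ <- seq_len(b$no)
  vir <- if (b$nv > 0L) b$no + seq_len(b$nv) else integer(0)
  Co <- C[, occ, drop = FALSE]
  Cv <- C[, vir, drop = FALSE]
  Y <- x1 %*% x2 + x2 %*% x1
  T1 <- Cv %*% Y[vir, occ, drop = FALSE] %*% t(Co); T1 <- T1 + t(T1)
  T2 <- Co %*% Y[occ, occ, drop = FALSE] %*% t(Co)
  Z <- x1[, occ, drop = FALSE] %*% t(x2[, occ, drop = FALSE])
  T3 <- C %*% (Z + t(Z)) %*% t(C)
  T1 + T2 + T3
}

#' Solve the second-order CPHF equations for a parameter pair
#'
#' @param ctx A `cphf_context`.
#' @param r1,r2 First-order solutions from [cphf_first_order()] for the two
#'   parameters.
#' @param printed_form Debug switch: use the superscript combination exactly
#'   as printed in the source formalism's second-order right-hand side
#'   instead of the q1<->q2 symmetric form (default FALSE).
#' @return A list with per-spin `gamma_ov`, second density derivatives
#'   `d2P` (per spin and `tot`), and `d2eps` (orbital-energy second
#'   derivatives).
#' @export
cphf_second_order <- function(ctx, r1, r2, printed_form = FALSE) {
  scf <- ctx$scf; mi <- ctx$mi
  k1 <- r1$k; k2 <- r2$k
  q1 <- .actq(mi, k1); q2 <- .actq(mi, k2)
  zero <- matrix(0, mi$nbf, mi$nbf)
  el1 <- q1$field %in% .electronic_fields
  el2 <- q2$field %in% .electronic_fields
  if (!el1 || !el2) {
    return(list(gamma_ov = NULL,
                d2P = list(a = zero, b = zero, tot = zero),
                d2eps = list(a = numeric(mi$nbf), b = numeric(mi$nbf))))
  }
  z1 <- q1$field %in% .zeta_fields; z2 <- q2$field %in% .zeta_fields
  tag12 <- .tag_qq(k1, k2)
  t1 <- .tag_q(k1); t2 <- .tag_q(k2)

  # spin-summed pieces
  sig <- list(); Fstat <- list()
  J12P <- if (z1 && z2) J_of(mi, tag12, scf$P) else zero
  J1d2 <- if (z1) J_of(mi, t1, r2$dP$tot) else zero
  J2d1 <- if (z2) J_of(mi, t2, r1$dP$tot) else zero
  for (s in ctx$spins)
    sig[[s]] <- .sigma_matrix(ctx, s, r1$x[[s]], r2$x[[s]])
  if (scf$is_rhf) sig$b <- sig$a
  sig_tot <- sig$a + sig$b
  Jsig <- J_of(mi, "0", sig_tot)
  d2H <- d2H_dq(mi, k1, k2)
  for (s in ctx$spins) {
    Fs <- d2H + J12P + J1d2 + J2d1 + Jsig -
      K_of(mi, "0", sig[[s]])
    if (z1 && z2) Fs <- Fs - K_of(mi, tag12, scf$Pspin[[s]])
    if (z1) Fs <- Fs - K_of(mi, t1, r2$dP[[s]])
    if (z2) Fs <- Fs - K_of(mi, t2, r1$dP[[s]])
    Fstat[[s]] <- Fs
  }

  F12_mo <- list()
  rhs <- numeric(ctx$tot)
  for (s in ctx$spins) {
    C <- scf$C[[s]]; eps <- scf$eps[[s]]
    x1 <- r1$x[[s]]; x2 <- r2$x[[s]]
    G1 <- r1$Fq_mo[[s]] + r1$Rq_mo[[s]]
    G2 <- r2$Fq_mo[[s]] + r2$Rq_mo[[s]]
    # printed form pairs F^{q1} with R^{q2} in the x2-transpose row; the
    # symmetric form uses F^{q1} + R^{q1}
    G1a <- if (printed_form) r1$Fq_mo[[s]] + r2$Rq_mo[[s]] else G1
    Y <- x1 %*% x2 + x2 %*% x1
    Fmo <- t(C) %*% Fstat[[s]] %*% C +
      Y * rep(eps, each = nrow(Y)) +
      t(x1) %*% G2 + t(x1) %*% (x2 * rep(eps, nrow(x2))) + G2 %*% x1 +
      t(x2) %*% G1a + t(x2) %*% (x1 * rep(eps, nrow(x1))) + G1 %*% x2
    F12_mo[[s]] <- Fmo
    b <- ctx$blocks[[s]]
    if (b$dim > 0L)
      rhs[ctx$off[[s]] + seq_len(b$dim)] <-
        as.vector(Fmo[seq_len(b$no), b$no + seq_len(b$nv), drop = FALSE])
  }
  u <- if (ctx$tot > 0L) solve(ctx$lu, rhs) else numeric(0)
  rho <- ctx$dP_of(u)
  rho_tot <- rho$a + rho$b
  Jr <- J_of(mi, "0", rho_tot)
  gamma_ov <- list(); d2P <- list(); d2eps <- list(); R12_mo <- list()
  for (s in ctx$spins) {
    Rs <- Jr - K_of(mi, "0", rho[[s]])
    R12_mo[[s]] <- t(scf$C[[s]]) %*% Rs %*% scf$C[[s]]
    b <- ctx$blocks[[s]]
    gamma_ov[[s]] <- if (b$dim > 0L)
      matrix(u[ctx$off[[s]] + seq_len(b$dim)], b$no, b$nv) else
        matrix(0, b$no, b$nv)
    d2P[[s]] <- rho[[s]] + sig[[s]]
    d2eps[[s]] <- diag(F12_mo[[s]] + R12_mo[[s]])
  }
  if (scf$is_rhf) {
    gamma_ov$b <- gamma_ov$a; d2P$b <- d2P$a; d2eps$b <- d2eps$a
    R12_mo$b <- R12_mo$a; F12_mo$b <- F12_mo$a
  }
  list(gamma_ov = gamma_ov,
       d2P = list(a = d2P$a, b = d2P$b, tot = d2P$a + d2P$b),
       d2eps = d2eps, F12_mo = F12_mo, R12_mo = R12_mo)
}
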