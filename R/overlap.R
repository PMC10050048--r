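# Slater-orbital overlap integrals in the diatomic frame.
#
# Overlaps between 1s/2s/2p Slater orbitals are evaluated in prolate
# spheroidal coordinates.  With xi in [1, Inf), eta in [-1, 1],
#   r_A = (R/2)(xi + eta),  r_B = (R/2)(xi - eta),
#   z_A = (R/2)(1 + xi eta), z_B = (R/2)(xi eta - 1),
#   x^2 + y^2 = (R/2)^2 (xi^2 - 1)(1 - eta^2),
# every s/sigma/pi orbital product becomes a small polynomial in (xi, eta)
# times exp(-p xi - q eta) with p = (za + zb) R/2, q = (za - zb) R/2, and the
# integral reduces to sums of auxiliary integrals
#   A_k(p) = int_1^Inf xi^k exp(-p xi) dxi,
#   B_k(q) = int_-1^1 eta^k exp(-q eta) deta.
# All quantities are computed in jet arithmetic, so derivatives with respect
# to the Slater exponents and the interatomic distance come out analytically.
# The near-degenerate branch q -> 0 (zeta_A ~ zeta_B) uses the series form of
# B_k, which is smooth through q = 0.

aux_A <- function(B, p, kmax) {
  out <- vector("list", kmax + 1L)
  ep <- jexp(B, -p)
  ip <- jinv(B, p)
  out[[1]] <- jmul(B, ep, ip)
  if (kmax >= 1L) for (k in 1:kmax)
    out[[k + 1]] <- jmul(B, ep + k * out[[k]], ip)
  out
}

aux_B <- function(B, q, kmax) {
  out <- vector("list", kmax + 1L)
  if (abs(.jval(q)[1]) < 0.5) {
    # series: B_k(q) = sum_m (-q)^m/m! * (1 + (-1)^(k+m)) / (k + m + 1)
    mmax <- 24L
    qpow <- vector("list", mmax + 1L)
    qpow[[1]] <- jet_const(B, 1)
    for (m in 1:mmax) qpow[[m + 1]] <- jmul(B, qpow[[m]], -q) / m
    for (k in 0:kmax) {
      acc <- jet_const(B, 0)
      for (m in 0:mmax) {
        c0 <- (1 + (-1)^(k + m)) / (k + m + 1)
        if (c0 != 0) acc <- acc + c0 * qpow[[m + 1]]
      }
      out[[k + 1]] <- acc
    }
  } else {
    eq <- jexp(B, q); emq <- jexp(B, -q); iq <- jinv(B, q)
    out[[1]] <- jmul(B, eq - emq, iq)
    if (kmax >= 1L) for (k in 1:kmax)
      out[[k + 1]] <- jmul(B, k * out[[k]] + (-1)^k * eq - emq, iq)
  }
  out
}

# polynomials in (xi, eta) with jet coefficients: array [nslot, dx+1, de+1]
.pnew <- function(B, dx, de) array(0, c(B$n, dx + 1L, de + 1L))

.pmul <- function(B, P, Q) {
  dP <- dim(P); dQ <- dim(Q)
  out <- .pnew(B, dP[2] + dQ[2] - 2L, dP[3] + dQ[3] - 2L)
  for (i in seq_len(dP[2])) for (j in seq_len(dP[3])) {
    pij <- P[, i, j]
    if (all(pij == 0)) next
    for (k in seq_len(dQ[2])) for (l in seq_len(dQ[3])) {
      qkl <- Q[, k, l]
      if (all(qkl == 0)) next
      out[, i + k - 1L, j + l - 1L] <- out[, i + k - 1L, j + l - 1L] +
        jmul(B, pij, qkl)
    }
  }
  out
}

# building blocks; Rh = R/2 as a jet (bohr)
.poly_one  <- function(B) { P <- .pnew(B, 0L, 0L); P[1, 1, 1] <- 1; P }
.poly_ra   <- function(B, Rh) { P <- .pnew(B, 1L, 1L); P[, 2, 1] <- Rh; P[, 1, 2] <- Rh; P }
.poly_rb   <- function(B, Rh) { P <- .pnew(B, 1L, 1L); P[, 2, 1] <- Rh; P[, 1, 2] <- -Rh; P }
.poly_zA   <- function(B, Rh) { P <- .pnew(B, 1L, 1L); P[, 1, 1] <- Rh; P[, 2, 2] <- Rh; P }
.poly_zB   <- function(B, Rh) { P <- .pnew(B, 1L, 1L); P[, 1, 1] <- -Rh; P[, 2, 2] <- Rh; P }
.poly_vol  <- function(B) { P <- .pnew(B, 2L, 2L); P[1, 3, 1] <- 1; P[1, 1, 3] <- -1; P }
.poly_perp2 <- function(B, Rh) {
  # (R/2)^2 (xi^2 - 1)(1 - eta^2)
  Rh2 <- jmul(B, Rh, Rh)
  P <- .pnew(B, 2L, 2L)
  P[, 3, 1] <- Rh2; P[, 3, 3] <- -Rh2; P[, 1, 1] <- -Rh2; P[, 1, 3] <- Rh2
  P
}

# overlap between one orbital on A and one on B in the local diatomic frame.
# kind: "s" (s orbital), "sig" (p_sigma), "pi" (p_pi); n = principal number;
# za, zb, Rbohr are jets.
sto_overlap_entry <- function(B, na, kind_a, za, nb, kind_b, zb, Rbohr) {
  Rh <- 0.5 * Rbohr
  fac <- function(n, kind, which_atom) {
    if (kind == "s") {
      if (n == 1L) .poly_one(B) else
        if (which_atom == "A") .poly_ra(B, Rh) else .poly_rb(B, Rh)
    } else if (kind == "sig") {
      if (which_atom == "A") .poly_zA(B, Rh) else .poly_zB(B, Rh)
    } else NULL  # pi handled jointly
  }
  if (xor(kind_a == "pi", kind_b == "pi")) return(jet_const(B, 0))
  if (kind_a == "pi") {
    poly <- .poly_perp2(B, Rh)
    angfac <- 3 / 4
  } else {
    poly <- .pmul(B, fac(na, kind_a, "A"), fac(nb, kind_b, "B"))
    angfac <- c(2, sqrt(12), 6)[1 + (kind_a == "sig") + (kind_b == "sig")] / 4
    # s-s: 2pi/(4pi) = 1/2 ; s-sig: 2pi sqrt(3)/(4pi) = sqrt(3)/2 ; sig-sig: 3/2
  }
  poly <- .pmul(B, poly, .poly_vol(B))
  p <- jmul(B, za + zb, Rh)
  q <- jmul(B, za - zb, Rh)
  # overlap ~ exp(-(p - |q|)); far below machine precision return an exact
  # zero (also avoids overflow of the individual auxiliary integrals)
  if (.jval(p)[1] - abs(.jval(q)[1]) > 50) return(jet_const(B, 0))
  dxe <- dim(poly)
  Ak <- aux_A(B, p, dxe[2] - 1L)
  Bk <- aux_B(B, q, dxe[3] - 1L)
  acc <- jet_const(B, 0)
  for (i in seq_len(dxe[2])) for (j in seq_len(dxe[3])) {
    cij <- poly[, i, j]
    if (all(cij == 0)) next
    acc <- acc + jmul(B, cij, jmul(B, Ak[[i]], Bk[[j]]))
  }
  nrad <- function(n, z) jmul(B, jpowr(B, 2 * z, n + 0.5),
                              jet_const(B, 1 / sqrt(factorial(2 * n))))
  pref <- jmul(B, nrad(na, za), nrad(nb, zb))
  pref <- jmul(B, pref, jpow(B, Rh, 3L))
  angfac * jmul(B, pref, acc)
}
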