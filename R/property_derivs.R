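# First and second parameter derivatives of the objective properties:
# heat of formation, Koopmans ionization energy, dipole magnitude, and the
# Cartesian gradient norm at a reference geometry.
#
# The heat-of-formation derivatives exploit SCF stationarity: first
# derivatives need only static integral derivatives contracted with the
# density, second derivatives additionally need the first-order density
# response (never the second-order response).  Ionization-energy and dipole
# derivatives require the full first- and second-order CPHF solutions.  The
# gradient-norm chain contracts density responses with mixed
# Cartesian-parameter integral derivatives up to third order.

.norm_eps <- 1e-8  # smoothing of |g| and |mu| in the derivative chain

# ---- generic pair contraction helpers ---------------------------------

.pair_ix <- function(mi, p) {
  list(a = mi$orb0[p$i] + seq_len(p$nA), b = mi$orb0[p$j] + seq_len(p$nB))
}

.h_V <- function(p, tt, Daa, Dbb) {
  -.core_charge[[p$elB]] * sum(matrix(tt$J[, 1], p$nA, p$nA) * Daa) -
    .core_charge[[p$elA]] * sum(matrix(tt$J[1, ], p$nB, p$nB) * Dbb)
}
.h_beta <- function(tt, wmat, Dab) 2 * sum(Dab * (wmat * tt$S))
.h_coul <- function(tt, Daa, Dbb)
  as.numeric(crossprod(as.vector(Daa), tt$J %*% as.vector(Dbb)))
.h_ex <- function(tt, D1ab, D2ab)
  as.numeric(crossprod(as.vector(D1ab), tt$K %*% as.vector(D2ab)))

# beta weight matrices for a pair: values (beta_mu+beta_nu)/2 and indicator
# version for a beta-type parameter
.beta_wmat <- function(mi, p, ind = NULL) {
  ix <- .pair_ix(mi, p)
  v <- if (is.null(ind)) mi$beta_orb else ind
  outer(v[ix$a], v[ix$b], "+") / 2
}

# full pair-energy-like contraction of tensor set `tt` with densities
.pair_full_contract <- function(mi, p, tt, P, Pa, Pb) {
  ix <- .pair_ix(mi, p)
  .h_V(p, tt, P[ix$a, ix$a], P[ix$b, ix$b]) +
    .h_beta(tt, .beta_wmat(mi, p), P[ix$a, ix$b, drop = FALSE]) +
    .h_coul(tt, P[ix$a, ix$a], P[ix$b, ix$b]) -
    .h_ex(tt, Pa[ix$a, ix$b, drop = FALSE], Pa[ix$a, ix$b, drop = FALSE]) -
    .h_ex(tt, Pb[ix$a, ix$b, drop = FALSE], Pb[ix$a, ix$b, drop = FALSE])
}

# contraction of `tt` with the density varied once: bilinear terms carry
# (dD, P) + (P, dD)
.pair_resp_contract <- function(mi, p, tt, P, Pa, Pb, dP, dPa, dPb) {
  ix <- .pair_ix(mi, p)
  .h_V(p, tt, dP[ix$a, ix$a], dP[ix$b, ix$b]) +
    .h_beta(tt, .beta_wmat(mi, p), dP[ix$a, ix$b, drop = FALSE]) +
    .h_coul(tt, dP[ix$a, ix$a], P[ix$b, ix$b]) +
    .h_coul(tt, P[ix$a, ix$a], dP[ix$b, ix$b]) -
    2 * .h_ex(tt, dPa[ix$a, ix$b, drop = FALSE], Pa[ix$a, ix$b, drop = FALSE]) -
    2 * .h_ex(tt, dPb[ix$a, ix$b, drop = FALSE], Pb[ix$a, ix$b, drop = FALSE])
}

# contraction of `tt` with the density varied twice
.pair_resp2_contract <- function(mi, p, tt, P, Pa, Pb, r1, r2, so) {
  ix <- .pair_ix(mi, p)
  d2P <- so$d2P$tot; d2Pa <- so$d2P$a; d2Pb <- so$d2P$b
  d1 <- r1$dP; d2 <- r2$dP
  out <- .h_V(p, tt, d2P[ix$a, ix$a], d2P[ix$b, ix$b]) +
    .h_beta(tt, .beta_wmat(mi, p), d2P[ix$a, ix$b, drop = FALSE]) +
    .h_coul(tt, d2P[ix$a, ix$a], P[ix$b, ix$b]) +
    .h_coul(tt, P[ix$a, ix$a], d2P[ix$b, ix$b]) +
    .h_coul(tt, d1$tot[ix$a, ix$a], d2$tot[ix$b, ix$b]) +
    .h_coul(tt, d2$tot[ix$a, ix$a], d1$tot[ix$b, ix$b])
  for (s in c("a", "b")) {
    Ps <- if (s == "a") Pa else Pb
    d2s <- so$d2P[[s]]
    out <- out - 2 * .h_ex(tt, d2s[ix$a, ix$b, drop = FALSE],
                           Ps[ix$a, ix$b, drop = FALSE]) -
      2 * .h_ex(tt, d1[[s]][ix$a, ix$b, drop = FALSE],
                d2[[s]][ix$a, ix$b, drop = FALSE])
  }
  out
}

# static cross derivative d^2 E_AB / d tau d q for parameter k (plain
# densities; no response)
.pair_static_cross <- function(mi, p, cc, k, P, Pa, Pb) {
  q <- .actq(mi, k)
  tot <- 0
  if (q$field %in% .zeta_fields) {
    tt <- p$tens[[.tag_tq(cc, k)]]
    if (!is.null(tt)) tot <- tot + .pair_full_contract(mi, p, tt, P, Pa, Pb)
  } else if (q$field %in% c("beta_s", "beta_p")) {
    tt <- p$tens[[.tag_t(cc)]]
    ind <- .beta_indicator(mi, q)
    if (!is.null(tt)) {
      ix <- .pair_ix(mi, p)
      tot <- tot + .h_beta(tt, .beta_wmat(mi, p, ind),
                           P[ix$a, ix$b, drop = FALSE])
    }
  } else if (q$field == "alpha") {
    v <- p$crf[[.tag_tq(cc, k)]]
    if (!is.null(v)) tot <- tot + v
  }
  tot
}

# static double-cross derivative d^3 E_AB / d tau d q1 d q2
.pair_static_cross2 <- function(mi, p, cc, k1, k2, P, Pa, Pb) {
  q1 <- .actq(mi, k1); q2 <- .actq(mi, k2)
  z1 <- q1$field %in% .zeta_fields; z2 <- q2$field %in% .zeta_fields
  b1 <- q1$field %in% c("beta_s", "beta_p"); b2 <- q2$field %in% c("beta_s", "beta_p")
  tot <- 0
  if (z1 && z2) {
    tt <- p$tens[[.tag_tqq(cc, k1, k2)]]
    if (!is.null(tt)) tot <- tot + .pair_full_contract(mi, p, tt, P, Pa, Pb)
  } else if ((b1 && z2) || (b2 && z1)) {
    kb <- if (b1) k1 else k2; kz <- if (b1) k2 else k1
    tt <- p$tens[[.tag_tq(cc, kz)]]
    if (!is.null(tt)) {
      ind <- .beta_indicator(mi, .actq(mi, kb))
      ix <- .pair_ix(mi, p)
      tot <- tot + .h_beta(tt, .beta_wmat(mi, p, ind),
                           P[ix$a, ix$b, drop = FALSE])
    }
  } else if (q1$field == "alpha" && q2$field == "alpha") {
    v <- p$crf[[.tag_tqq(cc, k1, k2)]]
    if (!is.null(v)) tot <- tot + v
  }
  tot
}

# ---- heat of formation ------------------------------------------------

.dHf_first <- function(mi, scf, resp) {
  nact <- nrow(mi$act)
  out <- numeric(nact)
  kcv <- mndo_units$kcal_per_ev
  for (k in seq_len(nact)) {
    q <- .actq(mi, k)
    if (q$field == "e_isol") {
      out[k] <- -kcv * sum(mi$elems == q$element)
    } else if (q$field == "alpha") {
      out[k] <- kcv * core_repulsion_sum(mi, .tag_q(k))
    } else {
      dH <- dH_dq(mi, k)
      de <- sum(dH * scf$P)
      if (q$field %in% .zeta_fields) {
        tag <- .tag_q(k)
        de <- de + 0.5 * (sum(J_of(mi, tag, scf$P) * scf$P) -
                            sum(K_of(mi, tag, scf$Pspin$a) * scf$Pspin$a) -
                            sum(K_of(mi, tag, scf$Pspin$b) * scf$Pspin$b))
      }
      out[k] <- kcv * de
    }
  }
  out
}

.dHf_second <- function(mi, scf, resp, k1, k2) {
  q1 <- .actq(mi, k1); q2 <- .actq(mi, k2)
  kcv <- mndo_units$kcal_per_ev
  if (q1$field == "e_isol" || q2$field == "e_isol") return(0)
  a1 <- q1$field == "alpha"; a2 <- q2$field == "alpha"
  if (a1 && a2) return(kcv * core_repulsion_sum(mi, .tag_qq(k1, k2)))
  if (a1 || a2) return(0)
  # electronic-electronic: Tr(d2H P) + 1/2 Tr(J''(P)P - K''(Pa)Pa - K''(Pb)Pb)
  #                        + sum_s Tr(F^k1_static dP^k2)
  de <- sum(d2H_dq(mi, k1, k2) * scf$P)
  z1 <- q1$field %in% .zeta_fields; z2 <- q2$field %in% .zeta_fields
  if (z1 && z2) {
    tag <- .tag_qq(k1, k2)
    de <- de + 0.5 * (sum(J_of(mi, tag, scf$P) * scf$P) -
                        sum(K_of(mi, tag, scf$Pspin$a) * scf$Pspin$a) -
                        sum(K_of(mi, tag, scf$Pspin$b) * scf$Pspin$b))
  }
  r1 <- resp[[k1]]; r2 <- resp[[k2]]
  de <- de + sum(r1$Fq$a * r2$dP$a) + sum(r1$Fq$b * r2$dP$b)
  kcv * de
}

# ---- ionization energy ------------------------------------------------

.homo_info <- function(scf) {
  cand <- c(a = if (scf$na > 0L) scf$eps$a[scf$na] else -Inf,
            b = if (scf$nb > 0L) scf$eps$b[scf$nb] else -Inf)
  s <- names(which.max(cand))
  n <- if (s == "a") scf$na else scf$nb
  list(spin = s, idx = n)
}

# ---- dipole -----------------------------------------------------------

# dipole vector derivative (e*Angstrom scale before Debye conversion is
# applied by the caller) for a density derivative dP and the D1 derivative
# selected by parameter k (0 for non-zeta parameters)
.dmu_vec <- function(mi, scf, dP, k = NULL) {
  cm <- .center_of_mass(scf$mol)
  dmu <- numeric(3)
  for (a in seq_len(mi$nat)) {
    ix <- mi$orb0[a] + seq_len(mi$norb[a])
    dmu <- dmu - sum(diag(dP)[ix]) * (scf$mol$coords[a, ] - cm)
    if (mi$norb[a] == 4L) {
      D1 <- .jval(mi$mp_val[[a]]$D1)[1]
      s <- mi$orb0[a] + 1L
      for (tau in 1:3)
        dmu[tau] <- dmu[tau] - 2 * D1 * dP[s, s + tau]
    }
  }
  if (!is.null(k)) {
    q <- .actq(mi, k)
    if (q$field %in% .zeta_fields) {
      for (a in seq_len(mi$nat)) {
        if (mi$norb[a] != 4L || mi$elems[a] != q$element) next
        Ba <- .atom_basis(mi$mode, TRUE)
        v <- if (q$field == "zeta_s") c(zs = 1) else c(zp = 1)
        dD1 <- jet_deriv(Ba, mi$D1_jets[[q$element]], v)
        s <- mi$orb0[a] + 1L
        for (tau in 1:3)
          dmu[tau] <- dmu[tau] - 2 * dD1 * scf$P[s, s + tau]
      }
    }
  }
  dmu
}

# second-order dipole vector derivative
.d2mu_vec <- function(mi, scf, r1, r2, so, k1, k2) {
  dmu <- .dmu_vec(mi, scf, so$d2P$tot, k = NULL)
  q1 <- .actq(mi, k1); q2 <- .actq(mi, k2)
  add_cross <- function(kz, dPother) {
    q <- .actq(mi, kz)
    out <- numeric(3)
    if (!q$field %in% .zeta_fields) return(out)
    for (a in seq_len(mi$nat)) {
      if (mi$norb[a] != 4L || mi$elems[a] != q$element) next
      Ba <- .atom_basis(mi$mode, TRUE)
      v <- if (q$field == "zeta_s") c(zs = 1) else c(zp = 1)
      dD1 <- jet_deriv(Ba, mi$D1_jets[[q$element]], v)
      s <- mi$orb0[a] + 1L
      for (tau in 1:3)
        out[tau] <- out[tau] - 2 * dD1 * dPother[s, s + tau]
    }
    out
  }
  dmu <- dmu + add_cross(k1, r2$dP$tot) + add_cross(k2, r1$dP$tot)
  # second derivative of D1 itself
  z1 <- q1$field %in% .zeta_fields; z2 <- q2$field %in% .zeta_fields
  if (z1 && z2 && q1$element == q2$element) {
    el <- q1$element
    if (.n_basis_elem[[el]] == 4L && el %in% mi$elems) {
      Ba <- .atom_basis(mi$mode, TRUE)
      vn <- c(zeta_s = "zs", zeta_p = "zp")
      e <- table(c(vn[[q1$field]], vn[[q2$field]]))
      d2D1 <- jet_deriv(Ba, mi$D1_jets[[el]],
                        stats::setNames(as.integer(e), names(e)))
      for (a in which(mi$elems == el)) {
        if (mi$norb[a] != 4L) next
        s <- mi$orb0[a] + 1L
        for (tau in 1:3)
          dmu[tau] <- dmu[tau] - 2 * d2D1 * scf$P[s, s + tau]
      }
    }
  }
  dmu
}

# ---- gradient ---------------------------------------------------------

# d g / d q for one parameter (matrix nat x 3, kcal/mol/bohr units applied
# by caller)
.dg_dq <- function(mi, scf, k, rk) {
  g <- matrix(0, mi$nat, 3)
  P <- scf$P; Pa <- scf$Pspin$a; Pb <- scf$Pspin$b
  dP <- rk$dP
  for (p in mi$pairs) {
    for (cc in 1:3) {
      d <- .pair_static_cross(mi, p, cc, k, P, Pa, Pb)
      tt0 <- p$tens[[.tag_t(cc)]]
      if (!is.null(tt0))
        d <- d + .pair_resp_contract(mi, p, tt0, P, Pa, Pb,
                                     dP$tot, dP$a, dP$b)
      g[p$i, cc] <- g[p$i, cc] - d
      g[p$j, cc] <- g[p$j, cc] + d
    }
  }
  g
}

# d^2 g / d q1 d q2
.d2g_dq <- function(mi, scf, k1, k2, r1, r2, so) {
  g <- matrix(0, mi$nat, 3)
  P <- scf$P; Pa <- scf$Pspin$a; Pb <- scf$Pspin$b
  for (p in mi$pairs) {
    for (cc in 1:3) {
      d <- .pair_static_cross2(mi, p, cc, k1, k2, P, Pa, Pb)
      # first-order static cross with the other parameter's response
      q1 <- .actq(mi, k1); q2 <- .actq(mi, k2)
      cross_resp <- function(kz, rother) {
        q <- .actq(mi, kz)
        if (q$field %in% .zeta_fields) {
          tt <- p$tens[[.tag_tq(cc, kz)]]
          if (!is.null(tt))
            return(.pair_resp_contract(mi, p, tt, P, Pa, Pb,
                                       rother$dP$tot, rother$dP$a, rother$dP$b))
        } else if (q$field %in% c("beta_s", "beta_p")) {
          tt <- p$tens[[.tag_t(cc)]]
          if (!is.null(tt)) {
            ind <- .beta_indicator(mi, q)
            ix <- .pair_ix(mi, p)
            return(.h_beta(tt, .beta_wmat(mi, p, ind),
                           rother$dP$tot[ix$a, ix$b, drop = FALSE]))
          }
        }
        0
      }
      d <- d + cross_resp(k1, r2) + cross_resp(k2, r1)
      tt0 <- p$tens[[.tag_t(cc)]]
      if (!is.null(tt0))
        d <- d + .pair_resp2_contract(mi, p, tt0, P, Pa, Pb, r1, r2, so)
      g[p$i, cc] <- g[p$i, cc] - d
      g[p$j, cc] <- g[p$j, cc] + d
    }
  }
  g
}

# batched assembly of the gradient-vector derivative chain: computes
# dg/dq for every active parameter and d2g/dq1dq2 for every pair in one
# sweep, hoisting all density-block extractions and fixed-density
# matrix-vector products out of the parameter-pair loops.
.grad_chain_all <- function(mi, scf, resp, iel, so_get, order) {
  nact <- nrow(mi$act)
  nat <- mi$nat
  P <- scf$P; Pa <- scf$Pspin$a; Pb <- scf$Pspin$b
  fields <- mi$act_f
  is_z <- fields %in% .zeta_fields
  is_b <- fields %in% c("beta_s", "beta_p")
  # per-pair, per-cc precomputations
  pre <- vector("list", length(mi$pairs))
  for (ip in seq_along(mi$pairs)) {
    p <- mi$pairs[[ip]]
    ia <- mi$orb0[p$i] + seq_len(p$nA)
    ib <- mi$orb0[p$j] + seq_len(p$nB)
    ZA <- .core_charge[[p$elA]]; ZB <- .core_charge[[p$elB]]
    bw <- outer(mi$beta_orb[ia], mi$beta_orb[ib], "+") / 2
    vPaa <- as.vector(P[ia, ia]); vPbb <- as.vector(P[ib, ib])
    vPab <- as.vector(P[ia, ib])
    vPsa <- as.vector(Pa[ia, ib]); vPsb <- as.vector(Pb[ia, ib])
    dblk <- lapply(seq_len(nact), function(k) {
      dP <- resp[[k]]$dP
      list(aa = as.vector(dP$tot[ia, ia]), bb = as.vector(dP$tot[ib, ib]),
           ab = as.vector(dP$tot[ia, ib]),
           sa = as.vector(dP$a[ia, ib]), sb = as.vector(dP$b[ia, ib]))
    })
    percc <- vector("list", 3L)
    for (cc in 1:3) {
      tt <- p$tens[[.tag_t(cc)]]
      if (is.null(tt)) { percc[[cc]] <- NULL; next }
      Jm <- tt$J; Km <- tt$K
      Vva <- -ZB * Jm[, 1]                    # dot with vec(Daa)
      Vvb <- -ZA * Jm[1, ]                    # dot with vec(Dbb)
      bvec <- as.vector(bw * tt$S)            # x2, dot with vec(Dab)
      vJb <- as.vector(Jm %*% vPbb)           # dot with vec(Daa)
      vJa <- as.vector(crossprod(Jm, vPaa))   # dot with vec(Dbb)
      vKa <- as.vector(Km %*% vPsa)           # dot with vec(Da_ab)
      vKb <- as.vector(Km %*% vPsb)
      wJb <- wJa <- wKa <- wKb <- vector("list", nact)
      for (k in iel) {
        wJb[[k]] <- as.vector(Jm %*% dblk[[k]]$bb)
        wJa[[k]] <- as.vector(crossprod(Jm, dblk[[k]]$aa))
        wKa[[k]] <- as.vector(Km %*% dblk[[k]]$sa)
        wKb[[k]] <- as.vector(Km %*% dblk[[k]]$sb)
      }
      # per-parameter static cross terms (zeta via mixed tensors, beta via
      # the indicator-weighted overlap derivative, alpha via the CRF)
      stat1 <- numeric(nact)
      uJb <- uJa <- uKa <- uKb <- uVa <- uVb <- ubv <- vector("list", nact)
      for (k in seq_len(nact)) {
        if (is_z[k]) {
          tq <- p$tens[[.tag_tq(cc, k)]]
          if (!is.null(tq)) {
            stat1[k] <- -ZB * sum(tq$J[, 1] * vPaa) -
              ZA * sum(tq$J[1, ] * vPbb) +
              2 * sum((bw * tq$S) * matrix(vPab, p$nA, p$nB)) +
              sum(vPaa * (tq$J %*% vPbb)) -
              sum(vPsa * (tq$K %*% vPsa)) - sum(vPsb * (tq$K %*% vPsb))
            if (order >= 2) {
              uVa[[k]] <- -ZB * tq$J[, 1]; uVb[[k]] <- -ZA * tq$J[1, ]
              ubv[[k]] <- as.vector(bw * tq$S)
              uJb[[k]] <- as.vector(tq$J %*% vPbb)
              uJa[[k]] <- as.vector(crossprod(tq$J, vPaa))
              uKa[[k]] <- as.vector(tq$K %*% vPsa)
              uKb[[k]] <- as.vector(tq$K %*% vPsb)
            }
          }
        } else if (is_b[k]) {
          ind <- .beta_indicator(mi, .actq(mi, k))
          bwk <- outer(ind[ia], ind[ib], "+") / 2
          ubv[[k]] <- as.vector(bwk * tt$S)
          stat1[k] <- 2 * sum(ubv[[k]] * vPab)
        } else if (fields[k] == "alpha") {
          v <- p$crf[[.tag_tq(cc, k)]]
          if (!is.null(v)) stat1[k] <- v
        }
      }
      # static double-cross scalars (fixed densities) for every active pair
      st2 <- NULL
      if (order >= 2) {
        st2 <- matrix(0, nact, nact)
        patt <- paste0("^t", cc, "q(\\d+)_(\\d+)$")
        for (nm2 in grep(patt, names(p$tens), value = TRUE)) {
          ij <- as.integer(strsplit(sub(paste0("^t", cc, "q"), "", nm2),
                                    "_", fixed = TRUE)[[1]])
          tq2 <- p$tens[[nm2]]
          v <- -ZB * sum(tq2$J[, 1] * vPaa) - ZA * sum(tq2$J[1, ] * vPbb) +
            2 * sum((bw * tq2$S) * matrix(vPab, p$nA, p$nB)) +
            sum(vPaa * (tq2$J %*% vPbb)) -
            sum(vPsa * (tq2$K %*% vPsa)) - sum(vPsb * (tq2$K %*% vPsb))
          st2[ij[1], ij[2]] <- st2[ij[2], ij[1]] <- v
        }
        for (nm2 in grep(patt, names(p$crf), value = TRUE)) {
          ij <- as.integer(strsplit(sub(paste0("^t", cc, "q"), "", nm2),
                                    "_", fixed = TRUE)[[1]])
          st2[ij[1], ij[2]] <- st2[ij[1], ij[2]] + p$crf[[nm2]]
          if (ij[1] != ij[2])
            st2[ij[2], ij[1]] <- st2[ij[2], ij[1]] + p$crf[[nm2]]
        }
        for (kb in which(is_b)) for (kz in which(is_z)) {
          tq2 <- p$tens[[.tag_tq(cc, kz)]]
          if (is.null(tq2)) next
          ind <- .beta_indicator(mi, .actq(mi, kb))
          bwk <- outer(ind[ia], ind[ib], "+") / 2
          v <- 2 * sum((bwk * tq2$S) * matrix(vPab, p$nA, p$nB))
          st2[kb, kz] <- st2[kb, kz] + v
          st2[kz, kb] <- st2[kz, kb] + v
        }
      }
      percc[[cc]] <- list(stat1 = stat1, st2 = st2,
                          Vva = Vva, Vvb = Vvb, bvec = bvec,
                          vJb = vJb, vJa = vJa, vKa = vKa, vKb = vKb,
                          wJb = wJb, wJa = wJa, wKa = wKa, wKb = wKb,
                          uVa = uVa, uVb = uVb, ubv = ubv,
                          uJb = uJb, uJa = uJa, uKa = uKa, uKb = uKb)
    }
    pre[[ip]] <- list(p = p, ia = ia, ib = ib, ZA = ZA, ZB = ZB, bw = bw,
                      vPaa = vPaa, vPbb = vPbb, vPab = vPab,
                      vPsa = vPsa, vPsb = vPsb, dblk = dblk, percc = percc)
  }

  dg <- lapply(seq_len(nact), function(k) matrix(0, nat, 3))
  for (ip in seq_along(pre)) {
    pp <- pre[[ip]]; p <- pp$p
    for (cc in 1:3) {
      pc <- pp$percc[[cc]]
      if (is.null(pc)) next
      for (k in seq_len(nact)) {
        d <- pc$stat1[k]
        if (k %in% iel) {
          db <- pp$dblk[[k]]
          d <- d + sum(pc$Vva * db$aa) + sum(pc$Vvb * db$bb) +
            2 * sum(pc$bvec * db$ab) +
            sum(pc$vJb * db$aa) + sum(pc$vJa * db$bb) -
            2 * sum(pc$vKa * db$sa) - 2 * sum(pc$vKb * db$sb)
        }
        dg[[k]][p$i, cc] <- dg[[k]][p$i, cc] - d
        dg[[k]][p$j, cc] <- dg[[k]][p$j, cc] + d
      }
    }
  }
  if (order < 2) return(list(dg = dg, d2g = NULL))

  d2g <- vector("list", nact * nact)
  for (k1 in seq_len(nact)) for (k2 in k1:nact) {
    both_el <- (k1 %in% iel) && (k2 %in% iel)
    so <- if (both_el) so_get(k1, k2) else NULL
    g2 <- matrix(0, nat, 3)
    for (ip in seq_along(pre)) {
      pp <- pre[[ip]]; p <- pp$p
      ia <- pp$ia; ib <- pp$ib
      d2b <- if (both_el)
        list(aa = as.vector(so$d2P$tot[ia, ia]),
             bb = as.vector(so$d2P$tot[ib, ib]),
             ab = as.vector(so$d2P$tot[ia, ib]),
             sa = as.vector(so$d2P$a[ia, ib]),
             sb = as.vector(so$d2P$b[ia, ib])) else NULL
      d1 <- pp$dblk[[k1]]; d2 <- pp$dblk[[k2]]
      for (cc in 1:3) {
        pc <- pp$percc[[cc]]
        if (is.null(pc)) next
        d <- pc$st2[k1, k2]
        # mixed static-response: d(tensor)/dk1 against dP/dk2 and v.v.
        cross1 <- function(ka, db) {
          if (is_z[ka] && !is.null(pc$uJb[[ka]])) {
            sum(pc$uVa[[ka]] * db$aa) + sum(pc$uVb[[ka]] * db$bb) +
              2 * sum(pc$ubv[[ka]] * db$ab) +
              sum(pc$uJb[[ka]] * db$aa) + sum(pc$uJa[[ka]] * db$bb) -
              2 * sum(pc$uKa[[ka]] * db$sa) - 2 * sum(pc$uKb[[ka]] * db$sb)
          } else if (is_b[ka] && !is.null(pc$ubv[[ka]])) {
            2 * sum(pc$ubv[[ka]] * db$ab)
          } else 0
        }
        if (k2 %in% iel) d <- d + cross1(k1, d2)
        if (k1 %in% iel) d <- d + cross1(k2, d1)
        if (both_el) {
          # plain tensor against the twice-varied density
          d <- d + sum(pc$Vva * d2b$aa) + sum(pc$Vvb * d2b$bb) +
            2 * sum(pc$bvec * d2b$ab) +
            sum(pc$vJb * d2b$aa) + sum(pc$vJa * d2b$bb) -
            2 * sum(pc$vKa * d2b$sa) - 2 * sum(pc$vKb * d2b$sb) +
            sum(pc$wJb[[k2]] * d1$aa) + sum(pc$wJa[[k2]] * d1$bb) -
            2 * sum(pc$wKa[[k2]] * d1$sa) - 2 * sum(pc$wKb[[k2]] * d1$sb)
        }
        g2[p$i, cc] <- g2[p$i, cc] - d
        g2[p$j, cc] <- g2[p$j, cc] + d
      }
    }
    d2g[[(k1 - 1L) * nact + k2]] <- g2
  }
  list(dg = dg, d2g = d2g)
}

# ---- public assembly --------------------------------------------------

#' Analytic parameter derivatives of the objective properties
#'
#' Computes first- and (optionally) second-order derivatives of the heat of
#' formation, ionization energy, dipole magnitude and gradient norm with
#' respect to every optimizable parameter of the supplied parameter set,
#' mapped onto the flattened parameter vector.
#'
#' @param entry A `training_entry` (its references select which properties
#'   are differentiated).
#' @param pset A `parameter_set`.
#' @param order 1 for first derivatives only, 2 to include the property
#'   Hessians.
#' @param scf Optional pre-converged `scf_state` built on integral tables
#'   of mode "param" (or "full" when the entry carries a geometry term).
#' @param warm Optional warm-start densities (see [scf_solve()]).
#' @return A list with per-property components `val`, `d1` (named vector on
#'   the full parameter vector) and `d2` (matrix), for each referenced
#'   property among `hf`, `ie`, `dip`, `gnorm`; plus `scf`.
#' @export
property_derivatives <- function(entry, pset, order = 2, scf = NULL,
                                 warm = NULL) {
  mol <- entry$mol
  need_geo <- isTRUE(entry$geo)
  mode <- if (need_geo) "full" else "param"
  if (is.null(scf)) {
    mi <- molecule_integrals(mol, pset, mode)
    scf <- scf_solve(mol, pset, mi = mi, warm = warm)
  } else {
    mi <- scf$mi
    if (!(mi$mode == "full" || (mi$mode == "param" && !need_geo)))
      stop("scf state built with integral mode '", mi$mode,
           "' lacks required derivative tensors")
  }
  fl <- flatten_parameters(pset)
  np <- length(fl$p)
  loc2glob <- match(mi$act$name, names(fl$p))
  if (anyNA(loc2glob)) stop("parameter set does not cover molecule elements")
  nact <- nrow(mi$act)
  ctx <- cphf_context(scf)
  resp <- lapply(seq_len(nact), function(k) cphf_first_order(ctx, k))

  need_resp2 <- order >= 2 && (!is.na(entry$ie) || !is.na(entry$dip) || need_geo)
  iel <- mi$idx_electronic
  so <- NULL
  if (need_resp2) {
    so <- vector("list", nact * nact)
    for (k1 in iel) for (k2 in iel) if (k1 <= k2)
      so[[(k1 - 1L) * nact + k2]] <-
        cphf_second_order(ctx, resp[[k1]], resp[[k2]])
  }
  so_get <- function(k1, k2) {
    i <- min(k1, k2); j <- max(k1, k2)
    v <- so[[(i - 1L) * nact + j]]
    if (is.null(v)) cphf_second_order(ctx, resp[[i]], resp[[j]]) else v
  }
  glob_vec <- function(loc) {
    v <- stats::setNames(numeric(np), names(fl$p)); v[loc2glob] <- loc; v
  }
  glob_mat <- function(locM) {
    M <- matrix(0, np, np, dimnames = list(names(fl$p), names(fl$p)))
    M[loc2glob, loc2glob] <- locM
    M
  }
  out <- list(scf = scf)
  kcv <- mndo_units$kcal_per_ev

  {  # heat-of-formation derivatives are cheap and always provided
    d1 <- .dHf_first(mi, scf, resp)
    res <- list(val = heat_of_formation(scf), d1 = glob_vec(d1))
    if (order >= 2) {
      d2 <- matrix(0, nact, nact)
      for (k1 in seq_len(nact)) for (k2 in k1:nact) {
        v <- .dHf_second(mi, scf, resp, k1, k2)
        d2[k1, k2] <- d2[k2, k1] <- v
      }
      res$d2 <- glob_mat(d2)
    }
    out$hf <- res
  }

  if (!is.na(entry$ie)) {
    hi <- .homo_info(scf)
    s <- hi$spin; n <- hi$idx
    eps <- scf$eps[[s]]
    if (n < length(eps) && abs(eps[n + 1] - eps[n]) < .deg_tol)
      stop(mol$name, ": degenerate HOMO/LUMO, IE derivative ill-defined")
    d1 <- vapply(seq_len(nact), function(k) -resp[[k]]$deps[[s]][n], 0)
    res <- list(val = ionization_energy(scf), d1 = glob_vec(d1))
    if (order >= 2) {
      d2 <- matrix(0, nact, nact)
      for (k1 in iel) for (k2 in iel) if (k1 <= k2) {
        v <- -so_get(k1, k2)$d2eps[[s]][n]
        d2[k1, k2] <- d2[k2, k1] <- v
      }
      res$d2 <- glob_mat(d2)
    }
    out$ie <- res
  }

  if (!is.na(entry$dip)) {
    if (!scf$is_rhf) stop(mol$name, ": dipole derivatives require RHF")
    cD <- mndo_units$debye_per_eA
    dpv <- dipole_moment(scf)
    mu <- dpv$mu
    ms <- sqrt(sum(mu^2) + .norm_eps^2)
    dmu <- lapply(seq_len(nact), function(k)
      cD * .dmu_vec(mi, scf, resp[[k]]$dP$tot, k))
    d1 <- vapply(seq_len(nact), function(k) sum(mu * dmu[[k]]) / ms, 0)
    res <- list(val = dpv$mag, d1 = glob_vec(d1))
    if (order >= 2) {
      d2 <- matrix(0, nact, nact)
      for (k1 in seq_len(nact)) for (k2 in k1:nact) {
        el1 <- k1 %in% iel; el2 <- k2 %in% iel
        d2mu <- if (el1 && el2)
          cD * .d2mu_vec(mi, scf, resp[[k1]], resp[[k2]],
                         so_get(k1, k2), k1, k2)
        else numeric(3)
        v <- (sum(dmu[[k1]] * dmu[[k2]]) + sum(mu * d2mu) -
                d1[k1] * d1[k2]) / ms
        d2[k1, k2] <- d2[k2, k1] <- v
      }
      res$d2 <- glob_mat(d2)
    }
    out$dip <- res
  }

  if (need_geo) {
    conv <- mndo_units$kcal_per_ev * mndo_units$bohr
    gr <- cartesian_gradient(scf)
    g <- gr$g
    gs <- sqrt(sum(g^2) + .norm_eps^2)
    ch <- .grad_chain_all(mi, scf, resp, iel, so_get, order)
    dg <- lapply(ch$dg, function(m) conv * m)
    d1 <- vapply(seq_len(nact), function(k) sum(g * dg[[k]]) / gs, 0)
    res <- list(val = gr$norm, d1 = glob_vec(d1), g = g, dg = dg)
    if (order >= 2) {
      d2 <- matrix(0, nact, nact)
      for (k1 in seq_len(nact)) for (k2 in k1:nact) {
        d2gm <- conv * ch$d2g[[(k1 - 1L) * nact + k2]]
        v <- (sum(dg[[k1]] * dg[[k2]]) + sum(g * d2gm) -
                d1[k1] * d1[k2]) / gs
        d2[k1, k2] <- d2[k2, k1] <- v
      }
      res$d2 <- glob_mat(d2)
    }
    out$gnorm <- res
  }
  out
}
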