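# Molecule-level integral tables: rotated pair blocks (overlap, two-electron
# tensor, core attraction, core-core repulsion) together with every analytic
# derivative tensor the downstream response machinery needs.
#
# Each atom pair is evaluated in the local diatomic frame and rotated to the
# global frame with jet-valued rotation matrices, so Cartesian derivatives
# flow through both the local distance dependence and the frame rotation.
# Derivative modes:
#   "val"   values only (SCF / objective evaluation)
#   "grad"  + first Cartesian derivatives (gradient-norm property)
#   "param" + first/second Slater-exponent and alpha derivatives
#   "full"  param + grad + mixed third-order (1 Cartesian x 2 parameters)
#           required by the gradient-norm Hessian chain

.electronic_fields <- c("beta_s", "beta_p", "u_ss", "u_pp", "zeta_s", "zeta_p")
.zeta_fields <- c("zeta_s", "zeta_p")

# fast active-parameter lookup (avoids data.frame row indexing in hot loops)
.actq <- function(mi, k) list(element = mi$act_el[k], field = mi$act_f[k])

.jet_cache_get <- function(key, builder) {
  if (is.null(.mndopt_env$jb)) .mndopt_env$jb <- new.env(parent = emptyenv())
  v <- .mndopt_env$jb[[key]]
  if (is.null(v)) { v <- builder(); .mndopt_env$jb[[key]] <- v }
  v
}

.pair_basis <- function(mode, hasPA, hasPB) {
  key <- paste("pair", mode, hasPA, hasPB)
  .jet_cache_get(key, function() {
    groups <- list()
    if (mode %in% c("grad", "full"))
      groups <- c(groups, list(list(vars = c("x", "y", "z"), cap = 1L)))
    if (mode %in% c("param", "full")) {
      zv <- c("zsA", if (hasPA) "zpA", "zsB", if (hasPB) "zpB")
      groups <- c(groups, list(list(vars = zv, cap = 2L)))
    }
    jet_basis(groups)
  })
}

.crf_basis <- function(mode) {
  key <- paste("crf", mode)
  .jet_cache_get(key, function() {
    groups <- list()
    if (mode %in% c("grad", "full"))
      groups <- c(groups, list(list(vars = c("x", "y", "z"), cap = 1L)))
    if (mode %in% c("param", "full"))
      groups <- c(groups, list(list(vars = c("aA", "aB"), cap = 2L)))
    jet_basis(groups)
  })
}

.atom_basis <- function(mode, hasP) {
  key <- paste("atom", mode, hasP)
  .jet_cache_get(key, function() {
    if (mode %in% c("param", "full")) {
      jet_basis(list(list(vars = c("zs", if (hasP) "zp"), cap = 2L)))
    } else jet_basis(list())
  })
}

# local axes and 4x4 (or 1x1) orbital rotation as jet arrays
.orbital_rotation <- function(B, xj, yj, zj, nA) {
  if (nA == 1L) {
    O <- array(0, c(B$n, 1L, 1L)); O[1, 1, 1] <- 1
    return(O)
  }
  R2 <- jmul(B, xj, xj) + jmul(B, yj, yj) + jmul(B, zj, zj)
  iR <- jinvsqrt(B, R2)
  ez <- list(jmul(B, xj, iR), jmul(B, yj, iR), jmul(B, zj, iR))
  ezv <- vapply(ez, function(u) .jval(u)[1], 0)
  k <- which.min(abs(ezv))
  v <- lapply(1:3, function(i) {
    d <- if (i == k) jet_const(B, 1) else jet_const(B, 0)
    d - jmul(B, ez[[k]], ez[[i]])
  })
  v2 <- jmul(B, v[[1]], v[[1]]) + jmul(B, v[[2]], v[[2]]) + jmul(B, v[[3]], v[[3]])
  iv <- jinvsqrt(B, v2)
  exv <- lapply(v, function(u) jmul(B, u, iv))
  eyv <- list(jmul(B, ez[[2]], exv[[3]]) - jmul(B, ez[[3]], exv[[2]]),
              jmul(B, ez[[3]], exv[[1]]) - jmul(B, ez[[1]], exv[[3]]),
              jmul(B, ez[[1]], exv[[2]]) - jmul(B, ez[[2]], exv[[1]]))
  O <- array(0, c(B$n, 4L, 4L))
  O[1, 1, 1] <- 1
  for (i in 1:3) {
    O[, 1 + i, 2] <- exv[[i]]
    O[, 1 + i, 3] <- eyv[[i]]
    O[, 1 + i, 4] <- ez[[i]]
  }
  O
}

# local overlap block [nslot, nA, nB] in orbital order (s, px, py, pz)
.local_overlap <- function(B, elA, zsA, zpA, elB, zsB, zpB, Rbohr) {
  nA <- .n_basis_elem[[elA]]; nB <- .n_basis_elem[[elB]]
  naQ <- .principal_n[[elA]]; nbQ <- .principal_n[[elB]]
  S <- array(0, c(B$n, nA, nB))
  S[, 1, 1] <- sto_overlap_entry(B, naQ, "s", zsA, nbQ, "s", zsB, Rbohr)
  if (nB == 4L)
    S[, 1, 4] <- sto_overlap_entry(B, naQ, "s", zsA, nbQ, "sig", zpB, Rbohr)
  if (nA == 4L)
    S[, 4, 1] <- sto_overlap_entry(B, naQ, "sig", zpA, nbQ, "s", zsB, Rbohr)
  if (nA == 4L && nB == 4L) {
    S[, 4, 4] <- sto_overlap_entry(B, naQ, "sig", zpA, nbQ, "sig", zpB, Rbohr)
    pp <- sto_overlap_entry(B, naQ, "pi", zpA, nbQ, "pi", zpB, Rbohr)
    S[, 2, 2] <- pp; S[, 3, 3] <- pp
  }
  S
}

.kron4 <- function(B, O) {
  n <- dim(O)[2]
  if (B$n == 1L) {
    Om <- matrix(O[1, , ], n, n)
    # kron with our pair-label convention (mu fastest)
    Tk <- matrix(0, n * n, n * n)
    for (nu in seq_len(n)) for (nup in seq_len(n))
      Tk[(nu - 1L) * n + seq_len(n), (nup - 1L) * n + seq_len(n)] <-
        Om * Om[nu, nup]
    return(array(Tk, c(1L, n * n, n * n)))
  }
  # single vectorized restricted product over all n^4 element pairs
  Om <- matrix(O, B$n, n * n)           # columns indexed (mu, mup) mu fastest
  g <- expand.grid(mu = seq_len(n), nu = seq_len(n),
                   mup = seq_len(n), nup = seq_len(n))
  li <- g$mu + (g$mup - 1L) * n
  ri <- g$nu + (g$nup - 1L) * n
  P <- jmul_rot(B, Om[, li, drop = FALSE], Om[, ri, drop = FALSE])
  rr <- (g$nu - 1L) * n + g$mu
  cc <- (g$nup - 1L) * n + g$mup
  Tk <- matrix(0, B$n, n^4)
  Tk[, rr + (cc - 1L) * n * n] <- P
  array(Tk, c(B$n, n * n, n * n))
}

# ordered derivative-variable lists for a global parameter on this pair
.pair_vlist <- function(pair, q) {
  v <- character(0)
  if (q$field == "zeta_s") {
    if (pair$elA == q$element) v <- c(v, "zsA")
    if (pair$elB == q$element) v <- c(v, "zsB")
  } else if (q$field == "zeta_p") {
    if (pair$elA == q$element && pair$nA == 4L) v <- c(v, "zpA")
    if (pair$elB == q$element && pair$nB == 4L) v <- c(v, "zpB")
  } else if (q$field == "alpha") {
    if (pair$elA == q$element) v <- c(v, "aA")
    if (pair$elB == q$element) v <- c(v, "aB")
  }
  v
}

# slot/factor table for a derivative request, memoized per basis
.jet_slice_plan <- function(B, vlists, cart) {
  key <- paste(B$id, paste(vapply(vlists, paste, "", collapse = "+"),
                           collapse = ";"), paste(cart, collapse = ","))
  if (is.null(.mndopt_env$sl)) .mndopt_env$sl <- new.env(parent = emptyenv())
  pl <- .mndopt_env$sl[[key]]
  if (!is.null(pl)) return(pl)
  combos <- if (length(vlists)) expand.grid(vlists, stringsAsFactors = FALSE) else
    data.frame(row.names = 1)
  slots <- integer(0)
  for (r in seq_len(nrow(combos))) {
    vars <- unlist(combos[r, ], use.names = FALSE)
    tab <- table(c(vars, cart))
    e <- stats::setNames(as.integer(tab), names(tab))
    s <- do.call(jet_slot, c(list(B), list(e)))
    if (is.na(s)) stop("jet basis does not track requested derivative")
    slots <- c(slots, s)
  }
  agg <- tapply(B$fact[slots], slots, sum)
  pl <- list(slots = as.integer(names(agg)), w = as.numeric(agg))
  .mndopt_env$sl[[key]] <- pl
  pl
}

# slice a jet array: sum of derivatives for ordered combinations of the
# variable lists (each a character vector), plus optional cart exponent
.jet_slice <- function(B, arr, vlists, cart = NULL) {
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  dm <- dim(arr)
  pl <- .jet_slice_plan(B, vlists, cart)
  if (length(pl$slots) == 1L)
    return(array(arr[pl$slots, , ], dm[-1]) * pl$w)
  m <- matrix(arr, dm[1], dm[2] * dm[3])
  array(as.vector(pl$w %*% m[pl$slots, , drop = FALSE]), dm[-1])
}

# exchange-ordered copy of a two-electron matrix: rows (mu in A, nu in B),
# cols (la in A, si in B) with X[(mu,nu),(la,si)] = (mu la | nu si)
.exchange_order <- function(W, nA, nB) {
  W4 <- array(W, c(nA, nA, nB, nB))          # W4[m1,m2,m3,m4] = (m1 m2|m3 m4)
  matrix(aperm(W4, c(1, 3, 2, 4)), nA * nB, nA * nB)
}

#' Build the integral tables for one molecule
#'
#' Computes all rotated pair blocks and the analytic derivative tensors for
#' the requested mode, evaluated at the given parameter set.
#'
#' @param mol A `molecule`.
#' @param pset A `parameter_set` covering the molecule's elements.
#' @param mode One of "val", "grad", "param", "full" (see source header).
#' @return An opaque list consumed by the SCF/CPHF/property layers.
#' @keywords internal
molecule_integrals <- function(mol, pset, mode = "val") {
  elems <- mol$elements
  nat <- length(elems)
  norb <- .n_basis_elem[elems]
  orb0 <- cumsum(c(0L, norb[-nat]))
  nbf <- sum(norb)
  present <- intersect(.elements, unique(elems))
  missing_el <- setdiff(unique(elems), names(pset))
  if (length(missing_el))
    stop("parameter set lacks element(s): ", paste(missing_el, collapse = ", "))

  # active parameter table for present elements
  act <- do.call(rbind, lapply(present, function(el) {
    data.frame(element = el, field = .fields_for(el), stringsAsFactors = FALSE)
  }))
  act$name <- paste(act$element, act$field, sep = ".")
  idx_zeta <- which(act$field %in% .zeta_fields)
  idx_alpha <- which(act$field == "alpha")
  with_param <- mode %in% c("param", "full")
  with_grad <- mode %in% c("grad", "full")

  # per-atom multipole data (value basis) and per-element D1 jets
  mp_val <- vector("list", nat)
  B1 <- .jet_scalar_basis()
  for (a in seq_len(nat)) {
    ep <- pset[[elems[a]]]
    mp_val[[a]] <- if (norb[a] == 1L)
      atom_multipole_data(B1, elems[a], jet_const(B1, ep$zeta_s))
    else
      atom_multipole_data(B1, elems[a], jet_const(B1, ep$zeta_s),
                          jet_const(B1, ep$zeta_p))
  }
  D1_jets <- list()
  if (with_param) {
    for (el in present) {
      if (.n_basis_elem[[el]] == 1L) next
      Ba <- .atom_basis(mode, TRUE)
      ep <- pset[[el]]
      D1_jets[[el]] <- mp_D1(Ba, .principal_n[[el]],
                             jet_var(Ba, "zs", ep$zeta_s),
                             jet_var(Ba, "zp", ep$zeta_p))
    }
  }

  # orbital-wise beta and U values and (element, s/p) tags
  orb_el <- character(nbf); orb_p <- logical(nbf)
  for (a in seq_len(nat)) {
    ix <- orb0[a] + seq_len(norb[a])
    orb_el[ix] <- elems[a]
    orb_p[ix] <- c(FALSE, TRUE, TRUE, TRUE)[seq_len(norb[a])]
  }
  beta_orb <- vapply(seq_len(nbf), function(i) {
    ep <- pset[[orb_el[i]]]
    if (orb_p[i]) ep$beta_p else ep$beta_s
  }, 0)
  u_orb <- vapply(seq_len(nbf), function(i) {
    ep <- pset[[orb_el[i]]]
    if (orb_p[i]) ep$u_pp else ep$u_ss
  }, 0)

  one_center <- lapply(seq_len(nat), function(a) {
    W <- one_center_tensor(elems[a])
    list(J = W, K = .exchange_order(W, norb[a], norb[a]))
  })

  # derivative tags
  ztags <- list()   # list of list(ids = act indices (<=2), cart = int or NULL)
  add_tag <- function(name, ids, cart) {
    ztags[[name]] <<- list(ids = ids, cart = cart)
  }
  add_tag("0", integer(0), NULL)
  if (with_grad) for (cc in 1:3) add_tag(paste0("t", cc), integer(0), cc)
  if (with_param) {
    for (i in idx_zeta) add_tag(paste0("q", i), i, NULL)
    for (i in idx_zeta) for (j in idx_zeta) if (i <= j)
      add_tag(paste0("q", i, "_", j), c(i, j), NULL)
    if (mode == "full") {
      for (cc in 1:3) for (i in idx_zeta) add_tag(paste0("t", cc, "q", i), i, cc)
      for (cc in 1:3) for (i in idx_zeta) for (j in idx_zeta) if (i <= j)
        add_tag(paste0("t", cc, "q", i, "_", j), c(i, j), cc)
    }
  }
  atags <- list()
  add_atag <- function(name, ids, cart) { atags[[name]] <<- list(ids = ids, cart = cart) }
  add_atag("0", integer(0), NULL)
  if (with_grad) for (cc in 1:3) add_atag(paste0("t", cc), integer(0), cc)
  if (with_param) {
    for (i in idx_alpha) add_atag(paste0("q", i), i, NULL)
    for (i in idx_alpha) for (j in idx_alpha) if (i <= j)
      add_atag(paste0("q", i, "_", j), c(i, j), NULL)
    if (mode == "full") {
      for (cc in 1:3) for (i in idx_alpha) add_atag(paste0("t", cc, "q", i), i, cc)
      for (cc in 1:3) for (i in idx_alpha) for (j in idx_alpha) if (i <= j)
        add_atag(paste0("t", cc, "q", i, "_", j), c(i, j), cc)
    }
  }
  cart_names <- c("x", "y", "z")

  pairs <- list()
  for (i in seq_len(nat - 1L)) for (j in (i + 1L):nat) {
    elA <- elems[i]; elB <- elems[j]
    nA <- norb[i]; nB <- norb[j]
    hasPA <- nA == 4L; hasPB <- nB == 4L
    B <- .pair_basis(mode, hasPA, hasPB)
    rv <- mol$coords[j, ] - mol$coords[i, ]
    R0 <- sqrt(sum(rv^2))
    if (R0 < 1e-6) stop("coincident atoms ", i, " and ", j)
    mkc <- function(nm, val) {
      if (with_grad) jet_var(B, nm, val) else jet_const(B, val)
    }
    xj <- mkc("x", rv[1]); yj <- mkc("y", rv[2]); zj <- mkc("z", rv[3])
    R2 <- jmul(B, xj, xj) + jmul(B, yj, yj) + jmul(B, zj, zj)
    Rj <- jsqrt(B, R2)
    mkz <- function(nm, val) {
      if (with_param) jet_var(B, nm, val) else jet_const(B, val)
    }
    epA <- pset[[elA]]; epB <- pset[[elB]]
    zsA <- mkz("zsA", epA$zeta_s); zsB <- mkz("zsB", epB$zeta_s)
    zpA <- if (hasPA) mkz("zpA", epA$zeta_p) else NULL
    zpB <- if (hasPB) mkz("zpB", epB$zeta_p) else NULL
    mpA <- atom_multipole_data(B, elA, zsA, zpA)
    mpB <- atom_multipole_data(B, elB, zsB, zpB)
    Wloc <- pair_twoel_local(B, mpA, mpB, Rj)
    Sloc <- .local_overlap(B, elA, zsA, zpA, elB, zsB, zpB, Rj / .a0)
    O <- .orbital_rotation(B, xj, yj, zj, max(nA, nB))
    OA <- if (nA == 4L) O else array(c(1, numeric(B$n - 1L)), c(B$n, 1L, 1L))
    OB <- if (nB == 4L) O else array(c(1, numeric(B$n - 1L)), c(B$n, 1L, 1L))
    Sglob <- jmm(B, OA, jmm(B, Sloc, aperm(OB, c(1, 3, 2)), rot = "right"),
                 rot = "left")
    TA <- if (nA == 4L) .kron4(B, OA) else OA
    TB <- if (nB == 4L) .kron4(B, OB) else OB
    Wglob <- jmm(B, TA, jmm(B, Wloc, aperm(TB, c(1, 3, 2)), rot = "right"),
                 rot = "left")
    pair <- list(i = i, j = j, elA = elA, elB = elB, nA = nA, nB = nB)

    # slice all requested derivative tensors into plain matrices
    tens <- list()
    for (nm in names(ztags)) {
      tg <- ztags[[nm]]
      vlists <- lapply(tg$ids, function(k) .pair_vlist(pair, act[k, ]))
      if (any(vapply(vlists, length, 0L) == 0L)) next  # exact zero
      cart <- if (is.null(tg$cart)) NULL else cart_names[tg$cart]
      Wm <- matrix(.jet_slice(B, Wglob, vlists, cart), nA * nA, nB * nB)
      Sm <- matrix(.jet_slice(B, Sglob, vlists, cart), nA, nB)
      tens[[nm]] <- list(J = Wm, K = .exchange_order(Wm, nA, nB), S = Sm)
    }
    pair$tens <- tens

    # core-core repulsion (separate jet basis over x,y,z,aA,aB)
    Bc <- .crf_basis(mode)
    mka <- function(nm, val) if (with_param) jet_var(Bc, nm, val) else jet_const(Bc, val)
    mkcc <- function(nm, val) if (with_grad) jet_var(Bc, nm, val) else jet_const(Bc, val)
    xc <- mkcc("x", rv[1]); yc <- mkcc("y", rv[2]); zc <- mkcc("z", rv[3])
    R2c <- jmul(Bc, xc, xc) + jmul(Bc, yc, yc) + jmul(Bc, zc, zc)
    Rc <- jsqrt(Bc, R2c)
    aA <- mka("aA", epA$alpha); aB <- mka("aB", epB$alpha)
    rho0s <- .jval(mp_val[[i]]$rho0)[1] + .jval(mp_val[[j]]$rho0)[1]
    g00 <- .e2 * jinvsqrt(Bc, R2c + jet_const(Bc, rho0s^2))
    eA <- jexp(Bc, -jmul(Bc, aA, Rc))
    eB <- jexp(Bc, -jmul(Bc, aB, Rc))
    nh <- (elA == "H" && elB %in% c("N", "O")) ||
      (elB == "H" && elA %in% c("N", "O"))
    if (nh) {
      # R multiplies the heavy atom's exponential (original MNDO N-H/O-H form)
      if (elA %in% c("N", "O")) eA <- jmul(Bc, Rc, eA) else eB <- jmul(Bc, Rc, eB)
    }
    f <- jet_const(Bc, 1) + eA + eB
    ZZ <- .core_charge[[elA]] * .core_charge[[elB]]
    crfj <- ZZ * jmul(Bc, g00, f)
    crf <- list()
    for (nm in names(atags)) {
      tg <- atags[[nm]]
      vlists <- lapply(tg$ids, function(k) .pair_vlist(pair, act[k, ]))
      if (any(vapply(vlists, length, 0L) == 0L)) next
      cart <- if (is.null(tg$cart)) NULL else cart_names[tg$cart]
      crf[[nm]] <- as.numeric(.jet_slice(Bc, matrix(crfj, Bc$n, 1), vlists, cart))
    }
    pair$crf <- crf
    pairs[[length(pairs) + 1L]] <- pair
  }

  list(mol = mol, pset = pset, mode = mode, nat = nat, nbf = nbf,
       norb = norb, orb0 = orb0, elems = elems, act = act,
       act_el = act$element, act_f = act$field,
       idx_zeta = idx_zeta, idx_alpha = idx_alpha,
       idx_eisol = which(act$field == "e_isol"),
       idx_electronic = which(act$field %in% .electronic_fields),
       orb_el = orb_el, orb_p = orb_p, beta_orb = beta_orb, u_orb = u_orb,
       one_center = one_center, mp_val = mp_val, D1_jets = D1_jets,
       pairs = pairs)
}

# tag helpers -----------------------------------------------------------

.tag_q <- function(i) paste0("q", i)
.tag_qq <- function(i, j) paste0("q", min(i, j), "_", max(i, j))
.tag_t <- function(cc) paste0("t", cc)
.tag_tq <- function(cc, i) paste0("t", cc, "q", i)
.tag_tqq <- function(cc, i, j) paste0("t", cc, "q", min(i, j), "_", max(i, j))

# generalized Coulomb matrix J(Delta) with the tensor set selected by tag
# ("0" includes the one-center constants; derivative tags are two-center only)
J_of <- function(mi, tag, Delta) {
  J <- matrix(0, mi$nbf, mi$nbf)
  if (tag == "0") {
    for (a in seq_len(mi$nat)) {
      ix <- mi$orb0[a] + seq_len(mi$norb[a])
      J[ix, ix] <- J[ix, ix] +
        matrix(mi$one_center[[a]]$J %*% as.vector(Delta[ix, ix]),
               mi$norb[a], mi$norb[a])
    }
  }
  for (p in mi$pairs) {
    tt <- p$tens[[tag]]
    if (is.null(tt)) next
    ia <- mi$orb0[p$i] + seq_len(p$nA)
    ib <- mi$orb0[p$j] + seq_len(p$nB)
    J[ia, ia] <- J[ia, ia] + matrix(tt$J %*% as.vector(Delta[ib, ib]), p$nA, p$nA)
    J[ib, ib] <- J[ib, ib] + matrix(crossprod(tt$J, as.vector(Delta[ia, ia])), p$nB, p$nB)
  }
  J
}

# generalized exchange matrix K(Lambda)
K_of <- function(mi, tag, Lambda) {
  K <- matrix(0, mi$nbf, mi$nbf)
  if (tag == "0") {
    for (a in seq_len(mi$nat)) {
      ix <- mi$orb0[a] + seq_len(mi$norb[a])
      K[ix, ix] <- K[ix, ix] +
        matrix(mi$one_center[[a]]$K %*% as.vector(Lambda[ix, ix]),
               mi$norb[a], mi$norb[a])
    }
  }
  for (p in mi$pairs) {
    tt <- p$tens[[tag]]
    if (is.null(tt)) next
    ia <- mi$orb0[p$i] + seq_len(p$nA)
    ib <- mi$orb0[p$j] + seq_len(p$nB)
    Kab <- matrix(tt$K %*% as.vector(Lambda[ia, ib]), p$nA, p$nB)
    K[ia, ib] <- K[ia, ib] + Kab
    K[ib, ia] <- K[ib, ia] + t(Kab)
  }
  K
}

# core Hamiltonian and its parameter derivatives ------------------------

core_hamiltonian <- function(mi) {
  H <- matrix(0, mi$nbf, mi$nbf)
  diag(H) <- mi$u_orb
  for (p in mi$pairs) {
    tt <- p$tens[["0"]]
    ia <- mi$orb0[p$i] + seq_len(p$nA)
    ib <- mi$orb0[p$j] + seq_len(p$nB)
    ZA <- .core_charge[[p$elA]]; ZB <- .core_charge[[p$elB]]
    H[ia, ia] <- H[ia, ia] - ZB * matrix(tt$J[, 1], p$nA, p$nA)
    H[ib, ib] <- H[ib, ib] - ZA * matrix(tt$J[1, ], p$nB, p$nB)
    bmat <- outer(mi$beta_orb[ia], mi$beta_orb[ib], "+") / 2 * tt$S
    H[ia, ib] <- H[ia, ib] + bmat
    H[ib, ia] <- H[ib, ia] + t(bmat)
  }
  H
}

# indicator weights for beta derivatives: d beta_mu / d q over orbitals
.beta_indicator <- function(mi, q) {
  ind <- as.numeric(mi$orb_el == q$element &
                      mi$orb_p == (q$field == "beta_p"))
  ind
}

# dH/dq for an active parameter index k (matrix; exact zeros for alpha and
# e_isol, which do not enter the electronic problem)
dH_dq <- function(mi, k) {
  q <- .actq(mi, k)
  H <- matrix(0, mi$nbf, mi$nbf)
  if (q$field %in% c("u_ss", "u_pp")) {
    ind <- mi$orb_el == q$element & mi$orb_p == (q$field == "u_pp")
    diag(H)[ind] <- 1
    return(H)
  }
  if (q$field %in% c("beta_s", "beta_p")) {
    ind <- .beta_indicator(mi, q)
    for (p in mi$pairs) {
      tt <- p$tens[["0"]]
      ia <- mi$orb0[p$i] + seq_len(p$nA)
      ib <- mi$orb0[p$j] + seq_len(p$nB)
      bmat <- outer(ind[ia], ind[ib], "+") / 2 * tt$S
      H[ia, ib] <- H[ia, ib] + bmat
      H[ib, ia] <- H[ib, ia] + t(bmat)
    }
    return(H)
  }
  if (q$field %in% .zeta_fields) {
    tag <- .tag_q(k)
    for (p in mi$pairs) {
      tt <- p$tens[[tag]]
      if (is.null(tt)) next
      ia <- mi$orb0[p$i] + seq_len(p$nA)
      ib <- mi$orb0[p$j] + seq_len(p$nB)
      ZA <- .core_charge[[p$elA]]; ZB <- .core_charge[[p$elB]]
      H[ia, ia] <- H[ia, ia] - ZB * matrix(tt$J[, 1], p$nA, p$nA)
      H[ib, ib] <- H[ib, ib] - ZA * matrix(tt$J[1, ], p$nB, p$nB)
      bmat <- outer(mi$beta_orb[ia], mi$beta_orb[ib], "+") / 2 * tt$S
      H[ia, ib] <- H[ia, ib] + bmat
      H[ib, ia] <- H[ib, ia] + t(bmat)
    }
    return(H)
  }
  H  # alpha, e_isol: zero
}

# d2H/dq1 dq2
d2H_dq <- function(mi, k1, k2) {
  q1 <- .actq(mi, k1); q2 <- .actq(mi, k2)
  H <- matrix(0, mi$nbf, mi$nbf)
  f1 <- q1$field; f2 <- q2$field
  isz1 <- f1 %in% .zeta_fields; isz2 <- f2 %in% .zeta_fields
  isb1 <- f1 %in% c("beta_s", "beta_p"); isb2 <- f2 %in% c("beta_s", "beta_p")
  if (isz1 && isz2) {
    tag <- .tag_qq(k1, k2)
    for (p in mi$pairs) {
      tt <- p$tens[[tag]]
      if (is.null(tt)) next
      ia <- mi$orb0[p$i] + seq_len(p$nA)
      ib <- mi$orb0[p$j] + seq_len(p$nB)
      ZA <- .core_charge[[p$elA]]; ZB <- .core_charge[[p$elB]]
      H[ia, ia] <- H[ia, ia] - ZB * matrix(tt$J[, 1], p$nA, p$nA)
      H[ib, ib] <- H[ib, ib] - ZA * matrix(tt$J[1, ], p$nB, p$nB)
      bmat <- outer(mi$beta_orb[ia], mi$beta_orb[ib], "+") / 2 * tt$S
      H[ia, ib] <- H[ia, ib] + bmat
      H[ib, ia] <- H[ib, ia] + t(bmat)
    }
    return(H)
  }
  if ((isb1 && isz2) || (isb2 && isz1)) {
    kb <- if (isb1) k1 else k2
    kz <- if (isb1) k2 else k1
    ind <- .beta_indicator(mi, .actq(mi, kb))
    tag <- .tag_q(kz)
    for (p in mi$pairs) {
      tt <- p$tens[[tag]]
      if (is.null(tt)) next
      ia <- mi$orb0[p$i] + seq_len(p$nA)
      ib <- mi$orb0[p$j] + seq_len(p$nB)
      bmat <- outer(ind[ia], ind[ib], "+") / 2 * tt$S
      H[ia, ib] <- H[ia, ib] + bmat
      H[ib, ia] <- H[ib, ia] + t(bmat)
    }
    return(H)
  }
  H  # u-u, beta-beta, anything with alpha/e_isol: zero
}

# core-core repulsion sum and derivatives --------------------------------

core_repulsion_sum <- function(mi, tag = "0") {
  tot <- 0
  for (p in mi$pairs) {
    v <- p$crf[[tag]]
    if (!is.null(v)) tot <- tot + v
  }
  tot
}
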