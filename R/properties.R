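# Molecular properties entering the parameterization objective:
# heat of formation, Koopmans ionization energy, dipole moment, and the
# Cartesian gradient of the total energy (frozen-density form, valid at the
# SCF solution).

#' Heat of formation
#'
#' dHf = k_conv (E_el + V_core - sum_A E_isol(A)) + sum_A dHf_atom(A),
#' in kcal/mol, with E_isol the per-element isolated-atom electronic energy
#' parameter and dHf_atom the fixed experimental atomic heats of formation.
#'
#' @param scf A converged `scf_state`.
#' @return Heat of formation in kcal/mol.
#' @export
heat_of_formation <- function(scf) {
  pset <- scf$pset
  eisol <- sum(vapply(scf$mol$elements, function(el) pset[[el]]$e_isol, 0))
  hof_at <- sum(vapply(scf$mol$elements,
                       function(el) element_constants(el)$hof_atom, 0))
  mndo_units$kcal_per_ev * (scf$E_el + scf$V_core - eisol) + hof_at
}

#' Ionization energy (Koopmans)
#'
#' IE = -max occupied orbital energy over both spins, in eV.
#'
#' @param scf A converged `scf_state`.
#' @return Ionization energy in eV.
#' @export
ionization_energy <- function(scf) {
  cand <- c(if (scf$na > 0L) scf$eps$a[scf$na], if (scf$nb > 0L) scf$eps$b[scf$nb])
  -max(cand)
}

.center_of_mass <- function(mol) {
  m <- .atomic_mass[mol$elements]
  colSums(mol$coords * m) / sum(m)
}

#' Dipole moment
#'
#' Point-charge term from net atomic charges plus the one-center sp
#' hybridization term -2 D1 P_sp per heavy atom.
#'
#' @param scf A converged `scf_state`.
#' @return List with `mu` (vector, Debye) and `mag` (magnitude, Debye).
#' @export
dipole_moment <- function(scf) {
  mi <- scf$mi
  cm <- .center_of_mass(scf$mol)
  mu <- numeric(3)
  for (a in seq_len(mi$nat)) {
    ix <- mi$orb0[a] + seq_len(mi$norb[a])
    qa <- .core_charge[[mi$elems[a]]] - sum(diag(scf$P)[ix])
    mu <- mu + qa * (scf$mol$coords[a, ] - cm)
    if (mi$norb[a] == 4L) {
      D1 <- .jval(mi$mp_val[[a]]$D1)[1]
      s <- mi$orb0[a] + 1L
      for (tau in 1:3)
        mu[tau] <- mu[tau] - 2 * D1 * scf$P[s, s + tau]
    }
  }
  mu <- mndo_units$debye_per_eA * mu
  list(mu = mu, mag = sqrt(sum(mu^2)))
}

# pairwise two-center energy derivative contraction for one derivative tag;
# returns the scalar d E_AB / d(tag) for pair p at density scf
.pair_energy_deriv <- function(mi, scf, p, tag) {
  tt <- p$tens[[tag]]
  vcrf <- p$crf[[tag]]
  tot <- if (is.null(vcrf)) 0 else vcrf
  if (!is.null(tt)) {
    ia <- mi$orb0[p$i] + seq_len(p$nA)
    ib <- mi$orb0[p$j] + seq_len(p$nB)
    ZA <- .core_charge[[p$elA]]; ZB <- .core_charge[[p$elB]]
    Paa <- scf$P[ia, ia, drop = FALSE]; Pbb <- scf$P[ib, ib, drop = FALSE]
    Pab <- scf$P[ia, ib, drop = FALSE]
    # core attraction
    tot <- tot - ZB * sum(matrix(tt$J[, 1], p$nA, p$nA) * Paa)
    tot <- tot - ZA * sum(matrix(tt$J[1, ], p$nB, p$nB) * Pbb)
    # resonance
    bmat <- outer(mi$beta_orb[ia], mi$beta_orb[ib], "+") / 2 * tt$S
    tot <- tot + 2 * sum(Pab * bmat)
    # two-electron Coulomb and exchange
    tot <- tot + as.numeric(crossprod(as.vector(Paa), tt$J %*% as.vector(Pbb)))
    for (s in c("a", "b")) {
      Ps <- scf$Pspin[[s]][ia, ib, drop = FALSE]
      tot <- tot - as.numeric(crossprod(as.vector(Ps), tt$K %*% as.vector(Ps)))
    }
  }
  tot
}

#' Cartesian gradient of the total energy
#'
#' Frozen-density pairwise gradient: density-matrix contractions with the
#' Cartesian derivatives of the two-center integrals plus the core-repulsion
#' derivatives.  Requires integral tables built in mode "grad" or "full".
#'
#' @param scf A converged `scf_state` whose `mi` carries Cartesian
#'   derivative tensors.
#' @return List with `g` (matrix n_atoms x 3, kcal mol^-1 bohr^-1) and
#'   `norm` (Euclidean norm of the full gradient vector).
#' @export
cartesian_gradient <- function(scf) {
  mi <- scf$mi
  if (!mi$mode %in% c("grad", "full"))
    stop("integral tables lack Cartesian derivatives (mode '", mi$mode, "')")
  g <- matrix(0, mi$nat, 3)
  for (p in mi$pairs) {
    for (cc in 1:3) {
      d <- .pair_energy_deriv(mi, scf, p, .tag_t(cc))
      g[p$i, cc] <- g[p$i, cc] - d   # pair variables are R_j - R_i
      g[p$j, cc] <- g[p$j, cc] + d
    }
  }
  g <- g * mndo_units$kcal_per_ev * mndo_units$bohr
  list(g = g, norm = sqrt(sum(g^2)))
}

#' All objective properties of a molecule
#'
#' Convenience wrapper computing heat of formation, ionization energy,
#' dipole magnitude and (optionally) the gradient norm at the given
#' parameters.
#'
#' @param mol A `molecule`.
#' @param pset A `parameter_set`.
#' @param geo Include the Cartesian gradient norm (needs "grad" tables).
#' @param mi Optional precomputed integral tables.
#' @param warm Optional warm-start densities (see [scf_solve()]).
#' @return List with `hf` (kcal/mol), `ie` (eV), `dip` (D), `gnorm`
#'   (kcal mol^-1 bohr^-1, or NA), and the underlying `scf` state.
#' @export
molecule_properties <- function(mol, pset, geo = FALSE, mi = NULL,
                                warm = NULL) {
  if (is.null(mi))
    mi <- molecule_integrals(mol, pset, if (geo) "grad" else "val")
  scf <- scf_solve(mol, pset, mi = mi, warm = warm)
  dp <- dipole_moment(scf)
  list(hf = heat_of_formation(scf),
       ie = ionization_energy(scf),
       dip = dp$mag,
       gnorm = if (geo) cartesian_gradient(scf)$norm else NA_real_,
       scf = scf)
}
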