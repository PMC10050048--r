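# Assembled property derivatives against FD oracles, zero-block structure,
# and the cross-derivative consistency of the gradient chain.

test_that("all four property first derivatives match FD on distorted water", {
  mol <- fix_h2o_dist()
  entry <- training_entry(mol, hf = 0, ie = 10, dip = 1, geo = TRUE)
  pd <- property_derivatives(entry, mndo_pset, order = 1)
  fl <- flatten_parameters(mndo_pset)
  f <- props_fun(mol, mndo_pset, geo = TRUE)
  for (nm in c("O.alpha", "O.beta_p", "O.u_pp", "O.zeta_s", "O.zeta_p",
               "H.beta_s", "H.zeta_s", "H.e_isol")) {
    for (prop in c("hf", "ie", "dip", "gnorm")) {
      fd <- fd_param(function(p) f(p)[[prop]], fl$p, nm, h = 1e-5)
      an <- pd[[prop]]$d1[[nm]]
      expect_lt(abs(an - fd$value),
                1e-5 * max(abs(fd$value), 1e-3),
                label = sprintf("d%s/d%s", prop, nm))
    }
  }
})

test_that("second derivatives match FD for representative parameter pairs", {
  mol <- fix_h2o_dist()
  entry <- training_entry(mol, hf = 0, ie = 10, dip = 1, geo = TRUE)
  pd <- property_derivatives(entry, mndo_pset, order = 2)
  fl <- flatten_parameters(mndo_pset)
  f <- props_fun(mol, mndo_pset, geo = TRUE)
  pairs <- list(c("O.zeta_p", "H.zeta_s"), c("O.beta_p", "O.zeta_p"),
                c("O.u_pp", "O.u_pp"), c("O.alpha", "O.alpha"),
                c("O.zeta_s", "O.zeta_s"), c("H.beta_s", "H.u_ss"))
  for (pr in pairs) {
    for (prop in c("hf", "ie", "dip", "gnorm")) {
      # step sizes balance truncation against the SCF-limited precision of
      # the property values (the heat of formation carries ~1e-8 kcal/mol
      # of convergence noise, amplified by 1/h^2)
      h <- if (prop == "hf") 1e-3 else 5e-4
      fd <- fd_param(function(p) f(p)[[prop]], fl$p, pr[1], pr[2], h = h)
      an <- pd[[prop]]$d2[pr[1], pr[2]]
      expect_lt(abs(an - fd$value),
                2e-4 * max(abs(fd$value), 0.5),
                label = sprintf("d2%s/d%s d%s", prop, pr[1], pr[2]))
    }
  }
  # symmetry of each property Hessian
  for (prop in c("hf", "ie", "dip", "gnorm"))
    expect_lt(max(abs(pd[[prop]]$d2 - t(pd[[prop]]$d2))), 1e-8)
})

test_that("derivative blocks of absent elements are exactly zero and the
           E_isol column touches only the heat of formation", {
  mol <- fix_h2o_dist()
  entry <- training_entry(mol, hf = 0, ie = 10, dip = 1, geo = TRUE)
  pd <- property_derivatives(entry, mndo_pset, order = 2)
  absent <- grep("^(C|N|F)\\.", names(flatten_parameters(mndo_pset)$p),
                 value = TRUE)
  for (prop in c("hf", "ie", "dip", "gnorm")) {
    expect_true(all(pd[[prop]]$d1[absent] == 0))
    expect_true(all(pd[[prop]]$d2[absent, ] == 0))
  }
  for (prop in c("ie", "dip", "gnorm")) {
    expect_identical(pd[[prop]]$d1[["O.e_isol"]], 0)
    expect_true(all(pd[[prop]]$d2["O.e_isol", ] == 0))
  }
  # dHf/dE_isol = -k_conv * n_Z and its whole second-derivative row is zero
  expect_equal(pd$hf$d1[["H.e_isol"]], -2 * mndo_units$kcal_per_ev,
               tolerance = 1e-12)
  expect_true(all(pd$hf$d2["H.e_isol", ] == 0))
})

test_that("alpha mixes with no electronic parameter in the heat of
           formation Hessian", {
  mol <- fix_nh3()
  entry <- training_entry(mol, hf = 0)
  pd <- property_derivatives(entry, mndo_pset, order = 2)
  for (nm in c("N.beta_s", "N.zeta_p", "H.u_ss", "N.e_isol"))
    expect_identical(pd$hf$d2["N.alpha", nm], 0)
  # diagonal alpha curvature is alive; the alpha_A-alpha_B cross term
  # vanishes because the two core-repulsion exponentials separate
  expect_gt(abs(pd$hf$d2["N.alpha", "N.alpha"]), 1e-6)
  expect_lt(abs(pd$hf$d2["N.alpha", "H.alpha"]), 1e-12)
})

test_that("single-atom closed forms: dIE/dU_ss = -1 for hydrogen", {
  h1 <- molecule("H", matrix(0, 1, 3), mult = 2L, name = "h1")
  entry <- training_entry(h1, ie = 13)
  pd <- property_derivatives(entry, mndo_pset, order = 1)
  expect_equal(pd$ie$d1[["H.u_ss"]], -1, tolerance = 1e-12)
})

test_that("homonuclear symmetry: H2 dipole vector derivatives vanish", {
  entry <- training_entry(fix_h2(), dip = 0.5)
  pd <- property_derivatives(entry, mndo_pset, order = 1)
  # |mu| = 0; the smoothed-norm chain gives zero magnitude derivatives
  expect_lt(max(abs(pd$dip$d1)), 1e-8)
})

test_that("gradient-vector derivatives: translation invariance and the
           energy-chain cross-derivative oracle", {
  mol <- fix_nh3()
  co <- mol$coords; co[2, 1] <- co[2, 1] + 0.05; co[3, 3] <- co[3, 3] - 0.04
  mold <- molecule(mol$elements, co, name = "nh3_dist")
  entry <- training_entry(mold, geo = TRUE)
  pd <- property_derivatives(entry, mndo_pset, order = 1)
  kcv <- mndo_units$kcal_per_ev
  conv <- kcv * mndo_units$bohr
  # locate dg matrices via the active-parameter ordering used internally
  mi <- pd$scf$mi
  for (nm in c("N.zeta_p", "H.beta_s", "N.alpha")) {
    k <- which(mi$act$name == nm)
    dg <- pd$gnorm$dg[[k]]
    expect_lt(max(abs(colSums(dg))), 1e-8)   # sum over atoms vanishes
    # FD over a coordinate of the analytic dE/dp energy chain
    dEdp_at <- function(coords) {
      m2 <- molecule(mold$elements, coords, name = "nh3_fd")
      e2 <- training_entry(m2, hf = 0)
      pd2 <- property_derivatives(e2, mndo_pset, order = 1)
      pd2$hf$d1[[nm]] / kcv    # eV per parameter unit
    }
    h <- 2e-4
    for (probe in list(c(1, 3), c(2, 1))) {
      a <- probe[1]; cc <- probe[2]
      cp <- mold$coords; cp[a, cc] <- cp[a, cc] + h
      cm <- mold$coords; cm[a, cc] <- cm[a, cc] - h
      fd <- (dEdp_at(cp) - dEdp_at(cm)) / (2 * h) * conv
      expect_lt(abs(dg[a, cc] - fd), 1e-5 * max(1, abs(fd)),
                label = sprintf("dg/d%s atom %d comp %d", nm, a, cc))
    }
  }
})
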