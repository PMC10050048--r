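# Weighted least-squares objective: arithmetic, additivity, analytic
# gradient/Hessian against FD, Gram approximant, modified Hessian.

small_entries <- function() {
  ps <- mndo_pset
  mols <- list(fix_h2(), fix_hf(), fix_h2o_dist())
  lapply(mols, function(m) {
    v <- molecule_properties(m, ps, geo = TRUE)
    training_entry(m, hf = v$hf + 1, ie = v$ie - 0.1,
                   dip = if (m$mult == 1L) v$dip + 0.05 else NA,
                   geo = TRUE)
  })
}

test_that("S follows the weighted square-error arithmetic", {
  m <- fix_h2o()
  v <- molecule_properties(m, mndo_pset, geo = TRUE)
  # offsets 1 kcal/mol, 0.1 eV, 0.05 D plus the gradient-norm term
  e <- training_entry(m, hf = v$hf + 1, ie = v$ie + 0.1, dip = v$dip + 0.05,
                      geo = TRUE)
  r <- evaluate_objective(list(e), mndo_pset, order = 0)
  # weights 1, 10, 20, 0.5: contributions 1, 1, 1 and (0.5 |g|)^2
  expect_equal(r$S, 3 + (0.5 * v$gnorm)^2, tolerance = 1e-7)
  # with |g| = 2 the geometry term would contribute exactly 1 as well
  expect_equal((0.5 * 2)^2, 1)
})

test_that("S is additive over entries and zero at a perfect fit", {
  ents <- small_entries()
  r_all <- evaluate_objective(ents, mndo_pset, order = 0)
  parts <- vapply(ents, function(e)
    evaluate_objective(list(e), mndo_pset, order = 0)$S, 0)
  expect_equal(r_all$S, sum(parts), tolerance = 1e-9)
  # perfect fit: references equal to computed values, no geometry term
  perfect <- lapply(list(fix_h2(), fix_hf()), function(m) {
    v <- molecule_properties(m, mndo_pset)
    training_entry(m, hf = v$hf, ie = v$ie, dip = v$dip, geo = FALSE)
  })
  rp <- evaluate_objective(perfect, mndo_pset, order = 2)
  expect_lt(rp$S, 1e-15)
  expect_lt(max(abs(rp$gradient)), 1e-6)
  # at a perfect fit the exact Hessian equals the Gram approximant
  expect_lt(max(abs(rp$H - rp$H_pm7)), 1e-6)
})

test_that("objective gradient and Hessian match FD on a small fixture", {
  ents <- small_entries()
  rep2 <- evaluate_objective(ents, mndo_pset, order = 2)
  fl <- flatten_parameters(mndo_pset)
  S_at <- function(p)
    evaluate_objective(ents, unflatten_parameters(p, mndo_pset), order = 0)$S
  for (nm in c("H.beta_s", "O.zeta_p", "F.alpha", "O.e_isol")) {
    fd <- fd_param(S_at, fl$p, nm, h = 1e-6)
    expect_lt(abs(rep2$gradient[[nm]] - fd$value),
              1e-5 * max(1, abs(fd$value)))
  }
  # Hessian vs FD of the analytic gradient
  g_at <- function(p)
    evaluate_objective(ents, unflatten_parameters(p, mndo_pset), order = 1)$gradient
  h <- 1e-5
  for (nm in c("O.zeta_p", "H.u_ss")) {
    pp <- fl$p; pp[nm] <- pp[nm] + h
    pm <- fl$p; pm[nm] <- pm[nm] - h
    fdrow <- (g_at(pp) - g_at(pm)) / (2 * h)
    act <- abs(fdrow) > 1e-8
    expect_lt(max(abs(rep2$H[nm, act] - fdrow[act]) /
                    pmax(abs(fdrow[act]), 1e-2)), 1e-4)
  }
  expect_lt(rep2$asym, 1e-6)
})

test_that("the Gram approximant equals an explicit outer-product loop and
           is positive semidefinite", {
  ents <- small_entries()
  r <- evaluate_objective(ents, mndo_pset, order = 1)
  acc <- matrix(0, r$n_par, r$n_par)
  for (i in seq_len(nrow(r$residuals)))
    acc <- acc + 2 * r$residuals$weight[i]^2 * tcrossprod(r$jacobian[i, ])
  expect_equal(unname(r$H_pm7), unname(acc), tolerance = 1e-12)
  ev <- eigen(r$H_pm7, symmetric = TRUE)$values
  expect_gte(min(ev), -1e-8)
})

test_that("H minus the Gram part equals the residual-weighted second
           derivative sum", {
  ents <- small_entries()[1:2]
  r <- evaluate_objective(ents, mndo_pset, order = 2)
  acc <- matrix(0, r$n_par, r$n_par)
  for (e in ents) {
    pd <- property_derivatives(e, mndo_pset, order = 2)
    for (prop in c("hf", "ie", "dip", "gnorm")) {
      if (is.null(pd[[prop]])) next
      ref <- switch(prop, hf = e$hf, ie = e$ie, dip = e$dip, gnorm = 0)
      if (is.na(ref)) next
      w <- switch(prop, hf = e$weights[["hf"]], ie = e$weights[["ie"]],
                  dip = e$weights[["dip"]], gnorm = e$weights[["geo"]])
      acc <- acc + 2 * w^2 * (pd[[prop]]$val - ref) * pd[[prop]]$d2
    }
  }
  expect_equal(unname(r$H - r$H_pm7), unname((acc + t(acc)) / 2),
               tolerance = 1e-8)
})

test_that("modified Hessian: identity on PSD input, brute-force 2x2 case,
           absolute spectrum in general", {
  Hp <- crossprod(matrix(stats::rnorm(16), 4))
  expect_equal(modified_hessian(Hp), Hp, tolerance = 1e-12)
  H2 <- matrix(c(0, 2, 2, 0), 2)
  expect_equal(modified_hessian(H2), diag(c(2, 2)), tolerance = 1e-12)
  set.seed(21)
  for (i in 1:5) {
    M <- matrix(stats::rnorm(49), 7); M <- M + t(M)
    Hm <- modified_hessian(M)
    expect_equal(sort(eigen(Hm, symmetric = TRUE)$values),
                 sort(abs(eigen(M, symmetric = TRUE)$values)),
                 tolerance = 1e-10)
    # eigenvectors preserved: Hm and M commute
    expect_lt(max(abs(Hm %*% M - M %*% Hm)), 1e-8)
  }
})

test_that("eigen reports are ascending with a deterministic sign convention", {
  set.seed(5)
  M <- matrix(stats::rnorm(36), 6); M <- M + t(M)
  e <- hessian_eigen(M)
  expect_true(!is.unsorted(e$values))
  for (k in seq_len(ncol(e$vectors))) {
    nz <- which(abs(e$vectors[, k]) > 1e-12)
    expect_gt(e$vectors[nz[1], k], 0)
  }
})

test_that("a failing molecule aborts the objective with its name", {
  m <- molecule(c("O", "O"), rbind(c(0, 0, 0), c(0, 0, 1e-8)), name = "clash")
  e <- training_entry(m, hf = 0)
  expect_error(evaluate_objective(list(e), mndo_pset, order = 0), "clash")
})
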