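# The weighted least-squares parameterization objective
#   S = sum_alpha C_alpha^2 (xi_ref - xi)^2
# over a training set, with its analytic gradient, the exact parameter
# Hessian, the positive-semidefinite Gram (PM7-style) approximant that
# drops residual-weighted second derivatives, and the eigenvalue-rectified
# modified Hessian.

.entry_props <- function(entry) {
  props <- character(0)
  if (!is.na(entry$hf)) props <- c(props, "hf")
  if (!is.na(entry$ie)) props <- c(props, "ie")
  if (!is.na(entry$dip)) props <- c(props, "dip")
  if (isTRUE(entry$geo)) props <- c(props, "gnorm")
  props
}

.entry_ref <- function(entry, prop) {
  switch(prop, hf = entry$hf, ie = entry$ie, dip = entry$dip, gnorm = 0)
}

.entry_weight <- function(entry, prop) {
  switch(prop, hf = entry$weights[["hf"]], ie = entry$weights[["ie"]],
         dip = entry$weights[["dip"]], gnorm = entry$weights[["geo"]])
}

#' Evaluate the parameterization objective
#'
#' Computes S and, on request, its analytic gradient and Hessians over the
#' flattened parameter vector.  A non-converging molecule aborts with an
#' error naming it: silently skipping entries would change S
#' discontinuously during optimization.
#'
#' @param entries List of `training_entry` objects.
#' @param pset A `parameter_set` covering all elements in the set.
#' @param order 0: S and residuals only; 1: + gradient; 2: + exact and
#'   Gram Hessians.
#' @param warm Optional environment carrying per-entry warm-start densities
#'   in `warm$dens` (density continuation during optimization).
#' @param warm_update Store the converged densities back into `warm`.
#' @return An object of class `objective_report`: list with `S`,
#'   `residuals` (data.frame), and for higher orders `gradient`, `H`
#'   (exact, symmetrized with asymmetry monitor), `H_pm7`, `asym` (pre-
#'   symmetrization asymmetry), `n_par`.
#' @export
evaluate_objective <- function(entries, pset, order = 0, warm = NULL,
                               warm_update = FALSE) {
  fl <- flatten_parameters(pset)
  np <- length(fl$p)
  S <- 0
  rows <- list()
  jac <- list()
  g <- stats::setNames(numeric(np), names(fl$p))
  H <- matrix(0, np, np, dimnames = list(names(fl$p), names(fl$p)))
  Hp <- H
  for (ei in seq_along(entries)) {
    entry <- entries[[ei]]
    props <- .entry_props(entry)
    wdens <- if (!is.null(warm) && length(warm$dens) >= ei)
      warm$dens[[ei]] else NULL
    if (order == 0) {
      vals <- tryCatch(
        molecule_properties(entry$mol, pset, geo = isTRUE(entry$geo),
                            warm = wdens),
        error = function(e)
          stop("objective evaluation failed for molecule '",
               entry$mol$name, "': ", conditionMessage(e), call. = FALSE))
      getv <- function(prop)
        switch(prop, hf = vals$hf, ie = vals$ie, dip = vals$dip,
               gnorm = vals$gnorm)
      scf_used <- vals$scf
    } else {
      pd <- tryCatch(
        property_derivatives(entry, pset, order = order, warm = wdens),
        error = function(e)
          stop("objective evaluation failed for molecule '",
               entry$mol$name, "': ", conditionMessage(e), call. = FALSE))
      getv <- function(prop) pd[[prop]]$val
      scf_used <- pd$scf
    }
    if (!is.null(warm) && warm_update)
      warm$dens[[ei]] <- list(Pa = scf_used$Pspin$a, Pb = scf_used$Pspin$b)
    for (prop in props) {
      val <- getv(prop)
      ref <- .entry_ref(entry, prop)
      w <- .entry_weight(entry, prop)
      resid <- ref - val
      S <- S + w^2 * resid^2
      rows[[length(rows) + 1L]] <-
        data.frame(entry = ei, molecule = entry$mol$name, property = prop,
                   ref = ref, value = val, weight = w,
                   wresid = w * resid, stringsAsFactors = FALSE)
      if (order >= 1) {
        d1 <- pd[[prop]]$d1
        g <- g + 2 * w^2 * (val - ref) * d1
        jac[[length(jac) + 1L]] <- d1
        if (order >= 2) {
          Hp <- Hp + 2 * w^2 * tcrossprod(d1)
          H <- H + 2 * w^2 * (tcrossprod(d1) + (val - ref) * pd[[prop]]$d2)
        }
      }
    }
  }
  out <- list(S = S, residuals = do.call(rbind, rows), n_par = np,
              par = fl$p)
  if (order >= 1) {
    out$gradient <- g
    out$jacobian <- do.call(rbind, jac)  # rows align with residuals
    # Gram approximant available already from first derivatives
    w2 <- out$residuals$weight^2
    out$H_pm7 <- 2 * crossprod(out$jacobian * sqrt(w2))
  }
  if (order >= 2) {
    out$asym <- max(abs(H - t(H)))
    out$H <- (H + t(H)) / 2
  }
  class(out) <- "objective_report"
  out
}

#' @export
print.objective_report <- function(x, ...) {
  cat(sprintf("<objective: S = %.6g over %d residuals, %d parameters>\n",
              x$S, nrow(x$residuals), x$n_par))
  invisible(x)
}

#' Eigenvalue-rectified (modified) Hessian
#'
#' Replaces the eigenvalues of a symmetric matrix by their absolute values
#' while preserving its eigenvectors, yielding a positive-semidefinite
#' curvature model whose descent steps cannot point uphill.
#'
#' @param H Symmetric matrix.
#' @return Matrix of the same dimension.
#' @export
modified_hessian <- function(H) {
  e <- eigen((H + t(H)) / 2, symmetric = TRUE)
  e$vectors %*% (abs(e$values) * t(e$vectors))
}

#' Sorted eigen-decomposition report of a Hessian
#'
#' @param H Symmetric matrix.
#' @return List with `values` (ascending) and `vectors` (columns, sign
#'   fixed so the first nonzero component is positive).
#' @export
hessian_eigen <- function(H) {
  e <- eigen((H + t(H)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  for (k in seq_len(ncol(vecs))) {
    nz <- which(abs(vecs[, k]) > 1e-12)
    if (length(nz) && vecs[nz[1], k] < 0) vecs[, k] <- -vecs[, k]
  }
  list(values = vals, vectors = vecs)
}
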