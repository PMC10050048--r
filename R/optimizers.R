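# Parameter-update schemes for the least-squares objective: approximated
# line search (ALS), trust-radius Hessian descent (HD-TR) and trust-region
# optimization (TRO), each usable with the exact Hessian, the Gram (PM7)
# approximant, or the eigenvalue-rectified modified Hessian.

#' Approximated line-search step
#'
#' Direction is the (pseudo-)inverse Hessian descent direction, normalized;
#' the step length minimizes the linearized surrogate of S along the
#' direction in closed form (a quadratic in the step length), capped.
#'
#' @param g Objective gradient.
#' @param B Hessian or approximant.
#' @param report An order >= 1 `objective_report` supplying the residual
#'   jacobian for the surrogate.
#' @param cap Maximum step length.
#' @return List with `d` (step), `k` (length), `dhat` (unit direction).
#' @export
als_step <- function(g, B, report, cap = 2) {
  dn <- tryCatch(-solve(B, g), error = function(e) {
    warning("singular curvature matrix in ALS step; using pseudo-inverse")
    -as.vector(MASS_ginv(B) %*% g)
  })
  nd <- sqrt(sum(dn^2))
  if (nd < 1e-300) return(list(d = 0 * g, k = 0, dhat = 0 * g))
  dhat <- dn / nd
  r <- report$residuals$ref - report$residuals$value
  w2 <- report$residuals$weight^2
  t <- as.vector(report$jacobian %*% dhat)
  denom <- sum(w2 * t^2)
  k <- if (denom > 0) sum(w2 * r * t) / denom else 0
  k <- min(max(k, 0), cap)
  list(d = k * dhat, k = k, dhat = dhat)
}

# minimal pseudo-inverse (avoids a MASS dependency)
MASS_ginv <- function(M, tol = 1e-12) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Trust-radius update rule
#'
#' Compares the actual reduction with the quadratic-model prediction
#' Q = d'g + d'Bd/2 and adapts the radius: x5/4 for good agreement with a
#' decrease, /2 for poor agreement or any increase, unchanged otherwise;
#' the radius is capped and the step is rejected iff S did not decrease.
#'
#' @param Q Quadratic-model value for the step.
#' @param S_old,S_new Objective before/after the trial step.
#' @param R Current radius.
#' @param dmax Radius cap.
#' @return List with `R` (updated), `accept`, `rho`.
#' @export
trust_radius_update <- function(Q, S_old, S_new, R, dmax = 2) {
  decreased <- is.finite(S_new) && S_new < S_old
  rho <- if (abs(Q) < 1e-14) (if (decreased) 1 else 0) else (S_new - S_old) / Q
  if (!is.finite(rho)) rho <- 0
  R_new <- if (rho > 0.8 && decreased) 1.25 * R
  else if (rho < 0.25 || !decreased) 0.5 * R
  else R
  list(R = min(R_new, dmax), accept = decreased, rho = rho)
}

#' Trust-region step
#'
#' Minimizes the quadratic model d'g + d'Bd/2 subject to |d| <= R via the
#' spectral shift: d = -(B + lambda I)^-1 g with lambda >= 0 chosen so that
#' B + lambda I is positive definite and |d| = R on the boundary; the
#' unconstrained Newton step is taken when it is interior and B is PD.
#' The hard case (gradient orthogonal to the lowest eigenvector) is
#' resolved by adding an explicit eigenvector component on the boundary.
#'
#' @param g Gradient.
#' @param B Symmetric Hessian or approximant.
#' @param R Trust radius.
#' @return List with `d`, `lambda`, `Q` (model value), `hard` flag.
#' @export
tro_step <- function(g, B, R) {
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lam <- e$values
  gt <- as.vector(crossprod(e$vectors, g))
  model_Q <- function(d) sum(d * g) + 0.5 * sum(d * (B %*% d))
  dn_of <- function(shift) -gt / (lam + shift)
  lmin <- min(lam)
  if (lmin > 0) {
    dint <- dn_of(0)
    if (sqrt(sum(dint^2)) <= R) {
      d <- as.vector(e$vectors %*% dint)
      return(list(d = d, lambda = 0, Q = model_Q(d), hard = FALSE))
    }
  }
  lo <- max(0, -lmin)
  psi <- function(shift) sqrt(sum((gt / (lam + shift))^2))
  eps0 <- max(1e-12, abs(lo) * 1e-12)
  hard <- FALSE
  if (psi(lo + eps0) < R) {
    # hard case: boundary step with explicit lowest-eigenvector component
    hard <- TRUE
    shift <- lo
    safe <- abs(lam + shift) > 1e-10
    dpart <- numeric(length(lam))
    dpart[safe] <- -gt[safe] / (lam[safe] + shift)
    tau2 <- R^2 - sum(dpart^2)
    tau <- sqrt(max(tau2, 0))
    imin <- which.min(lam)
    dpart[imin] <- dpart[imin] + tau
    d <- as.vector(e$vectors %*% dpart)
    return(list(d = d, lambda = shift, Q = model_Q(d), hard = TRUE))
  }
  # psi is decreasing in the shift; bracket and root-find
  hi <- lo + max(1, sqrt(sum(gt^2)) / R)
  while (psi(hi) > R) hi <- lo + (hi - lo) * 4
  root <- stats::uniroot(function(s) psi(s) - R, c(lo + eps0, hi),
                         tol = 1e-13)$root
  d <- as.vector(e$vectors %*% dn_of(root))
  list(d = d, lambda = root, Q = model_Q(d), hard = hard)
}

.S_at <- function(entries, pset, p, warm = NULL) {
  ps <- unflatten_parameters(p, pset)
  tryCatch(evaluate_objective(entries, ps, order = 0, warm = warm)$S,
           error = function(e) Inf)
}

#' Optimize semi-empirical parameters against a training set
#'
#' Driver loop for the three update schemes.  Derivative information is
#' recomputed at every accepted point; trial points are evaluated
#' value-only, and a trial whose SCF fails counts as an infinite S (the
#' step is rejected and the radius shrinks).
#'
#' The driver carries the converged densities of the current accepted
#' point and offers them as warm starts for every SCF alongside the two
#' cold guesses (lowest-energy solution wins): semi-empirical parameter
#' surfaces support multiple SCF solutions away from physical parameter
#' values, and density continuation prevents spurious objective
#' discontinuities where a cold guess's convergence basin happens to
#' switch.  When the trust radius underflows at a point with a sizeable
#' gradient (a rejected-step deadlock at a surface wall) the radius is
#' reset to its initial value a bounded number of times.
#'
#' @param entries List of `training_entry` objects.
#' @param pset Starting `parameter_set`.
#' @param method One of "tro" (trust region), "hdtr" (Hessian descent with
#'   trust radius), "als" (approximated line search).
#' @param hessian One of "exact", "pm7" (Gram approximant), "abs"
#'   (eigenvalue-rectified exact Hessian).
#' @param maxiter Maximum number of update attempts.
#' @param R0 Initial trust radius / step size.
#' @param dmax Maximum step length.
#' @param gtol Gradient-norm termination threshold.
#' @param Stol Terminate when S falls below this value.
#' @param verbose Print per-iteration progress.
#' @return List with `pset` (final parameters), `p` (final vector), `S`,
#'   `trace` (data.frame: iter, S, grad_norm, step_norm, R, rho, accepted),
#'   `converged`, `final_report` (order per `hessian`).
#' @export
optimize_parameters <- function(entries, pset, method = c("tro", "hdtr", "als"),
                                hessian = c("abs", "exact", "pm7"),
                                maxiter = 300L, R0 = 0.1, dmax = 2,
                                gtol = 1e-8, Stol = -Inf, verbose = FALSE) {
  method <- match.arg(method)
  hessian <- match.arg(hessian)
  ord <- if (hessian == "pm7") 1 else 2
  fl <- flatten_parameters(pset)
  p <- fl$p
  R <- R0
  cap <- dmax
  trace <- list()
  warm <- new.env(parent = emptyenv())
  warm$dens <- list()
  n_restart <- 0L
  rep_now <- evaluate_objective(entries, unflatten_parameters(p, pset),
                                order = ord, warm = warm, warm_update = TRUE)
  for (it in seq_len(maxiter)) {
    g <- rep_now$gradient
    gn <- sqrt(sum(g^2))
    if (gn < gtol || rep_now$S < Stol) break
    B <- switch(hessian, exact = rep_now$H, pm7 = rep_now$H_pm7,
                abs = modified_hessian(rep_now$H))
    if (method == "als") {
      st <- als_step(g, B, rep_now, cap = cap)
      d <- st$d
      Q <- sum(d * g) + 0.5 * sum(d * (B %*% d))
      S_new <- .S_at(entries, pset, p + d, warm = warm)
      accept <- is.finite(S_new) && S_new < rep_now$S
      rho <- NA_real_
      if (!accept) cap <- cap / 2
    } else if (method == "hdtr") {
      dn <- tryCatch(-solve(B, g), error = function(e)
        -as.vector(MASS_ginv(B) %*% g))
      nd <- sqrt(sum(dn^2))
      d <- if (nd > 0) dn / nd * min(R, dmax) else 0 * g
      Q <- sum(d * g) + 0.5 * sum(d * (B %*% d))
      S_new <- .S_at(entries, pset, p + d, warm = warm)
      up <- trust_radius_update(Q, rep_now$S, S_new, R, dmax)
      R <- up$R; accept <- up$accept; rho <- up$rho
    } else {
      st <- tro_step(g, B, min(R, dmax))
      d <- st$d
      Q <- st$Q
      S_new <- .S_at(entries, pset, p + d, warm = warm)
      up <- trust_radius_update(Q, rep_now$S, S_new, R, dmax)
      R <- up$R; accept <- up$accept; rho <- up$rho
    }
    trace[[it]] <- data.frame(iter = it, S = rep_now$S, grad_norm = gn,
                              step_norm = sqrt(sum(d^2)), R = R,
                              rho = rho, accepted = accept)
    if (verbose)
      cat(sprintf("it %3d  S %.6g  |g| %.3g  |d| %.3g  R %.3g  %s\n",
                  it, rep_now$S, gn, sqrt(sum(d^2)), R,
                  if (accept) "accept" else "reject"))
    if (accept) {
      p <- p + d
      rep_now <- evaluate_objective(entries, unflatten_parameters(p, pset),
                                    order = ord, warm = warm,
                                    warm_update = TRUE)
    } else if (method != "als" && R < 1e-10) {
      if (n_restart < 3L && sqrt(sum(g^2)) > 1e3 * gtol) {
        n_restart <- n_restart + 1L
        R <- R0
      } else break
    } else if (method == "als" && cap < 1e-10) break
  }
  list(pset = unflatten_parameters(p, pset), p = p, S = rep_now$S,
       trace = do.call(rbind, trace),
       converged = sqrt(sum(rep_now$gradient^2)) < gtol,
       final_report = rep_now)
}
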