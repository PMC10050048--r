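# Forward-mode truncated-Taylor ("jet") arithmetic.
#
# Analytic derivatives of the molecular integrals with respect to Slater
# exponents, core-repulsion exponents and Cartesian coordinates are obtained
# by evaluating the closed-form integral routines in a truncated multivariate
# Taylor arithmetic: every intermediate quantity carries the Taylor
# coefficients of the final result with respect to a chosen set of variables,
# so the chain rule is applied mechanically and exactly (this is analytic
# differentiation, not finite differencing).
#
# A jet is a numeric vector of Taylor coefficients over a fixed monomial
# basis; a "jet matrix" stores one jet per column ([n_slots x m]) so that
# batches of interaction terms can be processed with vectorized operations.
# The monomial basis is capped per variable group (e.g. Cartesian components
# to first order, Slater exponents to second order) which keeps the mixed
# third-order coefficients needed by the gradient-norm Hessian chain while
# dropping everything unused.

jet_basis <- function(groups) {
  vars <- unlist(lapply(groups, `[[`, "vars"))
  if (anyDuplicated(vars)) stop("duplicate jet variables")
  nv <- length(vars)
  if (nv == 0L) {
    expo <- matrix(0L, 1, 0)
  } else {
    caps <- integer(nv); names(caps) <- vars
    for (g in groups) caps[g$vars] <- g$cap
    grids <- lapply(caps, function(k) 0:k)
    expo <- as.matrix(do.call(expand.grid, grids))
    keep <- rep(TRUE, nrow(expo))
    for (g in groups) {
      cols <- match(g$vars, vars)
      keep <- keep & rowSums(expo[, cols, drop = FALSE]) <= g$cap
    }
    expo <- expo[keep, , drop = FALSE]
    expo <- expo[order(rowSums(expo),
                       apply(expo, 1, paste, collapse = ",")), , drop = FALSE]
  }
  storage.mode(expo) <- "integer"
  rownames(expo) <- NULL
  n <- nrow(expo)
  slot_of <- new.env(parent = emptyenv())
  if (nv > 0L) {
    key <- apply(expo, 1, paste, collapse = ",")
    for (i in seq_len(n)) assign(key[i], i, envir = slot_of)
  } else key <- "0"
  # multiplication table: (i, j) -> slot of monomial product, truncated
  I <- integer(0); J <- integer(0); K <- integer(0)
  if (n > 1L) {
    for (i in seq_len(n)) {
      sums <- sweep(expo, 2, expo[i, ], "+")
      skey <- apply(sums, 1, paste, collapse = ",")
      k <- vapply(skey, function(s) {
        v <- mget(s, envir = slot_of, ifnotfound = list(NA_integer_))[[1]]
        as.integer(v)
      }, 1L)
      ok <- !is.na(k)
      I <- c(I, rep.int(i, sum(ok))); J <- c(J, which(ok)); K <- c(K, k[ok])
    }
    ord <- order(K, I)
    I <- I[ord]; J <- J[ord]; K <- K[ord]
  }
  fact <- apply(expo, 1, function(e) prod(factorial(e)))
  maxord <- if (n > 1L) max(rowSums(expo)) else 0L
  B <- list(n = n, vars = vars, expo = expo, key = key, slot_of = slot_of,
            I = I, J = J, K = K, fact = fact, maxord = maxord)
  if (n > 1L) {
    # accumulation helpers: K is sorted and covers every slot
    B$ends <- c(which(diff(K) > 0), length(K))
    B$acc <- Matrix::sparseMatrix(i = K, j = seq_along(I), x = 1,
                                  dims = c(n, length(I)))
    # restricted table for multiplication by jets that live on the
    # Cartesian-only slots (rotation matrices): much smaller product set
    cartv <- intersect(vars, c("x", "y", "z"))
    other <- setdiff(vars, cartv)
    cart_slots <- if (length(other))
      which(rowSums(expo[, other, drop = FALSE]) == 0L) else seq_len(n)
    keep <- J %in% cart_slots
    B$cart_slots <- cart_slots
    B$Ir <- I[keep]; B$Jr <- J[keep]; Kr <- K[keep]
    B$accr <- matrix(0, n, length(Kr))           # dense: few hundred columns
    B$accr[cbind(Kr, seq_along(Kr))] <- 1
    B$id <- paste(vars, collapse = "|")
  }
  B
}

# product with a jet (matrix) `b` known to be supported on Cartesian-only
# slots; falls back to the value fast path for scalar bases
jmul_rot <- function(B, a, b) {
  if (B$n == 1L) return(a * b)
  if (!is.matrix(a)) a <- matrix(a, B$n)
  if (!is.matrix(b)) b <- matrix(b, B$n)
  p <- a[B$Ir, , drop = FALSE] * b[B$Jr, , drop = FALSE]
  B$accr %*% p
}

# slot index of the monomial with the given named exponents
jet_slot <- function(B, ...) {
  dots0 <- c(...)
  if (length(B$vars) == 0L)
    return(if (length(dots0) == 0L || all(dots0 == 0)) 1L else NA_integer_)
  e <- integer(length(B$vars)); names(e) <- B$vars
  dots <- dots0
  if (length(dots)) {
    if (any(!names(dots) %in% B$vars)) return(NA_integer_)
    e[names(dots)] <- dots
  }
  v <- mget(paste(e, collapse = ","), envir = B$slot_of,
            ifnotfound = list(NA_integer_))[[1]]
  as.integer(v)
}

jet_const <- function(B, x) { v <- numeric(B$n); v[1] <- x; v }

jet_var <- function(B, name, value) {
  v <- numeric(B$n); v[1] <- value
  s <- jet_slot(B, stats::setNames(1L, name))
  if (!is.na(s)) v[s] <- 1
  v
}

# product of two jets (vectors) or jet matrices ([n x m], column = jet)
jmul <- function(B, a, b) {
  if (B$n == 1L) return(a * b)
  if (is.matrix(a) || is.matrix(b)) {
    if (!is.matrix(a)) a <- matrix(a, B$n, ncol(b))
    if (!is.matrix(b)) b <- matrix(b, B$n, ncol(a))
    p <- a[B$I, , drop = FALSE] * b[B$J, , drop = FALSE]
    as.matrix(B$acc %*% p)
  } else {
    cs <- cumsum(a[B$I] * b[B$J])
    e <- cs[B$ends]
    c(e[1], diff(e))
  }
}

# f applied to jets via Taylor composition around the value coefficient.
# d is a function(u0) returning a list/matrix of derivative rows d0..d3.
jet_compose <- function(B, u, dlist) {
  if (B$n == 1L) return(if (is.matrix(u)) matrix(dlist[[1]], 1, ncol(u)) else dlist[[1]])
  mo <- B$maxord
  if (is.matrix(u)) {
    m <- ncol(u)
    w <- u; w[1, ] <- 0
    out <- matrix(0, B$n, m)
    out[1, ] <- dlist[[1]]
    term <- w
    for (k in 1:mo) {
      out <- out + term * matrix(dlist[[k + 1]] / factorial(k), B$n, m, byrow = TRUE)
      if (k < mo) term <- jmul(B, term, w)
    }
    out
  } else {
    w <- u; w[1] <- 0
    out <- numeric(B$n); out[1] <- dlist[[1]]
    term <- w
    for (k in 1:mo) {
      out <- out + term * (dlist[[k + 1]] / factorial(k))
      if (k < mo) term <- jmul(B, term, w)
    }
    out
  }
}

.jval <- function(u) if (is.matrix(u)) u[1, ] else u[1]

jinv <- function(B, u) {
  x <- .jval(u)
  jet_compose(B, u, list(1 / x, -1 / x^2, 2 / x^3, -6 / x^4))
}

jdiv <- function(B, a, b) jmul(B, a, jinv(B, b))

jsqrt <- function(B, u) {
  x <- .jval(u)
  s <- sqrt(x)
  jet_compose(B, u, list(s, 0.5 / s, -0.25 / (s * x), 0.375 / (s * x^2)))
}

# u^(-1/2), the workhorse of the damped Coulomb interactions
jinvsqrt <- function(B, u) {
  x <- .jval(u)
  s <- 1 / sqrt(x)
  jet_compose(B, u, list(s, -0.5 * s / x, 0.75 * s / x^2, -1.875 * s / x^3))
}

jexp <- function(B, u) {
  e <- exp(.jval(u))
  jet_compose(B, u, list(e, e, e, e))
}

jlog <- function(B, u) {
  x <- .jval(u)
  jet_compose(B, u, list(log(x), 1 / x, -1 / x^2, 2 / x^3))
}

# real power u^r for positive base
jpowr <- function(B, u, r) {
  x <- .jval(u)
  jet_compose(B, u, list(x^r, r * x^(r - 1), r * (r - 1) * x^(r - 2),
                         r * (r - 1) * (r - 2) * x^(r - 3)))
}

# small non-negative integer power
jpow <- function(B, u, k) {
  if (k == 0L) return(if (is.matrix(u)) matrix(jet_const(B, 1), B$n, ncol(u)) else jet_const(B, 1))
  out <- u
  if (k > 1L) for (i in 2:k) out <- jmul(B, out, u)
  out
}

# extract the derivative d^|e| f / prod(dvar^e) from a jet
jet_deriv <- function(B, u, ...) {
  s <- jet_slot(B, ...)
  if (is.na(s)) stop("derivative not tracked by this jet basis")
  f <- B$fact[s]
  if (is.matrix(u)) u[s, ] * f else u[s] * f
}

# jet matrix product: A is [n x (p*q)] column-major blocks? Use explicit
# 3-d arrays: A [n, p, q], Bm [n, q, r] -> [n, p, r]
# jet matrix product; `rot` declares that one factor is supported on the
# Cartesian-only slots (a rotation), enabling the restricted product table
jmm <- function(B, A, Bm, rot = c("none", "left", "right")) {
  rot <- match.arg(rot)
  p <- dim(A)[2]; q <- dim(A)[3]; r <- dim(Bm)[3]
  if (B$n == 1L)
    return(array(matrix(A[1, , ], p, q) %*% matrix(Bm[1, , ], q, r),
                 c(1L, p, r)))
  out <- array(0, c(B$n, p, r))
  for (k in seq_len(q)) {
    Ak <- matrix(A[, , k], B$n, p)
    Bk <- matrix(Bm[, k, ], B$n, r)
    left <- Ak[, rep(seq_len(p), times = r), drop = FALSE]
    right <- Bk[, rep(seq_len(r), each = p), drop = FALSE]
    prod <- switch(rot,
                   none = jmul(B, left, right),
                   left = jmul_rot(B, right, left),
                   right = jmul_rot(B, left, right))
    out <- out + array(prod, c(B$n, p, r))
  }
  out
}
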