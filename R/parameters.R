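# Optimizable MNDO parameters: domain types, the flattened 37-vector index
# map, and plain-text parameter file I/O.

.param_fields <- c("alpha", "beta_s", "beta_p", "u_ss", "u_pp",
                   "zeta_s", "zeta_p", "e_isol")
.h_fields <- c("alpha", "beta_s", "u_ss", "zeta_s", "e_isol")

.fields_for <- function(element) {
  if (element == "H") .h_fields else .param_fields
}

#' Per-element optimizable MNDO parameters
#'
#' Bundles the optimizable parameters of one element.  Hydrogen carries no
#' p-type fields (`beta_p`, `u_pp`, `zeta_p` must be absent / NULL).
#'
#' @param element Element symbol ("H", "C", "N", "O" or "F").
#' @param alpha Core-repulsion exponent (Angstrom^-1).
#' @param beta_s,beta_p Resonance parameters (eV).
#' @param u_ss,u_pp One-center one-electron energies (eV).
#' @param zeta_s,zeta_p Slater orbital exponents (bohr^-1).
#' @param e_isol Isolated-atom electronic energy (eV).
#' @return An object of class `element_params`.
#' @export
element_params <- function(element, alpha, beta_s, u_ss, zeta_s, e_isol,
                           beta_p = NULL, u_pp = NULL, zeta_p = NULL) {
  if (!element %in% .elements)
    stop("unsupported element: ", element)
  if (element == "H") {
    if (!is.null(beta_p) || !is.null(u_pp) || !is.null(zeta_p))
      stop("hydrogen carries no p-type parameters")
  } else {
    if (is.null(beta_p) || is.null(u_pp) || is.null(zeta_p))
      stop(element, ": beta_p, u_pp and zeta_p are mandatory")
  }
  if (zeta_s <= 0) stop(element, ": zeta_s must be positive")
  if (!is.null(zeta_p) && zeta_p <= 0) stop(element, ": zeta_p must be positive")
  obj <- list(element = element, alpha = alpha, beta_s = beta_s,
              beta_p = beta_p, u_ss = u_ss, u_pp = u_pp,
              zeta_s = zeta_s, zeta_p = zeta_p, e_isol = e_isol,
              const = element_constants(element))
  class(obj) <- "element_params"
  obj
}

#' Parameter set for a collection of elements
#'
#' @param ... `element_params` objects (or a single list of them).
#' @return An object of class `parameter_set`: a named list of
#'   `element_params` in canonical element order (H, C, N, O, F subset).
#' @export
parameter_set <- function(...) {
  eps <- list(...)
  if (length(eps) == 1L && !inherits(eps[[1]], "element_params"))
    eps <- eps[[1]]
  names(eps) <- vapply(eps, function(e) e$element, "")
  ord <- intersect(.elements, names(eps))
  if (anyDuplicated(names(eps))) stop("duplicate element in parameter set")
  pset <- eps[ord]
  class(pset) <- "parameter_set"
  pset
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("MNDO parameter set:", paste(names(x), collapse = " "),
      sprintf("(%d optimizable parameters)\n", length(flatten_parameters(x)$p)))
  invisible(x)
}

#' Flatten a parameter set into the optimization vector
#'
#' The ordering is element-major (H, C, N, O, F) and field-major within an
#' element (alpha, beta_s, beta_p, u_ss, u_pp, zeta_s, zeta_p, e_isol),
#' skipping fields hydrogen does not carry.  The full CHNOF set flattens to
#' a vector of length 37.
#'
#' @param pset A `parameter_set`.
#' @return A list with `p` (named numeric vector) and `index` (data.frame
#'   with columns `element`, `field`).
#' @export
flatten_parameters <- function(pset) {
  stopifnot(inherits(pset, "parameter_set"))
  elems <- character(0); fields <- character(0); vals <- numeric(0)
  for (el in names(pset)) {
    ep <- pset[[el]]
    for (f in .fields_for(el)) {
      v <- ep[[f]]
      if (is.null(v)) stop(el, ": missing mandatory field ", f)
      elems <- c(elems, el); fields <- c(fields, f); vals <- c(vals, v)
    }
  }
  names(vals) <- paste(elems, fields, sep = ".")
  list(p = vals, index = data.frame(element = elems, field = fields,
                                    stringsAsFactors = FALSE))
}

#' Rebuild a parameter set from a flattened vector
#'
#' Inverse of [flatten_parameters()]: `unflatten_parameters(flatten(p)$p, pset)`
#' reproduces `pset` bit-exactly.
#'
#' @param p Numeric vector in the canonical flattened order.
#' @param template A `parameter_set` providing element coverage and the fixed
#'   constants.
#' @return A `parameter_set`.
#' @export
unflatten_parameters <- function(p, template) {
  idx <- flatten_parameters(template)$index
  if (length(p) != nrow(idx))
    stop("parameter vector has length ", length(p), ", expected ", nrow(idx))
  out <- template
  for (k in seq_len(nrow(idx)))
    out[[idx$element[k]]][[idx$field[k]]] <- p[[k]]
  out
}

#' Read a parameter file
#'
#' The format is plain text, one value per line: `ELEMENT KEY VALUE`
#' (e.g. `C alpha 2.660499`), `#` starts a comment.  Keys are
#' alpha, beta_s, beta_p, u_ss, u_pp, zeta_s, zeta_p, e_isol.
#'
#' @param path Path to the file.
#' @return A `parameter_set`.
#' @export
read_parameter_file <- function(path) {
  lines <- readLines(path)
  store <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(ln))) next
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(tok) != 3L)
      stop(sprintf("%s:%d: expected 'ELEMENT KEY VALUE', got '%s'", path, i, lines[i]))
    el <- tok[1]; key <- tolower(tok[2]); val <- suppressWarnings(as.numeric(tok[3]))
    if (!el %in% .elements)
      stop(sprintf("%s:%d: unknown element '%s'", path, i, el))
    if (!key %in% .param_fields)
      stop(sprintf("%s:%d: unknown key '%s'", path, i, key))
    if (is.na(val))
      stop(sprintf("%s:%d: bad numeric value '%s'", path, i, tok[3]))
    if (is.null(store[[el]])) store[[el]] <- list()
    store[[el]][[key]] <- val
  }
  eps <- lapply(names(store), function(el) {
    do.call(element_params, c(list(element = el), store[[el]]))
  })
  parameter_set(eps)
}

#' Write a parameter file
#'
#' @param pset A `parameter_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameter_file <- function(pset, path) {
  stopifnot(inherits(pset, "parameter_set"))
  lines <- character(0)
  for (el in names(pset)) {
    for (f in .fields_for(el)) {
      v <- pset[[el]][[f]]
      lines <- c(lines, sprintf("%s %s %.10g", el, f, v))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Packaged parameter sets
#'
#' Loads one of the parameter sets shipped with the package: the original
#' MNDO parameters (`"mndo"`), the PDDG/MNDO (`"pddg"`) and NO-MNDO
#' (`"nomndo"`) values used as alternative optimization starting points
#' (NO-MNDO covers C, H, N, O; fluorine falls back to original MNDO), or
#' the reparameterized end point of the trust-region optimization
#' (`"opt"`).
#'
#' @param which One of "mndo", "pddg", "nomndo", "opt".
#' @return A `parameter_set` covering H, C, N, O, F.
#' @export
load_parameter_fixture <- function(which = c("mndo", "pddg", "nomndo", "opt")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("params_", which, ".par"),
                      package = "mndopt")
  if (!nzchar(path)) stop("packaged parameter file not found")
  read_parameter_file(path)
}
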