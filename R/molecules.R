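# Molecules and training entries, plus the block-format training-set reader.

#' Construct a molecule
#'
#' @param elements Character vector of element symbols (H, C, N, O, F).
#' @param coords Numeric matrix (n x 3) of Cartesian coordinates in Angstrom.
#' @param charge Net charge (integer).
#' @param mult Spin multiplicity (2S+1).
#' @param name Optional identifier.
#' @return An object of class `molecule`.
#' @export
molecule <- function(elements, coords, charge = 0L, mult = 1L, name = "mol") {
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (length(elements) != nrow(coords))
    stop("elements and coords disagree in length")
  bad <- setdiff(unique(elements), .elements)
  if (length(bad))
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  zsum <- sum(.core_charge[elements])
  nel <- zsum - charge
  if (nel < 1) stop("molecule has no electrons")
  if ((nel - (mult - 1)) %% 2 != 0)
    stop("electron count ", nel, " incompatible with multiplicity ", mult)
  if (mult < 1 || mult - 1 > nel)
    stop("invalid multiplicity")
  structure(list(elements = elements, coords = coords,
                 charge = as.integer(charge), mult = as.integer(mult),
                 n_electrons = as.integer(nel), name = name),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule %s: %s, charge %d, mult %d>\n", x$name,
              paste(x$elements, collapse = ""), x$charge, x$mult))
  invisible(x)
}

#' Default objective weighting factors
#'
#' The weighting factors C for the four reference properties of the error
#' function: 1 (kcal/mol)^-1 for the heat of formation, 10 eV^-1 for the
#' ionization energy, 20 D^-1 for the dipole magnitude and
#' 0.5 mol bohr/kcal for the gradient norm at a reference geometry.
#'
#' @return Named numeric vector with entries hf, ie, dip, geo.
#' @export
default_weights <- function() c(hf = 1, ie = 10, dip = 20, geo = 0.5)

#' Construct a training entry
#'
#' Pairs a molecule with reference data.  At least one reference must be
#' present.  The geometry flag adds a term with the gradient norm |g| as the
#' property and 0 as its reference value.
#'
#' @param mol A `molecule`.
#' @param hf Reference heat of formation (kcal/mol) or NA.
#' @param ie Reference ionization energy (eV) or NA.
#' @param dip Reference dipole magnitude (D) or NA.
#' @param geo Logical: include the gradient-norm (reference-geometry) term.
#' @param weights Named vector overriding [default_weights()] entries.
#' @return An object of class `training_entry`.
#' @export
training_entry <- function(mol, hf = NA_real_, ie = NA_real_, dip = NA_real_,
                           geo = FALSE, weights = NULL) {
  stopifnot(inherits(mol, "molecule"))
  if (is.na(hf) && is.na(ie) && is.na(dip) && !geo)
    stop(mol$name, ": training entry carries no reference data")
  w <- default_weights()
  if (!is.null(weights)) {
    if (any(weights <= 0)) stop("weights must be positive")
    w[names(weights)] <- weights
  }
  if (!is.na(dip) && mol$mult != 1L)
    stop(mol$name, ": dipole references require a closed-shell (RHF) entry")
  structure(list(mol = mol, hf = hf, ie = ie, dip = dip, geo = geo,
                 weights = w),
            class = "training_entry")
}

#' Read a training-set file
#'
#' The file is a sequence of blocks:
#' \preformatted{
#' [molecule] name=h2o charge=0 mult=1
#' O  0.0000  0.0000  0.1173
#' H  0.0000  0.7572 -0.4692
#' H  0.0000 -0.7572 -0.4692
#' [ref] hf=-57.80 ie=12.2 dip=2.10 geo=1
#' [weights] hf=1 ie=10
#' }
#' with any subset of hf/ie/dip in the `[ref]` line and an optional
#' `[weights]` override.  `#` starts a comment.
#'
#' @param path Path to the file.
#' @return A list of `training_entry` objects.
#' @export
read_training_set <- function(path) {
  lines <- readLines(path)
  entries <- list()
  cur <- NULL
  flush_entry <- function(cur) {
    if (is.null(cur)) return(NULL)
    if (length(cur$elements) == 0L)
      stop(cur$name, ": molecule block has no atoms")
    mol <- molecule(cur$elements, do.call(rbind, cur$coords),
                    charge = cur$charge, mult = cur$mult, name = cur$name)
    training_entry(mol, hf = cur$hf, ie = cur$ie, dip = cur$dip,
                   geo = cur$geo, weights = cur$weights)
  }
  parse_kv <- function(tokens, lineno) {
    kv <- list()
    for (tok in tokens) {
      parts <- strsplit(tok, "=", fixed = TRUE)[[1]]
      if (length(parts) != 2L)
        stop(sprintf("%s:%d: malformed key=value '%s'", path, lineno, tok))
      kv[[parts[1]]] <- parts[2]
    }
    kv
  }
  for (i in seq_along(lines)) {
    ln <- trimws(sub("#.*$", "", lines[i]))
    if (!nzchar(ln)) next
    if (startsWith(ln, "[molecule]")) {
      if (!is.null(cur)) entries[[length(entries) + 1L]] <- flush_entry(cur)
      kv <- parse_kv(strsplit(ln, "[[:space:]]+")[[1]][-1], i)
      cur <- list(name = if (is.null(kv$name)) sprintf("mol%d", length(entries) + 1L) else kv$name,
                  charge = if (is.null(kv$charge)) 0L else as.integer(kv$charge),
                  mult = if (is.null(kv$mult)) 1L else as.integer(kv$mult),
                  elements = character(0), coords = list(),
                  hf = NA_real_, ie = NA_real_, dip = NA_real_, geo = FALSE,
                  weights = NULL)
    } else if (startsWith(ln, "[ref]")) {
      if (is.null(cur)) stop(sprintf("%s:%d: [ref] before [molecule]", path, i))
      kv <- parse_kv(strsplit(ln, "[[:space:]]+")[[1]][-1], i)
      if (!is.null(kv$hf)) cur$hf <- as.numeric(kv$hf)
      if (!is.null(kv$ie)) cur$ie <- as.numeric(kv$ie)
      if (!is.null(kv$dip)) cur$dip <- as.numeric(kv$dip)
      if (!is.null(kv$geo)) cur$geo <- as.integer(kv$geo) != 0L
    } else if (startsWith(ln, "[weights]")) {
      if (is.null(cur)) stop(sprintf("%s:%d: [weights] before [molecule]", path, i))
      kv <- parse_kv(strsplit(ln, "[[:space:]]+")[[1]][-1], i)
      cur$weights <- vapply(kv, as.numeric, 0)
    } else {
      if (is.null(cur)) stop(sprintf("%s:%d: atom line before [molecule]", path, i))
      tok <- strsplit(ln, "[[:space:]]+")[[1]]
      if (length(tok) != 4L)
        stop(sprintf("%s:%d: expected 'element x y z', got '%s'", path, i, ln))
      xyz <- suppressWarnings(as.numeric(tok[2:4]))
      if (anyNA(xyz))
        stop(sprintf("%s:%d: bad coordinates in '%s'", path, i, ln))
      cur$elements <- c(cur$elements, tok[1])
      cur$coords[[length(cur$coords) + 1L]] <- xyz
    }
  }
  if (!is.null(cur)) entries[[length(entries) + 1L]] <- flush_entry(cur)
  if (length(entries) == 0L) stop(path, ": empty training set")
  entries
}

#' Write a training-set file
#'
#' @param entries List of `training_entry` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_training_set <- function(entries, path) {
  lines <- character(0)
  for (e in entries) {
    m <- e$mol
    lines <- c(lines, sprintf("[molecule] name=%s charge=%d mult=%d",
                              m$name, m$charge, m$mult))
    for (a in seq_along(m$elements))
      lines <- c(lines, sprintf("%s % .10f % .10f % .10f", m$elements[a],
                                m$coords[a, 1], m$coords[a, 2], m$coords[a, 3]))
    refs <- character(0)
    if (!is.na(e$hf)) refs <- c(refs, sprintf("hf=%.8f", e$hf))
    if (!is.na(e$ie)) refs <- c(refs, sprintf("ie=%.8f", e$ie))
    if (!is.na(e$dip)) refs <- c(refs, sprintf("dip=%.8f", e$dip))
    refs <- c(refs, sprintf("geo=%d", as.integer(e$geo)))
    lines <- c(lines, paste("[ref]", paste(refs, collapse = " ")))
    wd <- default_weights()
    if (any(e$weights != wd)) {
      ww <- e$weights[e$weights != wd]
      lines <- c(lines, paste("[weights]",
                              paste(sprintf("%s=%g", names(ww), ww), collapse = " ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
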