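# Fixture molecules and the synthetic reference-data generator.
#
# The fixture library holds small CHNOF molecules at literature-style
# geometries.  Synthetic training sets pair these molecules (optionally
# distorted copies) with reference properties computed by the engine itself
# at a known parameter vector p*, so that the objective has a known global
# minimum S = 0 at p* and closed-loop parameter recovery can be tested
# without external data.

.deg <- pi / 180

.fixture_library <- function() {
  mk <- molecule
  lib <- list()
  diat <- function(e1, e2, R, name, mult = 1L)
    mk(c(e1, e2), rbind(c(0, 0, 0), c(0, 0, R)), mult = mult, name = name)
  lib$h2 <- diat("H", "H", 0.741, "h2")
  lib$hf <- diat("F", "H", 0.917, "hf")
  lib$n2 <- diat("N", "N", 1.098, "n2")
  lib$f2 <- diat("F", "F", 1.412, "f2")
  lib$co <- diat("C", "O", 1.128, "co")
  bent <- function(e1, e2, R, ang, name) {
    a <- ang * .deg / 2
    mk(c(e1, e2, e2), rbind(c(0, 0, 0),
                            c(R * sin(a), 0, R * cos(a)),
                            c(-R * sin(a), 0, R * cos(a))), name = name)
  }
  lib$h2o <- bent("O", "H", 0.9572, 104.52, "h2o")
  lib$of2 <- bent("O", "F", 1.405, 103.1, "of2")
  pyramid <- function(e1, e2, R, ang, name) {
    # ang = X-E-X angle
    ca <- cos(ang * .deg)
    z <- R * sqrt((1 + 2 * ca) / 3)
    rh <- sqrt(max(R^2 - z^2, 0))
    mk(c(e1, rep(e2, 3)),
       rbind(c(0, 0, 0),
             t(sapply(0:2, function(k)
               c(rh * cos(2 * pi * k / 3), rh * sin(2 * pi * k / 3), z)))),
       name = name)
  }
  lib$nh3 <- pyramid("N", "H", 1.012, 106.7, "nh3")
  lib$nf3 <- pyramid("N", "F", 1.365, 102.4, "nf3")
  tetra <- function(e1, e2, R, name) {
    a <- R / sqrt(3)
    mk(c(e1, rep(e2, 4)),
       rbind(c(0, 0, 0), c(a, a, a), c(a, -a, -a), c(-a, a, -a), c(-a, -a, a)),
       name = name)
  }
  lib$ch4 <- tetra("C", "H", 1.087, "ch4")
  lib$cf4 <- tetra("C", "F", 1.320, "cf4")
  lib$co2 <- mk(c("O", "C", "O"),
                rbind(c(0, 0, -1.162), c(0, 0, 0), c(0, 0, 1.162)),
                name = "co2")
  lib$hcn <- mk(c("H", "C", "N"),
                rbind(c(0, 0, -1.064), c(0, 0, 0), c(0, 0, 1.156)),
                name = "hcn")
  lib$fcn <- mk(c("F", "C", "N"),
                rbind(c(0, 0, -1.262), c(0, 0, 0), c(0, 0, 1.159)),
                name = "fcn")
  lib$n2o <- mk(c("N", "N", "O"),
                rbind(c(0, 0, -1.128), c(0, 0, 0), c(0, 0, 1.184)),
                name = "n2o")
  lib$c2h2 <- mk(c("C", "C", "H", "H"),
                 rbind(c(0, 0, 0), c(0, 0, 1.203),
                       c(0, 0, -1.063), c(0, 0, 2.266)), name = "c2h2")
  # ethylene, planar
  ang <- 121.2 * .deg; rch <- 1.086
  lib$c2h4 <- mk(c("C", "C", "H", "H", "H", "H"),
                 rbind(c(0, 0, 0), c(0, 0, 1.339),
                       c(rch * sin(ang), 0, rch * cos(ang)),
                       c(-rch * sin(ang), 0, rch * cos(ang)),
                       c(rch * sin(ang), 0, 1.339 - rch * cos(ang)),
                       c(-rch * sin(ang), 0, 1.339 - rch * cos(ang))),
                 name = "c2h4")
  # ethane, staggered
  rcc <- 1.536; rch <- 1.091; hcc <- 110.9 * .deg
  zh <- rch * cos(hcc); rh <- rch * sin(hcc)
  lib$c2h6 <- mk(c("C", "C", rep("H", 6)),
                 rbind(c(0, 0, 0), c(0, 0, rcc),
                       t(sapply(0:2, function(k)
                         c(rh * cos(2 * pi * k / 3), rh * sin(2 * pi * k / 3), zh))),
                       t(sapply(0:2, function(k)
                         c(rh * cos(2 * pi * k / 3 + pi / 3),
                           rh * sin(2 * pi * k / 3 + pi / 3), rcc - zh)))),
                 name = "c2h6")
  # formaldehyde
  a <- 116.5 * .deg / 2; rch <- 1.116
  lib$ch2o <- mk(c("C", "O", "H", "H"),
                 rbind(c(0, 0, 0), c(0, 0, 1.208),
                       c(rch * sin(a), 0, -rch * cos(a)),
                       c(-rch * sin(a), 0, -rch * cos(a))), name = "ch2o")
  # methyl fluoride (C3v)
  rcf <- 1.383; rch <- 1.087; fch <- 108.8 * .deg
  zh <- rch * cos(fch)  # H z relative to C (F on +z)
  rh <- rch * sin(fch)
  lib$ch3f <- mk(c("C", "F", rep("H", 3)),
                 rbind(c(0, 0, 0), c(0, 0, rcf),
                       t(sapply(0:2, function(k)
                         c(rh * cos(2 * pi * k / 3), rh * sin(2 * pi * k / 3), zh)))),
                 name = "ch3f")
  # difluoromethane (C2v, approximate)
  rcf <- 1.357; rch <- 1.093
  af <- 108.3 * .deg / 2; ah <- 113.7 * .deg / 2
  lib$ch2f2 <- mk(c("C", "F", "F", "H", "H"),
                  rbind(c(0, 0, 0),
                        c(rcf * sin(af), 0, rcf * cos(af)),
                        c(-rcf * sin(af), 0, rcf * cos(af)),
                        c(0, rch * sin(ah), -rch * cos(ah)),
                        c(0, -rch * sin(ah), -rch * cos(ah))), name = "ch2f2")
  # hydrogen peroxide (gauche)
  roo <- 1.475; roh <- 0.950; aooh <- 94.8 * .deg; dih <- 111.5 * .deg
  h1 <- c(roh * sin(aooh), 0, roh * cos(aooh))
  h2 <- c(roh * sin(aooh) * cos(dih), roh * sin(aooh) * sin(dih),
          roo - roh * cos(aooh))
  lib$h2o2 <- mk(c("O", "O", "H", "H"),
                 rbind(c(0, 0, 0), c(0, 0, roo), h1, h2), name = "h2o2")
  # hydrazine (gauche, approximate)
  rnn <- 1.449; rnh <- 1.021; annh <- 112 * .deg
  hz <- rnh * cos(annh); hr <- rnh * sin(annh)
  lib$n2h4 <- mk(c("N", "N", rep("H", 4)),
                 rbind(c(0, 0, 0), c(0, 0, rnn),
                       c(hr * cos(0.4), hr * sin(0.4), hz),
                       c(hr * cos(2.3), hr * sin(2.3), hz),
                       c(hr * cos(pi + 0.4), -hr * sin(pi + 0.4), rnn - hz),
                       c(hr * cos(pi + 2.3), -hr * sin(pi + 2.3), rnn - hz)),
                 name = "n2h4")
  # methanol (staggered, approximate)
  rco <- 1.427; roh <- 0.956; aCOH <- 108.5 * .deg
  rch <- 1.094; aOCH <- 109.5 * .deg
  hz <- rch * cos(aOCH); hr <- rch * sin(aOCH)
  lib$ch3oh <- mk(c("C", "O", "H", "H", "H", "H"),
                  rbind(c(0, 0, 0), c(0, 0, rco),
                        c(roh * sin(aCOH), 0, rco - roh * cos(aCOH)),
                        t(sapply(0:2, function(k)
                          c(hr * cos(2 * pi * k / 3 + pi), hr * sin(2 * pi * k / 3 + pi), hz)))),
                  name = "ch3oh")
  # methylamine (approximate)
  rcn <- 1.471; rnh <- 1.010; rch <- 1.093
  hz <- rch * cos(109.5 * .deg); hr <- rch * sin(109.5 * .deg)
  lib$ch3nh2 <- mk(c("C", "N", "H", "H", "H", "H", "H"),
                   rbind(c(0, 0, 0), c(0, 0, rcn),
                         t(sapply(0:2, function(k)
                           c(hr * cos(2 * pi * k / 3), hr * sin(2 * pi * k / 3), hz))),
                         c(rnh * sin(112 * .deg) * cos(pi / 3),
                           rnh * sin(112 * .deg) * sin(pi / 3),
                           rcn - rnh * cos(112 * .deg)),
                         c(rnh * sin(112 * .deg) * cos(-pi / 3),
                           rnh * sin(112 * .deg) * sin(-pi / 3),
                           rcn - rnh * cos(112 * .deg))), name = "ch3nh2")
  # hypofluorous acid
  aof <- 97.2 * .deg
  lib$hof <- mk(c("O", "F", "H"),
                rbind(c(0, 0, 0), c(0, 0, 1.442),
                      c(0.960 * sin(aof), 0, 0.960 * cos(aof))), name = "hof")
  # radicals (UHF doublets)
  lib$oh <- diat("O", "H", 0.970, "oh", mult = 2L)
  lib$ch3 <- mk(c("C", "H", "H", "H"),
                rbind(c(0, 0, 0),
                      t(sapply(0:2, function(k)
                        c(1.079 * cos(2 * pi * k / 3), 1.079 * sin(2 * pi * k / 3), 0)))),
                mult = 2L, name = "ch3")
  anh <- 103.4 * .deg / 2
  lib$nh2 <- mk(c("N", "H", "H"),
                rbind(c(0, 0, 0),
                      c(1.024 * sin(anh), 0, 1.024 * cos(anh)),
                      c(-1.024 * sin(anh), 0, 1.024 * cos(anh))),
                mult = 2L, name = "nh2")
  lib
}

#' Fixture molecule library
#'
#' Small CHNOF molecules (plus a few open-shell radicals) at
#' literature-style geometries, used to build synthetic training sets.
#'
#' @return Named list of `molecule` objects.
#' @export
fixture_molecules <- function() .fixture_library()

#' Build a deterministic fixture suite
#'
#' Selects `n` molecules from the fixture library in a fixed order; when
#' `n` exceeds the library size, additional entries are geometrically
#' distorted copies (Gaussian displacements, deterministic under `seed`).
#'
#' @param n Number of molecules.
#' @param seed Seed for distorted copies.
#' @param distort_sd Displacement standard deviation (Angstrom) for copies.
#' @param closed_shell_only Drop open-shell library members.
#' @param max_atoms Keep only library members with at most this many atoms.
#' @return List of `molecule` objects.
#' @export
make_fixture_suite <- function(n = 25L, seed = 1L, distort_sd = 0.04,
                               closed_shell_only = FALSE,
                               max_atoms = Inf) {
  lib <- .fixture_library()
  # OH and CH3 carry symmetry-degenerate partially occupied shells whose
  # parameter response is singular; they stay in the library for SCF-level
  # work but are excluded from derivative-driven training suites
  lib <- lib[setdiff(names(lib), c("oh", "ch3"))]
  if (closed_shell_only) lib <- Filter(function(m) m$mult == 1L, lib)
  lib <- Filter(function(m) length(m$elements) <= max_atoms, lib)
  base <- unname(lib)
  out <- list()
  set.seed(seed)
  i <- 0L
  while (length(out) < n) {
    i <- i + 1L
    m <- base[[((i - 1L) %% length(base)) + 1L]]
    if (i > length(base)) {
      dd <- matrix(stats::rnorm(length(m$coords), sd = distort_sd),
                   nrow(m$coords), 3)
      m <- molecule(m$elements, m$coords + dd, charge = m$charge,
                    mult = m$mult,
                    name = sprintf("%s_d%d", m$name, (i - 1L) %/% length(base)))
    }
    out[[length(out) + 1L]] <- m
  }
  out
}

#' Generate synthetic reference data at a known parameter vector
#'
#' Computes the reference properties of each molecule with the engine
#' itself at `pset_star`, optionally perturbed by Gaussian noise, and
#' returns training entries.  With zero noise the objective surface has a
#' global minimum S = 0 at `pset_star`.
#'
#' @param mols List of `molecule` objects.
#' @param pset_star The generating `parameter_set`.
#' @param noise Named vector of noise standard deviations for `hf`
#'   (kcal/mol), `ie` (eV), `dip` (D); zero entries add no noise.
#' @param seed Random seed for the noise.
#' @param geo Set the reference-geometry (gradient-norm) flag on each entry.
#' @param props Character subset of c("hf","ie","dip") to reference.
#' @return List of `training_entry` objects.
#' @export
generate_reference_data <- function(mols, pset_star,
                                    noise = c(hf = 0, ie = 0, dip = 0),
                                    seed = 1L, geo = TRUE,
                                    props = c("hf", "ie", "dip")) {
  set.seed(seed)
  nz <- c(hf = 0, ie = 0, dip = 0)
  nz[names(noise)] <- noise
  exact <- all(nz == 0)
  entries <- list()
  for (m in mols) {
    vals <- tryCatch(molecule_properties(m, pset_star, geo = FALSE),
                     error = function(e) e)
    if (inherits(vals, "error")) {
      if (exact) stop("reference generation failed for '", m$name, "': ",
                      conditionMessage(vals))
      warning("dropping '", m$name, "': ", conditionMessage(vals))
      next
    }
    hf <- if ("hf" %in% props) vals$hf + stats::rnorm(1, 0, nz[["hf"]]) else NA_real_
    ie <- if ("ie" %in% props) vals$ie + stats::rnorm(1, 0, nz[["ie"]]) else NA_real_
    dip <- if ("dip" %in% props && m$mult == 1L)
      vals$dip + stats::rnorm(1, 0, nz[["dip"]]) else NA_real_
    entries[[length(entries) + 1L]] <-
      training_entry(m, hf = hf, ie = ie, dip = dip, geo = geo)
  }
  if (length(entries) == 0L) stop("no usable molecules")
  entries
}
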