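# Physical constants and fixed per-element MNDO configuration data.
#
# Unit conventions used throughout the package:
#   lengths      Angstrom (coordinates, multipole distances after conversion)
#   energies     eV internally; heats of formation reported in kcal/mol
#   zeta         bohr^-1 (Slater exponents)
#   alpha        Angstrom^-1 (core-repulsion exponents)
#   dipoles      Debye
#   gradients    kcal mol^-1 bohr^-1

#' Unit conversion constants
#'
#' @format A list with elements:
#' \describe{
#'   \item{bohr}{Bohr radius in Angstrom (0.52917721).}
#'   \item{kcal_per_ev}{kcal/mol per eV (23.060548).}
#'   \item{e2}{Electrostatic coupling e^2 in eV * Angstrom (14.399645).}
#'   \item{debye_per_eA}{Debye per unit charge * Angstrom (4.8032045).}
#' }
#' @export
mndo_units <- list(
  bohr         = 0.52917721,
  kcal_per_ev  = 23.060548,
  e2           = 14.399645,
  debye_per_eA = 4.8032045
)

# Supported elements, their core charges, valence basis sizes and masses.
.elements <- c("H", "C", "N", "O", "F")
.core_charge <- c(H = 1, C = 4, N = 5, O = 6, F = 7)
.n_basis_elem <- c(H = 1L, C = 4L, N = 4L, O = 4L, F = 4L)
.atomic_mass <- c(H = 1.00794, C = 12.011, N = 14.007, O = 15.999, F = 18.998403)
.principal_n <- c(H = 1L, C = 2L, N = 2L, O = 2L, F = 2L)

# Fixed one-center two-electron integrals (eV) and experimental atomic heats
# of formation (kcal/mol).  These are configuration constants of the MNDO
# formalism, not optimizable parameters.
.one_center <- list(
  H = list(g_ss = 12.848, g_sp = NA, g_pp = NA, g_p2 = NA, h_sp = NA),
  C = list(g_ss = 12.23, g_sp = 11.47, g_pp = 11.08, g_p2 = 9.84, h_sp = 2.43),
  N = list(g_ss = 13.59, g_sp = 12.66, g_pp = 12.98, g_p2 = 11.59, h_sp = 3.14),
  O = list(g_ss = 15.42, g_sp = 14.48, g_pp = 14.52, g_p2 = 12.98, h_sp = 3.94),
  F = list(g_ss = 16.92, g_sp = 17.25, g_pp = 16.71, g_p2 = 14.91, h_sp = 4.83)
)

.atomic_hof <- c(H = 52.102, C = 170.89, N = 113.0, O = 59.559, F = 18.86)

#' Fixed per-element configuration constants
#'
#' One-center two-electron integrals (eV) and the experimental atomic heat of
#' formation (kcal/mol) for a supported element.  These quantities are fixed
#' in the MNDO formalism and are excluded from the optimizable parameter
#' vector.
#'
#' @param element Element symbol, one of "H", "C", "N", "O", "F".
#' @return A list with entries `g_ss`, `g_sp`, `g_pp`, `g_p2`, `h_sp`
#'   (eV; p-type entries are `NA` for hydrogen), `hof_atom` (kcal/mol),
#'   `z` (core charge), `nbasis`, `mass` and `n` (principal quantum number).
#' @export
element_constants <- function(element) {
  if (!element %in% .elements)
    stop("unsupported element: ", element)
  c(.one_center[[element]],
    list(hof_atom = .atomic_hof[[element]],
         z = .core_charge[[element]],
         nbasis = .n_basis_elem[[element]],
         mass = .atomic_mass[[element]],
         n = .principal_n[[element]]))
}
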