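Package: mndopt
Title: Semi-Empirical MNDO Engine with Analytic Parameter Derivatives
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained MNDO-class semi-empirical quantum chemistry
    engine (s,p basis, point-multipole two-electron model, exponential
    core-core repulsion) for the elements H, C, N, O and F, together with
    fully analytic first- and second-order derivatives of molecular
    properties (heat of formation, ionization energy, dipole moment,
    Cartesian gradient norm) with respect to the semi-empirical parameters,
    obtained by solving the first- and second-order coupled-perturbed
    Hartree-Fock equations in the orthogonalized NDDO basis.  On top of the
    derivative machinery the package provides the weighted least-squares
    parameterization objective, its exact 37x37 parameter Hessian, the
    Gram (PM7-style) approximant, an eigenvalue-rectified modified Hessian,
    and three parameter optimizers (approximated line search, trust-radius
    Hessian descent, trust-region).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, methods, Matrix
Suggests: testthat (>= 3.0.0), pracma, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
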