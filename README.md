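# mndopt

Semi-empirical quantum chemistry engines of the MNDO/NDDO family are
parameterized by minimizing a weighted least-squares error

    S = sum_a C_a^2 (xi_a_ref - xi_a)^2

over reference heats of formation (kcal/mol), ionization energies (eV),
dipole moments (D) and reference-geometry gradient norms
(kcal mol^-1 bohr^-1).  Doing this well requires first *and second*
derivatives of every property with respect to every semi-empirical
parameter — quantities that finite differences deliver unreliably.

`mndopt` is a self-contained R implementation, for the elements H, C, N,
O, F, of

- an MNDO-class electronic-structure engine (s,p Slater basis, NDDO
  point-multipole two-electron model, exponential core-core repulsion,
  RHF/UHF SCF in the orthogonalized basis);
- fully analytic first- and second-order parameter derivatives of the
  heat of formation, Koopmans ionization energy, dipole magnitude and
  Cartesian gradient norm, via first- and second-order coupled-perturbed
  Hartree-Fock response;
- the parameterization objective with its analytic 37-component gradient,
  exact 37x37 Hessian, the positive-semidefinite Gram approximant used by
  PM7-style schemes, and the eigenvalue-rectified "modified" Hessian;
- three parameter optimizers: approximated line search, trust-radius
  Hessian descent, and a trust-region scheme with spectral shift;
- a synthetic-data generator that produces training sets from the engine
  itself at known parameters, enabling closed-loop recovery experiments.

It is aimed at method developers studying parameterization procedures, not
at production thermochemistry.

## Worked example

```r
library(mndopt)

pset <- load_parameter_fixture("mndo")     # original MNDO parameters
h2o  <- fixture_molecules()$h2o
molecule_properties(h2o, pset, geo = TRUE)[c("hf", "ie", "dip", "gnorm")]
#> $hf     -60.59303     # kcal/mol, matches the published MNDO value -60.9
#> $ie      12.19201     # eV
#> $dip      1.790203    # D
#> $gnorm   19.53282     # kcal/(mol bohr) at the experimental geometry

# analytic derivatives of all properties w.r.t. all 37 parameters
entry <- training_entry(h2o, hf = -57.8, ie = 12.62, dip = 1.85, geo = TRUE)
pd <- property_derivatives(entry, pset, order = 2)
pd$hf$d1[c("O.zeta_p", "H.e_isol")]
#>  O.zeta_p  H.e_isol
#>  293.0453  -46.1211       # dHf/dE_isol(H) = -2 k_conv exactly

# closed-loop experiment: references generated at p*, start perturbed
mols    <- make_fixture_suite(8, seed = 3)
entries <- generate_reference_data(mols, pset, geo = TRUE)
p0   <- flatten_parameters(pset)$p
set.seed(1); start <- unflatten_parameters(p0 * runif(37, .99, 1.01), pset)
fit  <- optimize_parameters(entries, start, method = "tro", hessian = "abs",
                            R0 = 0.1, dmax = 2, maxiter = 50)
fit$S / evaluate_objective(entries, start)$S   # S drops by orders of magnitude
```

The engine reproduces the original published MNDO heats of formation,
ionization energies and dipole moments of small CHNOF molecules to about
1 kcal/mol / 0.1 eV / 0.05 D at comparable geometries, which is the
integration-level check that the integral model, SCF and property code are
assembled correctly.

A thin command-line wrapper is installed with the package
(`system.file("cli", "mndopt", package = "mndopt")`) with subcommands
`props`, `evaluate`, `gradient`, `hessian`, `fit`, `fdcheck` and
`make-fixtures` over the plain-text parameter and training-set formats
documented in `?read_parameter_file` and `?read_training_set`.

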