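# Shared fixtures: parameter sets, small molecules and FD conveniences.

mndo_pset <- load_parameter_fixture("mndo")

fix_h2 <- function() fixture_molecules()$h2
fix_h2o <- function() fixture_molecules()$h2o
fix_ch4 <- function() fixture_molecules()$ch4
fix_nh3 <- function() fixture_molecules()$nh3
fix_hf <- function() fixture_molecules()$hf

# water with a slightly distorted geometry (nonzero gradient, no symmetry)
fix_h2o_dist <- function() {
  ang <- 104.52 * pi / 180; r <- 0.9572
  molecule(c("O", "H", "H"),
           rbind(c(0, 0, 0),
                 c(r * sin(ang / 2), 0, r * cos(ang / 2) + 0.03),
                 c(-(r - 0.04) * sin(ang / 2), 0, (r - 0.04) * cos(ang / 2))),
           name = "h2o_dist")
}

# property evaluation as a function of the flattened parameter vector,
# used as the target of finite-difference oracles
props_fun <- function(mol, template, geo = FALSE) {
  function(pvec) {
    ps <- unflatten_parameters(pvec, template)
    v <- molecule_properties(mol, ps, geo = geo)
    c(hf = v$hf, ie = v$ie, dip = v$dip, gnorm = v$gnorm)
  }
}

rigid_rotation <- function(axis = c(0.3, -1, 0.5), angle = 0.83) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

rotate_molecule <- function(mol, Rm = rigid_rotation()) {
  molecule(mol$elements, mol$coords %*% t(Rm), charge = mol$charge,
           mult = mol$mult, name = paste0(mol$name, "_rot"))
}
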