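# shared fixtures: printed tissue coefficients and a small test-scale mesh
lib <- default_tissue_library()
mucosa <- lib$mucosa
cartilage <- lib$cartilage

# coarse mesh used by the simulation tests; the methods vignette documents
# the problem sizes used for testing versus analysis
test_mesh <- local({
  cache <- new.env(parent = emptyenv())
  function(diameter = 6) {
    key <- as.character(diameter)
    if (is.null(cache[[key]]))
      cache[[key]] <- build_trachea_mesh(trachea_config(
        diameter = diameter, n_arc = 8, n_chord = 4, n_wall = 1))
    cache[[key]]
  }
})

# incompressible-uniaxial equilibrium deformation gradient at finite kappa
uniaxial_equilibrium_F <- function(material, stretch) {
  lat <- stats::uniroot(function(s)
    cauchy_stress_tensor(material, diag(c(s, s, stretch)))[1, 1],
    c(0.4, 1.5), tol = 1e-12)$root
  diag(c(lat, lat, stretch))
}

rotation_z <- function(th) {
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}
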