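# shared fixtures: fictitious media and small scenes with closed-form answers

vacuum_mat <- function() fictitious_material(0)
absorber_mat <- function(mu = 0.5, density = 1) {
  fictitious_material(mu, photo_fraction = 1, density = density)
}
scatterer_mat <- function(mu = 0.5, density = 1) {
  fictitious_material(mu, photo_fraction = 0, density = density)
}
# a faintly interacting absorber used as a "transparent but scoring" medium
thin_mat <- function() fictitious_material(1e-9, photo_fraction = 1)

test_chamber <- function(wall = vacuum_mat(), cavity = thin_mat(),
                         ambient = vacuum_mat(), ...) {
  chamber_spec(2.899, 3.200, wall_material = wall, cavity_material = cavity,
               ambient_material = ambient, ...)
}
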