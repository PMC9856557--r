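# shared fixtures built in code

water_medium <- function(attenuation = 0.0022) {
  medium("water", 994.23, 1520.6, attenuation, 0.62, 4178)
}

tissue_medium <- function() {
  medium("tissue", 1090, 1600, 0.780, 0.49, 3421)
}

baseline_setting <- function(duty = 0.5, power = 8.40) {
  transducer_setting(1e6, 24e-3, 24.944e-9 * sqrt(power / 8.40), power, duty)
}

baseline_suspension <- function(zeta = -30.3e-3, temperature_C = 37.0) {
  gnp_suspension(3.7e-9, 2.5e-19, zeta, 0.4052, temperature_C)
}

# small reduced domain for fast solver tests (not a study configuration)
coarse_geometry <- function(...) {
  axisym_geometry(water_radius = 14e-3, standoff = 4e-3,
                  tissue_radius = 10e-3, tissue_height = 10e-3,
                  chamber_radius = 3e-3, chamber_height = 3e-3,
                  water_below = 4e-3, pml_thickness = 2e-3, ...)
}

coarse_grid <- function(ppw = 5) {
  build_grid(coarse_geometry(), 1520.6 / 1e6, ppw)
}

all_water_media <- function(attenuation = 0.0022) {
  w <- water_medium(attenuation)
  list(water = w, tissue = w, chamber = w)
}

baseline_media <- function() {
  list(water = water_medium(), tissue = tissue_medium(),
       chamber = water_medium())
}

# uniform synthetic intensity field on a grid (for heat-source tests)
uniform_intensity <- function(grid, I = 1e4, duty_folded = FALSE,
                              duty = NA_real_) {
  structure(list(I = matrix(I, grid$nr, grid$nz), grid = grid,
                 duty_folded = duty_folded, duty = duty, frequency = 1e6),
            class = "intensity_field")
}
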