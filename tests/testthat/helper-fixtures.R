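# Reference parameter set used across tests: the measured bottom leaf of
# the template weed and the literature elastic modulus.

paper_leaf <- function() leaf_geometry(0.035, 0.015, 4e-4, 33.222)
paper_material <- function() leaf_material(E = 272.5e6, density = 700)

# impact chain at 0.4 MPa used in several frozen-value tests
paper_v1 <- 28.380712437983476   # arrival speed for v0 = sqrt(800), 35 deg, t = 0.012 s
paper_F0 <- 5.299746209906038e-6 # single 1 mm droplet at paper_v1

random_launch <- function() {
  launch_state(v0 = runif(1, 0, 40), tilt = runif(1, 0, 89.9))
}
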