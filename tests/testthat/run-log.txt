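leafspray 0.1.0
subcommand: coverage
seed: 1
config_hash: 7994fc29
effective config:
g: 9.8
rho: 1000.0
air_density: 1.225
air_viscosity: 1.7894e-05
outlet_radius: 0.0005
discharge_coef: 0.6
height: 0.3
lateral_range: 0.2
P: 400000.0
droplet_radius: 0.001
self_weight: 0.0003
volume_mode: aggregate
window: 5.0
leaf_length: 0.035
leaf_width: 0.015
leaf_thickness: 0.0004
leaf_angle: 33.222
E: 2.725e+08
deflection_mode: literal
E_plant: 2.2285e+08
leaf_density: 700.0
jitter: 0.0
damping_ratio: 0.05
dt: 0.001
duration: 0.5
restitution: 0.3
splash_threshold: 15.0
rebound_cutoff: 1.0
film_response_time: 0.02
resolution: 0.00025
spread_factor: 2.0
target_test: 0.16
target_control_left: 0.72
target_control_right: 0.68
seed: 1.0

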