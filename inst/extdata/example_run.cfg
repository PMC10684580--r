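# Example run configuration: fast/intermediate-exchange preset,
# full titration protocol grid.
scheme.k1_on_per_M_s = 1e9
scheme.k1_off_per_s = 300
scheme.k2_per_s = 30
scheme.k2_prime_per_s = 700
spin.omega_P_hz = 0
spin.omega_PL_hz = 294
spin.R2_per_s = 50
spin.echo_time_s = 0.011
mix.P0_M = 250e-6
titration.grid = default
acq.spectral_width_hz = 4000
acq.n_points = 2048
acq.zero_fill_factor = 2
acq.apodization = cosine
synth.noise_sigma = 0.01
synth.seed = 1
out.dir = example_out
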