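# Shared simulated study conditions, built once per test run.
#
# `std_arrays` mirrors the reference study shape (48 comparable arrays,
# 297 peptides, 9 within-array replicates) under the generator defaults;
# `low_arrays` is the low signal-to-noise condition (overcorrected
# background, ~half of all spots negative after background correction)
# used for the normalization sensitivity contrast.

std_arrays <- simulate_repository(n = 48, m = 297, l = 9, seed = 20150432)
std_repo <- build_repository(std_arrays)
std_list <- lapply(unique(std_arrays$array_id),
                   function(id) std_arrays[std_arrays$array_id == id, ])

low_cond <- low_signal_conditions()
low_arrays <- simulate_repository(n = 24, m = 297, l = 9,
                                  mu_dist = low_cond$mu_dist,
                                  noise = low_cond$noise,
                                  seed = 20150433)
low_repo <- build_repository(low_arrays)
low_list <- lapply(unique(low_arrays$array_id),
                   function(id) low_arrays[low_arrays$array_id == id, ])
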