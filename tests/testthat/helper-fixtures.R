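# Shared fixtures: published kinetic parameter sets and small builders.

TABLE1 <- data.frame(
  variant = c("parent", "F238A", "TS"),
  k_tau = c(0.076, 0.124, 0.098),
  K_A = c(37.95, 75.38, 95.51))

noise_free <- function(seed = 1, ...) sim_config(seed = seed, noise_sd_rel = 0, ...)

# Noise-free full-pipeline rate dataset for one parameter row.
pipeline_rates <- function(k_tau, K_A, cfg = noise_free()) {
  gt <- kinetic_truth(k_tau, K_A)
  ex <- simulate_kinetic_experiment(gt, cfg)
  lapply(ex$traces, function(tr)
    estimate_initial_rate(compute_relative_turbidity(tr), lag = cfg$lag_time))
}

# 13 binding hotspots with conservation rates set so that only 87, 238 and
# 280 fall on the variable side of the 1.2 threshold among the non-excluded.
hotspot_sites <- function() {
  data.frame(
    residue = c(86, 87, 93, 159, 160, 161, 185, 208, 237, 238, 239, 241, 280),
    mean_dg = c(-1.2, -2.1, -1.1, -1.5, -1.3, -1.8, -2.5, -2.0, -1.6, -2.8,
                -1.4, -1.1, -2.2),
    rate = c(0.9, 1.8, 0.8, 0.4, 0.3, 0.5, 0.7, 1.5, 0.4, 2.1, 1.0, 0.9, 1.9))
}

ile208_exclusion <- function() {
  data.frame(residue = 208,
             reason = "prior engineering: substitutions reduce activity")
}

# simple symmetric ligand pose built from explicit atom coordinates
make_pose <- function(xyz, atoms = c("C1", "O1", "C2")) {
  data.frame(atom = atoms, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}
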