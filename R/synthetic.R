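# Seeded generators reproducing the statistical structure of every assay
# the analysis modules consume: square-root-linear turbidity decay with a
# lag, Langmuir-saturating rate vs enzyme concentration, two-state CD
# melts, first-order activity decay, PSP plate layouts with controls, and
# pose/energy/conservation fixtures with controllable hotspot structure.
# Noise-free outputs satisfy their closed forms to machine precision.

#' Simulation configuration
#'
#' @param seed Integer RNG seed, recorded in all generated metadata. `NULL`
#'   leaves the current RNG state untouched.
#' @param noise_sd_rel Relative Gaussian noise SD (fraction of the local
#'   model signal; >= 0, default 0.02 as typical for plate readers and
#'   spectrophotometers).
#' @param lag_time Lag before the linear turbidity decline, minutes
#'   (default 1.5, the midpoint of the 1-2 min mixing transient).
#' @param sampling_interval Sampling interval, seconds (> 0, default 10).
#' @param duration Trace duration, minutes (default 20).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, noise_sd_rel = 0.02, lag_time = 1.5,
                       sampling_interval = 10, duration = 20) {
  check_number(noise_sd_rel, "noise_sd_rel", min = 0)
  check_number(sampling_interval, "sampling_interval", min = 0, allow_min = FALSE)
  check_number(lag_time, "lag_time", min = 0)
  check_number(duration, "duration", min = 0, allow_min = FALSE)
  structure(list(seed = seed, noise_sd_rel = noise_sd_rel,
                 lag_time = lag_time, sampling_interval = sampling_interval,
                 duration = duration),
            class = "sim_config")
}

apply_seed <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  invisible(NULL)
}

#' Kinetic ground truth for the turbidimetric assay
#'
#' @param k_tau Maximal square-root-turbidity decline rate, 1/min (> 0).
#' @param K_A Adsorption equilibrium constant, mL/mg (> 0).
#' @param enzyme_concs Enzyme concentrations to simulate, mg/mL
#'   (non-negative, strictly increasing).
#' @return Object of class `kinetic_truth`.
#' @export
kinetic_truth <- function(k_tau, K_A,
                          enzyme_concs = c(0.002, 0.005, 0.01, 0.02, 0.04, 0.08)) {
  check_number(k_tau, "k_tau", min = 0, allow_min = FALSE)
  check_number(K_A, "K_A", min = 0, allow_min = FALSE)
  if (any(enzyme_concs < 0)) stop_input("'enzyme_concs' must be non-negative")
  if (length(enzyme_concs) > 1) check_increasing(enzyme_concs, "enzyme_concs")
  structure(list(k_tau = k_tau, K_A = K_A, enzyme_concs = enzyme_concs),
            class = "kinetic_truth")
}

#' Simulate a turbidity trace
#'
#' Forward model: after the lag, the square root of the relative turbidity
#' declines linearly at the Langmuir rate
#' `v = k_tau * K_A * e / (1 + K_A * e)`, i.e.
#' `tau/tau0(t) = max(0, 1 - v * (t - lag))^2`, and
#' `OD600(t) = blank + tau0 * tau/tau0(t)` plus relative Gaussian noise.
#'
#' @param gt A [kinetic_truth()].
#' @param e_conc Enzyme concentration, mg/mL (>= 0).
#' @param cfg A [sim_config()]; `noise_sd_rel = 0` gives the exact forward
#'   model.
#' @param od600_init Initial suspension OD600 including the blank
#'   (default 0.45, typical for ~94 ug/mL nanoparticles).
#' @param blank Buffer-only OD600 (default 0.05).
#' @return A [turbidity_trace()] with the generator parameters attached as
#'   attribute `ground_truth`.
#' @export
simulate_turbidity <- function(gt, e_conc, cfg = sim_config(),
                               od600_init = 0.45, blank = 0.05) {
  stopifnot(inherits(gt, "kinetic_truth"))
  if (e_conc < 0) stop_input("'e_conc' must be >= 0, got %g", e_conc)
  apply_seed(cfg)
  trace <- simulate_turbidity_trace(gt, e_conc, cfg, od600_init, blank)
  trace
}

# unseeded core so multi-trace experiments share one RNG stream
simulate_turbidity_trace <- function(gt, e_conc, cfg, od600_init, blank) {
  times <- seq(0, cfg$duration * 60, by = cfg$sampling_interval) # seconds
  t_min <- times / 60
  v <- langmuir_rate(e_conc, gt$k_tau, gt$K_A)
  tau_rel <- pmax(0, 1 - v * pmax(t_min - cfg$lag_time, 0))^2
  tau0 <- od600_init - blank
  od <- blank + tau0 * tau_rel
  if (cfg$noise_sd_rel > 0)
    od <- od + rnorm(length(od), sd = cfg$noise_sd_rel * od)
  tr <- turbidity_trace(times, od, blank, e_conc)
  attr(tr, "ground_truth") <- list(k_tau = gt$k_tau, K_A = gt$K_A, v = v,
                                   lag = cfg$lag_time, seed = cfg$seed)
  tr
}

#' Simulate a full rate-versus-concentration kinetic experiment
#'
#' One turbidity trace per enzyme concentration in the ground truth, with
#' optional replicates, all drawn from a single seeded RNG stream.
#'
#' @inheritParams simulate_turbidity
#' @param replicates Traces per concentration (default 1).
#' @return List with `traces` (list of [turbidity_trace()]) and `design`
#'   (data frame `enzyme_conc`, `replicate`).
#' @export
simulate_kinetic_experiment <- function(gt, cfg = sim_config(), replicates = 1,
                                        od600_init = 0.45, blank = 0.05) {
  stopifnot(inherits(gt, "kinetic_truth"))
  apply_seed(cfg)
  design <- expand.grid(replicate = seq_len(replicates),
                        enzyme_conc = gt$enzyme_concs)[, 2:1]
  traces <- lapply(design$enzyme_conc, function(e)
    simulate_turbidity_trace(gt, e, cfg, od600_init, blank))
  list(traces = traces, design = design)
}

#' Simulate a two-state CD melt curve
#'
#' Boltzmann sigmoid between two linear ellipticity baselines (see
#' [melt_signal()]). The noise SD is `noise_sd_rel` times the
#' folded-to-unfolded dynamic range (a purely proportional-to-signal model
#' degenerates when one baseline sits at zero ellipticity).
#'
#' @param t_m Midpoint temperature, degrees C.
#' @param transition_width Transition width, degrees C (> 0).
#' @param folded,unfolded Baselines as `c(intercept, slope)`.
#' @param temperatures Temperature grid, degrees C, strictly increasing
#'   (default 30-75 by 0.5).
#' @param cfg A [sim_config()] (seed and noise level).
#' @return Data frame of class `melt_curve` (`temperature`, `signal`), with
#'   attribute `out_of_range = TRUE` (and a warning) when `t_m` lies
#'   outside the grid.
#' @export
simulate_melt <- function(t_m, transition_width = 2, folded = c(0, 0),
                          unfolded = c(-1, 0),
                          temperatures = seq(30, 75, by = 0.5),
                          cfg = sim_config()) {
  check_number(transition_width, "transition_width", min = 0, allow_min = FALSE)
  check_increasing(temperatures, "temperatures")
  apply_seed(cfg)
  sig <- melt_signal(temperatures, t_m, transition_width, folded, unfolded)
  rng <- abs((unfolded[1] + unfolded[2] * t_m) - (folded[1] + folded[2] * t_m))
  if (cfg$noise_sd_rel > 0)
    sig <- sig + rnorm(length(sig), sd = cfg$noise_sd_rel * rng)
  out <- data.frame(temperature = temperatures, signal = sig)
  oor <- t_m < min(temperatures) || t_m > max(temperatures)
  if (oor) warning("t_m lies outside the simulated temperature range")
  structure(out, class = c("melt_curve", "data.frame"),
            ground_truth = list(t_m = t_m, transition_width = transition_width,
                                seed = cfg$seed),
            out_of_range = oor)
}

#' Simulate a first-order activity decay series
#'
#' `a(t) = a0 * exp(-k_in * t)` plus relative Gaussian noise; the series is
#' renormalized so the t = 0 reading is exactly 1, as in the assay (the
#' activity at time zero is set to 100%).
#'
#' @param k_in First-order inactivation constant, 1/h (>= 0).
#' @param times Sampling times, hours (non-negative; must include 0).
#' @param cfg A [sim_config()].
#' @param a0 Initial activity fraction (default 1).
#' @return Data frame of class `activity_series` (`time_h`, `activity`).
#' @export
simulate_decay <- function(k_in, times, cfg = sim_config(), a0 = 1) {
  check_number(k_in, "k_in", min = 0)
  if (any(times < 0)) stop_input("'times' must be non-negative")
  apply_seed(cfg)
  a <- a0 * exp(-k_in * times)
  if (cfg$noise_sd_rel > 0)
    a <- pmax(a + rnorm(length(a), sd = cfg$noise_sd_rel * a), 0)
  i0 <- which.min(times)
  a <- a / a[i0]
  structure(data.frame(time_h = times, activity = a),
            class = c("activity_series", "data.frame"),
            ground_truth = list(k_in = k_in, seed = cfg$seed))
}

#' Simulate a PSP screening plate
#'
#' Control wells are drawn around their nominal A540 means; each sample
#' well's expected A540 interpolates linearly between the negative control
#' (relative activity 0) and the parent control (relative activity 1) and
#' extrapolates beyond the parent for improved clones:
#' `A540 = neg_mean - activity * (neg_mean - parent_mean)`.
#'
#' @param layout A [plate_layout()] (must contain both control roles).
#' @param activity Named numeric vector of relative activities (parent = 1)
#'   for every sample well in the layout.
#' @param cfg A [sim_config()].
#' @param neg_mean,parent_mean Nominal control A540 means (defaults 0.80
#'   and 0.40: less hydrolysis keeps the dye red, more hydrolysis
#'   acidifies and bleaches it).
#' @return A [plate_reading()] with attribute `ground_truth`.
#' @export
simulate_plate <- function(layout, activity, cfg = sim_config(),
                           neg_mean = 0.80, parent_mean = 0.40) {
  stopifnot(inherits(layout, "plate_layout"))
  sample_wells <- layout$well[layout$role == "sample"]
  missing <- setdiff(sample_wells, names(activity))
  if (length(missing))
    stop_input("'activity' missing for sample well(s): %s",
               paste(head(missing, 5), collapse = ", "))
  apply_seed(cfg)
  span <- neg_mean - parent_mean
  wells <- layout$well[layout$role != "empty"]
  mu <- vapply(wells, function(w) {
    switch(layout$role[layout$well == w],
           negative_control = neg_mean,
           parent_control = parent_mean,
           blank = 0.05,
           sample = neg_mean - activity[[w]] * span)
  }, numeric(1))
  a540 <- mu
  if (cfg$noise_sd_rel > 0)
    a540 <- pmax(mu + rnorm(length(mu), sd = cfg$noise_sd_rel * abs(mu)), 0)
  rd <- plate_reading(layout, setNames(a540, wells))
  attr(rd, "ground_truth") <- list(activity = activity, neg_mean = neg_mean,
                                   parent_mean = parent_mean, seed = cfg$seed)
  rd
}

# --- hotspot fixtures ------------------------------------------------------

# Fixed synthetic geometry for the catalytic machinery (Angstrom): the
# serine gamma-O at the origin and the two oxyanion-hole backbone amides
# flanking it. A "competent" ligand template places the ester carbon 3.5 A
# from OG and the carbonyl oxygen ~2.1 A from both amide nitrogens.
catalytic_site_geometry <- function(catalytic_ser = 160,
                                    oxyanion_residues = c(87, 161)) {
  data.frame(
    atom = c("OG", "CB", "N", "N"),
    resno = c(catalytic_ser, catalytic_ser, oxyanion_residues),
    resid = c("SER", "SER", "TYR", "MET"),
    x = c(0, -0.8, 1.5, -1.5),
    y = c(0, -1.2, 2.8, 2.8),
    z = c(0, 0.3, 0.5, 0.5))
}

competent_ligand_template <- function() {
  data.frame(
    atom = c("C1", "O1", "C2", "C3", "O2"),
    x = c(0.0, 0.0, 1.4, -1.4, 2.2),
    y = c(2.0, 2.8, 2.0, 2.3, 1.2),
    z = c(2.87, 2.0, 3.4, 3.7, 3.0))
}

#' Simulate hotspot-selection fixtures
#'
#' Builds, from a per-site scenario table, the three inputs of the
#' mutagenesis-position selection workflow: a docked [pose_set()] with
#' controlled competence and cluster structure, a per-residue
#' binding-energy table and a per-site conservation table.
#'
#' Poses are jittered copies of a catalytically competent ligand template
#' (ester carbon 3.5 A from the serine OG); non-competent poses are
#' translated 5 A per cluster away from the active site, so the pose set
#' partitions into `n_clusters` clusters at a 1 A RMSD threshold, with
#' cluster 1 (best docking scores) the competent one.
#'
#' @param sites Data frame with columns `residue` (unique numbers),
#'   `mean_dg` (kcal/mol), `rate` and optionally `resid` (3-letter name)
#'   and `sd` (kcal/mol, default 0.2). May have zero rows: all outputs are
#'   then empty.
#' @param cfg A [sim_config()] (seed; jitter below is uniform, not scaled
#'   by `noise_sd_rel`).
#' @param n_poses Number of docked poses (default 20).
#' @param frac_competent Fraction of poses built on the competent template
#'   (default 0.4).
#' @param n_clusters Total pose clusters (default 3; cluster 1 holds the
#'   competent poses).
#' @param jitter Uniform per-coordinate jitter half-width, Angstrom
#'   (default 0.15; small enough to keep within-cluster RMSD < 1 A and
#'   competence distances < 4 A).
#' @return List with `poses` (a [pose_set()], or NULL for an empty
#'   scenario), `energy` (residue, mean_dg, sd), `conservation` (residue,
#'   rate).
#' @export
simulate_hotspot_fixtures <- function(sites, cfg = sim_config(), n_poses = 20,
                                      frac_competent = 0.4, n_clusters = 3,
                                      jitter = 0.15) {
  if (nrow(sites) == 0) {
    return(list(poses = NULL,
                energy = data.frame(residue = integer(), mean_dg = numeric(),
                                    sd = numeric()),
                conservation = data.frame(residue = integer(), rate = numeric())))
  }
  if (anyDuplicated(sites$residue))
    stop_input("duplicate residue identifier(s) in scenario: %s",
               paste(unique(sites$residue[duplicated(sites$residue)]),
                     collapse = ", "))
  if (!all(c("residue", "mean_dg", "rate") %in% names(sites)))
    stop_input("scenario needs columns residue, mean_dg, rate")
  apply_seed(cfg)

  energy <- data.frame(residue = sites$residue, mean_dg = sites$mean_dg,
                       sd = if ("sd" %in% names(sites)) sites$sd else 0.2)
  conservation <- data.frame(residue = sites$residue, rate = sites$rate)

  receptor <- catalytic_site_geometry()
  # one CA placeholder per scenario residue not already in the machinery
  extra <- setdiff(sites$residue, receptor$resno)
  if (length(extra)) {
    ang <- seq(0, 2 * pi, length.out = length(extra) + 1)[-1]
    receptor <- rbind(receptor, data.frame(
      atom = "CA", resno = extra,
      resid = if ("resid" %in% names(sites))
        sites$resid[match(extra, sites$residue)] else "ALA",
      x = 8 * cos(ang), y = 8 * sin(ang), z = 1.0))
  }

  template <- competent_ligand_template()
  n_comp <- round(frac_competent * n_poses)
  cluster_of <- c(rep(1L, n_comp),
                  if (n_poses > n_comp)
                    rep(seq(2L, length.out = max(n_clusters - 1L, 1L)),
                        length.out = n_poses - n_comp))
  cluster_of <- sort(cluster_of)
  poses <- lapply(cluster_of, function(cl) {
    shift <- c(5 * (cl - 1L), 0, 0)
    jit <- matrix(runif(3 * nrow(template), -jitter, jitter), ncol = 3)
    data.frame(atom = template$atom,
               x = template$x + shift[1] + jit[, 1],
               y = template$y + shift[2] + jit[, 2],
               z = template$z + shift[3] + jit[, 3])
  })
  # competent cluster gets the best (lowest) docking scores
  scores <- sort(runif(n_poses, -10, -4))[order(order(cluster_of))]
  esters <- data.frame(group = "E1", ester_c = "C1", carbonyl_o = "O1")
  list(poses = pose_set(receptor, poses, esters, scores),
       energy = energy, conservation = conservation)
}

# --- writers ---------------------------------------------------------------

#' Write a turbidity trace to CSV with metadata header
#' @param trace A [turbidity_trace()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_turbidity_csv <- function(trace, path) {
  gt <- attr(trace, "ground_truth", exact = TRUE)
  write_meta_csv(data.frame(time_s = trace$times, od600 = trace$od600), path,
                 meta = c(list(od600_blank = trace$od600_blank,
                               enzyme_conc = trace$enzyme_conc),
                          if (!is.null(gt)) gt["seed"]))
}

#' Write a melt curve to CSV (columns temp_C, signal)
#' @param curve A `melt_curve` data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_melt_csv <- function(curve, path) {
  gt <- attr(curve, "ground_truth", exact = TRUE)
  write_meta_csv(data.frame(temp_C = curve$temperature, signal = curve$signal),
                 path, meta = if (!is.null(gt)) gt[c("t_m", "seed")] else list())
}

#' Write an activity decay series to CSV (columns time_h, activity_frac)
#' @param series An `activity_series` data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_decay_csv <- function(series, path) {
  gt <- attr(series, "ground_truth", exact = TRUE)
  write_meta_csv(data.frame(time_h = series$time_h,
                            activity_frac = series$activity),
                 path, meta = if (!is.null(gt)) gt[c("k_in", "seed")] else list())
}

#' Write a plate reading (long format) and its layout to CSV
#' @param reading A [plate_reading()].
#' @param plate_path,layout_path Output paths.
#' @return `plate_path`, invisibly.
#' @export
write_plate_csv <- function(reading, plate_path, layout_path) {
  write_meta_csv(data.frame(well = names(reading$a540), a540 = reading$a540),
                 plate_path, meta = list(substrate = reading$substrate))
  write_meta_csv(reading$layout, layout_path)
  invisible(plate_path)
}

#' Write a pose set as PDB files plus an ester-map CSV
#'
#' The receptor goes to one PDB; poses to a multi-MODEL PDB (one MODEL per
#' pose); the ester map CSV carries the flagged atoms and a `# scores:`
#' metadata line with the per-pose docking scores.
#'
#' @param ps A [pose_set()].
#' @param receptor_path,poses_path,ester_map_path Output paths.
#' @return `poses_path`, invisibly.
#' @export
write_pose_pdb <- function(ps, receptor_path, poses_path, ester_map_path) {
  rec <- ps$receptor
  bio3d::write.pdb(file = receptor_path,
                   xyz = as.numeric(t(as.matrix(rec[, c("x", "y", "z")]))),
                   resno = rec$resno,
                   resid = if ("resid" %in% names(rec)) rec$resid
                           else rep("ALA", nrow(rec)),
                   elety = rec$atom, chain = rep("A", nrow(rec)))
  # write.pdb emits single models; wrap each pose in MODEL/ENDMDL records
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  blocks <- vapply(seq_along(ps$poses), function(m) {
    p <- ps$poses[[m]]
    na <- nrow(p)
    bio3d::write.pdb(file = tmp,
                     xyz = as.numeric(t(as.matrix(p[, c("x", "y", "z")]))),
                     resno = rep(1L, na), resid = rep("LIG", na),
                     elety = p$atom, type = rep("HETATM", na),
                     chain = rep("L", na))
    rec <- grep("^(ATOM|HETATM|TER)", readLines(tmp), value = TRUE)
    paste(c(sprintf("MODEL     %4d", m), rec, "ENDMDL"), collapse = "\n")
  }, character(1))
  writeLines(c(blocks, "END"), poses_path)
  write_meta_csv(ps$esters, ester_map_path, meta = list(scores = ps$scores))
  invisible(poses_path)
}
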