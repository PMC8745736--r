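# The generators must hit their closed forms exactly when noise is off,
# be bit-reproducible under a seed, and reject malformed inputs.

test_that("noise-free turbidity traces follow the square-root-linear forward model", {
  gt <- kinetic_truth(0.076, 37.95)
  cfg <- noise_free()
  tr <- simulate_turbidity(gt, e_conc = 0.04, cfg = cfg)
  rel <- compute_relative_turbidity(tr)
  v <- langmuir_rate(0.04, 0.076, 37.95)
  expect_equal(v, 0.04582, tolerance = 1e-4)
  # hand-evaluated closed form at lag + 10 min
  at <- which.min(abs(rel$time_min - (cfg$lag_time + 10)))
  expect_equal(rel$tau_rel[at], (1 - v * 10)^2, tolerance = 1e-12)
  expect_equal(rel$tau_rel[at], 0.2936, tolerance = 1e-3)
  # whole trace matches the model to machine precision
  model <- pmax(0, 1 - v * pmax(rel$time_min - cfg$lag_time, 0))^2
  expect_equal(rel$tau_rel, model, tolerance = 1e-12)
})

test_that("zero enzyme gives a flat trace and saturation approaches k_tau", {
  gt <- kinetic_truth(0.076, 37.95)
  tr <- simulate_turbidity(gt, e_conc = 0, cfg = noise_free())
  expect_equal(unique(tr$od600), tr$od600[1])
  expect_equal(langmuir_rate(0, 0.076, 37.95), 0)
  expect_equal(langmuir_rate(1e9, 0.076, 37.95), 0.076, tolerance = 1e-6)
})

test_that("negative enzyme concentration is rejected with the field named", {
  gt <- kinetic_truth(0.076, 37.95)
  expect_error(simulate_turbidity(gt, e_conc = -0.01), "e_conc")
})

test_that("seeded generation is bit-reproducible", {
  gt <- kinetic_truth(0.1, 50)
  cfg <- sim_config(seed = 42, noise_sd_rel = 0.05)
  a <- simulate_turbidity(gt, 0.02, cfg)
  b <- simulate_turbidity(gt, 0.02, cfg)
  expect_identical(a$od600, b$od600)
  m1 <- simulate_melt(55.3, cfg = cfg)
  m2 <- simulate_melt(55.3, cfg = cfg)
  expect_identical(m1$signal, m2$signal)
  d1 <- simulate_decay(2.46, 0:5, cfg)
  d2 <- simulate_decay(2.46, 0:5, cfg)
  expect_identical(d1$activity, d2$activity)
})

test_that("noise-free melt curve hits the baseline midpoint at t_m", {
  # evaluate on a grid that contains t_m itself
  mc <- simulate_melt(55.3, transition_width = 2, folded = c(0, 0),
                      unfolded = c(-1, 0),
                      temperatures = seq(30.3, 75.3, 0.5), cfg = noise_free())
  expect_equal(mc$signal[mc$temperature == 55.3], -0.5, tolerance = 1e-12)
  expect_equal(mc$signal,
               melt_signal(mc$temperature, 55.3, 2, c(0, 0), c(-1, 0)),
               tolerance = 1e-12)
  # vanishing width approaches a step function around t_m
  step <- simulate_melt(55.3, transition_width = 1e-9, cfg = noise_free())
  expect_equal(step$signal[step$temperature < 55.2], rep(0, sum(step$temperature < 55.2)))
  expect_equal(step$signal[step$temperature > 55.4], rep(-1, sum(step$temperature > 55.4)))
})

test_that("melt midpoint outside the ramp raises the out-of-range flag", {
  expect_warning(mc <- simulate_melt(90, temperatures = seq(30, 75, 0.5),
                                     cfg = noise_free()),
                 "outside")
  expect_true(attr(mc, "out_of_range"))
})

test_that("noise-free decay matches the exponential closed form", {
  times <- c(0, 1/6, 1/3, 0.5, 1)
  d <- simulate_decay(2.46, times, noise_free())
  expect_equal(d$activity, exp(-2.46 * times), tolerance = 1e-12)
  # the published constants bracket the observed residual activities
  expect_equal(exp(-2.46 / 3), 0.440, tolerance = 1e-3)   # ~40% left at 20 min
  expect_equal(exp(-8.40 / 3), 0.061, tolerance = 1e-2)   # almost inactive
  d0 <- simulate_decay(0, times, noise_free())
  expect_equal(d0$activity, rep(1, length(times)))
  expect_error(simulate_decay(2.46, c(-1, 0, 1), noise_free()), "times")
})

test_that("noisy decay series are renormalized to activity 1 at t = 0", {
  d <- simulate_decay(2.46, c(0, 0.2, 0.4, 0.8), sim_config(seed = 7, noise_sd_rel = 0.05))
  expect_equal(d$activity[1], 1)
})

test_that("noise-free plates place samples on the control-anchored line", {
  lay <- default_screen_layout()
  act <- setNames(rep(1, 88), lay$well[lay$role == "sample"])
  act["A1"] <- 1.65
  rd <- simulate_plate(lay, act, noise_free())
  sc <- score_plate(rd)
  expect_equal(sc$activity_pct[sc$well == "A1"], 165)
  others <- sc$activity_pct[sc$role == "sample" & sc$well != "A1"]
  expect_equal(others, rep(100, length(others)))
})

test_that("plate simulation demands activities for all sample wells", {
  lay <- default_screen_layout()
  expect_error(simulate_plate(lay, c(A1 = 1), noise_free()), "missing")
  # and a layout without controls is rejected at construction
  expect_error(plate_layout(c(A1 = "sample", A2 = "parent_control")),
               "negative_control")
})

test_that("hotspot fixtures honour the scenario table and reject duplicates", {
  fx <- simulate_hotspot_fixtures(hotspot_sites(), noise_free(3))
  expect_equal(fx$energy$mean_dg, hotspot_sites()$mean_dg)
  expect_equal(fx$conservation$rate, hotspot_sites()$rate)
  expect_s3_class(fx$poses, "pose_set")
  dup <- rbind(hotspot_sites(), hotspot_sites()[1, ])
  expect_error(simulate_hotspot_fixtures(dup, noise_free()), "duplicate")
  # empty scenario -> empty everything
  empty <- simulate_hotspot_fixtures(hotspot_sites()[0, ], noise_free())
  expect_null(empty$poses)
  expect_equal(nrow(empty$energy), 0)
})

test_that("fixture poses have the constructed competence and cluster structure", {
  fx <- simulate_hotspot_fixtures(hotspot_sites(), noise_free(5),
                                  n_poses = 20, frac_competent = 0.4,
                                  n_clusters = 3)
  comp <- filter_competent_poses(fx$poses)
  expect_equal(sum(comp$competent), 8)
  expect_true(all(comp$d_ester_c_og[comp$competent] < 4))
  cl <- cluster_poses(fx$poses)
  expect_equal(length(unique(cl$cluster)), 3)
  # competent poses carry the best docking scores, so they form cluster 1
  expect_setequal(cl$pose[cl$cluster == 1], comp$pose[comp$competent])
})

test_that("generated CSVs round-trip through the readers", {
  dir <- withr::local_tempdir()
  gt <- kinetic_truth(0.076, 37.95)
  tr <- simulate_turbidity(gt, 0.04, noise_free())
  f <- file.path(dir, "trace.csv")
  write_turbidity_csv(tr, f)
  tr2 <- read_turbidity_csv(f)
  expect_equal(tr2$od600, tr$od600, tolerance = 1e-10)
  expect_equal(tr2$enzyme_conc, 0.04)

  mc <- simulate_melt(55.3, cfg = noise_free())
  f <- file.path(dir, "melt.csv")
  write_melt_csv(mc, f)
  mc2 <- read_melt_csv(f)
  expect_equal(mc2$signal, mc$signal, tolerance = 1e-10)

  d <- simulate_decay(2.46, c(0, 0.5, 1), noise_free())
  f <- file.path(dir, "decay.csv")
  write_decay_csv(d, f)
  expect_equal(read_activity_csv(f)$activity, d$activity, tolerance = 1e-10)

  lay <- default_screen_layout()
  act <- setNames(runif(88, 0.2, 1.2), lay$well[lay$role == "sample"])
  rd <- simulate_plate(lay, act, sim_config(seed = 9, noise_sd_rel = 0.02))
  fp <- file.path(dir, "plate.csv"); fl <- file.path(dir, "layout.csv")
  write_plate_csv(rd, fp, fl)
  rd2 <- read_plate_csv(fp, fl)
  expect_equal(rd2$a540, rd$a540, tolerance = 1e-10)
})
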