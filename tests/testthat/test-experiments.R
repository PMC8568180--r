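test_that("sweep summaries degenerate correctly for single and noise-free runs", {
  s1 <- run_sweep_summary("ebm", "saddle", from = 0.2, to = 0.4, length = 50,
    realizations = 1, sigma = 0.01, seed = 1)
  expect_equal(s1$min, s1$mean)
  expect_equal(s1$max, s1$mean)

  s0 <- run_sweep_summary("ebm", "saddle", from = 0.2, to = 0.4, length = 50,
    realizations = 5, sigma = 0, seed = 1)
  expect_true(all(s0$sd == 0))
  expect_equal(nrow(s0), 50)
  expect_equal(s0$parameter, seq(0.2, 0.4, length.out = 50))
})

test_that("lattice sweep fluctuations peak near the transition", {
  s <- run_sweep_summary("abm", "saddle", from = -0.2, to = 0.2, length = 300,
    realizations = 15, temperature = 2.12, L = 50, equilibrate = 50, seed = 5)
  # transition region: where the ensemble mean moves between the plateaus
  swing <- range(s$mean)
  trans <- which(s$mean < swing[2] - 0.2 * diff(swing) &
    s$mean > swing[1] + 0.2 * diff(swing))
  expect_gt(length(trans), 0)
  expect_true(which.max(s$sd) >= min(trans) - 30)
  # plateau noise is much smaller than transition noise
  plateau_sd <- mean(s$sd[1:50])
  expect_gt(max(s$sd), 3 * plateau_sd)
})

test_that("sigma calibration degenerates to a singleton grid and self-calibrates", {
  target <- run_sweep_summary("ebm", "saddle", from = 0.2, to = 0.5, length = 150,
    realizations = 40, sigma = 0.01, start = "lower", seed = 3)
  single <- calibrate_sigma(target, sigma_grid = 0.02, seed = 4)
  expect_equal(single$sigma, 0.02)

  # self-consistency: an EBM target generated at sigma = 0.01 picks 0.01
  cal <- calibrate_sigma(target, sigma_grid = c(0.005, 0.01, 0.02), seed = 5)
  expect_equal(cal$sigma, 0.01)
  expect_equal(nrow(cal$table), 3)
  expect_error(calibrate_sigma(target, numeric(0)), "nonempty")
})

test_that("experiment configs enforce scenario consistency", {
  expect_error(
    experiment_config("ebm", "pitchfork", values = c(0.7, 0.9), field = 0.3),
    "zero external field"
  )
  cfg <- experiment_config("ebm", "saddle", values = c(-0.8, -0.7))
  expect_equal(cfg$amplitude, 1)  # alternative equilibrium by default
  cfg_pf <- experiment_config("ebm", "pitchfork", values = c(0.7, 0.9),
    direction = "below")
  expect_equal(cfg_pf$amplitude, 1)
  cfg_pf2 <- experiment_config("ebm", "pitchfork", values = c(1.3, 1.2),
    direction = "above")
  expect_equal(cfg_pf2$amplitude, 0.01)
})

test_that("prediction experiments run end to end, reproducibly, and write artifacts", {
  out <- file.path(tempdir(), "pred-test")
  cfg <- experiment_config("ebm", "saddle",
    values = c(-0.82, -0.72), temperature = 2.12, amplitude = 1.5,
    transient = 100, recovery_length = 300, realizations = 20,
    sigma = 0.01, seed = 9, output_dir = out
  )
  est <- run_prediction_experiment(cfg)
  expect_s3_class(est, "bifurcation_estimate")
  expect_true(is.finite(est$c_hat))
  expect_lt(est$c_hat, -0.6)  # beyond the innermost perturbation, toward the fold
  expect_gt(est$c_hat, -0.72)
  expect_true(file.exists(file.path(out, "recovery_curves.csv")))
  expect_true(file.exists(file.path(out, "estimate.json")))
  expect_true(file.exists(file.path(out, "config.json")))
  js <- jsonlite::read_json(file.path(out, "estimate.json"))
  expect_equal(js$c_hat, est$c_hat, tolerance = 1e-12)

  cfg2 <- experiment_config("ebm", "saddle",
    values = c(-0.82, -0.72), temperature = 2.12, amplitude = 1.5,
    transient = 100, recovery_length = 300, realizations = 20,
    sigma = 0.01, seed = 9
  )
  est2 <- run_prediction_experiment(cfg2)
  expect_identical(est$c_hat, est2$c_hat)
})

test_that("the pitchfork pipeline brackets the mean-field branching point", {
  cfg <- experiment_config("ebm", "pitchfork",
    values = c(0.80, 0.90), direction = "below", amplitude = 1,
    transient = 100, recovery_length = 600, realizations = 30,
    sigma = 0.005, seed = 21
  )
  est <- run_prediction_experiment(cfg)
  # the subcritical branch loses stability at T = 1
  expect_gt(est$c_hat, 0.9)
  expect_lt(abs(est$c_hat - 1), 0.15)
})

test_that("trajectory round-trips through CSV preserve data and metadata", {
  traj <- simulate_meanfield(meanfield_config(2, field = 0.1, sigma = 0.01,
    n_steps = 50, m0 = 0.5, seed = 2))
  path <- file.path(tempdir(), "traj.csv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(back$state, traj$state)
  expect_equal(back$parameter, traj$parameter)
  expect_equal(attr(back, "dt"), attr(traj, "dt"))
  expect_equal(attr(back, "parameter_name"), "H")
})

test_that("lattice snapshots round-trip as plain text", {
  set.seed(3)
  lat <- lattice_random(12)
  path <- file.path(tempdir(), "lat.txt")
  write_lattice_snapshot(lat, path)
  expect_identical(read_lattice_snapshot(path), lat)
})

test_that("the command-line layer dispatches and writes outputs", {
  tmp <- file.path(tempdir(), "cli-out")
  dir.create(tmp, showWarnings = FALSE)
  traj_path <- file.path(tmp, "t.csv")
  expect_message(
    isingcsd:::cli_main(c("sim-ebm", "--T", "2.12", "--H", "-0.7",
      "--n-steps", "200", "--m0", "-0.9", "--seed", "4", "--out", traj_path)),
    "wrote"
  )
  expect_true(file.exists(traj_path))
  ews_path <- file.path(tmp, "e.csv")
  # long enough series for the default rolling window
  isingcsd:::cli_main(c("sim-ebm", "--n-steps", "600", "--m0", "-0.9",
    "--sigma", "0.01", "--H", "-0.7", "--seed", "5", "--out", traj_path))
  expect_message(
    isingcsd:::cli_main(c("ews", "--in", traj_path, "--out", ews_path)),
    "wrote"
  )
  tab <- readr::read_csv(ews_path, show_col_types = FALSE)
  expect_true(all(c("ar1", "std", "dfa", "fr") %in% names(tab)))
  expect_error(isingcsd:::cli_main(c("frobnicate")), "unknown command")
})

test_that("plot methods return ggplot objects", {
  traj <- simulate_meanfield(meanfield_config(2, field = 0, sigma = 0.01,
    n_steps = 300, m0 = 0.5, seed = 2))
  expect_s3_class(autoplot(traj), "ggplot")
  expect_s3_class(autoplot(rolling_ews(traj, window = 100, step = 50)), "ggplot")
  est <- estimate_bifurcation(data.frame(c = c(-0.2, -0.12), m = c(-0.05, -0.02)))
  expect_s3_class(autoplot(est), "ggplot")
})
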