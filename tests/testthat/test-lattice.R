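test_that("neighbor sums use the von Neumann neighborhood with periodic wrap", {
  expect_equal(neighbor_sum(lattice_uniform(5, 1L), 1, 1), 4)
  expect_equal(neighbor_sum(lattice_uniform(5, -1L), 3, 5), -4)
  # checkerboard: all four neighbors carry the opposite color
  L <- 6
  cb <- outer(1:L, 1:L, function(i, j) ifelse((i + j) %% 2 == 0, 1L, -1L))
  for (site in list(c(1, 1), c(1, L), c(4, 3), c(L, L))) {
    expect_equal(
      neighbor_sum(cb, site[1], site[2]),
      -4L * cb[site[1], site[2]]
    )
  }
  # explicit wrap check on a small hand-built lattice
  m <- lattice_uniform(3, 1L)
  m[3, 1] <- -1L  # wraps to be the "up" neighbor of (1, 1)
  expect_equal(neighbor_sum(m, 1, 1), 2)
  expect_error(neighbor_sum(m, 0, 1), "out of range")
  expect_error(neighbor_sum(m, 1, 4), "out of range")
})

test_that("flip energetics follow Ediff = 2 S (NB - H)", {
  expect_equal(energy_diff(1, 4, 0), 8)
  expect_equal(energy_diff(-1, 2, 0.2), -3.6)
  expect_equal(energy_diff(1, 0, 0), 0)
})

test_that("the Metropolis acceptance rule is exact at its boundary", {
  expect_true(flip_decision(-1, 2, 0.999))
  expect_true(flip_decision(0, 2, 0.999))  # Ediff <= 0 branch includes 0
  # exp(-4) = 0.018315639 (frozen from an independent evaluation)
  expect_true(flip_decision(8, 2, 0.0183))
  expect_false(flip_decision(8, 2, 0.0184))
  expect_error(flip_decision(1, 0, 0.5), "temperature")
})

test_that("sweeps preserve the spin domain and freeze in the zero-temperature limit", {
  set.seed(1)
  lat <- lattice_random(12)
  for (k in 1:5) lat <- metropolis_sweep(lat, temperature = 2.5, field = 0.1)
  expect_true(all(lat %in% c(-1L, 1L)))
  expect_true(abs(magnetization(lat)) <= 1)

  # T -> 0+: an aligned lattice is absorbing at zero field
  frozen <- lattice_uniform(10, 1L)
  cfg <- lattice_config(L = 10, temperature = 1e-6, field = 0, sweeps = 100,
    init = frozen, seed = 2)
  traj <- simulate_lattice(cfg)
  expect_true(all(traj$state == 1))

  # a single misaligned defect flips once visited (Ediff = -8)
  defect <- lattice_uniform(8, 1L)
  defect[4, 4] <- -1L
  set.seed(3)
  for (k in 1:10) defect <- metropolis_sweep(defect, temperature = 1e-6, field = 0)
  expect_true(all(defect == 1L))
})

test_that("a strong field aligns all spins against its sign within a few sweeps", {
  # Ediff = 2 S (NB - H): |H| > 4 dominates the neighbor term, so spins
  # lock to -sign(H) even from adversarial starts
  set.seed(4)
  lat <- lattice_random(10)
  cfg <- lattice_config(L = 10, temperature = 1e-6, field = -5, sweeps = 5,
    init = lat, seed = 5)
  expect_equal(tail(simulate_lattice(cfg)$state, 1), 1)
  cfg2 <- lattice_config(L = 10, temperature = 1e-6, field = 5, sweeps = 5,
    init = lat, seed = 6)
  expect_equal(tail(simulate_lattice(cfg2)$state, 1), -1)
})

test_that("magnetization is the mean spin", {
  expect_equal(magnetization(lattice_uniform(4, 1L)), 1)
  expect_equal(magnetization(lattice_uniform(4, -1L)), -1)
  cb <- outer(1:4, 1:4, function(i, j) ifelse((i + j) %% 2 == 0, 1L, -1L))
  expect_equal(magnetization(cb), 0)
})

test_that("lattice simulations are seed-deterministic and ordered/disordered as temperature dictates", {
  cfg <- lattice_config(L = 20, temperature = 2.2, field = 0.05, sweeps = 60, seed = 11)
  expect_identical(simulate_lattice(cfg)$state, simulate_lattice(cfg)$state)

  # deep in the ordered phase an aligned start stays aligned
  set.seed(12)
  finals <- vapply(1:20, function(s) {
    cfg <- lattice_config(L = 20, temperature = 1.5, field = 0, sweeps = 100,
      init = "up", seed = 100 + s)
    tail(simulate_lattice(cfg)$state, 1)
  }, numeric(1))
  expect_gte(mean(finals > 0.9), 0.95)

  # far above the critical temperature the time-mean magnetization vanishes
  cfg_hot <- lattice_config(L = 20, temperature = 10, field = 0, sweeps = 200,
    init = "random", seed = 13)
  expect_lt(abs(mean(simulate_lattice(cfg_hot)$state)), 0.05)
})

test_that("order parameter separates warm and cool phases (3-sigma check)", {
  set.seed(21)
  absmag <- function(Tv, seed) {
    cfg <- lattice_config(L = 50, temperature = Tv, field = 0, sweeps = 500,
      record_every = 5, init = "up", seed = seed)
    traj <- simulate_lattice(cfg)
    abs(mean(tail(traj$state, 60)))
  }
  cool <- vapply(1:20, function(s) absmag(1.5, 200 + s), numeric(1))
  warm <- vapply(1:20, function(s) absmag(3.5, 300 + s), numeric(1))
  pooled_se <- sqrt(var(cool) / 20 + var(warm) / 20)
  expect_gt(mean(cool) - mean(warm), 3 * pooled_se)
})

test_that("alignment perturbations hit their binomial targets", {
  lat <- lattice_uniform(100, -1L)
  set.seed(31)
  expect_equal(magnetization(perturb_alignment(lat, 0, -1L)), 1)
  expect_equal(magnetization(perturb_alignment(lat, 1, -1L)), -1)
  # r = 0.5: magnetization within 3 binomial standard errors in most draws
  hits <- vapply(1:50, function(k) {
    abs(magnetization(perturb_alignment(lat, 0.5, -1L))) < 3 / sqrt(100^2)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  expect_error(perturb_alignment(lat, 1.5, -1L), "\\[0, 1\\]")
})

test_that("site-state probabilities are ensemble fractions", {
  # frozen all-(-1) ensemble
  cfgs <- lapply(1:3, function(s) {
    lattice_config(L = 8, temperature = 1e-6, field = 0, sweeps = 20,
      init = "down", seed = 400 + s, track_site = "center")
  })
  runs <- lapply(cfgs, simulate_lattice)
  trace <- site_state_probability(runs, state = -1L)
  expect_true(all(trace$probability == 1))
  # complementarity
  trace_up <- site_state_probability(runs, state = 1L)
  expect_equal(trace$probability + trace_up$probability, rep(1, nrow(trace)))
  # deep ordered +1 phase: -1 probability is small
  runs_up <- lapply(1:10, function(s) {
    simulate_lattice(lattice_config(L = 15, temperature = 1.5, field = 0,
      sweeps = 30, init = "up", seed = 500 + s, track_site = "center"))
  })
  trace2 <- site_state_probability(runs_up, state = -1L)
  expect_lt(mean(trace2$probability), 0.05)
  expect_error(site_state_probability(runs[1]), "at least 2")
})

test_that("hysteresis loops stay bounded and carry both directions", {
  loop <- hysteresis_loop(temperature = 2.12, L = 20, sweeps_per_leg = 300, seed = 61)
  expect_setequal(unique(loop$direction), c("up", "down"))
  expect_true(all(abs(loop$state) <= 1))
})
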