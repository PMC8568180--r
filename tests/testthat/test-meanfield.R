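test_that("a single Euler step reproduces hand-computed updates", {
  # fixed point of tanh at the origin
  cfg <- meanfield_config(temperature = 2.12, field = 0, sigma = 0, n_steps = 1)
  expect_equal(step_meanfield(0, cfg), 0)
  # pure linear decay when the coupling term vanishes
  cfg0 <- meanfield_config(temperature = 0, field = 0, dt = 0.1, sigma = 0, n_steps = 1)
  expect_equal(step_meanfield(1, cfg0), 0.9)
  # tanh(1) = 0.7615941559557649 (frozen from an independent evaluation)
  cfg2 <- meanfield_config(temperature = 2, field = 0, dt = 0.1, sigma = 0, n_steps = 1)
  expect_equal(step_meanfield(0.5, cfg2), 0.5 + (-0.5 + 0.7615941559557649) * 0.1,
    tolerance = 1e-12
  )
})

test_that("noise-free trajectories decay to the subcritical equilibrium and stay on fixed points", {
  traj <- simulate_meanfield(
    meanfield_config(temperature = 0.5, field = 0, sigma = 0, n_steps = 200, m0 = 0.8)
  )
  expect_equal(nrow(traj), 201)
  expect_lt(abs(traj$state[201]), 1e-3)
  # monotone decay toward 0
  expect_true(all(diff(traj$state) < 0))

  # starting exactly on an equilibrium root keeps the trajectory constant
  eq <- meanfield_equilibria(2, 0)
  root <- max(eq$state)
  traj2 <- simulate_meanfield(
    meanfield_config(temperature = 2, field = 0, sigma = 0, n_steps = 50, m0 = root)
  )
  expect_equal(traj2$state, rep(root, 51), tolerance = 1e-9)
})

test_that("identical seeds give bit-identical noisy trajectories", {
  cfg <- meanfield_config(temperature = 2.12, field = -0.7, sigma = 0.01,
    n_steps = 300, m0 = -0.9, seed = 42)
  expect_identical(simulate_meanfield(cfg)$state, simulate_meanfield(cfg)$state)
})

test_that("trajectories obey the odd symmetry of the model", {
  # (H, m0) and (-H, -m0) give exact negatives when noise-free
  for (H in c(0.1, -0.3)) {
    a <- simulate_meanfield(meanfield_config(2.12, field = H, sigma = 0, n_steps = 100, m0 = 0.4))
    b <- simulate_meanfield(meanfield_config(2.12, field = -H, sigma = 0, n_steps = 100, m0 = -0.4))
    expect_equal(a$state, -b$state, tolerance = 1e-14)
  }
})

test_that("divergent parameters abort with a diagnostic", {
  expect_error(
    simulate_meanfield(meanfield_config(2, field = 0, dt = 50, sigma = 0,
      n_steps = 200, m0 = 1.2)),
    "diverged"
  )
})

test_that("equilibria satisfy the self-consistency equation to 1e-9 and match the iteration oracle", {
  # fixed-point iteration of M <- tanh(2M) is an independent oracle for the
  # stable root at T = 2, H = 0; frozen value 0.9575040241
  eq <- meanfield_equilibria(2, 0)
  expect_equal(nrow(eq), 3)
  expect_equal(sort(eq$state), sort(c(-0.9575040241, 0, 0.9575040241)), tolerance = 1e-6)
  expect_setequal(eq$stability[eq$state == 0], "unstable")
  expect_setequal(eq$stability[eq$state != 0], "stable")

  # residuals, symmetry, and root counts across a parameter sample
  cases <- expand.grid(T = c(0.5, 1.5, 2, 2.12, 3), H = c(0, 0.05, -0.3, 0.7))
  for (i in seq_len(nrow(cases))) {
    eq <- meanfield_equilibria(cases$T[i], cases$H[i])
    expect_true(nrow(eq) %in% c(1, 3))
    resid <- abs(eq$state - tanh(cases$T[i] * eq$state + cases$H[i]))
    expect_lt(max(resid), 1e-9)
    if (cases$H[i] == 0) {
      expect_equal(sort(eq$state), sort(-eq$state), tolerance = 1e-12)
    }
  }
  expect_equal(meanfield_equilibria(0.5, 0)$state, 0)
  expect_equal(meanfield_equilibria(0.5, 0)$stability, "stable")
})

test_that("noise-free trajectories converge into the stable root of their basin", {
  cases <- list(
    list(T = 2, H = 0, m0 = 0.3), list(T = 2, H = 0, m0 = -0.2),
    list(T = 2.12, H = -0.7, m0 = 1.4), list(T = 1.5, H = 0.1, m0 = 0.01)
  )
  for (cs in cases) {
    traj <- simulate_meanfield(
      meanfield_config(cs$T, field = cs$H, sigma = 0, n_steps = 5000, m0 = cs$m0)
    )
    eq <- meanfield_equilibria(cs$T, cs$H)
    stable <- eq$state[eq$stability == "stable"]
    final <- traj$state[nrow(traj)]
    expect_lt(min(abs(final - stable)), 1e-6)
  }
})

test_that("fold points match brute-force root counting and vanish at the pitchfork limit", {
  fp <- fold_points(2.12)
  expect_equal(fp[["lower"]], -fp[["upper"]])
  # brute force: count roots of M = tanh(T M + H) on a fine H grid around
  # the closed-form fold and locate the 1 <-> 3 transition
  count_roots <- function(T, H) {
    g <- seq(-1, 1, by = 1e-3)
    f <- tanh(T * g + H) - g
    sum(abs(diff(sign(f))) > 0)
  }
  Hgrid <- seq(fp[["upper"]] - 0.01, fp[["upper"]] + 0.01, by = 1e-4)
  counts <- vapply(Hgrid, function(h) count_roots(2.12, h), numeric(1))
  boundary <- Hgrid[max(which(counts >= 3))]
  expect_equal(boundary, fp[["upper"]], tolerance = 2e-4)

  # folds collapse to zero as the coupling approaches 1 from above
  expect_lt(fold_points(1.0001)[["upper"]], 1e-4)
  expect_error(fold_points(0.9), "no bistable region")
})

test_that("equilibrium branch curves are continuous and flip stability only at folds", {
  fp <- fold_points(2)
  grid <- seq(-0.6, 0.6, by = 0.01)
  curves <- equilibrium_curves(2, grid, parameter = "H")
  # the H = 0 column carries all three roots
  expect_equal(sum(curves$parameter == 0), 3)
  # single stable branch below threshold
  sub <- equilibrium_curves(0.5, grid, parameter = "H")
  expect_true(all(sub$stability == "stable"))
  expect_equal(sub$state[sub$parameter == 0], 0)
  # continuity within branches
  for (br in unique(curves$branch)) {
    b <- curves[curves$branch == br, ]
    expect_lt(max(abs(diff(b$state))), 0.1)
    # stability is constant within a branch away from the folds
    inner <- b[b$parameter > fp[["lower"]] + 0.02 & b$parameter < fp[["upper"]] - 0.02, ]
    expect_lte(length(unique(inner$stability)), 1)
  }
})
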