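test_that("model potentials evaluate to their closed forms", {
  gw <- potential_spec("gaussian_well", depth = 5, width = 0.5, center = 0,
                       wall_position = 100)
  expect_equal(potential_energy(gw, 0), -5)
  expect_lt(abs(potential_energy(gw, 50)), 1e-9)  # decay limit below the wall
  ha <- potential_spec("harmonic", center = 1, wall_stiffness = 2)
  expect_equal(potential_energy(ha, 2), 1)
  dw <- potential_spec("double_well", depth = 3, width = 0.2,
                       centers = c(0.2, 0.8), wall_position = 100)
  expect_equal(potential_energy(dw, 0.2),
               -3 - 3 * exp(-0.6^2 / (2 * 0.04)))
})

test_that("analytic force matches a central finite difference on every form", {
  specs <- list(
    potential_spec("gaussian_well", depth = 5, width = 0.5, wall_position = 1,
                   wall_stiffness = 60),
    potential_spec("double_well", depth = 4, width = 0.3, centers = c(0.3, 1.2),
                   wall_position = 2, wall_stiffness = 40),
    potential_spec("harmonic", center = 0.5, wall_stiffness = 2)
  )
  h <- 1e-6
  for (spec in specs) {
    s <- seq(0.05, 2.5, length.out = 100)
    f_fd <- (potential_energy(spec, s - h) - potential_energy(spec, s + h)) / (2 * h)
    f_an <- potential_force(spec, s)
    expect_lt(max(abs(f_an - f_fd) / pmax(1, abs(f_an))), 1e-6)
  }
  expect_equal(potential_force(specs[[1]], 0), 0)      # stationary point
  expect_equal(potential_force(specs[[3]], 1.5), -2)   # -k (s - c)
})

test_that("the Euler-Maruyama update is the documented map", {
  p <- dyn_params(dt = 0.01, friction = 1, kT = 1, n_steps = 10, seed = 1)
  expect_equal(step_langevin(1, -1, p, 0), 0.99)  # pure drift
  # vanishing thermal energy: no noise contribution regardless of the draw
  p0 <- dyn_params(dt = 0.01, friction = 1, kT = 1e-300, n_steps = 10, seed = 1)
  expect_equal(step_langevin(0, 0, p0, 3.2), 0, tolerance = 1e-140)
  expect_error(step_langevin(0, NaN, p, 0), "non-finite")
  expect_error(step_langevin(0, 0, p, Inf), "non-finite")
})

test_that("unbiased trajectories are seed-deterministic", {
  spec <- potential_spec("harmonic", center = 0.5, wall_stiffness = 1)
  p <- dyn_params(dt = 0.01, n_steps = 2000, seed = 42)
  t1 <- run_langevin(spec, p, reflect = FALSE)
  t2 <- run_langevin(spec, p, reflect = FALSE)
  expect_identical(t1, t2)
  t3 <- run_langevin(spec, dyn_params(dt = 0.01, n_steps = 2000, seed = 43),
                     reflect = FALSE)
  expect_false(identical(t1$cv, t3$cv))
})

test_that("a long harmonic run reproduces the equilibrium variance kT/k", {
  k <- 2; kT <- 1
  spec <- potential_spec("harmonic", center = 0, wall_stiffness = k)
  p <- dyn_params(dt = 0.01, friction = 1, kT = kT, n_steps = 200000, seed = 7)
  traj <- run_langevin(spec, p, s0 = 0, reflect = FALSE)
  x <- traj$cv[-(1:5000)]  # discard equilibration
  v <- mean(x^2)
  # OU autocorrelation time is friction/(k dt) steps; 3 standard errors of
  # the variance estimate with that effective sample size
  n_eff <- length(x) / (2 * p$friction / (k * p$dt))
  se <- sqrt(2 / n_eff) * kT / k
  expect_lt(abs(v - kT / k), 3 * se + kT / k * k * p$dt / 2)
})

test_that("rmsd is the plain displacement root-mean-square", {
  a <- matrix(rnorm(30), 10, 3)
  expect_identical(rmsd(a, a), 0)
  expect_equal(rmsd(matrix(c(3, 4, 0), 1), matrix(0, 1, 3)), 5)
  f <- matrix(0, 2, 3); f[1, 1] <- 1; f[2, 1] <- 3
  expect_equal(rmsd(f, matrix(0, 2, 3)), sqrt(5))
  b <- matrix(rnorm(30), 10, 3)
  expect_equal(rmsd(a, b), rmsd(b, a))  # symmetry
  expect_error(rmsd(a, matrix(0, 9, 3)), "shape")
})

test_that("COLVAR-style trajectory export round-trips", {
  spec <- potential_spec("harmonic", center = 0, wall_stiffness = 1)
  traj <- run_langevin(spec, dyn_params(dt = 0.01, n_steps = 50, seed = 3))
  path <- withr::local_tempfile()
  write_colvar(traj, path)
  expect_identical(readLines(path, n = 1), "#! FIELDS time cv")
  back <- read_colvar(path)
  expect_equal(back$cv, traj$cv, tolerance = 1e-12)
  expect_error(read_colvar(withr::local_tempfile(lines = "nonsense")), "header")
})
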