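th <- thermo_params(300, 10)

test_that("the well-tempered height rule tempers as exp(-V/((gamma-1)kT))", {
  expect_equal(wt_hill_height(1.2, 0, th), 1.2)
  expect_equal(wt_hill_height(1.0, (th$gamma - 1) * log(2), th), 0.5)
  expect_equal(wt_hill_height(1.0, 3.7, th), exp(-3.7 / 9), tolerance = 1e-9)
  expect_error(thermo_params(300, 1), "> 1")
  expect_error(thermo_params(300, 0.5), "> 1")
})

test_that("deposition appends tempered hills in time order", {
  hl <- deposit_hill(hills(), 1.0, 0, w0 = 1.0, sigma = 0.1, th)
  expect_equal(nrow(hl), 1L)
  expect_equal(hl$height, 1.0)  # first hill sees zero bias
  for (t in 1:10) hl <- deposit_hill(hl, 1.0, t, 1.0, 0.1, th)
  expect_true(all(diff(hl$height) < 0))  # strictly decreasing at a fixed center
  expect_true(all(hl$height <= 1.0))     # tempering ceiling
  expect_error(deposit_hill(hl, 1.0, 5, 1.0, 0.1, th), "out-of-order")
})

test_that("a huge bias factor recovers non-tempered deposition", {
  th_big <- thermo_params(300, 1e9)
  hl <- hills()
  for (t in 0:9) hl <- deposit_hill(hl, 0.5, t, 1.0, 0.1, th_big)
  expect_true(all(abs(hl$height - 1.0) < 1e-6))
})

test_that("bias evaluation equals the per-hill summation oracle", {
  expect_identical(bias_value(hills(), c(0, 1, 2)), c(0, 0, 0))
  one <- hills(time = 1, center = 1, sigma = 0.3, height = 2)
  expect_equal(bias_value(one, 1, t = 5), 2)
  expect_equal(bias_value(one, 1, t = 0.5), 0)  # hill not yet deposited
  hl <- random_hills(50, seed = 101)
  s <- seq(-1, 6, length.out = 200)
  expect_equal(bias_value(hl, s), oracle_bias(hl, s), tolerance = 1e-10)
  t_mid <- median(hl$time)
  expect_equal(bias_value(hl, s, t_mid), oracle_bias(hl, s, t_mid),
               tolerance = 1e-10)
})

test_that("bias accumulates pointwise monotonically in time", {
  hl <- random_hills(40, seed = 7)
  s <- seq(0, 5, length.out = 60)
  ts <- sort(c(0, runif(8, 0, 100), 101))
  prev <- rep(-Inf, length(s))
  for (t in ts) {
    v <- bias_value(hl, s, t)
    expect_true(all(v >= prev - 1e-12))
    expect_true(all(v >= 0))
    prev <- v
  }
})

test_that("HILLS files round-trip within 1e-9 including unit conversion", {
  for (seed in 1:10) {
    hl <- random_hills(100, seed = seed)
    path <- withr::local_tempfile()
    write_hills(hl, path, th)
    back <- read_hills(path, th)
    expect_equal(as.data.frame(back), as.data.frame(hl), tolerance = 1e-9)
  }
})

test_that("HILLS heights written in kJ/mol read back as kT at 300 K", {
  path <- withr::local_tempfile(lines = c(
    "#! FIELDS time cv sigma_cv height biasf",
    "0.5 1.0 0.02 2.494 10"
  ))
  hl <- read_hills(path, th)
  expect_equal(hl$height, 1.0, tolerance = 1e-3)  # kT(300 K) = 2.494 kJ/mol
})

test_that("HILLS parsing reports malformed input with line numbers", {
  th_loc <- thermo_params(300, 10)
  expect_error(read_hills(withr::local_tempfile(lines = "1 2 3"), th_loc),
               "header")
  bad_tok <- withr::local_tempfile(lines = c(
    "#! FIELDS time cv sigma_cv height biasf",
    "0.5 1.0 0.02 1.0 10",
    "1.0 oops 0.02 1.0 10"
  ))
  expect_error(read_hills(bad_tok, th_loc), ":3:")
  bad_time <- withr::local_tempfile(lines = c(
    "#! FIELDS time cv sigma_cv height biasf",
    "2 1.0 0.02 1.0 10",
    "1 1.0 0.02 1.0 10"
  ))
  expect_error(read_hills(bad_time, th_loc), "non-monotone")
  short <- withr::local_tempfile(lines = c(
    "#! FIELDS time cv sigma_cv height biasf",
    "0.5 1.0 0.02"
  ))
  expect_error(read_hills(short, th_loc), "expected 5 fields")
  # header-only file is an empty hill list
  empty <- withr::local_tempfile(lines = "#! FIELDS time rmsd sigma_rmsd height biasf")
  expect_equal(nrow(read_hills(empty, th_loc)), 0L)
  # biasf inconsistent with the declared gamma
  mism <- withr::local_tempfile(lines = c(
    "#! FIELDS time cv sigma_cv height biasf",
    "0.5 1.0 0.02 1.0 15"
  ))
  expect_warning(read_hills(mism, th_loc), "biasf")
})

test_that("the metadynamics engine is seed-deterministic and tempered", {
  spec <- potential_spec("gaussian_well", depth = 4, width = 0.1,
                         wall_position = 1, wall_stiffness = 100)
  p <- dyn_params(n_steps = 20000, seed = 5)
  h1 <- run_wtmetad(spec, p, metad_params(), th)
  h2 <- run_wtmetad(spec, p, metad_params(), th)
  expect_identical(as.data.frame(h1), as.data.frame(h2))
  expect_equal(nrow(h1), 40L)  # n_steps / pace
  w0_kt <- 1.2 / th$kT_kj
  expect_true(all(h1$height <= w0_kt + 1e-12))
  expect_true(all(h1$center >= 0))  # reflecting convention
})
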