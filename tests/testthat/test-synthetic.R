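test_that("zero-noise generation reproduces the exact forward values", {
  study <- default_synthetic_study(noise_sd = 0, n_runs = 2)
  meas <- generate_measurements(study$truth, study$ensemble, study$field,
                                seed = 3)
  ens_true <- oscillator_ensemble(study$ensemble$n_molecules_N,
                                  study$ensemble$strength_NQ2_over_M,
                                  study$truth$gamma_true)
  expected <- forward_permittivity(ens_true, study$field,
                                   study$truth$omega0_true)
  expect_identical(meas$epsilon_r, rep(expected, times = 2))
  expect_identical(attr(meas, "clipped"), 0L)
  expect_true(all(meas$epsilon_r > 1))
})

test_that("generation is seed-deterministic and leaves the caller's RNG alone", {
  study <- default_synthetic_study(noise_sd = 0.05)
  a <- generate_measurements(study$truth, study$ensemble, study$field, seed = 1)
  b <- generate_measurements(study$truth, study$ensemble, study$field, seed = 1)
  c <- generate_measurements(study$truth, study$ensemble, study$field, seed = 2)
  expect_identical(a, b)
  expect_false(identical(a$epsilon_r, c$epsilon_r))
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(
    generate_measurements(study$truth, study$ensemble, study$field, seed = 9))
  expect_identical(runif(1), before)
})

test_that("huge noise is clipped at 1 + 1e-6 with a logged count", {
  study <- default_synthetic_study(noise_sd = 5, n_runs = 10)
  meas <- generate_measurements(study$truth, study$ensemble, study$field,
                                seed = 1)
  expect_true(all(meas$epsilon_r >= 1 + 1e-6))
  expect_gt(attr(meas, "clipped"), 0)
})

test_that("pipeline recovery bias vanishes as the noise level shrinks", {
  bias_at <- function(noise_sd, n_runs, seed) {
    study <- default_synthetic_study(noise_sd = noise_sd, n_runs = n_runs)
    meas <- generate_measurements(study$truth, study$ensemble, study$field,
                                  seed = seed)
    res <- run_sweep(study$registry, meas)
    sols <- attr(res, "solutions")
    max(vapply(seq_along(study$truth$temperatures), function(i) {
      sol <- sols[[sprintf("synthetic@%g", study$truth$temperatures[i])]]
      min(Mod(sol$omega0_roots - study$truth$omega0_true[i])) /
        study$truth$omega0_true[i]
    }, numeric(1)))
  }
  b0 <- bias_at(0, 2, 17)
  b1 <- bias_at(0.01, 20, 17)
  expect_lt(b0, 1e-9)
  expect_lt(b1, 0.01)
  expect_lt(b0, b1)
})

test_that("the example dataset carries the reported values and validates cleanly", {
  fx <- corona_fixture()
  m <- fx$measurements
  lookup <- function(sid, tc) m$epsilon_r[m$sample_id == sid &
                                            m$temperature_C == tc]
  expect_identical(lookup("I", 30), 68)
  expect_identical(lookup("I", 55), 370)
  expect_identical(lookup("P1", 30), 27)
  expect_identical(lookup("P1", 55), 31)
  expect_identical(lookup("P2", 30), 24)
  expect_identical(lookup("P3", 30), 22)
  expect_identical(lookup("IZnO_S", 30), 40)
  expect_identical(lookup("IZnO_S", 55), 167)
  expect_identical(lookup("IZnO_T", 30), 95)
  expect_identical(lookup("IZnO_T", 55), 351)

  sp <- fx$registry$species
  expect_identical(sp$insulin$charge_Q, 74.805e-10)
  expect_identical(sp$insulin$mass_M, 9.52e-18)
  expect_identical(sp$insulin$dipole_lit, 369)
  expect_identical(sp$papain$charge_Q, 4.01e-8)
  expect_identical(sp$papain$mass_M, 3.88e-17)
  expect_identical(sp$papain$dipole_lit, 150)
  expect_true(sp$zno_s$inert && sp$zno_t$inert)

  # 2:1 insulin:ZnO volume ratio in the 250 ul holder
  comp <- fx$registry$samples$IZnO_T$components
  expect_equal(comp$volume[1] / comp$volume[2], 2)
  expect_equal(sum(comp$volume), 250e-6)

  # round-trips through the readers with zero rejected rows
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_table(m, p1)
  expect_no_warning(back <- read_measurements(p1))
  expect_identical(length(attr(back, "rejected_lines")), 0L)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_table(fx$aux, p2)
  expect_no_warning(read_aux(p2))
})

test_that("the installed example data files mirror the in-code dataset", {
  fx <- corona_fixture()
  meas_path <- system.file("extdata", "measurements.csv",
                           package = "lorentzcorona")
  expect_true(nzchar(meas_path))
  expect_equal(read_measurements(meas_path), fx$measurements,
               ignore_attr = TRUE)
  expect_equal(read_aux(system.file("extdata", "aux.csv",
                                    package = "lorentzcorona")),
               fx$aux, ignore_attr = TRUE)
  reg <- read_registry(system.file("extdata", "registry.yaml",
                                   package = "lorentzcorona"))
  expect_equal(reg$species$insulin$charge_Q, 74.805e-10)
  expect_equal(reg$samples$IZnO_T$components$volume,
               fx$registry$samples$IZnO_T$components$volume,
               tolerance = 1e-12)
})
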