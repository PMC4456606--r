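test_that("degenerate isotherms carry no heat", {
  expt <- dilution_experiment()
  expect_equal(forward_isotherm(36, 0, expt)$q_ucal, rep(0, 40))
  # infinitely stable dimer: nothing dissociates on dilution
  expect_equal(forward_isotherm(0, 9328, expt)$q_ucal, rep(0, 40))
})

test_that("the forward model matches a brute-force bookkeeping oracle", {
  expt <- dilution_experiment(
    cell_volume_ul = 200, syringe_conc_um = 1000,
    injection_volumes_ul = rep(1, 5)
  )
  iso <- forward_isotherm(36, 9328, expt)
  q_oracle <- oracle_itc_heats(36, 9328, 200, 1000, rep(1, 5))
  expect_equal(iso$q_ucal, q_oracle, tolerance = 1e-6)
  # single-injection case to high precision
  one <- dilution_experiment(injection_volumes_ul = 1)
  expect_equal(
    forward_isotherm(36, 9328, one)$q_ucal,
    oracle_itc_heats(36, 9328, 200, 1000, 1),
    tolerance = 1e-9
  )
})

test_that("dilution heats decay and the cell monomer fraction falls", {
  iso <- forward_isotherm(36, 9328, dilution_experiment())
  # all heats share the sign of dh
  expect_true(all(iso$q_ucal > 0))
  # first injection has the largest normalised heat, then monotone decay
  expect_equal(which.max(iso$ndh_cal_mol), 1L)
  expect_true(all(diff(iso$ndh_cal_mol) < 0))
  expect_true(all(diff(iso$f_mono) < 0))
  # exothermic-instrument convention flips the sign only
  flipped <- forward_isotherm(36, 9328, dilution_experiment(), sign = -1)
  expect_equal(flipped$q_ucal, -iso$q_ucal)
  # very weak dimer: essentially fully monomeric cell throughout
  weak <- forward_isotherm(1e6, 9328, dilution_experiment())
  expect_true(all(weak$f_mono > 0.99))
  # mass bookkeeping: cell concentration matches direct recursion
  v0 <- 200
  c_ref <- Reduce(function(c, v) (c * (v0 - v) + 1000 * v) / v0,
    rep(1, 40),
    accumulate = TRUE, init = 0
  )[-1]
  expect_equal(iso$c_cell_um, c_ref)
})

test_that("noiseless isotherms round-trip through the fitter exactly", {
  iso <- forward_isotherm(36, 9328, dilution_experiment())
  fit <- fit_dilution(iso)
  expect_equal(fit$kd, 36, tolerance = 1e-4)
  expect_equal(fit$dh, 9328, tolerance = 1e-4)
  expect_equal(fit$baseline, 0, tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("noisy isotherms in the measured regime are recovered", {
  sim <- sim_itc(kd = 36, dh = 9328, noise_frac = 0.01, seed = 8)
  fit <- fit_dilution(sim$data)
  expect_equal(fit$kd, 36, tolerance = 0.20)
  expect_equal(fit$dh, 9328, tolerance = 0.05)
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$se)))
  td <- tidy(fit)
  expect_equal(td$term, c("kd", "dh", "baseline"))
  prof <- percent_dissociated_profile(fit)
  expect_true(all(diff(prof$f_mono) < 0))
})

test_that("unidentifiable isotherms are flagged, weak regimes warned", {
  flat <- tibble::tibble(
    injection = 1:12, volume_ul = 1, q_ucal = rep(0.5, 12)
  )
  expect_warning(
    expect_warning(fit <- fit_dilution(flat), "unidentifiable"),
    "weakly identified"
  )
  expect_false(fit$converged)
  expect_true(fit$flat)
  # syringe fewer than ten-fold above kd: weak identifiability warning
  weak_expt <- dilution_experiment(syringe_conc_um = 300)
  iso <- forward_isotherm(200, 9000, weak_expt)
  expect_warning(fit_dilution(iso, weak_expt), "ten-fold|10 x")
  expect_error(fit_dilution(flat[1:5, ]), "10 injections")
})
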