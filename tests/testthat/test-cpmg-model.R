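nu_grid <- c(25, 50, 75, 100, 150, 175, 200, 300, 600, 1000)

test_that("intensity-to-rate conversion follows -ln(I/I0)/T", {
  expect_equal(r2eff_from_intensities(1, 1, 0.02), 0)
  expect_equal(r2eff_from_intensities(0.5, 1, 0.02), log(2) / 0.02)
  # smaller surviving intensity means faster relaxation
  r <- r2eff_from_intensities(c(0.9, 0.5, 0.1), 1, 0.02)
  expect_true(all(diff(r) > 0))
  expect_error(r2eff_from_intensities(0, 1), "i")
})

test_that("no-exchange limits return the intrinsic rate", {
  expect_equal(carver_richards_r2eff(1000, 0, 500, 15, nu_grid),
               rep(15, length(nu_grid)))
  expect_equal(carver_richards_r2eff(1000, 0.05, 0, 15, nu_grid),
               rep(15, length(nu_grid)))
  expect_equal(bloch_mcconnell_r2eff(1000, 0, 500, 15, nu_grid),
               rep(15, length(nu_grid)))
})

test_that("closed form matches the numerical propagator across regimes", {
  # a representative sub-grid; the full grid is exercised by the
  # acceptance suite
  for (kex in c(300, 1000, 3000)) {
    for (pb in c(0.02, 0.1)) {
      for (dw_ppm in c(1, 4)) {
        dw <- ppm_to_rad_s(dw_ppm, 600)
        cr <- carver_richards_r2eff(kex, pb, dw, 15, nu_grid)
        bm <- bloch_mcconnell_r2eff(kex, pb, dw, 15, nu_grid)
        expect_lt(max(abs(cr - bm)), 0.5)
      }
    }
  }
})

test_that("fast exchange reduces to the Luz-Meiboom form", {
  kex <- 10000
  pb <- 0.03
  dw <- ppm_to_rad_s(1, 600)
  phi <- (1 - pb) * pb * dw^2
  lm <- luz_meiboom_r2eff(kex, phi, 15, nu_grid)
  bm <- bloch_mcconnell_r2eff(kex, pb, dw, 15, nu_grid)
  rex <- lm - 15
  expect_equal(lm, bm, tolerance = 0.02 * max(rex) / max(lm))
  # kex -> infinity: dispersion collapses onto r20
  fast <- bloch_mcconnell_r2eff(1e7, 0.05, ppm_to_rad_s(2, 600), 15, nu_grid)
  expect_equal(fast, rep(15, length(nu_grid)), tolerance = 1e-2)
})

test_that("slow exchange at slow pulsing shows minor-state lifetime broadening", {
  kex <- 200
  pb <- 0.05
  dw <- ppm_to_rad_s(6, 800) # far slow-exchange: dw >> kex
  r <- bloch_mcconnell_r2eff(kex, pb, dw, 15, 25)
  expect_equal(r - 15, pb * kex, tolerance = 0.01)
})

test_that("dispersion profiles are non-increasing in pulsing frequency", {
  nu_dense <- seq(25, 1000, by = 25)
  # intermediate-to-fast exchange: strictly dispersive
  for (kex in c(1500, 3000)) {
    r <- carver_richards_r2eff(kex, 0.05, ppm_to_rad_s(3, 800), 15, nu_dense)
    expect_true(all(diff(r) <= 1e-6))
  }
  # slow exchange (kex << dw): the per-cycle rate carries small coherent
  # ripples on top of a decaying envelope
  r_slow <- carver_richards_r2eff(500, 0.05, ppm_to_rad_s(3, 800), 15,
                                  nu_dense)
  expect_lt(max(diff(r_slow)), 0.2)
  expect_gt(r_slow[1], r_slow[length(r_slow)])
})

test_that("shift differences convert between ppm and rad/s consistently", {
  dw6 <- ppm_to_rad_s(2, 600)
  dw8 <- ppm_to_rad_s(2, 800)
  expect_equal(dw8 / dw6, 800 / 600) # linear in field in rad/s
  expect_equal(rad_s_to_ppm(dw8, 800), 2) # field-invariant in ppm
  expect_equal(ppm_to_rad_s(1, 600) / (2 * pi), 60.82, tolerance = 1e-3)
})

test_that("chi-square target counts sigma-normalised residuals", {
  obs <- c(20, 18, 16)
  expect_equal(chi2_target(obs, obs, 0.5)$chi2, 0)
  calc <- obs
  calc[2] <- obs[2] - 2 * 0.5 # one point off by 2 sigma
  expect_equal(chi2_target(obs, calc, 0.5)$chi2, 4)
  # random Gaussian residuals give reduced chi2 near 1
  set.seed(1)
  o <- rnorm(500, 20, 0.3)
  expect_equal(chi2_target(o, rep(20, 500), 0.3, 3)$chi2_red, 1,
    tolerance = 0.15
  )
})
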