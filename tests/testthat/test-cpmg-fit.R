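test_that("sigma estimation pools duplicate differences per curve", {
  base <- tibble::tibble(
    residue = 1, field_mhz = 600,
    nu_cpmg_hz = c(25, 25, 50, 200, 200, 1000),
    r2eff = c(30, 30.6, 28, 25, 25, 20)
  )
  out <- estimate_sigma_from_repeats(base, sigma_floor = 0.05)
  # pairs differ by 0.6 and 0: pooled sqrt(mean(c(0.36, 0))/2)
  expect_equal(unique(out$sigma), sqrt(mean(c(0.36, 0)) / 2))
  # a single pair differing by d gives |d|/sqrt(2)
  one <- base[1:2, ]
  one$r2eff <- c(30, 30.4)
  expect_equal(
    unique(estimate_sigma_from_repeats(one)$sigma),
    0.4 / sqrt(2),
    tolerance = 1e-12
  )
  # identical duplicates fall back to the floor
  flat <- base
  flat$r2eff <- rep(20, 6)
  expect_equal(unique(estimate_sigma_from_repeats(flat)$sigma), 0.05)
})

test_that("the amplitude screen keeps exactly the dispersive residues", {
  nu <- c(25, 50, 200, 1000)
  mk <- function(res, rex) {
    tibble::tibble(
      residue = res, field_mhz = 600, nu_cpmg_hz = nu,
      r2eff = 15 + rex * c(1, 0.8, 0.3, 0), sigma = 0.3
    )
  }
  data <- dplyr::bind_rows(mk(1, 0), mk(2, 10), mk(3, 7.9), mk(4, 8.1))
  kept <- screen_dispersive_residues(data, threshold = 8)
  expect_setequal(unique(kept$residue), c(2, 4))
  screen <- attr(kept, "screen")
  expect_equal(screen$delta_r2eff[screen$residue == 2], 10)
  # synthetic generator truth: amplitudes above threshold retained
  sim <- sim_dispersion(n_residues = 4, dw_range_ppm = c(3, 5), seed = 9)
  kept2 <- screen_dispersive_residues(sim$data)
  expect_setequal(unique(kept2$residue), 1:4)
})

test_that("single-residue fits recover generating parameters", {
  sim <- sim_dispersion(n_residues = 1, kex_range = c(900, 900), pb = 0.05,
                        dw_range_ppm = c(3, 3), sigma = 0.3, seed = 21)
  fit <- fit_dispersion(sim$data)
  expect_s3_class(fit, "cpmg_fit")
  expect_false(fit$rejected)
  expect_equal(fit$estimate$kex, 900, tolerance = 0.10)
  expect_equal(fit$estimate$pb, 0.05, tolerance = 0.20)
  expect_equal(fit$estimate$dw_ppm, 3, tolerance = 0.10)
  expect_lt(fit$chi2_red, 10)
  # tidy/glance/augment surfaces
  td <- tidy(fit)
  expect_true(all(c("kex", "pb", "dw_ppm") %in% td$term))
  expect_equal(nrow(glance(fit)), 1)
  aug <- augment(fit)
  expect_equal(aug$.resid, aug$r2eff - aug$.fitted)
})

test_that("a flat profile yields no spurious exchange", {
  # at near-zero noise the fitted dispersion amplitude is negligible
  sim <- sim_dispersion(n_residues = 1, dw_range_ppm = c(0, 0),
                        sigma = 1e-3, seed = 5)
  fit <- fit_dispersion(sim$data)
  rex <- augment(fit) |>
    dplyr::group_by(.data$field_mhz) |>
    dplyr::summarise(rex = max(.data$.fitted) - min(.data$.fitted))
  expect_true(fit$rejected || max(rex$rex) < 0.05)
  # at realistic noise a flat residue never reaches the fitter: the
  # amplitude screen removes it
  noisy <- sim_dispersion(n_residues = 1, dw_range_ppm = c(0, 0),
                          sigma = 0.3, seed = 5)
  expect_equal(nrow(screen_dispersive_residues(noisy$data)), 0)
})

test_that("the fast-exchange model fits the composite amplitude", {
  sim <- sim_dispersion(n_residues = 1, kex_range = c(3000, 3000), pb = 0.05,
                        dw_range_ppm = c(2, 2), sigma = 0.2, seed = 31)
  fit <- fit_dispersion(sim$data, model = "model2")
  expect_equal(fit$model, "model2")
  expect_false(fit$rejected)
  # phi = pa pb dw^2 in ppm^2
  expect_equal(fit$estimate$phi_ppm2, 0.95 * 0.05 * 4, tolerance = 0.25)
  expect_equal(fit$estimate$kex, 3000, tolerance = 0.15)
})

test_that("global fits share kex and pb across a residue group", {
  sim <- sim_dispersion(n_residues = 3, shared_kex = TRUE,
                        dw_range_ppm = c(2, 4), sigma = 0.3, seed = 13)
  g <- global_fit(sim$data)
  expect_equal(g$kex, sim$truth$kex[1], tolerance = 0.05)
  expect_equal(g$pb, 0.05, tolerance = 0.05)
  expect_equal(g$per_residue$dw_ppm, sim$truth$dw_ppm, tolerance = 0.05)
  expect_false(g$rejected)
  # single-residue group reduces to the individual fit
  one <- sim$data[sim$data$residue == 1, ]
  g1 <- global_fit(one)
  f1 <- fit_dispersion(one)
  expect_equal(g1$kex, f1$estimate$kex, tolerance = 0.02)
  expect_equal(g1$per_residue$dw_ppm, f1$estimate$dw_ppm, tolerance = 0.02)
})

test_that("a heterogeneous-kex group fits worse globally than individually", {
  lo <- sim_dispersion(n_residues = 1, kex_range = c(400, 400),
                       dw_range_ppm = c(3, 3), sigma = 0.2, seed = 41)
  hi <- sim_dispersion(n_residues = 1, kex_range = c(3000, 3000),
                       dw_range_ppm = c(3, 3), sigma = 0.2, seed = 42)
  hi$data$residue <- 2
  both <- dplyr::bind_rows(lo$data, hi$data)
  g <- global_fit(both)
  indiv <- fit_dispersion_all(both)
  expect_gt(g$chi2_red, max(indiv$chi2_red) * 2)
})

test_that("Monte Carlo errors shrink with sigma and are seed-stable", {
  sim <- sim_dispersion(n_residues = 1, kex_range = c(900, 900),
                        dw_range_ppm = c(3, 3), sigma = 0.3, seed = 55)
  fit <- fit_dispersion(sim$data)
  # reproducible under a fixed seed
  a <- monte_carlo_errors(fit, n = 15, seed = 99)
  b <- monte_carlo_errors(fit, n = 15, seed = 99)
  expect_identical(a$mc_errors, b$mc_errors)
  expect_true(all(a$mc_errors > 0))
  # errors scale with the noise level (4x sigma -> roughly 4x error)
  small <- fit
  small$data$sigma <- small$data$sigma / 4
  e_small <- monte_carlo_errors(small, n = 25, seed = 7)$mc_errors
  big <- fit
  e_big <- monte_carlo_errors(big, n = 25, seed = 7)$mc_errors
  ratio <- e_big["kex"] / e_small["kex"]
  expect_gt(ratio, 2)
  expect_lt(ratio, 8)
  # near-zero noise gives near-zero parameter scatter
  tiny <- fit
  tiny$data$sigma <- 1e-4
  tiny$data$r2eff <- augment(fit)$.fitted
  e_tiny <- monte_carlo_errors(tiny, n = 10, seed = 3)$mc_errors
  expect_lt(e_tiny["kex"] / fit$estimate$kex, 1e-3)
})
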