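test_that("solve_dimer_monomer reproduces the worked concentration examples", {
  # tight dimer at NMR concentrations: ~4% monomer
  eq <- solve_dimer_monomer(kd = 2, c_total = 700)
  expect_equal(round(100 * eq$f_mono), 4)

  # weaker dimer at 37 degrees: ~100 uM monomer (103.6 exact)
  eq36 <- solve_dimer_monomer(kd = 36, c_total = 700)
  expect_equal(eq36$m, 103.6, tolerance = 1e-3)

  # infinitely tight dimer
  eq0 <- solve_dimer_monomer(kd = 0, c_total = 700)
  expect_equal(eq0$m, 0)
  expect_equal(eq0$d, 350)

  # frozen value from the bisection oracle at 200 uM
  expect_equal(solve_dimer_monomer(36, 200)$m, 51.67, tolerance = 1e-3)
})

test_that("the closed-form root agrees with a bisection oracle", {
  set.seed(42)
  kd <- 10^runif(50, -3, 4)
  ct <- 10^runif(50, -3, 4)
  m <- solve_dimer_monomer(kd, ct)$m
  m_oracle <- mapply(oracle_monomer_bisect, kd, ct)
  expect_equal(m, m_oracle, tolerance = 1e-8)
})

test_that("mass balance and the equilibrium relation hold over random inputs", {
  set.seed(7)
  kd <- 10^runif(100, -3, 4)
  ct <- 10^runif(100, -3, 4)
  eq <- solve_dimer_monomer(kd, ct)
  expect_equal(eq$m + 2 * eq$d, eq$c_total, tolerance = 1e-9)
  # d = (c - m)/2 suffers cancellation as f_mono -> 1, so the recovered
  # kd is checked a shade looser than mass balance
  nz <- eq$d > 1e-12
  expect_equal(eq$m[nz]^2 / eq$d[nz], eq$kd[nz], tolerance = 1e-6)
  expect_true(all(eq$f_mono >= 0 & eq$f_mono <= 1))
})

test_that("monomer fraction is monotone in concentration and in kd", {
  ct <- 10^seq(0, 4, length.out = 30)
  f <- solve_dimer_monomer(36, ct)$f_mono
  expect_true(all(diff(f) < 0))
  kd <- 10^seq(-2, 3, length.out = 30)
  f2 <- solve_dimer_monomer(kd, 700)$f_mono
  expect_true(all(diff(f2) > 0))
})

test_that("decompose_kex reproduces the printed rate constants", {
  kin <- decompose_kex(kex = 1500, kd = 36, c_total = 700)
  expect_equal(kin$kmd, 1.1e7, tolerance = 0.05)
  expect_equal(kin$kdm, 400, tolerance = 0.05)
  # the returned triple satisfies both constraints exactly
  expect_equal(kin$kmd * kin$m * 1e-6 + kin$kdm, 1500)
  expect_equal(kin$kdm / kin$kmd * 1e6, 36)
})

test_that("kd = 0 decomposition is degenerate with a warning", {
  expect_warning(kin <- decompose_kex(1500, 0, 700), "degenerate")
  expect_equal(kin$kdm, 0)
})

test_that("predict_kex matches forward arithmetic and round-trips", {
  # printed-value forward check
  pred <- predict_kex(kmd = 1.1e7, kdm = 400, c_total = 700)
  expect_equal(pred$kex, 1545, tolerance = 0.01)
  # frozen oracle arithmetic at 200 uM from the calibrated pair
  kin <- decompose_kex(1500, 36, 700)
  p200 <- predict_kex(kin$kmd, kin$kdm, 200)
  expect_equal(p200$kex, 941.9, tolerance = 1e-3)
  # round trip at the calibration concentration is exact
  p700 <- predict_kex(kin$kmd, kin$kdm, 700)
  expect_equal(p700$kex, 1500, tolerance = 1e-12)
  # no association: kex is just kdm
  expect_equal(predict_kex(0, 400, 123)$kex, 400)
  # monotone non-decreasing in total concentration
  curve <- predict_kex(kin$kmd, kin$kdm, seq(10, 2000, by = 10))
  expect_true(all(diff(curve$kex) >= 0))
})

test_that("subunit counts use round-half-up on mw / monomer mass", {
  out <- subunits_from_mw(c(720, 20, 810), monomer_mass = 20)
  expect_equal(out$n_subunits, c(36L, 1L, 41L))
  expect_equal(out$n_subunits_real[3], 40.5)
})

test_that("invalid equilibrium inputs error", {
  expect_error(solve_dimer_monomer(-1, 700), "kd")
  expect_error(solve_dimer_monomer(2, 0), "c_total")
  expect_error(subunits_from_mw(0, 20), "mw")
})
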