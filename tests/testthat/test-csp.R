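test_that("combined perturbations follow the scaled quadrature formula", {
  expect_equal(compute_csp(0, 0), 0)
  expect_equal(compute_csp(0.1, 1.0), sqrt(0.01 + 0.04) / sqrt(2))
  expect_equal(compute_csp(0.1, 1.0), 0.158, tolerance = 1e-3)
  # symmetric under sign flips of either input
  expect_equal(compute_csp(-0.1, 1.0), compute_csp(0.1, 1.0))
  expect_equal(compute_csp(0.1, -1.0), compute_csp(0.1, 1.0))
  # a norm: zero iff both zero, linear under joint scaling
  expect_gt(compute_csp(1e-4, 0), 0)
  expect_equal(compute_csp(0.2, 2.0), 2 * compute_csp(0.1, 1.0))
})

test_that("perturbation classes use left-closed boundaries", {
  expect_equal(as.character(classify_csp(c(0.05, 0.15, 0.25))),
               c("minor", "moderate", "strong"))
  # boundary values are deterministic: [0.1, 0.2] is moderate
  expect_equal(as.character(classify_csp(c(0.1, 0.2, 0.2000001))),
               c("moderate", "moderate", "strong"))
})

test_that("csp_table joins two conditions and classifies each residue", {
  a <- tibble::tibble(residue = 1:3, hn_ppm = c(8.0, 8.5, 9.0),
                      n_ppm = c(110, 115, 120))
  b <- tibble::tibble(residue = 1:3, hn_ppm = c(8.0, 8.55, 9.2),
                      n_ppm = c(110, 116, 121.5))
  out <- csp_table(a, b)
  expect_equal(out$delta[1], 0)
  expect_equal(out$delta, compute_csp(out$d_hn, out$d_n))
  expect_equal(as.character(out$csp_class[1]), "minor")
})

test_that("exchange regimes follow peak doubling across the series", {
  data <- dplyr::bind_rows(
    tibble::tibble(residue = 1, ph = c(8.4, 7.5, 7.0, 6.5),
                   doubled = FALSE),
    tibble::tibble(residue = 2, ph = c(8.4, 7.5, 7.0, 6.5),
                   doubled = c(FALSE, FALSE, TRUE, TRUE)),
    tibble::tibble(residue = 3, ph = c(8.4, 7.5, 7.0, 6.5),
                   doubled = TRUE)
  )
  out <- classify_exchange_regime(data)
  expect_equal(out$regime, c("fast", "mixed", "slow"))
})

test_that("identical shift vectors give perfect concordance", {
  fits <- tibble::tibble(residue = 1:5, dw_ppm = c(1, 2, 3, 4, 5))
  csp <- tibble::tibble(residue = 1:5, d_n = -c(1, 2, 3, 4, 5))
  out <- compare_dw_csp(fits, csp)
  conc <- attr(out, "concordance")
  expect_equal(conc$pearson_r, 1)
  expect_equal(conc$mean_abs_diff, 0)
})

test_that("disjoint residue sets give an empty comparison with a warning", {
  fits <- tibble::tibble(residue = 1:3, dw_ppm = 1:3)
  csp <- tibble::tibble(residue = 4:6, d_n = 1:3)
  expect_warning(out <- compare_dw_csp(fits, csp), "common")
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "concordance")$n, 0L)
})

test_that("generated peak lists reproduce programmed offsets and regimes", {
  truth <- tibble::tibble(residue = 1:6, dw_ppm = seq(0.5, 5.5, 1))
  pl <- sim_peaklists(truth, noise_hn_ppm = 0, noise_n_ppm = 0, seed = 3)
  a <- dplyr::filter(pl$data, condition == "reference")
  b <- dplyr::filter(pl$data, condition == "low_ph")
  out <- csp_table(a, b)
  expect_equal(out$d_n, truth$dw_ppm)
  # low-pH condition is 50/50: every resolvable residue doubles there
  expect_true(all(b$doubled))
  expect_false(any(a$doubled))
  regimes <- classify_exchange_regime(pl$data)
  expect_true(all(regimes$regime == "mixed"))
})
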