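#' Tidy a CPMG dispersion fit
#'
#' @param x A `cpmg_fit` object.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`
#'   (Monte Carlo SD when [monte_carlo_errors()] has been run, `NA`
#'   otherwise).
#' @exportS3Method generics::tidy
tidy.cpmg_fit <- function(x, ...) {
  est <- x$estimate
  terms <- if (x$model == "model2") {
    c(kex = est$kex, phi_ppm2 = est$phi_ppm2)
  } else {
    c(kex = est$kex, pb = est$pb, dw_ppm = est$dw_ppm)
  }
  terms <- c(terms, setNames(est$r20, paste0("r20_", names(est$r20))))
  se <- rep(NA_real_, length(terms))
  names(se) <- names(terms)
  if (!is.null(x$mc_errors)) {
    common <- intersect(names(se), names(x$mc_errors))
    se[common] <- x$mc_errors[common]
  }
  tibble::tibble(
    term = names(terms),
    estimate = unname(terms),
    std.error = unname(se)
  )
}

#' Summarise a CPMG dispersion fit in one row
#'
#' @param x A `cpmg_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with the residue, model, fitted parameters,
#'   chi-square statistics and acceptance flags.
#' @exportS3Method generics::glance
glance.cpmg_fit <- function(x, ...) {
  tibble::tibble(
    residue = x$residue,
    model = x$model,
    kex = x$estimate$kex,
    pb = x$estimate$pb,
    dw_ppm = x$estimate$dw_ppm,
    phi_ppm2 = x$estimate$phi_ppm2,
    chi2 = x$chi2,
    chi2_red = x$chi2_red,
    n_points = x$n_points,
    n_params = x$n_params,
    converged = x$converged,
    rejected = x$rejected
  )
}

#' Augment the data of a CPMG dispersion fit with fitted values
#'
#' @param x A `cpmg_fit` object.
#' @param ... Unused.
#' @return The fit's data with `.fitted` and `.resid` columns.
#' @exportS3Method generics::augment
augment.cpmg_fit <- function(x, ...) {
  calc <- cpmg_calc(
    if (x$model == "model2") "model2" else "model3", x$data,
    kex = x$estimate$kex, pb = x$estimate$pb,
    dw_ppm = x$estimate$dw_ppm, phi_ppm2 = x$estimate$phi_ppm2,
    r20_by_field = as.list(x$estimate$r20), t_relax = x$t_relax
  )
  dplyr::mutate(x$data, .fitted = calc, .resid = .data$r2eff - calc)
}

#' @rdname tidy.cpmg_fit
#' @exportS3Method generics::tidy
tidy.cpmg_global_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(
      residue = NA_integer_,
      term = c("kex", "pb"), estimate = c(x$kex, x$pb)
    ),
    tibble::tibble(
      residue = x$per_residue$residue,
      term = "dw_ppm", estimate = x$per_residue$dw_ppm
    )
  )
}

#' @rdname glance.cpmg_fit
#' @exportS3Method generics::glance
glance.cpmg_global_fit <- function(x, ...) {
  tibble::tibble(
    n_residues = length(x$residues),
    kex = x$kex, pb = x$pb,
    chi2 = x$chi2, chi2_red = x$chi2_red,
    n_points = x$n_points, n_params = x$n_params,
    converged = x$converged, rejected = x$rejected
  )
}

#' Tidy a pK_R titration fit
#'
#' @param x A `pkr_fit` object.
#' @param ... Unused.
#' @return One row per parameter with `term`, `estimate`, `std.error`.
#' @exportS3Method generics::tidy
tidy.pkr_fit <- function(x, ...) {
  tibble::tibble(
    term = c("pkr", "delta_ha", "delta_a"),
    estimate = c(x$pkr, x$delta_ha, x$delta_a),
    std.error = unname(x$se)
  )
}

#' Summarise a pK_R titration fit in one row
#'
#' @param x A `pkr_fit` object.
#' @param ... Unused.
#' @return One-row tibble with `atom_id`, `pkr`, asymptote shifts,
#'   `status` and the reported `bound` for below-range fits.
#' @exportS3Method generics::glance
glance.pkr_fit <- function(x, ...) {
  tibble::tibble(
    atom_id = x$atom_id,
    pkr = x$pkr,
    pkr_se = unname(x$se["pkr"]),
    delta_ha = x$delta_ha,
    delta_a = x$delta_a,
    status = x$status,
    bound = x$bound,
    n = nrow(x$data)
  )
}

#' @rdname tidy.pkr_fit
#' @exportS3Method generics::augment
augment.pkr_fit <- function(x, ...) {
  if (x$status == "undetermined") {
    return(dplyr::mutate(x$data, .fitted = NA_real_, .resid = NA_real_))
  }
  calc <- hh_forward(x$data$ph, x$pkr, x$delta_ha, x$delta_a)
  dplyr::mutate(x$data, .fitted = calc, .resid = .data$shift_ppm - calc)
}

#' Tidy an ITC dilution fit
#'
#' @param x A `dilution_fit` object.
#' @param ... Unused.
#' @return One row per parameter with `term`, `estimate`, `std.error`.
#' @exportS3Method generics::tidy
tidy.dilution_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kd", "dh", "baseline"),
    estimate = c(x$kd, x$dh, x$baseline),
    std.error = unname(x$se)
  )
}

#' Summarise an ITC dilution fit in one row
#'
#' @param x A `dilution_fit` object.
#' @param ... Unused.
#' @return One-row tibble with `kd` (uM), `dh` (cal/mol), `baseline`
#'   (ucal), their standard errors, residual sum of squares and flags.
#' @exportS3Method generics::glance
glance.dilution_fit <- function(x, ...) {
  tibble::tibble(
    kd = x$kd, kd_se = unname(x$se["kd"]),
    dh = x$dh, dh_se = unname(x$se["dh"]),
    baseline = x$baseline,
    rss = x$rss, n = x$n,
    converged = x$converged, flat = x$flat
  )
}

#' @rdname tidy.dilution_fit
#' @exportS3Method generics::augment
augment.dilution_fit <- function(x, ...) {
  dplyr::mutate(x$data,
    .fitted = x$fitted, .resid = .data$q_ucal - x$fitted
  )
}
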