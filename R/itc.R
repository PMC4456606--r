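#' Define a dilution-ITC experiment geometry
#'
#' Concentrated, predominantly dimeric protein in the syringe is
#' injected into buffer in the cell; dissociation upon dilution releases
#' measurable heat. Defaults follow common practice for a dissociating
#' alpha-crystallin domain: a 200 ul cell, 1 mM (subunit) syringe stock
#' and forty 1 ul injections.
#'
#' @param cell_volume_ul Active cell volume (ul); default 200.
#' @param syringe_conc_um Syringe total subunit concentration (uM);
#'   default 1000.
#' @param injection_volumes_ul Injection volumes (ul); default
#'   `rep(1, 40)`.
#' @param temperature_c Temperature (deg C, annotation only).
#' @return A `dilution_experiment` list.
#' @export
dilution_experiment <- function(cell_volume_ul = 200,
                                syringe_conc_um = 1000,
                                injection_volumes_ul = rep(1, 40),
                                temperature_c = 37) {
  check_number(cell_volume_ul, "cell_volume_ul", min = 0, allow_zero = FALSE)
  check_number(syringe_conc_um, "syringe_conc_um", min = 0, allow_zero = FALSE)
  check_number(injection_volumes_ul, "injection_volumes_ul",
    min = 0, allow_zero = FALSE
  )
  if (length(injection_volumes_ul) < 1) abort("Need at least one injection.")
  structure(
    list(
      cell_volume_ul = cell_volume_ul,
      syringe_conc_um = syringe_conc_um,
      injection_volumes_ul = injection_volumes_ul,
      temperature_c = temperature_c
    ),
    class = "dilution_experiment"
  )
}

#' Forward-model a homodimer dissociation dilution isotherm
#'
#' Tracks the cell composition injection by injection. The syringe
#' material is pre-equilibrated at the syringe concentration. Each
#' injection of volume `v` into the constant-volume cell displaces an
#' equal volume of the pre-injection cell mixture (the standard
#' perfusion/overflow approximation), after which the cell re-equilibrates
#' at its new total subunit concentration. The heat of injection `i` is
#'
#' `q_i = dh * (increase in moles of dissociated dimer)`,
#'
#' i.e. `dh` times half the monomer moles created in the cell beyond
#' those carried in by the (pre-equilibrated) injectant, with equilibria
#' from [solve_dimer_monomer()]. With `dh` the dissociation enthalpy in
#' cal/mol of dimer, positive `dh` (endothermic dissociation) gives
#' positive heats; instruments that report exothermic deflections
#' negative can be matched with `sign = -1`.
#'
#' @param kd Dimer dissociation constant (uM).
#' @param dh Dissociation enthalpy (cal per mol of dimer).
#' @param experiment A [dilution_experiment()].
#' @param baseline_ucal Constant per-injection offset (ucal, e.g. heat
#'   of mechanical injection); default 0.
#' @param sign +1 (default) to report dissociation heats with the sign
#'   of `dh`; -1 for the instrument's exothermic-negative convention.
#' @return A tibble with `injection`, `volume_ul`, `c_cell_um` (total
#'   subunit concentration after injection), `f_mono` (cell monomer
#'   fraction), `q_ucal` (heat), and `ndh_cal_mol` (heat normalised per
#'   mole of injected subunits).
#' @export
#' @examples
#' forward_isotherm(kd = 36, dh = 9328, dilution_experiment())
forward_isotherm <- function(kd, dh, experiment = dilution_experiment(),
                             baseline_ucal = 0, sign = 1) {
  stopifnot(inherits(experiment, "dilution_experiment"))
  check_number(kd, "kd", min = 0)
  v0 <- experiment$cell_volume_ul
  cs <- experiment$syringe_conc_um
  monomer_at <- function(c_tot) (-kd + sqrt(kd^2 + 8 * kd * c_tot)) / 4
  m_syr <- monomer_at(cs)
  vols <- experiment$injection_volumes_ul
  n_inj <- length(vols)
  c_cell <- 0
  m_cell <- 0
  c_out <- f_out <- q_out <- numeric(n_inj)
  for (i in seq_len(n_inj)) {
    v <- vols[i]
    # displaced-volume overflow: v ul of pre-injection mixture leaves
    c_new <- (c_cell * (v0 - v) + cs * v) / v0
    m_new <- monomer_at(c_new)
    # monomer moles created by re-equilibration, in pmol (uM * ul)
    dn_mono <- m_new * v0 - (m_cell * (v0 - v) + m_syr * v)
    dn_diss <- dn_mono / 2 # mol dimer dissociated, pmol
    c_out[i] <- c_new
    f_out[i] <- m_new / c_new
    q_out[i] <- sign * (dh * dn_diss * 1e-12 * 1e6) + baseline_ucal # ucal
    c_cell <- c_new
    m_cell <- m_new
  }
  tibble::tibble(
    injection = seq_len(n_inj), volume_ul = vols,
    c_cell_um = c_out, f_mono = f_out,
    q_ucal = q_out,
    ndh_cal_mol = q_out * 1e-6 / (cs * vols * 1e-12)
  )
}

#' Fit a dimer-dissociation model to a dilution isotherm
#'
#' Least-squares fit of `(kd, dh, baseline)` to measured injection heats
#' using the forward model of [forward_isotherm()]. `kd` is fitted on a
#' log scale. Standard errors come from the Jacobian-based covariance at
#' the optimum. Identifiability requires the syringe concentration to be
#' roughly ten-fold above `kd`; the fitter warns otherwise and flags
#' isotherms that carry no curvature (non-dissociating species).
#'
#' @param iso Tibble with columns `injection`, `volume_ul`, `q_ucal` (as
#'   written by [forward_isotherm()] or read from an injection table).
#' @param experiment A [dilution_experiment()]; its injection volumes are
#'   taken from `iso`.
#' @param sign Heat sign convention passed to the forward model.
#' @param start Optional named list with `kd`, `dh` start values.
#' @return A `dilution_fit` object.
#' @export
#' @examples
#' iso <- forward_isotherm(36, 9328, dilution_experiment())
#' fit_dilution(iso, dilution_experiment())
fit_dilution <- function(iso, experiment = dilution_experiment(), sign = 1,
                         start = NULL) {
  need <- c("injection", "volume_ul", "q_ucal")
  if (!all(need %in% names(iso))) {
    abort(paste("`iso` must have columns", paste(need, collapse = ", ")))
  }
  if (nrow(iso) < 10) abort("Need at least 10 injections to fit.")
  iso <- dplyr::arrange(iso, .data$injection)
  experiment$injection_volumes_ul <- iso$volume_ul
  q <- iso$q_ucal
  flat <- sd(q) < 1e-9 || diff(range(abs(q))) < 1e-6 * max(abs(q), 1e-12)
  if (is.null(start)) {
    start <- list(kd = experiment$syringe_conc_um / 20, dh = NULL)
  }
  # dh scale from the first heat if not given
  model_q <- function(kd, dh, baseline) {
    forward_isotherm(kd, dh, experiment,
      baseline_ucal = baseline, sign = sign
    )$q_ucal
  }
  if (is.null(start$dh)) {
    unit <- model_q(start$kd, 1, 0)
    start$dh <- sum(unit * q) / sum(unit^2)
  }
  obj <- function(p) {
    sum((q - model_q(exp(p[1]), p[2], p[3]))^2)
  }
  res <- optim(c(log(start$kd), start$dh, 0), obj,
    method = "Nelder-Mead",
    control = list(maxit = 5000, reltol = 1e-12)
  )
  res2 <- optim(res$par, obj,
    method = "Nelder-Mead",
    control = list(maxit = 5000, reltol = 1e-12)
  )
  # a restarted simplex that cannot improve further has converged even
  # when the first run hit its iteration cap
  improved <- (res$value - res2$value) > 1e-10 * max(res$value, 1e-30)
  converged <- !flat && (res2$convergence == 0 || !improved)
  res <- res2
  kd_hat <- exp(res$par[1])
  dh_hat <- res$par[2]
  b_hat <- res$par[3]
  if (flat) {
    warn("Isotherm is flat: kd is unidentifiable; fit flagged.")
  }
  if (experiment$syringe_conc_um < 10 * kd_hat) {
    warn(paste(
      "Syringe concentration is below ~10 x fitted kd;",
      "the dissociation constant is weakly identified."
    ))
  }
  # SEs from the numeric Jacobian of residuals at the optimum
  se <- rep(NA_real_, 3)
  if (converged) {
    pars <- c(log(kd_hat), dh_hat, b_hat)
    eps <- pmax(abs(pars) * 1e-4, 1e-6)
    jac <- sapply(1:3, function(j) {
      pp <- pars; pp[j] <- pp[j] + eps[j]
      pm <- pars; pm[j] <- pm[j] - eps[j]
      (model_q(exp(pp[1]), pp[2], pp[3]) -
        model_q(exp(pm[1]), pm[2], pm[3])) / (2 * eps[j])
    })
    s2 <- res$value / max(length(q) - 3, 1)
    cov <- try(solve(crossprod(jac)) * s2, silent = TRUE)
    if (!inherits(cov, "try-error")) {
      se <- sqrt(pmax(diag(cov), 0))
      se[1] <- se[1] * kd_hat # delta method for log-kd
    }
  }
  structure(
    list(
      kd = kd_hat, dh = dh_hat, baseline = b_hat,
      se = c(kd = se[1], dh = se[2], baseline = se[3]),
      rss = res$value,
      n = length(q),
      converged = converged, flat = flat,
      sign = sign, experiment = experiment,
      data = tibble::as_tibble(iso),
      fitted = model_q(kd_hat, dh_hat, b_hat)
    ),
    class = "dilution_fit"
  )
}

#' @export
print.dilution_fit <- function(x, ...) {
  cat(sprintf(
    "<dilution_fit> kd = %.3g uM (+/- %.2g), dh = %.0f cal/mol (+/- %.2g)%s\n",
    x$kd, x$se["kd"], x$dh, x$se["dh"],
    if (!x$converged) " [flagged]" else ""
  ))
  invisible(x)
}

#' Per-injection dissociation diagnostics for a fitted isotherm
#'
#' Re-runs the forward model at the fitted parameters and returns the
#' monomer fraction in the cell after each injection; as material
#' accumulates the cell concentration rises and the monomer fraction
#' falls, which is why the first injections carry the largest normalised
#' heats.
#'
#' @param fit A `dilution_fit` object.
#' @return Tibble with `injection`, `c_cell_um`, `f_mono`,
#'   `ndh_cal_mol`.
#' @export
percent_dissociated_profile <- function(fit) {
  stopifnot(inherits(fit, "dilution_fit"))
  forward_isotherm(fit$kd, fit$dh, fit$experiment,
    baseline_ucal = fit$baseline, sign = fit$sign
  ) |>
    dplyr::select("injection", "c_cell_um", "f_mono", "ndh_cal_mol")
}
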