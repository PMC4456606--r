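#' The chi-square target function for dispersion fits
#'
#' `chi2 = sum(((obs - calc) / sigma)^2)` over all CPMG frequencies (and
#' fields); the reduced value divides by `n - n_params`.
#'
#' @param obs Observed R2,eff values (s^-1).
#' @param calc Calculated R2,eff values (same length).
#' @param sigma Per-point uncertainties (s^-1, > 0).
#' @param n_params Number of fitted parameters (for the reduced value).
#' @return A list with `chi2` and `chi2_red`.
#' @export
chi2_target <- function(obs, calc, sigma, n_params = 0) {
  check_number(sigma, "sigma", min = 0, allow_zero = FALSE)
  if (length(obs) != length(calc)) {
    abort("`obs` and `calc` must have the same length.")
  }
  chi2 <- sum(((obs - calc) / sigma)^2)
  dof <- length(obs) - n_params
  list(chi2 = chi2, chi2_red = if (dof > 0) chi2 / dof else NA_real_)
}

#' Estimate per-curve R2,eff uncertainty from repeated frequencies
#'
#' Uncertainties are estimated from duplicate measurements: frequencies
#' recorded twice (conventionally 25 and 200 Hz) give paired differences
#' `d`, and the pooled standard deviation `sqrt(mean(d^2) / 2)` per curve
#' (residue x field) is broadcast to all points of that curve. A floor
#' keeps degenerate (identical-duplicate) curves from claiming zero
#' uncertainty.
#'
#' @param data Dispersion tibble with columns `residue`, `field_mhz`,
#'   `nu_cpmg_hz`, `r2eff`.
#' @param sigma_floor Minimum sigma (s^-1); default 0.05.
#' @return The input with a `sigma` column added (replaced if present).
#' @export
estimate_sigma_from_repeats <- function(data, sigma_floor = 0.05) {
  check_number(sigma_floor, "sigma_floor", min = 0, allow_zero = FALSE)
  need <- c("residue", "field_mhz", "nu_cpmg_hz", "r2eff")
  if (!all(need %in% names(data))) {
    abort(paste("`data` must have columns", paste(need, collapse = ", ")))
  }
  sig <- data |>
    dplyr::group_by(.data$residue, .data$field_mhz, .data$nu_cpmg_hz) |>
    dplyr::filter(dplyr::n() == 2) |>
    dplyr::summarise(d = diff(.data$r2eff), .groups = "drop_last") |>
    dplyr::summarise(sigma = sqrt(mean(.data$d^2) / 2), .groups = "drop")
  data |>
    dplyr::select(-dplyr::any_of("sigma")) |>
    dplyr::left_join(sig, by = c("residue", "field_mhz")) |>
    dplyr::mutate(sigma = pmax(
      dplyr::coalesce(.data$sigma, sigma_floor), sigma_floor
    ))
}

#' Screen residues for dispersive behaviour
#'
#' Keeps residues whose dispersion amplitude
#' `R2,eff(nu_low) - R2,eff(nu_high)` exceeds a threshold (8 s^-1 by
#' convention, with the amplitude read at 25 Hz and 1000 Hz). Duplicate
#' points at either frequency are averaged. A residue is retained if any
#' field passes.
#'
#' @param data Dispersion tibble (`residue`, `field_mhz`, `nu_cpmg_hz`,
#'   `r2eff`, optionally `sigma`).
#' @param threshold Minimum amplitude (s^-1); default 8.
#' @param nu_low,nu_high Frequencies (Hz) at which the "0" and "infinity"
#'   plateaus are read; defaults 25 and 1000.
#' @return The rows of `data` for retained residues; the per-residue
#'   screening table is attached as attribute `"screen"`.
#' @export
screen_dispersive_residues <- function(data, threshold = 8,
                                       nu_low = 25, nu_high = 1000) {
  screen <- data |>
    dplyr::filter(.data$nu_cpmg_hz %in% c(nu_low, nu_high)) |>
    dplyr::group_by(.data$residue, .data$field_mhz) |>
    dplyr::summarise(
      delta_r2eff = mean(.data$r2eff[.data$nu_cpmg_hz == nu_low]) -
        mean(.data$r2eff[.data$nu_cpmg_hz == nu_high]),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$residue) |>
    dplyr::summarise(
      delta_r2eff = max(.data$delta_r2eff),
      dispersive = .data$delta_r2eff > threshold,
      .groups = "drop"
    )
  keep <- screen$residue[screen$dispersive]
  out <- dplyr::filter(data, .data$residue %in% keep)
  attr(out, "screen") <- screen
  out
}

# evaluate calculated r2eff for rows of one residue given natural params
cpmg_calc <- function(model, rows, kex, pb, dw_ppm, phi_ppm2, r20_by_field,
                      t_relax) {
  fields <- names(r20_by_field)
  out <- numeric(nrow(rows))
  for (f in fields) {
    idx <- rows$field_mhz == as.numeric(f)
    if (!any(idx)) next
    nu <- rows$nu_cpmg_hz[idx]
    r20 <- r20_by_field[[f]]
    if (model == "model2") {
      phi <- ppm_to_rad_s(sqrt(phi_ppm2), as.numeric(f))^2
      out[idx] <- luz_meiboom_r2eff(kex, phi, r20, nu)
    } else {
      dw <- ppm_to_rad_s(dw_ppm, as.numeric(f))
      out[idx] <- carver_richards_r2eff(kex, pb, dw, r20, nu)
    }
  }
  out
}

fit_one_start <- function(rows, model, start, t_relax) {
  fields <- as.character(sort(unique(rows$field_mhz)))
  nf <- length(fields)
  if (model == "model2") {
    par0 <- c(log(start$kex), log(start$phi_ppm2), start$r20)
    lower <- c(log(1), log(1e-6), rep(0.1, nf))
    upper <- c(log(1e6), log(1e4), rep(500, nf))
    obj <- function(p) {
      calc <- cpmg_calc(
        "model2", rows,
        kex = exp(p[1]), pb = NA, dw_ppm = NA, phi_ppm2 = exp(p[2]),
        r20_by_field = setNames(as.list(p[3:(2 + nf)]), fields),
        t_relax = t_relax
      )
      sum(((rows$r2eff - calc) / rows$sigma)^2)
    }
  } else {
    par0 <- c(log(start$kex), stats::qlogis(start$pb / 0.5),
              log(start$dw_ppm), start$r20)
    lower <- c(log(1), -15, log(1e-3), rep(0.1, nf))
    upper <- c(log(1e6), 15, log(100), rep(500, nf))
    obj <- function(p) {
      calc <- cpmg_calc(
        "model3", rows,
        kex = exp(p[1]), pb = 0.5 * stats::plogis(p[2]),
        dw_ppm = exp(p[3]), phi_ppm2 = NA,
        r20_by_field = setNames(as.list(p[4:(3 + nf)]), fields),
        t_relax = t_relax
      )
      sum(((rows$r2eff - calc) / rows$sigma)^2)
    }
  }
  res <- try(
    optim(par0, obj,
      method = "L-BFGS-B", lower = lower, upper = upper,
      control = list(maxit = 500)
    ),
    silent = TRUE
  )
  if (inherits(res, "try-error")) {
    return(list(value = Inf, par = par0, converged = FALSE))
  }
  list(value = res$value, par = res$par, converged = res$convergence == 0)
}

#' Fit a two-site exchange model to dispersion curves of one residue
#'
#' Minimises the sigma-weighted chi-square over all fields jointly by
#' multi-start bounded quasi-Newton optimisation. Three model variants
#' follow the conventional naming: `"model2"` (fast exchange;
#' Luz-Meiboom, fitting `kex` and the composite `phi = pa pb dw^2`),
#' `"model3"` (slow exchange; full Carver-Richards with separate `pb` and
#' `dw`), and `"general"` (Carver-Richards, the default; identical
#' parameterisation to model-3 but applicable on all timescales). Fits
#' with reduced chi-square >= `chi2_red_max` are flagged `rejected`.
#'
#' The shift difference is fitted in ppm (field-invariant) and converted
#' per field to rad/s. Intrinsic rates `R2^0` are fitted per field.
#' Multi-start initial values cover `kex` in {200, 500, 1000, 2000,
#' 4000} s^-1, `pb` in {0.02, 0.05, 0.1}, `dw` in {1, 2, 4} ppm; ties
#' are broken by lowest chi-square, then lowest `kex`.
#'
#' @param data Dispersion tibble for a single residue, columns
#'   `residue`, `field_mhz`, `nu_cpmg_hz`, `r2eff`, `sigma`.
#' @param model `"general"`, `"model2"` or `"model3"`.
#' @param t_relax Total CPMG delay (s); default 0.020.
#' @param chi2_red_max Rejection threshold on reduced chi-square;
#'   default 10.
#' @param n_starts Number of best grid starts refined by optimisation;
#'   default 5.
#' @return A `cpmg_fit` object; see [tidy.cpmg_fit()] and
#'   [glance.cpmg_fit()].
#' @export
#' @examples
#' sim <- sim_dispersion(n_residues = 1, seed = 1)
#' fit <- fit_dispersion(sim$data)
#' glance(fit)
fit_dispersion <- function(data, model = c("general", "model3", "model2"),
                           t_relax = 0.020, chi2_red_max = 10,
                           n_starts = 5) {
  model <- match.arg(model)
  if (length(unique(data$residue)) != 1) {
    abort("`data` must contain a single residue; see `fit_dispersion_all()`.")
  }
  if (!"sigma" %in% names(data)) {
    abort("`data` needs a `sigma` column; see `estimate_sigma_from_repeats()`.")
  }
  fields <- as.character(sort(unique(data$field_mhz)))
  nf <- length(fields)
  n_params <- if (model == "model2") 1 + 1 + nf else 3 + nf
  if (nrow(data) < 2 * n_params) {
    abort("Too few points: need at least 2 x n_params observations.")
  }
  # r20 start: plateau at the fastest pulsing
  r20_start <- vapply(fields, function(f) {
    rows <- data[data$field_mhz == as.numeric(f), ]
    min(rows$r2eff[rows$nu_cpmg_hz == max(rows$nu_cpmg_hz)])
  }, numeric(1))
  grid <- expand.grid(
    kex = c(200, 500, 1000, 2000, 4000),
    pb = c(0.02, 0.05, 0.1),
    dw_ppm = c(1, 2, 4)
  )
  grid$phi_ppm2 <- (1 - grid$pb) * grid$pb * grid$dw_ppm^2
  # rank starts by their unrefined chi2, refine the best few
  grid$chi2 <- vapply(seq_len(nrow(grid)), function(i) {
    calc <- cpmg_calc(
      if (model == "model2") "model2" else "model3", data,
      kex = grid$kex[i], pb = grid$pb[i], dw_ppm = grid$dw_ppm[i],
      phi_ppm2 = grid$phi_ppm2[i],
      r20_by_field = setNames(as.list(r20_start), fields),
      t_relax = t_relax
    )
    sum(((data$r2eff - calc) / data$sigma)^2)
  }, numeric(1))
  starts <- grid[order(grid$chi2), ][seq_len(min(n_starts, nrow(grid))), ]
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    fit_one_start(
      data, model,
      list(
        kex = starts$kex[i], pb = starts$pb[i],
        dw_ppm = starts$dw_ppm[i], phi_ppm2 = starts$phi_ppm2[i],
        r20 = r20_start
      ),
      t_relax
    )
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  kexs <- vapply(fits, function(f) exp(f$par[1]), numeric(1))
  best <- fits[[order(vals, kexs)[1]]]
  p <- best$par
  if (model == "model2") {
    est <- list(
      kex = unname(exp(p[1])), pb = NA_real_, dw_ppm = NA_real_,
      phi_ppm2 = unname(exp(p[2])),
      r20 = setNames(p[3:(2 + nf)], fields)
    )
  } else {
    est <- list(
      kex = unname(exp(p[1])), pb = unname(0.5 * stats::plogis(p[2])),
      dw_ppm = unname(exp(p[3])), phi_ppm2 = NA_real_,
      r20 = setNames(p[4:(3 + nf)], fields)
    )
  }
  calc <- cpmg_calc(
    if (model == "model2") "model2" else "model3", data,
    kex = est$kex, pb = est$pb, dw_ppm = est$dw_ppm,
    phi_ppm2 = est$phi_ppm2,
    r20_by_field = as.list(est$r20), t_relax = t_relax
  )
  ch <- chi2_target(data$r2eff, calc, data$sigma, n_params)
  structure(
    list(
      residue = data$residue[1],
      model = model,
      estimate = est,
      dw_rad_s = if (model == "model2") NULL else
        setNames(ppm_to_rad_s(est$dw_ppm, as.numeric(fields)), fields),
      chi2 = ch$chi2, chi2_red = ch$chi2_red,
      n_points = nrow(data), n_params = n_params,
      converged = best$converged,
      rejected = !is.na(ch$chi2_red) && ch$chi2_red >= chi2_red_max,
      chi2_red_max = chi2_red_max,
      t_relax = t_relax,
      data = tibble::as_tibble(data),
      mc_errors = NULL
    ),
    class = "cpmg_fit"
  )
}

#' @export
print.cpmg_fit <- function(x, ...) {
  cat(sprintf(
    "<cpmg_fit> residue %s, %s: kex = %.0f s^-1%s%s, chi2_red = %.2f%s\n",
    x$residue, x$model, x$estimate$kex,
    if (is.na(x$estimate$pb)) "" else sprintf(", pb = %.3f", x$estimate$pb),
    if (is.na(x$estimate$dw_ppm)) {
      sprintf(", phi = %.2f ppm^2", x$estimate$phi_ppm2)
    } else {
      sprintf(", dw = %.2f ppm", x$estimate$dw_ppm)
    },
    x$chi2_red,
    if (x$rejected) " [rejected]" else ""
  ))
  invisible(x)
}

#' Fit every residue of a dispersion table
#'
#' Convenience wrapper mapping [fit_dispersion()] over residues.
#'
#' @inheritParams fit_dispersion
#' @return A tibble with one row per residue (the [glance.cpmg_fit()]
#'   columns plus fitted parameters) and the fit objects in a `fit`
#'   list-column.
#' @export
fit_dispersion_all <- function(data, model = c("general", "model3", "model2"),
                               t_relax = 0.020, chi2_red_max = 10,
                               n_starts = 5) {
  model <- match.arg(model)
  data |>
    dplyr::group_by(.data$residue) |>
    dplyr::group_split() |>
    purrr::map(function(rows) {
      fit <- fit_dispersion(rows,
        model = model, t_relax = t_relax,
        chi2_red_max = chi2_red_max, n_starts = n_starts
      )
      dplyr::mutate(glance(fit), fit = list(fit))
    }) |>
    purrr::list_rbind()
}

#' Globally fit a residue group with shared exchange parameters
#'
#' Residues in one exchange process (e.g. the dimer interface) share a
#' single `(kex, pb)`; each residue keeps its own shift difference (ppm)
#' and per-field intrinsic rate. The total sigma-weighted chi-square is
#' minimised by bounded quasi-Newton optimisation started from the
#' median of per-residue individual fits.
#'
#' @inheritParams fit_dispersion
#' @param data Dispersion tibble with one or more residues.
#' @return A `cpmg_global_fit` object.
#' @export
global_fit <- function(data, t_relax = 0.020, chi2_red_max = 10) {
  residues <- sort(unique(data$residue))
  fields <- as.character(sort(unique(data$field_mhz)))
  nf <- length(fields)
  nr <- length(residues)
  indiv <- fit_dispersion_all(data, model = "general", t_relax = t_relax)
  kex0 <- median(indiv$kex)
  pb0 <- min(max(median(indiv$pb), 1e-3), 0.45)
  dw0 <- vapply(indiv$fit, function(f) f$estimate$dw_ppm, numeric(1))
  r200 <- unlist(lapply(indiv$fit, function(f) f$estimate$r20))
  par0 <- c(
    log(kex0), stats::qlogis(pb0 / 0.5), log(pmax(dw0, 1e-2)), r200
  )
  lower <- c(log(1), -15, rep(log(1e-3), nr), rep(0.1, nr * nf))
  upper <- c(log(1e6), 15, rep(log(100), nr), rep(500, nr * nf))
  rows_by_res <- lapply(residues, function(r) data[data$residue == r, ])
  obj <- function(p) {
    kex <- exp(p[1]); pb <- 0.5 * stats::plogis(p[2])
    tot <- 0
    for (i in seq_len(nr)) {
      r20 <- setNames(
        as.list(p[2 + nr + (i - 1) * nf + seq_len(nf)]), fields
      )
      calc <- cpmg_calc("model3", rows_by_res[[i]],
        kex = kex, pb = pb, dw_ppm = exp(p[2 + i]), phi_ppm2 = NA,
        r20_by_field = r20, t_relax = t_relax
      )
      tot <- tot +
        sum(((rows_by_res[[i]]$r2eff - calc) / rows_by_res[[i]]$sigma)^2)
    }
    tot
  }
  res <- optim(par0, obj,
    method = "L-BFGS-B", lower = lower, upper = upper,
    control = list(maxit = 1000)
  )
  p <- res$par
  n_params <- 2 + nr + nr * nf
  n_points <- nrow(data)
  dof <- n_points - n_params
  per_res <- tibble::tibble(
    residue = residues,
    dw_ppm = unname(exp(p[2 + seq_len(nr)]))
  )
  structure(
    list(
      residues = residues,
      kex = unname(exp(p[1])), pb = unname(0.5 * stats::plogis(p[2])),
      per_residue = per_res,
      r20 = matrix(p[(3 + nr):length(p)],
        nrow = nr, byrow = TRUE,
        dimnames = list(residues, fields)
      ),
      chi2 = res$value,
      chi2_red = if (dof > 0) res$value / dof else NA_real_,
      n_points = n_points, n_params = n_params,
      converged = res$convergence == 0,
      rejected = dof > 0 && res$value / dof >= chi2_red_max,
      t_relax = t_relax,
      data = tibble::as_tibble(data)
    ),
    class = "cpmg_global_fit"
  )
}

#' @export
print.cpmg_global_fit <- function(x, ...) {
  cat(sprintf(
    "<cpmg_global_fit> %d residues: kex = %.0f s^-1, pb = %.3f, chi2_red = %.2f\n",
    length(x$residues), x$kex, x$pb, x$chi2_red
  ))
  invisible(x)
}

#' Monte Carlo parameter uncertainties for a dispersion fit
#'
#' Resamples synthetic datasets from the fitted curve plus Gaussian noise
#' at the per-point sigma, refits each replicate (single start at the
#' fitted values), and reports the standard deviation of each parameter
#' over the replicate distribution (conventionally 100 simulations).
#'
#' @param fit A `cpmg_fit` object.
#' @param n Number of simulations; default 100.
#' @param seed Random seed; default 7304.
#' @return The fit with `mc_errors` (named vector of SDs for `kex`,
#'   `pb`, `dw_ppm` or `phi_ppm2`) filled in.
#' @export
monte_carlo_errors <- function(fit, n = 100, seed = 7304) {
  stopifnot(inherits(fit, "cpmg_fit"))
  data <- fit$data
  fields <- as.character(sort(unique(data$field_mhz)))
  calc <- cpmg_calc(
    if (fit$model == "model2") "model2" else "model3", data,
    kex = fit$estimate$kex, pb = fit$estimate$pb,
    dw_ppm = fit$estimate$dw_ppm, phi_ppm2 = fit$estimate$phi_ppm2,
    r20_by_field = as.list(fit$estimate$r20), t_relax = fit$t_relax
  )
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    code()
  }
  draws <- withr_seed(function() {
    replicate(n, {
      sim <- data
      sim$r2eff <- calc + rnorm(nrow(data), sd = data$sigma)
      start <- list(
        kex = fit$estimate$kex,
        pb = if (is.na(fit$estimate$pb)) 0.05 else fit$estimate$pb,
        dw_ppm = if (is.na(fit$estimate$dw_ppm)) 2 else fit$estimate$dw_ppm,
        phi_ppm2 = fit$estimate$phi_ppm2,
        r20 = fit$estimate$r20
      )
      res <- fit_one_start(sim, fit$model, start, fit$t_relax)
      p <- res$par
      nf <- length(fields)
      if (fit$model == "model2") {
        c(kex = exp(p[1]), phi_ppm2 = exp(p[2]))
      } else {
        c(kex = exp(p[1]), pb = 0.5 * stats::plogis(p[2]), dw_ppm = exp(p[3]))
      }
    })
  })
  fit$mc_errors <- apply(draws, 1, sd)
  fit$mc_n <- n
  fit$mc_seed <- seed
  fit
}
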