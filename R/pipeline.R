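#' Run the full analysis pipeline on tabular inputs
#'
#' Executes, on whatever inputs are supplied: the dispersion-amplitude
#' screen, per-residue exchange fits (with optional Monte Carlo errors),
#' pK_R titration fits, the two-condition CSP table and exchange-regime
#' calls, the dispersion-vs-CSP concordance, the ITC dilution fit, and
#' the equilibrium/kinetics summary tying the fitted dissociation
#' constant and exchange rate together. Every threshold applied is the
#' one recorded in `config`, which is echoed into the bundle.
#'
#' @param dispersion Dispersion tibble (or `NULL` to skip).
#' @param titration Titration tibble (or `NULL`).
#' @param peaks_a,peaks_b Peak lists for the two conditions (or `NULL`).
#' @param itc ITC injection tibble (or `NULL`).
#' @param itc_experiment A [dilution_experiment()] describing the ITC
#'   geometry.
#' @param c_total_um Total subunit concentration (uM) for the kinetics
#'   summary; default 700.
#' @param config An [analysis_config()].
#' @param mc Run Monte Carlo errors on accepted dispersion fits;
#'   default `FALSE` (they are the slow step).
#' @return An `acdimer_pipeline` list of result tibbles; see
#'   [write_pipeline_bundle()].
#' @export
run_pipeline <- function(dispersion = NULL, titration = NULL,
                         peaks_a = NULL, peaks_b = NULL, itc = NULL,
                         itc_experiment = dilution_experiment(),
                         c_total_um = 700,
                         config = analysis_config(), mc = FALSE) {
  out <- list(config = config)
  if (!is.null(dispersion) && nrow(dispersion) > 0) {
    if (!"sigma" %in% names(dispersion)) {
      dispersion <- estimate_sigma_from_repeats(dispersion)
    }
    screened <- screen_dispersive_residues(
      dispersion,
      threshold = config$delta_r2eff_min
    )
    out$screen <- attr(screened, "screen")
    if (nrow(screened) > 0) {
      fits <- fit_dispersion_all(
        screened,
        chi2_red_max = config$chi2_red_max
      )
      if (mc) {
        fits$fit <- purrr::map(fits$fit, function(f) {
          if (f$rejected) f else {
            monte_carlo_errors(f, n = config$mc_n, seed = config$seed)
          }
        })
      }
      out$dispersion_fits <- fits
    }
  } else if (!is.null(dispersion)) {
    warn("Empty dispersion input; skipping exchange fits.")
  }
  if (!is.null(titration) && nrow(titration) > 0) {
    out$pkr_fits <- fit_pkr_all(titration)
  } else if (!is.null(titration)) {
    warn("Empty titration input; skipping pK_R fits.")
  }
  if (!is.null(peaks_a) && !is.null(peaks_b) &&
        nrow(peaks_a) > 0 && nrow(peaks_b) > 0) {
    out$csp <- csp_table(peaks_a, peaks_b,
      n_scale = config$n_scale, overall_scale = config$overall_scale
    )
    both <- dplyr::bind_rows(peaks_a, peaks_b)
    if ("doubled" %in% names(both)) {
      out$regimes <- classify_exchange_regime(both)
    }
    if (!is.null(out$dispersion_fits)) {
      accepted <- dplyr::filter(out$dispersion_fits, !.data$rejected)
      cmp <- compare_dw_csp(accepted, out$csp)
      out$dw_csp <- cmp
      out$dw_csp_concordance <- attr(cmp, "concordance")
    }
  }
  if (!is.null(itc) && nrow(itc) >= 10) {
    out$itc_fit <- fit_dilution(itc, itc_experiment)
    kd_um <- out$itc_fit$kd
    eq <- solve_dimer_monomer(kd_um, c_total_um)
    out$equilibrium <- eq
    if (!is.null(out$dispersion_fits)) {
      accepted <- dplyr::filter(out$dispersion_fits, !.data$rejected)
      if (nrow(accepted) > 0) {
        out$kinetics <- decompose_kex(
          median(accepted$kex), kd_um, c_total_um
        )
      }
    }
  } else if (!is.null(itc)) {
    warn("Fewer than 10 ITC injections; skipping dilution fit.")
  }
  structure(out, class = "acdimer_pipeline")
}

#' Write a pipeline result bundle to disk
#'
#' Tabular results go to TSV, scalar results and the configuration to a
#' versioned JSON file (`bundle.json`). Numeric columns keep their units
#' in the column names throughout the package (`_um`, `_ppm`, `_ucal`,
#' s^-1 rates).
#'
#' @param bundle An `acdimer_pipeline` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "acdimer_pipeline"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json <- list(
    schema = "acdimer-bundle/1",
    config = unclass(bundle$config)
  )
  tab <- function(x, name) {
    if (!is.null(x)) {
      readr::write_tsv(
        dplyr::select(x, -dplyr::any_of("fit")),
        file.path(dir, paste0(name, ".tsv"))
      )
    }
  }
  tab(bundle$screen, "screen")
  tab(bundle$dispersion_fits, "dispersion_fits")
  tab(bundle$pkr_fits, "pkr_fits")
  tab(bundle$csp, "csp")
  tab(bundle$regimes, "regimes")
  tab(bundle$dw_csp, "dw_csp")
  tab(bundle$equilibrium, "equilibrium")
  tab(bundle$kinetics, "kinetics")
  if (!is.null(bundle$dw_csp_concordance)) {
    json$dw_csp_concordance <- as.list(bundle$dw_csp_concordance)
  }
  if (!is.null(bundle$itc_fit)) {
    json$itc_fit <- list(
      kd_um = bundle$itc_fit$kd, dh_cal_mol = bundle$itc_fit$dh,
      baseline_ucal = bundle$itc_fit$baseline,
      se = as.list(bundle$itc_fit$se),
      converged = bundle$itc_fit$converged
    )
  }
  jsonlite::write_json(
    json, file.path(dir, "bundle.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
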