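# strict TSV/CSV readers with line-numbered validation -----------------------

read_validated <- function(path, required, delim, numeric_cols,
                           logical_cols = character()) {
  raw <- readr::read_delim(path,
    delim = delim, show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s: missing required column(s): %s",
      basename(path), paste(missing, collapse = ", ")
    ))
  }
  for (col in intersect(numeric_cols, names(raw))) {
    vals <- raw[[col]]
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & vals != "" & is.na(num))
    if (length(bad) > 0) {
      abort(sprintf(
        "%s: non-numeric value '%s' in column '%s' at data line %d",
        basename(path), vals[bad[1]], col, bad[1]
      ))
    }
    raw[[col]] <- num
  }
  for (col in intersect(logical_cols, names(raw))) {
    vals <- toupper(trimws(raw[[col]]))
    lg <- dplyr::case_when(
      vals %in% c("TRUE", "T", "1", "YES") ~ TRUE,
      vals %in% c("FALSE", "F", "0", "NO") ~ FALSE,
      TRUE ~ NA
    )
    bad <- which(!is.na(raw[[col]]) & raw[[col]] != "" & is.na(lg))
    if (length(bad) > 0) {
      abort(sprintf(
        "%s: non-logical value '%s' in column '%s' at data line %d",
        basename(path), raw[[col]][bad[1]], col, bad[1]
      ))
    }
    raw[[col]] <- lg
  }
  raw
}

#' Read and write dispersion tables
#'
#' Tab-separated with a mandatory header; required columns `residue`,
#' `field_mhz`, `nu_cpmg_hz` and either `r2eff` or `intensity` (+
#' `intensity_ref`, converted via [r2eff_from_intensities()]); optional
#' `sigma`. Extra columns are preserved.
#'
#' @param path File path.
#' @param t_relax Total CPMG delay (s) for intensity conversion.
#' @return A tibble with (at least) `residue`, `field_mhz`,
#'   `nu_cpmg_hz`, `r2eff` and, when present, `sigma`.
#' @export
read_dispersion_table <- function(path, t_relax = 0.020) {
  raw <- read_validated(
    path,
    required = c("residue", "field_mhz", "nu_cpmg_hz"),
    delim = "\t",
    numeric_cols = c(
      "residue", "field_mhz", "nu_cpmg_hz", "r2eff",
      "intensity", "intensity_ref", "sigma"
    )
  )
  if (!"r2eff" %in% names(raw)) {
    if (!all(c("intensity", "intensity_ref") %in% names(raw))) {
      abort(paste(
        basename(path), "needs either an `r2eff` column or",
        "`intensity` + `intensity_ref` columns."
      ))
    }
    raw$r2eff <- r2eff_from_intensities(
      raw$intensity, raw$intensity_ref, t_relax
    )
  }
  raw
}

#' @rdname read_dispersion_table
#' @param data Tibble to write.
#' @export
write_dispersion_table <- function(data, path) {
  readr::write_tsv(data, path)
  invisible(path)
}

#' Read and write titration tables
#'
#' Tab-separated columns `atom_id`, `ph`, `shift_ppm`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_titration_table <- function(path) {
  read_validated(
    path,
    required = c("atom_id", "ph", "shift_ppm"),
    delim = "\t",
    numeric_cols = c("ph", "shift_ppm")
  )
}

#' @rdname read_titration_table
#' @param data Tibble to write.
#' @export
write_titration_table <- function(data, path) {
  readr::write_tsv(data, path)
  invisible(path)
}

#' Read and write peak lists
#'
#' Tab-separated columns `residue`, `condition`, `hn_ppm`, `n_ppm`,
#' optional `doubled` (logical) with partner positions `hn2_ppm`,
#' `n2_ppm`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_peak_list <- function(path) {
  out <- read_validated(
    path,
    required = c("residue", "condition", "hn_ppm", "n_ppm"),
    delim = "\t",
    numeric_cols = c("residue", "hn_ppm", "n_ppm", "hn2_ppm", "n2_ppm"),
    logical_cols = "doubled"
  )
  if ("doubled" %in% names(out)) {
    bad <- which(out$doubled & (is.na(out$hn2_ppm) | is.na(out$n2_ppm)))
    if (length(bad) > 0) {
      abort(sprintf(
        "%s: doubled peak without partner shifts at data line %d",
        basename(path), bad[1]
      ))
    }
  }
  out
}

#' @rdname read_peak_list
#' @param data Tibble to write.
#' @export
write_peak_list <- function(data, path) {
  readr::write_tsv(data, path)
  invisible(path)
}

#' Read and write ITC injection tables
#'
#' Comma-separated columns `injection`, `volume_ul`, `heat_ucal`.
#'
#' @param path File path.
#' @return A tibble with `injection`, `volume_ul`, `q_ucal`.
#' @export
read_itc_table <- function(path) {
  raw <- read_validated(
    path,
    required = c("injection", "volume_ul", "heat_ucal"),
    delim = ",",
    numeric_cols = c("injection", "volume_ul", "heat_ucal")
  )
  dplyr::rename(raw, q_ucal = "heat_ucal")
}

#' @rdname read_itc_table
#' @param data Tibble to write (a `q_ucal` column is written as
#'   `heat_ucal`).
#' @export
write_itc_table <- function(data, path) {
  if ("q_ucal" %in% names(data)) {
    data <- dplyr::rename(data, heat_ucal = "q_ucal")
  }
  readr::write_csv(data, path)
  invisible(path)
}

#' Analysis configuration with conventional thresholds
#'
#' Collects every tunable threshold so result bundles can record their
#' provenance: the reduced chi-square rejection cutoff (10), the
#' dispersion amplitude screen (8 s^-1), CSP class boundaries (0.1 and
#' 0.2 ppm), the ring-nitrogen tautomer threshold (190 ppm), the
#' hydrogen-bond NH threshold (12 ppm), scale factors of the combined
#' CSP, and the random seed.
#'
#' @param chi2_red_max,delta_r2eff_min,csp_moderate,csp_strong
#'   Numeric thresholds; see Description.
#' @param ring_n_threshold,nh_hbond_threshold Classification thresholds
#'   (ppm).
#' @param n_scale,overall_scale CSP scale factors.
#' @param mc_n Monte Carlo simulation count; default 100.
#' @param seed Default random seed; 7304.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(chi2_red_max = 10, delta_r2eff_min = 8,
                            csp_moderate = 0.1, csp_strong = 0.2,
                            ring_n_threshold = 190,
                            nh_hbond_threshold = 12,
                            n_scale = 1 / 5, overall_scale = 1 / sqrt(2),
                            mc_n = 100, seed = 7304) {
  cfg <- list(
    schema = "acdimer-config/1",
    chi2_red_max = chi2_red_max, delta_r2eff_min = delta_r2eff_min,
    csp_moderate = csp_moderate, csp_strong = csp_strong,
    ring_n_threshold = ring_n_threshold,
    nh_hbond_threshold = nh_hbond_threshold,
    n_scale = n_scale, overall_scale = overall_scale,
    mc_n = mc_n, seed = seed
  )
  for (nm in setdiff(names(cfg), "schema")) {
    check_number(cfg[[nm]], nm, min = 0, allow_zero = FALSE)
  }
  structure(cfg, class = "analysis_config")
}
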