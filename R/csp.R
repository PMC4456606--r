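#' Combined amide chemical-shift perturbation
#'
#' `delta = overall_scale * sqrt(d_hn^2 + (d_n * n_scale)^2)` with the
#' conventional 15N down-weighting `n_scale = 1/5` and
#' `overall_scale = 1/sqrt(2)`, i.e.
#' `Delta delta = sqrt((Delta HN^2 + (Delta N / 5)^2) / 2)`.
#'
#' @param d_hn Amide 1H shift difference (ppm).
#' @param d_n Amide 15N shift difference (ppm).
#' @param n_scale 15N scale factor; default 1/5.
#' @param overall_scale Overall scale; default `1/sqrt(2)`.
#' @return Combined perturbation (ppm, non-negative).
#' @export
#' @examples
#' compute_csp(0.1, 1.0) # 0.158 ppm
compute_csp <- function(d_hn, d_n, n_scale = 1 / 5,
                        overall_scale = 1 / sqrt(2)) {
  check_number(d_hn, "d_hn")
  check_number(d_n, "d_n")
  overall_scale * sqrt(d_hn^2 + (d_n * n_scale)^2)
}

#' Classify a perturbation magnitude
#'
#' Conventional classes: `"strong"` above 0.2 ppm, `"moderate"` within
#' `[0.1, 0.2]` (left-closed, right-closed), `"minor"` below 0.1 ppm.
#'
#' @param delta Combined perturbation (ppm).
#' @param moderate,strong Class boundaries (ppm); defaults 0.1 and 0.2.
#' @return Factor with levels `minor`, `moderate`, `strong`.
#' @export
#' @examples
#' classify_csp(c(0.05, 0.15, 0.25))
classify_csp <- function(delta, moderate = 0.1, strong = 0.2) {
  check_number(delta, "delta", min = 0)
  factor(
    dplyr::case_when(
      delta > strong ~ "strong",
      delta >= moderate ~ "moderate",
      TRUE ~ "minor"
    ),
    levels = c("minor", "moderate", "strong")
  )
}

#' Per-residue perturbations between two conditions
#'
#' Joins two peak lists (e.g. pH 7.5 and pH 6.5) on residue, computes
#' per-residue `Delta HN`, `Delta N`, the combined perturbation and its
#' class.
#'
#' @param peaks_a,peaks_b Peak-list tibbles with columns `residue`,
#'   `hn_ppm`, `n_ppm` (condition A is the reference).
#' @inheritParams compute_csp
#' @return Tibble with `residue`, `d_hn`, `d_n`, `delta`, `csp_class`.
#' @export
csp_table <- function(peaks_a, peaks_b, n_scale = 1 / 5,
                      overall_scale = 1 / sqrt(2)) {
  need <- c("residue", "hn_ppm", "n_ppm")
  for (nm in list(peaks_a, peaks_b)) {
    if (!all(need %in% names(nm))) {
      abort(paste("peak lists need columns", paste(need, collapse = ", ")))
    }
  }
  dplyr::inner_join(
    dplyr::select(peaks_a, "residue", "hn_ppm", "n_ppm"),
    dplyr::select(peaks_b, "residue", "hn_ppm", "n_ppm"),
    by = "residue", suffix = c("_a", "_b")
  ) |>
    dplyr::mutate(
      d_hn = .data$hn_ppm_b - .data$hn_ppm_a,
      d_n = .data$n_ppm_b - .data$n_ppm_a,
      delta = compute_csp(.data$d_hn, .data$d_n, n_scale, overall_scale),
      csp_class = classify_csp(.data$delta)
    ) |>
    dplyr::select("residue", "d_hn", "d_n", "delta", "csp_class")
}

#' Classify the exchange regime of a residue across a pH series
#'
#' A residue whose peak moves continuously (never doubled) titrates in
#' fast exchange; one that shows two peaks at every observed pH is in
#' slow exchange; doubling over only part of the range (e.g. single
#' above pH 7, doubled below) is mixed.
#'
#' @param data Peak records for one or more residues: columns `residue`,
#'   `ph` (or any ordered condition), `doubled` (logical).
#' @return Tibble with `residue` and `regime` (`fast`, `slow`, `mixed`).
#' @export
classify_exchange_regime <- function(data) {
  need <- c("residue", "doubled")
  if (!all(need %in% names(data))) {
    abort("`data` must have columns `residue` and `doubled`.")
  }
  data |>
    dplyr::group_by(.data$residue) |>
    dplyr::summarise(
      regime = dplyr::case_when(
        !any(.data$doubled) ~ "fast",
        all(.data$doubled) ~ "slow",
        TRUE ~ "mixed"
      ),
      .groups = "drop"
    )
}

#' Compare dispersion-derived shift differences with pH perturbations
#'
#' The minor species seen by relaxation dispersion at the higher pH and
#' the state populated at the lower pH are the same species when the
#' fitted `|dw|` (ppm, field-invariant) agrees residue-by-residue with
#' the directly measured 15N shift difference between the two pH
#' conditions. Returns the paired table, restricted to residues present
#' in both sets, with Pearson correlation and mean absolute difference
#' as concordance metrics.
#'
#' @param fits Tibble with columns `residue` and `dw_ppm` (e.g. from
#'   [fit_dispersion_all()]).
#' @param csp Tibble with columns `residue` and `d_n` (15N difference,
#'   ppm; e.g. from [csp_table()]).
#' @return A tibble with `residue`, `dw_calc` (= fitted |dw|), `ddn_exp`
#'   (= |Delta N|) and `diff`; concordance (`pearson_r`, `mean_abs_diff`,
#'   `n`) is attached as attribute `"concordance"`.
#' @export
compare_dw_csp <- function(fits, csp) {
  paired <- dplyr::inner_join(
    dplyr::select(fits, "residue", "dw_ppm"),
    dplyr::select(csp, "residue", "d_n"),
    by = "residue"
  ) |>
    dplyr::transmute(
      residue = .data$residue,
      dw_calc = abs(.data$dw_ppm),
      ddn_exp = abs(.data$d_n),
      diff = .data$dw_calc - .data$ddn_exp
    )
  if (nrow(paired) == 0) {
    warn("No residues in common between the dispersion fits and the CSP set.")
    conc <- tibble::tibble(
      pearson_r = NA_real_, mean_abs_diff = NA_real_, n = 0L
    )
  } else {
    conc <- tibble::tibble(
      pearson_r = if (nrow(paired) >= 3) {
        cor(paired$dw_calc, paired$ddn_exp)
      } else {
        NA_real_
      },
      mean_abs_diff = mean(abs(paired$diff)),
      n = nrow(paired)
    )
  }
  attr(paired, "concordance") <- conc
  paired
}
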