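#' Henderson-Hasselbalch forward model for an NMR titration
#'
#' Observed shift of a nucleus reporting on a single protonation site:
#' `delta_obs = delta_ha + (delta_a - delta_ha) * f` with the
#' deprotonated fraction `f = 10^(ph - pkr) / (1 + 10^(ph - pkr))`.
#' `delta_ha` and `delta_a` are the shifts of the fully protonated and
#' fully deprotonated states; the Hill coefficient is fixed at 1.
#'
#' @param ph pH values (vectorised).
#' @param pkr Side-chain pKa (pK_R for a histidine ring).
#' @param delta_ha Shift of the protonated state (ppm).
#' @param delta_a Shift of the deprotonated state (ppm).
#' @return Observed shifts (ppm).
#' @export
#' @examples
#' hh_forward(7.0, pkr = 6.6, delta_ha = 8.60, delta_a = 7.60) # 7.885
hh_forward <- function(ph, pkr, delta_ha, delta_a) {
  check_number(ph, "ph")
  x <- 10^(ph - pkr)
  delta_ha + (delta_a - delta_ha) * x / (1 + x)
}

#' Fit a pK_R from a shift-vs-pH titration series
#'
#' Nonlinear least-squares fit of `(pkr, delta_ha, delta_a)` to the
#' single-site Henderson-Hasselbalch curve. When the fitted inflection
#' lies below the sampled pH range (more than `oor_margin` below its
#' minimum) the point estimate is unstable and the fit is reported as a
#' bound (`status = "out_of_range_low"`, e.g. "<6"). Series that are too
#' short, span too little pH, or are flat (pkr unidentifiable) give
#' `status = "undetermined"`.
#'
#' @param data Tibble with columns `ph` and `shift_ppm` (one atom's
#'   series); an `atom_id` column, if present, is carried through.
#' @param oor_margin How far below `min(ph)` the fitted pkr may lie
#'   before being reported as a bound; default 0.5 pH units.
#' @param se_bound_threshold A fitted pkr below `min(ph)` (but within
#'   the margin) is still reported as a bound when its standard error
#'   exceeds this value, since an unbracketed inflection leaves pkr and
#'   the protonated-state shift strongly correlated; default 0.2.
#' @return A `pkr_fit` object; `tidy()` gives the parameter table.
#' @export
#' @examples
#' ph <- c(9.3, 8.56, 7.86, 7.44, 7.0, 6.83, 6.7, 6.52, 6.0)
#' d <- tibble::tibble(ph = ph, shift_ppm = hh_forward(ph, 6.6, 8.6, 7.6))
#' fit_pkr(d)
fit_pkr <- function(data, oor_margin = 0.5, se_bound_threshold = 0.2) {
  if (!all(c("ph", "shift_ppm") %in% names(data))) {
    abort("`data` must have columns `ph` and `shift_ppm`.")
  }
  atom_id <- if ("atom_id" %in% names(data)) data$atom_id[1] else NA_character_
  data <- dplyr::arrange(data, .data$ph)
  ph <- data$ph
  y <- data$shift_ppm
  base <- list(
    atom_id = atom_id, data = tibble::as_tibble(data),
    pkr = NA_real_, delta_ha = NA_real_, delta_a = NA_real_,
    se = c(pkr = NA_real_, delta_ha = NA_real_, delta_a = NA_real_),
    status = "undetermined", bound = NA_character_
  )
  if (nrow(data) < 4 || diff(range(ph)) < 1) {
    return(structure(base, class = "pkr_fit"))
  }
  span <- diff(range(y))
  if (span < 1e-6) { # flat series: no titration information
    return(structure(base, class = "pkr_fit"))
  }
  # start values: asymptotes from the extremes, pkr from the midpoint
  d_ha0 <- y[which.min(ph)]
  d_a0 <- y[which.max(ph)]
  mid <- (d_ha0 + d_a0) / 2
  pkr0 <- ph[which.min(abs(y - mid))]
  fit <- try(
    minpack.lm::nlsLM(
      shift_ppm ~ delta_ha + (delta_a - delta_ha) *
        10^(ph - pkr) / (1 + 10^(ph - pkr)),
      data = data,
      start = list(pkr = pkr0, delta_ha = d_ha0, delta_a = d_a0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    silent = TRUE
  )
  if (inherits(fit, "try-error")) {
    return(structure(base, class = "pkr_fit"))
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
  out <- base
  out$pkr <- unname(cf["pkr"])
  out$delta_ha <- unname(cf["delta_ha"])
  out$delta_a <- unname(cf["delta_a"])
  out$se <- c(pkr = unname(se[1]), delta_ha = unname(se[2]),
              delta_a = unname(se[3]))
  below_margin <- out$pkr < min(ph) - oor_margin
  below_range_uncertain <- out$pkr < min(ph) &&
    (!is.finite(se[1]) || se[1] > se_bound_threshold)
  if (!is.finite(out$pkr)) {
    out$status <- "undetermined"
  } else if (below_margin || below_range_uncertain) {
    # inflection below (or not credibly within) the sampled range: the
    # point estimate is unstable, so report a bound instead
    out$status <- "out_of_range_low"
    out$bound <- sprintf("<%.3g", min(ph))
  } else if (is.finite(se[1]) && se[1] > diff(range(ph))) {
    out$status <- "undetermined"
  } else {
    out$status <- "fitted"
  }
  structure(out, class = "pkr_fit")
}

#' @export
print.pkr_fit <- function(x, ...) {
  lab <- if (!is.na(x$atom_id)) paste0(" ", x$atom_id) else ""
  if (x$status == "fitted") {
    cat(sprintf(
      "<pkr_fit>%s pK_R = %.2f (+/- %.2f), delta_HA = %.3f, delta_A = %.3f ppm\n",
      lab, x$pkr, x$se["pkr"], x$delta_ha, x$delta_a
    ))
  } else if (x$status == "out_of_range_low") {
    cat(sprintf("<pkr_fit>%s pK_R %s (below sampled range)\n", lab, x$bound))
  } else {
    cat(sprintf("<pkr_fit>%s undetermined\n", lab))
  }
  invisible(x)
}

#' Fit pK_R for every atom of a titration table
#'
#' @param data Tibble with columns `atom_id`, `ph`, `shift_ppm`.
#' @param ... Passed to [fit_pkr()].
#' @return A tibble with one row per atom (`glance()` columns) and the
#'   fits in a `fit` list-column.
#' @export
fit_pkr_all <- function(data, ...) {
  data |>
    dplyr::group_by(.data$atom_id) |>
    dplyr::group_split() |>
    purrr::map(function(rows) {
      fit <- fit_pkr(rows, ...)
      dplyr::mutate(glance(fit), fit = list(fit))
    }) |>
    purrr::list_rbind()
}

#' Classify the tautomeric state of a histidine imidazole ring
#'
#' Ring 15N shifts distinguish a protonated (amine-like, low-ppm) from a
#' non-protonated (pyridine-like, high-ppm) nitrogen; the midpoint of
#' the canonical histidine ranges, 190 ppm, is the default threshold. A
#' protonated Ndelta1 with pyridine-like Nepsilon2 is the less common
#' Ndelta1H tautomer; the converse is Nepsilon2H; both nitrogens
#' protonated is the cationic ring. Shifts outside the credible ring
#' window give `"undetermined"`.
#'
#' @param nd1_ppm,ne2_ppm Ring 15N shifts (ppm) of Ndelta1 and Nepsilon2.
#' @param threshold Protonated/pyridine classification threshold (ppm);
#'   default 190.
#' @param window Credible ring 15N shift window (ppm); default
#'   `c(150, 260)`.
#' @return A tibble with `state` (`"Nd1H"`, `"Ne2H"`,
#'   `"protonated_both"` or `"undetermined"`) and an `evidence` string.
#' @export
#' @examples
#' classify_tautomer(nd1_ppm = 170, ne2_ppm = 250) # Nd1H, as for His-104
classify_tautomer <- function(nd1_ppm, ne2_ppm, threshold = 190,
                              window = c(150, 260)) {
  n <- max(length(nd1_ppm), length(ne2_ppm))
  nd1 <- rep_len(nd1_ppm, n)
  ne2 <- rep_len(ne2_ppm, n)
  in_window <- function(x) is.finite(x) & x >= window[1] & x <= window[2]
  state <- dplyr::case_when(
    !in_window(nd1) | !in_window(ne2) ~ "undetermined",
    nd1 < threshold & ne2 >= threshold ~ "Nd1H",
    nd1 >= threshold & ne2 < threshold ~ "Ne2H",
    nd1 < threshold & ne2 < threshold ~ "protonated_both",
    TRUE ~ "undetermined"
  )
  tibble::tibble(
    nd1_ppm = nd1, ne2_ppm = ne2, state = state,
    evidence = sprintf(
      "Nd1 %.1f ppm (%s), Ne2 %.1f ppm (%s), threshold %g ppm",
      nd1, ifelse(nd1 < threshold, "protonated-type", "pyridine-type"),
      ne2, ifelse(ne2 < threshold, "protonated-type", "pyridine-type"),
      threshold
    )
  )
}

#' Flag a hydrogen-bonded ring NH from its 1H shift
#'
#' Strongly downfield exchangeable ring NH protons indicate hydrogen
#' bonding; shifts at or above the threshold (default 12.0 ppm) are
#' flagged. The 12.4 ppm Ndelta1H resonance of His-104 is the canonical
#' positive case.
#'
#' @param nh_proton_shift Exchangeable ring NH 1H shift (ppm).
#' @param threshold Flagging threshold (ppm); default 12.0, inclusive.
#' @return Logical vector.
#' @export
#' @examples
#' flag_hbonded_nh(c(12.4, 10.0))
flag_hbonded_nh <- function(nh_proton_shift, threshold = 12.0) {
  check_number(nh_proton_shift, "nh_proton_shift")
  nh_proton_shift >= threshold
}
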