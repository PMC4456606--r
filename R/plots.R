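#' Plot a dispersion fit
#'
#' Observed R2,eff vs CPMG frequency with the fitted curve, one panel
#' per static field.
#'
#' @param object A `cpmg_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cpmg_fit <- function(object, ...) {
  aug <- augment(object)
  nu_grid <- tidyr::expand_grid(
    field_mhz = sort(unique(aug$field_mhz)),
    nu_cpmg_hz = seq(min(aug$nu_cpmg_hz), max(aug$nu_cpmg_hz),
      length.out = 80
    )
  )
  nu_grid$r2eff <- cpmg_calc(
    if (object$model == "model2") "model2" else "model3", nu_grid,
    kex = object$estimate$kex, pb = object$estimate$pb,
    dw_ppm = object$estimate$dw_ppm, phi_ppm2 = object$estimate$phi_ppm2,
    r20_by_field = as.list(object$estimate$r20), t_relax = object$t_relax
  )
  ggplot2::ggplot(aug, ggplot2::aes(.data$nu_cpmg_hz, .data$r2eff)) +
    ggplot2::geom_line(data = nu_grid, colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$r2eff - .data$sigma, ymax = .data$r2eff + .data$sigma
    ), size = 0.2) +
    ggplot2::facet_wrap(~field_mhz, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = expression(nu[CPMG] ~ "(Hz)"),
      y = expression(R["2,eff"] ~ (s^-1)),
      title = sprintf(
        "Residue %s: kex = %.0f s^-1, chi2_red = %.1f",
        object$residue, object$estimate$kex, object$chi2_red
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a pK_R titration fit
#'
#' Observed shifts vs pH with the fitted Henderson-Hasselbalch curve
#' and the fitted pK_R marked.
#'
#' @param object A `pkr_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pkr_fit <- function(object, ...) {
  p <- ggplot2::ggplot(
    object$data, ggplot2::aes(.data$ph, .data$shift_ppm)
  ) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "pH", y = "shift (ppm)") +
    ggplot2::theme_minimal()
  if (object$status != "undetermined") {
    grid <- tibble::tibble(ph = seq(min(object$data$ph) - 0.5,
      max(object$data$ph) + 0.5,
      length.out = 200
    ))
    grid$shift_ppm <- hh_forward(
      grid$ph, object$pkr, object$delta_ha, object$delta_a
    )
    p <- p + ggplot2::geom_line(data = grid, colour = "grey40")
    if (object$status == "fitted") {
      p <- p + ggplot2::geom_vline(
        xintercept = object$pkr, linetype = "dashed", colour = "grey60"
      ) +
        ggplot2::labs(
          title = sprintf("pK_R = %.2f", object$pkr)
        )
    } else {
      p <- p + ggplot2::labs(title = sprintf("pK_R %s", object$bound))
    }
  }
  p
}

#' Plot an ITC dilution fit
#'
#' Injection heats with the fitted isotherm.
#'
#' @param object A `dilution_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.dilution_fit <- function(object, ...) {
  aug <- augment(object)
  ggplot2::ggplot(aug, ggplot2::aes(.data$injection, .data$q_ucal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), colour = "grey40") +
    ggplot2::labs(
      x = "injection", y = expression(q ~ (mu * cal)),
      title = sprintf(
        "kd = %.3g uM, dh = %.0f cal/mol", object$kd, object$dh
      )
    ) +
    ggplot2::theme_minimal()
}

#' Per-residue CSP bar plot with class colouring
#'
#' @param csp A tibble from [csp_table()].
#' @param moderate,strong Class boundary annotations (ppm).
#' @return A ggplot.
#' @export
plot_csp <- function(csp, moderate = 0.1, strong = 0.2) {
  ggplot2::ggplot(csp, ggplot2::aes(
    .data$residue, .data$delta,
    fill = .data$csp_class
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(
      yintercept = c(moderate, strong),
      linetype = "dashed", colour = "grey60"
    ) +
    ggplot2::scale_fill_manual(values = c(
      minor = "grey70", moderate = "orange", strong = "red"
    ), drop = FALSE) +
    ggplot2::labs(
      x = "residue", y = expression(Delta * delta ~ "(ppm)"),
      fill = "class"
    ) +
    ggplot2::theme_minimal()
}

#' Scatter of dispersion-derived vs pH-difference 15N shifts
#'
#' @param paired A tibble from [compare_dw_csp()].
#' @return A ggplot with the identity line and the Pearson r annotated.
#' @export
plot_dw_csp <- function(paired) {
  conc <- attr(paired, "concordance")
  ggplot2::ggplot(paired, ggplot2::aes(.data$ddn_exp, .data$dw_calc)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression("|" * Delta * delta * N * "| observed (ppm)"),
      y = expression("|" * delta * omega * "| fitted (ppm)"),
      title = if (!is.null(conc)) {
        sprintf("Pearson r = %.3f (n = %d)", conc$pearson_r, conc$n)
      } else {
        NULL
      }
    ) +
    ggplot2::theme_minimal()
}
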