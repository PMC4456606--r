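#' Solve the dimer-monomer equilibrium
#'
#' For a homodimer that dissociates as D <-> 2M with dissociation constant
#' `kd = [M]^2 / [D]` (subunit-molar units), mass balance over subunits
#' gives `m + 2 d = c_total`. Substituting `d = m^2 / kd` yields the
#' quadratic `2 m^2 + kd m - kd c_total = 0`, whose unique non-negative
#' root is
#' `m = (-kd + sqrt(kd^2 + 8 kd c_total)) / 4`.
#'
#' All concentrations are in micromolar. Inputs are vectorised and
#' recycled against each other.
#'
#' @param kd Dimer dissociation constant (uM), `[M]^2/[D]`.
#' @param c_total Total subunit concentration (uM).
#' @return A tibble with columns `kd`, `c_total`, `m` (monomer, uM),
#'   `d` (dimer, uM) and `f_mono` (fraction of subunits monomeric).
#' @export
#' @examples
#' # ACD at 700 uM subunits with the ITC-measured Kd of 2 uM: ~4% monomer
#' solve_dimer_monomer(kd = 2, c_total = 700)
#' # at the 37 degrees C Kd of 36 uM the monomer pool is ~100 uM
#' solve_dimer_monomer(kd = 36, c_total = 700)
solve_dimer_monomer <- function(kd, c_total) {
  check_number(kd, "kd", min = 0)
  check_number(c_total, "c_total", min = 0, allow_zero = FALSE)
  n <- max(length(kd), length(c_total))
  kd <- rep_len(kd, n)
  c_total <- rep_len(c_total, n)
  m <- (-kd + sqrt(kd^2 + 8 * kd * c_total)) / 4
  d <- (c_total - m) / 2
  tibble::tibble(
    kd = kd, c_total = c_total,
    m = m, d = d, f_mono = m / c_total
  )
}

#' Decompose an observed exchange rate into association/dissociation rates
#'
#' For dimer-monomer interconversion probed by relaxation dispersion the
#' observed exchange rate is `kex = kmd * [monomer] + kdm`, where `kmd`
#' (M^-1 s^-1) is the monomer-dimer association rate constant and `kdm`
#' (s^-1) the dimer dissociation rate constant. With detailed balance
#' `kd = kdm / kmd`, a single measured `kex` at a known total subunit
#' concentration determines both constants:
#' `kmd = kex / (m + kd)` and `kdm = kd * kmd` (concentrations in molar
#' for the division).
#'
#' @param kex Observed exchange rate (s^-1).
#' @param kd Dimer dissociation constant (uM).
#' @param c_total Total subunit concentration (uM).
#' @return A tibble with `kex`, `kd`, `c_total`, `m` (uM), `kmd`
#'   (M^-1 s^-1) and `kdm` (s^-1).
#' @export
#' @examples
#' # kex ~1500 s^-1 at 700 uM subunits, Kd = 36 uM (pH 7.5, 37 degrees C)
#' decompose_kex(kex = 1500, kd = 36, c_total = 700)
decompose_kex <- function(kex, kd, c_total) {
  check_number(kex, "kex", min = 0, allow_zero = FALSE)
  check_number(kd, "kd", min = 0)
  eq <- solve_dimer_monomer(kd, c_total)
  n <- nrow(eq)
  kex <- rep_len(kex, n)
  if (any(eq$kd == 0)) {
    warn(paste(
      "kd = 0 is degenerate (no free monomer at equilibrium):",
      "kdm = 0 and kmd = kex / m is unbounded."
    ))
  }
  # uM -> M for the bimolecular constant
  kmd <- kex / ((eq$m + eq$kd) * 1e-6)
  kdm <- ifelse(eq$kd == 0, 0, eq$kd * 1e-6 * kmd)
  tibble::tibble(
    kex = kex, kd = eq$kd, c_total = eq$c_total, m = eq$m,
    kmd = kmd, kdm = kdm
  )
}

#' Predict the observed exchange rate at another concentration
#'
#' Given association/dissociation rate constants (e.g. from
#' [decompose_kex()]), predicts `kex = kmd * m(c_total) + kdm` at a new
#' total subunit concentration, with the monomer concentration obtained
#' from the equilibrium implied by `kd = kdm / kmd`.
#'
#' @param kmd Association rate constant (M^-1 s^-1).
#' @param kdm Dissociation rate constant (s^-1).
#' @param c_total Total subunit concentration (uM).
#' @return A tibble with `c_total`, `m`, and predicted `kex` (s^-1).
#' @export
#' @examples
#' predict_kex(kmd = 1.1e7, kdm = 400, c_total = c(200, 700))
predict_kex <- function(kmd, kdm, c_total) {
  check_number(kmd, "kmd", min = 0)
  check_number(kdm, "kdm", min = 0)
  kd_um <- ifelse(kmd > 0, kdm / kmd * 1e6, 0)
  eq <- solve_dimer_monomer(kd_um, c_total)
  n <- nrow(eq)
  kmd <- rep_len(kmd, n)
  kdm <- rep_len(kdm, n)
  tibble::tibble(
    c_total = eq$c_total, m = eq$m,
    kex = kmd * eq$m * 1e-6 + kdm
  )
}

#' Subunit count of an oligomer from its weight-average molar mass
#'
#' Divides a SEC-MALS weight-average molar mass by the subunit mass and
#' rounds half-up to the nearest integer, the arithmetic used to quote
#' oligomer stoichiometries (465 kDa / 20.2 kDa per subunit -> ~24
#' subunits).
#'
#' @param mw Weight-average molar mass (kDa).
#' @param monomer_mass Subunit molar mass (kDa); default 20.2 kDa
#'   (full-length HSPB5 subunit).
#' @return A tibble with `mw`, `monomer_mass`, `n_subunits_real` and the
#'   rounded `n_subunits`.
#' @export
#' @examples
#' subunits_from_mw(c(465, 720, 810), monomer_mass = 20)
subunits_from_mw <- function(mw, monomer_mass = 20.2) {
  check_number(mw, "mw", min = 0, allow_zero = FALSE)
  check_number(monomer_mass, "monomer_mass", min = 0, allow_zero = FALSE)
  real <- mw / monomer_mass
  tibble::tibble(
    mw = mw, monomer_mass = monomer_mass,
    n_subunits_real = real,
    # round-half-up, not banker's rounding
    n_subunits = as.integer(floor(real + 0.5))
  )
}
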