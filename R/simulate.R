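#' Default CPMG experiment geometry
#'
#' Two static fields (600 and 800 MHz 1H), refocusing frequencies 25,
#' 50, 75, 100, 150, 175, 200, 300, 600 and 1000 Hz with duplicate
#' measurements at 25 and 200 Hz, and a 20 ms constant-time CPMG block.
#'
#' @param fields_mhz Static fields (1H MHz).
#' @param nu_cpmg_hz Refocusing frequency grid (Hz).
#' @param duplicates_hz Frequencies measured twice (Hz).
#' @param t_relax Total CPMG delay (s).
#' @return A `cpmg_experiment` list.
#' @export
cpmg_experiment <- function(fields_mhz = c(600, 800),
                            nu_cpmg_hz = c(25, 50, 75, 100, 150, 175,
                                           200, 300, 600, 1000),
                            duplicates_hz = c(25, 200),
                            t_relax = 0.020) {
  check_number(nu_cpmg_hz, "nu_cpmg_hz", min = 0, allow_zero = FALSE)
  check_number(t_relax, "t_relax", min = 0, allow_zero = FALSE)
  if (!all(duplicates_hz %in% nu_cpmg_hz)) {
    abort("`duplicates_hz` must be a subset of `nu_cpmg_hz`.")
  }
  structure(
    list(
      fields_mhz = fields_mhz, nu_cpmg_hz = nu_cpmg_hz,
      duplicates_hz = duplicates_hz, t_relax = t_relax
    ),
    class = "cpmg_experiment"
  )
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  force(code)
}

#' Simulate a two-field CPMG dispersion dataset with ground truth
#'
#' Draws per-residue exchange parameters emulating a dimer-monomer
#' exchanging alpha-crystallin domain: `kex` uniform over the
#' experimentally typical 760-1119 s^-1 window, minor-state population
#' `pb` around 5%, 15N shift differences `dw` uniform over
#' `dw_range_ppm`, intrinsic rates around 15 s^-1. R2,eff values come
#' from the Carver-Richards model (or the Bloch-McConnell propagator)
#' plus Gaussian noise of `sigma` s^-1; duplicate points are drawn
#' independently.
#'
#' @param n_residues Number of residues; default 20.
#' @param kex_range True exchange-rate window (s^-1).
#' @param pb True minor-state population; default 0.05.
#' @param dw_range_ppm Window for true |dw| (ppm 15N).
#' @param r20_range Window for true intrinsic rates (s^-1).
#' @param sigma Gaussian noise on R2,eff (s^-1); default 0.3.
#' @param shared_kex If `TRUE` all residues share one `kex` (and `pb`),
#'   the global-fit scenario; default `FALSE`.
#' @param experiment A [cpmg_experiment()].
#' @param forward `"carver_richards"` (default) or `"bloch_mcconnell"`.
#' @param seed Random seed; default 7304.
#' @return A list with `data` (tibble: `residue`, `field_mhz`,
#'   `nu_cpmg_hz`, `r2eff`, `sigma`) and `truth` (tibble of per-residue
#'   generating parameters plus the seed).
#' @export
#' @examples
#' sim <- sim_dispersion(n_residues = 2, seed = 1)
#' head(sim$data)
#' sim$truth
sim_dispersion <- function(n_residues = 20,
                           kex_range = c(760, 1119),
                           pb = 0.05,
                           dw_range_ppm = c(2, 5),
                           r20_range = c(12, 18),
                           sigma = 0.3,
                           shared_kex = FALSE,
                           experiment = cpmg_experiment(),
                           forward = c("carver_richards", "bloch_mcconnell"),
                           seed = 7304) {
  forward <- match.arg(forward)
  stopifnot(inherits(experiment, "cpmg_experiment"))
  with_seed(seed, {
    kex <- if (shared_kex) {
      rep(runif(1, kex_range[1], kex_range[2]), n_residues)
    } else {
      runif(n_residues, kex_range[1], kex_range[2])
    }
    dw <- runif(n_residues, dw_range_ppm[1], dw_range_ppm[2])
    truth <- tibble::tibble(
      residue = seq_len(n_residues),
      kex = kex, pb = pb, dw_ppm = dw,
      sigma = sigma, seed = seed
    )
    nu_all <- sort(c(experiment$nu_cpmg_hz, experiment$duplicates_hz))
    rows <- tidyr::expand_grid(
      residue = seq_len(n_residues),
      field_mhz = experiment$fields_mhz
    )
    rows$r20 <- runif(nrow(rows), r20_range[1], r20_range[2])
    data <- purrr::list_rbind(lapply(seq_len(nrow(rows)), function(i) {
      res <- rows$residue[i]
      f <- rows$field_mhz[i]
      dwr <- ppm_to_rad_s(truth$dw_ppm[res], f)
      clean <- if (forward == "carver_richards") {
        carver_richards_r2eff(truth$kex[res], pb, dwr, rows$r20[i], nu_all)
      } else {
        bloch_mcconnell_r2eff(truth$kex[res], pb, dwr, rows$r20[i], nu_all,
          t_relax = experiment$t_relax
        )
      }
      tibble::tibble(
        residue = res, field_mhz = f, nu_cpmg_hz = nu_all,
        r2eff = clean + if (sigma > 0) rnorm(length(nu_all), 0, sigma) else 0,
        sigma = sigma
      )
    }))
    list(data = data, truth = truth, truth_r20 = rows)
  })
}

#' Simulate histidine titration series with ground truth
#'
#' Henderson-Hasselbalch curves on the conventional nine-point pH grid
#' (9.3 to 6.0) plus Gaussian shift noise. The default scenario carries
#' one ring proton per histidine with pK_R values emulating the
#' alpha-crystallin domain histidines, including a low (5.0) case whose
#' inflection falls below the sampled range.
#'
#' @param truth Tibble with columns `atom_id`, `pkr`, `delta_ha`,
#'   `delta_a`; defaults emulate His-83 (6.6), His-119 (7.7) and a
#'   below-range His (5.0).
#' @param ph_grid pH values; default the nine-point grid.
#' @param noise_ppm Gaussian noise SD (ppm); default 0.01.
#' @param seed Random seed; default 7304.
#' @return A list with `data` (tibble `atom_id`, `ph`, `shift_ppm`) and
#'   `truth`.
#' @export
sim_titration <- function(truth = NULL,
                          ph_grid = c(9.3, 8.56, 7.86, 7.44, 7.0,
                                      6.83, 6.7, 6.52, 6.0),
                          noise_ppm = 0.01,
                          seed = 7304) {
  if (is.null(truth)) {
    truth <- tibble::tibble(
      atom_id = c("H83_He1", "H119_He1", "H101_He1"),
      pkr = c(6.6, 7.7, 5.0),
      delta_ha = c(8.60, 8.55, 8.65),
      delta_a = c(7.60, 7.65, 7.70)
    )
  }
  with_seed(seed, {
    data <- purrr::pmap(truth, function(atom_id, pkr, delta_ha, delta_a, ...) {
      tibble::tibble(
        atom_id = atom_id,
        ph = ph_grid,
        shift_ppm = hh_forward(ph_grid, pkr, delta_ha, delta_a) +
          if (noise_ppm > 0) rnorm(length(ph_grid), 0, noise_ppm) else 0
      )
    }) |>
      purrr::list_rbind()
    list(data = data, truth = dplyr::mutate(truth, seed = seed))
  })
}

#' Simulate paired-condition peak lists with doubling
#'
#' Emulates amide peak lists of a dimer-monomer system at two pH
#' conditions. At the reference (high) pH the dimer dominates and each
#' residue shows a single peak at the dimer position; at the low pH the
#' monomer is substantially populated, so residues whose monomer peak is
#' resolved show doubling and the reported (major) position is the
#' monomer one. The 15N monomer-minus-dimer offsets are the same `dw`
#' values used for the dispersion scenario, so dispersion-fitted `|dw|`
#' and the pH shift differences have positive ground-truth concordance.
#'
#' @param truth Tibble with `residue`, `dw_ppm` (15N offset), optionally
#'   `dw_hn_ppm` (1H offset; default one tenth of the 15N offset in
#'   ppm). If `NULL`, taken from `sim_dispersion(seed = seed)$truth`.
#' @param p_mono_low Monomer population at the low-pH condition; default
#'   0.5 (doubling expected).
#' @param p_mono_high Monomer population at the reference condition;
#'   default 0.05 (no doubling).
#' @param doubling_threshold Minimum minor population for a resolved
#'   second peak; default 0.2.
#' @param noise_hn_ppm,noise_n_ppm Peak-position noise SDs; defaults
#'   0.01 (1H) and 0.05 (15N).
#' @param seed Random seed; default 7304.
#' @return A list with `data` (tibble `residue`, `condition`, `hn_ppm`,
#'   `n_ppm`, `doubled`, `hn2_ppm`, `n2_ppm`) and `truth`.
#' @export
sim_peaklists <- function(truth = NULL,
                          p_mono_low = 0.5, p_mono_high = 0.05,
                          doubling_threshold = 0.2,
                          noise_hn_ppm = 0.01, noise_n_ppm = 0.05,
                          seed = 7304) {
  if (is.null(truth)) {
    truth <- sim_dispersion(seed = seed)$truth |>
      dplyr::select("residue", "dw_ppm")
  }
  if (!"dw_hn_ppm" %in% names(truth)) {
    truth$dw_hn_ppm <- truth$dw_ppm / 10
  }
  with_seed(seed, {
    n <- nrow(truth)
    dimer_hn <- runif(n, 7.5, 9.5)
    dimer_n <- runif(n, 105, 130)
    mono_hn <- dimer_hn + truth$dw_hn_ppm
    mono_n <- dimer_n + truth$dw_ppm
    mk <- function(condition, p_mono) {
      doubled <- p_mono >= doubling_threshold &
        (1 - p_mono) >= doubling_threshold
      # the reported position follows the monomer when it is at least
      # co-dominant
      use_mono <- p_mono >= 0.5
      major_hn <- if (use_mono) mono_hn else dimer_hn
      major_n <- if (use_mono) mono_n else dimer_n
      minor_hn <- if (use_mono) dimer_hn else mono_hn
      minor_n <- if (use_mono) dimer_n else mono_n
      hn2 <- if (doubled) {
        minor_hn + rnorm(n, 0, noise_hn_ppm)
      } else {
        rep(NA_real_, n)
      }
      n2 <- if (doubled) {
        minor_n + rnorm(n, 0, noise_n_ppm)
      } else {
        rep(NA_real_, n)
      }
      tibble::tibble(
        residue = truth$residue,
        condition = condition,
        hn_ppm = major_hn + rnorm(n, 0, noise_hn_ppm),
        n_ppm = major_n + rnorm(n, 0, noise_n_ppm),
        doubled = rep(doubled, length.out = n),
        hn2_ppm = hn2,
        n2_ppm = n2
      )
    }
    data <- dplyr::bind_rows(
      mk("reference", p_mono_high),
      mk("low_ph", p_mono_low)
    )
    list(
      data = data,
      truth = dplyr::mutate(truth,
        p_mono_low = p_mono_low, p_mono_high = p_mono_high, seed = seed
      )
    )
  })
}

#' Simulate a dilution-ITC injection table with ground truth
#'
#' Forward isotherm for a dissociating dimer plus Gaussian noise scaled
#' to the largest heat. The default parameter regime is a dissociation
#' constant of 36 uM and dissociation enthalpy of 9328 cal/mol with the
#' standard 200 ul / 1 mM / 40 x 1 ul geometry.
#'
#' @param kd True dissociation constant (uM); default 36.
#' @param dh True dissociation enthalpy (cal/mol); default 9328.
#' @param experiment A [dilution_experiment()].
#' @param noise_frac Noise SD as a fraction of the largest |heat|;
#'   default 0.01.
#' @param seed Random seed; default 7304.
#' @return A list with `data` (tibble `injection`, `volume_ul`,
#'   `q_ucal`) and `truth`.
#' @export
sim_itc <- function(kd = 36, dh = 9328,
                    experiment = dilution_experiment(),
                    noise_frac = 0.01, seed = 7304) {
  clean <- forward_isotherm(kd, dh, experiment)
  with_seed(seed, {
    q <- clean$q_ucal +
      if (noise_frac > 0) {
        rnorm(nrow(clean), 0, noise_frac * max(abs(clean$q_ucal)))
      } else {
        0
      }
    list(
      data = tibble::tibble(
        injection = clean$injection,
        volume_ul = clean$volume_ul,
        q_ucal = q
      ),
      truth = tibble::tibble(
        kd = kd, dh = dh, noise_frac = noise_frac, seed = seed
      )
    )
  })
}
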