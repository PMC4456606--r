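# Independent numerical oracles, deliberately naive: used only to check
# the package's closed-form / bookkeeping implementations.

# monomer concentration by bisection on the mass-balance equation
# m + 2 m^2 / kd = c_total
oracle_monomer_bisect <- function(kd, c_total, tol = 1e-12) {
  if (kd == 0) return(0)
  f <- function(m) m + 2 * m^2 / kd - c_total
  lo <- 0
  hi <- c_total
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol * max(1, c_total)) break
  }
  (lo + hi) / 2
}

# brute-force mole bookkeeping for one dilution-ITC injection sequence;
# tracks moles (pmol) explicitly instead of concentrations
oracle_itc_heats <- function(kd, dh, v0, cs, vols) {
  mono <- function(c_tot) oracle_monomer_bisect(kd, c_tot)
  m_syr <- mono(cs)
  n_cell <- 0   # total subunit moles in the cell, pmol
  nm_cell <- 0  # monomer moles in the cell, pmol
  q <- numeric(length(vols))
  for (i in seq_along(vols)) {
    v <- vols[i]
    # the injection displaces v ul of the pre-injection mixture
    frac_left <- (v0 - v) / v0
    n_after <- n_cell * frac_left + cs * v
    nm_carried <- nm_cell * frac_left + m_syr * v
    m_eq <- mono(n_after / v0)
    nm_eq <- m_eq * v0
    q[i] <- dh * (nm_eq - nm_carried) / 2 * 1e-12 * 1e6 # ucal
    n_cell <- n_after
    nm_cell <- nm_eq
  }
  q
}
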