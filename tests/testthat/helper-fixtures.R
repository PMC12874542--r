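# Shared fixtures: the reference-bead material system used throughout the
# tests (polystyrene substrate in water, PEO coat), and a brute-force
# effective-medium inversion oracle kept deliberately independent of the
# closed-form implementation under test.

ps_water_peo <- function(sigma = FALSE) {
  if (sigma) {
    optical_constants(n0 = 1.6019, nm = 1.340, n1 = 1.470,
                      sigma_nm = 0.001, sigma_n1 = 0.005)
  } else {
    optical_constants(n0 = 1.6019, nm = 1.340, n1 = 1.470)
  }
}

peo34 <- function() {
  brush_parameters(mw_coat = 34, monomer_mass = 44, increment = 0.28,
                   r_g = 9.1, m_ps = 3.8, rho_ps = 1.05, v_s = 44.5)
}

# Brute-force oracle: invert the coated-sphere relation for the coating
# index, numerically solve the Maxwell Garnett mixing rule for the volume
# fraction, and convert to a grafting density. Shares no algebra with
# grafting_constraint().
oracle_grafting <- function(a_c, delta_d, v_s, oc) {
  n_c <- oc$nm + delta_d * (oc$n0 - oc$nm) / (2 * a_c)
  LL <- function(m) (m^2 - 1) / (m^2 + 2)
  target <- LL(n_c / oc$nm)
  phi <- uniroot(function(p) p * LL(oc$n1 / oc$nm) - target,
                 c(0, 60), tol = 1e-15)$root
  phi * a_c / v_s
}
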