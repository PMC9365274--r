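# Small configurations shared across tests.  All fixtures are built in
# code; nothing is read from disk.

# one functional element, no cooperativity
single_site_config <- function(kd = 1, kd_d = kd, kon_m = 0.5, kon_d = 0.5,
                               k_pol = 0, tau = Inf, pol_gap = 4) {
  crm_config(
    cis_element("e1", 100, kd_monomer = kd, kd_dimer = kd_d),
    kinetics = crm_kinetics(kon_monomer = kon_m, kon_dimer = kon_d,
                            k_pol = k_pol, pol_gap = pol_gap,
                            residence_limit = tau),
    coop = cooperativity("none"),
    label = "single"
  )
}

# n independent-but-configurable elements at the CLV3-like spacings
multi_site_config <- function(n = 2, mode = "none", c_mono = 0.01,
                              c_dim = 0.2, kon_m = 0.5, kon_d = 0.5,
                              k_pol = 0, tau = Inf,
                              kds = c(1, 2, 3, 1.5, 5)) {
  pos <- c(950, 970, 997, 1007, 1060)[seq_len(n)]
  el <- dplyr::bind_rows(purrr::map(seq_len(n), function(i) {
    cis_element(paste0("e", i), pos[i], kd_monomer = kds[i])
  }))
  crm_config(
    el,
    kinetics = crm_kinetics(kon_monomer = kon_m, kon_dimer = kon_d,
                            k_pol = k_pol, residence_limit = tau),
    coop = cooperativity(mode, c_monomer = c_mono, c_dimer = c_dim),
    label = paste0("multi", n)
  )
}

# Monte-Carlo standard error of a time-averaged occupancy fraction,
# estimated from independent replicate trajectories.
replicate_fractions <- function(config, dose, t_end, n_rep, seed,
                                column = "frac_monomer") {
  vapply(seq_len(n_rep), function(r) {
    tr <- simulate_cell(config, dose, t_end, seed = seed + r,
                        record_events = FALSE)
    occupancy_fractions(tr)[[column]][1]
  }, numeric(1))
}
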