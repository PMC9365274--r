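test_that("the single-site generator is the three-state birth-death chain", {
  cfg <- single_site_config(kd = 2, kd_d = 3, kon_m = 0.5, kon_d = 0.4)
  W <- 1.5
  G <- build_generator(cfg, W)
  expect_equal(dim(G$Q), c(3, 3))
  expect_equal(G$labels, c("-", "M", "D"))
  expect_equal(G$Q[1, 2], 0.5 * W)          # empty -> monomer
  expect_equal(G$Q[2, 1], 2 * 0.5)          # monomer -> empty
  expect_equal(G$Q[2, 3], 0.4 * W)          # monomer -> dimer
  expect_equal(G$Q[3, 2], 3 * 0.4)          # dimer -> monomer
  expect_equal(rowSums(G$Q), rep(0, 3), tolerance = 1e-12)
})

test_that("dose zero leaves only unbinding transitions", {
  G <- build_generator(multi_site_config(2), 0)
  off_diag <- G$Q - diag(diag(G$Q))
  # transitions only to states with strictly fewer bound molecules
  n_bound <- rowSums(G$states)
  for (s in seq_len(nrow(G$Q))) {
    targets <- which(off_diag[s, ] > 0)
    expect_true(all(n_bound[targets] < n_bound[s]))
  }
})

test_that("independent sites give a Kronecker-sum generator", {
  cfg <- multi_site_config(2, mode = "none", kds = c(1, 2.5))
  W <- 1.2
  G <- build_generator(cfg, W)
  cfg1 <- single_site_config(kd = 1, kon_m = 0.5, kon_d = 0.5)
  cfg2 <- single_site_config(kd = 2.5, kon_m = 0.5, kon_d = 0.5)
  Q1 <- build_generator(cfg1, W)$Q
  Q2 <- build_generator(cfg2, W)$Q
  # state index = 1 + digit1 + 3*digit2 (first element = fastest digit)
  kron_sum <- kronecker(diag(3), Q1) + kronecker(Q2, diag(3))
  expect_equal(G$Q, kron_sum, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("stationary law satisfies detailed balance on a single site", {
  cfg <- single_site_config(kd = 2, kd_d = 5, kon_m = 0.3, kon_d = 0.7)
  for (W in c(0.5, 2, 8)) {
    pi_hat <- stationary_distribution(build_generator(cfg, W))$probability
    expect_equal(pi_hat[2] / pi_hat[1], W / 2, tolerance = 1e-10)
    expect_equal(pi_hat[3] / pi_hat[2], W / 5, tolerance = 1e-10)
  }
  # kon_dimer = 0: two-state chain, pi(M)/pi(-) = W/Kd exactly
  cfg0 <- single_site_config(kd = 2, kon_d = 0)
  p <- stationary_distribution(build_generator(cfg0, 3))$probability
  expect_equal(p[2] / p[1], 3 / 2, tolerance = 1e-10)
  expect_equal(p[3], 0, tolerance = 1e-12)
})

test_that("dose zero puts all stationary mass on the all-empty state", {
  G <- build_generator(multi_site_config(2), 0)
  p <- stationary_distribution(G)$probability
  expect_equal(p[G$labels == "--"], 1, tolerance = 1e-10)
})

test_that("analytic single-site law matches the CME across a dose grid", {
  kd_m <- 1.3
  kd_d <- 0.6
  cfg <- single_site_config(kd = kd_m, kd_d = kd_d, kon_m = 0.8, kon_d = 0.2)
  for (W in c(0.1, 0.5, 1.3, 4, 10)) {
    a <- analytic_single_site(kd_m, kd_d, W)
    p <- stationary_distribution(build_generator(cfg, W))$probability
    expect_equal(p, c(a$p_empty, a$p_monomer, a$p_dimer), tolerance = 1e-10)
  }
  expect_equal(analytic_single_site(1, 1, 0)$p_empty, 1)
  # half-saturation in the no-dimer limit
  a <- analytic_single_site(2, 1e12, 2)
  expect_equal(a$p_monomer, 0.5, tolerance = 1e-6)
})

test_that("mode=none joint stationary law factorises over sites", {
  for (n in 2:3) {
    cfg <- multi_site_config(n, mode = "none", kds = c(1, 3, 0.5))
    W <- 1.7
    G <- build_generator(cfg, W)
    pi_hat <- stationary_distribution(G)$probability
    marg <- lapply(seq_len(n), function(j) {
      a <- analytic_single_site(cfg$elements$kd_monomer[j],
                                cfg$elements$kd_dimer[j], W)
      c(a$p_empty, a$p_monomer, a$p_dimer)
    })
    prod_law <- vapply(seq_len(nrow(G$states)), function(s) {
      prod(vapply(seq_len(n), function(j) marg[[j]][G$states[s, j] + 1],
                  numeric(1)))
    }, numeric(1))
    expect_equal(pi_hat, prod_law, tolerance = 1e-10)
  }
})

test_that("cooperativity-modified generators keep zero row sums", {
  cfg <- multi_site_config(3, mode = "distance", c_mono = 0.02, c_dim = 0.1)
  G <- build_generator(cfg, 2)
  expect_equal(rowSums(G$Q), rep(0, 27), tolerance = 1e-12)
  p <- stationary_distribution(G)
  expect_equal(sum(p$probability), 1, tolerance = 1e-12)
  expect_true(all(p$probability >= 0))
})

test_that("the state-space guard rejects oversized modules", {
  el <- dplyr::bind_rows(purrr::map(1:9, function(i) {
    cis_element(paste0("e", i), 100 + 10 * i, 1)
  }))
  cfg <- crm_config(el, crm_kinetics(), cooperativity("none"))
  expect_error(build_generator(cfg, 1), "at most 8")
})

test_that("SSA matches CME stationary marginals on a two-site module", {
  cfg <- multi_site_config(2, mode = "distance", c_mono = 0.05, c_dim = 0.3,
                           kds = c(1, 2))
  W <- 1.5
  exact <- stationary_occupancy(cfg, W)
  fracs <- replicate_fractions(cfg, W, t_end = 4000, n_rep = 12, seed = 300)
  se <- stats::sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - exact$p_monomer[1]), 3 * se + 1e-12)
})

test_that("fine-grid oracle agrees with the CME when Pol II is off", {
  cfg <- single_site_config(kd = 1, kon_m = 0.3, kon_d = 0.3, k_pol = 0)
  W <- 1
  exact <- analytic_single_site(1, 1, W)
  runs <- vapply(1:6, function(r) {
    fine_grid_oracle(cfg, W, dt = 0.01, t_end = 400, seed = 500 + r,
                     burnin = 0.2)$fractions$frac_monomer
  }, numeric(1))
  se <- stats::sd(runs) / sqrt(length(runs))
  expect_lt(abs(mean(runs) - exact$p_monomer), 3 * se + 1e-12)
  expect_error(fine_grid_oracle(cfg, W, dt = 1, t_end = 10, seed = 1),
               "too large")
})

test_that("initiation rate obeys the renewal identity without constraints", {
  # tau = Inf, pol_gap = 0: rate = k_pol * E[active monomers] with
  # E[active] = P(monomer) from the stationary law
  cfg <- single_site_config(kd = 1, kon_m = 0.4, kon_d = 0.4, k_pol = 0.3)
  cfg$kinetics$pol_gap <- 0
  W <- 1
  p_mono <- analytic_single_site(1, 1, W)$p_monomer
  rates <- vapply(1:10, function(r) {
    tr <- simulate_cell(cfg, W, 3000, seed = 600 + r, record_events = FALSE)
    length(attr(tr, "initiation_times")) / 3000
  }, numeric(1))
  se <- stats::sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 0.3 * p_mono), 3 * se + 1e-12)
  # dose 0: rate exactly zero
  o <- fine_grid_oracle(cfg, 0, dt = 0.01, t_end = 50, seed = 1)
  expect_equal(o$initiation_rate, 0)
})

test_that("SSA and fine-grid oracle agree on random parameter draws", {
  withr::with_seed(77, {
    for (draw in 1:5) {
      cfg <- single_site_config(kd = runif(1, 0.5, 3),
                                kon_m = runif(1, 0.1, 0.5),
                                kon_d = runif(1, 0, 0.5),
                                k_pol = runif(1, 0.05, 0.3),
                                tau = sample(c(10, Inf), 1))
      W <- runif(1, 0.5, 3)
      ssa_mrna <- vapply(1:8, function(r) {
        tr <- simulate_cell(cfg, W, 250, seed = 700 + 20 * draw + r,
                            record_events = FALSE)
        as.numeric(attr(tr, "mrna"))
      }, numeric(1))
      fine_mrna <- vapply(1:8, function(r) {
        fine_grid_oracle(cfg, W, dt = 0.005, t_end = 250,
                         seed = 800 + 20 * draw + r)$mrna
      }, numeric(1))
      se <- sqrt(stats::var(ssa_mrna) / 8 + stats::var(fine_mrna) / 8)
      expect_lt(abs(mean(ssa_mrna) - mean(fine_mrna)), 3 * se + 2)
    }
  })
})
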