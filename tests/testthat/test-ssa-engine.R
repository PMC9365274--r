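test_that("identical seeds give bitwise-identical trajectories", {
  cfg <- multi_site_config(3, mode = "distance", k_pol = 0.1, tau = 10)
  a <- simulate_cell(cfg, 1.5, 500, seed = 99)
  b <- simulate_cell(cfg, 1.5, 500, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "initiation_times"), attr(b, "initiation_times"))
  expect_identical(attr(a, "accumulators"), attr(b, "accumulators"))
  c <- simulate_cell(cfg, 1.5, 500, seed = 100)
  expect_false(identical(nrow(a), nrow(c)) &&
                 identical(a$time, c$time))
})

test_that("zero dose means no binding and no transcription", {
  cfg <- multi_site_config(2, k_pol = 0.2)
  tr <- simulate_cell(cfg, 0, 300, seed = 1)
  expect_equal(nrow(tr), 0)
  expect_equal(attr(tr, "mrna"), 0)
  fr <- occupancy_fractions(tr)
  expect_equal(fr$frac_empty, c(1, 1))
  expect_equal(fr$frac_monomer, c(0, 0))
  expect_equal(fr$frac_dimer, c(0, 0))
  expect_equal(fr$frac_active, c(0, 0))
})

test_that("k_pol = 0 leaves occupancy dynamics intact with zero mRNA", {
  cfg0 <- single_site_config(k_pol = 0)
  tr <- simulate_cell(cfg0, 2, 1000, seed = 5)
  expect_equal(attr(tr, "mrna"), 0)
  expect_length(initiation_gaps(tr), 0)
  fr <- occupancy_fractions(tr)
  expect_gt(fr$frac_monomer + fr$frac_dimer, 0)
})

test_that("single-site long-run monomer occupancy matches the binding law", {
  # no dimerisation, no residence limit: stationary P(monomer) = W/(Kd+W)
  kd <- 2
  for (w in c(0.5, 2, 6)) {
    cfg <- single_site_config(kd = kd, kon_d = 0, k_pol = 0)
    fracs <- replicate_fractions(cfg, w, t_end = 4000, n_rep = 12, seed = 70)
    expected <- w / (kd + w)
    se <- stats::sd(fracs) / sqrt(length(fracs))
    expect_lt(abs(mean(fracs) - expected), 3 * se + 1e-12)
  }
})

test_that("occupancy fractions sum to one per element", {
  withr::with_seed(8, {
    for (rep in 1:5) {
      cfg <- multi_site_config(sample(1:3, 1),
                               mode = sample(c("none", "distance"), 1),
                               k_pol = 0.1, tau = sample(c(5, Inf), 1))
      tr <- simulate_cell(cfg, runif(1, 0, 4), 400, seed = rep)
      fr <- occupancy_fractions(tr)
      expect_equal(fr$frac_empty + fr$frac_monomer + fr$frac_dimer,
                   rep(1, nrow(fr)), tolerance = 1e-9)
      expect_true(all(fr$frac_active <= fr$frac_monomer + 1e-12))
    }
  })
})

test_that("no inter-initiation interval ever beats the refractory gap", {
  cfg <- multi_site_config(3, mode = "none", k_pol = 2, tau = Inf)
  cfg$kinetics$pol_gap <- 4
  gaps <- unlist(lapply(1:10, function(r) {
    initiation_gaps(simulate_cell(cfg, 2, 800, seed = 200 + r))
  }))
  expect_gt(length(gaps), 50)
  expect_true(all(gaps >= 4))
})

test_that("pol_gap = 0 removes the floor on initiation intervals", {
  cfg <- single_site_config(k_pol = 5)
  cfg$kinetics$pol_gap <- 0
  gaps <- initiation_gaps(simulate_cell(cfg, 3, 800, seed = 31))
  expect_gt(length(gaps), 10)
  expect_lt(min(gaps), 1) # exponential competition: tiny gaps occur
})

test_that("dose_response summarises replicates and flags replicates = 1", {
  cfg <- single_site_config(k_pol = 0.2, tau = 10)
  dr <- dose_response(cfg, doses = c(0, 1), t_end = 300, replicates = 4,
                      seed = 3)
  s <- summary(dr)
  expect_equal(s$mean_mrna[s$dose == 0], 0)
  expect_equal(s$sd_mrna[s$dose == 0], 0)
  # summary is exactly the group-wise recomputation from raw replicates
  manual <- tapply(dr$mrna, dr$dose, mean)
  expect_equal(as.numeric(manual[as.character(s$dose)]), s$mean_mrna)
  dr1 <- dose_response(cfg, doses = 1, t_end = 200, replicates = 1, seed = 3)
  expect_equal(summary(dr1)$sd_mrna, 0)
  expect_match(attr(dr1, "warnings"), "replicates = 1")
  expect_error(dose_response(cfg, doses = numeric(0)), "non-empty")
})

test_that("replicate sub-seeds are independent of execution order", {
  cfg <- single_site_config(k_pol = 0.2, tau = 10)
  d1 <- dose_response(cfg, doses = c(0.5, 2), t_end = 300, replicates = 3,
                      seed = 11)
  d2 <- dose_response(cfg, doses = c(2, 0.5), t_end = 300, replicates = 3,
                      seed = 11)
  a <- dplyr::arrange(as.data.frame(d1), dose, replicate)
  b <- dplyr::arrange(as.data.frame(d2), dose, replicate)
  expect_equal(a$mrna, b$mrna)
})

test_that("mean mRNA is non-decreasing in the residence limit", {
  cfg <- function(tau) single_site_config(kd = 1, kon_m = 0.15, kon_d = 0.15,
                                          k_pol = 0.1, tau = tau)
  means <- vapply(c(1, 10, 1000), function(tau) {
    summary(dose_response(cfg(tau), doses = 0.5, t_end = 1500,
                          replicates = 30, seed = 17))$mean_mrna
  }, numeric(1))
  expect_true(all(diff(means) > -1e-9))
  # tau = 1000 reproduces the unlimited model within 3 SE
  no_lim <- dose_response(cfg(Inf), doses = 0.5, t_end = 1500,
                          replicates = 30, seed = 23)
  s <- summary(no_lim)
  se <- sqrt(s$se_mrna^2 +
               (summary(dose_response(cfg(1000), doses = 0.5, t_end = 1500,
                                      replicates = 30,
                                      seed = 17))$se_mrna)^2)
  expect_lt(abs(means[3] - s$mean_mrna), 3 * se + 1e-9)
})

test_that("count-based residence mode deactivates after k initiations", {
  cfg <- single_site_config(kd = 0.2, kon_m = 1, kon_d = 0, k_pol = 5)
  cfg$kinetics$residence_mode <- "count"
  cfg$kinetics$residence_count <- 1L
  cfg$kinetics$pol_gap <- 0
  # each bound monomer can fire at most once; koff is tiny, so over a
  # window almost every initiation requires a fresh binding event
  tr <- simulate_cell(cfg, 5, 2000, seed = 41)
  n_binds <- sum(tr$event == "monomer_bind")
  n_inits <- length(attr(tr, "initiation_times"))
  expect_lte(n_inits, n_binds + 1)
  expect_gt(n_inits, 5)
})
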