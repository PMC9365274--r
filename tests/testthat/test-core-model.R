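test_that("off-rates follow koff = Kd * kon", {
  expect_equal(koff_from_kd(1, 1), 1)
  expect_equal(koff_from_kd(2.5, 0.4), 1.0)
  expect_equal(koff_from_kd(1 / 3, 0.9), 0.3)
  expect_error(koff_from_kd(0, 1), "kd")
  expect_error(koff_from_kd(-2, 1), "kd")
})

test_that("distance weight caps at the reference gap and decays beyond it", {
  expect_equal(distance_weight(10, 10), 1)
  expect_equal(distance_weight(20, 10), 0.5)
  expect_equal(distance_weight(5, 10), 1)
  # monotone non-increasing in d
  d <- seq(1, 200, by = 1)
  w <- distance_weight(d, 27)
  expect_true(all(diff(w) <= 0))
  expect_true(all(w > 0 & w <= 1))
  expect_error(distance_weight(0, 10), "gap")
  expect_error(distance_weight(10, -1), "d_ref")
})

test_that("constructors validate their invariants", {
  expect_error(cis_element("x", 1, kd_monomer = -1), "kd_monomer")
  expect_error(crm_kinetics(kon_monomer = -1), ">= 0")
  expect_error(crm_kinetics(residence_limit = 0), "residence_limit")
  expect_error(cooperativity(c_monomer = 0), "factors")
  expect_error(cooperativity(c_dimer = 1.5), "factors")
  el_bad <- dplyr::bind_rows(cis_element("a", 100, 1),
                             cis_element("b", 90, 1))
  expect_error(crm_config(el_bad), "increasing")
  el_none <- cis_element("a", 100, 1, functional = FALSE)
  expect_error(crm_config(el_none), "functional")
  el_dup <- dplyr::bind_rows(cis_element("a", 100, 1),
                             cis_element("a", 120, 1))
  expect_error(crm_config(el_dup), "unique")
})

test_that("cooperativity multiplies the off-rate per qualifying neighbour", {
  cfg <- multi_site_config(3, mode = "equal", c_mono = 0.01, kds = c(1, 1, 1))
  base <- koff_from_kd(1, cfg$kinetics$kon_monomer)
  # single occupied element: no neighbours, any mode
  st1 <- cell_state(cfg, occupancy = c(1, 0, 0))
  expect_equal(effective_off_rate(st1, 1, cfg), base)
  # equal mode, monomer with two monomer neighbours: base * c^2
  st3 <- cell_state(cfg, occupancy = c(1, 1, 1))
  expect_equal(effective_off_rate(st3, 1, cfg), base * 0.01^2)
  # mode none leaves the base rate untouched
  cfg_none <- multi_site_config(3, mode = "none", kds = c(1, 1, 1))
  expect_equal(effective_off_rate(st3, 1, cfg_none), base)
  # unoccupied element is a state error
  expect_error(effective_off_rate(st1, 2, cfg), "unoccupied")
})

test_that("distance mode weights neighbours by their gap", {
  # elements at 950, 970, 997: gaps 20 and 27, d_ref = 20
  cfg <- multi_site_config(3, mode = "distance", c_mono = 0.01,
                           kds = c(1, 1, 1))
  expect_equal(cfg$cooperativity$reference_distance, 20)
  st <- cell_state(cfg, occupancy = c(1, 0, 1))
  base <- koff_from_kd(1, cfg$kinetics$kon_monomer)
  w <- distance_weight(997 - 950, 20)
  expect_equal(effective_off_rate(st, 1, cfg), base * 0.01^w)
})

test_that("dimer off-rates count only dimer neighbours by default", {
  cfg <- multi_site_config(3, mode = "equal", c_dim = 0.2, kds = c(1, 1, 1))
  base_d <- koff_from_kd(1, cfg$kinetics$kon_dimer)
  # dimer flanked by a monomer and a dimer: only the dimer qualifies
  st <- cell_state(cfg, occupancy = c(2, 1, 2))
  expect_equal(effective_off_rate(st, 1, cfg), base_d * 0.2)
  # but the monomer at 2 is stabilised by both occupied neighbours
  base_m <- koff_from_kd(1, cfg$kinetics$kon_monomer)
  expect_equal(effective_off_rate(st, 2, cfg), base_m * 0.01^2)
})

test_that("propensity table enumerates exactly the enabled channels", {
  cfg <- single_site_config(kd = 1, kon_m = 0.5, k_pol = 0.1)
  # empty element at dose 0: a single zero-propensity bind entry
  st0 <- cell_state(cfg)
  pt0 <- propensity_table(st0, 0, cfg)
  expect_equal(pt0$event, "monomer_bind")
  expect_equal(pt0$propensity, 0)
  # linear binding law kon * [WUS]
  pt2 <- propensity_table(st0, 2, cfg)
  expect_equal(pt2$propensity, 1.0)
  # Pol II channel is gated by the refractory clock
  stm <- cell_state(cfg, occupancy = 1, pol_ready_at = 10, t = 5)
  expect_false("pol_recruit" %in% propensity_table(stm, 1, cfg)$event)
  stm2 <- cell_state(cfg, occupancy = 1, pol_ready_at = 10, t = 10)
  pol <- dplyr::filter(propensity_table(stm2, 1, cfg),
                       event == "pol_recruit")
  expect_equal(pol$propensity, 0.1)
})

test_that("non-functional elements contribute no propensity entries", {
  el <- dplyr::bind_rows(cis_element("a", 100, 1),
                         cis_element("b", 130, 1, functional = FALSE))
  cfg <- crm_config(el, crm_kinetics(k_pol = 0), cooperativity("none"))
  pt <- propensity_table(cell_state(cfg), 2, cfg)
  expect_equal(pt$element, "a")
})

test_that("propensities are non-negative over random reachable states", {
  withr::with_seed(42, {
    for (rep in 1:25) {
      n <- sample(1:4, 1)
      cfg <- multi_site_config(
        n, mode = sample(c("none", "equal", "distance"), 1),
        c_mono = runif(1, 0.001, 1), c_dim = runif(1, 0.001, 1),
        k_pol = runif(1, 0, 0.5), kds = runif(5, 0.2, 8))
      occ <- sample(0:2, n, replace = TRUE)
      st <- cell_state(cfg, occupancy = occ, t = runif(1, 0, 100))
      pt <- propensity_table(st, runif(1, 0, 5), cfg)
      expect_true(all(pt$propensity >= 0))
    }
  })
})

test_that("effective off-rate is monotone in neighbour count and distance", {
  cfg <- multi_site_config(3, mode = "equal", c_mono = 0.3, kds = c(1, 1, 1))
  r0 <- effective_off_rate(cell_state(cfg, occupancy = c(1, 0, 0)), 1, cfg)
  r1 <- effective_off_rate(cell_state(cfg, occupancy = c(1, 1, 0)), 1, cfg)
  r2 <- effective_off_rate(cell_state(cfg, occupancy = c(1, 1, 1)), 1, cfg)
  expect_true(r0 >= r1 && r1 >= r2)
  # distance mode: farther neighbour stabilises less (higher off-rate)
  cfgd <- multi_site_config(3, mode = "distance", c_mono = 0.3,
                            kds = c(1, 1, 1))
  near <- effective_off_rate(cell_state(cfgd, occupancy = c(1, 1, 0)), 1, cfgd)
  far <- effective_off_rate(cell_state(cfgd, occupancy = c(1, 0, 1)), 1, cfgd)
  expect_true(near <= far)
})
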