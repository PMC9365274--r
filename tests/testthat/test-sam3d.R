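test_that("the dome has concentric shells with area-scaled cell counts", {
  dome <- build_dome(7, cells_l1 = 196)
  counts <- dplyr::count(tibble::as_tibble(dome), layer)
  counts <- counts$n[order(as.integer(sub("^L", "", counts$layer)))]
  expect_length(counts, 7)
  expect_true(all(diff(counts) < 0)) # strictly decreasing L1 -> L7
  # shell radii: layer k sits at radius (8 - k) * spacing
  r <- sqrt(dome$x^2 + dome$y^2 + dome$z^2)
  expect_equal(r, 8 - as.integer(sub("^L", "", dome$layer)),
               tolerance = 1e-9)
  expect_true(all(dome$z >= 0)) # half dome
  one <- build_dome(1, cells_l1 = 10)
  expect_true(all(one$layer == "L1"))
})

test_that("cells keep a minimum packing distance within each shell", {
  dome <- build_dome(3, spacing = 1, cells_l1 = 60)
  for (l in unique(dome$layer)) {
    pts <- as.matrix(dome[dome$layer == l, c("x", "y", "z")])
    if (nrow(pts) < 2) next
    d <- as.matrix(stats::dist(pts))
    diag(d) <- Inf
    # Fibonacci shells at area-proportional counts keep near-unit spacing
    expect_gt(min(d), 1 * (1 - 0.35))
  }
})

test_that("gradients dose cells by layer and validate their length", {
  dome <- build_dome(3, cells_l1 = 20)
  tis <- assign_gradient(dome, c(0.5, 1, 2))
  expect_equal(unique(tis$dose[tis$layer == "L2"]), 1)
  expect_error(assign_gradient(dome, c(1, 2)), "3 layers")
  expect_error(assign_gradient(dome, c(-1, 1, 2)), ">= 0")
  uni <- assign_gradient(dome, rep(2, 3))
  expect_equal(unique(uni$dose), 2)
})

test_that("a zero gradient silences the whole tissue", {
  tis <- assign_gradient(build_dome(2, cells_l1 = 8), c(0, 0))
  res <- simulate_tissue(tis, build_variant("WT"), t_end = 100, seed = 1)
  expect_true(all(res$mrna == 0))
  expect_true(all(res$frac_monomer == 0))
})

test_that("k_pol = 0 silences mRNA but occupancy maps stay populated", {
  cfg <- build_variant("WT",
                       kinetics = crm_kinetics(k_pol = 0,
                                               residence_limit = Inf))
  tis <- assign_gradient(build_dome(2, cells_l1 = 8), c(1, 2))
  res <- simulate_tissue(tis, cfg, t_end = 300, seed = 2)
  expect_true(all(res$mrna == 0))
  expect_true(all(res$frac_monomer + res$frac_dimer > 0))
  maps <- occupancy_maps(res)
  expect_true(all(maps$mean_occupancy >= 0 & maps$mean_occupancy <= 1))
})

test_that("per-cell results do not depend on cell simulation order", {
  tis <- assign_gradient(build_dome(2, cells_l1 = 10), c(0.5, 2))
  res1 <- simulate_tissue(tis, build_variant("WT"), t_end = 200, seed = 5)
  shuffled <- tis[rev(seq_len(nrow(tis))), ]
  res2 <- simulate_tissue(shuffled, build_variant("WT"), t_end = 200,
                          seed = 5)
  a <- dplyr::arrange(tibble::as_tibble(res1), cell_id)
  b <- dplyr::arrange(tibble::as_tibble(res2), cell_id)
  expect_equal(a$mrna, b$mrna)
  expect_equal(a$frac_dimer, b$frac_dimer)
})

test_that("layer summaries are exactly the per-cell recomputation", {
  tis <- assign_gradient(build_dome(3, cells_l1 = 15), c(0.5, 1, 2))
  res <- simulate_tissue(tis, build_variant("WT"), t_end = 200, seed = 9)
  summ <- layer_summary(res)
  manual <- tibble::as_tibble(res) |>
    dplyr::group_by(layer) |>
    dplyr::summarise(m = mean(mrna), s = stats::sd(mrna), .groups = "drop")
  joined <- dplyr::left_join(summ, manual, by = "layer")
  expect_equal(joined$mean_mrna, joined$m)
  expect_equal(joined$sd_mrna[joined$n_cells > 1],
               joined$s[joined$n_cells > 1])
  expect_true(all(summ$sd_mrna >= 0))
})

test_that("uncooperative tissue cells match the single-cell dose response", {
  cfg <- build_variant("970i") # mode none, single functional element
  dome <- build_dome(1, cells_l1 = 24)
  tis <- assign_gradient(dome, 1)
  res <- simulate_tissue(tis, cfg, t_end = 1000, seed = 33)
  dr <- dose_response(cfg, doses = 1, t_end = 1000, replicates = 24,
                      seed = 77)
  s <- summary(dr)
  se <- sqrt(s$se_mrna^2 + (stats::sd(res$mrna) / sqrt(nrow(res)))^2)
  expect_lt(abs(mean(res$mrna) - s$mean_mrna), 3 * se + 1e-9)
})

test_that("a factorial cooperativity sweep covers the grid", {
  tis <- build_dome(2, cells_l1 = 8)
  sw <- cooperativity_sweep(build_variant("WT"), c(0.5, 2),
                            c_mono_list = c(1, 0.01),
                            c_dim_list = c(1, 0.2),
                            tissue = tis, t_end = 150, seed = 4)
  expect_equal(nrow(dplyr::distinct(sw, c_monomer, c_dimer)), 4)
  expect_equal(nrow(sw), 4 * 2) # grid x layers
  # both factors at 1 reproduce a mode=none run exactly (same seed)
  none_cfg <- build_variant("WT", coop = cooperativity("none"),
                            kinetics = crm_kinetics(residence_limit = Inf))
  none <- simulate_tissue(assign_gradient(tis, c(0.5, 2)), none_cfg,
                          t_end = 150, seed = 4)
  both1 <- dplyr::filter(sw, c_monomer == 1, c_dimer == 1)
  expect_equal(both1$mean_mrna, layer_summary(none)$mean_mrna)
  expect_error(cooperativity_sweep(build_variant("WT"), c(0.5, 2),
                                   c_mono_list = 2, c_dim_list = 1,
                                   tissue = tis),
               "c_mono_list")
})
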