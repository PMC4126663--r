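test_that("phage placement maps modes to the expected compartments", {
  expect_equal(place_phages("centre", 1, 11), 6L)
  expect_equal(place_phages("centre", 2, 11), c(6L, 6L))
  expect_equal(place_phages("quarters", 2, 12), c(4L, 10L))
  expect_equal(place_phages("poles", 2, 12), c(1L, 12L))
  expect_equal(place_phages("explicit", 3, 10, positions = c(0, 0.5, 1)),
               c(1L, 6L, 10L))
  expect_error(place_phages("quarters", 3, 12), "moi = 2")
  # poles placement is mirror-symmetric for any n; quarters for odd grids
  for (n in c(11L, 12L)) {
    comps <- place_phages("poles", 2, n)
    expect_setequal(n + 1L - comps, comps)
  }
  q11 <- place_phages("quarters", 2, 11L)
  expect_setequal(12L - q11, q11)
})

test_that("traversal time is quadratic in length and inverse in D", {
  expect_equal(traversal_time(1, 0.5), 1)
  expect_equal(traversal_time(2, 0.5), 4)
  expect_equal(traversal_time(3, 10 * 0.2), traversal_time(3, 0.2) / 10)
  # defaults separate the mRNA and protein timescales around the 60-min window
  sc <- spatial_config(placement_mode = "centre")
  expect_equal(traversal_time(1, sc$D_mrna), 10)
  expect_lt(traversal_time(1, sc$D_protein), 1)
})

test_that("one-compartment discretisation is the well-mixed network", {
  nw <- build_network(default_parameters(), cell_config(moi = 1))
  nw1 <- discretise(nw, spatial_config(n_compartments = 1,
                                       placement_mode = "centre"))
  expect_identical(nw1$species, nw$species)
  expect_identical(nw1$rates, nw$rates)
  expect_identical(nw1$reactants, nw$reactants)
  expect_identical(nw1$products, nw$products)
})

test_that("hop propensities and compartment volumes follow the RDME scaling", {
  nw <- build_network(default_parameters(), cell_config(moi = 1))
  sc <- spatial_config(n_compartments = 2, cell_length = 1,
                       D_mrna = 0.3, D_protein = 0.3,
                       placement_mode = "explicit", positions = 0.1)
  snw <- discretise(nw, sc)
  # hop propensity D/h^2 * x for 7 molecules, h = 0.5
  state <- stats::setNames(rep(0L, length(snw$species)), snw$species)
  state["mCI_c1"] <- 7L
  j <- match("hop_mCI_1to2", snw$reaction_names)
  expect_equal(propensity(snw, j, state, volume = 1), 7 * 0.3 / 0.25)
  # bimolecular rates are rescaled by n to per-compartment volume
  jb <- match("bind_PRE_c1", snw$reaction_names)
  expect_equal(snw$rates[jb], 2 * default_parameters()$bind_CII)
})

test_that("pure diffusion conserves mass and equilibrates evenly", {
  # two compartments, one diffusible species, no reactions
  base <- birth_death_network(0, 0)
  sc <- spatial_config(n_compartments = 2, D_mrna = 1, D_protein = 1,
                       placement_mode = "explicit", positions = 0)
  snw <- discretise(base, sc)
  p <- fast_params(output_interval = 1)
  cfg <- minimal_cell()
  x0 <- stats::setNames(c(10L, 0L), snw$species)
  finals <- matrix(0, 200, 2)
  total_ok <- TRUE
  for (i in seq_len(200)) {
    tr <- simulate_ssa(snw, cfg, p, horizon = 10, seed = 1000 + i, x0 = x0)
    total_ok <- total_ok && all(rowSums(tr$counts) == 10)
    finals[i, ] <- tr$counts[nrow(tr$counts), ]
  }
  expect_true(total_ok)
  # long-run expectation is (5, 5); mean of 200 endpoint draws
  se <- sd(finals[, 1]) / sqrt(200)
  expect_lt(abs(mean(finals[, 1]) - 5), 3 * se)
})

test_that("spatial ensemble at moderate n matches the well-mixed mean [CII]", {
  # fast-diffusion reduction at desk scale: both coefficients x100 on a
  # coarse grid makes every species well mixed within a fraction of a minute
  p <- default_parameters()
  cfg <- cell_config(moi = 1, volume = 1)
  nw <- build_network(p, cfg)
  ns <- run_decision_ensemble(nw, cfg, p, n = 200, horizon = 10, seed = 2,
                              window = c(0, 10))
  sc <- spatial_config(n_compartments = 3, D_mrna = 5, D_protein = 250,
                       placement_mode = "centre")
  snw <- discretise(nw, sc, volume = 1)
  x0 <- initial_state_spatial(snw, cfg, sc)
  e <- lysolatch:::.spatial_decision_ensemble(snw, cfg, p, x0, n = 12,
                                              horizon = 10, seed = 3,
                                              window = c(0, 10))
  i_end <- length(ns$readout_mean)
  se <- sqrt(e$readout_sd[i_end]^2 / e$n + ns$readout_sd[i_end]^2 / ns$n)
  expect_lt(abs(e$readout_mean[i_end] - ns$readout_mean[i_end]), 3 * se)
})

test_that("spatial initial state pins phage genomes to their slices", {
  p <- default_parameters()
  cfg <- cell_config(moi = 2, volume = 2)
  nw <- build_network(p, cfg)
  sc <- spatial_config(n_compartments = 11, cell_length = 2,
                       placement_mode = "poles")
  snw <- discretise(nw, sc, volume = 2)
  x0 <- initial_state_spatial(snw, cfg, sc)
  expect_equal(unname(x0[c("PR_c1", "PRE_c1", "PR_c11", "PRE_c11")]),
               rep(1L, 4))
  expect_equal(sum(x0), 4L)
  # offsets and replication are not supported spatially
  cfg_off <- cell_config(moi = 2, volume = 2, infection_offsets = c(0, 5))
  expect_error(initial_state_spatial(snw, cfg_off, sc), "not supported")
  expect_error(initial_state(snw, cfg), "discretised")
})
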