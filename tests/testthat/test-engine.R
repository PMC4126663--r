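test_that("SSA reproduces birth-death stationary mean and Fano factor", {
  nw <- birth_death_network(birth = 10, death = 1)
  p <- fast_params(output_interval = 5)
  cfg <- minimal_cell()
  finals <- vapply(seed_stream(42, 400), function(s) {
    tr <- simulate_ssa(nw, cfg, p, horizon = 40, seed = s, x0 = c(X = 0L))
    tr$counts[nrow(tr$counts), "X"]
  }, numeric(1))
  se_mean <- sqrt(10 / 400)
  expect_lt(abs(mean(finals) - 10), 3 * se_mean)
  fano <- var(finals) / mean(finals)
  expect_lt(abs(fano - 1), 3 * sqrt(2 / 400))
})

test_that("zero rates freeze the state on the full output grid", {
  nw <- birth_death_network(birth = 0, death = 0)
  p <- fast_params(output_interval = 0.5)
  tr <- simulate_ssa(nw, minimal_cell(), p, horizon = 10, seed = 1, x0 = c(X = 7L))
  expect_equal(tr$times, seq(0, 10, by = 0.5))
  expect_true(all(tr$counts[, "X"] == 7))
})

test_that("identical seeds give bit-identical trajectories", {
  p <- default_parameters()
  cfg <- cell_config(moi = 2, volume = 2,
                     variants = variant_flags(phage_replication = TRUE))
  nw <- build_network(p, cfg)
  a <- simulate_ssa(nw, cfg, p, horizon = 20, seed = 123)
  b <- simulate_ssa(nw, cfg, p, horizon = 20, seed = 123)
  expect_identical(a$counts, b$counts)
  c2 <- simulate_ssa(nw, cfg, p, horizon = 20, seed = 124)
  expect_false(identical(a$counts, c2$counts))
})

test_that("phage replication follows the capped doubling schedule", {
  expect_equal(phage_copies(1, 0), 1)
  expect_equal(phage_copies(1, 7), 4)
  expect_equal(phage_copies(1, 15), 32)
  expect_equal(phage_copies(1, 60), 32)
  expect_equal(phage_copies(3, 4), 6)
  expect_error(phage_copies(1, 5, doubling_period = 0), "positive")

  # event correctness: genome count along a trajectory matches the formula
  p <- default_parameters()
  cfg <- cell_config(moi = 1, variants = variant_flags(phage_replication = TRUE))
  nw <- build_network(p, cfg)
  tr <- simulate_ssa(nw, cfg, p, horizon = 30, seed = 5)
  expect_equal(genome_copies(tr, nw), phage_copies(1, tr$times))
})

test_that("delayed infection adds genomes at the offset time", {
  p <- default_parameters()
  cfg <- cell_config(moi = 2, volume = 2, infection_offsets = c(0, 10))
  nw <- build_network(p, cfg)
  tr <- simulate_ssa(nw, cfg, p, horizon = 20, seed = 9)
  g <- genome_copies(tr, nw)
  expect_true(all(g[tr$times < 10] == 1))
  expect_true(all(g[tr$times >= 10] == 2))
  # offsets are relative to the first infection
  expect_error(cell_config(moi = 2, infection_offsets = c(5, 10)), "origin")
})

test_that("dilution removes free species at the growth rate", {
  nw <- birth_death_network(birth = 0, death = 0)
  g <- 0.05
  cfg <- cell_config(growth = growth_model(rate = g, dilution = TRUE,
                                           volume_growth = FALSE))
  p <- fast_params(output_interval = 10)
  finals <- vapply(seed_stream(8, 300), function(s) {
    tr <- simulate_ssa(nw, cfg, p, horizon = 20, seed = s, x0 = c(X = 200L))
    tr$counts[nrow(tr$counts), "X"]
  }, numeric(1))
  expected <- 200 * exp(-g * 20)
  se <- sd(finals) / sqrt(300)
  expect_lt(abs(mean(finals) - expected), 3 * se)
})

test_that("deterministic integrator matches closed forms and the SSA grid", {
  nw <- birth_death_network(birth = 10, death = 1)
  p <- fast_params(output_interval = 0.5)
  det <- integrate_deterministic(nw, minimal_cell(), p, horizon = 8,
                                 x0 = c(X = 0))
  expect_equal(det$times, seq(0, 8, by = 0.5))
  expect_equal(det$counts[det$times == 5, "X"], 10 * (1 - exp(-5)),
               tolerance = 1e-6, ignore_attr = TRUE)
  # all-zero rates give the constant solution
  det0 <- integrate_deterministic(birth_death_network(0, 0), minimal_cell(),
                                  p, horizon = 5, x0 = c(X = 3))
  expect_true(all(det0$counts[, "X"] == 3))
})

test_that("mean-field concentrations depend on MOI and volume only via their ratio", {
  p <- default_parameters()
  ro <- lapply(c(1, 2), function(m) {
    cfg <- cell_config(moi = m, volume = m)
    nw <- build_network(p, cfg)
    cii_readout(integrate_deterministic(nw, cfg, p, horizon = 60))
  })
  expect_equal(ro[[1]], ro[[2]], tolerance = 1e-5)
})

test_that("ensembles are seeded, summarised, and reproducible", {
  p <- default_parameters()
  cfg <- cell_config(moi = 1)
  nw <- build_network(p, cfg)
  e1 <- run_ensemble(nw, cfg, p, horizon = 10, n = 1, seed = 4)
  expect_equal(e1$mean, e1$trajectories[[1]]$counts, ignore_attr = TRUE)
  expect_true(all(e1$sd == 0))
  e3a <- run_ensemble(nw, cfg, p, horizon = 10, n = 3, seed = 4)
  e3b <- run_ensemble(nw, cfg, p, horizon = 10, n = 3, seed = 4)
  expect_identical(e3a$mean, e3b$mean)
})

test_that("ensemble summary TSV has per-species mean and SD columns", {
  p <- default_parameters()
  cfg <- cell_config(moi = 1)
  nw <- build_network(p, cfg)
  e <- run_ensemble(nw, cfg, p, horizon = 5, n = 4, seed = 6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ensemble_tsv(e, path)
  df <- read.delim(path, check.names = FALSE)
  expect_equal(nrow(df), length(e$times))
  expect_true(all(c("time", "mean_CII", "sd_CII") %in% names(df)))
  expect_equal(df$mean_CII, unname(e$mean[, "CII"]))
})

test_that("trajectory TSV round-trips counts, times and volumes", {
  p <- default_parameters()
  cfg <- cell_config(moi = 1)
  nw <- build_network(p, cfg)
  tr <- simulate_ssa(nw, cfg, p, horizon = 5, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory_tsv(tr, path)
  back <- read_trajectory_tsv(path)
  expect_equal(back$times, tr$times)
  expect_equal(back$counts, tr$counts, ignore_attr = TRUE)
  expect_equal(back$volumes, tr$volumes)
})

test_that("growth transcription multiplier interpolates between the anchors", {
  gm_slow <- growth_model(rate = log(2) / 90, tx_coupling = TRUE)
  gm_fast <- growth_model(rate = log(2) / 30, tx_coupling = TRUE)
  expect_equal(lysolatch:::.tx_multiplier(gm_slow), 2)
  expect_equal(lysolatch:::.tx_multiplier(gm_fast), 1)
  gm_mid <- growth_model(rate = (log(2) / 90 + log(2) / 30) / 2, tx_coupling = TRUE)
  expect_equal(lysolatch:::.tx_multiplier(gm_mid), 1.5)
  # clamped outside the anchor range
  expect_equal(lysolatch:::.tx_multiplier(growth_model(rate = 0)), 2)
})
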