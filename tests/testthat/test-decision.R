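test_that("CII readout sums protein equivalents and divides by volume", {
  nw <- build_network(default_parameters(), cell_config(moi = 1))
  counts <- matrix(0, 2, length(nw$species),
                   dimnames = list(NULL, nw$species))
  counts[, "CII"] <- 3; counts[, "CII2"] <- 2; counts[, "PREact"] <- 1
  traj <- structure(list(times = c(0, 1), counts = counts,
                         volumes = c(1, 2), cii_weight = nw$cii_weight),
                    class = "trajectory")
  expect_equal(cii_readout(traj), c(9, 4.5))
  expect_equal(cii_readout(traj, "free_monomer"), c(3, 1.5))
  expect_equal(cii_readout(traj, "free_dimer"), c(4, 2))
  # tetramer counts 4 equivalents
  nw4 <- build_network(default_parameters(),
                       cell_config(variants = variant_flags(cii_tetramer = TRUE)))
  expect_equal(unname(nw4$cii_weight[c("CII4", "PREact")]), c(4, 4))
  # all-zero state reads zero
  counts[] <- 0
  traj$counts <- counts
  expect_equal(cii_readout(traj), c(0, 0))
})

test_that("decide applies window, mode, and the tie-to-lysis rule", {
  mk_traj <- function(readout, times = seq(0, 60, by = 0.5)) {
    counts <- matrix(readout, length(times), 1, dimnames = list(NULL, "CII"))
    structure(list(times = times, counts = counts,
                   volumes = rep(1, length(times)), cii_weight = c(CII = 1)),
              class = "trajectory")
  }
  tr5 <- mk_traj(5)
  out <- decide(tr5, decision_criterion(4))
  expect_equal(out$statistic, 5)
  expect_equal(out$label, "lysogeny")
  # ties classify as lysis
  expect_equal(decide(tr5, decision_criterion(5))$label, "lysis")
  # step readout: 0 on [0,30], 10 on (30,60] -> time average just under 5
  step <- mk_traj(ifelse(seq(0, 60, by = 0.5) > 30, 10, 0))
  expect_equal(decide(step, decision_criterion(4))$statistic,
               mean(ifelse(seq(0, 60, by = 0.5) > 30, 10, 0)))
  expect_equal(decide(step, decision_criterion(4))$label, "lysogeny")
  # single-timepoint mode reads the window end
  expect_equal(decide(step, decision_criterion(4, mode = "single_timepoint"))$statistic, 10)
  # window must fit the trajectory
  expect_error(decide(tr5, decision_criterion(4, window = c(0, 90))), "window")
})

test_that("lysogeny rate is a binomial fraction with Wald SE", {
  out <- lysogeny_rate(rep(c("lysogeny", "lysis"), c(250, 250)))
  expect_equal(out$rate, 0.5)
  expect_equal(out$se, sqrt(0.25 / 500))
  expect_equal(lysogeny_rate(rep("lysis", 10))$rate, 0)
  expect_equal(lysogeny_rate(rep("lysis", 10))$se, 0)
  shuffled <- sample(rep(c("lysogeny", "lysis"), c(100, 300)))
  expect_equal(lysogeny_rate(shuffled)$rate, 0.25)
  expect_error(lysogeny_rate(character(0)), "no outcomes")
  wi <- wilson_interval(lysogeny_rate(rep("lysis", 10)))
  expect_true(wi[1] >= 0 && wi[2] <= 1 && wi[2] > 0)
})

test_that("analytic rate matches the Gaussian tail and its limits", {
  expect_equal(analytic_rate(10, 2, 10), 0.5)
  # frozen from numerical integration of the standard normal density:
  # integrate(dnorm, 1, Inf) = 0.1586553
  expect_equal(analytic_rate(10, 2, 12), 0.1586553, tolerance = 1e-6)
  expect_equal(analytic_rate(10, 0, 12), 0)
  expect_equal(analytic_rate(13, 0, 12), 1)
  # strictly decreasing in K (within +/- 4 sigma), 0.5 at the mean
  for (s in c(2, 7)) {
    Ks <- seq(10 - 4 * s, 10 + 4 * s, length.out = 33)
    r <- analytic_rate(10, s, Ks)
    expect_true(all(diff(r) < 0))
    expect_equal(analytic_rate(10, s, 10), 0.5)
  }
})

test_that("phenomenological rate has Hill midpoint, unanimity, and saturation", {
  expect_equal(pheno_rate(1, 1, K_half = 1, h = 2), 0.5)
  expect_equal(pheno_rate(2, 2, K_half = 1, h = 3), 0.25)
  expect_equal(pheno_rate(3, 3, K_half = 1, h = 2), 0.5^3)
  # monotone increasing in concentration at fixed MOI
  vols <- c(4, 2, 1, 0.5, 0.25)
  r <- pheno_rate(2, vols, K_half = 1, h = 2)
  expect_true(all(diff(r) > 0))
  expect_equal(pheno_rate(1, 1e-6, K_half = 1, h = 2), 1, tolerance = 1e-4)
  expect_error(pheno_rate(0, 1), "positive")
})

test_that("decision ensembles support post-hoc thresholding", {
  p <- default_parameters()
  cfg <- cell_config(moi = 1)
  nw <- build_network(p, cfg)
  e <- run_decision_ensemble(nw, cfg, p, n = 60, horizon = 20, seed = 3,
                             window = c(0, 20))
  expect_length(e$stat, 60)
  # rates monotone non-increasing in K when one ensemble is reused
  Ks <- quantile(e$stat, c(0.1, 0.3, 0.5, 0.7, 0.9))
  tab <- threshold_rates(e, Ks)
  expect_true(all(diff(tab$rate) <= 0))
  expect_true(all(tab$rate >= 0 & tab$rate <= 1))
  expect_equal(tab$se, sqrt(tab$rate * (1 - tab$rate) / tab$n))
  # extreme thresholds give rates 1 and 0
  expect_equal(threshold_rates(e, -1)$rate, 1)
  expect_equal(threshold_rates(e, max(e$stat) + 1)$rate, 0)
  # per-run decision table round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_decision_tsv(e, median(e$stat), path)
  df <- read.delim(path)
  expect_equal(nrow(df), 60)
  expect_equal(sum(df$label == "lysogeny"),
               unname(threshold_rates(e, median(e$stat))$n_lysogeny))
  # time-average and single-timepoint rate curves order thresholds the same way
  lo_hi <- quantile(e$stat, c(0.2, 0.8))
  ta <- threshold_rates(e, lo_hi, mode = "time_average")$rate
  st <- threshold_rates(e, quantile(e$endpoint, c(0.2, 0.8)),
                        mode = "single_timepoint")$rate
  expect_true(ta[1] > ta[2] && st[1] > st[2])
})
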