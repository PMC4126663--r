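test_that("default parameter set is positive, pure, and regime-valid", {
  p <- default_parameters()
  vals <- unlist(unclass(p))
  expect_true(all(vals > 0))
  expect_identical(p, default_parameters())

  # deterministic limit at MOI=1, V=1: [CII] rises from zero and stays high
  cfg <- cell_config(moi = 1, volume = 1)
  nw <- build_network(p, cfg)
  det <- integrate_deterministic(nw, cfg, p, horizon = 60)
  ro <- cii_readout(det)
  expect_gt(mean(ro), 0)
  expect_true(all(diff(ro[det$times <= 15]) > 0))     # monotone early rise
  expect_gt(ro[length(ro)], 0.75 * max(ro))           # no late collapse
})

test_that("baseline network has the documented 14 species and 25 reactions", {
  nw <- build_network(default_parameters(), cell_config(moi = 1))
  expect_length(nw$species, 14)
  expect_length(nw$rates, 25)
  # reaction classes: 6 dimerisation, 3 protein decay, 3 mRNA decay,
  # 3 translation, 6 promoter (un)binding, 4 transcription
  expect_equal(sum(nw$order == 2), 3 + 3)   # dimerisations + bindings
  expect_equal(sum(nw$order == 0), 0)
  expect_equal(sum(startsWith(nw$reaction_names, "tx_")), 4)
})

test_that("variant flags extend the network as specified", {
  p <- default_parameters()
  tet <- build_network(p, cell_config(variants = variant_flags(cii_tetramer = TRUE)))
  expect_true("CII4" %in% tet$species)
  expect_length(tet$rates, 27)
  # PRE binding consumes CII4, not CII2
  j <- match("bind_PRE", tet$reaction_names)
  expect_equal(unname(tet$reactants["CII4", j]), 1L)
  expect_equal(unname(tet$reactants["CII2", j]), 0L)

  rep_nw <- build_network(p, cell_config(variants = variant_flags(ci_self_repression = TRUE)))
  expect_true("PRCI2rep" %in% rep_nw$species)
  expect_length(rep_nw$rates, 27)

  # replication is an event-schedule feature, not extra reactions
  repl <- build_network(p, cell_config(variants = variant_flags(phage_replication = TRUE)))
  expect_length(repl$rates, 25)
})

test_that("MOI enters through initial promoter copies, not the reaction list", {
  p <- default_parameters()
  nw1 <- build_network(p, cell_config(moi = 1))
  nw2 <- build_network(p, cell_config(moi = 2))
  expect_identical(nw1$reaction_names, nw2$reaction_names)
  x0 <- initial_state(nw2, cell_config(moi = 2))
  expect_equal(unname(x0["PR"]), 2L)
  expect_equal(unname(x0["PRE"]), 2L)
  expect_true(all(x0[setdiff(names(x0), c("PR", "PRE"))] == 0))
})

test_that("promoter copies are conserved by every reaction", {
  for (vf in list(variant_flags(),
                  variant_flags(cii_tetramer = TRUE, ci_self_repression = TRUE))) {
    nw <- build_network(default_parameters(), cell_config(variants = vf))
    for (group in nw$promoter_species) {
      expect_true(all(colSums(nw$net_change[group, , drop = FALSE]) == 0))
    }
  }
})

test_that("propensities follow stochastic mass action with volume scaling", {
  nw <- build_network(default_parameters(), cell_config(moi = 1))
  state <- initial_state(nw, cell_config(moi = 1))
  state["CII2"] <- 4; state["PRE"] <- 1
  p <- default_parameters()
  # heterodimeric binding: (k/V) x y
  expect_equal(propensity(nw, "bind_PRE", state, volume = 2),
               p$bind_CII * 4 * 1 / 2)
  # homodimerisation: (k/V) x (x-1) / 2
  state["CI"] <- 3
  expect_equal(propensity(nw, "dim_CI", state, volume = 1),
               p$dim_fwd_CI * 3 * 2 / 2)
  # unimolecular reactions are volume-free
  state["mCI"] <- 5
  expect_equal(propensity(nw, "deg_mCI", state, volume = 1),
               propensity(nw, "deg_mCI", state, volume = 2))
  # negative counts are a hard error
  state["CI"] <- -1
  expect_error(propensity(nw, "dim_CI", state, volume = 1), "negative")
})

test_that("noise scaling moves translation and mRNA decay only, at fixed mean", {
  p <- default_parameters()
  expect_identical(apply_noise_scaling(p, 1), p)
  p2 <- apply_noise_scaling(p, 2)
  expect_equal(p2$translation, 2 * p$translation)
  expect_equal(p2$mrna_decay, 2 * p$mrna_decay)
  same <- setdiff(names(unclass(p)), c("translation", "mrna_decay"))
  expect_identical(unclass(p2)[same], unclass(p)[same])
  # stationary mean of a constitutive gene is invariant in f
  mean_of <- function(pp) pp$tx_CII * pp$translation / (pp$mrna_decay * pp$decay_CII)
  expect_equal(mean_of(apply_noise_scaling(p, 4)), mean_of(p))
  expect_error(apply_noise_scaling(p, 0), "positive")
})

test_that("parameter perturbation is log-uniform within the fold bound", {
  p <- default_parameters()
  rate_fields <- setdiff(names(unclass(p)), c("output_interval", "cell_width"))
  # support: every multiplier inside [1/c, c] over many draws
  mult <- replicate(400, {
    q <- perturb_parameters(p, 2, seed = sample.int(1e6, 1))
    unlist(unclass(q)[rate_fields]) / unlist(unclass(p)[rate_fields])
  })
  expect_true(all(mult >= 0.5 - 1e-12 & mult <= 2 + 1e-12))
  # log-uniform symmetry: median multiplier near 1
  expect_gt(median(mult), 0.95)
  expect_lt(median(mult), 1.05)
  # determinism and control-field invariance
  expect_identical(perturb_parameters(p, 10, seed = 7),
                   perturb_parameters(p, 10, seed = 7))
  q <- perturb_parameters(p, 10, seed = 7)
  expect_identical(q$output_interval, p$output_interval)
  expect_identical(q$cell_width, p$cell_width)
})

test_that("capsule volume matches spherocylinder geometry and is superlinear", {
  expect_equal(capsule_volume(1, 1), 4 / 3 * pi * 0.125)
  expect_equal(capsule_volume(2, 1), pi * 0.25 + 4 / 3 * pi * 0.125)
  for (L in c(1.2, 2, 5)) {
    expect_gt(capsule_volume(2 * L, 1), 2 * capsule_volume(L, 1))
  }
  expect_error(capsule_volume(0.5, 1), ">=")
})

test_that("parameter config round-trips exactly and rejects unknown keys", {
  p <- perturb_parameters(default_parameters(), 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_params(p, path)
  expect_equal(read_params(path), p)
  writeLines("translatoin: 2.0", path)
  expect_error(read_params(path), "translatoin")
})
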