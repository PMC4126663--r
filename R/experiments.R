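# Figure-level experiment drivers. Each driver runs seeded decision
# ensembles (one ensemble per condition, reused across every threshold:
# thresholding is post hoc) and returns a `sweep_result`: a long-format
# results table plus the underlying ensembles for further analysis.

.sweep_result <- function(table, ensembles = NULL, extra = list()) {
  structure(c(list(table = table, ensembles = ensembles), extra),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Sweep result (", nrow(x$table), " rows)\n", sep = "")
  print(utils::head(x$table, 12))
  if (nrow(x$table) > 12) cat("...\n")
  invisible(x)
}

# normalise a `conditions` argument: a named list whose elements are either
# cell_configs or list(config=, params=) pairs
.normalise_conditions <- function(conditions, params) {
  if (is.null(names(conditions)) || any(names(conditions) == ""))
    stop("conditions must be a named list (labels must be unique)")
  if (anyDuplicated(names(conditions)))
    stop("condition labels must be unique within a sweep")
  lapply(conditions, function(cond) {
    if (inherits(cond, "cell_config"))
      list(config = cond, params = params)
    else if (is.list(cond) && inherits(cond$config, "cell_config"))
      list(config = cond$config,
           params = if (is.null(cond$params)) params else cond$params)
    else stop("each condition must be a cell_config or list(config=, params=)")
  })
}

.default_conditions <- function(variants = variant_flags()) {
  list("MOI1_V1" = cell_config(moi = 1, volume = 1, variants = variants),
       "MOI2_V2" = cell_config(moi = 2, volume = 2, variants = variants))
}

# run one decision ensemble per condition, on disjoint seed streams
.condition_ensembles <- function(conds, n, horizon, window, seed) {
  out <- vector("list", length(conds))
  names(out) <- names(conds)
  for (i in seq_along(conds)) {
    cond <- conds[[i]]
    nw <- build_network(cond$params, cond$config)
    out[[i]] <- run_decision_ensemble(
      nw, cond$config, cond$params, n = n, horizon = horizon,
      seed = seed_stream(seed, 1, stream = i)[1], window = window)
  }
  out
}

.pooled_stat <- function(ensembles) {
  all_stats <- unlist(lapply(ensembles, function(e) e$stat))
  c(mean = mean(all_stats), sd = stats::sd(all_stats))
}

#' Lysogeny rate across decision thresholds
#'
#' For each condition, runs one ensemble of `n` cells and computes the
#' lysogeny rate at every threshold in `K_grid` (default: a grid spanning
#' the pooled mean +/- 2.5 pooled SD of the decision statistic). The
#' Gaussian [analytic_rate()] computed from each condition's ensemble
#' moments is reported alongside.
#'
#' @param conditions named list of [cell_config()]s (or
#'   `list(config=, params=)` for per-condition parameter overrides);
#'   default: the MOI=1,V=1 vs MOI=2,V=2 comparison
#' @param K_grid thresholds (concentration units); `NULL` for the automatic
#'   pooled grid
#' @param n runs per condition
#' @param seed master seed
#' @param params parameter set used for conditions without an override
#' @param horizon simulated time, min
#' @param window decision window, min
#' @return a `sweep_result`; `$table` has columns `condition`, `K`, `n`,
#'   `n_lysogeny`, `rate`, `se`, `mu`, `sigma`, `analytic`
#' @export
threshold_sweep <- function(conditions = .default_conditions(), K_grid = NULL,
                            n = 5000, seed = 1L,
                            params = default_parameters(), horizon = 60,
                            window = c(0, 60)) {
  conds <- .normalise_conditions(conditions, params)
  ens <- .condition_ensembles(conds, n, horizon, window, seed)
  pooled <- .pooled_stat(ens)
  if (is.null(K_grid))
    K_grid <- pooled["mean"] + seq(-2.5, 2.5, by = 0.25) * pooled["sd"]
  K_grid <- pmax(K_grid, 0)
  rows <- lapply(names(ens), function(lab) {
    e <- ens[[lab]]
    tab <- threshold_rates(e, K_grid)
    mu <- mean(e$stat); sigma <- stats::sd(e$stat)
    cbind(condition = lab, tab, mu = mu, sigma = sigma,
          analytic = analytic_rate(mu, sigma, tab$K))
  })
  .sweep_result(do.call(rbind, rows), ens,
                list(pooled_mean = unname(pooled["mean"]),
                     pooled_sd = unname(pooled["sd"])))
}

#' Lysogeny rate and noise across an MOI series at fixed concentration
#'
#' Simulates MOI = `moi_list` with `V = moi / concentration`, so every
#' condition has the same viral concentration but different absolute copy
#' numbers. Thresholds are expressed as offsets from the pooled mean in
#' pooled-SD units (`policy_offsets`, default low/mean/high = -1, 0, +1).
#' The phenomenological reference rate is reported per MOI.
#'
#' @param concentration viral concentration MOI/V shared by all conditions
#' @param moi_list integer MOIs
#' @param policy_offsets named numeric vector of threshold offsets in
#'   pooled-SD units
#' @inheritParams threshold_sweep
#' @param K_half,h constants of the [pheno_rate()] reference
#' @return a `sweep_result`; `$table` has one row per (moi, policy)
#' @export
moi_series <- function(concentration = 1, moi_list = 1:5,
                       policy_offsets = c(low = -1, mean = 0, high = 1),
                       n = 2000, seed = 1L, params = default_parameters(),
                       horizon = 60, window = c(0, 60), K_half = 1, h = 2) {
  conds <- lapply(moi_list, function(m)
    cell_config(moi = m, volume = m / concentration))
  names(conds) <- paste0("MOI", moi_list)
  conds <- .normalise_conditions(conds, params)
  ens <- .condition_ensembles(conds, n, horizon, window, seed)
  pooled <- .pooled_stat(ens)
  rows <- list()
  for (i in seq_along(moi_list)) {
    e <- ens[[i]]
    mu <- mean(e$stat); sigma <- stats::sd(e$stat)
    for (pol in names(policy_offsets)) {
      K <- max(0, pooled["mean"] + policy_offsets[[pol]] * pooled["sd"])
      tab <- threshold_rates(e, K)
      rows[[length(rows) + 1L]] <- cbind(
        moi = moi_list[i], volume = moi_list[i] / concentration,
        policy = pol, tab, mu = mu, sigma = sigma, cv = sigma / mu,
        pheno = pheno_rate(moi_list[i], moi_list[i] / concentration,
                           K_half, h))
    }
  }
  .sweep_result(do.call(rbind, rows), ens,
                list(pooled_mean = unname(pooled["mean"]),
                     pooled_sd = unname(pooled["sd"])))
}

#' Lysogeny rate under modulated intrinsic noise
#'
#' Scales burstiness with [apply_noise_scaling()] over `f_list` at fixed
#' MOI = 1, V = 1, and thresholds every ensemble at offsets from the
#' baseline (f = 1) mean measured in baseline-SD units, so the three policy
#' thresholds are identical absolute concentrations across f.
#'
#' By default this sweep classifies on the single-time-point statistic (the
#' CII concentration at the window end) rather than the time average. The
#' two criteria give very similar fate calls, but the joint
#' translation/mRNA-decay scaling acts on the instantaneous fluctuations of
#' CII — for a linear expression cascade the zero-frequency (long-window
#' time-averaged) noise is invariant under it — so the single-time-point
#' readout is where the modulation is visible and where the Gaussian
#' analytic theory applies (see the methods vignette).
#'
#' @param f_list noise scale factors (must include 1, the baseline)
#' @param policy_offsets named numeric vector of threshold offsets in
#'   baseline-SD units
#' @param mode statistic used for `mu`, `sigma` and the rates:
#'   `"single_timepoint"` (default) or `"time_average"`
#' @inheritParams threshold_sweep
#' @param config infection configuration (default MOI = 1, V = 1)
#' @return a `sweep_result`; `$table` has one row per (f, policy)
#' @export
noise_sweep <- function(f_list = c(0.5, 1, 2, 4),
                        policy_offsets = c(low = -1, mean = 0, high = 1),
                        n = 2000, seed = 1L, params = default_parameters(),
                        config = cell_config(moi = 1, volume = 1),
                        horizon = 60, window = c(0, 60),
                        mode = c("single_timepoint", "time_average")) {
  mode <- match.arg(mode)
  if (!any(f_list == 1)) stop("f_list must include the baseline f = 1")
  conds <- lapply(f_list, function(f)
    list(config = config, params = apply_noise_scaling(params, f)))
  names(conds) <- paste0("f", f_list)
  conds <- .normalise_conditions(conds, params)
  ens <- .condition_ensembles(conds, n, horizon, window, seed)
  pick <- function(e) if (mode == "single_timepoint") e$endpoint else e$stat
  base <- pick(ens[[which(f_list == 1)]])
  base_mu <- mean(base); base_sd <- stats::sd(base)
  rows <- list()
  for (i in seq_along(f_list)) {
    x <- pick(ens[[i]])
    for (pol in names(policy_offsets)) {
      K <- max(0, base_mu + policy_offsets[[pol]] * base_sd)
      tab <- threshold_rates(ens[[i]], K, mode = mode)
      rows[[length(rows) + 1L]] <- cbind(
        f = f_list[i], policy = pol, tab,
        mu = mean(x), sigma = stats::sd(x))
    }
  }
  .sweep_result(do.call(rbind, rows), ens,
                list(baseline_mean = base_mu, baseline_sd = base_sd))
}

#' Global parameter sensitivity of the MOI dependence
#'
#' Draws `n_sets` perturbed parameter sets (log-uniform within
#' `factor_bound`), and for each set: runs a calibration ensemble pooled over
#' the MOI=1,V=1 and MOI=2,V=2 conditions, fixes the per-set threshold at the
#' pooled mean plus `K_offset_sd` pooled SDs, then estimates both lysogeny
#' rates with `n_sims` fresh runs per condition.
#'
#' @param n_sets number of perturbed parameter sets
#' @param factor_bound fold bound of the perturbation (2 or 10)
#' @param n_sims simulations per condition per set
#' @param n_calibration calibration runs per condition per set
#' @param K_offset_sd threshold offset above the per-set pooled mean, in
#'   pooled-SD units
#' @inheritParams threshold_sweep
#' @return a `sweep_result`; `$table` has one row per set: `set`, `factor`,
#'   `K`, `rate_M1V1`, `rate_M2V2` and the binomial SEs
#' @export
sensitivity_scan <- function(n_sets = 200, factor_bound = 2, n_sims = 500,
                             n_calibration = 100, K_offset_sd = 1,
                             seed = 1L, params = default_parameters(),
                             horizon = 60, window = c(0, 60)) {
  set_seeds <- seed_stream(seed, n_sets, stream = 101)
  cfg1 <- cell_config(moi = 1, volume = 1)
  cfg2 <- cell_config(moi = 2, volume = 2)
  rows <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    ps <- if (factor_bound == 1) params else
      perturb_parameters(params, factor_bound, set_seeds[s])
    nw1 <- build_network(ps, cfg1)
    nw2 <- build_network(ps, cfg2)
    cal1 <- run_decision_ensemble(nw1, cfg1, ps, n = n_calibration,
                                  horizon = horizon,
                                  seed = seed_stream(set_seeds[s], 1, 1)[1],
                                  window = window)
    cal2 <- run_decision_ensemble(nw2, cfg2, ps, n = n_calibration,
                                  horizon = horizon,
                                  seed = seed_stream(set_seeds[s], 1, 2)[1],
                                  window = window)
    pooled_stats <- c(cal1$stat, cal2$stat)
    K <- max(0, mean(pooled_stats) + K_offset_sd * stats::sd(pooled_stats))
    e1 <- run_decision_ensemble(nw1, cfg1, ps, n = n_sims, horizon = horizon,
                                seed = seed_stream(set_seeds[s], 1, 3)[1],
                                window = window)
    e2 <- run_decision_ensemble(nw2, cfg2, ps, n = n_sims, horizon = horizon,
                                seed = seed_stream(set_seeds[s], 1, 4)[1],
                                window = window)
    r1 <- threshold_rates(e1, K)
    r2 <- threshold_rates(e2, K)
    rows[[s]] <- data.frame(set = s, factor = factor_bound, K = K,
                            rate_M1V1 = r1$rate, se_M1V1 = r1$se,
                            rate_M2V2 = r2$rate, se_M2V2 = r2$se)
  }
  .sweep_result(do.call(rbind, rows))
}

#' Threshold sweep under model variants
#'
#' Re-runs the threshold sweep with the given [variant_flags()] applied to
#' both standard conditions and reports the shift in the window-averaged
#' mean [CII] relative to the unmodified model.
#'
#' @param flags a [variant_flags()] object
#' @inheritParams threshold_sweep
#' @return a `sweep_result` with the variant sweep table; `$baseline` holds
#'   the matched baseline sweep and `$mean_shift` the per-condition change in
#'   mean statistic (variant minus baseline)
#' @export
variant_comparison <- function(flags, K_grid = NULL, n = 2000, seed = 1L,
                               params = default_parameters(), horizon = 60,
                               window = c(0, 60)) {
  if (!inherits(flags, "variant_flags")) stop("`flags` must be variant_flags")
  base <- threshold_sweep(.default_conditions(), K_grid = K_grid, n = n,
                          seed = seed, params = params, horizon = horizon,
                          window = window)
  if (is.null(K_grid))
    K_grid <- base$pooled_mean + seq(-2.5, 2.5, by = 0.25) * base$pooled_sd
  var <- threshold_sweep(.default_conditions(variants = flags),
                         K_grid = K_grid, n = n, seed = seed + 1L,
                         params = params, horizon = horizon, window = window)
  shift <- vapply(names(var$ensembles), function(lab)
    mean(var$ensembles[[lab]]$stat) - mean(base$ensembles[[lab]]$stat),
    numeric(1))
  .sweep_result(var$table, var$ensembles,
                list(baseline = base, mean_shift = shift,
                     pooled_mean = var$pooled_mean,
                     pooled_sd = var$pooled_sd))
}

.growth_for_mode <- function(mode, g, ...) {
  switch(mode,
    none = NULL,
    dilution_only = growth_model(rate = g, dilution = TRUE,
                                 volume_growth = TRUE, tx_coupling = FALSE, ...),
    dilution_plus_tx = growth_model(rate = g, dilution = TRUE,
                                    volume_growth = TRUE, tx_coupling = TRUE, ...),
    stop("unknown growth mode: ", mode)
  )
}

#' Effect of cell growth on the lysogeny rate
#'
#' Compares a non-growing cell against growing cells under two couplings:
#' `dilution_only` (first-order dilution of free species plus exponential
#' volume growth) and `dilution_plus_tx` (additionally scaling transcription
#' with growth rate; see [growth_model()]). Thresholds default to offsets
#' from the non-growing condition's statistic in its SD units, shared across
#' all modes so rates are comparable.
#'
#' @param modes subset of `c("none", "dilution_only", "dilution_plus_tx")`
#' @param growth_rates elongation rates to simulate, per min
#' @param K_grid absolute thresholds; `NULL` for the non-growing-anchored
#'   default (mean + (-1, 0, 1) SD)
#' @param config infection configuration (default MOI = 1, V = 1)
#' @inheritParams threshold_sweep
#' @return a `sweep_result`; `$table` has one row per (mode, g, K)
#' @export
growth_experiment <- function(modes = c("none", "dilution_only",
                                        "dilution_plus_tx"),
                              growth_rates = c(log(2) / 90, log(2) / 30),
                              K_grid = NULL, n = 2000, seed = 1L,
                              params = default_parameters(),
                              config = cell_config(moi = 1, volume = 1),
                              horizon = 60, window = c(0, 60)) {
  conds <- list()
  for (mode in modes) {
    gs <- if (mode == "none") 0 else growth_rates
    for (g in gs) {
      cfg <- cell_config(moi = config$moi, volume = config$volume,
                         infection_offsets = config$infection_offsets,
                         growth = .growth_for_mode(mode, g),
                         variants = config$variants)
      conds[[sprintf("%s_g%.5f", mode, g)]] <-
        list(config = cfg, mode = mode, g = g)
    }
  }
  ens <- vector("list", length(conds))
  names(ens) <- names(conds)
  for (i in seq_along(conds)) {
    cfg <- conds[[i]]$config
    nw <- build_network(params, cfg)
    ens[[i]] <- run_decision_ensemble(nw, cfg, params, n = n,
                                      horizon = horizon,
                                      seed = seed_stream(seed, 1, i)[1],
                                      window = window)
  }
  anchor_idx <- if ("none" %in% modes) which(startsWith(names(ens), "none"))[1] else 1L
  mu0 <- mean(ens[[anchor_idx]]$stat)
  sd0 <- stats::sd(ens[[anchor_idx]]$stat)
  if (is.null(K_grid)) K_grid <- pmax(0, mu0 + c(-1, 0, 1) * sd0)
  rows <- list()
  for (i in seq_along(conds)) {
    tab <- threshold_rates(ens[[i]], K_grid)
    rows[[i]] <- cbind(mode = conds[[i]]$mode, g = conds[[i]]$g, tab,
                       mu = mean(ens[[i]]$stat),
                       sigma = stats::sd(ens[[i]]$stat))
  }
  .sweep_result(do.call(rbind, rows), ens,
                list(anchor_mean = mu0, anchor_sd = sd0))
}

#' Lysogeny rate across growth media
#'
#' Varies the elongation rate (emulating different growth media) at fixed
#' cell size, for MOI = 1 and MOI = 2 in the same volume (so MOI = 2 has
#' twice the viral concentration), under dilution plus transcription
#' coupling. The threshold is fixed across the whole sweep at
#' `K_offset_sd` SDs above the mean statistic of the reference condition
#' (MOI = 1 at the median growth rate).
#'
#' @param g_grid elongation rates, per min
#' @param moi_list MOIs simulated at the shared `volume`
#' @param volume fixed cell volume
#' @param K_offset_sd threshold offset in reference-SD units
#' @inheritParams threshold_sweep
#' @return a `sweep_result`; `$table` has one row per (moi, g)
#' @export
media_sweep <- function(g_grid = log(2) / c(90, 60, 45, 30),
                        moi_list = c(1, 2), volume = 1, K_offset_sd = 1,
                        n = 2000, seed = 1L, params = default_parameters(),
                        horizon = 60, window = c(0, 60)) {
  g_grid <- sort(g_grid)
  ens <- list()
  for (m in moi_list) for (g in g_grid) {
    cfg <- cell_config(moi = m, volume = volume,
                       growth = .growth_for_mode("dilution_plus_tx", g))
    lab <- sprintf("MOI%d_g%.5f", m, g)
    nw <- build_network(params, cfg)
    ens[[lab]] <- run_decision_ensemble(
      nw, cfg, params, n = n, horizon = horizon,
      seed = seed_stream(seed, 1, length(ens) + 1L)[1], window = window)
  }
  ref_g <- g_grid[ceiling(length(g_grid) / 2)]
  ref <- ens[[sprintf("MOI%d_g%.5f", min(moi_list), ref_g)]]
  K <- max(0, mean(ref$stat) + K_offset_sd * stats::sd(ref$stat))
  rows <- list()
  for (m in moi_list) for (g in g_grid) {
    e <- ens[[sprintf("MOI%d_g%.5f", m, g)]]
    tab <- threshold_rates(e, K)
    rows[[length(rows) + 1L]] <- cbind(moi = m, g = g, tab,
                                       mu = mean(e$stat),
                                       sigma = stats::sd(e$stat))
  }
  .sweep_result(do.call(rbind, rows), ens, list(K = K, ref_g = ref_g))
}

#' Effect of asynchronous infection at MOI = 2
#'
#' Compares synchronous double infection with configurations where the second
#' phage arrives `tau` minutes later. Reports the mean statistic and the
#' lysogeny rate at a high threshold anchored on the synchronous condition.
#'
#' @param tau_list second-phage delays, min (0 = synchronous)
#' @param volume cell volume (default 2, the standard MOI = 2 comparison)
#' @param K_offset_sd threshold offset above the synchronous mean, in
#'   synchronous-SD units
#' @inheritParams threshold_sweep
#' @return a `sweep_result`; `$table` has one row per tau
#' @export
infection_offset_experiment <- function(tau_list = c(0, 5, 10, 30),
                                        volume = 2, K_offset_sd = 1,
                                        n = 2000, seed = 1L,
                                        params = default_parameters(),
                                        horizon = 60, window = c(0, 60)) {
  ens <- list()
  for (i in seq_along(tau_list)) {
    tau <- tau_list[i]
    cfg <- cell_config(moi = 2, volume = volume,
                       infection_offsets = c(0, tau))
    nw <- build_network(params, cfg)
    ens[[paste0("tau", tau)]] <- run_decision_ensemble(
      nw, cfg, params, n = n, horizon = horizon,
      seed = seed_stream(seed, 1, i)[1], window = window)
  }
  sync_label <- "tau0"
  if (!sync_label %in% names(ens)) sync_label <- names(ens)[1]
  sync <- ens[[sync_label]]
  K <- max(0, mean(sync$stat) + K_offset_sd * stats::sd(sync$stat))
  rows <- lapply(seq_along(tau_list), function(i) {
    e <- ens[[i]]
    tab <- threshold_rates(e, K)
    cbind(tau = tau_list[i], tab, mu = mean(e$stat),
          sigma = stats::sd(e$stat))
  })
  .sweep_result(do.call(rbind, rows), ens, list(K = K))
}
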