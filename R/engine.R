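#' Cell growth model
#'
#' Couples the circuit to cell physiology. A growing cell elongates
#' exponentially at rate `g` (per min). Its consequences for the circuit are
#' switchable: `dilution` adds a first-order removal channel at rate `g` for
#' every free cytoplasmic species (promoter states, i.e. genomes, are not
#' diluted within a cell cycle); `volume_growth` makes bimolecular
#' propensities use `V(t) = V0 exp(g t)`; `tx_coupling` multiplies all
#' transcription rates by a growth-dependent factor interpolated linearly
#' between `(g_slow, tx_scale_slow)` and `(g_fast, tx_scale_fast)` and
#' clamped outside that range.
#'
#' The default orientation, `tx_scale_slow = 2, tx_scale_fast = 1`, gives a
#' two-fold transcription enhancement at the slow-growth end; see the methods
#' vignette for why this orientation was adopted.
#'
#' @param rate elongation rate `g`, per min
#' @param dilution logical, dilute free species at rate `g`
#' @param tx_coupling logical, scale transcription with growth rate
#' @param volume_growth logical, grow the compartment volume as `V0 exp(g t)`
#' @param tx_scale_slow,tx_scale_fast transcription multipliers at the
#'   reference slow/fast growth rates
#' @param g_slow,g_fast reference growth rates (defaults: 90- and 30-minute
#'   doubling times)
#' @return an object of class `growth_model`
#' @export
growth_model <- function(rate = log(2) / 60, dilution = TRUE,
                         tx_coupling = FALSE, volume_growth = TRUE,
                         tx_scale_slow = 2, tx_scale_fast = 1,
                         g_slow = log(2) / 90, g_fast = log(2) / 30) {
  .stopifnot_scalar_number(rate, "rate")
  if (rate < 0) stop("growth rate must be >= 0")
  .stopifnot_scalar_number(tx_scale_slow, "tx_scale_slow", positive = TRUE)
  .stopifnot_scalar_number(tx_scale_fast, "tx_scale_fast", positive = TRUE)
  if (g_fast <= g_slow) stop("g_fast must exceed g_slow")
  structure(list(rate = rate, dilution = isTRUE(dilution),
                 tx_coupling = isTRUE(tx_coupling),
                 volume_growth = isTRUE(volume_growth),
                 tx_scale_slow = tx_scale_slow, tx_scale_fast = tx_scale_fast,
                 g_slow = g_slow, g_fast = g_fast),
            class = "growth_model")
}

# transcription multiplier at growth rate g (linear, clamped at the ends)
.tx_multiplier <- function(growth) {
  g <- min(max(growth$rate, growth$g_slow), growth$g_fast)
  w <- (g - growth$g_slow) / (growth$g_fast - growth$g_slow)
  (1 - w) * growth$tx_scale_slow + w * growth$tx_scale_fast
}

#' Phage genome copies under early replication
#'
#' Deterministic replication doubles the genome count every
#' `doubling_period` minutes for the first `duration` minutes, then stops:
#' `M0 * 2^min(floor(t / doubling_period), floor(duration / doubling_period))`.
#'
#' @param M0 initial genome count (>= 1)
#' @param t time since that genome's infection, min
#' @param doubling_period doubling period, min
#' @param duration length of the replication phase, min
#' @return integer genome count
#' @examples
#' phage_copies(1, 7)   # two doublings completed
#' phage_copies(1, 60)  # capped at 2^5 after 15 min
#' @export
phage_copies <- function(M0, t, doubling_period = 3, duration = 15) {
  if (any(M0 < 1) || any(M0 != round(M0))) stop("M0 must be a positive integer")
  if (doubling_period <= 0 || duration <= 0) stop("periods must be positive")
  if (any(t < 0)) stop("t must be >= 0")
  M0 * 2^pmin(floor(t / doubling_period), floor(duration / doubling_period))
}

# Build the event schedule (times + per-species state increments) implied by
# a cell_config: late-arriving phage (positive infection offsets) and the
# deterministic replication doublings of each phage lineage.
.event_schedule <- function(network, config, horizon) {
  times <- numeric(0)
  genomes <- numeric(0)
  late <- config$infection_offsets[config$infection_offsets > 0]
  if (length(late)) {
    tab <- table(late)
    times <- c(times, as.numeric(names(tab)))
    genomes <- c(genomes, as.numeric(tab))
  }
  if (config$variants$phage_replication) {
    for (tau in config$infection_offsets) {
      k <- seq_len(5)
      tt <- tau + 3 * k
      keep <- tt <= horizon
      times <- c(times, tt[keep])
      genomes <- c(genomes, (2^(k - 1))[keep])
    }
  }
  if (!length(times))
    return(list(times = numeric(0),
                changes = matrix(0L, length(network$species), 0)))
  ord <- order(times)
  times <- times[ord]
  genomes <- genomes[ord]
  changes <- matrix(0L, length(network$species), length(times),
                    dimnames = list(network$species, NULL))
  changes["PR", ] <- as.integer(genomes)
  changes["PRE", ] <- as.integer(genomes)
  list(times = times, changes = changes)
}

# Resolve growth/dilution/extrinsic-noise adjustments into a concrete
# (network, v0, g, volume_growth) bundle ready for the simulator core.
.resolve_run <- function(network, config, params, seed = NULL) {
  rates <- network$rates
  growth <- config$growth
  g <- if (is.null(growth)) 0 else growth$rate
  volume_growth <- !is.null(growth) && growth$volume_growth && g > 0

  if (!is.null(growth) && growth$tx_coupling) {
    is_tx <- startsWith(network$rate_symbols, "tx_")
    rates[is_tx] <- rates[is_tx] * .tx_multiplier(growth)
  }
  cv <- config$variants$extrinsic_noise_cv
  if (cv > 0) {
    if (is.null(seed)) stop("extrinsic noise requires a run seed")
    sdlog <- sqrt(log(1 + cv^2))
    is_expr <- network$rate_symbols %in%
      c("tx_Cro", "tx_CII", "tx_CI_p1", "tx_CI_p2", "translation")
    mult <- with_local_seed(seed + 7L,
      stats::rlnorm(sum(is_expr), meanlog = -sdlog^2 / 2, sdlog = sdlog))
    rates[is_expr] <- rates[is_expr] * mult
  }

  reactants <- network$reactants
  net_change <- network$net_change
  order <- network$order
  volexp <- network$volexp
  if (!is.null(growth) && growth$dilution && g > 0) {
    promoters <- unlist(network$promoter_species, use.names = FALSE)
    dilute <- setdiff(network$species, promoters)
    S <- length(network$species)
    extraR <- length(dilute)
    re <- matrix(0L, S, extraR, dimnames = list(network$species, NULL))
    for (j in seq_along(dilute)) re[dilute[j], j] <- 1L
    reactants <- cbind(reactants, re)
    net_change <- cbind(net_change, -re)
    rates <- c(rates, rep(g, extraR))
    order <- c(order, rep(1L, extraR))
    volexp <- c(volexp, rep(0L, extraR))
  }

  list(reactants = reactants, net_change = net_change, rates = rates,
       order = as.integer(order), volexp = as.integer(volexp),
       g = g, volume_growth = volume_growth)
}

#' Stochastic simulation of one infected cell
#'
#' Generates one statistically exact sample path of the jump process defined
#' by the network's mass-action propensities, sampled on the regular output
#' grid `0, dt, 2 dt, ..., horizon` with `dt = params$output_interval`.
#' Scheduled events (late infections, replication doublings) add naked
#' free-promoter copies at their exact times. Growth effects follow the
#' `cell_config`'s [growth_model()].
#'
#' @param network a `reaction_network` from [build_network()] (or
#'   [discretise()])
#' @param config the matching [cell_config()]
#' @param params the `lambda_params` used to build the network
#' @param horizon simulated time, min
#' @param seed integer seed; identical arguments give bit-identical output
#' @param x0 optional initial state override (named integer vector)
#' @param max_steps hard cap on the number of reaction events
#' @return an object of class `trajectory` with fields `times`, `counts`
#'   (samples x species matrix), `volumes`, `cii_weight`
#' @export
simulate_ssa <- function(network, config, params, horizon = 60, seed = 1L,
                         x0 = NULL, max_steps = 5e7) {
  if (!inherits(network, "reaction_network")) stop("`network` must be a reaction_network")
  .stopifnot_scalar_number(horizon, "horizon", positive = TRUE)
  if (is.null(x0)) x0 <- initial_state(network, config)
  x0 <- x0[network$species]
  ev <- .event_schedule(network, config, horizon)
  run <- .resolve_run(network, config, params, seed = seed)
  res <- .ssa_core(run$reactants, run$net_change, run$rates, run$order,
                   run$volexp, as.integer(x0), config$volume, run$g,
                   run$volume_growth, horizon, params$output_interval,
                   0.1, ev$times, ev$changes, as.integer(seed), max_steps)
  counts <- res$counts
  colnames(counts) <- network$species
  structure(list(times = res$times, counts = counts, volumes = res$volumes,
                 cii_weight = network$cii_weight, steps = res$steps),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d samples over [0, %g] min, %d species\n",
              length(x$times), max(x$times), ncol(x$counts)))
  invisible(x)
}

#' Genome copy number along a trajectory
#'
#' Total phage genome copies at each sample, computed as the sum of the PR
#' promoter states (conserved per genome by every reaction).
#'
#' @param traj a `trajectory`
#' @param network the `reaction_network` it was simulated from
#' @return numeric vector, one value per sample
#' @export
genome_copies <- function(traj, network) {
  pr <- network$promoter_species$PR
  rowSums(traj$counts[, pr, drop = FALSE])
}

#' Ensemble of stochastic runs with per-time summaries
#'
#' Performs `n` independent seeded runs (seeds derived from `seed` via
#' [seed_stream()]) and accumulates the per-time mean and standard deviation
#' of every species. Trajectories themselves are returned only when
#' `keep_trajectories` is `TRUE` (the summaries do not require storing them).
#'
#' @inheritParams simulate_ssa
#' @param n number of runs
#' @param keep_trajectories logical
#' @return a list with `times`, `mean` and `sd` (samples x species matrices),
#'   `n`, and optionally `trajectories`
#' @export
run_ensemble <- function(network, config, params, horizon = 60, n = 100,
                         seed = 1L, keep_trajectories = (n <= 200)) {
  if (n < 1) stop("n must be >= 1")
  seeds <- seed_stream(seed, n)
  msum <- NULL; ssum <- NULL
  trajs <- if (keep_trajectories) vector("list", n) else NULL
  times <- NULL
  for (i in seq_len(n)) {
    tr <- simulate_ssa(network, config, params, horizon, seeds[i])
    if (is.null(msum)) {
      times <- tr$times
      msum <- matrix(0, nrow(tr$counts), ncol(tr$counts))
      ssum <- matrix(0, nrow(tr$counts), ncol(tr$counts))
    }
    msum <- msum + tr$counts
    ssum <- ssum + tr$counts^2
    if (keep_trajectories) trajs[[i]] <- tr
  }
  mean_mat <- msum / n
  var_mat <- pmax(ssum / n - mean_mat^2, 0) * if (n > 1) n / (n - 1) else 0
  sd_mat <- sqrt(var_mat)
  colnames(mean_mat) <- colnames(sd_mat) <- network$species
  out <- list(times = times, mean = mean_mat, sd = sd_mat, n = n)
  if (keep_trajectories) out$trajectories <- trajs
  out
}

#' Write / read a trajectory as TSV
#'
#' Plain-text exchange format: a header row, then one row per sample with
#' time, each species count, and the volume.
#'
#' @param traj a `trajectory`
#' @param path file path
#' @return [read_trajectory_tsv()] returns a `trajectory` (without readout
#'   weights, which belong to the network).
#' @export
write_trajectory_tsv <- function(traj, path) {
  df <- data.frame(time = traj$times, traj$counts, volume = traj$volumes,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ensemble per-time summaries as TSV
#'
#' One row per sample time with the mean and SD of every species
#' (`time`, `mean_<species>`, `sd_<species>`).
#'
#' @param ensemble result of [run_ensemble()]
#' @param path file path
#' @return the path, invisibly
#' @export
write_ensemble_tsv <- function(ensemble, path) {
  m <- ensemble$mean
  s <- ensemble$sd
  colnames(m) <- paste0("mean_", colnames(m))
  colnames(s) <- paste0("sd_", colnames(s))
  df <- data.frame(time = ensemble$times, m, s, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_tsv
#' @export
read_trajectory_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  species <- setdiff(names(df), c("time", "volume"))
  structure(list(times = df$time,
                 counts = as.matrix(df[, species, drop = FALSE]),
                 volumes = df$volume, cii_weight = NULL),
            class = "trajectory")
}
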