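#' Decision criterion for the lysis--lysogeny call
#'
#' A trajectory is classified by comparing a CII concentration statistic to a
#' threshold `K`: either the time average of [CII] over the window
#' `(t0, t1)` (the area under the curve divided by the window length) or the
#' value at the single time point `t1`.
#'
#' @param threshold threshold `K` in concentration units (>= 0)
#' @param window numeric length-2, window `(t0, t1)` in minutes, `t0 < t1`
#' @param mode `"time_average"` or `"single_timepoint"`
#' @return an object of class `decision_criterion`
#' @export
decision_criterion <- function(threshold, window = c(0, 60),
                               mode = c("time_average", "single_timepoint")) {
  mode <- match.arg(mode)
  .stopifnot_scalar_number(threshold, "threshold")
  if (threshold < 0) stop("threshold must be >= 0")
  if (length(window) != 2 || window[1] < 0 || window[1] >= window[2])
    stop("window must be (t0, t1) with 0 <= t0 < t1")
  structure(list(threshold = threshold, window = as.numeric(window),
                 mode = mode),
            class = "decision_criterion")
}

#' CII concentration readout of a trajectory
#'
#' Per-sample total CII protein equivalents divided by the per-sample volume.
#' With the default `"total"` accounting a free monomer counts 1, a free or
#' promoter-bound dimer counts 2, and a tetramer (tetramer variant) counts 4;
#' `"free_monomer"` and `"free_dimer"` restrict the sum to those species.
#'
#' @param traj a `trajectory` carrying readout weights (from [simulate_ssa()]
#'   or [integrate_deterministic()])
#' @param which readout accounting, one of `"total"`, `"free_monomer"`,
#'   `"free_dimer"`
#' @return numeric vector of concentrations, one per sample
#' @export
cii_readout <- function(traj, which = c("total", "free_monomer", "free_dimer")) {
  which <- match.arg(which)
  w <- traj$cii_weight
  if (is.null(w)) stop("trajectory carries no CII readout weights")
  if (which == "free_monomer") w <- w * (names(w) == "CII")
  if (which == "free_dimer") w <- w * (names(w) == "CII2")
  present <- intersect(names(w)[w != 0], colnames(traj$counts))
  as.numeric(traj$counts[, present, drop = FALSE] %*% w[present]) / traj$volumes
}

# statistic of a readout series under a criterion (shared by decide() and the
# ensemble drivers, which precompute readout series in bulk)
.readout_statistic <- function(times, readout, criterion) {
  if (criterion$mode == "single_timepoint") {
    i <- which.min(abs(times - criterion$window[2]))
    return(readout[i])
  }
  in_win <- times >= criterion$window[1] - 1e-9 &
    times <= criterion$window[2] + 1e-9
  if (!any(in_win)) stop("decision window contains no sample points")
  mean(readout[in_win])
}

#' Classify one trajectory as lysis or lysogeny
#'
#' Computes the criterion's CII statistic and labels the run `lysogeny` when
#' the statistic strictly exceeds the threshold (ties count as lysis).
#'
#' @param traj a `trajectory`
#' @param criterion a [decision_criterion()]
#' @param which readout accounting passed to [cii_readout()]
#' @return a list of class `decision_outcome` with `statistic` and `label`
#' @export
decide <- function(traj, criterion, which = "total") {
  if (!inherits(criterion, "decision_criterion"))
    stop("`criterion` must be a decision_criterion")
  if (criterion$window[2] > max(traj$times) + 1e-9)
    stop("decision window extends beyond the trajectory span")
  stat <- .readout_statistic(traj$times, cii_readout(traj, which), criterion)
  structure(list(statistic = stat,
                 label = if (stat > criterion$threshold) "lysogeny" else "lysis",
                 threshold = criterion$threshold),
            class = "decision_outcome")
}

#' Ensemble lysogeny rate with binomial uncertainty
#'
#' @param outcomes a list of `decision_outcome` objects, or a character/factor
#'   vector of labels
#' @return a list of class `lysogeny_estimate`: `n_runs`, `n_lysogeny`,
#'   `rate`, and the binomial (Wald) standard error
#'   `sqrt(rate (1 - rate) / n)`
#' @export
lysogeny_rate <- function(outcomes) {
  labels <- if (is.list(outcomes))
    vapply(outcomes, function(o) o$label, character(1)) else as.character(outcomes)
  n <- length(labels)
  if (n < 1) stop("no outcomes supplied")
  if (!all(labels %in% c("lysis", "lysogeny"))) stop("unknown outcome label")
  k <- sum(labels == "lysogeny")
  rate <- k / n
  structure(list(n_runs = n, n_lysogeny = k, rate = rate,
                 se = sqrt(rate * (1 - rate) / n)),
            class = "lysogeny_estimate")
}

#' @export
print.lysogeny_estimate <- function(x, ...) {
  cat(sprintf("Lysogeny rate: %.4f +/- %.4f (SE), %d / %d runs\n",
              x$rate, x$se, x$n_lysogeny, x$n_runs))
  invisible(x)
}

#' Wilson score interval for a lysogeny rate
#'
#' More reliable than the Wald interval when the rate is near 0 or 1.
#'
#' @param estimate a `lysogeny_estimate`
#' @param conf confidence level
#' @return numeric length-2 interval
#' @export
wilson_interval <- function(estimate, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  n <- estimate$n_runs
  p <- estimate$rate
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(max(0, centre - half), min(1, centre + half))
}

#' Gaussian (error-function) approximation to the lysogeny rate
#'
#' Assuming the CII statistic at decision time is Gaussian with mean `mu` and
#' standard deviation `sigma`, the probability of exceeding the threshold is
#' `P = (1 - erf((K - mu) / (sigma sqrt(2)))) / 2`. The sign of the error
#' function's argument flips with `K - mu`, so raising the noise `sigma`
#' raises the rate when `K > mu` and lowers it when `K < mu` — the mechanism
#' through which MOI acts at fixed viral concentration. At `sigma = 0` the
#' limit is the indicator of `mu > K`.
#'
#' @param mu mean of the CII statistic
#' @param sigma standard deviation (>= 0)
#' @param K decision threshold
#' @return probability of lysogeny
#' @export
analytic_rate <- function(mu, sigma, K) {
  if (any(sigma < 0)) stop("sigma must be >= 0")
  n <- max(length(mu), length(sigma), length(K))
  mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n)
  K <- rep_len(K, n)
  out <- numeric(n)
  pos <- sigma > 0
  out[pos] <- stats::pnorm((mu[pos] - K[pos]) / sigma[pos])
  out[!pos] <- as.numeric(mu[!pos] > K[!pos])
  out
}

#' Phenomenological lysogeny probability (unanimous-decision form)
#'
#' The empirical rate of lysogeny as a function of MOI and volume: each of
#' the `moi` phage "votes" for lysogeny with a Hill probability in the viral
#' concentration `c = moi / volume`, and lysogeny requires unanimity:
#' `[c^h / (c^h + K_half^h)]^moi`. Monotone increasing in `c` at fixed MOI.
#'
#' @param moi positive integer
#' @param volume positive cell volume
#' @param K_half half-saturation constant (concentration units)
#' @param h Hill exponent
#' @return probability of lysogeny
#' @export
pheno_rate <- function(moi, volume, K_half = 1, h = 2) {
  if (any(moi < 1) || any(moi != round(moi))) stop("moi must be a positive integer")
  if (any(volume <= 0) || any(K_half <= 0) || any(h <= 0))
    stop("volume, K_half and h must be positive")
  conc <- moi / volume
  (conc^h / (conc^h + K_half^h))^moi
}

#' Ensemble of runs reduced to decision statistics
#'
#' The workhorse behind the experiment drivers: runs `n` seeded simulations,
#' and for each run computes the CII readout series, the time-averaged
#' statistic over `window`, and the single-time-point value at the window
#' end. Also accumulates the per-time mean and SD of the readout. Ensembles
#' produced this way can be re-thresholded at any `K` without re-simulating.
#'
#' @inheritParams simulate_ssa
#' @param n number of runs
#' @param window decision window `(t0, t1)`, min
#' @param which readout accounting (see [cii_readout()])
#' @return a list of class `decision_ensemble`: `stat` (time-average
#'   statistic per run), `endpoint` (single-time-point value per run),
#'   `readout_mean`, `readout_sd`, `times`, `n`
#' @export
run_decision_ensemble <- function(network, config, params, n = 1000,
                                  horizon = 60, seed = 1L, window = c(0, 60),
                                  which = "total") {
  seeds <- seed_stream(seed, n)
  stat <- numeric(n)
  endpoint <- numeric(n)
  msum <- NULL; ssum <- NULL; times <- NULL
  crit <- decision_criterion(0, window = window, mode = "time_average")
  for (i in seq_len(n)) {
    tr <- simulate_ssa(network, config, params, horizon, seeds[i])
    ro <- cii_readout(tr, which)
    if (is.null(msum)) {
      times <- tr$times
      msum <- numeric(length(ro)); ssum <- numeric(length(ro))
    }
    msum <- msum + ro
    ssum <- ssum + ro^2
    stat[i] <- .readout_statistic(tr$times, ro, crit)
    endpoint[i] <- ro[which.min(abs(tr$times - window[2]))]
  }
  m <- msum / n
  v <- pmax(ssum / n - m^2, 0) * if (n > 1) n / (n - 1) else 0
  structure(list(stat = stat, endpoint = endpoint, readout_mean = m,
                 readout_sd = sqrt(v), times = times, n = n),
            class = "decision_ensemble")
}

#' Write per-run decision calls as TSV
#'
#' One row per run: run id, the decision statistic, the threshold, and the
#' lysis/lysogeny label (ties count as lysis).
#'
#' @param ensemble a `decision_ensemble`
#' @param K threshold
#' @param path file path
#' @param mode statistic to threshold
#' @return the path, invisibly
#' @export
write_decision_tsv <- function(ensemble, K, path,
                               mode = c("time_average", "single_timepoint")) {
  mode <- match.arg(mode)
  x <- if (mode == "time_average") ensemble$stat else ensemble$endpoint
  df <- data.frame(run = seq_along(x), statistic = x, K = K,
                   label = ifelse(x > K, "lysogeny", "lysis"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Threshold an existing decision ensemble
#'
#' @param ensemble a `decision_ensemble`
#' @param K threshold (scalar or vector)
#' @param mode statistic to threshold, `"time_average"` or
#'   `"single_timepoint"`
#' @return a data.frame with one row per `K`: `K`, `n`, `n_lysogeny`, `rate`,
#'   `se`
#' @export
threshold_rates <- function(ensemble, K,
                            mode = c("time_average", "single_timepoint")) {
  mode <- match.arg(mode)
  x <- if (mode == "time_average") ensemble$stat else ensemble$endpoint
  n <- length(x)
  rows <- lapply(K, function(k) {
    nk <- sum(x > k)
    r <- nk / n
    data.frame(K = k, n = n, n_lysogeny = nk, rate = r,
               se = sqrt(r * (1 - r) / n))
  })
  do.call(rbind, rows)
}
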