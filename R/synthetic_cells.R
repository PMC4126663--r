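#' Configuration for a synthetic time-lapse cohort
#'
#' Describes the generative model for a cohort of single-cell records
#' emulating two-frame time-lapse measurements of infected bacteria: per
#' cell, an MOI draw, an exponential elongation rate that decreases with MOI,
#' a per-MOI probability of not growing at all, multiplicative length
#' measurement noise, and a fate drawn from the phenomenological lysogeny
#' model. Lysogens can carry a configurable decision-time delay relative to
#' the division time of uninfected cells.
#'
#' @param n_cells number of cells
#' @param moi_mean Poisson mean of the MOI distribution (truncated at
#'   `moi_max`), used when `moi_weights` is `NULL`
#' @param moi_weights optional explicit weights for MOI `0..moi_max`
#' @param moi_max largest MOI generated
#' @param g0 baseline elongation rate of an uninfected cell, per min
#' @param delta_g per-phage elongation-rate decrement, per min (>= 0)
#' @param noise_cv coefficient of variation of the multiplicative final-length
#'   measurement noise
#' @param nongrower_frac probability that a cell is a non-grower, per unit of
#'   MOI (probability `min(1, moi * nongrower_frac)`)
#' @param frame_interval nominal time between first and final frame for
#'   dividing/lysing cells, min
#' @param time_jitter_sd SD of the Gaussian cell-to-cell variation in the
#'   final-frame time, min
#' @param lysogeny_delay extra decision time for cells that choose lysogeny,
#'   min
#' @param K_half,h constants of the phenomenological fate model
#'   (see [pheno_rate()])
#' @param volume cell volume used in the fate model, a.u.
#' @param elongation `"exponential"` (default) or `"linear"` length growth
#' @return an object of class `cohort_config`
#' @export
cohort_config <- function(n_cells = 500, moi_mean = 1, moi_weights = NULL,
                          moi_max = 5L, g0 = log(2) / 60, delta_g = 0.0015,
                          noise_cv = 0.05, nongrower_frac = 0.05,
                          frame_interval = 60, time_jitter_sd = 5,
                          lysogeny_delay = 20,
                          K_half = 1, h = 2, volume = 1,
                          elongation = c("exponential", "linear")) {
  elongation <- match.arg(elongation)
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (g0 < 0 || delta_g < 0) stop("g0 and delta_g must be >= 0")
  if (g0 - moi_max * delta_g < 0)
    stop("g0 - moi_max * delta_g must be >= 0 over the supported MOI range")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (time_jitter_sd < 0) stop("time_jitter_sd must be >= 0")
  if (!is.null(moi_weights) && length(moi_weights) != moi_max + 1)
    stop("moi_weights must have length moi_max + 1 (MOI 0..moi_max)")
  structure(list(n_cells = as.integer(n_cells), moi_mean = moi_mean,
                 moi_weights = moi_weights, moi_max = as.integer(moi_max),
                 g0 = g0, delta_g = delta_g, noise_cv = noise_cv,
                 nongrower_frac = nongrower_frac,
                 frame_interval = frame_interval,
                 time_jitter_sd = time_jitter_sd,
                 lysogeny_delay = lysogeny_delay, K_half = K_half, h = h,
                 volume = volume, elongation = elongation),
            class = "cohort_config")
}

#' Generate a synthetic single-cell cohort
#'
#' Draws one record per cell: MOI from the (truncated Poisson or explicit)
#' MOI distribution; true elongation rate `g = max(0, g0 - moi * delta_g)`,
#' set to zero for non-growers; a final-frame time jittered around the
#' nominal interval; final length `Lf = L0 exp(g (tf - t0)) * eps` with
#' multiplicative lognormal measurement noise of the configured CV
#' (median-unbiased, so the log-ratio growth estimator is unbiased; a linear
#' elongation option exists); and a fate — `division` for uninfected cells,
#' otherwise `lysogeny` with probability [pheno_rate()] and `lysis`
#' otherwise. Lysogens get `tf` inflated by the configured decision delay.
#' Fully determined by `(config, seed)`.
#'
#' @param config a [cohort_config()]
#' @param seed integer seed
#' @return a data.frame with one row per cell: `moi`, `L0`, `Lf`, `t0`, `tf`,
#'   `true_g`, `nongrower`, `fate`
#' @export
generate_cohort <- function(config, seed = 1L) {
  if (!inherits(config, "cohort_config")) stop("`config` must be a cohort_config")
  with_local_seed(seed, {
    n <- config$n_cells
    mois <- 0:config$moi_max
    w <- config$moi_weights
    if (is.null(w)) w <- stats::dpois(mois, config$moi_mean)
    moi <- sample(mois, n, replace = TRUE, prob = w / sum(w))

    nongrow <- stats::runif(n) < pmin(1, moi * config$nongrower_frac)
    g <- pmax(0, config$g0 - moi * config$delta_g)
    g[nongrow] <- 0

    fate <- rep("division", n)
    infected <- moi > 0
    if (any(infected)) {
      p_lys <- pheno_rate(pmax(moi[infected], 1L), config$volume,
                          config$K_half, config$h)
      lys <- stats::runif(sum(infected)) < p_lys
      fate[infected] <- ifelse(lys, "lysogeny", "lysis")
    }

    t0 <- rep(0, n)
    jitter <- if (config$time_jitter_sd > 0)
      stats::rnorm(n, 0, config$time_jitter_sd) else rep(0, n)
    tf <- pmax(config$frame_interval + jitter, 1) +
      ifelse(fate == "lysogeny", config$lysogeny_delay, 0)

    L0 <- stats::runif(n, 0.8, 1.2)
    growth_factor <- if (config$elongation == "exponential")
      exp(g * (tf - t0)) else 1 + g * (tf - t0)
    eps <- if (config$noise_cv > 0)
      stats::rlnorm(n, meanlog = 0, sdlog = sqrt(log(1 + config$noise_cv^2)))
    else rep(1, n)
    Lf <- L0 * growth_factor * eps

    data.frame(moi = as.integer(moi), L0 = L0, Lf = Lf, t0 = t0, tf = tf,
               true_g = g, nongrower = nongrow, fate = fate,
               stringsAsFactors = FALSE)
  })
}

#' Elongation rate from a two-frame measurement
#'
#' The exponential-elongation estimator `ln(Lf / L0) / delta_t`. A linear
#' variant `(Lf - L0) / (L0 delta_t)` is available for robustness checks.
#'
#' @param L0,Lf cell length at the first and final frame
#' @param delta_t time between the frames, min
#' @param method `"exponential"` (default) or `"linear"`
#' @return elongation rate, per min
#' @examples
#' estimate_growth_rate(2, 4, 60) # ln(2)/60
#' @export
estimate_growth_rate <- function(L0, Lf, delta_t,
                                 method = c("exponential", "linear")) {
  method <- match.arg(method)
  if (any(L0 <= 0) || any(Lf <= 0)) stop("lengths must be positive")
  if (any(delta_t <= 0)) stop("delta_t must be positive")
  if (method == "exponential") log(Lf / L0) / delta_t
  else (Lf - L0) / (L0 * delta_t)
}

#' Mean elongation rate by MOI
#'
#' Applies [estimate_growth_rate()] to every record, excludes non-growing
#' cells (flagged as such, or with estimated rate <= 0), and summarises the
#' growing cells per MOI.
#'
#' @param records a cohort data.frame from [generate_cohort()]
#' @param method estimator variant (see [estimate_growth_rate()])
#' @return a data.frame: `moi`, `n`, `mean_g`, `se`
#' @export
growth_by_moi <- function(records, method = "exponential") {
  g_hat <- estimate_growth_rate(records$L0, records$Lf,
                                records$tf - records$t0, method)
  flagged <- if ("nongrower" %in% names(records)) records$nongrower else FALSE
  keep <- !flagged & g_hat > 0
  if (!any(keep))
    return(data.frame(moi = integer(0), n = integer(0), mean_g = numeric(0),
                      se = numeric(0)))
  moi <- records$moi[keep]
  g_hat <- g_hat[keep]
  out <- lapply(sort(unique(moi)), function(m) {
    gi <- g_hat[moi == m]
    data.frame(moi = m, n = length(gi), mean_g = mean(gi),
               se = stats::sd(gi) / sqrt(length(gi)))
  })
  do.call(rbind, out)
}

#' Decision/division time summary by group
#'
#' Compares the observation span `tf - t0` of uninfected dividing cells with
#' that of infected cells that chose lysogeny (whose final frame is the
#' lysogeny decision).
#'
#' @param records a cohort data.frame from [generate_cohort()]
#' @return a data.frame: `group`, `n`, `mean_time`, `se`
#' @export
division_time_summary <- function(records) {
  groups <- list(uninfected = records$fate == "division" & records$moi == 0,
                 lysogenic = records$fate == "lysogeny")
  rows <- lapply(names(groups), function(gname) {
    sel <- groups[[gname]]
    if (!any(sel)) return(NULL)
    dt <- records$tf[sel] - records$t0[sel]
    data.frame(group = gname, n = sum(sel), mean_time = mean(dt),
               se = if (sum(sel) > 1) stats::sd(dt) / sqrt(sum(sel)) else 0)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Write a cohort as TSV
#' @param records cohort data.frame
#' @param path file path
#' @export
write_cohort_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
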