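#' Deterministic (mean-field) limit of the circuit
#'
#' Integrates the mass-action ODEs matching the stochastic network: an
#' order-2 reaction between distinct species contributes `(k/V) x y`, a
#' homodimerisation contributes `(k/V) x^2 / 2`, and promoter-state
#' occupancies are treated as continuous fractions. Events from the infection
#' and replication schedule are applied at their exact times, and growth
#' (dilution, volume growth, transcription coupling) follows the
#' `cell_config`'s [growth_model()]. The solution is reported on the same
#' output grid as [simulate_ssa()].
#'
#' In this mean-field limit the equations depend on MOI and volume only
#' through their ratio, so scaling `(MOI, V) -> (2 MOI, 2 V)` leaves all
#' concentration trajectories unchanged.
#'
#' @inheritParams simulate_ssa
#' @param rtol,atol integration tolerances passed to [deSolve::lsoda()]
#' @return a `trajectory` (continuous-valued counts)
#' @export
integrate_deterministic <- function(network, config, params, horizon = 60,
                                    x0 = NULL, rtol = 1e-8, atol = 1e-8) {
  if (!inherits(network, "reaction_network")) stop("`network` must be a reaction_network")
  if (is.null(x0)) x0 <- initial_state(network, config)
  x0 <- as.numeric(x0[network$species])
  run <- .resolve_run(network, config, params, seed = NULL)
  ev <- .event_schedule(network, config, horizon)

  S <- length(network$species)
  R <- length(run$rates)
  re <- run$reactants
  nc <- run$net_change
  ord <- run$order
  homo <- logical(R)
  s1 <- integer(R); s2 <- integer(R)
  for (j in seq_len(R)) {
    idx <- which(re[, j] > 0)
    if (ord[j] >= 1L) s1[j] <- idx[1]
    if (ord[j] == 2L) {
      if (length(idx) == 1L) homo[j] <- TRUE else s2[j] <- idx[2]
    }
  }
  v0 <- config$volume
  g <- run$g
  vgrow <- run$volume_growth

  deriv <- function(t, y, parms) {
    y <- pmax(y, 0)
    vol <- if (vgrow) v0 * exp(g * t) else v0
    a <- run$rates
    for (j in seq_len(R)) {
      if (ord[j] == 1L) a[j] <- a[j] * y[s1[j]]
      else if (ord[j] == 2L) {
        a[j] <- if (homo[j]) a[j] / vol * y[s1[j]]^2 / 2
                else a[j] / vol * y[s1[j]] * y[s2[j]]
      }
    }
    list(as.numeric(nc %*% a))
  }

  times <- seq(0, horizon, by = params$output_interval)
  events <- NULL
  if (length(ev$times)) {
    nz <- which(ev$changes != 0, arr.ind = TRUE)
    events <- list(data = data.frame(
      var = network$species[nz[, 1]],
      time = ev$times[nz[, 2]],
      value = as.numeric(ev$changes[nz]),
      method = "add"))
  }
  names(x0) <- network$species
  sol <- deSolve::lsoda(x0, times, deriv, parms = NULL, rtol = rtol,
                        atol = atol, events = events)
  if (attr(sol, "istate")[1] < 0)
    stop("stiff integration failure in deterministic limit (istate < 0)")
  counts <- unname(sol[, -1, drop = FALSE])
  colnames(counts) <- network$species
  vols <- if (vgrow) v0 * exp(g * times) else rep(v0, length(times))
  structure(list(times = times, counts = counts, volumes = vols,
                 cii_weight = network$cii_weight),
            class = "trajectory")
}
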