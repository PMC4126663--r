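#' Kinetic parameters of the lambda lysis--lysogeny circuit
#'
#' A `lambda_params` object collects every rate constant of the CI/Cro/CII
#' promoter-binding circuit together with the two simulation controls
#' (trajectory output interval and the cell width used by the spherocylinder
#' geometry correction). All rates are per minute; bimolecular rates
#' (dimerisation, dimer--promoter binding) are expressed at unit cell volume
#' and are divided by the current volume inside the simulator.
#'
#' @details
#' The nominal values returned by [default_parameters()] are the package's
#' documented reference set for the three-gene circuit (constitutive PR
#' transcription of cro and cII, CII-activated PRE transcription of cI, CI
#' self-activation, competitive CI2/Cro2 repression of PR). They were chosen
#' once so that the deterministic limit at MOI = 1, V = 1 shows the canonical
#' regime: [CII] rises from zero after infection and stays high over the
#' 60-minute decision window, with copy numbers in the tens-to-hundreds.
#' Every value can be overridden through the plain-text configuration file
#' (see [read_params()]).
#'
#' @section Fields:
#' \describe{
#'   \item{dim_fwd_CI, dim_fwd_Cro, dim_fwd_CII}{dimerisation rate at unit
#'     volume, per (molecule min)}
#'   \item{dim_rev_CI, dim_rev_Cro, dim_rev_CII}{dimer dissociation, per min}
#'   \item{decay_CI, decay_Cro, decay_CII}{protein first-order decay, per min}
#'   \item{mrna_decay}{shared first-order mRNA decay, per min}
#'   \item{bind_CI, bind_Cro, bind_CII}{dimer--promoter binding at unit
#'     volume, per (molecule min)}
#'   \item{unbind_CI, unbind_Cro, unbind_CII}{dimer--promoter unbinding, per min}
#'   \item{tx_CI_p1}{cI transcription from the CI2-bound (self-activated)
#'     promoter configuration, per min}
#'   \item{tx_CI_p2}{cI transcription from the CII-activated configuration, per min}
#'   \item{tx_Cro, tx_CII}{constitutive transcription from unbound PR, per min}
#'   \item{translation}{translation rate per mRNA, per min}
#'   \item{output_interval}{trajectory sampling interval, min}
#'   \item{cell_width}{cell diameter for the geometry correction, length a.u.}
#' }
#'
#' @return A named list of class `lambda_params`.
#' @examples
#' p <- default_parameters()
#' p$translation
#' @export
default_parameters <- function() {
  p <- list(
    dim_fwd_CI  = 0.002, dim_fwd_Cro = 0.002, dim_fwd_CII = 0.002,
    dim_rev_CI  = 0.5,   dim_rev_Cro = 0.5,   dim_rev_CII = 0.5,
    decay_CI    = 0.1,   decay_Cro   = 0.15,  decay_CII   = 0.3,
    mrna_decay  = 0.2,
    bind_CI     = 0.005, bind_Cro    = 0.06,  bind_CII    = 0.15,
    unbind_CI   = 3.0,   unbind_Cro  = 3.0,   unbind_CII  = 3.0,
    tx_CI_p1    = 1.2,   tx_CI_p2    = 1.2,
    tx_Cro      = 2.4,   tx_CII      = 7.2,
    translation = 1.5,
    output_interval = 0.5,
    cell_width  = 0.5
  )
  structure(p, class = "lambda_params")
}

# field names split by role; used by validation, perturbation and config I/O
.param_fields <- function() names(unclass(default_parameters()))
.control_fields <- function() c("output_interval", "cell_width")
.rate_fields <- function() setdiff(.param_fields(), .control_fields())

.validate_params <- function(params) {
  if (!inherits(params, "lambda_params"))
    stop("`params` must be a lambda_params object (see default_parameters())")
  fields <- .param_fields()
  missing <- setdiff(fields, names(params))
  if (length(missing))
    stop("parameter set is missing field(s): ", paste(missing, collapse = ", "))
  for (f in fields) {
    v <- params[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("parameter '", f, "' must be a single nonnegative number")
  }
  if (params$output_interval <= 0) stop("output_interval must be > 0")
  if (params$cell_width <= 0) stop("cell_width must be > 0")
  invisible(params)
}

#' @export
print.lambda_params <- function(x, ...) {
  cat("Lambda circuit parameter set (rates per min, unit volume)\n")
  v <- unlist(unclass(x))
  print(noquote(format(v, digits = 4)))
  invisible(x)
}

#' Scale the burstiness of gene expression at fixed mean
#'
#' Multiplies the translation rate and the mRNA decay rate by a common factor
#' `f`. Because the stationary mean protein level of a constitutive gene is
#' `tx * translation / (mrna_decay * decay)`, the factor cancels and the mean
#' is untouched, while shortening the mRNA lifetime (f > 1) makes protein
#' production burstier and therefore noisier.
#'
#' @param params a `lambda_params` object
#' @param f positive scale factor (1 = no change)
#' @return a modified copy of `params`
#' @export
apply_noise_scaling <- function(params, f) {
  .validate_params(params)
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f <= 0)
    stop("noise scale factor `f` must be a single positive number")
  params$translation <- params$translation * f
  params$mrna_decay <- params$mrna_decay * f
  params
}

#' Randomly perturb all kinetic rates within a fold bound
#'
#' Each kinetic rate is multiplied by an independent log-uniform draw on
#' `[1/c, c]` (symmetric on the fold scale), as used for global sensitivity
#' analysis. Simulation controls (`output_interval`, `cell_width`) are left
#' untouched. The draw is seeded and reproducible.
#'
#' @param params a `lambda_params` object
#' @param factor_bound fold bound `c > 1` (typically 2 or 10)
#' @param seed integer seed
#' @return a perturbed copy of `params`
#' @export
perturb_parameters <- function(params, factor_bound, seed) {
  .validate_params(params)
  if (!is.numeric(factor_bound) || length(factor_bound) != 1L || factor_bound <= 1)
    stop("`factor_bound` must be a single number > 1")
  rates <- .rate_fields()
  mult <- with_local_seed(seed, {
    exp(stats::runif(length(rates), -log(factor_bound), log(factor_bound)))
  })
  for (i in seq_along(rates)) params[[rates[i]]] <- params[[rates[i]]] * mult[i]
  params
}

#' Spherocylinder (capsule) volume of a rod-shaped cell
#'
#' Because an E. coli cell has hemispherical caps, doubling its length does
#' not exactly double its volume. This helper converts a (length, width) pair
#' to the capsule volume `pi (w/2)^2 (L - w) + (4/3) pi (w/2)^3`, used when
#' translating measured cell lengths into simulation volumes.
#'
#' @param length total cell length (pole to pole), `length >= width`
#' @param width cell diameter
#' @return volume in the cube of the length unit
#' @examples
#' capsule_volume(2, 1) # cylinder of length 1 plus a unit sphere
#' @export
capsule_volume <- function(length, width) {
  if (any(width <= 0)) stop("width must be positive")
  if (any(length < width)) stop("length must be >= width (spherocylinder)")
  r <- width / 2
  pi * r^2 * (length - width) + (4 / 3) * pi * r^3
}

#' Read / write a parameter configuration file
#'
#' The configuration format is a flat YAML mapping whose keys are exactly the
#' `lambda_params` field names; omitted keys take their default values and
#' unknown keys are a hard error. Round-tripping a parameter set through
#' [write_params()] and [read_params()] reproduces it exactly.
#'
#' @param path file path
#' @param params a `lambda_params` object (for writing)
#' @return [read_params()] returns a `lambda_params` object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  params <- default_parameters()
  unknown <- setdiff(names(raw), .param_fields())
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  for (k in names(raw)) params[[k]] <- as.numeric(raw[[k]])
  .validate_params(params)
  params
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  .validate_params(params)
  # write numbers at full precision so the round trip is exact
  vals <- unclass(params)
  lines <- vapply(names(vals), function(k) {
    sprintf("%s: %.17g", k, vals[[k]])
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
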