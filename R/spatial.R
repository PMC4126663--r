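#' Spatial (1-D compartmentalized) simulation configuration
#'
#' The cell is discretised along its long axis into `n_compartments` equal
#' slices; molecules diffuse between neighbouring slices as first-order hops
#' at rate `D / h^2` (`h` the slice width) with reflecting ends, and phage
#' genomes are pinned to the slice they infected. This
#' reaction--diffusion-master-equation picture captures the diffusion delay
#' between spatially separated genomes; it stands in for a full 3-D
#' particle-tracking treatment (see the methods vignette).
#'
#' Default diffusion coefficients are set so that an mRNA traverses a unit
#' cell in about 10 minutes and a protein in a few seconds
#' (see [traversal_time()]), the physiological separation of timescales.
#'
#' @param n_compartments integer >= 1 (odd values give a single centre slice)
#' @param cell_length cell length, a.u.
#' @param D_mrna,D_protein diffusion coefficients, length^2/min
#' @param placement_mode one of `"centre"`, `"quarters"`, `"poles"`,
#'   `"explicit"`
#' @param positions fractional positions in `[0, 1]` (explicit mode only)
#' @return an object of class `spatial_config`
#' @export
spatial_config <- function(n_compartments = 11L, cell_length = 1,
                           D_mrna = 0.05, D_protein = 2.5,
                           placement_mode = c("centre", "quarters", "poles",
                                              "explicit"),
                           positions = NULL) {
  placement_mode <- match.arg(placement_mode)
  if (n_compartments < 1 || n_compartments != round(n_compartments))
    stop("n_compartments must be a positive integer")
  .stopifnot_scalar_number(cell_length, "cell_length", positive = TRUE)
  if (D_mrna < 0 || D_protein < 0) stop("diffusion coefficients must be >= 0")
  if (placement_mode == "explicit") {
    if (is.null(positions)) stop("explicit placement requires `positions`")
    if (any(positions < 0 | positions > 1)) stop("positions must lie in [0, 1]")
  }
  structure(list(n_compartments = as.integer(n_compartments),
                 cell_length = cell_length, D_mrna = D_mrna,
                 D_protein = D_protein, placement_mode = placement_mode,
                 positions = positions),
            class = "spatial_config")
}

#' Compartment indices for infecting phage
#'
#' Named modes reproduce the placements studied experimentally and in
#' simulation: all phage in the centre slice, phage at one quarter and three
#' quarters of the cell length, or phage at the two poles. Indices are
#' 1-based; a fractional position `p` maps to compartment
#' `min(floor(p n) + 1, n)`.
#'
#' @param mode placement mode (see [spatial_config()])
#' @param moi number of phage (named modes support the studied cases:
#'   `centre` any moi, `quarters`/`poles` exactly 2)
#' @param n_compartments number of slices
#' @param positions fractional positions (explicit mode)
#' @return integer vector of compartment indices, length `moi`
#' @examples
#' place_phages("centre", 1, 11)   # middle slice, 6
#' place_phages("quarters", 2, 12) # slices 4 and 10
#' @export
place_phages <- function(mode, moi, n_compartments, positions = NULL) {
  n <- as.integer(n_compartments)
  frac_to_comp <- function(p) pmin(floor(p * n) + 1L, n)
  switch(mode,
    centre = rep(frac_to_comp(0.5), moi),
    quarters = {
      if (moi != 2) stop("quarters placement is defined for moi = 2")
      frac_to_comp(c(0.25, 0.75))
    },
    poles = {
      if (moi != 2) stop("poles placement is defined for moi = 2")
      c(1L, n)
    },
    explicit = {
      if (length(positions) != moi)
        stop("explicit placement needs one position per phage")
      frac_to_comp(positions)
    },
    stop("unknown placement mode: ", mode)
  )
}

#' Expected diffusive traversal time of the cell
#'
#' Characteristic time `L^2 / (2 D)` for a molecule with diffusion
#' coefficient `D` to cross a cell of length `L`; reported as a diagnostic
#' alongside the decision window.
#'
#' @param cell_length cell length, a.u.
#' @param D diffusion coefficient, length^2/min
#' @return time in minutes
#' @export
traversal_time <- function(cell_length, D) {
  if (any(cell_length <= 0) || any(D <= 0))
    stop("cell_length and D must be positive")
  cell_length^2 / (2 * D)
}

#' Discretise a well-mixed network into a 1-D RDME network
#'
#' Every species is replicated per compartment and every reaction runs in
#' every compartment with bimolecular propensities rescaled to the
#' compartment volume `V / n` (the unit-volume rate constant is multiplied by
#' `n`, preserving the well-mixed limit). Diffusible species (everything
#' except promoter states) additionally hop between neighbouring
#' compartments at `D / h^2` per molecule, with reflecting boundaries. With
#' one compartment the construction reduces species-for-species and
#' rate-for-rate to the well-mixed network.
#'
#' @param network a well-mixed `reaction_network` from [build_network()]
#' @param spatial a [spatial_config()]
#' @param volume total cell volume (defaults to the volume recorded when the
#'   network was built)
#' @return a `reaction_network` whose `meta$spatial` records the mapping
#' @export
discretise <- function(network, spatial, volume = NULL) {
  if (!inherits(spatial, "spatial_config")) stop("`spatial` must be a spatial_config")
  if (!is.null(network$meta$spatial)) stop("network is already discretised")
  n <- spatial$n_compartments
  if (is.null(volume)) volume <- network$meta$volume
  base <- network$species
  promoters <- unlist(network$promoter_species, use.names = FALSE)
  diffusible <- setdiff(base, promoters)
  mrna <- intersect(base, c("mCI", "mCro", "mCII"))

  if (n == 1L) {
    network$meta$spatial <- list(n_compartments = 1L, base_species = base,
                                 compartment = stats::setNames(1L, NULL),
                                 config = spatial, total_volume = volume)
    return(network)
  }

  comp_name <- function(sp, j) paste0(sp, "_c", j)
  species <- as.vector(vapply(seq_len(n), function(j)
    comp_name(base, j), character(length(base))))

  # per-compartment copies of every reaction; order-2 rates rescaled by n
  rx <- list()
  R <- length(network$rates)
  for (j in seq_len(n)) {
    for (r in seq_len(R)) {
      from_idx <- which(network$reactants[, r] > 0)
      to_idx <- which(network$products[, r] > 0)
      from <- if (length(from_idx))
        stats::setNames(as.list(network$reactants[from_idx, r]),
                        comp_name(base[from_idx], j)) else list()
      to <- if (length(to_idx))
        stats::setNames(as.list(network$products[to_idx, r]),
                        comp_name(base[to_idx], j)) else list()
      k <- network$rates[r]
      if (network$order[r] == 2L) k <- k * n
      rx[[length(rx) + 1L]] <- list(
        name = paste0(network$reaction_names[r], "_c", j),
        from = from, to = to, rate = k, symbol = network$rate_symbols[r])
    }
  }

  # diffusion hops (reflecting ends)
  h <- spatial$cell_length / n
  for (sp in diffusible) {
    D <- if (sp %in% mrna) spatial$D_mrna else spatial$D_protein
    if (D <= 0) next
    hop <- D / h^2
    for (j in seq_len(n - 1)) {
      rx[[length(rx) + 1L]] <- list(
        name = paste0("hop_", sp, "_", j, "to", j + 1),
        from = stats::setNames(list(1), comp_name(sp, j)),
        to = stats::setNames(list(1), comp_name(sp, j + 1)),
        rate = hop, symbol = "diffusion")
      rx[[length(rx) + 1L]] <- list(
        name = paste0("hop_", sp, "_", j + 1, "to", j),
        from = stats::setNames(list(1), comp_name(sp, j + 1)),
        to = stats::setNames(list(1), comp_name(sp, j)),
        rate = hop, symbol = "diffusion")
    }
  }

  w <- network$cii_weight
  cii_weight <- stats::setNames(rep(unname(w), n), species)
  promoter_species <- lapply(network$promoter_species, function(states)
    as.vector(vapply(seq_len(n), function(j) comp_name(states, j),
                     character(length(states)))))

  out <- .new_network(species, rx, cii_weight, promoter_species,
                      meta = c(network$meta,
                               list(spatial = list(
                                 n_compartments = n, base_species = base,
                                 config = spatial, total_volume = volume))))
  out
}

#' @rdname initial_state
#' @param spatial a [spatial_config()] (spatial networks only); phage are
#'   placed with [place_phages()]
#' @export
initial_state_spatial <- function(network, config, spatial) {
  sp_meta <- network$meta$spatial
  if (is.null(sp_meta)) stop("network is not discretised; use initial_state()")
  x0 <- stats::setNames(integer(length(network$species)), network$species)
  if (any(config$infection_offsets > 0) || config$variants$phage_replication)
    stop("infection offsets and phage replication are not supported spatially")
  comps <- place_phages(spatial$placement_mode, config$moi,
                        spatial$n_compartments, spatial$positions)
  if (sp_meta$n_compartments == 1L) {
    x0["PR"] <- config$moi
    x0["PRE"] <- config$moi
    return(x0)
  }
  for (cc in comps) {
    x0[paste0("PR_c", cc)] <- x0[paste0("PR_c", cc)] + 1L
    x0[paste0("PRE_c", cc)] <- x0[paste0("PRE_c", cc)] + 1L
  }
  x0
}
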