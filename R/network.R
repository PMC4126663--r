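#' Optional model variants
#'
#' Flags switching on the robustness variants of the circuit: CII
#' tetramerisation (PRE activation by CII4 instead of CII2), deterministic
#' phage genome replication early in infection, CI self-repression (a second,
#' weaker CI2 operator that silences the self-activated cI promoter
#' configuration), and per-cell extrinsic noise (lognormal multipliers with
#' the given coefficient of variation applied to all transcription and
#' translation rates, fixed for the cell's lifetime). Flags are independent
#' and freely combinable.
#'
#' @param cii_tetramer logical
#' @param phage_replication logical
#' @param ci_self_repression logical
#' @param extrinsic_noise_cv nonnegative scalar; 0 disables extrinsic noise
#' @return an object of class `variant_flags`
#' @export
variant_flags <- function(cii_tetramer = FALSE, phage_replication = FALSE,
                          ci_self_repression = FALSE, extrinsic_noise_cv = 0) {
  stopifnot(is.logical(cii_tetramer), is.logical(phage_replication),
            is.logical(ci_self_repression))
  .stopifnot_scalar_number(extrinsic_noise_cv, "extrinsic_noise_cv")
  if (extrinsic_noise_cv < 0) stop("extrinsic_noise_cv must be >= 0")
  structure(list(cii_tetramer = cii_tetramer,
                 phage_replication = phage_replication,
                 ci_self_repression = ci_self_repression,
                 extrinsic_noise_cv = extrinsic_noise_cv),
            class = "variant_flags")
}

#' Per-cell infection configuration
#'
#' Describes one simulated infection: the number of infecting phage (MOI),
#' the standardized cell volume (V = 1 is the unit cell), per-phage infection
#' time offsets (the first infection defines time zero), an optional growth
#' model and the model variant flags.
#'
#' @param moi positive integer, number of infecting phage
#' @param volume positive cell volume in standardized units
#' @param infection_offsets numeric vector of per-phage infection times (min),
#'   length `moi`, minimum must be 0; defaults to simultaneous infection
#' @param growth a [growth_model()] or `NULL` for a non-growing cell
#' @param variants a [variant_flags()] object
#' @return an object of class `cell_config`
#' @export
cell_config <- function(moi = 1L, volume = 1, infection_offsets = NULL,
                        growth = NULL, variants = variant_flags()) {
  if (!is.numeric(moi) || length(moi) != 1L || is.na(moi) || moi < 1 ||
      moi != round(moi))
    stop("`moi` must be a positive integer")
  moi <- as.integer(moi)
  .stopifnot_scalar_number(volume, "volume", positive = TRUE)
  if (is.null(infection_offsets)) infection_offsets <- rep(0, moi)
  if (length(infection_offsets) != moi)
    stop("length(infection_offsets) must equal moi")
  if (any(infection_offsets < 0)) stop("infection offsets must be >= 0")
  if (min(infection_offsets) != 0)
    stop("the earliest infection offset must be 0 (time origin is first infection)")
  if (!is.null(growth) && !inherits(growth, "growth_model"))
    stop("`growth` must be NULL or a growth_model object")
  if (!inherits(variants, "variant_flags"))
    stop("`variants` must be a variant_flags object")
  structure(list(moi = moi, volume = volume,
                 infection_offsets = as.numeric(infection_offsets),
                 growth = growth, variants = variants),
            class = "cell_config")
}

#' @export
print.cell_config <- function(x, ...) {
  cat(sprintf("Infection config: MOI = %d, V = %g", x$moi, x$volume))
  if (any(x$infection_offsets > 0))
    cat(", offsets =", paste(signif(x$infection_offsets, 3), collapse = ", "), "min")
  if (!is.null(x$growth)) cat(sprintf(", growth g = %g/min", x$growth$rate))
  v <- x$variants
  on_flags <- c("CII tetramer", "phage replication", "CI self-repression")[
    c(v$cii_tetramer, v$phage_replication, v$ci_self_repression)]
  if (length(on_flags)) cat(", variants:", paste(on_flags, collapse = " + "))
  cat("\n")
  invisible(x)
}

# internal constructor shared by build_network() and discretise()
.new_network <- function(species, reactions, cii_weight, promoter_species,
                         meta = list()) {
  S <- length(species)
  R <- length(reactions)
  reactants <- matrix(0L, S, R, dimnames = list(species, NULL))
  products <- matrix(0L, S, R, dimnames = list(species, NULL))
  rate <- numeric(R)
  rate_symbol <- character(R)
  name <- character(R)
  for (j in seq_len(R)) {
    rx <- reactions[[j]]
    name[j] <- rx$name
    rate[j] <- rx$rate
    rate_symbol[j] <- rx$symbol
    for (sp in names(rx$from)) reactants[sp, j] <- reactants[sp, j] + rx$from[[sp]]
    for (sp in names(rx$to)) products[sp, j] <- products[sp, j] + rx$to[[sp]]
  }
  order <- colSums(reactants)
  if (any(order > 2L)) stop("kinetic order > 2 is not supported")
  volexp <- ifelse(order == 2L, -1L, 0L)
  structure(list(species = species,
                 reactants = reactants,
                 products = products,
                 net_change = products - reactants,
                 reaction_names = name,
                 rates = rate,
                 rate_symbols = rate_symbol,
                 order = as.integer(order),
                 volexp = as.integer(volexp),
                 cii_weight = cii_weight,
                 promoter_species = promoter_species,
                 meta = meta),
            class = "reaction_network")
}

.rx <- function(name, from, to, rate, symbol) {
  list(name = name, from = as.list(from), to = as.list(to),
       rate = rate, symbol = symbol)
}

#' Build the lysis--lysogeny reaction network
#'
#' Constructs the stochastic mass-action network of the early lambda genes:
#' monomers CI, Cro, CII with reversible dimerisation and first-order decay;
#' one mRNA species per gene with shared decay and a common translation rate;
#' per-genome promoter states for PR (free, CI2-bound, Cro2-bound) and PRE
#' (free, CII-multimer-bound). Unbound PR transcribes cro and cII
#' constitutively (activation-free events); the CI2-bound PR configuration
#' transcribes cI (self-activation) and the CII-activated PRE configuration
#' transcribes cI. Gene dosage enters through the initial promoter copy
#' numbers (= MOI), not through extra reactions.
#'
#' Variant flags extend the network: `cii_tetramer` adds CII4 (2 CII2 <-> CII4)
#' and moves PRE activation to CII4; `ci_self_repression` adds a second, weaker
#' CI2 binding step on the CI2-bound PR configuration which silences cI
#' transcription while occupied. Phage replication is an event-schedule
#' feature handled by the simulator, not a reaction.
#'
#' @param params a `lambda_params` object
#' @param config a [cell_config()]
#' @return an object of class `reaction_network`
#' @examples
#' nw <- build_network(default_parameters(), cell_config(moi = 1))
#' nw
#' @export
build_network <- function(params, config) {
  .validate_params(params)
  if (!inherits(config, "cell_config")) stop("`config` must be a cell_config")
  v <- config$variants
  p <- params

  species <- c("CI", "Cro", "CII", "CI2", "Cro2", "CII2",
               "mCI", "mCro", "mCII",
               "PR", "PRCI2", "PRCro2", "PRE", "PREact")
  if (v$cii_tetramer) species <- append(species, "CII4", after = 6L)
  if (v$ci_self_repression) species <- c(species, "PRCI2rep")

  activator <- if (v$cii_tetramer) "CII4" else "CII2"

  rx <- list(
    .rx("dim_CI",    c(CI = 2),  c(CI2 = 1),  p$dim_fwd_CI,  "dim_fwd_CI"),
    .rx("undim_CI",  c(CI2 = 1), c(CI = 2),   p$dim_rev_CI,  "dim_rev_CI"),
    .rx("dim_Cro",   c(Cro = 2), c(Cro2 = 1), p$dim_fwd_Cro, "dim_fwd_Cro"),
    .rx("undim_Cro", c(Cro2 = 1), c(Cro = 2), p$dim_rev_Cro, "dim_rev_Cro"),
    .rx("dim_CII",   c(CII = 2), c(CII2 = 1), p$dim_fwd_CII, "dim_fwd_CII"),
    .rx("undim_CII", c(CII2 = 1), c(CII = 2), p$dim_rev_CII, "dim_rev_CII"),
    .rx("decay_CI",  c(CI = 1),  c(),         p$decay_CI,    "decay_CI"),
    .rx("decay_Cro", c(Cro = 1), c(),         p$decay_Cro,   "decay_Cro"),
    .rx("decay_CII", c(CII = 1), c(),         p$decay_CII,   "decay_CII"),
    .rx("deg_mCI",   c(mCI = 1), c(),         p$mrna_decay,  "mrna_decay"),
    .rx("deg_mCro",  c(mCro = 1), c(),        p$mrna_decay,  "mrna_decay"),
    .rx("deg_mCII",  c(mCII = 1), c(),        p$mrna_decay,  "mrna_decay"),
    .rx("tl_CI",   c(mCI = 1),  c(mCI = 1, CI = 1),   p$translation, "translation"),
    .rx("tl_Cro",  c(mCro = 1), c(mCro = 1, Cro = 1), p$translation, "translation"),
    .rx("tl_CII",  c(mCII = 1), c(mCII = 1, CII = 1), p$translation, "translation"),
    .rx("bind_PR_CI2",    c(CI2 = 1, PR = 1),  c(PRCI2 = 1),        p$bind_CI,   "bind_CI"),
    .rx("unbind_PR_CI2",  c(PRCI2 = 1),        c(CI2 = 1, PR = 1),  p$unbind_CI, "unbind_CI"),
    .rx("bind_PR_Cro2",   c(Cro2 = 1, PR = 1), c(PRCro2 = 1),       p$bind_Cro,  "bind_Cro"),
    .rx("unbind_PR_Cro2", c(PRCro2 = 1),       c(Cro2 = 1, PR = 1), p$unbind_Cro, "unbind_Cro"),
    .rx("bind_PRE",   stats::setNames(c(1, 1), c(activator, "PRE")), c(PREact = 1),
        p$bind_CII, "bind_CII"),
    .rx("unbind_PRE", c(PREact = 1), stats::setNames(c(1, 1), c(activator, "PRE")),
        p$unbind_CII, "unbind_CII"),
    .rx("tx_Cro", c(PR = 1), c(PR = 1, mCro = 1), p$tx_Cro, "tx_Cro"),
    .rx("tx_CII", c(PR = 1), c(PR = 1, mCII = 1), p$tx_CII, "tx_CII"),
    .rx("tx_CI_p1", c(PRCI2 = 1),  c(PRCI2 = 1, mCI = 1),  p$tx_CI_p1, "tx_CI_p1"),
    .rx("tx_CI_p2", c(PREact = 1), c(PREact = 1, mCI = 1), p$tx_CI_p2, "tx_CI_p2")
  )

  if (v$cii_tetramer) {
    rx <- c(rx, list(
      .rx("tet_CII",   c(CII2 = 2), c(CII4 = 1), p$dim_fwd_CII, "dim_fwd_CII"),
      .rx("untet_CII", c(CII4 = 1), c(CII2 = 2), p$dim_rev_CII, "dim_rev_CII")
    ))
  }
  if (v$ci_self_repression) {
    # weaker secondary operator: affinity one tenth of the primary CI2 site
    rx <- c(rx, list(
      .rx("bind_PRM_rep",   c(CI2 = 1, PRCI2 = 1), c(PRCI2rep = 1),
          p$bind_CI / 10, "bind_CI/10"),
      .rx("unbind_PRM_rep", c(PRCI2rep = 1),       c(CI2 = 1, PRCI2 = 1),
          p$unbind_CI, "unbind_CI")
    ))
  }

  cii_weight <- stats::setNames(numeric(length(species)), species)
  cii_weight["CII"] <- 1
  cii_weight["CII2"] <- 2
  cii_weight["PREact"] <- 2
  if (v$cii_tetramer) {
    cii_weight["CII4"] <- 4
    cii_weight["PREact"] <- 4
  }

  pr_states <- c("PR", "PRCI2", "PRCro2",
                 if (v$ci_self_repression) "PRCI2rep")
  pre_states <- c("PRE", "PREact")

  .new_network(species, rx, cii_weight,
               promoter_species = list(PR = pr_states, PRE = pre_states),
               meta = list(variants = v, volume = config$volume,
                           moi = config$moi))
}

#' Initial molecular state of an infected cell
#'
#' All cytoplasmic species start at zero; each phage genome present at time
#' zero contributes one free PR and one free PRE copy. Genomes arriving later
#' (positive infection offsets) or created by replication are added by the
#' simulator's event schedule.
#'
#' @param network a `reaction_network` from [build_network()]
#' @param config the matching [cell_config()]
#' @return named integer vector of initial copy numbers
#' @export
initial_state <- function(network, config) {
  sp <- network$meta$spatial
  if (!is.null(sp) && sp$n_compartments > 1L)
    stop("network is discretised; build the state with initial_state_spatial()")
  x0 <- stats::setNames(integer(length(network$species)), network$species)
  n0 <- sum(config$infection_offsets == 0)
  x0["PR"] <- n0
  x0["PRE"] <- n0
  x0
}

#' Mass-action propensity of one reaction
#'
#' Order 0 gives `k`; order 1 gives `k x`; an order-2 reaction between
#' distinct species gives `(k/V) x y` and a homodimerisation gives
#' `(k/V) x (x - 1) / 2`. Unimolecular rates are volume-free.
#'
#' @param network a `reaction_network`
#' @param reaction reaction index or name
#' @param state named (or network-ordered) vector of copy numbers
#' @param volume current cell volume
#' @return the propensity, per minute
#' @export
propensity <- function(network, reaction, state, volume) {
  if (is.character(reaction))
    reaction <- match(reaction, network$reaction_names)
  if (is.na(reaction) || reaction < 1 || reaction > length(network$rates))
    stop("unknown reaction")
  .stopifnot_scalar_number(volume, "volume", positive = TRUE)
  if (!is.null(names(state))) state <- state[network$species]
  if (any(state < 0)) stop("negative copy number in state")
  k <- network$rates[reaction]
  re <- network$reactants[, reaction]
  idx <- which(re > 0)
  ord <- network$order[reaction]
  if (ord == 0L) return(k)
  if (ord == 1L) return(k * state[[idx]])
  if (length(idx) == 1L) {
    n <- state[[idx]]
    return(k / volume * n * (n - 1) / 2)
  }
  k / volume * state[[idx[1]]] * state[[idx[2]]]
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("Reaction network: %d species, %d reactions\n",
              length(x$species), length(x$rates)))
  cat("Species:", paste(x$species, collapse = ", "), "\n")
  invisible(x)
}

#' Write a human-readable reaction table
#'
#' Dumps the network as TSV (reaction name, reactants, products, rate symbol,
#' rate value, kinetic order), one row per reaction.
#'
#' @param network a `reaction_network`
#' @param path output file path
#' @return the path, invisibly
#' @export
write_network_tsv <- function(network, path) {
  side <- function(mat, j) {
    idx <- which(mat[, j] > 0)
    if (!length(idx)) return("-")
    paste(ifelse(mat[idx, j] > 1, paste0(mat[idx, j], " "), ""),
          rownames(mat)[idx], sep = "", collapse = " + ")
  }
  df <- data.frame(
    reaction = network$reaction_names,
    reactants = vapply(seq_along(network$rates), function(j)
      side(network$reactants, j), character(1)),
    products = vapply(seq_along(network$rates), function(j)
      side(network$products, j), character(1)),
    rate_symbol = network$rate_symbols,
    rate = network$rates,
    order = network$order,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
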