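# Toy networks and small fixtures shared across the suite. Everything is
# built in code; no stored data.

# single-species birth-death process: 0 -> X at rate `birth`, X -> 0 at `death`
birth_death_network <- function(birth = 10, death = 1) {
  species <- "X"
  reactants <- matrix(c(0L, 1L), 1, 2, dimnames = list(species, NULL))
  products <- matrix(c(1L, 0L), 1, 2, dimnames = list(species, NULL))
  structure(list(species = species, reactants = reactants,
                 products = products, net_change = products - reactants,
                 reaction_names = c("birth", "death"),
                 rates = c(birth, death), rate_symbols = c("birth", "death"),
                 order = c(0L, 1L), volexp = c(0L, 0L),
                 cii_weight = c(X = 1), promoter_species = list(),
                 meta = list()),
            class = "reaction_network")
}

# reversible dimerisation A + A <-> A2 in volume 1, closed system
dimerisation_network <- function(kf = 0.2, kr = 1) {
  species <- c("A", "A2")
  reactants <- matrix(c(2L, 0L, 0L, 1L), 2, 2, dimnames = list(species, NULL))
  products <- matrix(c(0L, 1L, 2L, 0L), 2, 2, dimnames = list(species, NULL))
  structure(list(species = species, reactants = reactants,
                 products = products, net_change = products - reactants,
                 reaction_names = c("dim", "undim"),
                 rates = c(kf, kr), rate_symbols = c("kf", "kr"),
                 order = c(2L, 1L), volexp = c(-1L, 0L),
                 cii_weight = c(A = 0, A2 = 0), promoter_species = list(),
                 meta = list()),
            class = "reaction_network")
}

# stationary distribution of the closed dimerisation system solved directly
# from the master equation generator (the independent oracle for the SSA):
# states are d = 0..floor(N/2) dimers with a = N - 2d monomers.
dimerisation_cme_stationary <- function(N, kf = 0.2, kr = 1) {
  nd <- 0:(N %/% 2)
  S <- length(nd)
  Q <- matrix(0, S, S)
  for (i in seq_len(S)) {
    d <- nd[i]
    a <- N - 2 * d
    up <- kf * a * (a - 1) / 2
    down <- kr * d
    if (i < S && up > 0) Q[i, i + 1] <- up
    if (i > 1) Q[i, i - 1] <- down
  }
  diag(Q) <- -rowSums(Q)
  # solve pi Q = 0 with sum(pi) = 1
  A <- rbind(t(Q), rep(1, S))
  b <- c(rep(0, S), 1)
  pi_hat <- qr.solve(A, b)
  pmax(pi_hat, 0) / sum(pmax(pi_hat, 0))
}

# tiny horizon/interval parameter set for fast structural tests
fast_params <- function(...) {
  p <- default_parameters()
  ov <- list(...)
  for (k in names(ov)) p[[k]] <- ov[[k]]
  p
}

minimal_cell <- function(moi = 1, volume = 1, ...) {
  cell_config(moi = moi, volume = volume, ...)
}
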