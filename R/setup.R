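# System construction: concentration/box conversions, random placement of
# chains, Maxwell-Boltzmann velocity initialization, and the dmd_state
# container shared by the engine and the analysis layer.

.AVOGADRO <- 6.02214076e23

# run a block with a private, seed-derived RNG stream, restoring the
# caller's .Random.seed afterwards
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Peptide concentration of n chains in a cubic box
#'
#' @param n_peptides chain count.
#' @param box_length cubic box edge in Angstrom.
#' @return concentration in mM (1 A^3 = 1e-27 L).
#' @export
concentration_of <- function(n_peptides, box_length) {
  stopifnot(box_length > 0)
  1000 * n_peptides / (.AVOGADRO * box_length^3 * 1e-27)
}

#' Box edge for a target concentration
#'
#' Exact inverse of [concentration_of()].
#'
#' @param n_peptides chain count.
#' @param concentration target concentration in mM.
#' @return cubic box edge in Angstrom.
#' @export
box_length_for <- function(n_peptides, concentration) {
  stopifnot(concentration > 0)
  (1000 * n_peptides / (.AVOGADRO * concentration * 1e-27))^(1 / 3)
}

# minimum-image displacement(s); x may be a matrix of row vectors
.min_image <- function(x, L) x - L * round(x / L)

# uniform random rotation matrix (Arvo's quaternion method)
.random_rotation <- function() {
  u <- runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# assemble a dmd_state from per-chain coordinates
.make_state <- function(positions, topology, n_chains, box_length,
                        hbonds = matrix(integer(0), 0, 2)) {
  m <- topology$n_beads
  beads <- topology$beads
  meta <- data.frame(
    chain = rep(seq_len(n_chains), each = m),
    residue = rep(beads$residue, n_chains),
    res_letter = rep(beads$res_letter, n_chains),
    type = rep(beads$type, n_chains),
    mass = rep(beads$mass, n_chains),
    radius = rep(beads$diameter / 2, n_chains))
  colnames(hbonds) <- c("donor_bead", "acceptor_bead")
  structure(list(positions = positions,
                 velocities = matrix(0, nrow(positions), 3),
                 box_length = box_length, clock = 0,
                 meta = meta, topology = topology, n_chains = n_chains,
                 hbonds = hbonds),
            class = "dmd_state")
}

#' @export
print.dmd_state <- function(x, ...) {
  cat(sprintf("dmd_state: %d chains (%d beads), box %.1f A, t = %.3f tau, %d H-bonds\n",
              x$n_chains, nrow(x$positions), x$box_length, x$clock,
              nrow(x$hbonds)))
  invisible(x)
}

#' Randomly place peptide chains in a periodic box
#'
#' Chains are placed in the extended reference conformation with uniform
#' random orientation and position, rejecting placements with any
#' inter-bead hard-core overlap (minimum-image).  Deterministic for a given
#' seed.
#'
#' @param n_peptides number of chains.
#' @param box_length cubic box edge (A).
#' @param topology `peptide_topology` shared by all chains.
#' @param seed integer RNG seed.
#' @param max_tries rejection-sampling cap per chain.
#' @return a `dmd_state` (velocities zero; call [init_velocities()]).
#' @export
random_initial_configuration <- function(n_peptides, box_length, topology,
                                         seed = 1L, max_tries = 1e5) {
  stopifnot(n_peptides >= 1)
  ref <- reference_conformation(topology)
  ref <- sweep(ref, 2, colMeans(ref))
  m <- topology$n_beads
  radius <- topology$beads$diameter / 2
  extent <- 2 * sqrt(max(rowSums(ref^2)))
  if (box_length < extent)
    stop(sprintf("box length %.1f A cannot accommodate a chain of extent %.1f A",
                 box_length, extent))
  .with_seed(seed, {
    placed <- matrix(NA_real_, n_peptides * m, 3)
    placed_r <- rep(radius, n_peptides)
    for (c_i in seq_len(n_peptides)) {
      ok <- FALSE
      for (trial in seq_len(max_tries)) {
        Rm <- .random_rotation()
        cand <- ref %*% t(Rm) +
          matrix(runif(3, 0, box_length), m, 3, byrow = TRUE)
        if (c_i > 1L) {
          prev <- placed[seq_len((c_i - 1L) * m), , drop = FALSE]
          clash <- FALSE
          for (b in seq_len(m)) {
            d <- .min_image(sweep(prev, 2, cand[b, ]), box_length)
            dist2 <- rowSums(d^2)
            lim <- (placed_r[seq_len((c_i - 1L) * m)] + radius[b])^2
            if (any(dist2 < lim)) { clash <- TRUE; break }
          }
          if (clash) next
        }
        placed[(c_i - 1L) * m + seq_len(m), ] <- cand
        ok <- TRUE
        break
      }
      if (!ok)
        stop(sprintf("placement failed for chain %d after %d tries (density too high)",
                     c_i, as.integer(max_tries)))
    }
    placed <- placed %% box_length
    .make_state(placed, topology, n_peptides, box_length)
  })
}

#' Draw Maxwell-Boltzmann velocities at reduced temperature T*
#'
#' Components are Gaussian with variance T*/m (energies in eps_HB units,
#' k_B = 1); net linear momentum is removed and the instantaneous reduced
#' temperature rescaled to exactly T*.
#'
#' @param state a `dmd_state`.
#' @param tstar reduced temperature T* = k_B T / eps_HB.
#' @param seed integer RNG seed.
#' @return the state with velocities set.
#' @export
init_velocities <- function(state, tstar, seed = 1L) {
  stopifnot(tstar > 0)
  m <- state$meta$mass
  n <- length(m)
  .with_seed(seed, {
    v <- matrix(rnorm(3 * n), n, 3) / sqrt(m)
    v <- v * sqrt(tstar)
    # remove net momentum
    p <- colSums(v * m) / sum(m)
    v <- sweep(v, 2, p)
    tin <- sum(m * rowSums(v^2)) / (3 * n)
    state$velocities <- v * sqrt(tstar / tin)
    state
  })
}

#' Instantaneous reduced temperature of a state
#'
#' @param state a `dmd_state`.
#' @return 2 KE / (3 n) in eps_HB units.
#' @export
instantaneous_temperature <- function(state) {
  m <- state$meta$mass
  sum(m * rowSums(state$velocities^2)) / (3 * length(m))
}
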