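# Synthetic fixtures: ideal beta-sheet lattices with construction-time
# ground truth, random monomer gases, synthetic MS peak lists and CCS
# calibrant sets.  Fixtures are built to satisfy the engine's hydrogen-bond
# criteria first and the experimental 4.9 / 9.9 A spacing targets second.
#
# Lattice construction: strands run along x with CaH spacing 3.8 A; strand
# s of a layer sits at y = s * strand_spacing; layer l is lifted by
# l * layer_spacing in z and staggered by 1.9 A in x so that the
# up-pointing aromatic sidechains of one layer fall inside the square wells
# of the down-pointing sidechains of the next.  In antiparallel sheets
# alternate strands are reversed; hydrogen-bond rungs alternate sides along
# each strand (rung at residue i of strand s toward strand s+1 when i+s is
# even) so that no NH donates or CO accepts twice.

.sheet_arrangements <- c("antiparallel_in_register",
                         "antiparallel_out_of_register",
                         "parallel_in_register",
                         "parallel_out_of_register")

#' Build an ideal beta-sheet lattice fixture with ground truth
#'
#' @param arrangement one of `"antiparallel_in_register"`,
#'   `"antiparallel_out_of_register"`, `"parallel_in_register"`,
#'   `"parallel_out_of_register"`.
#' @param n_strands strands per layer (>= 2).
#' @param n_layers stacked sheet layers.
#' @param offset registry offset in residues (used by the out-of-register
#'   arrangements; magnitude < chain length).
#' @param topology `peptide_topology` of the strand.
#' @param strand_spacing,layer_spacing lattice spacings in A (defaults 4.9
#'   and 9.9, the cross-beta reflections).
#' @param margin padding added around the lattice to size the periodic box.
#' @return list with elements `state` (a `dmd_state` including the
#'   constructed hydrogen bonds) and `ground_truth` (per-pair
#'   classifications, per-residue beta labels, layer count, expected
#'   nearest sidechain partners).
#' @export
build_sheet_fixture <- function(arrangement, n_strands, n_layers = 1L,
                                offset = 0L,
                                topology = build_topology("KLVFFAE"),
                                strand_spacing = 4.9, layer_spacing = 9.9,
                                margin = 25) {
  arrangement <- match.arg(arrangement, .sheet_arrangements)
  antiparallel <- grepl("^antiparallel", arrangement)
  if (grepl("in_register$", arrangement)) offset <- 0L
  res <- strsplit(topology$sequence, "")[[1]]
  n <- length(res)
  if (abs(offset) >= n) stop("offset magnitude must be < chain length")
  if (n_strands < 2L) stop("need at least 2 strands")
  geo <- topology$params$geometry
  m <- topology$n_beads
  ref_fwd <- reference_conformation(topology)
  # reversed strand: mirror x about the CaH span midpoint
  ref_rev <- ref_fwd
  ref_rev[, 1] <- geo$ca_ca * (n - 1) - ref_fwd[, 1]

  # per-strand x offsets a_s chosen so adjacent pairs bond with the given
  # registry offset (see module comments)
  a <- numeric(n_strands)
  for (s in seq_len(n_strands - 1L)) {
    if (antiparallel) {
      a[s + 1L] <- a[s] + (if (s %% 2L == 1L) -1 else 1) * geo$ca_ca * offset
    } else {
      a[s + 1L] <- a[s] - 2.0 - geo$ca_ca * offset
    }
  }

  n_chains <- n_strands * n_layers
  pos <- matrix(NA_real_, n_chains * m, 3)
  chain_of <- function(layer, s) (layer - 1L) * n_strands + s
  for (layer in seq_len(n_layers)) {
    for (s in seq_len(n_strands)) {
      rev_strand <- antiparallel && (s %% 2L == 0L)
      base <- if (rev_strand) ref_rev else ref_fwd
      shift <- c(a[s] + 1.9 * (layer - 1L),
                 strand_spacing * (s - 1L),
                 layer_spacing * (layer - 1L))
      ci <- chain_of(layer, s)
      pos[(ci - 1L) * m + seq_len(m), ] <- sweep(base, 2, -shift)
    }
  }

  # hydrogen bonds: rungs at residue i (1-based) of strand s with
  # (i-1 + s-1) even, toward strand s+1
  hb <- list()
  gt_pairs <- list()
  bonded_res <- vector("list", n_chains)  # residues carrying a bond
  for (layer in seq_len(n_layers)) {
    for (s in seq_len(n_strands - 1L)) {
      ci <- chain_of(layer, s); cj <- chain_of(layer, s + 1L)
      off_i <- (ci - 1L) * m; off_j <- (cj - 1L) * m
      nb <- 0L
      pair_offsets <- integer(0)
      for (i in seq_len(n)) {
        if ((i - 1L + s - 1L) %% 2L != 0L) next
        if (antiparallel) {
          p <- n + 1L - i - offset          # partner residue on strand s+1
          if (p < 1L || p > n) next
          hb <- c(hb, list(c(off_i + topology$bb_index[i, "NH"],
                             off_j + topology$bb_index[p, "CO"]),
                           c(off_j + topology$bb_index[p, "NH"],
                             off_i + topology$bb_index[i, "CO"])))
          nb <- nb + 2L
          pair_offsets <- c(pair_offsets, rep((i - 1L) + (p - 1L) - (n - 1L), 2L))
          bonded_res[[ci]] <- union(bonded_res[[ci]], i)
          bonded_res[[cj]] <- union(bonded_res[[cj]], p)
        } else {
          p <- i + offset
          if (p >= 1L && p <= n) {
            hb <- c(hb, list(c(off_i + topology$bb_index[i, "NH"],
                               off_j + topology$bb_index[p, "CO"])))
            nb <- nb + 1L
            pair_offsets <- c(pair_offsets, (p - 1L) - (i - 1L))
            bonded_res[[ci]] <- union(bonded_res[[ci]], i)
            bonded_res[[cj]] <- union(bonded_res[[cj]], p)
          }
          if (p + 1L >= 1L && p + 1L <= n) {
            hb <- c(hb, list(c(off_j + topology$bb_index[p + 1L, "NH"],
                               off_i + topology$bb_index[i, "CO"])))
            nb <- nb + 1L
            pair_offsets <- c(pair_offsets, (p + 1L - 1L) - (i - 1L))
            bonded_res[[ci]] <- union(bonded_res[[ci]], i)
            bonded_res[[cj]] <- union(bonded_res[[cj]], p + 1L)
          }
        }
      }
      gt_pairs[[length(gt_pairs) + 1L]] <- data.frame(
        chain_i = ci, chain_j = cj,
        orientation = if (antiparallel) "antiparallel" else "parallel",
        registry_offset = .registry_median(pair_offsets),
        n_hbonds = nb)
    }
  }
  hb <- do.call(rbind, hb)

  # shift into a periodic box with a safety margin
  span <- apply(pos, 2, range)
  box_length <- max(span[2, ] - span[1, ]) + 2 * margin
  pos <- sweep(pos, 2, span[1, ] - margin)

  state <- .make_state(pos, topology, n_chains, box_length, hbonds = hb)

  # beta labels: residue is beta iff within one position of a bonded residue
  beta <- matrix(FALSE, n_chains, n)
  for (ci in seq_len(n_chains)) {
    for (r in bonded_res[[ci]]) {
      beta[ci, max(1L, r - 1L):min(n, r + 1L)] <- TRUE
    }
  }

  # expected nearest interpeptide sidechain partner per (chain, residue),
  # from the constructed geometry
  nearest <- matrix(NA_character_, n_chains, n)
  sc_global <- function(ci, r) (ci - 1L) * m + topology$sc_index[r]
  sc_ids <- unlist(lapply(seq_len(n_chains), function(ci)
    vapply(seq_len(n), function(r)
      if (topology$sc_index[r] > 0L) sc_global(ci, r) else NA_integer_,
      integer(1))))
  sc_chain <- rep(seq_len(n_chains), each = n)
  sc_res <- rep(seq_len(n), n_chains)
  keep <- !is.na(sc_ids)
  sc_ids <- sc_ids[keep]; sc_chain <- sc_chain[keep]; sc_res <- sc_res[keep]
  for (idx in seq_along(sc_ids)) {
    other <- sc_chain != sc_chain[idx]
    d <- .min_image(sweep(pos[sc_ids[other], , drop = FALSE], 2,
                          pos[sc_ids[idx], ]), box_length)
    j <- which.min(rowSums(d^2))
    partner <- res[sc_res[other][j]]
    pp <- pair_potential(res[sc_res[idx]], partner, topology$params)
    cutoff <- if (pp$well_depth > 0) pp$well_width else 1.2 * pp$contact_distance
    if (sqrt(rowSums(d^2))[j] <= cutoff)
      nearest[sc_chain[idx], sc_res[idx]] <- partner
  }

  ground_truth <- list(
    arrangement = arrangement, offset = offset,
    pairs = do.call(rbind, gt_pairs),
    beta_labels = beta,
    beta_fraction = 100 * mean(beta),
    layer_count = n_layers,
    nearest_partner = nearest,
    n_hbonds = nrow(hb))
  list(state = state, ground_truth = ground_truth)
}

#' Random monomer gas fixture
#'
#' Thin wrapper over [random_initial_configuration()] with fixture
#' labelling: zero hydrogen bonds, zero beta content.
#'
#' @inheritParams random_initial_configuration
#' @param tstar if non-NULL, also draw Maxwell-Boltzmann velocities.
#' @export
build_random_gas <- function(n_peptides, box_length,
                             topology = build_topology("KLVFFAE"),
                             seed = 1L, tstar = NULL) {
  state <- random_initial_configuration(n_peptides, box_length, topology,
                                        seed = seed)
  if (!is.null(tstar)) state <- init_velocities(state, tstar, seed = seed + 1L)
  state
}

#' Verify that a fixture is a valid engine state
#'
#' Checks that every recorded hydrogen bond satisfies the engine's
#' geometric criteria (donor-acceptor within the well, auxiliary beads
#' outside the exclusion distance) and that no hard cores overlap.
#'
#' @param state a `dmd_state`.
#' @param params an `sw_parameter_table`.
#' @return TRUE invisibly; stops with a message otherwise.
#' @export
validate_fixture <- function(state, params = default_parameter_table()) {
  chk <- hbond_geometry_ok(state, params)
  if (!all(chk))
    stop("hydrogen bond(s) violating geometric criteria: ",
         paste(which(!chk), collapse = ", "))
  ov <- max_core_overlap(state, params)
  if (ov > 1e-9)
    stop(sprintf("hard-core overlap of %.3g A in fixture", ov))
  invisible(TRUE)
}

#' Synthetic fragment peak list for a species
#'
#' Generates the theoretical fragment m/z values of a (cross-linked)
#' species at the requested charge states, optionally adding seeded decoy
#' peaks and mass jitter; the generating species is recorded as ground
#' truth.
#'
#' @param species a `molecular_species`.
#' @param charge_states integer vector of charges.
#' @param decoy_fraction decoys added as a fraction of the true peak count.
#' @param mass_jitter_da Gaussian jitter (s.d., Da, neutral-mass scale).
#' @param seed RNG seed.
#' @return data.frame `(mz, z)` with attribute `"ground_truth"`.
#' @export
synthetic_peaklist <- function(species, charge_states = 1L,
                               decoy_fraction = 0, mass_jitter_da = 0,
                               seed = 1L) {
  fr <- fragment_ions(species, max_charge = max(charge_states),
                      include_double = TRUE)
  fr <- fr[fr$z %in% charge_states, ]
  .with_seed(seed, {
    neutral <- fr$neutral_mass
    if (mass_jitter_da > 0)
      neutral <- neutral + rnorm(length(neutral), 0, mass_jitter_da)
    peaks <- data.frame(mz = neutral_mass_to_mz(neutral, fr$z), z = fr$z)
    if (decoy_fraction > 0) {
      nd <- max(1L, round(decoy_fraction * nrow(peaks)))
      decoys <- data.frame(mz = runif(nd, min(peaks$mz), max(peaks$mz)),
                           z = sample(charge_states, nd, replace = TRUE))
      peaks <- rbind(peaks, decoys)
    }
    peaks <- peaks[order(peaks$mz), ]
    rownames(peaks) <- NULL
    attr(peaks, "ground_truth") <- species$crosslink
    peaks
  })
}

#' Synthetic TWIMS calibrant set
#'
#' Drift times are drawn log-uniformly on [1, 20]; reference CCS values are
#' generated from the power-law calibration relation with optional
#' multiplicative Gaussian noise.
#'
#' @param A,B generating calibration constants (A > 0).
#' @param n number of calibrants (>= 2).
#' @param noise relative (multiplicative) noise s.d., e.g. 0.01 for 1%.
#' @param seed RNG seed.
#' @param gas_mass drift-gas mass (Da).
#' @return calibrant data.frame `(t_d, z, m_ion, ccs_ref)`.
#' @export
synthetic_calibrants <- function(A, B, n, noise = 0, seed = 1L,
                                 gas_mass = .N2_GAS_MASS) {
  stopifnot(A > 0, n >= 2)
  .with_seed(seed, {
    t_d <- exp(runif(n, log(1), log(20)))
    z <- sample(1:3, n, replace = TRUE)
    m_ion <- runif(n, 500, 8000)
    ccs <- A * t_d^B * z * sqrt(1 / m_ion + 1 / gas_mass)
    if (noise > 0) ccs <- ccs * (1 + rnorm(n, 0, noise))
    data.frame(t_d = t_d, z = z, m_ion = m_ion, ccs_ref = ccs)
  })
}
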