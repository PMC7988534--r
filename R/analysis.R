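# Trajectory observables: hydrogen-bond maps, beta-sheet residue fraction,
# strand-pair orientation/registry classification, nearest interpeptide
# sidechain contacts, oligomer clustering, layer counting, and time series.
#
# Beta-residue convention (the observable behind the "percentage of
# residues in beta-sheet structure" curve): a residue counts as beta iff
# its chain participates in a classified strand pair (>= 2 hydrogen bonds
# with one other chain) and the residue is within one sequence position of
# a residue donating or accepting one of those bonds.  This gives 0% for a
# monomer gas and ~100% for ideal lattices, and is insensitive to termini
# conventions.

# registry offset from a set of per-bond pairing offsets: median with
# half-integer ties broken toward zero
.registry_median <- function(v) as.integer(trunc(stats::median(v)))

# map bead ids to (chain, residue) using state metadata
.bead_chain <- function(state, bead) state$meta$chain[bead]
.bead_res <- function(state, bead) state$meta$residue[bead]

#' Hydrogen-bond map of a snapshot
#'
#' Returns the engine's live hydrogen-bond set as a residue-level table.
#' Geometric consistency can be audited with [hbond_geometry_ok()].
#'
#' @param state a `dmd_state` (or trajectory snapshot).
#' @return data.frame `(donor_chain, donor_res, acceptor_chain,
#'   acceptor_res)`.
#' @export
hydrogen_bond_map <- function(state) {
  hb <- state$hbonds
  data.frame(donor_chain = .bead_chain(state, hb[, 1]),
             donor_res = .bead_res(state, hb[, 1]),
             acceptor_chain = .bead_chain(state, hb[, 2]),
             acceptor_res = .bead_res(state, hb[, 2]))
}

#' Audit recorded hydrogen bonds against the geometric criteria
#'
#' @param state a `dmd_state`.
#' @param params an `sw_parameter_table`.
#' @return logical vector, one entry per recorded bond: donor-acceptor
#'   distance inside the HB well and all auxiliary beads (CaH and CO
#'   flanking the NH; CaH and NH flanking the CO) outside the exclusion
#'   distance.
#' @export
hbond_geometry_ok <- function(state, params = default_parameter_table()) {
  hb <- state$hbonds
  if (nrow(hb) == 0L) return(logical(0))
  topo <- state$topology
  m <- topo$n_beads
  L <- state$box_length
  pos <- state$positions
  dist1 <- function(i, j) {
    sqrt(sum(.min_image(pos[j, ] - pos[i, ], L)^2))
  }
  aux_of <- function(bead) {
    ch <- state$meta$chain[bead]
    r <- state$meta$residue[bead]
    ty <- state$meta$type[bead]
    base <- (ch - 1L) * m
    if (ty == "NH") {
      c(base + topo$bb_index[r, "CA"],
        if (r > 1L) base + topo$bb_index[r - 1L, "CO"] else NA_integer_)
    } else {
      c(base + topo$bb_index[r, "CA"],
        if (r < nrow(topo$bb_index)) base + topo$bb_index[r + 1L, "NH"]
        else NA_integer_)
    }
  }
  vapply(seq_len(nrow(hb)), function(k) {
    nh <- hb[k, 1]; co <- hb[k, 2]
    if (dist1(nh, co) > params$hb_well_width) return(FALSE)
    for (a in stats::na.omit(c(aux_of(nh)))) {
      if (dist1(a, co) <= params$hb_aux_distance) return(FALSE)
    }
    for (a in stats::na.omit(c(aux_of(co)))) {
      if (dist1(a, nh) <= params$hb_aux_distance) return(FALSE)
    }
    TRUE
  }, logical(1))
}

#' Largest hard-core overlap in a state
#'
#' @param state a `dmd_state`.
#' @param params parameter table (for the near-chain core scaling).
#' @return max over bead pairs of (core distance - separation), clamped at
#'   0; bonded/pseudobonded pairs excluded.
#' @export
max_core_overlap <- function(state, params = default_parameter_table()) {
  info <- .pair_exclusions(state$topology)
  pos <- state$positions
  L <- state$box_length
  n <- nrow(pos)
  m <- state$topology$n_beads
  radius <- state$meta$radius
  worst <- 0
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    d2 <- rowSums(.min_image(sweep(pos[js, , drop = FALSE], 2, pos[i, ]), L)^2)
    core <- radius[i] + radius[js]
    same <- state$meta$chain[js] == state$meta$chain[i]
    li <- (i - 1L) %% m + 1L
    lj <- (js - 1L) %% m + 1L
    code <- ifelse(same, info$code[cbind(li, lj)], 0L)
    # NH-CO pairs use the reduced hydrogen-bond core
    hbpair <- (state$meta$type[i] == "NH" & state$meta$type[js] == "CO") |
      (state$meta$type[i] == "CO" & state$meta$type[js] == "NH")
    eligible <- !same | abs(state$meta$residue[js] - state$meta$residue[i]) >=
      params$geometry$hb_min_res_sep
    core[hbpair & eligible & code == 0L] <- params$hb_core
    core[code == 2L] <- core[code == 2L] * params$geometry$core_scale_near
    core[code == 1L] <- 0  # walled pairs handled by bond walls
    worst <- max(worst, max(core - sqrt(d2), 0))
  }
  worst
}

# same-chain pair classification shared with the engine: code m x m matrix
# (0 plain, 1 walled, 2 scaled core), wall bounds, from the topology's
# bonds, pseudobonds and bond-graph distances
.pair_exclusions <- function(topology) {
  m <- topology$n_beads
  code <- matrix(0L, m, m)
  wmin <- matrix(0, m, m)
  wmax <- matrix(0, m, m)
  all_walls <- rbind(topology$bonds, topology$pseudobonds)
  for (k in seq_len(nrow(all_walls))) {
    i <- all_walls$i[k]; j <- all_walls$j[k]
    code[i, j] <- code[j, i] <- 1L
    wmin[i, j] <- wmin[j, i] <- all_walls$min[k]
    wmax[i, j] <- wmax[j, i] <- all_walls$max[k]
  }
  # bond-graph distances (covalent bonds only) for near-chain core scaling
  adj <- lapply(seq_len(m), function(i) integer(0))
  for (k in seq_len(nrow(topology$bonds))) {
    i <- topology$bonds$i[k]; j <- topology$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  for (s in seq_len(m)) {
    dist <- rep(NA_integer_, m); dist[s] <- 0L
    frontier <- s
    for (step in 1:3) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.na(dist[nxt])]
      if (!length(nxt)) break
      dist[nxt] <- step
      frontier <- nxt
    }
    near <- which(!is.na(dist) & dist > 0L)
    for (j in near) if (code[s, j] == 0L) code[s, j] <- 2L
  }
  list(code = code, wall_min = wmin, wall_max = wmax)
}

#' Classify the orientation and registry of a hydrogen-bonded strand pair
#'
#' Orientation comes from the pairing pattern of donor/acceptor residue
#' indices across the pair's hydrogen bonds: a parallel pair has a constant
#' residue-index difference, an antiparallel pair a constant sum.  The
#' registry offset is the median pairing offset (ties toward zero):
#' `i + j - (n - 1)` (0-based) for antiparallel pairs, `j - i` for
#' parallel; offset 0 is in-register.
#'
#' @param chain_i,chain_j chain indices.
#' @param hbmap a [hydrogen_bond_map()] table.
#' @param n_residues chain length.
#' @return list `(chain_i, chain_j, orientation, registry_offset,
#'   n_hbonds)`, or `NULL` when the pair has fewer than 2 bonds.
#' @export
classify_strand_pair <- function(chain_i, chain_j, hbmap, n_residues) {
  sel_ij <- hbmap$donor_chain == chain_i & hbmap$acceptor_chain == chain_j
  sel_ji <- hbmap$donor_chain == chain_j & hbmap$acceptor_chain == chain_i
  ri <- c(hbmap$donor_res[sel_ij], hbmap$acceptor_res[sel_ji]) - 1L
  rj <- c(hbmap$acceptor_res[sel_ij], hbmap$donor_res[sel_ji]) - 1L
  nb <- length(ri)
  if (nb < 2L) return(NULL)
  v_par <- stats::var(rj - ri)
  v_anti <- stats::var(ri + rj)
  if (v_par < v_anti) {
    orientation <- "parallel"
  } else if (v_anti < v_par) {
    orientation <- "antiparallel"
  } else {
    # degenerate tie: fall back to the sign of the pairing slope
    slope <- sum((ri - mean(ri)) * (rj - mean(rj)))
    orientation <- if (slope > 0) "parallel" else "antiparallel"
  }
  off <- if (orientation == "antiparallel") {
    .registry_median(ri + rj - (n_residues - 1L))
  } else {
    .registry_median(rj - ri)
  }
  list(chain_i = chain_i, chain_j = chain_j, orientation = orientation,
       registry_offset = off, n_hbonds = nb)
}

#' Classify all hydrogen-bonded strand pairs in a snapshot
#'
#' @param state a `dmd_state`.
#' @return data.frame of classifications (pairs with >= 2 bonds only).
#' @export
classify_all_pairs <- function(state) {
  hbmap <- hydrogen_bond_map(state)
  n <- nchar(state$topology$sequence)
  if (nrow(hbmap) == 0L)
    return(data.frame(chain_i = integer(0), chain_j = integer(0),
                      orientation = character(0),
                      registry_offset = integer(0), n_hbonds = integer(0)))
  key <- cbind(pmin(hbmap$donor_chain, hbmap$acceptor_chain),
               pmax(hbmap$donor_chain, hbmap$acceptor_chain))
  pairs <- unique(key[key[, 1] != key[, 2], , drop = FALSE])
  out <- lapply(seq_len(nrow(pairs)), function(k)
    classify_strand_pair(pairs[k, 1], pairs[k, 2], hbmap, n))
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(chain_i = integer(0), chain_j = integer(0),
                      orientation = character(0),
                      registry_offset = integer(0), n_hbonds = integer(0)))
  do.call(rbind, lapply(out, as.data.frame))
}

#' Percentage of residues in beta-sheet structure
#'
#' See the module notes for the residue convention.
#'
#' @param state a `dmd_state`.
#' @return percentage in [0, 100].
#' @export
beta_sheet_fraction <- function(state) {
  hbmap <- hydrogen_bond_map(state)
  n <- nchar(state$topology$sequence)
  n_chains <- state$n_chains
  if (nrow(hbmap) == 0L) return(0)
  cls <- classify_all_pairs(state)
  if (nrow(cls) == 0L) return(0)
  beta <- matrix(FALSE, n_chains, n)
  for (k in seq_len(nrow(cls))) {
    ci <- cls$chain_i[k]; cj <- cls$chain_j[k]
    sel <- (hbmap$donor_chain == ci & hbmap$acceptor_chain == cj) |
      (hbmap$donor_chain == cj & hbmap$acceptor_chain == ci)
    for (r in seq_len(sum(sel))) {
      dch <- hbmap$donor_chain[sel][r]; dres <- hbmap$donor_res[sel][r]
      ach <- hbmap$acceptor_chain[sel][r]; ares <- hbmap$acceptor_res[sel][r]
      beta[dch, max(1L, dres - 1L):min(n, dres + 1L)] <- TRUE
      beta[ach, max(1L, ares - 1L):min(n, ares + 1L)] <- TRUE
    }
  }
  100 * mean(beta)
}

# residue label helper: position -> e.g. "F20" with a numbering offset
# (Abeta16-22 numbering uses offset 15: K16..E22)
.residue_label <- function(pos, sequence, numbering_offset = 15L) {
  paste0(substr(sequence, pos, pos), pos + numbering_offset)
}

.parse_residue_label <- function(label, sequence, numbering_offset = 15L) {
  if (is.numeric(label)) return(as.integer(label))
  num <- as.integer(sub("^[A-Z]", "", label))
  pos <- num - numbering_offset
  if (pos < 1L || pos > nchar(sequence))
    stop("focal residue ", label, " outside the sequence")
  if (substr(sequence, pos, pos) != substr(label, 1, 1))
    stop("focal residue label ", label, " does not match the sequence")
  pos
}

#' Nearest interpeptide sidechain contacts of a focal residue
#'
#' For every chain, the closest sidechain bead on any other chain to the
#' focal residue's sidechain bead is found (minimum image); it is counted
#' as a contact iff the pair sits inside its square well (or within 1.2x
#' the contact distance for zero-depth pairs).  Partner identities are
#' tallied.
#'
#' @param state a `dmd_state`.
#' @param focal residue position (1-based) or label such as `"F20"`
#'   (Abeta16-22 numbering, offset 15).
#' @param params an `sw_parameter_table`.
#' @param numbering_offset added to positions when forming labels.
#' @return named integer vector of contact counts per partner residue
#'   label, with attribute `"modal_partner"` (NA when no contacts).
#' @export
nearest_sidechain_contacts <- function(state, focal,
                                       params = default_parameter_table(),
                                       numbering_offset = 15L) {
  topo <- state$topology
  seqs <- topo$sequence
  pos_f <- .parse_residue_label(focal, seqs, numbering_offset)
  if (topo$sc_index[pos_f] == 0L) stop("focal residue has no sidechain bead")
  m <- topo$n_beads
  sc_res <- which(topo$sc_index > 0L)
  sc_local <- topo$sc_index[sc_res]
  L <- state$box_length
  counts <- integer(0)
  res_letters <- strsplit(seqs, "")[[1]]
  all_sc <- as.vector(outer(sc_local, (seq_len(state$n_chains) - 1L) * m, "+"))
  all_chain <- rep(seq_len(state$n_chains), each = length(sc_local))
  all_res <- rep(sc_res, state$n_chains)
  pos_all <- state$positions[all_sc, , drop = FALSE]
  for (ci in seq_len(state$n_chains)) {
    focal_bead <- (ci - 1L) * m + topo$sc_index[pos_f]
    other <- all_chain != ci
    d2 <- rowSums(.min_image(sweep(pos_all[other, , drop = FALSE], 2,
                                   state$positions[focal_bead, ]), L)^2)
    j <- which.min(d2)
    partner_res <- all_res[other][j]
    pp <- pair_potential(res_letters[pos_f], res_letters[partner_res], params)
    cutoff <- if (pp$well_depth > 0) pp$well_width else 1.2 * pp$contact_distance
    if (sqrt(d2[j]) <= cutoff) {
      lab <- .residue_label(partner_res, seqs, numbering_offset)
      counts[lab] <- (if (lab %in% names(counts)) counts[[lab]] else 0L) + 1L
    }
  }
  modal <- if (length(counts)) names(counts)[which.max(counts)] else NA_character_
  structure(counts, modal_partner = modal)
}

# inter-chain edges: any shared hydrogen bond, or any occupied attractive
# sidechain well (geometric)
.chain_edges <- function(state, params) {
  hbmap <- hydrogen_bond_map(state)
  edges <- cbind(hbmap$donor_chain, hbmap$acceptor_chain)
  topo <- state$topology
  m <- topo$n_beads
  sc_res <- which(topo$sc_index > 0L)
  sc_local <- topo$sc_index[sc_res]
  res_letters <- strsplit(topo$sequence, "")[[1]]
  all_sc <- as.vector(outer(sc_local, (seq_len(state$n_chains) - 1L) * m, "+"))
  all_chain <- rep(seq_len(state$n_chains), each = length(sc_local))
  all_res <- rep(sc_res, state$n_chains)
  pos <- state$positions[all_sc, , drop = FALSE]
  L <- state$box_length
  nsc <- length(all_sc)
  for (i in seq_len(nsc - 1L)) {
    js <- (i + 1L):nsc
    keep <- all_chain[js] != all_chain[i]
    if (!any(keep)) next
    js <- js[keep]
    d2 <- rowSums(.min_image(sweep(pos[js, , drop = FALSE], 2, pos[i, ]), L)^2)
    w <- params$pair_well_width[res_letters[all_res[i]], res_letters[all_res[js]]]
    dep <- params$pair_well_depth[res_letters[all_res[i]], res_letters[all_res[js]]]
    hit <- dep > 0 & d2 < w^2
    if (any(hit))
      edges <- rbind(edges, cbind(all_chain[i], all_chain[js][hit]))
  }
  edges
}

#' Cluster chains into oligomers
#'
#' Chains are graph nodes; edges join chains sharing at least one hydrogen
#' bond or one occupied attractive sidechain well.  Connected components
#' are returned with an order parameter: the fraction of edge-connected
#' chain pairs inside the cluster that form a classified (>= 2 H-bond)
#' strand pair.
#'
#' @param state a `dmd_state`.
#' @param params an `sw_parameter_table`.
#' @return list with `membership` (chain -> cluster id) and `clusters`
#'   (data.frame: cluster, size, n_classified_pairs, order_parameter).
#' @export
cluster_oligomers <- function(state, params = default_parameter_table()) {
  n_chains <- state$n_chains
  edges <- .chain_edges(state, params)
  g <- igraph::make_empty_graph(n = n_chains, directed = FALSE)
  if (nrow(edges)) {
    ue <- unique(t(apply(edges, 1, sort)))
    g <- igraph::add_edges(g, t(ue))
  }
  comp <- igraph::components(g)
  cls <- classify_all_pairs(state)
  cls_key <- if (nrow(cls)) paste(pmin(cls$chain_i, cls$chain_j),
                                  pmax(cls$chain_i, cls$chain_j)) else character(0)
  summaries <- lapply(seq_len(comp$no), function(k) {
    members <- which(comp$membership == k)
    sub_edges <- if (nrow(edges)) {
      ue <- unique(t(apply(edges, 1, sort)))
      ue[ue[, 1] %in% members & ue[, 2] %in% members, , drop = FALSE]
    } else matrix(integer(0), 0, 2)
    n_adj <- nrow(sub_edges)
    n_cls <- if (n_adj) sum(paste(sub_edges[, 1], sub_edges[, 2]) %in% cls_key)
    else 0L
    data.frame(cluster = k, size = length(members),
               n_classified_pairs = n_cls,
               order_parameter = if (n_adj) n_cls / n_adj else NA_real_)
  })
  list(membership = comp$membership, clusters = do.call(rbind, summaries))
}

#' Number of beta-sheet layers in an ordered cluster
#'
#' Within a cluster, chains connected by hydrogen bonds form one sheet
#' (layer); layers are stacked through sidechain-well adjacency.  The layer
#' count is the number of connected components of the hydrogen-bond-only
#' subgraph restricted to the cluster's chains.
#'
#' @param cluster_chains integer vector of chain ids in the cluster.
#' @param state a `dmd_state`.
#' @return integer >= 1.
#' @export
sheet_layer_count <- function(cluster_chains, state) {
  hbmap <- hydrogen_bond_map(state)
  sel <- hbmap$donor_chain %in% cluster_chains &
    hbmap$acceptor_chain %in% cluster_chains
  idx <- match(cluster_chains, cluster_chains)
  g <- igraph::make_empty_graph(n = length(cluster_chains), directed = FALSE)
  if (any(sel)) {
    e <- cbind(match(hbmap$donor_chain[sel], cluster_chains),
               match(hbmap$acceptor_chain[sel], cluster_chains))
    g <- igraph::add_edges(g, t(unique(t(apply(e, 1, sort)))))
  }
  igraph::components(g)$no
}

#' Energy and beta-content time series of a trajectory
#'
#' @param trajectory a [run_dmd()] result with at least 2 snapshots.
#' @return data.frame `(time, potential_energy, beta_percent)` of class
#'   `energy_profile`; potential energy in eps_HB units.
#' @export
energy_and_beta_timeseries <- function(trajectory) {
  stopifnot(length(trajectory$snapshots) >= 2L)
  beta <- vapply(trajectory$snapshots, beta_sheet_fraction, numeric(1))
  out <- data.frame(time = trajectory$times,
                    potential_energy = trajectory$potential_energy,
                    beta_percent = beta)
  class(out) <- c("energy_profile", "data.frame")
  out
}

#' Block-average a series
#'
#' @param x numeric vector.
#' @param block block size (default 10 snapshots).
#' @return vector of block means.
#' @export
block_average <- function(x, block = 10L) {
  nb <- floor(length(x) / block)
  if (nb < 1L) return(mean(x))
  vapply(seq_len(nb), function(k) mean(x[((k - 1L) * block + 1L):(k * block)]),
         numeric(1))
}
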