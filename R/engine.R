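# R-side engine interface: simulation configuration, marshalling of the
# dmd_state and parameter tables into the C++ event loop, and trajectory
# containers.

.TYPE_CODES <- c(NH = 0L, CA = 1L, CO = 2L, SC = 3L)

#' Simulation configuration
#'
#' @param n_peptides number of chains.
#' @param box_length cubic box edge (A); exactly one of `box_length` and
#'   `concentration` must be given.
#' @param concentration peptide concentration in mM.
#' @param tstar reduced temperature T* = k_B T / eps_HB (the study
#'   temperature for Abeta16-22 assembly is 0.193).
#' @param eps_hb hydrogen-bond well depth in kJ/mol (12.47), used only for
#'   unit conversion of reported energies.
#' @param thermostat_rate Andersen ghost-collision rate per bead per tau
#'   (0 = microcanonical).
#' @param max_events event budget.
#' @param max_time reduced-time budget.
#' @param snapshot_interval reduced time between snapshots.
#' @param seed integer RNG seed.
#' @param real_temperature_annotation informational real-temperature label
#'   in K (not used by the dynamics).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_peptides, box_length = NULL,
                              concentration = NULL, tstar = 0.193,
                              eps_hb = 12.47, thermostat_rate = 0.1,
                              max_events = 1e6, max_time = Inf,
                              snapshot_interval = 25, seed = 1L,
                              real_temperature_annotation = 326) {
  if (is.null(box_length) == is.null(concentration))
    stop("give exactly one of box_length and concentration")
  if (is.null(box_length)) box_length <- box_length_for(n_peptides, concentration)
  stopifnot(tstar > 0, n_peptides >= 1, box_length > 0)
  structure(list(n_peptides = n_peptides, box_length = box_length,
                 concentration = concentration_of(n_peptides, box_length),
                 tstar = tstar, eps_hb = eps_hb,
                 thermostat_rate = thermostat_rate,
                 max_events = max_events, max_time = max_time,
                 snapshot_interval = snapshot_interval, seed = as.integer(seed),
                 real_temperature_annotation = real_temperature_annotation),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("simulation_config: %d chains, box %.1f A (%.2f mM), ",
                     "T* = %.3f, thermostat %.3g /bead/tau, %.3g events\n"),
              x$n_peptides, x$box_length, x$concentration, x$tstar,
              x$thermostat_rate, x$max_events))
  invisible(x)
}

# build the per-bead aux-bead arrays for the directional HB test
.aux_arrays <- function(state) {
  topo <- state$topology
  m <- topo$n_beads
  nres <- nrow(topo$bb_index)
  n <- nrow(state$positions)
  aux1 <- rep(-1L, n); aux2 <- rep(-1L, n)
  for (b in seq_len(n)) {
    ty <- state$meta$type[b]
    if (ty != "NH" && ty != "CO") next
    r <- state$meta$residue[b]
    base <- (state$meta$chain[b] - 1L) * m
    aux1[b] <- base + topo$bb_index[r, "CA"] - 1L
    if (ty == "NH") {
      if (r > 1L) aux2[b] <- base + topo$bb_index[r - 1L, "CO"] - 1L
    } else {
      if (r < nres) aux2[b] <- base + topo$bb_index[r + 1L, "NH"] - 1L
    }
  }
  list(aux1 = aux1, aux2 = aux2)
}

#' Run the event-driven dynamics
#'
#' Advances a state with the DMD event loop: exact free flight between
#' analytically predicted events (hard cores, square-well edges, bond
#' walls, directional hydrogen bonding, Andersen ghost collisions), with
#' cell lists for neighbour pruning and periodic boundaries.  Identical
#' `(state, config)` including the seed reproduce the event sequence
#' exactly.
#'
#' @param state a `dmd_state` with velocities initialized.
#' @param config a [simulation_config()].
#' @param params an `sw_parameter_table`.
#' @param audit_interval events between from-scratch energy/overlap audits
#'   (0 disables).
#' @return object of class `dmd_trajectory`: snapshot states, time series
#'   of potential energy (eps_HB units), final state, event counts, audit
#'   results.
#' @export
run_dmd <- function(state, config, params = default_parameter_table(),
                    audit_interval = 1e5) {
  topo <- state$topology
  aux <- .aux_arrays(state)
  excl <- .pair_exclusions(topo)
  geo <- params$geometry
  type_code <- .TYPE_CODES[state$meta$type]
  res20 <- match(state$meta$res_letter, .aa_letters) - 1L
  res <- engine_run_cpp(
    pos0 = state$positions, vel0 = state$velocities,
    box = state$box_length,
    chain = state$meta$chain - 1L, resi = state$meta$residue,
    type = unname(type_code), res20 = res20,
    radius = state$meta$radius, mass = state$meta$mass,
    aux1 = aux$aux1, aux2 = aux$aux2,
    mchain = topo$n_beads,
    excl_code = excl$code, wall_min = excl$wall_min, wall_max = excl$wall_max,
    sw_width = params$pair_well_width, sw_depth = params$pair_well_depth,
    hb_width = params$hb_well_width, hb_core = params$hb_core,
    hb_depth = params$hb_well_depth, hb_aux = params$hb_aux_distance,
    hb_min_sep = geo$hb_min_res_sep, core_scale = geo$core_scale_near,
    hb_init = matrix(as.integer(state$hbonds) - 1L, ncol = 2),
    tstar = config$tstar, ghost_rate = config$thermostat_rate,
    max_events = config$max_events, max_time = config$max_time,
    snap_interval = config$snapshot_interval,
    audit_interval = audit_interval,
    seed = config$seed)
  if (isTRUE(res$error))
    stop("engine aborted: ", res$error_message)
  as_snap <- function(s) {
    st <- state
    st$positions <- s$positions
    st$velocities <- NULL
    st$clock <- s$time
    st$hbonds <- s$hbonds + 1L
    st$potential_energy <- s$potential_energy
    st
  }
  final <- state
  final$positions <- res$final_positions
  final$velocities <- res$final_velocities
  final$clock <- res$clock
  final$hbonds <- res$final_hbonds + 1L
  final$potential_energy <- res$final_potential_energy
  structure(list(
    times = res$times,
    potential_energy = res$potential_energy,
    kinetic_energy = res$kinetic_energy,
    snapshots = lapply(res$snapshots, as_snap),
    final_state = final,
    n_events = res$n_events,
    event_counts = res$event_counts,
    audit = list(max_energy_drift = res$max_energy_drift,
                 max_pe_error = res$max_pe_error,
                 max_overlap = res$max_overlap,
                 n_audits = res$n_audits),
    scheduler = list(n_push = res$n_push, n_pop = res$n_pop,
                     n_scan = res$n_scan, n_predict = res$n_predict),
    config = config), class = "dmd_trajectory")
}

#' @export
print.dmd_trajectory <- function(x, ...) {
  cat(sprintf("dmd_trajectory: %.3g events to t = %.1f tau, %d snapshots\n",
              x$n_events, x$final_state$clock, length(x$snapshots)))
  cat(sprintf("  final PE %.2f eps_HB, %d H-bonds; max |dE| %.2e, max overlap %.2e\n",
              x$final_state$potential_energy, nrow(x$final_state$hbonds),
              x$audit$max_energy_drift, x$audit$max_overlap))
  invisible(x)
}

#' Predict the next event for an isolated bead pair
#'
#' Exposes the engine's analytic event prediction for a single pair with a
#' hard core and (optionally) a square well: the earliest root of
#' `|r_ij + v_ij t| = d` over the pair's discontinuity distances `d`.
#'
#' @param ri,vi,rj,vj position/velocity 3-vectors.
#' @param core hard-core contact distance.
#' @param well square-well width (0 = hard sphere only).
#' @param depth well depth (eps_HB).
#' @param occupied is the pair currently inside the well?
#' @param box periodic box edge (0 = open boundaries).
#' @return list `(kind, time)`; `kind = "none"` with time `NA` when no
#'   event will occur.
#' @export
predict_pair_event <- function(ri, vi, rj, vj, core, well = 0, depth = 0,
                               occupied = FALSE, box = 0) {
  pair_event_cpp(as.numeric(ri), as.numeric(vi), as.numeric(rj),
                 as.numeric(vj), core, well, depth, occupied, box)
}

#' One-call self-assembly simulation
#'
#' Builds a random monomer gas at the configured concentration, draws
#' Maxwell-Boltzmann velocities, and runs the event loop.
#'
#' @param config a [simulation_config()].
#' @param sequence peptide sequence (default the Abeta16-22 heptapeptide).
#' @param params parameter table.
#' @param audit_interval see [run_dmd()].
#' @return a `dmd_trajectory`.
#' @export
simulate_assembly <- function(config, sequence = "KLVFFAE",
                              params = default_parameter_table(),
                              audit_interval = 1e5) {
  topo <- build_topology(sequence, params = params)
  state <- random_initial_configuration(config$n_peptides, config$box_length,
                                        topo, seed = config$seed)
  state <- init_velocities(state, config$tstar, seed = config$seed + 1L)
  run_dmd(state, config, params, audit_interval = audit_interval)
}
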