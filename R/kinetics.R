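# Qualitative assembly-kinetics checks on energy/beta time series.
#
# These operationalize the two hallmarks of the full-scale assembly runs
# at desk scale: (a) the beta-sheet residue percentage rises monotonically
# (on a smoothed time axis) from zero to a substantial plateau, and (b)
# the system potential energy decays in two phases - an initial fast
# (nucleation/collapse) phase followed by a slower ordering phase.  The
# thresholds are fixed conventions of the package, chosen from the physics
# (block-mean noise of a ~25-chain system is a few percent beta; a
# "substantial" rise is more than 15 percentage points; a late phase is
# "slow" when its mean decay rate is below half the steepest block rate).

#' Monotone smoothed rise of the beta-sheet fraction
#'
#' @param profile an [energy_and_beta_timeseries()] table.
#' @param block snapshots per smoothing block.
#' @param dip_tol maximum allowed block-to-block drop (percentage points).
#' @param min_rise required overall rise (percentage points).
#' @param max_start maximum starting block value (percent).
#' @return logical; details as attribute `"detail"`.
#' @export
check_monotone_rise <- function(profile, block = 10L, dip_tol = 2,
                                min_rise = 15, max_start = 5) {
  b <- block_average(profile$beta_percent, block)
  ok_start <- b[1] <= max_start
  ok_rise <- (b[length(b)] - b[1]) >= min_rise
  ok_mono <- all(diff(b) >= -dip_tol)
  structure(ok_start && ok_rise && ok_mono,
            detail = list(blocks = b, ok_start = ok_start,
                          ok_rise = ok_rise, ok_monotone = ok_mono))
}

#' Fast-then-slow two-phase potential-energy decay
#'
#' The decay is two-phase when the energy drops substantially overall and
#' the mean decay rate over the final quarter of the run is less than half
#' the steepest block-to-block rate.
#'
#' @param profile an [energy_and_beta_timeseries()] table.
#' @param block snapshots per smoothing block.
#' @param min_drop required total energy drop (eps_HB).
#' @param slow_factor late-phase rate must be below this fraction of the
#'   steepest rate.
#' @return logical; details as attribute `"detail"`.
#' @export
check_two_phase_decay <- function(profile, block = 10L, min_drop = 10,
                                  slow_factor = 0.5) {
  e <- block_average(profile$potential_energy, block)
  nb <- length(e)
  drop <- e[1] - e[nb]
  rates <- -diff(e)                      # positive = decaying
  steepest <- max(rates)
  q4 <- e[max(1L, floor(3 * nb / 4)):nb]
  late_rate <- (q4[1] - q4[length(q4)]) / max(1L, length(q4) - 1L)
  ok <- drop >= min_drop && steepest > 0 && late_rate < slow_factor * steepest
  structure(ok, detail = list(blocks = e, total_drop = drop,
                              steepest = steepest, late_rate = late_rate))
}

#' Reference desk-scale assembly conditions
#'
#' The scaled stand-in for the full assembly runs: 24 chains of
#' Ac-KLVFFAE-NH2 at 10 mM and T* = 0.193 with weak Andersen coupling
#' (0.002 ghosts per bead per tau) for 2.5e7 events.  Kept in one place so
#' tests, scripts and the vignette run the same conditions.
#'
#' @param seed RNG seed.
#' @param max_events event budget.
#' @return a [simulation_config()].
#' @export
assembly_proxy_config <- function(seed = 1L, max_events = 2.5e7) {
  simulation_config(n_peptides = 24, concentration = 10, tstar = 0.193,
                    thermostat_rate = 0.002, max_events = max_events,
                    snapshot_interval = 100, seed = seed)
}
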