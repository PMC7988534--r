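# File interfaces: multi-frame XYZ snapshots, tab-separated time series
# and analysis tables, flat key-value simulation configs, JSON provenance
# and text checkpoints.

#' Write a state (or trajectory) as (multi-frame) XYZ
#'
#' One pseudo-atom per bead; the atom name encodes bead type and the
#' comment line carries time, box edge and chain count.  Chain identity is
#' preserved through bead order (chains are contiguous blocks).
#'
#' @param x a `dmd_state` or `dmd_trajectory`.
#' @param path output file.
#' @export
write_xyz <- function(x, path) {
  states <- if (inherits(x, "dmd_trajectory")) x$snapshots else list(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (st in states) {
    n <- nrow(st$positions)
    writeLines(as.character(n), con)
    writeLines(sprintf("t=%.6f box=%.4f chains=%d", st$clock, st$box_length,
                       st$n_chains), con)
    writeLines(sprintf("%s %.4f %.4f %.4f",
                       ifelse(st$meta$type == "SC",
                              paste0("S", st$meta$res_letter), st$meta$type),
                       st$positions[, 1], st$positions[, 2],
                       st$positions[, 3]), con)
  }
  invisible(path)
}

#' Write a trajectory's energy/beta time series as tab-separated text
#'
#' @param trajectory a `dmd_trajectory`.
#' @param path output file.
#' @return the [energy_and_beta_timeseries()] table, invisibly.
#' @export
write_timeseries <- function(trajectory, path) {
  ts <- energy_and_beta_timeseries(trajectory)
  utils::write.table(ts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ts)
}

#' Write per-snapshot nearest-contact tallies
#'
#' @param trajectory a `dmd_trajectory`.
#' @param focal character vector of focal residues (e.g. `c("F19","F20")`).
#' @param path output file.
#' @param params parameter table.
#' @return long data.frame `(time, focal, partner, count)`, invisibly
#'   written as TSV.
#' @export
write_contact_series <- function(trajectory, focal, path,
                                 params = default_parameter_table()) {
  rows <- list()
  for (s in seq_along(trajectory$snapshots)) {
    st <- trajectory$snapshots[[s]]
    for (f in focal) {
      ct <- nearest_sidechain_contacts(st, f, params)
      if (length(ct))
        rows[[length(rows) + 1L]] <- data.frame(
          time = st$clock, focal = f, partner = names(ct),
          count = as.integer(ct))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time = numeric(0), focal = character(0),
               partner = character(0), count = integer(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Read a flat key-value simulation config file
#'
#' Lines of the form `key value` (# comments allowed) mirroring the
#' [simulation_config()] fields.
#'
#' @param path config file.
#' @return a `simulation_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    kv[[f[1]]] <- utils::type.convert(f[2], as.is = TRUE)
  }
  do.call(simulation_config, kv)
}

#' Write provenance JSON for a prepared system
#'
#' @param config a `simulation_config`.
#' @param path output file.
#' @param extra named list merged into the record.
#' @export
write_provenance <- function(config, path, extra = list()) {
  rec <- c(unclass(config),
           list(package = "pepdmd",
                package_version = as.character(utils::packageVersion("pepdmd"))),
           extra)
  rec$max_time <- if (is.finite(rec$max_time)) rec$max_time else "Inf"
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Text checkpoint of a full state
#'
#' JSON with positions, velocities, hydrogen bonds, clock and box; exact
#' round-trip through [read_checkpoint()] given the same topology.
#'
#' @param state a `dmd_state`.
#' @param path output file.
#' @export
write_checkpoint <- function(state, path) {
  rec <- list(box_length = state$box_length, clock = state$clock,
              n_chains = state$n_chains,
              sequence = state$topology$sequence,
              positions = state$positions,
              velocities = state$velocities,
              hbonds = state$hbonds)
  jsonlite::write_json(rec, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @param topology the `peptide_topology` the checkpoint was written with.
#' @export
read_checkpoint <- function(path, topology) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (rec$sequence != topology$sequence)
    stop("checkpoint sequence does not match the supplied topology")
  st <- .make_state(matrix(rec$positions, ncol = 3), topology,
                    rec$n_chains, rec$box_length,
                    hbonds = matrix(as.integer(rec$hbonds), ncol = 2))
  st$velocities <- matrix(rec$velocities, ncol = 3)
  st$clock <- rec$clock
  st
}
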