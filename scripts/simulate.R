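#!/usr/bin/env Rscript
# Thin shell front-end over the simulator:
#   Rscript scripts/simulate.R --config <file> --seed N --out <dir>
# The config file is a flat key-value format mirroring simulation_config();
# outputs: multi-frame XYZ trajectory, tab-separated energy/beta series,
# contact tallies for F19/F20, and a provenance JSON.

suppressMessages(library(pepdmd))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) && i < length(args)) args[i + 1] else default
}
config_file <- get_arg("--config")
seed <- get_arg("--seed")
outdir <- get_arg("--out", "simulation_out")
if (is.null(config_file)) stop("usage: simulate.R --config <file> [--seed N] [--out dir]")

cfg <- read_config(config_file)
if (!is.null(seed)) cfg$seed <- as.integer(seed)
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

message(sprintf("simulating %d chains at %.2f mM, T* = %.3f, seed %d",
                cfg$n_peptides, cfg$concentration, cfg$tstar, cfg$seed))
traj <- simulate_assembly(cfg)

write_xyz(traj, file.path(outdir, "trajectory.xyz"))
write_timeseries(traj, file.path(outdir, "timeseries.tsv"))
write_contact_series(traj, c("F19", "F20"),
                     file.path(outdir, "contacts.tsv"))
write_checkpoint(traj$final_state, file.path(outdir, "final_state.json"))
write_provenance(cfg, file.path(outdir, "provenance.json"),
                 extra = list(n_events = traj$n_events,
                              final_clock = traj$final_state$clock))
message("wrote ", outdir)
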