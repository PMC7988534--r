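# Independent oracles used across the suite.

# monoisotopic element masses, independent of the package's internal table
ORACLE_EL <- c(H = 1.00782503, C = 12.0, N = 14.00307401, O = 15.99491462,
               S = 31.97207069, F = 18.99840322)

# element-composition mass oracle: counts is a named vector
oracle_mass <- function(counts) sum(ORACLE_EL[names(counts)] * counts)

# residue compositions written out independently (counts of C,H,N,O,S)
ORACLE_RES <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),  A = c(C = 3, H = 5, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),  L = c(C = 6, H = 11, N = 1, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),  S = c(C = 3, H = 5, N = 1, O = 2),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1))

# neutral monoisotopic mass of a capped peptide, assembled element by
# element: sum of residue formulas + H (N-term) + OH (C-term), with
# acetyl = +C2H2O and amide = -O +N +H applied on top
oracle_peptide_mass <- function(seq_letters, acetyl = FALSE, amide = FALSE) {
  tot <- c(C = 0, H = 1, N = 0, O = 1, S = 0, F = 0)  # H- and -OH caps
  tot["H"] <- tot["H"] + 1
  for (r in seq_letters) {
    rc <- ORACLE_RES[[r]]
    for (e in names(rc)) tot[e] <- tot[e] + rc[[e]]
  }
  if (acetyl) { tot["C"] <- tot["C"] + 2; tot["H"] <- tot["H"] + 2; tot["O"] <- tot["O"] + 1 }
  if (amide) { tot["O"] <- tot["O"] - 1; tot["N"] <- tot["N"] + 1; tot["H"] <- tot["H"] + 1 }
  oracle_mass(tot[tot != 0])
}

# brute-force first-crossing time of |d + v t| = R: fine time stepping
# (vectorized grid scan) plus bisection refinement; returns NA if no
# crossing before t_max
oracle_crossing_time <- function(d0, v, R, t_max = 50, dt = 1e-4) {
  f <- function(t) sqrt((d0[1] + v[1] * t)^2 + (d0[2] + v[2] * t)^2 +
                          (d0[3] + v[3] * t)^2) - R
  s0 <- sign(f(0))
  chunk <- 5e4
  t_lo <- 0
  lo <- NA_real_; hi <- NA_real_
  while (t_lo < t_max) {
    t_hi <- min(t_lo + chunk * dt, t_max)
    tg <- seq(t_lo, t_hi, by = dt)
    s <- sign(f(tg))
    flip <- which(s != s0)
    if (length(flip)) {
      lo <- tg[flip[1] - 1L]; hi <- tg[flip[1]]
      break
    }
    t_lo <- t_hi
  }
  if (is.na(lo)) return(NA_real_)
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == s0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

topo_klvffae <- function() build_topology("KLVFFAE")

# random two-bead configuration for oracle comparisons: mostly approaching
# pairs (so events actually occur), with transverse components providing
# grazing/miss cases; uses the caller's RNG stream
sample_pair_config <- function() {
  ri <- runif(3, -4, 4)
  dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
  core <- runif(1, 2, 4)
  well <- core + runif(1, 1, 3)
  sep <- runif(1, core + 0.1, 12)
  rj <- ri + dir * sep
  vi <- rnorm(3, 0, 0.3)
  # radial approach speed plus transverse noise (some cases recede)
  vj <- vi - dir * runif(1, -0.2, 1.2) + rnorm(3, 0, 0.25)
  list(ri = ri, vi = vi, rj = rj, vj = vj, core = core, well = well,
       occupied = sep < well)
}
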