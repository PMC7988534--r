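# Coarse-grained peptide representation in the PRIME20 style: three
# backbone beads (NH, CaH, CO) plus one sidechain bead per residue (none
# for glycine), near-rigid bonds/pseudobonds with hard walls at +/-2% of
# the nominal length, square-well sidechain interactions and a directional
# square-well backbone hydrogen bond.
#
# All geometry defaults live in .geometry_defaults below; they are model
# conventions (documented in the methods vignette), not published values.

.BOND_TOL <- 0.02  # hard walls at nominal * (1 -/+ .BOND_TOL)

.geometry_defaults <- local({
  # sidechain bead diameters (A) and CaH-SC bond lengths (A), loosely
  # proportional to residue volume
  sc_d <- c(A = 3.4, S = 3.6, C = 3.7, T = 3.8, P = 3.9, V = 4.0, N = 4.0,
            D = 4.0, L = 4.3, I = 4.3, Q = 4.2, E = 4.0, M = 4.3, K = 4.4,
            H = 4.3, F = 4.4, R = 4.6, Y = 4.5, W = 4.7)
  sc_h <- c(A = 1.6, S = 1.7, C = 1.8, T = 1.9, P = 1.9, V = 2.0, N = 2.1,
            D = 2.1, L = 2.4, I = 2.4, Q = 2.4, E = 2.5, M = 2.6, K = 2.9,
            H = 2.5, F = 2.5, R = 3.1, Y = 2.8, W = 2.9)
  list(
    backbone_diameter = c(NH = 3.3, CA = 3.7, CO = 3.5),
    sc_diameter = sc_d,
    sc_bond = sc_h,
    bond_n_ca = 1.25,   # NH-CaH
    bond_ca_c = 1.25,   # CaH-CO
    bond_c_n = 1.30,    # CO-NH(next)
    ca_ca = 3.80,       # CaH-CaH virtual spacing along an extended strand
    bond_tol = .BOND_TOL,
    core_scale_near = 0.75,  # hard-core scaling for pairs <=3 bonds apart
    hb_well_width = 5.0,     # NH...CO square-well diameter (A)
    hb_core = 2.6,           # reduced NH-CO hard core (A)
    hb_depth = 1.0,          # eps_HB units by definition
    hb_aux_distance = 4.6,   # auxiliary-bead exclusion distance (A)
    hb_min_res_sep = 3L      # intra-chain |i-j| below which HB is ineligible
  )
})

.EPS_HB_KJMOL <- 12.47  # hydrogen-bond well depth in kJ/mol

#' Energy unit conversions
#'
#' Potential energies are bookkept in units of the hydrogen-bond well depth
#' eps_HB; these helpers convert to/from kJ/mol (eps_HB = 12.47 kJ/mol).
#'
#' @param e energy value(s).
#' @param eps_hb well depth in kJ/mol.
#' @return converted energy.
#' @export
eps_to_kjmol <- function(e, eps_hb = .EPS_HB_KJMOL) e * eps_hb

#' @rdname eps_to_kjmol
#' @export
kjmol_to_eps <- function(e, eps_hb = .EPS_HB_KJMOL) e / eps_hb

# ---- parameter table -------------------------------------------------------

# Hydrophobic interaction weights used by the bundled default table.  The
# published PRIME20 scheme (210 widths / 19 depths, fit to PDB native
# states) is not printed in the literature this model follows; the default
# table is an explicit approximation: mutually attractive hydrophobics,
# K/R-D/E salt bridges, hard-sphere-only like-charge pairs, zero otherwise.
.hydrophobic_weight <- c(A = 0.35, V = 0.55, L = 0.65, I = 0.65, M = 0.60,
                         F = 1.00, W = 1.00, Y = 0.70, P = 0.30)
.positive_res <- c("K", "R")
.negative_res <- c("D", "E")
.SW_HYDRO_SCALE <- 0.30   # depth of F-F in eps_HB units
.SW_SALT_DEPTH <- 0.30    # opposite-charge well depth
.SW_WELL_PAD <- 1.6       # well width = contact distance + pad (A)

#' The bundled default square-well parameter table
#'
#' Builds the package's default interaction table: symmetric sidechain
#' square-well widths/depths for all 210 unordered residue pairs, the
#' hydrogen-bond well parameters, and bead geometry.  Depths follow a
#' simple documented scheme (geometric-mean hydrophobic attraction scaled
#' to 0.30 eps_HB for F-F, 0.30 eps_HB salt bridges, zero elsewhere) and do
#' not claim to reproduce any published parameter set.
#'
#' @return object of class `sw_parameter_table`.
#' @export
default_parameter_table <- function() {
  aa <- .aa_letters
  geo <- .geometry_defaults
  n <- length(aa)
  width <- matrix(NA_real_, n, n, dimnames = list(aa, aa))
  depth <- matrix(0, n, n, dimnames = list(aa, aa))
  scd <- function(r) if (r == "G") NA_real_ else geo$sc_diameter[[r]]
  for (i in seq_len(n)) {
    for (j in i:n) {
      ri <- aa[i]; rj <- aa[j]
      if (ri == "G" || rj == "G") {
        width[i, j] <- width[j, i] <- 0
        next
      }
      contact <- (scd(ri) + scd(rj)) / 2
      width[i, j] <- width[j, i] <- contact + .SW_WELL_PAD
      d <- 0
      if (ri %in% names(.hydrophobic_weight) &&
          rj %in% names(.hydrophobic_weight)) {
        d <- .SW_HYDRO_SCALE *
          sqrt(.hydrophobic_weight[[ri]] * .hydrophobic_weight[[rj]])
      } else if ((ri %in% .positive_res && rj %in% .negative_res) ||
                 (ri %in% .negative_res && rj %in% .positive_res)) {
        d <- .SW_SALT_DEPTH
      }
      depth[i, j] <- depth[j, i] <- d
    }
  }
  structure(list(
    version = 1L,
    residues = aa,
    pair_well_width = width,
    pair_well_depth = depth,
    hb_well_width = geo$hb_well_width,
    hb_well_depth = geo$hb_depth,
    hb_core = geo$hb_core,
    hb_aux_distance = geo$hb_aux_distance,
    geometry = geo
  ), class = "sw_parameter_table")
}

.validate_parameter_table <- function(tab) {
  aa <- tab$residues
  w <- tab$pair_well_width
  d <- tab$pair_well_depth
  for (i in seq_along(aa)) for (j in seq_along(aa)) {
    ri <- aa[i]; rj <- aa[j]
    if (is.na(w[i, j]))
      stop("missing pair entry: ", ri, "-", rj)
    if (w[i, j] != w[j, i] || d[i, j] != d[j, i])
      stop("asymmetric entries for pair ", ri, "-", rj)
    if (ri != "G" && rj != "G") {
      if (w[i, j] <= 0) stop("non-positive well width for pair ", ri, "-", rj)
      contact <- (tab$geometry$sc_diameter[[ri]] +
                    tab$geometry$sc_diameter[[rj]]) / 2
      if (w[i, j] < contact)
        stop("well width below contact distance for pair ", ri, "-", rj)
    }
    if (d[i, j] < 0) stop("negative well depth for pair ", ri, "-", rj)
  }
  invisible(tab)
}

#' Square-well triple for a sidechain pair
#'
#' @param residue_i,residue_j one-letter residue types.
#' @param table an `sw_parameter_table`.
#' @return list `(contact_distance, well_width, well_depth)`; depth > 0
#'   means an attractive well of energy -depth (eps_HB units) between the
#'   contact distance and the well width; depth 0 is hard-sphere only.
#' @export
pair_potential <- function(residue_i, residue_j, table = default_parameter_table()) {
  for (r in c(residue_i, residue_j)) {
    if (!r %in% table$residues) stop("unknown residue type: ", r)
    if (r == "G") stop("glycine has no sidechain bead")
  }
  contact <- (table$geometry$sc_diameter[[residue_i]] +
                table$geometry$sc_diameter[[residue_j]]) / 2
  list(contact_distance = contact,
       well_width = table$pair_well_width[residue_i, residue_j],
       well_depth = table$pair_well_depth[residue_i, residue_j])
}

# ---- parameter file I/O ----------------------------------------------------

#' Write a parameter table to the documented text format
#'
#' One record per line: `PAIR <res1> <res2> <width_A> <depth_epsHB>` for the
#' 210 unordered residue pairs, `HB <width> <depth> <core> <aux_distance>`,
#' and `GEOM` records for bead diameters and bond lengths; `#` comments and
#' a `VERSION` header.
#'
#' @param table an `sw_parameter_table`.
#' @param path output file path.
#' @export
write_parameter_table <- function(table, path) {
  geo <- table$geometry
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# pepdmd square-well parameter table")
  w("# Approximate default set: hydrophobics mutually attractive, K/R-D/E")
  w("# salt bridges, like charges hard-sphere only; widths = contact + %.2f A.",
    .SW_WELL_PAD)
  w("VERSION %d", table$version)
  w("HB %.4f %.4f %.4f %.4f", table$hb_well_width, table$hb_well_depth,
    table$hb_core, table$hb_aux_distance)
  for (b in names(geo$backbone_diameter))
    w("GEOM BEAD %s %.4f", b, geo$backbone_diameter[[b]])
  for (r in names(geo$sc_diameter))
    w("GEOM SC %s %.4f %.4f", r, geo$sc_diameter[[r]], geo$sc_bond[[r]])
  w("GEOM BOND N_CA %.4f", geo$bond_n_ca)
  w("GEOM BOND CA_C %.4f", geo$bond_ca_c)
  w("GEOM BOND C_N %.4f", geo$bond_c_n)
  w("GEOM BOND CA_CA %.4f", geo$ca_ca)
  w("GEOM TOL %.4f", geo$bond_tol)
  aa <- table$residues
  # all 210 unordered pairs of the 20 residue types; glycine carries no
  # sidechain bead, so its records are zero-width placeholders
  for (i in seq_along(aa)) for (j in i:length(aa)) {
    w("PAIR %s %s %.6f %.6f", aa[i], aa[j],
      table$pair_well_width[i, j], table$pair_well_depth[i, j])
  }
  invisible(path)
}

#' Load a square-well parameter table
#'
#' Reads the documented key-value text format (see
#' [write_parameter_table()]); validates symmetry, completeness and
#' positivity, naming the first missing pair on failure.
#'
#' @param path file path; defaults to the bundled table.
#' @return `sw_parameter_table`.
#' @export
load_parameter_table <- function(path = system.file("extdata",
                                                    "sw_params_v1.txt",
                                                    package = "pepdmd")) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  tab <- default_parameter_table()  # geometry scaffold; PAIR/HB overwritten
  aa <- tab$residues
  tab$pair_well_width[,] <- NA_real_
  tab$pair_well_depth[,] <- NA_real_
  g <- which(aa == "G")
  tab$pair_well_width[g, ] <- tab$pair_well_width[, g] <- 0
  tab$pair_well_depth[g, ] <- tab$pair_well_depth[, g] <- 0
  seen <- matrix(FALSE, length(aa), length(aa), dimnames = list(aa, aa))
  for (ln in lines) {
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    kind <- f[1]
    if (kind == "VERSION") {
      tab$version <- as.integer(f[2])
    } else if (kind == "HB") {
      tab$hb_well_width <- as.numeric(f[2])
      tab$hb_well_depth <- as.numeric(f[3])
      tab$hb_core <- as.numeric(f[4])
      tab$hb_aux_distance <- as.numeric(f[5])
    } else if (kind == "GEOM") {
      sub_kind <- f[2]
      if (sub_kind == "BEAD") {
        tab$geometry$backbone_diameter[[f[3]]] <- as.numeric(f[4])
      } else if (sub_kind == "SC") {
        tab$geometry$sc_diameter[[f[3]]] <- as.numeric(f[4])
        tab$geometry$sc_bond[[f[3]]] <- as.numeric(f[5])
      } else if (sub_kind == "BOND") {
        key <- c(N_CA = "bond_n_ca", CA_C = "bond_ca_c",
                 C_N = "bond_c_n", CA_CA = "ca_ca")[[f[3]]]
        tab$geometry[[key]] <- as.numeric(f[4])
      } else if (sub_kind == "TOL") {
        tab$geometry$bond_tol <- as.numeric(f[3])
      } else stop("unknown GEOM record: ", ln)
    } else if (kind == "PAIR") {
      ri <- f[2]; rj <- f[3]
      if (!ri %in% aa || !rj %in% aa) stop("unknown residue in PAIR: ", ln)
      wv <- as.numeric(f[4]); dv <- as.numeric(f[5])
      glyc <- ri == "G" || rj == "G"
      if (!glyc && wv <= 0) stop("non-positive width in PAIR: ", ln)
      if (glyc && (wv != 0 || dv != 0))
        stop("glycine has no sidechain bead; PAIR must be zero: ", ln)
      if (seen[ri, rj] && (tab$pair_well_width[ri, rj] != wv ||
                           tab$pair_well_depth[ri, rj] != dv))
        stop("conflicting duplicate PAIR entry: ", ri, "-", rj)
      tab$pair_well_width[ri, rj] <- tab$pair_well_width[rj, ri] <- wv
      tab$pair_well_depth[ri, rj] <- tab$pair_well_depth[rj, ri] <- dv
      seen[ri, rj] <- seen[rj, ri] <- TRUE
    } else stop("unknown record: ", ln)
  }
  .validate_parameter_table(tab)
  tab
}

#' @export
print.sw_parameter_table <- function(x, ...) {
  nonG <- setdiff(x$residues, "G")
  npair <- length(nonG) * (length(nonG) + 1) / 2 + length(x$residues)
  cat(sprintf("square-well parameter table v%d: %d residue types\n",
              x$version, length(x$residues)))
  cat(sprintf("  HB well %.2f A, depth %.2f eps_HB, core %.2f A, aux %.2f A\n",
              x$hb_well_width, x$hb_well_depth, x$hb_core, x$hb_aux_distance))
  cat(sprintf("  %d attractive sidechain pairs (max depth %.3f eps_HB)\n",
              sum(x$pair_well_depth[upper.tri(x$pair_well_depth, diag = TRUE)] > 0),
              max(x$pair_well_depth)))
  invisible(x)
}

# ---- topology --------------------------------------------------------------

# backbone united-atom masses (Da): NH = N+H, CaH = C+H, CO = C+O;
# glycine's second alpha hydrogen is folded into its CaH bead.
.BB_MASS <- c(NH = 15.0109, CA = 13.0078, CO = 27.9949)

#' Build the coarse-grained topology of a peptide chain
#'
#' Every non-glycine residue contributes four beads (NH, CaH, CO, SC) and
#' glycine three; bonds and pseudobonds carry hard walls at +/-2% of the
#' nominal length taken from the geometry table.  Sidechain bead masses are
#' the residue mass minus the shared backbone mass; a modification adds its
#' mass delta to the modified sidechain bead (the simulation otherwise
#' treats a TFMD-modified Phe as plain Phe).
#'
#' @param sequence one-letter residue string.
#' @param modifications list of `list(position =, id =)`.
#' @param params an `sw_parameter_table` (geometry source).
#' @return object of class `peptide_topology` with `beads`, `bonds`,
#'   `pseudobonds` data.frames and `n_beads`.
#' @export
build_topology <- function(sequence, modifications = list(),
                           params = default_parameter_table()) {
  res <- strsplit(sequence, "")[[1]]
  if (!length(res)) stop("empty sequence")
  bad <- setdiff(res, .aa_letters)
  if (length(bad)) stop("unknown residue letter(s): ",
                        paste(unique(bad), collapse = ", "))
  mod_by_pos <- list()
  for (m in modifications) {
    mod <- get_modification(m$id)
    if (m$position < 1 || m$position > length(res))
      stop("modification position out of range: ", m$position)
    if (res[m$position] != mod$attaches_to)
      stop(sprintf("modification %s attaches to %s, not %s",
                   mod$id, mod$attaches_to, res[m$position]))
    mod_by_pos[[as.character(m$position)]] <- mod
  }
  geo <- params$geometry
  rmass <- residue_masses("mono")
  beads <- list(); k <- 0L
  sc_index <- integer(length(res))  # bead index of each residue's SC (0 = none)
  bb_index <- matrix(0L, nrow = length(res), ncol = 3,
                     dimnames = list(NULL, c("NH", "CA", "CO")))
  for (i in seq_along(res)) {
    r <- res[i]
    ca_mass <- .BB_MASS[["CA"]] + if (r == "G") .H_mono else 0
    for (b in c("NH", "CA", "CO")) {
      k <- k + 1L
      bb_index[i, b] <- k
      beads[[k]] <- data.frame(
        label = if (b == "CA") "CaH" else b, type = b, residue = i,
        res_letter = r,
        diameter = geo$backbone_diameter[[b]],
        mass = if (b == "CA") ca_mass else .BB_MASS[[b]])
    }
    if (r != "G") {
      k <- k + 1L
      sc_index[i] <- k
      sc_mass <- rmass[[r]] - sum(.BB_MASS)
      mod <- mod_by_pos[[as.character(i)]]
      mod_id <- NA_character_
      if (!is.null(mod)) {
        sc_mass <- sc_mass + mod$mass_delta_mono
        mod_id <- mod$id
      }
      beads[[k]] <- data.frame(
        label = paste0("SC-", r), type = "SC", residue = i, res_letter = r,
        diameter = geo$sc_diameter[[r]], mass = sc_mass)
      beads[[k]]$modification <- mod_id
    } else {
      # keep columns aligned
    }
  }
  beads <- do.call(rbind, lapply(beads, function(b) {
    if (is.null(b$modification)) b$modification <- NA_character_
    b
  }))
  rownames(beads) <- NULL
  tol <- geo$bond_tol
  bond <- function(i, j, nominal) data.frame(
    i = i, j = j, nominal = nominal,
    min = nominal * (1 - tol), max = nominal * (1 + tol))
  bonds <- list(); pseudo <- list()
  for (i in seq_along(res)) {
    nh <- bb_index[i, "NH"]; ca <- bb_index[i, "CA"]; co <- bb_index[i, "CO"]
    bonds <- c(bonds, list(bond(nh, ca, geo$bond_n_ca),
                           bond(ca, co, geo$bond_ca_c)))
    pseudo <- c(pseudo, list(bond(nh, co, geo$bond_n_ca + geo$bond_ca_c)))
    if (sc_index[i] > 0L) {
      h <- geo$sc_bond[[res[i]]]
      arm <- sqrt(geo$bond_n_ca^2 + h^2)  # NH/CO to SC, fixing the SC cone
      bonds <- c(bonds, list(bond(ca, sc_index[i], h)))
      pseudo <- c(pseudo, list(bond(nh, sc_index[i], arm),
                               bond(co, sc_index[i], arm)))
    }
    if (i < length(res)) {
      nh2 <- bb_index[i + 1L, "NH"]; ca2 <- bb_index[i + 1L, "CA"]
      bonds <- c(bonds, list(bond(co, nh2, geo$bond_c_n)))
      # trans-planarity of the peptide unit: Ca-Ca spacing plus the two
      # diagonals of the Ca(i)-CO(i)-NH(i+1)-Ca(i+1) quadrilateral
      pseudo <- c(pseudo, list(
        bond(ca, ca2, geo$ca_ca),
        bond(ca, nh2, geo$bond_ca_c + geo$bond_c_n),
        bond(co, ca2, geo$bond_c_n + geo$bond_n_ca)))
    }
  }
  bonds <- do.call(rbind, bonds)
  pseudo <- do.call(rbind, pseudo)
  structure(list(sequence = sequence, modifications = modifications,
                 beads = beads, bonds = bonds, pseudobonds = pseudo,
                 bb_index = bb_index, sc_index = sc_index,
                 n_beads = nrow(beads), params = params),
            class = "peptide_topology")
}

#' Reference extended conformation of a chain
#'
#' Places the chain in the canonical extended (all-trans) geometry that the
#' bond and pseudobond nominal lengths are derived from: backbone beads on
#' a line with CaH spacing 3.8 A, sidechain beads alternating above/below
#' the backbone.  All bonds sit exactly at their nominal lengths.
#'
#' @param topology a `peptide_topology`.
#' @return n_beads x 3 coordinate matrix (A).
#' @export
reference_conformation <- function(topology) {
  geo <- topology$params$geometry
  res <- strsplit(topology$sequence, "")[[1]]
  pos <- matrix(0, topology$n_beads, 3)
  for (i in seq_along(res)) {
    x0 <- geo$ca_ca * (i - 1)
    pos[topology$bb_index[i, "NH"], ] <- c(x0 - geo$bond_n_ca, 0, 0)
    pos[topology$bb_index[i, "CA"], ] <- c(x0, 0, 0)
    pos[topology$bb_index[i, "CO"], ] <- c(x0 + geo$bond_ca_c, 0, 0)
    if (topology$sc_index[i] > 0L) {
      h <- geo$sc_bond[[res[i]]]
      pos[topology$sc_index[i], ] <- c(x0, 0, h * (-1)^(i - 1))
    }
  }
  pos
}

#' @export
print.peptide_topology <- function(x, ...) {
  cat(sprintf("peptide topology %s: %d residues, %d beads, %d bonds, %d pseudobonds\n",
              x$sequence, nchar(x$sequence), x$n_beads,
              nrow(x$bonds), nrow(x$pseudobonds)))
  invisible(x)
}

#' Human-readable topology dump
#'
#' @param topology a `peptide_topology`.
#' @param file connection or path (default stdout).
#' @export
dump_topology <- function(topology, file = stdout()) {
  b <- topology$beads
  lines <- c(
    sprintf("# topology %s (%d beads)", topology$sequence, topology$n_beads),
    sprintf("%4d %-6s res %2d %s d=%.2f m=%.3f", seq_len(nrow(b)), b$label,
            b$residue, b$res_letter, b$diameter, b$mass),
    "# bonds (i j nominal min max)",
    sprintf("%4d %4d %.3f %.3f %.3f", topology$bonds$i, topology$bonds$j,
            topology$bonds$nominal, topology$bonds$min, topology$bonds$max),
    "# pseudobonds",
    sprintf("%4d %4d %.3f %.3f %.3f", topology$pseudobonds$i,
            topology$pseudobonds$j, topology$pseudobonds$nominal,
            topology$pseudobonds$min, topology$pseudobonds$max))
  writeLines(lines, file)
  invisible(topology)
}
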