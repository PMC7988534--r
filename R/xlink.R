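# Molecular species, cross-linked dimers, b/y fragment enumeration and
# cross-link site localization for photo-induced cross-linking (PIC) MS.
#
# Chemistry conventions: a diazirine-modified residue (TFMD-Phe, "F*")
# loses N2 on photolysis; the resulting carbene either inserts into a
# proximal bond on a neighbouring chain (inter-molecular cross-link), into
# its own chain (intra-molecular link), or is quenched by water (+H2O).
# Exactly one N2 is lost per formed cross-link or quench.

# mass of the H atom capping fragment termini and of common losses
.H_mono <- 1.0078250319
.N2_mono <- 2 * 14.0030740052

#' Construct a peptide chain description
#'
#' @param sequence one-letter amino-acid string.
#' @param nterm,cterm terminal groups (see [peptide_mass()]).
#' @param modifications list of `list(position =, id =)`.
#' @return list of class `peptide_chain`.
#' @export
peptide_chain <- function(sequence, nterm = "Ac", cterm = "NH2",
                          modifications = list()) {
  # validates residues/mods as a side effect
  invisible(peptide_composition(sequence, nterm, cterm, modifications))
  structure(list(sequence = sequence, nterm = nterm, cterm = cterm,
                 modifications = modifications),
            class = "peptide_chain")
}

# per-residue effective monoisotopic masses for a chain, including its
# modifications and any per-residue deltas (named by position) such as the
# -N2 of a spent diazirine or +H2O of a water quench.
.chain_residue_masses <- function(chain, residue_deltas = numeric(0)) {
  res <- strsplit(chain$sequence, "")[[1]]
  rm <- residue_masses("mono")[res]
  for (m in chain$modifications) {
    rm[m$position] <- rm[m$position] + get_modification(m$id)$mass_delta_mono
  }
  if (length(residue_deltas)) {
    pos <- as.integer(names(residue_deltas))
    rm[pos] <- rm[pos] + as.numeric(residue_deltas)
  }
  unname(rm)
}

.nterm_group_mass <- function(nterm) {
  composition_mass(parse_formula(.terminal_groups$nterm[[nterm]]))
}
.cterm_group_mass <- function(cterm) {
  composition_mass(parse_formula(.terminal_groups$cterm[[cterm]]))
}

.chain_neutral_mass <- function(chain, residue_deltas = numeric(0)) {
  sum(.chain_residue_masses(chain, residue_deltas)) +
    .nterm_group_mass(chain$nterm) + .cterm_group_mass(chain$cterm)
}

#' Build a molecular species (monomer, quenched monomer, or cross-linked
#' dimer)
#'
#' A species holds one or two chains, an optional cross-link, and the
#' photolysis bookkeeping (one N2 loss per formed link or quench).
#'
#' @param chains list of one or two [peptide_chain()] objects.
#' @param crosslink `NULL` or
#'   `list(donor_chain =, donor_pos =, acceptor_chain =, acceptor_pos =)`;
#'   the donor residue must carry a diazirine-type modification.  For an
#'   intramolecular link use the same chain index for donor and acceptor.
#' @param quenches list of `list(chain =, position =)` water-quench sites
#'   (each implies -N2 +H2O at that residue's modification).
#' @return object of class `molecular_species` with fields `chains`,
#'   `crosslink`, `quenches`, `mono_mass`, `avg_mass`, `composition`.
#' @export
molecular_species <- function(chains, crosslink = NULL, quenches = list()) {
  stopifnot(length(chains) %in% 1:2)
  for (ch in chains) stopifnot(inherits(ch, "peptide_chain"))
  if (!is.null(crosslink)) {
    dc <- crosslink$donor_chain
    dp <- crosslink$donor_pos
    mods <- chains[[dc]]$modifications
    has_diazirine <- any(vapply(mods, function(m) {
      m$position == dp && identical(m$id, "TFMD")
    }, logical(1)))
    if (!has_diazirine) {
      stop("cross-link donor residue lacks a diazirine-type modification")
    }
  }
  comps <- lapply(chains, function(ch)
    peptide_composition(ch$sequence, ch$nterm, ch$cterm, ch$modifications))
  n_n2 <- (!is.null(crosslink)) + length(quenches)
  extra <- list()
  if (n_n2 > 0) extra <- c(extra, list(c(N = -2L * as.integer(n_n2))))
  if (length(quenches) > 0)
    extra <- c(extra, list(c(H = 2L, O = 1L) * length(quenches)))
  comp <- do.call(combine_compositions, c(comps, extra))
  structure(list(chains = chains, crosslink = crosslink, quenches = quenches,
                 composition = comp,
                 mono_mass = composition_mass(comp, "mono"),
                 avg_mass = composition_mass(comp, "avg")),
            class = "molecular_species")
}

#' Cross-linked dimer of two diazirine-modified peptides
#'
#' Composition is the sum of the two chains minus one N2 (carbene
#' formation); the link connects the donor residue of chain A to the
#' acceptor residue of chain B.
#'
#' @param species_a,species_b [peptide_chain()] objects (chain A carries the
#'   reactive diazirine at `site_donor`).
#' @param site_donor 1-based residue position of the diazirine on chain A.
#' @param site_acceptor 1-based residue position of the insertion site on
#'   chain B.
#' @return `molecular_species` with two chains and one cross-link.
#' @export
crosslinked_dimer <- function(species_a, species_b, site_donor, site_acceptor) {
  molecular_species(
    chains = list(species_a, species_b),
    crosslink = list(donor_chain = 1L, donor_pos = site_donor,
                     acceptor_chain = 2L, acceptor_pos = site_acceptor))
}

#' Intramolecular cross-link (monomer minus N2)
#'
#' @param chain a [peptide_chain()] carrying the diazirine at `site_donor`.
#' @param site_donor,site_acceptor 1-based residue positions.
#' @export
intramolecular_crosslink <- function(chain, site_donor, site_acceptor) {
  molecular_species(
    chains = list(chain),
    crosslink = list(donor_chain = 1L, donor_pos = site_donor,
                     acceptor_chain = 1L, acceptor_pos = site_acceptor))
}

# residue_deltas vector for a chain given the species-level events
.species_chain_deltas <- function(species, chain_idx) {
  deltas <- numeric(0)
  xl <- species$crosslink
  if (!is.null(xl) && xl$donor_chain == chain_idx) {
    deltas[as.character(xl$donor_pos)] <- -.N2_mono
  }
  for (q in species$quenches) {
    if (q$chain == chain_idx) {
      key <- as.character(q$position)
      prev <- if (key %in% names(deltas)) deltas[[key]] else 0
      deltas[key] <- prev - .N2_mono + composition_mass(c(H = 2L, O = 1L))
    }
  }
  deltas
}

# neutral masses of the b/y pieces of one chain: b_k = sum(res 1..k) +
# nterm_group - H; y_m = sum(last m res) + cterm_group + H.  These satisfy
# b_k + y_(n-k) = M for every k.
.chain_piece_masses <- function(chain, residue_deltas = numeric(0)) {
  rm <- .chain_residue_masses(chain, residue_deltas)
  n <- length(rm)
  list(
    n = n,
    b = cumsum(rm)[-n] + .nterm_group_mass(chain$nterm) - .H_mono,
    y = rev(cumsum(rev(rm)))[-1] + .cterm_group_mass(chain$cterm) + .H_mono,
    full = sum(rm) + .nterm_group_mass(chain$nterm) +
      .cterm_group_mass(chain$cterm)
  )
}

#' Enumerate b/y fragment ions of a species
#'
#' For a linear chain all b and y ions are produced and complementary pairs
#' sum to the precursor neutral mass.  For a cross-linked dimer, the
#' fragment that contains the link site carries the full partner chain;
#' double-fragmentation products (one backbone cleavage per chain, the two
#' link-containing pieces remaining joined) are enumerated on request.
#' Fragments of an intramolecular link that would span the link (the ring)
#' are omitted.
#'
#' @param species a [molecular_species()].
#' @param max_charge enumerate charge states 1..max_charge.
#' @param include_double also enumerate double-fragmentation products of a
#'   cross-linked dimer.
#' @return data.frame with columns `series` ("b", "y" or "double"), `chain`,
#'   `index`, `index2` (second cleavage for doubles, else NA),
#'   `retains_partner`, `neutral_mass`, `z`, `mz`.
#' @export
fragment_ions <- function(species, max_charge = 1L, include_double = FALSE) {
  stopifnot(inherits(species, "molecular_species"))
  xl <- species$crosslink
  nchain <- length(species$chains)
  rows <- list()
  add <- function(series, chain, index, index2, retains, neutral) {
    rows[[length(rows) + 1L]] <<- data.frame(
      series = series, chain = chain, index = index, index2 = index2,
      retains_partner = retains, neutral_mass = neutral)
  }
  pieces <- lapply(seq_len(nchain), function(ci)
    .chain_piece_masses(species$chains[[ci]],
                        .species_chain_deltas(species, ci)))
  intra <- !is.null(xl) && nchain == 1L
  inter <- !is.null(xl) && nchain == 2L
  for (ci in seq_len(nchain)) {
    p <- pieces[[ci]]
    for (k in seq_len(p$n - 1L)) {
      if (intra) {
        lo <- min(xl$donor_pos, xl$acceptor_pos)
        hi <- max(xl$donor_pos, xl$acceptor_pos)
        if (k >= lo && k < hi) next  # cleavage inside the ring: no separation
      }
      site <- if (inter) {
        if (ci == xl$donor_chain) xl$donor_pos else xl$acceptor_pos
      } else NA_integer_
      partner_mass <- if (inter) pieces[[3L - ci]]$full else 0
      b_retains <- inter && site <= k
      y_retains <- inter && site > k
      add("b", ci, k, NA_integer_, b_retains,
          p$b[k] + if (b_retains) partner_mass else 0)
      add("y", ci, p$n - k, NA_integer_, y_retains,
          p$y[k] + if (y_retains) partner_mass else 0)
    }
  }
  if (inter && include_double) {
    pa <- pieces[[xl$donor_chain]]; sa <- xl$donor_pos
    pb <- pieces[[xl$acceptor_chain]]; sb <- xl$acceptor_pos
    for (k in seq_len(pa$n - 1L)) {
      ma <- if (sa <= k) pa$b[k] else pa$y[k]
      for (l in seq_len(pb$n - 1L)) {
        mb <- if (sb <= l) pb$b[l] else pb$y[l]
        add("double", NA_integer_, k, l, TRUE, ma + mb)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[rep(seq_len(nrow(out)), each = max_charge), ]
  out$z <- rep(seq_len(max_charge), times = nrow(out) / max_charge)
  out$mz <- neutral_mass_to_mz(out$neutral_mass, out$z)
  rownames(out) <- NULL
  out
}

#' Build candidate cross-linked dimers for a set of acceptor sites
#'
#' @param donor_chain,acceptor_chain [peptide_chain()] objects; the donor
#'   carries the diazirine at `donor_site`.
#' @param donor_site 1-based diazirine position on the donor chain.
#' @param acceptor_sites integer vector of candidate acceptor positions.
#' @return named list of `molecular_species` (names like `"F5->K1"`).
#' @export
candidate_dimers <- function(donor_chain, acceptor_chain, donor_site,
                             acceptor_sites) {
  res_d <- strsplit(donor_chain$sequence, "")[[1]]
  res_a <- strsplit(acceptor_chain$sequence, "")[[1]]
  out <- lapply(acceptor_sites, function(s)
    crosslinked_dimer(donor_chain, acceptor_chain, donor_site, s))
  names(out) <- sprintf("%s%d->%s%d", res_d[donor_site], donor_site,
                        res_a[acceptor_sites], acceptor_sites)
  out
}

#' Rank candidate cross-link sites against an observed peak list
#'
#' Each candidate's theoretical fragment set (including doubles) is matched
#' against the peaks; candidates are ranked by the number of explained
#' peaks, ties broken by the summed absolute mass error.
#'
#' @param peaks data.frame with columns `mz` and `z` (charge annotation;
#'   defaults to 1 when missing).
#' @param candidates named list of `molecular_species` cross-linked dimers,
#'   e.g. from [candidate_dimers()].
#' @param tolerance_da matching tolerance on the neutral-mass scale (Da).
#' @param max_charge fragment charge states to consider.
#' @return data.frame (one row per candidate, best first) with columns
#'   `candidate`, `n_matched`, `n_peaks`, `frac_explained`, `sum_abs_error`;
#'   the per-peak match table of the top candidate is attached as attribute
#'   `"matches"`.
#' @export
assign_crosslink_site <- function(peaks, candidates, tolerance_da = 0.2,
                                  max_charge = 2L) {
  if (is.null(peaks$z)) peaks$z <- 1L
  if (nrow(peaks) == 0L) stop("empty peak list")
  stopifnot(length(candidates) >= 1L)
  if (is.null(names(candidates)))
    names(candidates) <- paste0("candidate", seq_along(candidates))
  neutral <- mz_to_neutral_mass(peaks$mz, peaks$z)
  score_one <- function(sp) {
    fr <- fragment_ions(sp, max_charge = 1L, include_double = TRUE)
    theo <- unique(fr$neutral_mass)
    err <- vapply(neutral, function(m) min(abs(theo - m)), numeric(1))
    hit <- err <= tolerance_da
    list(n_matched = sum(hit),
         sum_abs_error = sum(err[hit]),
         err = err, hit = hit)
  }
  scored <- lapply(candidates, score_one)
  out <- data.frame(
    candidate = names(candidates),
    n_matched = vapply(scored, `[[`, integer(1) + 0, "n_matched"),
    n_peaks = nrow(peaks),
    sum_abs_error = vapply(scored, `[[`, numeric(1), "sum_abs_error"))
  out$frac_explained <- out$n_matched / out$n_peaks
  ord <- order(-out$n_matched, out$sum_abs_error)
  out <- out[ord, c("candidate", "n_matched", "n_peaks", "frac_explained",
                    "sum_abs_error")]
  rownames(out) <- NULL
  top <- scored[[out$candidate[1L]]]
  attr(out, "matches") <- data.frame(mz = peaks$mz, z = peaks$z,
                                     neutral = neutral,
                                     abs_error = top$err, matched = top$hit)
  out
}
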