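# Element and residue mass tables, composition arithmetic.
#
# All "composition" objects are named integer vectors over element symbols
# (e.g. c(C = 2, H = 3, N = 1, O = 1)); negative counts are allowed in
# deltas.  Monoisotopic masses are the default throughout; average masses
# are carried in parallel for completeness.

.element_masses <- list(
  mono = c(H = 1.0078250319, C = 12.0, N = 14.0030740052,
           O = 15.9949146221, S = 31.97207069, F = 18.99840322,
           P = 30.97376151),
  avg  = c(H = 1.00794, C = 12.0107, N = 14.0067,
           O = 15.9994, S = 32.065, F = 18.9984032, P = 30.973761)
)

# proton mass used for m/z arithmetic (Da)
.proton_mass <- 1.00728

# Residue (amino-acid minus water) elemental compositions, one-letter codes.
.residue_formulas <- c(
  G = "C2H3NO",   A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",   T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO",  N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3",  M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",   R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O"
)

.aa_letters <- names(.residue_formulas)

#' Parse a molecular formula into an element-count vector
#'
#' Understands simple Hill-style formulas such as `"C9H9NO"` and signed
#' deltas written with a bracketed minus count, e.g. `"C2N2F3H-1"` meaning
#' plus C2 N2 F3 and minus one H.
#'
#' @param formula character scalar.
#' @return named integer vector of element counts (possibly negative).
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)(-?[0-9]*)", formula, perl = TRUE)[[1]]
  pieces <- regmatches(formula, list(m))[[1]]
  pieces <- pieces[nzchar(pieces)]
  out <- integer(0)
  for (p in pieces) {
    el <- sub("^([A-Z][a-z]?).*$", "\\1", p)
    cnt <- sub("^[A-Z][a-z]?", "", p)
    n <- if (nzchar(cnt)) as.integer(cnt) else 1L
    if (!el %in% names(.element_masses$mono)) {
      stop("unknown element in formula: ", el)
    }
    out[el] <- (if (el %in% names(out)) out[[el]] else 0L) + n
  }
  out
}

#' Combine element-count vectors
#'
#' @param ... named integer vectors as returned by [parse_formula()].
#' @return the summed composition with zero entries dropped.
#' @export
combine_compositions <- function(...) {
  comps <- list(...)
  els <- unique(unlist(lapply(comps, names)))
  out <- vapply(els, function(e) {
    sum(vapply(comps, function(cc) {
      if (e %in% names(cc)) as.numeric(cc[[e]]) else 0
    }, numeric(1)))
  }, numeric(1))
  out <- as.integer(round(out))
  names(out) <- els
  out[out != 0L]
}

#' Mass of an element composition
#'
#' @param composition named integer vector of element counts.
#' @param kind `"mono"` (monoisotopic, default) or `"avg"`.
#' @return mass in Da.
#' @export
composition_mass <- function(composition, kind = c("mono", "avg")) {
  kind <- match.arg(kind)
  tab <- .element_masses[[kind]]
  bad <- setdiff(names(composition), names(tab))
  if (length(bad)) stop("unknown element(s): ", paste(bad, collapse = ", "))
  sum(tab[names(composition)] * as.numeric(composition))
}

#' Monoisotopic residue masses for the 20 standard amino acids
#' @return named numeric vector (Da), one-letter codes.
#' @export
residue_masses <- function(kind = c("mono", "avg")) {
  kind <- match.arg(kind)
  vapply(.residue_formulas, function(f) composition_mass(parse_formula(f), kind),
         numeric(1))
}

# ---- modifications ---------------------------------------------------------

# Registry of covalent modifications.  TFMD is the photo-reactive
# 4-(trifluoromethyl)diazirine group on phenylalanine ("F*"); on photolysis
# it loses N2 and the resulting carbene either inserts into a proximal bond
# (cross-link) or is quenched by water (+H2O).
.modifications <- list(
  TFMD = list(
    id = "TFMD",
    composition_delta = "C2N2F3H-1",
    attaches_to = "F"
  )
)

#' Look up a covalent modification
#'
#' @param id modification identifier, e.g. `"TFMD"`.
#' @return list with `id`, `composition_delta` (element-count vector),
#'   `mass_delta_mono`, `mass_delta_avg`, `attaches_to`.
#' @export
get_modification <- function(id) {
  if (!id %in% names(.modifications)) {
    stop("unknown modification: ", id)
  }
  m <- .modifications[[id]]
  delta <- parse_formula(m$composition_delta)
  list(id = m$id,
       composition_delta = delta,
       mass_delta_mono = composition_mass(delta, "mono"),
       mass_delta_avg = composition_mass(delta, "avg"),
       attaches_to = m$attaches_to)
}

.terminal_groups <- list(
  # group capping the backbone N (free amine contributes H; acetyl C2H3O)
  nterm = list(H = "H", Ac = "C2H3O"),
  # group capping the backbone C=O (free acid OH; amide NH2)
  cterm = list(OH = "OH", NH2 = "NH2")
)

#' Elemental composition of a (possibly modified) peptide
#'
#' @param sequence one-letter amino-acid string.
#' @param nterm `"H"` (free amine) or `"Ac"` (N-acetyl).
#' @param cterm `"OH"` (free acid) or `"NH2"` (C-terminal amide).
#' @param modifications list of `list(position =, id =)` entries; positions
#'   are 1-based within `sequence`.
#' @param lost_n2 number of N2 molecules lost (diazirine photolysis).
#' @param gained_h2o number of water molecules gained (carbene quench).
#' @return named integer element-count vector.
#' @export
peptide_composition <- function(sequence, nterm = "H", cterm = "OH",
                                modifications = list(), lost_n2 = 0L,
                                gained_h2o = 0L) {
  res <- strsplit(sequence, "")[[1]]
  if (!length(res)) stop("empty sequence")
  bad <- setdiff(res, .aa_letters)
  if (length(bad)) stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "))
  if (!nterm %in% names(.terminal_groups$nterm)) stop("unknown N-terminal group: ", nterm)
  if (!cterm %in% names(.terminal_groups$cterm)) stop("unknown C-terminal group: ", cterm)
  comps <- lapply(res, function(r) parse_formula(.residue_formulas[[r]]))
  comps <- c(comps,
             list(parse_formula(.terminal_groups$nterm[[nterm]]),
                  parse_formula(.terminal_groups$cterm[[cterm]])))
  for (m in modifications) {
    mod <- get_modification(m$id)
    pos <- m$position
    if (pos < 1L || pos > length(res)) stop("modification position out of range: ", pos)
    if (res[pos] != mod$attaches_to) {
      stop(sprintf("modification %s attaches to %s, not %s (position %d)",
                   mod$id, mod$attaches_to, res[pos], pos))
    }
    comps <- c(comps, list(mod$composition_delta))
  }
  if (lost_n2 > 0)
    comps <- c(comps, list(c(N = -2L) * as.integer(lost_n2)))
  if (gained_h2o > 0)
    comps <- c(comps, list(c(H = 2L, O = 1L) * as.integer(gained_h2o)))
  do.call(combine_compositions, comps)
}

#' Peptide mass with terminal groups and modifications
#'
#' Computes the neutral mass of a peptide from its elemental composition,
#' e.g. `peptide_mass("KLVFFAE", nterm = "Ac", cterm = "NH2")` for the
#' capped Abeta16-22 heptapeptide.
#'
#' @inheritParams peptide_composition
#' @param kind `"mono"` or `"avg"`.
#' @return mass in Da.
#' @export
peptide_mass <- function(sequence, nterm = "H", cterm = "OH",
                         modifications = list(), kind = c("mono", "avg")) {
  kind <- match.arg(kind)
  composition_mass(
    peptide_composition(sequence, nterm, cterm, modifications), kind)
}

#' m/z to neutral mass and back
#'
#' `M = z * (m/z) - z * m_proton` for positive ions with `z` protons.
#'
#' @param mz observed mass-to-charge ratio.
#' @param z charge state (>= 1).
#' @return neutral mass in Da.
#' @export
mz_to_neutral_mass <- function(mz, z) {
  stopifnot(all(z >= 1))
  z * mz - z * .proton_mass
}

#' @rdname mz_to_neutral_mass
#' @param mass neutral mass in Da.
#' @export
neutral_mass_to_mz <- function(mass, z) {
  stopifnot(all(z >= 1))
  (mass + z * .proton_mass) / z
}
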