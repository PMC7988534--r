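# Mass arithmetic, fragment enumeration, cross-link site assignment.

test_that("peptide masses match the element-composition oracle", {
  # free glycine: residue + water, textbook constants
  expect_equal(peptide_mass("G"), 57.02146 + 18.01056, tolerance = 1e-4)
  # capped heptapeptide, assembled independently element by element
  expect_equal(peptide_mass("KLVFFAE", "Ac", "NH2"),
               oracle_peptide_mass(strsplit("KLVFFAE", "")[[1]],
                                   acetyl = TRUE, amide = TRUE),
               tolerance = 1e-6)
  # TFMD adds +C2N2F3 -H
  mod <- list(list(position = 5, id = "TFMD"))
  expect_equal(peptide_mass("KLVFFAE", "Ac", "NH2", mod) -
                 peptide_mass("KLVFFAE", "Ac", "NH2"),
               oracle_mass(c(C = 2, N = 2, F = 3)) - oracle_mass(c(H = 1)),
               tolerance = 1e-9)
  expect_error(peptide_mass("KLZ"), "unknown residue")
  expect_error(peptide_mass("KLVFFAE", modifications =
                              list(list(position = 2, id = "TFMD"))),
               "attaches to F")
})

test_that("species masses are consistent with their compositions", {
  ch <- peptide_chain("KLVFFAE",
                      modifications = list(list(position = 5, id = "TFMD")))
  mono <- molecular_species(list(ch))
  expect_equal(mono$mono_mass, composition_mass(mono$composition, "mono"),
               tolerance = 1e-9)
  dim <- crosslinked_dimer(ch, ch, 5, 1)
  # dimer composition is the sum of the chains minus one N2
  expect_equal(dim$mono_mass, 2 * mono$mono_mass - oracle_mass(c(N = 2)),
               tolerance = 1e-9)
  # intramolecular link: monomer minus N2
  intra <- intramolecular_crosslink(ch, 5, 7)
  expect_equal(intra$mono_mass, mono$mono_mass - oracle_mass(c(N = 2)),
               tolerance = 1e-9)
  # water-quenched monomer: -N2 +H2O
  q <- molecular_species(list(ch), quenches = list(list(chain = 1, position = 5)))
  expect_equal(q$mono_mass, mono$mono_mass - oracle_mass(c(N = 2)) +
                 oracle_mass(c(H = 2, O = 1)), tolerance = 1e-9)
  # donor without a diazirine is rejected
  plain <- peptide_chain("KLVFFAE")
  expect_error(crosslinked_dimer(plain, plain, 5, 1), "diazirine")
})

test_that("m/z arithmetic reproduces the printed precursor mass", {
  # the published cross-linked dimer peak: m/z 988.58 at 2+ -> 1975.16 Da
  expect_equal(mz_to_neutral_mass(988.58, 2), 1975.16, tolerance = 0.02)
  expect_equal(mz_to_neutral_mass(100.0, 1), 98.99272, tolerance = 1e-6)
  # round trip
  for (z in 1:4) {
    expect_equal(mz_to_neutral_mass(neutral_mass_to_mz(1975.145, z), z),
                 1975.145, tolerance = 1e-10)
  }
})

test_that("b/y complement identity holds for every cleavage", {
  ch <- peptide_chain("KLVFFAE",
                      modifications = list(list(position = 5, id = "TFMD")))
  sp <- molecular_species(list(ch))
  fr <- fragment_ions(sp)
  b <- fr[fr$series == "b", ]
  y <- fr[fr$series == "y", ]
  for (k in 1:6) {
    expect_equal(b$neutral_mass[b$index == k] +
                   y$neutral_mass[y$index == 7 - k],
                 sp$mono_mass, tolerance = 1e-9, info = paste("k =", k))
  }
  # b2 of Ac-KLVFFAE-NH2 equals acetyl + K + L residues (as 1+ acylium,
  # neutral convention: sum + Ac - H)
  b2 <- b$neutral_mass[b$index == 2]
  expect_equal(b2, oracle_mass(c(C = 2, H = 2, O = 1)) +
                 oracle_mass(ORACLE_RES$K) + oracle_mass(ORACLE_RES$L),
               tolerance = 1e-4)
})

test_that("dimer fragments reproduce the printed b/y annotations", {
  ch <- peptide_chain("KLVFFAE",
                      modifications = list(list(position = 5, id = "TFMD")))
  dim <- crosslinked_dimer(ch, ch, 5, 1)
  fr <- fragment_ions(dim, max_charge = 1, include_double = TRUE)
  # published annotations: b ion at 1503.82 (loss of F*-Ala-Glu) and y ion
  # at 1692.95 (loss of Lys-Leu), both within the 0.2 Da convention window
  expect_lt(min(abs(fr$mz[fr$series == "b"] - 1503.82)), 0.2)
  expect_lt(min(abs(fr$mz[fr$series == "y"] - 1692.95)), 0.2)
  # every fragment either carries the full partner chain or avoids the link
  simple <- fr[fr$series != "double", ]
  heavier <- simple$neutral_mass > dim$mono_mass / 2
  expect_true(all(simple$retains_partner == heavier | simple$series == "double"))
})

test_that("cross-link site assignment recovers the generating site", {
  ch <- peptide_chain("KLVFFAE",
                      modifications = list(list(position = 5, id = "TFMD")))
  cands <- candidate_dimers(ch, ch, 5, c(1, 2, 3, 7))  # K16, L17, V18, E22
  truth <- crosslinked_dimer(ch, ch, 5, 1)             # F20 -> K16
  peaks <- synthetic_peaklist(truth, charge_states = 1L, seed = 1)
  rk <- assign_crosslink_site(peaks, cands, tolerance_da = 0.2)
  expect_identical(rk$candidate[1], "F5->K1")
  expect_equal(rk$frac_explained[1], 1)
  # 20% decoys: still top ranked
  noisy <- synthetic_peaklist(truth, charge_states = 1L,
                              decoy_fraction = 0.2, seed = 7)
  rk2 <- assign_crosslink_site(noisy, cands, tolerance_da = 0.2)
  expect_identical(rk2$candidate[1], "F5->K1")
  # control: peaks from the F20 -> V18 dimer must not rank F20 -> K16 first
  alt <- crosslinked_dimer(ch, ch, 5, 3)
  peaks_alt <- synthetic_peaklist(alt, charge_states = 1L, seed = 2)
  rk3 <- assign_crosslink_site(peaks_alt, cands, tolerance_da = 0.2)
  expect_identical(rk3$candidate[1], "F5->V3")
  expect_error(assign_crosslink_site(peaks[0, ], cands), "empty peak list")
})

test_that("site assignment is robust to jitter and decoys across seeds", {
  ch <- peptide_chain("KLVFFAE",
                      modifications = list(list(position = 5, id = "TFMD")))
  cands <- candidate_dimers(ch, ch, 5, c(1, 3, 7))
  truth <- crosslinked_dimer(ch, ch, 5, 1)
  hits <- 0L
  n_seeds <- 25L
  for (s in seq_len(n_seeds)) {
    peaks <- synthetic_peaklist(truth, charge_states = 1L,
                                decoy_fraction = 0.5, mass_jitter_da = 0.05,
                                seed = s)
    rk <- assign_crosslink_site(peaks, cands, tolerance_da = 0.2)
    if (rk$candidate[1] == "F5->K1") hits <- hits + 1L
  }
  expect_gte(hits, round(0.95 * n_seeds))
})
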