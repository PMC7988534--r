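# Synthetic fixtures: lattice validity and ground-truth bookkeeping.

test_that("all four arrangements build valid engine states", {
  topo <- topo_klvffae()
  specs <- list(
    list(arr = "antiparallel_in_register", off = 0L),
    list(arr = "antiparallel_out_of_register", off = 1L),
    list(arr = "parallel_in_register", off = 0L),
    list(arr = "parallel_out_of_register", off = 1L))
  for (sp in specs) {
    fx <- build_sheet_fixture(sp$arr, n_strands = 6, offset = sp$off,
                              topology = topo)
    expect_true(validate_fixture(fx$state), info = sp$arr)
    # every recorded bond passes the geometric criteria individually
    expect_true(all(hbond_geometry_ok(fx$state)), info = sp$arr)
    # pairs have >= 2 bonds each and carry the constructed labels
    expect_true(all(fx$ground_truth$pairs$n_hbonds >= 2))
  }
  expect_error(build_sheet_fixture("antiparallel_in_register", 1),
               "at least 2 strands")
  expect_error(build_sheet_fixture("antiparallel_out_of_register", 4,
                                   offset = 7L, topology = topo),
               "offset magnitude")
})

test_that("random gas fixtures are empty of structure and reproducible", {
  gas <- build_random_gas(10, 140, seed = 5)
  expect_identical(nrow(gas$hbonds), 0L)
  expect_equal(beta_sheet_fraction(gas), 0)
  gas2 <- build_random_gas(10, 140, seed = 5)
  expect_identical(gas$positions, gas2$positions)
  cl <- cluster_oligomers(gas)
  expect_equal(nrow(cl$clusters), 10)         # all singletons
  expect_true(all(cl$clusters$size == 1))
})

test_that("synthetic peak lists honour noise controls and record truth", {
  ch <- peptide_chain("KLVFFAE",
                      modifications = list(list(position = 5, id = "TFMD")))
  dim <- crosslinked_dimer(ch, ch, 5, 1)
  clean <- synthetic_peaklist(dim, charge_states = 1:2, seed = 1)
  expect_identical(attr(clean, "ground_truth")$acceptor_pos, 1)
  withdec <- synthetic_peaklist(dim, charge_states = 1:2,
                                decoy_fraction = 0.5, seed = 1)
  expect_equal(nrow(withdec), nrow(clean) + round(0.5 * nrow(clean)))
  # jitter perturbs but same seed reproduces
  j1 <- synthetic_peaklist(dim, mass_jitter_da = 0.05, seed = 2)
  j2 <- synthetic_peaklist(dim, mass_jitter_da = 0.05, seed = 2)
  expect_identical(j1, j2)
  expect_false(identical(j1$mz, clean$mz[seq_len(nrow(j1))]))
})

test_that("synthetic calibrants follow the generating power law", {
  tab <- synthetic_calibrants(300, 0.5, 12, noise = 0, seed = 11)
  expect_true(all(tab$t_d >= 1 & tab$t_d <= 20))
  manual <- 300 * tab$t_d^0.5 * tab$z * sqrt(1 / tab$m_ion + 1 / 28.0134)
  expect_equal(tab$ccs_ref, manual, tolerance = 1e-12)
})
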