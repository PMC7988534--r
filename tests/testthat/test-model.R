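# Coarse-grained model: topologies, parameter tables, pair potentials.

test_that("bead counting follows the 4n minus glycine rule", {
  cases <- list(
    list(seq = "KLVFFAE", n = 28),   # 7 residues, no Gly
    list(seq = "G", n = 3),          # glycine has no sidechain bead
    list(seq = "GAG", n = 10),       # 4*3 - 2
    list(seq = "AGGA", n = 14))
  for (cs in cases) {
    topo <- build_topology(cs$seq)
    expect_equal(topo$n_beads, cs$n, info = cs$seq)
    ng <- lengths(regmatches(cs$seq, gregexpr("G", cs$seq)))
    expect_equal(topo$n_beads, 4 * nchar(cs$seq) - ng)
  }
  expect_error(build_topology("KLZ"), "unknown residue")
  expect_error(build_topology(""), "empty")
})

test_that("a TFMD modification keeps the bead count and adds its mass delta", {
  plain <- build_topology("KLVFFAE")
  mod <- build_topology("KLVFFAE", list(list(position = 5, id = "TFMD")))
  expect_equal(mod$n_beads, plain$n_beads)
  sc5 <- plain$sc_index[5]
  delta <- mod$beads$mass[sc5] - plain$beads$mass[sc5]
  # oracle: +C2 +N2 +F3 -H from the element table
  expect_equal(delta,
               oracle_mass(c(C = 2, N = 2, F = 3)) - oracle_mass(c(H = 1)),
               tolerance = 1e-9)
  expect_identical(mod$beads$modification[sc5], "TFMD")
  expect_error(build_topology("KLVFFAE", list(list(position = 1, id = "TFMD"))),
               "attaches to F")
})

test_that("reference conformation satisfies every bond and pseudobond exactly", {
  topo <- build_topology("KLVFFAE")
  pos <- reference_conformation(topo)
  walls <- rbind(topo$bonds, topo$pseudobonds)
  d <- sqrt(rowSums((pos[walls$i, ] - pos[walls$j, ])^2))
  expect_true(all(d >= walls$min & d <= walls$max))
  expect_equal(d, walls$nominal, tolerance = 1e-12)
})

test_that("the default table is symmetric and complete over 210 pairs", {
  tab <- default_parameter_table()
  aa <- tab$residues
  expect_length(aa, 20)
  for (i in aa) for (j in aa) {
    expect_identical(tab$pair_well_width[i, j], tab$pair_well_width[j, i])
    expect_identical(tab$pair_well_depth[i, j], tab$pair_well_depth[j, i])
  }
  nonG <- setdiff(aa, "G")
  # 19 sidechain types -> 190 unordered pairs carry positive widths; the
  # remaining 20 involve glycine (no sidechain bead)
  ut <- tab$pair_well_width[nonG, nonG][upper.tri(matrix(0, 19, 19), diag = TRUE)]
  expect_length(ut, 190)
  expect_true(all(ut > 0))
  # all widths at least the contact distance
  for (i in nonG) for (j in nonG) {
    pp <- pair_potential(i, j, tab)
    expect_gte(pp$well_width, pp$contact_distance)
  }
})

test_that("pair_potential returns the expected physics", {
  tab <- default_parameter_table()
  ff <- pair_potential("F", "F", tab)
  expect_gt(ff$well_depth, 0)           # hydrophobic collapse needs F-F
  ke <- pair_potential("K", "E", tab)
  ek <- pair_potential("E", "K", tab)
  expect_identical(ke, ek)              # symmetry
  expect_gt(ke$well_depth, 0)           # salt bridge
  kk <- pair_potential("K", "K", tab)
  expect_identical(kk$well_depth, 0)    # like charges: hard sphere only
  expect_error(pair_potential("B", "F", tab), "unknown residue")
})

test_that("parameter tables round-trip through the text format", {
  tab <- default_parameter_table()
  tmp <- tempfile(fileext = ".txt")
  write_parameter_table(tab, tmp)
  back <- load_parameter_table(tmp)
  expect_equal(back$pair_well_width, tab$pair_well_width, tolerance = 1e-4)
  expect_equal(back$pair_well_depth, tab$pair_well_depth, tolerance = 1e-4)
  expect_equal(back$hb_well_width, tab$hb_well_width)
  # the bundled default table is the same object and carries one record
  # per unordered pair of the 20 residue types
  bundled_path <- system.file("extdata", "sw_params_v1.txt", package = "pepdmd")
  expect_equal(sum(grepl("^PAIR", readLines(bundled_path))), 210)
  bundled <- load_parameter_table()
  expect_equal(bundled$pair_well_depth, tab$pair_well_depth, tolerance = 1e-4)
})

test_that("table loading validates symmetry, completeness and positivity", {
  tab <- default_parameter_table()
  tmp <- tempfile(fileext = ".txt")
  write_parameter_table(tab, tmp)
  lines <- readLines(tmp)
  # truncation: drop the last PAIR record -> error names the missing pair
  pair_lines <- grep("^PAIR", lines)
  writeLines(lines[-pair_lines[length(pair_lines)]], tmp)
  expect_error(load_parameter_table(tmp), "missing pair entry")
  # conflicting duplicate
  writeLines(c(lines, "PAIR A A 9.9 0.5"), tmp)
  expect_error(load_parameter_table(tmp), "conflicting duplicate")
  # non-positive width
  bad <- sub("^PAIR A A [0-9.]+", "PAIR A A -1.0", lines)
  writeLines(bad, tmp)
  expect_error(load_parameter_table(tmp), "non-positive width")
})

test_that("energy unit conversion via eps_HB is an identity round trip", {
  e <- c(-3.5, 0, 1.25)
  expect_equal(kjmol_to_eps(eps_to_kjmol(e)), e, tolerance = 1e-15)
  expect_equal(eps_to_kjmol(1), 12.47)
})
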