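# System construction: concentration/box conversions, placement,
# velocity initialization.

test_that("concentration bookkeeping matches the closed-form oracle", {
  # 192 chains in a 321.0 A cubic box is 10 mM to the nearest millimolar
  conc <- concentration_of(192, 321.0)
  expect_equal(round(conc), 10)
  expect_equal(conc, 9.64, tolerance = 0.005)
  # independent closed form: n / (N_A V) with V in litres
  oracle <- function(n, L) 1000 * n / (6.02214076e23 * (L * 1e-9)^3 * 1e27 * 1e-27)
  expect_equal(concentration_of(1, 1e4), 1 / (6.02214076e23 * 1e12 * 1e-27) * 1000,
               tolerance = 1e-12)
  # scaling law: doubling the box divides the concentration by 8
  expect_equal(concentration_of(10, 100) / concentration_of(10, 200), 8,
               tolerance = 1e-12)
})

test_that("box_length_for inverts concentration_of exactly", {
  expect_equal(box_length_for(192, 9.64), 321.0, tolerance = 0.5)
  expect_equal(box_length_for(192, 10),
               (1000 * 192 / (6.02214076e23 * 10 * 1e-27))^(1 / 3),
               tolerance = 1e-12)
  for (x in c(0.5, 5, 50)) {
    expect_equal(concentration_of(37, box_length_for(37, x)), x,
                 tolerance = 1e-12)
  }
})

test_that("random placement is overlap-free and deterministic per seed", {
  topo <- topo_klvffae()
  st1 <- random_initial_configuration(12, 120, topo, seed = 42)
  st2 <- random_initial_configuration(12, 120, topo, seed = 42)
  expect_identical(st1$positions, st2$positions)
  st3 <- random_initial_configuration(12, 120, topo, seed = 43)
  expect_false(identical(st1$positions, st3$positions))
  expect_lt(max_core_overlap(st1), 1e-9)
})

test_that("infeasible packing fails with a clear error", {
  topo <- topo_klvffae()
  expect_error(random_initial_configuration(2, 20, topo, seed = 1),
               "cannot accommodate")
  # feasible box but hopeless density: bounded retries
  expect_error(random_initial_configuration(60, 40, topo, seed = 1,
                                            max_tries = 50),
               "placement failed")
})

test_that("velocity initialization is Maxwell-Boltzmann at exactly T*", {
  topo <- topo_klvffae()
  st <- random_initial_configuration(12, 150, topo, seed = 7)
  st <- init_velocities(st, 0.193, seed = 8)
  # net momentum removed
  p <- colSums(st$velocities * st$meta$mass)
  expect_equal(max(abs(p)), 0, tolerance = 1e-9)
  # instantaneous reduced temperature rescaled to exactly T*
  expect_equal(instantaneous_temperature(st), 0.193, tolerance = 1e-12)
  # component variances scale as T*/m: compare light vs heavy beads
  v2m <- rowSums(st$velocities^2) * st$meta$mass
  grp <- split(v2m, round(st$meta$mass))
  grp <- grp[lengths(grp) >= 50]       # avoid tiny-sample noise
  means <- vapply(grp, mean, numeric(1))
  expect_lt(max(abs(means / mean(v2m) - 1)), 0.25)  # statistical check
})
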