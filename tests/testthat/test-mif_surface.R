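single_atom <- function(el = "C", at = c(0, 0, 0)) {
  molecule("probe_atom", el, coords = matrix(at, 1, 3))
}

test_that("grid construction follows the box arithmetic", {
  g <- build_grid(single_atom(), spacing = 1, padding = 5)
  expect_equal(g$dims, c(11L, 11L, 11L))
  expect_error(build_grid(single_atom(), spacing = 0), "spacing")
  expect_error(build_grid(read_smiles("C", "noc"), 1, 5), "coordinates")

  shifted <- single_atom(at = c(3, -2, 7))
  g2 <- build_grid(shifted, spacing = 1, padding = 5)
  expect_equal(g2$origin, g$origin + c(3, -2, 7))
  expect_equal(g2$dims, g$dims)
})

test_that("the probe field decays far away and repels at atomic centers", {
  m <- single_atom()
  far <- water_probe_energy(m, matrix(c(15, 0, 0), 1, 3), charges = NA)
  expect_lt(abs(far), 0.01)
  core <- water_probe_energy(m, matrix(c(0.1, 0, 0), 1, 3), charges = NA)
  expect_gt(core, 1000)
})

test_that("the field respects a symmetric diatomic's mirror plane", {
  dimer <- molecule("dimer", c("O", "O"),
                    coords = matrix(c(-0.6, 0, 0, 0.6, 0, 0), 2, 3,
                                    byrow = TRUE))
  pts <- matrix(c(1.8, 0.4, 0.2, -1.8, 0.4, 0.2,
                  2.5, -1, 1, -2.5, -1, 1), 4, 3, byrow = TRUE)
  e <- water_probe_energy(dimer, pts)
  expect_equal(e[1], e[2], tolerance = 1e-10)
  expect_equal(e[3], e[4], tolerance = 1e-10)
})

test_that("calibrated isosurface area approaches the analytic sphere", {
  m <- single_atom()
  iso <- water_probe_energy(m, matrix(c(1.7, 0, 0), 1, 3), charges = NA)
  true_area <- 4 * pi * 1.7^2
  errs <- vapply(c(0.8, 0.4, 0.2), function(sp) {
    f <- water_probe_field(m, build_grid(m, sp, 4), charges = NA)
    abs(interaction_surface_area(f, iso) - true_area) / true_area
  }, 1.0)
  expect_true(all(diff(errs) < 0))   # error shrinks as spacing halves
  expect_lt(errs[3], 0.05)
})

test_that("disjoint surfaces add; coincident atoms share one surface", {
  m1 <- single_atom()
  iso <- water_probe_energy(m1, matrix(c(1.7, 0, 0), 1, 3), charges = NA)
  f1 <- water_probe_field(m1, build_grid(m1, 0.25, 4), charges = NA)
  a1 <- interaction_surface_area(f1, iso)

  pair <- molecule("pair", c("C", "C"),
                   coords = matrix(c(0, 0, 0, 20, 0, 0), 2, 3, byrow = TRUE))
  f2 <- water_probe_field(pair, build_grid(pair, 0.25, 4), charges = NA)
  expect_equal(interaction_surface_area(f2, iso), 2 * a1, tolerance = 0.02)

  overlap <- molecule("overlap", c("C", "C"),
                      coords = matrix(0, 2, 3))
  fo <- water_probe_field(overlap, build_grid(overlap, 0.25, 4),
                          charges = NA)
  iso_o <- water_probe_energy(overlap, matrix(c(1.7, 0, 0), 1, 3),
                              charges = NA)
  expect_equal(interaction_surface_area(fo, iso_o), a1, tolerance = 0.02)
})

test_that("rigid-body motion changes the area by less than 2 percent", {
  m <- embed_3d(read_smiles("CCO", "ethanol"), 4)
  area0 <- vsurf_s(m, spacing = 0.3)
  rot <- with_seed(9, qr.Q(qr(matrix(rnorm(9), 3, 3))))
  moved <- m
  moved$coords <- sweep(m$coords %*% rot, 2, c(-2.3, 1.1, 0.7))
  expect_equal(vsurf_s(moved, spacing = 0.3), area0, tolerance = 0.02)
})

test_that("the surface grows with chain length", {
  areas <- vapply(c(2, 4, 6), function(n) {
    chain <- molecule(paste0("chain", n), rep("C", n),
                      coords = cbind(6 * seq_len(n), 0, 0))
    f <- water_probe_field(chain, build_grid(chain, 0.4, 4), charges = NA)
    interaction_surface_area(f, 5)
  }, 1.0)
  expect_true(all(diff(areas) > 0))
})

test_that("an out-of-range iso level warns and returns zero area", {
  m <- single_atom()
  f <- water_probe_field(m, build_grid(m, 0.5, 3), charges = NA)
  expect_warning(a <- interaction_surface_area(f, max(f$values) + 1),
                 "range")
  expect_equal(a, 0)
})

test_that("Gasteiger-type charges are deterministic with sensible signs", {
  eth <- read_smiles("CCO", "ethanol")
  q <- gasteiger_charges(eth)
  expect_equal(sum(q), 0, tolerance = 1e-8)       # neutral molecule
  expect_lt(q[eth$elements == "O"], 0)            # oxygen pulls density
  expect_identical(q, gasteiger_charges(eth))

  ion <- read_smiles("C[NH3+]", "methylammonium")
  expect_equal(sum(gasteiger_charges(ion)), 1, tolerance = 1e-8)
})
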