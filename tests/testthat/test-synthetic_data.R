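test_that("noiseless generation recovers the planted model exactly", {
  tab <- gen_descriptor_table(planted_model_spec(n = 60, pool_width = 12,
                                                 noise_sd = 0, seed = 8))
  m <- fit_ols(tab, c("vsurf_S", "wienerPath"))
  expect_equal(m$intercept, -1.26777, tolerance = 1e-8)
  expect_equal(m$coefficients[["vsurf_S"]], -0.01161, tolerance = 1e-8)
  expect_equal(m$coefficients[["wienerPath"]], 0.00007, tolerance = 1e-8)
  expect_equal(m$stats$r2, 1, tolerance = 1e-10)
})

test_that("default noise puts the sample R2 near the design target", {
  r2s <- vapply(1:5, function(s) {
    tab <- gen_descriptor_table(planted_model_spec(seed = 400 + s))
    fit_ols(tab, c("vsurf_S", "wienerPath"))$stats$r2
  }, 1.0)
  expect_true(all(abs(r2s - 0.93) < 0.05))
})

test_that("tables are seed-deterministic with a stable schema", {
  spec <- planted_model_spec(n = 30, pool_width = 20)
  t1 <- gen_descriptor_table(spec)
  t2 <- gen_descriptor_table(spec)
  expect_identical(t1, t2)
  spec2 <- spec
  spec2$seed <- 2L
  t3 <- gen_descriptor_table(spec2)
  expect_identical(names(t3), names(t1))
  expect_false(identical(descriptor_matrix(t3), descriptor_matrix(t1)))
  expect_error(gen_descriptor_table(planted_model_spec(pool_width = 1)),
               "pool_width")
})

test_that("decoy columns stay uncorrelated with the response", {
  tab <- gen_descriptor_table(planted_model_spec(seed = 13))
  y <- response_of(tab)
  decoys <- grep("^pool_", names(tab), value = TRUE)
  cors <- vapply(decoys, function(d) abs(cor(tab[[d]], y)), 1.0)
  expect_gte(mean(cors < 0.2), 0.95)
})

test_that("random molecular graphs are connected, legal and seed-pure", {
  expect_identical(wiener_path(gen_random_molgraph(1)), 0L)
  for (n in 2:10) {
    p <- gen_random_molgraph(n, branch_prob = 0)
    expect_identical(wiener_path(p), as.integer(n * (n^2 - 1) / 6))
  }
  for (s in 1:25) {
    mol <- gen_random_molgraph(12, branch_prob = 0.5, ring_prob = 0.2,
                               seed = s)
    g_deg <- table(factor(c(mol$bonds$i, mol$bonds$j),
                          levels = seq_len(n_atoms(mol))))
    expect_true(all(g_deg <= 4))
    expect_true(all(implicit_h_counts(mol) >= 0))
    expect_no_error(wiener_path(mol))    # connected
  }
  m1 <- gen_random_molgraph(9, 0.4, 0.1, seed = 6)
  m2 <- gen_random_molgraph(9, 0.4, 0.1, seed = 6)
  expect_identical(m1, m2)
})

test_that("toy complexes round-trip through the PDB machinery", {
  dir <- withr::local_tempdir()
  pose <- gen_toy_complex("ch_pi", dir = dir)
  back <- read_pdb(file.path(dir, "receptor.pdb"))
  expect_equal(back$atoms$name, pose$receptor$atoms$name)
  expect_equal(back$atoms$resname, pose$receptor$atoms$resname)
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(pose$receptor$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  lig <- read_sdf(file.path(dir, "ligand.sdf"))[[1]]
  expect_equal(lig$coords, pose$ligand$coords, tolerance = 1e-3)
})

test_that("jittered fixtures move the ligand but keep the seed contract", {
  p1 <- gen_toy_complex("pi_stack", jitter = 0.1, seed = 3)
  p2 <- gen_toy_complex("pi_stack", jitter = 0.1, seed = 3)
  p3 <- gen_toy_complex("pi_stack", jitter = 0.1, seed = 4)
  expect_identical(p1$ligand$coords, p2$ligand$coords)
  expect_false(identical(p1$ligand$coords, p3$ligand$coords))
})
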