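test_that("SMILES parsing yields the implied heavy-atom graph", {
  bz <- read_smiles("c1ccccc1", "benzene")
  expect_equal(n_atoms(bz), 6)
  expect_equal(nrow(bz$bonds), 6)
  expect_true(all(bz$aromatic))

  me <- read_smiles("C", "methane")
  expect_equal(n_atoms(me), 1)
  expect_equal(nrow(me$bonds), 0)
  expect_equal(sum(implicit_h_counts(me)), 4)

  cat2 <- read_smiles("Oc1ccccc1O", "catechol")
  expect_equal(n_atoms(cat2), 8)
  expect_equal(nrow(cat2$bonds), 8)
})

test_that("batch SMILES reader skips bad records without aborting", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("# header comment",
               "c1ccccc1 benzene",
               "not_a_smiles((( broken",
               "CCO ethanol"), f)
  mols <- suppressWarnings(read_smiles_file(f))
  expect_setequal(names(mols), c("benzene", "ethanol"))
  expect_warning(read_smiles_file(f), "broken")
})

test_that("multi-fragment SMILES keeps the largest fragment with a message", {
  expect_message(m <- read_smiles("C[NH3+].[Cl-]", "salt"), "largest")
  expect_equal(n_atoms(m), 2)
  expect_equal(sort(m$elements), c("C", "N"))
  expect_equal(m$charges[m$elements == "N"], 1L)
})

test_that("parsing the SMILES writer's output reproduces the same graph", {
  for (smi in c("c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O", "CCO",
                "C1CN2CC3=CCOC4CC(=O)N5C6C4C3CC2C61C7=CC=CC=C75")) {
    m1 <- read_smiles(smi, "orig")
    m2 <- read_smiles(write_smiles(m1), "rt")
    expect_equal(n_atoms(m2), n_atoms(m1))
    expect_equal(nrow(m2$bonds), nrow(m1$bonds))
    expect_equal(element_counts(m2), element_counts(m1))
    expect_equal(wiener_path(m2), wiener_path(m1))
  }
})

test_that("SDF round-trips coordinates, charges and pose scores", {
  m <- embed_3d(read_smiles("CCO", "ethanol"), 3)
  attr(m, "score") <- -7.25
  f <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(m, f)
  back <- read_sdf(f)
  expect_equal(names(back), "ethanol")
  expect_equal(back[[1]]$coords, m$coords, tolerance = 1e-3)
  expect_equal(attr(back[[1]], "score"), -7.25)

  ion <- read_smiles("C[NH3+]", "methylammonium")
  ion$coords <- matrix(c(0, 0, 0, 1.5, 0, 0.2), 2, 3, byrow = TRUE)
  write_sdf(ion, f)
  expect_equal(read_sdf(f)[[1]]$charges, ion$charges)
})

test_that("PDB reader round-trips the fixture writer and validates input", {
  pose <- gen_toy_complex("salt_bridge")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(pose$receptor, f)
  back <- read_pdb(f)
  orig <- pose$receptor$atoms
  expect_equal(nrow(back$atoms), nrow(orig))
  expect_equal(back$atoms$name, orig$name)
  expect_equal(back$atoms$resname, orig$resname)
  expect_equal(back$atoms$resno, orig$resno)
  expect_equal(back$atoms$x, orig$x, tolerance = 1e-3)
  expect_equal(nrow(receptor_residues(back)), 1)

  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", empty)
  expect_warning(r0 <- read_pdb(empty), "no ATOM")
  expect_equal(nrow(r0$atoms), 0)

  bad <- withr::local_tempfile(fileext = ".pdb")
  lines <- readLines(f)
  atom1 <- grep("^ATOM", lines)[1]
  substr(lines[atom1], 31, 38) <- "  xx.yyy"
  writeLines(lines, bad)
  expect_error(read_pdb(bad), paste0("line ", atom1))
})

test_that("descriptor CSV and model JSON round-trip losslessly", {
  tab <- gen_descriptor_table(planted_model_spec(n = 20, pool_width = 8,
                                                 seed = 5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_table(tab, f)
  back <- read_descriptor_table(f)
  expect_equal(descriptor_matrix(back), descriptor_matrix(tab))
  expect_equal(response_of(back), response_of(tab))
  expect_error(read_descriptor_table(f, response_col = "missing_response"),
               "missing_response")

  m <- qsar_model(-1.26777, c(vsurf_S = -0.01161, wienerPath = 0.00007),
                  stats = list(r2 = 0.9359, q2 = 0.9003))
  fj <- withr::local_tempfile(fileext = ".json")
  write_qsar_model(m, fj)
  back_m <- read_qsar_model(fj)
  expect_identical(back_m$intercept, -1.26777)
  expect_identical(back_m$coefficients, m$coefficients)
})

test_that("3D embedding is deterministic with sane geometry", {
  me1 <- embed_3d(read_smiles("C", "methane"), 1)
  me2 <- embed_3d(read_smiles("C", "methane"), 1)
  expect_identical(me1$coords, me2$coords)

  et <- embed_3d(read_smiles("CC", "ethane"), 1)
  d_cc <- sqrt(sum((et$coords[1, ] - et$coords[2, ])^2))
  expect_gt(d_cc, 1.4)
  expect_lt(d_cc, 1.7)

  bz <- embed_3d(read_smiles("c1ccccc1", "benzene"), 1)
  pc <- prcomp(bz$coords)
  expect_lt(sqrt(mean(pc$x[, 3]^2)), 0.1)

  asp <- embed_3d(read_smiles("CC(=O)Oc1ccccc1C(=O)O", "aspirin"), 2)
  b <- asp$bonds
  dd <- sqrt(rowSums((asp$coords[b$i, ] - asp$coords[b$j, ])^2))
  expect_true(all(dd > 0.9 & dd < 1.9))
})
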