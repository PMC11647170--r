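test_that("each toy complex yields exactly its designed record set", {
  for (kind in c("salt_bridge", "hbond", "pi_stack", "ch_pi", "none")) {
    pose <- gen_toy_complex(kind)
    rec <- detect_interactions(pose)
    expect_setequal(rec$kind, attr(pose, "designed_kinds"))
    expect_equal(nrow(rec), length(attr(pose, "designed_kinds")),
                 label = kind)
  }
})

test_that("the glutamate fixture shows the paired salt-bridge pattern", {
  rec <- detect_interactions(gen_toy_complex("salt_bridge"))
  expect_setequal(rec$kind, c("H-Donor", "Ionic"))
  expect_true(all(rec$resname == "GLU" & rec$resno == 265))
  th <- interaction_thresholds()
  expect_lte(rec$distance_A[rec$kind == "H-Donor"], th$hbond_dist)
  expect_lte(rec$distance_A[rec$kind == "Ionic"], th$ionic_dist)
})

test_that("typing is invariant under rigid-body motion of the complex", {
  for (kind in c("salt_bridge", "pi_stack", "ch_pi")) {
    pose <- gen_toy_complex(kind)
    rec0 <- detect_interactions(pose)
    rec1 <- detect_interactions(transform_pose(pose, seed = 3))
    expect_equal(rec1$kind, rec0$kind)
    expect_equal(rec1$distance_A, rec0$distance_A, tolerance = 1e-8)
  }
})

test_that("every record respects its kind's cutoff on jittered fixtures", {
  th <- interaction_thresholds()
  cutoff <- c(`H-Donor` = th$hbond_dist, `H-Acceptor` = th$hbond_dist,
              Ionic = th$ionic_dist, `pi-pi` = th$pipi_dist,
              `H-pi` = th$hpi_dist, `pi-H` = th$hpi_dist)
  for (s in 1:12) {
    kind <- c("salt_bridge", "hbond", "pi_stack", "ch_pi")[1 + s %% 4]
    rec <- detect_interactions(gen_toy_complex(kind, jitter = 0.15, seed = s))
    if (nrow(rec) > 0)
      expect_true(all(rec$distance_A <= cutoff[rec$kind] + 1e-12))
  }
})

test_that("shrinking cutoffs never adds records", {
  th <- interaction_thresholds()
  tight <- th
  tight$hbond_dist <- 2.0
  tight$ionic_dist <- 2.5
  tight$pipi_dist <- 3.0
  tight$hpi_dist <- 3.0
  for (kind in c("salt_bridge", "hbond", "pi_stack", "ch_pi")) {
    pose <- gen_toy_complex(kind)
    expect_lte(nrow(detect_interactions(pose, tight)),
               nrow(detect_interactions(pose, th)))
  }
})

test_that("lowest-energy pose selection obeys the tie and exclusion rules", {
  pose <- gen_toy_complex("hbond")
  mk <- function(score) complex_pose(pose$receptor, pose$ligand, score)
  sel <- suppressMessages(
    lowest_energy_selection(list(mk(-6.0), mk(-7.5), mk(-7.5))))
  expect_length(sel, 1)
  expect_equal(sel[[1]]$score, -7.5)
  expect_message(lowest_energy_selection(list(mk(-1), mk(-1))), "tied")
  expect_equal(lowest_energy_selection(list(mk(-4)))[[1]]$score, -4)
  none <- complex_pose(pose$receptor, pose$ligand)
  expect_warning(out <- lowest_energy_selection(list(none)), "no scored")
  expect_length(out, 0)
})

test_that("population percentages match the printed count/total pairs", {
  fake_records <- function(counts) {
    do.call(rbind, lapply(names(counts), function(k) {
      data.frame(compound_id = "x", chain = "A",
                 resno = as.integer(sub("^[A-Z]+", "", k)),
                 resname = sub("[0-9]+$", "", k),
                 generic_label = NA_character_, kind = "H-Donor",
                 distance_A = 3, lig_part = "a", rec_part = "b",
                 stringsAsFactors = FALSE)[rep(1, counts[[k]]), ]
    }))
  }
  pm <- population_map(fake_records(c(GLU265 = 250, TRP88 = 203)))
  expect_equal(pm$total, 453)
  expect_equal(pm$percentages[["GLU265"]], 55.2)

  pm2 <- population_map(fake_records(c(TRP88 = 12, GLU265 = 11, SER180 = 22)))
  expect_equal(pm2$total, 45)
  expect_equal(pm2$percentages[["TRP88"]], 26.7)
  expect_equal(pm2$percentages[["GLU265"]], 24.4)

  single <- population_map(fake_records(c(TRP88 = 1)))
  expect_equal(single$percentages[["TRP88"]], 100.0)
  expect_equal(sum(pm2$counts), pm2$total)
  expect_equal(unname(pm2$percentages),
               unname(round(100 * pm2$counts / pm2$total, 1)))

  empty <- population_map(NULL)
  expect_equal(empty$total, 0L)
  expect_length(empty$counts, 0)
})

test_that("the arene summary flags ring contacts as R and polar separately", {
  rec <- rbind(
    detect_interactions(gen_toy_complex("pi_stack")),
    detect_interactions(gen_toy_complex("salt_bridge")))
  out <- arene_vs_polar_summary(rec, c("PHE252", "GLU265"))
  stack_row <- out[out$compound_id == "lig_benzene", ]
  expect_equal(stack_row$PHE252, "R")
  expect_equal(stack_row$GLU265, "-")
  salt_row <- out[out$compound_id == "lig_ammonium", ]
  expect_equal(salt_row$PHE252, "-")
  expect_true(salt_row$GLU265_polar)
  expect_equal(salt_row$GLU265, "-")

  none <- arene_vs_polar_summary(rec[0, ], c("PHE252"), compounds = "ghost")
  expect_equal(none$PHE252, "-")
})

test_that("generic residue annotations propagate into records", {
  pose <- gen_toy_complex("salt_bridge")
  annotated <- receptor_structure(pose$receptor$atoms,
                                  annotations = c("A:265" = "7.39"))
  rec <- detect_interactions(complex_pose(annotated, pose$ligand))
  expect_true(all(rec$generic_label == "7.39"))
})
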