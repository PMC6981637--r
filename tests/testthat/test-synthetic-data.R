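test_that("generators are pure functions of (config, seed)", {
  e1 <- gen_pose_ensemble(pose_ensemble_config(n_ligands = 4,
                                               poses_per_ligand = 10), seed = 5)
  e2 <- gen_pose_ensemble(pose_ensemble_config(n_ligands = 4,
                                               poses_per_ligand = 10), seed = 5)
  expect_identical(e1$poses$meta, e2$poses$meta)
  expect_identical(e1$poses$coords, e2$poses$coords)
  e3 <- gen_pose_ensemble(pose_ensemble_config(n_ligands = 4,
                                               poses_per_ligand = 10), seed = 6)
  expect_false(identical(e1$poses$meta$rescore_dg, e3$poses$meta$rescore_dg))
  k1 <- gen_kinetics(inhibition_model("MM", vmax = 1, km = 0.1), seed = 3)
  k2 <- gen_kinetics(inhibition_model("MM", vmax = 1, km = 0.1), seed = 3)
  expect_identical(k1$data, k2$data)
  s1 <- gen_site_scene(list(list(type = "hbond", residue = "TRP279",
                                 distance = 3.0)), seed = 9)
  s2 <- gen_site_scene(list(list(type = "hbond", residue = "TRP279",
                                 distance = 3.0)), seed = 9)
  expect_identical(s1$receptor$atoms, s2$receptor$atoms)
  # generators restore the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(gen_pose_ensemble(
    pose_ensemble_config(n_ligands = 3, poses_per_ligand = 4), seed = 1))
  expect_identical(runif(1), before)
})

test_that("written ensembles are byte-identical across same-seed runs", {
  cfg <- pose_ensemble_config(n_ligands = 4, poses_per_ligand = 10)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_pose_ensemble(gen_pose_ensemble(cfg, seed = 8), d1)
  write_pose_ensemble(gen_pose_ensemble(cfg, seed = 8), d2)
  for (f in c("poses.sdf", "scores.tsv", "activity.tsv", "truth.tsv",
              "core_map.txt")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # config hash travels in the SDF header
  expect_true(any(grepl("^config:", readLines(file.path(d1, "poses.sdf")))))
})

test_that("pose ensembles honor their configuration contract", {
  cfg <- pose_ensemble_config(n_ligands = 5, n_receptors = 3,
                              poses_per_ligand = 20, n_modes = 2)
  ens <- gen_pose_ensemble(cfg, seed = 2)
  meta <- ens$poses$meta
  expect_equal(nrow(meta), 100L)
  expect_equal(unname(table(meta$ligand_id)), rep(20L, 5), ignore_attr = TRUE)
  expect_equal(sort(unique(meta$receptor_id)),
               sprintf("rec%02d", 1:3))
  # truth sidecar covers every pose and the modes split evenly
  expect_equal(nrow(ens$truth$pose_modes), nrow(meta))
  expect_equal(unname(table(ens$truth$pose_modes$mode)), c(50L, 50L),
               ignore_attr = TRUE)
  # true-mode energies correlate with activity, decoys do not
  true_idx <- which(ens$truth$pose_modes$is_true_mode)
  r_true <- cor(meta$rescore_dg[true_idx],
                ens$dg_expt[meta$ligand_id[true_idx]])
  expect_gt(r_true, 0.7)
  # separation guard
  expect_error(pose_ensemble_config(mode_separation = 1, jitter = 0.3),
               "separated")
})

test_that("noiseless energy model yields perfect consensus correlation", {
  cfg <- pose_ensemble_config(sigma_e = 0, sigma_pose = 0, decoy_offset = 6)
  ens <- gen_pose_ensemble(cfg, seed = 13)
  rep <- run_consensus(ens$poses, ens$map, ens$dg_expt)
  expect_equal(rep$ranking$r_squared[1], 1.0, tolerance = 1e-9)
})

test_that("kinetics generator matches the rate law at zero noise and counts rows", {
  truth <- inhibition_model("competitive", vmax = 1, km = 0.1, ki = 3)
  kin0 <- gen_kinetics(truth, cv = 0, replicates = 2, seed = 1)
  expect_equal(kin0$data$v,
               model_rate(truth, kin0$data$S_mM, kin0$data$I_uM),
               tolerance = 1e-12)
  expect_equal(nrow(kin0$data), 8 * 3 * 2)
  expect_equal(sort(unique(kin0$data$I_uM)), c(0, 2.12, 4.24))
  expect_equal(range(kin0$data$S_mM), c(3.75e-3, 0.48), tolerance = 1e-9)
  # the alternative probe design
  d6aa <- kinetics_design(3.97)
  expect_equal(d6aa$I_uM, c(0, 1.985, 3.97))
})

test_that("site scenes plant each contact class at its stated geometry", {
  sc <- gen_site_scene(list(
    list(type = "pi_sandwich", residue = "PHE330", distance = 3.56),
    list(type = "pi_parallel_displaced", residue = "TRP84", distance = 4.10,
         offset = 2.0),
    list(type = "pi_t_shaped", residue = "TYR334", distance = 4.55),
    list(type = "hbond", residue = "TRP279", distance = 3.17),
    list(type = "weak_ch_hbond", residue = "PHE330", distance = 1.99),
    list(type = "cation_pi", residue = "PHE331", distance = 4.0)
  ), seed = 2)
  pi <- detect_pi_stacking(sc$ligand$rings, sc$receptor$rings, ligand_id = "L")
  expect_setequal(pi$type, c("pi_sandwich", "pi_parallel_displaced",
                             "pi_t_shaped"))
  expect_equal(pi$distance[pi$type == "pi_sandwich"], 3.56, tolerance = 1e-6)
  hb <- detect_hbonds(sc$ligand$atoms, sc$receptor$atoms, ligand_id = "L")
  expect_setequal(hb$type, c("hbond", "weak_ch_hbond"))
  expect_equal(hb$distance[hb$type == "hbond"], 3.17, tolerance = 1e-6)
  expect_equal(hb$distance[hb$type == "weak_ch_hbond"], 1.99, tolerance = 1e-6)
  cp <- detect_cation_pi(sc$cations, sc$receptor$rings, ligand_id = "L")
  expect_equal(nrow(cp), 1L)
  expect_equal(cp$distance, 4.0, tolerance = 1e-9)
  # empty spec -> nothing detected
  empty <- gen_site_scene(list(), seed = 1)
  expect_equal(nrow(detect_pi_stacking(empty$ligand$rings,
                                       empty$receptor$rings)), 0L)
  # infeasible geometry is refused
  expect_error(gen_site_scene(list(list(type = "pi_sandwich", residue = "X",
                                        distance = 9))), "infeasible")
})

test_that("scene files round-trip through the standard formats", {
  sc <- gen_site_scene(list(
    list(type = "pi_sandwich", residue = "PHE330", distance = 3.56)
  ), seed = 4)
  dir <- withr::local_tempdir()
  write_site_scene(sc, dir)
  rec <- read_receptor(file.path(dir, "receptor.pdb"))
  rings <- receptor_rings(rec)
  expect_length(rings, 1L)
  expect_equal(rings[[1]]$owner, "PHE330")
  lig <- read_poses(file.path(dir, "ligand.sdf"))
  expect_equal(nrow(lig$meta), 1L)
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(truth$type, "pi_sandwich")
})

test_that("synthetic activity panels use published potencies, then log-uniform fill", {
  act <- gen_activity(6, seed = 3)
  expect_equal(act$compound[1:2], c("5n", "6aa"))
  expect_equal(act$ic50_uM[1], 4.24)
  syn <- act$ic50_uM[-(1:2)]
  expect_true(all(syn >= 1 & syn <= 100))
  expect_identical(gen_activity(6, seed = 3), act)
})
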