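test_that("core RMSD matches translation geometry and a direct-sum oracle", {
  xyz <- scaffold_at(c(0, 0, 0))
  map <- default_core_map()
  expect_identical(core_rmsd(xyz, xyz, map), 0)
  shifted <- xyz + rep(c(3, 4, 0), each = nrow(xyz))
  expect_equal(core_rmsd(xyz, shifted, map), 5)
  set.seed(31)
  for (i in 1:1000) {
    a <- matrix(rnorm(15, sd = 5), 5, 3)
    b <- matrix(rnorm(15, sd = 5), 5, 3)
    rownames(a) <- rownames(b) <- paste0("A", 1:5)
    expect_equal(core_rmsd(a, b, paste0("A", 1:5)), oracle_rmsd(a, b),
                 tolerance = 1e-10)
  }
})

test_that("leader clustering recovers planted modes and matches graph truth", {
  skip_if_not_installed("mclust")
  ens <- gen_pose_ensemble(
    pose_ensemble_config(n_ligands = 4, poses_per_ligand = 12), seed = 3
  )
  for (method in c("leader", "average")) {
    cl <- cluster_poses(ens$poses, ens$map, cluster_params(), method = method)
    got <- integer(nrow(ens$poses$meta))
    for (c_ in cl) got[c_$members] <- c_$cluster_id
    truth <- ens$truth$pose_modes$mode
    expect_equal(mclust::adjustedRandIndex(got, truth), 1.0,
                 label = paste("ARI for", method))
    # brute-force threshold-graph components agree for well-separated data
    comp <- oracle_threshold_components(ens$poses, ens$map, 2.0)
    expect_equal(mclust::adjustedRandIndex(got, comp), 1.0)
  }
})

test_that("clustering is a partition, never mixes chirality, ignores input order", {
  set.seed(41)
  coords <- c(lapply(1:10, function(i) scaffold_at(c(0, 0, 0), 0.3)),
              lapply(1:10, function(i) scaffold_at(c(9, 0, 0), 0.3)))
  ps <- make_pose_set(coords, ligand_ids = rep(c("L1", "L2"), 10),
                      stereo_tags = rep(c("R", "S"), each = 10),
                      rescore = rnorm(20, -8))
  cl <- cluster_poses(ps, default_core_map(), cluster_params())
  members <- sort(unlist(lapply(cl, `[[`, "members")))
  expect_identical(members, seq_len(20L))  # exact partition
  for (c_ in cl)
    expect_length(unique(ps$meta$stereo_tag[c_$members]), 1L)
  # same poses, permuted storage order -> same partition of pose keys
  perm <- sample(20)
  ps2 <- thqche:::new_pose_set(ps$meta[perm, ], ps$coords[perm])
  cl2 <- cluster_poses(ps2, default_core_map(), cluster_params())
  keysets <- function(cls, meta) {
    s <- lapply(cls, function(c_) sort(c_$keys))
    s[order(vapply(s, `[[`, "", 1))]
  }
  expect_identical(keysets(cl, ps$meta), keysets(cl2, ps2$meta))
})

test_that("degenerate clustering cases: one pose, threshold beyond diameter", {
  one <- make_pose_set(list(scaffold_at(c(0, 0, 0))), "L1", rescore = -8)
  cl <- cluster_poses(one, default_core_map(), cluster_params())
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$population, 1L)
  set.seed(8)
  coords <- lapply(1:12, function(i) scaffold_at(runif(3, 0, 2), 0.1))
  ps <- make_pose_set(coords, rep(c("L1", "L2", "L3"), 4),
                      stereo_tags = rep(c("R", "S"), 6), rescore = rnorm(12, -8))
  cl <- cluster_poses(ps, default_core_map(), cluster_params(rmsd_threshold = 500))
  expect_length(cl, 2L)  # one per stereo tag
})

test_that("population filter applies the per-ligand minimum and top-k cap", {
  set.seed(55)
  mk_cluster_poses <- function(spec) {
    # spec: list of per-cluster named vectors ligand -> n poses
    coords <- list(); ligs <- character(0)
    centers <- seq(0, by = 30, length.out = length(spec))
    for (ci in seq_along(spec)) {
      for (lig in names(spec[[ci]])) {
        n <- spec[[ci]][[lig]]
        coords <- c(coords, lapply(seq_len(n), function(i)
          scaffold_at(c(centers[ci], 0, 0), 0.2)))
        ligs <- c(ligs, rep(lig, n))
      }
    }
    make_pose_set(coords, ligs, rescore = rnorm(length(coords), -8))
  }
  # 7 qualifying clusters (>= 10 per ligand each) -> 5 most populated kept
  spec <- lapply(1:7, function(i) c(A = 9 + i, B = 10))
  ps <- mk_cluster_poses(spec)
  cl <- cluster_poses(ps, default_core_map(), cluster_params())
  kept <- filter_top_clusters(cl, ps, cluster_params())
  expect_length(kept, 5L)
  pops <- vapply(kept, `[[`, 0L, "population")
  expect_equal(pops, sort(vapply(cl, `[[`, 0L, "population"),
                          decreasing = TRUE)[1:5])
  # a ligand contributing 9 poses at min = 10 disqualifies its cluster
  spec <- list(c(A = 9, B = 20), c(A = 10, B = 10))
  ps <- mk_cluster_poses(spec)
  cl <- cluster_poses(ps, default_core_map(), cluster_params())
  kept <- filter_top_clusters(cl, ps, cluster_params())
  expect_length(kept, 1L)
  expect_equal(sort(table(ps$meta$ligand_id[kept[[1]]$members])),
               sort(table(c(rep("A", 10), rep("B", 10)))), ignore_attr = TRUE)
  # min 1 reduces the filter to top-k by population
  kept_all <- filter_top_clusters(cl, ps, cluster_params(min_poses_per_ligand = 1))
  expect_length(kept_all, 2L)
  # nothing qualifying -> empty list, not an error
  none <- filter_top_clusters(cl, ps, cluster_params(min_poses_per_ligand = 50))
  expect_identical(none, list())
})

test_that("representative selection: lowest energy, ties by pose index, greedy gain", {
  coords <- lapply(1:6, function(i) scaffold_at(c(0, 0, 0), 0.1, seed = i))
  ps <- make_pose_set(coords, ligand_ids = rep(c("L1", "L2", "L3"), each = 2),
                      rescore = c(-8.1, -7.2, -6.5, -6.5, -7.7, -9.0))
  cl <- cluster_poses(ps, default_core_map(), cluster_params())[[1]]
  reps <- pick_representatives(cl, ps)
  expect_equal(ps$meta$rescore_dg[reps[["L1"]]], -8.1)
  # L2 poses tied on energy: the lower pose index wins deterministically
  expect_equal(ps$meta$pose_index[reps[["L2"]]], 1L)
  # greedy mode never does worse than lowest-energy on the same data
  dg_expt <- c(L1 = -8.0, L2 = -7.0, L3 = -7.5)
  r2_low <- fit_dg(ps$meta$rescore_dg[reps], dg_expt[names(reps)])$r_squared
  reps_g <- pick_representatives(cl, ps, "best_fit_greedy", dg_expt = dg_expt)
  r2_g <- fit_dg(ps$meta$rescore_dg[reps_g], dg_expt[names(reps_g)])$r_squared
  expect_gte(r2_g, r2_low)
  # missing experimental value for a covered ligand is an error
  expect_error(pick_representatives(cl, ps, "best_fit_greedy",
                                    dg_expt = dg_expt[-1]), "L1")
  ps_na <- ps; ps_na$meta$rescore_dg[1] <- NA
  cl_na <- cl
  expect_error(pick_representatives(cl_na, ps_na), "rescore_dg")
})

test_that("energy regression matches the normal equations and is affine-invariant", {
  expect_equal(fit_dg(c(1, 2, 3), c(1, 2, 3)),
               list(slope = 1, intercept = 0, r_squared = 1, n = 3L),
               tolerance = 1e-12)
  expect_error(fit_dg(c(1, 2, 3), c(2, 2, 2)), "variance")
  expect_error(fit_dg(c(1, 2), c(1, 2)), "at least 3")
  set.seed(71)
  for (i in 1:20) {
    x <- rnorm(5); y <- rnorm(5)
    got <- fit_dg(x, y)
    want <- oracle_ols(x, y)
    expect_equal(got$slope, want$slope, tolerance = 1e-10)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
    expect_equal(got$r_squared, want$r_squared, tolerance = 1e-10)
    # R^2 invariant under affine maps of the predictions
    expect_equal(fit_dg(3.7 * x - 11, y)$r_squared, got$r_squared,
                 tolerance = 1e-10)
  }
})

test_that("consensus selects the planted activity-correlated mode", {
  ens <- gen_pose_ensemble(pose_ensemble_config(), seed = 7)
  rep <- run_consensus(ens$poses, ens$map, ens$dg_expt)
  chosen <- Filter(function(c_) c_$cluster_id == rep$chosen, rep$clusters)[[1]]
  modes <- ens$truth$pose_modes$mode[chosen$members]
  expect_true(all(modes == 1L))  # pure true-mode cluster
  expect_gt(rep$ranking$r_squared[1], 0.5)
  # decoy cluster ranks below with near-zero correlation
  expect_lt(rep$ranking$r_squared[2], rep$ranking$r_squared[1])
})

test_that("shuffling the experimental energies destroys the chosen-cluster fit", {
  ens <- gen_pose_ensemble(pose_ensemble_config(), seed = 19)
  rep <- run_consensus(ens$poses, ens$map, ens$dg_expt)
  r2_true <- rep$ranking$r_squared[1]
  reps <- rep$representatives[[1]]
  pred <- ens$poses$meta$rescore_dg[reps]
  set.seed(20)
  worse <- 0L
  for (i in 1:50) {
    shuffled <- stats::setNames(sample(ens$dg_expt), names(ens$dg_expt))
    r2_null <- fit_dg(pred, shuffled[names(reps)])$r_squared
    if (r2_null < r2_true) worse <- worse + 1L
  }
  expect_gte(worse, 48L)  # >= 95% of 50 permutations
})

test_that("empty filter result yields a flagged report, not an error", {
  set.seed(77)
  coords <- lapply(1:6, function(i) scaffold_at(c(0, 0, 0), 0.2))
  ps <- make_pose_set(coords, rep(c("L1", "L2", "L3"), 2),
                      rescore = rnorm(6, -8))
  expect_warning(
    rep <- run_consensus(ps, default_core_map(),
                         c(L1 = -8, L2 = -7, L3 = -6),
                         cluster_params(min_poses_per_ligand = 100)),
    "no cluster"
  )
  expect_true(rep$empty_filter)
  expect_true(is.na(rep$chosen))
})
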