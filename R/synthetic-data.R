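# Seeded generators for every input the pipeline consumes, each with a
# ground-truth sidecar. All generators are pure functions of (config, seed):
# they save and restore the caller's RNG state.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}

#' Default core-scaffold atom names used by the pose generator
#' @return Character vector of ten atom names.
#' @export
default_core_map <- function() {
  c("C1", "C2", "C3", "C4", "N1", "O1", "C5", "C6", "N2", "O2")
}

# fixed base geometry for the abstract scaffold: a bent 10-atom chain,
# chemically meaningless but rigid and non-degenerate
core_template <- function() {
  t <- seq(0, 3 * pi / 2, length.out = 10)
  xyz <- cbind(2.5 * cos(t), 2.5 * sin(t), 0.4 * seq(0, 4.5, length.out = 10))
  rownames(xyz) <- default_core_map()
  xyz
}

#' Configuration for the synthetic pose-ensemble generator
#'
#' Defaults define the "two-mode-clean" benchmark: 12 ligands docked into
#' 2 receptor conformations, 100 retained poses per ligand spread over two
#' binding modes 8 Angstrom apart with 0.3 Angstrom isotropic jitter, and
#' rescoring energies for the true mode drawn as a linear map of the
#' experimental free energy plus noise calibrated so the planted
#' coefficient of determination is `target_r2` (0.85).
#'
#' The energy noise has two components: a per-ligand term (sd `sigma_e`,
#' or calibrated from `target_r2` when `sigma_e` is `NULL`) shared by all
#' of a ligand's true-mode poses, and a small per-pose term (`sigma_pose`).
#' Rescoring error is dominated by ligand-specific systematics, and a
#' per-ligand term is also what keeps the planted R^2 meaningful under
#' lowest-energy representative selection (a minimum over many poses would
#' otherwise shrink purely per-pose noise).
#'
#' @param n_ligands,n_receptors,poses_per_ligand,n_modes Ensemble shape.
#' @param mode_separation Distance between mode templates, Angstrom.
#' @param jitter Isotropic per-coordinate jitter sd, Angstrom.
#' @param energy_a,energy_b Linear map dG_true = a dG_expt + b, kcal/mol.
#' @param sigma_e Per-ligand energy noise sd (kcal/mol), or `NULL` to
#'   calibrate from `target_r2` against the realized dG_expt spread.
#' @param target_r2 Planted population R^2 used when `sigma_e` is `NULL`.
#' @param sigma_pose Per-pose energy noise sd, kcal/mol.
#' @param decoy_offset Decoy-mode energies sit this many kcal/mol above the
#'   mean true-mode energy (uncorrelated with activity).
#' @param decoy_sd Sd of the decoy energy noise, kcal/mol.
#' @param stereo_tag Chirality label given to all generated poses.
#' @return A `pose_ensemble_config` list.
#' @export
pose_ensemble_config <- function(n_ligands = 12L, n_receptors = 2L,
                                 poses_per_ligand = 100L, n_modes = 2L,
                                 mode_separation = 8, jitter = 0.3,
                                 energy_a = 1, energy_b = 0,
                                 sigma_e = NULL, target_r2 = 0.85,
                                 sigma_pose = 0.05,
                                 decoy_offset = 3, decoy_sd = 0.5,
                                 stereo_tag = "R") {
  stopifnot(n_ligands >= 1, n_receptors >= 1, poses_per_ligand >= 1,
            n_modes >= 1, mode_separation > 0, jitter >= 0,
            is.null(sigma_e) || sigma_e >= 0,
            target_r2 > 0, target_r2 < 1)
  if (n_modes > 1 && mode_separation <= 4 * jitter)
    stop("modes are not well separated: require separation > 4 * jitter",
         call. = FALSE)
  structure(list(n_ligands = as.integer(n_ligands),
                 n_receptors = as.integer(n_receptors),
                 poses_per_ligand = as.integer(poses_per_ligand),
                 n_modes = as.integer(n_modes),
                 mode_separation = mode_separation, jitter = jitter,
                 energy_a = energy_a, energy_b = energy_b,
                 sigma_e = sigma_e, target_r2 = target_r2,
                 sigma_pose = sigma_pose, decoy_offset = decoy_offset,
                 decoy_sd = decoy_sd, stereo_tag = stereo_tag),
            class = "pose_ensemble_config")
}

#' Synthetic activity table for generated ligand panels
#'
#' Uses the published IC50 values for the compounds that have them (for
#' AChE: 5n, plus 6aa's value back-derived from its selectivity index) and
#' pads the panel with synthetic ligands whose IC50s are drawn log-uniform
#' between 1 and 100 uM.
#'
#' @param n_ligands Panel size.
#' @param seed RNG seed.
#' @param target `"AChE"` or `"BChE"`.
#' @return data.frame with `compound`, `ic50_uM`, `dg` (kcal/mol at
#'   298.15 K).
#' @export
gen_activity <- function(n_ligands, seed = 1L, target = "AChE") {
  act <- activity_table()
  real <- act[act$target == target & !is.na(act$ic50_uM), ]
  real <- real[real$compound != "galantamine", ]  # reference drug, not a ligand
  with_seed(seed, {
    n_real <- min(nrow(real), n_ligands)
    ids <- real$compound[seq_len(n_real)]
    ic50 <- real$ic50_uM[seq_len(n_real)]
    n_syn <- n_ligands - n_real
    if (n_syn > 0) {
      ids <- c(ids, sprintf("syn%02d", seq_len(n_syn)))
      ic50 <- c(ic50, 10^stats::runif(n_syn, 0, 2))  # 1-100 uM log-uniform
    }
    data.frame(compound = ids, target = target, ic50_uM = ic50,
               dg = ic50_to_dg(ic50 * 1e-6)$dg, stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic docking pose ensemble with planted binding modes
#'
#' Produces an in-memory `pose_set` plus a ground-truth sidecar. Poses of
#' each ligand are split evenly over `n_modes` mode templates (mode 1 is
#' the true, activity-correlated mode) translated `mode_separation`
#' Angstrom apart, with isotropic Gaussian jitter. True-mode poses carry
#' `rescore_dg = a dG_expt + b + noise`; decoy-mode poses get offset,
#' activity-uncorrelated energies. Docking scores are a noisy rescaling of
#' the rescoring energies. Deterministic per seed.
#'
#' @param cfg A [pose_ensemble_config()].
#' @param activity data.frame as from [gen_activity()]; its first
#'   `n_ligands` rows define the panel. Defaults to
#'   `gen_activity(cfg$n_ligands, seed)`.
#' @param seed RNG seed.
#' @return List with `poses` (`pose_set`), `activity`, `dg_expt` (named
#'   vector), `truth` (list: `pose_modes` data.frame, `energy_model`,
#'   `config_hash`), and `map` (the core atom names).
#' @export
gen_pose_ensemble <- function(cfg = pose_ensemble_config(), activity = NULL,
                              seed = 1L) {
  if (is.null(activity)) activity <- gen_activity(cfg$n_ligands, seed)
  if (nrow(activity) < cfg$n_ligands)
    stop("activity table has fewer rows than n_ligands", call. = FALSE)
  activity <- activity[seq_len(cfg$n_ligands), ]
  with_seed(seed + 1L, {
    base <- core_template()
    modes <- lapply(seq_len(cfg$n_modes), function(m)
      sweep(base, 2, c((m - 1) * cfg$mode_separation, 0, 0), `+`))
    dg <- stats::setNames(activity$dg, activity$compound)
    sigma_e <- cfg$sigma_e
    if (is.null(sigma_e)) {
      s <- stats::sd(cfg$energy_a * dg)
      sigma_e <- s * sqrt((1 - cfg$target_r2) / cfg$target_r2)
    }
    eps_lig <- stats::rnorm(cfg$n_ligands, 0, sigma_e)
    true_mean <- mean(cfg$energy_a * dg + cfg$energy_b)
    per_mode <- diff(round(seq(0, cfg$poses_per_ligand,
                               length.out = cfg$n_modes + 1)))
    metas <- list()
    coords <- list()
    truth_rows <- list()
    for (li in seq_len(cfg$n_ligands)) {
      lig <- activity$compound[li]
      pidx <- 0L
      for (m in seq_len(cfg$n_modes)) {
        for (j in seq_len(per_mode[m])) {
          pidx <- pidx + 1L
          xyz <- modes[[m]] + matrix(stats::rnorm(30, 0, cfg$jitter), 10, 3)
          rownames(xyz) <- default_core_map()
          attr(xyz, "elements") <- substr(default_core_map(), 1, 1)
          rescore <- if (m == 1)
            cfg$energy_a * dg[[lig]] + cfg$energy_b + eps_lig[li] +
              stats::rnorm(1, 0, cfg$sigma_pose)
          else
            true_mean + cfg$decoy_offset + stats::rnorm(1, 0, cfg$decoy_sd)
          dock <- 0.8 * rescore + stats::rnorm(1, 0, 0.3)
          k <- length(metas) + 1L
          metas[[k]] <- data.frame(
            ligand_id = lig, stereo_tag = cfg$stereo_tag,
            receptor_id = sprintf("rec%02d", 1L + (pidx - 1L) %% cfg$n_receptors),
            pose_index = pidx, docking_score = dock, rescore_dg = rescore,
            stringsAsFactors = FALSE
          )
          coords[[k]] <- xyz
          truth_rows[[k]] <- data.frame(ligand_id = lig, pose_index = pidx,
                                        mode = m, is_true_mode = m == 1L)
        }
      }
    }
    meta <- do.call(rbind, metas)
    truth <- list(
      pose_modes = do.call(rbind, truth_rows),
      energy_model = list(a = cfg$energy_a, b = cfg$energy_b,
                          sigma_e = sigma_e, sigma_pose = cfg$sigma_pose,
                          target_r2 = cfg$target_r2),
      config_hash = config_hash(cfg)
    )
    list(poses = new_pose_set(meta, coords), activity = activity,
         dg_expt = dg, truth = truth, map = default_core_map())
  })
}

#' Write a generated pose ensemble to files
#'
#' Emits `poses.sdf`, `scores.tsv`, `core_map.txt`, `activity.tsv`,
#' receptor PDB stubs, and `truth.tsv` + `truth.json` sidecars into a
#' directory. The SDF header line carries the generator config hash.
#'
#' @param ens Output of [gen_pose_ensemble()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pose_ensemble <- function(ens, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_poses(ens$poses, file.path(dir, "poses.sdf"),
              header = paste0("config:", ens$truth$config_hash))
  sc <- ens$poses$meta
  utils::write.table(sc, file.path(dir, "scores.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeLines(ens$map, file.path(dir, "core_map.txt"))
  utils::write.table(ens$activity, file.path(dir, "activity.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (rid in unique(sc$receptor_id)) {
    write_receptor(synthetic_receptor(rid), file.path(dir, paste0(rid, ".pdb")))
  }
  utils::write.table(ens$truth$pose_modes, file.path(dir, "truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(ens$truth$energy_model, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# minimal rigid 3-residue receptor stub sharing one frame across ids
synthetic_receptor <- function(id = "rec01") {
  atoms <- data.frame(
    name = rep(c("N", "CA", "C", "O"), 3),
    element = rep(c("N", "C", "C", "O"), 3),
    resname = rep(c("GLY", "ALA", "GLY"), each = 4),
    resno = rep(1:3, each = 4), chain = "A", insert = "",
    x = rep(c(0, 1.46, 2.0, 3.2), 3) + rep((0:2) * 3.8, each = 4),
    y = rep(c(0, 0.5, 1.9, 2.1), 3),
    z = rep(c(0, -0.4, 0.2, 0.1), 3),
    stringsAsFactors = FALSE
  )
  structure(list(id = id, atoms = atoms), class = "receptor")
}

#' Default kinetics assay design
#'
#' Eight substrate concentrations log-spaced over 3.75e-3 to 0.48 mM and
#' inhibitor levels at 0, half, and the full IC50 of the probe compound
#' (4.24 uM by default, giving 0/2.12/4.24).
#'
#' @param ic50_uM Probe IC50 setting the inhibitor levels.
#' @return List with `S_mM` and `I_uM` vectors.
#' @export
kinetics_design <- function(ic50_uM = 4.24) {
  list(S_mM = exp(seq(log(3.75e-3), log(0.48), length.out = 8)),
       I_uM = c(0, ic50_uM / 2, ic50_uM))
}

#' Generate a synthetic kinetics dataset
#'
#' Velocities are the model rates perturbed by multiplicative Gaussian
#' noise, `v = rate (1 + N(0, cv^2))`, clipped at zero -- absorbance-rate
#' noise scales with signal. Deterministic per seed.
#'
#' @param model An [inhibition_model()] (the generating truth).
#' @param design List with `S_mM`, `I_uM` (default [kinetics_design()]).
#' @param cv Coefficient of variation of the noise (default 0.02).
#' @param replicates Replicates per (S, I) cell.
#' @param seed RNG seed.
#' @return List with `data` (data.frame `S_mM`, `I_uM`, `v`, `replicate`)
#'   and `truth` (generating model, cv, config hash).
#' @export
gen_kinetics <- function(model, design = kinetics_design(), cv = 0.02,
                         replicates = 3L, seed = 1L) {
  grid <- expand.grid(replicate = seq_len(replicates), S_mM = design$S_mM,
                      I_uM = design$I_uM)[, c("S_mM", "I_uM", "replicate")]
  with_seed(seed, {
    rate <- model_rate(model, grid$S_mM, grid$I_uM)
    v <- pmax(0, rate * (1 + stats::rnorm(nrow(grid), 0, cv)))
    data <- data.frame(grid, v = v)
    list(data = data[, c("S_mM", "I_uM", "v", "replicate")],
         truth = list(model = unclass(model), cv = cv,
                      config_hash = config_hash(list(model = unclass(model),
                                                     design = design, cv = cv,
                                                     replicates = replicates))))
  })
}

#' Generate a synthetic dose-response dataset
#'
#' Five (by default) log-spaced concentrations bracketing the true IC50,
#' with additive Gaussian noise on the percent-inhibition scale.
#'
#' @param ic50 True IC50, uM.
#' @param hill,top,bottom True 4PL parameters.
#' @param concs Concentrations, uM; default `ic50 * 10^seq(-1, 1, length 5)`.
#' @param sd Noise sd in percentage points (default 3).
#' @param seed RNG seed.
#' @return List with `concs`, `inhibition`, `truth`.
#' @export
gen_dose_response <- function(ic50, hill = 1, top = 100, bottom = 0,
                              concs = NULL, sd = 3, seed = 1L) {
  if (is.null(concs)) concs <- ic50 * 10^seq(-1, 1, length.out = 5)
  with_seed(seed, {
    y <- bottom + (top - bottom) / (1 + (ic50 / concs)^hill)
    inhibition <- y + stats::rnorm(length(concs), 0, sd)
    list(concs = concs, inhibition = inhibition,
         truth = list(ic50 = ic50, hill = hill, top = top, bottom = bottom,
                      sd = sd))
  })
}

#' Construct a synthetic binding-site scene with planted contacts
#'
#' Builds coordinates in which each requested contact satisfies its
#' detection criteria exactly at the stated geometry, plus distractor atoms
#' far outside every cutoff. The ligand contributes one aromatic six-ring
#' at the origin (plane z = 0); each contact gets its own spatial sector so
#' planted contacts do not interfere. Supported types and their spec
#' fields:
#'
#' * `pi_sandwich` / `pi_parallel_displaced` / `pi_t_shaped`: `residue`
#'   (e.g. `"PHE330"`), `distance` (centroid-centroid), optional `offset`
#'   (lateral, parallel-displaced only; default 2.5).
#' * `hbond`: receptor N-H donor to a dedicated ligand acceptor O;
#'   `distance` is donor-acceptor.
#' * `weak_ch_hbond`: receptor aromatic C-H donor to a ligand acceptor O;
#'   `distance` is H-acceptor.
#' * `cation_pi`: cation placed `distance` along the ligand ring normal.
#'
#' A request whose geometry violates its own class criteria (infeasible
#' spec) is an error.
#'
#' @param contacts List of contact specs (lists with `type`, `residue`,
#'   `distance`, ...).
#' @param n_distractors Number of far-away carbon atoms added to the
#'   receptor.
#' @param seed RNG seed (used for distractor placement).
#' @return A `site_scene`: list with `ligand` (atoms data.frame, `rings`),
#'   `receptor` (atoms data.frame, `rings`), `cations` (matrix), `truth`
#'   (data.frame of planted contacts), `config_hash`.
#' @export
gen_site_scene <- function(contacts, n_distractors = 20L, seed = 1L) {
  cut <- interaction_cutoffs()
  hexagon <- function(center, radius = 1.39, axis = c(0, 0, 1)) {
    ang <- seq(0, 2 * pi, length.out = 7)[-7]
    flat <- cbind(radius * cos(ang), radius * sin(ang), 0)
    R <- rotation_to(c(0, 0, 1), axis)
    sweep(flat %*% t(R), 2, center, `+`)
  }
  lig_ring_xyz <- hexagon(c(0, 0, 0))
  rownames(lig_ring_xyz) <- paste0("LC", 1:6)
  lig_atoms <- data.frame(name = rownames(lig_ring_xyz), element = "C",
                          x = lig_ring_xyz[, 1], y = lig_ring_xyz[, 2],
                          z = lig_ring_xyz[, 3], is_aromatic = TRUE,
                          stringsAsFactors = FALSE)
  rec_atoms <- list()
  rec_rings <- list()
  cations <- NULL
  truth <- list()
  resno <- 0L
  # each contact lives in its own sector: planted geometries never interact
  sector <- function(i) {
    th <- (i - 1) * 2 * pi / max(8, length(contacts))
    c(cos(th), sin(th), 0)
  }
  add_rec_atoms <- function(df) rec_atoms[[length(rec_atoms) + 1L]] <<- df
  for (i in seq_along(contacts)) {
    sp <- contacts[[i]]
    resno <- resno + 1L
    rn <- if (!is.null(sp$residue)) sp$residue else sprintf("RES%d", resno)
    resname <- gsub("[0-9]", "", rn)
    rnum <- suppressWarnings(as.integer(gsub("[^0-9]", "", rn)))
    if (is.na(rnum)) rnum <- resno
    if (sp$type %in% c("pi_sandwich", "pi_parallel_displaced", "pi_t_shaped")) {
      d <- sp$distance
      if (sp$type == "pi_sandwich") {
        if (d > cut$pi_parallel_max_dist)
          stop("infeasible sandwich contact: distance ", d, " exceeds cutoff",
               call. = FALSE)
        center <- c(0, 0, d)
        axis <- c(0, 0, 1)
      } else if (sp$type == "pi_parallel_displaced") {
        off <- if (!is.null(sp$offset)) sp$offset else 2.5
        if (d > cut$pi_parallel_max_dist || off <= cut$pi_sandwich_max_offset ||
            off > cut$pi_displaced_max_offset || off >= d)
          stop("infeasible parallel-displaced contact", call. = FALSE)
        center <- c(off, 0, sqrt(d^2 - off^2))
        axis <- c(0, 0, 1)
      } else {
        if (d > cut$pi_t_max_dist)
          stop("infeasible t-shaped contact: distance ", d, " exceeds cutoff",
               call. = FALSE)
        center <- c(0, 0, d)
        axis <- c(1, 0, 0)  # perpendicular ring
      }
      xyz <- hexagon(center, axis = axis)
      nm <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
      add_rec_atoms(data.frame(name = nm, element = "C", resname = resname,
                               resno = rnum, x = xyz[, 1], y = xyz[, 2],
                               z = xyz[, 3], is_aromatic = TRUE,
                               stringsAsFactors = FALSE))
      rec_rings[[length(rec_rings) + 1L]] <-
        ring_geometry(xyz, owner = rn)
    } else if (sp$type == "hbond") {
      d <- sp$distance
      if (d > cut$hbond_max_da)
        stop("infeasible hbond: donor-acceptor distance ", d, " exceeds cutoff",
             call. = FALSE)
      p <- 8 * sector(i)  # dedicated ligand acceptor, well away from the ring
      lig_atoms <- rbind(lig_atoms,
                         data.frame(name = sprintf("LO%d", i), element = "O",
                                    x = p[1], y = p[2], z = p[3],
                                    is_aromatic = FALSE))
      D <- p + c(0, 0, d)
      H <- D - c(0, 0, 1.0)  # colinear D-H...A
      add_rec_atoms(data.frame(name = c("NE1", "HE1"), element = c("N", "H"),
                               resname = resname, resno = rnum,
                               x = c(D[1], H[1]), y = c(D[2], H[2]),
                               z = c(D[3], H[3]), is_aromatic = FALSE,
                               stringsAsFactors = FALSE))
    } else if (sp$type == "weak_ch_hbond") {
      d <- sp$distance
      if (d > cut$weak_hbond_max_ha)
        stop("infeasible weak hbond: H-acceptor distance ", d,
             " exceeds cutoff", call. = FALSE)
      p <- 8 * sector(i)
      lig_atoms <- rbind(lig_atoms,
                         data.frame(name = sprintf("LO%d", i), element = "O",
                                    x = p[1], y = p[2], z = p[3],
                                    is_aromatic = FALSE))
      H <- p + c(0, 0, d)
      C <- H + c(0, 0, 1.09)
      add_rec_atoms(data.frame(name = c("CD1", "HD1"), element = c("C", "H"),
                               resname = resname, resno = rnum,
                               x = c(C[1], H[1]), y = c(C[2], H[2]),
                               z = c(C[3], H[3]), is_aromatic = TRUE,
                               stringsAsFactors = FALSE))
    } else if (sp$type == "cation_pi") {
      # ligand cation against a receptor aromatic ring (the ring owner is
      # the residue reported for the contact)
      d <- sp$distance
      if (d > cut$cation_pi_max_dist)
        stop("infeasible cation-pi: distance ", d, " exceeds cutoff",
             call. = FALSE)
      center <- 15 * sector(i)  # outside every ring-ring cutoff
      xyz <- hexagon(center, axis = c(0, 0, 1))
      nm <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
      add_rec_atoms(data.frame(name = nm, element = "C", resname = resname,
                               resno = rnum, x = xyz[, 1], y = xyz[, 2],
                               z = xyz[, 3], is_aromatic = TRUE,
                               stringsAsFactors = FALSE))
      rec_rings[[length(rec_rings) + 1L]] <- ring_geometry(xyz, owner = rn)
      cat_xyz <- matrix(center + c(0, 0, d), 1, 3,
                        dimnames = list("LIG:N+", NULL))
      cations <- rbind(cations, cat_xyz)
    } else {
      stop("unknown contact type: ", sp$type, call. = FALSE)
    }
    truth[[length(truth) + 1L]] <- data.frame(type = sp$type, residue = rn,
                                              distance = sp$distance,
                                              stringsAsFactors = FALSE)
  }
  scene <- with_seed(seed, {
    if (n_distractors > 0) {
      u <- matrix(stats::rnorm(3 * n_distractors), ncol = 3)
      u <- u / sqrt(rowSums(u^2)) * (25 + stats::runif(n_distractors, 0, 10))
      add_rec_atoms(data.frame(name = sprintf("DX%d", seq_len(n_distractors)),
                               element = "C", resname = "DST",
                               resno = 900L + seq_len(n_distractors),
                               x = u[, 1], y = u[, 2], z = u[, 3],
                               is_aromatic = FALSE, stringsAsFactors = FALSE))
    }
    rec <- if (length(rec_atoms)) do.call(rbind, rec_atoms)
           else data.frame(name = character(0), element = character(0),
                           resname = character(0), resno = integer(0),
                           x = numeric(0), y = numeric(0), z = numeric(0),
                           is_aromatic = logical(0))
    list(
      ligand = list(atoms = lig_atoms,
                    rings = list(ring_geometry(lig_ring_xyz, owner = "ligand"))),
      receptor = list(atoms = rec, rings = rec_rings),
      cations = cations,
      truth = if (length(truth)) do.call(rbind, truth)
              else data.frame(type = character(0), residue = character(0),
                              distance = numeric(0)),
      config_hash = config_hash(list(contacts = contacts,
                                     n_distractors = n_distractors))
    )
  })
  structure(scene, class = "site_scene")
}

# rotation matrix taking unit vector a to unit vector b
rotation_to <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (abs(c_ + 1) < 1e-12) {  # antiparallel: rotate pi about any orthogonal
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Write a site scene to receptor PDB and ligand SDF files
#'
#' @param scene A `site_scene` from [gen_site_scene()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_site_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ra <- scene$receptor$atoms
  rec <- structure(list(id = "site", atoms = data.frame(
    name = ra$name, element = ra$element, resname = ra$resname,
    resno = ra$resno, chain = "A", insert = "",
    x = ra$x, y = ra$y, z = ra$z, stringsAsFactors = FALSE
  )), class = "receptor")
  write_receptor(rec, file.path(dir, "receptor.pdb"))
  la <- scene$ligand$atoms
  xyz <- as.matrix(la[, c("x", "y", "z")])
  rownames(xyz) <- la$name
  attr(xyz, "elements") <- la$element
  ps <- new_pose_set(data.frame(ligand_id = "scene_ligand", stereo_tag = "R",
                                receptor_id = "site", pose_index = 1L,
                                docking_score = 0, rescore_dg = NA_real_,
                                stringsAsFactors = FALSE),
                     list(xyz))
  write_poses(ps, file.path(dir, "ligand.sdf"),
              header = paste0("config:", scene$config_hash))
  utils::write.table(scene$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
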