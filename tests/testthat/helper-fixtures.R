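# small builders shared across test files

new_formula_for_test <- function(els, counts) {
  parse_formula(paste0(els, counts, collapse = ""))
}

# a pose_set built directly from a list of coordinate matrices
make_pose_set <- function(coord_list, ligand_ids, stereo_tags = "R",
                          receptor_ids = "rec01", rescore = NA_real_,
                          docking = -8) {
  n <- length(coord_list)
  meta <- data.frame(
    ligand_id = rep_len(ligand_ids, n),
    stereo_tag = rep_len(stereo_tags, n),
    receptor_id = rep_len(receptor_ids, n),
    pose_index = stats::ave(seq_len(n), rep_len(ligand_ids, n),
                            FUN = seq_along),
    docking_score = rep_len(docking, n),
    rescore_dg = rep_len(rescore, n),
    stringsAsFactors = FALSE
  )
  coords <- lapply(coord_list, function(xyz) {
    xyz <- as.matrix(xyz)
    if (is.null(attr(xyz, "elements")))
      attr(xyz, "elements") <- substr(rownames(xyz), 1, 1)
    xyz
  })
  thqche:::new_pose_set(meta, coords)
}

# named k-atom scaffold at a given center with optional jitter
scaffold_at <- function(center, jitter = 0, seed = NULL, names = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names)) names <- default_core_map()
  k <- length(names)
  base <- cbind(seq_len(k), (seq_len(k) %% 3), 0.5 * seq_len(k))
  xyz <- sweep(base, 2, center, `+`)
  if (jitter > 0) xyz <- xyz + matrix(rnorm(3 * k, 0, jitter), k, 3)
  rownames(xyz) <- names
  xyz
}

# hexagonal ring coordinates: radius r, centered at c, normal along axis
hexagon_at <- function(center = c(0, 0, 0), radius = 1.39, axis = c(0, 0, 1)) {
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  flat <- cbind(radius * cos(ang), radius * sin(ang), 0)
  R <- thqche:::rotation_to(c(0, 0, 1), axis)
  sweep(flat %*% t(R), 2, center, `+`)
}
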