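#' Geometric cutoffs for interaction detection
#'
#' The detection thresholds follow common published conventions for
#' protein-ligand fingerprinting; reported literature distances for this
#' compound class (e.g. pi-stacking at 3.56, 4.10, 4.55, 4.92 Angstrom and
#' H-bonds at 1.99-3.17 Angstrom) all fall inside these windows, which the
#' test suite asserts. All values live in this one block so they can be
#' overridden coherently.
#'
#' @param pi_parallel_max_angle Max interplanar angle (deg) for the
#'   parallel (sandwich / parallel-displaced) classes.
#' @param pi_parallel_max_dist Max centroid-centroid distance (Angstrom).
#' @param pi_sandwich_max_offset Max lateral offset (Angstrom) for sandwich.
#' @param pi_displaced_max_offset Max lateral offset for parallel-displaced.
#' @param pi_t_min_angle,pi_t_max_angle Interplanar angle window (deg) for
#'   T-shaped.
#' @param pi_t_max_dist Max centroid distance (Angstrom) for T-shaped.
#' @param hbond_max_da H-bond donor-acceptor distance cutoff (Angstrom).
#' @param hbond_min_angle D-H...A angle cutoff (deg).
#' @param weak_hbond_max_ha Weak (aromatic C-H) H...A distance cutoff.
#' @param weak_hbond_min_angle Weak H-bond angle cutoff (deg).
#' @param cation_pi_max_dist Cation-centroid distance cutoff (Angstrom).
#' @param cation_pi_max_angle Max angle (deg) between centroid-to-cation
#'   vector and the ring normal.
#' @param ring_planarity_tol Max out-of-plane deviation (Angstrom) accepted
#'   by [ring_geometry()].
#' @return Named list of cutoffs.
#' @export
interaction_cutoffs <- function(pi_parallel_max_angle = 30,
                                pi_parallel_max_dist = 5.5,
                                pi_sandwich_max_offset = 1.5,
                                pi_displaced_max_offset = 4.0,
                                pi_t_min_angle = 60, pi_t_max_angle = 90,
                                pi_t_max_dist = 6.0,
                                hbond_max_da = 3.5, hbond_min_angle = 120,
                                weak_hbond_max_ha = 3.0,
                                weak_hbond_min_angle = 110,
                                cation_pi_max_dist = 6.0,
                                cation_pi_max_angle = 45,
                                ring_planarity_tol = 0.3) {
  as.list(environment())
}

#' Ring centroid and plane normal
#'
#' Builds a `ring` from 5 or 6 near-coplanar atom coordinates: centroid is
#' the coordinate mean, normal the least-squares plane normal (smallest
#' principal direction of the centered coordinates), sign-canonicalized
#' toward +z, ties broken toward +x then +y.
#'
#' @param atoms n x 3 coordinate matrix, n in {5, 6}.
#' @param owner Optional label (e.g. `"Phe330"` or a ligand id).
#' @param planarity_tol Max out-of-plane deviation in Angstrom (default from
#'   [interaction_cutoffs()]).
#' @return A `ring`: list with `owner`, `atoms`, `centroid`, `normal`.
#' @export
ring_geometry <- function(atoms, owner = NULL,
                          planarity_tol = interaction_cutoffs()$ring_planarity_tol) {
  atoms <- as.matrix(atoms)
  if (!nrow(atoms) %in% c(5L, 6L))
    stop("a ring has 5 or 6 atoms, got ", nrow(atoms), call. = FALSE)
  centroid <- colMeans(atoms)
  centered <- sweep(atoms, 2, centroid)
  sv <- svd(centered)
  normal <- sv$v[, 3]
  dev <- abs(centered %*% normal)
  if (max(dev) > planarity_tol)
    stop("ring atoms deviate from planarity by ", round(max(dev), 3),
         " A (tolerance ", planarity_tol, ")", call. = FALSE)
  tol <- 1e-9
  flip <- if (abs(normal[3]) > tol) normal[3] < 0
          else if (abs(normal[1]) > tol) normal[1] < 0
          else normal[2] < 0
  if (flip) normal <- -normal
  structure(list(owner = owner, atoms = atoms,
                 centroid = as.numeric(centroid), normal = as.numeric(normal)),
            class = "ring")
}

vec_angle_deg <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Classify an aromatic ring pair
#'
#' Assigns the pi-stacking class of two rings from centroid distance d,
#' interplanar angle theta (folded to 0-90 deg) and lateral centroid
#' offset: sandwich (theta small, small offset), parallel-displaced (theta
#' small, larger offset) or T-shaped (theta near perpendicular), or `NULL`
#' when no criterion is met. The offset is the mean of the displacement
#' projections into each ring's plane, making the parallel classes exactly
#' symmetric in their arguments.
#'
#' @param a,b `ring` objects.
#' @param cutoffs Cutoff block from [interaction_cutoffs()].
#' @return A list (contact record) with `type` (`"pi_sandwich"`,
#'   `"pi_parallel_displaced"` or `"pi_t_shaped"`), `distance` (centroid-
#'   centroid, Angstrom), `angle` (deg), `offset` (Angstrom), `owner_a`,
#'   `owner_b`; or `NULL`.
#' @export
classify_ring_pair <- function(a, b, cutoffs = interaction_cutoffs()) {
  v <- b$centroid - a$centroid
  d <- sqrt(sum(v^2))
  theta <- vec_angle_deg(a$normal, b$normal)
  if (theta > 90) theta <- 180 - theta
  off_a <- sqrt(max(0, sum(v^2) - sum(v * a$normal)^2))
  off_b <- sqrt(max(0, sum(v^2) - sum(v * b$normal)^2))
  offset <- (off_a + off_b) / 2
  type <- NULL
  if (theta <= cutoffs$pi_parallel_max_angle && d <= cutoffs$pi_parallel_max_dist) {
    if (offset <= cutoffs$pi_sandwich_max_offset) type <- "pi_sandwich"
    else if (offset <= cutoffs$pi_displaced_max_offset) type <- "pi_parallel_displaced"
  } else if (theta >= cutoffs$pi_t_min_angle && theta <= cutoffs$pi_t_max_angle &&
             d <= cutoffs$pi_t_max_dist) {
    type <- "pi_t_shaped"
  }
  if (is.null(type)) return(NULL)
  list(type = type, distance = d, angle = theta, offset = offset,
       owner_a = a$owner, owner_b = b$owner)
}

# split an atom table into donor triples (D,H) and acceptor rows.
# typing rules: N/O with a covalently attached H (< 1.2 A) donate; N/O
# accept; aromatic carbons (is_aromatic flag) with attached H are weak
# donors. No bond-order perception.
hb_typing <- function(atoms) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  is_h <- atoms$element == "H"
  heavy <- which(!is_h)
  hs <- which(is_h)
  donors <- list()
  for (i in heavy) {
    el <- atoms$element[i]
    aromatic_c <- el == "C" && isTRUE(atoms$is_aromatic[i])
    if (!el %in% c("N", "O") && !aromatic_c) next  # plain C-H never donates
    if (length(hs)) {
      dh <- sqrt(rowSums(sweep(xyz[hs, , drop = FALSE], 2, xyz[i, ])^2))
      for (j in hs[dh < 1.2]) {
        donors[[length(donors) + 1L]] <- list(d = i, h = j, element = el,
                                              weak = aromatic_c)
      }
    }
  }
  acceptors <- heavy[atoms$element[heavy] %in% c("N", "O")]
  list(donors = donors, acceptors = acceptors, xyz = xyz)
}

#' Detect hydrogen bonds between a ligand pose and a receptor
#'
#' Donor/acceptor typing is rule-based (no bond-order perception): N or O
#' bearing an explicit hydrogen within 1.2 Angstrom donates, N and O
#' accept, and aromatic carbons (rows flagged `is_aromatic`) with a
#' hydrogen act as weak donors. A conventional H-bond requires
#' donor-acceptor distance <= 3.5 Angstrom and D-H...A angle >= 120 deg and
#' reports the donor-acceptor distance; a weak C-H bond requires H...A <=
#' 3.0 Angstrom and angle >= 110 deg and reports the H...A distance. The
#' `distance_convention` field makes the reported convention explicit,
#' and `distance_da`/`distance_ha` always carry both values. Both
#' ligand-to-receptor and receptor-to-ligand directions are scanned.
#'
#' @param ligand_atoms data.frame with `name`, `element`, `x`, `y`, `z` and
#'   optional logical `is_aromatic`; explicit hydrogens required for any
#'   donor role.
#' @param receptor_atoms Same shape, plus `resname` and `resno`.
#' @param cutoffs Cutoff block from [interaction_cutoffs()].
#' @param ligand_id Label copied into the contact records.
#' @return data.frame of contacts: `type` (`"hbond"`/`"weak_ch_hbond"`),
#'   `ligand_id`, `residue`, `distance`, `distance_convention`,
#'   `distance_da`, `distance_ha`, `angle`, `donor_side`.
#' @export
detect_hbonds <- function(ligand_atoms, receptor_atoms,
                          cutoffs = interaction_cutoffs(), ligand_id = NA) {
  lt <- hb_typing(ligand_atoms)
  rt <- hb_typing(receptor_atoms)
  res_label <- function(i) paste0(receptor_atoms$resname[i], receptor_atoms$resno[i])
  out <- list()
  scan <- function(dt, at, d_xyz, a_xyz, donor_side, res_of) {
    for (don in dt$donors) {
      D <- d_xyz[don$d, ]; H <- d_xyz[don$h, ]
      for (ai in at) {
        A <- a_xyz[ai, ]
        d_da <- sqrt(sum((D - A)^2))
        d_ha <- sqrt(sum((H - A)^2))
        ang <- vec_angle_deg(D - H, A - H)
        rec <- NULL
        if (!don$weak && d_da <= cutoffs$hbond_max_da &&
            ang >= cutoffs$hbond_min_angle) {
          rec <- list(type = "hbond", distance = d_da, convention = "donor-acceptor")
        } else if (don$weak && d_ha <= cutoffs$weak_hbond_max_ha &&
                   ang >= cutoffs$weak_hbond_min_angle) {
          rec <- list(type = "weak_ch_hbond", distance = d_ha,
                      convention = "hydrogen-acceptor")
        }
        if (!is.null(rec)) {
          out[[length(out) + 1L]] <<- data.frame(
            type = rec$type, ligand_id = ligand_id,
            residue = res_of(don, ai), distance = rec$distance,
            distance_convention = rec$convention,
            distance_da = d_da, distance_ha = d_ha, angle = ang,
            donor_side = donor_side, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  scan(lt, rt$acceptors, lt$xyz, rt$xyz, "ligand",
       function(don, ai) res_label(ai))
  scan(rt, lt$acceptors, rt$xyz, lt$xyz, "receptor",
       function(don, ai) res_label(don$d))
  if (!length(out))
    return(data.frame(type = character(0), ligand_id = character(0),
                      residue = character(0), distance = numeric(0),
                      distance_convention = character(0),
                      distance_da = numeric(0), distance_ha = numeric(0),
                      angle = numeric(0), donor_side = character(0)))
  do.call(rbind, out)
}

#' Detect cation-pi contacts
#'
#' A contact is recorded when a cation center (protonated amine nitrogen or
#' guanidinium centroid, supplied by the caller) lies within the distance
#' cutoff of a ring centroid and the centroid-to-cation vector makes at
#' most the angle cutoff with the ring normal (folded, so either face
#' counts). A cation in the ring plane (angle 90 deg) never qualifies.
#'
#' @param cations n x 3 matrix of cation-center coordinates (rownames used
#'   as labels when present).
#' @param rings List of `ring` objects.
#' @param cutoffs Cutoff block.
#' @param ligand_id Label copied into the records.
#' @return data.frame with `type` (`"cation_pi"`), `ligand_id`, `residue`
#'   (ring owner), `cation`, `distance`, `angle`.
#' @export
detect_cation_pi <- function(cations, rings,
                             cutoffs = interaction_cutoffs(), ligand_id = NA) {
  cations <- matrix(as.matrix(cations), ncol = 3,
                    dimnames = list(rownames(cations), NULL))
  out <- list()
  for (ci in seq_len(nrow(cations))) {
    for (rg in rings) {
      v <- cations[ci, ] - rg$centroid
      d <- sqrt(sum(v^2))
      if (d > cutoffs$cation_pi_max_dist) next
      ang <- vec_angle_deg(v, rg$normal)
      if (ang > 90) ang <- 180 - ang
      if (ang > cutoffs$cation_pi_max_angle) next
      out[[length(out) + 1L]] <- data.frame(
        type = "cation_pi", ligand_id = ligand_id,
        residue = if (is.null(rg$owner)) NA_character_ else rg$owner,
        cation = if (is.null(rownames(cations))) as.character(ci)
                 else rownames(cations)[ci],
        distance = d, angle = ang, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out))
    return(data.frame(type = character(0), ligand_id = character(0),
                      residue = character(0), cation = character(0),
                      distance = numeric(0), angle = numeric(0)))
  do.call(rbind, out)
}

#' Classify all ligand-receptor ring pairs of a scene
#'
#' Convenience scan: every ligand ring against every receptor ring through
#' [classify_ring_pair()], yielding a contact table in the same shape the
#' other detectors produce.
#'
#' @param ligand_rings,receptor_rings Lists of `ring` objects (receptor
#'   ring owners should be residue labels).
#' @param cutoffs Cutoff block.
#' @param ligand_id Label for the records.
#' @return data.frame with `type`, `ligand_id`, `residue`, `distance`,
#'   `angle`, `offset`.
#' @export
detect_pi_stacking <- function(ligand_rings, receptor_rings,
                               cutoffs = interaction_cutoffs(), ligand_id = NA) {
  out <- list()
  for (lr in ligand_rings) {
    for (rr in receptor_rings) {
      rec <- classify_ring_pair(lr, rr, cutoffs)
      if (!is.null(rec)) {
        out[[length(out) + 1L]] <- data.frame(
          type = rec$type, ligand_id = ligand_id,
          residue = if (is.null(rr$owner)) NA_character_ else rr$owner,
          distance = rec$distance, angle = rec$angle, offset = rec$offset,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out))
    return(data.frame(type = character(0), ligand_id = character(0),
                      residue = character(0), distance = numeric(0),
                      angle = numeric(0), offset = numeric(0)))
  do.call(rbind, out)
}

#' Summarize contacts across a ligand set
#'
#' Groups contact records (one representative pose per ligand) by
#' (residue, interaction type) and reports the number of distinct ligands,
#' the mean contact distance and the sample (n-1) standard deviation --
#' reported as 0 for singleton groups.
#'
#' @param contacts data.frame with at least `type`, `ligand_id`, `residue`,
#'   `distance` (rbind of detector outputs).
#' @return data.frame with `residue`, `type`, `n_ligands`, `mean_distance`,
#'   `sd_distance`, sorted by residue then type.
#' @export
summarize_contacts <- function(contacts) {
  if (!nrow(contacts))
    return(data.frame(residue = character(0), type = character(0),
                      n_ligands = integer(0), mean_distance = numeric(0),
                      sd_distance = numeric(0)))
  key <- interaction(contacts$residue, contacts$type, drop = TRUE)
  rows <- lapply(split(contacts, key), function(g) {
    data.frame(residue = g$residue[1], type = g$type[1],
               n_ligands = length(unique(g$ligand_id)),
               mean_distance = mean(g$distance),
               sd_distance = if (nrow(g) > 1) stats::sd(g$distance) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$residue, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aromatic ring atom names for standard residues
#'
#' Template atom-name sets used to build receptor rings automatically from
#' a PDB: PHE/TYR six-ring, TRP five- and six-rings, HIS five-ring.
#'
#' @return Named list: residue name -> list of character vectors.
#' @export
residue_ring_templates <- function() {
  list(
    PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
    TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
    TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
               c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")),
    HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2"))
  )
}

#' Build receptor rings from a structure
#'
#' Extracts `ring` objects for every aromatic residue (PHE, TYR, TRP, HIS)
#' of a receptor using [residue_ring_templates()]; residues with missing
#' ring atoms are skipped.
#'
#' @param receptor A `receptor` from [read_receptor()].
#' @param planarity_tol Passed to [ring_geometry()].
#' @return List of `ring`s with owners like `"PHE330"`.
#' @export
receptor_rings <- function(receptor,
                           planarity_tol = interaction_cutoffs()$ring_planarity_tol) {
  a <- receptor$atoms
  tmpl <- residue_ring_templates()
  out <- list()
  for (res in split(a, paste(a$chain, a$resno, a$insert))) {
    rn <- res$resname[1]
    if (!rn %in% names(tmpl)) next
    for (names_set in tmpl[[rn]]) {
      hit <- match(names_set, res$name)
      if (anyNA(hit)) next
      out[[length(out) + 1L]] <- ring_geometry(
        as.matrix(res[hit, c("x", "y", "z")]),
        owner = paste0(rn, res$resno[1]), planarity_tol = planarity_tol
      )
    }
  }
  out
}
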