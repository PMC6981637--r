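#' Read a receptor structure from a PDB file
#'
#' Loads all ATOM/HETATM records (via bio3d) into a `receptor` object.
#' Coordinates are taken as-is in Angstrom -- no transformation is applied;
#' ensemble poses are assumed to live in a common, pre-aligned receptor
#' frame (see [check_receptor_alignment()]). Insertion codes are preserved.
#'
#' @param path PDB file path.
#' @param id Receptor identifier; defaults to the file base name.
#' @return A `receptor`: list with `id` and `atoms` (data.frame with
#'   `name`, `element`, `resname`, `resno`, `chain`, `insert`, `x`, `y`, `z`).
#' @export
read_receptor <- function(path, id = NULL) {
  if (!file.exists(path)) stop("no such PDB file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("empty structure: no ATOM/HETATM records in ", path, call. = FALSE)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed ATOM/HETATM record at line ", i, ": truncated coordinates",
           call. = FALSE)
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz) || any(!is.finite(xyz)))
      stop("malformed ATOM/HETATM record at line ", i, ": unparseable coordinates",
           call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  atoms <- data.frame(
    name = trimws(a$elety), element = trimws(a$elesy), resname = trimws(a$resid),
    resno = a$resno, chain = ifelse(is.na(a$chain), "", a$chain),
    insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE
  )
  structure(list(id = if (is.null(id)) sub("\\.pdb$", "", basename(path)) else id,
                 atoms = atoms),
            class = "receptor")
}

#' Write a receptor to a PDB file
#'
#' Emits plain ATOM records at standard column positions (readable by any
#' PDB parser, including the one behind [read_receptor()]).
#'
#' @param receptor A `receptor` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_receptor <- function(receptor, path) {
  a <- receptor$atoms
  name4 <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
  lines <- sprintf("ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   seq_len(nrow(a)), name4, a$resname,
                   ifelse(nzchar(a$chain), a$chain, "A"), a$resno,
                   ifelse(nzchar(a$insert), a$insert, " "),
                   a$x, a$y, a$z, 1.0, 0.0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Check that a receptor ensemble is pre-aligned
#'
#' Pose clustering across receptors assumes all structures share one frame.
#' This computes the pairwise C-alpha RMSD (matched by residue number and
#' chain) against the first receptor and warns when any exceeds 1 Angstrom.
#'
#' @param receptors List of `receptor` objects.
#' @return Named numeric vector of C-alpha RMSDs versus the first receptor
#'   (invisible).
#' @export
check_receptor_alignment <- function(receptors) {
  if (length(receptors) < 2) return(invisible(numeric(0)))
  ca <- lapply(receptors, function(r) {
    a <- r$atoms[r$atoms$name == "CA", ]
    a[order(a$chain, a$resno, a$insert), ]
  })
  ref <- ca[[1]]
  out <- vapply(ca[-1], function(cur) {
    key <- function(d) paste(d$chain, d$resno, d$insert)
    common <- intersect(key(ref), key(cur))
    if (!length(common)) return(NA_real_)
    r1 <- as.matrix(ref[match(common, key(ref)), c("x", "y", "z")])
    r2 <- as.matrix(cur[match(common, key(cur)), c("x", "y", "z")])
    sqrt(mean(rowSums((r1 - r2)^2)))
  }, numeric(1))
  names(out) <- vapply(receptors[-1], `[[`, "", "id")
  if (any(is.na(out)))
    warning("receptors share no common C-alpha atoms; cannot verify alignment")
  else if (any(out >= 1))
    warning("receptor ensemble not aligned: C-alpha RMSD >= 1 A for ",
            paste(names(out)[out >= 1], collapse = ", "))
  invisible(out)
}

pose_key <- function(meta) {
  paste(meta$ligand_id, meta$stereo_tag, meta$receptor_id, meta$pose_index,
        sep = "|")
}

new_pose_set <- function(meta, coords) {
  stopifnot(nrow(meta) == length(coords))
  rownames(meta) <- NULL
  structure(list(meta = meta, coords = coords), class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  cat("<pose_set> ", nrow(x$meta), " poses, ",
      length(unique(x$meta$ligand_id)), " ligands, ",
      length(unique(x$meta$receptor_id)), " receptors\n", sep = "")
  invisible(x)
}

#' Write a ligand pose set to SDF (V2000)
#'
#' One molecule record per pose. Because the V2000 atom block stores only
#' element symbols, the atom names that drive the scaffold correspondence
#' travel in an `<atom_names>` data field (space-separated, atom-block
#' order); identity and score fields (`ligand_id`, `stereo_tag`,
#' `receptor_id`, `pose_index`, `docking_score`, `rescore_dg`) are emitted
#' as SDF data items. Coordinates are written at the format's 4-decimal
#' precision.
#'
#' @param poses A `pose_set`.
#' @param path Output SDF path.
#' @param header Optional comment string placed on each record's third line
#'   (e.g. a generator config hash).
#' @return `path`, invisibly.
#' @export
write_poses <- function(poses, path, header = "") {
  meta <- poses$meta
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(meta))) {
    xyz <- poses$coords[[i]]
    el <- attr(xyz, "elements")
    nb <- max(nrow(xyz) - 1L, 0L)  # chain bonds: topology is immaterial here
    lines <- c(
      pose_key(meta[i, ]), "  thqche", header,
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(xyz), nb),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              xyz[, 1], xyz[, 2], xyz[, 3], el),
      if (nb > 0)
        sprintf("%3d%3d  1  0  0  0  0", seq_len(nb), seq_len(nb) + 1L),
      "M  END",
      sdf_field("ligand_id", meta$ligand_id[i]),
      sdf_field("stereo_tag", meta$stereo_tag[i]),
      sdf_field("receptor_id", meta$receptor_id[i]),
      sdf_field("pose_index", meta$pose_index[i]),
      sdf_field("atom_names", paste(rownames(xyz), collapse = " ")),
      if (!is.na(meta$docking_score[i]))
        sdf_field("docking_score", format(meta$docking_score[i], digits = 10)),
      if (!is.na(meta$rescore_dg[i]))
        sdf_field("rescore_dg", format(meta$rescore_dg[i], digits = 10)),
      "$$$$"
    )
    writeLines(lines, con)
  }
  invisible(path)
}

sdf_field <- function(name, value) c(sprintf(">  <%s>", name), as.character(value), "")

#' Read ligand poses from SDF, joining a score table
#'
#' Parses a V2000 SDF written in the conventions of [write_poses()] (via
#' ChemmineR) and joins per-pose scores from a delimited table keyed by
#' (`ligand_id`, `stereo_tag`, `receptor_id`, `pose_index`). The score table
#' takes precedence over score fields embedded in the SDF; poses with no
#' score row fall back to the SDF `docking_score`/`rescore_dg` fields, and
#' it is an error for a pose to end up with no docking score at all.
#'
#' @param path SDF file path.
#' @param score_table Optional path to a TSV with columns `ligand_id`,
#'   `stereo_tag`, `receptor_id`, `pose_index`, `docking_score`,
#'   `rescore_dg`, or a data.frame of the same shape.
#' @return A `pose_set`: `meta` data.frame plus a list of per-pose
#'   coordinate matrices (rownames = atom names, `elements` attribute).
#' @export
read_poses <- function(path, score_table = NULL) {
  if (!file.exists(path)) stop("no such SDF file: ", path, call. = FALSE)
  sdf <- ChemmineR::read.SDFset(path)
  n <- length(sdf)
  if (n == 0) stop("empty SDF: ", path, call. = FALSE)
  metas <- vector("list", n)
  coords <- vector("list", n)
  for (i in seq_len(n)) {
    mol <- sdf[[i]]
    ab <- ChemmineR::atomblock(mol)
    db <- ChemmineR::datablock(mol)
    need <- c("ligand_id", "stereo_tag", "receptor_id", "pose_index", "atom_names")
    miss <- setdiff(need, names(db))
    if (length(miss))
      stop("SDF record ", i, " lacks data field(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    nm <- strsplit(db[["atom_names"]], "[ ]+")[[1]]
    if (length(nm) != nrow(ab))
      stop("SDF record ", i, ": atom_names length != atom count", call. = FALSE)
    if (anyDuplicated(nm))
      stop("SDF record ", i, ": duplicate atom names within a pose", call. = FALSE)
    xyz <- unname(ab[, 1:3, drop = FALSE])
    rownames(xyz) <- nm
    attr(xyz, "elements") <- sub("_.*$", "", rownames(ab))
    coords[[i]] <- xyz
    metas[[i]] <- data.frame(
      ligand_id = db[["ligand_id"]], stereo_tag = db[["stereo_tag"]],
      receptor_id = db[["receptor_id"]],
      pose_index = as.integer(db[["pose_index"]]),
      docking_score = if ("docking_score" %in% names(db))
        as.numeric(db[["docking_score"]]) else NA_real_,
      rescore_dg = if ("rescore_dg" %in% names(db))
        as.numeric(db[["rescore_dg"]]) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  meta <- do.call(rbind, metas)
  if (anyDuplicated(pose_key(meta)))
    stop("duplicate pose key(s) in SDF: ",
         paste(unique(pose_key(meta)[duplicated(pose_key(meta))]), collapse = ", "),
         call. = FALSE)
  # atom-name multiset must be identical across all poses of one ligand
  for (lig in unique(meta$ligand_id)) {
    idx <- which(meta$ligand_id == lig)
    ref <- sort(rownames(coords[[idx[1]]]))
    for (j in idx[-1]) {
      if (!identical(sort(rownames(coords[[j]])), ref))
        stop("atom-name mismatch across poses of ligand ", lig, call. = FALSE)
    }
  }
  if (!is.null(score_table)) {
    sc <- if (is.data.frame(score_table)) score_table
          else utils::read.delim(score_table, stringsAsFactors = FALSE)
    if (nrow(sc)) {
      sk <- pose_key(sc)
      if (anyDuplicated(sk))
        stop("duplicate pose key(s) in score table", call. = FALSE)
      hit <- match(pose_key(meta), sk)
      got <- !is.na(hit)
      if ("docking_score" %in% names(sc))
        meta$docking_score[got] <- sc$docking_score[hit[got]]
      if ("rescore_dg" %in% names(sc))
        meta$rescore_dg[got] <- sc$rescore_dg[hit[got]]
    }
  }
  if (anyNA(meta$docking_score))
    stop("pose(s) without docking score after join: ",
         paste(pose_key(meta)[is.na(meta$docking_score)][1:min(3, sum(is.na(meta$docking_score)))],
               collapse = ", "),
         call. = FALSE)
  new_pose_set(meta, coords)
}

#' Read a scaffold core-atom map
#'
#' The core map is the ordered list of atom names shared by every ligand in
#' an ensemble (the THQ ring, pyrrolidone, methylene bridge and
#' isoxazole/isoxazoline core) that defines the cross-ligand coordinate
#' correspondence for RMSD. Plain text, one atom name per line; blank lines
#' and `#` comments ignored.
#'
#' @param path File path.
#' @return Character vector of atom names.
#' @export
read_core_map <- function(path) {
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (!length(ln)) stop("core map is empty: ", path, call. = FALSE)
  if (anyDuplicated(ln)) stop("core map has duplicate atom names", call. = FALSE)
  ln
}

#' Core-scaffold coordinates of one pose
#'
#' Extracts the coordinates of the core-map atoms, in map order, regardless
#' of the atom order in the source file.
#'
#' @param xyz Pose coordinate matrix (rownames = atom names), i.e. one
#'   element of `pose_set$coords`.
#' @param map Character vector of core atom names.
#' @return |map| x 3 coordinate matrix.
#' @export
core_coordinates <- function(xyz, map) {
  hit <- match(map, rownames(xyz))
  if (anyNA(hit))
    stop("pose is missing core atom(s): ", paste(map[is.na(hit)], collapse = ", "),
         call. = FALSE)
  out <- xyz[hit, , drop = FALSE]
  rownames(out) <- map
  out
}

# flat n_pose x (3k) matrix of core coordinates for fast vectorized RMSD
core_matrix <- function(poses, map) {
  t(vapply(poses$coords, function(xyz) as.vector(core_coordinates(xyz, map)),
           numeric(3 * length(map))))
}
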