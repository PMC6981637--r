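#' Clustering parameters for consensus binding-mode selection
#'
#' Defaults mirror the ensemble-docking post-processing this package
#' implements: poses clustered at a 2.0 Angstrom RMSD threshold, the five
#' most populated clusters kept, each covered ligand required to contribute
#' at least ten member poses, with one hundred poses retained per ligand
#' upstream.
#'
#' @param rmsd_threshold Cluster radius in Angstrom (> 0).
#' @param top_k Number of most-populated clusters carried into ranking.
#' @param min_poses_per_ligand Minimum member poses each covered ligand must
#'   contribute for a cluster to qualify (see `per_ligand_rule`).
#' @param poses_retained_per_ligand Upstream pose retention count (recorded
#'   for provenance; generators use it as their default).
#' @param per_ligand_rule If `TRUE` (default) the minimum applies to every
#'   covered ligand individually; if `FALSE` the cluster qualifies when its
#'   total population meets the minimum and every covered ligand contributes
#'   at least one pose (the alternative reading of "at least ten poses per
#'   ligand").
#' @return A `cluster_params` list.
#' @export
cluster_params <- function(rmsd_threshold = 2.0, top_k = 5L,
                           min_poses_per_ligand = 10L,
                           poses_retained_per_ligand = 100L,
                           per_ligand_rule = TRUE) {
  stopifnot(rmsd_threshold > 0, top_k >= 1, min_poses_per_ligand >= 1,
            poses_retained_per_ligand >= 1)
  structure(list(rmsd_threshold = rmsd_threshold, top_k = as.integer(top_k),
                 min_poses_per_ligand = as.integer(min_poses_per_ligand),
                 poses_retained_per_ligand = as.integer(poses_retained_per_ligand),
                 per_ligand_rule = isTRUE(per_ligand_rule)),
            class = "cluster_params")
}

#' Core-scaffold RMSD between two poses
#'
#' Root-mean-square deviation over the core-map atoms, matched by atom name,
#' computed in the common receptor frame: no superposition and no
#' graph-symmetry correction are applied, so an exact direct-sum oracle
#' exists and a rigid translation by t gives RMSD |t|.
#'
#' @param a,b Pose coordinate matrices (rownames = atom names).
#' @param map Core atom names (character vector).
#' @return RMSD in Angstrom.
#' @examples
#' xyz <- matrix(0, 2, 3, dimnames = list(c("C1", "C2"), NULL))
#' core_rmsd(xyz, xyz + rep(c(3, 4, 0), each = 2), c("C1", "C2"))  # 5
#' @export
core_rmsd <- function(a, b, map) {
  ca <- core_coordinates(a, map)
  cb <- core_coordinates(b, map)
  sqrt(mean(rowSums((ca - cb)^2)))
}

#' Cluster docking poses by core RMSD
#'
#' Partitions a pose set into binding-mode clusters within each stereo-tag
#' partition (poses of different chirality are never grouped together).
#' Two algorithms are provided:
#'
#' * `"leader"` (default): deterministic leader clustering. Poses are
#'   visited in a documented order -- `rescore_dg` ascending (NAs last),
#'   ties by ligand id then pose index -- and each pose joins the first
#'   existing cluster whose leader lies within `rmsd_threshold`, else founds
#'   a new cluster with itself as leader. O(n k), standard for pose
#'   ensembles, and independent of input file order.
#' * `"average"`: hierarchical average-linkage on the core-coordinate
#'   distance (Euclidean rescaled to RMSD), cut at `rmsd_threshold`.
#'
#' @param poses A `pose_set`.
#' @param map Core atom names.
#' @param params A [cluster_params()] object.
#' @param method `"leader"` or `"average"`.
#' @return List of `pose_cluster` objects, each a list with `cluster_id`,
#'   `stereo_tag`, `members` (row indices into `poses$meta`), `keys`,
#'   `population` and `ligands`. Cluster ids are assigned by decreasing
#'   population (ties: stereo tag, then founding order).
#' @export
cluster_poses <- function(poses, map, params = cluster_params(),
                          method = c("leader", "average")) {
  method <- match.arg(method)
  meta <- poses$meta
  if (!nrow(meta)) stop("no poses to cluster", call. = FALSE)
  if (anyNA(meta$stereo_tag)) stop("all poses must carry a stereo_tag", call. = FALSE)
  X <- core_matrix(poses, map)
  k <- length(map)
  assign <- integer(nrow(meta))
  next_id <- 0L
  for (tag in sort(unique(meta$stereo_tag))) {
    idx <- which(meta$stereo_tag == tag)
    if (method == "leader") {
      ord <- idx[order(ifelse(is.na(meta$rescore_dg[idx]), Inf, meta$rescore_dg[idx]),
                       meta$ligand_id[idx], meta$pose_index[idx])]
      leaders <- matrix(numeric(0), 0, ncol(X))
      lab <- integer(0)
      part <- integer(length(ord))
      for (j in seq_along(ord)) {
        x <- X[ord[j], ]
        if (nrow(leaders)) {
          d2 <- rowSums(sweep(leaders, 2, x)^2) / k
          hit <- which(d2 <= params$rmsd_threshold^2)
        } else hit <- integer(0)
        if (length(hit)) {
          part[j] <- lab[hit[1]]
        } else {
          leaders <- rbind(leaders, x)
          lab <- c(lab, next_id + length(lab) + 1L)
          part[j] <- lab[length(lab)]
        }
      }
      assign[ord] <- part
      next_id <- next_id + nrow(leaders)
    } else {
      if (length(idx) == 1) {
        assign[idx] <- next_id + 1L
        next_id <- next_id + 1L
      } else {
        d <- stats::dist(X[idx, , drop = FALSE]) / sqrt(k)
        hc <- stats::hclust(d, method = "average")
        ct <- stats::cutree(hc, h = params$rmsd_threshold)
        assign[idx] <- next_id + ct
        next_id <- next_id + max(ct)
      }
    }
  }
  split_idx <- split(seq_len(nrow(meta)), assign)
  pop <- lengths(split_idx)
  tag_of <- vapply(split_idx, function(i) meta$stereo_tag[i[1]], "")
  ord <- order(-pop, tag_of, as.integer(names(split_idx)))
  clusters <- vector("list", length(split_idx))
  for (r in seq_along(ord)) {
    i <- split_idx[[ord[r]]]
    clusters[[r]] <- structure(list(
      cluster_id = r, stereo_tag = meta$stereo_tag[i[1]],
      members = i, keys = pose_key(meta[i, , drop = FALSE]),
      population = length(i), ligands = sort(unique(meta$ligand_id[i]))
    ), class = "pose_cluster")
  }
  clusters
}

#' @export
print.pose_cluster <- function(x, ...) {
  cat("<pose_cluster> id ", x$cluster_id, " [", x$stereo_tag, "]: ",
      x$population, " poses, ", length(x$ligands), " ligands\n", sep = "")
  invisible(x)
}

#' Keep the most populated qualifying clusters
#'
#' A cluster qualifies when its ligand coverage satisfies the per-ligand
#' minimum (see [cluster_params()]); of the qualifiers, the `top_k` by
#' population are returned, ties broken by cluster id. An empty list (not
#' an error) is returned when nothing qualifies.
#'
#' @param clusters Output of [cluster_poses()].
#' @param poses The `pose_set` the clusters index into.
#' @param params A [cluster_params()].
#' @return Filtered list of clusters.
#' @export
filter_top_clusters <- function(clusters, poses, params = cluster_params()) {
  ok <- vapply(clusters, function(cl) {
    per_lig <- table(poses$meta$ligand_id[cl$members])
    if (params$per_ligand_rule) all(per_lig >= params$min_poses_per_ligand)
    else cl$population >= params$min_poses_per_ligand && all(per_lig >= 1)
  }, logical(1))
  kept <- clusters[ok]
  if (!length(kept)) return(list())
  ord <- order(-vapply(kept, `[[`, 0L, "population"),
               vapply(kept, `[[`, 0L, "cluster_id"))
  kept[ord][seq_len(min(params$top_k, length(kept)))]
}

#' Select one representative pose per ligand within a cluster
#'
#' `"lowest_energy"` (default) takes the member with the lowest
#' `rescore_dg` for each covered ligand, ties broken by lowest pose index.
#' `"best_fit_greedy"` starts from that selection and greedily swaps one
#' ligand's representative at a time, accepting a swap only while the R^2
#' of the representative energies against the experimental free energies
#' strictly improves, until a fixpoint. The greedy mode conditions pose
#' selection on the experimental values it will later be correlated with --
#' an experiment-guided choice that inflates the apparent fit -- so it is
#' an explicit opt-in, never a default.
#'
#' @param cluster A `pose_cluster`.
#' @param poses The `pose_set`.
#' @param mode `"lowest_energy"` or `"best_fit_greedy"`.
#' @param dg_expt Named vector of experimental dG (kcal/mol) by ligand id;
#'   required for `"best_fit_greedy"`, where every covered ligand must have
#'   a value.
#' @return Named integer vector: row index into `poses$meta` per ligand id.
#' @export
pick_representatives <- function(cluster, poses,
                                 mode = c("lowest_energy", "best_fit_greedy"),
                                 dg_expt = NULL) {
  mode <- match.arg(mode)
  meta <- poses$meta
  mem <- cluster$members
  if (!length(mem)) stop("empty cluster", call. = FALSE)
  if (anyNA(meta$rescore_dg[mem]))
    stop("rescore_dg missing for cluster member pose(s)", call. = FALSE)
  by_lig <- split(mem, meta$ligand_id[mem])
  reps <- vapply(by_lig, function(i) {
    i[order(meta$rescore_dg[i], meta$pose_index[i])][1]
  }, integer(1))
  if (mode == "lowest_energy") return(reps)
  miss <- setdiff(names(by_lig), names(dg_expt))
  if (length(miss))
    stop("best_fit_greedy requires experimental dG for ligand(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  r2_of <- function(sel) {
    fit_dg(meta$rescore_dg[sel], dg_expt[names(sel)])$r_squared
  }
  if (length(reps) < 3) return(reps)
  best <- r2_of(reps)
  repeat {
    improved <- FALSE
    for (lig in names(by_lig)) {
      for (cand in by_lig[[lig]]) {
        if (cand == reps[[lig]]) next
        trial <- reps
        trial[[lig]] <- cand
        r2 <- r2_of(trial)
        if (r2 > best) {
          reps <- trial
          best <- r2
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  reps
}

#' Regress experimental on predicted binding free energies
#'
#' Ordinary least squares of dGexpt on dGpred over the representative poses;
#' R^2 is the squared Pearson correlation, hence invariant under affine
#' transformation of the predictions.
#'
#' @param dg_pred Predicted (rescored) energies, kcal/mol.
#' @param dg_expt Experimental energies, kcal/mol, same length >= 3.
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
fit_dg <- function(dg_pred, dg_expt) {
  if (length(dg_pred) != length(dg_expt))
    stop("dg_pred and dg_expt must have equal length", call. = FALSE)
  if (length(dg_pred) < 3) stop("need at least 3 paired values", call. = FALSE)
  if (stats::var(dg_expt) == 0) stop("zero variance in dg_expt", call. = FALSE)
  if (stats::var(dg_pred) == 0) stop("zero variance in dg_pred", call. = FALSE)
  co <- stats::.lm.fit(cbind(1, dg_pred), dg_expt)$coefficients
  list(slope = co[2], intercept = co[1],
       r_squared = stats::cor(dg_pred, dg_expt)^2, n = length(dg_pred))
}

#' Run the full consensus binding-mode selection
#'
#' Pipeline: cluster poses by core RMSD within chirality partitions, keep
#' the top populated qualifying clusters, pick one representative pose per
#' ligand in each, regress experimental against predicted free energies,
#' and rank clusters by R^2 (descending; ties broken by population then
#' cluster id). The chosen cluster is the top-ranked one. Ligands without
#' an experimental value are carried through clustering but excluded from
#' the fit; clusters covering fewer than three ligands with experimental
#' values are reported with NA fit and ranked last.
#'
#' @param poses A `pose_set` with `rescore_dg` populated.
#' @param map Core atom names.
#' @param dg_expt Named vector of experimental dG by ligand id.
#' @param params A [cluster_params()].
#' @param mode Representative-selection mode, see [pick_representatives()].
#' @param method Clustering algorithm, see [cluster_poses()].
#' @return A `consensus_report`: list with `clusters` (all clusters),
#'   `ranking` (data.frame of evaluated clusters with slope, intercept,
#'   r_squared), `representatives` (per evaluated cluster), `chosen`
#'   (cluster id or NA), `empty_filter` flag and `params`.
#' @export
run_consensus <- function(poses, map, dg_expt, params = cluster_params(),
                          mode = c("lowest_energy", "best_fit_greedy"),
                          method = c("leader", "average")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  clusters <- cluster_poses(poses, map, params, method)
  top <- filter_top_clusters(clusters, poses, params)
  if (!length(top)) {
    warning("no cluster passed the population filter; empty consensus ranking")
    return(structure(list(clusters = clusters,
                          ranking = data.frame(), representatives = list(),
                          chosen = NA_integer_, empty_filter = TRUE,
                          params = params),
                     class = "consensus_report"))
  }
  rows <- vector("list", length(top))
  rep_list <- vector("list", length(top))
  for (i in seq_along(top)) {
    cl <- top[[i]]
    reps_all <- pick_representatives(cl, poses, "lowest_energy")
    fitted_lig <- intersect(names(reps_all), names(dg_expt))
    fit <- NULL
    reps <- reps_all
    if (length(fitted_lig) >= 3) {
      if (mode == "best_fit_greedy") {
        sub_cl <- cl
        sub_cl$members <- cl$members[poses$meta$ligand_id[cl$members] %in% fitted_lig]
        reps_fit <- pick_representatives(sub_cl, poses, "best_fit_greedy",
                                         dg_expt = dg_expt)
        reps[names(reps_fit)] <- reps_fit
      }
      sel <- reps[fitted_lig]
      fit <- fit_dg(poses$meta$rescore_dg[sel], dg_expt[fitted_lig])
    }
    rep_list[[i]] <- reps
    rows[[i]] <- data.frame(
      cluster_id = cl$cluster_id, stereo_tag = cl$stereo_tag,
      population = cl$population, n_ligands = length(cl$ligands),
      n_fitted = length(fitted_lig),
      slope = if (is.null(fit)) NA_real_ else fit$slope,
      intercept = if (is.null(fit)) NA_real_ else fit$intercept,
      r_squared = if (is.null(fit)) NA_real_ else fit$r_squared
    )
  }
  ranking <- do.call(rbind, rows)
  ord <- order(-ifelse(is.na(ranking$r_squared), -Inf, ranking$r_squared),
               -ranking$population, ranking$cluster_id)
  ranking <- ranking[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  rep_list <- rep_list[ord]
  names(rep_list) <- as.character(ranking$cluster_id)
  chosen <- if (all(is.na(ranking$r_squared))) NA_integer_ else ranking$cluster_id[1]
  structure(list(clusters = clusters, ranking = ranking,
                 representatives = rep_list, chosen = chosen,
                 empty_filter = FALSE, params = params),
            class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat("<consensus_report> ", length(x$clusters), " clusters, ",
      nrow(x$ranking), " evaluated; chosen cluster: ", x$chosen, "\n", sep = "")
  if (nrow(x$ranking)) print(x$ranking, digits = 4)
  invisible(x)
}

#' Serialize a consensus report
#'
#' Writes the report as structured JSON plus a flat per-cluster summary
#' table next to it.
#'
#' @param report A `consensus_report`.
#' @param path Output JSON path; the table goes to the same path with
#'   extension `.tsv`.
#' @param poses The `pose_set` used (for representative keys).
#' @return `path`, invisibly.
#' @export
write_consensus_report <- function(report, path, poses) {
  reps <- lapply(report$representatives, function(r)
    as.list(stats::setNames(pose_key(poses$meta[r, , drop = FALSE]), names(r))))
  jsonlite::write_json(
    list(chosen_cluster = report$chosen, empty_filter = report$empty_filter,
         params = unclass(report$params), ranking = report$ranking,
         representatives = reps),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  utils::write.table(report$ranking, sub("\\.json$", ".tsv", path),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
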