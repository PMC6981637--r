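test_that("ring geometry: centroid, normal, sign rule, planarity tolerance", {
  hex <- hexagon_at(c(0, 0, 0), radius = 1.4)
  rg <- ring_geometry(hex)
  expect_equal(rg$centroid, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(rg$normal, c(0, 0, 1), tolerance = 1e-12)
  # rotated 90 deg about x: normal in -y/+y; sign rule picks +y (z = x = 0)
  rot <- hexagon_at(c(0, 0, 0), axis = c(0, -1, 0))
  expect_equal(abs(ring_geometry(rot)$normal), c(0, 1, 0), tolerance = 1e-9)
  expect_gte(ring_geometry(rot)$normal[2], 0)
  # chair pucker alternating +/-0.4 A: 0.4 A off any plane, beyond the
  # 0.3 A coplanarity tolerance
  puck <- hex
  puck[c(1, 3, 5), 3] <- 0.4
  puck[c(2, 4, 6), 3] <- -0.4
  expect_error(ring_geometry(puck), "planarity")
  expect_error(ring_geometry(hex[1:4, ]), "5 or 6")
})

test_that("ring-pair classes follow the distance/angle/offset windows", {
  lig <- ring_geometry(hexagon_at(c(0, 0, 0)))
  sandwich <- ring_geometry(hexagon_at(c(0, 0, 3.5)))
  got <- classify_ring_pair(lig, sandwich)
  expect_equal(got$type, "pi_sandwich")
  expect_equal(got$distance, 3.5)
  displaced <- ring_geometry(hexagon_at(c(1.8, 0, 3.4)))
  expect_equal(classify_ring_pair(lig, displaced)$type, "pi_parallel_displaced")
  tshape <- ring_geometry(hexagon_at(c(0, 0, 5.0), axis = c(1, 0, 0)))
  expect_equal(classify_ring_pair(lig, tshape)$type, "pi_t_shaped")
  far_t <- ring_geometry(hexagon_at(c(0, 0, 8.0), axis = c(1, 0, 0)))
  expect_null(classify_ring_pair(lig, far_t))
  # parallel classes are symmetric in their arguments
  for (other in list(sandwich, displaced)) {
    ab <- classify_ring_pair(lig, other)
    ba <- classify_ring_pair(other, lig)
    expect_equal(ab$type, ba$type)
    expect_equal(ab$offset, ba$offset, tolerance = 1e-12)
  }
})

test_that("published contact distances all fall inside the detection windows", {
  # reported mean distances for this compound class, replayed as geometry
  lig <- ring_geometry(hexagon_at(c(0, 0, 0)))
  expect_equal(classify_ring_pair(
    lig, ring_geometry(hexagon_at(c(0, 0, 3.56))))$type, "pi_sandwich")
  expect_equal(classify_ring_pair(
    lig, ring_geometry(hexagon_at(c(2.0, 0, sqrt(4.10^2 - 4)))))$type,
    "pi_parallel_displaced")
  expect_equal(classify_ring_pair(
    lig, ring_geometry(hexagon_at(c(0, 0, 4.55), axis = c(1, 0, 0))))$type,
    "pi_t_shaped")
  expect_equal(classify_ring_pair(
    lig, ring_geometry(hexagon_at(c(3.0, 0, sqrt(4.92^2 - 9)))))$type,
    "pi_parallel_displaced")
  cut <- interaction_cutoffs()
  expect_lte(3.17, cut$hbond_max_da)   # methoxy-Trp279 H-bond mean
  expect_lte(2.68, cut$hbond_max_da)
  expect_lte(1.99, cut$weak_hbond_max_ha)
})

test_that("hydrogen-bond detection honors geometry cutoffs and conventions", {
  lig <- data.frame(name = "O1", element = "O", x = 0, y = 0, z = 0,
                    is_aromatic = FALSE)
  rec <- data.frame(name = c("NE1", "HE1"), element = c("N", "H"),
                    resname = "TRP", resno = 279L,
                    x = c(0, 0), y = c(0, 0), z = c(3.0, 2.0),
                    is_aromatic = FALSE)
  got <- detect_hbonds(lig, rec, ligand_id = "L")
  expect_equal(nrow(got), 1L)
  expect_equal(got$type, "hbond")
  expect_equal(got$distance, 3.0)  # donor-acceptor convention
  expect_equal(got$residue, "TRP279")
  expect_equal(got$distance_ha, 2.0)  # both conventions always reported
  rec_far <- rec
  rec_far$z <- c(3.6, 2.6)
  expect_equal(nrow(detect_hbonds(lig, rec_far)), 0L)
  # bent geometry below the angle cutoff is rejected
  rec_bent <- rec
  rec_bent[2, c("x", "z")] <- c(1.1, 3.0)
  expect_equal(nrow(detect_hbonds(lig, rec_bent)), 0L)
})

test_that("planted donor-acceptor sets match the exhaustive pair-scan oracle", {
  lig <- data.frame(name = "O1", element = "O", x = 0, y = 0, z = 0,
                    is_aromatic = FALSE)
  rec <- do.call(rbind, lapply(seq_along(c(2.9, 3.2, 3.4)), function(i) {
    d <- c(2.9, 3.2, 3.4)[i]
    u <- c(sin(i), 0, cos(i)); u <- u / sqrt(sum(u^2))
    data.frame(name = c("N", "H"), element = c("N", "H"),
               resname = "ASN", resno = i,
               x = u[1] * c(d, d - 1), y = 0, z = u[3] * c(d, d - 1),
               is_aromatic = FALSE)
  }))
  got <- detect_hbonds(lig, rec, ligand_id = "L")
  want <- oracle_hbonds(lig, rec)
  expect_equal(nrow(got), want$n)
  expect_equal(sort(got$distance), sort(c(2.9, 3.2, 3.4)), tolerance = 1e-9)
})

test_that("cation-pi detection requires axial approach within range", {
  ring <- ring_geometry(hexagon_at(c(0, 0, 0)), owner = "PHE330")
  above <- matrix(c(0, 0, 4), 1)
  got <- detect_cation_pi(above, list(ring))
  expect_equal(nrow(got), 1L)
  expect_equal(got$distance, 4)
  expect_equal(got$residue, "PHE330")
  in_plane <- matrix(c(4, 0, 0), 1)
  expect_equal(nrow(detect_cation_pi(in_plane, list(ring))), 0L)
  below <- matrix(c(0, 0, -4), 1)  # either ring face counts
  expect_equal(nrow(detect_cation_pi(below, list(ring))), 1L)
  too_far <- matrix(c(0, 0, 6.5), 1)
  expect_equal(nrow(detect_cation_pi(too_far, list(ring))), 0L)
})

test_that("detectors agree with brute-force scans on random scenes", {
  set.seed(101)
  for (rep_i in 1:100) {
    n_don <- sample(3:8, 1)
    n_acc <- sample(3:8, 1)
    # random receptor donors (N with an H at ~1 A) and ligand acceptors
    rec <- do.call(rbind, lapply(seq_len(n_don), function(i) {
      p <- runif(3, -6, 6)
      h <- p + rnorm(3, 0, 0.6) * 0.5
      h <- p + (h - p) / sqrt(sum((h - p)^2)) * 1.0
      data.frame(name = c("N", "H"), element = c("N", "H"),
                 resname = "ASN", resno = i,
                 x = c(p[1], h[1]), y = c(p[2], h[2]), z = c(p[3], h[3]),
                 is_aromatic = FALSE)
    }))
    lig <- data.frame(name = paste0("O", seq_len(n_acc)), element = "O",
                      x = runif(n_acc, -6, 6), y = runif(n_acc, -6, 6),
                      z = runif(n_acc, -6, 6), is_aromatic = FALSE)
    expect_equal(nrow(detect_hbonds(lig, rec)), oracle_hbonds(lig, rec)$n)
    # cations vs rings
    rings <- lapply(1:3, function(i) {
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      ring_geometry(hexagon_at(runif(3, -6, 6), axis = ax), owner = paste0("R", i))
    })
    cats <- matrix(runif(9, -6, 6), 3)
    expect_equal(nrow(detect_cation_pi(cats, rings)),
                 oracle_cation_pi(cats, rings))
  }
})

test_that("contact geometry is invariant under rigid motion of the scene", {
  base_rings <- list(
    a = hexagon_at(c(0, 0, 0)),
    b = hexagon_at(c(1.8, 0, 3.4)),
    t = hexagon_at(c(0, 0, 5.0), axis = c(1, 0, 0))
  )
  for (s in 1:25) {
    rt <- random_rigid(s)
    moved <- lapply(base_rings, function(x) apply_rigid(x, rt))
    r0 <- classify_ring_pair(ring_geometry(base_rings$a),
                             ring_geometry(base_rings$b))
    r1 <- classify_ring_pair(ring_geometry(moved$a), ring_geometry(moved$b))
    expect_equal(r1$type, r0$type)
    expect_equal(r1$distance, r0$distance, tolerance = 1e-9)
    # acos is ill-conditioned at 0 deg: micro-degree agreement is the
    # meaningful bound there
    expect_lt(abs(r1$angle - r0$angle), 1e-5)
    expect_equal(r1$offset, r0$offset, tolerance = 1e-9)
    t0 <- classify_ring_pair(ring_geometry(base_rings$a),
                             ring_geometry(base_rings$t))
    t1 <- classify_ring_pair(ring_geometry(moved$a), ring_geometry(moved$t))
    expect_equal(t1$type, t0$type)
    expect_equal(t1$distance, t0$distance, tolerance = 1e-9)
  }
})

test_that("contact summaries equal a two-pass mean/sd oracle", {
  contacts <- data.frame(
    type = c("pi_sandwich", "pi_sandwich", "pi_sandwich", "hbond"),
    ligand_id = c("L1", "L2", "L3", "L1"),
    residue = c("PHE330", "PHE330", "PHE330", "TRP279"),
    distance = c(3.2, 3.5, 3.8, 3.17)
  )
  s <- summarize_contacts(contacts)
  row <- s[s$residue == "PHE330", ]
  expect_equal(row$mean_distance, 3.5)
  expect_equal(row$sd_distance, 0.3, tolerance = 1e-12)
  expect_equal(row$n_ligands, 3L)
  want <- oracle_mean_sd(c(3.2, 3.5, 3.8))
  expect_equal(row$mean_distance, unname(want["mean"]))
  expect_equal(row$sd_distance, unname(want["sd"]), tolerance = 1e-12)
  single <- s[s$residue == "TRP279", ]
  expect_equal(single$sd_distance, 0)
  expect_equal(nrow(summarize_contacts(contacts[0, ])), 0L)
})

test_that("receptor rings are built from residue templates", {
  rec_atoms <- data.frame(
    name = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    element = "C", resname = "PHE", resno = 330L, chain = "A", insert = "",
    x = hexagon_at(c(1, 2, 3))[, 1], y = hexagon_at(c(1, 2, 3))[, 2],
    z = hexagon_at(c(1, 2, 3))[, 3]
  )
  rec <- structure(list(id = "r", atoms = rec_atoms), class = "receptor")
  rings <- receptor_rings(rec)
  expect_length(rings, 1L)
  expect_equal(rings[[1]]$owner, "PHE330")
  expect_equal(rings[[1]]$centroid, c(1, 2, 3), tolerance = 1e-9)
})
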