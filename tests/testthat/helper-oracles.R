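# Independent oracles used across the suite. Each is a deliberately naive
# implementation (scalar loops, direct formulas) kept separate from the
# package's code paths.

# direct per-atom-sum RMSD
oracle_rmsd <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  s <- 0
  for (i in seq_len(nrow(a))) {
    for (j in 1:3) s <- s + (a[i, j] - b[i, j])^2
  }
  unname(sqrt(s / nrow(a)))
}

# threshold-graph connected components over a pose set's core coordinates:
# ground-truth partition for well-separated ensembles
oracle_threshold_components <- function(poses, map, threshold) {
  n <- nrow(poses$meta)
  xyz <- lapply(poses$coords, core_coordinates, map = map)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- poses$meta$stereo_tag[i] == poses$meta$stereo_tag[j] &&
        oracle_rmsd(xyz[[i]], xyz[[j]]) <= threshold
    }
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# closed-form normal-equations OLS of y on x
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  r <- (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * sum(y^2) - sy^2))
  list(slope = slope, intercept = intercept, r_squared = r^2)
}

# exhaustive all-pairs hydrogen-bond scan (same typing rules, scalar code)
oracle_hbonds <- function(lig, rec) {
  ang <- function(u, v) acos(max(-1, min(1, sum(u * v) /
                                 sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  xyz <- function(df, i) c(df$x[i], df$y[i], df$z[i])
  donors_of <- function(df) {
    arom <- if (is.null(df$is_aromatic)) rep(FALSE, nrow(df))
            else df$is_aromatic %in% TRUE
    out <- list()
    for (i in which(df$element %in% c("N", "O") | (df$element == "C" & arom))) {
      for (j in which(df$element == "H")) {
        if (sqrt(sum((xyz(df, i) - xyz(df, j))^2)) < 1.2)
          out[[length(out) + 1L]] <- list(d = i, h = j, weak = df$element[i] == "C")
      }
    }
    out
  }
  count <- 0L
  recs <- list()
  sides <- list(list(don = lig, acc = rec, lab = "ligand"),
                list(don = rec, acc = lig, lab = "receptor"))
  for (sd in sides) {
    for (don in donors_of(sd$don)) {
      for (ai in which(sd$acc$element %in% c("N", "O"))) {
        D <- xyz(sd$don, don$d); H <- xyz(sd$don, don$h); A <- xyz(sd$acc, ai)
        dda <- sqrt(sum((D - A)^2)); dha <- sqrt(sum((H - A)^2))
        theta <- ang(D - H, A - H)
        hit <- if (!don$weak) dda <= 3.5 && theta >= 120
               else dha <= 3.0 && theta >= 110
        if (hit) {
          count <- count + 1L
          recs[[count]] <- c(side = sd$lab, d = don$d, a = ai)
        }
      }
    }
  }
  list(n = count, recs = recs)
}

# exhaustive cation-ring scan
oracle_cation_pi <- function(cations, rings) {
  n <- 0L
  for (ci in seq_len(nrow(cations))) {
    for (rg in rings) {
      v <- cations[ci, ] - rg$centroid
      d <- sqrt(sum(v^2))
      a <- acos(max(-1, min(1, sum(v * rg$normal) / d))) * 180 / pi
      if (a > 90) a <- 180 - a
      if (d <= 6.0 && a <= 45) n <- n + 1L
    }
  }
  n
}

# streaming two-pass mean/sd
oracle_mean_sd <- function(x) {
  m <- sum(x) / length(x)
  if (length(x) == 1) return(c(mean = m, sd = 0))
  c(mean = m, sd = sqrt(sum((x - m)^2) / (length(x) - 1)))
}

# random rigid motion (proper rotation + translation)
random_rigid <- function(seed) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = rnorm(3, 0, 10))
}
apply_rigid <- function(xyz, rt) sweep(as.matrix(xyz) %*% t(rt$R), 2, rt$t, `+`)
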