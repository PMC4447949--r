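# Small vector-geometry helpers shared by the analysis modules.

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) v / vnorm(v)

# Angle at vertex b for points a-b-c, degrees.
vangle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  ct <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

# Angle between two direction vectors, degrees.
dir_angle <- function(u, v) {
  ct <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

# All cross distances between two coordinate matrices (nA x nB).
cross_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * (a %*% t(b))
  sqrt(pmax(d2, 0))
}

# Index pairs (i, j, dist) with cross distance <= cutoff; chunked so that the
# distance matrix never exceeds ~4e6 entries at a time.
close_pairs <- function(a, b, cutoff, chunk = 2000L) {
  res <- list()
  nb <- nrow(b)
  for (start in seq(1L, nrow(a), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(a))
    d <- cross_dist(a[idx, , drop = FALSE], b)
    hit <- which(d <= cutoff, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      res[[length(res) + 1L]] <- tibble::tibble(
        i = idx[hit[, 1]], j = hit[, 2],
        dist = d[hit]
      )
    }
  }
  if (length(res) == 0) {
    return(tibble::tibble(i = integer(), j = integer(), dist = numeric()))
  }
  dplyr::bind_rows(res)
}

# Rotation matrix about an arbitrary unit axis by angle degrees (Rodrigues).
rotation_about <- function(axis, angle_deg) {
  u <- unitv(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Deterministic random rotation from a seed (uniform axis, uniform angle).
random_rotation <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3)
  rotation_about(ax, stats::runif(1, 0, 360))
}

# First principal direction of a point cloud (rows), sign-aligned with `along`.
principal_axis <- function(pts, along = NULL) {
  ctr <- colMeans(pts)
  s <- svd(sweep(pts, 2, ctr))
  v <- s$v[, 1]
  if (!is.null(along) && sum(v * along) < 0) v <- -v
  v
}
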