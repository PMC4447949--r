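# Independent oracles used to validate the package implementations. Each is
# a deliberately naive re-computation (nested loops, exhaustive recursion,
# closed forms, Monte-Carlo) kept separate from the code paths it checks.

# --- quaternion (Horn) absolute-orientation oracle ---------------------------
# optimal rotation via the eigenvector of the 4x4 quaternion matrix
horn_superpose <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  A <- sweep(P, 2, cp)
  B <- sweep(Q, 2, cq)
  S <- t(A) %*% B
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  moved <- sweep(A %*% t(R), 2, cq, "+")
  list(rotation = R, rmsd = sqrt(mean(rowSums((moved - Q)^2))))
}

# --- all-pairs contact oracles -----------------------------------------------
# nested-loop hydrogen-bond detection applying the same chemistry dictionary
# and cutoffs as the package, but with none of its pair-pruning machinery
oracle_hbonds <- function(structure, kinds_a = "protein", kinds_b = "dna",
                          max_da = 3.5, min_angle = 90) {
  pol <- etsface:::polar_atoms(structure)
  at <- tibble::as_tibble(structure)
  sb <- etsface:::.salt_bridge_rows(structure)
  pa <- pol[pol$kind %in% kinds_a, ]
  pb <- pol[pol$kind %in% kinds_b, ]
  res <- character()
  for (i in seq_len(nrow(pa))) {
    for (j in seq_len(nrow(pb))) {
      if (pa$.row[i] == pb$.row[j]) next
      if (pa$chain[i] == pb$chain[j] && pa$resno[i] == pb$resno[j]) next
      d <- sqrt((pa$x[i] - pb$x[j])^2 + (pa$y[i] - pb$y[j])^2 +
                  (pa$z[i] - pb$z[j])^2)
      if (d > max_da) next
      if ((pa$.row[i] %in% sb$pos && pb$.row[j] %in% sb$neg) ||
          (pb$.row[j] %in% sb$pos && pa$.row[i] %in% sb$neg)) next
      ok <- FALSE
      check_dir <- function(dn, ac) {
        if (!(dn$role %in% c("donor", "both") && ac$role %in% c("acceptor", "both"))) {
          return(FALSE)
        }
        if (is.na(dn$antecedent)) return(TRUE)
        ant <- at[at$chain == dn$chain & at$resno == dn$resno &
                    at$elety == dn$antecedent, ]
        if (nrow(ant) == 0) return(TRUE)
        u <- c(ant$x[1], ant$y[1], ant$z[1]) - c(dn$x, dn$y, dn$z)
        v <- c(ac$x, ac$y, ac$z) - c(dn$x, dn$y, dn$z)
        ang <- acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
        ang >= min_angle
      }
      if (check_dir(pa[i, ], pb[j, ]) || check_dir(pb[j, ], pa[i, ])) ok <- TRUE
      if (ok) {
        res <- c(res, paste(pa$chain[i], pa$resno[i], pa$elety[i],
                            pb$chain[j], pb$resno[j], pb$elety[j]))
      }
    }
  }
  sort(unique(res))
}

oracle_salt_bridges <- function(structure, max_no = 4.0) {
  ch <- etsface:::charged_atoms(structure)
  pos <- ch[ch$charge == "pos", ]
  neg <- ch[ch$charge == "neg", ]
  res <- character()
  for (i in seq_len(nrow(pos))) {
    for (j in seq_len(nrow(neg))) {
      d <- sqrt((pos$x[i] - neg$x[j])^2 + (pos$y[i] - neg$y[j])^2 +
                  (pos$z[i] - neg$z[j])^2)
      if (d <= max_no) {
        res <- c(res, paste(pos$chain[i], pos$resno[i], neg$chain[j], neg$resno[j]))
      }
    }
  }
  sort(unique(res))
}

# --- recursive backtracking hydrogen-assignment oracle -----------------------
oracle_assignments <- function(graph) {
  E <- nrow(graph$edges)
  don <- integer(nrow(graph$nodes))
  acc <- integer(nrow(graph$nodes))
  maxd <- graph$nodes$max_don
  maxa <- graph$nodes$max_acc
  count <- 0L
  recurse <- function(e) {
    if (e > E) {
      count <<- count + 1L
      return(invisible(NULL))
    }
    i <- graph$edges$from[e]
    j <- graph$edges$to[e]
    if (don[i] < maxd[i] && acc[j] < maxa[j]) {
      don[i] <<- don[i] + 1L; acc[j] <<- acc[j] + 1L
      recurse(e + 1L)
      don[i] <<- don[i] - 1L; acc[j] <<- acc[j] - 1L
    }
    if (don[j] < maxd[j] && acc[i] < maxa[i]) {
      don[j] <<- don[j] + 1L; acc[i] <<- acc[i] + 1L
      recurse(e + 1L)
      don[j] <<- don[j] - 1L; acc[i] <<- acc[i] - 1L
    }
  }
  recurse(1L)
  count
}

# random constraint graph on n nodes with <= max_edges edges
random_hbond_graph <- function(seed, n_nodes = 7, max_edges = 12) {
  set.seed(seed)
  classes <- sample(c("water", "donor_only", "acceptor_only", "ambivalent"),
                    n_nodes, replace = TRUE)
  caps <- t(vapply(classes, etsface:::.node_capacity, integer(2)))
  nodes <- tibble::tibble(id = seq_len(n_nodes), class = classes,
                          max_don = caps[, 1], max_acc = caps[, 2])
  all_pairs <- t(combn(n_nodes, 2))
  k <- sample(seq_len(min(max_edges, nrow(all_pairs))), 1)
  pick <- all_pairs[sample(nrow(all_pairs), k), , drop = FALSE]
  edges <- tibble::tibble(from = pick[, 1], to = pick[, 2],
                          distance = runif(k, 2.6, 3.5))
  list(nodes = nodes, edges = edges, cutoff = 3.5)
}

# --- Needleman-Wunsch dynamic-programming oracle -----------------------------
oracle_nw <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  F <- matrix(0, n + 1, m + 1)
  F[, 1] <- gap * (0:n)
  F[1, ] <- gap * (0:m)
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (a[i] == b[j]) match else mismatch
      F[i + 1, j + 1] <- max(F[i, j] + s, F[i, j + 1] + gap, F[i + 1, j] + gap)
    }
  }
  F[n + 1, m + 1]
}

# --- Monte-Carlo SASA estimator ----------------------------------------------
mc_sasa <- function(structure, probe = 1.4, n_samples = 20000, seed = 7) {
  at <- tibble::as_tibble(structure)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  r <- etsface::vdw_radius(at$element) + probe
  set.seed(seed)
  total <- 0
  for (i in seq_len(nrow(at))) {
    u <- matrix(rnorm(3 * n_samples), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * r[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_samples)
    for (j in seq_len(nrow(at))) {
      if (j == i) next
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      acc <- acc & d2 > r[j]^2
    }
    total <- total + 4 * pi * r[i]^2 * mean(acc)
  }
  total
}

# --- small structure builders ------------------------------------------------
toy_atoms <- function(df) etsface::new_structure(tibble::as_tibble(df))

# duplex with a planted kink: two straight halves joined with the top half
# rotated by `kink_deg` about the x-axis through the junction midplane
kinked_duplex <- function(sequence = "ACGTACGTACGTACGT", kink_deg = 30) {
  s <- etsface::build_bdna(sequence)
  at <- tibble::as_tibble(s)
  n <- nchar(sequence)
  half <- n / 2
  zcut <- (half - 0.5) * 3.38
  top <- (at$chain == "A" & at$resno > half) |
    (at$chain == "B" & at$resno <= n - half)
  R <- etsface:::rotation_about(c(1, 0, 0), kink_deg)
  xyz <- as.matrix(at[top, c("x", "y", "z")])
  xyz[, 3] <- xyz[, 3] - zcut
  xyz <- xyz %*% t(R)
  xyz[, 3] <- xyz[, 3] + zcut
  at[top, c("x", "y", "z")] <- as.data.frame(xyz)
  etsface::new_structure(at, id = "kinked")
}

# cached synthetic recognition-water fixture (expensive; built once)
water_fixture <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- etsface::build_water_network_fixture()
    fx
  }
})

expect_close <- function(actual, expected, tol) {
  testthat::expect_lt(abs(actual - expected), tol)
}
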