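# Synthetic recognition-water fixture: a four-water hydrogen-bond network in
# the major groove upstream of the GGA core, built from the fiber duplex plus
# free-standing side-chain fragments. It is a SYNTHETIC stand-in emulating
# the composition of the conserved water cluster seen in Ets domain-DNA
# complexes (aspartate, serine, arginine and tyrosine side chains, the -1
# cytosine N4, guanine O6 and backbone phosphate oxygens); it is not derived
# from deposited coordinates. The chemistry classes and capacities force
# every edge direction, so the hydrogen assignment is unique, with the water
# nearest the -1 base accepting from N4.

# best point with distances to two anchors inside given bands, maximizing a
# clearance score over a local grid (coarse pass then refinement)
.region_place <- function(a, band_a, b, band_b, score, step = 0.35) {
  ctr <- (a + b) / 2
  hw <- vnorm(a - b) / 2 + max(band_a[2], band_b[2])
  ax <- seq(-hw, hw, by = step)
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  g <- sweep(g, 2, ctr, "+")
  da <- sqrt(rowSums(sweep(g, 2, a)^2))
  db <- sqrt(rowSums(sweep(g, 2, b)^2))
  keep <- da >= band_a[1] & da <= band_a[2] & db >= band_b[1] & db <= band_b[2]
  g <- g[keep, , drop = FALSE]
  if (nrow(g) == 0) return(NULL)
  v <- apply(g, 1, score)
  i <- which.max(v)
  if (v[i] < 0) return(NULL)
  p0 <- g[i, ]
  fx <- seq(-step, step, by = step / 4)
  g2 <- as.matrix(expand.grid(x = fx, y = fx, z = fx))
  g2 <- sweep(g2, 2, p0, "+")
  da <- sqrt(rowSums(sweep(g2, 2, a)^2))
  db <- sqrt(rowSums(sweep(g2, 2, b)^2))
  keep <- da >= band_a[1] & da <= band_a[2] & db >= band_b[1] & db <= band_b[2]
  g2 <- g2[keep, , drop = FALSE]
  if (nrow(g2) == 0) return(p0)
  v2 <- apply(g2, 1, score)
  j <- which.max(v2)
  if (v2[j] >= v[i]) g2[j, ] else p0
}

#' Build the synthetic four-water recognition network fixture
#'
#' Constructs the standard 10-mer consensus duplex, plants a chain of four
#' waters from the major-groove edge of the -1 cytosine toward the phosphate
#' backbone, and places aspartate, arginine, serine and tyrosine side-chain
#' fragments so that the hydrogen-bond graph at the default 3.5 A cutoff has
#' exactly the designed edge set: N4(-1) donates to W1; W1 donates to both
#' aspartate oxygens; W2 donates to W1 and a guanine O6; arginine donates to
#' W2; W3 donates to W2 and a backbone acceptor; serine donates to W3; W4
#' donates to W3 and a second backbone acceptor; tyrosine donates to W4.
#' Every direction is forced by the chemistry classes and capacities, so the
#' hydrogen-assignment enumeration has exactly one solution, in which the
#' base-facing water accepts from the cytosine N4. The builder verifies the
#' realized edge set and the uniqueness of the assignment, aborting on any
#' mismatch.
#'
#' @param sequence duplex sequence; the default carries the GGA core at
#'   pairs 4-6 with a cytosine at -1.
#' @return list: `structure` (an `ets_structure`), `pairs`, `waters` (tibble
#'   naming the four planted waters), `graph` (the realized
#'   [hbond_graph()]), `design_edges` (canonical edge keys).
#' @export
build_water_network_fixture <- function(sequence = "ACCGGAAGTG") {
  cached <- .fixture_cache[[sequence]]
  if (!is.null(cached)) return(cached)
  s <- build_bdna(sequence, id = "water_network_fixture")
  pairs <- find_base_pairs(s)
  stopifnot(pairs$base_i[3] == "C", pairs$ebs_position[3] == -1)
  at <- tibble::as_tibble(s)
  axyz <- function(ch, rn, el) atom_xyz(s, ch, rn, el)
  n4 <- axyz("A", 3, "N4")
  c4 <- axyz("A", 3, "C4")
  o6b9 <- axyz("B", 9, "O6") # -2 pair guanine, major-groove acceptor

  pol <- polar_atoms(s)
  pol_xyz <- as.matrix(pol[, c("x", "y", "z")])
  tpol <- t(pol_xyz)
  all_xyz <- as.matrix(at[, c("x", "y", "z")])
  tall <- t(all_xyz)
  pol_lab <- sprintf("%s/%d/%s", pol$chain, pol$resno, pol$elety)

  # clearance of p: >= 3.6 A from every duplex polar atom except the allowed
  # partners, and >= 2.6 A sterically from every other duplex atom
  clear_fn <- function(allowed_labels) {
    allow <- pol_lab %in% allowed_labels
    allow_xyz <- pol_xyz[allow, , drop = FALSE]
    function(p) {
      dpol <- sqrt(colSums((tpol - p)^2))
      m <- min(dpol[!allow]) - 3.6
      dall <- sqrt(colSums((tall - p)^2))
      for (k in seq_len(nrow(allow_xyz))) {
        dall[colSums((tall - allow_xyz[k, ])^2) < 1e-10] <- Inf
      }
      min(m, min(dall) - 2.6)
    }
  }

  # W1: 2.85 A from N4 on the free amino direction, clear of everything else
  ring <- at[at$chain == "A" & at$resno == 3 &
               at$elety %in% c("N1", "C2", "N3", "C4", "C5", "C6"), ]
  rmx <- as.matrix(ring[, c("x", "y", "z")])
  nrm <- svd(sweep(rmx, 2, colMeans(rmx)))$v[, 3]
  cl_w1 <- clear_fn("A/3/N4")
  u0 <- unitv(n4 - c4)
  best <- NULL
  bv <- -Inf
  for (adeg in seq(-120, 120, by = 2)) {
    for (tilt in c(-20, -10, 0, 10, 20)) {
      dir <- as.numeric(rotation_about(nrm, adeg) %*% u0)
      dir <- as.numeric(rotation_about(pracma_cross(nrm, dir), tilt) %*% dir)
      p <- n4 + 2.85 * dir
      v <- min(cl_w1(p), 0.6) - 0.15 * abs(vnorm(p - o6b9) - 4.2)
      if (v > bv) {
        bv <- v
        best <- p
      }
    }
  }
  w1 <- best
  if (cl_w1(w1) < 0) abort("W1 placement failed")

  # W2: banded distances to W1 and the guanine O6
  band <- c(2.75, 3.40)
  cl_w2 <- clear_fn("B/9/O6")
  w2 <- .region_place(w1, band, o6b9, band, function(p) {
    min(cl_w2(p), vnorm(p - n4) - 3.6)
  })
  if (is.null(w2)) abort("W2 placement failed")

  # W3 and W4 anchor on acceptor-only DNA oxygens chosen by reachability
  acc_sel <- pol$kind == "dna" &
    vapply(seq_len(nrow(pol)), function(i) {
      pol$kind[i] == "dna" &&
        .chem_class("dna", pol$resid[i], pol$elety[i]) == "acceptor_only"
    }, logical(1))
  acc_only <- pol[acc_sel, ]
  acc_lab <- pol_lab[acc_sel]

  axm <- as.matrix(acc_only[, c("x", "y", "z")])
  candidates <- function(prev, used_labels) {
    dprev <- sqrt(rowSums(sweep(axm, 2, prev)^2))
    pen <- ifelse(grepl("OP", acc_lab), 0, 1.0) # prefer phosphate oxygens
    ord <- order(abs(dprev - 4.3) + pen)
    ord[dprev[ord] >= 3.8 & dprev[ord] <= 6.2 &
          !(acc_lab[ord] %in% used_labels)]
  }
  try_place <- function(prev, i, avoid_pts) {
    cl <- clear_fn(acc_lab[i])
    .region_place(prev, band, axm[i, ], band, function(p) {
      m <- cl(p)
      for (q in avoid_pts) m <- min(m, vnorm(p - q) - 3.6)
      m
    })
  }
  # choose the W3 anchor by backtracking: accept only chains for which a W4
  # anchor is also reachable
  w3 <- NULL
  for (i in candidates(w2, "B/9/O6")) {
    p3 <- try_place(w2, i, list(w1, n4))
    if (is.null(p3)) next
    for (j in candidates(p3, c("B/9/O6", acc_lab[i]))) {
      p4 <- try_place(p3, j, list(w1, w2, n4, axm[i, ]))
      if (!is.null(p4)) {
        w3 <- p3
        w4 <- p4
        r3 <- list(label = acc_lab[i])
        r4 <- list(label = acc_lab[j])
        break
      }
    }
    if (!is.null(w3)) break
  }
  if (is.null(w3)) abort("W3/W4 placement failed: no reachable acceptor chain")

  waters <- rbind(w1, w2, w3, w4)

  # side-chain fragments: key atom planted on its water, everything else
  # clear of all waters (3.6 A) and sterically clear (2.6 A)
  frag_rows <- list()
  placed_xyz <- matrix(numeric(0), 0, 3)
  # `bidentate`: pair of atoms whose midpoint is planted at `key_dist` from
  # the water along the carboxylate bisector, so that both oxygens fall
  # inside the hydrogen-bond cutoff
  place_frag <- function(res, key_dist, water, resno, bidentate = NULL) {
    tpl <- .fragment_templates[[res]]
    away <- water - c(0, 0, water[3])
    for (wq in seq_len(4)) {
      if (vnorm(waters[wq, ] - water) > 1e-9) {
        away <- away + 1.2 * unitv(water - waters[wq, ])
      }
    }
    away <- unitv(away)
    wat_other <- waters[apply(waters, 1, function(w) vnorm(w - water) > 1e-9), ,
                        drop = FALSE]
    steric_obs <- rbind(all_xyz, placed_xyz)
    txyz0 <- as.matrix(tpl$atoms[, c("x", "y", "z")])
    if (is.null(bidentate)) {
      contact_rows <- which(tpl$atoms$elety == tpl$key)
      # template body extends -x from the key atom at the origin
      tpl_axis <- c(1, 0, 0)
    } else {
      contact_rows <- which(tpl$atoms$elety %in% bidentate)
      mid <- colMeans(txyz0[contact_rows, , drop = FALSE])
      root <- txyz0[tpl$atoms$elety == "CG", ]
      txyz0 <- sweep(txyz0, 2, mid)
      tpl_axis <- unitv(mid - root)
    }
    best <- NULL
    bv <- -Inf
    for (adeg in seq(-90, 90, by = 15)) {
      for (bdeg in seq(-75, 75, by = 15)) {
        dir <- as.numeric(rotation_about(c(0, 0, 1), adeg) %*% away)
        perp <- pracma_cross(c(0, 0, 1), dir)
        if (vnorm(perp) > 1e-9) {
          dir <- as.numeric(rotation_about(perp, bdeg) %*% dir)
        }
        dir <- unitv(dir)
        key_pos <- water + key_dist * dir
        R0 <- .align_rotation(tpl_axis, -dir)
        for (spin in seq(0, 345, by = 15)) {
          R <- rotation_about(dir, spin) %*% R0
          xyz <- sweep(txyz0 %*% t(R), 2, key_pos, "+")
          # only polar fragment atoms can create hydrogen-bond edges; carbons
          # need steric clearance only
          polar_rows <- setdiff(which(grepl("^[NO]", tpl$atoms$elety)),
                                contact_rows)
          carbon_rows <- setdiff(seq_len(nrow(xyz)),
                                 c(polar_rows, contact_rows))
          dw_pol <- cross_dist(xyz[polar_rows, , drop = FALSE],
                               rbind(wat_other, matrix(water, 1)))
          dw_c <- cross_dist(xyz[carbon_rows, , drop = FALSE],
                             rbind(wat_other, matrix(water, 1)))
          dw_ckey <- cross_dist(xyz[contact_rows, , drop = FALSE], wat_other)
          dst <- cross_dist(xyz, steric_obs)
          # planted contacts must fall inside the hydrogen-bond cutoff
          dcon <- sqrt(colSums((t(xyz[contact_rows, , drop = FALSE]) - water)^2))
          hard2 <- min(0, min(dcon) - 2.65, 3.40 - max(dcon))
          clear <- min(min(dw_pol) - 3.6, min(dw_ckey) - 3.6,
                       min(dw_c) - 2.9, min(dst) - 2.6, hard2)
          v <- if (clear < 0) -1000 + 100 * clear else min(clear, 0.5)
          if (v > bv) {
            bv <- v
            best <- xyz
          }
        }
      }
    }
    if (bv < -500) {
      abort(sprintf("fragment %s could not be placed without a spurious contact",
                    res))
    }
    frag_rows[[length(frag_rows) + 1L]] <<- tibble::tibble(
      chain = "P", resid = res, resno = resno, elety = tpl$atoms$elety,
      x = best[, 1], y = best[, 2], z = best[, 3]
    )
    placed_xyz <<- rbind(placed_xyz, best)
    invisible(bv)
  }
  place_frag("ASP", 2.55, w1, 1L, bidentate = c("OD1", "OD2"))
  place_frag("ARG", 2.95, w2, 2L)
  place_frag("SER", 2.75, w3, 3L)
  place_frag("TYR", 2.75, w4, 4L)

  atoms <- dplyr::bind_rows(
    at[, c("chain", "resid", "resno", "elety", "x", "y", "z")],
    dplyr::bind_rows(frag_rows),
    tibble::tibble(chain = "W", resid = "HOH", resno = 501:504, elety = "O",
                   x = waters[, 1], y = waters[, 2], z = waters[, 3])
  )
  out <- new_structure(atoms, id = "water_network_fixture",
                       meta = list(generator = "build_water_network_fixture",
                                   synthetic = TRUE))

  wtab <- tibble::tibble(chain = "W", resno = 501:504)
  out_pairs <- find_base_pairs(out)
  g <- hbond_graph(out, wtab, pairs = out_pairs)
  design <- c(
    "A/3/N4--W/501/O",
    "P/1/OD1--W/501/O", "P/1/OD2--W/501/O",
    "W/501/O--W/502/O",
    "P/2/NH1--W/502/O", "B/9/O6--W/502/O",
    "W/502/O--W/503/O",
    "P/3/OG--W/503/O", paste0(r3$label, "--W/503/O"),
    "W/503/O--W/504/O",
    "P/4/OH--W/504/O", paste0(r4$label, "--W/504/O")
  )
  design <- vapply(strsplit(design, "--"), function(x) {
    paste(sort(x), collapse = "--")
  }, character(1))
  realized <- .edge_keys(g)
  if (!setequal(realized, design)) {
    abort(paste0("water fixture geometry does not realize the designed network;\n",
                 "missing: ", paste(setdiff(design, realized), collapse = ", "),
                 "\nextra: ", paste(setdiff(realized, design), collapse = ", ")))
  }
  asn <- enumerate_h_assignments(g)
  if (asn$n_solutions != 1) {
    abort(sprintf("water fixture assignment not unique: %d solutions",
                  asn$n_solutions))
  }
  res <- list(structure = out, pairs = out_pairs, waters = wtab, graph = g,
              design_edges = design)
  .fixture_cache[[sequence]] <- res
  res
}

# placement is deterministic but not cheap; memoize per sequence
.fixture_cache <- new.env(parent = emptyenv())

.edge_keys <- function(graph) {
  lab <- function(id) {
    n <- graph$nodes[graph$nodes$id == id, ]
    sprintf("%s/%d/%s", n$chain, n$resno, n$elety)
  }
  vapply(seq_len(nrow(graph$edges)), function(k) {
    a <- lab(graph$edges$from[k])
    b <- lab(graph$edges$to[k])
    paste(sort(c(a, b)), collapse = "--")
  }, character(1))
}
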