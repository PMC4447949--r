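# DNA shape analysis: Watson-Crick base-pair detection, per-pair reference
# frames, helical-axis bend angle, raw cross-strand P-P groove widths, and
# comparison against the idealized straight B-form reference of the same
# sequence. All quantities are heavy-atom geometric; there is no full
# step-parameter (roll/tilt/twist) decomposition.

.wc_partner <- c(A = "T", T = "A", G = "C", C = "G", U = "A")
.ring_atoms <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")

# per-nucleotide key atoms for pairing
.nucleotide_table <- function(structure) {
  at <- tibble::as_tibble(structure)
  dna <- dplyr::filter(at, .data$kind == "dna")
  if (nrow(dna) == 0) return(NULL)
  dna$base <- base_letter(dna$resid)
  nest <- dna |>
    dplyr::group_by(.data$chain, .data$resno, .data$resid, .data$base) |>
    tidyr::nest() |>
    dplyr::ungroup()
  nest$wc <- purrr::map2(nest$data, nest$base, function(d, b) {
    wa <- if (b %in% c("A", "G")) "N1" else "N3"
    r <- d[d$elety == wa, ]
    if (nrow(r) == 0) NULL else c(r$x[1], r$y[1], r$z[1])
  })
  nest$c1 <- purrr::map(nest$data, function(d) {
    r <- d[d$elety == "C1'", ]
    if (nrow(r) == 0) NULL else c(r$x[1], r$y[1], r$z[1])
  })
  nest$normal <- purrr::map(nest$data, function(d) {
    r <- d[d$elety %in% .ring_atoms, ]
    if (nrow(r) < 3) return(NULL)
    m <- as.matrix(r[, c("x", "y", "z")])
    s <- svd(sweep(m, 2, colMeans(m)))
    s$v[, 3]
  })
  nest$centroid <- purrr::map(nest$data, function(d) {
    r <- d[d$elety %in% .ring_atoms, ]
    if (nrow(r) == 0) return(NULL)
    colMeans(as.matrix(r[, c("x", "y", "z")]))
  })
  nest
}

#' Detect Watson-Crick base pairs
#'
#' Pairs complementary nucleotides on geometric criteria (WC-edge N1/N3
#' distance, C1'-C1' distance, base-plane normal angle), keeps the maximal
#' non-conflicting set, orders pairs 5'->3' along the reference strand, and
#' registers the Ets-binding-site coordinate (first G of the GGA core = +1,
#' positions -3...+6 with no position 0) by locating GGA on either strand.
#'
#' @param structure an `ets_structure` containing a DNA duplex.
#' @param max_wc maximum N1-N3 distance (Angstrom).
#' @param c1_range admissible C1'-C1' distance range.
#' @param max_plane_angle maximum angle between base-plane normals (degrees).
#' @param ref_chain reference strand chain id; default: the strand whose
#'   5'->3' sequence contains GGA, else the first DNA chain.
#' @return tibble of class `ets_base_pairs`: one row per pair with columns
#'   `pair_index`, `chain_i`, `resno_i`, `base_i`, `chain_j`, `resno_j`,
#'   `base_j`, `wc_class`, `wc_dist`, `ebs_position` (NA when no GGA core).
#' @export
find_base_pairs <- function(structure, max_wc = 3.5, c1_range = c(9.5, 11),
                            max_plane_angle = 65, ref_chain = NULL) {
  nt <- .nucleotide_table(structure)
  if (is.null(nt) || nrow(nt) < 2) {
    warn("no base pairs: structure has fewer than 2 nucleotides")
    return(.empty_pairs())
  }
  ok <- !purrr::map_lgl(nt$wc, is.null) & !purrr::map_lgl(nt$c1, is.null) &
    !purrr::map_lgl(nt$normal, is.null)
  nt <- nt[ok, ]
  n <- nrow(nt)
  cand <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (nt$base[j] != .wc_partner[[nt$base[i]]]) next
      dwc <- vnorm(nt$wc[[i]] - nt$wc[[j]])
      if (dwc > max_wc) next
      dc1 <- vnorm(nt$c1[[i]] - nt$c1[[j]])
      if (dc1 < c1_range[1] || dc1 > c1_range[2]) next
      a <- dir_angle(nt$normal[[i]], nt$normal[[j]])
      if (min(a, 180 - a) > max_plane_angle) next
      cand[[length(cand) + 1L]] <- tibble::tibble(i = i, j = j, wc_dist = dwc)
    }
  }
  if (length(cand) == 0) {
    warn("no base pairs detected")
    return(.empty_pairs())
  }
  cand <- dplyr::arrange(dplyr::bind_rows(cand), .data$wc_dist)
  used <- rep(FALSE, n)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (!used[i] && !used[j]) {
      keep[k] <- TRUE
      used[i] <- used[j] <- TRUE
    }
  }
  cand <- cand[keep, ]

  # orient: i-member on the reference strand
  chains <- unique(nt$chain)
  seq_of <- function(ch) {
    r <- nt[nt$chain == ch, ]
    r <- r[order(r$resno), ]
    paste(r$base, collapse = "")
  }
  if (is.null(ref_chain)) {
    withgga <- chains[vapply(chains, function(ch) grepl("GGA", seq_of(ch)),
                             logical(1))]
    ref_chain <- if (length(withgga) > 0) withgga[1] else nt$chain[1]
  }
  swap <- nt$chain[cand$j] == ref_chain & nt$chain[cand$i] != ref_chain
  tmp <- cand$i[swap]; cand$i[swap] <- cand$j[swap]; cand$j[swap] <- tmp
  cand <- cand[nt$chain[cand$i] == ref_chain, , drop = FALSE]
  ord <- order(nt$resno[cand$i])
  cand <- cand[ord, ]

  pairs <- tibble::tibble(
    pair_index = seq_len(nrow(cand)),
    chain_i = nt$chain[cand$i], resno_i = nt$resno[cand$i],
    base_i = nt$base[cand$i],
    chain_j = nt$chain[cand$j], resno_j = nt$resno[cand$j],
    base_j = nt$base[cand$j],
    wc_class = "WC",
    wc_dist = cand$wc_dist,
    ebs_position = NA_integer_
  )

  # EBS registration on either strand
  ref_seq <- paste(pairs$base_i, collapse = "")
  cmp_seq <- paste(rev(pairs$base_j), collapse = "") # other strand 5'->3'
  g <- regexpr("GGA", ref_seq)[1]
  if (g > 0) {
    pairs$ebs_position <- .ebs_labels(seq_len(nrow(pairs)), g)
  } else {
    g2 <- regexpr("GGA", cmp_seq)[1]
    if (g2 > 0) {
      # register along the complementary strand (its 5'->3' order)
      idx_along_cmp <- rev(seq_len(nrow(pairs)))
      pairs$ebs_position <- .ebs_labels(idx_along_cmp, g2)
    } else {
      warn("GGA core not found on either strand; ebs_position left NA")
    }
  }
  class(pairs) <- c("ets_base_pairs", class(pairs))
  attr(pairs, "ref_chain") <- ref_chain
  pairs
}

.ebs_labels <- function(idx, g) {
  lab <- idx - g + 1L
  lab[lab <= 0L] <- lab[lab <= 0L] - 1L # no position 0: ...,-2,-1,+1,...
  lab
}

.empty_pairs <- function() {
  p <- tibble::tibble(pair_index = integer(), chain_i = character(),
                      resno_i = integer(), base_i = character(),
                      chain_j = character(), resno_j = integer(),
                      base_j = character(), wc_class = character(),
                      wc_dist = numeric(), ebs_position = integer())
  class(p) <- c("ets_base_pairs", class(p))
  p
}

#' Base-pair reference frames
#'
#' For each detected pair: origin at the midpoint of the two Watson-Crick-edge
#' nitrogens; y-axis from the complementary strand's C1' toward the reference
#' strand's C1'; z-axis the mean base-plane normal, sign-aligned 5'->3' along
#' the reference strand; x-axis completing a right-handed orthonormal triad
#' (pointing into the major groove).
#'
#' @param structure an `ets_structure`.
#' @param pairs result of [find_base_pairs()].
#' @return tibble with `pair_index`, origin (`ox`,`oy`,`oz`) and the triad as
#'   list-columns `x_axis`, `y_axis`, `z_axis` (orthonormal to 1e-8).
#' @export
bp_frames <- function(structure, pairs) {
  nt <- .nucleotide_table(structure)
  key <- paste(nt$chain, nt$resno)
  gi <- match(paste(pairs$chain_i, pairs$resno_i), key)
  gj <- match(paste(pairs$chain_j, pairs$resno_j), key)
  n <- nrow(pairs)
  origin <- matrix(NA_real_, n, 3)
  zs <- vector("list", n)
  ys <- vector("list", n)
  for (k in seq_len(n)) {
    origin[k, ] <- (nt$wc[[gi[k]]] + nt$wc[[gj[k]]]) / 2
    ni <- nt$normal[[gi[k]]]
    nj <- nt$normal[[gj[k]]]
    if (sum(ni * nj) < 0) nj <- -nj
    zs[[k]] <- unitv(ni + nj)
    ys[[k]] <- unitv(nt$c1[[gi[k]]] - nt$c1[[gj[k]]])
  }
  # orient z along the 5'->3' direction of the reference strand
  if (n >= 2) {
    for (k in seq_len(n)) {
      step <- if (k < n) origin[k + 1, ] - origin[k, ] else origin[k, ] - origin[k - 1, ]
      if (sum(zs[[k]] * step) < 0) zs[[k]] <- -zs[[k]]
    }
  }
  out <- tibble::tibble(
    pair_index = pairs$pair_index,
    ox = origin[, 1], oy = origin[, 2], oz = origin[, 3]
  )
  out$x_axis <- vector("list", n)
  out$y_axis <- vector("list", n)
  out$z_axis <- vector("list", n)
  for (k in seq_len(n)) {
    z <- zs[[k]]
    y <- ys[[k]]
    x <- unitv(pracma_cross(y, z))
    y <- unitv(pracma_cross(z, x))
    out$x_axis[[k]] <- x
    out$y_axis[[k]] <- y
    out$z_axis[[k]] <- z
  }
  out
}

#' Helical bend angle between duplex ends
#'
#' Estimates a local helix axis at each end of the duplex as the normalized
#' mean of the terminal `end_len` pair z-axes (pair origins lie off the helix
#' axis, so a straight average of pair normals is the stable local-axis
#' estimator at these segment lengths) and reports the angle between the two
#' end axes.
#'
#' @param frames result of [bp_frames()].
#' @param end_len pairs per terminal segment (>= 2; default 4).
#' @return list of class `ets_bend`: `bend_angle` (degrees, 0-180),
#'   `axis_5p`, `axis_3p`, `end_len`.
#' @export
bend_angle <- function(frames, end_len = 4) {
  n <- nrow(frames)
  if (n < 2 * end_len) {
    abort(sprintf("insufficient data: %d pairs, need >= %d for end_len %d",
                  n, 2 * end_len, end_len))
  }
  zmean <- function(idx) {
    m <- do.call(rbind, frames$z_axis[idx])
    unitv(colMeans(m))
  }
  i1 <- seq_len(end_len)
  i2 <- (n - end_len + 1):n
  a1 <- zmean(i1)
  a2 <- zmean(i2)
  out <- list(bend_angle = dir_angle(a1, a2), axis_5p = a1, axis_3p = a2,
              end_len = end_len)
  class(out) <- "ets_bend"
  out
}

#' @export
print.ets_bend <- function(x, ...) {
  cat(sprintf("<bend>  %.2f degrees (terminal %d-pair axes)\n",
              x$bend_angle, x$end_len))
  invisible(x)
}

# pair-level offset windows (reference-strand P at level i vs complementary
# strand P at level i - m) whose cross-strand minima track the two grooves of
# the fiber model; raw P-P distances, no probe-radius correction
.groove_windows <- list(minor = 2:5, major = -(1:5))

#' Groove-width profile
#'
#' Raw cross-strand phosphorus-phosphorus distances: at each level the minor
#' (and major) groove width is the minimum P-P distance over the pair-level
#' offset window characteristic of that groove on the B-DNA register. Levels
#' where a phosphate is missing (chain termini) are NA, flagged `undefined`.
#'
#' @param structure an `ets_structure`.
#' @param pairs result of [find_base_pairs()].
#' @param windows named list with integer offset windows `minor` and `major`.
#' @return tibble of class `ets_grooves`: `pair_index`, `minor`, `major`
#'   (Angstrom or NA), `undefined_minor`, `undefined_major`.
#' @export
groove_widths <- function(structure, pairs, windows = .groove_windows) {
  at <- tibble::as_tibble(structure)
  p_of <- function(ch, rn) {
    r <- at[at$chain == ch & at$resno == rn & at$elety == "P", ]
    if (nrow(r) == 0) NULL else c(r$x[1], r$y[1], r$z[1])
  }
  n <- nrow(pairs)
  pI <- purrr::map(seq_len(n), ~ p_of(pairs$chain_i[.x], pairs$resno_i[.x]))
  pII <- purrr::map(seq_len(n), ~ p_of(pairs$chain_j[.x], pairs$resno_j[.x]))
  width_at <- function(i, offs) {
    ds <- purrr::map_dbl(offs, function(m) {
      j <- i - m
      if (j < 1 || j > n || is.null(pI[[i]]) || is.null(pII[[j]])) return(NA_real_)
      vnorm(pI[[i]] - pII[[j]])
    })
    if (all(is.na(ds))) NA_real_ else min(ds, na.rm = TRUE)
  }
  out <- tibble::tibble(
    pair_index = pairs$pair_index,
    minor = purrr::map_dbl(seq_len(n), width_at, offs = windows$minor),
    major = purrr::map_dbl(seq_len(n), width_at, offs = windows$major)
  )
  out$undefined_minor <- is.na(out$minor)
  out$undefined_major <- is.na(out$major)
  class(out) <- c("ets_grooves", class(out))
  out
}

#' Summary extrema of a groove profile
#' @param grooves result of [groove_widths()].
#' @return one-row tibble with minor min/max and major min/max (Angstrom).
#' @export
groove_extrema <- function(grooves) {
  tibble::tibble(
    minor_min = suppressWarnings(min(grooves$minor, na.rm = TRUE)),
    minor_max = suppressWarnings(max(grooves$minor, na.rm = TRUE)),
    major_min = suppressWarnings(min(grooves$major, na.rm = TRUE)),
    major_max = suppressWarnings(max(grooves$major, na.rm = TRUE))
  )
}

#' Compare duplex geometry with the canonical straight B form
#'
#' Builds the idealized fiber duplex of the same reference-strand sequence,
#' superposes it on the central four pairs (C1' atoms of both strands), and
#' reports per-level groove deltas, the bend-angle delta, and per-pair origin
#' displacement.
#'
#' @param structure an `ets_structure` containing the duplex to assess.
#' @param pairs optional precomputed [find_base_pairs()] result.
#' @param end_len passed to [bend_angle()].
#' @return list of class `ets_bform_report`: `per_level` tibble (pair_index,
#'   minor/major deltas, origin displacement), `bend_delta` (degrees),
#'   `bend`, `bend_ref`, and `superposition`.
#' @export
compare_to_bform <- function(structure, pairs = NULL, end_len = 4) {
  if (is.null(pairs)) pairs <- find_base_pairs(structure)
  if (nrow(pairs) < 2 * end_len) abort("too few base pairs for comparison")
  seq_ref <- paste(pairs$base_i, collapse = "")
  ref <- build_bdna(seq_ref, id = "bform_ref")
  ref_pairs <- find_base_pairs(ref)
  if (paste(ref_pairs$base_i, collapse = "") != seq_ref) {
    abort("sequence mismatch between duplex and rebuilt reference")
  }

  # pair C1' atoms of the central 4 pairs for superposition
  n <- nrow(pairs)
  ctr <- seq(floor(n / 2) - 1, length.out = 4)
  ctr <- ctr[ctr >= 1 & ctr <= n]
  at_s <- tibble::as_tibble(structure)
  at_r <- tibble::as_tibble(ref)
  row_of <- function(at, ch, rn) which(at$chain == ch & at$resno == rn &
                                         at$elety == "C1'")[1]
  mi <- c(); ri <- c()
  for (k in ctr) {
    mi <- c(mi, row_of(at_r, ref_pairs$chain_i[k], ref_pairs$resno_i[k]),
            row_of(at_r, ref_pairs$chain_j[k], ref_pairs$resno_j[k]))
    ri <- c(ri, row_of(at_s, pairs$chain_i[k], pairs$resno_i[k]),
            row_of(at_s, pairs$chain_j[k], pairs$resno_j[k]))
  }
  sup <- superpose(ref, structure, pairing = tibble::tibble(i = mi, j = ri))
  ref_fit <- sup$mobile_transformed

  fr_s <- bp_frames(structure, pairs)
  fr_r <- bp_frames(ref_fit, ref_pairs)
  g_s <- groove_widths(structure, pairs)
  g_r <- groove_widths(ref_fit, ref_pairs)
  m <- min(nrow(pairs), nrow(ref_pairs))
  per_level <- tibble::tibble(
    pair_index = pairs$pair_index[seq_len(m)],
    minor_delta = g_s$minor[seq_len(m)] - g_r$minor[seq_len(m)],
    major_delta = g_s$major[seq_len(m)] - g_r$major[seq_len(m)],
    origin_displacement = purrr::map_dbl(seq_len(m), function(k) {
      vnorm(c(fr_s$ox[k] - fr_r$ox[k], fr_s$oy[k] - fr_r$oy[k],
              fr_s$oz[k] - fr_r$oz[k]))
    })
  )
  b_s <- bend_angle(fr_s, end_len = end_len)
  b_r <- bend_angle(fr_r, end_len = end_len)
  out <- list(per_level = per_level,
              bend = b_s$bend_angle, bend_ref = b_r$bend_angle,
              bend_delta = b_s$bend_angle - b_r$bend_angle,
              superposition = sup)
  class(out) <- "ets_bform_report"
  out
}

#' @export
print.ets_bform_report <- function(x, ...) {
  cat(sprintf("<B-form comparison>  bend %.2f deg (ref %.2f, delta %+.2f)\n",
              x$bend, x$bend_ref, x$bend_delta))
  cat(sprintf("  mean |origin displacement| %.2f A; major-groove delta range [%.2f, %.2f] A\n",
              mean(x$per_level$origin_displacement, na.rm = TRUE),
              suppressWarnings(min(x$per_level$major_delta, na.rm = TRUE)),
              suppressWarnings(max(x$per_level$major_delta, na.rm = TRUE))))
  invisible(x)
}
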