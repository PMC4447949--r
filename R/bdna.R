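# Idealized fiber-model B-DNA generator. Geometry is an idealized straight
# fiber: fixed twist/rise, planar Watson-Crick pairs built from literal 2D
# base templates (regular-ring idealization), and a cylindrical sugar-
# phosphate backbone. The model is the canonical reference that complexed DNA
# is compared against; it makes no attempt at sequence-dependent shape.

# --- frozen fiber constants ---------------------------------------------------
.bdna <- list(
  twist = 36.0,      # degrees per step
  rise = 3.38,       # Angstrom per step
  c1_x = -2.2,       # pair-frame x of C1' (minor-groove side)
  c1_y = 5.2,        # half the C1'-C1' separation
  lambda = 54.5,     # glycosidic bond angle vs the C1'-C1' line, degrees
  n_c1 = 1.48,       # C1'-N glycosidic bond length
  hbond = 2.9,       # WC N1...N3 distance
  p_r = 9.918,       # phosphorus cylinder radius (successive P-P ~ 7.0 A)
  p_phi = 87.768,    # P azimuth offset from the pair x-axis, degrees
  p_z = -1.879       # P z offset below its own pair plane (5' side)
)

# --- literal 2D base templates ------------------------------------------------
# Regular hexagon (side 1.37 A) with glycosidic N1 at the origin; purines add
# a regular fused pentagon. Exocyclic substituents sit on the external angle
# bisectors at standard bond lengths (C=O 1.23, C-N 1.34, C-CH3 1.50).

.hexagon <- local({
  ctr <- c(1.37, 0)
  ang <- c(180, 120, 60, 0, -60, -120) * pi / 180
  v <- t(vapply(ang, function(a) ctr + 1.37 * c(cos(a), sin(a)), numeric(2)))
  rownames(v) <- c("N1", "C2", "N3", "C4", "C5", "C6")
  v
})

.exo <- function(ring, at, len) {
  d <- ring[at, ] - c(1.37, 0)
  ring[at, ] + len * d / sqrt(sum(d^2))
}

.pentagon <- local({
  c4 <- .hexagon["C4", ]
  c5 <- .hexagon["C5", ]
  m <- (c4 + c5) / 2
  perp <- c(0.866, -0.5) # unit normal of C4-C5, away from the hexagon centre
  rp <- 1.37 / (2 * sin(36 * pi / 180))
  ctr <- m + rp * cos(36 * pi / 180) * perp
  a0 <- atan2(c4[2] - ctr[2], c4[1] - ctr[1])
  ang <- a0 + (0:4) * 72 * pi / 180
  v <- t(vapply(ang, function(a) ctr + rp * c(cos(a), sin(a)), numeric(2)))
  rownames(v) <- c("C4", "C5", "N7", "C8", "N9")
  v[c("N7", "C8", "N9"), ]
})

# 2D templates: matrix of base heavy atoms, plus names of the glycosidic and
# Watson-Crick-edge nitrogen used to place the base in the pair frame.
.base_templates <- local({
  hex <- .hexagon
  pur <- rbind(hex, .pentagon)
  tpl <- list(
    A = list(xy = rbind(pur, N6 = .exo(hex, "C6", 1.34)),
             gly = "N9", wc = "N1"),
    G = list(xy = rbind(pur, O6 = .exo(hex, "C6", 1.23),
                        N2 = .exo(hex, "C2", 1.34)),
             gly = "N9", wc = "N1"),
    C = list(xy = rbind(hex, O2 = .exo(hex, "C2", 1.23),
                        N4 = .exo(hex, "C4", 1.34)),
             gly = "N1", wc = "N3"),
    T = list(xy = rbind(hex, O2 = .exo(hex, "C2", 1.23),
                        O4 = .exo(hex, "C4", 1.23),
                        C7 = .exo(hex, "C5", 1.50)),
             gly = "N1", wc = "N3")
  )
  tpl
})

.complement <- c(A = "T", T = "A", G = "C", C = "G")

# Glycosidic-bond direction angles (radians; direction of the C1'->N bond in
# the pair frame). The base ring is slaved to this direction: its external
# ring-angle bisector at the glycosidic nitrogen points back at C1'. The four
# angles were fixed once by least squares so that every canonical Watson-Crick
# hydrogen bond (N1-N3, G:O6-C:N4, G:N2-C:O2, A:N6-T:O4) closes at 2.8-2.97 A
# with no cross-base clash. Purines are parameterized on strand I, pyrimidines
# on strand II.
.base_theta <- list(G = -2.35580, C = 2.59291, A = -2.36506, T = 2.60287)

# Ring neighbors of the glycosidic nitrogen, per template (for the bisector).
.gly_neighbors <- list(A = c("C4", "C8"), G = c("C4", "C8"),
                       C = c("C2", "C6"), T = c("C2", "C6"))

# Place a base template: glycosidic N at c1 + 1.48 * (cos theta, sin theta),
# ring oriented so the external bisector at the glycosidic N points at C1'.
.place_base <- function(letter, theta, c1) {
  tpl <- .base_templates[[letter]]
  xy <- tpl$xy
  xy[, 2] <- -xy[, 2] # template chirality
  ng <- xy[tpl$gly, ]
  nb <- .gly_neighbors[[letter]]
  b <- -(unitv(xy[nb[1], ] - ng) + unitv(xy[nb[2], ] - ng))
  b <- b / sqrt(sum(b^2))
  u <- c(cos(theta), sin(theta))
  th <- atan2(-u[2], -u[1]) - atan2(b[2], b[1])
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  sweep(t(R %*% t(sweep(xy, 2, ng))), 2, c1 + 1.48 * u, "+")
}

# Base atoms of one nucleotide in the pair frame, strand-I orientation
# (C1' anchored on the +y side, WC edge meeting the partner).
.strand1_base <- function(letter) {
  p <- .bdna
  if (letter %in% c("A", "G")) {
    xy <- .place_base(letter, .base_theta[[letter]], c(p$c1_x, p$c1_y))
  } else {
    # pyrimidines are parameterized on strand II; mirror onto strand I
    xy <- .place_base(letter, .base_theta[[letter]], c(p$c1_x, -p$c1_y))
    xy[, 2] <- -xy[, 2]
  }
  cbind(xy, z = 0)
}

.flip_about_x <- function(xyz) {
  xyz[, 2] <- -xyz[, 2]
  xyz[, 3] <- -xyz[, 3]
  xyz
}

#' Build an idealized B-form DNA duplex
#'
#' Generates two antiparallel complementary strands on a straight helical
#' fiber (twist 36 deg, rise 3.38 A by default) with standard nucleotide atom
#' names. Watson-Crick pairing is exact by construction; the 5'-terminal
#' phosphate group of each strand is omitted.
#'
#' @param sequence 5'->3' reference-strand sequence over A/C/G/T (length >= 2).
#' @param twist degrees per base-pair step, in (0, 360).
#' @param rise Angstrom per step, > 0.
#' @param id structure label.
#' @return an `ets_structure` with chains A (reference strand, 5'->3') and B
#'   (complementary strand).
#' @export
build_bdna <- function(sequence, twist = 36, rise = 3.38, id = "bdna") {
  bases <- strsplit(toupper(sequence), "")[[1]]
  if (length(bases) < 2) abort("sequence must have length >= 2")
  bad <- setdiff(bases, c("A", "C", "G", "T"))
  if (length(bad) > 0) {
    abort(paste0("invalid base letter(s): ", paste(unique(bad), collapse = ", ")))
  }
  if (!(twist > 0 && twist < 360)) abort("twist must be in (0, 360) degrees")
  if (!(rise > 0)) abort("rise must be > 0")
  p <- .bdna
  n <- length(bases)

  step_rot <- function(k) rotation_about(c(0, 0, 1), (k - 1) * twist)
  place <- function(xyz, k) {
    out <- xyz %*% t(step_rot(k))
    out[, 3] <- out[, 3] + (k - 1) * rise
    out
  }

  # anchors per pair, strand I and strand II, in global coordinates
  c1_I <- cbind(p$c1_x, p$c1_y, 0)
  p_I <- cbind(p$p_r * cos(p$p_phi * pi / 180),
               p$p_r * sin(p$p_phi * pi / 180), p$p_z)

  nt_rows <- list()
  add_atoms <- function(xyz, names_, chain, resno, resid) {
    nt_rows[[length(nt_rows) + 1L]] <<- tibble::tibble(
      chain = chain, resid = resid, resno = as.integer(resno),
      elety = names_, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
    )
  }

  for (k in seq_len(n)) {
    bI <- bases[k]
    bII <- .complement[[bI]]
    # strand I (chain A), residue k == pair k
    baseI <- place(.strand1_base(bI), k)
    add_atoms(baseI, rownames(.strand1_base(bI)), "A", k, paste0("D", bI))
    # strand II (chain B): flipped strand-I construction of the complement
    baseII <- place(.flip_about_x(.strand1_base(bII)), k)
    add_atoms(baseII, rownames(.strand1_base(bII)), "B", n + 1L - k,
              paste0("D", bII))
  }

  # backbone anchors in global coordinates (incl. virtual flanking P's)
  pI_all <- t(vapply(0:(n + 1), function(k) place(p_I, k)[1, ], numeric(3)))
  c1I_all <- t(vapply(seq_len(n), function(k) place(c1_I, k)[1, ], numeric(3)))
  glyI <- cbind(p$c1_x + p$n_c1 * sin(p$lambda * pi / 180),
                p$c1_y - p$n_c1 * cos(p$lambda * pi / 180), 0)
  glyI_all <- t(vapply(seq_len(n), function(k) place(glyI, k)[1, ], numeric(3)))
  pII_ref <- .flip_about_x(p_I)
  pII_all <- t(vapply(0:(n + 1), function(k) place(pII_ref, k)[1, ], numeric(3)))
  c1II_all <- t(vapply(seq_len(n), function(k) place(.flip_about_x(c1_I), k)[1, ],
                       numeric(3)))
  glyII_all <- t(vapply(seq_len(n), function(k) place(.flip_about_x(glyI), k)[1, ],
                        numeric(3)))

  # sugar + phosphate atoms for one residue given its anchors; p5/p3 are the
  # 5'- and 3'-side phosphorus positions along this strand
  sugar <- function(a, g, p5, p3, first) {
    e1 <- unitv(g - a)                 # toward the base
    d <- unitv(p3 - p5)                # local 5'->3' strand direction
    e3 <- unitv(d - sum(d * e1) * e1)  # strand direction, orthogonal to e1
    e2 <- unitv(pracma_cross(e3, e1))
    lf <- function(v) a + v[1] * e1 + v[2] * e2 + v[3] * e3
    pos <- rbind(
      "C2'" = lf(.sugar_local[["C2'"]]),
      "C3'" = lf(.sugar_local[["C3'"]]),
      "O4'" = lf(.sugar_local[["O4'"]]),
      "C4'" = lf(.sugar_local[["C4'"]]),
      "C5'" = lf(.sugar_local[["C5'"]])
    )
    c3 <- pos["C3'", ]
    o3 <- p3 + 1.60 * unitv(c3 - p3)
    c5 <- pos["C5'", ]
    o5 <- p5 + 1.59 * unitv(c5 - p5)
    pos <- rbind(pos, "O3'" = o3, "O5'" = o5)
    if (!first) {
      ax <- unitv(p5 - colMeans(rbind(a, g)))  # roughly radial-out at P
      up <- c(0, 0, 1)
      op1 <- p5 + 1.48 * unitv(ax + 0.9 * up)
      op2 <- p5 + 1.48 * unitv(ax - 0.9 * up)
      pos <- rbind(pos, "P" = p5, "OP1" = op1, "OP2" = op2)
    }
    pos
  }

  for (k in seq_len(n)) {
    sI <- sugar(c1I_all[k, ], glyI_all[k, ], pI_all[k + 1, ], pI_all[k + 2, ],
                first = (k == 1))
    add_atoms(rbind(sI, "C1'" = c1I_all[k, ]),
              c(rownames(sI), "C1'"), "A", k, paste0("D", bases[k]))
    # strand II residue paired with pair k; its 5' side is at pair k+1
    sII <- sugar(c1II_all[k, ], glyII_all[k, ], pII_all[k + 1, ], pII_all[k, ],
                 first = (k == n))
    add_atoms(rbind(sII, "C1'" = c1II_all[k, ]),
              c(rownames(sII), "C1'"), "B", n + 1L - k,
              paste0("D", .complement[[bases[k]]]))
  }

  atoms <- dplyr::bind_rows(nt_rows) |>
    dplyr::arrange(.data$chain, .data$resno)
  new_structure(atoms, id = id,
                meta = list(generator = "build_bdna", sequence = sequence,
                            twist = twist, rise = rise))
}

# deoxyribose ring offsets in the nucleotide local frame (e1 toward base,
# e3 along the strand); idealized, frozen after geometric calibration
.sugar_local <- list(
  "C2'" = c(-0.801, -0.715, -1.027),
  "C3'" = c(-2.146, 0.110, -0.978),
  "O4'" = c(-0.424, 1.373, -0.117),
  "C4'" = c(-1.553, 1.527, -1.033),
  "C5'" = c(-0.986, 1.763, -2.423)
)

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
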