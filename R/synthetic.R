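# Synthetic fixture generation: toy protein-DNA complexes with planted
# interactions at exact distances, Gaussian coordinate perturbation, and a
# synthetic recognition-water network. Planted fixtures provide ground truth
# for every detection stage without any external coordinate file.

# Minimal side-chain fragment templates in a local frame: the interaction
# ("key") atom at the origin, the residue body extending into the -x
# half-space (so the key atom is always the closest atom to the target).
.fragment_templates <- list(
  SER = list(key = "OG", atoms = tibble::tribble(
    ~elety, ~x, ~y, ~z,
    "OG", 0, 0, 0,
    "CB", -1.43, 0, 0,
    "CA", -2.25, 1.17, -0.35,
    "N", -3.60, 0.95, -0.85,
    "C", -2.35, 2.25, 0.72,
    "O", -1.85, 3.36, 0.55
  )),
  LYS = list(key = "NZ", atoms = tibble::tribble(
    ~elety, ~x, ~y, ~z,
    "NZ", 0, 0, 0,
    "CE", -1.49, 0, 0,
    "CD", -2.12, 1.30, -0.42,
    "CG", -3.64, 1.24, -0.45,
    "CB", -4.27, 2.55, -0.90,
    "CA", -5.79, 2.50, -0.93,
    "N", -6.35, 1.65, -2.00,
    "C", -6.37, 3.90, -1.05,
    "O", -5.95, 4.78, -0.30
  )),
  ASP = list(key = "OD1", atoms = tibble::tribble(
    ~elety, ~x, ~y, ~z,
    "OD1", 0, 0, 0,
    "CG", -1.25, 0, 0.35,
    "OD2", -1.85, -1.05, 0.55,
    "CB", -2.05, 1.28, 0.45,
    "CA", -3.53, 1.05, 0.75,
    "N", -4.25, 0.35, -0.35,
    "C", -4.20, 2.38, 1.05,
    "O", -3.75, 3.45, 0.62
  )),
  ARG = list(key = "NH1", atoms = tibble::tribble(
    ~elety, ~x, ~y, ~z,
    "NH1", 0, 0, 0,
    "CZ", -1.33, 0, 0,
    "NH2", -2.00, -1.10, 0.28,
    "NE", -2.00, 1.12, -0.30,
    "CD", -3.45, 1.20, -0.40,
    "CG", -4.05, 2.55, -0.75,
    "CB", -5.55, 2.55, -0.85,
    "CA", -6.15, 3.90, -1.15,
    "N", -5.75, 4.90, -0.18,
    "C", -7.65, 3.80, -1.25,
    "O", -8.25, 2.90, -0.68
  )),
  TYR = list(key = "OH", atoms = tibble::tribble(
    ~elety, ~x, ~y, ~z,
    "OH", 0, 0, 0,
    "CZ", -1.38, 0, 0,
    "CE1", -2.08, 1.18, -0.22,
    "CE2", -2.08, -1.18, 0.22,
    "CD1", -3.47, 1.18, -0.25,
    "CD2", -3.47, -1.19, 0.20,
    "CG", -4.17, -0.01, -0.03,
    "CB", -5.67, -0.02, -0.05,
    "CA", -6.30, 1.35, -0.35,
    "N", -6.00, 2.30, 0.70,
    "C", -7.80, 1.25, -0.50,
    "O", -8.40, 0.30, 0.05
  )),
  GLN = list(key = "NE2", atoms = tibble::tribble(
    ~elety, ~x, ~y, ~z,
    "NE2", 0, 0, 0,
    "CD", -1.33, 0, 0.30,
    "OE1", -1.95, -1.02, 0.62,
    "CG", -2.10, 1.30, 0.28,
    "CB", -3.60, 1.15, 0.52,
    "CA", -4.35, 2.47, 0.45,
    "N", -4.05, 3.25, -0.72,
    "C", -5.85, 2.25, 0.55,
    "O", -6.40, 1.30, -0.05
  )),
  ALA = list(key = "CB", atoms = tibble::tribble(
    ~elety, ~x, ~y, ~z,
    "CB", 0, 0, 0,
    "CA", -1.52, 0, 0,
    "N", -2.10, 1.15, -0.70,
    "C", -2.10, -1.28, -0.55,
    "O", -1.55, -2.35, -0.30
  ))
)

# rotation taking unit vector `from` to unit vector `to`
.align_rotation <- function(from, to) {
  from <- unitv(from); to <- unitv(to)
  ax <- pracma_cross(from, to)
  s <- vnorm(ax)
  ct <- sum(from * to)
  if (s < 1e-12) {
    if (ct > 0) return(diag(3))
    perp <- if (abs(from[1]) < 0.9) pracma_cross(from, c(1, 0, 0)) else
      pracma_cross(from, c(0, 1, 0))
    return(rotation_about(perp, 180))
  }
  rotation_about(ax, atan2(s, ct) * 180 / pi)
}

# xyz of one named atom of a structure
atom_xyz <- function(structure, chain, resno, elety) {
  at <- tibble::as_tibble(structure)
  r <- at[at$chain == chain & at$resno == resno & at$elety == elety, ]
  if (nrow(r) == 0) {
    abort(sprintf("atom not found: %s/%d/%s", chain, resno, elety))
  }
  c(r$x[1], r$y[1], r$z[1])
}

# approach direction at a target atom: away from its covalent antecedent if
# the dictionary knows one, else radially away from the DNA helix axis (z)
.approach_dir <- function(structure, target) {
  txyz <- atom_xyz(structure, target$chain, target$resno, target$elety)
  pol <- polar_atoms(structure)
  hit <- pol[pol$chain == target$chain & pol$resno == target$resno &
               pol$elety == target$elety, ]
  if (nrow(hit) == 1 && !is.na(hit$antecedent)) {
    ax <- tryCatch(atom_xyz(structure, target$chain, target$resno,
                            hit$antecedent),
                   error = function(e) NULL)
    if (!is.null(ax)) return(unitv(txyz - ax))
  }
  radial <- c(txyz[1], txyz[2], 0)
  if (vnorm(radial) < 1e-6) radial <- c(1, 0, 0)
  unitv(radial)
}

#' Build a toy complex with planted interactions
#'
#' Constructs a short idealized duplex plus side-chain fragments positioned so
#' that each requested interaction exists at the requested distance (within
#' 0.05 A), the fragment body pointing away from the DNA. Waters are planted
#' either at explicit coordinates or between two named atoms at stated
#' distances.
#'
#' @param sequence duplex sequence for the DNA scaffold (NULL for no DNA).
#' @param hbonds list of planted hydrogen bonds; each element is
#'   `list(res = "SER", target = list(chain=, resno=, elety=), distance = 2.9)`
#'   (`res` picks the fragment template; its key atom makes the bond).
#' @param salt_bridges same shape (use `res = "LYS"` or `"ARG"`).
#' @param waters list of planted waters: either `list(xyz = c(x, y, z))` or
#'   `list(between = list(a = list(chain=,resno=,elety=), b = list(...)),
#'   d_a = 2.8, d_b = 2.8)`.
#' @param protein_chain chain id for the planted fragments.
#' @param min_sep smallest allowed distance between non-planted atom pairs of
#'   different residues before a geometry-conflict error is raised.
#' @return an `ets_structure`.
#' @export
build_planted_complex <- function(sequence = "ACCGGAAGTG", hbonds = list(),
                                  salt_bridges = list(), waters = list(),
                                  protein_chain = "P", min_sep = 1.5) {
  stopifnot(!is.null(sequence))
  s <- build_bdna(sequence, id = "planted_complex")
  frags <- list()
  resno <- 0L
  for (spec in c(hbonds, salt_bridges)) {
    resno <- resno + 1L
    d <- spec$distance
    if (d < 2.2 || d > 4.5) {
      abort(sprintf("planted distance %.2f A outside detection-feasible range 2.2-4.5", d))
    }
    tpl <- .fragment_templates[[spec$res]]
    if (is.null(tpl)) abort(paste0("no fragment template for residue ", spec$res))
    txyz <- atom_xyz(s, spec$target$chain, spec$target$resno, spec$target$elety)
    u <- .approach_dir(s, spec$target)
    key_pos <- txyz + d * u
    R <- .align_rotation(c(1, 0, 0), -u) # body (-x) extends along +u
    xyz <- as.matrix(tpl$atoms[, c("x", "y", "z")]) %*% t(R)
    xyz <- sweep(xyz, 2, key_pos, "+")
    frags[[length(frags) + 1L]] <- tibble::tibble(
      chain = protein_chain, resid = spec$res, resno = resno,
      elety = tpl$atoms$elety, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
    )
  }
  wat <- list()
  wno <- 500L
  all_so_far <- if (length(frags) > 0) {
    new_structure(dplyr::bind_rows(tibble::as_tibble(s)[, c("chain", "resid", "resno", "elety", "x", "y", "z")],
                                   dplyr::bind_rows(frags)), id = "tmp")
  } else s
  for (w in waters) {
    wno <- wno + 1L
    if (!is.null(w$xyz)) {
      pos <- w$xyz
    } else {
      a <- atom_xyz(all_so_far, w$between$a$chain, w$between$a$resno,
                    w$between$a$elety)
      b <- atom_xyz(all_so_far, w$between$b$chain, w$between$b$resno,
                    w$between$b$elety)
      L <- vnorm(b - a)
      if (L >= w$d_a + w$d_b) {
        abort(sprintf("unsatisfiable water placement: anchors %.2f A apart, distances %.2f + %.2f",
                      L, w$d_a, w$d_b))
      }
      along <- (w$d_a^2 - w$d_b^2 + L^2) / (2 * L)
      h <- sqrt(max(w$d_a^2 - along^2, 0))
      abu <- unitv(b - a)
      radial <- c((a + b) / 2)[1:2]
      perp0 <- c(radial, 0)
      perp <- perp0 - sum(perp0 * abu) * abu
      if (vnorm(perp) < 1e-6) perp <- pracma_cross(abu, c(0, 0, 1))
      pos <- a + along * abu + h * unitv(perp)
    }
    wat[[length(wat) + 1L]] <- tibble::tibble(
      chain = "W", resid = "HOH", resno = wno, elety = "O",
      x = pos[1], y = pos[2], z = pos[3]
    )
  }
  atoms <- dplyr::bind_rows(
    tibble::as_tibble(s)[, c("chain", "resid", "resno", "elety", "x", "y", "z")],
    dplyr::bind_rows(frags), dplyr::bind_rows(wat)
  )
  out <- new_structure(atoms, id = "planted_complex",
                       meta = list(generator = "build_planted_complex",
                                   sequence = sequence))
  .check_geometry_conflicts(out, min_sep)
  out
}

.check_geometry_conflicts <- function(structure, min_sep) {
  at <- tibble::as_tibble(structure)
  xyz <- coords(structure)
  cp <- close_pairs(xyz, xyz, min_sep)
  cp <- cp[cp$i < cp$j, ]
  if (nrow(cp) == 0) return(invisible(TRUE))
  same_res <- at$chain[cp$i] == at$chain[cp$j] & at$resno[cp$i] == at$resno[cp$j]
  # sequence neighbours share covalent backbone bonds only on the DNA chains;
  # planted protein fragments are independent residues
  adj <- at$chain[cp$i] == at$chain[cp$j] &
    abs(at$resno[cp$i] - at$resno[cp$j]) == 1L &
    at$kind[cp$i] == "dna" & at$kind[cp$j] == "dna"
  bad <- cp[!(same_res | adj), ]
  if (nrow(bad) > 0) {
    k <- which.min(bad$dist)
    abort(sprintf("geometry conflict: %s and %s only %.2f A apart",
                  .atom_label(at, bad$i[k]), .atom_label(at, bad$j[k]),
                  bad$dist[k]))
  }
  invisible(TRUE)
}

#' Perturb atomic coordinates with Gaussian noise
#'
#' Adds i.i.d. Gaussian displacement (per coordinate, SD `noise_sd`) to every
#' atom; seed-reproducible.
#'
#' @param structure an `ets_structure`.
#' @param noise_sd displacement SD per coordinate (Angstrom, >= 0).
#' @param seed integer seed.
#' @return perturbed structure.
#' @export
perturb_structure <- function(structure, noise_sd, seed = 1L) {
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (noise_sd == 0) return(structure)
  xyz <- coords(structure)
  set.seed(seed)
  xyz <- xyz + matrix(rnorm(length(xyz), sd = noise_sd), ncol = 3)
  set_coords(structure, xyz)
}
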