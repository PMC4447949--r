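# In-silico base and side-chain modifications with steric clash scanning:
# 5-methylcytosine (methyl on C5, in-plane) and phosphoserine (PO3 on OG,
# scannable torsion). The model is rigid -- no relaxation after modification
# -- mirroring static clash assessment; reports state this limitation.

#' Add a 5-methyl group to a cytosine
#'
#' Places the methyl carbon (C7) in the base plane at 1.50 A from C5 on the
#' external bisector of the C4-C5-C6 ring angle, renames the residue to 5CM,
#' and flags the new atom as modified. All other atoms are untouched.
#'
#' @param structure an `ets_structure`.
#' @param chain,resno the target cytosine.
#' @return modified structure; the added atom carries `modified = TRUE`.
#' @export
add_5_methyl <- function(structure, chain, resno) {
  at <- tibble::as_tibble(structure)
  sel <- at$chain == chain & at$resno == resno
  if (!any(sel)) abort(sprintf("residue %s/%d not found", chain, resno))
  if (base_letter(at$resid[sel][1]) != "C") {
    abort(sprintf("residue %s/%d is %s, not a cytosine", chain, resno,
                  at$resid[sel][1]))
  }
  g <- function(el) {
    r <- at[sel & at$elety == el, ]
    if (nrow(r) == 0) abort(paste0("missing ring atom ", el))
    c(r$x[1], r$y[1], r$z[1])
  }
  c5 <- g("C5"); c4 <- g("C4"); c6 <- g("C6")
  dir <- -(unitv(c4 - c5) + unitv(c6 - c5))
  c7 <- c5 + 1.50 * unitv(dir)
  if (!("modified" %in% names(at))) at$modified <- FALSE
  at$resid[sel] <- "5CM"
  new_row <- at[sel, ][1, ]
  new_row$elety <- "C7"
  new_row$element <- "C"
  new_row$x <- c7[1]; new_row$y <- c7[2]; new_row$z <- c7[3]
  new_row$modified <- TRUE
  out <- dplyr::bind_rows(at, new_row)
  new_structure(out, id = attr(structure, "id"), meta = attr(structure, "meta"))
}

#' Phosphorylate a serine
#'
#' Builds a PO3 group on OG with P-OG 1.61 A, three P=O at 1.48 A in
#' tetrahedral geometry, renames the residue to SEP. The CB-OG-P orientation
#' uses the tetrahedral angle; `torsion` (degrees, about the CB-OG bond,
#' relative to the CA-CB direction) selects the rotamer and defaults to the
#' staggered 180.
#'
#' @param structure an `ets_structure`.
#' @param chain,resno the target serine.
#' @param torsion CA-CB-OG-P dihedral in degrees.
#' @return modified structure; added atoms carry `modified = TRUE`.
#' @export
add_phosphoserine <- function(structure, chain, resno, torsion = 180) {
  at <- tibble::as_tibble(structure)
  sel <- at$chain == chain & at$resno == resno
  if (!any(sel)) abort(sprintf("residue %s/%d not found", chain, resno))
  if (toupper(at$resid[sel][1]) != "SER") {
    abort(sprintf("residue %s/%d is %s, not a serine", chain, resno,
                  at$resid[sel][1]))
  }
  g <- function(el) {
    r <- at[sel & at$elety == el, ]
    if (nrow(r) == 0) abort(paste0("missing atom ", el))
    c(r$x[1], r$y[1], r$z[1])
  }
  ca <- g("CA"); cb <- g("CB"); og <- g("OG")
  p <- .place_dihedral(ca, cb, og, bond = 1.61, angle = 109.5, dihedral = torsion)
  # three phosphate oxygens tetrahedral about P, staggered around the OG-P axis
  o_list <- lapply(c(60, 180, 300), function(d) {
    .place_dihedral(cb, og, p, bond = 1.48, angle = 109.5, dihedral = d)
  })
  if (!("modified" %in% names(at))) at$modified <- FALSE
  at$resid[sel] <- "SEP"
  mk <- function(el, xyz) {
    r <- at[sel, ][1, ]
    r$elety <- el
    r$element <- substr(el, 1, 1)
    r$x <- xyz[1]; r$y <- xyz[2]; r$z <- xyz[3]
    r$modified <- TRUE
    r
  }
  out <- dplyr::bind_rows(at, mk("P", p), mk("O1P", o_list[[1]]),
                          mk("O2P", o_list[[2]]), mk("O3P", o_list[[3]]))
  new_structure(out, id = attr(structure, "id"), meta = attr(structure, "meta"))
}

# internal-coordinate (Z-matrix style) placement: position X given bonded
# predecessor c (bond length), angle at c w.r.t. b, and dihedral a-b-c-X
.place_dihedral <- function(a, b, c, bond, angle, dihedral) {
  bc <- unitv(c - b)
  n <- unitv(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), bond * sin(ang) * sin(dih))
  c + d[1] * bc + d[2] * m + d[3] * n
}

#' Scan a modified structure for steric clashes
#'
#' All non-bonded pairs between modified atoms and atoms of other residues
#' with positive van der Waals overlap (sum of radii minus distance), sorted
#' by overlap. Overlaps of at least `clash_cut` are classed `"clash"`, the
#' rest `"contact"`.
#'
#' @param structure a structure with `modified`-flagged atoms (from
#'   [add_5_methyl()] / [add_phosphoserine()]).
#' @param clash_cut overlap threshold (Angstrom) separating a hard clash from
#'   a close contact.
#' @param default_radius vdW radius for unknown elements.
#' @return tibble of class `ets_clashes`: both atom refs, distance, overlap,
#'   severity.
#' @export
clash_scan <- function(structure, clash_cut = 0.4, default_radius = 1.70) {
  at <- tibble::as_tibble(structure)
  if (!("modified" %in% names(at)) || !any(at$modified)) {
    return(.empty_clashes())
  }
  mod <- which(at$modified)
  r_all <- vdw_radius(at$element, default = default_radius)
  maxr <- max(r_all)
  cp <- close_pairs(coords(structure)[mod, , drop = FALSE],
                    coords(structure), 2 * maxr)
  im <- mod[cp$i]
  keep <- !(at$chain[im] == at$chain[cp$j] & at$resno[im] == at$resno[cp$j])
  cp <- cp[keep, ]
  im <- im[keep]
  overlap <- r_all[im] + r_all[cp$j] - cp$dist
  pos <- overlap > 0
  if (!any(pos)) return(.empty_clashes())
  ov <- overlap[pos]
  res <- tibble::tibble(
    chain1 = at$chain[im[pos]], resid1 = at$resid[im[pos]],
    resno1 = at$resno[im[pos]], atom1 = at$elety[im[pos]],
    chain2 = at$chain[cp$j[pos]], resid2 = at$resid[cp$j[pos]],
    resno2 = at$resno[cp$j[pos]], atom2 = at$elety[cp$j[pos]],
    distance = cp$dist[pos], overlap = ov,
    severity = ifelse(ov >= clash_cut, "clash", "contact")
  ) |>
    dplyr::arrange(dplyr::desc(.data$overlap))
  class(res) <- c("ets_clashes", class(res))
  res
}

.empty_clashes <- function() {
  res <- tibble::tibble(chain1 = character(), resid1 = character(),
                        resno1 = integer(), atom1 = character(),
                        chain2 = character(), resid2 = character(),
                        resno2 = integer(), atom2 = character(),
                        distance = numeric(), overlap = numeric(),
                        severity = character())
  class(res) <- c("ets_clashes", class(res))
  res
}

#' Phosphoserine rotamer scan against nearby atoms
#'
#' Rebuilds the phosphoserine at each torsion in `torsions` and reports the
#' minimum distance from any phosphate oxygen/phosphorus to any DNA atom,
#' plus the worst vdW overlap -- the repulsive-proximity profile of the
#' modification.
#'
#' @param structure structure containing the target serine (unmodified).
#' @param chain,resno the serine.
#' @param torsions vector of CA-CB-OG-P dihedrals (degrees).
#' @return tibble: torsion, min_dist_to_dna, worst_overlap.
#' @export
phosphoserine_scan <- function(structure, chain, resno,
                               torsions = seq(0, 330, by = 30)) {
  purrr::map_dfr(torsions, function(tor) {
    m <- add_phosphoserine(structure, chain, resno, torsion = tor)
    at <- tibble::as_tibble(m)
    mod <- at[at$modified %in% TRUE, ]
    dna <- at[at$kind == "dna", ]
    md <- if (nrow(dna) > 0) {
      min(cross_dist(as.matrix(mod[, c("x", "y", "z")]),
                     as.matrix(dna[, c("x", "y", "z")])))
    } else NA_real_
    cl <- clash_scan(m)
    tibble::tibble(torsion = tor, min_dist_to_dna = md,
                   worst_overlap = if (nrow(cl) > 0) max(cl$overlap) else 0)
  })
}
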