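# Shrake-Rupley solvent-accessible surface area with a deterministic
# Fibonacci-sphere point set, and buried interface area between two parts.

# Fibonacci sphere: n approximately evenly distributed unit vectors
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the structure: for each atom, test points on an
#' inflated sphere of radius vdW + probe are counted accessible when outside
#' every neighbouring inflated sphere. Deterministic for a fixed `n_points`
#' (Fibonacci point generation). Waters (and optionally other parts) are
#' excluded by default.
#'
#' @param structure an `ets_structure`.
#' @param probe probe radius (Angstrom; water = 1.4).
#' @param n_points test points per atom.
#' @param include_water include crystallographic waters.
#' @param default_radius vdW radius for elements missing from the table.
#' @return list of class `ets_sasa`: `atoms` (per-atom tibble with `area`),
#'   `by_residue`, `total` (Angstrom^2), `probe`, `n_points`.
#' @export
sasa <- function(structure, probe = 1.4, n_points = 960L,
                 include_water = FALSE, default_radius = 1.70) {
  at <- tibble::as_tibble(structure)
  if (!include_water) at <- at[at$kind != "water", ]
  if (nrow(at) == 0) abort("no atoms to compute SASA on")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  r <- vdw_radius(at$element, default = default_radius) + probe
  n <- nrow(at)
  sph <- .fibonacci_sphere(n_points)
  # neighbour lists within max reach
  maxr <- max(r)
  nb <- close_pairs(xyz, xyz, 2 * maxr)
  nb <- nb[nb$i != nb$j, ]
  nb <- nb[nb$dist < r[nb$i] + r[nb$j], ]
  nb_split <- split(nb$j, factor(nb$i, levels = seq_len(n)))
  area <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(sph * r[i], 2, xyz[i, ], "+")
    js <- nb_split[[i]]
    acc <- rep(TRUE, n_points)
    eps <- 1e-8
    for (j in js) {
      if (!any(acc)) break
      d2 <- (pts[acc, 1] - xyz[j, 1])^2 + (pts[acc, 2] - xyz[j, 2])^2 +
        (pts[acc, 3] - xyz[j, 3])^2
      # points exactly on a neighbour's surface (coincident spheres) are
      # kept by exactly one atom: deterministic index tie-break
      inside <- d2 < r[j]^2 - eps
      tie <- !inside & d2 <= r[j]^2 + eps & j < i
      acc[acc] <- !(inside | tie)
    }
    area[i] <- 4 * pi * r[i]^2 * sum(acc) / n_points
  }
  at$area <- area
  by_res <- at |>
    dplyr::group_by(.data$chain, .data$resno, .data$resid, .data$kind) |>
    dplyr::summarise(area = sum(.data$area), .groups = "drop")
  out <- list(atoms = at, by_residue = by_res, total = sum(area),
              probe = probe, n_points = n_points)
  class(out) <- "ets_sasa"
  out
}

#' @export
print.ets_sasa <- function(x, ...) {
  cat(sprintf("<SASA>  total %.1f A^2 over %d atoms (probe %.2f A, %d points)\n",
              x$total, nrow(x$atoms), x$probe, x$n_points))
  invisible(x)
}

#' Buried interface area between two parts of a structure
#'
#' Contact area reported in the half-dSASA convention:
#' `buried = (SASA(A) + SASA(B) - SASA(A+B)) / 2` (one face). Per-side burial
#' is the unhalved dSASA of that side; `percent_of_monomer` relates it to the
#' separated side's SASA. Interface residues lose more than `min_loss` A^2.
#'
#' @param structure an `ets_structure`.
#' @param partA,partB disjoint selections (`ets_structure` subsets or lists of
#'   [str_select()] arguments).
#' @param convention `"half"` (dSASA/2, default) or `"sum"` (total dSASA).
#' @param min_loss threshold (Angstrom^2) for calling an interface residue.
#' @param ... passed to [sasa()].
#' @return list of class `ets_interface`: `buried_area`, per-side tibbles of
#'   `interface_residues`, `percent_of_monomer`, component totals, and the
#'   convention used.
#' @export
interface_area <- function(structure, partA, partB, convention = c("half", "sum"),
                           min_loss = 0.1, ...) {
  convention <- match.arg(convention)
  rowsA <- .part_rows(structure, partA)
  rowsB <- .part_rows(structure, partB)
  if (length(intersect(rowsA, rowsB)) > 0) {
    abort("overlapping selections: partA and partB share atoms")
  }
  at <- tibble::as_tibble(structure)
  sA <- new_structure(at[rowsA, ], id = "partA", allow_empty = FALSE)
  sB <- new_structure(at[rowsB, ], id = "partB", allow_empty = FALSE)
  sAB <- new_structure(at[c(rowsA, rowsB), ], id = "partAB")
  resA <- sasa(sA, ...)
  resB <- sasa(sB, ...)
  resAB <- sasa(sAB, ...)

  dsasa <- resA$total + resB$total - resAB$total
  buried <- if (convention == "half") dsasa / 2 else dsasa

  per_res_delta <- function(alone, joint_by_res) {
    dplyr::left_join(alone$by_residue, joint_by_res,
                     by = c("chain", "resno", "resid", "kind"),
                     suffix = c("_alone", "_joint")) |>
      dplyr::mutate(loss = .data$area_alone -
                      dplyr::coalesce(.data$area_joint, 0)) |>
      dplyr::filter(.data$loss > min_loss) |>
      dplyr::select("chain", "resno", "resid", "loss")
  }
  ifaceA <- per_res_delta(resA, resAB$by_residue)
  ifaceB <- per_res_delta(resB, resAB$by_residue)

  # per-side unhalved burial
  joint_atoms <- resAB$atoms
  keyJ <- paste(joint_atoms$chain, joint_atoms$resno, joint_atoms$elety)
  side_total <- function(alone) {
    k <- paste(alone$atoms$chain, alone$atoms$resno, alone$atoms$elety)
    sum(joint_atoms$area[match(k, keyJ)], na.rm = TRUE)
  }
  burA <- resA$total - side_total(resA)
  burB <- resB$total - side_total(resB)

  out <- list(
    buried_area = buried,
    convention = convention,
    interface_residues = list(A = ifaceA, B = ifaceB),
    percent_of_monomer = c(A = 100 * burA / resA$total,
                           B = 100 * burB / resB$total),
    sasa_A = resA$total, sasa_B = resB$total, sasa_AB = resAB$total,
    buried_per_side = c(A = burA, B = burB)
  )
  class(out) <- "ets_interface"
  out
}

#' @export
print.ets_interface <- function(x, ...) {
  cat(sprintf("<interface>  buried %.1f A^2 (%s convention); %d + %d interface residues; %% of monomer: %.1f / %.1f\n",
              x$buried_area, x$convention,
              nrow(x$interface_residues$A), nrow(x$interface_residues$B),
              x$percent_of_monomer["A"], x$percent_of_monomer["B"]))
  invisible(x)
}

#' @method glance ets_interface
#' @export
glance.ets_interface <- function(x, ...) {
  tibble::tibble(buried_area = x$buried_area, convention = x$convention,
                 n_iface_A = nrow(x$interface_residues$A),
                 n_iface_B = nrow(x$interface_residues$B),
                 pct_monomer_A = unname(x$percent_of_monomer["A"]),
                 pct_monomer_B = unname(x$percent_of_monomer["B"]),
                 sasa_A = x$sasa_A, sasa_B = x$sasa_B, sasa_AB = x$sasa_AB)
}
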