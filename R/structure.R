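# The coordinate data model: a structure is an atom table (tibble) with one
# row per atom plus `id`/`meta` attributes. Author residue numbering is kept
# throughout, matching the numbering used for every residue cited in reports.

.structure_cols <- c("chain", "resid", "resno", "kind", "elety", "element",
                     "altloc", "x", "y", "z", "o", "b")

#' Construct a structure from an atom table
#'
#' A structure is a tibble with one row per atom and columns `chain`, `resid`
#' (residue name), `resno` (author residue number), `kind` (protein / dna /
#' water / other), `elety` (atom name), `element`, `altloc`, `x`, `y`, `z`
#' (Angstrom), `o` (occupancy) and `b` (isotropic B-factor, Angstrom^2).
#'
#' @param atoms data frame with at least `chain`, `resid`, `resno`, `elety`,
#'   `x`, `y`, `z`. Missing `element` is inferred from the atom name; missing
#'   `o`/`b`/`altloc` default to 1 / 0 / "".
#' @param id label for the structure (accession or free text).
#' @param meta named list of provenance fields.
#' @param allow_empty keep a zero-atom table (used by selections).
#' @return an `ets_structure` tibble.
#' @export
new_structure <- function(atoms, id = "structure", meta = list(),
                          allow_empty = FALSE) {
  atoms <- tibble::as_tibble(atoms)
  need <- c("chain", "resid", "resno", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    abort(paste0("atom table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(atoms) == 0 && !allow_empty) {
    abort("empty structure: no atoms")
  }
  if (!("element" %in% names(atoms)) || all(is.na(atoms$element))) {
    atoms$element <- guess_element(atoms$elety)
  } else if (anyNA(atoms$element) || any(!nzchar(trimws(atoms$element)))) {
    i <- is.na(atoms$element) | !nzchar(trimws(atoms$element))
    atoms$element[i] <- guess_element(atoms$elety[i])
  }
  if (!("o" %in% names(atoms))) atoms$o <- 1
  if (!("b" %in% names(atoms))) atoms$b <- 0
  if (!("altloc" %in% names(atoms))) atoms$altloc <- ""
  atoms$altloc[is.na(atoms$altloc)] <- ""
  atoms$o[is.na(atoms$o)] <- 1
  atoms$b[is.na(atoms$b)] <- 0
  atoms$kind <- residue_kind(atoms$resid)
  atoms$resno <- as.integer(atoms$resno)

  if (nrow(atoms) > 0) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    if (!all(is.finite(xyz))) abort("non-finite coordinates in atom table")
    if (any(atoms$o < 0 | atoms$o > 1)) abort("occupancy outside [0, 1]")
  }
  atoms <- atoms[, c(.structure_cols, setdiff(names(atoms), .structure_cols))]
  structure(atoms,
            class = c("ets_structure", class(tibble::tibble()))) -> out
  attr(out, "id") <- id
  attr(out, "meta") <- meta
  out
}

#' @export
print.ets_structure <- function(x, ...) {
  ch <- unique(x$chain)
  cat(sprintf("<ets_structure '%s'>  %d atoms, %d chains (%s)\n",
              attr(x, "id") %||% "?", nrow(x), length(ch),
              paste(ch, collapse = ", ")))
  NextMethod()
}

#' Test for the structure class
#' @param x object.
#' @return logical scalar.
#' @export
is_structure <- function(x) inherits(x, "ets_structure")

#' Coordinate matrix of a structure
#' @param structure an `ets_structure` (or any atom table with x/y/z).
#' @return n x 3 numeric matrix in Angstrom.
#' @export
coords <- function(structure) {
  as.matrix(tibble::as_tibble(structure)[, c("x", "y", "z")])
}

# Replace coordinates, preserving attributes.
set_coords <- function(structure, xyz) {
  structure$x <- xyz[, 1]
  structure$y <- xyz[, 2]
  structure$z <- xyz[, 3]
  structure
}

#' Residue table of a structure
#'
#' One row per residue (chain + author number + name), with atom counts.
#'
#' @param structure an `ets_structure`.
#' @return tibble with columns chain, resno, resid, kind, n_atoms.
#' @export
residues <- function(structure) {
  tibble::as_tibble(structure) |>
    dplyr::group_by(.data$chain, .data$resno, .data$resid, .data$kind) |>
    dplyr::summarise(n_atoms = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$chain, .data$resno)
}

#' Rigid-body transform of a structure
#'
#' @param structure an `ets_structure`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation vector (Angstrom).
#' @return transformed structure (input is not modified).
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  xyz <- coords(structure) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  set_coords(structure, xyz)
}

#' Merge several structures into one
#'
#' Chains are kept as-is; duplicated chain identifiers across inputs are
#' relabelled to keep chain ids unique.
#'
#' @param ... `ets_structure` objects.
#' @param id label of the merged structure.
#' @return an `ets_structure`.
#' @export
merge_structures <- function(..., id = "merged") {
  parts <- list(...)
  seen <- character()
  pool <- c(LETTERS, letters, as.character(0:9))
  out <- purrr::map(parts, function(s) {
    s <- tibble::as_tibble(s)
    for (ch in unique(s$chain)) {
      if (ch %in% seen) {
        newch <- setdiff(pool, c(seen, unique(s$chain)))[1]
        s$chain[s$chain == ch] <- newch
        seen <<- c(seen, newch)
      } else {
        seen <<- c(seen, ch)
      }
    }
    s
  })
  new_structure(dplyr::bind_rows(out), id = id)
}
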