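# Contact detection and classification at a protein-DNA (or any two-part)
# interface. Heavy-atom criteria throughout: hydrogen-bond = donor-acceptor
# distance cutoff plus an antecedent-angle proxy; salt bridge = charged-group
# nitrogen-oxygen distance; van der Waals = any-atom distance. The three
# classes are mutually exclusive per atom pair (salt bridge wins, then
# hydrogen bond).

.default_cutoffs <- list(hbond = 3.5, salt_bridge = 4.0, vdw = 3.9,
                         min_angle = 90)

# rows of `structure` selected by a part: either an ets_structure (subset of
# the same atoms), or a named list of str_select() arguments
.part_rows <- function(structure, part) {
  at <- tibble::as_tibble(structure)
  if (is_structure(part)) {
    key <- paste(at$chain, at$resno, at$elety, at$altloc)
    pk <- paste(part$chain, part$resno, part$elety, part$altloc)
    which(key %in% pk)
  } else if (is.list(part)) {
    sel <- suppressWarnings(do.call(str_select, c(list(structure), part)))
    .part_rows(structure, sel)
  } else {
    abort("part must be an ets_structure or a list of str_select arguments")
  }
}

.atom_label <- function(at, rows) {
  sprintf("%s/%s%d/%s", at$chain[rows], at$resid[rows], at$resno[rows],
          at$elety[rows])
}

# antecedent coordinates for polar atoms (same residue, named atom)
.antecedent_xyz <- function(at, polar) {
  key <- paste(at$chain, at$resno, at$elety)
  ak <- paste(polar$chain, polar$resno, polar$antecedent)
  idx <- match(ak, key)
  cbind(at$x[idx], at$y[idx], at$z[idx])
}

#' Detect hydrogen bonds between two parts of a structure
#'
#' Heavy-atom criterion: donor and acceptor chemistry from the internal
#' per-residue atom dictionary; donor-acceptor distance <= `max_da`; where the
#' donor has a covalent antecedent, the antecedent-donor-acceptor angle must
#' be >= `min_angle` (proxy for a plausible hydrogen position). Atom pairs
#' that qualify as salt bridges are excluded here (exclusive classification).
#'
#' @param structure an `ets_structure`.
#' @param partA,partB the two sides: `ets_structure` subsets or lists of
#'   [str_select()] arguments, e.g. `list(kind = "protein")`.
#' @param max_da donor-acceptor distance cutoff (Angstrom).
#' @param min_angle antecedent-donor-acceptor angle cutoff (degrees).
#' @return tibble of class `ets_contacts`: kind, chain/resid/resno/atom for
#'   both partners (donor first where defined), distance, angle (NA if no
#'   antecedent).
#' @export
find_hbonds <- function(structure, partA = list(kind = "protein"),
                        partB = list(kind = "dna"),
                        max_da = .default_cutoffs$hbond,
                        min_angle = .default_cutoffs$min_angle) {
  at <- tibble::as_tibble(structure)
  rowsA <- .part_rows(structure, partA)
  rowsB <- .part_rows(structure, partB)
  if (length(rowsA) == 0 || length(rowsB) == 0) {
    warn("empty selection: no atoms on one side")
    return(.empty_contacts())
  }
  pol <- polar_atoms(structure)
  polA <- pol[pol$.row %in% rowsA, ]
  polB <- pol[pol$.row %in% rowsB, ]
  if (nrow(polA) == 0 || nrow(polB) == 0) return(.empty_contacts())

  cp <- close_pairs(as.matrix(polA[, c("x", "y", "z")]),
                    as.matrix(polB[, c("x", "y", "z")]), max_da)
  if (nrow(cp) == 0) return(.empty_contacts())

  antA <- .antecedent_xyz(at, polA)
  antB <- .antecedent_xyz(at, polB)
  sb_rows <- .salt_bridge_rows(structure)

  out <- list()
  for (k in seq_len(nrow(cp))) {
    ia <- cp$i[k]; ib <- cp$j[k]
    ra <- polA$.row[ia]; rb <- polB$.row[ib]
    if (ra == rb) next
    # same residue: skip intra-residue polar pairs
    if (polA$chain[ia] == polB$chain[ib] && polA$resno[ia] == polB$resno[ib]) next
    # exclusive classification: salt-bridge-capable pairs are not H-bonds
    if ((ra %in% sb_rows$pos && rb %in% sb_rows$neg) ||
        (rb %in% sb_rows$pos && ra %in% sb_rows$neg)) next
    dirs <- list()
    if (polA$role[ia] %in% c("donor", "both") &&
        polB$role[ib] %in% c("acceptor", "both")) {
      dirs[[length(dirs) + 1L]] <- list(d = ia, a = ib, dside = "A")
    }
    if (polB$role[ib] %in% c("donor", "both") &&
        polA$role[ia] %in% c("acceptor", "both")) {
      dirs[[length(dirs) + 1L]] <- list(d = ib, a = ia, dside = "B")
    }
    ok <- FALSE; ang_keep <- NA_real_
    for (dd in dirs) {
      if (dd$dside == "A") {
        dpos <- c(polA$x[dd$d], polA$y[dd$d], polA$z[dd$d])
        apos <- c(polB$x[dd$a], polB$y[dd$a], polB$z[dd$a])
        antec <- antA[dd$d, ]
      } else {
        dpos <- c(polB$x[dd$d], polB$y[dd$d], polB$z[dd$d])
        apos <- c(polA$x[dd$a], polA$y[dd$a], polA$z[dd$a])
        antec <- antB[dd$d, ]
      }
      ang <- if (all(is.finite(antec))) vangle(antec, dpos, apos) else NA_real_
      if (is.na(ang) || ang >= min_angle) {
        ok <- TRUE
        ang_keep <- ang
        break
      }
    }
    if (!ok) next
    out[[length(out) + 1L]] <- tibble::tibble(
      kind = "hbond",
      chain1 = polA$chain[ia], resid1 = polA$resid[ia],
      resno1 = polA$resno[ia], atom1 = polA$elety[ia],
      chain2 = polB$chain[ib], resid2 = polB$resid[ib],
      resno2 = polB$resno[ib], atom2 = polB$elety[ib],
      distance = cp$dist[k], angle = ang_keep
    )
  }
  if (length(out) == 0) return(.empty_contacts())
  res <- dplyr::bind_rows(out) |>
    dplyr::distinct(.data$chain1, .data$resno1, .data$atom1,
                    .data$chain2, .data$resno2, .data$atom2,
                    .keep_all = TRUE) |>
    dplyr::arrange(.data$distance)
  class(res) <- c("ets_contacts", class(res))
  res
}

.salt_bridge_rows <- function(structure) {
  ch <- charged_atoms(structure)
  list(pos = ch$.row[ch$charge == "pos"], neg = ch$.row[ch$charge == "neg"])
}

#' Detect salt bridges between two parts of a structure
#'
#' Charged-group dictionary: Lys NZ and Arg NE/NH1/NH2 (positive) against
#' Asp/Glu carboxylate oxygens and DNA phosphate OP1/OP2 (negative), at an
#' N-O distance <= `max_no`. One contact per residue pair, at the minimum
#' N-O distance.
#'
#' @inheritParams find_hbonds
#' @param max_no nitrogen-oxygen distance cutoff (Angstrom).
#' @return tibble of class `ets_contacts` (kind = `"salt_bridge"`).
#' @export
find_salt_bridges <- function(structure, partA = list(kind = "protein"),
                              partB = list(kind = "dna"),
                              max_no = .default_cutoffs$salt_bridge) {
  rowsA <- .part_rows(structure, partA)
  rowsB <- .part_rows(structure, partB)
  if (length(rowsA) == 0 || length(rowsB) == 0) {
    warn("empty selection: no atoms on one side")
    return(.empty_contacts())
  }
  ch <- charged_atoms(structure)
  chA <- ch[ch$.row %in% rowsA, ]
  chB <- ch[ch$.row %in% rowsB, ]
  if (nrow(chA) == 0 || nrow(chB) == 0) return(.empty_contacts())
  cp <- close_pairs(as.matrix(chA[, c("x", "y", "z")]),
                    as.matrix(chB[, c("x", "y", "z")]), max_no)
  if (nrow(cp) == 0) return(.empty_contacts())
  opp <- chA$charge[cp$i] != chB$charge[cp$j]
  cp <- cp[opp, ]
  if (nrow(cp) == 0) return(.empty_contacts())
  res <- tibble::tibble(
    kind = "salt_bridge",
    chain1 = chA$chain[cp$i], resid1 = chA$resid[cp$i],
    resno1 = chA$resno[cp$i], atom1 = chA$elety[cp$i],
    chain2 = chB$chain[cp$j], resid2 = chB$resid[cp$j],
    resno2 = chB$resno[cp$j], atom2 = chB$elety[cp$j],
    distance = cp$dist, angle = NA_real_
  ) |>
    dplyr::group_by(.data$chain1, .data$resno1, .data$chain2, .data$resno2) |>
    dplyr::slice_min(.data$distance, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$distance)
  class(res) <- c("ets_contacts", class(res))
  res
}

#' Detect any-atom van der Waals contacts between two parts
#'
#' @inheritParams find_hbonds
#' @param max_dist any-atom distance cutoff (Angstrom).
#' @param exclude_polar drop pairs already classified as hydrogen bonds or
#'   salt bridges (keeps the three classes mutually exclusive).
#' @return tibble of class `ets_contacts` (kind = `"vdw"`).
#' @export
find_vdw_contacts <- function(structure, partA = list(kind = "protein"),
                              partB = list(kind = "dna"),
                              max_dist = .default_cutoffs$vdw,
                              exclude_polar = TRUE) {
  at <- tibble::as_tibble(structure)
  rowsA <- .part_rows(structure, partA)
  rowsB <- .part_rows(structure, partB)
  if (length(rowsA) == 0 || length(rowsB) == 0) {
    warn("empty selection: no atoms on one side")
    return(.empty_contacts())
  }
  cp <- close_pairs(coords(structure)[rowsA, , drop = FALSE],
                    coords(structure)[rowsB, , drop = FALSE], max_dist)
  if (nrow(cp) == 0) return(.empty_contacts())
  ra <- rowsA[cp$i]; rb <- rowsB[cp$j]
  keep <- ra != rb & !(at$chain[ra] == at$chain[rb] & at$resno[ra] == at$resno[rb])
  cp <- cp[keep, ]; ra <- ra[keep]; rb <- rb[keep]
  res <- tibble::tibble(
    kind = "vdw",
    chain1 = at$chain[ra], resid1 = at$resid[ra], resno1 = at$resno[ra],
    atom1 = at$elety[ra],
    chain2 = at$chain[rb], resid2 = at$resid[rb], resno2 = at$resno[rb],
    atom2 = at$elety[rb],
    distance = cp$dist, angle = NA_real_
  )
  if (exclude_polar) {
    hb <- find_hbonds(structure, partA, partB)
    sb <- find_salt_bridges(structure, partA, partB)
    taken <- c(paste(hb$chain1, hb$resno1, hb$atom1, hb$chain2, hb$resno2, hb$atom2),
               paste(sb$chain1, sb$resno1, sb$atom1, sb$chain2, sb$resno2, sb$atom2))
    key <- paste(res$chain1, res$resno1, res$atom1, res$chain2, res$resno2,
                 res$atom2)
    res <- res[!key %in% taken, ]
  }
  res <- dplyr::arrange(res, .data$distance)
  class(res) <- c("ets_contacts", class(res))
  res
}

.empty_contacts <- function() {
  res <- tibble::tibble(kind = character(), chain1 = character(),
                        resid1 = character(), resno1 = integer(),
                        atom1 = character(), chain2 = character(),
                        resid2 = character(), resno2 = integer(),
                        atom2 = character(), distance = numeric(),
                        angle = numeric())
  class(res) <- c("ets_contacts", class(res))
  res
}

#' Classify the DNA moiety and binding-site position of contacts
#'
#' Adds `dna_part` (phosphate_backbone / sugar / base_major / base_minor /
#' none) from the atom-name dictionary and `ebs_position` from the base-pair
#' registration (NA when the contacted nucleotide is unpaired or no GGA core
#' was located).
#'
#' @param contacts an `ets_contacts` tibble (partner 2 is the DNA side where
#'   applicable; both sides are checked).
#' @param pairs result of [find_base_pairs()].
#' @return the contacts tibble with `dna_part` and `ebs_position` columns.
#' @export
classify_dna_contact <- function(contacts, pairs = NULL) {
  if (nrow(contacts) == 0) {
    contacts$dna_part <- character()
    contacts$ebs_position <- integer()
    return(contacts)
  }
  side2_dna <- residue_kind(contacts$resid2) == "dna"
  side1_dna <- residue_kind(contacts$resid1) == "dna"
  dna_side <- ifelse(side2_dna, 2L, ifelse(side1_dna, 1L, NA_integer_))
  elety <- ifelse(dna_side == 2L, contacts$atom2, contacts$atom1)
  resid <- ifelse(dna_side == 2L, contacts$resid2, contacts$resid1)
  contacts$dna_part <- ifelse(is.na(dna_side), "none",
                              dna_part_of(elety, base_letter(resid)))
  contacts$ebs_position <- NA_integer_
  if (!is.null(pairs) && nrow(pairs) > 0) {
    keys_i <- paste(pairs$chain_i, pairs$resno_i)
    keys_j <- paste(pairs$chain_j, pairs$resno_j)
    ck <- ifelse(dna_side == 2L, paste(contacts$chain2, contacts$resno2),
                 paste(contacts$chain1, contacts$resno1))
    pos <- pairs$ebs_position[match(ck, keys_i)]
    pos2 <- pairs$ebs_position[match(ck, keys_j)]
    contacts$ebs_position <- ifelse(!is.na(pos), pos, pos2)
  }
  contacts
}

#' Per-residue protein-DNA contact map
#'
#' Runs hydrogen-bond, salt-bridge and van der Waals detection between the
#' two parts, classifies the DNA side of each contact, and summarises per
#' protein residue.
#'
#' @inheritParams find_hbonds
#' @param pairs optional [find_base_pairs()] result for EBS labelling.
#' @param cutoffs named list overriding the default cutoffs.
#' @return list of class `ets_contact_map`: `contacts` (all classified
#'   contacts), `by_residue` (per-residue counts by kind), `summary` (counts
#'   by kind and dna_part).
#' @export
contact_map <- function(structure, partA = list(kind = "protein"),
                        partB = list(kind = "dna"), pairs = NULL,
                        cutoffs = .default_cutoffs) {
  hb <- find_hbonds(structure, partA, partB, max_da = cutoffs$hbond)
  sb <- find_salt_bridges(structure, partA, partB, max_no = cutoffs$salt_bridge)
  vw <- find_vdw_contacts(structure, partA, partB, max_dist = cutoffs$vdw)
  all <- dplyr::bind_rows(hb, sb, vw)
  all <- classify_dna_contact(all, pairs)
  by_res <- all |>
    dplyr::count(.data$chain1, .data$resid1, .data$resno1, .data$kind) |>
    tidyr::pivot_wider(names_from = "kind", values_from = "n", values_fill = 0L)
  summ <- dplyr::count(all, .data$kind, .data$dna_part)
  out <- list(contacts = all, by_residue = by_res, summary = summ,
              cutoffs = cutoffs)
  class(out) <- "ets_contact_map"
  out
}

#' @export
print.ets_contact_map <- function(x, ...) {
  cat(sprintf("<contact map>  %d contacts (%d hbond, %d salt_bridge, %d vdw) over %d residues\n",
              nrow(x$contacts), sum(x$contacts$kind == "hbond"),
              sum(x$contacts$kind == "salt_bridge"),
              sum(x$contacts$kind == "vdw"), nrow(x$by_residue)))
  invisible(x)
}

#' Base-pair span contacted by the protein
#'
#' The inclusive index distance between the first and last contacted base
#' pair, using any-atom contacts at the given cutoff.
#'
#' @param structure an `ets_structure`.
#' @param pairs result of [find_base_pairs()].
#' @param partA protein side selection (default all protein atoms).
#' @param max_dist any-atom contact cutoff (Angstrom).
#' @return integer span in base pairs (0 when there are no contacts).
#' @export
contacted_bp_span <- function(structure, pairs,
                              partA = list(kind = "protein"),
                              max_dist = .default_cutoffs$vdw) {
  vw <- find_vdw_contacts(structure, partA, list(kind = "dna"),
                          max_dist = max_dist, exclude_polar = FALSE)
  if (nrow(vw) == 0) return(0L)
  keys_i <- paste(pairs$chain_i, pairs$resno_i)
  keys_j <- paste(pairs$chain_j, pairs$resno_j)
  ck <- paste(vw$chain2, vw$resno2)
  idx <- c(pairs$pair_index[match(ck, keys_i)],
           pairs$pair_index[match(ck, keys_j)])
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) return(0L)
  as.integer(max(idx) - min(idx) + 1L)
}
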