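# Interfacial bridging waters, their conservation across superposed
# complexes, and exhaustive enumeration of hydrogen donor/acceptor
# assignments over the local network under fixed chemistry (normal
# protonation states): each candidate hydrogen bond is an edge that must be
# directed donor -> acceptor without exceeding any site's donation/acceptance
# capacity.

#' Find bridging waters at a protein-DNA interface
#'
#' A bridging water has at least one protein polar partner and at least one
#' DNA polar partner within `cutoff`. Water-water links are reported (for
#' network building) but do not count toward the bridge criterion. Waters
#' with occupancy below `min_occ` are ignored.
#'
#' @param structure an `ets_structure` containing waters.
#' @param cutoff polar-contact distance cutoff (Angstrom).
#' @param min_occ minimum water occupancy.
#' @return tibble of class `ets_water_bridges`: one row per bridging water
#'   (chain, resno) with list-columns `protein_partners`, `dna_partners`,
#'   `water_partners` (each a tibble of atom refs + distance).
#' @export
find_bridging_waters <- function(structure, cutoff = 3.5, min_occ = 0.5) {
  at <- tibble::as_tibble(structure)
  wat <- which(at$kind == "water" & at$element == "O" & at$o >= min_occ)
  if (length(wat) == 0) {
    warn(paste0("no waters in structure (bridging-water analysis needs ",
                "ordered waters, i.e. < 2.0 A resolution data)"))
    return(.empty_bridges())
  }
  pol <- polar_atoms(structure)
  pol_nw <- pol[pol$kind != "water", ]
  wxyz <- coords(structure)[wat, , drop = FALSE]
  cp <- close_pairs(wxyz, as.matrix(pol_nw[, c("x", "y", "z")]), cutoff)
  cpw <- close_pairs(wxyz, wxyz, cutoff)
  cpw <- cpw[cpw$i != cpw$j, ]
  out <- list()
  for (k in seq_along(wat)) {
    hits <- cp[cp$i == k, ]
    part <- tibble::tibble(
      chain = pol_nw$chain[hits$j], resid = pol_nw$resid[hits$j],
      resno = pol_nw$resno[hits$j], elety = pol_nw$elety[hits$j],
      kind = pol_nw$kind[hits$j], distance = hits$dist
    )
    wp <- cpw[cpw$i == k, ]
    water_part <- tibble::tibble(
      chain = at$chain[wat[wp$j]], resid = at$resid[wat[wp$j]],
      resno = at$resno[wat[wp$j]], elety = at$elety[wat[wp$j]],
      kind = "water", distance = wp$dist
    )
    pp <- part[part$kind == "protein", ]
    dp <- part[part$kind == "dna", ]
    if (nrow(pp) >= 1 && nrow(dp) >= 1) {
      out[[length(out) + 1L]] <- tibble::tibble(
        chain = at$chain[wat[k]], resno = at$resno[wat[k]],
        protein_partners = list(pp), dna_partners = list(dp),
        water_partners = list(water_part)
      )
    }
  }
  if (length(out) == 0) return(.empty_bridges())
  res <- dplyr::bind_rows(out)
  class(res) <- c("ets_water_bridges", class(res))
  res
}

.empty_bridges <- function() {
  res <- tibble::tibble(chain = character(), resno = integer(),
                        protein_partners = list(), dna_partners = list(),
                        water_partners = list())
  class(res) <- c("ets_water_bridges", class(res))
  res
}

#' Conserved bridging waters across superposed structures
#'
#' Superposes every structure onto the first (alpha-carbon pairing on the
#' shared protein core), pools the bridging waters, and clusters them by
#' greedy mutual-nearest-neighbour matching. A cluster is conserved when it
#' contains a water from every input structure within `match_radius`.
#'
#' @param structures list of >= 2 `ets_structure` objects.
#' @param match_radius maximum pairwise distance within a cluster (Angstrom).
#' @param cutoff bridging-water contact cutoff.
#' @return tibble: cluster id, n_structures, conserved flag, mean position,
#'   and a list-column `members` (structure index, chain, resno, xyz).
#' @export
conserved_waters <- function(structures, match_radius = 1.0, cutoff = 3.5) {
  if (length(structures) < 2) abort("need >= 2 structures")
  aligned <- vector("list", length(structures))
  aligned[[1]] <- structures[[1]]
  for (k in 2:length(structures)) {
    sup <- superpose(structures[[k]], structures[[1]])
    aligned[[k]] <- sup$mobile_transformed
  }
  memb <- list()
  for (k in seq_along(aligned)) {
    br <- suppressWarnings(find_bridging_waters(aligned[[k]], cutoff = cutoff))
    if (nrow(br) == 0) next
    at <- tibble::as_tibble(aligned[[k]])
    xyz <- t(vapply(seq_len(nrow(br)), function(i) {
      r <- at[at$chain == br$chain[i] & at$resno == br$resno[i] &
                at$kind == "water", ]
      c(r$x[1], r$y[1], r$z[1])
    }, numeric(3)))
    memb[[k]] <- tibble::tibble(structure = k, chain = br$chain,
                                resno = br$resno,
                                x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  pool <- dplyr::bind_rows(memb)
  if (nrow(pool) == 0) {
    return(tibble::tibble(cluster = integer(), n_structures = integer(),
                          conserved = logical(), x = numeric(), y = numeric(),
                          z = numeric(), members = list()))
  }
  # greedy clustering: closest unassigned cross-structure pairs first
  pool$cluster <- NA_integer_
  xyz <- as.matrix(pool[, c("x", "y", "z")])
  cl <- 0L
  for (i in order(pool$structure)) {
    if (!is.na(pool$cluster[i])) next
    cl <- cl + 1L
    pool$cluster[i] <- cl
    for (s in setdiff(unique(pool$structure), pool$structure[i])) {
      cand <- which(pool$structure == s & is.na(pool$cluster))
      if (length(cand) == 0) next
      d <- sqrt(rowSums((xyz[cand, , drop = FALSE] -
                           matrix(xyz[i, ], length(cand), 3, byrow = TRUE))^2))
      j <- cand[which.min(d)]
      if (min(d) <= match_radius) pool$cluster[j] <- cl
    }
  }
  ns <- length(structures)
  pool |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n_structures = dplyr::n_distinct(.data$structure),
      conserved = dplyr::n_distinct(.data$structure) == ns,
      x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
      members = list(dplyr::pick(dplyr::everything())),
      .groups = "drop"
    )
}

# --- hydrogen-assignment constraint network ----------------------------------

# chemistry classes and capacities (donations, acceptances) per node type
.node_capacity <- function(class) {
  switch(class,
    water = c(2L, 2L),
    donor_only = c(2L, 0L),
    acceptor_only = c(0L, 2L),
    ambivalent = c(1L, 2L),
    abort(paste0("unknown chemistry class: ", class))
  )
}

# chemistry class of a polar atom (for graph building)
.chem_class <- function(kind, resid, elety) {
  if (kind == "water") return("water")
  base <- base_letter(resid)
  if (kind == "dna") {
    if (elety %in% c("OP1", "OP2", "O1P", "O2P", "O5'", "O3'", "O4'")) {
      return("acceptor_only")
    }
    if ((base == "C" && elety == "N4") || (base == "A" && elety == "N6")) {
      return("donor_only") # exocyclic amino toward exocyclic partners
    }
    if ((base == "G" && elety %in% c("O6", "N7", "N3")) ||
        (base == "A" && elety %in% c("N1", "N3", "N7")) ||
        (base %in% c("C", "T", "U") && elety %in% c("O2", "O4", "N3"))) {
      return("acceptor_only")
    }
    if (base == "G" && elety %in% c("N1", "N2")) return("donor_only")
    return("acceptor_only")
  }
  # protein
  if (elety %in% c("OD1", "OD2", "OE1", "OE2", "O", "OXT")) return("acceptor_only")
  if (elety %in% c("NZ", "NE", "NH1", "NH2", "ND2", "NE2", "N", "NE1")) {
    if (resid == "HIS") return("ambivalent")
    return("donor_only")
  }
  if (elety %in% c("OG", "OG1", "OH")) return("ambivalent")
  if (resid == "HIS" && elety %in% c("ND1", "NE2")) return("ambivalent")
  "ambivalent"
}

#' Build the hydrogen-bond graph around a set of waters
#'
#' Nodes are the waters plus every polar site within `cutoff` of any of them;
#' edges are candidate hydrogen bonds (pairwise distance <= `cutoff`). Each
#' node carries a chemistry class (`donor_only`, `acceptor_only`,
#' `ambivalent`, `water`) and donation/acceptance capacities (water: 2 and 2).
#'
#' @param structure an `ets_structure`.
#' @param waters tibble with columns `chain`, `resno` naming the water
#'   molecules (e.g. from [find_bridging_waters()]).
#' @param cutoff hydrogen-bond distance cutoff (Angstrom).
#' @param pairs optional [find_base_pairs()] result: base nodes get an
#'   `ebs_position`.
#' @return list of class `ets_hbond_graph` with `nodes` (tibble: id, label,
#'   class, capacities, ebs_position) and `edges` (tibble: node ids, distance).
#' @export
hbond_graph <- function(structure, waters, cutoff = 3.5, pairs = NULL) {
  at <- tibble::as_tibble(structure)
  pol <- polar_atoms(structure)
  wsel <- pol$kind == "water" &
    paste(pol$chain, pol$resno) %in% paste(waters$chain, waters$resno)
  wpol <- pol[wsel, ]
  if (nrow(wpol) == 0) abort("no water oxygen atoms matched")
  other <- pol[!pol$kind == "water" | !wsel, ]
  other <- pol[!wsel, ]
  cp <- close_pairs(as.matrix(wpol[, c("x", "y", "z")]),
                    as.matrix(other[, c("x", "y", "z")]), cutoff)
  keep_other <- sort(unique(cp$j))
  nodes_df <- dplyr::bind_rows(wpol, other[keep_other, ])
  nodes_df <- dplyr::distinct(nodes_df, .data$chain, .data$resno, .data$elety,
                              .keep_all = TRUE)
  nodes_df$class <- vapply(seq_len(nrow(nodes_df)), function(i) {
    .chem_class(nodes_df$kind[i], nodes_df$resid[i], nodes_df$elety[i])
  }, character(1))
  caps <- t(vapply(nodes_df$class, .node_capacity, integer(2)))
  nodes <- tibble::tibble(
    id = seq_len(nrow(nodes_df)),
    chain = nodes_df$chain, resid = nodes_df$resid, resno = nodes_df$resno,
    elety = nodes_df$elety, kind = nodes_df$kind, class = nodes_df$class,
    max_don = caps[, 1], max_acc = caps[, 2],
    x = nodes_df$x, y = nodes_df$y, z = nodes_df$z,
    ebs_position = NA_integer_
  )
  if (!is.null(pairs) && nrow(pairs) > 0) {
    ki <- paste(pairs$chain_i, pairs$resno_i)
    kj <- paste(pairs$chain_j, pairs$resno_j)
    nk <- paste(nodes$chain, nodes$resno)
    pos <- pairs$ebs_position[match(nk, ki)]
    pos2 <- pairs$ebs_position[match(nk, kj)]
    nodes$ebs_position <- ifelse(nodes$kind == "dna",
                                 ifelse(!is.na(pos), pos, pos2), NA_integer_)
  }
  xyz <- as.matrix(nodes[, c("x", "y", "z")])
  ep <- close_pairs(xyz, xyz, cutoff)
  ep <- ep[ep$i < ep$j, ]
  # candidate H-bonds must involve a water, and be chemically directable
  wids <- nodes$id[nodes$kind == "water"]
  ep <- ep[ep$i %in% wids | ep$j %in% wids, ]
  feasible <- vapply(seq_len(nrow(ep)), function(k) {
    ci <- nodes$class[ep$i[k]]; cj <- nodes$class[ep$j[k]]
    !(ci == "donor_only" && cj == "donor_only") &&
      !(ci == "acceptor_only" && cj == "acceptor_only")
  }, logical(1))
  ep <- ep[feasible, ]
  edges <- tibble::tibble(from = ep$i, to = ep$j, distance = ep$dist)
  out <- list(nodes = nodes, edges = edges, cutoff = cutoff)
  class(out) <- "ets_hbond_graph"
  out
}

#' @export
print.ets_hbond_graph <- function(x, ...) {
  cat(sprintf("<hbond graph>  %d nodes (%d waters), %d edges (cutoff %.2f A)\n",
              nrow(x$nodes), sum(x$nodes$kind == "water"), nrow(x$edges),
              x$cutoff))
  invisible(x)
}

#' Enumerate hydrogen donor/acceptor assignments over a network
#'
#' Considers every orientation of every edge (donor -> acceptor), keeping the
#' assignments in which no node donates or accepts beyond its capacity and no
#' `donor_only` node accepts / `acceptor_only` node donates. The enumeration
#' is exhaustive over all 2^E orientations (edge-by-edge expansion with
#' capacity pruning, which discards only partial assignments that already
#' violate a constraint).
#'
#' @param graph an `ets_hbond_graph`.
#' @param max_edges refuse larger graphs (exhaustive domain).
#' @return list of class `ets_h_assignments`: `n_solutions`, `solutions`
#'   (list of tibbles `from`, `to`, `donor` giving each edge's donor node id),
#'   `feasible`, and the input graph.
#' @export
enumerate_h_assignments <- function(graph, max_edges = 25L) {
  E <- nrow(graph$edges)
  if (E > max_edges) {
    abort(sprintf("graph too large for exhaustive enumeration: %d edges (max %d)",
                  E, max_edges))
  }
  if (E == 0) {
    out <- list(n_solutions = 1L, solutions = list(), feasible = TRUE,
                graph = graph)
    class(out) <- "ets_h_assignments"
    return(out)
  }
  nN <- nrow(graph$nodes)
  maxd <- graph$nodes$max_don
  maxa <- graph$nodes$max_acc
  # partial assignments: matrices of donation / acceptance counts per node,
  # one row per surviving partial assignment, expanded edge by edge
  don <- matrix(0L, 1, nN)
  acc <- matrix(0L, 1, nN)
  choice <- matrix(integer(0), 1, 0)
  for (e in seq_len(E)) {
    i <- graph$edges$from[e]
    j <- graph$edges$to[e]
    # orientation 1: i donates to j; orientation 2: j donates to i
    don1 <- don; don1[, i] <- don1[, i] + 1L
    acc1 <- acc; acc1[, j] <- acc1[, j] + 1L
    don2 <- don; don2[, j] <- don2[, j] + 1L
    acc2 <- acc; acc2[, i] <- acc2[, i] + 1L
    ok1 <- don1[, i] <= maxd[i] & acc1[, j] <= maxa[j]
    ok2 <- don2[, j] <= maxd[j] & acc2[, i] <= maxa[i]
    don <- rbind(don1[ok1, , drop = FALSE], don2[ok2, , drop = FALSE])
    acc <- rbind(acc1[ok1, , drop = FALSE], acc2[ok2, , drop = FALSE])
    choice <- rbind(
      cbind(choice[ok1, , drop = FALSE], rep(i, sum(ok1))),
      cbind(choice[ok2, , drop = FALSE], rep(j, sum(ok2)))
    )
    if (nrow(don) == 0) break
  }
  n_sol <- nrow(don)
  sols <- purrr::map(seq_len(n_sol), function(r) {
    tibble::tibble(from = graph$edges$from, to = graph$edges$to,
                   donor = as.integer(choice[r, ]))
  })
  out <- list(n_solutions = n_sol, solutions = sols, feasible = n_sol > 0,
              graph = graph)
  class(out) <- "ets_h_assignments"
  out
}

#' @export
print.ets_h_assignments <- function(x, ...) {
  cat(sprintf("<hydrogen assignments>  %d solution(s) over %d edges\n",
              x$n_solutions, nrow(x$graph$edges)))
  invisible(x)
}

#' Base selectivity implied by the water network
#'
#' Given a unique hydrogen assignment, inspects the water facing the base at
#' `ebs_position`: if the network forces that water to accept from the base,
#' the base must present an exocyclic hydrogen-bond donor -- satisfied by
#' cytosine (N4-H) and adenine (N6-H, with an elongated ~4.0 A contact);
#' if it forces the water to donate, the base must present an exocyclic
#' acceptor (guanine O6, thymine O4).
#'
#' @param assignments result of [enumerate_h_assignments()].
#' @param ebs_position base position of interest (default -1).
#' @return list of class `ets_selectivity`: `unique` flag, `water_role`
#'   (`"acceptor"` or `"donor"` toward the base), `allowed_bases`, `notes`.
#' @export
selectivity_report <- function(assignments, ebs_position = -1) {
  g <- assignments$graph
  if (assignments$n_solutions != 1) {
    out <- list(unique = FALSE, water_role = NA_character_,
                allowed_bases = character(),
                notes = sprintf("ambiguous: %d solutions", assignments$n_solutions))
    class(out) <- "ets_selectivity"
    return(out)
  }
  sol <- assignments$solutions[[1]]
  base_nodes <- g$nodes$id[!is.na(g$nodes$ebs_position) &
                             g$nodes$ebs_position == ebs_position &
                             g$nodes$kind == "dna" &
                             !g$nodes$elety %in% c("OP1", "OP2", "O1P", "O2P",
                                                   "O5'", "O3'", "O4'")]
  if (length(base_nodes) == 0) {
    out <- list(unique = TRUE, water_role = NA_character_,
                allowed_bases = character(),
                notes = sprintf("no base-edge node at position %+d in the graph",
                                ebs_position))
    class(out) <- "ets_selectivity"
    return(out)
  }
  wids <- g$nodes$id[g$nodes$kind == "water"]
  be <- sol[(sol$from %in% base_nodes & sol$to %in% wids) |
              (sol$to %in% base_nodes & sol$from %in% wids), ]
  if (nrow(be) == 0) {
    out <- list(unique = TRUE, water_role = NA_character_,
                allowed_bases = character(),
                notes = "no water-base edge in the network")
    class(out) <- "ets_selectivity"
    return(out)
  }
  base_donates <- be$donor %in% base_nodes
  if (all(base_donates)) {
    role <- "acceptor"
    allowed <- c(C = "N4-H", A = "N6-H (elongated, ~4.0 A)")
    notes <- "base must present an exocyclic H-bond donor"
  } else if (all(!base_donates)) {
    role <- "donor"
    allowed <- c(G = "O6", T = "O4")
    notes <- "base must present an exocyclic H-bond acceptor"
  } else {
    role <- "mixed"
    allowed <- character()
    notes <- "base both donates and accepts in the unique solution"
  }
  out <- list(unique = TRUE, water_role = role,
              allowed_bases = names(allowed), acceptor_atoms = unname(allowed),
              notes = notes)
  class(out) <- "ets_selectivity"
  out
}

#' @export
print.ets_selectivity <- function(x, ...) {
  if (!x$unique) {
    cat("<selectivity>  no unique assignment:", x$notes, "\n")
  } else {
    cat(sprintf("<selectivity>  water is %s toward the base; allowed bases: %s (%s)\n",
                x$water_role, paste(x$allowed_bases, collapse = ", "), x$notes))
  }
  invisible(x)
}
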