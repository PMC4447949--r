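# Bridging waters, conservation across superposed structures, and the
# hydrogen-assignment constraint network.

test_that("the planted four-water network is recovered edge-for-edge", {
  fx <- water_fixture()
  br <- find_bridging_waters(fx$structure)
  expect_equal(nrow(br), 4) # every planted water bridges protein and DNA
  expect_setequal(br$resno, 501:504)
  # each has at least one partner on each side
  expect_true(all(vapply(br$protein_partners, nrow, integer(1)) >= 1))
  expect_true(all(vapply(br$dna_partners, nrow, integer(1)) >= 1))
  # realized graph equals the design
  g <- hbond_graph(fx$structure, fx$waters, pairs = fx$pairs)
  expect_setequal(etsface:::.edge_keys(g), fx$design_edges)
})

test_that("bridging-water search matches a brute-force filter on the fixture", {
  fx <- water_fixture()
  s <- fx$structure
  pol <- etsface:::polar_atoms(s)
  at <- tibble::as_tibble(s)
  wat <- at[at$kind == "water", ]
  bridging <- vapply(seq_len(nrow(wat)), function(k) {
    d <- sqrt((pol$x - wat$x[k])^2 + (pol$y - wat$y[k])^2 + (pol$z - wat$z[k])^2)
    near <- pol[d <= 3.5 & pol$kind != "water", ]
    any(near$kind == "protein") && any(near$kind == "dna")
  }, logical(1))
  br <- find_bridging_waters(s)
  expect_equal(sort(br$resno), sort(wat$resno[bridging]))
})

test_that("a structure without waters warns about the resolution caveat", {
  s <- build_bdna("ACCGGAAGTG")
  expect_warning(br <- find_bridging_waters(s), "resolution")
  expect_equal(nrow(br), 0)
})

test_that("hydrogen assignment over the fixture network is unique and the
           base-facing water accepts from the cytosine N4", {
  fx <- water_fixture()
  asn <- enumerate_h_assignments(fx$graph)
  expect_equal(asn$n_solutions, 1)
  sol <- asn$solutions[[1]]
  nodes <- fx$graph$nodes
  n4 <- nodes$id[nodes$elety == "N4" & nodes$resno == 3]
  w1 <- nodes$id[nodes$kind == "water" & nodes$resno == 501]
  edge <- sol[(sol$from == n4 & sol$to == w1) | (sol$from == w1 & sol$to == n4), ]
  expect_equal(nrow(edge), 1)
  expect_equal(edge$donor, n4) # the base donates; the water accepts
})

test_that("selectivity reporting follows the forced water role", {
  fx <- water_fixture()
  asn <- enumerate_h_assignments(fx$graph)
  sel <- selectivity_report(asn, ebs_position = -1)
  expect_true(sel$unique)
  expect_equal(sel$water_role, "acceptor")
  expect_setequal(sel$allowed_bases, c("C", "A")) # N4-H / elongated N6-H

  # forced-donor variant: base presents an acceptor instead; drop one Asp
  # edge so the base-facing water has a donation slot
  g2 <- fx$graph
  n4 <- g2$nodes$id[g2$nodes$elety == "N4" & g2$nodes$resno == 3]
  g2$nodes$class[g2$nodes$id == n4] <- "acceptor_only"
  g2$nodes$max_don[g2$nodes$id == n4] <- 0L
  g2$nodes$max_acc[g2$nodes$id == n4] <- 2L
  od2 <- g2$nodes$id[g2$nodes$elety == "OD2"]
  keep <- !((g2$edges$from == od2) | (g2$edges$to == od2))
  g2$edges <- g2$edges[keep, ]
  asn2 <- enumerate_h_assignments(g2)
  expect_equal(asn2$n_solutions, 1)
  sel2 <- selectivity_report(asn2, ebs_position = -1)
  expect_equal(sel2$water_role, "donor")
  expect_setequal(sel2$allowed_bases, c("G", "T")) # O6 / O4 acceptors
})

test_that("forced single-water configurations have exactly one assignment", {
  # one water between two acceptor-only phosphate oxygens: water donates both
  g <- list(
    nodes = tibble::tibble(id = 1:3, class = c("water", "acceptor_only",
                                               "acceptor_only"),
                           max_don = c(2L, 0L, 0L), max_acc = c(2L, 2L, 2L)),
    edges = tibble::tibble(from = c(1L, 1L), to = c(2L, 3L),
                           distance = c(2.8, 3.0)),
    cutoff = 3.5
  )
  expect_equal(enumerate_h_assignments(g)$n_solutions, 1)
  # water saturated by two donors and two acceptors, 4 edges
  g2 <- list(
    nodes = tibble::tibble(id = 1:5,
                           class = c("water", "donor_only", "donor_only",
                                     "acceptor_only", "acceptor_only"),
                           max_don = c(2L, 2L, 2L, 0L, 0L),
                           max_acc = c(2L, 0L, 0L, 2L, 2L)),
    edges = tibble::tibble(from = c(1L, 1L, 1L, 1L), to = 2:5,
                           distance = rep(3, 4)),
    cutoff = 3.5
  )
  expect_equal(enumerate_h_assignments(g2)$n_solutions, 1)
})

test_that("enumeration equals the recursive backtracking oracle on random graphs", {
  for (seed in 1:100) {
    g <- random_hbond_graph(seed)
    expect_equal(enumerate_h_assignments(g)$n_solutions, oracle_assignments(g),
                 info = paste("seed", seed))
  }
})

test_that("the solution count is invariant under node relabeling", {
  for (seed in c(3, 17, 52)) {
    g <- random_hbond_graph(seed)
    n <- nrow(g$nodes)
    set.seed(seed + 1000)
    perm <- sample(n) # old id -> new id
    ord <- order(perm)
    g2 <- list(
      nodes = tibble::tibble(id = seq_len(n),
                             class = g$nodes$class[ord],
                             max_don = g$nodes$max_don[ord],
                             max_acc = g$nodes$max_acc[ord]),
      edges = tibble::tibble(from = perm[g$edges$from],
                             to = perm[g$edges$to],
                             distance = g$edges$distance),
      cutoff = g$cutoff
    )
    expect_equal(enumerate_h_assignments(g2)$n_solutions,
                 enumerate_h_assignments(g)$n_solutions)
  }
})

test_that("oversize graphs are refused rather than searched heuristically", {
  g <- random_hbond_graph(1)
  g$edges <- dplyr::bind_rows(replicate(10, g$edges, simplify = FALSE))[1:26, ]
  expect_error(enumerate_h_assignments(g), "too large")
})

test_that("waters conserved across superposed copies are found at distance zero", {
  fx <- water_fixture()
  cw <- conserved_waters(list(fx$structure, fx$structure))
  expect_equal(sum(cw$conserved), 4)
  expect_true(all(cw$n_structures[cw$conserved] == 2))
})

test_that("an unshared water breaks exactly one cluster", {
  fx <- water_fixture()
  at <- tibble::as_tibble(fx$structure)
  drop_w4 <- new_structure(at[!(at$chain == "W" & at$resno == 504), ],
                           id = "minus_w4")
  cw <- conserved_waters(list(fx$structure, drop_w4))
  expect_equal(sum(cw$conserved), 3)
  # symmetric in structure order
  cw2 <- conserved_waters(list(drop_w4, fx$structure))
  expect_equal(sum(cw2$conserved), 3)
})

test_that("conservation tolerates displacement up to the match radius", {
  fx <- water_fixture()
  at <- tibble::as_tibble(fx$structure)
  wsel <- at$chain == "W"
  at$x[wsel] <- at$x[wsel] + 0.4 # displace every water by 0.4 A
  moved <- new_structure(at, id = "shifted_waters")
  cw <- conserved_waters(list(fx$structure, moved), match_radius = 1.0)
  expect_equal(sum(cw$conserved), 4)
  cw_tight <- conserved_waters(list(fx$structure, moved), match_radius = 0.2)
  expect_equal(sum(cw_tight$conserved), 0)
})
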