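# In-silico 5-methylcytosine / phosphoserine construction and clash scans.

ser_complex <- function() {
  build_planted_complex(
    hbonds = list(list(res = "SER", target = list(chain = "A", resno = 4,
                                                  elety = "OP1"),
                       distance = 2.9)))
}

test_that("the 5-methyl carbon is built in-plane at the standard bond length", {
  s <- build_bdna("ACCGGAAGTG")
  m <- add_5_methyl(s, "A", 3)
  at <- tibble::as_tibble(m)
  expect_equal(at$resid[at$chain == "A" & at$resno == 3][1], "5CM")
  c7 <- unlist(at[at$chain == "A" & at$resno == 3 & at$elety == "C7",
                  c("x", "y", "z")])
  g <- function(el) unlist(at[at$chain == "A" & at$resno == 3 & at$elety == el,
                              c("x", "y", "z")])
  expect_equal(sqrt(sum((c7 - g("C5"))^2)), 1.50, tolerance = 0.01)
  # in the base plane: distance from the ring least-squares plane < 0.05 A
  ring <- at[at$chain == "A" & at$resno == 3 &
               at$elety %in% c("N1", "C2", "N3", "C4", "C5", "C6"), ]
  rm <- as.matrix(ring[, c("x", "y", "z")])
  nrm <- svd(sweep(rm, 2, colMeans(rm)))$v[, 3]
  expect_lt(abs(sum((c7 - colMeans(rm)) * nrm)), 0.05)
})

test_that("methyl placement coincides with an internal-coordinate oracle", {
  s <- build_bdna("ACCGGAAGTG")
  m <- add_5_methyl(s, "A", 3)
  at <- tibble::as_tibble(m)
  g <- function(el) unlist(at[at$chain == "A" & at$resno == 3 & at$elety == el,
                              c("x", "y", "z")])
  # oracle: Z-matrix placement off C4-C6-C5 with the angles implied by the
  # external-bisector construction (C6-C5-C7 angle = 180 - ring/2 each side)
  ring_angle <- acos(sum((g("C4") - g("C5")) * (g("C6") - g("C5"))) /
                       (sqrt(sum((g("C4") - g("C5"))^2)) *
                          sqrt(sum((g("C6") - g("C5"))^2)))) * 180 / pi
  oracle <- etsface:::.place_dihedral(g("C4"), g("C6"), g("C5"),
                                      bond = 1.50,
                                      angle = 180 - ring_angle / 2,
                                      dihedral = 180)
  expect_lt(sqrt(sum((g("C7") - oracle)^2)), 1e-3)
})

test_that("the phosphoserine group carries standard bond geometry", {
  s <- ser_complex()
  m <- add_phosphoserine(s, "P", 1)
  at <- tibble::as_tibble(m)
  g <- function(el) unlist(at[at$chain == "P" & at$resno == 1 & at$elety == el,
                              c("x", "y", "z")])
  expect_equal(sqrt(sum((g("P") - g("OG"))^2)), 1.61, tolerance = 0.01)
  for (el in c("O1P", "O2P", "O3P")) {
    expect_equal(sqrt(sum((g("P") - g(el))^2)), 1.48, tolerance = 0.01)
  }
  expect_equal(at$resid[at$chain == "P" & at$resno == 1][1], "SEP")
  # oracle: rebuild P with the same internal coordinates
  oracle <- etsface:::.place_dihedral(g("CA"), g("CB"), g("OG"),
                                      bond = 1.61, angle = 109.5,
                                      dihedral = 180)
  expect_lt(sqrt(sum((g("P") - oracle)^2)), 1e-9)
})

test_that("modification targets are type-checked", {
  s <- build_bdna("ACCGGAAGTG")
  expect_error(add_5_methyl(s, "A", 4), "not a cytosine") # guanine
  sc <- ser_complex()
  expect_error(add_phosphoserine(sc, "A", 3), "not a serine")
  expect_error(add_5_methyl(s, "Z", 1), "not found")
})

test_that("builders are local: pre-existing atoms do not move", {
  s <- build_bdna("ACCGGAAGTG")
  m <- add_5_methyl(s, "A", 3)
  at0 <- tibble::as_tibble(s)
  at1 <- tibble::as_tibble(m)
  at1 <- at1[!(at1$modified %in% TRUE), ]
  expect_equal(nrow(at1), nrow(at0))
  expect_equal(as.matrix(at1[, c("x", "y", "z")]),
               as.matrix(at0[, c("x", "y", "z")]))
})

test_that("clash scanning measures positive vdW overlap only", {
  s <- build_bdna("ACCGGAAGTG")
  expect_equal(nrow(clash_scan(s)), 0) # unmodified -> nothing to scan
  m <- add_5_methyl(s, "A", 3)
  at <- tibble::as_tibble(m)
  c7 <- unlist(at[at$elety == "C7" & at$chain == "A" & at$resno == 3,
                  c("x", "y", "z")])
  # planted atom 2.0 A from the methyl carbon: overlap 1.70 + 1.70 - 2.0 = 1.40
  probe <- at[1, ]
  probe$chain <- "Q"; probe$resno <- 999L; probe$resid <- "ALA"
  probe$elety <- "CB"; probe$element <- "C"; probe$modified <- FALSE
  probe$x <- c7[1] + 2.0; probe$y <- c7[2]; probe$z <- c7[3]
  m2 <- new_structure(dplyr::bind_rows(at, probe), id = "clash_toy")
  cl <- clash_scan(m2)
  hit <- cl[cl$chain2 == "Q", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$overlap, 1.40, tolerance = 1e-6)
  expect_equal(hit$severity, "clash")
  expect_true(all(cl$overlap > 0))
})

test_that("clash scanning equals a brute-force all-pairs oracle", {
  s <- build_bdna("ACCGGA")
  m <- add_5_methyl(s, "A", 3)
  at <- tibble::as_tibble(m)
  r <- vdw_radius(at$element)
  mod <- which(at$modified)
  expected <- character()
  for (i in mod) {
    for (j in seq_len(nrow(at))) {
      if (at$chain[i] == at$chain[j] && at$resno[i] == at$resno[j]) next
      d <- sqrt(sum((unlist(at[i, c("x", "y", "z")]) -
                       unlist(at[j, c("x", "y", "z")]))^2))
      if (r[i] + r[j] - d > 0) {
        expected <- c(expected, paste(at$chain[j], at$resno[j], at$elety[j]))
      }
    }
  }
  cl <- clash_scan(m)
  expect_setequal(paste(cl$chain2, cl$resno2, cl$atom2), expected)
})

test_that("clash lists are invariant under rigid transforms", {
  s <- build_bdna("ACCGGAAGTG")
  m <- add_5_methyl(s, "A", 3)
  m2 <- transform_structure(m, etsface:::random_rotation(9), c(3, 1, -8))
  cl1 <- clash_scan(m)
  cl2 <- clash_scan(m2)
  key <- function(x) paste(x$chain2, x$resno2, x$atom2)
  expect_setequal(key(cl1), key(cl2))
  expect_equal(sort(cl1$overlap), sort(cl2$overlap), tolerance = 1e-9)
})

test_that("the phosphoserine rotamer scan reports per-torsion proximity", {
  s <- ser_complex()
  scan <- phosphoserine_scan(s, "P", 1)
  expect_equal(nrow(scan), 12)
  expect_true(all(is.finite(scan$min_dist_to_dna)))
  expect_true(any(scan$min_dist_to_dna < 6)) # some rotamers approach the DNA
  expect_true(all(diff(scan$torsion) == 30))
})
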