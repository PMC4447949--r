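# Coordinate parsing, writing, selection and superposition.

test_that("PDB write -> parse round trip preserves the atom model", {
  s <- build_bdna("ACGTAC")
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, tmp)
  s2 <- read_structure(tmp)
  expect_equal(nrow(s2), nrow(s))
  expect_equal(sort(unique(s2$chain)), c("A", "B"))
  # PDB dialect carries 3 decimals
  expect_lt(max(abs(coords(s2) - coords(s))), 5e-4 + 1e-9)
  expect_equal(s2$resno, s$resno)
  expect_equal(s2$elety, s$elety)
})

test_that("multi-model files yield model 1 only, matching a record-count oracle", {
  s <- build_bdna("ACGT")
  tmp1 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, tmp1)
  body <- readLines(tmp1)
  atoms <- body[grepl("^(ATOM|HETATM)", body)]
  shifted <- sub("^(.{30})", "\\1", atoms) # same records, second model
  multi <- c("MODEL     1", atoms, "ENDMDL", "MODEL     2", shifted, "ENDMDL", "END")
  tmp2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(multi, tmp2)
  parsed <- read_structure(tmp2)
  # oracle: count ATOM/HETATM lines inside the first MODEL block
  m1 <- seq(which(multi == "MODEL     1") + 1, which(multi == "ENDMDL")[1] - 1)
  expect_equal(nrow(parsed), sum(grepl("^(ATOM|HETATM)", multi[m1])))
})

test_that("alternate locations keep blank/'A' by default, all on request", {
  lines <- c(
    "ATOM      1  CA AALA A   1      11.000  12.000  13.000  0.50 10.00           C",
    "ATOM      2  CA BALA A   1      11.500  12.000  13.000  0.50 10.00           C",
    "ATOM      3  CB  ALA A   1      12.000  13.000  14.000  1.00 10.00           C",
    "END"
  )
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, tmp)
  expect_equal(nrow(read_structure(tmp)), 2)
  expect_equal(nrow(read_structure(tmp, keep_all_altlocs = TRUE)), 3)
})

test_that("mmCIF atom_site records parse with author numbering and waters typed", {
  cif <- c(
    "data_test",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.auth_atom_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id",
    "_atom_site.label_alt_id",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C CA ALA A 42 . 1.000 2.000 3.000 1.00 20.00 1",
    "ATOM 2 O O ALA A 42 . 2.000 2.500 3.500 1.00 21.00 1",
    "HETATM 3 O O HOH W 501 . 5.000 5.000 5.000 1.00 30.00 1",
    "#"
  )
  tmp <- withr::local_tempfile(fileext = ".cif")
  writeLines(cif, tmp)
  s <- read_structure(tmp)
  expect_equal(nrow(s), 3)
  expect_equal(s$resno, c(42L, 42L, 501L))
  expect_equal(s$kind, c("protein", "protein", "water"))
  expect_equal(s$x, c(1, 2, 5))
})

test_that("unreadable input raises a parse error and empty structures are refused", {
  expect_error(read_structure(file.path(tempdir(), "nope.pdb")), "not found")
  tmp <- withr::local_tempfile(fileext = ".cif")
  writeLines(c("data_x", "_cell.length_a 10"), tmp)
  expect_error(read_structure(tmp), "atom_site")
  expect_error(new_structure(tibble::tibble(chain = character(),
                                            resid = character(),
                                            resno = integer(),
                                            elety = character(),
                                            x = numeric(), y = numeric(),
                                            z = numeric())),
               "empty")
})

test_that("selection covers chain, kind, residue ranges, atom names and negation", {
  s <- build_bdna("ACCGGAAGTG")
  expect_equal(nrow(str_select(s)), nrow(s))             # identity
  expect_warning(sel <- str_select(s, kind = "water"), "no atoms")
  expect_equal(nrow(sel), 0)
  sub <- str_select(s, chain = "A", resno = 3:6)
  at <- tibble::as_tibble(s)
  expect_equal(nrow(sub), sum(at$chain == "A" & at$resno %in% 3:6)) # brute force
  # idempotent
  expect_equal(nrow(str_select(sub, chain = "A", resno = 3:6)), nrow(sub))
  inv <- str_select(s, chain = "A", invert = TRUE)
  expect_equal(nrow(inv), sum(at$chain == "B"))
  p_only <- str_select(s, elety = "P")
  expect_true(all(p_only$elety == "P"))
  expect_error(str_select(s, kind = "lipid"), "unknown residue kind")
  expect_error(str_select(s, resno = "five"), "numeric")
})

test_that("superposition recovers exact transforms and stays orthonormal", {
  s <- build_bdna("ACGTACGT")
  idpair <- tibble::tibble(i = seq_len(nrow(s)), j = seq_len(nrow(s)))
  self <- superpose(s, s, pairing = idpair)
  expect_lt(self$rmsd, 1e-10)
  expect_lt(max(abs(self$rotation - diag(3))), 1e-8)

  Rz <- etsface:::rotation_about(c(0, 0, 1), 90)
  moved <- transform_structure(s, Rz, c(4, -2, 7))
  sup <- superpose(moved, s, pairing = idpair)
  expect_lt(sup$rmsd, 1e-8)
  expect_lt(max(abs(sup$rotation %*% Rz - diag(3))), 1e-6)
  expect_lt(max(abs(t(sup$rotation) %*% sup$rotation - diag(3))), 1e-8)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-8)
})

test_that("superposition rmsd matches the quaternion oracle on random clouds", {
  for (seed in 1:5) {
    set.seed(seed)
    P <- matrix(rnorm(30, sd = 5), ncol = 3)
    Q <- matrix(rnorm(30, sd = 5), ncol = 3)
    sp <- toy_atoms(tibble::tibble(chain = "A", resid = "ALA", resno = 1:10,
                                   elety = "CA", x = P[, 1], y = P[, 2], z = P[, 3]))
    sq <- toy_atoms(tibble::tibble(chain = "A", resid = "ALA", resno = 1:10,
                                   elety = "CA", x = Q[, 1], y = Q[, 2], z = Q[, 3]))
    sup <- superpose(sp, sq, pairing = tibble::tibble(i = 1:10, j = 1:10))
    orc <- horn_superpose(P, Q)
    expect_close(sup$rmsd, orc$rmsd, 1e-4)
    # symmetric under swapping mobile/reference
    sup2 <- superpose(sq, sp, pairing = tibble::tibble(i = 1:10, j = 1:10))
    expect_close(sup$rmsd, sup2$rmsd, 1e-8)
  }
})

test_that("degenerate pairings are rejected", {
  s <- build_bdna("ACGT")
  expect_error(superpose(s, s, pairing = tibble::tibble(i = 1:2, j = 1:2)),
               "insufficient")
  line <- toy_atoms(tibble::tibble(chain = "A", resid = "ALA", resno = 1:4,
                                   elety = "CA", x = 1:4, y = 0, z = 0))
  expect_error(superpose(line, line, pairing = tibble::tibble(i = 1:4, j = 1:4)),
               "collinear")
})
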