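# Contact detection, classification and the contacted base-pair span.

planted_toy <- function() {
  build_planted_complex(
    hbonds = list(
      list(res = "SER", target = list(chain = "A", resno = 4, elety = "OP1"),
           distance = 2.9),
      list(res = "GLN", target = list(chain = "B", resno = 3, elety = "OP2"),
           distance = 3.1)),
    salt_bridges = list(
      list(res = "LYS", target = list(chain = "A", resno = 8, elety = "OP2"),
           distance = 3.2),
      list(res = "ARG", target = list(chain = "B", resno = 5, elety = "OP1"),
           distance = 3.5))
  )
}

test_that("detection equals the all-pairs oracle on toy systems", {
  s <- planted_toy()
  for (seed in c(0L, 1L, 2L)) {
    sp <- if (seed == 0L) s else perturb_structure(s, 0.15, seed = seed)
    hb <- find_hbonds(sp, list(kind = "protein"), list(kind = "dna"))
    got <- sort(unique(paste(hb$chain1, hb$resno1, hb$atom1,
                             hb$chain2, hb$resno2, hb$atom2)))
    expect_equal(got, oracle_hbonds(sp))
    sb <- find_salt_bridges(sp, list(kind = "protein"), list(kind = "dna"))
    got_sb <- sort(unique(paste(sb$chain1, sb$resno1, sb$chain2, sb$resno2)))
    expect_equal(got_sb, oracle_salt_bridges(sp))
  }
})

test_that("contact classes are mutually exclusive per atom pair", {
  s <- planted_toy()
  hb <- find_hbonds(s, list(kind = "protein"), list(kind = "dna"))
  sb <- find_salt_bridges(s, list(kind = "protein"), list(kind = "dna"))
  vw <- find_vdw_contacts(s, list(kind = "protein"), list(kind = "dna"))
  key <- function(x) paste(x$chain1, x$resno1, x$atom1, x$chain2, x$resno2, x$atom2)
  expect_length(intersect(key(hb), key(sb)), 0)
  expect_length(intersect(key(hb), key(vw)), 0)
  expect_length(intersect(key(sb), key(vw)), 0)
})

test_that("contact lists are invariant under rigid transformation", {
  s <- planted_toy()
  R <- etsface:::random_rotation(42)
  s2 <- transform_structure(s, R, c(13, -7, 4))
  key <- function(x) paste(x$kind, x$chain1, x$resno1, x$atom1,
                           x$chain2, x$resno2, x$atom2)
  cm1 <- contact_map(s)
  cm2 <- contact_map(s2)
  expect_setequal(key(cm1$contacts), key(cm2$contacts))
  expect_equal(sort(cm1$contacts$distance), sort(cm2$contacts$distance),
               tolerance = 1e-9)
})

test_that("the contacted base-pair span is the inclusive pair-index distance", {
  # fragments touching pairs 4 and 8 only -> span 5 (8 - 4 + 1)
  s <- build_planted_complex(
    hbonds = list(
      list(res = "SER", target = list(chain = "A", resno = 4, elety = "OP1"),
           distance = 2.9),
      list(res = "GLN", target = list(chain = "A", resno = 8, elety = "OP1"),
           distance = 2.9))
  )
  pairs <- find_base_pairs(s)
  # manual enumeration oracle: contacted pair indices from any-atom contacts
  vw <- find_vdw_contacts(s, list(kind = "protein"), list(kind = "dna"),
                          max_dist = 3.9, exclude_polar = FALSE)
  idx <- pairs$pair_index[match(paste(vw$chain2, vw$resno2),
                                paste(pairs$chain_i, pairs$resno_i))]
  idx <- c(idx, pairs$pair_index[match(paste(vw$chain2, vw$resno2),
                                       paste(pairs$chain_j, pairs$resno_j))])
  idx <- idx[!is.na(idx)]
  expect_equal(contacted_bp_span(s, pairs), max(idx) - min(idx) + 1L)
  expect_equal(contacted_bp_span(s, pairs), 5L)
})

test_that("span is zero without contacts", {
  s <- build_bdna("ACCGGAAGTG")
  pairs <- find_base_pairs(s)
  expect_warning(sp <- contacted_bp_span(s, pairs), "no atoms")
  expect_equal(sp, 0L)
})

test_that("DNA moiety classification partitions every guanine atom exactly once", {
  s <- build_bdna("ACCGGAAGTG")
  at <- tibble::as_tibble(s)
  g4 <- at[at$chain == "A" & at$resno == 4, ]
  parts <- etsface:::dna_part_of(g4$elety, etsface:::base_letter(g4$resid))
  expect_true(all(parts %in% c("phosphate_backbone", "sugar", "base_major",
                               "base_minor")))
  expect_equal(length(parts), nrow(g4)) # exactly one class per atom
  expect_equal(unname(parts[g4$elety == "OP1"]), "phosphate_backbone")
  expect_equal(unname(parts[g4$elety == "O6"]), "base_major")
  expect_equal(unname(parts[g4$elety == "N3"]), "base_minor")
  expect_equal(unname(parts[g4$elety == "C1'"]), "sugar")
})

test_that("contacts carry the binding-site position register", {
  s <- planted_toy()
  pairs <- find_base_pairs(s)
  cm <- contact_map(s, pairs = pairs)
  hb <- cm$contacts[cm$contacts$kind == "hbond" & cm$contacts$resid1 == "SER", ]
  # chain A resno 4 is the first G of the GGA core
  expect_equal(hb$ebs_position, 1L)
  expect_equal(hb$dna_part, "phosphate_backbone")
})

test_that("empty selections warn and return no contacts", {
  s <- build_bdna("ACCGGAAGTG")
  expect_warning(hb <- find_hbonds(s, list(kind = "protein"), list(kind = "dna")),
                 "empty selection")
  expect_equal(nrow(hb), 0)
})
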