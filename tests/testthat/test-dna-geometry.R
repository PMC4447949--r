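# Base-pair detection, frames, bend angle, groove widths, B-form comparison.

test_that("the consensus duplex gives 10 WC pairs with the GGA register", {
  s <- build_bdna("ACCGGAAGTG")
  p <- find_base_pairs(s)
  expect_equal(nrow(p), 10)
  expect_true(all(p$wc_class == "WC"))
  expect_equal(p$ebs_position[p$pair_index == 4], 1L)  # first G of GGA
  expect_equal(p$ebs_position[p$pair_index == 3], -1L) # no position zero
  expect_equal(p$ebs_position[p$pair_index == 1], -3L)
})

test_that("the GGA core is registered from the complementary strand too", {
  s <- build_bdna("TACTTCCGGT") # GGA only on the complement (ACCGGAAGTA)
  # automatic reference selection roots on the GGA-bearing strand
  p <- find_base_pairs(s)
  expect_false(all(is.na(p$ebs_position)))
  g_auto <- p$pair_index[!is.na(p$ebs_position) & p$ebs_position == 1L]
  expect_equal(p$base_i[p$pair_index == g_auto], "G")
  # forcing the GGA-free strand as reference exercises the fallback: the +1
  # guanine then sits on the complementary side
  p2 <- find_base_pairs(s, ref_chain = "A")
  g2 <- p2$pair_index[!is.na(p2$ebs_position) & p2$ebs_position == 1L]
  expect_length(g2, 1)
  expect_equal(p2$base_j[p2$pair_index == g2], "G")
})

test_that("pairing is deterministic and order-invariant", {
  s <- build_bdna("ACCGGAAGTG")
  p1 <- find_base_pairs(s)
  set.seed(5)
  shuffled <- new_structure(tibble::as_tibble(s)[sample(nrow(s)), ],
                            id = "shuffled")
  p2 <- find_base_pairs(shuffled)
  expect_equal(p1$resno_i, p2$resno_i)
  expect_equal(p1$resno_j, p2$resno_j)
  expect_equal(p1$ebs_position, p2$ebs_position)
})

test_that("base-pair frames are orthonormal right-handed triads", {
  s <- build_bdna("ACCGGAAGTG")
  fr <- bp_frames(s, find_base_pairs(s))
  for (k in c(1, 5, 10)) {
    M <- cbind(fr$x_axis[[k]], fr$y_axis[[k]], fr$z_axis[[k]])
    expect_lt(max(abs(t(M) %*% M - diag(3))), 1e-8)
    expect_equal(det(M), 1, tolerance = 1e-8)
  }
})

test_that("a straight fiber bends less than 2 degrees for any sequence", {
  for (seq in c("ACGTACGTAC", "GGGGGGGGGGGG", "ATATATATATATAT")) {
    s <- build_bdna(seq)
    fr <- bp_frames(s, suppressWarnings(find_base_pairs(s))) # no GGA core
    expect_lt(bend_angle(fr)$bend_angle, 2)
  }
})

test_that("a planted 30-degree kink is recovered within 2 degrees", {
  s <- kinked_duplex(kink_deg = 30)
  p <- suppressWarnings(find_base_pairs(s)) # no GGA core in this sequence
  expect_equal(nrow(p), 16)
  fr <- bp_frames(s, p)
  b <- bend_angle(fr, end_len = 4)
  expect_equal(b$bend_angle, 30, tolerance = 2)
})

test_that("groove widths match the closed form on the fiber cylinder", {
  s <- build_bdna("ACGTACGTACGTACGT")
  p <- suppressWarnings(find_base_pairs(s))
  g <- groove_widths(s, p)
  geom <- etsface:::.bdna
  d_m <- function(m) {
    dphi <- (36 * m + 2 * geom$p_phi) %% 360
    dphi <- ifelse(dphi > 180, dphi - 360, dphi)
    sqrt((2 * geom$p_r * sin(abs(dphi) / 2 * pi / 180))^2 +
           (3.38 * m + 2 * geom$p_z)^2)
  }
  minor_cf <- min(d_m(2:5))
  major_cf <- min(d_m(-(1:5)))
  mid <- 7:10 # interior levels, all window members defined
  expect_lt(max(abs(g$minor[mid] - minor_cf)), 1e-6)
  expect_lt(max(abs(g$major[mid] - major_cf)), 1e-6)
  # the fiber baselines sit near the canonical raw P-P values
  expect_equal(minor_cf, 11.7, tolerance = 0.3)
  expect_equal(major_cf, 17.5, tolerance = 0.3)
  # termini flagged undefined, not zero-filled
  expect_true(g$undefined_minor[1])
  expect_true(all(is.na(g$minor[g$undefined_minor])))
})

test_that("geometry is invariant under rigid-body transforms", {
  s <- build_bdna("ACCGGAAGTG")
  p <- find_base_pairs(s)
  g1 <- groove_widths(s, p)
  b1 <- bend_angle(bp_frames(s, p))$bend_angle
  for (seed in 1:3) {
    R <- etsface:::random_rotation(seed)
    s2 <- transform_structure(s, R, c(seed, -seed, 2 * seed))
    p2 <- find_base_pairs(s2)
    g2 <- groove_widths(s2, p2)
    expect_equal(g1$minor, g2$minor, tolerance = 1e-9)
    expect_equal(g1$major, g2$major, tolerance = 1e-9)
    expect_equal(bend_angle(bp_frames(s2, p2))$bend_angle, b1, tolerance = 1e-6)
  }
})

test_that("comparison of a duplex against itself reports zero deviation", {
  s <- build_bdna("ACCGGAAGTG")
  rep <- compare_to_bform(s)
  expect_lt(abs(rep$bend_delta), 1e-6)
  expect_lt(max(rep$per_level$origin_displacement), 1e-6)
  ml <- rep$per_level$major_delta
  expect_lt(max(abs(ml[!is.na(ml)])), 1e-6)
})

test_that("a planted kink shows up as a bend delta of the planted size", {
  s <- kinked_duplex(kink_deg = 30)
  rep <- suppressWarnings(compare_to_bform(s))
  expect_equal(rep$bend_delta, 30, tolerance = 2)
})

test_that("too few pairs raise an insufficient-data error", {
  s <- build_bdna("ACGTA")
  fr <- bp_frames(s, suppressWarnings(find_base_pairs(s)))
  expect_error(bend_angle(fr, end_len = 4), "insufficient")
})
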