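test_that("gaussian overlap matches the closed-form single-pair integral", {
  for (case in list(c(1.7, 1.7, 0), c(1.7, 1.7, 1.2), c(1.2, 2.05, 0.8))) {
    a <- sphere_pose("a", case[1])
    b <- sphere_pose("b", case[2], c(case[3], 0, 0))
    expect_equal(gaussian_overlap(a, b),
                 single_pair_gaussian_overlap(case[1], case[2], case[3]),
                 tolerance = 1e-12)
  }
})

test_that("gaussian overlap is symmetric, maximal at self, and decays", {
  a <- random_pose("a", n = 10, seed = 1001)
  b <- random_pose("b", n = 12, seed = 1002)
  expect_equal(gaussian_overlap(a, b), gaussian_overlap(b, a))
  self <- gaussian_overlap(a, a)
  withr::with_seed(7, {
    for (k in 1:5) {
      moved <- transform_pose(a, random_rotation(), stats::runif(3, -2, 2))
      expect_lte(gaussian_overlap(a, moved), self + 1e-9)
    }
  })
  far <- transform_pose(a, diag(3), c(100, 0, 0))
  expect_lt(gaussian_overlap(a, far), 1e-6)
})

test_that("alignment recovers rotated and translated copies of the reference", {
  withr::with_seed(11, {
    for (k in 1:3) {
      ref <- random_pose("ref", n = 12 + k, seed = 1100 + k)
      probe <- transform_pose(ref, random_rotation(), stats::runif(3, -8, 8))
      probe$id <- "probe"
      expect_gte(shape_tanimoto(ref, probe), 0.99)
    }
    ref <- random_pose("ref", n = 15, seed = 1200)
    shifted <- transform_pose(ref, diag(3), c(5, -3, 2))
    expect_gte(shape_tanimoto(ref, shifted), 0.999)
  })
})

test_that("refinement only ever increases the alignment score", {
  ref <- random_pose("ref", n = 10, seed = 1301)
  probe <- random_pose("probe", n = 12, seed = 1302)
  al <- align_to_reference(ref, probe)
  expect_true(all(al$refined_scores >= al$start_scores - 1e-9))
  expect_gte(al$score, max(al$start_scores) - 1e-9)
})

test_that("degenerate probes fall back to translation-only alignment", {
  ref <- random_pose("ref", n = 8, seed = 1401)
  line <- molecule_pose("line", rep("C", 4),
                        cbind(seq(0, 3), 0, 0) + 50, radius = 1.7)
  expect_warning(al <- align_to_reference(ref, line), "degenerate")
  expect_equal(al$transform$rotation, diag(3))
})

test_that("a mirror image scores below self and matches the rotation-grid oracle", {
  withr::with_seed(3, {
    xyz <- matrix(stats::rnorm(36, sd = 1.2), 12, 3)
  })
  ref <- molecule_pose("ref", rep("C", 12), xyz, radius = 1.7)
  mir <- molecule_pose("mir", rep("C", 12), xyz %*% diag(c(-1, 1, 1)),
                       radius = 1.7)
  al <- align_to_reference(ref, mir)
  self <- gaussian_overlap(ref, ref)
  expect_lt(al$score, self * 0.999)  # reflections are never searched
  oracle <- so3_grid_best_overlap(ref, mir)
  expect_equal(al$score, oracle, tolerance = 0.01)
})

test_that("shape Tanimoto hits its exact landmark values", {
  p <- random_pose("p", n = 9, seed = 1501)
  expect_equal(shape_tanimoto(p, p, align = FALSE), 1.0)
  far <- transform_pose(p, diag(3), c(60, 0, 0))
  expect_identical(shape_tanimoto(p, far, align = FALSE), 0)
  small <- sphere_pose("s", 1)
  big <- sphere_pose("b", 2)
  expect_equal(shape_tanimoto(small, big, align = FALSE,
                              settings = volume_settings(grid_spacing = 0.1)),
               0.125, tolerance = 0.01)
})

test_that("aligned shape Tanimoto is rigid-motion invariant and beats unaligned", {
  withr::with_seed(23, {
    ref <- random_pose("ref", n = 10, seed = 1601)
    probe <- random_pose("probe", n = 11, seed = 1602)
    aligned <- shape_tanimoto(ref, probe, align = TRUE)
    expect_gte(aligned + 0.01, shape_tanimoto(ref, probe, align = FALSE))
    for (k in 1:3) {
      moved <- transform_pose(probe, random_rotation(), stats::runif(3, -9, 9))
      expect_equal(shape_tanimoto(ref, moved, align = TRUE), aligned,
                   tolerance = 0.01)
    }
  })
})

test_that("pharmacophore features follow the typing rules", {
  # N-H donor, lone O acceptor, shielded and exposed carbons, charges, ring
  xyz <- rbind(c(0, 0, 0),    # N (donor: H at 1.0)
               c(1, 0, 0),    # H
               c(5, 0, 0),    # O (acceptor only)
               c(6.2, 0, 0),  # C within 2.0 of O -> not hydrophobe
               c(12, 0, 0),   # C isolated -> hydrophobe
               c(20, 0, 0),   # N+ cation
               c(25, 0, 0))   # O- anion
  p <- molecule_pose("m", c("N", "H", "O", "C", "C", "N", "O"), xyz,
                     charge = c(0, 0, 0, 0, 0, 1, -1))
  f <- derive_features(p)
  expect_setequal(f$type[f$x == 0], c("donor", "acceptor"))
  expect_true("acceptor" %in% f$type[f$x == 5])
  expect_false("hydrophobe" %in% f$type[f$x == 6.2])
  expect_true("hydrophobe" %in% f$type[f$x == 12])
  expect_true("cation" %in% f$type[f$x == 20])
  expect_true("anion" %in% f$type[f$x == 25])
  expect_true(all(f$sigma == 1.0))
  # hexagonal ring via the bond block -> centroid feature
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  ring_xyz <- cbind(cos(ang), sin(ang), 0) + 40
  rp <- molecule_pose("ring", rep("C", 6), ring_xyz,
                      bonds = cbind(1:6, c(2:6, 1)))
  rf <- derive_features(rp)
  cent <- rf[rf$type == "ring", c("x", "y", "z")]
  expect_equal(nrow(cent), 1L)
  expect_equal(unlist(cent), colMeans(ring_xyz), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("color Tanimoto scores feature co-location by type", {
  f1 <- feature_points("donor", matrix(c(0, 0, 0), 1, 3))
  f2 <- feature_points("donor", matrix(c(1.5, 0, 0), 1, 3))
  dummy <- sphere_pose("d", 1.7)
  expect_equal(color_tanimoto(dummy, dummy, f1, f1), 1.0)
  # single-pair closed form: o_ab = o_aa * exp(-d^2 / (4 sigma^2))
  k <- exp(-1.5^2 / 4)
  expect_equal(color_tanimoto(dummy, dummy, f1, f2), k / (2 - k),
               tolerance = 1e-9)
  f3 <- feature_points("hydrophobe", matrix(c(0, 0, 0), 1, 3))
  expect_identical(color_tanimoto(dummy, dummy, f1, f3), 0)
  expect_warning(z <- color_tanimoto(dummy, dummy, f1, f1[0, ]), "empty")
  expect_identical(z, 0)
})

test_that("combo ranking is deterministic and groups families together", {
  withr::with_seed(37, {
    ref <- random_pose("ref", n = 12, seed = 1700)
    near <- lapply(1:3, function(k) {
      p <- transform_pose(ref, random_rotation(), stats::runif(3, -5, 5))
      p$id <- sprintf("near%d", k)
      p$xyz <- p$xyz + matrix(stats::rnorm(length(p$xyz), sd = 0.1),
                              nrow(p$xyz))
      p
    })
    unrelated <- lapply(1:3, function(k) {
      p <- random_pose(sprintf("far%d", k), n = 25, seed = 1800 + k, sd = 4)
      transform_pose(p, diag(3), c(30, 0, 0))
    })
    self <- ref; self$id <- "self"
    probes <- c(list(self), near, unrelated)
    rk <- rank_by_combo(ref, probes)
    expect_equal(rk$id[1], "self")
    expect_gte(rk$tc_combo[1], 1.98)
    expect_setequal(rk$id[1:4], c("self", "near1", "near2", "near3"))
    expect_true(all(rk$tc_shape >= 0 & rk$tc_shape <= 1))
    expect_true(all(rk$tc_color >= 0 & rk$tc_color <= 1))
    expect_equal(rk$tc_combo, rk$tc_shape + rk$tc_color)
    rk2 <- rank_by_combo(ref, probes[c(4, 2, 7, 1, 5, 3, 6)])
    expect_equal(rk2$id, rk$id)
    expect_equal(rk2$tc_combo, rk$tc_combo)
  })
})
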