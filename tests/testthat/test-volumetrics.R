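fine_grid <- volume_settings(grid_spacing = 0.15)

test_that("volume settings are validated", {
  expect_error(volume_settings(grid_spacing = 0.01), "grid_spacing")
  expect_error(volume_settings(grid_spacing = 2), "grid_spacing")
  expect_error(volume_settings(mc_samples = 100), "mc_samples")
  p <- sphere_pose("s", 2.0)
  expect_error(union_volume(p, volume_settings(padding = 0.5)), "padding")
})

test_that("grid union volume matches the analytic sphere", {
  p <- sphere_pose("s", 2.0)
  v <- union_volume(p, fine_grid)
  expect_equal(v, sphere_volume(2.0), tolerance = 0.005)
  expect_equal(v, 33.51, tolerance = 0.005)
})

test_that("two overlapping spheres match the closed-form lens oracle", {
  a <- sphere_pose("a", 1.7)
  b <- sphere_pose("b", 1.7, c(1, 0, 0))
  expect_equal(intersection_volume(a, b, fine_grid), lens_volume(1.7, 1.7, 1),
               tolerance = 0.005)
  expect_equal(union_volume(molecule_pose(
    "u", c("X", "X"), rbind(c(0, 0, 0), c(1, 0, 0)),
    radius = c(1.7, 1.7)), fine_grid),
    2 * sphere_volume(1.7) - lens_volume(1.7, 1.7, 1), tolerance = 0.005)
})

test_that("disjoint spheres are additive and intersect exactly nowhere", {
  a <- sphere_pose("a", 1.5)
  b <- sphere_pose("b", 1.5, c(4, 0, 0))
  both <- molecule_pose("ab", c("X", "X"), rbind(c(0, 0, 0), c(4, 0, 0)),
                        radius = 1.5)
  expect_equal(union_volume(both, fine_grid), 2 * sphere_volume(1.5),
               tolerance = 0.005)
  expect_identical(intersection_volume(a, b, fine_grid), 0)   # short-circuit
  expect_identical(overlap_percent(a, b, fine_grid), 0)
})

test_that("self-intersection reproduces the union volume", {
  p <- random_pose("p", n = 8, seed = 21)
  expect_equal(intersection_volume(p, p), union_volume(p), tolerance = 0.01)
})

test_that("containment scores exactly 100 percent", {
  small <- sphere_pose("small", 1)
  big <- sphere_pose("big", 2)
  expect_identical(overlap_percent(small, big), 100)
  expect_identical(overlap_percent(big, small), 100)  # min-normalization
  p <- random_pose("p", n = 6, seed = 4)
  expect_identical(overlap_percent(p, p), 100)
})

test_that("overlap percent is symmetric and bounded", {
  set.seed(31)
  for (k in 1:5) {
    a <- random_pose("a", n = 7, seed = 100 + k)
    b <- random_pose("b", n = 9, seed = 200 + k)
    pab <- overlap_percent(a, b)
    expect_identical(pab, overlap_percent(b, a))
    expect_gte(pab, 0); expect_lte(pab, 100)
  }
})

test_that("union obeys inclusion-exclusion against the combined atom list", {
  a <- random_pose("a", n = 6, seed = 41)
  b <- random_pose("b", n = 6, seed = 42, sd = 1.5)
  v <- poseoverlap:::pair_volumes(a, b, volume_settings())
  merged <- molecule_pose("m", c(a$element, b$element), rbind(a$xyz, b$xyz),
                          radius = c(a$radius, b$radius))
  expect_equal(union_volume(merged),
               v[["va"]] + v[["vb"]] - v[["vint"]], tolerance = 0.01)
})

test_that("overlap percent is invariant under a common rigid transform", {
  withr::with_seed(52, {
    a <- random_pose("a", n = 8, seed = 61)
    b <- random_pose("b", n = 8, seed = 62)
    base <- overlap_percent(a, b)
    for (k in 1:3) {
      R <- random_rotation()
      t <- stats::runif(3, -5, 5)
      moved <- overlap_percent(transform_pose(a, R, t), transform_pose(b, R, t))
      expect_equal(moved, base, tolerance = 0.01 * max(base, 1))
    }
  })
})

test_that("grid error against the analytic sphere shrinks with spacing", {
  p <- sphere_pose("s", 1.7, c(0.123, -0.456, 0.789))
  truth <- sphere_volume(1.7)
  errs <- vapply(c(0.5, 0.3, 0.2, 0.15), function(s)
    abs(union_volume(p, volume_settings(grid_spacing = s)) - truth) / truth,
    numeric(1))
  expect_lt(errs[4], errs[1])
  expect_true(all(diff(errs) < 0.003))  # monotone within discretization noise
  expect_true(all(errs < 0.02))
})

test_that("Monte Carlo estimates are seed-reproducible and track the grid", {
  p <- random_pose("p", n = 10, seed = 71)
  m1 <- union_volume(p, volume_settings("mc", mc_samples = 1e5, seed = 9))
  m2 <- union_volume(p, volume_settings("mc", mc_samples = 1e5, seed = 9))
  m3 <- union_volume(p, volume_settings("mc", mc_samples = 1e5, seed = 10))
  expect_identical(m1, m2)
  expect_false(identical(m1, m3))
  for (k in 1:5) {
    q <- random_pose("q", n = 10, seed = 300 + k)
    g <- union_volume(q, fine_grid)
    m <- union_volume(q, volume_settings("mc", mc_samples = 1e6, seed = k))
    expect_equal(m, g, tolerance = 0.01)
  }
})

test_that("similarity matrices have a forced diagonal, symmetry and bounds", {
  poses <- lapply(1:5, function(k) random_pose(sprintf("p%d", k), n = 6,
                                               seed = 400 + k))
  m <- overlap_matrix(poses)
  v <- as.matrix(m)
  expect_identical(unname(diag(v)), rep(100, 5))
  expect_identical(v, t(v))
  expect_true(all(v >= 0 & v <= 100))
  expect_equal(m$mode, "similarity")
  expect_error(overlap_matrix(poses[c(1, 1)]), "duplicate")
  expect_error(overlap_matrix(poses[1]), "at least 2")
})

test_that("permuting the input poses permutes the matrix and nothing else", {
  poses <- lapply(1:4, function(k) random_pose(sprintf("p%d", k), n = 5,
                                               seed = 500 + k))
  m1 <- as.matrix(overlap_matrix(poses))
  perm <- c(3, 1, 4, 2)
  m2 <- as.matrix(overlap_matrix(poses[perm]))
  expect_identical(m2, m1[perm, perm])
})

test_that("cross matrices agree with the self matrix off the forced diagonal", {
  poses <- lapply(1:4, function(k) random_pose(sprintf("p%d", k), n = 5,
                                               seed = 600 + k))
  sim <- as.matrix(overlap_matrix(poses))
  cross <- as.matrix(cross_overlap_matrix(poses, poses))
  off <- upper.tri(sim) | lower.tri(sim)
  expect_identical(cross[off], sim[off])
})

test_that("a monomer and its dimer docked at disjoint sites never overlap", {
  mono <- random_pose("7x", n = 12, seed = 700)
  dim2 <- make_dimer(mono, center = c(40, 0, 0))
  expect_equal(dim2$id, "7x.2")
  expect_equal(dim2$form, "dimer")
  expect_identical(overlap_percent(mono, dim2), 0)
  cm <- cross_overlap_matrix(list(mono), list(dim2))
  expect_identical(unname(as.matrix(cm)[1, 1]), 0)
})

test_that("pose sets split across two far-apart sites give an all-zero block", {
  near <- lapply(1:3, function(k) random_pose(sprintf("n%d", k), n = 6,
                                              seed = 800 + k))
  far <- lapply(1:3, function(k)
    transform_pose(random_pose(sprintf("f%d", k), n = 6, seed = 900 + k),
                   diag(3), c(50, 0, 0)))
  expect_true(all(as.matrix(cross_overlap_matrix(near, far)) == 0))
})

test_that("normalized volumes scale by the group's largest compound", {
  small <- sphere_pose("small", 1)
  big <- sphere_pose("big", 2, c(10, 0, 0))
  nv <- normalized_volumes(list(small, big), fine_grid)
  expect_equal(nv$vn[nv$id == "big"], 1.0)
  expect_equal(nv$vn[nv$id == "small"], 0.125, tolerance = 0.01)
  expect_error(normalized_volumes(list()), "empty")
})

test_that("the bulkiest pose in the default study is the propidium analog", {
  st <- make_study()
  nv <- normalized_volumes(st$poses)
  expect_equal(nv$id[which.max(nv$vn)], "prm")
  expect_equal(max(nv$vn), 1.0)
})

test_that("overlap matrices serialize with a self-describing header", {
  f <- withr::local_tempfile(fileext = ".csv")
  poses <- lapply(1:3, function(k) random_pose(sprintf("p%d", k), n = 4,
                                               seed = 950 + k))
  write_overlap_csv(overlap_matrix(poses), f)
  lines <- readLines(f)
  expect_match(lines[1], "^# mode=similarity spacing=0.2")
  expect_equal(length(lines), 5L)  # header + column row + 3 data rows
  parsed <- utils::read.csv(f, skip = 1, row.names = 1)
  expect_equal(unname(diag(as.matrix(parsed))), rep(100, 3))
})
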