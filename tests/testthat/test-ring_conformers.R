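test_that("superposition RMSD is zero on identity and rigid transforms", {
  set.seed(3)
  for (rep in 1:8) {
    n <- sample(3:8, 1)
    x <- matrix(stats::rnorm(n * 3, sd = 2), ncol = 3)
    expect_identical(superposition_rmsd(x, x), 0)
    y <- rigid_transform(x, seed = rep)
    expect_lt(superposition_rmsd(x, y), 1e-6)
    expect_lt(superposition_rmsd(y, x), 1e-6)
  }
})

test_that("superposition RMSD matches the rotation-grid oracle", {
  # planar reference case: unit square vs 1x2 rectangle, in-order points
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
  rect <- cbind(c(0, 1, 1, 0), c(0, 0, 2, 2), 0)
  expect_equal(superposition_rmsd(sq, rect), grid_rmsd_oracle(sq, rect),
               tolerance = 1e-3)
  set.seed(17)
  for (rep in 1:4) {
    n <- sample(4:8, 1)
    x <- matrix(stats::rnorm(n * 3), ncol = 3)
    y <- matrix(stats::rnorm(n * 3), ncol = 3)
    expect_equal(superposition_rmsd(x, y), grid_rmsd_oracle(x, y),
                 tolerance = 1e-3, label = sprintf("random pair %d", rep))
  }
})

test_that("superposition RMSD is a pseudometric", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    x <- matrix(stats::rnorm(n * 3), ncol = 3)
    y <- matrix(stats::rnorm(n * 3), ncol = 3)
    z <- matrix(stats::rnorm(n * 3), ncol = 3)
    dxy <- superposition_rmsd(x, y)
    expect_gte(dxy, 0)
    expect_equal(dxy, superposition_rmsd(y, x), tolerance = 1e-9)
    expect_lte(superposition_rmsd(x, z), dxy + superposition_rmsd(y, z) + 1e-9)
  }
  expect_error(superposition_rmsd(matrix(0, 3, 3), matrix(0, 4, 3)), "equal-size")
})

test_that("non-aromatic ring extraction excludes aromatic rings", {
  expect_length(extract_nonaromatic_rings(pg("c1ccccc1")), 0)
  r <- extract_nonaromatic_rings(pg("C1CCCCC1"))
  expect_length(r, 1)
  expect_length(r[[1]], 6)
  # tetralin: one aromatic + one saturated six-ring
  r <- extract_nonaromatic_rings(pg("c1ccc2CCCCc2c1"))
  expect_length(r, 1)
})

test_that("ring fingerprints: f_1 is the zero vector; rigid copies are zero", {
  set.seed(9)
  ring1 <- matrix(stats::rnorm(18), ncol = 3)
  ring2 <- matrix(stats::rnorm(15), ncol = 3)
  m1 <- list(ring1, ring2)
  fps <- ring_fingerprints(list(m1))
  expect_identical(dim(fps), c(1L, 2L))
  expect_equal(as.numeric(fps[1, ]), c(0, 0))
  # models 2..M rigidly transformed copies -> all-zero fingerprints
  models <- list(m1,
                 lapply(m1, rigid_transform, seed = 2),
                 lapply(m1, rigid_transform, seed = 3))
  fps <- ring_fingerprints(models)
  expect_lt(max(fps), 1e-6)
  expect_equal(as.numeric(fps[1, ]), c(0, 0))
})

test_that("medoid selection collapses duplicates and keeps distinct points", {
  fps <- matrix(1.5, nrow = 7, ncol = 2)
  expect_identical(select_ring_medoids(fps, 5), 1L)
  fps <- matrix(c(0, 1, 2), ncol = 1)
  expect_identical(select_ring_medoids(fps, 5), c(1L, 2L, 3L))
})

test_that("medoid selection matches the exhaustive-partition oracle", {
  set.seed(23)
  centers <- c(0, 5, 10)
  x <- matrix(centers[rep(1:3, each = 3)] + stats::rnorm(9, sd = 0.01), ncol = 1)
  got <- select_ring_medoids(x, k_max = 3, seed = 7)
  want <- exhaustive_medoid_oracle(x, 3)
  expect_identical(got, want)
  # one medoid per blob, each inside its blob
  blob <- rep(1:3, each = 3)
  expect_identical(sort(unique(blob[got])), 1:3)
  # 2-D case, 4 blobs of unequal size (10 points)
  x2 <- rbind(matrix(0, 3, 2), matrix(4, 3, 2),
              cbind(8, 0)[rep(1, 2), ], cbind(0, 8)[rep(1, 2), ]) +
        matrix(stats::rnorm(20, sd = 0.01), ncol = 2)
  got2 <- select_ring_medoids(x2, k_max = 4, seed = 7)
  want2 <- exhaustive_medoid_oracle(x2, 4)
  expect_identical(got2, want2)
})

test_that("stub embedding is deterministic and honors the contract", {
  be <- stub_backend()
  g <- pg("CC")
  c1 <- embed_models(g, 3, seed = 5, backend = be)
  c2 <- embed_models(g, 3, seed = 5, backend = be)
  expect_length(c1, 3)
  for (i in 1:3) {
    expect_identical(c1[[i]]$coords, c2[[i]]$coords)
    expect_true(is.finite(c1[[i]]$energy))
  }
  c3 <- embed_models(g, 3, seed = 6, backend = be)
  expect_false(identical(c1[[1]]$coords, c3[[1]]$coords))
})

test_that("six-ring torsion classification separates chair from twist-boat", {
  # ideal chair: alternating +/-55 degrees -> build from standard chair coords
  chair <- ideal_cyclohexane("chair")
  expect_identical(classify_ring_conformation(chair), "chair")
  twist <- ideal_cyclohexane("twist")
  expect_identical(classify_ring_conformation(twist), "twist_boat")
  flat <- cbind(cos(2 * pi * 0:5 / 6), sin(2 * pi * 0:5 / 6), 0)
  expect_identical(classify_ring_conformation(flat), "planar")
})
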