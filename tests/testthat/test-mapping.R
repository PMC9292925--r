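make_map <- function(X, spacing = 5) {
  V <- ncol(X)
  d <- ceiling(V^(1 / 3))
  coords <- lattice_grid(c(d, d, d), spacing)[seq_len(V), , drop = FALSE]
  voxel_map(X, coords, "delta", paste0("s", seq_len(nrow(X))), spacing)
}

# expose the internal lattice enumeration for fixtures
lattice_grid <- function(dims, spacing) {
  as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                        k = seq_len(dims[3]))) * spacing
}

test_that("voxelwise correlation matches the covariance/SD oracle", {
  set.seed(2)
  X <- matrix(rnorm(15), 5, 3)
  scores <- rnorm(5)
  sm <- voxelwise_correlation(make_map(X), scores)
  for (v in 1:3) {
    expect_equal(sm$r[v], oracle_pearson(X[, v], scores)$r, tolerance = 1e-12)
  }
  # self-correlation and antisymmetry
  X2 <- cbind(scores, X)
  sm2 <- voxelwise_correlation(make_map(X2), scores)
  expect_equal(sm2$r[1], 1)
  smn <- voxelwise_correlation(make_map(X2), -scores)
  expect_equal(smn$r, -sm2$r)
})

test_that("constant voxels are flagged with r = 0 and constant scores rejected", {
  X <- cbind(rep(1, 6), rnorm(6))
  sm <- voxelwise_correlation(make_map(X), rnorm(6))
  expect_equal(sm$r[1], 0)
  expect_true(sm$constant_voxels[1])
  expect_false(sm$constant_voxels[2])
  expect_error(voxelwise_correlation(make_map(X), rep(2, 6)), "constant")
})

test_that("a perfectly correlated voxel attains the minimum permutation p", {
  set.seed(3)
  n <- 20
  scores <- rnorm(n)
  X <- cbind(scores, matrix(rnorm(n * 30), n))
  pr <- permutation_correct(make_map(X), scores, n_permutations = 199, seed = 4)
  expect_equal(pr$corrected_p[1], 1 / 200)
  expect_true(all(pr$corrected_p >= 1 / 200 & pr$corrected_p <= 1))
  # monotone: larger |r| never has larger corrected p
  ord <- order(abs(pr$stat_map$r))
  expect_true(all(diff(pr$corrected_p[ord]) <= 1e-12))
})

test_that("jointly relabelling subjects leaves observed r and the null distribution unchanged", {
  set.seed(6)
  n <- 15
  X <- matrix(rnorm(n * 10), n)
  scores <- rnorm(n)
  perm <- sample(n)
  pr1 <- permutation_correct(make_map(X), scores, n_permutations = 999, seed = 7)
  pr2 <- permutation_correct(make_map(X[perm, ]), scores[perm],
                             n_permutations = 999, seed = 7)
  # observed statistics are exactly invariant
  expect_equal(pr1$stat_map$r, pr2$stat_map$r, tolerance = 1e-12)
  # the Monte-Carlo null max is equal in distribution (not element-wise)
  ks <- suppressWarnings(ks.test(pr1$null_max, pr2$null_max))
  expect_gt(ks$p.value, 0.01)
  expect_equal(pr1$critical_r, pr2$critical_r, tolerance = 0.05)
})

test_that("permutation correction is reproducible under a seed and warns when alpha unresolvable", {
  set.seed(8)
  X <- matrix(rnorm(120), 12)
  s <- rnorm(12)
  a <- permutation_correct(make_map(X), s, n_permutations = 99, seed = 5)
  b <- permutation_correct(make_map(X), s, n_permutations = 99, seed = 5)
  expect_identical(a$null_max, b$null_max)
  expect_warning(
    permutation_correct(make_map(X), s, n_permutations = 99, alpha = 0.005, seed = 1),
    "resolve"
  )
})

test_that("cluster extraction matches a flood-fill oracle at 6/18/26 connectivity", {
  # L-shaped supra set plus diagonal-only satellites in a 3x3x3 block
  dims <- c(3, 3, 3)
  coords <- lattice_grid(dims, 5)
  supra_ijk <- rbind(
    c(1, 1, 1), c(2, 1, 1), c(3, 1, 1), c(3, 2, 1), # L in the z=1 plane
    c(2, 2, 2),                                      # diagonal neighbour of the L corner
    c(1, 3, 3)                                       # isolated far corner
  )
  r <- rep(0, nrow(coords))
  key <- apply(coords / 5, 1, paste, collapse = ",")
  sk <- apply(supra_ijk, 1, paste, collapse = ",")
  idx <- match(sk, key)
  r[idx] <- seq(0.5, 0.8, length.out = length(idx))
  sm <- structure(
    list(r = r, band = "delta", score_name = "rt", n_subjects = 10,
         constant_voxels = rep(FALSE, length(r)), coords_mm = coords,
         spacing_mm = 5),
    class = "stat_map"
  )
  for (conn in c(6, 18, 26)) {
    cl <- find_clusters(sm, 0.4, conn)
    oracle <- oracle_flood_fill(supra_ijk, conn)
    expect_equal(nrow(cl), length(unique(oracle)))
    # membership partition matches: compare sorted size multisets and exact sets
    got <- lapply(cl$voxel_ids, sort)
    want <- lapply(split(idx, oracle), sort)
    expect_setequal(
      vapply(got, paste, character(1), collapse = "-"),
      vapply(want, paste, character(1), collapse = "-")
    )
    # every supra voxel in exactly one cluster
    expect_equal(sort(unlist(got)), sort(idx))
  }
})

test_that("cluster summaries report peak and mean statistics", {
  dims <- c(4, 1, 1)
  coords <- lattice_grid(dims, 5)
  r <- c(0.6, -0.5, 0.9, 0.7)
  sm <- structure(
    list(r = r, band = "delta", score_name = "rt", n_subjects = 10,
         constant_voxels = rep(FALSE, 4), coords_mm = coords, spacing_mm = 5),
    class = "stat_map"
  )
  cl <- find_clusters(sm, 0.4, 26)
  # sign homogeneity splits voxel 2 from its positive neighbours
  expect_equal(nrow(cl), 3)
  big <- cl[cl$size == 2, ]
  expect_equal(big$peak_r, 0.9)
  expect_equal(big$mean_r, 0.8)
  expect_equal(big$min_abs_r, 0.7)
  expect_equal(big$peak_x_mm, 15)
  # two supra voxels at opposite corners are always two clusters
  r2 <- c(0.9, 0, 0, 0.8)
  sm2 <- sm; sm2$r <- r2
  expect_equal(nrow(find_clusters(sm2, 0.5, 26)), 2)
  # singleton
  r3 <- c(0, 0.9, 0, 0)
  sm3 <- sm; sm3$r <- r3
  one <- find_clusters(sm3, 0.5, 6)
  expect_equal(one$size, 1)
  expect_equal(one$peak_voxel, 2)
  # empty result allowed
  expect_equal(nrow(find_clusters(sm3, 0.95, 6)), 0)
})

test_that("sphere ROI selects the exact lattice ball", {
  dims <- c(9, 9, 9)
  coords <- lattice_grid(dims, 5)
  set.seed(9)
  X <- matrix(rnorm(4 * nrow(coords)), 4)
  map <- voxel_map(X, coords, "delta", paste0("s", 1:4), 5)
  centre <- c(5, 5, 5) * 5
  roi0 <- sphere_roi(map, centre, 0)
  expect_length(roi0$voxel_ids, 1)
  expect_equal(unname(roi0$values), X[, roi0$voxel_ids])

  roi10 <- sphere_roi(map, centre, 10)
  expect_length(roi10$voxel_ids, 33) # 1 + 6 + 12 + 8 + 6 lattice offsets
  d2 <- colSums((t(coords) - centre)^2)
  expect_setequal(roi10$voxel_ids, which(d2 <= 100 + 1e-9))

  cmap <- voxel_map(matrix(3.5, 4, nrow(coords)), coords, "delta",
                    paste0("s", 1:4), 5)
  expect_equal(unname(sphere_roi(cmap, centre, 10)$values), rep(3.5, 4))

  expect_error(sphere_roi(map, c(1e5, 1e5, 1e5), 10), "empty ROI")
})

test_that("voxel map container validates its inputs", {
  X <- matrix(rnorm(12), 3, 4)
  coords <- lattice_grid(c(4, 1, 1), 5)
  expect_error(voxel_map(X, coords[1:3, ]), "match")
  expect_error(voxel_map(X, coords[c(1, 1, 2, 3), ]), "unique")
  m <- voxel_map(X, coords, "delta")
  expect_error(band_matrix(m, "theta"), "unknown band")
})
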