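test_that("threshold draws are integer-uniform with mean 15 under defaults", {
  cfg <- sim_config(n_subjects = 1, n_trials = 1e5, seed = 3)
  set.seed(11)
  thr <- generate_thresholds(cfg)
  expect_true(all(thr >= 2 & thr <= 28))
  expect_true(all(thr == round(thr)))
  # integer-uniform on [2, 28]: mean 15, var (27^2 - 1)/12
  se <- sqrt((27^2 - 1) / 12 / length(thr))
  expect_lt(abs(mean(thr) - 15), 3 * se)

  deg <- sim_config(n_subjects = 1, n_trials = 50,
                    threshold_low = 10, threshold_high = 10)
  expect_true(all(generate_thresholds(deg) == 10))

  expect_error(sim_config(threshold_low = 1), ">= 2")
  expect_error(sim_config(threshold_low = 9, threshold_high = 5), ">=")
})

test_that("threshold sequences are reproducible under a fixed seed", {
  cfg <- sim_config(n_subjects = 1, n_trials = 20)
  set.seed(99); a <- generate_thresholds(cfg)
  set.seed(99); b <- generate_thresholds(cfg)
  expect_identical(a, b)
})

test_that("deterministic pumping policies behave as specified", {
  set.seed(1)
  s <- simulate_bart_subject(10, 0, rep(30L, 20), "iid")
  expect_equal(s$pumps, rep(10L, 20))
  expect_equal(sum(s$exploded), 0)

  s2 <- simulate_bart_subject(10, 0, rep(5L, 20), "iid")
  expect_equal(s2$pumps, rep(5L, 20))
  expect_equal(sum(s2$exploded), 20)

  s3 <- simulate_bart_subject(8, 0, rep(30L, 10), "adaptive")
  expect_equal(s3$pumps, as.integer(8:17))

  expect_error(simulate_bart_subject(0.5, 1, rep(10L, 5)), "mu")
  expect_error(simulate_bart_subject(5, -1, rep(10L, 5)), "sigma")
  expect_error(simulate_bart_subject(5, 1, integer(0)), "nonempty")
})

test_that("recorded pumps never exceed thresholds; explosions cap at the threshold", {
  set.seed(21)
  for (rep in 1:20) {
    thr <- 2L + sample.int(27L, 20, replace = TRUE) - 1L
    s <- simulate_bart_subject(runif(1, 2, 20), runif(1, 0, 6), thr,
                               sample(c("iid", "adaptive"), 1))
    expect_true(all(s$pumps <= thr))
    expect_true(all(s$pumps[s$exploded] == thr[s$exploded]))
    expect_true(all(s$pumps[!s$exploded] < thr[!s$exploded]))
  }
})

test_that("cohorts are bit-identical under a fixed seed", {
  cfg <- sim_config(n_subjects = 12, grid_dims = c(6, 6, 6),
                    cluster_specs = list(planted_cluster(c(3, 3, 3))),
                    seed = 17)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$sessions, b$sessions)
  expect_identical(a$traits, b$traits)
  expect_identical(a$maps$values, b$maps$values)
})

test_that("containers share subject ordering and ground truth covers all clusters", {
  co <- simulate_cohort(sim_config(n_subjects = 15, seed = 2))
  ids <- co$traits$subject_id
  expect_identical(unique(co$sessions$subject_id), ids)
  expect_identical(co$maps$subject_ids, ids)
  expect_identical(co$ground_truth$latents$subject_id, ids)
  expect_equal(nrow(co$ground_truth$clusters), length(co$config$cluster_specs))
  expect_true(all(co$ground_truth$clusters$n_voxels >= 1))
})

test_that("a noise-free chain yields a perfect latent-behaviour correlation", {
  cl <- planted_cluster(c(4, 4, 4), radius_mm = 0, band = "delta",
                        trait = "extraversion", a = 1, behaviour = "rt", b = 1)
  cfg <- sim_config(
    n_subjects = 40, grid_dims = c(8, 8, 8), cluster_specs = list(cl),
    noise_sds = list(neural = 0, behaviour = 0, voxel = 0, background = 1),
    seed = 5
  )
  co <- simulate_cohort(cfg)
  gt <- co$ground_truth
  expect_equal(cor(gt$latents[[gt$clusters$cluster[1]]], gt$latents$risk_latent), 1)
  pk <- gt$clusters$peak_voxel[1]
  expect_gt(cor(band_matrix(co$maps, "delta")[, pk], gt$latents$risk_latent), 0.99)
})

test_that("planted maps are normalized log densities", {
  co <- simulate_cohort(sim_config(n_subjects = 8, grid_dims = c(6, 6, 6),
                                   cluster_specs = list(), seed = 3))
  expect_true(co$maps$normalized)
  sums <- apply(exp(co$maps$values), c(1, 3), sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-12)
})

test_that("zero loadings give voxel-behaviour correlations matching the null r distribution", {
  set.seed(31)
  n <- 30
  rs <- c()
  for (i in 1:12) {
    co <- simulate_cohort(sim_config(n_subjects = n, grid_dims = c(5, 5, 5),
                                     cluster_specs = list(), smooth_fwhm_mm = 0,
                                     seed = sample.int(1e6, 1)))
    sm <- voxelwise_correlation(co$maps, co$traits$rt, "delta")
    rs <- c(rs, sm$r[seq(1, 125, by = 12)])
  }
  # null r has t-distributed transform: compare via KS on the probability scale
  tt <- rs * sqrt((n - 2) / (1 - rs^2))
  ks <- suppressWarnings(ks.test(pt(tt, n - 2), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("cluster centres outside the grid are rejected", {
  expect_error(
    sim_config(grid_dims = c(4, 4, 4),
               cluster_specs = list(planted_cluster(c(5, 1, 1)))),
    "outside"
  )
  expect_error(planted_cluster(c(1, 1, 1), band = "gamma"), "unknown band")
})

test_that("cohorts round-trip through the plain-text layout", {
  co <- simulate_cohort(sim_config(n_subjects = 6, grid_dims = c(4, 4, 4),
                                   cluster_specs = list(), seed = 9))
  dir <- tempfile("cohort")
  paths <- write_cohort(co, dir)
  sess <- read_bart_sessions(paths$sessions)
  expect_equal(sess$pumps, co$sessions$pumps)
  expect_equal(sess$exploded, co$sessions$exploded)
  traits <- read_traits(paths$traits)
  expect_equal(traits$rt, co$traits$rt, tolerance = 1e-12)
  m <- read_voxel_map(paths$maps)
  expect_equal(m$values, co$maps$values, tolerance = 1e-12)
  expect_identical(m$band_names, co$maps$band_names)
  unlink(dir, recursive = TRUE)
})
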