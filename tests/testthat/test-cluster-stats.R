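test_that("voxel adjacency uses 26-connectivity", {
  ds <- make_toy_fmri(dim = c(3, 3, 3), seed = 40)
  adj <- feature_adjacency(ds)
  corner <- which(ds$fa$i == 1 & ds$fa$j == 1 & ds$fa$k == 1)
  expect_equal(length(adj$neighbors[[corner]]), 8)  # 7 neighbors + itself
  center <- which(ds$fa$i == 2 & ds$fa$j == 2 & ds$fa$k == 2)
  expect_equal(length(adj$neighbors[[center]]), 27)
  # brute-force offsets for the corner
  expected <- which(ds$fa$i <= 2 & ds$fa$j <= 2 & ds$fa$k <= 2)
  expect_identical(adj$neighbors[[corner]], expected)
})

test_that("1-D adjacency connects adjacent bins", {
  gm <- make_group_maps(n_participants = 4, n_features = 5, seed = 41)
  adj <- feature_adjacency(gm)
  expect_identical(adj$neighbors[[1]], 1:2)
  expect_identical(adj$neighbors[[3]], 2:4)
  expect_identical(adj$neighbors[[5]], 4:5)
})

test_that("channel-by-time adjacency is the conjunction of proximities", {
  ds <- make_toy_meeg(seed = 42)
  lay <- load_layout("toy9")
  adj <- feature_adjacency(ds, layout = lay)
  chan_names <- ds$a$fdim$values$chan
  xy <- cbind(lay$x[match(chan_names, lay$channel)],
              lay$y[match(chan_names, lay$channel)])
  for (f in c(1, 20, 45, 90)) {
    d2 <- (xy[ds$fa$chan, 1] - xy[ds$fa$chan[f], 1])^2 +
          (xy[ds$fa$chan, 2] - xy[ds$fa$chan[f], 2])^2
    expected <- which(d2 <= 1.5^2 & abs(ds$fa$time - ds$fa$time[f]) <= 1)
    expect_identical(adj$neighbors[[f]], expected)
  }
  expect_error(feature_adjacency(ds), "layout")
})

test_that("TFCE matches an independent per-threshold loop", {
  gm <- make_group_maps(n_participants = 4, n_features = 30, seed = 43)
  adj <- feature_adjacency(gm)

  expect_identical(tfce_transform(rep(0, 30), adj), rep(0, 30))

  for (s in 1:10) {
    map <- with(list(), {set.seed(50 + s); rnorm(30)})
    got <- tfce_transform(map, adj)
    expect_equal(got, signed_oracle_tfce(map, adj$neighbors),
                 tolerance = 1e-12)
  }

  # monotonicity: scaling a non-negative map up never decreases TFCE
  set.seed(44)
  pos_map <- abs(rnorm(30))
  base <- tfce_transform(pos_map, adj)
  scaled <- tfce_transform(2.5 * pos_map, adj)
  expect_true(all(scaled >= base - 1e-12))

  expect_error(tfce_transform(c(rep(0, 29), Inf), adj), "finite")
})

test_that("TFCE of a constant cluster approaches the closed form", {
  gm <- make_group_maps(n_participants = 4, n_features = 30, seed = 45)
  adj <- feature_adjacency(gm)
  v <- 2
  n <- 10
  map <- rep(c(0, v, 0), c(10, n, 10))
  got <- tfce_transform(map, adj, dh = 0.01)
  inside <- got[11:20]
  closed_form <- sqrt(n) * v^3 / 3
  expect_true(all(abs(inside - closed_form) < sqrt(n) * v^2 * 0.01 * 2))
  expect_true(all(got[c(1:10, 21:30)] == 0))
})

test_that("find_clusters equals a flood-fill oracle", {
  gm <- make_group_maps(n_participants = 4, n_features = 50, seed = 46)
  adj <- feature_adjacency(gm)

  expect_equal(find_clusters(rep(0, 50), 1, adj)$clusters, list())

  two_blobs <- rep(0, 50)
  two_blobs[5:10] <- 3
  two_blobs[20:22] <- 2
  fc <- find_clusters(two_blobs, 1.5, adj)
  expect_equal(length(fc$clusters), 2)
  expect_identical(fc$clusters[[1]], 5:10)
  expect_equal(fc$mass, c(18, 6))

  for (trial in 1:100) {
    set.seed(trial)
    map <- rnorm(50)
    thr <- runif(1, -1, 1.5)
    got <- find_clusters(map, thr, adj)
    expected <- oracle_clusters(map, thr, adj$neighbors)
    expect_identical(got$clusters, expected)
  }
})

test_that("montecarlo cluster stat is deterministic and well-behaved", {
  gm <- make_group_maps(n_participants = 10, n_features = 40,
                        true_effect = rep(c(0, 1.3, 0), c(15, 10, 15)),
                        seed = 47)
  adj <- feature_adjacency(gm)
  opt <- list(niter = 100, h0_mean = 0, tails = 1, seed = 7)
  r1 <- montecarlo_cluster_stat(gm, adj, opt)
  r2 <- montecarlo_cluster_stat(gm, adj, opt)
  expect_identical(r1$null_max, r2$null_max)
  expect_identical(r1$z$samples, r2$z$samples)
  expect_equal(length(r1$null_max), 100)
  expect_true(all(r1$p >= 1 / 101 & r1$p <= 1))
  expect_true(all(is.finite(r1$z$samples)))
  # strongest evidence inside the planted plateau
  expect_true(which.max(r1$z$samples[1, ]) %in% 16:25)

  r3 <- montecarlo_cluster_stat(gm, adj,
                                list(niter = 100, tails = 1, seed = 8))
  expect_false(identical(r1$null_max, r3$null_max))
})

test_that("degenerate group maps give z = 0 everywhere", {
  gm <- make_group_maps(n_participants = 5, n_features = 10,
                        noise_sd = 0, true_effect = 0.3, seed = 48)
  adj <- feature_adjacency(gm)
  res <- montecarlo_cluster_stat(gm, adj, list(niter = 50, h0_mean = 0.3,
                                               seed = 1))
  expect_true(all(res$z$samples == 0))
})

test_that("fixed-threshold cluster correction and null sampling work", {
  gm <- make_group_maps(n_participants = 12, n_features = 40,
                        true_effect = rep(c(0, 1.5, 0), c(15, 10, 15)),
                        seed = 49)
  adj <- feature_adjacency(gm)
  res <- montecarlo_cluster_stat(
    gm, adj, list(niter = 100, tails = 1, seed = 2,
                  cluster_stat = list(type = "fixed", threshold = 2)))
  expect_true(max(res$z$samples[1, 16:25]) >
                max(res$z$samples[1, c(1:10, 31:40)]))

  null_maps <- lapply(seq_len(12), function(p) {
    set.seed(900 + p)
    matrix(rnorm(20 * 40), 20, 40)
  })
  res_nm <- montecarlo_cluster_stat(
    gm, adj, list(niter = 100, tails = 1, seed = 3,
                  method = "null_map_sampling", null_maps = null_maps))
  expect_equal(length(res_nm$null_max), 100)
  expect_true(max(res_nm$z$samples[1, 16:25]) > 1.645)

  expect_error(montecarlo_cluster_stat(
    gm, adj, list(niter = 100, method = "null_map_sampling")),
    "null map")
  expect_error(montecarlo_cluster_stat(gm, adj, list(niter = 0)),
               "niter")
})

test_that("montecarlo errors on single participants and bad input", {
  gm <- make_group_maps(n_participants = 1, n_features = 10, seed = 50)
  adj <- feature_adjacency(gm)
  expect_error(montecarlo_cluster_stat(gm, adj, list(niter = 10)),
               "participants")
})
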