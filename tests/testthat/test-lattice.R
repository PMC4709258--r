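test_that("labeling probabilities are honored in the degenerate cases", {
  none <- label_lattice(c(8, 8), c(0, 0, 0), seed = 1)
  expect_true(all(none$color == 0))

  all_one <- label_lattice(c(8, 8), 1, seed = 1)
  expect_true(all(all_one$color == 1))
  expect_equal(nrow(same_color_clusters(all_one)$clusters), 1)

  expect_error(label_lattice(c(8, 8), c(0.6, 0.6)), "sum")
  expect_error(label_lattice(c(8, 8), -0.1), "non-negative")
})

test_that("empirical labeled fraction converges to the labeling probability", {
  coloring <- label_lattice(c(1000, 1000), 0.17, seed = 3)
  frac <- mean(coloring$color == 1)
  expect_lt(abs(frac - 0.17), 4 * sqrt(0.17 * 0.83 / 1e6))
})

test_that("hand-built colorings cluster as expected", {
  m <- matrix(0L, 10, 10)
  m[5, 5] <- 1L
  m[5, 6] <- 1L # axial neighbors
  cl <- same_color_clusters(make_coloring(m))
  expect_equal(cl$clusters$size, 2L)

  m2 <- matrix(0L, 10, 10)
  m2[1, 1] <- 1L
  m2[10, 10] <- 1L
  cl2 <- same_color_clusters(make_coloring(m2, boundary = "open"))
  expect_equal(sort(cl2$clusters$size), c(1L, 1L))
  expect_equal(nrow(cl2$clusters), 2)

  # adjacent but differently colored sites stay separate
  m3 <- matrix(0L, 5, 5)
  m3[3, 3] <- 1L
  m3[3, 4] <- 2L
  cl3 <- same_color_clusters(make_coloring(m3, n_colors = 2))
  expect_equal(nrow(cl3$clusters), 2)
})

test_that("neighbor pairs match literal triangular-lattice geometry", {
  pairs <- clonedyn:::tri_neighbor_pairs(c(5, 7), "open")
  coords <- cbind(
    x = as.vector(col(matrix(0, 5, 7))) + as.vector(row(matrix(0, 5, 7))) / 2,
    y = as.vector(row(matrix(0, 5, 7))) * sqrt(3) / 2
  )
  geo <- which(
    abs(as.matrix(dist(coords)) - 1) < 1e-9 &
      upper.tri(matrix(0, 35, 35)),
    arr.ind = TRUE
  )
  norm <- function(m) {
    m2 <- cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
    unname(m2[order(m2[, 1], m2[, 2]), ])
  }
  expect_equal(norm(pairs), norm(geo))
  expect_false(any(duplicated(norm(pairs))))
  # every interior site of a periodic lattice has exactly 6 neighbors
  per <- clonedyn:::tri_neighbor_pairs(c(8, 8), "periodic")
  expect_equal(unname(tabulate(c(per), 64)), rep(6L, 64))
})

test_that("components agree with an exhaustive flood-fill oracle on 3x3", {
  for (bits in 0:511) {
    m <- matrix(as.integer(intToBits(bits)[1:9]), 3, 3)
    cl <- same_color_clusters(make_coloring(m, boundary = "open"))
    oracle <- geometry_components(m)
    expect_equal(nrow(cl$clusters), oracle$n)
    expect_equal(sort(cl$clusters$size), oracle$sizes)
  }
})

test_that("clusters partition the labeled sites", {
  for (seed in 1:5) {
    coloring <- label_lattice(c(30, 30), c(0.15, 0.15, 0.15), seed = seed)
    cl <- same_color_clusters(coloring)
    expect_equal(sum(cl$clusters$size), sum(coloring$color != 0))
    # membership only on labeled sites, and color-homogeneous
    expect_true(all(is.na(cl$membership[coloring$color == 0])))
    for (k in cl$clusters$cluster) {
      expect_equal(length(unique(coloring$color[which(cl$membership == k)])), 1)
    }
  }
})

test_that("merging factor approaches 1 for sparse labeling and grows with density", {
  sparse <- merging_factor(0.004, dims = c(64, 64), n_replicates = 30, seed = 2)
  expect_lt(abs(sparse$estimate - 1), 0.05)
  expect_gte(sparse$estimate, 1)

  sweep <- merging_sweep(c(0.05, 0.10, 0.15, 0.20), dims = c(96, 96),
                         n_replicates = 15, seed = 4)
  expect_true(all(diff(sweep$estimate) > 0))
})

test_that("open and periodic boundaries agree on large lattices", {
  a <- merging_factor(rep(0.17, 3), dims = c(96, 96), n_replicates = 25,
                      boundary = "periodic", seed = 5)
  b <- merging_factor(rep(0.17, 3), dims = c(96, 96), n_replicates = 25,
                      boundary = "open", seed = 6)
  # CIs overlap (open boundary is slightly depressed by edge sites)
  expect_lt(b$conf.low, a$conf.high + 0.05)
  expect_gt(b$conf.high + 0.05, a$conf.low)
})

test_that("fragmentation/merging balance flags near-cancellation", {
  bal <- fragmentation_merging_balance(2.6, 2.6)
  expect_equal(bal$ratio, 1)
  expect_true(bal$balanced)

  bal2 <- fragmentation_merging_balance(2.6, 2.75)
  expect_equal(bal2$ratio, 2.6 / 2.75, tolerance = 1e-12)
  expect_true(bal2$balanced)

  bal3 <- fragmentation_merging_balance(2.6, 5.2)
  expect_equal(bal3$ratio, 0.5)
  expect_false(bal3$balanced)
})
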