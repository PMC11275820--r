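test_that("affinity follows the clipped reciprocal-square-distance law", {
  lay <- channel_layout(c("a", "b", "c"),
                        rbind(c(0, 0, 0), c(sqrt(6), 0, 0), c(10, 0, 0)))
  aff <- channel_affinity(lay, theta = 6)
  expect_equal(aff["a", "b"], 1)            # distance sqrt(theta): clip boundary
  expect_equal(aff["a", "c"], 6 / 100)
  expect_equal(diag(aff), setNames(rep(0, 3), c("a", "b", "c")))
  expect_equal(aff, t(aff))

  # doubling coordinates divides unclipped affinities by 4 (pairwise oracle)
  set.seed(1)
  coords <- matrix(runif(15, 0, 10), 5, 3)
  lay1 <- channel_layout(letters[1:5], coords)
  lay2 <- channel_layout(letters[1:5], coords * 2)
  a1 <- channel_affinity(lay1, 2)
  a2 <- channel_affinity(lay2, 2)
  for (i in 1:5) for (j in 1:5) {
    if (i == j) next
    d2 <- sum((coords[i, ] - coords[j, ])^2)  # brute-force pairwise distance
    if (2 / d2 < 1 && 2 / (4 * d2) < 1) {
      expect_equal(a2[i, j], a1[i, j] / 4)
    }
  }

  expect_error(channel_layout(c("a", "b"), rbind(c(1, 1, 1), c(1, 1, 1))),
               "identical coordinates")
})

test_that("base adjacency keeps edges at the threshold boundary", {
  aff <- matrix(c(0, 0.1, 0.05,
                  0.1, 0, 0.9,
                  0.05, 0.9, 0), 3, 3, byrow = TRUE)
  adj <- base_adjacency(aff, delta = 0.1)
  expect_equal(adj[1, 2], 1L)  # >= , not >
  expect_equal(adj[1, 3], 0L)
  expect_equal(adj[2, 3], 1L)

  full <- base_adjacency(matrix(0.5, 4, 4), delta = 0.1)
  expect_equal(sum(full), 12)
  expect_error(base_adjacency(aff, delta = 1.2), "0, 1")
})

test_that("GC augmentation prunes and orients but never adds", {
  set.seed(2)
  base <- matrix(1L, 4, 4) - diag(1L, 4)
  sp <- var_spec(4, 1, coupling = data.frame(source = 1, target = 2,
                                             lag = 1, coefficient = 0.7),
                 seed = 3)
  x <- simulate_var(sp, 2000)
  gm <- granger_matrix(x, lag_order = 1)
  aug <- augment_adjacency(base, gm)
  expect_equal(aug[2, 1], 1L)            # row = receiver
  expect_lte(sum(aug) - aug[2, 1], 1)    # at most one spurious edge
  expect_lte(sum(aug), sum(base))        # monotone pruning

  # no gate passes -> zero matrix
  gm0 <- gm
  gm0$significant <- FALSE
  expect_equal(sum(augment_adjacency(base, gm0)), 0)

  # all gates pass -> augmentation equals the base graph
  gm1 <- gm
  gm1$significant <- TRUE
  expect_equal(unname(augment_adjacency(base, gm1)), unname(base) * 1L)

  # raw mode keeps gc_value > 0 edges
  raw <- augment_adjacency(base, gm, gate = "raw")
  expect_gte(sum(raw), sum(aug))
})

test_that("degenerate GC rows drop their edges with a warning", {
  base <- matrix(1L, 3, 3) - diag(1L, 3)
  X <- cbind(rnorm(100), rep(1, 100), rnorm(100))
  suppressWarnings(gm <- granger_matrix(X, lag_order = 1))
  expect_warning(aug <- augment_adjacency(base, gm), "Degenerate")
  expect_equal(sum(aug[, 2]) + sum(aug[2, ]), 0)
})

test_that("degree flow balances and ranks sources and sinks", {
  sym <- matrix(1L, 4, 4) - diag(1L, 4)
  expect_true(all(degree_flow(sym)$flow == 0))

  # star: hub (channel 1) sends to all 5 leaves; A[leaf, hub] = 1
  star <- matrix(0L, 6, 6)
  star[2:6, 1] <- 1L
  df <- degree_flow(star, k = 2)
  expect_equal(df$flow[1], 5L)
  expect_true(all(df$flow[2:6] == -1L))
  expect_equal(df$rank_source[1], 1L)

  set.seed(3)
  for (rep in 1:10) {
    A <- matrix(rbinom(49, 1, 0.4), 7, 7)
    diag(A) <- 0
    df <- degree_flow(A)
    # brute-force row/column sums
    expect_equal(df$out_degree, as.integer(colSums(A)))
    expect_equal(df$in_degree, as.integer(rowSums(A)))
    expect_equal(sum(df$flow), 0)
  }
})

test_that("the bundled synthetic montage loads as a valid layout", {
  path <- system.file("extdata", "synthetic_ring32_layout.csv",
                      package = "grangercl")
  lay <- read_channel_layout(path)
  expect_equal(nrow(lay), 32)
  aff <- channel_affinity(lay)
  expect_true(all(aff >= 0 & aff <= 1))
  expect_gt(sum(base_adjacency(aff)), 0)
})

test_that("channel graphs round-trip layouts and export edge lists", {
  lay <- ring_layout(4, radius = 3)  # neighbours within the affinity gate
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(lay, path, row.names = FALSE)
  expect_equal(read_channel_layout(path), lay)

  sp <- var_spec(4, 1, coupling = data.frame(source = 1, target = 2,
                                             lag = 1, coefficient = 0.7),
                 seed = 4)
  x <- simulate_var(sp, 1500)
  colnames(x) <- lay$name
  gm <- granger_matrix(x, lag_order = 1)
  g <- channel_graph(lay, gc = gm)
  edges <- gc_edge_list(g)
  expect_true(all(c("source", "target", "gc_value", "p_value") %in%
                    names(edges)))
  expect_equal(nrow(edges), sum(g$gc_adjacency))
  expect_true(paste("ch1", "ch2") %in% paste(edges$source, edges$target))
})
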