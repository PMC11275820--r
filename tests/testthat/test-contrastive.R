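test_that("cosine similarity matches the explicit dot/norm oracle", {
  expect_equal(cosine_sim(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_sim(c(1, 0), c(0, 1)), 0)
  set.seed(1)
  for (rep in 1:10) {
    a <- rnorm(6)
    b <- rnorm(6)
    oracle <- sum(a * b) / (sqrt(sum(a * a)) * sqrt(sum(b * b)))
    expect_equal(cosine_sim(a, b), oracle, tolerance = 1e-12)
    expect_lte(abs(cosine_sim(a, b)), 1 + 1e-12)
  }
  expect_error(cosine_sim(c(0, 0), c(1, 1)), "zero")
})

test_that("InfoNCE matches closed forms and stays finite", {
  expect_equal(info_nce(1, list(rep(0, 30)), temperature = 0.1),
               log(1 + 30 * exp(-10)))
  expect_equal(info_nce(0.5, list(c(0.5, 0.5)), temperature = 0.1), log(3))
  expect_equal(info_nce(1, list(numeric())), 0)  # empty negative set

  # monotone decreasing in the positive similarity on a grid
  grid <- seq(-1, 1, by = 0.1)
  losses <- vapply(grid, function(sp) info_nce(sp, list(rep(0.2, 5)), 0.1),
                   numeric(1))
  expect_true(all(diff(losses) < 0))

  # stability at extreme similarities and small temperature
  expect_true(is.finite(info_nce(1, list(rep(-1, 50)), 1e-3)))
  expect_true(is.finite(info_nce(-1, list(rep(1, 50)), 1e-3)))

  # permuting negatives leaves the loss unchanged
  negs <- rnorm(8)
  expect_equal(info_nce(0.3, list(negs), 0.1),
               info_nce(0.3, list(sample(negs)), 0.1))
})

test_that("total loss is the unweighted sum and composes", {
  expect_equal(total_loss(0, 0), 0)
  expect_equal(total_loss(1.5, 2.5), 4)
  l_s <- info_nce(0.8, list(c(0.1, 0.2)))
  l_t <- info_nce(0.6, list(c(0.3)))
  expect_equal(total_loss(l_s, l_t), l_s + l_t)
})

test_that("spatial pair sampling respects video and subject structure", {
  meta <- tidyr::expand_grid(subject = 1:2, video = 1:2, window = 1:3)
  meta$segment_id <- seq_len(nrow(meta))
  meta$class <- meta$video
  pairs <- sample_spatial_pairs(meta, n_negatives = 3, seed = 1)
  expect_equal(nrow(pairs), nrow(meta))  # every anchor has its single match
  for (i in seq_len(nrow(pairs))) {
    a <- meta[meta$segment_id == pairs$anchor[i], ]
    p <- meta[meta$segment_id == pairs$positive[i], ]
    expect_false(a$subject == p$subject)
    expect_equal(a$video, p$video)
    expect_equal(a$window, p$window)
    nvid <- meta$video[match(pairs$negatives[[i]], meta$segment_id)]
    expect_true(all(nvid != a$video))
  }
  expect_identical(pairs, sample_spatial_pairs(meta, n_negatives = 3,
                                               seed = 1))
  expect_false(identical(pairs$positive,
                         sample_spatial_pairs(meta, n_negatives = 3,
                                              seed = 2)$positive) &&
                 identical(pairs$negatives,
                           sample_spatial_pairs(meta, n_negatives = 3,
                                                seed = 2)$negatives))
})

test_that("negatives never share the anchor's video over many draws", {
  meta <- tidyr::expand_grid(subject = 1:3, video = 1:4, window = 1:2)
  meta$segment_id <- seq_len(nrow(meta))
  for (s in 1:25) {
    pairs <- sample_spatial_pairs(meta, n_negatives = 5, seed = s)
    anchors_video <- meta$video[match(pairs$anchor, meta$segment_id)]
    for (i in seq_len(nrow(pairs))) {
      nvid <- meta$video[match(pairs$negatives[[i]], meta$segment_id)]
      expect_true(all(nvid != anchors_video[i]))
    }
  }
})

test_that("videos without a cross-subject match are skipped with a warning", {
  meta <- tibble::tibble(subject = c(1, 1, 2), video = c(1, 2, 1),
                         window = 1, segment_id = 1:3)
  expect_warning(pairs <- sample_spatial_pairs(meta, seed = 1), "skipped")
  expect_true(all(meta$video[match(pairs$anchor, meta$segment_id)] == 1))
})

test_that("embedding-level InfoNCE gradient matches finite differences", {
  set.seed(9)
  Z <- matrix(rnorm(24), 6, 4)
  prs <- list(anchor = c(1L, 2L), positive = c(4L, 5L),
              negatives = list(c(3L, 6L), c(3L, 6L, 1L)))
  res <- grangercl:::info_nce_embed(Z, prs, 0.1)
  eps <- 1e-6
  for (i in 1:6) {
    for (j in 1:4) {
      Zp <- Z; Zp[i, j] <- Zp[i, j] + eps
      Zm <- Z; Zm[i, j] <- Zm[i, j] - eps
      num <- (grangercl:::info_nce_embed(Zp, prs, 0.1)$loss -
                grangercl:::info_nce_embed(Zm, prs, 0.1)$loss) / (2 * eps)
      expect_equal(res$dZ[i, j], num, tolerance = 1e-6)
    }
  }
})
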