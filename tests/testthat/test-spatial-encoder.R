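test_that("graph convolution matches hand-computable cases and the edge oracle", {
  X <- matrix(abs(rnorm(12)), 4, 3)
  W <- diag(3)
  A0 <- matrix(0L, 4, 4)
  expect_equal(gcn_layer(X, A0, W), X)  # self-loop only, identity mix

  Afull <- matrix(1L, 4, 4) - diag(1L, 4)
  Xc <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  out <- gcn_layer(Xc, Afull, W)
  expect_equal(out, Xc)  # averaging preserves constants

  set.seed(1)
  for (rep in 1:5) {
    C <- sample(3:6, 1)
    A <- matrix(rbinom(C * C, 1, 0.5), C, C)
    diag(A) <- 0
    Xr <- matrix(rnorm(C * 4), C, 4)
    Wr <- matrix(rnorm(8), 4, 2)
    expect_equal(gcn_layer(Xr, A, Wr), oracle_gcn_layer(Xr, A, Wr),
                 tolerance = 1e-6)
  }
})

test_that("zeroed block weights make every residual block the identity", {
  cfg <- spatial_encoder_config(n_blocks = 4, hidden_dim = 6, embed_dim = 4,
                                seed = 2)
  W <- init_spatial_encoder(cfg, in_dim = 10)
  for (b in seq_along(W$blocks)) {
    for (l in seq_along(W$blocks[[b]])) W$blocks[[b]][[l]][] <- 0
  }
  A <- matrix(rbinom(25, 1, 0.4), 5, 5)
  diag(A) <- 0
  X <- matrix(rnorm(50), 5, 10)
  fw <- grangercl:::resgcn_sample_forward(W, X, grangercl:::norm_propagation(A))
  stem_out <- gcn_layer(X, A, W$stem$W)
  for (b in seq_along(W$blocks)) {
    block_out <- fw$concat[, ((b - 1) * 6 + 1):(b * 6)]
    expect_equal(block_out, stem_out)  # identity composed across blocks
  }
})

test_that("node permutations leave the pooled representation unchanged", {
  cfg <- spatial_encoder_config(n_blocks = 3, hidden_dim = 8, embed_dim = 6,
                                seed = 3)
  W <- init_spatial_encoder(cfg, in_dim = 12)
  set.seed(4)
  A <- matrix(rbinom(36, 1, 0.5), 6, 6)
  diag(A) <- 0
  X <- matrix(rnorm(72), 6, 12)
  perm <- sample(6)
  g1 <- grangercl:::resgcn_sample_forward(W, X,
                                          grangercl:::norm_propagation(A))$g
  g2 <- grangercl:::resgcn_sample_forward(
    W, X[perm, ], grangercl:::norm_propagation(A[perm, perm]))$g
  expect_equal(g1, g2, tolerance = 1e-10)
})

test_that("forward pass is deterministic and batch-norm modes differ", {
  cfg <- spatial_encoder_config(n_blocks = 2, hidden_dim = 5, embed_dim = 4,
                                seed = 5)
  W <- init_spatial_encoder(cfg, in_dim = 8)
  bn <- grangercl:::init_bn_state(cfg)
  X <- array(rnorm(3 * 4 * 8), dim = c(3, 4, 8))
  A <- matrix(rbinom(16, 1, 0.5), 4, 4)
  diag(A) <- 0
  f1 <- spatial_forward(W, X, A, cfg, bn, train = TRUE)
  f2 <- spatial_forward(W, X, A, cfg, bn, train = TRUE)
  expect_identical(f1$z, f2$z)
  expect_equal(ncol(f1$z), 4)  # embedding dimension contract

  expect_warning(spatial_forward(W, X[1, , , drop = FALSE], A, cfg, bn,
                                 train = TRUE),
                 "size 1")
})

test_that("analytic gradients match finite differences", {
  cfg <- spatial_encoder_config(n_blocks = 2, hidden_dim = 5, embed_dim = 4,
                                seed = 9)
  W <- init_spatial_encoder(cfg, in_dim = 6)
  bn <- grangercl:::init_bn_state(cfg)
  set.seed(42)
  X <- array(rnorm(3 * 4 * 6), dim = c(3, 4, 6))
  A <- matrix(rbinom(16, 1, 0.5), 4, 4)
  diag(A) <- 0
  R <- matrix(rnorm(12), 3, 4)
  lossfun <- function(W) {
    sum(spatial_forward(W, X, A, cfg, bn, train = TRUE)$z * R)
  }
  fw <- spatial_forward(W, X, A, cfg, bn, train = TRUE)
  gr <- spatial_backward(W, fw$cache, R, cfg)
  flatW <- grangercl:::flatten_params(W)
  flatG <- grangercl:::flatten_params(gr)
  eps <- 1e-6
  for (nm in names(flatW)) {
    ks <- sample(length(flatW[[nm]]), min(2, length(flatW[[nm]])))
    for (k in ks) {
      Wp <- flatW; Wp[[nm]][k] <- Wp[[nm]][k] + eps
      Wm <- flatW; Wm[[nm]][k] <- Wm[[nm]][k] - eps
      num <- (lossfun(grangercl:::unflatten_params(Wp, W)) -
                lossfun(grangercl:::unflatten_params(Wm, W))) / (2 * eps)
      expect_equal(flatG[[nm]][k], num, tolerance = 1e-4)
    }
  }
})
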