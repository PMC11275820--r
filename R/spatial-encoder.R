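# Residual GCN spatial encoder. Node features are each electrode's raw
# baseline-corrected 1 s series; propagation is row-normalised by the
# in-degree of (A + I) so a node aggregates from its GC-parents under the
# row-receiver orientation. Nine residual blocks of two GCN layers, a 1x1
# convolution fusing all block outputs, max pooling over nodes, and a
# three-stage 1x1-conv + batch-norm projection head. Forward and backward
# passes are explicit so training has no external autodiff dependency.

#' Spatial encoder configuration
#'
#' @param n_blocks Residual blocks (default 9), each holding
#'   `layers_per_block` graph-convolution layers.
#' @param layers_per_block GCN layers per block (default 2).
#' @param hidden_dim Node feature width inside the blocks.
#' @param embed_dim Output embedding dimension F_e.
#' @param seed Seed for weight initialisation.
#' @return List of class `spatial_encoder_config`.
#' @export
spatial_encoder_config <- function(n_blocks = 9, layers_per_block = 2,
                                   hidden_dim = 64, embed_dim = 128,
                                   seed = 1L) {
  structure(list(n_blocks = check_positive_int(n_blocks, "n_blocks"),
                 layers_per_block = check_positive_int(layers_per_block,
                                                       "layers_per_block"),
                 hidden_dim = check_positive_int(hidden_dim, "hidden_dim"),
                 embed_dim = check_positive_int(embed_dim, "embed_dim"),
                 seed = as.integer(seed)),
            class = "spatial_encoder_config")
}

#' Initialise spatial encoder weights
#'
#' @param config A [spatial_encoder_config()].
#' @param in_dim Node feature length (the segment length L).
#' @return Nested list of weight arrays (`stem`, `blocks`, `mix`, projector
#'   stages with batch-norm parameters and running statistics).
#' @export
init_spatial_encoder <- function(config, in_dim) {
  h <- config$hidden_dim
  fe <- config$embed_dim
  local_seed(config$seed, {
    blocks <- lapply(seq_len(config$n_blocks), function(b) {
      ws <- lapply(seq_len(config$layers_per_block), function(l) init_matrix(h, h))
      names(ws) <- paste0("W", seq_along(ws))
      ws
    })
    names(blocks) <- paste0("b", seq_len(config$n_blocks))
    list(
      stem = list(W = init_matrix(in_dim, h)),
      blocks = blocks,
      mix = list(W = init_matrix(config$n_blocks * h, h)),
      proj = list(
        W1 = init_matrix(h, h), g1 = rep(1, h), b1 = rep(0, h),
        W2 = init_matrix(h, h), g2 = rep(1, h), b2 = rep(0, h),
        W3 = init_matrix(h, fe), g3 = rep(1, fe), b3 = rep(0, fe))
    )
  })
}

# Fresh batch-norm running statistics for the projector (state, not weights).
init_bn_state <- function(config) {
  h <- config$hidden_dim
  fe <- config$embed_dim
  list(mean1 = rep(0, h), var1 = rep(1, h),
       mean2 = rep(0, h), var2 = rep(1, h),
       mean3 = rep(0, fe), var3 = rep(1, fe))
}

# Row-normalised propagation matrix D_in^-1 (A + I); A's row i lists the
# parents of node i, so rowSums give in-degrees (>= 1 after the self-loop).
norm_propagation <- function(adjacency) {
  A <- (adjacency != 0) * 1
  diag(A) <- diag(A) + 1
  A / rowSums(A)
}

#' One graph-convolution layer
#'
#' Computes `activation(D_in^-1 (A + I) X W)`: features are averaged over
#' each node's GC-parents (self-loop included) and mixed by `W`.
#'
#' @param features Node features `[C x F_in]`.
#' @param adjacency Binary directed adjacency `[C x C]` (row = receiver).
#' @param weights Weight matrix `[F_in x F_out]`.
#' @param activation Function applied elementwise (default ReLU).
#' @return Features `[C x F_out]`.
#' @export
gcn_layer <- function(features, adjacency, weights, activation = relu) {
  activation(norm_propagation(adjacency) %*% features %*% weights)
}

# Forward pass of stem + residual blocks + fusion for ONE sample.
# Returns fused vector g and caches for backprop.
resgcn_sample_forward <- function(weights, X, Nhat) {
  A0 <- Nhat %*% X                    # pre-weight aggregate for the stem
  H <- relu(A0 %*% weights$stem$W)
  block_caches <- vector("list", length(weights$blocks))
  block_outputs <- vector("list", length(weights$blocks))
  for (b in seq_along(weights$blocks)) {
    Hin <- H
    layer_caches <- vector("list", length(weights$blocks[[b]]))
    Hl <- Hin
    for (l in seq_along(weights$blocks[[b]])) {
      Al <- Nhat %*% Hl
      Ml <- Al %*% weights$blocks[[b]][[l]]
      Hl <- relu(Ml)
      layer_caches[[l]] <- list(A = Al, M = Ml)
    }
    H <- Hl + Hin                      # residual connection
    block_caches[[b]] <- layer_caches
    block_outputs[[b]] <- H
  }
  concat <- do.call(cbind, block_outputs)
  fused <- concat %*% weights$mix$W    # [C x h]
  argmax <- max.col(t(fused), ties.method = "first")  # per column, first max row
  g <- fused[cbind(argmax, seq_len(ncol(fused)))]
  list(g = g, argmax = argmax, concat = concat, A0 = A0,
       block_caches = block_caches)
}

# Backward through fusion + blocks + stem for one sample, accumulating into
# `grads` (same shape as weights). Returns updated grads.
resgcn_sample_backward <- function(weights, cache, Nhat, dg, grads) {
  C <- nrow(cache$A0)
  h <- length(dg)
  dFused <- matrix(0, C, h)
  dFused[cbind(cache$argmax, seq_len(h))] <- dg
  grads$mix$W <- grads$mix$W + crossprod(cache$concat, dFused)
  dConcat <- dFused %*% t(weights$mix$W)
  nb <- length(weights$blocks)
  dH <- matrix(0, C, h)  # gradient flowing into the output of block nb
  tN <- t(Nhat)
  for (b in rev(seq_len(nb))) {
    dH <- dH + dConcat[, ((b - 1) * h + 1):(b * h), drop = FALSE]
    dHl <- dH          # into the block's last layer output
    for (l in rev(seq_along(weights$blocks[[b]]))) {
      ca <- cache$block_caches[[b]][[l]]
      dM <- dHl * (ca$M > 0)
      grads$blocks[[b]][[l]] <- grads$blocks[[b]][[l]] + crossprod(ca$A, dM)
      dHl <- tN %*% (dM %*% t(weights$blocks[[b]][[l]]))
    }
    dH <- dH + dHl      # residual path into the block input
  }
  # stem: H0 = relu(A0 W_stem); dH is gradient at H0
  M0 <- cache$A0 %*% weights$stem$W
  dM0 <- dH * (M0 > 0)
  grads$stem$W <- grads$stem$W + crossprod(cache$A0, dM0)
  grads
}

bn_forward <- function(x, gamma, beta, run_mean, run_var, train,
                       momentum = 0.1, eps = 1e-5) {
  if (train) {
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2, mu)^2)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean
    v <- run_var
  }
  xhat <- sweep(sweep(x, 2, mu), 2, sqrt(v + eps), "/")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = out, xhat = xhat, mu = mu, v = v, eps = eps,
       run_mean = run_mean, run_var = run_var, train = train)
}

bn_backward <- function(cache, dout, gamma) {
  B <- nrow(dout)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, gamma, "*")
  inv_sd <- 1 / sqrt(cache$v + cache$eps)
  if (cache$train) {
    dx <- sweep(
      dxhat - matrix(colMeans(dxhat), B, ncol(dout), byrow = TRUE) -
        cache$xhat * matrix(colMeans(dxhat * cache$xhat), B, ncol(dout),
                            byrow = TRUE),
      2, inv_sd, "*")
  } else {
    dx <- sweep(dxhat, 2, inv_sd, "*")
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

#' Spatial encoder forward pass
#'
#' Encodes a batch of segments into spatial embeddings Z_S. Each residual
#' block computes its graph convolutions and adds its input; the block
#' outputs are concatenated along the feature axis, mixed by a 1x1
#' convolution, max-pooled over nodes, and projected by three 1x1-conv +
#' batch-norm stages.
#'
#' @param weights From [init_spatial_encoder()].
#' @param X Batch array `[B x C x L]` (or a single `[C x L]` matrix).
#' @param adjacency Either one `[C x C]` directed adjacency shared by the
#'   batch or a list of per-sample adjacencies.
#' @param config The [spatial_encoder_config()].
#' @param bn_state Batch-norm running statistics (from `init_bn_state()`).
#' @param train Logical; `TRUE` uses batch statistics (and updates the
#'   running ones), `FALSE` freezes them.
#' @return List with `z` (`[B x F_e]` embeddings), updated `bn_state`, and a
#'   `cache` for [spatial_backward()].
#' @export
spatial_forward <- function(weights, X, adjacency, config, bn_state,
                            train = TRUE) {
  if (length(dim(X)) == 2) X <- array(X, dim = c(1, dim(X)))
  B <- dim(X)[1]
  if (train && B == 1) {
    warn("Batch of size 1 in training mode: batch-norm statistics degenerate.")
  }
  adj_list <- if (is.list(adjacency)) adjacency else
    rep(list(adjacency), B)
  nhats <- lapply(adj_list, norm_propagation)
  sample_caches <- vector("list", B)
  G <- matrix(0, B, config$hidden_dim)
  for (i in seq_len(B)) {
    sc <- resgcn_sample_forward(weights, X[i, , , drop = TRUE], nhats[[i]])
    sample_caches[[i]] <- sc
    G[i, ] <- sc$g
  }
  p <- weights$proj
  s1 <- G %*% p$W1
  bn1 <- bn_forward(s1, p$g1, p$b1, bn_state$mean1, bn_state$var1, train)
  a1 <- relu(bn1$out)
  s2 <- a1 %*% p$W2
  bn2 <- bn_forward(s2, p$g2, p$b2, bn_state$mean2, bn_state$var2, train)
  a2 <- relu(bn2$out)
  s3 <- a2 %*% p$W3
  bn3 <- bn_forward(s3, p$g3, p$b3, bn_state$mean3, bn_state$var3, train)
  z <- bn3$out
  bn_state <- list(mean1 = bn1$run_mean, var1 = bn1$run_var,
                   mean2 = bn2$run_mean, var2 = bn2$run_var,
                   mean3 = bn3$run_mean, var3 = bn3$run_var)
  list(z = z, bn_state = bn_state,
       cache = list(G = G, a1 = a1, a2 = a2, bn1 = bn1, bn2 = bn2, bn3 = bn3,
                    sample_caches = sample_caches, nhats = nhats))
}

#' Spatial encoder backward pass
#'
#' Backpropagates a gradient on the embeddings through projector, fusion,
#' residual blocks and stem.
#'
#' @param weights,config As in [spatial_forward()].
#' @param cache The cache returned by [spatial_forward()].
#' @param dz Gradient `[B x F_e]` of the loss w.r.t. the embeddings.
#' @return Nested list of weight gradients (same shape as `weights`).
#' @export
spatial_backward <- function(weights, cache, dz, config) {
  p <- weights$proj
  grads <- rapply(weights, function(w) array(0, dim = dim(w) %||% length(w)),
                  how = "replace")
  b3 <- bn_backward(cache$bn3, dz, p$g3)
  grads$proj$g3 <- b3$dgamma; grads$proj$b3 <- b3$dbeta
  grads$proj$W3 <- crossprod(cache$a2, b3$dx)
  da2 <- b3$dx %*% t(p$W3)
  da2 <- da2 * (cache$a2 > 0)
  b2 <- bn_backward(cache$bn2, da2, p$g2)
  grads$proj$g2 <- b2$dgamma; grads$proj$b2 <- b2$dbeta
  grads$proj$W2 <- crossprod(cache$a1, b2$dx)
  da1 <- b2$dx %*% t(p$W2)
  da1 <- da1 * (cache$a1 > 0)
  b1 <- bn_backward(cache$bn1, da1, p$g1)
  grads$proj$g1 <- b1$dgamma; grads$proj$b1 <- b1$dbeta
  grads$proj$W1 <- crossprod(cache$G, b1$dx)
  dG <- b1$dx %*% t(p$W1)
  for (i in seq_along(cache$sample_caches)) {
    grads <- resgcn_sample_backward(weights, cache$sample_caches[[i]],
                                    cache$nhats[[i]], dG[i, ], grads)
  }
  grads
}
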