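# Granger-Former temporal encoder: every time point is expanded into the
# forward window of length P that follows it; linear maps produce queries,
# keys and values; attention scores are Granger-causality values between
# key and query window series (key -> query), rectified and softmax-
# normalised; values are collapsed over the window axis and aggregated.
# Attention weights are treated as constants in the backward pass (OLS-based
# scores have ill-conditioned gradients), so gradients flow through the
# value path, the transformer skeleton, and the MLP projector.

#' Temporal encoder configuration
#'
#' @param embed_dim Embedding dimension F_e of queries/keys/values and the
#'   output representation.
#' @param window_len Sliding-window length P (must satisfy
#'   `P > 3 * att_lag` so the in-window Granger fits are feasible).
#' @param att_lag Lag order of the attention-internal Granger test.
#' @param feature_subsample Number of feature dimensions sampled (seeded,
#'   fixed per encoder) when averaging Granger scores; `Inf` uses all.
#' @param hidden_dim Width of the MLP projector's hidden layer.
#' @param seed Seed for initialisation and the feature subsample.
#' @return List of class `temporal_encoder_config`.
#' @export
temporal_encoder_config <- function(embed_dim = 128, window_len = 8,
                                    att_lag = 1, feature_subsample = 8,
                                    hidden_dim = NULL, seed = 1L) {
  att_lag <- check_positive_int(att_lag, "att_lag")
  window_len <- check_positive_int(window_len, "window_len")
  if (window_len <= 3 * att_lag) {
    abort("`window_len` must exceed 3 * att_lag for feasible in-window fits.")
  }
  structure(list(embed_dim = check_positive_int(embed_dim, "embed_dim"),
                 window_len = window_len, att_lag = att_lag,
                 feature_subsample = feature_subsample,
                 hidden_dim = hidden_dim %||% embed_dim,
                 seed = as.integer(seed)),
            class = "temporal_encoder_config")
}

#' Forward sliding-window expansion
#'
#' Window t holds `x[t .. t + P - 1]`; positions with fewer than P remaining
#' samples are zero-padded on the right.
#'
#' @param x Numeric matrix `[L x V]` (a vector is treated as `V = 1`).
#' @param window_len Window length P (`2 <= P <= L`).
#' @return Array `[L x P x V]` with attribute `pad_count` (per-position
#'   number of padded zeros).
#' @export
make_windows <- function(x, window_len) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  P <- check_positive_int(window_len, "window_len")
  if (P < 2) abort("`window_len` must be at least 2.")
  L <- nrow(x)
  if (P > L) abort("`window_len` exceeds the series length.")
  V <- ncol(x)
  out <- array(0, dim = c(L, P, V))
  for (p in seq_len(P)) {
    valid <- seq_len(L - p + 1)
    out[valid, p, ] <- x[valid + p - 1, ]
  }
  structure(out, pad_count = pmax(0L, seq_len(L) + P - 1L - L))
}

# Map a windowed array [L x P x V] through a [V x F] matrix -> [L x P x F].
window_linear <- function(xp, W) {
  d <- dim(xp)
  flat <- matrix(xp, d[1] * d[2], d[3])
  array(flat %*% W, dim = c(d[1], d[2], ncol(W)))
}

# Seeded, fixed choice of feature dimensions entering the score average.
attention_feature_idx <- function(config) {
  fe <- config$embed_dim
  k <- min(config$feature_subsample, fe)
  if (!is.finite(k) || k >= fe) return(seq_len(fe))
  local_seed(config$seed, sample.int(fe, k))
}

#' Granger-attention score matrix
#'
#' Entry (t, s) is the mean over sampled feature dimensions of the
#' Granger-causality value of key-window s onto query-window t (source = key,
#' target = query), computed at `config$att_lag` on the length-P window
#' series. Constant windows contribute a zero score.
#'
#' @param Q,K Arrays `[L x P x F_e]` of query / key window series.
#' @param config A [temporal_encoder_config()].
#' @return Raw score matrix `[L x L]` (pre-ReLU, pre-softmax).
#' @export
granger_attention_scores <- function(Q, K, config) {
  idx <- attention_feature_idx(config)
  cpp_gc_score_matrix(Q[, , idx, drop = FALSE], K[, , idx, drop = FALSE],
                      config$att_lag)
}

#' Granger attention
#'
#' Applies ReLU then a row-wise softmax to the Granger score matrix and
#' aggregates the values, which are first collapsed over the window axis by
#' their mean: output row t is the attention-weighted combination of the
#' collapsed value rows.
#'
#' @param Q,K,V Arrays `[L x P x F_e]`.
#' @param config A [temporal_encoder_config()].
#' @param scores Optional precomputed raw score matrix (cached during
#'   training, since the query/key maps receive no gradient).
#' @return List with `output` (`[L x F_e]`), `weights` (`[L x L]` rows
#'   summing to 1), `scores`, and `v_bar` (collapsed values).
#' @export
granger_attention <- function(Q, K, V, config, scores = NULL) {
  if (is.null(scores)) scores <- granger_attention_scores(Q, K, config)
  weights <- softmax_rows(relu(scores))
  v_bar <- apply(V, c(1, 3), mean)
  list(output = weights %*% v_bar, weights = weights, scores = scores,
       v_bar = v_bar)
}

#' Initialise temporal encoder weights
#'
#' @param config A [temporal_encoder_config()].
#' @param n_channels Number of input channels V.
#' @return Nested list: query/key/value maps, layer-norm gain/bias, and the
#'   two-layer MLP projector.
#' @export
init_temporal_encoder <- function(config, n_channels) {
  fe <- config$embed_dim
  local_seed(config$seed + 1L, list(
    Wq = init_matrix(n_channels, fe),
    Wk = init_matrix(n_channels, fe),
    Wv = init_matrix(n_channels, fe),
    ln_g = rep(1, fe), ln_b = rep(0, fe),
    mlp = list(W1 = init_matrix(fe, config$hidden_dim),
               b1 = rep(0, config$hidden_dim),
               W2 = init_matrix(config$hidden_dim, fe),
               b2 = rep(0, fe))))
}

layernorm_rows <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(out = xhat * matrix(g, nrow(x), length(g), byrow = TRUE) +
         matrix(b, nrow(x), length(b), byrow = TRUE),
       xhat = xhat, inv = inv)
}

layernorm_backward <- function(cache, dout, g) {
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, g, "*")
  Fd <- ncol(dout)
  dx <- (dxhat - rowMeans(dxhat) -
           cache$xhat * rowMeans(dxhat * cache$xhat)) * cache$inv
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

#' Temporal encoder forward pass
#'
#' Sliding-window expansion, linear Q/K/V maps, Granger attention, residual
#' addition of the collapsed value path, layer normalisation, mean pooling
#' over time, and the MLP projector to Z_T.
#'
#' @param weights From [init_temporal_encoder()].
#' @param x Input segment `[L x V]`.
#' @param config A [temporal_encoder_config()].
#' @param scores Optional cached raw attention scores for this segment.
#' @return List with `z` (length-F_e embedding) and a `cache` for
#'   [temporal_backward()].
#' @export
temporal_forward <- function(weights, x, config, scores = NULL) {
  xp <- make_windows(x, config$window_len)
  if (is.null(scores)) {
    Q <- window_linear(xp, weights$Wq)
    K <- window_linear(xp, weights$Wk)
    scores <- granger_attention_scores(Q, K, config)
  }
  att_w <- softmax_rows(relu(scores))
  M <- apply(xp, c(1, 3), mean)          # collapsed windows [L x V]
  v_bar <- M %*% weights$Wv              # collapsed values  [L x F_e]
  zt_tilde <- att_w %*% v_bar
  R <- zt_tilde + v_bar                  # residual over the value path
  ln <- layernorm_rows(R, weights$ln_g, weights$ln_b)
  pooled <- colMeans(ln$out)
  h1_pre <- drop(pooled %*% weights$mlp$W1) + weights$mlp$b1
  h1 <- relu(h1_pre)
  z <- drop(h1 %*% weights$mlp$W2) + weights$mlp$b2
  list(z = z,
       cache = list(M = M, att_w = att_w, ln = ln, pooled = pooled,
                    h1_pre = h1_pre, h1 = h1, L = nrow(x), scores = scores))
}

#' Temporal encoder backward pass
#'
#' Gradient of a loss on Z_T with respect to the value map, layer-norm and
#' MLP parameters; the attention weights (and hence the query/key maps) are
#' constants by design.
#'
#' @param weights As in [temporal_forward()].
#' @param cache Cache from [temporal_forward()].
#' @param dz Gradient vector of length F_e.
#' @return Nested list of gradients with the shapes of `weights` (`Wq`, `Wk`
#'   are zero).
#' @export
temporal_backward <- function(weights, cache, dz) {
  grads <- rapply(weights, function(w) array(0, dim = dim(w) %||% length(w)),
                  how = "replace")
  grads$mlp$W2 <- outer(cache$h1, dz)
  grads$mlp$b2 <- dz
  dh1 <- drop(weights$mlp$W2 %*% dz) * (cache$h1_pre > 0)
  grads$mlp$W1 <- outer(cache$pooled, dh1)
  grads$mlp$b1 <- dh1
  dpooled <- drop(weights$mlp$W1 %*% dh1)
  dln <- matrix(dpooled, cache$L, length(dpooled), byrow = TRUE) / cache$L
  lb <- layernorm_backward(cache$ln, dln, weights$ln_g)
  grads$ln_g <- lb$dgamma
  grads$ln_b <- lb$dbeta
  dR <- lb$dx
  dv_bar <- crossprod(cache$att_w, dR) + dR
  grads$Wv <- crossprod(cache$M, dv_bar)
  grads
}
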