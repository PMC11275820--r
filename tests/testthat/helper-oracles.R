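# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (qr/lm machinery, the C++ kernels): explicit normal
# equations, explicit residuals, explicit loops.

# GC log variance ratio by explicit normal-equations OLS on rows P+1..n.
oracle_gc_value <- function(target, source, P) {
  n <- length(target)
  y <- target[(P + 1):n]
  Xu <- sapply(seq_len(P), function(p) target[(P + 1 - p):(n - p)])
  Xb <- cbind(Xu, sapply(seq_len(P), function(p) source[(P + 1 - p):(n - p)]))
  rss <- function(X) {
    X <- as.matrix(X)
    b <- solve(t(X) %*% X, t(X) %*% y)
    r <- y - X %*% b
    sum(r * r)
  }
  log(rss(Xu) / rss(Xb))
}

# Amplitude spectrum by an explicit DFT sum (no fft()).
oracle_dft_amplitude <- function(x) {
  L <- length(x)
  E <- L %/% 2 + 1
  sapply(seq_len(E) - 1, function(k) {
    re <- sum(x * cos(-2 * pi * k * (seq_len(L) - 1) / L))
    im <- sum(x * sin(-2 * pi * k * (seq_len(L) - 1) / L))
    sqrt(re^2 + im^2)
  })
}

# Graph-convolution propagation by an explicit loop over edges.
oracle_gcn_layer <- function(features, adjacency, weights) {
  C <- nrow(features)
  agg <- matrix(0, C, ncol(features))
  for (i in seq_len(C)) {
    parents <- c(i, which(adjacency[i, ] != 0))
    parents <- unique(parents)
    for (j in parents) agg[i, ] <- agg[i, ] + features[j, ]
    agg[i, ] <- agg[i, ] / length(parents)
  }
  pmax(agg %*% weights, 0)
}

# Fixture: small labelled session shared by training tests.
tiny_session <- function(seed = 5, n_subjects = 2, n_videos = 4) {
  conn <- lapply(1:2, function(k) var_spec(4, 1, coupling = data.frame(
    source = k, target = k + 2, lag = 1, coefficient = 0.5), seed = seed + k))
  spec <- session_spec(n_subjects = n_subjects,
                       n_trials_per_subject = n_videos,
                       trial_duration_s = 7, baseline_duration_s = 3,
                       sampling_rate_hz = 32, n_channels = 4, n_classes = 2,
                       class_connectivity = conn, noise_sd = 0.3, seed = seed)
  simulate_session(spec)
}

tiny_config <- function(seed = 3, ...) {
  run_config(seed = seed,
             pretrain = list(iterations = 4, batch_size = 4),
             finetune = list(epochs = 2, batch_size = 8),
             cv_folds = 2, top_k = 5,
             spatial = spatial_encoder_config(n_blocks = 3, hidden_dim = 8,
                                              embed_dim = 8, seed = seed),
             temporal = temporal_encoder_config(embed_dim = 8, window_len = 6,
                                                feature_subsample = 3,
                                                seed = seed),
             ...)
}
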