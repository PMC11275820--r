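# Contrastive objective: cosine similarity, the InfoNCE loss for the spatial
# and temporal branches, positive-pair samplers and negative-set
# construction. The embedding-level gradient used in training is implemented
# here and finite-difference checked in the test suite.

#' Cosine similarity
#'
#' @param a,b Non-zero numeric vectors of equal length.
#' @return Scalar in `[-1, 1]`.
#' @export
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) abort("Cosine similarity undefined for zero vectors.")
  sum(a * b) / (na * nb)
}

#' InfoNCE contrastive loss from similarities
#'
#' Mean over anchors of `-log( exp(s+/tau) / (exp(s+/tau) + sum exp(s-/tau)) )`,
#' computed with max-subtraction so the default temperature 0.1 cannot
#' overflow. An anchor with an empty negative set contributes 0 (log of 1).
#'
#' @param sim_pos Length-N vector of anchor-positive similarities.
#' @param sim_neg List of N numeric vectors (possibly empty) of
#'   anchor-negative similarities, or an `[N x M]` matrix.
#' @param temperature Softmax temperature tau > 0; default 0.1.
#' @return Non-negative scalar loss.
#' @examples
#' info_nce(1, list(rep(0, 30)))  # = log(1 + 30 * exp(-10))
#' @export
info_nce <- function(sim_pos, sim_neg, temperature = 0.1) {
  if (temperature <= 0) abort("`temperature` must be positive.")
  if (is.matrix(sim_neg)) sim_neg <- asplit(sim_neg, 1)
  stopifnot(length(sim_pos) == length(sim_neg))
  terms <- vapply(seq_along(sim_pos), function(i) {
    sn <- sim_neg[[i]]
    if (length(sn) == 0) return(0)
    s <- c(sim_pos[i], sn) / temperature
    m <- max(s)
    -(s[1] - m) + log(sum(exp(s - m)))
  }, numeric(1))
  mean(terms)
}

#' Total pretraining loss
#'
#' Unweighted sum of the spatial and temporal contrastive losses.
#'
#' @param l_s,l_t Spatial and temporal loss values.
#' @return `l_s + l_t`.
#' @export
total_loss <- function(l_s, l_t) l_s + l_t

#' Sample spatial positive pairs and negative sets
#'
#' For each segment (anchor), the positive is a segment from a different
#' subject that watched the same video — by default additionally aligned to
#' the same 1 s window within the video, so positives are stimulus-aligned.
#' Negatives are drawn without replacement from segments of other videos.
#' Videos watched by a single subject are skipped with a warning.
#'
#' @param meta Segment metadata tibble with columns `segment_id`, `subject`,
#'   `video`, `window`.
#' @param n_negatives Negatives per anchor; `NULL` leaves negative selection
#'   to the training loop (in-batch negatives).
#' @param align_window Require the positive to share the anchor's within-
#'   video window index (default `TRUE`).
#' @param seed Integer seed.
#' @return Tibble with `anchor`, `positive` (segment ids) and, when
#'   `n_negatives` is given, a `negatives` list-column.
#' @export
sample_spatial_pairs <- function(meta, n_negatives = NULL,
                                 align_window = TRUE, seed = 1L) {
  if (length(unique(meta$video)) < 2) {
    abort("Need at least 2 distinct videos for negative sampling.")
  }
  local_seed(seed, {
    rows <- purrr::map(seq_len(nrow(meta)), function(i) {
      anchor <- meta[i, ]
      cand <- meta$subject != anchor$subject & meta$video == anchor$video
      if (align_window) cand <- cand & meta$window == anchor$window
      cand <- which(cand)
      if (length(cand) == 0) return(NULL)
      positive <- meta$segment_id[if (length(cand) == 1) cand else
        sample(cand, 1)]
      out <- tibble::tibble(anchor = anchor$segment_id, positive = positive)
      if (!is.null(n_negatives)) {
        pool <- meta$segment_id[meta$video != anchor$video]
        out$negatives <- list(sample(pool, min(n_negatives, length(pool))))
      }
      out
    })
    skipped <- sum(vapply(rows, is.null, logical(1)))
    if (skipped > 0) {
      warn(sprintf("%d segments had no cross-subject same-video match; skipped.",
                   skipped))
    }
    dplyr::bind_rows(rows)
  })
}

# ---- internal: InfoNCE on embedding matrices with analytic gradients ----
#
# Z: [n x F] embedding matrix holding all batch embeddings (anchors,
# positives, queue entries, ...). pairs: list with integer vectors `anchor`,
# `positive` and list `negatives` (indices into Z rows; possibly empty).
# Returns loss and dZ. Negatives taken from a fixed `extra` matrix (memory
# queue) are referenced by negative indices <= 0: index -k means extra[k, ].
info_nce_embed <- function(Z, pairs, temperature = 0.1, extra = NULL) {
  n <- nrow(Z)
  dZ <- matrix(0, n, ncol(Z))
  norms <- sqrt(rowSums(Z^2))
  get_vec <- function(idx) if (idx > 0) Z[idx, ] else extra[-idx, ]
  get_norm <- function(idx) if (idx > 0) norms[idx] else
    sqrt(sum(extra[-idx, ]^2))
  N <- length(pairs$anchor)
  loss <- 0
  for (i in seq_len(N)) {
    ai <- pairs$anchor[i]
    pi <- pairs$positive[i]
    ni <- pairs$negatives[[i]]
    others <- c(pi, ni)
    a <- Z[ai, ]; na <- norms[ai]
    sims <- vapply(others, function(o) sum(a * get_vec(o)) / (na * get_norm(o)),
                   numeric(1))
    s <- sims / temperature
    m <- max(s)
    p <- exp(s - m) / sum(exp(s - m))
    loss <- loss - (s[1] - m - log(sum(exp(s - m))))
    # dL/ds_k = (p_k - 1[k == positive]) / (N * tau)
    dsims <- (p - c(1, rep(0, length(ni)))) / (N * temperature)
    for (k in seq_along(others)) {
      o <- others[k]
      b <- get_vec(o); nb <- get_norm(o)
      ck <- sims[k]
      dZ[ai, ] <- dZ[ai, ] + dsims[k] * (b / (na * nb) - ck * a / na^2)
      if (o > 0) {
        dZ[o, ] <- dZ[o, ] + dsims[k] * (a / (na * nb) - ck * b / nb^2)
      }
    }
  }
  list(loss = loss / N, dZ = dZ)
}

# FIFO memory queue of past embeddings used as extra negatives (opt-in).
queue_push <- function(queue, embeddings, size) {
  if (size <= 0) return(queue)
  q <- rbind(queue, embeddings)
  if (nrow(q) > size) q <- q[(nrow(q) - size + 1):nrow(q), , drop = FALSE]
  q
}
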