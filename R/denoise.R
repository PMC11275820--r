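# Frequency-domain top-K denoising: keep the K one-sided spectral bins with
# the largest amplitude, zero the rest, invert. Manufactures the temporal
# positive sample of the contrastive objective.

denoise_vector <- function(x, top_k, keep_dc) {
  L <- length(x)
  if (all(x == 0)) return(x)
  f <- fft(x)
  E <- L %/% 2 + 1
  amp <- Mod(f[seq_len(E)])  # A(F) = sqrt(Re^2 + Im^2), one-sided bins
  ord <- order(-amp, seq_len(E))  # ties broken by lower bin index
  keep <- if (keep_dc && !(1 %in% ord[seq_len(top_k)])) {
    c(1L, ord[seq_len(top_k - 1)])
  } else {
    ord[seq_len(top_k)]
  }
  mask <- rep(FALSE, L)
  mask[keep] <- TRUE
  mirror <- keep[keep > 1 & keep < L - keep + 2]
  mask[L - mirror + 2] <- TRUE  # conjugate-symmetric partners
  f[!mask] <- 0
  Re(fft(f, inverse = TRUE)) / L
}

#' Top-K frequency-domain denoising
#'
#' Transforms each channel with a one-sided real FFT (E = floor(L/2) + 1
#' bins), keeps the complex values of the K bins with largest amplitude
#' (phases preserved), zeroes every other bin, and inverts. Selection is
#' independent per channel; amplitude ties at the K-th rank are broken
#' towards the lower bin index, so the operation is deterministic and
#' idempotent. An all-zero channel is returned unchanged.
#'
#' @param x Numeric vector `[L]`, matrix `[L x V]`, or array `[N x L x V]`.
#' @param top_k Number of retained bins K; must satisfy
#'   `K <= floor(L / 2) + 1`. Default 20.
#' @param keep_dc If `TRUE` the DC bin is always retained (occupying one of
#'   the K slots); by default it competes in the top-K like any other bin.
#' @return Denoised signal with the shape of `x`.
#' @examples
#' x <- tonal_signal(c(5, 12), c(1, 1), 128, 128, noise_sd = 0.5)
#' xd <- denoise_topk(x, top_k = 2)
#' @export
denoise_topk <- function(x, top_k = 20, keep_dc = FALSE) {
  top_k <- check_positive_int(top_k, "top_k")
  if (is.vector(x)) return(denoise_matrix(matrix(x, ncol = 1), top_k, keep_dc)[, 1])
  if (length(dim(x)) == 2) return(denoise_matrix(x, top_k, keep_dc))
  if (length(dim(x)) == 3) {
    out <- x
    for (n in seq_len(dim(x)[1])) {
      out[n, , ] <- denoise_matrix(x[n, , , drop = TRUE], top_k, keep_dc)
    }
    return(out)
  }
  abort("`x` must be a vector, [L x V] matrix, or [N x L x V] array.")
}

denoise_matrix <- function(x, top_k, keep_dc) {
  L <- nrow(x)
  if (L < 2) abort("Need at least 2 samples.")
  E <- L %/% 2 + 1
  if (top_k > E) {
    abort(sprintf("`top_k` = %d exceeds the %d one-sided bins.", top_k, E))
  }
  apply(x, 2, denoise_vector, top_k = top_k, keep_dc = keep_dc)
}

# Mask-based temporal augmentation (ablation alternative to denoising):
# a random contiguous window covering `fraction` of L is zeroed per channel.
mask_augment <- function(x, fraction = 0.1) {
  L <- nrow(x)
  w <- max(1L, floor(fraction * L))
  out <- x
  for (v in seq_len(ncol(x))) {
    start <- sample.int(L - w + 1L, 1L)
    out[start:(start + w - 1L), v] <- 0
  }
  out
}
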