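# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so generators are pure functions of (spec, seed).
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Numerically stable row-wise softmax.
softmax_rows <- function(m) {
  shifted <- m - apply(m, 1, max)
  e <- exp(shifted)
  e / rowSums(e)
}

# Uniform fan-in initialisation (weights in +/- 1/sqrt(fan_in)).
init_matrix <- function(n_in, n_out) {
  bound <- 1 / sqrt(n_in)
  matrix(runif(n_in * n_out, -bound, bound), n_in, n_out)
}

check_positive_int <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x < 1 || x != round(x)) {
    abort(sprintf("`%s` must be a single positive integer, got %s.",
                  name, paste(format(x), collapse = ", ")))
  }
  as.integer(x)
}

# Adam optimiser over a flat named list of arrays. `state` carries first and
# second moments plus the step counter; created on first use.
adam_init <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Flatten a nested list of numeric arrays to a flat named list (for the
# optimiser) and the inverse. Names are dot-joined paths.
flatten_params <- function(x, prefix = NULL) {
  out <- list()
  for (nm in names(x)) {
    key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    if (is.list(x[[nm]])) {
      out <- c(out, flatten_params(x[[nm]], key))
    } else {
      out[[key]] <- x[[nm]]
    }
  }
  out
}

unflatten_params <- function(flat, skeleton, prefix = NULL) {
  for (nm in names(skeleton)) {
    key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    if (is.list(skeleton[[nm]])) {
      skeleton[[nm]] <- unflatten_params(flat, skeleton[[nm]], key)
    } else if (!is.null(flat[[key]])) {
      skeleton[[nm]] <- flat[[key]]
    }
  }
  skeleton
}
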