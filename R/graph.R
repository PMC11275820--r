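# Electrode graph construction: distance-based affinity, thresholded base
# adjacency, Granger-augmented directed adjacency, and degree-flow summaries.
# Orientation convention throughout: adjacency[i, j] = 1 means information
# flows j -> i (row = receiving channel).

#' Electrode layout constructors
#'
#' A channel layout is a tibble with columns `name`, `x`, `y`, `z` giving 3-D
#' electrode coordinates (units arbitrary but consistent). `channel_layout()`
#' validates one, `read_channel_layout()` reads the `name,x,y,z` CSV format,
#' and `ring_layout()` builds a synthetic circular montage for simulated
#' sessions.
#'
#' @param names Unique channel labels.
#' @param coords Numeric `[C x 3]` coordinate matrix.
#' @return A tibble with columns `name`, `x`, `y`, `z`.
#' @export
channel_layout <- function(names, coords) {
  coords <- as.matrix(coords)
  if (anyDuplicated(names)) abort("Duplicate channel names in layout.")
  if (nrow(coords) != length(names) || ncol(coords) != 3) {
    abort("`coords` must be a [C x 3] matrix matching `names`.")
  }
  if (anyDuplicated(round(coords, 12))) {
    abort("Two channels share identical coordinates.")
  }
  tibble::tibble(name = as.character(names),
                 x = coords[, 1], y = coords[, 2], z = coords[, 3])
}

#' @rdname channel_layout
#' @param path CSV file with header `name,x,y,z`.
#' @export
read_channel_layout <- function(path) {
  df <- read.csv(path)
  channel_layout(df$name, as.matrix(df[, c("x", "y", "z")]))
}

#' @rdname channel_layout
#' @param n Number of electrodes.
#' @param radius Ring radius, scaled so that with the default affinity
#'   parameters nearby electrodes connect and distant ones are pruned.
#' @export
ring_layout <- function(n, radius = 6) {
  ang <- 2 * pi * (seq_len(n) - 1) / n
  channel_layout(paste0("ch", seq_len(n)),
                 cbind(radius * cos(ang), radius * sin(ang), 0))
}

layout_coords <- function(layout) {
  as.matrix(layout[, c("x", "y", "z")])
}

#' Distance-based channel affinity
#'
#' Inter-channel affinity decays with the square of the Euclidean electrode
#' distance: entry (i, j) is `min(1, theta / d_ij^2)` for i != j, so the
#' calibration constant `theta` normalises the reciprocal squared distance
#' into (0, 1]. Diagonal is zero.
#'
#' @param layout A [channel_layout()].
#' @param theta Calibration constant (> 0); default 6.
#' @return Symmetric `[C x C]` matrix with entries in `[0, 1]`.
#' @export
channel_affinity <- function(layout, theta = 6) {
  if (theta <= 0) abort("`theta` must be positive.")
  coords <- layout_coords(layout)
  d <- as.matrix(stats::dist(coords))
  if (any(d[upper.tri(d)] == 0)) abort("Coincident electrodes (distance 0).")
  aff <- pmin(theta / d^2, 1)
  diag(aff) <- 0
  dimnames(aff) <- list(layout$name, layout$name)
  aff
}

#' Threshold the affinity into the symmetric base adjacency
#'
#' An undirected edge is kept where the affinity reaches the threshold
#' (`affinity >= delta`, boundary inclusive); weakly related channel pairs
#' are removed.
#'
#' @param affinity Symmetric affinity matrix from [channel_affinity()].
#' @param delta Threshold in (0, 1); default 0.1.
#' @return Binary symmetric `[C x C]` matrix with zero diagonal.
#' @export
base_adjacency <- function(affinity, delta = 0.1) {
  if (delta <= 0 || delta >= 1) abort("`delta` must lie in (0, 1).")
  adj <- (affinity >= delta) * 1L
  diag(adj) <- 0L
  adj
}

#' Augment the base adjacency with Granger-causality directions
#'
#' Turns the symmetric base graph into a directed graph: the directed edge
#' j -> i (entry `[i, j]`) survives iff the undirected base edge exists and
#' the j -> i Granger test passes the gate. The default gate is the F test at
#' the level used when `gc` was computed; `gate = "raw"` instead keeps edges
#' with a literal `gc_value > 0` (in-sample OLS makes this almost always
#' true, so the raw gate barely prunes — it is provided for completeness).
#' Augmentation only prunes or orients edges, never adds one.
#'
#' @param base Binary symmetric adjacency from [base_adjacency()].
#' @param gc Tidy GC table from [granger_matrix()] computed on the same
#'   channels (matched by dimnames of `base` when present).
#' @param gate `"ftest"` (default) or `"raw"`.
#' @return Binary directed `[C x C]` matrix; `[i, j] = 1` means flow j -> i.
#' @export
augment_adjacency <- function(base, gc, gate = c("ftest", "raw")) {
  gate <- match.arg(gate)
  C <- nrow(base)
  labels <- rownames(base) %||% as.character(seq_len(C))
  out <- matrix(0L, C, C, dimnames = list(labels, labels))
  tgt <- match(gc$target, labels)
  src <- match(gc$source, labels)
  if (anyNA(tgt) || anyNA(src)) {
    abort("GC table channels do not match the adjacency dimnames.")
  }
  if (any(gc$degenerate)) {
    warn("Degenerate GC pairs present; their edges are removed.")
  }
  pass <- !gc$degenerate &
    if (gate == "ftest") gc$significant else gc$gc_value > 0
  pass[is.na(pass)] <- FALSE
  out[cbind(tgt, src)] <- as.integer(pass)
  out * (base != 0)
}

#' Out-minus-in degree flow of a directed adjacency
#'
#' For each channel, the difference between its out-degree (edges it sends:
#' its column sum under the row-receiver convention) and its in-degree (its
#' row sum). Positive flow marks an information source, negative a sink; the
#' differences always sum to zero.
#'
#' @param gc_adjacency Binary directed matrix (row = receiver).
#' @param k How many top sources / sinks to rank.
#' @return Tibble with `channel`, `out_degree`, `in_degree`, `flow`, and
#'   `rank_source` / `rank_sink` (1..k, NA outside the top k).
#' @export
degree_flow <- function(gc_adjacency, k = 5) {
  C <- nrow(gc_adjacency)
  labels <- rownames(gc_adjacency) %||% as.character(seq_len(C))
  out_deg <- colSums(gc_adjacency != 0)
  in_deg <- rowSums(gc_adjacency != 0)
  flow <- out_deg - in_deg
  k <- min(k, C)
  src_order <- order(-flow, seq_len(C))
  snk_order <- order(flow, seq_len(C))
  rank_source <- rank_sink <- rep(NA_integer_, C)
  rank_source[src_order[seq_len(k)]] <- seq_len(k)
  rank_sink[snk_order[seq_len(k)]] <- seq_len(k)
  tibble::tibble(channel = labels, out_degree = as.integer(out_deg),
                 in_degree = as.integer(in_deg), flow = as.integer(flow),
                 rank_source = rank_source, rank_sink = rank_sink)
}

#' Bundle layout, affinity and adjacencies into a channel graph
#'
#' Convenience constructor running [channel_affinity()], [base_adjacency()]
#' and, when a GC table is supplied, [augment_adjacency()].
#'
#' @inheritParams channel_affinity
#' @inheritParams base_adjacency
#' @inheritParams augment_adjacency
#' @param gc Optional GC table; without it the graph holds only the
#'   undirected base adjacency.
#' @return An object of class `channel_graph`.
#' @export
channel_graph <- function(layout, theta = 6, delta = 0.1, gc = NULL,
                          gate = c("ftest", "raw")) {
  aff <- channel_affinity(layout, theta)
  base <- base_adjacency(aff, delta)
  gc_adj <- if (!is.null(gc)) augment_adjacency(base, gc, gate) else NULL
  structure(list(layout = layout, theta = theta, delta = delta,
                 affinity = aff, base_adjacency = base,
                 gc_adjacency = gc_adj, gc = gc),
            class = "channel_graph")
}

#' @export
print.channel_graph <- function(x, ...) {
  cat(sprintf("<channel_graph> %d channels, theta = %g, delta = %g\n",
              nrow(x$base_adjacency), x$theta, x$delta))
  cat(sprintf("  base edges (undirected pairs): %d\n",
              sum(x$base_adjacency) / 2))
  if (!is.null(x$gc_adjacency)) {
    cat(sprintf("  directed GC edges: %d\n", sum(x$gc_adjacency)))
  }
  invisible(x)
}

#' Export the directed GC edges as a tidy edge list
#'
#' @param graph A [channel_graph()] with a GC-augmented adjacency.
#' @param path Optional CSV path; when given, the edge list is also written
#'   with columns `source,target,gc_value,p_value`.
#' @return Tibble of surviving directed edges.
#' @export
gc_edge_list <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "channel_graph"))
  if (is.null(graph$gc_adjacency)) abort("Graph has no GC augmentation.")
  labels <- rownames(graph$gc_adjacency)
  keep <- which(graph$gc_adjacency != 0, arr.ind = TRUE)
  edges <- tibble::tibble(source = labels[keep[, 2]],
                          target = labels[keep[, 1]])
  edges <- dplyr::left_join(
    edges, dplyr::select(graph$gc, "source", "target", "gc_value", "p_value"),
    by = c("source", "target"))
  if (!is.null(path)) write.csv(edges, path, row.names = FALSE)
  edges
}

#' Precision, recall and F1 of recovered directed edges
#'
#' Compares a recovered directed adjacency against a ground-truth edge set
#' (e.g. the coupling table of a [var_spec()]).
#'
#' @param recovered Binary directed adjacency (row = receiver).
#' @param truth Data frame with `source` and `target` columns of true
#'   directed edges (channel indices).
#' @return One-row tibble with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
edge_recovery_score <- function(recovered, truth) {
  C <- nrow(recovered)
  truth <- truth[truth$source != truth$target, , drop = FALSE]  # own-lag terms are not edges
  true_adj <- matrix(0L, C, C)
  if (nrow(truth) > 0) true_adj[cbind(truth$target, truth$source)] <- 1L
  rec <- (recovered != 0) * 1L
  dimnames(rec) <- NULL
  tp <- sum(rec == 1 & true_adj == 1)
  fp <- sum(rec == 1 & true_adj == 0)
  fn <- sum(rec == 0 & true_adj == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  tibble::tibble(tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall, f1 = f1)
}
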