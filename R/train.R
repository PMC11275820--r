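# Pretraining (joint spatial + temporal InfoNCE), fine-tuning with k-fold
# cross-validation, ablation switches, and the noise-perturbation harness.

#' Build a run configuration
#'
#' Nested configuration for pretraining and fine-tuning. Defaults follow the
#' reference protocol: Adam at learning rate 0.001, 3000 pretraining
#' iterations at batch size 32, 100 fine-tuning epochs at batch size 256,
#' five-fold cross-validation, temperature 0.1, graph parameters theta = 6
#' and delta = 0.1, and top-K = 20 retained frequency bins. Any field can be
#' overridden with a nested list, e.g.
#' `run_config(pretrain = list(iterations = 200))`.
#'
#' @param ... Nested overrides of the defaults.
#' @return List of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    pretrain = list(iterations = 3000L, batch_size = 32L, lr = 1e-3),
    finetune = list(epochs = 100L, batch_size = 256L, lr = 1e-3),
    cv_folds = 5L,
    split_unit = "trial",          # "trial" keeps a trial's segments together
    gc_scope = "trial",            # granularity of the GC graph
    temperature = 0.1,
    top_k = 20L,
    keep_dc = FALSE,
    align_window = TRUE,
    queue_size = 0L,
    mask_fraction = 0.1,           # mask-augmentation ablation parameter
    edge_drop_prob = 0.2,          # random-edge-drop ablation parameter
    graph = list(theta = 6, delta = 0.1, lag_order = 2L, alpha = 0.05,
                 gate = "ftest"),
    spatial = spatial_encoder_config(),
    temporal = temporal_encoder_config(),
    ablation = list(spatial_off = FALSE, temporal_off = FALSE,
                    mask_instead_of_denoise = FALSE,
                    vanilla_attention = FALSE, random_edge_drop = FALSE)
  )
  structure(modify_nested(defaults, list(...)), class = "run_config")
}

modify_nested <- function(base, upd) {
  for (nm in names(upd)) {
    if (is.list(upd[[nm]]) && is.list(base[[nm]]) &&
        !inherits(upd[[nm]], c("spatial_encoder_config",
                               "temporal_encoder_config"))) {
      base[[nm]] <- modify_nested(base[[nm]], upd[[nm]])
    } else {
      base[[nm]] <- upd[[nm]]
    }
  }
  base
}

# ---- graph preparation -----------------------------------------------------

trial_key <- function(subject, video) paste(subject, video, sep = ".")

# Stack a trial's consecutive windows back into its continuous [T x C]
# emotion-period signal for GC estimation.
stack_trial <- function(segments, ids, channel_names = NULL) {
  x <- do.call(rbind, lapply(ids, function(i) segments[i, , , drop = TRUE]))
  if (!is.null(channel_names)) colnames(x) <- channel_names
  x
}

build_graphs <- function(session, config, layout = NULL) {
  C <- dim(session$segments)[3]
  layout <- layout %||% ring_layout(C)
  aff <- channel_affinity(layout, config$graph$theta)
  base <- base_adjacency(aff, config$graph$delta)
  adj <- list()
  if (!config$ablation$random_edge_drop && config$gc_scope != "none") {
    groups <- dplyr::group_split(session$meta, .data$subject, .data$video)
    if (config$gc_scope == "session") {
      ids <- head(session$meta$segment_id, 40)
      gc <- granger_matrix(stack_trial(session$segments, ids, layout$name),
                           config$graph$lag_order, config$graph$alpha)
      shared <- augment_adjacency(base, gc, config$graph$gate)
      for (g in groups) {
        adj[[trial_key(g$subject[1], g$video[1])]] <- shared
      }
    } else {
      for (g in groups) {
        gc <- granger_matrix(stack_trial(session$segments, g$segment_id, layout$name),
                             config$graph$lag_order, config$graph$alpha)
        adj[[trial_key(g$subject[1], g$video[1])]] <-
          augment_adjacency(base, gc, config$graph$gate)
      }
    }
  }
  list(layout = layout, base = base, adjacency = adj)
}

segment_adjacency <- function(graphs, meta_row, config) {
  if (config$ablation$random_edge_drop || config$gc_scope == "none") {
    A <- graphs$base
    if (config$ablation$random_edge_drop) {
      mask <- matrix(runif(length(A)) >= config$edge_drop_prob,
                     nrow(A), ncol(A))
      A <- A * mask
    }
    return(A)
  }
  graphs$adjacency[[trial_key(meta_row$subject, meta_row$video)]]
}

# ---- temporal helpers ------------------------------------------------------

# Segment matrix [L x V] for segment id.
segment_matrix <- function(segments, id) segments[id, , , drop = TRUE]

# Attention-score cache: the query/key maps receive no gradient, so raw
# scores depend only on the input segment and can be reused across
# iterations, fine-tuning and evaluation.
scores_for <- function(cache, key, x, weights_t, config) {
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  xp <- make_windows(x, config$temporal$window_len)
  s <- if (config$ablation$vanilla_attention) {
    dot_product_scores(xp, weights_t$Wq, weights_t$Wk)
  } else {
    Q <- window_linear(xp, weights_t$Wq)
    K <- window_linear(xp, weights_t$Wk)
    granger_attention_scores(Q, K, config$temporal)
  }
  if (!is.null(cache)) cache[[key]] <- s
  s
}

# Scaled dot-product scores over flattened windows (vanilla-transformer
# ablation of the Granger attention).
dot_product_scores <- function(xp, Wq, Wk) {
  d <- dim(xp)
  Qf <- matrix(window_linear(xp, Wq), d[1])  # [L x (P * F_e)]
  Kf <- matrix(window_linear(xp, Wk), d[1])
  (Qf %*% t(Kf)) / sqrt(ncol(Qf))
}

temporal_batch_forward <- function(weights_t, segments, ids, keys, config,
                                   cache, x_override = NULL) {
  B <- length(ids)
  Z <- matrix(0, B, config$temporal$embed_dim)
  caches <- vector("list", B)
  for (i in seq_len(B)) {
    x <- if (is.null(x_override)) segment_matrix(segments, ids[i]) else
      x_override[[i]]
    sc <- scores_for(cache, keys[i], x, weights_t, config)
    fw <- temporal_forward(weights_t, x, config$temporal, scores = sc)
    Z[i, ] <- fw$z
    caches[[i]] <- fw$cache
  }
  list(z = Z, caches = caches)
}

temporal_batch_backward <- function(weights_t, caches, dZ) {
  total <- NULL
  for (i in seq_along(caches)) {
    g <- temporal_backward(weights_t, caches[[i]], dZ[i, ])
    total <- if (is.null(total)) g else add_grads(total, g)
  }
  total
}

add_grads <- function(a, b) {
  for (nm in names(a)) {
    a[[nm]] <- if (is.list(a[[nm]])) add_grads(a[[nm]], b[[nm]]) else
      a[[nm]] + b[[nm]]
  }
  a
}

# ---- pretraining -----------------------------------------------------------

#' Pretrain the spatial and temporal encoders with contrastive losses
#'
#' Joint optimisation of `L = L_S + L_T`: at each iteration a batch of
#' (anchor, positive) pairs is drawn — cross-subject same-video pairs for the
#' spatial branch, segment/denoised-copy pairs for the temporal branch —
#' embeddings are computed, the two InfoNCE losses and their gradients are
#' evaluated, and all trainable weights are updated with Adam.
#'
#' @param session An [simulate_session()] result (or compatible object with
#'   `segments` and `meta`).
#' @param config A [run_config()].
#' @param layout Optional electrode layout; defaults to a synthetic ring.
#' @return An object of class `eeg_checkpoint`: encoder weights, batch-norm
#'   state, graphs, config, and the loss trajectory (`history`).
#' @export
pretrain <- function(session, config = run_config(), layout = NULL) {
  meta <- session$meta
  segments <- session$segments
  L <- dim(segments)[2]
  C <- dim(segments)[3]
  n_iter <- config$pretrain$iterations
  bsz <- config$pretrain$batch_size

  set.seed(config$seed)
  graphs <- build_graphs(session, config, layout)
  pairs_tbl <- sample_spatial_pairs(meta, align_window = config$align_window,
                                    seed = config$seed)
  if (nrow(pairs_tbl) == 0) {
    abort("No spatial positive pairs available: need >= 2 subjects per video.")
  }
  meta_by_id <- meta[match(seq_len(nrow(meta)), meta$segment_id), ]

  weights_s <- if (config$ablation$spatial_off) NULL else
    init_spatial_encoder(config$spatial, in_dim = L)
  bn_state <- init_bn_state(config$spatial)
  weights_t <- if (config$ablation$temporal_off) NULL else
    init_temporal_encoder(config$temporal, n_channels = C)

  # fixed positive inputs for the temporal branch (denoised, or masked for
  # the ablation), generated once so attention scores are cacheable
  aug_segments <- NULL
  if (!config$ablation$temporal_off) {
    aug_segments <- if (config$ablation$mask_instead_of_denoise) {
      out <- segments
      for (i in seq_len(dim(segments)[1])) {
        out[i, , ] <- mask_augment(segments[i, , , drop = TRUE],
                                   config$mask_fraction)
      }
      out
    } else {
      denoise_topk(segments, config$top_k, config$keep_dc)
    }
  }

  score_cache <- new.env(parent = emptyenv())
  adam_s <- if (!is.null(weights_s)) adam_init(flatten_params(weights_s))
  adam_t <- if (!is.null(weights_t)) adam_init(flatten_params(weights_t))
  queue_s <- queue_t <- NULL
  history <- vector("list", n_iter)

  for (it in seq_len(n_iter)) {
    rows <- pairs_tbl[sample.int(nrow(pairs_tbl), min(bsz, nrow(pairs_tbl))), ]
    B <- nrow(rows)
    l_s <- 0
    l_t <- 0

    if (!is.null(weights_s)) {
      ids <- c(rows$anchor, rows$positive)
      Xb <- array(0, dim = c(2 * B, C, L))
      adj <- vector("list", 2 * B)
      for (i in seq_along(ids)) {
        Xb[i, , ] <- t(segment_matrix(segments, ids[i]))
        adj[[i]] <- segment_adjacency(graphs, meta_by_id[ids[i], ], config)
      }
      fw <- spatial_forward(weights_s, Xb, adj, config$spatial, bn_state,
                            train = TRUE)
      bn_state <- fw$bn_state
      videos <- meta_by_id$video[ids]
      n_extra <- if (is.null(queue_s)) 0 else nrow(queue_s)
      prs <- list(anchor = seq_len(B), positive = B + seq_len(B),
                  negatives = lapply(seq_len(B), function(i) {
                    c(which(videos != videos[i]),
                      if (n_extra > 0) -seq_len(n_extra))
                  }))
      res <- info_nce_embed(fw$z, prs, config$temperature, extra = queue_s)
      l_s <- res$loss
      gr <- spatial_backward(weights_s, fw$cache, res$dZ, config$spatial)
      upd <- adam_step(flatten_params(weights_s), flatten_params(gr),
                       adam_s, lr = config$pretrain$lr)
      weights_s <- unflatten_params(upd$params, weights_s)
      adam_s <- upd$state
      if (config$queue_size > 0) {
        queue_s <- queue_push(queue_s, fw$z[B + seq_len(B), , drop = FALSE],
                              config$queue_size)
      }
    }

    if (!is.null(weights_t)) {
      fa <- temporal_batch_forward(weights_t, segments, rows$anchor,
                                   paste0("o", rows$anchor), config,
                                   score_cache)
      fp <- temporal_batch_forward(weights_t, aug_segments, rows$anchor,
                                   paste0("p", rows$anchor), config,
                                   score_cache)
      Zt <- rbind(fa$z, fp$z)
      n_extra <- if (is.null(queue_t)) 0 else nrow(queue_t)
      prs <- list(anchor = seq_len(B), positive = B + seq_len(B),
                  negatives = lapply(seq_len(B), function(i) {
                    c(setdiff(seq_len(2 * B), c(i, B + i)),
                      if (n_extra > 0) -seq_len(n_extra))
                  }))
      res <- info_nce_embed(Zt, prs, config$temperature, extra = queue_t)
      l_t <- res$loss
      gr <- add_grads(
        temporal_batch_backward(weights_t, fa$caches,
                                res$dZ[seq_len(B), , drop = FALSE]),
        temporal_batch_backward(weights_t, fp$caches,
                                res$dZ[B + seq_len(B), , drop = FALSE]))
      upd <- adam_step(flatten_params(weights_t), flatten_params(gr),
                       adam_t, lr = config$pretrain$lr)
      weights_t <- unflatten_params(upd$params, weights_t)
      adam_t <- upd$state
      if (config$queue_size > 0) {
        queue_t <- queue_push(queue_t, fp$z, config$queue_size)
      }
    }

    history[[it]] <- tibble::tibble(step = it, l_s = l_s, l_t = l_t,
                                    l_total = total_loss(l_s, l_t))
  }

  structure(
    list(spatial = weights_s, temporal = weights_t, bn_state = bn_state,
         graphs = graphs, config = config,
         history = dplyr::bind_rows(history),
         score_cache = score_cache, aug_segments_key = NULL),
    class = "eeg_checkpoint")
}

#' @export
print.eeg_checkpoint <- function(x, ...) {
  branches <- c(if (!is.null(x$spatial)) "spatial",
                if (!is.null(x$temporal)) "temporal")
  cat(sprintf("<eeg_checkpoint> branches: %s; %d pretraining steps\n",
              paste(branches, collapse = " + "), nrow(x$history)))
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final losses: L_S = %.4f, L_T = %.4f, L = %.4f\n",
                last$l_s, last$l_t, last$l_total))
  }
  invisible(x)
}

# ---- fine-tuning and evaluation -------------------------------------------

assign_folds <- function(meta, k, split_unit, seed) {
  for (try in 0:4) {
    fold_of <- local_seed(seed + try, {
      if (split_unit == "trial") {
        groups <- dplyr::distinct(meta, .data$subject, .data$video,
                                  .data$class)
        groups$fold <- NA_integer_
        for (cl in unique(groups$class)) {
          idx <- sample(which(groups$class == cl))
          groups$fold[idx] <- rep_len(seq_len(k), length(idx))
        }
        dplyr::left_join(meta, groups,
                         by = c("subject", "video", "class"))$fold
      } else {
        fold <- rep(NA_integer_, nrow(meta))
        for (cl in unique(meta$class)) {
          idx <- sample(which(meta$class == cl))
          fold[idx] <- rep_len(seq_len(k), length(idx))
        }
        fold
      }
    })
    ok <- all(vapply(seq_len(k), function(f) {
      length(unique(meta$class[fold_of != f])) ==
        length(unique(meta$class)) && any(fold_of == f)
    }, logical(1)))
    if (ok) return(fold_of)
  }
  abort("Could not build folds with every class present in each training set.")
}

model_forward <- function(model, segments, ids, meta_by_id, config, cache,
                          train, x_override = NULL) {
  n <- length(ids)
  z_total <- NULL
  sp_fw <- tp_fw <- NULL
  if (!is.null(model$spatial)) {
    C <- dim(segments)[3]
    L <- dim(segments)[2]
    Xb <- array(0, dim = c(n, C, L))
    adj <- vector("list", n)
    for (i in seq_len(n)) {
      xm <- if (is.null(x_override)) segment_matrix(segments, ids[i]) else
        x_override[[i]]
      Xb[i, , ] <- t(xm)
      adj[[i]] <- segment_adjacency(model$graphs, meta_by_id[ids[i], ], config)
    }
    sp_fw <- spatial_forward(model$spatial, Xb, adj, config$spatial,
                             model$bn_state, train = train)
    z_total <- sp_fw$z
  }
  if (!is.null(model$temporal)) {
    keys <- if (is.null(x_override)) paste0("o", ids) else
      paste0("x", seq_len(n))  # uncacheable ad-hoc inputs
    tp_cache <- if (is.null(x_override)) cache else NULL
    tp_fw <- temporal_batch_forward(model$temporal, segments, ids, keys,
                                    config, tp_cache,
                                    x_override = x_override)
    z_total <- if (is.null(z_total)) tp_fw$z else z_total + tp_fw$z
  }
  list(z = z_total, sp_fw = sp_fw, tp_fw = tp_fw)
}

softmax_ce <- function(logits, y) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y)], 1e-12)))
  dlogits <- p
  dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
  list(loss = loss, dlogits = dlogits / n)
}

#' Fine-tune the pretrained encoders and evaluate by cross-validation
#'
#' Adds a linear classifier with softmax cross-entropy on the summed
#' representation `Z = Z_T + Z_S`, unfreezes the encoders, and runs k-fold
#' cross-validation (folds keep all segments of a trial together by default,
#' stratified by class).
#'
#' @param session Labelled session.
#' @param checkpoint An [pretrain()] checkpoint.
#' @param config The [run_config()]; `finetune$epochs`, `finetune$batch_size`
#'   and `cv_folds` control this stage.
#' @param shuffle_labels Permute class labels before training (null
#'   calibration check).
#' @param keep_models Retain per-fold fitted models (needed by
#'   [noise_perturbation_eval()]).
#' @return An object of class `eval_report`: per-fold accuracies, mean and
#'   SD, pooled confusion matrix, and run metadata.
#' @export
finetune_and_evaluate <- function(session, checkpoint,
                                  config = checkpoint$config,
                                  shuffle_labels = FALSE,
                                  keep_models = FALSE) {
  meta <- session$meta
  segments <- session$segments
  labels <- meta$class
  if (shuffle_labels) {
    # permute at the split-unit level: under trial-level CV a segment-level
    # shuffle would place differently relabelled windows of one trial on
    # both sides of a fold, which is a leakage test, not a null calibration
    labels <- local_seed(config$seed + 999L, {
      if (config$split_unit == "trial") {
        key <- paste(meta$subject, meta$video)
        uk <- unique(key)
        perm <- sample(meta$class[match(uk, key)])
        perm[match(key, uk)]
      } else {
        sample(labels)
      }
    })
  }
  classes <- sort(unique(labels))
  K <- length(classes)
  y_all <- match(labels, classes)
  meta_by_id <- meta[match(seq_len(nrow(meta)), meta$segment_id), ]
  fold_of <- assign_folds(dplyr::mutate(meta, class = labels),
                          config$cv_folds, config$split_unit, config$seed)
  fe <- config$temporal$embed_dim
  cache <- checkpoint$score_cache %||% new.env(parent = emptyenv())

  per_fold <- vector("list", config$cv_folds)
  confusion <- matrix(0L, K, K, dimnames = list(true = classes,
                                                pred = classes))
  models <- vector("list", config$cv_folds)

  for (f in seq_len(config$cv_folds)) {
    set.seed(config$seed * 131L + f)
    train_ids <- meta$segment_id[fold_of != f]
    test_ids <- meta$segment_id[fold_of == f]
    model <- list(spatial = checkpoint$spatial,
                  temporal = checkpoint$temporal,
                  bn_state = checkpoint$bn_state,
                  graphs = checkpoint$graphs)
    clf <- local_seed(config$seed * 7L + f,
                      list(W = init_matrix(fe, K), b = rep(0, K)))
    params <- flatten_params(list(s = model$spatial %||% list(),
                                  t = model$temporal %||% list(),
                                  c = clf))
    adam <- adam_init(params)
    for (ep in seq_len(config$finetune$epochs)) {
      order_ids <- sample(train_ids)
      splits <- split(order_ids,
                      ceiling(seq_along(order_ids) /
                                config$finetune$batch_size))
      if (length(splits) > 1 && length(splits[[length(splits)]]) < 2) {
        # a singleton batch would degenerate the batch-norm statistics
        n <- length(splits)
        splits[[n - 1]] <- c(splits[[n - 1]], splits[[n]])
        splits[[n]] <- NULL
      }
      for (batch_ids in splits) {
        fw <- model_forward(model, segments, batch_ids, meta_by_id, config,
                            cache, train = TRUE)
        if (!is.null(fw$sp_fw)) model$bn_state <- fw$sp_fw$bn_state
        logits <- fw$z %*% clf$W +
          matrix(clf$b, nrow(fw$z), K, byrow = TRUE)
        ce <- softmax_ce(logits, y_all[batch_ids])
        dZ <- ce$dlogits %*% t(clf$W)
        grads <- list(c = list(W = crossprod(fw$z, ce$dlogits),
                               b = colSums(ce$dlogits)))
        if (!is.null(fw$sp_fw)) {
          grads$s <- spatial_backward(model$spatial, fw$sp_fw$cache, dZ,
                                      config$spatial)
        }
        if (!is.null(fw$tp_fw)) {
          grads$t <- temporal_batch_backward(model$temporal, fw$tp_fw$caches,
                                             dZ)
        }
        params <- flatten_params(list(s = model$spatial %||% list(),
                                      t = model$temporal %||% list(),
                                      c = clf))
        upd <- adam_step(params, flatten_params(grads), adam,
                         lr = config$finetune$lr)
        adam <- upd$state
        if (!is.null(model$spatial)) {
          model$spatial <- unflatten_params(upd$params, model$spatial,
                                            prefix = "s")
        }
        if (!is.null(model$temporal)) {
          model$temporal <- unflatten_params(upd$params, model$temporal,
                                             prefix = "t")
        }
        clf <- unflatten_params(upd$params, clf, prefix = "c")
      }
    }
    pred <- predict_classes(model, clf, segments, test_ids, meta_by_id,
                            config, cache)
    acc <- mean(pred == y_all[test_ids])
    for (i in seq_along(test_ids)) {
      confusion[y_all[test_ids[i]], pred[i]] <-
        confusion[y_all[test_ids[i]], pred[i]] + 1L
    }
    per_fold[[f]] <- tibble::tibble(fold = f, accuracy = acc,
                                    n_test = length(test_ids))
    if (keep_models) {
      models[[f]] <- list(model = model, clf = clf, test_ids = test_ids)
    }
  }

  per_fold <- dplyr::bind_rows(per_fold)
  structure(
    list(per_fold = per_fold,
         mean_accuracy = mean(per_fold$accuracy),
         sd_accuracy = sd(per_fold$accuracy),
         confusion = confusion,
         metadata = list(config_hash = rlang::hash(config),
                         seed = config$seed, gc_scope = config$gc_scope,
                         split_unit = config$split_unit,
                         shuffle_labels = shuffle_labels,
                         timestamp = format(Sys.time())),
         models = if (keep_models) models,
         classes = classes,
         session_meta = meta, labels_used = labels, fold_of = fold_of,
         config = config, score_cache = cache),
    class = "eval_report")
}

predict_classes <- function(model, clf, segments, ids, meta_by_id, config,
                            cache, x_override = NULL) {
  fw <- model_forward(model, segments, ids, meta_by_id, config, cache,
                      train = FALSE, x_override = x_override)
  logits <- fw$z %*% clf$W + matrix(clf$b, nrow(fw$z), ncol(clf$W),
                                    byrow = TRUE)
  max.col(logits, ties.method = "first")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d-fold CV accuracy: %.3f +/- %.3f\n",
              nrow(x$per_fold), x$mean_accuracy, x$sd_accuracy))
  print(x$per_fold)
  invisible(x)
}

#' Evaluate robustness to additive input noise
#'
#' Re-evaluates the fine-tuned per-fold models on test inputs perturbed with
#' additive Gaussian noise whose SD is `level` times each channel's SD within
#' the segment. Level 0 reproduces the clean cross-validated accuracy
#' exactly.
#'
#' @param session Labelled session (the one evaluated).
#' @param report An [finetune_and_evaluate()] report with `keep_models =
#'   TRUE`.
#' @param levels Noise fractions, e.g. `c(0, 0.01, 0.05, 0.10, 0.20)`.
#' @param config Run configuration (defaults to the report's).
#' @return Tibble with `level` and pooled `accuracy`.
#' @export
noise_perturbation_eval <- function(session, report,
                                    levels = c(0, 0.01, 0.05, 0.10, 0.20),
                                    config = report$config) {
  if (is.null(report$models)) {
    abort("Run finetune_and_evaluate() with keep_models = TRUE first.")
  }
  segments <- session$segments
  meta_by_id <- report$session_meta[
    match(seq_len(nrow(report$session_meta)),
          report$session_meta$segment_id), ]
  classes <- report$classes
  y_all <- match(report$labels_used, classes)
  purrr::map_dfr(levels, function(level) {
    correct <- 0L
    total <- 0L
    for (f in seq_along(report$models)) {
      m <- report$models[[f]]
      ids <- m$test_ids
      if (level == 0) {
        pred <- predict_classes(m$model, m$clf, segments, ids, meta_by_id,
                                config, report$score_cache)
      } else {
        xs <- local_seed(config$seed * 1000L + f + round(level * 1e4), {
          lapply(ids, function(id) {
            x <- segment_matrix(segments, id)
            sds <- apply(x, 2, sd)
            x + matrix(rnorm(length(x)), nrow(x), ncol(x)) *
              rep(level * sds, each = nrow(x))
          })
        })
        pred <- predict_classes(m$model, m$clf, segments, ids, meta_by_id,
                                config, NULL, x_override = xs)
      }
      correct <- correct + sum(pred == y_all[ids])
      total <- total + length(ids)
    }
    tibble::tibble(level = level, accuracy = correct / total)
  })
}
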