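# The frequency-pyramid network: per-pathway stacks of frequency-domain GCN
# layers over partition-restricted skeleton graphs, coarse-to-fine
# cross-domain fusion, mean pooling and a linear head. Forward and backward
# passes are hand-derived; training batches use the internal layout
# (C, V, T, N) so the (C, V) block flattens contiguously into the spatial
# FFT axis.

#' Model configuration for the pyramid classifier
#'
#' @param layout Layout name or `fpgait_layout` object; supplies the
#'   skeleton graph and default partition. Alternatively pass `graph` and
#'   `partition` explicitly (e.g. for toy models).
#' @param n_classes Number of gait classes `K >= 2`.
#' @param frames Frames `T` the model operates on.
#' @param channels_in Input coordinate channels (defaults to the layout's).
#' @param widths Channel width per pathway, coarse to fine. The default
#'   64/48/32 realises the "heavier global, lighter limb" capacity
#'   ordering; the reduced benchmark model uses 16/12/8.
#' @param depth Layers per pathway (same for all pathways).
#' @param variant `"fpgcn"` (full model), `"fgcn_only"` (global pathway
#'   only, no fusion), `"pgcn_only"` (pyramid with the spectral weighting
#'   frozen at identity), or `"tcn"` (global pathway with the fixed-window
#'   temporal-convolution baseline layer in place of the spectral layer).
#' @param slope LeakyReLU negative slope.
#' @param epsilon Default label-smoothing factor carried into training.
#' @param tcn_stride Temporal window `s_d` of the `"tcn"` variant.
#' @param graph,partition Optional explicit [skeleton_graph()] and
#'   [partition_scheme()] overriding the layout's.
#' @return A `fpgcn_config` list.
#' @export
model_config <- function(layout = "kinect25", n_classes, frames,
                         channels_in = NULL, widths = c(64, 48, 32),
                         depth = 2, variant = c("fpgcn", "fgcn_only",
                                                "pgcn_only", "tcn"),
                         slope = 0.01, epsilon = 0.1, tcn_stride = 5,
                         graph = NULL, partition = NULL) {
  variant <- match.arg(variant)
  if (!is_count(n_classes, min = 2)) abort_validation("n_classes must be >= 2")
  if (!is_count(depth)) abort_validation("depth must be >= 1")
  if (!is_count(frames, min = 2)) abort_validation("frames must be >= 2")
  layout_name <- NULL
  if (is.null(graph)) {
    if (is.character(layout)) layout <- skeleton_layout(layout)
    stopifnot(inherits(layout, "fpgait_layout"))
    layout_name <- layout$name
    graph <- layout$graph
    channels_in <- channels_in %||% layout$n_channels
    if (is.null(partition)) partition <- default_partition(graph, layout)
  } else {
    if (is.null(partition)) {
      partition <- partition_scheme(
        list(global = list(all = seq_len(graph$n_joints) - 1L))
      )
    }
    if (is.null(channels_in)) abort_config("channels_in required with explicit graph")
  }
  single_path <- variant %in% c("fgcn_only", "tcn")
  n_path <- if (single_path) 1L else length(partition$pathways)
  widths <- rep_len(as.integer(widths), length(partition$pathways))[seq_len(n_path)]
  structure(
    list(
      layout = layout_name,
      graph = graph,
      partition = partition,
      n_classes = as.integer(n_classes),
      frames = as.integer(frames),
      channels_in = as.integer(channels_in),
      widths = widths,
      depth = as.integer(depth),
      variant = variant,
      slope = slope,
      epsilon = epsilon,
      tcn_stride = as.integer(tcn_stride),
      n_pathways = n_path,
      fuse = !single_path && n_path > 1L
    ),
    class = "fpgcn_config"
  )
}

#' Cross-domain fusion parameters
#'
#' @param fine_width,coarse_width Channel widths of the receiving (fine)
#'   and injecting (coarse) pathway features.
#' @return A `fusion_params` list with `W_fine` (`Cf x Cf`), `W_coarse`
#'   (`Cc x Cc`) and the post-concatenation projection `W_out`
#'   (`Cf x (Cf+Cc)`), initialised as a pass-through of the fine branch.
#' @export
fusion_params <- function(fine_width, coarse_width) {
  structure(
    list(
      W_fine = diag(1, fine_width),
      W_coarse = diag(1, coarse_width),
      W_out = cbind(diag(1, fine_width),
                    matrix(0, fine_width, coarse_width))
    ),
    class = "fusion_params"
  )
}

init_layer_params <- function(cfg, c_in, c_out, pg) {
  w <- list(
    W_proj = matrix(rnorm(c_out * c_in, sd = sqrt(2 / (c_in + c_out))),
                    c_out, c_in),
    b = rep(0, c_out)
  )
  if (cfg$variant == "tcn") {
    w$W_kt <- matrix(rnorm(c_out * cfg$tcn_stride,
                           sd = sqrt(1 / cfg$tcn_stride)),
                     c_out, cfg$tcn_stride)
  } else {
    w$W_E <- rep(1, nrow(pg$edges) + pg$n_joints)
    w$W_A <- rep(1, c_out * pg$n_joints)
    w$W_F <- rep(1, cfg$frames %/% 2 + 1L)
  }
  w
}

#' Initialise a pyramid model
#'
#' Draws the projection and head weights from seeded Gaussians and sets all
#' edge weights and spectral masks to 1, so every untrained spectral layer
#' starts as a near-identity filter.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the weight draws.
#' @return An `fpgcn_model`.
#' @export
fpgcn_init <- function(config, seed = 1L) {
  stopifnot(inherits(config, "fpgcn_config"))
  withr::with_seed(seed, {
    pgraphs <- lapply(
      config$partition$pathways[seq_len(config$n_pathways)],
      function(subsets) pathway_graph(config$graph, subsets)
    )
    params <- list(pathways = list(), fusions = list(), head = NULL)
    for (p in seq_len(config$n_pathways)) {
      layers <- vector("list", config$depth)
      for (i in seq_len(config$depth)) {
        c_in <- if (i == 1L) config$channels_in else config$widths[p]
        layers[[i]] <- init_layer_params(config, c_in, config$widths[p],
                                         pgraphs[[p]])
      }
      params$pathways[[p]] <- list(layers = layers)
    }
    if (config$fuse) {
      for (p in 2:config$n_pathways) {
        params$fusions[[p]] <- vector("list", config$depth)
        for (i in seq_len(config$depth)) {
          fine_w <- if (i == 1L) config$channels_in else config$widths[p]
          params$fusions[[p]][[i]] <- fusion_params(fine_w, config$widths[p - 1L])
        }
      }
    }
    emb_w <- sum(config$widths)
    params$head <- list(
      gamma = rep(1, emb_w),
      beta = rep(0, emb_w),
      W = matrix(rnorm(config$n_classes * emb_w, sd = sqrt(1 / emb_w)),
                 config$n_classes, emb_w),
      b = rep(0, config$n_classes)
    )
    structure(
      list(config = config, pgraphs = pgraphs, params = params,
           bn_running = list(mean = rep(0, emb_w), var = rep(1, emb_w))),
      class = "fpgcn_model")
  })
}

#' @export
print.fpgcn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<fpgcn_model> variant %s: %d pathway(s) x depth %d, widths %s, K = %d, T = %d, V = %d\n",
    cfg$variant, cfg$n_pathways, cfg$depth,
    paste(cfg$widths, collapse = "/"), cfg$n_classes, cfg$frames,
    cfg$graph$n_joints
  ))
  cat(sprintf("  parameters: %d\n", length(unlist(x$params))))
  invisible(x)
}

# ---------------------------------------------------------------------------
# internal batched forward / backward

# (C,T,V) array -> (C,V,T) array
ctv_to_cvt <- function(x) aperm(x, c(1, 3, 2))
cvt_to_ctv <- function(x) aperm(x, c(1, 3, 2))

stack_sequences <- function(xs) {
  d <- dim(xs[[1]])
  out <- array(0, c(d[1], d[3], d[2], length(xs)))
  for (i in seq_along(xs)) out[, , , i] <- ctv_to_cvt(xs[[i]])
  out
}

expand_temporal_mask <- function(mt, T) {
  Fb <- length(mt)
  if (T %% 2 == 0L) c(mt, rev(mt[seq.int(2L, Fb - 1L)])) else c(mt, rev(mt[seq.int(2L, Fb)]))
}

fold_temporal_grad <- function(dmt_full, T) {
  Fb <- T %/% 2 + 1L
  dmt <- dmt_full[seq_len(Fb)]
  if (T %% 2 == 0L) {
    idx <- seq.int(2L, Fb - 1L)
  } else {
    idx <- seq.int(2L, Fb)
  }
  if (length(idx)) dmt[idx] <- dmt[idx] + rev(dmt_full[seq.int(Fb + 1L, T)])
  dmt
}

sym_spatial <- function(a) {
  S <- length(a)
  rev_idx <- c(1L, rev(seq_len(S - 1L) + 1L))
  (a + a[rev_idx]) / 2
}

# One spectral-GCN layer on a (C_in, V, T, N) batch (compiled kernel).
layer_forward <- function(X, lw, pg, cfg, spectral, keep_cache = TRUE) {
  d <- dim(X)
  V <- d[2]; T <- d[3]; N <- d[4]
  M <- aggregation_matrix(pg, lw$W_E)
  if (spectral) {
    g <- mean(leaky_relu(lw$W_E, cfg$slope))
    a_act <- leaky_relu(g * lw$W_A, cfg$slope)
    ms <- sym_spatial(a_act)
    mt_full <- expand_temporal_mask(leaky_relu(lw$W_F, cfg$slope), T)
  } else {
    g <- 0; a_act <- numeric(0); ms <- numeric(0); mt_full <- numeric(0)
  }
  res <- fgcn_layer_fwd_cpp(array(X, c(d[1], V, T * N)), lw$W_proj, lw$b, M,
                            spectral, ms, mt_full, cfg$slope, T, N)
  c_out <- nrow(lw$W_proj)
  out <- array(res$out, c(c_out, V, T, N))
  cache <- NULL
  if (keep_cache) {
    cache <- list(X = X, h = res$h, a = res$a, y = res$y, fx = res$fx,
                  M = M, ms = ms, mt_full = mt_full, g = g, a_act = a_act,
                  spectral = spectral)
  }
  list(out = out, cache = cache)
}

layer_backward <- function(dout, lw, pg, cfg, cache) {
  d <- dim(dout)
  c_out <- d[1]; V <- d[2]; T <- d[3]; N <- d[4]
  res <- fgcn_layer_bwd_cpp(array(dout, c(c_out, V, T * N)),
                            array(cache$X, c(dim(cache$X)[1], V, T * N)),
                            cache$h, cache$a, cache$y, cache$fx,
                            lw$W_proj, cache$M, cache$spectral, cache$ms,
                            cache$mt_full, cfg$slope, T, N)
  grads <- list(W_proj = res$dw, b = as.numeric(res$db))
  if (cache$spectral) {
    G <- res$g
    dms <- as.numeric(G %*% cache$mt_full)
    dmt_full <- as.numeric(crossprod(G, cache$ms))
    da_act <- sym_spatial(dms)
    ga <- cache$g * lw$W_A
    grads$W_A <- leaky_relu_grad(ga, cfg$slope) * cache$g * da_act
    dg <- sum(leaky_relu_grad(ga, cfg$slope) * lw$W_A * da_act)
    dWE_spec <- dg * leaky_relu_grad(lw$W_E, cfg$slope) / length(lw$W_E)
    grads$W_F <- leaky_relu_grad(lw$W_F, cfg$slope) *
      fold_temporal_grad(dmt_full, T)
  } else {
    dWE_spec <- 0
  }
  # edge-weight gradient through M[u,v] = w_e / d_u
  dM <- res$dm
  k <- nrow(pg$edges)
  dWE <- numeric(k + V)
  if (k > 0) {
    iu <- pg$edges[, 1] + 1L; iv <- pg$edges[, 2] + 1L
    dWE[seq_len(k)] <- dM[cbind(iu, iv)] / pg$degrees[iu] +
      dM[cbind(iv, iu)] / pg$degrees[iv]
  }
  dWE[k + seq_len(V)] <- diag(dM) / pg$degrees
  grads$W_E <- dWE + dWE_spec
  if (cfg$variant == "pgcn_only") {
    # masks are frozen at identity in this variant
    grads$W_A <- NULL; grads$W_F <- NULL
  }
  dX <- array(res$dx, dim(cache$X))
  list(dX = dX, grads = grads)
}

# TCN baseline layer (global pathway of the "tcn" variant).
tcn_layer_forward <- function(X, lw, pg, cfg, keep_cache = TRUE) {
  d <- dim(X)
  V <- d[2]; T <- d[3]; N <- d[4]
  res <- tcn_layer_fwd_cpp(array(X, c(d[1], V, T * N)), lw$W_proj, lw$b,
                           pg$adjacency, lw$W_kt, T, N)
  c_out <- nrow(lw$W_proj)
  out <- array(res$out, c(c_out, V, T, N))
  cache <- if (keep_cache) list(X = X, nb = res$nb, z = res$z) else NULL
  list(out = out, cache = cache)
}

tcn_layer_backward <- function(dout, lw, pg, cfg, cache) {
  d <- dim(dout)
  res <- tcn_layer_bwd_cpp(array(dout, c(d[1], d[2], d[3] * d[4])),
                           array(cache$X, c(dim(cache$X)[1], d[2],
                                            d[3] * d[4])),
                           cache$nb, cache$z, lw$W_proj, pg$adjacency,
                           lw$W_kt, d[3], d[4])
  list(dX = array(res$dx, dim(cache$X)),
       grads = list(W_proj = res$dw, b = as.numeric(res$db),
                    W_kt = res$dkern))
}

fuse_forward <- function(Xf, Xc, fp, keep_cache = TRUE) {
  df <- dim(Xf)
  U1 <- fp$W_fine %*% matrix(Xf, df[1])
  U2 <- fp$W_coarse %*% matrix(Xc, dim(Xc)[1])
  Zc <- rbind(U1, U2)
  out <- array(fp$W_out %*% Zc, c(nrow(fp$W_out), df[2], df[3], df[4]))
  cache <- if (keep_cache) {
    list(Xf = Xf, Xc = Xc, Zc = Zc, df = df, dc = dim(Xc))
  } else NULL
  list(out = out, cache = cache)
}

fuse_backward <- function(dout, fp, cache) {
  dom <- matrix(dout, dim(dout)[1])
  dW_out <- tcrossprod(dom, cache$Zc)
  dZc <- crossprod(fp$W_out, dom)
  cf <- nrow(fp$W_fine); cc <- nrow(fp$W_coarse)
  dU1 <- dZc[seq_len(cf), , drop = FALSE]
  dU2 <- dZc[cf + seq_len(cc), , drop = FALSE]
  Xfm <- matrix(cache$Xf, cf)
  Xcm <- matrix(cache$Xc, cc)
  list(
    dXf = array(crossprod(fp$W_fine, dU1), cache$df),
    dXc = array(crossprod(fp$W_coarse, dU2), cache$dc),
    grads = list(
      W_fine = tcrossprod(dU1, Xfm),
      W_coarse = tcrossprod(dU2, Xcm),
      W_out = dW_out
    )
  )
}

# Full forward on a (C, V, T, N) batch. Returns scores (K x N) and, when
# training, all caches needed by network_backward().
network_forward <- function(model, X, keep_cache = FALSE) {
  cfg <- model$config
  P <- cfg$n_pathways
  spectral <- cfg$variant %in% c("fpgcn", "fgcn_only")
  is_tcn <- cfg$variant == "tcn"
  feats <- rep(list(X), P)
  caches <- list()
  for (i in seq_len(cfg$depth)) {
    caches[[i]] <- list(layers = vector("list", P),
                        fusions = vector("list", P))
    new_feats <- vector("list", P)
    for (p in seq_len(P)) {
      x_in <- feats[[p]]
      if (cfg$fuse && p > 1L) {
        fz <- fuse_forward(x_in, new_feats[[p - 1L]],
                           model$params$fusions[[p]][[i]], keep_cache)
        caches[[i]]$fusions[[p]] <- fz$cache
        x_in <- fz$out
      }
      lw <- model$params$pathways[[p]]$layers[[i]]
      lz <- if (is_tcn) {
        tcn_layer_forward(x_in, lw, model$pgraphs[[p]], cfg, keep_cache)
      } else {
        layer_forward(x_in, lw, model$pgraphs[[p]], cfg, spectral, keep_cache)
      }
      caches[[i]]$layers[[p]] <- lz$cache
      new_feats[[p]] <- lz$out
    }
    feats <- new_feats
  }
  # mean over joints and frames per item, then embedding standardisation
  pooled <- lapply(feats, apply_mean_pool)
  emb <- do.call(rbind, pooled)
  hd <- model$params$head
  if (keep_cache) {
    mu <- rowMeans(emb)
    s2 <- rowMeans((emb - mu)^2)
  } else {
    mu <- model$bn_running$mean
    s2 <- model$bn_running$var
  }
  s_bn <- sqrt(s2 + 1e-5)
  z <- (emb - mu) / s_bn
  y <- hd$gamma * z + hd$beta
  scores <- hd$W %*% y + hd$b
  list(scores = scores, emb = emb, z = z, s_bn = s_bn, y = y,
       batch_mean = mu, batch_var = s2, feats = feats, caches = caches)
}

apply_mean_pool <- function(f) {
  dd <- dim(f)
  m <- matrix(aperm(f, c(1, 4, 2, 3)), dd[1] * dd[4])
  matrix(rowMeans(m), dd[1], dd[4])
}

network_backward <- function(model, fw, dscores) {
  cfg <- model$config
  P <- cfg$n_pathways
  is_tcn <- cfg$variant == "tcn"
  hd <- model$params$head
  dW_head <- tcrossprod(dscores, fw$y)
  db_head <- rowSums(dscores)
  dy <- crossprod(hd$W, dscores)
  dgamma <- rowSums(dy * fw$z)
  dbeta <- rowSums(dy)
  dz <- dy * hd$gamma
  # exact backward of per-dimension batch standardisation
  demb <- (dz - rowMeans(dz) - fw$z * rowMeans(dz * fw$z)) / fw$s_bn
  grads <- list(pathways = vector("list", P),
                fusions = vector("list", P),
                head = list(gamma = dgamma, beta = dbeta,
                            W = dW_head, b = db_head))
  offset <- 0L
  dfeats <- vector("list", P)
  for (p in seq_len(P)) {
    w <- cfg$widths[p]
    dpool <- demb[offset + seq_len(w), , drop = FALSE]
    offset <- offset + w
    dd <- dim(fw$feats[[p]])
    df <- array(0, dd)
    scale <- 1 / (dd[2] * dd[3])
    # broadcast pooled gradient back over joints and frames
    df <- aperm(array(rep(dpool, times = dd[2] * dd[3]) * scale,
                      c(w, dd[4], dd[2], dd[3])), c(1, 3, 4, 2))
    dfeats[[p]] <- df
    grads$pathways[[p]] <- list(layers = vector("list", cfg$depth))
    if (cfg$fuse && p > 1L) grads$fusions[[p]] <- vector("list", cfg$depth)
  }
  for (i in rev(seq_len(cfg$depth))) {
    new_dfeats <- vector("list", P)
    for (p in rev(seq_len(P))) {
      lw <- model$params$pathways[[p]]$layers[[i]]
      bk <- if (is_tcn) {
        tcn_layer_backward(dfeats[[p]], lw, model$pgraphs[[p]], cfg,
                           fw$caches[[i]]$layers[[p]])
      } else {
        layer_backward(dfeats[[p]], lw, model$pgraphs[[p]], cfg,
                       fw$caches[[i]]$layers[[p]])
      }
      grads$pathways[[p]]$layers[[i]] <- bk$grads
      dx <- bk$dX
      if (cfg$fuse && p > 1L) {
        fb <- fuse_backward(dx, model$params$fusions[[p]][[i]],
                            fw$caches[[i]]$fusions[[p]])
        grads$fusions[[p]][[i]] <- fb$grads
        new_dfeats[[p]] <- add_or_init(new_dfeats[[p]], fb$dXf)
        # coarse branch feeds the previous pathway's *current-depth* output
        dfeats[[p - 1L]] <- dfeats[[p - 1L]] + fb$dXc
      } else {
        new_dfeats[[p]] <- add_or_init(new_dfeats[[p]], dx)
      }
    }
    dfeats <- new_dfeats
  }
  grads
}

add_or_init <- function(acc, x) if (is.null(acc)) x else acc + x

# ---------------------------------------------------------------------------
# public forward surface

as_batch <- function(x, config) {
  if (is.array(x) && length(dim(x)) == 3L) x <- list(x)
  if (inherits(x, "gait_dataset") || (is.data.frame(x) && "seq" %in% names(x))) {
    x <- lapply(x$seq, function(s) s$values)
  }
  if (is.list(x) && all(vapply(x, is.array, logical(1)))) {
    d <- dim(x[[1]])
    if (d[1] != config$channels_in || d[3] != config$graph$n_joints ||
        d[2] != config$frames) {
      abort_validation(
        "sequence shape (%s) does not match model (C=%d, T=%d, V=%d)",
        paste(d, collapse = "x"), config$channels_in, config$frames,
        config$graph$n_joints)
    }
    return(stack_sequences(x))
  }
  abort_validation("cannot interpret input as skeleton sequences")
}

#' Pyramid network forward pass
#'
#' Runs all pathways with cross-domain fusion, mean-pools each pathway's
#' final feature map over frames and joints, concatenates the pathway
#' embeddings and applies the linear head.
#'
#' @param model An [fpgcn_init()] model (possibly trained).
#' @param x A `(C, T, V)` array, a list of such arrays, or a
#'   `gait_dataset`.
#' @return Numeric `n x K` matrix of unnormalised class scores.
#' @export
fpgcn_forward <- function(model, x) {
  stopifnot(inherits(model, "fpgcn_model"))
  X <- as_batch(x, model$config)
  fw <- network_forward(model, X, keep_cache = FALSE)
  t(fw$scores)
}

#' Single-pathway forward pass
#'
#' Applies one pathway's stack of layers to a sequence without cross-domain
#' fusion (the global pathway of the full model is exactly this).
#'
#' @param x A `(C, T, V)` feature array.
#' @param model An `fpgcn_model`.
#' @param pathway Pathway index (1 = global) or name.
#' @return The pathway's final `(C_p, T, V)` feature map.
#' @export
pathway_forward <- function(x, model, pathway = 1L) {
  cfg <- model$config
  if (is.character(pathway)) {
    pathway <- match(pathway, names(cfg$partition$pathways))
  }
  if (is.na(pathway) || pathway < 1L || pathway > cfg$n_pathways) {
    abort_validation("unknown pathway")
  }
  X <- as_batch(x, cfg)
  spectral <- cfg$variant %in% c("fpgcn", "fgcn_only")
  for (i in seq_len(cfg$depth)) {
    lw <- model$params$pathways[[pathway]]$layers[[i]]
    X <- if (cfg$variant == "tcn") {
      tcn_layer_forward(X, lw, model$pgraphs[[pathway]], cfg, FALSE)$out
    } else {
      layer_forward(X, lw, model$pgraphs[[pathway]], cfg, spectral, FALSE)$out
    }
  }
  cvt_to_ctv(array(X, dim(X)[1:3]))
}

#' Cross-domain fusion of two pathway feature maps
#'
#' Applies the per-branch linear weights, concatenates fine and coarse
#' features along channels and projects back to the fine pathway's width.
#' Coarse features are aligned to the fine pathway by joint index (all
#' pathways cover the full joint set, so no interpolation is needed).
#'
#' @param fine `(Cf, T, V)` feature array of the receiving pathway.
#' @param coarse `(Cc, T, V)` feature array of the coarser pathway.
#' @param params A [fusion_params()].
#' @return `(Cf, T, V)` fused feature array.
#' @export
cross_domain_fuse <- function(fine, coarse, params) {
  df <- dim(fine); dc <- dim(coarse)
  if (length(df) != 3L || length(dc) != 3L || any(df[2:3] != dc[2:3])) {
    abort_validation("fine and coarse features must share frames and joints")
  }
  if (df[1] != nrow(params$W_fine) || dc[1] != nrow(params$W_coarse)) {
    abort_validation("fusion weights do not match feature widths")
  }
  out <- fuse_forward(array(ctv_to_cvt(fine), c(df[1], df[3], df[2], 1)),
                      array(ctv_to_cvt(coarse), c(dc[1], dc[3], dc[2], 1)),
                      params, keep_cache = FALSE)$out
  cvt_to_ctv(array(out, dim(out)[1:3]))
}

#' Label-smoothed cross-entropy loss
#'
#' Cross-entropy of softmax scores against smoothed targets that put
#' `1 - epsilon` on the true class and `epsilon / (K - 1)` on every other
#' class, averaged over the batch. `epsilon = 0` recovers the standard
#' cross-entropy.
#'
#' @param scores `n x K` matrix of unnormalised class scores.
#' @param labels Integer class labels in `1..K`, length `n`.
#' @param epsilon Smoothing factor in `[0, 1)`.
#' @return Scalar loss.
#' @export
label_smoothed_loss <- function(scores, labels, epsilon = 0.1) {
  scores <- as.matrix(scores)
  K <- ncol(scores)
  n <- nrow(scores)
  if (epsilon < 0 || epsilon >= 1) {
    abort_validation("epsilon must be in [0, 1)")
  }
  labels <- as.integer(labels)
  if (any(labels < 1L) || any(labels > K)) {
    abort_validation("labels must be in 1..%d", K)
  }
  lp <- log_softmax_rows(scores)
  q <- matrix(epsilon / (K - 1), n, K)
  q[cbind(seq_len(n), labels)] <- 1 - epsilon
  -sum(q * lp) / n
}

log_softmax_rows <- function(scores) {
  m <- apply(scores, 1, max)
  z <- scores - m
  z - log(rowSums(exp(z)))
}

smoothed_ce_grad <- function(scores_kn, labels, epsilon) {
  # scores K x N; returns K x N gradient of the mean loss
  K <- nrow(scores_kn); n <- ncol(scores_kn)
  z <- scores_kn - rep(apply(scores_kn, 2, max), each = K)
  p <- exp(z)
  p <- p / rep(colSums(p), each = K)
  q <- matrix(epsilon / (K - 1), K, n)
  q[cbind(labels, seq_len(n))] <- 1 - epsilon
  (p - q) / n
}

# ---------------------------------------------------------------------------
# parameter utilities (flatten / update), used by SGD and gradient checks

param_vector <- function(params) unlist(params, use.names = FALSE)

param_relist <- function(vec, skeleton) {
  pos <- 0L
  fill <- function(sk) {
    if (is.null(sk)) return(NULL)
    if (is.list(sk)) {
      out <- sk
      for (j in seq_along(sk)) {
        val <- fill(sk[[j]])
        if (is.null(val)) out[j] <- list(NULL) else out[[j]] <- val
      }
      return(out)
    }
    n <- length(sk)
    val <- vec[pos + seq_len(n)]
    pos <<- pos + n
    dim(val) <- dim(sk)
    val
  }
  out <- fill(skeleton)
  stopifnot(pos == length(vec))
  out
}

# elementwise walk over two parallel nested lists of numerics; the second
# list may be missing entries (treated as NULL), so index by name wherever
# names exist
map_params <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    keys <- names(a) %||% seq_along(a)
    for (j in seq_along(a)) {
      key <- if (is.character(keys)) keys[j] else j
      if (is.null(a[[key]])) next
      bb <- if (is.null(b)) NULL else b[[key]]
      out[[key]] <- map_params(a[[key]], bb, f)
    }
    out
  } else {
    f(a, b)
  }
}
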