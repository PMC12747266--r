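# The two-branch regressor. Graph branch: learned element-hybridization
# embedding + 10 numeric node features -> linear projection -> two
# edge-conditioned graph-attention layers (multi-head, ReLU, batch norm,
# dropout) -> concatenated global mean/max pooling (256). Descriptor branch:
# normalized 544-vector -> 256 -> 128 feed-forward. Fusion: [256 || 128 ||
# mol_size] = 385 -> 64 -> 1 producing log10 IC50.

#' Architecture hyperparameters
#'
#' Defaults reproduce the published architecture: a two-layer graph
#' attention network with hidden dimension 128 and two attention heads per
#' layer (per-head width 64, concatenated), dropout 0.2; a descriptor
#' network 544 -> 256 -> 128 with dropout 0.3; and a fusion head
#' 385 -> 64 -> 1 with dropout 0.2. The fused width is
#' `2 * gat_hidden + desc_dims[3] + 1 = 385` under defaults.
#'
#' @param gat_hidden GAT hidden width (mean+max pooling doubles it).
#' @param gat_layers number of attention layers.
#' @param gat_heads attention heads per layer; must divide `gat_hidden`.
#' @param gat_dropout,desc_dropout,head_dropout dropout rates per branch.
#' @param desc_dims descriptor branch widths `c(in, hidden, out)`.
#' @param head_hidden fusion head hidden width.
#' @param atom_embed_dim width of the learned element-hybridization
#'   embedding table.
#' @param use_graph,use_descriptors branch ablation switches; the fusion
#'   width shrinks accordingly.
#' @param mol_size_scale multiplier applied to the raw molecular-size
#'   feature (1 = fed raw).
#' @param leaky_slope negative slope of the attention LeakyReLU.
#' @param bn_momentum,bn_eps batch-normalization running-statistics momentum
#'   and variance floor.
#' @return a `model_config` list.
#' @export
model_config <- function(gat_hidden = 128L, gat_layers = 2L, gat_heads = 2L,
                         gat_dropout = 0.2,
                         desc_dims = c(544L, 256L, 128L), desc_dropout = 0.3,
                         head_hidden = 64L, head_dropout = 0.2,
                         atom_embed_dim = 32L,
                         use_graph = TRUE, use_descriptors = TRUE,
                         mol_size_scale = 1,
                         leaky_slope = 0.2, bn_momentum = 0.1, bn_eps = 1e-5) {
  if (gat_hidden %% gat_heads != 0L) stopf("gat_heads must divide gat_hidden")
  stopifnot(length(desc_dims) == 3, gat_layers >= 1)
  cfg <- list(
    gat_hidden = as.integer(gat_hidden), gat_layers = as.integer(gat_layers),
    gat_heads = as.integer(gat_heads), gat_dropout = gat_dropout,
    desc_dims = as.integer(desc_dims), desc_dropout = desc_dropout,
    head_hidden = as.integer(head_hidden), head_dropout = head_dropout,
    atom_embed_dim = as.integer(atom_embed_dim),
    use_graph = use_graph, use_descriptors = use_descriptors,
    mol_size_scale = mol_size_scale,
    leaky_slope = leaky_slope, bn_momentum = bn_momentum, bn_eps = bn_eps
  )
  cfg$fused_dim <- as.integer(
    (if (use_graph) 2L * cfg$gat_hidden else 0L) +
      (if (use_descriptors) cfg$desc_dims[3] else 0L) + 1L
  )
  class(cfg) <- "model_config"
  cfg
}

#' Initialize an untrained hybrid model
#'
#' Seeded fan-based (Glorot uniform) initialization of every trainable
#' array; batch-normalization scales start at 1, shifts at 0, running
#' statistics at (0, 1).
#'
#' @param config a [model_config()].
#' @param vocab an `atom_vocab` (fixes the embedding-table rows).
#' @param seed integer seed for the initialization draw.
#' @return an object of class `ic50net_model` (parameters, batch-norm state,
#'   config, vocab).
#' @export
init_ic50net <- function(config = model_config(), vocab = build_atom_vocab(),
                         seed = 1L) {
  stopifnot(inherits(config, "model_config"), inherits(vocab, "atom_vocab"))
  h <- config$gat_hidden
  node_in <- config$atom_embed_dim + (N_NODE_FEATURES - 1L)
  params <- list()
  state <- list()
  with_seed(seed, {
    if (config$use_graph) {
      params$embed <- glorot(vocab$size, config$atom_embed_dim)
      params$in_W <- glorot(node_in, h)
      params$in_b <- numeric(h)
      hd <- h %/% config$gat_heads
      for (l in seq_len(config$gat_layers)) {
        p <- sprintf("gat%d.", l)
        params[[paste0(p, "W")]] <- glorot(h, h)
        params[[paste0(p, "We")]] <- glorot(N_EDGE_FEATURES, h)
        params[[paste0(p, "a_src")]] <- glorot(hd, config$gat_heads, c(hd, config$gat_heads))
        params[[paste0(p, "a_dst")]] <- glorot(hd, config$gat_heads, c(hd, config$gat_heads))
        params[[paste0(p, "a_edge")]] <- glorot(hd, config$gat_heads, c(hd, config$gat_heads))
        params[[paste0(p, "b")]] <- numeric(h)
        params[[paste0(p, "bn_gamma")]] <- rep(1, h)
        params[[paste0(p, "bn_beta")]] <- numeric(h)
        state[[paste0(p, "bn_mean")]] <- numeric(h)
        state[[paste0(p, "bn_var")]] <- rep(1, h)
      }
    }
    if (config$use_descriptors) {
      d <- config$desc_dims
      params$desc.W1 <- glorot(d[1], d[2])
      params$desc.b1 <- numeric(d[2])
      params$desc.bn1_gamma <- rep(1, d[2])
      params$desc.bn1_beta <- numeric(d[2])
      params$desc.W2 <- glorot(d[2], d[3])
      params$desc.b2 <- numeric(d[3])
      params$desc.bn2_gamma <- rep(1, d[3])
      params$desc.bn2_beta <- numeric(d[3])
      state$desc.bn1_mean <- numeric(d[2])
      state$desc.bn1_var <- rep(1, d[2])
      state$desc.bn2_mean <- numeric(d[3])
      state$desc.bn2_var <- rep(1, d[3])
    }
    params$head.W1 <- glorot(config$fused_dim, config$head_hidden)
    params$head.b1 <- numeric(config$head_hidden)
    params$head.bn_gamma <- rep(1, config$head_hidden)
    params$head.bn_beta <- numeric(config$head_hidden)
    params$head.W2 <- glorot(config$head_hidden, 1L)
    params$head.b2 <- 0
    state$head.bn_mean <- numeric(config$head_hidden)
    state$head.bn_var <- rep(1, config$head_hidden)
  })
  structure(list(params = params, state = state, config = config,
                 vocab = vocab, init_seed = as.integer(seed)),
            class = "ic50net_model")
}

#' @export
print.ic50net_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf(
    "<ic50net_model> %s%s fused %d -> %d -> 1; %s parameters\n",
    if (x$config$use_graph) sprintf("GAT %dx(h=%d, heads=%d) + ", x$config$gat_layers,
                                    x$config$gat_hidden, x$config$gat_heads) else "",
    if (x$config$use_descriptors) sprintf("descriptor %s", paste(x$config$desc_dims, collapse = "->")) else "",
    x$config$fused_dim, x$config$head_hidden, format(n_par, big.mark = ",")
  ))
  invisible(x)
}

# --- batch assembly ---------------------------------------------------------

# Concatenate molecular graphs into one block-diagonal batch graph with
# self-loops (zero edge features) so every node receives at least one
# attention edge and softmax groups are never empty.
collate_graphs <- function(graphs) {
  n_nodes <- vapply(graphs, function(g) g$n_nodes, integer(1))
  offsets <- c(0L, cumsum(n_nodes))
  N <- offsets[length(offsets)]
  X <- do.call(rbind, lapply(graphs, function(g) g$node_features))
  dimnames(X) <- NULL
  src <- integer(0); dst <- integer(0)
  ef <- vector("list", length(graphs))
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    if (ncol(g$edge_index)) {
      src <- c(src, g$edge_index[1, ] + offsets[i])
      dst <- c(dst, g$edge_index[2, ] + offsets[i])
    }
    ef[[i]] <- g$edge_features
  }
  EF <- do.call(rbind, ef)
  dimnames(EF) <- NULL
  # self-loops
  src <- c(src, seq_len(N))
  dst <- c(dst, seq_len(N))
  EF <- rbind(EF, matrix(0, N, N_EDGE_FEATURES))
  graph_id <- rep.int(seq_along(graphs), n_nodes)
  list(
    X = X, vocab_id = as.integer(X[, 1]),
    src = src, dst = dst, EF = EF,
    graph_id = graph_id, n_graphs = length(graphs), n_nodes = n_nodes,
    node_split = split(seq_len(N), graph_id),
    dst_split = split(seq_along(dst), factor(dst, levels = seq_len(N)))
  )
}

seg_max <- function(x, split_idx) {
  vapply(split_idx, function(ii) max(x[ii]), numeric(1))
}

# --- forward / backward -----------------------------------------------------

gat_layer_forward <- function(H, pfx, params, state, cb, config, training) {
  heads <- config$gat_heads
  hd <- config$gat_hidden %/% heads
  N <- nrow(H)
  Z <- H %*% params[[paste0(pfx, "W")]]
  Ep <- cb$EF %*% params[[paste0(pfx, "We")]]
  M <- matrix(0, N, config$gat_hidden)
  hcache <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * hd + 1L):(h * hd)
    Zh <- Z[, cols, drop = FALSE]
    Eph <- Ep[, cols, drop = FALSE]
    a_src <- params[[paste0(pfx, "a_src")]][, h]
    a_dst <- params[[paste0(pfx, "a_dst")]][, h]
    a_edge <- params[[paste0(pfx, "a_edge")]][, h]
    s_src <- as.vector(Zh %*% a_src)
    s_dst <- as.vector(Zh %*% a_dst)
    s_e <- as.vector(Eph %*% a_edge)
    logit <- s_src[cb$src] + s_dst[cb$dst] + s_e
    act <- leaky_relu(logit, config$leaky_slope)
    gmax <- seg_max(act, cb$dst_split)
    ex <- exp(act - gmax[cb$dst])
    den <- segment_sum_vec(ex, cb$dst, N)
    alpha <- ex / den[cb$dst]
    M[, cols] <- segment_sum(alpha * Zh[cb$src, , drop = FALSE], cb$dst, N)
    hcache[[h]] <- list(cols = cols, alpha = alpha, logit_pos = logit > 0)
  }
  O <- sweep(M, 2, params[[paste0(pfx, "b")]], "+")
  A <- pmax(O, 0)
  bn <- bn_forward(A, params[[paste0(pfx, "bn_gamma")]], params[[paste0(pfx, "bn_beta")]],
                   state[[paste0(pfx, "bn_mean")]], state[[paste0(pfx, "bn_var")]],
                   training, config$bn_momentum, config$bn_eps)
  state[[paste0(pfx, "bn_mean")]] <- bn$rmean
  state[[paste0(pfx, "bn_var")]] <- bn$rvar
  out <- bn$y
  mask <- if (training) dropout_mask(dim(out), config$gat_dropout) else NULL
  if (!is.null(mask)) out <- out * mask
  list(out = out,
       cache = list(H = H, Z = Z, Ep = Ep, heads = hcache, O = O,
                    bn = bn$cache, mask = mask),
       state = state)
}

gat_layer_backward <- function(dout, pfx, params, cache, cb, config) {
  heads <- config$gat_heads
  N <- nrow(cache$H)
  grads <- list()
  if (!is.null(cache$mask)) dout <- dout * cache$mask
  bnb <- bn_backward(dout, cache$bn, params[[paste0(pfx, "bn_gamma")]])
  grads[[paste0(pfx, "bn_gamma")]] <- bnb$dgamma
  grads[[paste0(pfx, "bn_beta")]] <- bnb$dbeta
  dO <- bnb$dx * (cache$O > 0)
  grads[[paste0(pfx, "b")]] <- colSums(dO)

  dZ <- matrix(0, N, config$gat_hidden)
  dEp <- matrix(0, nrow(cache$Ep), config$gat_hidden)
  da_src <- da_dst <- da_edge <- matrix(0, config$gat_hidden %/% heads, heads)
  for (h in seq_len(heads)) {
    hc <- cache$heads[[h]]
    cols <- hc$cols
    Zh <- cache$Z[, cols, drop = FALSE]
    Eph <- cache$Ep[, cols, drop = FALSE]
    a_src <- params[[paste0(pfx, "a_src")]][, h]
    a_dst <- params[[paste0(pfx, "a_dst")]][, h]
    a_edge <- params[[paste0(pfx, "a_edge")]][, h]
    alpha <- hc$alpha
    dM <- dO[, cols, drop = FALSE]
    dM_dst <- dM[cb$dst, , drop = FALSE]
    Zh_src <- Zh[cb$src, , drop = FALSE]
    dalpha <- rowSums(dM_dst * Zh_src)
    dZh <- segment_sum(alpha * dM_dst, cb$src, N)
    S <- segment_sum_vec(alpha * dalpha, cb$dst, N)
    dact <- alpha * (dalpha - S[cb$dst])
    dlogit <- dact * ifelse(hc$logit_pos, 1, config$leaky_slope)
    ds_src <- segment_sum_vec(dlogit, cb$src, N)
    ds_dst <- segment_sum_vec(dlogit, cb$dst, N)
    dZh <- dZh + outer(ds_src, a_src) + outer(ds_dst, a_dst)
    da_src[, h] <- as.vector(crossprod(Zh, ds_src))
    da_dst[, h] <- as.vector(crossprod(Zh, ds_dst))
    da_edge[, h] <- as.vector(crossprod(Eph, dlogit))
    dEp[, cols] <- outer(dlogit, a_edge)
    dZ[, cols] <- dZh
  }
  grads[[paste0(pfx, "a_src")]] <- da_src
  grads[[paste0(pfx, "a_dst")]] <- da_dst
  grads[[paste0(pfx, "a_edge")]] <- da_edge
  grads[[paste0(pfx, "W")]] <- crossprod(cache$H, dZ)
  grads[[paste0(pfx, "We")]] <- crossprod(cb$EF, dEp)
  list(dH = dZ %*% t(params[[paste0(pfx, "W")]]), grads = grads)
}

dense_block_forward <- function(X, W, b, gamma, beta, rmean, rvar, dropout_p,
                                training, config) {
  L <- sweep(X %*% W, 2, b, "+")
  A <- pmax(L, 0)
  bn <- bn_forward(A, gamma, beta, rmean, rvar, training,
                   config$bn_momentum, config$bn_eps)
  out <- bn$y
  mask <- if (training) dropout_mask(dim(out), dropout_p) else NULL
  if (!is.null(mask)) out <- out * mask
  list(out = out, cache = list(X = X, L = L, bn = bn$cache, mask = mask),
       rmean = bn$rmean, rvar = bn$rvar)
}

dense_block_backward <- function(dout, cache, W, gamma) {
  if (!is.null(cache$mask)) dout <- dout * cache$mask
  bnb <- bn_backward(dout, cache$bn, gamma)
  dL <- bnb$dx * (cache$L > 0)
  list(dX = dL %*% t(W), dW = crossprod(cache$X, dL), db = colSums(dL),
       dgamma = bnb$dgamma, dbeta = bnb$dbeta)
}

# Full forward pass over one collated batch. Returns predictions plus the
# cache needed for backprop and the updated batch-norm running state.
net_forward <- function(model, batch, training = FALSE,
                        collect_attention = FALSE) {
  params <- model$params
  state <- model$state
  config <- model$config
  cache <- list()
  B <- batch$n_graphs %||% nrow(batch$desc)
  fused_parts <- list()
  attention <- NULL

  if (config$use_graph) {
    cb <- batch$graph
    H0 <- cbind(params$embed[cb$vocab_id, , drop = FALSE],
                cb$X[, -1, drop = FALSE])
    H <- sweep(H0 %*% params$in_W, 2, params$in_b, "+")
    layer_caches <- vector("list", config$gat_layers)
    if (collect_attention) attention <- vector("list", config$gat_layers)
    for (l in seq_len(config$gat_layers)) {
      fw <- gat_layer_forward(H, sprintf("gat%d.", l), params, state, cb,
                              config, training)
      H <- fw$out
      state <- fw$state
      layer_caches[[l]] <- fw$cache
      if (collect_attention) {
        attention[[l]] <- lapply(fw$cache$heads, function(hc) hc$alpha)
      }
    }
    counts <- cb$n_nodes
    gmean <- segment_sum(H, cb$graph_id, cb$n_graphs) / counts
    gmax <- matrix(0, cb$n_graphs, config$gat_hidden)
    amax <- matrix(0L, cb$n_graphs, config$gat_hidden)
    for (g in seq_len(cb$n_graphs)) {
      ii <- cb$node_split[[g]]
      Hm <- H[ii, , drop = FALSE]
      j <- max.col(t(Hm), ties.method = "first")
      amax[g, ] <- ii[j]
      gmax[g, ] <- Hm[cbind(j, seq_len(ncol(Hm)))]
    }
    gemb <- cbind(gmean, gmax)
    cache$graph <- list(H0 = H0, layers = layer_caches, Hfinal = H,
                        counts = counts, amax = amax, cb = cb)
    fused_parts$graph <- gemb
  }

  if (config$use_descriptors) {
    d1 <- dense_block_forward(batch$desc, params$desc.W1, params$desc.b1,
                              params$desc.bn1_gamma, params$desc.bn1_beta,
                              state$desc.bn1_mean, state$desc.bn1_var,
                              config$desc_dropout, training, config)
    state$desc.bn1_mean <- d1$rmean; state$desc.bn1_var <- d1$rvar
    d2 <- dense_block_forward(d1$out, params$desc.W2, params$desc.b2,
                              params$desc.bn2_gamma, params$desc.bn2_beta,
                              state$desc.bn2_mean, state$desc.bn2_var,
                              config$desc_dropout, training, config)
    state$desc.bn2_mean <- d2$rmean; state$desc.bn2_var <- d2$rvar
    cache$desc <- list(d1 = d1$cache, d2 = d2$cache)
    fused_parts$desc <- d2$out
  }

  Fmat <- do.call(cbind, c(unname(fused_parts),
                           list(matrix(batch$mol_size * config$mol_size_scale,
                                       ncol = 1))))
  hb <- dense_block_forward(Fmat, params$head.W1, params$head.b1,
                            params$head.bn_gamma, params$head.bn_beta,
                            state$head.bn_mean %||% numeric(config$head_hidden),
                            state$head.bn_var %||% rep(1, config$head_hidden),
                            config$head_dropout, training, config)
  state$head.bn_mean <- hb$rmean; state$head.bn_var <- hb$rvar
  pred <- as.vector(sweep(hb$out %*% params$head.W2, 2, params$head.b2, "+"))
  cache$head <- hb$cache
  cache$fused <- Fmat
  cache$head_out <- hb$out

  list(pred = pred, cache = cache, state = state, fused = Fmat,
       graph_embedding = fused_parts$graph, desc_embedding = fused_parts$desc,
       attention = attention)
}

net_backward <- function(model, batch, cache, dpred) {
  params <- model$params
  config <- model$config
  grads <- list()

  dHead_out <- matrix(dpred, ncol = 1) %*% t(params$head.W2)
  grads$head.W2 <- crossprod(cache$head_out, matrix(dpred, ncol = 1))
  grads$head.b2 <- sum(dpred)
  hb <- dense_block_backward(dHead_out, cache$head, params$head.W1,
                             params$head.bn_gamma)
  grads$head.W1 <- hb$dW; grads$head.b1 <- hb$db
  grads$head.bn_gamma <- hb$dgamma; grads$head.bn_beta <- hb$dbeta
  dF <- hb$dX

  off <- 0L
  if (config$use_graph) {
    gw <- 2L * config$gat_hidden
    dGemb <- dF[, seq_len(gw), drop = FALSE]
    off <- gw
  }
  if (config$use_descriptors) {
    dw <- config$desc_dims[3]
    dDemb <- dF[, off + seq_len(dw), drop = FALSE]
  }

  if (config$use_descriptors) {
    d2 <- dense_block_backward(dDemb, cache$desc$d2, params$desc.W2,
                               params$desc.bn2_gamma)
    grads$desc.W2 <- d2$dW; grads$desc.b2 <- d2$db
    grads$desc.bn2_gamma <- d2$dgamma; grads$desc.bn2_beta <- d2$dbeta
    d1 <- dense_block_backward(d2$dX, cache$desc$d1, params$desc.W1,
                               params$desc.bn1_gamma)
    grads$desc.W1 <- d1$dW; grads$desc.b1 <- d1$db
    grads$desc.bn1_gamma <- d1$dgamma; grads$desc.bn1_beta <- d1$dbeta
  }

  if (config$use_graph) {
    gc <- cache$graph
    cb <- gc$cb
    h <- config$gat_hidden
    dGmean <- dGemb[, seq_len(h), drop = FALSE]
    dGmax <- dGemb[, h + seq_len(h), drop = FALSE]
    dH <- (dGmean / gc$counts)[cb$graph_id, , drop = FALSE]
    for (g in seq_len(cb$n_graphs)) {
      idx <- cbind(gc$amax[g, ], seq_len(h))
      dH[idx] <- dH[idx] + dGmax[g, ]
    }
    for (l in rev(seq_len(config$gat_layers))) {
      bw <- gat_layer_backward(dH, sprintf("gat%d.", l), params,
                               gc$layers[[l]], cb, config)
      grads <- c(grads, bw$grads)
      dH <- bw$dH
    }
    dH0 <- dH %*% t(params$in_W)
    grads$in_W <- crossprod(gc$H0, dH)
    grads$in_b <- colSums(dH)
    grads$embed <- segment_sum(dH0[, seq_len(config$atom_embed_dim), drop = FALSE],
                               cb$vocab_id, model$vocab$size)
  }

  # any parameter untouched above (ablated branch) gets a zero gradient
  for (nm in names(params)) {
    if (is.null(grads[[nm]])) grads[[nm]] <- params[[nm]] * 0
  }
  grads[names(params)]
}

# Build a model batch (graph collation + descriptor matrix) from rows of a
# mol_features object.
make_batch <- function(feats, idx = seq_len(feats_n(feats))) {
  cfgless <- list(
    desc = unname(feats$desc[idx, , drop = FALSE]),
    mol_size = feats$mol_size[idx],
    y = feats$y[idx],
    n_graphs = length(idx)
  )
  cfgless$graph <- collate_graphs(feats$graphs[idx])
  cfgless
}

#' Graph-branch embedding of molecules
#'
#' Runs the graph attention branch only: embedded element-hybridization
#' nodes through the attention layers, then concatenated global mean and max
#' pooling. In eval mode (the default) the result is deterministic and
#' independent of batch composition.
#'
#' @param model an `ic50net_model` or fitted `ic50net` object.
#' @param graphs a `molecular_graph`, list of them, or character vector of
#'   SMILES (featurized with the model's vocabulary).
#' @param mode `"eval"` (running batch-norm statistics, no dropout) or
#'   `"train"`.
#' @return numeric matrix, one row per molecule, `2 * gat_hidden` columns.
#' @export
encode_graph <- function(model, graphs, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  model <- as_model(model)
  if (!model$config$use_graph) stopf("graph branch is disabled in this config")
  if (is.character(graphs)) graphs <- smiles_to_graph(graphs, model$vocab, simplify = FALSE)
  if (inherits(graphs, "molecular_graph")) graphs <- list(graphs)
  if (!length(graphs)) stopf("no graphs supplied")
  for (g in graphs) {
    if (g$n_nodes == 0L) stopf("cannot encode an empty graph")
    if (ncol(g$node_features) != N_NODE_FEATURES) stopf("node feature width mismatch")
  }
  cb <- collate_graphs(graphs)
  graph_branch_only(model, cb, training = (mode == "train"))
}

graph_branch_only <- function(model, cb, training) {
  params <- model$params; state <- model$state; config <- model$config
  H0 <- cbind(params$embed[cb$vocab_id, , drop = FALSE], cb$X[, -1, drop = FALSE])
  H <- sweep(H0 %*% params$in_W, 2, params$in_b, "+")
  for (l in seq_len(config$gat_layers)) {
    fw <- gat_layer_forward(H, sprintf("gat%d.", l), params, state, cb, config, training)
    H <- fw$out
    state <- fw$state
  }
  gmean <- segment_sum(H, cb$graph_id, cb$n_graphs) / cb$n_nodes
  gmax <- matrix(0, cb$n_graphs, config$gat_hidden)
  for (g in seq_len(cb$n_graphs)) {
    ii <- cb$node_split[[g]]
    Hm <- H[ii, , drop = FALSE]
    gmax[g, ] <- apply(Hm, 2, max)
  }
  cbind(gmean, gmax)
}

#' Descriptor-branch embedding
#'
#' Feed-forward encoding of normalized 544-dimensional descriptor vectors to
#' the 128-dimensional descriptor embedding. Deterministic in eval mode.
#'
#' @param model an `ic50net_model` or fitted `ic50net`.
#' @param desc numeric vector (length 544) or matrix (n x 544) of
#'   *normalized* descriptors.
#' @param mode `"eval"` or `"train"`.
#' @return numeric matrix, n x 128.
#' @export
encode_descriptors <- function(model, desc, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  model <- as_model(model)
  config <- model$config
  if (!config$use_descriptors) stopf("descriptor branch is disabled in this config")
  if (is.null(dim(desc))) desc <- matrix(desc, nrow = 1)
  if (ncol(desc) != config$desc_dims[1]) {
    stopf("descriptor length %d does not match expected %d", ncol(desc), config$desc_dims[1])
  }
  training <- mode == "train"
  params <- model$params; state <- model$state
  d1 <- dense_block_forward(desc, params$desc.W1, params$desc.b1,
                            params$desc.bn1_gamma, params$desc.bn1_beta,
                            state$desc.bn1_mean, state$desc.bn1_var,
                            config$desc_dropout, training, config)
  d2 <- dense_block_forward(d1$out, params$desc.W2, params$desc.b2,
                            params$desc.bn2_gamma, params$desc.bn2_beta,
                            state$desc.bn2_mean, state$desc.bn2_var,
                            config$desc_dropout, training, config)
  d2$out
}

# Recompute batch-normalization running statistics from the training set
# after optimization: one pass in batch-statistics mode with momentum 1 and
# dropout disabled, so eval-mode normalization reflects the full training
# distribution rather than the last noisy mini-batches.
refresh_bn_stats <- function(model, feats, max_n = 2048L) {
  n <- feats_n(feats)
  idx <- if (n > max_n) round(seq(1L, n, length.out = max_n)) else seq_len(n)
  cfg <- model$config
  cfg$bn_momentum <- 1
  cfg$gat_dropout <- 0
  cfg$desc_dropout <- 0
  cfg$head_dropout <- 0
  tmp <- model
  tmp$config <- cfg
  fw <- net_forward(tmp, make_batch(feats, idx), training = TRUE)
  model$state <- fw$state
  model
}

as_model <- function(x) {
  if (inherits(x, "ic50net_model")) return(x)
  if (inherits(x, "ic50net")) return(x$model)
  stopf("expected an ic50net_model or fitted ic50net object")
}

# Eval-mode predictions (and optionally attention weights) for a
# mol_features object.
model_predict_feats <- function(model, feats, chunk = 256L,
                                collect_attention = FALSE) {
  model <- as_model(model)
  n <- feats_n(feats)
  preds <- numeric(n)
  attn <- if (collect_attention) vector("list", n) else NULL
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    batch <- make_batch(feats, idx)
    fw <- net_forward(model, batch, training = FALSE,
                      collect_attention = collect_attention)
    preds[idx] <- fw$pred
    if (collect_attention) {
      attn[idx] <- rep(list(fw$attention), length(idx))
    }
  }
  if (collect_attention) list(pred = preds, attention = attn) else preds
}
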