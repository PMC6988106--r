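# Learned graph potentials. Patch-NET turns one oriented intensity patch
# into a sigmoid feature vector (stacked 3x3x3 convolutions, stride 1, zero
# padding 1, each followed by ReLU and 2x2x2 max-pooling with stride equal
# to the pool size). The unary network (T-NET) runs one Patch-NET pathway
# per scale in parallel and regresses the per-node scar probability; the
# pairwise network (N-NET) applies a shared (siamese) Patch-NET to the two
# nodes of an edge, fuses the features through the elementwise similarity
# map, appends the normalized geodesic distance and regresses the label
# similarity. Both are trained with SGD on squared error.
#
# Everything is plain vectorized R: 3-D convolution is im2col + one matrix
# product per layer, with gather/scatter index tables cached per patch
# geometry. Samples are stacked row-blocks of length n_voxels, so a whole
# minibatch is one BLAS call per layer.

# ---------------------------------------------------------------------------
# Label / feature similarity primitives.

#' Ground-truth label similarity of a node pair
#'
#' `M_ij = L_i * L_j + (1 - L_i) * (1 - L_j)`: 1 for identical binary
#' labels, 0 for opposite ones.
#'
#' @param l_i,l_j Label probabilities in \[0, 1\] (vectorized).
#' @return Similarity in \[0, 1\].
#' @export
label_similarity <- function(l_i, l_j) {
  if (any(l_i < 0 | l_i > 1 | l_j < 0 | l_j > 1))
    stop("label probabilities must be in [0, 1]")
  l_i * l_j + (1 - l_i) * (1 - l_j)
}

#' Elementwise similarity map of two feature vectors
#'
#' `G_ij = F_i * F_j + (1 - F_i) * (1 - F_j)`, applied componentwise to
#' sigmoid-bounded features; each element is a similarity in \[0, 1\],
#' symmetric in its arguments and invariant to complementing both inputs.
#'
#' @param f_i,f_j Numeric vectors (or matrices of row-wise feature vectors)
#'   with components in \[0, 1\] and equal dimensions.
#' @return Object of the same shape as the inputs.
#' @export
similarity_features <- function(f_i, f_j) {
  if (length(f_i) != length(f_j)) stop("feature dimensions must match")
  if (any(f_i < 0 | f_i > 1 | f_j < 0 | f_j > 1))
    stop("features must be in [0, 1]")
  f_i * f_j + (1 - f_i) * (1 - f_j)
}

# ---------------------------------------------------------------------------
# Architecture / training configuration.

#' Network architecture configuration
#'
#' @param channels Convolution channel widths, one per conv+pool block.
#' @param d_feat Patch feature width (sigmoid output of Patch-NET).
#' @param hidden Width of the fully connected head layer.
#' @return Object of class `net_arch`.
#' @export
net_config <- function(channels = c(16, 32, 64), d_feat = 64L, hidden = 32L) {
  stopifnot(length(channels) >= 1, all(channels >= 1), d_feat >= 1,
            hidden >= 1)
  structure(list(channels = as.integer(channels), d_feat = as.integer(d_feat),
                 hidden = as.integer(hidden)), class = "net_arch")
}

#' SGD training configuration
#'
#' Defaults follow the reference training protocol: SGD with momentum 0.9,
#' batch size 50, weight decay 1e-4, initial learning rate 0.01 with a
#' stepped decay of 0.8 every 1000 iterations; 15 epochs for the unary
#' network and 10 for the pairwise network.
#'
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param lr Initial learning rate.
#' @param momentum Momentum coefficient.
#' @param weight_decay L2 penalty coefficient.
#' @param lr_decay,lr_step Multiply `lr` by `lr_decay` every `lr_step`
#'   iterations.
#' @param seed RNG seed for shuffling and per-epoch patch resampling.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 15L, batch_size = 50L, lr = 0.01,
                         momentum = 0.9, weight_decay = 1e-4,
                         lr_decay = 0.8, lr_step = 1000L, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, lr >= 0, momentum >= 0,
            weight_decay >= 0, lr_decay > 0, lr_step >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 momentum = momentum, weight_decay = weight_decay,
                 lr_decay = lr_decay, lr_step = as.integer(lr_step),
                 seed = as.integer(seed)), class = "train_config")
}

# ---------------------------------------------------------------------------
# Index tables (cached per patch geometry).

.net_cache <- new.env(parent = emptyenv())

# 27-neighborhood gather table for a 3x3x3 convolution with zero padding:
# (n_vox x 27) of 1-based in-sample linear indices, 0 = outside.
conv_indices <- function(dims) {
  key <- paste0("conv", paste(dims, collapse = "x"))
  if (!is.null(.net_cache[[key]])) return(.net_cache[[key]])
  gr <- as.matrix(expand.grid(1:dims[1], 1:dims[2], 1:dims[3]))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- matrix(0L, nrow(gr), 27)
  for (k in 1:27) {
    nb <- sweep(gr, 2, offs[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
      nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
    lin <- nb[, 1] + dims[1] * (nb[, 2] - 1) + dims[1] * dims[2] * (nb[, 3] - 1)
    out[ok, k] <- as.integer(lin[ok])
  }
  .net_cache[[key]] <- out
  out
}

# 2x2x2 ceil-mode pooling gather table: (n_out x 8), 0 = outside.
pool_indices <- function(dims) {
  key <- paste0("pool", paste(dims, collapse = "x"))
  if (!is.null(.net_cache[[key]])) return(.net_cache[[key]])
  od <- ceiling(dims / 2)
  gr <- as.matrix(expand.grid(1:od[1], 1:od[2], 1:od[3]))
  offs <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  out <- matrix(0L, nrow(gr), 8)
  for (k in 1:8) {
    nb <- sweep((gr - 1) * 2 + 1, 2, offs[k, ], "+")
    ok <- nb[, 1] <= dims[1] & nb[, 2] <= dims[2] & nb[, 3] <= dims[3]
    lin <- nb[, 1] + dims[1] * (nb[, 2] - 1) + dims[1] * dims[2] * (nb[, 3] - 1)
    out[ok, k] <- as.integer(lin[ok])
  }
  .net_cache[[key]] <- structure(out, out_dims = od)
  .net_cache[[key]]
}

# Offset a per-sample gather table to a stacked batch of B sample blocks.
# Cached: the same (table, batch size) pair recurs every SGD step.
batch_indices <- function(base, nvox, B, tag = "") {
  key <- paste0("batch", tag, nrow(base), "x", nvox, "x", B)
  if (!is.null(.net_cache[[key]])) return(.net_cache[[key]])
  rep_base <- base[rep(seq_len(nvox_rows <- nrow(base)), times = B), ,
                   drop = FALSE]
  off <- rep((0:(B - 1)) * nvox, each = nvox_rows)
  .net_cache[[key]] <- rep_base + off * (rep_base > 0L)
  .net_cache[[key]]
}

# ---------------------------------------------------------------------------
# Layers. Activations are (B * n_vox) x C matrices, sample-major blocks.

conv3_forward <- function(M, W, b, dims, B) {
  nvox <- prod(dims)
  cin <- ncol(M)
  idx <- batch_indices(conv_indices(dims), nvox, B,
                        tag = paste0("c", paste(dims, collapse = "x")))
  Mp <- rbind(matrix(0, 1, cin), M)
  A <- Mp[as.vector(idx) + 1L, , drop = FALSE]      # (Bn*27) x Cin
  Mcol <- matrix(array(A, c(nrow(M), 27L, cin)), nrow(M), 27L * cin)
  out <- Mcol %*% W
  out <- sweep(out, 2, b, "+")
  list(out = out, Mcol = Mcol, idx = idx, cin = cin)
}

conv3_backward <- function(dOut, W, cache) {
  dW <- crossprod(cache$Mcol, dOut)
  db <- colSums(dOut)
  dMcol <- dOut %*% t(W)
  Bn <- nrow(dOut)
  cin <- cache$cin
  # Scatter-add per neighbour slot: within one slot every input voxel
  # occurs at most once, so plain indexed addition is safe and avoids a
  # grouped rowsum over Bn * 27 rows.
  dM <- matrix(0, Bn, cin)
  col0 <- (seq_len(cin) - 1L) * 27L
  for (k in 1:27) {
    rows <- cache$idx[, k]
    valid <- rows > 0L
    if (!any(valid)) next
    blk <- dMcol[, col0 + k, drop = FALSE]
    dM[rows[valid], ] <- dM[rows[valid], , drop = FALSE] +
      blk[valid, , drop = FALSE]
  }
  list(dM = dM, dW = dW, db = db)
}

pool2_forward <- function(M, dims, B) {
  base <- pool_indices(dims)
  od <- attr(base, "out_dims")
  nvox <- prod(dims)
  idx <- batch_indices(base, nvox, B,
                       tag = paste0("p", paste(dims, collapse = "x")))
  C <- ncol(M)
  Mp <- rbind(matrix(-Inf, 1, C), M)
  out <- Mp[idx[, 1] + 1L, , drop = FALSE]
  argk <- matrix(1L, nrow(out), C)
  for (k in 2:8) {
    cand <- Mp[idx[, k] + 1L, , drop = FALSE]
    upd <- cand > out
    if (any(upd)) {
      out[upd] <- cand[upd]
      argk[upd] <- k
    }
  }
  list(out = out, argk = argk, idx = idx, in_rows = nrow(M), out_dims = od)
}

pool2_backward <- function(dOut, cache) {
  dM <- matrix(0, cache$in_rows, ncol(dOut))
  for (k in 1:8) {
    rows <- cache$idx[, k]
    sel <- cache$argk == k
    valid <- rows > 0L
    if (!any(valid)) next
    contrib <- dOut * sel
    dM[rows[valid], ] <- dM[rows[valid], ] + contrib[valid, , drop = FALSE]
  }
  dM
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# ---------------------------------------------------------------------------
# Patch-NET.

# Spatial dims after each block.
patchnet_dims <- function(dims, n_blocks) {
  out <- vector("list", n_blocks + 1)
  out[[1]] <- dims
  for (i in seq_len(n_blocks)) out[[i + 1]] <- ceiling(out[[i]] / 2)
  out
}

init_patchnet <- function(dims, arch) {
  ch <- c(1L, arch$channels)
  params <- list()
  for (i in seq_along(arch$channels)) {
    fan_in <- 27 * ch[i]
    params[[paste0("conv", i, ".W")]] <-
      matrix(stats::rnorm(fan_in * ch[i + 1], sd = sqrt(2 / fan_in)),
             fan_in, ch[i + 1])
    params[[paste0("conv", i, ".b")]] <- numeric(ch[i + 1])
  }
  dd <- patchnet_dims(dims, length(arch$channels))
  flat <- prod(dd[[length(dd)]]) * utils::tail(arch$channels, 1)
  params[["feat.W"]] <- matrix(stats::rnorm(flat * arch$d_feat,
                                            sd = sqrt(1 / flat)),
                               flat, arch$d_feat)
  params[["feat.b"]] <- numeric(arch$d_feat)
  params
}

# X: (B x n_vox) single-channel patches. Returns sigmoid features (B x d).
patchnet_forward <- function(X, params, dims, arch) {
  B <- nrow(X)
  M <- matrix(as.vector(t(X)), ncol = 1)         # sample-major blocks
  caches <- vector("list", length(arch$channels))
  cur <- dims
  for (i in seq_along(arch$channels)) {
    cv <- conv3_forward(M, params[[paste0("conv", i, ".W")]],
                        params[[paste0("conv", i, ".b")]], cur, B)
    relu_mask <- cv$out > 0
    act <- cv$out * relu_mask
    pl <- pool2_forward(act, cur, B)
    caches[[i]] <- list(conv = cv, relu = relu_mask, pool = pl, dims = cur)
    M <- pl$out
    cur <- pl$out_dims
  }
  nvoxf <- prod(cur)
  cf <- ncol(M)
  arr <- array(M, c(nvoxf, B, cf))
  Fin <- matrix(aperm(arr, c(2, 1, 3)), B, nvoxf * cf)
  Z <- sweep(Fin %*% params[["feat.W"]], 2, params[["feat.b"]], "+")
  Fout <- sigmoid(Z)
  list(F = Fout, cache = list(blocks = caches, Fin = Fin, Fout = Fout,
                              nvoxf = nvoxf, cf = cf, B = B))
}

# dF: (B x d) gradient w.r.t. the sigmoid features. Returns named gradients.
patchnet_backward <- function(dF, cache, params, arch) {
  g <- list()
  dZ <- dF * cache$Fout * (1 - cache$Fout)
  g[["feat.W"]] <- crossprod(cache$Fin, dZ)
  g[["feat.b"]] <- colSums(dZ)
  dFin <- dZ %*% t(params[["feat.W"]])
  B <- cache$B
  arr <- aperm(array(dFin, c(B, cache$nvoxf, cache$cf)), c(2, 1, 3))
  dM <- matrix(arr, cache$nvoxf * B, cache$cf)
  for (i in rev(seq_along(cache$blocks))) {
    blk <- cache$blocks[[i]]
    dAct <- pool2_backward(dM, blk$pool)
    dConv <- dAct * blk$relu
    bk <- conv3_backward(dConv, params[[paste0("conv", i, ".W")]], blk$conv)
    g[[paste0("conv", i, ".W")]] <- bk$dW
    g[[paste0("conv", i, ".b")]] <- bk$db
    dM <- bk$dM
  }
  g[names(params)]   # same leaf order as the parameter list
}

# ---------------------------------------------------------------------------
# Parameter-tree utilities (params are nested named lists of arrays).

tree_map <- function(x, f) {
  if (is.list(x)) lapply(x, tree_map, f = f) else f(x)
}

tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(tree_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    out
  } else f(a, b)
}

tree_add <- function(a, b) tree_map2(a, b, `+`)

n_params <- function(theta) sum(unlist(tree_map(theta$params, length)))

# One SGD-with-momentum update; returns list(params, velocity).
sgd_step <- function(params, grads, velocity, lr, momentum, weight_decay) {
  velocity <- tree_map2(velocity, tree_map2(grads, params, function(g, p)
    g + weight_decay * p), function(v, g) momentum * v - lr * g)
  list(params = tree_add(params, velocity), velocity = velocity)
}

# ---------------------------------------------------------------------------
# T-NET: parallel Patch-NET pathways (one per scale) + fully connected head.

#' Initialize the unary (t-link) network
#'
#' One Patch-NET pathway per scale; the concatenated sigmoid features feed a
#' fully connected layer (ReLU) and a sigmoid output scalar, the predicted
#' scar probability `Lhat`.
#'
#' @param msp_cfg An [msp_config()] fixing patch dims and scale count.
#' @param arch A [net_config()].
#' @param seed RNG seed for weight initialization.
#' @return Object of class `t_net`.
#' @export
init_t_net <- function(msp_cfg = msp_config(), arch = net_config(),
                       seed = 1L) {
  with_seed(seed, {
    pn <- lapply(seq_len(msp_cfg$n_scales), function(s)
      init_patchnet(msp_cfg$dims, arch))
    din <- msp_cfg$n_scales * arch$d_feat
    params <- list(pn = pn,
                   head = list(
                     W1 = matrix(stats::rnorm(din * arch$hidden,
                                              sd = sqrt(2 / din)),
                                 din, arch$hidden),
                     b1 = rep(0.1, arch$hidden),
                     W2 = matrix(stats::rnorm(arch$hidden, sd = 0.1),
                                 arch$hidden, 1),
                     b2 = 0))
    structure(list(params = params, arch = arch, msp_cfg = msp_cfg,
                   trained = FALSE, loss = numeric(0)),
              class = "t_net")
  })
}

t_net_forward <- function(X, theta) {
  cfg <- theta$msp_cfg
  pcaches <- vector("list", cfg$n_scales)
  feats <- vector("list", cfg$n_scales)
  for (s in seq_len(cfg$n_scales)) {
    pf <- patchnet_forward(X[[s]], theta$params$pn[[s]], cfg$dims, theta$arch)
    feats[[s]] <- pf$F
    pcaches[[s]] <- pf$cache
  }
  Fc <- do.call(cbind, feats)
  h <- theta$params$head
  # Features are sigmoid outputs in [0, 1]; centre them so ReLU head units
  # start half-active instead of sign-locked by all-positive inputs.
  Z1 <- sweep((Fc - 0.5) %*% h$W1, 2, h$b1, "+")
  H <- Z1 * (Z1 > 0)
  Z2 <- H %*% h$W2 + h$b2
  pred <- as.vector(sigmoid(Z2))
  list(pred = pred, cache = list(pcaches = pcaches, Fc = Fc, Z1 = Z1, H = H,
                                 pred = pred))
}

t_net_backward <- function(dpred, cache, theta) {
  h <- theta$params$head
  dZ2 <- matrix(dpred * cache$pred * (1 - cache$pred), ncol = 1)
  gW2 <- crossprod(cache$H, dZ2)
  gb2 <- sum(dZ2)
  dH <- dZ2 %*% t(h$W2)
  dZ1 <- dH * (cache$Z1 > 0)
  gW1 <- crossprod(cache$Fc - 0.5, dZ1)
  gb1 <- colSums(dZ1)
  dFc <- dZ1 %*% t(h$W1)
  d <- theta$arch$d_feat
  gpn <- vector("list", theta$msp_cfg$n_scales)
  for (s in seq_len(theta$msp_cfg$n_scales)) {
    dF <- dFc[, (s - 1) * d + seq_len(d), drop = FALSE]
    gpn[[s]] <- patchnet_backward(dF, cache$pcaches[[s]],
                                  theta$params$pn[[s]], theta$arch)
  }
  list(pn = gpn, head = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}

#' Predict per-node scar probabilities
#'
#' @param X Either an `msp_stack` from [extract_msp()] or a list of `N_s`
#'   matrices (nodes x patch voxels) from batched extraction.
#' @param theta A trained `t_net`.
#' @return Numeric vector of probabilities `Lhat` in \[0, 1\].
#' @export
t_net_predict <- function(X, theta) {
  stopifnot(inherits(theta, "t_net"))
  if (inherits(X, "msp_stack"))
    X <- lapply(X$patches, function(p) matrix(as.vector(p), 1))
  nvox <- prod(theta$msp_cfg$dims)
  if (length(X) != theta$msp_cfg$n_scales || ncol(X[[1]]) != nvox)
    stop("patch dimensions do not match the network architecture")
  t_net_forward(X, theta)$pred
}

# ---------------------------------------------------------------------------
# N-NET: siamese Patch-NET + similarity fusion + distance feature + head.

#' Initialize the pairwise (n-link) network
#'
#' A shared Patch-NET (one pathway per scale) embeds both nodes' MSPs; the
#' elementwise [similarity_features()] of the two embeddings, concatenated
#' with the min-max normalized geodesic distance, feeds a fully connected
#' head with a sigmoid output, the predicted label similarity `Mhat`.
#' Symmetric under swapping the two nodes by construction.
#'
#' @inheritParams init_t_net
#' @return Object of class `n_net`.
#' @export
init_n_net <- function(msp_cfg = msp_config(), arch = net_config(),
                       seed = 1L) {
  with_seed(seed, {
    pn <- lapply(seq_len(msp_cfg$n_scales), function(s)
      init_patchnet(msp_cfg$dims, arch))
    din <- msp_cfg$n_scales * arch$d_feat + 1L
    params <- list(pn = pn,
                   head = list(
                     W1 = matrix(stats::rnorm(din * arch$hidden,
                                              sd = sqrt(2 / din)),
                                 din, arch$hidden),
                     b1 = rep(0.1, arch$hidden),
                     W2 = matrix(stats::rnorm(arch$hidden, sd = 0.1),
                                 arch$hidden, 1),
                     b2 = 0))
    structure(list(params = params, arch = arch, msp_cfg = msp_cfg,
                   trained = FALSE, loss = numeric(0),
                   d_range = c(0, 1)),
              class = "n_net")
  })
}

# Normalize geodesic distances with the training-set range.
normalize_dij <- function(d, range) {
  if (diff(range) <= 0) return(rep(0.5, length(d)))
  pmin(1, pmax(0, (d - range[1]) / diff(range)))
}

n_net_forward <- function(Xi, Xj, dnorm, theta) {
  cfg <- theta$msp_cfg
  ci <- cj <- vector("list", cfg$n_scales)
  Fi <- Fj <- vector("list", cfg$n_scales)
  for (s in seq_len(cfg$n_scales)) {
    a <- patchnet_forward(Xi[[s]], theta$params$pn[[s]], cfg$dims, theta$arch)
    b <- patchnet_forward(Xj[[s]], theta$params$pn[[s]], cfg$dims, theta$arch)
    Fi[[s]] <- a$F; Fj[[s]] <- b$F
    ci[[s]] <- a$cache; cj[[s]] <- b$cache
  }
  Fi <- do.call(cbind, Fi); Fj <- do.call(cbind, Fj)
  G <- Fi * Fj + (1 - Fi) * (1 - Fj)
  In <- cbind(G, dnorm)
  h <- theta$params$head
  Z1 <- sweep((In - 0.5) %*% h$W1, 2, h$b1, "+")
  H <- Z1 * (Z1 > 0)
  Z2 <- H %*% h$W2 + h$b2
  pred <- as.vector(sigmoid(Z2))
  list(pred = pred,
       cache = list(ci = ci, cj = cj, Fi = Fi, Fj = Fj, In = In, Z1 = Z1,
                    H = H, pred = pred))
}

n_net_backward <- function(dpred, cache, theta) {
  h <- theta$params$head
  dZ2 <- matrix(dpred * cache$pred * (1 - cache$pred), ncol = 1)
  gW2 <- crossprod(cache$H, dZ2)
  gb2 <- sum(dZ2)
  dZ1 <- (dZ2 %*% t(h$W2)) * (cache$Z1 > 0)
  gW1 <- crossprod(cache$In - 0.5, dZ1)
  gb1 <- colSums(dZ1)
  dIn <- dZ1 %*% t(h$W1)
  dG <- dIn[, -ncol(dIn), drop = FALSE]
  dFi <- dG * (2 * cache$Fj - 1)
  dFj <- dG * (2 * cache$Fi - 1)
  d <- theta$arch$d_feat
  gpn <- vector("list", theta$msp_cfg$n_scales)
  for (s in seq_len(theta$msp_cfg$n_scales)) {
    cols <- (s - 1) * d + seq_len(d)
    gi <- patchnet_backward(dFi[, cols, drop = FALSE], cache$ci[[s]],
                            theta$params$pn[[s]], theta$arch)
    gj <- patchnet_backward(dFj[, cols, drop = FALSE], cache$cj[[s]],
                            theta$params$pn[[s]], theta$arch)
    gpn[[s]] <- tree_add(gi, gj)
  }
  list(pn = gpn, head = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}

#' Predict pairwise label similarity for node pairs
#'
#' @param Xi,Xj Patch inputs for the two nodes of each pair: `msp_stack`s or
#'   lists of per-scale matrices.
#' @param d_ij Geodesic distances (mm, >= 0) between the pairs.
#' @param theta A trained `n_net`.
#' @return Similarities `Mhat` in \[0, 1\].
#' @export
n_net_predict <- function(Xi, Xj, d_ij, theta) {
  stopifnot(inherits(theta, "n_net"))
  if (inherits(Xi, "msp_stack"))
    Xi <- lapply(Xi$patches, function(p) matrix(as.vector(p), 1))
  if (inherits(Xj, "msp_stack"))
    Xj <- lapply(Xj$patches, function(p) matrix(as.vector(p), 1))
  if (any(d_ij < 0)) stop("geodesic distances must be >= 0")
  n_net_forward(Xi, Xj, normalize_dij(d_ij, theta$d_range), theta)$pred
}

# ---------------------------------------------------------------------------
# Balanced node sampling.

#' Balanced training node sample
#'
#' Collects all scar nodes and all scar-boundary nodes (background nodes
#' adjacent to at least one scar node), then adds a uniform random background
#' sample of the same total size, mitigating the heavy class imbalance of
#' scar vs. normal wall.
#'
#' @param mesh A [surface_mesh()].
#' @param labels Binary node labels (ground truth).
#' @param seed RNG seed for the background draw.
#' @return List: `nodes` (indices), `labels`, and the index sets `scar`,
#'   `boundary`, `background`.
#' @export
make_training_set <- function(mesh, labels, seed = NULL) {
  labels <- as.integer(labels)
  if (length(labels) != nrow(mesh$vertices))
    stop("one label per mesh node required")
  scar <- which(labels == 1L)
  if (!length(scar)) stop("degenerate training case: no scar nodes")
  if (length(scar) == length(labels))
    stop("degenerate training case: no background nodes")
  ed <- mesh$edges
  is_scar <- labels == 1L
  bnd <- unique(c(ed[is_scar[ed[, 1]] & !is_scar[ed[, 2]], 2],
                  ed[is_scar[ed[, 2]] & !is_scar[ed[, 1]], 1]))
  bg_pool <- setdiff(which(!is_scar), bnd)
  n_pos <- length(scar) + length(bnd)
  bg <- with_seed(seed, sample(bg_pool, min(n_pos, length(bg_pool))))
  nodes <- c(scar, bnd, bg)
  list(nodes = nodes, labels = labels[nodes], scar = scar, boundary = bnd,
       background = bg)
}

# ---------------------------------------------------------------------------
# Training loops.

# Resolve a data argument into a per-epoch provider function.
as_provider <- function(data) {
  if (is.function(data)) data else function(epoch) data
}

run_sgd <- function(theta, provider, cfg, forward, backward, kind) {
  velocity <- tree_map(theta$params, function(x) x * 0)
  iter <- 0L
  epoch_loss <- numeric(cfg$epochs)
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      d <- provider(ep)
      n <- length(d$y)
      if (!n) stop("empty training set")
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, by = cfg$batch_size)) {
        ids <- ord[start:min(n, start + cfg$batch_size - 1L)]
        fw <- forward(theta, d, ids)
        resid <- fw$pred - d$y[ids]
        loss <- mean(resid^2)
        if (!is.finite(loss))
          stop(kind, " training diverged (non-finite loss at iteration ",
               iter, ")")
        losses <- c(losses, loss)
        dpred <- 2 * resid / length(ids)
        grads <- backward(theta, fw, dpred)
        if (!all(is.finite(unlist(grads))))
          stop(kind, " training diverged (non-finite gradient at iteration ",
               iter, "); lower the learning rate or normalize the inputs")
        lr <- cfg$lr * cfg$lr_decay^(iter %/% cfg$lr_step)
        upd <- sgd_step(theta$params, grads, velocity, lr, cfg$momentum,
                        cfg$weight_decay)
        theta$params <- upd$params
        velocity <- upd$velocity
        iter <- iter + 1L
      }
      epoch_loss[ep] <- mean(losses)
    }
  })
  theta$loss <- epoch_loss
  theta$trained <- TRUE
  theta
}

#' Train the unary network on node samples
#'
#' Minimizes the sum of squared differences between the predicted and
#' ground-truth node label over the training nodes by minibatch SGD.
#'
#' @param data Either a list with `X` (list of `N_s` matrices, nodes x patch
#'   voxels) and `y` (labels), or a function `f(epoch)` returning such a
#'   list — use a function to redraw the random patch shifts each epoch.
#' @param theta An initialized `t_net` from [init_t_net()].
#' @param cfg A [train_config()] (15 epochs by default).
#' @return The trained `t_net` with per-epoch `loss`.
#' @export
train_t_net <- function(data, theta, cfg = train_config()) {
  stopifnot(inherits(theta, "t_net"))
  run_sgd(theta, as_provider(data), cfg,
          forward = function(th, d, ids) {
            X <- lapply(d$X, function(m) m[ids, , drop = FALSE])
            t_net_forward(X, th)
          },
          backward = function(th, fw, dpred) t_net_backward(dpred, fw$cache, th),
          kind = "T-NET")
}

#' Train the pairwise network on edge samples
#'
#' Minimizes the squared error between predicted and ground-truth label
#' similarity over edge samples. The geodesic-distance feature is min-max
#' normalized with the range of the first epoch's training distances, and
#' the same range is stored for prediction.
#'
#' @param data A list with `Xi`, `Xj` (lists of per-scale matrices), `d`
#'   (geodesic distances, mm) and `y` (label similarities), or a function
#'   `f(epoch)` returning such a list.
#' @param theta An initialized `n_net` from [init_n_net()].
#' @param cfg A [train_config()]; the reference protocol uses 10 epochs.
#' @return The trained `n_net`.
#' @export
train_n_net <- function(data, theta, cfg = train_config(epochs = 10L)) {
  stopifnot(inherits(theta, "n_net"))
  provider <- as_provider(data)
  d1 <- provider(1L)
  theta$d_range <- range(d1$d)
  run_sgd(theta, provider, cfg,
          forward = function(th, d, ids) {
            Xi <- lapply(d$Xi, function(m) m[ids, , drop = FALSE])
            Xj <- lapply(d$Xj, function(m) m[ids, , drop = FALSE])
            n_net_forward(Xi, Xj, normalize_dij(d$d[ids], th$d_range), th)
          },
          backward = function(th, fw, dpred) n_net_backward(dpred, fw$cache, th),
          kind = "N-NET")
}

#' @export
print.t_net <- function(x, ...) {
  cat("<t_net> ", x$msp_cfg$n_scales, " pathway(s), patch ",
      paste(x$msp_cfg$dims, collapse = "x"), ", ",
      format(n_params(x), big.mark = ","), " parameters, ",
      if (x$trained) sprintf("trained (final loss %.4g)",
                             utils::tail(x$loss, 1)) else "untrained",
      "\n", sep = "")
  invisible(x)
}

#' @export
print.n_net <- function(x, ...) {
  cat("<n_net> siamese, patch ", paste(x$msp_cfg$dims, collapse = "x"), ", ",
      format(n_params(x), big.mark = ","), " parameters, ",
      if (x$trained) sprintf("trained (final loss %.4g)",
                             utils::tail(x$loss, 1)) else "untrained",
      "\n", sep = "")
  invisible(x)
}
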