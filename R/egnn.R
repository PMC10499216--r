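# E(3)-equivariant graph convolution stack.
#
# Each layer consumes node embeddings h (L x H) and coordinate embeddings
# x (L x 3) and produces updated (h, x). Messages for a directed edge
# (i <- j) are m_ij = phi_e(h_i, h_j, ||x_i - x_j||^2, a_ij); coordinates
# move along the difference vectors, x_i <- x_i + C * sum_j (x_i - x_j) *
# phi_x(m_ij) with C = 1/(M-1) and M the node count; aggregated messages
# m_i = sum_j m_ij are optionally gated by a sigmoid attention embedding
# and combined with h_i through phi_h with a residual connection. Because
# coordinates enter only through squared distances, node embeddings (and
# hence predictions) are invariant under rotation, translation and
# reflection of the input, while the coordinate embeddings transform
# equivariantly.
#
# All MLPs are two-layer with SiLU nonlinearity; phi_a is linear+sigmoid.
# No deep-learning framework is used: forward and backward passes are
# hand-vectorized over the edge list.

silu <- function(z) z / (1 + exp(-z))
dsilu <- function(z) {
  s <- 1 / (1 + exp(-z))
  s * (1 + z * (1 - s))
}

#' EGNN model configuration
#'
#' @param n_layers number of equivariant graph convolution layers
#'   (default 10, the production depth).
#' @param hidden_dim hidden width (default 256).
#' @param input_dim node feature channels (default 118).
#' @param use_attention gate aggregated messages with a sigmoid attention
#'   embedding (default `TRUE`); `FALSE` gives the "w/o attention" variant.
#' @param update_coordinates update coordinate embeddings each layer
#'   (default `TRUE`); `FALSE` freezes them, giving the invariant variant.
#' @param fully_connected aggregate over all node pairs instead of the
#'   residue graph's edges (edge features then computed for every pair).
#' @param clamp_coord clamp the scalar coordinate weights to \[-100, 100\]
#'   for stability at depth (default `FALSE`).
#' @param seed seed for parameter initialization.
#' @return object of class `egnn_config`.
#' @export
egnn_config <- function(n_layers = 10, hidden_dim = 256, input_dim = 118,
                        use_attention = TRUE, update_coordinates = TRUE,
                        fully_connected = FALSE, clamp_coord = FALSE,
                        seed = 1) {
  stopifnot(n_layers >= 1, hidden_dim >= 1, input_dim >= 1)
  structure(list(n_layers = as.integer(n_layers),
                 hidden_dim = as.integer(hidden_dim),
                 input_dim = as.integer(input_dim),
                 use_attention = isTRUE(use_attention),
                 update_coordinates = isTRUE(update_coordinates),
                 fully_connected = isTRUE(fully_connected),
                 clamp_coord = isTRUE(clamp_coord),
                 seed = as.integer(seed)),
            class = "egnn_config")
}

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize EGNN parameters
#'
#' Glorot-uniform weights, zero biases, seeded from `config$seed`.
#'
#' @param config an [egnn_config()].
#' @return nested parameter list (input embedding, per-layer MLPs, head).
#' @export
egnn_init_params <- function(config) {
  set.seed(config$seed)
  H <- config$hidden_dim
  layer <- function() {
    p <- list(
      We1 = .glorot(2 * H + 2, H), be1 = numeric(H),
      We2 = .glorot(H, H), be2 = numeric(H),
      Wx1 = .glorot(H, H), bx1 = numeric(H),
      # small-gain init of the coordinate-weight output keeps the
      # coordinate updates stable at depth (standard EGNN practice)
      Wx2 = .glorot(H, 1) * 1e-3, bx2 = numeric(1),
      Wh1 = .glorot(2 * H, H), bh1 = numeric(H),
      Wh2 = .glorot(H, H), bh2 = numeric(H)
    )
    if (config$use_attention) {
      p$Wa <- .glorot(H, H)
      p$ba <- numeric(H)
    }
    p
  }
  list(
    W_in = .glorot(config$input_dim, H), b_in = numeric(H),
    layers = lapply(seq_len(config$n_layers), function(l) layer()),
    w0 = .glorot(H, 1), b0 = numeric(1)
  )
}

# directed edge list + per-edge feature, honoring the fully_connected flag
.model_edges <- function(graph, config) {
  if (!config$fully_connected) {
    return(list(edges = graph$edges, a = graph$edge_attr))
  }
  L <- graph$n_nodes
  ij <- which(matrix(TRUE, L, L) & !diag(TRUE, L), arr.ind = TRUE)
  d <- sqrt(rowSums((graph$x[ij[, 1], , drop = FALSE] -
                       graph$x[ij[, 2], , drop = FALSE])^2))
  sep <- pmax(abs(ij[, 1] - ij[, 2]), 1L)
  list(edges = ij, a = log(sep) / pmax(d, 1e-9))
}

# scatter-add edge rows into an L-row matrix by node index
.agg <- function(mat, idx, L) {
  out <- matrix(0, L, ncol(mat))
  rs <- rowsum(mat, idx)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

#' One equivariant graph convolution layer
#'
#' @param state list with `h` (L x H) and `x` (L x 3).
#' @param graph a `residue_graph` (or its directed edges via `config`).
#' @param params single-layer parameter list from [egnn_init_params()].
#' @param config an [egnn_config()].
#' @param keep_cache retain intermediates for backpropagation.
#' @return updated state; with `keep_cache`, a `cache` attribute-free list
#'   element holding the intermediates.
#' @export
egcl_forward <- function(state, graph, params, config, keep_cache = FALSE) {
  h <- state$h
  x <- state$x
  L <- nrow(h)
  if (ncol(h) != ncol(params$We2)) stop("hidden width mismatch")
  ed <- .model_edges(graph, config)
  idx_i <- ed$edges[, 1]
  idx_j <- ed$edges[, 2]
  C <- if (L > 1) 1 / (L - 1) else 0
  if (nrow(ed$edges) == 0) {
    m_i <- matrix(0, L, ncol(h))
    e_in <- NULL; ze1 <- ae1 <- ze2 <- m <- NULL
    zx1 <- ax1 <- w <- d_vec <- NULL
    x_new <- x
  } else {
    d_vec <- x[idx_i, , drop = FALSE] - x[idx_j, , drop = FALSE]
    sq <- rowSums(d_vec^2)
    # fixed 1/100 scaling of the squared distance keeps this input on the
    # same order as the unit-scale feature channels (a reparameterization
    # absorbed by the first edge-MLP layer; it conditions optimization)
    e_in <- cbind(h[idx_i, , drop = FALSE], h[idx_j, , drop = FALSE],
                  sq / 100, ed$a)
    ze1 <- sweep(e_in %*% params$We1, 2, params$be1, "+")
    ae1 <- silu(ze1)
    ze2 <- sweep(ae1 %*% params$We2, 2, params$be2, "+")
    m <- silu(ze2)
    zx1 <- sweep(m %*% params$Wx1, 2, params$bx1, "+")
    ax1 <- silu(zx1)
    w <- as.vector(ax1 %*% params$Wx2) + params$bx2
    if (config$clamp_coord) w <- pmin(pmax(w, -100), 100)
    x_new <- if (config$update_coordinates) {
      x + C * .agg(d_vec * w, idx_i, L)
    } else x
    m_i <- .agg(m, idx_i, L)
  }
  if (config$use_attention) {
    za <- sweep(m_i %*% params$Wa, 2, params$ba, "+")
    g <- 1 / (1 + exp(-za))
    m_att <- g * m_i
  } else {
    za <- g <- NULL
    m_att <- m_i
  }
  hh <- cbind(h, m_att)
  zh1 <- sweep(hh %*% params$Wh1, 2, params$bh1, "+")
  ah1 <- silu(zh1)
  zh2 <- sweep(ah1 %*% params$Wh2, 2, params$bh2, "+")
  h_new <- h + zh2
  out <- list(h = h_new, x = x_new)
  if (keep_cache) {
    out$cache <- list(h = h, x = x, idx_i = idx_i, idx_j = idx_j, C = C,
                      e_in = e_in, ze1 = ze1, ae1 = ae1, ze2 = ze2, m = m,
                      zx1 = zx1, ax1 = ax1, w = w, d_vec = d_vec,
                      m_i = m_i, za = za, g = g, hh = hh, zh1 = zh1,
                      ah1 = ah1)
  }
  out
}

# backward through one layer; returns list(dh, dx, grads)
.egcl_backward <- function(dh_new, dx_new, cache, params, config) {
  H <- ncol(params$We2)
  L <- nrow(dh_new)
  gr <- list()
  dzh2 <- dh_new
  gr$Wh2 <- t(cache$ah1) %*% dzh2
  gr$bh2 <- colSums(dzh2)
  dah1 <- dzh2 %*% t(params$Wh2)
  dzh1 <- dah1 * dsilu(cache$zh1)
  gr$Wh1 <- t(cache$hh) %*% dzh1
  gr$bh1 <- colSums(dzh1)
  dhh <- dzh1 %*% t(params$Wh1)
  dh <- dh_new + dhh[, 1:H, drop = FALSE]
  dm_att <- dhh[, (H + 1):(2 * H), drop = FALSE]
  if (config$use_attention) {
    dg <- dm_att * cache$m_i
    dm_i <- dm_att * cache$g
    dza <- dg * cache$g * (1 - cache$g)
    gr$Wa <- t(cache$m_i) %*% dza
    gr$ba <- colSums(dza)
    dm_i <- dm_i + dza %*% t(params$Wa)
  } else {
    dm_i <- dm_att
  }
  dx <- dx_new
  if (length(cache$idx_i) == 0) {
    zero <- function(p) p * 0
    for (nm in c("We1", "be1", "We2", "be2", "Wx1", "bx1", "Wx2", "bx2")) {
      gr[[nm]] <- zero(params[[nm]])
    }
    return(list(dh = dh, dx = dx, grads = gr))
  }
  idx_i <- cache$idx_i
  idx_j <- cache$idx_j
  dm <- dm_i[idx_i, , drop = FALSE]
  dd_vec <- matrix(0, length(idx_i), 3)
  if (config$update_coordinates) {
    dupd <- cache$C * dx_new[idx_i, , drop = FALSE]
    dw <- rowSums(dupd * cache$d_vec)
    dd_vec <- dd_vec + dupd * cache$w
    if (config$clamp_coord) dw <- dw * (abs(cache$w) < 100)
    gr$Wx2 <- t(cache$ax1) %*% matrix(dw, ncol = 1)
    gr$bx2 <- sum(dw)
    dax1 <- outer(dw, params$Wx2[, 1])
    dzx1 <- dax1 * dsilu(cache$zx1)
    gr$Wx1 <- t(cache$m) %*% dzx1
    gr$bx1 <- colSums(dzx1)
    dm <- dm + dzx1 %*% t(params$Wx1)
  } else {
    gr$Wx1 <- params$Wx1 * 0; gr$bx1 <- params$bx1 * 0
    gr$Wx2 <- params$Wx2 * 0; gr$bx2 <- params$bx2 * 0
  }
  dze2 <- dm * dsilu(cache$ze2)
  gr$We2 <- t(cache$ae1) %*% dze2
  gr$be2 <- colSums(dze2)
  dae1 <- dze2 %*% t(params$We2)
  dze1 <- dae1 * dsilu(cache$ze1)
  gr$We1 <- t(cache$e_in) %*% dze1
  gr$be1 <- colSums(dze1)
  de_in <- dze1 %*% t(params$We1)
  dh <- dh + .agg(de_in[, 1:H, drop = FALSE], idx_i, L) +
    .agg(de_in[, (H + 1):(2 * H), drop = FALSE], idx_j, L)
  dsq <- de_in[, 2 * H + 1] / 100  # matches the forward-pass input scaling
  dd_vec <- dd_vec + 2 * cache$d_vec * dsq
  dx <- dx + .agg(dd_vec, idx_i, L) - .agg(dd_vec, idx_j, L)
  list(dh = dh, dx = dx, grads = gr)
}

#' Sigmoid classification head
#'
#' Applies the linear squeeze `phi_0` to the final node embeddings and a
#' sigmoid to obtain per-residue interface probabilities.
#'
#' @param hL L x H matrix of final-layer node embeddings.
#' @param params list with `w0` (H x 1) and `b0` (scalar); any parameter
#'   list from [egnn_init_params()] works.
#' @return list of class `prediction_result` with field `p` in (0, 1).
#' @export
classification_head <- function(hL, params) {
  z <- as.vector(hL %*% params$w0) + params$b0
  structure(list(p = 1 / (1 + exp(-z)), logit = z),
            class = "prediction_result")
}

#' Full EGNN forward pass
#'
#' Embeds the 118-channel features, applies the configured stack of
#' equivariant layers seeded with the graph's C-alpha coordinates, and
#' produces per-residue interface probabilities.
#'
#' @param graph a `residue_graph` from [build_residue_graph()].
#' @param features a `node_feature_matrix` (or plain L x input_dim matrix).
#' @param config an [egnn_config()].
#' @param params parameters from [egnn_init_params()].
#' @param keep_cache retain layer intermediates (for training).
#' @return list with `p` (probabilities), `logit`, `h` (final embeddings),
#'   `x` (final coordinate embeddings) and, if requested, `caches`.
#' @export
egnn_forward <- function(graph, features, config, params,
                         keep_cache = FALSE) {
  F_ <- if (inherits(features, "node_feature_matrix")) {
    features$matrix
  } else as.matrix(features)
  if (nrow(F_) != graph$n_nodes) {
    stop("feature rows (", nrow(F_), ") != graph nodes (", graph$n_nodes, ")")
  }
  if (ncol(F_) != config$input_dim) {
    stop("feature channels (", ncol(F_), ") != config input_dim (",
         config$input_dim, ")")
  }
  h <- sweep(F_ %*% params$W_in, 2, params$b_in, "+")
  x <- graph$x
  state <- list(h = h, x = x)
  caches <- if (keep_cache) vector("list", config$n_layers) else NULL
  for (l in seq_len(config$n_layers)) {
    state <- egcl_forward(state, graph, params$layers[[l]], config,
                          keep_cache = keep_cache)
    if (keep_cache) caches[[l]] <- state$cache
    state$cache <- NULL
  }
  head_ <- classification_head(state$h, params)
  list(p = head_$p, logit = head_$logit, h = state$h, x = state$x,
       F_ = if (keep_cache) F_ else NULL, caches = caches)
}

#' Binary cross-entropy loss and full parameter gradient
#'
#' Runs a cached forward pass and hand-derived backward pass. The loss is
#' the mean BCE over all residues of the graph (optionally with a
#' positive-class weight).
#'
#' @param graph,features,config,params as in [egnn_forward()].
#' @param labels 0/1 vector of length L.
#' @param pos_weight multiplicative weight on positive-residue terms
#'   (default 1 = plain BCE).
#' @return list with `loss`, `p` and `grads` (same shape as `params`).
#' @export
egnn_loss_grad <- function(graph, features, config, params, labels,
                           pos_weight = 1) {
  fwd <- egnn_forward(graph, features, config, params, keep_cache = TRUE)
  p <- fwd$p
  y <- as.numeric(labels)
  wts <- ifelse(y == 1, pos_weight, 1)
  n <- length(y)
  eps <- 1e-12
  loss <- -sum(wts * (y * log(p + eps) + (1 - y) * log(1 - p + eps))) / n
  dz <- wts * (p - y) / n
  gr <- list()
  gr$w0 <- t(fwd$h) %*% matrix(dz, ncol = 1)
  gr$b0 <- sum(dz)
  dh <- outer(dz, params$w0[, 1])
  dx <- matrix(0, graph$n_nodes, 3)
  gr$layers <- vector("list", config$n_layers)
  for (l in rev(seq_len(config$n_layers))) {
    bk <- .egcl_backward(dh, dx, fwd$caches[[l]], params$layers[[l]], config)
    dh <- bk$dh
    dx <- bk$dx
    gr$layers[[l]] <- bk$grads
  }
  gr$W_in <- t(fwd$F_) %*% dh
  gr$b_in <- colSums(dh)
  list(loss = loss, p = p, grads = gr)
}
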