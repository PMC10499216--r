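# Independent reference implementations used as oracles. These are
# deliberately naive (double loops, brute force) and share no code with
# the package internals they check.

# O(L^2) residue-graph oracle: double loop over all pairs
oracle_edge_set <- function(ca, cutoff = 14, min_sep = 6) {
  L <- nrow(ca)
  out <- NULL
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (i == j) next
      if (abs(i - j) < min_sep) next
      if (sqrt(sum((ca[i, ] - ca[j, ])^2)) > cutoff) next
      out <- rbind(out, c(i, j))
    }
  }
  out
}

edge_key <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0) return(character(0))
  sort(paste(edges[, 1], edges[, 2], sep = "-"))
}

# naive loop-based EGNN forward pass: per-node, per-edge arithmetic with
# explicit MLP evaluation; mirrors the layer equations, not the code
oracle_egnn_forward <- function(graph, fmat, config, params) {
  silu1 <- function(z) z / (1 + exp(-z))
  mlp2 <- function(v, W1, b1, W2, b2, final_silu = TRUE) {
    a <- silu1(as.vector(v %*% W1) + b1)
    out <- as.vector(a %*% W2) + b2
    if (final_silu) silu1(out) else out
  }
  L <- graph$n_nodes
  h <- matrix(NA_real_, L, ncol(params$W_in))
  for (i in seq_len(L)) {
    h[i, ] <- as.vector(fmat[i, ] %*% params$W_in) + params$b_in
  }
  x <- graph$x
  C <- if (L > 1) 1 / (L - 1) else 0
  for (l in seq_len(config$n_layers)) {
    pl <- params$layers[[l]]
    H <- ncol(pl$We2)
    m_i <- matrix(0, L, H)
    x_acc <- matrix(0, L, 3)
    for (e in seq_len(nrow(graph$edges))) {
      i <- graph$edges[e, 1]
      j <- graph$edges[e, 2]
      dv <- x[i, ] - x[j, ]
      ein <- c(h[i, ], h[j, ], sum(dv^2) / 100, graph$edge_attr[e])
      mij <- mlp2(ein, pl$We1, pl$be1, pl$We2, pl$be2)
      m_i[i, ] <- m_i[i, ] + mij
      wij <- mlp2(mij, pl$Wx1, pl$bx1, pl$Wx2, pl$bx2, final_silu = FALSE)
      x_acc[i, ] <- x_acc[i, ] + dv * wij
    }
    h_new <- matrix(NA_real_, L, H)
    for (i in seq_len(L)) {
      mi <- m_i[i, ]
      if (config$use_attention) {
        gate <- 1 / (1 + exp(-(as.vector(mi %*% pl$Wa) + pl$ba)))
        mi <- gate * mi
      }
      h_new[i, ] <- h[i, ] +
        mlp2(c(h[i, ], mi), pl$Wh1, pl$bh1, pl$Wh2, pl$bh2,
             final_silu = FALSE)
    }
    if (config$update_coordinates) x <- x + C * x_acc
    h <- h_new
  }
  z <- as.vector(h %*% params$w0) + params$b0
  list(p = 1 / (1 + exp(-z)), x = x)
}

# pair-counting ROC-AUC oracle: P(random positive outranks random negative)
oracle_roc_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (sp in pos) {
    for (sn in neg) {
      tot <- tot + (sp > sn) + 0.5 * (sp == sn)
    }
  }
  tot / (length(pos) * length(neg))
}

# brute-force confusion recount
oracle_confusion <- function(labels, calls) {
  tp <- fp <- tn <- fn <- 0
  for (k in seq_along(labels)) {
    if (labels[k] == 1 && calls[k] == 1) tp <- tp + 1
    if (labels[k] == 0 && calls[k] == 1) fp <- fp + 1
    if (labels[k] == 0 && calls[k] == 0) tn <- tn + 1
    if (labels[k] == 1 && calls[k] == 0) fn <- fn + 1
  }
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

# independent ideal tetrahedral C-beta builder: rotate the N direction
# about the bisector frame rather than using the fixed linear combination
oracle_cb <- function(n, ca, c) {
  v1 <- n - ca
  v2 <- c - ca
  v1 <- v1 / sqrt(sum(v1^2))
  v2 <- v2 / sqrt(sum(v2^2))
  bis <- -(v1 + v2)
  bis <- bis / sqrt(sum(bis^2))
  perp <- pracma::cross(v1, v2)  # L-amino-acid chirality
  perp <- perp / sqrt(sum(perp^2))
  half <- (109.5 / 2) * pi / 180
  dir_ <- cos(half) * bis + sin(half) * perp
  ca + 1.53 * dir_
}

# hand-written 3-residue PDB fixture (ALA, GLY, VAL with full backbones)
write_three_residue_pdb <- function(path, drop_gly_ca = FALSE) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.300   2.400   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       2.000  -0.800  -1.200  1.00  0.00           C",
    "ATOM      6  N   GLY A   2       3.300   1.500   0.200  1.00  0.00           N",
    "ATOM      7  CA  GLY A   2       4.000   2.800   0.300  1.00  0.00           C",
    "ATOM      8  C   GLY A   2       5.500   2.600   0.400  1.00  0.00           C",
    "ATOM      9  O   GLY A   2       6.000   1.500   0.500  1.00  0.00           O",
    "ATOM     10  N   VAL A   3       6.200   3.700   0.400  1.00  0.00           N",
    "ATOM     11  CA  VAL A   3       7.650   3.700   0.500  1.00  0.00           C",
    "ATOM     12  C   VAL A   3       8.200   5.100   0.600  1.00  0.00           C",
    "ATOM     13  O   VAL A   3       7.500   6.100   0.700  1.00  0.00           O",
    "ATOM     14  CB  VAL A   3       8.200   2.900  -0.700  1.00  0.00           C",
    "TER", "END")
  if (drop_gly_ca) lines <- lines[-7]
  writeLines(lines, path)
  path
}

# small deterministic random graph + features for model oracles
random_toy_instance <- function(L, seed, n_layers = 2, hidden = 6,
                                input_dim = 10) {
  set.seed(seed)
  ca <- matrix(rnorm(L * 3, sd = 4), L, 3)
  mono <- NULL
  edges <- oracle_edge_set(ca, cutoff = 14, min_sep = 2)
  if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
  a <- if (nrow(edges) > 0) {
    log(abs(edges[, 1] - edges[, 2])) /
      sqrt(rowSums((ca[edges[, 1], , drop = FALSE] -
                      ca[edges[, 2], , drop = FALSE])^2))
  } else numeric(0)
  graph <- structure(list(n_nodes = L, edges = edges, edge_attr = a,
                          x = ca), class = "residue_graph")
  cfg <- egnn_config(n_layers = n_layers, hidden_dim = hidden,
                     input_dim = input_dim, seed = seed)
  params <- egnn_init_params(cfg)
  fmat <- matrix(runif(L * input_dim), L, input_dim)
  list(graph = graph, cfg = cfg, params = params, fmat = fmat)
}
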