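# Training loop: Adam with decoupled weight decay, cosine-annealed
# learning rate, one graph per optimization step, model selection by
# validation PR-AUC. Entirely deterministic given the seeds.

#' Training configuration
#'
#' Defaults follow the production setup: Adam with learning rate 1e-4,
#' weight decay 1e-16, binary cross-entropy loss, cosine annealing of the
#' learning rate over at most 50 epochs.
#'
#' @param lr initial learning rate.
#' @param weight_decay decoupled weight decay coefficient.
#' @param max_epochs maximum number of epochs (annealing period).
#' @param seed RNG seed for epoch shuffling.
#' @param pos_weight optional positive-class weight in the BCE loss
#'   (default 1, plain unweighted BCE).
#' @param lr_min floor of the cosine schedule.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, weight_decay = 1e-16, max_epochs = 50,
                         seed = 1, pos_weight = 1, lr_min = 0) {
  stopifnot(lr > 0, max_epochs >= 1)
  structure(list(lr = lr, weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed), pos_weight = pos_weight,
                 lr_min = lr_min),
            class = "train_config")
}

cosine_lr <- function(epoch, cfg) {
  cfg$lr_min + 0.5 * (cfg$lr - cfg$lr_min) *
    (1 + cos(pi * (epoch - 1) / max(cfg$max_epochs - 1, 1)))
}

# ---- recursive parameter-tree arithmetic ----------------------------------

.tree_map <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1]])) {
    keys <- if (!is.null(names(trees[[1]]))) {
      names(trees[[1]])  # align branches by name, not position
    } else {
      seq_along(trees[[1]])
    }
    out <- lapply(keys, function(k) {
      do.call(.tree_map, c(list(f), lapply(trees, `[[`, k)))
    })
    names(out) <- if (is.character(keys)) keys else names(trees[[1]])
    out
  } else {
    do.call(f, trees)
  }
}

.tree_zero <- function(tree) .tree_map(function(a) a * 0, tree)

.tree_dot <- function(a, b) {
  tot <- 0
  walk <- function(x, y) {
    if (is.list(x)) {
      keys <- if (!is.null(names(x))) names(x) else seq_along(x)
      for (k in keys) walk(x[[k]], y[[k]])
    } else {
      tot <<- tot + sum(x * y)
    }
  }
  walk(a, b)
  tot
}

adam_init <- function(params) {
  list(m = .tree_zero(params), v = .tree_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- .tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- .tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- .tree_map(function(p, m, v) {
    p - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + weight_decay * p)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

# ---- training -------------------------------------------------------------

#' Train the EGNN interface classifier
#'
#' Optimizes the binary cross-entropy over all residues, one labeled graph
#' per Adam step, with a cosine-annealed learning rate. When a validation
#' set is supplied, the checkpoint keeps the parameters of the epoch with
#' the best pooled validation PR-AUC; otherwise the final epoch is kept.
#'
#' @param train_set nonempty list of labeled graphs (elements with
#'   `graph`, `features`, `labels`, as produced by [generate_dataset()]).
#' @param val_set optional validation list of the same form.
#' @param model_cfg an [egnn_config()].
#' @param train_cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return object of class `egnn_checkpoint`: `params`, `model_cfg`,
#'   `train_cfg` and a per-epoch `history` data frame.
#' @export
train_model <- function(train_set, val_set = NULL,
                        model_cfg = egnn_config(),
                        train_cfg = train_config(), verbose = FALSE) {
  if (length(train_set) == 0) stop("empty training set")
  for (g in train_set) {
    stopifnot(length(g$labels) == g$graph$n_nodes,
              all(g$labels %in% c(0, 1)))
  }
  params <- egnn_init_params(model_cfg)
  opt <- adam_init(params)
  best <- list(params = params, val_pr_auc = -Inf, epoch = 0L)
  hist <- data.frame()
  set.seed(train_cfg$seed)
  for (epoch in seq_len(train_cfg$max_epochs)) {
    lr <- cosine_lr(epoch, train_cfg)
    ord <- sample(length(train_set))
    losses <- numeric(length(ord))
    for (s in seq_along(ord)) {
      g <- train_set[[ord[s]]]
      lg <- egnn_loss_grad(g$graph, g$features, model_cfg, params,
                           g$labels, pos_weight = train_cfg$pos_weight)
      if (!is.finite(lg$loss)) {
        stop("non-finite loss at epoch ", epoch, ", step ", s,
             "; consider clamp_coord = TRUE or a lower learning rate")
      }
      st <- adam_step(params, lg$grads, opt, lr,
                      weight_decay = train_cfg$weight_decay)
      params <- st$params
      opt <- st$state
      losses[s] <- lg$loss
    }
    val_pr <- NA_real_
    if (!is.null(val_set) && length(val_set) > 0) {
      ev <- evaluate_model(params, model_cfg, val_set)
      val_pr <- ev$pr_auc
      if (val_pr > best$val_pr_auc) {
        best <- list(params = params, val_pr_auc = val_pr, epoch = epoch)
      }
    }
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                   train_bce = mean(losses),
                                   val_pr_auc = val_pr))
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  bce %.4f  val PR-AUC %s",
                      epoch, lr, mean(losses),
                      ifelse(is.na(val_pr), "-", sprintf("%.3f", val_pr))))
    }
  }
  if (is.null(val_set) || length(val_set) == 0 || best$epoch == 0L) {
    best <- list(params = params, val_pr_auc = NA_real_,
                 epoch = train_cfg$max_epochs)
  }
  structure(list(params = best$params, model_cfg = model_cfg,
                 train_cfg = train_cfg, best_epoch = best$epoch,
                 val_pr_auc = best$val_pr_auc, history = hist),
            class = "egnn_checkpoint")
}

#' Pooled evaluation of parameters on a labeled-graph set
#'
#' @param params,model_cfg model parameters and configuration.
#' @param dataset list of labeled graphs.
#' @return list with pooled `p`, `labels`, `roc_auc`, `pr_auc`.
#' @export
evaluate_model <- function(params, model_cfg, dataset) {
  p <- unlist(lapply(dataset, function(g) {
    egnn_forward(g$graph, g$features, model_cfg, params)$p
  }))
  labels <- unlist(lapply(dataset, `[[`, "labels"))
  aucs <- auc_metrics(labels, p)
  list(p = p, labels = labels, roc_auc = aucs$roc_auc,
       pr_auc = aucs$pr_auc)
}

#' Save / load a checkpoint
#'
#' The checkpoint is a self-describing archive (configuration plus all
#' parameters); loading restores bit-identical predictions on the same
#' platform.
#'
#' @param checkpoint an `egnn_checkpoint`.
#' @param path file path.
#' @return `path` (save) or the checkpoint (load).
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "egnn_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck, "egnn_checkpoint")) stop("not a checkpoint: ", path)
  ck
}

#' Predict interface sites for a monomer or structure file
#'
#' Runs the full pipeline: parse (if given a file path), build the residue
#' graph, featurize, forward pass, threshold.
#'
#' @param checkpoint an `egnn_checkpoint` from [train_model()].
#' @param input a [protein_monomer()] or a PDB/mmCIF file path.
#' @param chain chain identifier when `input` is a path.
#' @param profile_provider,embedding_provider feature providers
#'   (`sequence -> L x 20` / `L x 33`); supply [mock_feature_providers()]
#'   components, a parsed PSSM via [read_pssm()], or real embeddings.
#' @param threshold probability cutoff for the binary call (default 0.5).
#' @return data frame with columns `residue_index`, `aa`, `probability`,
#'   `call`; the raw `prediction_result` is attached as an attribute.
#' @export
predict_sites <- function(checkpoint, input, chain = NULL,
                          profile_provider = NULL,
                          embedding_provider = NULL, threshold = 0.5) {
  stopifnot(inherits(checkpoint, "egnn_checkpoint"))
  monomer <- if (inherits(input, "protein_monomer")) {
    input
  } else {
    parse_structure(input, chain = chain)
  }
  if (is.null(profile_provider) || is.null(embedding_provider)) {
    stop("profile and embedding providers are required; supply a parsed ",
         "PSSM / embedding matrix (wrapped as a provider function) or ",
         "mock_feature_providers() for testing")
  }
  graph <- build_residue_graph(monomer)
  feats <- node_features(monomer, profile_provider, embedding_provider)
  fwd <- egnn_forward(graph, feats, checkpoint$model_cfg, checkpoint$params)
  out <- data.frame(
    residue_index = monomer$residue_index,
    aa = monomer$sequence,
    probability = fwd$p,
    call = as.integer(fwd$p >= threshold)
  )
  attr(out, "prediction") <- structure(list(p = fwd$p),
                                       class = "prediction_result")
  attr(out, "x_embedding") <- fwd$x
  out
}
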