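# User-facing model interface in the classic R idiom: one fitting function
# returning a classed object with the usual methods.

#' Fit an equivariant interface-site classifier
#'
#' Trains the E(3)-equivariant graph neural network on a list of labeled
#' residue graphs and returns a fitted-model object supporting `print`,
#' `summary`, `coef`, `predict`, `fitted`, `residuals`, `simulate` and
#' `plot`.
#'
#' @param train_set list of labeled graphs (see [generate_dataset()] for
#'   the element structure).
#' @param val_set optional validation list used for model selection
#'   (epoch with best pooled PR-AUC).
#' @param n_layers,hidden_dim,use_attention,update_coordinates model
#'   architecture, passed to [egnn_config()]. Defaults are the production
#'   10 x 256 configuration.
#' @param lr,weight_decay,max_epochs,pos_weight optimization settings,
#'   passed to [train_config()].
#' @param seed seed for initialization and epoch shuffling.
#' @param verbose print per-epoch progress.
#' @param ... further arguments to [egnn_config()].
#' @return object of class `equippis`.
#' @export
equippis_fit <- function(train_set, val_set = NULL,
                         n_layers = 10, hidden_dim = 256,
                         use_attention = TRUE, update_coordinates = TRUE,
                         lr = 1e-4, weight_decay = 1e-16, max_epochs = 50,
                         pos_weight = 1, seed = 1, verbose = FALSE, ...) {
  model_cfg <- egnn_config(n_layers = n_layers, hidden_dim = hidden_dim,
                           use_attention = use_attention,
                           update_coordinates = update_coordinates,
                           seed = seed, ...)
  train_cfg <- train_config(lr = lr, weight_decay = weight_decay,
                            max_epochs = max_epochs, seed = seed,
                            pos_weight = pos_weight)
  ck <- train_model(train_set, val_set, model_cfg, train_cfg,
                    verbose = verbose)
  fit <- list(checkpoint = ck, train_set = train_set, val_set = val_set,
              call = match.call())
  class(fit) <- "equippis"
  fit
}

#' @export
print.equippis <- function(x, ...) {
  ck <- x$checkpoint
  cat("E(3)-equivariant interface-site classifier\n")
  cat(sprintf("  layers: %d  hidden: %d  attention: %s  coordinate updates: %s\n",
              ck$model_cfg$n_layers, ck$model_cfg$hidden_dim,
              ck$model_cfg$use_attention, ck$model_cfg$update_coordinates))
  cat(sprintf("  trained %d epoch(s) on %d graph(s); selected epoch %d",
              nrow(ck$history), length(x$train_set), ck$best_epoch))
  if (!is.na(ck$val_pr_auc)) {
    cat(sprintf(" (val PR-AUC %.3f)", ck$val_pr_auc))
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.equippis <- function(object, ...) {
  ck <- object$checkpoint
  tr <- evaluate_model(ck$params, ck$model_cfg, object$train_set)
  thr <- select_threshold(tr$labels, tr$p)
  rep_ <- metrics_report(tr$labels, tr$p, threshold = thr)
  out <- list(model_cfg = ck$model_cfg, history = ck$history,
              best_epoch = ck$best_epoch, train_metrics = rep_,
              n_parameters = .count_params(ck$params))
  class(out) <- "summary.equippis"
  out
}

#' @export
print.summary.equippis <- function(x, ...) {
  cat(sprintf("EGNN with %d layer(s), hidden %d, %d parameters\n",
              x$model_cfg$n_layers, x$model_cfg$hidden_dim, x$n_parameters))
  cat(sprintf("selected epoch %d; final train BCE %.4f\n", x$best_epoch,
              utils::tail(x$history$train_bce, 1)))
  cat("training-set metrics (threshold ",
      sprintf("%.3f", x$train_metrics$threshold), "):\n", sep = "")
  print(x$train_metrics)
  cat(sprintf("  ROC-AUC %.3f  PR-AUC %.3f\n", x$train_metrics$roc_auc,
              x$train_metrics$pr_auc))
  invisible(x)
}

.count_params <- function(tree) {
  n <- 0
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else n <<- n + length(x)
  }
  walk(tree)
  n
}

#' @export
coef.equippis <- function(object, ...) object$checkpoint$params

#' Predict interface probabilities from a fitted model
#'
#' @param object a fitted `equippis` model.
#' @param newdata a labeled-graph list (as from [generate_dataset()]), a
#'   single labeled graph, a [protein_monomer()], or a structure file
#'   path. Defaults to the training set.
#' @param type `"response"` for probabilities, `"call"` for thresholded
#'   0/1 calls.
#' @param threshold cutoff for `type = "call"`.
#' @param ... passed to [predict_sites()] for monomer/file inputs
#'   (providers, chain).
#' @return numeric vector of probabilities (or integer calls); for a list
#'   of graphs, a list of vectors.
#' @export
predict.equippis <- function(object, newdata = NULL,
                             type = c("response", "call"),
                             threshold = 0.5, ...) {
  type <- match.arg(type)
  ck <- object$checkpoint
  pred_graph <- function(g) {
    egnn_forward(g$graph, g$features, ck$model_cfg, ck$params)$p
  }
  p <- if (is.null(newdata)) {
    lapply(object$train_set, pred_graph)
  } else if (inherits(newdata, "protein_monomer") ||
             (is.character(newdata) && length(newdata) == 1)) {
    predict_sites(ck, newdata, threshold = threshold, ...)$probability
  } else if (!is.null(newdata$graph)) {
    pred_graph(newdata)
  } else {
    lapply(newdata, pred_graph)
  }
  if (type == "call") {
    if (is.list(p)) lapply(p, function(v) as.integer(v >= threshold))
    else as.integer(p >= threshold)
  } else p
}

#' @export
fitted.equippis <- function(object, ...) {
  predict.equippis(object)
}

#' @export
residuals.equippis <- function(object, ...) {
  p <- fitted(object)
  lapply(seq_along(p), function(k) object$train_set[[k]]$labels - p[[k]])
}

#' Simulate interface labels from the fitted probabilities
#'
#' Draws Bernoulli labels per residue from the model's predicted
#' probabilities, e.g. for parametric-bootstrap checks.
#'
#' @param object a fitted `equippis` model.
#' @param nsim number of simulated label sets.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return list of length `nsim`; each element is a list of 0/1 vectors
#'   matching the training graphs.
#' @export
simulate.equippis <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- fitted(object)
  lapply(seq_len(nsim), function(s) {
    lapply(p, function(v) stats::rbinom(length(v), 1, v))
  })
}

#' Training-history plot
#'
#' @param x a fitted `equippis` model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.equippis <- function(x, ...) {
  h <- x$checkpoint$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_bce, type = "b", pch = 20,
                 xlab = "epoch", ylab = "training BCE", ...)
  if (!all(is.na(h$val_pr_auc))) {
    graphics::plot(h$epoch, h$val_pr_auc, type = "b", pch = 20,
                   xlab = "epoch", ylab = "validation PR-AUC", ...)
    graphics::abline(v = x$checkpoint$best_epoch, lty = 2)
  } else {
    graphics::plot.new()
  }
  invisible(x)
}
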