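# The predictive model: stacked graph-attention convolutions (each followed
# by a linear transform + batch normalization), a global multihead scaled
# dot-product attention block with residual connection, concatenated global
# max/mean pooling, and a two-layer prediction head.

#' Model configuration
#'
#' @param n_conv_layers number of graph-attention convolution layers.
#' @param embed_dim embedding dimension; must be divisible by both head
#'   counts.
#' @param n_global_heads number of global multihead-attention heads.
#' @param n_conv_heads attention heads inside each convolution; when > 1 the
#'   per-layer attention matrix used downstream is the arithmetic mean over
#'   heads (which preserves row-stochasticity).
#' @param dropout_conv dropout rate after each convolution (training only).
#' @param dropout_attention dropout rate on global attention weights.
#' @param head_kind `"regression"` or `"binary-classification"`.
#' @return object of class `ModelConfig`.
#' @export
model_config <- function(n_conv_layers = 3L, embed_dim = 128L,
                         n_global_heads = 4L, n_conv_heads = 1L,
                         dropout_conv = 0.1, dropout_attention = 0.2,
                         head_kind = c("regression", "binary-classification")) {
  head_kind <- match.arg(head_kind)
  n_conv_layers <- as.integer(n_conv_layers)
  embed_dim <- as.integer(embed_dim)
  n_global_heads <- as.integer(n_global_heads)
  n_conv_heads <- as.integer(n_conv_heads)
  if (n_conv_layers < 1L) stop("n_conv_layers must be >= 1")
  if (embed_dim %% n_global_heads != 0L) {
    stop("embed_dim (", embed_dim, ") must be divisible by n_global_heads (",
         n_global_heads, ")")
  }
  if (embed_dim %% n_conv_heads != 0L) {
    stop("embed_dim must be divisible by n_conv_heads")
  }
  for (dr in c(dropout_conv, dropout_attention)) {
    if (dr < 0 || dr >= 1) stop("dropout rates must be in [0, 1)")
  }
  structure(list(
    n_conv_layers = n_conv_layers, embed_dim = embed_dim,
    n_global_heads = n_global_heads, n_conv_heads = n_conv_heads,
    dropout_conv = dropout_conv, dropout_attention = dropout_attention,
    head_kind = head_kind
  ), class = "ModelConfig")
}

.CHECKPOINT_VERSION <- "toxgat-ckpt-1"

#' Initialize a model
#'
#' Weights are Glorot-uniform, reproducible for a fixed seed. Batch-norm
#' running statistics start at mean 0 / variance 1.
#'
#' @param config a [model_config()].
#' @param seed integer seed controlling initialization.
#' @return object of class `gat_model` (the ModelState: config, weights,
#'   batch-norm statistics, seed, format version).
#' @export
init_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "ModelConfig"))
  lay <- feature_layout()
  params <- withr_seed(seed, .init_params(config, lay$n_node_features))
  structure(list(
    config = config,
    params = params,
    bn = .init_bn(config),
    seed = as.integer(seed),
    n_node_features = lay$n_node_features,
    y_stats = NULL,
    version = .CHECKPOINT_VERSION
  ), class = "gat_model")
}

# evaluate `expr` under a temporary RNG seed, restoring global RNG state
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.gat_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<gat_model> %s head; %d conv layers, embed %d, %d global heads (seed %d)\n",
    cfg$head_kind, cfg$n_conv_layers, cfg$embed_dim, cfg$n_global_heads,
    x$seed))
  invisible(x)
}

#' Forward pass
#'
#' Generic: evaluates a model on one featurized molecule in evaluation mode
#' (stored batch-norm statistics, no dropout), so the result is deterministic
#' and independent of batching. For classification models the returned value
#' is the raw logit; use [stats::plogis()] or `capture = TRUE` for the
#' probability.
#'
#' @param state a model (e.g. `gat_model` or a mock from [mock_model()]).
#' @param graph a `MoleculeGraph`.
#' @param capture when TRUE, also return the attention trace.
#' @param ... passed to methods.
#' @return numeric scalar, or when `capture = TRUE` a list with elements
#'   `prediction`, `probability` (classification only) and `trace` (list with
#'   `local`: per-layer m x m row-stochastic attention matrices, `global`:
#'   per-head m x m row-stochastic matrices).
#' @export
forward <- function(state, graph, capture = FALSE, ...) {
  UseMethod("forward")
}

#' @export
forward.gat_model <- function(state, graph, capture = FALSE, ...) {
  .check_graph_compat(state, graph)
  batch <- .compile_batch(list(graph))
  res <- .nn_forward(state$params, state$bn, state$config, batch,
                     training = FALSE, capture = capture)
  y <- .postprocess_y(state, res$y)
  if (!capture) return(y)
  out <- list(prediction = y, trace = res$trace)
  if (state$config$head_kind == "binary-classification") {
    out$probability <- stats::plogis(y)
  }
  out
}

.postprocess_y <- function(state, y) {
  if (!is.null(state$y_stats)) {
    y * state$y_stats$sd + state$y_stats$mean
  } else {
    y
  }
}

.check_graph_compat <- function(state, graph) {
  if (ncol(graph$node_features) != state$n_node_features) {
    stop("graph has ", ncol(graph$node_features),
         " node features but model expects ", state$n_node_features)
  }
}

#' Batched prediction
#'
#' Evaluates the model on a list of graphs; element `i` equals
#' `forward(state, graphs[[i]])` regardless of batch composition (evaluation
#' mode uses stored normalization statistics and attention is confined to
#' each molecule's block).
#'
#' @param state a model.
#' @param graphs nonempty list of `MoleculeGraph` objects.
#' @param chunk_nodes approximate number of atoms per internal batch.
#' @return numeric vector of predictions (logits for classification).
#' @export
predict_batch <- function(state, graphs, chunk_nodes = 20000L) {
  UseMethod("predict_batch")
}

#' @export
predict_batch.gat_model <- function(state, graphs, chunk_nodes = 20000L) {
  if (length(graphs) == 0L) stop("empty graph list")
  for (g in graphs) .check_graph_compat(state, g)
  sizes <- vapply(graphs, n_atoms, integer(1))
  out <- numeric(length(graphs))
  start <- 1L
  while (start <= length(graphs)) {
    end <- start
    tot <- sizes[start]
    while (end < length(graphs) && tot + sizes[end + 1L] <= chunk_nodes) {
      end <- end + 1L
      tot <- tot + sizes[end]
    }
    batch <- .compile_batch(graphs[start:end])
    res <- .nn_forward(state$params, state$bn, state$config, batch,
                       training = FALSE)
    out[start:end] <- .postprocess_y(state, res$y)
    start <- end + 1L
  }
  out
}

#' @export
predict_batch.default <- function(state, graphs, chunk_nodes = NULL) {
  if (length(graphs) == 0L) stop("empty graph list")
  vapply(graphs, function(g) forward(state, g), numeric(1))
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single serialized file embedding config, seed, weights,
#' normalization statistics and a format version string.
#'
#' @param state a `gat_model`.
#' @param path file path.
#' @return `load_model` returns the `gat_model`.
#' @export
save_model <- function(state, path) {
  stopifnot(inherits(state, "gat_model"))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  state <- readRDS(path)
  if (!identical(state$version, .CHECKPOINT_VERSION)) {
    stop("checkpoint format '", state$version %||% "?",
         "' not supported (expected ", .CHECKPOINT_VERSION, ")")
  }
  state
}

#' Wrap an arbitrary scoring function as a model
#'
#' Useful for tests and oracles: `fun(graph)` must return a numeric scalar.
#' The wrapper participates in [forward()], [predict_batch()] and the Shapley
#' machinery like any trained model.
#'
#' @param fun function of one `MoleculeGraph`.
#' @param head_kind output semantics (`"regression"` or
#'   `"binary-classification"`, in which case `fun` returns a logit).
#' @return object of class `mock_model`.
#' @export
mock_model <- function(fun, head_kind = "regression") {
  structure(list(fun = fun, config = list(head_kind = head_kind),
                 n_node_features = feature_layout()$n_node_features),
            class = "mock_model")
}

#' @export
forward.mock_model <- function(state, graph, capture = FALSE, ...) {
  y <- state$fun(graph)
  if (!capture) return(y)
  out <- list(prediction = y, trace = NULL)
  if (identical(state$config$head_kind, "binary-classification")) {
    out$probability <- stats::plogis(y)
  }
  out
}
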