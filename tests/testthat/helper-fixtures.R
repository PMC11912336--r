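# Shared fixtures: small model configs, mock models, graph utilities.

# session cache so expensive trained models are shared between tests
.test_cache <- new.env(parent = emptyenv())

# Desk-scale training setup shared by the module and acceptance tests:
# generator defaults (n = 2000 pretraining molecules, noise_sd 0.2), model
# scaled to embed_dim 32 with correspondingly larger learning rates so one
# run fits in ~1.5 min on a single CPU.
acc_model_config <- function(head_kind = "regression") {
  model_config(n_conv_layers = 3, embed_dim = 32, n_global_heads = 4,
               head_kind = head_kind)
}

get_cached_pretrained <- function(seed = 1L) {
  key <- paste0("pretrained_", seed)
  if (is.null(.test_cache[[key]])) {
    ds <- make_pretrain_set(2000, seed = seed)
    .test_cache[[key]] <- pretrain(
      ds, acc_model_config(),
      train_config(learning_rate = 1e-3, max_epochs = 40,
                   patience = 8, batch_size = 64, seed = seed))
  }
  .test_cache[[key]]
}

get_cached_task <- function(seed = 1L) {
  key <- paste0("task_", seed)
  if (is.null(.test_cache[[key]])) {
    .test_cache[[key]] <- make_task_set(250, seed = 100L + seed)
  }
  .test_cache[[key]]
}

finetune_train_config <- function(seed) {
  train_config(learning_rate = 5e-4, max_epochs = 30, patience = 8,
               batch_size = 32, seed = seed, validation_fraction = 1 / 9)
}

scratch_train_config <- function(seed) {
  train_config(learning_rate = 1e-3, max_epochs = 30, patience = 8,
               batch_size = 32, seed = seed, validation_fraction = 1 / 9)
}

get_cached_finetuned <- function(seed = 1L) {
  key <- paste0("finetuned_", seed)
  if (is.null(.test_cache[[key]])) {
    .test_cache[[key]] <- finetune(get_cached_pretrained(seed),
                                   get_cached_task(seed),
                                   finetune_train_config(1000L + seed))
  }
  .test_cache[[key]]
}

small_config <- function(head_kind = "regression", embed = 16L, layers = 2L,
                         heads = 2L) {
  model_config(n_conv_layers = layers, embed_dim = embed,
               n_global_heads = heads, n_conv_heads = 1L,
               dropout_conv = 0, dropout_attention = 0,
               head_kind = head_kind)
}

# deterministic label-independent scorer (for random-predictor baselines)
hash_score_model <- function() {
  mock_model(function(graph) {
    h <- sum(utf8ToInt(graph$smiles) * seq_len(nchar(graph$smiles)))
    (h * 2654435761) %% 100003 / 100003
  })
}

# apply an atom permutation to a MoleculeGraph: atom k -> position perm[k]
permute_graph <- function(graph, perm) {
  inv <- order(perm)
  out <- graph
  out$node_features <- graph$node_features[inv, , drop = FALSE]
  bl <- cbind(perm[graph$bond_list[, 1]], perm[graph$bond_list[, 2]])
  swap <- bl[, 1] > bl[, 2]
  bl[swap, ] <- bl[swap, c(2, 1)]
  out$bond_list <- bl
  out$adjacency <- graph$adjacency[inv, inv, drop = FALSE]
  out
}

# all connected atom subsets of a graph up to a size cap
connected_subsets <- function(graph, max_size = Inf) {
  A <- graph$adjacency
  m <- nrow(A)
  found <- new.env(hash = TRUE)
  out <- list()
  grow <- function(set) {
    key <- paste(set, collapse = ",")
    if (!is.null(found[[key]])) return(invisible())
    found[[key]] <- TRUE
    out[[length(out) + 1L]] <<- set
    if (length(set) >= max_size) return(invisible())
    nb <- setdiff(which(colSums(A[set, , drop = FALSE] != 0) > 0), set)
    for (w in nb) grow(sort(c(set, w)))
  }
  for (s in seq_len(m)) grow(s)
  out
}

# row-stochastic random matrix
rand_stochastic <- function(m) {
  M <- matrix(stats::runif(m * m), m, m)
  M / rowSums(M)
}

# tiny delimited-table writer for read_smiles_table tests
write_table_fixture <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
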