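test_that("config validation and reproducible initialization", {
  expect_error(model_config(embed_dim = 130, n_global_heads = 4), "divisible")
  expect_error(model_config(dropout_conv = 1), "dropout")
  expect_error(model_config(n_conv_layers = 0), "n_conv_layers")

  cfg <- small_config()
  a <- init_model(cfg, seed = 5)
  b <- init_model(cfg, seed = 5)
  c <- init_model(cfg, seed = 6)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params$conv1_W, c$params$conv1_W))
})

test_that("analytic gradients match finite differences", {
  cfg <- model_config(n_conv_layers = 2, embed_dim = 8, n_global_heads = 2,
                      n_conv_heads = 2, dropout_conv = 0,
                      dropout_attention = 0)
  st <- init_model(cfg, seed = 3)
  batch <- toxgat:::.compile_batch(list(featurize("CCO"),
                                        featurize("c1ccccc1N")))
  y <- c(0.5, -1.2)
  lossfun <- function(params) {
    r <- toxgat:::.nn_forward(params, st$bn, cfg, batch, training = TRUE)
    sum((r$y - y)^2)
  }
  r <- toxgat:::.nn_forward(st$params, st$bn, cfg, batch, training = TRUE)
  gr <- toxgat:::.nn_backward(st$params, cfg, batch, r$cache, 2 * (r$y - y))
  eps <- 1e-5
  set.seed(7)
  for (nm in names(st$params)) {
    p <- st$params[[nm]]
    for (k in sample(length(p), min(3, length(p)))) {
      pp <- st$params; pp[[nm]][k] <- pp[[nm]][k] + eps
      pm <- st$params; pm[[nm]][k] <- pm[[nm]][k] - eps
      num <- (lossfun(pp) - lossfun(pm)) / (2 * eps)
      expect_equal(unname(gr[[nm]][k]), num, tolerance = 1e-3,
                   label = paste("grad", nm, k))
    }
  }
})

test_that("forward is deterministic in eval mode and batching-independent", {
  st <- init_model(small_config(), seed = 1)
  g1 <- featurize("CCO")
  g2 <- featurize("c1ccc(Cl)cc1")
  ga <- featurize("C")  # single atom
  expect_identical(forward(st, g1), forward(st, g1))
  f1 <- forward(st, g1); f2 <- forward(st, g2); fa <- forward(st, ga)
  pb <- predict_batch(st, list(g1, g2, ga))
  pb_rev <- predict_batch(st, list(ga, g2, g1))
  expect_equal(pb, c(f1, f2, fa), tolerance = 1e-6)
  expect_equal(pb_rev, c(fa, f2, f1), tolerance = 1e-6)
  expect_equal(predict_batch(st, list(g2)), f2, tolerance = 1e-12)
  expect_error(predict_batch(st, list()), "empty")
})

test_that("attention trace invariants hold", {
  st <- init_model(small_config(layers = 3), seed = 2)
  for (smi in c("CCO", "c1ccccc1", "NC(=S)Nc1ccccc1")) {
    g <- featurize(smi)
    m <- n_atoms(g)
    res <- forward(st, g, capture = TRUE)
    tr <- res$trace
    expect_length(tr$local, 3)
    expect_length(tr$global, st$config$n_global_heads)
    closed <- g$adjacency + diag(m)
    for (Cl in tr$local) {
      expect_equal(rowSums(Cl), rep(1, m), tolerance = 1e-5)
      expect_true(all(Cl[closed == 0] == 0))  # closed-neighborhood support
    }
    for (Ah in tr$global) {
      expect_equal(rowSums(Ah), rep(1, m), tolerance = 1e-5)
    }
  }
  # single-atom molecule: every global head is [[1]]
  tra <- forward(st, featurize("C"), capture = TRUE)$trace
  for (Ah in tra$global) expect_equal(Ah, matrix(1, 1, 1))
})

test_that("forward and trace are permutation-equivariant", {
  st <- init_model(small_config(), seed = 4)
  g <- featurize("NC(=S)Nc1ccccc1")
  m <- n_atoms(g)
  set.seed(11)
  perm <- sample(m)
  gp <- permute_graph(g, perm)
  expect_equal(forward(st, gp), forward(st, g), tolerance = 1e-5)
  tr <- forward(st, g, capture = TRUE)$trace
  trp <- forward(st, gp, capture = TRUE)$trace
  P <- diag(m)[, perm, drop = FALSE]  # maps original coords to permuted
  for (l in seq_along(tr$local)) {
    expect_equal(trp$local[[l]], P %*% tr$local[[l]] %*% t(P),
                 tolerance = 1e-5)
  }
  for (h in seq_along(tr$global)) {
    expect_equal(trp$global[[h]], P %*% tr$global[[h]] %*% t(P),
                 tolerance = 1e-5)
  }
})

test_that("classification head exposes logit and probability", {
  st <- init_model(small_config(head_kind = "binary-classification"), seed = 9)
  g <- featurize("CCN")
  res <- forward(st, g, capture = TRUE)
  expect_equal(res$probability, stats::plogis(res$prediction))
  expect_gt(res$probability, 0)
  expect_lt(res$probability, 1)
})

test_that("checkpoint round trip preserves predictions", {
  st <- init_model(small_config(), seed = 8)
  path <- tempfile(fileext = ".rds")
  save_model(st, path)
  st2 <- load_model(path)
  g <- featurize("c1ccncc1")
  expect_identical(forward(st2, g), forward(st, g))
  broken <- st
  broken$version <- "bogus"
  path2 <- tempfile(fileext = ".rds")
  saveRDS(broken, path2)
  expect_error(load_model(path2), "format")
})
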