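# Internal neural-network engine: batched forward/backward passes for the
# GAT + global-multihead-attention architecture, plus AdamW.
#
# Molecules in a mini-batch are laid out as one block-diagonal graph (edges
# never cross molecules); graph-attention convolutions operate on the edge
# list, the global attention block and the pooled readout operate per
# molecule. Gradients are hand-derived; test-gat_net.R checks them against
# central finite differences.

.LRELU_SLOPE <- 0.2
.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1

# --- batch compilation ------------------------------------------------------

# A compiled graph: node features + directed edge list (both directions per
# bond) + self loops appended last.
.compile_graph <- function(graph) {
  m <- nrow(graph$node_features)
  bl <- graph$bond_list
  if (nrow(bl) > 0) {
    src <- c(bl[, 1], bl[, 2], seq_len(m))
    dst <- c(bl[, 2], bl[, 1], seq_len(m))
  } else {
    src <- dst <- seq_len(m)
  }
  list(X = graph$node_features, src = src, dst = dst, m = m)
}

# Stack compiled graphs into one batch.
.compile_batch <- function(graphs) {
  cgs <- lapply(graphs, .compile_graph)
  ms <- vapply(cgs, `[[`, integer(1), "m")
  offs <- cumsum(c(0L, ms[-length(ms)]))
  M <- sum(ms)
  X <- do.call(rbind, lapply(cgs, `[[`, "X"))
  src <- unlist(mapply(function(cg, o) cg$src + o, cgs, offs,
                       SIMPLIFY = FALSE), use.names = FALSE)
  dst <- unlist(mapply(function(cg, o) cg$dst + o, cgs, offs,
                       SIMPLIFY = FALSE), use.names = FALSE)
  gid <- rep(seq_along(ms), ms)
  list(
    X = X, src = src, dst = dst, M = M, G = length(ms),
    node_idx = split(seq_len(M), gid),
    dst_f = factor(dst, levels = seq_len(M)),
    src_f = factor(src, levels = seq_len(M))
  )
}

.lrelu <- function(x) ifelse(x > 0, x, .LRELU_SLOPE * x)

# per-group max over a vector (groups = factor with all levels present)
.group_max <- function(x, f, n) {
  out <- rep(-Inf, n)
  idx <- as.integer(f)
  for (k in seq_along(x)) if (x[k] > out[idx[k]]) out[idx[k]] <- x[k]
  out
}

.add_rows <- function(M, v) M + rep(v, each = nrow(M))

# --- forward ----------------------------------------------------------------

# params: flat named list (see .init_params). bn: list(mean=list, var=list).
# Returns list(y, cache, bn, trace).
.nn_forward <- function(params, bn, cfg, batch, training = FALSE,
                        capture = FALSE) {
  D <- cfg$embed_dim
  Kc <- cfg$n_conv_heads
  dhc <- D %/% Kc
  X <- batch$X
  M <- batch$M
  src <- batch$src; dst <- batch$dst
  cache <- list(layers = vector("list", cfg$n_conv_layers))
  trace_local <- if (capture) vector("list", cfg$n_conv_layers) else NULL
  new_bn <- bn

  for (l in seq_len(cfg$n_conv_layers)) {
    p <- function(nm) params[[paste0("conv", l, "_", nm)]]
    Z <- .add_rows(X %*% p("W"), p("b"))
    Hagg <- matrix(0, M, D)
    heads <- vector("list", Kc)
    if (capture) alpha_dense <- matrix(0, M, M)
    for (k in seq_len(Kc)) {
      hc <- ((k - 1L) * dhc + 1L):(k * dhc)
      Zk <- Z[, hc, drop = FALSE]
      s_src <- drop(Zk %*% p("a_src")[, k])
      s_dst <- drop(Zk %*% p("a_dst")[, k])
      epre <- s_src[src] + s_dst[dst]
      e <- .lrelu(epre)
      gm <- .group_max(e, batch$dst_f, M)
      ex <- exp(e - gm[dst])
      den <- rowsum(ex, batch$dst_f)[, 1]
      alpha <- ex / den[dst]
      Asp <- Matrix::sparseMatrix(i = dst, j = src, x = alpha,
                                  dims = c(M, M))
      Hagg[, hc] <- as.matrix(Asp %*% Zk)
      heads[[k]] <- list(alpha = alpha, epre = epre, Asp = Asp)
      if (capture) {
        alpha_dense[cbind(dst, src)] <- alpha_dense[cbind(dst, src)] +
          alpha / Kc
      }
    }
    Hlin <- .add_rows(Hagg %*% p("P"), p("pb"))
    if (training) {
      mu <- colMeans(Hlin)
      xc <- .add_rows(Hlin, -mu)
      va <- colMeans(xc * xc)
      invstd <- 1 / sqrt(va + .BN_EPS)
      xhat <- xc * rep(invstd, each = M)
      new_bn$mean[[l]] <- (1 - .BN_MOMENTUM) * new_bn$mean[[l]] +
        .BN_MOMENTUM * mu
      new_bn$var[[l]] <- (1 - .BN_MOMENTUM) * new_bn$var[[l]] +
        .BN_MOMENTUM * va
    } else {
      invstd <- 1 / sqrt(bn$var[[l]] + .BN_EPS)
      xhat <- .add_rows(Hlin, -bn$mean[[l]]) * rep(invstd, each = M)
    }
    bno <- .add_rows(xhat * rep(p("gamma"), each = M), p("beta"))
    act <- pmax(bno, 0)
    if (training && cfg$dropout_conv > 0) {
      dmask <- matrix(
        (stats::runif(M * D) >= cfg$dropout_conv) / (1 - cfg$dropout_conv),
        M, D)
      out <- act * dmask
    } else {
      dmask <- NULL
      out <- act
    }
    cache$layers[[l]] <- list(X_in = X, Z = Z, heads = heads, Hagg = Hagg,
                              xhat = xhat, invstd = invstd, bno = bno,
                              dmask = dmask)
    if (capture) trace_local[[l]] <- alpha_dense
    X <- out
  }

  H <- X
  N <- cfg$n_global_heads
  dh <- D %/% N
  Q <- .add_rows(H %*% params$glob_Wq, params$glob_bq)
  Km <- .add_rows(H %*% params$glob_Wk, params$glob_bk)
  V <- .add_rows(H %*% params$glob_Wv, params$glob_bv)
  O <- matrix(0, M, D)
  attn <- vector("list", batch$G)
  trace_global <- if (capture) vector("list", N) else NULL
  for (g in seq_len(batch$G)) {
    ix <- batch$node_idx[[g]]
    attn[[g]] <- vector("list", N)
    for (h in seq_len(N)) {
      hc <- ((h - 1L) * dh + 1L):(h * dh)
      Qh <- Q[ix, hc, drop = FALSE]
      Kh <- Km[ix, hc, drop = FALSE]
      S <- tcrossprod(Qh, Kh) / sqrt(dh)
      S <- S - apply(S, 1, max)
      Aexp <- exp(S)
      A <- Aexp / rowSums(Aexp)
      if (training && cfg$dropout_attention > 0) {
        Am <- matrix(
          (stats::runif(length(A)) >= cfg$dropout_attention) /
            (1 - cfg$dropout_attention), nrow(A), ncol(A))
        Au <- A * Am
      } else {
        Am <- NULL
        Au <- A
      }
      O[ix, hc] <- Au %*% V[ix, hc, drop = FALSE]
      attn[[g]][[h]] <- list(A = A, Am = Am)
      if (capture) trace_global[[h]] <- A  # G == 1 when capturing
    }
  }
  Gout <- .add_rows(O %*% params$glob_Wo, params$glob_bo)
  U <- Gout + H

  Gm <- matrix(0, batch$G, 2L * D)
  amx <- vector("list", batch$G)
  for (g in seq_len(batch$G)) {
    ix <- batch$node_idx[[g]]
    Ug <- U[ix, , drop = FALSE]
    am <- max.col(t(Ug), ties.method = "first")
    amx[[g]] <- ix[am]
    Gm[g, ] <- c(Ug[cbind(am, seq_len(D))], colMeans(Ug))
  }
  h1pre <- .add_rows(Gm %*% params$head_W1, params$head_b1)
  h1 <- pmax(h1pre, 0)
  y <- drop(.add_rows(h1 %*% params$head_W2, params$head_b2))

  cache$glob <- list(H = H, Q = Q, K = Km, V = V, O = O, attn = attn)
  cache$read <- list(U = U, Gm = Gm, amx = amx, h1pre = h1pre, h1 = h1)
  list(
    y = y, cache = cache, bn = new_bn,
    trace = if (capture) list(local = trace_local, global = trace_global)
  )
}

# --- backward ---------------------------------------------------------------

# dy: gradient of loss wrt y (length G). Returns flat grads list.
.nn_backward <- function(params, cfg, batch, cache, dy) {
  D <- cfg$embed_dim
  Kc <- cfg$n_conv_heads
  dhc <- D %/% Kc
  N <- cfg$n_global_heads
  dh <- D %/% N
  M <- batch$M
  grads <- lapply(params, function(x) array(0, dim = dim(x) %||% length(x)))
  names(grads) <- names(params)

  rd <- cache$read
  gl <- cache$glob
  dy <- matrix(dy, ncol = 1)
  grads$head_W2 <- crossprod(rd$h1, dy)
  grads$head_b2 <- colSums(dy)
  dh1 <- (dy %*% t(params$head_W2)) * (rd$h1pre > 0)
  grads$head_W1 <- crossprod(rd$Gm, dh1)
  grads$head_b1 <- colSums(dh1)
  dGm <- dh1 %*% t(params$head_W1)

  dU <- matrix(0, M, D)
  for (g in seq_len(batch$G)) {
    ix <- batch$node_idx[[g]]
    mg <- length(ix)
    dU[cbind(rd$amx[[g]], seq_len(D))] <-
      dU[cbind(rd$amx[[g]], seq_len(D))] + dGm[g, seq_len(D)]
    dU[ix, ] <- dU[ix, ] +
      rep(dGm[g, (D + 1L):(2L * D)] / mg, each = mg)
  }

  dGout <- dU
  grads$glob_Wo <- crossprod(gl$O, dGout)
  grads$glob_bo <- colSums(dGout)
  dO <- dGout %*% t(params$glob_Wo)
  dQ <- matrix(0, M, D); dK <- matrix(0, M, D); dV <- matrix(0, M, D)
  for (g in seq_len(batch$G)) {
    ix <- batch$node_idx[[g]]
    for (h in seq_len(N)) {
      hc <- ((h - 1L) * dh + 1L):(h * dh)
      st <- gl$attn[[g]][[h]]
      A <- st$A
      Au <- if (is.null(st$Am)) A else A * st$Am
      dOh <- dO[ix, hc, drop = FALSE]
      dAu <- tcrossprod(dOh, gl$V[ix, hc, drop = FALSE])
      dV[ix, hc] <- dV[ix, hc] + crossprod(Au, dOh)
      dA <- if (is.null(st$Am)) dAu else dAu * st$Am
      dS <- A * (dA - rowSums(A * dA))
      dQ[ix, hc] <- dQ[ix, hc] + dS %*% gl$K[ix, hc, drop = FALSE] / sqrt(dh)
      dK[ix, hc] <- dK[ix, hc] + crossprod(dS, gl$Q[ix, hc, drop = FALSE]) /
        sqrt(dh)
    }
  }
  H <- gl$H
  grads$glob_Wq <- crossprod(H, dQ); grads$glob_bq <- colSums(dQ)
  grads$glob_Wk <- crossprod(H, dK); grads$glob_bk <- colSums(dK)
  grads$glob_Wv <- crossprod(H, dV); grads$glob_bv <- colSums(dV)
  dX <- dQ %*% t(params$glob_Wq) + dK %*% t(params$glob_Wk) +
    dV %*% t(params$glob_Wv) + dU  # + dU: residual path

  for (l in rev(seq_len(cfg$n_conv_layers))) {
    ca <- cache$layers[[l]]
    p <- function(nm) params[[paste0("conv", l, "_", nm)]]
    gname <- function(nm) paste0("conv", l, "_", nm)
    dact <- if (is.null(ca$dmask)) dX else dX * ca$dmask
    dbno <- dact * (ca$bno > 0)
    grads[[gname("gamma")]] <- colSums(dbno * ca$xhat)
    grads[[gname("beta")]] <- colSums(dbno)
    dxhat <- dbno * rep(p("gamma"), each = M)
    # batch-norm backward (training statistics)
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * ca$xhat)
    dHlin <- (rep(ca$invstd, each = M) / M) *
      (M * dxhat - rep(s1, each = M) - ca$xhat * rep(s2, each = M))
    grads[[gname("P")]] <- crossprod(ca$Hagg, dHlin)
    grads[[gname("pb")]] <- colSums(dHlin)
    dHagg <- dHlin %*% t(p("P"))
    dZ <- matrix(0, M, D)
    da_src <- matrix(0, dhc, Kc)
    da_dst <- matrix(0, dhc, Kc)
    for (k in seq_len(Kc)) {
      hc <- ((k - 1L) * dhc + 1L):(k * dhc)
      hd <- ca$heads[[k]]
      Zk <- ca$Z[, hc, drop = FALSE]
      dHk <- dHagg[, hc, drop = FALSE]
      dZ[, hc] <- as.matrix(Matrix::crossprod(hd$Asp, dHk))
      dalpha <- rowSums(dHk[batch$dst, , drop = FALSE] *
                          Zk[batch$src, , drop = FALSE])
      gsum <- rowsum(hd$alpha * dalpha, batch$dst_f)[, 1]
      de <- hd$alpha * (dalpha - gsum[batch$dst])
      depre <- de * ifelse(hd$epre > 0, 1, .LRELU_SLOPE)
      s_by_src <- rowsum(depre, batch$src_f)[, 1]
      s_by_dst <- rowsum(depre, batch$dst_f)[, 1]
      dZ[, hc] <- dZ[, hc] + outer(s_by_src, p("a_src")[, k]) +
        outer(s_by_dst, p("a_dst")[, k])
      da_src[, k] <- crossprod(Zk[batch$src, , drop = FALSE], depre)
      da_dst[, k] <- crossprod(Zk[batch$dst, , drop = FALSE], depre)
    }
    grads[[gname("a_src")]] <- da_src
    grads[[gname("a_dst")]] <- da_dst
    grads[[gname("b")]] <- colSums(dZ)
    grads[[gname("W")]] <- crossprod(ca$X_in, dZ)
    dX <- dZ %*% t(p("W"))
  }
  grads
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- initialization ---------------------------------------------------------

.glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

.init_params <- function(cfg, n_node_features) {
  D <- cfg$embed_dim
  Kc <- cfg$n_conv_heads
  dhc <- D %/% Kc
  p <- list()
  d_in <- n_node_features
  for (l in seq_len(cfg$n_conv_layers)) {
    p[[paste0("conv", l, "_W")]] <- .glorot(d_in, D)
    p[[paste0("conv", l, "_b")]] <- numeric(D)
    p[[paste0("conv", l, "_a_src")]] <- matrix(
      stats::runif(dhc * Kc, -sqrt(6 / dhc), sqrt(6 / dhc)), dhc, Kc)
    p[[paste0("conv", l, "_a_dst")]] <- matrix(
      stats::runif(dhc * Kc, -sqrt(6 / dhc), sqrt(6 / dhc)), dhc, Kc)
    p[[paste0("conv", l, "_P")]] <- .glorot(D, D)
    p[[paste0("conv", l, "_pb")]] <- numeric(D)
    p[[paste0("conv", l, "_gamma")]] <- rep(1, D)
    p[[paste0("conv", l, "_beta")]] <- numeric(D)
    d_in <- D
  }
  for (nm in c("Wq", "Wk", "Wv", "Wo")) {
    p[[paste0("glob_", nm)]] <- .glorot(D, D)
  }
  for (nm in c("bq", "bk", "bv", "bo")) {
    p[[paste0("glob_", nm)]] <- numeric(D)
  }
  p$head_W1 <- .glorot(2L * D, D)
  p$head_b1 <- numeric(D)
  p$head_W2 <- .glorot(D, 1L)
  p$head_b2 <- numeric(1L)
  p
}

.init_bn <- function(cfg) {
  list(
    mean = rep(list(numeric(cfg$embed_dim)), cfg$n_conv_layers),
    var = rep(list(rep(1, cfg$embed_dim)), cfg$n_conv_layers)
  )
}

# --- AdamW ------------------------------------------------------------------

.adamw_init <- function(params) {
  list(
    m = lapply(params, function(x) x * 0),
    v = lapply(params, function(x) x * 0),
    t = 0L
  )
}

# decoupled weight decay applied to weight matrices only (not biases,
# attention vectors or batch-norm scales)
.adamw_step <- function(params, grads, opt, lr, weight_decay,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  b1t <- 1 - beta1^opt$t
  b2t <- 1 - beta2^opt$t
  decayed <- grepl("_(W|P|Wq|Wk|Wv|Wo|W1|W2)$", names(params))
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    step <- (opt$m[[nm]] / b1t) / (sqrt(opt$v[[nm]] / b2t) + eps)
    if (decayed[match(nm, names(params))]) {
      step <- step + weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - lr * step
  }
  list(params = params, opt = opt)
}
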