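## Low-level neural primitives: dense layers, attention pooling,
## (bi)directional sequence LSTMs (C++ kernels) and child-sum tree LSTMs.
## Each *_fwd returns output + cache; each *_bwd consumes the cache and the
## upstream gradient and returns input and parameter gradients.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.runif_mat <- function(nr, nc, k) {
  matrix(stats::runif(nr * nc, -k, k), nr, nc)
}

## ---- dense ----------------------------------------------------------

.dense_fwd <- function(X, W, b) {
  # X: n x D (or vector treated as 1 x D)
  if (is.null(dim(X))) X <- matrix(X, 1)
  list(out = sweep(X %*% W, 2, b, "+"), X = X)
}

.dense_bwd <- function(cache, W, d_out) {
  if (is.null(dim(d_out))) d_out <- matrix(d_out, 1)
  list(dX = d_out %*% t(W),
       dW = t(cache$X) %*% d_out,
       db = colSums(d_out))
}

## ---- attention pooling ----------------------------------------------

## out = sum_j alpha_j H[j, ], alpha = softmax(H w + b)
.attn_fwd <- function(Hm, w, b) {
  if (is.null(dim(Hm))) Hm <- matrix(Hm, 1)
  s <- as.vector(Hm %*% w) + b
  s <- s - max(s)
  alpha <- exp(s) / sum(exp(s))
  list(out = as.vector(crossprod(Hm, alpha)), alpha = alpha, Hm = Hm)
}

.attn_bwd <- function(cache, w, d_out) {
  Hm <- cache$Hm; alpha <- cache$alpha
  dalpha <- as.vector(Hm %*% d_out)
  ds <- alpha * (dalpha - sum(alpha * dalpha))
  dHm <- tcrossprod(alpha, d_out) + tcrossprod(ds, w)
  list(dHm = dHm,
       dw = as.vector(crossprod(Hm, ds)),
       db = sum(ds))
}

## ---- sequence LSTM (C++ kernel) -------------------------------------

.lstm_fwd <- function(X, p) {
  cache <- .lstm_fwd_cpp(X, p$W, p$U, p$b)
  list(out = cache$H, X = X, cache = cache)
}

.lstm_bwd <- function(fw, p, dH) {
  .lstm_bwd_cpp(fw$X, p$W, p$U, fw$cache, dH)
}

## Bidirectional wrapper: f runs 1..T, b runs T..1; outputs concatenated.
.bilstm_fwd <- function(X, pf, pb) {
  f <- .lstm_fwd(X, pf)
  rev_idx <- rev(seq_len(nrow(X)))
  b <- .lstm_fwd(X[rev_idx, , drop = FALSE], pb)
  list(out = cbind(f$out, b$out[rev_idx, , drop = FALSE]),
       f = f, b = b, rev_idx = rev_idx)
}

.bilstm_bwd <- function(fw, pf, pb, dH) {
  H <- ncol(fw$f$out)
  gf <- .lstm_bwd(fw$f, pf, dH[, seq_len(H), drop = FALSE])
  gb <- .lstm_bwd(fw$b, pb,
                  dH[fw$rev_idx, H + seq_len(H), drop = FALSE])
  dX <- gf$dX + gb$dX[fw$rev_idx, , drop = FALSE]
  list(dX = dX, f = gf[c("dW", "dU", "db")], b = gb[c("dW", "dU", "db")])
}

## ---- child-sum tree LSTM --------------------------------------------

## Generic over a predecessor structure: preds[[v]] are the nodes whose
## (h, c) states feed node v's cell; `order` is a valid processing order
## (all predecessors before v). Bottom-up traversal uses preds = children
## with leaves first; top-down uses preds = parent with the root first.
## The forget gate has its own recurrent slice applied per predecessor;
## i/g/o act on the summed predecessor state (the child-sum variant, which
## makes the encoding invariant to branch order).
.treelstm_fwd_r <- function(X, p, order, preds) {
  n <- nrow(X); H <- nrow(p$U)
  idx <- function(k) (k - 1) * H + seq_len(H)
  XP <- sweep(X %*% p$W, 2, p$b, "+")
  Ui <- p$U[, idx(1), drop = FALSE]; Uf <- p$U[, idx(2), drop = FALSE]
  Ug <- p$U[, idx(3), drop = FALSE]; Uo <- p$U[, idx(4), drop = FALSE]
  h <- matrix(0, n, H); cst <- matrix(0, n, H); tc <- matrix(0, n, H)
  I <- matrix(0, n, H); G <- matrix(0, n, H); O <- matrix(0, n, H)
  HS <- matrix(0, n, H) # summed predecessor h per node
  Fg <- vector("list", n)
  for (v in order) {
    ks <- preds[[v]]
    h_sum <- if (length(ks)) colSums(h[ks, , drop = FALSE]) else
      numeric(H)
    i <- .sigmoid(XP[v, idx(1)] + h_sum %*% Ui)
    g <- tanh(XP[v, idx(3)] + h_sum %*% Ug)
    o <- .sigmoid(XP[v, idx(4)] + h_sum %*% Uo)
    cv <- as.vector(i * g)
    if (length(ks)) {
      fk <- matrix(0, length(ks), H)
      for (j in seq_along(ks)) {
        fk[j, ] <- .sigmoid(XP[v, idx(2)] + h[ks[j], , drop = FALSE] %*% Uf)
        cv <- cv + fk[j, ] * cst[ks[j], ]
      }
      Fg[[v]] <- fk
    }
    I[v, ] <- i; G[v, ] <- g; O[v, ] <- o; HS[v, ] <- h_sum
    cst[v, ] <- cv; tc[v, ] <- tanh(cv); h[v, ] <- O[v, ] * tc[v, ]
  }
  list(out = h, X = X, C = cst, TC = tc, I = I, G = G, O = O, HS = HS,
       Fg = Fg, order = order, preds = preds)
}

.treelstm_bwd_r <- function(fw, p, dH_ext) {
  X <- fw$X; n <- nrow(X); H <- nrow(p$U)
  idx <- function(k) (k - 1) * H + seq_len(H)
  Ui <- p$U[, idx(1), drop = FALSE]; Uf <- p$U[, idx(2), drop = FALSE]
  Ug <- p$U[, idx(3), drop = FALSE]; Uo <- p$U[, idx(4), drop = FALSE]
  dW <- matrix(0, nrow(p$W), ncol(p$W)); dU <- matrix(0, H, 4 * H)
  db <- numeric(4 * H); dX <- matrix(0, n, ncol(X))
  dh <- dH_ext; dc <- matrix(0, n, H)
  for (v in rev(fw$order)) {
    ks <- fw$preds[[v]]
    i <- fw$I[v, ]; g <- fw$G[v, ]; o <- fw$O[v, ]; tc <- fw$TC[v, ]
    dhv <- dh[v, ]
    dcv <- dc[v, ] + dhv * o * (1 - tc^2)
    da_i <- dcv * g * i * (1 - i)
    da_g <- dcv * i * (1 - g^2)
    da_o <- dhv * tc * o * (1 - o)
    da_f_sum <- numeric(H)
    dh_sum <- as.vector(da_i %*% t(Ui)) + as.vector(da_g %*% t(Ug)) +
      as.vector(da_o %*% t(Uo))
    if (length(ks)) {
      fk <- fw$Fg[[v]]
      for (j in seq_along(ks)) {
        k <- ks[j]
        df <- dcv * fw$C[k, ]
        da_f <- df * fk[j, ] * (1 - fk[j, ])
        da_f_sum <- da_f_sum + da_f
        dc[k, ] <- dc[k, ] + dcv * fk[j, ]
        dh[k, ] <- dh[k, ] + as.vector(da_f %*% t(Uf)) + dh_sum
        dU[, idx(2)] <- dU[, idx(2)] + tcrossprod(fw$out[k, ], da_f)
      }
    }
    da <- c(da_i, da_f_sum, da_g, da_o)
    dX[v, ] <- da %*% t(p$W)
    dW <- dW + tcrossprod(X[v, ], da)
    hs <- fw$HS[v, ]
    dU[, idx(1)] <- dU[, idx(1)] + tcrossprod(hs, da_i)
    dU[, idx(3)] <- dU[, idx(3)] + tcrossprod(hs, da_g)
    dU[, idx(4)] <- dU[, idx(4)] + tcrossprod(hs, da_o)
    db <- db + da
  }
  list(dX = dX, dW = dW, dU = dU, db = db)
}

## ---- dropout ---------------------------------------------------------

.dropout_fwd <- function(X, rate, training) {
  if (!training || rate <= 0) {
    return(list(out = X, mask = NULL))
  }
  mask <- matrix(stats::rbinom(length(X), 1, 1 - rate) / (1 - rate),
                 nrow(X), ncol(X))
  list(out = X * mask, mask = mask)
}

.dropout_bwd <- function(cache, d_out) {
  if (is.null(cache$mask)) d_out else d_out * cache$mask
}

## ---- parameter containers and Adam ----------------------------------

.lstm_params <- function(D, H) {
  k <- 1 / sqrt(H)
  list(W = .runif_mat(D, 4 * H, k), U = .runif_mat(H, 4 * H, k),
       b = stats::runif(4 * H, -k, k))
}

.dense_params <- function(D, Dout, bias = 0) {
  k <- 1 / sqrt(D)
  list(W = .runif_mat(D, Dout, k), b = rep(bias, Dout))
}

.attn_params <- function(D) {
  k <- 1 / sqrt(D)
  list(w = stats::runif(D, -k, k), b = 0)
}

## Flatten a nested parameter list to named numeric leaves and back.
.flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(p[[nm]])) {
      out <- c(out, .flatten_params(p[[nm]], full))
    } else {
      out[[full]] <- p[[nm]]
    }
  }
  out
}

.zero_like <- function(flat) lapply(flat, function(x) x * 0)

.adam_state <- function(flat) {
  list(m = .zero_like(flat), v = .zero_like(flat), t = 0)
}

.adam_step <- function(flat, grads, state, lr, frozen = character(0),
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(flat)) {
    if (nm %in% frozen) next
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    flat[[nm]] <- flat[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = flat, state = state)
}

.add_grad <- function(acc, add, prefix) {
  for (nm in names(add)) {
    key <- paste0(prefix, ".", nm)
    acc[[key]] <- if (is.null(acc[[key]])) add[[nm]] else
      acc[[key]] + add[[nm]]
  }
  acc
}

## C++-backed tree LSTM wrappers (the R implementations above are kept as
## an independent oracle for the kernel tests).
.treelstm_fwd <- function(X, p, order, preds) {
  poff <- c(0L, cumsum(lengths(preds)))
  pidx <- unlist(preds, use.names = FALSE)
  if (is.null(pidx)) pidx <- integer(0)
  cache <- .treelstm_fwd_cpp(X, p$W, p$U, p$b, order - 1L, pidx - 1L,
                             poff)
  cache$X <- X
  cache$order <- order
  cache$pidx <- pidx
  cache$poff <- poff
  cache
}

.treelstm_bwd <- function(fw, p, dH_ext) {
  .treelstm_bwd_cpp(fw$X, p$W, p$U, fw$order - 1L, fw$pidx - 1L,
                    fw$poff, fw, dH_ext)
}
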