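## Hand-derived backward pass mirroring .model_fwd, plus the spectral-angle
## loss layer. Gradients are returned as a flat named list matching
## .flatten_params(model$params); correctness is asserted against finite
## differences in the test suite.

.model_bwd <- function(fw, params, cfg, d) {
  p <- params
  cc <- fw$cache
  H <- cfg$hidden
  L <- cc$L
  n <- cc$n
  tree <- cc$tree
  graph <- fw$graph
  g <- list() # flat gradient accumulator

  dht <- matrix(0, n, H)     # grad into top-down node features
  dh4 <- matrix(0, L, 2 * H) # grad into post-fusion peptide features
  dchg <- numeric(2)

  ## ratio head
  r <- fw$ratio
  dz <- d$d_ratio * r * (1 - r)
  gb <- .dense_bwd(cc$rh, p$ratio_head$W, dz)
  g <- .acc(g, "ratio_head.W", gb$dW)
  g <- .acc(g, "ratio_head.b", gb$db)
  d_rap <- gb$dX[1, seq_len(2 * H)]
  d_rag <- gb$dX[1, 2 * H + seq_len(H)]
  ab <- .attn_bwd(cc$rap, p$ratio_att_p$w, d_rap)
  dh4 <- dh4 + ab$dHm
  g <- .acc(g, "ratio_att_p.w", ab$dw); g <- .acc(g, "ratio_att_p.b", ab$db)
  ab <- .attn_bwd(cc$rag, p$ratio_att_g$w, d_rag)
  dht <- dht + ab$dHm
  g <- .acc(g, "ratio_att_g.w", ab$dw); g <- .acc(g, "ratio_att_g.b", ab$db)

  ## fragment intensity heads -> cleavage features (batched kernels)
  dCF <- matrix(0, nrow(cc$CF), 2 * H)
  gy <- graph$groups[graph$groups$ion_class == "Y", ]
  if (!is.null(d$d_Y)) {
    dY_struct <- matrix(0, graph$n_Y, 3)
    for (gi in seq_len(nrow(gy))) {
      m <- gy$members[[gi]]
      dY_struct[m, ] <- matrix(d$d_Y[gi, ], length(m), 3, byrow = TRUE)
    }
    dY_struct <- dY_struct * cc$y_relu
    yb <- .frags_bwd_cpp(cc$CF, cc$yrun$idx, cc$yrun$off, p$yagg$W,
                         p$yagg$U, p$att_y$w, p$y_head$W, cc$yrun,
                         dY_struct)
    g <- .acc(g, "yagg.W", yb$dW); g <- .acc(g, "yagg.U", yb$dU)
    g <- .acc(g, "yagg.b", as.vector(yb$db))
    g <- .acc(g, "att_y.w", as.vector(yb$dattw))
    g <- .acc(g, "att_y.b", yb$dattb)
    g <- .acc(g, "y_head.W", yb$dheadW)
    g <- .acc(g, "y_head.b", as.vector(yb$dheadb))
    dCF <- dCF + yb$dCF
  }
  if (!is.null(d$d_B) && graph$n_B > 0 && length(d$d_B) > 0) {
    gbr <- graph$groups[graph$groups$ion_class == "B", ]
    dB_struct <- numeric(graph$n_B)
    for (gi in seq_len(nrow(gbr))) {
      dB_struct[gbr$members[[gi]] - graph$n_Y] <- d$d_B[gi]
    }
    dB_struct <- dB_struct * cc$b_relu
    bb2 <- .frags_bwd_cpp(cc$CF, cc$brun$idx, cc$brun$off, p$bagg$W,
                          p$bagg$U, p$att_b$w, p$b_head$W, cc$brun,
                          matrix(dB_struct, ncol = 1))
    g <- .acc(g, "bagg.W", bb2$dW); g <- .acc(g, "bagg.U", bb2$dU)
    g <- .acc(g, "bagg.b", as.vector(bb2$db))
    g <- .acc(g, "att_b.w", as.vector(bb2$dattw))
    g <- .acc(g, "att_b.b", bb2$dattb)
    g <- .acc(g, "b_head.W", bb2$dheadW)
    g <- .acc(g, "b_head.b", as.vector(bb2$dheadb))
    dCF <- dCF + bb2$dCF
  }

  ## cleavage features -> node features
  sites <- graph$cleavages
  for (s in seq_along(sites)) {
    dcf <- dCF[s, ]
    if (all(dcf == 0)) next
    ab <- .attn_bwd(cc$attn_lost[[s]], p$att_lost$w, dcf[seq_len(H)])
    dht[sites[[s]]$lost, ] <- dht[sites[[s]]$lost, , drop = FALSE] + ab$dHm
    g <- .acc(g, "att_lost.w", ab$dw); g <- .acc(g, "att_lost.b", ab$db)
    if (length(sites[[s]]$retained) > 0) {
      ab <- .attn_bwd(cc$attn_ret[[s]], p$att_ret$w, dcf[H + seq_len(H)])
      dht[sites[[s]]$retained, ] <-
        dht[sites[[s]]$retained, , drop = FALSE] + ab$dHm
      g <- .acc(g, "att_ret.w", ab$dw); g <- .acc(g, "att_ret.b", ab$db)
    }
  }

  ## top-down tree LSTM
  dht <- .dropout_bwd(cc$dot, dht)
  tb <- .treelstm_bwd(cc$td, p$td, dht)
  g <- .acc(g, "td.W", tb$dW); g <- .acc(g, "td.U", tb$dU)
  g <- .acc(g, "td.b", tb$db)
  dhb <- tb$dX[, 5 + seq_len(H), drop = FALSE]
  dchg <- dchg + colSums(tb$dX[, 5 + H + 1:2, drop = FALSE])

  ## peptide -> glycan fusion
  d_p2g <- dhb[tree$root, ]
  pb <- .dense_bwd(cc$p2g, p$p2g$W, matrix(d_p2g, 1))
  g <- .acc(g, "p2g.W", pb$dW); g <- .acc(g, "p2g.b", pb$db)
  d_s_pep <- pb$dX[1, ]

  ## peptide head
  d_pep <- d$d_pep * cc$pep_relu
  hb2 <- .dense_bwd(cc$ph, p$pep_head$W, d_pep)
  g <- .acc(g, "pep_head.W", hb2$dW); g <- .acc(g, "pep_head.b", hb2$db)
  dh4[seq_len(L - 1), ] <- dh4[seq_len(L - 1), , drop = FALSE] + hb2$dX

  ## second peptide stack
  dh4 <- .dropout_bwd(cc$do4, dh4)
  b4 <- .bilstm_bwd(cc$bl4, p$pep4$f, p$pep4$b, dh4)
  g <- .acc_bilstm(g, "pep4", b4)
  b3 <- .bilstm_bwd(cc$bl3, p$pep3$f, p$pep3$b, b4$dX)
  g <- .acc_bilstm(g, "pep3", b3)
  dpfuse <- b3$dX[, seq_len(2 * H), drop = FALSE]
  dchg <- dchg + colSums(b3$dX[, 2 * H + 1:2, drop = FALSE])

  ## glycan -> peptide fusion
  gp <- cc$gp
  d_g2p <- dpfuse[gp$glycosite, ]
  gb2 <- .dense_bwd(cc$g2p, p$g2p$W, matrix(d_g2p, 1))
  g <- .acc(g, "g2p.W", gb2$dW); g <- .acc(g, "g2p.b", gb2$db)
  dhb[tree$root, ] <- dhb[tree$root, ] + gb2$dX[1, ]

  ## first peptide stack (plus the final-state summary path)
  dh2 <- dpfuse
  dh2[L, seq_len(H)] <- dh2[L, seq_len(H)] + d_s_pep[seq_len(H)]
  dh2[1, H + seq_len(H)] <- dh2[1, H + seq_len(H)] +
    d_s_pep[H + seq_len(H)]
  dh2 <- .dropout_bwd(cc$do2, dh2)
  b2 <- .bilstm_bwd(cc$bl2, p$pep2$f, p$pep2$b, dh2)
  g <- .acc_bilstm(g, "pep2", b2)
  b1 <- .bilstm_bwd(cc$bl1, p$pep1$f, p$pep1$b, b2$dX)
  g <- .acc_bilstm(g, "pep1", b1)

  ## bottom-up tree LSTM
  dhb <- .dropout_bwd(cc$dob, dhb)
  bb <- .treelstm_bwd(cc$bu, p$bu, dhb)
  g <- .acc(g, "bu.W", bb$dW); g <- .acc(g, "bu.U", bb$dU)
  g <- .acc(g, "bu.b", bb$db)

  ## charge embedding
  dE <- matrix(0, nrow(p$chg), 2)
  dE[gp$charge, ] <- dchg
  g <- .acc(g, "chg", dE)

  g
}

.acc <- function(g, key, val) {
  g[[key]] <- if (is.null(g[[key]])) val else g[[key]] + val
  g
}

.acc_bilstm <- function(g, prefix, b) {
  for (dir in c("f", "b")) {
    g <- .acc(g, paste0(prefix, ".", dir, ".W"), b[[dir]]$dW)
    g <- .acc(g, paste0(prefix, ".", dir, ".U"), b[[dir]]$dU)
    g <- .acc(g, paste0(prefix, ".", dir, ".b"), b[[dir]]$db)
  }
  g
}

## ---- spectral-angle loss layer --------------------------------------

## d SA / d s1 for SA(s1, s2); SA = (2/pi) acos(dp).
.sa_grad <- function(s1, s2) {
  n1 <- sqrt(sum(s1^2)); n2 <- sqrt(sum(s2^2))
  if (n1 == 0 || n2 == 0) return(NULL)
  dp <- sum(s1 * s2) / (n1 * n2)
  dpc <- min(1 - 1e-9, max(-1 + 1e-9, dp))
  ddp <- s2 / (n1 * n2) - dpc * s1 / n1^2
  -(2 / pi) / sqrt(1 - dpc^2) * ddp
}

## Per-sample multi-task loss and its gradients w.r.t. the raw model
## outputs (pep matrix, Y composition matrix, B vector, ratio). Targets
## are aligned by composition name. Parts without any observed intensity
## are skipped (their SA is undefined), mirroring the spectrum filters
## that make this rare.
.loss_and_grads <- function(fw, target, weights, with_B = FALSE,
                            compute_grads = TRUE) {
  pep_p <- as.vector(fw$pep)
  pep_t <- as.vector(target$pep)
  yord <- match(rownames(fw$Y), rownames(target$Y))
  Yt <- target$Y[yord, , drop = FALSE]
  y_p <- as.vector(fw$Y)
  y_t <- as.vector(Yt)
  b_p <- as.vector(fw$B)
  b_t <- if (with_B && length(fw$B) > 0) {
    as.vector(target$B[match(names(fw$B), names(target$B))])
  } else numeric(0)
  b_t[is.na(b_t)] <- 0
  r_t <- target$ratio

  full_p <- assemble_spectrum(pep_p, y_p, b_p, fw$ratio)
  full_t <- assemble_spectrum(pep_t, y_t, b_t, r_t)

  sa <- function(a, b) {
    if (sum(a) == 0 || sum(b) == 0) NA_real_ else spectral_angle(a, b)
  }
  comp <- c(
    sa_total = sa(full_p, full_t),
    sa_pep = sa(pep_p, pep_t),
    sa_gly = sa(y_p, y_t),
    mse_ratio = (fw$ratio - r_t)^2
  )
  if (with_B) {
    comp <- c(comp, sa_B = if (length(b_p)) sa(b_p, b_t) else NA_real_)
  }
  w <- weights
  loss <- sum(w * ifelse(is.na(comp), 0, comp))
  if (!compute_grads) {
    return(list(loss = loss, components = comp))
  }

  np <- length(pep_p); ny <- length(y_p); nb <- length(b_p)
  d_pep <- numeric(np); d_y <- numeric(ny); d_b <- numeric(nb)
  d_r <- 0

  ## SA_total through the assembly normalization
  if (!is.na(comp["sa_total"])) {
    dA <- .sa_grad(full_p, full_t)
    if (!is.null(dA)) {
      dA <- w[1] * dA
      sp <- sum(pep_p); sg <- sum(c(y_p, b_p))
      if (sp > 0) {
        dA_pep <- dA[seq_len(np)]
        u <- pep_p / sp
        d_pep <- d_pep + (fw$ratio / sp) * (dA_pep - sum(dA_pep * u))
        d_r <- d_r + sum(dA_pep * u)
      }
      if (sg > 0) {
        dA_gly <- dA[np + seq_len(ny + nb)]
        vg <- c(y_p, b_p) / sg
        dg <- ((1 - fw$ratio) / sg) * (dA_gly - sum(dA_gly * vg))
        d_y <- d_y + dg[seq_len(ny)]
        if (nb > 0) d_b <- d_b + dg[ny + seq_len(nb)]
        d_r <- d_r - sum(dA_gly * vg)
      }
    }
  }
  if (!is.na(comp["sa_pep"])) {
    gsa <- .sa_grad(pep_p, pep_t)
    if (!is.null(gsa)) d_pep <- d_pep + w[2] * gsa
  }
  if (!is.na(comp["sa_gly"])) {
    gsa <- .sa_grad(y_p, y_t)
    if (!is.null(gsa)) d_y <- d_y + w[3] * gsa
  }
  d_r <- d_r + w[4] * 2 * (fw$ratio - r_t)
  if (with_B && length(b_p) && !is.na(comp["sa_B"])) {
    gsa <- .sa_grad(b_p, b_t)
    if (!is.null(gsa)) d_b <- d_b + w[5] * gsa
  }

  list(
    loss = loss, components = comp,
    d = list(
      d_pep = matrix(d_pep, nrow(fw$pep), 4),
      d_Y = matrix(d_y, nrow(fw$Y), 3),
      d_B = d_b,
      d_ratio = d_r
    )
  )
}
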