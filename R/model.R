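#' Model configuration
#'
#' Hyperparameters of the spectrum-prediction network. The defaults
#' fix the reference architecture sizes: hidden width 256 throughout
#' (so cleavage feature vectors are 512-wide), dropout 0.25, two stacked
#' BiLSTM layers before and two after the glycan fusion, a 2-dimensional
#' precursor-charge embedding, a 4-channel peptide head (b/y at charges
#' 1-2), a 3-channel Y head (charges 1-3) and a 1-channel B head.
#'
#' @param hidden Hidden width of every LSTM/tree-LSTM layer.
#' @param dropout Dropout rate, applied in training mode only.
#' @param with_B Include the B-ion (branch fragment) prediction head.
#' @param max_charge Largest precursor charge supported by the embedding.
#' @return A `glyco_config` list.
#' @export
glyco_config <- function(hidden = 256, dropout = 0.25, with_B = FALSE,
                         max_charge = 6) {
  stopifnot(hidden >= 1, dropout >= 0, dropout < 1, max_charge >= 1)
  structure(list(hidden = as.integer(hidden), dropout = dropout,
                 with_B = isTRUE(with_B),
                 max_charge = as.integer(max_charge)),
            class = "glyco_config")
}

.init_b_params <- function(H) {
  list(
    bagg = .lstm_params(2 * H, H),
    att_b = .attn_params(H),
    b_head = .dense_params(H, 1, bias = 0.1)
  )
}

#' Initialize a spectrum-prediction model
#'
#' @param config A [glyco_config()].
#' @param seed Optional RNG seed for reproducible initialization.
#' @return A `glyco_model` object (configuration + parameters).
#' @export
glyco_model <- function(config = glyco_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  H <- config$hidden
  params <- list(
    pep1 = list(f = .lstm_params(26, H), b = .lstm_params(26, H)),
    pep2 = list(f = .lstm_params(2 * H, H), b = .lstm_params(2 * H, H)),
    g2p = .dense_params(H, 2 * H),
    chg = .runif_mat(config$max_charge, 2, 1 / sqrt(2)),
    pep3 = list(f = .lstm_params(2 * H + 2, H),
                b = .lstm_params(2 * H + 2, H)),
    pep4 = list(f = .lstm_params(2 * H, H), b = .lstm_params(2 * H, H)),
    pep_head = .dense_params(2 * H, 4, bias = 0.1),
    bu = .lstm_params(5, H),
    p2g = .dense_params(2 * H, H),
    td = .lstm_params(5 + H + 2, H),
    att_lost = .attn_params(H),
    att_ret = .attn_params(H),
    yagg = .lstm_params(2 * H, H),
    att_y = .attn_params(H),
    y_head = .dense_params(H, 3, bias = 0.1),
    ratio_att_p = .attn_params(2 * H),
    ratio_att_g = .attn_params(H),
    ratio_head = .dense_params(3 * H, 1)
  )
  if (config$with_B) params <- c(params, .init_b_params(H))
  structure(list(config = config, params = params), class = "glyco_model")
}

#' Add a B-ion head to a trained model
#'
#' Creates the branch-fragment extension: the base model's layers are
#' reused and a freshly initialized B aggregation LSTM, attention and
#' intensity head are added.
#'
#' @param model A `glyco_model` without B head.
#' @param seed Optional RNG seed.
#' @return A `glyco_model` with `with_B = TRUE`.
#' @export
add_b_head <- function(model, seed = NULL) {
  stopifnot(inherits(model, "glyco_model"))
  if (model$config$with_B) return(model)
  if (!is.null(seed)) set.seed(seed)
  model$params <- c(model$params, .init_b_params(model$config$hidden))
  model$config$with_B <- TRUE
  model
}

#' @export
print.glyco_model <- function(x, ...) {
  cat("<glyco_model> hidden ", x$config$hidden,
      if (x$config$with_B) ", with B-ion head", "; ",
      format(n_parameters(x), big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param model A `glyco_model`.
#' @return Integer parameter count (about 7 million at the default
#'   configuration).
#' @export
n_parameters <- function(model) {
  sum(vapply(.flatten_params(model$params), length, integer(1)))
}

## ---- input encodings -------------------------------------------------

.aa_alphabet <- names(.aa_mass)

.encode_peptide_input <- function(gp) {
  aa <- strsplit(gp$peptide, "")[[1]]
  L <- length(aa)
  X <- matrix(0, L, 26)
  X[cbind(seq_len(L), match(aa, .aa_alphabet))] <- 1
  if (nrow(gp$mods) > 0) {
    for (k in seq_len(nrow(gp$mods))) {
      X[gp$mods$pos[k], 21:26] <-
        X[gp$mods$pos[k], 21:26] + parse_formula(gp$mods$formula[k])
    }
  }
  X
}

.mono_onehot_order <- c("H", "N", "A", "G", "F")

.encode_glycan_input <- function(tree) {
  n <- length(tree$code)
  X <- matrix(0, n, 5)
  X[cbind(seq_len(n), match(tree$code, .mono_onehot_order))] <- 1
  X
}

.tree_traversals <- function(tree) {
  # breadth-first order from the root
  bfs <- tree$root
  i <- 1L
  while (i <= length(bfs)) {
    bfs <- c(bfs, tree$children[[bfs[i]]])
    i <- i + 1L
  }
  preds_td <- lapply(seq_along(tree$code), function(v) {
    if (is.na(tree$parent[v])) integer(0) else tree$parent[v]
  })
  list(order_bu = rev(bfs), preds_bu = tree$children,
       order_td = bfs, preds_td = preds_td)
}

## ---- forward pass ----------------------------------------------------

## Full forward pass. Returns predicted parts and, when `keep_cache`, all
## intermediates needed by .model_bwd.
.model_fwd <- function(params, cfg, gp, graph = NULL, training = FALSE,
                       shuffle = FALSE, keep_cache = training) {
  H <- cfg$hidden
  p <- params
  if (gp$charge < 1 || gp$charge > cfg$max_charge) {
    stop("unsupported precursor charge ", gp$charge,
         " (model supports 1-", cfg$max_charge, ")")
  }
  if (is.null(graph)) {
    graph <- build_fragmentation_graph(gp$glycan, with_B = cfg$with_B)
  }
  tree <- gp$glycan
  L <- nchar(gp$peptide)
  stopifnot(L >= 2)

  ## peptide encoder
  X <- .encode_peptide_input(gp)
  bl1 <- .bilstm_fwd(X, p$pep1$f, p$pep1$b)
  bl2 <- .bilstm_fwd(bl1$out, p$pep2$f, p$pep2$b)
  do2 <- .dropout_fwd(bl2$out, cfg$dropout, training)
  h2 <- do2$out
  s_pep <- c(h2[L, seq_len(H)], h2[1, H + seq_len(H)])

  ## glycan bottom-up encoder
  trv <- .tree_traversals(tree)
  Xg <- .encode_glycan_input(tree)
  bu <- .treelstm_fwd(Xg, p$bu, trv$order_bu, trv$preds_bu)
  dob <- .dropout_fwd(bu$out, cfg$dropout, training)
  hb <- dob$out

  ## fusion glycan -> peptide, charge concat, second peptide stack
  g2p <- .dense_fwd(hb[tree$root, ], p$g2p$W, p$g2p$b)
  pfuse <- h2
  pfuse[gp$glycosite, ] <- pfuse[gp$glycosite, ] + as.vector(g2p$out)
  chg <- p$chg[gp$charge, ]
  P3in <- cbind(pfuse, matrix(chg, L, 2, byrow = TRUE))
  bl3 <- .bilstm_fwd(P3in, p$pep3$f, p$pep3$b)
  bl4 <- .bilstm_fwd(bl3$out, p$pep4$f, p$pep4$b)
  do4 <- .dropout_fwd(bl4$out, cfg$dropout, training)
  h4 <- do4$out
  ph <- .dense_fwd(h4[seq_len(L - 1), , drop = FALSE],
                   p$pep_head$W, p$pep_head$b)
  pep_int <- pmax(ph$out, 0)
  colnames(pep_int) <- c("b1", "b2", "y1", "y2")

  ## fusion peptide -> glycan, charge concat, top-down tree LSTM
  p2g <- .dense_fwd(s_pep, p$p2g$W, p$p2g$b)
  hb2 <- hb
  hb2[tree$root, ] <- hb2[tree$root, ] + as.vector(p2g$out)
  n <- length(tree$code)
  TDin <- cbind(Xg, hb2, matrix(chg, n, 2, byrow = TRUE))
  td <- .treelstm_fwd(TDin, p$td, trv$order_td, trv$preds_td)
  dot <- .dropout_fwd(td$out, cfg$dropout, training)
  ht <- dot$out

  ## cleavage feature vectors (attention over lost / retained nodes)
  sites <- graph$cleavages
  CF <- matrix(0, length(sites), 2 * H)
  attn_lost <- vector("list", length(sites))
  attn_ret <- vector("list", length(sites))
  for (s in seq_along(sites)) {
    al <- .attn_fwd(ht[sites[[s]]$lost, , drop = FALSE],
                    p$att_lost$w, p$att_lost$b)
    attn_lost[[s]] <- al
    u_ret <- numeric(H)
    if (length(sites[[s]]$retained) > 0) {
      ar <- .attn_fwd(ht[sites[[s]]$retained, , drop = FALSE],
                      p$att_ret$w, p$att_ret$b)
      attn_ret[[s]] <- ar
      u_ret <- ar$out
    }
    CF[s, ] <- c(al$out, u_ret)
  }

  ## per-fragment aggregation: LSTM over cleavage features + attention,
  ## batched into one kernel call per ion class
  frags <- graph$fragments
  agg_run <- function(ids, agg_p, att_p, head_p) {
    ords <- lapply(ids, function(j) {
      o <- frags[[j]]$cleavages
      if (shuffle && length(o) > 1) o <- sample(o)
      o
    })
    idx <- unlist(ords, use.names = FALSE) - 1L
    off <- c(0L, cumsum(lengths(ords)))
    res <- .frags_fwd_cpp(CF, idx, off, agg_p$W, agg_p$U, agg_p$b,
                          att_p$w, att_p$b, head_p$W, head_p$b)
    res$idx <- idx
    res$off <- off
    res
  }
  yrun <- agg_run(seq_len(graph$n_Y), p$yagg, p$att_y, p$y_head)
  y_struct <- pmax(yrun$out, 0)
  brun <- NULL
  b_struct <- numeric(graph$n_B)
  if (graph$n_B > 0) {
    brun <- agg_run(graph$n_Y + seq_len(graph$n_B),
                    p$bagg, p$att_b, p$b_head)
    b_struct <- pmax(as.vector(brun$out), 0)
  }

  ## composition-level intensities (sum over isomeric members)
  gy <- graph$groups[graph$groups$ion_class == "Y", ]
  Ymat <- matrix(0, nrow(gy), 3, dimnames = list(gy$comp, NULL))
  for (gi in seq_len(nrow(gy))) {
    m <- gy$members[[gi]]
    Ymat[gi, ] <- colSums(y_struct[m, , drop = FALSE])
  }
  gb <- graph$groups[graph$groups$ion_class == "B", ]
  Bvec <- numeric(nrow(gb))
  names(Bvec) <- gb$comp
  for (gi in seq_len(nrow(gb))) {
    Bvec[gi] <- sum(b_struct[gb$members[[gi]] - graph$n_Y])
  }

  ## peptide-fraction ratio head
  rap <- .attn_fwd(h4, p$ratio_att_p$w, p$ratio_att_p$b)
  rag <- .attn_fwd(ht, p$ratio_att_g$w, p$ratio_att_g$b)
  rh <- .dense_fwd(c(rap$out, rag$out), p$ratio_head$W, p$ratio_head$b)
  ratio <- .sigmoid(rh$out[1, 1])

  out <- list(pep = pep_int, Y = Ymat, B = Bvec, ratio = ratio,
              y_struct = y_struct, b_struct = b_struct, graph = graph)
  if (keep_cache) {
    out$cache <- list(
      X = X, bl1 = bl1, bl2 = bl2, do2 = do2, s_pep = s_pep,
      Xg = Xg, bu = bu, dob = dob, g2p = g2p, P3in = P3in, bl3 = bl3,
      bl4 = bl4, do4 = do4, ph = ph, p2g = p2g, TDin = TDin, td = td,
      dot = dot, CF = CF, attn_lost = attn_lost, attn_ret = attn_ret,
      yrun = yrun, brun = brun, rap = rap, rag = rag, rh = rh, trv = trv,
      L = L, n = n, tree = tree, gp = gp, hb = hb, h2 = h2, h4 = h4,
      ht = ht, pep_relu = ph$out > 0,
      y_relu = yrun$out > 0,
      b_relu = if (is.null(brun)) NULL else as.vector(brun$out) > 0
    )
  }
  out
}

#' Assemble a full predicted spectrum from its parts
#'
#' The peptide part is scaled to total intensity `ratio`, the glycan part
#' (Y and B jointly) to `1 - ratio`, so the assembled vector sums to one.
#' A part with zero total contributes zeros while the other part keeps its
#' share.
#'
#' @param pep Non-negative peptide intensities (vector or matrix).
#' @param Y Non-negative Y intensities (vector or matrix).
#' @param B Optional non-negative B intensities.
#' @param ratio Peptide fraction in `(0, 1)`.
#' @return Numeric vector: peptide entries, then Y, then B.
#' @export
assemble_spectrum <- function(pep, Y, B = numeric(0), ratio) {
  vp <- as.vector(pep)
  vg <- c(as.vector(Y), as.vector(B))
  sp <- sum(vp); sg <- sum(vg)
  c(if (sp > 0) ratio * vp / sp else vp * 0,
    if (sg > 0) (1 - ratio) * vg / sg else vg * 0)
}

#' Predict the fragment spectrum of a glycopeptide
#'
#' Runs the model in evaluation mode (deterministic; dropout off; canonical
#' cleavage ordering) and returns the predicted spectrum as a tibble on the
#' model's output index.
#'
#' @param object A `glyco_model`.
#' @param gp A [glycopeptide()] (or list of them).
#' @param ... Unused.
#' @return A tibble with columns `part`, `series`, `pos`, `comp`, `charge`,
#'   `mz`, `intensity` (assembled, summing to 1 per precursor), plus
#'   attribute-like columns `precursor` and `ratio`.
#' @export
predict.glyco_model <- function(object, gp, ...) {
  if (inherits(gp, "glycopeptide")) gp <- list(gp)
  purrr::map_dfr(gp, function(g) {
    fw <- .model_fwd(object$params, object$config, g,
                     training = FALSE, keep_cache = FALSE)
    prediction_table(g, fw)
  })
}

#' Tabulate a forward-pass result
#'
#' @param gp The [glycopeptide()] that was predicted.
#' @param fw A forward-pass result from the model.
#' @return Tibble of assembled fragment intensities with m/z values.
#' @keywords internal
#' @export
prediction_table <- function(gp, fw) {
  L1 <- nrow(fw$pep)
  pep_tab <- tidyr::expand_grid(pos = seq_len(L1),
                                col = c("b1", "b2", "y1", "y2"))
  pep_tab$series <- substr(pep_tab$col, 1, 1)
  pep_tab$charge <- as.integer(substr(pep_tab$col, 2, 2))
  pep_tab$part <- "pep"
  pep_tab$comp <- NA_character_
  pep_tab$raw <- fw$pep[cbind(pep_tab$pos,
                              match(pep_tab$col, colnames(fw$pep)))]
  y_tab <- tidyr::expand_grid(comp = rownames(fw$Y), charge = 1:3)
  y_tab$part <- "Y"; y_tab$series <- "Y"; y_tab$pos <- NA_integer_
  y_tab$raw <- fw$Y[cbind(match(y_tab$comp, rownames(fw$Y)),
                          y_tab$charge)]
  b_tab <- NULL
  if (length(fw$B) > 0) {
    b_tab <- tibble::tibble(part = "B", series = "B", pos = NA_integer_,
                            comp = names(fw$B), charge = 1L,
                            raw = unname(fw$B))
  }
  tab <- dplyr::bind_rows(pep_tab[, c("part", "series", "pos", "comp",
                                      "charge", "raw")],
                          y_tab[, c("part", "series", "pos", "comp",
                                    "charge", "raw")],
                          b_tab)
  full <- assemble_spectrum(
    tab$raw[tab$part == "pep"],
    tab$raw[tab$part == "Y"],
    if (is.null(b_tab)) numeric(0) else tab$raw[tab$part == "B"],
    fw$ratio
  )
  tab$intensity <- full
  tab$mz <- NA_real_
  is_pep <- tab$part == "pep"
  if (any(is_pep)) {
    pf <- peptide_fragments(gp)
    key <- paste(pf$series, pf$pos, pf$charge)
    tk <- paste(tab$series[is_pep], tab$pos[is_pep], tab$charge[is_pep])
    tab$mz[is_pep] <- pf$mz[match(tk, key)]
  }
  gl <- !is_pep
  tab$mz[gl] <- mapply(function(cp, cls, z)
    glycan_fragment_mz(gp, cp, cls, z),
    tab$comp[gl], tab$part[gl], tab$charge[gl])
  tab$precursor <- precursor_id(gp)
  tab$ratio <- fw$ratio
  tab$raw <- NULL
  tibble::as_tibble(tab[, c("precursor", "part", "series", "pos", "comp",
                            "charge", "mz", "intensity", "ratio")])
}

## ---- checkpoint I/O --------------------------------------------------

#' Save / load model checkpoints
#'
#' A checkpoint is a single RDS file holding the configuration and the
#' named parameter tensors, with a format version tag.
#'
#' @param model A `glyco_model`.
#' @param path File path.
#' @return `save_model()`: `path` invisibly; `load_model()`: the model.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "glycospectra-checkpoint",
               version = 1L,
               config = unclass(model$config),
               params = model$params),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "glycospectra-checkpoint")) {
    stop("not a glycospectra checkpoint: ", path)
  }
  structure(list(config = structure(x$config, class = "glyco_config"),
                 params = x$params),
            class = "glyco_model")
}
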