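ns <- asNamespace("glycospectra")

test_that("the C++ tree LSTM agrees with the reference R implementation", {
  set.seed(81)
  for (i in 1:5) {
    tr <- random_tree(sample(3:10, 1))
    trv <- ns$.tree_traversals(tr)
    H <- 6
    p <- ns$.lstm_params(5, H)
    X <- matrix(runif(length(tr$code) * 5), ncol = 5)
    a <- ns$.treelstm_fwd(X, p, trv$order_bu, trv$preds_bu)
    b <- ns$.treelstm_fwd_r(X, p, trv$order_bu, trv$preds_bu)
    expect_equal(a$out, b$out, tolerance = 1e-12)
    dH <- matrix(runif(length(a$out)), nrow(a$out))
    ga <- ns$.treelstm_bwd(a, p, dH)
    gb <- ns$.treelstm_bwd_r(b, p, dH)
    expect_equal(ga$dX, gb$dX, tolerance = 1e-12)
    expect_equal(ga$dW, gb$dW, tolerance = 1e-12)
    expect_equal(ga$dU, gb$dU, tolerance = 1e-12)
    expect_equal(as.vector(ga$db), gb$db, tolerance = 1e-12)
  }
})

test_that("analytic gradients match finite differences on a tiny model", {
  set.seed(82)
  cfg <- glyco_config(hidden = 3, dropout = 0, with_B = TRUE,
                      max_charge = 4)
  m <- glyco_model(cfg, seed = 2)
  gp <- tiny_precursor(glycan = "(N(F)(N(H(H(N))(H(N(H))))))",
                       peptide = "ANSTK", glycosite = 2, charge = 3)
  graph <- build_fragmentation_graph(gp$glycan, with_B = TRUE)
  fw <- ns$.model_fwd(m$params, cfg, gp, graph, training = TRUE,
                      keep_cache = TRUE)
  tgt <- list(pep = matrix(runif(length(fw$pep)), nrow(fw$pep), 4),
              Y = matrix(runif(length(fw$Y)), nrow(fw$Y), 3,
                         dimnames = dimnames(fw$Y)),
              B = stats::setNames(runif(length(fw$B)), names(fw$B)),
              ratio = 0.3)
  w <- rep(1, 5)
  lg <- ns$.loss_and_grads(fw, tgt, w, with_B = TRUE)
  grads <- ns$.model_bwd(fw, m$params, cfg, lg$d)

  flat <- ns$.flatten_params(m$params)
  loss_at <- function(flat2) {
    p2 <- ns$.unflatten_params(flat2, m$params)
    fw2 <- ns$.model_fwd(p2, cfg, gp, graph, training = FALSE,
                         keep_cache = FALSE)
    ns$.loss_and_grads(fw2, tgt, w, with_B = TRUE,
                       compute_grads = FALSE)$loss
  }
  eps <- 1e-5
  check_names <- c("pep1.f.W", "pep2.b.U", "bu.U", "td.W", "g2p.W",
                   "p2g.b", "chg", "pep_head.W", "yagg.U", "att_y.w",
                   "y_head.b", "bagg.W", "att_b.w", "b_head.W",
                   "att_lost.w", "att_ret.w", "ratio_head.W",
                   "ratio_att_g.w")
  for (nm in check_names) {
    x <- flat[[nm]]
    i <- sample(length(x), 1)
    f2 <- flat
    f2[[nm]][i] <- x[i] + eps
    up <- loss_at(f2)
    f2[[nm]][i] <- x[i] - eps
    dn <- loss_at(f2)
    num <- (up - dn) / (2 * eps)
    ana <- if (is.null(grads[[nm]])) 0 else grads[[nm]][i]
    expect_equal(ana, num, tolerance = 1e-3,
                 label = paste("gradient of", nm))
  }
})

test_that("peptide encoding uses one-hot residues and elemental PTM vectors", {
  gp <- glycopeptide("ACNSTK", core_struct, 3, 2,
                     mods = tibble::tibble(pos = 2, formula = "C2H3NO"))
  X <- ns$.encode_peptide_input(gp)
  expect_equal(dim(X), c(6, 26))
  expect_true(all(rowSums(X[, 1:20]) == 1))
  # carbamidomethyl elemental vector over (H, C, N, O, S, P)
  expect_equal(X[2, 21:26], c(3, 2, 1, 1, 0, 0))
  expect_equal(X[1, 21:26], rep(0, 6)) # unmodified placeholder
  expect_error(glycopeptide("AZN", core_struct, 3, 2),
               "unknown amino acid")
})

test_that("forward pass output obeys its structural contracts", {
  m <- tiny_model(hidden = 4)
  gp <- tiny_precursor(peptide = "ANSTLYK", glycosite = 2, charge = 2)
  fw <- ns$.model_fwd(m$params, m$config, gp, training = FALSE,
                      keep_cache = FALSE)
  L <- nchar(gp$peptide)
  expect_equal(dim(fw$pep), c(L - 1, 4))
  expect_true(all(fw$pep >= 0))
  expect_true(all(fw$Y >= 0))
  expect_gt(fw$ratio, 0)
  expect_lt(fw$ratio, 1)

  # evaluation mode is deterministic
  fw2 <- ns$.model_fwd(m$params, m$config, gp, training = FALSE,
                       keep_cache = FALSE)
  expect_identical(fw$pep, fw2$pep)
  expect_identical(fw$Y, fw2$Y)
  expect_identical(fw$ratio, fw2$ratio)

  expect_error(ns$.model_fwd(m$params, m$config,
                             tiny_precursor(charge = 9)),
               "unsupported precursor charge")
})

test_that("composition-level Y intensities conserve their structure members", {
  m <- tiny_model(hidden = 4, with_B = TRUE)
  set.seed(83)
  for (i in 1:5) {
    gp <- tiny_precursor(glycan = glycan_canonical(
      glycospectra:::.sim_glycan(sim_config())), charge = 3)
    graph <- build_fragmentation_graph(gp$glycan, with_B = TRUE)
    fw <- ns$.model_fwd(m$params, m$config, gp, graph,
                        training = FALSE, keep_cache = FALSE)
    gy <- graph$groups[graph$groups$ion_class == "Y", ]
    for (gi in seq_len(nrow(gy))) {
      expect_equal(fw$Y[gi, ],
                   colSums(fw$y_struct[gy$members[[gi]], ,
                                       drop = FALSE]),
                   tolerance = 1e-12)
    }
    gb <- graph$groups[graph$groups$ion_class == "B", ]
    for (gi in seq_len(nrow(gb))) {
      expect_equal(unname(fw$B[gi]),
                   sum(fw$b_struct[gb$members[[gi]] - graph$n_Y]),
                   tolerance = 1e-12)
    }
  }
})

test_that("attention weights sum to one on every aggregation", {
  m <- tiny_model(hidden = 4)
  gp <- tiny_precursor(glycan = "(N(N(H(H(N))(H(N)))))", charge = 2)
  fw <- ns$.model_fwd(m$params, m$config, gp, training = FALSE,
                      keep_cache = TRUE)
  for (al in fw$cache$attn_lost) {
    expect_equal(sum(al$alpha), 1, tolerance = 1e-12)
  }
  run <- fw$cache$yrun
  for (k in seq_len(length(run$off) - 1)) {
    seg <- (run$off[k] + 1):run$off[k + 1]
    expect_equal(sum(run$alpha[seg]), 1, tolerance = 1e-12)
  }
  # single lost node: softmax over one element is exactly 1
  leaf_site <- which(vapply(fw$graph$cleavages, function(s)
    length(s$lost) == 1, logical(1)))[1]
  expect_equal(fw$cache$attn_lost[[leaf_site]]$alpha, 1)
})

test_that("the forward pass is invariant to branch permutation of the glycan", {
  m <- tiny_model(hidden = 4, with_B = TRUE)
  set.seed(84)
  for (i in 1:6) {
    g1 <- glycospectra:::.sim_glycan(sim_config())
    g2 <- permute_tree(g1)
    gp1 <- tiny_precursor(glycan = g1, charge = 3)
    gp2 <- tiny_precursor(glycan = g2, charge = 3)
    p1 <- predict(m, gp1)
    p2 <- predict(m, gp2)
    key <- function(x) paste(x$part, x$series, x$pos, x$comp, x$charge)
    p2 <- p2[match(key(p1), key(p2)), ]
    expect_equal(p1$intensity, p2$intensity, tolerance = 1e-6)
    expect_equal(p1$ratio[1], p2$ratio[1], tolerance = 1e-6)
  }
})

test_that("glycan fusion makes peptide output sensitive to the glycan", {
  m <- tiny_model(hidden = 4)
  gp1 <- tiny_precursor(glycan = core_struct)
  gp2 <- tiny_precursor(glycan = "(N(N(H(H(N(H)))(H(N)))))")
  fw1 <- ns$.model_fwd(m$params, m$config, gp1, training = FALSE)
  fw2 <- ns$.model_fwd(m$params, m$config, gp2, training = FALSE)
  expect_gt(max(abs(fw1$pep - fw2$pep)), 1e-8)

  # and the top-down pass makes leaves sensitive to sibling branches
  fwc1 <- ns$.model_fwd(m$params, m$config, gp1, training = FALSE,
                        keep_cache = TRUE)
  expect_false(isTRUE(all.equal(fwc1$cache$ht, fwc1$cache$hb)))
})

test_that("assembled spectra sum to one and split by the ratio", {
  pep <- c(1, 2, 3)
  Y <- c(4, 5)
  full <- assemble_spectrum(pep, Y, numeric(0), ratio = 0.3)
  expect_equal(sum(full), 1)
  expect_equal(sum(full[1:3]), 0.3)
  expect_equal(sum(full[4:5]), 0.7)
  # scaling either part leaves the output unchanged
  expect_equal(assemble_spectrum(10 * pep, 0.2 * Y, numeric(0), 0.3),
               full)
  # zero-total part contributes zeros, the other keeps its share
  z <- assemble_spectrum(c(0, 0), Y, numeric(0), 0.3)
  expect_equal(z[1:2], c(0, 0))
  expect_equal(sum(z), 0.7)
})

test_that("prediction tables carry m/z and normalized intensities", {
  m <- tiny_model(hidden = 4)
  gp <- tiny_precursor(charge = 2)
  tab <- predict(m, gp)
  expect_s3_class(tab, "tbl_df")
  expect_equal(sum(tab$intensity), 1, tolerance = 1e-9)
  expect_true(all(tab$mz > 0))
  expect_true(all(tab$intensity >= 0))
  # model without B head predicts no B rows
  expect_false("B" %in% tab$part)
  # list input binds rows
  tab2 <- predict(m, list(gp, tiny_precursor(charge = 3)))
  expect_equal(length(unique(tab2$precursor)), 2)
})

test_that("checkpoints round-trip models bit-exactly", {
  m <- tiny_model(hidden = 4, with_B = TRUE)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(back$params, m$params)
  expect_equal(unclass(back$config), unclass(m$config))
  gp <- tiny_precursor()
  expect_identical(predict(m, gp)$intensity, predict(back, gp)$intensity)
  expect_error(load_model(withr::local_tempfile(fileext = ".rds",
                                                lines = "x")),
               "checkpoint|readRDS|unknown")
})

test_that("parameter count is near 7 million at defaults", {
  cfg <- glyco_config()
  expect_equal(cfg$hidden, 256L)
  expect_equal(cfg$dropout, 0.25)
  m <- glyco_model(glyco_config(), seed = 1)
  n <- n_parameters(m)
  expect_gt(n, 5e6)
  expect_lt(n, 9e6)
  # cleavage features are 2 x hidden = 512-wide at defaults
  expect_equal(2 * m$config$hidden, 512)
})
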