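#' Training configuration
#'
#' Default optimization settings: Adam with batch
#' size 16; learning rate warmed up linearly from 0 to 0.001 over 5 epochs
#' then scheduled by cosine annealing with warm restarts (initial interval
#' 15 epochs, doubled after each restart); finetuning starts at 0.001
#' without warmup and is cut to 10% after 5 epochs without improvement;
#' the B-ion model trains at 0.0001 with the warmup + cosine schedule.
#'
#' @param batch_size Samples per optimizer step.
#' @param base_lr Peak learning rate of the main schedule.
#' @param warmup_epochs Linear warmup length in epochs.
#' @param cosine_interval Initial cosine-annealing restart interval.
#' @param restart_multiplier Interval growth factor after each restart.
#' @param finetune_lr,finetune_patience,finetune_factor Plateau-decay
#'   finetuning settings.
#' @param b_model_lr Learning rate for B-ion head training.
#' @param max_epochs Epoch budget.
#' @param seed RNG seed controlling shuffling, dropout and batch order.
#' @param dwa_temperature Softmax temperature of the dynamic weight
#'   average.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 16, base_lr = 0.001,
                         warmup_epochs = 5, cosine_interval = 15,
                         restart_multiplier = 2, finetune_lr = 0.001,
                         finetune_patience = 5, finetune_factor = 0.1,
                         b_model_lr = 0.0001, max_epochs = 60,
                         seed = 1L, dwa_temperature = 2) {
  cfg <- as.list(environment())
  stopifnot(batch_size >= 1, base_lr > 0, max_epochs >= 1)
  structure(cfg, class = "train_config")
}

#' Split a dataset into training, validation and holdout subsets
#'
#' Random, disjoint 3/5 - 1/5 - 1/5 partition at the precursor level,
#' reproducible given the seed.
#'
#' @param spectra List of one consensus `annotated_spectrum` per
#'   precursor.
#' @param seed RNG seed.
#' @return List with elements `train`, `validation`, `holdout`.
#' @export
split_dataset <- function(spectra, seed = 1L) {
  n <- length(spectra)
  if (n < 5) stop("need at least 5 spectra to split 3/5-1/5-1/5")
  idx <- withr::with_seed(seed, sample.int(n))
  n_train <- floor(n * 3 / 5)
  n_val <- floor(n / 5)
  list(train = spectra[idx[seq_len(n_train)]],
       validation = spectra[idx[n_train + seq_len(n_val)]],
       holdout = spectra[idx[(n_train + n_val + 1):n]])
}

#' Learning rate schedule
#'
#' Linear warmup from 0 to `base_lr`, followed by cosine annealing to 0
#' with warm restarts at intervals 15, 30, 60, ... epochs.
#'
#' @param epoch Epoch position (0-based; fractional values allowed).
#' @param config A [train_config()].
#' @return Learning rate.
#' @export
lr_at <- function(epoch, config = train_config()) {
  stopifnot(epoch >= 0)
  if (epoch < config$warmup_epochs) {
    return(config$base_lr * epoch / config$warmup_epochs)
  }
  t <- epoch - config$warmup_epochs
  interval <- config$cosine_interval
  while (t >= interval) {
    t <- t - interval
    interval <- interval * config$restart_multiplier
  }
  config$base_lr / 2 * (1 + cos(pi * t / interval))
}

## Expand frozen-module prefixes ("pep1", "yagg") into flat keys.
.expand_frozen <- function(flat_names, frozen) {
  if (length(frozen) == 0) return(character(0))
  hit <- vapply(flat_names, function(nm) {
    any(nm == frozen | startsWith(nm, paste0(frozen, ".")))
  }, logical(1))
  flat_names[hit]
}

## Precompute per-sample training records (targets + fragmentation graph).
## Graphs are cached per canonical glycan string: simulated datasets reuse
## tree topologies heavily.
.prep_samples <- function(spectra, with_B) {
  cache <- new.env(parent = emptyenv())
  lapply(spectra, function(ann) {
    gp <- ann$precursor
    key <- paste0(glycan_canonical(gp$glycan), "/", as.integer(with_B))
    graph <- cache[[key]]
    if (is.null(graph)) {
      graph <- build_fragmentation_graph(gp$glycan, with_B = with_B)
      cache[[key]] <- graph
    }
    list(gp = gp, graph = graph, target = spectrum_parts(ann))
  })
}

.mean_components <- function(mat) {
  apply(mat, 2, function(x) mean(x[is.finite(x)]))
}

.eval_loss <- function(params, cfg, samples, weights) {
  comps <- t(vapply(samples, function(s) {
    fw <- .model_fwd(params, cfg, s$gp, s$graph, training = FALSE,
                     keep_cache = FALSE)
    lg <- .loss_and_grads(fw, s$target, weights, with_B = cfg$with_B,
                          compute_grads = FALSE)
    c(lg$loss, lg$components)
  }, numeric(1 + length(weights))))
  colnames(comps) <- c("loss", names(.component_names(cfg$with_B)))
  .mean_components(comps)
}

.component_names <- function(with_B) {
  nm <- c(sa_total = 1, sa_pep = 2, sa_gly = 3, mse_ratio = 4)
  if (with_B) nm <- c(nm, sa_B = 5)
  nm
}

## Shared epoch loop used by train(), finetune() and train_b_model().
.run_training <- function(model, datasets, config, lr_fun,
                          frozen = character(0), use_dwa = TRUE,
                          loss_weights = NULL) {
  cfg <- model$config
  withB <- cfg$with_B
  K <- if (withB) 5L else 4L
  flat <- .flatten_params(model$params)
  frozen_keys <- .expand_frozen(names(flat), frozen)
  frozen_snapshot <- flat[frozen_keys]
  adam <- .adam_state(flat)
  train_s <- .prep_samples(datasets$train, withB)
  val_s <- .prep_samples(datasets$validation, withB)
  set.seed(config$seed)

  history <- list()
  task_hist <- list() # per-epoch mean task losses (for DWA)
  best <- list(loss = Inf, params = model$params, epoch = NA_integer_)
  uniform_w <- rep(1, K)

  for (epoch in seq_len(config$max_epochs)) {
    lr <- lr_fun(epoch - 1)
    w <- if (!use_dwa) {
      if (is.null(loss_weights)) uniform_w else loss_weights
    } else if (epoch <= 2) uniform_w else {
      dwa_weights(task_hist[[epoch - 1]], task_hist[[epoch - 2]],
                  temperature = config$dwa_temperature)
    }

    ord <- sample(length(train_s))
    batch_starts <- seq(1, length(ord), by = config$batch_size)
    epoch_comps <- matrix(NA_real_, length(train_s), K)
    epoch_loss <- numeric(0)
    si <- 0L
    cur <- .unflatten_params(flat, model$params)
    for (bs in batch_starts) {
      ids <- ord[bs:min(bs + config$batch_size - 1, length(ord))]
      gacc <- list()
      for (i in ids) {
        s <- train_s[[i]]
        fw <- .model_fwd(cur, cfg, s$gp, s$graph, training = TRUE,
                         shuffle = TRUE)
        lg <- .loss_and_grads(fw, s$target, w, with_B = withB)
        if (!is.finite(lg$loss)) {
          stop("training diverged (non-finite loss) at epoch ", epoch)
        }
        si <- si + 1L
        epoch_comps[si, ] <- lg$components
        epoch_loss <- c(epoch_loss, lg$loss)
        gs <- .model_bwd(fw, cur, cfg, lg$d)
        for (nm in names(gs)) {
          gacc[[nm]] <- if (is.null(gacc[[nm]])) gs[[nm]] else
            gacc[[nm]] + gs[[nm]]
        }
      }
      gacc <- lapply(gacc, function(x) x / length(ids))
      stepped <- .adam_step(flat, gacc, adam, lr, frozen = frozen_keys)
      flat <- stepped$params
      adam <- stepped$state
      cur <- .unflatten_params(flat, model$params)
    }

    task_means <- pmax(.mean_components(epoch_comps), 1e-8)
    task_hist[[epoch]] <- task_means
    val <- .eval_loss(.unflatten_params(flat, model$params), cfg, val_s,
                      uniform_w)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr, train_loss = mean(epoch_loss),
      val_loss = val[["loss"]],
      !!!stats::setNames(as.list(task_means),
                         paste0("train_", names(.component_names(withB)))),
      !!!stats::setNames(as.list(w), paste0("w_", seq_len(K)))
    )
    if (val[["loss"]] < best$loss - 1e-12) {
      best <- list(loss = val[["loss"]],
                   params = .unflatten_params(flat, model$params),
                   epoch = epoch)
    }
  }

  ## freezing contract: frozen parameters must be bit-identical
  final_flat <- flat
  for (nm in frozen_keys) {
    stopifnot(identical(final_flat[[nm]], frozen_snapshot[[nm]]))
  }

  model$params <- best$params
  structure(
    list(model = model, history = dplyr::bind_rows(history),
         best_epoch = best$epoch, best_val_loss = best$loss,
         final_params = .unflatten_params(final_flat, model$params),
         frozen = frozen_keys),
    class = "glyco_fit"
  )
}

.unflatten_params <- function(flat, template) {
  out <- template
  for (nm in names(flat)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) {
      out[[parts]] <- flat[[nm]]
    } else if (length(parts) == 2) {
      out[[parts[1]]][[parts[2]]] <- flat[[nm]]
    } else {
      out[[parts[1]]][[parts[2]]][[parts[3]]] <- flat[[nm]]
    }
  }
  out
}

#' Train the spectrum-prediction model
#'
#' Multi-task training: spectral angles of the whole spectrum, the peptide
#' part and the glycan Y part plus the squared error of the peptide
#' fraction are minimized jointly, with task weights balanced per epoch by
#' the dynamic weight average. The validation set controls overfitting:
#' the returned model is the checkpoint with the lowest validation total
#' loss (uniform weights).
#'
#' @param model A `glyco_model`.
#' @param datasets List with `train` and `validation` lists of
#'   `annotated_spectrum` objects (see [split_dataset()]).
#' @param config A [train_config()].
#' @param frozen Character vector of parameter-module names to freeze
#'   (e.g. `c("pep1", "pep2")` for transfer learning from a pre-trained
#'   peptide model).
#' @return A `glyco_fit`: the best model, the per-epoch loss history
#'   (tibble with losses, DWA weights, learning rate) and bookkeeping.
#' @export
train <- function(model, datasets, config = train_config(),
                  frozen = character(0)) {
  .run_training(model, datasets, config,
                lr_fun = function(e) lr_at(e, config),
                frozen = frozen, use_dwa = TRUE)
}

#' Finetune a trained model on a new dataset
#'
#' Constant initial learning rate (no warmup), reduced to 10% whenever
#' the validation loss has not improved by more than 1e-4 for
#' `finetune_patience` epochs.
#'
#' @inheritParams train
#' @return A `glyco_fit`.
#' @export
finetune <- function(model, datasets, config = train_config(),
                     frozen = character(0)) {
  sched <- local({
    lr <- config$finetune_lr
    best <- Inf
    stale <- 0L
    function(val_loss = NULL) {
      if (!is.null(val_loss)) {
        if (val_loss < best - 1e-4) {
          best <<- val_loss; stale <<- 0L
        } else {
          stale <<- stale + 1L
          if (stale >= config$finetune_patience) {
            lr <<- lr * config$finetune_factor
            stale <<- 0L
          }
        }
      }
      lr
    }
  })
  .run_plateau_training(model, datasets, config, sched, frozen = frozen)
}

## Variant of the epoch loop with plateau-based lr decay (finetuning).
.run_plateau_training <- function(model, datasets, config, sched,
                                  frozen = character(0)) {
  cfg <- model$config
  withB <- cfg$with_B
  K <- if (withB) 5L else 4L
  flat <- .flatten_params(model$params)
  frozen_keys <- .expand_frozen(names(flat), frozen)
  adam <- .adam_state(flat)
  train_s <- .prep_samples(datasets$train, withB)
  val_s <- .prep_samples(datasets$validation, withB)
  set.seed(config$seed)
  history <- list()
  task_hist <- list()
  best <- list(loss = Inf, params = model$params, epoch = NA_integer_)
  uniform_w <- rep(1, K)
  lr <- sched()
  for (epoch in seq_len(config$max_epochs)) {
    w <- if (epoch <= 2) uniform_w else {
      dwa_weights(task_hist[[epoch - 1]], task_hist[[epoch - 2]],
                  temperature = config$dwa_temperature)
    }
    ord <- sample(length(train_s))
    epoch_comps <- matrix(NA_real_, length(train_s), K)
    epoch_loss <- numeric(0)
    si <- 0L
    cur <- .unflatten_params(flat, model$params)
    for (bs in seq(1, length(ord), by = config$batch_size)) {
      ids <- ord[bs:min(bs + config$batch_size - 1, length(ord))]
      gacc <- list()
      for (i in ids) {
        s <- train_s[[i]]
        fw <- .model_fwd(cur, cfg, s$gp, s$graph, training = TRUE,
                         shuffle = TRUE)
        lg <- .loss_and_grads(fw, s$target, w, with_B = withB)
        if (!is.finite(lg$loss)) {
          stop("finetuning diverged (non-finite loss) at epoch ", epoch)
        }
        si <- si + 1L
        epoch_comps[si, ] <- lg$components
        epoch_loss <- c(epoch_loss, lg$loss)
        gs <- .model_bwd(fw, cur, cfg, lg$d)
        for (nm in names(gs)) {
          gacc[[nm]] <- if (is.null(gacc[[nm]])) gs[[nm]] else
            gacc[[nm]] + gs[[nm]]
        }
      }
      gacc <- lapply(gacc, function(x) x / length(ids))
      stepped <- .adam_step(flat, gacc, adam, lr, frozen = frozen_keys)
      flat <- stepped$params
      adam <- stepped$state
      cur <- .unflatten_params(flat, model$params)
    }
    task_hist[[epoch]] <- pmax(.mean_components(epoch_comps), 1e-8)
    val <- .eval_loss(.unflatten_params(flat, model$params), cfg, val_s,
                      uniform_w)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr, train_loss = mean(epoch_loss),
      val_loss = val[["loss"]],
      !!!stats::setNames(as.list(task_hist[[epoch]]),
                         paste0("train_",
                                names(.component_names(withB)))),
      !!!stats::setNames(as.list(w), paste0("w_", seq_len(K)))
    )
    if (val[["loss"]] < best$loss - 1e-12) {
      best <- list(loss = val[["loss"]],
                   params = .unflatten_params(flat, model$params),
                   epoch = epoch)
    }
    lr <- sched(val[["loss"]])
  }
  model$params <- best$params
  structure(
    list(model = model, history = dplyr::bind_rows(history),
         best_epoch = best$epoch, best_val_loss = best$loss,
         final_params = .unflatten_params(flat, model$params),
         frozen = frozen_keys),
    class = "glyco_fit"
  )
}

#' Train the B-ion extension of a trained model
#'
#' Adds (or reuses) the branch-fragment head and trains only its layers:
#' all modules serving peptide b/y and glycan Y prediction are frozen, so
#' Y-part predictions are unchanged for any precursor. Uses the warmup +
#' cosine schedule at the B-model learning rate; the loss gains the B-ion
#' spectral-angle term.
#'
#' @param model A trained `glyco_model` (without or with B head).
#' @param datasets As in [train()]; spectra must be annotated with B ions
#'   and should exclude high-mannose precursors and spectra failing the
#'   B-ion filter.
#' @param config A [train_config()].
#' @return A `glyco_fit` with `with_B = TRUE`.
#' @export
train_b_model <- function(model, datasets, config = train_config()) {
  model <- add_b_head(model, seed = config$seed)
  b_modules <- c("bagg", "att_b", "b_head")
  all_modules <- names(model$params)
  frozen <- setdiff(all_modules, b_modules)
  bcfg <- config
  bcfg$base_lr <- config$b_model_lr
  .run_training(model, datasets, bcfg,
                lr_fun = function(e) lr_at(e, bcfg),
                frozen = frozen, use_dwa = TRUE)
}

#' @export
print.glyco_fit <- function(x, ...) {
  cat("<glyco_fit> ", nrow(x$history), " epochs; best epoch ",
      x$best_epoch, " (validation loss ",
      signif(x$best_val_loss, 4), ")\n", sep = "")
  invisible(x)
}

#' Evaluate a model on annotated spectra
#'
#' @param model A `glyco_model`.
#' @param spectra List of `annotated_spectrum` objects.
#' @return Tibble with one row per spectrum: precursor id, the spectral
#'   angle of each part, the assembled-spectrum SA and the ratio error.
#' @export
evaluate_model <- function(model, spectra) {
  cfg <- model$config
  samples <- .prep_samples(spectra, cfg$with_B)
  purrr::map_dfr(samples, function(s) {
    fw <- .model_fwd(model$params, cfg, s$gp, s$graph, training = FALSE,
                     keep_cache = FALSE)
    lg <- .loss_and_grads(fw, s$target,
                          rep(1, if (cfg$with_B) 5 else 4),
                          with_B = cfg$with_B, compute_grads = FALSE)
    tibble::tibble(
      precursor = precursor_id(s$gp),
      sa_total = lg$components[["sa_total"]],
      sa_pep = lg$components[["sa_pep"]],
      sa_gly = lg$components[["sa_gly"]],
      sa_B = if (cfg$with_B) lg$components[["sa_B"]] else NA_real_,
      mse_ratio = lg$components[["mse_ratio"]],
      ratio_pred = fw$ratio, ratio_true = s$target$ratio
    )
  })
}
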