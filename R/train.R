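# Training protocol: shuffled minibatch Adam on the binary cross-entropy
# loss, per-epoch validation ROC-AUC, and selection of the best-validation
# epoch's weights.

#' Training configuration
#'
#' Defaults follow the full-scale training protocol: Adam with learning rate 1e-5,
#' batch size 64, up to 30 epochs, model selection by validation ROC-AUC.
#' [desk_train_config()] raises the learning rate to 1e-3 for the small desk
#' profile.
#'
#' @param lr Learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum epochs.
#' @param seed Integer seed governing shuffling (and dropout, if enabled).
#' @param beta1,beta2,eps Adam moment parameters.
#' @param stop_at_train_loss Optional early stop: end training once the mean
#'   epoch training loss falls below this value (NULL to disable).
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-5, batch_size = 64, max_epochs = 30, seed = 1L,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         stop_at_train_loss = NULL) {
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 stop_at_train_loss = stop_at_train_loss),
            class = "train_config")
}

#' @rdname train_config
#' @param ... Overrides passed to [train_config()].
#' @export
desk_train_config <- function(...) {
  args <- list(lr = 1e-3, batch_size = 32, max_epochs = 10)
  override <- list(...)
  args[names(override)] <- override
  do.call(train_config, args)
}

# Mean loss and gradient over one minibatch of indexed pairs.
batch_loss_grad <- function(model, d_idx_list, p_idx_list, y, train = TRUE) {
  n <- length(y)
  acc <- NULL
  loss <- 0
  eps <- 1e-7
  for (i in seq_len(n)) {
    fw <- pair_forward(model, d_idx_list[[i]], p_idx_list[[i]], train = train)
    p <- min(max(fw$p, eps), 1 - eps)
    loss <- loss - (y[i] * log(p) + (1 - y[i]) * log(1 - p))
    g <- pair_backward(model, fw$cache, (fw$p - y[i]) / n)
    acc <- if (is.null(acc)) g else params_axpy(acc, g)
  }
  list(loss = loss / n, grads = acc)
}

#' Train a model with validation-based selection
#'
#' Runs shuffled minibatch Adam on the binary cross-entropy loss; after each
#' epoch the validation ROC-AUC is computed and the weights of the best
#' validation epoch are retained in the returned model.
#'
#' @param model A `dti_model`.
#' @param split A `dti_split` with non-empty train/validation/test parts (the
#'   test part is not touched).
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return List with `model` (best-epoch weights) and `history`, a data.frame
#'   of per-epoch `train_loss` and `val_roc_auc`.
#' @export
train_model <- function(model, split, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "dti_model"), inherits(cfg, "train_config"))
  tr <- split$train
  va <- split$validation
  if (nrow(tr) == 0 || nrow(va) == 0) stop("train and validation splits must be non-empty")
  cache <- build_index_cache(model, rbind(tr[, c("drug_smiles", "protein_sequence")],
                                          va[, c("drug_smiles", "protein_sequence")]))
  d_idx <- lapply(tr$drug_smiles, function(s) cache$drug[[s]])
  p_idx <- lapply(tr$protein_sequence, function(s) cache$protein[[s]])
  y <- tr$label
  state <- adam_init(model$params)
  best <- list(val = -Inf, params = model$params, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_roc_auc = numeric(0))
  n <- nrow(tr)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      perm <- sample.int(n)
      starts <- seq(1, n, by = cfg$batch_size)
      ep_loss <- 0
      for (s in starts) {
        b <- perm[s:min(s + cfg$batch_size - 1, n)]
        bg <- batch_loss_grad(model, d_idx[b], p_idx[b], y[b])
        if (!is.finite(bg$loss)) {
          stop(sprintf("non-finite training loss at epoch %d (loss=%g); aborting",
                       epoch, bg$loss))
        }
        st <- adam_step(model$params, bg$grads, state, cfg$lr,
                        cfg$beta1, cfg$beta2, cfg$eps)
        model$params <- st$params
        state <- st$state
        ep_loss <- ep_loss + bg$loss * length(b)
      }
      ep_loss <- ep_loss / n
      val_scores <- predict_pairs(model, va, index_cache = cache)
      val_auc <- roc_auc(val_scores, va$label)
      history <- rbind(history, data.frame(epoch = epoch, train_loss = ep_loss,
                                           val_roc_auc = val_auc))
      if (verbose) {
        message(sprintf("epoch %d: train loss %.4f, val ROC-AUC %.4f",
                        epoch, ep_loss, val_auc))
      }
      if (val_auc > best$val) {
        best <- list(val = val_auc, params = model$params, epoch = epoch)
      }
      if (!is.null(cfg$stop_at_train_loss) && ep_loss < cfg$stop_at_train_loss) break
    }
  })
  model$params <- best$params
  list(model = model, history = history, best_epoch = best$epoch)
}

#' Evaluate a trained model on held-out pairs
#'
#' The decision threshold is always derived from the validation pairs (best
#' F1), never from the test pairs.
#'
#' @param model A trained `dti_model`.
#' @param test_pairs,val_pairs Pairs data.frames.
#' @return An `eval_report` (see [evaluate_scores()]).
#' @export
evaluate_model <- function(model, test_pairs, val_pairs) {
  if (nrow(test_pairs) == 0) stop("empty test set")
  cache <- build_index_cache(model, rbind(
    test_pairs[, c("drug_smiles", "protein_sequence")],
    val_pairs[, c("drug_smiles", "protein_sequence")]))
  thr <- select_threshold(predict_pairs(model, val_pairs, cache), val_pairs$label)
  evaluate_scores(predict_pairs(model, test_pairs, cache), test_pairs$label, thr)
}
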