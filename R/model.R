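# Full model assembly: two FCS tokenizers + two transformer encoders feeding
# the interaction head, with the ablation variants expressed as model
# configurations.

#' Model configuration
#'
#' Defaults reproduce the full-scale architecture (embedding 384, 2 encoder
#' layers, 12 heads, feed-forward 1536, dropout 0.1, drug/protein maximum
#' lengths 50/545, three 3x3 CNN filters).  [desk_model_config()] provides a
#' small profile for laptop-scale experiments and the test-suite fixtures.
#'
#' @param embed_dim,n_layers,n_heads,ffn_dim,dropout Encoder hyperparameters
#'   (shared by the drug and protein encoders, which keep separate weights).
#' @param max_len_drug,max_len_protein Maximum sub-structure sequence lengths.
#' @param cnn_filters,kernel_size Interaction-head CNN shape.
#' @param interaction_fn Pairwise interaction function (see
#'   [interaction_map()]).
#' @param variant One of `"full"`, `"no_cnn"`, `"no_augembed"`,
#'   `"no_interaction"` selecting the ablation structure: `no_cnn` flattens
#'   the interaction map straight into the decoder; `no_augembed` drops the
#'   transformer stack (raw content+positional embeddings feed the map);
#'   `no_interaction` additionally drops the map and decodes the concatenated
#'   masked-mean drug/protein embeddings.
#' @return A `dti_model_config` list.
#' @export
dti_model_config <- function(embed_dim = 384, n_layers = 2, n_heads = 12,
                             ffn_dim = 1536, dropout = 0.1,
                             max_len_drug = 50, max_len_protein = 545,
                             cnn_filters = 3, kernel_size = 3,
                             interaction_fn = c("dot", "sum", "average"),
                             variant = c("full", "no_cnn", "no_augembed",
                                         "no_interaction")) {
  structure(list(embed_dim = as.integer(embed_dim),
                 n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 ffn_dim = as.integer(ffn_dim),
                 dropout = dropout,
                 max_len_drug = as.integer(max_len_drug),
                 max_len_protein = as.integer(max_len_protein),
                 cnn_filters = as.integer(cnn_filters),
                 kernel_size = as.integer(kernel_size),
                 interaction_fn = match.arg(interaction_fn),
                 variant = match.arg(variant)),
            class = "dti_model_config")
}

#' Desk-scale model configuration
#'
#' A deliberately small profile (embedding 16, 1 layer, 4 heads, feed-forward
#' 32, no dropout, maximum lengths 24/48) that trains in seconds on a single
#' CPU while keeping every architectural element of the full model.
#'
#' @param ... Overrides passed to [dti_model_config()].
#' @export
desk_model_config <- function(...) {
  args <- list(embed_dim = 16, n_layers = 1, n_heads = 4, ffn_dim = 32,
               dropout = 0, max_len_drug = 24, max_len_protein = 48)
  override <- list(...)
  args[names(override)] <- override
  do.call(dti_model_config, args)
}

uses_transformer <- function(cfg) {
  cfg$variant %in% c("full", "no_cnn") && cfg$n_layers > 0
}

decoder_input_length <- function(cfg) {
  k <- cfg$kernel_size
  switch(cfg$variant,
         full = ,
         no_augembed = cfg$cnn_filters * (cfg$max_len_drug - k + 1) *
           (cfg$max_len_protein - k + 1),
         no_cnn = cfg$max_len_drug * cfg$max_len_protein,
         no_interaction = 2L * cfg$embed_dim)
}

#' Build a drug-target interaction model
#'
#' Initializes separate drug and protein encoders (content and positional
#' embedding tables plus transformer stacks), the interaction-head CNN and the
#' sigmoid decoder.  Embedding tables use truncated-normal init (sd 0.02); all
#' randomness is governed by `seed`.
#'
#' @param drug_merges,protein_merges `fcs_merges` objects defining the two
#'   sub-structure vocabularies.
#' @param config A [dti_model_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `dti_model` list carrying config, vocabularies, merge tables and
#'   parameters.
#' @export
dti_model <- function(drug_merges, protein_merges, config = dti_model_config(),
                      seed = 1L) {
  stopifnot(inherits(drug_merges, "fcs_merges"),
            inherits(protein_merges, "fcs_merges"))
  dv <- merges_vocabulary(drug_merges)
  pv <- merges_vocabulary(protein_merges)
  d_cfg <- encoder_config(length(dv$tokens), config$max_len_drug,
                          config$embed_dim,
                          if (uses_transformer(config)) config$n_layers else 0L,
                          config$n_heads, config$ffn_dim, config$dropout)
  p_cfg <- encoder_config(length(pv$tokens), config$max_len_protein,
                          config$embed_dim,
                          if (uses_transformer(config)) config$n_layers else 0L,
                          config$n_heads, config$ffn_dim, config$dropout)
  params <- with_seed(seed, {
    p <- list(drug = encoder_init(d_cfg), protein = encoder_init(p_cfg))
    if (config$variant %in% c("full", "no_augembed")) {
      k <- config$kernel_size
      p$cnn <- list(K = array(trunc_normal(k * k * config$cnn_filters, sd = 0.1),
                              c(k, k, config$cnn_filters)),
                    b = numeric(config$cnn_filters))
    }
    nd <- decoder_input_length(config)
    p$dec <- list(w = trunc_normal(nd, sd = 0.02), b = 0)
    p
  })
  structure(list(config = config,
                 drug_merges = drug_merges, protein_merges = protein_merges,
                 drug_vocab = dv, protein_vocab = pv,
                 drug_encoder_config = d_cfg, protein_encoder_config = p_cfg,
                 params = params, seed = as.integer(seed)),
            class = "dti_model")
}

#' @export
print.dti_model <- function(x, ...) {
  cat(sprintf(paste0("DTI interaction-map model (variant %s): dim %d, ",
                     "%d layer(s), %d heads; drug vocab %d, protein vocab %d\n"),
              x$config$variant, x$config$embed_dim, x$config$n_layers,
              x$config$n_heads, length(x$drug_vocab$tokens),
              length(x$protein_vocab$tokens)))
  invisible(x)
}

# Tokenize + index one pair against the model's vocabularies.
model_index_pair <- function(model, smiles, protein_seq) {
  list(drug = index_sequence(tokenize_sequence(smiles, model$drug_merges),
                             model$drug_vocab, model$config$max_len_drug),
       protein = index_sequence(tokenize_sequence(protein_seq, model$protein_merges),
                                model$protein_vocab, model$config$max_len_protein))
}

# Forward pass for one indexed pair.  Returns the probability plus every
# cache needed by pair_backward.
pair_forward <- function(model, d_idx, p_idx, train = FALSE) {
  cfg <- model$config
  pr <- model$params
  Ed0 <- embed_sequence(d_idx, pr$drug)
  Ep0 <- embed_sequence(p_idx, pr$protein)
  if (uses_transformer(cfg)) {
    fd <- encoder_stack_forward(Ed0, d_idx$mask, pr$drug$layers, cfg$n_heads,
                                dropout = cfg$dropout, train = train)
    fp <- encoder_stack_forward(Ep0, p_idx$mask, pr$protein$layers, cfg$n_heads,
                                dropout = cfg$dropout, train = train)
    Ed <- fd$out; Ep <- fp$out
  } else {
    fd <- fp <- NULL
    Ed <- Ed0; Ep <- Ep0
  }
  cache <- list(d_idx = d_idx, p_idx = p_idx, Ed0 = Ed0, Ep0 = Ep0,
                fd = fd, fp = fp, Ed = Ed, Ep = Ep)
  if (cfg$variant == "no_interaction") {
    md <- d_idx$mask > 0
    mp <- p_idx$mask > 0
    pooled <- c(colMeans(Ed[md, , drop = FALSE]), colMeans(Ep[mp, , drop = FALSE]))
    cache$pooled <- pooled
    feat <- pooled
  } else {
    I <- interaction_map(Ed, Ep, cfg$interaction_fn)
    cache$I <- I
    if (cfg$variant == "no_cnn") {
      feat <- as.numeric(I)
    } else {
      cv <- conv_relu_forward(I, pr$cnn$K, pr$cnn$b)
      cache$conv <- cv
      feat <- as.numeric(cv$out)
    }
  }
  cache$feat <- feat
  logit <- sum(pr$dec$w * feat) + pr$dec$b
  list(p = stats::plogis(logit), logit = logit, cache = cache)
}

# Backward pass from d(loss)/d(logit) for one pair; returns gradients in the
# same nested structure as model$params.
pair_backward <- function(model, cache, dlogit) {
  cfg <- model$config
  pr <- model$params
  g <- list()
  g$dec <- list(w = cache$feat * dlogit, b = dlogit)
  dfeat <- pr$dec$w * dlogit
  if (cfg$variant == "no_interaction") {
    d <- cfg$embed_dim
    md <- cache$d_idx$mask > 0
    mp <- cache$p_idx$mask > 0
    dEd <- matrix(0, cfg$max_len_drug, d)
    dEp <- matrix(0, cfg$max_len_protein, d)
    dEd[md, ] <- matrix(dfeat[1:d] / sum(md), sum(md), d, byrow = TRUE)
    dEp[mp, ] <- matrix(dfeat[(d + 1):(2 * d)] / sum(mp), sum(mp), d, byrow = TRUE)
  } else {
    if (cfg$variant == "no_cnn") {
      dI <- matrix(dfeat, cfg$max_len_drug, cfg$max_len_protein)
    } else {
      dO <- array(dfeat, dim(cache$conv$out))
      cb <- conv_relu_backward(dO, cache$I, pr$cnn$K, cache$conv$pre)
      dI <- cb$dI
      g$cnn <- list(K = cb$dK, b = cb$db)
    }
    if (cfg$interaction_fn == "dot") {
      dEd <- dI %*% cache$Ep
      dEp <- t(dI) %*% cache$Ed
    } else {
      scale <- if (cfg$interaction_fn == "average") 1 / cfg$embed_dim else 1
      dEd <- matrix(rowSums(dI) * scale, nrow(cache$Ed), ncol(cache$Ed))
      dEp <- matrix(colSums(dI) * scale, nrow(cache$Ep), ncol(cache$Ep))
    }
  }
  if (uses_transformer(cfg)) {
    bd <- encoder_stack_backward(dEd, pr$drug$layers, cache$fd$caches)
    bp <- encoder_stack_backward(dEp, pr$protein$layers, cache$fp$caches)
    dEd0 <- bd$dx; dEp0 <- bp$dx
    d_layer_grads <- bd$grads
    p_layer_grads <- bp$grads
  } else {
    dEd0 <- dEd; dEp0 <- dEp
    d_layer_grads <- lapply(pr$drug$layers, params_zeros_like)
    p_layer_grads <- lapply(pr$protein$layers, params_zeros_like)
  }
  ed <- embedding_backward(dEd0, cache$d_idx, nrow(pr$drug$Wcont))
  ep <- embedding_backward(dEp0, cache$p_idx, nrow(pr$protein$Wcont))
  g$drug <- list(Wcont = ed$dWcont, Wpos = ed$dWpos, layers = d_layer_grads)
  g$protein <- list(Wcont = ep$dWcont, Wpos = ep$dWpos, layers = p_layer_grads)
  # order to mirror model$params
  out <- list(drug = g$drug, protein = g$protein)
  if (!is.null(pr$cnn)) {
    out$cnn <- if (is.null(g$cnn)) params_zeros_like(pr$cnn) else g$cnn
  }
  out$dec <- g$dec
  out
}

#' Predict interaction probabilities for labeled pairs
#'
#' @param model A `dti_model`.
#' @param pairs Pairs data.frame with `drug_smiles` and `protein_sequence`.
#' @param index_cache Optional environment used to memoize tokenized/indexed
#'   sequences across calls.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_pairs <- function(model, pairs, index_cache = NULL) {
  idx <- build_index_cache(model, pairs, index_cache)
  vapply(seq_len(nrow(pairs)), function(i) {
    pair_forward(model,
                 idx$drug[[pairs$drug_smiles[i]]],
                 idx$protein[[pairs$protein_sequence[i]]])$p
  }, numeric(1))
}

# Tokenize/index each unique sequence once; returns (and fills) a cache of
# two named lists keyed by raw sequence string.
build_index_cache <- function(model, pairs, cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  if (is.null(cache$drug)) cache$drug <- list()
  if (is.null(cache$protein)) cache$protein <- list()
  for (s in unique(pairs$drug_smiles)) {
    if (is.null(cache$drug[[s]])) {
      cache$drug[[s]] <- index_sequence(tokenize_sequence(s, model$drug_merges),
                                        model$drug_vocab, model$config$max_len_drug)
    }
  }
  for (s in unique(pairs$protein_sequence)) {
    if (is.null(cache$protein[[s]])) {
      cache$protein[[s]] <- index_sequence(
        tokenize_sequence(s, model$protein_merges),
        model$protein_vocab, model$config$max_len_protein)
    }
  }
  cache
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles the merge tables, configuration and all weights so a
#' reloaded model tokenizes and scores identically.
#'
#' @param model A `dti_model`.
#' @param path Checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "dti_model"))
  m
}
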