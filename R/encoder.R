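# Augmented transformer embedding: a sub-structure sequence is mapped to
# indices, embedded as content + positional lookups, and contextualized by a
# stack of post-norm transformer encoder layers with PAD keys masked out of
# self-attention.

#' Encoder configuration
#'
#' Defaults are the full-scale architecture: embedding width 384, 2 layers,
#' 12 heads, feed-forward width 1536, dropout 0.1.  Maximum sub-structure
#' sequence lengths default to 50 for drugs and 545 for proteins (set via
#' `max_len`).
#'
#' @param vocab_size Vocabulary cardinality (PAD and UNK included).
#' @param max_len Maximum sub-structure sequence length.
#' @param embed_dim Latent embedding size per sub-structure.
#' @param n_layers Number of transformer encoder layers.
#' @param n_heads Attention heads (must divide `embed_dim`).
#' @param ffn_dim Feed-forward intermediate width.
#' @param dropout Dropout rate applied inside encoder layers during training.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(vocab_size, max_len, embed_dim = 384, n_layers = 2,
                           n_heads = 12, ffn_dim = 1536, dropout = 0.1) {
  stopifnot(max_len >= 1, vocab_size >= 2, n_layers >= 0)
  if (embed_dim %% n_heads != 0) stop("embed_dim must be divisible by n_heads")
  structure(list(vocab_size = as.integer(vocab_size),
                 max_len = as.integer(max_len),
                 embed_dim = as.integer(embed_dim),
                 n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 ffn_dim = as.integer(ffn_dim),
                 dropout = dropout),
            class = "encoder_config")
}

#' Map a token sequence to padded vocabulary indices
#'
#' The first `max_len` tokens are mapped to 0-based vocabulary indices
#' (PAD = 0, UNK = 1, unknown tokens become UNK); shorter sequences are padded
#' with PAD and a binary mask marks real positions.  Truncation keeps the
#' head of the sequence.
#'
#' @param tokens Character vector of sub-structure tokens.
#' @param vocab An `fcs_vocabulary`.
#' @param max_len Target length.
#' @return List with `indices` (0-based, length `max_len`), `mask` and
#'   `true_length`.
#' @export
index_sequence <- function(tokens, vocab, max_len) {
  if (length(tokens) == 0) stop("cannot index an empty token sequence")
  n <- min(length(tokens), max_len)
  toks <- tokens[seq_len(n)]
  idx <- unname(vocab$index[toks])
  idx[is.na(idx)] <- vocab$index[[UNK_TOKEN]]
  indices <- c(idx, rep(vocab$index[[PAD_TOKEN]], max_len - n))
  list(indices = as.integer(indices),
       mask = c(rep(1L, n), rep(0L, max_len - n)),
       true_length = as.integer(n))
}

# Parameter initialization for one encoder (embedding tables + layer stack).
encoder_init <- function(cfg) {
  list(Wcont = mat_init(cfg$vocab_size, cfg$embed_dim),
       Wpos = mat_init(cfg$max_len, cfg$embed_dim),
       layers = lapply(seq_len(cfg$n_layers), function(i) {
         encoder_layer_init(cfg$embed_dim, cfg$ffn_dim)
       }))
}

#' Content + positional embedding lookup
#'
#' Row i of the result is the content embedding of the token at position i
#' plus the positional embedding of position i, for every position including
#' PAD.
#'
#' @param idx An indexed sequence from [index_sequence()].
#' @param tables List with `Wcont` (vocab_size x dim) and `Wpos`
#'   (max_len x dim).
#' @return A max_len x dim numeric matrix.
#' @export
embed_sequence <- function(idx, tables) {
  if (any(idx$indices >= nrow(tables$Wcont))) stop("token index out of range")
  tables$Wcont[idx$indices + 1L, , drop = FALSE] +
    tables$Wpos[seq_along(idx$indices), , drop = FALSE]
}

# Forward through the layer stack; returns output and per-layer caches.
encoder_stack_forward <- function(E, mask, layers, n_heads, dropout = 0,
                                  train = FALSE) {
  if (any(!is.finite(E))) stop("non-finite values in embedding input")
  key_mask <- mask > 0
  x <- E
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- encoder_layer_forward(x, layers[[i]], n_heads, key_mask,
                               dropout = dropout, train = train)
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

encoder_stack_backward <- function(dout, layers, caches) {
  grads <- vector("list", length(layers))
  dx <- dout
  for (i in rev(seq_along(layers))) {
    b <- encoder_layer_backward(dx, layers[[i]], caches[[i]])
    dx <- b$dx
    grads[[i]] <- b$grads
  }
  list(dx = dx, grads = grads)
}

#' Contextualize an embedding matrix with a transformer encoder stack
#'
#' PAD positions are excluded from attention keys, so perturbing a PAD
#' position's embedding cannot change the output at real positions.  A
#' zero-layer configuration returns the input unchanged.
#'
#' @param E max_len x dim embedding matrix from [embed_sequence()].
#' @param mask Binary vector (1 = real token, 0 = PAD).
#' @param encoder Encoder parameters (from an initialized model), i.e. a list
#'   with a `layers` component.
#' @param n_heads Attention heads.
#' @param dropout,train Dropout rate and training flag.
#' @return max_len x dim matrix of contextual embeddings.
#' @export
contextualize <- function(E, mask, encoder, n_heads, dropout = 0, train = FALSE) {
  encoder_stack_forward(E, mask, encoder$layers, n_heads,
                        dropout = dropout, train = train)$out
}

# Accumulate dE rows into the content table by token index; positional table
# gradient is dE itself.
embedding_backward <- function(dE, idx, vocab_size) {
  dWcont <- matrix(0, vocab_size, ncol(dE))
  rs <- rowsum(dE, group = idx$indices)
  dWcont[as.integer(rownames(rs)) + 1L, ] <- rs
  list(dWcont = dWcont, dWpos = dE)
}
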