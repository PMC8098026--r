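# Independent brute-force oracles.  These deliberately share no code with the
# package implementation: naive loops, recounting from scratch, so that
# agreement is evidence of correctness rather than of shared bugs.

# Count greedy left-to-right non-overlapping occurrences of (a, b) in one
# token vector by explicit scanning.
oracle_pair_count_one <- function(toks, a, b) {
  i <- 1L
  n <- length(toks)
  cnt <- 0L
  while (i < n) {
    if (toks[i] == a && toks[i + 1] == b) {
      cnt <- cnt + 1L
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  cnt
}

# All adjacent-pair counts for a tokenized corpus, via per-pair rescanning.
oracle_count_pairs <- function(tokenized) {
  seen <- character(0)
  for (toks in tokenized) {
    n <- length(toks)
    if (n >= 2) seen <- union(seen, paste(toks[-n], toks[-1], sep = "\x1f"))
  }
  counts <- integer(length(seen))
  names(counts) <- seen
  for (k in seen) {
    ab <- strsplit(k, "\x1f", fixed = TRUE)[[1]]
    for (toks in tokenized) {
      counts[k] <- counts[k] + oracle_pair_count_one(toks, ab[1], ab[2])
    }
  }
  counts
}

# Rewrite one token vector, merging greedy left-to-right occurrences of (a, b).
oracle_apply_merge_one <- function(toks, a, b) {
  out <- character(0)
  i <- 1L
  n <- length(toks)
  while (i <= n) {
    if (i < n && toks[i] == a && toks[i + 1] == b) {
      out <- c(out, paste0(a, b))
      i <- i + 2L
    } else {
      out <- c(out, toks[i])
      i <- i + 1L
    }
  }
  out
}

# Reference miner: recounts from scratch every round; same stopping and
# tie-break contract (most frequent pair; ties to the lexicographically
# smallest concatenated token under C collation).
oracle_mine_fcs <- function(corpus, theta, max_vocab = Inf) {
  tokenized <- strsplit(corpus[nzchar(corpus)], "", fixed = TRUE)
  alphabet <- sort(unique(unlist(tokenized)), method = "radix")
  merges <- list()
  vocab <- alphabet
  repeat {
    if (is.finite(max_vocab) && length(vocab) + 2L >= max_vocab) break
    counts <- oracle_count_pairs(tokenized)
    if (length(counts) == 0 || max(counts) < theta) break
    best <- max(counts)
    cand <- names(counts)[counts == best]
    concat <- vapply(cand, function(k) {
      paste(strsplit(k, "\x1f", fixed = TRUE)[[1]], collapse = "")
    }, character(1))
    key <- cand[order(concat, method = "radix")[1]]
    ab <- strsplit(key, "\x1f", fixed = TRUE)[[1]]
    tokenized <- lapply(tokenized, oracle_apply_merge_one, a = ab[1], b = ab[2])
    merges[[length(merges) + 1L]] <- c(ab, best)
    vocab <- c(vocab, paste0(ab[1], ab[2]))
  }
  list(merges = merges, vocab = vocab)
}

# Interaction map by explicit double loop.
oracle_interaction_map <- function(Ed, Ep) {
  I <- matrix(0, nrow(Ed), nrow(Ep))
  for (j in seq_len(nrow(Ed))) {
    for (i in seq_len(nrow(Ep))) {
      s <- 0
      for (t in seq_len(ncol(Ed))) s <- s + Ed[j, t] * Ep[i, t]
      I[j, i] <- s
    }
  }
  I
}

# Valid 2-D convolution + ReLU by direct summation.
oracle_conv_relu <- function(I, K, bias) {
  k <- dim(K)[1]
  nf <- dim(K)[3]
  Ho <- nrow(I) - k + 1
  Wo <- ncol(I) - k + 1
  out <- array(0, c(Ho, Wo, nf))
  for (f in seq_len(nf)) {
    for (x in seq_len(Ho)) {
      for (y in seq_len(Wo)) {
        s <- bias[f]
        for (u in seq_len(k)) {
          for (v in seq_len(k)) {
            s <- s + K[u, v, f] * I[x + u - 1, y + v - 1]
          }
        }
        out[x, y, f] <- max(s, 0)
      }
    }
  }
  out
}

# ROC-AUC by comparing every positive-negative score pair.
oracle_roc_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) {
    for (b in sn) {
      tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  tot / (length(sp) * length(sn))
}

# Random test corpus within the property-test envelope.
random_corpus <- function(n_alpha, n_seq, max_len) {
  alpha <- LETTERS[seq_len(n_alpha)]
  vapply(seq_len(n_seq), function(i) {
    paste(sample(alpha, sample(2:max_len, 1), replace = TRUE), collapse = "")
  }, character(1))
}

# Compare mined merge tables (left, right, frequency rows in order).
expect_same_mining <- function(got, oracle) {
  om <- if (length(oracle$merges)) {
    do.call(rbind, lapply(oracle$merges, function(m) {
      data.frame(left = m[1], right = m[2], frequency = as.numeric(m[3]),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(left = character(0), right = character(0), frequency = numeric(0))
  }
  expect_equal(got$merges$merges, om, ignore_attr = TRUE)
  expect_equal(setdiff(got$vocab$tokens, c("<PAD>", "<UNK>")), oracle$vocab)
}
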