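# Frequent consecutive sub-sequence (FCS) mining.
#
# A byte-pair-style procedure over molecular strings: starting from single
# characters, the corpus is repeatedly scanned for the most frequent adjacent
# token pair, which is merged into a new vocabulary token, until the best
# pair's frequency drops below a threshold theta or the vocabulary reaches a
# maximum size.  Drugs (SMILES) and proteins (amino-acid strings) each get
# their own miner and vocabulary.

PAD_TOKEN <- "<PAD>"
UNK_TOKEN <- "<UNK>"

#' Build the initial character vocabulary and tokenize a corpus
#'
#' The vocabulary reserves index 0 for PAD and index 1 for UNK; the remaining
#' entries are the distinct single characters observed in the corpus (sorted
#' for determinism).  Each sequence is split into its character list.  Empty
#' sequences are dropped with a warning.
#'
#' @param corpus Character vector of sequences (SMILES or amino-acid strings).
#' @return A list with `vocab` (a `fcs_vocabulary`) and `tokenized`, a list of
#'   character vectors.
#' @export
initialize_vocabulary <- function(corpus) {
  if (length(corpus) == 0) stop("corpus is empty")
  empty <- !nzchar(corpus)
  if (any(empty)) {
    warning(sprintf("dropping %d empty sequence(s) from corpus", sum(empty)))
    corpus <- corpus[!empty]
    if (length(corpus) == 0) stop("corpus is empty after dropping empty sequences")
  }
  tokenized <- strsplit(corpus, "", fixed = TRUE)
  alphabet <- sort_cstr(unique(unlist(tokenized, use.names = FALSE)))
  vocab <- new_vocabulary(alphabet)
  list(vocab = vocab, tokenized = tokenized)
}

new_vocabulary <- function(alphabet, merged = character(0)) {
  tokens <- c(PAD_TOKEN, UNK_TOKEN, alphabet, merged)
  index <- seq_along(tokens) - 1L  # 0-based: PAD 0, UNK 1
  names(index) <- tokens
  structure(list(tokens = tokens, index = index, alphabet = alphabet),
            class = "fcs_vocabulary")
}

#' @export
print.fcs_vocabulary <- function(x, ...) {
  cat(sprintf("FCS vocabulary: %d tokens (%d alphabet, %d merged, 2 reserved)\n",
              length(x$tokens), length(x$alphabet),
              length(x$tokens) - length(x$alphabet) - 2L))
  invisible(x)
}

#' Count adjacent token pairs in a tokenized corpus
#'
#' Counting is greedy, left-to-right and non-overlapping within each sequence,
#' matching exactly the number of replacements a merge of that pair would
#' perform: in `A A A` the pair (A, A) occurs once, not twice.
#'
#' @param tokenized List of character vectors (token sequences).
#' @return Named integer vector; names are `left\x1fright` keys, see
#'   [pair_key()].
#' @export
count_adjacent_pairs <- function(tokenized) {
  counts <- integer(0)
  acc <- new.env(parent = emptyenv())
  for (toks in tokenized) {
    n <- length(toks)
    if (n < 2) next
    keys <- paste(toks[-n], toks[-1], sep = "\x1f")
    r <- rle(keys)
    # within a run of identical adjacent-pair keys (only possible for (A,A)
    # inside a character run), greedy non-overlap realizes ceiling(len/2)
    eff <- (r$lengths + 1L) %/% 2L
    for (i in seq_along(r$values)) {
      k <- r$values[i]
      prev <- acc[[k]]
      acc[[k]] <- if (is.null(prev)) eff[i] else prev + eff[i]
    }
  }
  keys <- ls(acc, sorted = FALSE)
  if (length(keys) == 0) return(integer(0))
  counts <- vapply(keys, function(k) acc[[k]], integer(1))
  names(counts) <- keys
  counts
}

pair_key <- function(left, right) paste(left, right, sep = "\x1f")

split_pair_key <- function(key) strsplit(key, "\x1f", fixed = TRUE)[[1]]

# Replace greedy left-to-right non-overlapping occurrences of the adjacent
# pair (left, right) by their concatenation, in one token sequence.
merge_tokens <- function(toks, left, right) {
  n <- length(toks)
  if (n < 2) return(toks)
  hit <- toks[-n] == left & toks[-1] == right
  if (!any(hit)) return(toks)
  pos <- which(hit)
  # drop overlapping hits: a hit at i+1 shares the middle token with one at i
  keep <- integer(0)
  last <- -2L
  for (p in pos) {
    if (p > last + 1L) {
      keep <- c(keep, p)
      last <- p
    }
  }
  out <- character(0)
  i <- 1L
  ki <- 1L
  nk <- length(keep)
  while (i <= n) {
    if (ki <= nk && i == keep[ki]) {
      out <- c(out, paste0(left, right))
      i <- i + 2L
      ki <- ki + 1L
    } else {
      out <- c(out, toks[i])
      i <- i + 1L
    }
  }
  out
}

#' Apply one merge across a tokenized corpus
#'
#' @param tokenized List of token sequences.
#' @param pair Character vector of length 2: the (left, right) tokens to merge.
#' @return The rewritten tokenized corpus; string content of every sequence is
#'   unchanged.
#' @export
apply_merge <- function(tokenized, pair) {
  stopifnot(length(pair) == 2)
  lapply(tokenized, merge_tokens, left = pair[1], right = pair[2])
}

#' Mine frequent consecutive sub-sequences from a corpus
#'
#' Iterates scan / identify / update: count adjacent pairs, merge the most
#' frequent one (ties broken by the lexicographically smallest concatenated
#' token), append it to the vocabulary, and repeat until the best pair's
#' frequency falls below `theta` or the vocabulary reaches `max_vocab`
#' entries (reserved tokens included).
#'
#' @param corpus Character vector of sequences.
#' @param theta Minimum pair frequency to keep merging (>= 1).
#' @param max_vocab Maximum vocabulary size including the two reserved tokens;
#'   `Inf` (default) for theta-driven stopping only.
#' @return A list with `vocab` (`fcs_vocabulary`) and `merges` (`fcs_merges`):
#'   ordered merge table with the realized frequency of each merge.
#' @export
mine_fcs <- function(corpus, theta, max_vocab = Inf) {
  stopifnot(theta >= 1)
  init <- initialize_vocabulary(corpus)
  W <- init$tokenized
  alphabet <- init$vocab$alphabet
  if (is.finite(max_vocab) && max_vocab <= length(alphabet) + 2L) {
    stop("max_vocab must exceed the alphabet size plus the 2 reserved tokens")
  }
  merged <- character(0)
  merges <- list()
  repeat {
    if (is.finite(max_vocab) && length(alphabet) + length(merged) + 2L >= max_vocab) break
    counts <- count_adjacent_pairs(W)
    if (length(counts) == 0) break
    best_n <- max(counts)
    if (best_n < theta) break
    cand <- names(counts)[counts == best_n]
    concat <- vapply(cand, function(k) paste(split_pair_key(k), collapse = ""),
                     character(1))
    key <- cand[order(concat, method = "radix")[1]]
    pair <- split_pair_key(key)
    W <- apply_merge(W, pair)
    merged <- c(merged, paste0(pair[1], pair[2]))
    merges[[length(merges) + 1L]] <-
      list(left = pair[1], right = pair[2], frequency = best_n)
  }
  merge_df <- if (length(merges)) {
    data.frame(left = vapply(merges, `[[`, character(1), "left"),
               right = vapply(merges, `[[`, character(1), "right"),
               frequency = vapply(merges, `[[`, numeric(1), "frequency"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(left = character(0), right = character(0), frequency = numeric(0))
  }
  merges_obj <- structure(
    list(merges = merge_df, theta = theta, max_vocab = max_vocab,
         alphabet = alphabet),
    class = "fcs_merges")
  list(vocab = new_vocabulary(alphabet, merged), merges = merges_obj)
}

#' @export
print.fcs_merges <- function(x, ...) {
  cat(sprintf("FCS merge table: %d merges (theta = %g, max_vocab = %s)\n",
              nrow(x$merges), x$theta,
              if (is.finite(x$max_vocab)) format(x$max_vocab) else "unbounded"))
  invisible(x)
}

#' Tokenize a sequence into mined sub-structures
#'
#' Splits the input into characters, maps characters unseen at mining time to
#' the UNK token, then replays the learned merges in order, each applied
#' greedily left-to-right.  For inputs containing no unseen characters,
#' concatenating the returned tokens reconstructs the input exactly.
#'
#' @param sequence A single non-empty string.
#' @param merges An `fcs_merges` object from [mine_fcs()] or
#'   [read_merge_table()].
#' @return Character vector of sub-structure tokens (possibly `"<UNK>"`).
#' @export
tokenize_sequence <- function(sequence, merges) {
  stopifnot(inherits(merges, "fcs_merges"))
  if (length(sequence) != 1 || !nzchar(sequence)) stop("sequence must be a single non-empty string")
  toks <- strsplit(sequence, "", fixed = TRUE)[[1]]
  toks[!(toks %in% merges$alphabet)] <- UNK_TOKEN
  m <- merges$merges
  for (i in seq_len(nrow(m))) {
    toks <- merge_tokens(toks, m$left[i], m$right[i])
  }
  toks
}

#' Write a merge table to a plain-text file
#'
#' Line format: two leading comment lines recording theta / max_vocab and the
#' alphabet, then one `left<TAB>right<TAB>frequency` line per merge in learned
#' order.
#'
#' @param merges An `fcs_merges` object.
#' @param path Output file path.
#' @export
write_merge_table <- function(merges, path) {
  stopifnot(inherits(merges, "fcs_merges"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# theta=%g max_vocab=%s",
            merges$theta,
            if (is.finite(merges$max_vocab)) format(merges$max_vocab) else "Inf"),
    sprintf("# alphabet=%s", paste(merges$alphabet, collapse = ""))
  ), con)
  m <- merges$merges
  if (nrow(m)) {
    writeLines(sprintf("%s\t%s\t%g", m$left, m$right, m$frequency), con)
  }
  invisible(path)
}

#' Read a merge table written by [write_merge_table()]
#'
#' @param path File path.
#' @return An `fcs_merges` object.
#' @export
read_merge_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2 || !startsWith(lines[1], "#") || !startsWith(lines[2], "#")) {
    stop("merge table must start with two comment lines (parameters, alphabet)")
  }
  hdr <- sub("^#\\s*", "", lines[1])
  theta <- as.numeric(sub(".*theta=([0-9.eE+-]+).*", "\\1", hdr))
  mv_str <- sub(".*max_vocab=([^ ]+).*", "\\1", hdr)
  max_vocab <- if (mv_str == "Inf") Inf else as.numeric(mv_str)
  alphabet <- strsplit(sub("^#\\s*alphabet=", "", lines[2]), "", fixed = TRUE)[[1]]
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 3)
    if (length(bad)) stop(sprintf("malformed merge line %d", bad[1] + 2L))
    m <- data.frame(left = vapply(parts, `[`, character(1), 1),
                    right = vapply(parts, `[`, character(1), 2),
                    frequency = as.numeric(vapply(parts, `[`, character(1), 3)),
                    stringsAsFactors = FALSE)
  } else {
    m <- data.frame(left = character(0), right = character(0), frequency = numeric(0))
  }
  structure(list(merges = m, theta = theta, max_vocab = max_vocab,
                 alphabet = alphabet),
            class = "fcs_merges")
}

#' Vocabulary implied by a merge table
#'
#' @param merges An `fcs_merges` object.
#' @return The `fcs_vocabulary` containing PAD, UNK, the alphabet and each
#'   merged token in merge order.
#' @export
merges_vocabulary <- function(merges) {
  stopifnot(inherits(merges, "fcs_merges"))
  m <- merges$merges
  new_vocabulary(merges$alphabet,
                 if (nrow(m)) paste0(m$left, m$right) else character(0))
}
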