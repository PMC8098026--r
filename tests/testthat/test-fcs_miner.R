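test_that("vocabulary initialization splits sequences into observed characters", {
  r <- initialize_vocabulary(c("AB", "BC"))
  expect_true(all(c("A", "B", "C") %in% r$vocab$tokens))
  expect_identical(r$vocab$tokens[1:2], c("<PAD>", "<UNK>"))
  expect_identical(unname(r$vocab$index[r$vocab$tokens[1:2]]), c(0L, 1L))
  expect_identical(r$tokenized, list(c("A", "B"), c("B", "C")))

  r2 <- initialize_vocabulary("CCO")
  expect_true(all(c("C", "O") %in% r2$vocab$tokens))
  expect_identical(r2$tokenized[[1]], c("C", "C", "O"))

  expect_warning(r3 <- initialize_vocabulary(c("AB", "")), "empty")
  expect_length(r3$tokenized, 1)
  expect_error(initialize_vocabulary(character(0)), "empty")
})

test_that("adjacent pair counting is greedy, left-to-right, non-overlapping", {
  expect_identical(count_adjacent_pairs(list(c("A", "A", "A"))),
                   c("A\x1fA" = 1L))
  got <- count_adjacent_pairs(list(c("A", "B", "A", "B")))
  expect_identical(got[["A\x1fB"]], 2L)
  expect_identical(got[["B\x1fA"]], 1L)
  expect_length(count_adjacent_pairs(list("A")), 0)
  # agreement with the rescanning oracle on random corpora
  set.seed(41)
  for (i in 1:25) {
    toks <- strsplit(random_corpus(sample(2:4, 1), sample(1:8, 1), 15), "")
    got <- count_adjacent_pairs(toks)
    exp <- oracle_count_pairs(toks)
    expect_identical(got[order(names(got))], exp[order(names(exp))])
  }
})

test_that("apply_merge rewrites pairs greedily and preserves string content", {
  expect_identical(apply_merge(list(c("A", "B", "A", "B")), c("A", "B")),
                   list(c("AB", "AB")))
  expect_identical(apply_merge(list(c("A", "A", "A")), c("A", "A")),
                   list(c("AA", "A")))
  w <- list(c("X", "Y"))
  expect_identical(apply_merge(w, c("A", "B")), w)
  set.seed(42)
  for (i in 1:20) {
    toks <- strsplit(random_corpus(3, 5, 20), "")
    pair <- c(sample(LETTERS[1:3], 1), sample(LETTERS[1:3], 1))
    merged <- apply_merge(toks, pair)
    expect_identical(vapply(merged, paste, character(1), collapse = ""),
                     vapply(toks, paste, character(1), collapse = ""))
  }
})

test_that("mining reproduces the worked corpus and honors stopping rules", {
  r <- mine_fcs(c("ABAB", "ABAB", "ABC"), theta = 2)
  expect_identical(r$merges$merges$left, c("A", "AB"))
  expect_identical(r$merges$merges$right, c("B", "AB"))
  expect_setequal(setdiff(r$vocab$tokens, c("<PAD>", "<UNK>")),
                  c("A", "B", "C", "AB", "ABAB"))

  none <- mine_fcs(c("ABAB", "ABC"), theta = 100)
  expect_identical(nrow(none$merges$merges), 0L)
  expect_setequal(setdiff(none$vocab$tokens, c("<PAD>", "<UNK>")),
                  c("A", "B", "C"))

  # alphabet {A,B,C} + 2 reserved + room for exactly one merge
  one <- mine_fcs(c("ABAB", "ABAB", "ABC"), theta = 2, max_vocab = 6)
  expect_identical(nrow(one$merges$merges), 1L)
  expect_identical(one$merges$merges$left[1], "A")
})

test_that("mining agrees with the brute-force reference miner", {
  set.seed(77)
  for (i in 1:40) {
    corpus <- random_corpus(sample(2:6, 1), sample(3:20, 1), sample(5:25, 1))
    theta <- sample(2:4, 1)
    expect_same_mining(mine_fcs(corpus, theta), oracle_mine_fcs(corpus, theta))
  }
})

test_that("every recorded merge frequency is at least theta", {
  set.seed(5)
  for (i in 1:10) {
    corpus <- random_corpus(3, 12, 20)
    r <- mine_fcs(corpus, theta = 3)
    expect_true(all(r$merges$merges$frequency >= 3))
  }
})

test_that("tokenization replays merges and reconstructs the input", {
  merges <- mine_fcs(c("ABAB", "ABAB", "ABC"), theta = 2)$merges
  expect_identical(tokenize_sequence("ABABC", merges), c("ABAB", "C"))

  empty <- mine_fcs(c("XY"), theta = 100)$merges
  expect_identical(tokenize_sequence("YXY", empty), c("Y", "X", "Y"))

  toks <- tokenize_sequence("AZB", merges)
  expect_true("<UNK>" %in% toks)
  expect_error(tokenize_sequence("", merges), "non-empty")

  # reconstruction + idempotence on random in-alphabet sequences
  set.seed(13)
  corpus <- random_corpus(4, 30, 25)
  m <- mine_fcs(corpus, theta = 2)$merges
  for (s in random_corpus(4, 30, 25)) {
    toks <- tokenize_sequence(s, m)
    expect_identical(paste(toks, collapse = ""), s)
    expect_identical(tokenize_sequence(paste(toks, collapse = ""), m), toks)
  }
})

test_that("a planted high-frequency motif is recovered in the vocabulary", {
  motif <- "NCCO"
  corpus <- generate_corpus(c("C", "N", "O", "S"), 80, c(12, 18),
                            list(list(motif = motif, prob = 1)), seed = 19)
  r <- mine_fcs(corpus, theta = 10)
  expect_true(any(grepl(motif, r$vocab$tokens, fixed = TRUE)))
})

test_that("merge tables survive a write/read round trip", {
  r <- mine_fcs(c("ABAB", "ABAB", "ABC"), theta = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_merge_table(r$merges, path)
  back <- read_merge_table(path)
  expect_equal(back$merges, r$merges$merges)
  expect_identical(back$alphabet, r$merges$alphabet)
  expect_identical(back$theta, 2)
  expect_identical(tokenize_sequence("ABABC", back), c("ABAB", "C"))
})
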