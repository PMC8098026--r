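test_that("FASTA reading handles single, wrapped and empty inputs", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "MKV"), f)
  r <- read_fasta(f)
  expect_identical(r$id, "p1")
  expect_identical(r$sequence, "MKV")

  writeLines(c(">p1", "MKV", ">p2", "MK", "VAL", "KK"), f)
  r <- read_fasta(f)
  expect_identical(nrow(r), 2L)
  expect_identical(r$sequence[2], "MKVALKK")

  writeLines(character(0), f)
  expect_identical(nrow(read_fasta(f)), 0L)

  writeLines(c("MKV", ">p1", "MK"), f)
  expect_error(read_fasta(f), "line 1")
})

test_that("SMILES reading assigns ids and skips blank interior lines", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines("CCO", f)
  expect_identical(read_smiles(f), data.frame(id = "D1", smiles = "CCO",
                                              stringsAsFactors = FALSE))
  writeLines("CCO\tethanol", f)
  expect_identical(read_smiles(f)$id, "ethanol")

  writeLines(c("CCO", "", "CCN"), f)
  expect_warning(r <- read_smiles(f), "blank")
  expect_identical(r$smiles, c("CCO", "CCN"))
  expect_identical(r$id, c("D1", "D3"))  # line numbers, not row numbers
})

test_that("affinity binarization uses a strict threshold", {
  expect_identical(binarize_affinity(29.9), 1L)
  expect_identical(binarize_affinity(30.0), 0L)
  expect_identical(binarize_affinity(10000), 0L)
  expect_identical(binarize_affinity(c(0, 29.999, 30, 31)), c(1L, 1L, 0L, 0L))
  expect_error(binarize_affinity(-1), "non-negative")
  expect_error(binarize_affinity(NaN), "finite")
})

test_that("negative sampling draws only unseen pairs, deterministically", {
  drugs <- data.frame(id = c("d1", "d2"), smiles = c("CC", "CO"),
                      stringsAsFactors = FALSE)
  prots <- data.frame(id = c("p1", "p2"), sequence = c("MK", "MV"),
                      stringsAsFactors = FALSE)
  pos <- make_pairs(drugs, prots, c("d1", "d1", "d2"), c("p1", "p2", "p1"),
                    label = c(1L, 1L, 1L))
  neg <- sample_negatives(pos, drugs, prots, ratio = 1 / 3, seed = 1)
  expect_identical(nrow(neg), 1L)
  expect_identical(neg$drug_id, "d2")
  expect_identical(neg$protein_id, "p2")
  expect_identical(neg$label, 0L)
  expect_error(sample_negatives(pos, drugs, prots, ratio = 1, seed = 1),
               "short by")

  # balanced sampling at scale, determinism, and the no-positive invariant
  drugs <- data.frame(id = paste0("d", 1:20),
                      smiles = replicate(20, paste(sample(c("C", "N", "O"), 6,
                                                          TRUE), collapse = "")),
                      stringsAsFactors = FALSE)
  prots <- data.frame(id = paste0("p", 1:15),
                      sequence = replicate(15, paste(sample(LETTERS[1:5], 8,
                                                            TRUE), collapse = "")),
                      stringsAsFactors = FALSE)
  pos <- make_pairs(drugs, prots, sample(drugs$id, 40, TRUE),
                    sample(prots$id, 40, TRUE), label = rep(1L, 40))
  n1 <- sample_negatives(pos, drugs, prots, ratio = 1, seed = 9)
  n2 <- sample_negatives(pos, drugs, prots, ratio = 1, seed = 9)
  expect_identical(n1, n2)
  expect_identical(nrow(n1), nrow(pos))
  overlap <- intersect(paste(n1$drug_id, n1$protein_id),
                       paste(pos$drug_id, pos$protein_id))
  expect_length(overlap, 0)
})

test_that("dataset splitting is a seeded exact partition", {
  pairs <- data.frame(drug_id = paste0("d", 1:10), drug_smiles = "CC",
                      protein_id = paste0("p", 1:10), protein_sequence = "MK",
                      label = rep(0:1, 5), affinity = NA_real_,
                      stringsAsFactors = FALSE)
  sp <- split_dataset(pairs, seed = 4)
  expect_identical(c(nrow(sp$train), nrow(sp$validation), nrow(sp$test)),
                   c(7L, 1L, 2L))
  recon <- rbind(sp$train, sp$validation, sp$test)
  expect_setequal(paste(recon$drug_id, recon$protein_id),
                  paste(pairs$drug_id, pairs$protein_id))
  keys <- list(paste(sp$train$drug_id, sp$train$protein_id),
               paste(sp$validation$drug_id, sp$validation$protein_id),
               paste(sp$test$drug_id, sp$test$protein_id))
  expect_length(intersect(keys[[1]], keys[[2]]), 0)
  expect_length(intersect(keys[[1]], keys[[3]]), 0)
  expect_length(intersect(keys[[2]], keys[[3]]), 0)

  expect_identical(split_dataset(pairs, seed = 4), sp)
  all_train <- split_dataset(pairs, ratios = c(1, 0, 0), seed = 4)
  expect_identical(nrow(all_train$train), 10L)
  expect_error(split_dataset(pairs[1:2, ], seed = 1), "at least 3")
  expect_error(split_dataset(pairs, ratios = c(0.5, 0.2, 0.2), seed = 1),
               "sum to 1")
})

test_that("pair TSVs round-trip exactly and headerless files are accepted", {
  pairs <- data.frame(drug_id = c("d1", "d2"), drug_smiles = c("CCO", "CN"),
                      protein_id = c("p1", "p2"),
                      protein_sequence = c("MKV", "AKVM"),
                      label = c(1L, 0L), affinity = c(NA_real_, NA_real_),
                      stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dti_pairs(pairs, f)
  expect_identical(read_dti_pairs(f), pairs)

  writeLines(c("CCO\tMKV\t1", "CN\tAKVM\t0"), f)
  r <- read_dti_pairs(f)
  expect_identical(r$drug_smiles, c("CCO", "CN"))
  expect_identical(r$label, c(1L, 0L))

  writeLines(c("drug_smiles\tprotein_sequence\taffinity",
               "CCO\tMKV\t12.5", "CN\tAKVM\t45"), f)
  r <- read_dti_pairs(f)
  expect_identical(r$label, c(1L, 0L))  # binarized from the affinity column
})
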