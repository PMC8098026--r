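# Readers/writers for the external formats and dataset assembly: FASTA
# proteins, .smi/TSV drugs, labeled pair TSVs, affinity binarization, negative
# sampling over unseen drug x protein pairs, and the 7:1:2 split protocol.

#' Read a protein FASTA file
#'
#' The header token before the first whitespace becomes the record id and the
#' sequence is uppercased; wrapped sequence lines are concatenated.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` and `sequence` (one row per record);
#'   zero rows for an empty file.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    return(data.frame(id = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop(sprintf("malformed FASTA: sequence data before any header at line %d", first))
  }
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1)
  data.frame(id = ids,
             sequence = toupper(as.character(aa)),
             stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Read a SMILES file
#'
#' One SMILES per line, optionally followed by a tab and an id.  Records
#' missing an id get `D<line-number>`.  Blank interior lines are skipped with
#' a warning.
#'
#' @param path Path to a `.smi`/TSV file.
#' @return A data.frame with columns `id` and `smiles`, in file order.
#' @export
read_smiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  n_interior_blank <- sum(!keep[seq_len(max(which(keep), 0))])
  if (any(!keep) && n_interior_blank > 0) {
    warning(sprintf("skipping %d blank line(s) in %s", sum(!keep), path))
  }
  idx <- which(keep)
  if (length(idx) == 0) {
    return(data.frame(id = character(0), smiles = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  smiles <- vapply(parts, `[`, character(1), 1)
  ids <- vapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) >= 2 && nzchar(p[2])) p[2] else paste0("D", idx[i])
  }, character(1))
  if (any(grepl("\\s", smiles))) stop("SMILES strings must not contain whitespace")
  data.frame(id = ids, smiles = smiles, stringsAsFactors = FALSE)
}

#' Binarize a dissociation constant into an interaction label
#'
#' Affinities strictly below the threshold (default Kd 30, in the units of the
#' source assay) are positives; the boundary value itself is negative.
#'
#' @param affinity Numeric vector of non-negative finite Kd values.
#' @param threshold Positive cutoff (default 30).
#' @return Integer vector of 0/1 labels.
#' @export
binarize_affinity <- function(affinity, threshold = 30) {
  if (any(!is.finite(affinity)) || any(affinity < 0)) {
    stop("affinity values must be finite and non-negative")
  }
  as.integer(affinity < threshold)
}

#' Assemble a labeled pair table
#'
#' @param drugs data.frame with `id`, `smiles`.
#' @param proteins data.frame with `id`, `sequence`.
#' @param drug_id,protein_id Parallel id vectors naming each pair.
#' @param label 0/1 labels (or NULL when `affinity` is given).
#' @param affinity Optional Kd values, binarized via [binarize_affinity()].
#' @return A pairs data.frame with columns `drug_id`, `drug_smiles`,
#'   `protein_id`, `protein_sequence`, `label`, `affinity`.
#' @export
make_pairs <- function(drugs, proteins, drug_id, protein_id,
                       label = NULL, affinity = NULL) {
  stopifnot(length(drug_id) == length(protein_id))
  if (is.null(label)) {
    if (is.null(affinity)) stop("either label or affinity must be supplied")
    label <- binarize_affinity(affinity)
  }
  stopifnot(all(label %in% c(0L, 1L)))
  di <- match(drug_id, drugs$id)
  pi_ <- match(protein_id, proteins$id)
  if (anyNA(di)) stop("unknown drug id: ", drug_id[which(is.na(di))[1]])
  if (anyNA(pi_)) stop("unknown protein id: ", protein_id[which(is.na(pi_))[1]])
  data.frame(drug_id = drug_id,
             drug_smiles = drugs$smiles[di],
             protein_id = protein_id,
             protein_sequence = proteins$sequence[pi_],
             label = as.integer(label),
             affinity = if (is.null(affinity)) NA_real_ else affinity,
             stringsAsFactors = FALSE)
}

#' Sample negative pairs from the unseen drug x protein space
#'
#' Draws `floor(ratio * nrow(positives))` pairs uniformly without replacement
#' from all (drug, protein) combinations not present in `positives`, labeling
#' them 0.  Deterministic given `seed`.
#'
#' @param positives Pairs data.frame (the positive set).
#' @param drugs,proteins Record data.frames spanning the sampling space.
#' @param ratio Negatives per positive (> 0, default 1 for a balanced set).
#' @param seed Integer seed.
#' @return Pairs data.frame of negatives (label 0).
#' @export
sample_negatives <- function(positives, drugs, proteins, ratio = 1, seed) {
  stopifnot(ratio > 0)
  nd <- nrow(drugs)
  np <- nrow(proteins)
  n_neg <- floor(ratio * nrow(positives))
  pos_key <- paste(positives$drug_id, positives$protein_id, sep = "\x1f")
  all_idx <- seq_len(nd * np)
  di <- ((all_idx - 1L) %% nd) + 1L
  pj <- ((all_idx - 1L) %/% nd) + 1L
  all_key <- paste(drugs$id[di], proteins$id[pj], sep = "\x1f")
  unseen <- all_idx[!(all_key %in% pos_key)]
  if (length(unseen) < n_neg) {
    stop(sprintf("insufficient unseen pairs: need %d, only %d available (short by %d)",
                 n_neg, length(unseen), n_neg - length(unseen)))
  }
  pick <- with_seed(seed, unseen[sample.int(length(unseen), n_neg)])
  make_pairs(drugs, proteins,
             drug_id = drugs$id[di[pick]],
             protein_id = proteins$id[pj[pick]],
             label = rep(0L, n_neg))
}

#' Split labeled pairs into train / validation / test sets
#'
#' Applies a seeded random permutation followed by contiguous slicing, so each
#' split size differs from its exact ratio share by less than one pair.
#'
#' @param pairs Pairs data.frame.
#' @param ratios Three non-negative reals summing to 1 (default 0.7/0.1/0.2).
#' @param seed Integer seed.
#' @return A `dti_split`: list with `train`, `validation`, `test` data.frames
#'   plus the `seed` and `ratios` used.
#' @export
split_dataset <- function(pairs, ratios = c(0.7, 0.1, 0.2), seed) {
  stopifnot(length(ratios) == 3, all(ratios >= 0))
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1")
  n <- nrow(pairs)
  if (n < 3) stop("need at least 3 pairs to split")
  perm <- with_seed(seed, sample.int(n))
  cuts <- floor(cumsum(ratios) * n + 1e-9)
  cuts[3] <- n
  idx <- list(train = seq_len(cuts[1]),
              validation = if (cuts[2] > cuts[1]) (cuts[1] + 1):cuts[2] else integer(0),
              test = if (cuts[3] > cuts[2]) (cuts[2] + 1):cuts[3] else integer(0))
  out <- lapply(idx, function(i) pairs[perm[i], , drop = FALSE])
  out <- lapply(out, function(d) { rownames(d) <- NULL; d })
  structure(c(out, list(seed = seed, ratios = ratios)), class = "dti_split")
}

#' @export
print.dti_split <- function(x, ...) {
  cat(sprintf("DTI split: %d train / %d validation / %d test (seed %s)\n",
              nrow(x$train), nrow(x$validation), nrow(x$test), format(x$seed)))
  invisible(x)
}

#' Write labeled pairs to TSV
#'
#' Tab-separated with a header row (`drug_smiles`, `protein_sequence`,
#' `label`, plus ids and affinity when present).
#'
#' @param pairs Pairs data.frame.
#' @param path Output path.
#' @export
write_dti_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a labeled pair TSV
#'
#' A header row is detected by a literal `smiles` token in the first line;
#' headerless files are read positionally as
#' `drug_smiles<TAB>protein_sequence<TAB>label` (or a 4th affinity column).
#'
#' @param path Input path.
#' @param affinity_threshold Used to binarize an `affinity` column when no
#'   `label` column is present.
#' @return Pairs data.frame.
#' @export
read_dti_pairs <- function(path, affinity_threshold = 30) {
  first <- readLines(path, n = 1)
  has_header <- grepl("smiles", first, ignore.case = TRUE)
  d <- utils::read.table(path, sep = "\t", header = has_header,
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "")
  if (!has_header) {
    nm <- c("drug_smiles", "protein_sequence",
            if (ncol(d) >= 3) "label", if (ncol(d) >= 4) "affinity")
    names(d)[seq_along(nm)] <- nm
  }
  if (!"label" %in% names(d)) {
    if (!"affinity" %in% names(d)) stop("pair file has neither label nor affinity")
    d$label <- binarize_affinity(d$affinity, affinity_threshold)
  }
  d$label <- as.integer(d$label)
  if (!"drug_id" %in% names(d)) d$drug_id <- paste0("D", seq_len(nrow(d)))
  if (!"protein_id" %in% names(d)) d$protein_id <- paste0("P", seq_len(nrow(d)))
  if (!"affinity" %in% names(d)) d$affinity <- NA_real_
  d$affinity <- as.numeric(d$affinity)
  d[, c("drug_id", "drug_smiles", "protein_id", "protein_sequence",
        "label", "affinity")]
}
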