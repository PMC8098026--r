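# Interaction-map interpretability: extract the labeled drug x protein
# interaction map for a single pair and report the highest-intensity
# sub-structure pairs.

#' Extract the labeled interaction map for one pair
#'
#' Runs the encoder forward pass and captures the pairwise interaction map,
#' restricted to real (non-PAD) positions, with rows labeled by the drug's
#' sub-structure tokens and columns by the protein's.
#'
#' @param model A `dti_model` (the `no_interaction` variant has no map).
#' @param smiles Drug SMILES string.
#' @param protein_seq Protein amino-acid sequence.
#' @return A `labeled_interaction_map`: list with `map` (n_drug x n_protein
#'   matrix), `drug_tokens`, `protein_tokens`.
#' @export
extract_map <- function(model, smiles, protein_seq) {
  if (model$config$variant == "no_interaction") {
    stop("the no_interaction variant does not compute an interaction map")
  }
  d_tok <- tokenize_sequence(smiles, model$drug_merges)
  p_tok <- tokenize_sequence(protein_seq, model$protein_merges)
  idx <- model_index_pair(model, smiles, protein_seq)
  fw <- pair_forward(model, idx$drug, idx$protein)
  nd <- idx$drug$true_length
  np <- idx$protein$true_length
  structure(list(map = fw$cache$I[seq_len(nd), seq_len(np), drop = FALSE],
                 drug_tokens = d_tok[seq_len(nd)],
                 protein_tokens = p_tok[seq_len(np)],
                 probability = fw$p),
            class = "labeled_interaction_map")
}

#' @export
print.labeled_interaction_map <- function(x, ...) {
  cat(sprintf("Interaction map: %d drug x %d protein sub-structures (P = %.3f)\n",
              nrow(x$map), ncol(x$map), x$probability))
  invisible(x)
}

#' Report the strongest sub-structure interactions
#'
#' Filters the labeled map either to cells with intensity at or above a
#' threshold, or to the k most intense cells (exactly one selector must be
#' given).  Entries are sorted by intensity descending, ties broken by
#' (drug position, protein position).
#'
#' @param map A `labeled_interaction_map` from [extract_map()].
#' @param threshold Minimum intensity (mutually exclusive with `k`).
#' @param k Number of top cells to keep (mutually exclusive with
#'   `threshold`).
#' @return A data.frame with columns `drug_token`, `drug_pos`,
#'   `protein_token`, `protein_pos`, `intensity`.
#' @export
top_interactions <- function(map, threshold = NULL, k = NULL) {
  stopifnot(inherits(map, "labeled_interaction_map"))
  if (is.null(threshold) == is.null(k)) {
    stop("give exactly one of `threshold` or `k`")
  }
  I <- map$map
  df <- data.frame(
    drug_token = rep(map$drug_tokens, times = ncol(I)),
    drug_pos = rep(seq_len(nrow(I)), times = ncol(I)),
    protein_token = rep(map$protein_tokens, each = nrow(I)),
    protein_pos = rep(seq_len(ncol(I)), each = nrow(I)),
    intensity = as.numeric(I),
    stringsAsFactors = FALSE)
  df <- df[order(-df$intensity, df$drug_pos, df$protein_pos), , drop = FALSE]
  if (!is.null(threshold)) {
    df <- df[df$intensity >= threshold, , drop = FALSE]
  } else {
    stopifnot(k >= 1)
    df <- utils::head(df, k)
  }
  rownames(df) <- NULL
  df
}

#' Write an explanation report to disk
#'
#' Writes the full labeled map as TSV (`map.tsv`, rows = drug tokens) and the
#' top-interaction entries (`entries.tsv`).
#'
#' @param map A `labeled_interaction_map`.
#' @param dir Output directory.
#' @param k Number of entries to report (default 10).
#' @export
write_explanation <- function(map, dir, k = 10) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- as.data.frame(map$map)
  names(m) <- sprintf("%s@%d", map$protein_tokens, seq_along(map$protein_tokens))
  rownames(m) <- sprintf("%s@%d", map$drug_tokens, seq_along(map$drug_tokens))
  utils::write.table(m, file.path(dir, "map.tsv"), sep = "\t", quote = FALSE,
                     col.names = NA)
  utils::write.table(top_interactions(map, k = k), file.path(dir, "entries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
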