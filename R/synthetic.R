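# Synthetic corpora and labeled DTI pairs with the statistical structure the
# pipeline assumes: planted high-frequency motifs give the FCS miner signal,
# and the interaction label is a deterministic motif co-occurrence rule plus
# optional label noise, so the interaction model has learnable structure.

#' Specification for a synthetic DTI dataset
#'
#' Defaults emulate real cardinalities at toy scale: an 8-symbol SMILES-like
#' drug alphabet and the 20 standard amino acids, 60 drugs x 60 proteins,
#' drug lengths 16-24 and protein lengths 30-45, one planted motif per side
#' (inserted with probability 0.7), and the interaction rule
#' "label 1 iff the drug contains `drug_motif` AND the protein contains
#' `protein_motif`", flipped with probability `label_noise`.
#'
#' @param drug_alphabet,protein_alphabet Symbol sets.
#' @param n_drugs,n_proteins Corpus sizes.
#' @param drug_length,protein_length Integer length ranges `c(min, max)`.
#' @param drug_motif,protein_motif Motif strings over their alphabets.
#' @param motif_prob Insertion probability for both motifs.
#' @param n_pairs Number of labeled pairs to draw.
#' @param positive_fraction Fraction of rule-positive pairs (default balanced).
#' @param label_noise Label flip probability, in [0, 0.5).
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(drug_alphabet = c("C", "N", "O", "S", "P", "F", "B", "I"),
                           protein_alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                           n_drugs = 60, n_proteins = 60,
                           drug_length = c(16, 24), protein_length = c(30, 45),
                           drug_motif = "NCCO", protein_motif = "KNWVH",
                           motif_prob = 0.7,
                           n_pairs = 2000, positive_fraction = 0.5,
                           label_noise = 0, seed = 1L) {
  stopifnot(label_noise >= 0, label_noise < 0.5,
            positive_fraction > 0, positive_fraction < 1)
  if (!all(strsplit(drug_motif, "")[[1]] %in% drug_alphabet)) {
    stop("drug motif contains symbols outside the drug alphabet")
  }
  if (!all(strsplit(protein_motif, "")[[1]] %in% protein_alphabet)) {
    stop("protein motif contains symbols outside the protein alphabet")
  }
  structure(list(drug_alphabet = drug_alphabet,
                 protein_alphabet = protein_alphabet,
                 n_drugs = as.integer(n_drugs),
                 n_proteins = as.integer(n_proteins),
                 drug_length = as.integer(drug_length),
                 protein_length = as.integer(protein_length),
                 drug_motif = drug_motif, protein_motif = protein_motif,
                 motif_prob = motif_prob,
                 n_pairs = as.integer(n_pairs),
                 positive_fraction = positive_fraction,
                 label_noise = label_noise, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a random sequence corpus with planted motifs
#'
#' Sequences are uniform over the alphabet with lengths uniform in
#' `length_range`; each motif is then written over a uniformly chosen window
#' with its insertion probability (overwriting keeps lengths in range).
#'
#' @param alphabet Character vector of symbols.
#' @param n Number of sequences.
#' @param length_range `c(min, max)` sequence lengths.
#' @param planted_motifs List of `list(motif = , prob = )` entries.
#' @param seed Integer seed.
#' @return Character vector of sequences.
#' @export
generate_corpus <- function(alphabet, n, length_range, planted_motifs = list(),
                            seed) {
  for (m in planted_motifs) {
    if (nchar(m$motif) > length_range[1]) {
      stop(sprintf("motif '%s' is longer than the minimum sequence length", m$motif))
    }
  }
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      len <- sample(length_range[1]:length_range[2], 1)
      chars <- sample(alphabet, len, replace = TRUE)
      for (m in planted_motifs) {
        if (stats::runif(1) < m$prob) {
          mc <- strsplit(m$motif, "")[[1]]
          start <- sample(len - length(mc) + 1L, 1)
          chars[start:(start + length(mc) - 1L)] <- mc
        }
      }
      paste(chars, collapse = "")
    }, character(1))
  })
}

#' Generate a labeled synthetic DTI dataset
#'
#' Drug and protein corpora are generated from `spec`; the rule label of a
#' pair is 1 iff the drug contains the drug motif AND the protein contains
#' the protein motif.  Pairs are drawn uniformly without replacement from the
#' rule-positive and rule-negative cross spaces to hit `positive_fraction`,
#' and the observed label flips the rule label with probability `label_noise`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `drugs`, `proteins` (record data.frames), `pairs` (with
#'   `label` observed and `rule_label` ground truth) and `spec`.
#' @export
generate_dti <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  drugs_s <- generate_corpus(spec$drug_alphabet, spec$n_drugs, spec$drug_length,
                             list(list(motif = spec$drug_motif, prob = spec$motif_prob)),
                             seed = spec$seed)
  prot_s <- generate_corpus(spec$protein_alphabet, spec$n_proteins,
                            spec$protein_length,
                            list(list(motif = spec$protein_motif, prob = spec$motif_prob)),
                            seed = spec$seed + 1L)
  drugs <- data.frame(id = paste0("D", seq_along(drugs_s)), smiles = drugs_s,
                      stringsAsFactors = FALSE)
  proteins <- data.frame(id = paste0("P", seq_along(prot_s)), sequence = prot_s,
                         stringsAsFactors = FALSE)
  has_d <- grepl(spec$drug_motif, drugs_s, fixed = TRUE)
  has_p <- grepl(spec$protein_motif, prot_s, fixed = TRUE)
  nd <- spec$n_drugs
  all_idx <- seq_len(nd * spec$n_proteins)
  di <- ((all_idx - 1L) %% nd) + 1L
  pj <- ((all_idx - 1L) %/% nd) + 1L
  rule <- has_d[di] & has_p[pj]
  n_pos <- round(spec$n_pairs * spec$positive_fraction)
  n_neg <- spec$n_pairs - n_pos
  if (sum(rule) == 0 || sum(!rule) == 0) {
    stop(paste("the motif rule yields single-class data;",
               "adjust motif insertion probabilities"))
  }
  if (sum(rule) < n_pos || sum(!rule) < n_neg) {
    stop(sprintf(paste("cannot draw %d positive / %d negative pairs from %d / %d",
                       "available; increase corpus sizes or adjust motif_prob"),
                 n_pos, n_neg, sum(rule), sum(!rule)))
  }
  with_seed(spec$seed + 2L, {
    pick <- c(sample(all_idx[rule], n_pos), sample(all_idx[!rule], n_neg))
    rule_label <- as.integer(rule[pick])
    flips <- stats::rbinom(length(pick), 1, spec$label_noise)
    label <- as.integer(xor(rule_label, flips))
    pairs <- data.frame(drug_id = drugs$id[di[pick]],
                        drug_smiles = drugs_s[di[pick]],
                        protein_id = proteins$id[pj[pick]],
                        protein_sequence = prot_s[pj[pick]],
                        label = label,
                        affinity = NA_real_,
                        rule_label = rule_label,
                        stringsAsFactors = FALSE)
  })
  list(drugs = drugs, proteins = proteins, pairs = pairs, spec = spec)
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes `drugs.smi` (SMILES TAB id), `proteins.fasta`, `pairs.tsv` and
#' `ground_truth.json` (motifs, rule, noise rate) into `dir`.
#'
#' @param dataset Output of [generate_dti()].
#' @param dir Output directory (created if needed).
#' @export
write_synthetic <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(paste(dataset$drugs$smiles, dataset$drugs$id, sep = "\t"),
             file.path(dir, "drugs.smi"))
  writeLines(as.vector(rbind(paste0(">", dataset$proteins$id),
                             dataset$proteins$sequence)),
             file.path(dir, "proteins.fasta"))
  write_dti_pairs(dataset$pairs, file.path(dir, "pairs.tsv"))
  spec <- dataset$spec
  jsonlite::write_json(
    list(rule = "label = 1 iff drug contains drug_motif AND protein contains protein_motif",
         drug_motif = spec$drug_motif, protein_motif = spec$protein_motif,
         label_noise = spec$label_noise, seed = spec$seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
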