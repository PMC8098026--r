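# Shared model fixtures.  Heavy trained-model results (the learnability runs)
# are computed once per test session and memoized, since several checks look
# at the same trained models from different angles.

tiny_model <- function(seed = 3, variant = "full", n_layers = 1) {
  dm <- mine_fcs(c("CCO", "CNO", "OCC", "CCN"), theta = 2)$merges
  pm <- mine_fcs(c("MKVA", "MKAV", "AKVM", "MKVV"), theta = 2)$merges
  cfg <- dti_model_config(embed_dim = 8, n_layers = n_layers, n_heads = 2,
                          ffn_dim = 12, dropout = 0, max_len_drug = 6,
                          max_len_protein = 8, variant = variant)
  dti_model(dm, pm, cfg, seed = seed)
}

# 64 separable pairs with short sequences: the overfit fixture.
overfit_fixture <- function(seed = 7) {
  spec <- synthetic_spec(n_drugs = 16, n_proteins = 16, n_pairs = 64,
                         drug_length = c(10, 14), protein_length = c(16, 24),
                         seed = seed)
  ds <- generate_dti(spec)
  dm <- mine_fcs(ds$drugs$smiles, theta = 3)$merges
  pm <- mine_fcs(ds$proteins$sequence, theta = 3)$merges
  split <- structure(list(train = ds$pairs, validation = ds$pairs,
                          test = ds$pairs, seed = seed, ratios = c(1, 0, 0)),
                     class = "dti_split")
  list(dataset = ds, drug_merges = dm, protein_merges = pm, split = split)
}

# One learnability run: 2000 motif-rule pairs, desk profile, 5 training epochs.
learnability_run <- function(seed, label_noise = 0, variant = "full") {
  spec <- synthetic_spec(label_noise = label_noise, seed = seed)
  ds <- generate_dti(spec)
  dm <- mine_fcs(ds$drugs$smiles, theta = 5)$merges
  pm <- mine_fcs(ds$proteins$sequence, theta = 5)$merges
  split <- split_dataset(ds$pairs, seed = seed)
  model <- dti_model(dm, pm, desk_model_config(variant = variant), seed = seed)
  fit <- train_model(model, split,
                     desk_train_config(seed = seed, max_epochs = 5))
  report <- evaluate_model(fit$model, split$test, split$validation)
  list(model = fit$model, history = fit$history, report = report,
       split = split, dataset = ds)
}

.learnability_cache <- new.env(parent = emptyenv())

learnability_results <- function() {
  if (is.null(.learnability_cache$res)) {
    seeds <- 1:3
    .learnability_cache$res <- list(
      clean = lapply(seeds, function(s) learnability_run(s, label_noise = 0)),
      noisy = lapply(seeds, function(s) learnability_run(s, label_noise = 0.1)),
      no_interaction = lapply(seeds, function(s) {
        learnability_run(s, label_noise = 0, variant = "no_interaction")
      }))
  }
  .learnability_cache$res
}
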