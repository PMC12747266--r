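# Shared fixtures, computed once per test run and memoized in this
# environment (chemistry subprocess calls are batched and cached).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

panel_graphs <- function() {
  cached("panel_graphs", smiles_to_graph(oracle_panel, simplify = FALSE))
}

panel_physchem <- function() {
  cached("panel_physchem", compute_physchem(oracle_panel))
}

# small raw activity table exercising every provenance bucket
dirty_table <- function() {
  cached("dirty_table", {
    spec <- fixture_spec(n_molecules = 40, n_targets = 2, dirty_fraction = 0.15,
                         dup_fraction = 0.1, seed = 303)
    generate_activity_table(spec)
  })
}

# a tiny trained fit shared by the modelling-method tests
tiny_fit <- function() {
  cached("tiny_fit", {
    spec <- fixture_spec(n_molecules = 40, n_targets = 2, dirty_fraction = 0,
                         dup_fraction = 0, seed = 7)
    clean <- clean_activities(generate_activity_table(spec))
    sp <- split_activities(clean, 0.25, seed = 1)
    ic50net(sp$train, test = sp$test,
            control = train_control(epochs = 8, batch_size = 16, seed = 1,
                                    eval_every = 4))
  })
}

tiny_features <- function() {
  cached("tiny_features", {
    smi <- canonicalize_smiles(c("CCO", "c1ccccc1", "C[C@H](N)C(=O)O",
                                 "Clc1ccccc1", "CCCCO", "c1ccncc1"))
    df <- data.frame(canonical_smiles = smi, target_id = "T1",
                     log_ic50 = c(2, 3, 2.5, 4, 3.5, 1.5),
                     stringsAsFactors = FALSE)
    feats <- featurize_dataset(df)
    norm <- fit_normalizer(feats$desc)
    feats$desc <- apply_normalizer(norm, feats$desc)
    feats$normalizer <- norm
    feats
  })
}
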