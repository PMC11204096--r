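# Fixtures are generated in code; nothing is stored on disk.

toy_counts <- function(values, features, samples, kind = "mrna") {
  count_matrix(
    matrix(values, nrow = length(features), byrow = TRUE,
           dimnames = list(features, samples)),
    feature_kind = kind
  )
}

toy_meta <- function(sample_ids, diet, mmi = NULL, ph = NULL,
                     compartment = "kidney") {
  n <- length(sample_ids)
  data.frame(
    sample_id = sample_ids, animal_id = sample_ids, diet = diet,
    mmi = mmi %||% rep(FALSE, n), ph = ph %||% rep(FALSE, n),
    weight_g = NA_real_, albuminuria_ng_ml = NA_real_,
    compartment = compartment, stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small null-model configuration (no embedded effects)
null_config <- function(seed, n_per_group = 4, n_genes = 500) {
  sim_config(
    n_per_group = n_per_group, n_genes = n_genes, n_mirnas = 0,
    n_true_regulations = 0, effect_log2 = 0, n_decoy_edges = 0,
    n_lesion_genes = 0, frac_unexpressed_targets = 0, seed = seed
  )
}

# the truth-bearing study conditions used for recovery checks:
# 50 embedded suppressions (4 converging on one hub gene), 200 decoy
# edges, effect 2 on the log2 scale, dispersion 0.05, n = 8 + 8
signal_config <- function(seed, n_genes = 500, n_mirnas = 40) {
  sim_config(
    n_per_group = 8, n_genes = n_genes, n_mirnas = n_mirnas,
    n_true_regulations = 50, effect_log2 = 2, dispersion = 0.05,
    n_decoy_edges = 200, seed = seed
  )
}

kidney_meta <- function(study) {
  study$meta[study$meta$compartment == "kidney", , drop = FALSE]
}
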