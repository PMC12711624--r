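# Small fixtures shared across tests; everything is generated in code.

# a compact simulation config so tests stay fast
small_config <- function(n = 120, seed = 7, ...) {
  simulation_config(
    n_samples = n,
    views = list(
      list(name = "mutation", n_features = 80, modality = "binary",
           noise_sd = NA),
      list(name = "mrna", n_features = 200, modality = "continuous",
           noise_sd = 0.7),
      list(name = "protein", n_features = 150, modality = "continuous",
           noise_sd = 0.5),
      list(name = "phospho", n_features = 150, modality = "continuous",
           noise_sd = 1.0)),
    seed = seed, ...)
}

# a tiny config for survival simulations: the hazard acts on the factor
# scores, so the omics views can be minimal
survival_config <- function(n = 100, seed = 1, ...) {
  args <- list(
    n_samples = n,
    views = list(
      list(name = "mrna", n_features = 40, modality = "continuous",
           noise_sd = 0.7),
      list(name = "protein", n_features = 40, modality = "continuous",
           noise_sd = 0.5)),
    n_factors_true = 2,
    prognostic_factor_index = 2,
    n_signature_genes = 5,
    missing_view_fraction = 0,
    seed = seed)
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

# all permutations of 1:5, for small assignment oracles
permutations_5 <- function() {
  p <- expand.grid(a = 1:5, b = 1:5, c = 1:5, d = 1:5, e = 1:5)
  unname(as.matrix(p[apply(p, 1, function(r) length(unique(r)) == 5), ]))
}

toy_view <- function(X, name = "toy", modality = "continuous") {
  if (is.null(rownames(X))) rownames(X) <- paste0("S", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("F", seq_len(ncol(X)))
  omics_view(X, name = name, modality = modality)
}
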