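#!/usr/bin/env Rscript
# Simulate the study cohorts: a discovery cohort with planted multi-omics
# factor structure, a validation cohort drawn from the same planted
# loadings (for cross-cohort projection), and single-cell counts in which
# one cell type over-expresses the planted signature genes.
#
# Writes delimited matrices + clinical tables under results/data/ and the
# ground-truth objects under results/ for downstream stages.

library(omicsfactor)

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260921

cfg <- simulation_config(seed = seed)
disc <- generate_multiomics(cfg)
valid <- generate_multiomics(simulation_config(n_samples = 150,
                                               seed = seed + 1),
                             truth = disc$truth)

# sprinkle feature-level dropout on the discovery phospho view so the
# detection-rate filter has something to do: 10% of features lose ~30%
# of their entries
set.seed(seed)
ph <- disc$dataset$views$phospho$X
drop_feat <- sample(ncol(ph), ncol(ph) %/% 10)
for (j in drop_feat) {
  obs <- which(!is.na(ph[, j]))
  ph[sample(obs, round(0.3 * length(obs))), j] <- NA
}
disc$dataset$views$phospho <- omics_view(ph, "phospho", "continuous")

for (v in disc$dataset$views)
  write_matrix(v, file.path(out, paste0("discovery_", v$name, ".tsv")))
write_clinical(disc$dataset$clinical, file.path(out, "discovery_clinical.tsv"))
write_matrix(valid$dataset$views$protein,
             file.path(out, "validation_protein.tsv"))
write_clinical(valid$dataset$clinical,
               file.path(out, "validation_clinical.tsv"))

sc <- generate_sc_counts(n_cells = 3000, n_genes = 400,
                         signature_genes = disc$truth$signature_genes,
                         fold_change = 4, seed = seed)
saveRDS(sc, "results/sc_counts.rds")
saveRDS(disc$truth, "results/truth_discovery.rds")
saveRDS(valid$truth, "results/truth_validation.rds")

cat("Discovery cohort:", cfg$n_samples, "samples,",
    length(disc$dataset$views), "views\n")
cat("Validation cohort:", nrow(valid$dataset$clinical),
    "samples (protein view only)\n")
cat("Planted signature genes:", length(disc$truth$signature_genes), "\n")
cat("Single cells:", nrow(sc$counts), "across",
    length(unique(sc$cell_type)), "cell types\n")
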