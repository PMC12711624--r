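#!/usr/bin/env Rscript
# Read the simulated cohort back from delimited text and apply the
# per-view filters: mutation burden > 10 carriers, the 800 most variable
# mRNAs, phospho features with > 80% detection; z-score the continuous
# views and restrict to samples present in every view.

library(omicsfactor)

dat <- "results/data"
mutation <- read_matrix(file.path(dat, "discovery_mutation.tsv"),
                        name = "mutation", modality = "binary")
mrna <- read_matrix(file.path(dat, "discovery_mrna.tsv"), name = "mrna")
protein <- read_matrix(file.path(dat, "discovery_protein.tsv"),
                       name = "protein")
phospho <- read_matrix(file.path(dat, "discovery_phospho.tsv"),
                       name = "phospho")
clinical <- read_clinical(file.path(dat, "discovery_clinical.tsv"))

n0 <- vapply(list(mutation, mrna, protein, phospho),
             function(v) ncol(v$X), numeric(1))

mutation <- filter_mutation_burden(mutation, min_mutated = 10)
mrna <- select_top_variable(mrna, 800)
phospho <- filter_detection(phospho, min_rate = 0.8)

mrna <- zscore_view(mrna)
protein <- zscore_view(protein)
phospho <- zscore_view(phospho)

ds <- multiomics_dataset(list(mutation = mutation, mrna = mrna,
                              protein = protein, phospho = phospho),
                         clinical)
cc <- intersect_samples(ds)

cat("Features per view before filtering:", n0, "\n")
cat("After filtering: mutation", ncol(mutation$X),
    "| mrna", ncol(mrna$X), "| protein", ncol(protein$X),
    "| phospho", ncol(phospho$X), "\n")
cat("Complete-case samples (all views observed):",
    length(cc$sample_ids), "of", length(ds$sample_ids), "\n")

saveRDS(ds, "results/dataset_full.rds")
saveRDS(cc, "results/dataset_complete.rds")
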