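#!/usr/bin/env Rscript
# Stage 1: generate the two synthetic longitudinal cohorts.
#
# Each cohort is a 7-phylum gut community sampled weekly from 3 to 15
# weeks of age in 12 mice, sequenced to 10,000 reads per sample, with a
# known ground-truth interaction network: an untreated community in which
# Proteobacteria form an interaction hub, and a vancomycin-type community
# in which the hub is absent and Firmicutes facilitate Verrucomicrobia.
# A small 3-taxon community is generated alongside as a quick test bed.

library(glvnet)

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

for (name in c("control", "vancomycin", "three_taxon")) {
  spec <- make_scenario(name)
  ds <- generate_dataset(spec)
  write_abundance(ds$table,
                  file.path("results/data", paste0(name, "_counts.tsv")))
  write_metadata(ds$meta,
                 file.path("results/data", paste0(name, "_metadata.tsv")))
  write_model_json(scenario_model(spec),
                   file.path("results/data", paste0(name, "_truth.json")))
  write_edgelist_tsv(true_network(spec),
                     file.path("results/data",
                               paste0(name, "_true_edges.tsv")))
  cat(sprintf(
    "%s: %d taxa rows x %d samples (%d mice, weeks %d-%d, depth %g)\n",
    name, length(ds$table$taxa), length(ds$table$samples),
    spec$n_subjects, min(spec$weeks), max(spec$weeks), spec$depth))
}
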