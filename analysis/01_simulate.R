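#!/usr/bin/env Rscript
# Stage 1: generate the synthetic 4-plex TMT proximity-labeling experiment
# that stands in for the study's mass-spectrometry data, and write every
# input the downstream stages read: the quantification table, the two
# compartment false-positive lists, a synthetic GO term map, the truth
# labels, and the resolved configuration.

suppressPackageStartupMessages(library(proxfpi))

out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 7)   # default study conditions
sim <- simulate_experiment(cfg)

write_quant_table(sim$quant, file.path(out, "quant_table.tsv"))
write_compartment_list(sim$er_list, file.path(out, "er_membrane_list.txt"))
write_compartment_list(sim$cm_list, file.path(out, "cell_membrane_list.txt"))
utils::write.table(sim$truth, file.path(out, "truth.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

go <- simulate_go_annotations(sim$quant$accession, seed = cfg$seed)
writeLines(unlist(lapply(names(go), function(a)
  if (length(go[[a]])) paste(a, go[[a]], sep = "\t") else character(0))),
  file.path(out, "go_map.tsv"))

jsonlite::write_json(unclass(cfg), file.path(out, "config.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat("simulated", nrow(sim$quant), "proteins:",
    sum(sim$truth$class == "true_proximal"), "true proximal,",
    sum(sim$truth$class == "background"), "nuclear background,",
    length(sim$er_list$accessions), "ER-membrane FP,",
    length(sim$cm_list$accessions), "cell-membrane FP,",
    sum(sim$truth$class == "contaminant"), "contaminants, plus the bait\n")
cat("inputs written under", out, "\n")
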