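#!/usr/bin/env Rscript
# Stage 2: enrichment ratios and replicate-agreement QC.
# Reads the stage-1 quantification table, applies the >2-unique-peptide
# identification filter and median channel normalization, computes the four
# log2 enrichment tables, and reports how well the two independent bait
# replicates agree (OLS fit of replicate 2 on replicate 1).

suppressPackageStartupMessages(library(proxfpi))

indir <- "results/simulated"
out <- "results/enrichment"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

quant <- read_quant_table(file.path(indir, "quant_table.tsv"))
cat("proteins in table:", nrow(quant), "\n")
quant <- filter_by_peptides(quant, min_unique = 2)
cat("with > 2 unique peptides:", nrow(quant), "\n")
quant <- normalize_channels(quant)
ratios <- compute_enrichment(quant)

for (k in names(ratios)) {
  df <- data.frame(accession = names(ratios[[k]]$values),
                   log2_ratio = unname(ratios[[k]]$values))
  utils::write.table(df, file.path(out, paste0("log2_", k, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

corr <- replicate_correlation(ratios[["vs_spatial_control.rep1"]],
                              ratios[["vs_spatial_control.rep2"]])
cat(sprintf("replicate agreement (vs spatial control): R^2 = %.3f, slope = %.2f, intercept = %.2f, n = %d\n",
            corr$r_squared, corr$slope, corr$intercept, corr$n))
utils::write.table(
  data.frame(r_squared = corr$r_squared, slope = corr$slope,
             intercept = corr$intercept, n = corr$n),
  file.path(out, "replicate_correlation.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

p <- plot_replicate_scatter(ratios[["vs_spatial_control.rep1"]],
                            ratios[["vs_spatial_control.rep2"]], corr)
ggplot2::ggsave(file.path(out, "replicate_scatter.png"), p,
                width = 5, height = 5, dpi = 150)
cat("tables and scatter written under", out, "\n")
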