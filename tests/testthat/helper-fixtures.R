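# shared fixture builders; everything is generated in code at test time

default_channels <- unname(default_channel_roles())

# a quant_table built directly in memory
make_quant <- function(accession,
                       intensities,  # matrix n x 4, columns = channels
                       unique_peptides = rep(5L, length(accession)),
                       gene_symbol = accession,
                       channels = default_channels,
                       channel_roles = default_channel_roles()) {
  df <- data.frame(accession = accession, gene_symbol = gene_symbol,
                   unique_peptides = unique_peptides,
                   stringsAsFactors = FALSE)
  for (j in seq_along(channels)) df[[channels[j]]] <- intensities[, j]
  as_quant_table(df, channels = channels, channel_roles = channel_roles)
}

# random positive quant table
random_quant <- function(n, seed = 1) {
  set.seed(seed)
  make_quant(sprintf("P%04d", seq_len(n)),
             matrix(2^rnorm(n * 4, 16, 2), n, 4),
             unique_peptides = 1L + rpois(n, 5))
}

# enrichment table straight from a named numeric vector
make_enrichment <- function(values, axis = "vs_no_ligase", replicate = "rep1") {
  structure(list(axis = axis, replicate = replicate, values = values,
                 n_dropped = 0L),
            class = "enrichment_table")
}

# brute-force minimal cutoff: smallest observed FP ratio c such that the
# strictly-above fraction is <= target (independent of fpi_curve internals)
brute_force_cutoff <- function(fp_values, target) {
  cand <- sort(unique(fp_values))
  for (c in cand) {
    if (mean(fp_values > c) <= target) return(c)
  }
  stop("no candidate satisfies the target")  # unreachable: max has fpi 0
}

write_tmp_lines <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}
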