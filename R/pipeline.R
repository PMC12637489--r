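#' Run the full proximity-proteome filtering pipeline
#'
#' Orchestrates the analysis end to end: unique-peptide filtering, optional
#' median channel normalization, the four log2 enrichment tables, the
#' replicate-agreement OLS fit, per-replicate FPI cutoff calibration on both
#' axes (no-ligase axis against the ER-membrane list, spatial-control axis
#' against the cell-membrane list), dual filtering, replicate intersection,
#' and optional GO-keyword tagging. Deterministic: identical inputs give
#' identical outputs.
#'
#' @param quant A `quant_table` or a path readable by [read_quant_table()].
#' @param er_list,cm_list `compartment_list`s (or paths) used to calibrate
#'   the no-ligase and spatial-control filters respectively.
#' @param bait Bait accession.
#' @param go_map Optional `go_map` (or path) for category tagging.
#' @param min_unique Unique-peptide filter threshold (survivors have
#'   strictly more). Default 2.
#' @param normalize Median-equalize channels before ratioing (default TRUE).
#' @param fpi_filter1 Target FPI rate for the no-ligase filter (default 0.03).
#' @param fpi_filter2 Target FPI rate for the spatial-control filter
#'   (default 0.05; a warning is raised if filter 1's target exceeds it).
#' @param channel_roles Role -> channel map used when `quant` is a path.
#' @param out_dir Optional directory; when given, result tables, FPI curves,
#'   cutoff provenance, a summary and a JSON run manifest are written there.
#' @return A `pipeline_result` list: `proteome`, `correlation`
#'   (vs-spatial-control axis, rep2 on rep1), `curves`, `cutoffs`,
#'   `fold_reduction`, `counts` (proteins at each stage), `params`.
#' @export
run_pipeline <- function(quant, er_list, cm_list, bait,
                         go_map = NULL,
                         min_unique = 2,
                         normalize = TRUE,
                         fpi_filter1 = 0.03,
                         fpi_filter2 = 0.05,
                         channel_roles = default_channel_roles(),
                         out_dir = NULL) {
  if (is.character(quant)) {
    quant <- read_quant_table(quant, channel_roles = channel_roles)
  }
  if (is.character(er_list)) er_list <- read_compartment_list(er_list, "ER_membrane")
  if (is.character(cm_list)) cm_list <- read_compartment_list(cm_list, "cell_membrane")
  if (is.character(go_map)) go_map <- read_go_map(go_map)
  for (t in c(fpi_filter1, fpi_filter2)) {
    if (t <= 0 || t >= 1) stop("FPI targets must lie in (0, 1)", call. = FALSE)
  }
  if (fpi_filter1 > fpi_filter2) {
    warning("filter-1 FPI target (", fpi_filter1, ") exceeds filter-2 target (",
            fpi_filter2, "); the no-ligase filter is usually the stricter one",
            call. = FALSE)
  }

  n_input <- nrow(quant)
  quant_f <- filter_by_peptides(quant, min_unique)
  n_peptide <- nrow(quant_f)
  if (normalize) quant_f <- normalize_channels(quant_f)
  ratios <- compute_enrichment(quant_f)

  correlation <- replicate_correlation(ratios[["vs_spatial_control.rep1"]],
                                       ratios[["vs_spatial_control.rep2"]])

  curves <- list(
    vs_no_ligase.rep1 = fpi_curve(ratios[["vs_no_ligase.rep1"]], er_list),
    vs_no_ligase.rep2 = fpi_curve(ratios[["vs_no_ligase.rep2"]], er_list),
    vs_spatial_control.rep1 = fpi_curve(ratios[["vs_spatial_control.rep1"]], cm_list),
    vs_spatial_control.rep2 = fpi_curve(ratios[["vs_spatial_control.rep2"]], cm_list))
  targets <- c(vs_no_ligase.rep1 = fpi_filter1, vs_no_ligase.rep2 = fpi_filter1,
               vs_spatial_control.rep1 = fpi_filter2,
               vs_spatial_control.rep2 = fpi_filter2)
  cutoffs <- lapply(names(curves),
                    function(k) cutoff_at_fpi(curves[[k]], targets[[k]]))
  names(cutoffs) <- names(curves)
  pass_sets <- lapply(names(curves),
                      function(k) apply_filter(ratios[[k]], cutoffs[[k]]))
  names(pass_sets) <- names(curves)

  gene_symbols <- stats::setNames(quant$gene_symbol, quant$accession)
  proteome <- build_proteome(
    pass_sets, ratios, bait, gene_symbols = gene_symbols,
    provenance = list(cutoffs = cutoffs,
                      fpi_targets = list(filter1 = fpi_filter1,
                                         filter2 = fpi_filter2),
                      min_unique = min_unique, normalize = normalize,
                      n_input = n_input, n_peptide_filtered = n_peptide))
  if (!is.null(go_map)) proteome <- tag_proteome(proteome, go_map)

  reduction <- fold_reduction(n_peptide, nrow(proteome$entries))
  result <- structure(
    list(proteome = proteome,
         correlation = correlation,
         curves = curves,
         cutoffs = cutoffs,
         fold_reduction = reduction,
         counts = list(input = n_input, peptide_filtered = n_peptide,
                       rep1_survivors = proteome$provenance$rep1_survivors,
                       rep2_survivors = proteome$provenance$rep2_survivors,
                       final = nrow(proteome$entries)),
         params = list(min_unique = min_unique, normalize = normalize,
                       fpi_filter1 = fpi_filter1, fpi_filter2 = fpi_filter2,
                       bait = bait, channel_roles = channel_roles),
         ratios = ratios),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' Write all pipeline result files to a directory
#'
#' Materialises the proteome table, the four FPI curves, cutoff provenance,
#' a human-readable summary and a JSON manifest (parameters, counts,
#' package version). Tables are bit-stable for a fixed result.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_proteome_table(result$proteome, file.path(out_dir, "proximal_proteome.tsv"))
  for (k in names(result$curves)) {
    utils::write.table(result$curves[[k]]$points,
                       file.path(out_dir, paste0("fpi_curve_", k, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cuts <- do.call(rbind, lapply(result$cutoffs, function(co) {
    data.frame(axis = co$axis, replicate = co$replicate,
               fp_list = co$fp_list_name, target_fpi = co$target_fpi,
               cutoff = co$cutoff, achieved_fpi = co$achieved_fpi,
               n_fp_above = co$n_fp_above, stringsAsFactors = FALSE)
  }))
  utils::write.table(cuts, file.path(out_dir, "cutoffs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summary_lines <- c(
    sprintf("proteins in input table: %d", result$counts$input),
    sprintf("proteins with > %s unique peptides: %d",
            result$params$min_unique, result$counts$peptide_filtered),
    sprintf("replicate correlation (vs spatial control): R^2 = %.4f, slope = %.4f, n = %d",
            result$correlation$r_squared, result$correlation$slope,
            result$correlation$n),
    sprintf("replicate 1 survivors (both filters): %d", result$counts$rep1_survivors),
    sprintf("replicate 2 survivors (both filters): %d", result$counts$rep2_survivors),
    sprintf("final proximal proteome: %d", result$counts$final),
    sprintf("fold reduction (peptide-filtered -> final): %.1f",
            result$fold_reduction))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  manifest <- list(package = "proxfpi",
                   version = as.character(utils::packageVersion("proxfpi")),
                   params = result$params,
                   counts = result$counts,
                   fold_reduction = result$fold_reduction,
                   r_squared = result$correlation$r_squared)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("proxfpi pipeline result\n")
  cat(sprintf("  input proteins:        %d\n", x$counts$input))
  cat(sprintf("  peptide-filtered:      %d\n", x$counts$peptide_filtered))
  cat(sprintf("  replicate R-squared:   %.3f\n", x$correlation$r_squared))
  for (k in names(x$cutoffs)) {
    co <- x$cutoffs[[k]]
    cat(sprintf("  cutoff %-24s %.3f (achieved FPI %.4f, target %.2f)\n",
                paste0(k, ":"), co$cutoff, co$achieved_fpi, co$target_fpi))
  }
  cat(sprintf("  final proteome:        %d proteins (%.1f-fold reduction)\n",
              x$counts$final, x$fold_reduction))
  invisible(x)
}

#' Score a filtered proteome against simulated ground truth
#'
#' Recall is the fraction of simulated true-proximal proteins recovered in
#' the final list; precision the fraction of non-bait entries that are true
#' proximal. The bait counts toward neither.
#'
#' @param proteome A `proximal_proteome`.
#' @param truth Truth data.frame from [simulate_experiment()] (`accession`,
#'   `class`).
#' @return List with `recall`, `precision`, `bait_rank` (NA when the bait
#'   is absent), `n_true_proximal`, `n_called`.
#' @export
evaluate_recovery <- function(proteome, truth) {
  entries <- proteome$entries
  tp_all <- truth$accession[truth$class == "true_proximal"]
  called <- entries$accession[!entries$is_bait]
  hits <- intersect(called, tp_all)
  bait_rank <- if (any(entries$is_bait)) entries$rank[entries$is_bait] else NA_integer_
  list(recall = if (length(tp_all)) length(hits) / length(tp_all) else NA_real_,
       precision = if (length(called)) length(hits) / length(called) else NA_real_,
       bait_rank = bait_rank,
       n_true_proximal = length(tp_all),
       n_called = length(called))
}
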