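#' Empirical false-positive-identification curve
#'
#' The core calibration of the pipeline. For every distinct log2 ratio
#' observed among the false-positive-list proteins present in an enrichment
#' table, computes the FPI rate: the fraction of those proteins whose ratio
#' lies strictly above the candidate cutoff. Candidate cutoffs are
#' restricted to observed values — no interpolation — so the curve is a
#' step function that reaches exactly 0 at the largest observed ratio.
#'
#' @param ratios An `enrichment_table`.
#' @param fp_list A `compartment_list` of false-positive accessions; at
#'   least one must be present in `ratios`.
#' @return An `fpi_curve`: list with `fp_list_name`, `axis`, `replicate`,
#'   `points` (data.frame `cutoff`, `fpi`, sorted by cutoff ascending, fpi
#'   non-increasing) and `n_fp_observed`.
#' @export
fpi_curve <- function(ratios, fp_list) {
  stopifnot(inherits(ratios, "enrichment_table"),
            inherits(fp_list, "compartment_list"))
  x <- ratios$values[names(ratios$values) %in% fp_list$accessions]
  n <- length(x)
  if (n == 0) {
    stop("no protein of false-positive list '", fp_list$name,
         "' is present in the enrichment table (", ratios$axis, "/",
         ratios$replicate, ")", call. = FALSE)
  }
  x <- sort(unname(x))
  cutoffs <- unique(x)
  # strictly-above count at each distinct value: n minus the cumulative
  # count of values <= cutoff
  n_le <- cumsum(tabulate(match(x, cutoffs), nbins = length(cutoffs)))
  fpi <- (n - n_le) / n
  structure(list(fp_list_name = fp_list$name,
                 axis = ratios$axis,
                 replicate = ratios$replicate,
                 points = data.frame(cutoff = cutoffs, fpi = fpi),
                 n_fp_observed = n),
            class = "fpi_curve")
}

#' Log2-ratio cutoff at a target FPI rate
#'
#' Returns the smallest candidate cutoff whose FPI rate does not exceed the
#' target — equivalently, with `n` observed false-positive ratios and
#' `k = floor(target * n)` allowed exceedances, the `(n - k)`-th smallest
#' observed ratio, with ties collapsing toward fewer exceedances. The
#' guarantee `achieved_fpi <= target` holds for every input.
#'
#' @param curve An `fpi_curve`.
#' @param target Target FPI rate, strictly between 0 and 1 (e.g. 0.03 for
#'   the no-ligase filter, 0.05 for the spatial-control filter).
#' @return A `cutoff_result`: list with `cutoff`, `target_fpi`,
#'   `achieved_fpi`, `n_fp_above`, plus the curve's `axis`, `replicate` and
#'   `fp_list_name` for provenance.
#' @export
cutoff_at_fpi <- function(curve, target) {
  stopifnot(inherits(curve, "fpi_curve"))
  if (!is.numeric(target) || length(target) != 1 || target <= 0 || target >= 1) {
    stop("target FPI must be a single number in (0, 1)", call. = FALSE)
  }
  pts <- curve$points
  i <- which(pts$fpi <= target)[1]  # fpi is non-increasing, so this is minimal
  n_above <- as.integer(round(pts$fpi[i] * curve$n_fp_observed))
  structure(list(cutoff = pts$cutoff[i],
                 target_fpi = target,
                 achieved_fpi = pts$fpi[i],
                 n_fp_above = n_above,
                 axis = curve$axis,
                 replicate = curve$replicate,
                 fp_list_name = curve$fp_list_name),
            class = "cutoff_result")
}

#' Apply a cutoff to an enrichment table
#'
#' @param ratios An `enrichment_table`.
#' @param cutoff A `cutoff_result` derived on the same axis/replicate.
#' @return Character vector of accessions whose log2 ratio lies strictly
#'   above the cutoff.
#' @export
apply_filter <- function(ratios, cutoff) {
  stopifnot(inherits(ratios, "enrichment_table"),
            inherits(cutoff, "cutoff_result"))
  names(ratios$values)[ratios$values > cutoff$cutoff]
}

#' Intersect per-replicate dual-filter survivors into the proximal proteome
#'
#' A replicate's survivors are the intersection of its no-ligase-filter and
#' spatial-control-filter pass sets; the final proteome is the intersection
#' of the two replicates' survivors. Entries are ranked by mean enrichment —
#' the mean over the two replicates of the vs-spatial-control log2 ratio —
#' in descending order. The bait is kept in the list (its self-labeling
#' should top the ranking) but flagged, so category summaries can exclude
#' it.
#'
#' @param pass_sets Named list of four accession sets:
#'   `vs_no_ligase.rep1`, `vs_no_ligase.rep2`,
#'   `vs_spatial_control.rep1`, `vs_spatial_control.rep2`.
#' @param ratios Named list of the four matching `enrichment_table`s (as
#'   from [compute_enrichment()]).
#' @param bait Bait accession; a warning is raised if it is absent from the
#'   final list.
#' @param gene_symbols Optional named character vector accession -> symbol.
#' @param provenance Optional list (cutoffs, targets, configuration)
#'   recorded verbatim in the result.
#' @return A `proximal_proteome`: list with `entries` (ranked data.frame:
#'   `accession`, `gene_symbol`, the four log2 ratios, `mean_enrichment`,
#'   `rank`, `is_bait`, `tags`) and `provenance`.
#' @export
build_proteome <- function(pass_sets, ratios, bait,
                           gene_symbols = NULL, provenance = list()) {
  keys <- c("vs_no_ligase.rep1", "vs_no_ligase.rep2",
            "vs_spatial_control.rep1", "vs_spatial_control.rep2")
  missing_keys <- setdiff(keys, names(pass_sets))
  if (length(missing_keys) > 0) {
    stop("pass_sets is missing: ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(keys %in% names(ratios)))
  rep1 <- intersect(pass_sets[["vs_no_ligase.rep1"]],
                    pass_sets[["vs_spatial_control.rep1"]])
  rep2 <- intersect(pass_sets[["vs_no_ligase.rep2"]],
                    pass_sets[["vs_spatial_control.rep2"]])
  final <- intersect(rep1, rep2)
  if (!bait %in% final) {
    warning("bait '", bait, "' did not pass both filters in both replicates",
            call. = FALSE)
  }
  entries <- data.frame(
    accession = final,
    gene_symbol = if (is.null(gene_symbols)) final else
      unname(ifelse(is.na(gene_symbols[final]), final, gene_symbols[final])),
    log2_vs_no_ligase_rep1 = unname(ratios[["vs_no_ligase.rep1"]]$values[final]),
    log2_vs_no_ligase_rep2 = unname(ratios[["vs_no_ligase.rep2"]]$values[final]),
    log2_vs_spatial_control_rep1 = unname(ratios[["vs_spatial_control.rep1"]]$values[final]),
    log2_vs_spatial_control_rep2 = unname(ratios[["vs_spatial_control.rep2"]]$values[final]),
    stringsAsFactors = FALSE)
  entries$mean_enrichment <- (entries$log2_vs_spatial_control_rep1 +
                                entries$log2_vs_spatial_control_rep2) / 2
  ord <- order(-entries$mean_enrichment, entries$accession)
  entries <- entries[ord, , drop = FALSE]
  rownames(entries) <- NULL
  entries$rank <- seq_len(nrow(entries))
  entries$is_bait <- entries$accession == bait
  entries$tags <- rep("", nrow(entries))
  provenance$rep1_survivors <- length(rep1)
  provenance$rep2_survivors <- length(rep2)
  provenance$bait <- bait
  structure(list(entries = entries, provenance = provenance),
            class = "proximal_proteome")
}

#' Fold reduction of candidate-list size by filtering
#'
#' @param before Number of candidate proteins before filtering.
#' @param after Number after filtering.
#' @return `before / after`; `Inf` with a warning when `after` is zero.
#' @export
fold_reduction <- function(before, after) {
  stopifnot(before >= 0, after >= 0)
  if (after == 0) {
    warning("no proteins survived filtering; fold reduction is infinite",
            call. = FALSE)
    return(Inf)
  }
  before / after
}

#' @export
print.proximal_proteome <- function(x, ...) {
  cat("Proximal proteome:", nrow(x$entries), "proteins\n")
  if (nrow(x$entries) > 0) {
    top <- utils::head(x$entries[, c("accession", "gene_symbol",
                                     "mean_enrichment", "rank", "is_bait")], 10)
    print(top, row.names = FALSE)
  }
  invisible(x)
}
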