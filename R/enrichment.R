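#' Filter proteins by unique-peptide support
#'
#' Keeps proteins identified by strictly more than `min_unique` unique
#' peptides (the conventional ">2 unique peptides" identification filter is
#' the default). Row order is preserved.
#'
#' @param quant A `quant_table`.
#' @param min_unique Minimum count; survivors have `unique_peptides > min_unique`.
#' @return The filtered `quant_table`.
#' @export
filter_by_peptides <- function(quant, min_unique = 2) {
  stopifnot(min_unique >= 0)
  keep <- quant$unique_peptides > min_unique
  out <- quant[keep, , drop = FALSE]
  rownames(out) <- NULL
  as_quant_table(out, channels = quant_channels(quant),
                 channel_roles = attr(quant, "channel_roles"))
}

#' Equalize channel loading by median scaling
#'
#' Divides each channel's intensities by that channel's median positive
#' intensity and rescales by the median of the per-channel medians, so every
#' channel ends up with the same median positive intensity. Zeros stay zero.
#' The operation is idempotent.
#'
#' @param quant A `quant_table`; every channel must contain at least one
#'   positive intensity.
#' @return The normalized `quant_table`.
#' @export
normalize_channels <- function(quant) {
  channels <- quant_channels(quant)
  med <- vapply(channels, function(ch) {
    x <- quant[[ch]]
    pos <- x[x > 0]
    if (length(pos) == 0) {
      stop("channel ", ch, " has no positive intensity; cannot normalize",
           call. = FALSE)
    }
    stats::median(pos)
  }, numeric(1))
  grand <- stats::median(med)
  for (ch in channels) quant[[ch]] <- quant[[ch]] / med[[ch]] * grand
  quant
}

#' Per-protein log2 enrichment ratio between two channels
#'
#' Computes `log2(numerator / denominator)` per protein. Proteins with a
#' zero intensity in either channel have no defined ratio; they are dropped
#' (never imputed) and counted in `n_dropped`.
#'
#' @param quant A `quant_table`.
#' @param numerator,denominator Channel column labels.
#' @param axis Label recording what the ratio contrasts
#'   (`"vs_no_ligase"` or `"vs_spatial_control"`).
#' @param replicate Label for the bait replicate (`"rep1"` or `"rep2"`).
#' @return An `enrichment_table`: list with `axis`, `replicate`, `values`
#'   (named numeric vector of finite log2 ratios, one per retained
#'   accession) and `n_dropped`.
#' @export
log2_ratio <- function(quant, numerator, denominator,
                       axis = "ratio", replicate = "rep1") {
  channels <- quant_channels(quant)
  for (ch in c(numerator, denominator)) {
    if (!ch %in% channels) {
      stop("unknown channel '", ch, "'; table has: ",
           paste(channels, collapse = ", "), call. = FALSE)
    }
  }
  num <- quant[[numerator]]
  den <- quant[[denominator]]
  ok <- num > 0 & den > 0
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(n_dropped, " protein(s) dropped from ", axis, "/", replicate,
            ": zero intensity in ", numerator, " or ", denominator)
  }
  values <- log2(num[ok] / den[ok])
  names(values) <- quant$accession[ok]
  structure(list(axis = axis, replicate = replicate, values = values,
                 n_dropped = n_dropped),
            class = "enrichment_table")
}

#' Compute the four standard enrichment tables of the 4-plex design
#'
#' For each bait replicate, computes log2 ratios against the no-ligase
#' control (`vs_no_ligase`) and against the nuclear spatial control
#' (`vs_spatial_control`), using the table's channel-role mapping.
#'
#' @param quant A `quant_table` whose `channel_roles` attribute maps all
#'   four roles.
#' @return Named list of four `enrichment_table`s:
#'   `vs_no_ligase.rep1`, `vs_no_ligase.rep2`,
#'   `vs_spatial_control.rep1`, `vs_spatial_control.rep2`.
#' @export
compute_enrichment <- function(quant) {
  roles <- attr(quant, "channel_roles")
  if (is.null(roles)) {
    stop("quant table carries no channel_roles; read it with read_quant_table()",
         call. = FALSE)
  }
  validate_channel_roles(roles)
  list(
    vs_no_ligase.rep1 = log2_ratio(quant, roles[["bait_rep1"]],
                                   roles[["no_ligase"]],
                                   "vs_no_ligase", "rep1"),
    vs_no_ligase.rep2 = log2_ratio(quant, roles[["bait_rep2"]],
                                   roles[["no_ligase"]],
                                   "vs_no_ligase", "rep2"),
    vs_spatial_control.rep1 = log2_ratio(quant, roles[["bait_rep1"]],
                                         roles[["spatial_control"]],
                                         "vs_spatial_control", "rep1"),
    vs_spatial_control.rep2 = log2_ratio(quant, roles[["bait_rep2"]],
                                         roles[["spatial_control"]],
                                         "vs_spatial_control", "rep2"))
}

#' Between-replicate linear correlation of enrichment values
#'
#' Ordinary least-squares fit of replicate `b` on replicate `a` over their
#' shared accessions; the replicate-agreement QC used before filtering.
#' `r_squared` is the squared Pearson correlation, so it is symmetric in
#' the two arguments.
#'
#' @param a,b Two `enrichment_table`s on the same axis.
#' @return A `correlation_report`: list with `r_squared`, `slope`,
#'   `intercept`, `n` (shared proteins).
#' @export
replicate_correlation <- function(a, b) {
  stopifnot(inherits(a, "enrichment_table"), inherits(b, "enrichment_table"))
  if (!identical(a$axis, b$axis)) {
    stop("enrichment tables are on different axes: ", a$axis, " vs ", b$axis,
         call. = FALSE)
  }
  shared <- intersect(names(a$values), names(b$values))
  if (length(shared) < 2) {
    stop("need at least 2 shared proteins to correlate; found ",
         length(shared), call. = FALSE)
  }
  x <- a$values[shared]
  y <- b$values[shared]
  if (stats::var(x) == 0) {
    stop("zero variance in first replicate; correlation undefined",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  structure(list(r_squared = stats::cor(x, y)^2,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n = length(shared)),
            class = "correlation_report")
}
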