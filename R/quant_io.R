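#' Default TMT channel role assignment
#'
#' Maps the four roles of the 4-plex design to reporter-channel labels:
#' the no-ligase control (`134N`), the nuclear spatial control (`133C`),
#' and the two independent bait replicates (`133N`, `126C`). Channel labels
#' are opaque strings; any plex works as long as the four roles are mapped
#' to columns that exist in the quantification table.
#'
#' @return Named character vector with names `no_ligase`, `spatial_control`,
#'   `bait_rep1`, `bait_rep2`.
#' @export
default_channel_roles <- function() {
  c(no_ligase = "134N",
    spatial_control = "133C",
    bait_rep1 = "133N",
    bait_rep2 = "126C")
}

.required_roles <- c("no_ligase", "spatial_control", "bait_rep1", "bait_rep2")

#' Read a protein-level TMT quantification table
#'
#' Reads a delimited text export with one row per protein: an accession, a
#' gene symbol, a unique-peptide count, and one reporter-intensity column per
#' TMT channel. Column names are configurable because supplementary-table
#' schemas vary between labs.
#'
#' @param path Path to a delimited text file with a header row.
#' @param channel_roles Named character vector mapping the four roles
#'   (`no_ligase`, `spatial_control`, `bait_rep1`, `bait_rep2`) to channel
#'   column labels. Defaults to [default_channel_roles()].
#' @param sep Field separator; tab by default, use `","` for CSV exports.
#' @param accession_col,gene_col,peptides_col Names of the identifier columns.
#' @return A `quant_table`: a data.frame with columns `accession`,
#'   `gene_symbol`, `unique_peptides` and one numeric column per channel,
#'   carrying attributes `channels` (channel labels) and `channel_roles`.
#' @export
read_quant_table <- function(path,
                             channel_roles = default_channel_roles(),
                             sep = "\t",
                             accession_col = "accession",
                             gene_col = "gene_symbol",
                             peptides_col = "unique_peptides") {
  if (!file.exists(path)) {
    stop("quant table not found: ", path, call. = FALSE)
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", stringsAsFactors = FALSE)
  validate_channel_roles(channel_roles)
  for (col in c(accession_col, gene_col, peptides_col)) {
    if (!col %in% names(raw)) {
      stop("quant table is missing required column '", col, "'", call. = FALSE)
    }
  }
  channels <- unname(channel_roles)
  missing_ch <- setdiff(channels, names(raw))
  if (length(missing_ch) > 0) {
    stop("quant table is missing mapped channel column(s): ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }

  n <- nrow(raw)
  peptides <- suppressWarnings(as.numeric(raw[[peptides_col]]))
  bad <- which(is.na(peptides) | peptides < 0 | peptides != floor(peptides))
  if (length(bad) > 0) {
    stop("invalid unique-peptide count '", raw[[peptides_col]][bad[1]],
         "' at data row ", bad[1], call. = FALSE)
  }
  quant <- data.frame(accession = raw[[accession_col]],
                      gene_symbol = raw[[gene_col]],
                      unique_peptides = as.integer(peptides),
                      stringsAsFactors = FALSE)
  for (ch in channels) {
    x <- suppressWarnings(as.numeric(raw[[ch]]))
    bad <- which(is.na(x))
    if (length(bad) > 0) {
      stop("non-numeric intensity '", raw[[ch]][bad[1]], "' in channel ", ch,
           " at data row ", bad[1], call. = FALSE)
    }
    bad <- which(x < 0)
    if (length(bad) > 0) {
      stop("negative intensity in channel ", ch, " at data row ", bad[1],
           call. = FALSE)
    }
    quant[[ch]] <- x
  }
  dup <- quant$accession[duplicated(quant$accession)]
  if (length(dup) > 0) {
    stop("duplicate accession(s) in quant table: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  as_quant_table(quant, channels = channels, channel_roles = channel_roles)
}

validate_channel_roles <- function(channel_roles) {
  missing_roles <- setdiff(.required_roles, names(channel_roles))
  if (length(missing_roles) > 0) {
    stop("channel_roles must map roles: ",
         paste(missing_roles, collapse = ", "), call. = FALSE)
  }
  invisible(channel_roles)
}

#' Construct a quant_table from an in-memory data.frame
#'
#' @param df Data frame with `accession`, `gene_symbol`, `unique_peptides`
#'   and one numeric column per channel.
#' @param channels Character vector of channel column names.
#' @param channel_roles Named role -> channel map (optional but required by
#'   the enrichment stage).
#' @return A `quant_table` data.frame.
#' @export
as_quant_table <- function(df, channels, channel_roles = NULL) {
  stopifnot(all(c("accession", "gene_symbol", "unique_peptides") %in% names(df)),
            all(channels %in% names(df)))
  attr(df, "channels") <- channels
  attr(df, "channel_roles") <- channel_roles
  class(df) <- unique(c("quant_table", class(df)))
  df
}

#' Channel labels of a quant table
#' @param quant A `quant_table`.
#' @return Character vector of channel column names.
#' @export
quant_channels <- function(quant) attr(quant, "channels")

#' Write a quant table back to delimited text
#'
#' Inverse of [read_quant_table()]; used to materialise synthetic
#' experiments and round-trip fixtures.
#'
#' @param quant A `quant_table`.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_quant_table <- function(quant, path, sep = "\t") {
  cols <- c("accession", "gene_symbol", "unique_peptides", quant_channels(quant))
  utils::write.table(as.data.frame(quant)[, cols], path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a compartment false-positive protein list
#'
#' One accession per line, as exported from UniProt; blank lines and lines
#' starting with `#` are ignored. Duplicate accessions are collapsed with a
#' warning.
#'
#' @param path Path to the plain-text list.
#' @param name Label for the list (e.g. `"ER_membrane"`).
#' @return A `compartment_list`: list with elements `name` and `accessions`.
#' @export
read_compartment_list <- function(path, name) {
  if (!file.exists(path)) {
    stop("compartment list not found: ", path, call. = FALSE)
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    stop("compartment list '", name, "' is empty after parsing: ", path,
         call. = FALSE)
  }
  n_dup <- sum(duplicated(lines))
  if (n_dup > 0) {
    warning("compartment list '", name, "': collapsed ", n_dup,
            " duplicate accession(s)", call. = FALSE)
  }
  compartment_list(name, unique(lines))
}

#' Construct a compartment list in memory
#' @param name Label for the list.
#' @param accessions Character vector of protein accessions (deduplicated).
#' @return A `compartment_list` object.
#' @export
compartment_list <- function(name, accessions) {
  accessions <- unique(as.character(accessions))
  if (length(accessions) == 0) {
    stop("compartment list '", name, "' must be non-empty", call. = FALSE)
  }
  structure(list(name = name, accessions = accessions),
            class = "compartment_list")
}

#' Write a compartment list to plain text
#' @param x A `compartment_list`.
#' @param path Output path.
#' @export
write_compartment_list <- function(x, path) {
  writeLines(x$accessions, path)
  invisible(path)
}

#' Read an accession-to-GO-term-name map
#'
#' Two-column delimited text (accession, GO term name), multiple rows per
#' accession allowed. Term names are lower-cased so downstream keyword
#' matching is case-insensitive.
#'
#' @param path Path to the two-column file (no header).
#' @param sep Field separator.
#' @return A `go_map`: named list, accession -> character vector of
#'   lower-cased term names. Empty file gives an empty map.
#' @export
read_go_map <- function(path, sep = "\t") {
  if (!file.exists(path)) {
    stop("GO map not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(structure(list(), class = "go_map"))
  }
  parts <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad) > 0) {
    stop("malformed GO map row ", bad[1], ": expected 2 fields, got ",
         length(parts[[bad[1]]]), call. = FALSE)
  }
  acc <- vapply(parts, `[[`, character(1), 1L)
  term <- tolower(vapply(parts, `[[`, character(1), 2L))
  structure(split(term, factor(acc, levels = unique(acc))), class = "go_map")
}

#' Write the final proximal-proteome table
#'
#' Delimited text with one row per protein, ranked by mean enrichment:
#' accession, gene symbol, the four per-axis per-replicate log2 ratios, mean
#' enrichment, rank, bait flag, and semicolon-joined category tags. Output is
#' bit-stable for a fixed input.
#'
#' @param proteome A `proximal_proteome` (see [build_proteome()]).
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_proteome_table <- function(proteome, path, sep = "\t") {
  stopifnot(inherits(proteome, "proximal_proteome"))
  df <- proteome$entries
  df$is_bait <- ifelse(df$is_bait, "TRUE", "FALSE")
  utils::write.table(format_ratios(df), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# full-precision decimal rendering so write -> read is the identity
format_ratios <- function(df) {
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "rank"
  df[num] <- lapply(df[num], function(x) formatC(x, format = "g", digits = 17))
  df
}

#' Read a proximal-proteome table written by [write_proteome_table()]
#'
#' @param path Path to the table.
#' @param sep Field separator.
#' @return A `proximal_proteome` with empty provenance.
#' @export
read_proteome_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  num_cols <- setdiff(names(df), c("accession", "gene_symbol", "rank",
                                   "is_bait", "tags"))
  for (col in num_cols) df[[col]] <- as.numeric(df[[col]])
  df$rank <- as.integer(df$rank)
  df$is_bait <- df$is_bait == "TRUE"
  df$tags[is.na(df$tags)] <- ""
  structure(list(entries = df, provenance = list()),
            class = "proximal_proteome")
}
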