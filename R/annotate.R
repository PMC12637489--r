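#' Default GO-keyword category rules
#'
#' Reporting categories defined operationally as case-insensitive substring
#' matches on GO term names (not IDs, no ontology traversal):
#' phosphatase-related ("dephosphorylation"), protein quality control
#' ("proteasome", "ubiquitin", "protein folding"), nuclear import
#' ("import into nucleus"), mitochondria ("mitoch") and cell division
#' ("cell division", "mitotic").
#'
#' @return Named list of `category_rule`s.
#' @export
default_rules <- function() {
  list(
    phosphatase = category_rule("phosphatase", "dephosphorylation"),
    quality_control = category_rule("quality_control",
                                    c("proteasome", "ubiquitin",
                                      "protein folding")),
    nuclear_import = category_rule("nuclear_import", "import into nucleus"),
    mitochondria = category_rule("mitochondria", "mitoch"),
    cell_division = category_rule("cell_division",
                                  c("cell division", "mitotic")))
}

#' Construct a GO-keyword category rule
#'
#' @param category Category label.
#' @param substrings Non-empty character vector of keywords; a protein is
#'   tagged when any keyword is a substring of any of its GO term names.
#' @return A `category_rule`.
#' @export
category_rule <- function(category, substrings) {
  substrings <- tolower(as.character(substrings))
  if (length(substrings) == 0 || any(!nzchar(substrings))) {
    stop("category rule '", category, "' needs non-empty keywords",
         call. = FALSE)
  }
  structure(list(category = category, substrings = substrings),
            class = "category_rule")
}

#' Does a set of GO term names match a rule?
#' @param terms Character vector of term names (any case).
#' @param rule A `category_rule`.
#' @return Logical scalar.
#' @export
rule_matches <- function(terms, rule) {
  if (length(terms) == 0) return(FALSE)
  terms <- tolower(terms)
  any(vapply(rule$substrings,
             function(kw) any(grepl(kw, terms, fixed = TRUE)),
             logical(1)))
}

#' Tag proximal-proteome entries with GO-keyword categories
#'
#' Each entry's tags are the categories whose keywords match any of its GO
#' term names; multi-tagging is allowed, proteins missing from the map get
#' no tags. Tagging is idempotent and independent of entry or rule order.
#'
#' @param proteome A `proximal_proteome`.
#' @param go_map A `go_map` (accession -> lower-cased term names).
#' @param rules List of `category_rule`s; defaults to [default_rules()].
#' @return The proteome with `entries$tags` filled (semicolon-joined, in
#'   rule order).
#' @export
tag_proteome <- function(proteome, go_map, rules = default_rules()) {
  stopifnot(inherits(proteome, "proximal_proteome"))
  entries <- proteome$entries
  entries$tags <- vapply(entries$accession, function(acc) {
    terms <- go_map[[acc]]
    hits <- vapply(rules, function(r) rule_matches(terms, r), logical(1))
    paste(vapply(rules[hits], `[[`, character(1), "category"), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  proteome$entries <- entries
  proteome
}

#' Per-category protein counts in a proximal proteome
#'
#' @param proteome A tagged `proximal_proteome`.
#' @param exclude_bait Drop the bait from the counts (default), since its
#'   self-labeling is not informative about neighbor categories.
#' @return Named integer vector, one count per category present.
#' @export
category_counts <- function(proteome, exclude_bait = TRUE) {
  entries <- proteome$entries
  if (exclude_bait) entries <- entries[!entries$is_bait, , drop = FALSE]
  tags <- unlist(strsplit(entries$tags[nzchar(entries$tags)], ";", fixed = TRUE))
  if (length(tags) == 0) return(integer(0))
  table_to_int(table(tags))
}

table_to_int <- function(tb) {
  out <- as.integer(tb)
  names(out) <- names(tb)
  out
}
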