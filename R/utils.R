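#' Normalize protein identifiers
#'
#' Identifiers are treated as opaque keys: trimmed of surrounding whitespace
#' and upper-cased. The same normalization is applied everywhere (abundance
#' tables, reference lists, exclusion lists) so set operations never miss a
#' member through case differences. Idempotent.
#'
#' @param ids Character vector of protein identifiers (gene symbols or
#'   accessions).
#' @return Character vector of normalized identifiers.
#' @export
#' @examples
#' normalize_ids(c(" itga5", "Igsf8"))
normalize_ids <- function(ids) {
  toupper(trimws(as.character(ids)))
}

# Accept either a reference_list or a bare character vector of members.
as_members <- function(x) {
  if (inherits(x, "reference_list")) x$members else normalize_ids(x)
}

# Sniff the delimiter of a delimited text file: tab wins if present in the
# header line, otherwise comma.
detect_delim <- function(path) {
  first <- readr::read_lines(path, n_max = 1L)
  if (length(first) && grepl("\t", first)) "\t" else ","
}
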